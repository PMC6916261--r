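#' Allocate broad-wetland predictions to their contained papyrus patches
#'
#' Species modelled at the whole-wetland level (the broad-wetland users) get
#' their predictions re-expressed on the papyrus patch network: every papyrus
#' patch lying inside a broad wetland inherits that wetland's survival and
#' colonization probabilities and category, so that all species' networks are
#' directly comparable. Papyrus patches without a parent are unchanged.
#'
#' @param predictions a `persistence_result` for one broad-wetland species,
#'   indexed by broad-wetland (and possibly other) patch ids.
#' @param network the [patch_network()] carrying `parent_wetland_id` links.
#' @return `persistence_result` re-indexed on the harmonized patch universe:
#'   papyrus and shoreline patches, plus broad wetlands containing no papyrus
#'   patch (kept with a warning).
#' @export
allocate_broad_to_papyrus <- function(predictions, network) {
  p <- network$patches
  parent <- stats::setNames(p$parent_wetland_id, p$patch_id)
  broad_ids <- p$patch_id[p$patch_type == "broad_wetland"]
  has_parent <- !is.na(parent) & nzchar(parent)
  bad <- has_parent & !parent %in% broad_ids
  if (any(bad))
    stop_arg("parent_wetland_id does not name a broad_wetland patch: ",
             paste(unique(parent[bad]), collapse = ", "))

  pred_idx <- match(p$patch_id, predictions$patch_id)
  rows <- lapply(seq_len(nrow(p)), function(i) {
    id <- p$patch_id[i]
    src <- if (p$patch_type[i] != "broad_wetland" && has_parent[i])
      match(parent[id], predictions$patch_id) else pred_idx[i]
    if (is.na(src)) src <- pred_idx[i]  # parent already dissolved: keep own
    if (is.na(src)) return(NULL)
    r <- predictions[src, , drop = FALSE]
    r$patch_id <- id
    r
  })
  out <- do.call(rbind, rows)
  childless <- setdiff(broad_ids, parent[has_parent])
  keep_broad <- intersect(childless, out$patch_id)
  if (length(keep_broad))
    warning(length(keep_broad), " broad wetland(s) contain no papyrus patch; ",
            "retained as their own units", call. = FALSE)
  drop_broad <- setdiff(intersect(broad_ids, out$patch_id), keep_broad)
  out <- out[!out$patch_id %in% drop_broad, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(predictions)
  out
}

#' Force shoreline patches to marginal for species that do not use them
#'
#' Applied on the overlap layer only: shoreline fringing patches are not
#' habitat for some species, so their category there is `marginal` whatever
#' the models predict. Other patch types are never modified.
#'
#' @param predictions a `persistence_result`.
#' @param network the [patch_network()].
#' @param params the species' [species_params()].
#' @return the predictions with shoreline categories overridden when
#'   `params$uses_shoreline` is `FALSE`.
#' @export
mark_marginal_for_nonusers <- function(predictions, network, params) {
  if (params$uses_shoreline) return(predictions)
  p <- network$patches
  shore <- p$patch_id[p$patch_type == "shoreline"]
  idx <- predictions$patch_id %in% shore
  predictions$category[idx] <- "marginal"
  # shoreline patches absent from this species' map (not habitat, so never
  # modelled) enter the overlap layer as marginal with no probabilities
  add <- setdiff(shore, predictions$patch_id)
  if (length(add)) {
    extra <- predictions[rep(1L, length(add)), , drop = FALSE]
    extra$patch_id <- add
    for (col in intersect(c("S_prob", "C_prob", "P_no_rescue", "P_rescue"),
                          names(extra)))
      extra[[col]] <- NA_real_
    extra$category <- factor("marginal", levels = CATEGORIES)
    predictions <- rbind(predictions, extra)
    rownames(predictions) <- NULL
  }
  predictions
}

PANEL_SETS <- list(
  a = "resistant_and_resilient",
  b = "marginal",
  c = c("resistant_and_resilient", "resistant_only"),
  d = "resistant_only",
  e = c("resistant_and_resilient", "resilient_only"),
  f = "resilient_only")

#' Multi-species overlap counts
#'
#' Combines harmonized per-species classifications into per-patch counts:
#' for each category the number of species assigned that category, and the
#' derived map layers (a) both probabilities high, (b) both low (marginal),
#' (c) high resistance regardless of resilience, (d) high resistance and low
#' resilience, (e) high resilience regardless of resistance, (f) low
#' resistance and high resilience.
#'
#' @param classified named list of `persistence_result` objects (one per
#'   species), all covering the same harmonized patch set — i.e. after
#'   [allocate_broad_to_papyrus()] and [mark_marginal_for_nonusers()].
#' @return data.frame of class `overlap_map`: one row per patch with a count
#'   column per category and per panel letter; attribute `species_total`.
#' @export
overlap_counts <- function(classified) {
  if (!length(classified)) stop_arg("no species maps supplied")
  ids <- sort(unique(classified[[1]]$patch_id))
  for (m in classified) {
    if (!setequal(m$patch_id, ids))
      stop_arg("species maps do not cover the same harmonized patch set")
  }
  K <- length(classified)
  cat_mat <- vapply(classified, function(m)
    as.character(m$category[match(ids, m$patch_id)]), character(length(ids)))
  cat_mat <- matrix(cat_mat, nrow = length(ids))

  out <- data.frame(patch_id = ids, stringsAsFactors = FALSE)
  for (cc in CATEGORIES) out[[cc]] <- rowSums(cat_mat == cc)
  for (pn in names(PANEL_SETS))
    out[[paste0("panel_", pn)]] <- rowSums(
      matrix(cat_mat %in% PANEL_SETS[[pn]], nrow = length(ids)))
  attr(out, "species_total") <- K
  class(out) <- c("overlap_map", "data.frame")
  out
}

#' Harmonize, classify and overlap a set of per-species predictions
#'
#' Convenience wrapper running [allocate_broad_to_papyrus()] for
#' broad-wetland species, [mark_marginal_for_nonusers()] for every species,
#' then [overlap_counts()] over the common patch universe.
#'
#' @param predictions named list of `persistence_result` objects.
#' @param network the [patch_network()].
#' @param params_list named list of [species_params()] matching `predictions`.
#' @return an `overlap_map`.
#' @export
overlap_map <- function(predictions, network, params_list) {
  harm <- lapply(names(predictions), function(sp) {
    pr <- predictions[[sp]]
    if (params_list[[sp]]$uses_broad)
      pr <- allocate_broad_to_papyrus(pr, network)
    pr <- mark_marginal_for_nonusers(pr, network, params_list[[sp]])
    pr
  })
  names(harm) <- names(predictions)
  universe <- Reduce(intersect, lapply(harm, `[[`, "patch_id"))
  harm <- lapply(harm, function(m) m[m$patch_id %in% universe, , drop = FALSE])
  overlap_counts(harm)
}

#' @export
print.overlap_map <- function(x, ...) {
  cat("Overlap map:", nrow(x), "patches x", attr(x, "species_total"),
      "species\n")
  cat("Patches where every species is resistant and resilient:",
      sum(x$panel_a == attr(x, "species_total")), "\n")
  cat("Patches marginal for every species:",
      sum(x$panel_b == attr(x, "species_total")), "\n")
  invisible(x)
}
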