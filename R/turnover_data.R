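# ids of patches occupied by `species` in `year`
occupied_ids <- function(occupancy, species, year) {
  o <- occupancy[occupancy$species == species & occupancy$year == year, ]
  o$patch_id[o$present == 1]
}

#' Build colonization and survival model datasets from two-year occupancy
#'
#' Partitions the surveyed, suitable patches of a species by year-1 state:
#' patches where the species was absent in year 1 form the colonization
#' dataset (response 1 = colonized by year 2, 0 = stayed vacant); patches
#' where it was present form the survival dataset (1 = survived, 0 = local
#' extinction). Covariates are the year-2 local variables (area, circularity,
#' the disturbed/undisturbed/mixed vegetation proportions — the moderately
#' disturbed category is omitted because the four proportions sum to one) plus
#' the connectivity index computed from year-1 occupancy. Patches of a type
#' the species does not use, and patches unsurveyed in either year, are
#' excluded and reported.
#'
#' @param network a [patch_network()].
#' @param occupancy an [occupancy_table()] with two consecutive years.
#' @param species species name.
#' @param params a [species_params()] (supplies alpha, b and habitat use).
#' @param years the two survey years; default the two smallest in the table.
#' @param use_density weight connectivity sources by the species density
#'   column when present.
#' @return list of class `turnover_data`: data.frames `colonization` and
#'   `survival` (columns `patch_id`, `y`, covariates), `counts` (named vector
#'   colonized/survived/extinct/vacant), `excluded` (unsurveyed patch ids),
#'   `species`, `years`.
#' @export
build_turnover_datasets <- function(network, occupancy, species, params,
                                    years = NULL, use_density = TRUE) {
  if (!species %in% unique(occupancy$species))
    stop_arg("species not in occupancy table: ", species)
  yrs <- years %||% occ_years(occupancy)[1:2]
  if (length(yrs) != 2L || anyNA(yrs) || diff(yrs) != 1L)
    stop_arg("need two consecutive survey years")

  p <- network$patches
  suit <- suitable_ids(network, params)

  occ <- occupancy[occupancy$species == species & occupancy$year %in% yrs, ]
  w <- stats::reshape(as.data.frame(occ[, c("patch_id", "year", "present")]),
                      idvar = "patch_id", timevar = "year", direction = "wide")
  names(w) <- sub("^present\\.", "y", names(w))
  y1 <- paste0("y", yrs[1]); y2 <- paste0("y", yrs[2])
  for (col in c(y1, y2)) if (!col %in% names(w)) w[[col]] <- NA_real_

  w <- w[w$patch_id %in% suit, ]
  unsurveyed <- w$patch_id[is.na(w[[y1]]) | is.na(w[[y2]])]
  # patches suitable but entirely absent from the table are also unsurveyed
  unsurveyed <- union(unsurveyed, setdiff(suit, w$patch_id))
  if (length(unsurveyed))
    message(species, ": excluding ", length(unsurveyed),
            " patch(es) unsurveyed in one or both years")
  w <- w[!w$patch_id %in% unsurveyed, ]

  caps <- network_capacities(network, species, use_density)
  S <- connectivity_index(network, occupied_ids(occupancy, species, yrs[1]),
                          params, caps)

  covars <- p[match(w$patch_id, p$patch_id),
              c("area", "circularity", "veg_disturbed", "veg_undisturbed",
                "veg_mixed")]
  covars$connectivity <- as.numeric(S[w$patch_id])
  rownames(covars) <- NULL

  absent1 <- w[[y1]] == 0
  colonization <- data.frame(patch_id = w$patch_id[absent1],
                             y = w[[y2]][absent1], covars[absent1, ],
                             row.names = NULL)
  survival <- data.frame(patch_id = w$patch_id[!absent1],
                         y = w[[y2]][!absent1], covars[!absent1, ],
                         row.names = NULL)
  counts <- c(colonized = sum(colonization$y == 1),
              survived = sum(survival$y == 1),
              extinct = sum(survival$y == 0),
              vacant = sum(colonization$y == 0))
  structure(list(colonization = colonization, survival = survival,
                 counts = counts, excluded = unsurveyed,
                 species = species, years = yrs),
            class = "turnover_data")
}

#' @export
print.turnover_data <- function(x, ...) {
  cat("Turnover datasets for", x$species, "—", x$years[1], "to", x$years[2], "\n")
  cat(sprintf("  surveyed %d | colonized %d | survived %d | extinct %d | vacant %d\n",
              sum(x$counts), x$counts["colonized"], x$counts["survived"],
              x$counts["extinct"], x$counts["vacant"]))
  if (length(x$excluded)) cat("  excluded (unsurveyed):", length(x$excluded), "\n")
  invisible(x)
}
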