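RUN_CONFIG_KEYS <- c("patch_csv", "occupancy_csv", "simulate", "species",
                     "s_threshold", "c_threshold", "rescue", "seed",
                     "use_density", "quadratic_screen", "delta", "out_dir")
SPECIES_KEYS <- c("name", "alpha", "b", "uses_shoreline", "uses_broad",
                  "fit_alpha")

#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a YAML/JSON file path) with the keys:
#' `patch_csv` + `occupancy_csv` (input paths) or `simulate` (a
#' [synth_config()] argument list), `species` (list of per-species entries:
#' `name`, `alpha`, optional `b`, `uses_shoreline`, `uses_broad`, or
#' `fit_alpha: true` to estimate the decay rate from the data),
#' `s_threshold`, `c_threshold`, `rescue`, `seed`, `out_dir` and optional
#' fitting switches. Unknown keys are rejected before any stage runs.
#'
#' @param config named list or path to a YAML/JSON file.
#' @return the validated config list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) jsonlite::fromJSON(config, simplifyVector = FALSE)
              else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_arg("config must be a list or a file path")
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown)) stop_arg("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$species) || !length(config$species))
    stop_arg("config$species must list at least one species")
  for (sp in config$species) {
    unknown <- setdiff(names(sp), SPECIES_KEYS)
    if (length(unknown)) stop_arg("unknown species key(s): ", paste(unknown, collapse = ", "))
    if (is.null(sp$name)) stop_arg("every species entry needs a name")
    if (is.null(sp$alpha) && !isTRUE(sp$fit_alpha))
      stop_arg("species ", sp$name, ": supply alpha or set fit_alpha: true")
  }
  if (is.null(config$seed)) stop_arg("config$seed is required")
  has_files <- !is.null(config$patch_csv) && !is.null(config$occupancy_csv)
  if (!has_files && is.null(config$simulate))
    stop_arg("supply patch_csv + occupancy_csv, or a simulate block")
  config$s_threshold <- config$s_threshold %||% 0.5
  config$c_threshold <- config$c_threshold %||% 0.5
  config$rescue <- config$rescue %||% TRUE
  config$use_density <- config$use_density %||% TRUE
  config$quadratic_screen <- config$quadratic_screen %||% TRUE
  config$delta <- config$delta %||% 2
  config
}

#' Run the full resistance/resilience pipeline
#'
#' Stages, in dependency order: load (or simulate) the patch network and
#' two-year occupancy; per species, estimate or accept the dispersal decay
#' rate, build the colonization and survival datasets, fit and average the
#' turnover model sets, predict both probabilities for every suitable patch
#' and classify it; finally combine all species into the overlap map and
#' write the turnover summary and semivariogram diagnostics. Every stage
#' writes CSV outputs under `out_dir`, and a `manifest.json` records the
#' config hash and seed so that re-running with the same config reproduces
#' all numeric outputs.
#'
#' @param config run configuration (see [validate_run_config()]).
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return invisibly, a list with the network, per-species fits, persistence
#'   tables, overlap map, turnover summary and manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- validate_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop_arg("no out_dir given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    sc <- do.call(synth_config, c(config$simulate, list(seed = config$seed)))
    network <- generate_network(sc)
    truths <- lapply(config$species, function(sp)
      species_truth(sp$name, alpha = sp$alpha %||% 1, b = sp$b %||% 1,
                    uses_shoreline = isTRUE(sp$uses_shoreline),
                    uses_broad = isTRUE(sp$uses_broad)))
    occupancy <- simulate_occupancy(network, truths, sc)
    make_two_year_dataset(network, occupancy, out_dir)
  } else {
    network <- read_patch_table(config$patch_csv)
    occupancy <- occupancy_table(utils::read.csv(config$occupancy_csv,
                                                 stringsAsFactors = FALSE))
  }

  fits <- list(); preds <- list(); params_list <- list(); datasets <- list()
  for (sp in config$species) {
    nm <- sp$name
    message("[", nm, "] building datasets and fitting models")
    params <- species_params(nm, alpha = sp$alpha %||% 0, b = sp$b %||% 1,
                             uses_shoreline = isTRUE(sp$uses_shoreline),
                             uses_broad = isTRUE(sp$uses_broad))
    if (isTRUE(sp$fit_alpha)) {
      af <- fit_alpha(network, occupancy, nm, params,
                      use_density = config$use_density)
      params$alpha <- af$alpha
      utils::write.csv(af$profile,
                       file.path(out_dir, paste0("alpha_profile_", safe_name(nm), ".csv")),
                       row.names = FALSE)
    }
    td <- build_turnover_datasets(network, occupancy, nm, params,
                                  use_density = config$use_density)
    fit_c <- fit_turnover(td$colonization, process = "colonization",
                          quadratic_screen = config$quadratic_screen,
                          delta = config$delta)
    fit_s <- fit_turnover(td$survival, process = "survival",
                          quadratic_screen = config$quadratic_screen,
                          delta = config$delta)

    suit <- suitable_ids(network, params)
    newdata <- network$patches[match(suit, network$patches$patch_id), ]
    newdata$connectivity <- as.numeric(
      connectivity_index(network, occupied_ids(occupancy, nm, td$years[1]),
                         params, network_capacities(network, nm, config$use_density))[suit])
    base_col <- function(t) { b <- quad_base(t); if (is.na(b)) t else b }
    ok <- stats::complete.cases(newdata[unique(c("area",
            vapply(fit_c$average$term[-1], base_col, ""),
            vapply(fit_s$average$term[-1], base_col, "")))])
    newdata <- newdata[ok, , drop = FALSE]
    C_prob <- predict(fit_c, newdata)
    S_prob <- predict(fit_s, newdata)
    pt <- persistence_table(newdata$patch_id, S_prob, C_prob, nm,
                            config$s_threshold, config$c_threshold)

    base <- safe_name(nm)
    utils::write.csv(fit_c$ranking, file.path(out_dir, paste0("ranking_colonization_", base, ".csv")), row.names = FALSE)
    utils::write.csv(fit_s$ranking, file.path(out_dir, paste0("ranking_survival_", base, ".csv")), row.names = FALSE)
    utils::write.csv(fit_c$average, file.path(out_dir, paste0("avg_colonization_", base, ".csv")), row.names = FALSE)
    utils::write.csv(fit_s$average, file.path(out_dir, paste0("avg_survival_", base, ".csv")), row.names = FALSE)
    utils::write.csv(as.data.frame(pt), file.path(out_dir, paste0("classification_", base, ".csv")), row.names = FALSE)

    fits[[nm]] <- list(colonization = fit_c, survival = fit_s)
    preds[[nm]] <- pt
    params_list[[nm]] <- params
    datasets[[nm]] <- td

    res <- td$colonization
    resid <- res$y - predict(fit_c, res)
    xy <- network$patches[match(res$patch_id, network$patches$patch_id), c("x", "y")]
    sv <- empirical_semivariogram(resid, xy)
    utils::write.csv(as.data.frame(sv), file.path(out_dir, paste0("semivariogram_colonization_", base, ".csv")), row.names = FALSE)
  }

  ov <- overlap_map(preds, network, params_list)
  utils::write.csv(as.data.frame(ov), file.path(out_dir, "overlap.csv"), row.names = FALSE)
  ts <- turnover_summary(datasets)
  utils::write.csv(ts, file.path(out_dir, "turnover_summary.csv"), row.names = FALSE)

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   n_patches = nrow(network$patches),
                   species = vapply(config$species, `[[`, "", "name"),
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("patchres")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(network = network, occupancy = occupancy, fits = fits,
                 persistence = preds, overlap = ov, turnover_summary = ts,
                 manifest = manifest))
}

safe_name <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

# md5 of the canonical JSON serialisation of the scientific config
# (out_dir is location, not science: two runs into different directories
# from one config must hash identically)
config_hash <- function(config) {
  config$out_dir <- NULL
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config[order(names(config))], tf, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tf))
}
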