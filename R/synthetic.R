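#' Configuration for the synthetic patch-network generator
#'
#' Defaults emulate the structure of a fragmented papyrus-swamp network
#' surveyed over two consecutive years: a few hundred patches scattered over
#' a ~10-km lake basin, strongly right-skewed (lognormal) patch areas on the
#' hectare scale, compact-to-elongate shapes (Beta-distributed circularity),
#' vegetation composition on the 4-category simplex (Dirichlet), and a
#' minority of shoreline-fringing and broad-wetland patches, the latter
#' containing papyrus patches.
#'
#' @param n_patches number of patches (>= 2).
#' @param extent_km side of the square study extent, km. Coordinates are
#'   stored in metres; the distance matrix is built in km, so dispersal decay
#'   rates are per km.
#' @param area_meanlog,area_sdlog lognormal parameters of patch area (ha).
#' @param circ_shape1,circ_shape2 Beta parameters of circularity.
#' @param veg_concentration Dirichlet concentration over the four vegetation
#'   categories (disturbed, moderate, undisturbed, mixed).
#' @param frac_shoreline,frac_broad fractions of shoreline / broad-wetland
#'   patches.
#' @param children_max maximum papyrus patches adopted by a broad wetland.
#' @param n_years number of simulated survey years.
#' @param init_occupancy initial occupancy probability.
#' @param rescue allow same-year rescue in the occupancy simulation.
#' @param seed mandatory RNG seed; every stochastic call derives from it.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_patches = 500, extent_km = 10,
                         area_meanlog = log(1.5), area_sdlog = 1,
                         circ_shape1 = 5, circ_shape2 = 2,
                         veg_concentration = c(2, 2, 2, 2),
                         frac_shoreline = 0.3, frac_broad = 0.1,
                         children_max = 3,
                         n_years = 2, init_occupancy = 0.35,
                         rescue = TRUE, seed) {
  if (missing(seed)) stop_arg("seed is mandatory")
  if (n_patches < 2) stop_arg("n_patches must be >= 2")
  if (extent_km <= 0) stop_arg("degenerate extent")
  if (any(veg_concentration <= 0)) stop_arg("Dirichlet concentrations must be > 0")
  structure(as.list(environment()), class = "synth_config")
}

#' Ground-truth parameters for a simulated species
#'
#' Coefficients are on the logit scale over the raw covariates; names must
#' match patch covariate columns (`area`, `circularity`, `veg_disturbed`,
#' `veg_undisturbed`, `veg_mixed`, `connectivity`) plus `"(Intercept)"`.
#' The defaults put colonization under area and connectivity control and
#' survival under area and mixed-vegetation control, with intercepts chosen
#' so that a 500-patch network yields tens of colonization and extinction
#' events per year — the event regime of a real two-year passerine survey.
#'
#' @param species species name.
#' @param alpha true dispersal-kernel decay rate (per km here).
#' @param b emigration scaling exponent.
#' @param beta_col named colonization coefficients.
#' @param beta_surv named survival coefficients.
#' @param uses_shoreline,uses_broad habitat-use flags.
#' @return list of class `species_truth`.
#' @export
species_truth <- function(species = "sim_species", alpha = 1, b = 1,
                          beta_col = c(`(Intercept)` = -5, area = 0.25,
                                       connectivity = 0.1),
                          beta_surv = c(`(Intercept)` = 1.2, area = 0.3,
                                        veg_mixed = -4),
                          uses_shoreline = FALSE, uses_broad = FALSE) {
  structure(list(species = species,
                 params = species_params(species, alpha, b,
                                         uses_shoreline, uses_broad),
                 beta_col = beta_col, beta_surv = beta_surv),
            class = "species_truth")
}

# n draws from Dirichlet(conc)
rdirichlet <- function(n, conc) {
  g <- matrix(stats::rgamma(n * length(conc), shape = conc), n, byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic patch network
#'
#' Patch centres uniform over the extent; lognormal areas; perimeters set so
#' that circularity is Beta-distributed; Dirichlet vegetation proportions;
#' patch types assigned at the configured fractions, with each broad wetland
#' adopting up to `children_max` nearest papyrus patches as contained
#' children. Byte-identical for a fixed seed.
#'
#' @param config a [synth_config()].
#' @return a [patch_network()] with distances in km.
#' @export
generate_network <- function(config) {
  set.seed(config$seed)
  n <- config$n_patches
  x <- stats::runif(n, 0, config$extent_km * 1000)
  y <- stats::runif(n, 0, config$extent_km * 1000)
  area <- stats::rlnorm(n, config$area_meanlog, config$area_sdlog)
  circ <- stats::rbeta(n, config$circ_shape1, config$circ_shape2)
  perimeter <- sqrt(4 * pi * area * 1e4 / circ)
  veg <- rdirichlet(n, config$veg_concentration)

  n_shore <- round(config$frac_shoreline * n)
  n_broad <- round(config$frac_broad * n)
  type <- rep("papyrus", n)
  idx <- sample.int(n)                       # random type assignment
  type[idx[seq_len(n_shore)]] <- "shoreline"
  type[idx[n_shore + seq_len(n_broad)]] <- "broad_wetland"

  id <- sprintf("P%03d", seq_len(n))
  parent <- rep(NA_character_, n)
  pap <- which(type == "papyrus")
  free <- rep(TRUE, n)
  for (bw in which(type == "broad_wetland")) {
    cand <- pap[free[pap]]
    if (!length(cand)) break
    d <- sqrt((x[cand] - x[bw])^2 + (y[cand] - y[bw])^2)
    take <- cand[order(d)][seq_len(min(config$children_max, length(cand)))]
    parent[take] <- id[bw]
    free[take] <- FALSE
  }

  patches <- data.frame(
    patch_id = id, patch_type = type, x = x, y = y,
    area = area, perimeter = perimeter,
    veg_disturbed = veg[, 1], veg_moderate = veg[, 2],
    veg_undisturbed = veg[, 3], veg_mixed = veg[, 4],
    parent_wetland_id = parent, stringsAsFactors = FALSE)
  d <- edge_distances(cbind(x, y) / 1000, ids = id, unit = "km")
  patch_network(patches, dist = d)
}

# linear predictor from named truth coefficients over patch covariates + S
truth_linpred <- function(patches, beta, S) {
  eta <- rep(unname(beta["(Intercept)"]), nrow(patches))
  for (tm in setdiff(names(beta), "(Intercept)")) {
    v <- if (tm == "connectivity") S else patches[[tm]]
    eta <- eta + beta[tm] * v
  }
  eta
}

#' Simulate multi-year occupancy with known dynamics
#'
#' Year-to-year transitions follow the generating model the turnover
#' estimator targets: occupied patches survive with probability
#' inverse-logit of the survival linear predictor; empty patches are
#' colonized with probability inverse-logit of the colonization predictor,
#' whose covariates include the connectivity index computed from the current
#' year's occupancy. In rescue mode a patch that just went extinct is
#' re-colonized the same year with its colonization probability.
#'
#' @param network a [patch_network()].
#' @param truth a [species_truth()] (or list of them for several species).
#' @param config the [synth_config()] (supplies n_years, initial occupancy,
#'   rescue flag and seed).
#' @return an [occupancy_table()] with years `2014, 2015, ...`.
#' @export
simulate_occupancy <- function(network, truth, config) {
  if (inherits(truth, "species_truth")) truth <- list(truth)
  if (config$init_occupancy < 0 || config$init_occupancy > 1)
    stop_arg("invalid initial occupancy probability")
  set.seed(config$seed + 1L)
  years <- 2014L + seq_len(config$n_years) - 1L
  out <- list()
  for (tr in truth) {
    ids <- suitable_ids(network, tr$params)
    sub <- network$patches[match(ids, network$patches$patch_id), ]
    caps <- network_capacities(network, tr$species)
    occ <- as.numeric(stats::runif(length(ids)) < config$init_occupancy)
    names(occ) <- ids
    rows <- data.frame(patch_id = ids, species = tr$species,
                       year = years[1], present = occ)
    for (t in seq_len(config$n_years - 1L)) {
      S <- connectivity_index(network, names(occ)[occ == 1], tr$params, caps)[ids]
      p_surv <- inv_logit(truth_linpred(sub, tr$beta_surv, S))
      p_col <- inv_logit(truth_linpred(sub, tr$beta_col, S))
      new_occ <- occ
      was_occ <- occ == 1
      survived <- stats::runif(length(ids)) < p_surv
      new_occ[was_occ] <- as.numeric(survived[was_occ])
      if (config$rescue) {
        fresh_ext <- was_occ & new_occ == 0
        rescued <- stats::runif(length(ids)) < p_col
        new_occ[fresh_ext & rescued] <- 1
      }
      colonized <- stats::runif(length(ids)) < p_col
      new_occ[!was_occ] <- as.numeric(colonized[!was_occ])
      occ <- new_occ
      rows <- rbind(rows, data.frame(patch_id = ids, species = tr$species,
                                     year = years[t + 1L], present = occ))
    }
    out[[tr$species]] <- rows
  }
  occupancy_table(do.call(rbind, out))
}

#' Write a simulated two-year dataset in the loader's file dialects
#'
#' @param network a [patch_network()].
#' @param occupancy a simulated [occupancy_table()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths (`patches`,
#'   `occupancy`).
#' @export
make_two_year_dataset <- function(network, occupancy, dir) {
  if (length(occ_years(occupancy)) < 2L) stop_arg("need at least two years")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, "patches.csv")
  op <- file.path(dir, "occupancy.csv")
  write_patch_csv(network, pp)
  write_occupancy_csv(occupancy, op)
  c(patches = pp, occupancy = op)
}
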