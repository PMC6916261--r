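# Hand-built fixtures shared across the suite. Coordinates are in metres and
# deliberately outside the lat/long range so the projected-CRS guard passes.

tiny_patches <- function() {
  data.frame(
    patch_id = c("A", "B", "C", "D", "E", "F"),
    patch_type = c("papyrus", "papyrus", "papyrus", "shoreline",
                   "broad_wetland", "broad_wetland"),
    x = c(1000, 1300, 2000, 2500, 1100, 3000),
    y = c(1000, 1400, 1000, 1800, 1050, 3000),
    area = c(2, 1.5, 4, 0.5, 10, 8),
    perimeter = c(600, 500, 800, 300, 1300, 1200),
    veg_disturbed = c(0.1, 0.2, 0.25, 0.4, 0.1, 0.2),
    veg_moderate = c(0.3, 0.3, 0.25, 0.2, 0.4, 0.3),
    veg_undisturbed = c(0.4, 0.3, 0.25, 0.2, 0.3, 0.3),
    veg_mixed = c(0.2, 0.2, 0.25, 0.2, 0.2, 0.2),
    parent_wetland_id = c("E", "E", NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

tiny_network <- function() patch_network(tiny_patches())

# long-format occupancy for given wide year columns
make_occ <- function(ids, species, y1, y2, years = c(2014L, 2015L)) {
  occupancy_table(data.frame(
    patch_id = rep(ids, 2), species = species,
    year = rep(years, each = length(ids)), present = c(y1, y2)))
}

# 4 papyrus patches realising each transition exactly once
four_patch_fixture <- function() {
  p <- data.frame(
    patch_id = paste0("P", 1:4), patch_type = "papyrus",
    x = c(1000, 2000, 3000, 4000), y = rep(1000, 4),
    area = c(1, 2, 3, 4), perimeter = c(400, 560, 700, 800),
    veg_disturbed = 0.25, veg_moderate = 0.25, veg_undisturbed = 0.25,
    veg_mixed = 0.25, stringsAsFactors = FALSE)
  net <- patch_network(p)
  # P1 survives, P2 goes extinct, P3 is colonized, P4 stays vacant
  occ <- make_occ(p$patch_id, "sp", c(1, 1, 0, 0), c(1, 0, 1, 0))
  list(network = net, occupancy = occ,
       params = species_params("sp", alpha = 1))
}

# generating conditions of the alpha-recovery study
alpha_recovery_config <- function(seed = 11) {
  list(config = synth_config(n_patches = 400, extent_km = 50,
                             frac_shoreline = 0, frac_broad = 0,
                             rescue = FALSE, seed = seed),
       truth = species_truth("sim", alpha = 0.1,
                             beta_col = c(`(Intercept)` = -3.5, area = 0.25,
                                          connectivity = 0.05)))
}

# one simulated two-year dataset under the default study conditions
recovery_sim <- function(seed, n_patches = 1000) {
  cfg <- synth_config(n_patches = n_patches, rescue = FALSE, seed = seed)
  truth <- species_truth("sim")
  net <- generate_network(cfg)
  occ <- suppressMessages(simulate_occupancy(net, truth, cfg))
  td <- suppressMessages(build_turnover_datasets(net, occ, "sim", truth$params))
  list(network = net, occupancy = occ, datasets = td, truth = truth)
}
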