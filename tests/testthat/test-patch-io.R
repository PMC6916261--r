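test_that("circularity matches the isoperimetric identities and is scale invariant", {
  expect_equal(compute_circularity(pi, 2 * pi, area_unit = "m2"), 1)
  expect_equal(compute_circularity(1, 4, area_unit = "m2"), pi / 4)
  # hectare default: 1 ha circle has perimeter 2*pi*r with r = sqrt(1e4/pi)
  r <- sqrt(1e4 / pi)
  expect_equal(compute_circularity(1, 2 * pi * r), 1)
  # scaling a polygon by s scales area by s^2 and perimeter by s
  for (s in c(0.1, 3, 250)) {
    expect_equal(compute_circularity(1 * s^2, 4 * s, area_unit = "m2"),
                 compute_circularity(1, 4, area_unit = "m2"))
  }
  expect_error(compute_circularity(1, 0), "positive")
  expect_error(compute_circularity(-1, 4), "positive")
})

test_that("edge distances handle points and polygon boundaries", {
  d <- edge_distances(rbind(c(0, 0), c(3, 4)), ids = c("a", "b"))
  expect_equal(d["a", "b"], 5)
  expect_equal(diag(d), c(a = 0, b = 0))
  expect_equal(d, t(d))

  sq <- function(x0, y0) rbind(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1),
                               c(x0, y0 + 1))
  # disjoint unit squares with a 10 m gap between facing edges
  d <- edge_distances(list(sq(0, 0), sq(11, 0)))
  expect_equal(d[1, 2], 10)
  # diagonal offset: nearest corners at (1,1) and (3,3)
  d <- edge_distances(list(sq(0, 0), sq(3, 3)))
  expect_equal(d[1, 2], sqrt(8))
  # overlapping and touching polygons sit at distance 0
  expect_equal(edge_distances(list(sq(0, 0), sq(0.5, 0.5)))[1, 2], 0)
  expect_equal(edge_distances(list(sq(0, 0), sq(1, 0)))[1, 2], 0)
  # containment without boundary crossing
  big <- rbind(c(-5, -5), c(5, -5), c(5, 5), c(-5, 5))
  expect_equal(edge_distances(list(big, sq(0, 0)))[1, 2], 0)

  expect_error(edge_distances(rbind(c(0, 0))), "at least 2")
})

test_that("the patch network constructor enforces its invariants", {
  net <- tiny_network()
  expect_s3_class(net, "patch_network")
  expect_equal(nrow(net$patches), 6)
  expect_equal(net$patches$circularity,
               compute_circularity(net$patches$area, net$patches$perimeter))
  expect_true(all(abs(rowSums(net$patches[c("veg_disturbed", "veg_moderate",
                                            "veg_undisturbed", "veg_mixed")]) - 1) < 1e-9))

  p <- tiny_patches()
  p$veg_mixed[2] <- 0.1  # sums to 0.9
  expect_error(patch_network(p), "sum to 1.*B")

  p <- tiny_patches()
  p$patch_id[2] <- "A"
  expect_error(patch_network(p), "duplicate")

  p <- tiny_patches()
  p$parent_wetland_id[1] <- "C"  # a papyrus patch, not a broad wetland
  expect_error(patch_network(p), "broad_wetland")

  p <- tiny_patches()
  p$veg_moderate <- NULL
  expect_error(patch_network(p), "missing required column")

  # near-1 sums are renormalised silently
  p <- tiny_patches()
  p[1, VEG <- c("veg_disturbed", "veg_moderate", "veg_undisturbed", "veg_mixed")] <-
    c(0.1, 0.3, 0.4, 0.2) * 1.0005
  net <- patch_network(p)
  expect_equal(sum(net$patches[1, VEG]), 1)
})

test_that("missing perimeter leaves circularity missing with a warning", {
  p <- tiny_patches()
  p$perimeter[3] <- NA
  expect_warning(net <- patch_network(p), "circularity")
  expect_true(is.na(net$patches$circularity[3]))
  expect_false(anyNA(net$patches$circularity[-3]))
})

test_that("CSV loader round-trips, validates occupancy, and refuses lat/long", {
  net <- tiny_network()
  occ <- make_occ(rep(net$patches$patch_id, 2), rep(c("sp1", "sp2"), each = 6),
                  rep(c(1, 0, 1, 0, 1, 0), 2), rep(c(1, 1, 0, 0, 1, 1), 2))
  d <- withr::local_tempdir()
  paths <- make_two_year_dataset(net, occ, d)
  got <- read_patch_table(paths["patches"], occupancy = paths["occupancy"])
  expect_equal(got$network$patches[names(tiny_patches())], net$patches[names(tiny_patches())],
               tolerance = 1e-12)
  expect_equal(nrow(got$occupancy), 6 * 2 * 2)
  # writer round-trip is byte identical for the data columns
  p2 <- file.path(d, "again.csv")
  write_patch_csv(got$network, p2)
  expect_identical(readLines(paths["patches"]), readLines(p2))

  expect_error(occupancy_table(data.frame(patch_id = "A", species = "s",
                                          year = 2014, present = 2)), "0 or 1")
  geo <- tiny_patches()
  geo$x <- geo$x / 100; geo$y <- geo$y / 100  # degree-like magnitudes
  gp <- file.path(d, "geo.csv")
  utils::write.csv(geo, gp, row.names = FALSE)
  expect_error(read_patch_table(gp), "projected")
})

test_that("GeoJSON polygons load with boundary distances", {
  sq <- function(x0, y0, s = 200) list(list(
    list(x0, y0), list(x0 + s, y0), list(x0 + s, y0 + s), list(x0, y0 + s),
    list(x0, y0)))
  props <- tiny_patches()[3:4, ]  # C, D: no parent links
  feats <- lapply(1:2, function(i) list(
    type = "Feature",
    properties = as.list(props[i, setdiff(names(props), c("x", "y"))]),
    geometry = list(type = "Polygon", coordinates = sq(c(1000, 2000)[i], 1000))))
  gj <- list(type = "FeatureCollection", features = feats)
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  net <- read_patch_table(path)
  expect_equal(net$dist["C", "D"], 800)  # gap between 200 m squares at x=1200, 2000
})

test_that("turnover datasets partition surveyed patches and count each transition", {
  fx <- four_patch_fixture()
  td <- build_turnover_datasets(fx$network, fx$occupancy, "sp", fx$params)
  expect_equal(unname(td$counts), c(1, 1, 1, 1))
  expect_setequal(td$colonization$patch_id, c("P3", "P4"))
  expect_setequal(td$survival$patch_id, c("P1", "P2"))
  # partition: together they cover all surveyed patches exactly once
  expect_length(intersect(td$colonization$patch_id, td$survival$patch_id), 0)
  expect_equal(sum(td$counts), 4)

  expect_error(build_turnover_datasets(fx$network, fx$occupancy, "nope", fx$params),
               "species")
})

test_that("habitat-use flags and unsurveyed patches restrict the datasets", {
  net <- tiny_network()
  ids <- net$patches$patch_id
  occ <- make_occ(ids, "sp", c(1, 0, 1, 1, 1, 0), c(1, 1, 0, 1, 1, 0))
  # papyrus-only species: D (shoreline), E, F (broad) excluded
  td <- build_turnover_datasets(net, occ, "sp", species_params("sp", 1))
  expect_setequal(c(td$colonization$patch_id, td$survival$patch_id), c("A", "B", "C"))
  # broad-wetland user sees E and F too
  td2 <- build_turnover_datasets(net, occ, "sp",
                                 species_params("sp", 1, uses_broad = TRUE))
  expect_setequal(c(td2$colonization$patch_id, td2$survival$patch_id),
                  c("A", "B", "C", "E", "F"))
  # a patch missing year 2 is dropped and reported
  occ3 <- occ[!(occ$patch_id == "A" & occ$year == 2015), ]
  expect_message(
    td3 <- build_turnover_datasets(net, occupancy_table(occ3), "sp",
                                   species_params("sp", 1)),
    "unsurveyed")
  expect_equal(td3$excluded, "A")
  expect_equal(sum(td3$counts), 2)
})

test_that("a species absent everywhere yields an empty survival set", {
  net <- tiny_network()
  ids <- net$patches$patch_id
  occ <- make_occ(ids, "sp", rep(0, 6), rep(0, 6))
  td <- build_turnover_datasets(net, occ, "sp", species_params("sp", 1))
  expect_equal(nrow(td$survival), 0)
  expect_true(all(td$colonization$y == 0))
  expect_equal(unname(td$counts), c(0, 0, 0, 3))
})
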