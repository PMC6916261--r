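#' Patch shape circularity
#'
#' Shape index \code{4 * pi * area / perimeter^2}: 1 for a circle, approaching
#' 0 for long thin patches with a high edge-to-area ratio. The value is
#' scale-invariant and, for simple polygons, bounded above by 1 (the
#' isoperimetric inequality).
#'
#' @param area patch area; hectares by default (converted internally).
#' @param perimeter patch perimeter in metres.
#' @param area_unit `"ha"` (default) or `"m2"`.
#' @return numeric vector of circularity values in (0, 1] for simple shapes.
#' @examples
#' compute_circularity(pi, 2 * pi, area_unit = "m2") # circle of radius 1 -> 1
#' compute_circularity(1, 4, area_unit = "m2")       # unit square -> pi/4
#' @export
compute_circularity <- function(area, perimeter, area_unit = c("ha", "m2")) {
  area_unit <- match.arg(area_unit)
  if (any(!is.finite(area)) || any(!is.finite(perimeter)))
    stop_arg("area and perimeter must be finite")
  if (any(area <= 0)) stop_arg("area must be positive")
  if (any(perimeter <= 0)) stop_arg("perimeter must be positive")
  a_m2 <- if (area_unit == "ha") area * 1e4 else area
  4 * pi * a_m2 / perimeter^2
}

#' Pairwise nearest-edge distances
#'
#' Builds the symmetric distance matrix used by the connectivity index. Point
#' input gives Euclidean centre-to-centre distances; polygon input gives the
#' minimum boundary-to-boundary distance, with overlapping or touching
#' polygons at distance 0. All features must share one projected coordinate
#' system; the unit is recorded on the result and never rescaled silently.
#'
#' @param x either a two-column matrix/data.frame of point coordinates, or a
#'   list of polygons, each a two-column matrix of vertices (closed or open
#'   rings both accepted).
#' @param ids feature identifiers used as dimnames.
#' @param unit length unit of the coordinates, recorded as an attribute.
#' @return symmetric numeric matrix with zero diagonal and a `"unit"` attribute.
#' @export
edge_distances <- function(x, ids = NULL, unit = "m") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (nrow(x) < 2L) stop_arg("need at least 2 features")
    d <- as.matrix(stats::dist(x))
  } else if (is.list(x)) {
    n <- length(x)
    if (n < 2L) stop_arg("need at least 2 features")
    x <- lapply(x, function(p) {
      p <- as.matrix(p)
      if (ncol(p) != 2L || nrow(p) < 3L) stop_arg("polygons need >= 3 xy vertices")
      p
    })
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- polygon_distance(x[[i]], x[[j]])
  } else stop_arg("x must be a coordinate matrix or a list of polygons")
  dimnames(d) <- list(ids, ids)
  attr(d, "unit") <- unit
  d
}

# min distance between two polygons: 0 if boundaries cross or one contains the
# other, else the minimum over all boundary segment pairs
polygon_distance <- function(a, b) {
  sa <- close_ring(a); sb <- close_ring(b)
  if (point_in_polygon(sa[1, ], sb) || point_in_polygon(sb[1, ], sa)) return(0)
  dmin <- Inf
  for (i in seq_len(nrow(sa) - 1L)) {
    for (j in seq_len(nrow(sb) - 1L)) {
      d <- segment_distance(sa[i, ], sa[i + 1L, ], sb[j, ], sb[j + 1L, ])
      if (d < dmin) dmin <- d
      if (dmin == 0) return(0)
    }
  }
  dmin
}

close_ring <- function(p) {
  if (!all(p[1, ] == p[nrow(p), ])) p <- rbind(p, p[1, ])
  p
}

# even-odd ray casting
point_in_polygon <- function(pt, ring) {
  x <- pt[1]; y <- pt[2]
  xs <- ring[, 1]; ys <- ring[, 2]
  n <- length(xs) - 1L
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xs[i + 1L]; y2 <- ys[i + 1L]
    if ((y1 > y) != (y2 > y)) {
      xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
      if (x < xint) inside <- !inside
    }
  }
  inside
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((a + t * ab - p)^2))
}

segments_intersect <- function(p1, p2, q1, q2) {
  o <- function(a, b, c) sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2); o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  (o1 != o2 && o3 != o4)
}

segment_distance <- function(p1, p2, q1, q2) {
  if (segments_intersect(p1, p2, q1, q2)) return(0)
  min(point_segment_distance(p1, q1, q2), point_segment_distance(p2, q1, q2),
      point_segment_distance(q1, p1, p2), point_segment_distance(q2, p1, p2))
}

#' Construct and validate a habitat patch network
#'
#' Bundles the patch table with a nearest-edge distance matrix. Patch areas are
#' stored in hectares; coordinates and distances must be in one projected
#' system (unit recorded explicitly). Vegetation proportions must lie on the
#' unit simplex; proportions whose sum deviates from 1 by more than
#' `renorm_tol` raise an error naming the offending patch, smaller deviations
#' are renormalised.
#'
#' @param patches data.frame with columns `patch_id`, `patch_type` (one of
#'   `"papyrus"`, `"shoreline"`, `"broad_wetland"`), `x`, `y` (projected
#'   metres), `area` (ha), the four vegetation proportions `veg_disturbed`,
#'   `veg_moderate`, `veg_undisturbed`, `veg_mixed`, and optionally
#'   `perimeter` (m), `parent_wetland_id`, and per-species density columns
#'   named `density_<species>` (birds per ha).
#' @param dist optional precomputed distance matrix (from [edge_distances()]);
#'   when `NULL`, Euclidean point distances are computed from `x`, `y`.
#' @param dist_unit length unit of the distance matrix.
#' @param renorm_tol maximum tolerated deviation of vegetation sums from 1.
#' @return object of class `patch_network`: list with elements `patches`,
#'   `dist`, `dist_unit`.
#' @export
patch_network <- function(patches, dist = NULL, dist_unit = "m",
                          renorm_tol = 1e-3) {
  patches <- as.data.frame(patches, stringsAsFactors = FALSE)
  req <- c("patch_id", "patch_type", "x", "y", "area", VEG_COLS)
  miss <- setdiff(req, names(patches))
  if (length(miss)) stop_arg("missing required column(s): ", paste(miss, collapse = ", "))
  patches$patch_id <- as.character(patches$patch_id)
  if (anyDuplicated(patches$patch_id))
    stop_arg("duplicate patch_id: ",
             paste(unique(patches$patch_id[duplicated(patches$patch_id)]), collapse = ", "))
  bad <- !patches$patch_type %in% PATCH_TYPES
  if (any(bad)) stop_arg("unknown patch_type for patch ",
                         paste(patches$patch_id[bad], collapse = ", "))
  if (any(!is.finite(patches$area)) || any(patches$area <= 0))
    stop_arg("area must be positive and finite")

  v <- as.matrix(patches[VEG_COLS])
  if (any(!is.finite(v)) || any(v < -1e-9) || any(v > 1 + 1e-9))
    stop_arg("vegetation proportions must lie in [0, 1]")
  s <- rowSums(v)
  off <- abs(s - 1) > renorm_tol
  if (any(off))
    stop_arg("vegetation proportions do not sum to 1 for patch ",
             paste(patches$patch_id[off], collapse = ", "))
  patches[VEG_COLS] <- v / s

  if (!"perimeter" %in% names(patches)) patches$perimeter <- NA_real_
  has_p <- !is.na(patches$perimeter)
  if (any(has_p & patches$perimeter <= 0)) stop_arg("perimeter must be positive")
  patches$circularity <- NA_real_
  if (any(has_p))
    patches$circularity[has_p] <-
      compute_circularity(patches$area[has_p], patches$perimeter[has_p], "ha")
  if (any(!has_p))
    warning(sum(!has_p), " patch(es) without perimeter: circularity left missing",
            call. = FALSE)

  if (!"parent_wetland_id" %in% names(patches)) patches$parent_wetland_id <- NA_character_
  patches$parent_wetland_id <- as.character(patches$parent_wetland_id)
  pp <- !is.na(patches$parent_wetland_id) & nzchar(patches$parent_wetland_id)
  if (any(pp)) {
    broad <- patches$patch_id[patches$patch_type == "broad_wetland"]
    orphan <- !patches$parent_wetland_id[pp] %in% broad
    if (any(orphan))
      stop_arg("parent_wetland_id must name an existing broad_wetland patch; bad parent for ",
               paste(patches$patch_id[pp][orphan], collapse = ", "))
  }

  if (is.null(dist)) {
    dist <- edge_distances(as.matrix(patches[, c("x", "y")]),
                           ids = patches$patch_id, unit = dist_unit)
  } else {
    if (!is.null(attr(dist, "unit"))) dist_unit <- attr(dist, "unit")
    dist <- as.matrix(dist)
    if (!isTRUE(all.equal(dist, t(dist))) || any(diag(dist) != 0) || any(dist < 0))
      stop_arg("dist must be symmetric, nonnegative, with zero diagonal")
    if (nrow(dist) != nrow(patches)) stop_arg("dist dimension does not match patches")
    if (is.null(rownames(dist))) dimnames(dist) <- list(patches$patch_id, patches$patch_id)
    dist <- dist[patches$patch_id, patches$patch_id]
  }
  structure(list(patches = patches, dist = unname_attr(dist), dist_unit = dist_unit),
            class = "patch_network")
}

unname_attr <- function(d) { attr(d, "unit") <- NULL; d }

#' @export
print.patch_network <- function(x, ...) {
  tab <- table(factor(x$patches$patch_type, PATCH_TYPES))
  cat("Patch network:", nrow(x$patches), "patches (",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), ")\n")
  cat("Distances in", x$dist_unit,
      sprintf("| median inter-patch distance %.3g\n",
              stats::median(x$dist[upper.tri(x$dist)])))
  invisible(x)
}

#' Two-year occupancy table
#'
#' Long-format presence/absence records, one row per patch, species and survey
#' year. Values must be 0/1; a (patch, species) pair missing a year is treated
#' as unsurveyed for that species and excluded from turnover datasets.
#'
#' @param data data.frame with columns `patch_id`, `species`, `year`,
#'   `present`.
#' @return the validated data.frame with class `occupancy_table`.
#' @export
occupancy_table <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  req <- c("patch_id", "species", "year", "present")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop_arg("missing required column(s): ", paste(miss, collapse = ", "))
  if (!all(data$present %in% c(0, 1)))
    stop_arg("occupancy values must be 0 or 1")
  data$patch_id <- as.character(data$patch_id)
  data$species <- as.character(data$species)
  data$year <- as.integer(data$year)
  if (anyDuplicated(data[c("patch_id", "species", "year")]))
    stop_arg("duplicate (patch_id, species, year) records")
  rownames(data) <- NULL
  class(data) <- c("occupancy_table", "data.frame")
  data
}

occ_years <- function(occ) sort(unique(occ$year))

#' Read a patch table (CSV or GeoJSON) and optional occupancy table
#'
#' The CSV dialect is a plain UTF-8 comma-separated table with '.' decimal
#' separator and the columns documented in [patch_network()]. GeoJSON input
#' must carry the same fields as feature properties; Point geometry supplies
#' the coordinates directly, Polygon geometry supplies vertex rings from which
#' centroids and nearest-edge distances are derived. Geographic (longitude/
#' latitude) coordinates are refused: distances in degrees are meaningless for
#' a dispersal kernel.
#'
#' @param path file path.
#' @param format `"csv"` or `"geojson"` (default guessed from the extension).
#' @param occupancy optional path to a long-format occupancy CSV
#'   (`patch_id,species,year,present`).
#' @param dist_unit unit of the coordinate system, recorded on the network.
#' @return a `patch_network`; if `occupancy` is given, a list with elements
#'   `network` and `occupancy`.
#' @export
read_patch_table <- function(path, format = NULL, occupancy = NULL,
                             dist_unit = "m") {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  format <- format %||% if (grepl("\\.geo?json$", path, ignore.case = TRUE))
    "geojson" else "csv"
  if (format == "csv") {
    patches <- utils::read.csv(path, stringsAsFactors = FALSE)
    check_projected(patches$x, patches$y)
    net <- patch_network(patches, dist_unit = dist_unit)
  } else {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!identical(gj$type, "FeatureCollection")) stop_arg("not a GeoJSON FeatureCollection")
    feats <- gj$features
    props <- do.call(rbind, lapply(feats, function(f) {
      pr <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
      as.data.frame(pr, stringsAsFactors = FALSE)
    }))
    geoms <- lapply(feats, function(f) f$geometry)
    types <- vapply(geoms, function(g) g$type, "")
    if (all(types == "Point")) {
      xy <- t(vapply(geoms, function(g) unlist(g$coordinates)[1:2], numeric(2)))
      check_projected(xy[, 1], xy[, 2])
      props$x <- xy[, 1]; props$y <- xy[, 2]
      net <- patch_network(props, dist_unit = dist_unit)
    } else if (all(types == "Polygon")) {
      rings <- lapply(geoms, function(g) {
        ring <- g$coordinates[[1]]
        do.call(rbind, lapply(ring, function(pt) unlist(pt)[1:2]))
      })
      cent <- t(vapply(rings, colMeans, numeric(2)))
      check_projected(cent[, 1], cent[, 2])
      props$x <- cent[, 1]; props$y <- cent[, 2]
      d <- edge_distances(rings, ids = props$patch_id, unit = dist_unit)
      net <- patch_network(props, dist = d, dist_unit = dist_unit)
    } else stop_arg("mixed or unsupported geometry types in GeoJSON")
  }
  if (is.null(occupancy)) return(net)
  occ <- occupancy_table(utils::read.csv(occupancy, stringsAsFactors = FALSE))
  list(network = net, occupancy = occ)
}

# heuristic lat/long guard: projected metre coordinates of a real network are
# far outside [-180, 180] x [-90, 90]
check_projected <- function(x, y) {
  if (all(abs(x) <= 180) && all(abs(y) <= 90))
    stop_arg("coordinates look geographic (degrees); supply a projected CRS in metres")
  invisible(TRUE)
}

#' Write the patch table and occupancy table back to their CSV dialects
#'
#' @param network a `patch_network`.
#' @param path output CSV path.
#' @export
write_patch_csv <- function(network, path) {
  p <- network$patches
  p$circularity <- NULL  # derived; recomputed on load
  utils::write.csv(p, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_patch_csv
#' @param occupancy an `occupancy_table`.
#' @export
write_occupancy_csv <- function(occupancy, path) {
  utils::write.csv(as.data.frame(occupancy), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
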