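#' Empirical (Matheron) semivariogram of model residuals
#'
#' gamma(h) = (1/2N_h) * sum over pairs with separation in bin h of
#' (z_i - z_j)^2. Used as a diagnostic of residual spatial structure after
#' fitting the turnover models: a flat semivariogram near the residual
#' variance indicates no spatial autocorrelation left unexplained. Bins with
#' no pairs are returned as `NA` (undefined), never as zero.
#'
#' @param residuals numeric residuals (observed 0/1 minus predicted
#'   probability by default in this package).
#' @param coords two-column coordinate matrix (same projected unit
#'   throughout).
#' @param breaks strictly increasing bin edges; default `n_bins` equal-width
#'   bins up to `max_dist`.
#' @param n_bins number of default bins.
#' @param max_dist upper distance bound of the default bins; defaults to the
#'   60% quantile of pairwise distances (standard geostatistical practice —
#'   long-lag bins hold few, highly dependent pairs).
#' @return data.frame of class `semivariogram`: `lag` (bin centre), `gamma`,
#'   `n_pairs`.
#' @export
empirical_semivariogram <- function(residuals, coords, breaks = NULL,
                                    n_bins = 10, max_dist = NULL) {
  coords <- as.matrix(coords)
  n <- length(residuals)
  if (n < 2L || nrow(coords) != n) stop_arg("need >= 2 points with coordinates")
  d <- stats::dist(coords)
  dz2 <- stats::dist(matrix(residuals, ncol = 1))^2
  if (is.null(breaks)) {
    max_dist <- max_dist %||% stats::quantile(d, 0.6, names = FALSE)
    breaks <- seq(0, max_dist, length.out = n_bins + 1L)
  }
  if (any(diff(breaks) <= 0)) stop_arg("breaks must be strictly increasing")
  bin <- cut(as.vector(d), breaks, include.lowest = TRUE)
  np <- as.vector(table(bin))
  gamma <- as.vector(tapply(as.vector(dz2), bin, sum)) / (2 * np)
  gamma[np == 0] <- NA_real_
  out <- data.frame(lag = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    gamma = gamma, n_pairs = np)
  class(out) <- c("semivariogram", "data.frame")
  out
}

#' @export
plot.semivariogram <- function(x, ...) {
  plot(x$lag, x$gamma, type = "b", xlab = "lag distance",
       ylab = expression(gamma(h)), ylim = c(0, max(x$gamma, na.rm = TRUE)), ...)
  invisible(x)
}

#' Turnover accounting table across species
#'
#' One row per species with the surveyed-patch count and the four transition
#' counts (colonized, survived, extinct, vacant); surveyed always equals
#' their sum, which is checked.
#'
#' @param datasets named list of [build_turnover_datasets()] results.
#' @return data.frame: species, surveyed, colonized, survived, extinct,
#'   vacant.
#' @export
turnover_summary <- function(datasets) {
  rows <- lapply(datasets, function(td) {
    ct <- td$counts
    stopifnot(sum(ct) == nrow(td$colonization) + nrow(td$survival))
    data.frame(species = td$species, surveyed = sum(ct),
               colonized = ct[["colonized"]], survived = ct[["survived"]],
               extinct = ct[["extinct"]], vacant = ct[["vacant"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
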