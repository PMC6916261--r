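#' Steady-state persistence of a patch
#'
#' Long-run probability that a patch is occupied, given its annual survival
#' probability S and annual colonization probability C — the stationary
#' occupancy of the per-patch two-state Markov chain. Without a rescue effect
#' the stationary probability is \code{C / (1 - S + C)}; it exceeds 0.5
#' exactly when S + C > 1 and equals 0.5 on the line S + C = 1. With a rescue
#' effect (a population going extinct can be re-established by colonists in
#' the same year, so an occupied patch stays occupied with probability
#' S + (1-S)C) it is \code{C / (1 - S + S*C)}, which can exceed 0.5 even when
#' S + C < 1. The degenerate pair S = 1, C = 0 leaves the chain wherever it
#' started; `NaN` is returned with a warning.
#'
#' @param S annual survival probability, in `[0, 1]` (resistance).
#' @param C annual colonization probability, in `[0, 1]` (resilience).
#' @param rescue allow same-year re-colonization of fresh extinctions.
#' @return persistence probability, vectorised over `S` and `C`.
#' @examples
#' steady_state_persistence(0.6, 0.5, rescue = FALSE)  # 0.5/0.9
#' steady_state_persistence(0.5, 0.4, rescue = TRUE)   # 0.4/0.7 > 0.5
#' @export
steady_state_persistence <- function(S, C, rescue = TRUE) {
  if (any(!is.finite(S)) || any(!is.finite(C)) ||
      any(S < 0 | S > 1) || any(C < 0 | C > 1))
    stop_arg("S and C must be probabilities in [0, 1]")
  denom <- if (rescue) 1 - S + S * C else 1 - S + C
  out <- C / denom
  ind <- denom == 0
  if (any(ind)) {
    warning("S = 1 with C = 0: steady state is indeterminate (defined only by ",
            "the initial state); returning NaN", call. = FALSE)
    out[ind] <- NaN
  }
  out
}

#' Simulate the per-patch occupancy chain to equilibrium
#'
#' Independent stochastic oracle for [steady_state_persistence()]: runs the
#' two-state chain (occupied survives with probability S — in rescue mode a
#' fresh extinction is re-colonized the same year with probability C; an
#' empty patch is colonized with probability C) and returns the post-burn-in
#' occupancy frequency.
#'
#' @param S,C annual survival / colonization probabilities.
#' @param rescue allow same-year rescue.
#' @param steps chain length; must be at least `10 * burn_in`.
#' @param burn_in initial steps discarded.
#' @param seed RNG seed.
#' @return empirical occupancy fraction over the retained steps.
#' @export
markov_equilibrium_simulation <- function(S, C, rescue = TRUE, steps = 1e5,
                                          burn_in = steps %/% 20, seed = 1) {
  if (!is_num1(S) || !is_num1(C) || S < 0 || S > 1 || C < 0 || C > 1)
    stop_arg("S and C must be probabilities in [0, 1]")
  if (steps < 10 * burn_in) stop_arg("steps must be >= 10 * burn_in")
  set.seed(seed)
  p_stay <- if (rescue) S + (1 - S) * C else S
  u <- stats::runif(steps)
  occ <- logical(steps)
  state <- stats::runif(1) < 0.5
  for (t in seq_len(steps)) {
    state <- if (state) u[t] < p_stay else u[t] < C
    occ[t] <- state
  }
  mean(occ[(burn_in + 1):steps])
}

#' Classify patches into resistance/resilience quadrants
#'
#' Crosses the survival (resistance) and colonization (resilience)
#' probabilities against thresholds: both high gives
#' `resistant_and_resilient`; high survival only, `resistant_only`; high
#' colonization only, `resilient_only`; neither, `marginal` (low steady-state
#' persistence). A value equal to its threshold counts as high. The default
#' 0.5 cut is illustrative; thresholds are configurable per axis.
#'
#' @param S_prob,C_prob survival and colonization probabilities.
#' @param s_threshold,c_threshold thresholds in `(0, 1)`.
#' @return factor with levels `resistant_and_resilient`, `resistant_only`,
#'   `resilient_only`, `marginal`.
#' @export
classify_patch <- function(S_prob, C_prob, s_threshold = 0.5,
                           c_threshold = 0.5) {
  if (s_threshold <= 0 || s_threshold >= 1 || c_threshold <= 0 || c_threshold >= 1)
    stop_arg("thresholds must lie in (0, 1)")
  if (any(S_prob < 0 | S_prob > 1, na.rm = TRUE) ||
      any(C_prob < 0 | C_prob > 1, na.rm = TRUE))
    stop_arg("probabilities must lie in [0, 1]")
  hiS <- S_prob >= s_threshold
  hiC <- C_prob >= c_threshold
  out <- ifelse(hiS & hiC, "resistant_and_resilient",
         ifelse(hiS, "resistant_only",
         ifelse(hiC, "resilient_only", "marginal")))
  factor(out, levels = CATEGORIES)
}

#' Per-patch persistence table for one species
#'
#' Combines predicted survival and colonization probabilities into the
#' package's standard per-species result: both steady-state persistence
#' values (with and without rescue) and the quadrant category.
#'
#' @param patch_id patch identifiers.
#' @param S_prob,C_prob predicted survival / colonization probabilities.
#' @param species species name.
#' @param s_threshold,c_threshold classification thresholds.
#' @return data.frame of class `persistence_result`: patch_id, species,
#'   S_prob, C_prob, P_no_rescue, P_rescue, category.
#' @export
persistence_table <- function(patch_id, S_prob, C_prob, species,
                              s_threshold = 0.5, c_threshold = 0.5) {
  stopifnot(length(patch_id) == length(S_prob), length(S_prob) == length(C_prob))
  out <- data.frame(
    patch_id = as.character(patch_id), species = species,
    S_prob = S_prob, C_prob = C_prob,
    P_no_rescue = steady_state_persistence(S_prob, C_prob, rescue = FALSE),
    P_rescue = steady_state_persistence(S_prob, C_prob, rescue = TRUE),
    category = classify_patch(S_prob, C_prob, s_threshold, c_threshold),
    stringsAsFactors = FALSE)
  class(out) <- c("persistence_result", "data.frame")
  out
}

#' @export
plot.persistence_result <- function(x, ...) {
  cols <- c(resistant_and_resilient = "purple", resistant_only = "red",
            resilient_only = "blue", marginal = "black")
  plot(x$C_prob, x$S_prob, col = cols[as.character(x$category)], pch = 19,
       xlim = c(0, 1), ylim = c(0, 1),
       xlab = "colonization probability (resilience)",
       ylab = "survival probability (resistance)", ...)
  graphics::abline(h = 0.5, v = 0.5, lty = 3)
  invisible(x)
}
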