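#' Small-sample corrected Akaike Information Criterion
#'
#' @param loglik maximised log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size; requires `n - k - 1 > 0`.
#' @return `-2*loglik + 2k + 2k(k+1)/(n-k-1)`.
#' @export
aicc <- function(loglik, k, n) {
  if (any(n - k - 1 <= 0)) stop_arg("model too rich for sample (n - k - 1 <= 0)")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Maximum-likelihood logistic regression
#'
#' Binomial-logit fit by iteratively reweighted least squares (deviance
#' tolerance 1e-8). An intercept is always included. Quasi-complete
#' separation (fitted probabilities numerically at 0 or 1) is flagged with a
#' warning; coefficients are still reported, with the inflated standard
#' errors that entails. A Jeffreys-prior (Firth) penalised fit is available
#' for separated data.
#'
#' @param y 0/1 response vector.
#' @param X covariate matrix or data.frame (no intercept column).
#' @param penalized use Firth's Jeffreys-prior penalised likelihood.
#' @return list: `coefficients`, `se`, `vcov`, `loglik`, `k`, `n`,
#'   `separation`, `converged`.
#' @export
fit_logistic <- function(y, X = NULL, penalized = FALSE) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_arg("y must be 0/1")
  Xm <- if (is.null(X) || NCOL(X) == 0) matrix(numeric(0), length(y), 0)
        else as.matrix(X)
  if (!is.numeric(Xm) && length(Xm)) stop_arg("X must be numeric")
  if (any(!is.finite(Xm))) stop_arg("covariates must be finite")
  D <- cbind(`(Intercept)` = 1, Xm)
  if (nrow(D) < ncol(D)) stop_arg("more parameters than observations")
  if (qr(D)$rank < ncol(D)) stop_arg("design matrix is rank deficient")

  if (penalized) return(firth_logistic(y, D))

  fit <- suppressWarnings(
    stats::glm.fit(D, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  if (!fit$converged)
    stop_arg("IRLS failed to converge after ", fit$iter, " iterations; ",
             "deviance trace ends at ", signif(fit$deviance, 6))
  mu <- fit$fitted.values
  separation <- any(mu < 1e-8 | mu > 1 - 1e-8)
  if (separation)
    warning("possible quasi-complete separation: fitted probabilities at 0/1; ",
            "standard errors are inflated", call. = FALSE)
  W <- mu * (1 - mu)
  XtWX <- crossprod(D, D * W)
  V <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, ncol(D), ncol(D)))
  dimnames(V) <- list(colnames(D), colnames(D))
  ll <- sum(stats::dbinom(y, 1, mu, log = TRUE))
  list(coefficients = stats::setNames(fit$coefficients, colnames(D)),
       se = sqrt(diag(V)), vcov = V, loglik = ll,
       k = ncol(D), n = length(y), separation = separation, converged = TRUE)
}

# Firth-penalised logistic: score modified by hat-value correction
firth_logistic <- function(y, D, maxit = 100, tol = 1e-8) {
  beta <- rep(0, ncol(D))
  for (it in seq_len(maxit)) {
    eta <- drop(D %*% beta)
    mu <- inv_logit(eta)
    W <- mu * (1 - mu)
    XtWX <- crossprod(D, D * W)
    V <- solve(XtWX)
    # hat values of the weighted design
    H <- rowSums((D %*% V) * D) * W
    U <- crossprod(D, y - mu + H * (0.5 - mu))
    step <- drop(V %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  mu <- inv_logit(drop(D %*% beta))
  ll <- sum(stats::dbinom(y, 1, mu, log = TRUE)) +
    0.5 * determinant(crossprod(D, D * (mu * (1 - mu))))$modulus[1]
  V <- solve(crossprod(D, D * (mu * (1 - mu))))
  dimnames(V) <- list(colnames(D), colnames(D))
  list(coefficients = stats::setNames(beta, colnames(D)), se = sqrt(diag(V)),
       vcov = V, loglik = as.numeric(ll), k = ncol(D), n = length(y),
       separation = FALSE, converged = it < maxit, penalized = TRUE)
}

quad_base <- function(term) {
  m <- regmatches(term, regexec("^I\\((.+)\\^2\\)$", term))[[1]]
  if (length(m)) m[2] else NA_character_
}
is_quad <- function(term) !is.na(vapply(term, quad_base, ""))

#' Screen vegetation terms for quadratic (intermediate-optimum) effects
#'
#' For each candidate proportion independently, a single-predictor logistic
#' model is compared by AIC with the model adding its square; the squared
#' term enters the global model only when AIC strictly decreases (ties drop
#' it). This admits hump-shaped responses to intermediate disturbance levels
#' without inflating every candidate model set.
#'
#' @param data dataset with response column `y` and the candidate columns.
#' @param terms global linear terms.
#' @param candidates terms to screen; default the vegetation proportions
#'   present in `terms`.
#' @return `terms` with any retained `I(term^2)` entries inserted after their
#'   linear term.
#' @export
screen_quadratic_terms <- function(data, terms,
                                   candidates = intersect(terms,
                                     c("veg_disturbed", "veg_undisturbed", "veg_mixed"))) {
  out <- terms
  for (v in candidates) {
    res <- tryCatch({
      lin <- fit_logistic(data$y, data[, v, drop = FALSE])
      sq <- fit_logistic(data$y, cbind(data[, v, drop = FALSE],
                                       stats::setNames(data.frame(data[[v]]^2),
                                                       paste0("I(", v, "^2)"))))
      aic_lin <- -2 * lin$loglik + 2 * lin$k
      aic_sq <- -2 * sq$loglik + 2 * sq$k
      aic_sq < aic_lin
    }, error = function(e) {
      warning("quadratic screening skipped for ", v, ": ", conditionMessage(e),
              call. = FALSE)
      FALSE
    })
    if (isTRUE(res)) {
      pos <- match(v, out)
      out <- append(out, paste0("I(", v, "^2)"), after = pos)
    }
  }
  out
}

#' All submodels of a global model
#'
#' Enumerates every subset of the global terms (intercept always included),
#' enforcing marginality: a squared term `I(v^2)` never appears without its
#' linear term `v`.
#'
#' @param terms character vector of global (non-intercept) terms.
#' @param max_terms combinatorial guard.
#' @return list of character vectors (term subsets), including `character(0)`
#'   for the intercept-only model.
#' @export
all_subsets <- function(terms, max_terms = 12) {
  p <- length(terms)
  if (p > max_terms) stop_arg("too many terms for all-subsets enumeration (", p, ")")
  if (p == 0L) return(list(character(0)))
  subsets <- list()
  for (mask in 0:(2^p - 1)) {
    keep <- as.logical(bitwAnd(mask, 2^(seq_len(p) - 1)))
    sel <- terms[keep]
    bases <- vapply(sel, quad_base, "")
    ok <- all(is.na(bases) | bases %in% sel)
    if (ok) subsets[[length(subsets) + 1L]] <- sel
  }
  subsets
}

#' Fit, rank and average binomial-logit turnover models
#'
#' The package's core estimator. Starting from a global set of patch
#' covariates, it (1) optionally screens the vegetation proportions for
#' quadratic terms by AIC, (2) fits every admissible submodel, (3) ranks them
#' by AICc, (4) forms the confidence set of models within `delta` AICc of the
#' best with Akaike weights renormalised inside the set, and (5) computes
#' full model-averaged coefficients (zero substituted where a term is absent)
#' with unconditional standard errors, normal 95% confidence intervals,
#' relative importance (sum of weights of top-set models containing each
#' term), and a significance flag (CI excluding 0).
#'
#' @param data a data.frame with a 0/1 response column `y` and covariate
#'   columns (one element of [build_turnover_datasets()]'s output); rows with
#'   missing covariates (e.g. circularity without a perimeter) are dropped
#'   with a warning.
#' @param terms global model terms; default all standard patch covariates
#'   present in `data`.
#' @param process label, `"colonization"` or `"survival"`.
#' @param quadratic_screen run [screen_quadratic_terms()] first.
#' @param delta AICc radius of the top model set (inclusive).
#' @param average `"full"` (zero substitution, default) or `"conditional"`
#'   (average only over models containing the term).
#' @param standardize centre/scale covariates for fitting; coefficients are
#'   mapped back to the raw scale, so reported estimates are unchanged in
#'   meaning.
#' @param penalized use the Firth penalised fit for every model (for
#'   separated data).
#' @return object of class `turnover_fit` with components `ranking` (one row
#'   per candidate model: spec, k, loglik, AICc, delta, weight), `top`
#'   (indices of the top set), `average` (coefficient table), `terms_global`,
#'   `n`, `process`. Methods: `print`, `summary`, `coef`, `predict`.
#' @export
fit_turnover <- function(data, terms = NULL, process = "turnover",
                         quadratic_screen = TRUE, delta = 2,
                         average = c("full", "conditional"),
                         standardize = FALSE, penalized = FALSE) {
  average <- match.arg(average)
  data <- as.data.frame(data)
  if (!"y" %in% names(data)) stop_arg("data must contain a 0/1 response column 'y'")
  terms <- terms %||% intersect(
    c("area", "circularity", "veg_disturbed", "veg_undisturbed", "veg_mixed",
      "connectivity"), names(data))
  lin <- terms[!is_quad(terms)]
  miss <- setdiff(lin, names(data))
  if (length(miss)) stop_arg("terms not in data: ", paste(miss, collapse = ", "))

  keep <- stats::complete.cases(data[c("y", lin)])
  if (any(!keep)) {
    warning(sum(!keep), " row(s) with missing covariates dropped", call. = FALSE)
    data <- data[keep, , drop = FALSE]
  }
  n <- nrow(data)

  if (standardize) {
    ctr <- vapply(lin, function(v) mean(data[[v]]), numeric(1))
    scl <- vapply(lin, function(v) {
      s <- stats::sd(data[[v]]); if (s == 0) 1 else s
    }, numeric(1))
    for (v in lin) data[[v]] <- (data[[v]] - ctr[v]) / scl[v]
  } else {
    ctr <- stats::setNames(rep(0, length(lin)), lin)
    scl <- stats::setNames(rep(1, length(lin)), lin)
  }

  if (quadratic_screen) terms <- screen_quadratic_terms(data, terms)

  specs <- all_subsets(terms)
  models <- lapply(specs, function(sp) {
    X <- design_columns(data, sp)
    f <- fit_logistic(data$y, X, penalized = penalized)
    f$spec <- sp
    f$AICc <- aicc(f$loglik, f$k, f$n)
    f
  })
  a <- vapply(models, `[[`, numeric(1), "AICc")
  k <- vapply(models, `[[`, numeric(1), "k")
  spec_str <- vapply(specs, function(s) if (length(s)) paste(s, collapse = " + ")
                     else "(intercept only)", "")
  ord <- order(a, k, spec_str)
  models <- models[ord]; specs <- specs[ord]
  a <- a[ord]; k <- k[ord]; spec_str <- spec_str[ord]

  del <- a - a[1]
  top <- which(del <= delta)
  w_all <- rep(NA_real_, length(a))
  w <- exp(-del[top] / 2); w <- w / sum(w)
  w_all[top] <- w

  ranking <- data.frame(spec = spec_str, k = k,
                        loglik = vapply(models, `[[`, numeric(1), "loglik"),
                        AICc = a, delta = del, weight = w_all,
                        stringsAsFactors = FALSE)

  avg <- model_average(models[top], w, terms, average = average)
  avg <- unstandardize_average(avg, ctr, scl)

  structure(list(ranking = ranking, models = models, top = top,
                 average = avg, terms_global = terms, n = n,
                 process = process, delta = delta, average_type = average,
                 standardized = standardize,
                 center = ctr, scale = scl),
            class = "turnover_fit")
}

# design matrix columns for a spec, including squared terms
design_columns <- function(data, spec) {
  if (!length(spec)) return(NULL)
  cols <- lapply(spec, function(tm) {
    b <- quad_base(tm)
    if (is.na(b)) data[[tm]] else data[[b]]^2
  })
  m <- do.call(cbind, cols)
  colnames(m) <- spec
  m
}

#' Full model averaging across a confidence set
#'
#' Weighted average of each coefficient across models, substituting zero
#' where the term is absent (full averaging); the unconditional standard
#' error is `sum_m w_m * sqrt(se_m^2 + (beta_m - beta_bar)^2)`. Conditional
#' averaging (renormalising over the containing models only) is available.
#'
#' @param models list of [fit_logistic()] results carrying `$spec`.
#' @param weights Akaike weights, summing to 1.
#' @param terms the global term set to report.
#' @param average `"full"` or `"conditional"`.
#' @return data.frame: term, estimate, se, ci_lo, ci_hi, ri, significant.
#' @export
model_average <- function(models, weights, terms,
                          average = c("full", "conditional")) {
  average <- match.arg(average)
  if (abs(sum(weights) - 1) > 1e-8) stop_arg("weights must sum to 1")
  all_terms <- c("(Intercept)", terms)
  B <- SE <- matrix(0, length(models), length(all_terms),
                    dimnames = list(NULL, all_terms))
  for (m in seq_along(models)) {
    cf <- models[[m]]$coefficients
    B[m, names(cf)] <- cf
    SE[m, names(cf)] <- models[[m]]$se
  }
  present <- matrix(FALSE, length(models), length(all_terms),
                    dimnames = list(NULL, all_terms))
  present[, "(Intercept)"] <- TRUE
  for (m in seq_along(models)) present[m, models[[m]]$spec] <- TRUE

  ri <- colSums(weights * present)
  if (average == "full") {
    est <- colSums(weights * B)
    se <- vapply(seq_along(all_terms), function(j)
      sum(weights * sqrt(SE[, j]^2 + (B[, j] - est[j])^2)), numeric(1))
  } else {
    est <- se <- numeric(length(all_terms))
    for (j in seq_along(all_terms)) {
      inm <- present[, j]
      if (!any(inm)) next
      wj <- weights[inm] / sum(weights[inm])
      est[j] <- sum(wj * B[inm, j])
      se[j] <- sum(wj * sqrt(SE[inm, j]^2 + (B[inm, j] - est[j])^2))
    }
  }
  z <- stats::qnorm(0.975)
  out <- data.frame(term = all_terms, estimate = est, se = se,
                    ci_lo = est - z * se, ci_hi = est + z * se,
                    ri = ri, stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- out$ci_lo > 0 | out$ci_hi < 0
  out$significant[out$ri == 0] <- FALSE
  out
}

# Map averaged coefficients fitted on standardized covariates v_s = (v-m)/s
# back to the raw scale:
#   beta1 v_s + beta2 v_s^2  =  (beta1/s - 2 beta2 m/s^2) v + (beta2/s^2) v^2
#                               + (beta2 m^2/s^2 - beta1 m/s)
# SEs are rescaled by the same factors per term (the linear/quadratic
# covariance is ignored, as this flag exists for numerical stability only).
unstandardize_average <- function(avg, ctr, scl) {
  if (all(scl == 1) && all(ctr == 0)) return(avg)
  est <- stats::setNames(avg$estimate, avg$term)
  se <- stats::setNames(avg$se, avg$term)
  raw_e <- est; raw_s <- se
  ic_shift <- 0
  for (tm in avg$term) {
    if (tm == "(Intercept)") next
    b <- quad_base(tm)
    if (!is.na(b)) {
      raw_e[tm] <- est[tm] / scl[b]^2
      raw_s[tm] <- se[tm] / scl[b]^2
      raw_e[b] <- raw_e[b] - 2 * est[tm] * ctr[b] / scl[b]^2
      ic_shift <- ic_shift - est[tm] * ctr[b]^2 / scl[b]^2
    } else {
      raw_e[tm] <- raw_e[tm] - est[tm] + est[tm] / scl[tm]
      raw_s[tm] <- se[tm] / scl[tm]
      ic_shift <- ic_shift + est[tm] * ctr[tm] / scl[tm]
    }
  }
  raw_e["(Intercept)"] <- est["(Intercept)"] - ic_shift
  z <- stats::qnorm(0.975)
  avg$estimate <- unname(raw_e[avg$term])
  avg$se <- unname(raw_s[avg$term])
  avg$ci_lo <- avg$estimate - z * avg$se
  avg$ci_hi <- avg$estimate + z * avg$se
  avg$significant <- (avg$ci_lo > 0 | avg$ci_hi < 0) & avg$ri > 0
  avg
}

#' @export
print.turnover_fit <- function(x, ...) {
  cat("Turnover model set (", x$process, "): ", nrow(x$ranking),
      " candidate models, n = ", x$n, "\n", sep = "")
  cat("Top set (delta AICc <= ", x$delta, "): ", length(x$top), " model(s)\n",
      sep = "")
  cat("Best model:", x$ranking$spec[1], "\n")
  invisible(x)
}

#' @export
summary.turnover_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.turnover_fit")
}

#' @export
print.summary.turnover_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nModel ranking (top set):\n")
  print(f$ranking[f$top, ], row.names = FALSE, digits = 4)
  cat("\nFull model-averaged coefficients:\n")
  avg <- f$average
  avg$ri <- round(avg$ri, 2)
  print(avg, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.turnover_fit <- function(object, ...) {
  stats::setNames(object$average$estimate, object$average$term)
}

#' Predict occupancy-transition probabilities for patches
#'
#' Inverse-logit of the model-averaged linear predictor, evaluated for any
#' patch with the required covariates — typically the whole suitable network,
#' not only the patches the models were fitted to.
#'
#' @param object a [fit_turnover()] result.
#' @param newdata data.frame of patch covariates; a `patch_id` column, if
#'   present, names the result.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.turnover_fit <- function(object, newdata, ...) {
  avg <- object$average
  used <- avg$term[avg$term != "(Intercept)"]
  eta <- rep(avg$estimate[avg$term == "(Intercept)"], nrow(newdata))
  for (tm in used) {
    b <- quad_base(tm)
    col <- if (is.na(b)) tm else b
    if (!col %in% names(newdata))
      stop_arg("missing covariate '", col, "' required for term ", tm)
    v <- newdata[[col]]
    bad <- !is.finite(v)
    if (any(bad)) {
      id <- if ("patch_id" %in% names(newdata)) newdata$patch_id[bad] else which(bad)
      stop_arg("missing covariate '", col, "' for patch ",
               paste(id, collapse = ", "))
    }
    x <- if (is.na(b)) v else v^2
    eta <- eta + avg$estimate[avg$term == tm] * x
  }
  p <- inv_logit(eta)
  if ("patch_id" %in% names(newdata)) names(p) <- newdata$patch_id
  p
}

#' Akaike weights of a confidence model set
#'
#' @param aicc_values vector of AICc values.
#' @param delta inclusion radius relative to the minimum (inclusive).
#' @return list: `top` (indices), `weight` (renormalised weights over the set).
#' @export
top_model_set <- function(aicc_values, delta = 2) {
  d <- aicc_values - min(aicc_values)
  top <- which(d <= delta)
  w <- exp(-d[top] / 2)
  list(top = top, weight = w / sum(w))
}
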