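test_that("AICc follows the small-sample correction and its guards", {
  expect_equal(aicc(-10, 2, 20), 24 + 12 / 17)
  # correction vanishes in the large-n limit
  expect_equal(aicc(-10, 2, 1e8), 24, tolerance = 1e-6)
  expect_error(aicc(-10, 19, 20), "too rich")
  expect_error(aicc(-10, 25, 20), "too rich")
})

test_that("the logistic fit maximises the Bernoulli likelihood", {
  # intercept-only, 5 successes in 10
  f <- fit_logistic(rep(c(0, 1), 5))
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-8)

  # 6-row fixture against a brute-force grid over (b0, b1)
  y <- c(0, 0, 1, 0, 1, 1)
  x <- c(-2, -1, -0.5, 0.5, 1, 2)
  f <- fit_logistic(y, data.frame(x = x))
  grid_ll <- function(b0s, b1s) {
    g <- expand.grid(b0 = b0s, b1 = b1s)
    g$ll <- 0
    for (i in seq_along(y))
      g$ll <- g$ll + dbinom(y[i], 1, plogis(g$b0 + g$b1 * x[i]), log = TRUE)
    g[which.max(g$ll), ]
  }
  coarse <- grid_ll(seq(-3, 3, by = 0.05), seq(0, 5, by = 0.05))
  best <- grid_ll(seq(coarse$b0 - 0.1, coarse$b0 + 0.1, by = 0.001),
                  seq(coarse$b1 - 0.1, coarse$b1 + 0.1, by = 0.001))
  expect_equal(unname(f$coefficients["(Intercept)"]), best$b0, tolerance = 1e-3)
  expect_equal(unname(f$coefficients["x"]), best$b1, tolerance = 1e-3)
  expect_equal(f$loglik, best$ll, tolerance = 1e-6)

  expect_warning(fit_logistic(rep(0, 10)), "separation")
  expect_error(fit_logistic(c(0, 1, 2)), "0/1")
  expect_error(fit_logistic(c(0, 1, 0), data.frame(a = c(1, 2, 3), b = c(2, 4, 6))),
               "rank")
})

test_that("separated data are flagged and the penalised fit tames them", {
  y <- c(0, 0, 0, 1, 1, 1)
  x <- c(-3, -2, -1, 1, 2, 3)  # complete separation
  expect_warning(f <- fit_logistic(y, data.frame(x = x)), "separation")
  fp <- fit_logistic(y, data.frame(x = x), penalized = TRUE)
  expect_true(is.finite(fp$coefficients["x"]))
  expect_lt(abs(fp$coefficients["x"]), 5)
})

test_that("all-subsets enumeration respects marginality", {
  expect_length(all_subsets(c("a", "b", "c")), 8)
  expect_length(all_subsets(character(0)), 1)
  s <- all_subsets(c("v", "I(v^2)"))
  expect_length(s, 3)  # {}, {v}, {v, v^2}
  expect_true(all(vapply(s, function(sp) !"I(v^2)" %in% sp || "v" %in% sp, TRUE)))
  # mixed: 2 plain terms + a quadratic pair -> 4 * 3 = 12
  expect_length(all_subsets(c("a", "b", "v", "I(v^2)")), 12)
  expect_error(all_subsets(letters[1:13]), "too many")
})

test_that("the top model set uses the inclusive delta-2 rule with renormalised weights", {
  ts <- top_model_set(c(100, 101.9, 102.1))
  expect_equal(ts$top, 1:2)
  expect_equal(sum(ts$weight), 1)
  ts1 <- top_model_set(104.2)
  expect_equal(ts1$weight, 1)
  ts2 <- top_model_set(c(50, 50))
  expect_equal(ts2$weight, c(0.5, 0.5))
  # boundary is inclusive
  expect_equal(top_model_set(c(10, 12))$top, 1:2)
})

test_that("full model averaging zero-substitutes and tracks relative importance", {
  m1 <- list(coefficients = c(`(Intercept)` = 0.2, a = 1), se = c(0.1, 0.3),
             spec = "a")
  m2 <- list(coefficients = c(`(Intercept)` = 0.4), se = c(0.1), spec = character(0))
  avg <- model_average(list(m1, m2), c(0.5, 0.5), terms = c("a", "b"))
  a_row <- avg[avg$term == "a", ]
  expect_equal(a_row$estimate, 0.5)
  expect_equal(a_row$ri, 0.5)
  # unconditional SE: 0.5*sqrt(0.3^2 + 0.25) + 0.5*sqrt(0 + 0.25)
  expect_equal(a_row$se, 0.5 * sqrt(0.09 + 0.25) + 0.5 * 0.5)
  b_row <- avg[avg$term == "b", ]
  expect_equal(b_row$estimate, 0)
  expect_equal(b_row$ri, 0)
  expect_false(b_row$significant)
  expect_true(all(avg$ri >= 0 & avg$ri <= 1))

  # single model: identity
  avg1 <- model_average(list(m1), 1, terms = "a")
  expect_equal(avg1$estimate, unname(m1$coefficients))
  expect_equal(avg1$ri, c(1, 1))
  # conditional averaging renormalises within containing models
  avgc <- model_average(list(m1, m2), c(0.5, 0.5), terms = "a",
                        average = "conditional")
  expect_equal(avgc[avgc$term == "a", "estimate"], 1)
  expect_error(model_average(list(m1), 0.7, "a"), "sum to 1")
})

test_that("quadratic screening keeps humps and drops noise", {
  set.seed(42)
  n <- 500
  v <- runif(n)
  # hump at intermediate proportions: logit = -2 + 8v - 8v^2
  y <- rbinom(n, 1, plogis(-2 + 8 * v - 8 * v^2))
  terms <- screen_quadratic_terms(data.frame(y = y, veg_disturbed = v),
                                  "veg_disturbed")
  expect_equal(terms, c("veg_disturbed", "I(veg_disturbed^2)"))

  # null responses: retention happens at roughly the chance rate P(chi2 > 2)
  kept <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    v <- runif(n)
    y <- rbinom(n, 1, 0.3)
    length(screen_quadratic_terms(data.frame(y = y, veg_disturbed = v),
                                  "veg_disturbed")) > 1
  }, TRUE)
  expect_lt(mean(kept), 0.5)  # dropped far more often than chance retention

  # a degenerate candidate cannot improve and is skipped with a warning
  expect_warning(
    out <- screen_quadratic_terms(data.frame(y = rbinom(20, 1, 0.5),
                                             veg_disturbed = rep(0.5, 20)),
                                  "veg_disturbed"),
    "skipped")
  expect_equal(out, "veg_disturbed")
})

test_that("fit_turnover ranks, averages and predicts coherently", {
  sim <- recovery_sim(seed = 3, n_patches = 400)
  td <- sim$datasets
  fit <- fit_turnover(td$colonization, process = "colonization")
  expect_s3_class(fit, "turnover_fit")
  # weights sum to one within the top set
  expect_equal(sum(fit$ranking$weight, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_true(all(diff(fit$ranking$AICc) >= 0))
  expect_equal(fit$ranking$delta[1], 0)
  # coef() returns the averaged coefficients
  expect_equal(unname(coef(fit)), fit$average$estimate)
  # predictions are probabilities and match the hand-computed linear predictor
  p <- predict(fit, td$colonization)
  expect_true(all(p >= 0 & p <= 1))
  i <- 5
  eta <- sum(vapply(seq_len(nrow(fit$average)), function(j) {
    tm <- fit$average$term[j]
    if (tm == "(Intercept)") return(fit$average$estimate[j])
    base <- sub("^I\\((.+)\\^2\\)$", "\\1", tm)
    v <- td$colonization[[base]][i]
    fit$average$estimate[j] * (if (grepl("\\^2", tm)) v^2 else v)
  }, numeric(1)))
  expect_equal(unname(p[i]), plogis(eta), tolerance = 1e-12)
  # missing covariate errors name the term
  expect_error(predict(fit, td$colonization[, c("patch_id", "y", "area")]),
               "missing covariate")
})

test_that("an averaged model with only an intercept of zero predicts one half", {
  avg <- model_average(list(list(coefficients = c(`(Intercept)` = 0), se = 0.1,
                                 spec = character(0))), 1, terms = character(0))
  fake <- structure(list(average = avg), class = "turnover_fit")
  expect_equal(unname(predict(fake, data.frame(area = c(1, 7)))), c(0.5, 0.5))
})

test_that("a covariate never entering the top set does not move predictions", {
  # search deterministically for a replicate where some covariate has RI = 0
  found <- FALSE
  for (s in 1:10) {
    sim <- recovery_sim(seed = 200 + s, n_patches = 300)
    td <- sim$datasets
    fit <- suppressWarnings(fit_turnover(td$survival, process = "survival",
                                         quadratic_screen = FALSE))
    zero <- fit$average$term[fit$average$ri == 0 & fit$average$term != "(Intercept)"]
    if (!length(zero)) next
    found <- TRUE
    reduced <- suppressWarnings(
      fit_turnover(td$survival, terms = setdiff(fit$terms_global, zero),
                   process = "survival", quadratic_screen = FALSE))
    expect_equal(predict(reduced, td$survival), predict(fit, td$survival),
                 tolerance = 1e-12)
    break
  }
  expect_true(found)
})

test_that("standardised fitting reports coefficients on the raw scale", {
  sim <- recovery_sim(seed = 9, n_patches = 400)
  td <- sim$datasets
  raw <- suppressWarnings(fit_turnover(td$colonization, quadratic_screen = FALSE))
  std <- suppressWarnings(fit_turnover(td$colonization, quadratic_screen = FALSE,
                                       standardize = TRUE))
  # same model ranking, near-identical averaged estimates after back-transform
  expect_equal(std$ranking$spec, raw$ranking$spec)
  expect_equal(std$average$estimate, raw$average$estimate, tolerance = 1e-4)
})
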