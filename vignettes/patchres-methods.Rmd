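---
title: "Methods: estimating patch resistance and resilience from two-year occupancy"
author: "patchres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating patch resistance and resilience from two-year occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchres)
```

## The estimation problem

A patch network is surveyed in two consecutive breeding seasons and each
species is scored present/absent in every patch. Between the two surveys a
patch either keeps its population (survival), loses it (local extinction),
gains one (colonization) or stays vacant. `patchres` treats the two
transitions as separate binomial processes, estimates how patch and
landscape covariates drive each, and converts the resulting per-patch
probabilities into long-run persistence and conservation categories.

The two datasets partition the surveyed, suitable patches by year-1 state:
colonization models use only the patches where the species was absent in
year 1, survival models only those where it was present. Covariates are
taken from the year-2 habitat data (patch area in hectares, circularity,
and the vegetation-category proportions), because habitat measured in the
same season as the outcome best reflects the conditions under which the
transition happened; connectivity is computed from year-1 occupancy, since
year-1 occupants are the potential sources of year-2 colonists. One of the
four vegetation proportions (the moderately disturbed category) is excluded
from the models: the four sum to one, so including all four would make the
design collinear.

Patches unsurveyed in either year are excluded from both datasets and
reported. Patch types a species does not use (shoreline fringing patches,
broad wetland) are excluded from all of its computations via per-species
habitat-use flags; the default flag set for the five papyrus-endemic
passerines restricts shoreline patches to two species and broad wetland to
two others.

## Connectivity and the dispersal kernel

The connectivity of focal patch $i$ is the incidence-function sum
$S_i = \sum_{j \ne i} p_j \, e^{-\alpha d_{ij}} A_j^b$, where $p_j$ is
year-1 occupancy, $d_{ij}$ the nearest-edge distance, $A_j$ the source
carrying capacity and $b$ (default 1) scales emigration with abundance.
$A_j$ is density $\times$ area when a per-species density column is
present, and raw area otherwise; both options exist because kernel fits
reported for real networks do not always state which weighting was used,
and the density-weighted form is the default for consistency with how the
index is used downstream.

Two deliberate unit rules: areas are stored in hectares and distances in
whatever single projected unit the distance matrix records. $\alpha$ is
interpreted *per unit of that matrix* and is never rescaled silently — an
exponential kernel is meaningless if the unit is ambiguous, which is also
why the loader refuses longitude/latitude input outright.

When $\alpha$ must be estimated, `fit_alpha()` profiles the Bernoulli
log-likelihood of the observed colonization outcomes over a deterministic
grid (default 200 log-spaced values): at each candidate $\alpha$ the
connectivity index is recomputed and a logistic regression (intercept +
slope on $S$) refit, so both nuisance coefficients are profiled out. A grid
search was chosen over a stochastic sampler for exact reproducibility; the
full profile is returned so weak identification is visible rather than
hidden. Two diagnostics accompany the estimate:

* **boundary** — the maximum sits on a grid endpoint (widen the grid);
* **flat** — the best $\alpha$'s likelihood-ratio against the
  intercept-only model does not exceed the 95th percentile of the same
  statistic under 49 response permutations (computed on a 25-point
  subgrid). A fixed internal seed makes the diagnostic deterministic, and
  the caller's RNG state is restored. Permutation calibration is used
  because the maximum over a grid of correlated likelihood-ratio statistics
  is not $\chi^2_1$; a naive threshold either always or never fires.

Within the profile loop $S$ is rescaled by its maximum before the logistic
fit. The profiled likelihood is invariant to linear rescaling of a
covariate, and steep kernels otherwise drive $S$ into the subnormal
floating-point range where the IRLS step fails. Degenerate or
non-convergent profile fits fall back to the intercept-only likelihood, a
conservative lower bound.

## Model set, AICc ranking and full averaging

Before enumeration, each vegetation proportion is screened for a quadratic
term: a single-predictor model is compared by AIC (not AICc — the screening
step deliberately uses the uncorrected criterion, with the small-sample
correction reserved for the ranking stage) with the model adding its
square, and the squared term enters the global model only when AIC strictly
decreases; ties drop it. This admits hump-shaped responses to intermediate
disturbance without doubling every candidate set.

`fit_turnover()` then fits every submodel of the global term set
(marginality enforced: a squared term never appears without its linear
term; at most 12 non-intercept terms), ranks by
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$, and keeps the
confidence set $\Delta\mathrm{AICc} \le 2$ (boundary inclusive; ties broken
by fewer parameters, then lexicographic term order, so output order is
deterministic). Akaike weights are renormalised within the set.

Coefficients are averaged with **full** (zero-substitution) averaging:
$\bar\beta = \sum_m w_m \beta_m$ with $\beta_m = 0$ where the term is
absent. The unconditional standard error is the revised
Burnham–Anderson estimator
$\mathrm{SE}(\bar\beta) = \sum_m w_m \sqrt{se_m^2 + (\beta_m - \bar\beta)^2}$
(with $se_m = 0$ for absent terms), and the 95% interval is the normal one;
how averaged-coefficient intervals "should" be formed is genuinely open in
the literature, so the package documents this choice and also offers
conditional averaging behind a flag. Relative importance of a term is the
summed weight of top-set models containing it, reported in [0, 1]. A term
is flagged significant when its interval excludes zero.

Full averaging shrinks weakly supported coefficients toward zero. That is
intended — it is what makes averaged predictions conservative — but it
means nominal coverage is not expected for weak terms, which is why the
recovery study below asserts a floor (85%) rather than 95% coverage.

Covariates enter untransformed. An optional standardisation flag
centres/scales internally for numerical stability and maps the averaged
coefficients back to the raw scale exactly (including quadratic terms);
reported estimates are unchanged in meaning. Logistic fits use IRLS with
deviance tolerance $10^{-8}$; quasi-complete separation (fitted
probabilities numerically at 0/1, which happens with very few events)
triggers a warning rather than a failure, and a Jeffreys-prior (Firth)
penalised fit is available behind a flag while plain maximum likelihood
remains the default.

## Steady-state persistence and classification

Annual survival $S$ and colonization $C$ define a two-state Markov chain
per patch. Its stationary occupancy is
$P = C/(1 - S + C)$ without rescue and $P = C/(1 - S + SC)$ when a freshly
extinct patch can be re-colonized the same year (occupied patches then stay
occupied with probability $S + (1-S)C$). The first form crosses one half
exactly on the line $S + C = 1$; the second dominates it everywhere and can
exceed one half even when $S + C < 1$. The degenerate pair $S=1, C=0$
leaves the chain wherever it started; the functions return `NaN` with a
warning rather than picking a limit. `markov_equilibrium_simulation()` is
kept in the package as an independent stochastic oracle for both formulas.

Classification crosses the two probabilities against per-axis thresholds
(default 0.5, explicitly illustrative and configurable): both high gives
`resistant_and_resilient`, survival-only high `resistant_only`,
colonization-only high `resilient_only`, neither `marginal`. A value equal
to its threshold counts as high — a documented, deterministic tie rule.
Classification operates on $(S, C)$ directly, not on $P$; both $P$ values
are always emitted alongside. Rescue is the default reporting mode because
breeding phenology in the motivating system makes same-year establishment
plausible, but nothing downstream depends on that choice.

For multi-species overlap the per-species maps are first harmonized:
predictions made at the whole-wetland level for broad-wetland species are
inherited by the papyrus patches inside each wetland (classification is
applied *before* allocation, so categories are inherited as-is — the
alternative order is not documented anywhere authoritative, and inheriting
categories keeps a wetland's patches internally consistent); broad wetlands
containing no papyrus patch are retained as their own units with a warning;
and shoreline patches are forced to `marginal` for species that do not use
them, on the overlap layer only. Harmonization is idempotent. Overlap
counts per patch and category, plus six derived layers (both-high,
both-low, high-resistance, high-resistance-and-low-resilience,
high-resilience, low-resistance-and-high-resilience), follow.

## The synthetic generator and what passing tests show

`generate_network()` draws patch centres uniformly on a square extent,
lognormal areas (ha), perimeters back-calculated so circularity is
Beta-distributed on (0, 1], Dirichlet vegetation proportions over the four
categories, and a configurable mix of papyrus, shoreline and broad-wetland
patches with containment links. `simulate_occupancy()` runs the exact
process the estimator targets: logit-linear survival and colonization in
the patch covariates and the connectivity index of the current year's
occupancy, with optional same-year rescue. A single seeded RNG stream makes
every dataset byte-reproducible.

Default study conditions (chosen once, as a realistic two-year passerine
survey): 500 patches on a 10-km extent, areas lognormal(meanlog log 1.5,
sdlog 1), circularity Beta(5, 2), vegetation Dirichlet(2, 2, 2, 2), initial
occupancy 0.35, $\alpha = 1$ km$^{-1}$, $b = 1$. The generating
coefficients — colonization: intercept $-5$, area $+0.25$, connectivity
$+0.1$; survival: intercept $+1.2$, area $+0.3$, mixed vegetation $-4$ —
were set by two criteria: the intercepts keep yearly event counts at the
scale of a real survey of this size (tens of colonizations and extinctions
among hundreds of patches), and the slopes give each true term a Wald
$z \approx 4$–$5$ at that scale. The power criterion matters: a truth the
data cannot resolve would make any sign-recovery or coverage assessment
meaningless for any estimator, and the motivating system's reported effects
(connectivity with relative importance 1) are of clearly detectable
magnitude. The recovery study simulates with rescue off, because the
turnover GLMs estimate the no-rescue transition probabilities; with rescue
on, observed survival is $S + (1-S)C$ and the survival model would be
misspecified by construction.

The recovery study itself (in the test suite): 50 replicates of a
1000-patch network; full-averaged coefficients of the true terms must agree
in sign in at least 95% of cases and their 95% intervals must cover the
truth in at least 85%. The $\alpha$-recovery condition uses 400 all-papyrus
patches on a 50-km extent with true $\alpha^* = 0.1$ km$^{-1}$ (decay
length 10 km, well resolved by that network) and a colonization slope of
0.05; the profile estimate must land within a factor of two of truth.
Simulated years run 2014–2015 to mirror a two-season field campaign.

What the generator does **not** emulate: real shoreline geometry (patch
centres are uniform, not strung along a lake edge), imperfect detection
(occupancy is observed without error; a real survey adds false absences),
inter-annual habitat change (covariates are static), density dependence,
and correlated environmental shocks. Passing tests therefore demonstrate
that the estimation machinery is correct and well calibrated under the
assumed observation model — not that the assumed model holds in any
particular field system; the semivariogram diagnostic below exists
precisely because one such violation (residual spatial structure) is
checkable from the data.

## Diagnostics

Residual spatial structure is checked with the Matheron empirical
semivariogram $\gamma(h) = \frac{1}{2N_h}\sum_{d_{ij} \in h}(z_i - z_j)^2$
of the response residuals (observed 0/1 minus predicted probability;
deviance residuals are a flag away). Default binning is 10 equal-width bins
up to the 60% quantile of pairwise distances — long-lag bins contain few,
highly interdependent pairs and are standard to truncate. Empty bins are
reported `NA`, never 0. A flat semivariogram near the residual variance
indicates no unexplained spatial autocorrelation. `turnover_summary()`
tabulates surveyed/colonized/survived/extinct/vacant per species and checks
the accounting identity that the four transition counts sum to the surveyed
total.

## Numerical and edge-case choices, in one place

* Vegetation proportions within $10^{-3}$ of summing to 1 are renormalised;
  larger deviations are an error naming the patch.
* Missing perimeter leaves circularity missing; such rows are dropped from
  model fitting with a warning, never imputed.
* Nearest-edge distances: Euclidean for point input; for polygons, the
  minimum over boundary segment pairs, with crossing or contained polygons
  at distance 0 (brute-force segment minimisation — networks have hundreds
  of patches, so the quadratic cost is immaterial).
* `aicc()` refuses $n - k - 1 \le 0$ ("model too rich for sample").
* All-subsets enumeration refuses more than 12 non-intercept terms.
* The pipeline manifest hashes the scientific configuration (excluding the
  output directory) so identical configs produce identical hashes across
  runs and locations.

## Known limitations

Detection error is not modelled; with a single visit per season the
estimates are of *apparent* survival and colonization. Model-averaged
intervals are approximate by construction. The $\alpha$ grid search
profiles a single connectivity covariate; joint kernel-plus-habitat
profiling is not attempted. Broad-wetland allocation assumes the
containment mapping is supplied; the package validates but does not infer
it from geometry.
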