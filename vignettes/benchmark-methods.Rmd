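---
title: "Benchmarking interaction selectors on a synthetic exposome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking interaction selectors on a synthetic exposome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`exposelect` is a simulation laboratory for a specific applied question:
when hundreds of correlated environmental exposures are screened for
main effects and two-way interactions on a continuous outcome, which
variable-selection strategies find the truth, which find convincing
proxies, and what does it cost to search for interactions that may not
exist? This vignette explains the generative model, the selectors, the
performance measures, and the numerical and design choices the package
makes — including what the synthetic data do and do not emulate.

## The synthetic exposome

All simulations start from a correlation model for p = 237 standardized
exposures in 15 families (sizes 1 to 51). Published summaries of a real
pregnancy-cohort exposome pin down its marginal structure: 81% of the
27,966 absolute pairwise correlations below 0.2 and 64% below 0.1, a
median |r| of 0.06, 78% of exposures having at least one partner with
|r| > 0.6, one 13-exposure block with every pairwise |r| ≥ 0.62 (mean
0.78), and one 13-exposure set with every pairwise |r| ≤ 0.1. The raw
matrix itself is not public, so `build_correlation_model()` emulates it
with a two-level factor model:

* **Entities.** Exposures load on latent *entities*: within-family
  clusters of 7–11 exposures (loadings 0.82–0.92, the high block
  calibrated to mean pairwise r = 0.78 exactly), or themselves when
  unclustered. Clusters are what give 78% of exposures a strong partner
  — the package plans the cluster cover so the partner fraction is
  structural (185/237), not statistical.
* **Entity correlations.** Entities correlate through their family
  factor, through one of four cross-family "source profile" factors
  (think diet, urbanicity, smoking, housing), and through a weak
  three-dimensional background whose connectivity is deliberately
  bimodal (some entities well connected, most barely) — that mixture is
  what reproduces a median |r| of 0.06 together with a quarter of pairs
  above 0.15. Every entity spends at most 0.58 of its unit variance on
  shared factors, which bounds all cross-entity correlations below the
  0.6 partner threshold and keeps the matrix positive definite by
  construction (no eigenvalue repair is ever needed for generated
  models; `nearest_positive_definite()` exists for user-supplied
  matrices and uses alternating eigenvalue clipping and diagonal
  restoration, tolerance 1e-6, at most 100 iterations).
* **Calibration.** Two allocation weights — background versus source
  profiles — are tuned by a 15-iteration deterministic loop against the
  median |r| and the fraction below 0.2. The model is accepted only if
  all six targets sit inside the tolerances (±3 percentage points on
  fractions and partner coverage, ±0.02 on the median and the
  high-block mean); otherwise the structure is redrawn (up to 4
  retries) and a failure names the violated target. Across seeds the
  calibrated model also lands near the published |r| percentiles
  (2.5th/25th/75th/97.5th ≈ 0.003/0.03/0.15/0.61), though only the six
  targets above are enforced.

What the generator does *not* emulate: non-Gaussian exposure marginals,
missing data, the unpublished within- versus between-family correlation
breakdown, and any fine structure of the real matrix beyond the
published summaries. Results that depend on those features — in
particular exact reproduction of the original benchmark's headline
figures — are out of reach by design; the package reproduces the
published *marginal* structure and checks the original comparison only
qualitatively.

## Scenarios and calibration of the noise

`scenario_registry()` encodes 21 subscenarios. The true model is always
five exposures with unit coefficients; scenarios add zero, one
(γ₁₂X₁X₂) or two (also γ₁₃X₁X₃) interactions, with γ = ±1 ("strong",
equal to the mains) or ±0.5 ("moderate"). Predictors are drawn uniformly
from the whole exposome ("mixed"), from the high block ("high"), or —
for one sensitivity subscenario — from the low block ("low"). Each
row's residual standard deviation σ is the design value that yields the
intended adjusted R² (≈0.1 or ≈0.3); the low-correlation row does not
come with a published σ, so the package calibrates it at run time.

Calibration is closed-form rather than simulated. For multivariate
normal exposures, Isserlis' theorem gives

* Var(Σβᵢ Xᵢ) = β'Rβ,
* Cov(XₐXᵦ, X꜀X𝒹) = r_{ac} r_{bd} + r_{ad} r_{bc} (so Var(XₐXᵦ) =
  1 + r², and shared-index pairs follow the same formula),
* Cov(Xₖ, XₐXᵦ) = 0,

so `expected_r2()` returns Var(F)/(Var(F)+σ²) exactly and
`calibrate_sigma()` inverts it, averaging Var(F) over 200 seeded
predictor draws for the scenario's mode. On the high block this machinery
reproduces the design values from first principles: five equicorrelated
(r = 0.78) predictors give Var(F) = 20.6, hence σ = 13 for R² = 0.11 and
σ = 12 for the strong-interaction case with R² = 0.13. The test suite
verifies both the algebra (against hand-computed constants) and the
Monte-Carlo behaviour (empirical mean adjusted R² of the true OLS fit
against the closed form). `true_model_sensitivity()` is the companion
diagnostic: the fraction of true terms significant when only the true
terms are fitted, which matches a noncentral-t power calculation on
independent designs.

## The selectors

All selectors share one container (`selected_model`): a canonical set of
terms (mains, quadratics, unordered interactions), optional
coefficients, capability flags, and — when the method predicts — a
native predictor function. Flags, not method names, decide which
measures apply downstream.

**EWAS₂** fits one single-exposure regression per exposure, applies the
Benjamini–Yekutieli step-up correction at α = 0.05 (the
dependence-robust c(m) = Σ 1/l variant, delegated to `p.adjust`), then
tests the product term in a two-exposure-plus-product model for every
pair of survivors and corrects again. It returns sets of marginally
associated terms, not a model, so it carries no predictor. Step 2 tests
only the product coefficient; pairs are formed among step-1 survivors
only. A pure interaction without marginal effects is invisible to it by
construction — the tests document this blind spot, including the caveat
that product terms make marginal correlation estimates heavy-tailed, so
the blind spot fails stochastically (roughly 1 seed in 5 at n = 600).

**DSA** searches term sets directly. The candidate universe is all
mains (order 1) plus all quadratics and pairwise products (order 2); a
sweep offers every incumbent of size k its deletions, substitutions
(swap one in-model term for one out-of-model term) and additions, a move
updating the incumbent of its target size whenever it strictly lowers
the residual sum of squares (relative tolerance 1e-12); sweeps repeat to
a fixed point (cap 30). Additions are evaluated in one vectorized
projection per incumbent, so the sweep cost is a handful of BLAS calls.
The final size minimizes 5-fold cross-validated RMSE *of the search*:
the per-size incumbents are recomputed on each fold's training rows and
scored out of fold. The alternative — scoring full-data incumbents by
CV — leaks the selection into the validation folds and makes pure noise
yield non-empty models; cross-validating the procedure restores the
expected behaviour (noise gives the empty model in most runs, and the
package asserts agreement with an exhaustive best-subset-by-CV oracle on
small instances). Ties in CV go to the smaller size; the chosen set is
refit by OLS; no hierarchy is imposed, so a bare interaction can be
selected without its mains.

**Sun3step** screens within families (connected components of the
|r| > 0.6 sample-correlation graph; one survivor per component, the
smallest marginal p-value — connected components because the source
description fixes no clustering rule and components are deterministic
and order-invariant), grows a regression tree on the survivors (`rpart`,
cp = 0.001), prunes to the subtree with minimum cross-validated error
(the literal minimum, not the one-standard-error rule), and hands the
split variables to the order-2 DSA search.

**LASSO** is `glmnet` behind the package interface: mains only, 50-value
path, ratio 0.01, 3-fold cross-validation on seeded shared folds,
minimum-CV penalty, coefficients reported on the original scale. Three
folds keep it comparable with the group-lasso model.

**GLINTERNET-style group lasso** is implemented in the package itself:
besides one singleton group per exposure, every candidate pair (i, j)
contributes a three-coefficient group (Xᵢ, Xⱼ, XᵢXⱼ) penalized by its
Euclidean norm with weight √3 (square root of the group dimension, so
group size does not bias selection). Because the product coefficient can
only be nonzero when its whole group is active, every selected
interaction arrives with its main effects — strong hierarchy by
construction, and asserted on every output. The solver is FISTA with
group soft-thresholding, objective-based restart, and a warm-started
decreasing path from the analytic λ_max; it matches `glmnet` to ~1e-6
when the interaction groups are disabled and the orthonormal
soft-threshold closed form to machine precision, and the tests check the
KKT conditions at the optimum. Exposures are standardized before
products are formed; products are centred but not rescaled, which keeps
the penalty comparable across groups and the fit reversible to the
original scale. With more than 100 exposures the full pair universe
(27,966 groups at p = 237) is first sure-screened to the 5,000 products
most correlated with the outcome; the screen is configurable and off for
small p, where the objective is exact. The minimum-CV rule picks λ*, on
the same fold split as the lasso.

**BRT** wraps depth-4 squared-error gradient boosting (via `xgboost`,
shrinkage 0.01, 50% row subsampling, at most 5,000 trees, the number of
trees chosen at the minimum of a fixed 25% holdout error). Importance is
the total squared split improvement per variable averaged over trees.
Backward elimination drops the least important half at each step
(retention ⌈(1−f)p⌉: 237 → 119 → 60 → 30 → 15 → 8 → 4 → 2 → 1) with the
holdout fixed across steps so errors are comparable, and returns the
smallest recorded set attaining the minimum holdout error. The learning
rate, bag fraction and holdout estimator are not pinned down by the
benchmark's source description; the defaults follow common boosting
practice and are exposed in `brt_config()`.

## Performance measures

Thirteen measures compare a selection with the truth. Term-level: the
relative model size, sensitivity and false discovery proportion over
exact terms, and the same restricted to interaction terms. Variable
level: the relative number of variables and the variable versions of
sensitivity and FDP. Correlation-aware: AltSens and AltFDP (and their
interaction versions) replace exact matching with the average best
absolute correlation between true and selected variables, so a proxy
correlated 0.9 with a missed predictor scores 0.9 instead of 0.
Predictive: the validation-set R² of the method's native predictor
divided by that of an OLS fit of the true terms (N = 10,000 validation
sets in the full design). Conventions where the definitions are silent:
correlations in the alternative measures come from the data-generating
Σ in absolute value (proxy detection should not depend on sign); an
empty selection scores 0 on sensitivity-type and FDP-type measures (no
discoveries, no false discoveries) and is marked missing on the
alternative measures, with the empty-model rate reported alongside;
quadratic terms never match a true term (true models contain none) but
do contribute their variable; and each method's capability flags
reproduce the availability pattern of the original comparison (the
two-step scan has no predictor; the tree ensemble has no term-level
measures; mains-only selectors have no interaction measures).

## The benchmark loop

`run_benchmark()` crosses subscenarios, methods and replicates. Each
replicate draws predictors, simulates one training set (N = 1200) and
one validation set (N = 10,000) and hands the *same* data to every
method; all randomness derives from one master seed through a
deterministic tag-based stream splitter, so any component can be
regenerated independently and results are identical regardless of which
methods run together. Failing method-runs are recorded and skipped in
means rather than aborting the loop. Results stream to per-replicate CSV
when an output directory is given, making runs resumable;
`aggregate_results()` takes means over non-missing replicates and
`ratio_report()` forms the interaction-cost ratios (interaction-capable
method over its mains-only counterpart) that summarize the cost of
searching for interactions when none exist.

## Problem sizes used by the shipped checks

The package's own tests and the acceptance script run at sizes chosen to
exercise every code path with comfortable statistical margins: the
correlation model always at the full p = 237; the adjusted-R²
reproduction at the design's N = 1200 with 100 replicates; selector
oracles on 4–20 exposures where exhaustive enumeration is feasible; the
planted-interaction recovery study on 20 equicorrelated (r = 0.2)
exposures, N = 400, strong interaction, 7 replicates per method. The
full 21 × 7 × 100 factorial at p = 237 is a research run the user
launches deliberately; nothing in it differs from the shipped checks but
scale.

## Known limitations

The generator matches published marginal summaries, not the real
exposome's joint law; conclusions about method rankings transfer only to
the extent that those summaries capture what matters (the original
comparison suggests predictor correlation is the dominant driver, which
the generator does reproduce). Outcomes are linear-Gaussian with at most
two product terms and no confounders; the boosted-tree selector in
particular is evaluated on terrain that favours regression methods.
The penalized-path and boosting tuning constants not fixed by the
benchmark's description (λ rule, group weights, learning rate, holdout
estimator, screening size) are package choices, documented above and
exposed in the configuration objects — sensitivity to them is the
user's experiment, not a package constant.
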