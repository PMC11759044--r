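---
title: "Trait-mediated drivers of community stability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-mediated drivers of community stability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabsem)
```

## The scientific question

Temporal community stability — the year-to-year constancy of a community's
total abundance — is shaped by a small set of widely recognised mechanisms:
*compensatory dynamics* (species fluctuating out of phase buffer one
another), the *portfolio effect* (richer communities average over more
independent fluctuations), and *dominant species variability* (a community
dominated by volatile populations is itself volatile). Land-use intensity
(LUI) is known to erode stability, but mostly indirectly, and the causal
chain is unresolved. The working hypothesis implemented here is that
*trait-based community features* — the traits of the dominant species and
the functional diversity of the community — are the middle links: land use
filters species by their traits, and trait composition in turn moves the
stability-driving mechanisms, both within a trophic level (H1) and across
trophic levels, plants to herbivores to carnivores (H2).

`stabsem` implements the full analysis chain: community time-series metrics,
trait-based features, piecewise structural equation models (SEMs) with
directed-separation tests, evidence-ratio model reduction, and bootstrapped
effect decomposition — together with a synthetic multi-trophic landscape
generator with known causal structure, so every stage can be validated
against ground truth.

## Community time-series metrics

All metrics operate on a per-plot species × year abundance matrix
(`community_ts`): percent cover for plants, counts for arthropods. With
$x_{it}$ the abundance of species $i$ in year $t$ and $X_t = \sum_i x_{it}$:

* **Temporal stability** $= \mu(X_t)/\sigma(X_t)$, the inverse coefficient
  of variation of the yearly totals (`temporal_stability`). Sample SD
  (denominator $T-1$) throughout. Constant totals have no defined CV and are
  flagged `NA`, not $\infty$.
* **Mean richness** and **mean total abundance**: yearly species counts and
  yearly totals, averaged over years.
* **Weighted synchrony** $\eta_w = \sum_i w_i\,
  \mathrm{cor}(x_{i\cdot},\, X_\cdot - x_{i\cdot})$ — each species'
  correlation with the aggregated rest of the community, weighted by its
  share $w_i$ of the grand total (`synchrony_eta_w`). Species with zero
  temporal variance (or a zero-variance remainder) carry no defined
  correlation; they are excluded and the weights renormalised, which the
  function records in an attribute. Low $\eta_w$ is evidence of
  compensatory dynamics.
* **Weighted average population variability**
  $\mathrm{wAPV} = \sum_i \bar p_i\, \mathrm{CV}_i$, the community-weighted
  mean of species-level CVs (`wapv`). The weight $\bar p_i$ is the *mean of
  the yearly relative abundances* $x_{it}/X_t$ (zero-total years skipped);
  a variant weighting by each species' share of the grand total is
  available via `weights = "total"`, but the mean-share form is the
  default because it matches the metric's verbal definition. Two exact
  identities pin the implementation down: a single-species community has
  `stability * wapv == 1` to machine precision, and a two-species
  community's $\eta_w$ equals the Pearson correlation of the two series.

Surveyed years with zero abundance are informative zeros; years without a
survey are simply absent from the matrix and are never imputed. Plots whose
community is effectively absent are screened with `filter_min_presence`
(the analysis scripts use 8 years, two-thirds of a 12–13-year series).

## Trait-based features

Trait features are computed on the *pooled* community: each species enters
with the mean relative abundance it showed across the series
(`pool_mean_relative_abundance`), renormalised to sum to one.

* **Community-weighted means** (`cwm`): $\sum_i p_i t_i$ for quantitative
  traits; for a categorical trait, the summed relative abundance of each
  category (the proportion of the community in that category). Species
  missing a trait are dropped for that trait only, with renormalisation.
* **Balanced Gower dissimilarity** (`gower_balanced`): per-trait distances
  are range-normalised absolute differences (quantitative/ordinal) or
  averaged per-category mismatches (categorical, so a multi-level trait
  stays one trait in $[0,1]$). Traits are combined as
  $d_{ij} = \sum_k w_k d^{(k)}_{ij}$. In `balanced` mode the weights are
  the analytic solution $w_k \propto 1/\overline{d^{(k)}}$, which makes
  every trait's mean contribution $w_k \overline{d^{(k)}}$ identical —
  the balancing goal stated for unequal-contribution-corrected Gower
  distances. The analytic form is deterministic and directly testable;
  iterative optimisation over fuzzy trait groups is deliberately out of
  scope.
* **Rao's Q** (`rao_q`): $Q = \sum_{ij} p_i p_j d_{ij}$, the expected trait
  dissimilarity of two random draws — the functional-diversity metric.
* **Dominant-trait axes** (`dominant_trait_axes`): a correlation-matrix PCA
  of the plot × CWM table; the first two axes summarise the traits of the
  dominant species. Eigenvector signs are arbitrary, so each axis is
  anchored: the named anchor trait (SLA for plants, so that high PC1 reads
  "acquisitive") or, by default, the trait with the largest absolute
  loading is made to load positively. Scores are exactly centred and their
  covariance is diagonal with the eigenvalues on the diagonal — both are
  tested invariants.

For arthropods the feature sets are split by metadata role, mirroring
standard practice: Rao's Q uses the morphometric traits plus dispersal
(`metric_role = "fd"`), while the dominant-trait PCA uses the feeding-guild,
feeding-mode and stratum CWM proportions (`metric_role = "cwm_pca"`);
computing both from the same traits makes the two metrics strongly
collinear.

## The piecewise SEM engine

A causal model is a DAG plus optional correlated-error pairs, written in a
plain text syntax (`parse_model`): `y ~ x1 + x2` for directed edges,
`a ~~ b` for a free covariance. The engine then:

1. **Standardizes** every variable to mean 0, SD 1 (`standardize`), so all
   slopes are standardized effects comparable across predictors.
2. **Fits one OLS regression per endogenous node** on its parents
   (`fit_local`). Estimation is deliberately OLS-only; the local models the
   chain was designed around are linear models.
3. **Derives the basis set** (`basis_set`): one independence claim per
   non-adjacent node pair, excluding declared correlated errors and pairs
   of two exogenous variables. The claim's response is the later node in
   topological order (ties broken by declaration order, so the set is
   deterministic); the conditioning set is the union of both nodes'
   parents.
4. **Tests each claim** (`dsep_tests`) by the two-sided t-test of the other
   pair member's partial slope, and combines the claim p-values into
   **Fisher's C** $= -2\sum \ln p_i \sim \chi^2_{2k}$ (`fishers_c`). A
   global $P > 0.05$ means the data are consistent with the claimed
   structure. An empty basis set is a saturated model, reported as such
   with $P = 1$. Claim p-values that underflow to zero are clamped to the
   smallest positive double before the log — Fisher's C must not receive
   an exact zero.
5. **Scores the whole model** by
   $\mathrm{AICc} = C + 2K\,n/(n-K-1)$ (`sem_aicc`), with $K$ counting one
   slope per edge, an intercept and a residual variance per equation, and
   one parameter per correlated-error pair. Conventions differ in the
   literature, so this one is stated explicitly and tested as arithmetic.
6. **Reduces each equation** (optional, `fit_sem(..., reduce = TRUE)`): all
   $2^p$ submodels are fitted (`select_terms`), scored by the per-equation
   small-sample AICc ($\mathrm{AIC} + 2K(K+1)/(n-K-1)$), converted to
   Akaike weights, and each term's summed weight $s$ is turned into an
   evidence ratio $\mathrm{ER} = s/(1-s)$. Terms with
   $\mathrm{ER} > 2.72$ (about $e$, "a likely effect") are retained. The
   whole-model AICc of the a-priori and reduced fits are reported side by
   side. The per-equation and whole-model AICc conventions are both
   implemented; the per-equation form is used inside selection because
   selection compares submodels of a single equation.
7. **Quantifies correlated-error pairs** as the Pearson correlation of the
   two variables' equation residuals (an exogenous member enters raw),
   with a t-test p-value. Rejected claims are listed in `missing_paths` as
   candidate omitted links but are never auto-added — whether a suggested
   path is causal is a modelling decision, not an algorithmic one.

Residual normality (Shapiro–Wilk), heteroscedasticity (Breusch–Pagan) and
multicollinearity (VIF) checks are available behind
`fit_sem(..., diagnostics = TRUE)`; they warn and never gate the fit.

## Effect decomposition

On the fitted standardized coefficients, effects follow path-tracing
algebra (`path_effects`, `mediator_effect`): the **direct** effect of $x$
on $y$ is the $x$ coefficient in $y$'s equation; each directed path
contributes the product of its edge coefficients; the **indirect** effect
is the sum over paths of length two or more; the **total** effect is their
sum; and a **mediator effect** is the sum over the paths passing through a
given mediator. The totals of every pair coincide with the matrix closed
form $(I-B)^{-1} - I$, which the tests verify to $10^{-10}$ against
exhaustive enumeration on random DAGs. Correlated-error pairs contribute no
directed paths and never enter effect computation.

**Bootstrap intervals** (`bootstrap_effects`): rows are resampled with
replacement; each replicate is re-standardized and every equation refitted
with the *fixed* (already selected) structure; the queried effects are
recomputed. Intervals are bias-corrected percentile by default (plain
percentile available), the point estimate comes from the full-data fit, and
an effect is "significant" when its interval excludes zero. Selection is
performed once on the full data and then frozen — the bootstrap
characterises the uncertainty of the final model's effects, not of the
selection path. This mirrors the standard practice of bootstrapping the
reduced model; its known cost is post-selection optimism: an effect routed
through a spuriously retained edge is flagged significant somewhat more
often than the nominal 5%. Replicates with singular designs are dropped and
counted; more than 10% failures aborts. Default `n_boot = 2000`; the
analysis scripts use 200–500 for desk runtime.

## The synthetic landscape generator

Since the original field data live in a restricted repository, validation
runs on synthetic landscapes with *known* causal structure
(`simulate_multitrophic`). The generator emulates the study design — by
default 150 plots × 13 years, 40 plant, 30 herbivore and 20 carnivore
species along a uniform LUI gradient — with these mechanisms:

* each plant species carries a latent *leaf-economics score*; its SLA,
  LDMC and leaf nutrient contents are lognormal functions of the score
  (SLA up, LDMC down — the acquisitive/conservative trade-off);
  arthropods carry an analogous morphometric score;
* species presence is a LUI-dependent logistic, so richness declines with
  intensity;
* the species-by-plot mean log abundance is tilted along the trait score by
  `coupling$lui_trait` times centred LUI *plus a plot-level assembly
  deviate* (`assembly_sd`, default 0.5). The deviate represents
  composition differences no measured covariate explains (soil, history,
  dispersal); without it the plant CWM would be an almost deterministic
  function of LUI and the two would be statistically inseparable as
  predictors;
* yearly abundances are lognormal around the species-by-plot mean, driven
  by species-specific loadings on one shared yearly environmental deviate
  per plot; similar loadings mean synchronous communities. Loadings
  correlate with the trait score (`env_loading$trait_cor`, default 0.6):
  acquisitive, fast species track the environment more closely, so
  communities tilted toward them have more variable populations (higher
  wAPV) and higher synchrony *by construction* — this is the causal link
  through which trait composition reaches the stability drivers;
* herbivore composition is tilted along the realized plant CWM score and
  carnivore composition along the herbivore CWM
  (`coupling$plant_herbivore`, `coupling$herbivore_carnivore`), creating a
  genuine cross-trophic mediation path;
* plant cover is capped at 100% per species; arthropod counts are
  Poisson-lognormal (a Poisson draw around the lognormal intensity),
  overdispersed nonnegative integers like sweep-net counts.

Every generating parameter is returned in the `truth` element, so tests can
ask targeted recovery questions (e.g. zeroing `coupling$plant_herbivore`
must make the herbivore–plant CWM regression non-significant in ≥90% of
replicate landscapes — it does).

What the generator does *not* emulate: taxonomy, phenology, spatial
autocorrelation among plots, the three-region block design, observer error,
and any nonlinearity beyond the lognormal/Poisson structure. A consequence
worth knowing: the linear meta-model is *not* the generator's true model
(the fd–composition link, for instance, is a folded, nonlinear function of
the trait tilt), so at the full study scale the reduced SEMs on synthetic
landscapes often *fail* the global Fisher's C test even though every
constructed path is recovered. That is the d-separation test doing its job
on a misspecified linear approximation, and it is why the calibration tests
use data simulated from exactly linear-Gaussian SEMs instead.

## Validation strategy and problem sizes

The test suite validates each layer against an independent oracle:
literal double-loop implementations of every community/trait metric
(agreement to $10^{-12}$ on hundreds of random communities), textbook
matrix algebra for effects ($10^{-10}$), hand-enumerated model selection,
and Monte-Carlo checks of the statistical machinery — d-sep p-value
uniformity under the true model, Fisher's C rejection rate at $n = 300$
over 500 replicates inside the exact binomial 99% band around 0.05, power
≥95% against an omitted $\beta = 0.6$ edge at $n = 500$, edge-coefficient
recovery within ±0.02 over 200 replicates at $n = 2000$ with bootstrap CI
coverage in the 93–97% band, and detection (presence and absence) of the
constructed cross-trophic mediation over 50 replicate landscapes per arm at
the 150-plot study scale. These sizes were chosen so the entire suite runs
in a few minutes on one core while leaving the Monte-Carlo bands tight
enough to be informative.

## Numerical and design choices

* Sample ($T-1$) standard deviations everywhere, matching the default of
  the statistical environments these analyses are usually run in.
* OLS is solved through the QR decomposition (`lm.fit`) with explicit
  rank-deficiency errors naming the collinear terms; the Monte-Carlo-heavy
  paths (all-subsets selection, bootstrap) share this fast path.
* Zero-variance species, constant traits and constant CWM columns are
  dropped with a recorded warning rather than silently imputed.
* Evidence-ratio threshold 2.72 is the package default and a function
  argument; it corresponds to a summed Akaike weight of about 0.731.
* All randomness flows through explicit seeds: the landscape seed lives in
  its config, the bootstrap seed in the call, and written outputs carry a
  config hash plus the seed in a JSON manifest, so any table can be
  re-created exactly.

## Limitations

* Estimation is OLS-only: no mixed models (the block/region structure of
  the original design is out of scope), no GLS, no latent variables, no
  categorical endogenous variables.
* The basis-set construction conditions on the union of parents; other
  d-separation variants (e.g. conditioning on smaller separating sets)
  would give different claim sets for some graphs.
* Post-selection inference: bootstrap intervals are computed on the reduced
  structure and inherit the usual optimism (see above).
* The generator is a test harness, not an ecological forecast: passing its
  recovery tests shows the machinery is correct, not that the linear SEM is
  the right model for any particular field system.
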