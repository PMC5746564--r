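---
title: "Random-forest dasymetric mapping and covariate-class importance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-forest dasymetric mapping and covariate-class importance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the model it implements,
the choices that were genuinely open, and what the synthetic studies do
and do not demonstrate.

## 1. The population model

### Training frame

Census counts live on administrative units; covariates live on pixels.
The model is trained at the unit level: continuous covariates are
summarized by their mean over a unit's valid pixels, binary covariates by
the covered proportion, categorical covariates by per-level proportions
(`zonal_summarize()`).  The response is log population density,

$$y_i = \log\!\big(c_i / (a \cdot m_i) + \varepsilon_{\mathrm{floor}}\big),$$

with $c_i$ the unit count, $m_i$ its valid-pixel count, $a$ the pixel
area (km²) and $\varepsilon_{\mathrm{floor}} = 10^{-8}$ km⁻².  The log
keeps the dasymetric weights positive after exponentiation and tames the
heavy right tail of density data; the floor keeps zero-count units in the
training set (they carry real information — some admin units are
genuinely empty) at a finite response.  Both the transform and the
treatment of zero-count units are deliberate design decisions: neither is
dictated by the method's usual description, and both are exposed
(`density_floor`, and units can be filtered upstream).

### Forest

`fit_forest()` grows `k` unpruned CART regression trees, each on an
independent bootstrap resample of the units (n draws with replacement),
with `mtry` randomly chosen candidate variables per node.  Defaults are
the standard regression-forest settings: `k = 500`,
`mtry = max(1, floor(p/3))`, minimum terminal node size 5.  The trees are
implemented in C++ (Rcpp) inside the package rather than through an
external RF library because the importance definition below needs
per-tree bootstrap membership and per-tree predictions on *modified* OOB
data — quantities the established implementations do not expose in the
required form.  An independent implementation (`randomForest`) serves as
a cross-check in the test suite: predictions of the two forests on smooth
test functions correlate above 0.97 and their OOB R² agree closely.

Two error summaries coexist and should not be confused:

* `oob_mse` — the **average over trees of the per-tree OOB MSE**.  This
  follows the classic description of OOB error ("average the OOB error of
  all trees") and is the basis of the reported *variance explained*,
  $100\,(1 - \mathrm{oob\_mse}/\widehat{\mathrm{Var}}(y))$ (population
  variance; the value may be negative, and is flagged `NA` for a constant
  response).  Because a single tree is a weaker predictor than the
  ensemble, this is a conservative pseudo-R².
* the ensemble OOB predictions (each unit predicted by the trees that did
  not train on it), stored for `residuals()` and the cross-check tests.

### Importance: Per.Inc.m.s.e.

For tree $b$ with OOB set $O_b$ and baseline OOB error $e_b$, permuting
covariate $j$'s values within $O_b$ gives $e_{b\pi}$; the covariate's
importance is

$$\mathrm{Per.Inc.m.s.e.}_j \;=\; 100 \cdot
  \operatorname{mean}_b \frac{e_{b\pi} - e_b}{e_b},$$

averaged **only over trees that used $j$ as a split variable**.  A
covariate used by no tree scores exactly 0 (a decision — the permutation
cannot change any prediction, so 0 is the only value consistent with the
mechanism).  One permutation pass per tree is used, seed-controlled; the
estimate is noisier than a multi-pass average but matches the classical
implementation, and downstream analysis consumes only ranks.  Two
further numerical decisions: trees whose OOB set has fewer than two
units are skipped (a permutation there is vacuous), and trees with
$e_b = 0$ contribute no ratio (the relative increase is undefined).  The
per-tree relative increase is *not* divided by its standard error: the
rank-based analysis downstream makes the scaling irrelevant, and the
unscaled form matches the "average per cent increase" definition.  The
test suite re-derives every per-tree error and permuted error of small
forests with an independent R tree-walker and checks the module to
1e-12.

### Selection, weighting layer, redistribution

`iterative_covariate_selection()` repeats fit → importance → *drop all
covariates with negative importance* until none is negative or one
covariate remains (if an iteration turns everything negative at once, the
single best covariate is kept).  Termination is guaranteed because the
retained set strictly shrinks otherwise.  Each iteration's fit and
permutation seeds derive deterministically from one master seed.

The final forest, trained on zonal summaries, is applied to *pixel*
covariate values and exponentiated into a strictly positive density
weighting layer.  This train-on-zones / predict-on-pixels scale mismatch
is inherent to the dasymetric method and intentionally not "corrected";
it is the documented mechanism by which unit-level associations are
downscaled.  `dasymetric_redistribute()` then assigns
$\mathrm{pop} = c_z \cdot w / \sum_{z} w$ within each zone; zones whose
weights sum to zero (possible only for degenerate weight inputs, since
$e^x > 0$) fall back to uniform allocation so that mass conservation
holds for *every* input.  Conservation is exact up to floating point
(per-zone relative error below 1e-9 in all tests).

## 2. WIR and class standardization

Covariate names are mapped to 18 standardized variable classes by an
ordered, case-insensitive pattern list shipped as an editable CSV
(`inst/extdata/covariate_classes.csv`); the first matching row wins, so
specific patterns ("non-residential") precede general ones
("residential").  Unmatched names soft-fail to `"unclassified"`; both
`"unclassified"` and the bookkeeping class `"no data"` are retained in
tables but excluded from hypothesis tests.  The class vocabulary keeps
"classified populated place" (hierarchical settlement classes) and
"populated place" (gazetteer points) separate; users who consider them
one class can merge them by editing the map.

Within a country with $n$ final covariates, ranks descend by
Per.Inc.m.s.e. (average ranks for ties) and

$$\mathrm{WIR} = \frac{\mathrm{rank} - 1}{n - 1}, \qquad
  \mathrm{WIR} = 0 \text{ for } n = 1.$$

This is the unique linear map placing the most important covariate at 0
and the least important at 1; with ties at an extreme the average rank
pulls the endpoint inward (e.g. importances $\{5,5,1\}$ give WIR
$0.25, 0.25, 1$), which is accepted rather than renormalized — the tied
covariates genuinely share a rank.

## 3. The comparison designs

All tests operate on joint mid-ranks with tie corrections, since WIR
values tie heavily (small $n$ per country puts WIR on a coarse lattice):

* Kruskal–Wallis: $H = [\frac{12}{N(N+1)}\sum_j R_j^2/n_j - 3(N+1)]/C$,
  $C = 1 - \sum_t (t^3-t)/(N^3-N)$, $p$ from $\chi^2_{k-1}$.  All values
  tied gives $H = 0$, $p = 1$.
* Dunn: $Z_{ij} = (\bar R_i - \bar R_j)/\sqrt{(\frac{N(N+1)}{12} -
  \frac{\sum_t t^3 - t}{12(N-1)})(\frac1{n_i}+\frac1{n_j})}$, two-sided
  normal p-values.
* Holm's step-down correction, applied **within one test family** (the
  pairwise set of a single Kruskal–Wallis gate), not jointly across
  designs: each reported table stands on its own family-wise error rate.

Four designs mirror the hierarchical analysis: global (classes pooled
across all countries), inter-regional (one class, regions as groups),
intra-regional between countries (one region and class), and
intra-regional between classes (one region).  The Dunn follow-up runs
only when its gating Kruskal–Wallis is significant at α = 0.05; scopes
with fewer than two non-empty groups are reported as *untestable* rather
than erroring, so full study sweeps always complete.  Whether the
between-class tests should pool all covariate rows or first take
per-country medians is ambiguous; the package pools rows by default and
exposes `aggregate = "country-median"` as a switch.

## 4. The synthetic-country generator

The generator exists so that every downstream stage is testable offline
with planted, known structure.  A `landscape_spec` fixes the grid, the
pixel area (default 0.01 km², a 100 m analog), the number of zones, the
covariate set and the generating model

$$\log \lambda(s) = \beta_0 + \sum_k \beta_k z_k(s) + \epsilon(s),
  \qquad \epsilon \sim N(0, \sigma^2)\ \text{i.i.d.},$$

with $z_k$ the per-covariate standardization over valid pixels.  Noise is
on the log scale — multiplicative on density — because densities are
positive and heavy-tailed.  Census counts are zonal integrals of
$e^{\log\lambda} \cdot a$, rounded half-to-even; zero-count zones are
legal and exercised.  Admin zones are nearest-seed (Voronoi) partitions
of random seed pixels: irregular, size-heterogeneous, contiguous units
whose area spread resembles real census geographies without vector
machinery.  Covariate kinds emulate the usual predictor families:
thresholded smooth fields (binary extents), Euclidean distance
transforms of random polylines (roads, rivers), Gaussian-smoothed white
noise (lights, elevation, climate), gradient magnitudes (slope), and
quantile-binned fields (categorical land cover, entering the generating
model through standardized level codes — an ordinal simplification —
and the feature tables as per-level indicators).

What the generator does **not** emulate: the spatial autocorrelation of
its fields is a free smoothness knob calibrated to no particular
country; covariates are generated independently of each other (real
predictors are strongly collinear); census counts carry no enumeration
error; and zone boundaries ignore terrain.  Passing tests therefore
demonstrate the *mechanics* — conservation, selection behaviour, rank
statistics, calibration — not predictive skill on real data.

## 5. Packaged study designs and problem sizes

Chosen once as realistic small-study analogs, and used at these sizes by
the tests and the acceptance script:

* `landscape_demo` — 40×40 px, 150 zones, 8 covariates (6 with nonzero
  coefficients); `study_demo`: 4 regions × 3 countries, between-country
  coefficient jitter `beta_sd = 0.1`.
* `landscape_recovery` — 60×60 px, 300 zones, 3 planted drivers
  (β = 1.2, 1.0, −0.8; σ = 0.2) among 7 zero-coefficient covariates;
  the recovery benchmark asks that the planted drivers survive selection
  and hold the top three ranks across 50 seeds.
* `landscape_null` — 20×20 px, 40 zones, 8 covariates with modest
  coefficients (σ = 0.3); `study_null`: 4 regions × 8 countries with
  *identical* coefficients everywhere, the exchangeable null.  The
  calibration check runs 500 replicate studies (forest size 50) and
  pools the per-class inter-regional Kruskal–Wallis rejections.

Two statistical facts shaped the null design, established by simulation
before the checks were frozen.  First, with few countries per region the
$\chi^2$ approximation of the tie-corrected Kruskal–Wallis is
conservative on the WIR lattice (rejection ≈ 0.02 at 3 countries/region);
eight countries per region — the size of the comparative design this
emulates — brings the size to ≈ 0.045.  Second, few covariates per model
coarsen the WIR lattice and deepen the conservatism, so the null
landscape carries eight covariates, matching the ~9–13 covariates of
typical country models.

Intercepts default to 7 on the log-density scale (≈ 1100 persons/km²)
so that zones of a dozen 0.01 km² pixels hold enough people for integer
rounding to be negligible relative to the model signal.

## 6. Known limitations

* The importance of correlated covariates is shared and
  context-dependent; permutation importance under collinearity inherits
  the usual caveats, and the generator's independent covariates sidestep
  rather than solve this.
* Variance explained based on tree-averaged OOB error underestimates the
  ensemble's accuracy by construction; comparisons with ensemble-based
  R² values should expect a downward shift.
* The chi-squared approximation is used for all Kruskal–Wallis p-values,
  including small, heavily tied samples where it is conservative; no
  exact permutation option is provided.
* Grid I/O is ESRI ASCII (plain text, GIS-readable); no GeoTIFF writer
  or coordinate reference system handling is included.
* The scale mismatch between zonal training and pixel prediction means
  pixel weights extrapolate beyond the covariate ranges seen in
  training; regression trees clamp rather than extrapolate, which bounds
  but does not remove the effect.
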