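---
title: "Event-boundary fMRI statistics and imaging genetics with eventconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-boundary fMRI statistics and imaging genetics with eventconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

When people watch a continuous movie, cortical and hippocampal activity is
punctuated at *event boundaries* — moments where observers agree that one
meaningful episode has ended and another begun. Two signatures are well
established: a transient univariate BOLD increase in hippocampus and
posterior default-mode network (DMN) regions, and a transient increase in
*coactivation* (pairwise coupling) among posterior DMN regions. Because
these same regions degrade early in Alzheimer's disease, a natural
imaging-genetics question is whether carriers of the APOE ε4 risk allele
show altered boundary responses across the adult lifespan, and — when they
do not — how much evidence the data provide *for* that absence.

`eventconn` implements the full ROI-level analysis chain for this question:
nuisance cleaning and prewhitening of ROI time series, consensus boundary
definition from observer annotations, boundary-locked activation and
PPI-style coactivation statistics, genotype × age linear models with
Zellner–Siow Bayes factors, permutation-tested genotype classification, and
brain-network system segregation. A synthetic-data generator emulating a
movie-watching cohort design (193 volumes at TR = 2.47 s, adults aged
18–88, ε4+ vs ε3/ε3 groups) makes every stage testable without access to
any managed dataset.

```{r setup}
library(eventconn)
```

## Event boundaries and the transition vector

Boundary annotations are modelled as observer × onset records. Candidate
boundaries are single-linkage clusters of clicks (tolerance one TR by
default, 2.47 s; the grouping rule for clicks is not part of the published
record, so it is a package decision), and a candidate is retained when at
least `ceiling(threshold * n_observers)` distinct observers contributed —
with the default 50% threshold and 16 observers, 8 clicks keep a boundary
and 7 do not.

Retained onsets become a per-volume indicator. For an onset $t$ the
transition period is $[t - 2\,\mathrm{TR},\; t + 2\,\mathrm{TR}]$, shifted
forward by 2 TRs (≈5 s) for the hemodynamic lag:

```{r}
transition_window(30, tr_s = 2.47, window_tr = 2, lag_tr = 0)  # pre-shift
transition_window(30, tr_s = 2.47, window_tr = 2, lag_tr = 2)  # applied
```

A volume is marked when its onset time ($i \cdot \mathrm{TR}$, 0-based $i$)
falls in the half-open applied window $[\mathrm{start}, \mathrm{end})$.
The half-open convention is a deliberate numerical choice: it makes the
window arithmetic exactly representable, is independent of volume order,
and gives each disjoint ±2 TR window exactly 4 volumes. Overlapping
windows are unioned; onsets outside the scan are rejected by name.

## Nuisance regression, filtering, and prewhitening

Each subject's ROI series is cleaned with a single least-squares model
containing an intercept, 32 confound regressors — six motion parameters
plus white-matter and CSF means, their backward-difference temporal
derivatives (leading 0, the SPM convention; the difference scheme is
another package decision), their squares, and squared derivatives — and a
discrete-cosine high-pass set at 0.008 Hz, so filtering and confound
removal happen simultaneously rather than sequentially. The DCT set
contains the $K = \lfloor 2 \, n_\mathrm{vols} \, \mathrm{TR} \cdot
f_c \rfloor$ non-constant cosines at or below the cutoff (7 columns for a
193-volume scan at TR 2.47 s); collinear columns are pivoted out with a
warning.

Residual autocorrelation is modelled as a nonnegative mixture of eight
exponentials with half-lives 0.5, 1, 2, 4, 8, 16, 32 and 64 TRs plus a
white component, fit to the empirical autocovariance (lags 0–128) by
nonnegative least squares. NNLS is our choice among the estimators the
published description leaves open; it is fast, respects the nonnegativity
that keeps the implied covariance positive definite, and is exercised by a
Monte-Carlo oracle in the tests. One pooled model per subject is fit on
the ROI-averaged autocovariance by default (`pooled = FALSE` gives per-ROI
models). Whitening multiplies by the inverse Cholesky factor of the
implied stationary Toeplitz covariance, computed by the Levinson–Durbin
recursion, so each output sample is a normalised one-step prediction
error; a relative ridge of $10^{-6}$ on the lag-0 autocovariance guards
positive definiteness. White input therefore passes through as a pure
rescaling, and AR(1) input at $\rho = 0.5$ comes out with lag-1
autocorrelation within ±0.03 of zero at $T = 10{,}000$ (verified in the
test suite).

## Boundary metrics

**Univariate response.** The default estimator is the window-mean
contrast — mean whitened signal over transition volumes minus mean over
within-event volumes — which is linear, assumption-light, and exactly 0
for constant input. An HRF-based alternative (`"hrf-glm-beta"`, canonical
double-gamma) is available because the published quantity names the
contrast but not the estimator.

**Coactivation.** For each ROI pair a logistic regression predicts the
transition indicator from the two z-scored signals and their product;
the product-term coefficient is the boundary-locked coupling change,
as in psychophysiological-interaction analysis. Z-scoring before the
product makes the statistic invariant to additive shifts and symmetric in
its arguments. Detected separation triggers a refit with an L2 penalty of
1.0 on the slope coefficients; such values are flagged and their SEs
(taken from the unpenalised information) should be read cautiously.

**ROI definition.** `select_coactive_cluster()` merges atlas parcels into
super-regions when their group-mean coactivations are all positive among
each other and with the hippocampus, by exhaustive subset search (≤ 20
candidates; ties on size break toward larger total coactivation). Spatial
contiguity is *not* enforced — ROI-level inputs carry no geometry — which
is a documented limitation relative to an atlas-based workflow.
`merge_rois()` averages member series per volume, unweighted.

## Genotype × age models and Bayes factors

For each dependent variable $y$ (one value per subject) the model is

$$y \sim \beta_0 + \beta_1 z(\mathrm{age}) + \beta_2 z(z(\mathrm{age})^2)
 + \beta_3\,\mathrm{APOE} + \beta_4\,\mathrm{APOE} \times z(\mathrm{age})
 + \beta_5\,\mathrm{APOE} \times z(z(\mathrm{age})^2)$$

with APOE coded 1 for ε4+ (ε3/ε4 and ε4/ε4 collapsed) against the ε3/ε3
reference and ε2 carriers excluded. The quadratic regressor is the square
of z-scored age, itself re-z-scored — the most literal reading of
"z-score all regressors of interest" — rather than an orthogonal
polynomial; the two differ only in how shared variance is attributed
between the age terms. Outliers are removed per dependent variable by the
1.5 × IQR rule on residuals from a quadratic age fit (fences collapse to a
point under zero IQR, so identical values are never flagged; a
floating-point tolerance prevents flagging pure rounding jitter around an
exact fit). Terms are tested with two-tailed t-tests on the residual df
and p-values are left uncorrected, matching the modelling tradition the
package follows.

Evidence *for* absent genotype effects is quantified with BF$_{01}$, the
Bayes factor of the term-absent over the term-present model under a
Zellner–Siow prior: a g-prior on standardised coefficients with
inverse-gamma(1/2, $n r^2/2$) mixing, i.e. a Cauchy prior of scale $r$ on
the standardised effect. The prior scale defaults to $r = \sqrt{2}/2$ —
the conventional "medium" scale for standardised effects; the published
analysis does not state its prior, so this default is prominent and
adjustable. The marginal over $g$ is evaluated by adaptive quadrature on a
bounded transform (relative tolerance $10^{-10}$); a seeded Monte-Carlo
estimator over the $g$ prior (`method = "mc"`) provides an independent
sampling-based route in the spirit of the original MCMC analysis. The
quadrature agrees with a determinant-route numerical integration of the
same marginal to well within 5% on fixture data, and on null simulations
BF$_{01}$ exceeds 1 in over 80% of replicates and grows with $n$.

## Classification and system segregation

The exploratory classifier asks whether the full coactivation matrix
carries any genotype information: lower-triangle vectorised features, a
linear-kernel SVM (cost 1), stratified k-fold cross-validation (default
k = 5; fold count and SVM settings are unpublished, so these are package
defaults), with features standardised inside training folds only.
Performance is balanced accuracy (mean of per-class recalls, chance 0.5
under any imbalance) pooled over folds; significance comes from re-running
the entire cross-validation on label permutations (default 5000) with
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n_\mathrm{perm})$,
which is never zero.

System segregation summarises whole-scan modularity after global signal
regression: $\mathrm{SyS} = (\bar r_\mathrm{within} -
\bar r_\mathrm{between}) / \bar r_\mathrm{within}$ over off-diagonal
Pearson correlations. Raw correlations are averaged with negatives
retained by default — the published formula names neither choice — with
Fisher-z averaging and negative truncation exposed as toggles. When the
within-network mean is not positive the ratio is meaningless and the
result is flagged undefined rather than reported; with few ROIs global
signal regression forces mean correlations negative, so segregation is
only meaningful for reasonably sized parcellations.

## What the generator emulates

`sim_config()` encodes the emulated design: 193 volumes at TR 2.47 s,
ages uniform on 18–88 (the published cohort reports a range and mean
only; a uniform draw gives stable leverage for the quadratic term),
genotype frequencies 0.583 / 0.253 / 0.016 / 0.148 for ε3/ε3, ε3/ε4,
ε4/ε4 and ε2 carriers — the proportions implied by a genotyped sample of
499 that retains 425 after ε2 exclusion — twelve boundary onsets in the
~8-minute scan, and a genotype effect of zero by default, because the null
is the design's reference condition. Per ROI the signal is a boxcar over
the lag-shifted transition window (HRF convolution optional) with
amplitude modulated by an age polynomial and the genotype effect, plus
AR(1) noise whose innovations share (i) a common factor over designated
ROIs whose weight switches between `baseline_rho` within events and
`boundary_coact_rho` (default 0.3) at transitions, and (ii) a per-network
factor (`within_network_rho`, default 0.3, two contiguous equal halves)
that provides the modular structure a segregation analysis presumes, plus
small mixtures (≤ 0.3 of the noise SD) of eight smoothed random-walk
confound sources. Because the published work reports no numerical effect
sizes for these quantities, the defaults are realistic round numbers
chosen once, not calibrations to any dataset.

What passing tests therefore show is that every stage *recovers what was
injected* under the design's geometry — not that real BOLD data meet the
generator's assumptions. Real data have HRF dispersion, non-Gaussian and
non-stationary noise, spatially structured motion artefacts, and
genotype–age sampling imbalances that the generator deliberately omits,
along with everything upstream of ROI extraction (multi-echo denoising,
realignment, normalisation), which is out of scope.

## Validation scale and reproducibility

The test suite fixes every random seed and validates at sizes chosen to
make the statistical oracles sharp yet quick: 1000 null replicates
(n = 400) for per-term type-I error within [0.035, 0.065]; 500 replicates
of 199-permutation tests (48 subjects, 2 folds) for p-value uniformity;
100 replicates at 5000 volumes for PPI sign recovery, plus one dense
grid-search MLE comparison at $10^{-3}$; 200 null replicates for
BF$_{01}$ consistency; and 20 end-to-end cohort runs (400 subjects, 4
ROIs) confirming that every genotype term's median BF$_{01}$ exceeds 1
under a null simulation. `scripts/acceptance.R` recomputes the
deterministic design quantities (window edges, 32 confound columns, 8
half-lives, 134/425 grouping counts) from a fresh run of the package.

## Known limitations

* The boundary injection uses the analysis-side window, so amplitude
  round-trips are exact by construction; HRF-convolved injection tests
  the mismatch case instead.
* The all-positive coactivation merge rule ignores spatial contiguity.
* Negative within-network means leave SyS undefined; small parcellations
  after global signal regression routinely hit this.
* BF$_{01}$ values depend on the Cauchy prior scale; report $r$ alongside
  any Bayes factor.
* The penalised-logistic fallback reports unpenalised SEs, which are
  optimistic near separation.
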