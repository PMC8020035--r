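---
title: "Methods: paired urinary 1H NMR metabolomics with urometab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired urinary 1H NMR metabolomics with urometab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`urometab` implements an end-to-end analysis for small paired-design
urinary ^1^H NMR metabolomics studies: each subject contributes one
urine spectrum at each of two timepoints, and the questions are (i)
which spectral bins change between timepoints, (ii) how well a small
bin panel discriminates the timepoints, (iii) whether bin levels or
their changes track a clinical recovery score, and (iv) which metabolic
pathways the altered metabolites implicate. This vignette records the
models, the tunable parameters, and the design decisions behind each
stage, in the order the pipeline runs them.

## The synthetic cohort and what it does (not) emulate

Real studies of this kind rarely deposit raw spectra, so the package is
exercised end to end on simulated cohorts with known ground truth.
`generate_spectrum()` builds a frequency-domain spectrum as a sum of
per-metabolite Lorentzian lines (the natural NMR lineshape; a Gaussian
option exists behind `lineshape`), each line scaled by concentration
times a library intensity, plus optional constant baseline and
pointwise Gaussian read noise. Chemical-shift jitter is drawn once per
metabolite per sample, not per peak, because pH-driven shifts move
whole multiplets coherently. The default axis is 0.5–9.5 ppm on 2048
points: dense enough that adaptive binning is non-trivial, small enough
that a cohort simulates in well under a second.

`generate_cohort()` layers a lognormal concentration model on top:
log-concentration = log baseline + subject random effect (SD 0.35
natural-log units ≈ 40% CV, a typical between-subject spread for urine)
+ planted timepoint effect + within-subject biological noise (SD 0.28
≈ 30% CV). The planted defaults are three purine metabolites
(hypoxanthine, inosine up; xanthine down) at ±0.7 natural-log units,
i.e. about two-fold changes — the magnitude a urine NMR study would
call a clear biomarker, and deliberately not so large that a single bin
separates the classes perfectly. A SCIM-like 0–100 clinical score is
generated with improvement linearly coupled to the initial hypoxanthine
level (−25 points per log10-unit, noise SD 4 points) and clipped to the
scale, which makes Pearson correlation the correct recovery estimand.

`simulate_bin_matrix()` generates the same paired structure directly at
the bin level (log10 units: planted effects 0.30 ≈ two-fold, subject SD
0.15, sample noise 0.12). It exists because several calibration studies
are posed at realistic bin counts (hundreds of bins), while 2048
simulated points cannot resolve hundreds of distinct peaks; with the
default peak library the spectral pipeline yields roughly 40–70 signal
bins, and the bin count is data-dependent, never a contract.

What the simulation does *not* emulate: baseline distortions and phase
errors (spectra are assumed to enter fully processed), peak overlap
beyond what the library encodes, non-lognormal concentration
distributions, and diet-driven covariance between metabolites. Passing
tests therefore demonstrate that the statistics recover planted truth
under realistic noise magnitudes, not that any specific real cohort
would reproduce.

## Spectral processing

`align_to_reference()` performs recursive segment-wise alignment: the
segment is shifted by the integer offset (within ±`max_shift`, default
0.02 ppm) maximizing cosine cross-correlation with the reference, then
split at its lowest interior point and each half aligned recursively
down to `min_segment` (40 points). Ties break toward the smaller
|shift|; vacated points are filled with edge values, so total intensity
is preserved up to the padding contribution (asserted ≤ 1% in tests).
A segment whose best attainable correlation stays below 0.5 is left
unshifted and flagged — a displacement beyond the search window should
be reported, not half-corrected. The reference is the cohort mean
spectrum, recomputed once after a first alignment pass.

`adaptive_bin()` places bin boundaries at local minima of the
moving-average-smoothed mean spectrum (window 11 points). The published
adaptive-binning and alignment algorithms this stage follows are
wavelet-based in their sources; the moving average is a deliberate,
documented simplification with the same intent — boundaries at troughs
— that keeps every boundary decision reproducible by a brute-force
minimum search in the tests. Contiguous regions whose smoothed maximum
never exceeds `noise_threshold` become excluded noise bins; the default
threshold is five times the point-noise estimate
`mad(diff(x))/sqrt(2)`, which is insensitive to how much of the axis
carries signal (a plain MAD of the intensities inflates badly on
peak-dense spectra). Signal bins narrower than `min_width` (0.01 ppm)
merge across their weaker boundary. Manual bin correction is realized
as a reproducible edit script (`apply_manual_edits()`: merge / split /
exclude), not an interactive step.

Integration is trapezoidal on the shared grid; adjacent bins share
their boundary point, so splitting a bin conserves the integral
exactly.

## Preprocessing

The order is fixed: total-metabolome normalization (excluding noise
bins and the water 4.5–5.0 and urea 5.5–6.0 ppm windows, both
configurable) so every retained row sums to one; then `log10(x + eps)`
with `eps` = half the smallest positive value (zero-safe, recorded);
then pareto scaling (centre, divide by the square root of the sample
SD). Log base 10 and the half-minimum offset are conventional
metabolomics choices; the (n−1) SD is used throughout. The recorded
per-bin means and SDs invert the scaling exactly, and the normalized
(unscaled) matrix is kept alongside because the clinical correlation
stage works on normalized concentrations, not pareto-scaled ones.

One consequence worth knowing: total-area normalization couples bins
(closure). If planted metabolites change while all other noise is
nearly zero, *every* normalized bin shifts detectably between
timepoints. That is correct arithmetic, not a bug; the low-noise
end-to-end test keeps biological noise above the closure shift for
exactly this reason.

## Univariate screen

For each bin, the Shapiro–Wilk test is applied to the paired
differences — the quantity whose normality the paired t-test actually
assumes — and routes to a paired t-test when p > 0.05, otherwise to the
Wilcoxon signed-rank test. The signed-rank test is implemented in the
package with tied midranks and an exact null distribution by
convolution over doubled ranks for n ≤ 25, because the standard
implementation abandons exactness under ties while the test suite
demands exact agreement with 2^n sign-flip enumeration. Bins with
identical differences are reported untestable rather than forced
through either test. No multiplicity correction is applied at this
stage; the significant set feeds the multivariate stage, and only the
clinical correlations are Bonferroni-controlled.

## Multivariate models

OPLS-DA codes the classes −1/+1, removes `n_orthogonal`
orthogonal-signal-correction components (X-variation uncorrelated with
y), then fits one predictive PLS component; with zero orthogonal
components it reduces exactly to single-component PLS1-DA, which the
tests assert to 1e-8. R²Y is the fraction of class variance explained
on the training fit; Q² comes from double (nested) cross-validation:
the outer loop holds out samples, the inner loop picks the orthogonal
count (0–3; deeper models are unstable at n ≈ 12) by inner-CV Q², the
whole validation repeats three times with fresh fold assignments so
every sample is held out several times, and Q² = 1 − PRESS/TSS pooled
over all held-out predictions. The repetition removes most
fold-assignment noise, which at small n is comparable to the
data-driven part of Q².

Two choices matter on paired data and are worth stating plainly:

* **Folds hold out whole subjects.** With sample-level folds, a held-out
  sample's within-subject twin remains in training, and the shared
  subject random effect makes held-out PLS predictions *anti*-correlated
  with the label; with hundreds of bins this artifact is large enough to
  invert variable selection. Every cross-validated quantity in the
  package accepts a `subject` argument and the pipeline uses it
  throughout. When a class has fewer members than the fold count, folds
  collapse to leave-one-out (over subjects), which also guarantees every
  sample is held out at least once.
* **Permutation tests.** p = (#{permuted ≥ observed} + 1)/(n_perm + 1),
  2000 permutations by default. R²Y permutations refit the full model;
  Q² permutations re-run the outer CV with the orthogonal count fixed at
  the observed model's choice rather than repeating the inner selection
  per permutation — a two-order-of-magnitude saving whose effect on the
  null is conservative (the permuted models are denied the chance to
  re-tune).

Heat-map ordering uses Euclidean distance with Ward (`ward.D2`)
linkage on rows and columns, matching common metabolomics-suite
defaults; the merge sequence is verified against a Lance–Williams
brute-force oracle in the tests.

## VIAVC variable selection

Importance of a bin is the gain in cross-validated AUC when it is
included in random bin subsets: a binary Bernoulli(0.5) matrix with 500
rows defines the subsets (all-zero rows are redrawn), each row's subset
is scored by subject-grouped CV single-component PLS-DA AUC (oriented
≥ 0.5), and importance = mean(AUC | included) − mean(AUC | excluded).
Measured directly, a single such round cannot rank a handful of true
bins among hundreds: with ~250 bins per subset, including one
informative bin moves the subset AUC by ~0.01, below the resampling
noise at 500 rows. The ranking therefore eliminates the lower-scoring
half of the bins and re-runs the round while more than `max_round_bins`
(30) remain — the iterative-elimination structure of the published
selector — and the final round ranks the survivors; eliminated bins
follow in reverse elimination order.

Per-bin categories are calibrated by max-statistic label permutation:
the labels are permuted 20 times, the final round re-run each time, and
a bin is `positive` only if its importance exceeds the largest
importance *any* bin reached in *every* permuted round (family-wise
level 1/21). A per-bin include-vs-exclude rank test is unusable here —
each bin's chance association with the labels is fixed in the data, so
under label noise such a test confidently flags the largest chance
association — and a robust z-score against the other bins fails too,
because the null importance distribution is heavy-tailed (measured null
maxima of 1.3–4.6 robust SDs versus ~12 for a planted bin).

The best subset evaluates the nested heads top-1 … top-`max_k` (10) of
the ranking by CV-AUC and takes the maximizer, ties toward fewer bins.
The top-19 head of the ranking is the list the clinical correlation
stage screens.

## Biomarker evaluation

ROC curves are computed as tie-grouped step curves whose trapezoidal
area equals the rank (Mann–Whitney) AUC to 1e-12; the confidence
interval is a stratified percentile bootstrap (2000 resamples,
within-class resampling so no draw loses a class). Note the null
spread of a *cross-validated* AUC at n = 40 is about 0.14 — wider than
the in-sample AUC's ~0.10 — which the calibration tests acknowledge
with two-SD bands. Panel accuracy fits the first k panel bins per
training fold, thresholds the training predictions at the maximum
Youden index (ties toward the smallest threshold), and pools held-out
classifications. `panel_example_cohort()` is a hand-constructed
12-sample cohort in which two informative bins leave exactly one
sample misclassified and a third resolves it, stepping the nested
accuracies 92% → 100% with AUC 1 and bootstrap CI 1–1.

## Clinical correlations

The SCIM percent difference is 100·(post − pre)/((post + pre)/2) —
antisymmetric under swapping the scores. The metabolite delta follows
the convention initial − post (the stated sentence convention of the
analysis this mirrors, even though it inverts the usual sign); the
opposite convention is available behind an argument. For each of the
top-19 F-ranked bins and each predictor family (initial level; delta),
Pearson R against the percent difference is computed with the exact
t-transform p-value (df = n − 2), and each family is Bonferroni
corrected over the 19-bin list (α/19); pooling both families into one
38-test family is available behind `pool_families`. At n = 6 the screen
is honest but underpowered — the sign-recovery tests therefore run at
n = 30, where the planted negative coupling is recovered among the
significant hits in ≥ 16/20 seeds.

## Pathway analysis

Over-representation is the exact hypergeometric upper tail
P(X ≥ k) for k hits among n significant compounds against a background
universe; topology impact is the sum of betweenness centralities of the
matched nodes over the pathway's total (falling back to degree
centrality when betweenness is identically zero, and to the matched
fraction for edgeless graphs). The pathway library is a bundled JSON
fixture of about a dozen small toy graphs — including purine- and
tyrosine-metabolism-shaped ones — because a live database dependency
would make the analysis untestable and version-unstable; the file is
explicitly labelled synthetic. Compound mapping from bins is an
explicit input (`assign_bins()` maps a bin to the strongest library
peak it contains), never inferred from data. No multiple-testing
correction is applied to pathway p-values by default, matching raw
per-pathway reporting; Holm adjustment is available behind a flag.

## Pipeline, determinism, and problem sizes

`run_pipeline()` chains the stages — simulate (or load) → align → bin →
preprocess → univariate → VIAVC → PCA/OPLS-DA/heat map on the *union*
of the univariate-significant bins and the VIAVC best subset → ROC on
the best subset → correlations on the top-19 bins → pathway screen on
the significant compounds — writing each stage's artifacts as CSV plus
a JSON manifest (stages, parameters, seed, headline statistics). Every
stochastic step flows from one seed; re-running a configuration
reproduces byte-identical numeric outputs, which the tests assert
file-by-file.

Test and acceptance problem sizes were chosen so the full suite runs in
minutes on one core: 60-replicate generator calibrations, 100-replicate
null Q² studies, 200-replicate permutation calibrations, 20-seed
recovery studies at 500 bins, and 2000 permutations only where a single
model is involved. Each such size is stated in the test that uses it.

## Known limitations

* The adaptive binner is a trough-placing moving-average variant, not a
  wavelet implementation; on heavily overlapped multiplets it merges
  more aggressively than the wavelet original would.
* OPLS-DA is two-class only, with a single predictive component; no
  S-plots or multi-class extensions.
* The Q² permutation null is mildly conservative (fixed orthogonal
  count, see above).
* Closure from total-area normalization couples bins; correlations on
  normalized concentrations inherit that coupling, as they do in any
  total-normalized metabolomics analysis.
* At n = 6 subjects the clinical screen's power is low; the package
  reports honest p-values rather than pretending otherwise.
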