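# urometab

Paired urinary ¹H NMR metabolomics in R: spectral binning and
alignment, total-metabolome normalization, paired univariate screens,
OPLS-DA with double cross-validation and permutation testing,
AUC-driven variable selection (VIAVC), ROC evaluation of biomarker
panels, clinical-score correlation, and pathway topology analysis —
with a synthetic-cohort generator so the whole chain is testable
without any external data.

## Who this is for

Small paired-design biofluid NMR studies: each subject contributes a
spectrum at two timepoints (e.g. early after a spinal cord injury and
at follow-up), and the analysis must say which spectral bins changed,
how well a small bin panel separates the timepoints, whether bin
levels track a clinical recovery score such as the SCIM (Spinal Cord
Independence Measure, 0–100), and which metabolic pathways are
implicated. At n ≈ 6 subjects every statistic here is chosen for honest
behaviour at tiny sample sizes: exact Wilcoxon null distributions,
subject-grouped cross-validation folds, permutation p-values with the
add-one rule, and Bonferroni-controlled correlation screens.

## The methods in brief

* **Binning** — boundaries at local minima of the smoothed cohort mean
  spectrum; sub-width bins merged; below-noise regions excluded;
  recursive segment-wise alignment against the cohort mean beforehand.
* **Preprocessing** — rows normalized to the total metabolome
  (water/urea windows excluded), log₁₀ with half-minimum offset,
  pareto scaling (x − mean)/√SD.
* **Univariate** — Shapiro–Wilk on paired differences routes each bin
  to a paired t-test or an exact Wilcoxon signed-rank test.
* **OPLS-DA** — one predictive component after removal of
  y-orthogonal components; R²Y on the fit, Q² = 1 − PRESS/TSS from
  double (nested) ten-fold cross-validation; both tested by label
  permutation, p = (#{perm ≥ obs} + 1)/(n_perm + 1).
* **VIAVC** — importance of a bin = gain in cross-validated AUC when it
  is included in random Bernoulli(½) bin subsets, with iterative
  halving of the bin list and max-statistic permutation calibration of
  the significance categories; the best subset is the nested head of
  the ranking maximizing CV-AUC (ties → fewer bins).
* **Clinical correlation** — SCIM percent difference
  100·(post − pre)/((post + pre)/2) against initial bin levels and
  deltas (initial − post), Pearson R with exact t p-values, Bonferroni
  α/19 over the top F-ranked bins.
* **Pathways** — exact hypergeometric over-representation plus
  relative-betweenness topology impact over a bundled (synthetic)
  pathway graph library.

## Worked example

```r
library(urometab)

# the bundled six-patient SCI pilot cohort
cohort <- sci_pilot_cohort()
s <- improvement_summary(cohort)
sprintf("SCIM improvement: %.1f +/- %.1f points", s$mean, s$sd)
#> "SCIM improvement: 10.8 +/- 10.4 points"
sprintf("age: %.0f +/- %.0f years", mean(cohort$age), sd(cohort$age))
#> "age: 55 +/- 20 years"
sprintf("pct diff (77 -> 100): %.2f%%", scim_pct_diff(77, 100))
#> "pct diff (77 -> 100): 25.99%"

# a full synthetic run: 6 subjects x 2 timepoints, three planted
# purine biomarkers (~2-fold changes) among ~60 bins
run <- run_pipeline(NULL, cohort_config(seed = 1),
                    n_perm = 499, viavc_rows = 200)
summary(run)
#> Paired urinary NMR metabolomics run
#>   samples: 12   bins: 63 (46 signal)
#>   univariate-significant bins: 10
#>   VIAVC best subset: bin036 (CV-AUC 1.000)
#>   OPLS-DA: R2Y = 0.911 (p = 0.004), Q2 = 0.773 (p = 0.004)
#>   ROC AUC = 1.000, 95% CI 1.000-1.000
#>   significant clinical correlations: 0
#>   top pathway: Purine metabolism (p = 0.0212, impact 0.87)
```

Reading the output: the paired screen flags the planted purine bins
(plus the expected handful of α = 0.05 false positives), VIAVC's best
subset is a single hypoxanthine bin because one bin already reaches
CV-AUC 1 at this effect size and the selector is parsimonious under
ties, the OPLS-DA separates the timepoints strongly (R²Y ≈ 0.91) and —
more importantly — predicts held-out subjects (Q² ≈ 0.77, permutation
p ≈ 0.004), and the purine-shaped pathway tops the screen. No
clinical correlation survives Bonferroni at n = 6; that is the honest
answer at this sample size (the sign-recovery tests run at n = 30).
Passing `out_dir` writes every stage's CSV artifacts plus a JSON
manifest, and re-running the same configuration reproduces them
byte-for-byte.

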