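---
title: "Discovering serum protein panels in multi-site case-control cohorts"
author: "seropanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering serum protein panels in multi-site case-control cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seropanel)
```

## The problem

Broad serum proteomic platforms report hundreds of protein analytes per
sample as relative fluorescence units (RFU). Given a case-control cohort
collected at several clinical sites, the goal is to find a small panel of
proteins whose joint distribution discriminates cases from high-risk
controls, while guarding against the two classic failure modes of such
studies: overfitting (too many analytes, too few samples) and
preanalytical artifacts (site-to-site differences in collection and
handling masquerading as biology).

seropanel implements a complete discovery pipeline for this setting:
distribution-free marker screening, parametric class-conditional
modelling, combinatorial panel search under a simple score, pre-specified
acceptance criteria with cross-validation, structurally enforced blinded
verification, and an explicit audit of between-site variability.

## The statistical model

**Class-conditional marginals.** Serum analyte concentrations are
approximately normal in the logarithm, but with heavy tails that degrade
maximum-likelihood estimates. Each analyte's per-class distribution is
therefore modelled as log-normal with parameters $(\mu, \sigma)$
estimated by least squares between the empirical CDF of the log values
and the normal CDF:

$$\min_{\mu,\sigma} \sum_{i=1}^n
  \left[\hat F(x_{(i)}) - \Phi\!\left(\frac{x_{(i)}-\mu}{\sigma}\right)\right]^2,
  \qquad \hat F(x_{(i)}) = \frac{i - 0.5}{n},$$

minimised by Gauss-Newton iterations with step halving from the moment
start $(\bar x, s_x)$. The CDF objective weights the bulk of the
distribution rather than the tails, which is what makes it robust:
`heavy_tail_robustness_check()` shows that multiplying 5% of samples by
10 displaces the mean of logs by an order of magnitude more than the CDF
fit's location estimate.

**The classifier.** A panel of $n$ markers is scored with a multivariate
normal model per class over the log values with *diagonal* covariance —
a naive Bayes classifier. The log-likelihood ratio is then a sum of
per-marker terms,

$$\mathrm{LLR}(\mathbf x) = \sum_{j=1}^{n}
  \left[\log\phi_{\mu^{c}_j,\sigma^{c}_j}(x_j)
      - \log\phi_{\mu^{k}_j,\sigma^{k}_j}(x_j)\right],$$

and the posterior is the logistic transform of
$\mathrm{LLR} + \log\frac{\pi}{1-\pi}$ for class prior $\pi$
(`prior_case`, default 0.5 — the balanced operating point; other priors
shift the sensitivity/specificity trade-off monotonically, which is a
tested property). A sample is called a case when the posterior exceeds
0.5. Additivity is what makes the panel search fast: each candidate's
per-sample LLR contribution is computed once and any panel's LLR is a
column sum.

**Screening.** Single markers are ranked by the two-sample
Kolmogorov-Smirnov distance $D = \sup_t |\hat F_{case}(t) - \hat
F_{ctrl}(t)|$, which is invariant under monotone transforms (so raw and
log RFU agree) and distribution-free. P-values use the asymptotic
Kolmogorov series with effective size $n m/(n+m)$, and q-values use
Benjamini-Hochberg step-up — the FDR dialect is a package choice, made
explicit here because "FDR-corrected" alone does not pin one down.

## Panel search and selection

`beam_search()` scores all single-marker classifiers, then repeatedly
extends every retained panel by every unused candidate, keeping the best
`beam_width` (default 10,000) unique panels by sensitivity + specificity
at each size, until the best score plateaus (no improvement > 1e-6 for
two consecutive sizes) or deteriorates. Ties are broken
lexicographically on sorted analyte ids so runs are byte-reproducible.
With `scoring = "cross_validated"` every sample's LLR contribution comes
from marginals fit with that sample's fold held out, which makes the
retention criterion itself leak-free at roughly the cost of `cv_folds`
extra marginal fits.

`select_biomarkers()` runs the six-analysis procedure: two populations
(cases vs benign-nodule controls; cases vs all other smoker controls) ×
three screening criteria (KS ≥ 0.3 within every evaluable site; KS ≥ 0.3
pooled; both). Each analysis beam-searches its candidate set and counts
how often each analyte appears in retained panels of size ≥ 2 scoring ≥
1.7; analytes reaching the frequency threshold (default 10, applied per
analysis before the union) qualify, and the final set is the union with
provenance. Sites lacking a class within a population (the mimic's BS
site has no benign-nodule controls) are skipped in the per-site
criterion rather than failing it — a site with an empty class cannot be
compared. Assay-internal QC exclusions are not reconstructible from
first principles, so they are exposed as `exclusion_list`, which
composes naturally with the preanalytical audit's flag set.

## Criteria gating, cross-validation, and blinded verification

`cross_validate()` re-fits every per-class marginal inside each of k
class-stratified folds and pools the held-out confusion counts
(micro-average), reporting a single sensitivity/specificity pair.
Re-fitting per fold is the only reading of "cross-validated training"
that cannot leak; pooling matches how a single operating point is
reported. Stratification is by class only; fold assignment deals
shuffled class members cyclically, so per-fold class counts differ by at
most one.

The pre-specified cascade (`criteria_gate()`) mirrors a conservative
discovery protocol: training score ≥ 1.7, training stage-I sensitivity ≥
0.85, cross-validated score ≥ 1.7, cross-validated stage-I sensitivity ≥
0.85, and specificity ≥ 0.65 among controls with severe airflow
obstruction (GOLD III/IV) — the subgroup most likely to be misclassified
as cases. `apply_criteria()` records survivor counts per stage;
`choose_final()` takes the best cross-validated survivor, preferring
smaller panels on ties. Because the cross-validated and subgroup metrics
are the expensive part, `run_discovery()` computes them only for the top
`max_gate_panels` (default 25) panels per size by training score — the
cheap training-score stage acts as the shortlist, as a frequency
criterion did in the protocol this package operationalises.

Verification is enforced structurally rather than by convention:
`verify_blinded()` is the only function that accepts a blinding key, and
it requires a *frozen* model file whose content hash is checked on read,
so training on verification data is a type error, and the audit record
(model hash, key hash, timestamp) proves which model was scored.

## The preanalytical audit

`site_variability()` computes, per analyte, the pooled case-vs-control
KS distance and the mean KS over all between-site, within-class
comparisons (6 site pairs × 2 classes = 12 with four sites; site-class
cells under 2 samples are skipped). Analytes whose mean between-site KS
reaches 0.4 are flagged as handling-sensitive; ordering by (mean site KS
− disease KS) displays artifact-like analytes first and disease-like
analytes last. A well-designed multi-site study should — and in the
synthetic world verifiably does — separate the two groups completely.

## The synthetic world

`generate_cohort()` states the world the analysis assumes, nothing more:

- every analyte is log-normal, with control log-mean drawn uniformly
  over a 4-decade concentration range and log-SD in [0.2, 0.8];
- a disease marker shifts the case log-mean by $\delta$ control log-SDs
  ($\sigma$ unchanged — a pure location alternative, for which the
  population KS is exactly $2\Phi(\delta/2) - 1$, the calibration the
  tests check);
- a site-artifact analyte shifts *both* classes at each site by a
  per-site offset, also in $\sigma$ units — handling effects are
  class-independent;
- clinical covariates (age, sex, smoking, stage, histology, GOLD grade)
  are drawn independently of analyte values, so the generated world has
  no confounding and subgroup performance is homogeneous by
  construction.

`default_study_mimic()` fixes the four-site composition (106 + 248 +
498 + 474 = 1,326 samples; 291 cases, 565 benign-nodule and 470 smoker
controls, case:control ≈ 1:3.5), 813 analytes, 44 disease markers with
$|\delta| \sim U(0.6, 1.4)$ and random sign, and 7 site-artifact
analytes. Artifact analytes receive a systematic per-site pattern — a
random assignment of $\pm0.5\sigma$ / $\pm1.5\sigma$ across the four
sites scaled by a severity in [0.75, 1] — so each per-site offset stays
within $1.5\sigma$ while the mean between-site KS lands in the 0.4–0.7
range reported for handling-sensitive serum proteins (complement
fragments and coagulation factors being the canonical examples). A
single offset at a single site cannot reach the 0.4 flag threshold,
because only 6 of the 12 between-site comparisons involve that site;
the pattern construction is what makes planted artifacts genuinely
flaggable, and it was fixed before any acceptance measurement.

What a green test does *not* establish: the generator has no missing
values, no assay drift, no covariate-linked biology (no age-dependent
analytes), no heavy-tailed or multimodal analytes, and its planted
effect sizes are choices, not estimates from any real cohort. Green
means the machinery is correct and the procedure recovers truth in the
world it assumes — not that any particular clinical performance is
reproduced.

## Numerical choices and edge cases

- Empirical CDFs use the right-continuous convention at pooled values;
  the KS fast path and the brute-force oracle in the tests share it, so
  tied RFU values (common after rounding) are handled identically.
- The Kolmogorov p-value series is clipped to (0, 1] and returns 1
  exactly at D = 0, where the alternating series does not converge.
- Plotting positions $(i - 0.5)/n$ avoid 0 and 1 and make the quantile
  reconstruction test exact at the optimum.
- Gauss-Newton convergence: parameter step < 1e-8 or 100 iterations,
  with up to 10 step halvings; a stall with no improving step is treated
  as convergence (a local minimum), while hitting the iteration cap
  falls back to the moment estimates with `converged = FALSE` — a
  813-analyte sweep must not abort on one ill-behaved analyte.
- Degenerate samples (< 5 values or < 3 distinct) are errors, not
  fallbacks: they indicate a broken upstream subset, not a hard fit.
- `split_samples()` draws the verification set by simple random
  sampling, unstratified, with `round(fraction × n)` samples — the
  protocol's wording ("randomly selected") does not license
  stratification, and the choice is recorded rather than guessed.
- Metrics whose class is absent in a subset are `NA`, never 0:
  specificity-only subgroups (e.g. GOLD grades among controls) are a
  normal reporting situation, not an error.

## Known limitations

- The beam search's training-mode score is optimistically biased, which
  is why the gate's cross-validated stages exist; beam retention itself
  can still overfit marker choice at very small n.
- The naive Bayes independence assumption is wrong for correlated
  analytes (the generator plants independent ones); correlated markers
  add less than their marginal KS suggests.
- Per-site criteria lose power at small sites; a site with very few
  cases passes or fails its KS threshold noisily.
- The package does not model covariate-adjusted priors (e.g.
  age-dependent prevalence); `prior_case` is global.
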