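---
title: "Models and methods behind microICT"
author: "microICT authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microICT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microICT)
```

# Scope

microICT analyses longitudinal gut metagenomic profiles of advanced
non-small-cell lung cancer patients under anti-PD-1 immune checkpoint
therapy. Patients are graded by RECIST response — partial response (PR),
stable disease (SD), progressive disease (PD), fast death (FD) — and the
package asks, at several levels, which features of the gut microbiota
track that grading: community diversity over time, individual
metagenomic species (MGS), KEGG-orthology (KO) functional pathways,
community types (enterotypes), clinical survival strata, and finally a
classifier that predicts the response class from baseline profiles.

Because the real cohort data are access-controlled sequencing archives,
the package ships a synthetic cohort generator whose output has the same
shape and the statistical structure the analyses assume. Every analysis
stage is exercised and tested end-to-end against cohorts with known
planted truth.

# The synthetic cohort model

`generateCohort()` draws, per patient, a response group (largest-remainder
apportionment of the configured proportions, so the default 85-patient
cohort splits exactly 13 PR / 24 SD / 43 PD / 5 FD), clinical covariates,
and one sample per retained visit on the week grid M0 = 0, W1 = 1, W2 = 2,
M1 = 4, M2 = 8, M3 = 12, M4 = 16. Dropout after baseline is monotone with
per-visit probability `dropoutRate`; FD patients contribute only baseline.

**Abundances.** Each species has a latent baseline log-abundance
$\mu_j \sim N(0, 1.5^2)$; a sample's latent value adds the planted group
shift (each planted species is assigned an enriched group cycling PR, SD,
PD and gains `mgsEffectSize` natural-log units there), a BMI term
(`bmiConfounderStrength` per centred kg/m² on a random 20% feature
subset), an enterotype term, and unit-variance Gaussian noise. Latent
values are exponentiated and closed to relative abundances summing to 1.

**Zeros.** Zeros are modelled as *detection-limit* events: a species is
unobserved in a sample when its latent log-abundance falls below the
species' own `zeroInflation` quantile computed under no shift. The
marginal zero rate of an unshifted feature is exactly `zeroInflation`
(default 0.3), while enriched groups show both higher abundance and
higher occurrence — the pattern real below-detection zeros produce, and
the reason occurrence-based enrichment labelling is informative at all.
An abundance-independent Bernoulli mask was considered and rejected: it
decouples occurrence from abundance (which no detection process does)
and, after the `log10(x + eps)` transform, places zeros so far below the
data that per-feature ANOVA power collapses.

**Functional profiles.** A binary species-by-KO carriage matrix projects
the species profile onto KO space (`mgsToKO()`), with per-sample
renormalisation. Planted pathways receive dedicated KOs carried only by
PR-enriched planted species, so the functional signal points toward PR
with strength inherited from the taxonomic effect.

**Outcomes.** Progression-free survival is exponential with a
group-specific baseline hazard (median 12 / 5 / 2 / 0.7 months for
PR / SD / PD / FD — ordered as clinical experience suggests; values are a
one-time modelling choice, not fitted to anything) multiplied by hazard
ratios for antibiotics exposure (default 2.5), high tumour mutational
burden (> 5.6 mutations/Mb, default 0.5) and high HLA-E (default 1.8).
A fraction `censorRate` of times is right-censored uniformly.

**Randomness.** All draws derive from one seed through per-patient
sub-streams with separate streams for abundances, dropout and outcomes,
so a config + seed pair reproduces a bit-identical cohort and changing
the dropout rate cannot perturb abundance draws.

## What the generator does not emulate

Samples within a patient are drawn independently given the patient's
covariates: there is no within-patient autocorrelation beyond enterotype
and BMI effects, no true longitudinal treatment dynamics (group
trajectories are flat in expectation), no read-level noise, and no
strain-level structure. Passing tests therefore demonstrate correctness
and calibration of the statistical machinery under the stated model, not
performance on any real cohort.

# Diversity dynamics

Alpha diversity is the Shannon index in nats; beta diversity is
Bray-Curtis dissimilarity, and `groupDispersion()` collects all
within-group pairwise dissimilarities at a visit. The longitudinal group
comparison (`permusplineTest()`) fits one tricube local-linear smoother
(span 0.75, matching the default behaviour class of the spline-based
longitudinal test the field uses) per group on a 50-point grid over the
shared week range, takes the mean absolute difference between smoothers
as the statistic, and permutes group labels between whole patients —
never individual samples — to respect repeated measures. The p-value uses
the add-one convention, so it is never exactly zero. The smoother is
implemented in closed form and agrees with `stats::loess(degree = 1,
span = 0.75, surface = "direct")` to numerical precision (tested).

# Differential species testing

For each species the relative abundances are transformed as
`log10(x + eps)` with `eps` half the smallest nonzero value of the
matrix, then tested by a BMI-adjusted ANOVA: the extra-sum-of-squares F
test of `value ~ group + bmi` against `value ~ bmi`. Because the design
is shared across features, the screen is computed with two QR
decompositions for the entire matrix. Benjamini-Hochberg q-values are
reported alongside raw p-values; "significant" defaults to raw p < 0.05
(the convention of a per-feature ANOVA screen) and can be switched to
q < 0.05. Significant species get Tukey HSD pairwise contrasts and an
enrichment label: highest-median group ("+") and lowest ("-"), gated by
an occurrence threshold (default: no group reaches 20% occurrence gives
NA), with median ties broken by occurrence and then the fixed order
PR > SD > PD.

The primary test pools all longitudinal samples, as the original analysis
did. This is a known limitation: any patient-level community structure
(enterotypes in particular) makes pooled samples non-exchangeable and
inflates the per-feature type-I error several-fold at nominal 5% on
enterotype-driver features of an otherwise-null heterogeneous cohort
(the test-suite demonstrates this). Calibration claims are therefore
made on homogeneous-community null cohorts (`enterotypeCount = 1`,
nothing planted), where the p-values are uniform to Kolmogorov-Smirnov
precision. A per-timepoint mode (`timepoint =` argument) avoids the
pooling issue at the cost of power.

# Reporter-score pathway enrichment

Per KO, a two-sided Wilcoxon rank-sum test (normal approximation, tie
corrected) compares the two groups of an oriented contrast — (PR,SD),
(PR,PD), (SD,PD), first member "better" — at one visit. The signed score
is $z_i = \Phi^{-1}(1 - p_i/2) \cdot \mathrm{sign}(\Delta\mathrm{median})$,
capped at ±8 against p-value underflow, with zero median difference
mapped to +1 and constant KOs to z = 0. A pathway with k scored KOs gets
$Z = \sum z_i / \sqrt{k}$, standardised against the mean and standard
deviation of the same statistic over 1000 seeded random draws of k KOs
(without replacement) from all scored KOs:
$Z_{adj} = (Z - \mu_k)/\sigma_k$. Backgrounds with spread below 1e-8
(e.g. all-zero score vectors) return 0 rather than dividing by noise.
Significance uses the two-sided normal quantiles — 1.96 at 0.05, 2.576 at
0.01; the package always computes the quantile rather than hard-coding a
rounded value. Cross-timepoint consistency is the Spearman correlation of
a later visit's corrected-score vector against baseline, per contrast.
Later-visit contrasts are cross-sectional (not paired within patients);
paired deltas would need a different null and are out of scope.

# Enterotyping

Genus-level profiles (species summed by genus, renormalised, scaled to a
pseudo-count depth of 10,000 and rounded half-to-even, with rounding
residue removed from the largest genus) are clustered with a K-component
Dirichlet-multinomial mixture fitted by EM: posterior memberships in the
E-step, mixture weights and weighted Minka fixed-point updates of each
component's Dirichlet parameters (5 inner iterations) in the M-step. The
observed-data log-likelihood is asserted non-decreasing each iteration
and convergence is declared at a relative change below 1e-6 (cap 500
iterations; non-convergence returns the best fit, flagged).
Initialisation is k-means on proportion profiles; `selectK()` uses 5
restarts per K (one for K = 1, which is deterministic; the restart loop
stops early once two restarts reproduce the incumbent optimum).

Model order is chosen by the score in `logEvidence`. A Laplace
approximation is implemented (responsibility-weighted per-component
Hessian blocks of the form diag(d) + c 11', determinants via the
matrix-determinant lemma), but at desk-scale data it underpenalises:
components that capture few samples contribute near-singular curvature
blocks, and spurious extra components survive. BIC is therefore the
default score; on planted 1-, 2- and 3-component data (n = 200, depth
5000) it recovers the true order in well over 90% of seeds (tested).

# Survival analysis

Responders are patients with PFS strictly beyond 3 months; patients
censored at or before the cutoff are indeterminate (NA), censored beyond
it are responders. Kaplan-Meier curves and two-group log-rank tests are
delegated to the survival package, with strata builders for antibiotics,
TMB dichotomised at 5.6 mutations/Mb, HLA-E level and the four-way
TMB-by-HLA-E cross. Both are verified in the test-suite against
hand-rolled product-limit and observed-minus-expected oracles.

# The two-tiered predictor

Stage A is a random forest separating PR from PD; stage B separates SD
from everything else. Training draws 8 PR + 8 PD patients (stage A),
which double as stage B's 16 non-SD examples alongside 16 SD patients.
Feature selection per stage is repeated stratified cross-validation
(default 8 folds, 200 repetitions; with 16 training samples the folds are
degenerate 1-per-class pairs, which is legal and handled): each fold
trains a 100-tree forest on a random candidate subset of
$\lceil 4\sqrt{p} \rceil$ features and adds
`impurity importance x held-out accuracy` to each candidate's running
contribution (selection-frequency bookkeeping is available as an
alternative). A literal single decision tree per repetition would be
noise-dominated; a small forest preserves the described bookkeeping while
stabilising the importances. The per-stage feature count is picked from
the grid {5, 10, 20, 30, 50} (capped at 30) by out-of-fold AUC, ties to
the smaller k. Final stage forests use 500 trees; class probabilities are
tree-vote fractions.

Per-sample probabilities combine multiplicatively:
$p_{SD} = p_B$, $p_{PR} = (1-p_B)\,p_A$, $p_{PD} = (1-p_B)(1-p_A)$,
summing to one exactly — the factorisation consistent with "multiply the
two model probabilities" that yields a proper three-class distribution.
Evaluation is one-vs-rest AUC by the rank formulation (ties half), with a
stratified-bootstrap percentile 95% CI. Predictions from models trained
on different data modalities (e.g. species, KO, tumour genetics encoded
as numeric TMB plus binary EGFR/ALK) are fused by a weighted arithmetic
mean of probability vectors, renormalised — the fusion rule is a package
choice, as the source analysis does not print one. The default 200
cross-validation repetitions keep test runs tractable; the original
description's 1000 repetitions are one argument away (`nReps = 1000`).

# Numerical and design notes

* Problem sizes in the shipped tests are chosen for a laptop-scale run:
  null-calibration sweeps use a few hundred features over a handful of
  seeds; planted-recovery uses the full 1500-species cohort once;
  predictor properties use 20 seeds at 200 repetitions; enterotype
  recovery uses 50 seeds per planted order at n = 200, depth 5000.
* The percentile-bootstrap AUC interval under-covers when a held-out
  class has only a handful of members (with two positives an AUC of 0
  yields the degenerate interval \[0, 0\]). Predictor *null-calibration*
  experiments therefore run on 150-patient cohorts, where held-out
  classes are large enough for the interval to be meaningful, and
  coverage of 0.5 is judged as a calibration rate against its nominal
  95% level rather than seed-by-seed. Point AUCs on study-sized cohorts
  are unaffected.
* Tie-breaks are deterministic everywhere (feature order in rankings,
  smaller k on AUC ties, PR > SD > PD in enrichment labels), so equal
  inputs and seeds reproduce equal outputs bit-for-bit.
* Degenerate inputs have defined behaviour rather than accidents:
  constant features give NA (ANOVA) or z = 0 (reporter); pathways with no
  scored KO are dropped with a message; all-zero samples are an error in
  `mgsToKO()`; a fully zeroed visit retains its single largest latent
  feature so closure stays defined.
* `validateCohort()` implements the antibiotics exclusion of the study
  design (12 of 85 patients under the defaults, leaving 73) and reports
  orphan samples/metadata without failing; only a disjoint
  sample/metadata pair is fatal.
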