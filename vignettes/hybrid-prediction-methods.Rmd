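---
title: "Models and methods for factorial hybrid prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for factorial hybrid prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hybridgp` implements the statistical machinery of a hybrid breeding
experiment built on a female x male factorial crossing scheme: inbred
parents are crossed to produce F1 hybrids, all genotypes are evaluated in
partially replicated multi-environment field trials, and marker data on the
parents (hybrid genotypes follow deterministically) feed association mapping
and genomic prediction. This vignette describes the models, their
assumptions, the tunable parameters, and the design decisions taken where
the methodology left genuine choices.

## The data-generating model

The synthetic-data module is a first-class part of the package: every
statistical claim the test suite makes is evaluated against populations it
generates, so its assumptions delimit what the tests demonstrate.

**Genotypes.** `simulate_parents()` draws biallelic SNPs in linkage
equilibrium with per-marker allele frequencies uniform on
`[maf_low, maf_high]` (defaults 0.05--0.5, mirroring a post-QC panel with a
5% minor-allele-frequency floor). Parents are fully inbred (dosages 0/2);
`derive_hybrid_genotypes()` sets each hybrid dosage to the parental mean, an
exact integer identity for inbred parents. Real panels carry linkage
disequilibrium, ascertainment bias and genotyping error; none of these are
modelled, so test results say nothing about LD-driven phenomena such as
tagging of unobserved causal variants.

**Genetic values.** `simulate_genetic_values()` uses the F-infinity
parameterisation: additive codes -1/0/+1 for dosages 0/1/2 and a dominance
indicator for the heterozygote. `n_qtl` markers receive additive effects
`a ~ N(0, additive_sd^2)` and dominance effects `d ~ N(0, dominance_sd^2)`;
a single large-effect QTL can be injected on top to emulate a major gene on
a polygenic background. With `dominance_sd = 0` every hybrid value is
exactly the mid-parent value, which the tests exploit as a heterosis null.

**Field trials.** `simulate_trials()` emulates partially replicated alpha
designs: genotypes are split at random into 3 adjacent trials per
environment, linked by 10 common checks present in every trial; lines,
checks and 29% of the hybrids appear in both replications, the remaining
hybrids in one. Every plot value is `mu + l + t + r + b + g + (g x l) + e`
with each non-genetic term drawn iid normal with its component variance.
Blocks are iid within replication (no spatial or AR1 structure) and
genotype-by-environment effects are iid (no factor-analytic structure),
matching the assumptions of the one-step analysis model; the simulator can
therefore not be used to probe robustness against spatial trend or
structured GxE.

## Two-stage phenotypic analysis

Stage one fits, per environment, `y = mu + g + t + r + b + e` with genotype
fixed and trial/replication/block random, by REML (lme4), and reports the
fixed genotype means. Random terms with a single level in an environment are
dropped. Stage two stacks the per-environment means and fits
`mean = mu + g + l + e` with environment random, giving one BLUE per
genotype. In balanced designs these BLUEs collapse to simple means, which
provides exact oracle tests. REML here is a standard model fit, so it is
delegated to lme4 rather than re-implemented; the numeric contract is the
maximised restricted likelihood, not a particular algorithm.

Mid-parent heterosis is `MPH = (HYB - MP) / MP * 100` with
`MP = (P1 + P2) / 2`; it is undefined (an error) when `MP = 0`, which can
only occur for traits without a natural positive scale. Combining ability is
decomposed as `y = mu + gca_f + gca_m + sca` under sum-to-zero constraints
(the identifiability constraint is not dictated by the model; sum-to-zero
makes the balanced-case estimates equal marginal mean deviations, which is
the convention the tests verify).

The one-step variance-component model treats everything except the intercept
as random: environment, trial, replication, block, line genetic effects,
line x environment, hybrid genetic effects, hybrid x environment, and the
plot residual. Check genotypes are treated as lines. Per-component
significance uses a likelihood-ratio test against the model without the
component with the halved-p-value boundary convention (a statistic of 0
gives p = 0.5). Entry-mean heritability is
`h2 = s2_G / (s2_G + s2_GxE / E + s2_e / (E R))` and plot-basis heritability
`s2_G / (s2_G + s2_GxE + s2_e)`, both clamped to [0, 1]; the entry-mean
formula is the standard one for means over `E` environments and `R`
replications, adopted here because the source methodology prints the
heritability values but not the formula.

A note on what "recovery" means at desk scale: the package's
parameter-recovery check (20 replicates of 200 genotypes x 4 environments)
bounds the median relative error of the *genetic* components and the
residual at 20%. The design components cannot carry such a bound at any
implementation quality -- an environment variance estimated from 4
environment levels has the spread of a 3-df chi-square -- so they are checked
for plausibility, not relative error.

## Association mapping

The scan model is `Y = X beta + S s + Z u + e` where `Y` are adjusted entry
means (stacked within environments with environment fixed effects, or a
single BLUE vector), `s` is the fixed SNP effect and `u` a polygenic
background with covariance proportional to a marker kinship matrix
`K = W W' / m` (`W` the additive or dominance design matrix; the
normalisation by marker count is a documented choice, with `2 sum p(1-p)`
available as an alternative). The variance components are estimated once by
spectral REML under the no-marker null and reused for every marker -- the
standard "population parameters previously determined" approximation; an
exact per-marker re-estimation mode exists behind a flag. Tests are Wald F
tests; dominance scans are restricted to genotypes that actually carry
heterozygous calls, since inbreds contain no dominance contrast.

Multiple testing uses the Bonferroni-Holm step-down rule (reject while
`p_(i) < alpha / (m - i + 1)`). Explained phenotypic variance is sequential
ANOVA R-squared with QTL in ascending-p order; the joint adjusted R-squared
standardised by broad-sense heritability gives the explained genotypic
proportion `p_G = R2_adj / h2`, capped at 1 with a warning (the cap is a
package decision; the ratio can exceed 1 by sampling error).

Two properties of kinship-corrected scans in factorial populations are worth
stating because the acceptance checks depend on them. First, under a global
null with family structure and a polygenic background driven by markers
disjoint from the scanned panel, the Holm family-wise error is controlled
(measured ~0.02 at alpha = 0.05). Second, the correction absorbs a large
part of any single marker's signal, because a marker's dosage vector aligns
with the family structure that the kinship matrix encodes. At the package's
study scale (estimation sets of 90 parents + 610 hybrids, 1,384 markers) a
QTL must carry roughly 40% of the genotypic variance for its
allele-substitution effect to be Holm-significant in >= 90% of resamples;
the package's stability check therefore injects a major QTL calibrated to
the printed allele-effect-to-range scale of the motivating experiment
(which, at its ~2.5x larger scan population, showed the same ~90/100
stability at a smaller variance share). The floor of 15% explained
genotypic variance is asserted alongside.

## Genomic prediction

**RR-BLUP.** Marker effects are estimated from the block mixed-model
equations for `Y = 1 mu + ZA a + ZD d + e` with ridge penalties `lambda_A`
on all additive and `lambda_D` on all dominance effects; the system is
solved exactly, via the dense `(1 + 2m)`-dimensional system when markers are
few and via the numerically identical n-dimensional dual (Woodbury) form
when `2m + 1 > n`. The shrinkage parameters follow the printed definition
`lambda_A = (s2_e / n_env) / (s2_GCA / n_marker)` (and SCA for dominance);
`shrinkage_params()` computes them from a combining-ability analysis, and
`estimate_lambda()` offers a direct spectral-REML alternative on the marker
model itself (`lambda_A = s2_e / s2_a`), with `lambda_D` from a second REML
fit of the dominance relationship to the additive-model residuals -- a
pragmatic two-step choice; a joint two-component REML is deliberately not
attempted. Additive-only RR-BLUP is algebraically identical to GBLUP with
`K = ZA ZA' / m`, which the tests verify to 1e-6.

**W-BLUP.** Functional markers (by default the 3 most significant of a scan
on the training set) receive an extra effect block whose penalty is
`lambda / w`; `w = 100` leaves them nearly unshrunken. The methodology that
motivated this model prints the functional blocks without stating their
penalty; the `lambda / w` interpolation is this package's decision because
it makes the two ends testable: `w = 1` reduces exactly to RR-BLUP on a
panel with the functional columns duplicated, and large `w` approaches a
fixed-covariate fit.

**Bayes-C-pi.** The variable-selection model includes each marker with
probability `1 - pi_g` per effect class, with a uniform(0, 1) prior on
`pi_g` (beta full conditional), normal effects within the slab, and
scaled-inverse-chi-square priors (df 4) on the effect and residual
variances; the effect-variance scale is matched to half the phenotypic
variance spread over the expected number of included markers. The Gibbs
sampler is compiled (Rcpp/Armadillo) and uses R's RNG, so seeded chains are
bitwise reproducible. Chain defaults are 10,000 iterations, 2,000 burn-in,
thinning 10. With `fix_pi = 0` the model collapses to a Bayesian ridge whose
posterior-mean effects track RR-BLUP at the matched variance ratio
(correlation > 0.98 in the acceptance check).

**Classical predictors.** `gca_predict()` returns `mu + gca_f + gca_m` and
is only defined when both parents carry GCA estimates -- i.e. for fully
related (T2) targets; `mp_predict()` averages the parental BLUEs and within
cross-validation is likewise evaluated on T2 targets, since the parents of
less related test hybrids are outside the estimation data.

## Relatedness-stratified cross-validation

`sample_t_scheme()` draws 80 of 120 females, 10 of 15 males and 610
estimation hybrids among the crosses internal to them, then classifies every
remaining hybrid: T2 = both parents in the estimation parent sets, T1 =
exactly one, T0 = none. On a full 120 x 15 factorial this yields 190 T2, 800
T1 and 200 T0 hybrids. When the realised plan is not a full factorial the
610-hybrid contract may be infeasible; the sampler then errors unless
`best_effort = TRUE`, which takes all internal crosses (the pipeline uses
best-effort mode because a 1,604-cross plan leaves fewer than 800 internal
crosses in some draws). Accuracy is the Pearson correlation between
predicted and observed test-set performance divided by the square root of
the entry-mean heritability, clamped at 1; the heritability is estimated
once from the full data, not per run. Marker-assisted selection is
cross-validated by scanning the estimation set, selecting markers at
Bonferroni-Holm or fixed unadjusted thresholds, estimating their joint
effects by GLS under the scan's polygenic covariance, and predicting the
test sets; runs with empty selections contribute an accuracy of 0 rather
than being dropped (a conservative choice the methodology leaves open).

The three resampling studies vary (a) the number of female parents (30--120,
estimation sets of two thirds of them, 10 males, 100 hybrids), (b) the
number of estimation hybrids (610 down to 100 at fixed 80F/10M), and (c)
marker density via equidistant subsampling (k markers drawn from every
window of 173). Run seeds are shared across grid points so comparisons are
paired.

## Numerical choices and degenerate inputs

* REML fits use lme4 with derivative checks disabled; stage-one models drop
  random factors with fewer than two levels and fall back to OLS when none
  remain.
* The spectral REML for kinship models clamps negative eigenvalues at zero
  and profiles the variance ratio on `log delta` in [-12, 12].
* Monomorphic markers are skipped (flagged) in scans, excluded from LD
  (`NA`), and removed first in QC; QC attribution order is fixed
  (monomorphic, missingness, heterozygosity, MAF) so reports partition the
  removals reproducibly.
* Missing-dosage imputation, when enabled, is the column mean rounded to the
  nearest legal dosage -- deterministic, and bounded in impact because QC
  caps missingness at 5%.
* Ties in `top_k_markers()` break lexicographically by (chromosome,
  position, id), so functional-marker sets are reproducible.
* `solve_mme()` refuses singular systems rather than regularising beyond the
  stated penalties.
* All stochastic steps take explicit seeds; studies derive per-run seeds
  from a master seed by fixed offsets.

## Problem sizes used by the verification suite

The acceptance checks run on synthetic populations chosen to mirror the
design constants while staying desk-sized: the full 120 x 15 factorial
(1,800 hybrids) genotyped at 1,384 markers (8 windows of 173) on 21
chromosomes; 300 polygenic QTL with small dominance; entry-mean heritability
0.8; 30 cross-validation runs per comparison; 200 global-null replicates for
family-wise error; 20 replicates of 200 genotypes x 4 environments for
variance-component recovery; Gibbs chains of 4,000 iterations for the
Bayes-C-pi collapse check. The same quantities are recomputed from scratch
by `scripts/acceptance.R`.

## Known limitations

* Linkage equilibrium by default; the acceptance properties do not exercise
  LD except through the optional duplicate-with-noise device used in tests
  of LD computation itself.
* The GWAS approximation reuses null variance components per marker; exact
  per-marker REML is available but quadratically slower.
* `lambda_D` from the two-step REML is a plug-in, not a joint estimate, and
  dominance variance in sparse heterozygote panels is weakly identified.
* GCA estimates exist only for parents represented among estimation crosses;
  rare T2 targets of unrepresented parents are skipped in cross-validation.
* The one-step model assumes iid GxE and iid blocks; spatial adjustments are
  out of scope.
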