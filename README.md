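# hybridgp

Genomic prediction of hybrid performance in factorial crossing designs.

Hybrid breeding programs in selfing crops such as wheat must pick superior
single crosses out of thousands of possible parent combinations, with field
capacity for only a fraction of them. `hybridgp` is an R toolkit for the
statistical backbone of such a program: it simulates factorial hybrid
populations with known genetic architecture, runs the two-stage phenotypic
analysis of partially replicated multi-environment trials, performs
kinship-corrected genome-wide association scans, fits genomic prediction
models with additive and dominance marker effects, and evaluates everything
by cross-validation stratified by the relatedness between estimation and
test hybrids.

## Models at the core

* **Two-stage phenotypic analysis.** Per environment,
  `y = mu + g + t + r + b + e` (genotype fixed; trial, replication, block
  random, REML) gives adjusted entry means; stacking them under
  `mean = mu + g + l + e` (environment random) gives one BLUE per genotype.
  A one-step model with all effects random yields the variance components
  and entry-mean heritability
  `h2 = s2_G / (s2_G + s2_GxE/E + s2_e/(E R))`, with per-component
  halved-LRT significance. Mid-parent heterosis is
  `MPH = (HYB - MP)/MP x 100`, `MP = (P1 + P2)/2`; combining ability is
  decomposed as `y = mu + gca_f + gca_m + sca`.
* **Association mapping.** `Y = X beta + S s + Z u + e` with a fixed SNP
  effect and a polygenic background with covariance `K sigma2_u`,
  `K = W W'/m` from F-infinity marker codes; spectral REML under the null,
  Wald F tests per marker, Bonferroni-Holm control, sequential R-squared and
  explained genotypic variance `p_G = R2_adj / h2`.
* **Genomic prediction.** RR-BLUP via the exact block mixed-model equations
  for `Y = 1 mu + ZA a + ZD d + e` with shrinkage
  `lambda_A = (s2_e/n_env)/(s2_GCA/n_marker)` (dual-form solver when
  markers outnumber genotypes); W-BLUP with near-unshrunken functional
  markers; Bayes-C-pi by a compiled Gibbs sampler with marker inclusion
  probability `1 - pi` and a uniform prior on `pi`; plus mid-parent and
  GCA-based prediction as classical baselines.
* **Cross-validation by relatedness.** Estimation sets of 80 of 120 female
  and 10 of 15 male parents with 610 of their hybrids; test hybrids split
  into T2/T1/T0 by sharing two/one/zero parents with the estimation set;
  accuracy = Pearson correlation standardised by `sqrt(h2)`, clamped at 1.
  Resampling studies vary parent count, hybrid count and marker density.

## Worked example

```r
library(hybridgp)

parents <- simulate_parents(n_female = 40, n_male = 8, n_markers = 600,
                            n_chromosomes = 7, seed = 11)
plan    <- make_factorial(parents$parents, n_hybrids = 280, seed = 12)
hybrids <- derive_hybrid_genotypes(parents, plan)
geno    <- new_geno_matrix(rbind(parents$dosage, hybrids$dosage), parents$map)
geno
#> geno_matrix: 328 individuals x 600 markers (7 chromosomes)
#>   heterozygous calls: 31.0%; missing: 0.00%

truth <- simulate_genetic_values(geno, n_qtl = 150, additive_sd = 1,
                                 dominance_sd = 0.2, seed = 13)
plots <- simulate_trials(truth$values, trial_design(n_env = 4),
                         trial_varcomp(), mu = 45,
                         trait_name = "sds_volume", seed = 14)

em    <- adjust_entry_means_per_env(plots)
blues <- blues_across_env(em)
het   <- mid_parent_stats(blues, plan)
attr(het, "mean_MPH"); attr(het, "mean_abs_MPH")
#> [1] -1.44...   # mean mid-parent heterosis, percent
#> [1] 2.55...    # mean absolute MPH, percent

vc <- variance_components_one_step(plots, hybrid_ids = plan$hybrid)
h2 <- heritability(vc, E = 4, R = 2, group = "hybrids")
h2$entry_mean; h2$plot
#> [1] 0.99...    # entry-mean heritability of hybrid means over 4 envs
#> [1] 0.96...    # plot-basis heritability

bundle <- cv_data(plan, geno, blues[plan$hybrid],
                  blues[c(parents$parents$female_ids,
                          parents$parents$male_ids)],
                  h2 = h2$entry_mean)
cv <- run_cv(bundle, "rrblup", n_runs = 10, n_f_est = 26, n_m_est = 5,
             n_hyb_est = 90, seed = 15)
round(attr(cv, "means"), 2)
#>   T0   T1   T2
#> 0.21 0.67 0.97
```

The accuracy gradient is the central phenomenon: hybrids whose parents both
contributed training hybrids (T2) are predicted almost perfectly, hybrids
sharing one parent (T1) moderately, and hybrids of entirely untested parents
(T0) poorly -- which is why estimation-set composition, not marker density,
is the binding constraint on predicting unrelated material.

An end-to-end pipeline (simulate -> QC -> phenotypic analysis -> GWAS ->
prediction -> cross-validation, with plain-text artifacts and a checksummed
manifest) is available as `run_all(validate_config(list(...)))`.

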