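test_that("stage-one means reduce to raw genotype means in balanced designs", {
  g <- setNames(c(3, -1, 0.5, 2), c("g1", "g2", "g3", "g4"))
  plots <- balanced_plots(g, n_trial = 2, n_rep = 2, mu = 10, noise_sd = 0)
  em <- adjust_entry_means_per_env(plots)
  # orthogonal design: fixed genotype means are invariant to the variance
  # components, hence equal the raw means exactly
  raw <- tapply(plots$value, plots$genotype, mean)
  expect_equal(em$mean, as.vector(raw[em$genotype]), tolerance = 1e-8)
})

test_that("stage-one means equal a GLS solve at the REML variance estimates", {
  g <- setNames(c(5, 0, -2), c("g1", "g2", "g3"))
  plots <- balanced_plots(g, n_trial = 2, n_rep = 1, mu = 20,
                          trial_eff = c(1.5, -1.5), noise_sd = 0.4, seed = 8)
  # replication constant within trial -> only the trial term remains random
  plots$replication <- "r1"
  em <- adjust_entry_means_per_env(plots)

  fit <- lme4::lmer(value ~ 0 + genotype + (1 | trial), data = plots)
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2_t <- vc$vcov[vc$grp == "trial"]
  s2_e <- vc$vcov[vc$grp == "Residual"]
  Zt <- model.matrix(~ 0 + trial, data = plots)
  V <- s2_t * tcrossprod(Zt) + s2_e * diag(nrow(plots))
  X <- model.matrix(~ 0 + genotype, data = plots)
  beta <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, plots$value))
  expect_equal(em$mean, as.vector(beta), tolerance = 1e-6)
})

test_that("genotypes unobserved in an environment are omitted", {
  g <- setNames(1:4, c("g1", "g2", "g3", "g4"))
  plots <- rbind(balanced_plots(g, env = "env1"),
                 balanced_plots(g[1:3], env = "env2"))
  class(plots) <- c("plot_records", "data.frame")
  em <- adjust_entry_means_per_env(plots)
  expect_false("g4" %in% em$genotype[em$environment == "env2"])
  expect_true("g4" %in% em$genotype[em$environment == "env1"])
})

test_that("across-environment BLUEs match balanced closed forms", {
  em1 <- data.frame(genotype = c("a", "b"), environment = "env1",
                    mean = c(10, 12))
  # single environment: BLUEs are the stage-one means
  expect_equal(blues_across_env(em1), c(a = 10, b = 12))

  # balanced two-environment case: simple mean across environments
  em <- rbind(em1, data.frame(genotype = c("a", "b"), environment = "env2",
                              mean = c(14, 18)))
  em <- rbind(em, data.frame(genotype = c("a", "b"), environment = "env3",
                             mean = c(9, 13)))
  bl <- blues_across_env(em)
  expect_equal(bl, c(a = mean(c(10, 14, 9)), b = mean(c(12, 18, 13))),
               tolerance = 1e-8)
})

test_that("mid-parent heterosis follows its defining arithmetic", {
  plan <- structure(data.frame(hybrid = c("AxB", "CxD"),
                               female = c("A", "C"), male = c("B", "D"),
                               stringsAsFactors = FALSE),
                    class = c("crossing_plan", "data.frame"))
  bl <- c(A = 40, B = 50, AxB = 45, C = 40, D = 50, CxD = 49.5)
  hs <- mid_parent_stats(bl, plan)
  expect_equal(hs$MP, c(45, 45))
  expect_equal(hs$MPH, c(0, 10))
  expect_equal(attr(hs, "mean_abs_MPH"), 5)

  expect_error(mid_parent_stats(bl[-1], plan), "A")
  bl0 <- c(A = -50, B = 50, AxB = 10, C = 40, D = 50, CxD = 49.5)
  expect_error(mid_parent_stats(bl0, plan), "MPH undefined")
})

test_that("combining-ability decomposition matches two-way ANOVA identities", {
  # balanced 3x2 factorial with known effects
  fem <- c(f1 = 2, f2 = -1, f3 = -1)
  mal <- c(m1 = 1.5, m2 = -1.5)
  plan <- structure(expand.grid(female = names(fem), male = names(mal),
                                KEEP.OUT.ATTRS = FALSE,
                                stringsAsFactors = FALSE),
                    class = c("crossing_plan", "data.frame"))
  plan$hybrid <- paste(plan$female, plan$male, sep = "x")
  y <- setNames(20 + fem[plan$female] + mal[plan$male], plan$hybrid)

  gm <- gca_sca(y, plan)
  expect_equal(gm$mu, 20, tolerance = 1e-8)
  expect_equal(gm$gca_f[names(fem)], fem, tolerance = 1e-8)
  expect_equal(gm$gca_m[names(mal)], mal, tolerance = 1e-8)
  # saturated additive case: all SCA zero; constraints hold
  expect_equal(unname(gm$sca), rep(0, 6), tolerance = 1e-8)
  expect_equal(sum(gm$gca_f), 0, tolerance = 1e-10)
  expect_equal(sum(gm$gca_m), 0, tolerance = 1e-10)

  # ANOVA identity: GCA = marginal mean deviations from the grand mean
  y2 <- y + c(0.3, -0.2, 0.1, -0.3, 0.2, -0.1)  # add interaction
  gm2 <- gca_sca(y2, plan)
  rowm <- tapply(y2, plan$female, mean) - mean(y2)
  expect_equal(unname(gm2$gca_f[names(rowm)]), as.vector(rowm),
               tolerance = 1e-8)
})

test_that("one-step model recovers variances and the halved-LRT convention", {
  expect_equal(halved_lrt_p(0), 0.5)
  expect_equal(halved_lrt_p(3.84), 0.5 * pchisq(3.84, 1, lower.tail = FALSE))

  pop <- toy_population(n_f = 30, n_m = 5, n_markers = 30, seed = 17,
                        n_hybrids = 90)
  set.seed(18)
  vals <- c(setNames(rnorm(35, 0, sqrt(2)), rownames(pop$parents$dosage)),
            setNames(rnorm(90, 0, 1), pop$plan$hybrid))
  vc_true <- trial_varcomp(environment = 1, trial = 0.3, replication = 0.2,
                           block = 0.4, gxe = 0.5, error = 1)
  plots <- simulate_trials(vals, trial_design(n_env = 4, block_size = 15),
                           vc_true, seed = 19)
  vc <- variance_components_one_step(plots, hybrid_ids = pop$plan$hybrid)
  expect_named(vc$sigma2, c("environment", "trial", "replication", "block",
                            "lines", "lines_x_env", "hybrids",
                            "hybrids_x_env", "error"))
  expect_true(all(vc$sigma2 >= 0))
  # the well-replicated components are estimated in the right region
  expect_lt(abs(vc$sigma2[["error"]] - 1), 0.35)
  expect_lt(abs(vc$sigma2[["hybrids"]] - 1), 0.6)

  # a component simulated at zero lands at the boundary with halved-LRT
  # p-values that are never small
  vc0 <- trial_varcomp(environment = 1, trial = 0, replication = 0.2,
                       block = 0.4, gxe = 0.5, error = 1)
  plots0 <- simulate_trials(vals, trial_design(n_env = 3, block_size = 15),
                            vc0, seed = 23)
  fit0 <- variance_components_one_step(plots0, hybrid_ids = pop$plan$hybrid,
                                       lrt = TRUE)
  expect_lt(fit0$sigma2[["trial"]], 0.05)
  expect_gte(fit0$p_values[["trial"]], 0.25)
  expect_true(all(fit0$p_values > 0 & fit0$p_values <= 0.5 + 1e-12))
})

test_that("heritability formulas and clamping behave as defined", {
  vc <- c(hybrids = 1, hybrids_x_env = 1, error = 2)
  h <- heritability(vc, E = 2, R = 2, group = "hybrids")
  expect_equal(h$entry_mean, 1 / (1 + 1 / 2 + 2 / 4))  # = 0.5
  expect_equal(h$plot, 0.25)

  h1 <- heritability(c(hybrids = 1, hybrids_x_env = 0, error = 0), 3, 2,
                     "hybrids")
  expect_equal(h1$entry_mean, 1)

  # entry-mean heritability is nondecreasing in E
  hs <- vapply(1:6, function(E)
    heritability(vc, E, 2, "hybrids")$entry_mean, numeric(1))
  expect_true(all(diff(hs) >= 0))
  expect_gte(h$entry_mean, h$plot)

  expect_error(heritability(vc, 0, 2, "hybrids"), ">= 1")
  expect_error(heritability(c(hybrids = 0, hybrids_x_env = 0, error = 0),
                            2, 2, "hybrids"), "zero")
})

test_that("noise-free two-stage chain returns the true genetic values", {
  pop <- toy_population(n_f = 6, n_m = 3, n_markers = 40, seed = 29)
  tr <- simulate_genetic_values(pop$geno, n_qtl = 15, additive_sd = 1,
                                dominance_sd = 0.4, seed = 30)
  vc0 <- trial_varcomp(environment = 0, trial = 0, replication = 0,
                       block = 0, gxe = 0, error = 0)
  plots <- simulate_trials(tr$values, trial_design(n_env = 2, block_size = 10),
                           vc0, mu = 50, seed = 31)
  bl <- blues_across_env(adjust_entry_means_per_env(plots))
  expect_equal(unname(bl), unname(50 + tr$values[names(bl)]),
               tolerance = 1e-8)
})
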