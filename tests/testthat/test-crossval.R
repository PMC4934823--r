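# compact synthetic study population for cross-validation tests:
# full factorial so the estimation-internal cross count is deterministic
cv_fixture <- function(n_f = 30, n_m = 8, n_markers = 150, n_qtl = 60,
                       h2 = 0.8, seed = 81, dominance_sd = 0) {
  pop <- toy_population(n_f = n_f, n_m = n_m, n_markers = n_markers,
                        seed = seed)
  tr <- simulate_genetic_values(pop$geno, n_qtl = n_qtl, additive_sd = 1,
                                dominance_sd = dominance_sd, seed = seed + 1)
  gh <- tr$values[pop$plan$hybrid]
  set.seed(seed + 2)
  noise_sd <- sqrt(var(gh) * (1 - h2) / h2)
  yh <- gh + rnorm(length(gh), 0, noise_sd)
  yp <- tr$values[rownames(pop$parents$dosage)] +
    rnorm(nrow(pop$parents$dosage), 0, noise_sd)
  list(data = cv_data(pop$plan, pop$geno, yh, yp, h2 = h2),
       truth = tr, pop = pop)
}

test_that("sampled schemes satisfy the shared-parent partition rules", {
  pop <- toy_population(n_f = 20, n_m = 6, n_markers = 10, seed = 83)
  for (s in 1:25) {
    sch <- sample_t_scheme(pop$plan, n_f_est = 12, n_m_est = 4,
                           n_hyb_est = 30, seed = s)
    # brute-force set arithmetic
    expect_length(sch$est_hybrids, 30)
    all_sets <- c(sch$est_hybrids, sch$T2, sch$T1, sch$T0)
    expect_equal(sort(all_sets), sort(pop$plan$hybrid))
    expect_equal(anyDuplicated(all_sets), 0L)
    fe <- pop$plan$female[match(all_sets, pop$plan$hybrid)]
    ma <- pop$plan$male[match(all_sets, pop$plan$hybrid)]
    shared <- (fe %in% sch$est_females) + (ma %in% sch$est_males)
    grp <- rep(c("est", "T2", "T1", "T0"),
               c(length(sch$est_hybrids), length(sch$T2), length(sch$T1),
                 length(sch$T0)))
    expect_true(all(shared[grp == "est"] == 2))
    expect_true(all(shared[grp == "T2"] == 2))
    expect_true(all(shared[grp == "T1"] == 1))
    expect_true(all(shared[grp == "T0"] == 0))
  }
  # full-factorial set arithmetic: 12x4 internal = 48, minus 30 estimation
  sch <- sample_t_scheme(pop$plan, 12, 4, 30, seed = 91)
  expect_length(sch$T2, 48 - 30)
  expect_length(sch$T1, 12 * 2 + 8 * 4)
  expect_length(sch$T0, 8 * 2)
  expect_error(sample_t_scheme(pop$plan, 12, 4, 49, seed = 1),
               "internal")
  expect_length(sample_t_scheme(pop$plan, 12, 4, 49, seed = 1,
                                best_effort = TRUE)$est_hybrids, 48)
})

test_that("accuracy standardises by sqrt(h2) and clamps at one", {
  p <- c(1, 2, 3, 4, 5); o <- c(1.1, 2.2, 2.9, 4.3, 4.8)
  expect_equal(accuracy(p, o, h2 = 1), cor(p, o))
  # perfect prediction with h2 = 0.81: 1/0.9 > 1 -> clamped to 1
  expect_equal(accuracy(p, p, h2 = 0.81), 1)
  expect_equal(accuracy(p, o, h2 = 0.25), min(1, cor(p, o) / 0.5))
  expect_error(accuracy(rep(1, 5), o), "zero variance")
  expect_error(accuracy(p[1:2], o[1:2]), ">= 3")
  expect_error(accuracy(p, o, h2 = 0), "h2")
})

test_that("cross-validation runs are reproducible and scenario-complete", {
  fx <- cv_fixture()
  cv1 <- run_cv(fx$data, "rrblup", n_runs = 3, n_f_est = 20, n_m_est = 5,
                n_hyb_est = 60, lambda = c(lambda_A = 20, lambda_D = 1e6),
                seed = 5)
  cv2 <- run_cv(fx$data, "rrblup", n_runs = 3, n_f_est = 20, n_m_est = 5,
                n_hyb_est = 60, lambda = c(lambda_A = 20, lambda_D = 1e6),
                seed = 5)
  expect_identical(cv1$accuracy, cv2$accuracy)
  expect_equal(sort(unique(cv1$scenario)), c("T0", "T1", "T2"))
  expect_true(all(cv1$accuracy <= 1, na.rm = TRUE))
  expect_error(run_cv(fx$data, "rrblup", n_runs = 0), "n_runs")

  # GCA and mid-parent predictors are T2-only by construction
  gca <- run_cv(fx$data, "gca", n_runs = 2, n_f_est = 20, n_m_est = 5,
                n_hyb_est = 60, seed = 7)
  expect_true(all(is.na(gca$accuracy[gca$scenario %in% c("T0", "T1")])))
  expect_true(all(!is.na(gca$accuracy[gca$scenario == "T2"])))
  mp <- run_cv(fx$data, "mp", n_runs = 2, n_f_est = 20, n_m_est = 5,
               n_hyb_est = 60, seed = 7)
  expect_true(all(!is.na(mp$accuracy[mp$scenario == "T2"])))
})

test_that("marker-based prediction beats combining-ability baselines nowhere on T2 with additive truth", {
  # with purely additive genetics and a saturated factorial, GCA-based
  # prediction is the oracle for T2; RR-BLUP should come close but not exceed
  fx <- cv_fixture(h2 = 0.9)
  args <- list(n_runs = 3, n_f_est = 20, n_m_est = 5, n_hyb_est = 60,
               seed = 11)
  gca <- do.call(run_cv, c(list(fx$data, "gca"), args))
  rr <- do.call(run_cv, c(list(fx$data, "rrblup",
                               lambda = c(lambda_A = 10, lambda_D = 1e6)),
                          args))
  m_gca <- mean(gca$accuracy[gca$scenario == "T2"])
  m_rr <- mean(rr$accuracy[rr$scenario == "T2"])
  expect_gt(m_rr, 0.5)
  expect_gt(m_gca, m_rr - 0.1)
})

test_that("MAS cross-validation tracks selections per threshold", {
  fx <- cv_fixture(n_f = 25, n_m = 6, n_markers = 80, n_qtl = 20,
                   seed = 95)
  res <- mas_cv(fx$data, thresholds = list("holm", 0.001, 0.05),
                n_runs = 3, n_f_est = 16, n_m_est = 4, n_hyb_est = 40,
                seed = 13)
  acc <- res$accuracy
  expect_equal(sort(unique(acc$threshold)), sort(c("holm", "0.001", "0.05")))
  # within each run the selected-set size is monotone in the threshold
  for (r in unique(acc$run)) {
    n_sel <- sapply(c("0.001", "0.05"), function(th)
      acc$n_selected[acc$run == r & acc$threshold == th][1])
    expect_true(diff(n_sel) >= 0)
  }
  # occurrence counts are bounded by the number of runs
  expect_true(all(res$occurrence >= 0 & res$occurrence <= 3))
  # empty selections recorded as zero accuracy, never dropped
  expect_true(all(acc$accuracy[acc$n_selected == 0] == 0))
  expect_equal(nrow(acc), 3 * 3 * 3)
})

test_that("resampling studies respect their grids and reduction cases", {
  fx <- cv_fixture(n_f = 24, n_m = 6, n_markers = 90, seed = 97)
  lam <- c(lambda_A = 20, lambda_D = 1e6)

  expect_error(population_size_study(fx$data, female_grid = c(12, 50),
                                     n_runs = 1),
               "exceeds")
  ps <- population_size_study(fx$data, female_grid = c(12, 24),
                              n_m_total = 6, n_m_est = 4, n_hyb_est = 20,
                              n_runs = 2, lambda = lam, seed = 17)
  expect_equal(sort(unique(ps$n_females)), c(12, 24))
  # est females = ceiling(2/3 * grid)
  expect_true(all(ps$accuracy <= 1))

  expect_warning(hc <- hybrid_count_study(fx$data, hybrid_grid = c(40, 40),
                                          n_f_est = 16, n_m_est = 4,
                                          n_runs = 2, lambda = lam,
                                          seed = 19),
                 "duplicate")
  expect_equal(unique(hc$n_hybrids), 40)

  # the full-panel density reproduces run_cv under the same seeds
  md <- marker_density_study(fx$data, k_grid = c(30), window = 30,
                             n_f_est = 16, n_m_est = 4, n_hyb_est = 40,
                             n_runs = 2, lambda = lam, seed = 21)
  cv <- run_cv(fx$data, "rrblup", n_runs = 2, n_f_est = 16, n_m_est = 4,
               n_hyb_est = 40, lambda = lam, seed = 21)
  md_means <- tapply(md$accuracy, md$scenario, mean)
  cv_means <- tapply(cv$accuracy, cv$scenario, mean)
  expect_equal(as.vector(md_means), as.vector(cv_means[names(md_means)]),
               tolerance = 1e-10)
  expect_error(marker_density_study(fx$data, k_grid = 0, window = 30),
               ">= 1")
  expect_error(marker_density_study(fx$data, k_grid = 31, window = 30),
               "exceeds")
})
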