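# dense direct inversion of the full block mixed-model equation system:
# independent oracle for the MME solver
mme_dense_oracle <- function(y, ZA, ZD, lA, lD) {
  n <- length(y); m <- ncol(ZA)
  ones <- rep(1, n)
  W <- cbind(ZA, ZD)
  C <- rbind(cbind(crossprod(ones), t(crossprod(W, ones))),
             cbind(crossprod(W, ones),
                   crossprod(W) + diag(c(rep(lA, m), rep(lD, m)))))
  sol <- solve(C) %*% c(sum(y), crossprod(W, y))
  list(mu = sol[1], a = sol[1 + seq_len(m)], d = sol[1 + m + seq_len(m)])
}

random_instance <- function(n, m, seed, het = TRUE) {
  set.seed(seed)
  dos <- matrix(sample(if (het) 0:2 else c(0L, 2L), n * m, TRUE), n, m)
  g <- toy_geno(dos)
  dm <- code_design_matrices(g)
  rownames(dm$ZA) <- rownames(dm$ZD) <- rownames(g$dosage)
  y <- setNames(rnorm(n), rownames(g$dosage))
  list(dm = dm, y = y)
}

test_that("shrinkage parameters follow the variance-ratio definition", {
  lam <- shrinkage_params(sigma2_e = 4, sigma2_gca = 1, sigma2_sca = 2,
                          n_env = 4, n_marker = 10)
  expect_equal(unname(lam["lambda_A"]), 10)
  expect_equal(unname(lam["lambda_D"]), 5)
  # linear in the marker count
  lam2 <- shrinkage_params(4, 1, 2, 4, 20)
  expect_equal(unname(lam2["lambda_A"]), 20)
  expect_error(shrinkage_params(4, 0, 2, 4, 10), "sigma2_gca")
  expect_error(shrinkage_params(4, 1, 0, 4, 10), "sigma2_sca")
})

test_that("direct and dual MME solvers agree with dense inversion", {
  for (case in list(c(20, 8), c(15, 40), c(30, 30))) {
    inst <- random_instance(case[1], case[2], seed = 100 + case[2])
    lA <- 2.5; lD <- 7
    eff_dir <- rrblup_fit(inst$y, inst$dm, lA, lD, method = "direct")
    eff_dual <- rrblup_fit(inst$y, inst$dm, lA, lD, method = "dual")
    oracle <- mme_dense_oracle(unname(inst$y), inst$dm$ZA, inst$dm$ZD, lA, lD)
    expect_lt(max(abs(c(eff_dir$mu - oracle$mu,
                        eff_dir$additive - oracle$a,
                        eff_dir$dominance - oracle$d))), 1e-8)
    expect_lt(max(abs(c(eff_dual$mu - oracle$mu,
                        eff_dual$additive - oracle$a,
                        eff_dual$dominance - oracle$d))), 1e-8)
  }
})

test_that("infinite shrinkage collapses predictions to the training mean", {
  inst <- random_instance(25, 30, seed = 7)
  eff <- rrblup_fit(inst$y, inst$dm, 1e12, 1e12)
  expect_lt(max(abs(eff$additive)), 1e-9)
  pred <- predict_values(eff, inst$dm)
  expect_equal(unname(pred), rep(mean(inst$y), 25), tolerance = 1e-6)
})

test_that("noise-free additive traits are recovered under tiny shrinkage", {
  set.seed(9)
  inst <- random_instance(60, 25, seed = 9)
  a_true <- rnorm(25, 0, 1)
  y <- setNames(drop(3 + inst$dm$ZA %*% a_true), rownames(inst$dm$ZA))
  eff <- rrblup_fit(y, inst$dm, 1e-6, include_dominance = FALSE)
  pred <- predict_values(eff, inst$dm)
  expect_gt(cor(pred, y), 0.99)
  expect_gt(cor(eff$additive, a_true), 0.99)
})

test_that("additive-plus-dominance converges to additive-only as lambda_D grows", {
  inst <- random_instance(30, 40, seed = 11)
  eff_ad <- rrblup_fit(inst$y, inst$dm, 3, 1e10)
  eff_a <- rrblup_fit(inst$y, inst$dm, 3, include_dominance = FALSE)
  expect_lt(max(abs(predict_values(eff_ad, inst$dm) -
                      predict_values(eff_a, inst$dm))), 1e-4)
})

test_that("additive-only RR-BLUP equals kinship-based GBLUP", {
  inst <- random_instance(35, 80, seed = 13)
  lA <- 5
  eff <- rrblup_fit(inst$y, inst$dm, lA, include_dominance = FALSE)
  pred <- predict_values(eff, inst$dm)

  # GBLUP oracle: K = ZA ZA'/m, variance ratio lambda_A/m
  m <- inst$dm$m
  K <- tcrossprod(inst$dm$ZA) / m
  V <- K + (lA / m) * diag(35)
  Vi1 <- solve(V, rep(1, 35)); Viy <- solve(V, unname(inst$y))
  mu <- sum(Viy) / sum(Vi1)
  g_hat <- K %*% solve(V, unname(inst$y) - mu)
  expect_lt(max(abs(pred - (mu + drop(g_hat)))), 1e-6)
  expect_lt(abs(eff$mu - mu), 1e-6)
})

test_that("W-BLUP reduces to RR-BLUP on a duplicated-column panel at w = 1", {
  inst <- random_instance(25, 15, seed = 17)
  fid <- colnames(inst$dm$ZA)[c(3, 8)]
  wb <- wblup_fit(inst$y, inst$dm, fid, lambda_A = 4, lambda_D = 6, w = 1)

  # oracle: plain RR-BLUP on the panel with the functional columns duplicated
  ZA2 <- cbind(inst$dm$ZA, inst$dm$ZA[, fid])
  ZD2 <- cbind(inst$dm$ZD, inst$dm$ZD[, fid])
  oracle <- mme_dense_oracle(unname(inst$y), ZA2, ZD2, 4, 6)
  a_tot <- oracle$a[1:15]; a_tot[c(3, 8)] <- a_tot[c(3, 8)] + oracle$a[16:17]
  expect_lt(max(abs(wb$additive - a_tot)), 1e-6)
  expect_lt(abs(wb$mu - oracle$mu), 1e-6)

  expect_error(wblup_fit(inst$y, inst$dm, c("m03", "m03"), 4), "duplicate")
  expect_error(wblup_fit(inst$y, inst$dm, "nope", 4), "unknown")
})

test_that("declaring a large QTL functional sharpens its effect estimate", {
  hits <- 0L
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    set.seed(300 + r)
    dos <- matrix(sample(0:2, 120 * 60, TRUE), 120, 60)
    g <- toy_geno(dos)
    dm <- code_design_matrices(g)
    rownames(dm$ZA) <- rownames(dm$ZD) <- rownames(g$dosage)
    a_true <- rnorm(60, 0, 0.15); a_true[30] <- 2.5
    y <- setNames(drop(dm$ZA %*% a_true) + rnorm(120, 0, 1),
                  rownames(g$dosage))
    lam <- c(lambda_A = 30, lambda_D = 1e6)
    rb <- rrblup_fit(y, dm, lam[1], lam[2])
    wb <- wblup_fit(y, dm, colnames(dm$ZA)[30], lam[1], lam[2], w = 100)
    if (abs(wb$additive[30] - 2.5) < abs(rb$additive[30] - 2.5))
      hits <- hits + 1L
  }
  expect_gte(hits, 0.8 * n_rep)
})

test_that("prediction is the fitted linear score over target rows", {
  inst <- random_instance(10, 12, seed = 19)
  eff <- rrblup_fit(inst$y, inst$dm, 2, 3)
  # hand-computed dot product for one individual
  i <- 4
  manual <- eff$mu + sum(inst$dm$ZA[i, ] * eff$additive) +
    sum(inst$dm$ZD[i, ] * eff$dominance)
  expect_equal(unname(predict_values(eff, inst$dm)[i]), manual,
               tolerance = 1e-10)

  # all-zero effects predict the constant intercept
  eff0 <- eff; eff0$additive[] <- 0; eff0$dominance[] <- 0
  expect_equal(unname(predict_values(eff0, inst$dm)),
               rep(eff$mu, 10))

  # marker panel mismatch is an error naming the offender
  dm2 <- inst$dm
  colnames(dm2$ZA) <- paste0("x_", colnames(dm2$ZA))
  expect_error(predict_values(eff, dm2), "mismatch")
})

test_that("GCA prediction reconstructs additive factorials and rejects T0", {
  pop <- toy_population(n_f = 6, n_m = 4, n_markers = 30, seed = 23)
  tr <- simulate_genetic_values(pop$geno, n_qtl = 12, additive_sd = 1,
                                dominance_sd = 0, seed = 24)
  y <- tr$values[pop$plan$hybrid]
  gm <- gca_sca(y, pop$plan)
  pred <- gca_predict(gm, pop$plan)
  # saturated additive factorial: exact reconstruction
  expect_equal(unname(pred[names(y)]), unname(y), tolerance = 1e-8)

  t0_plan <- structure(data.frame(hybrid = "ZxQ", female = "Z", male = "Q"),
                       class = c("crossing_plan", "data.frame"))
  expect_error(gca_predict(gm, t0_plan), "not all T2")
})

test_that("mid-parent prediction averages the parental values", {
  plan <- structure(data.frame(hybrid = c("AxB", "BxA2"),
                               female = c("A", "A2"), male = c("B", "B"),
                               stringsAsFactors = FALSE),
                    class = c("crossing_plan", "data.frame"))
  bl <- c(A = 40, B = 50, A2 = 30)
  expect_equal(unname(mp_predict(bl, plan)), c(45, 40))
  # symmetric in parent order
  plan_sw <- plan; plan_sw$female <- plan$male; plan_sw$male <- plan$female
  class(plan_sw) <- c("crossing_plan", "data.frame")
  expect_equal(unname(mp_predict(bl, plan_sw)), c(45, 40))
  expect_error(mp_predict(bl[-1], plan), "missing parental BLUE")

  # whole-plan brute force
  pop <- toy_population(n_f = 5, n_m = 3, n_markers = 10, seed = 27)
  set.seed(28)
  pb <- setNames(rnorm(8), rownames(pop$parents$dosage))
  mp <- mp_predict(pb, pop$plan)
  expect_equal(unname(mp),
               unname((pb[pop$plan$female] + pb[pop$plan$male]) / 2))
})

test_that("REML-estimated shrinkage recovers the simulated variance ratio", {
  set.seed(31)
  dos <- matrix(sample(c(0L, 2L), 200 * 120, TRUE), 200, 120)
  g <- toy_geno(dos)
  dm <- code_design_matrices(g)
  rownames(dm$ZA) <- rownames(dm$ZD) <- rownames(g$dosage)
  a_true <- rnorm(120, 0, sqrt(0.02))
  y <- setNames(drop(dm$ZA %*% a_true) + rnorm(200, 0, 1),
                rownames(g$dosage))
  lam <- estimate_lambda(y, dm, include_dominance = FALSE)
  # true lambda_A = sigma2_e / sigma2_a = 1 / 0.02 = 50
  expect_gt(lam[["lambda_A"]], 15)
  expect_lt(lam[["lambda_A"]], 170)
})
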