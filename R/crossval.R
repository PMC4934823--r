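#' Bundle the inputs of a cross-validation study
#'
#' @param plan `crossing_plan` of all realised hybrids.
#' @param geno `geno_matrix` covering parents and hybrids (post-QC).
#' @param pheno_hybrids Named numeric vector: hybrid phenotypes (BLUEs or
#'   entry means) for every hybrid of the plan.
#' @param pheno_parents Named numeric vector of parental phenotypes (needed
#'   for mid-parent prediction).
#' @param h2 Entry-mean heritability used to standardise accuracies,
#'   estimated once from the full data.
#' @return List of class `cv_data` with precomputed design matrices.
#' @export
cv_data <- function(plan, geno, pheno_hybrids, pheno_parents = NULL, h2 = 1) {
  stopifnot(inherits(plan, "crossing_plan"), inherits(geno, "geno_matrix"))
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  absent <- setdiff(plan$hybrid, names(pheno_hybrids))
  if (length(absent)) stop("phenotypes missing for ",
                           length(absent), " hybrids")
  dm <- code_design_matrices(geno, impute = TRUE)
  rownames(dm$ZA) <- rownames(dm$ZD) <- rownames(geno$dosage)
  structure(list(plan = plan, geno = geno, dm = dm,
                 pheno_hybrids = pheno_hybrids,
                 pheno_parents = pheno_parents, h2 = h2),
            class = "cv_data")
}

#' Sample one relatedness-stratified cross-validation scheme
#'
#' Uniformly samples estimation parents (`n_f_est` females, `n_m_est` males)
#' and `n_hyb_est` estimation hybrids among the crosses internal to them,
#' then classifies every remaining hybrid of the plan by the shared-parent
#' rule: T2 = both parents in the estimation parent sets (but the hybrid
#' itself unevaluated), T1 = exactly one parent (either female or male)
#' shared, T0 = no parent in common with the estimation set.
#'
#' @param plan `crossing_plan`.
#' @param n_f_est,n_m_est,n_hyb_est Estimation-set composition (defaults
#'   80 females of 120, 10 males of 15, 610 hybrids of the up-to-800
#'   internal crosses).
#' @param seed Integer seed.
#' @param best_effort If the internal crosses number fewer than `n_hyb_est`,
#'   take all of them instead of raising an error.
#' @return List of class `cv_scheme`: `est_females`, `est_males`,
#'   `est_hybrids`, `T2`, `T1`, `T0` (hybrid id vectors), `seed`.
#' @export
sample_t_scheme <- function(plan, n_f_est = 80, n_m_est = 10,
                            n_hyb_est = 610, seed = NULL,
                            best_effort = FALSE) {
  stopifnot(inherits(plan, "crossing_plan"))
  females <- unique(plan$female); males <- unique(plan$male)
  if (n_f_est > length(females) || n_m_est > length(males))
    stop("requested more estimation parents than the plan contains")
  if (!is.null(seed)) set.seed(seed)
  ef <- sample(females, n_f_est)
  em <- sample(males, n_m_est)
  internal <- plan$hybrid[plan$female %in% ef & plan$male %in% em]
  if (length(internal) < n_hyb_est) {
    if (!best_effort)
      stop(sprintf("only %d crosses internal to the estimation parents (%d requested)",
                   length(internal), n_hyb_est))
    n_hyb_est <- length(internal)
  }
  est_h <- sample(internal, n_hyb_est)
  rest <- setdiff(plan$hybrid, est_h)
  pf <- plan$female[match(rest, plan$hybrid)] %in% ef
  pm <- plan$male[match(rest, plan$hybrid)] %in% em
  structure(list(est_females = sort(ef), est_males = sort(em),
                 est_hybrids = sort(est_h),
                 T2 = sort(rest[pf & pm]),
                 T1 = sort(rest[xor(pf, pm)]),
                 T0 = sort(rest[!pf & !pm]),
                 seed = seed),
            class = "cv_scheme")
}

#' @export
print.cv_scheme <- function(x, ...) {
  cat(sprintf("cv_scheme: est %dF x %dM, %d hybrids | T2 %d, T1 %d, T0 %d\n",
              length(x$est_females), length(x$est_males),
              length(x$est_hybrids), length(x$T2), length(x$T1),
              length(x$T0)))
  invisible(x)
}

#' Prediction accuracy standardised by heritability
#'
#' Pearson correlation between predicted and observed values divided by the
#' square root of the entry-mean heritability; values above 1 are set to 1.
#'
#' @param predicted,observed Numeric vectors (>= 3 pairs).
#' @param h2 Heritability in (0, 1].
#' @return Single accuracy value (<= 1).
#' @export
accuracy <- function(predicted, observed, h2 = 1) {
  if (length(predicted) != length(observed) || length(predicted) < 3)
    stop("need >= 3 prediction/observation pairs")
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    stop("zero variance in predictions or observations")
  min(1, stats::cor(predicted, observed) / sqrt(h2))
}

fit_and_predict <- function(data, model, scheme, lambda, w = 100,
                            chain = list(), functional_k = 3, alpha = 0.05) {
  est <- scheme$est_hybrids
  y <- data$pheno_hybrids[est]
  scen <- list(T2 = scheme$T2, T1 = scheme$T1, T0 = scheme$T0)
  pred_all <- function(eff) {
    targets <- unlist(scen, use.names = FALSE)
    predict_values(eff, data$dm, ids = targets)
  }
  if (model %in% c("rrblup", "rrblup_a", "wblup", "bayescpi")) {
    if (is.null(lambda) && model != "bayescpi")
      lambda <- estimate_lambda(y, data$dm,
                                include_dominance = model != "rrblup_a")
    eff <- switch(model,
      rrblup = rrblup_fit(y, data$dm, lambda["lambda_A"], lambda["lambda_D"]),
      rrblup_a = rrblup_fit(y, data$dm, lambda["lambda_A"],
                            include_dominance = FALSE),
      wblup = {
        Kest <- tcrossprod(data$dm$ZA[est, , drop = FALSE]) / data$dm$m
        rownames(Kest) <- colnames(Kest) <- est
        scan <- gwas_scan(y, subset_geno(data$geno, est), Kest, "additive")
        wblup_fit(y, data$dm, top_k_markers(scan, functional_k),
                  lambda["lambda_A"], lambda["lambda_D"], w = w)
      },
      bayescpi = bayescpi_fit(y, data$dm, chain = chain))
    ph <- pred_all(eff)
    lapply(scen, function(ids) if (length(ids)) ph[ids] else numeric(0))
  } else if (model == "gca") {
    gm <- gca_sca(y, data$plan)
    out <- lapply(scen, function(ids) NULL)
    # GCA is estimable only for parents represented among the estimation
    # crosses; T2 targets of unrepresented parents are skipped
    t2 <- plan_subset(data$plan, scheme$T2)
    ok <- t2$female %in% names(gm$gca_f) & t2$male %in% names(gm$gca_m)
    out$T2 <- gca_predict(gm, plan_subset(data$plan, t2$hybrid[ok]))
    out
  } else if (model == "mp") {
    pb <- data$pheno_parents
    if (is.null(pb)) stop("mid-parent prediction needs parental phenotypes")
    pb <- pb[names(pb) %in% c(scheme$est_females, scheme$est_males)]
    out <- lapply(scen, function(ids) NULL)
    out$T2 <- mp_predict(pb, plan_subset(data$plan, scheme$T2))
    out
  } else stop("unknown model: ", model)
}

plan_subset <- function(plan, hybrids) {
  out <- plan[plan$hybrid %in% hybrids, , drop = FALSE]
  class(out) <- c("crossing_plan", "data.frame")
  out
}

subset_geno <- function(geno, ids) {
  out <- geno
  out$dosage <- geno$dosage[ids, , drop = FALSE]
  out
}

#' Relatedness-stratified cross-validation of a prediction model
#'
#' For each run, samples a fresh estimation/T2/T1/T0 scheme (seed = master
#' seed + run), fits the model on the estimation hybrids, predicts every test
#' scenario it is defined for, and computes heritability-standardised
#' accuracies. GCA- and mid-parent-based prediction are only defined for T2
#' test hybrids.
#'
#' @param data A `cv_data` bundle.
#' @param model One of `"rrblup"`, `"rrblup_a"` (additive only), `"wblup"`,
#'   `"bayescpi"`, `"gca"`, `"mp"`.
#' @param n_runs Number of cross-validation runs (default 100).
#' @param n_f_est,n_m_est,n_hyb_est Estimation-set composition.
#' @param lambda Optional fixed `c(lambda_A, lambda_D)`; default: REML
#'   estimates per run via [estimate_lambda()].
#' @param seed Master seed; run r uses `seed + r`.
#' @param ... Passed to the model fit (`w`, `chain`, `functional_k`).
#' @param best_effort Passed to [sample_t_scheme()].
#' @return Data.frame of class `accuracy_result`: `run`, `scenario`, `model`,
#'   `accuracy`, `n_test`; attribute `means` holds per-scenario mean
#'   accuracies.
#' @export
run_cv <- function(data, model = "rrblup", n_runs = 100, n_f_est = 80,
                   n_m_est = 10, n_hyb_est = 610, lambda = NULL, seed = 1,
                   best_effort = FALSE, ...) {
  stopifnot(inherits(data, "cv_data"))
  if (n_runs < 1) stop("n_runs must be >= 1")
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    scheme <- sample_t_scheme(data$plan, n_f_est, n_m_est, n_hyb_est,
                              seed = seed + r, best_effort = best_effort)
    preds <- fit_and_predict(data, model, scheme, lambda, ...)
    acc <- vapply(names(preds), function(sc) {
      p <- preds[[sc]]
      if (is.null(p) || length(p) < 3) return(NA_real_)
      accuracy(p, data$pheno_hybrids[names(p)], data$h2)
    }, numeric(1))
    rows[[r]] <- data.frame(run = r, scenario = names(acc), model = model,
                            accuracy = unname(acc),
                            n_test = vapply(preds, length, 0L),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "means") <- tapply(res$accuracy, res$scenario, mean,
                               na.rm = TRUE)
  class(res) <- c("accuracy_result", "data.frame")
  res
}

#' Cross-validated marker-assisted selection over significance thresholds
#'
#' Per run: an association scan on the estimation hybrids, marker selection
#' at each threshold (`"holm"` = Bonferroni-Holm at alpha, numeric entries =
#' unadjusted p-value cutoffs), joint effect estimation of the selected
#' markers by generalised least squares with the polygenic covariance of the
#' scan's null model, and prediction of the test scenarios. Runs with an
#' empty selection contribute an accuracy of 0 at that threshold. Occurrence
#' frequencies count, per marker and threshold, the runs in which the marker
#' was selected.
#'
#' @param data A `cv_data` bundle.
#' @param thresholds List/vector mixing the string `"holm"` and numeric
#'   cutoffs; default `list("holm", 1e-4, 1e-3, 1e-2, 0.05, 0.1)`.
#' @param alpha Family-wise level for the Holm threshold.
#' @param n_runs,n_f_est,n_m_est,n_hyb_est,seed,best_effort As in [run_cv()].
#' @return List of class `mas_cv_result`: `accuracy` (data.frame run,
#'   scenario, threshold, accuracy, n_selected), `occurrence` (marker x
#'   threshold count matrix), `n_runs`.
#' @export
mas_cv <- function(data, thresholds = list("holm", 1e-4, 1e-3, 1e-2, 0.05,
                                           0.1),
                   alpha = 0.05, n_runs = 100, n_f_est = 80, n_m_est = 10,
                   n_hyb_est = 610, seed = 1, best_effort = FALSE) {
  stopifnot(inherits(data, "cv_data"))
  thr_names <- vapply(thresholds, function(t)
    if (identical(t, "holm")) "holm" else format(t, scientific = FALSE),
    character(1))
  markers <- colnames(data$dm$ZA)
  occ <- matrix(0L, length(markers), length(thresholds),
                dimnames = list(markers, thr_names))
  rows <- list()
  for (r in seq_len(n_runs)) {
    scheme <- sample_t_scheme(data$plan, n_f_est, n_m_est, n_hyb_est,
                              seed = seed + r, best_effort = best_effort)
    est <- scheme$est_hybrids
    y <- data$pheno_hybrids[est]
    Kest <- tcrossprod(data$dm$ZA[est, , drop = FALSE]) / data$dm$m
    rownames(Kest) <- colnames(Kest) <- est
    scan <- gwas_scan(y, subset_geno(data$geno, est), Kest, "additive")
    scen <- list(T2 = scheme$T2, T1 = scheme$T1, T0 = scheme$T0)
    for (ti in seq_along(thresholds)) {
      t <- thresholds[[ti]]
      sel <- if (identical(t, "holm")) scan$marker[holm_correct(scan$p_value, alpha)]
             else scan$marker[!is.na(scan$p_value) & scan$p_value < t]
      occ[sel, ti] <- occ[sel, ti] + 1L
      for (sc in names(scen)) {
        ids <- scen[[sc]]
        if (length(ids) < 3) next
        acc <- if (!length(sel)) 0 else {
          pred <- mas_gls_predict(y, data$dm, est, sel, ids,
                                  attr(scan, "delta"))
          if (stats::sd(pred) == 0) 0
          else accuracy(pred, data$pheno_hybrids[ids], data$h2)
        }
        rows[[length(rows) + 1L]] <-
          data.frame(run = r, scenario = sc, threshold = thr_names[ti],
                     accuracy = acc, n_selected = length(sel),
                     stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(list(accuracy = res, occurrence = occ, n_runs = n_runs),
            class = "mas_cv_result")
}

# joint GLS effect estimates of selected markers under the polygenic
# covariance V = K_est + delta I (variance ratio from the scan's null fit)
mas_gls_predict <- function(y, dm, est, sel, target, delta) {
  Zt <- dm$ZA[est, sel, drop = FALSE]
  X <- cbind(1, Zt)
  K <- tcrossprod(dm$ZA[est, , drop = FALSE]) / dm$m
  V <- K + diag(delta, length(est))
  Vi_X <- solve(V, X)
  XtViX <- crossprod(X, Vi_X)
  beta <- tryCatch(solve(XtViX, crossprod(Vi_X, y)),
                   error = function(e) qr.solve(XtViX, crossprod(Vi_X, y)))
  drop(cbind(1, dm$ZA[target, sel, drop = FALSE]) %*% beta)
}

#' Effect of parental-line count on prediction accuracy
#'
#' For each grid entry: per run, a random subset of that many female parents
#' (all `n_m_total` males kept) defines a subpopulation; an estimation set of
#' two thirds of the selected females, 10 males and 100 hybrids is sampled
#' within it and RR-BLUP accuracies are computed for the T2/T1/T0 scenarios.
#'
#' @param data A `cv_data` bundle.
#' @param female_grid Numbers of female parents (default 30, 60, 90, 120).
#' @param n_m_total Males kept in each subpopulation (default 15).
#' @param n_m_est,n_hyb_est Estimation males and hybrids (defaults 10, 100).
#' @param n_runs Runs per grid entry (default 100).
#' @param lambda,seed,best_effort As in [run_cv()].
#' @return Data.frame `n_females`, `run`, `scenario`, `accuracy`.
#' @export
population_size_study <- function(data, female_grid = c(30, 60, 90, 120),
                                  n_m_total = 15, n_m_est = 10,
                                  n_hyb_est = 100, n_runs = 100,
                                  lambda = NULL, seed = 1,
                                  best_effort = FALSE) {
  stopifnot(inherits(data, "cv_data"))
  females <- unique(data$plan$female)
  if (any(female_grid > length(females)))
    stop("female_grid exceeds the number of female parents available")
  out <- list()
  for (nf in female_grid) {
    n_f_est <- ceiling(2 / 3 * nf)
    for (r in seq_len(n_runs)) {
      set.seed(seed + 7919L * match(nf, female_grid) + r)
      fsub <- sample(females, nf)
      sub_plan <- plan_subset(data$plan,
                              data$plan$hybrid[data$plan$female %in% fsub])
      sub <- data; sub$plan <- sub_plan
      scheme <- sample_t_scheme(sub_plan, n_f_est, n_m_est, n_hyb_est,
                                seed = seed + 104729L * match(nf, female_grid) + r,
                                best_effort = best_effort)
      preds <- fit_and_predict(sub, "rrblup", scheme, lambda)
      for (sc in names(preds)) {
        p <- preds[[sc]]
        if (length(p) < 3) next
        out[[length(out) + 1L]] <- data.frame(
          n_females = nf, run = r, scenario = sc,
          accuracy = accuracy(p, data$pheno_hybrids[names(p)], data$h2),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Effect of estimation-hybrid count on prediction accuracy
#'
#' Keeps the estimation parent composition fixed (80 females, 10 males by
#' default) and varies the number of estimation hybrids over the grid.
#'
#' @param data A `cv_data` bundle.
#' @param hybrid_grid Estimation hybrid counts (default 610, 500, 300, 100;
#'   duplicates are collapsed with a warning).
#' @param n_f_est,n_m_est,n_runs,lambda,seed,best_effort As in [run_cv()].
#' @return Data.frame `n_hybrids`, `run`, `scenario`, `accuracy`.
#' @export
hybrid_count_study <- function(data, hybrid_grid = c(610, 500, 300, 100),
                               n_f_est = 80, n_m_est = 10, n_runs = 100,
                               lambda = NULL, seed = 1,
                               best_effort = FALSE) {
  if (anyDuplicated(hybrid_grid)) {
    warning("duplicate entries in hybrid_grid collapsed")
    hybrid_grid <- unique(hybrid_grid)
  }
  out <- list()
  for (nh in hybrid_grid) {
    cv <- run_cv(data, "rrblup", n_runs = n_runs, n_f_est = n_f_est,
                 n_m_est = n_m_est, n_hyb_est = nh, lambda = lambda,
                 seed = seed, best_effort = best_effort)
    cv$n_hybrids <- nh
    out[[length(out) + 1L]] <- as.data.frame(cv)[, c("n_hybrids", "run",
                                                     "scenario", "accuracy")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Effect of marker density on prediction accuracy
#'
#' For each density (k markers kept per window of `window` markers,
#' see [equidistant_subsample()]): per run, markers are resampled, RR-BLUP is
#' fitted on the estimation hybrids of the run's scheme, and scenario
#' accuracies are computed. Run seeds are shared across densities so the
#' schemes are paired.
#'
#' @param data A `cv_data` bundle.
#' @param k_grid Markers per window to retain (k = window keeps the full
#'   panel).
#' @param window Window size on the marker axis.
#' @param n_f_est,n_m_est,n_hyb_est,n_runs,lambda,seed,best_effort As in
#'   [run_cv()].
#' @return Data.frame `k`, `n_markers`, `run`, `scenario`, `accuracy`.
#' @export
marker_density_study <- function(data, k_grid, window = 173, n_f_est = 80,
                                 n_m_est = 10, n_hyb_est = 610,
                                 n_runs = 100, lambda = NULL, seed = 1,
                                 best_effort = FALSE) {
  stopifnot(inherits(data, "cv_data"))
  if (any(k_grid < 1)) stop("densities must be >= 1 marker per window")
  if (any(k_grid > window)) stop("density exceeds the window size")
  m <- data$dm$m
  out <- list()
  for (k in k_grid) {
    for (r in seq_len(n_runs)) {
      idx <- equidistant_subsample(m, k, window, seed = seed + 7L * r + k)
      sub <- data
      sub$dm <- list(ZA = data$dm$ZA[, idx, drop = FALSE],
                     ZD = data$dm$ZD[, idx, drop = FALSE],
                     n = data$dm$n, m = length(idx))
      class(sub$dm) <- "design_matrices"
      scheme <- sample_t_scheme(data$plan, n_f_est, n_m_est, n_hyb_est,
                                seed = seed + r, best_effort = best_effort)
      preds <- fit_and_predict(sub, "rrblup", scheme, lambda)
      for (sc in names(preds)) {
        p <- preds[[sc]]
        if (length(p) < 3) next
        out[[length(out) + 1L]] <- data.frame(
          k = k, n_markers = length(idx), run = r, scenario = sc,
          accuracy = accuracy(p, data$pheno_hybrids[names(p)], data$h2),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
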