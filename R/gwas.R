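#' REML fit of the null polygenic model y = Xb + u + e, var(u) = H * s2_u
#'
#' Spectral (eigendecomposition-based) restricted maximum likelihood for a
#' single genetic variance component: the covariance H (a kinship matrix
#' expanded to observation level) is diagonalised once and the REML criterion
#' is profiled over the variance ratio delta = s2_e / s2_u.
#'
#' @param y Numeric response vector.
#' @param X Fixed-effects design matrix (full column rank).
#' @param H Symmetric covariance structure of the genetic term (n x n).
#' @param log_delta_bounds Search interval for log(delta).
#' @return List: `sigma2_u`, `sigma2_e`, `delta`, `U` (eigenvectors),
#'   `lambda` (eigenvalues, clamped at 0), `reml_loglik`.
#' @keywords internal
reml_polygenic <- function(y, X, H, log_delta_bounds = c(-12, 12)) {
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(H) == n)
  p <- ncol(X)
  eg <- eigen(H, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)

  neg_reml <- function(log_delta) {
    w <- lambda + exp(log_delta)
    sw <- 1 / sqrt(w)
    Xw <- Xs * sw
    yw <- ys * sw
    XtX <- crossprod(Xw)
    bh <- solve(XtX, crossprod(Xw, yw))
    r <- yw - Xw %*% bh
    rss <- sum(r^2)
    s2u <- rss / (n - p)
    0.5 * ((n - p) * log(s2u) + sum(log(w)) +
             determinant(XtX, logarithm = TRUE)$modulus + (n - p))
  }
  opt <- stats::optimize(neg_reml, interval = log_delta_bounds)
  delta <- exp(opt$minimum)
  w <- lambda + delta
  sw <- 1 / sqrt(w)
  Xw <- Xs * sw
  yw <- ys * sw
  bh <- solve(crossprod(Xw), crossprod(Xw, yw))
  s2u <- sum((yw - Xw %*% bh)^2) / (n - p)
  list(sigma2_u = s2u, sigma2_e = s2u * delta, delta = delta,
       U = U, lambda = lambda, reml_loglik = -opt$objective)
}

#' Kinship-corrected genome-wide association scan
#'
#' Tests each marker in the mixed model `Y = X beta + S s + Z u + e`, where
#' `Y` are adjusted entry means (within environments, stacked, with
#' environment fixed effects; or a single vector of BLUEs), `s` is the fixed
#' SNP effect and `u` is a polygenic background with covariance proportional
#' to the kinship matrix. By default the genetic and residual variances are
#' estimated once under the no-marker null and reused for every marker test
#' (the standard population-parameters-previously-determined approximation);
#' `exact = TRUE` re-estimates them per marker. Wald F tests.
#'
#' @param entry_means Either a data.frame `genotype`, `environment`, `mean`
#'   (stacked stage-one output) or a named numeric vector of BLUEs.
#' @param geno A `geno_matrix` covering the scanned genotypes.
#' @param K Kinship matrix with dimnames covering the genotypes (see
#'   [kinship()]); rows are matched by genotype id if dimnames are present,
#'   else by position against `geno`.
#' @param effect `"additive"` (F-infinity -1/0/1 codes) or `"dominance"`
#'   (0/1 heterozygote codes; only genotypes carrying heterozygous calls --
#'   i.e. hybrids -- are informative and the scan is restricted to them).
#' @param exact Re-estimate variance components per marker (slow).
#' @param gxe Also test a marker-by-environment interaction (F test on the
#'   interaction block); only meaningful with stacked per-environment means.
#' @return A data.frame of class `assoc_result` with columns `marker`,
#'   `chrom`, `pos_cM`, `effect_type`, `estimate`, `p_value`, `skipped`;
#'   `p_gxe` when `gxe = TRUE`. Attributes: `delta`, `sigma2_u`, `sigma2_e`,
#'   `n_genotypes`.
#' @export
gwas_scan <- function(entry_means, geno, K, effect = c("additive", "dominance"),
                      exact = FALSE, gxe = FALSE) {
  stopifnot(inherits(geno, "geno_matrix"))
  effect <- match.arg(effect)
  if (is.data.frame(entry_means)) {
    gid <- entry_means$genotype
    env <- factor(entry_means$environment)
    y <- entry_means$mean
  } else {
    gid <- names(entry_means)
    env <- factor(rep("all", length(gid)))
    y <- unname(entry_means)
  }
  dos <- geno$dosage
  if (effect == "dominance") {
    informative <- rownames(dos)[rowSums(dos == 1L, na.rm = TRUE) > 0L]
    keep <- gid %in% informative
    gid <- gid[keep]; env <- droplevels(env[keep]); y <- y[keep]
    if (!length(y)) stop("no heterozygous genotypes: dominance scan undefined")
  }
  miss <- setdiff(unique(gid), rownames(dos))
  if (length(miss)) stop("genotypes without marker data: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  M <- if (effect == "additive") dos[gid, , drop = FALSE] - 1
       else 1 * (dos[gid, , drop = FALSE] == 1L)
  if (anyNA(M)) stop("missing dosages in scan panel; impute or filter first")

  if (!is.null(rownames(K))) {
    missK <- setdiff(unique(gid), rownames(K))
    if (length(missK)) stop("kinship matrix lacks genotypes: ",
                            paste(utils::head(missK, 5), collapse = ", "))
    H <- K[gid, gid]
  } else {
    if (nrow(K) != nrow(dos))
      stop("kinship dimension does not match the genotype panel")
    rownames(K) <- colnames(K) <- rownames(dos)
    H <- K[gid, gid]
  }

  X <- if (nlevels(env) > 1) stats::model.matrix(~env) else
    matrix(1, length(y), 1)
  null_fit <- reml_polygenic(y, X, H)

  sw <- 1 / sqrt(null_fit$lambda + null_fit$delta)
  Ut <- t(null_fit$U)
  yw <- drop(Ut %*% y) * sw
  Xw <- (Ut %*% X) * sw
  Mw <- (Ut %*% M) * sw

  ry <- stats::resid(stats::lm.fit(Xw, yw))
  RM <- Mw - Xw %*% solve(crossprod(Xw), crossprod(Xw, Mw))
  ss_m <- colSums(RM^2)
  n <- length(y); p <- ncol(X)
  col_sd <- apply(M, 2, stats::sd)
  skipped <- col_sd == 0 | ss_m < 1e-10

  est <- pval <- rep(NA_real_, ncol(M))
  ok <- which(!skipped)
  b <- colSums(RM[, ok, drop = FALSE] * ry) / ss_m[ok]
  rss0 <- sum(ry^2)
  rss1 <- rss0 - b^2 * ss_m[ok]
  df2 <- n - p - 1
  Fstat <- pmax(0, (rss0 - rss1)) / (rss1 / df2)
  est[ok] <- b
  pval[ok] <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)

  if (exact) {
    for (j in ok) {
      fitj <- reml_polygenic(y, cbind(X, M[, j]), H)
      swj <- 1 / sqrt(fitj$lambda + fitj$delta)
      Xj <- (t(fitj$U) %*% cbind(X, M[, j])) * swj
      yj <- drop(t(fitj$U) %*% y) * swj
      cf <- stats::lm.fit(Xj, yj)
      rssj <- sum(cf$residuals^2)
      ryj <- stats::resid(stats::lm.fit(Xj[, seq_len(p), drop = FALSE], yj))
      Fj <- (sum(ryj^2) - rssj) / (rssj / df2)
      est[j] <- cf$coefficients[p + 1]
      pval[j] <- stats::pf(max(0, Fj), 1, df2, lower.tail = FALSE)
    }
  }

  res <- data.frame(marker = colnames(dos), chrom = geno$map$chrom,
                    pos_cM = geno$map$pos_cM, effect_type = effect,
                    estimate = est, p_value = pval, skipped = skipped,
                    stringsAsFactors = FALSE)

  if (gxe && nlevels(env) > 1) {
    env_ind <- stats::model.matrix(~ 0 + env)
    p_gxe <- rep(NA_real_, ncol(M))
    for (j in ok) {
      SX <- cbind(Xw, Mw[, j])
      # interaction columns: marker code within each environment
      SXI <- cbind(Xw, (Ut %*% (env_ind * M[, j])) * sw)
      f_main <- stats::lm.fit(SX, yw)
      f_int <- stats::lm.fit(SXI, yw)
      df_extra <- f_main$df.residual - f_int$df.residual
      if (df_extra > 0 && f_int$df.residual > 0) {
        rss_m <- sum(f_main$residuals^2)
        rss_i <- sum(f_int$residuals^2)
        Fi <- ((rss_m - rss_i) / df_extra) / (rss_i / f_int$df.residual)
        p_gxe[j] <- stats::pf(max(0, Fi), df_extra, f_int$df.residual,
                              lower.tail = FALSE)
      }
    }
    res$p_gxe <- p_gxe
  }

  attr(res, "delta") <- null_fit$delta
  attr(res, "sigma2_u") <- null_fit$sigma2_u
  attr(res, "sigma2_e") <- null_fit$sigma2_e
  attr(res, "n_genotypes") <- length(unique(gid))
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Bonferroni-Holm step-down multiple-testing correction
#'
#' Sorts the p-values ascending and rejects hypothesis (i) while
#' `p_(i) < alpha / (m - i + 1)`, stopping at the first failure.
#'
#' @param pvalues Numeric vector (NAs are never rejected).
#' @param alpha Family-wise significance level in (0, 1).
#' @return Logical vector in the input order: `TRUE` = rejected.
#' @export
holm_correct <- function(pvalues, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  m <- length(pvalues)
  reject <- logical(m)
  if (m == 0L) return(reject)
  ord <- order(pvalues, na.last = TRUE)
  ps <- pvalues[ord]
  for (i in seq_len(m)) {
    if (is.na(ps[i]) || ps[i] >= alpha / (m - i + 1)) break
    reject[ord[i]] <- TRUE
  }
  reject
}

#' Observed-vs-expected quantiles for a QQ plot of p-values
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return A data.frame `expected` and `observed` (-log10 scale), sorted by
#'   significance.
#' @export
qq_data <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (any(pvalues <= 0)) stop("p-values must be > 0")
  m <- length(pvalues)
  data.frame(expected = -log10(seq_len(m) / (m + 1)),
             observed = -log10(sort(pvalues)))
}

#' Phenotypic and genotypic variance explained by detected QTL
#'
#' Sequential (type-I) R-squared per QTL with the QTL ordered by ascending
#' p-value, joint adjusted R-squared from the multiple regression of the
#' BLUEs on all selected markers, and the proportion of genotypic variance
#' `p_G = R2_adj / h2` (capped at 1 with a warning).
#'
#' @param result An `assoc_result` restricted to the selected markers (or any
#'   data.frame with `marker` and `p_value`).
#' @param blues Named numeric vector of BLUEs.
#' @param dm `design_matrices` whose rows are named by genotype and cover
#'   `names(blues)`.
#' @param h2 Broad-sense heritability used for standardisation.
#' @return List of class `variance_explained`: `per_qtl` (data.frame marker,
#'   R2), `R2_adj`, `p_G`, `h2`, `collinear` flag.
#' @export
variance_explained <- function(result, blues, dm, h2) {
  stopifnot(inherits(dm, "design_matrices"))
  if (nrow(result) == 0L)
    return(structure(list(per_qtl = data.frame(marker = character(0),
                                               R2 = numeric(0)),
                          R2_adj = 0, p_G = 0, h2 = h2, collinear = FALSE),
                     class = "variance_explained"))
  ord <- order(result$p_value)
  mk <- result$marker[ord]
  Z <- dm$ZA[names(blues), mk, drop = FALSE]
  d <- data.frame(y = unname(blues), Z, check.names = FALSE)
  fml <- stats::as.formula(paste("y ~", paste(sprintf("`%s`", mk), collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  collinear <- any(is.na(stats::coef(fit)))
  av <- stats::anova(fit)
  ss <- av$`Sum Sq`
  tot <- sum(ss)
  per <- data.frame(marker = mk, R2 = ss[seq_along(mk)] / tot,
                    stringsAsFactors = FALSE)
  r2adj <- summary(fit)$adj.r.squared
  p_g <- r2adj / h2
  if (p_g > 1) {
    warning("p_G exceeded 1 and was capped")
    p_g <- 1
  }
  structure(list(per_qtl = per, R2_adj = r2adj, p_G = p_g, h2 = h2,
                 collinear = collinear),
            class = "variance_explained")
}

#' Most significant markers of a scan
#'
#' The `k` markers with the smallest p-values; ties are broken
#' deterministically by (chromosome, cM position, marker id).
#'
#' @param result An `assoc_result`.
#' @param k Number of markers (default 3, the usual functional-marker count
#'   for weighted BLUP).
#' @return Character vector of marker ids.
#' @export
top_k_markers <- function(result, k = 3) {
  ok <- !is.na(result$p_value)
  if (k > sum(ok)) stop("k exceeds the number of tested markers")
  r <- result[ok, , drop = FALSE]
  ord <- order(r$p_value, r$chrom, r$pos_cM, r$marker)
  r$marker[ord[seq_len(k)]]
}
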