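#' Shrinkage parameters for the marker mixed-model equations
#'
#' `lambda_A = (s2_e / n_env) / (s2_GCA / n_marker)` and
#' `lambda_D = (s2_e / n_env) / (s2_SCA / n_marker)`: the ratio between the
#' residual variance of an entry mean over `n_env` environments and the
#' per-marker share of the general (additive) or specific (dominance)
#' combining-ability variance.
#'
#' @param sigma2_e Residual variance.
#' @param sigma2_gca,sigma2_sca GCA and SCA variance components (> 0).
#' @param n_env Number of environments behind the entry means.
#' @param n_marker Number of markers in the panel.
#' @return Named vector `c(lambda_A = ..., lambda_D = ...)`.
#' @export
shrinkage_params <- function(sigma2_e, sigma2_gca, sigma2_sca, n_env,
                             n_marker) {
  if (sigma2_gca <= 0) stop("sigma2_gca must be > 0")
  if (sigma2_sca <= 0) stop("sigma2_sca must be > 0")
  if (sigma2_e <= 0 || n_env < 1 || n_marker < 1)
    stop("sigma2_e, n_env and n_marker must be positive")
  c(lambda_A = (sigma2_e / n_env) / (sigma2_gca / n_marker),
    lambda_D = (sigma2_e / n_env) / (sigma2_sca / n_marker))
}

#' Solve ridge mixed-model equations with an unpenalised intercept
#'
#' Solves `[1 W]' [1 W] + diag(0, pen)` normal equations, i.e. the block
#' mixed-model equation system for `y = 1 mu + W u + e` with `u` penalised by
#' the per-column shrinkage in `pen`. Uses the direct dense solve of the
#' (1 + M)-dimensional system when M + 1 <= n and the numerically equivalent
#' n-dimensional dual (Woodbury) form otherwise.
#'
#' @param y Response vector.
#' @param W Combined effect design matrix (n x M).
#' @param pen Positive penalty per column of `W`.
#' @param method `"auto"`, `"direct"` or `"dual"`.
#' @return List `mu`, `u` (length M).
#' @keywords internal
solve_mme <- function(y, W, pen, method = c("auto", "direct", "dual")) {
  method <- match.arg(method)
  n <- length(y); M <- ncol(W)
  stopifnot(nrow(W) == n, length(pen) == M)
  if (any(pen <= 0)) stop("shrinkage penalties must be > 0")
  if (method == "auto") method <- if (M + 1 <= n) "direct" else "dual"
  if (method == "direct") {
    ones <- rep(1, n)
    C <- rbind(c(n, crossprod(ones, W)),
               cbind(crossprod(W, ones), crossprod(W) + diag(pen, M)))
    rhs <- c(sum(y), crossprod(W, y))
    sol <- tryCatch(solve(C, rhs), error = function(e)
      stop("singular mixed-model equation system: ", conditionMessage(e)))
    list(mu = sol[1], u = sol[-1])
  } else {
    Wd <- sweep(W, 2, pen, "/")          # W D^-1
    V <- tcrossprod(Wd, W) + diag(1, n)  # W D^-1 W' + I
    Vi_y <- solve(V, y)
    Vi_1 <- solve(V, rep(1, n))
    mu <- sum(Vi_y) / sum(Vi_1)
    alpha <- Vi_y - Vi_1 * mu
    list(mu = mu, u = drop(crossprod(Wd, alpha)))
  }
}

#' RR-BLUP marker effects from the mixed-model equations
#'
#' Fits `Y = 1 mu + ZA a + ZD d + e` with all additive effects shrunk by
#' `lambda_A` and all dominance effects by `lambda_D`, solving the block
#' mixed-model equation system exactly. `include_dominance = FALSE` drops the
#' dominance blocks (`Y = 1 mu + ZA a + e`).
#'
#' @param y Named numeric vector of entry means / BLUEs; names select rows of
#'   the design matrices (rownames of `dm$ZA`); unnamed vectors must match
#'   the row count.
#' @param dm `design_matrices` (see [code_design_matrices()]).
#' @param lambda_A,lambda_D Positive shrinkage parameters (see
#'   [shrinkage_params()] or [estimate_lambda()]).
#' @param include_dominance Fit dominance effects (default `TRUE`).
#' @param method MME solver: `"auto"`, `"direct"` or `"dual"`.
#' @return Object of class `marker_effects`: `model`, `mu`, `additive`,
#'   `dominance` (NULL if absent), `lambda`, `markers`.
#' @export
rrblup_fit <- function(y, dm, lambda_A, lambda_D = lambda_A,
                       include_dominance = TRUE, method = "auto") {
  za <- dm_rows(dm, y, "ZA")
  y <- za$y; ZA <- za$Z
  markers <- colnames(dm$ZA)
  if (include_dominance) {
    ZD <- dm$ZD[za$rows, , drop = FALSE]
    W <- cbind(ZA, ZD)
    pen <- c(rep(lambda_A, dm$m), rep(lambda_D, dm$m))
  } else {
    W <- ZA
    pen <- rep(lambda_A, dm$m)
  }
  sol <- solve_mme(y, W, pen, method)
  a <- stats::setNames(sol$u[seq_len(dm$m)], markers)
  d <- if (include_dominance)
    stats::setNames(sol$u[dm$m + seq_len(dm$m)], markers) else NULL
  structure(list(model = if (include_dominance) "rrblup" else "rrblup_additive",
                 mu = sol$mu, additive = a, dominance = d,
                 lambda = c(lambda_A = lambda_A,
                            lambda_D = if (include_dominance) lambda_D else NA),
                 markers = markers),
            class = "marker_effects")
}

dm_rows <- function(dm, y, which = "ZA") {
  Z <- dm[[which]]
  if (!is.null(names(y))) {
    absent <- setdiff(names(y), rownames(Z))
    if (length(absent))
      stop("no design-matrix rows for: ",
           paste(utils::head(absent, 5), collapse = ", "))
    rows <- names(y)
  } else {
    if (length(y) != nrow(Z)) stop("unnamed y must match design-matrix rows")
    rows <- seq_len(nrow(Z))
  }
  list(y = unname(y), Z = Z[rows, , drop = FALSE], rows = rows)
}

#' Weighted BLUP: separate weak shrinkage for functional markers
#'
#' Extends the RR-BLUP mixed-model equations with additional additive (and
#' dominance) effect blocks for a small set of functional markers (typically
#' the 3 most significant markers of an association scan on the training
#' set). The functional blocks are shrunk by `lambda / w`, so `w = 100`
#' leaves them almost unshrunken while the genome-wide effects keep the
#' RR-BLUP shrinkage. The returned per-marker effects are the totals
#' (genome-wide + functional component).
#'
#' @inheritParams rrblup_fit
#' @param functional_ids Distinct marker ids present in the panel.
#' @param w Shrinkage weight for the functional blocks (default 100).
#' @return A `marker_effects` object (`model = "wblup"`); the functional
#'   components are kept in `functional`.
#' @export
wblup_fit <- function(y, dm, functional_ids, lambda_A, lambda_D = lambda_A,
                      w = 100, include_dominance = TRUE, method = "auto") {
  if (anyDuplicated(functional_ids)) stop("duplicate functional marker ids")
  markers <- colnames(dm$ZA)
  if (!all(functional_ids %in% markers))
    stop("unknown functional markers: ",
         paste(setdiff(functional_ids, markers), collapse = ", "))
  if (w <= 0) stop("w must be > 0")
  za <- dm_rows(dm, y, "ZA")
  y <- za$y; ZA <- za$Z
  FA <- ZA[, functional_ids, drop = FALSE]
  nf <- length(functional_ids)
  if (include_dominance) {
    ZD <- dm$ZD[za$rows, , drop = FALSE]
    FD <- ZD[, functional_ids, drop = FALSE]
    W <- cbind(ZA, FA, ZD, FD)
    pen <- c(rep(lambda_A, dm$m), rep(lambda_A / w, nf),
             rep(lambda_D, dm$m), rep(lambda_D / w, nf))
  } else {
    W <- cbind(ZA, FA)
    pen <- c(rep(lambda_A, dm$m), rep(lambda_A / w, nf))
  }
  sol <- solve_mme(y, W, pen, method)
  a <- stats::setNames(sol$u[seq_len(dm$m)], markers)
  af <- stats::setNames(sol$u[dm$m + seq_len(nf)], functional_ids)
  a[functional_ids] <- a[functional_ids] + af
  d <- df_ <- NULL
  if (include_dominance) {
    off <- dm$m + nf
    d <- stats::setNames(sol$u[off + seq_len(dm$m)], markers)
    df_ <- stats::setNames(sol$u[off + dm$m + seq_len(nf)], functional_ids)
    d[functional_ids] <- d[functional_ids] + df_
  }
  structure(list(model = "wblup", mu = sol$mu, additive = a, dominance = d,
                 functional = list(ids = functional_ids, a = af, d = df_,
                                   w = w),
                 lambda = c(lambda_A = lambda_A,
                            lambda_D = if (include_dominance) lambda_D else NA),
                 markers = markers),
            class = "marker_effects")
}

#' REML estimation of RR-BLUP shrinkage from the data
#'
#' Estimates `lambda_A = s2_e / s2_a` via the spectral REML fit of the
#' equivalent genomic-relationship model (`K = ZA ZA' / m`), and, when
#' dominance codes segregate, `lambda_D` from a second REML fit of the
#' dominance relationship to the additive-model residuals (a pragmatic
#' two-step approximation; a joint two-component REML is not attempted).
#'
#' @param y Named numeric vector of entry means / BLUEs.
#' @param dm `design_matrices`.
#' @param include_dominance Also estimate `lambda_D`.
#' @return Named vector `c(lambda_A, lambda_D)`; `lambda_D` is a large finite
#'   value (1e8) when no dominance signal is estimable.
#' @export
estimate_lambda <- function(y, dm, include_dominance = TRUE) {
  za <- dm_rows(dm, y, "ZA")
  KA <- tcrossprod(za$Z) / dm$m
  X <- matrix(1, length(za$y), 1)
  fa <- reml_polygenic(za$y, X, KA)
  lambda_A <- max(fa$delta * dm$m, 1e-6)
  lambda_D <- 1e8
  if (include_dominance) {
    ZD <- dm$ZD[za$rows, , drop = FALSE]
    if (any(ZD != 0)) {
      eff <- rrblup_fit(y, dm, lambda_A, include_dominance = FALSE)
      r <- za$y - unname(predict_values(eff, dm)[za$rows])
      KD <- tcrossprod(ZD) / dm$m
      if (stats::var(diag(KD)) + mean(KD^2) > 0) {
        fd <- try(reml_polygenic(r, X, KD), silent = TRUE)
        if (!inherits(fd, "try-error"))
          lambda_D <- min(max(fd$delta * dm$m, 1e-6), 1e8)
      }
    }
  }
  c(lambda_A = lambda_A, lambda_D = lambda_D)
}

#' Predict genotypic values from fitted marker effects
#'
#' `y_hat = mu + ZA a + ZD d` over the requested individuals.
#'
#' @param effects A `marker_effects` object.
#' @param dm `design_matrices` for the target individuals (same marker panel
#'   as the training fit).
#' @param ids Optional rownames (or indices) of the target individuals;
#'   default: all rows of `dm`.
#' @return Named numeric vector of predictions.
#' @export
predict_values <- function(effects, dm, ids = NULL) {
  stopifnot(inherits(effects, "marker_effects"),
            inherits(dm, "design_matrices"))
  if (!identical(effects$markers, colnames(dm$ZA))) {
    bad <- c(setdiff(effects$markers, colnames(dm$ZA)),
             setdiff(colnames(dm$ZA), effects$markers))
    stop("marker panel mismatch between effects and targets: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  ZA <- dm$ZA; ZD <- dm$ZD
  if (!is.null(ids)) {
    ZA <- ZA[ids, , drop = FALSE]
    ZD <- ZD[ids, , drop = FALSE]
  }
  yhat <- effects$mu + drop(ZA %*% effects$additive)
  if (!is.null(effects$dominance))
    yhat <- yhat + drop(ZD %*% effects$dominance)
  stats::setNames(yhat, rownames(ZA))
}

#' @export
print.marker_effects <- function(x, ...) {
  cat(sprintf("marker_effects [%s]: %d markers, mu = %.4g\n",
              x$model, length(x$markers), x$mu))
  cat(sprintf("  additive effects sd = %.4g%s\n", stats::sd(x$additive),
              if (!is.null(x$dominance))
                sprintf("; dominance effects sd = %.4g", stats::sd(x$dominance))
              else ""))
  invisible(x)
}

#' Hybrid prediction from general combining ability
#'
#' `y_hat(f, m) = mu + gca_f + gca_m`. Both parents of every target hybrid
#' must carry a GCA estimate, i.e. the targets must be of the fully related
#' (T2) kind; an unavailable parent signals a less related target and raises
#' an error.
#'
#' @param model A `gca_model` (see [gca_sca()]).
#' @param plan A `crossing_plan` of the target hybrids.
#' @return Named numeric vector of predictions.
#' @export
gca_predict <- function(model, plan) {
  stopifnot(inherits(model, "gca_model"), inherits(plan, "crossing_plan"))
  bad <- c(setdiff(plan$female, names(model$gca_f)),
           setdiff(plan$male, names(model$gca_m)))
  if (length(bad))
    stop("no GCA estimate for parent(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (targets are not all T2)")
  stats::setNames(model$mu + unname(model$gca_f[plan$female]) +
                    unname(model$gca_m[plan$male]), plan$hybrid)
}

#' Mid-parent prediction of hybrid performance
#'
#' `y_hat = (BLUE(P1) + BLUE(P2)) / 2`; symmetric in the parent order.
#'
#' @param parent_blues Named numeric vector of parental BLUEs.
#' @param plan A `crossing_plan` of the target hybrids.
#' @return Named numeric vector of predictions.
#' @export
mp_predict <- function(parent_blues, plan) {
  stopifnot(inherits(plan, "crossing_plan"))
  bad <- setdiff(unique(c(plan$female, plan$male)), names(parent_blues))
  if (length(bad))
    stop("missing parental BLUE for ",
         paste(utils::head(bad, 5), collapse = ", "))
  stats::setNames((unname(parent_blues[plan$female]) +
                     unname(parent_blues[plan$male])) / 2, plan$hybrid)
}
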