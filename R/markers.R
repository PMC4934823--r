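#' Marker quality control
#'
#' Removes markers that are (in this fixed attribution order) monomorphic,
#' above the missingness threshold, above the inbred-line heterozygosity
#' threshold, or below the minor-allele-frequency threshold. Each removed
#' marker is counted under the first rule it fails, so the report partitions
#' the removals. MAF and monomorphism are assessed on the non-missing calls of
#' the individuals in `inbred_ids` (typically the parents, since hybrid
#' genotypes are deduced from them); heterozygosity likewise.
#'
#' @param geno A `geno_matrix`.
#' @param max_missing Maximum tolerated fraction of missing calls (default 0.05).
#' @param max_het Maximum tolerated heterozygosity among inbreds (default 0.05).
#' @param min_maf Minimum minor-allele frequency (default 0.05).
#' @param inbred_ids Individuals treated as inbred lines for the het/MAF rules;
#'   default: all individuals without a heterozygous call, or all individuals
#'   if every row carries heterozygotes.
#' @return A list: `geno` (filtered `geno_matrix`, original marker order kept)
#'   and `report` (class `qc_report`): counts of input, removed-by-reason and
#'   retained markers.
#' @export
qc_filter <- function(geno, max_missing = 0.05, max_het = 0.05,
                      min_maf = 0.05, inbred_ids = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  thr <- c(max_missing, max_het, min_maf)
  if (any(thr < 0 | thr > 1)) stop("thresholds must lie in [0, 1]")
  X <- geno$dosage
  if (nrow(X) == 0L || ncol(X) == 0L) stop("genotype matrix is empty")
  if (is.null(inbred_ids)) {
    no_het <- rowSums(X == 1L, na.rm = TRUE) == 0L
    inbred_ids <- if (any(no_het)) rownames(X)[no_het] else rownames(X)
  }
  Xi <- X[inbred_ids, , drop = FALSE]

  p <- colMeans(Xi, na.rm = TRUE) / 2          # allele frequency on inbreds
  maf <- pmin(p, 1 - p)
  mono <- apply(Xi, 2, function(v) length(unique(v[!is.na(v)])) <= 1L)
  miss <- colMeans(is.na(X))
  het <- colMeans(Xi == 1L, na.rm = TRUE)

  reason <- rep(NA_character_, ncol(X))
  reason[is.na(reason) & mono] <- "monomorphic"
  reason[is.na(reason) & miss > max_missing] <- "missing"
  reason[is.na(reason) & het > max_het] <- "heterozygous"
  reason[is.na(reason) & maf < min_maf] <- "low_maf"
  keep <- is.na(reason)

  report <- structure(list(
    n_input = ncol(X),
    n_removed = c(monomorphic = sum(reason == "monomorphic", na.rm = TRUE),
                  missing = sum(reason == "missing", na.rm = TRUE),
                  heterozygous = sum(reason == "heterozygous", na.rm = TRUE),
                  low_maf = sum(reason == "low_maf", na.rm = TRUE)),
    n_retained = sum(keep)), class = "qc_report")

  out <- geno
  out$dosage <- X[, keep, drop = FALSE]
  out$map <- geno$map[keep, , drop = FALSE]
  rownames(out$map) <- NULL
  list(geno = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("marker QC: %d in, %d retained\n", x$n_input, x$n_retained))
  for (r in names(x$n_removed))
    cat(sprintf("  removed (%s): %d\n", r, x$n_removed[[r]]))
  invisible(x)
}

#' F-infinity additive/dominance design matrices
#'
#' Codes allele dosages to the F-infinity metric: additive code -1/0/+1 for
#' dosage 0/1/2 and dominance code 1 for the heterozygote, 0 otherwise. Inbred
#' rows therefore have an all-zero dominance row.
#'
#' @param geno A `geno_matrix` without missing dosages (use `impute = TRUE` to
#'   mean-impute, rounded to the nearest legal dosage, first).
#' @param impute Impute missing dosages by column mean rounded to the nearest
#'   of 0/1/2 (default `FALSE`: missing values are an error).
#' @return A list of class `design_matrices`: `ZA` (n x m, in \{-1,0,1\}),
#'   `ZD` (n x m, in \{0,1\}), `n`, `m`.
#' @export
code_design_matrices <- function(geno, impute = FALSE) {
  stopifnot(inherits(geno, "geno_matrix"))
  X <- geno$dosage
  if (anyNA(X)) {
    if (!impute)
      stop("missing dosages present; set impute = TRUE or filter first")
    for (j in which(colSums(is.na(X)) > 0L)) {
      fill <- round(mean(X[, j], na.rm = TRUE))
      X[is.na(X[, j]), j] <- max(0L, min(2L, as.integer(fill)))
    }
  }
  ZA <- X - 1
  ZD <- 1 * (X == 1L)
  structure(list(ZA = ZA, ZD = ZD, n = nrow(X), m = ncol(X)),
            class = "design_matrices")
}

#' Marker-derived kinship matrix
#'
#' `K = W W' / c` with `W` the additive (`ZA`) or dominance (`ZD`) design
#' matrix. The default normalisation is the marker count `c = m`; the
#' alternative `"2pq"` uses `c = 2 * sum(p (1 - p))` computed from the
#' additive codes.
#'
#' @param dm A `design_matrices` object.
#' @param flavor `"additive"` or `"dominance"`.
#' @param normalize `"m"` (marker count, default) or `"2pq"`.
#' @return A symmetric positive semi-definite matrix with a `flavor` attribute.
#' @export
kinship <- function(dm, flavor = c("additive", "dominance"),
                    normalize = c("m", "2pq")) {
  stopifnot(inherits(dm, "design_matrices"))
  flavor <- match.arg(flavor)
  normalize <- match.arg(normalize)
  if (dm$m == 0L) stop("no markers")
  W <- if (flavor == "additive") dm$ZA else dm$ZD
  cc <- if (normalize == "m") dm$m else {
    p <- (colMeans(dm$ZA) + 1) / 2
    2 * sum(p * (1 - p))
  }
  if (cc <= 0) stop("degenerate kinship normalisation constant")
  K <- tcrossprod(W) / cc
  attr(K, "flavor") <- flavor
  K
}

#' Pairwise linkage disequilibrium (r^2)
#'
#' Squared Pearson correlation of the additive marker codes across
#' individuals. Monomorphic markers have undefined correlation and yield `NA`
#' entries.
#'
#' @param geno A `geno_matrix`.
#' @param markers Optional character vector or index of markers to include.
#' @return A symmetric matrix of r^2 values in `[0, 1]` (diagonal 1 for
#'   polymorphic markers).
#' @export
ld_r2 <- function(geno, markers = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  X <- geno$dosage
  if (!is.null(markers)) X <- X[, markers, drop = FALSE]
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  r2 <- r^2
  r2[sds == 0, ] <- NA_real_
  r2[, sds == 0] <- NA_real_
  r2
}

#' Equidistant marker subsampling
#'
#' Cuts the marker axis into consecutive windows of `window` markers and draws
#' `k` indices uniformly without replacement from each full window (a trailing
#' partial window contributes `min(k, its size)`), emulating marker-density
#' reduction on a dense array while preserving genome coverage.
#'
#' @param m_total Total number of markers.
#' @param k Markers to draw per window (1 <= k <= window).
#' @param window Window size (default 173, i.e. 1/100 of a ~17.3k panel).
#' @param seed Integer seed.
#' @return Sorted integer vector of retained marker indices.
#' @export
equidistant_subsample <- function(m_total, k, window = 173, seed = NULL) {
  if (k < 1 || k > window) stop("k must satisfy 1 <= k <= window")
  if (m_total < 1) stop("m_total must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  starts <- seq(1L, m_total, by = window)
  idx <- lapply(starts, function(s) {
    e <- min(s + window - 1L, m_total)
    size <- e - s + 1L
    s - 1L + sort(sample.int(size, min(k, size)))
  })
  sort(unlist(idx))
}
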