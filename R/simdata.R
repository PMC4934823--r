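#' Simulate a panel of inbred parental lines
#'
#' Generates biallelic SNP genotypes for a factorial set of inbred parents
#' (females and males). Parents are fully inbred, so allele dosages are 0 or 2
#' only. Markers are simulated in linkage equilibrium with per-marker allele
#' frequencies drawn uniformly on `[maf_low, maf_high]`, mirroring a post-QC
#' panel with a minor-allele-frequency floor, and are placed at uniformly
#' distributed cM positions on `n_chromosomes` chromosomes.
#'
#' @param n_female,n_male Numbers of female and male parents (defaults 120 and
#'   15, the factorial design this package is organised around).
#' @param n_markers Total number of SNP markers.
#' @param n_chromosomes Number of chromosomes markers are spread over.
#' @param maf_low,maf_high Bounds of the uniform distribution the per-marker
#'   minor-allele frequencies are drawn from; `maf_low` must be at least 0.05
#'   (the QC floor applied to real panels).
#' @param chrom_length_cM Genetic length of each chromosome in centimorgan.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `geno_matrix` (fields `dosage`, an individuals x
#'   markers integer matrix, and `map`, a data.frame with `marker`, `chrom`,
#'   `pos_cM`) with an attached `parents` element of class `parent_set`
#'   (fields `female_ids`, `male_ids`).
#' @examples
#' g <- simulate_parents(n_female = 6, n_male = 3, n_markers = 50,
#'                       n_chromosomes = 2, seed = 1)
#' table(g$dosage)
#' @export
simulate_parents <- function(n_female = 120, n_male = 15, n_markers = 1000,
                             n_chromosomes = 21, maf_low = 0.05,
                             maf_high = 0.5, chrom_length_cM = 150,
                             seed = NULL) {
  if (n_female < 1 || n_male < 1 || n_markers < 1 || n_chromosomes < 1)
    stop("all counts must be >= 1")
  if (maf_low > maf_high) stop("maf bounds inverted: maf_low > maf_high")
  if (maf_low < 0.05) stop("maf_low must be >= 0.05 (post-QC panel floor)")
  if (n_markers < n_chromosomes)
    stop("n_markers must be >= n_chromosomes")
  if (!is.null(seed)) set.seed(seed)

  female_ids <- sprintf("F%03d", seq_len(n_female))
  male_ids <- sprintf("M%03d", seq_len(n_male))
  ids <- c(female_ids, male_ids)
  n <- length(ids)

  p <- stats::runif(n_markers, maf_low, maf_high)
  # inbred line = one allele sampled per line, dosage doubled
  dosage <- matrix(2L * (stats::runif(n * n_markers) < rep(p, each = n)),
                   nrow = n, ncol = n_markers)
  storage.mode(dosage) <- "integer"

  chrom <- sort(rep_len(seq_len(n_chromosomes), n_markers))
  pos <- stats::runif(n_markers, 0, chrom_length_cM)
  ord <- order(chrom, pos)
  chrom <- chrom[ord]
  pos <- pos[ord]
  marker_ids <- sprintf("snp%05d", seq_len(n_markers))
  dimnames(dosage) <- list(ids, marker_ids)

  map <- data.frame(marker = marker_ids,
                    chrom = sprintf("chr%02d", chrom),
                    pos_cM = pos, stringsAsFactors = FALSE)
  geno <- new_geno_matrix(dosage, map)
  geno$parents <- structure(list(female_ids = female_ids, male_ids = male_ids),
                            class = "parent_set")
  geno
}

#' Construct a genotype container
#'
#' @param dosage Integer matrix (individuals x markers) with entries in
#'   \{0, 1, 2\} or `NA`; rownames are individual ids, colnames marker ids.
#' @param map Optional data.frame with columns `marker`, `chrom`, `pos_cM`
#'   sorted by position within chromosome; defaults to a single dummy
#'   chromosome.
#' @return An object of class `geno_matrix`.
#' @export
new_geno_matrix <- function(dosage, map = NULL) {
  stopifnot(is.matrix(dosage))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("ind%04d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("snp%05d", seq_len(ncol(dosage)))
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(map)) {
    map <- data.frame(marker = colnames(dosage), chrom = "chr01",
                      pos_cM = seq_len(ncol(dosage)),
                      stringsAsFactors = FALSE)
  }
  if (!identical(map$marker, colnames(dosage)))
    stop("map rows must match dosage columns in order")
  structure(list(dosage = dosage, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d markers (%d chromosomes)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  het <- mean(x$dosage == 1L, na.rm = TRUE)
  cat(sprintf("  heterozygous calls: %.1f%%; missing: %.2f%%\n",
              100 * het, 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Build a factorial crossing plan
#'
#' Either the full female x male factorial or a uniform random subset of it,
#' emulating a breeding program that realises only part of the possible
#' single-cross combinations (e.g. 1,604 out of 120 x 15 = 1,800).
#'
#' @param parents A `parent_set` (e.g. `simulate_parents(...)$parents`).
#' @param n_hybrids Number of crosses to realise, or `"full"` for the complete
#'   factorial.
#' @param seed Integer seed used when subsetting.
#' @return A data.frame of class `crossing_plan` with columns `hybrid`,
#'   `female`, `male`.
#' @export
make_factorial <- function(parents, n_hybrids = "full", seed = NULL) {
  stopifnot(inherits(parents, "parent_set"))
  full <- expand.grid(female = parents$female_ids, male = parents$male_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_full <- nrow(full)
  if (identical(n_hybrids, "full")) {
    plan <- full
  } else {
    n_hybrids <- as.integer(n_hybrids)
    if (n_hybrids > n_full)
      stop(sprintf("requested %d hybrids but only %d crosses possible",
                   n_hybrids, n_full))
    if (!is.null(seed)) set.seed(seed)
    plan <- full[sort(sample.int(n_full, n_hybrids)), , drop = FALSE]
  }
  plan <- data.frame(hybrid = paste(plan$female, plan$male, sep = "x"),
                     female = plan$female, male = plan$male,
                     stringsAsFactors = FALSE)
  rownames(plan) <- NULL
  class(plan) <- c("crossing_plan", "data.frame")
  plan
}

#' Deduce hybrid genotypes from parental genotypes
#'
#' F1 hybrids of inbred parents carry, at every locus, one allele from each
#' parent, so the hybrid dosage is the mean of the two parental dosages:
#' like homozygotes give the same homozygote, unlike homozygotes give a
#' heterozygote (dosage 1). Missing parental calls propagate as missing.
#'
#' @param parent_geno A `geno_matrix` holding the parents.
#' @param plan A `crossing_plan`.
#' @return A `geno_matrix` of the hybrids (same marker map as the parents).
#' @export
derive_hybrid_genotypes <- function(parent_geno, plan) {
  stopifnot(inherits(parent_geno, "geno_matrix"), inherits(plan, "crossing_plan"))
  ids <- rownames(parent_geno$dosage)
  missing_par <- setdiff(unique(c(plan$female, plan$male)), ids)
  if (length(missing_par))
    stop("crossing plan references ungenotyped parents: ",
         paste(missing_par, collapse = ", "))
  df <- parent_geno$dosage[plan$female, , drop = FALSE]
  dm <- parent_geno$dosage[plan$male, , drop = FALSE]
  hyb <- (df + dm) %/% 2L
  hyb[which((df + dm) %% 2L != 0L)] <- NA_integer_  # non-inbred parent call: undefined
  rownames(hyb) <- plan$hybrid
  out <- new_geno_matrix(hyb, parent_geno$map)
  out
}

#' Simulate true genetic values from an additive + dominance QTL architecture
#'
#' Draws `n_qtl` QTL positions among the markers, samples additive effects
#' `a ~ N(0, additive_sd^2)` and dominance effects `d ~ N(0, dominance_sd^2)`,
#' and computes each individual's genetic value under F-infinity coding
#' (homozygotes -1/+1 additive, heterozygote 0 additive and 1 dominance):
#' `g_i = sum_q a_q zA(i,q) + d_q zD(i,q)`. Optionally injects a single
#' large-effect QTL at a named marker, emulating a major gene segregating on
#' a polygenic background.
#'
#' @param geno `geno_matrix` of all individuals (parents and hybrids).
#' @param n_qtl Number of QTL.
#' @param additive_sd,dominance_sd Standard deviations of the QTL effect
#'   distributions, in trait units; `dominance_sd = 0` gives a purely additive
#'   architecture.
#' @param large_qtl Optional `list(marker = <id>, a = <additive effect>,
#'   d = <dominance effect, default 0>)`.
#' @param seed Integer seed.
#' @return A list of class `sim_truth`: `qtl` (data.frame marker/a/d),
#'   `values` (named numeric vector of true genetic values),
#'   `geno_var` (variance of the values).
#' @export
simulate_genetic_values <- function(geno, n_qtl, additive_sd = 1,
                                    dominance_sd = 0, large_qtl = NULL,
                                    seed = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  m <- ncol(geno$dosage)
  if (n_qtl > m) stop("n_qtl exceeds the number of markers")
  if (!is.null(seed)) set.seed(seed)
  qtl_idx <- sort(sample.int(m, n_qtl))
  qtl_id <- colnames(geno$dosage)[qtl_idx]
  a <- stats::rnorm(n_qtl, 0, additive_sd)
  d <- if (dominance_sd > 0) stats::rnorm(n_qtl, 0, dominance_sd) else numeric(n_qtl)
  if (!is.null(large_qtl)) {
    j <- match(large_qtl$marker, colnames(geno$dosage))
    if (is.na(j)) stop("large_qtl marker not found: ", large_qtl$marker)
    if (!(j %in% qtl_idx)) {
      qtl_idx <- sort(c(qtl_idx, j))
      pos <- match(j, qtl_idx)
      a <- append(a, 0, after = pos - 1L)
      d <- append(d, 0, after = pos - 1L)
      qtl_id <- colnames(geno$dosage)[qtl_idx]
    }
    k <- match(large_qtl$marker, qtl_id)
    a[k] <- large_qtl$a
    d[k] <- if (!is.null(large_qtl$d)) large_qtl$d else 0
  }
  zA <- geno$dosage[, qtl_idx, drop = FALSE] - 1   # 0/1/2 -> -1/0/+1
  zD <- 1 * (geno$dosage[, qtl_idx, drop = FALSE] == 1L)
  values <- drop(zA %*% a + zD %*% d)
  names(values) <- rownames(geno$dosage)
  structure(list(qtl = data.frame(marker = qtl_id, a = a, d = d,
                                  stringsAsFactors = FALSE),
                 values = values,
                 geno_var = stats::var(values)),
            class = "sim_truth")
}

#' Describe a multi-environment partially replicated trial layout
#'
#' @param n_env Number of environments (location-year combinations).
#' @param trials_per_env Number of adjacent trials per environment the
#'   genotypes are split into (default 3).
#' @param replications Replications per trial (default 2).
#' @param block_size Plots per incomplete block within a replication.
#' @param replicated_hybrid_fraction Fraction of hybrids observed in both
#'   replications (default 0.29); the rest appear once. Lines and checks are
#'   always fully replicated.
#' @param n_checks Number of common check genotypes linking the trials
#'   (default 10).
#' @return A list of class `trial_design`.
#' @export
trial_design <- function(n_env = 6, trials_per_env = 3, replications = 2,
                         block_size = 20, replicated_hybrid_fraction = 0.29,
                         n_checks = 10) {
  if (any(c(n_env, trials_per_env, replications, block_size) < 1))
    stop("all design counts must be >= 1")
  if (replicated_hybrid_fraction < 0 || replicated_hybrid_fraction > 1)
    stop("replicated_hybrid_fraction must be in [0, 1]")
  structure(list(n_env = n_env, trials_per_env = trials_per_env,
                 replications = replications, block_size = block_size,
                 replicated_hybrid_fraction = replicated_hybrid_fraction,
                 n_checks = n_checks),
            class = "trial_design")
}

#' Default variance components for trial simulation
#'
#' All components in squared trait units: environment, trial, replication,
#' block, genotype-by-environment interaction and plot residual. Genetic
#' variance is carried by the true genetic values, not drawn here.
#'
#' @param environment,trial,replication,block,gxe,error Variances (>= 0).
#' @return Named numeric vector.
#' @export
trial_varcomp <- function(environment = 1.5, trial = 0.1, replication = 0.1,
                          block = 0.3, gxe = 0.5, error = 1.0) {
  vc <- c(environment = environment, trial = trial, replication = replication,
          block = block, gxe = gxe, error = error)
  if (any(vc < 0)) stop("variance components must be >= 0")
  vc
}

#' Simulate plot-level phenotypes for a partially replicated trial series
#'
#' Each plot value is `mu + l + t + r + b + g + (g x l) + e` with every random
#' term drawn independently from a normal distribution with its component
#' variance. Genotypes are split at random into `trials_per_env` trials per
#' environment; checks appear in every trial. Lines, checks and a fraction of
#' the hybrids are observed in both replications, the remaining hybrids in a
#' randomly chosen single replication.
#'
#' @param true_values Named numeric vector of true genetic values; names are
#'   genotype ids. Hybrid ids are taken to be those containing `"x"`
#'   (as produced by [make_factorial()]) unless `hybrid_ids` is given.
#' @param design A [trial_design()].
#' @param varcomp Named vector from [trial_varcomp()].
#' @param mu Overall trait mean.
#' @param trait_name Trait label stored in the records.
#' @param hybrid_ids Optional explicit character vector of hybrid ids.
#' @param seed Integer seed.
#' @return A data.frame of class `plot_records` with columns `genotype`,
#'   `environment`, `trial`, `replication`, `block`, `trait`, `value`,
#'   `is_check`; attribute `design` keeps the design used.
#' @export
simulate_trials <- function(true_values, design = trial_design(),
                            varcomp = trial_varcomp(), mu = 50,
                            trait_name = "trait", hybrid_ids = NULL,
                            seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  if (any(varcomp < 0)) stop("variance components must be >= 0")
  req <- c("environment", "trial", "replication", "block", "gxe", "error")
  if (!all(req %in% names(varcomp)))
    stop("varcomp must contain: ", paste(req, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  ids <- names(true_values)
  if (is.null(hybrid_ids)) hybrid_ids <- ids[grepl("x", ids, fixed = TRUE)]
  entry_ids <- ids
  n_checks <- min(design$n_checks, sum(!(entry_ids %in% hybrid_ids)))
  check_ids <- setdiff(entry_ids, hybrid_ids)[seq_len(n_checks)]

  rsd <- function(v) sqrt(unname(v))
  envs <- sprintf("env%d", seq_len(design$n_env))
  env_eff <- stats::setNames(stats::rnorm(design$n_env, 0, rsd(varcomp["environment"])), envs)
  gxe_eff <- matrix(stats::rnorm(length(ids) * design$n_env, 0, rsd(varcomp["gxe"])),
                    nrow = length(ids), dimnames = list(ids, envs))

  out <- vector("list", design$n_env)
  for (ei in seq_along(envs)) {
    env <- envs[ei]
    # random split of non-check genotypes into trials; checks in all trials
    pool <- setdiff(entry_ids, check_ids)
    trial_of <- sample(rep_len(seq_len(design$trials_per_env), length(pool)))
    rows <- vector("list", design$trials_per_env)
    for (tr in seq_len(design$trials_per_env)) {
      members <- c(pool[trial_of == tr], check_ids)
      hmem <- intersect(members, hybrid_ids)
      n_rep2 <- round(design$replicated_hybrid_fraction * length(hmem))
      rep2_h <- if (length(hmem)) sample(hmem, n_rep2) else character(0)
      both <- c(setdiff(members, hybrid_ids), rep2_h)
      once <- setdiff(members, both)
      t_eff <- stats::rnorm(1, 0, rsd(varcomp["trial"]))
      reps <- vector("list", design$replications)
      single_rep <- sample.int(design$replications, length(once), replace = TRUE)
      for (rp in seq_len(design$replications)) {
        r_eff <- stats::rnorm(1, 0, rsd(varcomp["replication"]))
        g_here <- c(both, once[single_rep == rp])
        if (!length(g_here)) next
        g_here <- sample(g_here)                  # randomise field order
        blk <- ceiling(seq_along(g_here) / design$block_size)
        b_eff <- stats::rnorm(max(blk), 0, rsd(varcomp["block"]))
        val <- mu + env_eff[env] + t_eff + r_eff + b_eff[blk] +
          true_values[g_here] + gxe_eff[g_here, env] +
          stats::rnorm(length(g_here), 0, rsd(varcomp["error"]))
        reps[[rp]] <- data.frame(
          genotype = g_here, environment = env,
          trial = sprintf("%s_t%d", env, tr),
          replication = sprintf("%s_t%d_r%d", env, tr, rp),
          block = sprintf("%s_t%d_r%d_b%d", env, tr, rp, blk),
          trait = trait_name, value = unname(val),
          is_check = g_here %in% check_ids,
          stringsAsFactors = FALSE)
      }
      rows[[tr]] <- do.call(rbind, reps)
    }
    out[[ei]] <- do.call(rbind, rows)
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  attr(rec, "design") <- design
  attr(rec, "check_ids") <- check_ids
  class(rec) <- c("plot_records", "data.frame")
  rec
}
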