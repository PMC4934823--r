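# small in-code fixtures shared across test files

# toy genotype container from an explicit dosage matrix
toy_geno <- function(dosage, chrom = NULL, pos = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("i%02d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("m%02d", seq_len(ncol(dosage)))
  map <- data.frame(marker = colnames(dosage),
                    chrom = if (is.null(chrom)) "chr01" else chrom,
                    pos_cM = if (is.null(pos)) seq_len(ncol(dosage)) else pos,
                    stringsAsFactors = FALSE)
  new_geno_matrix(dosage, map)
}

# small factorial population: parents + hybrids + combined genotypes
toy_population <- function(n_f = 8, n_m = 4, n_markers = 60, seed = 42,
                           n_hybrids = "full") {
  parents <- simulate_parents(n_female = n_f, n_male = n_m,
                              n_markers = n_markers, n_chromosomes = 3,
                              seed = seed)
  plan <- make_factorial(parents$parents, n_hybrids, seed = seed + 1)
  hybrids <- derive_hybrid_genotypes(parents, plan)
  all_geno <- new_geno_matrix(rbind(parents$dosage, hybrids$dosage),
                              parents$map)
  list(parents = parents, plan = plan, hybrids = hybrids, geno = all_geno)
}

# balanced complete plot records built by hand (every genotype in every
# trial x replication); used where orthogonality makes closed forms exact
balanced_plots <- function(g_values, n_trial = 2, n_rep = 2, mu = 10,
                           trial_eff = rep(0, n_trial),
                           rep_eff = matrix(0, n_trial, n_rep),
                           noise_sd = 0, env = "env1", seed = 1) {
  set.seed(seed)
  ids <- names(g_values)
  rows <- expand.grid(genotype = ids, trial = seq_len(n_trial),
                      rep = seq_len(n_rep), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  val <- mu + g_values[rows$genotype] + trial_eff[rows$trial] +
    rep_eff[cbind(rows$trial, rows$rep)] +
    if (noise_sd > 0) rnorm(nrow(rows), 0, noise_sd) else 0
  out <- data.frame(genotype = rows$genotype, environment = env,
                    trial = sprintf("%s_t%d", env, rows$trial),
                    replication = sprintf("%s_t%d_r%d", env, rows$trial,
                                          rows$rep),
                    block = "b1", trait = "trait", value = unname(val),
                    stringsAsFactors = FALSE)
  class(out) <- c("plot_records", "data.frame")
  out
}

# brute-force Bonferroni-Holm step-down rule (independent oracle)
holm_brute <- function(p, alpha = 0.05) {
  m <- length(p)
  reject <- logical(m)
  ord <- order(p)
  for (i in seq_len(m)) {
    if (p[ord[i]] < alpha / (m - i + 1)) reject[ord[i]] <- TRUE else break
  }
  reject
}
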