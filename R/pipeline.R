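config_schema <- function() {
  list(
    seed = list(default = 1, type = "count"),
    out_dir = list(default = "hybridgp_run", type = "character"),
    sim = list(
      n_female = list(default = 120, type = "count"),
      n_male = list(default = 15, type = "count"),
      n_hybrids = list(default = 1604, type = "count"),
      n_markers = list(default = 1000, type = "count"),
      n_chromosomes = list(default = 21, type = "count"),
      maf_low = list(default = 0.05, type = "fraction"),
      maf_high = list(default = 0.5, type = "fraction"),
      n_qtl = list(default = 100, type = "count"),
      additive_sd = list(default = 1, type = "nonneg"),
      dominance_sd = list(default = 0.3, type = "nonneg")),
    design = list(
      n_env = list(default = 6, type = "count"),
      trials_per_env = list(default = 3, type = "count"),
      replications = list(default = 2, type = "count"),
      block_size = list(default = 20, type = "count"),
      replicated_hybrid_fraction = list(default = 0.29, type = "fraction"),
      n_checks = list(default = 10, type = "count")),
    qc = list(
      max_missing = list(default = 0.05, type = "fraction"),
      max_het = list(default = 0.05, type = "fraction"),
      min_maf = list(default = 0.05, type = "fraction")),
    gwas = list(
      alpha = list(default = 0.05, type = "fraction")),
    cv = list(
      n_runs = list(default = 100, type = "count"),
      n_f_est = list(default = 80, type = "count"),
      n_m_est = list(default = 10, type = "count"),
      n_hyb_est = list(default = 610, type = "count"),
      model = list(default = "rrblup", type = "character")))
}

#' Validate and complete a run configuration
#'
#' Fills defaults (the factorial design, trial layout and QC thresholds the
#' package is organised around: 120 females x 15 males, 1,604 hybrids, 6
#' environments, 3 trials, 2 replications, 29% replicated hybrids, 10
#' checks, 5% QC thresholds), type- and range-checks every value, and
#' rejects unknown keys with the path to the offending entry.
#'
#' @param config A named list, a YAML file path, or `NULL` (all defaults).
#' @return A fully populated configuration list of class `run_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  walk <- function(schema, given, path) {
    unknown <- setdiff(names(given), names(schema))
    if (length(unknown))
      stop("unknown config key: ",
           paste(paste0(path, unknown), collapse = ", "))
    out <- list()
    for (key in names(schema)) {
      node <- schema[[key]]
      if (is.list(node) && is.null(node$default)) {     # subsection
        out[[key]] <- walk(node, if (is.null(given[[key]])) list()
                           else given[[key]], paste0(path, key, "."))
      } else {
        val <- if (!is.null(given[[key]])) given[[key]] else node$default
        kp <- paste0(path, key)
        ok <- switch(node$type,
          count = is.numeric(val) && length(val) == 1 && val >= 1 &&
            val == round(val),
          fraction = is.numeric(val) && length(val) == 1 && val >= 0 &&
            val <= 1,
          nonneg = is.numeric(val) && length(val) == 1 && val >= 0,
          character = is.character(val) && length(val) == 1)
        if (!ok) stop("config value out of range or wrong type at: ", kp)
        out[[key]] <- val
      }
    }
    out
  }
  cfg <- walk(config_schema(), config, "")
  if (cfg$sim$maf_low > cfg$sim$maf_high)
    stop("config value out of range: sim.maf_low > sim.maf_high")
  class(cfg) <- c("run_config", "list")
  cfg
}

stage_files <- list(
  simulate = c("parents_geno.tsv", "marker_map.tsv", "hybrids_geno.tsv",
               "crossing_plan.tsv", "truth_qtl.tsv", "plots.csv"),
  qc = c("geno_qc.tsv", "map_qc.tsv", "qc_report.tsv"),
  pheno = c("entry_means.tsv", "blues.tsv", "heterosis.tsv",
            "variance_components.tsv"),
  gwas = c("assoc_scan.tsv", "qq_data.tsv"),
  predict = c("marker_effects.tsv"),
  cv = c("cv_accuracy.tsv"))

#' Run the full analysis pipeline
#'
#' Executes simulate -> qc -> pheno -> gwas -> predict -> cv in order,
#' persisting every intermediate artifact as plain text under
#' `config$out_dir` and recording a manifest (config hash, file checksums,
#' stage timings). A stage whose output files already exist under the same
#' config hash is skipped, so a completed run is resumable/idempotent; a
#' failing stage halts the pipeline with the stage named, retaining the
#' outputs of completed stages.
#'
#' @param config A `run_config` (see [validate_config()]), raw list, or YAML
#'   path.
#' @return The manifest (list): `config_hash`, `package_version`, per-stage
#'   `files` (named md5 vector) and `seconds`. Also written as
#'   `manifest.yaml`.
#' @export
run_all <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), tf)
  cfg_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  manifest_path <- file.path(cfg$out_dir, "manifest.yaml")
  manifest <- if (file.exists(manifest_path))
    yaml::read_yaml(manifest_path) else list()
  if (!identical(manifest$config_hash, cfg_hash))
    manifest <- list(config_hash = cfg_hash,
                     package_version = as.character(
                       utils::packageVersion("hybridgp")),
                     stages = list())

  path <- function(f) file.path(cfg$out_dir, f)
  done <- function(stage) {
    !is.null(manifest$stages[[stage]]) &&
      all(file.exists(path(stage_files[[stage]])))
  }
  finish <- function(stage, t0) {
    fs <- path(stage_files[[stage]])
    manifest$stages[[stage]] <<- list(
      files = as.list(stats::setNames(unname(tools::md5sum(fs)),
                                      stage_files[[stage]])),
      seconds = round(as.numeric(Sys.time()) - t0, 2))
    yaml::write_yaml(manifest, manifest_path)
  }
  run_stage <- function(stage, fun) {
    if (done(stage)) {
      message("stage '", stage, "' already complete; skipping")
      return(invisible(NULL))
    }
    t0 <- as.numeric(Sys.time())
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    finish(stage, t0)
  }

  env <- new.env()
  load_simulated <- function() {
    env$parents <- read_geno_tsv(path("parents_geno.tsv"), path("marker_map.tsv"))
    pl <- utils::read.delim(path("crossing_plan.tsv"), stringsAsFactors = FALSE)
    class(pl) <- c("crossing_plan", "data.frame")
    env$plan <- pl
    env$hybrids <- read_geno_tsv(path("hybrids_geno.tsv"), path("marker_map.tsv"))
    env$plots <- read_plots_csv(path("plots.csv"))
    env$parent_set <- structure(
      list(female_ids = unique(pl$female), male_ids = unique(pl$male)),
      class = "parent_set")
  }

  run_stage("simulate", function() {
    s <- cfg$sim
    parents <- simulate_parents(s$n_female, s$n_male, s$n_markers,
                                s$n_chromosomes, s$maf_low, s$maf_high,
                                seed = cfg$seed)
    plan <- make_factorial(parents$parents, s$n_hybrids, seed = cfg$seed + 1)
    hybrids <- derive_hybrid_genotypes(parents, plan)
    all_geno <- new_geno_matrix(rbind(parents$dosage, hybrids$dosage),
                                parents$map)
    truth <- simulate_genetic_values(all_geno, s$n_qtl, s$additive_sd,
                                     s$dominance_sd, seed = cfg$seed + 2)
    des <- trial_design(cfg$design$n_env, cfg$design$trials_per_env,
                        cfg$design$replications, cfg$design$block_size,
                        cfg$design$replicated_hybrid_fraction,
                        cfg$design$n_checks)
    plots <- simulate_trials(truth$values, des, seed = cfg$seed + 3)
    write_geno_tsv(parents, path("parents_geno.tsv"), path("marker_map.tsv"))
    write_geno_tsv(hybrids, path("hybrids_geno.tsv"))
    utils::write.table(as.data.frame(plan), path("crossing_plan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth$qtl, path("truth_qtl.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_plots_csv(plots, path("plots.csv"))
  })
  load_simulated()

  run_stage("qc", function() {
    qc <- qc_filter(env$parents, cfg$qc$max_missing, cfg$qc$max_het,
                    cfg$qc$min_maf)
    write_geno_tsv(qc$geno, path("geno_qc.tsv"), path("map_qc.tsv"))
    rep <- data.frame(reason = c("input", names(qc$report$n_removed),
                                 "retained"),
                      n = c(qc$report$n_input, unname(qc$report$n_removed),
                            qc$report$n_retained))
    utils::write.table(rep, path("qc_report.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  qc_parents <- read_geno_tsv(path("geno_qc.tsv"), path("map_qc.tsv"))
  keep <- colnames(qc_parents$dosage)
  geno_all <- new_geno_matrix(
    rbind(qc_parents$dosage,
          env$hybrids$dosage[, keep, drop = FALSE]),
    env$parents$map[match(keep, env$parents$map$marker), , drop = FALSE])

  run_stage("pheno", function() {
    em <- adjust_entry_means_per_env(env$plots)
    utils::write.table(em, path("entry_means.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    bl <- blues_across_env(em)
    utils::write.table(data.frame(genotype = names(bl), blue = unname(bl)),
                       path("blues.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    het <- mid_parent_stats(bl, env$plan)
    utils::write.table(het, path("heterosis.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    vc <- variance_components_one_step(env$plots,
                                       hybrid_ids = env$plan$hybrid)
    h2h <- heritability(vc, cfg$design$n_env, cfg$design$replications,
                        "hybrids")
    vt <- data.frame(component = c(names(vc$sigma2), "h2_hybrids_entry_mean"),
                     value = c(unname(vc$sigma2), h2h$entry_mean))
    utils::write.table(vt, path("variance_components.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
  blues <- with(utils::read.delim(path("blues.tsv"),
                                  stringsAsFactors = FALSE),
                stats::setNames(blue, genotype))
  vt <- utils::read.delim(path("variance_components.tsv"),
                          stringsAsFactors = FALSE)
  h2 <- vt$value[vt$component == "h2_hybrids_entry_mean"]
  if (h2 <= 0) h2 <- 1e-3

  run_stage("gwas", function() {
    em <- utils::read.delim(path("entry_means.tsv"), stringsAsFactors = FALSE)
    em <- em[em$genotype %in% rownames(geno_all$dosage), , drop = FALSE]
    dm <- code_design_matrices(geno_all, impute = TRUE)
    rownames(dm$ZA) <- rownames(dm$ZD) <- rownames(geno_all$dosage)
    K <- kinship(dm, "additive")
    dimnames(K) <- list(rownames(geno_all$dosage), rownames(geno_all$dosage))
    scan <- gwas_scan(em, geno_all, K, "additive")
    scan$holm_significant <- holm_correct(scan$p_value, cfg$gwas$alpha)
    utils::write.table(scan, path("assoc_scan.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    qq <- qq_data(scan$p_value[!scan$skipped])
    utils::write.table(qq, path("qq_data.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  dm_all <- code_design_matrices(geno_all, impute = TRUE)
  rownames(dm_all$ZA) <- rownames(dm_all$ZD) <- rownames(geno_all$dosage)

  run_stage("predict", function() {
    yh <- blues[names(blues) %in% env$plan$hybrid]
    lam <- estimate_lambda(yh, dm_all)
    eff <- rrblup_fit(yh, dm_all, lam["lambda_A"], lam["lambda_D"])
    write_effects_tsv(eff, path("marker_effects.tsv"))
  })

  run_stage("cv", function() {
    yh <- blues[names(blues) %in% env$plan$hybrid]
    yp <- blues[names(blues) %in% c(env$parent_set$female_ids,
                                    env$parent_set$male_ids)]
    bundle <- cv_data(env$plan, geno_all, yh, yp, h2 = min(1, max(h2, 1e-3)))
    cv <- run_cv(bundle, cfg$cv$model, n_runs = cfg$cv$n_runs,
                 n_f_est = cfg$cv$n_f_est, n_m_est = cfg$cv$n_m_est,
                 n_hyb_est = cfg$cv$n_hyb_est, seed = cfg$seed + 10,
                 best_effort = TRUE)
    utils::write.table(as.data.frame(cv), path("cv_accuracy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  manifest <- yaml::read_yaml(manifest_path)
  invisible(manifest)
}
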