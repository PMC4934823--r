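#' Per-environment adjusted entry means (stage one)
#'
#' Fits, separately within each environment, the model
#' `y = mu + g + t + r + b + e` with genotype effects `g` fixed and trial,
#' replication and block effects random (REML), and returns the estimated
#' fixed genotype means `mu + g`. Random terms whose factor has fewer than two
#' levels in an environment are dropped from the model for that environment;
#' if no random term remains the model reduces to ordinary least squares.
#'
#' @param plots A `plot_records` data.frame (one row per plot).
#' @param trait Trait to analyse; default the single trait present.
#' @param environments Environments to analyse (default: all).
#' @return A data.frame `genotype`, `environment`, `mean` of class
#'   `entry_means`. Genotypes never observed in an environment are absent from
#'   its block of rows.
#' @export
adjust_entry_means_per_env <- function(plots, trait = NULL,
                                       environments = NULL) {
  plots <- check_plots(plots, trait)
  if (is.null(environments)) environments <- unique(plots$environment)
  out <- lapply(environments, function(env) {
    d <- plots[plots$environment == env, , drop = FALSE]
    d$genotype <- factor(d$genotype)
    if (nlevels(d$genotype) < 2)
      stop("environment ", env, " has fewer than 2 genotypes")
    rand <- c("trial", "replication", "block")
    rand <- rand[vapply(rand, function(f) length(unique(d[[f]])) > 1, TRUE)]
    mu_g <- if (length(rand)) {
      fml <- stats::as.formula(paste(
        "value ~ 0 + genotype +",
        paste(sprintf("(1 | %s)", rand), collapse = " + ")))
      fit <- lme4::lmer(fml, data = d,
                        control = lme4::lmerControl(calc.derivs = FALSE,
                                                    check.nobs.vs.nlev = "ignore",
                                                    check.nobs.vs.nRE = "ignore"))
      lme4::fixef(fit)
    } else {
      stats::coef(stats::lm(value ~ 0 + genotype, data = d))
    }
    names(mu_g) <- sub("^genotype", "", names(mu_g))
    data.frame(genotype = names(mu_g), environment = env,
               mean = unname(mu_g), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("entry_means", "data.frame")
  res
}

check_plots <- function(plots, trait = NULL) {
  need <- c("genotype", "environment", "trial", "replication", "block",
            "trait", "value")
  if (!all(need %in% names(plots)))
    stop("plot records need columns: ", paste(need, collapse = ", "))
  if (is.null(trait)) {
    tr <- unique(plots$trait)
    if (length(tr) > 1) stop("several traits present; pick one via `trait`")
    trait <- tr
  }
  plots[plots$trait == trait, , drop = FALSE]
}

#' Across-environment BLUEs (stage two)
#'
#' Stacks the per-environment adjusted entry means and fits
#' `mean = mu + g + l + e` with genotype fixed and environment random,
#' returning one best linear unbiased estimate per genotype. With a single
#' environment the stage-one means are returned unchanged.
#'
#' @param entry_means Output of [adjust_entry_means_per_env()].
#' @return Named numeric vector of BLUEs (names = genotype ids).
#' @export
blues_across_env <- function(entry_means) {
  stopifnot(all(c("genotype", "environment", "mean") %in% names(entry_means)))
  envs <- unique(entry_means$environment)
  if (length(envs) == 1L)
    return(stats::setNames(entry_means$mean, entry_means$genotype))
  d <- entry_means
  d$genotype <- factor(d$genotype)
  fit <- lme4::lmer(mean ~ 0 + genotype + (1 | environment), data = d,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.nobs.vs.nlev = "ignore",
                                                check.nobs.vs.nRE = "ignore"))
  b <- lme4::fixef(fit)
  names(b) <- sub("^genotype", "", names(b))
  b
}

#' Mid-parent value and mid-parent heterosis per cross
#'
#' For each cross, the mid-parent value is `MP = (P1 + P2) / 2` and relative
#' mid-parent heterosis is `MPH = (HYB - MP) / MP * 100` (percent).
#'
#' @param blues Named numeric vector of BLUEs covering all parents and hybrids
#'   of the plan.
#' @param plan A `crossing_plan`.
#' @return A data.frame `hybrid`, `P1`, `P2`, `HYB`, `MP`, `MPH`; attributes
#'   `mean_MPH` and `mean_abs_MPH` hold the across-cross summaries.
#' @export
mid_parent_stats <- function(blues, plan) {
  stopifnot(inherits(plan, "crossing_plan"))
  need <- unique(c(plan$female, plan$male, plan$hybrid))
  absent <- setdiff(need, names(blues))
  if (length(absent))
    stop("no BLUE for: ", paste(utils::head(absent, 5), collapse = ", "))
  P1 <- unname(blues[plan$female])
  P2 <- unname(blues[plan$male])
  HYB <- unname(blues[plan$hybrid])
  MP <- (P1 + P2) / 2
  if (any(MP == 0)) stop("mid-parent value of 0: MPH undefined for cross ",
                         plan$hybrid[which(MP == 0)[1]])
  MPH <- (HYB - MP) / MP * 100
  out <- data.frame(hybrid = plan$hybrid, P1 = P1, P2 = P2, HYB = HYB,
                    MP = MP, MPH = MPH, stringsAsFactors = FALSE)
  attr(out, "mean_MPH") <- mean(MPH)
  attr(out, "mean_abs_MPH") <- mean(abs(MPH))
  out
}

#' Combining-ability decomposition of hybrid performance
#'
#' Decomposes hybrid BLUEs as `y = mu + gca_f + gca_m + sca` under sum-to-zero
#' constraints on the female and male general combining ability (GCA) effects;
#' the cross-specific residual is the specific combining ability (SCA).
#'
#' @param hybrid_blues Named numeric vector of hybrid BLUEs.
#' @param plan A `crossing_plan` covering those hybrids.
#' @return A list of class `gca_model`: `mu`, `gca_f`, `gca_m` (named, each
#'   summing to zero), `sca` (named by hybrid).
#' @export
gca_sca <- function(hybrid_blues, plan) {
  stopifnot(inherits(plan, "crossing_plan"))
  plan <- plan[plan$hybrid %in% names(hybrid_blues), , drop = FALSE]
  if (!nrow(plan)) stop("no hybrid BLUEs match the plan")
  d <- data.frame(y = unname(hybrid_blues[plan$hybrid]),
                  f = factor(plan$female), m = factor(plan$male))
  fit <- stats::lm(y ~ f + m, data = d,
                   contrasts = list(f = "contr.sum", m = "contr.sum"))
  cf <- stats::coef(fit)
  lev_f <- levels(d$f); lev_m <- levels(d$m)
  gf <- cf[grep("^f[0-9]+$", names(cf))]
  gm <- cf[grep("^m[0-9]+$", names(cf))]
  gca_f <- stats::setNames(c(gf, -sum(gf)), lev_f)
  gca_m <- stats::setNames(c(gm, -sum(gm)), lev_m)
  sca <- stats::setNames(stats::resid(fit), plan$hybrid)
  structure(list(mu = unname(cf["(Intercept)"]), gca_f = gca_f,
                 gca_m = gca_m, sca = sca),
            class = "gca_model")
}

#' One-step variance-component analysis across lines and hybrids
#'
#' Fits, on the complete plot-level data, a model with a fixed intercept and
#' random effects for environment, trial, replication, block, line genetic
#' value, line-by-environment interaction, hybrid genetic value,
#' hybrid-by-environment interaction, and plot residual (REML via lme4).
#' Check genotypes are treated as lines. Optionally, each variance component
#' is tested by a likelihood-ratio test against the model without it, using
#' the halved-p-value convention for a variance testing on the boundary
#' (statistic 0 gives p = 0.5).
#'
#' @param plots A `plot_records` data.frame covering lines and hybrids.
#' @param hybrid_ids Hybrid genotype ids; default: ids containing `"x"`.
#' @param trait Trait to analyse.
#' @param lrt Compute halved-LRT p-values per component (default `FALSE`;
#'   requires one refit per component).
#' @return A list of class `variance_components`: `sigma2` (named vector with
#'   components environment, trial, replication, block, lines, lines_x_env,
#'   hybrids, hybrids_x_env, error), optionally `p_values`, and `fit`.
#' @export
variance_components_one_step <- function(plots, hybrid_ids = NULL,
                                         trait = NULL, lrt = FALSE) {
  d <- check_plots(plots, trait)
  if (is.null(hybrid_ids))
    hybrid_ids <- unique(d$genotype[grepl("x", d$genotype, fixed = TRUE)])
  d$line_ind <- as.numeric(!(d$genotype %in% hybrid_ids))
  d$hyb_ind <- 1 - d$line_ind
  d$line_geno <- d$genotype; d$hyb_geno <- d$genotype
  d$line_env <- paste(d$genotype, d$environment, sep = "@")
  d$hyb_env <- d$line_env
  terms <- c(environment = "(1 | environment)",
             trial = "(1 | trial)",
             replication = "(1 | replication)",
             block = "(1 | block)",
             lines = "(0 + line_ind | line_geno)",
             lines_x_env = "(0 + line_ind | line_env)",
             hybrids = "(0 + hyb_ind | hyb_geno)",
             hybrids_x_env = "(0 + hyb_ind | hyb_env)")
  fit_with <- function(keep) {
    fml <- stats::as.formula(paste("value ~ 1 +", paste(terms[keep], collapse = " + ")))
    lme4::lmer(fml, data = d,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore"))
  }
  full <- fit_with(names(terms))
  vc <- as.data.frame(lme4::VarCorr(full))
  grp_of <- c(environment = "environment", trial = "trial",
              replication = "replication", block = "block",
              lines = "line_geno", lines_x_env = "line_env",
              hybrids = "hyb_geno", hybrids_x_env = "hyb_env")
  sigma2 <- vapply(grp_of, function(g) vc$vcov[match(g, vc$grp)], numeric(1))
  sigma2 <- c(sigma2, error = vc$vcov[vc$grp == "Residual"])
  out <- list(sigma2 = sigma2, fit = full)
  if (lrt) {
    ll_full <- as.numeric(stats::logLik(full))
    pv <- vapply(names(terms), function(comp) {
      red <- fit_with(setdiff(names(terms), comp))
      stat <- max(0, 2 * (ll_full - as.numeric(stats::logLik(red))))
      if (stat <= 0) 0.5 else 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
    }, numeric(1))
    out$p_values <- pv
  }
  class(out) <- "variance_components"
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat("one-step REML variance components:\n")
  tab <- data.frame(sigma2 = round(x$sigma2, 4))
  if (!is.null(x$p_values))
    tab$halved_LRT_p <- c(signif(x$p_values, 3), NA)[seq_len(nrow(tab))]
  print(tab)
  invisible(x)
}

#' Halved-LRT p-value for a variance component
#'
#' Likelihood-ratio statistic against a chi-square(1) reference with the p
#' value halved to account for the null hypothesis lying on the boundary of
#' the parameter space; a statistic of 0 gives p = 0.5.
#'
#' @param stat Nonnegative LRT statistic.
#' @return p-value in (0, 0.5].
#' @export
halved_lrt_p <- function(stat) {
  if (stat < 0) stat <- 0
  if (stat == 0) return(0.5)
  0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Heritability on entry-mean and plot basis
#'
#' Entry-mean heritability `h2 = s2_G / (s2_G + s2_GxE / E + s2_e / (E R))`
#' and plot-basis heritability `s2_G / (s2_G + s2_GxE + s2_e)`, both clamped
#' to `[0, 1]`.
#'
#' @param vc A `variance_components` object or a named numeric vector
#'   containing the needed components.
#' @param E Number of environments the genotype group was tested in.
#' @param R Number of replications.
#' @param group `"hybrids"` or `"lines"`: which genetic and interaction
#'   variance to use when `vc` is a `variance_components` object.
#' @return A list `entry_mean`, `plot` with the two heritabilities.
#' @export
heritability <- function(vc, E, R, group = c("hybrids", "lines")) {
  group <- match.arg(group)
  if (E < 1 || R < 1) stop("E and R must be >= 1")
  if (inherits(vc, "variance_components")) vc <- vc$sigma2
  s2_g <- unname(vc[group])
  s2_ge <- unname(vc[paste0(group, "_x_env")])
  s2_e <- unname(vc["error"])
  if (anyNA(c(s2_g, s2_ge, s2_e)))
    stop("variance components for group '", group, "' not found")
  tot <- s2_g + s2_ge + s2_e
  if (tot <= 0) stop("all variance components are zero")
  clamp01 <- function(x) min(1, max(0, x))
  list(entry_mean = clamp01(s2_g / (s2_g + s2_ge / E + s2_e / (E * R))),
       plot = clamp01(s2_g / tot))
}
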