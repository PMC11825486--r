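#' Simulation configuration for synthetic GWAS summary statistics
#'
#' Defines a linked exposure / mediator / outcome triad with known causal
#' structure: instrument effects `gamma_j` act on the exposure; the mediator
#' receives `a * gamma_j` plus optional mediator-side pleiotropy; the
#' outcome receives `(c + a b) * gamma_j` plus `b` times the mediator
#' pleiotropy, outcome-side pleiotropy, and any contamination direct
#' effects. Defaults emulate the statistical shape of the motivating data
#' sources: a gut-microbiota-scale exposure GWAS (n = 5,959), an
#' immune-trait-scale mediator GWAS (n = 3,757) and a biobank-scale binary
#' outcome GWAS (n = 321,040), with instrument effects strong enough to
#' clear a suggestive threshold at the exposure sample size.
#'
#' @param n_variants Number of candidate instruments.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes (>= 100).
#' @param eaf_range Interval in (0,1) for effect-allele frequencies.
#' @param gamma_mean,gamma_sd Instrument-effect distribution on the exposure.
#' @param a,b,c Causal effects: exposure-to-mediator, mediator-to-outcome
#'   (conditional), and direct exposure-to-outcome.
#' @param pleiotropy Outcome-side pleiotropy: list with `type` in
#'   `{"none","balanced","directional"}`, `mean`, `sd`, `fraction` affected.
#' @param mediator_pleiotropy Same structure, applied to the mediator.
#' @param contamination Fraction of variants with large independent direct
#'   effects on the outcome (drawn as random-sign Uniform(5, 10) times the
#'   pleiotropy SD, or times 0.05 when that SD is zero).
#' @param weak_fraction,weak_scale Fraction of variants whose instrument
#'   effect is shrunk by `weak_scale`.
#' @param palindromic_fraction Fraction of variants assigned A/T or G/C
#'   allele pairs.
#' @param confounding SD of a shared-confounder effect on the secondary
#'   trait in [simulate_null_reverse()] (no causal path).
#' @param seed Mandatory integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 20,
                       n_exposure = 5959, n_mediator = 3757,
                       n_outcome = 321040,
                       eaf_range = c(0.1, 0.9),
                       gamma_mean = 0.15, gamma_sd = 0.05,
                       a = 0.5, b = 0.2, c = 0.1,
                       pleiotropy = list(type = "none", mean = 0, sd = 0,
                                         fraction = 0),
                       mediator_pleiotropy = list(type = "none", mean = 0,
                                                  sd = 0, fraction = 0),
                       contamination = 0,
                       weak_fraction = 0, weak_scale = 0.1,
                       palindromic_fraction = 0,
                       confounding = 0,
                       seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  stopifnot(n_variants >= 1,
            n_exposure >= 100, n_mediator >= 100, n_outcome >= 100,
            length(eaf_range) == 2, eaf_range[1] > 0, eaf_range[2] < 1,
            eaf_range[1] < eaf_range[2],
            contamination >= 0, contamination <= 1,
            weak_fraction >= 0, weak_fraction <= 1,
            palindromic_fraction >= 0, palindromic_fraction <= 1)
  for (pl in list(pleiotropy, mediator_pleiotropy)) {
    stopifnot(pl$type %in% c("none", "balanced", "directional"),
              pl$fraction >= 0, pl$fraction <= 1)
  }
  structure(mget(names(formals())), class = "sim_config")
}

draw_pleiotropy <- function(pl, k) {
  out <- numeric(k)
  if (pl$type == "none" || pl$fraction == 0 ||
      (pl$sd == 0 && pl$type == "balanced")) return(out)
  hit <- stats::runif(k) < pl$fraction
  mu <- if (pl$type == "balanced") 0 else pl$mean
  out[hit] <- stats::rnorm(sum(hit), mean = mu, sd = pl$sd)
  out
}

# Analytic per-variant SE for a standardized trait.
sim_se <- function(n, eaf) 1 / sqrt(2 * n * eaf * (1 - eaf))

sim_alleles <- function(k, palindromic_fraction) {
  non_pal <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pal <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  is_pal <- stats::runif(k) < palindromic_fraction
  idx_np <- sample.int(nrow(non_pal), k, replace = TRUE)
  idx_p <- sample.int(nrow(pal), k, replace = TRUE)
  ea <- ifelse(is_pal, pal[idx_p, 1], non_pal[idx_np, 1])
  oa <- ifelse(is_pal, pal[idx_p, 2], non_pal[idx_np, 2])
  list(ea = ea, oa = oa)
}

sim_trait <- function(trait_id, snp_id, chrom, pos, ea, oa, eaf, true_beta,
                      n, trait_type = "quantitative") {
  se <- sim_se(n, eaf)
  beta <- true_beta + stats::rnorm(length(eaf), sd = se)
  p <- 2 * stats::pnorm(-abs(beta / se))
  p[p == 0] <- .Machine$double.xmin
  sumstat_set(trait_id,
              data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                         effect_allele = ea, other_allele = oa,
                         eaf = eaf, beta = beta, se = se, pvalue = p,
                         n = n, stringsAsFactors = FALSE),
              trait_type = trait_type)
}

#' Simulate a linked exposure / mediator / outcome summary-statistic triad
#'
#' Draws per-variant frequencies, instrument effects and pleiotropy per the
#' configuration, then observes each trait's effects with analytic sampling
#' noise `se = 1/sqrt(2 n f (1-f))`. Variant positions are spaced 20 Mb
#' apart so LD clumping is trivially satisfiable, and the LD matrix is the
#' identity. Fully reproducible from the configured seed.
#'
#' @param config A [sim_config()].
#' @return A list with `exposure`, `mediator`, `outcome` ([sumstat_set()]s),
#'   `truth` (realized `gamma`, pleiotropic and contamination effects,
#'   `a`, `b`, `c`, `theta_total = c + a b`,
#'   `proportion_mediated = a b/(c + a b)`, contamination indicator) and
#'   `ld` (identity `ld_matrix`).
#' @export
simulate_triad <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    k <- cf$n_variants
    snp_id <- sprintf("rs%06d", seq_len(k))
    chrom <- as.character(rep_len(1:22, k))
    # same-chromosome neighbours sit 20 Mb apart: clumping windows never overlap
    pos <- 1 + ((seq_len(k) - 1) %/% 22) * 2e7
    eaf <- stats::runif(k, cf$eaf_range[1], cf$eaf_range[2])
    al <- sim_alleles(k, cf$palindromic_fraction)
    gamma <- stats::rnorm(k, cf$gamma_mean, cf$gamma_sd)
    weak <- stats::runif(k) < cf$weak_fraction
    gamma[weak] <- gamma[weak] * cf$weak_scale
    pleio_m <- draw_pleiotropy(cf$mediator_pleiotropy, k)
    pleio_y <- draw_pleiotropy(cf$pleiotropy, k)
    contam <- stats::runif(k) < cf$contamination
    contam_scale <- if (cf$pleiotropy$sd > 0) cf$pleiotropy$sd else 0.05
    contam_eff <- numeric(k)
    contam_eff[contam] <- sample(c(-1, 1), sum(contam), replace = TRUE) *
      stats::runif(sum(contam), 5 * contam_scale, 10 * contam_scale)

    true_x <- gamma
    true_m <- cf$a * gamma + pleio_m
    true_y <- (cf$c + cf$a * cf$b) * gamma + cf$b * pleio_m + pleio_y +
      contam_eff

    exposure <- sim_trait("exposure", snp_id, chrom, pos, al$ea, al$oa, eaf,
                          true_x, cf$n_exposure)
    mediator <- sim_trait("mediator", snp_id, chrom, pos, al$ea, al$oa, eaf,
                          true_m, cf$n_mediator)
    outcome <- sim_trait("outcome", snp_id, chrom, pos, al$ea, al$oa, eaf,
                         true_y, cf$n_outcome, trait_type = "binary")
    theta_total <- cf$c + cf$a * cf$b
    truth <- list(gamma = gamma, pleio_mediator = pleio_m,
                  pleio_outcome = pleio_y, contaminated = contam,
                  contamination_effect = contam_eff,
                  a = cf$a, b = cf$b, c = cf$c,
                  theta_total = theta_total,
                  proportion_mediated = if (theta_total != 0)
                    cf$a * cf$b / theta_total else NA_real_)
    list(exposure = exposure, mediator = mediator, outcome = outcome,
         truth = truth, ld = ld_identity(snp_id))
  })
}

#' Simulate a null reverse-direction trait pair
#'
#' Generates a primary trait with genuine instruments and a secondary trait
#' on which those instruments have no causal effect; optionally a shared
#' confounder gives the secondary trait variant effects uncorrelated with
#' the instrument strengths. Used to check the type-I error of the
#' reverse-direction screen.
#'
#' @param config A [sim_config()]; `n_outcome` is used for the
#'   instrumented (primary) trait and `n_exposure` for the null secondary
#'   trait, matching a biobank outcome instrumenting against a smaller
#'   exposure GWAS. `confounding` sets the SD of the shared-confounder
#'   effects on the secondary trait.
#' @return A list with `primary` and `secondary` [sumstat_set()]s, `truth`,
#'   and an identity `ld`.
#' @export
simulate_null_reverse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    k <- cf$n_variants
    snp_id <- sprintf("rs%06d", seq_len(k))
    chrom <- as.character(rep_len(1:22, k))
    pos <- 1 + ((seq_len(k) - 1) %/% 22) * 2e7
    eaf <- stats::runif(k, cf$eaf_range[1], cf$eaf_range[2])
    al <- sim_alleles(k, cf$palindromic_fraction)
    gamma <- stats::rnorm(k, cf$gamma_mean, cf$gamma_sd)
    conf_eff <- if (cf$confounding > 0)
      stats::rnorm(k, 0, cf$confounding) else numeric(k)
    primary <- sim_trait("primary", snp_id, chrom, pos, al$ea, al$oa, eaf,
                         gamma, cf$n_outcome, trait_type = "binary")
    secondary <- sim_trait("secondary", snp_id, chrom, pos, al$ea, al$oa,
                           eaf, conf_eff, cf$n_exposure)
    list(primary = primary, secondary = secondary,
         truth = list(gamma = gamma, confounder_effect = conf_eff,
                      theta = 0),
         ld = ld_identity(snp_id))
  })
}

#' Write a simulated triad to a directory
#'
#' Writes the three summary-statistic TSVs (`exposure.tsv`, `mediator.tsv`,
#' `outcome.tsv`), `ld.tsv` and the generating truth as `truth.json`.
#'
#' @param sim Output of [simulate_triad()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_triad <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sumstats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(sim$mediator, file.path(dir, "mediator.tsv"))
  write_sumstats(sim$outcome, file.path(dir, "outcome.tsv"))
  write_ld_matrix(sim$ld, file.path(dir, "ld.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
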