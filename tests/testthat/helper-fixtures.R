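# Shared fixture builders. Everything is generated in code; no stored data.

# Minimal canonical records data.frame.
make_records <- function(snp_id, beta, se, pvalue = NULL,
                         eaf = 0.3, chrom = "1",
                         pos = seq_along(snp_id) * 2e7 + 1,
                         effect_allele = "A", other_allele = "G",
                         n = 10000) {
  k <- length(snp_id)
  if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(beta / se))
  pvalue <- pmax(pvalue, 1e-300)
  data.frame(snp_id = snp_id, chrom = rep_len(chrom, k),
             pos = rep_len(pos, k),
             effect_allele = rep_len(effect_allele, k),
             other_allele = rep_len(other_allele, k),
             eaf = rep_len(eaf, k), beta = beta, se = rep_len(se, k),
             pvalue = pvalue, n = rep_len(n, k), stringsAsFactors = FALSE)
}

make_set <- function(trait_id, ...) sumstat_set(trait_id, make_records(...))

# beta giving per-variant F exactly `f` at (se, n) under the printed
# formulas with k = 1: R2/(1-R2) = F/(n-2), R2 = beta^2/(beta^2 + se^2 n).
beta_for_f <- function(f, se, n) se * sqrt(n * f / (n - 2))

# Write a canonical sumstats TSV and return its path.
write_fixture_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Homogeneous ratio fixture: every variant has by = ratio * bx exactly.
homogeneous_pair <- function(k = 6, ratio = 0.1, bx = NULL, byse = 0.01,
                             bxse = 0) {
  if (is.null(bx)) bx <- seq(0.1, by = 0.05, length.out = k)
  mr_input(bx = bx, bxse = rep_len(bxse, k), by = ratio * bx,
           byse = rep_len(byse, k))
}

# Concordant variants plus one planted outlier with a deviant ratio.
outlier_pair <- function(k_good = 10, good_ratio = 0.1, bad_ratio = 2,
                         byse = 0.01, seed = 7) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  bx <- withr_seed(runif(k_good + 1, 0.1, 0.4))
  by <- good_ratio * bx
  by[k_good + 1] <- bad_ratio * bx[k_good + 1]
  noise <- withr_seed(rnorm(k_good + 1, sd = byse / 10))
  mr_input(bx = bx, bxse = rep(0, k_good + 1), by = by + noise,
           byse = rep(byse, k_good + 1))
}

# Small screen cohort: several exposures with disjoint instruments and one
# shared outcome; exposure i has true outcome effect theta_vec[i].
make_screen_cohort <- function(theta_vec, k = 12, seed = 11,
                               n_exp = 5959, n_out = 321040) {
  set.seed(seed)
  exposures <- list()
  out_rows <- NULL
  for (i in seq_along(theta_vec)) {
    ids <- sprintf("rs%02d%04d", i, seq_len(k))
    eaf <- runif(k, 0.2, 0.8)
    gamma <- rnorm(k, 0.25, 0.05)
    se_x <- 1 / sqrt(2 * n_exp * eaf * (1 - eaf))
    bx <- gamma + rnorm(k, sd = se_x)
    ex <- make_records(ids, beta = bx, se = se_x, eaf = eaf,
                       chrom = as.character(i), n = n_exp)
    ex$se <- se_x
    exposures[[i]] <- sumstat_set(sprintf("exposure_%d", i), ex)
    se_y <- 1 / sqrt(2 * n_out * eaf * (1 - eaf))
    by <- theta_vec[i] * gamma + rnorm(k, sd = se_y)
    oy <- make_records(ids, beta = by, se = se_y, eaf = eaf,
                       chrom = as.character(i), n = n_out)
    oy$se <- se_y
    out_rows <- rbind(out_rows, oy)
  }
  outcome <- sumstat_set("outcome", out_rows, trait_type = "binary")
  list(exposures = exposures, outcome = outcome)
}
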