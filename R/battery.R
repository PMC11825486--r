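#' Battery configuration
#'
#' @param methods Character vector of estimator labels to run. The default
#'   battery is the four IVW flavours (primary auto fixed/random, robust,
#'   penalized, penalized robust), the four Egger flavours, maximum
#'   likelihood, debiased IVW, contamination mixture, MR-Lasso, BWMR and
#'   cML (MA-BIC with data perturbation) — 14 estimates — plus MR-PRESSO.
#' @param presso Logical, run MR-PRESSO alongside the estimators.
#' @param presso_nsim Simulations for MR-PRESSO.
#' @param cml_dp_reps Data perturbations for cML.
#' @param include_ivw_flavors Also emit explicit `ivw_fixed` and
#'   `ivw_random` rows in addition to the auto-flavoured primary `ivw` row.
#' @return A list of class `battery_config`.
#' @export
battery_config <- function(methods = c("ivw", "ivw_robust", "ivw_penalized",
                                       "ivw_penalized_robust",
                                       "egger", "egger_robust",
                                       "egger_penalized",
                                       "egger_penalized_robust",
                                       "maximum_likelihood", "debiased_ivw",
                                       "contamination_mixture", "mr_lasso",
                                       "bwmr", "cml"),
                           presso = TRUE, presso_nsim = 1000,
                           cml_dp_reps = 200, include_ivw_flavors = FALSE) {
  if (include_ivw_flavors)
    methods <- union(methods, c("ivw_fixed", "ivw_random"))
  structure(list(methods = methods, presso = presso,
                 presso_nsim = presso_nsim, cml_dp_reps = cml_dp_reps),
            class = "battery_config")
}

battery_dispatch <- function(method, h, config, seed) {
  switch(method,
    ivw = mr_ivw(h, model = "auto"),
    ivw_fixed = mr_ivw(h, model = "fixed"),
    ivw_random = mr_ivw(h, model = "random"),
    ivw_robust = mr_ivw(h, robust = TRUE),
    ivw_penalized = mr_ivw(h, penalized = TRUE),
    ivw_penalized_robust = mr_ivw(h, robust = TRUE, penalized = TRUE),
    egger = mr_egger(h),
    egger_robust = mr_egger(h, robust = TRUE),
    egger_penalized = mr_egger(h, penalized = TRUE),
    egger_penalized_robust = mr_egger(h, robust = TRUE, penalized = TRUE),
    maximum_likelihood = mr_maxlik(h),
    debiased_ivw = mr_divw(h),
    contamination_mixture = mr_conmix(h),
    mr_lasso = mr_lasso(h),
    bwmr = mr_bwmr(h),
    cml = mr_cml(h, variant = "MA-BIC", dp_reps = config$cml_dp_reps,
                 seed = child_seed(seed, 7)),
    stop("unknown battery method: ", method)
  )
}

DIAG_COLS <- c("egger_intercept", "egger_intercept_p", "cochran_q",
               "q_pvalue", "selected_k", "valid_set_size", "psi",
               "iterations")

estimate_row <- function(method, est = NULL, err = NULL) {
  row <- data.frame(method = method, theta = NA_real_, se = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    pvalue = NA_real_, n_snps = NA_integer_,
                    stringsAsFactors = FALSE)
  for (dc in DIAG_COLS) row[[dc]] <- NA_real_
  row$error <- NA_character_
  if (!is.null(err)) {
    row$error <- conditionMessage(err)
    return(row)
  }
  row$method <- est$method
  row$theta <- est$theta; row$se <- est$se
  row$ci_low <- est$ci_low; row$ci_high <- est$ci_high
  row$pvalue <- est$pvalue; row$n_snps <- est$n_snps
  for (dc in DIAG_COLS) {
    v <- est$diagnostics[[dc]]
    if (!is.null(v) && length(v) == 1L && is.numeric(v)) row[[dc]] <- v
  }
  row
}

#' Run the full estimator battery on a harmonized exposure-outcome pair
#'
#' Executes every configured estimator; a failing method is recorded with
#' its error message and never aborts the battery. Output row order follows
#' the configured method order deterministically.
#'
#' @param h A `harmonized_set` (exposure first, outcome second) or
#'   [mr_input()] frame.
#' @param config A [battery_config()].
#' @param seed Integer seed driving the stochastic procedures (MR-PRESSO
#'   simulations, cML data perturbation).
#' @return A `battery_result`: list with `estimates` (one data-frame row per
#'   method, diagnostics flattened to columns) and `presso` (a
#'   `presso_result` or `NULL`).
#' @export
run_battery <- function(h, config = battery_config(), seed = 1L) {
  stopifnot(inherits(config, "battery_config"))
  rows <- lapply(config$methods, function(m) {
    tryCatch(estimate_row(m, battery_dispatch(m, h, config, seed)),
             error = function(e) estimate_row(m, err = e))
  })
  estimates <- do.call(rbind, rows)
  presso <- NULL
  if (isTRUE(config$presso)) {
    presso <- tryCatch(mr_presso(h, n_sim = config$presso_nsim,
                                 seed = child_seed(seed, 11)),
                       error = function(e) e)
  }
  structure(list(estimates = estimates, presso = presso, seed = seed),
            class = "battery_result")
}

#' @export
print.battery_result <- function(x, ...) {
  cat(sprintf("<battery_result> %d methods\n", nrow(x$estimates)))
  print(x$estimates[, c("method", "theta", "se", "pvalue", "n_snps", "error")])
  invisible(x)
}

#' Write battery estimates as TSV
#'
#' One row per method with theta, se, 95% CI, p-value, instrument count and
#' flattened diagnostics — the tabular equivalent of a forest plot.
#'
#' @param battery A `battery_result`.
#' @param path Output path.
#' @param exposure,outcome Optional trait labels prefixed as columns.
#' @export
write_battery <- function(battery, path, exposure = NA, outcome = NA) {
  df <- cbind(data.frame(exposure = exposure, outcome = outcome,
                         stringsAsFactors = FALSE),
              battery$estimates)
  write_tsv(df, path)
}
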