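#' Screening configuration
#'
#' Thresholds reproducing the workflow defaults: suggestive instrument
#' threshold 1e-5 for the forward direction, genome-wide 5e-8 for the
#' reverse direction, LD clump r2 < 0.001 within 10,000 kb, weak-instrument
#' bound F > 10, nominal significance 0.05.
#'
#' @param p_exposure,p_reverse Instrument p-value thresholds.
#' @param r2_clump,window_kb,f_min Instrument-selection parameters.
#' @param alpha Nominal significance level for verdicts and mediation steps.
#' @param battery A [battery_config()].
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(p_exposure = 1e-5, p_reverse = 5e-8,
                          r2_clump = 0.001, window_kb = 10000, f_min = 10,
                          alpha = 0.05, battery = battery_config()) {
  structure(list(p_exposure = p_exposure, p_reverse = p_reverse,
                 r2_clump = r2_clump, window_kb = window_kb, f_min = f_min,
                 alpha = alpha, battery = battery),
            class = "screen_config")
}

SUPPLEMENTARY_METHODS <- c("maximum_likelihood", "debiased_ivw",
                           "contamination_mixture", "mr_lasso", "bwmr",
                           "cml_ma_bic_dp", "cml_ma_bic", "cml_bic_dp",
                           "cml_bic")

#' Robustness verdict from a battery of estimates
#'
#' Pure function of the battery outputs codifying "strong and robust":
#' the verdict is `robust` iff the primary IVW p-value is below `alpha` and
#' all five checks hold — direction consistency (sign agreement across all
#' succeeding estimators), Egger-intercept cleanliness (every intercept
#' variant p > 0.05), MR-PRESSO cleanliness (no flagged outliers, or a
#' corrected estimate that retains the sign and stays significant),
#' supplementary support (all supplementary methods significant with the
#' primary sign) and reverse nullity (reverse-direction p at or above the
#' threshold; a non-estimable reverse analysis counts as null by convention
#' and is flagged). `suggestive` when the primary p passes but a check
#' fails; `rejected` otherwise.
#'
#' @param battery A `battery_result`.
#' @param reverse_p Reverse-direction primary p-value (`NA` when not
#'   estimable).
#' @param alpha Significance level.
#' @param exposure_id Label carried into the output.
#' @return A one-row data frame: the five booleans, primary p, verdict.
#' @export
robustness_verdict <- function(battery, reverse_p = NA_real_, alpha = 0.05,
                               exposure_id = NA_character_) {
  est <- battery$estimates
  ok <- !is.na(est$theta)
  primary <- est[est$method == "ivw" & ok, , drop = FALSE]
  primary_p <- if (nrow(primary)) primary$pvalue[1] else NA_real_
  primary_sign <- if (nrow(primary)) sign(primary$theta[1]) else NA_real_
  direction_consistent <- nrow(primary) > 0 &&
    all(sign(est$theta[ok]) == primary_sign)
  egger_rows <- est[grepl("^egger", est$method) & ok, , drop = FALSE]
  egger_intercept_ok <- nrow(egger_rows) > 0 &&
    all(egger_rows$egger_intercept_p > 0.05, na.rm = FALSE)
  presso <- battery$presso
  presso_estimable <- inherits(presso, "presso_result")
  presso_ok <- if (!presso_estimable) {
    TRUE  # too few instruments to test; flagged via presso_estimable
  } else if (!any(presso$outliers$flagged)) {
    TRUE
  } else if (!is.null(presso$corrected_estimate)) {
    ce <- presso$corrected_estimate
    sign(ce$theta) == primary_sign && ce$pvalue < alpha
  } else FALSE
  supp <- est[est$method %in% SUPPLEMENTARY_METHODS & ok, , drop = FALSE]
  supplementary_ok <- nrow(supp) > 0 &&
    all(supp$pvalue < alpha & sign(supp$theta) == primary_sign)
  reverse_estimable <- !is.na(reverse_p)
  reverse_null <- !reverse_estimable || reverse_p >= alpha
  all_ok <- isTRUE(direction_consistent) && isTRUE(egger_intercept_ok) &&
    isTRUE(presso_ok) && isTRUE(supplementary_ok) && isTRUE(reverse_null)
  verdict <- if (is.na(primary_p) || primary_p >= alpha) "rejected"
             else if (all_ok) "robust" else "suggestive"
  data.frame(exposure_id = exposure_id, primary_p = primary_p,
             direction_consistent = direction_consistent,
             egger_intercept_ok = egger_intercept_ok,
             presso_ok = presso_ok,
             presso_estimable = presso_estimable,
             supplementary_ok = supplementary_ok,
             reverse_null = reverse_null,
             reverse_estimable = reverse_estimable,
             verdict = verdict, stringsAsFactors = FALSE)
}

screen_one <- function(exposure, outcome, ld, config, seed, p_threshold) {
  iv <- select_instruments(exposure, ld, p_threshold = p_threshold,
                           f_min = config$f_min, r2_clump = config$r2_clump,
                           window_kb = config$window_kb)
  h <- harmonize(instruments_as_sumstats(iv, exposure$trait_type), outcome)
  battery <- run_battery(h, config$battery, seed = seed)
  list(instruments = iv, harmonized = h, battery = battery)
}

#' Screen many exposures against one outcome
#'
#' Runs instrument selection (suggestive threshold), harmonization, the
#' full estimator battery and a robustness verdict for each exposure.
#' Per-exposure failures are recorded and never abort the screen. Also
#' assembles a heatmap-shaped method-by-exposure p-value table (with a
#' significance flag column layout) mirroring the usual multi-method
#' summary figure.
#'
#' @param exposures Non-empty list of [sumstat_set()] objects.
#' @param outcome A [sumstat_set()].
#' @param ld An `ld_matrix` or `NULL`.
#' @param config A [screen_config()].
#' @param seed Integer seed; each exposure gets a derived child seed.
#' @param reverse_p Optional named vector of reverse-direction p-values per
#'   exposure trait id, merged into the verdicts.
#' @return A `screen_result`: list with `results` (per-exposure battery or
#'   error), `verdicts` (data frame) and `heatmap` (data frame, one row per
#'   method, one column per exposure holding p-values).
#' @export
screen <- function(exposures, outcome, ld = NULL, config = screen_config(),
                   seed = 1L, reverse_p = NULL) {
  if (!length(exposures)) stop("screen: empty exposure list")
  if (inherits(exposures, "sumstat_set")) exposures <- list(exposures)
  ids <- vapply(exposures, `[[`, "", "trait_id")
  results <- stats::setNames(vector("list", length(exposures)), ids)
  verdicts <- NULL
  for (i in seq_along(exposures)) {
    id <- ids[i]
    res <- tryCatch(
      screen_one(exposures[[i]], outcome, ld, config,
                 seed = child_seed(seed, i), p_threshold = config$p_exposure),
      error = function(e) e)
    results[[i]] <- res
    rp <- if (!is.null(reverse_p) && id %in% names(reverse_p))
      reverse_p[[id]] else NA_real_
    v <- if (inherits(res, "error")) {
      data.frame(exposure_id = id, primary_p = NA_real_,
                 direction_consistent = FALSE, egger_intercept_ok = FALSE,
                 presso_ok = FALSE, presso_estimable = FALSE,
                 supplementary_ok = FALSE, reverse_null = NA,
                 reverse_estimable = FALSE, verdict = "rejected",
                 stringsAsFactors = FALSE)
    } else {
      robustness_verdict(res$battery, reverse_p = rp, alpha = config$alpha,
                         exposure_id = id)
    }
    verdicts <- rbind(verdicts, v)
  }
  methods <- config$battery$methods
  heatmap <- data.frame(method = methods, stringsAsFactors = FALSE)
  for (i in seq_along(exposures)) {
    res <- results[[i]]
    pv <- rep(NA_real_, length(methods))
    if (!inherits(res, "error")) {
      est <- res$battery$estimates
      pv <- est$pvalue[match(methods, config$battery$methods)]
    }
    heatmap[[ids[i]]] <- pv
  }
  structure(list(results = results, verdicts = verdicts, heatmap = heatmap,
                 config = config, seed = seed),
            class = "screen_result")
}

#' Reverse-direction MR screen
#'
#' Treats the original outcome as the exposure, instruments it at the
#' genome-wide threshold (`p_reverse`), and estimates its effect on each of
#' the original exposures. When no instrument passes the stricter
#' threshold the pair is reported non-estimable and counts as reverse-null
#' by convention (flagged in the output).
#'
#' @param outcome_as_exposure The outcome [sumstat_set()], now instrumented.
#' @param exposures_as_outcomes List of [sumstat_set()] targets.
#' @param ld An `ld_matrix` or `NULL`.
#' @param config A [screen_config()].
#' @param seed Integer seed.
#' @return A data frame: target trait, theta, se, pvalue, n_snps,
#'   `estimable`, `reverse_null`.
#' @export
reverse_screen <- function(outcome_as_exposure, exposures_as_outcomes,
                           ld = NULL, config = screen_config(), seed = 1L) {
  if (inherits(exposures_as_outcomes, "sumstat_set"))
    exposures_as_outcomes <- list(exposures_as_outcomes)
  iv <- tryCatch(
    select_instruments(outcome_as_exposure, ld,
                       p_threshold = config$p_reverse, f_min = config$f_min,
                       r2_clump = config$r2_clump,
                       window_kb = config$window_kb),
    error = function(e) NULL)
  rows <- lapply(exposures_as_outcomes, function(target) {
    id <- target$trait_id
    if (is.null(iv))
      return(data.frame(target = id, theta = NA_real_, se = NA_real_,
                        pvalue = NA_real_, n_snps = 0L, estimable = FALSE,
                        reverse_null = TRUE, stringsAsFactors = FALSE))
    est <- tryCatch({
      h <- harmonize(instruments_as_sumstats(iv, "binary"), target)
      mr_ivw(h, model = "auto")
    }, error = function(e) NULL)
    if (is.null(est))
      return(data.frame(target = id, theta = NA_real_, se = NA_real_,
                        pvalue = NA_real_, n_snps = 0L, estimable = FALSE,
                        reverse_null = TRUE, stringsAsFactors = FALSE))
    data.frame(target = id, theta = est$theta, se = est$se,
               pvalue = est$pvalue, n_snps = est$n_snps, estimable = TRUE,
               reverse_null = est$pvalue >= config$alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Scan candidate mediators between one exposure and one outcome
#'
#' Runs [two_step_mediation()] for every candidate mediator, reporting both
#' nominal and Benjamini-Hochberg-adjusted step-1 p-values (the headline
#' supported/unsupported call stays nominal). Per-mediator failures are
#' recorded, never fatal. A volcano-shaped table (step-1 effect vs p per
#' mediator) is included for plotting.
#'
#' @param exposure,outcome [sumstat_set()] objects.
#' @param mediators Non-empty list of mediator [sumstat_set()]s.
#' @param ld An `ld_matrix` or `NULL`.
#' @param config A [screen_config()].
#' @return A `mediator_scan_result`: list with `report` (one row per
#'   mediator: total/step-1/step-2 beta, se, p, proportion mediated in
#'   percent, supported flag, BH-adjusted step-1 p), `volcano` and
#'   `details` (full per-mediator outputs).
#' @export
mediator_scan <- function(exposure, mediators, outcome, ld = NULL,
                          config = screen_config()) {
  if (!length(mediators)) stop("mediator_scan: empty mediator list")
  if (inherits(mediators, "sumstat_set")) mediators <- list(mediators)
  ids <- vapply(mediators, `[[`, "", "trait_id")
  details <- stats::setNames(vector("list", length(mediators)), ids)
  rows <- NULL
  for (i in seq_along(mediators)) {
    res <- tryCatch(
      two_step_mediation(exposure, mediators[[i]], outcome, ld,
                         p_threshold = config$p_exposure,
                         step_alpha = config$alpha, f_min = config$f_min,
                         r2_clump = config$r2_clump,
                         window_kb = config$window_kb),
      error = function(e) e)
    details[[i]] <- res
    row <- data.frame(exposure = exposure$trait_id, mediator = ids[i],
                      outcome = outcome$trait_id,
                      beta_total = NA_real_, se_total = NA_real_,
                      p_total = NA_real_,
                      beta1 = NA_real_, se1 = NA_real_, p1 = NA_real_,
                      beta2 = NA_real_, se2 = NA_real_, p2 = NA_real_,
                      proportion_pct = NA_real_, supported = FALSE,
                      failed_step = NA_integer_, error = NA_character_,
                      stringsAsFactors = FALSE)
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
    } else {
      row$beta_total <- res$total$theta
      row$se_total <- res$total$se
      row$p_total <- res$total$pvalue
      row$beta1 <- res$step1$theta
      row$se1 <- res$step1$se
      row$p1 <- res$step1$pvalue
      if (!is.null(res$step2)) {
        row$beta2 <- res$step2$theta
        row$se2 <- res$step2$se
        row$p2 <- res$step2$pvalue
      }
      row$supported <- res$supported
      row$failed_step <- res$failed_step
      if (res$supported) row$proportion_pct <- 100 * res$result$proportion
    }
    rows <- rbind(rows, row)
  }
  rows$p1_bh <- stats::p.adjust(rows$p1, method = "BH")
  volcano <- rows[, c("mediator", "beta1", "p1", "p1_bh")]
  structure(list(report = rows, volcano = volcano, details = details),
            class = "mediator_scan_result")
}

#' Write screen outputs to a directory
#'
#' Emits deterministic TSVs: `verdicts.tsv`, `heatmap.tsv` and one
#' `battery_<exposure>.tsv` per successful exposure, plus a JSON-lines run
#' log (`run_log.jsonl`: stage, counts, seed).
#'
#' @param sr A `screen_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_screen <- function(sr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(sr$verdicts, file.path(dir, "verdicts.tsv"))
  write_tsv(sr$heatmap, file.path(dir, "heatmap.tsv"))
  log_con <- file(file.path(dir, "run_log.jsonl"), "w")
  on.exit(close(log_con))
  for (id in names(sr$results)) {
    res <- sr$results[[id]]
    if (!inherits(res, "error")) {
      write_battery(res$battery,
                    file.path(dir, paste0("battery_", gsub("[^A-Za-z0-9_.-]", "_", id), ".tsv")),
                    exposure = id)
      writeLines(jsonlite::toJSON(list(stage = "battery", exposure = id,
                                       n_instruments = nrow(res$instruments$records),
                                       seed = sr$seed), auto_unbox = TRUE),
                 log_con)
    } else {
      writeLines(jsonlite::toJSON(list(stage = "battery", exposure = id,
                                       error = conditionMessage(res)),
                                  auto_unbox = TRUE), log_con)
    }
  }
  invisible(dir)
}
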