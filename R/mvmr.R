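#' Multivariable inverse-variance weighted regression
#'
#' Regresses variant-outcome effects jointly on two or more exposures'
#' variant effects (no intercept) with weights `1/byse^2`, yielding each
#' exposure's conditional (direct) effect given the others. A conditional
#' instrument-strength F-statistic is reported per exposure, computed from
#' the weighted residual heterogeneity of that exposure's variant effects
#' after regression on the other exposures (`Q_l / (k - L)`, an
#' approximation that ignores the cross-trait sampling covariance, which
#' two-sample summary data do not provide).
#'
#' @param h A `harmonized_set` whose traits are the exposures followed by
#'   the outcome (outcome last), or a list with matrices `bx` (k x L),
#'   `bxse` (k x L) and vectors `by`, `byse`.
#' @return An `mvmr_estimate`: list with `exposure_ids`, `theta`, `se`,
#'   `pvalue` (each length L), `conditional_f`, `n_snps`.
#' @export
mvmr_ivw <- function(h) {
  if (inherits(h, "harmonized_set")) {
    nt <- length(h$trait_ids)
    stopifnot(nt >= 3L)
    bx <- h$beta[, -nt, drop = FALSE]
    bxse <- h$se[, -nt, drop = FALSE]
    by <- h$beta[, nt]
    byse <- h$se[, nt]
    exposure_ids <- h$trait_ids[-nt]
  } else {
    bx <- as.matrix(h$bx); bxse <- as.matrix(h$bxse)
    by <- h$by; byse <- h$byse
    exposure_ids <- colnames(bx)
    if (is.null(exposure_ids)) exposure_ids <- paste0("exposure", seq_len(ncol(bx)))
  }
  k <- nrow(bx); L <- ncol(bx)
  if (k <= L)
    stop("multivariable IVW needs more instruments than exposures (k > L)")
  # an exposure with no genetic signal at these instruments contributes
  # nothing to the regression; drop it from the fit, report NA for it
  active <- colSums(bx != 0) > 0L
  La <- sum(active)
  if (La == 0L) stop("all exposure effect columns are zero")
  w <- 1 / byse^2
  Xw <- bx[, active, drop = FALSE] * sqrt(w)
  yw <- by * sqrt(w)
  qr_x <- qr(Xw)
  if (qr_x$rank < La) {
    bad <- exposure_ids[active][qr_x$pivot[(qr_x$rank + 1):La]]
    stop("collinear exposure effect matrix; offending exposure(s): ",
         paste(bad, collapse = ", "))
  }
  xtx <- crossprod(Xw)
  xtx_inv <- solve(xtx)
  theta_a <- drop(xtx_inv %*% crossprod(Xw, yw))
  resid <- by - drop(bx[, active, drop = FALSE] %*% theta_a)
  q <- sum(w * resid^2)
  phi <- max(1, q / (k - La))
  se_a <- sqrt(diag(xtx_inv) * phi)
  theta <- se <- rep(NA_real_, L)
  theta[active] <- theta_a
  se[active] <- se_a
  pvalue <- 2 * stats::pnorm(-abs(theta / se))
  cond_f <- vapply(seq_len(L), function(l) {
    wl <- 1 / bxse[, l]^2
    if (L == 1L) {
      resl <- bx[, l]
    } else {
      Xo <- bx[, -l, drop = FALSE] * sqrt(wl)
      yl <- bx[, l] * sqrt(wl)
      resl <- stats::lm.fit(Xo, yl)$residuals / sqrt(wl)
    }
    sum(wl * resl^2) / (k - L)
  }, 0)
  names(theta) <- names(se) <- names(pvalue) <- names(cond_f) <- exposure_ids
  structure(list(exposure_ids = exposure_ids, theta = theta, se = se,
                 pvalue = pvalue, conditional_f = cond_f, n_snps = k),
            class = "mvmr_estimate")
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat(sprintf("<mvmr_estimate> %d instruments, %d exposures\n",
              x$n_snps, length(x$exposure_ids)))
  print(data.frame(exposure = x$exposure_ids, theta = x$theta, se = x$se,
                   pvalue = x$pvalue, conditional_f = x$conditional_f,
                   row.names = NULL))
  invisible(x)
}

#' Mediation decomposition of a total causal effect
#'
#' Decomposes a total exposure-outcome effect into the component running
#' through a mediator and the residual direct component:
#' mediated effect = `beta1 * beta2` (exposure-to-mediator times conditional
#' mediator-to-outcome), direct effect = `beta_total - beta1 * beta2`, and
#' proportion mediated = `beta1 * beta2 / beta_total`. The proportion's SE
#' uses the delta method on the product,
#' `var(b1 b2) ~ b1^2 se2^2 + b2^2 se1^2`, propagated through division by
#' the total effect treated as fixed (the product term dominates; the full
#' three-term variance is available via `total_fixed = FALSE`).
#'
#' @param beta_total Total exposure-outcome effect (log-OR scale for a
#'   binary outcome).
#' @param se_total Its SE (used only when `total_fixed = FALSE`).
#' @param beta1,se1 Exposure-mediator effect and SE.
#' @param beta2,se2 Conditional mediator-outcome effect and SE.
#' @param total_fixed Treat `beta_total` as fixed in the proportion CI.
#' @return A `mediation_result`: list with the three input effects, the
#'   mediated and direct effects, `proportion` (with SE and 95% CI) and
#'   `sign_consistent`. When `beta_total` is 0 the proportion is `NA` with
#'   `proportion_defined = FALSE`.
#' @export
#' @examples
#' mediate(beta_total = -0.133, se_total = 0.052,
#'         beta1 = 0.174, se1 = 0.073,
#'         beta2 = -0.018, se2 = 0.008)
mediate <- function(beta_total, se_total = NA_real_, beta1, se1, beta2, se2,
                    total_fixed = TRUE) {
  mediation <- beta1 * beta2
  direct <- beta_total - mediation
  defined <- beta_total != 0
  var_prod <- beta1^2 * se2^2 + beta2^2 * se1^2
  if (defined) {
    proportion <- mediation / beta_total
    if (total_fixed || is.na(se_total)) {
      prop_var <- var_prod / beta_total^2
    } else {
      prop_var <- var_prod / beta_total^2 +
        mediation^2 * se_total^2 / beta_total^4
    }
    prop_se <- sqrt(prop_var)
    ci <- proportion + c(-1, 1) * stats::qnorm(0.975) * prop_se
  } else {
    proportion <- prop_se <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }
  structure(list(beta_total = beta_total, se_total = se_total,
                 beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
                 mediation_effect = mediation, direct_effect = direct,
                 proportion = proportion, proportion_se = prop_se,
                 proportion_ci = ci,
                 proportion_defined = defined,
                 sign_consistent = defined &&
                   sign(mediation) == sign(beta_total)),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> total = %.4g, mediated = %.4g, direct = %.4g\n",
              x$beta_total, x$mediation_effect, x$direct_effect))
  if (x$proportion_defined)
    cat(sprintf("  proportion mediated = %.2f%% (se %.2f%%), sign consistent: %s\n",
                100 * x$proportion, 100 * x$proportion_se, x$sign_consistent))
  else cat("  proportion undefined (total effect is zero)\n")
  invisible(x)
}

#' Two-step mediation analysis from raw summary statistics
#'
#' Runs the full two-step multivariable-MR mediation workflow:
#' step 0 estimates the total exposure-outcome effect by univariable MR on
#' the exposure's instruments; step 1 estimates the exposure-mediator
#' effect (BETA1) the same way and requires p < `step_alpha`; step 2 takes
#' the mediator's conditional effect on the outcome (BETA2) from a
#' multivariable IVW of exposure + mediator on the outcome using the
#' jointly re-clumped union of both traits' instruments, again requiring
#' p < `step_alpha`; the decomposition then follows [mediate()]. A failed
#' step returns a labelled `mediation-not-supported` outcome rather than an
#' error.
#'
#' @param exposure,mediator,outcome [sumstat_set()] objects.
#' @param ld An `ld_matrix` or `NULL`.
#' @param p_threshold Instrument significance threshold for both the
#'   exposure and the mediator.
#' @param step_alpha Nominal significance required at steps 1 and 2.
#' @param f_min,r2_clump,window_kb Instrument-selection parameters, see
#'   [select_instruments()].
#' @param primary_method Estimator for the total and step-1 effects:
#'   `"ivw"` (auto flavour) or `"ivw_fixed"`.
#' @return A list with `supported` (logical), `failed_step` (`NA`, 1 or 2),
#'   `result` (a `mediation_result` when supported), the three estimates
#'   (`total`, `step1`, `step2`), and an `audit` list of instrument counts.
#' @export
two_step_mediation <- function(exposure, mediator, outcome, ld = NULL,
                               p_threshold = 1e-5, step_alpha = 0.05,
                               f_min = 10, r2_clump = 0.001,
                               window_kb = 10000,
                               primary_method = c("ivw", "ivw_fixed")) {
  primary_method <- match.arg(primary_method)
  est_fun <- function(h) {
    if (primary_method == "ivw") mr_ivw(h, model = "auto")
    else mr_ivw(h, model = "fixed")
  }
  iv_x <- select_instruments(exposure, ld, p_threshold = p_threshold,
                             f_min = f_min, r2_clump = r2_clump,
                             window_kb = window_kb)
  sel_x <- instruments_as_sumstats(iv_x, exposure$trait_type)

  h_xy <- harmonize(sel_x, outcome)
  total <- est_fun(h_xy)
  h_xm <- harmonize(sel_x, mediator)
  step1 <- est_fun(h_xm)

  audit <- list(exposure_instruments = nrow(iv_x$records),
                exposure_attrition = iv_x$attrition,
                xy_variants = length(h_xy$snp_ids),
                xm_variants = length(h_xm$snp_ids))

  out <- list(supported = FALSE, failed_step = NA_integer_, result = NULL,
              total = total, step1 = step1, step2 = NULL, audit = audit)
  if (is.na(step1$pvalue) || step1$pvalue >= step_alpha) {
    out$failed_step <- 1L
    return(out)
  }

  # step 2: joint instrument union, re-clumped, then three-trait harmonization
  iv_m <- tryCatch(select_instruments(mediator, ld, p_threshold = p_threshold,
                                      f_min = f_min, r2_clump = r2_clump,
                                      window_kb = window_kb),
                   error = function(e) NULL)
  union_ids <- unique(c(iv_x$records$snp_id,
                        if (!is.null(iv_m)) iv_m$records$snp_id))
  pool <- exposure$records[exposure$records$snp_id %in% union_ids, ,
                           drop = FALSE]
  pool_set <- sumstat_set(exposure$trait_id, pool, exposure$trait_type)
  pool_clumped <- clump(pool_set, ld, r2_threshold = r2_clump,
                        window_kb = window_kb)
  h3 <- harmonize(pool_clumped, list(mediator, outcome))
  audit$mvmr_variants <- length(h3$snp_ids)
  out$audit <- audit

  mv_in <- list(bx = cbind(exposure = h3$beta[, 1], mediator = h3$beta[, 2]),
                bxse = cbind(h3$se[, 1], h3$se[, 2]),
                by = h3$beta[, 3], byse = h3$se[, 3])
  mv <- mvmr_ivw(mv_in)
  step2 <- list(theta = unname(mv$theta["mediator"]),
                se = unname(mv$se["mediator"]),
                pvalue = unname(mv$pvalue["mediator"]),
                mvmr = mv)
  out$step2 <- step2
  if (is.na(step2$pvalue) || step2$pvalue >= step_alpha) {
    out$failed_step <- 2L
    return(out)
  }

  out$supported <- TRUE
  out$result <- mediate(beta_total = total$theta, se_total = total$se,
                        beta1 = step1$theta, se1 = step1$se,
                        beta2 = step2$theta, se2 = step2$se)
  out
}

#' Write a mediation report row as TSV
#'
#' Columns mirror the canonical mediation table: exposure, mediator,
#' outcome, (beta, se, p) for the total, step-1 and step-2 effects, and the
#' proportion mediated in percent.
#'
#' @param rows A data frame assembled from `two_step_mediation` outputs
#'   (see [mediator_scan()]).
#' @param path Output path.
#' @export
write_mediation_report <- function(rows, path) {
  write_tsv(rows, path)
}
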