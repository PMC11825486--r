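#' Assemble a two-trait MR input
#'
#' Most estimators accept either a `harmonized_set` (first trait = exposure,
#' second = outcome) or a plain data frame of per-variant effects built with
#' this constructor.
#'
#' @param bx,bxse Variant-exposure effects and standard errors.
#' @param by,byse Variant-outcome effects and standard errors.
#' @param snp_id Optional variant identifiers.
#' @return A data frame of class `mr_pair`.
#' @export
mr_input <- function(bx, bxse, by, byse, snp_id = NULL) {
  k <- length(bx)
  bxse <- rep_len(bxse, k)
  byse <- rep_len(byse, k)
  stopifnot(length(by) == k, all(bxse >= 0), all(byse > 0))
  if (is.null(snp_id)) snp_id <- sprintf("snp%03d", seq_len(k))
  structure(data.frame(snp_id = snp_id, bx = bx, bxse = bxse,
                       by = by, byse = byse, stringsAsFactors = FALSE),
            class = c("mr_pair", "data.frame"))
}

# Coerce harmonized_set / mr_pair / data.frame to the canonical pair frame.
as_mr_pair <- function(x, exposure = 1L, outcome = 2L) {
  if (inherits(x, "harmonized_set")) {
    stopifnot(length(x$trait_ids) >= 2L)
    return(mr_input(bx = x$beta[, exposure], bxse = x$se[, exposure],
                    by = x$beta[, outcome], byse = x$se[, outcome],
                    snp_id = x$snp_ids))
  }
  stopifnot(is.data.frame(x),
            all(c("bx", "bxse", "by", "byse") %in% names(x)))
  if (is.null(x$snp_id)) x$snp_id <- sprintf("snp%03d", seq_len(nrow(x)))
  x
}

# Single MR estimate container; CI from normal quantiles unless df given.
mr_estimate <- function(method, theta, se, n_snps, diagnostics = list(),
                        df = Inf) {
  q <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  pvalue <- if (is.na(se) || se == 0) {
    if (!is.na(theta) && theta == 0) 1 else NA_real_
  } else if (is.finite(df)) {
    2 * stats::pt(-abs(theta / se), df)
  } else 2 * stats::pnorm(-abs(theta / se))
  structure(list(method = method, theta = theta, se = se,
                 ci_low = theta - q * se, ci_high = theta + q * se,
                 pvalue = pvalue, n_snps = n_snps,
                 diagnostics = diagnostics),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: theta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g, k = %d\n",
              x$method, x$theta, x$se, x$ci_low, x$ci_high, x$pvalue, x$n_snps))
  if (length(x$diagnostics)) {
    d <- x$diagnostics[vapply(x$diagnostics, is.numeric, TRUE)]
    d <- d[vapply(d, length, 0L) == 1L]
    if (length(d))
      cat("  ", paste(sprintf("%s=%.4g", names(d), unlist(d)), collapse = ", "),
          "\n", sep = "")
  }
  invisible(x)
}

insufficient_instruments <- function(method, need, have) {
  stop(structure(class = c("insufficient_instruments_error", "error", "condition"),
                 list(message = sprintf("%s requires >= %d variants, got %d",
                                        method, need, have),
                      call = sys.call(-1))))
}

# Closed-form zero-intercept weighted regression of by on bx, weights w.
ivw_closed <- function(bx, by, w) {
  sxx <- sum(w * bx^2)
  theta <- sum(w * bx * by) / sxx
  list(theta = theta, se_fixed = sqrt(1 / sxx),
       q = sum(w * (by - theta * bx)^2))
}

# Penalization weight multipliers: min(1, 20 * upper-tail chi^2_1 prob of the
# per-variant heterogeneity contribution at the candidate fit.
penalty_multipliers <- function(resid, w) {
  qj <- w * resid^2
  pmin(1, 20 * stats::pchisq(qj, df = 1, lower.tail = FALSE))
}

# MM-type robust weighted regression via MASS::rlm (Tukey bisquare,
# c = 4.685, S-estimate start). Falls back to the closed-form fit when the
# data are numerically exact (zero residual scale breaks the M scale step).
robust_wls <- function(x, y, w, intercept = FALSE) {
  X <- if (intercept) cbind(`(Intercept)` = 1, x = x) else cbind(x = x)
  ls <- stats::lm.wfit(X, y, w)
  resid_scale <- sqrt(sum(w * ls$residuals^2) / max(1, length(y) - ncol(X)))
  typical <- sqrt(stats::median(w)) * max(abs(y), 1e-12)
  if (resid_scale < 1e-10 * max(typical, 1)) {
    cf <- ls$coefficients
    cov_unscaled <- solve(crossprod(X * sqrt(w)))
    return(list(coefficients = cf, se = sqrt(diag(cov_unscaled)),
                sigma = 0, exact = TRUE))
  }
  fit <- suppressWarnings(
    MASS::rlm(X, y, weights = w, wt.method = "inv.var", method = "MM",
              maxit = 200)
  )
  sm <- summary(fit, method = "XtX")
  ses <- stats::setNames(sm$coefficients[, 2], rownames(sm$coefficients))
  list(coefficients = stats::coef(fit), se = ses,
       sigma = fit$s, exact = FALSE)
}

#' Per-variant Wald ratio estimate
#'
#' The outcome effect divided by the exposure effect, with the first-order
#' delta-method standard error `|by_se / bx|` (exposure uncertainty ignored).
#'
#' @param bx,bxse Variant-exposure effect and SE.
#' @param by,byse Variant-outcome effect and SE.
#' @return An `mr_estimate` with method `"wald_ratio"`.
#' @export
wald_ratio <- function(bx, bxse, by, byse) {
  if (bx == 0) stop("wald ratio undefined for bx = 0")
  mr_estimate("wald_ratio", theta = by / bx, se = abs(byse / bx), n_snps = 1L)
}

#' Inverse-variance weighted estimator
#'
#' Weighted regression of variant-outcome effects on variant-exposure
#' effects through the origin with weights `1/byse^2`. The fixed-effect
#' model uses the analytic weighted-mean SE; the (multiplicative) random
#' effect model inflates it by `max(1, sqrt(Q/(k-1)))`; `model = "auto"`
#' reports the random-effects SE when Q exceeds its degrees of freedom and
#' the fixed-effect SE otherwise. `robust = TRUE` swaps ordinary weighted
#' least squares for MM-type robust regression (Tukey bisquare, c = 4.685,
#' S-estimate start); `penalized = TRUE` first down-weights heterogeneous
#' variants by `min(1, 20 p_j)` with `p_j` the upper-tail chi-square(1)
#' probability of the variant's heterogeneity contribution, then refits;
#' both flags compose (penalize, then robust fit). Cochran's Q and its
#' p-value are always reported in `diagnostics`.
#'
#' @param x A `harmonized_set` (exposure, outcome) or [mr_input()] frame.
#' @param model `"fixed"`, `"random"`, or `"auto"`.
#' @param robust,penalized Logical flags, see Details.
#' @return An `mr_estimate`.
#' @export
mr_ivw <- function(x, model = c("auto", "fixed", "random"),
                   robust = FALSE, penalized = FALSE) {
  model <- match.arg(model)
  d <- as_mr_pair(x)
  k <- nrow(d)
  min_k <- if (robust || penalized) 2L else if (model == "fixed") 1L else 2L
  if (k < min_k) insufficient_instruments("mr_ivw", min_k, k)
  w <- 1 / d$byse^2
  base <- ivw_closed(d$bx, d$by, w)
  q <- base$q
  q_p <- if (k > 1) stats::pchisq(q, df = k - 1, lower.tail = FALSE) else NA_real_
  pen <- rep(1, k)
  if (penalized) {
    pen <- penalty_multipliers(d$by - base$theta * d$bx, w)
    w_used <- w * pen
  } else w_used <- w
  label <- paste0("ivw",
                  if (penalized) "_penalized" else "",
                  if (robust) "_robust" else "",
                  if (!robust && !penalized && model != "auto")
                    paste0("_", model) else "")
  if (robust) {
    fit <- robust_wls(d$bx, d$by, w_used, intercept = FALSE)
    theta <- unname(fit$coefficients["x"])
    se <- unname(fit$se["x"])
    if (!fit$exact) se <- se * max(1, fit$sigma) / max(fit$sigma, .Machine$double.eps)
  } else {
    refit <- ivw_closed(d$bx, d$by, w_used)
    theta <- refit$theta
    se <- refit$se_fixed
    use_random <- switch(model, fixed = FALSE, random = TRUE,
                         auto = k > 1 && q > k - 1)
    if (use_random && k > 1) se <- se * max(1, sqrt(refit$q / (k - 1)))
  }
  mr_estimate(label, theta, se, k,
              diagnostics = list(cochran_q = q, q_pvalue = q_p,
                                 model = model,
                                 penalty_weights = if (penalized) pen else NULL))
}

#' MR-Egger regression
#'
#' Weighted regression of variant-outcome on variant-exposure effects
#' *with* an intercept (weights `1/byse^2`), after orienting every variant
#' to a non-negative exposure effect. The slope is the causal estimate; the
#' intercept estimates the mean directional-pleiotropy effect, and its
#' two-sided p-value (t distribution, k - 2 df) is the pleiotropy test:
#' p > 0.05 is read as no significant directional pleiotropy. Robust and
#' penalized variants as in [mr_ivw()].
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate` with `egger_intercept`, `egger_intercept_se` and
#'   `egger_intercept_p` in `diagnostics`.
#' @export
mr_egger <- function(x, robust = FALSE, penalized = FALSE) {
  d <- as_mr_pair(x)
  k <- nrow(d)
  if (k < 3L) insufficient_instruments("mr_egger", 3L, k)
  flip <- d$bx < 0
  d$bx[flip] <- -d$bx[flip]
  d$by[flip] <- -d$by[flip]
  w <- 1 / d$byse^2
  X <- cbind(1, d$bx)
  base <- stats::lm.wfit(X, d$by, w)
  resid0 <- base$residuals
  q <- sum(w * resid0^2)
  q_p <- stats::pchisq(q, df = k - 2, lower.tail = FALSE)
  pen <- rep(1, k)
  if (penalized) {
    pen <- penalty_multipliers(resid0, w)
    w_used <- w * pen
  } else w_used <- w
  if (robust) {
    fit <- robust_wls(d$bx, d$by, w_used, intercept = TRUE)
    coefs <- fit$coefficients
    ses <- fit$se
    if (!fit$exact)
      ses <- ses * max(1, fit$sigma) / max(fit$sigma, .Machine$double.eps)
  } else {
    refit <- stats::lm.wfit(X, d$by, w_used)
    coefs <- refit$coefficients
    rq <- sum(w_used * refit$residuals^2)
    phi <- max(1, rq / (k - 2))
    cov_unscaled <- solve(crossprod(X * sqrt(w_used)))
    ses <- sqrt(diag(cov_unscaled) * phi)
  }
  intercept <- unname(coefs[1]); slope <- unname(coefs[2])
  int_se <- unname(ses[1]); slope_se <- unname(ses[2])
  int_p <- 2 * stats::pt(-abs(intercept / int_se), df = k - 2)
  label <- paste0("egger",
                  if (penalized) "_penalized" else "",
                  if (robust) "_robust" else "")
  mr_estimate(label, slope, slope_se, k, df = k - 2,
              diagnostics = list(egger_intercept = intercept,
                                 egger_intercept_se = int_se,
                                 egger_intercept_p = int_p,
                                 cochran_q = q, q_pvalue = q_p,
                                 penalty_weights = if (penalized) pen else NULL))
}

# Profile log-likelihood for the bivariate-normal measurement model with
# per-variant nuisance means profiled out.
maxlik_profile <- function(theta, bx, bxse, by, byse) {
  -0.5 * sum((by - theta * bx)^2 / (byse^2 + theta^2 * bxse^2))
}

#' Maximum-likelihood estimator
#'
#' Maximizes the joint likelihood of the observed variant-exposure and
#' variant-outcome effects, `bx_j ~ N(xi_j, bxse_j^2)` and
#' `by_j ~ N(theta xi_j, byse_j^2)`, over the causal effect `theta` and the
#' per-variant nuisance means `xi_j` (profiled in closed form, leaving a
#' one-dimensional numerical optimization). The SE comes from the observed
#' information of the profile likelihood.
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate`.
#' @export
mr_maxlik <- function(x) {
  d <- as_mr_pair(x)
  k <- nrow(d)
  if (k < 1L) insufficient_instruments("mr_maxlik", 1L, k)
  start <- ivw_closed(d$bx, d$by, 1 / d$byse^2)$theta
  width <- max(1, 10 * abs(start), 10 * max(abs(d$by / ifelse(d$bx == 0, NA, d$bx)),
                                            na.rm = TRUE))
  opt <- stats::optimize(function(t) -maxlik_profile(t, d$bx, d$bxse, d$by, d$byse),
                         interval = c(start - width, start + width),
                         tol = 1e-10)
  theta <- opt$minimum
  h <- 1e-5 * (1 + abs(theta))
  ll <- function(t) maxlik_profile(t, d$bx, d$bxse, d$by, d$byse)
  info <- -(ll(theta + h) - 2 * ll(theta) + ll(theta - h)) / h^2
  se <- if (info > 0) sqrt(1 / info) else NA_real_
  mr_estimate("maximum_likelihood", theta, se, k,
              diagnostics = list(loglik = ll(theta)))
}

#' Debiased inverse-variance weighted estimator
#'
#' Corrects the IVW denominator for measurement error in the
#' variant-exposure effects, making the estimator consistent under many
#' weak instruments without pre-screening:
#' `theta = sum(bx by / byse^2) / sum((bx^2 - bxse^2) / byse^2)`.
#' The SE is a method-of-moments sandwich evaluated at the estimate.
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate`.
#' @export
mr_divw <- function(x) {
  d <- as_mr_pair(x)
  k <- nrow(d)
  if (k < 2L) insufficient_instruments("mr_divw", 2L, k)
  w <- 1 / d$byse^2
  denom <- sum((d$bx^2 - d$bxse^2) * w)
  if (denom <= 0)
    stop("debiased IVW denominator non-positive: instruments too weak")
  theta <- sum(d$bx * d$by * w) / denom
  psi <- (d$bx * d$by - theta * (d$bx^2 - d$bxse^2)) * w
  se <- sqrt(sum(psi^2)) / denom
  mr_estimate("debiased_ivw", theta, se, k,
              diagnostics = list(denominator = denom))
}

#' Contamination-mixture estimator
#'
#' Models each variant's ratio estimate as coming from either a valid
#' component centered on the causal effect or an invalid component centered
#' on zero with inflated variance `se_j^2 + psi^2`. A profile log-likelihood
#' over a grid of candidate effects takes, per variant, the better of the
#' two components; the estimate is the grid argmax and the 95% interval is
#' the set of grid values within `qchisq(0.95, 1)/2` of the maximum
#' (reported as its hull, with a multimodality flag when the set is not
#' contiguous).
#'
#' @inheritParams mr_ivw
#' @param psi Invalid-component SD; `"auto"` sets 1.5 x the SD of the ratio
#'   estimates.
#' @param grid_points Number of grid points spanning mean(ratios) +/- 6
#'   SD(ratios).
#' @return An `mr_estimate` with `psi`, `valid_set_size`, `multimodal` and
#'   `degenerate` in `diagnostics`.
#' @export
mr_conmix <- function(x, psi = "auto", grid_points = 2001) {
  d <- as_mr_pair(x)
  k <- nrow(d)
  if (k < 2L) insufficient_instruments("mr_conmix", 2L, k)
  if (any(d$bx == 0)) stop("contamination mixture requires nonzero bx")
  ratio <- d$by / d$bx
  rse <- d$byse / abs(d$bx)
  sd_r <- stats::sd(ratio)
  if (sd_r < 1e-12) {
    theta <- ratio[1]
    se <- sqrt(1 / sum(1 / rse^2))
    return(mr_estimate("contamination_mixture", theta, se, k,
                       diagnostics = list(psi = 0, valid_set_size = k,
                                          multimodal = FALSE,
                                          degenerate = TRUE)))
  }
  if (identical(psi, "auto")) psi <- 1.5 * sd_r
  grid <- seq(mean(ratio) - 6 * sd_r, mean(ratio) + 6 * sd_r,
              length.out = grid_points)
  ll_valid <- outer(ratio, grid, function(r, t)
    stats::dnorm(r, mean = t, sd = rse, log = TRUE))
  ll_invalid <- stats::dnorm(ratio, mean = 0, sd = sqrt(rse^2 + psi^2),
                             log = TRUE)
  prof <- colSums(pmax(ll_valid, ll_invalid))
  imax <- which.max(prof)
  theta <- grid[imax]
  inset <- prof >= prof[imax] - stats::qchisq(0.95, 1) / 2
  ci <- range(grid[inset])
  runs <- rle(inset)
  multimodal <- sum(runs$values) > 1
  valid <- ll_valid[, imax] >= ll_invalid
  se <- (ci[2] - ci[1]) / (2 * stats::qnorm(0.975))
  est <- mr_estimate("contamination_mixture", theta, se, k,
                     diagnostics = list(psi = psi, valid_set_size = sum(valid),
                                        multimodal = multimodal,
                                        degenerate = FALSE,
                                        valid = valid))
  est$ci_low <- ci[1]; est$ci_high <- ci[2]
  est
}

#' MR-Lasso estimator
#'
#' Fits `by_j = theta bx_j + alpha_j` with an L1 penalty on the per-variant
#' direct effects `alpha_j` on inverse-variance weighted data. The tuning
#' parameter follows the heterogeneity stopping rule: along a decreasing
#' penalty path, the chosen lambda is the largest one whose selected valid
#' subset (`alpha_j = 0`) has Cochran Q not exceeding its chi-square 95th
#' percentile. Variants penalized out are reported invalid; the estimate is
#' the post-selection fixed-effect IVW on the valid subset.
#'
#' @inheritParams mr_ivw
#' @param n_lambda Length of the penalty path.
#' @return An `mr_estimate` with `valid_set_size`, `invalid_snps` and
#'   `lambda` in `diagnostics`.
#' @export
mr_lasso <- function(x, n_lambda = 100) {
  d <- as_mr_pair(x)
  k <- nrow(d)
  if (k < 3L) insufficient_instruments("mr_lasso", 3L, k)
  w <- 1 / d$byse^2
  fit_at_lambda <- function(lambda) {
    theta <- ivw_closed(d$bx, d$by, w)$theta
    alpha <- rep(0, k)
    for (it in 1:200) {
      r <- d$by - theta * d$bx
      thr <- lambda * d$byse^2 / 2
      alpha_new <- sign(r) * pmax(0, abs(r) - thr)
      theta_new <- sum(w * d$bx * (d$by - alpha_new)) / sum(w * d$bx^2)
      delta <- max(abs(alpha_new - alpha), abs(theta_new - theta))
      alpha <- alpha_new; theta <- theta_new
      if (delta < 1e-10) break
    }
    list(theta = theta, alpha = alpha, valid = alpha == 0)
  }
  base_theta <- ivw_closed(d$bx, d$by, w)$theta
  r0 <- d$by - base_theta * d$bx
  lambda_max <- max(max(2 * abs(r0) / d$byse^2) * 1.001, 1e-10)
  lambdas <- exp(seq(log(lambda_max), log(lambda_max / 1000),
                     length.out = n_lambda))
  chosen <- NULL
  for (lam in lambdas) {
    f <- fit_at_lambda(lam)
    m <- sum(f$valid)
    if (m < 2L) next
    sub <- ivw_closed(d$bx[f$valid], d$by[f$valid], w[f$valid])
    crit <- stats::qchisq(0.95, df = m - 1)
    if (sub$q <= crit) {
      chosen <- list(lambda = lam, fit = f, sub = sub, m = m)
      break
    }
  }
  if (is.null(chosen))
    stop("mr_lasso: no penalty level yields a homogeneous valid subset")
  if (chosen$m == 0L) stop("mr_lasso: all variants selected invalid")
  v <- chosen$fit$valid
  mr_estimate("mr_lasso", chosen$sub$theta, chosen$sub$se_fixed, k,
              diagnostics = list(valid_set_size = chosen$m,
                                 invalid_snps = d$snp_id[!v],
                                 lambda = chosen$lambda,
                                 cochran_q = chosen$sub$q))
}
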