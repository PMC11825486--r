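# Constrained-ML fit for a fixed number K of invalid instruments: alternating
# minimization of
#   sum_j (bx_j - mu_j)^2/bxse_j^2 + (by_j - theta mu_j - r_j)^2/byse_j^2
# where exactly K variants get a free direct effect r_j (those with the
# largest profiled residual contribution at each step).
cml_fit_k <- function(bx, bxse, by, byse, K, maxit = 200, tol = 1e-10) {
  k <- length(bx)
  bxse <- pmax(bxse, 1e-8)  # exact-exposure limit: avoid 0/0 in mu update
  theta <- ivw_closed(bx, by, 1 / byse^2)$theta
  invalid <- rep(FALSE, k)
  obj_prev <- Inf
  for (it in seq_len(maxit)) {
    contrib <- (by - theta * bx)^2 / (byse^2 + theta^2 * bxse^2)
    invalid_new <- rep(FALSE, k)
    if (K > 0) invalid_new[order(contrib, decreasing = TRUE)[seq_len(K)]] <- TRUE
    v <- !invalid_new
    mu <- (bx / bxse^2 + theta * by / byse^2) / (1 / bxse^2 + theta^2 / byse^2)
    mu[invalid_new] <- bx[invalid_new]
    denom <- sum(mu[v]^2 / byse[v]^2)
    theta_new <- if (denom > 0) sum(mu[v] * by[v] / byse[v]^2) / denom else theta
    obj <- sum(contrib[v])
    done <- abs(theta_new - theta) < tol &&
      (identical(invalid_new, invalid) || abs(obj - obj_prev) < tol)
    theta <- theta_new
    invalid <- invalid_new
    obj_prev <- obj
    if (done) break
  }
  if (it == maxit)
    stop(structure(class = c("convergence_error", "error", "condition"),
                   list(message = sprintf(
                          "cML inner loop did not converge for K = %d (%d iterations)",
                          K, maxit),
                        call = sys.call(-1))))
  v <- !invalid
  nll <- 0.5 * sum((by[v] - theta * bx[v])^2 / (byse[v]^2 + theta^2 * bxse[v]^2))
  g <- function(t) 0.5 * sum((by[v] - t * bx[v])^2 / (byse[v]^2 + t^2 * bxse[v]^2))
  h <- 1e-5 * (1 + abs(theta))
  info <- (g(theta + h) - 2 * g(theta) + g(theta - h)) / h^2
  se <- if (info > 0) sqrt(1 / info) else NA_real_
  list(theta = theta, se = se, nll = nll, invalid = invalid)
}

cml_point <- function(bx, bxse, by, byse, variant, n_eff) {
  k <- length(bx)
  Ks <- 0:(k - 2)
  fits <- lapply(Ks, function(K) cml_fit_k(bx, bxse, by, byse, K))
  bic <- vapply(seq_along(Ks), function(i)
    2 * fits[[i]]$nll + log(n_eff) * Ks[i], 0)
  best <- which.min(bic)
  if (variant == "BIC") {
    f <- fits[[best]]
    list(theta = f$theta, se = f$se, selected_k = Ks[best],
         invalid = f$invalid, bic = bic)
  } else {
    wts <- exp(-(bic - min(bic)) / 2)
    wts <- wts / sum(wts)
    thetas <- vapply(fits, `[[`, 0, "theta")
    ses <- vapply(fits, `[[`, 0, "se")
    theta <- sum(wts * thetas)
    se <- sqrt(sum(wts * (ses^2 + (thetas - theta)^2)))
    list(theta = theta, se = se, selected_k = Ks[best],
         invalid = fits[[best]]$invalid, bic = bic)
  }
}

#' Constrained maximum-likelihood estimator (cML)
#'
#' For each candidate count K of invalid instruments (0 to k - 2), fits a
#' constrained ML model in which exactly K variants receive a free direct
#' effect on the outcome (selected each iteration as the largest profiled
#' residual contributors), and scores models by
#' `BIC(K) = 2 nll + log(n_eff) K` with `n_eff` the smallest GWAS sample
#' size across traits. `variant = "BIC"` reports the argmin-K model;
#' `"MA-BIC"` model-averages the causal estimate across K with BIC weights.
#' Data perturbation (`dp_reps > 0`) reruns the procedure on data resampled
#' as `beta + se * z` with standard-normal `z` and uses the spread of the
#' perturbed estimates for the SE (floored at the unperturbed analytic SE);
#' the point estimate is always the unperturbed one.
#'
#' @inheritParams mr_ivw
#' @param variant `"MA-BIC"` (default) or `"BIC"`.
#' @param dp_reps Number of data perturbations; 0 disables.
#' @param seed Seed for the perturbations.
#' @param n_eff Effective sample size for the BIC penalty; when `x` is a
#'   `harmonized_set` it defaults to the minimum per-variant sample size
#'   across traits.
#' @return An `mr_estimate` with `selected_k`, `invalid_snps` and `dp_reps`
#'   in `diagnostics`.
#' @export
mr_cml <- function(x, variant = c("MA-BIC", "BIC"), dp_reps = 200,
                   seed = 1L, n_eff = NULL) {
  variant <- match.arg(variant)
  d <- as_mr_pair(x)
  k <- nrow(d)
  if (k < 2L) insufficient_instruments("mr_cml", 2L, k)
  if (is.null(n_eff)) {
    n_eff <- if (inherits(x, "harmonized_set")) min(x$n, na.rm = TRUE) else 1e5
    if (!is.finite(n_eff)) n_eff <- 1e5
  }
  pt <- cml_point(d$bx, d$bxse, d$by, d$byse, variant, n_eff)
  se <- pt$se
  if (dp_reps > 0) {
    thetas <- with_seed(seed, {
      vapply(seq_len(dp_reps), function(r) {
        bx_p <- d$bx + d$bxse * stats::rnorm(k)
        by_p <- d$by + d$byse * stats::rnorm(k)
        tryCatch(cml_point(bx_p, d$bxse, by_p, d$byse, variant, n_eff)$theta,
                 error = function(e) NA_real_)
      }, 0)
    })
    thetas <- thetas[is.finite(thetas)]
    if (length(thetas) >= 2)
      se <- max(pt$se, stats::sd(thetas), na.rm = TRUE)
  }
  label <- paste0("cml_", tolower(gsub("-", "_", variant)),
                  if (dp_reps > 0) "_dp" else "")
  mr_estimate(label, pt$theta, se, k,
              diagnostics = list(selected_k = pt$selected_k,
                                 invalid_snps = d$snp_id[pt$invalid],
                                 dp_reps = dp_reps))
}
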