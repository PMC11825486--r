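test_that("wald ratio divides effects and propagates the outcome SE", {
  e <- wald_ratio(0.1, 0, 0.01, 0.01)
  expect_equal(e$theta, 0.1)
  expect_equal(e$se, 0.1)
  expect_equal(wald_ratio(0.3, 0, 0, 0.01)$theta, 0)
  e2 <- wald_ratio(0.2, 0, 0.02, 0.01)
  expect_equal(e2$theta, 0.1)
  expect_equal(e2$se, 0.05)
  expect_error(wald_ratio(0, 0, 0.1, 0.01), "bx = 0")
})

test_that("IVW matches the closed-form weighted regression oracle", {
  d <- mr_input(bx = c(0.1, 0.2), bxse = 0, by = c(0.01, 0.02),
                byse = c(0.01, 0.01))
  e <- mr_ivw(d, model = "fixed")
  oracle <- sum(d$bx * d$by / d$byse^2) / sum(d$bx^2 / d$byse^2)
  expect_equal(e$theta, oracle, tolerance = 1e-12)
  expect_equal(e$theta, 0.1, tolerance = 1e-12)
  expect_equal(e$se, sqrt(1 / sum(d$bx^2 / d$byse^2)), tolerance = 1e-12)
  expect_equal(e$diagnostics$cochran_q, 0, tolerance = 1e-20)
})

test_that("all IVW flag combinations return the common ratio on homogeneous data", {
  d <- homogeneous_pair(k = 8, ratio = 0.1)
  for (rb in c(FALSE, TRUE)) for (pn in c(FALSE, TRUE)) {
    e <- mr_ivw(d, robust = rb, penalized = pn)
    expect_equal(e$theta, 0.1, tolerance = 1e-8,
                 label = sprintf("robust=%s penalized=%s", rb, pn))
  }
  expect_equal(mr_ivw(d, model = "random")$theta, 0.1, tolerance = 1e-10)
})

test_that("penalized IVW pulls a planted outlier's influence toward the consensus", {
  d <- outlier_pair(k_good = 10, good_ratio = 0.1, bad_ratio = 2)
  fixed <- mr_ivw(d, model = "fixed")
  pen <- mr_ivw(d, penalized = TRUE)
  expect_lt(abs(pen$theta - 0.1), abs(fixed$theta - 0.1))
  rob <- mr_ivw(d, robust = TRUE)
  expect_lt(abs(rob$theta - 0.1), abs(fixed$theta - 0.1))
  # robust fits report a usable uncertainty, not a placeholder
  expect_true(is.finite(rob$se) && rob$se > 0)
  expect_true(is.finite(rob$pvalue))
  rob_e <- mr_egger(d, robust = TRUE)
  expect_true(is.finite(rob_e$se) && rob_e$se > 0)
})

test_that("Egger solves the two-parameter weighted normal equations", {
  # exact linear data with pleiotropic intercept
  bx <- c(0.1, 0.15, 0.2, 0.3, 0.4)
  by <- 0.05 + 0.1 * bx
  d <- mr_input(bx = bx, bxse = 0, by = by, byse = rep(0.01, 5))
  e <- mr_egger(d)
  expect_equal(e$diagnostics$egger_intercept, 0.05, tolerance = 1e-10)
  expect_equal(e$theta, 0.1, tolerance = 1e-10)

  d0 <- mr_input(bx = bx, bxse = 0, by = 0.1 * bx, byse = rep(0.01, 5))
  e0 <- mr_egger(d0)
  expect_equal(e0$diagnostics$egger_intercept, 0, tolerance = 1e-12)
  expect_equal(e0$theta, 0.1, tolerance = 1e-12)

  # random fixture vs an independent normal-equations solve
  set.seed(31)
  bx <- runif(6, 0.1, 0.5)
  by <- 0.02 + 0.3 * bx + rnorm(6, sd = 0.01)
  byse <- runif(6, 0.005, 0.02)
  d2 <- mr_input(bx = bx, bxse = 0, by = by, byse = byse)
  e2 <- mr_egger(d2)
  W <- diag(1 / byse^2)
  X <- cbind(1, bx)
  coef_oracle <- solve(t(X) %*% W %*% X, t(X) %*% W %*% by)
  expect_equal(e2$diagnostics$egger_intercept, coef_oracle[1], tolerance = 1e-10)
  expect_equal(e2$theta, coef_oracle[2], tolerance = 1e-10)
})

test_that("Egger orients exposure effects to be non-negative before fitting", {
  set.seed(5)
  bx <- runif(6, 0.1, 0.5)
  by <- 0.01 + 0.2 * bx + rnorm(6, sd = 0.005)
  d <- mr_input(bx = bx, bxse = 0, by = by, byse = rep(0.01, 6))
  # negating some rows (both bx and by) must not change the fit
  d_neg <- d
  idx <- c(2, 5)
  d_neg$bx[idx] <- -d_neg$bx[idx]
  d_neg$by[idx] <- -d_neg$by[idx]
  expect_equal(mr_egger(d_neg)$theta, mr_egger(d)$theta, tolerance = 1e-12)
  expect_error(mr_egger(d[1:2, ]), "3")
})

test_that("maximum likelihood agrees with a grid-search oracle and its limits", {
  set.seed(41)
  bx <- runif(5, 0.1, 0.4)
  bxse <- rep(0.02, 5)
  by <- 0.25 * bx + rnorm(5, sd = 0.01)
  byse <- rep(0.01, 5)
  d <- mr_input(bx, bxse, by, byse)
  e <- mr_maxlik(d)
  grid <- seq(0, 0.6, length.out = 60001)
  ll <- vapply(grid, function(t)
    -0.5 * sum((by - t * bx)^2 / (byse^2 + t^2 * bxse^2)), 0)
  expect_equal(e$theta, grid[which.max(ll)], tolerance = 1e-4)

  # bxse -> 0 reduces to fixed-effect IVW
  d0 <- mr_input(bx, rep(0, 5), by, byse)
  expect_equal(mr_maxlik(d0)$theta, mr_ivw(d0, model = "fixed")$theta,
               tolerance = 1e-6)

  # single variant reduces to the Wald ratio
  d1 <- mr_input(0.2, 0.02, 0.04, 0.01)
  expect_equal(mr_maxlik(d1)$theta, 0.2, tolerance = 1e-6)
})

test_that("debiased IVW matches hand arithmetic and the no-error limit", {
  d <- mr_input(bx = c(0.1, 0.1), bxse = c(0.05, 0.05),
                by = c(0.01, 0.01), byse = c(0.01, 0.01))
  # (2 * 0.1 * 0.01 / 1e-4) / (2 * (0.01 - 0.0025) / 1e-4) = 20/150
  expect_equal(mr_divw(d)$theta, 0.002 / 0.015, tolerance = 1e-12)

  set.seed(3)
  bx <- runif(6, 0.1, 0.4); by <- 0.2 * bx + rnorm(6, sd = 0.01)
  d0 <- mr_input(bx, rep(0, 6), by, rep(0.01, 6))
  expect_equal(mr_divw(d0)$theta, mr_ivw(d0, model = "fixed")$theta,
               tolerance = 1e-12)

  weak <- mr_input(bx = c(0.01, 0.01), bxse = c(0.5, 0.5),
                   by = c(0.001, 0.001), byse = c(0.01, 0.01))
  expect_error(mr_divw(weak), "weak")
})

test_that("debiased IVW is less biased than IVW under many weak instruments", {
  # 200 variants with low mean F, 200 replicates, known theta = 0.2
  theta_true <- 0.2
  k <- 200
  est <- t(vapply(1:200, function(s) {
    set.seed(s)
    gamma <- rnorm(k, 0, 0.03)
    bxse <- rep(0.02, k)
    byse <- rep(0.02, k)
    bx <- gamma + rnorm(k, sd = bxse)
    by <- theta_true * gamma + rnorm(k, sd = byse)
    d <- mr_input(bx, bxse, by, byse)
    c(ivw = mr_ivw(d, model = "fixed")$theta, divw = mr_divw(d)$theta)
  }, c(ivw = 0, divw = 0)))
  expect_lt(abs(mean(est[, "divw"]) - theta_true),
            abs(mean(est[, "ivw"]) - theta_true))
})

test_that("contamination mixture identifies the majority-valid set", {
  d <- homogeneous_pair(k = 5, ratio = 0.1)
  e <- mr_conmix(d)
  expect_equal(e$theta, 0.1, tolerance = 1e-10)
  expect_true(e$diagnostics$degenerate)
  expect_equal(e$diagnostics$valid_set_size, 5L)

  bx <- rep(0.2, 10)
  by <- c(rep(0.02, 8), rep(0.2, 2))
  d2 <- mr_input(bx, 0, by, rep(0.002, 10))
  e2 <- mr_conmix(d2)
  expect_equal(e2$theta, 0.1, tolerance = 0.01)
  expect_equal(sum(e2$diagnostics$valid), 8L)
  expect_equal(unname(which(!e2$diagnostics$valid)), c(9L, 10L))

  # refinement oracle: 10x finer grid argmax within one coarse step
  set.seed(13)
  bx3 <- runif(8, 0.1, 0.4)
  by3 <- 0.15 * bx3 + rnorm(8, sd = 0.01)
  d3 <- mr_input(bx3, 0, by3, rep(0.01, 8))
  coarse <- mr_conmix(d3, grid_points = 2001)
  fine <- mr_conmix(d3, grid_points = 20001)
  ratio <- d3$by / d3$bx
  step <- (max(ratio) - min(ratio) + 12 * sd(ratio)) / 2000
  expect_lt(abs(coarse$theta - fine$theta), step)
})

test_that("MR-Lasso keeps homogeneous data intact and excises gross outliers", {
  d <- homogeneous_pair(k = 6, ratio = 0.1)
  e <- mr_lasso(d)
  expect_equal(e$diagnostics$valid_set_size, 6L)
  expect_equal(e$theta, mr_ivw(d, model = "fixed")$theta, tolerance = 1e-10)

  d2 <- outlier_pair(k_good = 10, good_ratio = 0.1, bad_ratio = 2)
  e2 <- mr_lasso(d2)
  out_id <- d2$snp_id[11]
  expect_true(out_id %in% e2$diagnostics$invalid_snps)
  refit <- mr_ivw(d2[!(d2$snp_id %in% e2$diagnostics$invalid_snps), ],
                  model = "fixed")
  expect_equal(e2$theta, refit$theta, tolerance = 1e-10)
})

test_that("BWMR agrees with IVW on clean data and down-weights the outlier most", {
  set.seed(8)
  bx <- runif(10, 0.1, 0.4)
  by <- 0.2 * bx + rnorm(10, sd = 0.01)
  d <- mr_input(bx, rep(0.01, 10), by, rep(0.01, 10))
  e <- mr_bwmr(d)
  ivw <- mr_ivw(d, model = "fixed")
  expect_lt(abs(e$theta - ivw$theta), 2 * ivw$se)
  expect_true(e$diagnostics$iterations >= 1)

  d2 <- outlier_pair(k_good = 10, good_ratio = 0.1, bad_ratio = 2)
  d2$bxse <- rep(0.005, 11)
  e2 <- mr_bwmr(d2)
  expect_equal(unname(which.min(e2$diagnostics$weights)), 11L)
})

test_that("cML selects the invalid-instrument count and matches ML when clean", {
  d <- homogeneous_pair(k = 6, ratio = 0.1, bxse = 0.01)
  e <- mr_cml(d, variant = "BIC", dp_reps = 0, n_eff = 50000)
  expect_equal(e$diagnostics$selected_k, 0)
  expect_equal(e$theta, mr_maxlik(d)$theta, tolerance = 1e-6)

  # 8-variant fixture with exactly 2 planted large direct effects
  set.seed(17)
  bx <- runif(8, 0.2, 0.4)
  by <- 0.1 * bx
  by[c(3, 7)] <- by[c(3, 7)] + c(0.3, -0.25)
  d2 <- mr_input(bx, rep(0.005, 8), by, rep(0.005, 8))
  e2 <- mr_cml(d2, variant = "BIC", dp_reps = 0, n_eff = 50000)
  expect_equal(e2$diagnostics$selected_k, 2)
  expect_setequal(e2$diagnostics$invalid_snps, d2$snp_id[c(3, 7)])
  expect_equal(e2$theta, 0.1, tolerance = 1e-3)

  # data perturbation leaves the point estimate alone, never shrinks the SE
  e_nodp <- mr_cml(d2, variant = "MA-BIC", dp_reps = 0, n_eff = 50000)
  e_dp <- mr_cml(d2, variant = "MA-BIC", dp_reps = 200, seed = 5,
                 n_eff = 50000)
  expect_equal(e_dp$theta, e_nodp$theta, tolerance = 1e-12)
  expect_gte(e_dp$se, e_nodp$se)
})

test_that("MR-PRESSO flags the planted outlier and its correction equals a refit", {
  # homogeneous noise-free data: nothing flagged, global p large
  d0 <- homogeneous_pair(k = 6, ratio = 0.1, bxse = 0.001)
  p0 <- mr_presso(d0, n_sim = 500, seed = 2)
  expect_false(any(p0$outliers$flagged))
  expect_gt(p0$global_rss_p, 0.05)
  expect_null(p0$corrected_estimate)

  # 12 concordant + 1 tenfold-ratio outlier
  set.seed(19)
  bx <- runif(13, 0.2, 0.4)
  by <- 0.1 * bx + rnorm(13, sd = 0.01)
  by[13] <- 1.0 * bx[13]
  d <- mr_input(bx, rep(0.002, 13), by, rep(0.02, 13))
  p1 <- mr_presso(d, n_sim = 1000, seed = 3)
  expect_true(p1$outliers$flagged[13])
  expect_equal(sum(p1$outliers$flagged), 1L)
  refit <- mr_ivw(d[1:12, ], model = "fixed")
  expect_identical(p1$corrected_estimate$theta, refit$theta)
  expect_lt(p1$global_rss_p, 0.05)

  # determinism contract
  p2 <- mr_presso(d, n_sim = 1000, seed = 3)
  expect_identical(p1, p2)
  expect_error(mr_presso(d[1:3, ]), "4")
})

test_that("the battery runs every configured method and records failures", {
  set.seed(23)
  bx <- runif(10, 0.1, 0.4)
  by <- 0.2 * bx + rnorm(10, sd = 0.01)
  d <- mr_input(bx, rep(0.01, 10), by, rep(0.01, 10))
  b <- run_battery(d, battery_config(presso_nsim = 200, cml_dp_reps = 20),
                   seed = 6)
  expect_equal(nrow(b$estimates), 14L)
  expect_true(all(is.na(b$estimates$error)))
  expect_s3_class(b$presso, "presso_result")

  b1 <- run_battery(d, battery_config(methods = "ivw_fixed", presso = FALSE))
  expect_equal(nrow(b1$estimates), 1L)

  d2 <- d[1:2, ]
  b2 <- run_battery(d2, battery_config(presso_nsim = 100, cml_dp_reps = 0),
                    seed = 6)
  egger_rows <- b2$estimates[grepl("^egger", b2$estimates$method), ]
  expect_true(all(!is.na(egger_rows$error)))
  ivw_row <- b2$estimates[b2$estimates$method == "ivw", ]
  expect_true(is.na(ivw_row$error))
})

test_that("estimators are equivariant to outcome and exposure rescaling", {
  set.seed(29)
  bx <- runif(8, 0.1, 0.4)
  by <- 0.2 * bx + rnorm(8, sd = 0.01)
  d <- mr_input(bx, rep(0.01, 8), by, rep(0.01, 8))
  cc <- 3.7
  d_y <- mr_input(bx, rep(0.01, 8), cc * by, cc * rep(0.01, 8))
  d_x <- mr_input(cc * bx, cc * rep(0.01, 8), by, rep(0.01, 8))
  fns <- list(ivw = function(z) mr_ivw(z, model = "fixed"),
              ivw_rand = function(z) mr_ivw(z, model = "random"),
              egger = mr_egger,
              ml = mr_maxlik,
              divw = mr_divw,
              conmix = mr_conmix,
              lasso = mr_lasso,
              bwmr = mr_bwmr)
  for (nm in names(fns)) {
    base <- fns[[nm]](d)
    scaled <- fns[[nm]](d_y)
    expect_equal(scaled$theta, cc * base$theta, tolerance = 1e-6, label = nm)
    expect_equal(scaled$se, cc * base$se, tolerance = 1e-4, label = nm)
    inv <- fns[[nm]](d_x)
    expect_equal(inv$theta, base$theta / cc, tolerance = 1e-6,
                 label = paste0(nm, "_x"))
  }
})

test_that("every method recovers the common ratio on a noise-free fixture", {
  d <- homogeneous_pair(k = 10, ratio = 0.1, bxse = 0)
  closed <- list(mr_ivw(d, model = "fixed"), mr_ivw(d, model = "random"),
                 mr_egger(d), mr_divw(d))
  for (e in closed) expect_equal(e$theta, 0.1, tolerance = 1e-8,
                                 label = e$method)
  iterative <- list(mr_maxlik(d), mr_conmix(d), mr_lasso(d), mr_bwmr(d),
                    mr_cml(d, dp_reps = 0, n_eff = 1e4))
  for (e in iterative) expect_equal(e$theta, 0.1, tolerance = 1e-4,
                                    label = e$method)
})
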