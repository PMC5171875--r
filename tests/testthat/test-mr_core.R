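test_that("wald_ratio: point estimate, first-order SE and degenerate limits", {
  h <- make_harmonized(1.0, 0.1, 0.5, 0.1)
  w <- wald_ratio(h)
  expect_equal(w$theta_hat, 0.5)
  expect_equal(w$se_theta, 0.1)
  expect_equal(w$fieller_case, "bounded")
  expect_true(w$fieller_low <= w$theta_hat & w$theta_hat <= w$fieller_high)

  # se_gamma -> 0: Fieller limits converge to the plain normal interval
  h2 <- make_harmonized(0.2, 1e-10, 0.1, 0.02)
  w2 <- wald_ratio(h2)
  z <- qnorm(0.975)
  expect_equal(w2$fieller_low, 0.5 - z * 0.02 / 0.2, tolerance = 1e-6)
  expect_equal(w2$fieller_high, 0.5 + z * 0.02 / 0.2, tolerance = 1e-6)

  # zero exposure beta is a weak-instrument error
  expect_error(wald_ratio(make_harmonized(0, 0.1, 0.5, 0.1)),
               "weak-instrument")

  # weak instrument relative to its SE: the set is not a bounded interval
  w3 <- wald_ratio(make_harmonized(0.01, 0.05, 0.1, 0.02))
  expect_true(w3$fieller_case %in% c("unbounded", "exclusive"))
})

test_that("Fieller limits agree with a root-search of the pivotal quantity", {
  # oracle: solve (Gamma - t*gamma)^2 / (se_G^2 + t^2 se_g^2) = z^2 for t by
  # bracketing + uniroot, independently of the quadratic closed form
  fieller_oracle <- function(g, sg, G, sG, alpha = 0.05) {
    z <- qnorm(1 - alpha / 2)
    pivot <- function(t) (G - t * g)^2 / (sG^2 + t^2 * sg^2) - z^2
    grid <- seq(-50, 50, length.out = 400001)
    v <- pivot(grid)
    sgn <- sign(v)
    cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    sort(vapply(cross, function(i)
      uniroot(pivot, c(grid[i], grid[i + 1]), tol = 1e-12)$root, numeric(1)))
  }
  cases <- list(c(0.2, 0.05, 0.1, 0.02),
                c(1.0, 0.1, 0.5, 0.1),
                c(0.3, 0.02, -0.15, 0.05),
                c(-0.25, 0.03, 0.1, 0.03))
  for (cs in cases) {
    h <- make_harmonized(cs[1], cs[2], cs[3], cs[4])
    w <- wald_ratio(h)
    roots <- fieller_oracle(cs[1], cs[2], cs[3], cs[4])
    expect_equal(length(roots), 2L)
    expect_equal(w$fieller_low, roots[1], tolerance = 1e-6)
    expect_equal(w$fieller_high, roots[2], tolerance = 1e-6)
  }
})

test_that("Fieller 95% intervals cover a known ratio at nominal rate", {
  # strong instrument (gamma/se = 20): coverage within 95% +/- 1%
  set.seed(314)
  n <- 10000
  gamma <- 0.2; se_g <- 0.01
  theta <- 0.4
  sG <- 0.02
  g_hat <- rnorm(n, gamma, se_g)
  G_hat <- rnorm(n, theta * gamma, sG)
  h <- make_harmonized(g_hat, se_g, G_hat, sG,
                       snp_id = sprintf("rs%05d", 1:n))
  w <- wald_ratio(h)
  covered <- w$fieller_case == "bounded" &
    w$fieller_low <= theta & theta <= w$fieller_high
  expect_gt(mean(covered), 0.94)
  expect_lt(mean(covered), 0.96)
})

test_that("IVW: reductions, replication symmetry and the WLS identity", {
  h1 <- make_harmonized(0.2, 0.05, 0.1, 0.02)
  e1 <- mr_ivw(h1)
  expect_equal(e1$beta, 0.5)
  expect_equal(e1$se, 0.02 / 0.2)
  expect_equal(e1$max_weight_share, 1)
  expect_equal(e1$n_snps, 1L)

  # k identical instruments: same beta, se shrunk by sqrt(k)
  k <- 5
  hk <- make_harmonized(rep(0.2, k), 0.05, rep(0.1, k), 0.02)
  ek <- mr_ivw(hk)
  expect_equal(ek$beta, e1$beta)
  expect_equal(ek$se, e1$se / sqrt(k))
  expect_equal(ek$max_weight_share, 1 / k)

  # weighted-mean-of-ratios equals the zero-intercept WLS slope (1e-10 rel)
  for (seed in 1:5) {
    h <- random_harmonized(12, seed)
    est <- mr_ivw(h)
    wls <- lm(big_gamma_hat ~ 0 + gamma_hat, data = h,
              weights = 1 / h$se_big_gamma^2)
    expect_equal(est$beta, unname(coef(wls)[1]), tolerance = 1e-10)
  }

  expect_error(mr_ivw(make_harmonized(numeric(0), numeric(0), numeric(0),
                                      numeric(0))),
               "at least 1")
})

test_that("MR-Egger: exact fits and a normal-equations-independent oracle", {
  g <- c(0.1, 0.15, 0.2, 0.25, 0.3)
  h <- make_harmonized(g, 0.01, 0.4 * g, 0.02)
  e <- mr_egger(h)
  expect_equal(e$beta, 0.4, tolerance = 1e-12)
  expect_equal(e$egger_intercept, 0, tolerance = 1e-12)

  h2 <- make_harmonized(g, 0.01, 0.02 + 0.4 * g, 0.02)
  e2 <- mr_egger(h2)
  expect_equal(e2$beta, 0.4, tolerance = 1e-12)
  expect_equal(e2$egger_intercept, 0.02, tolerance = 1e-12)

  # independent oracle: stats::lm on the re-oriented data, fixed-effect SEs
  # from the unscaled covariance
  for (seed in 6:9) {
    h <- random_harmonized(5, seed)
    e <- mr_egger(h)
    flip <- h$gamma_hat < 0
    gg <- abs(h$gamma_hat)
    GG <- ifelse(flip, -h$big_gamma_hat, h$big_gamma_hat)
    w <- 1 / h$se_big_gamma^2
    fit <- lm(GG ~ gg, weights = w)
    expect_equal(e$beta, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(e$egger_intercept, unname(coef(fit)[1]), tolerance = 1e-10)
    ses <- sqrt(diag(summary(fit)$cov.unscaled))
    expect_equal(e$se, unname(ses[2]), tolerance = 1e-10)
    expect_equal(e$egger_intercept_se, unname(ses[1]), tolerance = 1e-10)
    # multiplicative mode scales both SEs by the residual SD
    em <- mr_egger(h, variance = "multiplicative")
    expect_equal(em$se, unname(ses[2]) * summary(fit)$sigma,
                 tolerance = 1e-10)
    expect_equal(em$beta, e$beta)
  }

  expect_error(mr_egger(make_harmonized(c(0.1, 0.2), 0.01, c(0.1, 0.2),
                                        0.01)),
               "at least 3")
})

test_that("weighted median: interpolation, scan oracle, bootstrap and routing", {
  # equal weights, odd count: the middle ratio
  h <- make_harmonized(rep(1, 3), 0.01, c(0.1, 0.3, 0.9), 0.05)
  wm <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(wm$beta, 0.3)

  # cumulative-weight scan oracle on random sets
  for (seed in 21:25) {
    h <- random_balanced(9, seed)
    wm <- mr_weighted_median(h, n_boot = 10, seed = 1)
    theta <- h$big_gamma_hat / h$gamma_hat
    w <- h$gamma_hat^2 / h$se_big_gamma^2
    expect_equal(wm$beta, wm_scan_oracle(theta, w), tolerance = 1e-12)
    expect_gte(wm$beta, min(theta))
    expect_lte(wm$beta, max(theta))
  }

  # same seed, same bootstrap SE; different seed, different SE
  h <- random_harmonized(8, 33)
  a <- mr_weighted_median(h, n_boot = 200, seed = 5)
  b <- mr_weighted_median(h, n_boot = 200, seed = 5)
  c_ <- mr_weighted_median(h, n_boot = 200, seed = 6)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c_$se))

  # dominant SNP (> 50% of the weight) is a routing error naming it
  hd <- make_harmonized(c(1, 0.1, 0.1), 0.01, c(0.5, 0.05, 0.05), 0.05,
                        snp_id = c("rsBIG", "rs2", "rs3"))
  expect_error(mr_weighted_median(hd), "rsBIG")
})

test_that("odds-ratio conversion is exp on point and limits", {
  h <- make_harmonized(0.2, 0.05, 0, 0.02)
  e <- to_odds_ratio(mr_ivw(h))
  expect_equal(e$or_point, 1.0)

  e2 <- new_est <- mr_ivw(make_harmonized(1, 0.01, log(2), 1e-12))
  # construct a known CI by hand instead: beta ln2 with ci +/- ln2
  e2$beta <- log(2); e2$ci_low <- 0; e2$ci_high <- 2 * log(2)
  e2 <- to_odds_ratio(e2)
  expect_equal(c(e2$or_low, e2$or_point, e2$or_high), c(1, 2, 4))

  # back-solved published-style case: beta 1.0952, se 0.3127
  e3 <- mr_ivw(make_harmonized(1, 1e-9, 1.0952, 0.3127))
  e3 <- to_odds_ratio(e3)
  expect_equal(round(e3$or_point, 2), 2.99)
  expect_equal(round(e3$or_low, 2), 1.62)
  expect_equal(round(e3$or_high, 2), 5.52)
})

test_that("estimators are orientation-invariant and scale-equivariant", {
  h <- random_harmonized(10, 77)
  base <- list(ivw = mr_ivw(h)$beta, egger = mr_egger(h)$beta,
               wm = mr_weighted_median(h, n_boot = 5, seed = 1)$beta)

  # flip the sign of both betas for an arbitrary subset
  set.seed(8)
  flip <- sample(c(TRUE, FALSE), 10, replace = TRUE)
  h2 <- h
  h2$gamma_hat <- ifelse(flip, -h$gamma_hat, h$gamma_hat)
  h2$big_gamma_hat <- ifelse(flip, -h$big_gamma_hat, h$big_gamma_hat)
  expect_equal(mr_ivw(h2)$beta, base$ivw, tolerance = 1e-12)
  expect_equal(mr_egger(h2)$beta, base$egger, tolerance = 1e-12)
  expect_equal(mr_weighted_median(h2, n_boot = 5, seed = 1)$beta, base$wm,
               tolerance = 1e-12)

  # rescaling the exposure by c divides every causal estimate by c
  cc <- 2.5
  h3 <- h
  h3$gamma_hat <- cc * h$gamma_hat
  h3$se_gamma <- cc * h$se_gamma
  expect_equal(mr_ivw(h3)$beta, base$ivw / cc, tolerance = 1e-12)
  expect_equal(mr_egger(h3)$beta, base$egger / cc, tolerance = 1e-12)
  expect_equal(mr_weighted_median(h3, n_boot = 5, seed = 1)$beta,
               base$wm / cc, tolerance = 1e-12)

  # pooled IVW se is no larger than any single-SNP Wald se
  w <- wald_ratio(h)
  expect_lte(mr_ivw(h)$se, min(w$se_theta))
})
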