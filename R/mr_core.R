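# Accept either an instrument_set or a bare harmonized table everywhere in
# the estimator kernel.
as_harmonized <- function(x) {
  if (inherits(x, "instrument_set")) x$instruments
  else if (is.data.frame(x)) x
  else stop("expected an instrument_set or harmonized data.frame")
}

check_instruments <- function(h, min_n = 1L, caller = "estimator") {
  if (nrow(h) < min_n)
    stop(caller, " requires at least ", min_n, " instrument(s), got ",
         nrow(h))
  if (any(h$gamma_hat == 0))
    stop("weak-instrument error: zero exposure beta for ",
         paste(h$snp_id[h$gamma_hat == 0], collapse = ", "))
  stopifnot(all(h$se_gamma > 0), all(h$se_big_gamma > 0))
  h
}

#' Per-SNP Wald ratio with Fieller's-theorem confidence limits
#'
#' The Wald estimate is the ratio of the SNP-outcome to the SNP-exposure
#' association, theta = Gamma/gamma, with first-order standard error
#' se(Gamma)/|gamma|. Confidence limits come from Fieller's theorem: the set
#' of t with (Gamma - t*gamma)^2 <= z^2 (se_Gamma^2 + t^2 se_gamma^2),
#' i.e. the roots of
#'   (gamma^2 - z^2 se_gamma^2) t^2 - 2 gamma Gamma t
#'     + (Gamma^2 - z^2 se_Gamma^2) = 0,
#' with zero exposure-outcome covariance (two non-overlapping samples).
#' When the leading coefficient is positive the set is a bounded interval;
#' when it is negative and the discriminant positive the set excludes an
#' interval ("exclusive"); otherwise it is the whole line ("unbounded").
#'
#' @param x an `"instrument_set"` or harmonized table.
#' @param alpha confidence level complement (0.05 gives 95% limits).
#' @return data.frame with one row per SNP: `snp_id`, `theta_hat`,
#'   `se_theta`, `fieller_low`, `fieller_high`, `fieller_case`.
#' @export
wald_ratio <- function(x, alpha = 0.05) {
  h <- check_instruments(as_harmonized(x), 1L, "wald_ratio")
  z <- qnorm(1 - alpha / 2)
  g <- h$gamma_hat; G <- h$big_gamma_hat
  sg <- h$se_gamma; sG <- h$se_big_gamma
  theta <- G / g
  se <- sG / abs(g)

  a <- g^2 - z^2 * sg^2          # leading coefficient
  b <- g * G                     # half the linear coefficient
  cc <- G^2 - z^2 * sG^2
  disc <- b^2 - a * cc

  low <- high <- rep(NA_real_, length(g))
  case <- character(length(g))
  for (i in seq_along(g)) {
    if (a[i] > 0 && disc[i] > 0) {
      case[i] <- "bounded"
      low[i] <- (b[i] - sqrt(disc[i])) / a[i]
      high[i] <- (b[i] + sqrt(disc[i])) / a[i]
    } else if (a[i] < 0 && disc[i] > 0) {
      # confidence set is the complement of (r1, r2)
      case[i] <- "exclusive"
      low[i] <- (b[i] + sqrt(disc[i])) / a[i]
      high[i] <- (b[i] - sqrt(disc[i])) / a[i]
    } else {
      case[i] <- "unbounded"
      low[i] <- -Inf
      high[i] <- Inf
    }
  }
  data.frame(snp_id = h$snp_id, theta_hat = theta, se_theta = se,
             fieller_low = low, fieller_high = high, fieller_case = case,
             stringsAsFactors = FALSE)
}

new_mr_estimate <- function(method, beta, se, n_snps, max_weight_share,
                            egger_intercept = NA_real_,
                            egger_intercept_se = NA_real_,
                            egger_intercept_p = NA_real_) {
  z <- qnorm(0.975)
  structure(list(
    method = method, beta = beta, se = se,
    ci_low = beta - z * se, ci_high = beta + z * se,
    or_point = NA_real_, or_low = NA_real_, or_high = NA_real_,
    n_snps = n_snps, max_weight_share = max_weight_share,
    egger_intercept = egger_intercept,
    egger_intercept_se = egger_intercept_se,
    egger_intercept_p = egger_intercept_p
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s (%d SNPs): beta %.4f (SE %.4f), 95%% CI %.4f to %.4f\n",
              x$method, x$n_snps, x$beta, x$se, x$ci_low, x$ci_high))
  if (!is.na(x$or_point))
    cat(sprintf("  OR %.2f (95%% CI %.2f to %.2f)\n",
                x$or_point, x$or_low, x$or_high))
  if (!is.na(x$egger_intercept))
    cat(sprintf("  intercept %.4g (SE %.4g), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  invisible(x)
}

ivw_weights <- function(h) {
  se_theta <- h$se_big_gamma / abs(h$gamma_hat)
  1 / se_theta^2
}

#' Fixed-effect inverse-variance-weighted estimate
#'
#' Pools the per-SNP Wald ratios theta_j = Gamma_j/gamma_j with first-order
#' weights w_j = gamma_j^2 / se_Gamma_j^2: beta = sum(w theta)/sum(w), se =
#' 1/sqrt(sum(w)). Algebraically identical to the slope of the zero-intercept
#' weighted regression of Gamma on gamma with weights 1/se_Gamma^2. A single
#' instrument reduces to its Wald ratio with weight share 1.
#'
#' @param x an `"instrument_set"` or harmonized table with >= 1 instrument.
#' @return An `"mr_estimate"` (`method = "IVW"`), whose `max_weight_share`
#'   is the largest single-SNP share of the total weight.
#' @export
mr_ivw <- function(x) {
  h <- check_instruments(as_harmonized(x), 1L, "mr_ivw")
  theta <- h$big_gamma_hat / h$gamma_hat
  w <- ivw_weights(h)
  beta <- sum(w * theta) / sum(w)
  se <- 1 / sqrt(sum(w))
  new_mr_estimate("IVW", beta, se, nrow(h), max(w) / sum(w))
}

#' MR-Egger regression
#'
#' Re-orients every instrument so the exposure beta is positive (flipping the
#' sign of both betas where needed), then fits the weighted regression
#' Gamma_j = b0 + b1 gamma_j with weights 1/se_Gamma_j^2. The slope b1 is the
#' causal estimate; the intercept b0 estimates the average directional
#' pleiotropic effect across variants, with a two-sided normal p-value
#' (p < 0.05 conventionally read as directional pleiotropy — reported, never
#' auto-acted on). `variance = "none"` (default) uses fixed-effect
#' normal-theory SEs from (X'WX)^-1; `"multiplicative"` scales them by the
#' residual variance.
#'
#' @param x an `"instrument_set"` or harmonized table with >= 3 instruments.
#' @param variance residual-variance mode, `"none"` or `"multiplicative"`.
#' @return An `"mr_estimate"` (`method = "MR-Egger"`) with intercept fields.
#' @export
mr_egger <- function(x, variance = c("none", "multiplicative")) {
  variance <- match.arg(variance)
  h <- check_instruments(as_harmonized(x), 3L, "mr_egger")
  flip <- h$gamma_hat < 0
  g <- ifelse(flip, -h$gamma_hat, h$gamma_hat)
  G <- ifelse(flip, -h$big_gamma_hat, h$big_gamma_hat)
  w <- 1 / h$se_big_gamma^2

  X <- cbind(1, g)
  xtwx <- crossprod(X, w * X)
  coef <- solve(xtwx, crossprod(X, w * G))
  vcov <- solve(xtwx)
  if (variance == "multiplicative") {
    resid <- G - X %*% coef
    sigma2 <- sum(w * resid^2) / (nrow(h) - 2L)
    vcov <- vcov * sigma2
  }
  b0 <- coef[1L]; b1 <- coef[2L]
  se0 <- sqrt(vcov[1L, 1L]); se1 <- sqrt(vcov[2L, 2L])
  new_mr_estimate("MR-Egger", b1, se1, nrow(h),
                  max(ivw_weights(h)) / sum(ivw_weights(h)),
                  egger_intercept = b0, egger_intercept_se = se0,
                  egger_intercept_p = 2 * pnorm(-abs(b0 / se0)))
}

weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  wn <- w[ord] / sum(w)
  p <- cumsum(wn) - wn / 2
  if (0.5 <= p[1L]) return(theta[1L])
  if (0.5 >= p[length(p)]) return(theta[length(theta)])
  approx(p, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimate with parametric-bootstrap standard error
#'
#' The weighted median is the Wald ratio at the 50th weight percentile:
#' ratios are sorted, IVW weights normalized, and theta is linearly
#' interpolated at cumulative-midpoint positions p_j = S_j - w'_j/2. It is
#' consistent when instruments carrying at least half the weight are valid.
#' The SE is a parametric bootstrap: gamma*_j ~ N(gamma_j, se_gamma_j),
#' Gamma*_j ~ N(Gamma_j, se_Gamma_j), recomputing the weighted median
#' `n_boot` times; the 95% CI is beta +/- 1.96 se. A set whose largest
#' weight share exceeds 50% violates the estimator's precondition (the
#' selection rule routes such sets to MR-Egger) and is an error naming the
#' dominant SNP.
#'
#' @param x an `"instrument_set"` or harmonized table with >= 3 instruments.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed optional integer seed for the bootstrap; the caller's RNG
#'   state is preserved.
#' @return An `"mr_estimate"` (`method = "WeightedMedian"`).
#' @export
mr_weighted_median <- function(x, n_boot = 1000L, seed = NULL) {
  h <- check_instruments(as_harmonized(x), 3L, "mr_weighted_median")
  w <- ivw_weights(h)
  share <- w / sum(w)
  if (max(share) > 0.5)
    stop("routing error: ", h$snp_id[which.max(share)],
         sprintf(" carries %.1f%% of the IVW weight (> 50%%); use MR-Egger",
                 100 * max(share)))
  theta <- h$big_gamma_hat / h$gamma_hat
  beta <- weighted_median_point(theta, w)

  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      g <- rnorm(nrow(h), h$gamma_hat, h$se_gamma)
      G <- rnorm(nrow(h), h$big_gamma_hat, h$se_big_gamma)
      ok <- g != 0
      weighted_median_point(G[ok] / g[ok], g[ok]^2 / h$se_big_gamma[ok]^2)
    }, numeric(1))
  })
  se <- sd(boots)
  new_mr_estimate("WeightedMedian", beta, se, nrow(h), max(share))
}

#' Express an estimate on the odds-ratio scale
#'
#' For binary outcomes whose betas are log-odds: exponentiates the point
#' estimate and confidence limits into `or_point`, `or_low`, `or_high`,
#' leaving the beta-scale fields untouched.
#'
#' @param est an `"mr_estimate"`.
#' @export
to_odds_ratio <- function(est) {
  stopifnot(inherits(est, "mr_estimate"))
  est$or_point <- exp(est$beta)
  est$or_low <- exp(est$ci_low)
  est$or_high <- exp(est$ci_high)
  est
}
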