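#' Specify the ground truth of a synthetic two-sample dataset
#'
#' Describes the generative model the estimators assume: true instrument
#' strengths gamma_j, direct (pleiotropic) effects alpha_j, a causal effect
#' beta, and Gaussian sampling error on both sets of summary statistics.
#' Under `pleiotropy = "none"` all alpha_j are 0. Under `"balanced"` the
#' invalid fraction draws alpha_j ~ N(0, sigma_alpha); `"directional_inside"`
#' draws alpha_j ~ N(mu_alpha, sigma_alpha) independently of gamma_j (the
#' InSIDE assumption holds); `"directional_inside_violated"` correlates
#' alpha_j with gamma_j (correlation `rho_alpha_gamma`), breaking InSIDE.
#'
#' Defaults describe a realistic liver-enzyme-style instrument panel:
#' exposure betas in proportional-change units (1.0 = 100% change) of
#' 0.15-0.25 with SE 0.005 (instrument F well above 100, i.e. strong), and
#' outcome log-odds SE 0.02, typical of consortium case-control GWAS of
#' tens of thousands of cases.
#'
#' @param beta_causal true causal effect per unit (100% change in) exposure.
#' @param n_snps number of instruments.
#' @param gamma_range length-2 range of the uniform distribution of true
#'   instrument strengths.
#' @param se_gamma,se_big_gamma per-SNP sampling SEs (scalars or length
#'   `n_snps`).
#' @param pleiotropy regime; see Details.
#' @param mu_alpha,sigma_alpha mean and SD of the direct effects of invalid
#'   instruments.
#' @param invalid_fraction proportion of instruments with alpha_j != 0.
#' @param rho_alpha_gamma correlation between alpha and gamma under the
#'   InSIDE-violated regime.
#' @param palindromic_fraction proportion of SNPs given A/T or C/G alleles.
#' @param seed integer seed; identical truths give byte-identical tables.
#' @return list of class `"simulation_truth"`.
#' @export
simulation_truth <- function(beta_causal = 0.3, n_snps = 50L,
                             gamma_range = c(0.15, 0.25),
                             se_gamma = 0.005, se_big_gamma = 0.02,
                             pleiotropy = c("none", "balanced",
                                            "directional_inside",
                                            "directional_inside_violated"),
                             mu_alpha = 0.05, sigma_alpha = 0.02,
                             invalid_fraction = 0, rho_alpha_gamma = 0.7,
                             palindromic_fraction = 0, seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(is_count(n_snps), n_snps >= 1,
            length(gamma_range) == 2L, gamma_range[1] <= gamma_range[2],
            all(se_gamma > 0), all(se_big_gamma > 0),
            invalid_fraction >= 0, invalid_fraction <= 1,
            sigma_alpha >= 0, abs(rho_alpha_gamma) <= 1,
            palindromic_fraction >= 0, palindromic_fraction <= 1)
  if (pleiotropy == "none" && invalid_fraction > 0)
    stop("pleiotropy regime 'none' requires invalid_fraction = 0")
  if (pleiotropy != "none" && invalid_fraction == 0)
    stop("regime '", pleiotropy, "' requires invalid_fraction > 0")
  structure(list(
    beta_causal = beta_causal, n_snps = as.integer(n_snps),
    gamma_range = gamma_range,
    se_gamma = rep_len(se_gamma, n_snps),
    se_big_gamma = rep_len(se_big_gamma, n_snps),
    pleiotropy = pleiotropy, mu_alpha = mu_alpha,
    sigma_alpha = sigma_alpha, invalid_fraction = invalid_fraction,
    rho_alpha_gamma = rho_alpha_gamma,
    palindromic_fraction = palindromic_fraction,
    seed = as.integer(seed)
  ), class = "simulation_truth")
}

# Allele pairs: non-palindromic by default so letter-based harmonization is
# exact; a palindromic fraction can be injected to exercise the warning path.
draw_alleles <- function(n, palindromic_fraction) {
  non_pal <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
  pal <- list(c("A", "T"), c("C", "G"))
  pick <- function(pool) pool[[sample.int(length(pool), 1L)]]
  t(vapply(seq_len(n), function(i) {
    pair <- if (runif(1) < palindromic_fraction) pick(pal) else pick(non_pal)
    if (runif(1) < 0.5) pair else rev(pair)
  }, character(2)))
}

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Draws true instrument strengths gamma_j ~ U(gamma_range); sets direct
#' effects alpha_j by regime; forms true outcome associations
#' Gamma_j = beta_causal * gamma_j + alpha_j; and observes
#' gamma_hat_j ~ N(gamma_j, se_gamma_j), Gamma_hat_j ~ N(Gamma_j,
#' se_big_gamma_j). Both tables are emitted in the reader's format with
#' p-values from a two-sided normal test; the outcome table's allele
#' orientation is randomly flipped per SNP (allele swap + beta sign flip) so
#' harmonization is exercised, and the truth record retains the flips.
#'
#' @param truth a `"simulation_truth"`.
#' @return list: `exposure` and `outcome` (`"gwas_assoc"` tables) and
#'   `truth` (the input plus the realized `gamma`, `alpha`, `big_gamma`,
#'   `invalid` flags and outcome-side `flipped` indicator per SNP).
#' @export
simulate_two_sample <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  with_seed(truth$seed, {
    k <- truth$n_snps
    gamma <- runif(k, truth$gamma_range[1], truth$gamma_range[2])
    invalid <- rep(FALSE, k)
    alpha <- rep(0, k)
    if (truth$invalid_fraction > 0) {
      n_inv <- round(truth$invalid_fraction * k)
      invalid[sample.int(k, n_inv)] <- TRUE
      mu <- if (truth$pleiotropy == "balanced") 0 else truth$mu_alpha
      z <- rnorm(k)
      if (truth$pleiotropy == "directional_inside_violated") {
        gs <- as.numeric(scale(gamma))
        z <- truth$rho_alpha_gamma * gs +
          sqrt(1 - truth$rho_alpha_gamma^2) * z
      }
      alpha <- ifelse(invalid, mu + truth$sigma_alpha * z, 0)
    }
    big_gamma <- truth$beta_causal * gamma + alpha

    gamma_hat <- rnorm(k, gamma, truth$se_gamma)
    big_gamma_hat <- rnorm(k, big_gamma, truth$se_big_gamma)
    alleles <- draw_alleles(k, truth$palindromic_fraction)
    flipped <- runif(k) < 0.5
    snp <- sprintf("rs%07d", seq_len(k))

    # clamp: z-scores beyond ~38 underflow to p = 0, which the validator
    # rightly rejects
    two_sided <- function(b, s) pmax(2 * pnorm(-abs(b) / s),
                                     .Machine$double.xmin)
    exposure <- gwas_assoc(
      snp_id = snp, effect_allele = alleles[, 1], other_allele = alleles[, 2],
      beta = gamma_hat, se = truth$se_gamma,
      p_value = two_sided(gamma_hat, truth$se_gamma),
      eaf = round(runif(k, 0.1, 0.9), 3), trait_id = "sim_exposure")
    outcome <- gwas_assoc(
      snp_id = snp,
      effect_allele = ifelse(flipped, alleles[, 2], alleles[, 1]),
      other_allele = ifelse(flipped, alleles[, 1], alleles[, 2]),
      beta = ifelse(flipped, -big_gamma_hat, big_gamma_hat),
      se = truth$se_big_gamma,
      p_value = two_sided(big_gamma_hat, truth$se_big_gamma),
      eaf = round(runif(k, 0.1, 0.9), 3), trait_id = "sim_outcome")

    truth$gamma <- gamma
    truth$alpha <- alpha
    truth$big_gamma <- big_gamma
    truth$invalid <- invalid
    truth$flipped <- flipped
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Replicate estimator performance under a known truth
#'
#' Repeats [simulate_two_sample()] `reps` times (re-seeding each replicate
#' from `seed`), harmonizes, and records the IVW, MR-Egger and weighted
#' median point estimates, the IVW 95% CI coverage of the true effect, and
#' the Egger intercept p-value. The weighted median point estimate needs no
#' bootstrap, so replicates are cheap.
#'
#' @param truth a `"simulation_truth"`; its own seed is ignored in favour of
#'   per-replicate seeds derived from `seed`.
#' @param reps number of replicates.
#' @param seed integer base seed.
#' @param egger_variance residual-variance mode for the Egger fit; use
#'   `"multiplicative"` when the generating model adds pleiotropic
#'   heterogeneity beyond the sampling SEs (e.g. the balanced regime), so
#'   the intercept test stays calibrated.
#' @return data.frame with one row per replicate: `ivw`, `egger`, `wm`,
#'   `ivw_cover` (logical), `egger_intercept_p`.
#' @export
simulate_replicates <- function(truth, reps = 500L, seed = 1L,
                                egger_variance = "none") {
  stopifnot(inherits(truth, "simulation_truth"), is_count(reps))
  base <- as.integer(seed) %% 1000000L
  out <- lapply(seq_len(reps), function(r) {
    truth$seed <- base + r
    sim <- simulate_two_sample(truth)
    h <- harmonize(sim$exposure, sim$outcome)
    ivw <- mr_ivw(h)
    egg <- mr_egger(h, variance = egger_variance)
    wm <- tryCatch(mr_weighted_median(h, n_boot = 0L)$beta,
                   error = function(e) NA_real_)
    data.frame(ivw = ivw$beta, egger = egg$beta, wm = wm,
               ivw_cover = ivw$ci_low <= truth$beta_causal &
                 truth$beta_causal <= ivw$ci_high,
               egger_intercept_p = egg$egger_intercept_p)
  })
  do.call(rbind, out)
}
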