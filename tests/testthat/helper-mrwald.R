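# Builders used across the suite.

make_harmonized <- function(gamma, se_gamma, big_gamma, se_big_gamma,
                            snp_id = sprintf("rs%03d", seq_along(gamma))) {
  structure(data.frame(
    snp_id = snp_id,
    effect_allele = rep_len("A", length(gamma)),
    other_allele = rep_len("G", length(gamma)),
    gamma_hat = gamma, se_gamma = rep_len(se_gamma, length(gamma)),
    big_gamma_hat = big_gamma,
    se_big_gamma = rep_len(se_big_gamma, length(gamma)),
    palindromic = rep_len(FALSE, length(gamma)), stringsAsFactors = FALSE
  ), class = c("harmonized", "data.frame"))
}

random_harmonized <- function(k, seed) {
  set.seed(seed)
  make_harmonized(
    gamma = runif(k, 0.05, 0.3) * sample(c(-1, 1), k, replace = TRUE),
    se_gamma = runif(k, 0.005, 0.02),
    big_gamma = rnorm(k, 0.05, 0.1),
    se_big_gamma = runif(k, 0.01, 0.05)
  )
}

# like random_harmonized but with homogeneous instrument strength, so no
# single SNP can dominate the IVW weight (weighted-median precondition)
random_balanced <- function(k, seed) {
  set.seed(seed)
  make_harmonized(
    gamma = runif(k, 0.15, 0.2) * sample(c(-1, 1), k, replace = TRUE),
    se_gamma = 0.01,
    big_gamma = rnorm(k, 0.05, 0.1),
    se_big_gamma = runif(k, 0.02, 0.03)
  )
}

make_assoc <- function(snp_id, beta, se, p, ea = "A", oa = "G",
                       trait = "x") {
  suppressWarnings(gwas_assoc(snp_id = snp_id, effect_allele = ea,
                              other_allele = oa, beta = beta, se = se,
                              p_value = p, trait_id = trait))
}

# Independent scan oracle for the interpolated weighted median: walk the
# sorted ratios' cumulative-midpoint positions and interpolate by hand.
wm_scan_oracle <- function(theta, w) {
  ord <- order(theta)
  th <- theta[ord]
  wn <- w[ord] / sum(w)
  p <- numeric(length(wn))
  run <- 0
  for (j in seq_along(wn)) {
    p[j] <- run + wn[j] / 2
    run <- run + wn[j]
  }
  if (0.5 <= p[1]) return(th[1])
  for (j in 2:length(p)) {
    if (p[j] >= 0.5)
      return(th[j - 1] + (th[j] - th[j - 1]) * (0.5 - p[j - 1]) /
               (p[j] - p[j - 1]))
  }
  th[length(th)]
}
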