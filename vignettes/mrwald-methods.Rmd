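---
title: "Two-sample Mendelian randomization with mrwald: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrwald}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Mendelian randomization (MR) uses genetic variants as instrumental
variables for a modifiable exposure. In the two-sample summary-data
setting, each instrument SNP *j* contributes an estimated SNP–exposure
association $\hat\gamma_j$ (SE $\sigma_{\gamma j}$) from one study and an
estimated SNP–outcome association $\hat\Gamma_j$ (SE $\sigma_{\Gamma j}$)
from a second, non-overlapping study. If SNP *j* is a valid instrument —
associated with the exposure, independent of confounders, and affecting the
outcome only through the exposure — then $\Gamma_j = \beta\,\gamma_j$ and
the per-SNP Wald ratio $\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$ estimates
the causal effect $\beta$.

`mrwald` implements this workflow for the kind of analysis in which the
exposure is a continuously measured biomarker (the motivating application
is serum liver enzymes, with exposure betas in proportional-change units so
that a pooled $\beta$ reads "per 100% change in concentration") and the
outcomes are binary disease endpoints (betas are log-odds; estimates are
reported as odds ratios) or continuous traits (SD or trait units).

### Estimators

* **Wald ratio + Fieller limits** (`wald_ratio`). Point estimate
  $\hat\Gamma_j/\hat\gamma_j$, first-order SE
  $\sigma_{\Gamma j}/|\hat\gamma_j|$. Confidence limits use Fieller's
  theorem: the set of $t$ with
  $(\hat\Gamma_j - t\hat\gamma_j)^2 \le z^2(\sigma_{\Gamma j}^2 +
  t^2\sigma_{\gamma j}^2)$, i.e. the roots of the quadratic
  $(\hat\gamma^2 - z^2\sigma_\gamma^2)t^2 - 2\hat\gamma\hat\Gamma t +
  (\hat\Gamma^2 - z^2\sigma_\Gamma^2) = 0$. The exposure–outcome covariance
  is set to zero because the two samples do not overlap. The set is a
  bounded interval only when the instrument is strong
  ($|\hat\gamma| > z\sigma_\gamma$); weak instruments yield "exclusive" or
  "unbounded" sets, which the function labels rather than hides.
* **Fixed-effect IVW** (`mr_ivw`). Weighted mean of the Wald ratios with
  first-order weights $w_j = \hat\gamma_j^2/\sigma_{\Gamma j}^2$, SE
  $1/\sqrt{\sum w_j}$. This is algebraically the zero-intercept weighted
  regression of $\hat\Gamma$ on $\hat\gamma$ with weights
  $1/\sigma_{\Gamma j}^2$, and the test suite asserts the two forms agree
  to 1e-10 relative tolerance. First-order weights were chosen over
  Fieller-based ones because they are the standard fixed-effect IVW
  construction and reproduce symmetric 95% CIs; Fieller limits are still
  computed per SNP as diagnostics.
* **MR-Egger** (`mr_egger`). After re-orienting every SNP so
  $\hat\gamma_j > 0$, fits $\hat\Gamma_j = \beta_0 + \beta_1\hat\gamma_j$
  by WLS with weights $1/\sigma_{\Gamma j}^2$. The slope is consistent for
  $\beta$ even when all instruments are invalid, provided instrument
  strength is independent of the direct effects (InSIDE). The intercept
  estimates the average directional pleiotropic effect; its two-sided
  normal p-value below 0.05 is conventionally read as evidence of
  directional pleiotropy — the package reports the p-value and never acts
  on it automatically. By default SEs come from $(X'WX)^{-1}$ with no
  residual-variance scaling ("fixed-effect"); a `"multiplicative"` switch
  scales by the weighted residual variance, which matters when the data
  carry pleiotropic heterogeneity beyond the sampling SEs (see the
  calibration note below).
* **Weighted median** (`mr_weighted_median`). Ratios are sorted, IVW
  weights normalized, and the estimate is the linear interpolation of
  $\hat\theta$ at cumulative-midpoint position
  $p_j = S_j - w'_j/2 = 0.5$. It is consistent while valid instruments
  carry at least half the weight. The SE is a parametric bootstrap
  (default 1000 draws, seeded) resampling both $\hat\gamma_j$ and
  $\hat\Gamma_j$ from normal distributions at their reported SEs — the
  same error model the simulator uses, keeping generator and estimator
  assumptions aligned.

### The sensitivity battery

`run_sensitivity` mirrors the published analysis design: IVW on all
instruments and again after excluding SNPs annotated (via an input tag
file, not a live phenotype-database query) as directly associated with the
outcome; plus a secondary estimator chosen by the 50% weight-share rule —
weighted median when every SNP carries less than half the IVW weight,
MR-Egger when a single SNP carries more than half. An exact 50% share is
routed to MR-Egger: the source rule leaves equality open, and MR-Egger is
the conservative choice because it does not let the dominant SNP set the
median. The Egger intercept and p-value are computed for every
configuration with at least 3 SNPs, even when the weighted median is the
chosen secondary, since the intercept is the pleiotropy diagnostic printed
alongside every primary row.

## Instrument selection and harmonization

* **Significance filter**: strict `p < 5e-8` (the conventional genome-wide
  threshold), order-preserving.
* **LD pruning** (`ld_prune`): pairwise $r^2$ is an *input* (no reference
  panel is queried). SNPs are processed in ascending p-value order, ties
  broken by descending $|\beta|$ then lexicographic rsID, and kept iff
  their $r^2$ with every already-kept SNP is below 0.8. The source rule
  only says to retain the SNP with "smaller p-value and/or larger effect";
  the deterministic total order makes results reproducible and
  input-order-invariant, which the suite asserts.
* **Harmonization** (`harmonize`): outcome betas are aligned to the
  exposure's effect allele, sign-flipping when the outcome reports the
  complementary orientation. Palindromic (A/T, C/G) SNPs cannot be
  strand-resolved from letters; they are harmonized by letters with a
  warning rather than dropped, because dropping would silently change the
  instrument counts the analysis design fixes, and no allele-frequency
  inference is attempted. A missing outcome "other allele" is tolerated
  only when effect alleles already match. Exposure SNPs absent from the
  outcome table are logged, never silently dropped; every pipeline stage
  preserves the invariant |kept| + |logged exclusions| = |input|.

## The synthetic world

`simulation_truth`/`simulate_two_sample` generate summary statistics at the
summary level (the estimators see nothing else, so individual-level
simulation would add cost without adding truth):
$\gamma_j \sim U(a, b)$; direct effects $\alpha_j$ are zero for valid
instruments and $N(\mu_\alpha, \sigma_\alpha)$ for the invalid fraction —
independent of $\gamma_j$ under the InSIDE regimes, correlated
(configurable, default 0.7) under the violated regime; $\Gamma_j = \beta
\gamma_j + \alpha_j$; observations add independent normal error at the
stated SEs; outcome rows are randomly allele-flipped so harmonization is
always exercised.

Defaults state a realistic strong-instrument panel for a biomarker
exposure: 50 SNPs, $\gamma \in [0.15, 0.25]$ proportional-change units
with SE 0.005 (instrument F well above 100), outcome log-odds SE 0.02
(consortium-scale case-control GWAS), causal effect 0.3, directional
pleiotropy mean 0.05 with SD 0.02. These were chosen once, from the scale
of the motivating application, and are not tuned to test outcomes.

What the simulator does **not** emulate: LD between instruments (the
pipeline prunes to independence before estimation), allele-frequency
information for palindromic resolution, sample overlap between the two
studies, non-normal sampling error, and winner's-curse selection of
instruments. A green simulation test therefore establishes estimator
correctness under the stated generative model, not robustness to those
real-data features.

The packaged fixture (`make_fixture`) reproduces the *structure* of the
motivating liver-enzyme analysis — instrument panels of 4 (ALT), 14 (ALP)
and 26 (GGT) SNPs, one SNP shared between ALT and ALP, and a pleiotropy-tag
file that reproduces the published exclusion counts (3/13/24 against
diabetes tags, 3/9/23 against CAD tags) — with synthetic effect sizes
throughout. rsIDs named in the published exclusion lists are real; the
remaining placeholders sit in an `rs9xxxxxxx` range and are labelled
synthetic. The fixture validates plumbing and bookkeeping; it cannot and
does not validate published effect estimates, which would require the
source study's per-SNP supplementary table as input.

## Numerical and calibration notes

* 95% intervals use $z = 1.96$ throughout (no small-sample t correction),
  matching the symmetric CIs the fixed-effect construction implies.
* The weighted-median interpolation clamps to the extreme ratio when 0.5
  falls outside the cumulative-midpoint range.
* Weak instruments: a zero $\hat\gamma_j$ is an explicit error; a
  $|\hat\gamma| \le z\sigma_\gamma$ instrument yields a non-bounded Fieller
  set, labelled as such.
* Simulated p-values are clamped at the smallest positive normal double:
  z-scores beyond about 38 underflow to zero, which the row validator
  would (correctly) reject.
* Intercept-test calibration: with balanced pleiotropy the residual
  variance exceeds the sampling SEs, so the fixed-effect ("none") Egger
  SEs are too small and the intercept test over-rejects. The calibration
  check therefore uses the `"multiplicative"` switch for the balanced
  regime (and "none" when there is no pleiotropy at all); both rejection
  rates are asserted near the nominal 5%.
* Bootstrap and simulation seeds are always taken as explicit arguments
  and restored after use, so identical configurations produce
  byte-identical outputs — asserted at the file level for the grid runner.

## Known limitations

No proxy-SNP search, no allele-frequency-based palindrome resolution, no
random-effects IVW, no mode-based estimators or outlier-search methods,
no multivariable MR. The pipeline treats LD and pleiotropy annotations as
inputs; their provenance and quality are the user's responsibility.
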