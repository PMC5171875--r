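#' Choose the secondary estimator from IVW weight shares
#'
#' When every SNP contributes less than 50% of the IVW weight the weighted
#' median is used; when a single SNP contributes more than 50% MR-Egger is
#' used (the median would then be driven by the possibly invalid dominant
#' SNP). An exact 50% share is routed to MR-Egger as the conservative choice,
#' with a note. Fewer than 3 instruments support neither method.
#'
#' @param set an `"instrument_set"` or harmonized table.
#' @return list with `method` ("WeightedMedian", "MR-Egger" or `NA` when
#'   unavailable), `max_weight_share`, and a human-readable `reason`.
#' @export
choose_secondary <- function(set) {
  h <- as_harmonized(set)
  if (nrow(h) < 3L)
    return(list(method = NA_character_, max_weight_share = NA_real_,
                reason = sprintf("%d instrument(s) < 3: no secondary method",
                                 nrow(h))))
  w <- ivw_weights(h)
  share <- max(w) / sum(w)
  if (share < 0.5) {
    list(method = "WeightedMedian", max_weight_share = share,
         reason = sprintf("max weight share %.2f < 0.5 -> WeightedMedian",
                          share))
  } else if (share > 0.5) {
    list(method = "MR-Egger", max_weight_share = share,
         reason = sprintf("max weight share %.2f > 0.5 -> MR-Egger", share))
  } else {
    list(method = "MR-Egger", max_weight_share = share,
         reason = "max weight share exactly 0.5 -> MR-Egger (conservative)")
  }
}

run_methods_on <- function(h, config) {
  out <- list(ivw = mr_ivw(h), secondary = NULL, egger = NULL,
              secondary_reason = NULL)
  sec <- choose_secondary(h)
  out$secondary_reason <- sec$reason
  if (nrow(h) >= 3L)
    out$egger <- mr_egger(h, variance = config$egger_variance %||% "none")
  if (is.na(sec$method)) {
    warning("fewer than 3 instruments: reporting IVW only", call. = FALSE)
  } else if (sec$method == "WeightedMedian") {
    out$secondary <- mr_weighted_median(h, n_boot = config$n_boot %||% 1000L,
                                        seed = config$seed %||% 1L)
  } else {
    out$secondary <- out$egger
  }
  out
}

maybe_or <- function(est, binary) {
  if (!is.null(est) && isTRUE(binary)) to_odds_ratio(est) else est
}

#' Run the sensitivity battery for one exposure-outcome pair
#'
#' Computes the fixed-effect IVW estimate and the weight-share-selected
#' secondary estimate (weighted median or MR-Egger) on the full instrument
#' set and again after excluding instruments tagged as directly associated
#' with the outcome. The MR-Egger intercept and its p-value are computed for
#' every configuration with >= 3 instruments, even when the weighted median
#' is the chosen secondary, since the intercept is the directional-pleiotropy
#' diagnostic reported alongside every IVW row.
#'
#' @param set an `"instrument_set"` whose instruments carry pleiotropy tags.
#' @param config list: `binary` (outcome betas are log-odds; report ORs),
#'   `n_boot` and `seed` for the weighted-median bootstrap,
#'   `egger_variance` ("none" or "multiplicative").
#' @return An object of class `"sensitivity_report"` with elements
#'   `primary`, `primary_excl`, `secondary`, `secondary_excl` (each an
#'   `"mr_estimate"` or `NULL`), per-set Egger intercepts, the routing
#'   reasons, and the excluded set's exclusion log.
#' @export
run_sensitivity <- function(set, config = list()) {
  stopifnot(inherits(set, "instrument_set"))
  excl <- exclude_pleiotropic(set)
  full <- run_methods_on(set$instruments, config)
  binary <- config$binary %||% FALSE

  rep <- list(
    exposure_id = set$exposure_id,
    outcome_id = set$outcome_id,
    primary = maybe_or(full$ivw, binary),
    secondary = maybe_or(full$secondary, binary),
    egger_full = maybe_or(full$egger, binary),
    secondary_method_reason = full$secondary_reason,
    primary_excl = NULL, secondary_excl = NULL, egger_excl = NULL,
    secondary_excl_method_reason = NULL,
    exclusion_log = excl$exclusion_log,
    n_excluded = nrow(set$instruments) - nrow(excl$instruments)
  )
  if (nrow(excl$instruments) == 0L) {
    warning("all instruments excluded as pleiotropic for ",
            set$outcome_id, "; excluded-set estimates unavailable",
            call. = FALSE)
  } else {
    ex <- run_methods_on(excl$instruments, config)
    rep$primary_excl <- maybe_or(ex$ivw, binary)
    rep$secondary_excl <- maybe_or(ex$secondary, binary)
    rep$egger_excl <- maybe_or(ex$egger, binary)
    rep$secondary_excl_method_reason <- ex$secondary_reason
  }
  class(rep) <- "sensitivity_report"
  rep
}

estimate_row <- function(set_label, est, egger) {
  if (is.null(est)) return(NULL)
  data.frame(
    set = set_label,
    n_snps = est$n_snps,
    method = est$method,
    estimate = if (!is.na(est$or_point)) est$or_point else est$beta,
    ci_low = if (!is.na(est$or_point)) est$or_low else est$ci_low,
    ci_high = if (!is.na(est$or_point)) est$or_high else est$ci_high,
    scale = if (!is.na(est$or_point)) "OR" else "beta",
    egger_intercept = if (!is.null(egger)) egger$egger_intercept else NA_real_,
    egger_intercept_p = if (!is.null(egger)) egger$egger_intercept_p else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Flatten a sensitivity report into a publication-shaped table
#'
#' One row per (instrument set, method): IVW then the secondary method, for
#' the full set and the pleiotropy-excluded set, with the per-set MR-Egger
#' intercept and its p-value on the IVW rows (the secondary rows leave them
#' `NA`, mirroring the conventional table layout).
#'
#' @param report a `"sensitivity_report"`.
#' @export
report_table <- function(report) {
  blank <- function(row) {
    if (is.null(row)) return(NULL)
    row$egger_intercept <- NA_real_
    row$egger_intercept_p <- NA_real_
    row
  }
  rows <- list(
    estimate_row("all", report$primary, report$egger_full),
    blank(estimate_row("all", report$secondary, NULL)),
    estimate_row("excluded", report$primary_excl, report$egger_excl),
    blank(estimate_row("excluded", report$secondary_excl, NULL))
  )
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(NULL)
  cbind(data.frame(exposure = report$exposure_id,
                   outcome = report$outcome_id,
                   stringsAsFactors = FALSE),
        out)
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %s -> %s (%d excluded as pleiotropic)\n",
              x$exposure_id, x$outcome_id, x$n_excluded))
  print(report_table(x))
  invisible(x)
}
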