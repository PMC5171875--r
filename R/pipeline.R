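#' Load and validate a grid-analysis configuration
#'
#' The configuration names the exposure and outcome summary tables (with
#' per-table column maps and a binary/continuous flag for outcomes), the
#' pleiotropy-tag file, the selection thresholds (`p_threshold`, default
#' 5e-8; `r2_threshold`, default 0.8, with an optional `r2_file` of pairwise
#' r2), weighted-median bootstrap settings (`n_boot`, `seed`), the MR-Egger
#' residual-variance mode, and the output directory. Relative paths are
#' resolved against the configuration file's own directory.
#'
#' @param config path to a YAML or JSON file, or an equivalent list.
#' @return validated config list of class `"analysis_config"`.
#' @export
analysis_config <- function(config) {
  base <- "."
  if (is.character(config)) {
    base <- dirname(config)
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config), length(config$exposures) >= 1L,
            length(config$outcomes) >= 1L)
  config$p_threshold <- config$p_threshold %||% 5e-8
  config$r2_threshold <- config$r2_threshold %||% 0.8
  config$n_boot <- as.integer(config$n_boot %||% 1000L)
  config$seed <- as.integer(config$seed %||% 1L)
  config$egger_variance <- config$egger_variance %||% "none"
  config$out_dir <- config$out_dir %||% "results"
  stopifnot(config$p_threshold > 0, config$p_threshold <= 1,
            config$r2_threshold > 0, config$r2_threshold <= 1,
            config$egger_variance %in% c("none", "multiplicative"))

  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p) && file.exists(file.path(base, p)))
      p <- file.path(base, p)
    if (!file.exists(p)) stop("configured path not found: ", p)
    p
  }
  for (nm in names(config$exposures))
    config$exposures[[nm]]$path <- resolve(config$exposures[[nm]]$path)
  for (nm in names(config$outcomes))
    config$outcomes[[nm]]$path <- resolve(config$outcomes[[nm]]$path)
  config$pleiotropy_tags <- resolve(config$pleiotropy_tags)
  config$r2_file <- resolve(config$r2_file)
  if (!is.null(config$out_dir) && !file.exists(config$out_dir) &&
      base != "." && !grepl("^/", config$out_dir))
    config$out_dir <- file.path(base, config$out_dir)
  class(config) <- c("analysis_config", "list")
  config
}

read_configured_table <- function(entry, trait_id) {
  read_summary_table(entry$path, unlist(entry$columns), trait_id)
}

#' Build the instrument set for one exposure-outcome pair
#'
#' Select (significance filter, LD prune), harmonize against the outcome
#' table, and bundle with pleiotropy tags and the accumulated exclusion log.
#'
#' @param exposure,outcome `"gwas_assoc"` tables.
#' @param exposure_id,outcome_id identifiers.
#' @param tags pleiotropy-tag data.frame or `NULL`.
#' @param r2 pairwise r2 data.frame or `NULL`.
#' @param p_threshold,r2_threshold selection thresholds.
#' @return an `"instrument_set"`.
#' @export
build_instrument_set <- function(exposure, outcome, exposure_id, outcome_id,
                                 tags = NULL, r2 = NULL,
                                 p_threshold = 5e-8, r2_threshold = 0.8) {
  log <- empty_exclusion_log()
  sel <- significance_filter(exposure, p_threshold)
  log <- add_exclusions(log, setdiff(exposure$snp_id, sel$snp_id),
                        sprintf("p>=%g", p_threshold))
  pruned <- ld_prune(sel, r2, r2_threshold)
  plog <- attr(pruned, "exclusion_log")
  log <- add_exclusions(log, plog$snp_id, plog$reason)
  h <- harmonize(pruned, outcome)
  miss <- attr(h, "missing")
  log <- add_exclusions(log, miss$snp_id, miss$reason)
  instrument_set(exposure_id, outcome_id, h, exclusion_log = log,
                 tags = tags)
}

#' Run the full exposure-by-outcome analysis grid
#'
#' For every configured exposure-outcome pair: select instruments,
#' harmonize, run the sensitivity battery, and write (1) `grid.tsv`, a
#' publication-shaped table rounded to 2 decimals for estimates/CIs and 2
#' significant figures for Egger intercepts, (2) `grid_full.json` at full
#' precision including exclusion logs, and (3) `run_log.json` recording the
#' package version, the resolved configuration and the seed. Outputs are
#' byte-identical across reruns with the same config and inputs. A pair that
#' fails validation is reported and skipped; its error is recorded in the
#' run log.
#'
#' @param config an `"analysis_config"`, or a path/list accepted by
#'   [analysis_config()].
#' @return Invisibly, the list of `"sensitivity_report"` objects.
#' @export
run_grid <- function(config) {
  config <- if (inherits(config, "analysis_config")) config
            else analysis_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tags <- if (!is.null(config$pleiotropy_tags))
    read.table(config$pleiotropy_tags, header = TRUE, sep = ",",
               stringsAsFactors = FALSE, quote = "\"")
  r2 <- if (!is.null(config$r2_file))
    read.table(config$r2_file, header = TRUE, sep = ",",
               stringsAsFactors = FALSE)

  reports <- list()
  failures <- list()
  rows <- list()
  for (ex in names(config$exposures)) {
    exposure <- tryCatch(read_configured_table(config$exposures[[ex]], ex),
                         error = function(e) e)
    if (inherits(exposure, "error")) {
      message("exposure ", ex, " failed: ", conditionMessage(exposure))
      failures[[ex]] <- conditionMessage(exposure)
      next
    }
    for (oc in names(config$outcomes)) {
      entry <- config$outcomes[[oc]]
      res <- tryCatch({
        outcome <- read_configured_table(entry, oc)
        iset <- build_instrument_set(
          exposure, outcome, ex, oc, tags = tags, r2 = r2,
          p_threshold = config$p_threshold,
          r2_threshold = config$r2_threshold)
        run_sensitivity(iset, config = list(
          binary = isTRUE(entry$binary), n_boot = config$n_boot,
          seed = config$seed, egger_variance = config$egger_variance))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        message("pair ", ex, " -> ", oc, " failed: ", conditionMessage(res))
        failures[[paste(ex, oc, sep = "->")]] <- conditionMessage(res)
        next
      }
      reports[[paste(ex, oc, sep = "->")]] <- res
      rows[[length(rows) + 1L]] <- report_table(res)
    }
  }
  grid <- do.call(rbind, rows)
  if (!is.null(grid)) {
    grid$estimate <- round(grid$estimate, 2)
    grid$ci_low <- round(grid$ci_low, 2)
    grid$ci_high <- round(grid$ci_high, 2)
    grid$egger_intercept <- signif(grid$egger_intercept, 2)
    grid$egger_intercept_p <- signif(grid$egger_intercept_p, 2)
    write.table(grid, file.path(config$out_dir, "grid.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  full <- lapply(reports, function(r) {
    lapply(r[!vapply(r, is.null, logical(1))], function(el)
      if (inherits(el, "mr_estimate")) unclass(el) else el)
  })
  jsonlite::write_json(full, file.path(config$out_dir, "grid_full.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  log <- list(package = "mrwald",
              version = as.character(packageVersion("mrwald")),
              seed = config$seed, n_boot = config$n_boot,
              p_threshold = config$p_threshold,
              r2_threshold = config$r2_threshold,
              egger_variance = config$egger_variance,
              pairs_run = names(reports), failures = failures)
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  if (length(failures))
    warning(length(failures), " pair(s) failed; see run_log.json",
            call. = FALSE)
  invisible(reports)
}

#' Summarize replicate simulations into bias/coverage statistics
#'
#' @param reps data.frame from [simulate_replicates()].
#' @param beta_causal the generating causal effect.
#' @return one-row data.frame: per-method means and biases, IVW coverage,
#'   and the Egger-intercept rejection rate at p < 0.05.
#' @export
summarize_replicates <- function(reps, beta_causal) {
  data.frame(
    reps = nrow(reps),
    beta_causal = beta_causal,
    ivw_mean = mean(reps$ivw), ivw_bias = mean(reps$ivw) - beta_causal,
    egger_mean = mean(reps$egger),
    egger_bias = mean(reps$egger) - beta_causal,
    wm_mean = mean(reps$wm, na.rm = TRUE),
    wm_bias = mean(reps$wm, na.rm = TRUE) - beta_causal,
    ivw_coverage = mean(reps$ivw_cover),
    egger_intercept_reject = mean(reps$egger_intercept_p < 0.05)
  )
}
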