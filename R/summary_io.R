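#' Construct a validated GWAS association table
#'
#' One row per SNP-trait association: effect/other allele, effect estimate
#' (log-odds for binary traits, trait units or proportional-change units for
#' continuous ones), its standard error and p-value, plus optional
#' effect-allele frequency and sample size. Rows violating the invariants
#' (non-positive SE, p outside (0,1], malformed or identical alleles) are
#' dropped, recorded in the `"rejected"` attribute, and reported with a
#' warning.
#'
#' @param snp_id character vector of rsIDs.
#' @param effect_allele,other_allele single upper-case nucleotides (A/C/G/T);
#'   `other_allele` may be `NA`.
#' @param beta,se numeric effect estimate per effect allele and its SE.
#' @param p_value numeric p-values in (0, 1].
#' @param eaf optional effect-allele frequency in \[0, 1\].
#' @param n optional sample size.
#' @param trait_id trait identifier attached to every row.
#' @return A `data.frame` of class `"gwas_assoc"` with attribute
#'   `"rejected"`: a data.frame (row, snp_id, reason) of dropped rows.
#' @export
gwas_assoc <- function(snp_id, effect_allele, beta, se, p_value,
                       other_allele = NA_character_, eaf = NA_real_,
                       n = NA_real_, trait_id = "") {
  k <- length(snp_id)
  x <- data.frame(
    snp_id = as.character(snp_id),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(rep_len(as.character(other_allele), k)),
    beta = as.numeric(beta),
    se = as.numeric(se),
    p_value = as.numeric(p_value),
    eaf = rep_len(as.numeric(eaf), k),
    n = rep_len(as.numeric(n), k),
    trait_id = rep_len(as.character(trait_id), k),
    stringsAsFactors = FALSE
  )
  validate_gwas_assoc(x)
}

NUCLEOTIDES <- c("A", "C", "G", "T")

# Row-level invariant screen; returns the clean table with a "rejected"
# attribute and warns once listing all offenders.
validate_gwas_assoc <- function(x) {
  reason <- rep(NA_character_, nrow(x))
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reason))
    reason[bad] <<- why
  }
  flag(is.na(x$snp_id) | !nzchar(x$snp_id), "missing SNP id")
  flag(!(x$effect_allele %in% NUCLEOTIDES), "invalid effect allele")
  flag(!is.na(x$other_allele) & !(x$other_allele %in% NUCLEOTIDES),
       "invalid other allele")
  flag(!is.na(x$other_allele) & x$other_allele == x$effect_allele,
       "identical alleles")
  flag(!is.finite(x$beta), "non-finite beta")
  flag(!is.finite(x$se) | x$se <= 0, "non-positive SE")
  flag(!is.finite(x$p_value) | x$p_value <= 0 | x$p_value > 1,
       "p-value outside (0,1]")
  flag(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1), "EAF outside [0,1]")

  bad <- which(!is.na(reason))
  rejected <- data.frame(row = bad, snp_id = x$snp_id[bad],
                         reason = reason[bad], stringsAsFactors = FALSE)
  if (length(bad)) {
    warning(sprintf("rejected %d row(s): %s", length(bad),
                    paste(sprintf("row %d (%s): %s", rejected$row,
                                  rejected$snp_id, rejected$reason),
                          collapse = "; ")),
            call. = FALSE)
    x <- x[-bad, , drop = FALSE]
    rownames(x) <- NULL
  }
  class(x) <- c("gwas_assoc", "data.frame")
  attr(x, "rejected") <- rejected
  x
}

#' Read a delimited GWAS summary-statistics table
#'
#' @param path delimited text file (delimiter sniffed from the header line
#'   unless `sep` is given).
#' @param column_map named character vector mapping the canonical field names
#'   (`snp_id`, `effect_allele`, `beta`, `se`, `p_value`; optionally
#'   `other_allele`, `eaf`, `n`) to column names in the file.
#' @param trait_id trait identifier attached to every row.
#' @param sep field delimiter; `NULL` to auto-detect tab vs comma.
#' @return A `"gwas_assoc"` table; see [gwas_assoc()] for row screening.
#'   A missing mandatory column is a configuration error; non-numeric
#'   beta/se/p entries are an error listing the offending rows.
#' @export
read_summary_table <- function(path, column_map, trait_id, sep = NULL) {
  if (!file.exists(path)) stop("summary table not found: ", path)
  mandatory <- c("snp_id", "effect_allele", "beta", "se", "p_value")
  missing_map <- setdiff(mandatory, names(column_map))
  if (length(missing_map))
    stop("column_map lacks mandatory field(s): ",
         paste(missing_map, collapse = ", "))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent))
    stop("mapped column(s) absent from ", path, ": ",
         paste(absent, collapse = ", "))

  pick <- function(field, default) {
    if (field %in% names(column_map)) raw[[column_map[[field]]]]
    else rep(default, nrow(raw))
  }
  num <- function(field, values) {
    v <- suppressWarnings(as.numeric(values))
    bad <- which(is.na(v) & !is.na(values) & nzchar(trimws(values)))
    if (length(bad))
      stop(sprintf("non-numeric %s in %s at row(s): %s", field, path,
                   paste(bad, collapse = ", ")))
    v
  }
  gwas_assoc(
    snp_id = pick("snp_id", NA_character_),
    effect_allele = pick("effect_allele", NA_character_),
    other_allele = pick("other_allele", NA_character_),
    beta = num("beta", pick("beta", NA)),
    se = num("se", pick("se", NA)),
    p_value = num("p_value", pick("p_value", NA)),
    eaf = num("eaf", pick("eaf", NA)),
    n = num("n", pick("n", NA)),
    trait_id = trait_id
  )
}

#' Write a GWAS association table as delimited text
#'
#' @param x a `"gwas_assoc"` table.
#' @param path output file; `sep` defaults to tab.
#' @export
write_summary_table <- function(x, path, sep = "\t") {
  write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Filter associations at a significance threshold
#'
#' Retains exactly the records with `p_value < threshold` (strict, matching
#' the conventional genome-wide cut p < 5e-8), preserving input order.
#'
#' @param assocs a `"gwas_assoc"` table.
#' @param threshold p-value threshold in (0, 1).
#' @export
significance_filter <- function(assocs, threshold = 5e-8) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1 || threshold == 1)
  keep <- assocs$p_value < threshold
  out <- assocs[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    message("significance_filter: no record passes p < ", threshold)
  class(out) <- class(assocs)
  out
}

r2_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# Pairwise r2 lookup table from a (snp_a, snp_b, r2) data.frame.
# Absent pairs mean r2 = 0; values outside [0,1] are a validation error.
build_r2_lookup <- function(r2) {
  if (is.null(r2) || nrow(r2) == 0L)
    return(function(a, b) 0)
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(r2)))
  if (any(!is.finite(r2$r2) | r2$r2 < 0 | r2$r2 > 1))
    stop("r2 values must lie in [0, 1]")
  tab <- setNames(r2$r2, r2_key(r2$snp_a, r2$snp_b))
  function(a, b) {
    v <- tab[r2_key(a, b)]
    ifelse(is.na(v), 0, unname(v))
  }
}

#' Greedy LD pruning of an instrument list
#'
#' Discards SNPs highly correlated (r2 at or above `r2_threshold`) with a
#' better instrument, keeping the SNP with the smaller p-value and/or larger
#' effect. SNPs are processed in ascending p-value order (ties broken by
#' descending |beta|, then lexicographic rsID) and kept iff their r2 with
#' every already-kept SNP is below the threshold, so the result does not
#' depend on input row order.
#'
#' @param assocs a `"gwas_assoc"` table.
#' @param r2 data.frame with columns `snp_a`, `snp_b`, `r2` giving symmetric
#'   pairwise r2; absent pairs are treated as r2 = 0. `NULL` means all
#'   independent.
#' @param r2_threshold discard threshold, default 0.8.
#' @return The kept records in processing (ascending p-value) order, with
#'   attribute `"exclusion_log"`: data.frame (snp_id, reason, displaced_by).
#' @export
ld_prune <- function(assocs, r2 = NULL, r2_threshold = 0.8) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  lookup <- build_r2_lookup(r2)
  ord <- order(assocs$p_value, -abs(assocs$beta), assocs$snp_id)
  x <- assocs[ord, , drop = FALSE]
  kept <- integer(0)
  log <- data.frame(snp_id = character(), reason = character(),
                    displaced_by = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(x))) {
    rr <- if (length(kept)) lookup(x$snp_id[i], x$snp_id[kept]) else numeric(0)
    hit <- which(rr >= r2_threshold)
    if (length(hit)) {
      by <- x$snp_id[kept[hit[1L]]]
      log <- rbind(log, data.frame(
        snp_id = x$snp_id[i],
        reason = sprintf("ld:r2=%.3g>=%.3g with %s", rr[hit[1L]],
                         r2_threshold, by),
        displaced_by = by, stringsAsFactors = FALSE))
    } else {
      kept <- c(kept, i)
    }
  }
  out <- x[kept, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(assocs)
  attr(out, "exclusion_log") <- log
  out
}

is_palindromic <- function(a, b) {
  !is.na(a) & !is.na(b) &
    ((a == "A" & b == "T") | (a == "T" & b == "A") |
       (a == "C" & b == "G") | (a == "G" & b == "C"))
}

#' Harmonize exposure and outcome associations to a common effect allele
#'
#' For every exposure SNP found in the outcome table, aligns the outcome beta
#' to the exposure's effect allele: copied when the effect alleles already
#' match, sign-flipped when the outcome effect allele equals the exposure
#' other allele. Palindromic SNPs (A/T or C/G) cannot be strand-resolved from
#' letters alone; they are harmonized by letters and flagged with a warning.
#' Exposure SNPs absent from the outcome table are reported in the
#' `"missing"` attribute, never silently dropped. An allele pair that is
#' neither a match nor a swap is an error naming the SNP. A missing outcome
#' other allele is tolerated when the effect alleles already match.
#'
#' @param exposure,outcome `"gwas_assoc"` tables keyed by `snp_id`.
#' @return A `data.frame` of class `"harmonized"` with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `gamma_hat`, `se_gamma`,
#'   `big_gamma_hat`, `se_big_gamma`, `palindromic`; attribute `"missing"`
#'   lists exposure SNPs without an outcome record.
#' @export
harmonize <- function(exposure, outcome) {
  if (anyDuplicated(exposure$snp_id))
    stop("duplicate snp_id in exposure table")
  idx <- match(exposure$snp_id, outcome$snp_id)
  present <- !is.na(idx)
  missing <- data.frame(snp_id = exposure$snp_id[!present],
                        reason = rep("missing_in_outcome", sum(!present)),
                        stringsAsFactors = FALSE)
  e <- exposure[present, , drop = FALSE]
  o <- outcome[idx[present], , drop = FALSE]

  flip <- logical(nrow(e))
  for (i in seq_len(nrow(e))) {
    ee <- e$effect_allele[i]; eo <- e$other_allele[i]
    oe <- o$effect_allele[i]; oo <- o$other_allele[i]
    if (oe == ee) {
      if (!is.na(oo) && !is.na(eo) && oo != eo)
        stop("allele mismatch for ", e$snp_id[i], ": exposure ", ee, "/", eo,
             " vs outcome ", oe, "/", oo)
      flip[i] <- FALSE
    } else if (!is.na(eo) && oe == eo) {
      if (!is.na(oo) && oo != ee)
        stop("allele mismatch for ", e$snp_id[i], ": exposure ", ee, "/", eo,
             " vs outcome ", oe, "/", oo)
      flip[i] <- TRUE
    } else {
      stop("allele mismatch for ", e$snp_id[i], ": outcome allele ", oe,
           " is neither the exposure effect (", ee, ") nor other (",
           ifelse(is.na(eo), "?", eo), ") allele")
    }
  }
  pal <- is_palindromic(e$effect_allele, e$other_allele)
  if (any(pal))
    warning("palindromic SNP(s) harmonized by allele letters alone: ",
            paste(e$snp_id[pal], collapse = ", "), call. = FALSE)

  out <- data.frame(
    snp_id = e$snp_id,
    effect_allele = e$effect_allele,
    other_allele = e$other_allele,
    gamma_hat = e$beta,
    se_gamma = e$se,
    big_gamma_hat = ifelse(flip, -o$beta, o$beta),
    se_big_gamma = o$se,
    palindromic = pal,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("harmonized", "data.frame")
  attr(out, "missing") <- missing
  out
}

#' Bundle harmonized instruments for one exposure-outcome pair
#'
#' @param exposure_id,outcome_id identifiers for the pair.
#' @param instruments a `"harmonized"` table.
#' @param exclusion_log data.frame (snp_id, reason) accumulating every SNP
#'   removed upstream (LD pruning, missing outcome records, pleiotropy);
#'   together with `instruments` it accounts for every input SNP.
#' @param tags optional pleiotropy annotation data.frame with columns
#'   `snp_id`, `outcome_id` and optionally `gene_label`; attaches per-SNP
#'   tag sets and gene labels to the instruments.
#' @return An object of class `"instrument_set"`.
#' @export
instrument_set <- function(exposure_id, outcome_id, instruments,
                           exclusion_log = NULL, tags = NULL) {
  if (anyDuplicated(instruments$snp_id))
    stop("duplicate snp_id in instrument set")
  stopifnot(all(instruments$se_gamma > 0), all(instruments$se_big_gamma > 0))
  instruments$pleiotropy_tags <- rep(list(character(0)),
                                     nrow(instruments))
  if (!("gene_label" %in% names(instruments)))
    instruments$gene_label <- NA_character_
  if (!is.null(tags) && nrow(tags)) {
    for (i in seq_len(nrow(instruments))) {
      hit <- tags$snp_id == instruments$snp_id[i]
      instruments$pleiotropy_tags[[i]] <- unique(tags$outcome_id[hit])
      if (any(hit) && "gene_label" %in% names(tags))
        instruments$gene_label[i] <- tags$gene_label[which(hit)[1L]]
    }
  }
  structure(list(
    exposure_id = exposure_id,
    outcome_id = outcome_id,
    instruments = instruments,
    exclusion_log = exclusion_log %||% empty_exclusion_log()
  ), class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s -> %s: %d instrument(s), %d excluded\n",
              x$exposure_id, x$outcome_id, nrow(x$instruments),
              nrow(x$exclusion_log)))
  invisible(x)
}

#' Remove instruments annotated as directly associated with the outcome
#'
#' Drops every instrument whose pleiotropy tags contain `outcome_id`,
#' appending each removal to the exclusion log with reason
#' `"pleiotropy:<outcome_id>"`. An empty result is allowed.
#'
#' @param set an `"instrument_set"` whose instruments carry pleiotropy tags.
#' @param outcome_id tag to match; defaults to the set's own outcome.
#' @export
exclude_pleiotropic <- function(set, outcome_id = set$outcome_id) {
  stopifnot(inherits(set, "instrument_set"))
  tagged <- vapply(set$instruments$pleiotropy_tags,
                   function(t) outcome_id %in% t, logical(1))
  set$exclusion_log <- add_exclusions(set$exclusion_log,
                                      set$instruments$snp_id[tagged],
                                      paste0("pleiotropy:", outcome_id))
  set$instruments <- set$instruments[!tagged, , drop = FALSE]
  rownames(set$instruments) <- NULL
  set
}
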