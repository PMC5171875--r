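# Instrument panels mirroring the published liver-enzyme analysis: 4 ALT,
# 14 ALP and 26 GGT SNPs, with rs2954021 (TRIB1) shared by ALT and ALP.
# rsIDs known from the published exclusion footnotes (and the four ALT SNPs)
# are real; the remaining ALP/GGT rsIDs are synthetic placeholders in the
# rs9xxxxxxx range. All betas/SEs are synthetic throughout.
fixture_panels <- function() {
  alt <- data.frame(
    snp_id = c("rs738409", "rs2954021", "rs6834314", "rs10883437"),
    gene_label = c("PNPLA3", "TRIB1", "MAPK10, HSD17B1", "CPN1"),
    stringsAsFactors = FALSE)
  alp <- data.frame(
    snp_id = c("rs174601", "rs314253", "rs2954021", "rs579459", "rs6984305",
               sprintf("rs9100%04d", 1:9)),
    gene_label = c("C11orf10, FADS1, FADS2", "ASGR1, DLG4", "TRIB1", "ABO",
                   "PPP1R3B", rep("synthetic", 9)),
    stringsAsFactors = FALSE)
  ggt <- data.frame(
    snp_id = c("rs516246", "rs7310409", "rs1260326",
               sprintf("rs9200%04d", 1:23)),
    gene_label = c("FUT2", "HNF1A", "C2orf16, GCKR", rep("synthetic", 23)),
    stringsAsFactors = FALSE)
  list(alt = alt, alp = alp, ggt = ggt)
}

# Pleiotropy annotations transcribed from the published exclusion lists:
# which instruments are directly associated with which outcome, per the
# phenotype cross-reference the analysis consulted. One row per
# (SNP, outcome).
fixture_tags <- function() {
  cad <- data.frame(
    snp_id = c("rs2954021", "rs174601", "rs314253", "rs579459", "rs6984305",
               "rs516246", "rs7310409", "rs1260326"),
    gene_label = c("TRIB1", "C11orf10, FADS1, FADS2", "ASGR1, DLG4", "ABO",
                   "PPP1R3B", "FUT2", "HNF1A", "C2orf16, GCKR"),
    stringsAsFactors = FALSE)
  diab <- data.frame(
    snp_id = c("rs2954021", "rs516246", "rs1260326"),
    gene_label = c("TRIB1", "FUT2", "C2orf16, GCKR"),
    stringsAsFactors = FALSE)
  expand <- function(base, outcomes, source) {
    do.call(rbind, lapply(outcomes, function(o)
      data.frame(snp_id = base$snp_id, outcome_id = o,
                 gene_label = base$gene_label, source = source,
                 stringsAsFactors = FALSE)))
  }
  rbind(
    expand(cad, c("cad_hapmap", "cad_1000g"), "cad_mi"),
    expand(diab, "t2dm", "diabetes"),
    expand(cad, c("ldl", "hdl", "tg"), "lipids"),
    expand(diab, c("hba1c", "fg", "homa_ir", "homa_b"), "glycemic")
  )
}

fixture_outcomes <- function() {
  data.frame(
    outcome_id = c("cad_hapmap", "cad_1000g", "t2dm", "ldl", "hdl", "tg",
                   "hba1c", "fg", "homa_ir", "homa_b"),
    binary = c(TRUE, TRUE, TRUE, rep(FALSE, 7)),
    stringsAsFactors = FALSE)
}

#' Write the packaged liver-enzyme fixture
#'
#' Generates a download-free analysis fixture mirroring the structure of the
#' published liver-enzyme study: exposure instrument tables for ALT (4
#' SNPs), ALP (14) and GGT (26) with rs2954021 (TRIB1) shared by ALT and
#' ALP; synthetic outcome tables for ten outcomes (two CAD/MI panels, T2DM,
#' three lipids, four glycemic traits); the pleiotropy-tag file transcribed
#' from the published exclusion lists; and a ready-to-run grid configuration.
#' Betas and SEs are synthetic (drawn under a small nominal causal effect),
#' so the fixture tests plumbing and bookkeeping, not published effect
#' sizes.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the synthetic betas.
#' @return Invisibly, the path to the written `config.yaml`.
#' @export
make_fixture <- function(dir, seed = 20161220L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panels <- fixture_panels()
  tags <- fixture_tags()
  outs <- fixture_outcomes()

  with_seed(seed, {
    # one allele assignment per unique rsID so the SNP shared by ALT and
    # ALP carries consistent alleles everywhere; non-palindromic pairs so
    # letter-based harmonization is exact
    uniq <- unique(unlist(lapply(panels, `[[`, "snp_id")))
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    pool <- c("A", "C", "G", "T")
    ea <- sample(pool, length(uniq), replace = TRUE)
    oa <- vapply(ea, function(a)
      sample(setdiff(pool, c(a, comp[[a]])), 1L), character(1))
    names(ea) <- names(oa) <- uniq

    # exposure tables: strong instruments in proportional-change units
    all_snps <- list()
    for (enz in names(panels)) {
      p <- panels[[enz]]
      k <- nrow(p)
      gamma <- runif(k, 0.04, 0.12)
      se <- gamma / runif(k, 8, 14)          # z in [8,14]: all pass 5e-8
      tab <- data.frame(
        rsid = p$snp_id,
        effect_allele = unname(ea[p$snp_id]),
        other_allele = unname(oa[p$snp_id]),
        beta = round(gamma, 5), se = round(se, 5),
        pval = signif(2 * pnorm(-gamma / se), 3),
        gene = p$gene_label, stringsAsFactors = FALSE)
      tab <- tab[, c("rsid", "effect_allele", "other_allele", "beta", "se",
                     "pval", "gene")]
      write.table(tab, file.path(dir, paste0("exposure_", enz, ".csv")),
                  sep = ",", row.names = FALSE, quote = TRUE)
      all_snps[[enz]] <- tab
    }
    # one outcome table per outcome, covering the union of instruments
    union_tab <- do.call(rbind, all_snps)
    union_tab <- union_tab[!duplicated(union_tab$rsid), , drop = FALSE]
    for (i in seq_len(nrow(outs))) {
      k <- nrow(union_tab)
      se_out <- if (outs$binary[i]) 0.02 else 0.015
      b_out <- 0.2 * union_tab$beta + rnorm(k, 0, se_out)
      flip <- runif(k) < 0.5
      otab <- data.frame(
        rsid = union_tab$rsid,
        effect_allele = ifelse(flip, union_tab$other_allele,
                               union_tab$effect_allele),
        other_allele = ifelse(flip, union_tab$effect_allele,
                              union_tab$other_allele),
        beta = round(ifelse(flip, -b_out, b_out), 5),
        se = se_out,
        pval = signif(2 * pnorm(-abs(b_out) / se_out), 3),
        stringsAsFactors = FALSE)
      write.table(otab,
                  file.path(dir, paste0("outcome_", outs$outcome_id[i],
                                        ".csv")),
                  sep = ",", row.names = FALSE, quote = FALSE)
    }
  })
  write.table(tags, file.path(dir, "pleiotropy_tags.csv"), sep = ",",
              row.names = FALSE, quote = TRUE)

  cols <- list(snp_id = "rsid", effect_allele = "effect_allele",
               other_allele = "other_allele", beta = "beta", se = "se",
               p_value = "pval")
  config <- list(
    exposures = setNames(lapply(names(panels), function(enz)
      list(path = paste0("exposure_", enz, ".csv"), columns = cols)),
      names(panels)),
    outcomes = setNames(lapply(seq_len(nrow(outs)), function(i)
      list(path = paste0("outcome_", outs$outcome_id[i], ".csv"),
           binary = outs$binary[i], columns = cols)),
      outs$outcome_id),
    pleiotropy_tags = "pleiotropy_tags.csv",
    r2_threshold = 0.8, p_threshold = 5e-8,
    n_boot = 1000L, seed = 42L, egger_variance = "none",
    out_dir = "results")
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}
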