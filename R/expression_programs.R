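# NRF2 pathway-activation scoring and enrichment, splice-variant filtering,
# MSI classification and TCR-diversity group comparison.

#' Default NRF2 target-gene signature
#'
#' A 27-gene set of canonical NFE2L2 downstream targets (oxidative-stress
#' response, glutathione and NADPH metabolism, aldo-keto reductases) used as
#' the default activation signature; override via the `signature_genes`
#' argument or the pipeline config when a study-specific list is available.
#' @return character vector of 27 gene symbols.
#' @export
nrf2_default_signature <- function() {
  c("NQO1", "GCLC", "GCLM", "GSTP1", "TXNRD1", "TXN", "SLC7A11", "FTL",
    "FTH1", "HMOX1", "G6PD", "PGD", "TALDO1", "TKT", "ME1", "IDH1",
    "SRXN1", "PRDX1", "GPX2", "ABCC1", "AKR1B10", "AKR1C1", "AKR1C2",
    "CBR1", "ADH7", "ALDH3A1", "UGT1A6")
}

#' NRF2 pathway-activation score and class
#'
#' Per-gene z-scores across samples are summed over the signature genes
#' present in the matrix; samples with a score strictly greater than the
#' threshold are classified NRF2+. The score is invariant to affine rescaling
#' of each gene's expression row. Zero-variance genes contribute 0 and are
#' flagged; signature genes absent from the matrix are reported.
#'
#' @param expr numeric matrix, genes x samples (any monotone normalised
#'   scale), no missing values.
#' @param signature_genes character vector (default the bundled 27-gene set).
#' @param threshold activation cut-off, strict `>` (default 15).
#' @return an object of class `nrf2_result`: list with `score` (named numeric
#'   per sample), `class` (`"NRF2+"`/`"NRF2-"`), `signature_genes`,
#'   `genes_used`, `missing_genes`, `zero_variance_genes`, `threshold`.
#' @export
nrf2_score <- function(expr, signature_genes = nrf2_default_signature(),
                       threshold = 15) {
  if (anyNA(expr)) .stopf("expression matrix contains missing values")
  if (ncol(expr) < 2L) .stopf("z-scores require at least 2 samples")
  present <- intersect(signature_genes, rownames(expr))
  if (!length(present)) .stopf("no signature gene present in the matrix")
  missing <- setdiff(signature_genes, present)
  sub <- expr[present, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, stats::sd)
  zero_var <- rownames(sub)[sdv == 0]
  sdv[sdv == 0] <- Inf # zero-variance gene contributes z = 0
  z <- sweep(sweep(sub, 1, mu, "-"), 1, sdv, "/")
  score <- colSums(z)
  structure(list(score = score,
                 class = ifelse(score > threshold, "NRF2+", "NRF2-"),
                 signature_genes = signature_genes, genes_used = present,
                 missing_genes = missing, zero_variance_genes = zero_var,
                 threshold = threshold),
            class = "nrf2_result")
}

#' Mutation enrichment among NRF2+ samples
#'
#' For each candidate gene, cross-tabulates samples by mutation status and
#' NRF2 class and applies [fisher_exact_2x2()]; q-values are
#' Benjamini-Hochberg over the candidate list. Genes unmutated everywhere are
#' retained with `p = 1`.
#'
#' @param classes named character vector (`"NRF2+"`/`"NRF2-"`) per sample,
#'   e.g. `nrf2_score(...)$class`; must contain at least 2 samples per class.
#' @param cohort a `gbc_cohort`.
#' @param candidate_genes character vector of genes to test.
#' @return data frame (`gene_symbol`, `mut_pos`, `mut_neg`, `wt_pos`,
#'   `wt_neg`, `odds_ratio`, `p`, `q`) sorted by `p`.
#' @export
nrf2_enrichment <- function(classes, cohort, candidate_genes) {
  ids <- intersect(names(classes), cohort$samples$sample_id)
  classes <- classes[ids]
  if (sum(classes == "NRF2+") < 2L || sum(classes == "NRF2-") < 2L)
    .stopf("need at least 2 samples in each NRF2 class")
  m <- cohort$mutations
  rows <- lapply(candidate_genes, function(g) {
    mut <- ids %in% m$sample_id[m$gene_symbol == g]
    pos <- classes == "NRF2+"
    ct <- fisher_exact_2x2(sum(mut & pos), sum(mut & !pos),
                           sum(!mut & pos), sum(!mut & !pos))
    data.frame(gene_symbol = g,
               mut_pos = sum(mut & pos), mut_neg = sum(mut & !pos),
               wt_pos = sum(!mut & pos), wt_neg = sum(!mut & !pos),
               odds_ratio = ct$odds_ratio, p = ct$p_two_sided,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter splice variants by expression, usage and normal-panel absence
#'
#' PSI values with supporting denominator below `psi_min_denominator` are set
#' to `NA` first. A variant is kept iff (i) at least one tumour sample has
#' `FPKM > fpkm_min` and non-missing `PSI > psi_min`, (ii) the fraction of
#' normal-panel samples with zero FPKM exceeds `panel_zero_fraction`, and
#' (iii) it carries no alternative-start, alternative-end or retained-intron
#' flag. The filter is idempotent and order-independent.
#'
#' @param records long-format data frame, one row per (variant, tumour
#'   sample): columns `variant_id`, `gene`, `sample_id`, `fpkm`, `psi`,
#'   `psi_denominator`, `panel_zero_fraction`, `event_flags`
#'   (comma-separated subset of `alt_start`, `alt_end`, `retained_intron`;
#'   empty for none).
#' @param config an [analysis_config()] supplying the thresholds.
#' @return the rows of `records` belonging to kept variants (with PSI
#'   nullification applied), sorted by `variant_id` then `sample_id`.
#' @export
filter_splice_variants <- function(records, config = analysis_config()) {
  if (!nrow(records)) return(records)
  records$psi <- as.numeric(records$psi)
  records$fpkm <- as.numeric(records$fpkm)
  records$psi[as.integer(records$psi_denominator) < config$psi_min_denominator] <- NA
  keep_variant <- vapply(split(records, records$variant_id), function(d) {
    flags <- setdiff(trimws(unlist(strsplit(d$event_flags, ","))), "")
    if (length(flags)) return(FALSE)
    if (!all(as.numeric(d$panel_zero_fraction) > config$panel_zero_fraction))
      return(FALSE)
    any(d$fpkm > config$fpkm_min & !is.na(d$psi) & d$psi > config$psi_min)
  }, TRUE)
  out <- records[records$variant_id %in% names(keep_variant)[keep_variant], ,
                 drop = FALSE]
  out <- out[order(out$variant_id, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify microsatellite instability from instability scores
#'
#' A sample is MSI iff its score strictly exceeds the threshold (default
#' 0.35, the recommended whole-exome operating point of score-based MSI
#' callers).
#'
#' @param scores named non-negative numeric vector, sample -> score.
#' @param threshold cut-off, strict `>` (default 0.35).
#' @return data frame (`sample_id`, `mantis_score`, `msi`).
#' @export
classify_msi <- function(scores, threshold = 0.35) {
  if (any(!is.finite(scores)) || any(scores < 0))
    .stopf("MSI scores must be non-negative")
  data.frame(sample_id = names(scores), mantis_score = as.numeric(scores),
             msi = as.numeric(scores) > threshold, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Compare TCR repertoire diversity between two groups
#'
#' Shannon entropy per sample ([shannon_entropy()]), compared between groups
#' with a two-sided Mann-Whitney test.
#'
#' @param clonotypes named list sample -> clonotype counts.
#' @param group_assignment named character vector sample -> group label (two
#'   levels, at least 2 samples each).
#' @return list with `entropy` (data frame `sample_id`, `group`, `entropy`),
#'   `p_two_sided`, and the two `groups`.
#' @export
compare_entropy_groups <- function(clonotypes, group_assignment) {
  ids <- intersect(names(clonotypes), names(group_assignment))
  groups <- sort(unique(group_assignment[ids]))
  if (length(groups) != 2L) .stopf("exactly two groups required")
  ent <- data.frame(sample_id = ids, group = unname(group_assignment[ids]),
                    entropy = vapply(ids, function(s)
                      shannon_entropy(clonotypes[[s]]), 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  nn <- table(ent$group)
  if (any(nn < 2L)) .stopf("each group needs at least 2 samples")
  p <- mann_whitney_u(ent$entropy[ent$group == groups[1]],
                      ent$entropy[ent$group == groups[2]])
  list(entropy = ent, p_two_sided = p, groups = groups)
}
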