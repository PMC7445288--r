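# Exact 2x2 statistics, FDR, diversity, hotspot and meta-hotspot detection,
# gene-significance q-scores, co-occurrence, and the truncating-fraction
# randomization test.

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the point-probability rule: the sum of hypergeometric
#' probabilities (margins fixed) of every table at most as probable as the
#' observed one, with the customary `1 + 1e-7` relative tolerance. The odds
#' ratio is the cross-product `(a d)/(b c)`; when any cell is zero, 0.5 is
#' added to every cell (Haldane-Anscombe) and the result flagged.
#'
#' @param a,b,c,d non-negative integer cell counts, rows = groups,
#'   columns = outcome (table `a, b / c, d`).
#' @return an object of class `contingency_result`: list with `table`,
#'   `odds_ratio`, `p_two_sided`, and `haldane` (zero-cell correction flag).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (!all(vapply(cells, .is_count, TRUE)))
    .stopf("cells must be non-negative integers")
  if (sum(cells) == 0) .stopf("all-zero 2x2 table")
  tab <- matrix(as.integer(cells), 2L, 2L, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  haldane <- any(cells == 0)
  x <- if (haldane) cells + 0.5 else cells
  or <- (x[1] * x[4]) / (x[2] * x[3])
  structure(list(table = tab, odds_ratio = or, p_two_sided = min(p, 1),
                 haldane = haldane),
            class = "contingency_result")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with enforced monotonicity, order-preserving.
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order (`q >= p` elementwise).
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null distribution for small samples (combined n <= 20, no ties),
#' normal approximation with tie correction otherwise.
#' @param x,y numeric vectors, both non-empty.
#' @return two-sided p-value.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) .stopf("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  suppressWarnings(stats::wilcox.test(x, y, exact = exact)$p.value)
}

#' Shannon diversity of a clonotype repertoire
#'
#' `H = -sum p_i ln p_i` over clonotype frequencies; zero-count clonotypes are
#' ignored. Natural-log units (nats).
#' @param counts non-negative clonotype counts with positive total.
#' @return Shannon index in nats.
#' @export
shannon_entropy <- function(counts) {
  if (any(counts < 0)) .stopf("counts must be non-negative")
  if (sum(counts) <= 0) .stopf("total clonotype count must be positive")
  as.numeric(vegan::diversity(counts[counts > 0], index = "shannon"))
}

#' Detect recurrent hotspot codons
#'
#' A hotspot is a (gene, codon) position carrying protein-altering mutations
#' in at least `min_samples` distinct samples. Codon positions follow
#' [mutation_codon()]; synonymous mutations are ignored.
#'
#' @param cohort a `gbc_cohort`.
#' @param min_samples minimum distinct mutated samples (default from config).
#' @return data frame (`gene_symbol`, `protein_pos`, `n_samples`,
#'   `consequences`) sorted by `n_samples` descending, then gene, then codon.
#' @export
detect_hotspots <- function(cohort, min_samples = cohort$config$hotspot_min_samples) {
  ann <- annotate_consequences(cohort)
  ann <- ann[ann$consequence != "synonymous", , drop = FALSE]
  if (!nrow(ann))
    return(data.frame(gene_symbol = character(), protein_pos = integer(),
                      n_samples = integer(), consequences = character(),
                      stringsAsFactors = FALSE))
  key <- paste(ann$gene_symbol, ann$protein_pos, sep = "\r")
  agg <- lapply(split(ann, key), function(d)
    data.frame(gene_symbol = d$gene_symbol[1], protein_pos = d$protein_pos[1],
               n_samples = length(unique(d$sample_id)),
               consequences = paste(sort(d$consequence), collapse = ","),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  out <- out[out$n_samples >= min_samples, , drop = FALSE]
  out <- out[order(-out$n_samples, out$gene_symbol, out$protein_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate every mutation with its consequence and codon
#'
#' @param cohort a `gbc_cohort`.
#' @return the mutation table with `consequence` and `protein_pos` columns.
#' @export
annotate_consequences <- function(cohort) {
  m <- cohort$mutations
  cons <- character(nrow(m))
  ov <- !is.na(m$consequence_override) &
    !m$consequence_override %in% c("", ".")
  cons[ov] <- m$consequence_override[ov]
  todo <- which(!ov)
  snv <- todo[m$mutation_type[todo] == "SNV"]
  # SNVs classified vectorised per gene by codon comparison (same rules as
  # classify_consequence); indels are few and go through the scalar path.
  for (gene in unique(m$gene_symbol[snv])) {
    idx <- snv[m$gene_symbol[snv] == gene]
    cds <- cohort$gene_models[[gene]]$cds_sequence
    pos <- m$cds_pos[idx]
    at <- pos - (pos - 1L) %% 3L
    wt_codon <- substring(cds, at, at + 2L)
    rel <- pos - at + 1L
    mt_codon <- paste0(substring(wt_codon, 1L, rel - 1L), m$alt_base[idx],
                       substring(wt_codon, rel + 1L, 3L))
    wt_aa <- unname(Biostrings::GENETIC_CODE[wt_codon])
    mt_aa <- unname(Biostrings::GENETIC_CODE[mt_codon])
    cons[idx] <- ifelse(at == 1L & mt_codon != "ATG", "start_lost",
                 ifelse(wt_aa == mt_aa, "synonymous",
                 ifelse(mt_aa == "*", "nonsense",
                 ifelse(wt_aa == "*", "stop_lost", "missense"))))
  }
  indel <- todo[m$mutation_type[todo] != "SNV"]
  for (i in indel)
    cons[i] <- classify_consequence(m[i, ], cohort$gene_models[[m$gene_symbol[i]]])
  m$consequence <- cons
  m$protein_pos <- if (nrow(m)) mutation_codon(m) else integer(0)
  m
}

#' Match cohort mutations against a hotspot catalog
#'
#' Pan-cancer meta-hotspot matching by exact (gene, codon) position.
#' @param cohort a `gbc_cohort`.
#' @param catalog data frame with columns `gene`, `codon` (and optionally
#'   `label`), e.g. from [read_hotspot_catalog()].
#' @return data frame of matched sites (`gene_symbol`, `protein_pos`, `label`,
#'   `n_samples`, `mutation_ids`).
#' @export
match_meta_hotspots <- function(cohort, catalog) {
  ann <- annotate_consequences(cohort)
  ann <- ann[ann$consequence != "synonymous", , drop = FALSE]
  if (is.null(catalog$label)) catalog$label <- ""
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    hit <- ann[ann$gene_symbol == catalog$gene[i] &
               ann$protein_pos == as.integer(catalog$codon[i]), , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    data.frame(gene_symbol = catalog$gene[i],
               protein_pos = as.integer(catalog$codon[i]),
               label = catalog$label[i],
               n_samples = length(unique(hit$sample_id)),
               mutation_ids = paste(sort(hit$mutation_id), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_symbol = character(), protein_pos = integer(),
                      label = character(), n_samples = integer(),
                      mutation_ids = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a hotspot catalog TSV (`gene`, `codon`, optional `label`)
#' @param path TSV file.
#' @return data frame.
#' @export
read_hotspot_catalog <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("gene", "codon"), path)
  df$codon <- as.integer(df$codon)
  df
}

#' Gene mutational significance (Poisson background q-score)
#'
#' A deliberately simple background model: the cohort-wide protein-altering
#' mutation rate per CDS base (MSI samples optionally excluded, given their
#' outlier burden) gives each gene an expected count proportional to its CDS
#' length; the per-gene p-value is the Poisson upper tail of the observed
#' protein-altering count, q-values are Benjamini-Hochberg, and
#' `q_score = -log10(q)`. Genes with `q_score >= qscore_min` are flagged as
#' significantly mutated (SMG).
#'
#' @param cohort a `gbc_cohort`.
#' @param exclude_msi drop samples whose MSI score exceeds the configured
#'   threshold before estimating the background (default `TRUE`).
#' @return data frame (`gene_symbol`, `observed`, `expected`, `p`, `q`,
#'   `q_score`, `smg`) sorted by `p`.
#' @export
gene_significance <- function(cohort, exclude_msi = TRUE) {
  genes <- names(cohort$gene_models)
  if (!length(genes))
    return(data.frame(gene_symbol = character(), observed = integer(),
                      expected = numeric(), p = numeric(), q = numeric(),
                      q_score = numeric(), smg = logical(),
                      stringsAsFactors = FALSE))
  ann <- annotate_consequences(cohort)
  ann <- ann[ann$consequence != "synonymous", , drop = FALSE]
  if (exclude_msi && !is.null(cohort$msi_scores)) {
    msi <- names(cohort$msi_scores)[cohort$msi_scores > cohort$config$msi_threshold]
    ann <- ann[!ann$sample_id %in% msi, , drop = FALSE]
  }
  lens <- vapply(cohort$gene_models, function(g) nchar(g$cds_sequence), 0)
  total <- nrow(ann)
  observed <- vapply(genes, function(g) sum(ann$gene_symbol == g), 0L)
  expected <- if (total == 0) rep(0, length(genes)) else
    total * lens[genes] / sum(lens)
  p <- ifelse(expected == 0 | total == 0, 1,
              stats::ppois(observed - 1L, expected, lower.tail = FALSE))
  q <- bh_fdr(p)
  out <- data.frame(gene_symbol = genes, observed = observed,
                    expected = expected, p = p, q = q,
                    q_score = -log10(q),
                    smg = -log10(q) >= cohort$config$qscore_min,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mutation co-occurrence between two genes
#'
#' Cross-tabulates samples by mutated/not-mutated status in each gene and
#' applies [fisher_exact_2x2()]. Table orientation: rows = gene A status
#' (mutated first), columns = gene B status (mutated first).
#'
#' @param cohort a `gbc_cohort`.
#' @param geneA,geneB gene symbols present in the cohort.
#' @return a `contingency_result`.
#' @export
cooccurrence <- function(cohort, geneA, geneB) {
  for (g in c(geneA, geneB))
    if (!g %in% names(cohort$gene_models)) .stopf("gene '%s' not in cohort", g)
  m <- cohort$mutations
  inA <- cohort$samples$sample_id %in% m$sample_id[m$gene_symbol == geneA]
  inB <- cohort$samples$sample_id %in% m$sample_id[m$gene_symbol == geneB]
  fisher_exact_2x2(sum(inA & inB), sum(inA & !inB),
                   sum(!inA & inB), sum(!inA & !inB))
}

# Cohort six-type SNV substitution frequencies (pyrimidine-collapsed), used
# as the null substitution distribution for the randomization test.
.six_type_freqs <- function(cohort) {
  types <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  m <- cohort$mutations
  snv <- m[m$mutation_type == "SNV", , drop = FALSE]
  counts <- stats::setNames(rep(0, 6), types)
  comp <- function(b) chartr("ACGT", "TGCA", b)
  for (i in seq_len(nrow(snv))) {
    r <- snv[i, ]; ref <- r$ref_base; alt <- r$alt_base
    if (ref %in% c("A", "G")) { ref <- comp(ref); alt <- comp(alt) }
    key <- paste0(ref, ">", alt)
    counts[key] <- counts[key] + 1
  }
  if (sum(counts) == 0) counts[] <- 1 # uniform fallback for indel-only cohorts
  counts / sum(counts)
}

#' Monte Carlo test for an excess of truncating mutations in a gene
#'
#' The observed statistic is the fraction of the gene's mutations that are
#' truncating (frameshift, nonsense, or splice override). Each null draw
#' re-places the same number of mutations at uniform-random CDS positions
#' (indels keep their type and length; SNV substitution types are drawn from
#' the cohort's six-type frequencies conditioned on the reference base at the
#' drawn site), re-classifies consequences, and recomputes the fraction. The
#' empirical p-value is `(1 + #\{null >= observed\}) / (1 + n_iter)`.
#'
#' @param gene gene symbol with at least one mutation in the cohort.
#' @param cohort a `gbc_cohort`.
#' @param n_iter number of null draws (>= 1).
#' @param seed integer seed.
#' @return an object of class `randomization_result`: list with
#'   `observed_statistic`, `null_draws`, `empirical_p`.
#' @export
randomization_test_truncating <- function(gene, cohort, n_iter = 1000, seed = 1L) {
  if (!.is_count(n_iter) || n_iter < 1) .stopf("n_iter must be >= 1")
  g <- cohort$gene_models[[gene]]
  if (is.null(g)) .stopf("gene '%s' not in cohort", gene)
  m <- cohort$mutations[cohort$mutations$gene_symbol == gene, , drop = FALSE]
  if (!nrow(m)) .stopf("gene '%s' has no mutations", gene)
  cons <- vapply(seq_len(nrow(m)), function(i)
    classify_consequence(m[i, ], g), "")
  observed <- mean(is_truncating(cons))
  L <- nchar(g$cds_sequence)
  freqs <- .six_type_freqs(cohort)
  types <- names(freqs)
  pyr_ref <- substring(types, 1, 1) # C or T per type
  comp <- function(b) chartr("ACGT", "TGCA", b)
  null_draws <- with_seed(derive_seed(seed, "randomization_truncating"), {
    vapply(seq_len(n_iter), function(it) {
      frac <- vapply(seq_len(nrow(m)), function(j) {
        r <- as.list(m[j, ])
        r$consequence_override <- NA_character_
        if (r$mutation_type == "SNV") {
          pos <- sample.int(L, 1L)
          ref <- substring(g$cds_sequence, pos, pos)
          pyr <- if (ref %in% c("A", "G")) comp(ref) else ref
          pr <- freqs[pyr_ref == pyr]
          if (sum(pr) == 0) pr <- rep(1, length(pr)) # unseen base: uniform
          sub <- sample(types[pyr_ref == pyr], 1L, prob = pr)
          alt_pyr <- substring(sub, 3, 3)
          alt <- if (ref %in% c("A", "G")) comp(alt_pyr) else alt_pyr
          r$cds_pos <- pos; r$ref_base <- ref; r$alt_base <- alt
        } else if (r$mutation_type == "DEL") {
          r$cds_pos <- sample.int(max(1L, L - r$del_length + 1L), 1L)
        } else {
          r$cds_pos <- sample.int(L, 1L)
        }
        is_truncating(classify_consequence(r, g))
      }, TRUE)
      mean(frac)
    }, 0)
  })
  structure(list(observed_statistic = observed, null_draws = null_draws,
                 empirical_p = (1 + sum(null_draws >= observed)) / (1 + n_iter)),
            class = "randomization_result")
}
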