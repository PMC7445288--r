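# Mutant-peptide enumeration, affinity prediction through a pluggable
# predictor contract, binder calling, per-patient neoantigen summaries and
# the immune-editing Monte Carlo.

#' Enumerate candidate neoantigen peptides from a mutant protein
#'
#' Slides windows of length `kmin..kmax` over the mutant protein and keeps
#' every window overlapping at least one residue of the novel span. Exact
#' duplicate sequences are merged, and peptides that occur verbatim in the
#' wild-type protein are discarded (by definition they are not neoantigens).
#'
#' @param mp a `mutant_protein` from [build_mutant_protein()].
#' @param wt wild-type protein sequence (defaults to `mp$wt`).
#' @param kmin,kmax window lengths (default 8 and 11).
#' @return data frame (`sequence`, `k`, `start`, `novel_positions`); zero rows
#'   when the novel span is empty or the mutant sequence is empty.
#' @export
enumerate_mutant_peptides <- function(mp, wt = mp$wt, kmin = 8, kmax = 11) {
  stopifnot(kmin <= kmax)
  empty <- data.frame(sequence = character(), k = integer(), start = integer(),
                      novel_positions = character(), stringsAsFactors = FALSE)
  if (!nchar(mp$sequence) || !length(mp$novel_span)) return(empty)
  L <- nchar(mp$sequence)
  a <- mp$novel_span[1]; b <- mp$novel_span[2]
  ks <- integer(0); ss <- integer(0)
  for (k in seq.int(kmin, kmax)) {
    if (k > L) next
    # windows [s, s+k-1] overlapping [a, b]
    s_lo <- max(1L, a - k + 1L); s_hi <- min(L - k + 1L, b)
    if (s_lo > s_hi) next
    s <- seq.int(s_lo, s_hi)
    ks <- c(ks, rep.int(k, length(s))); ss <- c(ss, s)
  }
  if (!length(ks)) return(empty)
  nov <- vapply(seq_along(ks), function(i)
    paste(seq.int(max(a, ss[i]), min(b, ss[i] + ks[i] - 1L)) - ss[i] + 1L,
          collapse = ","), "")
  out <- data.frame(sequence = substring(mp$sequence, ss, ss + ks - 1L),
                    k = ks, start = ss, novel_positions = nov,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$sequence), , drop = FALSE]
  out <- out[!vapply(out$sequence, function(p) grepl(p, wt, fixed = TRUE), TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag binders by inclusive IC50 threshold
#'
#' @param calls data frame with columns `peptide`, `allele`, `ic50_nM`
#'   (positive).
#' @param threshold_nM inclusive binder cut-off (default 500 nM).
#' @return `calls` with a logical `binder` column
#'   (`binder == (ic50_nM <= threshold_nM)`).
#' @export
call_binders <- function(calls, threshold_nM = 500) {
  if (!nrow(calls)) {
    calls$binder <- logical(0)
    return(calls)
  }
  if (any(!is.finite(calls$ic50_nM)) || any(calls$ic50_nM <= 0))
    .stopf("ic50_nM values must be positive")
  calls$binder <- calls$ic50_nM <= threshold_nM
  calls
}

#' Best-affinity representative call for one mutation
#'
#' Minimum IC50; ties broken by lexicographically smallest peptide, then
#' allele.
#' @param calls non-empty data frame with `peptide`, `allele`, `ic50_nM`.
#' @return the selected row.
#' @export
best_affinity <- function(calls) {
  if (!nrow(calls)) .stopf("no affinity calls supplied")
  ord <- order(calls$ic50_nM, calls$peptide, calls$allele)
  calls[ord[1], , drop = FALSE]
}

#' Deterministic surrogate IC50 predictor
#'
#' A stand-in affinity model satisfying the predictor contract: for each
#' (allele, peptide length k) a k x 20 position-weight matrix is derived from
#' a deterministic pseudo-random stream keyed by (allele, k, seed), entries
#' standard normal. The peptide score is
#' `z = sum(per-position weights) / sqrt(k)` (so `z ~ N(0,1)` for random
#' peptides) and `ic50 = clip(50000 * 10^(-a z), 0.1, 50000)` with sharpness
#' `a`. Identical inputs yield identical output on every platform.
#'
#' @param peptide amino-acid string over the 20-letter alphabet.
#' @param allele HLA allele name.
#' @param seed integer parameterization seed.
#' @param a sharpness of the affinity response (default 1).
#' @param kmin,kmax admissible peptide lengths (default 8 and 11).
#' @return IC50 in nanomolar, in `[0.1, 50000]`.
#' @export
surrogate_ic50 <- function(peptide, allele, seed = 1L, a = 1,
                           kmin = 8, kmax = 11) {
  k <- nchar(peptide)
  if (k < kmin || k > kmax)
    .stopf("peptide length %d outside [%d, %d]", k, kmin, kmax)
  aa <- match(strsplit(peptide, "")[[1]], .AA20)
  if (anyNA(aa)) .stopf("peptide contains non-standard amino acids")
  W <- .surrogate_weights(allele, k, seed)
  z <- sum(W[cbind(seq_len(k), aa)]) / sqrt(k)
  min(max(50000 * 10^(-a * z), 0.1), 50000)
}

.surrogate_weights <- function(allele, k, seed) {
  key <- derive_seed(seed, sprintf("surrogate|%s|%d", allele, k))
  with_seed(key, matrix(stats::rnorm(k * 20L), k, 20L,
                        dimnames = list(NULL, .AA20)))
}

#' Build a predictor function with a fixed parameterization
#'
#' Returns a memoised `function(peptide, allele) -> ic50_nM` wrapping
#' [surrogate_ic50()]; use [tsv_predictor()] to wire in scores from an
#' external NetMHC-class tool instead.
#'
#' @param seed,a,kmin,kmax passed to [surrogate_ic50()].
#' @return a predictor function.
#' @export
surrogate_predictor <- function(seed = 1L, a = 1, kmin = 8, kmax = 11) {
  wcache <- new.env(parent = emptyenv())
  getW <- function(allele, k) {
    key <- paste0(allele, "|", k)
    if (is.null(wcache[[key]]))
      wcache[[key]] <- .surrogate_weights(allele, k, seed)
    wcache[[key]]
  }
  score <- function(peptides, allele) {
    out <- numeric(length(peptides))
    kk <- nchar(peptides)
    bad <- kk < kmin | kk > kmax
    if (any(bad)) .stopf("peptide length outside [%d, %d]", kmin, kmax)
    for (k in unique(kk)) {
      i <- which(kk == k)
      W <- getW(allele, k)
      aam <- matrix(match(unlist(strsplit(peptides[i], "")), .AA20), nrow = k)
      if (anyNA(aam)) .stopf("peptide contains non-standard amino acids")
      z <- colSums(matrix(W[cbind(rep.int(seq_len(k), length(i)),
                                  as.vector(aam))], nrow = k)) / sqrt(k)
      out[i] <- pmin(pmax(50000 * 10^(-a * z), 0.1), 50000)
    }
    out
  }
  f <- function(peptide, allele) score(peptide, allele)
  attr(f, "batch") <- score
  f
}

#' Predictor backed by a scored-peptide TSV
#'
#' Adapter for external affinity predictions: a TSV with columns `peptide`,
#' `allele`, `ic50` becomes a predictor function; unknown (peptide, allele)
#' pairs raise an error naming the pair.
#'
#' @param path TSV of external scores.
#' @return a predictor function `(peptide, allele) -> ic50_nM`.
#' @export
tsv_predictor <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("peptide", "allele", "ic50"), path)
  lut <- stats::setNames(as.numeric(df$ic50), paste0(df$allele, "|", df$peptide))
  function(peptide, allele) {
    v <- lut[paste0(allele, "|", peptide)]
    if (is.na(v)) .stopf("no external score for (%s, %s)", peptide, allele)
    unname(v)
  }
}

# Best IC50 of one mutation against one allele (min over its peptide windows);
# Inf when the mutation yields no candidate peptides.
.best_ic50 <- function(peptides, allele, predictor) {
  if (!nrow(peptides)) return(Inf)
  batch <- attr(predictor, "batch")
  if (!is.null(batch)) return(min(batch(peptides$sequence, allele)))
  min(vapply(peptides$sequence, predictor, 0, allele = allele))
}

#' Per-patient neoantigen summary
#'
#' For each sample with HLA typings, counts mutations that (i) have RNA
#' expression support of at least `expression_min_reads` and (ii) yield at
#' least one peptide binding any of the sample's alleles at the inclusive
#' IC50 threshold. Samples without HLA typings are excluded with a warning.
#'
#' @param cohort a `gbc_cohort` with HLA typings.
#' @param predictor a predictor function (e.g. [surrogate_predictor()]).
#' @param config an [analysis_config()] (defaults to the cohort's).
#' @return an object of class `neoantigen_summary`: list with `per_sample`
#'   (data frame `sample_id`, `n_expressed_mutations`, `n_neoantigens`),
#'   `per_gene` (gene -> neoantigenic mutation count), `mean`, `range`.
#' @export
summarize_neoantigens <- function(cohort, predictor, config = cohort$config) {
  if (is.null(cohort$hla)) .stopf("cohort has no HLA typings")
  m <- cohort$mutations
  keep <- m$expressed_read_count >= config$expression_min_reads
  m <- m[keep, , drop = FALSE]
  samples <- cohort$samples$sample_id
  typed <- samples[samples %in% names(cohort$hla)]
  if (length(typed) < length(samples))
    warning(sprintf("%d sample(s) without HLA typing excluded",
                    length(samples) - length(typed)), call. = FALSE)
  per_gene <- integer(0)
  rows <- lapply(typed, function(s) {
    ms <- m[m$sample_id == s, , drop = FALSE]
    alleles <- unique(cohort$hla[[s]])
    n_neo <- 0L
    for (i in seq_len(nrow(ms))) {
      r <- ms[i, ]
      mp <- build_mutant_protein(r, cohort$gene_models[[r$gene_symbol]])
      pep <- enumerate_mutant_peptides(mp, kmin = config$peptide_kmin,
                                       kmax = config$peptide_kmax)
      if (!nrow(pep)) next
      best <- min(vapply(alleles, function(al) .best_ic50(pep, al, predictor), 0))
      if (best <= config$binder_threshold_nM) {
        n_neo <- n_neo + 1L
        per_gene[r$gene_symbol] <<-
          (if (is.na(per_gene[r$gene_symbol])) 0L else per_gene[r$gene_symbol]) + 1L
      }
    }
    data.frame(sample_id = s, n_expressed_mutations = nrow(ms),
               n_neoantigens = n_neo, stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, rows)
  if (is.null(per_sample))
    per_sample <- data.frame(sample_id = character(),
                             n_expressed_mutations = integer(),
                             n_neoantigens = integer(), stringsAsFactors = FALSE)
  structure(list(per_sample = per_sample, per_gene = per_gene,
                 mean = if (nrow(per_sample)) mean(per_sample$n_neoantigens) else NA_real_,
                 range = if (nrow(per_sample)) range(per_sample$n_neoantigens) else c(NA, NA)),
            class = "neoantigen_summary")
}

#' Build a population HLA allele pool
#'
#' Concatenates every observed allele copy across the population's typed
#' samples, preserving multiplicities exactly as observed (samples in sorted
#' order, alleles in within-sample order).
#'
#' @param cohort a `gbc_cohort` with HLA typings.
#' @param population population label.
#' @return an object of class `allele_pool`: list with `population`,
#'   `alleles` (character vector with multiplicity).
#' @export
build_allele_pool <- function(cohort, population) {
  if (is.null(cohort$hla)) .stopf("cohort has no HLA typings")
  s <- cohort$samples
  ids <- sort(s$sample_id[s$population == population])
  ids <- ids[ids %in% names(cohort$hla)]
  alleles <- unlist(cohort$hla[ids], use.names = FALSE)
  if (!length(alleles))
    .stopf("no HLA-typed samples for population '%s'", population)
  structure(list(population = population, alleles = alleles),
            class = "allele_pool")
}

#' Immune-editing Monte Carlo between two HLA populations
#'
#' Per iteration and per pool, one mutation (from `mutations`) and one allele
#' (from the pool, with multiplicity) are drawn uniformly and independently;
#' the mutation's 8-11mer peptides are scored, the best-affinity peptide
#' represents the pair, and a binder is recorded by the inclusive threshold.
#' After `n_sim` draws per pool, binder/non-binder counts are compared with a
#' two-sided Fisher's exact test, and the odds ratio of the two binder
#' fractions is reported. Deterministic given `seed`.
#'
#' @param mutations a [mutation_table()] restricted to the gene of interest.
#' @param gene_models named list of gene models covering those mutations.
#' @param poolA,poolB `allele_pool` objects.
#' @param predictor a predictor function.
#' @param n_sim Monte Carlo iterations per pool (default 5000).
#' @param seed integer seed.
#' @param config an [analysis_config()].
#' @return an object of class `immunoediting_result`: list with `n_sim`,
#'   per-pool binder/non-binder counts, `contingency`
#'   (a `contingency_result`), and `or_from_proportions`.
#' @export
immune_editing_mc <- function(mutations, gene_models, poolA, poolB, predictor,
                              n_sim = 5000, seed = 1L,
                              config = analysis_config()) {
  if (!nrow(mutations)) .stopf("no mutations supplied")
  for (p in list(poolA, poolB))
    if (!length(p$alleles)) .stopf("allele pool '%s' is empty", p$population)
  # Distinct mutations and alleles are few; precompute best IC50 per pair so
  # draws are table lookups.
  alleles <- unique(c(poolA$alleles, poolB$alleles))
  peps <- lapply(seq_len(nrow(mutations)), function(i) {
    r <- mutations[i, ]
    mp <- build_mutant_protein(r, gene_models[[r$gene_symbol]])
    enumerate_mutant_peptides(mp, kmin = config$peptide_kmin,
                              kmax = config$peptide_kmax)
  })
  best <- matrix(Inf, nrow(mutations), length(alleles),
                 dimnames = list(mutations$mutation_id, alleles))
  for (i in seq_len(nrow(mutations)))
    for (j in seq_along(alleles))
      best[i, j] <- .best_ic50(peps[[i]], alleles[j], predictor)
  thr <- config$binder_threshold_nM
  draw_pool <- function(pool, label) {
    with_seed(derive_seed(seed, paste0("immune_edit_", label)), {
      mi <- sample.int(nrow(mutations), n_sim, replace = TRUE)
      ai <- sample.int(length(pool$alleles), n_sim, replace = TRUE)
      sum(best[cbind(mi, match(pool$alleles[ai], alleles))] <= thr)
    })
  }
  bA <- draw_pool(poolA, "A"); bB <- draw_pool(poolB, "B")
  ct <- fisher_exact_2x2(bA, n_sim - bA, bB, n_sim - bB)
  pA <- bA / n_sim; pB <- bB / n_sim
  or_props <- if (pA > 0 && pA < 1 && pB > 0 && pB < 1)
    odds_ratio_from_props(pA, pB) else NA_real_
  structure(list(n_sim = n_sim, binders_A = bA, nonbinders_A = n_sim - bA,
                 binders_B = bB, nonbinders_B = n_sim - bB,
                 contingency = ct, or_from_proportions = or_props,
                 pool_A = poolA$population, pool_B = poolB$population),
            class = "immunoediting_result")
}

#' Odds ratio of two proportions
#'
#' `(p1/(1-p1)) / (p2/(1-p2))`, defined for proportions strictly inside
#' (0, 1).
#' @param p1,p2 proportions in (0, 1).
#' @return unitless odds ratio.
#' @export
odds_ratio_from_props <- function(p1, p2) {
  for (p in c(p1, p2))
    if (!is.finite(p) || p <= 0 || p >= 1)
      .stopf("proportions must lie strictly inside (0, 1)")
  (p1 / (1 - p1)) / (p2 / (1 - p2))
}
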