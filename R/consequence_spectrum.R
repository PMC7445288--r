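# Consequence annotation, mutant-protein construction, trinucleotide context
# classes and the cohort 96-channel spectrum.

#' The mutation consequence categories
#' @return character vector of the seven consequence labels.
#' @export
consequence_levels <- function() {
  c("synonymous", "missense", "nonsense", "stop_lost", "start_lost",
    "frameshift", "inframe_indel")
}

#' Translate a coding sequence
#'
#' Standard genetic code. Translation stops at (and excludes) the first stop
#' codon; if no stop is reached the last complete codon is translated and the
#' result carries attribute `no_stop = TRUE`. Trailing incomplete codons are
#' ignored.
#'
#' @param cds nucleotide string, alphabet A/C/G/T, length >= 3.
#' @return amino-acid string with logical attribute `no_stop`.
#' @export
translate_cds <- function(cds) {
  if (!.valid_nt(cds)) .stopf("CDS contains characters outside A/C/G/T")
  if (nchar(cds) < 3L) .stopf("CDS shorter than one codon")
  aa <- .translate_raw(cds)
  stop_at <- match("*", aa)
  if (is.na(stop_at)) {
    structure(paste(aa, collapse = ""), no_stop = TRUE)
  } else {
    structure(paste(aa[seq_len(stop_at - 1L)], collapse = ""), no_stop = FALSE)
  }
}

# Apply a mutation's edit to its gene's CDS (string surgery only).
.apply_edit <- function(m, g) {
  cds <- g$cds_sequence
  pos <- m$cds_pos
  switch(m$mutation_type,
    SNV = paste0(substring(cds, 1L, pos - 1L), m$alt_base,
                 substring(cds, pos + 1L)),
    INS = paste0(substring(cds, 1L, pos), m$inserted_seq,
                 substring(cds, pos + 1L)),
    DEL = paste0(substring(cds, 1L, pos - 1L),
                 substring(cds, pos + m$del_length)),
    .stopf("unknown mutation_type '%s'", m$mutation_type))
}

#' Classify the coding consequence of a somatic mutation
#'
#' SNVs are classified by codon comparison (synonymous, missense, nonsense,
#' stop_lost, start_lost); indels are `frameshift` when the indel length is
#' not a multiple of 3 and `inframe_indel` otherwise. Any edit that destroys
#' the ATG of codon 1 is `start_lost`. A non-missing `consequence_override`
#' on the mutation (used for events a CDS-only model cannot represent, e.g.
#' essential splice sites) is returned verbatim.
#'
#' @param m one row of a [mutation_table()].
#' @param g the corresponding [gene_model()].
#' @return a consequence label.
#' @export
classify_consequence <- function(m, g) {
  m <- as.list(m)
  ov <- m$consequence_override
  if (!is.null(ov) && !is.na(ov) && nzchar(ov) && ov != ".") return(ov)
  edited <- .apply_edit(m, g)
  if (substring(edited, 1L, 3L) != "ATG") return("start_lost")
  if (m$mutation_type == "SNV") {
    ci <- (m$cds_pos - 1L) %/% 3L # 0-based codon index
    at <- 3L * ci + 1L
    wt_aa <- unname(Biostrings::GENETIC_CODE[substring(g$cds_sequence, at, at + 2L)])
    mt_aa <- unname(Biostrings::GENETIC_CODE[substring(edited, at, at + 2L)])
    if (wt_aa == mt_aa) return("synonymous")
    if (mt_aa == "*") return("nonsense")
    if (wt_aa == "*") return("stop_lost")
    return("missense")
  }
  ilen <- if (m$mutation_type == "INS") nchar(m$inserted_seq) else m$del_length
  if (ilen %% 3L != 0L) "frameshift" else "inframe_indel"
}

#' Is a consequence truncating?
#'
#' Frameshift, nonsense and (overridden) essential splice-site events count
#' as truncating; everything else does not.
#' @param consequence character vector of consequence labels.
#' @return logical vector.
#' @export
is_truncating <- function(consequence) {
  consequence %in% c("frameshift", "nonsense") |
    grepl("splice", consequence, ignore.case = TRUE)
}

#' First codon affected by a mutation
#'
#' SNVs and deletions map to `ceiling(cds_pos / 3)`; insertions are anchored
#' after `cds_pos`, so their first affected codon is that of `cds_pos + 1`.
#' @param mutations a [mutation_table()] (or one row).
#' @return integer vector of 1-based codon positions.
#' @export
mutation_codon <- function(mutations) {
  pos <- mutations$cds_pos + ifelse(mutations$mutation_type == "INS", 1L, 0L)
  as.integer(ceiling(pos / 3))
}

#' Construct the mutant protein for a somatic mutation
#'
#' Applies the edit to the CDS and retranslates from the ATG. For frameshifts
#' the novel span runs from the first altered residue to the new C-terminus;
#' translation continues in the shifted frame until the first stop codon and
#' halts at the CDS end (flagged `no_stop_reached`) rather than reading into
#' 3' flanking sequence. A lost stop codon is translated onwards through any
#' provided `flank3` only. Loss of the initiator ATG yields an empty sequence
#' with `start_lost = TRUE` rather than an error.
#'
#' @param m one row of a [mutation_table()].
#' @param g the corresponding [gene_model()].
#' @return an object of class `mutant_protein`: list with `sequence`,
#'   `novel_span` (length-2 integer or empty), `truncated`, `no_stop_reached`,
#'   `start_lost`, `consequence`, and the wild-type protein `wt`.
#' @export
build_mutant_protein <- function(m, g) {
  m <- as.list(m)
  cons <- classify_consequence(m, g)
  wt <- as.character(translate_cds(g$cds_sequence))
  if (cons == "start_lost") {
    return(structure(list(sequence = "", novel_span = integer(0),
                          truncated = TRUE, no_stop_reached = FALSE,
                          start_lost = TRUE, consequence = cons, wt = wt),
                     class = "mutant_protein"))
  }
  edited <- .apply_edit(m, g)
  if (cons == "stop_lost" && !is.null(g$flank3)) {
    keep <- nchar(g$flank3) - nchar(g$flank3) %% 3L
    edited <- paste0(edited, substring(g$flank3, 1L, keep))
  }
  tr <- translate_cds(edited)
  seq <- as.character(tr)
  no_stop <- isTRUE(attr(tr, "no_stop"))
  lm <- nchar(seq); lw <- nchar(wt)
  ms <- strsplit(seq, "")[[1]]; ws <- strsplit(wt, "")[[1]]
  nmin <- min(lm, lw)
  prefix <- 0L
  while (prefix < nmin && ms[prefix + 1L] == ws[prefix + 1L]) prefix <- prefix + 1L
  if (cons %in% c("frameshift", "stop_lost")) {
    span <- if (prefix >= lm) integer(0) else c(prefix + 1L, lm)
  } else {
    suffix <- 0L
    while (suffix < nmin - prefix &&
           ms[lm - suffix] == ws[lw - suffix]) suffix <- suffix + 1L
    span <- if (lm - suffix >= prefix + 1L) c(prefix + 1L, lm - suffix) else integer(0)
  }
  structure(list(sequence = seq, novel_span = span, truncated = lm < lw,
                 no_stop_reached = no_stop, start_lost = FALSE,
                 consequence = cons, wt = wt),
            class = "mutant_protein")
}

#' The 96 trinucleotide context classes, in canonical order
#'
#' Ordered lexicographically by substitution type (C>A, C>G, C>T, T>A, T>C,
#' T>G), then 5' flank, then 3' flank.
#' @return character vector of 96 labels of the form `X[R>A]Y`.
#' @export
context_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  nts <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    unlist(lapply(nts, function(p5)
      vapply(nts, function(p3)
        sprintf("%s[%s]%s", p5, s, p3), "")))), use.names = FALSE)
}

#' Trinucleotide context class of an SNV
#'
#' The substituted base and its immediate 5'/3' neighbours, collapsed to the
#' pyrimidine strand: when the reference base is a purine the reference,
#' alternate and both flanks are reverse-complemented. Flanks at the CDS edge
#' come from the gene model's `flank5`/`flank3`; when unavailable the context
#' is unresolvable and `NA` is returned (such SNVs are excluded from the
#' spectrum).
#'
#' @param m one row of a [mutation_table()] (must be an SNV).
#' @param g the corresponding [gene_model()].
#' @return one of the 96 class labels, or `NA_character_`.
#' @export
trinucleotide_context <- function(m, g) {
  m <- as.list(m)
  if (m$mutation_type != "SNV") .stopf("trinucleotide_context requires an SNV")
  cds <- g$cds_sequence
  L <- nchar(cds)
  pos <- m$cds_pos
  five <- if (pos > 1L) substring(cds, pos - 1L, pos - 1L)
          else if (!is.null(g$flank5) && nchar(g$flank5) >= 1L)
            substring(g$flank5, nchar(g$flank5), nchar(g$flank5))
          else NA_character_
  three <- if (pos < L) substring(cds, pos + 1L, pos + 1L)
           else if (!is.null(g$flank3) && nchar(g$flank3) >= 1L)
             substring(g$flank3, 1L, 1L)
           else NA_character_
  if (is.na(five) || is.na(three)) return(NA_character_)
  ref <- m$ref_base; alt <- m$alt_base
  if (ref %in% c("A", "G")) {
    comp <- function(b) chartr("ACGT", "TGCA", b)
    tmp <- comp(five)
    five <- comp(three)
    three <- tmp
    ref <- comp(ref); alt <- comp(alt)
  }
  sprintf("%s[%s>%s]%s", five, ref, alt, three)
}

#' Build the samples x 96 mutation spectrum
#'
#' Counts every SNV with a resolvable trinucleotide context into its class;
#' unresolvable SNVs are excluded and reported via the `excluded` attribute.
#' Every cohort sample gets a row (all-zero when it has no SNVs).
#'
#' @param cohort a `gbc_cohort`.
#' @return integer matrix (samples x 96, canonical column order) of class
#'   `spectrum_matrix`, with attribute `excluded` naming the skipped
#'   mutation ids.
#' @export
build_spectrum <- function(cohort) {
  classes <- context_classes()
  samples <- cohort$samples$sample_id
  mat <- matrix(0L, nrow = length(samples), ncol = 96L,
                dimnames = list(samples, classes))
  m <- cohort$mutations
  snv <- m[m$mutation_type == "SNV", , drop = FALSE]
  cls <- character(nrow(snv))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (gene in unique(snv$gene_symbol)) {
    idx <- which(snv$gene_symbol == gene)
    g <- cohort$gene_models[[gene]]
    L <- nchar(g$cds_sequence)
    pos <- snv$cds_pos[idx]
    edge5 <- if (!is.null(g$flank5) && nchar(g$flank5))
      substring(g$flank5, nchar(g$flank5), nchar(g$flank5)) else NA_character_
    edge3 <- if (!is.null(g$flank3) && nchar(g$flank3))
      substring(g$flank3, 1L, 1L) else NA_character_
    five <- ifelse(pos > 1L, substring(g$cds_sequence, pos - 1L, pos - 1L), edge5)
    three <- ifelse(pos < L, substring(g$cds_sequence, pos + 1L, pos + 1L), edge3)
    ref <- snv$ref_base[idx]; alt <- snv$alt_base[idx]
    pur <- ref %in% c("A", "G")
    f5 <- ifelse(pur, unname(comp[three]), five)
    f3 <- ifelse(pur, unname(comp[five]), three)
    r <- ifelse(pur, unname(comp[ref]), ref)
    a <- ifelse(pur, unname(comp[alt]), alt)
    cls[idx] <- ifelse(is.na(f5) | is.na(f3), NA_character_,
                       sprintf("%s[%s>%s]%s", f5, r, a, f3))
  }
  excluded <- snv$mutation_id[is.na(cls)]
  ok <- !is.na(cls)
  tab <- table(factor(snv$sample_id[ok], levels = samples),
               factor(cls[ok], levels = classes))
  mat[] <- as.integer(tab)
  structure(mat, excluded = excluded, class = c("spectrum_matrix", class(mat)))
}

#' Write / read a spectrum matrix as TSV
#'
#' Fixed 96-column canonical order, one row per sample (first column
#' `sample_id`).
#' @param spectrum matrix from [build_spectrum()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  df <- data.frame(sample_id = rownames(spectrum), unclass(spectrum),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, context_classes(), drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "integer"
  structure(m, class = c("spectrum_matrix", class(m)))
}

#' Two-of-three deleteriousness consensus
#'
#' A mutation is called deleterious when at least two of the three external
#' impact predictions label it deleterious; `missing` labels count toward
#' neither side.
#'
#' @param labels character vector (recycled triple) of
#'   `deleterious`/`benign`/`missing`; `NA` is treated as `missing`.
#' @return logical scalar.
#' @export
deleterious_consensus <- function(labels) {
  labels[is.na(labels)] <- "missing"
  if (!all(labels %in% c("deleterious", "benign", "missing")))
    .stopf("impact labels must be deleterious/benign/missing")
  sum(labels == "deleterious") >= 2L
}
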