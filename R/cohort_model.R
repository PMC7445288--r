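# Domain types, file readers/writers and validation for the pipeline.
#
# All coordinates are 1-based positions in the CDS on the coding strand,
# closed intervals; codon i covers CDS positions 3i-2..3i. Insertions are
# anchored AFTER cds_pos (VCF-like left anchoring); deletions remove the
# inclusive range cds_pos..cds_pos+del_length-1.

#' Analysis configuration
#'
#' Bundles every threshold and size parameter the pipeline consumes. Defaults
#' are the published operating points: 500 nM inclusive binder threshold,
#' NRF2 activation score strictly greater than 15, MSI score strictly greater
#' than 0.35, splice-variant filters FPKM > 2 / PSI > 0.1 / normal-panel zero
#' fraction > 0.998 with PSI undefined below 10 supporting reads, q-score >= 1
#' for significantly mutated genes, expression support of at least 1 read,
#' 5000 Monte Carlo draws, and 8-11mer peptide windows.
#'
#' @param binder_threshold_nM inclusive IC50 binder cut-off, nanomolar.
#' @param nrf2_threshold NRF2 activation score cut-off (strict `>`).
#' @param msi_threshold MSI score cut-off (strict `>`).
#' @param hotspot_min_samples minimum distinct samples for a hotspot codon.
#' @param fpkm_min splice-variant FPKM cut-off (strict `>`).
#' @param psi_min splice-variant PSI cut-off (strict `>`).
#' @param panel_zero_fraction required fraction of normal-panel samples with
#'   zero FPKM (strict `>`).
#' @param psi_min_denominator PSI denominators below this are set to `NA`.
#' @param qscore_min q-score threshold for the SMG flag.
#' @param expression_min_reads minimum RNA read count confirming expression.
#' @param n_sim Monte Carlo iterations for the immune-editing simulation.
#' @param peptide_kmin,peptide_kmax peptide window lengths (amino acids).
#' @param seed integer master seed.
#' @return an object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(binder_threshold_nM = 500,
                            nrf2_threshold = 15,
                            msi_threshold = 0.35,
                            hotspot_min_samples = 2,
                            fpkm_min = 2,
                            psi_min = 0.1,
                            panel_zero_fraction = 0.998,
                            psi_min_denominator = 10,
                            qscore_min = 1,
                            expression_min_reads = 1,
                            n_sim = 5000,
                            peptide_kmin = 8,
                            peptide_kmax = 11,
                            seed = 1L) {
  cfg <- list(binder_threshold_nM = binder_threshold_nM,
              nrf2_threshold = nrf2_threshold,
              msi_threshold = msi_threshold,
              hotspot_min_samples = hotspot_min_samples,
              fpkm_min = fpkm_min, psi_min = psi_min,
              panel_zero_fraction = panel_zero_fraction,
              psi_min_denominator = psi_min_denominator,
              qscore_min = qscore_min,
              expression_min_reads = expression_min_reads,
              n_sim = n_sim,
              peptide_kmin = peptide_kmin, peptide_kmax = peptide_kmax,
              seed = as.integer(seed))
  num <- cfg[setdiff(names(cfg), "seed")]
  if (!all(vapply(num, function(x) length(x) == 1L && is.finite(x) && x > 0, TRUE)))
    .stopf("all analysis_config thresholds must be finite and positive")
  if (cfg$peptide_kmin > cfg$peptide_kmax)
    .stopf("peptide_kmin must not exceed peptide_kmax")
  structure(cfg, class = "analysis_config")
}

#' Gene model: a coding sequence with optional flanking context
#'
#' @param gene_symbol gene name (FASTA record id).
#' @param cds_sequence coding-strand CDS, `ATG`..stop, alphabet ACGT.
#' @param flank5,flank3 optional genomic context immediately 5'/3' of the CDS
#'   (coding strand), used to resolve trinucleotide contexts at CDS edges and
#'   to translate through a lost stop codon.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_symbol, cds_sequence, flank5 = NULL, flank3 = NULL) {
  stopifnot(is.character(gene_symbol), length(gene_symbol) == 1L,
            is.character(cds_sequence), length(cds_sequence) == 1L)
  structure(list(gene_symbol = gene_symbol,
                 cds_sequence = toupper(cds_sequence),
                 flank5 = if (is.null(flank5)) NULL else toupper(flank5),
                 flank3 = if (is.null(flank3)) NULL else toupper(flank3)),
            class = "gene_model")
}

# Canonical somatic-mutation table. One row per mutation; unused fields NA.
.mutation_cols <- c("mutation_id", "sample_id", "gene_symbol", "cds_pos",
                    "mutation_type", "ref_base", "alt_base", "inserted_seq",
                    "del_length", "population", "expressed_read_count",
                    "impact1", "impact2", "impact3", "consequence_override")

#' Build a somatic-mutation table
#'
#' Normalises a data frame to the canonical mutation columns used throughout
#' the package: `mutation_id`, `sample_id`, `gene_symbol`, `cds_pos` (1-based
#' CDS coordinate), `mutation_type` (`SNV`/`INS`/`DEL`), `ref_base`/`alt_base`
#' (SNV), `inserted_seq` (INS, inserted after `cds_pos`), `del_length` (DEL),
#' `population`, `expressed_read_count`, optional impact labels
#' (`deleterious`/`benign`/`missing`) from three external predictors, and an
#' optional `consequence_override` (e.g. `splice`) for events a CDS-only model
#' cannot represent.
#'
#' @param df data frame with at least the identifying columns.
#' @return a data frame with the canonical columns and types.
#' @export
mutation_table <- function(df = NULL) {
  empty <- data.frame(mutation_id = character(), sample_id = character(),
                      gene_symbol = character(), cds_pos = integer(),
                      mutation_type = character(), ref_base = character(),
                      alt_base = character(), inserted_seq = character(),
                      del_length = integer(), population = character(),
                      expressed_read_count = integer(),
                      impact1 = character(), impact2 = character(),
                      impact3 = character(), consequence_override = character(),
                      stringsAsFactors = FALSE)
  if (is.null(df) || nrow(df) == 0L) return(empty)
  for (cc in .mutation_cols) if (is.null(df[[cc]])) df[[cc]] <- NA
  out <- df[, .mutation_cols]
  for (cc in c("cds_pos", "del_length", "expressed_read_count"))
    out[[cc]] <- as.integer(out[[cc]])
  for (cc in setdiff(.mutation_cols, c("cds_pos", "del_length", "expressed_read_count")))
    out[[cc]] <- as.character(out[[cc]])
  rownames(out) <- NULL
  out
}

#' Assemble a cohort
#'
#' @param samples data frame with columns `sample_id`, `population`.
#' @param mutations a [mutation_table()] data frame.
#' @param gene_models named list of [gene_model()] objects.
#' @param expression optional numeric matrix, genes x samples.
#' @param hla optional named list: `sample_id` -> character vector of HLA
#'   allele names, one entry per allele copy.
#' @param clonotypes optional named list: `sample_id` -> named integer vector
#'   of clonotype counts.
#' @param msi_scores optional named numeric vector of per-sample MSI scores.
#' @param config an [analysis_config()].
#' @return an object of class `gbc_cohort`.
#' @export
new_cohort <- function(samples, mutations = mutation_table(),
                       gene_models = list(), expression = NULL, hla = NULL,
                       clonotypes = NULL, msi_scores = NULL,
                       config = analysis_config()) {
  samples <- data.frame(sample_id = as.character(samples$sample_id),
                        population = as.character(samples$population),
                        stringsAsFactors = FALSE)
  samples <- samples[order(samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  mutations <- mutation_table(mutations)
  mutations <- mutations[order(mutations$sample_id, mutations$mutation_id), ,
                         drop = FALSE]
  rownames(mutations) <- NULL
  names(gene_models) <- vapply(gene_models, `[[`, "", "gene_symbol")
  gene_models <- gene_models[order(names(gene_models))]
  structure(list(samples = samples, mutations = mutations,
                 gene_models = gene_models, expression = expression,
                 hla = hla, clonotypes = clonotypes, msi_scores = msi_scores,
                 config = config),
            class = "gbc_cohort")
}

#' @export
print.gbc_cohort <- function(x, ...) {
  cat(sprintf("gbc_cohort: %d samples (%s), %d mutations, %d gene models\n",
              nrow(x$samples),
              paste(sprintf("%s=%d", names(table(x$samples$population)),
                            as.integer(table(x$samples$population))),
                    collapse = ", "),
              nrow(x$mutations), length(x$gene_models)))
  invisible(x)
}

## ---- readers -------------------------------------------------------------

#' Read gene models from FASTA
#'
#' Record id is the gene symbol; optional `flank5=`/`flank3=` key=value pairs
#' in the description line supply flanking context.
#'
#' @param path FASTA file.
#' @return named list of [gene_model()] objects.
#' @export
read_gene_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    hdr <- strsplit(names(seqs)[i], "\\s+")[[1]]
    sym <- hdr[1]
    kv <- grep("=", hdr[-1], value = TRUE)
    pick <- function(key) {
      m <- grep(paste0("^", key, "="), kv, value = TRUE)
      if (length(m)) sub(paste0("^", key, "="), "", m[1]) else NULL
    }
    gene_model(sym, as.character(seqs[[i]]), flank5 = pick("flank5"),
               flank3 = pick("flank3"))
  })
  names(out) <- vapply(out, `[[`, "", "gene_symbol")
  out
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    .stopf("%s: missing required column(s): %s", path, paste(miss, collapse = ", "))
}

#' Read somatic mutations from the MAF-like TSV dialect
#'
#' Required columns: `mutation_id`, `sample_id`, `gene`, `cds_pos`, `type`,
#' `ref`, `alt`, `population`, `expressed_reads`. For SNVs `ref`/`alt` are
#' single bases; for INS `ref` is `-` and `alt` the inserted sequence; for DEL
#' `ref` is the deleted sequence and `alt` is `-`. Optional columns `impact1`,
#' `impact2`, `impact3` and `consequence_override` are carried through.
#' Multi-nucleotide substitutions are rejected.
#'
#' @param path TSV file.
#' @return a [mutation_table()] data frame.
#' @export
read_mutations_tsv <- function(path) {
  df <- .read_tsv(path)
  req <- c("mutation_id", "sample_id", "gene", "cds_pos", "type", "ref",
           "alt", "population", "expressed_reads")
  .require_cols(df, req, path)
  n <- nrow(df)
  out <- mutation_table(NULL)
  if (n == 0L) return(out)
  parse_row <- function(i) {
    r <- df[i, ]
    line <- i + 1L # header line is 1
    bad <- function(field, why)
      .stopf("%s line %d, field '%s': %s", path, line, field, why)
    ty <- r$type
    if (!ty %in% c("SNV", "INS", "DEL"))
      bad("type", sprintf("unknown mutation type '%s' (multi-nucleotide substitutions are not supported)", ty))
    pos <- suppressWarnings(as.integer(r$cds_pos))
    if (is.na(pos) || pos < 1L) bad("cds_pos", "not a positive integer")
    reads <- suppressWarnings(as.integer(r$expressed_reads))
    if (is.na(reads) || reads < 0L) bad("expressed_reads", "not a non-negative integer")
    ref <- toupper(r$ref); alt <- toupper(r$alt)
    rec <- list(mutation_id = r$mutation_id, sample_id = r$sample_id,
                gene_symbol = r$gene, cds_pos = pos, mutation_type = ty,
                ref_base = NA_character_, alt_base = NA_character_,
                inserted_seq = NA_character_, del_length = NA_integer_,
                population = r$population, expressed_read_count = reads,
                impact1 = if (is.null(df$impact1)) NA else r$impact1,
                impact2 = if (is.null(df$impact2)) NA else r$impact2,
                impact3 = if (is.null(df$impact3)) NA else r$impact3,
                consequence_override =
                  if (is.null(df$consequence_override)) NA else {
                    v <- r$consequence_override
                    if (is.na(v) || v %in% c("", ".")) NA_character_ else v
                  })
    if (ty == "SNV") {
      if (nchar(ref) != 1L || nchar(alt) != 1L)
        bad("ref", "SNV requires single-base ref and alt (multi-nucleotide substitutions are not supported)")
      if (!.valid_nt(ref) || !.valid_nt(alt)) bad("ref", "bases must be A/C/G/T")
      rec$ref_base <- ref; rec$alt_base <- alt
    } else if (ty == "INS") {
      if (!.valid_nt(alt)) bad("alt", "INS requires an inserted sequence over A/C/G/T")
      rec$inserted_seq <- alt
    } else {
      if (!.valid_nt(ref)) bad("ref", "DEL requires the deleted sequence over A/C/G/T")
      rec$del_length <- nchar(ref)
    }
    rec
  }
  rows <- lapply(seq_len(n), parse_row)
  mutation_table(do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE))))
}

#' Read somatic mutations from a minimal VCF-like dialect
#'
#' Convenience reader for a VCF subset in CDS space: `CHROM` carries the gene
#' symbol and `POS` the 1-based CDS coordinate. SNV/INS/DEL are inferred from
#' `REF`/`ALT` lengths with the usual anchor-base convention for indels.
#'
#' @param path VCF file (uncompressed).
#' @param sample_id,population labels applied to every record.
#' @return a [mutation_table()] data frame.
#' @export
read_mutations_vcf <- function(path, sample_id, population) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  out <- mutation_table(NULL)
  if (!length(body)) return(out)
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[i], "\t")[[1]]
    if (length(f) < 5L)
      .stopf("%s line %d: expected at least 5 tab-separated VCF fields", path, i)
    gene <- f[1]; pos <- as.integer(f[2]); id <- f[3]
    ref <- toupper(f[4]); alt <- toupper(f[5])
    if (id %in% c(".", "")) id <- sprintf("%s_%s_%d", sample_id, gene, pos)
    if (nchar(ref) == 1L && nchar(alt) == 1L) {
      list(mutation_id = id, sample_id = sample_id, gene_symbol = gene,
           cds_pos = pos, mutation_type = "SNV", ref_base = ref,
           alt_base = alt, inserted_seq = NA_character_,
           del_length = NA_integer_, population = population,
           expressed_read_count = 0L)
    } else if (nchar(ref) == 1L && nchar(alt) > 1L) {
      list(mutation_id = id, sample_id = sample_id, gene_symbol = gene,
           cds_pos = pos, mutation_type = "INS", ref_base = NA_character_,
           alt_base = NA_character_, inserted_seq = substring(alt, 2L),
           del_length = NA_integer_, population = population,
           expressed_read_count = 0L)
    } else if (nchar(ref) > 1L && nchar(alt) == 1L) {
      list(mutation_id = id, sample_id = sample_id, gene_symbol = gene,
           cds_pos = pos + 1L, mutation_type = "DEL", ref_base = NA_character_,
           alt_base = NA_character_, inserted_seq = NA_character_,
           del_length = nchar(ref) - 1L, population = population,
           expressed_read_count = 0L)
    } else {
      .stopf("%s line %d: multi-nucleotide substitutions are not supported", path, i)
    }
  })
  mutation_table(do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE))))
}

#' Read an expression matrix (genes x samples TSV)
#' @param path TSV; first column `gene`, remaining columns samples.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .require_cols(df, "gene", path)
  if (anyDuplicated(df$gene)) .stopf("%s: duplicated gene names", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(m)) .stopf("%s: expression matrix contains missing values", path)
  rownames(m) <- df$gene
  m
}

#' Read HLA genotypes (one row per allele copy)
#' @param path TSV with columns `sample_id`, `allele`.
#' @return named list sample_id -> character vector of alleles.
#' @export
read_hla_tsv <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("sample_id", "allele"), path)
  df <- df[order(df$sample_id, df$allele), , drop = FALSE]
  split(df$allele, df$sample_id)
}

#' Read clonotype counts
#' @param path TSV with columns `sample_id`, `clonotype_id`, `count`.
#' @return named list sample_id -> named integer vector of counts.
#' @export
read_clonotypes_tsv <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("sample_id", "clonotype_id", "count"), path)
  df$count <- as.integer(df$count)
  df <- df[order(df$sample_id, df$clonotype_id), , drop = FALSE]
  lapply(split(df[, c("clonotype_id", "count")], df$sample_id),
         function(d) stats::setNames(d$count, d$clonotype_id))
}

#' Read MSI scores
#' @param path TSV with columns `sample_id`, `score`.
#' @return named numeric vector.
#' @export
read_msi_tsv <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("sample_id", "score"), path)
  df <- df[order(df$sample_id), , drop = FALSE]
  stats::setNames(as.numeric(df$score), df$sample_id)
}

#' Load and validate a cohort from disk
#'
#' @param gene_fasta path to the gene-model FASTA.
#' @param mutations_tsv path to the mutation TSV.
#' @param samples_tsv optional TSV (`sample_id`, `population`); when absent the
#'   sample list is inferred from the mutation table.
#' @param expression_tsv,hla_tsv,clonotypes_tsv,msi_tsv optional companion files.
#' @param config an [analysis_config()].
#' @return a validated `gbc_cohort`; any invariant violation raises an error
#'   naming the offending entities.
#' @export
load_cohort <- function(gene_fasta, mutations_tsv, samples_tsv = NULL,
                        expression_tsv = NULL, hla_tsv = NULL,
                        clonotypes_tsv = NULL, msi_tsv = NULL,
                        config = analysis_config()) {
  for (p in c(gene_fasta, mutations_tsv, samples_tsv, expression_tsv,
              hla_tsv, clonotypes_tsv, msi_tsv))
    if (!is.null(p) && !file.exists(p)) .stopf("file not found: %s", p)
  genes <- read_gene_fasta(gene_fasta)
  muts <- read_mutations_tsv(mutations_tsv)
  if (!is.null(samples_tsv)) {
    sdf <- .read_tsv(samples_tsv)
    .require_cols(sdf, c("sample_id", "population"), samples_tsv)
  } else {
    sdf <- unique(muts[, c("sample_id", "population")])
  }
  cohort <- new_cohort(
    samples = sdf, mutations = muts, gene_models = genes,
    expression = if (!is.null(expression_tsv)) read_expression_tsv(expression_tsv),
    hla = if (!is.null(hla_tsv)) read_hla_tsv(hla_tsv),
    clonotypes = if (!is.null(clonotypes_tsv)) read_clonotypes_tsv(clonotypes_tsv),
    msi_scores = if (!is.null(msi_tsv)) read_msi_tsv(msi_tsv),
    config = config)
  v <- validate_cohort(cohort)
  if (nrow(v))
    .stopf("cohort validation failed:\n%s",
           paste(sprintf("  [%s] %s: %s", v$entity, v$invariant, v$message),
                 collapse = "\n"))
  cohort
}

## ---- validation ----------------------------------------------------------

.translate_raw <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3L
  if (n < 3L) return(character(0))
  starts <- seq.int(1L, n - 2L, by = 3L)
  unname(Biostrings::GENETIC_CODE[substring(cds, starts, starts + 2L)])
}

.validate_gene <- function(g) {
  bad <- function(inv, msg) data.frame(entity = g$gene_symbol, invariant = inv,
                                       message = msg, stringsAsFactors = FALSE)
  out <- list()
  cds <- g$cds_sequence
  if (!.valid_nt(cds))
    return(bad("alphabet", "CDS contains characters outside A/C/G/T"))
  if (nchar(cds) < 6L || nchar(cds) %% 3L != 0L)
    out <- c(out, list(bad("cds_length", "CDS length must be >= 6 and a multiple of 3")))
  if (substring(cds, 1L, 3L) != "ATG")
    out <- c(out, list(bad("start_codon", "CDS must begin with ATG")))
  aa <- .translate_raw(cds)
  if (length(aa)) {
    if (aa[length(aa)] != "*")
      out <- c(out, list(bad("stop_codon", "CDS must end with a stop codon")))
    if (any(aa[-length(aa)] == "*"))
      out <- c(out, list(bad("internal_stop", "translation has an internal stop codon")))
  }
  for (fl in c("flank5", "flank3"))
    if (!is.null(g[[fl]]) && !.valid_nt(g[[fl]]))
      out <- c(out, list(bad(fl, "flank contains characters outside A/C/G/T")))
  if (length(out)) do.call(rbind, out) else
    data.frame(entity = character(), invariant = character(),
               message = character(), stringsAsFactors = FALSE)
}

#' Validate a cohort against the data-model invariants
#'
#' Checks gene-model integrity (alphabet, length, start/stop codons, internal
#' stops), mutation integrity (registered sample and gene, in-bounds
#' coordinates, SNV reference-base agreement with the CDS, deletion extent,
#' non-negative expression counts, known impact labels), uniqueness of sample
#' ids, and that populations come from the declared sample table.
#'
#' @param cohort a `gbc_cohort`.
#' @return data frame of violations (`entity`, `invariant`, `message`); empty
#'   when the cohort satisfies every invariant.
#' @export
validate_cohort <- function(cohort) {
  out <- list()
  add <- function(entity, invariant, message)
    out[[length(out) + 1L]] <<- data.frame(entity = entity, invariant = invariant,
                                           message = message, stringsAsFactors = FALSE)
  s <- cohort$samples
  if (anyDuplicated(s$sample_id))
    add(paste(unique(s$sample_id[duplicated(s$sample_id)]), collapse = ","),
        "unique_samples", "duplicated sample_id")
  for (g in cohort$gene_models) {
    vg <- .validate_gene(g)
    if (nrow(vg)) out[[length(out) + 1L]] <- vg
  }
  pops <- unique(s$population)
  m <- cohort$mutations
  if (anyDuplicated(m$mutation_id))
    add(paste(unique(m$mutation_id[duplicated(m$mutation_id)]), collapse = ","),
        "unique_mutations", "duplicated mutation_id")
  for (i in seq_len(nrow(m))) {
    r <- m[i, ]
    id <- r$mutation_id
    if (!r$sample_id %in% s$sample_id) {
      add(id, "sample_registered", sprintf("unknown sample '%s'", r$sample_id))
      next
    }
    if (!r$population %in% pops)
      add(id, "population_declared", sprintf("population '%s' not in declared set", r$population))
    g <- cohort$gene_models[[r$gene_symbol]]
    if (is.null(g)) {
      add(id, "gene_registered", sprintf("unknown gene '%s'", r$gene_symbol))
      next
    }
    L <- nchar(g$cds_sequence)
    if (is.na(r$cds_pos) || r$cds_pos < 1L || r$cds_pos > L) {
      add(id, "cds_pos_bounds", sprintf("cds_pos %s outside CDS of length %d", r$cds_pos, L))
      next
    }
    if (r$mutation_type == "SNV") {
      have <- substring(g$cds_sequence, r$cds_pos, r$cds_pos)
      if (!identical(have, r$ref_base))
        add(id, "snv_ref_match",
            sprintf("ref_base '%s' differs from CDS base '%s' at position %d",
                    r$ref_base, have, r$cds_pos))
    } else if (r$mutation_type == "DEL") {
      if (is.na(r$del_length) || r$del_length < 1L)
        add(id, "del_length", "del_length must be a positive integer")
      else if (r$cds_pos + r$del_length - 1L > L)
        add(id, "del_bounds", "deletion extends past CDS end")
    } else if (r$mutation_type == "INS") {
      if (is.na(r$inserted_seq) || !.valid_nt(r$inserted_seq))
        add(id, "ins_seq", "inserted_seq must be a non-empty A/C/G/T string")
    } else {
      add(id, "mutation_type", sprintf("unknown mutation_type '%s'", r$mutation_type))
    }
    if (is.na(r$expressed_read_count) || r$expressed_read_count < 0L)
      add(id, "expressed_reads", "expressed_read_count must be >= 0")
    for (lab in c("impact1", "impact2", "impact3")) {
      v <- r[[lab]]
      if (!is.na(v) && !v %in% c("deleterious", "benign", "missing"))
        add(id, "impact_label", sprintf("%s '%s' not in deleterious/benign/missing", lab, v))
    }
  }
  if (!length(out))
    return(data.frame(entity = character(), invariant = character(),
                      message = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## ---- writer --------------------------------------------------------------

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a cohort to the package TSV/FASTA dialects
#'
#' Emits the same dialects accepted by [load_cohort()], with deterministic row
#' order (mutations sorted by `sample_id` then `mutation_id`), so two writes of
#' the same cohort are byte-identical and `load_cohort(write_tables(x))`
#' reproduces `x`.
#'
#' @param cohort a `gbc_cohort`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of written file paths (the manifest).
#' @export
write_tables <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c()
  gm <- cohort$gene_models
  fa <- file.path(out_dir, "genes.fasta")
  seqs <- Biostrings::DNAStringSet(vapply(gm, `[[`, "", "cds_sequence"))
  names(seqs) <- vapply(gm, function(g) {
    extra <- c(if (!is.null(g$flank5)) sprintf("flank5=%s", g$flank5),
               if (!is.null(g$flank3)) sprintf("flank3=%s", g$flank3))
    paste(c(g$gene_symbol, extra), collapse = " ")
  }, "")
  Biostrings::writeXStringSet(seqs, fa)
  manifest["genes"] <- fa

  m <- cohort$mutations
  ref <- alt <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    r <- m[i, ]
    if (r$mutation_type == "SNV") {
      ref[i] <- r$ref_base; alt[i] <- r$alt_base
    } else if (r$mutation_type == "INS") {
      ref[i] <- "-"; alt[i] <- r$inserted_seq
    } else {
      g <- cohort$gene_models[[r$gene_symbol]]
      ref[i] <- substring(g$cds_sequence, r$cds_pos, r$cds_pos + r$del_length - 1L)
      alt[i] <- "-"
    }
  }
  mdf <- data.frame(mutation_id = m$mutation_id, sample_id = m$sample_id,
                    gene = m$gene_symbol, cds_pos = m$cds_pos,
                    type = m$mutation_type, ref = ref, alt = alt,
                    population = m$population,
                    expressed_reads = m$expressed_read_count,
                    impact1 = ifelse(is.na(m$impact1), ".", m$impact1),
                    impact2 = ifelse(is.na(m$impact2), ".", m$impact2),
                    impact3 = ifelse(is.na(m$impact3), ".", m$impact3),
                    consequence_override = ifelse(is.na(m$consequence_override),
                                                  ".", m$consequence_override),
                    stringsAsFactors = FALSE)
  mdf <- mdf[order(mdf$sample_id, mdf$mutation_id), , drop = FALSE]
  manifest["mutations"] <- .write_tsv(mdf, file.path(out_dir, "mutations.tsv"))
  manifest["samples"] <- .write_tsv(cohort$samples, file.path(out_dir, "samples.tsv"))

  if (!is.null(cohort$expression)) {
    edf <- data.frame(gene = rownames(cohort$expression), cohort$expression,
                      check.names = FALSE, stringsAsFactors = FALSE)
    manifest["expression"] <- .write_tsv(edf, file.path(out_dir, "expression.tsv"))
  }
  if (!is.null(cohort$hla)) {
    hdf <- do.call(rbind, lapply(names(cohort$hla), function(s)
      data.frame(sample_id = s, allele = cohort$hla[[s]], stringsAsFactors = FALSE)))
    hdf <- hdf[order(hdf$sample_id, hdf$allele), , drop = FALSE]
    manifest["hla"] <- .write_tsv(hdf, file.path(out_dir, "hla.tsv"))
  }
  if (!is.null(cohort$clonotypes)) {
    cdf <- do.call(rbind, lapply(names(cohort$clonotypes), function(s) {
      ct <- cohort$clonotypes[[s]]
      data.frame(sample_id = s, clonotype_id = names(ct), count = as.integer(ct),
                 stringsAsFactors = FALSE)
    }))
    cdf <- cdf[order(cdf$sample_id, cdf$clonotype_id), , drop = FALSE]
    manifest["clonotypes"] <- .write_tsv(cdf, file.path(out_dir, "clonotypes.tsv"))
  }
  if (!is.null(cohort$msi_scores)) {
    sdf <- data.frame(sample_id = names(cohort$msi_scores),
                      score = as.numeric(cohort$msi_scores), stringsAsFactors = FALSE)
    sdf <- sdf[order(sdf$sample_id), , drop = FALSE]
    manifest["msi"] <- .write_tsv(sdf, file.path(out_dir, "msi.tsv"))
  }
  manifest
}
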