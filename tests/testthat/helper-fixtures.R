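# Shared fixtures, built in code at test time.

# A short gene with a hand-checkable translation:
# ATG AAA TGC CAA GGG TTT CAT TAG -> M K C Q G F H *
fixture_gene <- function(symbol = "GENE1", flank5 = "ACGTA", flank3 = "TTCCA") {
  gene_model(symbol, "ATGAAATGCCAAGGGTTTCATTAG", flank5 = flank5,
             flank3 = flank3)
}

# A second gene for cross-reference tests.
fixture_gene2 <- function(symbol = "GENE2") {
  gene_model(symbol, "ATGGGGCCCAAATTTTACGATTGA", flank5 = "AAAAA",
             flank3 = "GGGGG")
}

fixture_snv <- function(id = "m1", sample = "S1", gene = "GENE1", pos = 4L,
                        ref = "A", alt = "T", pop = "India", reads = 3L, ...) {
  mutation_table(data.frame(mutation_id = id, sample_id = sample,
                            gene_symbol = gene, cds_pos = pos,
                            mutation_type = "SNV", ref_base = ref,
                            alt_base = alt, population = pop,
                            expressed_read_count = reads, ...,
                            stringsAsFactors = FALSE))
}

fixture_indel <- function(id = "m1", sample = "S1", gene = "GENE1", pos = 6L,
                          type = "DEL", del_length = 1L, inserted = NA,
                          pop = "India", reads = 3L) {
  mutation_table(data.frame(mutation_id = id, sample_id = sample,
                            gene_symbol = gene, cds_pos = pos,
                            mutation_type = type,
                            inserted_seq = inserted, del_length = del_length,
                            population = pop, expressed_read_count = reads,
                            stringsAsFactors = FALSE))
}

fixture_cohort <- function(mutations = fixture_snv(),
                           samples = data.frame(
                             sample_id = c("S1", "S2"),
                             population = c("India", "Korea"),
                             stringsAsFactors = FALSE),
                           ...) {
  new_cohort(samples = samples, mutations = mutations,
             gene_models = list(fixture_gene(), fixture_gene2()), ...)
}

# Small simulation config for fast end-to-end tests.
small_sim_config <- function(seed = 1L, ...) {
  panel <- data.frame(
    symbol = c("BG1", "BG2", "ELF3", "CTNNB1", "NFE2L2", "KEAP1", "CUL3", "TP53"),
    n_codons = c(300L, 300L, 371L, 300L, 120L, 120L, 120L, 130L),
    weight = c(900, 900, 20, 900, 7, 7, 7, 8),
    stringsAsFactors = FALSE)
  simulation_config(genes = panel, burden_mean = 8, n_msi = 1L,
                    msi_burden_mean = 120,
                    n_clones = 20L, clonotype_reads = 200L,
                    n_expression_extra = 2L, alleles_per_sample = 2L,
                    seed = seed, ...)
}

# Random CDS for property tests (ATG + non-stop codons + stop).
random_cds <- function(n_codons, seed) {
  with_seed_test(seed, {
    codons <- apply(matrix(sample(c("A", "C", "G", "T"), 6L * n_codons, TRUE),
                           ncol = 3L), 1, paste, collapse = "")
    codons <- codons[!codons %in% c("TAA", "TAG", "TGA")][seq_len(n_codons - 2L)]
    paste0("ATG", paste(codons, collapse = ""),
           sample(c("TAA", "TAG", "TGA"), 1L))
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) .Random.seed else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

random_protein <- function(len, seed) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed_test(seed, paste(sample(aa, len, TRUE), collapse = ""))
}
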