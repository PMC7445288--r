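test_that("translate_cds follows the standard code and flags missing stops", {
  expect_equal(as.character(translate_cds("ATGAAATAG")), "MK")
  expect_equal(as.character(translate_cds("ATGTAA")), "M")
  expect_false(attr(translate_cds("ATGAAATAG"), "no_stop"))
  expect_true(attr(translate_cds("ATGAAA"), "no_stop"))
  expect_error(translate_cds("ATGNNN"), "A/C/G/T")
})

test_that("translate_cds agrees with Biostrings on random CDSs", {
  for (i in 1:100) {
    cds <- random_cds(sample(5:60, 1), seed = 1000 + i)
    mine <- as.character(translate_cds(cds))
    oracle <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    oracle <- sub("\\*.*$", "", oracle)
    expect_equal(mine, oracle, info = cds)
  }
})

test_that("consequences are classified by codon arithmetic", {
  g <- fixture_gene() # ATG AAA TGC CAA GGG TTT CAT TAG
  # CAA codon (pos 10-12): C->T at pos 10 makes TAA = nonsense
  expect_equal(classify_consequence(fixture_snv(pos = 10L, ref = "C", alt = "T"), g),
               "nonsense")
  # AAA -> AAG still K = synonymous
  expect_equal(classify_consequence(fixture_snv(pos = 6L, ref = "A", alt = "G"), g),
               "synonymous")
  # AAA -> ACA missense
  expect_equal(classify_consequence(fixture_snv(pos = 5L, ref = "A", alt = "C"), g),
               "missense")
  # stop codon TAG (22-24) -> CAG = stop lost
  expect_equal(classify_consequence(fixture_snv(pos = 22L, ref = "T", alt = "C"), g),
               "stop_lost")
  # ATG destroyed = start lost
  expect_equal(classify_consequence(fixture_snv(pos = 2L, ref = "T", alt = "C"), g),
               "start_lost")
  # 1-nt deletion mid-gene = frameshift; 3-nt codon-aligned deletion = inframe
  expect_equal(classify_consequence(fixture_indel(pos = 6L, del_length = 1L), g),
               "frameshift")
  expect_equal(classify_consequence(fixture_indel(pos = 4L, del_length = 3L), g),
               "inframe_indel")
  # insertion splitting codon 1 destroys the ATG
  expect_equal(classify_consequence(fixture_indel(pos = 1L, type = "INS",
                                                  del_length = NA,
                                                  inserted = "T"), g),
               "start_lost")
  # consequence override wins
  expect_equal(classify_consequence(fixture_snv(pos = 5L, ref = "A", alt = "C",
                                                consequence_override = "splice"), g),
               "splice")
})

test_that("mutant proteins carry the right spans and flags", {
  g <- fixture_gene() # protein MKCQGFH
  mp <- build_mutant_protein(fixture_snv(pos = 5L, ref = "A", alt = "C"), g)
  expect_equal(mp$sequence, "MTCQGFH")
  expect_equal(mp$novel_span, c(2L, 2L))
  expect_false(mp$truncated)
  # nonsense truncates to the wild-type prefix with an empty novel span
  mp <- build_mutant_protein(fixture_snv(pos = 10L, ref = "C", alt = "T"), g)
  expect_equal(mp$sequence, "MKC")
  expect_true(mp$truncated)
  expect_length(mp$novel_span, 0L)
  # frameshift: novel tail from first altered residue to new C-terminus
  mp <- build_mutant_protein(fixture_indel(pos = 6L, del_length = 1L), g)
  expect_equal(mp$consequence, "frameshift")
  expect_equal(substr(mp$sequence, 1, mp$novel_span[1] - 1L),
               substr(mp$wt, 1, mp$novel_span[1] - 1L))
  expect_equal(mp$novel_span[2], nchar(mp$sequence))
  # start loss yields empty sequence, flagged not thrown
  mp <- build_mutant_protein(fixture_snv(pos = 2L, ref = "T", alt = "C"), g)
  expect_true(mp$start_lost)
  expect_equal(mp$sequence, "")
})

test_that("random indels agree with an independent edit-then-translate oracle", {
  naive <- function(cds, m) {
    s <- strsplit(cds, "")[[1]]
    s <- switch(m$mutation_type,
                DEL = s[-(m$cds_pos:(m$cds_pos + m$del_length - 1L))],
                INS = append(s, strsplit(m$inserted_seq, "")[[1]],
                             after = m$cds_pos))
    dna <- paste(s, collapse = "")
    dna <- substr(dna, 1, nchar(dna) - nchar(dna) %% 3)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                             if.fuzzy.codon = "X"))
    sub("\\*.*$", "", aa)
  }
  set.seed(77)
  for (i in 1:200) {
    cds <- random_cds(sample(10:80, 1), seed = 400 + i)
    g <- gene_model("G", cds)
    L <- nchar(cds)
    if (runif(1) < 0.5) {
      len <- sample(1:4, 1)
      pos <- sample(seq_len(L - len), 1)
      m <- fixture_indel(pos = pos, del_length = len, gene = "G")
    } else {
      ins <- paste(sample(c("A", "C", "G", "T"), sample(1:4, 1), TRUE),
                   collapse = "")
      m <- fixture_indel(pos = sample(L, 1), type = "INS", del_length = NA,
                         inserted = ins, gene = "G")
    }
    mp <- build_mutant_protein(m, g)
    if (mp$start_lost) {
      edited <- gbcpipe:::.apply_edit(as.list(m[1, ]), g)
      expect_false(substr(edited, 1, 3) == "ATG")
    } else {
      expect_equal(mp$sequence, naive(cds, as.list(m[1, ])), info = i)
      # frameshift prefix property
      if (mp$consequence == "frameshift" && length(mp$novel_span))
        expect_equal(substr(mp$sequence, 1, mp$novel_span[1] - 1L),
                     substr(mp$wt, 1, mp$novel_span[1] - 1L))
    }
  }
})

test_that("trinucleotide contexts collapse to the pyrimidine strand", {
  g <- gene_model("G", "ATGACGTAA", flank5 = "TT", flank3 = "GG")
  # pos 5, ref C, flanks A/G, C>T
  m <- fixture_snv(pos = 5L, ref = "C", alt = "T", gene = "G")
  expect_equal(trinucleotide_context(m, g), "A[C>T]G")
  # purine ref: G with 5' T and 3' C -> reverse complement -> G[C>T]A
  g2 <- gene_model("G", "ATGTGCTAA")
  m2 <- fixture_snv(pos = 5L, ref = "G", alt = "A", gene = "G")
  expect_equal(trinucleotide_context(m2, g2), "G[C>T]A")
  # strand involution: the same physical event encoded on the reverse
  # complement (flipped position, complemented bases, swapped flanks) yields
  # the same class
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  set.seed(11)
  for (i in 1:20) {
    cds <- random_cds(12, seed = 600 + i)
    L <- nchar(cds)
    pos <- sample(2:(L - 1L), 1)
    ref <- substr(cds, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    gf <- gene_model("G", cds)
    gr <- gene_model("G", revcomp(cds))
    comp1 <- function(b) chartr("ACGT", "TGCA", b)
    mf <- fixture_snv(pos = pos, ref = ref, alt = alt, gene = "G")
    mr <- fixture_snv(pos = L + 1L - pos, ref = comp1(ref),
                      alt = comp1(alt), gene = "G")
    expect_equal(trinucleotide_context(mf, gf), trinucleotide_context(mr, gr),
                 info = i)
  }
  # edge without flank is unresolvable
  g5 <- gene_model("G", "CTGACGTAA")
  m5 <- fixture_snv(pos = 1L, ref = "C", alt = "T", gene = "G")
  expect_true(is.na(trinucleotide_context(m5, g5)))
})

test_that("there are exactly 96 distinct context classes", {
  cls <- context_classes()
  expect_length(cls, 96L)
  expect_equal(anyDuplicated(cls), 0L)
  # enumerate all (ref, alt, flank) combinations through the classifier
  seen <- character(0)
  for (ref in c("C", "T", "A", "G")) for (alt in setdiff(c("A", "C", "G", "T"), ref))
    for (f5 in c("A", "C", "G", "T")) for (f3 in c("A", "C", "G", "T")) {
      g <- gene_model("G", paste0("ATG", f5, ref, f3, "TAA"))
      m <- fixture_snv(pos = 5L, ref = ref, alt = alt, gene = "G")
      seen <- c(seen, trinucleotide_context(m, g))
    }
  expect_setequal(unique(seen), cls)
})

test_that("spectrum rows conserve resolvable SNV counts", {
  sim <- generate_cohort(small_sim_config(seed = 3))
  sp <- build_spectrum(sim$cohort)
  m <- sim$cohort$mutations
  snv_per_sample <- table(factor(m$sample_id[m$mutation_type == "SNV"],
                                 levels = rownames(sp)))
  resolvable <- as.integer(snv_per_sample) -
    as.integer(table(factor(
      m$sample_id[m$mutation_id %in% attr(sp, "excluded")],
      levels = rownames(sp))))
  expect_equal(unname(rowSums(sp)), resolvable)
  # empty cohort gives an all-zero matrix
  sp0 <- build_spectrum(fixture_cohort(mutations = mutation_table()))
  expect_true(all(sp0 == 0L))
})

test_that("spectrum rows agree with the scalar context classifier", {
  sim <- generate_cohort(small_sim_config(seed = 8))
  co <- sim$cohort
  sp <- build_spectrum(co)
  m <- co$mutations[co$mutations$mutation_type == "SNV", ]
  sid <- names(which.max(rowSums(sp)))
  ms <- m[m$sample_id == sid, ]
  cls <- vapply(seq_len(nrow(ms)), function(i)
    trinucleotide_context(ms[i, ], co$gene_models[[ms$gene_symbol[i]]]), "")
  expected <- table(factor(cls[!is.na(cls)], levels = context_classes()))
  expect_equal(unname(unclass(sp)[sid, ]), as.integer(expected))
})

test_that("deleterious consensus needs two of three calls", {
  expect_true(deleterious_consensus(c("deleterious", "deleterious", "benign")))
  expect_false(deleterious_consensus(c("deleterious", "benign", "benign")))
  expect_true(deleterious_consensus(c("deleterious", "deleterious", "missing")))
  expect_false(deleterious_consensus(c("deleterious", "missing", "missing")))
  expect_false(deleterious_consensus(c(NA, NA, "deleterious")))
  expect_error(deleterious_consensus(c("bad", "benign", "benign")), "labels")
})
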