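test_that("window counts match the overlap formula and boundary cases", {
  # single interior novel residue in a long protein: 8+9+10+11 windows
  seqs <- random_protein(40, seed = 1)
  p <- 20L
  wt <- paste0(substr(seqs, 1, p - 1), "W", substr(seqs, p + 1, 40))
  if (substr(seqs, p, p) == "W") wt <- sub("W", "Y", wt, fixed = TRUE)
  mp <- list(sequence = seqs, novel_span = c(p, p), wt = wt)
  expect_equal(nrow(enumerate_mutant_peptides(mp)), 38L)
  # novel residue at position 1: one window start per k
  mp1 <- list(sequence = seqs, novel_span = c(1L, 1L),
              wt = paste0("W", substr(seqs, 2, 40)))
  expect_equal(nrow(enumerate_mutant_peptides(mp1)), 4L)
  # exhaustive check of the count formula over lengths and positions
  for (L in c(8L, 9L, 12L, 25L, 50L)) {
    sq <- random_protein(L, seed = 100 + L)
    for (p in seq_len(L)) {
      wt <- paste0(substr(sq, 1, p - 1),
                   if (substr(sq, p, p) == "A") "C" else "A",
                   substr(sq, p + 1, L))
      mp <- list(sequence = sq, novel_span = c(p, p), wt = wt)
      got <- nrow(enumerate_mutant_peptides(mp))
      want <- sum(vapply(8:11, function(k)
        max(0L, min(p, L - k + 1L) - max(1L, p - k + 1L) + 1L), 0L))
      expect_equal(got, want, info = sprintf("L=%d p=%d", L, p))
    }
  }
})

test_that("peptides covering no novel residue or matching wild type are dropped", {
  sq <- random_protein(30, seed = 7)
  # synonymous-like: empty novel span
  expect_equal(nrow(enumerate_mutant_peptides(
    list(sequence = sq, novel_span = integer(0), wt = sq))), 0L)
  # empty mutant sequence
  expect_equal(nrow(enumerate_mutant_peptides(
    list(sequence = "", novel_span = c(1L, 1L), wt = sq))), 0L)
  # peptides identical to a wild-type substring are filtered
  mp <- list(sequence = sq, novel_span = c(10L, 10L), wt = sq)
  expect_equal(nrow(enumerate_mutant_peptides(mp)), 0L)
})

test_that("binder calling is inclusive at the threshold", {
  calls <- data.frame(peptide = c("A", "B", "C"), allele = "X",
                      ic50_nM = c(500.0, 500.1, 3), stringsAsFactors = FALSE)
  out <- call_binders(calls, 500)
  expect_equal(out$binder, c(TRUE, FALSE, TRUE))
  expect_equal(nrow(call_binders(calls[0, ], 500)), 0L)
  calls$ic50_nM[1] <- -1
  expect_error(call_binders(calls, 500), "positive")
})

test_that("best_affinity takes the minimum with deterministic tie-breaks", {
  calls <- data.frame(peptide = c("DDDDDDDD", "AAAAAAAA"), allele = c("X", "Y"),
                      ic50_nM = c(300, 700), stringsAsFactors = FALSE)
  expect_equal(best_affinity(calls)$ic50_nM, 300)
  tie <- data.frame(peptide = c("CCCCCCCCC", "AAAAAAAAA"), allele = c("X", "X"),
                    ic50_nM = c(400, 400), stringsAsFactors = FALSE)
  expect_equal(best_affinity(tie)$peptide, "AAAAAAAAA")
  one <- tie[1, ]
  expect_equal(best_affinity(one)$peptide, "CCCCCCCCC")
  expect_error(best_affinity(tie[0, ]), "no affinity")
})

test_that("the surrogate predictor is deterministic and allele-keyed", {
  p1 <- surrogate_ic50("ACDEFGHIK", "HLA-A*01:01", seed = 5)
  p2 <- surrogate_ic50("ACDEFGHIK", "HLA-A*01:01", seed = 5)
  expect_identical(p1, p2)
  expect_false(isTRUE(all.equal(
    p1, surrogate_ic50("ACDEFGHIK", "HLA-B*01:01", seed = 5))))
  W1 <- gbcpipe:::.surrogate_weights("HLA-A*01:01", 9L, 5L)
  W2 <- gbcpipe:::.surrogate_weights("HLA-B*01:01", 9L, 5L)
  expect_true(any(W1 != W2))
  expect_error(surrogate_ic50("ACDEFG", "X", seed = 5), "length")
  expect_true(p1 >= 0.1 && p1 <= 50000)
})

test_that("surrogate binder fraction at 500 nM matches the normal-tail rate", {
  set.seed(12)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  peps <- vapply(1:10000, function(i)
    paste(sample(aa, 9, TRUE), collapse = ""), "")
  pred <- surrogate_predictor(seed = 8)
  ic <- attr(pred, "batch")(peps, "HLA-A*02:01")
  frac <- mean(ic <= 500)
  # ic50 <= 500 iff z >= 2, so P ~ pnorm(-2) ~ 0.023
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.10)
  # golden consistency: scalar path equals batch path
  idx <- sample(10000, 50)
  scal <- vapply(peps[idx], surrogate_ic50, 0, allele = "HLA-A*02:01", seed = 8)
  expect_equal(unname(scal), ic[idx], tolerance = 1e-12)
})

test_that("allele pools preserve observed multiplicities", {
  hla <- list(S1 = c("X", "X"), S2 = c("X", "X"), S3 = c("Y", "Z"))
  co <- new_cohort(data.frame(sample_id = c("S1", "S2", "S3"),
                              population = c("India", "India", "Korea")),
                   gene_models = list(fixture_gene()), hla = hla)
  pool <- build_allele_pool(co, "India")
  expect_equal(sum(pool$alleles == "X"), 4L)
  expect_length(pool$alleles, 4L)
  expect_error(build_allele_pool(co, "Mars"), "Mars")
  pk <- build_allele_pool(co, "Korea")
  expect_setequal(pk$alleles, c("Y", "Z"))
})

test_that("neoantigen summaries match a brute-force pass", {
  sim <- generate_cohort(small_sim_config(seed = 9))
  co <- sim$cohort
  keep <- co$samples$sample_id[1:8]
  co$samples <- co$samples[co$samples$sample_id %in% keep, ]
  co$mutations <- co$mutations[co$mutations$sample_id %in% keep, ]
  co$hla <- co$hla[keep]
  pred <- surrogate_predictor(seed = 44)
  ns <- summarize_neoantigens(co, pred)
  cfg <- co$config
  brute <- vapply(keep, function(s) {
    ms <- co$mutations[co$mutations$sample_id == s &
                       co$mutations$expressed_read_count >= 1, ]
    cnt <- 0L
    for (i in seq_len(nrow(ms))) {
      mp <- build_mutant_protein(ms[i, ], co$gene_models[[ms$gene_symbol[i]]])
      pep <- enumerate_mutant_peptides(mp)
      if (!nrow(pep)) next
      hit <- FALSE
      for (al in unique(co$hla[[s]]))
        for (pp in pep$sequence)
          if (pred(pp, al) <= 500) hit <- TRUE
      if (hit) cnt <- cnt + 1L
    }
    cnt
  }, 0L)
  expect_equal(stats::setNames(ns$per_sample$n_neoantigens,
                               ns$per_sample$sample_id),
               brute)
  # unexpressed mutations never count, even when a peptide binds
  co2 <- co
  co2$mutations$expressed_read_count <- 0L
  ns0 <- summarize_neoantigens(co2, pred)
  expect_true(all(ns0$per_sample$n_neoantigens == 0L))
})

test_that("the immune-editing Monte Carlo is seeded and conserves draws", {
  sim <- generate_cohort(small_sim_config(seed = 10))
  co <- sim$cohort
  mg <- co$mutations[co$mutations$gene_symbol == "ELF3", ]
  pred <- surrogate_predictor(seed = 3)
  pa <- build_allele_pool(co, "India")
  pb <- build_allele_pool(co, "Korea")
  r1 <- immune_editing_mc(mg, co$gene_models, pa, pb, pred, n_sim = 200, seed = 6)
  r2 <- immune_editing_mc(mg, co$gene_models, pa, pb, pred, n_sim = 200, seed = 6)
  expect_identical(r1$binders_A, r2$binders_A)
  expect_identical(r1$binders_B, r2$binders_B)
  expect_equal(r1$binders_A + r1$nonbinders_A, 200L)
  expect_equal(r1$binders_B + r1$nonbinders_B, 200L)
  expect_s3_class(r1$contingency, "contingency_result")
})

test_that("odds ratios from proportions follow the closed form", {
  expect_equal(round(odds_ratio_from_props(0.43, 0.41), 1), 1.1)
  expect_equal(odds_ratio_from_props(0.5, 0.5), 1)
  expect_equal(odds_ratio_from_props(0.3, 0.7),
               1 / odds_ratio_from_props(0.7, 0.3))
  expect_error(odds_ratio_from_props(0, 0.5), "strictly")
  expect_error(odds_ratio_from_props(0.5, 1), "strictly")
})

test_that("a TSV-backed predictor serves external scores", {
  d <- withr::local_tempdir()
  utils::write.table(
    data.frame(peptide = c("ACDEFGHI", "ACDEFGHI"), allele = c("X", "Y"),
               ic50 = c(12.5, 900)),
    file.path(d, "scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  pred <- tsv_predictor(file.path(d, "scores.tsv"))
  expect_equal(pred("ACDEFGHI", "X"), 12.5)
  expect_equal(pred("ACDEFGHI", "Y"), 900)
  expect_error(pred("WWWWWWWW", "X"), "no external score")
})
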