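# Independent brute-force oracle: two-sided Fisher p by enumerating the
# hypergeometric distribution with choose() directly.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(n - r1, c1 - xs) - lchoose(n, c1)
  p <- exp(logp)
  obs <- p[match(a, xs)]
  sum(p[p <= obs * (1 + 1e-7)])
}

test_that("fisher_exact_2x2 matches brute-force enumeration on small tables", {
  set.seed(5)
  for (i in 1:300) {
    x <- rmultinom(1, sample(1:30, 1), rep(0.25, 4))[, 1]
    if (sum(x) == 0) next
    res <- fisher_exact_2x2(x[1], x[2], x[3], x[4])
    expect_equal(res$p_two_sided, fisher_oracle(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-9, info = paste(x, collapse = ","))
  }
})

test_that("fisher_exact_2x2 handles symmetry, zeros and bad input", {
  res <- fisher_exact_2x2(1, 1, 1, 1)
  expect_equal(res$p_two_sided, 1)
  expect_equal(res$odds_ratio, 1)
  expect_false(res$haldane)
  res0 <- fisher_exact_2x2(0, 5, 5, 5)
  expect_true(res0$haldane)
  expect_equal(res0$odds_ratio, (0.5 * 5.5) / (5.5 * 5.5))
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("bh_fdr reproduces step-up arithmetic and dominates p", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(2)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # order preserved
  expect_equal(q[order(p)], sort(bh_fdr(sort(p))))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("mann_whitney_u is exact for tiny samples and sane at equality", {
  expect_equal(mann_whitney_u(c(1, 2), c(10, 11)), 1 / 3, tolerance = 1e-9)
  expect_gte(mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0.99)
  # U is location-invariant within groups: shifting both equally keeps p
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6)),
               mann_whitney_u(c(11, 12, 13), c(14, 15, 16)))
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("shannon entropy matches closed forms and bounds", {
  expect_equal(shannon_entropy(c(10, 10, 10, 10)), log(4), tolerance = 1e-12)
  expect_equal(shannon_entropy(100), 0)
  expect_equal(shannon_entropy(c(3, 1)), 0.5623, tolerance = 1e-4)
  expect_equal(shannon_entropy(c(3, 1, 0, 0)), shannon_entropy(c(3, 1)))
  set.seed(4)
  for (i in 1:20) {
    x <- rpois(sample(2:30, 1), 5) + 1
    h <- shannon_entropy(x)
    expect_gte(h, 0)
    expect_lte(h, log(sum(x > 0)) + 1e-12)
  }
  expect_error(shannon_entropy(c(0, 0)), "positive")
})

test_that("hotspots require distinct samples at one codon", {
  samples <- data.frame(sample_id = sprintf("S%d", 1:6),
                        population = "India", stringsAsFactors = FALSE)
  # codon 2 of GENE1 spans positions 4-6
  muts <- rbind(fixture_snv("a", "S1", pos = 4L, ref = "A", alt = "C"),
                fixture_snv("b", "S2", pos = 5L, ref = "A", alt = "C"),
                fixture_snv("c", "S3", pos = 6L, ref = "A", alt = "C"),
                # same sample twice at codon 4 (positions 10-12): not a hotspot
                fixture_snv("d", "S4", pos = 10L, ref = "C", alt = "G"),
                fixture_snv("e", "S4", pos = 11L, ref = "A", alt = "G"),
                # synonymous at codon 2 must not count
                fixture_snv("f", "S5", pos = 6L, ref = "A", alt = "G"))
  co <- new_cohort(samples, muts, list(fixture_gene()))
  hs <- detect_hotspots(co, min_samples = 2)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$protein_pos, 2L)
  expect_equal(hs$n_samples, 3L)
  # brute-force grouping oracle on a random fixture
  sim <- generate_cohort(small_sim_config(seed = 12))
  ann <- annotate_consequences(sim$cohort)
  ann <- ann[ann$consequence != "synonymous", ]
  oracle <- stats::aggregate(sample_id ~ gene_symbol + protein_pos, ann,
                             function(s) length(unique(s)))
  oracle <- oracle[oracle$sample_id >= 2, ]
  hs2 <- detect_hotspots(sim$cohort, min_samples = 2)
  expect_equal(nrow(hs2), nrow(oracle))
  key <- function(d, n) paste(d$gene_symbol, d$protein_pos, d[[n]])
  expect_setequal(key(hs2, "n_samples"), key(oracle, "sample_id"))
})

test_that("meta-hotspot matching is exact on (gene, codon)", {
  muts <- rbind(fixture_snv("a", "S1", pos = 4L, ref = "A", alt = "C"),
                fixture_snv("b", "S2", pos = 5L, ref = "A", alt = "C"))
  co <- fixture_cohort(muts)
  catalog <- data.frame(gene = c("GENE1", "GENE1", "GENE9"),
                        codon = c(2L, 3L, 2L),
                        label = c("hit", "off_by_one", "absent"),
                        stringsAsFactors = FALSE)
  mm <- match_meta_hotspots(co, catalog)
  expect_equal(mm$label, "hit")
  expect_equal(mm$n_samples, 2L)
})

test_that("gene significance flags a planted gene and stays calibrated", {
  # q = 0.1 corresponds exactly to the SMG boundary q-score of 1
  expect_equal(-log10(0.1), 1)
  sim <- generate_cohort(small_sim_config(seed = 4))
  gs <- gene_significance(sim$cohort)
  expect_true(gs$smg[gs$gene_symbol == "CTNNB1"])
  expect_true(all(gs$q >= gs$p - 1e-12))
  expect_true(all(gs$q_score[gs$smg] >= 1))
  # empty cohort gives empty output
  empty <- new_cohort(data.frame(sample_id = "S1", population = "India"),
                      gene_models = list())
  expect_equal(nrow(gene_significance(empty)), 0L)
  # MSI exclusion removes outlier samples from the background
  msi_id <- sim$truth$msi_samples
  ann <- annotate_consequences(sim$cohort)
  gs_in <- gene_significance(sim$cohort, exclude_msi = FALSE)
  expect_gte(sum(gs_in$observed), sum(gs$observed))
})

test_that("co-occurrence cross-tabulates samples and propagates to Fisher", {
  samples <- data.frame(sample_id = sprintf("S%d", 1:6),
                        population = "India", stringsAsFactors = FALSE)
  muts <- rbind(fixture_snv("a", "S1", gene = "GENE1"),
                fixture_snv("b", "S1", gene = "GENE2", pos = 4L, ref = "G", alt = "T"),
                fixture_snv("c", "S2", gene = "GENE1"),
                fixture_snv("d", "S3", gene = "GENE2", pos = 4L, ref = "G", alt = "T"))
  co <- new_cohort(samples, muts, list(fixture_gene(), fixture_gene2()))
  res <- cooccurrence(co, "GENE1", "GENE2")
  expect_equal(as.vector(t(res$table)), c(1, 1, 1, 3))
  # perfect co-occurrence is highly significant
  n <- 40
  samples <- data.frame(sample_id = sprintf("P%02d", 1:n), population = "India")
  muts <- do.call(rbind, lapply(1:20, function(i) rbind(
    fixture_snv(paste0("x", i), sprintf("P%02d", i), gene = "GENE1"),
    fixture_snv(paste0("y", i), sprintf("P%02d", i), gene = "GENE2",
                pos = 4L, ref = "G", alt = "T"))))
  co2 <- new_cohort(samples, muts, list(fixture_gene(), fixture_gene2()))
  expect_lt(cooccurrence(co2, "GENE1", "GENE2")$p_two_sided, 0.001)
  expect_error(cooccurrence(co2, "GENE1", "NOPE"), "NOPE")
})

test_that("co-occurrence p-values are calibrated under independence", {
  set.seed(31)
  n <- 60
  samples <- data.frame(sample_id = sprintf("P%02d", 1:n), population = "India")
  gm <- list(fixture_gene(), fixture_gene2())
  pv <- replicate(400, {
    inA <- runif(n) < 0.4
    inB <- runif(n) < 0.4
    rows <- list()
    for (i in seq_len(n)) {
      if (inA[i]) rows[[length(rows) + 1L]] <-
        fixture_snv(paste0("a", i), samples$sample_id[i], gene = "GENE1")
      if (inB[i]) rows[[length(rows) + 1L]] <-
        fixture_snv(paste0("b", i), samples$sample_id[i], gene = "GENE2",
                    pos = 4L, ref = "G", alt = "T")
    }
    muts <- if (length(rows)) do.call(rbind, rows) else mutation_table()
    cooccurrence(new_cohort(samples, muts, gm), "GENE1", "GENE2")$p_two_sided
  })
  # type-I error within binomial bounds of the nominal 0.05
  rej <- mean(pv < 0.05)
  ci <- qbinom(c(0.005, 0.995), 400, 0.05) / 400
  expect_gte(rej, ci[1] - 1e-9)
  expect_lte(rej, ci[2] + 1e-9)
})

test_that("the truncating randomization test is seeded and sane", {
  expect_equal(round(27 / 37, 2), 0.73)
  sim <- generate_cohort(small_sim_config(seed = 6))
  r1 <- randomization_test_truncating("ELF3", sim$cohort, n_iter = 50, seed = 3)
  r2 <- randomization_test_truncating("ELF3", sim$cohort, n_iter = 50, seed = 3)
  expect_identical(r1$null_draws, r2$null_draws)
  expect_gt(r1$empirical_p, 0)
  expect_lte(r1$empirical_p, 1)
  expect_length(r1$null_draws, 50L)
  # observed statistic is the truncating fraction of the gene's mutations
  ann <- annotate_consequences(sim$cohort)
  elf <- ann[ann$gene_symbol == "ELF3", ]
  expect_equal(r1$observed_statistic, mean(is_truncating(elf$consequence)))
  expect_error(randomization_test_truncating("ELF3", sim$cohort, n_iter = 0),
               "n_iter")
  # degenerate null: observed 0 truncating on an all-missense set -> p = 1
  co <- fixture_cohort(fixture_snv(pos = 5L, ref = "A", alt = "C"))
  r3 <- randomization_test_truncating("GENE1", co, n_iter = 30, seed = 1)
  expect_equal(r3$observed_statistic, 0)
  expect_equal(r3$empirical_p, 1)
})
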