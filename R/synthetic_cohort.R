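# Seeded synthetic-cohort generator with ground truth for recovery tests.
#
# The generator emulates the statistical structure the analysis stages
# assume: a two-population cohort with negative-binomial mutation burden,
# SNV contexts drawn from a planted signature mixture, one frameshift-
# enriched driver gene with population-differential indel rates, a planted
# high-rate gene for significance calibration, an expression activation
# program tied to planted pathway mutations, population-specific HLA allele
# frequencies, and clonotype repertoires whose evenness depends on frameshift
# carrier status.

#' Simulation configuration
#'
#' Defaults encode the cohort structure the pipeline is designed around: 60
#' India-like and 91 Korea-like samples; frameshift rates of 4/60 vs 28/91 in
#' the ELF3-like driver with indels concentrated at codons 55/320/324; a
#' negative-binomial burden with mean 65 protein-altering events across the
#' modelled gene panel (MSI-like outliers at mean 1500); a two-signature
#' planted mixture (an aging-like NpCpG C>T process and an APOBEC-like TpC
#' process); a 27-gene activation program shifted by 1.5 SD in carriers of
#' planted pathway mutations; and clonotype repertoires with lower evenness
#' in frameshift carriers.
#'
#' @param populations named integer vector of per-population sample counts.
#' @param genes data frame (`symbol`, `n_codons`, `weight`) of gene models;
#'   `weight` is the per-population relative background SNV rate (0 disables
#'   background mutations for the gene). Defaults to a 46-gene panel.
#' @param burden_mean,burden_size negative-binomial mutation burden per
#'   sample.
#' @param n_msi number of MSI-like outlier samples.
#' @param msi_burden_mean burden mean for MSI-like samples (>1000).
#' @param signatures 96 x k matrix of planted signature probability vectors.
#' @param exposure_alpha Dirichlet concentration for per-sample exposures.
#' @param fs_gene frameshift-enriched gene symbol.
#' @param fs_rates named per-population probability that a sample carries a
#'   frameshift indel in `fs_gene`.
#' @param fs_hotspot_codons,fs_hotspot_weight codons receiving the planted
#'   indels and the probability mass concentrated on them.
#' @param smg_gene,smg_multiplier planted significantly mutated gene and its
#'   rate multiplier over the length-proportional background.
#' @param pathway_genes,pathway_rate genes whose planted mutations trigger
#'   the activation program, and the per-sample carrier probability.
#' @param cooccur_gene,cooccur_rate gene planted to co-occur with frameshift
#'   carriers, and the conditional mutation probability.
#' @param nrf2_genes activation-signature gene list (default 27 genes).
#' @param nrf2_delta expression shift (SD units) in activation carriers.
#' @param n_expression_extra additional null genes in the expression matrix.
#' @param hla_alleles allele universe (character vector).
#' @param hla_freqs list of per-population frequency vectors over
#'   `hla_alleles` (each sums to 1).
#' @param alleles_per_sample HLA allele copies drawn per sample.
#' @param n_clones,clonotype_reads clonotype richness and total read count.
#' @param evenness_background,evenness_carrier Dirichlet concentrations for
#'   clonotype frequencies (carrier = frameshift carrier; lower is less
#'   even).
#' @param expression_read_mean Poisson mean of per-mutation RNA support
#'   reads.
#' @param seed master seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(populations = c(India = 60L, Korea = 91L),
                              genes = NULL,
                              burden_mean = 65, burden_size = 1,
                              n_msi = 3L, msi_burden_mean = 1500,
                              signatures = NULL,
                              exposure_alpha = c(2, 2),
                              fs_gene = "ELF3",
                              fs_rates = c(India = 4 / 60, Korea = 28 / 91),
                              fs_hotspot_codons = c(55L, 320L, 324L),
                              fs_hotspot_weight = 0.7,
                              smg_gene = "CTNNB1", smg_multiplier = 10,
                              pathway_genes = c("NFE2L2", "KEAP1", "CUL3"),
                              pathway_rate = 0.08,
                              cooccur_gene = "TP53", cooccur_rate = 0.6,
                              nrf2_genes = nrf2_default_signature(),
                              nrf2_delta = 1.5,
                              n_expression_extra = 20L,
                              hla_alleles = NULL, hla_freqs = NULL,
                              alleles_per_sample = 6L,
                              n_clones = 150L, clonotype_reads = 3000L,
                              evenness_background = 1,
                              evenness_carrier = 0.15,
                              expression_read_mean = 4,
                              seed = 1L) {
  if (is.null(genes)) genes <- .default_gene_panel(fs_gene, smg_gene,
                                                   pathway_genes, cooccur_gene,
                                                   smg_multiplier)
  if (is.null(signatures)) signatures <- planted_signatures()
  if (is.null(hla_alleles))
    hla_alleles <- sprintf("HLA-%s*%02d:01",
                           rep(c("A", "B", "C"), each = 4), rep(1:4, 3))
  if (is.null(hla_freqs)) {
    k <- length(hla_alleles)
    base <- (k:1) / sum(k:1)
    hla_freqs <- lapply(seq_along(populations), function(i) {
      f <- base[((seq_len(k) + 3L * (i - 1L)) %% k) + 1L]
      f / sum(f)
    })
    names(hla_freqs) <- names(populations)
  }
  cfg <- list(populations = populations, genes = genes,
              burden_mean = burden_mean, burden_size = burden_size,
              n_msi = as.integer(n_msi), msi_burden_mean = msi_burden_mean,
              signatures = as.matrix(signatures),
              exposure_alpha = exposure_alpha,
              fs_gene = fs_gene, fs_rates = fs_rates,
              fs_hotspot_codons = as.integer(fs_hotspot_codons),
              fs_hotspot_weight = fs_hotspot_weight,
              smg_gene = smg_gene, smg_multiplier = smg_multiplier,
              pathway_genes = pathway_genes, pathway_rate = pathway_rate,
              cooccur_gene = cooccur_gene, cooccur_rate = cooccur_rate,
              nrf2_genes = nrf2_genes, nrf2_delta = nrf2_delta,
              n_expression_extra = as.integer(n_expression_extra),
              hla_alleles = hla_alleles, hla_freqs = hla_freqs,
              alleles_per_sample = as.integer(alleles_per_sample),
              n_clones = as.integer(n_clones),
              clonotype_reads = as.integer(clonotype_reads),
              evenness_background = evenness_background,
              evenness_carrier = evenness_carrier,
              expression_read_mean = expression_read_mean,
              seed = as.integer(seed))
  .validate_sim_config(cfg)
  structure(cfg, class = "simulation_config")
}

.default_gene_panel <- function(fs_gene, smg_gene, pathway_genes,
                                cooccur_gene, smg_multiplier) {
  bg <- data.frame(symbol = sprintf("BG%02d", 1:40), n_codons = 450L,
                   weight = NA_real_, stringsAsFactors = FALSE)
  driver <- data.frame(
    symbol = c(fs_gene, smg_gene, pathway_genes, cooccur_gene),
    n_codons = c(371L, 781L, 605L, 624L, 768L, 393L),
    weight = NA_real_, stringsAsFactors = FALSE)
  panel <- rbind(bg, driver)
  # background SNV weight: proportional to CDS length; drivers damped so the
  # planted effects dominate their mutation status; the planted SMG inflated.
  w <- 3 * panel$n_codons
  damp <- panel$symbol %in% c(fs_gene, pathway_genes, cooccur_gene)
  w[damp] <- w[damp] * 0.02
  w[panel$symbol == smg_gene] <- w[panel$symbol == smg_gene] * smg_multiplier
  panel$weight <- w
  panel
}

#' Planted two-signature mixture used by default
#'
#' Signature A concentrates 80% of its mass on C>T at NpCpG contexts
#' (aging-like); signature B concentrates 80% on C>T/C>G at TpCpN contexts
#' (APOBEC-like); the remainder is uniform over all 96 classes.
#' @return 96 x 2 matrix of probability vectors (canonical row order).
#' @export
planted_signatures <- function() {
  classes <- context_classes()
  uni <- rep(1 / 96, 96)
  s1 <- 0.2 * uni
  ncg <- grepl("^\\w\\[C>T\\]G$", classes)
  s1[ncg] <- s1[ncg] + 0.8 / sum(ncg)
  s2 <- 0.2 * uni
  tcn <- grepl("^T\\[C>(T|G)\\]\\w$", classes)
  s2[tcn] <- s2[tcn] + 0.8 / sum(tcn)
  m <- cbind(aging_like = s1, apobec_like = s2)
  rownames(m) <- classes
  m
}

.validate_sim_config <- function(cfg) {
  if (length(cfg$populations) < 2L)
    .stopf("at least two populations are required")
  if (nrow(cfg$signatures) != 96L)
    .stopf("planted signatures must have 96 rows, got %d", nrow(cfg$signatures))
  if (any(abs(colSums(cfg$signatures) - 1) > 1e-6))
    .stopf("planted signature columns must sum to 1")
  if (length(cfg$exposure_alpha) != ncol(cfg$signatures))
    .stopf("exposure_alpha length must equal the number of signatures")
  if (!all(names(cfg$fs_rates) %in% names(cfg$populations)))
    .stopf("fs_rates names must be population labels")
  rates <- c(cfg$burden_mean, cfg$fs_rates, cfg$pathway_rate, cfg$cooccur_rate)
  if (any(rates < 0)) .stopf("rates must be non-negative")
  for (f in cfg$hla_freqs)
    if (abs(sum(f) - 1) > 1e-6) .stopf("HLA frequency vectors must sum to 1")
  need <- c(cfg$fs_gene, cfg$smg_gene, cfg$pathway_genes, cfg$cooccur_gene)
  miss <- setdiff(need, cfg$genes$symbol)
  if (length(miss)) .stopf("gene panel lacks: %s", paste(miss, collapse = ", "))
  invisible(cfg)
}

# Random CDS: ATG + random non-stop codons + one stop; 5 bp flanks.
.random_gene <- function(symbol, n_codons, seed) {
  with_seed(seed, {
    codons <- apply(matrix(sample(c("A", "C", "G", "T"),
                                  3L * (n_codons * 2L), replace = TRUE),
                           ncol = 3L), 1, paste, collapse = "")
    codons <- codons[!codons %in% c("TAA", "TAG", "TGA")]
    codons <- codons[seq_len(n_codons - 2L)]
    stopc <- sample(c("TAA", "TAG", "TGA"), 1L)
    gene_model(symbol,
               paste0("ATG", paste(codons, collapse = ""), stopc),
               flank5 = paste(sample(c("A", "C", "G", "T"), 5L, TRUE),
                              collapse = ""),
               flank3 = paste(sample(c("A", "C", "G", "T"), 5L, TRUE),
                              collapse = ""))
  })
}

# Per-gene context index: pyrimidine-collapsed trinucleotide at every CDS
# position (flanks resolve the edges), plus positions grouped by trinuc.
.gene_context_index <- function(g) {
  cds <- strsplit(g$cds_sequence, "")[[1]]
  L <- length(cds)
  five <- c(substring(g$flank5, nchar(g$flank5), nchar(g$flank5)), cds[-L])
  three <- c(cds[-1], substring(g$flank3, 1L, 1L))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pyr <- cds %in% c("C", "T")
  tri <- ifelse(pyr, paste0(five, cds, three),
                paste0(comp[three], comp[cds], comp[five]))
  list(tri = tri, by_tri = split(seq_len(L), tri), pyr = pyr)
}

.class_tri <- function(classes = context_classes()) {
  paste0(substring(classes, 1, 1), substring(classes, 3, 3),
         substring(classes, 7, 7))
}

.class_alt <- function(classes = context_classes()) substring(classes, 5, 5)

.rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x <- rep(1, length(alpha))
  x / sum(x)
}

#' Generate a synthetic cohort with ground truth
#'
#' See [simulation_config()] for the generative model. All randomness flows
#' from the config seed through stable per-component derived streams, so a
#' fixed config reproduces the cohort exactly.
#'
#' @param config a [simulation_config()].
#' @return list with elements `cohort` (a `gbc_cohort`) and `truth` (class
#'   `ground_truth`): planted signatures and per-sample exposures, the
#'   planted SMG, enrichment and co-occurrence pairs, per-sample activation
#'   class, frameshift carriers, per-population HLA frequencies, MSI samples,
#'   and the entropy group assignment.
#' @export
generate_cohort <- function(config = simulation_config()) {
  cfg <- config
  seed <- cfg$seed
  pops <- cfg$populations
  sample_df <- do.call(rbind, lapply(names(pops), function(p)
    data.frame(sample_id = sprintf("%s%03d", toupper(substr(p, 1, 2)),
                                   seq_len(pops[[p]])),
               population = p, stringsAsFactors = FALSE)))
  n <- nrow(sample_df)

  genes <- lapply(seq_len(nrow(cfg$genes)), function(i)
    .random_gene(cfg$genes$symbol[i], cfg$genes$n_codons[i],
                 derive_seed(seed, paste0("gene_", cfg$genes$symbol[i]))))
  names(genes) <- cfg$genes$symbol
  ctx <- lapply(genes, .gene_context_index)
  cls_tri <- .class_tri()
  cls_alt <- .class_alt()
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  # MSI-like outlier samples and scores.
  msi_samples <- with_seed(derive_seed(seed, "msi"), {
    idx <- if (cfg$n_msi > 0L) sample.int(n, cfg$n_msi) else integer(0)
    sample_df$sample_id[idx]
  })
  msi_scores <- with_seed(derive_seed(seed, "msi_scores"), {
    s <- stats::runif(n, 0.02, 0.20)
    s[sample_df$sample_id %in% msi_samples] <-
      stats::runif(length(msi_samples), 0.45, 0.90)
    stats::setNames(s, sample_df$sample_id)
  })

  # Per-sample signature exposures and mutation burden.
  k <- ncol(cfg$signatures)
  exposures <- with_seed(derive_seed(seed, "exposures"),
    t(vapply(seq_len(n), function(i) .rdirichlet1(cfg$exposure_alpha),
             numeric(k))))
  rownames(exposures) <- sample_df$sample_id
  colnames(exposures) <- colnames(cfg$signatures)
  burden <- with_seed(derive_seed(seed, "burden"), {
    mu <- ifelse(sample_df$sample_id %in% msi_samples,
                 cfg$msi_burden_mean, cfg$burden_mean)
    ifelse(mu > 0, stats::rnbinom(n, size = cfg$burden_size, mu = mu), 0L)
  })

  gene_w <- cfg$genes$weight
  fs_carriers <- character(0)
  nrf2_carriers <- character(0)
  rows <- list()
  push <- function(r) rows[[length(rows) + 1L]] <<- r
  mut_counter <- 0L
  new_id <- function() {
    mut_counter <<- mut_counter + 1L
    sprintf("M%06d", mut_counter)
  }

  with_seed(derive_seed(seed, "mutations"), {
    for (i in seq_len(n)) {
      sid <- sample_df$sample_id[i]
      pop <- sample_df$population[i]
      mix <- as.numeric(cfg$signatures %*% exposures[i, ])
      nm <- burden[i]
      if (nm > 0 && sum(gene_w) > 0) {
        alloc <- as.integer(stats::rmultinom(1, nm, gene_w / sum(gene_w)))
        for (gi in which(alloc > 0L)) {
          g <- genes[[gi]]
          cx <- ctx[[gi]]
          avail <- names(cx$by_tri)
          w <- mix * (cls_tri %in% avail)
          if (sum(w) == 0) w <- as.numeric(cls_tri %in% avail)
          cls <- sample.int(96L, alloc[gi], replace = TRUE, prob = w)
          for (ci in cls) {
            posset <- cx$by_tri[[cls_tri[ci]]]
            pos <- if (length(posset) == 1L) posset else sample(posset, 1L)
            ref <- substring(g$cds_sequence, pos, pos)
            alt <- if (cx$pyr[pos]) cls_alt[ci] else unname(comp[cls_alt[ci]])
            push(list(mutation_id = new_id(), sample_id = sid,
                      gene_symbol = g$gene_symbol, cds_pos = pos,
                      mutation_type = "SNV", ref_base = ref, alt_base = alt,
                      inserted_seq = NA_character_, del_length = NA_integer_,
                      population = pop))
          }
        }
      }
      # Planted frameshift indel in the enriched driver gene.
      fs_rate <- if (pop %in% names(cfg$fs_rates)) cfg$fs_rates[[pop]] else 0
      carrier <- stats::runif(1) < fs_rate
      if (carrier) {
        g <- genes[[cfg$fs_gene]]
        ncod <- nchar(g$cds_sequence) / 3
        codon <- if (stats::runif(1) < cfg$fs_hotspot_weight)
          sample(cfg$fs_hotspot_codons, 1L) else
          sample.int(as.integer(ncod) - 2L, 1L) + 1L
        pos <- 3L * codon - 2L
        if (stats::runif(1) < 0.5) {
          push(list(mutation_id = new_id(), sample_id = sid,
                    gene_symbol = cfg$fs_gene, cds_pos = pos,
                    mutation_type = "DEL", ref_base = NA_character_,
                    alt_base = NA_character_, inserted_seq = NA_character_,
                    del_length = 1L, population = pop))
        } else {
          push(list(mutation_id = new_id(), sample_id = sid,
                    gene_symbol = cfg$fs_gene, cds_pos = pos,
                    mutation_type = "INS", ref_base = NA_character_,
                    alt_base = NA_character_,
                    inserted_seq = sample(c("A", "C", "G", "T"), 1L),
                    del_length = NA_integer_, population = pop))
        }
        # Planted co-occurrence: carriers also mutate the partner gene.
        if (stats::runif(1) < cfg$cooccur_rate) {
          g2 <- genes[[cfg$cooccur_gene]]
          pos2 <- sample.int(nchar(g2$cds_sequence), 1L)
          ref2 <- substring(g2$cds_sequence, pos2, pos2)
          push(list(mutation_id = new_id(), sample_id = sid,
                    gene_symbol = cfg$cooccur_gene, cds_pos = pos2,
                    mutation_type = "SNV", ref_base = ref2,
                    alt_base = sample(setdiff(c("A", "C", "G", "T"), ref2), 1L),
                    inserted_seq = NA_character_, del_length = NA_integer_,
                    population = pop))
        }
      }
      if (carrier) fs_carriers <- c(fs_carriers, sid)
      # Planted pathway mutation driving the activation program.
      if (stats::runif(1) < cfg$pathway_rate) {
        pg <- sample(cfg$pathway_genes, 1L)
        g3 <- genes[[pg]]
        pos3 <- sample.int(nchar(g3$cds_sequence), 1L)
        ref3 <- substring(g3$cds_sequence, pos3, pos3)
        push(list(mutation_id = new_id(), sample_id = sid,
                  gene_symbol = pg, cds_pos = pos3, mutation_type = "SNV",
                  ref_base = ref3,
                  alt_base = sample(setdiff(c("A", "C", "G", "T"), ref3), 1L),
                  inserted_seq = NA_character_, del_length = NA_integer_,
                  population = pop))
        nrf2_carriers <- c(nrf2_carriers, sid)
      }
    }
  })

  muts <- if (length(rows)) {
    pull <- function(nm, proto) vapply(rows, function(r) r[[nm]], proto)
    df <- data.frame(
      mutation_id = pull("mutation_id", ""), sample_id = pull("sample_id", ""),
      gene_symbol = pull("gene_symbol", ""),
      cds_pos = pull("cds_pos", 0L), mutation_type = pull("mutation_type", ""),
      ref_base = pull("ref_base", ""), alt_base = pull("alt_base", ""),
      inserted_seq = pull("inserted_seq", ""),
      del_length = pull("del_length", 0L),
      population = pull("population", ""), stringsAsFactors = FALSE)
    df$expressed_read_count <- NA_integer_
    df$impact1 <- df$impact2 <- df$impact3 <- NA_character_
    df$consequence_override <- NA_character_
    mutation_table(df)
  } else mutation_table(NULL)

  muts$expressed_read_count <- with_seed(derive_seed(seed, "expression_reads"),
    as.integer(stats::rpois(nrow(muts), cfg$expression_read_mean)))
  imp <- with_seed(derive_seed(seed, "impact"), {
    lab <- function(n) {
      x <- sample(c("deleterious", "benign", "missing"), n, replace = TRUE,
                  prob = c(0.5, 0.4, 0.1))
      x
    }
    list(lab(nrow(muts)), lab(nrow(muts)), lab(nrow(muts)))
  })
  muts$impact1 <- imp[[1]]; muts$impact2 <- imp[[2]]; muts$impact3 <- imp[[3]]

  # Expression: baseline N(0,1); activation carriers shifted on the program.
  expr_genes <- c(cfg$nrf2_genes,
                  sprintf("EXPR%02d", seq_len(cfg$n_expression_extra)))
  expr <- with_seed(derive_seed(seed, "expression"), {
    m <- matrix(stats::rnorm(length(expr_genes) * n), length(expr_genes), n,
                dimnames = list(expr_genes, sample_df$sample_id))
    m[cfg$nrf2_genes, sample_df$sample_id %in% nrf2_carriers] <-
      m[cfg$nrf2_genes, sample_df$sample_id %in% nrf2_carriers] + cfg$nrf2_delta
    m
  })

  # HLA genotypes from population-specific frequencies.
  hla <- with_seed(derive_seed(seed, "hla"), {
    out <- lapply(seq_len(n), function(i) {
      f <- cfg$hla_freqs[[sample_df$population[i]]]
      sort(sample(cfg$hla_alleles, cfg$alleles_per_sample, replace = TRUE,
                  prob = f))
    })
    names(out) <- sample_df$sample_id
    out
  })

  # Clonotype repertoires: frameshift carriers get lower evenness.
  clon <- with_seed(derive_seed(seed, "clonotypes"), {
    out <- lapply(seq_len(n), function(i) {
      conc <- if (sample_df$sample_id[i] %in% fs_carriers)
        cfg$evenness_carrier else cfg$evenness_background
      p <- .rdirichlet1(rep(conc, cfg$n_clones))
      cnt <- as.integer(stats::rmultinom(1, cfg$clonotype_reads, p))
      stats::setNames(cnt, sprintf("CL%04d", seq_len(cfg$n_clones)))
    })
    names(out) <- sample_df$sample_id
    out
  })

  cohort <- new_cohort(samples = sample_df, mutations = muts,
                       gene_models = genes, expression = expr, hla = hla,
                       clonotypes = clon, msi_scores = msi_scores,
                       config = analysis_config(seed = seed))
  truth <- structure(list(
    signatures = cfg$signatures, exposures = exposures,
    smg_genes = cfg$smg_gene,
    enrichment_pairs = data.frame(gene = cfg$pathway_genes,
                                  program = "nrf2",
                                  stringsAsFactors = FALSE),
    cooccur_pair = c(cfg$fs_gene, cfg$cooccur_gene),
    nrf2_class = stats::setNames(
      ifelse(sample_df$sample_id %in% nrf2_carriers, "NRF2+", "NRF2-"),
      sample_df$sample_id),
    fs_carriers = fs_carriers,
    fs_gene = cfg$fs_gene, fs_rates = cfg$fs_rates,
    hla_freqs = cfg$hla_freqs, msi_samples = msi_samples,
    entropy_groups = stats::setNames(
      ifelse(sample_df$sample_id %in% fs_carriers, "carrier", "background"),
      sample_df$sample_id)),
    class = "ground_truth")
  list(cohort = cohort, truth = truth)
}

#' Score pipeline outputs against simulation ground truth
#'
#' One row per recovery check, each with the measured value, its documented
#' tolerance and a pass flag; checks whose stage output is missing are marked
#' not-run.
#'
#' @param truth a `ground_truth` from [generate_cohort()].
#' @param outputs named list of stage outputs, any subset of: `signatures`
#'   (a `signature_set`), `smg` (from [gene_significance()]), `enrichment`
#'   (from [nrf2_enrichment()]), `nrf2` (from [nrf2_score()]), `entropy`
#'   (from [compare_entropy_groups()]).
#' @return data frame (`check`, `value`, `threshold`, `pass`, `run`).
#' @export
truth_report <- function(truth, outputs = list()) {
  rows <- list()
  add <- function(check, value, threshold, pass, run = TRUE)
    rows[[length(rows) + 1L]] <<-
      data.frame(check = check, value = value, threshold = threshold,
                 pass = pass, run = run, stringsAsFactors = FALSE)
  if (!is.null(outputs$signatures)) {
    cm <- cosine_match(outputs$signatures, truth$signatures)
    add("signature_recovery_mean_cosine", mean(cm$cosine), 0.9,
        mean(cm$cosine) >= 0.9)
  } else add("signature_recovery_mean_cosine", NA_real_, 0.9, NA, FALSE)
  if (!is.null(outputs$smg)) {
    hit <- all(truth$smg_genes %in% outputs$smg$gene_symbol[outputs$smg$smg])
    add("smg_planted_recovered", as.numeric(hit), 1, hit)
  } else add("smg_planted_recovered", NA_real_, 1, NA, FALSE)
  if (!is.null(outputs$enrichment)) {
    top <- outputs$enrichment$gene_symbol[1]
    ok <- top %in% truth$enrichment_pairs$gene &&
      outputs$enrichment$q[1] < 0.2
    add("enrichment_top_gene_planted", as.numeric(ok), 1, ok)
  } else add("enrichment_top_gene_planted", NA_real_, 1, NA, FALSE)
  if (!is.null(outputs$nrf2)) {
    cls <- outputs$nrf2$class
    tru <- truth$nrf2_class[names(cls)]
    sens <- mean(cls[tru == "NRF2+"] == "NRF2+")
    spec <- mean(cls[tru == "NRF2-"] == "NRF2-")
    bal <- mean(c(sens, spec))
    add("nrf2_balanced_accuracy", bal, 0.9, is.finite(bal) && bal >= 0.9)
  } else add("nrf2_balanced_accuracy", NA_real_, 0.9, NA, FALSE)
  if (!is.null(outputs$entropy)) {
    add("entropy_group_p", outputs$entropy$p_two_sided, 0.05,
        outputs$entropy$p_two_sided < 0.05)
  } else add("entropy_group_p", NA_real_, 0.05, NA, FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
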