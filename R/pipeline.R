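# End-to-end pipeline orchestration: configuration, stage execution with
# derived per-stage seeds, TSV outputs and a run manifest.

#' Read a hierarchical pipeline configuration (YAML)
#'
#' Top-level keys: `seed`; `input` (either `simulate: true` with an optional
#' `simulation` block of [simulation_config()] overrides, or file paths
#' `gene_fasta`, `mutations_tsv`, and optional `samples_tsv`,
#' `expression_tsv`, `hla_tsv`, `clonotypes_tsv`, `msi_tsv`); `analysis`
#' ([analysis_config()] overrides); `stages` (named logical switches, all on
#' by default); and optional reference paths `hotspot_catalog`,
#' `signature_catalog`, plus `signatures_k`.
#'
#' @param path YAML file.
#' @return the parsed configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  yaml::read_yaml(path)
}

.stage_names <- c("validate", "spectrum", "signatures", "hotspots",
                  "meta_hotspots", "smg", "cooccurrence", "randomization",
                  "neoantigen", "immune_edit", "nrf2", "splice_filter",
                  "msi", "tcr_entropy")

#' Run the full analysis pipeline
#'
#' Loads (or simulates) a cohort, then executes in order: validation,
#' spectrum construction, signature extraction, hotspot and meta-hotspot
#' detection, gene significance, co-occurrence, the truncating-fraction
#' randomization test, the neoantigen summary, the immune-editing Monte
#' Carlo, NRF2 scoring and enrichment, splice-variant filtering, MSI
#' classification, and the TCR entropy comparison. Each stage writes a TSV
#' under `out_dir` and can be switched off via `config$stages`; a JSON run
#' manifest (config snapshot, stage status, outputs) is written first as
#' `run_manifest.json` and updated at the end. Per-stage seeds are derived
#' from the global seed by stage name, so disabling one stage leaves the
#' others' randomness unchanged.
#'
#' @param config a list as returned by [read_pipeline_config()], or a path
#'   to a YAML file.
#' @param out_dir output directory.
#' @return invisibly, the run manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  acfg <- do.call(analysis_config,
                  c(config$analysis %||% list(), list(seed = seed)))
  stages_on <- function(s) !isFALSE((config$stages %||% list())[[s]])

  manifest <- list(config = config, seed = seed, stages = list(),
                   outputs = list())
  man_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  mark <- function(stage, status, outputs = character(0)) {
    manifest$stages[[stage]] <<- status
    if (length(outputs)) manifest$outputs[[stage]] <<- outputs
  }
  run_stage <- function(stage, fun) {
    if (!stages_on(stage)) {
      mark(stage, "skipped")
      return(NULL)
    }
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[stage]] <<- paste("failed:", conditionMessage(e))
      jsonlite::write_json(manifest, man_path, auto_unbox = TRUE,
                           pretty = TRUE, force = TRUE)
      .stopf("stage '%s' failed: %s", stage, conditionMessage(e))
    })
    mark(stage, "ok", attr(res, "outputs") %||% character(0))
    res
  }
  out <- function(name) file.path(out_dir, name)
  with_out <- function(x, ...) {
    attr(x, "outputs") <- c(...)
    x
  }

  truth <- NULL
  if (isTRUE((config$input %||% list())$simulate)) {
    sim_args <- (config$input$simulation %||% list())
    sim_args$seed <- derive_seed(seed, "simulate")
    sim <- generate_cohort(do.call(simulation_config, sim_args))
    cohort <- sim$cohort
    cohort$config <- acfg
    truth <- sim$truth
    write_tables(cohort, file.path(out_dir, "cohort"))
  } else {
    inp <- config$input %||% list()
    if (is.null(inp$gene_fasta) || is.null(inp$mutations_tsv))
      .stopf("config$input must provide gene_fasta and mutations_tsv (or simulate: true)")
    cohort <- load_cohort(inp$gene_fasta, inp$mutations_tsv,
                          samples_tsv = inp$samples_tsv,
                          expression_tsv = inp$expression_tsv,
                          hla_tsv = inp$hla_tsv,
                          clonotypes_tsv = inp$clonotypes_tsv,
                          msi_tsv = inp$msi_tsv, config = acfg)
  }

  run_stage("validate", function() {
    v <- validate_cohort(cohort)
    .write_tsv(v, out("validation.tsv"))
    if (nrow(v)) .stopf("%d validation violation(s); see validation.tsv", nrow(v))
    with_out(v, out("validation.tsv"))
  })

  ann <- annotate_consequences(cohort)
  .write_tsv(ann, out("consequences.tsv"))

  spectrum <- run_stage("spectrum", function() {
    sp <- build_spectrum(cohort)
    write_spectrum_tsv(sp, out("spectrum.tsv"))
    with_out(sp, out("spectrum.tsv"))
  })

  run_stage("signatures", function() {
    if (is.null(spectrum)) .stopf("signature stage requires the spectrum stage")
    k <- config$signatures_k %||% 2L
    sig <- nmf_extract(spectrum, k = k,
                       seed = derive_seed(seed, "signatures"))
    write_signatures_tsv(sig, out("signatures_W.tsv"), out("signatures_H.tsv"))
    if (!is.null(config$signature_catalog)) {
      cat96 <- read_signature_catalog(config$signature_catalog)
      .write_tsv(cosine_match(sig, cat96), out("signature_matches.tsv"))
    }
    with_out(sig, out("signatures_W.tsv"), out("signatures_H.tsv"))
  })

  run_stage("hotspots", function() {
    h <- detect_hotspots(cohort)
    .write_tsv(h, out("hotspots.tsv"))
    with_out(h, out("hotspots.tsv"))
  })

  run_stage("meta_hotspots", function() {
    if (is.null(config$hotspot_catalog)) return(NULL)
    mh <- match_meta_hotspots(cohort, read_hotspot_catalog(config$hotspot_catalog))
    .write_tsv(mh, out("meta_hotspots.tsv"))
    with_out(mh, out("meta_hotspots.tsv"))
  })

  smg <- run_stage("smg", function() {
    s <- gene_significance(cohort)
    .write_tsv(s, out("gene_significance.tsv"))
    with_out(s, out("gene_significance.tsv"))
  })

  run_stage("cooccurrence", function() {
    pairs <- config$cooccurrence_pairs %||%
      (if (!is.null(truth)) list(as.list(truth$cooccur_pair)) else list())
    rows <- lapply(pairs, function(p) {
      ct <- cooccurrence(cohort, p[[1]], p[[2]])
      data.frame(geneA = p[[1]], geneB = p[[2]],
                 both = ct$table[1, 1], a_only = ct$table[1, 2],
                 b_only = ct$table[2, 1], neither = ct$table[2, 2],
                 odds_ratio = ct$odds_ratio, p = ct$p_two_sided,
                 stringsAsFactors = FALSE)
    })
    res <- if (length(rows)) do.call(rbind, rows) else
      data.frame(geneA = character(), geneB = character())
    .write_tsv(res, out("cooccurrence.tsv"))
    with_out(res, out("cooccurrence.tsv"))
  })

  run_stage("randomization", function() {
    gene <- config$randomization_gene %||%
      (if (!is.null(truth)) truth$fs_gene else NULL)
    if (is.null(gene) || !any(cohort$mutations$gene_symbol == gene)) return(NULL)
    r <- randomization_test_truncating(gene, cohort,
                                       n_iter = config$randomization_iter %||% 1000,
                                       seed = derive_seed(seed, "randomization"))
    res <- data.frame(gene = gene, observed_truncating_fraction = r$observed_statistic,
                      empirical_p = r$empirical_p, stringsAsFactors = FALSE)
    .write_tsv(res, out("randomization.tsv"))
    with_out(res, out("randomization.tsv"))
  })

  predictor <- surrogate_predictor(seed = derive_seed(seed, "predictor"),
                                   kmin = acfg$peptide_kmin,
                                   kmax = acfg$peptide_kmax)

  run_stage("neoantigen", function() {
    if (is.null(cohort$hla)) return(NULL)
    ns <- summarize_neoantigens(cohort, predictor, acfg)
    .write_tsv(ns$per_sample, out("neoantigens_per_sample.tsv"))
    with_out(ns, out("neoantigens_per_sample.tsv"))
  })

  run_stage("immune_edit", function() {
    if (is.null(cohort$hla)) return(NULL)
    gene <- config$randomization_gene %||%
      (if (!is.null(truth)) truth$fs_gene else NULL)
    pops <- unique(cohort$samples$population)
    if (is.null(gene) || length(pops) < 2L) return(NULL)
    mg <- cohort$mutations[cohort$mutations$gene_symbol == gene, , drop = FALSE]
    if (!nrow(mg)) return(NULL)
    res <- immune_editing_mc(mg, cohort$gene_models,
                             build_allele_pool(cohort, pops[1]),
                             build_allele_pool(cohort, pops[2]),
                             predictor, n_sim = acfg$n_sim,
                             seed = derive_seed(seed, "immune_edit"),
                             config = acfg)
    df <- data.frame(pool_A = res$pool_A, pool_B = res$pool_B,
                     n_sim = res$n_sim, binders_A = res$binders_A,
                     binders_B = res$binders_B,
                     odds_ratio = res$or_from_proportions,
                     fisher_p = res$contingency$p_two_sided,
                     stringsAsFactors = FALSE)
    .write_tsv(df, out("immune_editing.tsv"))
    with_out(res, out("immune_editing.tsv"))
  })

  nrf2 <- run_stage("nrf2", function() {
    if (is.null(cohort$expression)) return(NULL)
    r <- nrf2_score(cohort$expression,
                    signature_genes = config$nrf2_genes %||% nrf2_default_signature(),
                    threshold = acfg$nrf2_threshold)
    df <- data.frame(sample_id = names(r$score), score = r$score,
                     class = r$class, stringsAsFactors = FALSE)
    .write_tsv(df, out("nrf2_scores.tsv"))
    if (sum(r$class == "NRF2+") >= 2L && sum(r$class == "NRF2-") >= 2L) {
      cand <- config$nrf2_candidate_genes %||% names(cohort$gene_models)
      enr <- nrf2_enrichment(r$class, cohort, cand)
      .write_tsv(enr, out("nrf2_enrichment.tsv"))
    }
    with_out(r, out("nrf2_scores.tsv"))
  })

  run_stage("splice_filter", function() {
    if (is.null(config$splice_records_tsv)) return(NULL)
    rec <- .read_tsv(config$splice_records_tsv)
    kept <- filter_splice_variants(rec, acfg)
    .write_tsv(kept, out("splice_kept.tsv"))
    with_out(kept, out("splice_kept.tsv"))
  })

  run_stage("msi", function() {
    if (is.null(cohort$msi_scores)) return(NULL)
    r <- classify_msi(cohort$msi_scores, acfg$msi_threshold)
    .write_tsv(r, out("msi_classification.tsv"))
    with_out(r, out("msi_classification.tsv"))
  })

  run_stage("tcr_entropy", function() {
    if (is.null(cohort$clonotypes)) return(NULL)
    ann_fs <- ann[ann$consequence == "frameshift", , drop = FALSE]
    groups <- stats::setNames(
      ifelse(cohort$samples$sample_id %in% ann_fs$sample_id,
             "frameshift", "no_frameshift"),
      cohort$samples$sample_id)
    if (length(unique(groups)) < 2L || any(table(groups) < 2L)) return(NULL)
    r <- compare_entropy_groups(cohort$clonotypes, groups)
    .write_tsv(r$entropy, out("tcr_entropy.tsv"))
    with_out(r, out("tcr_entropy.tsv"))
  })

  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
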