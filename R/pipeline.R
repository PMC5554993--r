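# End-to-end orchestration: configuration, ATC category counting, the four
# analysis stages, and a machine-readable run summary.

#' Count drugs per ATC level-2 therapeutic category
#'
#' A drug carrying several level-2 codes is counted once per code; drugs
#' missing from the mapping are counted under `"UNMAPPED"`.
#'
#' @param drugs drug ids to tabulate (e.g. the index-event drugs).
#' @param drug_to_atc data.frame with columns `drug_id`, `atc` (level-2
#'   codes such as `"C10"`); a drug may appear on several rows.
#' @return data.frame `atc`, `n_drugs`, count descending then code.
#' @export
count_by_atc <- function(drugs, drug_to_atc) {
  drugs <- unique(as.character(drugs))
  if (length(drugs) == 0)
    return(data.frame(atc = character(), n_drugs = integer()))
  m <- unique(drug_to_atc[drug_to_atc$drug_id %in% drugs,
                          c("drug_id", "atc"), drop = FALSE])
  unmapped <- setdiff(drugs, m$drug_id)
  if (length(unmapped))
    m <- rbind(m, data.frame(drug_id = unmapped, atc = "UNMAPPED"))
  tab <- table(m$atc)
  out <- data.frame(atc = names(tab), n_drugs = as.integer(tab))
  out <- out[order(-out$n_drugs, out$atc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Configure a pipeline run
#'
#' Either a synthetic-cohort block (`cohort`) or a named list of input
#' `paths` must be supplied, not neither. Recognised path keys:
#' `se_pairs`, `fingerprints`, `targets`, `ppi`, `pt_to_soc`,
#' `drug_to_atc` (required), `ranks`, `gene_sets`, `drugs`, `side_effects`
#' (optional); `fp_bits` must accompany `fingerprints`. The transcriptomic
#' stage is skipped gracefully when `ranks` or `gene_sets` is absent.
#'
#' A single global `seed` governs the run; stage `k` uses `seed + 100 * k`
#' (stages numbered 1 = simulate, 2 = chemical similarity, 3 = side-effect
#' screen, 4 = targets, 5 = transcriptome), so adding or re-running a stage
#' never perturbs the randomness of the others.
#'
#' @param cohort a [cohort_config()], or NULL when reading real inputs.
#' @param paths named list of input file paths, or NULL with a cohort block.
#' @param index_pt index side-effect id (default `"myopathy"`).
#' @param criteria a [significance_criteria()].
#' @param n_perm,perm_statistic permutation-test settings (defaults 10000,
#'   `"median"`).
#' @param similarity_threshold Jaccard cutoff for the similar-pair table.
#' @param n_sig_up,n_sig_down per-drug signature sizes (defaults 100/100).
#' @param n_representative size of the representative gene list.
#' @param enrichment_alpha BH level for enrichment.
#' @param top_k_targets how many top targets feed the PPI subnetwork.
#' @param ppi_min_score PPI confidence cutoff (strict, default 0.4).
#' @param fp_bits fingerprint bit-space size for file inputs.
#' @param seed global integer seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = NULL, paths = NULL,
                       index_pt = "myopathy",
                       criteria = significance_criteria(),
                       n_perm = 10000, perm_statistic = "median",
                       similarity_threshold = 0.4,
                       n_sig_up = 100, n_sig_down = 100,
                       n_representative = 100,
                       enrichment_alpha = 0.05,
                       top_k_targets = 10,
                       ppi_min_score = 0.4,
                       fp_bits = NULL,
                       seed = 1L) {
  if (is.null(cohort) && is.null(paths))
    stop("run_config needs either a synthetic `cohort` block or input `paths`")
  if (!is.null(cohort) && !inherits(cohort, "cohort_config"))
    cohort <- do.call(cohort_config, as.list(cohort))
  if (!is.null(paths)) {
    required <- c("se_pairs", "fingerprints", "targets", "ppi",
                  "pt_to_soc", "drug_to_atc")
    missing <- setdiff(required, names(paths))
    if (length(missing))
      stop("input paths missing: ", paste(missing, collapse = ", "))
    if (is.null(fp_bits))
      stop("`fp_bits` is required with file inputs")
  }
  structure(list(cohort = cohort, paths = paths, index_pt = index_pt,
                 criteria = criteria, n_perm = as.integer(n_perm),
                 perm_statistic = perm_statistic,
                 similarity_threshold = similarity_threshold,
                 n_sig_up = as.integer(n_sig_up),
                 n_sig_down = as.integer(n_sig_down),
                 n_representative = as.integer(n_representative),
                 enrichment_alpha = enrichment_alpha,
                 top_k_targets = as.integer(top_k_targets),
                 ppi_min_score = ppi_min_score,
                 fp_bits = if (is.null(fp_bits)) NULL else as.integer(fp_bits),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; `cohort:` and
#' `criteria:` blocks map onto [cohort_config()] and
#' [significance_criteria()]. `overrides` (e.g. parsed command-line flags)
#' replace top-level keys before construction.
#'
#' @param path YAML file path.
#' @param overrides named list of top-level overrides.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  if (!is.null(raw$criteria))
    raw$criteria <- do.call(significance_criteria, raw$criteria)
  if (!is.null(raw$cohort))
    raw$cohort <- do.call(cohort_config, raw$cohort)
  do.call(run_config, raw)
}

stage_seed <- function(seed, stage) seed + 100L * as.integer(stage)

load_pipeline_inputs <- function(config, out_dir) {
  if (!is.null(config$cohort)) {
    cfg <- config$cohort
    cfg$seed <- stage_seed(config$seed, 1L)
    cohort <- generate_cohort(cfg)
    input_dir <- file.path(out_dir, "input")
    write_cohort(cohort, input_dir)
    cohort$input_dir <- input_dir
    return(cohort)
  }
  p <- config$paths
  drug_ids <- if (!is.null(p$drugs))
    read_tsv(p$drugs, colClasses = "character")$drug_id else NULL
  pt_ids <- if (!is.null(p$side_effects))
    read_tsv(p$side_effects, colClasses = "character")$pt_id else NULL
  list(
    se_matrix = read_se_pairs(p$se_pairs, drug_ids = drug_ids, pt_ids = pt_ids),
    fingerprints = read_fingerprints(p$fingerprints, bit_space = config$fp_bits),
    target_map = read_target_map(p$targets),
    ppi = read_ppi_network(p$ppi),
    rank_data = if (!is.null(p$ranks)) read_rank_matrix(p$ranks) else NULL,
    gene_sets = if (!is.null(p$gene_sets)) read_gmt(p$gene_sets) else NULL,
    pt_to_soc = read_mapping(p$pt_to_soc, c("pt_id", "soc")),
    drug_to_atc = read_mapping(p$drug_to_atc, c("drug_id", "atc")),
    index_pt = config$index_pt
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic-cohort generation (when configured),
#' ATC category counting, the chemical-similarity permutation test, the
#' side-effect association screen with SOC roll-up and network export, the
#' target-frequency / PPI-subnetwork analysis, and the transcriptomic
#' signature + enrichment analysis (skipped with a note when rank data or
#' gene sets are absent). All stage outputs are written under `out_dir`;
#' a fixed seed reproduces every output file byte for byte.
#'
#' @param config a [run_config()] or path to a YAML config file.
#' @param out_dir output directory, created if needed.
#' @param quiet suppress stage progress messages.
#' @return Invisibly, the run summary (class `run_summary`), also written
#'   to `out_dir/run_summary.json`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) stop("`config` must be a run_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  files <- character()
  # file list kept relative to out_dir so summaries are location-independent
  rel <- function(paths) sub("^/+", "", sub(out_dir, "", paths, fixed = TRUE))
  note <- function(paths) files <<- c(files, rel(unname(paths)))
  stages <- list()

  ## stage 1: inputs -------------------------------------------------------
  say("[1/6] loading inputs",
      if (!is.null(config$cohort)) " (synthetic cohort)")
  inputs <- load_pipeline_inputs(config, out_dir)
  if (!is.null(inputs$input_dir))
    note(file.path(inputs$input_dir,
                   c(unname(cohort_files), "manifest.tsv")))
  index_pt <- inputs$index_pt %||% config$index_pt
  positives <- drugs_with_pt(inputs$se_matrix, index_pt)
  universe <- inputs$se_matrix$drug_ids
  stages$inputs <- list(
    mode = if (is.null(config$cohort)) "files" else "synthetic",
    n_drugs = length(universe),
    n_side_effects = length(inputs$se_matrix$pt_ids),
    index_pt = index_pt,
    n_index_drugs = length(positives))

  ## stage 2: ATC categories ----------------------------------------------
  say("[2/6] ATC therapeutic categories")
  atc <- count_by_atc(positives, inputs$drug_to_atc)
  note(write_tsv(atc, file.path(out_dir, "atc_counts.tsv")))
  stages$atc <- list(n_categories = nrow(atc))

  ## stage 3: chemical similarity ------------------------------------------
  say("[3/6] chemical similarity permutation test (n_perm = ",
      config$n_perm, ")")
  pairs <- pairwise_similarities(inputs$fingerprints, positives)
  note(write_tsv(pairs, file.path(out_dir, "similarity_pairs.tsv")))
  sim_pairs <- pairs[pairs$jaccard > config$similarity_threshold, , drop = FALSE]
  note(write_tsv(sim_pairs, file.path(out_dir, "similar_pairs.tsv")))
  perm <- permutation_test(inputs$fingerprints, positives, universe,
                           n_perm = config$n_perm,
                           statistic = config$perm_statistic,
                           seed = stage_seed(config$seed, 2L))
  note(write_tsv(
    data.frame(observed = perm$observed_statistic, p_value = perm$p_value,
               n_perm = perm$n_permutations, statistic = perm$statistic_name,
               seed = stage_seed(config$seed, 2L)),
    file.path(out_dir, "permutation_summary.tsv")))
  note(write_tsv(data.frame(null_statistic = perm$null_statistics),
                 file.path(out_dir, "permutation_null.tsv")))
  stages$chem_similarity <- list(
    n_pairs = nrow(pairs),
    n_similar_pairs = nrow(sim_pairs),
    observed_statistic = perm$observed_statistic,
    p_value = perm$p_value)

  ## stage 4: side-effect screen -------------------------------------------
  say("[4/6] side-effect association screen")
  screen <- screen_side_effects(inputs$se_matrix, index_pt, config$criteria)
  note(write_tsv(as.data.frame(screen),
                 file.path(out_dir, "association_table.tsv")))
  sig <- significant_associations(screen)
  rollup <- soc_rollup(sig, inputs$pt_to_soc)
  note(write_tsv(rollup, file.path(out_dir, "soc_rollup.tsv")))
  note(export_network(index_pt, sig, file.path(out_dir, "association_network")))
  stages$se_association <- list(
    n_candidates = nrow(screen),
    n_significant = nrow(sig),
    significant_pts = sig$pt_id)

  ## stage 5: target space --------------------------------------------------
  say("[5/6] target frequency and PPI subnetwork")
  freqs <- target_frequency(inputs$target_map, positives)
  note(write_tsv(freqs, file.path(out_dir, "target_frequency.tsv")))
  top <- top_targets(freqs, k = config$top_k_targets)
  subnet <- ppi_subnetwork(inputs$ppi, top, min_score = config$ppi_min_score)
  note(write_subnetwork(subnet, file.path(out_dir, "target_subnetwork")))
  stages$target_space <- list(
    top_targets = top,
    n_subnetwork_edges = nrow(subnet$edges),
    n_top_in_largest_component = subnet$n_queried_in_largest)

  ## stage 6: transcriptomic signatures --------------------------------------
  if (is.null(inputs$rank_data) || ncol(inputs$rank_data) == 0 ||
      is.null(inputs$gene_sets)) {
    say("[6/6] transcriptomic signatures: skipped (no input)")
    stages$transcriptome <- list(status = "skipped: no input")
  } else {
    say("[6/6] transcriptomic signatures and enrichment")
    cols <- strsplit(colnames(inputs$rank_data), ":", fixed = TRUE)
    col_drug <- vapply(cols, `[`, character(1), 1)
    sig_drugs <- sort(intersect(positives, col_drug))
    signatures <- lapply(sig_drugs, function(d) {
      prl <- borda_merge(inputs$rank_data[, col_drug == d, drop = FALSE],
                         drug_id = d)
      extract_signature(prl, config$n_sig_up, config$n_sig_down)
    })
    sig_rows <- do.call(rbind, lapply(signatures, function(s)
      data.frame(drug_id = s$drug_id,
                 direction = rep(c("up", "down"), c(length(s$up), length(s$down))),
                 rank = c(s$up_ranks, s$down_ranks),
                 gene_id = c(s$up, s$down))))
    note(write_tsv(sig_rows, file.path(out_dir, "signatures.tsv")))
    rep_genes <- representative_genes(signatures, top_n = config$n_representative)
    note(write_tsv(rep_genes, file.path(out_dir, "representative_genes.tsv")))
    enr <- enrich_gene_sets(rep_genes$gene_id, inputs$gene_sets,
                            universe = rownames(inputs$rank_data),
                            alpha = config$enrichment_alpha)
    note(write_tsv(enr, file.path(out_dir, "enrichment.tsv")))
    stages$transcriptome <- list(
      status = "run",
      n_drugs_with_ranks = length(sig_drugs),
      n_representative = nrow(rep_genes),
      n_enriched_sets = sum(enr$significant),
      top_set = if (nrow(enr)) enr$set_id[1] else NA_character_,
      top_set_p_adjusted = if (nrow(enr)) enr$p_adjusted[1] else NA_real_)
  }

  summary <- structure(list(
    package_version = as.character(utils::packageVersion("dimscreen")),
    seed = config$seed,
    parameters = list(
      index_pt = index_pt,
      n_perm = config$n_perm,
      perm_statistic = config$perm_statistic,
      similarity_threshold = config$similarity_threshold,
      criteria = unclass(config$criteria),
      n_sig_up = config$n_sig_up, n_sig_down = config$n_sig_down,
      n_representative = config$n_representative,
      enrichment_alpha = config$enrichment_alpha,
      top_k_targets = config$top_k_targets,
      ppi_min_score = config$ppi_min_score),
    stages = stages,
    files = sort(unique(files))
  ), class = "run_summary")
  summary_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(unclass(summary), summary_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Pipeline run (dimscreen ", x$package_version, ", seed ", x$seed, ")\n",
      sep = "")
  cat("  index drugs:", x$stages$inputs$n_index_drugs, "of",
      x$stages$inputs$n_drugs, "\n")
  cat("  similarity permutation p:",
      format(x$stages$chem_similarity$p_value, digits = 4), "\n")
  cat("  significant side effects:", x$stages$se_association$n_significant, "\n")
  cat("  top targets in largest PPI component:",
      x$stages$target_space$n_top_in_largest_component, "of",
      length(x$stages$target_space$top_targets), "\n")
  if (identical(x$stages$transcriptome$status, "run"))
    cat("  top enriched gene set:", x$stages$transcriptome$top_set,
        "(adjusted p", format(x$stages$transcriptome$top_set_p_adjusted,
                              digits = 3), ")\n")
  else cat("  transcriptome:", x$stages$transcriptome$status, "\n")
  invisible(x)
}
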