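# Serialization of a synthetic cohort to the pipeline's input formats,
# plus the lossless reload used by the file-based pipeline stages.

cohort_files <- c(
  drugs = "drugs.tsv",
  side_effects = "side_effects.tsv",
  se_pairs = "se_pairs.tsv",
  fingerprints = "fingerprints.tsv",
  targets = "targets.tsv",
  ppi = "ppi.tsv",
  ranks = "ranks.tsv",
  gene_sets = "gene_sets.gmt",
  pt_to_soc = "pt_to_soc.tsv",
  drug_to_atc = "drug_to_atc.tsv",
  truth = "ground_truth.txt"
)

#' Write a synthetic cohort to a directory
#'
#' Emits every table in the format its consuming module reads (sparse pair
#' TSV, fingerprint TSV, target TSV, STRING-style PPI TSV, rank TSV, GMT,
#' mapping TSVs), two axis files retaining drugs/PTs with no incident
#' pairs, and a key-value ground-truth sidecar. The cohort round-trips
#' losslessly through [read_cohort()].
#'
#' @param cohort a [generate_cohort()] result.
#' @param directory output directory, created if needed.
#' @return Invisibly, the manifest: data.frame `key`, `file`, `n_rows`
#'   (data rows, excluding headers).
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  p <- function(key) file.path(directory, cohort_files[[key]])

  write_tsv(data.frame(drug_id = cohort$se_matrix$drug_ids), p("drugs"))
  write_tsv(data.frame(pt_id = cohort$se_matrix$pt_ids), p("side_effects"))
  write_se_pairs(cohort$se_matrix, p("se_pairs"))
  write_fingerprints(cohort$fingerprints, p("fingerprints"))
  write_tsv(cohort$target_map, p("targets"))
  write_ppi_network(cohort$ppi, p("ppi"))
  write_rank_matrix(cohort$rank_data, p("ranks"))
  write_gmt(cohort$gene_sets, p("gene_sets"))
  write_tsv(cohort$pt_to_soc, p("pt_to_soc"))
  write_tsv(cohort$drug_to_atc, p("drug_to_atc"))

  truth_lines <- c(
    paste0("index_pt\t", cohort$index_pt),
    paste0("fp_bits\t", cohort$fingerprints$bit_space),
    vapply(names(cohort$truth), function(k)
      paste0(k, "\t", paste(cohort$truth[[k]], collapse = ",")),
      character(1))
  )
  writeLines(truth_lines, p("truth"))

  n_rows <- c(
    drugs = length(cohort$se_matrix$drug_ids),
    side_effects = length(cohort$se_matrix$pt_ids),
    se_pairs = sum(cohort$se_matrix$incidence),
    fingerprints = length(cohort$fingerprints$bits),
    targets = nrow(cohort$target_map),
    ppi = nrow(cohort$ppi$edges),
    ranks = nrow(cohort$rank_data),
    gene_sets = length(cohort$gene_sets),
    pt_to_soc = nrow(cohort$pt_to_soc),
    drug_to_atc = nrow(cohort$drug_to_atc),
    truth = length(truth_lines)
  )
  manifest <- data.frame(key = names(cohort_files),
                         file = unname(cohort_files),
                         n_rows = as.integer(n_rows[names(cohort_files)]))
  write_tsv(manifest, file.path(directory, "manifest.tsv"))
  invisible(manifest)
}

#' Reload a cohort written by [write_cohort()]
#'
#' @param directory the directory written by [write_cohort()].
#' @return A `synthetic_cohort` (without the generating `config`).
#' @export
read_cohort <- function(directory) {
  p <- function(key) file.path(directory, cohort_files[[key]])
  for (key in names(cohort_files))
    if (!file.exists(p(key))) stop("missing cohort file: ", p(key))

  truth_raw <- strsplit(readLines(p("truth")), "\t", fixed = TRUE)
  kv <- stats::setNames(
    lapply(truth_raw, function(x) if (length(x) > 1) x[[2]] else ""),
    vapply(truth_raw, `[`, character(1), 1))
  split_ids <- function(s) if (identical(s, "")) character() else
    strsplit(s, ",", fixed = TRUE)[[1]]
  truth <- list(
    dim_drugs = split_ids(kv$dim_drugs),
    planted_assoc_se = split_ids(kv$planted_assoc_se),
    core_bit_ids = as.integer(split_ids(kv$core_bit_ids)),
    hub_targets = split_ids(kv$hub_targets),
    sig_up_genes = split_ids(kv$sig_up_genes),
    sig_down_genes = split_ids(kv$sig_down_genes),
    planted_pathway = kv$planted_pathway
  )

  drug_ids <- read_tsv(p("drugs"), colClasses = "character")$drug_id
  pt_ids <- read_tsv(p("side_effects"), colClasses = "character")$pt_id
  structure(list(
    se_matrix = read_se_pairs(p("se_pairs"), drug_ids = drug_ids, pt_ids = pt_ids),
    fingerprints = read_fingerprints(p("fingerprints"),
                                     bit_space = as.integer(kv$fp_bits)),
    target_map = read_target_map(p("targets")),
    ppi = suppressMessages(read_ppi_network(p("ppi"))),
    rank_data = read_rank_matrix(p("ranks")),
    gene_sets = read_gmt(p("gene_sets")),
    pt_to_soc = read_mapping(p("pt_to_soc"), c("pt_id", "soc")),
    drug_to_atc = read_mapping(p("drug_to_atc"), c("drug_id", "atc")),
    index_pt = kv$index_pt,
    truth = truth,
    config = NULL
  ), class = "synthetic_cohort")
}
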