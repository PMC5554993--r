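# Synthetic cohort generation with planted ground truth.

#' Generate a synthetic study cohort
#'
#' Draws all seven input tables of the analysis with the statistical
#' structure the pipeline assumes, plus ground-truth annotations:
#'
#' * side-effect matrix: the designated index PT (`"myopathy"`) equals the
#'   cluster membership indicator exactly; background PTs are Bernoulli with
#'   Beta-distributed per-PT prevalence; planted PTs get their within-cluster
#'   odds multiplied by `assoc_lift` (probability capped at 0.95);
#' * fingerprints: background bits at `fp_density`; the cluster's core bits
#'   are drawn at `core_adopt_prob` instead (not in addition), so setting
#'   `core_adopt_prob = fp_density` yields an exact null;
#' * targets: Poisson background per drug; cluster drugs additionally hit
#'   each hub target with `hub_target_prob`;
#' * PPI: Erdos-Renyi background with uniform 0-0.999 confidence scores;
#'   hub targets are wired as a high-confidence clique (scores 0.7-0.95);
#' * ranked lists (cluster drugs x cell lines): i.i.d. uniform latent scores
#'   per gene, `+sig_strength` for planted up genes and `-sig_strength` for
#'   planted down genes, ranked descending (rank 1 = most up-regulated) with
#'   ties broken by gene id;
#' * gene sets: one planted pathway containing `pathway_sig_frac` of the
#'   planted signature genes (padded with random genes to `genes_per_set`),
#'   the rest uniform random sets.
#'
#' Deterministic for a fixed config and seed.
#'
#' @param config a [cohort_config()].
#' @return Object of class `synthetic_cohort` with elements `se_matrix`,
#'   `fingerprints`, `target_map`, `ppi`, `rank_data` (gene x drug:cell
#'   integer rank matrix), `gene_sets`, `pt_to_soc`, `drug_to_atc`, `truth`
#'   and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, as.list(config))
  validate_cohort_config(config)
  set.seed(config$seed)
  cfg <- config

  drug_ids <- sprintf("D%04d", seq_len(cfg$n_drugs))
  dim_drugs <- sort(sample(drug_ids, cfg$n_dim_drugs))
  is_dim <- drug_ids %in% dim_drugs

  index_pt <- "myopathy"
  other_pts <- sprintf("SE%04d", seq_len(cfg$n_side_effects - 1L))
  planted_se <- sort(sample(other_pts, cfg$n_assoc_se))

  ## --- side-effect matrix -------------------------------------------------
  prev <- stats::rbeta(length(other_pts), cfg$se_base_prev[1], cfg$se_base_prev[2])
  is_planted <- other_pts %in% planted_se
  prev[is_planted] <- stats::rbeta(sum(is_planted),
                                   cfg$assoc_se_prev[1], cfg$assoc_se_prev[2])
  odds <- prev / (1 - prev)
  lifted <- pmin(0.95, cfg$assoc_lift * odds / (1 + cfg$assoc_lift * odds))
  P <- matrix(prev, nrow = cfg$n_drugs, ncol = length(other_pts), byrow = TRUE)
  P[is_dim, is_planted] <- matrix(lifted[is_planted], nrow = sum(is_dim),
                                  ncol = sum(is_planted), byrow = TRUE)
  inc_other <- matrix(stats::runif(length(P)) < P, nrow = cfg$n_drugs)
  inc <- cbind(is_dim, inc_other)
  dimnames(inc) <- list(drug_ids, c(index_pt, other_pts))
  idx <- which(inc, arr.ind = TRUE)
  sem <- se_matrix(data.frame(drug_id = rownames(inc)[idx[, 1]],
                              pt_id = colnames(inc)[idx[, 2]]),
                   drug_ids = drug_ids, pt_ids = c(index_pt, other_pts))

  ## --- fingerprints -------------------------------------------------------
  core_bit_ids <- sort(sample(seq_len(cfg$fp_bits), cfg$core_bits)) - 1L
  fp <- matrix(stats::runif(cfg$n_drugs * cfg$fp_bits) < cfg$fp_density,
               nrow = cfg$n_drugs)
  if (cfg$core_bits > 0 && any(is_dim))
    fp[is_dim, core_bit_ids + 1L] <-
      stats::runif(sum(is_dim) * cfg$core_bits) < cfg$core_adopt_prob
  bits <- apply(fp, 1, function(row) which(row) - 1L, simplify = FALSE)
  names(bits) <- drug_ids
  fps <- fingerprint_set(bits, bit_space = cfg$fp_bits)

  ## --- drug-target map ----------------------------------------------------
  target_ids <- sprintf("T%03d", seq_len(cfg$n_targets))
  hub_targets <- sort(sample(target_ids, cfg$n_hub_targets))
  rows <- lapply(seq_len(cfg$n_drugs), function(i) {
    k <- min(stats::rpois(1, cfg$background_target_rate), cfg$n_targets)
    hits <- if (k > 0) sample(target_ids, k) else character()
    if (is_dim[i] && cfg$n_hub_targets > 0) {
      extra <- hub_targets[stats::runif(cfg$n_hub_targets) < cfg$hub_target_prob]
      hits <- union(hits, extra)
    }
    if (length(hits))
      data.frame(drug_id = drug_ids[i], target_id = sort(hits))
    else NULL
  })
  target_map <- do.call(rbind, c(rows, list(
    data.frame(drug_id = character(), target_id = character()))))
  rownames(target_map) <- NULL

  ## --- PPI edge list ------------------------------------------------------
  n_t <- cfg$n_targets
  if (n_t >= 2) {
    i <- rep.int(seq_len(n_t - 1L), rev(seq_len(n_t - 1L)))
    j <- unlist(lapply(seq_len(n_t - 1L), function(k) (k + 1L):n_t),
                use.names = FALSE)
    keep <- stats::runif(length(i)) < cfg$ppi_background_edge_prob
    ppi_edges <- data.frame(node_a = target_ids[i[keep]],
                            node_b = target_ids[j[keep]],
                            score = round(stats::runif(sum(keep)), 3))
  } else {
    ppi_edges <- data.frame(node_a = character(), node_b = character(),
                            score = numeric())
  }
  if (cfg$n_hub_targets >= 2) {  # high-confidence clique among the hubs
    hi <- utils::combn(hub_targets, 2)
    clique <- data.frame(node_a = hi[1, ], node_b = hi[2, ],
                         score = round(stats::runif(ncol(hi), 0.70, 0.95), 3))
    ppi_edges <- rbind(ppi_edges, clique)
  }
  ppi <- ppi_network(ppi_edges)

  ## --- ranked gene lists --------------------------------------------------
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  sig_genes <- sample(gene_ids, cfg$n_sig_up + cfg$n_sig_down)
  sig_up <- sort(sig_genes[seq_len(cfg$n_sig_up)])
  sig_down <- sort(sig_genes[cfg$n_sig_up + seq_len(cfg$n_sig_down)])
  cell_lines <- sprintf("CL%d", seq_len(cfg$n_cell_lines))
  cols <- as.vector(outer(dim_drugs, cell_lines, paste, sep = ":"))
  rank_data <- matrix(0L, nrow = cfg$n_genes, ncol = length(cols),
                      dimnames = list(gene_ids, cols))
  shift <- numeric(cfg$n_genes)
  shift[gene_ids %in% sig_up] <- cfg$sig_strength
  shift[gene_ids %in% sig_down] <- -cfg$sig_strength
  for (cidx in seq_along(cols)) {
    score <- stats::runif(cfg$n_genes) + shift
    ord <- order(-score, gene_ids)
    r <- integer(cfg$n_genes)
    r[ord] <- seq_len(cfg$n_genes)
    rank_data[, cidx] <- r
  }

  ## --- gene sets ----------------------------------------------------------
  set_ids <- sprintf("GS%02d", seq_len(cfg$n_gene_sets))
  planted_pathway <- sample(set_ids, 1)
  gene_sets <- lapply(set_ids, function(id) sort(sample(gene_ids, cfg$genes_per_set)))
  names(gene_sets) <- set_ids
  n_core <- ceiling(cfg$pathway_sig_frac * length(sig_genes))
  core <- sample(sig_genes, n_core)
  pad <- sample(setdiff(gene_ids, core),
                max(0L, cfg$genes_per_set - n_core))
  gene_sets[[planted_pathway]] <- sort(c(core, pad))

  ## --- ontology mappings --------------------------------------------------
  socs <- sprintf("SOC%02d", seq_len(cfg$n_socs))
  pt_to_soc <- data.frame(pt_id = c(index_pt, other_pts),
                          soc = sample(socs, cfg$n_side_effects, replace = TRUE))
  atc_groups <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N", "P", "R", "S", "V")
  atc_pool <- unique(paste0(sample(atc_groups, cfg$n_atc_codes, replace = TRUE),
                            sprintf("%02d", sample(1:16, cfg$n_atc_codes, replace = TRUE))))
  drug_to_atc <- data.frame(drug_id = drug_ids,
                            atc = sample(atc_pool, cfg$n_drugs, replace = TRUE))
  # a small fraction of drugs carry a second code, as real ATC does
  second <- drug_ids[stats::runif(cfg$n_drugs) < 0.03]
  if (length(second))
    drug_to_atc <- rbind(drug_to_atc,
                         data.frame(drug_id = second,
                                    atc = sample(atc_pool, length(second),
                                                 replace = TRUE)))
  drug_to_atc <- unique(drug_to_atc[order(drug_to_atc$drug_id, drug_to_atc$atc), ])
  rownames(drug_to_atc) <- NULL

  truth <- list(dim_drugs = dim_drugs,
                planted_assoc_se = planted_se,
                core_bit_ids = core_bit_ids,
                hub_targets = hub_targets,
                sig_up_genes = sig_up,
                sig_down_genes = sig_down,
                planted_pathway = planted_pathway)

  structure(list(se_matrix = sem,
                 fingerprints = fps,
                 target_map = target_map,
                 ppi = ppi,
                 rank_data = rank_data,
                 gene_sets = gene_sets,
                 pt_to_soc = pt_to_soc,
                 drug_to_atc = drug_to_atc,
                 index_pt = index_pt,
                 truth = truth,
                 config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$se_matrix$drug_ids), "drugs,",
      length(x$se_matrix$pt_ids), "side effects,",
      length(x$truth$dim_drugs), "index-event drugs\n")
  cat("  tables: fingerprints (", x$fingerprints$bit_space, " bits), ",
      nrow(x$target_map), " drug-target pairs, ",
      nrow(x$ppi$edges), " PPI edges, ",
      ncol(x$rank_data), " ranked lists, ",
      length(x$gene_sets), " gene sets\n", sep = "")
  invisible(x)
}
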