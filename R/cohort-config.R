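# Configuration of the synthetic study cohort.

#' Configure a synthetic drug-safety cohort
#'
#' Parameterizes [generate_cohort()]: a drug universe with a structurally
#' coherent index-event (DIM) drug cluster, a sparse drug-by-side-effect
#' matrix with planted associated side effects, a drug-target map with hub
#' targets shared by the cluster, a scored PPI edge list, per-(drug, cell
#' line) ranked gene lists with planted up/down signature genes, a gene-set
#' collection containing a planted pathway, and PT-to-SOC / drug-to-ATC
#' mappings.
#'
#' Defaults describe the test-scale cohort (200 drugs x 300 side effects,
#' 20 index drugs); full SIDER-scale dimensions (996 x 4500, 75 index drugs) are
#' supported by overriding `n_drugs`, `n_side_effects` and `n_dim_drugs`.
#'
#' @param n_drugs,n_side_effects matrix dimensions (the side-effect count
#'   includes the index term).
#' @param n_dim_drugs size of the index-event drug cluster.
#' @param fp_bits fingerprint bit-space size.
#' @param fp_density background per-bit set probability.
#' @param core_bits number of shared "core" substructure bits planted in the
#'   cluster.
#' @param core_adopt_prob probability that a cluster drug carries each core
#'   bit (core bits of cluster drugs are drawn at this rate instead of
#'   `fp_density`, so `core_adopt_prob = fp_density` is an exact null).
#' @param se_base_prev two shape parameters of the Beta law for background
#'   side-effect prevalence (default `c(0.3, 6)`, sparse and skewed).
#' @param assoc_se_prev Beta shape parameters for the baseline prevalence of
#'   the planted associated side effects (default `c(120, 270)`: moderately
#'   common terms with baseline prevalence near 0.31). Planted effects
#'   are deliberately drawn from a less skewed law than the background so
#'   that a lift-`assoc_lift` association lies inside the detectability
#'   window of the compound screening criterion; the methods vignette
#'   derives that window.
#' @param n_assoc_se number of side effects truly lifted in cluster drugs.
#' @param assoc_lift odds multiplier applied to the baseline prevalence of
#'   planted side effects within the cluster (lifted probability capped at
#'   0.95); `assoc_lift = 1` is a null.
#' @param n_targets,n_hub_targets target universe and planted hub count.
#' @param hub_target_prob probability a cluster drug hits each hub target.
#' @param background_target_rate mean (Poisson) number of background targets
#'   per drug.
#' @param n_genes,n_cell_lines rank-array dimensions; ranked lists are
#'   generated for the cluster drugs in every cell line.
#' @param n_sig_up,n_sig_down numbers of planted up/down signature genes.
#' @param sig_strength rank-shift intensity in `[0, 1]`: planted genes'
#'   latent scores are shifted by `sig_strength` times the score range.
#' @param n_gene_sets,genes_per_set gene-set collection shape.
#' @param pathway_sig_frac fraction of the planted signature genes included
#'   in the planted pathway set (default 0.9, always at least 0.8).
#' @param ppi_background_edge_prob background edge probability among targets.
#' @param n_socs,n_atc_codes sizes of the SOC and ATC level-2 code pools.
#' @param seed integer seed; equal configs with equal seeds generate
#'   byte-identical cohorts.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_drugs = 200,
                          n_side_effects = 300,
                          n_dim_drugs = 20,
                          fp_bits = 1024,
                          fp_density = 0.02,
                          core_bits = 40,
                          core_adopt_prob = 0.8,
                          se_base_prev = c(0.3, 6),
                          assoc_se_prev = c(120, 270),
                          n_assoc_se = 10,
                          assoc_lift = 20,
                          n_targets = 100,
                          n_hub_targets = 5,
                          hub_target_prob = 0.9,
                          background_target_rate = 2,
                          n_genes = 1000,
                          n_cell_lines = 3,
                          n_sig_up = 60,
                          n_sig_down = 40,
                          sig_strength = 0.8,
                          n_gene_sets = 50,
                          genes_per_set = 100,
                          pathway_sig_frac = 0.9,
                          ppi_background_edge_prob = 0.05,
                          n_socs = 15,
                          n_atc_codes = 20,
                          seed = 1L) {
  cfg <- list(n_drugs = as.integer(n_drugs),
              n_side_effects = as.integer(n_side_effects),
              n_dim_drugs = as.integer(n_dim_drugs),
              fp_bits = as.integer(fp_bits),
              fp_density = fp_density,
              core_bits = as.integer(core_bits),
              core_adopt_prob = core_adopt_prob,
              se_base_prev = as.numeric(se_base_prev),
              assoc_se_prev = as.numeric(assoc_se_prev),
              n_assoc_se = as.integer(n_assoc_se),
              assoc_lift = assoc_lift,
              n_targets = as.integer(n_targets),
              n_hub_targets = as.integer(n_hub_targets),
              hub_target_prob = hub_target_prob,
              background_target_rate = background_target_rate,
              n_genes = as.integer(n_genes),
              n_cell_lines = as.integer(n_cell_lines),
              n_sig_up = as.integer(n_sig_up),
              n_sig_down = as.integer(n_sig_down),
              sig_strength = sig_strength,
              n_gene_sets = as.integer(n_gene_sets),
              genes_per_set = as.integer(genes_per_set),
              pathway_sig_frac = pathway_sig_frac,
              ppi_background_edge_prob = ppi_background_edge_prob,
              n_socs = as.integer(n_socs),
              n_atc_codes = as.integer(n_atc_codes),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop("invalid cohort config: ", msg,
                                             call. = FALSE)
  chk(cfg$n_drugs >= 1, "n_drugs must be >= 1")
  chk(cfg$n_dim_drugs <= cfg$n_drugs, "n_dim_drugs must not exceed n_drugs")
  chk(cfg$n_dim_drugs >= 1, "n_dim_drugs must be >= 1")
  chk(cfg$n_side_effects >= 2, "n_side_effects must be >= 2")
  chk(cfg$core_bits <= cfg$fp_bits, "core_bits must not exceed fp_bits")
  chk(cfg$n_assoc_se < cfg$n_side_effects,
      "n_assoc_se must be below n_side_effects")
  chk(cfg$n_sig_up + cfg$n_sig_down <= cfg$n_genes,
      "n_sig_up + n_sig_down must not exceed n_genes")
  for (p in c("fp_density", "core_adopt_prob", "hub_target_prob",
              "sig_strength", "ppi_background_edge_prob", "pathway_sig_frac"))
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1, paste(p, "must lie in [0, 1]"))
  chk(all(cfg$se_base_prev > 0) && length(cfg$se_base_prev) == 2,
      "se_base_prev must be two positive Beta shapes")
  chk(all(cfg$assoc_se_prev > 0) && length(cfg$assoc_se_prev) == 2,
      "assoc_se_prev must be two positive Beta shapes")
  chk(cfg$assoc_lift > 0, "assoc_lift must be positive")
  chk(cfg$background_target_rate >= 0,
      "background_target_rate must be non-negative")
  chk(cfg$n_hub_targets <= cfg$n_targets,
      "n_hub_targets must not exceed n_targets")
  chk(cfg$n_cell_lines >= 1, "n_cell_lines must be >= 1")
  chk(cfg$pathway_sig_frac >= 0.8,
      "pathway_sig_frac must be >= 0.8 (planted pathway must cover the signature)")
  chk(!is.na(cfg$seed), "seed must be an integer")
  invisible(cfg)
}

#' Zero-effect variant of a cohort configuration
#'
#' Removes every planted effect: `assoc_lift = 1`,
#' `core_adopt_prob = fp_density`, `sig_strength = 0`,
#' `hub_target_prob = 0`. Downstream screens behave as null on such
#' cohorts.
#'
#' @param config a [cohort_config()].
#' @return A `cohort_config` with all effects switched off.
#' @export
null_config <- function(config) {
  config$assoc_lift <- 1
  config$core_adopt_prob <- config$fp_density
  config$sig_strength <- 0
  config$hub_target_prob <- 0
  validate_cohort_config(config)
  config
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort config:", x$n_drugs, "drugs x", x$n_side_effects,
      "side effects;", x$n_dim_drugs, "index-event drugs; seed", x$seed, "\n")
  cat("  planted: ", x$n_assoc_se, " side effects (lift ", x$assoc_lift,
      "), ", x$core_bits, " core bits (adopt ", x$core_adopt_prob, "), ",
      x$n_hub_targets, " hub targets, ",
      x$n_sig_up, "+", x$n_sig_down, " signature genes (strength ",
      x$sig_strength, ")\n", sep = "")
  invisible(x)
}
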