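# Shared fixtures: slim cohort configurations and small hand-built objects.

# fast cohort for replicate-heavy simulations: full-size drug axis, slim
# auxiliary tables
fast_config <- function(..., seed = 1L) {
  cohort_config(n_drugs = 200, n_side_effects = 60, n_dim_drugs = 20,
                n_genes = 200, n_cell_lines = 1, n_sig_up = 10, n_sig_down = 10,
                n_targets = 30, n_gene_sets = 5, genes_per_set = 25,
                n_assoc_se = 5,
                ..., seed = seed)
}

# tiny fingerprint set with hand-checkable similarities
toy_fps <- function() {
  fingerprint_set(list(
    A = c(1, 2, 3),
    B = c(2, 3, 4),      # J(A,B) = 2/4 = 0.5
    C = c(1, 2, 10, 11), # J(A,C) = 2/5 = 0.4
    D = c(20, 21)        # disjoint from A
  ), bit_space = 64)
}

# small drug x side-effect matrix from explicit drug sets
toy_se_matrix <- function() {
  pairs <- rbind(
    data.frame(drug_id = c("d1", "d2", "d3"), pt_id = "myopathy"),
    data.frame(drug_id = c("d1", "d2", "d4"), pt_id = "SE1"),
    data.frame(drug_id = c("d1", "d5"), pt_id = "SE2")
  )
  se_matrix(pairs, drug_ids = paste0("d", 1:6),
            pt_ids = c("myopathy", "SE1", "SE2"))
}

# exhaustive two-sided Fisher p over all tables with the observed margins,
# written directly from binomial coefficients (independent of fisher.test
# and of dhyper); same point-probability tie tolerance as the screen
fisher_oracle <- function(tp, fp, fn, tn, rel_tol = 1e-7) {
  r1 <- tp + fn; r2 <- fp + tn; c1 <- tp + fp; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  p_obs <- logp[ks == tp]
  sum(exp(logp[logp <= p_obs + log(1 + rel_tol)]))
}
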