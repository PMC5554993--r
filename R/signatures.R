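# Transcriptomic signature space: Borda merge of per-cell-line ranked gene
# lists into a prototype ranked list (PRL), top/bottom signature extraction,
# frequency-based representative genes, and gene-set over-representation.

#' Borda-merge ranked gene lists into a prototype ranked list
#'
#' Each list awards every gene a score of `G - rank` (rank 1 = most
#' up-regulated); summed scores define the merged order. Ties are resolved
#' by mean rank ascending, then gene id ascending, so the PRL is always a
#' total order.
#'
#' @param ranks integer matrix of ranks, genes in rows (rownames = gene
#'   ids), one column per ranked list (e.g. one per cell line for the same
#'   drug). Every column must be a permutation of `1..G` over the identical
#'   gene universe. A named list of rank vectors is also accepted; a
#'   universe mismatch between lists is an error naming the offending genes.
#' @param drug_id optional drug identifier carried in the result.
#' @return Object of class `prl`: `drug_id`, `ranking` (gene ids, best
#'   first), `borda_scores` (named, input gene order), `n_genes`, `n_lists`.
#' @export
borda_merge <- function(ranks, drug_id = NULL) {
  if (is.list(ranks) && !is.data.frame(ranks)) {
    universes <- lapply(ranks, function(r) sort(names(r)))
    for (i in seq_along(universes)[-1]) {
      diff <- c(setdiff(universes[[1]], universes[[i]]),
                setdiff(universes[[i]], universes[[1]]))
      if (length(diff))
        stop("gene universe mismatch between lists: ",
             paste(sort(unique(diff)), collapse = ", "))
    }
    genes <- names(ranks[[1]])
    ranks <- vapply(ranks, function(r) as.integer(r[genes]),
                    integer(length(genes)))
    rownames(ranks) <- genes
  }
  ranks <- as.matrix(ranks)
  if (is.null(rownames(ranks))) stop("`ranks` must carry gene ids as rownames")
  if (ncol(ranks) < 1L) stop("need at least one ranked list")
  G <- nrow(ranks)
  ok <- apply(ranks, 2, function(r) identical(sort(as.integer(r)), seq_len(G)))
  if (!all(ok))
    stop("column(s) ", paste(which(!ok), collapse = ", "),
         " are not permutations of 1..", G)
  score <- rowSums(G - ranks)
  mean_rank <- rowMeans(ranks)
  ord <- order(-score, mean_rank, rownames(ranks))
  structure(list(drug_id = drug_id,
                 ranking = rownames(ranks)[ord],
                 borda_scores = stats::setNames(score, rownames(ranks)),
                 n_genes = G,
                 n_lists = ncol(ranks)),
            class = "prl")
}

#' @export
print.prl <- function(x, ...) {
  cat("Prototype ranked list",
      if (!is.null(x$drug_id)) paste0("for ", x$drug_id) else "",
      "\n  merged from", x$n_lists, "list(s) over", x$n_genes, "genes\n")
  cat("  top genes:", paste(utils::head(x$ranking, 5), collapse = ", "), "...\n")
  invisible(x)
}

#' Extract the up/down signature from a prototype ranked list
#'
#' The signature is the first `n_up` genes (most up-regulated) and the last
#' `n_down` genes of the PRL, the latter reported most-down-regulated first.
#'
#' @param prl a [borda_merge()] result.
#' @param n_up,n_down signature sizes (defaults 100 each);
#'   `n_up + n_down` must not exceed the universe size (no silent clamping).
#' @return Object of class `signature_set`: `drug_id`, `up`, `down`
#'   (ordered gene vectors), `up_ranks`, `down_ranks` (PRL ranks of those
#'   genes), `n_genes`.
#' @export
extract_signature <- function(prl, n_up = 100, n_down = 100) {
  G <- prl$n_genes
  if (n_up < 0 || n_down < 0) stop("signature sizes must be non-negative")
  if (n_up + n_down > G)
    stop("n_up + n_down (", n_up + n_down, ") exceeds the gene universe (", G, ")")
  up <- utils::head(prl$ranking, n_up)
  down <- rev(utils::tail(prl$ranking, n_down))
  structure(list(drug_id = prl$drug_id,
                 up = up, down = down,
                 up_ranks = seq_len(n_up),
                 down_ranks = G + 1L - seq_len(n_down),
                 n_genes = G),
            class = "signature_set")
}

#' Representative genes across a collection of drug signatures
#'
#' Ranks genes by the number of drugs whose signature (up and down taken as
#' a union) contains them. Frequency ties are broken by summed extremity --
#' the gene's total distance from the mid-rank `(G + 1) / 2` over the drugs
#' that carry it, larger first -- and then by gene id, so the ordering is
#' fully deterministic.
#'
#' @param signatures list of [extract_signature()] results over a common
#'   gene universe.
#' @param top_n how many representative genes to return (default 100).
#' @return data.frame `gene_id`, `frequency`, `extremity`, first `top_n`
#'   rows of the full ordering.
#' @export
representative_genes <- function(signatures, top_n = 100) {
  if (length(signatures) == 0) stop("need at least one signature")
  G <- signatures[[1]]$n_genes
  mid <- (G + 1) / 2
  gene <- unlist(lapply(signatures, function(s) c(s$up, s$down)),
                 use.names = FALSE)
  rank <- unlist(lapply(signatures, function(s) c(s$up_ranks, s$down_ranks)),
                 use.names = FALSE)
  drug <- rep(seq_along(signatures),
              vapply(signatures, function(s) length(s$up) + length(s$down),
                     integer(1)))
  # union semantics: a gene in both halves of one drug counts once
  first <- !duplicated(paste(drug, gene, sep = "\r"))
  gene <- gene[first]; rank <- rank[first]
  freq <- table(gene)
  extremity <- tapply(abs(rank - mid), gene, sum)
  out <- data.frame(gene_id = names(freq),
                    frequency = as.integer(freq),
                    extremity = as.numeric(extremity[names(freq)]))
  out <- out[order(-out$frequency, -out$extremity, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Gene-set over-representation by hypergeometric test
#'
#' One-sided (enrichment) Fisher exact p per set from the 2x2 table of
#' set membership against list membership, computed on the hypergeometric
#' tail; BH correction across all tested sets. Every set is intersected
#' with the universe before testing.
#'
#' @param genes character vector, the gene list (must lie in `universe`).
#' @param gene_sets named list of gene-id vectors.
#' @param universe the measured gene universe (e.g. all genes on the rank
#'   arrays).
#' @param alpha BH significance level for the `significant` flag
#'   (default 0.05).
#' @return data.frame sorted by adjusted p ascending: `set_id`, `n_hits`,
#'   `hit_genes` (`;`-joined), `p_raw`, `p_adjusted`, `significant`.
#' @export
enrich_gene_sets <- function(genes, gene_sets, universe, alpha = 0.05) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("`universe` must be non-empty")
  genes <- unique(as.character(genes))
  outside <- setdiff(genes, universe)
  if (length(outside))
    stop("gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  if (length(gene_sets) == 0 || is.null(names(gene_sets)))
    stop("`gene_sets` must be a non-empty named list")
  N <- length(universe)
  k <- length(genes)
  rows <- lapply(names(gene_sets), function(id) {
    s <- intersect(unique(gene_sets[[id]]), universe)
    hits <- intersect(s, genes)
    m <- length(s)
    # P(X >= |hits|), X ~ Hypergeom(m in-set, N - m out, k drawn)
    p <- stats::phyper(length(hits) - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(set_id = id, n_hits = length(hits),
               hit_genes = paste(sort(hits), collapse = ";"),
               p_raw = p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_raw)
  out$significant <- out$p_adjusted < alpha
  out <- out[order(out$p_adjusted, out$p_raw, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
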