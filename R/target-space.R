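# Target space: drug-target frequency ranking and confidence-filtered
# PPI subnetwork extraction among the top targets.

#' Rank protein targets by frequency among a drug subset
#'
#' Counts, per target, the number of distinct drugs of the subset that hit
#' it. Ties are broken by target id so the ordering is deterministic.
#'
#' @param tmap data.frame of drug-target pairs: columns `drug_id`,
#'   `target_id`, optionally `category` and `organism`.
#' @param drugs drug ids defining the subset (e.g. the index-event drugs).
#' @param organism_filter optional organism value; if given and the map has
#'   an `organism` column, only matching rows are counted.
#' @return data.frame `target_id`, `n_drugs`, sorted by count descending
#'   then target id ascending.
#' @export
target_frequency <- function(tmap, drugs, organism_filter = NULL) {
  if (!all(c("drug_id", "target_id") %in% names(tmap)))
    stop("`tmap` needs columns drug_id and target_id")
  keep <- tmap$drug_id %in% drugs
  if (!is.null(organism_filter) && "organism" %in% names(tmap))
    keep <- keep & tmap$organism == organism_filter
  sub <- unique(tmap[keep, c("drug_id", "target_id")])
  if (nrow(sub) == 0)
    return(data.frame(target_id = character(), n_drugs = integer()))
  tab <- table(sub$target_id)
  out <- data.frame(target_id = names(tab), n_drugs = as.integer(tab))
  out <- out[order(-out$n_drugs, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-k most frequent targets
#'
#' @param freqs output of [target_frequency()].
#' @param k how many targets (default 10); shorter lists are returned whole.
#' @return Character vector of target ids.
#' @export
top_targets <- function(freqs, k = 10) {
  if (k < 1) stop("`k` must be >= 1")
  utils::head(freqs$target_id, k)
}

#' Construct a scored protein-protein interaction network
#'
#' Undirected, self-loops dropped, node pairs canonicalized, duplicate
#' edges collapsed to their maximum score. Scores must be confidence values
#' in `[0, 1]` (STRING-style 0-999 integer files are rescaled by the
#' reader, [read_ppi_network()]).
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `score`.
#' @return Object of class `ppi_network` holding the canonical edge table.
#' @export
ppi_network <- function(edges) {
  if (!all(c("node_a", "node_b", "score") %in% names(edges)))
    stop("`edges` needs columns node_a, node_b, score")
  if (nrow(edges) > 0 && (any(edges$score < 0) || any(edges$score > 1)))
    stop("scores must lie in [0, 1]")
  a <- as.character(edges$node_a)
  b <- as.character(edges$node_b)
  keep <- a != b
  ed <- data.frame(node_a = pmin(a[keep], b[keep]),
                   node_b = pmax(a[keep], b[keep]),
                   score = edges$score[keep])
  if (nrow(ed) > 0) {
    key <- paste(ed$node_a, ed$node_b, sep = "\r")
    ed <- ed[order(key, -ed$score), , drop = FALSE]
    ed <- ed[!duplicated(paste(ed$node_a, ed$node_b, sep = "\r")), , drop = FALSE]
    rownames(ed) <- NULL
  }
  structure(list(edges = ed), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  nodes <- unique(c(x$edges$node_a, x$edges$node_b))
  cat("PPI network:", length(nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Confidence-filtered PPI subnetwork among a node set
#'
#' Induced subgraph on `nodes` keeping only edges with confidence strictly
#' greater than `min_score` (screening default 0.4). Queried nodes absent
#' from the network, or left edgeless by the filter, appear as isolated
#' singleton components, so the component summary always accounts for every
#' queried node.
#'
#' @param net a [ppi_network()].
#' @param nodes node ids to induce on (e.g. the top-10 targets).
#' @param min_score confidence cutoff in `[0, 1]`, strict (default 0.4).
#' @return Object of class `ppi_subnetwork`: `edges` (filtered edge table),
#'   `membership` (data.frame node/component), `component_sizes` (descending),
#'   `n_queried_in_largest`.
#' @export
ppi_subnetwork <- function(net, nodes, min_score = 0.4) {
  if (min_score < 0 || min_score > 1) stop("`min_score` must be in [0, 1]")
  nodes <- sort(unique(as.character(nodes)))
  ed <- net$edges
  keep <- ed$node_a %in% nodes & ed$node_b %in% nodes & ed$score > min_score
  ed <- ed[keep, , drop = FALSE]
  rownames(ed) <- NULL
  g <- igraph::graph_from_data_frame(ed[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  structure(list(
    edges = ed,
    membership = data.frame(node = names(comp$membership),
                            component = as.integer(comp$membership)),
    component_sizes = sizes,
    n_queried_in_largest = if (length(sizes)) sizes[1] else 0L,
    min_score = min_score
  ), class = "ppi_subnetwork")
}

#' @export
print.ppi_subnetwork <- function(x, ...) {
  cat("PPI subnetwork (score >", x$min_score, "):",
      nrow(x$membership), "nodes,", nrow(x$edges), "edges\n")
  cat("  component sizes:", paste(x$component_sizes, collapse = ", "), "\n")
  cat("  queried nodes in largest component:", x$n_queried_in_largest, "\n")
  invisible(x)
}

#' Write a subnetwork as SIF plus component summary
#'
#' @param subnet a [ppi_subnetwork()].
#' @param path_prefix writes `<prefix>.sif` and `<prefix>_components.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_subnetwork <- function(subnet, path_prefix) {
  sif_path <- paste0(path_prefix, ".sif")
  comp_path <- paste0(path_prefix, "_components.tsv")
  sif <- data.frame(source = subnet$edges$node_a,
                    interaction = rep("pp", nrow(subnet$edges)),
                    target = subnet$edges$node_b)
  utils::write.table(sif, sif_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv(subnet$membership, comp_path)
  invisible(c(sif = sif_path, components = comp_path))
}
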