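# Readers and writers for the pipeline's plain-text table formats.
# All tables are tab-separated with a header line unless noted (SIF, GMT).

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read / write a sparse side-effect pair table
#'
#' Format: TSV with header, columns `drug_id`, `pt_id`, one row per incident
#' pair.
#'
#' @param path file path.
#' @param drug_ids,pt_ids optional full axes (see [se_matrix()]).
#' @return [read_se_pairs()]: an [se_matrix()]; writers return the path
#'   invisibly.
#' @export
read_se_pairs <- function(path, drug_ids = NULL, pt_ids = NULL) {
  se_matrix(read_tsv(path, colClasses = "character"),
            drug_ids = drug_ids, pt_ids = pt_ids)
}

#' @rdname read_se_pairs
#' @param matrix an [se_matrix()].
#' @export
write_se_pairs <- function(matrix, path) {
  idx <- which(as.matrix(matrix$incidence) > 0, arr.ind = TRUE)
  df <- data.frame(drug_id = matrix$drug_ids[idx[, 1]],
                   pt_id = matrix$pt_ids[idx[, 2]])
  df <- df[order(df$drug_id, df$pt_id), , drop = FALSE]
  write_tsv(df, path)
}

#' Read / write fingerprint tables
#'
#' Format: TSV with header, columns `drug_id` and `bits`, the latter a
#' comma-separated list of zero-based set-bit indices (empty for a drug
#' with no bits set).
#'
#' @param path file path.
#' @param bit_space bit-space size of the fingerprints.
#' @return [read_fingerprints()]: a [fingerprint_set()].
#' @export
read_fingerprints <- function(path, bit_space) {
  df <- read_tsv(path, colClasses = "character")
  if (!all(c("drug_id", "bits") %in% names(df)))
    stop("fingerprint file needs header columns drug_id and bits: ", path)
  bits <- lapply(df$bits, function(s) {
    if (is.na(s) || s == "") integer() else as.integer(strsplit(s, ",")[[1]])
  })
  names(bits) <- df$drug_id
  fingerprint_set(bits, bit_space = bit_space)
}

#' @rdname read_fingerprints
#' @param fps a [fingerprint_set()].
#' @export
write_fingerprints <- function(fps, path) {
  df <- data.frame(drug_id = names(fps$bits),
                   bits = vapply(fps$bits, paste, collapse = ",",
                                 FUN.VALUE = character(1)))
  write_tsv(df[order(df$drug_id), , drop = FALSE], path)
}

#' Read a drug-target table
#'
#' TSV with header; columns `drug_id`, `target_id`, optionally `category`
#' and `organism`.
#'
#' @param path file path.
#' @return data.frame of unique pairs.
#' @export
read_target_map <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  if (!all(c("drug_id", "target_id") %in% names(df)))
    stop("target file needs columns drug_id and target_id: ", path)
  unique(df)
}

#' Read a scored PPI edge list
#'
#' TSV with header, columns `node_a`, `node_b`, `combined_score`. Scores
#' may be STRING-style integers 0-999 or reals in `[0, 1]`; the scale is
#' auto-detected by magnitude (any score above 1 implies the integer
#' convention) and integer scores are divided by 1000, with a message.
#'
#' @param path file path.
#' @return A [ppi_network()].
#' @export
read_ppi_network <- function(path) {
  df <- read_tsv(path)
  if (!all(c("node_a", "node_b", "combined_score") %in% names(df)))
    stop("PPI file needs columns node_a, node_b, combined_score: ", path)
  score <- as.numeric(df$combined_score)
  if (length(score) && max(score) > 1) {
    message("PPI scores read as STRING-style 0-999 integers; dividing by 1000")
    score <- score / 1000
  }
  ppi_network(data.frame(node_a = as.character(df$node_a),
                         node_b = as.character(df$node_b),
                         score = score))
}

#' @rdname read_ppi_network
#' @param net a [ppi_network()]; written with integer 0-999 scores.
#' @export
write_ppi_network <- function(net, path) {
  df <- data.frame(node_a = net$edges$node_a,
                   node_b = net$edges$node_b,
                   combined_score = as.integer(round(net$edges$score * 1000)))
  write_tsv(df, path)
}

#' Read / write a rank matrix
#'
#' TSV with header: first column `gene_id`, then one column per ranked list
#' named `drug:cell_line`, holding integer ranks `1..G` (rank 1 = most
#' up-regulated).
#'
#' @param path file path.
#' @return Integer matrix, genes in rows (rownames), lists in columns.
#' @export
read_rank_matrix <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1] != "gene_id")
    stop("rank file must start with a gene_id column: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  m
}

#' @rdname read_rank_matrix
#' @param ranks integer rank matrix with gene rownames.
#' @export
write_rank_matrix <- function(ranks, path) {
  df <- data.frame(gene_id = rownames(ranks), ranks, check.names = FALSE)
  write_tsv(df, path)
}

#' Read / write GMT gene-set collections
#'
#' Standard GMT lines: `set_id TAB description TAB gene TAB gene ...`.
#'
#' @param path file path.
#' @return Named list of gene-id vectors; descriptions kept as an attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' @rdname read_gmt
#' @param gene_sets named list of gene-id vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- attr(gene_sets, "description") %||% names(gene_sets)
  lines <- mapply(function(id, desc, genes)
    paste(c(id, desc, genes), collapse = "\t"),
    names(gene_sets), descriptions, gene_sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read a two-column mapping table
#'
#' Generic loader for PT-to-SOC and drug-to-ATC tables: TSV with a header
#' naming the two columns.
#'
#' @param path file path.
#' @param columns expected column names, checked against the header.
#' @return data.frame with the two character columns.
#' @export
read_mapping <- function(path, columns) {
  df <- read_tsv(path, colClasses = "character")
  if (!all(columns %in% names(df)))
    stop("mapping file ", path, " must have columns: ",
         paste(columns, collapse = ", "))
  df[, columns, drop = FALSE]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
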