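# Chemical-similarity space: Jaccard similarity over binary fingerprints,
# similar-pair extraction, and the randomized-negative permutation test.

#' Construct a binary fingerprint set
#'
#' Holds one bit-index set per drug over a fixed bit space, the in-memory
#' representation of circular substructure fingerprints (ECFP-4-like).
#' Bit indices are zero-based, as in the on-disk TSV format.
#'
#' @param bits named list; one integer vector of set-bit indices per drug.
#'   Names are drug identifiers and must be unique. Empty vectors are allowed.
#' @param bit_space size of the bit space; every index must lie in
#'   `[0, bit_space)`.
#' @return An object of class `fingerprint_set` with elements `bit_space`
#'   and `bits` (sorted, de-duplicated index vectors).
#' @examples
#' fps <- fingerprint_set(list(D1 = c(0, 5, 9), D2 = c(5, 9, 20)), bit_space = 64)
#' jaccard(fps$bits$D1, fps$bits$D2)
#' @export
fingerprint_set <- function(bits, bit_space) {
  if (!is.list(bits)) stop("`bits` must be a named list of bit-index vectors")
  if (is.null(names(bits)) || any(names(bits) == "") || anyDuplicated(names(bits)))
    stop("`bits` must have unique, non-empty drug-id names")
  bit_space <- as.integer(bit_space)
  if (length(bit_space) != 1L || is.na(bit_space) || bit_space < 1L)
    stop("`bit_space` must be a single positive integer")
  bits <- lapply(bits, function(b) sort(unique(as.integer(b))))
  bad <- vapply(bits, function(b)
    length(b) > 0L && (b[1L] < 0L || b[length(b)] >= bit_space), logical(1))
  if (any(bad))
    stop("bit indices outside [0, bit_space) for drug(s): ",
         paste(names(bits)[bad], collapse = ", "))
  structure(list(bit_space = bit_space, bits = bits), class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat("Fingerprint set:", length(x$bits), "drugs over", x$bit_space, "bits\n")
  cat("  mean bits set per drug:",
      round(mean(lengths(x$bits)), 2), "\n")
  invisible(x)
}

#' Jaccard (Tanimoto) similarity of two bit-index sets
#'
#' `|a intersect b| / |a union b|`. Two empty sets are defined to have
#' similarity 0 (the 0/0 case carries no structural information).
#'
#' @param a,b vectors of set-bit indices.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

# drugs x bit_space sparse 0/1 matrix for fast pairwise intersections
fp_matrix <- function(fps, drugs) {
  missing <- setdiff(drugs, names(fps$bits))
  if (length(missing))
    stop("drug id(s) not in fingerprint set: ", paste(missing, collapse = ", "))
  idx <- fps$bits[drugs]
  Matrix::sparseMatrix(
    i = rep.int(seq_along(drugs), lengths(idx)),
    j = unlist(idx, use.names = FALSE) + 1L,
    x = 1,
    dims = c(length(drugs), fps$bit_space),
    dimnames = list(drugs, NULL)
  )
}

# dense drug x drug Jaccard matrix (diagonal = 1 where nonempty)
jaccard_matrix <- function(fps, drugs) {
  M <- fp_matrix(fps, drugs)
  inter <- as.matrix(Matrix::tcrossprod(M))
  sz <- Matrix::rowSums(M)
  un <- outer(sz, sz, `+`) - inter
  sim <- ifelse(un == 0, 0, inter / un)
  dimnames(sim) <- list(drugs, drugs)
  sim
}

#' All pairwise Jaccard similarities among a drug list
#'
#' Enumerates every unordered pair once, in lexicographic pair order, so
#' `n` drugs yield exactly `choose(n, 2)` rows (75 drugs give 2775 pairs).
#'
#' @param fps a [fingerprint_set()].
#' @param drugs character vector of distinct drug ids present in `fps`.
#' @return data.frame with columns `drug_a`, `drug_b`, `jaccard`.
#' @export
pairwise_similarities <- function(fps, drugs) {
  drugs <- as.character(drugs)
  if (anyDuplicated(drugs)) stop("`drugs` must be distinct")
  drugs <- sort(drugs)
  n <- length(drugs)
  if (n < 2L)
    return(data.frame(drug_a = character(), drug_b = character(),
                      jaccard = numeric()))
  sim <- jaccard_matrix(fps, drugs)
  i <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  data.frame(drug_a = drugs[i], drug_b = drugs[j], jaccard = sim[cbind(i, j)])
}

#' Extract similar drug pairs above a Jaccard threshold
#'
#' Pairs with similarity strictly greater than `threshold`; the screening
#' default is 0.4.
#'
#' @inheritParams pairwise_similarities
#' @param threshold Jaccard cutoff in `[0, 1]`; strict inequality.
#' @return data.frame as [pairwise_similarities()], filtered.
#' @export
similar_pairs <- function(fps, drugs, threshold = 0.4) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("`threshold` must be a single value in [0, 1]")
  pairs <- pairwise_similarities(fps, drugs)
  pairs[pairs$jaccard > threshold, , drop = FALSE]
}

#' Permutation test for excess self-similarity of a drug class
#'
#' Tests whether a positive drug class (e.g. drugs labelled with the index
#' side effect) is more chemically self-similar than random drug sets of the
#' same size. The observed statistic (median or mean of all pairwise Jaccard
#' similarities among the positives) is compared with the same statistic on
#' `n_perm` random draws of `|positives|` drugs, sampled uniformly without
#' replacement from `universe` minus the positives. The p-value uses the
#' add-one estimator `(1 + #{null >= observed}) / (n_perm + 1)`, which can
#' never be exactly zero and is well calibrated under the null.
#'
#' @param fps a [fingerprint_set()].
#' @param positives drug ids of the positive class.
#' @param universe drug ids defining the sampling universe; the negative pool
#'   is `setdiff(universe, positives)` and must contain at least
#'   `length(positives)` drugs.
#' @param n_perm number of permutations (default 10000).
#' @param statistic `"median"` (default) or `"mean"`.
#' @param seed optional integer seed for the permutation draws.
#' @return Object of class `perm_test`: `observed_statistic`,
#'   `null_statistics`, `p_value`, `statistic_name`, `n_permutations`, `seed`.
#' @seealso [similarity_var_test()] for a variance-ratio comparison of the
#'   two similarity distributions.
#' @export
permutation_test <- function(fps, positives, universe,
                             n_perm = 10000, statistic = c("median", "mean"),
                             seed = NULL) {
  statistic <- match.arg(statistic)
  positives <- unique(as.character(positives))
  universe <- unique(as.character(universe))
  if (length(positives) < 2L) stop("need at least 2 positive drugs")
  if (n_perm < 1L) stop("`n_perm` must be >= 1")
  pool <- setdiff(universe, positives)
  if (length(pool) < length(positives))
    stop("negative pool (", length(pool), " drugs) smaller than the positive set (",
         length(positives), ")")
  if (!is.null(seed)) set.seed(seed)

  statfun <- switch(statistic, median = stats::median, mean = mean)
  k <- length(positives)
  sim <- jaccard_matrix(fps, c(positives, pool))
  up <- upper.tri(matrix(0, k, k))
  set_stat <- function(idx) {
    statfun(sim[idx, idx][up])
  }
  observed <- set_stat(seq_len(k))
  pool_idx <- k + seq_along(pool)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    set_stat(sample(pool_idx, k))
  }, numeric(1))
  p <- (1 + sum(null_stats >= observed)) / (n_perm + 1)

  structure(list(observed_statistic = observed,
                 null_statistics = null_stats,
                 p_value = p,
                 statistic_name = statistic,
                 n_permutations = as.integer(n_perm),
                 seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Fingerprint similarity permutation test\n")
  cat(sprintf("  observed %s similarity: %.4f\n",
              x$statistic_name, x$observed_statistic))
  cat(sprintf("  null %s over %d permutations: median %.4f\n",
              x$statistic_name, x$n_permutations,
              stats::median(x$null_statistics)))
  cat(sprintf("  p-value (add-one): %.4g\n", x$p_value))
  invisible(x)
}

#' Variance-ratio (F) comparison of positive vs negative similarities
#'
#' Compares the variance of pairwise similarities among the positive class
#' with that of an equally sized random negative set, via [stats::var.test()].
#' Offered alongside [permutation_test()] because either construction is a
#' defensible reading of "are the positives more alike than chance".
#'
#' @inheritParams permutation_test
#' @param seed optional integer seed for sampling the negative set.
#' @return The `htest` object from [stats::var.test()].
#' @export
similarity_var_test <- function(fps, positives, universe, seed = NULL) {
  positives <- unique(as.character(positives))
  pool <- setdiff(unique(as.character(universe)), positives)
  if (length(pool) < length(positives))
    stop("negative pool smaller than the positive set")
  if (!is.null(seed)) set.seed(seed)
  negatives <- sample(pool, length(positives))
  pos_sims <- pairwise_similarities(fps, positives)$jaccard
  neg_sims <- pairwise_similarities(fps, negatives)$jaccard
  stats::var.test(pos_sims, neg_sims)
}
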