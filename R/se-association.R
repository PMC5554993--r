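# Side-effect co-occurrence screening against an index adverse event:
# 2x2 confusion matrices, Fisher's exact test, the seven screening metrics,
# BH correction, the compound significance criterion, SOC roll-up and
# network export.

#' Construct a binary drug-by-side-effect incidence matrix
#'
#' The screening substrate: rows are drugs, columns are MedDRA preferred
#' terms (PTs), entries are 1 where the drug label carries the term.
#' Stored sparsely.
#'
#' @param pairs data.frame with columns `drug_id`, `pt_id`; one row per
#'   incident (drug, side effect) pair. Duplicates are collapsed.
#' @param drug_ids,pt_ids optional full axes. Defaults to the ids present in
#'   `pairs`; pass explicitly to retain drugs or PTs with no incident pairs.
#' @return Object of class `se_matrix` with elements `drug_ids`, `pt_ids`,
#'   `incidence` (sparse 0/1 Matrix, drugs x PTs).
#' @export
se_matrix <- function(pairs, drug_ids = NULL, pt_ids = NULL) {
  if (!all(c("drug_id", "pt_id") %in% names(pairs)))
    stop("`pairs` needs columns drug_id and pt_id")
  pairs$drug_id <- as.character(pairs$drug_id)
  pairs$pt_id <- as.character(pairs$pt_id)
  drug_ids <- if (is.null(drug_ids)) sort(unique(pairs$drug_id)) else as.character(drug_ids)
  pt_ids <- if (is.null(pt_ids)) sort(unique(pairs$pt_id)) else as.character(pt_ids)
  if (anyDuplicated(drug_ids)) stop("duplicated drug ids")
  if (anyDuplicated(pt_ids)) stop("duplicated PT ids")
  bad_d <- setdiff(pairs$drug_id, drug_ids)
  if (length(bad_d)) stop("pair references unknown drug id(s): ",
                          paste(utils::head(bad_d, 5), collapse = ", "))
  bad_p <- setdiff(pairs$pt_id, pt_ids)
  if (length(bad_p)) stop("pair references unknown PT id(s): ",
                          paste(utils::head(bad_p, 5), collapse = ", "))
  inc <- Matrix::sparseMatrix(
    i = match(pairs$drug_id, drug_ids),
    j = match(pairs$pt_id, pt_ids),
    x = 1,
    dims = c(length(drug_ids), length(pt_ids)),
    dimnames = list(drug_ids, pt_ids),
    use.last.ij = TRUE
  )
  inc@x[] <- 1  # collapse duplicate pairs to binary
  structure(list(drug_ids = drug_ids, pt_ids = pt_ids, incidence = inc),
            class = "se_matrix")
}

#' @export
print.se_matrix <- function(x, ...) {
  cat("Drug x side-effect matrix:", length(x$drug_ids), "drugs x",
      length(x$pt_ids), "PTs;", sum(x$incidence), "incident pairs\n")
  invisible(x)
}

#' Drugs carrying a given side effect
#'
#' @param matrix an [se_matrix()].
#' @param pt_id a PT identifier.
#' @return Character vector of drug ids.
#' @export
drugs_with_pt <- function(matrix, pt_id) {
  if (!pt_id %in% matrix$pt_ids) stop("unknown PT id: ", pt_id)
  matrix$drug_ids[matrix$incidence[, pt_id] > 0]
}

#' Cross-tabulate an index side effect against a candidate side effect
#'
#' Standard 2x2 orientation with the index event (myopathy) as the
#' condition and the candidate event as the test:
#' `tp` = drugs with both, `fp` = candidate only, `fn` = index only,
#' `tn` = neither.
#'
#' @param matrix an [se_matrix()].
#' @param index_pt,other_pt distinct PT ids present in the matrix.
#' @return Object of class `confusion_matrix`: counts `tp`, `fp`, `fn`, `tn`.
#' @export
build_confusion <- function(matrix, index_pt, other_pt) {
  if (identical(index_pt, other_pt)) stop("index_pt and other_pt must differ")
  for (pt in c(index_pt, other_pt))
    if (!pt %in% matrix$pt_ids) stop("unknown PT id: ", pt)
  x <- matrix$incidence[, index_pt] > 0
  y <- matrix$incidence[, other_pt] > 0
  confusion_matrix(tp = sum(x & y), fp = sum(!x & y),
                   fn = sum(x & !y), tn = sum(!x & !y))
}

#' @rdname build_confusion
#' @param tp,fp,fn,tn non-negative counts.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(index = c("yes", "no"),
                              candidate = c("yes", "no")))
  print(m)
  invisible(x)
}

#' Two-sided Fisher's exact test on a confusion matrix
#'
#' Two-sided p summing, over all 2x2 tables with the observed margins,
#' the hypergeometric probabilities of tables no more probable than the
#' observed one. Delegates to [stats::fisher.test()]. Degenerate margins
#' (a zero row or column) give p = 1.
#'
#' @param cm a [confusion_matrix()].
#' @return Two-sided p-value.
#' @export
fisher_two_sided <- function(cm) {
  tab <- matrix(c(cm$tp, cm$fn, cm$fp, cm$tn), nrow = 2, byrow = TRUE)
  # fisher.test can exceed 1 by a rounding hair; clamp to the probability scale
  min(1, stats::fisher.test(tab, alternative = "two.sided")$p.value)
}

#' The seven screening metrics of a confusion matrix
#'
#' Accuracy, sensitivity, specificity, MCC, AUC (defined here as
#' `(sensitivity + specificity) / 2`), PPV and NPV. Undefined ratios (0/0)
#' are returned as `NA`; an MCC with a zero denominator is defined as 0.
#'
#' @param cm a [confusion_matrix()].
#' @return Named numeric vector with elements `accuracy`, `sensitivity`,
#'   `specificity`, `mcc`, `auc`, `ppv`, `npv`.
#' @export
confusion_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  n <- tp + fp + fn + tn
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- ratio(tp + tn, n)
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  auc <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  c(accuracy = acc, sensitivity = sens, specificity = spec,
    mcc = mcc, auc = auc,
    ppv = ratio(tp, tp + fp), npv = ratio(tn, fn + tn))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values (monotone, capped at 1, in input order),
#' with input validation. Thin wrapper over [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    stop("p-values must be numeric in [0, 1] with no missing values")
  stats::p.adjust(p_values, method = "BH")
}

#' Empirical quantile threshold under the nearest-rank convention
#'
#' Returns the smallest value whose empirical CDF reaches `1 - alpha`,
#' i.e. the upper bound of the top `alpha` tail. Used to calibrate metric
#' thresholds (MCC, sensitivity) from the empirical distribution over all
#' candidate associations.
#'
#' @param values non-empty numeric vector.
#' @param alpha upper-tail mass (default 0.05).
#' @return A single threshold value, always an element of `values`.
#' @export
derive_threshold <- function(values, alpha = 0.05) {
  if (length(values) == 0) stop("`values` must be non-empty")
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]")
  s <- sort(values)
  s[max(1L, ceiling(length(s) * (1 - alpha)))]
}

#' Compound significance criteria for the side-effect screen
#'
#' The screen flags a candidate side effect only if all four conditions
#' hold: BH-adjusted p below `alpha`, MCC at least `mcc_min`, sensitivity at
#' least `sens_min`, and strictly more than `tp_min` true-positive drugs.
#'
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param mcc_min minimum MCC (default 0.2).
#' @param sens_min minimum sensitivity (default 0.70).
#' @param tp_min true-positive floor, strict inequality (default 2, i.e.
#'   at least 3 co-labelled drugs).
#' @return Object of class `significance_criteria`.
#' @export
significance_criteria <- function(alpha = 0.05, mcc_min = 0.2,
                                  sens_min = 0.70, tp_min = 2) {
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]")
  if (mcc_min < -1 || mcc_min > 1) stop("`mcc_min` must be in [-1, 1]")
  if (sens_min < 0 || sens_min > 1) stop("`sens_min` must be in [0, 1]")
  if (tp_min < 0) stop("`tp_min` must be non-negative")
  structure(list(alpha = alpha, mcc_min = mcc_min,
                 sens_min = sens_min, tp_min = tp_min,
                 combine = "conjunction"),
            class = "significance_criteria")
}

#' Screen all side effects for association with an index side effect
#'
#' For every PT other than the index PT, cross-tabulates the drug sets,
#' computes the two-sided Fisher p, BH-adjusts across all candidates in one
#' family, derives the seven metrics, and applies the compound criterion.
#' Candidates whose sensitivity or MCC is undefined (empty column) can never
#' be flagged.
#'
#' @param matrix an [se_matrix()].
#' @param index_pt the index PT id (e.g. `"myopathy"`).
#' @param criteria a [significance_criteria()].
#' @return data.frame of class `se_screen`, one row per candidate PT:
#'   `pt_id`, counts, the seven metrics, `p_raw`, `p_adjusted`,
#'   `significant`. Row order follows the matrix PT axis.
#' @export
screen_side_effects <- function(matrix, index_pt,
                                criteria = significance_criteria()) {
  if (!index_pt %in% matrix$pt_ids) stop("unknown PT id: ", index_pt)
  if (!inherits(criteria, "significance_criteria"))
    stop("`criteria` must be a significance_criteria object")
  M <- matrix$incidence
  x <- as.numeric(M[, index_pt] > 0)
  n <- length(x)
  tp <- as.numeric(Matrix::crossprod(M, x))
  col_tot <- Matrix::colSums(M)
  fp <- col_tot - tp
  fn <- sum(x) - tp
  tn <- n - tp - fp - fn
  keep <- matrix$pt_ids != index_pt
  pt <- matrix$pt_ids[keep]
  tp <- tp[keep]; fp <- fp[keep]; fn <- fn[keep]; tn <- tn[keep]

  p_raw <- vapply(seq_along(pt), function(i)
    fisher_two_sided(confusion_matrix(tp[i], fp[i], fn[i], tn[i])),
    numeric(1))
  p_adj <- bh_adjust(p_raw)

  ratio <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  acc <- ratio(tp + tn, n)
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- ifelse(mcc_den == 0, 0, (tp * tn - fp * fn) / mcc_den)
  auc <- (sens + spec) / 2
  ppv <- ratio(tp, tp + fp)
  npv <- ratio(tn, fn + tn)

  significant <- p_adj < criteria$alpha &
    !is.na(mcc) & mcc >= criteria$mcc_min &
    !is.na(sens) & sens >= criteria$sens_min &
    tp > criteria$tp_min

  out <- data.frame(pt_id = pt, tp = tp, fp = fp, fn = fn, tn = tn,
                    accuracy = acc, sensitivity = sens, specificity = spec,
                    mcc = mcc, auc = auc, ppv = ppv, npv = npv,
                    p_raw = p_raw, p_adjusted = p_adj,
                    significant = significant)
  attr(out, "index_pt") <- index_pt
  attr(out, "criteria") <- criteria
  class(out) <- c("se_screen", "data.frame")
  out
}

#' Significant subset of a screen
#'
#' @param screen an `se_screen` from [screen_side_effects()].
#' @return The rows flagged significant, sorted by adjusted p ascending.
#' @export
significant_associations <- function(screen) {
  out <- screen[screen$significant, , drop = FALSE]
  out[order(out$p_adjusted, out$p_raw, out$pt_id), , drop = FALSE]
}

#' Roll significant side effects up to System Organ Class
#'
#' Counts flagged PTs per SOC. PTs missing from the mapping are counted
#' under `"UNMAPPED"` and reported with a warning, never dropped silently.
#'
#' @param results data.frame with a `pt_id` column (typically
#'   [significant_associations()] output).
#' @param pt_to_soc data.frame with columns `pt_id`, `soc`.
#' @return data.frame `soc`, `n_pts`, sorted by count descending then SOC id.
#' @export
soc_rollup <- function(results, pt_to_soc) {
  if (nrow(results) == 0)
    return(data.frame(soc = character(), n_pts = integer()))
  soc <- pt_to_soc$soc[match(results$pt_id, pt_to_soc$pt_id)]
  unmapped <- results$pt_id[is.na(soc)]
  if (length(unmapped))
    warning("PT(s) missing from SOC mapping, counted as UNMAPPED: ",
            paste(unmapped, collapse = ", "))
  soc[is.na(soc)] <- "UNMAPPED"
  tab <- table(soc)
  out <- data.frame(soc = names(tab), n_pts = as.integer(tab))
  out <- out[order(-out$n_pts, out$soc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export the index-centred association network
#'
#' Writes the star network of significant side effects around the index PT:
#' a SIF edge file (`index assoc candidate`) and an edge-attribute TSV with
#' the adjusted p and MCC of each association.
#'
#' @param index_pt the index PT id.
#' @param results significant-association data.frame (needs `pt_id`,
#'   `p_adjusted`, `mcc`).
#' @param path_prefix output path prefix; writes `<prefix>.sif` and
#'   `<prefix>_attributes.tsv`.
#' @return Invisibly, the paths written.
#' @export
export_network <- function(index_pt, results, path_prefix) {
  sif_path <- paste0(path_prefix, ".sif")
  attr_path <- paste0(path_prefix, "_attributes.tsv")
  sif <- data.frame(source = rep(index_pt, nrow(results)),
                    interaction = rep("assoc", nrow(results)),
                    target = results$pt_id)
  utils::write.table(sif, sif_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  attrs <- data.frame(pt_id = results$pt_id,
                      p_adjusted = results$p_adjusted,
                      mcc = results$mcc)
  write_tsv(attrs, attr_path)
  invisible(c(sif = sif_path, attributes = attr_path))
}
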