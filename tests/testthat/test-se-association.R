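test_that("build_confusion counts the four drug classes directly", {
  # four drugs, one in each cell
  pairs <- data.frame(drug_id = c("d1", "d1", "d2", "d3"),
                      pt_id = c("myopathy", "other", "myopathy", "other"))
  m <- se_matrix(pairs, drug_ids = paste0("d", 1:4),
                 pt_ids = c("myopathy", "other"))
  cm <- build_confusion(m, "myopathy", "other")
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))

  # candidate occurring in no drug
  m2 <- se_matrix(data.frame(drug_id = "d1", pt_id = "myopathy"),
                  drug_ids = paste0("d", 1:3), pt_ids = c("myopathy", "empty"))
  cm2 <- build_confusion(m2, "myopathy", "empty")
  expect_equal(cm2$tp, 0L); expect_equal(cm2$fp, 0L)
  expect_equal(cm2$fn, 1L); expect_equal(cm2$tn, 2L)

  # all drugs saturated with both PTs
  pairs3 <- expand.grid(drug_id = paste0("d", 1:5),
                        pt_id = c("myopathy", "x"), stringsAsFactors = FALSE)
  cm3 <- build_confusion(se_matrix(pairs3), "myopathy", "x")
  expect_equal(unlist(cm3[c("tp", "fp", "fn", "tn")]),
               c(tp = 5L, fp = 0L, fn = 0L, tn = 0L))

  expect_error(build_confusion(m, "myopathy", "nope"), "nope")
  expect_error(build_confusion(m, "myopathy", "myopathy"), "differ")
})

test_that("two-sided Fisher p matches hand enumeration on the 4,4;4,4 margins", {
  # tables with margins (4,4; 4,4): point probs 1,16,36,16,1 over 70;
  # observed tp = 3 -> sum of the four tables at most as probable = 34/70
  expect_equal(fisher_two_sided(confusion_matrix(3, 1, 1, 3)), 34 / 70,
               tolerance = 1e-12)
  # degenerate margins
  expect_equal(fisher_two_sided(confusion_matrix(0, 0, 0, 5)), 1)
  expect_equal(fisher_two_sided(confusion_matrix(0, 0, 3, 3)), 1)
  expect_equal(fisher_two_sided(confusion_matrix(2, 2, 0, 0)), 1)
})

test_that("Fisher p equals the exhaustive oracle on every table with n <= 12", {
  for (n in 0:12) {
    for (tp in 0:n) for (fp in 0:(n - tp)) for (fn in 0:(n - tp - fp)) {
      tn <- n - tp - fp - fn
      expect_equal(fisher_two_sided(confusion_matrix(tp, fp, fn, tn)),
                   fisher_oracle(tp, fp, fn, tn),
                   tolerance = 1e-9,
                   label = sprintf("table (%d,%d,%d,%d)", tp, fp, fn, tn))
    }
  }
})

test_that("the seven metrics match their formulas", {
  m0 <- confusion_metrics(confusion_matrix(5, 5, 5, 5))
  expect_equal(m0[["mcc"]], 0)
  expect_equal(m0[["auc"]], 0.5)
  m1 <- confusion_metrics(confusion_matrix(10, 0, 0, 10))
  expect_equal(unname(m1[c("accuracy", "sensitivity", "specificity",
                           "auc", "ppv", "npv")]), rep(1, 6))
  expect_equal(m1[["mcc"]], 1)
  m2 <- confusion_metrics(confusion_matrix(5, 2, 3, 90))
  expect_equal(m2[["mcc"]], 444 / sqrt(7 * 8 * 92 * 93), tolerance = 1e-12)
  # undefined ratios flagged, zero-denominator MCC is 0
  m3 <- confusion_metrics(confusion_matrix(0, 0, 3, 7))
  expect_true(is.na(m3[["ppv"]]))
  expect_equal(m3[["mcc"]], 0)
})

test_that("metrics equal an independent recomputation on random tables", {
  set.seed(21)
  for (i in 1:1000) {
    counts <- stats::rpois(4, sample(c(0.5, 3, 20), 1))
    cm <- confusion_matrix(counts[1], counts[2], counts[3], counts[4])
    m <- confusion_metrics(cm)
    tp <- counts[1]; fp <- counts[2]; fn <- counts[3]; tn <- counts[4]
    safe <- function(num, den) if (den == 0) NA_real_ else num / den
    expect_identical(m[["accuracy"]], safe(tp + tn, sum(counts)))
    expect_identical(m[["sensitivity"]], safe(tp, tp + fn))
    expect_identical(m[["specificity"]], safe(tn, tn + fp))
    expect_identical(m[["ppv"]], safe(tp, tp + fp))
    expect_identical(m[["npv"]], safe(tn, fn + tn))
    if (!is.na(m[["mcc"]])) {
      expect_gte(m[["mcc"]], -1); expect_lte(m[["mcc"]], 1)
    }
    if (!is.na(m[["auc"]]))
      expect_equal(m[["auc"]], (m[["sensitivity"]] + m[["specificity"]]) / 2)
  }
})

test_that("BH adjustment reproduces the hand step-up and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  # hand step-up on an unsorted vector: p * m / rank with tail minima
  p <- c(0.04, 0.001, 0.8, 0.01)
  expect_equal(bh_adjust(p), c(0.0533333333333333, 0.004, 0.8, 0.02),
               tolerance = 1e-12)
  # monotone on sorted input, never below raw
  set.seed(22)
  ps <- sort(runif(50))
  adj <- bh_adjust(ps)
  expect_true(all(diff(adj) >= -1e-15))
  expect_true(all(adj >= ps - 1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)))
})

test_that("nearest-rank quantile thresholds", {
  expect_equal(derive_threshold(1:100, alpha = 0.05), 95)
  expect_equal(derive_threshold(rep(7, 20)), 7)
  expect_equal(derive_threshold(c(3, 1, 2), alpha = 1), 1)
  expect_error(derive_threshold(numeric()), "non-empty")
})

test_that("screen flags require the full conjunction of criteria", {
  set.seed(23)
  co <- generate_cohort(fast_config(seed = 5))
  scr <- screen_side_effects(co$se_matrix, "myopathy")
  # an unsatisfiable TP floor empties the significant set regardless of p
  scr_hi <- screen_side_effects(co$se_matrix, "myopathy",
                                significance_criteria(tp_min = 10000))
  expect_equal(sum(scr_hi$significant), 0)
  expect_equal(scr_hi$p_adjusted, scr$p_adjusted)
  # flags honour each component
  sig <- scr[scr$significant, ]
  if (nrow(sig)) {
    expect_true(all(sig$p_adjusted < 0.05))
    expect_true(all(sig$mcc >= 0.2))
    expect_true(all(sig$sensitivity >= 0.70))
    expect_true(all(sig$tp > 2))
  }
  expect_true(all(scr$p_adjusted >= scr$p_raw))
})

test_that("screen p-values are invariant to drug-row permutation", {
  set.seed(24)
  co <- generate_cohort(fast_config(seed = 6))
  m <- co$se_matrix
  scr1 <- screen_side_effects(m, "myopathy")
  perm <- sample(length(m$drug_ids))
  m2 <- list(drug_ids = m$drug_ids[perm],
             pt_ids = m$pt_ids,
             incidence = m$incidence[perm, ])
  class(m2) <- "se_matrix"
  scr2 <- screen_side_effects(m2, "myopathy")
  expect_equal(scr2$p_raw, scr1$p_raw)
  expect_equal(scr2$p_adjusted, scr1$p_adjusted)
  expect_equal(scr2$significant, scr1$significant)
})

test_that("SOC rollup counts, sorts and reports unmapped PTs", {
  res <- data.frame(pt_id = c("p1", "p2", "p3", "p4"))
  mapping <- data.frame(pt_id = c("p1", "p2", "p3"),
                        soc = c("A", "A", "B"))
  expect_warning(out <- soc_rollup(res, mapping), "p4")
  expect_equal(out$soc, c("A", "B", "UNMAPPED"))
  expect_equal(out$n_pts, c(2L, 1L, 1L))
  # deterministic tie order and empty input
  res2 <- data.frame(pt_id = c("p1", "p3"))
  out2 <- soc_rollup(res2, mapping)
  expect_equal(out2$soc, c("A", "B"))
  expect_equal(nrow(soc_rollup(res[0, , drop = FALSE], mapping)), 0)
})

test_that("association network export round-trips the edge set", {
  res <- data.frame(pt_id = c("SE1", "SE2", "SE3"),
                    p_adjusted = c(1e-4, 2e-3, 0.01),
                    mcc = c(0.5, 0.4, 0.3))
  prefix <- file.path(withr::local_tempdir(), "net")
  paths <- export_network("myopathy", res, prefix)
  sif <- read.delim(paths[["sif"]], header = FALSE)
  expect_equal(nrow(sif), 3)
  expect_true(all(sif$V1 == "myopathy"))
  expect_setequal(sif$V3, res$pt_id)
  attrs <- read.delim(paths[["attributes"]])
  expect_equal(attrs$pt_id, res$pt_id)
  expect_equal(attrs$mcc, res$mcc)
  # empty set gives an empty SIF and header-only attributes
  paths0 <- export_network("myopathy", res[0, , drop = FALSE],
                           file.path(withr::local_tempdir(), "empty"))
  expect_equal(length(readLines(paths0[["sif"]])), 0)
  expect_equal(nrow(read.delim(paths0[["attributes"]])), 0)
})

test_that("se_matrix validates ids and collapses duplicate pairs", {
  expect_error(se_matrix(data.frame(drug_id = "d9", pt_id = "p"),
                         drug_ids = "d1", pt_ids = "p"), "d9")
  m <- se_matrix(data.frame(drug_id = c("d1", "d1"), pt_id = c("p", "p")))
  expect_equal(as.numeric(m$incidence["d1", "p"]), 1)
  expect_equal(drugs_with_pt(toy_se_matrix(), "SE2"), c("d1", "d5"))
})
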