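rank_cols <- function(...) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  m
}

# turn ordered gene vectors into a rank matrix (best first)
ranks_from_order <- function(orders) {
  genes <- sort(orders[[1]])
  m <- vapply(orders, function(o) match(genes, o), integer(length(genes)))
  rownames(m) <- genes
  m
}

test_that("borda merge of a single list is the identity", {
  ord <- c("C", "A", "B", "D")
  prl <- borda_merge(ranks_from_order(list(ord)))
  expect_equal(prl$ranking, ord)
  # two identical lists preserve the order
  prl2 <- borda_merge(ranks_from_order(list(ord, ord)))
  expect_equal(prl2$ranking, ord)
})

test_that("a list and its reversal tie completely and resolve by gene id", {
  # every gene scores (G - r) + (G - (G + 1 - r)) = G - 1
  prl <- borda_merge(ranks_from_order(list(c("A", "B", "C"), c("C", "B", "A"))))
  expect_equal(length(unique(prl$borda_scores)), 1)
  expect_equal(unname(prl$borda_scores[1]), 2)  # G - 1 with G = 3
  expect_equal(prl$ranking, c("A", "B", "C"))
})

test_that("borda merge is invariant to list order and to duplicated lists", {
  set.seed(41)
  genes <- sprintf("G%02d", 1:30)
  orders <- replicate(3, sample(genes), simplify = FALSE)
  m <- ranks_from_order(orders)
  expect_equal(borda_merge(m)$ranking,
               borda_merge(m[, c(3, 1, 2)])$ranking)
  # duplicating a list rescales scores but preserves a tie-free order
  base <- borda_merge(m)
  dup <- borda_merge(m[, c(1, 2, 3, 3)])
  if (length(unique(base$borda_scores)) == length(genes))
    expect_equal(dup$ranking[1], base$ranking[1])
  # unanimity: a gene ranked 1 in both lists is ranked 1 in the PRL
  o1 <- sample(genes); o2 <- c(o1[1], sample(o1[-1]))
  expect_equal(borda_merge(ranks_from_order(list(o1, o2)))$ranking[1], o1[1])
})

test_that("borda merge rejects mismatched universes and non-permutations", {
  r1 <- stats::setNames(1:3, c("A", "B", "C"))
  r2 <- stats::setNames(1:3, c("A", "B", "D"))
  expect_error(borda_merge(list(r1, r2)), "C.*D|D.*C")
  bad <- matrix(c(1L, 1L, 2L), ncol = 1,
                dimnames = list(c("A", "B", "C"), NULL))
  expect_error(borda_merge(bad), "permutation")
})

test_that("signatures take the PRL head and tail with no silent clamping", {
  set.seed(42)
  genes <- sprintf("G%03d", 1:300)
  prl <- borda_merge(ranks_from_order(list(sample(genes))))
  sig <- extract_signature(prl)  # defaults 100/100
  expect_length(sig$up, 100); expect_length(sig$down, 100)
  expect_length(intersect(sig$up, sig$down), 0)
  expect_equal(sig$up, prl$ranking[1:100])
  # most down-regulated first
  expect_equal(sig$down[1], prl$ranking[300])
  # boundary: whole ranking up
  all_up <- extract_signature(prl, n_up = 300, n_down = 0)
  expect_equal(all_up$up, prl$ranking)
  expect_error(extract_signature(prl, 200, 101), "exceeds")
})

test_that("representative genes rank by cross-drug frequency with declared ties", {
  set.seed(43)
  genes <- sprintf("G%02d", 1:40)
  # drug signatures engineered so G01 appears in all, the rest in one each
  sigs <- lapply(1:5, function(i) {
    ord <- c("G01", genes[1 + ((i * 3 + 1:2 - 1) %% 39) + 0], sample(setdiff(genes, c("G01"))))
    ord <- unique(ord)
    prl <- borda_merge(ranks_from_order(list(ord)))
    extract_signature(prl, n_up = 3, n_down = 2)
  })
  rep_genes <- representative_genes(sigs, top_n = 10)
  expect_equal(rep_genes$gene_id[1], "G01")
  expect_equal(rep_genes$frequency[1], 5L)
  # all-equal frequencies resolve deterministically
  sig_same <- sigs[c(1, 1)]
  r1 <- representative_genes(sig_same, top_n = 5)
  r2 <- representative_genes(sig_same, top_n = 5)
  expect_identical(r1, r2)
  expect_equal(r1$frequency, rep(2L, 5))
})

test_that("frequency counts the up/down union once per drug", {
  sig <- structure(list(drug_id = "d", up = c("A", "B"), down = c("B", "C"),
                        up_ranks = 1:2, down_ranks = c(10L, 9L), n_genes = 10L),
                   class = "signature_set")
  out <- representative_genes(list(sig), top_n = 10)
  expect_equal(sort(out$gene_id), c("A", "B", "C"))
  expect_true(all(out$frequency == 1L))
})

test_that("enrichment matches the hypergeometric tail and flags planted sets", {
  set.seed(44)
  universe <- sprintf("G%04d", 1:1000)
  sets <- c(list(hit = universe[1:10]),
            lapply(1:49, function(i) sample(universe, 10)))
  names(sets) <- c("hit", sprintf("S%02d", 1:49))
  res <- enrich_gene_sets(universe[1:10], sets, universe)
  expect_equal(res$set_id[1], "hit")
  expect_equal(res$n_hits[1], 10L)
  expect_lt(res$p_adjusted[1], 0.05)
  # oracle value: P(X >= 10), X ~ Hypergeom(10, 990, 10) = 1 / C(1000, 10)
  expect_equal(res$p_raw[1], 1 / choose(1000, 10), tolerance = 1e-9)

  # disjoint list: nothing significant
  res2 <- enrich_gene_sets(universe[900:950],
                           list(s = universe[1:10]), universe)
  expect_false(any(res2$significant))
  # universe restricted to the list itself saturates every p at 1
  res3 <- enrich_gene_sets(universe[1:20],
                           list(s1 = universe[1:5], s2 = universe[15:30]),
                           universe = universe[1:20])
  expect_true(all(res3$p_raw == 1))
})

test_that("enrichment p equals exhaustive enumeration for small universes", {
  set.seed(45)
  for (rep in 1:20) {
    N <- sample(10:60, 1)
    universe <- sprintf("g%02d", 1:N)
    s <- sample(universe, sample(2:min(15, N), 1))
    gl <- sample(universe, sample(2:min(15, N), 1))
    res <- enrich_gene_sets(gl, list(s = s), universe)
    # direct enumeration of the tail from binomial coefficients
    m <- length(s); k <- length(gl); obs <- length(intersect(s, gl))
    tail_p <- sum(vapply(obs:min(m, k), function(x)
      choose(m, x) * choose(N - m, k - x), numeric(1))) / choose(N, k)
    expect_equal(res$p_raw, tail_p, tolerance = 1e-9)
  }
})

test_that("enrichment validates the universe", {
  expect_error(enrich_gene_sets("A", list(s = "A"), character()), "non-empty")
  expect_error(enrich_gene_sets(c("A", "Z"), list(s = "A"), c("A", "B")), "Z")
})

test_that("GMT files round-trip", {
  sets <- list(GS1 = c("A", "B", "C"), GS2 = c("B", "D"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back$GS1, sets$GS1)
  expect_equal(back$GS2, sets$GS2)
})

test_that("rank matrices round-trip with drug:cell column names", {
  set.seed(46)
  m <- ranks_from_order(list(sample(LETTERS[1:10]), sample(LETTERS[1:10])))
  colnames(m) <- c("D0001:CL1", "D0001:CL2")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rank_matrix(m, path)
  expect_identical(read_rank_matrix(path), m)
})
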