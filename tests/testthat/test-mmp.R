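toy_mmp <- function(values, donors = NULL) {
  m <- matrix(values, ncol = 6,
              dimnames = list(donors %||% paste0("D", seq_len(length(values) / 6)),
                              c("inulin:acetate", "inulin:propionate",
                                "inulin:butyrate", "pectin:acetate",
                                "pectin:propionate", "pectin:butyrate")))
  attr(m, "scale") <- "raw"
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("z-scoring standardizes columns exactly and inverts cleanly", {
  m <- toy_mmp(c(1, 3, rep(c(0, 2), 5)))
  z <- zscore_columns(m)
  expect_equal(unname(z[, 1L]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 2L, sd) - 1)), 1e-12)
  back <- unzscore_columns(z)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(zscore_columns(m[1L, , drop = FALSE]), "at least 2 donors")

  const <- toy_mmp(c(rep(1, 4), rep(c(0, 1), 10)))
  zc <- zscore_columns(const)
  expect_equal(attr(zc, "constant_cols"), "inulin:acetate")
  expect_equal(unname(zc[, 1L]), rep(0, 4))
})

test_that("the high/low boundary lies at z = 0 and is inclusive", {
  m <- toy_mmp(seq_len(24))
  z <- zscore_columns(m)
  z[1L, 1L] <- 0; z[2L, 1L] <- -0.01
  b <- binarize_high_low(z)
  expect_true(b[1L, 1L])    # boundary counts as high
  expect_false(b[2L, 1L])
  expect_error(binarize_high_low(m), "z-scored")
  # a z-scored pair always splits one high, one low
  pair <- zscore_columns(toy_mmp(c(1, 3, rep(c(5, 7), 5))))
  expect_equal(colSums(binarize_high_low(pair)), rep(1, 6),
               ignore_attr = TRUE)
})

test_that("UPGMA merges duplicates at height zero and averages distances", {
  ex <- generate_worked_examples()$mmp_two_block
  cl <- upgma_cluster(ex, k = 2, distance = "euclidean")
  expect_equal(sort(cl$hclust$height)[1:2], c(0, 0))
  expect_equal(unname(cl$labels), c(1, 1, 2, 2))
  # correlation distance agrees on the duplicate-pair structure
  expect_equal(unname(upgma_cluster(ex, k = 2)$labels), c(1, 1, 2, 2))

  # hand-executed UPGMA on d(AB)=2, d(AC)=d(BC)=4: AB at height 2, then C
  # joins at the average distance 4
  pts <- matrix(c(-1, 0, 1, 0, 0, sqrt(15)), ncol = 2, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), NULL))
  hc <- upgma_cluster(pts, k = 2, distance = "euclidean")$hclust
  expect_equal(hc$height, c(2, 4), tolerance = 1e-12)

  expect_error(upgma_cluster(toy_mmp(c(NA, seq_len(11)))), "missing values")
  nwk <- upgma_newick(cl)
  expect_match(nwk, "^\\(.*\\);$")
})

test_that("UPGMA merge heights are monotone non-decreasing", {
  for (seed in 1:5) {
    z <- withr::with_seed(seed, matrix(rnorm(60), nrow = 10,
                                       dimnames = list(paste0("D", 1:10), NULL)))
    for (d in c("euclidean", "correlation")) {
      h <- upgma_cluster(z, k = 2, distance = d)$hclust$height
      expect_true(all(diff(h) >= -1e-12))
    }
  }
})

test_that("stability contingency counts class agreement over all cells", {
  coh <- generate_cohort(cohort_config(seed = 3, n_donors = 8,
                                       otu_spec = NULL))
  b1 <- binarized_from(coh$scfa_visit1)
  tab_same <- stability_contingency(b1, b1)
  expect_equal(sum(tab_same), 48L)
  expect_equal(tab_same[1L, 2L] + tab_same[2L, 1L], 0L)
  tab_inv <- stability_contingency(b1, !b1)
  expect_equal(tab_inv[1L, 1L] + tab_inv[2L, 2L], 0L)
  b_wrong <- b1; rownames(b_wrong)[1L] <- "someone_else"
  expect_error(stability_contingency(b1, b_wrong), "donor set mismatch")
  # row order must not matter
  perm <- b1[rev(rownames(b1)), ]
  expect_identical(stability_contingency(b1, perm), tab_same)
})

test_that("planted visit persistence shows up as the concordant fraction", {
  coh <- generate_cohort(cohort_config(seed = 21, n_donors = 200,
                                       otu_spec = NULL))
  tab <- stability_contingency(binarized_from(coh$scfa_visit1),
                               binarized_from(coh$scfa_visit2))
  observed <- (tab[1L, 1L] + tab[2L, 2L]) / sum(tab)
  # concordance of the true (noise-free) classes is the planted reference
  z1 <- zscore_columns(coh$truth$phi_visit1)
  z2 <- zscore_columns(coh$truth$phi_visit2)
  planted <- mean(binarize_high_low(z1) == binarize_high_low(z2))
  # estimation noise flips a few near-boundary cells per visit, so the
  # observed concordance sits slightly below the planted one
  expect_lt(abs(observed - planted), 0.1)
  expect_gt(observed, 0.8)
})

test_that("the exact Fisher test reproduces enumeration results", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 2, 2, 2), 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2)), 34 / 70,
               tolerance = 1e-12)
  tab <- matrix(c(9, 2, 3, 8), 2)
  expect_equal(fisher_exact_2x2(tab), fisher_bruteforce(tab),
               tolerance = 1e-12)
  # invariant under transpose and simultaneous row/column swap
  expect_equal(fisher_exact_2x2(t(tab)), fisher_exact_2x2(tab))
  expect_equal(fisher_exact_2x2(tab[2:1, 2:1]), fisher_exact_2x2(tab))
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "negative")
  expect_error(fisher_exact_2x2(matrix(c(0.5, 1, 1, 1), 2)), "non-integer")
  # agreement with the standard exact test implementation
  expect_equal(fisher_exact_2x2(tab),
               stats::fisher.test(tab)$p.value, tolerance = 1e-9)
})
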