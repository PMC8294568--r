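test_that("depth filtering keeps the 5000-read boundary sample", {
  counts <- matrix(c(4999L, 0L, 5000L, 0L, 6000L, 6000L), nrow = 3L,
                   byrow = TRUE, dimnames = list(c("s1", "s2", "s3"), NULL))
  ot <- otu_tab(counts)
  res <- filter_low_depth(ot)
  expect_equal(res$dropped, "s1")
  expect_equal(rownames(res$table$counts), c("s2", "s3"))
  expect_equal(filter_low_depth(ot, min_reads = 0)$dropped, character(0))
  expect_error(filter_low_depth(ot, min_reads = 1e7), "all samples")
})

test_that("planted shallow samples are dropped at about the planted rate", {
  spec <- default_otu_spec()
  spec$shallow_fraction <- 0.05
  coh <- generate_cohort(cohort_config(seed = 31, n_donors = 400,
                                       otu_spec = spec))
  res <- filter_low_depth(coh$otu)
  expect_equal(sort(res$dropped),
               sort(names(which(coh$truth$depth_class == "shallow"))))
  expect_lt(abs(length(res$dropped) / 400 - 0.05), 0.03)
})

test_that("rarefaction equalizes depths and is seed-deterministic", {
  ot <- generate_worked_examples()$otu_3x5
  r1 <- rarefy_table(ot, seed = 4L)
  expect_true(all(sample_depths(r1) == min(sample_depths(ot))))
  expect_identical(rarefy_table(ot, seed = 4L)$counts, r1$counts)
  # the sample already at the target depth is untouched
  shallowest <- which.min(sample_depths(ot))
  expect_identical(r1$counts[shallowest, ], ot$counts[shallowest, ])
  expect_error(rarefy_table(ot, depth = 100L), "exceeds sample depth")
})

test_that("rarefied counts match the hypergeometric expectation", {
  counts <- matrix(c(50L, 30L, 20L), 1L, dimnames = list("s", NULL))
  ot <- otu_tab(counts)
  draws <- vapply(1:1000, function(s) rarefy_table(ot, depth = 40L,
                                                   seed = s)$counts[1L, ],
                  integer(3))
  expected <- 40 * c(50, 30, 20) / 100
  se <- sqrt(apply(draws, 1L, var) / 1000)
  expect_true(all(abs(rowMeans(draws) - expected) < 2 * se + 1e-9))
})

test_that("relative abundance is row-stochastic and scale invariant", {
  ot <- otu_tab(matrix(c(2L, 3L, 5L), 1L, dimnames = list("s", NULL)))
  expect_equal(unname(relative_abundance(ot)[1L, ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(relative_abundance(
    otu_tab(matrix(c(20L, 30L, 50L), 1L)))[1L, ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(relative_abundance(
    otu_tab(matrix(7L, 1L)))[1L, ]), 1.0)
  expect_error(relative_abundance(otu_tab(matrix(c(0L, 0L), 1L))),
               "zero-depth")
  big <- generate_cohort(cohort_config(seed = 5, n_donors = 10))$otu
  expect_equal(unname(rowSums(relative_abundance(big))), rep(1, 10),
               tolerance = 1e-9)
})

test_that("taxonomic collapsing sums families and keeps unassigned apart", {
  ot <- generate_worked_examples()$otu_3x5
  rel <- relative_abundance(ot)
  fam <- collapse_taxonomy(rel, "family")
  lach <- grep("Lachnospiraceae", colnames(fam), value = TRUE)
  expect_length(lach, 1L)
  expect_equal(unname(fam[, lach]),
               unname(rowSums(rel[, c("OTU1", "OTU2", "OTU3")])))
  expect_equal(rowSums(fam), rowSums(rel), tolerance = 1e-12)

  gen <- collapse_taxonomy(rel, "genus")
  # the unassigned-genus Lachnospiraceae OTU stays distinct from assigned
  # genera of the same family
  expect_true(any(grepl("Lachnospiraceae;unassigned", colnames(gen))))
  expect_length(grep("Lachnospiraceae", colnames(gen)), 3L)
  expect_equal(rowSums(gen), rowSums(rel), tolerance = 1e-12)
  expect_error(collapse_taxonomy(rel, "tribe"), "unknown rank")
})

test_that("Shannon diversity follows the entropy definition", {
  expect_equal(shannon_diversity(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_diversity(1), 0)
  expect_equal(shannon_diversity(c(0.5, 0.5, 0, 0)),
               shannon_diversity(c(0.5, 0.5)))
  expect_error(shannon_diversity(c(-0.1, 1.1)), "negative")
  expect_error(shannon_diversity(c(0.2, 0.2)), "sum to 1")
})

test_that("Jensen-Shannon distance is a bounded metric", {
  p <- c(0.5, 0.5, 0); q <- c(0, 0, 1)
  expect_equal(jensen_shannon_distance(p, p), 0)
  expect_equal(jensen_shannon_distance(p, q), 1)
  expect_equal(jensen_shannon_distance(p, q), jensen_shannon_distance(q, p))
  expect_error(jensen_shannon_distance(c(0.5, 0.5), c(0.2, 0.3, 0.5)),
               "mismatched")
  # triangle inequality on random triples
  withr::with_seed(99, {
    for (i in 1:1000) {
      tri <- matrix(rexp(15), 3L)
      tri <- tri / rowSums(tri)
      d12 <- jensen_shannon_distance(tri[1L, ], tri[2L, ])
      d13 <- jensen_shannon_distance(tri[1L, ], tri[3L, ])
      d23 <- jensen_shannon_distance(tri[2L, ], tri[3L, ])
      expect_lte(d12, d13 + d23 + 1e-12)
    }
  })
})

test_that("a perfectly separating feature gives mean AUC 1", {
  x <- cbind(sep = c(rnorm(15, 10), rnorm(15, 0)),
             withr::with_seed(1, matrix(rnorm(150), 30L)))
  colnames(x) <- paste0("F", 1:6)
  rep <- train_high_low_classifier(x, rep(c(TRUE, FALSE), each = 15L),
                                   seed = 1L)
  expect_equal(rep$mean_auc, 1.0)
  expect_equal(names(sort(rep$importance, decreasing = TRUE))[1L], "F1")
  expect_equal(rep$mean_tpr[length(rep$mean_tpr)], 1.0)
})

test_that("label permutation yields chance-level AUC", {
  withr::with_seed(7, {
    x <- matrix(rlnorm(200 * 30), 200L)
    x <- x / rowSums(x)
    colnames(x) <- paste0("F", 1:30)
    y <- sample(rep(c(TRUE, FALSE), each = 100L))
  })
  rep <- train_high_low_classifier(x, y, seed = 1L)
  expect_gte(rep$mean_auc, 0.4)
  expect_lte(rep$mean_auc, 0.6)
})

test_that("classifier reports are reproducible and validated", {
  x <- withr::with_seed(2, matrix(runif(40 * 8), 40L))
  colnames(x) <- paste0("F", 1:8)
  y <- rep(c(TRUE, FALSE), 20L)
  r1 <- train_high_low_classifier(x, y, seed = 9L)
  r2 <- train_high_low_classifier(x, y, seed = 9L)
  expect_identical(r1, r2)
  expect_equal(sum(r1$importance), 1.0, tolerance = 1e-12)
  expect_true(all(r1$importance >= 0))
  expect_true(all(r1$auc_per_fold >= 0 & r1$auc_per_fold <= 1))
  expect_error(train_high_low_classifier(x, rep(TRUE, 40L)), "single class")
  expect_error(train_high_low_classifier(x, c(TRUE, rep(FALSE, 39L))),
               "two samples per class")
})

test_that("fold AUCs agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(5, {
    scores <- runif(40)
    labels <- rbinom(40, 1, plogis(3 * scores - 1.5)) == 1
  })
  rp <- mmpkit:::roc_points(scores, labels)
  ref <- pROC::auc(pROC::roc(response = labels, predictor = scores,
                             quiet = TRUE, direction = "<"))
  expect_equal(rp$auc, as.numeric(ref), tolerance = 1e-12)
})
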