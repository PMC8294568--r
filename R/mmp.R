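# The MMP proper: a donors x (fiber:SCFA) matrix of net production rates,
# z-scored across the cohort, clustered by UPGMA into phenotype types,
# binarized to high/low producers (z >= 0 is high), and compared between
# visits with an exact Fisher test.

#' Assemble an MMP rate matrix
#'
#' Casts net production rates into a donors x (fiber:SCFA) matrix. In the
#' study configuration the columns are inulin and pectin crossed with
#' acetate, propionate and butyrate (cellulose is indistinguishable from
#' control and excluded by default).
#'
#' @param net_rates Output of [net_production_rates()].
#' @param fibers Fibers to keep as columns (default inulin, pectin).
#' @param scfas SCFAs to keep (default all three).
#' @return Numeric matrix with donors as rows, columns named
#'   `"fiber:scfa"`, and attribute `scale = "raw"` (mM/h).
#' @export
mmp_matrix <- function(net_rates, fibers = c("inulin", "pectin"),
                       scfas = scfa_names()) {
  sub <- net_rates[net_rates$fiber %in% fibers & net_rates$scfa %in% scfas, ]
  donors <- sort(unique(sub$donor))
  cols <- as.vector(t(outer(fibers, scfas, paste, sep = ":")))
  m <- matrix(NA_real_, length(donors), length(cols),
              dimnames = list(donors, cols))
  m[cbind(match(sub$donor, donors),
          match(paste(sub$fiber, sub$scfa, sep = ":"), cols))] <-
    sub$rate_mM_per_h
  if (anyNA(m))
    stop("incomplete rate matrix: every donor needs every fiber:SCFA rate")
  attr(m, "scale") <- "raw"
  m
}

#' Z-score MMP columns across the cohort
#'
#' Standardizes each fiber:SCFA column to mean 0 and sample sd 1 (n-1
#' denominator) across donors. Constant columns (sd 0) are flagged in
#' attribute `"constant_cols"` and set to zero rather than dividing by zero.
#' The original center and sd are stored so [unzscore_columns()] can invert
#' the transform.
#'
#' @param m Raw-scale MMP matrix from [mmp_matrix()].
#' @return Z-scored matrix with attribute `scale = "z"`.
#' @export
zscore_columns <- function(m) {
  if (nrow(m) < 2L) stop("z-scoring needs at least 2 donors")
  ctr <- colMeans(m)
  sds <- apply(m, 2L, sd)
  const <- sds == 0
  sds2 <- ifelse(const, 1, sds)
  z <- sweep(sweep(m, 2L, ctr), 2L, sds2, "/")
  z[, const] <- 0
  attr(z, "scale") <- "z"
  attr(z, "center") <- ctr
  attr(z, "sd") <- sds
  attr(z, "constant_cols") <- colnames(m)[const]
  z
}

#' Invert column z-scoring
#' @param z Matrix produced by [zscore_columns()].
#' @return Raw-scale matrix.
#' @export
unzscore_columns <- function(z) {
  if (!identical(attr(z, "scale"), "z"))
    stop("expected a z-scored matrix")
  ctr <- attr(z, "center"); sds <- attr(z, "sd")
  m <- sweep(sweep(unclass(z), 2L, ifelse(sds == 0, 1, sds), "*"), 2L, ctr, "+")
  m <- m[, , drop = FALSE]
  attr(m, "scale") <- "raw"
  attr(m, "center") <- NULL; attr(m, "sd") <- NULL
  attr(m, "constant_cols") <- NULL
  m
}

#' Binarize a z-scored MMP to high/low producers
#'
#' A donor is a "high" producer for a fiber:SCFA pair when the production
#' rate z-score is greater than or equal to 0 (the boundary counts as high),
#' and "low" otherwise.
#'
#' @param z Z-scored MMP matrix.
#' @return Logical matrix (`TRUE` = high) with the same dimnames.
#' @export
binarize_high_low <- function(z) {
  if (!identical(attr(z, "scale"), "z"))
    stop("binarization expects a z-scored matrix (raw-scale input given?)")
  out <- unclass(z) >= 0
  attributes(out) <- list(dim = dim(z), dimnames = dimnames(z))
  out
}

#' UPGMA clustering of MMP phenotypes
#'
#' Average-linkage (UPGMA) agglomerative clustering of donor rows. The
#' default distance is `1 - Pearson correlation` between donor profiles:
#' phenotype types are profile *shapes* (which fiber:SCFA combinations a
#' donor is strong in), and correlation distance is insensitive to a
#' donor's overall fermentation magnitude, which otherwise dominates
#' Euclidean distances and makes low-`k` cuts isolate single
#' high-activity donors. Euclidean and other [stats::dist()] metrics are
#' available via `distance`. Cluster labels come from cutting the tree at
#' a requested cluster count `k` (default 2, mirroring a Type I / Type II
#' split) or height `h`.
#'
#' @param z MMP matrix (typically z-scored); no missing values allowed.
#' @param k Number of clusters to cut (ignored when `h` given).
#' @param h Optional cut height.
#' @param distance `"correlation"` (default) or a [stats::dist()] method
#'   such as `"euclidean"`.
#' @return List of class `"upgma_clustering"`: `hclust` (the tree),
#'   `labels` (named integer cluster labels), `k`, `distance`.
#' @export
upgma_cluster <- function(z, k = 2, h = NULL, distance = "correlation") {
  if (anyNA(z)) stop("missing values in MMP matrix")
  if (nrow(z) < 2L) stop("clustering needs at least 2 donors")
  d <- if (identical(distance, "correlation")) {
    if (any(apply(z, 1L, sd) == 0))
      stop("correlation distance undefined for a constant donor profile")
    as.dist(1 - cor(t(unclass(z))))
  } else {
    dist(unclass(z), method = distance)
  }
  hc <- hclust(d, method = "average")
  labels <- if (is.null(h)) cutree(hc, k = k) else cutree(hc, h = h)
  structure(list(hclust = hc, labels = labels,
                 k = length(unique(labels)), distance = distance),
            class = "upgma_clustering")
}

#' @export
print.upgma_clustering <- function(x, ...) {
  cat(sprintf("UPGMA clustering: %d donors, %d clusters (%s distance)\n",
              length(x$labels), x$k, x$distance))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Export a UPGMA tree as Newick text
#' @param x An `"upgma_clustering"`.
#' @return Single Newick string with merge heights as branch lengths.
#' @export
upgma_newick <- function(x) {
  stopifnot(inherits(x, "upgma_clustering"))
  ape::write.tree(ape::as.phylo(x$hclust))
}

#' Visit-to-visit stability contingency table
#'
#' Cross-tabulates high/low class at visit 1 against visit 2 over all
#' donor x fiber:SCFA cells. Rows index the visit-1 class, columns the
#' visit-2 class.
#'
#' @param visit1,visit2 Logical high/low matrices from
#'   [binarize_high_low()] with identical donors and columns.
#' @return 2x2 integer matrix with dimnames
#'   `list(visit1 = c("high","low"), visit2 = c("high","low"))`.
#' @export
stability_contingency <- function(visit1, visit2) {
  if (!setequal(rownames(visit1), rownames(visit2)))
    stop("donor set mismatch between visits")
  if (!setequal(colnames(visit1), colnames(visit2)))
    stop("column mismatch between visits")
  v2 <- visit2[rownames(visit1), colnames(visit1), drop = FALSE]
  tab <- matrix(c(sum(visit1 & v2), sum(visit1 & !v2),
                  sum(!visit1 & v2), sum(!visit1 & !v2)),
                2L, 2L,
                dimnames = list(visit1 = c("high", "low"),
                                visit2 = c("high", "low")))
  storage.mode(tab) <- "integer"
  tab
}

#' Exact Fisher test for a 2x2 table
#'
#' Exact conditional test with fixed margins; the top-left cell follows a
#' hypergeometric distribution. The two-tailed p-value uses the
#' point-probability rule: the sum of probabilities of all margin-fixed
#' tables whose point probability does not exceed that of the observed
#' table.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (one-sided in the top-left cell).
#' @return The p-value.
#' @export
fisher_exact_2x2 <- function(tab,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("expected a 2x2 table")
  if (any(tab < 0)) stop("negative entries in contingency table")
  if (any(abs(tab - round(tab)) > 1e-8)) stop("non-integer entries")
  x <- tab[1L, 1L]
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ]); c1 <- sum(tab[, 1L])
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(x, r1, r2, c1)
  p <- switch(alternative,
              two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
              greater = sum(probs[support >= x]),
              less = sum(probs[support <= x]))
  min(1, p)
}
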