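# Downstream OTU-table processing and composition -> phenotype prediction.
# The pipeline order is fixed: depth filter -> rarefy -> normalize ->
# (optional taxonomic collapse) -> classify. Alpha/beta diversity work on
# filtered counts; classification uses total-count-normalized abundances.

.tax_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
                "species")

#' Drop low-depth samples
#'
#' Removes samples with strictly fewer than `min_reads` reads (a sample at
#' exactly the threshold is kept).
#'
#' @param x An [otu_tab()].
#' @param min_reads Depth threshold in reads (default 5000).
#' @return List with `table` (filtered [otu_tab()]) and `dropped`
#'   (character vector of removed sample IDs).
#' @export
filter_low_depth <- function(x, min_reads = 5000) {
  stopifnot(inherits(x, "otu_tab"))
  depths <- sample_depths(x)
  keep <- depths >= min_reads
  if (!any(keep)) stop("all samples fall below the depth threshold")
  list(table = otu_tab(x$counts[keep, , drop = FALSE], x$taxonomy),
       dropped = names(depths)[!keep])
}

#' Rarefy an OTU table to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads (default: the lowest sample depth), via [vegan::rrarefy()] under a
#' fixed seed. A sample already at the target depth is returned unchanged.
#'
#' @param x An [otu_tab()].
#' @param depth Target depth; must not exceed any sample's depth.
#' @param seed Integer seed making the subsampling reproducible.
#' @return Rarefied [otu_tab()] (all depths equal to `depth`).
#' @export
rarefy_table <- function(x, depth = NULL, seed = 1L) {
  stopifnot(inherits(x, "otu_tab"))
  depths <- sample_depths(x)
  depth <- depth %||% min(depths)
  if (any(depths < depth))
    stop(sprintf("depth %d exceeds sample depth of '%s'", depth,
                 names(depths)[which(depths < depth)[1L]]))
  # counts are validated integers already; rrarefy's "observed counts"
  # heuristic warning (minimum count > 1) is a false alarm here
  rare <- withr::with_seed(seed, withCallingHandlers(
    vegan::rrarefy(x$counts, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  otu_tab(rare, x$taxonomy)
}

#' Total-count normalization to relative abundances
#'
#' @param x An [otu_tab()]; every sample must have positive depth
#'   (low-depth samples should have been filtered already).
#' @return Row-stochastic numeric matrix (samples x OTUs) with the
#'   taxonomy carried in attribute `"taxonomy"` and
#'   `"normalization" = "total_count"`.
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "otu_tab"))
  depths <- sample_depths(x)
  if (any(depths == 0))
    stop(sprintf("zero-depth sample '%s' (filter before normalizing)",
                 names(depths)[which(depths == 0)[1L]]))
  rel <- sweep(x$counts, 1L, depths, "/")
  attr(rel, "taxonomy") <- x$taxonomy
  attr(rel, "normalization") <- "total_count"
  rel
}

#' Collapse features to a taxonomic rank
#'
#' Sums relative abundances of all OTUs sharing the same lineage truncated
#' at `rank`. OTUs unassigned at that rank are pooled into one
#' `"unassigned"` feature per parent lineage, so e.g. an unassigned genus
#' of one family stays distinct from assigned genera and from unassigned
#' genera of other families. Row sums are preserved exactly.
#'
#' @param rel Relative-abundance matrix from [relative_abundance()] (or any
#'   samples x OTUs matrix) with taxonomy in `attr(rel, "taxonomy")` or
#'   supplied via `taxonomy`.
#' @param rank One of kingdom, phylum, class, order, family, genus, species.
#' @param taxonomy Optional named lineage vector overriding the attribute.
#' @return Samples x collapsed-features matrix.
#' @export
collapse_taxonomy <- function(rel, rank, taxonomy = attr(rel, "taxonomy")) {
  r <- match(tolower(rank), .tax_ranks)
  if (is.na(r)) stop(sprintf("unknown rank name '%s'", rank))
  if (is.null(taxonomy)) stop("taxonomy required to collapse features")
  tax <- taxonomy[colnames(rel)]
  labels <- vapply(tax, function(s) {
    toks <- trimws(strsplit(if (is.na(s)) "" else s, ";", fixed = TRUE)[[1L]])
    toks <- c(toks, rep("", max(0L, 7L - length(toks))))[1:7]
    unassigned <- toks == "" | tolower(toks) %in% c("unassigned", "na")
    toks[unassigned] <- "unassigned"
    # ranks below an unassigned rank are meaningless; keep parent prefix
    paste(toks[seq_len(r)], collapse = ";")
  }, "", USE.NAMES = FALSE)
  out <- t(rowsum(t(rel), group = labels))
  attr(out, "normalization") <- attr(rel, "normalization")
  out
}

#' Shannon diversity of one sample
#'
#' Shannon entropy `-sum(p * ln p)` (natural log, `0 ln 0 = 0`) of a
#' relative-abundance vector, computed via [vegan::diversity()].
#'
#' @param p Abundance vector summing to 1 (tolerance 1e-6).
#' @return Shannon index in nats.
#' @export
shannon_diversity <- function(p) {
  if (any(p < 0)) stop("negative abundance")
  if (abs(sum(p) - 1) > 1e-6) stop("abundances must sum to 1")
  as.numeric(vegan::diversity(p, index = "shannon"))
}

#' Jensen-Shannon distance between two samples
#'
#' Square root of the Jensen-Shannon divergence with log base 2, so the
#' distance lies in \[0, 1\] (1 for disjoint supports).
#'
#' @param p,q Relative-abundance vectors on the same feature set (same
#'   length; names, when present, must match), each summing to 1.
#' @return Distance in \[0, 1\].
#' @export
jensen_shannon_distance <- function(p, q) {
  if (length(p) != length(q)) stop("mismatched feature sets")
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q)))
    stop("mismatched feature names")
  if (any(p < 0) || any(q < 0)) stop("negative abundance")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("abundances must sum to 1")
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  jsd <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  sqrt(min(1, max(0, jsd)))
}

# empirical ROC points (FPR, TPR), starting at (0,0) and ending at (1,1)
roc_points <- function(scores, is_pos) {
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(is_pos[o]); fp <- cumsum(!is_pos[o])
  s <- scores[o]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, tp[last_of_tie] / sum(is_pos))
  fpr <- c(0, fp[last_of_tie] / sum(!is_pos))
  list(fpr = fpr, tpr = tpr,
       auc = sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2))
}

#' Cross-validated high/low classifier from community composition
#'
#' Trains a random forest per stratified fold to predict high/low phenotype
#' labels from relative abundances, builds each fold's ROC on the held-out
#' samples, vertically averages the ROCs on a fixed 101-point
#' false-positive-rate grid, and averages impurity-based (mean decrease in
#' Gini) feature importances across folds.
#'
#' @param features Samples x features numeric matrix (e.g. from
#'   [relative_abundance()] or [collapse_taxonomy()]).
#' @param labels Logical (`TRUE` = high) or two-level factor, one per
#'   sample; at least two samples per class.
#' @param folds Number of stratified CV folds (default 5).
#' @param seed Integer seed controlling fold assignment and tree growing.
#' @param ntree Trees per forest (default 500).
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @return Object of class `"mmp_classifier_report"`: list with `fpr_grid`,
#'   `mean_tpr`, `auc_per_fold`, `mean_auc`, `importance` (normalized to
#'   sum 1), `fold_assignments`, `folds`, `seed`, `ntree`.
#' @export
train_high_low_classifier <- function(features, labels, folds = 5, seed = 1L,
                                      ntree = 500, mtry = NULL) {
  features <- as.matrix(features)
  y <- if (is.logical(labels)) factor(ifelse(labels, "high", "low"),
                                      levels = c("low", "high"))
       else factor(labels)
  if (nlevels(droplevels(y)) < 2L) stop("labels contain a single class")
  if (any(table(y) < 2L)) stop("need at least two samples per class")
  if (nrow(features) != length(y)) stop("features/labels length mismatch")
  pos <- levels(y)[2L]
  withr::local_seed(seed)
  fold_of <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  grid <- seq(0, 1, length.out = 101L)
  tpr_mat <- matrix(NA_real_, folds, length(grid))
  aucs <- rep(NA_real_, folds)
  imp <- matrix(0, folds, ncol(features),
                dimnames = list(NULL, colnames(features)))
  for (f in seq_len(folds)) {
    test <- fold_of == f
    if (length(unique(y[test])) < 2L || length(unique(y[!test])) < 2L) next
    rf <- randomForest::randomForest(
      x = features[!test, , drop = FALSE], y = y[!test], ntree = ntree,
      mtry = mtry %||% max(1L, floor(sqrt(ncol(features)))))
    prob <- predict(rf, features[test, , drop = FALSE], type = "prob")[, pos]
    rp <- roc_points(prob, y[test] == pos)
    aucs[f] <- rp$auc
    tpr_mat[f, ] <- approx(rp$fpr, rp$tpr, xout = grid, method = "linear",
                           ties = max, yleft = 0, yright = 1)$y
    gi <- rf$importance[, "MeanDecreaseGini"]
    imp[f, ] <- if (sum(gi) > 0) gi / sum(gi) else 1 / length(gi)
  }
  ok <- !is.na(aucs)
  if (!any(ok)) stop("no fold had both classes in its test set")
  if (!all(ok))
    warning(sprintf("%d fold(s) lacked a class in the test set and were dropped",
                    sum(!ok)))
  importance <- colMeans(imp[ok, , drop = FALSE])
  importance <- importance / sum(importance)
  structure(list(fpr_grid = grid,
                 mean_tpr = colMeans(tpr_mat[ok, , drop = FALSE]),
                 auc_per_fold = aucs[ok],
                 mean_auc = mean(aucs[ok]),
                 importance = importance,
                 fold_assignments = fold_of,
                 folds = folds, seed = seed, ntree = ntree),
            class = "mmp_classifier_report")
}

#' @export
print.mmp_classifier_report <- function(x, ...) {
  cat(sprintf("High/low classifier: mean AUC %.3f over %d folds (seed %d)\n",
              x$mean_auc, length(x$auc_per_fold), x$seed))
  top <- sort(x$importance, decreasing = TRUE)[1:min(5, length(x$importance))]
  cat("Top features:", paste(sprintf("%s (%.3f)", names(top), top),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Binarize baseline stool SCFA content
#'
#' Labels donors high/low on their 0 h (pre-incubation) stool concentration
#' of one SCFA: replicate-averaged control-condition concentration at 0 h,
#' z-scored across donors, with z >= 0 labelled high — the same boundary
#' rule used for production rates.
#'
#' @param x Long SCFA data frame.
#' @param scfa Which SCFA to label on.
#' @return Named logical vector (`TRUE` = high) over donors.
#' @export
binarize_baseline_content <- function(x, scfa = "butyrate") {
  sub <- x[x$scfa == scfa & x$timepoint_h == 0 & x$condition == "control", ]
  if (!nrow(sub)) stop("no 0 h control measurements found")
  m <- tapply(sub$conc_mM, sub$donor, mean)
  z <- (m - mean(m)) / sd(m)
  setNames(z >= 0, names(m))
}
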