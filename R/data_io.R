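# I/O for the two table families the pipeline consumes: wide SCFA
# concentration tables keyed by sample ID, and OTU count tables with
# optional 7-rank taxonomy. Wide layouts exist only at this boundary; all
# internal processing uses long/tidy data frames.

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a wide SCFA concentration table
#'
#' Expects one row per sample ID with numeric columns `acetate`,
#' `propionate` and `butyrate` (mM), a `sample_id` column, and an optional
#' integer `replicate` column (defaults to 1). CSV, TSV and `.xlsx` (first
#' sheet, via readxl) are supported. Sample IDs are parsed with
#' [parse_sample_id()] under the stated dialect.
#'
#' @param path File path.
#' @param dialect Sample-ID timepoint dialect, `"A"` or `"B"`.
#' @return Long data frame with columns `donor`, `condition`, `timepoint_h`,
#'   `replicate`, `scfa`, `conc_mM` — one row per (sample, SCFA).
#' @export
read_scfa_table <- function(path, dialect = c("A", "B")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx requires the 'readxl' package")
    raw <- as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    raw <- read.delim(path, sep = .delim_for(path), header = TRUE,
                      colClasses = "character", check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
  names(raw) <- tolower(names(raw))
  needed <- c("sample_id", scfa_names())
  missing <- setdiff(needed, names(raw))
  if (length(missing))
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  rep_idx <- if ("replicate" %in% names(raw)) {
    r <- suppressWarnings(as.integer(raw$replicate))
    if (anyNA(r) || any(r < 1L))
      stop("column 'replicate' must hold integers >= 1")
    r
  } else rep(1L, nrow(raw))
  dup <- duplicated(paste(raw$sample_id, rep_idx))
  if (any(dup))
    stop(sprintf("duplicate sample ID '%s' at row %d",
                 raw$sample_id[which(dup)[1L]], which(dup)[1L]))
  for (sc in scfa_names()) {
    v <- suppressWarnings(as.numeric(raw[[sc]]))
    bad <- which(is.na(v) & !(is.na(raw[[sc]]) | raw[[sc]] == ""))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   raw[[sc]][bad[1L]], bad[1L], sc))
    if (any(v < 0, na.rm = TRUE))
      stop(sprintf("negative concentration at row %d, column '%s'",
                   which(v < 0)[1L], sc))
    raw[[sc]] <- v
  }
  keys <- parse_sample_ids(raw$sample_id, dialect)
  long <- do.call(rbind, lapply(scfa_names(), function(sc) {
    data.frame(keys, replicate = rep_idx, scfa = sc, conc_mM = raw[[sc]],
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}

#' Write a wide SCFA concentration table
#'
#' Inverse of [read_scfa_table()]: casts the long representation back to one
#' row per (donor, condition, timepoint, replicate) with one column per SCFA.
#'
#' @param x Long SCFA data frame as returned by [read_scfa_table()].
#' @param path Output path; `.csv` writes comma-separated, otherwise TSV.
#' @param dialect Dialect used to format sample IDs.
#' @return `path`, invisibly.
#' @export
write_scfa_table <- function(x, path, dialect = c("A", "B")) {
  dialect <- match.arg(dialect)
  key <- unique(x[, c("donor", "condition", "timepoint_h", "replicate")])
  key <- key[order(key$donor, key$condition, key$timepoint_h, key$replicate), ]
  wide <- data.frame(
    sample_id = mapply(format_sample_id, key$donor, key$condition,
                       key$timepoint_h, MoreArgs = list(dialect = dialect)),
    replicate = key$replicate, stringsAsFactors = FALSE)
  for (sc in scfa_names()) {
    sub <- x[x$scfa == sc, ]
    idx <- match(paste(key$donor, key$condition, key$timepoint_h, key$replicate),
                 paste(sub$donor, sub$condition, sub$timepoint_h, sub$replicate))
    wide[[sc]] <- sub$conc_mM[idx]
  }
  write.table(wide, path, sep = .delim_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Construct an OTU count table
#'
#' @param counts Integer matrix, samples in rows, OTUs in columns.
#' @param taxonomy Optional named character vector mapping OTU IDs to
#'   7-rank, semicolon-separated lineage strings (missing ranks may be
#'   `"unassigned"` or empty).
#' @return Object of class `"otu_tab"`: list with elements `counts` and
#'   `taxonomy`.
#' @export
otu_tab <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("OTU", seq_len(ncol(counts)))
  if (any(counts < 0)) stop("negative count in OTU table")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("fractional count in OTU table")
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[colnames(counts)]
    if (anyNA(names(taxonomy)))
      stop("taxonomy must cover every OTU ID in the count matrix")
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_tab")
}

#' @export
print.otu_tab <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs; depth %d-%d; taxonomy: %s\n",
              nrow(x$counts), ncol(x$counts), min(sample_depths(x)),
              max(sample_depths(x)),
              if (is.null(x$taxonomy)) "absent" else "present"))
  invisible(x)
}

#' Per-sample sequencing depths (row sums) of an OTU table
#' @param x An `"otu_tab"`.
#' @return Named integer vector of read counts per sample.
#' @export
sample_depths <- function(x) {
  stopifnot(inherits(x, "otu_tab"))
  rowSums(x$counts)
}

#' Read an OTU count table from TSV
#'
#' QIIME-classic-like layout: a header row, an ID column first, integer
#' counts, and optionally a trailing `taxonomy` column. Orientation is an
#' explicit flag, never guessed.
#'
#' @param path TSV path.
#' @param orientation `"samples_in_rows"` (default) or `"samples_in_columns"`.
#' @param taxonomy Optional path to a two-column TSV (`otu_id`, `taxonomy`)
#'   side file, or a named character vector.
#' @return An [otu_tab()].
#' @export
read_otu_table <- function(path,
                           orientation = c("samples_in_rows",
                                           "samples_in_columns"),
                           taxonomy = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- read.delim(path, sep = "\t", header = TRUE, row.names = 1L,
                    check.names = FALSE, stringsAsFactors = FALSE)
  tax_in_table <- NULL
  tax_col <- which(tolower(names(raw)) == "taxonomy")
  if (length(tax_col)) {
    tax_in_table <- setNames(as.character(raw[[tax_col]]), rownames(raw))
    raw <- raw[, -tax_col, drop = FALSE]
  }
  m <- as.matrix(raw)
  if (!is.numeric(m)) stop("OTU table contains non-numeric entries")
  if (orientation == "samples_in_columns") m <- t(m)
  if (!is.null(tax_in_table) && orientation == "samples_in_rows")
    stop("a 'taxonomy' column implies OTUs in rows; use samples_in_columns")
  tax <- tax_in_table
  if (!is.null(taxonomy)) {
    if (is.character(taxonomy) && length(taxonomy) == 1L && file.exists(taxonomy)) {
      tt <- read.delim(taxonomy, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
      tax <- setNames(as.character(tt[[2L]]), tt[[1L]])
    } else tax <- taxonomy
  }
  otu_tab(m, taxonomy = tax)
}

#' Write an OTU count table to TSV
#'
#' @param x An [otu_tab()].
#' @param path Output TSV path.
#' @param orientation Layout to write; with `"samples_in_columns"` any
#'   taxonomy is appended as a trailing column.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path,
                            orientation = c("samples_in_columns",
                                            "samples_in_rows")) {
  stopifnot(inherits(x, "otu_tab"))
  orientation <- match.arg(orientation)
  if (orientation == "samples_in_columns") {
    out <- as.data.frame(t(x$counts), check.names = FALSE)
    out <- cbind(otu_id = rownames(out), out)
    if (!is.null(x$taxonomy)) out$taxonomy <- unname(x$taxonomy[out$otu_id])
  } else {
    out <- as.data.frame(x$counts, check.names = FALSE)
    out <- cbind(sample_id = rownames(out), out)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
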