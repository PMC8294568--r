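# Sample identifiers follow the layout Donor-Condition-Timepoint, e.g.
# "H-Inul-04". Two timepoint-coding dialects are in circulation for the same
# layout: dialect A codes the token as zero-padded hours ("04" = 4 h) while
# dialect B codes it ordinally ("02" = 4 h, the second sampling). Because the
# two dialects assign different hours to the *same* token, the dialect is
# always an explicit argument and never auto-detected.

.condition_tokens <- c(control = "Ctrl", cellulose = "Cell",
                       inulin = "Inul", pectin = "Pect")

.timepoint_tokens <- list(
  A = c("00" = 0, "02" = 2, "04" = 4, "06" = 6, "08" = 8, "24" = 24),
  B = c("00" = 0, "01" = 2, "02" = 4, "03" = 6, "04" = 8, "05" = 24)
)

#' Parse a sample identifier
#'
#' Splits an identifier of the form `Donor-Condition-Timepoint` into its
#' components. Condition tokens are `Ctrl`, `Cell`, `Inul`, `Pect`
#' (case-insensitive). The timepoint token is interpreted under the given
#' dialect: dialect `"A"` maps `"02"` to 2 h and `"04"` to 4 h; dialect `"B"`
#' maps `"01"` to 2 h and `"02"` to 4 h.
#'
#' @param raw Sample identifier string.
#' @param dialect `"A"` or `"B"` (timepoint-token coding).
#' @return A list of class `"sample_key"` with fields `donor_id`,
#'   `condition`, `timepoint_h`, `replicate` (defaults to 1) and `dialect`.
#' @seealso [format_sample_id()] for the inverse.
#' @examples
#' parse_sample_id("H-Inul-04", "A")$timepoint_h  # 4
#' parse_sample_id("H-Inul-02", "B")$timepoint_h  # 4
#' @export
parse_sample_id <- function(raw, dialect = c("A", "B")) {
  dialect <- match.arg(dialect)
  stopifnot(is.character(raw), length(raw) == 1L)
  parts <- strsplit(raw, "-", fixed = TRUE)[[1L]]
  if (length(parts) < 3L)
    stop(sprintf("malformed sample ID '%s': expected Donor-Condition-Timepoint", raw))
  tp_tok <- parts[length(parts)]
  cond_tok <- parts[length(parts) - 1L]
  donor <- paste(parts[seq_len(length(parts) - 2L)], collapse = "-")
  ci <- match(tolower(cond_tok), tolower(.condition_tokens))
  if (is.na(ci))
    stop(sprintf("unknown condition token '%s' in sample ID '%s'", cond_tok, raw))
  map <- .timepoint_tokens[[dialect]]
  ti <- match(tp_tok, names(map))
  if (is.na(ti))
    stop(sprintf("unknown timepoint token '%s' for dialect %s in sample ID '%s'",
                 tp_tok, dialect, raw))
  structure(list(donor_id = donor,
                 condition = names(.condition_tokens)[ci],
                 timepoint_h = unname(map[ti]),
                 replicate = 1L,
                 dialect = dialect),
            class = "sample_key")
}

#' Format a sample identifier
#'
#' Inverse of [parse_sample_id()]: builds the `Donor-Condition-Timepoint`
#' string under the requested dialect. `parse_sample_id(format_sample_id(x))`
#' is the identity for study-layout timepoints (0, 2, 4, 6, 8, 24 h).
#'
#' @param donor_id Donor identifier (or a `"sample_key"` as sole argument).
#' @param condition One of [condition_names()].
#' @param timepoint_h Timepoint in hours.
#' @param dialect `"A"` or `"B"`.
#' @return Identifier string.
#' @export
format_sample_id <- function(donor_id, condition = NULL, timepoint_h = NULL,
                             dialect = c("A", "B")) {
  if (inherits(donor_id, "sample_key")) {
    key <- donor_id
    return(format_sample_id(key$donor_id, key$condition, key$timepoint_h,
                            key$dialect))
  }
  dialect <- match.arg(dialect)
  condition <- match.arg(condition, condition_names())
  map <- .timepoint_tokens[[dialect]]
  ti <- match(timepoint_h, map)
  if (is.na(ti))
    stop(sprintf("timepoint %g h has no token in dialect %s", timepoint_h, dialect))
  paste(donor_id, unname(.condition_tokens[condition]), names(map)[ti], sep = "-")
}

# vectorised parse used by the table reader; returns a data.frame
parse_sample_ids <- function(ids, dialect) {
  keys <- lapply(ids, parse_sample_id, dialect = dialect)
  data.frame(donor = vapply(keys, `[[`, "", "donor_id"),
             condition = vapply(keys, `[[`, "", "condition"),
             timepoint_h = vapply(keys, `[[`, 0, "timepoint_h"),
             stringsAsFactors = FALSE)
}
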