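#' Construct a table of genomic intervals
#'
#' The package represents genomic intervals as a plain `data.frame` with
#' columns `chrom`, `start`, `end`, `name`, `score`, `strand`. Coordinates
#' are 0-based, half-open (BED convention) everywhere inside the package;
#' 1-based coordinates only ever appear at display boundaries.
#'
#' @param chrom character vector of chromosome identifiers (no whitespace).
#' @param start integer vector of 0-based inclusive start positions.
#' @param end integer vector of exclusive end positions (`end > start`).
#' @param name optional character labels (`NA` when absent).
#' @param score optional numeric scores (`NA` when absent).
#' @param strand optional strand, each entry one of `"+"`, `"-"`, `"."`
#'   (`NA` when absent).
#' @return validated `data.frame` of intervals.
#' @export
intervals <- function(chrom, start, end, name = NA_character_,
                      score = NA_real_, strand = NA_character_) {
  n <- if (length(chrom) == 0L || length(start) == 0L) 0L else
    max(length(chrom), length(start), length(end))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

#' Validate an interval table
#'
#' Checks the invariants every interval consumer in the package relies on:
#' non-negative starts, `end > start`, chromosome tokens without whitespace,
#' and strand restricted to `+`, `-`, `.` (or `NA` for "not populated").
#'
#' @param df interval `data.frame`.
#' @param context string used to prefix error messages.
#' @return the input, invisibly.
#' @export
validate_intervals <- function(df, context = "interval") {
  required <- c("chrom", "start", "end")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(context, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) return(invisible(df))
  if (anyNA(df$chrom) || any(grepl("[[:space:]]", df$chrom))) {
    stop(context, ": chromosome identifiers must be non-missing tokens without whitespace")
  }
  if (anyNA(df$start) || anyNA(df$end)) {
    stop(context, ": start/end must be non-missing integers")
  }
  if (any(df$start < 0L)) {
    stop(context, ": negative start at row ", which(df$start < 0L)[1L])
  }
  bad <- which(df$end <= df$start)
  if (length(bad) > 0L) {
    stop(context, ": end <= start at row ", bad[1L])
  }
  if ("strand" %in% names(df)) {
    s <- df$strand[!is.na(df$strand)]
    if (length(s) > 0L && !all(s %in% c("+", "-", "."))) {
      stop(context, ": strand must be one of '+', '-', '.'")
    }
  }
  invisible(df)
}

# Fill absent optional columns so downstream code can index them blindly.
.complete_interval_cols <- function(df) {
  if (!"name" %in% names(df)) df$name <- NA_character_
  if (!"score" %in% names(df)) df$score <- NA_real_
  if (!"strand" %in% names(df)) df$strand <- NA_character_
  df[, c("chrom", "start", "end", "name", "score", "strand")]
}

# Convert half-open 0-based intervals to the 1-based closed IRanges used
# internally for overlap machinery. Book-ended BED intervals become adjacent
# closed ranges, which IRanges::reduce() merges by default.
.as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

#' Interval midpoints
#'
#' Midpoint of a half-open interval, defined as `floor((start + end) / 2)`
#' (a 0-based position guaranteed to lie inside the interval).
#'
#' @param df interval data.frame.
#' @return integer vector of 0-based midpoint positions.
#' @export
interval_midpoint <- function(df) {
  as.integer(floor((as.numeric(df$start) + as.numeric(df$end)) / 2))
}

#' Sort intervals and merge overlapping or book-ended spans
#'
#' Produces a canonical peak set: intervals sorted by (chrom, start, end)
#' with overlapping or boundary-sharing intervals collapsed to their union
#' span. Name/score/strand are dropped by merging (a merged region has no
#' single parent record).
#'
#' @param df interval data.frame.
#' @param label optional sample/factor label attached as an attribute.
#' @return a `PeakSet`: a sorted, merged interval data.frame with class
#'   `c("PeakSet", "data.frame")` and attribute `label`.
#' @export
sort_and_merge <- function(df, label = NULL) {
  df <- .complete_interval_cols(as.data.frame(df))
  validate_intervals(df, "sort_and_merge")
  out_list <- list()
  for (ch in sort(unique(df$chrom))) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    red <- IRanges::reduce(.as_iranges(sub))
    out_list[[ch]] <- data.frame(
      chrom = ch,
      start = IRanges::start(red) - 1L,
      end = IRanges::end(red),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(out_list) > 0L) do.call(rbind, out_list) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- .complete_interval_cols(out)
  class(out) <- c("PeakSet", "data.frame")
  attr(out, "label") <- label
  out
}

#' Test whether an interval table is a canonical (sorted, merged) peak set
#' @param df interval data.frame.
#' @return logical scalar.
#' @export
is_merged <- function(df) {
  if (nrow(df) < 2L) return(TRUE)
  o <- order(df$chrom, df$start, df$end)
  if (!identical(o, seq_len(nrow(df)))) return(FALSE)
  same <- df$chrom[-1L] == df$chrom[-nrow(df)]
  !any(same & df$start[-1L] <= df$end[-nrow(df)])
}

# Overlap hits between two interval tables (>= 1 bp shared), chromosome-aware.
# Returns a data.frame with columns `query` and `subject` (row indices).
.overlap_pairs <- function(query, subject) {
  qh <- integer(0); sh <- integer(0)
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    ov <- IRanges::findOverlaps(.as_iranges(query[qi, , drop = FALSE]),
                                .as_iranges(subject[si, , drop = FALSE]))
    qh <- c(qh, qi[S4Vectors::queryHits(ov)])
    sh <- c(sh, si[S4Vectors::subjectHits(ov)])
  }
  data.frame(query = qh, subject = sh)
}
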