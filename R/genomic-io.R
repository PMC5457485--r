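#' Read a BED file
#'
#' Reads BED3/BED6 with strict coordinate validation. `track` and `browser`
#' lines and `#` comments are skipped. Intervals are returned in file order
#' with 0-based half-open coordinates. BED score columns of `"."` are read
#' as `NA`.
#'
#' @param path path to a tab-separated BED file.
#' @param expect_strand if `TRUE`, a missing strand column is an error.
#' @return interval data.frame (columns chrom, start, end, name, score,
#'   strand).
#' @export
read_bed <- function(path, expect_strand = FALSE) {
  if (!file.exists(path)) stop("read_bed: file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    df <- .complete_interval_cols(
      data.frame(chrom = character(), start = integer(), end = integer()))
    if (expect_strand) stop("read_bed: strand column required but file is empty")
    return(df)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("read_bed: line ", line_no[which(nf < 3L)[1L]],
         ": fewer than 3 tab-separated columns")
  }
  get_col <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, character(1))
  chrom <- get_col(1L)
  start_raw <- get_col(2L)
  end_raw <- get_col(3L)
  start <- suppressWarnings(as.integer(start_raw))
  end <- suppressWarnings(as.integer(end_raw))
  bad <- which(is.na(start) | is.na(end) |
                 start_raw != as.character(start) | end_raw != as.character(end))
  if (length(bad) > 0L) {
    stop("read_bed: line ", line_no[bad[1L]], ": non-integer coordinates")
  }
  bad <- which(end <= start)
  if (length(bad) > 0L) {
    stop("read_bed: line ", line_no[bad[1L]], ": end <= start")
  }
  bad <- which(start < 0L)
  if (length(bad) > 0L) {
    stop("read_bed: line ", line_no[bad[1L]], ": negative start")
  }
  name <- if (max(nf) >= 4L) get_col(4L) else NA_character_
  score <- if (max(nf) >= 5L) {
    s <- get_col(5L)
    s[s == "."] <- NA_character_
    suppressWarnings(as.numeric(s))
  } else NA_real_
  strand <- if (max(nf) >= 6L) get_col(6L) else NA_character_
  if (expect_strand && (max(nf) < 6L || anyNA(strand))) {
    stop("read_bed: strand column required (expect_strand = TRUE) but missing")
  }
  if (any(!is.na(strand) & !strand %in% c("+", "-", "."))) {
    bad <- which(!is.na(strand) & !strand %in% c("+", "-", "."))[1L]
    stop("read_bed: line ", line_no[bad], ": invalid strand '", strand[bad], "'")
  }
  df <- data.frame(chrom = chrom, start = start, end = end, name = name,
                   score = score, strand = strand, stringsAsFactors = FALSE)
  validate_intervals(df, "read_bed")
  df
}

#' Write intervals as BED
#'
#' Emits as many of the name/score/strand columns as are populated, in BED
#' column order. A column must be populated consistently: every record or
#' none (strand mixing is an error; a populated score forces a name column,
#' filled with `"."` where absent). No header, trailing newline.
#'
#' @param df interval data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  df <- .complete_interval_cols(as.data.frame(df))
  validate_intervals(df, "write_bed")
  n <- nrow(df)
  if (n == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  has_strand <- !is.na(df$strand)
  if (any(has_strand) && !all(has_strand)) {
    stop("write_bed: strand populated for some records but not all")
  }
  has_score <- any(!is.na(df$score))
  has_name <- any(!is.na(df$name))
  ncol_out <- if (all(has_strand)) 6L else if (has_score) 5L else if (has_name) 4L else 3L
  cols <- list(df$chrom, df$start, df$end)
  if (ncol_out >= 4L) {
    nm <- df$name
    nm[is.na(nm)] <- "."
    cols <- c(cols, list(nm))
  }
  if (ncol_out >= 5L) {
    sc <- ifelse(is.na(df$score), ".", format(df$score, scientific = FALSE, trim = TRUE))
    cols <- c(cols, list(sc))
  }
  if (ncol_out >= 6L) cols <- c(cols, list(df$strand))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read FASTA sequence records
#'
#' Sequences are uppercased and restricted to the alphabet `A,C,G,T,N`;
#' anything else is an error naming the offending record. Record ids are
#' the first whitespace-delimited token of the header. Ids of the form
#' `chrom:start-end` (0-based half-open) declare a genomic offset used by
#' the motif scanner; plain ids map to offset 0 on a chromosome named by
#' the id itself.
#'
#' @param path FASTA path.
#' @return list of records, each `list(id, seq, chrom, offset)`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">")) {
    stop("read_fasta: file does not begin with '>'")
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1L)
  seqs <- unname(toupper(as.character(set)))
  records <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L) stop("read_fasta: record '", ids[i], "' is empty")
    if (grepl("[^ACGTN]", seqs[i])) {
      stop("read_fasta: record '", ids[i],
           "' contains characters outside {A,C,G,T,N}")
    }
    records[[i]] <- sequence_record(ids[i], seqs[i])
  }
  names(records) <- ids
  records
}

#' Construct a sequence record
#'
#' @param id record identifier; `chrom:start-end` declares genome placement.
#' @param seq sequence string (uppercased on construction).
#' @param chrom,offset explicit genome placement, overriding any placement
#'   parsed from `id`.
#' @return `list(id, seq, chrom, offset)`.
#' @export
sequence_record <- function(id, seq, chrom = NULL, offset = NULL) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence_record: '", id, "' contains characters outside {A,C,G,T,N}")
  }
  if (is.null(chrom) || is.null(offset)) {
    m <- regmatches(id, regexec("^([^:]+):([0-9]+)-([0-9]+)$", id))[[1]]
    if (length(m) == 4L) {
      chrom <- m[2]
      offset <- as.integer(m[3])
    } else {
      chrom <- id
      offset <- 0L
    }
  }
  list(id = id, seq = seq, chrom = chrom, offset = as.integer(offset))
}

#' Write sequence records as FASTA
#' @param records list of sequence records (or named character vector).
#' @param path output path.
#' @param width line-fold width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    records <- mapply(sequence_record, names(records), records,
                      SIMPLIFY = FALSE)
  }
  seqs <- vapply(records, `[[`, character(1), "seq")
  ids <- vapply(records, `[[`, character(1), "id")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Extract peak sequences from a genome
#'
#' Pulls the sequence under each interval and returns records carrying the
#' genomic offset, so motif hits scanned from them land on genome
#' coordinates.
#'
#' @param genome list of sequence records (one per chromosome).
#' @param peaks interval data.frame.
#' @return list of sequence records named `chrom:start-end`.
#' @export
peak_sequences <- function(genome, peaks) {
  by_id <- stats::setNames(genome, vapply(genome, `[[`, character(1), "chrom"))
  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]
    rec <- by_id[[ch]]
    if (is.null(rec)) stop("peak_sequences: chromosome '", ch, "' not in genome")
    if (peaks$end[i] > nchar(rec$seq)) {
      stop("peak_sequences: interval beyond end of '", ch, "'")
    }
    id <- sprintf("%s:%d-%d", ch, peaks$start[i], peaks$end[i])
    out[[i]] <- sequence_record(
      id, substr(rec$seq, peaks$start[i] + 1L, peaks$end[i]),
      chrom = ch, offset = peaks$start[i])
  }
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Read a two-column chromosome sizes table
#' @param path TSV with columns chrom, length (no header).
#' @return data.frame with columns `chrom`, `length`.
#' @export
read_genome_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "integer"))
  if (any(df$length <= 0L)) stop("read_genome_sizes: non-positive length")
  if (anyDuplicated(df$chrom)) stop("read_genome_sizes: duplicated chromosome")
  df
}

#' Read JASPAR-style position frequency matrices
#'
#' Parses count blocks of the form
#' \preformatted{>MA0001 motifname
#' A [ 10  5  0 ]
#' C [  0  5 10 ]
#' G ...
#' T ...}
#' (brackets and row labels optional, rows in A,C,G,T order when unlabeled)
#' and converts counts to per-column probabilities after adding a
#' pseudocount distributed by the background frequencies.
#'
#' @param path PFM text file.
#' @param pseudocount total pseudocount added per column (default 0.8),
#'   split across bases proportionally to `background`.
#' @param background length-4 background probabilities (A,C,G,T).
#' @return named list of `PWM` objects (see [pwm()]).
#' @export
read_pwm <- function(path, pseudocount = 0.8,
                     background = c(0.25, 0.25, 0.25, 0.25)) {
  if (!file.exists(path)) stop("read_pwm: file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  headers <- which(startsWith(lines, ">"))
  if (length(headers) == 0L) stop("read_pwm: no '>' headers found")
  out <- list()
  bounds <- c(headers, length(lines) + 1L)
  for (h in seq_along(headers)) {
    block <- lines[(bounds[h] + 1L):(bounds[h + 1L] - 1L)]
    if (length(block) != 4L) {
      stop("read_pwm: motif block '", lines[headers[h]],
           "' must have exactly 4 rows (A,C,G,T)")
    }
    id <- strsplit(sub("^>", "", lines[headers[h]]), "[[:space:]]+")[[1]][1]
    rows <- lapply(block, function(ln) {
      ln <- sub("^[ACGTacgt][[:space:]:]+", "", ln)
      ln <- gsub("[][]", " ", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]]))
      if (anyNA(vals)) stop("read_pwm: non-numeric counts in motif '", id, "'")
      vals
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop("read_pwm: rows of unequal length in motif '", id, "'")
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0)) stop("read_pwm: negative counts in motif '", id, "'")
    out[[id]] <- pwm_from_counts(id, counts, pseudocount = pseudocount,
                                 background = background)
  }
  out
}

#' Construct a PWM from a count matrix
#'
#' @param motif_id motif identifier.
#' @param counts 4 x L non-negative count matrix, rows A,C,G,T.
#' @param pseudocount total pseudocount per column, split by `background`.
#' @param background length-4 background probabilities (A,C,G,T).
#' @return a `PWM` object.
#' @export
pwm_from_counts <- function(motif_id, counts, pseudocount = 0.8,
                            background = c(0.25, 0.25, 0.25, 0.25)) {
  if (nrow(counts) != 4L) stop("pwm_from_counts: counts must have 4 rows")
  probs <- sweep(counts + pseudocount * background, 2, colSums(counts) + pseudocount, "/")
  pwm(motif_id, probs, background = background, pseudocount = pseudocount)
}

#' Construct and validate a PWM object
#'
#' @param motif_id motif identifier.
#' @param probabilities 4 x L probability matrix, rows A,C,G,T; each column
#'   must sum to 1 within 1e-9.
#' @param background length-4 background probabilities summing to 1.
#' @param pseudocount pseudocount used at construction (metadata).
#' @return `list(motif_id, probabilities, background, pseudocount)` with
#'   class `PWM`.
#' @export
pwm <- function(motif_id, probabilities, background = c(0.25, 0.25, 0.25, 0.25),
                pseudocount = 0) {
  probabilities <- as.matrix(probabilities)
  if (nrow(probabilities) != 4L) stop("pwm: probabilities must have 4 rows")
  rownames(probabilities) <- c("A", "C", "G", "T")
  if (any(abs(colSums(probabilities) - 1) > 1e-9)) {
    stop("pwm: columns of '", motif_id, "' do not sum to 1")
  }
  if (abs(sum(background) - 1) > 1e-9) stop("pwm: background does not sum to 1")
  structure(list(motif_id = motif_id, probabilities = probabilities,
                 background = background, pseudocount = pseudocount),
            class = "PWM")
}
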