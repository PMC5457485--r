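#' Construct a DNase I cut profile
#'
#' A `CutProfile` stores, per chromosome and per strand, a sparse mapping
#' from 0-based position to the number of DNase I cut 5' ends observed
#' there. It is the input signal for footprinting, tag counting, and all
#' signal heatmaps.
#'
#' @param cuts data.frame with columns `chrom`, `pos` (0-based), `strand`
#'   (`"+"`/`"-"`), and optionally `count` (default 1 per row); rows with
#'   equal (chrom, strand, pos) are accumulated.
#' @param genome_sizes data.frame with columns `chrom`, `length`.
#' @return object of class `CutProfile`: `list(data, genome_sizes,
#'   total_cuts)` where `data[[chrom]][[strand]]` holds sorted `pos`,
#'   `count`, and cumulative counts.
#' @export
cut_profile <- function(cuts, genome_sizes) {
  stopifnot(all(c("chrom", "pos", "strand") %in% names(cuts)))
  if (!"count" %in% names(cuts)) cuts$count <- rep(1L, nrow(cuts))
  if (any(!cuts$strand %in% c("+", "-"))) {
    stop("cut_profile: strand must be '+' or '-'")
  }
  sizes <- stats::setNames(genome_sizes$length, genome_sizes$chrom)
  unknown <- setdiff(unique(cuts$chrom), names(sizes))
  if (length(unknown) > 0L) {
    stop("cut_profile: unknown chromosome '", unknown[1L], "'")
  }
  bad <- which(cuts$pos < 0L | cuts$pos >= sizes[cuts$chrom])
  if (length(bad) > 0L) {
    stop("cut_profile: position beyond chromosome length at record ", bad[1L])
  }
  data <- list()
  total <- 0
  for (ch in unique(cuts$chrom)) {
    data[[ch]] <- list()
    for (st in c("+", "-")) {
      sub <- cuts[cuts$chrom == ch & cuts$strand == st, , drop = FALSE]
      if (nrow(sub) == 0L) {
        data[[ch]][[st]] <- list(pos = integer(0), count = integer(0),
                                 cum = numeric(0))
        next
      }
      agg <- rowsum(as.numeric(sub$count), group = sub$pos)
      pos <- as.integer(rownames(agg))
      o <- order(pos)
      pos <- pos[o]
      count <- as.numeric(agg[o, 1L])
      data[[ch]][[st]] <- list(pos = pos, count = count, cum = cumsum(count))
      total <- total + sum(count)
    }
  }
  structure(list(data = data, genome_sizes = genome_sizes,
                 total_cuts = total),
            class = "CutProfile")
}

#' Load a cut profile from a BED file of single-base cut sites
#'
#' Each BED record is one cut 5' end: a single-base interval
#' (`end == start + 1`) with strand. Reverse-strand reads are expected to
#' have been converted to their 5'-end position upstream.
#'
#' @param path_bed BED6 path.
#' @param genome_sizes data.frame with columns `chrom`, `length`, or a path
#'   to a two-column TSV.
#' @return a `CutProfile`.
#' @export
load_cut_profile <- function(path_bed, genome_sizes) {
  if (is.character(genome_sizes)) genome_sizes <- read_genome_sizes(genome_sizes)
  bed <- read_bed(path_bed, expect_strand = TRUE)
  wide <- which(bed$end - bed$start != 1L)
  if (length(wide) > 0L) {
    stop("load_cut_profile: record ", wide[1L], " is wider than 1 bp")
  }
  if (any(bed$strand == ".")) {
    stop("load_cut_profile: cut records must be stranded ('+' or '-')")
  }
  cut_profile(data.frame(chrom = bed$chrom, pos = bed$start,
                         strand = bed$strand, stringsAsFactors = FALSE),
              genome_sizes)
}

#' Write a cut profile back to single-base BED
#' @param profile a `CutProfile`.
#' @param path output BED path (one record per cut; multiplicities expanded).
#' @return `path`, invisibly.
#' @export
write_cut_profile <- function(profile, path) {
  chunks <- character(0)
  for (ch in names(profile$data)) {
    for (st in c("+", "-")) {
      d <- profile$data[[ch]][[st]]
      if (length(d$pos) == 0L) next
      pos <- rep(d$pos, times = d$count)
      chunks <- c(chunks, paste(ch, pos, pos + 1L, ".", 0L, st, sep = "\t"))
    }
  }
  writeLines(chunks, path)
  invisible(path)
}

#' Count cuts within windows
#'
#' Number of cut 5' ends with position in each half-open window
#' `[start, end)`.
#'
#' @param profile a `CutProfile`.
#' @param chrom chromosome (scalar).
#' @param starts,ends integer vectors of window bounds (0-based half-open).
#' @param strand `"+"`, `"-"`, or `"both"`.
#' @return numeric vector of counts, one per window.
#' @export
window_counts <- function(profile, chrom, starts, ends, strand = "both") {
  strands <- if (strand == "both") c("+", "-") else strand
  total <- numeric(length(starts))
  chd <- profile$data[[chrom]]
  if (is.null(chd)) return(total)
  for (st in strands) {
    d <- chd[[st]]
    if (length(d$pos) == 0L) next
    hi <- findInterval(ends - 1L, d$pos)
    lo <- findInterval(starts - 1L, d$pos)
    cum <- c(0, d$cum)
    total <- total + (cum[hi + 1L] - cum[lo + 1L])
  }
  total
}

#' Dense per-base cut counts over a window
#'
#' @param profile a `CutProfile`.
#' @param chrom chromosome.
#' @param start,end 0-based half-open window; clipped to the chromosome
#'   (positions outside contribute zero).
#' @param strand `"+"`, `"-"`, or `"both"`.
#' @return numeric vector of length `end - start`.
#' @export
dense_cuts <- function(profile, chrom, start, end, strand = "both") {
  strands <- if (strand == "both") c("+", "-") else strand
  v <- numeric(end - start)
  chd <- profile$data[[chrom]]
  if (is.null(chd)) return(v)
  for (st in strands) {
    d <- chd[[st]]
    sel <- d$pos >= start & d$pos < end
    if (any(sel)) {
      idx <- d$pos[sel] - start + 1L
      v[idx] <- v[idx] + d$count[sel]
    }
  }
  v
}
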