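#' Scan sequences with a position weight matrix
#'
#' Log-odds scanning of both strands. The per-window score is
#' `sum(log2(p[base, j] / bg[base]))`; a window is reported when its score
#' reaches `rel_threshold` of the attainable score range, i.e. at least
#' `rel_threshold * (max_score - min_score) + min_score`. Windows
#' containing `N` are skipped. Hit coordinates are genomic, via each
#' record's declared `chrom`/`offset`.
#'
#' @param sequence_set list of sequence records (see [sequence_record()]).
#' @param pwm a `PWM` object.
#' @param rel_threshold relative score threshold in `(0, 1]` (default 0.8).
#' @return a `MotifHitSet`: data.frame with columns `motif_id`, `chrom`,
#'   `start`, `end`, `strand`, `score` (bits), sorted by (chrom, start,
#'   strand) and deduplicated on that key, with class
#'   `c("MotifHitSet", "data.frame")`.
#' @export
scan_pwm <- function(sequence_set, pwm, rel_threshold = 0.8) {
  if (!inherits(pwm, "PWM")) stop("scan_pwm: pwm must be a PWM object")
  if (!is.numeric(rel_threshold) || rel_threshold <= 0 || rel_threshold > 1) {
    stop("scan_pwm: rel_threshold must be in (0, 1]")
  }
  lo_fw <- log2(pwm$probabilities / pwm$background)
  # reverse complement: reverse columns, swap A<->T and C<->G rows
  lo_rv <- log2(pwm$probabilities[4:1, ncol(pwm$probabilities):1, drop = FALSE] /
                  pwm$background[4:1])
  thr <- .pwm_threshold(lo_fw, rel_threshold)
  hits <- list()
  for (rec in sequence_set) {
    codes <- .encode_seq(rec$seq)
    for (st in c("+", "-")) {
      lo <- if (st == "+") lo_fw else lo_rv
      sc <- .window_scores(codes, lo)
      if (length(sc) == 0L) next
      at <- which(!is.na(sc) & sc >= thr)
      if (length(at) == 0L) next
      hits[[length(hits) + 1L]] <- data.frame(
        motif_id = pwm$motif_id,
        chrom = rec$chrom,
        start = rec$offset + at - 1L,
        end = rec$offset + at - 1L + ncol(lo),
        strand = st,
        score = sc[at],
        stringsAsFactors = FALSE
      )
    }
  }
  .as_hitset(hits, pwm$motif_id)
}

.encode_seq <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

.pwm_threshold <- function(lo, rel_threshold) {
  mx <- sum(apply(lo, 2L, max))
  mn <- sum(apply(lo, 2L, min))
  # a PWM identical to background carries no information: nothing can score
  # above chance, so no window qualifies
  if (mx - mn <= 1e-12) return(Inf)
  rel_threshold * (mx - mn) + mn
}

# Rolling log-odds scores for every window of width ncol(lo); NA where the
# window contains an unresolvable base.
.window_scores <- function(codes, lo) {
  L <- ncol(lo)
  n <- length(codes)
  if (n < L) return(numeric(0))
  sc <- numeric(n - L + 1L)
  for (j in seq_len(L)) {
    sc <- sc + lo[cbind(codes[j:(n - L + j)], j)]
  }
  sc
}

.as_hitset <- function(hits, motif_id) {
  df <- if (length(hits) > 0L) do.call(rbind, hits) else
    data.frame(motif_id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), score = numeric(),
               stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
  df <- df[!duplicated(df[, c("chrom", "start", "strand")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("MotifHitSet", "data.frame")
  attr(df, "motif_id") <- motif_id
  df
}

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

.iupac_complement <- function(code) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(code, "", fixed = TRUE)[[1]]]), collapse = "")
}

.iupac_regex <- function(consensus) {
  letters <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  bad <- setdiff(letters, names(.IUPAC))
  if (length(bad) > 0L) {
    stop("match_iupac: invalid IUPAC code '", bad[1L], "'")
  }
  paste(vapply(letters, function(l) {
    opts <- .IUPAC[[l]]
    if (nchar(opts) == 1L) opts else paste0("[", opts, "]")
  }, character(1)), collapse = "")
}

#' Exact degenerate (IUPAC) consensus matching
#'
#' Finds every occurrence of a degenerate consensus on both strands,
#' including overlapping occurrences. Reverse-strand hits are reported on
#' forward genome coordinates with strand `"-"`.
#'
#' @param sequence_set list of sequence records.
#' @param consensus IUPAC consensus string.
#' @return a `MotifHitSet` (score column is `NA`; exact matches carry no
#'   log-odds score).
#' @export
match_iupac <- function(sequence_set, consensus) {
  consensus <- toupper(consensus)
  fw_re <- .iupac_regex(consensus)
  rv_re <- .iupac_regex(.iupac_complement(consensus))
  L <- nchar(consensus)
  hits <- list()
  for (rec in sequence_set) {
    for (st in c("+", "-")) {
      re <- if (st == "+") fw_re else rv_re
      m <- gregexpr(paste0("(?=", re, ")"), rec$seq, perl = TRUE)[[1]]
      at <- as.integer(m)
      at <- at[at > 0L]
      if (length(at) == 0L) next
      hits[[length(hits) + 1L]] <- data.frame(
        motif_id = consensus, chrom = rec$chrom,
        start = rec$offset + at - 1L, end = rec$offset + at - 1L + L,
        strand = st, score = NA_real_, stringsAsFactors = FALSE)
    }
  }
  .as_hitset(hits, consensus)
}

#' Per-peak motif hit counts
#'
#' Counts, for each peak, the motif hits whose midpoint lies within the
#' peak (half-open). `presence` is count >= 1.
#'
#' @param hitset a `MotifHitSet`.
#' @param peaks merged peak set.
#' @return data.frame with one row per peak: `count`, `presence`.
#' @export
hits_in_peaks <- function(hitset, peaks) {
  if (!is_merged(peaks)) stop("hits_in_peaks: peaks must be sorted and merged")
  count <- integer(nrow(peaks))
  if (nrow(hitset) > 0L && nrow(peaks) > 0L) {
    mid <- interval_midpoint(hitset)
    pts <- data.frame(chrom = hitset$chrom, start = mid, end = mid + 1L)
    ov <- .overlap_pairs(pts, peaks)
    if (nrow(ov) > 0L) {
      tab <- table(ov$subject)
      count[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  data.frame(count = count, presence = count >= 1L)
}

#' In vitro EVI1-binding consensus sequences
#'
#' The two GATA-like sequences reported for EVI1 zinc-finger binding in
#' vitro, as degenerate IUPAC strings usable with [match_iupac()].
#'
#' @return named character vector of consensus strings.
#' @export
evi1_consensus <- function() {
  c(long = "GAYAAGAYAAGATAA", short = "TGACAAGATAA")
}
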