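#' Digital footprint detection from strand-specific cut profiles
#'
#' Strand-aware binomial footprint scoring in the style of the Wellington
#' algorithm. For a candidate footprint of size `f` at a position, the
#' forward-strand evidence compares the cuts inside the footprint
#' (`F_fw`) with the cuts in the `shoulder_size`-bp window immediately
#' upstream (`S_fw`): `p_fw` is the lower binomial tail of observing at
#' most `F_fw` footprint cuts among `F_fw + S_fw` trials with success
#' probability `f / (f + shoulder_size)`. The reverse strand is scored
#' symmetrically against the downstream shoulder. The footprint score is
#' `log10 p_fw + log10 p_rev` (more negative = stronger protection). For
#' each candidate centre the best score over `fp_sizes` is kept, and
#' non-overlapping footprints are selected greedily in ascending score
#' order until `score_cutoff` is reached.
#'
#' Candidate windows (footprint plus both shoulders) must lie entirely
#' inside a region; positions where they do not are skipped. A candidate
#' with zero trials on a strand contributes `log10 p = 0` for that strand.
#'
#' @param profile a `CutProfile`.
#' @param regions merged peak set to scan within.
#' @param fp_sizes candidate footprint sizes in bp (default odd sizes
#'   11 to 25).
#' @param shoulder_size shoulder width in bp (default 35).
#' @param score_cutoff only footprints with score <= this are called
#'   (default -10).
#' @return `FootprintCalls` data.frame: chrom, start, end, footprint_size,
#'   score, fw_footprint, fw_shoulder, rev_footprint, rev_shoulder
#'   (audit counts), sorted by (chrom, start).
#' @export
wellington_scan <- function(profile, regions, fp_sizes = seq(11L, 25L, by = 2L),
                            shoulder_size = 35L, score_cutoff = -10) {
  if (length(fp_sizes) == 0L) stop("wellington_scan: fp_sizes is empty")
  if (shoulder_size <= 0L) stop("wellington_scan: shoulder_size must be > 0")
  if (!is_merged(regions)) stop("wellington_scan: regions must be sorted and merged")
  calls <- list()
  for (r in seq_len(nrow(regions))) {
    cand <- .wellington_region(profile, regions$chrom[r], regions$start[r],
                               regions$end[r], fp_sizes, shoulder_size)
    if (is.null(cand)) next
    sel <- .greedy_select(cand, score_cutoff,
                          regions$end[r] - regions$start[r])
    if (nrow(sel) > 0L) {
      sel$chrom <- regions$chrom[r]
      sel$start <- sel$start + regions$start[r]
      sel$end <- sel$end + regions$start[r]
      calls[[length(calls) + 1L]] <- sel
    }
  }
  out <- if (length(calls) > 0L) do.call(rbind, calls) else
    data.frame(start = integer(), end = integer(), footprint_size = integer(),
               score = numeric(), fw_footprint = numeric(),
               fw_shoulder = numeric(), rev_footprint = numeric(),
               rev_shoulder = numeric(), chrom = character(),
               stringsAsFactors = FALSE)
  out <- out[, c("chrom", "start", "end", "footprint_size", "score",
                 "fw_footprint", "fw_shoulder", "rev_footprint", "rev_shoulder")]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("FootprintCalls", "data.frame")
  out
}

# Candidate footprints within one region, coordinates region-relative.
.wellington_region <- function(profile, chrom, start, end, fp_sizes, shoulder) {
  w <- end - start
  if (w < min(fp_sizes) + 2L * shoulder) return(NULL)
  fw <- dense_cuts(profile, chrom, start, end, strand = "+")
  rv <- dense_cuts(profile, chrom, start, end, strand = "-")
  cf <- c(0, cumsum(fw))
  cr <- c(0, cumsum(rv))
  log10e <- 1 / log(10)
  rows <- list()
  for (f in fp_sizes) {
    if (w < f + 2L * shoulder) next
    p0 <- shoulder:(w - f - shoulder)          # candidate starts, 0-based rel
    F_fw <- cf[p0 + f + 1L] - cf[p0 + 1L]
    S_fw <- cf[p0 + 1L] - cf[p0 - shoulder + 1L]
    F_rv <- cr[p0 + f + 1L] - cr[p0 + 1L]
    S_rv <- cr[p0 + f + shoulder + 1L] - cr[p0 + f + 1L]
    prob <- f / (f + shoulder)
    lp_fw <- stats::pbinom(F_fw, F_fw + S_fw, prob, log.p = TRUE) * log10e
    lp_rv <- stats::pbinom(F_rv, F_rv + S_rv, prob, log.p = TRUE) * log10e
    lp_fw[F_fw + S_fw == 0] <- 0
    lp_rv[F_rv + S_rv == 0] <- 0
    rows[[length(rows) + 1L]] <- data.frame(
      center = p0 + f %/% 2L, start = p0, end = p0 + f,
      footprint_size = f, score = lp_fw + lp_rv,
      fw_footprint = F_fw, fw_shoulder = S_fw,
      rev_footprint = F_rv, rev_shoulder = S_rv)
  }
  if (length(rows) == 0L) return(NULL)
  cand <- do.call(rbind, rows)
  # best (most negative) score per centre; ties broken by smaller size
  cand <- cand[order(cand$center, cand$score, cand$footprint_size), , drop = FALSE]
  cand[!duplicated(cand$center), , drop = FALSE]
}

# Greedy non-overlapping selection in ascending score order.
.greedy_select <- function(cand, score_cutoff, region_width) {
  cand <- cand[cand$score <= score_cutoff, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(cand$score, cand$start), , drop = FALSE]
  occupied <- logical(region_width)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- (cand$start[i] + 1L):cand$end[i]
    if (!any(occupied[span])) {
      occupied[span] <- TRUE
      keep[i] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

#' Occupied motifs: motif hits supported by a footprint
#'
#' Retains motif hits overlapping a footprint call by at least 1 bp,
#' annotated with the best (most negative) overlapping footprint score.
#'
#' @param footprints `FootprintCalls` data.frame.
#' @param hitsets named list of `MotifHitSet` objects.
#' @return named list of `OccupiedMotif` data.frames (hit columns plus
#'   `footprint_score`).
#' @export
occupied_motifs <- function(footprints, hitsets) {
  lapply(hitsets, function(h) {
    if (nrow(h) == 0L || nrow(footprints) == 0L) {
      out <- h[integer(0), , drop = FALSE]
      out$footprint_score <- numeric(0)
      return(out)
    }
    ov <- .overlap_pairs(h, footprints)
    if (nrow(ov) == 0L) {
      out <- h[integer(0), , drop = FALSE]
      out$footprint_score <- numeric(0)
      return(out)
    }
    best <- tapply(footprints$score[ov$subject], ov$query, min)
    idx <- as.integer(names(best))
    out <- h[idx, , drop = FALSE]
    out$footprint_score <- as.numeric(best)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Bootstrap significance of occupied-motif co-clustering at anchor sites
#'
#' For each motif, the observed statistic is the number of anchor peaks
#' whose centre lies within `window_bp` of at least one occupied motif
#' (centre-to-hit-midpoint distance). The null distribution is obtained by
#' drawing `|anchors|` regions uniformly without replacement from a
#' universe of accessible regions `n_boot` times and recomputing the
#' statistic. Reported per motif: observed count, null mean and sd, the
#' z-score, and the empirical p-value `(1 + #{null >= observed}) /
#' (1 + n_boot)`.
#'
#' @param anchor_peaks merged peak set of anchor binding sites (e.g. a
#'   fusion-protein ChIP peak set).
#' @param occupied named list of occupied-motif data.frames (from
#'   [occupied_motifs()]).
#' @param universe merged peak set to resample from (the accessible-region
#'   universe; must be at least as large as the anchor set).
#' @param window_bp co-clustering window in bp (default 50).
#' @param n_boot number of bootstrap draws (default 1000).
#' @param seed integer seed making the draw sequence reproducible.
#' @return a `CooccurrenceMatrix`: data.frame with one row per motif:
#'   motif_id, observed, null_mean, null_sd, z (NA when null_sd is 0),
#'   p_empirical, n_anchors, n_boot.
#' @export
bootstrap_cooccurrence <- function(anchor_peaks, occupied, universe,
                                   window_bp = 50L, n_boot = 1000L, seed) {
  if (missing(seed)) stop("bootstrap_cooccurrence: seed is required")
  if (n_boot < 100L) stop("bootstrap_cooccurrence: n_boot must be >= 100")
  nA <- nrow(anchor_peaks)
  nU <- nrow(universe)
  if (nU < nA) stop("bootstrap_cooccurrence: universe smaller than anchor set")
  anchor_ind <- vapply(occupied, function(h)
    .near_indicator(anchor_peaks, h, window_bp), logical(nA))
  anchor_ind <- matrix(anchor_ind, nrow = nA,
                       dimnames = list(NULL, names(occupied)))
  uni_ind <- vapply(occupied, function(h)
    .near_indicator(universe, h, window_bp), logical(nU))
  uni_ind <- matrix(uni_ind, nrow = nU,
                    dimnames = list(NULL, names(occupied)))
  observed <- colSums(anchor_ind)
  set.seed(seed)
  null_counts <- matrix(0L, nrow = n_boot, ncol = ncol(uni_ind))
  for (b in seq_len(n_boot)) {
    draw <- sample.int(nU, nA, replace = FALSE)
    null_counts[b, ] <- colSums(uni_ind[draw, , drop = FALSE])
  }
  null_mean <- colMeans(null_counts)
  null_sd <- apply(null_counts, 2L, stats::sd)
  z <- ifelse(null_sd > 0, (observed - null_mean) / null_sd, NA_real_)
  p_emp <- vapply(seq_along(observed), function(i)
    (1 + sum(null_counts[, i] >= observed[i])) / (1 + n_boot), numeric(1))
  out <- data.frame(motif_id = names(occupied), observed = as.integer(observed),
                    null_mean = null_mean, null_sd = null_sd, z = z,
                    p_empirical = p_emp, n_anchors = nA, n_boot = n_boot,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("CooccurrenceMatrix", "data.frame")
  out
}

# TRUE for each region whose centre is within `window` bp of the midpoint
# of at least one hit (same chromosome).
.near_indicator <- function(regions, hits, window) {
  out <- logical(nrow(regions))
  if (nrow(hits) == 0L) return(out)
  centers <- interval_midpoint(regions)
  mids <- interval_midpoint(hits)
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    hm <- sort(mids[hits$chrom == ch])
    if (length(hm) == 0L) next
    lo <- findInterval(centers[ri] - window - 1L, hm)
    hi <- findInterval(centers[ri] + window, hm)
    out[ri] <- hi > lo
  }
  out
}
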