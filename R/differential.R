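#' Rank union regions by between-sample fold change
#'
#' Library-size normalises the per-region tag counts of the two profiles
#' (tags per `norm_to`), forms `fold_change = (b + pseudocount) /
#' (a + pseudocount)`, and records the permutation sorting regions by
#' ascending fold change (ties broken by chrom, start).
#'
#' @param union merged union peak set.
#' @param profile_a,profile_b `CutProfile` objects for the two samples.
#' @param pseudocount pseudocount added to normalised counts (default 1).
#' @param norm_to library-size scaling target (default 1e7).
#' @return a `RankedComparison`: list with `regions`, `counts_a`,
#'   `counts_b` (normalised), `fold_change`, `order` (permutation of
#'   region rows, ascending fold change).
#' @export
rank_by_fold_change <- function(union, profile_a, profile_b, pseudocount = 1,
                                norm_to = 1e7) {
  if (pseudocount <= 0) stop("rank_by_fold_change: pseudocount must be > 0")
  tm <- tag_count_matrix(union, list(a = profile_a, b = profile_b),
                         norm_to = norm_to)
  a <- unname(tm$normalized[, "a"])
  b <- unname(tm$normalized[, "b"])
  fc <- (b + pseudocount) / (a + pseudocount)
  ord <- order(fc, union$chrom, union$start)
  structure(list(regions = union, counts_a = a, counts_b = b,
                 fold_change = fc, order = ord),
            class = "RankedComparison")
}

# Bin edges (0-based offsets within a window of `width` bp) for `n_bins`
# bins of nearest-integer width; any remainder accrues to the last bin.
.bin_edges <- function(width, n_bins) {
  base <- round(width / n_bins)
  edges <- c(0L, pmin(base * seq_len(n_bins), width))
  edges[n_bins + 1L] <- width
  edges
}

#' Binned signal heatmap matrix over ranked regions
#'
#' Cut counts (both strands) in windows of `window_bp` each side of every
#' region midpoint, binned into `n_bins` columns, rows ordered by the
#' ranking of `ranked`.
#'
#' @param ranked a `RankedComparison`.
#' @param profile `CutProfile` supplying the signal.
#' @param window_bp half-window in bp (default 2000, i.e. 4-kb windows).
#' @param n_bins number of bins (default 200).
#' @return numeric matrix (regions x bins) in ranked order, with attribute
#'   `centers` (the region midpoints in ranked order).
#' @export
signal_heatmap_matrix <- function(ranked, profile, window_bp = 2000L,
                                  n_bins = 200L) {
  regions <- ranked$regions[ranked$order, , drop = FALSE]
  centers <- interval_midpoint(regions)
  width <- 2L * window_bp
  edges <- .bin_edges(width, n_bins)
  m <- matrix(0, nrow = nrow(regions), ncol = n_bins)
  for (i in seq_len(nrow(regions))) {
    s <- centers[i] - window_bp
    starts <- s + edges[-length(edges)]
    ends <- s + edges[-1L]
    m[i, ] <- window_counts(profile, regions$chrom[i],
                            pmax(starts, 0L), pmax(ends, 0L))
  }
  attr(m, "centers") <- centers
  m
}

#' Average signal profile around peaks
#'
#' Per-position cut counts (both strands) in `window_bp` each side of every
#' peak midpoint, averaged over peaks. Window positions falling outside a
#' chromosome contribute zero.
#'
#' @param peaks interval data.frame (at least one peak).
#' @param profile `CutProfile`.
#' @param window_bp half-window in bp (default 2000).
#' @return numeric vector of length `2 * window_bp` (mean cuts per peak at
#'   each window offset).
#' @export
average_profile <- function(peaks, profile, window_bp = 2000L) {
  if (nrow(peaks) == 0L) stop("average_profile: no peaks")
  centers <- interval_midpoint(peaks)
  acc <- numeric(2L * window_bp)
  for (i in seq_len(nrow(peaks))) {
    s <- centers[i] - window_bp
    e <- centers[i] + window_bp
    v <- numeric(2L * window_bp)
    cs <- max(s, 0L)
    if (cs < e) {
      v[(cs - s + 1L):(e - s)] <- dense_cuts(profile, peaks$chrom[i], cs, e)
    }
    acc <- acc + v
  }
  acc / nrow(peaks)
}

#' Motif-density tracks along ranked regions
#'
#' For each motif, a binary regions x bins occurrence matrix (bin contains
#' a hit midpoint) over `window_bp` each side of region midpoints, rows in
#' ranked order, plus a display copy smoothed by a moving average over
#' `row_smoothing` consecutive ranked rows (partial windows at the edges).
#'
#' @param ranked a `RankedComparison`.
#' @param hitsets named list of `MotifHitSet` objects.
#' @param window_bp half-window in bp (default 1000, i.e. +/- 1-kb).
#' @param n_bins number of bins (default 100).
#' @param row_smoothing moving-average window over ranked rows
#'   (default 50; 1 = no smoothing).
#' @return named list per motif: `list(occurrence, smoothed)` matrices.
#' @export
motif_density_tracks <- function(ranked, hitsets, window_bp = 1000L,
                                 n_bins = 100L, row_smoothing = 50L) {
  regions <- ranked$regions[ranked$order, , drop = FALSE]
  centers <- interval_midpoint(regions)
  width <- 2L * window_bp
  edges <- .bin_edges(width, n_bins)
  lapply(hitsets, function(h) {
    occ <- matrix(0, nrow = nrow(regions), ncol = n_bins)
    if (nrow(h) > 0L) {
      mids <- interval_midpoint(h)
      for (ch in unique(regions$chrom)) {
        ri <- which(regions$chrom == ch)
        hm <- sort(mids[h$chrom == ch])
        if (length(hm) == 0L) next
        for (i in ri) {
          s <- centers[i] - window_bp
          sel <- hm[hm >= s & hm < centers[i] + window_bp] - s
          if (length(sel) > 0L) {
            bins <- findInterval(sel, edges, rightmost.closed = FALSE)
            bins <- pmin(bins, n_bins)
            occ[i, unique(bins)] <- 1
          }
        }
      }
    }
    list(occurrence = occ, smoothed = .row_smooth(occ, row_smoothing))
  })
}

# Column-wise moving average over `k` consecutive rows, partial at edges.
.row_smooth <- function(m, k) {
  if (k <= 1L || nrow(m) <= 1L) return(m)
  n <- nrow(m)
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k %/% 2L
  cs <- rbind(0, apply(m, 2L, cumsum))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

#' Classify accessibility changes into lost / shared / gained groups
#'
#' On library-size-normalised counts with pseudocount, a region is `lost`
#' when control/knockdown fold >= `fold_threshold`, `gained` when
#' knockdown/control fold >= `fold_threshold`, else `shared`. The three
#' groups partition the union; swapping the two conditions swaps lost and
#' gained exactly.
#'
#' @param union merged union peak set.
#' @param profile_control,profile_kd `CutProfile` objects, or numeric
#'   vectors of pre-normalised per-region counts.
#' @param fold_threshold group boundary fold (default 2, > 1).
#' @param pseudocount pseudocount on normalised counts (default 1).
#' @return `ChangeGroups` data.frame: region columns plus `count_control`,
#'   `count_kd`, `group` (factor lost/shared/gained).
#' @export
classify_dhs_groups <- function(union, profile_control, profile_kd,
                                fold_threshold = 2, pseudocount = 1) {
  if (fold_threshold <= 1) stop("classify_dhs_groups: fold_threshold must be > 1")
  if (inherits(profile_control, "CutProfile")) {
    tm <- tag_count_matrix(union, list(control = profile_control,
                                       kd = profile_kd))
    ctrl <- tm$normalized[, "control"]
    kd <- tm$normalized[, "kd"]
  } else {
    ctrl <- profile_control
    kd <- profile_kd
  }
  lost <- (ctrl + pseudocount) / (kd + pseudocount) >= fold_threshold
  gained <- (kd + pseudocount) / (ctrl + pseudocount) >= fold_threshold
  group <- rep("shared", nrow(union))
  group[lost] <- "lost"
  group[gained] <- "gained"
  out <- union[, c("chrom", "start", "end")]
  out$count_control <- ctrl
  out$count_kd <- kd
  out$group <- factor(group, levels = c("lost", "shared", "gained"))
  class(out) <- c("ChangeGroups", "data.frame")
  out
}

#' Construct an expression table
#'
#' @param fpkm genes x samples numeric matrix of FPKM values (unique
#'   rownames = gene ids).
#' @param sample_info data.frame with columns `sample`, `condition`,
#'   `timepoint` (one row per column of `fpkm`; replicates share a
#'   condition/timepoint pair).
#' @return an `ExpressionTable` list.
#' @export
expression_table <- function(fpkm, sample_info) {
  fpkm <- as.matrix(fpkm)
  stopifnot(all(c("sample", "condition", "timepoint") %in% names(sample_info)),
            identical(colnames(fpkm), as.character(sample_info$sample)))
  if (any(fpkm < 0)) stop("expression_table: negative FPKM")
  if (anyDuplicated(rownames(fpkm))) stop("expression_table: duplicate gene ids")
  structure(list(fpkm = fpkm, sample_info = sample_info),
            class = "ExpressionTable")
}

#' Differentially expressed genes over a knockdown time course
#'
#' Replicate FPKM values are averaged per (condition, timepoint); the
#' per-timepoint fold change is `(treated + pseudocount) / (control +
#' pseudocount)`. A gene qualifies when `|log2 FC| >= log2(fold_threshold)`
#' at one or more timepoints (closed boundary: FC exactly at the threshold
#' is included). Qualifying genes' log2 FC profiles are clustered
#' (average linkage, Euclidean) for heatmap display.
#'
#' @param expr an `ExpressionTable`.
#' @param fold_threshold DE threshold (default 1.5).
#' @param control_label value of `sample_info$condition` marking control
#'   samples (default `"control"`); all other conditions are "treated".
#' @param pseudocount added to averaged FPKM before the ratio
#'   (default 0.01).
#' @return list with `table` (per-gene data.frame: gene, log2 FC per
#'   timepoint, `max_abs_log2fc`, `direction`, `qualifies`), `genes`
#'   (qualifying gene ids), `fold_changes` (genes x timepoints log2 FC
#'   matrix), `clustering` (`hclust` of qualifying genes, `NULL` if < 2).
#' @export
de_genes <- function(expr, fold_threshold = 1.5, control_label = "control",
                     pseudocount = 0.01) {
  info <- expr$sample_info
  tps <- sort(unique(info$timepoint))
  is_ctrl <- info$condition == control_label
  if (!any(is_ctrl)) stop("de_genes: no control samples (condition '",
                          control_label, "')")
  l2fc <- matrix(NA_real_, nrow = nrow(expr$fpkm), ncol = length(tps),
                 dimnames = list(rownames(expr$fpkm), paste0("t", tps)))
  for (i in seq_along(tps)) {
    ci <- which(is_ctrl & info$timepoint == tps[i])
    ti <- which(!is_ctrl & info$timepoint == tps[i])
    if (length(ci) == 0L) stop("de_genes: missing control column at timepoint ",
                               tps[i])
    if (length(ti) == 0L) stop("de_genes: missing treated column at timepoint ",
                               tps[i])
    ctrl <- rowMeans(expr$fpkm[, ci, drop = FALSE])
    trt <- rowMeans(expr$fpkm[, ti, drop = FALSE])
    l2fc[, i] <- log2((trt + pseudocount) / (ctrl + pseudocount))
  }
  max_abs <- apply(abs(l2fc), 1L, max)
  qualifies <- max_abs >= log2(fold_threshold) - 1e-12
  peak_tp <- apply(abs(l2fc), 1L, which.max)
  direction <- ifelse(l2fc[cbind(seq_len(nrow(l2fc)), peak_tp)] >= 0, "up", "down")
  tab <- data.frame(gene = rownames(expr$fpkm), l2fc,
                    max_abs_log2fc = max_abs, direction = direction,
                    qualifies = qualifies, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  genes <- tab$gene[tab$qualifies]
  clustering <- if (length(genes) >= 2L) {
    stats::hclust(stats::dist(l2fc[genes, , drop = FALSE]), method = "average")
  } else NULL
  list(table = tab, genes = genes, fold_changes = l2fc, clustering = clustering)
}

#' Fraction of differentially expressed genes that are ChIP targets
#'
#' A gene is a ChIP target when at least one peak is assigned to it by the
#' nearest-TSS rule within `assignment_window` bp of the TSS.
#'
#' @param genes character vector of DE gene ids (or the list returned by
#'   [de_genes()], from which `$genes` is taken).
#' @param chip_peaks interval data.frame of ChIP peaks.
#' @param tss_table BED6-style gene table.
#' @param assignment_window maximum peak-to-TSS distance in bp
#'   (default 50000).
#' @return `TargetOverlap` data.frame: `n_de`, `n_de_targets`, `fraction`
#'   (`NA` with `undefined = TRUE` when the DE set is empty).
#' @export
target_overlap_fraction <- function(genes, chip_peaks, tss_table,
                                    assignment_window = 50000L) {
  if (is.list(genes) && !is.null(genes$genes)) genes <- genes$genes
  n_de <- length(genes)
  if (n_de == 0L) {
    return(data.frame(n_de = 0L, n_de_targets = 0L, fraction = NA_real_,
                      undefined = TRUE))
  }
  targets <- character(0)
  if (nrow(chip_peaks) > 0L) {
    ng <- nearest_gene(chip_peaks, tss_table)
    targets <- unique(ng$gene[abs(ng$distance) <= assignment_window])
  }
  n_hit <- sum(genes %in% targets)
  data.frame(n_de = n_de, n_de_targets = n_hit, fraction = n_hit / n_de,
             undefined = FALSE)
}

#' Nearest-gene expression ratio track for ranked regions
#'
#' The per-region expression ratio `(FPKM_a + pseudocount) / (FPKM_b +
#' pseudocount)` of the gene nearest each region, in ranked order — the
#' expression sidebar of a ranked accessibility heatmap.
#'
#' @param ranked a `RankedComparison`.
#' @param tss_table BED6-style gene table.
#' @param fpkm_a,fpkm_b named numeric vectors of FPKM per gene.
#' @param pseudocount added to both FPKM values (default 0.01).
#' @return data.frame in ranked order: `gene`, `ratio`.
#' @export
nearest_gene_expression_ratio <- function(ranked, tss_table, fpkm_a, fpkm_b,
                                          pseudocount = 0.01) {
  regions <- ranked$regions[ranked$order, , drop = FALSE]
  ng <- nearest_gene(regions, tss_table)
  a <- fpkm_a[ng$gene]
  b <- fpkm_b[ng$gene]
  data.frame(gene = ng$gene,
             ratio = (unname(a) + pseudocount) / (unname(b) + pseudocount),
             stringsAsFactors = FALSE)
}
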