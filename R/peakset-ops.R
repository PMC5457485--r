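#' Overlap analysis of two or three peak sets
#'
#' Computes the merged union of the inputs and assigns every union region
#' the subset of input sets overlapping it by at least 1 bp — the numbers
#' behind a Venn diagram of peak sets. Also reports, for every ordered pair
#' of sets, the fraction of the first set's own peaks that overlap the
#' second set.
#'
#' @param peaksets named list of 2 or 3 merged peak sets (see
#'   [sort_and_merge()]); list names are the set labels (falling back to the
#'   peak sets' `label` attributes).
#' @return an `OverlapSummary`: list with `set_labels`, `union` (merged
#'   union `PeakSet`), `membership` (logical union-regions x sets matrix),
#'   `region_counts` (named count per non-empty subset, names like
#'   `"A&B"`), and `fractions` (k x k matrix; entry `[i, j]` is the
#'   fraction of set i's peaks overlapping set j).
#' @export
overlap_counts <- function(peaksets) {
  k <- length(peaksets)
  if (k < 2L || k > 3L) {
    stop("overlap_counts: 2 or 3 peak sets supported, got ", k)
  }
  labels <- names(peaksets)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(seq_len(k), function(i) {
      lb <- attr(peaksets[[i]], "label")
      if (is.null(lb)) paste0("set", i) else lb
    }, character(1))
  }
  if (anyDuplicated(labels)) stop("overlap_counts: duplicate set labels")
  for (i in seq_len(k)) {
    if (!is_merged(peaksets[[i]])) {
      stop("overlap_counts: input '", labels[i], "' is not sorted and merged")
    }
  }
  union_set <- sort_and_merge(do.call(rbind, lapply(peaksets, function(p)
    p[, c("chrom", "start", "end")])))
  n_union <- nrow(union_set)
  membership <- matrix(FALSE, nrow = n_union, ncol = k,
                       dimnames = list(NULL, labels))
  for (i in seq_len(k)) {
    ov <- .overlap_pairs(union_set, peaksets[[i]])
    membership[unique(ov$query), i] <- TRUE
  }
  # subset keys use lexicographic label order so relabelled inputs agree
  subset_key <- apply(membership, 1L, function(m)
    paste(sort(labels[m]), collapse = "&"))
  all_subsets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(sort(labels), m, paste, collapse = "&", simplify = FALSE)))
  region_counts <- stats::setNames(integer(length(all_subsets)), all_subsets)
  tab <- table(subset_key)
  region_counts[names(tab)] <- as.integer(tab)
  fractions <- matrix(1, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      ov <- .overlap_pairs(peaksets[[i]], peaksets[[j]])
      fractions[i, j] <- if (nrow(peaksets[[i]]) == 0L) NA_real_ else
        length(unique(ov$query)) / nrow(peaksets[[i]])
    }
  }
  structure(list(set_labels = labels, union = union_set,
                 membership = membership, region_counts = region_counts,
                 fractions = fractions),
            class = "OverlapSummary")
}

#' Tag-count matrix over a union peak set
#'
#' Entry (r, s) is the number of cut 5' ends of sample s (both strands)
#' falling inside union region r. A per-sample library-size normalised
#' matrix (tags per `norm_to` total cuts) is stored alongside the raw
#' counts.
#'
#' @param union merged union `PeakSet`.
#' @param profiles named list of `CutProfile` objects (names are sample
#'   labels).
#' @param norm_to library size the normalised counts are scaled to
#'   (default 1e7, i.e. tags per 10 million).
#' @return a `SampleCountMatrix`: list with `regions`, `counts` (raw),
#'   `normalized`, `samples`.
#' @export
tag_count_matrix <- function(union, profiles, norm_to = 1e7) {
  if (nrow(union) == 0L) stop("tag_count_matrix: empty union peak set")
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    stop("tag_count_matrix: profiles must be named by sample")
  }
  counts <- matrix(0, nrow = nrow(union), ncol = length(profiles),
                   dimnames = list(NULL, names(profiles)))
  for (s in seq_along(profiles)) {
    for (ch in unique(union$chrom)) {
      idx <- which(union$chrom == ch)
      counts[idx, s] <- window_counts(profiles[[s]], ch,
                                      union$start[idx], union$end[idx])
    }
  }
  totals <- vapply(profiles, `[[`, numeric(1), "total_cuts")
  if (any(totals == 0)) {
    normalized <- counts * NA_real_
  } else {
    normalized <- sweep(counts, 2L, totals, "/") * norm_to
  }
  structure(list(regions = union, counts = counts, normalized = normalized,
                 samples = names(profiles)),
            class = "SampleCountMatrix")
}

#' Correlation clustering of samples
#'
#' Pearson correlation of `log2(normalised count + 1)` columns, followed by
#' average-linkage hierarchical clustering on distance `1 - r`. Samples are
#' ordered lexicographically before clustering so that leaf order is
#' deterministic under ties.
#'
#' @param matrix a `SampleCountMatrix` (from [tag_count_matrix()]) or a
#'   plain regions x samples numeric matrix of normalised counts.
#' @return a `CorrelationClustering`: list with `correlation` (samples x
#'   samples), `linkage` (an `hclust` object), `order` (leaf labels in
#'   dendrogram order).
#' @export
correlation_cluster <- function(matrix) {
  m <- if (inherits(matrix, "SampleCountMatrix")) matrix$normalized else as.matrix(matrix)
  if (ncol(m) < 2L) stop("correlation_cluster: need >= 2 samples")
  if (nrow(m) < 2L) stop("correlation_cluster: need >= 2 regions")
  m <- m[, order(colnames(m)), drop = FALSE]
  lm <- log2(m + 1)
  sds <- apply(lm, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("correlation_cluster: zero variance in sample '",
         colnames(m)[which(sds == 0)[1L]], "'")
  }
  r <- stats::cor(lm, method = "pearson")
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  structure(list(correlation = r, linkage = hc,
                 order = colnames(r)[hc$order]),
            class = "CorrelationClustering")
}

# TSS positions of a BED6-style gene table: start for '+' genes, end - 1
# for '-' genes (0-based); unstranded entries use start.
.tss_positions <- function(tss_table) {
  strand <- tss_table$strand
  if (is.null(strand)) strand <- rep(".", nrow(tss_table))
  ifelse(!is.na(strand) & strand == "-", tss_table$end - 1L, tss_table$start)
}

#' Classify peaks as promoter, intragenic, or distal
#'
#' A peak is `promoter` if its midpoint lies within `promoter_halfwidth` of
#' any TSS, else `intragenic` if the midpoint falls inside any gene body
#' span of the table, else `distal`.
#'
#' @param peaks interval data.frame.
#' @param tss_table BED6-style gene table (name = gene symbol; the interval
#'   is the gene body; TSS = strand-aware 5' end).
#' @param promoter_halfwidth promoter window half-width in bp
#'   (default 1500).
#' @return character vector of class labels, one per peak.
#' @export
annotate_region_class <- function(peaks, tss_table, promoter_halfwidth = 1500L) {
  if (nrow(tss_table) == 0L) stop("annotate_region_class: empty TSS table")
  mid <- interval_midpoint(peaks)
  tss <- .tss_positions(tss_table)
  out <- rep("distal", nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    gi <- which(tss_table$chrom == ch)
    if (length(gi) == 0L) next
    stss <- sort(tss[gi])
    # distance from each midpoint to the nearest TSS via sorted neighbours
    pos <- mid[pi]
    idx <- findInterval(pos, stss)
    left <- ifelse(idx >= 1L, abs(pos - stss[pmax(idx, 1L)]), Inf)
    right <- ifelse(idx < length(stss), abs(stss[pmin(idx + 1L, length(stss))] - pos), Inf)
    near <- pmin(left, right)
    out[pi[near <= promoter_halfwidth]] <- "promoter"
    rest <- pi[near > promoter_halfwidth]
    if (length(rest) > 0L) {
      bodies <- tss_table[gi, , drop = FALSE]
      pts <- data.frame(chrom = ch, start = mid[rest], end = mid[rest] + 1L)
      ov <- .overlap_pairs(pts, bodies)
      out[rest[unique(ov$query)]] <- "intragenic"
    }
  }
  out
}

#' Assign each peak its nearest gene
#'
#' Nearest TSS by absolute distance from the peak midpoint; ties broken by
#' lexicographically smaller gene name. The reported distance is signed by
#' gene orientation: positive when the peak lies downstream of the TSS
#' (in the gene's direction of transcription).
#'
#' @param peaks interval data.frame.
#' @param tss_table BED6-style gene table (name = gene symbol).
#' @return data.frame with columns `gene`, `distance` (signed; `Inf` with
#'   gene `"none"` when the peak's chromosome has no genes).
#' @export
nearest_gene <- function(peaks, tss_table) {
  if (nrow(tss_table) == 0L) stop("nearest_gene: empty TSS table")
  mid <- interval_midpoint(peaks)
  tss <- .tss_positions(tss_table)
  gene <- rep("none", nrow(peaks))
  distance <- rep(Inf, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    gi <- which(tss_table$chrom == ch)
    if (length(gi) == 0L) next
    # order genes by (TSS, name) so that among equidistant candidates the
    # lexicographically smaller name wins deterministically
    for (p in pi) {
      d_abs <- abs(mid[p] - tss[gi])
      best <- min(d_abs)
      cand <- gi[d_abs == best]
      nm <- tss_table$name[cand]
      pick <- cand[order(nm)][1L]
      gene[p] <- tss_table$name[pick]
      sgn <- if (!is.na(tss_table$strand[pick]) && tss_table$strand[pick] == "-")
        tss[pick] - mid[p] else mid[p] - tss[pick]
      distance[p] <- sgn
    }
  }
  data.frame(gene = gene, distance = distance, stringsAsFactors = FALSE)
}
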