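# Hypergeometric enrichment of motif presence in a target subset of a
# union peak population. Shared by the unique-vs-union and shared-peak
# entry points.
#
# target_idx: indices (rows of `union_peaks`) forming the target set.
# presence:   logical union-regions x motifs matrix.
.hyper_enrichment <- function(target_idx, presence, comparison_id) {
  N <- nrow(presence)
  n <- length(target_idx)
  motifs <- colnames(presence)
  res <- lapply(motifs, function(m) {
    K <- sum(presence[, m])
    k <- sum(presence[target_idx, m])
    undefined <- n == 0L
    if (undefined) {
      fold <- NA_real_; p_over <- NA_real_; p_under <- NA_real_; score <- NA_real_
    } else {
      fold <- if (K == 0L) NA_real_ else (k / n) / (K / N)
      p_over <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      p_under <- stats::phyper(k, K, N - K, n, lower.tail = TRUE)
      over <- is.na(fold) || fold >= 1
      score <- if (over) -log10(max(p_over, 1e-300)) else log10(max(p_under, 1e-300))
    }
    data.frame(motif_id = m, comparison_id = comparison_id,
               n_target = n, k_target = if (undefined) NA_integer_ else k,
               n_background = N, k_background = K,
               fold = fold, p_value = p_over, p_under = p_under,
               log10_enrichment_score = score, undefined = undefined,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- if (all(is.na(out$p_value))) NA_real_ else
    stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

# Presence matrix (union regions x motifs) from a named list of hit sets.
.presence_matrix <- function(union_peaks, hitsets) {
  if (is.null(names(hitsets)) || any(!nzchar(names(hitsets)))) {
    stop("enrichment: hitsets must be a named list (names = motif ids)")
  }
  pres <- vapply(hitsets, function(h) hits_in_peaks(h, union_peaks)$presence,
                 logical(nrow(union_peaks)))
  pres <- matrix(pres, nrow = nrow(union_peaks),
                 dimnames = list(NULL, names(hitsets)))
  pres
}

#' Unique-versus-union motif enrichment between two peak sets
#'
#' For a pair of cistromes, identifies the union regions supported by only
#' one input ("unique" peaks) and scores each motif's enrichment in each
#' unique set against the union of the pair: a hypergeometric test of
#' motif-containing peak counts, drawing the unique peaks from the union
#' population. The signed score is `-log10 p` of the over-representation
#' tail when the motif is enriched (fold >= 1) and `log10 p` of the
#' under-representation tail (negative) when depleted.
#'
#' @param setA,setB merged peak sets (labels from their `label` attribute,
#'   falling back to `"A"`/`"B"`).
#' @param hitsets named list of `MotifHitSet` objects.
#' @return `EnrichmentResult` data.frame with one row per (motif,
#'   comparison), comparisons labelled `"<A>_unique"` and `"<B>_unique"`.
#'   Columns: motif_id, comparison_id, n_target, k_target, n_background,
#'   k_background, fold, p_value (over-representation tail), p_under,
#'   log10_enrichment_score, undefined, q_value (BH across motifs within a
#'   comparison).
#' @export
unique_vs_union_enrichment <- function(setA, setB, hitsets) {
  la <- attr(setA, "label"); if (is.null(la)) la <- "A"
  lb <- attr(setB, "label"); if (is.null(lb)) lb <- "B"
  ov <- overlap_counts(stats::setNames(list(setA, setB), c(la, lb)))
  pres <- .presence_matrix(ov$union, hitsets)
  uniqA <- which(ov$membership[, la] & !ov$membership[, lb])
  uniqB <- which(ov$membership[, lb] & !ov$membership[, la])
  rbind(.hyper_enrichment(uniqA, pres, paste0(la, "_unique")),
        .hyper_enrichment(uniqB, pres, paste0(lb, "_unique")))
}

#' Motif enrichment in peaks shared by all input sets
#'
#' Target = union regions supported by every input (2 or 3 sets);
#' background = the union. Same statistic as
#' [unique_vs_union_enrichment()].
#'
#' @param peaksets named list of 2 or 3 merged peak sets.
#' @param hitsets named list of `MotifHitSet` objects.
#' @return `EnrichmentResult` data.frame (comparison labelled
#'   `"<labels>_shared"`).
#' @export
shared_peak_enrichment <- function(peaksets, hitsets) {
  ov <- overlap_counts(peaksets)
  pres <- .presence_matrix(ov$union, hitsets)
  shared <- which(rowSums(ov$membership) == length(peaksets))
  .hyper_enrichment(shared, pres,
                    paste0(paste(ov$set_labels, collapse = "&"), "_shared"))
}

#' Clustered motif-enrichment score matrix
#'
#' Pivots enrichment results into a motifs x comparisons matrix of signed
#' `log10` enrichment scores and clusters both dimensions (average linkage,
#' Euclidean distance). Rows and columns are sorted lexicographically
#' before clustering so tie-breaking is deterministic.
#'
#' @param results `EnrichmentResult` data.frame (rows for several
#'   comparisons).
#' @return an `EnrichmentMatrix`: list with `matrix`, `row_linkage`,
#'   `col_linkage` (`hclust` objects; `NULL` when that dimension has < 2
#'   entries), `row_order`, `col_order` (labels in dendrogram order).
#' @export
enrichment_matrix_cluster <- function(results) {
  motifs <- sort(unique(results$motif_id))
  comps <- sort(unique(results$comparison_id))
  if (length(motifs) < 2L || length(comps) < 2L) {
    stop("enrichment_matrix_cluster: need >= 2 motifs and >= 2 comparisons")
  }
  m <- matrix(0, nrow = length(motifs), ncol = length(comps),
              dimnames = list(motifs, comps))
  m[cbind(match(results$motif_id, motifs),
          match(results$comparison_id, comps))] <- results$log10_enrichment_score
  if (anyNA(m)) m[is.na(m)] <- 0
  row_hc <- stats::hclust(stats::dist(m), method = "average")
  col_hc <- stats::hclust(stats::dist(t(m)), method = "average")
  structure(list(matrix = m,
                 row_linkage = row_hc, col_linkage = col_hc,
                 row_order = motifs[row_hc$order],
                 col_order = comps[col_hc$order]),
            class = "EnrichmentMatrix")
}
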