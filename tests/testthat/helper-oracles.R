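# Brute-force oracles, kept deliberately independent of the package's
# implementation paths: per-base boolean masks for interval algebra,
# exhaustive per-window loops for motif scanning, and log-space
# combinatorial sums for the hypergeometric tail.

random_intervals <- function(n, chroms = c("chrA", "chrB"), max_pos = 5000L,
                             max_width = 200L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  intervals(chrom = sample(chroms, n, replace = TRUE),
            start = start, end = start + width)
}

# Union of intervals computed on a per-base boolean mask.
mask_merge_oracle <- function(df, mask_len = 6000L) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    mask <- logical(mask_len)
    sub <- df[df$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      mask[(sub$start[i] + 1L):sub$end[i]] <- TRUE
    }
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                            end = ends[keep], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Subset membership of each mask-derived union region: which input sets
# cover >= 1 bp of it.
mask_subset_oracle <- function(peaksets, mask_len = 6000L) {
  union <- mask_merge_oracle(do.call(rbind, lapply(peaksets, function(p)
    p[, c("chrom", "start", "end")])), mask_len)
  labels <- names(peaksets)
  member <- sapply(labels, function(lb) {
    p <- peaksets[[lb]]
    vapply(seq_len(nrow(union)), function(i) {
      sub <- p[p$chrom == union$chrom[i], , drop = FALSE]
      any(sub$start < union$end[i] & sub$end > union$start[i])
    }, logical(1))
  })
  key <- apply(matrix(member, ncol = length(labels)), 1L, function(m)
    paste(labels[m], collapse = "&"))
  table(key)
}

# Exhaustive per-window, per-strand PWM scan on one sequence string.
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

scan_oracle <- function(seq, pwm_obj, rel_threshold) {
  probs <- pwm_obj$probabilities
  bg <- pwm_obj$background
  L <- ncol(probs)
  score_word <- function(word) {
    bases <- strsplit(word, "")[[1]]
    if (any(!bases %in% c("A", "C", "G", "T"))) return(NA_real_)
    sum(vapply(seq_len(L), function(j)
      log2(probs[bases[j], j] / bg[match(bases[j], c("A", "C", "G", "T"))]),
      numeric(1)))
  }
  mx <- sum(apply(log2(probs / bg), 2, max))
  mn <- sum(apply(log2(probs / bg), 2, min))
  thr <- rel_threshold * (mx - mn) + mn
  hits <- list()
  for (i in seq_len(nchar(seq) - L + 1L)) {
    word <- substr(seq, i, i + L - 1L)
    sc_f <- score_word(word)
    if (!is.na(sc_f) && sc_f >= thr) {
      hits[[length(hits) + 1L]] <- data.frame(start = i - 1L, strand = "+",
                                              score = sc_f)
    }
    sc_r <- score_word(revcomp(word))
    if (!is.na(sc_r) && sc_r >= thr) {
      hits[[length(hits) + 1L]] <- data.frame(start = i - 1L, strand = "-",
                                              score = sc_r)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), strand = character(),
                      score = numeric()))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# Sliding-window degenerate matcher using explicit IUPAC sets.
iupac_oracle <- function(seq, consensus) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cl <- strsplit(consensus, "")[[1]]
  rc <- rev(vapply(cl, function(x) {
    opts <- sets[[x]]
    rc_opts <- unname(comp[opts])
    names(sets)[vapply(sets, function(s) setequal(s, rc_opts), logical(1))][1]
  }, character(1)))
  matches_at <- function(letters, pat) {
    vapply(seq_along(pat), function(j) letters[j] %in% sets[[pat[j]]],
           logical(1))
  }
  L <- length(cl)
  sl <- strsplit(seq, "")[[1]]
  hits <- list()
  for (i in seq_len(length(sl) - L + 1L)) {
    w <- sl[i:(i + L - 1L)]
    if (all(matches_at(w, cl))) {
      hits[[length(hits) + 1L]] <- data.frame(start = i - 1L, strand = "+")
    }
    if (all(matches_at(w, rc))) {
      hits[[length(hits) + 1L]] <- data.frame(start = i - 1L, strand = "-")
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), strand = character()))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# Hypergeometric upper tail P(X >= k) by direct log-space summation of
# combinatorial terms (independent of stats::phyper).
hyper_tail_oracle <- function(k, K, N, n) {
  if (k > min(K, n)) return(0)
  terms <- vapply(k:min(K, n), function(x)
    exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)), numeric(1))
  sum(terms)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Near-consensus count matrix used to build toy PWMs in tests.
.consensus_counts_test <- function(word) {
  bases <- strsplit(word, "")[[1]]
  counts <- matrix(3, nrow = 4, ncol = length(bases),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(match(bases, rownames(counts)), seq_along(bases))] <- 91
  counts
}

# Random sequence guaranteed not to contain `word` or its reverse complement.
random_seq_without <- function(n, word) {
  repeat {
    s <- random_seq(n)
    if (!grepl(word, s, fixed = TRUE) && !grepl(revcomp(word), s, fixed = TRUE))
      return(s)
  }
}

# Small planted two-condition dataset shared by several test files.
small_planted <- function(seed = 26, n_peaks = 200, chrom_length = 200000L) {
  d <- synthetic_design(seed = seed, n_peaks = n_peaks,
                        chrom_length = chrom_length)
  g <- simulate_genome(d)
  list(design = d, planted = plant_peaks_and_motifs(d, g))
}
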