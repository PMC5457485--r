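# Builds a cut profile from explicit per-position counts on one chromosome.
profile_from_counts <- function(fw_pos, rv_pos, len = 10000L) {
  cuts <- rbind(
    if (length(fw_pos)) data.frame(chrom = "c", pos = fw_pos, strand = "+"),
    if (length(rv_pos)) data.frame(chrom = "c", pos = rv_pos, strand = "-"))
  cut_profile(cuts, data.frame(chrom = "c", length = len))
}

test_that("footprint score matches the closed-form binomial endpoint", {
  # region exactly one candidate wide: f = 11, shoulder = 35, width 81;
  # 50 forward cuts in the upstream shoulder, 50 reverse in the downstream,
  # zero cuts in the footprint
  fw <- rep(0:34, length.out = 50)           # upstream shoulder [0, 35)
  rv <- rep(46:80, length.out = 50)          # downstream shoulder [46, 81)
  prof <- profile_from_counts(fw, rv, len = 100L)
  region <- sort_and_merge(intervals("c", 0, 81))
  calls <- wellington_scan(prof, region, fp_sizes = 11L, shoulder_size = 35L,
                           score_cutoff = -5)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$score, 2 * 50 * log10(35 / 46), tolerance = 1e-12)
  expect_equal(calls$fw_footprint, 0)
  expect_equal(calls$fw_shoulder, 50)
  expect_equal(calls$start, 35L)
  expect_equal(calls$end, 46L)
})

test_that("uniform cut density produces no footprint calls at cutoff -10", {
  set.seed(160)
  pos <- rep(0:999, each = 2)                # 2 cuts at every base
  prof <- profile_from_counts(pos, pos, len = 1000L)
  region <- sort_and_merge(intervals("c", 0, 1000))
  calls <- wellington_scan(prof, region, score_cutoff = -10)
  expect_equal(nrow(calls), 0L)
})

test_that("scores are invariant under strand-and-orientation reversal", {
  set.seed(161)
  len <- 400L
  fw <- sample.int(len, 300, replace = TRUE) - 1L
  rv <- sample.int(len, 300, replace = TRUE) - 1L
  prof <- profile_from_counts(fw, rv, len = len)
  # mirror the coordinate axis and swap strands
  prof_m <- profile_from_counts(len - 1L - rv, len - 1L - fw, len = len)
  region <- sort_and_merge(intervals("c", 0, len))
  calls <- wellington_scan(prof, region, score_cutoff = 0)
  calls_m <- wellington_scan(prof_m, region, score_cutoff = 0)
  expect_equal(sort(calls$score), sort(calls_m$score), tolerance = 1e-10)
})

test_that("planted footprints are recovered with high sensitivity and low FDR", {
  d <- synthetic_design(seed = 16, n_peaks = 20, chrom_length = 50000L,
                        shared_fraction = 0,
                        motif_assignments = list(cond1_unique = "GATA",
                                                 cond2_unique = "CEBP",
                                                 shared = character(0)),
                        footprint_occupancy_rate = 1)
  g <- simulate_genome(d)
  p <- plant_peaks_and_motifs(d, g)
  prof <- simulate_cuts(d, p, "cond1")
  truth <- p$motif_truth[p$motif_truth$group == "cond1", ]
  expect_equal(nrow(truth), 20L)
  calls <- wellington_scan(prof, p$peaks_cond1)
  hit <- chromcompare:::.overlap_pairs(truth, calls)
  sens <- length(unique(hit$query)) / nrow(truth)
  fdr <- 1 - length(unique(hit$subject)) / nrow(calls)
  expect_gte(sens, 0.8)
  expect_lte(fdr, 0.2)
})

test_that("occupied_motifs keeps hits overlapping footprints by >= 1 bp", {
  hits <- structure(data.frame(motif_id = "m", chrom = "c",
                               start = c(10, 50, 99), end = c(20, 60, 109),
                               strand = "+", score = 1),
                    class = c("MotifHitSet", "data.frame"))
  fps <- structure(data.frame(chrom = "c", start = c(15, 100),
                              end = c(30, 120), footprint_size = 15L,
                              score = c(-12, -20), fw_footprint = 0,
                              fw_shoulder = 0, rev_footprint = 0,
                              rev_shoulder = 0),
                   class = c("FootprintCalls", "data.frame"))
  occ <- occupied_motifs(fps, list(m = hits))$m
  expect_equal(occ$start, c(10, 99))
  expect_equal(occ$footprint_score, c(-12, -20))
  none <- occupied_motifs(fps[0, ], list(m = hits))$m
  expect_equal(nrow(none), 0L)

  set.seed(17)
  starts <- sample.int(5000L, 200L) - 1L
  hits <- structure(data.frame(motif_id = "m", chrom = "c", start = starts,
                               end = starts + 10L, strand = "+", score = 1),
                    class = c("MotifHitSet", "data.frame"))
  fstart <- sample.int(5000L, 40L) - 1L
  fps <- structure(data.frame(chrom = "c", start = fstart, end = fstart + 15L,
                              footprint_size = 15L, score = -15,
                              fw_footprint = 0, fw_shoulder = 0,
                              rev_footprint = 0, rev_shoulder = 0),
                   class = c("FootprintCalls", "data.frame"))
  occ <- occupied_motifs(fps, list(m = hits))$m
  direct <- vapply(seq_len(nrow(hits)), function(i)
    any(hits$start[i] < fps$end & hits$end[i] > fps$start), logical(1))
  expect_equal(sort(occ$start), sort(hits$start[direct]))
})

test_that("bootstrap co-occurrence handles the degenerate universe and plants", {
  uni <- sort_and_merge(intervals("c", seq(0, by = 1000, length.out = 50),
                                  seq(0, by = 1000, length.out = 50) + 200))
  ctr <- interval_midpoint(uni)
  occ <- list(m = data.frame(motif_id = "m", chrom = "c", start = ctr[1:10],
                             end = ctr[1:10] + 1L, strand = "+", score = 0,
                             footprint_score = -10))
  # anchors identical to universe: every draw reproduces the anchors
  cm <- bootstrap_cooccurrence(uni, occ, uni, window_bp = 50, n_boot = 100,
                               seed = 5)
  expect_equal(cm$null_sd, 0)
  expect_true(is.na(cm$z))
  expect_equal(cm$p_empirical, 1)
  expect_error(bootstrap_cooccurrence(uni, occ, uni[1:10, ], n_boot = 100,
                                      seed = 5),
               "universe smaller")
  expect_error(bootstrap_cooccurrence(uni, occ, uni, n_boot = 10, seed = 5),
               "n_boot")

  # planted co-occurrence: motif near 60% of anchors vs 10% of the rest
  set.seed(18)
  uni <- sort_and_merge(intervals("c", seq(0, by = 1000, length.out = 400),
                                  seq(0, by = 1000, length.out = 400) + 200))
  anchor_rows <- sort(sample.int(400, 100))
  anchors <- sort_and_merge(uni[anchor_rows, ])
  ctr <- interval_midpoint(uni)
  p_hit <- ifelse(seq_len(400) %in% anchor_rows, 0.6, 0.1)
  sel <- which(runif(400) < p_hit)
  occ <- list(planted = data.frame(motif_id = "p", chrom = "c",
                                   start = ctr[sel], end = ctr[sel] + 1L,
                                   strand = "+", score = 0,
                                   footprint_score = -10))
  cm <- bootstrap_cooccurrence(anchors, occ, uni, window_bp = 50,
                               n_boot = 500, seed = 18)
  expect_gt(cm$z, 3)
  expect_lt(cm$p_empirical, 0.05)
})

test_that("bootstrap draws are reproducible from the seed", {
  uni <- sort_and_merge(intervals("c", seq(0, by = 500, length.out = 60),
                                  seq(0, by = 500, length.out = 60) + 100))
  ctr <- interval_midpoint(uni)
  occ <- list(m = data.frame(motif_id = "m", chrom = "c",
                             start = ctr[seq(1, 60, 3)],
                             end = ctr[seq(1, 60, 3)] + 1L, strand = "+",
                             score = 0, footprint_score = -5))
  anchors <- sort_and_merge(uni[1:20, ])
  a <- bootstrap_cooccurrence(anchors, occ, uni, n_boot = 200, seed = 77)
  b <- bootstrap_cooccurrence(anchors, occ, uni, n_boot = 200, seed = 77)
  expect_identical(a, b)
})
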