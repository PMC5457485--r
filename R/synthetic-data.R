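#' Synthetic study design
#'
#' Parameters of the synthetic two-condition chromatin study the generator
#' emulates: two peak sets sharing a designed overlap fraction,
#' condition-specific motif composition at unique peaks (GATA-like in
#' condition 1, C/EBP-like plus E-box-like in condition 2, RUNX/ETS/AP-1
#' -like in shared peaks), footprint-shaped cut depletion at occupied
#' motifs on top of peak-shaped enrichment, and a knockdown expression
#' time course with progressively responding genes.
#'
#' @param seed master seed; every simulator derives its stream from it.
#' @param n_chroms,chrom_length genome shape (default 2 x 1 Mb).
#' @param n_peaks peaks per condition (default 1000).
#' @param shared_fraction designed fraction of peaks common to both
#'   conditions (default 0.3).
#' @param peak_width,peak_gap peak width and minimum inter-peak gap in bp.
#' @param motif_assignments list with elements `cond1_unique`,
#'   `cond2_unique`, `shared`: motif ids (from [builtin_consensus()])
#'   planted in each peak class.
#' @param footprint_occupancy_rate probability a planted motif instance is
#'   occupied (footprint-depleted) in its condition.
#' @param peak_cut_rate,background_cut_rate Poisson cut intensities per bp
#'   per strand inside/outside peaks.
#' @param footprint_depletion multiplicative rate factor over occupied
#'   motif spans (in (0,1)).
#' @param footprint_flank bp of protection either side of an occupied
#'   motif core (a bound protein shields more than the motif itself;
#'   default 6, giving ~20-22 bp protected spans).
#' @param n_genes,n_up,n_down expression design: total genes and planted
#'   up/down responders.
#' @param fold_range range of maximal responder fold changes.
#' @param timepoints knockdown timepoints (days).
#' @param n_replicates replicates per condition/timepoint.
#' @param expr_noise_sd sd of multiplicative log-normal expression noise.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline FPKM
#'   parameters.
#' @return validated `SyntheticDesign` list.
#' @export
synthetic_design <- function(seed = 1L,
                             n_chroms = 2L, chrom_length = 1000000L,
                             n_peaks = 1000L, shared_fraction = 0.3,
                             peak_width = 200L, peak_gap = 100L,
                             motif_assignments = list(
                               cond1_unique = "GATA",
                               cond2_unique = c("CEBP", "EBOX"),
                               shared = c("RUNX", "ETS", "AP1")),
                             footprint_occupancy_rate = 0.7,
                             peak_cut_rate = 2, background_cut_rate = 0.05,
                             footprint_depletion = 0.1,
                             footprint_flank = 6L,
                             n_genes = 1000L, n_up = 50L, n_down = 50L,
                             fold_range = c(2, 4),
                             timepoints = c(2L, 5L, 10L), n_replicates = 2L,
                             expr_noise_sd = 0.1,
                             baseline_meanlog = log(20), baseline_sdlog = 1) {
  design <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_peaks = as.integer(n_peaks),
                 shared_fraction = shared_fraction,
                 peak_width = as.integer(peak_width),
                 peak_gap = as.integer(peak_gap),
                 motif_assignments = motif_assignments,
                 footprint_occupancy_rate = footprint_occupancy_rate,
                 peak_cut_rate = peak_cut_rate,
                 background_cut_rate = background_cut_rate,
                 footprint_depletion = footprint_depletion,
                 footprint_flank = as.integer(footprint_flank),
                 n_genes = as.integer(n_genes), n_up = as.integer(n_up),
                 n_down = as.integer(n_down), fold_range = fold_range,
                 timepoints = timepoints,
                 n_replicates = as.integer(n_replicates),
                 expr_noise_sd = expr_noise_sd,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog)
  if (design$shared_fraction < 0 || design$shared_fraction > 1) {
    stop("synthetic_design: shared_fraction must be in [0, 1]")
  }
  if (design$peak_cut_rate <= 0 || design$background_cut_rate <= 0) {
    stop("synthetic_design: cut rates must be > 0")
  }
  if (design$footprint_depletion <= 0 || design$footprint_depletion > 1) {
    # 1 = no protection, the null case for footprint calling
    stop("synthetic_design: footprint_depletion must be in (0, 1]")
  }
  unknown <- setdiff(unlist(design$motif_assignments),
                     names(builtin_consensus()))
  if (length(unknown) > 0L) {
    stop("synthetic_design: unknown motif id '", unknown[1L], "'")
  }
  class(design) <- "SyntheticDesign"
  design
}

#' Simulate a random genome
#'
#' I.i.d. uniform ACGT background sequence, reproducible from the design
#' seed.
#'
#' @param design a `SyntheticDesign`.
#' @return list with `records` (sequence records, one per chromosome) and
#'   `sizes` (chrom/length data.frame).
#' @export
simulate_genome <- function(design) {
  set.seed(design$seed)
  chroms <- paste0("chr", seq_len(design$n_chroms))
  records <- lapply(chroms, function(ch) {
    seq <- paste(sample(c("A", "C", "G", "T"), design$chrom_length,
                        replace = TRUE), collapse = "")
    sequence_record(ch, seq, chrom = ch, offset = 0L)
  })
  names(records) <- chroms
  list(records = records,
       sizes = data.frame(chrom = chroms, length = design$chrom_length,
                          stringsAsFactors = FALSE))
}

# Non-overlapping interval placement on one chromosome: m intervals of
# width w with gaps >= g, uniform over admissible configurations.
.place_intervals <- function(m, w, g, chrom_length) {
  slack <- chrom_length - m * (w + g)
  if (slack <= 0) stop("genome too small for requested peaks")
  u <- sort(stats::runif(m, 0, slack))
  as.integer(floor(u + (seq_len(m) - 1L) * (w + g)) + g %/% 2L)
}

#' Plant peaks and motifs into a simulated genome
#'
#' Places non-overlapping peaks, assigns each to the shared class or to one
#' condition's unique class at the designed `shared_fraction`, writes each
#' class's motif consensus strings into the sequence at recorded offsets,
#' and flags each planted instance as occupied with probability
#' `footprint_occupancy_rate`.
#'
#' @param design a `SyntheticDesign`.
#' @param genome output of [simulate_genome()] (edited copy returned).
#' @return list with `genome` (edited), `peaks` (all placed peaks with
#'   `group` in shared/cond1/cond2), `peaks_cond1`, `peaks_cond2` (merged
#'   `PeakSet`s), `motif_truth` (planted hits: motif, chrom, start, end,
#'   strand, occupied, group).
#' @export
plant_peaks_and_motifs <- function(design, genome) {
  set.seed(design$seed + 1L)
  n_shared <- round(design$shared_fraction * design$n_peaks)
  n_unique <- design$n_peaks - n_shared
  n_total <- n_shared + 2L * n_unique
  chroms <- genome$sizes$chrom
  per_chrom <- diff(round(seq(0, n_total, length.out = length(chroms) + 1L)))
  placed <- list()
  for (i in seq_along(chroms)) {
    if (per_chrom[i] == 0L) next
    starts <- .place_intervals(per_chrom[i], design$peak_width,
                               design$peak_gap, design$chrom_length)
    placed[[i]] <- data.frame(chrom = chroms[i], start = starts,
                              end = starts + design$peak_width,
                              stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, placed)
  group <- sample(rep(c("shared", "cond1", "cond2"),
                      c(n_shared, n_unique, n_unique)))
  peaks$group <- group
  peaks$name <- sprintf("peak%05d", seq_len(nrow(peaks)))
  cons <- builtin_consensus()
  truth <- list()
  seqs <- lapply(genome$records, `[[`, "seq")
  for (i in seq_len(nrow(peaks))) {
    motifs <- switch(peaks$group[i],
                     shared = design$motif_assignments$shared,
                     cond1 = design$motif_assignments$cond1_unique,
                     cond2 = design$motif_assignments$cond2_unique)
    if (length(motifs) == 0L) next
    # one instance per motif, in disjoint equal slices of the peak
    # interior; the margin keeps planted motifs clear of the zone where a
    # footprint window plus shoulder cannot fit inside the peak
    margin <- 45L
    interior <- design$peak_width - 2L * margin
    slice <- interior %/% length(motifs)
    for (j in seq_along(motifs)) {
      word <- cons[[motifs[j]]]
      L <- nchar(word)
      if (slice < L) stop("plant_peaks_and_motifs: peak too narrow for motifs")
      off <- margin + (j - 1L) * slice +
        sample.int(slice - L + 1L, 1L) - 1L
      gstart <- peaks$start[i] + off
      ch <- peaks$chrom[i]
      substr(seqs[[ch]], gstart + 1L, gstart + L) <- word
      truth[[length(truth) + 1L]] <- data.frame(
        motif = motifs[j], chrom = ch, start = gstart, end = gstart + L,
        strand = "+",
        occupied = stats::runif(1) < design$footprint_occupancy_rate,
        group = peaks$group[i], peak = peaks$name[i],
        stringsAsFactors = FALSE)
    }
  }
  for (ch in names(seqs)) genome$records[[ch]]$seq <- seqs[[ch]]
  motif_truth <- do.call(rbind, truth)
  peaks_cond1 <- sort_and_merge(peaks[peaks$group %in% c("shared", "cond1"), ],
                                label = "cond1")
  peaks_cond2 <- sort_and_merge(peaks[peaks$group %in% c("shared", "cond2"), ],
                                label = "cond2")
  list(genome = genome, peaks = peaks, peaks_cond1 = peaks_cond1,
       peaks_cond2 = peaks_cond2, motif_truth = motif_truth)
}

#' Simulate strand-specific DNase I cut profiles
#'
#' Per-base, per-strand independent Poisson cuts: `background_cut_rate`
#' outside peaks, `peak_cut_rate` inside the condition's peaks, and
#' `peak_cut_rate * footprint_depletion` over occupied motif spans within
#' those peaks.
#'
#' @param design a `SyntheticDesign`.
#' @param planted output of [plant_peaks_and_motifs()].
#' @param condition `"cond1"` or `"cond2"`.
#' @return a `CutProfile`.
#' @export
simulate_cuts <- function(design, planted, condition = c("cond1", "cond2")) {
  condition <- match.arg(condition)
  set.seed(design$seed + 10L + match(condition, c("cond1", "cond2")))
  peaks <- if (condition == "cond1") planted$peaks_cond1 else planted$peaks_cond2
  groups <- c("shared", condition)
  occ <- planted$motif_truth[planted$motif_truth$occupied &
                               planted$motif_truth$group %in% groups, ,
                             drop = FALSE]
  sizes <- planted$genome$sizes
  cuts <- list()
  for (ch in sizes$chrom) {
    L <- sizes$length[sizes$chrom == ch]
    rate <- rep(design$background_cut_rate, L)
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(pk))) {
      rate[(pk$start[i] + 1L):pk$end[i]] <- design$peak_cut_rate
    }
    oc <- occ[occ$chrom == ch, , drop = FALSE]
    fl <- design$footprint_flank
    for (i in seq_len(nrow(oc))) {
      span <- max(oc$start[i] + 1L - fl, 1L):min(oc$end[i] + fl, L)
      rate[span] <- rate[span] * design$footprint_depletion
    }
    for (st in c("+", "-")) {
      counts <- stats::rpois(L, rate)
      nz <- which(counts > 0L)
      if (length(nz) > 0L) {
        cuts[[length(cuts) + 1L]] <- data.frame(
          chrom = ch, pos = nz - 1L, strand = st, count = counts[nz],
          stringsAsFactors = FALSE)
      }
    }
  }
  cut_profile(do.call(rbind, cuts), sizes)
}

#' Simulate a knockdown expression time course
#'
#' Log-normal baseline FPKM; planted responders change monotonically
#' across timepoints (geometric interpolation up to a per-gene maximal
#' fold drawn from `fold_range`), with multiplicative log-normal noise on
#' every observation. Gene TSSs are placed uniformly on the genome so that
#' peak-to-gene assignment is exercised.
#'
#' @param design a `SyntheticDesign`.
#' @param genome output of [simulate_genome()] (for TSS placement).
#' @param noise_sd overrides `design$expr_noise_sd` when given.
#' @return list with `expr` (an `ExpressionTable`), `truth` (gene,
#'   class up/down/null, max_fold), `tss_table` (BED6-style gene table).
#' @export
simulate_expression <- function(design, genome, noise_sd = NULL) {
  set.seed(design$seed + 20L)
  if (is.null(noise_sd)) noise_sd <- design$expr_noise_sd
  n <- design$n_genes
  genes <- sprintf("gene%04d", seq_len(n))
  cls <- sample(rep(c("up", "down", "null"),
                    c(design$n_up, design$n_down, n - design$n_up - design$n_down)))
  max_fold <- stats::runif(n, design$fold_range[1], design$fold_range[2])
  max_fold[cls == "null"] <- 1
  baseline <- stats::rlnorm(n, design$baseline_meanlog, design$baseline_sdlog)
  tps <- design$timepoints
  Tmax <- max(tps)
  cols <- list()
  info <- list()
  for (tp in tps) {
    fold_tp <- max_fold ^ (tp / Tmax)
    mult <- ifelse(cls == "up", fold_tp, ifelse(cls == "down", 1 / fold_tp, 1))
    for (cond in c("control", "kd")) {
      for (rep_i in seq_len(design$n_replicates)) {
        mean_val <- if (cond == "kd") baseline * mult else baseline
        noise <- if (noise_sd > 0) exp(stats::rnorm(n, 0, noise_sd)) else 1
        nm <- sprintf("%s_d%d_r%d", cond, tp, rep_i)
        cols[[nm]] <- mean_val * noise
        info[[nm]] <- data.frame(sample = nm, condition = cond,
                                 timepoint = tp, stringsAsFactors = FALSE)
      }
    }
  }
  fpkm <- do.call(cbind, cols)
  rownames(fpkm) <- genes
  sample_info <- do.call(rbind, info)
  rownames(sample_info) <- NULL
  # TSS table: genes of width 5 kb (clipped), uniform starts, random strand
  gl <- 5000L
  chrom <- sample(genome$sizes$chrom, n, replace = TRUE)
  start <- floor(stats::runif(n, 0, design$chrom_length - gl))
  tss_table <- data.frame(chrom = chrom, start = as.integer(start),
                          end = as.integer(start + gl), name = genes,
                          score = 0, strand = sample(c("+", "-"), n, TRUE),
                          stringsAsFactors = FALSE)
  list(expr = expression_table(fpkm, sample_info),
       truth = data.frame(gene = genes, class = cls, max_fold = max_fold,
                          stringsAsFactors = FALSE),
       tss_table = tss_table)
}

#' Generate a complete synthetic fixture on disk
#'
#' Runs every simulator and writes the standard-format files all pipeline
#' stages consume, together with a truth JSON and a manifest recording the
#' design, so a fixture is reproducible byte for byte from (seed, design).
#'
#' @param design a `SyntheticDesign`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with all in-memory objects and `files`
#'   (named vector of written paths).
#' @export
generate_fixture <- function(design, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L) {
    stop("generate_fixture: directory not writable: ", out_dir)
  }
  genome <- simulate_genome(design)
  planted <- plant_peaks_and_motifs(design, genome)
  cuts1 <- simulate_cuts(design, planted, "cond1")
  cuts2 <- simulate_cuts(design, planted, "cond2")
  expr_sim <- simulate_expression(design, genome)
  fp <- function(x) file.path(out_dir, x)
  files <- c(genome = fp("genome.fa"), sizes = fp("genome.sizes.tsv"),
             peaks_cond1 = fp("peaks_cond1.bed"),
             peaks_cond2 = fp("peaks_cond2.bed"),
             cuts_cond1 = fp("cuts_cond1.bed"),
             cuts_cond2 = fp("cuts_cond2.bed"),
             tss = fp("tss.bed"), expression = fp("expression.tsv"),
             samples = fp("sample_info.tsv"), truth = fp("truth.json"),
             manifest = fp("manifest.json"))
  write_fasta(planted$genome$records, files[["genome"]])
  utils::write.table(genome$sizes, files[["sizes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_bed(planted$peaks_cond1, files[["peaks_cond1"]])
  write_bed(planted$peaks_cond2, files[["peaks_cond2"]])
  write_cut_profile(cuts1, files[["cuts_cond1"]])
  write_cut_profile(cuts2, files[["cuts_cond2"]])
  write_bed(expr_sim$tss_table, files[["tss"]])
  expr_out <- data.frame(gene = rownames(expr_sim$expr$fpkm),
                         expr_sim$expr$fpkm, check.names = FALSE)
  utils::write.table(expr_out, files[["expression"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(expr_sim$expr$sample_info, files[["samples"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(peaks = planted$peaks, motif_truth = planted$motif_truth,
                expression = expr_sim$truth)
  jsonlite::write_json(truth, files[["truth"]], dataframe = "columns",
                       digits = NA)
  manifest <- c(unclass(design)[setdiff(names(unclass(design)), "motif_assignments")],
                list(motif_assignments = design$motif_assignments,
                     package_version = as.character(utils::packageVersion("chromcompare")),
                     files = as.list(basename(files))))
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(list(design = design, genome = planted$genome, planted = planted,
                 cuts_cond1 = cuts1, cuts_cond2 = cuts2,
                 expression = expr_sim, files = files))
}
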