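#' Built-in synthetic motif models
#'
#' A small library of near-consensus position frequency matrices for the
#' transcription factor families recurrently discussed in comparative AML
#' cistrome work: GATA, C/EBP, E-box, RUNX, ETS, AP-1, and CTCF. These are
#' synthetic stand-ins built from canonical consensus strings (91 consensus
#' counts vs 3 per alternative base per column), not matrices fitted to
#' experimental data; they are shipped as a JASPAR-style count file in
#' `inst/extdata/synthetic_motifs.pfm`.
#'
#' @param pseudocount,background passed to [read_pwm()].
#' @return named list of `PWM` objects.
#' @export
builtin_motifs <- function(pseudocount = 0.8,
                           background = c(0.25, 0.25, 0.25, 0.25)) {
  path <- system.file("extdata", "synthetic_motifs.pfm",
                      package = "chromcompare")
  if (!nzchar(path)) stop("builtin_motifs: packaged motif file not found")
  read_pwm(path, pseudocount = pseudocount, background = background)
}

#' Consensus strings of the built-in motif library
#'
#' The consensus each built-in PFM was derived from; the synthetic-data
#' generator plants these exact strings.
#'
#' @return named character vector.
#' @export
builtin_consensus <- function() {
  c(GATA = "AGATAAGA",
    CEBP = "ATTGCGCAAT",
    EBOX = "AACAGCTGTT",
    RUNX = "TGTGGTTT",
    ETS = "ACAGGAAGTG",
    AP1 = "TGACTCAT",
    CTCF = "CCACCAGGGGGCGC")
}

# Counts for a near-consensus PFM: 91 on the consensus base, 3 elsewhere.
.consensus_counts <- function(consensus) {
  bases <- strsplit(consensus, "", fixed = TRUE)[[1]]
  counts <- matrix(3, nrow = 4, ncol = length(bases),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(match(bases, rownames(counts)), seq_along(bases))] <- 91
  counts
}

# Regenerates inst/extdata/synthetic_motifs.pfm (development helper; the
# shipped file is the source of truth at run time).
.write_motif_library <- function(path) {
  cons <- builtin_consensus()
  out <- character(0)
  for (id in names(cons)) {
    counts <- .consensus_counts(cons[[id]])
    out <- c(out, paste0(">", id, " ", id, "-like_synthetic"))
    for (b in c("A", "C", "G", "T")) {
      out <- c(out, paste0(b, " [ ", paste(sprintf("%3d", counts[b, ]),
                                           collapse = " "), " ]"))
    }
  }
  writeLines(out, path)
  invisible(path)
}
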