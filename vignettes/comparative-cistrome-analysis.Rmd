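---
title: "Comparative cistrome analysis with chromcompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative cistrome analysis with chromcompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromcompare)
```

## The analytical problem

Two cell states — for instance two leukemia subtypes driven by different
fusion oncoproteins, or one cell line before and after knockdown of such a
protein — can be compared genome-wide through their open-chromatin
landscapes (DNase I hypersensitive sites, DHSs) and transcription factor
binding repertoires. chromcompare implements that comparison as a chain of
small, individually testable stages:

1. **Peak-set algebra.** Peaks from each condition are merged into a union;
   every union region is labelled by the subset of conditions supporting it
   (the numbers behind a Venn diagram), and per-set overlap fractions are
   reported.
2. **Correlation clustering.** Cut counts over union regions are
   library-size normalised, log-transformed, and samples are clustered by
   Pearson correlation (average linkage on `1 - r`).
3. **Motif scanning.** Position weight matrices are scanned over both
   strands with a log-odds score; exact degenerate consensus strings are
   matched with IUPAC codes.
4. **Unique-vs-union enrichment.** For a pair of cistromes, motifs are
   tested for enrichment in the peaks unique to each condition against the
   union of the pair, and the signed scores are clustered into a
   motifs-by-comparisons heatmap.
5. **Digital footprinting.** Strand-specific cut profiles are scanned for
   short protected regions, and footprinted ("occupied") motifs are
   intersected with motif hits.
6. **Bootstrap co-occurrence.** The tendency of occupied motifs to cluster
   within a fixed window of anchor binding sites is scored against random
   draws of accessible regions.
7. **Knockdown response.** Union regions are partitioned into
   lost/shared/gained accessibility groups, expression responders are
   selected by a fold-change rule over a time course, and responders are
   intersected with ChIP targets.

## Statistical definitions

### Unique-vs-union enrichment score

For a motif $m$ and a target set of $n$ peaks drawn from a union of $N$
peaks of which $K$ contain $m$ (a peak "contains" a motif when a hit
midpoint falls inside it), with $k$ target peaks containing $m$:

* fold $= (k/n) / (K/N)$;
* over-representation $p$ = upper hypergeometric tail
  $P(X \ge k)$, under-representation $p$ = lower tail $P(X \le k)$;
* signed score $= -\log_{10} p_\mathrm{over}$ when fold $\ge 1$, and
  $\log_{10} p_\mathrm{under}$ (negative) otherwise, with $p$ floored at
  $10^{-300}$.

The hypergeometric (sampling without replacement) is the natural model
because the unique peaks are literally a subset of the union population.
The exact statistic behind the published heatmaps of this analysis style is
described only verbally in the literature; the signed
$-\log_{10}$-hypergeometric used here is this package's own definition.
Benjamini–Hochberg $q$-values across motifs within a comparison are
reported alongside raw $p$ even though the original analyses state no
correction.

### Footprint score

For a candidate footprint of size $f$ at a position, with $F_{fw}$ forward
cuts inside the footprint and $S_{fw}$ forward cuts in the
`shoulder_size`-bp window immediately upstream, the forward evidence is the
lower binomial tail

$$p_{fw} = P\!\left[\mathrm{Bin}\!\left(F_{fw}+S_{fw},
\tfrac{f}{f+s}\right) \le F_{fw}\right],$$

and symmetrically for reverse-strand cuts against the downstream shoulder.
The score is $\log_{10} p_{fw} + \log_{10} p_{rev}$; zero-trial candidates
contribute 0 on that strand. Per position the best score over the
configured footprint sizes is kept, and non-overlapping footprints are
selected greedily in ascending score order down to `score_cutoff`. The
defaults — sizes 11 to 25 bp (odd), 35-bp shoulders, cutoff $-10$ — follow
the published defaults of this family of footprinters; all are
config-exposed because the exact settings used in any given study vary.

### Bootstrap co-occurrence

`observed(m)` is the number of anchor peaks whose centre lies within
`window_bp` (default 50) of at least one occupied motif midpoint. The null
resamples `|anchors|` regions uniformly **without replacement** from the
accessible-region universe `n_boot` times; $z$ is the moment standardisation
and the empirical $p$ is $(1 + \#\{null \ge obs\})/(1 + n_\mathrm{boot})$.
Three choices here were genuinely open and are recorded as this package's
definitions: the null resamples *anchor positions* (not motifs), the
sampling universe is the union DHS set rather than the whole genome
(restricting to accessible chromatin is the conservative choice), and the
50-bp window is measured centre-to-midpoint. Because the empirical $p$ is
discrete over small integer counts, the test is slightly conservative: on
null data the fraction of motifs with $p < 0.05$ sits a little below 0.05
(typically 0.035–0.045), which the calibration test accepts.

### Knockdown classification

On library-size-normalised counts with pseudocount 1, a region is *lost*
when control/knockdown $\ge$ `fold_threshold` (default 2), *gained* for the
reciprocal, else *shared* — a strict partition with exact label-swap
symmetry. Expression responders satisfy $|\log_2 FC| \ge \log_2 1.5$ at one
or more timepoints (closed boundary; replicates are averaged first;
FPKM pseudocount 0.01 so that moderately expressed genes are not dominated
by the offset). Whether the 1.5-fold rule applies per timepoint or across
the whole course was unstated in the source analyses; "at $\ge 1$
timepoint" is used here because a monotone time course makes the late
timepoint decisive either way. Peak-to-gene assignment for ChIP-target
fractions uses the nearest TSS within 50 kb — again config-exposed, since
no universal rule exists.

## The synthetic-data generator

Every stage is validated against data with known truth generated by
`synthetic_design()` and friends. The default design encodes the study
conditions the pipeline targets:

* two conditions of 1000 peaks (200 bp wide) on a 2 × 1 Mb uniform-ACGT
  genome, sharing exactly 30% of peaks;
* GATA-like consensus planted in condition-1-unique peaks; CEBP-like and
  E-box-like in condition-2-unique peaks; RUNX-, ETS- and AP-1-like in
  shared peaks (the partitioning structure reported for the two leukemia
  subtypes this analysis style was developed on);
* per-base Poisson cuts: 0.05/bp/strand background, 2/bp/strand inside
  peaks, multiplied by 0.1 over occupied motif spans. A bound protein
  shields more than its motif core, so protection extends 6 bp either side
  of the planted motif (`footprint_flank`), giving ~20–22-bp protected
  spans matching the detector's size range. 70% of planted instances are
  occupied;
* a knockdown expression course (days 2/5/10, two replicates, mirroring a
  typical two-week siRNA course): log-normal baseline FPKM
  (meanlog $\log 20$, sdlog 1), 50 up- and 50 down-regulated responders
  among 1000 genes with maximal folds drawn from [2, 4] reached by
  geometric interpolation across timepoints, multiplicative log-normal
  noise (sd 0.1 on the log scale).

Everything is deterministic given (seed, design), and
`generate_fixture()` writes the whole bundle as plain FASTA/BED/TSV plus a
truth JSON and manifest.

What the generator does *not* emulate — and therefore what passing tests do
not certify about real data: GC structure and sequence-dependent DNase cut
bias, overlapping/clustered peaks of variable width, PWM-sampled (rather
than exact-consensus) motif instances unless requested, replicate-level
biological variance models, and read-level artefacts. The generator
validates the algebra and statistics of the pipeline, not the biology of
any particular dataset.

## Numerical and design choices

* Coordinates are 0-based half-open (BED convention) everywhere internally;
  IRanges' closed 1-based ranges appear only inside the overlap machinery.
  Book-ended intervals merge.
* Overlap criterion is $\ge 1$ shared bp on merged inputs — the
  least-assumption default when no summit-distance rule is stated.
* Motif hits keep all overlapping same-strand occurrences (density tracks
  are count-based; greedy pruning would bias them). Windows containing `N`
  are skipped. A PWM identical to background scores no hits at any
  threshold. The default relative score threshold is 0.8 of the attainable
  score range; PWMs are built from counts with a total pseudocount of 0.8
  split by background frequency.
* Clustering tie-breaks are made deterministic by sorting labels
  lexicographically before `hclust`; nearest-gene ties resolve to the
  lexicographically smaller gene name.
* `phyper`, `pbinom` (log scale), `hclust`, `cor`, and `p.adjust` provide
  the standard statistical steps; the package's own code is the
  composition of these into the comparative statistics above.
* Degenerate cases return flagged results, not errors, where a scientist
  would expect them (empty unique sets, zero-variance bootstrap null);
  malformed inputs fail loudly with line numbers.

## Problem sizes used by the packaged checks

The bundled tests and the acceptance script run the full default design
(1000 peaks/condition on 2 Mb) for overlap, enrichment, and knockdown
classification; a 20-peak design for footprint recovery; 200 simulated
motif sets at 500 bootstrap draws for calibration; and exhaustive
enumeration of all $\binom{40}{5}$ subsets for the bootstrap's exactness
check. These sizes keep a complete run in the low minutes on one CPU while
leaving every statistic in its asymptotically meaningful regime.

## Known limitations

* Footprint detection assumes the upstream/downstream shoulder geometry of
  classical DNase I footprinting; it does not correct sequence cut bias and
  will under-call footprints at peak edges (candidates whose window leaves
  the region are skipped).
* The bootstrap co-occurrence null conditions on the DHS universe; if
  anchors systematically differ from the universe in width or accessibility
  the z-scores inherit that difference.
* The DE rule is a fold-change filter, deliberately not a variance-model
  test (no replicate dispersion estimation) — matching the analysis style
  it reproduces, not current best practice for RNA-seq inference.
```
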