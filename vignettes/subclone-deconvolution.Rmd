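---
title: "Resolving sub-clonal structure from shallow single-cell CNV profiles"
author: "scCloneCNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving sub-clonal structure from shallow single-cell CNV profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scCloneCNV)
```

## The problem

Droplet-based shallow single-cell whole-genome sequencing reads each cell of
a tumor or cell line at a few hundred reads per megabase — far too shallow
for variant calling, but enough to measure integer copy number in megabase
bins. Because the data are single-cell, relative depth can be anchored to an
integer lattice per cell ("quantum" copy number), and cells can be grouped
into sub-clones by the large copy-number events they share. Once cells are
assigned to groups, the groups behave like bulk samples: their reads can be
pooled for loss-of-heterozygosity (LOH), fold-change and structural-variant
breakpoint analysis.

scCloneCNV implements that workflow end to end for a cohort modeled on the
COLO829 melanoma line: a near-triploid genome carrying a derivative
chromosome 18 assembled from pieces of 1p, 10p and 18
(`der(18)(1pter->p22::10p14->10p11::18p11->18q)`), mixed with sub-clones
that either lost the derivative or gained a copy of chromosome 8. Four
clones (A-D, default proportions 653:117:43:560) differ along two
independent axes: chromosome 8 at total copy 3 (A, B) versus 4 (C, D), and
presence (A, D) versus absence (B, C) of the der(18), whose loss leaves
1pter-1p22.3 at two copies of a single haplotype (complete LOH), the 10p
segment likewise reduced, and chromosome 18 at copy 2.

## The synthetic cohort generator

`buildDefaultModel()` returns the genome (GRCh37 autosomes, 2 Mb bins), the
four haplotype-resolved clone profiles, and the default mixing proportions.
The generator family (`simulateCells()`, `simulateAlleleCounts()`,
`simulateReadPairs()`, `injectNoisyCells()`) emulates:

* **Binned read counts** — negative-binomial per cell and bin, mean
  proportional to clone copy number, normalized so a cell at the
  cohort-average ploidy totals 436 reads/Mb (the study depth). Dispersion
  defaults to 0.08, i.e. a coefficient of variation of about 28% at the
  ~870 reads expected per 2 Mb bin — the noisy end of what shallow
  single-cell coverage looks like after bias correction.
* **Het-SNP allele counts** — binomial reads at germline heterozygous sites
  (one per 500 kb by default), with success probability equal to the
  alt-carrying haplotype's share of the segment copy number, perturbed by a
  0.005 per-read allele error so fully homozygous segments read out in the
  high 90s rather than at exactly 100%.
* **Anomalous read pairs and split reads** — pairs straddling the two
  der(18) junctions (insert 350 +/- 50 bp), tagged with carrier-cell
  barcodes, plus uniform inter-chromosomal noise pairs; split reads carry
  the exact breakend bases.
* **Noisy cells** — a seeded fraction (default 102/1475, the study's 6.9%)
  re-drawn with 10x dispersion and per-bin lognormal rate jitter, so their
  segment means are not integer-consistent.

Besides the clone-defining events, all four clones share a set of clonal
background rearrangements (1q gained to four copies, 9p and 16q lost to
two, a copy-neutral-LOH 7q tip, a 15q-terminal gain, 18pter at two copies).
These mirror the line's karyotype — its chromosome 1 shows the 3-2-4 state
pattern visible in published per-cell profiles — and they matter
methodologically: a cell that were uniformly triploid would be
indistinguishable from a diploid cell at shallow depth, because the integer
lattice is only identifiable from copy-number *contrast* within the cell.

What the generator does **not** emulate: GC and mappability bias, the
20 kb native binning of droplet pipelines, FASTQ/BAM-level reads, doublets,
or replication-phase effects. Passing tests therefore demonstrate correct
inference under a clean count model at realistic depth and noise, not
robustness to technical artifacts of real libraries; real data should
arrive bias-corrected (the `weights` argument of `scaledDepth()` accepts an
external per-bin bias profile, and `normalizeCounts()` divides by an
explicit reference profile).

## Per-cell integer copy number

`callCellProfiles()` runs four steps per cell.

**Scaled depth.** Counts become per-bp rates, normalized to a genome mean
of 1, approximating `copy / meanCopy`. Terminal bins shorter than a quarter
of the bin width are masked — at 436 reads/Mb a 22 kb bin holds ~10 reads
and would otherwise seed spurious one-bin segments. We deliberately do
*not* divide by the cohort median per bin: with no technical bin bias in
the model, the cohort median tracks the majority clone's copy profile, and
dividing by it would erase exactly the signal being measured. For real
data with bin-level bias, supply `weights` (or use `normalizeCounts()`
with a normal-panel reference).

**Segmentation.** Penalized least-squares binary segmentation per
chromosome, penalty `1.5 * log(nBins) * sigma^2` with the noise variance
estimated robustly from successive bin differences. The coefficient is
calibrated so a one-copy arm-scale step at the default depth (SSE gain
~1.25 for the 16q loss) clears the penalty (~0.9) while chance splits of
uniform noise (~0.6 at the 99.9% level) do not. A second pass
(`refineSegments()`) re-tests each segment's best internal split at half
the penalty plus a 3.5-standard-error mean-separation requirement,
rescuing steps that fall just under the genome-wide penalty.

By default the cohort is segmented *jointly*: candidate breakpoints come
from the pooled cohort profile (`cohortBreakpoints()`), whose noise shrinks
with the square root of the cell count so even steps carried by a 10%
sub-clone are located precisely; each cell is cut at every candidate and
runs of equal assigned copy are re-merged. Joint segmentation gives all
cells identical segment coordinates, which makes the downstream
reciprocal-overlap merge of events essentially exact. The cost is that
events private to a single cell are not discoverable on this path; set
`jointSegmentation = FALSE` for strictly independent per-cell segmentation.

**Integer scaling.** `fitIntegerScale()` scans S over [1, 8] in steps of
0.01 and assigns `round(S * meanDepth)` copies. Three numerical choices
matter:

* Lattice distance is measured in depth units (copy-unit distance divided
  by S). In copy units the noise contribution grows as S^2 and the argmin
  collapses to coarse lattices; in depth units it is scale-free.
* Because every integer multiple of the true scale fits at least as well
  (its lattice contains the true one), selection is a consistency test,
  not an argmin: the smallest admissible S whose residual chi-square
  (computed over segments of at least 8 bins, variance scaled by squared
  segment depth since the coefficient of variation is roughly constant)
  stays under the 99.9% quantile. Exact ties therefore resolve to the
  smallest S, and a contrast-free profile resolves to the smallest
  admissible ploidy.
* Fits implying mean ploidy below 1.5 are rejected: a near-triploid
  profile also fits a near-diploid lattice at S/1.5, and the modeled line
  is known genome-doubled.

At 436 reads/Mb roughly one cell in ten is still ambiguous between its
true scale and a near-multiple. `callCellProfiles()` therefore applies a
cohort ploidy prior: cells whose implied ploidy deviates more than 0.75
from the cohort median are refit with the admissible window centered on
that median. This assumes a unimodal cohort ploidy — true for a single
genome-doubled line; disable `cohortPloidyPrior` for genuinely
mixed-ploidy material.

**Confidence and noisy flags.** Each segment's confidence is the
log-likelihood ratio of its assigned copy against the better flanking
integer state under a Poisson count model, summed over bins — hundreds for
an unambiguous arm event, near zero for a marginal one, so the downstream
quality cutoff of 15 (a fixed constant of the workflow) retains real
chromosome-scale events on even the smallest autosomes. The units are this
package's own; they are an analog of, not a match to, any external
pipeline's score, and real-data thresholds may need recalibration. Cells
are flagged noisy when the scaled-depth MAD around segment means exceeds
0.35 (in ploidy-normalized depth units, where clean cells sit near 0.28
at default dispersion and the injected noisy model sits above 0.8).

Resolution limits worth knowing: copy boundaries are bin-quantized, and
the shortest (3-bin) segments at dispersion 0.02 still carry ~0.25-copy
mean noise — exact planted-truth recovery holds at dispersion 0.005, and
99.8%+ of bins at 0.02.

## The binary event matrix

Per-cell segments become events; `filterEvents()` keeps those strictly
larger than 2 Mb with confidence strictly above 15; `mergeEvents()` groups
events across cells by single linkage over "identical copy number and
reciprocal overlap >= 0.90" (inclusive, so identical intervals always
merge; single linkage because the pairwise rule does not define cluster
closure — chains are auditable in the output). Canonical intervals are
coordinate-wise lower medians. `buildEventMatrix()` drops clusters carried
by fewer than 5% of cells and keeps event-less cells as all-zero rows.
Whole-chromosome events are columns like any other.

## DAPC clustering and the merge into major groups

`pcaEmbed()` projects cells onto the top principal components (90%
variance, capped at 40). `scanKBic()` scans k with seeded k-means (10
restarts) and selects k by BIC. The default BIC is the X-means-style
spherical-Gaussian hard-assignment form with mixing proportions; the
simpler `n ln(W/n) + k ln(n)` variant is available as `formula = "wss"`,
but for continuous within-cluster noise its W-term rewards splitting
homogeneous clusters faster than `k ln(n)` charges for it, so its argmin
drifts to the top of the scanned range rather than landing at the true
cluster count on separable data. `discriminantAxes()` then solves the
ridge-regularized generalized eigenproblem for axes maximizing
between-group over within-group variance; eigenvalues are those variance
ratios and axis scores are whitened within groups.

Fine clusters are merged into major groups by `mergeClustersToGroups()`:
two clusters stay apart only if their modal per-bin copy profiles disagree
over at least 50 Mb of genome. This formalizes the visual rule — groups
are separated by arm- or chromosome-scale differences — and is robust to
the stochastic per-cell call flips that break exact consensus-profile
equality (the consensus-equality rule remains as the fallback when no
copy matrix is supplied, and consensus hallmark profiles are reported
either way). Groups smaller than 1% of cells are absorbed into their
nearest group; the study's smallest real group is 3.1%. Letters A, B,
C, ... follow decreasing size and are presentational only.

`orderCellsHierarchically()` provides the deterministic average-linkage
leaf order used for heatmaps.

## Pseudo-bulk: fold change and LOH

`partitionAndAggregate()` sums member-cell counts per group (conserving
reads exactly); `log2FoldChange()` compares library-normalized group
tracks to a diploid reference track (simulated via
`simulateNormalReference()` or supplied), masking zero-reference bins and
flooring at -5. `filterHetSnps()` keeps germline sites with allele
fraction in [0.4, 0.6] (inclusive) and population MAF above 1%.
`segmentAlleleFractions()` reports per segment the lower-median major and
minor allele fractions as percentages; the lower median keeps values on
the observable lattice and is deterministic for even SNP counts. On the
default model the trisomic heterozygous 1p of the der(18) carriers reads
out near 67/33 while the der-less groups read out near 100/0 — the
diagnostic contrast between "2+1" and "2+0" segments.

## Junctions

`clusterReadPairs()` greedily clusters mapq-filtered anomalous pairs so
each side's span stays within 3x the insert distance, then rejects
candidates below 2 supporting pairs, with intra-chromosomal separation of
10 kb or less, or supported by a single read-orientation class (both
directions are required, orientation classes being defined by which mate
is the first read). `associateCnvBreakpoints()` annotates candidates with
distances to the nearest CNV-segment breakpoints (2 Mb window).
`refineWithSplitReads()` sets each breakend to the modal split-read
coordinate (ties to the smaller position). `junctionPresenceByGroup()`
matches candidates across groups within 3x insert and tabulates support,
zero marking absence — on the default cohort the two der(18) junction
rows are supported only in the A-like and D-like groups. The insert
default (350 +/- 50 bp) is a generic short-insert library; group-vs-group
subtraction is intentionally out of scope beyond this presence table.

## Orchestration and reproducibility

`pipelineConfig()` / `readPipelineConfig()` validate every threshold and
reject unknown keys; `runPipeline()` executes
simulate -> call-cnv -> build-matrix -> cluster -> pseudobulk ->
junctions -> report and writes CSV/BED/BEDPE/bedGraph artifacts plus a
`summary.json` with file checksums. All randomness derives from the single
configured seed; timings go to messages, not the summary, so identical
configurations produce byte-identical summaries. A thin command-line
wrapper (`inst/scripts/sccnv-pipeline.R`) exposes the same entry point
with exit codes 0 (success), 2 (configuration error), 3 (data-contract
error).

Problem sizes used by the shipped checks were chosen to exercise the
statistics at realistic per-cell depth while staying desk-sized: full
1475-cell runs for the end-to-end group recovery and noisy-cell
arithmetic, 500 cells for the ploidy calibration, 320 cells per seed for
the 20-seed recovery study, 200-500 SNPs per LOH segment.

## Known limitations

* The generator's clean NB/binomial model omits GC and mappability
  structure; real-data use requires externally corrected counts.
* Joint segmentation assumes cohort-shared breakpoints; single-cell
  private events need the per-cell path and deeper coverage.
* The cohort ploidy prior assumes one dominant ploidy state.
* Pooled-profile breakpoint localization for events carried by small
  sub-clones is noisy below ~300 cells (a few bins of drift).
* Confidence units are package-specific; the ">15" cutoff transfers as a
  convention, not a calibration.
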