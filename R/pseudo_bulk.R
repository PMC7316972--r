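#' Aggregate cell counts into per-group pseudo-bulk tracks
#'
#' Sums bin counts over the member cells of each group (the count-level
#' analog of splitting a barcoded BAM by cluster). Bin-wise, the tracks of
#' all groups sum exactly to the cohort total over the assigned cells.
#'
#' @param counts cells x bins count matrix with barcode rownames.
#' @param assignment data.frame with `barcode` and `group`; every barcode
#'   must exist in `counts` (noisy cells are simply left out).
#' @return groups x bins numeric matrix.
#' @export
partitionAndAggregate <- function(counts, assignment) {
  missing <- setdiff(assignment$barcode, rownames(counts))
  if (length(missing))
    dataError(sprintf("barcode(s) in assignment absent from cohort: %s",
                      paste(utils::head(missing, 3), collapse = ", ")))
  groups <- sort(unique(assignment$group))
  tracks <- matrix(0, nrow = length(groups), ncol = ncol(counts),
                   dimnames = list(groups, colnames(counts)))
  for (g in groups) {
    bc <- assignment$barcode[assignment$group == g]
    if (length(bc) == 0) {
      warning(sprintf("group %s has no cells; all-zero track emitted", g))
      next
    }
    tracks[g, ] <- colSums(counts[bc, , drop = FALSE])
  }
  tracks
}

#' Per-bin log2 fold change of a group track against a reference
#'
#' Library-size-normalized ratio:
#' `log2((group_b / sum(group)) / (ref_b / sum(ref)))`. Bins with zero
#' reference are masked (`NA`); values below `floor` (default -5, reached in
#' homozygous-deletion regions as group depth vanishes) are clamped to it.
#'
#' @param groupTrack,referenceTrack numeric vectors on the same bin grid.
#' @param floor lower clamp for the log2 fold change.
#' @return numeric vector of log2 fold changes, `NA` where masked.
#' @export
log2FoldChange <- function(groupTrack, referenceTrack, floor = -5) {
  if (length(groupTrack) != length(referenceTrack))
    dataError("group and reference tracks are on different bin grids")
  p <- groupTrack / sum(groupTrack)
  q <- referenceTrack / sum(referenceTrack)
  lfc <- suppressWarnings(log2(p / q))
  lfc[referenceTrack <= 0] <- NA_real_
  pmax(lfc, floor)
}

#' Filter germline SNPs to confident heterozygous sites
#'
#' Retains sites whose germline alternate-allele fraction lies in
#' `[afLow, afHigh]` (inclusive at both ends) and whose population minor
#' allele frequency exceeds `mafMin`. Sites with zero depth are dropped.
#'
#' @param germline data.frame with `refDepth`, `altDepth` and `maf`
#'   (population minor-allele frequency) columns.
#' @param afLow,afHigh germline allele-fraction window, default 0.4-0.6.
#' @param mafMin population MAF floor (exclusive), default 0.01.
#' @return the retained rows.
#' @export
filterHetSnps <- function(germline, afLow = 0.4, afHigh = 0.6, mafMin = 0.01) {
  depth <- germline$refDepth + germline$altDepth
  af <- ifelse(depth > 0, germline$altDepth / depth, NA_real_)
  keep <- !is.na(af) & af >= afLow & af <= afHigh & germline$maf > mafMin
  germline[keep, , drop = FALSE]
}

#' Segment-level LOH summaries from het-SNP allele counts
#'
#' Assigns SNPs to copy-number segments by position, computes per SNP the
#' major allele fraction `max(ref, alt) / (ref + alt)` and the complementary
#' minor fraction, and reports the (lower) median of each across the
#' segment's SNPs as percentages. Segments containing no SNPs are emitted
#' with `NA` medians and flagged.
#'
#' @param snpCounts data.frame with `chrom`, `pos` (1-based), `refDepth`,
#'   `altDepth`.
#' @param segments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); typically a group's consensus CNV segments.
#' @return data.frame: `chrom`, `start`, `end`, `nSnps`,
#'   `medianMajorPct`, `medianMinorPct`, `noSnps`.
#' @export
segmentAlleleFractions <- function(snpCounts, segments) {
  depth <- snpCounts$refDepth + snpCounts$altDepth
  major <- ifelse(depth > 0,
                  pmax(snpCounts$refDepth, snpCounts$altDepth) / depth, NA_real_)
  minor <- 1 - major
  segGr <- GRanges(segments$chrom, IRanges(segments$start + 1, segments$end))
  snpGr <- GRanges(snpCounts$chrom, IRanges(snpCounts$pos, snpCounts$pos))
  hit <- findOverlaps(snpGr, segGr, select = "first")
  out <- segments[, c("chrom", "start", "end")]
  out$nSnps <- 0L
  out$medianMajorPct <- NA_real_
  out$medianMinorPct <- NA_real_
  for (s in seq_len(nrow(segments))) {
    idx <- which(hit == s & !is.na(major))
    out$nSnps[s] <- length(idx)
    if (length(idx)) {
      out$medianMajorPct[s] <- 100 * medianLower(major[idx])
      out$medianMinorPct[s] <- 100 * medianLower(minor[idx])
    }
  }
  out$noSnps <- out$nSnps == 0L
  out
}

#' Simulate a diploid-normal pseudo-bulk reference track
#'
#' Sums a small simulated cohort of heterozygous diploid cells
#' ([normalCloneProfile()]) into one reference track for log2 fold-change
#' analysis against the tumor groups.
#'
#' @param model a [GenomeModel-class].
#' @param nCells cells to simulate, default 50.
#' @param readsPerMb,dispersion,seed as in [simulateCells()].
#' @return numeric per-bin reference track.
#' @export
simulateNormalReference <- function(model, nCells = 50, readsPerMb = 436,
                                    dispersion = 0.08, seed = 1) {
  normal <- normalCloneProfile(model)
  cohort <- simulateCells(model, list(normal = normal), c(normal = 1),
                          nCells = nCells, readsPerMb = readsPerMb,
                          dispersion = dispersion, seed = seed)
  colSums(countsMatrix(cohort))
}
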