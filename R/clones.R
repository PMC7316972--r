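#' Construct a clone profile from a baseline ploidy plus regional overrides
#'
#' Builds a haplotype-resolved copy-number profile covering every chromosome
#' of `model`: all positions start at `baseline` copies (hap1, hap2) and the
#' `overrides` regions replace the baseline. Override coordinates are 0-based
#' half-open bp and must not overlap each other.
#'
#' @param label clone label.
#' @param model a [GenomeModel-class].
#' @param overrides data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), `hap1`, `hap2`; may be `NULL`.
#' @param baseline length-2 integer vector, default `c(2, 1)` — the
#'   heterozygous near-triploid background.
#' @param junctions data.frame of breakend pairs (`name`, `chrom1`, `pos1`,
#'   `strand1`, `chrom2`, `pos2`, `strand2`, 1-based positions), or `NULL`.
#' @return a [CloneProfile-class].
#' @export
cloneProfile <- function(label, model, overrides = NULL, baseline = c(2, 1),
                         junctions = NULL) {
  genome <- GRanges(model@chromNames, IRanges(1, model@chromLengths))
  if (is.null(junctions))
    junctions <- data.frame(name = character(), chrom1 = character(),
                            pos1 = numeric(), strand1 = character(),
                            chrom2 = character(), pos2 = numeric(),
                            strand2 = character(), stringsAsFactors = FALSE)
  chromLen <- stats::setNames(model@chromLengths, model@chromNames)
  for (side in 1:2) {
    ch <- junctions[[paste0("chrom", side)]]
    po <- junctions[[paste0("pos", side)]]
    if (length(ch) && (any(!ch %in% model@chromNames) ||
                       any(po < 1 | po > chromLen[ch])))
      configError(sprintf("junction breakend outside the modeled genome (%s)", label))
  }
  if (is.null(overrides) || nrow(overrides) == 0) {
    reg <- genome
    S4Vectors::mcols(reg)$hap1 <- as.integer(baseline[1])
    S4Vectors::mcols(reg)$hap2 <- as.integer(baseline[2])
  } else {
    if (any(!overrides$chrom %in% model@chromNames))
      configError("override on a chromosome absent from the model")
    if (any(overrides$end > chromLen[overrides$chrom]) || any(overrides$start < 0))
      configError("override region outside the modeled genome")
    ovGr <- GRanges(overrides$chrom, IRanges(overrides$start + 1, overrides$end))
    S4Vectors::mcols(ovGr)$hap1 <- as.integer(overrides$hap1)
    S4Vectors::mcols(ovGr)$hap2 <- as.integer(overrides$hap2)
    rest <- GenomicRanges::setdiff(genome, ovGr)
    S4Vectors::mcols(rest)$hap1 <- as.integer(baseline[1])
    S4Vectors::mcols(rest)$hap2 <- as.integer(baseline[2])
    reg <- sort(c(ovGr, rest), ignore.strand = TRUE)
  }
  # constructor guarantees full coverage; validity re-checks overlap/ranges
  if (sum(width(reg)) != sum(model@chromLengths))
    configError("clone regions do not cover the modeled genome")
  new("CloneProfile", label = label, regions = reg, junctions = junctions)
}

#' Breakend pairs of the derivative chromosome 18
#'
#' The two junction fixtures of the derivative chromosome
#' (der18)(1pter->p22::10p14->10p11::18p11->18q) carried by two of the four
#' packaged clones: 1p22 joined to 10p14, and 10p11 joined to 18p11
#' (GRCh37 coordinates, 1-based). Strands follow BEDPE conventions and
#' encode which side of each breakend is retained on the derivative.
#'
#' @return a 2-row data.frame of breakend pairs.
#' @export
der18Junctions <- function() {
  data.frame(
    name = c("der18_1p22_10p14", "der18_10p11_18p11"),
    chrom1 = c("chr1", "chr10"), pos1 = c(87337015, 7634373),
    strand1 = c("+", "-"),
    chrom2 = c("chr10", "chr18"), pos2 = c(36119061, 9868810),
    strand2 = c("+", "-"),
    stringsAsFactors = FALSE)
}

#' The packaged four-clone COLO829-like model
#'
#' Returns the default study system: a GRCh37 autosomal genome, four
#' near-triploid clones A-D, and their default mixing proportions
#' (653:117:43:560 cells).
#'
#' All clones share a heterozygous triploid background (haplotype copies
#' 2+1) plus a set of clonal background rearrangements consistent with the
#' line's karyotype (1q gained to 4 copies, 9p and 16q lost to 2, a
#' copy-neutral-LOH 7q tip, a 15q-ter gain to 4, and 18pter at 2 copies).
#' The clones differ in two hallmark systems: chromosome 8 sits at total
#' copy 3 in clones A and B and at 4 in C and D; clones A and D carry the
#' derivative chromosome 18 (see [der18Junctions()]), which adds one
#' haplotype copy over 1pter-1p22.3, 10p14-10p11 and 18p11-qter. Clones B
#' and C lack it, leaving 1pter-1p22.3 at total copy 2 with complete loss
#' of one haplotype, the 10p segment likewise at 2+0, and chromosome 18 at
#' copy 2 throughout.
#'
#' @param binWidth bin width in bp for the genome model.
#' @return a list with elements `model` ([GenomeModel-class]), `clones`
#'   (named list of four [CloneProfile-class]), and `proportions` (named
#'   numeric, cells per clone among non-noisy cells).
#' @export
buildDefaultModel <- function(binWidth = 2e6) {
  model <- grch37Genome(binWidth = binWidth)
  jx <- der18Junctions()
  b1 <- jx$pos1[1]   # chr1:87,337,015
  b10a <- jx$pos1[2] # chr10:7,634,373
  b10b <- jx$pos2[1] # chr10:36,119,061
  b18 <- jx$pos2[2]  # chr18:9,868,810
  len <- stats::setNames(model@chromLengths, model@chromNames)
  shared <- data.frame(
    chrom = c("chr1", "chr9", "chr16", "chr7", "chr15", "chr18"),
    start = c(144e6, 0, 46e6, 152e6, 82e6, 0),
    end = c(len["chr1"], 40e6, len["chr16"], len["chr7"], len["chr15"], b18),
    hap1 = c(2L, 1L, 1L, 2L, 2L, 1L),
    hap2 = c(2L, 1L, 1L, 0L, 2L, 1L), stringsAsFactors = FALSE)
  variable <- function(der, chr8hap2) {
    rbind(shared, data.frame(
      chrom = c("chr1", "chr10", "chr18", "chr8"),
      start = c(0, b10a, b18, 0),
      end = c(b1, b10b, len["chr18"], len["chr8"]),
      hap1 = c(2L, 2L, if (der) 2L else 1L, 2L),
      hap2 = c(if (der) 1L else 0L, if (der) 1L else 0L, 1L, chr8hap2),
      stringsAsFactors = FALSE))
  }
  clones <- list(
    A = cloneProfile("A", model, variable(der = TRUE,  chr8hap2 = 1L), junctions = jx),
    B = cloneProfile("B", model, variable(der = FALSE, chr8hap2 = 1L)),
    C = cloneProfile("C", model, variable(der = FALSE, chr8hap2 = 2L)),
    D = cloneProfile("D", model, variable(der = TRUE,  chr8hap2 = 2L), junctions = jx))
  list(model = model, clones = clones,
       proportions = c(A = 653, B = 117, C = 43, D = 560))
}

#' A diploid heterozygous "matched normal" clone
#'
#' One haplotype copy each over the whole genome; used to generate the
#' diploid reference track for log2 fold-change analysis.
#'
#' @param model a [GenomeModel-class].
#' @return a [CloneProfile-class].
#' @export
normalCloneProfile <- function(model) {
  cloneProfile("normal", model, baseline = c(1, 1))
}
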