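#' Construct a binned genome model
#'
#' @param chromLengths named numeric vector of chromosome lengths in bp.
#' @param binWidth bin width in bp (default 2 Mb, the resolution used for
#'   all binned copy-number operations).
#' @return a [GenomeModel-class].
#' @examples
#' gm <- genomeModel(c(chrA = 5e6, chrB = 3e6), binWidth = 2e6)
#' length(genomeBins(gm))  # ceil(5/2) + ceil(3/2) = 5
#' @export
genomeModel <- function(chromLengths, binWidth = 2e6) {
  if (is.null(names(chromLengths)) || any(names(chromLengths) == ""))
    configError("chromLengths must be a named vector")
  if (binWidth <= 0) configError("binWidth must be positive")
  chroms <- names(chromLengths)
  starts <- ends <- seqn <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    len <- chromLengths[i]
    s <- seq(1, len, by = binWidth)
    e <- pmin(s + binWidth - 1, len)
    starts[[i]] <- s; ends[[i]] <- e
    seqn[[i]] <- rep(chroms[i], length(s))
  }
  bins <- GRanges(unlist(seqn), IRanges(unlist(starts), unlist(ends)))
  S4Vectors::mcols(bins)$bin <- seq_along(bins)
  new("GenomeModel", chromNames = chroms,
      chromLengths = as.numeric(chromLengths), binWidth = binWidth, bins = bins)
}

#' GRCh37 autosomal genome model
#'
#' Chromosomes 1-22 at their GRCh37 lengths (sex chromosomes omitted), binned
#' at the given width. Printed breakend coordinates from the packaged clone
#' model are representable on this genome.
#'
#' @param binWidth bin width in bp.
#' @return a [GenomeModel-class].
#' @export
grch37Genome <- function(binWidth = 2e6) {
  lens <- c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430,
            chr4 = 191154276, chr5 = 180915260, chr6 = 171115067,
            chr7 = 159138663, chr8 = 146364022, chr9 = 141213431,
            chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
            chr13 = 115169878, chr14 = 107349540, chr15 = 102531392,
            chr16 = 90354753, chr17 = 81195210, chr18 = 78077248,
            chr19 = 59128983, chr20 = 63025520, chr21 = 48129895,
            chr22 = 51304566)
  genomeModel(lens, binWidth = binWidth)
}

#' Miniature three-chromosome genome for fast tests
#'
#' @param binWidth bin width in bp.
#' @return a [GenomeModel-class] with chromosomes of 30, 24 and 16 Mb.
#' @export
toyGenome <- function(binWidth = 2e6) {
  genomeModel(c(chrA = 30e6, chrB = 24e6, chrC = 16e6), binWidth = binWidth)
}

# bin ids of the form "chr1:1-2000000", used as count-matrix column names
binIds <- function(model) {
  b <- model@bins
  sprintf("%s:%d-%d", as.character(seqnames(b)), start(b), end(b))
}

# genome length in bp
genomeLength <- function(model) sum(model@chromLengths)

#' Expected total copy number of a clone over genome bins
#'
#' Overlap-weighted average of the clone's region copy numbers over each bin
#' of the model; bins straddling a region boundary get fractional values.
#'
#' @param clone a [CloneProfile-class].
#' @param model a [GenomeModel-class].
#' @return numeric vector, one value per bin.
#' @export
binCopy <- function(clone, model) {
  bins <- model@bins
  reg <- clone@regions
  mc <- S4Vectors::mcols(reg)
  tot <- mc$hap1 + mc$hap2
  ov <- findOverlaps(bins, reg)
  w <- width(pintersect(bins[queryHits(ov)], reg[subjectHits(ov)]))
  num <- tapply(w * tot[subjectHits(ov)], queryHits(ov), sum)
  cp <- numeric(length(bins))
  cp[as.integer(names(num))] <- num / width(bins)[as.integer(names(num))]
  cp
}

# length-weighted mean copy number of a clone over the whole genome
cloneMeanCopy <- function(clone) {
  mc <- S4Vectors::mcols(clone@regions)
  w <- width(clone@regions)
  sum(w * (mc$hap1 + mc$hap2)) / sum(w)
}
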