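#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps pintersect
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' GenomeModel: a binned reference genome
#'
#' Chromosome names and lengths plus a fixed-width bin tiling used for all
#' binned read-count operations. Bins tile each chromosome left to right
#' without overlap; the last bin of a chromosome may be short.
#'
#' @slot chromNames character, chromosome names in order.
#' @slot chromLengths numeric, chromosome lengths in bp (same order).
#' @slot binWidth numeric, nominal bin width in bp.
#' @slot bins a `GRanges` with one range per bin, carrying an integer `bin`
#'   index column ordered over the whole genome.
#' @export
setClass("GenomeModel",
  representation(chromNames = "character", chromLengths = "numeric",
                 binWidth = "numeric", bins = "GRanges"))

setValidity("GenomeModel", function(object) {
  msgs <- character()
  if (length(object@chromNames) != length(object@chromLengths))
    msgs <- c(msgs, "chromNames and chromLengths differ in length")
  if (any(object@chromLengths <= 0)) msgs <- c(msgs, "chromosome lengths must be positive")
  if (object@binWidth <= 0) msgs <- c(msgs, "binWidth must be positive")
  expected <- sum(ceiling(object@chromLengths / object@binWidth))
  if (length(object@bins) != expected)
    msgs <- c(msgs, sprintf("bin count %d != sum of ceil(length/width) = %d",
                            length(object@bins), expected))
  # bins must tile each chromosome contiguously
  for (i in seq_along(object@chromNames)) {
    b <- object@bins[as.character(seqnames(object@bins)) == object@chromNames[i]]
    if (length(b) == 0) { msgs <- c(msgs, "chromosome without bins"); next }
    s <- start(b); e <- end(b)
    if (s[1] != 1 || e[length(e)] != object@chromLengths[i] ||
        (length(b) > 1 && any(s[-1] != e[-length(e)] + 1)))
      msgs <- c(msgs, sprintf("bins do not tile %s", object@chromNames[i]))
  }
  if (length(msgs)) msgs else TRUE
})

#' CloneProfile: haplotype-resolved copy number of one sub-clone
#'
#' Regions partition every modeled chromosome; each carries non-negative
#' integer copies of the two haplotypes. Junction rows describe
#' structural-variant breakend pairs carried by the clone (BEDPE-style
#' strands give breakend orientation).
#'
#' @slot label clone label, e.g. "A".
#' @slot regions `GRanges` with integer metadata columns `hap1` and `hap2`.
#' @slot junctions data.frame with columns `name`, `chrom1`, `pos1`,
#'   `strand1`, `chrom2`, `pos2`, `strand2` (1-based positions).
#' @export
setClass("CloneProfile",
  representation(label = "character", regions = "GRanges", junctions = "data.frame"))

setValidity("CloneProfile", function(object) {
  msgs <- character()
  mc <- S4Vectors::mcols(object@regions)
  if (!all(c("hap1", "hap2") %in% colnames(mc)))
    return("regions must carry hap1 and hap2 columns")
  if (any(mc$hap1 < 0) || any(mc$hap2 < 0)) msgs <- c(msgs, "haplotype copies must be >= 0")
  if (any(mc$hap1 != round(mc$hap1)) || any(mc$hap2 != round(mc$hap2)))
    msgs <- c(msgs, "haplotype copies must be integers")
  ov <- findOverlaps(object@regions, drop.self = TRUE)
  if (length(ov) > 0) msgs <- c(msgs, "regions overlap within the clone")
  jc <- c("name", "chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
  if (nrow(object@junctions) > 0 && !all(jc %in% colnames(object@junctions)))
    msgs <- c(msgs, "junction table lacks required columns")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticCohort: a simulated single-cell binned-count cohort
#'
#' @slot counts integer matrix, cells (rows, named by barcode) x bins.
#' @slot truth data.frame with `barcode`, `clone`, `noisy`, `seed`.
#' @slot model the [GenomeModel-class] the counts were binned on.
#' @slot clones named list of [CloneProfile-class] objects.
#' @slot params list of generator arguments (reads per Mb, dispersion,
#'   proportions, the cohort ploidy-scaling constant, seed).
#' @export
setClass("SyntheticCohort",
  representation(counts = "matrix", truth = "data.frame", model = "GenomeModel",
                 clones = "list", params = "list"))

setValidity("SyntheticCohort", function(object) {
  msgs <- character()
  if (nrow(object@truth) != nrow(object@counts))
    msgs <- c(msgs, "truth rows != count rows")
  if (anyDuplicated(object@truth$barcode)) msgs <- c(msgs, "barcodes not unique")
  if (!all(object@truth$clone %in% names(object@clones)))
    msgs <- c(msgs, "truth clone labels not all present in the model")
  if (ncol(object@counts) != length(object@model@bins))
    msgs <- c(msgs, "count columns != model bins")
  if (length(msgs)) msgs else TRUE
})

#' CellCnvCalls: per-cell segmented integer copy-number profiles
#'
#' Cohort-level container for the output of per-cell CNV calling: one row per
#' segment in `calls`, one row per cell in `cellSummary`.
#'
#' @slot calls data.frame: `chrom`, `start`, `end` (0-based half-open bp),
#'   `barcode`, `copy`, `confidence`.
#' @slot summary data.frame: `barcode`, `meanPloidy`, `scale`, `fitError`,
#'   `noiseMad`, `noisy`.
#' @slot model the [GenomeModel-class] used.
#' @slot params list of caller parameters.
#' @export
setClass("CellCnvCalls",
  representation(calls = "data.frame", summary = "data.frame",
                 model = "GenomeModel", params = "list"))

setValidity("CellCnvCalls", function(object) {
  msgs <- character()
  need <- c("chrom", "start", "end", "barcode", "copy", "confidence")
  if (!all(need %in% colnames(object@calls))) msgs <- c(msgs, "calls lack required columns")
  if (anyDuplicated(object@summary$barcode)) msgs <- c(msgs, "duplicate barcodes in summary")
  if (any(!is.finite(object@calls$confidence))) msgs <- c(msgs, "non-finite confidence")
  if (length(msgs)) msgs else TRUE
})

#' EventMatrix: binary cells x merged-CNV-events matrix
#'
#' The clustering substrate: rows are non-noisy cell barcodes, columns are
#' merged CNV event clusters (identical copy number, >= 90% reciprocal
#' overlap by default), entries are 0/1 membership. Columns below the
#' prevalence floor have already been dropped.
#'
#' @slot mat integer 0/1 matrix with barcode rownames.
#' @slot events data.frame describing each column: `chrom`, `start`, `end`,
#'   `copy`, `nCells`, `prevalence`, `sizeBp`.
#' @slot params list of filter/merge parameters used (provenance).
#' @export
setClass("EventMatrix",
  representation(mat = "matrix", events = "data.frame", params = "list"))

setValidity("EventMatrix", function(object) {
  msgs <- character()
  if (!all(object@mat %in% c(0L, 1L))) msgs <- c(msgs, "entries must be 0/1")
  if (ncol(object@mat) != nrow(object@events))
    msgs <- c(msgs, "event annotation rows != matrix columns")
  if (anyDuplicated(rownames(object@mat))) msgs <- c(msgs, "duplicate barcodes")
  if (length(msgs)) msgs else TRUE
})

#' ClusterSolution: DAPC clustering of the event matrix
#'
#' Holds the PCA embedding dimension, the BIC curve over candidate k, the
#' chosen k and per-cell cluster labels, the discriminant axes (per-cell
#' scores and between/within variance-ratio eigenvalues), and the merged
#' major-group labels.
#'
#' @slot nPcs integer, retained principal components.
#' @slot bic data.frame `k`, `withinSS`, `bic` over the scanned range.
#' @slot k chosen number of clusters.
#' @slot clusters integer vector, per-cell cluster label in 1..k.
#' @slot scores matrix of per-cell discriminant-axis scores.
#' @slot eigenvalues numeric, between/within variance ratio per axis,
#'   non-increasing.
#' @slot groups character vector, per-cell major-group letter.
#' @slot groupMap data.frame `cluster` -> `group`.
#' @slot consensus 0/1 matrix: cluster consensus over hallmark events.
#' @slot barcodes character, cell barcodes in row order.
#' @slot params list of clustering parameters.
#' @export
setClass("ClusterSolution",
  representation(nPcs = "integer", bic = "data.frame", k = "integer",
                 clusters = "integer", scores = "matrix",
                 eigenvalues = "numeric", groups = "character",
                 groupMap = "data.frame", consensus = "matrix",
                 barcodes = "character", params = "list"))

setValidity("ClusterSolution", function(object) {
  msgs <- character()
  n <- length(object@barcodes)
  if (length(object@clusters) != n || length(object@groups) != n)
    msgs <- c(msgs, "per-cell labels must match barcode count")
  ev <- object@eigenvalues
  if (length(ev) && (any(ev < -1e-8) || is.unsorted(rev(ev), strictly = FALSE)))
    msgs <- c(msgs, "eigenvalues must be non-negative and non-increasing")
  if (length(ev) > max(1L, object@k - 1L))
    msgs <- c(msgs, "more discriminant axes than k - 1")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GenomeModel", function(object) {
  cat(sprintf("GenomeModel: %d chromosomes, %.0f bp bins, %d bins total\n",
              length(object@chromNames), object@binWidth, length(object@bins)))
})

setMethod("show", "CloneProfile", function(object) {
  mc <- S4Vectors::mcols(object@regions)
  tot <- mc$hap1 + mc$hap2
  w <- width(object@regions)
  cat(sprintf("CloneProfile %s: %d regions, mean copy %.2f, %d junction(s)\n",
              object@label, length(object@regions),
              sum(w * tot) / sum(w), nrow(object@junctions)))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d cells x %d bins; clones: %s; %d noisy\n",
              nrow(object@counts), ncol(object@counts),
              paste(names(object@clones), collapse = ","),
              sum(object@truth$noisy)))
})

setMethod("show", "CellCnvCalls", function(object) {
  cat(sprintf("CellCnvCalls: %d cells, %d segments, %d flagged noisy\n",
              nrow(object@summary), nrow(object@calls), sum(object@summary$noisy)))
})

setMethod("show", "EventMatrix", function(object) {
  cat(sprintf("EventMatrix: %d cells x %d events (prevalence >= %s)\n",
              nrow(object@mat), ncol(object@mat),
              format(object@params$minPrevalence %||% NA)))
})

setMethod("show", "ClusterSolution", function(object) {
  cat(sprintf("ClusterSolution: k = %d clusters -> %d groups (%s), %d PCs\n",
              object@k, nrow(unique(object@groupMap["group"])),
              paste(sprintf("%s:%d", names(table(object@groups)),
                            as.integer(table(object@groups))), collapse = " "),
              object@nPcs))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- accessors ----

#' @describeIn GenomeModel-class bins as a `GRanges`.
#' @param object a GenomeModel.
#' @export
setGeneric("genomeBins", function(object) standardGeneric("genomeBins"))
#' @export
setMethod("genomeBins", "GenomeModel", function(object) object@bins)

#' Accessors for cohort and call containers
#'
#' `countsMatrix()` returns the cells x bins count matrix; `cohortTruth()`
#' the per-cell truth table; `cnvSegments()` the per-cell segment calls;
#' `cellSummary()` per-cell ploidy/scale/noise summaries; `eventTable()` the
#' per-column event annotation of an [EventMatrix-class]; `binaryMatrix()`
#' its 0/1 matrix; `groupAssignment()` the barcode -> cluster/group table of
#' a [ClusterSolution-class]; `bicCurve()` its BIC scan.
#'
#' @param object the container.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("countsMatrix", function(object) standardGeneric("countsMatrix"))
#' @rdname accessors
#' @export
setMethod("countsMatrix", "SyntheticCohort", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))
#' @rdname accessors
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(object) object@truth)

#' @rdname accessors
#' @export
setGeneric("cnvSegments", function(object) standardGeneric("cnvSegments"))
#' @rdname accessors
#' @export
setMethod("cnvSegments", "CellCnvCalls", function(object) object@calls)

#' @rdname accessors
#' @export
setGeneric("cellSummary", function(object) standardGeneric("cellSummary"))
#' @rdname accessors
#' @export
setMethod("cellSummary", "CellCnvCalls", function(object) object@summary)

#' @rdname accessors
#' @export
setGeneric("eventTable", function(object) standardGeneric("eventTable"))
#' @rdname accessors
#' @export
setMethod("eventTable", "EventMatrix", function(object) object@events)

#' @rdname accessors
#' @export
setGeneric("binaryMatrix", function(object) standardGeneric("binaryMatrix"))
#' @rdname accessors
#' @export
setMethod("binaryMatrix", "EventMatrix", function(object) object@mat)

#' @rdname accessors
#' @export
setGeneric("groupAssignment", function(object) standardGeneric("groupAssignment"))
#' @rdname accessors
#' @export
setMethod("groupAssignment", "ClusterSolution", function(object) {
  data.frame(barcode = object@barcodes, cluster = object@clusters,
             group = object@groups, stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setGeneric("bicCurve", function(object) standardGeneric("bicCurve"))
#' @rdname accessors
#' @export
setMethod("bicCurve", "ClusterSolution", function(object) object@bic)

#' @rdname accessors
#' @export
setGeneric("cloneRegions", function(object) standardGeneric("cloneRegions"))
#' @rdname accessors
#' @export
setMethod("cloneRegions", "CloneProfile", function(object) object@regions)

#' @rdname accessors
#' @export
setGeneric("cloneJunctions", function(object) standardGeneric("cloneJunctions"))
#' @rdname accessors
#' @export
setMethod("cloneJunctions", "CloneProfile", function(object) object@junctions)

#' @rdname accessors
#' @export
setGeneric("cloneLabel", function(object) standardGeneric("cloneLabel"))
#' @rdname accessors
#' @export
setMethod("cloneLabel", "CloneProfile", function(object) object@label)
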