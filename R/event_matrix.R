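#' Filter per-cell CNV events by size and confidence
#'
#' Retains events whose size is strictly greater than `minSizeBp` and whose
#' confidence is strictly greater than `minConfidence` (the study defaults:
#' > 2 Mb and quality > 15). Input order is preserved.
#'
#' @param events data.frame with `chrom`, `start`, `end`, `copy`,
#'   `confidence`, `barcode` (0-based half-open coordinates), e.g.
#'   `cnvSegments()` of a [CellCnvCalls-class].
#' @param minSizeBp minimum size in bp (exclusive), default 2e6.
#' @param minConfidence minimum confidence (exclusive), default 15.
#' @return the retained rows.
#' @export
filterEvents <- function(events, minSizeBp = 2e6, minConfidence = 15) {
  keep <- (events$end - events$start) > minSizeBp & events$confidence > minConfidence
  events[keep, , drop = FALSE]
}

#' Reciprocal overlap between two genomic intervals
#'
#' `min(overlap / |a|, overlap / |b|)`; 0 for intervals on different
#' chromosomes or disjoint intervals. Symmetric. Vectorized over rows.
#'
#' @param chromA,startA,endA first interval(s), 0-based half-open.
#' @param chromB,startB,endB second interval(s).
#' @return numeric fraction(s) in `[0, 1]`.
#' @export
reciprocalOverlap <- function(chromA, startA, endA, chromB, startB, endB) {
  ov <- pmax(0, pmin(endA, endB) - pmax(startA, startB))
  res <- pmin(ov / (endA - startA), ov / (endB - startB))
  res[chromA != chromB] <- 0
  res
}

# union-find with path compression
ufFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Merge equivalent CNV events across cells
#'
#' Groups filtered events by single-linkage over the relation "identical
#' copy number AND reciprocal overlap >= `roThreshold`" (inclusive, so
#' identical intervals always merge). Events are processed in
#' (chrom, start, end, barcode) order, making the partition independent of
#' input row order. Each cluster's canonical interval is the coordinate-wise
#' (lower) median of its members — the convention later reused for median
#' breakpoint locations.
#'
#' @param events filtered events data.frame (see [filterEvents()]).
#' @param roThreshold reciprocal-overlap threshold, default 0.90.
#' @return list: `clusters` (data.frame `chrom`, `start`, `end`, `copy`,
#'   `nEvents`, `nCells`, `sizeBp`) and `members` (data.frame `cluster`,
#'   `barcode`, one row per member event).
#' @export
mergeEvents <- function(events, roThreshold = 0.90) {
  if (nrow(events) == 0)
    return(list(clusters = data.frame(chrom = character(), start = numeric(),
                                      end = numeric(), copy = integer(),
                                      nEvents = integer(), nCells = integer(),
                                      sizeBp = numeric(), stringsAsFactors = FALSE),
                members = data.frame(cluster = integer(), barcode = character(),
                                     stringsAsFactors = FALSE)))
  ord <- order(events$chrom, events$start, events$end, events$barcode)
  ev <- events[ord, , drop = FALSE]
  n <- nrow(ev)
  # linkage depends only on (chrom, start, end, copy): collapse to unique
  # event shapes, link those, then expand back to member events
  shapeKey <- paste(ev$chrom, ev$start, ev$end, ev$copy)
  shapes <- which(!duplicated(shapeKey))
  shapeOf <- match(shapeKey, shapeKey[shapes])
  us <- ev[shapes, , drop = FALSE]
  m <- nrow(us)
  parent <- seq_len(m)
  gr <- GRanges(us$chrom, IRanges(us$start + 1, us$end))
  key <- paste(us$chrom, us$copy)
  hits <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  qi <- queryHits(hits); si <- subjectHits(hits)
  same <- key[qi] == key[si]
  qi <- qi[same]; si <- si[same]
  if (length(qi)) {
    ro <- reciprocalOverlap(us$chrom[qi], us$start[qi], us$end[qi],
                            us$chrom[si], us$start[si], us$end[si])
    link <- ro >= roThreshold
    for (e in which(link)) {
      a <- ufFind(parent, qi[e]); b <- ufFind(parent, si[e])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(m), function(i) ufFind(parent, i), integer(1))
  # cluster ids in first-appearance (sorted) order, expanded to all events
  cid <- match(root, unique(root))[shapeOf]
  clusters <- do.call(rbind, lapply(seq_len(max(cid)), function(k) {
    m <- which(cid == k)
    data.frame(chrom = ev$chrom[m[1]],
               start = medianLower(ev$start[m]),
               end = medianLower(ev$end[m]),
               copy = ev$copy[m[1]],
               nEvents = length(m),
               nCells = length(unique(ev$barcode[m])),
               stringsAsFactors = FALSE)
  }))
  clusters$sizeBp <- clusters$end - clusters$start
  list(clusters = clusters,
       members = data.frame(cluster = cid, barcode = ev$barcode,
                            stringsAsFactors = FALSE))
}

#' Build the binary cells x events matrix
#'
#' Entry (cell, cluster) is 1 iff the cell contributed a member event to the
#' cluster. Clusters present in fewer than `minPrevalence` of the supplied
#' cells are discarded; cells without any event are retained as all-zero
#' rows.
#'
#' @param merged output of [mergeEvents()].
#' @param barcodes all non-noisy cell barcodes (deduplicated).
#' @param minPrevalence minimum member-cell fraction per column (events
#'   below it are dropped), default 0.05.
#' @return an [EventMatrix-class].
#' @export
buildEventMatrix <- function(merged, barcodes, minPrevalence = 0.05) {
  if (anyDuplicated(barcodes)) configError("barcodes must be deduplicated")
  unknown <- setdiff(unique(merged$members$barcode), barcodes)
  if (length(unknown))
    dataError(sprintf("event cluster references unknown barcode(s): %s",
                      paste(utils::head(unknown, 3), collapse = ", ")))
  nClust <- nrow(merged$clusters)
  mat <- matrix(0L, nrow = length(barcodes), ncol = nClust,
                dimnames = list(barcodes, NULL))
  if (nClust > 0 && nrow(merged$members) > 0) {
    ri <- match(merged$members$barcode, barcodes)
    mat[cbind(ri, merged$members$cluster)] <- 1L
  }
  prevalence <- colMeans(mat)
  keep <- which(prevalence >= minPrevalence)
  events <- merged$clusters[keep, , drop = FALSE]
  events$prevalence <- prevalence[keep]
  mat <- mat[, keep, drop = FALSE]
  colnames(mat) <- sprintf("%s:%d-%d_cn%d", events$chrom, events$start,
                           events$end, events$copy)
  rownames(events) <- colnames(mat)
  new("EventMatrix", mat = mat, events = events,
      params = list(minPrevalence = minPrevalence))
}

#' One-call construction of the event matrix from per-cell CNV calls
#'
#' Applies [filterEvents()], [mergeEvents()] and [buildEventMatrix()] with
#' the study's default thresholds, using the non-noisy cells of `calls`.
#'
#' @param calls a [CellCnvCalls-class].
#' @param minSizeBp,minConfidence see [filterEvents()].
#' @param roThreshold see [mergeEvents()].
#' @param minPrevalence see [buildEventMatrix()].
#' @param barcodes cells to include; defaults to the non-noisy barcodes.
#' @return an [EventMatrix-class].
#' @export
eventMatrixFromCalls <- function(calls, minSizeBp = 2e6, minConfidence = 15,
                                 roThreshold = 0.90, minPrevalence = 0.05,
                                 barcodes = NULL) {
  summ <- cellSummary(calls)
  if (is.null(barcodes)) barcodes <- summ$barcode[!summ$noisy]
  ev <- cnvSegments(calls)
  ev <- ev[ev$barcode %in% barcodes, , drop = FALSE]
  ev <- filterEvents(ev, minSizeBp = minSizeBp, minConfidence = minConfidence)
  merged <- mergeEvents(ev, roThreshold = roThreshold)
  em <- buildEventMatrix(merged, barcodes, minPrevalence = minPrevalence)
  em@params <- c(em@params, list(minSizeBp = minSizeBp,
                                 minConfidence = minConfidence,
                                 roThreshold = roThreshold))
  em
}
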