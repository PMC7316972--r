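#' Normalize cell bin counts against a per-bin reference
#'
#' Divides each cell's bin counts by a per-bin reference profile — for real
#' data typically a cohort-median or normal-panel profile carrying the
#' technical (GC / mappability) bin bias. Bins whose reference is zero or
#' non-finite are masked: they are dropped from the output and excluded from
#' all downstream computation.
#'
#' Note that on cohorts whose cells *share* true copy-number events, a
#' cohort median per bin absorbs the shared biology as well as the bias; the
#' packaged pipeline therefore scales by a flat per-bp reference (see
#' [scaledDepth()]) and reserves this function for externally supplied bias
#' profiles.
#'
#' @param counts numeric vector (one cell) or matrix (cells x bins).
#' @param binReference per-bin reference values, length = number of bins.
#' @return normalized counts with masked bins removed; the retained bin
#'   indices are in attribute `keptBins`.
#' @export
normalizeCounts <- function(counts, binReference) {
  vec <- is.null(dim(counts))
  m <- if (vec) matrix(counts, nrow = 1) else counts
  if (ncol(m) != length(binReference))
    dataError("counts and binReference disagree on bin count")
  keep <- which(is.finite(binReference) & binReference > 0)
  if (length(keep) == 0) dataError("no usable bins: all bin references are zero")
  out <- sweep(m[, keep, drop = FALSE], 2, binReference[keep], `/`)
  if (vec) out <- out[1, ]
  attr(out, "keptBins") <- keep
  out
}

#' Per-cell scaled (relative) depth over bins
#'
#' Converts raw bin counts to ploidy-normalized relative depth: counts are
#' turned into per-bp rates (correcting short terminal bins), optionally
#' divided by user-supplied per-bin bias weights, and scaled so the
#' length-weighted genome mean is 1. For a cell of mean copy number P the
#' result approximates `copy / P` per bin — the quantity the integer-lattice
#' scale fit consumes.
#'
#' Terminal bins shorter than `minBinFraction` of the nominal bin width are
#' masked: their per-bp rate is unbiased but so noisy (down to tens of reads
#' at shallow depth) that they would seed spurious one-bin segments.
#'
#' @param counts numeric vector (one cell) or matrix (cells x bins).
#' @param model a [GenomeModel-class].
#' @param weights optional per-bin bias weights (mean ~1); zero/non-finite
#'   weights mask the bin (returned as `NA`).
#' @param minBinFraction smallest usable bin width as a fraction of the
#'   nominal width, default 0.25.
#' @return same shape as `counts`, relative depth with masked bins `NA`.
#' @export
scaledDepth <- function(counts, model, weights = NULL, minBinFraction = 0.25) {
  vec <- is.null(dim(counts))
  m <- if (vec) matrix(counts, nrow = 1) else counts
  w <- width(model@bins)
  if (ncol(m) != length(w)) dataError("counts do not match the model's bins")
  rate <- sweep(m, 2, w, `/`)
  mask <- w < minBinFraction * model@binWidth
  if (!is.null(weights)) {
    mask <- mask | !is.finite(weights) | weights <= 0
    rate[, !mask] <- sweep(rate[, !mask, drop = FALSE], 2, weights[!mask], `/`)
  }
  if (all(mask)) dataError("no usable bins: all bins masked by weights")
  wk <- w[!mask]
  meanRate <- as.vector(rate[, !mask, drop = FALSE] %*% wk) / sum(wk)
  out <- rate / meanRate
  out[, mask] <- NA_real_
  if (vec) out[1, ] else out
}

# ---- changepoint segmentation -------------------------------------------

# exhaustive best single split of x[lo..hi]; returns reduction in SSE and
# split index (last index of the left part), via cumulative sums
bestSplit <- function(cs, cs2, lo, hi) {
  n <- hi - lo + 1
  if (n < 2) return(list(gain = -Inf, at = NA_integer_))
  sAll <- cs[hi + 1] - cs[lo]
  sse <- function(s, s2, k) s2 - s^2 / k
  s2All <- cs2[hi + 1] - cs2[lo]
  ks <- seq_len(n - 1)
  sl <- cs[lo + ks] - cs[lo]
  s2l <- cs2[lo + ks] - cs2[lo]
  gains <- sse(sAll, s2All, n) - sse(sl, s2l, ks) - sse(sAll - sl, s2All - s2l, n - ks)
  i <- which.max(gains)
  list(gain = gains[i], at = lo + ks[i] - 1)
}

# penalized binary segmentation of one numeric vector; returns sorted
# changepoints (last index of each segment, excluding the final index)
binarySegment <- function(x, penalty) {
  n <- length(x)
  if (n < 2) return(integer(0))
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  cps <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    sp <- bestSplit(cs, cs2, seg[1], seg[2])
    if (is.finite(sp$gain) && sp$gain > penalty) {
      cps <- c(cps, sp$at)
      if (sp$at > seg[1]) stack[[length(stack) + 1]] <- c(seg[1], sp$at)
      if (sp$at + 1 < seg[2]) stack[[length(stack) + 1]] <- c(sp$at + 1L, seg[2])
    }
  }
  sort(cps)
}

#' Robust per-bin noise variance of a depth profile
#'
#' Estimated from the median absolute successive difference (scaled to the
#' normal), which is insensitive to the copy-number steps themselves.
#'
#' @param x numeric per-bin depth values.
#' @return the estimated per-bin variance.
#' @export
noiseVariance <- function(x) {
  d <- diff(x)
  d <- d[is.finite(d)]
  if (length(d) < 2) return(0)
  (stats::median(abs(d - stats::median(d))) * 1.4826 / sqrt(2))^2
}

#' Segment a per-bin scaled-depth profile
#'
#' Penalized least-squares changepoint detection (binary segmentation) run
#' independently per chromosome, so segments never span chromosome
#' boundaries. The default penalty is `1.5 * log(nBins) * sigma^2` with the
#' noise variance estimated robustly from successive bin differences across
#' the genome — calibrated so a one-copy arm-scale step at the default
#' cohort depth clears the penalty while chance splits of uniform noise
#' remain rare; `penalty = Inf` returns one segment per chromosome. Masked
#' (`NA`) bins are excluded.
#'
#' @param scaled numeric vector of per-bin scaled depth (one cell).
#' @param model a [GenomeModel-class].
#' @param penalty SSE-reduction threshold for accepting a changepoint;
#'   `NULL` for the default.
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open bp),
#'   `firstBin`, `lastBin` (genome-wide bin indices), `nBins`, `meanDepth`.
#' @export
segmentProfile <- function(scaled, model, penalty = NULL) {
  bins <- model@bins
  chroms <- as.character(seqnames(bins))
  ok <- is.finite(scaled)
  if (is.null(penalty)) {
    s2 <- noiseVariance(scaled[ok])
    penalty <- 1.5 * log(sum(ok)) * s2
  }
  # floor guards constant profiles against floating-point SSE residue
  penalty <- max(penalty, 1e-8)
  out <- list()
  for (ch in model@chromNames) {
    idx <- which(chroms == ch & ok)
    if (length(idx) == 0) next
    x <- scaled[idx]
    cps <- if (is.infinite(penalty)) integer(0) else binarySegment(x, penalty)
    bounds <- c(0, cps, length(x))
    for (si in seq_len(length(bounds) - 1)) {
      i1 <- bounds[si] + 1; i2 <- bounds[si + 1]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch,
        start = start(bins)[idx[i1]] - 1,
        end = end(bins)[idx[i2]],
        firstBin = idx[i1], lastBin = idx[i2],
        nBins = i2 - i1 + 1,
        meanDepth = mean(x[i1:i2]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Candidate breakpoints from the pooled cohort profile
#'
#' Segments the cohort-summed depth profile (whose noise shrinks with the
#' square root of the cell count, so even clone-shared steps too subtle for
#' any single cell are located precisely) and returns the changepoint bin
#' indices per chromosome. Used as the candidate set for joint per-cell
#' segmentation.
#'
#' @param counts cells x bins count matrix.
#' @param model a [GenomeModel-class].
#' @param penalty optional override of the segmentation penalty.
#' @return integer vector of genome-wide bin indices (the last bin of each
#'   segment, chromosome-internal boundaries only).
#' @export
cohortBreakpoints <- function(counts, model, penalty = NULL) {
  pooled <- colSums(counts)
  r <- scaledDepth(pooled, model)
  sigma2 <- noiseVariance(r[is.finite(r)])
  pen <- penalty %||% (1.5 * log(sum(is.finite(r))) * sigma2)
  segs <- segmentProfile(r, model, penalty = pen)
  segs <- refineSegments(r, segs, pen, model, sigma2)
  chromLast <- tapply(S4Vectors::mcols(model@bins)$bin,
                      as.character(seqnames(model@bins)), max)
  setdiff(segs$lastBin, as.integer(chromLast))
}

#' Segment one cell on a shared candidate-breakpoint set
#'
#' Joint segmentation step: the cell is cut at every candidate breakpoint.
#' Over-splitting is deliberate — where the cell's clone lacks a step the
#' two flanking segments round to the same copy number and are re-merged by
#' [mergeAdjacentSegments()] after integer assignment. Because every cell
#' uses one shared boundary set, the final segments have identical
#' coordinates across cells carrying the same events, which makes
#' downstream reciprocal-overlap merging of events essentially exact.
#'
#' @param scaled per-bin scaled depth of the cell.
#' @param model a [GenomeModel-class].
#' @param candidates genome-wide candidate breakpoint bins (from
#'   [cohortBreakpoints()]).
#' @return segments data.frame as from [segmentProfile()].
#' @export
segmentWithBreakpoints <- function(scaled, model, candidates) {
  bins <- model@bins
  chroms <- as.character(seqnames(bins))
  out <- list()
  for (ch in model@chromNames) {
    idx <- which(chroms == ch & is.finite(scaled))
    if (length(idx) == 0) next
    cuts <- sort(intersect(candidates, idx[-length(idx)]))
    bounds <- c(idx[1] - 1L, cuts, idx[length(idx)])
    for (s in seq_len(length(bounds) - 1)) {
      sel <- idx[idx > bounds[s] & idx <= bounds[s + 1]]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = start(bins)[min(sel)] - 1, end = end(bins)[max(sel)],
        firstBin = min(sel), lastBin = max(sel), nBins = length(sel),
        meanDepth = mean(scaled[sel]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Merge adjacent segments sharing a copy number
#'
#' Collapses runs of same-chromosome, same-copy adjacent segments into one
#' segment (mean depth re-averaged by bin count). Applied after integer
#' assignment in the joint-segmentation path.
#'
#' @param segments segments data.frame carrying a `copy` column.
#' @return the collapsed data.frame.
#' @export
mergeAdjacentSegments <- function(segments) {
  if (nrow(segments) < 2) return(segments)
  newRun <- c(TRUE, segments$chrom[-1] != segments$chrom[-nrow(segments)] |
                segments$copy[-1] != segments$copy[-nrow(segments)])
  run <- cumsum(newRun)
  out <- do.call(rbind, lapply(split(seq_len(nrow(segments)), run), function(m) {
    s <- segments[m, , drop = FALSE]
    data.frame(chrom = s$chrom[1], start = min(s$start), end = max(s$end),
               firstBin = min(s$firstBin), lastBin = max(s$lastBin),
               nBins = sum(s$nBins),
               meanDepth = sum(s$meanDepth * s$nBins) / sum(s$nBins),
               copy = s$copy[1], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fit an integer copy-number scale to segment means
#'
#' Exploits the quantum nature of single-cell copy number: searches a scale
#' factor S over a bounded grid minimizing the length-weighted squared
#' distance of each segment's mean depth to its nearest lattice point
#' `round(S * meanDepth) / S`, then assigns each segment
#' `round(S * meanDepth)` copies. Lattice distances are measured in depth
#' units (the copy-unit distance divided by S), which keeps the noise
#' contribution to the residuals independent of S.
#'
#' Scale selection is a consistency test rather than a bare argmin: any
#' integer multiple of the true scale fits the data at least as well (its
#' lattice contains the true one, and a denser lattice can absorb noise),
#' so the chosen S is the smallest admissible scale whose
#' bin-count-weighted residual chi-square statistic
#' `sum(nBins * residual^2 / meanDepth^2) / sigma2` is consistent with the
#' noise level. The statistic is evaluated over the well-measured segments
#' (at least `testMinBins` bins, one chi-square degree of freedom each):
#' lattice misfit concentrates in long segments while short segments mostly
#' contribute noise, so restricting the test sharpens it. Thresholded at
#' the 99.9% chi-square quantile; if no admissible scale is consistent the
#' admissible argmin is used. Exact ties resolve to the smallest S. Fits
#' implying a mean ploidy below `minPloidy` are rejected (a near-triploid
#' profile also fits a near-diploid lattice at S/1.5; the guard reflects
#' the known genome-doubled background), so a depth profile with no
#' internal contrast resolves to the smallest admissible ploidy.
#'
#' @param segments data.frame from [segmentProfile()] (needs `start`, `end`,
#'   `meanDepth`).
#' @param sRange grid limits for S, default `c(1, 8)`.
#' @param sStep grid step, default 0.01.
#' @param minPloidy smallest admissible implied mean ploidy, default 1.5.
#' @param sigma2 per-bin noise variance of the scaled depth (estimate it
#'   with `noiseVariance`); near-zero default suits exact arithmetic
#'   examples.
#' @param testMinBins segments with at least this many bins enter the
#'   consistency test (all segments always receive copies), default 8.
#' @param maxPloidy largest admissible implied mean ploidy, default `Inf`;
#'   a finite window is used by the cohort ploidy prior of
#'   [callCellProfiles()].
#' @return list: `S`, `fitError` (length-weighted mean squared lattice
#'   distance in depth units at the selected S), `chisq` (the consistency
#'   statistic), `copies` (integer per segment), `meanPloidy`.
#' @export
fitIntegerScale <- function(segments, sRange = c(1, 8), sStep = 0.01,
                            minPloidy = 1.5, sigma2 = 1e-8, testMinBins = 8,
                            maxPloidy = Inf) {
  if (is.null(segments) || nrow(segments) == 0)
    dataError("fitIntegerScale: empty segment list")
  m <- segments$meanDepth
  n <- if ("nBins" %in% names(segments)) segments$nBins else rep(1, nrow(segments))
  w <- segments$end - segments$start
  w <- w / sum(w)
  grid <- seq(sRange[1], sRange[2], by = sStep)
  q <- outer(grid, m)              # S x segments
  qi <- round(q)
  resid2 <- ((q - qi) / grid)^2    # depth-unit squared residuals
  err <- as.vector(resid2 %*% w)
  # per-segment variance scales with squared depth (roughly constant cv),
  # so normalize each segment's residual by its mean depth before the test
  testable <- n >= testMinBins
  if (!any(testable)) testable <- rep(TRUE, length(n))
  nw <- ifelse(testable, n, 0) / pmax(abs(m), 0.1)^2
  chisq <- as.vector(resid2 %*% nw) / max(sigma2, 1e-12)
  ploidy <- as.vector(qi %*% w)
  admissible <- ploidy >= minPloidy & ploidy <= maxPloidy
  cand <- if (any(admissible)) which(admissible) else seq_along(grid)
  thresh <- stats::qchisq(0.999, df = sum(testable))
  pass <- cand[chisq[cand] <= thresh]
  best <- if (length(pass)) pass[1] else cand[which.min(chisq[cand])]
  copies <- as.integer(qi[best, ])
  list(S = grid[best], fitError = err[best], chisq = chisq[best],
       copies = copies, meanPloidy = sum(w * copies))
}

#' Second-pass refinement of missed segment steps
#'
#' One pass over the segments of a cell: each segment is tested for its
#' best internal split, which is accepted when the SSE gain clears half the
#' genome-wide segmentation penalty *and* the two resulting means are
#' separated by at least `zThresh` standard errors (given the per-bin noise
#' variance). This rescues arm-scale copy steps whose gain fell just under
#' the genome-wide penalty — a missed step leaves an off-lattice segment
#' mean that distorts the integer scale fit — while the separation
#' requirement keeps chance splits of uniform segments out.
#'
#' @param scaled per-bin scaled depth of the cell.
#' @param segments data.frame from [segmentProfile()].
#' @param penalty the segmentation penalty in use.
#' @param model the [GenomeModel-class] (for split coordinates).
#' @param sigma2 per-bin noise variance of the scaled depth.
#' @param zThresh minimum mean separation in standard errors, default 3.5.
#' @return the (possibly) re-split segments data.frame.
#' @export
refineSegments <- function(scaled, segments, penalty, model, sigma2,
                           zThresh = 3.5) {
  bins <- model@bins
  mkSeg <- function(seg, first, last) {
    idx <- first:last
    x <- scaled[idx]
    data.frame(chrom = seg$chrom, start = start(bins)[first] - 1,
               end = end(bins)[last], firstBin = first, lastBin = last,
               nBins = sum(is.finite(x)), meanDepth = mean(x[is.finite(x)]),
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    idx <- seg$firstBin:seg$lastBin
    x <- scaled[idx]
    ok <- is.finite(x)
    accept <- FALSE
    if (sum(ok) >= 4) {
      cs <- c(0, cumsum(x[ok])); cs2 <- c(0, cumsum(x[ok]^2))
      sp <- bestSplit(cs, cs2, 1, sum(ok))
      if (is.finite(sp$gain) && sp$gain > penalty / 2) {
        i1 <- which(ok)[seq_len(sp$at)]
        i2 <- which(ok)[(sp$at + 1):sum(ok)]
        se <- sqrt(sigma2 * (1 / length(i1) + 1 / length(i2)))
        if (abs(mean(x[i1]) - mean(x[i2])) >= zThresh * se) {
          accept <- TRUE
          out[[length(out) + 1]] <- mkSeg(seg, idx[1], idx[max(i1)])
          out[[length(out) + 1]] <- mkSeg(seg, idx[min(i2)], idx[length(idx)])
        }
      }
    }
    if (!accept) out[[length(out) + 1]] <- seg
  }
  do.call(rbind, out)
}

#' Log-likelihood-ratio confidence of a segment's copy-number call
#'
#' Score of the assigned integer copy state against the better of the two
#' flanking states (copy - 1, copy + 1) under a negative-binomial read-count
#' model, summed over the segment's bins: doubling the supporting bins at
#' identical per-bin evidence doubles the score. Non-negative by
#' construction (clamped at 0 when the assigned state is not the local
#' maximum-likelihood integer).
#'
#' @param counts raw bin counts of the segment.
#' @param perCopyMu expected counts per copy for each bin.
#' @param copy assigned integer copy number.
#' @param dispersion negative-binomial dispersion of the count model;
#'   the default 0 scores against a Poisson model.
#' @return non-negative numeric score.
#' @export
scoreConfidence <- function(counts, perCopyMu, copy, dispersion = 0) {
  ll <- function(cn) {
    mu <- pmax(cn, 0.05) * perCopyMu
    if (dispersion > 0)
      sum(stats::dnbinom(counts, mu = mu, size = 1 / dispersion, log = TRUE))
    else sum(stats::dpois(counts, lambda = mu, log = TRUE))
  }
  rival <- max(ll(copy - 1), ll(copy + 1))
  max(0, ll(copy) - rival)
}

#' Flag a noisy cell from its residual depth scatter
#'
#' A cell is flagged noisy when the median absolute deviation (scaled,
#' `constant = 1.4826`) of its per-bin scaled depth around the fitted
#' segment means exceeds `threshold`. The statistic is computed in
#' ploidy-normalized depth units (copy / mean-copy), where a clean shallow-
#' coverage cell sits well below the default threshold and cells drawn from
#' the inflated-dispersion noisy model sit well above it. Deterministic.
#'
#' @param scaled per-bin scaled depth of the cell.
#' @param segments data.frame from [segmentProfile()].
#' @param threshold MAD threshold, default 0.35; `Inf` never flags.
#' @return list: `noisy` (logical), `noiseMad` (the statistic).
#' @export
flagNoisy <- function(scaled, segments, threshold = 0.35) {
  fitted <- rep(NA_real_, length(scaled))
  for (i in seq_len(nrow(segments)))
    fitted[segments$firstBin[i]:segments$lastBin[i]] <- segments$meanDepth[i]
  resid <- scaled - fitted
  stat <- stats::mad(resid[is.finite(resid)], center = 0)
  list(noisy = is.finite(stat) && stat > threshold, noiseMad = stat)
}

#' Per-cell integer copy number matrix over bins
#'
#' Expands the segment calls of a cohort into a cells x bins integer
#' matrix (the heatmap / hierarchical-ordering substrate).
#'
#' @param calls a [CellCnvCalls-class].
#' @return integer matrix, barcodes x bins.
#' @export
binCopyMatrix <- function(calls) {
  model <- calls@model
  segs <- calls@calls
  barcodes <- calls@summary$barcode
  m <- matrix(NA_integer_, nrow = length(barcodes), ncol = length(model@bins),
              dimnames = list(barcodes, binIds(model)))
  ri <- match(segs$barcode, barcodes)
  for (j in seq_len(nrow(segs)))
    m[ri[j], segs$firstBin[j]:segs$lastBin[j]] <- segs$copy[j]
  attr(m, "binWidthBp") <- width(model@bins)
  m
}

#' Call per-cell integer CNV profiles for a cohort
#'
#' Runs the whole per-cell caller — scaled depth, per-chromosome
#' segmentation (plus the second-pass step refinement), integer-lattice
#' scale fit, per-segment confidence scoring and noisy-cell flagging — over
#' every cell of a count matrix. Results do not depend on cell order.
#'
#' With `cohortPloidyPrior = TRUE` (default) a second pass refits cells
#' whose implied mean ploidy deviates from the cohort median by more than
#' `ploidyWindow`, restricting the admissible ploidy to that window. At
#' shallow depth the per-cell lattice is occasionally ambiguous (a profile
#' fits both its true scale and a near-multiple); in a cohort from one
#' genome-doubled line the ploidy distribution is unimodal, which resolves
#' the ambiguity. Disable for cohorts with genuinely mixed ploidy.
#'
#' @param counts cells x bins count matrix (barcode rownames) or a
#'   [SyntheticCohort-class].
#' @param model a [GenomeModel-class]; taken from the cohort if omitted.
#' @param weights optional per-bin bias weights for [scaledDepth()].
#' @param penalty segmentation penalty (`NULL` = default).
#' @param scoreDispersion dispersion of the count model used by
#'   [scoreConfidence()]; the default 0 scores against a Poisson model,
#'   which calibrates the score so unambiguous arm- and chromosome-scale
#'   events sit far above the downstream quality cutoff of 15.
#' @param noiseThreshold threshold for [flagNoisy()].
#' @param sRange,sStep,minPloidy passed to [fitIntegerScale()].
#' @param cohortPloidyPrior refit ploidy outliers within a window around
#'   the cohort median ploidy (default `TRUE`).
#' @param ploidyWindow half-width of that window, default 0.75.
#' @param jointSegmentation segment every cell on the shared candidate
#'   breakpoints of [cohortBreakpoints()] (default `TRUE` for cohorts of at
#'   least 20 cells), giving identical segment coordinates across cells;
#'   with `FALSE` each cell is segmented independently.
#' @return a [CellCnvCalls-class].
#' @export
callCellProfiles <- function(counts, model = NULL, weights = NULL,
                             penalty = NULL, scoreDispersion = 0,
                             noiseThreshold = 0.35, sRange = c(1, 8),
                             sStep = 0.01, minPloidy = 1.5,
                             cohortPloidyPrior = TRUE, ploidyWindow = 0.75,
                             jointSegmentation = TRUE) {
  if (is(counts, "SyntheticCohort")) {
    if (is.null(model)) model <- counts@model
    counts <- counts@counts
  }
  if (is.null(model)) configError("a GenomeModel is required")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("cell_%05d", seq_len(nrow(counts)))
  scaled <- scaledDepth(counts, model, weights = weights)
  widths <- width(model@bins)
  useJoint <- jointSegmentation && nrow(counts) >= 20
  candidates <- if (useJoint) cohortBreakpoints(counts, model, penalty)
                else integer(0)

  oneCell <- function(i, maxPloidy = Inf, minPl = minPloidy) {
    r <- scaled[i, ]
    sigma2 <- noiseVariance(r[is.finite(r)])
    pen <- max(penalty %||% (1.5 * log(sum(is.finite(r))) * sigma2), 1e-8)
    if (useJoint) {
      segs <- segmentWithBreakpoints(r, model, candidates)
    } else {
      segs <- segmentProfile(r, model, penalty = pen)
      segs <- refineSegments(r, segs, pen, model, sigma2)
    }
    fit <- fitIntegerScale(segs, sRange = sRange, sStep = sStep,
                           minPloidy = minPl, sigma2 = sigma2,
                           maxPloidy = maxPloidy)
    segs$copy <- fit$copies
    if (useJoint) segs <- mergeAdjacentSegments(segs)
    # expected counts per copy per bin, from the cell total and fitted copies
    binCopyHat <- rep(NA_real_, ncol(counts))
    for (s in seq_len(nrow(segs)))
      binCopyHat[segs$firstBin[s]:segs$lastBin[s]] <- segs$copy[s]
    okb <- is.finite(binCopyHat)
    denom <- sum(as.numeric(widths[okb]) * binCopyHat[okb])
    rho <- as.numeric(sum(counts[i, okb])) * as.numeric(widths) / max(denom, 1)
    segs$confidence <- vapply(seq_len(nrow(segs)), function(s) {
      b <- segs$firstBin[s]:segs$lastBin[s]
      scoreConfidence(counts[i, b], rho[b], segs$copy[s],
                      dispersion = scoreDispersion)
    }, numeric(1))
    nz <- flagNoisy(r, segs, threshold = noiseThreshold)
    w <- segs$end - segs$start
    list(calls = data.frame(chrom = segs$chrom, start = segs$start,
                            end = segs$end, barcode = rownames(counts)[i],
                            copy = segs$copy, confidence = segs$confidence,
                            firstBin = segs$firstBin, lastBin = segs$lastBin,
                            stringsAsFactors = FALSE),
         summary = data.frame(barcode = rownames(counts)[i],
                              meanPloidy = sum(w * segs$copy) / sum(w),
                              scale = fit$S, fitError = fit$fitError,
                              noiseMad = nz$noiseMad, noisy = nz$noisy,
                              stringsAsFactors = FALSE))
  }

  res <- lapply(seq_len(nrow(counts)), oneCell)
  if (cohortPloidyPrior && nrow(counts) >= 10) {
    ploidies <- vapply(res, function(x) x$summary$meanPloidy, numeric(1))
    noisyFlags <- vapply(res, function(x) x$summary$noisy, logical(1))
    center <- stats::median(ploidies[!noisyFlags])
    off <- which(abs(ploidies - center) > ploidyWindow & !noisyFlags)
    for (i in off)
      res[[i]] <- oneCell(i, maxPloidy = center + ploidyWindow,
                          minPl = max(minPloidy, center - ploidyWindow))
  }
  new("CellCnvCalls", calls = do.call(rbind, lapply(res, `[[`, "calls")),
      summary = do.call(rbind, lapply(res, `[[`, "summary")), model = model,
      params = list(penalty = penalty, scoreDispersion = scoreDispersion,
                    noiseThreshold = noiseThreshold, sRange = sRange,
                    sStep = sStep, minPloidy = minPloidy,
                    cohortPloidyPrior = cohortPloidyPrior,
                    ploidyWindow = ploidyWindow,
                    jointSegmentation = useJoint))
}
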