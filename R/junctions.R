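# canonical side order: side 1 is the lexicographically smaller
# (chrom, position); swapping sides flips the orientation class
canonicalizePairs <- function(pairs) {
  if (nrow(pairs) == 0) return(pairs)
  p1 <- (pairs$start1 + pairs$end1) / 2
  p2 <- (pairs$start2 + pairs$end2) / 2
  swap <- pairs$chrom2 < pairs$chrom1 |
    (pairs$chrom2 == pairs$chrom1 & p2 < p1)
  if (any(swap)) {
    sw <- function(a, b) {
      tmp <- pairs[[a]][swap]
      pairs[[a]][swap] <<- pairs[[b]][swap]
      pairs[[b]][swap] <<- tmp
    }
    sw("chrom1", "chrom2"); sw("start1", "start2"); sw("end1", "end2")
    if ("mapq1" %in% names(pairs)) sw("mapq1", "mapq2")
    if ("strand1" %in% names(pairs)) sw("strand1", "strand2")
    if ("class" %in% names(pairs))
      pairs$class[swap] <- ifelse(pairs$class[swap] == "12", "21", "12")
  }
  pairs
}

#' Cluster anomalous read pairs into junction candidates
#'
#' Greedy clustering of discordant pairs into donor/acceptor region pairs:
#' pairs with either mate's mapping quality below `minMapq` are discarded;
#' remaining pairs (canonicalized so side order is deterministic) are
#' clustered so that each side's span stays within `3 * insertDistance`.
#' Candidates are rejected when support is below `minSupport`, when both
#' breakends are on one chromosome separated by no more than
#' `minSeparation`, or when only one read-orientation class (first read on
#' side 1 vs side 2) supports them. Accepted candidates are sorted by
#' support, descending, then by coordinates.
#'
#' @param pairs BEDPE-like data.frame (see [simulateReadPairs()]); needs
#'   `chrom1/2`, `start1/2`, `end1/2`, `mapq1/2`, `class`.
#' @param insertDistance library insert size in bp (> 0), default 350.
#' @param minSeparation minimum intra-chromosomal breakend separation in bp
#'   (exclusive), default 10,000.
#' @param minMapq minimum mapping quality (pairs below are discarded),
#'   default 20.
#' @param minSupport minimum supporting pairs, default 2.
#' @return data.frame of candidates: `chrom1`, `pos1`, `chrom2`, `pos2`
#'   (median read midpoints per side), `support`, `nClasses`, `lo1`, `hi1`,
#'   `lo2`, `hi2` (side spans), `refined` (FALSE), `refinedPos1`,
#'   `refinedPos2` (NA).
#' @export
clusterReadPairs <- function(pairs, insertDistance = 350,
                             minSeparation = 10000, minMapq = 20,
                             minSupport = 2) {
  if (insertDistance <= 0) configError("insertDistance must be positive")
  emptyCand <- data.frame(chrom1 = character(), pos1 = numeric(),
                          chrom2 = character(), pos2 = numeric(),
                          support = integer(), nClasses = integer(),
                          lo1 = numeric(), hi1 = numeric(),
                          lo2 = numeric(), hi2 = numeric(),
                          refined = logical(), refinedPos1 = numeric(),
                          refinedPos2 = numeric(), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) return(emptyCand)
  keep <- pairs$mapq1 >= minMapq & pairs$mapq2 >= minMapq
  pairs <- canonicalizePairs(pairs[keep, , drop = FALSE])
  if (nrow(pairs) == 0) return(emptyCand)
  p1 <- (pairs$start1 + pairs$end1) / 2
  p2 <- (pairs$start2 + pairs$end2) / 2
  ord <- order(pairs$chrom1, pairs$chrom2, p1, p2)
  pairs <- pairs[ord, , drop = FALSE]
  p1 <- p1[ord]; p2 <- p2[ord]
  span <- 3 * insertDistance
  cl <- integer(nrow(pairs))
  active <- list() # per cluster: chrom pair + running min/max per side
  for (i in seq_len(nrow(pairs))) {
    assigned <- 0L
    for (j in seq_along(active)) {
      a <- active[[j]]
      if (a$c1 != pairs$chrom1[i] || a$c2 != pairs$chrom2[i]) next
      if (max(a$hi1, p1[i]) - min(a$lo1, p1[i]) <= span &&
          max(a$hi2, p2[i]) - min(a$lo2, p2[i]) <= span) {
        assigned <- j
        break
      }
    }
    if (assigned == 0L) {
      active[[length(active) + 1]] <- list(c1 = pairs$chrom1[i],
                                           c2 = pairs$chrom2[i],
                                           lo1 = p1[i], hi1 = p1[i],
                                           lo2 = p2[i], hi2 = p2[i])
      assigned <- length(active)
    } else {
      a <- active[[assigned]]
      a$lo1 <- min(a$lo1, p1[i]); a$hi1 <- max(a$hi1, p1[i])
      a$lo2 <- min(a$lo2, p2[i]); a$hi2 <- max(a$hi2, p2[i])
      active[[assigned]] <- a
    }
    cl[i] <- assigned
  }
  cands <- do.call(rbind, lapply(seq_along(active), function(j) {
    m <- which(cl == j)
    data.frame(chrom1 = active[[j]]$c1,
               pos1 = medianLower(p1[m]),
               chrom2 = active[[j]]$c2,
               pos2 = medianLower(p2[m]),
               support = length(m),
               nClasses = length(unique(pairs$class[m])),
               lo1 = active[[j]]$lo1, hi1 = active[[j]]$hi1,
               lo2 = active[[j]]$lo2, hi2 = active[[j]]$hi2,
               refined = FALSE, refinedPos1 = NA_real_,
               refinedPos2 = NA_real_, stringsAsFactors = FALSE)
  }))
  sep <- ifelse(cands$chrom1 == cands$chrom2,
                abs(cands$pos2 - cands$pos1), Inf)
  cands <- cands[cands$support >= minSupport & cands$nClasses >= 2 &
                   sep > minSeparation, , drop = FALSE]
  cands[order(-cands$support, cands$chrom1, cands$pos1, cands$chrom2,
              cands$pos2), , drop = FALSE]
}

#' Annotate junction candidates with nearby CNV breakpoints
#'
#' For each candidate, computes the distance from each breakend to the
#' nearest CNV segment breakpoint on the same chromosome; candidates with
#' both distances within `window` (default 2 Mb) are flagged CNV-associated.
#' Associated candidates are ranked first, nearest first.
#'
#' @param candidates data.frame from [clusterReadPairs()].
#' @param breakpoints data.frame with `chrom` and `pos` (e.g. the start/end
#'   coordinates of the merged CNV event clusters).
#' @param window association window in bp, default 2e6.
#' @return candidates with `dist1`, `dist2`, `cnvAssociated` columns,
#'   re-ranked.
#' @export
associateCnvBreakpoints <- function(candidates, breakpoints, window = 2e6) {
  nearest <- function(chrom, pos) {
    vapply(seq_along(chrom), function(i) {
      p <- breakpoints$pos[breakpoints$chrom == chrom[i]]
      if (length(p) == 0) Inf else min(abs(p - pos[i]))
    }, numeric(1))
  }
  candidates$dist1 <- nearest(candidates$chrom1, candidates$pos1)
  candidates$dist2 <- nearest(candidates$chrom2, candidates$pos2)
  candidates$cnvAssociated <- candidates$dist1 <= window &
    candidates$dist2 <= window
  candidates[order(-candidates$cnvAssociated,
                   candidates$dist1 + candidates$dist2,
                   -candidates$support), , drop = FALSE]
}

#' Refine a junction candidate to base-pair resolution with split reads
#'
#' Junction-spanning split reads carry the exact breakend base on each side;
#' the refined position is the modal split coordinate per side (majority
#' vote; ties to the smaller coordinate). Split reads incompatible with the
#' candidate (wrong chromosome pair or farther than `3 * insertDistance`
#' from its breakends) are ignored. Without compatible spanning reads the
#' candidate is returned unchanged at pair-interval resolution.
#'
#' @param candidate one row of the candidate table.
#' @param splits data.frame of split reads: `read`, `chrom1`, `pos1`,
#'   `chrom2`, `pos2` (1-based breakend coordinates).
#' @param insertDistance insert size in bp used for the compatibility
#'   window.
#' @return the candidate row with `refined`, `refinedPos1`, `refinedPos2`
#'   updated.
#' @export
refineWithSplitReads <- function(candidate, splits, insertDistance = 350) {
  if (nrow(splits) == 0) return(candidate)
  sp <- canonicalizePairs(data.frame(
    chrom1 = splits$chrom1, start1 = splits$pos1, end1 = splits$pos1,
    chrom2 = splits$chrom2, start2 = splits$pos2, end2 = splits$pos2,
    stringsAsFactors = FALSE))
  tol <- 3 * insertDistance
  compat <- sp$chrom1 == candidate$chrom1 & sp$chrom2 == candidate$chrom2 &
    sp$start1 >= candidate$lo1 - tol & sp$start1 <= candidate$hi1 + tol &
    sp$start2 >= candidate$lo2 - tol & sp$start2 <= candidate$hi2 + tol
  if (!any(compat)) return(candidate)
  candidate$refinedPos1 <- modalValue(sp$start1[compat])
  candidate$refinedPos2 <- modalValue(sp$start2[compat])
  candidate$refined <- TRUE
  candidate
}

#' Tabulate junction presence and support across groups
#'
#' Matches candidates across groups (both breakends within
#' `3 * insertDistance`) into canonical junction rows and reports the
#' supporting-pair count of each junction in each group, zero when absent.
#'
#' @param candidatesByGroup named list of candidate tables, one per group.
#' @param insertDistance insert size in bp for the matching tolerance.
#' @return data.frame: `junction` (id), `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   then one integer support column per group.
#' @export
junctionPresenceByGroup <- function(candidatesByGroup, insertDistance = 350) {
  tol <- 3 * insertDistance
  canonical <- NULL
  groups <- names(candidatesByGroup)
  support <- list()
  for (g in groups) {
    cands <- candidatesByGroup[[g]]
    if (is.null(cands) || nrow(cands) == 0) next
    for (i in seq_len(nrow(cands))) {
      row <- cands[i, ]
      match_j <- 0L
      if (!is.null(canonical)) {
        hit <- which(canonical$chrom1 == row$chrom1 &
                       canonical$chrom2 == row$chrom2 &
                       abs(canonical$pos1 - row$pos1) <= tol &
                       abs(canonical$pos2 - row$pos2) <= tol)
        if (length(hit)) match_j <- hit[1]
      }
      if (match_j == 0L) {
        canonical <- rbind(canonical,
                           data.frame(chrom1 = row$chrom1, pos1 = row$pos1,
                                      chrom2 = row$chrom2, pos2 = row$pos2,
                                      stringsAsFactors = FALSE))
        match_j <- nrow(canonical)
      }
      key <- as.character(match_j)
      if (is.null(support[[g]])) support[[g]] <- integer(0)
      support[[g]][key] <- (if (key %in% names(support[[g]]))
        support[[g]][[key]] else 0L) + row$support
    }
  }
  nj <- if (is.null(canonical)) 0L else nrow(canonical)
  out <- if (nj == 0) {
    data.frame(junction = character(), chrom1 = character(), pos1 = numeric(),
               chrom2 = character(), pos2 = numeric(), stringsAsFactors = FALSE)
  } else {
    data.frame(junction = sprintf("%s:%d-%s:%d", canonical$chrom1,
                                  as.integer(canonical$pos1),
                                  canonical$chrom2,
                                  as.integer(canonical$pos2)),
               canonical, stringsAsFactors = FALSE)
  }
  for (g in groups) {
    col <- integer(nj)
    if (!is.null(support[[g]]) && nj > 0) {
      idx <- as.integer(names(support[[g]]))
      col[idx] <- as.integer(support[[g]])
    }
    out[[g]] <- col
  }
  out
}
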