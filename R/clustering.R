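#' PCA embedding of the binary event matrix
#'
#' Projects cells onto the top right-singular directions of the
#' column-centered 0/1 matrix. The number of retained components defaults to
#' the smallest number explaining `varExplained` of the variance, capped at
#' `maxPcs` and at the matrix rank. Duplicated cells receive identical
#' scores.
#'
#' @param em an [EventMatrix-class] or a plain numeric matrix.
#' @param nComponents fixed number of components (overrides the variance
#'   rule); must be `<= min(cells - 1, events)`.
#' @param varExplained cumulative variance target, default 0.9.
#' @param maxPcs hard cap on retained components, default 40.
#' @return list: `scores` (cells x components), `sdev`, `nComponents`.
#' @export
pcaEmbed <- function(em, nComponents = NULL, varExplained = 0.9, maxPcs = 40) {
  x <- if (is(em, "EventMatrix")) binaryMatrix(em) else em
  if (nrow(x) == 0 || ncol(x) == 0 || all(x == 0))
    dataError("event matrix is empty or all-zero")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  tol <- max(dim(x)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (rank == 0) dataError("event matrix has rank 0 after centering")
  if (!is.null(nComponents)) {
    if (nComponents > min(nrow(x) - 1, ncol(x)))
      configError("nComponents exceeds min(cells - 1, events)")
    nc <- min(nComponents, rank)
  } else {
    varex <- cumsum(sv$d^2) / sum(sv$d^2)
    nc <- min(which(varex >= varExplained)[1], maxPcs, rank)
  }
  scores <- sv$u[, seq_len(nc), drop = FALSE] %*% diag(sv$d[seq_len(nc)], nc)
  rownames(scores) <- rownames(x)
  list(scores = scores, sdev = sv$d / sqrt(max(1, nrow(x) - 1)), nComponents = nc)
}

#' Scan cluster counts with k-means and BIC
#'
#' For each candidate k, runs seeded k-means (best of `nStarts` restarts) on
#' the PC scores and evaluates a BIC. Two formulas are available:
#'
#' * `"xmeans"` (default): the spherical-Gaussian hard-assignment
#'   likelihood with mixing proportions — a pooled variance
#'   `sigma2 = W_k / (d (n - k))`, log-likelihood
#'   `-n d/2 ln(2 pi sigma2) - d (n - k)/2 + sum_j n_j ln(n_j / n)`, and
#'   `k (d + 1)` parameters. The mixing term charges for splitting a
#'   homogeneous cluster, so the argmin lands at the true cluster count on
#'   separable data instead of drifting to the top of the range.
#' * `"wss"`: the simple variant `n ln(W_k / n) + k ln(n)`.
#'
#' `W_k` is floored at a small epsilon so degenerate geometries with
#' `W_k = 0` remain comparable. The chosen k is the BIC argmin; ties go to
#' the smaller k. k values exceeding the number of distinct points are
#' reported with `NA` BIC and never chosen. With a fixed seed the scan is
#' bit-reproducible.
#'
#' @param scores cells x components numeric matrix.
#' @param kRange integer candidate k values, default `2:20`.
#' @param nStarts k-means restarts per k, default 10.
#' @param seed integer RNG seed.
#' @param formula `"xmeans"` (default) or `"wss"`; see above.
#' @return list: `k` (chosen), `labels` (per-cell clusters for the chosen
#'   k), `bic` (data.frame `k`, `withinSS`, `bic`).
#' @export
scanKBic <- function(scores, kRange = 2:20, nStarts = 10, seed = 1,
                     formula = c("xmeans", "wss")) {
  formula <- match.arg(formula)
  n <- nrow(scores)
  d <- ncol(scores)
  kRange <- sort(unique(as.integer(kRange)))
  if (any(kRange < 1)) configError("k must be >= 1")
  if (max(kRange) > n) configError("k exceeds the number of cells")
  nDistinct <- nrow(unique(scores))
  eps <- 1e-10 * max(1, sum(scale(scores, scale = FALSE)^2))
  withinSS <- bic <- rep(NA_real_, length(kRange))
  labelsByK <- vector("list", length(kRange))
  set.seed(seed)
  for (i in seq_along(kRange)) {
    k <- kRange[i]
    if (k > nDistinct) next
    if (k == 1) {
      w <- sum(sweep(scores, 2, colMeans(scores))^2)
      labelsByK[[i]] <- rep(1L, n)
    } else {
      km <- suppressWarnings(stats::kmeans(scores, centers = k,
                                           nstart = nStarts, iter.max = 50))
      w <- km$tot.withinss
      labelsByK[[i]] <- km$cluster
    }
    withinSS[i] <- w
    if (formula == "wss") {
      bic[i] <- n * log(max(w, eps) / n) + k * log(n)
    } else {
      nj <- tabulate(labelsByK[[i]], k)
      nj <- nj[nj > 0]
      sigma2 <- max(w, eps) / (d * max(n - k, 1))
      lnL <- -n * d / 2 * log(2 * pi * sigma2) - d * (n - k) / 2 +
        sum(nj * log(nj / n))
      bic[i] <- -2 * lnL + k * (d + 1) * log(n)
    }
  }
  if (all(is.na(bic))) dataError("no feasible k in the scanned range")
  best <- which(bic == min(bic, na.rm = TRUE))[1]
  list(k = kRange[best], labels = as.integer(labelsByK[[best]]),
       bic = data.frame(k = kRange, withinSS = withinSS, bic = bic))
}

#' Linear discriminant axes between clusters
#'
#' Solves the generalized eigenproblem maximizing between-group over
#' within-group variance of the PC scores (the DAPC discriminant step). The
#' within-group scatter is regularized by a small ridge so perfectly
#' separated or degenerate groups remain solvable. Eigenvalues are the
#' between/within variance ratios, non-negative and non-increasing; axes are
#' scaled so within-group covariance of the axis scores is the identity
#' (axes are uncorrelated within groups).
#'
#' @param scores cells x components matrix.
#' @param labels per-cell cluster labels (>= 2 non-empty clusters).
#' @param ridge relative ridge on the within-scatter diagonal, default 1e-6.
#' @param nAxes number of axes to keep, default `min(k - 1, ncol(scores))`.
#' @return list: `scores` (cells x axes), `eigenvalues`, `axes` (loadings on
#'   the PC space).
#' @export
discriminantAxes <- function(scores, labels, ridge = 1e-6, nAxes = NULL) {
  labels <- as.factor(labels)
  k <- nlevels(droplevels(labels))
  if (k < 2) dataError("discriminant axes require >= 2 clusters")
  p <- ncol(scores)
  gm <- rowsum(scores, labels) / as.vector(table(labels))
  mu <- colMeans(scores)
  centered <- scores - gm[as.integer(labels), , drop = FALSE]
  W <- crossprod(centered)
  dm <- sweep(gm, 2, mu)
  B <- crossprod(dm * sqrt(as.vector(table(labels))))
  lambda <- ridge * (sum(diag(W)) / p) + 1e-12
  Wr <- W + diag(lambda, p)
  L <- chol(Wr)
  M <- backsolve(L, t(backsolve(L, t(B), transpose = TRUE)), transpose = TRUE)
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- seq_len(min(k - 1, p, if (is.null(nAxes)) p else nAxes))
  vals <- pmax(eig$values[keep], 0)
  axes <- backsolve(L, eig$vectors[, keep, drop = FALSE])
  # normalize so within-scatter of axis scores is the identity
  axisScores <- sweep(scores, 2, mu) %*% axes
  list(scores = axisScores, eigenvalues = vals, axes = axes)
}

#' Merge fine clusters into major groups by hallmark-scale copy differences
#'
#' Formalizes the merge of fine DAPC clusters into major groups: two
#' clusters belong to the same group unless they differ at hallmark scale.
#' When a per-cell copy-number matrix is supplied, each cluster's modal
#' integer copy per bin is computed and clusters are merged (single
#' linkage) whenever the genomic span over which their modal profiles
#' disagree is below `hallmarkMinSizeBp` — i.e. groups are separated only
#' by large (arm/chromosome scale) copy differences, small stochastic
#' call differences never split a group. Without a copy matrix the fallback
#' is consensus-profile equality over the hallmark event columns (size >=
#' `hallmarkMinSizeBp`; a column is set when at least `consensusThreshold`
#' of the cluster's cells carry it).
#'
#' Each group's consensus hallmark-event profile is reported either way.
#' Groups are lettered A, B, C, ... in decreasing size (cell count) order;
#' letters are presentational — compare partitions, not labels.
#'
#' @param labels per-cell cluster labels.
#' @param em the [EventMatrix-class] the clustering was computed on.
#' @param hallmarkMinSizeBp hallmark scale in bp, default 50 Mb.
#' @param consensusThreshold member fraction required to set a consensus
#'   bit, default 0.5.
#' @param copyMatrix optional cells x bins integer matrix (from
#'   [binCopyMatrix()]), rows matching the rows of `em`.
#' @param minGroupFraction smallest cell fraction a major group may have
#'   (default 0.01, floor of 5 cells); undersized groups are absorbed into
#'   the group with the smallest modal-profile disagreement. Only applies
#'   when a copy matrix is supplied.
#' @return list: `groups` (per-cell letters), `groupMap` (data.frame
#'   `cluster`, `group`), `consensus` (clusters x hallmark-events 0/1).
#' @export
mergeClustersToGroups <- function(labels, em, hallmarkMinSizeBp = 5e7,
                                  consensusThreshold = 0.5,
                                  copyMatrix = NULL, minGroupFraction = 0.01) {
  mat <- binaryMatrix(em)
  events <- eventTable(em)
  hall <- which(events$sizeBp >= hallmarkMinSizeBp)
  if (length(hall) == 0) hall <- seq_len(ncol(mat)) # degenerate: use all
  ulab <- sort(unique(labels))
  nc <- length(ulab)
  consensus <- matrix(unlist(lapply(ulab, function(cl) {
    as.integer(colMeans(mat[labels == cl, hall, drop = FALSE]) >= consensusThreshold)
  })), nrow = nc, byrow = TRUE)
  rownames(consensus) <- ulab
  colnames(consensus) <- colnames(mat)[hall]

  if (!is.null(copyMatrix)) {
    binW <- attr(copyMatrix, "binWidthBp")
    if (is.null(binW)) binW <- rep(1, ncol(copyMatrix))
    if (!is.null(rownames(copyMatrix)) && !is.null(rownames(mat))) {
      if (!all(rownames(mat) %in% rownames(copyMatrix)))
        dataError("copyMatrix lacks some event-matrix barcodes")
      copyMatrix <- copyMatrix[rownames(mat), , drop = FALSE]
    } else if (nrow(copyMatrix) != nrow(mat)) {
      dataError("copyMatrix rows do not match the event matrix")
    }
    modal <- matrix(NA_integer_, nrow = nc, ncol = ncol(copyMatrix))
    for (g in seq_len(nc)) {
      sub <- copyMatrix[labels == ulab[g], , drop = FALSE]
      modal[g, ] <- apply(sub, 2, function(x) {
        x <- x[!is.na(x)]
        if (length(x) == 0) NA_integer_ else modalValue(x)
      })
    }
    parent <- seq_len(nc)
    for (a in seq_len(nc - 1)) for (b in (a + 1):nc) {
      diffs <- which(modal[a, ] != modal[b, ])
      span <- sum(binW[diffs], na.rm = TRUE)
      if (span < hallmarkMinSizeBp) {
        ra <- ufFind(parent, a); rb <- ufFind(parent, b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
    root <- vapply(seq_len(nc), function(i) ufFind(parent, i), integer(1))
    protoGroup <- match(root, unique(root))
    # absorb undersized groups into the nearest group by modal disagreement
    minCells <- max(5, ceiling(minGroupFraction * length(labels)))
    repeat {
      gSizes <- vapply(seq_len(max(protoGroup)), function(g)
        sum(labels %in% ulab[protoGroup == g]), integer(1))
      small <- which(gSizes < minCells)
      if (length(small) == 0 || max(protoGroup) == 1) break
      g <- small[which.min(gSizes[small])]
      gModal <- function(g) {
        cl <- which(protoGroup == g)
        if (length(cl) == 1) modal[cl, ]
        else apply(modal[cl, , drop = FALSE], 2, function(x) {
          x <- x[!is.na(x)]
          if (length(x) == 0) NA_integer_ else modalValue(x)
        })
      }
      mg <- gModal(g)
      spans <- vapply(seq_len(max(protoGroup)), function(h) {
        if (h == g) return(Inf)
        sum(binW[which(gModal(h) != mg)], na.rm = TRUE)
      }, numeric(1))
      target <- which.min(spans)
      protoGroup[protoGroup == g] <- target
      protoGroup <- match(protoGroup, sort(unique(protoGroup)))
    }
  } else {
    profKey <- apply(consensus, 1, paste, collapse = "")
    protoGroup <- match(profKey, unique(profKey))
  }

  nGroups <- max(protoGroup)
  sizes <- vapply(seq_len(nGroups), function(g)
    sum(labels %in% ulab[protoGroup == g]), integer(1))
  ord <- order(sizes, seq_len(nGroups), decreasing = TRUE)
  letter <- character(nGroups)
  letter[ord] <- make.unique(rep(LETTERS, length.out = nGroups))[seq_len(nGroups)]
  groupOfCluster <- letter[protoGroup]
  names(groupOfCluster) <- as.character(ulab)
  list(groups = unname(groupOfCluster[as.character(labels)]),
       groupMap = data.frame(cluster = ulab, group = unname(groupOfCluster),
                             stringsAsFactors = FALSE),
       consensus = consensus)
}

#' Deterministic hierarchical leaf order for the cell heatmap
#'
#' Average-linkage hierarchical clustering on Euclidean distance between
#' per-cell copy-number vectors; cells are pre-sorted by barcode so the
#' returned leaf order does not depend on input row order.
#'
#' @param copyMatrix cells x bins numeric matrix with barcode rownames.
#' @return character vector of barcodes in leaf order.
#' @export
orderCellsHierarchically <- function(copyMatrix) {
  if (is.null(rownames(copyMatrix))) dataError("copyMatrix needs barcode rownames")
  m <- copyMatrix[order(rownames(copyMatrix)), , drop = FALSE]
  if (nrow(m) == 1) return(rownames(m))
  hc <- stats::hclust(stats::dist(m), method = "average")
  rownames(m)[hc$order]
}

#' Run the full DAPC sub-clone clustering
#'
#' PCA embedding, BIC-guided k-means scan, discriminant axes, and the merge
#' of fine clusters into major groups, bundled into a
#' [ClusterSolution-class].
#'
#' @param em an [EventMatrix-class].
#' @param kRange candidate cluster counts, default `2:20`.
#' @param nStarts k-means restarts, default 10.
#' @param seed integer RNG seed.
#' @param varExplained,maxPcs see [pcaEmbed()].
#' @param hallmarkMinSizeBp,consensusThreshold,copyMatrix see
#'   [mergeClustersToGroups()].
#' @return a [ClusterSolution-class].
#' @export
dapcSubclones <- function(em, kRange = 2:20, nStarts = 10, seed = 1,
                          varExplained = 0.9, maxPcs = 40,
                          hallmarkMinSizeBp = 5e7, consensusThreshold = 0.5,
                          copyMatrix = NULL) {
  pca <- pcaEmbed(em, varExplained = varExplained, maxPcs = maxPcs)
  scan <- scanKBic(pca$scores, kRange = kRange, nStarts = nStarts, seed = seed)
  da <- if (scan$k >= 2) discriminantAxes(pca$scores, scan$labels)
        else list(scores = matrix(0, nrow(pca$scores), 0), eigenvalues = numeric(0))
  mg <- mergeClustersToGroups(scan$labels, em,
                              hallmarkMinSizeBp = hallmarkMinSizeBp,
                              consensusThreshold = consensusThreshold,
                              copyMatrix = copyMatrix)
  new("ClusterSolution", nPcs = as.integer(pca$nComponents), bic = scan$bic,
      k = as.integer(scan$k), clusters = scan$labels, scores = da$scores,
      eigenvalues = da$eigenvalues, groups = mg$groups,
      groupMap = mg$groupMap, consensus = mg$consensus,
      barcodes = rownames(binaryMatrix(em)),
      params = list(kRange = kRange, nStarts = nStarts, seed = seed,
                    varExplained = varExplained, maxPcs = maxPcs,
                    hallmarkMinSizeBp = hallmarkMinSizeBp,
                    consensusThreshold = consensusThreshold))
}
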