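#' Simulate a single-cell binned-count cohort from a clone mixture
#'
#' Draws per-cell, per-bin read counts from a negative-binomial model whose
#' mean is proportional to the cell's clone copy number in the bin:
#' `mu = readsPerMb * binWidthMb * copy / P0`, where `P0` is the
#' proportion-weighted mean copy number of the mixture (the cohort scaling
#' constant), so that a cell at the cohort-average ploidy totals
#' `readsPerMb` reads per Mb genome-wide. Cells are allocated to clones by
#' largest-remainder apportionment of `proportions` (so the default
#' 653:117:43:560 mixture reproduces those counts exactly at n = 1373) and
#' shuffled with the seed. Identical arguments and seed reproduce the count
#' table bit for bit.
#'
#' @param model a [GenomeModel-class].
#' @param clones named list of [CloneProfile-class] objects.
#' @param proportions named non-negative weights over (a subset of) the
#'   clone labels; need not sum to 1.
#' @param nCells number of cells to simulate.
#' @param readsPerMb mean sequencing depth in reads per Mb for a cell at the
#'   cohort-average ploidy (default 436).
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts. Default 0.08.
#' @param seed integer RNG seed.
#' @return a [SyntheticCohort-class].
#' @export
simulateCells <- function(model, clones, proportions, nCells,
                          readsPerMb = 436, dispersion = 0.08, seed = 1) {
  if (nCells < 1) configError("nCells must be >= 1")
  if (readsPerMb <= 0) configError("readsPerMb must be positive")
  if (is.null(names(proportions)) || !all(names(proportions) %in% names(clones)))
    configError("unknown clone label in proportions")
  if (any(proportions < 0) || sum(proportions) <= 0)
    configError("proportions must be non-negative with positive sum")
  labels <- names(proportions)[proportions > 0]
  props <- proportions[labels] / sum(proportions[labels])

  # exact largest-remainder apportionment of cells to clones
  raw <- nCells * props
  alloc <- floor(raw)
  rem <- nCells - sum(alloc)
  if (rem > 0) {
    extra <- order(raw - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1
  }

  cp <- vapply(clones[labels], binCopy, numeric(length(model@bins)), model = model)
  meanCopy <- vapply(clones[labels], cloneMeanCopy, numeric(1))
  ploidyNorm <- sum(props * meanCopy)
  widthMb <- width(model@bins) / 1e6
  muClone <- t(cp) * rep(readsPerMb / ploidyNorm, each = 1) # labels x bins
  muClone <- sweep(muClone, 2, widthMb, `*`)

  set.seed(seed)
  assignment <- sample(rep(labels, alloc))
  mu <- muClone[assignment, , drop = FALSE]
  n <- length(mu)
  draws <- if (dispersion > 0) {
    stats::rnbinom(n, mu = as.vector(mu), size = 1 / dispersion)
  } else {
    stats::rpois(n, lambda = as.vector(mu))
  }
  counts <- matrix(as.integer(draws), nrow = nCells)
  barcodes <- sprintf("cell_%05d", seq_len(nCells))
  dimnames(counts) <- list(barcodes, binIds(model))
  truth <- data.frame(barcode = barcodes, clone = assignment, noisy = FALSE,
                      seed = seed, stringsAsFactors = FALSE)
  new("SyntheticCohort", counts = counts, truth = truth, model = model,
      clones = clones[labels],
      params = list(readsPerMb = readsPerMb, dispersion = dispersion,
                    proportions = proportions, ploidyNorm = ploidyNorm,
                    seed = seed))
}

#' Re-draw a random subset of cells under a "noisy cell" model
#'
#' Emulates the low-quality cells flagged and removed by single-cell CNV
#' pipelines: a seeded subset of cells has its bin counts re-drawn with the
#' dispersion inflated (default x10) and a per-bin lognormal rate jitter, so
#' segment means are no longer consistent with an integer copy lattice.
#' Flags are recorded in the cohort truth.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param fraction fraction of cells to perturb, in `[0, 1)`. The study
#'   default is `102/1475` (~6.9%).
#' @param seed integer RNG seed.
#' @param dispersionFactor multiplier on the cohort dispersion.
#' @param jitterSd lognormal sd of the per-bin rate jitter.
#' @return the cohort with perturbed counts and updated `noisy` flags.
#' @export
injectNoisyCells <- function(cohort, fraction, seed = 1,
                             dispersionFactor = 10, jitterSd = 0.4) {
  if (fraction < 0 || fraction >= 1) configError("fraction must be in [0, 1)")
  nCells <- nrow(cohort@counts)
  n <- round(fraction * nCells)
  if (n == 0) return(cohort)
  p <- cohort@params
  widthMb <- width(cohort@model@bins) / 1e6
  set.seed(seed)
  idx <- sort(sample(nCells, n))
  disp <- max(p$dispersion, 0.02) * dispersionFactor
  for (i in idx) {
    cp <- binCopy(cohort@clones[[cohort@truth$clone[i]]], cohort@model)
    mu <- p$readsPerMb * widthMb * cp / p$ploidyNorm
    mu <- mu * stats::rlnorm(length(mu), 0, jitterSd)
    cohort@counts[i, ] <- as.integer(stats::rnbinom(length(mu), mu = mu, size = 1 / disp))
  }
  cohort@truth$noisy[idx] <- TRUE
  cohort@params$noisyFraction <- fraction
  cohort@params$noisySeed <- seed
  cohort
}

#' Generate a germline heterozygous-SNP panel over a genome model
#'
#' One het site per `spacingBp` (default 500 kb), with population minor
#' allele frequencies drawn Uniform(0.01, 0.5) and the alternate allele
#' assigned to a random haplotype. Positions are strictly increasing within
#' each chromosome.
#'
#' @param model a [GenomeModel-class].
#' @param spacingBp spacing between sites in bp.
#' @param seed integer RNG seed.
#' @return data.frame: `chrom`, `pos` (1-based), `ref`, `alt`, `genotype`,
#'   `maf`, `altHap`.
#' @export
makeSnpPanel <- function(model, spacingBp = 5e5, seed = 1) {
  set.seed(seed)
  chrom <- pos <- NULL
  for (i in seq_along(model@chromNames)) {
    p <- seq(round(spacingBp / 2), model@chromLengths[i], by = spacingBp)
    chrom <- c(chrom, rep(model@chromNames[i], length(p)))
    pos <- c(pos, p)
  }
  n <- length(pos)
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), character(1))
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
             genotype = "het", maf = stats::runif(n, 0.01, 0.5),
             altHap = sample(1:2, n, replace = TRUE), stringsAsFactors = FALSE)
}

# haplotype copies of each panel site under one clone
siteHapCopies <- function(clone, panel) {
  sites <- GRanges(panel$chrom, IRanges(panel$pos, panel$pos))
  ov <- findOverlaps(sites, clone@regions, select = "first")
  mc <- S4Vectors::mcols(clone@regions)
  data.frame(hap1 = mc$hap1[ov], hap2 = mc$hap2[ov])
}

#' Simulate group-level SNP allele counts under clone haplotype copy numbers
#'
#' For each clone represented among the non-noisy cells, draws per-site read
#' depths `Poisson(meanDepth * groupScale * totalCopies / ploidyRef)` and
#' alternate-allele counts `Binomial(depth, p')`, where
#' `p = altCopies / totalCopies` and `p' = p (1 - errorRate) + (1 - p)
#' errorRate`. A haplotype lost entirely therefore still yields alternate
#' reads at rate `errorRate`. Sites in regions of total copy 0 get zero
#' expected depth (not an error). With `scaleByGroupSize = TRUE` the depth of
#' each group is proportional to its cell count, mirroring the larger
#' allele-fraction spread of small pseudo-bulk groups.
#'
#' @param model a [GenomeModel-class] (sites must lie within it).
#' @param clones named list of [CloneProfile-class].
#' @param truth cohort truth data.frame (`barcode`, `clone`, `noisy`).
#' @param panel SNP panel from [makeSnpPanel()].
#' @param meanDepth mean per-site depth for an average-sized group at
#'   `ploidyRef` total copies.
#' @param errorRate per-read probability of reporting the other allele.
#' @param seed integer RNG seed.
#' @param ploidyRef copy number at which a site attains `meanDepth`
#'   (default 3, the near-triploid background).
#' @param scaleByGroupSize scale depth by relative group size.
#' @return data.frame: `chrom`, `pos`, `ref`, `alt`, `refDepth`, `altDepth`,
#'   `group`, `maf`.
#' @export
simulateAlleleCounts <- function(model, clones, truth, panel, meanDepth = 60,
                                 errorRate = 0.005, seed = 1, ploidyRef = 3,
                                 scaleByGroupSize = TRUE) {
  if (meanDepth <= 0) configError("meanDepth must be positive")
  keep <- !truth$noisy
  sizes <- table(truth$clone[keep])
  groups <- sort(names(sizes))
  set.seed(seed)
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    hap <- siteHapCopies(clones[[g]], panel)
    tot <- hap$hap1 + hap$hap2
    altCopies <- ifelse(panel$altHap == 1, hap$hap1, hap$hap2)
    scale <- if (scaleByGroupSize) as.numeric(sizes[g]) / mean(as.numeric(sizes)) else 1
    depth <- stats::rpois(nrow(panel), meanDepth * scale * tot / ploidyRef)
    p <- ifelse(tot > 0, altCopies / tot, 0)
    pErr <- p * (1 - errorRate) + (1 - p) * errorRate
    alt <- stats::rbinom(nrow(panel), depth, pErr)
    out[[gi]] <- data.frame(chrom = panel$chrom, pos = panel$pos,
                            ref = panel$ref, alt = panel$alt,
                            refDepth = depth - alt, altDepth = alt,
                            group = g, maf = panel$maf, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate allele counts for a single copy-number segment
#'
#' Convenience generator for LOH calibration: `nSites` het SNPs in a segment
#' with fixed haplotype copies, per-site depth `Poisson(depth)` and the same
#' error model as [simulateAlleleCounts()]. The alternate allele is assigned
#' to a random haplotype per site.
#'
#' @param hap1,hap2 haplotype copy numbers (integers >= 0, not both 0).
#' @param nSites number of het sites.
#' @param depth mean total depth per site.
#' @param errorRate per-read allele error rate.
#' @param seed integer RNG seed.
#' @return data.frame with `refDepth`, `altDepth`.
#' @export
simulateSegmentAlleleCounts <- function(hap1, hap2, nSites, depth,
                                        errorRate = 0.005, seed = 1) {
  set.seed(seed)
  tot <- hap1 + hap2
  if (tot <= 0) configError("segment must have positive total copy number")
  altHap <- sample(1:2, nSites, replace = TRUE)
  p <- ifelse(altHap == 1, hap1, hap2) / tot
  pErr <- p * (1 - errorRate) + (1 - p) * errorRate
  d <- stats::rpois(nSites, depth)
  alt <- stats::rbinom(nSites, d, pErr)
  data.frame(refDepth = d - alt, altDepth = alt)
}

#' Simulate anomalous read pairs (and split reads) around a junction
#'
#' Supporting pairs straddle the junction: each mate maps on the retained
#' side of its breakend (given by the BEDPE strand), at a distance drawn
#' from the insert-size model, so both ends fall within 3x the insert
#' distance of the breakends. Both read orientation classes (first read on
#' side 1 vs side 2) are represented whenever `nSupport >= 2`. Noise pairs
#' are uniform random inter-chromosomal records. Split reads cover the exact
#' breakend base on both sides.
#'
#' @param junction one junction: a 1-row data.frame or list with `chrom1`,
#'   `pos1`, `strand1`, `chrom2`, `pos2`, `strand2` (1-based positions).
#' @param nSupport number of supporting pairs (>= 0).
#' @param insertMean,insertSd insert-size model in bp (`insertMean > 0`).
#' @param nNoise number of uniform inter-chromosomal noise pairs.
#' @param mapqRange integer range noise mapping qualities are drawn from;
#'   supporting pairs draw from 30-60.
#' @param model a [GenomeModel-class]; required when `nNoise > 0`.
#' @param nSplit number of error-free junction-spanning split reads.
#' @param seed integer RNG seed.
#' @return list with `pairs` (BEDPE-like data.frame: `chrom1`, `start1`,
#'   `end1`, `chrom2`, `start2`, `end2`, `name`, `mapq1`, `mapq2`,
#'   `strand1`, `strand2`, `class`, `barcode`) and `splits` (data.frame:
#'   `read`, `chrom1`, `pos1`, `chrom2`, `pos2`).
#' @export
simulateReadPairs <- function(junction, nSupport, insertMean = 350,
                              insertSd = 50, nNoise = 0, mapqRange = c(0, 60),
                              model = NULL, nSplit = 0, seed = 1) {
  if (insertMean <= 0) configError("insertMean must be positive")
  if (nSupport < 0) configError("nSupport must be >= 0")
  readLen <- 100
  set.seed(seed)
  jx <- as.list(junction)

  sideCoords <- function(pos, strand, d) {
    # 0-based half-open read interval on the retained side of the breakend
    if (strand == "+") cbind(pos - d - readLen, pos - d)
    else cbind(pos + d - 1, pos + d + readLen - 1)
  }
  pairs <- NULL
  if (nSupport > 0) {
    tlen <- pmax(2 * readLen + 5, round(stats::rnorm(nSupport, insertMean, insertSd)))
    inner <- tlen - 2 * readLen
    d1 <- floor(stats::runif(nSupport) * (inner + 1))
    d2 <- inner - d1
    c1 <- t(vapply(seq_len(nSupport), function(i)
      sideCoords(jx$pos1, jx$strand1, d1[i])[1, ], numeric(2)))
    c2 <- t(vapply(seq_len(nSupport), function(i)
      sideCoords(jx$pos2, jx$strand2, d2[i])[1, ], numeric(2)))
    pairs <- data.frame(
      chrom1 = jx$chrom1, start1 = c1[, 1], end1 = c1[, 2],
      chrom2 = jx$chrom2, start2 = c2[, 1], end2 = c2[, 2],
      name = sprintf("support_%03d", seq_len(nSupport)),
      mapq1 = sample(30:60, nSupport, replace = TRUE),
      mapq2 = sample(30:60, nSupport, replace = TRUE),
      strand1 = jx$strand1, strand2 = jx$strand2,
      class = rep_len(c("12", "21"), nSupport),
      barcode = NA_character_, stringsAsFactors = FALSE)
  }
  if (nNoise > 0) {
    if (is.null(model)) configError("model required to place noise pairs")
    nchr <- length(model@chromNames)
    i1 <- sample(nchr, nNoise, replace = TRUE)
    i2 <- vapply(i1, function(i) sample(setdiff(seq_len(nchr), i), 1), integer(1))
    p1 <- floor(stats::runif(nNoise) * (model@chromLengths[i1] - readLen)) + 1
    p2 <- floor(stats::runif(nNoise) * (model@chromLengths[i2] - readLen)) + 1
    noise <- data.frame(
      chrom1 = model@chromNames[i1], start1 = p1 - 1, end1 = p1 + readLen - 1,
      chrom2 = model@chromNames[i2], start2 = p2 - 1, end2 = p2 + readLen - 1,
      name = sprintf("noise_%04d", seq_len(nNoise)),
      mapq1 = sample(mapqRange[1]:mapqRange[2], nNoise, replace = TRUE),
      mapq2 = sample(mapqRange[1]:mapqRange[2], nNoise, replace = TRUE),
      strand1 = sample(c("+", "-"), nNoise, replace = TRUE),
      strand2 = sample(c("+", "-"), nNoise, replace = TRUE),
      class = sample(c("12", "21"), nNoise, replace = TRUE),
      barcode = NA_character_, stringsAsFactors = FALSE)
    pairs <- rbind(pairs, noise)
  }
  if (is.null(pairs))
    pairs <- data.frame(chrom1 = character(), start1 = numeric(), end1 = numeric(),
                        chrom2 = character(), start2 = numeric(), end2 = numeric(),
                        name = character(), mapq1 = numeric(), mapq2 = numeric(),
                        strand1 = character(), strand2 = character(),
                        class = character(), barcode = character(),
                        stringsAsFactors = FALSE)
  splits <- if (nSplit > 0) {
    data.frame(read = sprintf("split_%03d", seq_len(nSplit)),
               chrom1 = jx$chrom1, pos1 = jx$pos1,
               chrom2 = jx$chrom2, pos2 = jx$pos2, stringsAsFactors = FALSE)
  } else {
    data.frame(read = character(), chrom1 = character(), pos1 = numeric(),
               chrom2 = character(), pos2 = numeric(), stringsAsFactors = FALSE)
  }
  list(pairs = pairs, splits = splits)
}

#' Simulate the cohort-level anomalous-read-pair table
#'
#' For every junction of every clone, generates supporting pairs in
#' proportion to the clone's non-noisy cell count, tags each record with a
#' member-cell barcode (so the pipeline can partition read pairs by
#' discovered group), and adds barcode-tagged uniform noise pairs. Split
#' reads are emitted per junction with carrier-cell barcodes.
#'
#' @param model,clones,truth as in [simulateAlleleCounts()].
#' @param supportPerCell expected junction-supporting pairs per carrier cell.
#' @param noisePairs total noise pairs across the cohort.
#' @param insertMean,insertSd insert model in bp.
#' @param nSplitPerJunction split reads per junction.
#' @param seed integer RNG seed.
#' @return list with `pairs` and `splits` as in [simulateReadPairs()], with
#'   barcodes filled in.
#' @export
simulateCohortReadPairs <- function(model, clones, truth, supportPerCell = 0.05,
                                    noisePairs = 100, insertMean = 350,
                                    insertSd = 50, nSplitPerJunction = 5,
                                    seed = 1) {
  keep <- truth[!truth$noisy, , drop = FALSE]
  allPairs <- list(); allSplits <- list()
  off <- 0
  for (cl in names(clones)) {
    jx <- clones[[cl]]@junctions
    cells <- keep$barcode[keep$clone == cl]
    if (nrow(jx) == 0 || length(cells) == 0) next
    for (j in seq_len(nrow(jx))) {
      off <- off + 1
      n <- max(2, round(supportPerCell * length(cells)))
      sim <- simulateReadPairs(jx[j, ], nSupport = n, insertMean = insertMean,
                               insertSd = insertSd, nSplit = nSplitPerJunction,
                               seed = deriveSeed(seed, off))
      set.seed(deriveSeed(seed, off + 5000))
      sim$pairs$barcode <- sample(cells, nrow(sim$pairs), replace = TRUE)
      sim$pairs$name <- sprintf("%s_%s_%s", cl, jx$name[j], sim$pairs$name)
      sim$splits$read <- sprintf("%s_%s_%s", cl, jx$name[j], sim$splits$read)
      allPairs[[length(allPairs) + 1]] <- sim$pairs
      allSplits[[length(allSplits) + 1]] <- sim$splits
    }
  }
  if (noisePairs > 0) {
    noise <- simulateReadPairs(list(chrom1 = model@chromNames[1], pos1 = 1e6,
                                    strand1 = "+", chrom2 = model@chromNames[2],
                                    pos2 = 1e6, strand2 = "+"),
                               nSupport = 0, nNoise = noisePairs,
                               insertMean = insertMean, insertSd = insertSd,
                               model = model, seed = deriveSeed(seed, 9999))
    set.seed(deriveSeed(seed, 9998))
    noise$pairs$barcode <- sample(keep$barcode, nrow(noise$pairs), replace = TRUE)
    allPairs[[length(allPairs) + 1]] <- noise$pairs
  }
  list(pairs = do.call(rbind, allPairs),
       splits = do.call(rbind, c(allSplits, list(
         data.frame(read = character(), chrom1 = character(), pos1 = numeric(),
                    chrom2 = character(), pos2 = numeric(),
                    stringsAsFactors = FALSE)))))
}
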