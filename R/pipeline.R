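pipelineDefaults <- function() {
  list(
    genome = "grch37",          # default four-clone model genome
    binWidth = 2e6,             # bp
    nCells = 1475,
    proportions = c(A = 653, B = 117, C = 43, D = 560),
    readsPerMb = 436,
    dispersion = 0.08,
    noisyFraction = 102 / 1475,
    snpSpacingBp = 5e5,
    meanDepth = 60,
    errorRate = 0.005,
    minEventSizeBp = 2e6,
    minConfidence = 15,
    roThreshold = 0.90,
    minPrevalence = 0.05,
    kMin = 2, kMax = 20,
    nStarts = 10,
    varExplained = 0.9,
    maxPcs = 40,
    hallmarkMinSizeBp = 5e7,
    consensusThreshold = 0.5,
    insertMean = 350, insertSd = 50,
    supportPerCell = 0.05,
    noisePairs = 100,
    minSupport = 2, minMapq = 20, minSeparation = 1e4,
    breakpointWindow = 2e6,
    noiseThreshold = 0.35,
    referenceCells = 50,
    writeCounts = FALSE,        # counts CSV/MTX can be large; opt in
    seed = 1,
    outdir = NULL)
}

#' Build and validate a pipeline configuration
#'
#' Starts from the packaged defaults (the four-clone study model at its
#' default parameters) and overrides the named fields. Unknown fields and
#' out-of-range thresholds are rejected.
#'
#' @param ... named overrides of the default fields; see
#'   `pipelineDefaults` in the package source for the full list.
#' @return a validated named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  cfg <- pipelineDefaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    configError(sprintf("unknown configuration key(s): %s",
                        paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  validatePipelineConfig(cfg)
}

validatePipelineConfig <- function(cfg) {
  chk <- function(ok, msg) if (!ok) configError(msg)
  chk(identical(cfg$genome, "grch37"), "genome must be 'grch37'")
  chk(cfg$binWidth > 0, "binWidth must be positive")
  chk(cfg$nCells >= 1, "nCells must be >= 1")
  chk(all(cfg$proportions >= 0) && sum(cfg$proportions) > 0,
      "proportions must be non-negative with positive sum")
  chk(cfg$readsPerMb > 0, "readsPerMb must be positive")
  chk(cfg$dispersion >= 0, "dispersion must be >= 0")
  chk(cfg$noisyFraction >= 0 && cfg$noisyFraction < 1,
      "noisyFraction must be in [0, 1)")
  chk(cfg$meanDepth > 0, "meanDepth must be positive")
  chk(cfg$errorRate >= 0 && cfg$errorRate < 0.5, "errorRate must be in [0, 0.5)")
  chk(cfg$minEventSizeBp >= 0, "minEventSizeBp must be >= 0")
  chk(cfg$roThreshold > 0 && cfg$roThreshold <= 1, "roThreshold must be in (0, 1]")
  chk(cfg$minPrevalence >= 0 && cfg$minPrevalence <= 1,
      "minPrevalence must be in [0, 1]")
  chk(cfg$kMin >= 1 && cfg$kMax >= cfg$kMin, "need 1 <= kMin <= kMax")
  chk(cfg$consensusThreshold > 0 && cfg$consensusThreshold <= 1,
      "consensusThreshold must be in (0, 1]")
  chk(cfg$insertMean > 0, "insertMean must be positive")
  chk(cfg$minSupport >= 1, "minSupport must be >= 1")
  chk(cfg$noiseThreshold > 0, "noiseThreshold must be positive")
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [pipelineConfig()] arguments
#'   (`proportions` as a named mapping). Unknown keys are rejected.
#' @return a validated `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) configError(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  if (!is.null(y$proportions)) y$proportions <- unlist(y$proportions)
  do.call(pipelineConfig, y)
}

#' Write a pipeline configuration to YAML
#'
#' @param cfg a `PipelineConfig`.
#' @param path output path.
#' @export
writePipelineConfig <- function(cfg, path) {
  y <- unclass(cfg)
  y$proportions <- as.list(y$proportions)
  yaml::write_yaml(y, path)
}

# consensus segments a group carries: matrix columns present in >= half of
# the group's cells, as (chrom, start, end, copy) intervals
groupConsensusSegments <- function(em, groups, threshold = 0.5) {
  mat <- binaryMatrix(em)
  events <- eventTable(em)
  out <- list()
  for (g in sort(unique(groups))) {
    frac <- colMeans(mat[groups == g, , drop = FALSE])
    idx <- which(frac >= threshold)
    if (length(idx))
      out[[g]] <- data.frame(events[idx, c("chrom", "start", "end", "copy")],
                             group = g, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Run the full sub-clone deconvolution pipeline
#'
#' Executes simulate -> per-cell CNV calling -> event matrix -> DAPC
#' clustering -> pseudo-bulk (log2 fold change + segment LOH) -> junction
#' analysis -> report, end-to-end deterministic under the configured seed.
#' Stage outputs are written under `outdir` (a temporary directory when not
#' configured); timings go to `message()` so the machine-readable summary is
#' byte-stable.
#'
#' @param cfg a `PipelineConfig` from [pipelineConfig()] /
#'   [readPipelineConfig()].
#' @return invisibly, a `ResultsBundle` list: `summary` (the statistics
#'   written to `summary.json`), `files` (paths + md5 checksums), `config`,
#'   plus the in-memory stage objects (`cohort`, `calls`, `eventMatrix`,
#'   `solution`, `loh`, `junctions`).
#' @export
runPipeline <- function(cfg) {
  if (!inherits(cfg, "PipelineConfig")) cfg <- do.call(pipelineConfig, as.list(cfg))
  outdir <- cfg$outdir %||% tempfile("sccnv_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))

  stage("simulate: cohort")
  dm <- buildDefaultModel(binWidth = cfg$binWidth)
  cohort <- simulateCells(dm$model, dm$clones, cfg$proportions, cfg$nCells,
                          readsPerMb = cfg$readsPerMb,
                          dispersion = cfg$dispersion,
                          seed = deriveSeed(cfg$seed, 1))
  cohort <- injectNoisyCells(cohort, cfg$noisyFraction,
                             seed = deriveSeed(cfg$seed, 2))
  panel <- makeSnpPanel(dm$model, spacingBp = cfg$snpSpacingBp,
                        seed = deriveSeed(cfg$seed, 3))
  snps <- simulateAlleleCounts(dm$model, dm$clones, cohortTruth(cohort), panel,
                               meanDepth = cfg$meanDepth,
                               errorRate = cfg$errorRate,
                               seed = deriveSeed(cfg$seed, 4))
  rp <- simulateCohortReadPairs(dm$model, dm$clones, cohortTruth(cohort),
                                supportPerCell = cfg$supportPerCell,
                                noisePairs = cfg$noisePairs,
                                insertMean = cfg$insertMean,
                                insertSd = cfg$insertSd,
                                seed = deriveSeed(cfg$seed, 5))

  stage("call-cnv: per-cell profiles")
  calls <- callCellProfiles(cohort, noiseThreshold = cfg$noiseThreshold)
  summ <- cellSummary(calls)
  retained <- summ$barcode[!summ$noisy]
  writeCnvBed(cnvSegments(calls), file.path(outdir, "cnv_calls.bed"))

  stage("build-matrix: filter, merge, binarize")
  em <- eventMatrixFromCalls(calls, minSizeBp = cfg$minEventSizeBp,
                             minConfidence = cfg$minConfidence,
                             roThreshold = cfg$roThreshold,
                             minPrevalence = cfg$minPrevalence,
                             barcodes = retained)
  utils::write.csv(eventTable(em), file.path(outdir, "event_clusters.csv"),
                   row.names = FALSE)

  stage("cluster: DAPC")
  sol <- dapcSubclones(em, kRange = cfg$kMin:cfg$kMax, nStarts = cfg$nStarts,
                       seed = deriveSeed(cfg$seed, 6),
                       varExplained = cfg$varExplained, maxPcs = cfg$maxPcs,
                       hallmarkMinSizeBp = cfg$hallmarkMinSizeBp,
                       consensusThreshold = cfg$consensusThreshold,
                       copyMatrix = binCopyMatrix(calls))
  assign <- groupAssignment(sol)
  utils::write.csv(assign, file.path(outdir, "assignments.csv"), row.names = FALSE)
  utils::write.csv(bicCurve(sol), file.path(outdir, "bic_curve.csv"), row.names = FALSE)
  utils::write.csv(data.frame(axis = seq_along(sol@eigenvalues),
                              eigenvalue = sol@eigenvalues),
                   file.path(outdir, "eigenvalues.csv"), row.names = FALSE)
  if (ncol(sol@scores) > 0)
    utils::write.csv(data.frame(barcode = sol@barcodes, sol@scores,
                                check.names = FALSE),
                     file.path(outdir, "da_scores.csv"), row.names = FALSE)

  stage("pseudobulk: log2FC + LOH")
  counts <- countsMatrix(cohort)
  tracks <- partitionAndAggregate(counts, assign)
  reference <- simulateNormalReference(dm$model, nCells = cfg$referenceCells,
                                       readsPerMb = cfg$readsPerMb,
                                       dispersion = cfg$dispersion,
                                       seed = deriveSeed(cfg$seed, 7))
  # pair each discovered group with the clone its member cells mostly carry
  truth <- cohortTruth(cohort)
  cloneOfGroup <- vapply(sort(unique(assign$group)), function(g) {
    bc <- assign$barcode[assign$group == g]
    modalValue(truth$clone[match(bc, truth$barcode)])
  }, character(1))
  consSegs <- groupConsensusSegments(em, assign$group[match(rownames(binaryMatrix(em)),
                                                            assign$barcode)])
  loh <- list()
  for (g in rownames(tracks)) {
    lfc <- log2FoldChange(tracks[g, ], reference)
    writeBedgraph(lfc, dm$model, file.path(outdir, sprintf("log2fc_%s.bedGraph", g)),
                  name = sprintf("log2FC %s vs normal", g))
    segs <- consSegs[consSegs$group == g, , drop = FALSE]
    gsnps <- snps[snps$group == cloneOfGroup[[g]], , drop = FALSE]
    if (nrow(segs) && nrow(gsnps)) {
      tab <- segmentAlleleFractions(gsnps, segs)
      tab$group <- g
      loh[[g]] <- tab
      writeSnpTsv(tab, file.path(outdir, sprintf("segment_loh_%s.tsv", g)))
    }
  }
  lohTab <- do.call(rbind, loh)

  stage("junctions: read-pair clustering")
  groupOfBarcode <- stats::setNames(assign$group, assign$barcode)
  pairGroups <- groupOfBarcode[rp$pairs$barcode]
  candsByGroup <- list()
  ev <- eventTable(em)
  breakpoints <- data.frame(chrom = rep(ev$chrom, 2), pos = c(ev$start, ev$end))
  for (g in sort(unique(assign$group))) {
    gp <- rp$pairs[!is.na(pairGroups) & pairGroups == g, , drop = FALSE]
    cands <- clusterReadPairs(gp, insertDistance = cfg$insertMean,
                              minSeparation = cfg$minSeparation,
                              minMapq = cfg$minMapq, minSupport = cfg$minSupport)
    if (nrow(cands)) {
      cands <- associateCnvBreakpoints(cands, breakpoints,
                                       window = cfg$breakpointWindow)
      for (i in seq_len(nrow(cands)))
        cands[i, ] <- refineWithSplitReads(cands[i, ], rp$splits,
                                           insertDistance = cfg$insertMean)
    }
    candsByGroup[[g]] <- cands
  }
  jx <- junctionPresenceByGroup(candsByGroup, insertDistance = cfg$insertMean)
  utils::write.table(jx, file.path(outdir, "junction_support.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (cfg$writeCounts) {
    writeCountsMtx(counts, file.path(outdir, "counts"))
    utils::write.csv(truth, file.path(outdir, "truth.csv"), row.names = FALSE)
  }

  stage("report")
  groupSizes <- as.list(table(assign$group))
  summary <- list(
    cellsTotal = nrow(counts),
    noisyFlagged = sum(summ$noisy),
    cellsRetained = length(retained),
    eventsRetained = ncol(binaryMatrix(em)),
    nPcs = sol@nPcs,
    chosenK = sol@k,
    nGroups = length(groupSizes),
    groupSizes = groupSizes,
    junctionSupport = if (nrow(jx)) jx else NULL,
    medianPloidy = stats::median(summ$meanPloidy[!summ$noisy]),
    seed = cfg$seed)
  bundle <- list(summary = summary, config = unclass(cfg), outdir = outdir,
                 cohort = cohort, calls = calls, eventMatrix = em,
                 solution = sol, loh = lohTab, junctions = jx,
                 snps = snps, tracks = tracks, reference = reference,
                 version = as.character(utils::packageVersion("scCloneCNV")))
  class(bundle) <- "ResultsBundle"
  writeSummary(bundle)
  invisible(bundle)
}

#' Write the machine-readable results bundle
#'
#' Serializes the pipeline summary (plus config echo, tool version and file
#' checksums) as `summary.json` in the run's output directory. Written via a
#' temporary file and atomic rename. The summary contains no timestamps, so
#' identical configurations and seeds produce byte-identical files.
#'
#' @param bundle a `ResultsBundle` from [runPipeline()].
#' @return invisibly, the path of the written JSON.
#' @export
writeSummary <- function(bundle) {
  outdir <- bundle$outdir
  if (!dir.exists(outdir) || file.access(outdir, 2) != 0)
    dataError(sprintf("output directory not writable: %s", outdir))
  files <- sort(setdiff(list.files(outdir, full.names = TRUE),
                        file.path(outdir, "summary.json")))
  checks <- data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE)
  cfgEcho <- bundle$config
  cfgEcho$outdir <- NULL  # location-independent: identical runs byte-match
  payload <- list(summary = bundle$summary, files = checks,
                  config = cfgEcho, version = bundle$version)
  tmp <- tempfile(tmpdir = outdir)
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  file.rename(tmp, file.path(outdir, "summary.json"))
  invisible(file.path(outdir, "summary.json"))
}
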