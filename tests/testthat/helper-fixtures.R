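# Shared fixtures, all built in code.

# toy genome: 3 chromosomes, 35 bins at 2 Mb
toyModel <- toyGenome()

# two toy clones on the toy genome: X is flat heterozygous-triploid with a
# chrB copy-2 arm; Y additionally gains chrC to 4 copies
toyClones <- function(model = toyModel) {
  ov <- function(chrom, start, end, h1, h2)
    data.frame(chrom = chrom, start = start, end = end, hap1 = h1, hap2 = h2)
  list(
    X = cloneProfile("X", model, ov("chrB", 0, 12e6, 1L, 1L)),
    Y = cloneProfile("Y", model, rbind(ov("chrB", 0, 12e6, 1L, 1L),
                                       ov("chrC", 0, 16e6, 2L, 2L))))
}

# memoized default model (GRanges construction is not free)
defaultModelCache <- new.env()
getDefaultModel <- function() {
  if (is.null(defaultModelCache$dm)) defaultModelCache$dm <- buildDefaultModel()
  defaultModelCache$dm
}

# memoized full-scale acceptance pipeline run shared by acceptance blocks
acceptanceCache <- new.env()
acceptanceRun <- function() {
  if (is.null(acceptanceCache$bundle)) {
    cfg <- pipelineConfig(seed = 20240, outdir = tempfile("acc_run_"))
    acceptanceCache$bundle <- suppressMessages(runPipeline(cfg))
  }
  acceptanceCache$bundle
}

# brute-force reciprocal-overlap single-linkage clustering (transitive
# closure over the pairwise relation), the oracle for mergeEvents()
bruteForceMerge <- function(events, ro = 0.9) {
  n <- nrow(events)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- i == j ||
      (events$copy[i] == events$copy[j] &&
         reciprocalOverlap(events$chrom[i], events$start[i], events$end[i],
                           events$chrom[j], events$start[j], events$end[j]) >= ro)
  }
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach[, k] %o% reach[k, ]) > 0
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) if (is.na(comp[i])) {
    cid <- cid + 1
    comp[which(reach[i, ])] <- cid
  }
  comp
}
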