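test_that("count simulation is a pure function of arguments and seed", {
  cl <- toyClones()
  a <- simulateCells(toyModel, cl, c(X = 1, Y = 1), 20, seed = 9)
  b <- simulateCells(toyModel, cl, c(X = 1, Y = 1), 20, seed = 9)
  expect_identical(countsMatrix(a), countsMatrix(b))
  expect_identical(cohortTruth(a), cohortTruth(b))
  c2 <- simulateCells(toyModel, cl, c(X = 1, Y = 1), 20, seed = 10)
  expect_false(identical(countsMatrix(a), countsMatrix(c2)))
})

test_that("degenerate mixtures and invalid arguments behave as specified", {
  dm <- getDefaultModel()
  co <- simulateCells(dm$model, dm$clones, c(A = 1, B = 0, C = 0, D = 0), 10,
                      seed = 1)
  expect_true(all(cohortTruth(co)$clone == "A"))
  expect_error(simulateCells(dm$model, dm$clones, c(Q = 1), 5),
               class = "sccnv_config_error")
  expect_error(simulateCells(dm$model, dm$clones, c(A = 1), 5, readsPerMb = 0),
               class = "sccnv_config_error")
})

test_that("Poisson-limit bin means match the analytic expectation within 1%", {
  dm <- getDefaultModel()
  co <- simulateCells(dm$model, dm$clones["A"], c(A = 1), 1000,
                      readsPerMb = 436, dispersion = 0, seed = 2)
  cp <- binCopy(dm$clones$A, dm$model)
  sel <- which(as.character(GenomicRanges::seqnames(dm$model@bins)) == "chr8" &
                 GenomicRanges::width(dm$model@bins) == 2e6)
  mu <- 436 * 2 * cp[sel] / co@params$ploidyNorm
  emp <- colMeans(countsMatrix(co)[, sel])
  expect_lt(max(abs(emp - mu) / mu), 0.01)
})

test_that("a full-size cohort emits the full complement of unique barcodes", {
  dm <- getDefaultModel()
  co <- simulateCells(dm$model, dm$clones, dm$proportions, 1475, seed = 4)
  expect_equal(nrow(countsMatrix(co)), 1475)
  expect_equal(anyDuplicated(cohortTruth(co)$barcode), 0L)
})

test_that("per-cell read totals are conserved around the depth model", {
  cl <- toyClones()
  co <- simulateCells(toyModel, cl, c(X = 1), 50, readsPerMb = 436,
                      dispersion = 0.08, seed = 6)
  cp <- binCopy(cl$X, toyModel)
  w <- GenomicRanges::width(toyModel@bins)
  mu <- 436 * (w / 1e6) * cp / co@params$ploidyNorm
  expTotal <- sum(mu)
  sdTotal <- sqrt(sum(mu + 0.08 * mu^2))
  totals <- rowSums(countsMatrix(co))
  expect_true(all(abs(totals - expTotal) < 3 * sdTotal + 3 * sdTotal / sqrt(50) * 3))
  expect_lt(abs(mean(totals) - expTotal) / expTotal, 0.05)
})

test_that("allele-count simulation follows the haplotype copy model", {
  # balanced heterozygote, no error: mean alt fraction 0.5
  ac <- simulateSegmentAlleleCounts(1, 1, 2000, 80, errorRate = 0, seed = 3)
  af <- ac$altDepth / (ac$refDepth + ac$altDepth)
  expect_equal(mean(af), 0.5, tolerance = 0.01)
  # 2+1 trisomic heterozygote at depth 60: median major fraction ~67%
  ac2 <- simulateSegmentAlleleCounts(2, 1, 500, 60, errorRate = 0.005, seed = 11)
  major <- pmax(ac2$refDepth, ac2$altDepth) / (ac2$refDepth + ac2$altDepth)
  expect_equal(round(100 * medianLower(major)), 67, tolerance = 2)
  # pure LOH without error: fractions exactly 0 or 1
  ac3 <- simulateSegmentAlleleCounts(2, 0, 300, 50, errorRate = 0, seed = 5)
  af3 <- ac3$altDepth / pmax(1, ac3$refDepth + ac3$altDepth)
  expect_true(all(af3 %in% c(0, 1)))
})

test_that("cohort allele counts respect region haplotypes and copy zero", {
  model <- toyModel
  clZ <- cloneProfile("Z", model,
                      data.frame(chrom = "chrC", start = 0, end = 16e6,
                                 hap1 = 0, hap2 = 0))
  truth <- data.frame(barcode = sprintf("c%02d", 1:6), clone = "Z",
                      noisy = FALSE)
  panel <- makeSnpPanel(model, spacingBp = 1e6, seed = 2)
  ac <- simulateAlleleCounts(model, list(Z = clZ), truth, panel,
                             meanDepth = 60, errorRate = 0, seed = 7,
                             scaleByGroupSize = FALSE)
  onC <- ac$chrom == "chrC"
  expect_true(all(ac$refDepth[onC] + ac$altDepth[onC] == 0))  # copy 0: no reads
  offC <- !onC
  expect_gt(mean(ac$refDepth[offC] + ac$altDepth[offC]), 30)
})

test_that("junction read pairs straddle the breakends with both orientations", {
  jx <- der18Junctions()[1, ]
  sim <- simulateReadPairs(jx, nSupport = 10, insertMean = 350, insertSd = 50,
                           seed = 1)
  p <- sim$pairs
  expect_equal(nrow(p), 10)
  expect_true(all(abs((p$start1 + p$end1) / 2 - 87337015) <= 3 * 350))
  expect_true(all(abs((p$start2 + p$end2) / 2 - 36119061) <= 3 * 350))
  expect_setequal(unique(p$class), c("12", "21"))
  # no support: only noise records
  sim0 <- simulateReadPairs(jx, nSupport = 0, nNoise = 7, model = toyModel,
                            seed = 2)
  expect_equal(nrow(sim0$pairs), 7)
  expect_true(all(startsWith(sim0$pairs$name, "noise")))
  expect_error(simulateReadPairs(jx, 5, insertMean = 0),
               class = "sccnv_config_error")
})

test_that("noisy-cell injection flags the requested seeded subset", {
  dm <- getDefaultModel()
  co <- simulateCells(dm$model, dm$clones, dm$proportions, 1475, seed = 8)
  co0 <- injectNoisyCells(co, fraction = 0, seed = 1)
  expect_identical(countsMatrix(co0), countsMatrix(co))
  expect_false(any(cohortTruth(co0)$noisy))
  coN <- injectNoisyCells(co, fraction = 102 / 1475, seed = 3)
  expect_equal(sum(cohortTruth(coN)$noisy), 102)
  coN2 <- injectNoisyCells(co, fraction = 102 / 1475, seed = 3)
  expect_identical(cohortTruth(coN)$noisy, cohortTruth(coN2)$noisy)
  expect_identical(countsMatrix(coN), countsMatrix(coN2))
  expect_error(injectNoisyCells(co, 1), class = "sccnv_config_error")
})

test_that("SNP panels are ordered, spaced and bounded", {
  panel <- makeSnpPanel(toyModel, spacingBp = 5e5, seed = 1)
  for (ch in unique(panel$chrom)) {
    pos <- panel$pos[panel$chrom == ch]
    expect_true(all(diff(pos) > 0))
  }
  expect_true(all(panel$maf > 0.01 & panel$maf < 0.5))
  expect_true(all(panel$altHap %in% 1:2))
  expect_true(all(panel$ref != panel$alt))
})
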