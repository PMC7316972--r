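test_that("PCA embedding reproduces structure and handles duplicates", {
  # one informative column: single PC reproduces it up to centering and sign
  x <- matrix(c(1, 1, 1, 0, 0, 0), ncol = 1,
              dimnames = list(sprintf("c%d", 1:6), "e1"))
  p <- pcaEmbed(x, nComponents = 1)
  cor1 <- cor(p$scores[, 1], x[, 1])
  expect_equal(abs(cor1), 1)
  # duplicated cells receive identical scores
  x2 <- rbind(x, x)
  rownames(x2) <- sprintf("c%d", 1:12)
  p2 <- pcaEmbed(x2, nComponents = 1)
  expect_equal(p2$scores[1:6, 1], p2$scores[7:12, 1], ignore_attr = TRUE)
  expect_error(pcaEmbed(matrix(0, 4, 3)), class = "sccnv_data_error")
  expect_error(pcaEmbed(x, nComponents = 10), class = "sccnv_config_error")
  # two-clone toy: PC1 separates the clones with positive margin
  toy <- cbind(e1 = rep(c(1, 0), each = 10), e2 = rep(c(0, 1), each = 10))
  rownames(toy) <- sprintf("c%d", 1:20)
  pt <- pcaEmbed(toy, nComponents = 1)
  g1 <- range(pt$scores[1:10, 1]); g2 <- range(pt$scores[11:20, 1])
  expect_true(g1[2] < g2[1] || g2[2] < g1[1])
})

test_that("the BIC scan recovers the blob count and degenerate geometry", {
  set.seed(41)
  blobs <- rbind(matrix(rnorm(200, 0, 0.1), ncol = 2),
                 matrix(rnorm(200, 10, 0.1), ncol = 2))
  scan <- scanKBic(blobs, kRange = 1:6, nStarts = 5, seed = 2)
  expect_equal(scan$k, 2)
  expect_equal(nrow(scan$bic), 6)        # curve covers the whole range
  expect_equal(length(scan$labels), 200)
  # identical points: epsilon-floored W, chosen k = 1
  same <- matrix(1, nrow = 30, ncol = 2)
  expect_equal(scanKBic(same, kRange = 1:4, seed = 1)$k, 1)
  expect_error(scanKBic(blobs, kRange = 2:500), class = "sccnv_config_error")
  # fixed seed reproducibility
  s1 <- scanKBic(blobs, kRange = 2:6, seed = 9)
  s2 <- scanKBic(blobs, kRange = 2:6, seed = 9)
  expect_identical(s1, s2)
})

test_that("discriminant axes maximize between/within variance ratios", {
  # two degenerate 1-D clusters: ridge handles zero within-variance
  x <- matrix(c(0, 0, 0, 1, 1, 1), ncol = 1)
  da <- discriminantAxes(x, c(1, 1, 1, 2, 2, 2))
  expect_length(da$eigenvalues, 1)
  expect_gt(da$eigenvalues[1], 1e3)
  expect_error(discriminantAxes(x, rep(1, 6)), class = "sccnv_data_error")

  # random labels on one blob: leading eigenvalue near the permutation floor
  set.seed(5)
  blob <- matrix(rnorm(300), ncol = 3)
  labs <- rep(1:2, each = 50)
  struct <- blob; struct[labs == 2, 1] <- struct[labs == 2, 1] + 5
  evStruct <- discriminantAxes(struct, labs)$eigenvalues[1]
  permEv <- replicate(100, discriminantAxes(blob, sample(labs))$eigenvalues[1])
  expect_gt(evStruct, max(permEv))

  # sorted, non-negative eigenvalues; within-group covariance diagonal
  labs3 <- sample(rep(1:3, length.out = 100))
  x3 <- matrix(rnorm(400), ncol = 4) + outer(labs3, 1:4)
  da3 <- discriminantAxes(x3, labs3)
  expect_true(all(diff(da3$eigenvalues) <= 1e-9))
  expect_true(all(da3$eigenvalues >= 0))
  sc <- da3$scores
  within <- sc - rowsum(sc, labs3)[labs3, ] / as.vector(table(labs3))[labs3]
  cov <- crossprod(within)
  offdiag <- cov - diag(diag(cov))
  expect_lt(max(abs(offdiag)) / max(diag(cov)), 1e-6)
})

test_that("cluster merging keeps only hallmark-scale differences apart", {
  # binary fallback path: all clusters share one consensus -> one group
  mat <- matrix(rep(c(1, 0), each = 10), ncol = 2,
                dimnames = list(sprintf("c%d", 1:10), NULL))
  events <- data.frame(chrom = "chr1", start = 0, end = c(6e7, 6e7),
                       copy = 3:2, nEvents = 1, nCells = 1,
                       sizeBp = c(6e7, 6e7), prevalence = 1)
  rownames(events) <- sprintf("e%d", 1:2)
  em <- new("EventMatrix", mat = matrix(as.integer(mat), 10, 2,
                                        dimnames = dimnames(mat)),
            events = events, params = list())
  mg <- mergeClustersToGroups(c(rep(1, 5), rep(2, 5)), em)
  expect_equal(length(unique(mg$groups)), 1)

  # modal-copy path: small-span differences merge, hallmark spans separate
  cpm <- matrix(3L, nrow = 10, ncol = 100,
                dimnames = list(sprintf("c%d", 1:10), NULL))
  attr(cpm, "binWidthBp") <- rep(2e6, 100)
  cpm[6:10, 1:40] <- 4L                 # 80 Mb difference: hallmark scale
  cpm[1:2, 95:100] <- 2L                # 12 Mb difference: below hallmark
  labs <- c(1, 1, 2, 2, 2, 3, 3, 3, 3, 3)
  mg2 <- mergeClustersToGroups(labs, em2 <- {
    m2 <- matrix(0L, 10, 2, dimnames = dimnames(mat))
    new("EventMatrix", mat = m2, events = events, params = list())
  }, copyMatrix = cpm, minGroupFraction = 0)
  grp <- mg2$groups
  expect_equal(grp[1], grp[3])   # clusters 1 and 2 merge (12 Mb apart)
  expect_false(grp[1] == grp[6]) # cluster 3 stays apart (80 Mb apart)
})

test_that("hierarchical cell ordering is deterministic and groups clones", {
  m <- matrix(c(1, 1, 1, 1, 5, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("b", "a", "c"), NULL))
  ord <- orderCellsHierarchically(m)
  # identical cells a and b are adjacent leaves
  expect_equal(abs(diff(match(c("a", "b"), ord))), 1)
  expect_equal(orderCellsHierarchically(m[1, , drop = FALSE]), "b")
  # zero-noise four-clone cohort: clones occupy contiguous leaf runs
  dm <- getDefaultModel()
  co <- simulateCells(dm$model, dm$clones, dm$proportions, 40,
                      dispersion = 0.005, seed = 21)
  calls <- callCellProfiles(co)
  ord2 <- orderCellsHierarchically(binCopyMatrix(calls))
  tr <- cohortTruth(co)
  cloneSeq <- tr$clone[match(ord2, tr$barcode)]
  expect_equal(length(rle(cloneSeq)$lengths), 4)
})

test_that("the four-clone cohort yields clone-pure clusters at the BIC optimum", {
  dm <- getDefaultModel()
  co <- simulateCells(dm$model, dm$clones, dm$proportions, 120,
                      dispersion = 0.02, seed = 22)
  calls <- callCellProfiles(co)
  em <- eventMatrixFromCalls(calls)
  pca <- pcaEmbed(em)
  scan <- scanKBic(pca$scores, kRange = 2:10, seed = 3)
  expect_gte(scan$k, 4)
  tr <- cohortTruth(co)
  truthClone <- tr$clone[match(rownames(binaryMatrix(em)), tr$barcode)]
  purity <- tapply(truthClone, scan$labels,
                   function(x) max(table(x)) / length(x))
  expect_true(all(purity == 1))
})
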