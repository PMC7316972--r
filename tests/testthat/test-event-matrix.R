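mkEvents <- function(chrom, start, end, copy, barcode, confidence = 100) {
  data.frame(chrom = chrom, start = start, end = end, copy = copy,
             confidence = confidence, barcode = barcode,
             stringsAsFactors = FALSE)
}

test_that("size and confidence filters are strict thresholds", {
  ev <- mkEvents("chr1", c(0, 0, 0), c(1.5e6, 2.1e6, 2e6), 3,
                 c("a", "b", "c"), confidence = c(40, 16, 100))
  out <- filterEvents(ev)
  expect_equal(out$barcode, "b")      # 1.5 Mb dropped, 2.0 Mb not > 2 Mb
  ev2 <- mkEvents("chr1", 0, 5e6, 3, c("a", "b"), confidence = c(15, 15.01))
  expect_equal(filterEvents(ev2)$barcode, "b")
  expect_equal(nrow(filterEvents(ev[0, ])), 0)
})

test_that("reciprocal overlap is the min of mutual overlap fractions", {
  expect_equal(reciprocalOverlap("chr1", 0, 100, "chr1", 0, 100), 1.0)
  expect_equal(reciprocalOverlap("chr1", 0, 100, "chr1", 10, 110), 0.90)
  expect_equal(reciprocalOverlap("chr1", 0, 100, "chr1", 200, 300), 0)
  expect_equal(reciprocalOverlap("chr1", 0, 100, "chr2", 0, 100), 0)
  # symmetry
  expect_equal(reciprocalOverlap("chr1", 0, 80, "chr1", 20, 100),
               reciprocalOverlap("chr1", 20, 100, "chr1", 0, 80))
})

test_that("event merging follows copy identity and single linkage", {
  # identical events in two cells: one cluster of two members
  ev <- mkEvents("chr1", c(0, 0), c(1e7, 1e7), 3, c("a", "b"))
  m <- mergeEvents(ev)
  expect_equal(nrow(m$clusters), 1)
  expect_equal(m$clusters$nCells, 2)
  # same interval, different copy number: two clusters
  ev2 <- mkEvents("chr1", c(0, 0), c(1e7, 1e7), c(3, 4), c("a", "b"))
  expect_equal(nrow(mergeEvents(ev2)$clusters), 2)
  # chain a-b at 0.92, b-c at 0.905, a-c at 0.84: one cluster by single linkage
  ev3 <- mkEvents("chr1", c(0, 8, 17) * 1e5, c(100, 108, 112) * 1e5, 3,
                  c("a", "b", "c"))
  ro <- function(i, j) reciprocalOverlap("chr1", ev3$start[i], ev3$end[i],
                                         "chr1", ev3$start[j], ev3$end[j])
  expect_gte(ro(1, 2), 0.9); expect_gte(ro(2, 3), 0.9); expect_lt(ro(1, 3), 0.9)
  m3 <- mergeEvents(ev3)
  expect_equal(nrow(m3$clusters), 1)
  expect_equal(sort(m3$members$barcode), c("a", "b", "c"))
  # canonical interval is the coordinate-wise lower median
  expect_equal(m3$clusters$start, medianLower(ev3$start))
  expect_equal(m3$clusters$end, medianLower(ev3$end))
})

test_that("merging equals brute-force transitive closure on random inputs", {
  set.seed(31)
  for (trial in 1:20) {
    n <- sample(4:12, 1)
    ev <- mkEvents(sample(c("chr1", "chr2"), n, replace = TRUE),
                   start = sample(0:20, n, replace = TRUE) * 1e6,
                   end = 0, copy = sample(2:4, n, replace = TRUE),
                   barcode = sample(letters[1:5], n, replace = TRUE))
    ev$end <- ev$start + sample(5:30, n, replace = TRUE) * 1e6
    m <- mergeEvents(ev, roThreshold = 0.8)
    ord <- order(ev$chrom, ev$start, ev$end, ev$barcode)
    oracle <- bruteForceMerge(ev[ord, ], ro = 0.8)
    # same partition (cluster ids may differ)
    expect_equal(length(unique(m$members$cluster)), length(unique(oracle)))
    expect_true(all(tapply(m$members$cluster, oracle,
                           function(x) length(unique(x)) == 1)))
    # partition property: every event in exactly one cluster
    expect_equal(nrow(m$members), n)
  }
})

test_that("matrix construction applies the prevalence rule", {
  barcodes <- sprintf("c%02d", 1:50)
  ev <- rbind(mkEvents("chr1", 0, 1e7, 3, barcodes[1:2]),      # 4% prevalence
              mkEvents("chr2", 0, 1e7, 3, barcodes),           # 100%
              mkEvents("chr3", 0, 1e7, 2, barcodes[1:10]))     # 20%
  m <- mergeEvents(ev)
  em <- buildEventMatrix(m, barcodes)
  expect_equal(ncol(binaryMatrix(em)), 2)  # the 4% column is discarded
  full <- which(eventTable(em)$chrom == "chr2")
  expect_true(all(binaryMatrix(em)[, full] == 1))
  # event-less cells retained as all-zero rows
  em2 <- buildEventMatrix(mergeEvents(mkEvents("chr1", 0, 1e7, 3, "c01")),
                          barcodes, minPrevalence = 0)
  expect_equal(sum(binaryMatrix(em2)), 1)
  expect_equal(nrow(binaryMatrix(em2)), 50)
  expect_error(buildEventMatrix(m, barcodes[1:3]), class = "sccnv_data_error")
  expect_error(buildEventMatrix(m, c("x", "x")), class = "sccnv_config_error")
})

test_that("threshold monotonicity and row-order invariance hold", {
  set.seed(57)
  n <- 30
  ev <- mkEvents(sample(c("chr1", "chr2"), n, replace = TRUE),
                 start = sample(0:15, n, replace = TRUE) * 1e6, end = 0,
                 copy = sample(2:4, n, replace = TRUE),
                 barcode = sample(sprintf("c%02d", 1:8), n, replace = TRUE))
  ev$end <- ev$start + sample(5:25, n, replace = TRUE) * 1e6
  nClust <- vapply(c(0.5, 0.7, 0.9, 0.99), function(thr)
    nrow(mergeEvents(ev, roThreshold = thr)$clusters), numeric(1))
  expect_true(all(diff(nClust) >= 0))  # raising RO never decreases clusters
  m <- mergeEvents(ev)
  barcodes <- sprintf("c%02d", 1:8)
  nCols <- vapply(c(0, 0.2, 0.5, 0.9), function(p)
    ncol(binaryMatrix(buildEventMatrix(m, barcodes, minPrevalence = p))),
    numeric(1))
  expect_true(all(diff(nCols) <= 0))   # raising prevalence never adds columns
  # permuting input rows changes nothing
  perm <- sample(n)
  m2 <- mergeEvents(ev[perm, ])
  expect_equal(m$clusters, m2$clusters)
})
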