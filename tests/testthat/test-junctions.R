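test_that("read-pair clustering recovers a planted junction among noise", {
  dm <- getDefaultModel()
  jx <- der18Junctions()[1, ]
  sim <- simulateReadPairs(jx, nSupport = 10, nNoise = 50, model = dm$model,
                           mapqRange = c(25, 60), seed = 71)
  cands <- clusterReadPairs(sim$pairs, insertDistance = 350)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$support, 10)
  expect_equal(cands$chrom1, "chr1")
  expect_lt(abs(cands$pos1 - 87337015), 3 * 350)
  expect_lt(abs(cands$pos2 - 36119061), 3 * 350)
  expect_error(clusterReadPairs(sim$pairs, insertDistance = 0),
               class = "sccnv_config_error")
})

test_that("one-orientation, short-separation and low-mapq pairs are rejected", {
  jx <- der18Junctions()[1, ]
  sim <- simulateReadPairs(jx, nSupport = 8, seed = 72)
  # force a single orientation class
  one <- sim$pairs; one$class <- "12"
  expect_equal(nrow(clusterReadPairs(one, 350)), 0)
  # intra-chromosomal cluster separated by only 8 kb
  near <- simulateReadPairs(list(chrom1 = "chr5", pos1 = 1e6, strand1 = "+",
                                 chrom2 = "chr5", pos2 = 1.008e6, strand2 = "-"),
                            nSupport = 6, seed = 73)
  expect_equal(nrow(clusterReadPairs(near$pairs, 350)), 0)
  # the same geometry 20 kb apart is accepted
  far <- simulateReadPairs(list(chrom1 = "chr5", pos1 = 1e6, strand1 = "+",
                                chrom2 = "chr5", pos2 = 1.02e6, strand2 = "-"),
                           nSupport = 6, seed = 73)
  expect_equal(nrow(clusterReadPairs(far$pairs, 350)), 1)
  # low mapping quality discards the pair
  low <- sim$pairs; low$mapq1 <- 5
  expect_equal(nrow(clusterReadPairs(low, 350)), 0)
})

test_that("candidates rank by support and associate with CNV breakpoints", {
  j1 <- der18Junctions()[1, ]; j2 <- der18Junctions()[2, ]
  s1 <- simulateReadPairs(j1, nSupport = 4, seed = 74)
  s2 <- simulateReadPairs(j2, nSupport = 9, seed = 75)
  cands <- clusterReadPairs(rbind(s1$pairs, s2$pairs), 350)
  expect_equal(cands$support, c(9, 4))  # descending support
  bp <- data.frame(chrom = c("chr1", "chr10", "chr18"),
                   pos = c(87000000, 36000000, 10000000))
  ann <- associateCnvBreakpoints(cands, bp)
  j1row <- which(ann$chrom1 == "chr1")
  expect_equal(ann$dist1[j1row], 87337015 - 87000000, tolerance = 1200)
  expect_true(ann$cnvAssociated[j1row])
  # a candidate 5 Mb from every breakpoint is not associated
  farBp <- data.frame(chrom = "chr1", pos = 80e6)
  ann2 <- associateCnvBreakpoints(cands[j1row, ], farBp)
  expect_false(ann2$cnvAssociated)
  # among two candidates near one break, the nearer ranks first
  two <- cands
  ann3 <- associateCnvBreakpoints(two, bp)
  expect_true(!is.unsorted(ann3$dist1 + ann3$dist2 - 1e9 * ann3$cnvAssociated))
})

test_that("split reads refine breakends to the exact planted bases", {
  for (j in 1:2) {
    jx <- der18Junctions()[j, ]
    sim <- simulateReadPairs(jx, nSupport = 10, nSplit = 5, seed = j)
    cand <- clusterReadPairs(sim$pairs, 350)
    refined <- refineWithSplitReads(cand[1, ], sim$splits, 350)
    expect_true(refined$refined)
    expect_equal(refined$refinedPos1, jx$pos1)
    expect_equal(refined$refinedPos2, jx$pos2)
  }
  # no spanning reads: unchanged at pair-interval resolution
  jx <- der18Junctions()[1, ]
  sim <- simulateReadPairs(jx, nSupport = 10, seed = 76)
  cand <- clusterReadPairs(sim$pairs, 350)
  un <- refineWithSplitReads(cand[1, ], sim$splits, 350)
  expect_false(un$refined)
  expect_true(is.na(un$refinedPos1))
  # a discordant minority split does not move the mode
  sim2 <- simulateReadPairs(jx, nSupport = 10, nSplit = 5, seed = 77)
  odd <- sim2$splits
  odd$pos1[1] <- odd$pos1[1] + 37
  ref2 <- refineWithSplitReads(cand[1, ], odd, 350)
  expect_equal(ref2$refinedPos1, jx$pos1)
})

test_that("the group table reports support with zeros for absence", {
  dm <- getDefaultModel()
  truth <- data.frame(barcode = sprintf("c%03d", 1:200),
                      clone = rep(c("A", "B", "C", "D"), each = 50),
                      noisy = FALSE)
  rp <- simulateCohortReadPairs(dm$model, dm$clones, truth,
                                supportPerCell = 0.2, noisePairs = 40,
                                seed = 78)
  groupOf <- stats::setNames(truth$clone, truth$barcode)
  cands <- lapply(c(A = "A", B = "B", C = "C", D = "D"), function(g) {
    clusterReadPairs(rp$pairs[groupOf[rp$pairs$barcode] == g, ], 350)
  })
  tab <- junctionPresenceByGroup(cands, 350)
  expect_equal(nrow(tab), 2)           # the two der(18) junctions, matched
  expect_true(all(tab$A > 0 & tab$D > 0))
  expect_true(all(tab$B == 0 & tab$C == 0))
  # a group without read pairs yields an all-zero column
  cands$E <- clusterReadPairs(rp$pairs[0, ], 350)
  tabE <- junctionPresenceByGroup(cands, 350)
  expect_true(all(tabE$E == 0))
  # near-identical junctions from two groups collapse to one row
  j <- der18Junctions()[1, ]
  jNear <- j; jNear$pos1 <- j$pos1 + 100; jNear$pos2 <- j$pos2 + 100
  cA <- clusterReadPairs(simulateReadPairs(j, 5, seed = 79)$pairs, 350)
  cB <- clusterReadPairs(simulateReadPairs(jNear, 5, seed = 80)$pairs, 350)
  tab2 <- junctionPresenceByGroup(list(G1 = cA, G2 = cB), 350)
  expect_equal(nrow(tab2), 1)
})

test_that("planted junctions are recovered with exact support over seeds", {
  dm <- getDefaultModel()
  jx <- der18Junctions()
  for (seed in 1:50) {
    n <- 3 + seed %% 5
    sim1 <- simulateReadPairs(jx[1, ], nSupport = n, nNoise = 100,
                              model = dm$model, mapqRange = c(25, 60),
                              seed = seed)
    sim2 <- simulateReadPairs(jx[2, ], nSupport = n, nNoise = 100,
                              model = dm$model, mapqRange = c(25, 60),
                              seed = seed + 1000)
    cands <- clusterReadPairs(rbind(sim1$pairs, sim2$pairs), 350)
    expect_equal(nrow(cands), 2)
    expect_equal(cands$support, c(n, n))
  }
  # no false positives on junction-free inputs at minimum support 2
  for (seed in 1:20) {
    noise <- simulateReadPairs(jx[1, ], nSupport = 0, nNoise = 150,
                               model = dm$model, mapqRange = c(25, 60),
                               seed = seed)
    expect_equal(nrow(clusterReadPairs(noise$pairs, 350)), 0)
  }
})
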