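test_that("allele frequencies follow the reference-read definition", {
  expect_equal(alleleFrequency(18, total = 20), 0.9)
  expect_true(is.na(alleleFrequency(0, total = 0)))
  expect_error(alleleFrequency(21, total = 20), "total")

  set.seed(1)
  g1 <- matrix(rbinom(60, 1L, 0.3), 10, 6)
  g2 <- matrix(0L, 10, 4)                      # monomorphic reference
  pan <- makePanel(seq(10, 100, by = 10), g1, g2, chromLength = 100)
  expect_equal(alleleFrequency(pan, "pop2"), rep(1, 10))
  fRef <- alleleFrequency(pan, "pop1")
  fNonref <- rowMeans(g1 == 1L)
  expect_equal(fRef + fNonref, rep(1, 10))
})

test_that("windowed diversity matches hand values and the pairwise oracle", {
  # 2 haplotypes differing at exactly 1 of 5 sites in a 100 bp window
  pop1 <- cbind(c(0L, 0L, 1L, 0L, 0L), c(0L, 0L, 0L, 0L, 0L))
  pan <- makePanel(c(10, 30, 50, 70, 90), pop1, pop1, chromLength = 100)
  pw <- piWindow(pan, "pop1", window = 100, step = 100)
  expect_equal(windowValues(pw)[1L], 0.01)

  # monomorphic window is 0, not missing
  mono <- matrix(1L, 5, 4)
  panM <- makePanel(c(10, 30, 50, 70, 90), mono, mono, chromLength = 100)
  expect_equal(windowValues(piWindow(panM, "pop1", 100, 100))[1L], 0)

  # windowed pi equals mean pairwise difference count / window length
  set.seed(9)
  g <- matrix(rbinom(20 * 50, 1L, runif(50)), nrow = 50, ncol = 20)
  panR <- makePanel(sort(sample.int(1000, 50)), g, g, chromLength = 1000)
  pwR <- piWindow(panR, "pop1", window = 1000, step = 1000)
  pairs <- utils::combn(20, 2)
  meanDiff <- mean(apply(pairs, 2L, function(p) sum(g[, p[1]] != g[, p[2]])))
  expect_equal(windowValues(pwR)[1L], meanDiff / 1000, tolerance = 1e-12)
})

hudsonOracle <- function(g1, g2) {
  # textbook per-site Hudson components, ratio of averages
  p1 <- rowMeans(g1, na.rm = TRUE)
  p2 <- rowMeans(g2, na.rm = TRUE)
  n1 <- rowSums(!is.na(g1))
  n2 <- rowSums(!is.na(g2))
  keep <- n1 >= 2 & n2 >= 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num[keep]) / sum(den[keep])
}

test_that("windowed Fst matches the per-site Hudson oracle and its limits", {
  set.seed(11)
  g1 <- matrix(rbinom(200 * 25, 1L, rep(runif(200), 25)), 200, 25)
  g2 <- matrix(rbinom(200 * 9, 1L, rep(runif(200), 9)), 200, 9)
  g2[sample(length(g2), 30)] <- NA_integer_     # some missing calls
  pan <- makePanel(sort(sample.int(4000, 200)), g1, g2, chromLength = 4000)
  f <- fstWindow(pan, window = 4000, step = 4000)
  expect_equal(attr(f, "raw")[1L], hudsonOracle(g1, g2), tolerance = 1e-12)

  # multi-window grid agrees with per-window brute force
  fW <- fstWindow(pan, window = 1000, step = 500)
  pos <- positions(pan)
  starts <- seq(1, 4000, by = 500)
  brute <- vapply(starts, function(s) {
    sel <- pos >= s & pos < s + 1000
    if (!any(sel)) return(NA_real_)
    hudsonOracle(g1[sel, , drop = FALSE], g2[sel, , drop = FALSE])
  }, numeric(1))
  expect_equal(attr(fW, "raw"), brute, tolerance = 1e-12)
  expect_equal(windowValues(fW), pmax(brute, 0), tolerance = 1e-12)

  # fixed differences give Fst 1 under both estimators
  gA <- matrix(1L, 20, 6)
  gB <- matrix(0L, 20, 4)
  panF <- makePanel(seq(10, 200, by = 10), gA, gB, chromLength = 200)
  expect_equal(windowValues(fstWindow(panF, 200, 200))[1L], 1)
  expect_equal(windowValues(fstWindow(panF, 200, 200, "wc"))[1L], 1)
})

test_that("Hudson Fst is symmetric under population relabelling", {
  set.seed(13)
  g1 <- matrix(rbinom(100 * 12, 1L, rep(runif(100), 12)), 100, 12)
  g2 <- matrix(rbinom(100 * 5, 1L, rep(runif(100, 0.2, 0.9), 5)), 100, 5)
  pos <- sort(sample.int(2000, 100))
  f12 <- fstWindow(makePanel(pos, g1, g2, 2000), 500, 250)
  f21 <- fstWindow(makePanel(pos, g2, g1, 2000), 500, 250)
  expect_equal(attr(f12, "raw"), attr(f21, "raw"), tolerance = 1e-12)
})

test_that("sweep screening flags top-Fst windows with a diversity contrast", {
  pan <- simulatePanel(PanelConfig(seed = 21L))
  fst <- fstWindow(pan)
  piD <- piWindow(pan, "pop1")
  piW <- piWindow(pan, "pop2")
  sc <- sweepCandidates(fst, piD, piW)
  w <- sweepWindows(sc)
  fl <- w[w$flagged, ]
  expect_gt(nrow(fl), 0L)
  expect_true(all(fl$fst >= sc@cutoff))
  expect_true(all(fl$piDom < fl$piWild))

  # degenerate quantile: every window with the diversity contrast is flagged
  sc1 <- sweepCandidates(fst, piD, piW, topQ = 1)
  w1 <- sweepWindows(sc1)
  eligible <- !is.na(w1$fst) & !is.na(w1$piDom) & !is.na(w1$piWild) &
    w1$piDom < w1$piWild
  expect_identical(w1$flagged, eligible)

  # sweep-region invariants of the default simulated panel
  inTruth <- w$start >= 3.7e6 & w$end <= 4.0e6
  expect_gt(mean(w$fst[inTruth], na.rm = TRUE), sc@cutoff)
  outTruth <- w$end < 3.7e6 | w$start > 4.0e6
  expect_lt(mean(w$piDom[inTruth], na.rm = TRUE),
            0.5 * mean(w$piDom[outTruth], na.rm = TRUE))
})

test_that("gene overlap reports only genes touching flagged windows", {
  pan <- simulatePanel(PanelConfig(seed = 22L))
  sc <- sweepCandidates(fstWindow(pan), piWindow(pan, "pop1"),
                        piWindow(pan, "pop2"),
                        geneModels = makeSpanSet(
                          c("inside", "outside"), "chr1",
                          starts = c(3.80e6, 1.0e6),
                          ends = c(3.85e6, 1.1e6)))
  genes <- candidateGenes(sc)
  expect_true("inside" %in% genes$gene)
  expect_false("outside" %in% genes$gene)
})

test_that("allele-frequency tracks cover the requested interval", {
  pan <- simulatePanel(PanelConfig(seed = 23L))
  tr <- alleleFrequencyTrack(pan, c(3.7e6, 4.0e6))
  nSites <- sum(positions(pan) >= 3.7e6 & positions(pan) <= 4.0e6)
  expect_equal(nrow(tr), nSites)
  # near-fixed domestic alleles inside the sweep
  minor <- pmin(tr$freqDom, 1 - tr$freqDom)
  expect_lt(mean(minor), 0.05)
  # empty interval gives an empty track
  expect_equal(nrow(alleleFrequencyTrack(pan, c(0, 0))), 0L)
  # gene annotation labels sites by location
  tr2 <- alleleFrequencyTrack(pan, c(3.7e6, 3.9e6),
                              geneModels = makeSpanSet("g1", "chr1",
                                                       3.75e6, 3.80e6))
  inGene <- tr2$pos >= 3.75e6 & tr2$pos <= 3.80e6
  expect_true(all(tr2$gene[inGene] == "g1"))
  expect_true(all(is.na(tr2$gene[!inGene])))
})
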