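test_that("the per-site index is the non-reference read fraction", {
  expect_identical(snpIndex(20, 0), 0)
  expect_identical(snpIndex(0, 15), 1)
  expect_identical(snpIndex(12, 4), 0.25)
  expect_true(is.na(snpIndex(0, 0)))
  expect_error(snpIndex(-1, 5), "non-negative")
  x <- snpIndex(rpois(100, 10), rpois(100, 10))
  expect_true(all(x >= 0 & x <= 1, na.rm = TRUE))
})

twoMarkerTable <- function() {
  ref <- matrix(c(8L, 4L), ncol = 1, dimnames = list(NULL, "B1"))
  nonref <- matrix(c(2L, 6L), ncol = 1, dimnames = list(NULL, "B1"))
  gt <- matrix("het", 2, 1, dimnames = list(NULL, "B1"))
  makeMarkerTable(c(1e5, 5e5), ref, nonref, gt, bulks = "B1",
                  chromLength = 2e6)
}

test_that("window values are unweighted marker means; empty windows are missing", {
  wp <- windowProfile(twoMarkerTable(), "B1", window = 1e6, step = 1e6)
  expect_equal(windowValues(wp)[1L], mean(c(0.2, 0.6)))
  expect_equal(markerCounts(wp)[1L], 2L)
  expect_true(is.na(windowValues(wp)[2L]))
  expect_equal(markerCounts(wp)[2L], 0L)
  expect_error(windowProfile(twoMarkerTable(), "nope"), "not found")
})

test_that("windowed index equals brute-force recomputation on random markers", {
  mt <- randomCountTable(1000L, chromLength = 5e6, seed = 31L,
                         zeroDepthFrac = 0.02)
  W <- 1e6
  S <- 1e4
  wp <- windowProfile(mt, "B1", window = W, step = S)
  idx <- snpIndex(refCounts(mt)[, "B1"], nonrefCounts(mt)[, "B1"])
  pos <- positions(mt)
  starts <- seq(1, 5e6, by = S)
  brute <- vapply(starts, function(s) {
    sel <- pos >= s & pos < s + W & !is.na(idx)
    if (!any(sel)) NA_real_ else mean(idx[sel])
  }, numeric(1))
  expect_equal(windowValues(wp), brute, tolerance = 1e-12)
})

test_that("delta profiles are antisymmetric and refuse mismatched grids", {
  a <- windowProfile(randomCountTable(200L, 1e6, seed = 41L), "B1",
                     window = 1e5, step = 5e4, chromLength = 1e6)
  b <- windowProfile(randomCountTable(200L, 1e6, seed = 42L), "B1",
                     window = 1e5, step = 5e4, chromLength = 1e6)
  dab <- deltaProfile(a, b)
  dba <- deltaProfile(b, a)
  expect_equal(windowValues(dab), -windowValues(dba))
  expect_true(all(abs(windowValues(dab)) <= 1, na.rm = TRUE))
  expect_equal(windowValues(deltaProfile(a, a)),
               ifelse(is.na(windowValues(a)), NA_real_, 0))
  other <- windowProfile(randomCountTable(200L, 1e6, seed = 43L), "B1",
                         window = 1e5, step = 2.5e4, chromLength = 1e6)
  expect_error(deltaProfile(a, other), "grids differ")
})

nullCrossMarkers <- function(nMarkers = 2000L, depthMean = 30, seed = 42L) {
  cfg <- CrossConfig(nMarkers = nMarkers, depthMean = depthMean,
                     causalPosition = NA, seed = seed)
  selectMarkers(sampleBulkCounts(simulateCross(cfg)),
                parents = c("P_P50", "P_Wild"))
}

test_that("the permutation band is centred on zero and reproducible", {
  mk <- nullCrossMarkers()
  med <- permutationBand(mk, "B_pos", "B_neg", nPerm = 1000, level = 0,
                         seed = 7L)
  expect_true(all(abs(med@upper) < 0.02, na.rm = TRUE))
  b1 <- permutationBand(mk, "B_pos", "B_neg", nPerm = 300, seed = 9L)
  b2 <- permutationBand(mk, "B_pos", "B_neg", nPerm = 300, seed = 9L)
  expect_identical(b1@upper, b2@upper)
  expect_true(all(b1@lower <= 0 & b1@upper >= 0, na.rm = TRUE))
  expect_warning(permutationBand(mk, "B_pos", "B_neg", nPerm = 50, seed = 1L),
                 "unstable")
})

test_that("band half-width shrinks as 1/sqrt(marker density)", {
  b1 <- permutationBand(nullCrossMarkers(500L, seed = 51L),
                        "B_pos", "B_neg", nPerm = 600, seed = 3L)
  b4 <- permutationBand(nullCrossMarkers(2000L, seed = 52L),
                        "B_pos", "B_neg", nPerm = 600, seed = 4L)
  hw <- function(b) mean((b@upper - b@lower) / 2, na.rm = TRUE)
  ratio <- hw(b1) / hw(b4)
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("windowed delta under the no-linkage null is mean-zero", {
  mk <- nullCrossMarkers(seed = 61L)
  nd <- nullCounts(mk, seed = 62L)
  d <- deltaProfile(windowProfile(nd, "B_pos"), windowProfile(nd, "B_neg"))
  expect_lt(abs(mean(windowValues(d), na.rm = TRUE)), 0.01)
  # nullCounts preserves observed depths
  expect_identical(refCounts(nd) + nonrefCounts(nd),
                   refCounts(mk) + nonrefCounts(mk))
})

# Hand-built profile/band pairs for the region-calling rules.
gridProfile <- function(values, window = 1e6, stat = "delta") {
  n <- length(values)
  new("WindowProfile", chrom = "chr1",
      start = seq(1, by = window, length.out = n),
      end = seq(1 + window, by = window, length.out = n),
      value = values, n = rep(10L, n), stat = stat,
      window = window, step = window)
}

gridBand <- function(n, lower = -0.2, upper = 0.2, window = 1e6) {
  new("ThresholdBand", chrom = "chr1",
      start = seq(1, by = window, length.out = n),
      end = seq(1 + window, by = window, length.out = n),
      lower = rep(lower, n), upper = rep(upper, n),
      level = 0.95, nPerm = 1000L, nullFreq = 0.25,
      window = window, step = window)
}

test_that("strict region calling flags contiguous band exceedances only", {
  v <- rep(0.1, 10)
  expect_length(candidateRegions(gridProfile(v), gridBand(10), "strict"), 0L)
  v[4:5] <- 0.5                                   # windows spanning 3-5 Mb
  r <- candidateRegions(gridProfile(v), gridBand(10), "strict")
  expect_length(r, 1L)
  expect_equal(GenomicRanges::start(r), 3e6 + 1)
  expect_equal(GenomicRanges::end(r), 5e6)
  expect_equal(r$peakDelta, 0.5)
  # one-sided lower calling picks up negative excursions
  v2 <- rep(0, 10)
  v2[8] <- -0.6
  expect_length(candidateRegions(gridProfile(v2), gridBand(10),
                                 "strict", side = "upper"), 0L)
  expect_length(candidateRegions(gridProfile(v2), gridBand(10),
                                 "strict", side = "lower"), 1L)
})

test_that("peak mode takes the top quantile with leftmost tie-breaking", {
  v <- c(0.1, 0.4, 0.4, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  r <- candidateRegions(gridProfile(v), mode = "peak", q = 0.1)
  expect_length(r, 1L)
  expect_equal(GenomicRanges::start(r), 1e6 + 1)   # leftmost of the tie
  rna <- candidateRegions(gridProfile(c(v[1:9], NA)), mode = "peak", q = 0.1)
  expect_length(rna, 1L)                           # missing windows never called
  expect_error(candidateRegions(gridProfile(v), mode = "strict"),
               "requires a permutation band")
})

test_that("region intersection narrows and is idempotent", {
  gr <- function(s, e) GenomicRanges::GRanges("chr19",
                                              IRanges::IRanges(s, e))
  narrowed <- intersectRegions(gr(3e6, 5e6), gr(1e6, 5e6))
  expect_equal(GenomicRanges::start(narrowed), 3e6)
  expect_equal(GenomicRanges::end(narrowed), 5e6)
  expect_length(intersectRegions(gr(1e6, 2e6), gr(3e6, 4e6)), 0L)
  a <- gr(c(1e6, 7e6), c(2e6, 9e6))
  expect_equal(intersectRegions(a, a), a)
})
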