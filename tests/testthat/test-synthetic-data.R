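test_that("zero recombination gives non-recombinant gametes; genotypes are never hom-alt", {
  cfg <- CrossConfig(nMarkers = 50L, recombRate = 0, nBC1 = 100L,
                     bulkSize = 10L, seed = 11L)
  tr <- simulateCross(cfg)
  g <- truthGenotypes(tr)
  expect_true(all(g %in% c(0L, 1L)))
  expect_true(all(apply(g, 1L, function(r) all(r == r[1L]))))
  # backcross constraint holds across seeds and recombination rates
  for (s in 1:4) {
    gs <- truthGenotypes(simulateCross(CrossConfig(
      nMarkers = 40L, nBC1 = 50L, bulkSize = 5L, recombRate = s, seed = s)))
    expect_true(all(gs %in% c(0L, 1L)))
  }
})

test_that("full penetrance makes the phenotype the causal-het indicator and bulks pure", {
  cfg <- CrossConfig(nMarkers = 100L, seed = 3L)
  tr <- simulateCross(cfg)
  expect_identical(phenotypes(tr),
                   truthGenotypes(tr)[, tr@causalMarker])
  bm <- bulkMembers(tr)
  expect_length(bm$pos, 20L)
  expect_true(all(truthGenotypes(tr)[bm$pos, tr@causalMarker] == 1L))
  expect_true(all(truthGenotypes(tr)[bm$neg, tr@causalMarker] == 0L))
})

test_that("segregation is 1:1 within binomial error in a large backcross", {
  cfg <- CrossConfig(nBC1 = 2000L, bulkSize = 100L, nMarkers = 41L, seed = 5L)
  tr <- simulateCross(cfg)
  g <- truthGenotypes(tr)
  expect_lt(abs(mean(g[, tr@causalMarker]) - 0.5), 0.03)
  se4 <- 4 * sqrt(0.25 / 2000)
  expect_true(all(abs(colMeans(g) - 0.5) < se4))
})

test_that("genotype correlation decays with inter-marker distance", {
  cfg <- CrossConfig(nBC1 = 2000L, bulkSize = 10L, nMarkers = 201L,
                     causalPosition = 1e6, seed = 8L)
  g <- truthGenotypes(simulateCross(cfg))
  pos <- seq(1, 20e6, length.out = 201L)
  at <- function(d) which.min(abs(pos - (pos[1L] + d)))
  cors <- vapply(c(1e6, 5e6, 12e6),
                 function(d) stats::cor(g[, 1L], g[, at(d)]), numeric(1))
  expect_true(all(diff(cors) < 0))
  expect_gt(cors[1L], 0.5)
})

test_that("insufficient segregants and out-of-range causal positions are errors", {
  expect_error(
    simulateCross(CrossConfig(nMarkers = 20L, nBC1 = 10L, bulkSize = 10L,
                              seed = 1L)),
    "insufficient segregants")
  expect_error(
    simulateCross(CrossConfig(chromLength = 1e4, nMarkers = 3L,
                              markerPositions = c(100, 200, 300),
                              causalPosition = 9000, nBC1 = 20L,
                              bulkSize = 2L, seed = 1L)),
    "outside the marker range")
  expect_error(CrossConfig(nBC1 = 10L, bulkSize = 11L), "bulkSize")
})

test_that("pooled counts track bulk allele frequencies and configured depth", {
  # with zero recombination the trait-negative bulk is hom-ref everywhere
  cfg <- CrossConfig(nMarkers = 200L, recombRate = 0, depthMean = 10000,
                     seed = 22L)
  tr <- simulateCross(cfg)
  mt <- sampleBulkCounts(tr)
  expect_true(all(nonrefCounts(mt)[, "B_neg"] == 0L))
  # ... and the trait-positive bulk is all-het: deep-coverage fraction -> 0.5
  frac <- nonrefCounts(mt)[, "B_pos"] /
    (refCounts(mt)[, "B_pos"] + nonrefCounts(mt)[, "B_pos"])
  expect_true(all(abs(frac - 0.5) < 0.02))
  # Poisson depth: mean observed depth within 5% of the configured mean
  cfg2 <- CrossConfig(nMarkers = 500L, depthMean = 30, seed = 23L)
  mt2 <- sampleBulkCounts(simulateCross(cfg2))
  d <- refCounts(mt2)[, c("B_pos", "B_neg")] +
    nonrefCounts(mt2)[, c("B_pos", "B_neg")]
  expect_lt(abs(mean(d) - 30) / 30, 0.05)
  # parents are pure by construction
  expect_true(all(nonrefCounts(mt2)[, "P_P50"] == 0L))
  expect_true(all(refCounts(mt2)[, "P_Wild"] == 0L))
})

test_that("panel simulation realises the configured sweep structure", {
  cfgS <- PanelConfig(nPop1 = 30L, nPop2 = 10L, nSites = 4000L,
                      chromLength = 1e6, sweepInterval = c(4e5, 6e5),
                      sweepDiversityPop1 = 0, seed = 2L)
  pan <- simulatePanel(cfgS)
  inSweep <- positions(pan) >= 4e5 & positions(pan) <= 6e5
  g1 <- panelMatrix(pan, "pop1")[inSweep, ]
  expect_true(all(apply(g1, 1L, function(r) length(unique(r)) == 1L)))

  # no sweep, no divergence: genome-wide Fst ~ 0
  cfg0 <- PanelConfig(nPop1 = 50L, nPop2 = 50L, nSites = 5000L,
                      chromLength = 1e6, sweepInterval = NA,
                      divergenceBoost = 0, seed = 4L)
  f <- fstWindow(simulatePanel(cfg0), window = 1e6, step = 1e6)
  expect_lt(abs(attr(f, "raw")[1L]), 0.02)

  # inconsistent sweep parameters warn rather than error
  expect_warning(
    simulatePanel(PanelConfig(nPop1 = 4L, nPop2 = 4L, nSites = 100L,
                              chromLength = 1e4, sweepInterval = c(1e3, 2e3),
                              baselineDiversity = 0.1,
                              sweepDiversityPop1 = 0.3, seed = 1L)),
    "exceeds baseline")
})

test_that("mean windowed diversity matches the configured heterozygosity times site density", {
  cfg <- PanelConfig(nPop1 = 30L, nPop2 = 10L, nSites = 20000L,
                     chromLength = 2e6, sweepInterval = NA,
                     baselineDiversity = 0.2, seed = 6L)
  pan <- simulatePanel(cfg)
  pw <- piWindow(pan, "pop1", window = 1e4, step = 1e4)
  expected <- 0.2 * 20000 / 2e6
  got <- mean(windowValues(pw), na.rm = TRUE)
  expect_lt(abs(got - expected) / expected, 0.1)
})

test_that("identical seeds reproduce simulations and byte-identical fixtures", {
  cfg <- CrossConfig(nMarkers = 80L, seed = 13L)
  pcfg <- PanelConfig(nPop1 = 8L, nPop2 = 4L, nSites = 300L,
                      chromLength = 1e5, sweepInterval = c(4e4, 6e4),
                      seed = 13L)
  t1 <- simulateCross(cfg)
  t2 <- simulateCross(cfg)
  expect_identical(truthGenotypes(t1), truthGenotypes(t2))
  expect_identical(bulkMembers(t1), bulkMembers(t2))
  d1 <- tempfile()
  d2 <- tempfile()
  writeFixture(t1, sampleBulkCounts(t1), simulatePanel(pcfg), d1)
  writeFixture(t2, sampleBulkCounts(t2), simulatePanel(pcfg), d2)
  for (f in c("markers.vcf", "panel.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("fixtures round-trip through the VCF reader without loss", {
  cfg <- CrossConfig(nMarkers = 60L, seed = 17L)
  tr <- simulateCross(cfg)
  mt <- sampleBulkCounts(tr)
  dir <- tempfile()
  paths <- writeFixture(tr, mt, NULL, dir)
  rt <- readVariants(paths[["vcf"]])
  expect_equal(length(rt), 60L)
  expect_identical(positions(rt), positions(mt))
  expect_identical(refCounts(rt), refCounts(mt))
  expect_identical(nonrefCounts(rt), nonrefCounts(mt))
  expect_identical(genotypeCalls(rt), genotypeCalls(mt))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$causalPosition, causalPosition(tr))
})
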