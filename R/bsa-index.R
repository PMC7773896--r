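#' Per-site SNP/InDel index
#'
#' The fraction of reads supporting the non-reference genotype:
#' `nonref / (ref + nonref)`.  An index of 0 means every read matches the
#' recurrent (P50-like) parent's genotype; 1 means every read supports the
#' alternative genotype.  Zero-depth sites return `NA` (they contribute
#' nothing to windows), never 0.
#'
#' @param ref,nonref non-negative read counts (vectorised).
#' @return numeric vector of indexes in `[0, 1]`, `NA` at zero depth.
#' @examples
#' snpIndex(20, 0)   # 0: identical to the reference parent
#' snpIndex(0, 15)   # 1: fully non-reference
#' snpIndex(12, 4)   # 0.25
#' @export
snpIndex <- function(ref, nonref) {
  if (any(ref < 0, na.rm = TRUE) || any(nonref < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  depth <- ref + nonref
  ifelse(depth > 0, nonref / depth, NA_real_)
}

.singleChrom <- function(x) {
  chrom <- unique(x@chrom)
  if (length(chrom) != 1L)
    stop("windowed statistics operate on one chromosome at a time; found: ",
         paste(chrom, collapse = ", "))
  chrom
}

.chromLengthOf <- function(x) {
  if (!is.na(x@chromLength)) x@chromLength else max(x@pos)
}

#' Sliding-window profile of the SNP/InDel index for one bulk
#'
#' Tiles the chromosome with half-open windows of width `window` every `step`
#' bp (anchored at position 1; the trailing partial windows are kept) and
#' assigns each window the unweighted mean of the per-marker indexes of all
#' markers inside it.  Empty windows are `NA`.
#'
#' @param markers a filtered [MarkerTable-class].
#' @param bulk bulk sample name.
#' @param window window width in bp (default 1 Mb).
#' @param step step size in bp (default 10 kb).
#' @param chromLength chromosome length; defaults to the table's recorded
#'   length, else the last marker position.
#' @return a [WindowProfile-class].
#' @export
windowProfile <- function(markers, bulk, window = 1e6, step = 1e4,
                          chromLength = NULL) {
  stopifnot(is(markers, "MarkerTable"))
  if (!bulk %in% colnames(markers@ref))
    stop("sample not found in marker table: ", bulk)
  chrom <- .singleChrom(markers)
  if (is.null(chromLength)) chromLength <- .chromLengthOf(markers)
  grid <- .makeWindows(chromLength, window, step)
  idx <- snpIndex(markers@ref[, bulk], markers@nonref[, bulk])
  wm <- .windowedMean(markers@pos, idx, grid)
  .WindowProfile(chrom, grid, wm$value, wm$n,
                 stat = paste0("index:", bulk), window = window, step = step)
}

#' Delta index profile between two bulks
#'
#' Per-window difference of windowed indexes, trait-positive bulk minus
#' trait-negative bulk, so linkage to a dominant causal locus yields a
#' positive delta (ideally 0.5 in a BC1 design).  Windows missing on either
#' side are missing in the difference.
#'
#' @param profilePos windowed index of the trait-positive bulk.
#' @param profileNeg windowed index of the trait-negative (reference-like)
#'   bulk, on an identical window grid.
#' @return a [WindowProfile-class] with statistic `"delta"`.
#' @export
deltaProfile <- function(profilePos, profileNeg) {
  stopifnot(is(profilePos, "WindowProfile"), is(profileNeg, "WindowProfile"))
  if (!.sameGrid(profilePos, profileNeg))
    stop("window grids differ between the two profiles")
  .WindowProfile(
    profilePos@chrom,
    list(start = profilePos@start, end = profilePos@end),
    profilePos@value - profileNeg@value,
    pmin(profilePos@n, profileNeg@n),
    stat = "delta", window = profilePos@window, step = profilePos@step
  )
}

#' Permutation confidence band for the delta index
#'
#' Confidence band for the windowed delta index under the no-linkage null of
#' a BC1 extreme-bulk design.  At each replicate, both bulks' non-reference
#' counts are redrawn at the observed per-marker depths as
#' `Binomial(depth, nullFreq)` — `nullFreq = 0.25` because a random BC1 bulk
#' is half heterozygous and half homozygous-reference — the windowed delta is
#' recomputed, and the band is the per-window empirical
#' `(1 - level)/2` and `1 - (1 - level)/2` quantile over replicates.
#'
#' @param markers a filtered [MarkerTable-class].
#' @param bulkPos,bulkNeg bulk sample names (their observed depths set the
#'   null's sampling variance).
#' @param window,step window geometry in bp.
#' @param nPerm number of replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param nullFreq null non-reference frequency in each bulk (default 0.25).
#' @param seed optional seed for reproducibility.
#' @param chromLength chromosome length; default as in [windowProfile()].
#' @return a [ThresholdBand-class].
#' @export
permutationBand <- function(markers, bulkPos, bulkNeg,
                            window = 1e6, step = 1e4, nPerm = 1000,
                            level = 0.95, nullFreq = 0.25, seed = NULL,
                            chromLength = NULL) {
  stopifnot(is(markers, "MarkerTable"))
  if (nPerm < 100) warning("nPerm < 100: band quantiles will be unstable")
  chrom <- .singleChrom(markers)
  if (is.null(chromLength)) chromLength <- .chromLengthOf(markers)
  if (!is.null(seed)) set.seed(seed)

  grid <- .makeWindows(chromLength, window, step)
  wi <- .windowIndex(markers@pos, grid)
  m <- length(markers@pos)

  depth <- function(b) markers@ref[, b] + markers@nonref[, b]
  d1 <- depth(bulkPos)
  d2 <- depth(bulkNeg)

  # Windowed mean of an (m x nPerm) index matrix; NA pattern (zero-depth
  # markers) is fixed across replicates.
  winMeans <- function(idx, ok) {
    idx[!ok, ] <- 0
    cs <- apply(idx, 2L, cumsum)
    cs <- rbind(0, cs)
    cn <- c(0L, cumsum(as.integer(ok)))
    n <- cn[wi$hi + 1L] - cn[wi$lo + 1L]
    s <- cs[wi$hi + 1L, , drop = FALSE] - cs[wi$lo + 1L, , drop = FALSE]
    list(value = sweep(s, 1L, pmax(n, 1L), "/"), n = n)
  }

  drawIdx <- function(d) {
    nr <- stats::rbinom(m * nPerm, rep(d, nPerm), nullFreq)
    matrix(nr / pmax(d, 1L), nrow = m, ncol = nPerm)
  }
  w1 <- winMeans(drawIdx(d1), d1 > 0L)
  w2 <- winMeans(drawIdx(d2), d2 > 0L)
  delta <- w1$value - w2$value
  empty <- w1$n == 0L | w2$n == 0L

  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- t(apply(delta, 1L, stats::quantile, probs = probs, names = FALSE))
  qs[empty, ] <- NA_real_

  new("ThresholdBand",
    chrom = chrom, start = as.numeric(grid$start), end = as.numeric(grid$end),
    lower = qs[, 1L], upper = qs[, 2L], level = level,
    nPerm = as.integer(nPerm), nullFreq = nullFreq,
    window = as.numeric(window), step = as.numeric(step)
  )
}

.profileGRanges <- function(chrom, start, end, sel) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start[sel], end = end[sel] - 1L)
  )
}

#' Call candidate regions from a delta profile
#'
#' Two calling modes.  `"strict"`: maximal runs of windows whose delta lies
#' outside the permutation band (`side = "two"` by default; `"upper"` or
#' `"lower"` for one-sided calls), merged when gaps are smaller than one
#' window.  `"peak"`: the top `q` fraction of windows ranked by delta (ties
#' broken leftmost-first), merged the same way — the pragmatic rule when
#' peaks approach but do not exceed the band.  Missing windows are never
#' called.
#'
#' @param delta a [WindowProfile-class] from [deltaProfile()].
#' @param band a [ThresholdBand-class] on the same grid (required for
#'   `"strict"`).
#' @param mode `"strict"` or `"peak"`.
#' @param q top fraction of windows for `"peak"` mode (default 0.005).
#' @param side which band violations count in `"strict"` mode.
#' @return a [GenomicRanges::GRanges] of candidate regions with metadata
#'   columns `peakDelta` (most extreme delta), `nWindows` (flagged windows
#'   merged into the region) and `peakPos` (midpoint of the peak window).
#' @export
candidateRegions <- function(delta, band = NULL,
                             mode = c("strict", "peak"), q = 0.005,
                             side = c("two", "upper", "lower")) {
  mode <- match.arg(mode)
  side <- match.arg(side)
  stopifnot(is(delta, "WindowProfile"))
  v <- delta@value

  if (mode == "strict") {
    if (is.null(band)) stop("strict mode requires a permutation band")
    if (length(band@start) != length(delta@start) ||
        any(band@start != delta@start))
      stop("band and delta profile are on different window grids")
    flag <- switch(side,
      two = v > band@upper | v < band@lower,
      upper = v > band@upper,
      lower = v < band@lower
    )
    flag[is.na(flag)] <- FALSE
    score <- abs(v)
  } else {
    ok <- which(!is.na(v))
    k <- ceiling(q * length(ok))
    flag <- logical(length(v))
    if (k > 0L && length(ok)) {
      o <- ok[order(-v[ok], delta@start[ok])]
      flag[o[seq_len(min(k, length(o)))]] <- TRUE
    }
    score <- v
  }

  if (!any(flag)) {
    return(GenomicRanges::GRanges(
      peakDelta = numeric(0), nWindows = integer(0), peakPos = numeric(0)
    ))
  }

  gr <- .profileGRanges(delta@chrom, delta@start, delta@end, flag)
  gr$score <- score[flag]
  gr$val <- v[flag]
  gr$mid <- (delta@start[flag] + delta@end[flag]) / 2
  merged <- GenomicRanges::reduce(gr, min.gapwidth = delta@window)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  peakDelta <- nWin <- numeric(length(merged))
  peakPos <- numeric(length(merged))
  for (i in seq_along(merged)) {
    inReg <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i]
    best <- inReg[which.max(gr$score[inReg])]
    peakDelta[i] <- gr$val[best]
    nWin[i] <- length(inReg)
    peakPos[i] <- gr$mid[best]
  }
  merged$peakDelta <- peakDelta
  merged$nWindows <- as.integer(nWin)
  merged$peakPos <- peakPos
  merged
}

#' Intersect candidate regions from two bulk sets
#'
#' Interval intersection of two candidate-region sets (e.g. the two body-
#' colour sets of a cross), used to narrow a shared candidate interval.  An
#' empty result is allowed.
#'
#' @param regions1,regions2 [GenomicRanges::GRanges] of candidate regions.
#' @return a [GenomicRanges::GRanges] of intersected intervals.
#' @export
intersectRegions <- function(regions1, regions2) {
  GenomicRanges::intersect(regions1, regions2, ignore.strand = TRUE)
}

#' Redraw bulk counts under the no-linkage null
#'
#' Returns a copy of the marker table in which every bulk's non-reference
#' counts are redrawn as `Binomial(observed depth, nullFreq)` — an
#' independent draw from the null family the permutation band is built from,
#' useful for calibration checks of the band.
#'
#' @param markers a filtered [MarkerTable-class].
#' @param bulks bulk sample names to redraw (default: all recorded bulks).
#' @param nullFreq null non-reference frequency (default 0.25, the BC1
#'   no-linkage expectation).
#' @param seed optional seed.
#' @return a [MarkerTable-class] with redrawn bulk counts.
#' @export
nullCounts <- function(markers, bulks = bulkSamples(markers),
                       nullFreq = 0.25, seed = NULL) {
  stopifnot(is(markers, "MarkerTable"), length(bulks) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  ref <- markers@ref
  nonref <- markers@nonref
  for (b in bulks) {
    depth <- ref[, b] + nonref[, b]
    nr <- stats::rbinom(length(depth), depth, nullFreq)
    nonref[, b] <- nr
    ref[, b] <- depth - nr
  }
  initialize(markers, ref = ref, nonref = nonref)
}
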