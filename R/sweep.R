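#' @rdname alleleFrequency
#' @param population `"pop1"` (domestic) or `"pop2"` (wild).
#' @export
setMethod("alleleFrequency", "PopulationPanel", function(x, population = c("pop1", "pop2"), ...) {
  population <- match.arg(population)
  g <- slot(x, population)
  n <- rowSums(!is.na(g))
  f <- rowSums(g == 0L, na.rm = TRUE) / n
  f[n == 0L] <- NA_real_
  f
})

#' @rdname alleleFrequency
#' @param total total read counts covering each site (count mode).
#' @export
setMethod("alleleFrequency", "numeric", function(x, total, ...) {
  if (any(x < 0, na.rm = TRUE) || any(total < x, na.rm = TRUE))
    stop("need 0 <= reference reads <= total reads")
  ifelse(total > 0, x / total, NA_real_)
})

# Per-site frequency of allele 1 plus the non-missing haploid call count.
.siteFreq <- function(g) {
  n <- rowSums(!is.na(g))
  p <- rowSums(g == 1L, na.rm = TRUE) / pmax(n, 1L)
  p[n == 0L] <- NA_real_
  list(p = p, n = n)
}

#' Windowed nucleotide diversity
#'
#' Per window, the unbiased per-site heterozygosity
#' `2 * p * (1 - p) * n / (n - 1)` summed over segregating sites and divided
#' by the window length in bp (the denominator is window span, not callable
#' sites).  Sites with fewer than 2 non-missing calls are skipped; windows
#' with no usable site are missing.
#'
#' @param panel a [PopulationPanel-class].
#' @param population `"pop1"` or `"pop2"`.
#' @param window,step window geometry in bp (defaults 10 kb / 5 kb).
#' @return a [WindowProfile-class] with statistic `"pi"` (per-bp diversity).
#' @export
piWindow <- function(panel, population = c("pop1", "pop2"),
                     window = 1e4, step = 5e3) {
  population <- match.arg(population)
  stopifnot(is(panel, "PopulationPanel"))
  sf <- .siteFreq(slot(panel, population))
  h <- ifelse(sf$n >= 2L, 2 * sf$p * (1 - sf$p) * sf$n / (sf$n - 1), NA_real_)
  grid <- .makeWindows(panel@chromLength, window, step)
  ws <- .windowedSum(panel@positions, h, grid)
  val <- ws$value / (grid$end - grid$start)
  val[ws$n == 0L] <- NA_real_
  .WindowProfile(panel@chrom, grid, val, ws$n,
                 stat = paste0("pi:", population), window = window, step = step)
}

# Per-site Hudson numerator/denominator.
.hudsonSite <- function(p1, n1, p2, n2) {
  N <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  list(N = N, D = D)
}

# Per-site Weir & Cockerham (1984) variance components for haploid samples,
# two populations.
.wcSite <- function(p1, n1, p2, n2) {
  nT <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / nT
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2            # r - 1 = 1
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nT - 2)
  nc <- nT - (n1^2 + n2^2) / nT
  list(N = msp - msg, D = msp + (nc - 1) * msg)
}

#' Windowed Fst between the two populations
#'
#' Ratio-of-averages window estimate: per window,
#' `Fst = sum(N_site) / sum(D_site)` over contributing sites.  The default
#' Hudson estimator uses
#' `N = (p1 - p2)^2 - p1 (1 - p1)/(n1 - 1) - p2 (1 - p2)/(n2 - 1)` and
#' `D = p1 (1 - p2) + p2 (1 - p1)`; it is robust to strongly unequal sample
#' sizes (e.g. 137 vs 7).  A Weir–Cockerham variance-components estimator is
#' available as an option.  Sites with fewer than 2 non-missing calls in
#' either population are skipped; negative window values are clamped to 0 for
#' reporting (the raw value is kept in the `raw` attribute).
#'
#' @param panel a [PopulationPanel-class].
#' @param window,step window geometry in bp (defaults 10 kb / 5 kb).
#' @param estimator `"hudson"` (default) or `"wc"`.
#' @return a [WindowProfile-class] with statistic `"fst"`; `attr(, "raw")`
#'   holds the unclamped values.
#' @export
fstWindow <- function(panel, window = 1e4, step = 5e3,
                      estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  stopifnot(is(panel, "PopulationPanel"))
  f1 <- .siteFreq(panel@pop1)
  f2 <- .siteFreq(panel@pop2)
  usable <- f1$n >= 2L & f2$n >= 2L
  comp <- if (estimator == "hudson") {
    .hudsonSite(f1$p, f1$n, f2$p, f2$n)
  } else {
    .wcSite(f1$p, f1$n, f2$p, f2$n)
  }
  N <- ifelse(usable, comp$N, NA_real_)
  D <- ifelse(usable, comp$D, NA_real_)

  grid <- .makeWindows(panel@chromLength, window, step)
  sN <- .windowedSum(panel@positions, N, grid)
  sD <- .windowedSum(panel@positions, D, grid)
  raw <- ifelse(sD$n > 0L & sD$value != 0, sN$value / sD$value, NA_real_)
  prof <- .WindowProfile(panel@chrom, grid, pmax(raw, 0), sN$n,
                         stat = paste0("fst:", estimator),
                         window = window, step = step)
  attr(prof, "raw") <- raw
  prof
}

#' Screen windows for selective-sweep candidates
#'
#' Flags windows whose Fst lies in the top `topQ` quantile (computed over the
#' analysed windows) *and* whose domestic diversity is below the wild
#' diversity — the joint signature of a domestication sweep.  Genes whose
#' span intersects a flagged window are reported as candidate domesticated
#' genes.
#'
#' @param fstProfile windowed Fst ([fstWindow()]).
#' @param piDom,piWild windowed diversity of the domestic / wild population on
#'   the same grid ([piWindow()]).
#' @param geneModels optional [GeneModelSet-class] for gene overlap reporting.
#' @param topQ top quantile of Fst to flag (default 0.05, i.e. top 5%).
#' @return a [SweepScan-class].
#' @export
sweepCandidates <- function(fstProfile, piDom, piWild, geneModels = NULL,
                            topQ = 0.05) {
  stopifnot(is(fstProfile, "WindowProfile"))
  if (!.sameGrid(fstProfile, piDom) || !.sameGrid(fstProfile, piWild))
    stop("fst and pi profiles are on different window grids")
  fst <- fstProfile@value
  cutoff <- stats::quantile(fst, probs = 1 - topQ, na.rm = TRUE, names = FALSE)
  flagged <- !is.na(fst) & fst >= cutoff &
    !is.na(piDom@value) & !is.na(piWild@value) & piDom@value < piWild@value

  windows <- data.frame(
    chrom = fstProfile@chrom, start = fstProfile@start, end = fstProfile@end,
    fst = fst, piDom = piDom@value, piWild = piWild@value, flagged = flagged
  )
  regions <- if (any(flagged)) {
    GenomicRanges::reduce(
      .profileGRanges(fstProfile@chrom, fstProfile@start, fstProfile@end,
                      flagged),
      min.gapwidth = 1L
    )
  } else {
    GenomicRanges::GRanges()
  }

  genes <- data.frame(gene = character(0), tx = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0))
  if (!is.null(geneModels) && length(regions)) {
    spans <- geneModels@genes
    hits <- GenomicRanges::findOverlaps(spans, regions, ignore.strand = TRUE)
    sel <- unique(S4Vectors::queryHits(hits))
    if (length(sel)) {
      genes <- data.frame(
        gene = spans$gene_id[sel], tx = spans$tx_id[sel],
        chrom = as.character(GenomicRanges::seqnames(spans))[sel],
        start = BiocGenerics::start(spans)[sel],
        end = BiocGenerics::end(spans)[sel]
      )
    }
  }

  new("SweepScan", windows = windows, cutoff = cutoff, topQ = topQ,
      regions = regions, genes = genes)
}

#' Per-site allele-frequency track over an interval
#'
#' Reference-allele frequencies of both populations at every panel site in
#' `interval`, suitable for plotting domestic vs wild frequency tracks.  When
#' gene models are supplied, each site is annotated with the id of the gene
#' model it falls in and whether it lies in CDS, elsewhere in the gene, or is
#' intergenic.
#'
#' @param panel a [PopulationPanel-class].
#' @param interval numeric `(start, end)` in bp, inclusive.
#' @param geneModels optional [GeneModelSet-class].
#' @return a data.frame with columns `pos`, `freqDom`, `freqWild` and, when
#'   gene models are given, `gene` and `location`.
#' @export
alleleFrequencyTrack <- function(panel, interval, geneModels = NULL) {
  stopifnot(is(panel, "PopulationPanel"), length(interval) == 2L)
  sel <- panel@positions >= interval[1] & panel@positions <= interval[2]
  fd <- alleleFrequency(panel, "pop1")[sel]
  fw <- alleleFrequency(panel, "pop2")[sel]
  track <- data.frame(pos = panel@positions[sel], freqDom = fd, freqWild = fw)
  if (!is.null(geneModels) && nrow(track)) {
    sites <- GenomicRanges::GRanges(panel@chrom,
                                    IRanges::IRanges(track$pos, track$pos))
    spans <- geneModels@genes
    hit <- GenomicRanges::findOverlaps(sites, spans, ignore.strand = TRUE,
                                       select = "first")
    track$gene <- ifelse(is.na(hit), NA_character_, spans$gene_id[hit])
    inCds <- GenomicRanges::countOverlaps(
      sites, unlist(geneModels@cds), ignore.strand = TRUE) > 0L
    track$location <- ifelse(is.na(hit), "intergenic",
                             ifelse(inCds, "CDS", "genic"))
  }
  track
}
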