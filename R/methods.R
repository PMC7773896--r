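# Accessors, coercions and show methods.

#' @rdname accessors
#' @export
setMethod("positions", "MarkerTable", function(x, ...) x@pos)

#' @rdname accessors
#' @export
setMethod("positions", "PopulationPanel", function(x, ...) x@positions)

#' @rdname accessors
#' @export
setMethod("refCounts", "MarkerTable", function(x, ...) x@ref)

#' @rdname accessors
#' @export
setMethod("nonrefCounts", "MarkerTable", function(x, ...) x@nonref)

#' @rdname accessors
#' @export
setMethod("genotypeCalls", "MarkerTable", function(x, ...) x@genotype)

#' @rdname accessors
#' @export
setMethod("parentSamples", "MarkerTable", function(x, ...) x@parents)

#' @rdname accessors
#' @export
setMethod("bulkSamples", "MarkerTable", function(x, ...) x@bulks)

#' @rdname accessors
#' @export
setMethod("filterLog", "MarkerTable", function(x, ...) x@filters)

#' @rdname accessors
#' @export
setMethod("windowValues", "WindowProfile", function(x, ...) x@value)

#' @rdname accessors
#' @export
setMethod("markerCounts", "WindowProfile", function(x, ...) x@n)

#' @rdname accessors
#' @export
setMethod("causalPosition", "SimTruth", function(x, ...) x@causalPosition)

#' @rdname accessors
#' @export
setMethod("truthGenotypes", "SimTruth", function(x, ...) x@genotypes)

#' @rdname accessors
#' @export
setMethod("phenotypes", "SimTruth", function(x, ...) x@phenotypes)

#' @rdname accessors
#' @export
setMethod("bulkMembers", "SimTruth", function(x, ...)
  list(pos = x@bulkPos, neg = x@bulkNeg))

#' @rdname accessors
#' @export
setMethod("panelMatrix", "PopulationPanel", function(x, population = c("pop1", "pop2"), ...) {
  slot(x, match.arg(population))
})

#' @rdname accessors
#' @export
setMethod("sweepWindows", "SweepScan", function(x, ...) x@windows)

#' @rdname accessors
#' @export
setMethod("sweepRegions", "SweepScan", function(x, ...) x@regions)

#' @rdname accessors
#' @export
setMethod("candidateGenes", "SweepScan", function(x, ...) x@genes)

#' @export
setMethod("length", "MarkerTable", function(x) length(x@pos))

#' @export
setMethod("length", "WindowProfile", function(x) length(x@start))

#' Coerce a marker table to a data.frame
#'
#' One row per site: chrom, pos, type, then per-sample `<sample>.ref` /
#' `<sample>.nonref` counts.
#'
#' @param x a [MarkerTable-class].
#' @param ... ignored.
#' @export
as.data.frame.MarkerTable <- function(x, ...) {
  samples <- colnames(x@ref)
  counts <- do.call(cbind, lapply(samples, function(s) {
    d <- data.frame(x@ref[, s], x@nonref[, s])
    names(d) <- paste0(s, c(".ref", ".nonref"))
    d
  }))
  cbind(data.frame(chrom = x@chrom, pos = x@pos, type = x@type), counts)
}

#' Coerce a window profile to a BED-like data.frame
#'
#' @param x a [WindowProfile-class].
#' @param ... ignored.
#' @export
as.data.frame.WindowProfile <- function(x, ...) {
  data.frame(chrom = x@chrom, start = x@start, end = x@end,
             value = x@value, n = x@n)
}

setMethod("show", "CrossConfig", function(object) {
  cat("CrossConfig:", object@nBC1, "BC1 individuals,",
      object@nMarkers, "markers on", object@chromLength / 1e6, "Mb\n")
  cat("  causal:", if (is.na(object@causalPosition)) "none (null cross)"
      else sprintf("%.0f bp", object@causalPosition),
      "| penetrance:", object@penetrance,
      "| recomb:", object@recombRate, "M\n")
  cat("  bulks of", object@bulkSize, "| depth", object@depthMean,
      "x (parents", object@parentDepthMean, "x) | seed", object@seed, "\n")
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@genotypes), "BC1 x",
      ncol(object@genotypes), "markers;",
      sum(object@phenotypes), "trait-positive\n")
  if (!is.na(object@causalPosition))
    cat("  causal locus at", object@causalPosition, "bp (marker",
        object@causalMarker, ")\n")
})

setMethod("show", "MarkerTable", function(object) {
  cat("MarkerTable:", length(object@pos), "sites x",
      ncol(object@ref), "samples",
      if (length(object@filters)) "(filtered)" else "(raw)", "\n")
  cat("  samples:", paste(colnames(object@ref), collapse = ", "), "\n")
  if (length(object@filters))
    cat("  retained", object@filters$nRetained, "of",
        object@filters$nInput, "sites;",
        object@filters$nReoriented, "reoriented to the P50 reference\n")
})

setMethod("show", "WindowProfile", function(object) {
  cat("WindowProfile [", object@stat, "]: ", length(object@start),
      " windows of ", object@window / 1e3, " kb every ",
      object@step / 1e3, " kb on ", object@chrom, "\n", sep = "")
  v <- object@value[!is.na(object@value)]
  if (length(v))
    cat(sprintf("  value range %.4g .. %.4g (%d empty windows)\n",
                min(v), max(v), sum(is.na(object@value))))
})

setMethod("show", "ThresholdBand", function(object) {
  cat("ThresholdBand:", length(object@start), "windows,",
      object@nPerm, "replicates, level", object@level,
      ", null freq", object@nullFreq, "\n")
})

setMethod("show", "PopulationPanel", function(object) {
  cat("PopulationPanel:", length(object@positions), "sites;",
      ncol(object@pop1), "domestic +", ncol(object@pop2),
      "wild haploid samples on", object@chrom, "\n")
  if (!anyNA(object@sweepInterval))
    cat("  simulated sweep:", object@sweepInterval[1], "-",
        object@sweepInterval[2], "bp\n")
})

setMethod("show", "PanelConfig", function(object) {
  cat("PanelConfig:", object@nPop1, "+", object@nPop2, "haploid samples,",
      object@nSites, "sites on", object@chromLength / 1e6, "Mb\n")
})

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet:", length(object@cds), "gene models on",
      length(object@genome), "sequence(s)")
  if (length(object@flagged))
    cat(";", length(object@flagged), "flagged (incomplete CDS)")
  cat("\n")
})

setMethod("show", "SweepScan", function(object) {
  cat("SweepScan: top", object@topQ * 100, "% Fst cutoff =",
      signif(object@cutoff, 4), "\n")
  cat("  ", sum(object@windows$flagged), "of", nrow(object@windows),
      "windows flagged in", length(object@regions), "region(s);",
      nrow(object@genes), "candidate gene(s)\n")
})

#' Plot a window profile with an optional confidence band
#'
#' Simple base-graphics track of a windowed statistic along the chromosome;
#' a permutation band, when supplied, is drawn as dashed lines.
#'
#' @param x a [WindowProfile-class].
#' @param band optional [ThresholdBand-class].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plotProfile <- function(x, band = NULL, ...) {
  mid <- (x@start + x@end) / 2 / 1e6
  graphics::plot(mid, x@value, type = "l", xlab = "position (Mb)",
                 ylab = x@stat, ...)
  if (!is.null(band)) {
    bmid <- (band@start + band@end) / 2 / 1e6
    graphics::lines(bmid, band@upper, lty = 2, col = "blue")
    graphics::lines(bmid, band@lower, lty = 2, col = "blue")
  }
  invisible(NULL)
}
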