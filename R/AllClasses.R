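#' @import methods
#' @importFrom S4Vectors isSingleNumber
#' @importClassesFrom GenomicRanges GRanges CompressedGRangesList
#' @importClassesFrom Biostrings DNAStringSet
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Configuration of a simulated BC1 bulk-sequencing experiment
#'
#' Describes a backcross between a homozygous recessive recurrent parent and an
#' F1 carrier of a dominant allele, plus the pooled sequencing of two
#' extreme-phenotype bulks.  All random draws of the simulators derive from
#' `seed`.
#'
#' @slot chromLength chromosome length in bp.
#' @slot nMarkers number of informative markers (parent-divergent sites).
#' @slot markerPositions sorted bp positions, or length zero for an evenly
#'   spaced grid over the chromosome.
#' @slot causalPosition bp position of the causal locus, or `NA` for a null
#'   (no-linkage) cross in which phenotypes are random coin flips.
#' @slot recombRate expected crossovers per meiosis (Morgans per chromosome).
#' @slot nBC1 number of backcross individuals.
#' @slot bulkSize individuals pooled per bulk.
#' @slot penetrance probability that a carrier of the causal heterozygous
#'   genotype expresses the trait.
#' @slot depthMean mean pooled sequencing depth per marker per bulk.
#' @slot parentDepthMean mean per-parent sequencing depth per marker.
#' @slot seed master seed for the simulation.
#'
#' @seealso [CrossConfig()], [simulateCross()], [sampleBulkCounts()]
#' @export
setClass("CrossConfig",
  representation(
    chromLength = "numeric", nMarkers = "integer",
    markerPositions = "numeric", causalPosition = "numeric",
    recombRate = "numeric", nBC1 = "integer", bulkSize = "integer",
    penetrance = "numeric", depthMean = "numeric",
    parentDepthMean = "numeric", seed = "integer"
  )
)

setValidity("CrossConfig", function(object) {
  msg <- character()
  if (!isSingleNumber(object@chromLength) || object@chromLength < 1)
    msg <- c(msg, "chromLength must be a positive number")
  if (object@nMarkers < 1L) msg <- c(msg, "nMarkers must be positive")
  if (object@nBC1 < 1L) msg <- c(msg, "nBC1 must be positive")
  if (object@bulkSize < 1L) msg <- c(msg, "bulkSize must be positive")
  if (object@bulkSize > object@nBC1)
    msg <- c(msg, "bulkSize must not exceed nBC1")
  if (object@penetrance < 0 || object@penetrance > 1)
    msg <- c(msg, "penetrance must lie in [0, 1]")
  if (object@recombRate < 0) msg <- c(msg, "recombRate must be >= 0")
  if (object@depthMean <= 0 || object@parentDepthMean <= 0)
    msg <- c(msg, "sequencing depths must be positive")
  if (!is.na(object@causalPosition) &&
      (object@causalPosition < 1 || object@causalPosition > object@chromLength))
    msg <- c(msg, "causalPosition must lie in [1, chromLength]")
  if (length(object@markerPositions) &&
      is.unsorted(object@markerPositions, strictly = TRUE))
    msg <- c(msg, "markerPositions must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated backcross
#'
#' Holds the per-individual genotypes and phenotypes of a simulated BC1
#' population together with bulk membership and the causal locus, so that
#' downstream mapping statistics can be checked against truth.
#'
#' Genotypes are coded 0 = homozygous for the recurrent (P50-like) parent
#' allele and 1 = heterozygous; a BC1 individual is never homozygous for the
#' wild allele.
#'
#' @slot config the [CrossConfig-class] that produced the simulation.
#' @slot markerPositions realised marker positions (bp).
#' @slot genotypes integer matrix, individuals x markers, values in {0, 1}.
#' @slot phenotypes integer vector of 0/1 trait calls.
#' @slot bulkPos,bulkNeg indices of the trait-positive / trait-negative bulk
#'   members.
#' @slot causalPosition bp of the causal locus (`NA` for a null cross).
#' @slot causalMarker marker index at the causal position (`NA` for null).
#' @export
setClass("SimTruth",
  representation(
    config = "CrossConfig", markerPositions = "numeric",
    genotypes = "matrix", phenotypes = "integer",
    bulkPos = "integer", bulkNeg = "integer",
    causalPosition = "numeric", causalMarker = "integer"
  )
)

setValidity("SimTruth", function(object) {
  g <- object@genotypes
  if (!all(g %in% c(0L, 1L)))
    return("BC1 genotypes must be 0 (hom-ref) or 1 (het); hom-alt is impossible in a backcross")
  if (ncol(g) != length(object@markerPositions))
    return("genotype columns must match markerPositions")
  if (nrow(g) != length(object@phenotypes))
    return("genotype rows must match phenotypes")
  TRUE
})

#' Configuration of a simulated two-population genotype panel
#'
#' Emulates the structure of a resequenced strain panel: a large "domestic"
#' population and a small "wild" one, with an optional selective-sweep interval
#' in which the domestic population has depressed diversity and shifted allele
#' frequencies.
#'
#' @slot nPop1,nPop2 haploid sample counts for population 1 ("domestic") and
#'   population 2 ("wild").
#' @slot chromLength chromosome length (bp).
#' @slot nSites number of biallelic sites.
#' @slot sweepInterval numeric of length 2 (start, end in bp) or `NA` for no
#'   sweep.
#' @slot baselineDiversity expected per-site heterozygosity outside the sweep.
#' @slot sweepDiversityPop1 expected per-site heterozygosity of pop1 inside
#'   the sweep (much smaller than baseline for a sweep).
#' @slot divergenceBoost minimum allele-frequency shift between populations
#'   inside the sweep.
#' @slot seed master seed.
#' @export
setClass("PanelConfig",
  representation(
    nPop1 = "integer", nPop2 = "integer", chromLength = "numeric",
    nSites = "integer", sweepInterval = "numeric",
    baselineDiversity = "numeric", sweepDiversityPop1 = "numeric",
    divergenceBoost = "numeric", seed = "integer"
  )
)

setValidity("PanelConfig", function(object) {
  msg <- character()
  if (object@nPop1 < 2L || object@nPop2 < 2L)
    msg <- c(msg, "both populations need >= 2 haploid samples")
  if (object@nSites < 1L) msg <- c(msg, "nSites must be positive")
  if (object@baselineDiversity < 0 || object@baselineDiversity > 0.5 ||
      object@sweepDiversityPop1 < 0 || object@sweepDiversityPop1 > 0.5)
    msg <- c(msg, "per-site heterozygosities must lie in [0, 0.5]")
  si <- object@sweepInterval
  if (!anyNA(si)) {
    if (length(si) != 2L || si[1] >= si[2])
      msg <- c(msg, "sweepInterval must be (start, end) with start < end")
    else if (si[1] < 1 || si[2] > object@chromLength)
      msg <- c(msg, "sweepInterval must lie within the chromosome")
  }
  if (object@divergenceBoost < 0 || object@divergenceBoost > 1)
    msg <- c(msg, "divergenceBoost must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Biallelic genotype panel for two populations
#'
#' Haploid 0/1 allele matrices (sites x samples, `NA` = missing call) for a
#' "domestic" population 1 and a "wild" population 2 on one chromosome.
#' Allele 1 is the non-reference allele.
#'
#' @slot chrom chromosome name.
#' @slot chromLength chromosome length in bp.
#' @slot positions 1-based site positions, strictly increasing.
#' @slot pop1,pop2 integer allele matrices (sites x haploid samples).
#' @slot sweepInterval simulated truth interval (bp) or `NA` when unknown.
#' @export
setClass("PopulationPanel",
  representation(
    chrom = "character", chromLength = "numeric", positions = "numeric",
    pop1 = "matrix", pop2 = "matrix", sweepInterval = "numeric"
  )
)

setValidity("PopulationPanel", function(object) {
  msg <- character()
  if (nrow(object@pop1) != length(object@positions) ||
      nrow(object@pop2) != length(object@positions))
    msg <- c(msg, "allele matrices must have one row per site")
  if (is.unsorted(object@positions, strictly = TRUE))
    msg <- c(msg, "positions must be strictly increasing")
  vals <- c(object@pop1, object@pop2)
  if (!all(vals %in% c(0L, 1L, NA_integer_)))
    msg <- c(msg, "alleles must be 0, 1 or NA")
  if (length(msg)) msg else TRUE
})

#' Table of allele-count records for parents and bulks
#'
#' One row per variant site, with per-sample reference / non-reference read
#' counts and per-sample genotype calls.  Produced unfiltered by
#' [readVariants()] or [sampleBulkCounts()]; [selectMarkers()] returns the
#' filtered, P50-reoriented marker set on which all index statistics operate
#' (filter provenance is recorded in the `filters` slot).
#'
#' @slot chrom per-site chromosome.
#' @slot pos per-site 1-based position.
#' @slot type per-site variant type, `"SNP"` or `"InDel"`.
#' @slot ref,nonref integer matrices (sites x samples) of reads supporting the
#'   reference / non-reference genotype; column names are sample names.
#' @slot genotype character matrix (sites x samples) with values
#'   `"hom-ref"`, `"hom-alt"`, `"het"`, `"missing"`.
#' @slot parents names of the two parent samples, recurrent (P50-like) parent
#'   first; `NA` when roles are not yet assigned.
#' @slot bulks names of the bulk samples.
#' @slot chromLength chromosome length in bp when known, else `NA`.
#' @slot filters list recording applied marker filters (empty when raw).
#' @export
setClass("MarkerTable",
  representation(
    chrom = "character", pos = "numeric", type = "character",
    ref = "matrix", nonref = "matrix", genotype = "matrix",
    parents = "character", bulks = "character",
    chromLength = "numeric", filters = "list"
  )
)

setValidity("MarkerTable", function(object) {
  msg <- character()
  n <- length(object@pos)
  if (length(object@chrom) != n || length(object@type) != n)
    msg <- c(msg, "chrom, pos and type must have equal length")
  for (s in c("ref", "nonref", "genotype")) {
    m <- slot(object, s)
    if (nrow(m) != n) msg <- c(msg, sprintf("%s must have one row per site", s))
  }
  if (!identical(colnames(object@ref), colnames(object@nonref)) ||
      !identical(colnames(object@ref), colnames(object@genotype)))
    msg <- c(msg, "count and genotype matrices must share sample columns")
  if (any(object@ref < 0, na.rm = TRUE) || any(object@nonref < 0, na.rm = TRUE))
    msg <- c(msg, "read counts must be non-negative")
  bad <- !(object@genotype %in% c("hom-ref", "hom-alt", "het", "missing"))
  if (any(bad)) msg <- c(msg, "invalid genotype codes")
  if (length(msg)) msg else TRUE
})

#' Sliding-window statistic along a chromosome
#'
#' Half-open windows `[start, end)` of width `window` every `step` bp, each
#' carrying the mean (or windowed estimate) of a statistic over the markers or
#' sites it contains.  Windows containing no informative markers hold `NA`,
#' never 0.
#'
#' @slot chrom chromosome name.
#' @slot start,end window bounds (half-open, 1-based start).
#' @slot value per-window statistic (`NA` when empty).
#' @slot n per-window count of contributing markers/sites.
#' @slot stat label of the statistic (e.g. `"index"`, `"delta"`, `"fst"`,
#'   `"pi"`).
#' @slot window,step nominal window width and step (bp).
#' @export
setClass("WindowProfile",
  representation(
    chrom = "character", start = "numeric", end = "numeric",
    value = "numeric", n = "integer", stat = "character",
    window = "numeric", step = "numeric"
  )
)

setValidity("WindowProfile", function(object) {
  if (length(object@start) != length(object@end) ||
      length(object@start) != length(object@value) ||
      length(object@start) != length(object@n))
    return("start, end, value and n must have equal length")
  if (any(object@end <= object@start))
    return("windows must satisfy end > start")
  if (is.unsorted(object@start)) return("windows must be sorted")
  TRUE
})

#' Permutation confidence band for a delta-index profile
#'
#' Per-window lower/upper bounds of the windowed delta index under a
#' no-linkage null, obtained from `nPerm` replicate redraws of the bulk read
#' counts at the observed depths.
#'
#' @slot chrom chromosome name.
#' @slot start,end window bounds matching the profile grid.
#' @slot lower,upper per-window empirical quantile bounds (`NA` for empty
#'   windows).
#' @slot level confidence level (e.g. 0.95).
#' @slot nPerm number of permutation replicates.
#' @slot nullFreq non-reference allele frequency of the null model.
#' @slot window,step window geometry (bp).
#' @export
setClass("ThresholdBand",
  representation(
    chrom = "character", start = "numeric", end = "numeric",
    lower = "numeric", upper = "numeric", level = "numeric",
    nPerm = "integer", nullFreq = "numeric",
    window = "numeric", step = "numeric"
  )
)

setValidity("ThresholdBand", function(object) {
  if (length(object@lower) != length(object@start) ||
      length(object@upper) != length(object@start))
    return("lower/upper must match the window grid")
  ok <- !is.na(object@lower) & !is.na(object@upper)
  if (any(object@lower[ok] > object@upper[ok]))
    return("lower bound above upper bound")
  TRUE
})

#' Gene models with genome sequence access
#'
#' Spliced-CDS gene models parsed from GFF3 plus the genome they refer to.
#' Models whose total CDS length is not a multiple of 3 are flagged and
#' excluded from coding-effect calls.
#'
#' @slot cds [GenomicRanges::GRangesList] of CDS intervals per transcript,
#'   sorted in ascending genomic order.
#' @slot exons [GenomicRanges::GRangesList] of exon intervals per transcript
#'   (may be empty for a transcript).
#' @slot genes [GenomicRanges::GRanges] of transcript spans with `gene_id` and
#'   `tx_id` metadata.
#' @slot genome [Biostrings::DNAStringSet] genome sequences.
#' @slot flagged ids of models excluded because their CDS length is not
#'   divisible by 3.
#' @export
setClass("GeneModelSet",
  representation(
    cds = "CompressedGRangesList", exons = "CompressedGRangesList",
    genes = "GRanges", genome = "DNAStringSet", flagged = "character"
  )
)

#' Selective-sweep scan result
#'
#' Windows flagged as sweep candidates: top-quantile Fst combined with a
#' domestic-below-wild diversity contrast, plus the genes overlapping flagged
#' windows.
#'
#' @slot windows data.frame with per-window chrom, start, end, fst, piDom,
#'   piWild, and the `flagged` indicator.
#' @slot cutoff Fst value at the top-quantile cutoff.
#' @slot topQ quantile used (e.g. 0.05 for top 5%).
#' @slot regions [GenomicRanges::GRanges] of merged flagged windows.
#' @slot genes data.frame of candidate genes overlapping flagged windows.
#' @export
setClass("SweepScan",
  representation(
    windows = "data.frame", cutoff = "numeric", topQ = "numeric",
    regions = "GRanges", genes = "data.frame"
  )
)
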