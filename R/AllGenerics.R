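#' @importFrom BiocGenerics start end width strand
NULL

#' Accessors for bsasweep objects
#'
#' Small accessor family for the package's S4 containers; prefer these over
#' direct slot access.
#'
#' @param x a bsasweep object.
#' @param ... passed to methods.
#' @return the requested component; see the method for the class of `x`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("positions", function(x, ...) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("refCounts", function(x, ...) standardGeneric("refCounts"))

#' @rdname accessors
#' @export
setGeneric("nonrefCounts", function(x, ...) standardGeneric("nonrefCounts"))

#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x, ...) standardGeneric("genotypeCalls"))

#' @rdname accessors
#' @export
setGeneric("parentSamples", function(x, ...) standardGeneric("parentSamples"))

#' @rdname accessors
#' @export
setGeneric("bulkSamples", function(x, ...) standardGeneric("bulkSamples"))

#' @rdname accessors
#' @export
setGeneric("filterLog", function(x, ...) standardGeneric("filterLog"))

#' @rdname accessors
#' @export
setGeneric("windowValues", function(x, ...) standardGeneric("windowValues"))

#' @rdname accessors
#' @export
setGeneric("markerCounts", function(x, ...) standardGeneric("markerCounts"))

#' @rdname accessors
#' @export
setGeneric("causalPosition", function(x, ...) standardGeneric("causalPosition"))

#' @rdname accessors
#' @export
setGeneric("bulkMembers", function(x, ...) standardGeneric("bulkMembers"))

#' @rdname accessors
#' @export
setGeneric("truthGenotypes", function(x, ...) standardGeneric("truthGenotypes"))

#' @rdname accessors
#' @export
setGeneric("phenotypes", function(x, ...) standardGeneric("phenotypes"))

#' @rdname accessors
#' @export
setGeneric("panelMatrix", function(x, population, ...)
  standardGeneric("panelMatrix"))

#' @rdname accessors
#' @export
setGeneric("sweepWindows", function(x, ...) standardGeneric("sweepWindows"))

#' @rdname accessors
#' @export
setGeneric("sweepRegions", function(x, ...) standardGeneric("sweepRegions"))

#' @rdname accessors
#' @export
setGeneric("candidateGenes", function(x, ...) standardGeneric("candidateGenes"))

#' Per-site reference-allele frequency
#'
#' The paper-style allele frequency: the fraction of calls (genotype-matrix
#' mode, for a [PopulationPanel-class]) or of reads (count mode, for numeric
#' vectors) supporting the reference genotype.
#'
#' @param x a [PopulationPanel-class], or a numeric vector of reference read
#'   counts.
#' @param ... for the count mode, `total`, the total read counts.
#' @return numeric vector of frequencies in `[0, 1]`; `NA` where no call or
#'   read covers the site.
#' @examples
#' alleleFrequency(18, total = 20)   # 0.9
#' @export
setGeneric("alleleFrequency", function(x, ...) standardGeneric("alleleFrequency"))
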