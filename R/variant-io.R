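.MarkerTable <- function(chrom, pos, type, ref, nonref, genotype,
                         parents = c(NA_character_, NA_character_),
                         bulks = character(), chromLength = NA_real_,
                         filters = list()) {
  o <- order(chrom, pos)
  new("MarkerTable",
    chrom = as.character(chrom)[o], pos = as.numeric(pos)[o],
    type = as.character(type)[o],
    ref = ref[o, , drop = FALSE], nonref = nonref[o, , drop = FALSE],
    genotype = genotype[o, , drop = FALSE],
    parents = parents, bulks = bulks,
    chromLength = as.numeric(chromLength), filters = filters
  )
}

.gtClass <- function(gt) {
  # Collapse diploid GT strings to the genotype classes the filters use.
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep("missing", length(gt))
  out[gt %in% c("0/0", "0")] <- "hom-ref"
  out[gt %in% c("1/1", "1")] <- "hom-alt"
  out[gt %in% c("0/1", "1/0")] <- "het"
  out
}

#' Read per-sample allele counts from a VCF
#'
#' Reads a VCF 4.x (plain or gzipped) with per-sample `AD` (allelic depth)
#' FORMAT fields and returns an unfiltered [MarkerTable-class] of
#' reference / non-reference read counts and genotype classes.  Multiallelic
#' sites are skipped by default because the index statistic is defined for two
#' allele classes.
#'
#' @param path path to the VCF file.
#' @param multiallelic `"skip"` (default) or `"error"`.
#' @return a [MarkerTable-class] with parent/bulk roles unassigned; use
#'   [selectMarkers()] to assign roles and apply the marker filters.
#' @export
readVariants <- function(path, multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- VariantAnnotation::readVcf(path)
  hdr <- VariantAnnotation::header(vcf)
  if (!"AD" %in% rownames(VariantAnnotation::geno(hdr)))
    stop("VCF has no AD FORMAT field; per-sample allele depths are required")

  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  nAlt <- S4Vectors::elementNROWS(alt)
  if (any(nAlt > 1L)) {
    if (multiallelic == "error") stop("multiallelic sites present")
    keep <- nAlt == 1L
    vcf <- vcf[keep]
    rr <- rr[keep]
    alt <- alt[keep]
  }

  ad <- VariantAnnotation::geno(vcf)$AD
  gt <- VariantAnnotation::geno(vcf)$GT
  samples <- colnames(ad)
  n <- nrow(ad)
  ref <- nonref <- matrix(0L, nrow = n, ncol = length(samples),
                          dimnames = list(NULL, samples))
  genotype <- matrix("missing", nrow = n, ncol = length(samples),
                     dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    counts <- ad[, j]
    bad <- vapply(counts, function(v) length(v) < 2L || anyNA(v), logical(1))
    ref[!bad, j] <- vapply(counts[!bad], `[`, integer(1), 1L)
    nonref[!bad, j] <- vapply(counts[!bad], `[`, integer(1), 2L)
    gcls <- .gtClass(gt[, j])
    gcls[bad & gcls != "missing"] <- "missing"   # missing AD -> missing call
    genotype[, j] <- gcls
  }

  refW <- nchar(as.character(rr$REF))
  altW <- nchar(as.character(unlist(alt)))
  type <- ifelse(refW == 1L & altW == 1L, "SNP", "InDel")

  chrom <- as.character(GenomicRanges::seqnames(rr))
  sl <- GenomeInfoDb::seqlengths(rr)
  chromLength <- if (length(unique(chrom)) == 1L && !is.na(sl[unique(chrom)]))
    as.numeric(sl[unique(chrom)]) else NA_real_

  .MarkerTable(
    chrom = chrom, pos = BiocGenerics::start(rr), type = type,
    ref = ref, nonref = nonref, genotype = genotype,
    chromLength = chromLength
  )
}

#' Apply the marker-selection filters
#'
#' Retains only informative markers: sites where (a) both parents are
#' homozygous for different alleles, (b) each parent is covered by at least
#' `minParentDepth` reads, and (c) the site is not low-covered in every bulk
#' (all bulk depths below `minBulkDepth`) nor missing (zero depth) in any
#' bulk.  Exclusion by bulk depth requires *all* bulks below threshold; a
#' single low bulk is retained.
#'
#' Counts are then re-expressed so that "reference" means the recurrent
#' (P50-like) parent's allele: at sites where that parent is hom-alt relative
#' to the assembly, ref/nonref counts are swapped and genotypes flipped for
#' all samples.
#'
#' @param x a [MarkerTable-class] from [readVariants()] or
#'   [sampleBulkCounts()].
#' @param parents character of length 2: the recurrent (reference) parent
#'   sample first, then the donor (wild) parent.
#' @param bulks bulk sample names; defaults to all non-parent samples.
#' @param minParentDepth minimum reads covering each parent (default 7).
#' @param minBulkDepth bulk depth below which a bulk counts as low (default 7).
#' @return a filtered, reoriented [MarkerTable-class]; the applied filters and
#'   input/retained counts are recorded in [filterLog()].
#' @export
selectMarkers <- function(x, parents = parentSamples(x), bulks = NULL,
                          minParentDepth = 7, minBulkDepth = 7) {
  stopifnot(is(x, "MarkerTable"))
  samples <- colnames(x@ref)
  if (anyNA(parents) || length(parents) != 2L)
    stop("two parent sample names are required")
  missingParents <- setdiff(parents, samples)
  if (length(missingParents))
    stop("parent sample(s) not found in table: ",
         paste(missingParents, collapse = ", "))
  if (is.null(bulks)) bulks <- setdiff(samples, parents)
  if (length(bulks) < 1L) stop("at least one bulk sample is required")
  if (length(setdiff(bulks, samples)))
    stop("bulk sample(s) not found in table")

  gp <- x@genotype[, parents, drop = FALSE]
  homBoth <- gp[, 1L] %in% c("hom-ref", "hom-alt") &
    gp[, 2L] %in% c("hom-ref", "hom-alt")
  divergent <- homBoth & gp[, 1L] != gp[, 2L]

  pdepth <- x@ref[, parents, drop = FALSE] + x@nonref[, parents, drop = FALSE]
  parentsCovered <- rowSums(pdepth >= minParentDepth) == 2L

  bdepth <- x@ref[, bulks, drop = FALSE] + x@nonref[, bulks, drop = FALSE]
  allBulksLow <- rowSums(bdepth < minBulkDepth) == length(bulks)
  anyBulkMissing <- rowSums(bdepth == 0L) > 0L

  keep <- divergent & parentsCovered & !allBulksLow & !anyBulkMissing

  ref <- x@ref[keep, , drop = FALSE]
  nonref <- x@nonref[keep, , drop = FALSE]
  genotype <- x@genotype[keep, , drop = FALSE]

  # Re-orient: the recurrent parent's allele is the reference.
  flip <- genotype[, parents[1L]] == "hom-alt"
  if (any(flip)) {
    tmp <- ref[flip, , drop = FALSE]
    ref[flip, ] <- nonref[flip, , drop = FALSE]
    nonref[flip, ] <- tmp
    g <- genotype[flip, , drop = FALSE]
    g[g == "hom-ref"] <- ".swap."
    g[g == "hom-alt"] <- "hom-ref"
    g[g == ".swap."] <- "hom-alt"
    genotype[flip, ] <- g
  }

  .MarkerTable(
    chrom = x@chrom[keep], pos = x@pos[keep], type = x@type[keep],
    ref = ref, nonref = nonref, genotype = genotype,
    parents = parents, bulks = bulks, chromLength = x@chromLength,
    filters = list(
      minParentDepth = minParentDepth, minBulkDepth = minBulkDepth,
      nInput = length(keep), nRetained = sum(keep),
      nReoriented = sum(flip)
    )
  )
}
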