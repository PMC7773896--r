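.GENETIC_CODE <- Biostrings::GENETIC_CODE

.translateCodon <- function(codon) {
  unname(.GENETIC_CODE[[codon]])
}

.complementBase <- function(b) {
  chartr("ACGTacgt", "TGCAtgca", b)
}

#' Classify a variant against gene models
#'
#' Locates each variant in transcript coordinates and reports one effect call
#' per overlapping gene model.  For CDS SNPs the affected codon is mutated
#' and both codons translated: identical amino acids give `synonymous`, a
#' gained stop `stop-gain`, a lost stop `stop-loss`, anything else
#' `non-synonymous` with protein change notation like `G115D` (1-based
#' residue from the initiator methionine).  Indels in CDS are `frameshift`
#' when the length difference is not a multiple of 3, else `inframe-indel`.
#' Variants inside a gene but outside its CDS are `UTR` when they fall in an
#' exon (when exon features are available) and `intronic` otherwise;
#' variants in no gene are `intergenic`.  Minus-strand models are handled by
#' complementing the alternate allele.  Models flagged for an incomplete CDS
#' are excluded from coding calls.
#'
#' @param gms a [GeneModelSet-class].
#' @param chrom,pos,ref,alt variant description (vectorised; `pos` 1-based,
#'   alleles on the forward genome strand).
#' @return a data.frame with one row per variant x overlapping model (or a
#'   single `intergenic` row for variants in no model): columns `chrom`,
#'   `pos`, `ref`, `alt`, `gene`, `tx`, `effect`, `proteinChange`, `refAA`,
#'   `altAA`, `residue`.
#' @examples
#' \dontrun{
#' classifyVariant(gms, "chr1", 105, "G", "A")
#' }
#' @export
classifyVariant <- function(gms, chrom, pos, ref, alt) {
  stopifnot(is(gms, "GeneModelSet"))
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- .classifyOne(gms, chrom[i], pos[i], ref[i], alt[i])
  }
  do.call(rbind, out)
}

.effectRow <- function(chrom, pos, ref, alt, gene = NA_character_,
                       tx = NA_character_, effect, proteinChange = NA_character_,
                       refAA = NA_character_, altAA = NA_character_,
                       residue = NA_integer_) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             tx = tx, effect = effect, proteinChange = proteinChange,
             refAA = refAA, altAA = altAA, residue = residue)
}

.classifyOne <- function(gms, chrom, pos, ref, alt) {
  if (!chrom %in% names(gms@genome))
    stop("chromosome absent from genome: ", chrom)
  genomic <- as.character(Biostrings::subseq(
    gms@genome[[chrom]], pos, pos + nchar(ref) - 1L))
  if (genomic != ref)
    stop(sprintf("reference mismatch at %s:%d: VCF says %s, genome says %s",
                 chrom, as.integer(pos), ref, genomic))

  spans <- gms@genes
  keep <- !(spans$tx_id %in% gms@flagged)
  spans <- spans[keep]
  onChrom <- as.character(GenomicRanges::seqnames(spans)) == chrom
  inSpan <- onChrom & pos >= BiocGenerics::start(spans) &
    pos <= BiocGenerics::end(spans)
  if (!any(inSpan))
    return(.effectRow(chrom, pos, ref, alt, effect = "intergenic"))

  rows <- lapply(which(inSpan), function(k) {
    tx <- spans$tx_id[k]
    gene <- spans$gene_id[k]
    isIndel <- nchar(ref) != nchar(alt)
    cdsPos <- .cdsCoord(gms, tx, pos)

    if (is.na(cdsPos)) {
      ex <- gms@exons[[tx]]
      inExon <- length(ex) &&
        any(pos >= BiocGenerics::start(ex) & pos <= BiocGenerics::end(ex))
      return(.effectRow(chrom, pos, ref, alt, gene, tx,
                        effect = if (inExon) "UTR" else "intronic"))
    }

    if (isIndel) {
      shift <- abs(nchar(ref) - nchar(alt))
      return(.effectRow(chrom, pos, ref, alt, gene, tx,
                        effect = if (shift %% 3L == 0L) "inframe-indel"
                                 else "frameshift"))
    }

    cdsSeq <- .splicedCds(gms, tx)
    minus <- as.character(BiocGenerics::strand(gms@cds[[tx]]))[1L] == "-"
    altCds <- if (minus) .complementBase(alt) else alt

    residue <- (cdsPos - 1L) %/% 3L + 1L
    offset <- (cdsPos - 1L) %% 3L + 1L
    codonStart <- (residue - 1L) * 3L + 1L
    refCodon <- as.character(
      Biostrings::subseq(cdsSeq, codonStart, codonStart + 2L))
    altCodon <- refCodon
    substr(altCodon, offset, offset) <- altCds
    refAA <- .translateCodon(refCodon)
    altAA <- .translateCodon(altCodon)

    effect <-
      if (refAA == altAA) "synonymous"
      else if (altAA == "*") "stop-gain"
      else if (refAA == "*") "stop-loss"
      else "non-synonymous"
    pc <- if (effect %in% c("non-synonymous", "stop-gain", "stop-loss"))
      sprintf("%s%d%s", refAA, residue, altAA) else NA_character_
    .effectRow(chrom, pos, ref, alt, gene, tx, effect, pc, refAA, altAA,
               as.integer(residue))
  })
  do.call(rbind, rows)
}

#' Shortlist divergent non-synonymous variants
#'
#' Retains non-synonymous effect calls whose allele frequencies differ
#' between the domestic and wild populations by at least `freqGap` — the
#' filter used to shortlist candidate domestication substitutions.  Calls at
#' positions absent from the panel are dropped.
#'
#' @param calls a data.frame of effect calls from [classifyVariant()].
#' @param panel a [PopulationPanel-class] providing the per-site frequencies.
#' @param freqGap minimum absolute frequency difference (default 0.8).
#' @return the retained rows of `calls`, with `freqDom` and `freqWild`
#'   columns appended.
#' @export
divergentNonsynonymous <- function(calls, panel, freqGap = 0.8) {
  stopifnot(is.data.frame(calls), is(panel, "PopulationPanel"))
  idx <- match(calls$pos, panel@positions)
  fd <- alleleFrequency(panel, "pop1")[idx]
  fw <- alleleFrequency(panel, "pop2")[idx]
  gap <- abs(fd - fw)
  keep <- calls$effect == "non-synonymous" & !is.na(gap) & gap >= freqGap
  out <- calls[keep, , drop = FALSE]
  out$freqDom <- fd[keep]
  out$freqWild <- fw[keep]
  rownames(out) <- NULL
  out
}
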