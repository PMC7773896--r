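#' Read gene models from GFF3 with genome sequence access
#'
#' Parses `gene`/`mRNA`/`exon`/`CDS` features into spliced-CDS gene models and
#' loads the genome FASTA.  Minus-strand CDS are reverse-complemented for
#' translation.  Models whose total CDS length is not divisible by 3 are
#' flagged and excluded from coding-effect calls.
#'
#' @param gffPath path to a GFF3 file.
#' @param fastaPath path to the genome FASTA.
#' @return a [GeneModelSet-class].
#' @examples
#' \dontrun{
#' gms <- readGeneModels("genes.gff3", "genome.fa")
#' translateCds(gms, "gene1")
#' }
#' @export
readGeneModels <- function(gffPath, fastaPath) {
  gr <- rtracklayer::import(gffPath, format = "gff3")
  genome <- Biostrings::readDNAStringSet(fastaPath)
  names(genome) <- sub("\\s.*", "", names(genome))

  firstParent <- function(g) {
    p <- g$Parent
    vapply(as.list(p), function(v) if (length(v)) v[[1L]] else NA_character_,
           character(1))
  }

  cds <- gr[gr$type == "CDS"]
  if (!length(cds)) stop("GFF3 contains no CDS features")
  txOf <- firstParent(cds)
  txOf[is.na(txOf)] <- cds$ID[is.na(txOf)]

  mrna <- gr[gr$type == "mRNA"]
  geneOfTx <- structure(firstParent(mrna), names = mrna$ID)

  exons <- gr[gr$type == "exon"]
  exonTx <- firstParent(exons)

  missingChrom <- setdiff(unique(as.character(GenomicRanges::seqnames(cds))),
                          names(genome))
  if (length(missingChrom))
    stop("CDS reference sequence(s) absent from FASTA: ",
         paste(missingChrom, collapse = ", "))

  txIds <- unique(txOf)
  cdsList <- GenomicRanges::GRangesList(lapply(txIds, function(tx) {
    BiocGenerics::sort(cds[txOf == tx])
  }))
  names(cdsList) <- txIds
  exonList <- GenomicRanges::GRangesList(lapply(txIds, function(tx) {
    BiocGenerics::sort(exons[!is.na(exonTx) & exonTx == tx])
  }))
  names(exonList) <- txIds

  spans <- unlist(GenomicRanges::GRangesList(lapply(txIds, function(tx) {
    r <- range(c(cdsList[[tx]], exonList[[tx]]))
    r
  })))
  names(spans) <- NULL
  spans$tx_id <- txIds
  geneIds <- unname(geneOfTx[txIds])
  spans$gene_id <- ifelse(is.na(geneIds), txIds, geneIds)

  cdsLen <- vapply(txIds, function(tx)
    sum(BiocGenerics::width(cdsList[[tx]])), numeric(1))
  flagged <- txIds[cdsLen %% 3 != 0]
  if (length(flagged))
    warning("CDS length not divisible by 3; model(s) flagged and excluded ",
            "from effect calls: ", paste(flagged, collapse = ", "))

  new("GeneModelSet", cds = cdsList, exons = exonList, genes = spans,
      genome = genome, flagged = flagged)
}

# Spliced CDS of one model in transcription order (minus strand
# reverse-complemented).
.splicedCds <- function(gms, tx) {
  r <- gms@cds[[tx]]
  chrom <- as.character(GenomicRanges::seqnames(r))[1L]
  s <- gms@genome[[chrom]]
  parts <- Biostrings::DNAStringSet(lapply(seq_along(r), function(i) {
    Biostrings::subseq(s, BiocGenerics::start(r)[i], BiocGenerics::end(r)[i])
  }))
  spliced <- unlist(parts)
  if (as.character(BiocGenerics::strand(r))[1L] == "-")
    spliced <- Biostrings::reverseComplement(spliced)
  spliced
}

# 1-based CDS coordinate (in transcription order) of a genomic position, or
# NA when the position is not in the CDS.
.cdsCoord <- function(gms, tx, pos) {
  r <- gms@cds[[tx]]
  starts <- BiocGenerics::start(r)
  ends <- BiocGenerics::end(r)
  hit <- which(pos >= starts & pos <= ends)
  if (!length(hit)) return(NA_integer_)
  before <- if (hit > 1L) sum(ends[seq_len(hit - 1L)] -
                              starts[seq_len(hit - 1L)] + 1L) else 0L
  plusCoord <- before + (pos - starts[hit] + 1L)
  if (as.character(BiocGenerics::strand(r))[1L] == "-") {
    total <- sum(ends - starts + 1L)
    as.integer(total - plusCoord + 1L)
  } else {
    as.integer(plusCoord)
  }
}

#' Translate the spliced CDS of a gene model
#'
#' @param gms a [GeneModelSet-class].
#' @param tx transcript/model id.
#' @return a single character string of the protein sequence (stop codon as
#'   `"*"`, standard nuclear genetic code).
#' @export
translateCds <- function(gms, tx) {
  stopifnot(is(gms, "GeneModelSet"))
  if (!tx %in% names(gms@cds)) stop("unknown gene model: ", tx)
  if (tx %in% gms@flagged)
    stop("model ", tx, " is flagged (CDS length not divisible by 3)")
  as.character(Biostrings::translate(.splicedCds(gms, tx)))
}
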