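# Fixture builders shared across test files.  Everything is generated in code
# at test time; nothing is read from stored data files.

# Direct MarkerTable construction from count matrices (sites assumed sorted).
makeMarkerTable <- function(pos, ref, nonref, genotype,
                            chrom = "chr1", type = "SNP",
                            parents = c(NA_character_, NA_character_),
                            bulks = character(),
                            chromLength = NA_real_) {
  n <- length(pos)
  new("MarkerTable",
      chrom = rep_len(chrom, n), pos = as.numeric(pos),
      type = rep_len(type, n),
      ref = ref, nonref = nonref, genotype = genotype,
      parents = parents, bulks = bulks,
      chromLength = as.numeric(chromLength), filters = list())
}

# A marker table with random bulk counts for one bulk column, used by the
# window-oracle and profile tests.
randomCountTable <- function(m, chromLength, depth = 30, seed = 1,
                             zeroDepthFrac = 0) {
  set.seed(seed)
  pos <- sort(sample.int(chromLength, m))
  d <- stats::rpois(m, depth) + 1L
  if (zeroDepthFrac > 0)
    d[sample.int(m, ceiling(zeroDepthFrac * m))] <- 0L
  nr <- stats::rbinom(m, d, stats::runif(m))
  ref <- matrix(as.integer(d - nr), ncol = 1, dimnames = list(NULL, "B1"))
  nonref <- matrix(as.integer(nr), ncol = 1, dimnames = list(NULL, "B1"))
  gt <- matrix("het", nrow = m, ncol = 1, dimnames = list(NULL, "B1"))
  makeMarkerTable(pos, ref, nonref, gt, bulks = "B1",
                  chromLength = chromLength)
}

# Toy annotation fixture: one chromosome with a plus-strand gene (CDS
# ATGGGTTAA -> MG*), its minus-strand mirror, a two-exon gene split
# mid-codon, a contiguous equivalent of the split gene, and optionally a
# gene flagged for an incomplete CDS.
writeToyAnnotation <- function(dir = tempfile("toyann"), withFlagged = FALSE) {
  dir.create(dir)
  g <- rep("C", 120)
  put <- function(at, s) {
    g[at:(at + nchar(s) - 1L)] <<- strsplit(s, "")[[1]]
  }
  put(11, "ATGGGTTAA")                      # gene_plus CDS 11..19
  put(31, "TTAACCCAT")                      # gene_minus: revcomp(ATGGGTTAA)
  put(51, "ATGGG")                          # gene_split exon 1
  put(61, "TTAA")                           # gene_split exon 2
  put(71, "ATGGGTTAA")                      # gene_contig CDS 71..79
  if (withFlagged) put(91, "ATGGGTTA")      # 8 bp CDS -> flagged
  fasta <- file.path(dir, "toy.fa")
  writeLines(c(">chrT", paste(g, collapse = "")), fasta)

  lines <- c(
    "##gff-version 3",
    "chrT\t.\tgene\t6\t24\t.\t+\t.\tID=gene_plus",
    "chrT\t.\tmRNA\t6\t24\t.\t+\t.\tID=tx_plus;Parent=gene_plus",
    "chrT\t.\texon\t6\t24\t.\t+\t.\tParent=tx_plus",
    "chrT\t.\tCDS\t11\t19\t.\t+\t0\tParent=tx_plus",
    "chrT\t.\tgene\t31\t39\t.\t-\t.\tID=gene_minus",
    "chrT\t.\tmRNA\t31\t39\t.\t-\t.\tID=tx_minus;Parent=gene_minus",
    "chrT\t.\texon\t31\t39\t.\t-\t.\tParent=tx_minus",
    "chrT\t.\tCDS\t31\t39\t.\t-\t0\tParent=tx_minus",
    "chrT\t.\tgene\t51\t64\t.\t+\t.\tID=gene_split",
    "chrT\t.\tmRNA\t51\t64\t.\t+\t.\tID=tx_split;Parent=gene_split",
    "chrT\t.\texon\t51\t55\t.\t+\t.\tParent=tx_split",
    "chrT\t.\texon\t61\t64\t.\t+\t.\tParent=tx_split",
    "chrT\t.\tCDS\t51\t55\t.\t+\t0\tParent=tx_split",
    "chrT\t.\tCDS\t61\t64\t.\t+\t2\tParent=tx_split",
    "chrT\t.\tgene\t71\t79\t.\t+\t.\tID=gene_contig",
    "chrT\t.\tmRNA\t71\t79\t.\t+\t.\tID=tx_contig;Parent=gene_contig",
    "chrT\t.\texon\t71\t79\t.\t+\t.\tParent=tx_contig",
    "chrT\t.\tCDS\t71\t79\t.\t+\t0\tParent=tx_contig"
  )
  if (withFlagged) {
    lines <- c(lines,
      "chrT\t.\tgene\t91\t98\t.\t+\t.\tID=gene_flag",
      "chrT\t.\tmRNA\t91\t98\t.\t+\t.\tID=tx_flag;Parent=gene_flag",
      "chrT\t.\texon\t91\t98\t.\t+\t.\tParent=tx_flag",
      "chrT\t.\tCDS\t91\t98\t.\t+\t0\tParent=tx_flag")
  }
  gff <- file.path(dir, "toy.gff3")
  writeLines(lines, gff)
  list(fasta = fasta, gff = gff)
}

# Random multi-exon gene models on their own chromosomes, with an independent
# record of the spliced CDS and its genomic coordinate map, for the
# full-protein-diff oracle.
randomGeneFixture <- function(nGenes = 10, seed = 1, dir = tempfile("rgene")) {
  set.seed(seed)
  dir.create(dir)
  bases <- c("A", "C", "G", "T")
  rc <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  gffLines <- "##gff-version 3"
  fastaLines <- character()
  info <- list()
  for (gi in seq_len(nGenes)) {
    chrom <- sprintf("rchr%02d", gi)
    nCodons <- sample(20:60, 1)
    cdsTx <- paste0("ATG",
                    paste(sample(bases, (nCodons - 1) * 3, TRUE), collapse = ""))
    std <- if (gi %% 2 == 0) "-" else "+"
    nEx <- sample(1:3, 1)
    L <- nchar(cdsTx)
    cuts <- if (nEx > 1) sort(sample(seq_len(L - 1), nEx - 1)) else integer(0)
    bounds <- c(0, cuts, L)
    pieces <- substring(cdsTx, head(bounds, -1) + 1, bounds[-1])
    genomicPieces <- if (std == "+") pieces else rev(vapply(pieces, rc, ""))
    seqStr <- paste(sample(bases, 15, TRUE), collapse = "")
    starts <- ends <- integer(length(genomicPieces))
    for (k in seq_along(genomicPieces)) {
      starts[k] <- nchar(seqStr) + 1L
      seqStr <- paste0(seqStr, genomicPieces[k])
      ends[k] <- nchar(seqStr)
      if (k < length(genomicPieces))
        seqStr <- paste0(seqStr,
                         paste(sample(bases, sample(8:30, 1), TRUE),
                               collapse = ""))
    }
    seqStr <- paste0(seqStr, paste(sample(bases, 10, TRUE), collapse = ""))
    tx <- sprintf("tx%02d", gi)
    gffLines <- c(
      gffLines,
      sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=g_%s",
              chrom, starts[1], ends[length(ends)], std, tx),
      sprintf("%s\t.\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=g_%s",
              chrom, starts[1], ends[length(ends)], std, tx, tx),
      vapply(seq_along(starts), function(k)
        sprintf("%s\t.\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                chrom, starts[k], ends[k], std, tx), character(1))
    )
    fastaLines <- c(fastaLines, paste0(">", chrom), seqStr)
    posAsc <- unlist(lapply(seq_along(starts), function(k) starts[k]:ends[k]))
    info[[tx]] <- list(
      tx = tx, chrom = chrom, strand = std, cdsTx = cdsTx,
      cdsPos = if (std == "+") posAsc else rev(posAsc), genome = seqStr
    )
  }
  fasta <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "genes.gff3")
  writeLines(fastaLines, fasta)
  writeLines(gffLines, gff)
  list(fasta = fasta, gff = gff, info = info)
}

# Independent effect oracle: translate the full mutated CDS and diff the two
# proteins.  `j` is the 1-based CDS coordinate, `altTx` the alternate base in
# transcript orientation.
oracleEffect <- function(cdsTx, j, altTx) {
  mut <- cdsTx
  substr(mut, j, j) <- altTx
  p0 <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(cdsTx))), "")[[1]]
  p1 <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(mut))), "")[[1]]
  d <- which(p0 != p1)
  if (!length(d))
    return(list(effect = "synonymous", residue = NA_integer_,
                refAA = NA_character_, altAA = NA_character_))
  stopifnot(length(d) == 1L)
  effect <- if (p1[d] == "*") "stop-gain"
            else if (p0[d] == "*") "stop-loss"
            else "non-synonymous"
  list(effect = effect, residue = d, refAA = p0[d], altAA = p1[d])
}

# GeneModelSet with only gene spans populated (enough for overlap logic).
makeSpanSet <- function(ids, chrom, starts, ends) {
  spans <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(starts, ends), gene_id = ids, tx_id = ids)
  new("GeneModelSet",
      cds = GenomicRanges::GRangesList(),
      exons = GenomicRanges::GRangesList(),
      genes = spans, genome = Biostrings::DNAStringSet(),
      flagged = character())
}

# Small two-population panel from explicit matrices.
makePanel <- function(pos, pop1, pop2, chromLength = max(pos),
                      chrom = "chr1", sweepInterval = NA_real_) {
  new("PopulationPanel", chrom = chrom, chromLength = chromLength,
      positions = as.numeric(pos), pop1 = pop1, pop2 = pop2,
      sweepInterval = as.numeric(sweepInterval))
}
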