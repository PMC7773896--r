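#' Construct a BC1 bulk-sequencing simulation configuration
#'
#' Defaults emulate the mapping design the package targets: a backcross of
#' roughly 200 individuals between a homozygous recessive domestic parent and
#' an F1 carrying a fully penetrant dominant allele, extreme-phenotype bulks
#' of 20 larvae, pooled sequencing near 30x and parents near 21x, and ~2,000
#' informative markers on a 20 Mb chromosome with the causal locus at 4 Mb.
#'
#' `markerPositions = "uniform"` places markers on an evenly spaced grid; the
#' marker nearest `causalPosition` is relocated onto it so the causal locus is
#' always itself a marker.  `causalPosition = NA` gives a null cross: the
#' phenotype is a fair coin flip independent of genotype.
#'
#' @param chromLength chromosome length in bp.
#' @param nMarkers number of informative markers.
#' @param markerPositions `"uniform"` or a sorted numeric vector of bp
#'   positions (length `nMarkers`).
#' @param causalPosition bp of the causal locus, or `NA` for a null cross.
#' @param recombRate expected crossovers per meiosis (Morgans/chromosome).
#' @param nBC1 number of BC1 individuals.
#' @param bulkSize individuals per bulk.
#' @param penetrance probability a heterozygous carrier shows the trait.
#' @param depthMean mean pooled depth per marker per bulk.
#' @param parentDepthMean mean per-parent depth per marker.
#' @param seed master seed (integer).
#' @return a [CrossConfig-class] object.
#' @examples
#' cfg <- CrossConfig(nMarkers = 200L, seed = 1L)
#' truth <- simulateCross(cfg)
#' table(phenotypes(truth))
#' @export
CrossConfig <- function(chromLength = 20e6, nMarkers = 2000L,
                        markerPositions = "uniform", causalPosition = 4e6,
                        recombRate = 2, nBC1 = 200L, bulkSize = 20L,
                        penetrance = 1, depthMean = 30, parentDepthMean = 21,
                        seed = 1L) {
  if (identical(markerPositions, "uniform")) {
    pos <- numeric(0)
  } else {
    pos <- as.numeric(markerPositions)
    if (length(pos) != nMarkers)
      stop("explicit markerPositions must have length nMarkers")
  }
  new("CrossConfig",
    chromLength = as.numeric(chromLength), nMarkers = as.integer(nMarkers),
    markerPositions = pos, causalPosition = as.numeric(causalPosition),
    recombRate = as.numeric(recombRate), nBC1 = as.integer(nBC1),
    bulkSize = as.integer(bulkSize), penetrance = as.numeric(penetrance),
    depthMean = as.numeric(depthMean),
    parentDepthMean = as.numeric(parentDepthMean), seed = as.integer(seed)
  )
}

.markerGrid <- function(config) {
  if (length(config@markerPositions)) {
    pos <- config@markerPositions
  } else {
    pos <- round(seq(1, config@chromLength, length.out = config@nMarkers))
    if (anyDuplicated(pos))
      stop("nMarkers too large for chromLength: marker grid collides")
  }
  causal <- config@causalPosition
  causalMarker <- NA_integer_
  if (!is.na(causal)) {
    if (causal < min(pos) || causal > max(pos))
      stop("causalPosition lies outside the marker range")
    causalMarker <- which.min(abs(pos - causal))
    pos[causalMarker] <- causal
    if (is.unsorted(pos, strictly = TRUE))
      stop("relocating the causal marker broke position order")
  }
  list(pos = pos, causalMarker = causalMarker)
}

#' Simulate a BC1 backcross population
#'
#' One meiosis of the F1 parent is simulated per BC1 individual: the number of
#' crossovers is Poisson(`recombRate`) with breakpoints uniform on the
#' chromosome (no interference), and the gamete alternates between the two F1
#' haplotypes.  The recurrent parent contributes a constant recessive gamete,
#' so every BC1 genotype is hom-ref (0) or het (1) and segregates 1:1 at each
#' marker.  Phenotypes follow the causal genotype with the configured
#' penetrance; bulks are the first `bulkSize` trait-positive and first
#' `bulkSize` trait-negative individuals, for reproducibility.
#'
#' @param config a [CrossConfig-class].
#' @return a [SimTruth-class] with genotypes, phenotypes, bulk membership and
#'   the causal locus.
#' @seealso [sampleBulkCounts()] to turn the truth into pooled read counts.
#' @export
simulateCross <- function(config) {
  validObject(config)
  grid <- .markerGrid(config)
  pos <- grid$pos
  n <- config@nBC1
  m <- length(pos)

  set.seed(config@seed)
  nCross <- stats::rpois(n, config@recombRate)
  geno <- matrix(0L, nrow = n, ncol = m)
  for (i in seq_len(n)) {
    phase0 <- stats::rbinom(1L, 1L, 0.5)
    if (nCross[i] == 0L) {
      geno[i, ] <- phase0
    } else {
      breaks <- sort(stats::runif(nCross[i], 0, config@chromLength))
      geno[i, ] <- (phase0 + findInterval(pos, breaks)) %% 2L
    }
  }

  if (is.na(config@causalPosition)) {
    phen <- stats::rbinom(n, 1L, 0.5)
  } else {
    carrier <- geno[, grid$causalMarker] == 1L
    phen <- integer(n)
    phen[carrier] <- stats::rbinom(sum(carrier), 1L, config@penetrance)
  }

  posIdx <- which(phen == 1L)
  negIdx <- which(phen == 0L)
  if (length(posIdx) < config@bulkSize || length(negIdx) < config@bulkSize)
    stop(sprintf(
      "insufficient segregants: %d trait-positive and %d trait-negative individuals for bulks of %d",
      length(posIdx), length(negIdx), config@bulkSize
    ))

  new("SimTruth",
    config = config, markerPositions = pos, genotypes = geno,
    phenotypes = as.integer(phen),
    bulkPos = posIdx[seq_len(config@bulkSize)],
    bulkNeg = negIdx[seq_len(config@bulkSize)],
    causalPosition = config@causalPosition,
    causalMarker = grid$causalMarker
  )
}

#' Sample pooled sequencing read counts from a simulated cross
#'
#' Emulates pooled sequencing of the two bulks and the two parents.  For each
#' marker and bulk the true wild-allele frequency is
#' `(het members * 0.5) / bulkSize`; total depth is Poisson(`depthMean`)
#' truncated below at 1 and the non-reference count is Binomial(depth, f).
#' Parents are sequenced at `parentDepthMean` with frequencies 0 (recurrent
#' P50-like parent) and 1 (wild parent).  Allele counts carry no base-error
#' model: the index statistics operate on post-filtering counts.
#'
#' Draws use `set.seed(seed + 1)` so counts are reproducible independently of
#' when [simulateCross()] was run.
#'
#' @param truth a [SimTruth-class].
#' @param config the [CrossConfig-class] used to generate `truth` (defaults to
#'   the one recorded in `truth`).
#' @return a [MarkerTable-class] with samples `P_P50`, `P_Wild`, `B_pos`,
#'   `B_neg` (unfiltered; already P50-oriented by construction).
#' @export
sampleBulkCounts <- function(truth, config = truth@config) {
  stopifnot(is(truth, "SimTruth"))
  m <- length(truth@markerPositions)
  bulks <- list(
    B_pos = truth@genotypes[truth@bulkPos, , drop = FALSE],
    B_neg = truth@genotypes[truth@bulkNeg, , drop = FALSE]
  )

  set.seed(config@seed + 1L)
  samples <- c("P_P50", "P_Wild", "B_pos", "B_neg")
  ref <- nonref <- matrix(0L, nrow = m, ncol = length(samples),
                          dimnames = list(NULL, samples))

  dP50 <- pmax(1L, stats::rpois(m, config@parentDepthMean))
  dWild <- pmax(1L, stats::rpois(m, config@parentDepthMean))
  ref[, "P_P50"] <- dP50                      # f = 0
  nonref[, "P_Wild"] <- dWild                 # f = 1

  for (b in names(bulks)) {
    f <- colSums(bulks[[b]]) * 0.5 / nrow(bulks[[b]])
    depth <- pmax(1L, stats::rpois(m, config@depthMean))
    nr <- stats::rbinom(m, depth, f)
    nonref[, b] <- nr
    ref[, b] <- depth - nr
  }

  genotype <- matrix("het", nrow = m, ncol = length(samples),
                     dimnames = list(NULL, samples))
  genotype[, "P_P50"] <- "hom-ref"
  genotype[, "P_Wild"] <- "hom-alt"

  .MarkerTable(
    chrom = rep("chr1", m), pos = truth@markerPositions,
    type = rep("SNP", m), ref = ref, nonref = nonref, genotype = genotype,
    parents = c("P_P50", "P_Wild"), bulks = c("B_pos", "B_neg"),
    chromLength = config@chromLength, filters = list()
  )
}

#' Construct a two-population panel simulation configuration
#'
#' Defaults emulate a strain panel of 137 domestic and 7 wild haploid samples
#' on a 5 Mb chromosome segment, with 25,000 biallelic sites and a selective
#' sweep at 3.7-4.0 Mb in which the domestic population is nearly fixed
#' (heterozygosity 0.02 against a 0.3 baseline) and shifted from the wild
#' population by at least 0.5 in allele frequency.
#'
#' @param nPop1,nPop2 haploid sample counts ("domestic", "wild").
#' @param chromLength chromosome length (bp).
#' @param nSites number of biallelic sites.
#' @param sweepInterval numeric `(start, end)` in bp, or `NA` for no sweep.
#' @param baselineDiversity expected per-site heterozygosity outside the
#'   sweep, in `[0, 0.5]`.
#' @param sweepDiversityPop1 expected pop1 heterozygosity inside the sweep.
#' @param divergenceBoost minimum allele-frequency shift between populations
#'   inside the sweep.
#' @param seed master seed.
#' @return a [PanelConfig-class].
#' @export
PanelConfig <- function(nPop1 = 137L, nPop2 = 7L, chromLength = 5e6,
                        nSites = 25000L, sweepInterval = c(3.7e6, 4.0e6),
                        baselineDiversity = 0.3, sweepDiversityPop1 = 0.02,
                        divergenceBoost = 0.5, seed = 1L) {
  new("PanelConfig",
    nPop1 = as.integer(nPop1), nPop2 = as.integer(nPop2),
    chromLength = as.numeric(chromLength), nSites = as.integer(nSites),
    sweepInterval = as.numeric(sweepInterval),
    baselineDiversity = as.numeric(baselineDiversity),
    sweepDiversityPop1 = as.numeric(sweepDiversityPop1),
    divergenceBoost = as.numeric(divergenceBoost), seed = as.integer(seed)
  )
}

# Beta(a, a) shape giving E[2 p (1 - p)] = h for h in [0, 0.5).
.betaShapeForHet <- function(h) h / (1 - 2 * h)

# Near-fixation minor frequency eps with 2 eps (1 - eps) = h.
.fixationFreqForHet <- function(h) (1 - sqrt(1 - 2 * h)) / 2

#' Simulate a two-population genotype panel with an optional sweep
#'
#' Outside the sweep interval both populations share a per-site allele
#' frequency drawn from a symmetric Beta whose expected heterozygosity equals
#' `baselineDiversity`.  Inside it, population 2 ("wild") keeps the baseline
#' draw while population 1 ("domestic") sits at a near-fixation frequency with
#' heterozygosity `sweepDiversityPop1`, fixed for the allele that is minor in
#' the wild population when `divergenceBoost > 0` — the signature of a
#' domestication sweep: elevated Fst, depressed domestic diversity, near-fixed
#' domestic alleles.  Haploid calls are Bernoulli draws per sample.
#'
#' @param config a [PanelConfig-class].
#' @return a [PopulationPanel-class]; the simulated sweep interval is retained
#'   in the object for parameter-recovery tests.
#' @export
simulatePanel <- function(config) {
  validObject(config)
  if (!anyNA(config@sweepInterval) &&
      config@sweepDiversityPop1 > config@baselineDiversity)
    warning("sweep diversity exceeds baseline diversity: not a sweep")

  set.seed(config@seed)
  pos <- sort(sample.int(config@chromLength, config@nSites))

  h <- config@baselineDiversity
  if (h == 0) {
    p <- as.numeric(stats::rbinom(config@nSites, 1L, 0.5))
  } else if (h >= 0.5) {
    p <- rep(0.5, config@nSites)
  } else {
    a <- .betaShapeForHet(h)
    p <- stats::rbeta(config@nSites, a, a)
  }
  p1 <- p2 <- p

  if (!anyNA(config@sweepInterval)) {
    inSweep <- pos >= config@sweepInterval[1] & pos <= config@sweepInterval[2]
    eps <- .fixationFreqForHet(config@sweepDiversityPop1)
    pw <- p2[inSweep]
    fixAllele <- if (config@divergenceBoost > 0) {
      ifelse(pw <= 0.5, 1L, 0L)          # minor allele of the wild population
    } else {
      ifelse(pw > 0.5, 1L, 0L)
    }
    p1[inSweep] <- ifelse(fixAllele == 1L, 1 - eps, eps)
  }

  draw <- function(freq, nSamp) {
    matrix(stats::rbinom(length(freq) * nSamp, 1L, rep(freq, nSamp)),
           nrow = length(freq), ncol = nSamp)
  }
  pop1 <- draw(p1, config@nPop1)
  pop2 <- draw(p2, config@nPop2)
  colnames(pop1) <- sprintf("dom_%03d", seq_len(config@nPop1))
  colnames(pop2) <- sprintf("wild_%02d", seq_len(config@nPop2))

  new("PopulationPanel",
    chrom = "chr1", chromLength = config@chromLength, positions = pos,
    pop1 = pop1, pop2 = pop2, sweepInterval = config@sweepInterval
  )
}

#' Write a simulated dataset to plain-text fixture files
#'
#' Writes `markers.vcf` (VCF 4.2 with `GT` and `AD` FORMAT fields for the two
#' parents and the bulks), `panel.tsv` (sites x haploid samples 0/1 matrix for
#' the two populations) and `truth.json` (causal position, phenotypes, bulk
#' membership, genotypes).  Output is byte-deterministic given the simulation
#' seed, and the VCF round-trips through [readVariants()] without loss.
#'
#' @param truth a [SimTruth-class] (or `NULL` to skip `truth.json`).
#' @param counts a [MarkerTable-class] from [sampleBulkCounts()] (or `NULL`).
#' @param panel a [PopulationPanel-class] (or `NULL` to skip `panel.tsv`).
#' @param dir output directory (created if absent).
#' @return invisibly, a named character vector of the files written.
#' @export
writeFixture <- function(truth = NULL, counts = NULL, panel = NULL, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  out <- character()

  if (!is.null(counts)) {
    path <- file.path(dir, "markers.vcf")
    .writeMarkerVcf(counts, path)
    out["vcf"] <- path
  }
  if (!is.null(panel)) {
    path <- file.path(dir, "panel.tsv")
    df <- data.frame(chrom = panel@chrom, pos = panel@positions,
                     panel@pop1, panel@pop2, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
    out["panel"] <- path
  }
  if (!is.null(truth)) {
    path <- file.path(dir, "truth.json")
    jsonlite::write_json(
      list(
        causalPosition = truth@causalPosition,
        causalMarker = truth@causalMarker,
        markerPositions = truth@markerPositions,
        phenotypes = truth@phenotypes,
        bulkPos = truth@bulkPos, bulkNeg = truth@bulkNeg,
        parentHaplotypes = list(
          P_P50 = rep(0L, length(truth@markerPositions)),
          P_Wild = rep(1L, length(truth@markerPositions))
        ),
        genotypes = truth@genotypes
      ),
      path, auto_unbox = TRUE, digits = NA, na = "null"
    )
    out["truth"] <- path
  }
  invisible(out)
}

.gtString <- function(g) {
  c("hom-ref" = "0/0", "hom-alt" = "1/1", het = "0/1", missing = "./.")[g]
}

.writeMarkerVcf <- function(x, path) {
  stopifnot(is(x, "MarkerTable"))
  samples <- colnames(x@ref)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsasweep",
    if (!is.na(x@chromLength))
      sprintf("##contig=<ID=%s,length=%d>", unique(x@chrom),
              as.integer(x@chromLength))
    else sprintf("##contig=<ID=%s>", unique(x@chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  refAllele <- ifelse(x@type == "InDel", "AT", "A")
  altAllele <- ifelse(x@type == "InDel", "A", "T")
  fields <- vapply(seq_along(samples), function(j) {
    paste0(.gtString(x@genotype[, j]), ":", x@ref[, j], ",", x@nonref[, j])
  }, character(length(x@pos)))
  if (is.null(dim(fields))) fields <- matrix(fields, nrow = length(x@pos))
  body <- paste(
    x@chrom, format(x@pos, scientific = FALSE, trim = TRUE), ".",
    refAllele, altAllele, ".", "PASS", ".", "GT:AD",
    apply(fields, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
}
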