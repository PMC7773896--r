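#' Read an FPKM table with sample metadata
#'
#' @param fpkmPath TSV of genes (rows, first column = gene id) x samples.
#' @param metaPath TSV with one row per sample and columns `sample`, `group`
#'   and optionally `stage` and `libDepth` (total mapped reads).
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay `fpkm`.
#' @export
readFpkm <- function(fpkmPath, metaPath) {
  fpkm <- utils::read.delim(fpkmPath, check.names = FALSE)
  mat <- as.matrix(fpkm[, -1, drop = FALSE])
  rownames(mat) <- fpkm[[1]]
  meta <- utils::read.delim(metaPath)
  if (!all(c("sample", "group") %in% names(meta)))
    stop("metadata needs 'sample' and 'group' columns")
  idx <- match(colnames(mat), meta$sample)
  if (anyNA(idx)) stop("metadata missing for sample(s): ",
                       paste(colnames(mat)[is.na(idx)], collapse = ", "))
  if (any(mat < 0, na.rm = TRUE)) stop("FPKM values must be non-negative")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = mat),
    colData = S4Vectors::DataFrame(meta[idx, , drop = FALSE],
                                   row.names = colnames(mat))
  )
}

#' Row-wise Z-score normalisation
#'
#' Per gene, `(x - row mean) / row sd` with the sample standard deviation
#' (denominator `n - 1`), the normalisation used for expression heatmaps.
#' Constant rows become all zeros and are flagged in the `"constant"`
#' attribute.
#'
#' @param x numeric matrix (genes x samples) with at least 2 columns, or a
#'   `SummarizedExperiment` whose first assay is used.
#' @return a matrix of Z-scores with `attr(, "constant")`, a logical vector
#'   marking constant rows.
#' @examples
#' zscoreRows(rbind(a = c(1, 2, 3), b = c(5, 5, 5)))
#' @export
zscoreRows <- function(x) {
  if (is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x)
  stopifnot(is.matrix(x), ncol(x) >= 2L)
  mu <- rowMeans(x)
  sd <- apply(x, 1L, stats::sd)
  constant <- sd == 0
  z <- (x - mu) / ifelse(constant, 1, sd)
  z[constant, ] <- 0
  attr(z, "constant") <- constant
  z
}

#' Depth-normalised per-gene Student's t-test
#'
#' Scales each sample's FPKM by `reference depth / sample library depth`
#' (reference depth = mean library depth), then applies a classical
#' equal-variance two-sided Student's t-test per gene (and per stage when a
#' stage factor is given) between the two groups.  No multiple-testing
#' correction is applied.  Groups with fewer than 2 replicates give a missing
#' p-value; genes constant and equal in both groups give `p = 1`, flagged in
#' the `note` column.
#'
#' @param x numeric matrix (genes x samples) or a `SummarizedExperiment` with
#'   colData columns `group`, optional `stage`, optional `libDepth`.
#' @param groupA,groupB the two group labels to compare.
#' @param group per-sample group labels (matrix input).
#' @param libDepth per-sample total mapped reads; `NULL` skips depth
#'   normalisation.
#' @param stage optional per-sample stage labels; the test runs within each
#'   stage.
#' @return a data.frame with columns `gene`, `stage`, `meanA`, `meanB`, `t`,
#'   `df`, `p`, `note`.
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
#' depthNormalizeAndTest(m, "a", "b", group = rep(c("a", "b"), each = 3))
#' @export
depthNormalizeAndTest <- function(x, groupA, groupB, group = NULL,
                                  libDepth = NULL, stage = NULL) {
  if (is(x, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(x)
    if (is.null(group)) group <- as.character(cd$group)
    if (is.null(libDepth) && "libDepth" %in% names(cd))
      libDepth <- as.numeric(cd$libDepth)
    if (is.null(stage) && "stage" %in% names(cd))
      stage <- as.character(cd$stage)
    x <- SummarizedExperiment::assay(x)
  }
  stopifnot(is.matrix(x), !is.null(group), length(group) == ncol(x))
  if (!is.null(libDepth)) {
    stopifnot(length(libDepth) == ncol(x), all(libDepth > 0))
    x <- sweep(x, 2L, mean(libDepth) / libDepth, "*")
  }
  stages <- if (is.null(stage)) factor(rep("all", ncol(x))) else factor(stage)

  res <- list()
  for (st in levels(stages)) {
    inStage <- stages == st
    a <- x[, inStage & group == groupA, drop = FALSE]
    b <- x[, inStage & group == groupB, drop = FALSE]
    for (g in rownames(x)) {
      va <- a[g, ]
      vb <- b[g, ]
      row <- data.frame(gene = g, stage = st,
                        meanA = mean(va), meanB = mean(vb),
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        note = NA_character_)
      if (length(va) < 2L || length(vb) < 2L) {
        row$note <- "fewer than 2 replicates"
      } else if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
        if (mean(va) == mean(vb)) {
          row$t <- 0
          row$df <- length(va) + length(vb) - 2
          row$p <- 1
          row$note <- "zero variance in both groups"
        } else {
          row$note <- "zero variance, unequal means"
        }
      } else {
        tt <- stats::t.test(va, vb, var.equal = TRUE,
                            alternative = "two.sided")
        row$t <- unname(tt$statistic)
        row$df <- unname(tt$parameter)
        row$p <- tt$p.value
      }
      res[[length(res) + 1L]] <- row
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
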