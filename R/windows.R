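# Shared sliding-window machinery.  Windows are half-open [start, start + W)
# anchored at position 1 every `step` bp; the trailing partial windows are
# kept, truncated at the chromosome end.

.makeWindows <- function(chromLength, window, step) {
  stopifnot(window > 0, step > 0, chromLength >= 1)
  starts <- seq(1, chromLength, by = step)
  ends <- pmin(starts + window, chromLength + 1)
  list(start = starts, end = ends)
}

# Index bounds of sorted integer positions falling in each half-open window:
# window i holds positions pos[(lo[i] + 1):hi[i]].
.windowIndex <- function(pos, grid) {
  list(
    lo = findInterval(grid$start - 0.5, pos),
    hi = findInterval(grid$end - 0.5, pos)
  )
}

# Per-window mean of `values` (NA values excluded from both sum and count).
.windowedMean <- function(pos, values, grid) {
  wi <- .windowIndex(pos, grid)
  ok <- !is.na(values)
  cs <- c(0, cumsum(ifelse(ok, values, 0)))
  cn <- c(0L, cumsum(as.integer(ok)))
  n <- cn[wi$hi + 1L] - cn[wi$lo + 1L]
  s <- cs[wi$hi + 1L] - cs[wi$lo + 1L]
  list(value = ifelse(n > 0L, s / n, NA_real_), n = as.integer(n))
}

# Per-window sum of `values` plus count of contributing (non-NA) sites.
.windowedSum <- function(pos, values, grid) {
  wi <- .windowIndex(pos, grid)
  ok <- !is.na(values)
  cs <- c(0, cumsum(ifelse(ok, values, 0)))
  cn <- c(0L, cumsum(as.integer(ok)))
  list(
    value = cs[wi$hi + 1L] - cs[wi$lo + 1L],
    n = as.integer(cn[wi$hi + 1L] - cn[wi$lo + 1L])
  )
}

.WindowProfile <- function(chrom, grid, value, n, stat, window, step) {
  new("WindowProfile",
    chrom = as.character(chrom), start = as.numeric(grid$start),
    end = as.numeric(grid$end), value = as.numeric(value),
    n = as.integer(n), stat = stat,
    window = as.numeric(window), step = as.numeric(step)
  )
}

.sameGrid <- function(a, b) {
  identical(a@chrom, b@chrom) &&
    length(a@start) == length(b@start) &&
    all(a@start == b@start) && all(a@end == b@end)
}
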