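#' @importFrom IRanges IRanges findOverlaps reduce start end width
#' @importFrom S4Vectors queryHits subjectHits
NULL

# Run code with a private RNG state: seeds the Mersenne-Twister, restores the
# caller's .Random.seed afterwards so simulators don't perturb user code.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# 0-based half-open [start, end) -> IRanges (1-based closed). Zero-width
# intervals are not representable; callers guarantee end > start.
as_iranges0 <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

# Overlap (>= 1 bp) between two 0-based half-open interval tables restricted
# to one chromosome name vector each. Returns hits as a two-column matrix.
overlap_pairs <- function(chrom1, start1, end1, chrom2, start2, end2) {
  stopifnot(length(chrom1) == length(start1), length(chrom2) == length(start2))
  if (length(chrom1) == 0L || length(chrom2) == 0L)
    return(matrix(integer(0), ncol = 2L))
  out <- vector("list", 0L)
  for (ch in intersect(unique(chrom1), unique(chrom2))) {
    i1 <- which(chrom1 == ch)
    i2 <- which(chrom2 == ch)
    hits <- IRanges::findOverlaps(as_iranges0(start1[i1], end1[i1]),
                                  as_iranges0(start2[i2], end2[i2]))
    out[[ch]] <- cbind(i1[S4Vectors::queryHits(hits)], i2[S4Vectors::subjectHits(hits)])
  }
  if (length(out) == 0L) matrix(integer(0), ncol = 2L) else do.call(rbind, out)
}

# Union-merge 0-based half-open intervals per chromosome (touching intervals
# merge: gap 0 always merges, matching the linking tie rule).
merge_intervals <- function(chrom, start, end) {
  if (length(chrom) == 0L)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  res <- lapply(split(seq_along(chrom), chrom), function(idx) {
    r <- IRanges::reduce(as_iranges0(start[idx], end[idx]), min.gapwidth = 1L)
    data.frame(chrom = chrom[idx[1L]], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Fragment-base counts per fixed-width bin for one chromosome.
# starts/ends are 0-based half-open, already clipped to [0, chrom_len].
# Each fragment contributes its overlap in bases to every bin it spans.
bin_base_counts <- function(starts, ends, chrom_len, width) {
  nbins <- as.integer(ceiling(chrom_len / width))
  out <- numeric(nbins)
  if (length(starts) == 0L) return(out)
  first <- starts %/% width
  last <- (ends - 1L) %/% width
  span <- max(last - first) + 1L
  for (k in seq_len(span) - 1L) {
    sel <- which(first + k <= last)
    if (length(sel) == 0L) next
    b <- first[sel] + k
    lo <- pmax(starts[sel], b * width)
    hi <- pmin(ends[sel], (b + 1L) * width)
    contrib <- hi - lo
    tab <- rowsum(contrib, b)
    idx <- as.integer(rownames(tab)) + 1L
    out[idx] <- out[idx] + tab[, 1L]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
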