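# Metaprofiles: an external piecewise-constant signal (bedGraph semantics)
# averaged in fixed bins over windows centered on R-loop midpoints. Bin values
# are length-weighted means of the track over the bin; positions outside the
# chromosome contribute zero (zero-padding keeps n_used stable).

# Cumulative integral of a piecewise-constant track evaluated at positions x.
# d: data frame (start, end, value) sorted, non-overlapping. F(x) = integral
# of the track over [0, x), treating uncovered gaps as zero.
track_integral_at <- function(d, x) {
  if (is.null(d) || nrow(d) == 0L) return(numeric(length(x)))
  seg <- d$value * (d$end - d$start)
  cum <- c(0, cumsum(seg))              # integral up to start of interval k+1
  idx <- findInterval(x, d$start)       # last interval with start <= x
  out <- numeric(length(x))
  pos <- idx > 0L
  i <- idx[pos]
  out[pos] <- cum[i] +
    d$value[i] * pmax(0, pmin(x[pos], d$end[i]) - d$start[i])
  out
}

#' Signal matrix centered on intervals
#'
#' Builds the metaplot matrix: one row per center interval, \code{n_bins}
#' equal bins spanning [midpoint - flank, midpoint + flank). Each cell is the
#' length-weighted mean of the track over the bin; windows running past a
#' chromosome end are zero-padded and still counted. With
#' \code{orient_by_strand}, rows whose center is on the minus strand are
#' reversed so all profiles read 5' to 3'.
#'
#' @param track A \code{signal_track} from \code{\link{read_signal_track}}, or
#'   a named list of data frames (\code{start}, \code{end}, \code{value}) per
#'   chromosome.
#' @param centers Data frame with \code{chrom}, \code{start}, \code{end} and
#'   optionally \code{strand}.
#' @param flank Half-window in bp (default 2500).
#' @param n_bins Number of bins, even (default 100).
#' @param orient_by_strand Reverse minus-strand rows (default \code{FALSE}).
#' @return A \code{meta_matrix}: \code{matrix} (centers x bins),
#'   \code{mean_profile} (column means), \code{n_used}, \code{flank},
#'   \code{n_bins}, \code{bin_width}.
#' @export
signal_matrix <- function(track, centers, flank = 2500L, n_bins = 100L,
                          orient_by_strand = FALSE) {
  if (nrow(centers) == 0L) stop("no center intervals")
  if (n_bins %% 2L != 0L) stop("n_bins must be even")
  if (flank <= 0) stop("flank must be positive")
  bw <- 2 * flank / n_bins
  n <- nrow(centers)
  m <- matrix(0, nrow = n, ncol = n_bins)
  mid <- (centers$start + centers$end) / 2
  for (ch in unique(centers$chrom)) {
    rows <- which(centers$chrom == ch)
    d <- track[[ch]]
    edges <- outer(mid[rows] - flank, (0:n_bins) * bw, `+`)
    f <- matrix(track_integral_at(d, pmax(0, as.numeric(edges))),
                nrow = length(rows))
    m[rows, ] <- (f[, -1L, drop = FALSE] - f[, -(n_bins + 1L), drop = FALSE]) / bw
  }
  if (orient_by_strand && "strand" %in% names(centers)) {
    rev_rows <- which(!is.na(centers$strand) & centers$strand == "-")
    if (length(rev_rows))
      m[rev_rows, ] <- m[rev_rows, n_bins:1L, drop = FALSE]
  }
  structure(list(matrix = m, mean_profile = colMeans(m), n_used = n,
                 flank = flank, n_bins = as.integer(n_bins), bin_width = bw),
            class = "meta_matrix")
}

#' Write a metaprofile as TSV
#'
#' @param mm A \code{meta_matrix}.
#' @param path Output file for the mean profile (columns: bin center offset
#'   from the interval midpoint, mean signal).
#' @param matrix_path Optional second file receiving the full matrix.
#' @return \code{path}, invisibly.
#' @export
write_profile <- function(mm, path, matrix_path = NULL) {
  offset <- -mm$flank + (seq_len(mm$n_bins) - 0.5) * mm$bin_width
  write_tsv(data.frame(offset = offset, mean_signal = mm$mean_profile), path)
  if (!is.null(matrix_path))
    utils::write.table(mm$matrix, matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}
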