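# Treatment-vs-control enrichment caller. Sliding windows are scored with a
# Poisson upper-tail test against a local-lambda background estimated from the
# control (merged RNase-H samples for the total R-loop call; the opposite
# strand for the strand-enrichment call), q-values are Benjamini-Hochberg over
# all tested windows, and significant windows are linked into narrow and broad
# peaks.

#' Caller parameters
#'
#' @param window Test window width w in bp (default 200).
#' @param step Window step (default w/2); must divide \code{window}.
#' @param local_windows Nested background window sizes for the local lambda
#'   (default 1000, 5000, 10000 bp).
#' @param pseudocount Added to every lambda (default 0.5); guards empty
#'   controls.
#' @param q_narrow,q_broad Window q-value thresholds for the narrow (0.05) and
#'   broad (0.10) calls.
#' @param link_gap_narrow,link_gap_broad Maximum gap bridged when linking
#'   significant windows (defaults w and 4w).
#' @param min_peak_len Peaks shorter than this are dropped (default w).
#' @return A \code{caller_params} list.
#' @export
caller_params <- function(window = 200L, step = window %/% 2L,
                          local_windows = c(1000L, 5000L, 10000L),
                          pseudocount = 0.5,
                          q_narrow = 0.05, q_broad = 0.10,
                          link_gap_narrow = window,
                          link_gap_broad = 4L * window,
                          min_peak_len = window) {
  stopifnot(window > 0L, step > 0L, window %% step == 0L,
            all(local_windows > 0L), pseudocount >= 0,
            q_narrow > 0, q_narrow < 1, q_broad > 0, q_broad < 1,
            link_gap_narrow >= 0L, link_gap_broad >= 0L, min_peak_len >= 0L)
  structure(list(window = as.integer(window), step = as.integer(step),
                 local_windows = as.integer(local_windows),
                 pseudocount = pseudocount,
                 q_narrow = q_narrow, q_broad = q_broad,
                 link_gap_narrow = as.integer(link_gap_narrow),
                 link_gap_broad = as.integer(link_gap_broad),
                 min_peak_len = as.integer(min_peak_len)),
            class = "caller_params")
}

#' Poisson upper-tail probability
#'
#' P(X >= t) for X ~ Poisson(lambda), the enrichment p-value of an observed
#' window count against its background rate. Computed in log space via the
#' regularized incomplete gamma function (stable for large t and lambda).
#'
#' @param t Observed count(s), non-negative integer(s).
#' @param lambda Background rate(s), >= 0.
#' @return P(X >= t), vectorized over \code{t} and \code{lambda}.
#' @export
poisson_sf <- function(t, lambda) {
  if (any(lambda < 0)) stop("lambda must be >= 0")
  if (any(t < 0) || any(t != floor(t))) stop("t must be a non-negative integer")
  stats::ppois(t - 1, lambda, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q_i = min over j with p_j >= p_i of
#' p_j * m / rank_j, clipped at 1. Input order is preserved.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return q-values, same length and order.
#' @export
bh_qvalues <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Local-lambda background for one window
#'
#' Scalar, audit-friendly version of the background model used by
#' \code{\link{call_peaks}}: lambda = max(lambda_bg, lambda_L over the nested
#' local windows) + pseudocount, where lambda_L converts control
#' fragment-bases in a window of size L centered on the region midpoint into
#' expected treatment-scale fragments in the test window
#' (bases / mean_frag_len * (w / L) * depth_ratio), and lambda_bg is the
#' genome-wide control rate * w * depth_ratio. Local windows are clipped to
#' the chromosome and rescaled by their actual covered length.
#'
#' @param region List or vector-like with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open; the test window).
#' @param control Data frame of pooled control fragments (\code{chrom},
#'   \code{start}, \code{end}).
#' @param genome A \code{genome_model}.
#' @param params A \code{caller_params}.
#' @param depth_ratio r = N_treatment / N_control, > 0.
#' @param mean_frag_len Mean fragment length used to convert fragment-bases
#'   into fragment-equivalents.
#' @return The background rate lambda for the region.
#' @export
local_lambda <- function(region, control, genome, params = caller_params(),
                         depth_ratio = 1, mean_frag_len = 250) {
  if (depth_ratio <= 0) stop("depth_ratio must be > 0")
  if (nrow(control) == 0L && params$pseudocount == 0)
    stop("empty control with pseudocount 0")
  ch <- region$chrom
  clen <- genome$chrom_sizes[[ch]]
  if (is.null(clen)) stop("unknown chromosome: ", ch)
  w <- params$window
  mid <- (region$start + region$end) / 2
  sel <- control$chrom == ch
  lam <- vapply(params$local_windows, function(L) {
    lo <- max(0, mid - L / 2)
    hi <- min(clen, mid + L / 2)
    ov <- pmin(control$end[sel], hi) - pmax(control$start[sel], lo)
    bases <- sum(ov[ov > 0])
    (bases / mean_frag_len) * (w / (hi - lo)) * depth_ratio
  }, 0)
  total_bases <- sum(control$end - control$start)
  lam_bg <- (total_bases / mean_frag_len / sum(genome$chrom_sizes)) * w *
    depth_ratio
  max(c(lam_bg, lam)) + params$pseudocount
}

# Link significant windows into peaks. Windows are [starts, ends) sorted by
# start within one chromosome; gap <= link_gap merges (gap 0 always merges).
link_windows <- function(chrom, starts, ends, p, q, fold, link_gap,
                         min_peak_len) {
  if (length(starts) == 0L)
    return(NULL)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; p <- p[o]; q <- q[o]; fold <- fold[o]
  grp <- cumsum(c(1L, as.integer(starts[-1L] - cummax(ends)[-length(ends)] >
                                   link_gap)))
  res <- lapply(split(seq_along(starts), grp), function(idx) {
    i_best <- idx[which.max(fold[idx])]
    data.frame(chrom = chrom, start = min(starts[idx]), end = max(ends[idx]),
               summit = as.integer((starts[i_best] + ends[i_best]) / 2 -
                                     min(starts[idx])),
               max_fold = max(fold[idx]), p = min(p[idx]), q = min(q[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[out$end - out$start >= min_peak_len, , drop = FALSE]
}

empty_peaks <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), summit = integer(0), max_fold = numeric(0),
             p = numeric(0), q = numeric(0), mode = character(0),
             stringsAsFactors = FALSE)
}

#' Call enrichment peaks
#'
#' Slides windows of width w at the configured step over every chromosome,
#' converts fragment-base counts into fragment-equivalents
#' (bases / mean fragment length, rounded), tests each window with
#' \code{\link{poisson_sf}} against \code{\link{local_lambda}}, adjusts over
#' all tested windows with \code{\link{bh_qvalues}}, then links windows at
#' q <= q_narrow into narrow peaks (gap <= link_gap_narrow) and windows at
#' q <= q_broad into broad peaks (gap <= link_gap_broad). Peaks shorter than
#' \code{min_peak_len} are dropped; each peak carries its minimum window q.
#'
#' @param treatment A \code{fragment_set}.
#' @param controls A \code{fragment_set} or list of them; multiple controls
#'   are pooled ("merged") before use.
#' @param genome A \code{genome_model}.
#' @param params A \code{caller_params}.
#' @param strand_mode \code{"both"} (use all fragments), \code{"plus_only"}
#'   or \code{"minus_only"} (restrict treatment and control to one strand).
#' @return Peak data frame: \code{chrom}, \code{start}, \code{end},
#'   \code{strand}, \code{summit} (bp offset from peak start), \code{max_fold},
#'   \code{p}, \code{q}, \code{mode} (\code{narrow}/\code{broad}).
#' @export
call_peaks <- function(treatment, controls, genome, params = caller_params(),
                       strand_mode = c("both", "plus_only", "minus_only")) {
  strand_mode <- match.arg(strand_mode)
  if (inherits(controls, "fragment_set")) controls <- list(controls)
  ctrl <- do.call(rbind, lapply(controls, function(s) s$fragments))
  tr <- treatment$fragments
  if (strand_mode != "both") {
    s <- if (strand_mode == "plus_only") "+" else "-"
    tr <- tr[tr$strand == s, , drop = FALSE]
    ctrl <- ctrl[ctrl$strand != s, , drop = FALSE]
  }
  if (all(genome$chrom_sizes < params$window))
    stop("every chromosome is shorter than the test window")
  if (nrow(tr) == 0L) {
    warning("empty treatment: no peaks called")
    return(empty_peaks())
  }
  if (nrow(ctrl) == 0L && params$pseudocount == 0)
    stop("empty control with pseudocount 0")
  w <- params$window; step <- params$step
  wb <- w %/% step
  mean_len <- mean(tr$end - tr$start)
  r <- nrow(tr) / max(nrow(ctrl), 1L)
  lam_bg <- (sum(ctrl$end - ctrl$start) / mean_len / sum(genome$chrom_sizes)) *
    w * r
  win <- list(); tcount <- list(); lam <- list()
  for (ch in names(genome$chrom_sizes)) {
    clen <- genome$chrom_sizes[[ch]]
    if (clen < w) next
    selt <- tr$chrom == ch
    selc <- ctrl$chrom == ch
    bt <- bin_base_counts(pmax(0L, tr$start[selt]),
                          pmin(as.integer(clen), tr$end[selt]), clen, step)
    bc <- bin_base_counts(pmax(0L, ctrl$start[selc]),
                          pmin(as.integer(clen), ctrl$end[selc]), clen, step)
    nb <- length(bt)
    nwin <- nb - wb + 1L
    if (nwin < 1L) next
    cs_t <- c(0, cumsum(bt))
    cs_c <- c(0, cumsum(bc))
    i <- seq_len(nwin)                     # window covers bins i .. i+wb-1
    tb <- cs_t[i + wb] - cs_t[i]
    tc <- as.integer(round(tb / mean_len))
    mid <- (i - 1L) * step + w / 2
    lam_ch <- rep(lam_bg, nwin)
    for (L in params$local_windows) {
      lo_bin <- pmax(0, floor((mid - L / 2) / step))
      hi_bin <- pmin(nb, ceiling((mid + L / 2) / step))
      covered <- pmin(clen, hi_bin * step) - lo_bin * step
      cb <- cs_c[hi_bin + 1L] - cs_c[lo_bin + 1L]
      lam_ch <- pmax(lam_ch, (cb / mean_len) * (w / covered) * r)
    }
    lam_ch <- lam_ch + params$pseudocount
    win[[ch]] <- data.frame(chrom = ch, start = (i - 1L) * step,
                            end = pmin(as.integer(clen), (i - 1L) * step + w),
                            stringsAsFactors = FALSE)
    tcount[[ch]] <- tc
    lam[[ch]] <- lam_ch
  }
  if (length(win) == 0L) stop("no testable windows on this genome")
  windows <- do.call(rbind, win)
  tc <- unlist(tcount, use.names = FALSE)
  lm <- unlist(lam, use.names = FALSE)
  pvals <- poisson_sf(tc, lm)
  qvals <- bh_qvalues(pvals)
  fold <- tc / lm
  strand_lab <- switch(strand_mode, both = ".", plus_only = "+",
                       minus_only = "-")
  out <- list()
  for (mode in c("narrow", "broad")) {
    qt <- if (mode == "narrow") params$q_narrow else params$q_broad
    gap <- if (mode == "narrow") params$link_gap_narrow else
      params$link_gap_broad
    sel <- which(qvals <= qt)
    if (length(sel) == 0L) next
    pk <- lapply(unique(windows$chrom[sel]), function(ch) {
      ss <- sel[windows$chrom[sel] == ch]
      link_windows(ch, windows$start[ss], windows$end[ss], pvals[ss],
                   qvals[ss], fold[ss], gap, params$min_peak_len)
    })
    pk <- do.call(rbind, pk)
    if (is.null(pk) || nrow(pk) == 0L) next
    pk$strand <- strand_lab
    pk$mode <- mode
    out[[mode]] <- pk[, c("chrom", "start", "end", "strand", "summit",
                          "max_fold", "p", "q", "mode")]
  }
  if (length(out) == 0L) return(empty_peaks())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write peaks in narrowPeak-style BED6+4
#'
#' Columns: chrom, start, end, name, score = int(-10*log10 q) capped at 1000,
#' strand, fold, -log10 p, -log10 q, summit offset.
#'
#' @param peaks Peak data frame from \code{\link{call_peaks}}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  score <- pmin(1000L, as.integer(round(-10 * log10(pmax(peaks$q, 1e-100)))))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%.4f\t%.4f\t%.4f\t%d",
                   peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
                   paste0("peak_", seq_len(nrow(peaks)), "_", peaks$mode),
                   score, peaks$strand, peaks$max_fold,
                   -log10(pmax(peaks$p, 1e-100)),
                   -log10(pmax(peaks$q, 1e-100)), peaks$summit)
  writeLines(lines, path)
  invisible(path)
}
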