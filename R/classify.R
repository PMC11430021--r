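# Replicate consensus and stranded/unstranded classification. An R-loop is
# kept when qualifying peaks (q <= q_max, narrow or broad) from at least
# min_support distinct DRIP replicates overlap it; it is "stranded" when the
# strand-enrichment call (one strand tested against the other) passes the same
# consensus filter for exactly one strand.

qualifying <- function(peaks, q_max) peaks[peaks$q <= q_max, , drop = FALSE]

# For a set of candidate regions, count distinct samples whose qualifying
# peaks overlap each region by >= 1 bp, and collect support details.
support_counts <- function(regions, per_sample_peaks, q_max) {
  n <- nrow(regions)
  n_sup <- integer(n)
  best_q <- rep(NA_real_, n)
  modes <- matrix("none", nrow = n, ncol = length(per_sample_peaks))
  for (s in seq_along(per_sample_peaks)) {
    pk <- qualifying(per_sample_peaks[[s]], q_max)
    if (nrow(pk) == 0L) next
    hits <- overlap_pairs(regions$chrom, regions$start, regions$end,
                          pk$chrom, pk$start, pk$end)
    if (nrow(hits) == 0L) next
    hit_rows <- unique(hits[, 1L])
    n_sup[hit_rows] <- n_sup[hit_rows] + 1L
    for (k in seq_len(nrow(hits))) {
      i <- hits[k, 1L]; j <- hits[k, 2L]
      best_q[i] <- min(best_q[i], pk$q[j], na.rm = TRUE)
      m <- pk$mode[j]
      modes[i, s] <- if (modes[i, s] == "none") m
                     else if (modes[i, s] == m) m else "both"
    }
  }
  list(n_sup = n_sup, best_q = best_q,
       modes = apply(modes, 1L, paste, collapse = ","))
}

#' Build the replicate consensus R-loop set
#'
#' Union-merges all qualifying peaks (q <= \code{q_max}, narrow or broad)
#' across samples and keeps every merged region overlapped (>= 1 bp) by
#' qualifying peaks from at least \code{min_support} distinct samples.
#'
#' @param per_sample_peaks List (one element per DRIP replicate) of peak data
#'   frames from \code{\link{call_peaks}}.
#' @param min_support Minimum number of supporting samples (default 3).
#' @param q_max Peak q-value cutoff for support (default 0.001).
#' @return Data frame of consensus regions: \code{chrom}, \code{start},
#'   \code{end}, \code{n_supporting_samples}, \code{support_modes},
#'   \code{best_q}. Class is not yet assigned (see
#'   \code{\link{classify_strandedness}}).
#' @export
consensus_rloops <- function(per_sample_peaks, min_support = 3L,
                             q_max = 0.001) {
  if (min_support > length(per_sample_peaks))
    stop("min_support (", min_support, ") exceeds number of samples (",
         length(per_sample_peaks), ")")
  qual <- lapply(per_sample_peaks, qualifying, q_max = q_max)
  all_pk <- do.call(rbind, qual)
  if (is.null(all_pk) || nrow(all_pk) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_supporting_samples = integer(0),
                      support_modes = character(0), best_q = numeric(0),
                      stringsAsFactors = FALSE))
  regions <- merge_intervals(all_pk$chrom, all_pk$start, all_pk$end)
  sup <- support_counts(regions, per_sample_peaks, q_max)
  keep <- sup$n_sup >= min_support
  out <- regions[keep, , drop = FALSE]
  out$n_supporting_samples <- sup$n_sup[keep]
  out$support_modes <- sup$modes[keep]
  out$best_q <- sup$best_q[keep]
  rownames(out) <- NULL
  out
}

#' Call strand-enrichment peaks for one sample
#'
#' Runs the caller twice on reads split by strand: once with the plus-strand
#' fragments as treatment and the minus strand as control, and once the other
#' way around. Emitted peaks carry the treatment strand. Only DRIP samples
#' are eligible; RNase-H controls play no role in strand classification.
#'
#' @param sample A DRIP \code{fragment_set}.
#' @param genome A \code{genome_model}.
#' @param params A \code{caller_params}.
#' @return Strand-labelled peak data frame (both runs combined).
#' @export
call_strand_enrichment <- function(sample, genome, params = caller_params()) {
  if (sample$condition != "DRIP")
    stop("strand enrichment is only called on DRIP samples")
  f <- sample$fragments
  for (s in c("+", "-"))
    if (!any(f$strand == s))
      warning("sample ", sample$sample_id, " has no fragments on strand ", s,
              "; proceeding with pseudocount only")
  plus <- suppressWarnings(
    call_peaks(sample, sample, genome, params, strand_mode = "plus_only"))
  minus <- suppressWarnings(
    call_peaks(sample, sample, genome, params, strand_mode = "minus_only"))
  out <- rbind(plus, minus)
  rownames(out) <- NULL
  out
}

#' Classify consensus R-loops as stranded or unstranded
#'
#' A consensus R-loop is \code{"stranded"} when qualifying strand-enrichment
#' peaks of exactly one strand (>= \code{min_support} samples at
#' q <= \code{q_max}, the same filter as the consensus call) overlap it by
#' >= 1 bp; its strand is that strand. When both strands qualify
#' independently, or neither does, the loop is \code{"unstranded"} with
#' strand \code{NA}.
#'
#' @param consensus Consensus regions from \code{\link{consensus_rloops}}.
#' @param strand_peaks List (one element per DRIP replicate) of
#'   strand-labelled peak data frames from
#'   \code{\link{call_strand_enrichment}}.
#' @param min_support Minimum supporting samples per strand (default 3).
#' @param q_max q-value cutoff (default 0.001).
#' @return \code{consensus} with added columns \code{rloop_class}
#'   (\code{stranded}/\code{unstranded}), \code{strand}
#'   (\code{+}/\code{-}/\code{NA}) and per-strand support counts
#'   \code{n_support_plus}, \code{n_support_minus}.
#' @export
classify_strandedness <- function(consensus, strand_peaks, min_support = 3L,
                                  q_max = 0.001) {
  if (nrow(consensus) == 0L) stop("empty consensus set")
  count_strand <- function(s) {
    per_sample <- lapply(strand_peaks, function(pk)
      pk[pk$strand == s, , drop = FALSE])
    support_counts(consensus, per_sample, q_max)$n_sup
  }
  np <- count_strand("+")
  nm <- count_strand("-")
  plus_ok <- np >= min_support
  minus_ok <- nm >= min_support
  stranded <- xor(plus_ok, minus_ok)
  consensus$rloop_class <- ifelse(stranded, "stranded", "unstranded")
  consensus$strand <- ifelse(stranded, ifelse(plus_ok, "+", "-"), NA)
  consensus$n_support_plus <- np
  consensus$n_support_minus <- nm
  consensus
}

#' Write classified R-loops as BED6
#'
#' Name field carries the class, strand column is \code{+}/\code{-} for
#' stranded loops and \code{.} for unstranded ones, score is the consensus
#' support count.
#'
#' @param rloops Classified data frame from
#'   \code{\link{classify_strandedness}}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_rloops_bed <- function(rloops, path) {
  write_bed(data.frame(chrom = rloops$chrom, start = rloops$start,
                       end = rloops$end, name = rloops$rloop_class,
                       score = rloops$n_supporting_samples,
                       strand = ifelse(is.na(rloops$strand), ".",
                                       rloops$strand),
                       stringsAsFactors = FALSE), path)
}
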