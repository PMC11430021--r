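# Strand-split binned coverage and replicate PCA QC. "Coverage" is
# fragment-bases per bin: each fragment contributes its base overlap to every
# bin it spans, on its own strand, so the total over all bins equals the sum
# of (clipped) fragment lengths exactly.

#' Bin strand-split fragment coverage
#'
#' @param frags A \code{fragment_set}.
#' @param genome A \code{genome_model}; fragments on unknown chromosomes are
#'   an error, fragments extending past a chromosome end are clipped.
#' @param bin_width Bin width in bp (default 500).
#' @return A \code{stranded_coverage}: list with \code{sample_id},
#'   \code{condition}, \code{bin_width}, \code{total_fragment_bases} and
#'   \code{cov}, a per-chromosome list of \code{"+"}/\code{"-"} numeric
#'   vectors of length \code{ceiling(chrom_len / bin_width)}.
#' @export
bin_coverage <- function(frags, genome, bin_width = 500L) {
  if (bin_width <= 0) stop("bin_width must be positive")
  f <- frags$fragments
  unknown <- setdiff(unique(f$chrom), names(genome$chrom_sizes))
  if (length(unknown))
    stop("fragments on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  cov <- list()
  total <- 0
  for (ch in names(genome$chrom_sizes)) {
    clen <- genome$chrom_sizes[[ch]]
    cov[[ch]] <- list()
    for (s in c("+", "-")) {
      sel <- f$chrom == ch & f$strand == s
      starts <- pmax(0L, f$start[sel])
      ends <- pmin(as.integer(clen), f$end[sel])
      keep <- ends > starts
      v <- bin_base_counts(starts[keep], ends[keep], clen, bin_width)
      cov[[ch]][[s]] <- v
      total <- total + sum(v)
    }
  }
  structure(list(sample_id = frags$sample_id, condition = frags$condition,
                 bin_width = as.integer(bin_width), cov = cov,
                 total_fragment_bases = total),
            class = "stranded_coverage")
}

#' Assemble the coverage matrix for QC
#'
#' Rows are bins in a fixed deterministic order: chromosomes in genome order,
#' the full \code{"+"} strand block first, then the \code{"-"} block. Columns
#' are samples.
#'
#' @param covs List of \code{stranded_coverage} objects on the same genome and
#'   bin width.
#' @return Numeric matrix (bins x samples) with column names = sample ids.
#' @export
coverage_matrix <- function(covs) {
  if (length(covs) == 0L) stop("no samples")
  bw <- vapply(covs, `[[`, 0L, "bin_width")
  if (length(unique(bw)) != 1L) stop("mismatched bin_width across samples")
  chroms <- names(covs[[1L]]$cov)
  for (cv in covs)
    if (!identical(names(cv$cov), chroms) ||
        !identical(lengths(lapply(cv$cov, `[[`, "+")),
                   lengths(lapply(covs[[1L]]$cov, `[[`, "+"))))
      stop("samples binned on different genomes")
  col_of <- function(cv)
    c(unlist(lapply(chroms, function(ch) cv$cov[[ch]][["+"]]), use.names = FALSE),
      unlist(lapply(chroms, function(ch) cv$cov[[ch]][["-"]]), use.names = FALSE))
  m <- vapply(covs, col_of, numeric(sum(2L * vapply(chroms, function(ch)
    length(covs[[1L]]$cov[[ch]][["+"]]), 0L))))
  colnames(m) <- vapply(covs, `[[`, "", "sample_id")
  m
}

#' Replicate PCA quality control
#'
#' Standardizes each bin (row) to zero mean and unit variance (constant rows
#' dropped), runs PCA by singular value decomposition with samples as
#' observations, and flags whether DRIP and RNase-H samples occupy disjoint
#' PC1 ranges — the qualitative separation expected of a specific ssDRIP
#' experiment. The flag is sign-invariant.
#'
#' @param m Coverage matrix from \code{\link{coverage_matrix}}.
#' @param conditions Character vector per column, \code{"DRIP"} or
#'   \code{"RNASEH"}.
#' @return A \code{qc_report}: \code{scores} (samples x 2 PC coordinates),
#'   \code{variance_fraction} (all components), \code{separated} flag.
#' @export
pca_qc <- function(m, conditions) {
  if (ncol(m) < 3L) stop("PCA QC needs >= 3 samples")
  if (length(conditions) != ncol(m)) stop("one condition per sample required")
  if (!all(conditions %in% c("DRIP", "RNASEH")))
    stop("conditions must be DRIP or RNASEH")
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) stop("degenerate matrix: no bin varies across samples")
  z <- (m[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  # samples as observations; rows already standardized, no further scaling
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  pc1 <- scores[, 1L]
  drip <- pc1[conditions == "DRIP"]
  ctrl <- pc1[conditions == "RNASEH"]
  separated <- length(drip) > 0L && length(ctrl) > 0L &&
    (max(drip) < min(ctrl) || max(ctrl) < min(drip))
  structure(list(sample_id = colnames(m), conditions = conditions,
                 scores = scores, variance_fraction = vf,
                 separated = separated),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("PCA QC:", length(x$sample_id), "samples; PC1 variance",
      sprintf("%.1f%%;", 100 * x$variance_fraction[1L]),
      if (x$separated) "conditions separate on PC1" else
        "conditions DO NOT separate on PC1", "\n")
  invisible(x)
}
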