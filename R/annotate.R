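# Genomic-feature assignment and enrichment. Feature windows follow the
# orientation-aware definitions: promoter/TSS = [TSS-2.5kb, TSS+0.5kb), gene
# downstream = [end-0.5kb, end+2.5kb) with "end" the transcription termination
# side, both in gene orientation. Overlaps resolve by fixed priority so the
# labels partition the genome; R-loops are assigned the label at their
# midpoint.

FEATURE_LABELS <- c("promoter_tss", "exon", "intron", "downstream_tts",
                    "pseudogene", "intergenic")

#' Build the prioritized feature map
#'
#' Computes promoter/TSS and downstream windows in gene orientation for
#' non-pseudogene genes (clipped to chromosome bounds), labels pseudogene
#' bodies, and resolves overlaps by the priority promoter_tss > exon >
#' intron > downstream_tts > pseudogene > intergenic. Without an exon table,
#' gene bodies are labelled intron.
#'
#' @param genome A \code{genome_model} with stranded genes.
#' @param exons Optional data frame (\code{chrom}, \code{start}, \code{end})
#'   of exon intervals.
#' @return A \code{feature_map}: \code{partition} data frame (\code{chrom},
#'   \code{start}, \code{end}, \code{label}) covering the genome disjointly,
#'   \code{label_bp} named vector of genome bp per label, and the genome.
#' @export
build_feature_map <- function(genome, exons = NULL) {
  g <- genome$genes
  if (nrow(g) && !all(g$strand %in% c("+", "-")))
    stop("genes must be stranded")
  clen <- genome$chrom_sizes
  clip <- function(d) {
    if (nrow(d) == 0L) return(d)
    d$start <- pmax(0, d$start)
    d$end <- pmin(clen[d$chrom], d$end)
    d <- d[d$end > d$start, , drop = FALSE]
    d[, c("chrom", "start", "end")]
  }
  gg <- g[g$biotype != "pseudogene", , drop = FALSE]
  ps <- g[g$biotype == "pseudogene", , drop = FALSE]
  tss <- ifelse(gg$strand == "+", gg$start, gg$end)
  tts <- ifelse(gg$strand == "+", gg$end, gg$start)
  raw <- list(
    promoter_tss = data.frame(chrom = gg$chrom,
                              start = ifelse(gg$strand == "+", tss - 2500, tss - 500),
                              end = ifelse(gg$strand == "+", tss + 500, tss + 2500)),
    exon = if (is.null(exons)) data.frame(chrom = character(0), start = integer(0),
                                          end = integer(0))
           else exons[, c("chrom", "start", "end")],
    intron = data.frame(chrom = gg$chrom, start = gg$start, end = gg$end),
    downstream_tts = data.frame(chrom = gg$chrom,
                                start = ifelse(gg$strand == "+", tts - 500, tts - 2500),
                                end = ifelse(gg$strand == "+", tts + 2500, tts + 500)),
    pseudogene = data.frame(chrom = ps$chrom, start = ps$start, end = ps$end))
  parts <- list()
  taken <- list()   # per chrom, IRanges of already-assigned bp
  for (lab in setdiff(FEATURE_LABELS, "intergenic")) {
    d <- clip(raw[[lab]])
    if (nrow(d) == 0L) next
    for (ch in unique(d$chrom)) {
      ir <- IRanges::reduce(as_iranges0(d$start[d$chrom == ch],
                                        d$end[d$chrom == ch]))
      if (!is.null(taken[[ch]]))
        ir <- IRanges::setdiff(ir, taken[[ch]])
      if (length(ir) == 0L) next
      parts[[length(parts) + 1L]] <-
        data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
                   end = IRanges::end(ir), label = lab,
                   stringsAsFactors = FALSE)
      taken[[ch]] <- IRanges::reduce(c(taken[[ch]] %||% IRanges::IRanges(),
                                       ir))
    }
  }
  for (ch in names(clen)) {
    full <- as_iranges0(0L, as.integer(clen[[ch]]))
    ir <- if (is.null(taken[[ch]])) full else IRanges::setdiff(full, taken[[ch]])
    if (length(ir) == 0L) next
    parts[[length(parts) + 1L]] <-
      data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
                 end = IRanges::end(ir), label = "intergenic",
                 stringsAsFactors = FALSE)
  }
  partition <- do.call(rbind, parts)
  partition <- partition[order(partition$chrom, partition$start), ,
                         drop = FALSE]
  rownames(partition) <- NULL
  bp <- tapply(partition$end - partition$start, partition$label, sum)
  label_bp <- stats::setNames(rep(0, length(FEATURE_LABELS)), FEATURE_LABELS)
  label_bp[names(bp)] <- bp
  structure(list(partition = partition, label_bp = label_bp, genome = genome),
            class = "feature_map")
}

#' Assign genomic features by midpoint
#'
#' @param regions Data frame with \code{chrom}, \code{start}, \code{end}
#'   (R-loops or any intervals).
#' @param fmap A \code{feature_map}.
#' @return Character vector of labels, one per region (the label of the
#'   partition interval containing the region midpoint; midpoints outside any
#'   labelled interval are \code{"intergenic"}).
#' @export
assign_feature <- function(regions, fmap) {
  n <- nrow(regions)
  if (n == 0L) return(character(0))
  mid <- (regions$start + regions$end) %/% 2L
  lab <- rep("intergenic", n)
  hits <- overlap_pairs(regions$chrom, mid, mid + 1L,
                        fmap$partition$chrom, fmap$partition$start,
                        fmap$partition$end)
  if (nrow(hits)) lab[hits[, 1L]] <- fmap$partition$label[hits[, 2L]]
  lab
}

#' Observed/expected feature enrichment per R-loop class
#'
#' Observed = midpoint-assigned counts per feature; expected = class size
#' times the feature's genome fraction (uniform-placement model); the
#' confidence interval comes from resampling the same number of midpoints
#' uniformly over the genome \code{n_boot} times.
#'
#' @param rloops Classified R-loop data frame (needs \code{chrom},
#'   \code{start}, \code{end}, \code{rloop_class}).
#' @param fmap A \code{feature_map}.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the resampling (default 1).
#' @return Data frame with one row per (class, feature): \code{rloop_class},
#'   \code{feature}, \code{observed}, \code{expected}, \code{ratio},
#'   \code{ci_low}, \code{ci_high} (2.5/97.5 percent quantiles of the
#'   uniform-resample ratio).
#' @export
obs_exp_enrichment <- function(rloops, fmap, n_boot = 1000L, seed = 1L) {
  if (nrow(rloops) == 0L) stop("no R-loops to annotate")
  clen <- fmap$genome$chrom_sizes
  total_bp <- sum(clen)
  frac <- fmap$label_bp / total_bp
  classes <- sort(unique(rloops$rloop_class))
  out <- list()
  for (cl in classes) {
    r <- rloops[rloops$rloop_class == cl, , drop = FALSE]
    nc <- nrow(r)
    obs <- table(factor(assign_feature(r, fmap), levels = FEATURE_LABELS))
    expd <- nc * frac
    boot <- with_seed(seed, {
      sapply(seq_len(n_boot), function(b) {
        ch <- sample(names(clen), nc, replace = TRUE,
                     prob = clen / total_bp)
        mid <- as.integer(floor(stats::runif(nc) * clen[ch]))
        bt <- table(factor(assign_feature(
          data.frame(chrom = ch, start = mid, end = mid + 1L,
                     stringsAsFactors = FALSE), fmap),
          levels = FEATURE_LABELS))
        as.numeric(bt) / pmax(expd, .Machine$double.eps)
      })
    })
    ci <- apply(boot, 1L, stats::quantile, probs = c(0.025, 0.975))
    out[[cl]] <- data.frame(rloop_class = cl, feature = FEATURE_LABELS,
                            observed = as.integer(obs),
                            expected = as.numeric(expd),
                            ratio = ifelse(expd > 0, as.numeric(obs) / expd,
                                           NA_real_),
                            ci_low = ci[1L, ], ci_high = ci[2L, ],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

expressed_strata <- function(genes, floor_expr = 1) {
  eg <- genes[genes$expression > floor_expr, , drop = FALSE]
  if (nrow(eg) == 0L) stop("no expressed genes (expression > ", floor_expr, ")")
  br <- stats::quantile(eg$expression, c(1 / 3, 2 / 3), type = 1)
  eg$stratum <- cut(eg$expression, c(-Inf, br, Inf),
                    labels = c("low", "mid", "high"))
  eg
}

# gene span extended by the promoter and downstream windows: for either
# strand the union is [start-2500, end+2500) on the genome axis.
extended_span <- function(genes, clen, flank = 2500) {
  data.frame(chrom = genes$chrom,
             start = pmax(0, genes$start - flank),
             end = pmin(clen[genes$chrom], genes$end + flank))
}

#' Per-gene R-loop and factor-peak overlap by expression stratum
#'
#' Splits expressed genes (expression > 1, CPM-like) into low/mid/high
#' tertiles and flags each gene for >= 1 bp overlap of its extended span
#' (gene body plus promoter and downstream windows) with stranded R-loops,
#' unstranded R-loops, and an optional factor peak set (e.g. transcription
#' factor ChIP or Cut&Run peaks).
#'
#' @param genome A \code{genome_model}.
#' @param rloops Classified R-loop data frame.
#' @param factor_peaks Optional data frame (\code{chrom}, \code{start},
#'   \code{end}).
#' @return List with \code{genes} (per-gene table: \code{gene_id},
#'   \code{stratum}, \code{length}, \code{has_stranded},
#'   \code{has_unstranded}, \code{has_factor_peak}) and \code{proportions}
#'   (per-stratum means of the flags).
#' @export
overlap_gene_classes <- function(genome, rloops, factor_peaks = NULL) {
  eg <- expressed_strata(genome$genes)
  span <- extended_span(eg, genome$chrom_sizes)
  flag <- function(iv) {
    f <- logical(nrow(eg))
    if (!is.null(iv) && nrow(iv)) {
      hits <- overlap_pairs(span$chrom, span$start, span$end,
                            iv$chrom, iv$start, iv$end)
      if (nrow(hits)) f[unique(hits[, 1L])] <- TRUE
    }
    f
  }
  genes <- data.frame(gene_id = eg$gene_id, stratum = eg$stratum,
                      length = eg$end - eg$start,
                      has_stranded =
                        flag(rloops[rloops$rloop_class == "stranded", ]),
                      has_unstranded =
                        flag(rloops[rloops$rloop_class == "unstranded", ]),
                      has_factor_peak = flag(factor_peaks),
                      stringsAsFactors = FALSE)
  props <- do.call(rbind, lapply(split(genes, genes$stratum), function(d)
    data.frame(stratum = d$stratum[1L], n = nrow(d),
               prop_stranded = mean(d$has_stranded),
               prop_unstranded = mean(d$has_unstranded),
               prop_factor_peak = mean(d$has_factor_peak))))
  rownames(props) <- NULL
  list(genes = genes, proportions = props)
}

#' Gene length vs R-loop occupancy table
#'
#' For density plotting of gene lengths by R-loop occupancy: each expressed
#' gene is placed in exactly one set (\code{none}, \code{stranded_only},
#' \code{unstranded_only}, \code{both}) from its extended-span overlaps.
#'
#' @param genome A \code{genome_model}.
#' @param rloops Classified R-loop data frame.
#' @return List with \code{genes} (per-gene \code{gene_id}, \code{length},
#'   \code{stratum}, \code{rloop_set}) and \code{median_length} per set.
#' @export
gene_length_density <- function(genome, rloops) {
  ov <- overlap_gene_classes(genome, rloops)$genes
  ov$rloop_set <- ifelse(ov$has_stranded & ov$has_unstranded, "both",
                   ifelse(ov$has_stranded, "stranded_only",
                    ifelse(ov$has_unstranded, "unstranded_only", "none")))
  med <- tapply(ov$length, ov$rloop_set, stats::median)
  list(genes = ov[, c("gene_id", "length", "stratum", "rloop_set")],
       median_length = med)
}
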