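#' Construct a genome model
#'
#' A genome model bundles chromosome sizes with a gene table and is the
#' reference against which fragments, peaks and feature windows are
#' validated. All coordinates are 0-based half-open.
#'
#' @param chrom_sizes Named numeric/integer vector of chromosome lengths (bp).
#' @param genes Data frame with columns \code{gene_id}, \code{chrom},
#'   \code{strand} (\code{"+"}/\code{"-"}), \code{start}, \code{end},
#'   \code{biotype} (\code{protein_coding}, \code{pseudogene} or
#'   \code{other}) and \code{expression} (non-negative, CPM-like). May be
#'   empty.
#' @return An object of class \code{genome_model}.
#' @export
genome_model <- function(chrom_sizes, genes = NULL) {
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == ""))
    stop("chrom_sizes must be a named vector")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be positive")
  if (anyDuplicated(names(chrom_sizes)))
    stop("duplicate chromosome names")
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(0), chrom = character(0),
                        strand = character(0), start = integer(0),
                        end = integer(0), biotype = character(0),
                        expression = numeric(0), stringsAsFactors = FALSE)
  }
  req <- c("gene_id", "chrom", "strand", "start", "end", "biotype", "expression")
  if (!all(req %in% names(genes)))
    stop("genes is missing columns: ", paste(setdiff(req, names(genes)), collapse = ", "))
  genes <- genes[, req]
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ", genes$gene_id[anyDuplicated(genes$gene_id)][1L])
  if (nrow(genes)) {
    if (!all(genes$strand %in% c("+", "-")))
      stop("every gene needs strand '+' or '-'")
    if (!all(genes$chrom %in% names(chrom_sizes)))
      stop("gene chrom not in chrom_sizes: ",
           paste(unique(setdiff(genes$chrom, names(chrom_sizes))), collapse = ", "))
    bad <- genes$start < 0 | genes$start >= genes$end |
      genes$end > chrom_sizes[genes$chrom]
    if (any(bad))
      stop("gene coordinates out of bounds for: ",
           paste(utils::head(genes$gene_id[bad], 3L), collapse = ", "))
    genes$biotype <- ifelse(genes$biotype %in% c("protein_coding", "pseudogene"),
                            genes$biotype, "other")
    genes$expression[is.na(genes$expression)] <- 0
    if (any(genes$expression < 0)) stop("expression must be non-negative")
  }
  structure(list(chrom_sizes = chrom_sizes, genes = genes),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chrom_sizes), "chromosome(s),",
      sum(x$chrom_sizes), "bp,", nrow(x$genes), "gene(s)\n")
  invisible(x)
}

#' Construct a fragment set
#'
#' One sample's aligned, filtered ssDRIP fragments. Intervals are 0-based
#' half-open and every fragment carries a strand (the assay is
#' strand-resolved; strand is mandatory).
#'
#' @param sample_id Sample identifier.
#' @param condition \code{"DRIP"} (S9.6 immunoprecipitation) or
#'   \code{"RNASEH"} (RNase-H-treated negative control).
#' @param fragments Data frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand}.
#' @return An object of class \code{fragment_set}.
#' @export
fragment_set <- function(sample_id, condition, fragments) {
  condition <- match.arg(condition, c("DRIP", "RNASEH"))
  req <- c("chrom", "start", "end", "strand")
  if (!all(req %in% names(fragments)))
    stop("fragments is missing columns: ",
         paste(setdiff(req, names(fragments)), collapse = ", "))
  fragments <- fragments[, req]
  if (nrow(fragments)) {
    if (!all(fragments$strand %in% c("+", "-")))
      stop("fragment strand must be '+' or '-'")
    if (any(fragments$end <= fragments$start))
      stop("fragments must satisfy end > start")
    if (any(fragments$start < 0)) stop("negative fragment start")
  }
  structure(list(sample_id = sample_id, condition = condition,
                 fragments = fragments),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("fragment_set", x$sample_id, sprintf("[%s]:", x$condition),
      nrow(x$fragments), "fragments\n")
  invisible(x)
}

#' Validate a fragment set against a genome model
#'
#' Checks that every fragment lies on a known chromosome and within its
#' bounds. Kept separate from parsing so files can be inspected before a
#' genome is available.
#'
#' @param frags A \code{fragment_set}.
#' @param genome A \code{genome_model}.
#' @return \code{frags}, invisibly, on success; otherwise an error.
#' @export
validate_fragments <- function(frags, genome) {
  f <- frags$fragments
  if (nrow(f) == 0L) return(invisible(frags))
  unknown <- setdiff(unique(f$chrom), names(genome$chrom_sizes))
  if (length(unknown))
    stop("fragments on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  if (any(f$end > genome$chrom_sizes[f$chrom]))
    stop("fragment extends past chromosome end")
  invisible(frags)
}
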