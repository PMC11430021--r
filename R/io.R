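# Readers/writers for the plain-text genomic formats the pipeline touches.
# Single coordinate convention: 0-based half-open (BED) everywhere internally.

read_tsv_lines <- function(path, min_fields, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  if (length(bad))
    stop(sprintf("malformed %s line %d in %s: expected >= %d tab-separated fields, got %d",
                 what, bad[1L], path, min_fields, nf[bad[1L]]))
  fields
}

#' Read strand-split fragments from a BED6 file
#'
#' @param path BED6 file: chrom, start, end, name, score, strand. Strand must
#'   be \code{"+"} or \code{"-"}; ssDRIP fragments are strand-resolved by
#'   construction, so \code{"."} is rejected.
#' @param condition \code{"DRIP"} or \code{"RNASEH"}.
#' @param sample_id Sample label; defaults to the file name without extension.
#' @param blacklist Optional data frame (\code{chrom}, \code{start},
#'   \code{end}); fragments overlapping a blacklisted region by >= 1 bp are
#'   dropped at load.
#' @return A \code{fragment_set}. Input order is preserved.
#' @export
read_fragments <- function(path, condition, sample_id = NULL, blacklist = NULL) {
  fields <- read_tsv_lines(path, 6L, "BED6")
  if (length(fields) == 0L) {
    fr <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), strand = character(0),
                     stringsAsFactors = FALSE)
  } else {
    m <- do.call(rbind, lapply(fields, function(f) f[1:6]))
    strand <- m[, 6L]
    bad <- which(!strand %in% c("+", "-"))
    if (length(bad))
      stop(sprintf("line %d in %s: strand must be '+' or '-', got '%s'",
                   bad[1L], path, strand[bad[1L]]))
    start <- suppressWarnings(as.integer(m[, 2L]))
    end <- suppressWarnings(as.integer(m[, 3L]))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad))
      stop(sprintf("line %d in %s: non-integer coordinates", bad[1L], path))
    fr <- data.frame(chrom = m[, 1L], start = start, end = end,
                     strand = strand, stringsAsFactors = FALSE)
  }
  if (!is.null(blacklist) && nrow(fr)) {
    hits <- overlap_pairs(fr$chrom, fr$start, fr$end,
                          blacklist$chrom, blacklist$start, blacklist$end)
    if (nrow(hits)) fr <- fr[-unique(hits[, 1L]), , drop = FALSE]
    rownames(fr) <- NULL
  }
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  fragment_set(sample_id, condition, fr)
}

#' Read a gene annotation table
#'
#' @param path TSV with header columns \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{start}, \code{end}, \code{biotype},
#'   \code{expression}. Unknown biotypes map to \code{"other"}; missing
#'   expression maps to 0. Duplicate \code{gene_id} is an error.
#' @return Gene data frame (the \code{genes} slot of a genome model).
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  req <- c("gene_id", "chrom", "strand", "start", "end", "biotype", "expression")
  if (!all(req %in% names(g)))
    stop("gene table missing columns: ", paste(setdiff(req, names(g)), collapse = ", "))
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene_id in ", path, ": ",
         g$gene_id[anyDuplicated(g$gene_id)][1L])
  g$biotype <- ifelse(g$biotype %in% c("protein_coding", "pseudogene"),
                      g$biotype, "other")
  g$expression[is.na(g$expression)] <- 0
  g[, req]
}

#' Read a two-column chromosome-sizes table
#'
#' @param path TSV: chromosome name, length in bp. No header.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  fields <- read_tsv_lines(path, 2L, "chrom.sizes")
  if (length(fields) == 0L) stop("empty chrom sizes file: ", path)
  nm <- vapply(fields, `[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  if (any(is.na(len))) stop("non-numeric chromosome length in ", path)
  stats::setNames(len, nm)
}

#' Read a BED file of generic intervals
#'
#' @param path BED3+ file. Missing name/score/strand fields are filled with
#'   \code{"."}, 0 and \code{"."}.
#' @return Data frame with BED6 columns (\code{chrom}, \code{start},
#'   \code{end}, \code{name}, \code{score}, \code{strand}).
#' @export
read_bed <- function(path) {
  fields <- read_tsv_lines(path, 3L, "BED")
  if (length(fields) == 0L)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      name = character(0), score = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  pick <- function(i, default) vapply(fields, function(f)
    if (length(f) >= i) f[i] else default, "")
  data.frame(chrom = pick(1L, "."),
             start = as.integer(pick(2L, "0")),
             end = as.integer(pick(3L, "0")),
             name = pick(4L, "."),
             score = suppressWarnings(as.numeric(pick(5L, "0"))),
             strand = pick(6L, "."),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED6
#'
#' @param x Data frame with at least \code{chrom}, \code{start}, \code{end};
#'   optional \code{name}, \code{score}, \code{strand} (defaults \code{"."},
#'   0, \code{"."}).
#' @param path Output file.
#' @return \code{path}, invisibly. Write-then-read round-trips
#'   (chrom, start, end, strand, score) exactly.
#' @export
write_bed <- function(x, path) {
  name <- x$name %||% rep(".", nrow(x))
  score <- x$score %||% rep(0, nrow(x))
  strand <- x$strand %||% rep(".", nrow(x))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, as.integer(x$start),
                   as.integer(x$end), name, format(score, trim = TRUE,
                                                   scientific = FALSE),
                   strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write a binned track as bedGraph
#'
#' Adjacent equal-valued bins are merged into one record (run-length
#' encoding). The trailing bin is clipped to the chromosome length when a
#' genome is supplied.
#'
#' @param track Named list: chromosome -> numeric vector of per-bin values.
#' @param path Output file.
#' @param bin_width Bin width in bp.
#' @param genome Optional \code{genome_model} used to clip the last bin.
#' @param keep_zeros Emit zero-valued records (default \code{FALSE}: zero
#'   bins are dropped).
#' @return \code{path}, invisibly.
#' @export
write_bedgraph <- function(track, path, bin_width, genome = NULL,
                           keep_zeros = FALSE) {
  if (bin_width <= 0) stop("bin_width must be positive")
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track)) {
    v <- track[[ch]]
    if (length(v) == 0L) next
    if (any(!is.finite(v))) stop("non-finite value in track for ", ch)
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts <- (ends_bin - r$lengths) * bin_width
    ends <- ends_bin * bin_width
    if (!is.null(genome) && ch %in% names(genome$chrom_sizes))
      ends <- pmin(ends, genome$chrom_sizes[[ch]])
    keep <- if (keep_zeros) rep(TRUE, length(r$values)) else r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, as.integer(starts[keep]),
                       as.integer(ends[keep]),
                       format(r$values[keep], trim = TRUE, scientific = FALSE)),
               con)
  }
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph file (chrom, start, end, value); track lines and
#'   comments are skipped.
#' @return A \code{signal_track}: named list chromosome -> data frame
#'   (\code{start}, \code{end}, \code{value}) sorted by start, intervals
#'   non-overlapping.
#' @export
read_signal_track <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^(track|#|browser)", lines)]
  if (length(lines) == 0L) stop("empty bedGraph: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop(sprintf("malformed bedGraph line %d in %s", which(nf < 4L)[1L], path))
  m <- do.call(rbind, fields)
  df <- data.frame(chrom = m[, 1L], start = as.integer(m[, 2L]),
                   end = as.integer(m[, 3L]), value = as.numeric(m[, 4L]),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$value))) stop("non-finite value in ", path)
  out <- lapply(split(df[, c("start", "end", "value")], df$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (any(d$end[-nrow(d)] > d$start[-1L]))
      stop("overlapping bedGraph intervals in ", path)
    rownames(d) <- NULL
    d
  })
  structure(out, class = "signal_track")
}

#' Write a generic data frame as TSV with header
#' @param x Data frame.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
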