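# Protein-set overlap enrichment: 2x2 contingency table over a stated
# universe, tested with the Fisher exact (hypergeometric tail) test in log
# space so it stays finite for universes up to ~1e6.

#' Build a 2x2 contingency table from two id sets and a universe
#'
#' a = in both sets, b = set1 only, c = set2 only, d = in neither. Ids are
#' deduplicated; members outside the universe are dropped with a warning.
#'
#' @param set1,set2 Character vectors of ids.
#' @param universe Character vector of all eligible ids (non-empty).
#' @return A \code{contingency_table} list with \code{a}, \code{b}, \code{c},
#'   \code{d} and \code{n}.
#' @export
build_table <- function(set1, set2, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  set1 <- unique(set1); set2 <- unique(set2)
  out1 <- setdiff(set1, universe); out2 <- setdiff(set2, universe)
  if (length(out1) || length(out2))
    warning(length(out1) + length(out2),
            " id(s) outside the universe dropped")
  set1 <- intersect(set1, universe); set2 <- intersect(set2, universe)
  a <- length(intersect(set1, set2))
  b <- length(setdiff(set1, set2))
  cc <- length(setdiff(set2, set1))
  d <- length(universe) - a - b - cc
  structure(list(a = a, b = b, c = cc, d = d, n = length(universe)),
            class = "contingency_table")
}

#' Fisher exact test for set enrichment
#'
#' One-sided (\code{greater}, the default: is the overlap a larger than
#' expected?) via the hypergeometric upper tail, or two-sided by summing the
#' probabilities of all tables at the observed margins no more likely than
#' the observed one. Computed in log space; exact and finite for universes up
#' to at least 1e6.
#'
#' @param t A \code{contingency_table} or list with \code{a}, \code{b},
#'   \code{c}, \code{d}.
#' @param alternative \code{"greater"} (default) or \code{"two_sided"}.
#' @return The p-value.
#' @export
fisher_enrichment <- function(t, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  a <- t$a; b <- t$b; cc <- t$c; d <- t$d
  if (any(c(a, b, cc, d) < 0)) stop("counts must be non-negative")
  n <- a + b + cc + d
  if (n == 0) stop("empty table")
  K <- a + b      # size of set1
  k <- a + cc     # size of set2 (number drawn)
  if (alternative == "greater")
    return(stats::phyper(a - 1, K, n - K, k, lower.tail = FALSE))
  support <- max(0, k - (n - K)):min(K, k)
  logp <- stats::dhyper(support, K, n - K, k, log = TRUE)
  obs <- stats::dhyper(a, K, n - K, k, log = TRUE)
  sum(exp(logp[logp <= obs + 1e-7]))
}

#' Run the protein-set enrichment from id-list files
#'
#' @param set1_path,set2_path,universe_path Plain-text files, one id per line.
#' @param alternative Passed to \code{\link{fisher_enrichment}}.
#' @return Data frame with the table counts, odds ratio and p-value.
#' @export
set_enrichment_report <- function(set1_path, set2_path, universe_path,
                                  alternative = "greater") {
  read_ids <- function(p) {
    x <- readLines(p, warn = FALSE)
    x[nzchar(x)]
  }
  tab <- build_table(read_ids(set1_path), read_ids(set2_path),
                     read_ids(universe_path))
  or <- (tab$a * tab$d) / max(tab$b * tab$c, .Machine$double.eps)
  data.frame(a = tab$a, b = tab$b, c = tab$c, d = tab$d, n = tab$n,
             odds_ratio = or,
             p_value = fisher_enrichment(tab, alternative),
             alternative = alternative, stringsAsFactors = FALSE)
}
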