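# Shared fixtures and independent oracles, built in code at test time.

# Small, fast cohort config for module tests (full spec scale lives in
# test-acceptance.R).
small_cfg <- function(seed = 1L, ...) {
  args <- list(genome = c(chr1 = 5e5), n_genes = 40L, n_stranded = 10L,
               n_unstranded = 10L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

tiny_genome <- function(len = 1e5, genes = NULL) {
  genome_model(c(chr1 = len), genes)
}

make_frag_set <- function(chrom, start, end, strand, condition = "DRIP",
                          sample_id = "s1") {
  fragment_set(sample_id, condition,
               data.frame(chrom = chrom, start = as.integer(start),
                          end = as.integer(end), strand = strand,
                          stringsAsFactors = FALSE))
}

write_tmp_lines <- function(lines, ext = ".bed") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# ---- independent oracles ----

# Poisson upper tail by direct term summation of the tail itself (no
# 1-minus-lower-sum cancellation): P(X >= t) = sum_{k>=t} e^-l l^k / k!.
poisson_sf_oracle <- function(t, lambda) {
  if (t == 0) return(1)
  if (lambda == 0) return(0)
  k <- t:(t + 2000L)
  terms <- exp(-lambda + k * log(lambda) - lgamma(k + 1))
  sum(terms)
}

# Naive O(m^2) Benjamini-Hochberg: q_i = min over j with p_j >= p_i of
# p_j * m / rank_j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    cand <- p * m / r
    min(1, min(cand[p >= p[i]]))
  }, 0)
}

# Fisher greater-tail by full enumeration of the hypergeometric support.
fisher_oracle <- function(a, b, cc, d) {
  n <- a + b + cc + d
  K <- a + b
  k <- a + cc
  support <- max(0, k - (n - K)):min(K, k)
  probs <- choose(K, support) * choose(n - K, k - support) / choose(n, k)
  sum(probs[support >= a])
}

# Random piecewise-constant track with gaps (implicit zeros) on one chrom.
rand_track <- function(len, n, seed = 1) {
  set.seed(seed)
  edges <- sort(sample.int(len - 1L, n))
  starts <- c(0L, edges)
  ends <- c(edges, as.integer(len))
  keep <- runif(n + 1) < 0.7
  structure(list(chr1 = data.frame(start = starts, end = ends,
                                   value = round(runif(n + 1), 3))[keep, ]),
            class = "signal_track")
}

# Per-base metaprofile oracle: expand the track to one value per base and
# average bases per bin.
signal_matrix_oracle <- function(track, centers, flank, n_bins) {
  bw <- 2 * flank / n_bins
  out <- matrix(0, nrow(centers), n_bins)
  for (i in seq_len(nrow(centers))) {
    d <- track[[centers$chrom[i]]]
    mid <- (centers$start[i] + centers$end[i]) / 2
    base_val <- function(x) {           # value at base [x, x+1)
      if (is.null(d)) return(0)
      j <- which(d$start <= x & x < d$end)
      if (length(j)) d$value[j[1L]] else 0
    }
    for (b in seq_len(n_bins)) {
      lo <- mid - flank + (b - 1) * bw
      xs <- seq(lo, lo + bw - 1)
      out[i, b] <- mean(vapply(xs, base_val, 0))
    }
  }
  out
}

# Truth-vs-called matching: for each truth interval, the class/strand of an
# overlapping call (NA when unrecovered).
match_truth <- function(truth, rloops) {
  cls <- rep(NA_character_, nrow(truth))
  strnd <- rep(NA_character_, nrow(truth))
  if (nrow(rloops)) {
    hits <- ssdripr:::overlap_pairs(truth$chrom, truth$start, truth$end,
                                    rloops$chrom, rloops$start, rloops$end)
    for (k in seq_len(nrow(hits))) {
      cls[hits[k, 1L]] <- rloops$rloop_class[hits[k, 2L]]
      strnd[hits[k, 1L]] <- rloops$strand[hits[k, 2L]]
    }
  }
  data.frame(true_class = truth$true_class, true_strand = truth$true_strand,
             called_class = cls, called_strand = strnd,
             stringsAsFactors = FALSE)
}
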