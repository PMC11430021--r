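# Helper: a one-peak data frame overlapping [1000, 2000) on chr1, with a
# given q and mode, or an empty peak table.
peak_at <- function(q = 1e-5, mode = "narrow", start = 1000L, end = 2000L,
                    strand = ".") {
  data.frame(chrom = "chr1", start = start, end = end, strand = strand,
             summit = 100L, max_fold = 5, p = q / 10, q = q, mode = mode,
             stringsAsFactors = FALSE)
}
no_peak <- function() peak_at()[0, ]

test_that("consensus retention: exhaustive 2^4 support patterns x modes", {
  for (mode in c("narrow", "broad")) {
    for (pattern in 0:15) {
      has <- as.logical(bitwAnd(pattern, c(1L, 2L, 4L, 8L)) > 0)
      per_sample <- lapply(has, function(h)
        if (h) peak_at(mode = mode) else no_peak())
      cons <- consensus_rloops(per_sample, min_support = 3L, q_max = 0.001)
      expected <- sum(has) >= 3L   # brute-force oracle
      expect_identical(nrow(cons) == 1L, expected,
                       info = sprintf("mode=%s pattern=%d", mode, pattern))
      if (expected)
        expect_identical(cons$n_supporting_samples, sum(has))
    }
  }
})

test_that("consensus respects the q filter and min_support boundary", {
  # qualifying peaks in samples 1-3, none in 4 -> retained with support 3
  cons <- consensus_rloops(list(peak_at(), peak_at(), peak_at(), no_peak()))
  expect_identical(nrow(cons), 1L)
  expect_identical(cons$n_supporting_samples, 3L)
  expect_equal(cons$best_q, 1e-5)

  # q above the cutoff does not count as support
  cons2 <- consensus_rloops(list(peak_at(), peak_at(), peak_at(q = 0.01),
                                 no_peak()))
  expect_identical(nrow(cons2), 0L)

  # support from only 2 samples -> dropped
  expect_identical(nrow(consensus_rloops(list(peak_at(), peak_at(), no_peak(),
                                              no_peak()))), 0L)

  expect_error(consensus_rloops(list(peak_at(), peak_at()), min_support = 3L),
               "min_support")
})

test_that("raising min_support never increases the consensus count", {
  set.seed(13)
  per_sample <- lapply(1:5, function(i) {
    n <- sample(3:8, 1)
    s <- sort(sample.int(50000L, n)) * 10L
    data.frame(chrom = "chr1", start = s, end = s + sample(200:2000, n, TRUE),
               strand = ".", summit = 0L, max_fold = 2,
               p = 1e-6, q = 10^-runif(n, 2, 8), mode = "narrow",
               stringsAsFactors = FALSE)
  })
  counts <- vapply(1:5, function(ms)
    nrow(consensus_rloops(per_sample, min_support = ms)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("classification follows the per-strand consensus and tie rules", {
  cons <- consensus_rloops(list(peak_at(), peak_at(), peak_at(), peak_at()))
  plus3 <- list(peak_at(strand = "+"), peak_at(strand = "+"),
                peak_at(strand = "+"), no_peak())
  minus3 <- lapply(plus3, function(p) { p$strand[p$strand == "+"] <- "-"; p })
  both <- Map(rbind, plus3, minus3)

  got <- classify_strandedness(cons, plus3)
  expect_identical(got$rloop_class, "stranded")
  expect_identical(got$strand, "+")
  expect_identical(got$n_support_plus, 3L)

  got_m <- classify_strandedness(cons, minus3)
  expect_identical(got_m$strand, "-")

  # no qualifying strand peak -> unstranded, NA strand
  got_u <- classify_strandedness(cons, list(no_peak(), no_peak(), no_peak(),
                                            no_peak()))
  expect_identical(got_u$rloop_class, "unstranded")
  expect_true(is.na(got_u$strand))

  # both strands qualify independently -> tie rule: unstranded
  got_b <- classify_strandedness(cons, both)
  expect_identical(got_b$rloop_class, "unstranded")
  expect_true(is.na(got_b$strand))

  # partition: one class per loop, strand iff stranded
  for (g in list(got, got_m, got_u, got_b)) {
    expect_identical(nrow(g), nrow(cons))
    expect_identical(is.na(g$strand), g$rloop_class == "unstranded")
  }
})

test_that("call_strand_enrichment contracts", {
  gm <- tiny_genome(1e5)
  ctl <- make_frag_set("chr1", 0, 100, "+", condition = "RNASEH")
  expect_error(call_strand_enrichment(ctl, gm), "DRIP")

  # all fragments on + in a region, sparse balanced elsewhere
  set.seed(3)
  bg_start <- sort(sample.int(9e4, 400))
  region_start <- sample(50000:50800, 150, replace = TRUE)
  f <- data.frame(chrom = "chr1",
                  start = c(bg_start, region_start),
                  end = c(bg_start, region_start) + 200L,
                  strand = c(rep(c("+", "-"), 200), rep("+", 150)),
                  stringsAsFactors = FALSE)
  s <- fragment_set("d", "DRIP", f)
  pk <- call_strand_enrichment(s, gm)
  plus <- pk[pk$strand == "+", ]
  minus <- pk[pk$strand == "-", ]
  hits <- ssdripr:::overlap_pairs("chr1", 50000L, 51000L,
                                  plus$chrom, plus$start, plus$end)
  expect_gt(nrow(hits), 0)
  expect_true(all(plus$q[hits[, 2]] < 0.001))
  if (nrow(minus))
    expect_identical(nrow(ssdripr:::overlap_pairs("chr1", 50000L, 51000L,
                                                  minus$chrom, minus$start,
                                                  minus$end)), 0L)

  # one strand entirely empty -> warns, still runs
  plus_only <- fragment_set("p", "DRIP",
                            data.frame(chrom = "chr1", start = bg_start,
                                       end = bg_start + 200L, strand = "+"))
  expect_warning(call_strand_enrichment(plus_only, gm), "no fragments")
})

test_that("stranded loops are recovered with the right strand on a small cohort", {
  cfg <- small_cfg(seed = 51)
  co <- simulate_cohort(cfg)
  drip <- co$samples[1:4]
  ctl <- co$samples[5:8]
  pk <- lapply(drip, call_peaks, controls = ctl, genome = co$genome)
  sp <- lapply(drip, call_strand_enrichment, genome = co$genome)
  rl <- classify_strandedness(consensus_rloops(pk), sp)
  expect_identical(sum(rl$rloop_class == "stranded") +
                     sum(rl$rloop_class == "unstranded"), nrow(rl))
  m <- match_truth(co$truth, rl)
  rec <- !is.na(m$called_class)
  expect_gte(mean(rec), 0.9)
  s <- m$true_class == "stranded" & rec & m$called_class == "stranded"
  expect_gte(mean(m$called_strand[s] == m$true_strand[s]), 0.9)
})
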