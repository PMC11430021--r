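test_that("poisson_sf matches direct term summation and is monotone", {
  expect_identical(poisson_sf(0, 2.3), 1)
  expect_equal(poisson_sf(5, 1.0), 0.003659847, tolerance = 1e-7)
  expect_equal(poisson_sf(5, 1.0), poisson_sf_oracle(5, 1.0), tolerance = 1e-12)
  expect_equal(poisson_sf(10, 10), 0.5420703, tolerance = 1e-6)
  expect_equal(poisson_sf(10, 10), poisson_sf_oracle(10, 10), tolerance = 1e-12)
  expect_error(poisson_sf(3, -1), "lambda")
  expect_error(poisson_sf(2.5, 1), "integer")

  for (lam in c(0.1, 1, 7, 30)) {
    p_t <- poisson_sf(0:40, lam)
    expect_true(all(diff(p_t) <= 1e-15), info = paste("lambda", lam))
  }
  for (t in c(0L, 3L, 17L)) {
    p_l <- poisson_sf(rep(t, 50), seq(0.01, 25, length.out = 50))
    expect_true(all(diff(p_l) >= -1e-15), info = paste("t", t))
  }
})

test_that("bh_qvalues matches the naive O(m^2) step-up definition", {
  expect_identical(bh_qvalues(0.05), 0.05)
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(7)
  for (rep in 1:50) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)
    expect_equal(bh_qvalues(p), bh_oracle(p), tolerance = 1e-12,
                 info = paste("rep", rep))
  }
})

test_that("local_lambda takes the max of nested window rates plus pseudocount", {
  gm <- tiny_genome(1e5)
  params <- caller_params(pseudocount = 0)
  # constructed control: 1000 bases in the 1 kb window, 2000 in 5 kb,
  # 3000 in 10 kb, 20000 genome-wide, mean fragment length 100
  frag100 <- function(starts) data.frame(chrom = "chr1", start = starts,
                                         end = starts + 100L)
  ctrl <- rbind(frag100(49500L + (0:9) * 100L),
                frag100(47500L + (0:9) * 100L),
                frag100(45000L + (0:9) * 100L),
                frag100((0:169) * 100L))
  region <- list(chrom = "chr1", start = 49900L, end = 50100L)
  expect_equal(local_lambda(region, ctrl, gm, params, depth_ratio = 1,
                            mean_frag_len = 100), 2.0, tolerance = 1e-12)

  # uniform control: all window rates equal v -> lambda = v*w*r + pseudocount
  uni <- frag100((0:999) * 100L)
  p2 <- caller_params(pseudocount = 0.5)
  expect_equal(local_lambda(region, uni, gm, p2, depth_ratio = 2,
                            mean_frag_len = 100),
               0.01 * 200 * 2 + 0.5, tolerance = 1e-9)

  none <- ctrl[0, ]
  expect_equal(local_lambda(region, none, gm, p2, depth_ratio = 1), 0.5)
  expect_error(local_lambda(region, none, gm, params, depth_ratio = 1),
               "pseudocount 0")
  expect_error(local_lambda(region, uni, gm, p2, depth_ratio = 0),
               "depth_ratio")
})

test_that("call_peaks input contracts", {
  tiny <- genome_model(c(chr1 = 100))
  tr <- make_frag_set("chr1", 0, 50, "+")
  expect_error(call_peaks(tr, tr, tiny), "shorter than the test window")

  gm <- tiny_genome(1e5)
  empty <- fragment_set("e", "DRIP",
                        data.frame(chrom = character(0), start = integer(0),
                                   end = integer(0), strand = character(0)))
  ctl <- make_frag_set("chr1", 1000, 1200, "+", condition = "RNASEH")
  expect_warning(pk <- call_peaks(empty, ctl, gm), "empty treatment")
  expect_identical(nrow(pk), 0L)
})

test_that("an enriched cluster is called with a small q against merged controls", {
  cfg <- small_cfg(seed = 31)
  co <- simulate_cohort(cfg)
  pk <- call_peaks(co$samples[[1]], co$samples[5:8], co$genome)
  expect_true(all(pk$q >= pk$p))
  expect_true(all(pk$end > pk$start))
  expect_true(all(pk$mode %in% c("narrow", "broad")))
  tr <- co$truth
  hits <- ssdripr:::overlap_pairs(tr$chrom, tr$start, tr$end,
                                  pk$chrom, pk$start, pk$end)
  recall <- length(unique(hits[, 1])) / nrow(tr)
  expect_gte(recall, 0.9)
  # summit lies inside each peak
  expect_true(all(pk$summit >= 0 & pk$summit <= pk$end - pk$start))
})

test_that("treatment-equals-control yields ~no significant peaks", {
  for (seed in c(41, 42, 43)) {
    cfg <- sim_config(genome = c(chr1 = 3e5), n_genes = 0L, n_stranded = 0L,
                      n_unstranded = 0L, seed = seed)
    gm <- make_genome(cfg)
    s <- simulate_fragments(gm, NULL, cfg, "DRIP")
    pk <- call_peaks(s, s, gm)
    covered <- if (nrow(pk)) {
      mi <- ssdripr:::merge_intervals(pk$chrom, pk$start, pk$end)
      sum(mi$end - mi$start)
    } else 0
    expect_lt(covered / 3e5, 2 * 0.10, label = paste("seed", seed))
  }
})

test_that("window linking is idempotent", {
  # already-linked peaks, re-linked as windows, stay identical
  pk <- data.frame(start = c(100L, 1000L, 5000L), end = c(400L, 1400L, 5600L))
  relink <- ssdripr:::link_windows("chr1", pk$start, pk$end,
                                   p = rep(1e-5, 3), q = rep(1e-4, 3),
                                   fold = c(2, 3, 4), link_gap = 200L,
                                   min_peak_len = 200L)
  expect_identical(relink$start, pk$start)
  expect_identical(relink$end, pk$end)
  # gap 0 (touching) always merges
  touch <- ssdripr:::link_windows("chr1", c(0L, 300L), c(300L, 500L),
                                  p = c(1e-5, 1e-6), q = c(1e-4, 1e-5),
                                  fold = c(2, 5), link_gap = 0L,
                                  min_peak_len = 100L)
  expect_identical(nrow(touch), 1L)
  expect_identical(touch$end, 500L)
  expect_equal(touch$q, 1e-5)
})

test_that("caller params are validated", {
  expect_error(caller_params(window = 0))
  expect_error(caller_params(window = 200, step = 130))
  expect_error(caller_params(q_narrow = 0))
})
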