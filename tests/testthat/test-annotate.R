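gene_row <- function(id, chrom, strand, start, end,
                     biotype = "protein_coding", expression = 5) {
  data.frame(gene_id = id, chrom = chrom, strand = strand, start = start,
             end = end, biotype = biotype, expression = expression,
             stringsAsFactors = FALSE)
}

part_of <- function(fmap, label) {
  p <- fmap$partition
  out <- p[p$label == label, c("start", "end")]
  rownames(out) <- NULL
  out
}

test_that("feature windows follow the oriented promoter/downstream definitions", {
  # raw windows: promoter [TSS-2500, TSS+500), downstream [end-500, end+2500);
  # in the partition the gene body outranks the downstream window
  gm <- genome_model(c(chr1 = 5e4),
                     gene_row("g1", "chr1", "+", 10000L, 20000L))
  fmap <- build_feature_map(gm)
  expect_equal(part_of(fmap, "promoter_tss"),
               data.frame(start = 7500L, end = 10500L))
  expect_equal(part_of(fmap, "downstream_tts"),
               data.frame(start = 20000L, end = 22500L))
  expect_equal(part_of(fmap, "intron"),
               data.frame(start = 10500L, end = 20000L))

  # minus-strand gene: promoter extends rightward of the right end
  gm2 <- genome_model(c(chr1 = 5e4),
                      gene_row("g1", "chr1", "-", 5000L, 8000L))
  fmap2 <- build_feature_map(gm2)
  expect_equal(part_of(fmap2, "promoter_tss"),
               data.frame(start = 7500L, end = 10500L))
  expect_equal(part_of(fmap2, "downstream_tts"),
               data.frame(start = 2500L, end = 5000L))

  # windows clip at chromosome boundaries instead of erroring
  gm3 <- genome_model(c(chr1 = 21000),
                      gene_row("g1", "chr1", "+", 1000L, 20000L))
  fmap3 <- build_feature_map(gm3)
  expect_equal(part_of(fmap3, "promoter_tss"),
               data.frame(start = 0L, end = 1500L))
  expect_equal(part_of(fmap3, "downstream_tts"),
               data.frame(start = 20000L, end = 21000L))
})

test_that("the partition covers the genome disjointly and mirrors under strand flip", {
  cfg <- small_cfg(seed = 61)
  gm <- make_genome(cfg)
  fmap <- build_feature_map(gm)
  p <- fmap$partition
  expect_equal(sum(p$end - p$start), sum(gm$chrom_sizes))
  expect_equal(sum(fmap$label_bp), sum(gm$chrom_sizes))
  o <- p[order(p$chrom, p$start), ]
  for (ch in unique(o$chrom)) {
    d <- o[o$chrom == ch, ]
    expect_identical(d$start[-1], d$end[-nrow(d)])   # no gaps, no overlaps
  }

  # mirror: reverse coordinates and strands -> mirrored partition
  L <- gm$chrom_sizes
  mg <- gm$genes
  mirrored <- genome_model(L, data.frame(
    gene_id = mg$gene_id, chrom = mg$chrom,
    strand = ifelse(mg$strand == "+", "-", "+"),
    start = as.integer(L[mg$chrom] - mg$end),
    end = as.integer(L[mg$chrom] - mg$start),
    biotype = mg$biotype, expression = mg$expression))
  fmir <- build_feature_map(mirrored)
  pm <- fmir$partition
  pm2 <- data.frame(chrom = pm$chrom,
                    start = as.integer(L[pm$chrom] - pm$end),
                    end = as.integer(L[pm$chrom] - pm$start),
                    label = pm$label, stringsAsFactors = FALSE)
  pm2 <- pm2[order(pm2$chrom, pm2$start), ]
  rownames(pm2) <- NULL
  expect_identical(pm2, p)
})

test_that("assign_feature labels midpoints with priority fallback to intergenic", {
  gm <- genome_model(c(chr1 = 5e4),
                     gene_row("g1", "chr1", "+", 10000L, 20000L))
  fmap <- build_feature_map(gm)
  regions <- data.frame(chrom = "chr1",
                        start = c(9000L, 15000L, 21000L, 40000L),
                        end = c(9200L, 15400L, 21200L, 40100L))
  expect_identical(assign_feature(regions, fmap),
                   c("promoter_tss", "intron", "downstream_tts", "intergenic"))
  expect_identical(assign_feature(regions[0, ], fmap), character(0))
})

test_that("obs/exp enrichment matches independent arithmetic", {
  gm <- genome_model(c(chr1 = 5e4),
                     gene_row("g1", "chr1", "+", 10000L, 20000L))
  fmap <- build_feature_map(gm)
  # 10 loops of one class: 4 with midpoints in the 3 kb promoter window
  mids <- c(8000, 9000, 9500, 10400, rep(30000, 6))
  rl <- data.frame(chrom = "chr1", start = mids - 50, end = mids + 50,
                   rloop_class = "stranded", stringsAsFactors = FALSE)
  enr <- obs_exp_enrichment(rl, fmap, n_boot = 50, seed = 1)
  prom <- enr[enr$feature == "promoter_tss", ]
  expect_identical(prom$observed, 4L)
  expect_equal(prom$expected, 10 * 3000 / 5e4)   # n_c * genome fraction
  expect_equal(prom$ratio, 4 / (10 * 3000 / 5e4))
  expect_identical(enr[enr$feature == "downstream_tts", "observed"], 0L)
  expect_equal(enr[enr$feature == "downstream_tts", "ratio"], 0)
  # observed counts sum to the class size (midpoint = single label)
  expect_identical(sum(enr$observed), nrow(rl))
})

test_that("a featureless genome gives ratio 1 for intergenic", {
  gm <- tiny_genome(1e5)
  fmap <- build_feature_map(gm)
  rl <- data.frame(chrom = "chr1", start = c(100L, 50000L), end = c(300L, 50200L),
                   rloop_class = "unstranded", stringsAsFactors = FALSE)
  enr <- obs_exp_enrichment(rl, fmap, n_boot = 20, seed = 1)
  expect_equal(enr[enr$feature == "intergenic", "ratio"], 1)
})

test_that("uniform midpoints are calibrated (smoke version)", {
  cfg <- small_cfg(seed = 62)
  gm <- make_genome(cfg)
  fmap <- build_feature_map(gm)
  set.seed(1)
  mids <- sort(sample.int(5e5 - 1L, 500))
  rl <- data.frame(chrom = "chr1", start = mids, end = mids + 1L,
                   rloop_class = "unstranded", stringsAsFactors = FALSE)
  enr <- obs_exp_enrichment(rl, fmap, n_boot = 300, seed = 2)
  big <- enr[enr$expected >= 5, ]
  expect_true(all(big$ci_low <= 1 & 1 <= big$ci_high))
})

test_that("overlap_gene_classes flags and stratifies genes", {
  genes <- do.call(rbind, lapply(1:9, function(i)
    gene_row(paste0("g", i), "chr1", "+", i * 20000L, i * 20000L + 5000L,
             expression = i * 2)))
  gm <- genome_model(c(chr1 = 2e6), genes)
  # one stranded loop on gene 1 only (inside its body)
  rl <- data.frame(chrom = "chr1", start = 21000L, end = 21500L,
                   rloop_class = "stranded", strand = "+",
                   stringsAsFactors = FALSE)
  ov <- overlap_gene_classes(gm, rl)
  expect_identical(table(ov$genes$stratum)[["low"]], 3L)
  expect_identical(table(ov$genes$stratum)[["mid"]], 3L)
  expect_identical(table(ov$genes$stratum)[["high"]], 3L)
  g1 <- ov$genes[ov$genes$gene_id == "g1", ]
  expect_true(g1$has_stranded)
  expect_false(g1$has_unstranded)
  expect_false(g1$has_factor_peak)
  expect_true(all(!ov$genes$has_stranded[ov$genes$gene_id != "g1"]))

  # the extended span includes the 2.5 kb promoter/downstream flanks
  rl2 <- data.frame(chrom = "chr1", start = 17800L, end = 17900L,
                    rloop_class = "unstranded", strand = NA,
                    stringsAsFactors = FALSE)
  ov2 <- overlap_gene_classes(gm, rl2)
  expect_true(ov2$genes$has_unstranded[ov2$genes$gene_id == "g1"])

  silent <- genes; silent$expression <- 0.5
  expect_error(overlap_gene_classes(genome_model(c(chr1 = 2e6), silent), rl),
               "no expressed genes")
})

test_that("gene_length_density partitions genes into the four occupancy sets", {
  cfg <- small_cfg(seed = 63)
  co <- simulate_cohort(cfg)
  truth_as_calls <- data.frame(chrom = co$truth$chrom, start = co$truth$start,
                               end = co$truth$end,
                               rloop_class = co$truth$true_class,
                               stringsAsFactors = FALSE)
  gl <- gene_length_density(co$genome, truth_as_calls)
  expect_true(all(gl$genes$rloop_set %in%
                    c("none", "stranded_only", "unstranded_only", "both")))
  expect_identical(nrow(gl$genes),
                   sum(co$genome$genes$expression > 1))

  none_call <- truth_as_calls[0, ]
  gl0 <- gene_length_density(co$genome, none_call)
  expect_true(all(gl0$genes$rloop_set == "none"))
})

test_that("long_genes bias shows up as longer R-loop-bearing genes", {
  cfg <- small_cfg(seed = 64, placement_bias = "long_genes")
  genome <- make_genome(cfg)
  truth <- plant_rloops(genome, cfg)
  calls <- data.frame(chrom = truth$chrom, start = truth$start,
                      end = truth$end, rloop_class = truth$true_class,
                      stringsAsFactors = FALSE)
  gl <- gene_length_density(genome, calls)
  med <- tapply(gl$genes$length, gl$genes$rloop_set != "none", median)
  expect_gt(med[["TRUE"]], med[["FALSE"]])
})

test_that("tss/tts bias places stranded loops at promoters, unstranded downstream", {
  cfg <- small_cfg(seed = 65, placement_bias = "tss_stranded_tts_unstranded",
                   n_stranded = 30L, n_unstranded = 30L)
  genome <- make_genome(cfg)
  truth <- plant_rloops(genome, cfg)
  fmap <- build_feature_map(genome)
  lab <- assign_feature(truth, fmap)
  prom_s <- mean(lab[truth$true_class == "stranded"] == "promoter_tss")
  prom_u <- mean(lab[truth$true_class == "unstranded"] == "promoter_tss")
  down_s <- mean(lab[truth$true_class == "stranded"] == "downstream_tts")
  down_u <- mean(lab[truth$true_class == "unstranded"] == "downstream_tts")
  expect_gt(prom_s, prom_u)
  expect_gt(down_u, down_s)
})
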