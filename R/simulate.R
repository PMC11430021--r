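# Synthetic ssDRIP-seq cohorts with planted ground truth. The generator
# emulates the assay's stated world: 4 DRIP replicates + 4 RNase-H controls,
# ~250 bp mean fragment length, stranded R-loops (signal on one strand) and
# unstranded R-loops (balanced signal on both strands), uniform background
# identical in DRIP and control samples.

#' Simulation configuration
#'
#' @param genome Named vector of chromosome lengths; default two 2.5 Mb
#'   chromosomes (5 Mb desk-scale genome).
#' @param n_genes Number of non-overlapping genes to place (default 200).
#' @param n_stranded,n_unstranded Planted R-loops per class (default 50/50).
#' @param fold Total in-loop enrichment of DRIP coverage over background
#'   (default 10); must be > 1 for non-null cohorts, exactly 1 gives a null
#'   cohort with background only.
#' @param background_rate Background fragments per bp per strand
#'   (default 0.02, i.e. ~2e5 fragments per sample on 5 Mb).
#' @param frag_len_mean,frag_len_sd Fragment length Normal parameters
#'   (default 250/50 bp, truncated to [50, 2*mean]).
#' @param rloop_len_min,rloop_len_max Planted loop lengths, drawn uniformly
#'   (default 500-2000 bp).
#' @param n_reps,n_controls DRIP replicates and RNase-H controls (default 4/4).
#' @param seed Integer master seed; sample i uses seed + i*10007.
#' @param placement_bias \code{"none"}, \code{"tss_stranded_tts_unstranded"}
#'   (stranded loops near gene starts, unstranded downstream of gene ends) or
#'   \code{"long_genes"} (loops prefer the longest gene tertile).
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(genome = c(chr1 = 2.5e6, chr2 = 2.5e6),
                       n_genes = 200L,
                       n_stranded = 50L, n_unstranded = 50L,
                       fold = 10,
                       background_rate = 0.02,
                       frag_len_mean = 250, frag_len_sd = 50,
                       rloop_len_min = 500L, rloop_len_max = 2000L,
                       n_reps = 4L, n_controls = 4L,
                       seed = 1L,
                       placement_bias = c("none", "tss_stranded_tts_unstranded",
                                          "long_genes")) {
  placement_bias <- match.arg(placement_bias)
  stopifnot(length(genome) >= 1L, all(genome > 0),
            n_genes >= 0L, n_stranded >= 0L, n_unstranded >= 0L,
            fold >= 1, background_rate >= 0,
            frag_len_mean > 0, frag_len_sd >= 0,
            rloop_len_min > 0L, rloop_len_max >= rloop_len_min,
            n_reps >= 0L, n_controls >= 0L)
  structure(list(genome = genome, n_genes = as.integer(n_genes),
                 n_stranded = as.integer(n_stranded),
                 n_unstranded = as.integer(n_unstranded),
                 fold = fold, background_rate = background_rate,
                 frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
                 rloop_len_min = as.integer(rloop_len_min),
                 rloop_len_max = as.integer(rloop_len_max),
                 n_reps = as.integer(n_reps), n_controls = as.integer(n_controls),
                 seed = as.integer(seed), placement_bias = placement_bias),
            class = "sim_config")
}

# Place n non-overlapping intervals with given lengths uniformly on the
# genome. Without positional constraints, intervals are distributed across
# chromosomes by capacity and placed exactly (uniform gaps between them);
# with a pool of candidate regions (or pre-occupied intervals) bounded
# rejection sampling is used. Errors when space runs out.
place_nonoverlapping <- function(chrom_sizes, lengths, occupied = NULL,
                                 max_tries = 200L, chrom_pool = NULL,
                                 start_pool = NULL) {
  n <- length(lengths)
  if (is.null(chrom_pool) && is.null(occupied))
    return(place_uniform_gaps(chrom_sizes, lengths, max_tries))
  placed <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                       stringsAsFactors = FALSE)
  if (!is.null(occupied)) placed <- rbind(placed, occupied)
  out <- vector("list", n)
  probs <- chrom_sizes / sum(chrom_sizes)
  for (i in seq_len(n)) {
    len <- lengths[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      if (!is.null(chrom_pool)) {
        j <- sample.int(length(chrom_pool), 1L)
        ch <- chrom_pool[j]
        lo <- start_pool$lo[j]; hi <- start_pool$hi[j]
        if (hi - len < lo) next
        s <- lo + sample.int(hi - len - lo + 1L, 1L) - 1L
      } else {
        ch <- sample(names(chrom_sizes), 1L, prob = probs)
        if (chrom_sizes[[ch]] <= len) next
        s <- sample.int(chrom_sizes[[ch]] - len, 1L) - 1L
      }
      e <- s + len
      sel <- placed$chrom == ch
      if (!any(sel) || all(placed$end[sel] <= s | placed$start[sel] >= e)) {
        row <- data.frame(chrom = ch, start = as.integer(s), end = as.integer(e),
                          stringsAsFactors = FALSE)
        placed <- rbind(placed, row)
        out[[i]] <- row
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place ", n, " non-overlapping intervals after ",
           max_tries, " tries each (genome too crowded)")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Exact uniform placement of non-overlapping intervals: assign each interval
# to a chromosome with probability proportional to length (retrying until the
# assignment fits), then draw the inter-interval gaps uniformly.
place_uniform_gaps <- function(chrom_sizes, lengths, max_tries = 200L) {
  n <- length(lengths)
  chroms <- names(chrom_sizes)
  for (try in seq_len(max_tries)) {
    assign_ch <- sample(chroms, n, replace = TRUE,
                        prob = chrom_sizes / sum(chrom_sizes))
    if (all(vapply(chroms, function(ch)
      sum(lengths[assign_ch == ch]) <= chrom_sizes[[ch]], TRUE)))
      break
    if (try == max_tries)
      stop("could not place ", n, " non-overlapping intervals: ",
           "total length exceeds chromosome capacity")
  }
  out <- vector("list", n)
  for (ch in chroms) {
    idx <- which(assign_ch == ch)
    if (length(idx) == 0L) next
    perm <- idx[sample.int(length(idx))]
    L <- lengths[perm]
    free <- chrom_sizes[[ch]] - sum(L)
    gaps <- floor(sort(stats::runif(length(perm))) * free)
    starts <- as.integer(gaps + c(0, cumsum(L))[seq_along(L)])
    for (k in seq_along(perm))
      out[[perm[k]]] <- data.frame(chrom = ch, start = starts[k],
                                   end = starts[k] + L[k],
                                   stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a genome model with genes
#'
#' Genes are non-overlapping, have log-normal lengths (median ~8 kb,
#' desk-scale), random strands, ~10% pseudogenes, and expression drawn from a
#' zero-inflated log-normal so that genes with expression > 1 split into
#' meaningful low/mid/high tertiles. Deterministic given \code{cfg$seed}.
#'
#' @param cfg A \code{sim_config}.
#' @return A \code{genome_model}.
#' @export
make_genome <- function(cfg) {
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    if (n == 0L) return(genome_model(cfg$genome))
    lens <- pmax(1000L, as.integer(round(stats::rlnorm(n, log(8000), 0.6))))
    placed <- place_nonoverlapping(cfg$genome, lens)
    biotype <- sample(c("protein_coding", "pseudogene", "other"), n,
                      replace = TRUE, prob = c(0.8, 0.1, 0.1))
    expr <- ifelse(stats::runif(n) < 0.15, 0,
                   stats::rlnorm(n, meanlog = 2, sdlog = 1.5))
    genes <- data.frame(gene_id = sprintf("G%04d", seq_len(n)),
                        chrom = placed$chrom, strand = sample(c("+", "-"), n,
                                                              replace = TRUE),
                        start = placed$start, end = placed$end,
                        biotype = biotype, expression = expr,
                        stringsAsFactors = FALSE)
    genome_model(cfg$genome, genes)
  })
}

#' Plant ground-truth R-loops
#'
#' Places \code{n_stranded + n_unstranded} non-overlapping truth intervals.
#' Stranded loops carry the hosting gene's strand when a placement bias ties
#' them to genes, otherwise a random strand: the truth strand is simply the
#' strand on which the simulator will enrich signal. Unstranded loops have
#' strand \code{NA}.
#'
#' @param genome A \code{genome_model}.
#' @param cfg A \code{sim_config}.
#' @return Data frame (\code{chrom}, \code{start}, \code{end},
#'   \code{true_class}, \code{true_strand}, \code{enrichment_fold}).
#' @export
plant_rloops <- function(genome, cfg) {
  if (cfg$placement_bias != "none" && nrow(genome$genes) == 0L)
    stop("placement bias '", cfg$placement_bias, "' needs a genome with genes")
  with_seed(cfg$seed + 1L, {
    ns <- cfg$n_stranded; nu <- cfg$n_unstranded
    lens <- cfg$rloop_len_min +
      sample.int(cfg$rloop_len_max - cfg$rloop_len_min + 1L, ns + nu,
                 replace = TRUE) - 1L
    g <- genome$genes
    mk_pool <- function(lo, hi, chrom) list(chrom = chrom,
                                            pool = list(lo = lo, hi = hi))
    if (cfg$placement_bias == "none") {
      placed <- place_nonoverlapping(genome$chrom_sizes, lens)
      strands <- c(sample(c("+", "-"), ns, replace = TRUE), rep(NA, nu))
    } else if (cfg$placement_bias == "long_genes") {
      long <- g[g$end - g$start >= stats::quantile(g$end - g$start, 2 / 3), ]
      pool <- mk_pool(long$start, long$end, long$chrom)
      placed <- place_nonoverlapping(genome$chrom_sizes, lens,
                                     chrom_pool = pool$chrom,
                                     start_pool = pool$pool)
      strands <- c(sample(c("+", "-"), ns, replace = TRUE), rep(NA, nu))
    } else {
      # stranded near the TSS ([TSS-2kb, TSS+2kb]), unstranded downstream of
      # the gene end ([TTS, TTS+5kb] in gene orientation)
      tss <- ifelse(g$strand == "+", g$start, g$end)
      tts <- ifelse(g$strand == "+", g$end, g$start)
      lo_s <- as.integer(pmax(0, tss - 2000))
      hi_s <- as.integer(pmin(genome$chrom_sizes[g$chrom], tss + 2000))
      lo_u <- as.integer(ifelse(g$strand == "+", tts, pmax(0, tts - 5000)))
      hi_u <- as.integer(ifelse(g$strand == "+",
                                pmin(genome$chrom_sizes[g$chrom], tts + 5000), tts))
      idx_s <- sample.int(nrow(g), ns, replace = ns > nrow(g))
      p_s <- place_nonoverlapping(genome$chrom_sizes, lens[seq_len(ns)],
                                  chrom_pool = g$chrom[idx_s],
                                  start_pool = list(lo = lo_s[idx_s],
                                                    hi = hi_s[idx_s]))
      idx_u <- sample.int(nrow(g), nu, replace = nu > nrow(g))
      p_u <- place_nonoverlapping(genome$chrom_sizes, lens[ns + seq_len(nu)],
                                  occupied = p_s,
                                  chrom_pool = g$chrom[idx_u],
                                  start_pool = list(lo = lo_u[idx_u],
                                                    hi = hi_u[idx_u]))
      placed <- rbind(p_s, p_u)
      strands <- c(g$strand[idx_s], rep(NA, nu))
    }
    data.frame(chrom = placed$chrom, start = placed$start, end = placed$end,
               true_class = c(rep("stranded", ns), rep("unstranded", nu)),
               true_strand = strands,
               enrichment_fold = cfg$fold,
               stringsAsFactors = FALSE)
  })
}

rtrunc_norm_len <- function(n, mean, sd) {
  lo <- 50; hi <- 2 * mean
  if (sd == 0) return(rep(as.integer(round(mean)), n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  as.integer(round(x))
}

#' Simulate one sample's fragments
#'
#' Background: per strand and chromosome, a Poisson number of fragments
#' (rate * length) with uniform midpoints. DRIP samples add, inside each
#' truth interval, an extra Poisson((fold - 1) * 2 * rate * loop length)
#' fragments so the combined-strand in-loop coverage is fold x background for
#' both loop classes; stranded loops put all extra fragments on the truth
#' strand, unstranded loops split them 50/50. RNase-H samples get background
#' only. Fragment lengths ~ Normal(mean, sd) truncated to [50, 2*mean];
#' fragments are clipped to chromosome bounds.
#'
#' @param genome A \code{genome_model}.
#' @param truth Truth table from \code{\link{plant_rloops}} (may be empty).
#' @param cfg A \code{sim_config}.
#' @param condition \code{"DRIP"} or \code{"RNASEH"}.
#' @param sample_index Integer >= 1; sample i uses seed + i*10007 so
#'   replicates are reproducible yet independent.
#' @return A \code{fragment_set}.
#' @export
simulate_fragments <- function(genome, truth, cfg, condition,
                               sample_index = 1L) {
  condition <- match.arg(condition, c("DRIP", "RNASEH"))
  with_seed(cfg$seed + sample_index * 10007L, {
    chroms <- character(0); mids <- integer(0); strands <- character(0)
    for (ch in names(genome$chrom_sizes)) {
      len <- genome$chrom_sizes[[ch]]
      for (s in c("+", "-")) {
        nbg <- stats::rpois(1L, cfg$background_rate * len)
        if (nbg > 0L) {
          chroms <- c(chroms, rep(ch, nbg))
          mids <- c(mids, sample.int(len, nbg, replace = TRUE) - 1L)
          strands <- c(strands, rep(s, nbg))
        }
      }
    }
    if (condition == "DRIP" && !is.null(truth) && nrow(truth) > 0L &&
        cfg$fold > 1) {
      for (i in seq_len(nrow(truth))) {
        llen <- truth$end[i] - truth$start[i]
        nx <- stats::rpois(1L, (cfg$fold - 1) * 2 * cfg$background_rate * llen)
        if (nx == 0L) next
        m <- truth$start[i] + sample.int(llen, nx, replace = TRUE) - 1L
        s <- if (truth$true_class[i] == "stranded") rep(truth$true_strand[i], nx)
             else sample(c("+", "-"), nx, replace = TRUE)
        chroms <- c(chroms, rep(truth$chrom[i], nx))
        mids <- c(mids, m)
        strands <- c(strands, s)
      }
    }
    n <- length(mids)
    if (n == 0L) {
      fr <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       stringsAsFactors = FALSE)
    } else {
      flen <- rtrunc_norm_len(n, cfg$frag_len_mean, cfg$frag_len_sd)
      start <- pmax(0L, mids - flen %/% 2L)
      end <- pmin(as.integer(genome$chrom_sizes[chroms]), start + flen)
      keep <- end > start
      fr <- data.frame(chrom = chroms[keep], start = start[keep],
                       end = end[keep], strand = strands[keep],
                       stringsAsFactors = FALSE)
      fr <- fr[order(fr$chrom, fr$start, fr$end, fr$strand), , drop = FALSE]
      rownames(fr) <- NULL
    }
    fragment_set(sprintf("%s_%d", tolower(condition), sample_index),
                 condition, fr)
  })
}

#' Simulate a full cohort
#'
#' @param cfg A \code{sim_config}.
#' @param outdir Optional directory: writes \code{genome.chrom.sizes},
#'   \code{genes.tsv}, \code{truth.bed} (class in the name field, fold in
#'   score, truth strand in the strand column) and one fragments BED6 per
#'   sample.
#' @return List with \code{genome}, \code{truth} and \code{samples} (DRIP
#'   replicates first, then RNase-H controls).
#' @export
simulate_cohort <- function(cfg, outdir = NULL) {
  genome <- make_genome(cfg)
  truth <- plant_rloops(genome, cfg)
  samples <- vector("list", cfg$n_reps + cfg$n_controls)
  for (i in seq_len(cfg$n_reps))
    samples[[i]] <- simulate_fragments(genome, truth, cfg, "DRIP", i)
  for (j in seq_len(cfg$n_controls))
    samples[[cfg$n_reps + j]] <-
      simulate_fragments(genome, truth, cfg, "RNASEH", cfg$n_reps + j)
  names(samples) <- vapply(samples, `[[`, "", "sample_id")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeLines(sprintf("%s\t%d", names(genome$chrom_sizes),
                       as.integer(genome$chrom_sizes)),
               file.path(outdir, "genome.chrom.sizes"))
    write_tsv(genome$genes, file.path(outdir, "genes.tsv"))
    write_bed(data.frame(chrom = truth$chrom, start = truth$start,
                         end = truth$end, name = truth$true_class,
                         score = truth$enrichment_fold,
                         strand = ifelse(is.na(truth$true_strand), ".",
                                         truth$true_strand)),
              file.path(outdir, "truth.bed"))
    for (s in samples)
      write_bed(data.frame(chrom = s$fragments$chrom, start = s$fragments$start,
                           end = s$fragments$end,
                           name = s$sample_id, score = 0,
                           strand = s$fragments$strand),
                file.path(outdir, paste0(s$sample_id, ".fragments.bed")))
  }
  list(genome = genome, truth = truth, samples = samples)
}
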