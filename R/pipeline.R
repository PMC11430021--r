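# End-to-end orchestration. A single config list drives every stage; the
# "all" subcommand chains simulate -> qc -> call -> classify -> annotate
# (-> profile when tracks are given) and writes a JSON run manifest capturing
# every parameter that affects outputs.

default_config <- function() {
  list(seed = 1L, outdir = NULL,
       sim = list(),                 # sim_config overrides; NULL disables
       samples = NULL,               # data.frame(path, condition) for user data
       chrom_sizes = NULL, genes = NULL, blacklist = NULL,
       bin_width = 500L,
       caller = list(),              # caller_params overrides
       min_support = 3L, q_max = 0.001,
       tracks = NULL,                # named list of bedGraph paths
       factor_peaks = NULL,          # BED path
       flank = 2500L, n_bins = 100L,
       setstats = NULL)              # list(set1=, set2=, universe=)
}

merge_config <- function(config) {
  out <- default_config()
  bad <- setdiff(names(config), names(out))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  out[names(config)] <- config
  if (!is.null(out$samples)) {
    for (p in out$samples$path)
      if (!file.exists(p)) stop("fragments file not found: ", p)
    if (!all(out$samples$condition %in% c("DRIP", "RNASEH")))
      stop("sample condition must be DRIP or RNASEH")
  }
  for (f in c("chrom_sizes", "genes", "blacklist", "factor_peaks"))
    if (!is.null(out[[f]]) && !file.exists(out[[f]]))
      stop(f, " file not found: ", out[[f]])
  if (out$q_max <= 0 || out$q_max > 1) stop("q_max must be in (0, 1]")
  if (out$min_support < 1) stop("min_support must be >= 1")
  out
}

build_sim_cfg <- function(config) {
  args <- config$sim
  if (is.null(args$seed)) args$seed <- config$seed
  do.call(sim_config, args)
}

# Build the working state: genome + fragment sets, either simulated or loaded.
pipeline_state <- function(config) {
  if (!is.null(config$samples)) {
    if (is.null(config$chrom_sizes))
      stop("user data needs a chrom_sizes file")
    sizes <- read_chrom_sizes(config$chrom_sizes)
    genes <- if (is.null(config$genes)) NULL else read_gene_table(config$genes)
    genome <- genome_model(sizes, genes)
    bl <- if (is.null(config$blacklist)) NULL else read_bed(config$blacklist)
    samples <- lapply(seq_len(nrow(config$samples)), function(i)
      validate_fragments(read_fragments(config$samples$path[i],
                                        config$samples$condition[i],
                                        blacklist = bl), genome))
    names(samples) <- vapply(samples, `[[`, "", "sample_id")
    list(genome = genome, truth = NULL, samples = samples)
  } else {
    simulate_cohort(build_sim_cfg(config),
                    outdir = if (is.null(config$outdir)) NULL else
                      file.path(config$outdir, "simulated"))
  }
}

stage_qc <- function(state, config) {
  covs <- lapply(state$samples, bin_coverage, genome = state$genome,
                 bin_width = config$bin_width)
  m <- coverage_matrix(covs)
  qc <- pca_qc(m, vapply(state$samples, `[[`, "", "condition"))
  if (!is.null(config$outdir))
    write_tsv(data.frame(sample_id = qc$sample_id, condition = qc$conditions,
                         PC1 = qc$scores[, 1L],
                         PC2 = if (ncol(qc$scores) > 1L) qc$scores[, 2L] else NA,
                         var_frac_PC1 = qc$variance_fraction[1L],
                         separated = qc$separated),
              file.path(config$outdir, "qc.tsv"))
  qc
}

stage_call <- function(state, config) {
  params <- do.call(caller_params, config$caller)
  drip <- Filter(function(s) s$condition == "DRIP", state$samples)
  ctrl <- Filter(function(s) s$condition == "RNASEH", state$samples)
  if (length(drip) == 0L) stop("no DRIP samples")
  if (length(ctrl) == 0L) stop("no RNASEH control samples")
  peaks <- lapply(drip, call_peaks, controls = ctrl, genome = state$genome,
                  params = params)
  strand_peaks <- lapply(drip, call_strand_enrichment, genome = state$genome,
                         params = params)
  if (!is.null(config$outdir))
    for (nm in names(peaks)) {
      write_narrowpeak(peaks[[nm]],
                       file.path(config$outdir, paste0(nm, ".peaks.narrowPeak")))
      write_narrowpeak(strand_peaks[[nm]],
                       file.path(config$outdir,
                                 paste0(nm, ".strand.narrowPeak")))
    }
  list(peaks = peaks, strand_peaks = strand_peaks)
}

stage_classify <- function(state, calls, config) {
  cons <- consensus_rloops(calls$peaks, min_support = config$min_support,
                           q_max = config$q_max)
  if (nrow(cons) == 0L) {
    rl <- cbind(cons, data.frame(rloop_class = character(0),
                                 strand = character(0),
                                 n_support_plus = integer(0),
                                 n_support_minus = integer(0)))
  } else {
    rl <- classify_strandedness(cons, calls$strand_peaks,
                                min_support = config$min_support,
                                q_max = config$q_max)
  }
  if (!is.null(config$outdir)) {
    write_rloops_bed(rl, file.path(config$outdir, "rloops.bed"))
    write_tsv(rl, file.path(config$outdir, "rloops_support.tsv"))
  }
  rl
}

stage_annotate <- function(state, rloops, config) {
  if (nrow(state$genome$genes) == 0L) stop("annotation needs genes")
  fmap <- build_feature_map(state$genome)
  enr <- obs_exp_enrichment(rloops, fmap, seed = config$seed)
  fp <- if (is.null(config$factor_peaks)) NULL else
    read_bed(config$factor_peaks)
  ov <- overlap_gene_classes(state$genome, rloops, fp)
  gl <- gene_length_density(state$genome, rloops)
  if (!is.null(config$outdir)) {
    write_tsv(enr, file.path(config$outdir, "enrichment.tsv"))
    write_tsv(ov$proportions, file.path(config$outdir, "gene_overlap.tsv"))
    write_tsv(gl$genes, file.path(config$outdir, "gene_length.tsv"))
  }
  list(enrichment = enr, gene_overlap = ov, gene_length = gl)
}

stage_profile <- function(state, rloops, config) {
  if (is.null(config$tracks)) stop("profile stage needs config$tracks")
  out <- list()
  for (nm in names(config$tracks)) {
    track <- read_signal_track(config$tracks[[nm]])
    for (cl in unique(rloops$rloop_class)) {
      centers <- rloops[rloops$rloop_class == cl, , drop = FALSE]
      mm <- signal_matrix(track, centers, flank = config$flank,
                          n_bins = config$n_bins)
      out[[paste(nm, cl, sep = ".")]] <- mm
      if (!is.null(config$outdir))
        write_profile(mm, file.path(config$outdir,
                                    sprintf("profile.%s.%s.tsv", nm, cl)))
    }
  }
  out
}

write_manifest <- function(config, state, path) {
  inputs <- c(config$chrom_sizes, config$genes, config$blacklist,
              config$factor_peaks, unlist(config$tracks),
              if (!is.null(config$samples)) config$samples$path)
  checksums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
  manifest <- list(
    package = "ssdripr",
    version = as.character(utils::packageVersion("ssdripr")),
    seed = config$seed,
    bin_width = config$bin_width,
    caller = do.call(caller_params, config$caller)[],
    min_support = config$min_support, q_max = config$q_max,
    flank = config$flank, n_bins = config$n_bins,
    sim = if (is.null(config$samples)) build_sim_cfg(config)[] else NULL,
    n_samples = length(state$samples),
    input_checksums = checksums)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run a pipeline subcommand
#'
#' Subcommands: \code{simulate} (write a synthetic cohort),
#' \code{qc} (coverage PCA), \code{call} (per-replicate peaks vs merged
#' RNase-H controls plus strand-enrichment peaks), \code{classify}
#' (replicate consensus + stranded/unstranded classification),
#' \code{annotate} (feature enrichment, gene overlap, gene length),
#' \code{profile} (metaprofiles of external tracks), \code{setstats}
#' (Fisher set enrichment from id lists) and \code{all} (the full chain).
#' With no \code{samples} in the config, stages run on a synthetic cohort
#' generated from \code{config$sim} and \code{config$seed}; outputs are
#' deterministic given the config.
#'
#' @param name Subcommand name.
#' @param config List; see the package vignette. Recognized fields:
#'   \code{seed}, \code{outdir}, \code{sim}, \code{samples},
#'   \code{chrom_sizes}, \code{genes}, \code{blacklist}, \code{bin_width},
#'   \code{caller}, \code{min_support}, \code{q_max}, \code{tracks},
#'   \code{factor_peaks}, \code{flank}, \code{n_bins}, \code{setstats}.
#' @return Invisibly, a list with the computed stage results.
#' @export
run_subcommand <- function(name, config = list()) {
  valid <- c("simulate", "qc", "call", "classify", "annotate", "profile",
             "setstats", "all")
  if (!name %in% valid)
    stop("unknown subcommand '", name, "'; expected one of: ",
         paste(valid, collapse = ", "))
  config <- merge_config(config)
  if (!is.null(config$outdir))
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  if (name == "setstats") {
    ss <- config$setstats
    if (is.null(ss) || !all(c("set1", "set2", "universe") %in% names(ss)))
      stop("setstats needs config$setstats with set1, set2, universe paths")
    rep <- set_enrichment_report(ss$set1, ss$set2, ss$universe,
                                 ss$alternative %||% "greater")
    if (!is.null(config$outdir))
      write_tsv(rep, file.path(config$outdir, "set_enrichment.tsv"))
    return(invisible(list(setstats = rep)))
  }
  state <- pipeline_state(config)
  res <- list(state = state)
  if (name %in% c("qc", "all"))
    res$qc <- stage_qc(state, config)
  if (name %in% c("call", "classify", "annotate", "profile", "all"))
    res$calls <- stage_call(state, config)
  if (name %in% c("classify", "annotate", "profile", "all"))
    res$rloops <- stage_classify(state, res$calls, config)
  if (name %in% c("annotate", "all") && nrow(state$genome$genes) > 0L &&
      nrow(res$rloops) > 0L)
    res$annotation <- stage_annotate(state, res$rloops, config)
  if (name == "profile" || (name == "all" && !is.null(config$tracks)))
    res$profiles <- stage_profile(state, res$rloops, config)
  if (!is.null(config$outdir))
    write_manifest(config, state, file.path(config$outdir, "manifest.json"))
  invisible(res)
}
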