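#' Default pipeline configuration
#'
#' Study-scale defaults for the synthetic end-to-end run: a small genome at
#' the field-standard 10-kb resolution, two biological replicates per
#' channel, over-dispersed counts, and a depletion condition that removes
#' the CTCF-site dips and pushes LAD borders 20 kb into the iLAD.
#'
#' @param ... Named overrides of any default.
#' @return Named list of pipeline parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_chromosomes = 2, mean_length = 1e7, bin_size = 1e4,
    lad_fraction = 0.4, mean_lad_size = 1e6,
    ctcf_border_rate = 0.7, ctcf_intra_rate = 4, gene_rate = 2,
    dip_depth = 0.5, gatc_spacing = 256,
    depth = 5e5, dispersion = 0.1, replicates = 2,
    emission = "gaussian",
    conditions = list(
      condition_effect("control"),
      condition_effect("depleted", dip_multiplier = 0, border_shift = 2e4)
    )
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

# reads -> replicate-averaged z and log2-ratio tracks for one condition
.reads_to_z <- function(read_sets, gatc, genome, bin_size, pseudocount = 1) {
  reps <- sort(unique(vapply(read_sets, `[[`, 0L, "replicate")))
  lr_tracks <- lapply(reps, function(r) {
    pick <- function(chan) {
      for (rs in read_sets) {
        if (rs$channel == chan && rs$replicate == r) return(rs)
      }
      stop("missing ", chan, " channel for replicate ", r)
    }
    lamin <- cpm_normalize(count_reads_in_bins(pick("LaminB1"), gatc, genome,
                                               bin_size))
    dam <- cpm_normalize(count_reads_in_bins(pick("Dam"), gatc, genome,
                                             bin_size))
    log2_ratio(lamin, dam, pseudocount)
  })
  z <- average_replicates(lapply(lr_tracks, to_zscore))
  lr_avg <- average_replicates(lr_tracks)
  lr_avg$kind <- "log2ratio"
  list(z = z, log2 = lr_avg)
}

#' Run the full synthetic analysis pipeline
#'
#' Generates a genome, ground truth and read sets, processes reads to
#' replicate-averaged z-score tracks, segments LADs per condition, builds
#' the consensus, classifies borders, measures border shifts and per-border
#' outside changes against the control, scores detachment at filtered
#' intra-LAD CTCF sites, and computes per-LAD score changes. When `outdir`
#' is given, all tables are written as TSV/BED/bedGraph; runs with the same
#' config and seed produce byte-identical files.
#'
#' @param config From [pipeline_config()].
#' @param seed Integer seed driving every random substream.
#' @param outdir Output directory, or `NULL` to skip writing.
#' @return Invisible list with the genome, truth, per-condition z tracks and
#'   LAD sets, consensus, classified borders, shifts, detachment records,
#'   LAD score matrix and written file paths.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         outdir = NULL) {
  genome <- make_genome(config$n_chromosomes, config$mean_length, seed)
  truth <- place_truth(genome, lad_fraction = config$lad_fraction,
                       mean_lad_size = config$mean_lad_size,
                       ctcf_border_rate = config$ctcf_border_rate,
                       ctcf_intra_rate = config$ctcf_intra_rate,
                       gene_rate = config$gene_rate,
                       dip_depth = config$dip_depth, seed = seed)
  gatc <- make_gatc_map(genome, config$gatc_spacing, seed)
  annotation <- as_site_annotation(truth)

  z_tracks <- list()
  log2_tracks <- list()
  lad_sets <- list()
  for (effect in config$conditions) {
    expected <- expected_profile(truth, effect, config$bin_size)
    reads <- simulate_reads(list(lamin = expected), gatc,
                            depth = config$depth,
                            dispersion = config$dispersion,
                            replicates = config$replicates,
                            seed = substream_seed(seed,
                                                  paste0("cond/",
                                                         effect$name)),
                            sample_prefix = effect$name)
    tracks <- .reads_to_z(reads, gatc, genome, config$bin_size)
    z <- tracks$z
    model <- fit_hmm(z, emission = config$emission)
    path <- viterbi_segment(z, model)
    z_tracks[[effect$name]] <- z
    log2_tracks[[effect$name]] <- tracks$log2
    lad_sets[[effect$name]] <- call_lads(path, model, z,
                                         provenance = effect$name)
  }

  consensus <- consensus_lads(lad_sets)
  ref_name <- config$conditions[[1]]$name
  borders_ref <- extract_borders(lad_sets[[ref_name]])
  border_ann <- classify_borders(borders_ref, annotation)

  shifts <- NULL
  outside_deltas <- list()
  for (effect in config$conditions[-1]) {
    shifts <- border_shift_cdf(extract_borders(lad_sets[[effect$name]]),
                               borders_ref)
    outside_deltas[[effect$name]] <- border_outside_change(
      z_tracks[[effect$name]], z_tracks[[ref_name]], borders_ref)
  }

  sites <- filter_sites(annotation$ctcf, annotation$genes,
                        lad_sets[[ref_name]], borders_ref)
  detach <- data.frame(sites,
                       score = detachment_score(z_tracks[[ref_name]], sites),
                       stringsAsFactors = FALSE)
  if (nrow(detach) > 0) {
    detach$loop_class <- classify_loop_partner(detach, annotation$loops,
                                               lad_sets[[ref_name]])
  }

  scores <- sapply(z_tracks, lad_mean_scores, consensus = consensus)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1,
                                             dimnames = list(NULL,
                                                             names(z_tracks)))

  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(name) file.path(outdir, name)
    for (nm in names(z_tracks)) {
      write_bedgraph(z_tracks[[nm]], out(paste0("z_", nm, ".bedgraph")))
      write_bed(lad_sets[[nm]], out(paste0("lads_", nm, ".bed")))
      files <- c(files, out(paste0("z_", nm, ".bedgraph")),
                 out(paste0("lads_", nm, ".bed")))
    }
    write_bed(consensus, out("lads_consensus.bed"))
    write_tsv <- function(df, name) {
      utils::write.table(df, out(name), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <<- c(files, out(name))
    }
    write_tsv(border_ann, "borders.tsv")
    if (!is.null(shifts)) write_tsv(shifts$shifts, "border_shifts.tsv")
    write_tsv(detach, "detachment.tsv")
    write_tsv(data.frame(lad_id = seq_len(nrow(consensus)),
                         consensus[, c("chrom", "start", "end")], scores,
                         check.names = FALSE),
              "lad_scores.tsv")
    write_bed(truth$lads, out("truth_lads.bed"))
    write_tsv(truth$ctcf, "truth_ctcf.tsv")
    write_tsv(truth$genes, "truth_genes.tsv")
    files <- c(files, out("lads_consensus.bed"), out("truth_lads.bed"))
  }

  invisible(list(genome = genome, truth = truth, gatc = gatc,
                 annotation = annotation, z_tracks = z_tracks,
                 log2_tracks = log2_tracks, lad_sets = lad_sets,
                 consensus = consensus,
                 borders = border_ann, shifts = shifts,
                 outside_deltas = outside_deltas, detachment = detach,
                 lad_scores = scores, files = sort(files)))
}
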