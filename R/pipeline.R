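#' Run the full editing-discovery pipeline on simulated data
#'
#' Executes the complete workflow: simulate a genome and planted truth,
#' generate matched DNA and RNA reads, build filtered pileups, genotype the
#' DNA, call per-sample candidates, run the filter cascade and merge
#' samples, rescue hyper-edited reads by masked realignment, compute
#' per-family and global editing indexes, annotate and quantify recoding
#' sites, and profile the editing motif and noise. With one seed the run is
#' fully deterministic, including every file [write_report()] emits.
#'
#' @param config A [sim_config()].
#' @param outdir Optional report directory; when set, simulated reads and
#'   the report bundle are written beneath it.
#' @param thresholds A [detection_thresholds()].
#' @param fparams A [filter_params()].
#' @param hparams A [hyper_params()].
#' @param iparams An [index_params()].
#' @return An `edscope_run` list carrying every stage result (reference,
#'   truth, pileups, candidates, cascade, merged sites, hyper results,
#'   indexes, recoding tables, motif, noise).
#' @export
run_editing_pipeline <- function(config = sim_config(), outdir = NULL,
                                 thresholds = detection_thresholds(),
                                 fparams = filter_params(),
                                 hparams = hyper_params(),
                                 iparams = index_params()) {
  ref <- simulate_genome(config)
  truth <- plant_truth(ref, config)
  reads <- simulate_reads(ref, truth, config,
                          outdir = if (!is.null(outdir))
                            file.path(outdir, "reads") else NULL)

  dna_pileup <- build_pileup(reads$dna, ref, thresholds)
  genotypes <- genotype_dna(dna_pileup)

  rna_align <- reads$rna
  if (!is.null(iparams$harmonize_read_length)) {
    rna_align <- lapply(rna_align, harmonize_read_length,
                        target_length = iparams$harmonize_read_length)
  }
  rna_pileups <- lapply(rna_align, build_pileup, ref = ref,
                        thresholds = thresholds)
  candidates <- list_rbind(lapply(names(rna_pileups), function(sm) {
    call_candidates(rna_pileups[[sm]], genotypes, thresholds, sample_id = sm)
  }))
  candidates <- orient_sites(candidates, ref)

  cascade <- apply_cascade(candidates, ref, fparams)
  merged <- orient_sites(merge_samples(cascade$sites, fparams), ref)

  index <- build_masked_index(ref, hparams)
  rescued <- rescue_reads(reads$hyper, index, hparams)
  hyper_sites <- call_hyper_sites(rescued)

  overlap <- overlap_counts(merged, hyper_sites)

  pooled <- pool_pileups(rna_pileups)
  family_spectra <- family_index(pooled, ref$repeats, ref, iparams)
  family_selection <- select_families(family_spectra, iparams)
  sel <- family_selection$family[family_selection$selected]
  gindex <- if (length(sel) > 0) {
    global_index(pooled, ref$repeats, sel, iparams)
  } else {
    tibble(index = NA_real_, numerator = 0, denominator = 0, n_families = 0L)
  }

  annotated <- annotate_sites(merged, ref$genes)
  coding <- classify_effects(annotated, ref$genes, ref)
  coding_consensus <- consensus_recoding(coding, fparams)

  known <- truth$edit_sites |>
    filter(.data$in_cds) |>
    transmute(chrom = .data$chrom, pos = .data$pos,
              ref = ifelse(.data$strand == "+", "A", "T"),
              alt = ifelse(.data$strand == "+", "G", "C"))
  levels <- quantify_known(known, rna_pileups, thresholds)
  set_index <- site_set_index(levels)
  consistency <- level_consistency(levels)

  sense <- merged |>
    filter(.data$type == "A>G") |>
    select("chrom", "pos", "strand")
  bg <- background_adenosines(pooled, ref$repeats,
                              min_coverage = thresholds$min_coverage)
  motif <- motif_profile(sense, ref, bg)

  final_spectrum <- mismatch_spectrum(merged)
  noise <- noise_estimate(final_spectrum)

  run <- structure(list(
    seed = config$seed, config = config, thresholds = thresholds,
    filter_params = fparams, hyper_params = hparams, index_params = iparams,
    ref = ref, truth = truth,
    dna_pileup = dna_pileup, rna_pileups = rna_pileups,
    genotypes = genotypes, candidates = candidates,
    cascade = cascade, merged = merged,
    hyper_rescued = rescued, hyper_sites = hyper_sites, overlap = overlap,
    family_spectra = family_spectra, family_selection = family_selection,
    global_index = gindex,
    recoding = coding_consensus, recoding_all = coding,
    levels = levels, site_set_index = set_index,
    level_consistency = consistency,
    motif = motif, final_spectrum = final_spectrum, noise = noise
  ), class = "edscope_run")
  if (!is.null(outdir)) write_report(run, file.path(outdir, "report"))
  run
}

overlap_counts <- function(merged, hyper_sites) {
  mk <- paste(merged$chrom, merged$pos)
  hk <- paste(hyper_sites$chrom, hyper_sites$pos)
  n_overlap <- length(intersect(mk, hk))
  tibble(n_cascade = length(unique(mk)), n_hyper = length(unique(hk)),
         n_overlap = n_overlap,
         n_union = length(unique(mk)) + length(unique(hk)) - n_overlap)
}

#' @export
print.edscope_run <- function(x, ...) {
  cat("<edscope_run>\n")
  cat(sprintf("  seed %d; genome %d bp; %d RNA sample(s)\n", x$seed,
              x$config$genome_length, x$config$n_rna_samples))
  cat(sprintf("  candidates: %d -> cascade survivors: %d -> merged unique sites: %d\n",
              nrow(x$candidates), nrow(x$cascade$sites), nrow(x$merged)))
  ag <- if (nrow(x$merged) > 0)
    100 * mean(x$merged$type == "A>G") else NA_real_
  cat(sprintf("  A>G fraction of merged sites: %.1f%%; noise estimate: %s\n",
              ag, if (is.na(x$noise$noise_fraction)) "undefined" else
                sprintf("%.2f%%", 100 * x$noise$noise_fraction)))
  cat(sprintf("  hyper: %d rescued reads, %d unique sites (%d events)\n",
              nrow(x$hyper_rescued), attr(x$hyper_sites, "n_sites"),
              attr(x$hyper_sites, "n_events")))
  cat(sprintf("  global repeat editing index: %s\n",
              if (is.na(x$global_index$index)) "undefined" else
                sprintf("%.3f%%", 100 * x$global_index$index)))
  invisible(x)
}

#' @rdname run_editing_pipeline
#' @param x,object An `edscope_run`.
#' @param ... Unused.
#' @export
glance.edscope_run <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$candidates),
    n_sites = nrow(x$merged),
    frac_a_to_g = if (nrow(x$merged) > 0) mean(x$merged$type == "A>G")
      else NA_real_,
    noise_fraction = x$noise$noise_fraction,
    n_hyper_sites = attr(x$hyper_sites, "n_sites"),
    global_index = x$global_index$index,
    n_recoding_consensus = nrow(x$recoding),
    median_cov = x$level_consistency$median_cov
  )
}
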