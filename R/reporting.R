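#' Covered sense adenosines for motif background
#'
#' All positions inside the given stranded intervals whose sense base is A
#' and whose pileup coverage reaches `min_coverage` -- the background
#' sequence space against which the editing motif is compared.
#'
#' @param pileup Pileup tibble.
#' @param intervals Stranded interval tibble (chrom, start, end, strand),
#'   e.g. `ref$repeats`.
#' @param min_coverage Minimum pileup coverage (default 1).
#' @return A tibble: chrom, pos, strand.
#' @export
background_adenosines <- function(pileup, intervals, min_coverage = 1) {
  p <- filter(pileup, .data$coverage >= min_coverage)
  if (nrow(p) == 0L || nrow(intervals) == 0L) {
    return(tibble(chrom = character(), pos = integer(), strand = character()))
  }
  pg <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$pos, p$pos))
  ig <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start, intervals$end))
  ov <- GenomicRanges::findOverlaps(pg, ig)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  sense_ref <- ifelse(intervals$strand[sh] == "+", p$ref[qh],
                      comp_base(p$ref[qh]))
  tibble(chrom = p$chrom[qh], pos = p$pos[qh],
         strand = intervals$strand[sh])[sense_ref == "A", ] |>
    distinct()
}

# shared flank counting routine: per relative position (sense orientation),
# base frequencies over the given stranded positions
flank_base_freq <- function(positions, ref, k) {
  rel <- setdiff(seq(-k, k), 0L)
  n_trunc <- 0L
  counts <- matrix(0L, nrow = length(rel), ncol = 4L,
                   dimnames = list(as.character(rel), BASES))
  if (nrow(positions) > 0L) {
    for (ch in unique(positions$chrom)) {
      cs <- chrom_string(ref, ch)
      chrlen <- nchar(cs)
      rows <- positions[positions$chrom == ch, ]
      for (j in seq_along(rel)) {
        off <- ifelse(rows$strand == "+", rel[j], -rel[j])
        gp <- rows$pos + off
        inb <- gp >= 1L & gp <= chrlen
        n_trunc <- n_trunc + sum(!inb)
        b <- base_at(cs, gp[inb])
        b <- ifelse(rows$strand[inb] == "-", comp_base(b), b)
        tb <- table(factor(b, levels = BASES))
        counts[j, ] <- counts[j, ] + as.integer(tb)
      }
    }
  }
  list(counts = counts, rel = rel, n_truncated = n_trunc)
}

#' Nearest-neighbor motif profile around editing sites
#'
#' Base frequencies at every flank position from -k to +k (sense
#' orientation, position 0 excluded) among edited sites and among a
#' background set of covered sense adenosines, with per-base enrichment
#' ratios (site frequency / background frequency). ADAR targets show G
#' depleted at -1 and enriched at +1. Sites whose flank runs off the contig
#' are excluded from the affected positions and tallied.
#'
#' @param sites Tibble of sense-oriented A-to-G sites (chrom, pos, strand).
#' @param ref A `ref_bundle`.
#' @param background Tibble of background adenosines (chrom, pos, strand),
#'   e.g. from [background_adenosines()].
#' @param k Flank size in bp (default 3).
#' @return A `motif_profile` tibble: position, base, site_freq, bg_freq,
#'   enrichment; attributes `n_sites`, `n_background`, `n_truncated`.
#' @export
motif_profile <- function(sites, ref, background, k = 3) {
  fg <- flank_base_freq(sites, ref, k)
  bg <- flank_base_freq(background, ref, k)
  freq <- function(m) sweep(m, 1L, pmax(rowSums(m), 1L), "/")
  f1 <- freq(fg$counts); f2 <- freq(bg$counts)
  out <- tibble(
    position = rep(fg$rel, each = 4L),
    base = rep(BASES, length(fg$rel)),
    site_freq = as.vector(t(f1)),
    bg_freq = as.vector(t(f2))) |>
    mutate(enrichment = ifelse(.data$bg_freq > 0,
                               .data$site_freq / .data$bg_freq, NA_real_))
  attr(out, "n_sites") <- nrow(sites)
  attr(out, "n_background") <- nrow(background)
  attr(out, "n_truncated") <- fg$n_truncated
  new_tibble_class(out, "motif_profile")
}

#' @rdname motif_profile
#' @param object A `motif_profile`.
#' @param ... Unused.
#' @export
autoplot.motif_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$position),
                               y = .data$enrichment, fill = .data$base)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "position relative to edited adenosine",
                  y = "site / background frequency ratio") +
    ggplot2::theme_minimal()
}

#' Estimate the noise level of a site set
#'
#' The ratio of the next most frequent non-A-to-G substitution to the
#' A-to-G count. The basis type is reported rather than hard-coded: C-to-T
#' is typically the runner-up, but whichever type ranks second defines the
#' noise floor.
#'
#' @param spectrum Tibble from [mismatch_spectrum()].
#' @return A one-row tibble: noise_fraction, basis_type, n_a_to_g, n_basis;
#'   `noise_fraction` is NA (with `undefined` attribute) when no A-to-G
#'   sites exist.
#' @export
noise_estimate <- function(spectrum) {
  ag <- spectrum$n[spectrum$type == "A>G"]
  oth <- spectrum[spectrum$type != "A>G", ]
  basis <- oth$type[which.max(oth$n)]
  nb <- max(oth$n)
  out <- tibble(
    noise_fraction = if (ag > 0) nb / ag else NA_real_,
    basis_type = if (nb > 0) basis else NA_character_,
    n_a_to_g = ag, n_basis = nb)
  attr(out, "undefined") <- ag == 0
  out
}

#' Write the full report bundle
#'
#' Writes every analysis surface of a pipeline run as TSV under `outdir`:
#' per-step mismatch spectra and the filter report, the merged site table,
#' hyper-editing sites with cascade/hyper overlap counts, per-family and
#' global editing indexes, the recoding table and levels matrix, the motif
#' table, the noise estimate, and `run_info.json` recording configuration,
#' seed and package version. Rows are fully ordered, so identical runs give
#' byte-identical reports.
#'
#' @param run An `edscope_run` from [run_editing_pipeline()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  w <- function(x, name) {
    p <- file.path(outdir, name)
    readr::write_tsv(x, p)
    files <<- c(files, p)
  }
  w(run$cascade$report, "filter_report.tsv")
  w(run$cascade$spectra, "spectra_per_step.tsv")
  w(flatten_sites(run$merged), "sites_merged.tsv")
  w(run$hyper_sites, "sites_hyper.tsv")
  w(run$overlap, "cascade_hyper_overlap.tsv")
  w(run$family_spectra, "family_index.tsv")
  w(run$family_selection, "family_selection.tsv")
  w(run$global_index, "global_index.tsv")
  w(run$recoding, "recoding_sites.tsv")
  w(levels_matrix(run$levels), "levels_matrix.tsv")
  w(run$levels, "levels_long.tsv")
  w(as_tibble_motif(run$motif), "motif.tsv")
  w(run$noise, "noise.tsv")

  info <- list(package = "edscope",
               version = as.character(utils::packageVersion("edscope")),
               seed = run$seed, config = unclass(run$config),
               thresholds = unclass(run$thresholds),
               filter_params = unclass(run$filter_params),
               hyper_params = unclass(run$hyper_params),
               index_params = unclass(run$index_params))
  p <- file.path(outdir, "run_info.json")
  jsonlite::write_json(info, p, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  files <- c(files, p)
  invisible(files)
}

flatten_sites <- function(merged) {
  select(merged, -any_of("per_sample"))
}

as_tibble_motif <- function(m) {
  tibble::as_tibble(m)
}

#' Sites-by-samples editing-level matrix
#'
#' Wide layout of [quantify_known()] output: one row per site, one column
#' per sample, missing entries as NA.
#'
#' @param levels Long tibble from [quantify_known()].
#' @return A wide tibble.
#' @export
levels_matrix <- function(levels) {
  levels |>
    mutate(level = ifelse(.data$missing, NA_real_, .data$level)) |>
    select("chrom", "pos", "ref", "alt", "sample_id", "level") |>
    pivot_wider(names_from = "sample_id", values_from = "level") |>
    arrange(.data$chrom, .data$pos)
}
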