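#' Genotype positions from a matched DNA pileup
#'
#' Classifies every DNA-covered position as `homozygous_ref`,
#' `non_homozygous` or `insufficient_dna`. A position is homozygous-reference
#' only when DNA coverage reaches `dna_min_coverage` and the non-reference
#' fraction stays below `het_max_fraction`; a true heterozygote (~50\% alt)
#' is far above that bound, while the tolerance admits an occasional errored
#' DNA read.
#'
#' @param dna_pileup DNA pileup tibble from [build_pileup()].
#' @param dna_min_coverage Minimum DNA reads to call a genotype (default 10).
#' @param het_max_fraction Maximum non-reference fraction still called
#'   homozygous-reference (default 0.05).
#' @return A genotype tibble: chrom, pos, status, dna_coverage,
#'   nonref_fraction.
#' @export
genotype_dna <- function(dna_pileup, dna_min_coverage = 10,
                         het_max_fraction = 0.05) {
  ref_count <- pick_base_count(dna_pileup)
  out <- transmute(
    dna_pileup, chrom = .data$chrom, pos = .data$pos,
    dna_coverage = .data$coverage,
    nonref_fraction = (.data$coverage - ref_count) / .data$coverage)
  out$status <- dplyr::case_when(
    out$dna_coverage < dna_min_coverage ~ "insufficient_dna",
    out$nonref_fraction >= het_max_fraction ~ "non_homozygous",
    TRUE ~ "homozygous_ref")
  out
}

pick_base_count <- function(pileup, base = pileup$ref) {
  m <- cbind(pileup$A, pileup$C, pileup$G, pileup$T)
  idx <- match(base, BASES)
  m[cbind(seq_len(nrow(m)), idx)]
}

#' Combine genotype calls across DNA samples
#'
#' With several DNA samples, a position is homozygous-reference only when it
#' is homozygous-reference in *all* of them: a site non-homozygous in at
#' least one sample is excluded.
#'
#' @param genotype_list List of genotype tibbles from [genotype_dna()].
#' @return A combined genotype tibble.
#' @export
combine_genotypes <- function(genotype_list) {
  if (length(genotype_list) == 1L) return(genotype_list[[1]])
  all_pos <- distinct(
    list_rbind(lapply(genotype_list, function(g) select(g, "chrom", "pos"))))
  status_mat <- vapply(genotype_list, function(g) {
    s <- g$status[match(paste(all_pos$chrom, all_pos$pos),
                        paste(g$chrom, g$pos))]
    ifelse(is.na(s), "insufficient_dna", s)
  }, character(nrow(all_pos)))
  status_mat <- matrix(status_mat, nrow = nrow(all_pos))
  all_pos$status <- apply(status_mat, 1L, function(s) {
    if (any(s == "non_homozygous")) "non_homozygous"
    else if (any(s == "insufficient_dna")) "insufficient_dna"
    else "homozygous_ref"
  })
  all_pos$dna_coverage <- NA_integer_
  all_pos$nonref_fraction <- NA_real_
  all_pos
}

#' Call per-sample candidate mismatch sites
#'
#' Emits one candidate per (position, alternate base) in the RNA pileup that
#' reaches the coverage, frequency and alt-read thresholds at a position
#' genotyped homozygous-reference in the matched DNA. Positions without
#' qualifying DNA support are dropped entirely, so genomic SNPs never enter
#' the candidate list. Positions where two alternate bases both qualify are
#' emitted as separate candidates and resolved by the filter cascade.
#'
#' @param rna_pileup RNA pileup tibble.
#' @param genotypes Genotype tibble from [genotype_dna()] or
#'   [combine_genotypes()].
#' @param thresholds A [detection_thresholds()].
#' @param sample_id Sample label recorded on each candidate.
#' @return A candidate tibble: sample_id, chrom, pos, ref, alt, type,
#'   coverage, alt_count, frequency, the four base counts and dna_status.
#' @export
call_candidates <- function(rna_pileup, genotypes,
                            thresholds = detection_thresholds(),
                            sample_id = "sample1") {
  gt <- select(genotypes, "chrom", "pos", dna_status = "status")
  p <- inner_join(rna_pileup, gt, by = c("chrom", "pos")) |>
    filter(.data$dna_status == "homozygous_ref",
           .data$coverage >= thresholds$min_coverage,
           .data$ref %in% BASES)
  if (nrow(p) == 0L) return(empty_candidates())
  long <- pivot_longer(p, cols = c("A", "C", "G", "T"), names_to = "alt",
                       values_to = "alt_count",
                       cols_vary = "slowest") |>
    filter(.data$alt != .data$ref,
           .data$alt_count >= thresholds$min_alt_count,
           .data$alt_count / .data$coverage >= thresholds$min_frequency)
  if (nrow(long) == 0L) return(empty_candidates())
  counts <- select(p, "chrom", "pos", "A", "C", "G", "T")
  long |>
    mutate(sample_id = sample_id,
           type = paste0(.data$ref, ">", .data$alt),
           frequency = .data$alt_count / .data$coverage) |>
    left_join(counts, by = c("chrom", "pos")) |>
    select("sample_id", "chrom", "pos", "ref", "alt", "type", "coverage",
           "alt_count", "frequency", "A", "C", "G", "T", "dna_status") |>
    arrange(.data$chrom, .data$pos, .data$alt)
}

empty_candidates <- function() {
  tibble(sample_id = character(), chrom = character(), pos = integer(),
         ref = character(), alt = character(), type = character(),
         coverage = integer(), alt_count = integer(), frequency = numeric(),
         A = integer(), C = integer(), G = integer(), T = integer(),
         dna_status = character())
}

#' Orient sites onto their transcribed strand
#'
#' Pileup counts are reference-forward, but editing is a sense-strand
#' phenomenon: an A-to-G event on a minus-strand repeat or gene appears as a
#' forward T-to-C mismatch. This resolves each site's strand from the
#' overlapping annotated feature (repeats and genes; forward where no
#' feature overlaps, matching sense-stranded sequencing) and rewrites `type`
#' as the sense substitution, keeping `ref`/`alt` reference-forward. Run it
#' on candidates before the filter cascade so that cluster homogeneity and
#' the mismatch spectrum are judged on sense types.
#'
#' @param sites Tibble with chrom, pos, ref, alt columns.
#' @param ref A `ref_bundle` supplying repeat and gene strands.
#' @return The sites with a `strand` column and sense-oriented `type`.
#' @export
orient_sites <- function(sites, ref) {
  if (nrow(sites) == 0L) {
    return(mutate(sites, strand = character(0)))
  }
  feats <- bind_rows(
    select(ref$repeats, "chrom", "start", "end", "strand"),
    transmute(ref$genes, chrom = .data$chrom, start = .data$tx_start,
              end = .data$tx_end, strand = .data$strand))
  strand <- rep("+", nrow(sites))
  if (nrow(feats) > 0L) {
    sg <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos, sites$pos))
    fg <- GenomicRanges::GRanges(feats$chrom,
                                 IRanges::IRanges(feats$start, feats$end))
    ov <- GenomicRanges::findOverlaps(sg, fg, select = "first")
    hit <- !is.na(ov)
    strand[hit] <- feats$strand[ov[hit]]
  }
  sites$strand <- strand
  sites$type <- ifelse(strand == "-",
                       paste0(comp_base(sites$ref), ">", comp_base(sites$alt)),
                       paste0(sites$ref, ">", sites$alt))
  sites
}

#' Mismatch spectrum over the 12 substitution types
#'
#' Counts sites per substitution type and the fraction of each type. With an
#' empty input all counts are zero, fractions are reported as zero and the
#' `empty` attribute is set.
#'
#' @param sites Any tibble with a `type` column (candidates or final sites).
#' @return A tibble (type, n, fraction) over all 12 types, with attribute
#'   `empty`.
#' @export
mismatch_spectrum <- function(sites) {
  n <- table(factor(sites$type, levels = MISMATCH_TYPES))
  total <- sum(n)
  out <- tibble(type = MISMATCH_TYPES, n = as.integer(n),
                fraction = if (total > 0) as.integer(n) / total else
                  rep(0, length(MISMATCH_TYPES)))
  attr(out, "empty") <- total == 0L
  out
}

#' Plot a mismatch spectrum
#'
#' @param spectrum Tibble from [mismatch_spectrum()].
#' @return A ggplot object.
#' @export
plot_mismatch_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = .data$type, y = .data$fraction,
                               fill = .data$type == "A>G")) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = NULL, y = "fraction of sites") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
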