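#' Annotate sites against gene models
#'
#' Assigns each site the most specific region over all overlapping
#' transcripts (CDS > exon_noncoding > intron > intergenic; single-exon
#' models have no introns) and re-orients mismatches onto the transcript
#' strand: a reference-forward T-to-C call inside a minus-strand gene is an
#' A-to-G event on the transcript. Sites overlapping several transcripts get
#' one row per transcript.
#'
#' @param sites Site tibble with chrom, pos, ref, alt (reference-forward).
#' @param genes Gene-model tibble (gene_id, transcript_id, chrom, strand,
#'   tx_start, tx_end, cds_start, cds_end), e.g. `ref$genes`.
#' @return The sites with region, gene_id, transcript_id, gene_strand,
#'   sense_ref, sense_alt and sense_type columns (intergenic rows keep NA
#'   gene columns).
#' @export
annotate_sites <- function(sites, genes) {
  if (nrow(sites) == 0L) {
    return(mutate(sites, region = character(0), gene_id = character(0),
                  transcript_id = character(0), gene_strand = character(0),
                  sense_ref = character(0), sense_alt = character(0),
                  sense_type = character(0)))
  }
  sg <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, sites$pos))
  out <- mutate(sites, region = "intergenic", gene_id = NA_character_,
                transcript_id = NA_character_, gene_strand = NA_character_)
  rows <- list()
  if (nrow(genes) > 0L) {
    tg <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$tx_start, genes$tx_end))
    ov <- GenomicRanges::findOverlaps(sg, tg)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    if (length(qh)) {
      hit <- out[qh, ]
      hit$gene_id <- genes$gene_id[sh]
      hit$transcript_id <- genes$transcript_id[sh]
      hit$gene_strand <- genes$strand[sh]
      in_cds <- hit$pos >= genes$cds_start[sh] & hit$pos <= genes$cds_end[sh]
      hit$region <- ifelse(in_cds, "CDS", "exon_noncoding")
      rows <- list(hit)
      out <- out[-unique(qh), , drop = FALSE]
    }
  }
  ann <- bind_rows(c(list(out), rows))
  ann |>
    mutate(
      sense_ref = ifelse(!is.na(.data$gene_strand) & .data$gene_strand == "-",
                         comp_base(.data$ref), .data$ref),
      sense_alt = ifelse(!is.na(.data$gene_strand) & .data$gene_strand == "-",
                         comp_base(.data$alt), .data$alt),
      sense_type = paste0(.data$sense_ref, ">", .data$sense_alt)) |>
    arrange(.data$chrom, .data$pos)
}

#' Classify the coding effect of A-to-G sites in CDS
#'
#' Rebuilds the affected codon from the CDS sequence with the edited base
#' substituted (A-to-G on the coding strand), translates with the standard
#' genetic code and classifies the effect: `start_loss` when the edit hits
#' the initiator ATG, `stop_loss`/`stop_gain` for stop-codon changes, and
#' `synonymous`/`missense` otherwise. Sites are classified against every
#' overlapping transcript; a `worst_effect` summary per genomic site uses
#' the severity order start_loss > stop_gain > stop_loss > missense >
#' synonymous. A CDS whose annotated length is not divisible by 3 or that
#' contains an internal stop codon raises an annotation-integrity error.
#'
#' @param sites Annotated site tibble from [annotate_sites()]; only rows
#'   with region `"CDS"` and sense type A-to-G are classified.
#' @param genes Gene-model tibble.
#' @param ref A `ref_bundle`.
#' @return The CDS A-to-G rows with cds_pos, codon_index, codon_pos,
#'   ref_codon, alt_codon, ref_aa, alt_aa, aa_pos, effect and worst_effect.
#' @export
classify_effects <- function(sites, genes, ref) {
  cds_rows <- sites |>
    filter(.data$region == "CDS", .data$sense_type == "A>G")
  if (nrow(cds_rows) == 0L) {
    return(mutate(cds_rows, cds_pos = integer(0), codon_index = integer(0),
                  codon_pos = integer(0), ref_codon = character(0),
                  alt_codon = character(0), ref_aa = character(0),
                  alt_aa = character(0), aa_pos = integer(0),
                  effect = character(0), worst_effect = character(0)))
  }
  g_idx <- match(cds_rows$transcript_id, genes$transcript_id)
  res <- vector("list", nrow(cds_rows))
  for (i in seq_len(nrow(cds_rows))) {
    g <- genes[g_idx[i], ]
    cs <- chrom_string(ref, g$chrom)
    check_cds_integrity(cs, g)
    ann <- codon_annotation(cs, g, cds_rows$pos[i])
    cds_coord <- if (g$strand == "+") cds_rows$pos[i] - g$cds_start + 1L else
      g$cds_end - cds_rows$pos[i] + 1L
    res[[i]] <- tibble(
      cds_pos = cds_coord,
      codon_index = (cds_coord - 1L) %/% 3L + 1L,
      codon_pos = (cds_coord - 1L) %% 3L + 1L,
      ref_codon = ann$ref_codon, alt_codon = ann$alt_codon,
      ref_aa = ann$ref_aa, alt_aa = ann$alt_aa,
      aa_pos = (cds_coord - 1L) %/% 3L + 1L,
      effect = ann$effect)
  }
  out <- bind_cols(cds_rows, list_rbind(res))
  out |>
    group_by(.data$chrom, .data$pos) |>
    mutate(worst_effect =
             .data$effect[which.min(EFFECT_SEVERITY[.data$effect])]) |>
    ungroup()
}

check_cds_integrity <- function(chromstr, gene) {
  len <- gene$cds_end - gene$cds_start + 1L
  if (len %% 3L != 0L) {
    rlang::abort(sprintf("CDS of %s has length %d, not divisible by 3",
                         gene$transcript_id, len))
  }
  cds_seq <- substring(chromstr, gene$cds_start, gene$cds_end)
  if (gene$strand == "-") cds_seq <- revcomp_chr(cds_seq)
  codons <- substring(cds_seq, seq(1L, len, 3L), seq(3L, len, 3L))
  aa <- translate_codons(codons)
  if (any(aa[-length(aa)] == "*")) {
    rlang::abort(sprintf("CDS of %s contains an internal stop codon",
                         gene$transcript_id))
  }
  invisible(TRUE)
}

#' Multi-sample consensus for coding sites
#'
#' Coding calls are noisier than repeat calls, so a coding site is retained
#' only when detected in at least `consensus_min_samples` samples.
#'
#' @param sites Merged site tibble with an `n_samples_detected` column.
#' @param params A [filter_params()] (uses `consensus_min_samples`).
#' @return The consensus subset.
#' @export
consensus_recoding <- function(sites, params = filter_params()) {
  filter(sites, .data$n_samples_detected >= params$consensus_min_samples)
}

#' Quantify editing levels at known sites
#'
#' For a declared site list (reference-forward ref/alt), computes the
#' per-sample editing level alt/(ref+alt) from each sample's pileup. Entries
#' with pileup coverage below `min_coverage` -- or absent from the pileup --
#' are flagged missing rather than reported as zero.
#'
#' @param site_list Tibble with chrom, pos, ref, alt.
#' @param pileups Named list of per-sample pileup tibbles.
#' @param thresholds A [detection_thresholds()] (uses `min_coverage`).
#' @return A long tibble: chrom, pos, ref, alt, sample_id, ref_count,
#'   alt_count, coverage, level, missing.
#' @export
quantify_known <- function(site_list, pileups,
                           thresholds = detection_thresholds()) {
  if (is.null(names(pileups))) {
    names(pileups) <- paste0("sample", seq_along(pileups))
  }
  out <- lapply(names(pileups), function(sm) {
    p <- pileups[[sm]]
    j <- left_join(select(site_list, "chrom", "pos", "ref", "alt"),
                   select(p, "chrom", "pos", "A", "C", "G", "T", "coverage"),
                   by = c("chrom", "pos"))
    j$ref_count <- pick_base_count_safe(j, j$ref)
    j$alt_count <- pick_base_count_safe(j, j$alt)
    j |>
      mutate(
        sample_id = sm,
        coverage = ifelse(is.na(.data$coverage), 0L, .data$coverage),
        missing = .data$coverage < thresholds$min_coverage,
        level = ifelse(.data$missing | .data$ref_count + .data$alt_count == 0L,
                       NA_real_,
                       .data$alt_count / (.data$ref_count + .data$alt_count))) |>
      select("chrom", "pos", "ref", "alt", "sample_id", "ref_count",
             "alt_count", "coverage", "level", "missing")
  })
  list_rbind(out)
}

pick_base_count_safe <- function(j, base) {
  m <- cbind(j$A, j$C, j$G, j$T)
  m[is.na(m)] <- 0L
  idx <- match(base, BASES)
  out <- m[cbind(seq_len(nrow(j)), idx)]
  as.integer(out)
}

#' Pooled site-set editing index
#'
#' Total alternate (G) reads divided by total reference plus alternate
#' (G + A) reads, pooled over all sites and samples -- the site-set analogue
#' of the repeat editing index. Missing entries are excluded.
#'
#' @param levels Long tibble from [quantify_known()].
#' @return A one-row tibble (index, numerator, denominator) with attribute
#'   `empty` when no counts were available.
#' @export
site_set_index <- function(levels) {
  keep <- levels[!levels$missing, ]
  num <- sum(keep$alt_count); den <- sum(keep$alt_count + keep$ref_count)
  out <- tibble(index = if (den > 0) num / den else NA_real_,
                numerator = num, denominator = den)
  attr(out, "empty") <- den == 0
  out
}

#' Cross-sample consistency of editing levels
#'
#' Per-site coefficient of variation (n-1 sample standard deviation divided
#' by the mean of the non-missing levels; sites need at least two
#' non-missing levels) and the median CoV over sites.
#'
#' @param levels Long tibble from [quantify_known()].
#' @return A list with `per_site` (chrom, pos, n_levels, mean_level, cov)
#'   and `median_cov`.
#' @export
level_consistency <- function(levels) {
  per_site <- levels |>
    filter(!.data$missing, !is.na(.data$level)) |>
    group_by(.data$chrom, .data$pos) |>
    summarise(n_levels = n(), mean_level = mean(.data$level),
              cov = if (n() >= 2L && mean(.data$level) > 0)
                sd(.data$level) / mean(.data$level) else NA_real_,
              .groups = "drop")
  eligible <- per_site$cov[per_site$n_levels >= 2L & !is.na(per_site$cov)]
  list(per_site = per_site,
       median_cov = if (length(eligible)) median(eligible) else NA_real_)
}
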