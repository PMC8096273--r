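#' Editing-index parameters
#'
#' @param denominator_mode `"all_bases_at_A"` counts every base aligned to a
#'   reference adenosine in the denominator (the repeat-index definition);
#'   `"A_plus_G_only"` counts only A and G reads (the recoding site-set
#'   definition).
#' @param fold_threshold A repeat family is selected as reliably edited when
#'   its A-to-G index is at least this many fold above its next most
#'   frequent substitution (default 2; ties select).
#' @param harmonize_read_length Optional target read length (bp); reads are
#'   truncated with [harmonize_read_length()] before indexing when set.
#' @return An `index_params` list.
#' @export
index_params <- function(denominator_mode = c("all_bases_at_A", "A_plus_G_only"),
                         fold_threshold = 2, harmonize_read_length = NULL) {
  denominator_mode <- match.arg(denominator_mode)
  assert_that(fold_threshold > 1, "fold_threshold must be > 1")
  assert_that(is.null(harmonize_read_length) ||
                is_count(harmonize_read_length),
              "harmonize_read_length must be NULL or a positive integer")
  structure(list(denominator_mode = denominator_mode,
                 fold_threshold = fold_threshold,
                 harmonize_read_length = harmonize_read_length),
            class = "index_params")
}

# per (family, forward ref base) summed counts inside the family's intervals,
# split by interval strand
family_base_sums <- function(pileup, repeats) {
  if (nrow(pileup) == 0L || nrow(repeats) == 0L) {
    return(tibble(family = character(), strand = character(),
                  ref = character(), A = integer(), C = integer(),
                  G = integer(), T = integer(), coverage = integer()))
  }
  # reduce intervals within family x strand so overlapping copies count once
  red <- repeats |>
    group_by(.data$family, .data$strand, .data$chrom) |>
    reframe({
      ir <- IRanges::reduce(IRanges::IRanges(.data$start, .data$end))
      tibble(start = IRanges::start(ir), end = IRanges::end(ir))
    })
  pg <- GenomicRanges::GRanges(pileup$chrom,
                               IRanges::IRanges(pileup$pos, pileup$pos))
  rg <- GenomicRanges::GRanges(red$chrom, IRanges::IRanges(red$start, red$end))
  ov <- GenomicRanges::findOverlaps(pg, rg)
  if (length(ov) == 0L) {
    return(tibble(family = character(), strand = character(),
                  ref = character(), A = integer(), C = integer(),
                  G = integer(), T = integer(), coverage = integer()))
  }
  hits <- tibble(
    family = red$family[S4Vectors::subjectHits(ov)],
    strand = red$strand[S4Vectors::subjectHits(ov)],
    ref = pileup$ref[S4Vectors::queryHits(ov)],
    A = pileup$A[S4Vectors::queryHits(ov)],
    C = pileup$C[S4Vectors::queryHits(ov)],
    G = pileup$G[S4Vectors::queryHits(ov)],
    T = pileup$T[S4Vectors::queryHits(ov)],
    coverage = pileup$coverage[S4Vectors::queryHits(ov)])
  hits |>
    group_by(.data$family, .data$strand, .data$ref) |>
    summarise(across(c("A", "C", "G", "T", "coverage"), sum),
              .groups = "drop")
}

# turn strand-aware base sums into the 12 sense substitution indexes
spectrum_from_sums <- function(sums, denominator_mode) {
  rows <- list()
  for (t in MISMATCH_TYPES) {
    x <- substr(t, 1, 1); y <- substr(t, 3, 3)
    sel_fwd <- sums$strand == "+" & sums$ref == x
    sel_rev <- sums$strand == "-" & sums$ref == comp_base(x)
    num <- sum(sums[[y]][sel_fwd]) + sum(sums[[comp_base(y)]][sel_rev])
    den <- if (denominator_mode == "all_bases_at_A") {
      sum(sums$coverage[sel_fwd | sel_rev])
    } else {
      sum(sums[[x]][sel_fwd]) + sum(sums[[y]][sel_fwd]) +
        sum(sums[[comp_base(x)]][sel_rev]) + sum(sums[[comp_base(y)]][sel_rev])
    }
    rows[[t]] <- tibble(type = t, numerator = num, denominator = den,
                        index = if (den > 0) num / den else NA_real_,
                        defined = den > 0)
  }
  list_rbind(rows)
}

#' Per-repeat-family substitution spectra (editing index)
#'
#' For every repeat family, computes all 12 substitution indexes over the
#' union of the family's intervals: the index for X-to-Y is the number of
#' Y bases observed at sense reference-X positions divided by the total
#' counted bases there (or by X+Y bases only, depending on the denominator
#' mode). Counting is strand-aware: on minus-strand intervals a sense A-to-G
#' appears as reference-forward T-to-C and is re-oriented. A family with no
#' covered sense positions for a type gets an undefined (NA) index, not 0.
#'
#' @param pileup RNA pileup tibble.
#' @param repeats Repeat tibble (chrom, start, end, family, strand).
#' @param ref A `ref_bundle` (for genomic family abundance).
#' @param params An [index_params()].
#' @return A `family_spectrum` tibble: family, type, numerator, denominator,
#'   index, defined, genomic_abundance.
#' @export
family_index <- function(pileup, repeats, ref,
                         params = index_params()) {
  glen <- sum(Biostrings::width(ref$genome))
  abund <- repeats |>
    group_by(.data$family) |>
    summarise(genomic_abundance = sum(.data$end - .data$start + 1) / glen)
  sums <- family_base_sums(pileup, repeats)
  out <- lapply(unique(repeats$family), function(fam) {
    sp <- spectrum_from_sums(sums[sums$family == fam, ],
                             params$denominator_mode)
    mutate(sp, family = fam, .before = 1)
  })
  out <- if (length(out)) list_rbind(out) else
    tibble(family = character(), type = character(), numerator = numeric(),
           denominator = numeric(), index = numeric(), defined = logical())
  left_join(out, abund, by = "family") |>
    new_tibble_class("family_spectrum")
}

#' Select reliably edited repeat families
#'
#' A family is selected when its A-to-G index is at least `fold_threshold`
#' times the maximum of its other 11 substitution indexes (ties at exactly
#' the threshold select; a positive A-to-G index with all other indexes zero
#' selects). This keeps the global index dominated by bona fide editing
#' rather than technical mismatches.
#'
#' @param spectra A `family_spectrum` tibble from [family_index()].
#' @param params An [index_params()].
#' @return A tibble: family, index_ag, max_other_index, next_type,
#'   fold_ratio, selected.
#' @export
select_families <- function(spectra, params = index_params()) {
  spectra |>
    group_by(.data$family) |>
    summarise(
      index_ag = .data$index[.data$type == "A>G"],
      max_other_index = {
        oth <- .data$index[.data$type != "A>G" & .data$defined]
        if (length(oth)) max(oth) else NA_real_
      },
      next_type = {
        oth <- .data$index[.data$type != "A>G" & .data$defined]
        ty <- .data$type[.data$type != "A>G" & .data$defined]
        if (length(oth)) ty[which.max(oth)] else NA_character_
      }) |>
    mutate(
      fold_ratio = ifelse(
        is.na(.data$max_other_index) | .data$max_other_index == 0,
        Inf, .data$index_ag / .data$max_other_index),
      selected = !is.na(.data$index_ag) & .data$index_ag > 0 &
        .data$fold_ratio >= params$fold_threshold)
}

#' Global weighted editing index
#'
#' One coverage-weighted ratio over *all* positions of all selected
#' families: summed A-to-G numerators divided by summed denominators. This
#' is deliberately not the mean of per-family indexes -- highly covered
#' families weigh more.
#'
#' @param pileup RNA pileup tibble.
#' @param repeats Repeat tibble.
#' @param selected Character vector of selected family names (e.g. from
#'   [select_families()]).
#' @param params An [index_params()].
#' @return A one-row tibble: index, numerator, denominator, n_families.
#' @export
global_index <- function(pileup, repeats, selected,
                         params = index_params()) {
  assert_that(length(selected) >= 1, "at least one selected family required")
  reps <- repeats[repeats$family %in% selected, ]
  sums <- family_base_sums(pileup, reps)
  sums$family <- "all"
  sp <- spectrum_from_sums(sums, params$denominator_mode)
  ag <- sp[sp$type == "A>G", ]
  tibble(index = ag$index, numerator = ag$numerator,
         denominator = ag$denominator,
         n_families = length(unique(reps$family)))
}

#' Plot per-family A-to-G indexes against the strongest other substitution
#'
#' @param spectra A `family_spectrum` tibble.
#' @return A ggplot object.
#' @export
plot_family_index <- function(spectra) {
  d <- spectra |>
    filter(.data$defined) |>
    group_by(.data$family) |>
    summarise(index_ag = .data$index[.data$type == "A>G"],
              max_other = max(.data$index[.data$type != "A>G"]),
              abundance = .data$genomic_abundance[1])
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$family,
                                                     -.data$abundance))) +
    ggplot2::geom_col(ggplot2::aes(y = .data$index_ag), fill = "#2c7fb8") +
    ggplot2::geom_point(ggplot2::aes(y = .data$max_other), colour = "red") +
    ggplot2::labs(x = "repeat family (by genomic abundance)",
                  y = "A-to-G editing index",
                  caption = "red: next most frequent substitution") +
    ggplot2::theme_minimal()
}
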