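#' Filter-cascade parameters
#'
#' @param window Locality window in bp for the two neighbourhood filters:
#'   sites are removed when a different-type candidate lies within `window`
#'   bp, and kept only when a same-type candidate does (default 400).
#' @param max_second_alt_fraction A position is discarded entirely when its
#'   second-most-frequent alternate base reaches this frequency with at least
#'   two reads (default 0.01).
#' @param homopolymer_run Minimum identical-base run length that disqualifies
#'   a site lying inside or immediately adjacent to the run (default 5).
#' @param consensus_min_samples Samples a coding site must appear in to pass
#'   the recoding consensus (default 2).
#' @return A `filter_params` list.
#' @export
filter_params <- function(window = 400, max_second_alt_fraction = 0.01,
                          homopolymer_run = 5, consensus_min_samples = 2) {
  assert_that(window > 0, "window must be positive")
  assert_that(is_fraction(max_second_alt_fraction),
              "max_second_alt_fraction must be in [0,1]")
  assert_that(homopolymer_run >= 2, "homopolymer_run must be >= 2")
  assert_that(consensus_min_samples >= 1, "consensus_min_samples must be >= 1")
  structure(list(window = as.integer(window),
                 max_second_alt_fraction = max_second_alt_fraction,
                 homopolymer_run = as.integer(homopolymer_run),
                 consensus_min_samples = as.integer(consensus_min_samples)),
            class = "filter_params")
}

#' Remove multi-allelic positions
#'
#' A position showing substantial support for two different alternate bases
#' (second alternate at frequency >= `max_second_alt_fraction` with >= 2
#' reads) is a signature of alignment artifacts rather than editing; all its
#' candidates are removed.
#'
#' @param candidates Candidate tibble from [call_candidates()] (may span
#'   samples).
#' @param params A [filter_params()].
#' @return The surviving candidates.
#' @export
filter_multiallelic <- function(candidates, params = filter_params()) {
  if (nrow(candidates) == 0L) return(candidates)
  alt_counts <- cbind(candidates$A, candidates$C, candidates$G, candidates$T)
  alt_counts[cbind(seq_len(nrow(candidates)),
                   match(candidates$ref, BASES))] <- 0L
  second <- apply(alt_counts, 1L, function(x) sort(x, decreasing = TRUE)[2])
  bad <- second >= 2L &
    second / candidates$coverage >= params$max_second_alt_fraction
  candidates[!bad, ]
}

#' Remove sites in homopolymer runs
#'
#' A site lying inside, or immediately adjacent to, a run of
#' `homopolymer_run` or more identical reference bases is removed;
#' homopolymers carry elevated sequencing and alignment error rates.
#'
#' @param candidates Candidate tibble.
#' @param ref A `ref_bundle`.
#' @param params A [filter_params()].
#' @return The surviving candidates.
#' @export
filter_homopolymer <- function(candidates, ref, params = filter_params()) {
  if (nrow(candidates) == 0L) return(candidates)
  run <- params$homopolymer_run
  key <- distinct(candidates, .data$chrom, .data$pos)
  key$bad <- FALSE
  for (ch in unique(key$chrom)) {
    cs <- chrom_string(ref, ch)
    rows <- which(key$chrom == ch)
    key$bad[rows] <- in_homopolymer(cs, key$pos[rows], run)
  }
  bad_key <- key[key$bad, c("chrom", "pos")]
  anti_join(candidates, bad_key, by = c("chrom", "pos"))
}

# TRUE when pos lies inside or immediately adjacent to a run of >= `run`
# identical bases; a window of +/- run bases around the site is sufficient
# to see any qualifying run
in_homopolymer <- function(chromstr, pos, run) {
  chrlen <- nchar(chromstr)
  lo <- pmax(1L, pos - run)
  hi <- pmin(chrlen, pos + run)
  vapply(substring(chromstr, lo, hi), function(w) {
    max(rle(strsplit(w, "")[[1]])$lengths) >= run
  }, logical(1), USE.NAMES = FALSE)
}

#' Remove heterogeneous clusters
#'
#' A candidate is removed when any candidate of a *different* mismatch type
#' (same sample) lies within `window` bp. Mixed-type clusters are the typical
#' signature of reads mapped to the wrong copy of a duplicated locus.
#' Evaluated on a snapshot of the input: removing a neighbour never rescues a
#' site within the same pass.
#'
#' @param candidates Candidate tibble.
#' @param params A [filter_params()].
#' @return The surviving candidates.
#' @export
filter_heterogeneous_cluster <- function(candidates, params = filter_params()) {
  neighbour_counts(candidates, params$window, keep_if =
                     function(same, total) (total - same) == 0L)
}

#' Remove isolated sites
#'
#' A candidate survives only with at least one additional candidate of the
#' *same* mismatch type (same sample) within `window` bp; genuine editing
#' arrives in clusters of neighbouring sites. Snapshot semantics as in
#' [filter_heterogeneous_cluster()].
#'
#' @param candidates Candidate tibble.
#' @param params A [filter_params()].
#' @return The surviving candidates.
#' @export
filter_isolated <- function(candidates, params = filter_params()) {
  neighbour_counts(candidates, params$window, keep_if =
                     function(same, total) same >= 2L)
}

# shared windowed neighbour counting; `same` includes the site itself
neighbour_counts <- function(candidates, window, keep_if) {
  if (nrow(candidates) == 0L) return(candidates)
  keep <- logical(nrow(candidates))
  grp <- paste(candidates$sample_id, candidates$chrom)
  for (g in unique(grp)) {
    rows <- which(grp == g)
    p <- candidates$pos[rows]
    ty <- candidates$type[rows]
    o <- order(p)
    ps <- p[o]
    total <- findInterval(p + window, ps) - findInterval(p - window - 1L, ps)
    same <- integer(length(rows))
    for (t in unique(ty)) {
      sel <- ty == t
      pt <- sort(p[sel])
      same[sel] <- findInterval(p[sel] + window, pt) -
        findInterval(p[sel] - window - 1L, pt)
    }
    keep[rows] <- keep_if(same, total)
  }
  candidates[keep, ]
}

#' Apply the full filter cascade
#'
#' Runs the post-candidate filters in fixed order -- multi-allelic,
#' homopolymer, heterogeneous-cluster, isolated-site -- recording exact
#' per-step survival counts and the mismatch spectrum after every step.
#' Filters only ever remove candidates; the cascade is idempotent.
#'
#' @param candidates Candidate tibble (one or more samples).
#' @param ref A `ref_bundle`.
#' @param params A [filter_params()].
#' @return A `cascade_result` with `sites` (surviving candidates), `report`
#'   (tibble: step, sites_in, sites_out, removed), `spectra` (long tibble:
#'   step x type counts) and `params`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
apply_cascade <- function(candidates, ref, params = filter_params()) {
  steps <- list(
    multiallelic = function(x) filter_multiallelic(x, params),
    homopolymer = function(x) filter_homopolymer(x, ref, params),
    heterogeneous_cluster = function(x) filter_heterogeneous_cluster(x, params),
    isolated = function(x) filter_isolated(x, params)
  )
  report <- list()
  spectra <- list(
    mutate(mismatch_spectrum(candidates), step = "input", .before = 1))
  cur <- candidates
  for (nm in names(steps)) {
    n_in <- nrow(cur)
    cur <- steps[[nm]](cur)
    report[[nm]] <- tibble(step = nm, sites_in = n_in, sites_out = nrow(cur),
                           removed = n_in - nrow(cur))
    spectra[[length(spectra) + 1L]] <-
      mutate(mismatch_spectrum(cur), step = nm, .before = 1)
  }
  structure(list(sites = cur, report = list_rbind(report),
                 spectra = list_rbind(spectra), params = params),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result>\n")
  print(x$report)
  n <- nrow(x$sites)
  ag <- sum(x$sites$type == "A>G")
  cat(sprintf("  surviving sites: %d (%.1f%% A>G)\n",
              n, if (n > 0) 100 * ag / n else 0))
  invisible(x)
}

#' @rdname apply_cascade
#' @param x A `cascade_result`.
#' @param ... Unused.
#' @export
tidy.cascade_result <- function(x, ...) x$report

#' @rdname apply_cascade
#' @export
glance.cascade_result <- function(x, ...) {
  n <- nrow(x$sites)
  tibble(n_input = x$report$sites_in[1], n_surviving = n,
         n_steps = nrow(x$report),
         frac_a_to_g = if (n > 0) sum(x$sites$type == "A>G") / n else NA_real_)
}

#' @rdname apply_cascade
#' @param object A `cascade_result`.
#' @export
autoplot.cascade_result <- function(object, ...) {
  d <- bind_rows(
    tibble(step = "input", sites = object$report$sites_in[1]),
    transmute(object$report, step = .data$step, sites = .data$sites_out))
  d$step <- factor(d$step, levels = d$step)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$sites)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "candidate sites remaining") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Merge per-sample site lists
#'
#' Unifies surviving candidates across samples, keyed by (chrom, pos, ref,
#' alt). Per-sample coverage, alt count and frequency are retained in a
#' `per_sample` list-column and the number of detecting samples recorded.
#'
#' @param sites Candidate/site tibble spanning samples.
#' @param params A [filter_params()] (unused fields tolerated).
#' @return A merged site tibble: chrom, pos, ref, alt, type,
#'   n_samples_detected, samples, mean_frequency, total_alt, total_coverage,
#'   per_sample.
#' @export
merge_samples <- function(sites, params = filter_params()) {
  if (nrow(sites) == 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), type = character(),
                  n_samples_detected = integer(), samples = character(),
                  mean_frequency = numeric(), total_alt = integer(),
                  total_coverage = integer(), per_sample = list()))
  }
  sites |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt, .data$type) |>
    summarise(
      n_samples_detected = n_distinct(.data$sample_id),
      samples = paste(sort(unique(.data$sample_id)), collapse = ","),
      mean_frequency = mean(.data$frequency),
      total_alt = sum(.data$alt_count),
      total_coverage = sum(.data$coverage),
      per_sample = list(pick("sample_id", "coverage", "alt_count",
                             "frequency")),
      .groups = "drop") |>
    arrange(.data$chrom, .data$pos, .data$alt)
}
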