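#' Hyper-editing rescue parameters
#'
#' Thresholds for rescuing heavily edited reads by alignment in an
#' A-to-G-masked sequence space. A rescued read must carry a dense,
#' homogeneous cluster of A-to-G mismatches: at least
#' `min_same_type_mismatches` of them, covering at least
#' `min_edit_fraction_of_read` of the read length, and making up at least
#' `min_edit_fraction_of_mismatches` of all its mismatches.
#'
#' @param kmer Seed length for the masked-space index (default 21).
#' @param min_same_type_mismatches Minimum A-to-G mismatches per read
#'   (default 5).
#' @param min_edit_fraction_of_read Minimum A-to-G mismatches as a fraction
#'   of read length (default 0.05).
#' @param min_edit_fraction_of_mismatches Minimum fraction of all mismatches
#'   that are A-to-G (default 0.6).
#' @param require_unique_locus Reject reads whose seeds resolve to more than
#'   one locus, or only to repeated k-mers (default TRUE).
#' @param max_masked_mismatch_fraction Maximum mismatch fraction allowed in
#'   the masked space for the ungapped end-to-end verification (default
#'   0.05), absorbing non-A-to-G sequencing errors.
#' @return A `hyper_params` list.
#' @export
hyper_params <- function(kmer = 21, min_same_type_mismatches = 5,
                         min_edit_fraction_of_read = 0.05,
                         min_edit_fraction_of_mismatches = 0.6,
                         require_unique_locus = TRUE,
                         max_masked_mismatch_fraction = 0.05) {
  assert_that(kmer >= 11, "kmer must be >= 11")
  assert_that(min_same_type_mismatches >= 1,
              "min_same_type_mismatches must be >= 1")
  assert_that(is_fraction(min_edit_fraction_of_read, hi = 1) &&
                min_edit_fraction_of_read > 0,
              "min_edit_fraction_of_read must be in (0,1]")
  assert_that(is_fraction(min_edit_fraction_of_mismatches, hi = 1) &&
                min_edit_fraction_of_mismatches > 0,
              "min_edit_fraction_of_mismatches must be in (0,1]")
  assert_that(is.logical(require_unique_locus), "require_unique_locus must be logical")
  assert_that(is_fraction(max_masked_mismatch_fraction),
              "max_masked_mismatch_fraction must be in [0,1]")
  structure(list(kmer = as.integer(kmer),
                 min_same_type_mismatches = as.integer(min_same_type_mismatches),
                 min_edit_fraction_of_read = min_edit_fraction_of_read,
                 min_edit_fraction_of_mismatches = min_edit_fraction_of_mismatches,
                 require_unique_locus = require_unique_locus,
                 max_masked_mismatch_fraction = max_masked_mismatch_fraction),
            class = "hyper_params")
}

#' Transform a sequence into A-to-G-masked space
#'
#' @param x Character vector of DNA sequences.
#' @param from,to Bases of the transform (default A to G).
#' @return The transformed sequences.
#' @export
mask_sequence <- function(x, from = "A", to = "G") {
  chartr(from, to, x)
}

#' Build a seed index over the masked genome
#'
#' Indexes every k-mer of the A-to-G-transformed forward genome and of the
#' T-to-C-transformed forward genome (the reverse-strand space realised on
#' the forward sequence). K-mers occurring more than once across both spaces
#' are flagged non-unique; seeds landing on them cannot place a read.
#'
#' @param ref A `ref_bundle`.
#' @param params A [hyper_params()] (for the seed length).
#' @param transform Length-2 character vector `c(from, to)` of the masking
#'   transform on the editing-sense strand; default `c("A", "G")`. Other
#'   transforms reproduce the per-type specificity control.
#' @return A `masked_index` list.
#' @export
build_masked_index <- function(ref, params = hyper_params(),
                               transform = c("A", "G")) {
  k <- params$kmer
  lens <- Biostrings::width(ref$genome)
  if (any(lens < k)) rlang::abort("genome contig shorter than the seed k-mer")
  from <- transform[1]; to <- transform[2]
  from_rc <- comp_base(from); to_rc <- comp_base(to)
  tabs <- lapply(names(ref$genome), function(ch) {
    cs <- chrom_string(ref, ch)
    n <- nchar(cs) - k + 1L
    starts <- seq_len(n)
    fwd <- substring(chartr(from, to, cs), starts, starts + k - 1L)
    rev <- substring(chartr(from_rc, to_rc, cs), starts, starts + k - 1L)
    tibble(kmer = c(fwd, rev),
           chrom = ch, pos = c(starts, starts),
           strand = rep(c("+", "-"), each = n))
  })
  tab <- list_rbind(tabs)
  dup <- duplicated(tab$kmer) | duplicated(tab$kmer, fromLast = TRUE)
  structure(list(kmers = tab$kmer, chrom = tab$chrom, pos = tab$pos,
                 strand = tab$strand, is_unique = !dup, k = k,
                 transform = c(from, to), ref = ref),
            class = "masked_index")
}

#' @export
print.masked_index <- function(x, ...) {
  cat(sprintf("<masked_index> %d-mers: %d entries (%.1f%% unique), transform %s->%s\n",
              x$k, length(x$kmers), 100 * mean(x$is_unique),
              x$transform[1], x$transform[2]))
  invisible(x)
}

#' Rescue heavily edited reads by masked realignment
#'
#' Each read is transformed into the masked space, seed-anchored at several
#' offsets against the masked genome (both strands), and verified ungapped
#' end-to-end at the implied locus. Mismatches are then recovered against the
#' *unmasked* reference, and the read is kept only when its A-to-G cluster
#' meets every [hyper_params()] criterion. Reads anchoring to repeated
#' k-mers only, or to more than one locus, are rejected when
#' `require_unique_locus` is set.
#'
#' @param reads FASTQ path, or a tibble with `read_id` and `seq` columns.
#' @param index A `masked_index` from [build_masked_index()].
#' @param params A [hyper_params()].
#' @return A `hyper_alignments` tibble: read_id, chrom, start, strand,
#'   same_type_count, other_type_count, masked_mismatches and a `mismatches`
#'   list-column of (pos, ref, alt) tibbles against the unmasked reference.
#'   Attribute `counts` tallies input/unmatched/ambiguous/filtered reads.
#' @export
rescue_reads <- function(reads, index, params = hyper_params()) {
  if (is.character(reads)) {
    x <- Biostrings::readDNAStringSet(reads, format = "fastq")
    reads <- tibble(read_id = sub("\\s.*$", "", names(x)),
                    seq = as.character(x))
  }
  k <- index$k
  from <- index$transform[1]; to <- index$transform[2]
  ref <- index$ref
  chromstrs <- lapply(names(ref$genome), function(ch) chrom_string(ref, ch))
  names(chromstrs) <- names(ref$genome)
  masked_fwd <- lapply(chromstrs, function(s) chartr(from, to, s))
  masked_rev <- lapply(chromstrs, function(s)
    chartr(comp_base(from), comp_base(to), s))

  n_unmatched <- 0L; n_ambiguous <- 0L; n_filtered <- 0L
  L_all <- nchar(reads$seq)
  q_fwd_all <- chartr(from, to, reads$seq)
  q_rev_all <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(q_fwd_all)))

  # batch every seed of every read into one match() against the index
  seed_tbl <- list_rbind(lapply(seq_len(nrow(reads)), function(i) {
    L <- L_all[i]
    if (L < k) return(NULL)
    offs <- unique(c(seq(1L, L - k + 1L, by = k), L - k + 1L))
    tibble(read = i, off = rep(offs, 2L),
           strand = rep(c("+", "-"), each = length(offs)),
           seed = c(substring(q_fwd_all[i], offs, offs + k - 1L),
                    substring(q_rev_all[i], offs, offs + k - 1L)))
  }))
  if (nrow(seed_tbl %||% tibble()) > 0L) {
    seed_tbl$hit <- match(seed_tbl$seed, index$kmers)
  }
  seed_by_read <- if (!is.null(seed_tbl) && nrow(seed_tbl) > 0L)
    split(seed_tbl, seed_tbl$read) else list()

  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    r <- reads$seq[i]
    L <- L_all[i]
    st <- seed_by_read[[as.character(i)]]
    if (is.null(st)) { n_unmatched <- n_unmatched + 1L; next }
    q_fwd <- q_fwd_all[i]; q_rev <- q_rev_all[i]

    found <- !is.na(st$hit)
    # uniqueness is a census over both strand spaces, so a duplicated k-mer
    # can never anchor; a unique hit recorded for the other space simply
    # does not occur in this one
    amb <- found & !index$is_unique[st$hit]
    ok <- found & !amb & index$strand[st$hit] == st$strand
    if (!any(ok)) {
      if (any(amb)) n_ambiguous <- n_ambiguous + 1L
      else n_unmatched <- n_unmatched + 1L
      next
    }
    loci <- distinct(tibble(chrom = index$chrom[st$hit[ok]],
                            strand = st$strand[ok],
                            start = index$pos[st$hit[ok]] - st$off[ok] + 1L))

    # ungapped end-to-end verification in masked space, for every distinct
    # candidate locus; a stray single-seed hit that does not verify is not
    # an ambiguity
    verified <- list()
    for (li in seq_len(nrow(loci))) {
      l <- loci[li, ]
      chrlen <- nchar(chromstrs[[l$chrom]])
      if (l$start < 1L || l$start + L - 1L > chrlen) next
      span <- c(l$start, l$start + L - 1L)
      masked_ref <- if (l$strand == "+")
        substring(masked_fwd[[l$chrom]], span[1], span[2])
      else substring(masked_rev[[l$chrom]], span[1], span[2])
      q <- if (l$strand == "+") q_fwd else q_rev
      mm <- hamming(q, masked_ref)
      if (mm / L <= params$max_masked_mismatch_fraction) {
        verified[[length(verified) + 1L]] <- c(as.list(l), masked_mm = mm)
      }
    }
    if (length(verified) == 0L) { n_unmatched <- n_unmatched + 1L; next }
    if (length(verified) > 1L) {
      if (params$require_unique_locus) { n_ambiguous <- n_ambiguous + 1L; next }
      verified <- verified[order(vapply(verified, `[[`, 0, "masked_mm"))]
    }
    best <- verified[[1]]
    span <- c(best$start, best$start + L - 1L)
    masked_mm <- best$masked_mm

    # recover mismatches against the unmasked reference
    oriented <- if (best$strand == "+") r else revcomp_chr(r)
    gseq <- substring(chromstrs[[best$chrom]], span[1], span[2])
    gb <- strsplit(gseq, "")[[1]]
    rb <- strsplit(oriented, "")[[1]]
    mmi <- which(gb != rb)
    same_ref <- if (best$strand == "+") from else comp_base(from)
    same_alt <- if (best$strand == "+") to else comp_base(to)
    is_same <- gb[mmi] == same_ref & rb[mmi] == same_alt
    same_n <- sum(is_same); other_n <- length(mmi) - same_n
    if (same_n < params$min_same_type_mismatches ||
        same_n < params$min_edit_fraction_of_read * L ||
        (same_n + other_n > 0L &&
         same_n / (same_n + other_n) < params$min_edit_fraction_of_mismatches)) {
      n_filtered <- n_filtered + 1L; next
    }
    out[[i]] <- tibble(
      read_id = reads$read_id[i], chrom = best$chrom, start = best$start,
      strand = best$strand, same_type_count = same_n,
      other_type_count = other_n, masked_mismatches = masked_mm,
      mismatches = list(tibble(pos = span[1] + mmi - 1L, ref = gb[mmi],
                               alt = rb[mmi])))
  }
  res <- out[!vapply(out, is.null, TRUE)]
  res <- if (length(res)) list_rbind(res) else
    tibble(read_id = character(), chrom = character(), start = integer(),
           strand = character(), same_type_count = integer(),
           other_type_count = integer(), masked_mismatches = integer(),
           mismatches = list())
  attr(res, "counts") <- c(input = nrow(reads), rescued = nrow(res),
                           unmatched = n_unmatched, ambiguous = n_ambiguous,
                           filtered = n_filtered)
  res
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Call editing sites from rescued hyper-alignments
#'
#' Collapses the sense A-to-G mismatches of rescued reads into unique
#' genomic positions with per-position read support, reporting both unique
#' sites and total per-read events.
#'
#' @param hyper_alignments Output of [rescue_reads()].
#' @param min_support Minimum rescued reads covering a site (default 1).
#' @return A site tibble (chrom, pos, ref, alt, strand, type, support,
#'   source = "hyper") with attributes `n_sites` and `n_events`.
#' @export
call_hyper_sites <- function(hyper_alignments, min_support = 1) {
  if (nrow(hyper_alignments) == 0L) {
    out <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), strand = character(), type = character(),
                  support = integer(), source = character())
    attr(out, "n_sites") <- 0L; attr(out, "n_events") <- 0L
    return(out)
  }
  long <- hyper_alignments |>
    select("read_id", "chrom", "strand", "mismatches") |>
    unnest("mismatches")
  sense <- long |>
    filter((.data$strand == "+" & .data$ref == "A" & .data$alt == "G") |
             (.data$strand == "-" & .data$ref == "T" & .data$alt == "C"))
  out <- sense |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt, .data$strand) |>
    summarise(support = n(), .groups = "drop") |>
    filter(.data$support >= min_support) |>
    mutate(type = "A>G", source = "hyper") |>
    select("chrom", "pos", "ref", "alt", "strand", "type", "support",
           "source") |>
    arrange(.data$chrom, .data$pos)
  attr(out, "n_sites") <- nrow(out)
  attr(out, "n_events") <- sum(out$support)
  out
}
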