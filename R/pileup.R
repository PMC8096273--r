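#' Detection thresholds
#'
#' The per-base and per-site cutoffs used throughout detection: `trim_ends`
#' aligned bases ignored at both read ends, bases below `min_base_quality`
#' discarded, and candidate sites required to reach `min_coverage` reads,
#' `min_frequency` mismatch frequency and `min_alt_count` reads supporting
#' the variation. The alt-read floor follows the convention of matched
#' DNA/RNA editing callers, which by default demand three reads supporting a
#' variant; without it a single sequencing-error read at moderate coverage
#' already clears a 1\% frequency cutoff.
#'
#' @param trim_ends Aligned bases trimmed from each read end (default 10).
#' @param min_base_quality Minimum Phred base quality (default 30).
#' @param min_coverage Minimum filtered coverage at a site (default 10).
#' @param min_frequency Minimum mismatch frequency (default 0.01).
#' @param min_alt_count Minimum reads carrying the alternate base (default 3).
#' @return A `detection_thresholds` list.
#' @export
detection_thresholds <- function(trim_ends = 10, min_base_quality = 30,
                                 min_coverage = 10, min_frequency = 0.01,
                                 min_alt_count = 3) {
  assert_that(trim_ends >= 0, "trim_ends must be >= 0")
  assert_that(min_base_quality >= 0, "min_base_quality must be >= 0")
  assert_that(min_coverage >= 1, "min_coverage must be >= 1")
  assert_that(is_fraction(min_frequency) && min_frequency > 0,
              "min_frequency must be in (0, 1]")
  assert_that(min_alt_count >= 1, "min_alt_count must be >= 1")
  structure(list(trim_ends = as.integer(trim_ends),
                 min_base_quality = as.integer(min_base_quality),
                 min_coverage = as.integer(min_coverage),
                 min_frequency = min_frequency,
                 min_alt_count = as.integer(min_alt_count)),
            class = "detection_thresholds")
}

#' Read aligned records from SAM/BAM
#'
#' Yields mapped, primary, non-duplicate records with their CIGAR strings.
#' Unmapped, secondary, supplementary and duplicate-flagged records are
#' skipped and counted. SAM input is converted through
#' [Rsamtools::asBam()].
#'
#' @param path SAM or BAM file.
#' @param ref Optional `ref_bundle`; when given, the `@SQ` header is checked
#'   against the genome and a mismatch is an error.
#' @return An alignment tibble (qname, flag, chrom, pos, mapq, cigar, seq,
#'   qual, reverse) with attribute `skipped`, a named integer vector
#'   counting skipped records by reason.
#' @export
read_alignments <- function(path, ref = NULL) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE))
  }
  if (!is.null(ref)) {
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    miss <- setdiff(names(hdr), names(ref$genome))
    bad_len <- names(hdr)[!is.na(match(names(hdr), names(ref$genome))) &
                            hdr != Biostrings::width(ref$genome)[
                              match(names(hdr), names(ref$genome))]]
    if (length(miss) || length(bad_len)) {
      rlang::abort(sprintf(
        "alignment header does not match the reference (unknown contigs: %s; length mismatches: %s)",
        paste(miss, collapse = ",") %||% "-",
        paste(bad_len, collapse = ",") %||% "-"))
    }
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- r$flag
  unmapped <- bitwAnd(flag, 4L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L
  supplementary <- bitwAnd(flag, 2048L) > 0L
  duplicate <- bitwAnd(flag, 1024L) > 0L
  keep <- !(unmapped | secondary | supplementary | duplicate)
  out <- tibble(
    qname = r$qname[keep], flag = flag[keep],
    chrom = as.character(r$rname[keep]), pos = r$pos[keep],
    mapq = r$mapq[keep], cigar = r$cigar[keep],
    seq = as.character(r$seq[keep]), qual = as.character(r$qual[keep]),
    reverse = bitwAnd(flag[keep], 16L) > 0L
  )
  attr(out, "skipped") <- c(
    unmapped = sum(unmapped), secondary = sum(secondary & !unmapped),
    supplementary = sum(supplementary & !unmapped & !secondary),
    duplicate = sum(duplicate & !unmapped & !secondary & !supplementary))
  out
}

#' Build a filtered per-position pileup
#'
#' Converts alignments into per-position base counts. For every read the
#' first and last `trim_ends` *aligned* bases contribute nothing (soft-clipped
#' bases do not count towards the trim), bases below `min_base_quality`
#' contribute nothing, and deleted/skipped reference positions and `N` bases
#' are never counted. Only positions with at least one counted base are
#' emitted. Counts are recorded in reference-forward orientation; strand
#' resolution is left to annotation-aware consumers.
#'
#' @param alignments Alignment tibble from [read_alignments()] or the
#'   simulator.
#' @param ref A `ref_bundle` providing the genome.
#' @param thresholds A [detection_thresholds()].
#' @return A pileup tibble: chrom, pos (1-based), ref, A, C, G, T, coverage.
#' @export
build_pileup <- function(alignments, ref, thresholds = detection_thresholds()) {
  trim <- thresholds$trim_ends
  minq <- thresholds$min_base_quality
  chunk_size <- 50000L
  out <- lapply(names(ref$genome), function(ch) {
    chrlen <- Biostrings::width(ref$genome)[[match(ch, names(ref$genome))]]
    rows <- which(alignments$chrom == ch)
    if (length(rows) == 0L) return(NULL)
    counts <- integer(4L * chrlen)
    for (start_i in seq(1L, length(rows), by = chunk_size)) {
      idx <- rows[start_i:min(start_i + chunk_size - 1L, length(rows))]
      simple <- grepl("^[0-9]+M$", alignments$cigar[idx])
      if (any(simple)) {
        counts <- counts + pileup_simple(
          alignments$pos[idx[simple]], alignments$seq[idx[simple]],
          alignments$qual[idx[simple]], trim, minq, chrlen)
      }
      for (j in idx[!simple]) {
        counts <- pileup_one_cigar(counts, alignments$pos[j],
                                   alignments$cigar[j], alignments$seq[j],
                                   alignments$qual[j], trim, minq, chrlen,
                                   alignments$qname[j])
      }
    }
    m <- matrix(counts, nrow = 4L)
    cov <- colSums(m)
    pos <- which(cov > 0L)
    if (length(pos) == 0L) return(NULL)
    tibble(chrom = ch, pos = pos,
           ref = base_at(chrom_string(ref, ch), pos),
           A = m[1L, pos], C = m[2L, pos], G = m[3L, pos], T = m[4L, pos],
           coverage = as.integer(cov[pos]))
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  A = integer(), C = integer(), G = integer(), T = integer(),
                  coverage = integer()))
  }
  list_rbind(out)
}

# vectorised counting for all-match CIGARs
pileup_simple <- function(pos, seq, qual, trim, minq, chrlen) {
  L <- nchar(seq)
  off <- sequence(L) - 1L
  rp <- rep.int(pos, L) + off
  Lr <- rep.int(L, L)
  keep <- off >= trim & off <= Lr - 1L - trim
  qs <- as.integer(charToRaw(paste(qual, collapse = ""))) - 33L
  keep <- keep & qs >= minq
  bs <- as.integer(charToRaw(paste(seq, collapse = "")))
  code <- BASE_CODE[bs + 1L]
  keep <- keep & code > 0L & rp >= 1L & rp <= chrlen
  tabulate((rp[keep] - 1L) * 4L + code[keep], nbins = 4L * chrlen)
}

# general CIGAR walk for one read; trimming counts aligned (M/=/X) bases only
pileup_one_cigar <- function(counts, pos, cigar, seq, qual, trim, minq,
                             chrlen, qname) {
  ops <- parse_cigar(cigar)
  if (is.null(ops)) {
    rlang::warn(sprintf("skipping read %s: malformed CIGAR '%s'", qname, cigar))
    return(counts)
  }
  refp <- integer(0); qoff <- integer(0)
  rp <- pos; qp <- 1L
  for (k in seq_len(nrow(ops))) {
    n <- ops$n[k]
    switch(ops$op[k],
      "M" = , "=" = , "X" = {
        refp <- c(refp, rp:(rp + n - 1L)); qoff <- c(qoff, qp:(qp + n - 1L))
        rp <- rp + n; qp <- qp + n
      },
      "I" = , "S" = { qp <- qp + n },
      "D" = , "N" = { rp <- rp + n },
      "H" = , "P" = NULL,
      {
        rlang::warn(sprintf("skipping read %s: unsupported CIGAR op '%s'",
                            qname, ops$op[k]))
        return(counts)
      })
  }
  n_aligned <- length(refp)
  if (n_aligned == 0L) return(counts)
  rank <- seq_len(n_aligned)
  keep <- rank > trim & rank <= n_aligned - trim
  qs <- as.integer(charToRaw(qual)) - 33L
  keep <- keep & qs[qoff] >= minq
  code <- BASE_CODE[as.integer(charToRaw(seq))[qoff] + 1L]
  keep <- keep & code > 0L & refp >= 1L & refp <= chrlen
  if (!any(keep)) return(counts)
  counts + tabulate((refp[keep] - 1L) * 4L + code[keep], nbins = 4L * chrlen)
}

parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" ||
      !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)) return(NULL)
  n <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  data.frame(n = n, op = op, stringsAsFactors = FALSE)
}

#' Pool pileups across samples
#'
#' Sums per-position base counts over a list of pileups (e.g. all RNA
#' samples), for coverage-weighted global statistics.
#'
#' @param pileups List of pileup tibbles on the same reference.
#' @return A pooled pileup tibble.
#' @export
pool_pileups <- function(pileups) {
  list_rbind(pileups) |>
    group_by(.data$chrom, .data$pos, .data$ref) |>
    summarise(across(c("A", "C", "G", "T", "coverage"), sum),
              .groups = "drop") |>
    arrange(.data$chrom, .data$pos)
}

#' Truncate reads to a common length
#'
#' Keeps the first `target_length` bases of every read *in read orientation*
#' (for reverse-strand records this is the 3' end of the stored
#' reference-forward sequence), recomputing POS and CIGAR. The editing index
#' is sensitive to read length, so samples sequenced at different lengths
#' should be harmonized before indexes are compared.
#'
#' @param alignments Alignment tibble.
#' @param target_length Target read length in bp (must be positive).
#' @return The truncated alignment tibble.
#' @export
harmonize_read_length <- function(alignments, target_length) {
  assert_that(is_count(target_length), "target_length must be a positive integer")
  if (nrow(alignments) == 0L) return(alignments)
  out <- alignments
  for (i in seq_len(nrow(out))) {
    qlen <- nchar(out$seq[i])
    if (qlen <= target_length) next
    tr <- truncate_cigar(out$cigar[i], qlen, target_length, out$reverse[i])
    if (is.null(tr)) {
      rlang::warn(sprintf("dropping read %s: cannot truncate CIGAR '%s'",
                          out$qname[i], out$cigar[i]))
      out$cigar[i] <- NA_character_
      next
    }
    out$pos[i] <- out$pos[i] + tr$pos_shift
    out$cigar[i] <- tr$cigar
    out$seq[i] <- substring(out$seq[i], tr$q_from, tr$q_to)
    out$qual[i] <- substring(out$qual[i], tr$q_from, tr$q_to)
  }
  out[!is.na(out$cigar), ]
}

# keep `target` query bases: the first in read orientation
truncate_cigar <- function(cigar, qlen, target, reverse) {
  ops <- parse_cigar(cigar)
  if (is.null(ops)) return(NULL)
  # query interval to keep, in reference-forward (SEQ) coordinates
  if (!reverse) { q_from <- 1L; q_to <- target }
  else { q_from <- qlen - target + 1L; q_to <- qlen }
  qp <- 1L
  pos_shift <- 0L
  new <- list()
  for (k in seq_len(nrow(ops))) {
    n <- ops$n[k]; op <- ops$op[k]
    consumes_q <- op %in% c("M", "=", "X", "I", "S")
    consumes_r <- op %in% c("M", "=", "X", "D", "N")
    if (!consumes_q) {
      # D/N inside the kept window are kept; before it they shift POS
      if (qp > q_from && qp <= q_to + 1L && length(new) > 0L) {
        new[[length(new) + 1L]] <- c(n, op)
      } else if (qp <= q_from && consumes_r) {
        pos_shift <- pos_shift + n
      }
      next
    }
    lo <- qp; hi <- qp + n - 1L
    qp <- qp + n
    keep_lo <- max(lo, q_from); keep_hi <- min(hi, q_to)
    pre <- max(0L, min(hi, q_from - 1L) - lo + 1L)   # query bases cut before window
    if (pre > 0L && consumes_r) pos_shift <- pos_shift + pre
    if (keep_hi >= keep_lo) {
      new[[length(new) + 1L]] <- c(keep_hi - keep_lo + 1L, op)
    }
  }
  if (length(new) == 0L) return(NULL)
  cig <- paste(vapply(new, function(x) paste0(x[1], x[2]), character(1)),
               collapse = "")
  list(cigar = cig, pos_shift = pos_shift, q_from = q_from, q_to = q_to)
}
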