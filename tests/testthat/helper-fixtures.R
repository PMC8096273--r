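# Shared fixtures: small configurations, hand-built references/alignments and
# brute-force oracles that the scanning implementations are checked against.

small_config <- function(seed = 7, ...) {
  args <- list(
    genome_length = 40000, n_rna_samples = 2,
    repeat_families = list(
      list(name = "ANGEL", unit_length = 150, copies = 20, palindromic = TRUE),
      list(name = "HE1_DR1", unit_length = 300, copies = 20, palindromic = FALSE)
    ),
    n_genes = 4, hyper_molecules = 10, seed = seed
  )
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

# a reference bundle built directly from given chromosome strings
manual_ref <- function(seqs, repeats = NULL, genes = NULL) {
  genome <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(seqs))
  empty_rep <- tibble::tibble(chrom = character(), start = integer(),
                              end = integer(), family = character(),
                              strand = character(), copy_id = character())
  empty_gene <- tibble::tibble(gene_id = character(), transcript_id = character(),
                               chrom = character(), strand = character(),
                               tx_start = integer(), tx_end = integer(),
                               cds_start = integer(), cds_end = integer())
  structure(list(genome = genome, repeats = repeats %||% empty_rep,
                 genes = genes %||% empty_gene),
            class = "ref_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# alignment tibble row(s) in the internal layout
manual_aln <- function(chrom, pos, seq, qual = NULL, cigar = NULL, flag = 0L,
                       qname = NULL) {
  n <- max(length(chrom), length(pos), length(seq))
  chrom <- rep_len(chrom, n); pos <- rep_len(as.integer(pos), n)
  seq <- rep_len(seq, n); flag <- rep_len(as.integer(flag), n)
  qual <- rep_len(qual %||% strrep("J", max(nchar(seq))), n)
  qual <- substr(qual, 1, nchar(seq))
  cigar <- rep_len(cigar %||% paste0(nchar(seq), "M"), n)
  tibble::tibble(
    qname = qname %||% sprintf("r%03d", seq_len(n)),
    flag = flag, chrom = chrom, pos = pos, mapq = 60L, cigar = cigar,
    seq = seq, qual = qual, reverse = bitwAnd(flag, 16L) > 0L)
}

# candidate tibble for filter tests (counts consistent with alt/coverage)
manual_candidates <- function(pos, type, sample_id = "s1", chrom = "chr1",
                              coverage = 50L, alt_count = 5L) {
  n <- length(pos)
  type <- rep_len(type, n)
  ref <- substr(type, 1, 1); alt <- substr(type, 3, 3)
  counts <- matrix(0L, nrow = n, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  coverage <- rep_len(as.integer(coverage), n)
  alt_count <- rep_len(as.integer(alt_count), n)
  for (i in seq_len(n)) {
    counts[i, ref[i]] <- coverage[i] - alt_count[i]
    counts[i, alt[i]] <- alt_count[i]
  }
  tibble::tibble(
    sample_id = rep_len(sample_id, n), chrom = rep_len(chrom, n),
    pos = as.integer(pos), ref = ref, alt = alt, type = type,
    coverage = coverage, alt_count = alt_count,
    frequency = alt_count / coverage,
    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
    T = counts[, "T"], dna_status = "homozygous_ref")
}

# brute-force all-pairs window filters (oracle for the scanning versions)
brute_heterogeneous <- function(cand, window) {
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    others <- cand[-i, ]
    bad <- others$sample_id == cand$sample_id[i] &
      others$chrom == cand$chrom[i] &
      abs(others$pos - cand$pos[i]) <= window &
      others$type != cand$type[i]
    keep[i] <- !any(bad)
  }
  cand[keep, ]
}

brute_isolated <- function(cand, window) {
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    others <- cand[-i, ]
    support <- others$sample_id == cand$sample_id[i] &
      others$chrom == cand$chrom[i] &
      abs(others$pos - cand$pos[i]) <= window &
      others$type == cand$type[i]
    keep[i] <- any(support)
  }
  cand[keep, ]
}

# naive per-read pileup counter (oracle for build_pileup on M-only reads)
brute_pileup <- function(aln, ref, thresholds) {
  counts <- list()
  for (i in seq_len(nrow(aln))) {
    L <- nchar(aln$seq[i])
    b <- strsplit(aln$seq[i], "")[[1]]
    q <- utf8ToInt(aln$qual[i]) - 33L
    for (o in seq_len(L)) {
      if (o <= thresholds$trim_ends || o > L - thresholds$trim_ends) next
      if (q[o] < thresholds$min_base_quality) next
      if (!b[o] %in% c("A", "C", "G", "T")) next
      key <- paste(aln$chrom[i], aln$pos[i] + o - 1L, b[o])
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  counts
}

site_key <- function(x) paste(x$chrom, x$pos, x$sample_id %||% "", x$type %||% "")

# a two-gene reference carrying the same CDS on plus and minus strands
recoding_ref <- function(cds) {
  utr <- strrep("C", 30)
  plus_gene <- paste0(utr, cds, "TAA", utr)
  minus_gene <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(plus_gene)))
  pad <- strrep("T", 100)
  seqs <- paste0(pad, plus_gene, pad, minus_gene, pad)
  w <- nchar(plus_gene)
  genes <- tibble::tibble(
    gene_id = c("gp", "gm"), transcript_id = c("gp.t1", "gm.t1"),
    chrom = "chr1", strand = c("+", "-"),
    tx_start = c(101L, 100L + w + 100L + 1L),
    tx_end = c(100L + w, 100L + w + 100L + w),
    cds_start = c(131L, 100L + w + 100L + 1L + 33L),
    cds_end = c(130L + nchar(cds), 100L + w + 100L + 33L + nchar(cds)))
  manual_ref(seqs, genes = genes)
}

site_at_cds <- function(ref, gene_i, cds_pos) {
  g <- ref$genes[gene_i, ]
  pos <- if (g$strand == "+") g$cds_start + cds_pos - 1L else
    g$cds_end - cds_pos + 1L
  fwd_ref <- if (g$strand == "+") "A" else "T"
  fwd_alt <- if (g$strand == "+") "G" else "C"
  tibble::tibble(chrom = "chr1", pos = pos, ref = fwd_ref, alt = fwd_alt,
                 type = paste0(fwd_ref, ">", fwd_alt))
}
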