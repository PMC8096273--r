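#' Simulate DNA and RNA sequencing reads with planted truth
#'
#' Emits uniform-coverage single-end reads as pre-aligned SAM records with
#' true coordinates (CIGAR all-match, MAPQ 60) plus an unaligned FASTQ of
#' hyper-edited molecules:
#' \itemize{
#'   \item DNA reads carry planted SNPs (heterozygous at ~50\% allele balance)
#'     but never editing.
#'   \item RNA reads carry SNPs and, independently per overlapping read, each
#'     edit site converted A-to-G on its sense strand with probability equal
#'     to the site's true editing level. RNA reads are sense-stranded from the
#'     annotated repeat/gene strand; intergenic reads are forward.
#'   \item Hyper molecules are emitted only to FASTQ, each read carrying all
#'     of its edited positions converted.
#' }
#' Sequencing errors are injected at `reads$error_rate` per base (uniformly
#' choosing one of the three other bases); every base gets the constant
#' configured quality.
#'
#' @param ref A `ref_bundle`.
#' @param truth The matching `truth_set`.
#' @param config The same [sim_config()].
#' @param outdir Optional directory; when given, writes `dna.sam`,
#'   `rna_sample_<i>.sam`, `hyper.fastq` and the truth TSVs there.
#' @return A list with `dna` (alignment tibble), `rna` (named list of
#'   alignment tibbles, one per sample), `hyper` (tibble: read_id, seq, qual)
#'   and `files` (paths, when `outdir` was given).
#' @export
simulate_reads <- function(ref, truth, config, outdir = NULL) {
  validate_sim_config(config)
  L <- config$reads$length
  q <- config$reads$base_quality
  err <- config$reads$error_rate
  chrom_len <- setNames(Biostrings::width(ref$genome), names(ref$genome))
  chromstrs <- lapply(names(ref$genome), function(ch) chrom_string(ref, ch))
  names(chromstrs) <- names(ref$genome)

  dna <- withr::with_seed(derive_seed(config$seed, 33L), {
    r <- draw_reads(chromstrs, chrom_len, config$reads$dna_depth, L, q,
                    strand_lookup = NULL, prefix = "dna")
    r <- apply_snps(r, truth$snps, L)
    apply_errors(r, err)
  })

  rna <- lapply(seq_len(config$n_rna_samples), function(i) {
    withr::with_seed(derive_seed(config$seed, 100L + i), {
      r <- draw_reads(chromstrs, chrom_len, config$reads$rna_depth, L, q,
                      strand_lookup = feature_strands(ref),
                      prefix = sprintf("s%d", i))
      r <- apply_snps(r, truth$snps, L)
      r <- apply_edits(r, truth$edit_sites, L)
      apply_errors(r, err)
    })
  })
  names(rna) <- paste0("sample", seq_len(config$n_rna_samples))

  hyper <- withr::with_seed(derive_seed(config$seed, 55L), {
    make_hyper_reads(chromstrs, truth$hyper_molecules, q, err)
  })

  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- list(dna = file.path(outdir, "dna.sam"))
    write_sam(dna, ref, files$dna)
    files$rna <- vapply(seq_along(rna), function(i) {
      p <- file.path(outdir, sprintf("rna_sample_%d.sam", i))
      write_sam(rna[[i]], ref, p)
      p
    }, character(1))
    files$hyper <- file.path(outdir, "hyper.fastq")
    write_fastq(hyper, files$hyper)
    files <- c(files, write_truth_tables(truth, outdir))
  }

  list(dna = dna, rna = rna, hyper = hyper, files = files)
}

# interval -> strand lookup tables, one per chromosome
feature_strands <- function(ref) {
  feats <- bind_rows(
    select(ref$repeats, "chrom", "start", "end", "strand"),
    transmute(ref$genes, chrom = .data$chrom, start = .data$tx_start,
              end = .data$tx_end, strand = .data$strand)
  )
  feats <- arrange(feats, .data$chrom, .data$start)
  split(feats, feats$chrom)
}

draw_reads <- function(chromstrs, chrom_len, depth, L, q, strand_lookup,
                       prefix) {
  out <- lapply(names(chrom_len), function(ch) {
    len <- chrom_len[[ch]]
    n <- max(0L, round(len * depth / L))
    if (n == 0L || len < L) return(NULL)
    starts <- sample.int(len - L + 1L, n, replace = TRUE)
    if (is.null(strand_lookup)) {
      rev <- sample(c(TRUE, FALSE), n, replace = TRUE)
    } else {
      fl <- strand_lookup[[ch]]
      rev <- rep(FALSE, n)
      if (!is.null(fl) && nrow(fl) > 0L) {
        mid <- starts + L %/% 2L
        k <- findInterval(mid, fl$start)
        hit <- k > 0L & mid <= c(fl$end, 0L)[pmax(k, 1L)]
        rev[hit] <- fl$strand[k[hit]] == "-"
      }
    }
    tibble(
      qname = sprintf("%s_%s_%06d", prefix, ch, seq_len(n)),
      flag = ifelse(rev, 16L, 0L), chrom = ch, pos = starts,
      mapq = 60L, cigar = paste0(L, "M"),
      seq = substring(chromstrs[[ch]], starts, starts + L - 1L),
      qual = strrep(phred_char(q), L), reverse = rev
    )
  })
  list_rbind(out[!vapply(out, is.null, TRUE)])
}

# overlapping (read, site) pairs for one chromosome; reads need not be sorted
overlap_pairs <- function(read_pos, site_pos, L) {
  o <- order(read_pos)
  sp <- read_pos[o]
  lo <- findInterval(site_pos - L, sp) + 1L        # first start > pos - L
  hi <- findInterval(site_pos, sp)                 # last start <= pos
  n <- pmax(0L, hi - lo + 1L)
  if (sum(n) == 0L) {
    return(list(read = integer(0), site = integer(0)))
  }
  site_idx <- rep(seq_along(site_pos), n)
  read_sorted_idx <- unlist(lapply(which(n > 0L), function(i) lo[i]:hi[i]))
  list(read = o[read_sorted_idx], site = site_idx)
}

apply_subs <- function(seqs, ridx, off, base) {
  for (k in seq_along(ridx)) {
    substr(seqs[ridx[k]], off[k], off[k]) <- base[k]
  }
  seqs
}

apply_snps <- function(reads, snps, L) {
  if (nrow(snps) == 0L || nrow(reads) == 0L) return(reads)
  for (ch in intersect(unique(reads$chrom), unique(snps$chrom))) {
    ri <- which(reads$chrom == ch)
    sn <- snps[snps$chrom == ch, ]
    pr <- overlap_pairs(reads$pos[ri], sn$pos, L)
    if (length(pr$read) == 0L) next
    carry <- ifelse(sn$zygosity[pr$site] == "hom", TRUE,
                    rbinom(length(pr$read), 1L, 0.5) == 1L)
    pr$read <- pr$read[carry]; pr$site <- pr$site[carry]
    off <- sn$pos[pr$site] - reads$pos[ri][pr$read] + 1L
    reads$seq[ri] <- apply_subs(reads$seq[ri], pr$read, off, sn$alt[pr$site])
  }
  reads
}

apply_edits <- function(reads, edit_sites, L) {
  if (nrow(edit_sites) == 0L || nrow(reads) == 0L) return(reads)
  for (ch in intersect(unique(reads$chrom), unique(edit_sites$chrom))) {
    ri <- which(reads$chrom == ch)
    es <- edit_sites[edit_sites$chrom == ch, ]
    pr <- overlap_pairs(reads$pos[ri], es$pos, L)
    if (length(pr$read) == 0L) next
    edited <- rbinom(length(pr$read), 1L, es$true_level[pr$site]) == 1L
    pr$read <- pr$read[edited]; pr$site <- pr$site[edited]
    if (length(pr$read) == 0L) next
    off <- es$pos[pr$site] - reads$pos[ri][pr$read] + 1L
    newb <- ifelse(es$strand[pr$site] == "+", "G", "C")
    reads$seq[ri] <- apply_subs(reads$seq[ri], pr$read, off, newb)
  }
  reads
}

apply_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || nrow(reads) == 0L) return(reads)
  L <- nchar(reads$seq)
  n_err <- rbinom(1L, sum(L), error_rate)
  if (n_err == 0L) return(reads)
  ridx <- sample.int(nrow(reads), n_err, replace = TRUE, prob = L)
  off <- 1L + floor(runif(n_err) * L[ridx])
  for (k in seq_len(n_err)) {
    cur <- substr(reads$seq[ridx[k]], off[k], off[k])
    substr(reads$seq[ridx[k]], off[k], off[k]) <-
      sample(setdiff(BASES, cur), 1L)
  }
  reads
}

make_hyper_reads <- function(chromstrs, molecules, q, error_rate) {
  if (nrow(molecules) == 0L) {
    return(tibble(read_id = character(), seq = character(), qual = character()))
  }
  seqs <- character(nrow(molecules))
  for (i in seq_len(nrow(molecules))) {
    m <- molecules[i, ]
    s <- substring(chromstrs[[m$chrom]], m$start, m$end)
    epos <- m$edited_pos[[1]]
    off <- epos - m$start + 1L
    newb <- if (m$strand == "+") "G" else "C"
    for (o in off) substr(s, o, o) <- newb
    if (m$strand == "-") s <- revcomp_chr(s)
    seqs[i] <- s
  }
  out <- tibble(read_id = molecules$molecule_id, seq = seqs,
                qual = strrep(phred_char(q), nchar(seqs)))
  if (error_rate > 0) {
    tmp <- apply_errors(tibble(seq = out$seq), error_rate)
    out$seq <- tmp$seq
  }
  out
}

#' Generate mixed-mismatch control reads for hyper-editing specificity
#'
#' Builds forward-strand reads from random genomic windows and plants `n_ag`
#' A-to-G changes alongside `n_other` changes of a different substitution
#' type. Such reads emulate alignment artifacts rather than ADAR activity and
#' should be rejected by [rescue_reads()] when the same-type mismatch
#' fraction falls below its threshold.
#'
#' @param ref A `ref_bundle`.
#' @param n Number of control reads.
#' @param n_ag Planted A-to-G mismatches per read.
#' @param n_other Planted mismatches of `other_type` per read.
#' @param other_type Length-2 character vector `c(ref, alt)`; default C-to-T.
#' @param read_length Read length in bp.
#' @param base_quality Constant Phred quality.
#' @param seed Integer seed.
#' @return A tibble (read_id, chrom, start, seq, qual) of control reads.
#' @export
simulate_mixed_reads <- function(ref, n, n_ag = 6, n_other = 6,
                                 other_type = c("C", "T"), read_length = 150,
                                 base_quality = 37, seed = 1L) {
  withr::with_seed(derive_seed(seed, 66L), {
    chrom_len <- setNames(Biostrings::width(ref$genome), names(ref$genome))
    reps <- ref$repeats
    out <- vector("list", n)
    for (i in seq_len(n)) {
      for (attempt in seq_len(1000L)) {
        ch <- sample(names(chrom_len), 1L, prob = chrom_len)
        s <- sample.int(chrom_len[[ch]] - read_length + 1L, 1L)
        # stay out of repeat territory so controls test the type filter,
        # not locus uniqueness
        if (nrow(reps) > 0L &&
            any(reps$chrom == ch & reps$start <= s + read_length - 1L &
                  reps$end >= s)) next
        seqs <- substring(chrom_string(ref, ch), s, s + read_length - 1L)
        b <- strsplit(seqs, "")[[1]]
        a_off <- which(b == "A"); o_off <- which(b == other_type[1])
        o_off <- setdiff(o_off, a_off)
        if (length(a_off) < n_ag || length(o_off) < n_other) next
        b[sample(a_off, n_ag)] <- "G"
        b[sample(o_off, n_other)] <- other_type[2]
        out[[i]] <- tibble(
          read_id = sprintf("mixed%04d", i), chrom = ch, start = s,
          seq = paste(b, collapse = ""),
          qual = strrep(phred_char(base_quality), read_length))
        break
      }
      if (is.null(out[[i]])) rlang::abort("could not place a control read")
    }
    list_rbind(out)
  })
}

#' Write alignments as a SAM file
#'
#' Emits an `@HD`/`@SQ` header from the reference and one line per record.
#' Sequences are stored in reference-forward orientation; reverse-strand
#' reads carry FLAG bit 0x10.
#'
#' @param alignments Alignment tibble (qname, flag, chrom, pos, mapq, cigar,
#'   seq, qual).
#' @param ref A `ref_bundle` (for `@SQ` lines).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(alignments, ref, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref$genome),
                   Biostrings::width(ref$genome)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  alignments$qname, alignments$flag, alignments$chrom,
                  alignments$pos, alignments$mapq, alignments$cigar,
                  alignments$seq, alignments$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}
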