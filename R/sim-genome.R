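#' Simulate a reference genome with repeats and genes
#'
#' Builds a random genome and embeds (i) copies of each configured repeat
#' family -- palindromic families as a unit followed by its perfect reverse
#' complement -- and (ii) single-exon protein-coding genes whose CDS starts
#' with ATG, contains no internal stop codon and has length divisible by 3.
#' Features are placed without overlap and away from chromosome ends.
#'
#' @param config A [sim_config()].
#' @return A `ref_bundle` list with `genome` (a [Biostrings::DNAStringSet]),
#'   `repeats` (tibble: chrom, start, end, family, strand, copy_id; 1-based
#'   closed intervals) and `genes` (tibble: gene_id, transcript_id, chrom,
#'   strand, tx_start, tx_end, cds_start, cds_end).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  withr::with_seed(derive_seed(config$seed, 11L), {
    chrom_len <- split_lengths(config$genome_length, config$n_chromosomes)
    chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
    margin <- max(200L, config$reads$length)
    utr <- 30L

    # feasibility check before any placement
    feat_bp <- sum(vapply(config$repeat_families, function(f)
      f$copies * f$unit_length * (1L + f$palindromic), numeric(1))) +
      config$n_genes * (config$cds_length + 3L + 2L * utr)
    usable <- sum(pmax(0L, chrom_len - 2L * margin))
    if (feat_bp > 0.7 * usable) {
      rlang::abort(sprintf(
        "requested features (%d bp) exceed 70%% of usable genome (%d bp); enlarge genome_length",
        feat_bp, usable))
    }

    chars <- lapply(chrom_len, function(n) sample(BASES, n, replace = TRUE))

    occupied <- lapply(chrom_len, function(n) IRanges::IRanges())
    names(occupied) <- names(chars) <- chrom_names

    place <- function(width) {
      # weight chromosomes by usable length, rejection-sample a free slot
      for (i in seq_len(2000L)) {
        ci <- sample.int(length(chrom_len), 1L, prob = chrom_len)
        lo <- margin + 1L
        hi <- chrom_len[ci] - margin - width + 1L
        if (hi < lo) next
        s <- sample(lo:hi, 1L)
        cand <- IRanges::IRanges(s - 10L, s + width + 9L)  # 10 bp spacing
        if (length(IRanges::findOverlaps(cand, occupied[[ci]])) == 0L) {
          occupied[[ci]] <<- c(occupied[[ci]], cand)
          return(list(chrom = chrom_names[ci], start = s))
        }
      }
      rlang::abort("could not place a feature after 2000 attempts; genome too crowded")
    }

    repeats <- list()
    for (fam in config$repeat_families) {
      unit <- paste(sample(BASES, fam$unit_length, replace = TRUE), collapse = "")
      embedded <- if (fam$palindromic) paste0(unit, revcomp_chr(unit)) else unit
      w <- nchar(embedded)
      for (ci in seq_len(fam$copies)) {
        slot <- place(w)
        strand <- sample(c("+", "-"), 1L)
        seq_copy <- if (strand == "+") embedded else revcomp_chr(embedded)
        chars[[slot$chrom]][slot$start:(slot$start + w - 1L)] <-
          strsplit(seq_copy, "")[[1]]
        repeats[[length(repeats) + 1L]] <- tibble(
          chrom = slot$chrom, start = slot$start, end = slot$start + w - 1L,
          family = fam$name, strand = strand,
          copy_id = sprintf("%s_%03d", fam$name, ci)
        )
      }
    }
    repeats <- if (length(repeats)) list_rbind(repeats) else
      tibble(chrom = character(), start = integer(), end = integer(),
             family = character(), strand = character(), copy_id = character())

    sense_codons <- setdiff(names(Biostrings::GENETIC_CODE)[
      Biostrings::GENETIC_CODE != "*"], character(0))
    genes <- list()
    for (gi in seq_len(config$n_genes)) {
      n_codon <- config$cds_length / 3L
      cds <- paste0("ATG", paste(sample(sense_codons, n_codon - 1L,
                                        replace = TRUE), collapse = ""))
      gene_seq <- paste0(
        paste(sample(BASES, utr, replace = TRUE), collapse = ""),
        cds, "TAA",
        paste(sample(BASES, utr, replace = TRUE), collapse = "")
      )
      w <- nchar(gene_seq)
      slot <- place(w)
      strand <- if (gi %% 2L == 0L) "-" else "+"
      placed <- if (strand == "+") gene_seq else revcomp_chr(gene_seq)
      chars[[slot$chrom]][slot$start:(slot$start + w - 1L)] <-
        strsplit(placed, "")[[1]]
      tx_start <- slot$start; tx_end <- slot$start + w - 1L
      if (strand == "+") {
        cds_start <- tx_start + utr; cds_end <- cds_start + config$cds_length - 1L
      } else {
        cds_end <- tx_end - utr; cds_start <- cds_end - config$cds_length + 1L
      }
      genes[[gi]] <- tibble(
        gene_id = sprintf("gene%02d", gi),
        transcript_id = sprintf("gene%02d.t1", gi),
        chrom = slot$chrom, strand = strand,
        tx_start = tx_start, tx_end = tx_end,
        cds_start = cds_start, cds_end = cds_end
      )
    }
    genes <- if (length(genes)) list_rbind(genes) else
      tibble(gene_id = character(), transcript_id = character(),
             chrom = character(), strand = character(),
             tx_start = integer(), tx_end = integer(),
             cds_start = integer(), cds_end = integer())

    genome <- Biostrings::DNAStringSet(
      vapply(chars, paste, character(1), collapse = ""))
    names(genome) <- chrom_names

    structure(
      list(genome = genome,
           repeats = arrange(repeats, .data$chrom, .data$start),
           genes = arrange(genes, .data$chrom, .data$tx_start)),
      class = "ref_bundle")
  })
}

split_lengths <- function(total, n) {
  base <- total %/% n
  out <- rep(base, n)
  out[seq_len(total - base * n)] <- out[seq_len(total - base * n)] + 1L
  as.integer(out)
}

#' @export
print.ref_bundle <- function(x, ...) {
  cat("<ref_bundle>\n")
  cat(sprintf("  genome: %d chromosome(s), %d bp total\n",
              length(x$genome), sum(Biostrings::width(x$genome))))
  cat(sprintf("  repeats: %d copies in %d family/ies\n",
              nrow(x$repeats), length(unique(x$repeats$family))))
  cat(sprintf("  genes: %d\n", nrow(x$genes)))
  invisible(x)
}

#' Write a reference bundle to standard files
#'
#' Writes `genome.fa` (FASTA), `repeats.bed` (BED6; name column holds the
#' repeat family, column 6 the strand) and `genes.gtf` (gene, transcript and
#' CDS rows) under `dir`.
#'
#' @param ref A `ref_bundle`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the three file paths.
#' @export
write_reference_bundle <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(ref$genome, fa)

  bed <- file.path(dir, "repeats.bed")
  gr <- GenomicRanges::GRanges(
    ref$repeats$chrom,
    IRanges::IRanges(ref$repeats$start, ref$repeats$end),
    strand = ref$repeats$strand,
    name = ref$repeats$family, score = 0L)
  rtracklayer::export(gr, bed, format = "BED")

  gtf <- file.path(dir, "genes.gtf")
  g <- ref$genes
  feat <- function(type, s, e) {
    GenomicRanges::GRanges(g$chrom, IRanges::IRanges(s, e), strand = g$strand,
                           type = type, source = "edscope",
                           phase = if (type == "CDS") 0L else NA_integer_,
                           gene_id = g$gene_id, transcript_id = g$transcript_id)
  }
  all <- c(feat("gene", g$tx_start, g$tx_end),
           feat("transcript", g$tx_start, g$tx_end),
           feat("exon", g$tx_start, g$tx_end),
           feat("CDS", g$cds_start, g$cds_end))
  rtracklayer::export(sort(all), gtf, format = "GTF")
  invisible(list(fasta = fa, bed = bed, gtf = gtf))
}

#' Read a reference bundle from FASTA + BED + GTF
#'
#' Inverse of [write_reference_bundle()]. The BED name column is taken as the
#' repeat family; CDS coordinates come from GTF `CDS` rows and transcript
#' extents from `transcript` (or `exon`) rows.
#'
#' @param fasta,bed,gtf File paths.
#' @return A `ref_bundle`.
#' @export
read_reference_bundle <- function(fasta, bed, gtf) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))

  rep_gr <- rtracklayer::import(bed, format = "BED")
  repeats <- tibble(
    chrom = as.character(GenomicRanges::seqnames(rep_gr)),
    start = GenomicRanges::start(rep_gr),
    end = GenomicRanges::end(rep_gr),
    family = rep_gr$name %||% rep("repeat", length(rep_gr)),
    strand = as.character(GenomicRanges::strand(rep_gr))
  )
  repeats$copy_id <- paste0(repeats$family, "_",
                            sprintf("%03d", seq_len(nrow(repeats))))

  gtf_gr <- rtracklayer::import(gtf, format = "GTF")
  tx <- gtf_gr[gtf_gr$type %in% c("transcript", "mRNA")]
  cds <- gtf_gr[gtf_gr$type == "CDS"]
  cds_df <- tibble(
    transcript_id = cds$transcript_id,
    cds_start = GenomicRanges::start(cds),
    cds_end = GenomicRanges::end(cds)
  ) |>
    group_by(.data$transcript_id) |>
    summarise(cds_start = min(.data$cds_start), cds_end = max(.data$cds_end))
  genes <- tibble(
    gene_id = tx$gene_id,
    transcript_id = tx$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(tx)),
    strand = as.character(GenomicRanges::strand(tx)),
    tx_start = GenomicRanges::start(tx),
    tx_end = GenomicRanges::end(tx)
  ) |>
    inner_join(cds_df, by = "transcript_id")

  structure(list(genome = genome,
                 repeats = arrange(repeats, .data$chrom, .data$start),
                 genes = arrange(genes, .data$chrom, .data$tx_start)),
            class = "ref_bundle")
}
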