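#' Plant ground-truth variation into a simulated genome
#'
#' Places (in this order, so later features avoid earlier ones):
#' clustered A-to-I editing sites inside repeat copies, with per-site levels
#' drawn from the configured Beta distribution and the ADAR-like
#' nearest-neighbor bias (G disfavoured at the sense -1 position, favoured at
#' +1); isolated recoding sites at CDS adenosines with the codon effect
#' recorded; hyper-edited molecule footprints in unique background sequence;
#' and finally SNPs everywhere else. Every edit site has reference base A on
#' its transcribed strand and never coincides with a planted SNP.
#'
#' @param ref A `ref_bundle` from [simulate_genome()].
#' @param config The same [sim_config()].
#' @return A `truth_set` list with tibbles `snps` (chrom, pos, ref, alt,
#'   zygosity), `edit_sites` (chrom, pos, strand, true_level, in_repeat,
#'   in_cds, cluster_id, and codon annotation for CDS sites) and
#'   `hyper_molecules` (molecule_id, chrom, start, end, strand, edited_pos
#'   list-column). Positions are 1-based.
#' @export
plant_truth <- function(ref, config) {
  validate_sim_config(config)
  withr::with_seed(derive_seed(config$seed, 22L), {
    chromstrs <- lapply(names(ref$genome), function(ch) chrom_string(ref, ch))
    names(chromstrs) <- names(ref$genome)
    chrom_len <- setNames(Biostrings::width(ref$genome), names(ref$genome))
    ed <- config$editing

    ## ---- clustered editing sites in repeats -------------------------------
    edit_rows <- list()
    for (i in seq_len(nrow(ref$repeats))) {
      rp <- ref$repeats[i, ]
      cs <- chromstrs[[rp$chrom]]
      apos <- sense_adenosines(cs, rp$start, rp$end, rp$strand)
      if (ed$mode == "uniform_adenosines") {
        if (length(apos) == 0L) next
        lev <- ed$level_fixed %||% rbeta(length(apos), ed$level_shape1, ed$level_shape2)
        edit_rows[[length(edit_rows) + 1L]] <- tibble(
          chrom = rp$chrom, pos = apos, strand = rp$strand,
          true_level = rep_len(lev, length(apos)),
          in_repeat = TRUE, in_cds = FALSE, cluster_id = rp$copy_id)
        next
      }
      if (rbinom(1L, 1L, ed$cluster_rate) == 0L) next
      # confine the cluster to one 400-bp window of the copy
      if (rp$end - rp$start + 1L > 400L) {
        ws <- sample(rp$start:(rp$end - 400L + 1L), 1L)
        apos <- apos[apos >= ws & apos <= ws + 399L]
      }
      # ADAR disfavours homopolymeric runs, and the detection cascade
      # excludes them by design, so clusters avoid them
      if (length(apos)) apos <- apos[!in_homopolymer(cs, apos, 5L)]
      if (length(apos) < 2L) {
        rlang::abort(sprintf(
          "insufficient adenosines to place an editing cluster in repeat copy %s (%s:%d-%d)",
          rp$copy_id, rp$chrom, rp$start, rp$end))
      }
      w <- motif_weights(cs, apos, rp$strand, ed$motif_bias)
      n_take <- min(ed$sites_per_cluster, length(apos))
      take <- sort(sample(apos, n_take, prob = w))
      lev <- if (!is.null(ed$level_fixed)) rep(ed$level_fixed, n_take) else
        rbeta(n_take, ed$level_shape1, ed$level_shape2)
      edit_rows[[length(edit_rows) + 1L]] <- tibble(
        chrom = rp$chrom, pos = take, strand = rp$strand, true_level = lev,
        in_repeat = TRUE, in_cds = FALSE, cluster_id = rp$copy_id)
    }
    edit_sites <- if (length(edit_rows)) list_rbind(edit_rows) else
      empty_edit_sites()

    ## ---- isolated recoding sites in CDS -----------------------------------
    reco_rows <- list()
    if (config$recoding_sites > 0 && nrow(ref$genes) > 0) {
      levels <- rep_len(config$recoding_level, config$recoding_sites)
      gene_idx <- rep_len(seq_len(nrow(ref$genes)), config$recoding_sites)
      used <- character(0)
      for (j in seq_len(config$recoding_sites)) {
        g <- ref$genes[gene_idx[j], ]
        cs <- chromstrs[[g$chrom]]
        apos <- sense_adenosines(cs, g$cds_start, g$cds_end, g$strand)
        apos <- apos[!(paste0(g$chrom, ":", apos) %in% used)]
        # skip the initiator codon so planted sites are plain recoding events
        cds_coord <- if (g$strand == "+") apos - g$cds_start + 1L else g$cds_end - apos + 1L
        apos <- apos[cds_coord > 3L]
        if (length(apos)) apos <- apos[!in_homopolymer(cs, apos, 5L)]
        if (length(apos) == 0L) {
          rlang::abort(sprintf("insufficient CDS adenosines in gene %s", g$gene_id))
        }
        p <- sample(apos, 1L)
        used <- c(used, paste0(g$chrom, ":", p))
        ann <- codon_annotation(cs, g, p)
        reco_rows[[length(reco_rows) + 1L]] <- tibble(
          chrom = g$chrom, pos = p, strand = g$strand,
          true_level = levels[j], in_repeat = FALSE, in_cds = TRUE,
          cluster_id = NA_character_, gene_id = g$gene_id,
          ref_codon = ann$ref_codon, alt_codon = ann$alt_codon,
          ref_aa = ann$ref_aa, alt_aa = ann$alt_aa, effect = ann$effect)
      }
    }
    if (length(reco_rows)) {
      edit_sites <- bind_rows(edit_sites, list_rbind(reco_rows))
    }

    ## ---- hyper-edited molecules in unique background ----------------------
    occupied <- c(
      IRanges_from(ref$repeats$chrom, ref$repeats$start, ref$repeats$end),
      IRanges_from(ref$genes$chrom, ref$genes$tx_start, ref$genes$tx_end)
    )
    L <- config$reads$length
    hyper_rows <- list()
    for (m in seq_len(config$hyper_molecules)) {
      placedm <- FALSE
      for (attempt in seq_len(2000L)) {
        ch <- sample(names(chrom_len), 1L, prob = chrom_len)
        s <- sample(seq(L + 1L, chrom_len[[ch]] - 2L * L), 1L)
        cand <- paste0(ch, ":", s)
        ivl <- IRanges_from(ch, s - 10L, s + L + 9L)
        if (length(GenomicRanges::findOverlaps(ivl, occupied)) > 0L) next
        strand <- sample(c("+", "-"), 1L)
        apos <- sense_adenosines(chromstrs[[ch]], s, s + L - 1L, strand)
        if (length(apos) < config$edits_per_molecule) next
        epos <- sort(sample(apos, config$edits_per_molecule))
        occupied <- c(occupied, ivl)
        hyper_rows[[m]] <- tibble(
          molecule_id = sprintf("hyper%04d", m), chrom = ch,
          start = s, end = s + L - 1L, strand = strand,
          edited_pos = list(epos))
        placedm <- TRUE
        break
      }
      if (!placedm) rlang::abort("could not place a hyper-edited molecule; genome too crowded")
    }
    hyper_molecules <- if (length(hyper_rows)) list_rbind(hyper_rows) else
      tibble(molecule_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), edited_pos = list())

    ## ---- SNPs outside everything planted above ----------------------------
    protected <- c(
      occupied_edit_windows(edit_sites),
      IRanges_from(hyper_molecules$chrom, hyper_molecules$start, hyper_molecules$end)
    )
    snp_rows <- list()
    rate <- config$snp_rate_hom + config$snp_rate_het
    for (ch in names(chrom_len)) {
      n <- rbinom(1L, chrom_len[[ch]], rate)
      if (n == 0L) next
      prot <- protected[as.character(GenomicRanges::seqnames(protected)) == ch]
      bad <- unique(unlist(lapply(seq_along(prot), function(k)
        GenomicRanges::start(prot)[k]:GenomicRanges::end(prot)[k])))
      free <- setdiff(seq_len(chrom_len[[ch]]), bad)
      pos <- sort(sample(free, min(n, length(free))))
      refb <- base_at(chromstrs[[ch]], pos)
      altb <- vapply(refb, function(b) sample(setdiff(BASES, b), 1L), character(1))
      zyg <- sample(c("hom", "het"), length(pos), replace = TRUE,
                    prob = c(config$snp_rate_hom, config$snp_rate_het))
      snp_rows[[ch]] <- tibble(chrom = ch, pos = pos, ref = refb,
                               alt = unname(altb), zygosity = zyg)
    }
    snps <- if (length(snp_rows)) list_rbind(snp_rows) else
      tibble(chrom = character(), pos = integer(), ref = character(),
             alt = character(), zygosity = character())

    structure(list(snps = snps,
                   edit_sites = arrange(edit_sites, .data$chrom, .data$pos),
                   hyper_molecules = hyper_molecules),
              class = "truth_set")
  })
}

empty_edit_sites <- function() {
  tibble(chrom = character(), pos = integer(), strand = character(),
         true_level = numeric(), in_repeat = logical(), in_cds = logical(),
         cluster_id = character())
}

# 1-based positions in [start, end] whose base on `strand` is A
sense_adenosines <- function(chromstr, start, end, strand) {
  b <- strsplit(substring(chromstr, start, end), "")[[1]]
  target <- if (strand == "+") "A" else "T"
  (start:end)[b == target]
}

# weight ~ 1/bias when sense -1 base is G, ~ bias when sense +1 base is G
motif_weights <- function(chromstr, pos, strand, bias) {
  if (length(pos) == 0L) return(numeric(0))
  if (strand == "+") {
    up <- base_at(chromstr, pos - 1L); down <- base_at(chromstr, pos + 1L)
  } else {
    up <- comp_base(base_at(chromstr, pos + 1L))
    down <- comp_base(base_at(chromstr, pos - 1L))
  }
  w <- rep(1, length(pos))
  w[up == "G"] <- w[up == "G"] / bias
  w[down == "G"] <- w[down == "G"] * bias
  w
}

codon_annotation <- function(chromstr, gene, pos) {
  cds_seq <- substring(chromstr, gene$cds_start, gene$cds_end)
  if (gene$strand == "-") cds_seq <- revcomp_chr(cds_seq)
  cds_coord <- if (gene$strand == "+") pos - gene$cds_start + 1L else
    gene$cds_end - pos + 1L
  ci <- (cds_coord - 1L) %/% 3L + 1L
  off <- (cds_coord - 1L) %% 3L + 1L
  ref_codon <- substring(cds_seq, (ci - 1L) * 3L + 1L, ci * 3L)
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- "G"
  ref_aa <- translate_codons(ref_codon); alt_aa <- translate_codons(alt_codon)
  effect <- if (ci == 1L && ref_codon == "ATG") "start_loss"
    else if (ref_aa == "*") "stop_loss"
    else if (alt_aa == "*") "stop_gain"
    else if (ref_aa == alt_aa) "synonymous" else "missense"
  list(ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa, effect = effect)
}

IRanges_from <- function(chrom, start, end) {
  if (length(chrom) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

occupied_edit_windows <- function(edit_sites) {
  if (nrow(edit_sites) == 0L) return(GenomicRanges::GRanges())
  # protect the whole cluster neighbourhood (and the codon of recoding sites)
  pad <- ifelse(edit_sites$in_cds, 2L, 5L)
  IRanges_from(edit_sites$chrom, edit_sites$pos - pad, edit_sites$pos + pad)
}

#' @export
print.truth_set <- function(x, ...) {
  cat("<truth_set>\n")
  cat(sprintf("  SNPs: %d (%d hom / %d het)\n", nrow(x$snps),
              sum(x$snps$zygosity == "hom"), sum(x$snps$zygosity == "het")))
  cat(sprintf("  edit sites: %d (%d in repeats, %d in CDS)\n",
              nrow(x$edit_sites), sum(x$edit_sites$in_repeat),
              sum(x$edit_sites$in_cds)))
  cat(sprintf("  hyper molecules: %d\n", nrow(x$hyper_molecules)))
  invisible(x)
}

#' Write truth tables as TSV
#'
#' @param truth A `truth_set`.
#' @param dir Output directory.
#' @return Invisibly, the file paths.
#' @export
write_truth_tables <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "truth_snps.tsv")
  p2 <- file.path(dir, "truth_edit_sites.tsv")
  p3 <- file.path(dir, "truth_hyper_molecules.tsv")
  readr::write_tsv(truth$snps, p1)
  readr::write_tsv(truth$edit_sites, p2)
  hm <- truth$hyper_molecules
  hm$edited_pos <- vapply(hm$edited_pos, paste, character(1), collapse = ",")
  readr::write_tsv(hm, p3)
  invisible(list(snps = p1, edit_sites = p2, hyper_molecules = p3))
}
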