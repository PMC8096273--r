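test_that("sites are annotated to the most specific region", {
  ref <- recoding_ref("ATGCAGGCATTA")  # M Q A L
  g <- ref$genes[1, ]
  sites <- tibble::tibble(
    chrom = "chr1",
    pos = c(g$cds_start + 4L,   # inside CDS
            g$tx_start + 5L,    # 5' UTR -> exon_noncoding
            50L),               # intergenic
    ref = "A", alt = "G", type = "A>G")
  ann <- annotate_sites(sites, ref$genes)
  expect_equal(ann$region[match(sites$pos, ann$pos)],
               c("CDS", "exon_noncoding", "intergenic"))

  # forward T>C inside the minus-strand CDS is sense A>G in region CDS
  s2 <- site_at_cds(ref, 2, 5)
  ann2 <- annotate_sites(s2, ref$genes)
  expect_equal(ann2$region, "CDS")
  expect_equal(ann2$sense_type, "A>G")
  expect_equal(ann2$gene_strand, "-")
})

test_that("codon effects are classified exactly, on both strands", {
  cds <- "ATGCAGGCATTA"  # ATG CAG GCA TTA : M Q A L
  ref <- recoding_ref(cds)
  for (gi in 1:2) {
    # CAG codon, position 2 (the A): CAG -> CGG, Q -> R missense
    s <- annotate_sites(site_at_cds(ref, gi, 5), ref$genes)
    eff <- classify_effects(s, ref$genes, ref)
    expect_equal(eff$ref_codon, "CAG")
    expect_equal(eff$alt_codon, "CGG")
    expect_equal(eff$ref_aa, "Q")
    expect_equal(eff$alt_aa, "R")
    expect_equal(eff$effect, "missense")

    # GCA -> GCG at codon position 3: synonymous Ala
    s <- annotate_sites(site_at_cds(ref, gi, 9), ref$genes)
    eff <- classify_effects(s, ref$genes, ref)
    expect_equal(eff$effect, "synonymous")
    expect_equal(eff$ref_aa, "A")

    # initiator ATG hit at position 1 -> GTG, start_loss
    s <- annotate_sites(site_at_cds(ref, gi, 1), ref$genes)
    eff <- classify_effects(s, ref$genes, ref)
    expect_equal(eff$alt_codon, "GTG")
    expect_equal(eff$effect, "start_loss")
  }
})

test_that("strand round-trip gives identical amino-acid calls", {
  cds <- "ATGAAACGTACA"  # M K R T
  ref <- recoding_ref(cds)
  for (cp in c(4, 5, 11)) {
    ep <- classify_effects(annotate_sites(site_at_cds(ref, 1, cp), ref$genes),
                           ref$genes, ref)
    em <- classify_effects(annotate_sites(site_at_cds(ref, 2, cp), ref$genes),
                           ref$genes, ref)
    expect_equal(ep$ref_aa, em$ref_aa)
    expect_equal(ep$alt_aa, em$alt_aa)
    expect_equal(ep$effect, em$effect)
  }
})

test_that("effect classification matches a whole-CDS translation oracle", {
  cfg <- small_config(seed = 29, recoding_sites = 12)
  ref <- simulate_genome(cfg)
  truth <- plant_truth(ref, cfg)
  cds_sites <- dplyr::filter(truth$edit_sites, in_cds)
  sites <- dplyr::transmute(
    cds_sites, chrom = chrom, pos = pos,
    ref = ifelse(strand == "+", "A", "T"),
    alt = ifelse(strand == "+", "G", "C"),
    type = paste0(ref, ">", alt))
  eff <- classify_effects(annotate_sites(sites, ref$genes), ref$genes, ref)
  expect_equal(nrow(eff), nrow(sites))

  cs <- as.character(ref$genome[["chr1"]])
  translate_cds <- function(g, edit_pos = NULL) {
    s <- substring(cs, g$cds_start, g$cds_end)
    if (!is.null(edit_pos)) {
      off <- edit_pos - g$cds_start + 1L
      base <- if (g$strand == "+") "G" else "C"
      substr(s, off, off) <- base
    }
    if (g$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    as.character(Biostrings::translate(Biostrings::DNAString(s)))
  }
  for (i in seq_len(nrow(eff))) {
    g <- ref$genes[match(eff$transcript_id[i], ref$genes$transcript_id), ]
    before <- translate_cds(g)
    after <- translate_cds(g, eff$pos[i])
    d <- which(strsplit(before, "")[[1]] != strsplit(after, "")[[1]])
    oracle <- if (length(d) == 0) "synonymous"
      else if (d == 1 && substring(before, 1, 1) == "M") "start_loss"
      else if (substring(after, d, d) == "*") "stop_gain"
      else if (substring(before, d, d) == "*") "stop_loss"
      else "missense"
    expect_equal(eff$effect[i], oracle)
    if (length(d) == 1) expect_equal(eff$aa_pos[i], d)
  }
})

test_that("annotation-integrity errors are raised for corrupt CDS", {
  ref <- recoding_ref("ATGCAGGCATTA")
  genes_bad <- ref$genes
  genes_bad$cds_end[1] <- genes_bad$cds_end[1] + 1L  # length % 3 != 0
  s <- annotate_sites(site_at_cds(ref, 1, 5), genes_bad)
  expect_error(classify_effects(s, genes_bad, ref), "divisible by 3")
})

test_that("consensus keeps sites detected in enough samples", {
  sites <- tibble::tibble(pos = 1:4, n_samples_detected = c(1L, 2L, 3L, 4L))
  expect_equal(consensus_recoding(sites)$pos, 2:4)
  expect_equal(consensus_recoding(sites,
                                  filter_params(consensus_min_samples = 1))$pos,
               1:4)
})

test_that("quantify_known computes levels and flags low coverage as missing", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L, 300L),
                          ref = "A", alt = "G")
  p1 <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L),
                       ref = "A", A = c(42L, 5L), C = 0L, G = c(18L, 4L),
                       T = 0L, coverage = c(60L, 9L))
  lv <- quantify_known(sites, list(s1 = p1))
  expect_equal(lv$level[lv$pos == 100], 0.30)
  expect_true(lv$missing[lv$pos == 200])   # coverage 9 < 10: missing, not 0
  expect_true(is.na(lv$level[lv$pos == 200]))
  expect_true(lv$missing[lv$pos == 300])   # absent from the pileup
})

test_that("site-set index pools G over G+A across sites and samples", {
  lv <- tibble::tibble(chrom = "chr1", pos = c(1L, 2L), ref = "A", alt = "G",
                       sample_id = "s1", ref_count = c(6L, 10L),
                       alt_count = c(4L, 0L), coverage = c(10L, 10L),
                       level = c(0.4, 0), missing = FALSE)
  expect_equal(site_set_index(lv)$index, 4 / 20)
  lv2 <- lv; lv2$ref_count <- 0L; lv2$alt_count <- c(5L, 5L)
  expect_equal(site_set_index(lv2)$index, 1)
  empty <- site_set_index(lv[0, ])
  expect_true(is.na(empty$index))
  expect_true(attr(empty, "empty"))
})

test_that("level consistency uses the n-1 CoV and excludes lone levels", {
  lv <- tibble::tibble(
    chrom = "chr1", pos = c(1L, 1L, 1L, 2L, 2L, 3L),
    ref = "A", alt = "G",
    sample_id = c("s1", "s2", "s3", "s1", "s2", "s1"),
    ref_count = 10L, alt_count = 5L, coverage = 20L,
    level = c(0.2, 0.2, 0.2, 0.1, 0.3, 0.5), missing = FALSE)
  got <- level_consistency(lv)
  expect_equal(got$per_site$cov[got$per_site$pos == 1], 0)
  expect_equal(got$per_site$cov[got$per_site$pos == 2],
               sd(c(0.1, 0.3)) / 0.2)  # ~0.7071
  expect_true(is.na(got$per_site$cov[got$per_site$pos == 3]))
  expect_equal(got$median_cov, median(c(0, sd(c(0.1, 0.3)) / 0.2)))
})
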