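test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(snp_rate_hom = 1.5), "snp_rate_hom")
  expect_error(sim_config(cds_length = 100), "divisible by 3")
  expect_error(sim_config(editing = list(mode = "nonsense")), "mode")
  expect_error(sim_config(reads = list(error_rate = -0.1)), "error_rate")
  # requested features exceeding the genome is a sizing error
  expect_error(simulate_genome(sim_config(genome_length = 5000)),
               "exceed|crowded")
})

test_that("simulated genome embeds the configured repeats and genes", {
  cfg <- sim_config(
    genome_length = 100000,
    repeat_families = list(
      list(name = "famA", unit_length = 100, copies = 50, palindromic = FALSE),
      list(name = "famB", unit_length = 80, copies = 50, palindromic = TRUE)),
    n_genes = 3, seed = 3)
  ref <- simulate_genome(cfg)
  expect_equal(nrow(ref$repeats), 100)
  expect_true(all(ref$repeats$start >= 1))
  expect_true(all(ref$repeats$end <= 100000))
  expect_setequal(unique(ref$repeats$family), c("famA", "famB"))

  # palindromic copies are a unit followed by its perfect reverse complement
  pal <- ref$repeats[ref$repeats$family == "famB", ]
  cs <- as.character(ref$genome[["chr1"]])
  for (i in seq_len(nrow(pal))) {
    s <- substring(cs, pal$start[i], pal$end[i])
    if (pal$strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    unit <- substring(s, 1, 80)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(unit)))
    expect_identical(s, paste0(unit, rc))
  }

  # CDS integrity: starts with ATG, divisible by 3, no internal stop
  for (i in seq_len(nrow(ref$genes))) {
    g <- ref$genes[i, ]
    cds <- substring(cs, g$cds_start, g$cds_end)
    if (g$strand == "-")
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    expect_identical(substring(cds, 1, 3), "ATG")
    expect_equal(nchar(cds) %% 3, 0)
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    expect_false(any(Biostrings::GENETIC_CODE[codons] == "*"))
  }
})

test_that("same config and seed give byte-identical outputs", {
  cfg <- small_config(seed = 42)
  r1 <- simulate_genome(cfg); r2 <- simulate_genome(cfg)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(r1$repeats, r2$repeats)
  t1 <- plant_truth(r1, cfg); t2 <- plant_truth(r2, cfg)
  expect_identical(t1, t2)
  s1 <- simulate_reads(r1, t1, cfg); s2 <- simulate_reads(r2, t2, cfg)
  expect_identical(s1$dna$seq, s2$dna$seq)
  expect_identical(s1$rna[[1]]$seq, s2$rna[[1]]$seq)
  expect_identical(s1$hyper$seq, s2$hyper$seq)
})

test_that("planted truth respects its structural invariants", {
  cfg <- small_config(seed = 11)
  ref <- simulate_genome(cfg)
  truth <- plant_truth(ref, cfg)

  # every edit site is A on its transcribed strand
  cs <- as.character(ref$genome[["chr1"]])
  b <- substring(cs, truth$edit_sites$pos, truth$edit_sites$pos)
  expect_true(all(ifelse(truth$edit_sites$strand == "+", b == "A", b == "T")))

  # no edit site coincides with a planted SNP
  expect_length(intersect(paste(truth$edit_sites$chrom, truth$edit_sites$pos),
                          paste(truth$snps$chrom, truth$snps$pos)), 0)

  # clustered sites all lie within one 400-bp window of a neighbour
  reps <- subset(truth$edit_sites, in_repeat)
  by_cluster <- split(reps$pos, reps$cluster_id)
  spans <- vapply(by_cluster, function(p) diff(range(p)), numeric(1))
  expect_true(all(spans <= 400))

  # zero cluster rate plants no repeat sites
  cfg0 <- small_config(seed = 11, editing = list(cluster_rate = 0),
                       recoding_sites = 0)
  t0 <- plant_truth(simulate_genome(cfg0), cfg0)
  expect_equal(nrow(t0$edit_sites), 0)
})

test_that("motif bias depletes G upstream of planted sites", {
  cfg <- sim_config(
    genome_length = 150000,
    repeat_families = list(
      list(name = "famA", unit_length = 300, copies = 120, palindromic = FALSE)),
    n_genes = 0, recoding_sites = 0, hyper_molecules = 0,
    editing = list(cluster_rate = 1, sites_per_cluster = 6, motif_bias = 4),
    seed = 5)
  ref <- simulate_genome(cfg)
  truth <- plant_truth(ref, cfg)
  cs <- as.character(ref$genome[["chr1"]])

  up_base <- function(pos, strand) {
    b <- substring(cs, pos + ifelse(strand == "+", -1L, 1L),
                   pos + ifelse(strand == "+", -1L, 1L))
    ifelse(strand == "-", chartr("ACGT", "TGCA", b), b)
  }
  site_g <- mean(up_base(truth$edit_sites$pos, truth$edit_sites$strand) == "G")
  # background: all sense adenosines of the repeat territory
  bg <- lapply(seq_len(nrow(ref$repeats)), function(i) {
    rp <- ref$repeats[i, ]
    b <- strsplit(substring(cs, rp$start, rp$end), "")[[1]]
    target <- if (rp$strand == "+") "A" else "T"
    pos <- (rp$start:rp$end)[b == target]
    mean(up_base(pos, rp$strand) == "G")
  })
  bg_g <- mean(unlist(bg))
  expect_lt(site_g, bg_g)
})

test_that("null simulation produces no non-reference bases", {
  cfg <- small_config(seed = 9, snp_rate_hom = 0, snp_rate_het = 0,
                      editing = list(cluster_rate = 0), recoding_sites = 0,
                      hyper_molecules = 0, reads = list(error_rate = 0))
  ref <- simulate_genome(cfg)
  truth <- plant_truth(ref, cfg)
  sim <- simulate_reads(ref, truth, cfg)
  p <- build_pileup(sim$rna[[1]], ref, detection_thresholds(trim_ends = 0,
                                                            min_base_quality = 0))
  nonref <- p$coverage - ifelse(p$ref == "A", p$A,
                                ifelse(p$ref == "C", p$C,
                                       ifelse(p$ref == "G", p$G, p$T)))
  expect_equal(sum(nonref), 0)
})

test_that("a fully edited site converts every overlapping RNA read", {
  cfg <- small_config(seed = 13, snp_rate_hom = 0, snp_rate_het = 0,
                      editing = list(cluster_rate = 1, level_fixed = 1),
                      recoding_sites = 0, hyper_molecules = 0,
                      reads = list(error_rate = 0))
  ref <- simulate_genome(cfg)
  truth <- plant_truth(ref, cfg)
  sim <- simulate_reads(ref, truth, cfg)
  p <- build_pileup(sim$rna[[1]], ref,
                    detection_thresholds(trim_ends = 0, min_base_quality = 0))
  es <- truth$edit_sites
  j <- dplyr::inner_join(es, p, by = c("chrom", "pos"))
  alt <- ifelse(j$strand == "+", j$G, j$C)
  expect_true(all(alt == j$coverage))
  expect_true(all(j$coverage > 0))
})

test_that("DNA reads never carry edits and het SNPs are near 50% balance", {
  cfg <- small_config(seed = 17, snp_rate_het = 0.003,
                      reads = list(dna_depth = 60, error_rate = 0))
  ref <- simulate_genome(cfg)
  truth <- plant_truth(ref, cfg)
  sim <- simulate_reads(ref, truth, cfg)
  th0 <- detection_thresholds(trim_ends = 0, min_base_quality = 0)
  dp <- build_pileup(sim$dna, ref, th0)

  # DNA purity at edit sites
  j <- dplyr::inner_join(truth$edit_sites, dp, by = c("chrom", "pos"))
  alt <- ifelse(j$strand == "+", j$G, j$C)
  expect_equal(sum(alt), 0)

  # het allele balance: the exact binomial(n, 1/2) probability of the
  # [0.35, 0.65] window at each observed depth bounds the tail count
  het <- dplyr::inner_join(subset(truth$snps, zygosity == "het"), dp,
                           by = c("chrom", "pos"))
  m <- cbind(het$A, het$C, het$G, het$T)
  altc <- m[cbind(seq_len(nrow(het)), match(het$alt, c("A", "C", "G", "T")))]
  frac <- altc / het$coverage
  in_window <- frac >= 0.35 & frac <= 0.65
  p_window <- mean(vapply(het$coverage, function(n)
    sum(stats::dbinom(ceiling(0.35 * n):floor(0.65 * n), n, 0.5)), numeric(1)))
  # observed coverage of the window should not fall far below expectation
  expect_gt(mean(in_window), p_window - 3 * sqrt(p_window * (1 - p_window) /
                                                   length(in_window)))
  expect_gt(mean(in_window), 0.9)
})

test_that("realized RNA editing levels converge to the planted levels", {
  cfg <- small_config(seed = 19, reads = list(rna_depth = 80, error_rate = 0))
  ref <- simulate_genome(cfg)
  truth <- plant_truth(ref, cfg)
  sim <- simulate_reads(ref, truth, cfg)
  th0 <- detection_thresholds(trim_ends = 0, min_base_quality = 0)
  p <- build_pileup(sim$rna[[1]], ref, th0)
  j <- dplyr::inner_join(truth$edit_sites, p, by = c("chrom", "pos"))
  j <- j[j$coverage >= 50, ]
  alt <- ifelse(j$strand == "+", j$G, j$C)
  se <- sqrt(j$true_level * (1 - j$true_level) / j$coverage)
  dev <- abs(alt / j$coverage - j$true_level)
  # a few 3-sigma outliers among hundreds of sites are expected by chance
  expect_gt(mean(dev < pmax(3 * se, 1e-9) + 1e-12), 0.97)
})
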