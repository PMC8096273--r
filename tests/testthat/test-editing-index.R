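mk_pileup <- function(pos, ref, A = 0L, C = 0L, G = 0L, T = 0L,
                      chrom = "chr1") {
  n <- length(pos)
  tibble::tibble(chrom = rep_len(chrom, n), pos = as.integer(pos),
                 ref = rep_len(ref, n),
                 A = rep_len(as.integer(A), n), C = rep_len(as.integer(C), n),
                 G = rep_len(as.integer(G), n), T = rep_len(as.integer(T), n)) |>
    dplyr::mutate(coverage = A + C + G + T)
}

fam_ref <- function(strand = "+") {
  reps <- tibble::tibble(chrom = "chr1", start = 1L, end = 1000L,
                         family = "fam1", strand = strand, copy_id = "fam1_1")
  manual_ref(strrep("A", 2000), repeats = reps)
}

test_that("family A-to-G index is summed counts over summed coverage", {
  # three A positions: (A=8,G=2), (A=10,G=0), (A=5,G=5) -> 7/30
  p <- mk_pileup(c(10, 20, 30), "A", A = c(8, 10, 5), G = c(2, 0, 5))
  fs <- family_index(p, fam_ref()$repeats, fam_ref())
  ag <- fs[fs$type == "A>G", ]
  expect_equal(ag$numerator, 7)
  expect_equal(ag$denominator, 30)
  expect_equal(ag$index, 7 / 30)

  # no G anywhere: index 0, still defined
  p0 <- mk_pileup(c(10, 20), "A", A = 10)
  ag0 <- dplyr::filter(family_index(p0, fam_ref()$repeats, fam_ref()),
                       type == "A>G")
  expect_equal(ag0$index, 0)
  expect_true(ag0$defined)

  # no covered adenosines at all: undefined (NA), flagged, not 0
  pC <- mk_pileup(10, "C", C = 10)
  agC <- dplyr::filter(family_index(pC, fam_ref()$repeats, fam_ref()),
                       type == "A>G")
  expect_true(is.na(agC$index))
  expect_false(agC$defined)
})

test_that("denominator modes differ exactly as defined", {
  # (A=5,G=5,C=2): all_bases 5/12, A_plus_G 5/10
  p <- mk_pileup(10, "A", A = 5, G = 5, C = 2)
  r <- fam_ref()
  all_b <- dplyr::filter(family_index(p, r$repeats, r,
                                      index_params("all_bases_at_A")),
                         type == "A>G")
  apg <- dplyr::filter(family_index(p, r$repeats, r,
                                    index_params("A_plus_G_only")),
                       type == "A>G")
  expect_equal(all_b$index, 5 / 12)
  expect_equal(apg$index, 5 / 10)
  expect_lte(all_b$index, apg$index)
})

test_that("minus-strand intervals re-orient T>C counts to sense A>G", {
  # reference T positions with C reads on a minus-strand repeat are editing
  ref <- manual_ref(strrep("T", 2000),
                    repeats = tibble::tibble(chrom = "chr1", start = 1L,
                                             end = 1000L, family = "fam1",
                                             strand = "-", copy_id = "f1"))
  p <- mk_pileup(c(10, 20), "T", T = c(18, 10), C = c(2, 0))
  ag <- dplyr::filter(family_index(p, ref$repeats, ref), type == "A>G")
  expect_equal(ag$numerator, 2)
  expect_equal(ag$denominator, 30)
})

test_that("family selection applies the 2-fold rule with ties selecting", {
  mk_spec <- function(fam, ag, ct) {
    tibble::tibble(family = fam, type = c("A>G", "C>T", "G>A"),
                   numerator = c(ag, ct, 0) * 1000,
                   denominator = 1e5,
                   index = c(ag, ct, 0) / 100,
                   defined = TRUE, genomic_abundance = 0.1)
  }
  spectra <- dplyr::bind_rows(mk_spec("f3fold", 0.9, 0.3),
                              mk_spec("f1.3fold", 0.4, 0.3),
                              mk_spec("f2fold", 0.6, 0.3),
                              mk_spec("fzero", 0.2, 0.0))
  sel <- select_families(spectra, index_params())
  expect_true(sel$selected[sel$family == "f3fold"])
  expect_false(sel$selected[sel$family == "f1.3fold"])
  expect_true(sel$selected[sel$family == "f2fold"])     # tie at 2 selects
  expect_true(sel$selected[sel$family == "fzero"])      # infinite ratio
})

test_that("global index is coverage-weighted, not a mean of family indexes", {
  # two families: 2/100 and 8/100 -> 10/200 = 5%
  ref <- manual_ref(strrep("A", 4000),
                    repeats = tibble::tibble(
                      chrom = "chr1", start = c(1L, 2001L),
                      end = c(1000L, 3000L), family = c("f1", "f2"),
                      strand = "+", copy_id = c("a", "b")))
  p <- dplyr::bind_rows(
    mk_pileup(c(10, 20), "A", A = c(49, 49), G = c(1, 1)),          # f1: 2/100
    mk_pileup(c(2010, 2020), "A", A = c(46, 46), G = c(4, 4)))      # f2: 8/100
  g <- global_index(p, ref$repeats, c("f1", "f2"))
  expect_equal(g$index, 10 / 200)
  expect_equal(g$numerator, 10)
  # one family only: global equals that family's index
  g1 <- global_index(p, ref$repeats, "f1")
  f1 <- dplyr::filter(family_index(p, ref$repeats, ref),
                      family == "f1", type == "A>G")
  expect_equal(g1$index, f1$index)
  # index invariant to row order of the pileup
  g2 <- global_index(p[sample(nrow(p)), ], ref$repeats, c("f1", "f2"))
  expect_equal(g2$index, g$index)
})

test_that("planted uniform editing levels are recovered by the index", {
  for (p_true in c(0.01, 0.05)) {
    cfg <- small_config(
      seed = round(1000 * p_true),
      editing = list(mode = "uniform_adenosines", level_fixed = p_true),
      recoding_sites = 0, hyper_molecules = 0,
      snp_rate_hom = 0, snp_rate_het = 0,
      reads = list(error_rate = 0))
    ref <- simulate_genome(cfg)
    truth <- plant_truth(ref, cfg)
    sim <- simulate_reads(ref, truth, cfg)
    pu <- build_pileup(sim$rna[[1]], ref, detection_thresholds())
    g <- global_index(pu, ref$repeats, unique(ref$repeats$family))
    se <- sqrt(p_true * (1 - p_true) / g$denominator)
    expect_lt(abs(g$index - p_true), 3 * se + 1e-9)
  }
})

test_that("harmonized mixed-length samples give concordant indexes", {
  cfg150 <- small_config(seed = 3,
                         editing = list(mode = "uniform_adenosines",
                                        level_fixed = 0.05),
                         recoding_sites = 0, hyper_molecules = 0,
                         snp_rate_hom = 0, snp_rate_het = 0,
                         reads = list(error_rate = 0, length = 150))
  ref <- simulate_genome(cfg150)
  truth <- plant_truth(ref, cfg150)
  sim150 <- simulate_reads(ref, truth, cfg150)
  cfg75 <- small_config(seed = 3,
                        editing = list(mode = "uniform_adenosines",
                                       level_fixed = 0.05),
                        recoding_sites = 0, hyper_molecules = 0,
                        snp_rate_hom = 0, snp_rate_het = 0,
                        reads = list(error_rate = 0, length = 75))
  sim75 <- simulate_reads(ref, truth, cfg75)
  th <- detection_thresholds()
  h150 <- harmonize_read_length(sim150$rna[[1]], 50)
  h75 <- harmonize_read_length(sim75$rna[[1]], 50)
  # every truncated alignment spans at most 50 reference bases and, after
  # end trimming, contributes exactly 30 counted bases
  expect_true(all(nchar(h150$seq) <= 50))
  p150 <- build_pileup(h150, ref, th)
  expect_equal(sum(p150$coverage), nrow(h150) * 30)
  gi <- function(p) global_index(p, ref$repeats,
                                 unique(ref$repeats$family))
  g150 <- gi(p150)
  g75 <- gi(build_pileup(h75, ref, th))
  # both harmonized samples estimate the same planted level
  se <- sqrt(0.05 * 0.95 * (1 / g150$denominator + 1 / g75$denominator))
  expect_lt(abs(g150$index - g75$index), 4 * se)
})
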