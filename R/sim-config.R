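#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: the layout of the
#' simulated genome (repeat families, protein-coding genes), the planted
#' variation (homozygous and heterozygous SNPs, clustered A-to-I editing
#' sites, isolated recoding sites, hyper-edited molecules) and the sequencing
#' model (read length, depth, per-base error rate, constant base quality).
#' The same configuration with the same seed always reproduces byte-identical
#' outputs.
#'
#' @param genome_length Total genome size in bp, split near-evenly across
#'   chromosomes.
#' @param n_chromosomes Number of chromosomes.
#' @param repeat_families List of families, each a list with `name`,
#'   `unit_length` (bp), `copies` and `palindromic`. A palindromic copy embeds
#'   `unit` followed by its reverse complement, so it can fold into an
#'   intramolecular double-stranded RNA -- the canonical ADAR substrate.
#' @param n_genes Number of single-exon protein-coding genes.
#' @param cds_length Annotated CDS length in bp (excluding the stop codon);
#'   must be divisible by 3.
#' @param snp_rate_hom,snp_rate_het Per-bp probability of a planted
#'   homozygous-alternate / heterozygous SNP.
#' @param editing List controlling planted editing:
#'   `cluster_rate` (probability that a repeat copy hosts a cluster),
#'   `sites_per_cluster`, `level_shape1`/`level_shape2` (Beta parameters for
#'   per-site editing levels), `level_fixed` (overrides the Beta draw with a
#'   constant level when non-NULL), `motif_bias` (relative weight against G at
#'   the -1 sense position and for G at +1; 1 disables the bias) and `mode`
#'   (`"clusters"` or `"uniform_adenosines"`, the latter editing every sense
#'   adenosine of every repeat copy at `level_fixed`).
#' @param recoding_sites Number of isolated recoding sites planted at CDS
#'   adenosines.
#' @param recoding_level Editing level of planted recoding sites (recycled).
#' @param hyper_molecules Number of planted hyper-edited RNA molecules,
#'   emitted only to the unaligned FASTQ.
#' @param edits_per_molecule Number of edited adenosines per hyper molecule.
#' @param reads List with `length` (bp), `dna_depth`, `rna_depth` (fold
#'   coverage), `error_rate` (per base) and `base_quality` (constant Phred).
#' @param n_rna_samples Number of RNA samples sharing one DNA genotype.
#' @param seed Integer run seed.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 100000,
                       n_chromosomes = 1,
                       repeat_families = list(
                         list(name = "ANGEL", unit_length = 150, copies = 60,
                              palindromic = TRUE),
                         list(name = "HE1_DR1", unit_length = 300, copies = 60,
                              palindromic = FALSE)
                       ),
                       n_genes = 6,
                       cds_length = 300,
                       snp_rate_hom = 0.001,
                       snp_rate_het = 0.001,
                       editing = list(),
                       recoding_sites = 8,
                       recoding_level = 0.3,
                       hyper_molecules = 20,
                       edits_per_molecule = 12,
                       reads = list(),
                       n_rna_samples = 4,
                       seed = 1L) {
  editing_default <- list(
    cluster_rate = 0.8, sites_per_cluster = 5,
    level_shape1 = 1, level_shape2 = 4, level_fixed = NULL,
    motif_bias = 4, mode = "clusters"
  )
  reads_default <- list(
    length = 150, dna_depth = 30, rna_depth = 50,
    error_rate = 1e-3, base_quality = 37
  )
  editing <- utils::modifyList(editing_default, editing)
  reads <- utils::modifyList(reads_default, reads)

  cfg <- list(
    genome_length = genome_length, n_chromosomes = n_chromosomes,
    repeat_families = repeat_families, n_genes = n_genes,
    cds_length = cds_length,
    snp_rate_hom = snp_rate_hom, snp_rate_het = snp_rate_het,
    editing = editing, recoding_sites = recoding_sites,
    recoding_level = recoding_level,
    hyper_molecules = hyper_molecules,
    edits_per_molecule = edits_per_molecule,
    reads = reads, n_rna_samples = n_rna_samples,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  assert_that(is_count(cfg$genome_length), "genome_length must be a positive integer")
  assert_that(is_count(cfg$n_chromosomes), "n_chromosomes must be a positive integer")
  assert_that(is.list(cfg$repeat_families), "repeat_families must be a list")
  for (fam in cfg$repeat_families) {
    assert_that(
      is.character(fam$name) && is_count(fam$unit_length) &&
        is_count(fam$copies) && is.logical(fam$palindromic),
      "each repeat family needs name, unit_length, copies, palindromic"
    )
  }
  assert_that(cfg$n_genes >= 0 && cfg$n_genes == floor(cfg$n_genes),
              "n_genes must be a non-negative integer")
  assert_that(cfg$cds_length %% 3 == 0 && cfg$cds_length >= 9,
              "cds_length must be >= 9 and divisible by 3")
  assert_that(is_fraction(cfg$snp_rate_hom), "snp_rate_hom must be in [0,1]")
  assert_that(is_fraction(cfg$snp_rate_het), "snp_rate_het must be in [0,1]")
  ed <- cfg$editing
  assert_that(is_fraction(ed$cluster_rate), "editing$cluster_rate must be in [0,1]")
  assert_that(ed$sites_per_cluster >= 1, "editing$sites_per_cluster must be >= 1")
  assert_that(ed$level_shape1 > 0 && ed$level_shape2 > 0,
              "editing level Beta parameters must be positive")
  assert_that(is.null(ed$level_fixed) || is_fraction(ed$level_fixed),
              "editing$level_fixed must be NULL or in [0,1]")
  assert_that(ed$motif_bias > 0, "editing$motif_bias must be positive")
  assert_that(ed$mode %in% c("clusters", "uniform_adenosines"),
              "editing$mode must be 'clusters' or 'uniform_adenosines'")
  assert_that(cfg$recoding_sites >= 0, "recoding_sites must be >= 0")
  assert_that(all(is_fraction(cfg$recoding_level)) ||
                all(vapply(cfg$recoding_level, is_fraction, TRUE)),
              "recoding_level must be in [0,1]")
  assert_that(cfg$hyper_molecules >= 0, "hyper_molecules must be >= 0")
  assert_that(cfg$edits_per_molecule >= 1, "edits_per_molecule must be >= 1")
  rd <- cfg$reads
  assert_that(is_count(rd$length), "reads$length must be a positive integer")
  assert_that(rd$dna_depth > 0 && rd$rna_depth > 0, "depths must be positive")
  assert_that(is_fraction(rd$error_rate), "reads$error_rate must be in [0,1]")
  assert_that(rd$base_quality >= 0, "reads$base_quality must be >= 0")
  assert_that(is_count(cfg$n_rna_samples), "n_rna_samples must be >= 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d bp over %d chromosome(s)\n",
              x$genome_length, x$n_chromosomes))
  cat(sprintf("  repeat families: %s\n",
              paste(vapply(x$repeat_families, function(f)
                sprintf("%s (%dx%dbp%s)", f$name, f$copies, f$unit_length,
                        if (f$palindromic) ", palindromic" else ""),
                character(1)), collapse = ", ")))
  cat(sprintf("  genes: %d (CDS %d bp); SNP rates hom %.3g / het %.3g per bp\n",
              x$n_genes, x$cds_length, x$snp_rate_hom, x$snp_rate_het))
  cat(sprintf("  editing: mode=%s cluster_rate=%.2g sites/cluster=%d motif_bias=%.2g\n",
              x$editing$mode, x$editing$cluster_rate,
              x$editing$sites_per_cluster, x$editing$motif_bias))
  cat(sprintf("  reads: %d bp, DNA %gx, RNA %gx x %d samples, error %.2g, Q%d\n",
              x$reads$length, x$reads$dna_depth, x$reads$rna_depth,
              x$n_rna_samples, x$reads$error_rate, x$reads$base_quality))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
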