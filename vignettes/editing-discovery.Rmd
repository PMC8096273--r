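---
title: "Discovering A-to-I RNA editing from matched DNA and RNA sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering A-to-I RNA editing from matched DNA and RNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edscope)
```

## The problem

Adenosine-to-inosine (A-to-I) editing, catalysed by ADAR enzymes on
double-stranded RNA, is read by sequencers as guanosine: an edited adenosine
appears as an A-to-G mismatch between RNA reads and the reference genome.
The difficulty is that so do single-nucleotide polymorphisms, somatic
variation, sequencing errors and misalignment. `edscope` implements a
discovery pipeline that separates editing from these confounders using four
ingredients:

1. **Matched DNA genotyping.** RNA mismatches are only trusted at positions
   the same individual's DNA shows to be homozygous-reference, which removes
   genomic variants without any population SNP database.
2. **A filter cascade** exploiting the biology of editing: ADAR acts on
   duplexes and deposits *clusters* of same-type mismatches, while alignment
   artifacts produce mixed-type clusters and homopolymer errors.
3. **Hyper-editing rescue.** Reads so heavily edited that aligners reject
   them are realigned in an A-to-G-collapsed sequence space and their
   clusters recovered against the unmasked genome.
4. **Editing indexes.** Beyond per-site calls, a coverage-weighted global
   index -- G reads over all reads at reference adenosines within repeat
   territory -- summarises overall editing activity per repeat family.

Everything is exercised on synthetic data with planted ground truth: the
simulator is a first-class module whose output states exactly which SNPs,
editing clusters, recoding sites and hyper-edited molecules exist, so every
stage has an oracle.

## The detection model

Let a position have filtered RNA coverage $n$ and alternate count $k$. A
candidate requires

* read-end trimming: the first and last 10 *aligned* bases of every read are
  ignored (read-end artifacts), and bases under Phred 30 are discarded;
* $n \ge 10$ and frequency $k/n \ge 1\%$;
* at least 3 reads supporting the variant (`min_alt_count`). Matched DNA/RNA
  editing callers impose this floor by default, and it matters: at 50x
  coverage a single errored read is already a 2% "variant", and without the
  floor such singletons flood the neighbourhood filters below;
* matched DNA: coverage $\ge 10$ with non-reference fraction $< 5\%$
  (`genotype_dna()`); positions failing this in *any* DNA sample -- or
  lacking DNA support entirely -- are excluded.

The 5% heterozygosity bound is our quantification of "homozygous": it
tolerates one errored DNA read at 20x while a true heterozygote sits near
50%.

Candidates are then oriented onto the transcribed strand
(`orient_sites()`): counting is reference-forward, so sense A-to-G on a
minus-strand feature surfaces as forward T-to-C; using the annotated
repeat/gene strand (the simulator emits sense-stranded reads, as stranded
protocols do) restores the biological substitution type before any
type-based filtering.

## The filter cascade

Four snapshot filters run in fixed order (`apply_cascade()`), each only
ever removing sites, evaluated against the step's input so that the result
is independent of row order and re-application is a no-op:

1. **Multi-allelic** (`filter_multiallelic()`): a position whose
   second-most-frequent alternate base reaches 1% with at least 2 reads is
   discarded entirely -- two simultaneous "edits" at one position is an
   alignment signature. The 1%/2-read quantification is ours; it is
   configurable.
2. **Homopolymer** (`filter_homopolymer()`): sites inside or immediately
   adjacent to runs of 5 or more identical bases are removed. The run length
   is likewise a declared, configurable choice.
3. **Heterogeneous cluster** (`filter_heterogeneous_cluster()`): a site with
   any *different*-type candidate within 400 bp is removed. Mixed-type
   clusters typify reads mapped to the wrong copy of duplicated loci.
4. **Isolated sites** (`filter_isolated()`): a site survives only with a
   *same*-type candidate within 400 bp. This costs genuinely isolated
   recoding sites (a known, accepted blind spot of neighbour-support
   strategies) in exchange for a large specificity gain.

One 400-bp window serves both neighbourhood filters -- a single locality
scale rather than two knobs. Distances are centre-to-centre with the
boundary inclusive (400 acts, 401 does not), never across chromosomes or
samples. Survivors are merged across samples by position and substitution
(`merge_samples()`), recording per-sample support.

## Hyper-editing rescue

`build_masked_index()` collapses A onto G in the forward genome and T onto
C for the reverse-strand space, indexing every 21-mer of both. K-mers
occurring more than once across the two spaces cannot anchor anything --
this census is what rejects reads from palindromic repeats, which are
legitimately ambiguous between a sense arm and the antisense of the other
arm. `rescue_reads()` transforms each read the same way, seeds it at
several offsets, verifies every distinct candidate locus ungapped
end-to-end in masked space (up to 5% masked mismatches, absorbing
non-A-to-G sequencing errors), and requires exactly one verifying locus. A
stray single-seed hit that fails verification is not counted as ambiguity.
Mismatches are then recovered against the *unmasked* genome and the read
kept only if its A-to-G cluster has at least 5 members, covering at least
5% of the read, making up at least 60% of all its mismatches. These
thresholds follow the established hyper-editing screening scheme and are
all configurable; exact seed-and-verify alignment replaces the original
BWA-based realignment because the simulator's reads are gapless and the
upstream aligner is outside this package's scope.

## Editing indexes

The family index (`family_index()`) is, per repeat family and substitution
type, the ratio of mismatching bases to all bases aligned over the family's
reference positions of the relevant nucleotide -- *not* a mean of per-site
frequencies, so deeply covered positions weigh more. Two denominator
conventions exist in the literature and both are implemented: all bases at
reference adenosines (used for repeat indexes) and A+G bases only (used for
the recoding site-set index). A family is trusted for the global index when
its A-to-G index is at least 2-fold the next most frequent substitution
(`select_families()`; ties select; an undefined index never selects), and
`global_index()` pools numerators and denominators across all selected
families. The index deliberately applies no per-site frequency cutoff: it
is a global average over edited and unedited adenosines alike.

Because longer reads accumulate more edits per alignment in real aligners,
indexes should only be compared at a common read length;
`harmonize_read_length()` truncates reads to their first *n* bases in read
orientation, recomputing coordinates. Note a limitation of the synthetic
benchmark here: simulated reads are emitted pre-aligned, so the
length-dependent mapping bias that motivates harmonization does not arise
in simulation, and tests can only verify the truncation mechanics and
cross-length concordance, not the bias reduction itself.

## Recoding sites

`annotate_sites()` assigns the most specific region over all overlapping
transcripts (CDS over non-coding exon over intron over intergenic) and
re-orients forward T-to-C calls in minus-strand genes to sense A-to-G.
`classify_effects()` rebuilds the affected codon with A replaced by G on
the coding strand and translates with the standard genetic code:
synonymous, missense, stop gain/loss, and start loss when the initiator
ATG is hit. Stop categories are computed rather than assumed impossible.
Multi-transcript sites are classified per transcript with a worst-effect
summary (start loss > stop gain > stop loss > missense > synonymous).
Coding calls being noisier, `consensus_recoding()` keeps only sites
detected in at least 2 samples; "detected" means present in the per-sample
post-cascade coding set. `quantify_known()` measures levels at a declared
site list as G/(G+A) per sample, flagging entries under 10 reads as missing
rather than zero, and `level_consistency()` reports the per-site
coefficient of variation (n−1 standard deviation over mean) with its
median across sites.

## The synthetic study

`sim_config()` defaults define the simulated study:

* 100 kb genome, one chromosome; two repeat families of 60 copies each --
  one palindromic (unit + exact reverse complement, the self-folding dsRNA
  substrate) and one dispersed -- plus 6 single-exon protein-coding genes;
* homozygous and heterozygous SNPs at $10^{-3}$ per bp each;
* editing clusters in 80% of repeat copies, 5 sites per cluster, per-site
  levels drawn from Beta(1, 4) (mean 20%, right-skewed toward low levels,
  typical of repeat editing; no generative distribution is established in
  the literature, so the Beta parameters are exposed in the configuration);
* the ADAR nearest-neighbour bias planted by weighting candidate adenosines
  1/4 when G precedes and 4-fold when G follows (sense strand);
* 8 isolated recoding sites at CDS adenosines, level 0.3;
* 20 hyper-edited molecules of 12 edits each, placed in unique non-repeat
  background so that locus uniqueness holds by construction, and emitted
  only to the unaligned FASTQ;
* 150-bp single-end reads at 30x DNA and 50x RNA over 4 RNA samples sharing
  one DNA genotype, per-base error $10^{-3}$, constant Phred 37.

Design choices worth knowing:

* **Clusters avoid homopolymer contexts.** The cascade removes homopolymer
  sites by design, so planting edits there would make them undetectable by
  construction (and ADAR disfavours such runs); the generator therefore
  excludes them, which is what makes "100% cascade survival on noise-free
  data" a meaningful property.
* Editing is Bernoulli per read per site; hyper molecules model within-
  molecule correlation separately. Reads are emitted pre-aligned with true
  coordinates (the external aligner is out of scope); hyper molecules are
  the one unaligned output.
* Heterozygous SNPs segregate at 50% per read. DNA reads never carry edits.
* What the simulator does *not* model: indels, splicing, PCR duplicates,
  paired ends, quality-score variation, coverage biases, and aligner
  mapping bias. Passing tests therefore demonstrate the pipeline's logic
  and calibration under clean uniform coverage, not robustness to every
  artifact of real libraries.

Determinism: each operation derives its RNG stream from the single run
seed, so one seed reproduces every file byte-for-byte.

## Numerical and boundary conventions

* Coordinates are 1-based everywhere, in memory and on disk (VCF-like);
  intervals are closed.
* Frequency/coverage/fold thresholds are inclusive ($\ge$); the
  heterozygosity bound is exclusive at 5% (a 5.0% non-reference fraction is
  already non-homozygous).
* Undefined ratios (index with empty denominator, noise with no A-to-G,
  CoV of a single level) are `NA` with a flag, never silently 0.
* The noise estimate takes whichever non-A-to-G type ranks second -- the
  runner-up is usually C-to-T but is reported, not hard-coded.
* Motif flanks that run off a contig are excluded position-wise and
  tallied.

## Problem sizes used in the checks

The automated checks simulate, at fixed seeds: a 400-kb genome with ~1,000
homozygous and ~1,000 heterozygous SNPs and 2,000 clustered edit sites at
30x/50x over four samples (SNP exclusion and spectrum purity); 300 kb with
~100 kb of repeat territory at three uniform editing levels (index
recovery); 500 hyper-edited molecules with mixed-type controls (rescue
soundness); and 200 random candidate sets of up to 1,000 sites compared
against all-pairs brute-force filters. These sizes were chosen as the
smallest at which the binomial error bars of the planted quantities are
tight enough for the properties to be sharp.

## Known limitations

* Strand resolution relies on feature annotation; an unannotated antisense
  transcript would be mis-oriented.
* The cascade's isolated-site filter removes truly isolated recoding sites;
  quantification of a known site list (`quantify_known()`) is the intended
  path for those.
* The hyper-editing stage handles ungapped alignments only.
* Index values depend on read length and coverage profile and should not be
  compared across differently sequenced studies without harmonization.
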