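ref150 <- local({
  set.seed(101)
  manual_ref(paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                   collapse = ""))
})

test_that("read_alignments keeps mapped primary records and counts skips", {
  dir <- withr::local_tempdir()
  cs <- as.character(ref150$genome[["chr1"]])
  aln <- manual_aln("chr1", c(11, 21, 31), substring(cs, c(11, 21, 31),
                                                     c(110, 120, 130)))
  sam <- file.path(dir, "x.sam")
  lines <- c("@HD\tVN:1.6\tSO:unknown", "@SQ\tSN:chr1\tLN:400",
             sprintf("%s\t%d\tchr1\t%d\t60\t100M\t*\t0\t0\t%s\t%s",
                     aln$qname, aln$flag, aln$pos, aln$seq, aln$qual),
             sprintf("u1\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
                     strrep("A", 100), strrep("J", 100)),
             sprintf("d1\t1024\tchr1\t5\t60\t100M\t*\t0\t0\t%s\t%s",
                     substring(cs, 5, 104), strrep("J", 100)))
  writeLines(lines, sam)
  got <- read_alignments(sam, ref150)
  expect_equal(nrow(got), 3)
  sk <- attr(got, "skipped")
  expect_equal(unname(sk["unmapped"]), 1)
  expect_equal(unname(sk["duplicate"]), 1)

  # header/reference contig mismatch is an error
  bad <- file.path(dir, "bad.sam")
  writeLines(c("@SQ\tSN:chrZ\tLN:400",
               sprintf("r\t0\tchrZ\t1\t60\t10M\t*\t0\t0\t%s\t%s",
                       strrep("A", 10), strrep("J", 10))), bad)
  expect_error(read_alignments(bad, ref150), "does not match")
})

test_that("a record with CIGAR 100M at POS 11 covers positions 11..110", {
  cs <- as.character(ref150$genome[["chr1"]])
  aln <- manual_aln("chr1", 11, substring(cs, 11, 110))
  p <- build_pileup(aln, ref150, detection_thresholds(trim_ends = 0,
                                                      min_base_quality = 0))
  expect_equal(range(p$pos), c(11, 110))
  expect_equal(nrow(p), 100)
  expect_true(all(p$coverage == 1))
})

test_that("end trimming leaves exactly length - 2*trim counted positions", {
  cs <- as.character(ref150$genome[["chr1"]])
  aln <- manual_aln("chr1", 101, substring(cs, 101, 250))  # 150 bp
  p <- build_pileup(aln, ref150, detection_thresholds(trim_ends = 10,
                                                      min_base_quality = 0))
  expect_equal(nrow(p), 130)
  expect_equal(range(p$pos), c(111, 240))
})

test_that("bases below the quality threshold are not counted", {
  cs <- as.character(ref150$genome[["chr1"]])
  qual <- strrep(rawToChar(as.raw(30 + 33)), 50)      # Q30 everywhere
  substr(qual, 25, 25) <- rawToChar(as.raw(29 + 33))  # one Q29 base
  aln <- manual_aln("chr1", 11, substring(cs, 11, 60), qual = qual)
  th <- detection_thresholds(trim_ends = 0, min_base_quality = 30)
  p <- build_pileup(aln, ref150, th)
  expect_false(35 %in% p$pos)  # pos 11 + 25 - 1
  expect_equal(nrow(p), 49)
})

test_that("no-filter pileup equals raw depth and conserves counted bases", {
  cfg <- small_config(seed = 23)
  ref <- simulate_genome(cfg)
  truth <- plant_truth(ref, cfg)
  sim <- simulate_reads(ref, truth, cfg)
  th0 <- detection_thresholds(trim_ends = 0, min_base_quality = 0)
  p <- build_pileup(sim$rna[[1]], ref, th0)
  expect_equal(sum(p$coverage), sum(nchar(sim$rna[[1]]$seq)))
  expect_equal(sum(p$A + p$C + p$G + p$T), sum(p$coverage))

  # conservation with trimming: each 150-bp read contributes 130 bases
  th <- detection_thresholds(trim_ends = 10, min_base_quality = 0)
  pt <- build_pileup(sim$rna[[1]], ref, th)
  expect_equal(sum(pt$coverage), nrow(sim$rna[[1]]) * 130)
})

test_that("pileup equals a naive per-read counter on small instances", {
  set.seed(31)
  cs <- as.character(ref150$genome[["chr1"]])
  n <- 40
  pos <- sample(1:300, n, replace = TRUE)
  len <- sample(c(40, 60, 90), n, replace = TRUE)
  seqs <- substring(cs, pos, pos + len - 1)
  # sprinkle mismatches and low-quality bases
  quals <- vapply(len, function(L) paste(
    sample(c(rawToChar(as.raw(40 + 33)), rawToChar(as.raw(20 + 33))), L,
           replace = TRUE, prob = c(.9, .1)), collapse = ""), character(1))
  for (i in seq_len(n)) {
    o <- sample(len[i], 3)
    for (k in o) substr(seqs[i], k, k) <- sample(c("A", "C", "G", "T"), 1)
  }
  aln <- manual_aln("chr1", pos, seqs, qual = quals,
                    flag = sample(c(0L, 16L), n, replace = TRUE))
  th <- detection_thresholds(trim_ends = 5, min_base_quality = 30)
  p <- build_pileup(aln, ref150, th)
  oracle <- brute_pileup(aln, ref150, th)
  got <- list()
  for (i in seq_len(nrow(p))) {
    for (b in c("A", "C", "G", "T")) {
      cnt <- p[[b]][i]
      if (cnt > 0) got[[paste(p$chrom[i], p$pos[i], b)]] <- cnt
    }
  }
  expect_equal(got[order(names(got))], oracle[order(names(oracle))])
})

test_that("CIGAR insertions, deletions and soft clips are handled", {
  cs <- as.character(ref150$genome[["chr1"]])
  # 10S20M5D20M: query = 10 clip + 20 ref(11..30) + 20 ref(36..55)
  q <- paste0(strrep("A", 10), substring(cs, 11, 30), substring(cs, 36, 55))
  aln <- manual_aln("chr1", 11, q, cigar = "10S20M5D20M")
  th0 <- detection_thresholds(trim_ends = 0, min_base_quality = 0)
  p <- build_pileup(aln, ref150, th0)
  expect_setequal(p$pos, c(11:30, 36:55))     # deletion positions uncounted
  mism <- sum(p$coverage) - sum(
    ifelse(p$ref == "A", p$A, ifelse(p$ref == "C", p$C,
                                     ifelse(p$ref == "G", p$G, p$T))))
  expect_equal(mism, 0)

  # trimming counts aligned bases only: 10S then trim 10 removes ref 11..20
  th10 <- detection_thresholds(trim_ends = 10, min_base_quality = 0)
  p10 <- build_pileup(aln, ref150, th10)
  expect_setequal(p10$pos, c(21:30, 36:45))

  # malformed CIGAR: record skipped with a warning
  bad <- manual_aln("chr1", 11, substring(cs, 11, 40), cigar = "30Q")
  expect_warning(pb <- build_pileup(bad, ref150, th0), "malformed")
  expect_equal(nrow(pb), 0)
})

test_that("harmonize_read_length truncates in read orientation", {
  cs <- as.character(ref150$genome[["chr1"]])
  fwd <- manual_aln("chr1", 11, substring(cs, 11, 160), flag = 0L)
  rev <- manual_aln("chr1", 11, substring(cs, 11, 160), flag = 16L)
  hf <- harmonize_read_length(fwd, 50)
  hr <- harmonize_read_length(rev, 50)
  expect_equal(hf$pos, 11)
  expect_equal(hf$seq, substring(cs, 11, 60))
  expect_equal(hf$cigar, "50M")
  # a reverse read starts at its 3'-most reference position
  expect_equal(hr$pos, 111)
  expect_equal(hr$seq, substring(cs, 111, 160))
  # identity when the target equals the read length
  expect_identical(harmonize_read_length(fwd, 150)$seq, fwd$seq)
})
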