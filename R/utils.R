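# Internal helpers shared across modules.

`%||%` <- rlang::`%||%`

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

is_fraction <- function(x, lo = 0, hi = 1) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= lo && x <= hi
}

# Derive a stream-specific RNG seed from the run seed.  Kept below 2^31 so it
# is always a valid R integer.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587L)
}

comp_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# chromosome sequence as a single character string
chrom_string <- function(ref, chrom) {
  as.character(ref$genome[[chrom]])
}

# Vectorised single-base lookup on one chromosome (1-based positions).
base_at <- function(chromstr, pos) {
  substring(chromstr, pos, pos)
}

phred_char <- function(q) {
  rawToChar(as.raw(q + 33L))
}

# raw byte -> base code 1..4 (A,C,G,T), 0 otherwise
BASE_CODE <- {
  v <- integer(256)
  v[utf8ToInt("A") + 1L] <- 1L
  v[utf8ToInt("C") + 1L] <- 2L
  v[utf8ToInt("G") + 1L] <- 3L
  v[utf8ToInt("T") + 1L] <- 4L
  v
}

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

# severity order used for the worst-effect summary
EFFECT_SEVERITY <- c(
  start_loss = 1, stop_gain = 2, stop_loss = 3, missense = 4, synonymous = 5
)

new_tibble_class <- function(x, class) {
  class(x) <- c(class, class(x))
  x
}
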