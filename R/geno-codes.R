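# Internal genotype coding shared by all modules.
# Integer codes: 1 = LM (Lemont-type parent allele), 2 = TQ (TeQing-type),
# 3 = HET, NA = missing.  On-disk codes: A = LM, B = TQ, H = HET, "-" = NA.

GENO_LM <- 1L
GENO_TQ <- 2L
GENO_HET <- 3L

.geno_labels <- c("LM", "TQ", "HET")
.geno_disk <- c("A", "B", "H")

geno_label <- function(code) {
  out <- rep(NA_character_, length(code))
  ok <- !is.na(code)
  out[ok] <- .geno_labels[code[ok]]
  out
}

geno_disk_code <- function(code) {
  out <- rep("-", length(code))
  ok <- !is.na(code)
  out[ok] <- .geno_disk[code[ok]]
  out
}

geno_from_disk <- function(chr) {
  m <- match(chr, .geno_disk)
  m[chr == "-"] <- NA_integer_
  m
}

# Deterministic sub-stream seeding: every stage reseeds from the global seed
# plus a fixed stage offset, keeping all derived seeds under 2^31.
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(offset)) %% 2147483647)
}
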