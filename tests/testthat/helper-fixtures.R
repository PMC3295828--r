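library(data.table)

# ---- shared simulated dataset (computed once per test run) -----------

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# moderate dataset with planted sites, reused across test files
shared_ds <- function() fixture("shared_ds", {
  cfg <- sim_config(genome_length = 20000L, n_het = 60L, n_syserr = 120L,
                    coverage = 35, seed = 101L)
  simulate_dataset(cfg)
})

shared_calls <- function() fixture("shared_calls",
  read_alignments(shared_ds()$sam, shared_ds()$fasta))

shared_pairs <- function() fixture("shared_pairs",
  pair_overlaps(shared_calls()))

# ---- hand-built SAM fixtures -----------------------------------------

# write a reference FASTA and a SAM file from a record table with
# columns qname, flag, pos (1-based), seq, qual (character; "*" or
# string); cigar defaults to full-match
write_mini_sam <- function(records, refseq, chrom = "chrT",
                           dir = tempfile("mini")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "ref.fa")
  writeLines(c(paste0(">", chrom), refseq), fa)
  records <- as.data.table(records)
  if (!"cigar" %in% names(records))
    records[, cigar := paste0(nchar(seq), "M")]
  if (!"qual" %in% names(records))
    records[, qual := vapply(nchar(seq), function(n)
      paste(rep("I", n), collapse = ""), "")]
  if (!"rnext" %in% names(records)) records[, rnext := "*"]
  if (!"pnext" %in% names(records)) records[, pnext := 0L]
  if (!"tlen" %in% names(records)) records[, tlen := 0L]
  sam <- file.path(dir, "reads.sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, nchar(refseq)))
  rec <- records[, paste(qname, flag, chrom, pos, 60L, cigar, rnext,
                         pnext, tlen, seq, qual, sep = "\t")]
  writeLines(c(hdr, rec), sam)
  list(sam = sam, fasta = fa, chrom = chrom)
}

# paired-end record pair for one fragment: left mate forward (flag
# 99 = paired,proper,mate-reverse,first), right mate reverse (147)
paired_records <- function(qname, pos_left, seq_left, pos_right, seq_right,
                           qual_left = NULL, qual_right = NULL) {
  out <- data.table(
    qname = qname,
    flag = c(99L, 147L),
    pos = c(pos_left, pos_right),
    seq = c(seq_left, seq_right))
  if (!is.null(qual_left)) out[, qual := c(qual_left, qual_right)]
  out
}

phred_chr <- function(q) {
  vapply(q, function(x) rawToChar(as.raw(x + 33L)), "")
}

qual_str <- function(q) paste(phred_chr(q), collapse = "")

# ---- independent oracles ---------------------------------------------

# Poisson-binomial upper tail by exhaustive enumeration over all 2^n
# outcome vectors (independent of the DP implementation)
pb_tail_enum <- function(e, k_obs) {
  n <- length(e)
  total <- 0
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m)[1:n])
    if (sum(bits) >= k_obs)
      total <- total + prod(ifelse(bits == 1, e, 1 - e))
  }
  total
}

PAIR_LEVELS <- c("reference_pair", "snp_pair", "error_pair", "discordant")
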