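PAIR_CATEGORIES <- c("reference_pair", "snp_pair", "error_pair", "discordant")

#' Classify the two base calls of an overlapping mate pair
#'
#' At a position covered by both mates of one fragment, the two calls
#' were sequenced from the same DNA molecule, so they jointly reveal
#' whether a mismatch is a real variant or a base-call error: both
#' matching the reference is a reference-pair, both disagreeing with the
#' reference but agreeing with each other is a SNP-pair, and exactly one
#' disagreeing is an error-pair (the mismatching call is a verified
#' base-call error).  Pairs whose calls disagree with the reference and
#' with each other (two independent errors) are labelled discordant and
#' excluded from all downstream counts.
#'
#' @param ref,fwd,rev reference base and the forward-/reverse-read
#'   calls; vectors over \{A,C,G,T\}.
#' @return factor with levels reference_pair, snp_pair, error_pair,
#'   discordant.
#' @export
classify_pair <- function(ref, fwd, rev) {
  ok <- ref %in% DNA & fwd %in% DNA & rev %in% DNA
  if (!all(ok)) stop("classify_pair: bases must be in {A,C,G,T}")
  out <- ifelse(fwd == ref & rev == ref, "reference_pair",
         ifelse(fwd == rev, "snp_pair",
         ifelse(fwd == ref | rev == ref, "error_pair", "discordant")))
  factor(out, levels = PAIR_CATEGORIES)
}

#' Extract pair calls from overlapping mates
#'
#' Emits one row per (fragment, position) at which both mates cover the
#' position, carrying the forward-read and reverse-read calls and their
#' classification from [classify_pair()].  Fragments whose two mates
#' have inconsistent orientation flags at a position, and pairs
#' involving an N call, are skipped; their counts are recorded in the
#' `skipped` attribute.
#'
#' @param calls a call table from [read_alignments()].
#' @return data.table with columns `chrom`, `pos`, `read`, `ref`,
#'   `base_fwd`, `qual_fwd`, `base_rev`, `qual_rev`, `category`.
#' @export
pair_overlaps <- function(calls) {
  p1 <- calls[mate == 1L, .(chrom, pos, read, ref, base, qual, rev_strand)]
  p2 <- calls[mate == 2L, .(chrom, pos, read, base, qual, rev_strand)]
  m <- merge(p1, p2, by = c("chrom", "pos", "read"),
             suffixes = c("_1", "_2"))
  bad_orient <- m$rev_strand_1 == m$rev_strand_2
  m <- m[!bad_orient]
  pairs <- m[, .(chrom, pos, read, ref,
                 base_fwd = ifelse(rev_strand_1, base_2, base_1),
                 qual_fwd = ifelse(rev_strand_1, qual_2, qual_1),
                 base_rev = ifelse(rev_strand_1, base_1, base_2),
                 qual_rev = ifelse(rev_strand_1, qual_1, qual_2))]
  has_n <- !(pairs$base_fwd %in% DNA) | !(pairs$base_rev %in% DNA) |
    !(pairs$ref %in% DNA)
  pairs <- pairs[!has_n]
  pairs[, category := classify_pair(ref, base_fwd, base_rev)]
  setkey(pairs, chrom, pos)
  setattr(pairs, "skipped",
          c(inconsistent_orientation = sum(bad_orient), n_base = sum(has_n)))
  pairs[]
}

#' Per-site pair-call summary
#'
#' Counts pair categories per genomic position.  `n_pairs` counts the
#' pairs entering the error-rate analysis (reference-, SNP- and
#' error-pairs); discordant pairs are tallied separately and excluded.
#'
#' @param pairs output of [pair_overlaps()].
#' @return data.table with `chrom`, `pos`, `ref`, `n_pairs`, `n_ref`,
#'   `n_snp`, `n_err`, `n_disc`.
#' @export
pair_site_summary <- function(pairs) {
  s <- pairs[, .(
    ref = ref[1L],
    n_ref = sum(category == "reference_pair"),
    n_snp = sum(category == "snp_pair"),
    n_err = sum(category == "error_pair"),
    n_disc = sum(category == "discordant")), by = .(chrom, pos)]
  s[, n_pairs := n_ref + n_snp + n_err]
  setcolorder(s, c("chrom", "pos", "ref", "n_pairs"))
  setkey(s, chrom, pos)
  s[]
}

#' Background per-pair sequencing error rate
#'
#' The fraction of error-pairs among all classified pairs (reference-,
#' SNP- and error-pairs) over sites with at least `min_coverage` pairs.
#' This is the empirical background probability that one call of an
#' overlapping pair is a base-call error, the `p` of all binomial site
#' tests.
#'
#' @param pairs output of [pair_overlaps()].
#' @param min_coverage minimum analysis pairs per site (default 10).
#' @return scalar probability.
#' @export
error_rate <- function(pairs, min_coverage = 10L) {
  s <- pair_site_summary(pairs)[n_pairs >= min_coverage]
  if (!nrow(s)) stop("error_rate: no site meets min_coverage = ",
                     min_coverage)
  s[, sum(n_err)] / s[, sum(n_pairs)]
}

#' Per-site per-strand coverage and mismatch counts
#'
#' @param calls a call table from [read_alignments()].
#' @return data.table with `chrom`, `pos`, `ref`, `cov_fwd`, `mm_fwd`,
#'   `cov_rev`, `mm_rev` (calls with base N are ignored).
#' @export
site_strand_summary <- function(calls) {
  s <- calls[base %in% DNA, .(
    ref = ref[1L],
    cov_fwd = sum(!rev_strand),
    mm_fwd = sum(!rev_strand & base != ref),
    cov_rev = sum(rev_strand),
    mm_rev = sum(rev_strand & base != ref)), by = .(chrom, pos)]
  setattr(s, "class", c("data.table", "data.frame"))
  setkey(s, chrom, pos)
  s[]
}

#' One-site pileup view
#'
#' Convenience accessor returning the calls overlapping a single
#' position, for inspection and for site-at-a-time operations.
#'
#' @param calls a call table.
#' @param chrom_ reference name.
#' @param pos_ 0-based position.
#' @return data.table of the site's calls.
#' @export
site_pileup <- function(calls, chrom_, pos_) {
  calls[chrom == chrom_ & pos == pos_]
}
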