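#' Choose the error-enriched sequencing direction at a site
#'
#' The direction (forward or reverse read orientation) with the larger
#' proportion of base-calls differing from the reference is chosen;
#' `q1` is the mismatch proportion in the chosen direction and `q2` in
#' the other.  Ties choose forward; a direction with no coverage has
#' proportion 0.
#'
#' @param cov_fwd,mm_fwd,cov_rev,mm_rev per-strand coverage and
#'   mismatch counts (vectorized).
#' @return data.table with `direction` ("+"/"-"), `q1`, `q2`.
#' @export
choose_direction <- function(cov_fwd, mm_fwd, cov_rev, mm_rev) {
  qf <- ifelse(cov_fwd > 0, mm_fwd / cov_fwd, 0)
  qr <- ifelse(cov_rev > 0, mm_rev / cov_rev, 0)
  rev_chosen <- qr > qf
  data.table(direction = ifelse(rev_chosen, "-", "+"),
             q1 = pmax(qf, qr), q2 = pmin(qf, qr))
}

#' Paired t statistic between two quality-score vectors
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = w0 - w1` paired
#' elementwise (one element per read covering both positions).
#' Degenerate cases use bounded sentinels to keep design matrices
#' finite: fewer than 2 pairs gives 0 (flagged via the `degenerate`
#' attribute), and `sd(d) = 0` with nonzero mean gives +/-100.
#'
#' @param w0 quality scores at the site.
#' @param w1 quality scores one position onward, same reads, same order.
#' @return t statistic (scalar).
#' @export
paired_t <- function(w0, w1) {
  stopifnot(length(w0) == length(w1))
  n <- length(w0)
  if (n < 2L) {
    out <- 0
    attr(out, "degenerate") <- "fewer than 2 pairs"
    return(out)
  }
  d <- w0 - w1
  sdd <- sd(d)
  md <- mean(d)
  if (sdd == 0) {
    if (md == 0) return(0)
    out <- sign(md) * 100
    attr(out, "degenerate") <- "zero variance of differences"
    return(out)
  }
  md / (sdd / sqrt(n))
}

# vectorized paired-t over groups: n, mean(d), sd(d) per group
paired_t_vec <- function(n, md, sdd) {
  ifelse(n < 2L, 0,
  ifelse(is.na(sdd) | sdd == 0, ifelse(md == 0, 0, sign(md) * 100),
         md / (sdd / sqrt(n))))
}

#' Candidate heterozygous sites from a pileup
#'
#' The default candidate filter when no external site list (e.g. a
#' caller's VCF) is supplied: positions with at least `min_frac` of the
#' base-calls differing from the reference and at least `min_diff`
#' differences in absolute count.
#'
#' @param calls a call table from [read_alignments()].
#' @param min_frac minimum mismatch fraction (default 0.10).
#' @param min_diff minimum mismatch count (default 5).
#' @return data.table with `chrom`, `pos`, `cov`, `mm`.
#' @export
candidate_sites <- function(calls, min_frac = 0.10, min_diff = 5L) {
  s <- site_strand_summary(calls)
  s[, `:=`(cov = cov_fwd + cov_rev, mm = mm_fwd + mm_rev)]
  s[mm >= min_diff & mm >= min_frac * cov, .(chrom, pos, cov, mm)]
}

#' Extract classifier features for candidate sites
#'
#' For each site the error-enriched direction is chosen
#' ([choose_direction()]); the feature vector is `(b_-2, b_-1, b_0,
#' q1 - q2, q1, PT(w0, w1))` where `b_i` is the reference base `i`
#' places from the site walking in the chosen direction (read off the
#' reverse complement when the chosen direction is reverse), and
#' `PT(w0, w1)` is the paired t statistic between the quality scores at
#' the site and at the position one step onward in the chosen
#' direction, paired by read (all reads covering both positions,
#' regardless of orientation).
#'
#' Sites with no mismatching call, no coverage, or contexts beyond the
#' contig edge are rejected with a reason.
#'
#' @param calls a call table from [read_alignments()].
#' @param sites data.frame with `chrom`, `pos` (0-based).
#' @param reference a [Biostrings::DNAStringSet]; defaults to the
#'   reference attached to `calls`.
#' @return data.table with one row per input site: `chrom`, `pos`,
#'   `ok`, `reason`, `direction`, `b_m2`, `b_m1`, `b_0`, `delta_q`,
#'   `q1`, `pt`.
#' @export
site_features <- function(calls, sites, reference = NULL) {
  reference <- reference %||% attr(calls, "reference")
  if (is.null(reference)) stop("no reference supplied or attached")
  sites <- as.data.table(sites)[, .(chrom, pos)]
  sites[, site := .I]

  ss <- site_strand_summary(calls)
  f <- merge(sites, ss, by = c("chrom", "pos"), all.x = TRUE)
  setorder(f, site)
  f[is.na(cov_fwd), `:=`(cov_fwd = 0L, mm_fwd = 0L, cov_rev = 0L,
                         mm_rev = 0L)]
  cd <- choose_direction(f$cov_fwd, f$mm_fwd, f$cov_rev, f$mm_rev)
  f[, `:=`(direction = cd$direction, q1 = cd$q1, q2 = cd$q2,
           delta_q = cd$q1 - cd$q2)]

  refchars <- lapply(as.character(reference), function(s)
    strsplit(s, "", fixed = TRUE)[[1]])
  lens <- vapply(refchars, length, 0L)

  f[, ok := TRUE]
  f[, reason := NA_character_]
  f[cov_fwd + cov_rev == 0L, `:=`(ok = FALSE, reason = "no_coverage")]
  f[ok & mm_fwd + mm_rev == 0L, `:=`(ok = FALSE, reason = "no_mismatch")]
  # chosen-direction offsets -2..+1 must lie inside the contig
  L <- lens[f$chrom]
  edge <- ifelse(f$direction == "+",
                 f$pos - 2L < 0L | f$pos + 1L >= L,
                 f$pos + 2L >= L | f$pos - 1L < 0L)
  f[ok & edge, `:=`(ok = FALSE, reason = "contig_edge")]

  base_at <- function(chroms, gp) {
    out <- character(length(gp))
    for (ch in unique(chroms)) {
      i <- chroms == ch
      out[i] <- refchars[[ch]][gp[i] + 1L]
    }
    out
  }
  sgn <- ifelse(f$direction == "+", 1L, -1L)
  gp <- function(o) pmin(pmax(f$pos + sgn * o, 0L), L - 1L)
  b <- lapply(c(-2L, -1L, 0L), function(o) {
    ch <- base_at(f$chrom, gp(o))
    ifelse(f$direction == "+", ch, complement_chr(ch))
  })
  f[, `:=`(b_m2 = b[[1L]], b_m1 = b[[2L]], b_0 = b[[3L]])]
  f[!is.na(reason) & reason == "contig_edge",
    `:=`(b_m2 = NA_character_, b_m1 = NA_character_, b_0 = NA_character_)]

  # paired t: qualities at the site vs one step onward in read direction
  c0 <- calls[sites, on = c("chrom", "pos"), nomatch = NULL,
              .(site = i.site, read, mate, q0 = qual)]
  nb <- f[, .(site, chrom, pos = pos + ifelse(direction == "+", 1L, -1L))]
  c1 <- calls[nb, on = c("chrom", "pos"), nomatch = NULL,
              .(site = i.site, read, mate, q1n = qual)]
  pt_dt <- merge(c0, c1, by = c("site", "read", "mate"))
  ptv <- pt_dt[, .(npair = .N, md = mean(q0 - q1n),
                   sdd = sd(q0 - q1n)), by = site]
  f <- merge(f, ptv, by = "site", all.x = TRUE)
  f[, pt := ifelse(is.na(npair), 0,
                   paired_t_vec(npair, md, sdd))]
  setorder(f, site)
  f[, .(chrom, pos, ok, reason, direction, cov = cov_fwd + cov_rev,
        b_m2, b_m1, b_0, delta_q, q1, pt)]
}

#' Encode a feature table as a regression design matrix
#'
#' Nucleotide features are one-hot encoded with reference level A
#' (three indicator columns each), yielding 13 columns with the
#' intercept: `(Intercept)`, 9 base indicators, `delta_q`, `q1`, `pt`.
#' The `delta_q`-only encoding (directionality-bias ablation) has 2
#' columns.
#'
#' @param features output of [site_features()] (rows with `ok = TRUE`).
#' @param features_used "full" or "delta_q".
#' @return numeric design matrix.
#' @export
encode_features <- function(features, features_used = c("full", "delta_q")) {
  features_used <- match.arg(features_used)
  f <- as.data.table(features)
  n <- nrow(f)
  if (features_used == "delta_q")
    return(cbind(`(Intercept)` = rep(1, n), delta_q = f$delta_q))
  ind <- function(bcol, nm) {
    m <- vapply(c("C", "G", "T"), function(bb) as.numeric(bcol == bb),
                numeric(n))
    if (n == 1L) m <- matrix(m, nrow = 1L,
                             dimnames = list(NULL, c("C", "G", "T")))
    colnames(m) <- paste0(nm, colnames(m))
    m
  }
  cbind(`(Intercept)` = rep(1, n),
        ind(f$b_m2, "b_m2"), ind(f$b_m1, "b_m1"), ind(f$b_0, "b_0"),
        delta_q = f$delta_q, q1 = f$q1, pt = f$pt)
}
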