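#' Exact binomial upper-tail p-value for a site's error count
#'
#' Probability of observing `k` or more errors among `n` trials under a
#' background per-call (per-pair) error probability `p`:
#' `P(K >= k | n) = sum_{j=k}^{n} C(n,j) p^j (1-p)^(n-j)`.  Computed via
#' the regularized incomplete beta (`pbinom`), which is accurate deep
#' into the tail; results are clipped to `[1e-320, 1]`.
#'
#' @param k observed error count (vectorized).
#' @param n coverage (number of pairs or calls).
#' @param p background error probability in (0, 1).
#' @return p-value vector, non-increasing in `k` for fixed `n`.
#' @export
binomial_site_pvalue <- function(k, n, p) {
  if (length(p) != 1L || p <= 0 || p >= 1)
    stop("p must be a single probability in (0, 1)")
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n")
  out <- ifelse(k == 0, 1, pbinom(k - 1, n, p, lower.tail = FALSE))
  clip_pvalue(out)
}

#' Poisson-binomial upper-tail p-value from per-call error probabilities
#'
#' Conditioning on each call's own quality-implied error probability
#' `e_i = 10^(-q_i/10)`, the error count at a site is Poisson-binomial.
#' The exact tail `P(K >= k_obs)` is computed by the dynamic-programming
#' recurrence `P(K_n = k) = e_n P(K_{n-1} = k-1) + (1-e_n) P(K_{n-1} =
#' k)` in O(n^2) time and O(n) space.
#'
#' @param error_probs vector of per-call error probabilities in [0, 1].
#' @param k_obs observed error count, `0 <= k_obs <= length(error_probs)`.
#' @return scalar p-value.
#' @export
quality_dp_pvalue <- function(error_probs, k_obs) {
  n <- length(error_probs)
  if (n == 0L) {
    if (k_obs > 0) stop("empty probability vector with k_obs > 0")
    return(1)
  }
  stopifnot_prob(error_probs)
  if (k_obs < 0 || k_obs > n) stop("need 0 <= k_obs <= n")
  if (k_obs == 0L) return(1)
  pk <- 1  # P(K_0 = 0)
  for (e in error_probs)
    pk <- (1 - e) * c(pk, 0) + e * c(0, pk)
  clip_pvalue(sum(pk[(k_obs + 1L):(n + 1L)]))
}

# per-pair error probability from the two mates' qualities: exactly one
# of the two calls wrong
pair_error_probs <- function(qual_fwd, qual_rev) {
  ef <- phred_to_error(qual_fwd); er <- phred_to_error(qual_rev)
  ef * (1 - er) + er * (1 - ef)
}

#' Annotate sites as systematic errors under Bonferroni control
#'
#' Computes [binomial_site_pvalue()] for each site and flags those with
#' p-value at most `alpha / family_size`.  The Bonferroni correction
#' bounds the probability of even one false positive by `alpha`, giving
#' an annotation set clean enough to characterize.
#'
#' @param sites data.frame with columns `k` (errors) and `n` (coverage);
#'   `chrom`/`pos` are carried through if present.
#' @param p background error probability.
#' @param alpha family-wise significance level.
#' @param family_size number of tests; defaults to `nrow(sites)` (all
#'   sites passing the coverage filter in the current run).
#' @return data.table of annotated sites with `p_value`,
#'   `alpha_corrected` and `significant`.
#' @export
annotate_systematic <- function(sites, p, alpha = 0.05,
                                family_size = NULL) {
  sites <- as.data.table(sites)
  family_size <- family_size %||% nrow(sites)
  if (family_size == 0L) stop("family_size is 0: nothing to test")
  if (family_size < nrow(sites))
    stop("family_size smaller than the number of tested sites")
  stopifnot(alpha > 0, alpha < 1)
  out <- copy(sites)
  out[, p_value := binomial_site_pvalue(k, n, p)]
  out[, alpha_corrected := alpha / family_size]
  out[, significant := p_value <= alpha_corrected]
  out[]
}

#' Coverage spectrum of a site set
#'
#' @param n vector of per-site coverages.
#' @return data.table with `coverage` and `count` (`c_j`).
#' @export
coverage_spectrum <- function(n) {
  dt <- data.table(coverage = as.integer(n))[, .(count = .N),
                                             by = coverage]
  setkey(dt, coverage)
  dt[]
}

prop_bin_index <- function(prop, bin_width) {
  nb <- as.integer(round(1 / bin_width))
  pmin(floor(prop / bin_width) + 1L, nb)
}

#' Expected histogram of per-site error proportions under the null
#'
#' For each coverage `j` with `c_j` sites, the full binomial pmf over
#' error counts `0..j` at background rate `p` is evaluated and the mass
#' `c_j * P(K = k)` added to the bin containing `k/j`.  Summed over the
#' spectrum this gives the expected number of sites per error-proportion
#' bin; an observed excess in high-proportion bins is the signature of
#' systematic error.  Total expected mass equals the total site count.
#'
#' @param spectrum a [coverage_spectrum()] (data.frame with `coverage`,
#'   `count`).
#' @param p background error probability in (0, 1).
#' @param bin_width bin width on [0, 1]; must divide 1.  Bins are
#'   right-open except the last.
#' @return data.table with `lower`, `upper`, `expected`.
#' @export
expected_proportion_histogram <- function(spectrum, p, bin_width = 0.02) {
  spectrum <- as.data.table(spectrum)
  if (!nrow(spectrum)) stop("empty coverage spectrum")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  nb <- round(1 / bin_width)
  if (abs(nb * bin_width - 1) > 1e-9) stop("bin_width must divide 1")
  expected <- numeric(nb)
  for (i in seq_len(nrow(spectrum))) {
    j <- spectrum$coverage[i]; cj <- spectrum$count[i]
    kk <- 0:j
    bins <- prop_bin_index(kk / j, bin_width)
    mass <- cj * dbinom(kk, j, p)
    w <- tapply(mass, factor(bins, levels = seq_len(nb)), sum)
    w[is.na(w)] <- 0
    expected <- expected + as.numeric(w)
  }
  data.table(lower = bin_width * (seq_len(nb) - 1L),
             upper = bin_width * seq_len(nb),
             expected = expected)
}

#' Observed histogram of per-site error proportions
#'
#' @param k,n per-site error counts and coverages.
#' @param bin_width bin width, as in [expected_proportion_histogram()].
#' @return data.table with `lower`, `upper`, `observed`.
#' @export
observed_proportion_histogram <- function(k, n, bin_width = 0.02) {
  nb <- round(1 / bin_width)
  bins <- prop_bin_index(k / n, bin_width)
  counts <- tabulate(bins, nbins = nb)
  data.table(lower = bin_width * (seq_len(nb) - 1L),
             upper = bin_width * seq_len(nb),
             observed = counts)
}

#' Pearson chi-square test for strand directionality of mismatches
#'
#' Tests association between mismatch occurrence and read orientation
#' in a 2x2 table (strand x mismatch/match), the screen for systematic
#' error in data without overlapping mates.  Classical Pearson statistic
#' on 1 df, without continuity correction by default (`correct = TRUE`
#' enables Yates).  A warning is raised when any expected cell count is
#' below 5.
#'
#' @param mm_fwd,match_fwd,mm_rev,match_rev cell counts.
#' @param correct apply Yates continuity correction.
#' @return list with `statistic` and `p_value`.
#' @export
directionality_chisq <- function(mm_fwd, match_fwd, mm_rev, match_rev,
                                 correct = FALSE) {
  a <- mm_fwd; b <- match_fwd; c <- mm_rev; d <- match_rev
  N <- a + b + c + d
  if (min(a + b, c + d, a + c, b + d) == 0)
    stop("directionality_chisq: zero margin, test undefined")
  expmin <- min(outer(c(a + b, c + d), c(a + c, b + d)) / N)
  if (expmin < 5)
    warning("expected cell count below 5; chi-square approximation poor")
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - N / 2)
  stat <- N * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Directionality screen over all sufficiently covered sites
#'
#' Applies the [directionality_chisq()] test at every site covered by at
#' least `min_per_strand` forward and reverse reads, with Bonferroni
#' control over the tested family.  Sites with zero total mismatches
#' (zero margin; the test is undefined and the null cannot be rejected)
#' are skipped and counted in the `skipped` attribute.
#'
#' @param calls a call table from [read_alignments()].
#' @param min_per_strand minimum coverage per strand (default 10).
#' @param alpha family-wise significance level.
#' @param family_size number of tests; defaults to the number of sites
#'   meeting the coverage threshold (including skipped zero-margin
#'   sites, which count as tests that cannot reject).
#' @param correct Yates correction flag.
#' @return data.table with per-site counts, `statistic`, `p_value`,
#'   `significant`.
#' @export
scan_directionality <- function(calls, min_per_strand = 10L, alpha = 0.05,
                                family_size = NULL, correct = FALSE) {
  s <- site_strand_summary(calls)
  s <- s[cov_fwd >= min_per_strand & cov_rev >= min_per_strand]
  family_size <- family_size %||% nrow(s)
  n_skipped <- s[, sum(mm_fwd + mm_rev == 0)]
  s <- s[mm_fwd + mm_rev > 0]
  a <- s$mm_fwd; b <- s$cov_fwd - s$mm_fwd
  c_ <- s$mm_rev; d <- s$cov_rev - s$mm_rev
  N <- a + b + c_ + d
  num <- abs(a * d - b * c_)
  if (correct) num <- pmax(0, num - N / 2)
  stat <- N * num^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  s[, `:=`(statistic = stat,
           p_value = pchisq(stat, df = 1, lower.tail = FALSE))]
  s[, significant := p_value <= alpha / max(family_size, 1L)]
  setattr(s, "skipped", c(zero_margin = n_skipped))
  setattr(s, "family_size", family_size)
  s[]
}

#' Reference-sequence motif counts around error sites
#'
#' Counts the reference base at each offset of a window centred on each
#' site, in the site's error-enriched read direction: for a site whose
#' errors concentrate on reverse-oriented reads the window is read off
#' the reverse complement, walking in read direction, so that motifs
#' such as GGT line up regardless of which genome strand carries them.
#' Sites too close to a contig edge are dropped (count recorded in the
#' `dropped` attribute).
#'
#' @param sites data.frame with `chrom`, `pos` (0-based) and
#'   `direction` ("+"/"-"); a missing `direction` column defaults to "+".
#' @param reference a [Biostrings::DNAStringSet].
#' @param window integer offsets relative to the site (default -6..6).
#' @param stratify split counts by the reference base at offset 0.
#' @return 4 x length(window) count matrix (list of matrices keyed by
#'   site base when `stratify = TRUE`).
#' @export
motif_counts <- function(sites, reference, window = -6:6,
                         stratify = FALSE) {
  sites <- as.data.table(sites)
  if (!"direction" %in% names(sites)) sites[, direction := "+"]
  refchars <- lapply(as.character(reference), function(s)
    strsplit(s, "", fixed = TRUE)[[1]])
  mk <- function() matrix(0L, 4L, length(window),
                          dimnames = list(DNA, as.character(window)))
  if (!nrow(sites)) return(if (stratify) list() else mk())

  lens <- vapply(refchars, length, 0L)[sites$chrom]
  lo <- ifelse(sites$direction == "+", sites$pos + min(window),
               sites$pos - max(window))
  hi <- ifelse(sites$direction == "+", sites$pos + max(window),
               sites$pos - min(window))
  ok <- lo >= 0L & hi < lens
  dropped <- sum(!ok)
  sites <- sites[ok]

  ctx <- matrix("", nrow(sites), length(window))
  for (j in seq_along(window)) {
    o <- window[j]
    gp <- ifelse(sites$direction == "+", sites$pos + o, sites$pos - o)
    ch <- mapply(function(cr, p) refchars[[cr]][p + 1L], sites$chrom, gp,
                 USE.NAMES = FALSE)
    ctx[, j] <- ifelse(sites$direction == "+", ch, complement_chr(ch))
  }
  count_one <- function(rows) {
    m <- mk()
    for (j in seq_along(window)) {
      t <- table(factor(ctx[rows, j], levels = DNA))
      m[, j] <- as.integer(t)
    }
    m
  }
  if (!stratify) {
    m <- count_one(seq_len(nrow(sites)))
    attr(m, "dropped") <- dropped
    return(m)
  }
  b0 <- ctx[, which(window == 0L)]
  out <- lapply(split(seq_len(nrow(sites)), factor(b0, levels = DNA)),
                count_one)
  attr(out, "dropped") <- dropped
  out
}

#' Substitution spectrum of base-call errors
#'
#' Tallies reference base against erroneous call in a 4x4 matrix with an
#' empty diagonal.  Accepts either a pair table from [pair_overlaps()]
#' (the mismatching side of each error-pair is used) or a data.frame
#' with columns `ref` and `called`.
#'
#' @param x pair table or data.frame(ref, called).
#' @return 4x4 integer matrix, rows = reference base, columns = called
#'   base.
#' @export
substitution_spectrum <- function(x) {
  x <- as.data.table(x)
  if ("category" %in% names(x)) {
    e <- x[category == "error_pair"]
    called <- ifelse(e$base_fwd != e$ref, e$base_fwd, e$base_rev)
    x <- data.table(ref = e$ref, called = called)
  }
  m <- matrix(0L, 4L, 4L, dimnames = list(DNA, DNA))
  if (nrow(x)) {
    t <- table(factor(x$ref, levels = DNA), factor(x$called, levels = DNA))
    m[] <- as.integer(t)
  }
  if (any(diag(m) != 0)) stop("substitution_spectrum: ref == called entry")
  m
}

#' Error rate restricted to a motif site set
#'
#' @param summary per-site pair summary from [pair_site_summary()].
#' @param motif_sites data.frame with `chrom`, `pos` (0-based) of motif
#'   positions (e.g. [ggt_sites()] output).
#' @param min_coverage minimum pairs per site.
#' @return scalar per-pair error rate at the motif sites.
#' @export
motif_error_rate <- function(summary, motif_sites, min_coverage = 10L) {
  summary <- as.data.table(summary)
  ms <- unique(as.data.table(motif_sites)[, .(chrom, pos)])
  s <- summary[ms, on = c("chrom", "pos"), nomatch = NULL][
    n_pairs >= min_coverage]
  if (!nrow(s)) stop("no motif site meets min_coverage")
  s[, sum(n_err)] / s[, sum(n_pairs)]
}

#' Systematic-error annotation restricted to motif sites
#'
#' Identical machinery to [annotate_systematic()], but run only at a
#' precomputed motif site list (e.g. all GGT occurrences on both
#' strands) with a motif-specific background error rate and family size
#' equal to the number of motif sites tested.  Detects positions whose
#' error excess is not explained by the motif's own elevated rate.
#'
#' @param summary per-site pair summary from [pair_site_summary()].
#' @param motif_sites data.frame with `chrom`, `pos` (0-based).
#' @param p_motif motif background error rate; computed from the data
#'   via [motif_error_rate()] when NULL.
#' @param alpha family-wise significance level.
#' @param min_coverage minimum pairs per site.
#' @return annotated data.table as from [annotate_systematic()].
#' @export
restricted_motif_annotation <- function(summary, motif_sites,
                                        p_motif = NULL, alpha = 0.05,
                                        min_coverage = 10L) {
  summary <- as.data.table(summary)
  ms <- unique(as.data.table(motif_sites)[, .(chrom, pos)])
  s <- summary[ms, on = c("chrom", "pos"), nomatch = NULL][
    n_pairs >= min_coverage]
  p_motif <- p_motif %||% (s[, sum(n_err)] / s[, sum(n_pairs)])
  annotate_systematic(s[, .(chrom, pos, k = n_err, n = n_pairs)],
                      p = p_motif, alpha = alpha, family_size = nrow(s))
}

#' Expected overlap of two independently placed site sets
#'
#' Expected number of positions annotated in both of two experiments if
#' each experiment's `n1` (resp. `n2`) annotated sites were placed
#' uniformly at random among the `N` positions tested in both:
#' `n1 * n2 / N`.  An observed overlap far above this demonstrates
#' replicability of the annotated sites.
#'
#' @param n1,n2 annotated-set sizes.
#' @param N number of positions tested in both experiments.
#' @return expected overlap (real; round for display).
#' @export
expected_replication_overlap <- function(n1, n2, N) {
  if (N <= 0) stop("N must be positive")
  stopifnot(n1 >= 0, n2 >= 0, n1 <= N, n2 <= N)
  n1 * n2 / N
}

#' Probability that all errors at a site fall on the same strand
#'
#' Under a random error model each base-call error falls on the forward
#' or reverse read with probability 1/2 independently, so `k` errors all
#' landing on one strand (either one) has probability `2 * (1/2)^k`.
#' The smallness of this number at observed error stacks is what makes
#' one-sided error concentration the hallmark of systematic error.
#'
#' @param k number of errors (>= 1).
#' @return probability.
#' @export
same_strand_probability <- function(k) {
  if (any(k < 1)) stop("k must be >= 1")
  2 * 0.5^k
}
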