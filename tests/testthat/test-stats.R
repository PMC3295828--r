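test_that("binomial_site_pvalue matches closed forms and the summation oracle", {
  expect_equal(binomial_site_pvalue(0, 10, 0.0026), 1)
  expect_equal(binomial_site_pvalue(11, 11, 0.5), 0.5^11)  # 0.00048828125
  # independent oracle: explicit term-by-term summation of the pmf
  p <- 0.002611
  oracle <- sum(vapply(2:10, function(j)
    choose(10, j) * p^j * (1 - p)^(10 - j), 0))
  expect_equal(binomial_site_pvalue(2, 10, p), oracle, tolerance = 1e-14)
  expect_error(binomial_site_pvalue(11, 10, 0.1), "k <= n")
})

test_that("binomial_site_pvalue is monotone in k and in p", {
  for (n in c(10L, 57L, 200L)) {
    pv <- binomial_site_pvalue(0:n, n, 0.0026)
    expect_true(all(diff(pv) <= 0))
  }
  ps <- c(0.001, 0.01, 0.05, 0.2, 0.5)
  pv <- vapply(ps, function(p) binomial_site_pvalue(5, 40, p), 0)
  expect_true(all(diff(pv) >= 0))
})

test_that("quality DP p-value: trivial cases and binomial reduction", {
  expect_equal(quality_dp_pvalue(0.1, 1), 0.1)
  expect_equal(quality_dp_pvalue(numeric(0), 0), 1)
  expect_error(quality_dp_pvalue(numeric(0), 1), "empty")
  # constant per-call probabilities reduce to the exact binomial tail
  for (p in c(0.0026, 0.05, 0.3)) {
    e <- rep(p, 40)
    for (k in c(0L, 1L, 5L, 20L, 40L))
      expect_equal(quality_dp_pvalue(e, k),
                   binomial_site_pvalue(k, 40, p), tolerance = 1e-12)
  }
})

test_that("quality DP p-value equals exhaustive enumeration (n <= 12)", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(1:12, 1)
    e <- runif(n)
    k <- sample(0:n, 1)
    expect_equal(quality_dp_pvalue(e, k), pb_tail_enum(e, k),
                 tolerance = 1e-12)
  }
})

test_that("annotate_systematic flags only extreme sites and errors sanely", {
  sites <- data.table(chrom = "c", pos = 1:3,
                      k = c(0L, 0L, 30L), n = c(50L, 80L, 30L))
  ann <- annotate_systematic(sites, p = 0.0026, alpha = 0.05,
                             family_size = 1e6)
  expect_equal(ann$significant, c(FALSE, FALSE, TRUE))
  expect_equal(ann$p_value[3], 0.0026^30)
  expect_equal(ann$alpha_corrected, rep(5e-8, 3))
  expect_error(annotate_systematic(sites[0], p = 0.0026), "family_size")
  expect_error(annotate_systematic(sites, p = 0.0026, family_size = 2),
               "smaller")
})

test_that("expected proportion histogram conserves mass and hits the
           closed-form bin value", {
  spec <- data.table(coverage = 10L, count = 1000L)
  h <- expected_proportion_histogram(spec, p = 0.1, bin_width = 0.02)
  expect_equal(sum(h$expected), 1000)
  # proportion-0 bin holds 1000 * 0.9^10
  expect_equal(h$expected[1], 1000 * 0.9^10, tolerance = 1e-9)
  # conservation on a ragged spectrum
  spec2 <- data.table(coverage = c(10L, 17L, 33L, 250L),
                      count = c(5L, 11L, 7L, 3L))
  h2 <- expected_proportion_histogram(spec2, p = 0.0026)
  expect_equal(sum(h2$expected), sum(spec2$count), tolerance = 1e-6)
  expect_error(expected_proportion_histogram(spec2[0], 0.1), "empty")
})

test_that("observed histogram agrees with expected under a binomial null", {
  set.seed(5)
  spec <- data.table(coverage = c(15L, 40L, 90L),
                     count = c(4000L, 3000L, 2000L))
  n <- rep(spec$coverage, spec$count)
  k <- rbinom(length(n), n, 0.0026)
  he <- expected_proportion_histogram(spec, 0.0026)
  ho <- observed_proportion_histogram(k, n)
  expect_equal(sum(ho$observed), sum(spec$count))
  tol <- 3 * sqrt(pmax(he$expected, 1))
  expect_true(all(abs(ho$observed - he$expected) <= tol))
})

test_that("directionality chi-square matches stats::chisq.test", {
  # identical rows: no association
  r <- directionality_chisq(10, 90, 10, 90)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  set.seed(3)
  for (i in 1:10) {
    a <- sample(1:50, 1); b <- sample(1:200, 1)
    c_ <- sample(1:50, 1); d <- sample(1:200, 1)
    m <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    for (corr in c(FALSE, TRUE)) {
      ref <- suppressWarnings(stats::chisq.test(m, correct = corr))
      got <- suppressWarnings(
        directionality_chisq(a, b, c_, d, correct = corr))
      expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-12)
    }
    # invariance under swapping strand labels
    got_sw <- suppressWarnings(directionality_chisq(c_, d, a, b))
    got <- suppressWarnings(directionality_chisq(a, b, c_, d))
    expect_equal(got_sw$statistic, got$statistic)
  }
  expect_error(directionality_chisq(0, 100, 0, 90), "margin")
  expect_warning(directionality_chisq(2, 98, 1, 99), "below 5")
})

test_that("directionality screen controls FWER on a strand-balanced null", {
  set.seed(21)
  n_sites <- 2000L
  reps <- 50L
  fp <- 0L
  for (r in seq_len(reps)) {
    cf <- sample(10:60, n_sites, replace = TRUE)
    cr <- sample(10:60, n_sites, replace = TRUE)
    mf <- rbinom(n_sites, cf, 0.005)
    mr <- rbinom(n_sites, cr, 0.005)
    keep <- mf + mr > 0
    a <- mf[keep]; b <- cf[keep] - mf[keep]
    c_ <- mr[keep]; d <- cr[keep] - mr[keep]
    N <- a + b + c_ + d
    stat <- N * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    pv <- pchisq(stat, 1, lower.tail = FALSE)
    if (any(pv <= 0.05 / n_sites)) fp <- fp + 1L
  }
  expect_lte(fp / reps, 0.05)
})

test_that("motif counts read the reference in the chosen direction", {
  ref <- Biostrings::DNAStringSet(c(chrM = "AAAAAGGTCCAAAAAAAGGTCCCC"))
  # plus-strand GGT at 0-based 5..7 (T at 7); reverse-strand site: ACC
  # at 0-based 8..10 means a GGT on the minus strand with T at pos 8
  m <- motif_counts(data.table(chrom = "chrM", pos = 7L, direction = "+"),
                    ref, window = -2:0)
  expect_equal(m["G", "-2"], 1L)
  expect_equal(m["G", "-1"], 1L)
  expect_equal(m["T", "0"], 1L)
  ref2 <- Biostrings::DNAStringSet(c(chrM = "AAAAAACCAAAAAA"))
  m2 <- motif_counts(data.table(chrom = "chrM", pos = 5L, direction = "-"),
                     ref2, window = -2:0)
  expect_equal(m2["G", "-2"], 1L)
  expect_equal(m2["G", "-1"], 1L)
  expect_equal(m2["T", "0"], 1L)
  # empty input: all-zero matrix; near-edge sites dropped
  m0 <- motif_counts(data.table(chrom = character(), pos = integer(),
                                direction = character()), ref)
  expect_true(all(m0 == 0L))
  me <- motif_counts(data.table(chrom = "chrM", pos = 1L, direction = "+"),
                     ref, window = -6:6)
  expect_true(all(me == 0L))
  expect_equal(attr(me, "dropped"), 1L)
})

test_that("GGT-planted systematic errors give a pure G at offset -1", {
  ds <- fixture("ggt_ds", {
    cfg <- sim_config(genome_length = 15000L, n_het = 0L, n_syserr = 40L,
                      ggt_fraction = 1, coverage = 35, seed = 55L)
    simulate_dataset(cfg)
  })
  sys <- ds$truth[site_type == "syserr"]
  m <- motif_counts(data.table(chrom = sys$chrom, pos = sys$pos,
                               direction = sys$affected),
                    ds$genome, window = -2:0)
  expect_equal(unname(m["G", "-1"]), nrow(sys))
  expect_equal(unname(m["G", "-2"]), nrow(sys))
  expect_equal(unname(m["T", "0"]), nrow(sys))
})

test_that("substitution spectrum counts ref -> called errors", {
  pairs <- data.table(chrom = "c", pos = 1L, ref = "T",
                      base_fwd = c("G", "T"), base_rev = c("T", "T"),
                      category = factor(c("error_pair", "reference_pair"),
                                        PAIR_LEVELS))
  m <- substitution_spectrum(pairs)
  expect_equal(unname(m["T", "G"]), 1L)
  expect_equal(sum(m), 1L)
  m0 <- substitution_spectrum(data.table(ref = character(),
                                         called = character()))
  expect_true(all(m0 == 0L))
  expect_error(substitution_spectrum(data.table(ref = "A", called = "A")),
               "ref == called")
})

test_that("motif-restricted annotation reduces to the global machinery", {
  s <- data.table(chrom = "c", pos = 1:50,
                  n_pairs = 60L, n_ref = 58L, n_snp = 0L, n_err = 2L,
                  n_disc = 0L)
  s[1:5, `:=`(n_err = 30L, n_ref = 30L)]
  motif <- s[, .(chrom, pos)]
  # with the motif rate equal to the global rate and the same family,
  # significance calls are identical
  p_all <- s[, sum(n_err) / sum(n_pairs)]
  a1 <- annotate_systematic(s[, .(chrom, pos, k = n_err, n = n_pairs)],
                            p = p_all, family_size = nrow(s))
  a2 <- restricted_motif_annotation(s, motif, p_motif = p_all)
  expect_equal(a2$significant, a1$significant)
  # motif background rate at/above every observed proportion: nothing
  a3 <- restricted_motif_annotation(s, motif, p_motif = 0.6)
  expect_false(any(a3$significant))
})

test_that("GGT-restricted annotation finds planted motif-site errors", {
  ds <- fixture("ggt_ds", {
    cfg <- sim_config(genome_length = 15000L, n_het = 0L, n_syserr = 40L,
                      ggt_fraction = 1, coverage = 35, seed = 55L)
    simulate_dataset(cfg)
  })
  pairs <- pair_overlaps(read_alignments(ds$sam, ds$fasta))
  s <- pair_site_summary(pairs)
  ggt <- ds$ggt[, .(chrom, pos)]
  # motif background rate is inflated by the planted sites; the planted
  # sites still stand out against it
  ann <- restricted_motif_annotation(s, ggt)
  sig <- ann[significant == TRUE]
  planted <- ds$truth[site_type == "syserr", pos]
  expect_gt(nrow(sig), 10)
  expect_true(all(sig$pos %in% planted))
})

test_that("replication overlap expectation and same-strand probability", {
  # worked values: two replicate experiments, printed counts
  expect_equal(round(expected_replication_overlap(1916, 2519, 2160736)), 2)
  expect_equal(round(expected_replication_overlap(1596, 2080, 61779)), 54)
  expect_equal(expected_replication_overlap(0, 500, 1000), 0)
  expect_error(expected_replication_overlap(1, 1, 0), "positive")
  expect_equal(same_strand_probability(11), 1 / 1024)
  expect_equal(same_strand_probability(1), 1)
  expect_equal(same_strand_probability(2), 0.5)
  expect_error(same_strand_probability(0), ">= 1")
})
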