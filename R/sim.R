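#' Default substitution bias of systematic errors
#'
#' Row-stochastic 4x4 matrix (reference base x called base, zero
#' diagonal) used to draw the erroneous call planted at a systematic
#' error site.  The default concentrates mass on calls to G (the
#' dominant artifact substitution on Illumina-type data is T>G, with a
#' general excess of substitutions to G, then C, and little to A or T).
#'
#' @return 4x4 numeric matrix with rownames/colnames A, C, G, T.
#' @export
default_sub_bias <- function() {
  w <- c(A = 0.05, C = 0.20, G = 0.70, T = 0.05)
  m <- matrix(rep(w, each = 4), 4, 4, dimnames = list(DNA, DNA))
  diag(m) <- 0
  m / rowSums(m)
}

#' Per-base error rate matching a target per-pair error rate
#'
#' An error-pair arises when exactly one of the two overlapping mate
#' calls is wrong, so the per-pair rate is `2 e (1 - e)` for per-base
#' rate `e`.  Inverting gives the per-base rate to configure so that the
#' measured per-pair background error rate hits a target (default world:
#' 0.0026 per pair, the background rate of a deep methyl-Seq-like
#' library).
#'
#' @param pair_rate target per-pair error rate in (0, 0.5).
#' @return per-base error rate.
#' @export
base_error_for_pair_rate <- function(pair_rate = 0.0026) {
  stopifnot_prob(pair_rate)
  if (pair_rate >= 0.5) stop("pair_rate must be < 0.5")
  (1 - sqrt(1 - 2 * pair_rate)) / 2
}

#' Simulation configuration
#'
#' The stated world of the simulator: a methyl-Seq-like library of 76 bp
#' paired reads from 50-300 bp fragments, deep overlapping mate-pair
#' coverage concentrated at discrete fragment loci (as restriction-based
#' protocols produce), background per-pair error rate ~0.0026, planted
#' heterozygous sites at variant-allele fraction 0.5, and planted
#' systematic-error sites whose errors hit one read orientation at rate
#' `eps_sys` = 0.4, occur preferentially in GGT context, substitute
#' mostly to G, and carry locally depressed quality scores (`dq` = 10
#' below the Phred mean of 32).
#'
#' @param genome_length reference length in bp.
#' @param gc GC fraction of the random reference.
#' @param ggt_enrichment multiplicative enrichment of GGT trinucleotides
#'   over the random expectation.
#' @param n_het,n_syserr numbers of planted heterozygous and
#'   systematic-error sites.
#' @param vaf variant-allele fraction at heterozygous sites.
#' @param ggt_fraction fraction of systematic-error sites placed at
#'   GGT-context T positions (the rest are uniform).
#' @param eps baseline per-base error rate; default calibrated so the
#'   per-pair error rate is ~0.0026.
#' @param eps_sys per-call error rate on the affected orientation at a
#'   systematic-error site.
#' @param sub_bias 4x4 substitution matrix for systematic errors.
#' @param qual_mean,qual_sd Phred quality model (truncated normal,
#'   clipped to [2, 41]).
#' @param dq quality depression at systematic-error calls.
#' @param read_length read length in bp.
#' @param frag_min,frag_max fragment length range (uniform).
#' @param coverage mean pair coverage per fragment locus.
#' @param coverage_dispersion negative-binomial size of the per-locus
#'   copy number; small values give the heavy-tailed locus coverage that
#'   restriction-digest libraries show.
#' @param locus_spacing mean spacing of background fragment loci.
#' @param paired emit mate pairs (TRUE) or single-end reads.
#' @param chrom reference sequence name.
#' @param seed mandatory integer seed; all randomness derives from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 50000L, gc = 0.5,
                       ggt_enrichment = 4, n_het = 0L, n_syserr = 0L,
                       vaf = 0.5, ggt_fraction = 0.5,
                       eps = base_error_for_pair_rate(0.0026),
                       eps_sys = 0.4, sub_bias = default_sub_bias(),
                       qual_mean = 32, qual_sd = 3, dq = 10,
                       read_length = 76L, frag_min = 50L, frag_max = 300L,
                       coverage = 35, coverage_dispersion = 3,
                       locus_spacing = 400L, paired = TRUE,
                       chrom = "chrS", seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  stopifnot_prob(gc); stopifnot_prob(vaf); stopifnot_prob(ggt_fraction)
  stopifnot_prob(eps); stopifnot_prob(eps_sys)
  stopifnot(genome_length > 100, read_length > 10,
            frag_min <= frag_max, frag_min >= 20)
  cfg <- list(genome_length = as.integer(genome_length), gc = gc,
              ggt_enrichment = ggt_enrichment, n_het = as.integer(n_het),
              n_syserr = as.integer(n_syserr), vaf = vaf,
              ggt_fraction = ggt_fraction, eps = eps, eps_sys = eps_sys,
              sub_bias = sub_bias, qual_mean = qual_mean, qual_sd = qual_sd,
              dq = dq, read_length = as.integer(read_length),
              frag_min = as.integer(frag_min), frag_max = as.integer(frag_max),
              coverage = coverage, coverage_dispersion = coverage_dispersion,
              locus_spacing = as.integer(locus_spacing), paired = paired,
              chrom = chrom, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a random reference genome with GGT enrichment
#'
#' @param config a [sim_config()].
#' @return list with `genome` (a length-1 [Biostrings::DNAStringSet]),
#'   `seq` (the same sequence as a character scalar) and `ggt`, a
#'   data.table of GGT trinucleotide sites on both strands: `pos` is the
#'   0-based coordinate of the T of the motif (on the motif's strand)
#'   and `strand` the strand carrying the GGT reading.
#' @export
simulate_genome <- function(config) {
  set.seed(child_seed(config$seed, 1L))
  len <- config$genome_length
  prob <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2,
            (1 - config$gc) / 2)
  s <- sample(DNA, len, replace = TRUE, prob = prob)
  # inflate GGT count by overwriting spaced random triplets
  pG <- config$gc / 2; pT <- (1 - config$gc) / 2
  n_extra <- round((config$ggt_enrichment - 1) * len * pG^2 * pT)
  if (n_extra > 0) {
    cand <- sample.int(len - 2L, min(4L * n_extra, len %/% 8L))
    cand <- sort(cand)
    keep <- cand[c(TRUE, diff(cand) >= 4L)]
    keep <- head(keep, n_extra)
    for (i in keep) s[i:(i + 2L)] <- c("G", "G", "T")
  }
  seq <- paste(s, collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(seq, config$chrom))
  list(genome = genome, seq = seq, ggt = ggt_sites(genome)[[1L]])
}

#' Locate GGT motif sites on both strands of a reference
#'
#' A plus-strand GGT starting at 0-based `s` has its T (the error-prone
#' base) at `s + 2`; a minus-strand GGT corresponds to plus-strand ACC
#' at `s`, with the motif's T at plus-coordinate `s`.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @return named list (one element per sequence) of data.tables with
#'   columns `chrom`, `pos` (0-based T position) and `strand`.
#' @export
ggt_sites <- function(genome) {
  out <- lapply(seq_along(genome), function(i) {
    chrom <- names(genome)[i]
    fwd <- Biostrings::start(Biostrings::matchPattern("GGT", genome[[i]]))
    rev <- Biostrings::start(Biostrings::matchPattern("ACC", genome[[i]]))
    dt <- data.table(
      chrom = chrom,
      pos = c(fwd - 1L + 2L, rev - 1L),
      strand = rep(c("+", "-"), c(length(fwd), length(rev))))
    setkey(dt, pos)
    dt
  })
  setNames(out, names(genome))
}

# sample n positions from candidates keeping min_gap from each other and
# from already-used positions
pick_spaced <- function(candidates, n, used, min_gap = 8L) {
  cand <- setdiff(candidates, used)
  cand <- cand[sample.int(length(cand))]
  picked <- integer(0)
  occupied <- sort(used)
  for (p in cand) {
    if (length(picked) >= n) break
    all_pos <- c(occupied, picked)
    if (!length(all_pos) || min(abs(all_pos - p)) >= min_gap)
      picked <- c(picked, p)
  }
  if (length(picked) < n)
    stop("pick_spaced: demand (", n, ") exceeds eligible positions")
  picked
}

#' Plant heterozygous and systematic-error sites
#'
#' Heterozygous sites are uniform over the genome; a configurable
#' fraction of systematic-error sites is placed at GGT-context T
#' positions (affected strand = the strand carrying the motif), the rest
#' uniform with a uniformly chosen affected strand.  The erroneous call
#' at each systematic-error site is drawn once from the substitution
#' bias matrix and then reused for every error there (the errors are
#' systematic, not random).
#'
#' @param gen result of [simulate_genome()].
#' @param config a [sim_config()].
#' @return data.table truth record: `chrom`, `pos` (0-based),
#'   `site_type` (het / syserr), `alt` (het alternate allele or the
#'   systematic wrong call, reference-strand orientation), `affected`
#'   (read orientation hit by errors, "+"/"-"; NA for het), `f`,
#'   `eps_sys`.
#' @export
plant_sites <- function(gen, config) {
  set.seed(child_seed(config$seed, 2L))
  len <- config$genome_length
  refc <- strsplit(gen$seq, "", fixed = TRUE)[[1]]
  margin <- 10L
  eligible <- margin:(len - margin - 1L)
  used <- integer(0)

  n_ggt <- round(config$n_syserr * config$ggt_fraction)
  ggt_ok <- gen$ggt[pos %in% eligible]
  pos_ggt <- pick_spaced(ggt_ok$pos, n_ggt, used)
  used <- c(used, pos_ggt)
  strand_ggt <- ggt_ok[match(pos_ggt, pos), strand]

  n_free <- config$n_syserr - n_ggt
  pos_free <- pick_spaced(eligible, n_free, used)
  used <- c(used, pos_free)
  strand_free <- sample(c("+", "-"), n_free, replace = TRUE)

  pos_het <- pick_spaced(eligible, config$n_het, used)

  draw_sub <- function(ref_base) {
    vapply(ref_base, function(b) sample(DNA, 1L, prob = config$sub_bias[b, ]), "")
  }
  syserr_pos <- c(pos_ggt, pos_free)
  syserr <- data.table(
    chrom = config$chrom, pos = as.integer(syserr_pos), site_type = "syserr",
    alt = if (length(syserr_pos)) draw_sub(refc[syserr_pos + 1L]) else character(0),
    affected = c(strand_ggt, strand_free),
    f = NA_real_, eps_sys = config$eps_sys)
  het_alt <- vapply(pos_het, function(p)
    sample(setdiff(DNA, refc[p + 1L]), 1L), "")
  het <- data.table(
    chrom = config$chrom, pos = as.integer(pos_het), site_type = "het",
    alt = het_alt, affected = NA_character_,
    f = config$vaf, eps_sys = NA_real_)
  truth <- rbind(syserr, het)
  setkey(truth, chrom, pos)
  truth
}

qual_string <- local({
  qmap <- vapply(0:93, function(q) rawToChar(as.raw(q + 33L)), "")
  function(q) qmap[q + 1L]
})

# collapse a long per-base character vector into per-read strings;
# reads grouped by identical length for vectorized paste
collapse_reads <- function(chars, read_len) {
  out <- character(length(read_len))
  ends <- cumsum(read_len)
  starts <- ends - read_len + 1L
  for (L in unique(read_len)) {
    idx <- which(read_len == L)
    cols <- lapply(seq_len(L), function(j) chars[starts[idx] + j - 1L])
    out[idx] <- do.call(paste0, cols)
  }
  out
}

#' Simulate aligned reads with planted sites and write SAM output
#'
#' Fragments are drawn at discrete loci (each planted site gets a locus
#' whose mate-overlap region contains it; background loci fill the rest
#' of the genome), with per-locus copy numbers from a heavy-tailed
#' negative binomial, emulating the concentrated coverage of
#' restriction-digest libraries.  Reads are emitted pre-aligned: SAM
#' coordinates are exact by construction, no aligner is involved.
#'
#' @param gen result of [simulate_genome()].
#' @param truth result of [plant_sites()].
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param seed reads-stage seed; defaults to a child of `config$seed`.
#'   Passing different values replays the same genome and truth with
#'   independent reads (replicate experiments).
#' @param fastq also write a FASTQ export (Phred+33, reads in
#'   sequencing orientation).
#' @return list with paths (`sam`, `fasta`, `truth`, optionally
#'   `fastq`), the truth table, per-position bookkeeping `coverage`
#'   (`pos`, `reads`, `pairs` -- computed from fragment arithmetic,
#'   independent of any SAM parsing) and the fragment table.
#' @export
simulate_reads <- function(gen, truth, config, dir = tempfile("sim"),
                           seed = child_seed(config$seed, 3L),
                           fastq = FALSE) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  len <- config$genome_length
  R <- config$read_length
  refc <- strsplit(gen$seq, "", fixed = TRUE)[[1]]

  ## --- fragment loci -------------------------------------------------
  # one locus per planted site, overlap region guaranteed to contain it
  site_pos <- truth$pos
  max_ov_len <- min(config$frag_max, 2L * R - 8L)
  Ls <- sample(config$frag_min:max_ov_len, length(site_pos), replace = TRUE)
  lo <- ifelse(Ls <= R, site_pos - Ls + 1L, site_pos - (2L * R - Ls) + 1L)
  hi <- site_pos
  lo <- pmax(lo, ifelse(Ls <= R, 0L, 0L))
  start_site <- lo + floor(runif(length(site_pos)) * (hi - lo + 1L))
  start_site <- pmax(0L, pmin(start_site, len - Ls))
  n_bg <- max(1L, len %/% config$locus_spacing)
  Lb <- sample(config$frag_min:config$frag_max, n_bg, replace = TRUE)
  start_bg <- floor(runif(n_bg) * (len - Lb))
  loci <- data.table(start0 = as.integer(c(start_site, start_bg)),
                     fraglen = as.integer(c(Ls, Lb)))
  loci[, locus := .I]
  loci[, copies := rnbinom(.N, mu = config$coverage,
                           size = config$coverage_dispersion)]
  frags <- loci[copies > 0,
                .(start0 = rep(start0, copies), fraglen = rep(fraglen, copies),
                  locus = rep(locus, copies))]
  frags[, frag := .I]
  n_frag <- nrow(frags)

  ## --- haplotypes: het alleles carried per fragment ------------------
  het <- truth[site_type == "het"]
  het_carrier <- NULL
  if (nrow(het)) {
    ov <- frags[, .(frag, start0, end0 = start0 + fraglen - 1L)]
    setkey(ov, start0, end0)
    hq <- het[, .(site = pos, start0 = pos, end0 = pos, alt, f)]
    setkey(hq, start0, end0)
    het_carrier <- foverlaps(hq, ov, type = "within",
                             by.x = c("start0", "end0"))[
      , .(frag, site, alt, f)]
    het_carrier <- het_carrier[runif(.N) < f]
  }

  ## --- reads ----------------------------------------------------------
  rl <- pmin(R, frags$fraglen)
  if (config$paired) {
    # FR library: left read forward, right read reverse; mate-number
    # assignment (1/2) random per fragment
    left_is_1 <- runif(n_frag) < 0.5
    reads <- data.table(
      frag = rep(frags$frag, 2L),
      pos0 = c(frags$start0, frags$start0 + frags$fraglen - rl),
      len = c(rl, rl),
      rev_strand = rep(c(FALSE, TRUE), each = n_frag),
      mate = c(ifelse(left_is_1, 1L, 2L), ifelse(left_is_1, 2L, 1L)))
  } else {
    left <- runif(n_frag) < 0.5
    reads <- data.table(
      frag = frags$frag,
      pos0 = ifelse(left, frags$start0, frags$start0 + frags$fraglen - rl),
      len = rl,
      rev_strand = !left,
      mate = NA_integer_)
  }
  setorder(reads, frag, rev_strand)
  reads[, read := .I]

  ## --- per-base calls -------------------------------------------------
  gpos <- reads[, unlist(Map(function(p, l) seq.int(p, length.out = l),
                             pos0, len))]
  ridx <- rep(reads$read, reads$len)
  base <- refc[gpos + 1L]
  qual <- as.integer(round(rnorm(length(gpos), config$qual_mean,
                                 config$qual_sd)))
  qual <- pmax(2L, pmin(41L, qual))

  # het alleles (consistent within a fragment)
  if (!is.null(het_carrier) && nrow(het_carrier)) {
    key_rf <- paste(rep(reads$frag, reads$len), gpos)
    key_hc <- paste(het_carrier$frag, het_carrier$site)
    hit <- match(key_rf, key_hc)
    base[!is.na(hit)] <- het_carrier$alt[hit[!is.na(hit)]]
  }

  # systematic errors: affected orientation only, fixed wrong call,
  # depressed quality
  sys <- truth[site_type == "syserr"]
  if (nrow(sys)) {
    m <- match(gpos, sys$pos)
    strand_chr <- ifelse(rep(reads$rev_strand, reads$len), "-", "+")
    is_sys <- !is.na(m) & sys$affected[m] == strand_chr
    err <- is_sys & runif(length(gpos)) < config$eps_sys
    base[err] <- sys$alt[m[err]]
    qual[err] <- pmax(2L, qual[err] - as.integer(config$dq))
  } else err <- logical(length(gpos))

  # baseline errors everywhere else
  bg <- !err & runif(length(gpos)) < config$eps
  if (any(bg)) {
    shift <- sample.int(3L, sum(bg), replace = TRUE)
    base[bg] <- DNA[(match(base[bg], DNA) - 1L + shift) %% 4L + 1L]
  }

  seqs <- collapse_reads(base, reads$len)
  quals <- collapse_reads(qual_string(qual), reads$len)

  ## --- SAM ------------------------------------------------------------
  qname <- sprintf("f%07d", reads$frag)
  if (config$paired) {
    flag <- 1L + 2L + ifelse(reads$rev_strand, 16L, 32L) +
      ifelse(reads$mate == 1L, 64L, 128L)
    fl <- frags$fraglen[reads$frag]
    st <- frags$start0[reads$frag]
    mate_pos0 <- ifelse(reads$rev_strand, st, st + fl - pmin(R, fl))
    tlen <- ifelse(reads$rev_strand, -fl, fl)
    rec <- paste(qname, flag, config$chrom, reads$pos0 + 1L, 60L,
                 paste0(reads$len, "M"), "=", mate_pos0 + 1L, tlen,
                 seqs, quals, sep = "\t")
  } else {
    flag <- ifelse(reads$rev_strand, 16L, 0L)
    rec <- paste(qname, flag, config$chrom, reads$pos0 + 1L, 60L,
                 paste0(reads$len, "M"), "*", 0L, 0L,
                 seqs, quals, sep = "\t")
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", config$chrom, len),
           sprintf("@PG\tID:syserr-sim\tPN:syserr\tVN:%s",
                   as.character(packageVersion("syserr"))))
  sam_path <- file.path(dir, "reads.sam")
  writeLines(c(hdr, rec), sam_path)

  fasta_path <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(gen$genome, fasta_path)
  truth_path <- file.path(dir, "truth.tsv")
  out_truth <- copy(truth)[, .(chrom, pos = pos + 1L, site_type, alt,
                               affected, f, eps_sys)]
  write_tsv_header(out_truth, truth_path,
                   params = list(seed = config$seed, reads_seed = seed,
                                 coords = "1-based"))
  fq_path <- NULL
  if (fastq) {
    sseq <- seqs; squal <- quals
    rv <- reads$rev_strand
    sseq[rv] <- revcomp_chr(sseq[rv])
    squal[rv] <- vapply(strsplit(squal[rv], ""), function(x)
      paste(base::rev(x), collapse = ""), "")
    fq_path <- file.path(dir, "reads.fq")
    writeLines(paste0("@", qname, ifelse(is.na(reads$mate), "",
                                         paste0("/", reads$mate)), "\n",
                      sseq, "\n+\n", squal), fq_path)
  }

  ## --- bookkeeping (fragment arithmetic, independent of SAM) ---------
  cov_reads <- tabulate(gpos + 1L, nbins = len)
  cov_pairs <- integer(len)
  if (config$paired) {
    ov_lo <- ifelse(frags$fraglen <= R, frags$start0,
                    frags$start0 + frags$fraglen - R)
    ov_hi <- ifelse(frags$fraglen <= R, frags$start0 + frags$fraglen - 1L,
                    frags$start0 + R - 1L)
    has_ov <- ov_hi >= ov_lo
    opos <- unlist(Map(seq.int, ov_lo[has_ov], ov_hi[has_ov]))
    cov_pairs <- tabulate(opos + 1L, nbins = len)
  }
  coverage <- data.table(chrom = config$chrom, pos = 0:(len - 1L),
                         reads = cov_reads, pairs = cov_pairs)

  list(sam = sam_path, fasta = fasta_path, truth_path = truth_path,
       fastq = fq_path, truth = truth, coverage = coverage,
       fragments = frags, n_reads = nrow(reads))
}

#' Simulate a complete dataset (genome, truth, reads)
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @param reads_seed optional override of the reads-stage seed (for
#'   replicate experiments over the same genome and truth).
#' @param fastq also write a FASTQ export.
#' @return the [simulate_reads()] result, plus `genome` and `config`.
#' @export
simulate_dataset <- function(config, dir = tempfile("sim"),
                             reads_seed = NULL, fastq = FALSE) {
  gen <- simulate_genome(config)
  truth <- plant_sites(gen, config)
  args <- list(gen = gen, truth = truth, config = config, dir = dir,
               fastq = fastq)
  if (!is.null(reads_seed)) args$seed <- reads_seed
  out <- do.call(simulate_reads, args)
  out$genome <- gen$genome
  out$ggt <- gen$ggt
  out$config <- config
  out
}
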