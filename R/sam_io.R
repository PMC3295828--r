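# default exclusion mask: unmapped | secondary | QC-fail | duplicate |
# supplementary
DEFAULT_EXCLUDE <- 0x4L + 0x100L + 0x200L + 0x400L + 0x800L

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) stop("region must look like chrom:start-end (1-based)")
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

# expand CIGAR strings to aligned (reference position, query position)
# coordinates.  Fast path for pure-match CIGARs; general walk otherwise.
# Returns list(ridx, gpos [0-based], qpos [1-based within query]).
expand_cigar <- function(cigar, pos0, qwidth) {
  simple <- grepl("^[0-9]+M$", cigar)
  out_r <- out_g <- out_q <- vector("list", 2L)
  if (any(simple)) {
    w <- qwidth[simple]
    out_r[[1]] <- rep(which(simple), w)
    out_g[[1]] <- sequence(w, from = pos0[simple])
    out_q[[1]] <- sequence(w)
  }
  gen <- which(!simple)
  if (length(gen)) {
    res <- lapply(gen, function(i) {
      nums <- as.integer(regmatches(cigar[i],
        gregexpr("[0-9]+", cigar[i]))[[1]])
      ops <- regmatches(cigar[i], gregexpr("[MIDNSHP=X]", cigar[i]))[[1]]
      g <- pos0[i]; q <- 1L
      gp <- integer(0); qp <- integer(0)
      for (j in seq_along(ops)) {
        L <- nums[j]
        switch(ops[j],
          M = , `=` = , X = {
            gp <- c(gp, seq.int(g, length.out = L))
            qp <- c(qp, seq.int(q, length.out = L))
            g <- g + L; q <- q + L
          },
          I = , S = { q <- q + L },
          D = , N = { g <- g + L },
          H = , P = NULL)
      }
      list(r = rep(i, length(gp)), g = gp, q = qp)
    })
    out_r[[2]] <- unlist(lapply(res, `[[`, "r"))
    out_g[[2]] <- unlist(lapply(res, `[[`, "g"))
    out_q[[2]] <- unlist(lapply(res, `[[`, "q"))
  }
  list(ridx = unlist(out_r), gpos = unlist(out_g), qpos = unlist(out_q))
}

#' Read aligned reads into a per-base call table
#'
#' Ingests a SAM (or BAM) file against a FASTA reference and expands
#' every aligned read into one row per covered reference position: the
#' pileup, in long form.  Unmapped, secondary, supplementary, QC-fail
#' and duplicate-flagged records are excluded by default (override with
#' `exclude_flags`).  Insertions contribute no rows (no reference
#' coordinate), deletion/skip gaps contribute no calls, and positions
#' whose reference base is N are dropped.
#'
#' @param sam_path SAM or BAM file.
#' @param fasta_path reference FASTA.
#' @param region optional "chrom:start-end" (1-based, inclusive) filter.
#' @param exclude_flags integer FLAG mask; records with any of these
#'   bits set are skipped.
#' @return data.table of class `syserr_calls` with columns `chrom`,
#'   `pos` (0-based), `read` (fragment name), `mate` (1/2 or NA),
#'   `rev_strand` (read orientation), `base`, `qual` (Phred integer),
#'   `ref` (reference base).  The reference [Biostrings::DNAStringSet]
#'   is attached as attribute `reference`.
#' @export
read_alignments <- function(sam_path, fasta_path, region = NULL,
                            exclude_flags = DEFAULT_EXCLUDE) {
  reference <- Biostrings::readDNAStringSet(fasta_path)
  names(reference) <- sub("\\s.*", "", names(reference))

  bam <- sam_path
  if (!grepl("\\.bam$", sam_path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(sam_path, dest, overwrite = TRUE,
                       indexDestination = FALSE))
  }
  what <- c("qname", "flag", "rname", "pos", "cigar", "seq", "qual")
  b <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]

  keep <- bitwAnd(b$flag, as.integer(exclude_flags)) == 0L & !is.na(b$pos)
  if (!any(keep)) {
    empty <- data.table(chrom = character(), pos = integer(),
                        read = character(), mate = integer(),
                        rev_strand = logical(), base = character(),
                        qual = integer(), ref = character())
    setattr(empty, "reference", reference)
    setattr(empty, "class", c("syserr_calls", class(empty)))
    return(empty)
  }
  qname <- b$qname[keep]; flag <- b$flag[keep]
  rname <- as.character(b$rname)[keep]; pos1 <- b$pos[keep]
  cigar <- b$cigar[keep]
  seqs <- b$seq[keep]; quals <- b$qual[keep]

  miss <- setdiff(unique(rname), names(reference))
  if (length(miss))
    stop("reference sequence missing from FASTA: ",
         paste(miss, collapse = ", "))

  w <- Biostrings::width(seqs)
  ex <- expand_cigar(cigar, pos1 - 1L, w)
  offs <- cumsum(w) - w
  chars <- strsplit(paste(as.character(seqs), collapse = ""), "",
                    fixed = TRUE)[[1]]
  qints <- unlist(methods::as(quals, "IntegerList"), use.names = FALSE)

  idx <- offs[ex$ridx] + ex$qpos
  mate <- rep(NA_integer_, length(flag))
  mate[bitwAnd(flag, 0x40L) != 0L] <- 1L
  mate[bitwAnd(flag, 0x80L) != 0L] <- 2L

  calls <- data.table(
    chrom = rname[ex$ridx],
    pos = ex$gpos,
    read = qname[ex$ridx],
    mate = mate[ex$ridx],
    rev_strand = bitwAnd(flag[ex$ridx], 0x10L) != 0L,
    base = chars[idx],
    qual = qints[idx])

  # reference base per call
  refchars <- lapply(as.character(reference), function(s)
    strsplit(s, "", fixed = TRUE)[[1]])
  ci <- match(calls$chrom, names(refchars))
  calls[, ref := mapply(function(i, p) refchars[[i]][p + 1L], ci, pos,
                        USE.NAMES = FALSE)]
  # (mapply on two long vectors is slow; vectorize per chrom instead)
  for (ch in unique(calls$chrom)) {
    rc <- refchars[[ch]]
    calls[chrom == ch, ref := rc[pos + 1L]]
  }
  calls <- calls[ref != "N"]

  if (!is.null(region)) {
    rg <- parse_region(region)
    calls <- calls[chrom == rg$chrom & pos >= rg$start - 1L &
                     pos <= rg$end - 1L]
  }
  setkey(calls, chrom, pos)
  setattr(calls, "reference", reference)
  setattr(calls, "class", c("syserr_calls", class(calls)))
  calls
}

#' Reduce paired calls to a single-end dataset
#'
#' For each fragment one mate is chosen at random and the other's calls
#' are dropped, emulating a non-overlapping, non-paired-end experiment.
#' Calls without mate information are kept as-is.
#'
#' @param calls a call table from [read_alignments()].
#' @param seed integer seed.
#' @return filtered call table (same class and attributes).
#' @export
single_end_calls <- function(calls, seed) {
  set.seed(seed)
  frs <- unique(calls[!is.na(mate), read])
  if (!length(frs)) return(calls)
  pick <- data.table(read = frs, mate = sample(1:2, length(frs),
                                               replace = TRUE))
  out <- rbind(calls[is.na(mate)],
               calls[pick, on = c("read", "mate"), nomatch = NULL])
  setkey(out, chrom, pos)
  setattr(out, "reference", attr(calls, "reference"))
  setattr(out, "class", class(calls))
  out
}

#' Subsample whole reads from a call table
#'
#' Samples a fraction of read records (a record is one aligned read:
#' fragment name plus mate index) without replacement, emulating an
#' experiment of proportionally lower coverage.
#'
#' @param calls a call table.
#' @param fraction fraction of reads to keep in (0, 1].
#' @param seed integer seed.
#' @return filtered call table.
#' @export
subsample_calls <- function(calls, fraction, seed) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(calls)
  set.seed(seed)
  ids <- unique(calls[, .(read, mate)])
  keep <- ids[sample(.N, floor(fraction * .N))]
  out <- calls[keep, on = c("read", "mate"), nomatch = NULL]
  setkey(out, chrom, pos)
  setattr(out, "reference", attr(calls, "reference"))
  setattr(out, "class", class(calls))
  out
}
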