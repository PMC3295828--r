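DNA <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# vectorized reverse complement of character vectors of sequences
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# complement of single-character vectors (no reversal)
complement_chr <- function(x) unname(COMPLEMENT[x])

phred_to_error <- function(q) 10^(-q / 10)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_prob <- function(p, name = deparse(substitute(p))) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop(name, " must be a probability in [0, 1]", call. = FALSE)
}

# clip p-values to a reportable range; extreme tails underflow double
clip_pvalue <- function(p) pmin(pmax(p, 1e-320), 1)

#' Write a TSV with a provenance header
#'
#' All user-facing tables carry comment lines recording the package
#' version, the full parameterization of the run, and the seed, so any
#' output file can be traced back to the command that produced it.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param params named list recorded in the header (seed included here).
#' @return `path`, invisibly.
#' @export
write_tsv_header <- function(x, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# syserr v%s", as.character(packageVersion("syserr"))), con)
  if (length(params)) {
    kv <- vapply(names(params), function(nm)
      sprintf("%s=%s", nm, paste(format(params[[nm]]), collapse = ",")), "")
    writeLines(paste0("# ", kv), con)
  }
  suppressWarnings(write.table(x, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Read a TSV written by [write_tsv_header()]
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_header <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

# derive a child seed from a run seed; keeps results < 2^31
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587)
}
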