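CLASS_LEVELS <- c("systematic_error", "heterozygous")  # encoded 0 / 1

#' Build labelled training sets from overlapping-pair evidence
#'
#' Candidate training sites are positions with at least `coverage_min`
#' analysis pairs and a forward-strand mismatch fraction inside `band`
#' (heterozygous-looking sites).  Overlapping mates then supply the
#' labels: sites where every difference from the reference is a
#' SNP-pair are labelled heterozygous, sites where every difference is
#' an error-pair are labelled systematic errors, and sites with mixed
#' or discordant evidence are excluded.  With `balance = TRUE` the
#' larger class is randomly downsampled to the size of the smaller so
#' that predictions are feature-based only.
#'
#' @param pairs pair table from [pair_overlaps()].
#' @param calls the call table the pairs came from (for per-strand
#'   mismatch fractions).
#' @param coverage_min minimum pair coverage (default 40).
#' @param band forward-strand mismatch fraction window (default
#'   0.10 to 0.90).
#' @param balance downsample the larger class.
#' @param seed seed for the balancing draw.
#' @return data.table with `chrom`, `pos`, `label` (factor
#'   systematic_error / heterozygous).
#' @export
build_training_sets <- function(pairs, calls, coverage_min = 40L,
                                band = c(0.10, 0.90), balance = TRUE,
                                seed = 1L) {
  s <- pair_site_summary(pairs)
  ss <- site_strand_summary(calls)
  s <- merge(s, ss[, .(chrom, pos, cov_fwd, mm_fwd)],
             by = c("chrom", "pos"))
  s <- s[n_pairs >= coverage_min & cov_fwd > 0]
  s[, frac := mm_fwd / cov_fwd]
  s <- s[frac >= band[1] & frac <= band[2]]
  snp <- s[n_err == 0L & n_disc == 0L & n_snp > 0L]
  syserr <- s[n_snp == 0L & n_disc == 0L & n_err > 0L]
  if (!nrow(snp) || !nrow(syserr))
    stop("training aborted: empty class (snp: ", nrow(snp),
         ", syserr: ", nrow(syserr), ")")
  if (balance) {
    set.seed(seed)
    nmin <- min(nrow(snp), nrow(syserr))
    snp <- snp[sample(.N, nmin)]
    syserr <- syserr[sample(.N, nmin)]
  }
  out <- rbind(
    syserr[, .(chrom, pos, label = factor("systematic_error", CLASS_LEVELS))],
    snp[, .(chrom, pos, label = factor("heterozygous", CLASS_LEVELS))])
  setkey(out, chrom, pos)
  out[]
}

# ridge-penalized IRLS for the binomial log-likelihood; the intercept is
# unpenalized.  Used as fallback under perfect separation.
ridge_logistic <- function(X, y, lambda = 1e-4, tol = 1e-8, maxit = 100L) {
  p <- ncol(X)
  D <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta <- drop(solve(XtW %*% X + D, XtW %*% z))
    eta <- drop(X %*% beta)
    ll <- sum(y * eta - log1p(exp(eta))) - lambda * sum(beta[-1]^2) / 2
    if (is.finite(ll_old) && abs(ll - ll_old) <
        tol * (abs(ll_old) + tol)) break
    ll_old <- ll
  }
  list(coef = setNames(beta, colnames(X)), iterations = it,
       converged = it < maxit)
}

#' Train the heterozygous-vs-systematic-error logistic classifier
#'
#' Fits a logistic regression of class (systematic_error = 0,
#' heterozygous = 1) on the encoded feature design
#' ([encode_features()]) by maximum likelihood (IRLS, convergence by
#' relative log-likelihood change below 1e-8, at most 100 iterations).
#' Constant encoded columns are dropped with a warning (their
#' coefficients are reported as 0).  Under perfect separation -- which
#' the near-disjoint paired-t distributions of the two classes make
#' common -- the fit is redone with a small ridge penalty (lambda =
#' 1e-4) and flagged.
#'
#' @param features [site_features()] rows (only `ok` rows are used).
#' @param labels factor with levels systematic_error, heterozygous,
#'   aligned with `features` rows.
#' @param features_used "full" (all six features) or "delta_q" (the
#'   directionality-bias-only ablation).
#' @param lambda ridge penalty of the separation fallback.
#' @return object of class `syserr_model`: coefficient vector (full
#'   encoded design, dropped columns as 0), flags, and
#'   `training_coverage` (NA here; set by [train_bank()]).
#' @export
train_logistic <- function(features, labels,
                           features_used = c("full", "delta_q"),
                           lambda = 1e-4) {
  features_used <- match.arg(features_used)
  f <- as.data.table(features)
  labels <- factor(labels, CLASS_LEVELS)
  stopifnot(nrow(f) == length(labels))
  keep <- if ("ok" %in% names(f)) which(f$ok) else seq_len(nrow(f))
  f <- f[keep]; labels <- labels[keep]
  if (min(table(labels)) < 2L)
    stop("need at least 2 examples of each class")
  X_full <- encode_features(f, features_used)
  y <- as.integer(labels) - 1L
  const <- apply(X_full, 2L, function(col) length(unique(col)) == 1L)
  const[1L] <- FALSE  # keep intercept
  if (any(const))
    warning("dropping constant feature column(s): ",
            paste(colnames(X_full)[const], collapse = ", "))
  X <- X_full[, !const, drop = FALSE]

  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8,
                                                maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged || any(!is.finite(fit$coefficients))) {
    rfit <- ridge_logistic(X, y, lambda = lambda)
    if (!rfit$converged)
      stop("logistic fit failed to converge even with ridge fallback; ",
           "n = ", nrow(X), ", class sizes = ",
           paste(table(labels), collapse = "/"))
    coef <- rfit$coef
  } else {
    coef <- fit$coefficients
  }
  full_coef <- setNames(numeric(ncol(X_full)), colnames(X_full))
  full_coef[names(coef)] <- coef
  structure(list(coef = full_coef, features_used = features_used,
                 ridge = sep, n = nrow(X),
                 dropped = colnames(X_full)[const],
                 training_coverage = NA_real_),
            class = "syserr_model")
}

#' Posterior probability of heterozygosity for feature rows
#'
#' @param model a `syserr_model`.
#' @param features [site_features()] rows.
#' @return vector of posteriors `1 / (1 + exp(-beta' x))`, kept strictly
#'   inside (0, 1) by clipping at 1e-12 from either end (large linear
#'   predictors saturate `plogis` to exactly 0/1 in double precision).
#' @export
predict_posterior <- function(model, features) {
  X <- encode_features(features, model$features_used)
  p <- stats::plogis(drop(X %*% model$coef))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' @export
print.syserr_model <- function(x, ...) {
  cat("syserr logistic model (", x$features_used, " features, n = ",
      x$n, if (x$ridge) ", ridge fallback" else "", ")\n", sep = "")
  print(round(x$coef, 4))
  invisible(x)
}

#' Train a coverage-stratified model bank
#'
#' Lower-coverage experiments are emulated by sampling a fraction of
#' the reads without replacement; for each fraction the labelled sites
#' are refined to those retaining at least one mismatching call,
#' features are rebuilt on the subsampled reads, and a model is
#' trained.  Each model is keyed by the realized mean read coverage of
#' the training sites so that prediction can pick the model closest to
#' a new dataset's coverage.
#'
#' @param calls full-coverage call table (paired, for labelling).
#' @param reference reference genome ([Biostrings::DNAStringSet]).
#' @param training_sites optional labelled sites (from
#'   [build_training_sets()]); computed from `calls` when NULL.
#' @param fractions read fractions to train at.
#' @param seed run seed (drives labelling balance, the single-end
#'   reduction and every subsampling draw).
#' @param single_end reduce to one read per fragment before
#'   subsampling, so the bank matches single-end use.
#' @param train_n per-class training-set size; the labelled sites are
#'   downsampled to this (NULL = use all, balanced).
#' @param coverage_min,band passed to [build_training_sets()].
#' @param features_used "full" or "delta_q".
#' @return object of class `syserr_bank`: list of `syserr_model`s
#'   sorted by `training_coverage`.
#' @export
train_bank <- function(calls, reference = attr(calls, "reference"),
                       training_sites = NULL,
                       fractions = c(0.2, 0.4, 0.6, 0.8, 1.0),
                       seed = 1L, single_end = TRUE, train_n = NULL,
                       coverage_min = 40L, band = c(0.10, 0.90),
                       features_used = "full") {
  if (is.null(training_sites)) {
    pairs <- pair_overlaps(calls)
    training_sites <- build_training_sets(pairs, calls,
                                          coverage_min = coverage_min,
                                          band = band,
                                          seed = child_seed(seed, 1L))
  }
  base_calls <- if (single_end)
    single_end_calls(calls, child_seed(seed, 2L)) else calls
  models <- list()
  for (i in seq_along(fractions)) {
    fr <- fractions[i]
    sub <- subsample_calls(base_calls, fr, child_seed(seed, 10L + i))
    ss <- site_strand_summary(sub)
    refined <- merge(training_sites, ss, by = c("chrom", "pos"))
    refined <- refined[mm_fwd + mm_rev > 0L]
    if (!nrow(refined) || min(table(refined$label)) < 2L) {
      warning("fraction ", fr, ": a class became empty; model skipped")
      next
    }
    if (!is.null(train_n)) {
      set.seed(child_seed(seed, 20L + i))
      refined <- refined[, .SD[sample(.N, min(.N, train_n))], by = label]
    }
    feats <- site_features(sub, refined[, .(chrom, pos)], reference)
    ok <- feats$ok
    model <- train_logistic(feats[ok], refined$label[ok],
                            features_used = features_used)
    model$training_coverage <- mean(refined[, cov_fwd + cov_rev])
    model$fraction <- fr
    models[[length(models) + 1L]] <- model
  }
  if (!length(models)) stop("train_bank: no model could be trained")
  ord <- order(vapply(models, `[[`, 0, "training_coverage"))
  structure(models[ord], class = "syserr_bank")
}

bank_coverages <- function(bank)
  vapply(bank, `[[`, 0, "training_coverage")

# nearest training coverage; ties resolved to the higher coverage
select_model <- function(bank, coverage) {
  cv <- bank_coverages(bank)
  d <- abs(cv - coverage)
  idx <- which(d == min(d))
  bank[[idx[length(idx)]]]
}

#' Classify candidate sites as heterozygous or systematic errors
#'
#' Computes the dataset's mean coverage, picks the bank model trained
#' at the closest coverage, extracts features for each candidate site
#' and partitions the candidates by posterior probability of being a
#' true heterozygous site: posterior >= 0.5 goes to the heterozygous
#' list, below to the systematic-error list.  Sites whose features
#' cannot be extracted are emitted to a rejects table with a reason.
#' With multiply-mapped reads, every mapping present in the input
#' contributes independently.
#'
#' @param bank a `syserr_bank` (or a single `syserr_model`).
#' @param calls call table of the dataset to classify.
#' @param sites optional candidate list (`chrom`, `pos` 0-based);
#'   defaults to [candidate_sites()] on the dataset.
#' @param reference reference genome; defaults to the one attached to
#'   `calls`.
#' @param min_frac,min_diff thresholds of the default candidate filter.
#' @return list with data.tables `heterozygous`, `systematic_errors`
#'   (both: `chrom`, `pos`, `posterior`), `rejects` (`chrom`, `pos`,
#'   `reason`), plus `model_coverage` and `dataset_coverage`.
#' @export
classify_sites <- function(bank, calls, sites = NULL,
                           reference = attr(calls, "reference"),
                           min_frac = 0.10, min_diff = 5L) {
  if (inherits(bank, "syserr_model")) bank <- structure(list(bank),
                                                        class = "syserr_bank")
  if (is.null(sites)) sites <- candidate_sites(calls, min_frac, min_diff)
  sites <- as.data.table(sites)[, .(chrom, pos)]
  dataset_cov <- calls[, .N, by = .(chrom, pos)][, mean(N)]
  model <- select_model(bank, dataset_cov)
  feats <- site_features(calls, sites, reference)
  ok <- feats$ok
  post <- rep(NA_real_, nrow(feats))
  post[ok] <- predict_posterior(model, feats[ok])
  res <- data.table(chrom = feats$chrom, pos = feats$pos,
                    posterior = post)
  list(heterozygous = res[ok & post >= 0.5],
       systematic_errors = res[ok & post < 0.5],
       rejects = data.table(chrom = feats$chrom, pos = feats$pos,
                            reason = feats$reason)[!ok],
       model_coverage = model$training_coverage,
       dataset_coverage = dataset_cov)
}

#' Serialize a model bank to a human-readable TSV
#'
#' One row per (model, coefficient); the header records the package
#' version, the feature encoding (one-hot nucleotides, reference level
#' A) and per-model flags, so the file is a complete, auditable record
#' of the classifier.
#'
#' @param bank a `syserr_bank`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_bank <- function(bank, path) {
  rows <- rbindlist(lapply(seq_along(bank), function(i) {
    m <- bank[[i]]
    data.table(model = i, training_coverage = m$training_coverage,
               features_used = m$features_used, ridge = m$ridge,
               n_train = m$n, term = names(m$coef), estimate = m$coef)
  }))
  write_tsv_header(rows, path, params = list(
    format = "syserr-model-bank-v1",
    encoding = "one-hot nucleotides, reference level A"))
}

#' Read a model bank written by [write_model_bank()]
#' @param path TSV path.
#' @return a `syserr_bank`.
#' @export
read_model_bank <- function(path) {
  rows <- as.data.table(read_tsv_header(path))
  models <- lapply(split(rows, rows$model), function(r) {
    structure(list(coef = setNames(r$estimate, r$term),
                   features_used = r$features_used[1L],
                   ridge = r$ridge[1L], n = r$n_train[1L],
                   dropped = character(0),
                   training_coverage = r$training_coverage[1L]),
              class = "syserr_model")
  })
  ord <- order(vapply(models, `[[`, 0, "training_coverage"))
  structure(unname(models[ord]), class = "syserr_bank")
}

#' Coverage-stratified classifier benchmark on simulated data
#'
#' Implements the evaluation protocol for a simulated dataset: label
#' sites from full-coverage overlapping pairs, balance the two labelled
#' classes (capped at `class_n` sites per class), reduce the reads to
#' single-end, then for each read fraction subsample the reads, refine
#' the labelled sites to those retaining at least one mismatching call,
#' split each class in half into training and held-out test sets
#' (training size = half of the smaller refined class), train the
#' full-feature and the directionality-only (delta_q) models on the
#' training half, and record test accuracy for both.
#'
#' @param calls full paired call table of the simulated dataset.
#' @param reference reference genome.
#' @param fractions read fractions to evaluate.
#' @param seed run seed.
#' @param class_n per-class cap on the labelled sets (default 338).
#' @param coverage_min,band labelling thresholds (see
#'   [build_training_sets()]).
#' @return data.table with one row per fraction: realized `coverage`
#'   (mean single-end read coverage over the refined sites), `n_train`,
#'   `n_test`, `acc_full`, `acc_delta_q`.
#' @export
benchmark_classifier <- function(calls,
                                 reference = attr(calls, "reference"),
                                 fractions = c(0.2, 0.4, 0.6, 0.8),
                                 seed = 1L, class_n = 338L,
                                 coverage_min = 40L,
                                 band = c(0.10, 0.90)) {
  pairs <- pair_overlaps(calls)
  labelled <- build_training_sets(pairs, calls, coverage_min = coverage_min,
                                  band = band, balance = FALSE)
  set.seed(child_seed(seed, 1L))
  labelled <- labelled[, .SD[sample(.N, min(.N, class_n))], by = label]
  se <- single_end_calls(calls, child_seed(seed, 2L))
  out <- list()
  for (i in seq_along(fractions)) {
    fr <- fractions[i]
    sub <- subsample_calls(se, fr, child_seed(seed, 10L + i))
    ss <- site_strand_summary(sub)
    refined <- merge(labelled, ss, by = c("chrom", "pos"))
    refined <- refined[mm_fwd + mm_rev > 0L]
    n_half <- refined[, floor(min(table(label)) / 2)]
    set.seed(child_seed(seed, 20L + i))
    tr <- refined[, .SD[sample(.N, n_half)], by = label]
    te <- refined[!tr, on = c("chrom", "pos")]
    feats_tr <- site_features(sub, tr[, .(chrom, pos)], reference)
    feats_te <- site_features(sub, te[, .(chrom, pos)], reference)
    acc <- function(fu) {
      m <- train_logistic(feats_tr[feats_tr$ok], tr$label[feats_tr$ok],
                          features_used = fu)
      ok <- feats_te$ok
      pred <- ifelse(predict_posterior(m, feats_te[ok]) >= 0.5,
                     "heterozygous", "systematic_error")
      mean(pred == as.character(te$label[ok]))
    }
    out[[i]] <- data.table(
      fraction = fr,
      coverage = mean(refined[, cov_fwd + cov_rev]),
      n_train = nrow(tr), n_test = nrow(te),
      acc_full = suppressWarnings(acc("full")),
      acc_delta_q = suppressWarnings(acc("delta_q")))
  }
  rbindlist(out)
}
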