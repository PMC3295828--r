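# random feature tables over the encoded design
random_features <- function(n, seed) {
  set.seed(seed)
  data.table(b_m2 = sample(c("A","C","G","T"), n, TRUE),
             b_m1 = sample(c("A","C","G","T"), n, TRUE),
             b_0 = sample(c("A","C","G","T"), n, TRUE),
             delta_q = runif(n), q1 = runif(n),
             pt = rnorm(n, 0, 3))
}

logit_se <- function(X, coef) {
  mu <- stats::plogis(drop(X %*% coef))
  w <- mu * (1 - mu)
  sqrt(diag(solve(t(X * w) %*% X)))
}

test_that("null labels give near-zero coefficients", {
  f <- random_features(2000, seed = 4)
  set.seed(5)
  y <- factor(sample(c("systematic_error", "heterozygous"), 2000, TRUE),
              c("systematic_error", "heterozygous"))
  m <- train_logistic(f, y)
  X <- encode_features(f)
  se <- logit_se(X, m$coef)
  expect_true(all(abs(m$coef[-1]) < 3 * se[-1]))
  expect_false(m$ridge)
})

test_that("perfect separation triggers the ridge fallback with the right sign", {
  f <- random_features(200, seed = 8)
  y <- factor(ifelse(f$pt < 0, "systematic_error", "heterozygous"),
              c("systematic_error", "heterozygous"))
  m <- suppressWarnings(train_logistic(f, y))
  expect_true(m$ridge)
  expect_gt(m$coef[["pt"]], 0)
  # posterior still orders the classes perfectly
  post <- predict_posterior(m, f)
  expect_gt(min(post[y == "heterozygous"]), max(post[y == "systematic_error"]))
})

test_that("training recovers known coefficients within 3 SE", {
  beta <- c(`(Intercept)` = -0.4,
            b_m2C = 0.3, b_m2G = -0.2, b_m2T = 0.1,
            b_m1C = 0.5, b_m1G = -0.7, b_m1T = 0.2,
            b_0C = -0.3, b_0G = 0.4, b_0T = -0.1,
            delta_q = -1.5, q1 = 0.8, pt = 0.4)
  for (n in c(500L, 5000L)) {
    f <- random_features(n, seed = 31)
    X <- encode_features(f)
    set.seed(32)
    y01 <- rbinom(n, 1, stats::plogis(drop(X %*% beta)))
    y <- factor(ifelse(y01 == 1, "heterozygous", "systematic_error"),
                c("systematic_error", "heterozygous"))
    m <- train_logistic(f, y)
    se <- logit_se(X, m$coef)
    expect_true(all(abs(m$coef - beta) < 3 * se))
  }
  # and the error shrinks with n (convergence toward truth)
  errs <- vapply(c(500L, 5000L), function(n) {
    f <- random_features(n, seed = 31)
    X <- encode_features(f)
    set.seed(32)
    y01 <- rbinom(n, 1, stats::plogis(drop(X %*% beta)))
    y <- factor(ifelse(y01 == 1, "heterozygous", "systematic_error"),
                c("systematic_error", "heterozygous"))
    sqrt(mean((train_logistic(f, y)$coef - beta)^2))
  }, 0)
  expect_lt(errs[2], errs[1])
})

test_that("constant encoded columns are dropped with a warning", {
  f <- random_features(300, seed = 12)
  f[, b_m1 := "G"]
  set.seed(13)
  y <- factor(ifelse(runif(300) < stats::plogis(2 * f$delta_q - 1),
                     "heterozygous", "systematic_error"),
              c("systematic_error", "heterozygous"))
  expect_warning(m <- train_logistic(f, y), "constant")
  expect_equal(unname(m$coef[c("b_m1C", "b_m1G", "b_m1T")]), c(0, 0, 0))
})

test_that("a zero model scores 0.5 and labels heterozygous by convention", {
  f <- random_features(50, seed = 14)
  m <- structure(list(coef = setNames(numeric(13),
                                      colnames(encode_features(f[1]))),
                      features_used = "full", ridge = FALSE, n = 0L,
                      dropped = character(0), training_coverage = 10),
                 class = "syserr_model")
  post <- predict_posterior(m, f)
  expect_equal(post, rep(0.5, 50))
  # posterior is monotone in the linear predictor
  m$coef[["delta_q"]] <- 2
  grid <- data.table(b_m2 = "A", b_m1 = "A", b_0 = "A",
                     delta_q = seq(0, 1, 0.1), q1 = 0.5, pt = 0)
  expect_true(all(diff(predict_posterior(m, grid)) > 0))
})

test_that("training labels from pair evidence agree with simulator truth", {
  ds <- shared_ds()
  ts <- build_training_sets(shared_pairs(), shared_calls(),
                            coverage_min = 40L, balance = FALSE)
  tt <- merge(ts, ds$truth, by = c("chrom", "pos"))
  expect_gt(nrow(tt) / nrow(ts), 0.99)  # labelled sites are planted sites
  agree <- tt[, mean((label == "heterozygous") == (site_type == "het"))]
  expect_gte(agree, 0.99)
  expect_error(build_training_sets(shared_pairs(), shared_calls(),
                                   coverage_min = 10000L), "empty class")
})

test_that("model bank trains across fractions and selects by coverage", {
  bank <- fixture("bank", suppressWarnings(
    train_bank(shared_calls(), fractions = c(0.3, 1.0), seed = 17L)))
  cov <- vapply(bank, function(m) m$training_coverage, 0)
  expect_true(all(diff(cov) > 0))
  # nearest-coverage selection, ties to the higher coverage
  expect_equal(syserr:::select_model(bank, 0)$training_coverage, cov[1])
  expect_equal(syserr:::select_model(bank, 1e6)$training_coverage, cov[2])
  expect_equal(syserr:::select_model(bank, mean(cov))$training_coverage,
               cov[2])
})

test_that("model bank serialization round-trips", {
  bank <- fixture("bank", suppressWarnings(
    train_bank(shared_calls(), fractions = c(0.3, 1.0), seed = 17L)))
  path <- tempfile(fileext = ".tsv")
  write_model_bank(bank, path)
  bank2 <- read_model_bank(path)
  expect_equal(length(bank2), length(bank))
  for (i in seq_along(bank)) {
    expect_equal(bank2[[i]]$coef, bank[[i]]$coef)
    expect_equal(bank2[[i]]$training_coverage,
                 bank[[i]]$training_coverage)
    expect_equal(bank2[[i]]$features_used, bank[[i]]$features_used)
  }
  # header records the encoding
  expect_true(any(grepl("one-hot", readLines(path, n = 5))))
})

test_that("classification partitions candidates and ignores input order", {
  calls <- shared_calls()
  bank <- fixture("bank", suppressWarnings(
    train_bank(calls, fractions = c(0.3, 1.0), seed = 17L)))
  cand <- candidate_sites(calls)
  res <- classify_sites(bank, calls, sites = cand)
  got <- rbind(res$heterozygous[, .(chrom, pos)],
               res$systematic_errors[, .(chrom, pos)],
               res$rejects[, .(chrom, pos)])
  expect_equal(nrow(got), nrow(cand))
  expect_equal(got[order(chrom, pos)], cand[order(chrom, pos), .(chrom, pos)],
               ignore_attr = TRUE)
  expect_true(all(res$heterozygous$posterior >= 0.5))
  expect_true(all(res$systematic_errors$posterior < 0.5))
  expect_true(all(res$heterozygous$posterior > 0 &
                    res$heterozygous$posterior < 1))
  # permuting the candidate list permutes nothing but row order
  set.seed(3)
  res2 <- classify_sites(bank, calls, sites = cand[sample(.N)])
  expect_equal(res2$heterozygous[order(chrom, pos)],
               res$heterozygous[order(chrom, pos)])
  expect_equal(res2$systematic_errors[order(chrom, pos)],
               res$systematic_errors[order(chrom, pos)])
})

test_that("classifier separates planted site types on held-out data", {
  ds <- shared_ds()
  calls <- shared_calls()
  bank <- fixture("bank", suppressWarnings(
    train_bank(calls, fractions = c(0.3, 1.0), seed = 17L)))
  truth <- ds$truth
  res <- classify_sites(bank, calls,
                        sites = truth[, .(chrom, pos)])
  lab <- rbind(res$heterozygous[, .(chrom, pos, call = "het")],
               res$systematic_errors[, .(chrom, pos, call = "syserr")])
  m <- merge(lab, truth, by = c("chrom", "pos"))
  expect_gte(m[, mean(call == site_type)], 0.9)
})
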