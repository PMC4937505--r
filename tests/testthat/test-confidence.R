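mk_psms <- function(score, decoy, delta = NULL) {
  if (is.null(delta)) delta <- score / 2
  tibble::tibble(score = score,
                 delta_score = delta,
                 ppm_error = 0, missed_cleavages = 0, charge = 2,
                 decoy = decoy)
}

test_that("discriminant direction equals the closed-form Fisher solution", {
  set.seed(61)
  n <- 200
  x1 <- cbind(rnorm(n, 2), rnorm(n, 1))
  x0 <- cbind(rnorm(n, 0), rnorm(n, 0))
  psms <- tibble::tibble(score = c(x1[, 1], x0[, 1]),
                         delta_score = c(x1[, 2], x0[, 2]),
                         decoy = rep(c(0L, 1L), each = n))
  fit <- fit_discriminant(psms, features = c("score", "delta_score"))
  w <- attr(fit, "weights")
  sw <- ((n - 1) * cov(x1) + (n - 1) * cov(x0)) / (2 * n - 2)
  w_ref <- solve(sw, colMeans(x1) - colMeans(x0))
  expect_equal(unname(w), unname(w_ref), tolerance = 1e-10)
  # MASS::lda finds a proportional direction (independent implementation)
  ld <- MASS::lda(rbind(x1, x0), grouping = rep(c("t", "d"), each = n))
  ratio <- w / drop(ld$scaling)
  expect_lt(diff(range(ratio)) / abs(mean(ratio)), 1e-6)
})

test_that("separable and null feature sets behave as expected", {
  sep <- mk_psms(c(rep(10, 50), rep(0, 50)), rep(c(0L, 1L), each = 50))
  fit <- suppressWarnings(
    fit_discriminant(sep, features = c("score", "delta_score")))
  acc <- mean((fit$discriminant_score > 0) == (sep$decoy == 0))
  expect_equal(acc, 1)
  set.seed(62)
  null <- mk_psms(rnorm(4000), rep(c(0L, 1L), 2000), delta = rnorm(4000))
  nf <- fit_discriminant(null, features = c("score", "delta_score"))
  auc <- (mean(rank(nf$discriminant_score)[null$decoy == 0]) - (2000 + 1) / 2) /
    2000
  expect_lt(abs(auc - 0.5), 0.03)
  # constant feature triggers the ridge path with a warning
  const <- mk_psms(c(rep(5, 10), rep(1, 10)), rep(c(0L, 1L), each = 10))
  const$ppm_error <- 1
  expect_warning(
    fit_discriminant(const, features = c("score", "ppm_error")),
    "ridge")
  expect_error(fit_discriminant(mk_psms(1:4, rep(0L, 4))), "target and decoy")
})

test_that("FDR thresholding matches hand-traced and enumerated references", {
  x <- mk_psms(c(10, 9, 8, 7, 1), c(0L, 0L, 0L, 0L, 1L))
  # delta is collinear with score here, so the ridge path fires
  x <- suppressWarnings(
    fit_discriminant(x, features = c("score", "delta_score")))
  res <- threshold_at_fdr(x, 0.05)
  expect_equal(res$result$n_targets_kept, 4L)
  expect_equal(res$result$n_decoys_kept, 0L)
  expect_equal(res$result$estimated_fdr, 0)
  expect_equal(nrow(res$survivors), 4)
  # adversarial: all decoys outscore all targets
  bad <- mk_psms(c(1, 2, 9, 10), c(0L, 0L, 1L, 1L))
  bad$discriminant_score <- bad$score
  expect_warning(r2 <- threshold_at_fdr(bad, 0.05), "empty survivor")
  expect_equal(nrow(r2$survivors), 0)
  # random instances agree with exhaustive threshold enumeration
  set.seed(63)
  for (rep in 1:20) {
    sc <- round(rnorm(60), 1)  # ties included
    dc <- rbinom(60, 1, 0.4)
    df <- tibble::tibble(discriminant_score = sc, decoy = dc)
    lvl <- runif(1, 0.02, 0.5)
    ref <- oracle_fdr_threshold(sc, dc, lvl)
    got <- suppressWarnings(threshold_at_fdr(df, lvl))
    if (is.null(ref)) {
      expect_equal(nrow(got$survivors), 0)
    } else {
      expect_equal(got$result$threshold, ref$thr)
      expect_equal(got$result$n_targets_kept, ref$t)
      expect_equal(got$result$n_decoys_kept, ref$d)
    }
  }
})

test_that("survivor sets are monotone in the FDR level", {
  set.seed(64)
  df <- tibble::tibble(discriminant_score = rnorm(500),
                       decoy = rbinom(500, 1, 0.3),
                       id = 1:500)
  prev <- integer(0)
  for (lvl in c(0.01, 0.02, 0.05, 0.1, 0.3, 1)) {
    got <- suppressWarnings(threshold_at_fdr(df, lvl))
    expect_true(all(prev %in% got$survivors$id))
    if (nrow(got$survivors) > 0) {
      expect_lte(got$result$estimated_fdr, lvl)
    }
    prev <- got$survivors$id
  }
})

test_that("protein-level filtering reuses the decoy-counting rule", {
  single <- tibble::tibble(accession = "P1", decoy = 0L, score = 5)
  res <- protein_level_fdr(single, level = 0.02)
  expect_equal(nrow(res$survivors), 1)
  mixed <- tibble::tibble(
    accession = paste0("P", 1:40),
    decoy = rep(c(0L, 1L), c(30, 10)),
    score = c(rnorm(30, 3), rnorm(10, 0)))
  ref <- oracle_fdr_threshold(mixed$score, mixed$decoy, 0.1)
  got <- suppressWarnings(protein_level_fdr(mixed, 0.1))
  expect_equal(got$result$threshold, ref$thr)
  all_kept <- protein_level_fdr(mixed, 1.0)
  expect_equal(nrow(all_kept$survivors), 30)
  # best-peptide surrogate scoring
  psms <- tibble::tibble(proteins = c("P1", "P1", "P1;P2", "rev_P1"),
                         decoy = c(0L, 0L, 0L, 1L),
                         discriminant_score = c(1, 7, 3, 2))
  sp <- score_proteins(psms)
  expect_equal(sp$score[sp$accession == "P1"], 7)
  expect_equal(sp$score[sp$accession == "P2"], 3)
  expect_equal(sp$decoy[sp$accession == "rev_P1"], 1)
})
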