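test_that("theoretical reporter masses match the published series", {
  mz <- tmt6_reporter_mz()
  published <- c(126.12773, 127.12476, 128.13443, 129.13147,
                 130.14114, 131.13818)
  expect_equal(unname(mz), published, tolerance = 1e-6)
})

test_that("reporter extraction picks the highest in-window peak", {
  theo <- tmt6_reporter_mz()
  pk <- tibble::tibble(spectrum_id = "s1", mz = theo[["126"]],
                       intensity = 5000)
  out <- extract_reporters(pk)
  expect_equal(out$reporter_126, 5000)
  expect_equal(unlist(out[, paste0("reporter_", 127:131)]),
               rep(0, 5), ignore_attr = TRUE)
  # two peaks inside one window: the larger wins
  pk2 <- tibble::tibble(
    spectrum_id = "s1",
    mz = theo[["128"]] * (1 + c(-10, 10) * 1e-6),
    intensity = c(3000, 7000))
  expect_equal(extract_reporters(pk2)$reporter_128, 7000)
  # just outside the window is ignored
  pk3 <- tibble::tibble(spectrum_id = "s1",
                        mz = theo[["126"]] * (1 + 21e-6), intensity = 1e5)
  expect_equal(extract_reporters(pk3)$reporter_126, 0)
  # empty peak list: all-zero row, not an error
  empty <- tibble::tibble(spectrum_id = character(), mz = numeric(),
                          intensity = numeric())
  out0 <- extract_reporters(empty, spectrum_ids = "s9")
  expect_equal(sum(unlist(out0[, -1])), 0)
  expect_error(extract_reporters(pk, tol_ppm = -1), "non-negative")
})

test_that("reporter extraction agrees with a brute-force scan and ignores peak order", {
  set.seed(51)
  n <- 300
  ids <- sprintf("s%04d", seq_len(n))
  peaks <- tibble::tibble(
    spectrum_id = rep(ids, each = 12),
    mz = runif(12 * n, 125.9, 131.4),
    intensity = rlnorm(12 * n, log(2000), 1))
  mine <- extract_reporters(peaks)
  oracle <- oracle_extract(peaks)
  expect_equal(as.matrix(mine[match(rownames(oracle), mine$spectrum_id), -1]),
               oracle, ignore_attr = TRUE)
  shuffled <- peaks[sample.int(nrow(peaks)), ]
  mine2 <- extract_reporters(shuffled)
  expect_equal(mine2[match(mine$spectrum_id, mine2$spectrum_id), ],
               mine, ignore_attr = TRUE)
})

test_that("intensity filter is strict, order-preserving and idempotent", {
  mk <- function(total) {
    row <- tibble::tibble(peptide = paste0("p", total))
    rep <- matrix(total / 6, 1, 6,
                  dimnames = list(NULL, paste0("reporter_", 126:131)))
    dplyr::bind_cols(row, tibble::as_tibble(rep))
  }
  psms <- dplyr::bind_rows(mk(1999), mk(2000), mk(2001), mk(5000))
  kept <- filter_min_intensity(psms)
  expect_identical(kept$peptide, c("p2001", "p5000"))
  expect_identical(filter_min_intensity(kept)$peptide, kept$peptide)
  expect_equal(nrow(filter_min_intensity(psms[0, ])), 0)
})

test_that("peptide and protein rollup match brute-force accumulation", {
  rcols <- paste0("reporter_", 126:131)
  two <- tibble::tibble(peptide = "AAAD", proteins = "P1", decoy = 0L)
  two <- dplyr::bind_rows(two, two)
  two[rcols] <- 100
  pep <- rollup_peptides(two)
  expect_equal(unlist(pep[, rcols]), rep(200, 6), ignore_attr = TRUE)
  expect_equal(unlist(pep[, sub("reporter_", "rel_", rcols)]),
               rep(1, 6), ignore_attr = TRUE)
  one <- tibble::tibble(peptide = "CCCD", proteins = "P2")
  one[rcols] <- as.list(c(0, 0, 0, 0, 0, 600))
  pep1 <- rollup_peptides(one)
  expect_equal(unlist(pep1[, sub("reporter_", "rel_", rcols)]),
               c(0, 0, 0, 0, 0, 1), ignore_attr = TRUE)

  set.seed(52)
  rnd <- tibble::tibble(
    peptide = sample(paste0("pep", 1:20, "D"), 100, replace = TRUE),
    proteins = sample(c("P1", "P2", "P1;P3"), 100, replace = TRUE))
  rnd[rcols] <- as.data.frame(matrix(rlnorm(600), 100))
  mine <- rollup_peptides(rnd)
  for (i in sample.int(nrow(mine), 5)) {
    sel <- rnd$peptide == mine$peptide[i] & rnd$proteins == mine$proteins[i]
    expect_equal(unlist(mine[i, rcols]),
                 colSums(rnd[sel, rcols, drop = FALSE]),
                 ignore_attr = TRUE)
  }
  prot <- rollup_proteins(mine)
  relc <- sub("reporter_", "rel_", rcols)
  long <- tidyr::separate_rows(mine, "proteins", sep = ";")
  for (acc in prot$accession) {
    expect_equal(unlist(prot[prot$accession == acc, relc]),
                 colMeans(long[long$proteins == acc, relc]),
                 ignore_attr = TRUE)
  }
  # a shared peptide reaches both accessions; unique mode drops it
  shared_accs <- prot$accession
  expect_true(all(c("P1", "P3") %in% shared_accs))
  uniq <- rollup_proteins(mine, shared = "unique")
  expect_false("P3" %in% uniq$accession)

  # degenerate: two peptides, all ones and all zeros, average to one half
  pair <- tibble::tibble(peptide = c("AD", "ED"), proteins = "P9")
  pair[rcols] <- as.data.frame(rbind(rep(1, 6), rep(0, 6)))
  pp <- suppressWarnings(rollup_peptides(pair))
  expect_equal(unlist(rollup_proteins(pp)[, relc]), rep(0.5, 6),
               ignore_attr = TRUE)
})
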