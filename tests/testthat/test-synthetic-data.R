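test_that("protein database generation is deterministic, unique and D-rich", {
  db1 <- sim_protein_db(100, length_range = c(50, 500), seed = 11)
  db2 <- sim_protein_db(100, length_range = c(50, 500), seed = 11)
  expect_identical(db1, db2)
  expect_false(identical(db1, sim_protein_db(100, seed = 12)))
  expect_equal(nrow(db1), 100)
  expect_false(any(duplicated(db1$accession)))
  expect_true(all(strsplit(paste(db1$sequence, collapse = ""), "")[[1]] %in%
                    c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                      "N", "P", "Q", "R", "S", "T", "V", "W", "Y")))
  # D-containing count survives a FASTA round trip and a brute re-scan
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(db1, path)
  back <- read_fasta(path)
  expect_identical(back$sequence, db1$sequence)
  expect_identical(sum(grepl("D", back$sequence)),
                   sum(grepl("D", db1$sequence)))
  expect_gte(mean(grepl("D", substr(db1$sequence, 2,
                                    nchar(db1$sequence) - 1))), 0.3)
  expect_error(sim_protein_db(5, length_range = c(500, 50)), "length_range")
  expect_error(sim_protein_db(5, length_range = c(5, 10)), "length_range")
})

test_that("cleavage PSM generator plants exact kinetics and a forced decoy split", {
  db <- sim_protein_db(40, seed = 21)
  sim <- sim_cleavage_psms(db, n_psms = 1000, n_sites = 100, noise_sd = 0,
                           decoy_fraction = 0.5, seed = 22)
  expect_equal(sum(sim$psms$decoy), 500)
  arch <- cleavage_archetypes()
  tg <- sim$psms[sim$psms$decoy == 0, ]
  rep_m <- as.matrix(tg[, paste0("reporter_", 126:131)])
  z <- (rep_m - rowMeans(rep_m)) / apply(rep_m, 1, sd)
  planted <- arch[sim$truth$archetype[match(tg$peptide, sim$truth$peptide)], ]
  expect_lt(max(abs(z - planted)), 1e-9)
  # every target peptide ends in D and is a valid digest product
  expect_true(all(grepl("D$", tg$peptide)))
  prot <- db$sequence[match(sim$truth$accession, db$accession)]
  valid <- mapply(is_valid_digest, sim$truth$peptide, prot)
  expect_true(all(valid))
  # target and decoy score features are separable distributions
  dc <- sim$psms[sim$psms$decoy == 1, ]
  expect_lt(wilcox.test(tg$score, dc$score)$p.value, 0.01)
  expect_lt(wilcox.test(tg$delta_score, dc$delta_score)$p.value, 0.01)
  # a D-free database cannot yield cleavage peptides
  no_d <- tibble::tibble(accession = "X1",
                         sequence = paste(rep("AK", 30), collapse = ""))
  expect_error(sim_cleavage_psms(no_d, n_psms = 10, n_sites = 2),
               "Asp-terminal")
})

test_that("count generator honours null, planted and dispersion settings", {
  genes <- sprintf("G%03d", 1:300)
  d <- study_design()
  null_sim <- sim_counts(genes, d, dispersion = 0, target_up_fc = 1,
                         seed = 31)
  m <- null_sim$counts
  arm <- null_sim$samples$treatment
  t72 <- null_sim$samples$time_h == 72
  mu1 <- rowMeans(m[, arm == "tm" & t72])
  mu2 <- rowMeans(m[, arm == "tm_zvad" & t72])
  # equal means across arms up to Poisson error (3 sigma on the difference)
  pois_se <- sqrt((mu1 + mu2) / 3)
  expect_gt(mean(abs(mu1 - mu2) <= 3 * pmax(pois_se, 1)), 0.98)

  genes_big <- sprintf("G%04d", 1:2000)
  up <- sample(genes_big, 60)
  planted <- sim_counts(genes_big, d, up_genes = up,
                        target_up_fc = 4, seed = 32)
  pm <- planted$counts
  parm <- planted$samples$treatment
  pt72 <- planted$samples$time_h == 72
  sel <- planted$truth$planted_up
  ratio <- rowMeans(pm[sel, parm == "tm_zvad" & pt72]) /
    pmax(rowMeans(pm[sel, parm == "tm" & pt72]), 0.5)
  expect_gt(median(ratio), 3)
  expect_lt(median(ratio), 5)
  expect_error(sim_counts(genes, d, dispersion = -0.1), "dispersion")
})

test_that("non-planted (TF-like) genes stay below 2-fold in nearly all seeds", {
  genes <- sprintf("G%03d", 1:50)
  d <- study_design()
  ok <- vapply(1:100, function(s) {
    sim <- sim_counts(genes, d, dispersion = 0.05, seed = 1000 + s,
                      baseline_log_mean = log(300))
    m <- sim$counts
    t72 <- sim$samples$time_h == 72
    fc <- rowMeans(m[, sim$samples$treatment == "tm_zvad" & t72]) /
      pmax(rowMeans(m[, sim$samples$treatment == "tm" & t72]), 0.5)
    g <- 1  # the gene a TF would occupy
    fc[g] < 2 && fc[g] > 0.5
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("GMT round trip and TF set construction are consistent", {
  universe <- sprintf("G%04d", 1:2000)
  ts <- sim_tf_gene_sets(universe, n_sets = 20, n_dual = 3,
                         genes_per_set = 10, seed = 41)
  expect_length(ts$sets, 20)
  expect_true(all(lengths(ts$sets) == 10))
  # TF genes never sit inside their own (or any) target set
  expect_false(any(ts$tf_map$tf_gene %in% unlist(ts$sets)))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(ts$sets, path)
  back <- read_gmt(path)
  expect_identical(back, ts$sets)
  expect_error(sim_tf_gene_sets(universe[1:10], n_sets = 20), "universe")
})
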