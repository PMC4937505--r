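test_that("row standardization matches the z-score definition and is idempotent", {
  m <- matrix(as.numeric(1:6), 1)
  z <- standardize_trajectories(m)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  set.seed(81)
  r <- matrix(rnorm(60, 5, 3), 10)
  zs <- standardize_trajectories(r)
  ref <- t(apply(r, 1, function(x) (x - mean(x)) / sd(x)))
  expect_equal(zs, ref)
  expect_equal(standardize_trajectories(zs), zs, tolerance = 1e-12)
  # tibble in, tibble out; constant rows dropped with a warning
  df <- tibble::tibble(feature_id = c("a", "b"),
                       h0 = c(1, 2), h4 = c(2, 2), h8 = c(3, 2),
                       h24 = c(4, 2), h48 = c(5, 2), h72 = c(6, 2))
  expect_warning(out <- standardize_trajectories(df), "constant")
  expect_equal(nrow(out), 1)
  expect_s3_class(out, "tbl_df")
})

test_that("fuzzy c-means obeys membership, symmetry and limit conventions", {
  # two tight groups plus one point exactly halfway between them
  a <- matrix(rep(c(-2, 0, 0, 0, 0, 2), each = 5), 5)
  b <- -a
  mid <- matrix(0, 1, 6)
  x <- rbind(a, b, mid)
  fit <- fuzzy_cmeans(x, 2, seed = 1, n_starts = 5)
  expect_equal(unname(rowSums(fit$membership)), rep(1, 11), tolerance = 1e-9)
  expect_true(all(fit$membership >= 0 & fit$membership <= 1))
  expect_equal(unname(fit$membership[11, ]), c(0.5, 0.5), tolerance = 1e-4)
  # a point coinciding with a center takes membership 1 (d = 0 limit):
  # duplicated points force both centers onto the data point exactly
  dup <- fuzzy_cmeans(matrix(1, 2, 6), 2, seed = 2, n_starts = 1)
  expect_equal(unname(dup$membership), rbind(c(1, 0), c(1, 0)))
  expect_equal(dup$objective, 0)
  # objective non-increasing at every iteration
  expect_true(all(diff(fit$objective_trace) <=
                    1e-10 * (1 + fit$objective_trace[-1])))
  expect_error(fuzzy_cmeans(x, 1), "centers")
  expect_error(fuzzy_cmeans(x[1:3, ], 4), "more clusters")
  expect_error(fuzzy_cmeans(x, 2, m = 1), "fuzzifier")
})

test_that("fuzzy c-means reaches the dense-restart reference optimum", {
  set.seed(82)
  x <- matrix(rnorm(20 * 6), 20)
  fit <- fuzzy_cmeans(x, 3, seed = 3, n_starts = 10)
  ref <- oracle_fcm_optimum(x, 3, 1.5, restarts = 30)
  expect_lt(fit$objective, ref + 1e-6)
  # our own objective value is internally consistent
  expect_equal(fit$objective,
               oracle_fcm_objective(x, fit$centers, fit$membership, 1.5),
               tolerance = 1e-8)
})

test_that("assignments break ties deterministically and ignore relabeling", {
  u <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.8))
  lab <- assign_clusters(u)
  expect_equal(lab$cluster, c(1, 1, 2))
  expect_equal(lab$membership, c(0.9, 0.5, 0.8))
  # permuting cluster columns leaves the co-membership partition unchanged
  perm <- u[, c(2, 1)]
  co <- function(l) outer(l, l, "==")
  expect_equal(co(assign_clusters(u)$cluster)[-2, -2],
               co(assign_clusters(perm)$cluster)[-2, -2])
})

test_that("fixed seeds reproduce fits and tidiers expose the results", {
  tr <- sim_trajectories(80, noise_sd = 0.2, seed = 83)
  f1 <- fuzzy_cmeans(tr, 5, seed = 9)
  f2 <- fuzzy_cmeans(tr, 5, seed = 9)
  expect_identical(f1$membership, f2$membership)
  td <- tidy(f1)
  expect_identical(td$feature, tr$feature_id)
  gl <- glance(f1)
  expect_equal(gl$n_clusters, 5)
  expect_equal(gl$objective, f1$objective)
  ct <- cluster_table(f1)
  expect_true(all(c("feature", "cluster", "membership", "h0", "h72") %in%
                    names(ct)))
})

test_that("three-layer overlay joins, restricts and counts unmapped features", {
  mk_layer <- function(ids, cluster) {
    m <- matrix(seq_len(length(ids) * 6), length(ids))
    colnames(m) <- paste0("h", c(0, 4, 8, 24, 48, 72))
    dplyr::bind_cols(tibble::tibble(feature = ids, cluster = cluster,
                                    membership = 0.9),
                     tibble::as_tibble(m))
  }
  csp <- mk_layer(c("pepA", "pepB", "pepC"), c(1, 2, 1))
  gpp <- mk_layer(c("prot1", "prot2"), c(5, 2))
  rna <- mk_layer(c("g1", "g2"), c(3, 4))
  map <- tibble::tibble(peptide = c("pepA", "pepB"),
                        protein = c("prot1", "prot2"),
                        gene = c("g1", "g2"))
  ov <- suppressMessages(overlay_layers(csp, gpp, rna, map))
  expect_equal(nrow(ov), 3)
  row <- ov[ov$peptide == "pepA", ]
  expect_equal(row$protein_cluster, 5)
  expect_equal(row$transcript_cluster, 3)
  expect_true(all(c("cleavage_h0", "protein_h72", "transcript_h24") %in%
                    names(ov)))
  expect_equal(attr(ov, "n_unmapped"), 1)  # pepC has no mapping
  # restriction to designated protein clusters drops mapped outsiders only
  ov5 <- suppressMessages(overlay_layers(csp, gpp, rna, map,
                                         restrict_gpp = 5))
  expect_setequal(ov5$peptide, c("pepA", "pepC"))
  # row count equals a brute-force join on a random mapping
  set.seed(84)
  big_map <- tibble::tibble(
    peptide = paste0("pep", 1:30),
    protein = sample(c(paste0("prot", 1:4), NA), 30, replace = TRUE),
    gene = sample(c("g1", "g2"), 30, replace = TRUE))
  csp_big <- mk_layer(paste0("pep", 1:30), rep(1, 30))
  ov_big <- suppressMessages(
    overlay_layers(csp_big, mk_layer(paste0("prot", 1:4), 1:4), rna,
                   big_map))
  expect_equal(nrow(ov_big), 30)
  expect_error(
    overlay_layers(csp, gpp, rna,
                   dplyr::bind_rows(map, map[1, ])),
    "at most one")
})
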