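test_that("digest validation follows the protease + caspase rule", {
  # tryptic boundary after K2, C-terminal D, 2 internal missed sites (D, K)
  v <- validate_digest("TDAGKLD", "MKTDAGKLD")
  expect_true(v$valid)
  expect_equal(v$end, 9)
  # no C-terminal aspartate
  expect_false(is_valid_digest("TDAGKLG", "MKTDAGKLGA"))
  # five internal uncut K/R/D sites exceed the missed-cleavage budget
  pep <- "KAKARADAKAD"
  prot <- paste0("MR", pep, "AA")
  expect_false(is_valid_digest(pep, prot))
  expect_true(is_valid_digest(pep, prot, max_missed = 5))
  # N-terminal boundary must be a cut residue or the protein start
  expect_false(is_valid_digest("AGKLD", "MTTAGKLD"))
  expect_true(is_valid_digest("MTTAGKLD", "MTTAGKLD"))
  # chymotryptic boundary
  expect_true(is_valid_digest("TDAGGKLLLD", "MAAAFTDAGGKLLLDRRKSA",
                              protease = "chymotrypsin"))
  expect_false(is_valid_digest("TDAGGKLLLD", "MAAAFTDAGGKLLLDRRKSA",
                               protease = "trypsin"))
  expect_error(validate_digest("WWWWW", "MKTDAGKLD"), "not found")
})

test_that("site mapping collapses supporters, flags ambiguity and unions digests", {
  db <- toy_db()
  # tryptic and chymotryptic peptides ending at the same P1 aspartate (D11)
  sites_p1 <- map_sites(
    tibble::tibble(peptide = c("AFTDAGKLD", "TDAGKLD"),
                   protease = c("trypsin", "chymotrypsin")),
    db[1, ])
  one <- sites_p1[sites_p1$p1_position == 11, ]
  expect_equal(nrow(one), 1)
  expect_equal(one$n_peptides, 2)
  expect_setequal(strsplit(one$proteases, ";")[[1]],
                  c("chymotrypsin", "trypsin"))
  # peptide present in two homologous proteins -> two sites, flagged shared
  amb <- map_sites("AFTDAGKLD", db)
  expect_equal(nrow(amb), 2)
  expect_setequal(amb$accession, c("P1", "P3"))
  expect_true(all(amb$ambiguous))
  # union over digests equals the set union of per-digest runs
  peps <- tibble::tibble(
    peptide = c("AFTDAGKLD", "TDAGGKLLLD"),
    protease = c("trypsin", "chymotrypsin"))
  both <- map_sites(peps, db)
  t_only <- map_sites(peps[1, ], db)
  c_only <- map_sites(peps[2, ], db)
  expect_setequal(paste(both$accession, both$p1_position),
                  union(paste(t_only$accession, t_only$p1_position),
                        paste(c_only$accession, c_only$p1_position)))
  # idempotence: re-mapping the same peptides changes nothing
  expect_identical(map_sites(peps, db), both)
})

test_that("site mapping recovers every planted coordinate (brute-force check)", {
  db <- sim_protein_db(30, seed = 71)
  sim <- sim_cleavage_psms(db, n_psms = 200, n_sites = 60,
                           decoy_fraction = 0, seed = 72)
  sites <- map_sites(unique(sim$psms$peptide), db)
  planted <- unique(paste(sim$truth$accession, sim$truth$p1_position))
  expect_true(all(planted %in% paste(sites$accession, sites$p1_position)))
  # brute-force: every reported coordinate really is a D preceded by the
  # peptide occurrence
  seqs <- db$sequence[match(sites$accession, db$accession)]
  expect_true(all(substr(seqs, sites$p1_position, sites$p1_position) == "D"))
})

test_that("overlap reports are inclusion-exclusion consistent", {
  sites <- tibble::tibble(accession = c("P1", "P1", "P2"),
                          p1_position = c(4L, 9L, 7L))
  idem <- overlap_known(sites, list(self = sites))
  expect_equal(idem$shared[idem$reference == "self"], 3)
  expect_equal(idem$unique_study[idem$reference == "self"], 0)
  disjoint <- tibble::tibble(accession = "P1", p1_position = 99L)
  d <- overlap_known(sites, list(ref = disjoint))
  expect_equal(d$shared[d$reference == "ref"], 0)
  # planted overlap of k sites
  k_ref <- dplyr::bind_rows(sites[1:2, ],
                            tibble::tibble(accession = "P9",
                                           p1_position = 1L))
  rep <- overlap_known(sites, list(a = k_ref, b = disjoint))
  a <- rep[rep$reference == "a", ]
  expect_equal(a$shared, 2)
  expect_equal(a$shared + a$unique_study, a$n_study)
  expect_equal(a$shared + a$unique_reference, a$n_reference)
  comb <- rep[rep$reference == "combined", ]
  expect_equal(comb$shared, 2)
  expect_equal(comb$n_reference, 4)
  # accession space mismatch warns
  alien <- tibble::tibble(accession = "XX1", p1_position = 5L)
  expect_warning(overlap_known(sites, list(alien = alien)), "accessions")
  # protein-level matching option
  p <- overlap_known(sites, list(ref = disjoint), match = "protein")
  expect_equal(p$shared[p$reference == "ref"], 1)
})

test_that("motif matrices are proper per-position probability tables", {
  db <- sim_protein_db(30, seed = 73)
  sim <- sim_cleavage_psms(db, n_psms = 150, n_sites = 50,
                           decoy_fraction = 0, seed = 74)
  sites <- map_sites(unique(sim$psms$peptide), db)
  m <- motif_matrix(sites)
  counts <- attr(m, "counts")
  expect_equal(dim(m), c(20, 11))
  expect_equal(colSums(m)[counts > 0], rep(1, sum(counts > 0)),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(m["D", "P1"], 1)
  # brute-force tally at one position
  chars <- substr(sites$window, 3, 3)  # P3 column
  chars <- chars[chars != "-"]
  expect_equal(m["A", "P3"], mean(chars == "A"))
  # single site: point masses on every non-padded column
  single <- motif_matrix("AAKLD-GWSTN")
  expect_true(all(apply(single, 2, max)[attr(single, "counts") > 0] == 1))
  expect_equal(attr(single, "counts")[6], 0L, ignore_attr = TRUE)
  # windows padded at the terminus keep probabilities normalised
  padded <- motif_matrix(c("--KLDAGWSTN", "AAKLDAGWSTN"))
  expect_equal(colSums(padded)[1], 1, ignore_attr = TRUE)
  expect_equal(attr(padded, "counts")[1], 1)
})
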