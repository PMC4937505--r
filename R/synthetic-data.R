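#' Simulate a protein sequence database
#'
#' Random protein sequences over the 20 canonical residues, drawn with
#' human-proteome-like amino-acid frequencies. Internal aspartates (D) occur
#' naturally at about 5% of positions, so essentially every sequence offers
#' plantable caspase cleavage sites; a mid-sequence D is forced into any
#' sequence that happens to lack one.
#'
#' @param n_proteins Number of sequences (>= 1).
#' @param length_range Two increasing integers, the residue-count range
#'   (minimum allowed is 20 so that cleavage windows and digest boundaries
#'   fit).
#' @param seed Optional integer seed; a fixed seed reproduces the database
#'   exactly.
#' @return A tibble with `accession`, `sequence` and `length`.
#' @examples
#' db <- sim_protein_db(5, seed = 1)
#' db$accession
#' @export
sim_protein_db <- function(n_proteins, length_range = c(50, 500), seed = NULL) {
  if (length(length_range) != 2 || any(!is.finite(length_range)) ||
      length_range[1] > length_range[2] || length_range[1] < 20) {
    abort("length_range must be two increasing integers >= 20")
  }
  stopifnot(n_proteins >= 1)
  local_seed_if(seed)
  lens <- sample(seq(length_range[1], length_range[2]), n_proteins,
                 replace = TRUE)
  freqs <- aa_frequencies()
  seqs <- vapply(lens, function(L) {
    paste(sample(names(freqs), L, replace = TRUE, prob = freqs),
          collapse = "")
  }, character(1))
  # guarantee an internal D so cleavage sites can always be planted
  no_d <- !grepl("D", substr(seqs, 2, nchar(seqs) - 1))
  if (any(no_d)) {
    seqs[no_d] <- vapply(seqs[no_d], function(s) {
      pos <- max(2L, nchar(s) %/% 2L)
      paste0(substr(s, 1, pos - 1), "D", substr(s, pos + 1, nchar(s)))
    }, character(1), USE.NAMES = FALSE)
  }
  tibble(accession = sprintf("SYN%04d", seq_len(n_proteins)),
         sequence = seqs, length = nchar(seqs))
}

#' Read / write protein FASTA
#'
#' Thin wrappers around Biostrings for the tabular protein-database
#' representation used throughout the package.
#'
#' @param db Tibble with `accession` and `sequence` columns.
#' @param path File path.
#' @return `write_fasta()` returns `path` invisibly; `read_fasta()` returns
#'   a tibble like [sim_protein_db()].
#' @export
write_fasta <- function(db, path) {
  x <- Biostrings::AAStringSet(db$sequence)
  names(x) <- db$accession
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  tibble(accession = sub("\\s.*$", "", names(x)),
         sequence = unname(as.character(x)),
         length = Biostrings::width(x))
}

# Internal: enumerate digest-valid neo-C-terminal Asp peptides in one
# protein: C-terminus at an internal D, N-terminal boundary after a protease
# cut residue (or the protein N-terminus), length and missed-cleavage
# constrained.
candidate_cleavage_peptides <- function(accession, sequence,
                                        protease = "trypsin",
                                        min_len = 6, max_len = 30,
                                        max_missed = 4) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  d_pos <- which(chars == "D")
  d_pos <- d_pos[d_pos > min_len & d_pos < n]
  if (length(d_pos) == 0) return(NULL)
  cut_res <- protease_cut_residues(protease)
  boundary <- c(0L, which(chars %in% cut_res))   # cleavage after these
  out <- lapply(d_pos, function(p1) {
    starts <- boundary[boundary >= p1 - max_len & boundary <= p1 - min_len] + 1L
    if (length(starts) == 0) return(NULL)
    for (st in rev(starts)) {  # prefer the shortest valid peptide
      pep <- substr(sequence, st, p1)
      nm <- count_missed_cleavages(pep, protease)
      if (nm <= max_missed) {
        return(tibble(accession = accession, peptide = pep,
                      p1_position = p1, start = st, missed_cleavages = nm))
      }
    }
    NULL
  })
  dplyr::bind_rows(out)
}

#' Simulate caspase-cleavage PSM tables with planted kinetics
#'
#' Builds a peptide-spectrum-match table emulating a neo-C-terminal-Asp
#' enrichment experiment: target PSMs are digest-valid peptides ending in D
#' drawn from the database, each carrying TMT6 reporter intensities shaped
#' by one of five planted kinetic archetypes with multiplicative lognormal
#' noise; decoy PSMs are sequence-reversed peptides (C-terminal residue
#' kept) with score features drawn from a lower-scoring distribution.
#'
#' The decoy count is a deterministic split: `round(n_psms * decoy_fraction)`.
#'
#' @param db Protein database tibble ([sim_protein_db()]).
#' @param design [study_design()].
#' @param n_psms Total PSM rows (targets + decoys).
#' @param n_sites Number of distinct planted cleavage sites; target PSMs are
#'   distributed round-robin over them so each planted peptide has at least
#'   one supporting PSM.
#' @param archetypes Standardized archetype matrix ([cleavage_archetypes()]).
#' @param noise_sd SD of the lognormal (log-scale) reporter noise; 0 gives
#'   trajectories that standardize exactly to their archetype.
#' @param decoy_fraction Fraction of rows that are decoys, in `[0, 1)`.
#' @param base_intensity Median per-channel reporter intensity scale.
#' @param protease Digest rule used to construct target peptides.
#' @param seed Optional integer seed.
#' @return A list with `psms` (one row per PSM; columns `spectrum_id`,
#'   `peptide`, `proteins`, `decoy`, `score`, `delta_score`, `ppm_error`,
#'   `missed_cleavages`, `charge`, `reporter_126 ... reporter_131`) and
#'   `truth` (one row per target peptide: accession, P1 position, planted
#'   archetype).
#' @export
sim_cleavage_psms <- function(db, design = study_design(), n_psms = 600,
                              n_sites = 150,
                              archetypes = cleavage_archetypes(),
                              noise_sd = 0.2, decoy_fraction = 0.5,
                              base_intensity = 2e4, protease = "trypsin",
                              seed = NULL) {
  stopifnot(decoy_fraction >= 0, decoy_fraction < 1, noise_sd >= 0)
  local_seed_if(seed)
  cand <- dplyr::bind_rows(
    purrr::map2(db$accession, db$sequence, candidate_cleavage_peptides,
                protease = protease)
  )
  if (is.null(cand) || nrow(cand) == 0) {
    abort("database contains no digest-valid Asp-terminal peptide")
  }
  cand <- dplyr::distinct(cand, .data$peptide, .keep_all = TRUE)
  if (nrow(cand) < n_sites) {
    warn(sprintf("only %d candidate sites available (requested %d)",
                 nrow(cand), n_sites))
    n_sites <- nrow(cand)
  }
  sites <- cand[sample.int(nrow(cand), n_sites), ]
  sites$archetype <- rownames(archetypes)[
    rep_len(seq_len(nrow(archetypes)), n_sites)[sample.int(n_sites)]]

  n_decoy <- round(n_psms * decoy_fraction)
  n_target <- n_psms - n_decoy
  if (n_target < n_sites) {
    abort("n_psms too small for the requested number of sites")
  }
  idx <- rep_len(seq_len(n_sites), n_target)       # round-robin support
  tpl <- archetypes[sites$archetype[idx], , drop = FALSE]
  # positive template: affine shift of the standardized archetype, so
  # standardization of the generated intensities recovers it exactly
  pos_tpl <- tpl - apply(tpl, 1, min) + 0.25
  scale <- base_intensity * rlnorm(n_target, 0, 0.5)
  noise <- matrix(exp(rnorm(n_target * 6, -noise_sd^2 / 2, noise_sd)),
                  n_target)
  rep_t <- pos_tpl * scale * noise
  colnames(rep_t) <- reporter_cols()

  targets <- tibble(
    peptide = sites$peptide[idx],
    proteins = sites$accession[idx],
    decoy = 0L,
    score = rnorm(n_target, 60, 12),
    delta_score = rnorm(n_target, 25, 8),
    ppm_error = rnorm(n_target, 0, 3),
    missed_cleavages = sites$missed_cleavages[idx],
    charge = sample(2:4, n_target, replace = TRUE, prob = c(.5, .35, .15))
  )
  targets <- dplyr::bind_cols(targets, as_tibble(rep_t))

  decoys <- NULL
  if (n_decoy > 0) {
    src <- sites[rep_len(seq_len(n_sites), n_decoy), ]
    dpep <- vapply(src$peptide, function(p) {
      n <- nchar(p)
      paste0(paste(rev(strsplit(substr(p, 1, n - 1), "")[[1]]),
                   collapse = ""), substr(p, n, n))
    }, character(1), USE.NAMES = FALSE)
    rep_d <- matrix(rlnorm(n_decoy * 6, log(base_intensity / 2), 0.6),
                    n_decoy)
    colnames(rep_d) <- reporter_cols()
    decoys <- tibble(
      peptide = dpep,
      proteins = paste0("rev_", src$accession),
      decoy = 1L,
      score = rnorm(n_decoy, 35, 10),
      delta_score = rnorm(n_decoy, 8, 5),
      ppm_error = rnorm(n_decoy, 0, 8),
      missed_cleavages = sample(0:4, n_decoy, replace = TRUE),
      charge = sample(2:4, n_decoy, replace = TRUE)
    )
    decoys <- dplyr::bind_cols(decoys, as_tibble(rep_d))
  }

  psms <- dplyr::bind_rows(targets, decoys)
  psms <- psms[sample.int(nrow(psms)), ]
  psms <- dplyr::bind_cols(
    tibble(spectrum_id = sprintf("scan%06d", seq_len(nrow(psms)))), psms)
  truth <- tibble(peptide = sites$peptide, accession = sites$accession,
                  p1_position = sites$p1_position,
                  archetype = sites$archetype)
  list(psms = psms, truth = truth)
}

#' Simulate reporter-region peak lists
#'
#' Emits, per spectrum, six planted reporter peaks jittered within the
#' quantification tolerance around the theoretical TMT6 reporter m/z values,
#' plus distractor peaks guaranteed to fall outside every tolerance window.
#' The planted intensities are the ground truth that reporter extraction
#' must recover exactly.
#'
#' @param n_spectra Number of spectra.
#' @param planted Optional matrix (`n_spectra` x 6) of planted intensities;
#'   drawn lognormal if omitted.
#' @param n_distractors Distractor peaks per spectrum.
#' @param jitter_ppm Max |mass error| of planted peaks, must be below
#'   `tol_ppm`.
#' @param tol_ppm Quantification tolerance the distractors must stay clear of.
#' @param seed Optional integer seed.
#' @return A list with `peaks` (tibble `spectrum_id`, `mz`, `intensity`) and
#'   `truth` (tibble `spectrum_id` + `reporter_126 ... reporter_131`).
#' @export
sim_reporter_spectra <- function(n_spectra, planted = NULL,
                                 n_distractors = 10, jitter_ppm = 15,
                                 tol_ppm = 20, seed = NULL) {
  stopifnot(jitter_ppm < tol_ppm)
  local_seed_if(seed)
  theo <- tmt6_reporter_mz()
  ids <- sprintf("spec%06d", seq_len(n_spectra))
  if (is.null(planted)) {
    planted <- matrix(rlnorm(n_spectra * 6, log(5e3), 0.8), n_spectra)
  }
  stopifnot(nrow(planted) == n_spectra, ncol(planted) == 6)
  jit <- matrix(runif(n_spectra * 6, -jitter_ppm, jitter_ppm), n_spectra)
  mz_planted <- matrix(theo, n_spectra, 6, byrow = TRUE) * (1 + jit * 1e-6)
  # distractors: uniform over the reporter region, rejected from a widened
  # window around every theoretical value
  n_d <- n_spectra * n_distractors
  mz_d <- numeric(0)
  while (length(mz_d) < n_d) {
    prop <- runif(2 * n_d, 125.5, 132)
    ppm_min <- vapply(prop, function(x) min(abs(x - theo) / theo) * 1e6,
                      numeric(1))
    mz_d <- c(mz_d, prop[ppm_min > 1.5 * tol_ppm])
  }
  mz_d <- mz_d[seq_len(n_d)]
  peaks <- dplyr::bind_rows(
    tibble(spectrum_id = rep(ids, 6),
           mz = as.numeric(mz_planted),
           intensity = as.numeric(planted)),
    tibble(spectrum_id = rep(ids, n_distractors),
           mz = mz_d,
           intensity = rlnorm(n_d, log(8e3), 1))
  )
  peaks <- dplyr::arrange(peaks, .data$spectrum_id, .data$mz)
  colnames(planted) <- reporter_cols()
  truth <- as_tibble(planted)
  truth <- dplyr::bind_cols(tibble(spectrum_id = ids), truth)
  list(peaks = peaks, truth = truth)
}

#' Simulate protein-level trajectories for global protein profiling
#'
#' Assigns each accession to one of the proteome trajectory archetypes
#' (including the two down-regulated classes) and emits a standardized noisy
#' trajectory per protein. A named `class_map` can pin chosen accessions to
#' chosen archetypes, which the end-to-end pipeline uses to keep protein
#' behaviour consistent with planted regulatory modes.
#'
#' @param accessions Character vector of protein ids.
#' @param archetypes Standardized archetypes ([protein_archetypes()]).
#' @param noise_sd Additive noise SD on the standardized scale.
#' @param class_map Optional named character vector accession -> archetype.
#' @param seed Optional integer seed.
#' @return A list with `trajectories` (tibble `accession`, time columns) and
#'   `truth` (tibble `accession`, `class`).
#' @export
sim_protein_profiles <- function(accessions,
                                 archetypes = protein_archetypes(),
                                 noise_sd = 0.3, class_map = NULL,
                                 seed = NULL) {
  local_seed_if(seed)
  n <- length(accessions)
  lab <- rownames(archetypes)[sample.int(nrow(archetypes), n, replace = TRUE)]
  names(lab) <- accessions
  if (!is.null(class_map)) {
    bad <- setdiff(class_map, rownames(archetypes))
    if (length(bad) > 0) abort("unknown archetype in class_map")
    lab[names(class_map)] <- class_map
  }
  x <- archetypes[lab, , drop = FALSE] +
    matrix(rnorm(n * ncol(archetypes), sd = noise_sd), n)
  x <- (x - rowMeans(x)) / apply(x, 1, sd)
  traj <- as_tibble(x)
  colnames(traj) <- colnames(archetypes)
  list(trajectories = dplyr::bind_cols(tibble(accession = accessions), traj),
       truth = tibble(accession = accessions, class = unname(lab)))
}

#' Simulate an RNA-seq count matrix with planted effects
#'
#' Negative-binomial counts for a stress +/- caspase-inhibitor design with
#' replicated samples per condition. Optional planted structure: genes in
#' `up_genes` are up-regulated by `target_up_fc` in the inhibitor arm at
#' times `planted_time_h` and later (the caspase-dependent transcriptional
#' signature); a gene x time `trajectory` matrix of log2 profiles shapes the
#' shared time course of both arms (used to plant transcript kinetics for
#' regulatory-mode truth).
#'
#' @param genes Character vector of gene ids.
#' @param design [study_design()]; uses `rna_time_points_h`, `treatments`,
#'   `rna_replicates`. Pass `treatments = "tm"` inside the design (or a
#'   one-arm design) for a stress-only time course.
#' @param up_genes Genes planted up in the inhibitor arm.
#' @param stable_genes Genes whose expression must stay flat between arms
#'   (transcription-factor own genes): their baseline mean is floored at the
#'   typical expression level so replicate noise cannot push their realized
#'   fold change past the flatness ceiling.
#' @param target_up_fc Linear fold change of planted genes (inhibitor vs
#'   stress arm) at the planted times.
#' @param planted_time_h Earliest hour at which the planted effect is on.
#' @param trajectory Optional matrix (genes x time points, log2 scale)
#'   giving each gene's shared time profile.
#' @param dispersion NB dispersion (1/size); `0` gives Poisson counts;
#'   negative values are an error.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of
#'   baseline per-gene mean counts.
#' @param length_range Range of simulated transcript lengths (bp).
#' @param time_points_h Time points to simulate (defaults to the design's
#'   RNA time points).
#' @param treatments Treatment arms to simulate (defaults to the design's).
#' @param seed Optional integer seed.
#' @return A list with `counts` (integer matrix genes x samples),
#'   `gene_lengths` (tibble), `samples` (tibble `sample`, `treatment`,
#'   `time_h`, `replicate`) and `truth` (tibble `gene`, `planted_up`,
#'   `expected_fc`).
#' @export
sim_counts <- function(genes, design = study_design(), up_genes = character(),
                       stable_genes = character(),
                       target_up_fc = 4, planted_time_h = 72,
                       trajectory = NULL, dispersion = 0.05,
                       baseline_log_mean = log(200), baseline_log_sd = 1.5,
                       length_range = c(500, 5000),
                       time_points_h = design$rna_time_points_h,
                       treatments = design$treatments, seed = NULL) {
  if (dispersion < 0) abort("dispersion must be >= 0")
  stopifnot(target_up_fc > 0)
  local_seed_if(seed)
  n_genes <- length(genes)
  reps <- design$rna_replicates
  samples <- tidyr::expand_grid(treatment = treatments,
                                time_h = time_points_h,
                                replicate = seq_len(reps))
  samples$sample <- sprintf("%s_t%02d_r%d", samples$treatment,
                            samples$time_h, samples$replicate)
  base_mu <- rlnorm(n_genes, baseline_log_mean, baseline_log_sd)
  base_mu[genes %in% stable_genes] <-
    pmax(base_mu[genes %in% stable_genes], exp(baseline_log_mean))
  if (!is.null(trajectory)) {
    stopifnot(nrow(trajectory) == n_genes,
              ncol(trajectory) == length(time_points_h))
  }
  planted <- genes %in% up_genes
  inhibitor_arm <- if (length(treatments) > 1) treatments[2] else NA_character_
  mu <- matrix(base_mu, n_genes, nrow(samples))
  for (j in seq_len(nrow(samples))) {
    t_idx <- match(samples$time_h[j], time_points_h)
    if (!is.null(trajectory)) mu[, j] <- mu[, j] * 2^trajectory[, t_idx]
    if (!is.na(inhibitor_arm) && samples$treatment[j] == inhibitor_arm &&
        samples$time_h[j] >= planted_time_h) {
      mu[planted, j] <- mu[planted, j] * target_up_fc
    }
  }
  counts <- if (dispersion == 0) {
    matrix(rpois(length(mu), mu), n_genes)
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion), n_genes)
  }
  dimnames(counts) <- list(genes, samples$sample)
  list(
    counts = counts,
    gene_lengths = tibble(
      gene = genes,
      length = sample(seq(length_range[1], length_range[2]), n_genes,
                      replace = TRUE)),
    samples = samples[, c("sample", "treatment", "time_h", "replicate")],
    truth = tibble(gene = genes, planted_up = planted,
                   expected_fc = ifelse(planted, target_up_fc, 1))
  )
}

#' Simulate transcription-factor target gene sets
#'
#' Builds a named collection of disjointly-sampled target gene sets with a
#' TF -> set mapping. A chosen number of sets are flagged "dual-regulated":
#' their member genes are the ones a caller should plant as up-regulated
#' under caspase inhibition, while the TF's own transcript stays flat.
#'
#' @param universe Character vector of all gene ids.
#' @param n_sets Number of target sets (one TF each).
#' @param n_dual How many sets are planted dual-regulated.
#' @param genes_per_set Target genes per set.
#' @param seed Optional integer seed.
#' @return A list with `sets` (named list of gene vectors), `tf_map` (tibble
#'   `tf_gene`, `set`), and `truth` (tibble `set`, `tf_gene`, `dual`).
#' @export
sim_tf_gene_sets <- function(universe, n_sets = 50, n_dual = 5,
                             genes_per_set = 30, seed = NULL) {
  stopifnot(n_dual <= n_sets)
  need <- n_sets * (genes_per_set + 1)
  if (length(universe) < need) {
    abort(sprintf("universe too small: need >= %d genes", need))
  }
  local_seed_if(seed)
  picked <- sample(universe, need)
  tf_genes <- picked[seq_len(n_sets)]
  member <- matrix(picked[-seq_len(n_sets)], nrow = n_sets, byrow = TRUE)
  set_names <- sprintf("TF%02d_TARGETS", seq_len(n_sets))
  sets <- lapply(seq_len(n_sets), function(i) member[i, ])
  names(sets) <- set_names
  dual <- c(rep(TRUE, n_dual), rep(FALSE, n_sets - n_dual))
  list(sets = sets,
       tf_map = tibble(tf_gene = tf_genes, set = set_names),
       truth = tibble(set = set_names, tf_gene = tf_genes, dual = dual))
}

#' Read / write GMT gene-set files
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @param description Description field written per set.
#' @return `read_gmt()` returns a named list of gene-id vectors.
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
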