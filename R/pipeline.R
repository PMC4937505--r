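#' Pipeline configuration
#'
#' Builds the nested run configuration, starting from the package defaults
#' and merging any overrides given as named nested lists. Unknown keys are
#' rejected (schema validation), so typos fail loudly before a run starts.
#' All randomness in a run is funnelled through the single root `seed`.
#'
#' @param ... Named overrides, e.g. `synthetic = list(n_genes = 1000)`.
#' @param mode `"synthetic"` (generate all inputs) or `"user"` (read the
#'   inputs named under `paths`).
#' @param seed Root seed of the run.
#' @return A validated nested list of class `casptrace_config`.
#' @examples
#' cfg <- pipeline_config(synthetic = list(n_genes = 500))
#' cfg$synthetic$n_genes
#' @export
pipeline_config <- function(..., mode = c("synthetic", "user"), seed = 1) {
  mode <- match.arg(mode)
  cfg <- default_config()
  cfg$mode <- mode
  cfg$seed <- as.integer(seed)
  cfg <- merge_config(cfg, list(...), path = "")
  validate_config(cfg)
  cfg
}

# Full default configuration; the single source of the config schema.
default_config <- function() {
  list(
    mode = "synthetic",
    seed = 1L,
    design = list(time_points_h = c(0, 4, 8, 24, 48, 72),
                  rna_time_points_h = c(0, 8, 24, 72),
                  rna_replicates = 3,
                  treatments = c("tm", "tm_zvad")),
    synthetic = list(n_proteins = 300, length_range = c(60, 400),
                     n_psms = 1200, n_sites = 150, decoy_fraction = 0.4,
                     noise_sd = 0.2, gpp_noise_sd = 0.3,
                     rna_trend_amplitude = 0.8,
                     n_genes = 2000, dispersion = 0.05,
                     n_sets = 50, n_dual_tfs = 5, genes_per_set = 30,
                     target_up_fc = 4),
    quantify = list(min_total_intensity = 2000, tol_ppm = 20),
    fdr = list(psm_level = 0.05, protein_level = 0.02,
               estimator = "decoy-target-ratio",
               features = c("score", "delta_score", "ppm_error",
                            "missed_cleavages", "charge")),
    cleavage = list(protease = "trypsin", max_missed = 4),
    clustering = list(csp_c = 5, gpp_c = 6, rna_c = 9, m = 1.5,
                      tol = 1e-9, max_iter = 1000, n_starts = 10),
    overlay = list(restrict_to_down_gpp = TRUE),
    classify = list(trend_cut = 0.5, r_cut = 0.5),
    de = list(p_cut = 0.05, fc_cut = 2, contrast_time_h = 72),
    enrichment = list(inter_gene_cor = 0.01, min_size = 5,
                      p_cut = 0.05, fc_flat = 2),
    sample_clustering = list(top_n = 500, vst = "log"),
    paths = list(psms = NULL, fasta = NULL, counts = NULL,
                 gene_lengths = NULL, samples = NULL,
                 gpp_trajectories = NULL, gene_sets = NULL,
                 tf_map = NULL, known_sites = NULL)
  )
}

# Recursive merge of overrides into defaults, rejecting unknown keys.
merge_config <- function(base, overrides, path) {
  if (length(overrides) == 0) return(base)
  nms <- names(overrides)
  if (is.null(nms) || any(nms == "")) {
    abort(sprintf("config overrides under '%s' must be named", path))
  }
  for (nm in nms) {
    full <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(base)) {
      abort(sprintf("unknown config key: %s", full))
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(overrides[[nm]])) {
        abort(sprintf("config key %s must be a named list", full))
      }
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]], full)
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' @rdname pipeline_config
#' @param config A configuration list to validate.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  check <- function(ref_node, node, path) {
    unknown <- setdiff(names(node), names(ref_node))
    if (length(unknown) > 0) {
      abort(sprintf("unknown config key: %s",
                    paste0(path, unknown[1])))
    }
    for (nm in names(node)) {
      if (is.list(ref_node[[nm]]) && !is.null(names(ref_node[[nm]]))) {
        check(ref_node[[nm]], node[[nm]], paste0(path, nm, "."))
      }
    }
  }
  check(ref, config, "")
  if (!config$mode %in% c("synthetic", "user")) {
    abort("mode must be 'synthetic' or 'user'")
  }
  if (config$mode == "user") {
    required <- c("psms", "fasta", "counts", "gene_lengths", "samples",
                  "gpp_trajectories", "gene_sets", "tf_map")
    for (key in required) {
      p <- config$paths[[key]]
      if (is.null(p)) {
        abort(sprintf("config key paths.%s is required in user mode", key))
      }
      if (!file.exists(p)) {
        abort(sprintf("config key paths.%s: file not found: %s", key, p))
      }
    }
  }
  structure(config, class = "casptrace_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config A configuration list.
#' @param path File path.
#' @return `read_config()` returns a validated configuration.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  validate_config(merge_config(default_config(), yaml::read_yaml(path), ""))
}

# Deterministic per-stage seeds derived from the root seed.
stage_seeds <- function(seed) {
  nm <- c("db", "psm", "modes", "gpp", "rna", "de", "sets",
          "csp_cluster", "gpp_cluster", "rna_cluster", "reference")
  setNames(as.integer((as.numeric(seed) * 101 + seq_along(nm) * 1009) %%
                        .Machine$integer.max), nm)
}

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage %s: %s", name, conditionMessage(e)))
  })
}

write_table <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full multi-omics pipeline
#'
#' Orchestrates every stage end to end: input generation (synthetic mode)
#' or ingestion (user mode), reporter-intensity filtering, discriminant
#' scoring and target-decoy FDR control, peptide rollup, cleavage-site
#' mapping with motif and overlap summaries, trajectory standardization and
#' fuzzy c-means clustering of the three layers, differential expression
#' for the inhibitor-vs-stress contrast, competitive TF-target-set testing
#' and dual-regulation calling, three-layer overlay with regulatory-mode
#' classification, and a recovery report (synthetic mode) scoring every
#' stage against the planted truth. Given a fixed `config$seed` the run is
#' bit-reproducible; tables, a manifest (config hash plus file checksums)
#' and the report are written under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; existing tables overwritten).
#' @return Invisibly, a list with all in-memory stage results, the report
#'   and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab_dir <- file.path(out_dir, "tables")
  dir.create(tab_dir, showWarnings = FALSE)
  seeds <- stage_seeds(config$seed)
  design <- study_design(
    time_points_h = config$design$time_points_h,
    rna_replicates = config$design$rna_replicates,
    treatments = config$design$treatments,
    rna_time_points_h = config$design$rna_time_points_h)

  inputs <- with_stage("generate", {
    if (config$mode == "synthetic") {
      generate_inputs(config, design, seeds)
    } else {
      ingest_inputs(config)
    }
  })
  files <- character(0)
  files["psms"] <- write_table(inputs$psms, tab_dir, "psms")

  ## quantify + confidence -------------------------------------------------
  quant <- with_stage("quantify", {
    filter_min_intensity(inputs$psms, config$quantify$min_total_intensity)
  })
  conf <- with_stage("confidence", {
    scored <- fit_discriminant(quant, features = config$fdr$features)
    psm_fdr <- threshold_at_fdr(scored, config$fdr$psm_level,
                                estimator = config$fdr$estimator)
    prot <- score_proteins(scored[scored$discriminant_score >=
                                    psm_fdr$result$threshold |
                                    scored$decoy == 1, ])
    prot_fdr <- protein_level_fdr(prot, config$fdr$protein_level,
                                  estimator = config$fdr$estimator)
    list(scored = scored, psm_fdr = psm_fdr, prot_fdr = prot_fdr)
  })
  files["fdr_summary"] <- write_table(
    dplyr::bind_rows(psm = conf$psm_fdr$result,
                     protein = conf$prot_fdr$result, .id = "level_type"),
    tab_dir, "fdr_summary")

  peptides <- with_stage("quantify", rollup_peptides(conf$psm_fdr$survivors))
  files["peptides"] <- write_table(peptides, tab_dir, "peptides")

  ## cleavage mapping ------------------------------------------------------
  sites <- with_stage("cleavage_map", {
    map_sites(tibble(peptide = peptides$peptide,
                     protease = config$cleavage$protease),
              inputs$db, max_missed = config$cleavage$max_missed)
  })
  motif <- with_stage("cleavage_map", motif_matrix(sites))
  overlap <- NULL
  if (!is.null(inputs$known_sites)) {
    overlap <- with_stage("cleavage_map", {
      overlap_known(sites, inputs$known_sites)
    })
    files["site_overlap"] <- write_table(overlap, tab_dir, "site_overlap")
  }
  files["cleavage_sites"] <- write_table(sites, tab_dir, "cleavage_sites")
  files["motif_matrix"] <- write_table(
    dplyr::bind_cols(tibble(residue = rownames(motif)),
                     as_tibble(unclass(motif))),
    tab_dir, "motif_matrix")

  ## trajectory clustering -------------------------------------------------
  tcols <- time_cols(design)
  clus <- config$clustering
  csp_traj <- peptides[!peptides$all_zero, ]
  csp_m <- as.matrix(csp_traj[, sub("^reporter_", "rel_", reporter_cols())])
  colnames(csp_m) <- tcols
  rownames(csp_m) <- csp_traj$peptide
  cluster_layer <- function(m, c, seed) {
    fuzzy_cmeans(standardize_trajectories(m), centers = c, m = clus$m,
                 n_starts = clus$n_starts, max_iter = clus$max_iter,
                 tol = clus$tol, seed = seed)
  }
  csp_fit <- with_stage("kinetic_cluster",
                        cluster_layer(csp_m, clus$csp_c,
                                      seeds[["csp_cluster"]]))
  gpp_m <- as.matrix(inputs$gpp_trajectories[, tcols])
  rownames(gpp_m) <- inputs$gpp_trajectories$accession
  gpp_fit <- with_stage("kinetic_cluster",
                        cluster_layer(gpp_m, clus$gpp_c,
                                      seeds[["gpp_cluster"]]))
  rna_m <- with_stage("kinetic_cluster", {
    rk <- rpkm(inputs$rna_counts, inputs$rna_gene_lengths)
    agg <- sapply(design$time_points_h, function(tp) {
      rowMeans(rk[, inputs$rna_samples$time_h == tp, drop = FALSE])
    })
    colnames(agg) <- tcols
    log2(agg + 0.25)
  })
  rna_fit <- with_stage("kinetic_cluster", {
    cluster_layer(rna_m, clus$rna_c, seeds[["rna_cluster"]])
  })
  for (layer in c("csp", "gpp", "rna")) {
    fit <- get(paste0(layer, "_fit"))
    files[paste0(layer, "_clusters")] <- write_table(
      cluster_table(fit), tab_dir, paste0(layer, "_clusters"))
  }

  ## transcriptome ---------------------------------------------------------
  de <- with_stage("transcriptome", {
    fit_de(inputs$de_counts, inputs$de_samples,
           time_h = config$de$contrast_time_h)
  })
  sig <- significant_genes(de, config$de$p_cut, config$de$fc_cut)
  files["differential_expression"] <- write_table(de, tab_dir,
                                                  "differential_expression")
  files["significant_genes"] <- write_table(sig, tab_dir,
                                            "significant_genes")
  tree <- with_stage("transcriptome", {
    sample_cluster(inputs$de_counts, config$sample_clustering$top_n,
                   vst = config$sample_clustering$vst)
  })
  nwk_path <- file.path(tab_dir, "sample_tree.nwk")
  if (requireNamespace("ape", quietly = TRUE)) {
    writeLines(linkage_newick(tree), nwk_path)
    files["sample_tree"] <- nwk_path
  }

  ## enrichment ------------------------------------------------------------
  camera <- with_stage("enrichment", {
    camera_test(setNames(de$t, de$gene), inputs$gene_sets,
                rho = config$enrichment$inter_gene_cor,
                min_size = config$enrichment$min_size)
  })
  tf_calls <- with_stage("enrichment", {
    tf_dual_calls(camera, de, inputs$tf_map,
                  fc_flat = config$enrichment$fc_flat,
                  p_cut = config$enrichment$p_cut)
  })
  files["camera"] <- write_table(camera, tab_dir, "camera")
  files["tf_dual_calls"] <- write_table(tf_calls, tab_dir, "tf_dual_calls")

  ## integrate + classify --------------------------------------------------
  down_gpp <- NULL
  if (isTRUE(config$overlay$restrict_to_down_gpp)) {
    trends <- trend_r(gpp_fit$centers)
    down_gpp <- which(trends < -0.3)
  }
  overlay_all <- with_stage("integrate_classify", {
    overlay_layers(cluster_table(csp_fit), cluster_table(gpp_fit),
                   cluster_table(rna_fit), inputs$id_map,
                   restrict_gpp = NULL)
  })
  overlay_down <- if (!is.null(down_gpp)) {
    overlay_layers(cluster_table(csp_fit), cluster_table(gpp_fit),
                   cluster_table(rna_fit), inputs$id_map,
                   restrict_gpp = down_gpp)
  } else {
    overlay_all
  }
  complete <- !is.na(overlay_all$protein_cluster) &
    !is.na(overlay_all$transcript_cluster)
  calls <- with_stage("integrate_classify", {
    classify_mode(overlay_all[complete, ],
                  trend_cut = config$classify$trend_cut,
                  r_cut = config$classify$r_cut)
  })
  reg <- with_stage("integrate_classify", substrate_regression(calls))
  files["overlay"] <- write_table(strip_attrs(overlay_down), tab_dir,
                                  "overlay")
  files["regulatory_calls"] <- write_table(strip_attrs(calls), tab_dir,
                                           "regulatory_calls")
  files["substrate_regression"] <- write_table(reg, tab_dir,
                                               "substrate_regression")

  ## report ----------------------------------------------------------------
  report <- with_stage("report", {
    build_report(inputs, conf, sites, csp_fit, de, sig, tf_calls, calls, reg,
                 config)
  })
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files["report"] <- file.path(out_dir, "report.json")

  manifest <- list(
    package = "casptrace",
    version = as.character(utils::packageVersion("casptrace")),
    mode = config$mode,
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    tables = lapply(unname(files), function(f) {
      rel <- if (basename(dirname(f)) == "tables") {
        file.path("tables", basename(f))
      } else {
        basename(f)
      }
      list(file = rel, md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(config = config, inputs = inputs, quant = quant,
                 confidence = conf, peptides = peptides, sites = sites,
                 motif = motif, overlap = overlap, csp_fit = csp_fit,
                 gpp_fit = gpp_fit, rna_fit = rna_fit, de = de, sig = sig,
                 sample_tree = tree, camera = camera, tf_calls = tf_calls,
                 overlay = overlay_down, calls = calls, regression = reg,
                 report = report, manifest = manifest))
}

strip_attrs <- function(df) {
  attr(df, "n_unmapped") <- NULL
  attr(df, "counts") <- NULL
  df
}

# Synthetic-mode input generation with coherent cross-layer planted truth.
generate_inputs <- function(config, design, seeds) {
  syn <- config$synthetic
  db <- sim_protein_db(syn$n_proteins, syn$length_range, seed = seeds[["db"]])
  psm_sim <- sim_cleavage_psms(
    db, design, n_psms = syn$n_psms, n_sites = syn$n_sites,
    noise_sd = syn$noise_sd, decoy_fraction = syn$decoy_fraction,
    protease = config$cleavage$protease, seed = seeds[["psm"]])
  genes <- sprintf("G%04d", seq_len(syn$n_genes))
  acc_gene <- setNames(sub("^SYN", "G", db$accession), db$accession)
  id_map <- tibble(peptide = psm_sim$truth$peptide,
                   protein = psm_sim$truth$accession,
                   gene = unname(acc_gene[psm_sim$truth$accession]))
  id_map <- dplyr::distinct(id_map, .data$peptide, .keep_all = TRUE)
  substrate_acc <- unique(psm_sim$truth$accession)
  substrate_genes <- unique(id_map$gene)

  # planted regulatory mode per substrate protein, mirrored consistently in
  # the protein and transcript layers
  withr::with_seed(seeds[["modes"]], {
    modes <- sample(setdiff(regulatory_modes(), "ambiguous"),
                    length(substrate_acc), replace = TRUE)
  })
  names(modes) <- substrate_acc
  prot_class <- dplyr::case_when(
    modes == "co_upregulated" ~ "late_up",
    TRUE ~ "down_steady")
  names(prot_class) <- substrate_acc
  gpp <- sim_protein_profiles(db$accession, noise_sd = syn$gpp_noise_sd,
                              class_map = prot_class, seed = seeds[["gpp"]])

  # shared gene time trajectories (log2): mode templates for substrate
  # genes, gentle random walks elsewhere
  tp6 <- design$time_points_h
  withr::with_seed(seeds[["rna"]], {
    traj6 <- t(replicate(syn$n_genes,
                         cumsum(c(0, rnorm(length(tp6) - 1, 0, 0.25)))))
  })
  rownames(traj6) <- genes
  tmpl <- mode_templates()
  amp <- syn$rna_trend_amplitude
  for (acc in substrate_acc) {
    g <- acc_gene[[acc]]
    if (g %in% genes) {
      traj6[g, ] <- tmpl[[modes[[acc]]]]$transcript * amp
    }
  }
  rna_design <- study_design(time_points_h = tp6,
                             rna_replicates = design$rna_replicates,
                             treatments = design$treatments,
                             rna_time_points_h = design$rna_time_points_h)
  rna_sim <- sim_counts(genes, rna_design, trajectory = traj6,
                        dispersion = syn$dispersion,
                        time_points_h = tp6, treatments = "tm",
                        seed = seeds[["rna"]])

  # TF target sets on the non-substrate universe; dual sets' targets are
  # planted up in the inhibitor arm
  set_sim <- sim_tf_gene_sets(setdiff(genes, substrate_genes),
                              n_sets = syn$n_sets, n_dual = syn$n_dual_tfs,
                              genes_per_set = syn$genes_per_set,
                              seed = seeds[["sets"]])
  dual_sets <- set_sim$truth$set[set_sim$truth$dual]
  up_genes <- unique(unlist(set_sim$sets[dual_sets]))
  tp4 <- design$rna_time_points_h
  traj4 <- traj6[, match(tp4, tp6), drop = FALSE]
  de_sim <- sim_counts(genes, design, up_genes = up_genes,
                       stable_genes = set_sim$tf_map$tf_gene,
                       target_up_fc = syn$target_up_fc,
                       planted_time_h = config$de$contrast_time_h,
                       trajectory = traj4, dispersion = syn$dispersion,
                       time_points_h = tp4,
                       treatments = design$treatments,
                       seed = seeds[["de"]])

  # synthetic stand-in for a known-cleavage-site repository: half the
  # planted sites plus unrelated coordinates
  withr::with_seed(seeds[["reference"]], {
    truth_sites <- dplyr::distinct(psm_sim$truth, .data$accession,
                                   .data$p1_position)
    half <- truth_sites[sample.int(nrow(truth_sites),
                                   nrow(truth_sites) %/% 2), ]
    extra <- tibble(
      accession = sample(db$accession, 40, replace = TRUE),
      p1_position = sample.int(50, 40, replace = TRUE) + 5L)
    known <- list(synthetic_repository = dplyr::bind_rows(half, extra))
  })

  list(db = db, psms = psm_sim$psms, psm_truth = psm_sim$truth,
       id_map = id_map, modes = tibble(accession = substrate_acc,
                                       gene = unname(acc_gene[substrate_acc]),
                                       mode = unname(modes)),
       gpp_trajectories = gpp$trajectories, gpp_truth = gpp$truth,
       rna_counts = rna_sim$counts, rna_gene_lengths_tbl = rna_sim$gene_lengths,
       rna_gene_lengths = setNames(rna_sim$gene_lengths$length,
                                   rna_sim$gene_lengths$gene),
       rna_samples = rna_sim$samples,
       de_counts = de_sim$counts, de_samples = de_sim$samples,
       de_truth = de_sim$truth,
       gene_sets = set_sim$sets, tf_map = set_sim$tf_map,
       tf_truth = set_sim$truth,
       known_sites = known)
}

# User-mode ingestion of the external interfaces (TSV/FASTA/GMT).
ingest_inputs <- function(config) {
  p <- config$paths
  read_tsv_plain <- function(path) {
    as_tibble(utils::read.delim(path, check.names = FALSE))
  }
  psms <- read_tsv_plain(p$psms)
  db <- read_fasta(p$fasta)
  counts_df <- utils::read.delim(p$counts, check.names = FALSE)
  counts <- as.matrix(counts_df[, -1])
  rownames(counts) <- counts_df[[1]]
  lengths_df <- read_tsv_plain(p$gene_lengths)
  samples <- read_tsv_plain(p$samples)
  gpp <- read_tsv_plain(p$gpp_trajectories)
  sets <- read_gmt(p$gene_sets)
  tf_map <- read_tsv_plain(p$tf_map)
  known <- NULL
  if (!is.null(p$known_sites)) {
    known <- list(reference = read_tsv_plain(p$known_sites))
  }
  id_map <- tibble(peptide = psms$peptide[psms$decoy == 0],
                   protein = sub(";.*$", "", psms$proteins[psms$decoy == 0]))
  id_map <- dplyr::distinct(id_map, .data$peptide, .keep_all = TRUE)
  id_map$gene <- id_map$protein
  arms <- unique(samples$treatment)
  list(db = db, psms = psms, psm_truth = NULL, id_map = id_map, modes = NULL,
       gpp_trajectories = gpp, gpp_truth = NULL,
       rna_counts = counts[, samples$treatment == arms[1], drop = FALSE],
       rna_gene_lengths = setNames(lengths_df$length, lengths_df$gene),
       rna_samples = samples[samples$treatment == arms[1], ],
       de_counts = counts, de_samples = samples, de_truth = NULL,
       gene_sets = sets, tf_map = tf_map, tf_truth = NULL,
       known_sites = known)
}

# Planted-truth recovery metrics for the synthetic run report.
build_report <- function(inputs, conf, sites, csp_fit, de, sig, tf_calls,
                         calls, reg, config) {
  rep <- list(
    n_psms_after_filter = nrow(conf$scored),
    psm_fdr = as.list(conf$psm_fdr$result),
    protein_fdr = as.list(conf$prot_fdr$result),
    n_sites = nrow(sites),
    n_significant_genes = nrow(sig),
    substrate_regression = as.list(reg)
  )
  if (!is.null(inputs$psm_truth)) {
    truth <- inputs$psm_truth
    site_key <- paste(sites$accession, sites$p1_position)
    kept_pep <- rownames(csp_fit$membership)
    truth_kept <- truth[truth$peptide %in% kept_pep, ]
    truth_key <- paste(truth_kept$accession, truth_kept$p1_position)
    rep$site_recovery <- mean(truth_key %in% site_key)
    if (requireNamespace("mclust", quietly = TRUE)) {
      lab <- truth$archetype[match(kept_pep, truth$peptide)]
      ok <- !is.na(lab)
      rep$csp_cluster_ari <- mclust::adjustedRandIndex(
        lab[ok], csp_fit$cluster[ok])
    }
    dt <- inputs$de_truth
    de_fc <- sig$gene
    rep$de_sensitivity <- mean(dt$gene[dt$planted_up] %in% de_fc)
    rep$tf_true_calls <- sum(tf_calls$called &
                               tf_calls$set %in%
                               inputs$tf_truth$set[inputs$tf_truth$dual])
    rep$tf_false_calls <- sum(tf_calls$called &
                                !tf_calls$set %in%
                                inputs$tf_truth$set[inputs$tf_truth$dual])
    md <- inputs$modes
    called_modes <- as.character(calls$mode[match(md$gene, calls$gene)])
    ok <- !is.na(called_modes)
    rep$mode_accuracy <- if (any(ok)) {
      mean(called_modes[ok] == md$mode[ok])
    } else NA_real_
    rep$n_modes_evaluated = sum(ok)
  }
  rep
}
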