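#' Competitive gene-set test with inter-gene correlation adjustment
#'
#' For each gene set, compares the mean moderated statistic of in-set genes
#' against the remaining genes with a two-sample t construction whose
#' in-set variance term is inflated by the variance inflation factor
#' `VIF = 1 + (m - 1) * rho` for set size `m` and inter-gene correlation
#' `rho` (the published camera construction; `rho = 0.01` is its default).
#' Setting `rho = 0` gives the naive, correlation-ignoring competitive test.
#' P values are two-sided on `G - 2` degrees of freedom and BH-adjusted
#' across the set collection.
#'
#' @param gene_stats Named numeric vector of per-gene statistics (moderated
#'   t from [moderated_fit()]), or a tibble with `gene` and `t` columns.
#' @param sets Named list of gene-id vectors.
#' @param rho Inter-gene correlation estimate (default 0.01).
#' @param min_size Sets with fewer measured genes are skipped (message).
#' @return Tibble: `set`, `n_genes` (measured members), `vif`, `direction`
#'   (`"up"`/`"down"`), `p_value`, `adj_p`.
#' @export
camera_test <- function(gene_stats, sets, rho = 0.01, min_size = 5) {
  if (is.data.frame(gene_stats)) {
    gene_stats <- setNames(gene_stats$t, gene_stats$gene)
  }
  if (is.null(names(gene_stats))) abort("gene_stats must be named by gene id")
  if (any(!is.finite(gene_stats))) abort("gene statistics must be finite")
  stat <- gene_stats
  g <- length(stat)
  if (g < 3) abort("too few genes for a competitive test")
  mean_all <- mean(stat)
  var_all <- var(stat)
  df_camera <- g - 2L
  rows <- purrr::imap(sets, function(members, nm) {
    idx <- names(stat) %in% members
    m <- sum(idx)
    if (m < min_size) return(NULL)
    if (m >= g) return(NULL)
    vif <- 1 + (m - 1) * rho
    mean_in <- mean(stat[idx])
    delta <- g / (g - m) * (mean_in - mean_all)
    var_pooled <- ((g - 1) * var_all - delta^2 * m * (g - m) / g) / (g - 2)
    tstat <- delta / sqrt(var_pooled * (vif / m + 1 / (g - m)))
    tibble(set = nm, n_genes = m, vif = vif,
           direction = ifelse(delta > 0, "up", "down"),
           p_value = 2 * pt(-abs(tstat), df = df_camera))
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0) {
    inform(sprintf("%d set(s) skipped (fewer than %d measured genes)",
                   skipped, min_size))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(set = character(), n_genes = integer(), vif = numeric(),
                  direction = character(), p_value = numeric(),
                  adj_p = numeric()))
  }
  out$adj_p <- bh_adjust(out$p_value)
  out
}

#' Transcription-factor dual-regulation calls
#'
#' A transcription factor is called dual-regulated when its target gene set
#' is significantly up-regulated under caspase inhibition (set direction up,
#' BH-adjusted set p below `p_cut`) while its own transcript is essentially
#' flat (linear |fold change| below `fc_flat` in either direction). TFs
#' whose own gene moves more than `fc_flat` are reported but excluded from
#' calls (`excluded_high_fc`), mirroring the exclusion of strongly
#' auto-regulated factors in the emulated analysis. TFs absent from the DE
#' table are dropped with a message.
#'
#' @param camera_res [camera_test()] result on the inhibitor-vs-stress
#'   contrast.
#' @param de DE tibble of the same contrast ([moderated_fit()]).
#' @param tf_map Tibble `tf_gene`, `set`.
#' @param fc_flat Own-gene fold-change ceiling (default 2).
#' @param p_cut Set-level adjusted-p threshold (default 0.05).
#' @return Tibble: `tf_gene`, `set`, `own_log_fc`, `own_fold_change`
#'   (max of FC and 1/FC), `direction`, `set_p`, `set_adj_p`,
#'   `excluded_high_fc`, `called`.
#' @export
tf_dual_calls <- function(camera_res, de, tf_map, fc_flat = 2,
                          p_cut = 0.05) {
  joined <- dplyr::inner_join(tf_map, camera_res, by = "set")
  missing_tf <- setdiff(joined$tf_gene, de$gene)
  if (length(missing_tf) > 0) {
    inform(sprintf("%d TF gene(s) absent from the DE table; excluded",
                   length(missing_tf)))
  }
  joined <- dplyr::inner_join(
    joined, de[, c("gene", "log_fc")],
    by = c(tf_gene = "gene"))
  joined$own_log_fc <- joined$log_fc
  joined$own_fold_change <- pmax(2^joined$own_log_fc, 2^-joined$own_log_fc)
  joined$excluded_high_fc <- joined$own_fold_change >= fc_flat
  joined$called <- !joined$excluded_high_fc &
    joined$direction == "up" & joined$adj_p < p_cut
  tibble(tf_gene = joined$tf_gene, set = joined$set,
         own_log_fc = joined$own_log_fc,
         own_fold_change = joined$own_fold_change,
         direction = joined$direction,
         set_p = joined$p_value, set_adj_p = joined$adj_p,
         excluded_high_fc = joined$excluded_high_fc,
         called = joined$called)
}

#' Per-set count of individually significant target genes
#'
#' Transparency companion to the set-level test: how many of a set's genes
#' pass a stringent single-gene filter (defaults mirror the highlight filter
#' used for the volcano displays: adjusted p < 1e-4 and fold change > 2).
#'
#' @param de DE tibble.
#' @param sets Named list of gene sets.
#' @param p_cut,fc_cut Stringent single-gene thresholds.
#' @return Tibble: `set`, `n_measured`, `n_significant`.
#' @export
set_gene_counts <- function(de, sets, p_cut = 1e-4, fc_cut = 2) {
  sig <- significant_genes(de, p_cut = p_cut, fc_cut = fc_cut)$gene
  purrr::imap_dfr(sets, function(members, nm) {
    tibble(set = nm,
           n_measured = sum(de$gene %in% members),
           n_significant = sum(sig %in% members))
  })
}
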