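#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point facet_wrap
#'   labs scale_colour_gradient theme_minimal geom_text geom_hline
#'   geom_vline scale_colour_manual
#' @export
ggplot2::autoplot

# Internal: long format of a trajectory matrix with cluster/membership.
fcm_long <- function(fit) {
  df <- as_tibble(fit$data)
  hours <- as.numeric(sub("^h", "", colnames(fit$data)))
  df$feature <- rownames(fit$data) %||% as.character(seq_len(nrow(fit$data)))
  df$cluster <- fit$cluster
  df$membership <- fit$membership[cbind(seq_len(nrow(fit$membership)),
                                        fit$cluster)]
  out <- tidyr::pivot_longer(df, cols = colnames(fit$data),
                             names_to = "time", values_to = "value")
  out$hours <- hours[match(out$time, colnames(fit$data))]
  out
}

#' Plot a fuzzy c-means fit
#'
#' One panel per cluster; each line is a feature trajectory coloured by its
#' membership in the assigned cluster (darker = closer to the cluster
#' mean), with the cluster center overlaid.
#'
#' @param object A `fuzzy_cmeans` fit.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot fuzzy_cmeans
#' @export
autoplot.fuzzy_cmeans <- function(object, ...) {
  long <- fcm_long(object)
  centers <- as_tibble(object$centers)
  centers$cluster <- seq_len(nrow(object$centers))
  centers <- tidyr::pivot_longer(centers, cols = colnames(object$centers),
                                 names_to = "time", values_to = "value")
  centers$hours <- as.numeric(sub("^h", "", centers$time))
  ggplot(long, aes(x = .data$hours, y = .data$value)) +
    geom_line(aes(group = .data$feature, colour = .data$membership),
              alpha = 0.5) +
    geom_line(data = centers, linewidth = 1.1, colour = "black") +
    facet_wrap(~ cluster) +
    scale_colour_gradient(low = "#ffd9a0", high = "#c0392b") +
    labs(x = "tunicamycin exposure (h)", y = "standardized abundance",
         colour = "membership") +
    theme_minimal()
}

#' Plot a cleavage-site motif as a probability logo
#'
#' Basic residue-probability rendering: at each position the observed
#' residues are stacked with text size proportional to probability.
#'
#' @param object A `motif_matrix`.
#' @param min_prob Residues below this probability are not drawn.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot motif_matrix
#' @export
autoplot.motif_matrix <- function(object, min_prob = 0.02, ...) {
  m <- unclass(object)
  df <- as_tibble(as.table(m), .name_repair = ~ c("residue", "position", "p"))
  df <- df[df$p >= min_prob, ]
  df$position <- factor(df$position, levels = colnames(m))
  df <- df |>
    dplyr::arrange(.data$position, .data$p) |>
    dplyr::group_by(.data$position) |>
    dplyr::mutate(y = cumsum(.data$p) - .data$p / 2) |>
    dplyr::ungroup()
  ggplot(df, aes(x = .data$position, y = .data$y, label = .data$residue)) +
    geom_text(aes(size = .data$p), show.legend = FALSE, fontface = "bold") +
    ggplot2::scale_size_continuous(range = c(2, 10), limits = c(0, 1)) +
    ggplot2::ylim(0, 1) +
    labs(x = NULL, y = "residue probability") +
    theme_minimal()
}

#' Three-layer trajectory plot for one substrate
#'
#' Mirrors the per-gene correlation panels of the emulated study: cleavage
#' product (blue), protein (red) and transcript (green) standardized
#' trajectories on one time axis.
#'
#' @param triads Wide triad table ([overlay_layers()] / [classify_mode()]).
#' @param gene Gene id (or peptide id if genes are absent) selecting the row.
#' @return A ggplot object.
#' @export
plot_triad <- function(triads, gene) {
  id_col <- if ("gene" %in% names(triads)) "gene" else "peptide"
  row <- triads[triads[[id_col]] == gene, ][1, ]
  if (nrow(row) == 0 || is.na(row[[id_col]])) abort("gene not found")
  layers <- triad_layers()
  long <- purrr::map_dfr(layers, function(ly) {
    m <- layer_matrix(row, ly)
    tibble(layer = ly,
           hours = as.numeric(sub(paste0("^", ly, "_h"), "", colnames(m))),
           value = as.numeric(m[1, ]))
  })
  ggplot(long, aes(x = .data$hours, y = .data$value,
                   colour = .data$layer)) +
    geom_line(linewidth = 1) + geom_point() +
    scale_colour_manual(values = c(cleavage = "#2c6fbb",
                                   protein = "#c0392b",
                                   transcript = "#1e8449")) +
    labs(title = gene, x = "tunicamycin exposure (h)",
         y = "standardized abundance") +
    theme_minimal()
}

#' Volcano plot of a differential-expression contrast
#'
#' Log2 fold change against -log10 adjusted p, highlighting genes passing
#' the stringent filter (default adjusted p < 1e-4, fold change > 2) and,
#' optionally, only those inside a chosen gene set.
#'
#' @param de DE tibble ([moderated_fit()]).
#' @param highlight_genes Optional gene ids eligible for highlighting
#'   (e.g. one TF's target set).
#' @param p_cut,fc_cut Highlight thresholds.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, highlight_genes = NULL, p_cut = 1e-4,
                         fc_cut = 2) {
  de$highlight <- de$adj_p < p_cut &
    pmax(de$fold_change, 1 / de$fold_change) > fc_cut
  if (!is.null(highlight_genes)) {
    de$highlight <- de$highlight & de$gene %in% highlight_genes
  }
  ggplot(de, aes(x = .data$log_fc, y = -log10(.data$adj_p))) +
    geom_point(aes(colour = .data$highlight), alpha = 0.6,
               show.legend = FALSE) +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "#c0392b")) +
    geom_hline(yintercept = -log10(p_cut), linetype = "dashed") +
    geom_vline(xintercept = c(-log2(fc_cut), log2(fc_cut)),
               linetype = "dashed") +
    labs(x = "log2 fold change (inhibitor vs stress)",
         y = "-log10 adjusted p") +
    theme_minimal()
}
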