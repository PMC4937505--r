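# Layer prefixes used in overlay/triad tables.
triad_layers <- function() c("cleavage", "protein", "transcript")

# Internal: extract one layer's trajectory matrix from a wide triad table.
layer_matrix <- function(df, layer) {
  cols <- grep(paste0("^", layer, "_h\\d+$"), names(df), value = TRUE)
  if (length(cols) == 0) {
    abort(sprintf("no trajectory columns found for layer '%s'", layer))
  }
  m <- as.matrix(df[, cols])
  storage.mode(m) <- "double"
  m
}

# Internal: rowwise Pearson correlation of two trajectory matrices;
# NA when either row is incomplete or constant.
row_cor <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (anyNA(x) || anyNA(y) || sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
}

#' Pairwise Pearson correlations among the three omics layers
#'
#' Adds, per triad row, the Pearson correlations over the six time points
#' between protein and transcript (`r_pt`), protein and cleavage (`r_pc`),
#' and transcript and cleavage (`r_tc`). Correlations involving a missing
#' layer are `NA`.
#'
#' @param triads Wide triad table ([overlay_layers()] output or
#'   [sim_triads()]).
#' @return `triads` with `r_pt`, `r_pc`, `r_tc` columns added.
#' @export
correlate_layers <- function(triads) {
  cl <- layer_matrix(triads, "cleavage")
  pr <- layer_matrix(triads, "protein")
  tr <- layer_matrix(triads, "transcript")
  triads$r_pt <- row_cor(pr, tr)
  triads$r_pc <- row_cor(pr, cl)
  triads$r_tc <- row_cor(tr, cl)
  triads
}

# Internal: monotone-trend statistic of a trajectory: Pearson r against the
# time-point rank (robust to the strongly non-uniform 0-72 h sampling).
# Constant trajectories are flat (0); incomplete ones are NA.
trend_r <- function(m) {
  ranks <- seq_len(ncol(m))
  vapply(seq_len(nrow(m)), function(i) {
    x <- m[i, ]
    if (anyNA(x)) return(NA_real_)
    if (sd(x) == 0) return(0)
    cor(x, ranks)
  }, numeric(1))
}

#' Classify each substrate triad into a regulatory mode
#'
#' Reduces each layer's trajectory to a monotone trend (Pearson r against
#' the time-point rank: up if `r > trend_cut`, down if `r < -trend_cut`,
#' flat otherwise) and applies the decision table distilled from the
#' exemplar substrates of the emulated study:
#'
#' * transcript up, protein down, cleavage up  -> `caspase_degradation`
#'   (transcriptionally up-regulated yet falling at the protein level while
#'   cleavage products accumulate, the MAGED2-like pattern);
#' * transcript up, protein up                 -> `co_upregulated`
#'   (SQSTM1-like);
#' * transcript flat, protein down             -> `direct_caspase`
#'   (MAP3K7-like);
#' * transcript down, protein down             -> `transcription_coupled`
#'   (UHRF1-like);
#' * anything else                             -> `ambiguous`.
#'
#' The call is invariant to positive affine rescaling of any trajectory.
#'
#' @param triads Wide triad table; layer correlations are computed if absent.
#' @param trend_cut Trend threshold on |r| (default 0.5).
#' @param r_cut Correlation threshold used only for the advisory
#'   `high_confidence` flag (the supporting inter-layer correlation of the
#'   called mode exceeds it in absolute value).
#' @return `triads` with `mode` (factor), per-layer trends
#'   (`trend_cleavage`, `trend_protein`, `trend_transcript`), correlations
#'   and `high_confidence` added.
#' @export
classify_mode <- function(triads, trend_cut = 0.5, r_cut = 0.5) {
  stopifnot(trend_cut >= 0, trend_cut < 1)
  if (!all(c("r_pt", "r_pc", "r_tc") %in% names(triads))) {
    triads <- correlate_layers(triads)
  }
  tr_c <- trend_r(layer_matrix(triads, "cleavage"))
  tr_p <- trend_r(layer_matrix(triads, "protein"))
  tr_t <- trend_r(layer_matrix(triads, "transcript"))
  cat3 <- function(r) {
    dplyr::case_when(is.na(r) ~ NA_character_,
                     r > trend_cut ~ "up", r < -trend_cut ~ "down",
                     TRUE ~ "flat")
  }
  ct <- cat3(tr_c); pt <- cat3(tr_p); tt <- cat3(tr_t)
  mode <- dplyr::case_when(
    is.na(ct) | is.na(pt) | is.na(tt) ~ "ambiguous",
    tt == "up" & pt == "down" & ct == "up" ~ "caspase_degradation",
    tt == "up" & pt == "up" ~ "co_upregulated",
    tt == "flat" & pt == "down" ~ "direct_caspase",
    tt == "down" & pt == "down" ~ "transcription_coupled",
    TRUE ~ "ambiguous"
  )
  triads$trend_cleavage <- tr_c
  triads$trend_protein <- tr_p
  triads$trend_transcript <- tr_t
  triads$mode <- factor(mode, levels = regulatory_modes())
  support <- dplyr::case_when(
    mode == "caspase_degradation" ~ triads$r_pt,
    mode == "co_upregulated" ~ triads$r_pt,
    mode == "transcription_coupled" ~ triads$r_pt,
    mode == "direct_caspase" ~ triads$r_pc,
    TRUE ~ NA_real_
  )
  triads$high_confidence <- !is.na(support) & abs(support) > r_cut
  triads
}

#' @rdname classify_mode
#' @return `regulatory_modes()` returns the mode labels in their canonical
#'   order.
#' @export
regulatory_modes <- function() {
  c("caspase_degradation", "co_upregulated", "direct_caspase",
    "transcription_coupled", "ambiguous")
}

#' Pooled protein-transcript regression across substrates
#'
#' Pools every (substrate, time point) pair of standardized protein and
#' transcript values, computes the Pearson correlation, and fits the least
#' squares line protein ~ transcript (the substrate-level scatter summary of
#' the emulated study).
#'
#' @param triads Wide triad table with `protein_*` and `transcript_*` time
#'   columns.
#' @return One-row tibble: `r`, `p_value`, `slope`, `intercept`, `n_obs`.
#' @export
substrate_regression <- function(triads) {
  pr <- as.numeric(layer_matrix(triads, "protein"))
  tr <- as.numeric(layer_matrix(triads, "transcript"))
  ok <- !is.na(pr) & !is.na(tr)
  if (sum(ok) < 3) abort("fewer than 3 complete (protein, transcript) points")
  ct <- cor.test(tr[ok], pr[ok])
  fit <- lm(pr[ok] ~ tr[ok])
  tibble(r = unname(ct$estimate), p_value = ct$p.value,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         n_obs = sum(ok))
}

# Standardized mode templates over the 6-point time course.
mode_templates <- function() {
  up <- (1:6 - mean(1:6)) / sd(1:6)
  cleave_up <- c(0, 0.2, 0.5, 1.2, 1.8, 2.2)
  cleave_up <- (cleave_up - mean(cleave_up)) / sd(cleave_up)
  flat <- rep(0, 6)
  list(
    caspase_degradation = list(transcript = up, protein = -up,
                               cleavage = cleave_up),
    co_upregulated = list(transcript = up, protein = up,
                          cleavage = cleave_up),
    direct_caspase = list(transcript = flat, protein = -up,
                          cleavage = cleave_up),
    transcription_coupled = list(transcript = -up, protein = -up,
                                 cleavage = cleave_up)
  )
}

#' Simulate substrate triads with planted regulatory modes
#'
#' Generates idealized standardized trajectories for the four non-ambiguous
#' regulatory modes, adds Gaussian noise, and re-standardizes non-constant
#' rows (a planted flat layer at zero noise stays constant, which the trend
#' statistic reads as flat). The planted mode is the ground truth for
#' classification benchmarks.
#'
#' @param n Number of triads.
#' @param noise_sd Additive noise SD on the standardized scale.
#' @param time_points_h Time grid (labels only).
#' @param seed Optional integer seed.
#' @return Wide triad tibble: `gene`, `true_mode`, and `cleavage_*`,
#'   `protein_*`, `transcript_*` time columns.
#' @export
sim_triads <- function(n, noise_sd = 0.25,
                       time_points_h = c(0, 4, 8, 24, 48, 72),
                       seed = NULL) {
  local_seed_if(seed)
  tmpl <- mode_templates()
  modes <- sample(names(tmpl), n, replace = TRUE)
  mk_layer <- function(layer) {
    base <- do.call(rbind, lapply(modes, function(md) tmpl[[md]][[layer]]))
    x <- base + matrix(rnorm(n * 6, sd = noise_sd), n)
    sds <- apply(x, 1, sd)
    scale_ok <- sds > 0
    x[scale_ok, ] <- (x[scale_ok, , drop = FALSE] -
                        rowMeans(x[scale_ok, , drop = FALSE])) / sds[scale_ok]
    colnames(x) <- paste0(layer, "_h", time_points_h)
    as_tibble(x)
  }
  dplyr::bind_cols(
    tibble(gene = sprintf("G%05d", seq_len(n)), true_mode = modes),
    mk_layer("cleavage"), mk_layer("protein"), mk_layer("transcript"))
}
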