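#' Score PSMs with a Fisher linear discriminant
#'
#' Trains a Fisher linear discriminant separating target from decoy PSMs on
#' the configured search-score features and attaches a discriminant score to
#' every PSM. The projection direction is the closed form
#' `Sw^-1 (mu_target - mu_decoy)` (pooled within-class covariance `Sw`), so
#' higher scores are always more target-like. `ppm_error` enters as its
#' absolute value. A singular within-class covariance is ridge-regularised
#' (small diagonal inflation) with a warning.
#'
#' @param psms Tibble with a 0/1 `decoy` column and the feature columns.
#' @param features Feature columns to use.
#' @param ridge Relative ridge added to the covariance diagonal when it is
#'   numerically singular.
#' @return `psms` with an added `discriminant_score` column (zero at the
#'   midpoint between class means). The projection weights are attached as
#'   attribute `"weights"`.
#' @export
fit_discriminant <- function(psms,
                             features = c("score", "delta_score",
                                          "ppm_error", "missed_cleavages",
                                          "charge"),
                             ridge = 1e-8) {
  missing <- setdiff(features, names(psms))
  if (length(missing) > 0) {
    abort(paste0("missing feature columns: ", paste(missing, collapse = ", ")))
  }
  is_decoy <- psms$decoy == 1
  if (length(unique(is_decoy)) < 2) {
    abort("both target and decoy PSMs are required to fit the discriminant")
  }
  x <- as.matrix(psms[, features])
  storage.mode(x) <- "double"
  if ("ppm_error" %in% features) {
    x[, "ppm_error"] <- abs(x[, "ppm_error"])
  }
  xt <- x[!is_decoy, , drop = FALSE]
  xd <- x[is_decoy, , drop = FALSE]
  mu_t <- colMeans(xt)
  mu_d <- colMeans(xd)
  n_t <- nrow(xt)
  n_d <- nrow(xd)
  sw <- ((n_t - 1) * cov_or_zero(xt) + (n_d - 1) * cov_or_zero(xd)) /
    max(n_t + n_d - 2, 1)
  w <- tryCatch(
    solve(sw, mu_t - mu_d),
    error = function(e) {
      warn("within-class covariance is singular; applying ridge regularisation")
      eps <- ridge * mean(diag(sw)) + .Machine$double.eps
      solve(sw + diag(eps, ncol(sw)), mu_t - mu_d)
    }
  )
  proj <- drop(x %*% w)
  mid <- (sum(mu_t * w) + sum(mu_d * w)) / 2
  psms$discriminant_score <- proj - mid
  attr(psms, "weights") <- setNames(w, features)
  psms
}

# Internal: covariance that tolerates single-row classes.
cov_or_zero <- function(x) {
  if (nrow(x) < 2) return(matrix(0, ncol(x), ncol(x)))
  stats::cov(x)
}

#' Threshold scored PSMs at a target-decoy FDR level
#'
#' Scans score thresholds from the most to the least stringent and returns
#' the most permissive threshold whose estimated FDR does not exceed
#' `level`. The default estimator is the decoy/target ratio
#' `decoys_kept / targets_kept` of the concatenated target-decoy convention;
#' `estimator = "concatenated"` uses `2 * decoys / (targets + decoys)`
#' instead. Ties at the threshold are kept (ordering is score descending,
#' then row id ascending, so the rule is deterministic). Survivors exclude
#' decoys.
#'
#' @param scored Tibble with `decoy` and a score column.
#' @param level Requested FDR level in (0, 1].
#' @param score_col Name of the score column.
#' @param estimator FDR estimator (see above).
#' @return A list with `result` (one-row tibble: `threshold`,
#'   `n_targets_kept`, `n_decoys_kept`, `estimated_fdr`, `level`) and
#'   `survivors` (the surviving target rows). If no threshold attains the
#'   level the survivor set is empty and a warning is raised.
#' @examples
#' x <- tibble::tibble(decoy = c(0, 0, 0, 0, 1),
#'                     discriminant_score = c(10, 9, 8, 7, 1))
#' threshold_at_fdr(x, 0.05)$result
#' @export
threshold_at_fdr <- function(scored, level,
                             score_col = "discriminant_score",
                             estimator = c("decoy-target-ratio",
                                           "concatenated")) {
  estimator <- match.arg(estimator)
  if (!is.numeric(level) || level <= 0 || level > 1) {
    abort("level must be in (0, 1]")
  }
  s <- scored[[score_col]]
  if (any(!is.finite(s))) abort("scores must be finite")
  ord <- order(-s, seq_along(s))
  dec <- scored$decoy[ord] == 1
  cum_d <- cumsum(dec)
  cum_t <- cumsum(!dec)
  fdr <- switch(estimator,
    "decoy-target-ratio" = ifelse(cum_t == 0, Inf, cum_d / cum_t),
    "concatenated" = ifelse(cum_t + cum_d == 0, Inf,
                            2 * cum_d / (cum_t + cum_d))
  )
  # candidate cuts only at the last row of each tie group (inclusive ties)
  s_sorted <- s[ord]
  boundary <- c(s_sorted[-1] != s_sorted[-length(s_sorted)], TRUE)
  ok <- which(boundary & fdr <= level)
  if (length(ok) == 0) {
    warn(sprintf("no threshold attains FDR <= %g; returning empty survivor set",
                 level))
    result <- tibble(threshold = Inf, n_targets_kept = 0L,
                     n_decoys_kept = 0L, estimated_fdr = NA_real_,
                     level = level)
    return(list(result = result, survivors = scored[0, ]))
  }
  k <- max(ok)
  thr <- s_sorted[k]
  keep <- ord[seq_len(k)]
  survivors <- scored[sort(keep[scored$decoy[keep] == 0]), ]
  result <- tibble(threshold = thr,
                   n_targets_kept = cum_t[k],
                   n_decoys_kept = cum_d[k],
                   estimated_fdr = ifelse(cum_t[k] == 0, NA_real_, fdr[k]),
                   level = level)
  list(result = result, survivors = survivors)
}

#' Score proteins by their best surviving peptide
#'
#' Standard picked-best-surrogate protein scoring: each accession inherits
#' the maximum discriminant score over its surviving PSMs; decoy proteins
#' arise from decoy peptides (their reversed-sequence accessions).
#'
#' @param scored_psms PSMs with `proteins`, `decoy` and a score column
#'   (typically the survivors of the PSM-level filter plus the decoys that
#'   remain for protein-level decoy counting).
#' @param score_col Score column name.
#' @return Tibble with `accession`, `decoy`, `score`.
#' @export
score_proteins <- function(scored_psms, score_col = "discriminant_score") {
  scored_psms |>
    tidyr::separate_rows("proteins", sep = ";") |>
    dplyr::group_by(accession = .data$proteins) |>
    dplyr::summarise(decoy = max(.data$decoy),
                     score = max(.data[[score_col]]), .groups = "drop")
}

#' Protein-level FDR filtering
#'
#' Applies the same decoy-counting threshold rule as [threshold_at_fdr()]
#' at protein granularity (default level 2%).
#'
#' @param proteins Output of [score_proteins()].
#' @param level Protein-level FDR (default 0.02).
#' @param estimator Passed to [threshold_at_fdr()].
#' @return As [threshold_at_fdr()]: `result` and surviving target proteins.
#' @export
protein_level_fdr <- function(proteins, level = 0.02,
                              estimator = c("decoy-target-ratio",
                                            "concatenated")) {
  threshold_at_fdr(proteins, level, score_col = "score",
                   estimator = match.arg(estimator))
}
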