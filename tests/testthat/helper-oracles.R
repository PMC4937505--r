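# Independent brute-force oracles used across tests.

# Reporter extraction: plain double loop over spectra x channels.
oracle_extract <- function(peaks, theo = tmt6_reporter_mz(), tol_ppm = 20) {
  ids <- unique(peaks$spectrum_id)
  mz_by <- split(peaks$mz, factor(peaks$spectrum_id, levels = ids))
  int_by <- split(peaks$intensity, factor(peaks$spectrum_id, levels = ids))
  out <- matrix(0, length(ids), 6,
                dimnames = list(ids, paste0("reporter_", names(theo))))
  for (i in seq_along(ids)) {
    for (k in seq_along(theo)) {
      sel <- abs(mz_by[[i]] - theo[k]) / theo[k] * 1e6 <= tol_ppm
      if (any(sel)) out[i, k] <- max(int_by[[i]][sel])
    }
  }
  out
}

# FDR thresholding by exhaustive enumeration of all cutoffs.
oracle_fdr_threshold <- function(scores, decoy, level) {
  cuts <- sort(unique(scores))
  best <- NULL
  for (thr in cuts) {
    keep <- scores >= thr
    t_k <- sum(keep & decoy == 0)
    d_k <- sum(keep & decoy == 1)
    fdr <- if (t_k == 0) Inf else d_k / t_k
    if (fdr <= level && (is.null(best) || thr < best$thr)) {
      best <- list(thr = thr, t = t_k, d = d_k, fdr = fdr)
    }
  }
  best
}

# Fuzzy c-means objective recomputed from any fit's centers + memberships.
oracle_fcm_objective <- function(x, centers, u, m) {
  d2 <- outer(seq_len(nrow(x)), seq_len(nrow(centers)),
              Vectorize(function(i, j) sum((x[i, ] - centers[j, ])^2)))
  sum(u^m * d2)
}

# Dense-restart reference optimum via the independent e1071 implementation.
oracle_fcm_optimum <- function(x, c, m, restarts = 50) {
  best <- Inf
  for (s in seq_len(restarts)) {
    set.seed(s)
    r <- e1071::cmeans(x, c, m = m, iter.max = 500)
    best <- min(best, oracle_fcm_objective(x, r$centers, r$membership, m))
  }
  best
}

# Tiny synthetic database with hand-placed cleavage sites.
toy_db <- function() {
  tibble::tibble(
    accession = c("P1", "P2", "P3"),
    sequence = c("MKAFTDAGKLDAAAKGWSTNNR",   # D11 reachable by both digests
                 "MAAAFTDAGGKLLLDRRKSA",     # chymotryptic site at D15
                 "MKAFTDAGKLDGGGPPPQQQ"))    # homolog of the P1 head
}
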