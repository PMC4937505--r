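#' Row-standardize trajectory tables
#'
#' Standardizes each feature's trajectory to mean 0 and SD 1 across the time
#' points (the scale on which all clustering and overlay operations work).
#' Constant rows cannot be standardized and are dropped with a warning.
#' The operation is idempotent.
#'
#' @param traj A tibble whose first column(s) are identifiers and whose
#'   numeric columns are the time points, or a plain numeric matrix.
#' @param id_cols Character vector naming the identifier columns (ignored
#'   for matrices); all remaining numeric columns are standardized.
#' @return Same shape as the input, with rows standardized and constant
#'   rows removed.
#' @export
standardize_trajectories <- function(traj, id_cols = NULL) {
  if (is.matrix(traj)) {
    sds <- apply(traj, 1, sd)
    drop <- sds == 0 | !is.finite(sds)
    if (any(drop)) {
      warn(sprintf("dropping %d constant trajectory row(s)", sum(drop)))
      traj <- traj[!drop, , drop = FALSE]
      sds <- sds[!drop]
    }
    return((traj - rowMeans(traj)) / sds)
  }
  if (is.null(id_cols)) {
    id_cols <- names(traj)[!vapply(traj, is.numeric, logical(1))]
  }
  value_cols <- setdiff(names(traj), id_cols)
  m <- as.matrix(traj[, value_cols])
  sds <- apply(m, 1, sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warn(sprintf("dropping %d constant trajectory row(s)", sum(drop)))
    traj <- traj[!drop, , drop = FALSE]
    m <- m[!drop, , drop = FALSE]
    sds <- sds[!drop]
  }
  traj[, value_cols] <- as_tibble((m - rowMeans(m)) / sds)
  traj
}

# Internal: squared Euclidean distances points x centers.
dist2_to_centers <- function(x, v) {
  d2 <- matrix(rowSums(x^2), nrow(x), nrow(v)) +
    matrix(rowSums(v^2), nrow(x), nrow(v), byrow = TRUE) -
    2 * x %*% t(v)
  d2[d2 < 0] <- 0
  d2
}

# Internal: one fuzzy c-means run from a random membership start.
fcm_single <- function(x, c, m, tol, max_iter) {
  n <- nrow(x)
  u <- matrix(runif(n * c), n, c)
  u <- u / rowSums(u)
  j_prev <- Inf
  trace <- numeric(0)
  v_prev <- NULL
  for (it in seq_len(max_iter)) {
    um <- u^m
    cs <- colSums(um)
    v <- (t(um) %*% x) / cs
    if (any(cs == 0)) {
      # a cluster emptied out (degenerate membership); keep its last center
      v[cs == 0, ] <- if (is.null(v_prev)) x[sample.int(nrow(x), sum(cs == 0)), ] else
        v_prev[cs == 0, ]
    }
    v_prev <- v
    d2 <- dist2_to_centers(x, v)
    zero <- d2 <= .Machine$double.xmin
    any_zero <- rowSums(zero) > 0
    tmp <- d2^(-1 / (m - 1))
    u <- tmp / rowSums(tmp)
    if (any(any_zero)) {
      for (i in which(any_zero)) {
        u[i, ] <- 0
        u[i, which(zero[i, ])[1]] <- 1
      }
    }
    j <- sum(u^m * d2)
    trace <- c(trace, j)
    if (abs(j_prev - j) < tol) break
    j_prev <- j
  }
  list(centers = v, membership = u, objective = j, trace = trace,
       iterations = length(trace))
}

#' Fuzzy c-means clustering of kinetic trajectories
#'
#' Bezdek alternating optimization with Euclidean distances: centers
#' `v_i = sum_j u_ij^m x_j / sum_j u_ij^m` and memberships
#' `u_ij = 1 / sum_k (d_ij / d_kj)^(2/(m-1))`, iterated until the objective
#' `J = sum_ij u_ij^m d_ij^2` changes by less than `tol` or `max_iter` is
#' reached. The algorithm is non-convex, so `n_starts` random membership
#' initialisations are run and the best objective kept. A point coinciding
#' with a center receives membership 1 there (the limit convention). The
#' fuzzifier `m = 1.5` and the cluster counts used for the three omics
#' layers (5 for cleavage peptides, 6 for proteins, 9 for transcripts) are
#' exposed through the pipeline configuration.
#'
#' @param x Numeric matrix (features x time points), normally standardized,
#'   or a trajectory tibble accepted by [standardize_trajectories()] (its
#'   non-numeric columns become feature ids).
#' @param centers Number of clusters `c` (>= 2, <= rows).
#' @param m Fuzzifier (> 1).
#' @param n_starts Random restarts.
#' @param max_iter Iteration cap per start.
#' @param tol Absolute objective-change convergence tolerance.
#' @param seed Optional integer seed (fixed seed => identical fit).
#' @return An object of class `fuzzy_cmeans`: `centers` (c x T),
#'   `membership` (features x c, rows summing to 1), `cluster` (argmax
#'   labels, ties to the lowest index), `objective`, `objective_trace` (of
#'   the best start), `iterations`, `m`, `n_clusters`, `n_starts`, and the
#'   clustered `data`.
#' @examples
#' x <- sim_trajectories(60, noise_sd = 0.2, seed = 1)
#' fit <- fuzzy_cmeans(x, centers = 5, seed = 1)
#' glance(fit)
#' @export
fuzzy_cmeans <- function(x, centers, m = 1.5, n_starts = 10,
                         max_iter = 1000, tol = 1e-9, seed = NULL) {
  ids <- NULL
  if (is.data.frame(x)) {
    id_cols <- names(x)[!vapply(x, is.numeric, logical(1))]
    num_cols <- setdiff(names(x), id_cols)
    ids <- if ("feature_id" %in% id_cols) x$feature_id else
      if (length(id_cols) > 0) x[[id_cols[1]]] else NULL
    x <- as.matrix(x[, num_cols])
  }
  if (!is.null(ids)) rownames(x) <- ids
  if (centers < 2) abort("centers must be >= 2")
  if (centers > nrow(x)) abort("more clusters than data points")
  if (m <= 1) abort("fuzzifier m must be > 1")
  local_seed_if(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- fcm_single(x, centers, m, tol, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  u <- best$membership
  rownames(u) <- rownames(x)
  colnames(u) <- paste0("cluster", seq_len(centers))
  v <- best$centers
  dimnames(v) <- list(paste0("cluster", seq_len(centers)), colnames(x))
  structure(
    list(centers = v, membership = u,
         cluster = max.col(u, ties.method = "first"),
         objective = best$objective, objective_trace = best$trace,
         iterations = best$iterations, m = m, n_clusters = centers,
         n_starts = n_starts, seed = seed, data = x),
    class = "fuzzy_cmeans")
}

#' @export
print.fuzzy_cmeans <- function(x, ...) {
  cat(sprintf(
    "Fuzzy c-means fit: %d features, %d clusters, m = %g, J = %.6g (%d iter)\n",
    nrow(x$membership), x$n_clusters, x$m, x$objective, x$iterations))
  cat("cluster sizes:", paste(tabulate(x$cluster, x$n_clusters),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Hard cluster assignment from a membership matrix
#'
#' Argmax per row; ties are broken deterministically toward the lowest
#' cluster index.
#'
#' @param u Membership matrix (rows sum to 1) or a `fuzzy_cmeans` fit.
#' @return Tibble with `feature`, `cluster`, `membership` (the maximal
#'   membership value, the affinity to the assigned cluster).
#' @export
assign_clusters <- function(u) {
  if (inherits(u, "fuzzy_cmeans")) u <- u$membership
  idx <- max.col(u, ties.method = "first")
  tibble(feature = rownames(u) %||% as.character(seq_len(nrow(u))),
         cluster = idx,
         membership = u[cbind(seq_len(nrow(u)), idx)])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fuzzy_cmeans
#' @param x,... A `fuzzy_cmeans` fit (for the `tidy`/`glance` methods).
#' @method tidy fuzzy_cmeans
#' @export
tidy.fuzzy_cmeans <- function(x, ...) {
  assign_clusters(x)
}

#' @rdname fuzzy_cmeans
#' @method glance fuzzy_cmeans
#' @export
glance.fuzzy_cmeans <- function(x, ...) {
  tibble(n_features = nrow(x$membership), n_clusters = x$n_clusters,
         m = x$m, objective = x$objective, iterations = x$iterations,
         n_starts = x$n_starts)
}

#' Cluster-assignment table joined with trajectories
#'
#' Convenience accessor combining the hard assignments of a fit with the
#' clustered trajectory values, the layer currency consumed by
#' [overlay_layers()].
#'
#' @param fit A `fuzzy_cmeans` fit.
#' @return Tibble: `feature`, `cluster`, `membership`, time columns.
#' @export
cluster_table <- function(fit) {
  stopifnot(inherits(fit, "fuzzy_cmeans"))
  dplyr::bind_cols(assign_clusters(fit), as_tibble(fit$data))
}

#' Overlay cleavage, protein and transcript trajectories
#'
#' Joins each clustered cleavage peptide with its protein's trajectory and
#' its gene's transcript trajectory through an id map, producing one triad
#' row per peptide. When `restrict_gpp` names protein clusters (the
#' down-regulated classes in the emulated study), peptides whose protein
#' falls outside those clusters are excluded; peptides whose protein or
#' transcript is simply absent are retained with missing layer values and
#' counted in the `"n_unmapped"` attribute.
#'
#' @param csp,gpp,rna Layer tables from [cluster_table()] (features are
#'   peptides, protein accessions, and gene ids respectively).
#' @param id_map Tibble `peptide`, `protein`, `gene` (each peptide mapping
#'   to at most one protein and gene).
#' @param restrict_gpp Optional integer vector of protein clusters to keep.
#' @return A wide tibble, one row per peptide: ids, per-layer cluster and
#'   membership, and `cleavage_*`, `protein_*`, `transcript_*` time columns.
#' @export
overlay_layers <- function(csp, gpp, rna, id_map, restrict_gpp = NULL) {
  if (any(duplicated(id_map$peptide))) {
    abort("id_map must map each peptide to at most one protein/gene")
  }
  tcols <- setdiff(names(csp), c("feature", "cluster", "membership"))
  rename_layer <- function(df, prefix, feature_name) {
    nm <- c(feature = feature_name,
            cluster = paste0(prefix, "_cluster"),
            membership = paste0(prefix, "_membership"))
    names(df)[match(names(nm), names(df))] <- nm
    tc <- intersect(tcols, names(df))
    names(df)[match(tc, names(df))] <- paste0(prefix, "_", tc)
    df
  }
  out <- rename_layer(csp, "cleavage", "peptide") |>
    dplyr::left_join(id_map, by = "peptide") |>
    dplyr::left_join(rename_layer(gpp, "protein", "protein"),
                     by = "protein") |>
    dplyr::left_join(rename_layer(rna, "transcript", "gene"), by = "gene")
  n_unmapped <- sum(is.na(out$protein) | is.na(out$protein_cluster) |
                      is.na(out$gene) | is.na(out$transcript_cluster))
  if (!is.null(restrict_gpp)) {
    out <- out[is.na(out$protein_cluster) |
                 out$protein_cluster %in% restrict_gpp, ]
  }
  attr(out, "n_unmapped") <- n_unmapped
  if (n_unmapped > 0) {
    inform(sprintf("%d peptide(s) lack a complete protein/transcript mapping",
                   n_unmapped))
  }
  out
}
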