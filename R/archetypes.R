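#' Kinetic archetypes for caspase-cleavage trajectories
#'
#' Five piecewise-linear template trajectories over the six-point tunicamycin
#' time course (0, 4, 8, 24, 48, 72 h), mirroring the main kinetic classes
#' seen for caspase cleavage products during prolonged ER stress: substrates
#' cleaved early (before 24 h), substrates accumulating after 24 h,
#' substrates accumulating only by 72 h, and two bimodal classes whose
#' cleavage products dip around 48 h before rising again. Exact shapes are
#' free parameters of the generator; rows are returned standardized (mean 0,
#' SD 1) so they live on the same scale as standardized observed
#' trajectories.
#'
#' @param standardized If `TRUE` (default) each row is z-scored.
#' @return A 5 x 6 numeric matrix; rownames are archetype ids, colnames
#'   `h0 ... h72`.
#' @examples
#' cleavage_archetypes()
#' @export
cleavage_archetypes <- function(standardized = TRUE) {
  a <- rbind(
    early     = c(0.10, 0.70, 1.00, 0.95, 0.70, 0.90),
    post24    = c(0.05, 0.05, 0.10, 0.60, 0.90, 1.00),
    post72    = c(0.10, 0.10, 0.15, 0.35, 0.25, 1.00),
    bimodal_a = c(0.10, 0.50, 0.95, 0.40, 0.20, 0.90),
    bimodal_b = c(0.30, 0.90, 0.30, 0.80, 0.20, 1.00)
  )
  colnames(a) <- paste0("h", c(0, 4, 8, 24, 48, 72))
  if (standardized) a <- t(apply(a, 1, function(x) (x - mean(x)) / sd(x)))
  a
}

#' Trajectory archetypes for whole-proteome profiles
#'
#' Six template trajectories for global protein profiling, including two
#' down-regulated classes (a steady decline and a late collapse) emulating
#' the protein clusters whose members fall during ER stress, alongside flat,
#' early-up, late-up and transient classes.
#'
#' @inheritParams cleavage_archetypes
#' @return A 6 x 6 standardized (by default) matrix. The attribute
#'   `"down_classes"` names the two down-regulated archetypes.
#' @export
protein_archetypes <- function(standardized = TRUE) {
  a <- rbind(
    stable_drift = c(1.00, 0.98, 1.02, 0.97, 1.03, 0.99),
    early_up     = c(0.30, 0.80, 1.00, 0.95, 0.90, 0.85),
    late_up      = c(0.20, 0.25, 0.30, 0.50, 0.80, 1.00),
    transient    = c(0.30, 0.90, 1.00, 0.60, 0.35, 0.30),
    down_steady  = c(1.00, 0.90, 0.75, 0.55, 0.40, 0.25),
    down_late    = c(1.00, 1.00, 0.95, 0.80, 0.45, 0.15)
  )
  colnames(a) <- paste0("h", c(0, 4, 8, 24, 48, 72))
  if (standardized) a <- t(apply(a, 1, function(x) (x - mean(x)) / sd(x)))
  attr(a, "down_classes") <- c("down_steady", "down_late")
  a
}

#' Simulate standardized trajectories from planted archetypes
#'
#' Draws `n` features, assigns each to one archetype (uniformly at random),
#' adds independent Gaussian noise on the standardized scale, and re-
#' standardizes each row. The planted label is the recoverable ground truth
#' for clustering benchmarks.
#'
#' @param n Number of features (trajectories).
#' @param archetypes Standardized archetype matrix (rows = classes), e.g.
#'   [cleavage_archetypes()].
#' @param noise_sd SD of the additive Gaussian noise, on the standardized
#'   scale (so 0.3 means noise about a third of the trajectory SD).
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return A tibble with `feature_id`, the planted `archetype`, and one
#'   column per time point.
#' @examples
#' sim_trajectories(10, noise_sd = 0, seed = 1)
#' @export
sim_trajectories <- function(n, archetypes = cleavage_archetypes(),
                             noise_sd = 0.3, seed = NULL) {
  local_seed_if(seed)
  stopifnot(n >= 1, noise_sd >= 0)
  k <- nrow(archetypes)
  lab <- rownames(archetypes)[sample.int(k, n, replace = TRUE)]
  x <- archetypes[lab, , drop = FALSE] +
    matrix(rnorm(n * ncol(archetypes), sd = noise_sd), n)
  sds <- apply(x, 1, sd)
  keep_scale <- sds > 0
  x[keep_scale, ] <- (x[keep_scale, , drop = FALSE] -
                        rowMeans(x[keep_scale, , drop = FALSE])) /
    sds[keep_scale]
  out <- as_tibble(x)
  colnames(out) <- colnames(archetypes)
  dplyr::bind_cols(
    tibble(feature_id = sprintf("f%05d", seq_len(n)), archetype = lab),
    out
  )
}
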