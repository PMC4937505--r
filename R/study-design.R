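#' Study design for a TMT6plex ER-stress time course
#'
#' Describes the experimental layout the synthetic generators emulate: a
#' six-point tunicamycin time course multiplexed across the six TMT6plex
#' channels for the proteomics layers, plus a replicated RNA-seq arm with a
#' stress-only and a stress-plus-pan-caspase-inhibitor treatment.
#'
#' @param time_points_h Hours of tunicamycin exposure for the TMT time
#'   course; must be strictly increasing and of length 6 (one per channel).
#' @param channels TMT6plex channel labels, aligned position-by-position to
#'   `time_points_h`. Channel 126 maps to 0 h by default; the mapping is a
#'   design choice, not a measured quantity.
#' @param rna_replicates Biological replicates per RNA-seq condition
#'   (at least 2; the emulated study used 3).
#' @param treatments Treatment arm labels. The first is the stress-only arm,
#'   the second adds the pan-caspase inhibitor (z-VAD-FMK).
#' @param rna_time_points_h Hours sampled in the stress-vs-inhibitor RNA-seq
#'   comparison (the emulated study used 0, 8, 24 and 72 h).
#'
#' @return An object of class `study_design` (a validated list).
#' @examples
#' design <- study_design()
#' design$time_points_h
#' @export
study_design <- function(time_points_h = c(0, 4, 8, 24, 48, 72),
                         channels = tmt6_channels(),
                         rna_replicates = 3,
                         treatments = c("tm", "tm_zvad"),
                         rna_time_points_h = c(0, 8, 24, 72)) {
  if (length(channels) != 6) abort("exactly 6 TMT channels are required")
  if (length(time_points_h) != length(channels)) {
    abort("time_points_h must align one-to-one with channels")
  }
  if (any(diff(time_points_h) <= 0)) {
    abort("time_points_h must be strictly increasing")
  }
  if (any(diff(rna_time_points_h) <= 0)) {
    abort("rna_time_points_h must be strictly increasing")
  }
  if (rna_replicates < 2) abort("rna_replicates must be >= 2")
  if (length(treatments) < 2) abort("two treatment arms are required")
  structure(
    list(time_points_h = time_points_h,
         channels = as.character(channels),
         rna_replicates = as.integer(rna_replicates),
         treatments = as.character(treatments),
         rna_time_points_h = rna_time_points_h),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("ER-stress study design\n")
  cat("  TMT time course (h): ", paste(x$time_points_h, collapse = ", "), "\n")
  cat("  channels:            ", paste(x$channels, collapse = ", "), "\n")
  cat("  RNA time points (h): ", paste(x$rna_time_points_h, collapse = ", "), "\n")
  cat("  RNA replicates:      ", x$rna_replicates, "\n")
  cat("  treatments:          ", paste(x$treatments, collapse = ", "), "\n")
  invisible(x)
}

# Internal: column labels for trajectory tables, e.g. h0, h4, ... h72.
time_cols <- function(design) paste0("h", design$time_points_h)
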