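#' Theoretical TMT6plex reporter ion m/z values
#'
#' Monoisotopic m/z of the six TMT6plex reporter cations (the 126-131
#' series). The reporter is a C8H16N+ cation; the heavier channels replace
#' 12C by 13C and/or 14N by 15N. Values are computed from the isotope masses
#' rather than hard-coded, and agree with the published reporter masses
#' (126.12773 ... 131.13818) to five decimals.
#'
#' @return Named numeric vector of length 6 (names are channel labels).
#' @examples
#' tmt6_reporter_mz()
#' @export
tmt6_reporter_mz <- function() {
  m_c12 <- 12
  m_c13 <- 13.003354835
  m_h <- 1.0078250319
  m_n14 <- 14.0030740052
  m_n15 <- 15.0001088984
  m_e <- 0.00054857990946
  base <- 8 * m_c12 + 16 * m_h + m_n14 - m_e  # C8H16N+ cation
  d_c <- m_c13 - m_c12
  d_n <- m_n15 - m_n14
  setNames(
    c(base, base + d_n, base + 2 * d_c, base + 2 * d_c + d_n,
      base + 4 * d_c, base + 4 * d_c + d_n),
    tmt6_channels()
  )
}

#' Extract TMT6 reporter intensities from reporter-region peak lists
#'
#' For every spectrum and every channel, selects the highest peak intensity
#' within `tol_ppm` parts-per-million of the theoretical reporter m/z
#' (tolerance measured relative to the theoretical value). Channels with no
#' peak in the window get intensity 0; a spectrum with an empty peak list
#' yields an all-zero row.
#'
#' @param peaks Tibble with columns `spectrum_id`, `mz`, `intensity`.
#' @param theoretical_mz Six theoretical reporter m/z values
#'   ([tmt6_reporter_mz()]).
#' @param tol_ppm Tolerance window in ppm (>= 0); the match rule is
#'   `|mz - mz_theor| / mz_theor * 1e6 <= tol_ppm`.
#' @param spectrum_ids Optional character vector of spectra that must appear
#'   in the output even if they contributed no peaks.
#' @return Tibble with `spectrum_id` and `reporter_126 ... reporter_131`.
#' @examples
#' pk <- tibble::tibble(spectrum_id = "s1",
#'                      mz = tmt6_reporter_mz()[["126"]], intensity = 5000)
#' extract_reporters(pk)
#' @export
extract_reporters <- function(peaks, theoretical_mz = tmt6_reporter_mz(),
                              tol_ppm = 20, spectrum_ids = NULL) {
  if (!is.numeric(tol_ppm) || length(tol_ppm) != 1 || tol_ppm < 0) {
    abort("tol_ppm must be a single non-negative number")
  }
  stopifnot(length(theoretical_mz) == 6)
  if (any(peaks$mz <= 0, na.rm = TRUE)) abort("m/z values must be positive")
  if (any(peaks$intensity < 0, na.rm = TRUE)) {
    abort("intensities must be non-negative")
  }
  ids <- unique(c(as.character(peaks$spectrum_id), spectrum_ids))
  out <- tibble(spectrum_id = ids)
  for (k in seq_along(theoretical_mz)) {
    mz0 <- theoretical_mz[[k]]
    hit <- peaks[abs(peaks$mz - mz0) / mz0 * 1e6 <= tol_ppm, ]
    col <- reporter_cols()[k]
    if (nrow(hit) == 0) {
      out[[col]] <- 0
    } else {
      mx <- hit |>
        dplyr::group_by(.data$spectrum_id) |>
        dplyr::summarise(v = max(.data$intensity), .groups = "drop")
      out[[col]] <- mx$v[match(out$spectrum_id, mx$spectrum_id)]
      out[[col]][is.na(out[[col]])] <- 0
    }
  }
  out
}

#' Filter PSMs on combined reporter-ion intensity
#'
#' Keeps peptide-spectrum matches whose combined reporter intensity (the sum
#' of the six channels) is strictly greater than `min_total`; a PSM at
#' exactly the threshold is removed. Input order is preserved and the filter
#' is idempotent.
#'
#' @param psms Tibble with the six reporter columns (a `combined_intensity`
#'   column is computed if absent).
#' @param min_total Strict lower bound on combined intensity.
#' @return The filtered tibble, with `combined_intensity` populated.
#' @export
filter_min_intensity <- function(psms, min_total = 2000) {
  if (nrow(psms) == 0) {
    psms$combined_intensity <- numeric(0)
    return(psms)
  }
  psms$combined_intensity <- rowSums(reporter_matrix(psms))
  psms[psms$combined_intensity > min_total, ]
}

#' Roll PSMs up to peptide-level quantifications
#'
#' Sums reporter intensities over all PSMs of each (peptide, protein-set)
#' key, then expresses each channel relative to the maximal channel
#' (`rel_* = sum / max`), the form fed to trajectory clustering. Peptides
#' whose channels are all zero keep an all-zero relative profile and are
#' flagged.
#'
#' @param psms Filtered, confidence-passing PSM tibble with `peptide`,
#'   `proteins` and reporter columns.
#' @return Tibble with one row per (peptide, proteins): summed reporter
#'   columns, `rel_*` columns, `n_psms`, and `all_zero` flag.
#' @export
rollup_peptides <- function(psms) {
  sums <- psms |>
    dplyr::group_by(.data$peptide, .data$proteins) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(reporter_cols()), sum),
                     n_psms = dplyr::n(), .groups = "drop")
  m <- reporter_matrix(sums)
  mx <- apply(m, 1, max)
  rel <- m / ifelse(mx > 0, mx, 1)
  colnames(rel) <- sub("^reporter_", "rel_", reporter_cols())
  out <- dplyr::bind_cols(sums, as_tibble(rel))
  out$all_zero <- mx == 0
  if (any(out$all_zero)) {
    warn(sprintf("%d peptide(s) have all-zero reporter channels",
                 sum(out$all_zero)))
  }
  out
}

#' Roll peptides up to protein-level abundances
#'
#' Protein channel abundances are the unweighted mean of the relative
#' peptide profiles over all peptides mapping to the accession. Peptides
#' shared between accessions contribute to each by default; set
#' `shared = "unique"` to use only accession-unique peptides.
#'
#' @param peptides Output of [rollup_peptides()]. Multiple accessions are
#'   ";"-separated in `proteins`.
#' @param shared `"all"` (default) or `"unique"`.
#' @return Tibble with `accession`, mean `rel_*` columns and `n_peptides`.
#' @export
rollup_proteins <- function(peptides, shared = c("all", "unique")) {
  shared <- match.arg(shared)
  rel_cols <- sub("^reporter_", "rel_", reporter_cols())
  if (shared == "unique") {
    peptides <- peptides[!stringr::str_detect(peptides$proteins, ";"), ]
  }
  long <- tidyr::separate_rows(peptides, "proteins", sep = ";")
  long |>
    dplyr::group_by(accession = .data$proteins) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(rel_cols), mean),
                     n_peptides = dplyr::n(), .groups = "drop")
}
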