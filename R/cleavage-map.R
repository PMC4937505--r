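#' Protease cut residues
#'
#' P1 residues after which each digestion protease cleaves. The caspase
#' contribution (cleavage after D) is handled separately: every captured
#' peptide must end in the P1 aspartate.
#'
#' @param protease `"trypsin"` (after K/R) or `"chymotrypsin"` (after
#'   F/Y/W/L).
#' @return Character vector of residues.
#' @export
protease_cut_residues <- function(protease) {
  switch(protease,
         trypsin = c("K", "R"),
         chymotrypsin = c("F", "Y", "W", "L"),
         abort(sprintf("unknown protease '%s'", protease)))
}

# Internal: internal missed-cleavage count of a peptide under
# protease + caspase (Asp) chemistry. Counts protease residues (not before
# proline, the standard rule) and aspartates at positions 1..len-1.
count_missed_cleavages <- function(peptide, protease) {
  chars <- strsplit(peptide, "")[[1]]
  n <- length(chars)
  if (n < 2) return(0L)
  internal <- chars[seq_len(n - 1)]
  nxt <- chars[2:n]
  cut <- protease_cut_residues(protease)
  sum((internal %in% cut & nxt != "P") | internal == "D")
}

#' Validate a peptide as a protease + caspase digest product
#'
#' A captured neo-C-terminal peptide is digest-valid when (i) its C-terminal
#' residue is the P1 aspartate, (ii) its N-terminal boundary follows the
#' digestion protease rule (preceded in the protein by a cut residue, or at
#' the protein N-terminus), and (iii) it carries at most `max_missed`
#' internal missed cleavage sites (protease residues and aspartates).
#' All occurrences of the peptide in the protein are evaluated.
#'
#' @param peptide Peptide sequence (must occur in `protein`; an absent
#'   peptide is an error, distinct from an invalid digest).
#' @param protein Protein sequence.
#' @param protease Digestion protease.
#' @param max_missed Maximum internal missed cleavages (default 4).
#' @return A tibble with one row per occurrence: `start`, `end`,
#'   `c_term_is_asp`, `n_boundary_ok`, `missed_cleavages`, `valid`.
#' @examples
#' validate_digest("TDAGKLD", "MKTDAGKLD")
#' @export
validate_digest <- function(peptide, protein, protease = "trypsin",
                            max_missed = 4) {
  hits <- stringr::str_locate_all(protein, stringr::fixed(peptide))[[1]]
  if (nrow(hits) == 0) {
    abort(sprintf("peptide '%s' not found in protein", peptide))
  }
  cut <- protease_cut_residues(protease)
  nm <- count_missed_cleavages(peptide, protease)
  out <- tibble(
    start = unname(hits[, "start"]),
    end = unname(hits[, "end"]),
    c_term_is_asp = substr(peptide, nchar(peptide), nchar(peptide)) == "D",
    n_boundary_ok = hits[, "start"] == 1 |
      substr(protein, hits[, "start"] - 1, hits[, "start"] - 1) %in% cut,
    missed_cleavages = nm
  )
  out$valid <- out$c_term_is_asp & out$n_boundary_ok & nm <= max_missed
  out
}

#' @rdname validate_digest
#' @return `is_valid_digest()` returns a single logical: any occurrence
#'   valid.
#' @export
is_valid_digest <- function(peptide, protein, protease = "trypsin",
                            max_missed = 4) {
  any(validate_digest(peptide, protein, protease, max_missed)$valid)
}

# Internal: P5..P6' residue window (11 positions) around a P1 position,
# padded with "-" where the window runs past a terminus.
site_window <- function(sequence, p1, n_before = 4, n_after = 6) {
  n <- nchar(sequence)
  pos <- (p1 - n_before):(p1 + n_after)
  chars <- ifelse(pos >= 1 & pos <= n,
                  substring(sequence, pos, pos), "-")
  paste(chars, collapse = "")
}

#' Map neo-C-terminal peptides to protein cleavage sites
#'
#' Locates every digest-valid occurrence of each peptide in the database and
#' collapses occurrences sharing a (accession, P1 position) coordinate into
#' one cleavage site with its supporting peptides. Peptides from different
#' digestion proteases ending at the same aspartate therefore merge into a
#' single site. A peptide matching at more than one position (in one or
#' several proteins) contributes a site at every position and is flagged
#' ambiguous rather than discarded.
#'
#' @param peptides Tibble with `peptide` and optionally `protease`
#'   (defaulting to `protease`), or a character vector of peptides.
#' @param db Protein database tibble (`accession`, `sequence`).
#' @param protease Default protease for peptides without their own.
#' @param max_missed Maximum internal missed cleavages.
#' @return A tibble of cleavage sites: `accession`, `p1_position`, `window`
#'   (P5..P6', "-"-padded), `n_peptides`, `peptides` (";"-joined),
#'   `proteases` (";"-joined), `ambiguous`.
#' @export
map_sites <- function(peptides, db, protease = "trypsin", max_missed = 4) {
  if (is.character(peptides)) peptides <- tibble(peptide = peptides)
  if (!"protease" %in% names(peptides)) peptides$protease <- protease
  peptides <- dplyr::distinct(peptides, .data$peptide, .data$protease)

  hits <- purrr::pmap(peptides, function(peptide, protease) {
    in_db <- db[stringr::str_detect(db$sequence,
                                    stringr::fixed(peptide)), ]
    if (nrow(in_db) == 0) return(NULL)
    occ <- purrr::map2(in_db$accession, in_db$sequence, function(acc, seq) {
      v <- validate_digest(peptide, seq, protease, max_missed)
      v <- v[v$valid, , drop = FALSE]
      if (nrow(v) == 0) return(NULL)
      tibble(accession = acc, p1_position = v$end,
             peptide = peptide, protease = protease,
             sequence = seq)
    })
    dplyr::bind_rows(occ)
  })
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0) {
    return(tibble(accession = character(), p1_position = integer(),
                  window = character(), n_peptides = integer(),
                  peptides = character(), proteases = character(),
                  ambiguous = logical()))
  }
  n_pos <- hits |>
    dplyr::group_by(.data$peptide) |>
    dplyr::mutate(n_positions = dplyr::n_distinct(
      paste(.data$accession, .data$p1_position))) |>
    dplyr::ungroup()
  n_pos |>
    dplyr::group_by(.data$accession, .data$p1_position) |>
    dplyr::summarise(
      window = site_window(.data$sequence[1], .data$p1_position[1]),
      n_peptides = dplyr::n_distinct(.data$peptide),
      peptides = paste(sort(unique(.data$peptide)), collapse = ";"),
      proteases = paste(sort(unique(.data$protease)), collapse = ";"),
      ambiguous = any(.data$n_positions > 1),
      .groups = "drop") |>
    dplyr::arrange(.data$accession, .data$p1_position)
}

#' Overlap of cleavage sites with reference site lists
#'
#' Exact-coordinate comparison of the study's (accession, P1 position) sites
#' against one or more reference lists (e.g. flat-file stand-ins for the
#' TopFIND and CASBAH caspase-site repositories), reporting per-reference
#' and combined Venn counts. With `match = "protein"` comparison is at
#' accession granularity instead.
#'
#' @param sites Site tibble ([map_sites()]).
#' @param references Named list of tibbles with `accession` and
#'   `p1_position` (`p1_position` ignored for protein-level matching).
#' @param match `"site"` (exact coordinates, default) or `"protein"`.
#' @return Tibble with one row per reference plus a `combined` row (union of
#'   references): `reference`, `n_study`, `n_reference`, `shared`,
#'   `unique_study`, `unique_reference`.
#' @export
overlap_known <- function(sites, references, match = c("site", "protein")) {
  match <- match.arg(match)
  key <- function(df) {
    if (match == "site") paste(df$accession, df$p1_position) else
      unique(df$accession)
  }
  study <- unique(key(sites))
  one <- function(nm, ref) {
    rk <- unique(key(ref))
    unmatched_acc <- setdiff(unique(ref$accession), unique(sites$accession))
    if (length(unmatched_acc) == length(unique(ref$accession)) &&
        nrow(ref) > 0) {
      warn(sprintf(
        "reference '%s': none of its %d accessions occur in the study set",
        nm, length(unmatched_acc)))
    }
    tibble(reference = nm,
           n_study = length(study), n_reference = length(rk),
           shared = length(intersect(study, rk)),
           unique_study = length(setdiff(study, rk)),
           unique_reference = length(setdiff(rk, study)))
  }
  per_ref <- dplyr::bind_rows(
    unname(purrr::imap(references, function(ref, nm) one(nm, ref))))
  all_ref <- unique(unlist(lapply(references, key)))
  combined <- tibble(reference = "combined",
                     n_study = length(study),
                     n_reference = length(all_ref),
                     shared = length(intersect(study, all_ref)),
                     unique_study = length(setdiff(study, all_ref)),
                     unique_reference = length(setdiff(all_ref, study)))
  dplyr::bind_rows(per_ref, combined)
}

#' Residue probability matrix for cleavage-site motifs
#'
#' Tallies residues position-by-position across the P5..P6' windows of a
#' site set and converts counts to per-position probabilities, the units
#' used for sequence logos. Positions truncated at a protein terminus carry
#' the pad symbol `-`, which is excluded from the denominators; every
#' position with at least one non-pad residue therefore sums to 1. The P1
#' column is definitionally a point mass on D.
#'
#' @param sites Site tibble with a `window` column ([map_sites()]), or a
#'   character vector of equal-length windows.
#' @param positions Position labels; defaults to P5..P1, P1'..P6'.
#' @return A `motif_matrix`: 20 x n-position numeric matrix of residue
#'   probabilities with a `"counts"` attribute (non-pad count per position).
#' @export
motif_matrix <- function(sites,
                         positions = c(paste0("P", 5:1),
                                       paste0("P", 1:6, "p"))) {
  windows <- if (is.character(sites)) sites else sites$window
  if (length(windows) < 1) abort("at least one site window is required")
  wlen <- unique(nchar(windows))
  if (length(wlen) != 1) abort("windows must all have the same length")
  if (wlen != length(positions)) {
    abort("window length does not match the position labels")
  }
  chars <- do.call(rbind, strsplit(windows, ""))
  aa <- aa_alphabet()
  probs <- matrix(0, length(aa), wlen, dimnames = list(aa, positions))
  counts <- integer(wlen)
  for (j in seq_len(wlen)) {
    col <- chars[, j]
    col <- col[col != "-"]
    counts[j] <- length(col)
    if (length(col) > 0) {
      tab <- table(factor(col, levels = aa))
      probs[, j] <- as.numeric(tab) / length(col)
    }
  }
  structure(probs, counts = counts, class = c("motif_matrix", "matrix"))
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat("Cleavage-site motif probability matrix (",
      ncol(x), " positions, ", sum(attr(x, "counts") > 0),
      " informative)\n", sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}
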