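#' Mapping phosphosite windows onto structure sequences
#'
#' Phosphosite exports list each site as a 15-residue window
#' `XXXXXXX(S/T/Y)XXXXXXX` with the phosphoresidue at position 8 and `X`
#' padding past the protein termini. Windows are trimmed to octapeptides
#' `XXX(S/T/Y)XXXX` (phosphoresidue at position 4), located on the
#' structure's primary sequence, and failures are categorised as
#' disordered (residues without coordinates), mutated (exactly one
#' single-residue substitution restores the match), terminal (octapeptide
#' cannot be formed), low-coverage, or unmatched.
#'
#' @name site_mapper
NULL

CONVENTIONAL_RESIDUES <- c("S", "T", "Y")
UNCONVENTIONAL_RESIDUES <- c("H", "C", "D")

#' Parse a phosphosite table
#'
#' Expects a TSV with columns `accession`, `position`, `residue`,
#' `window15`. Rows violating the window invariants (length 15,
#' phosphoresidue at position 8 agreeing with the residue column) are
#' returned separately with reasons rather than silently dropped.
#'
#' @param tsv_text TSV text (single string or character vector of lines),
#'   or a path to a TSV file
#' @return list with `sites` (tibble of valid records, with a `conventional`
#'   flag) and `rejected` (tibble with a `reason` column)
#' @export
parse_phosphosite_table <- function(tsv_text) {
  if (length(tsv_text) == 1 && !grepl("[\n\t]", tsv_text) && file.exists(tsv_text)) {
    tsv_text <- readLines(tsv_text)
  }
  if (length(tsv_text) == 1) tsv_text <- strsplit(tsv_text, "\n", fixed = TRUE)[[1]]
  df <- utils::read.delim(text = paste(tsv_text, collapse = "\n"),
                          stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("accession", "position", "residue", "window15")
  if (!all(needed %in% names(df))) {
    stop("phosphosite table must have columns: ", paste(needed, collapse = ", "))
  }
  df <- tibble::as_tibble(df[needed])
  df$position <- suppressWarnings(as.integer(df$position))
  df$window15 <- toupper(df$window15)
  df$residue <- toupper(df$residue)

  reason <- rep(NA_character_, nrow(df))
  reason[is.na(df$position) | df$position < 1] <- "bad position"
  bad_len <- nchar(df$window15) != 15
  reason[is.na(reason) & bad_len] <- "window length"
  centre_ok <- !bad_len & substr(df$window15, 8, 8) == df$residue
  reason[is.na(reason) & !centre_ok] <- "centre residue mismatch"
  known <- df$residue %in% c(CONVENTIONAL_RESIDUES, UNCONVENTIONAL_RESIDUES)
  reason[is.na(reason) & !known] <- "unknown phosphoresidue type"

  ok <- is.na(reason)
  sites <- df[ok, ]
  sites$conventional <- sites$residue %in% CONVENTIONAL_RESIDUES
  rejected <- df[!ok, ]
  rejected$reason <- reason[!ok]
  list(sites = sites, rejected = rejected)
}

#' Trim a 15-residue window to the analysis octapeptide
#'
#' Keeps window positions 5-12, so the phosphoresidue (window position 8)
#' lands at octapeptide position 4. An `X` pad inside the octapeptide
#' means the site is too close to a terminus to form the full window.
#'
#' @param window15 15-character window string
#' @return 8-character octapeptide; attribute `terminal` is TRUE when the
#'   octapeptide contains pad characters
#' @export
trim_to_octapeptide <- function(window15) {
  if (nchar(window15) != 15) stop("window must have 15 characters")
  octa <- substr(window15, 5, 12)
  structure(octa, terminal = grepl("X", octa, fixed = TRUE))
}

#' Can a full octapeptide be formed at this position?
#'
#' TRUE when the site sits so close to a terminus that fewer than 3
#' residues precede it or fewer than 4 follow it.
#'
#' @param site_position 1-based position in the full sequence
#' @param sequence_length protein length
#' @return logical
#' @export
is_terminal <- function(site_position, sequence_length) {
  if (any(site_position < 1 | site_position > sequence_length)) {
    stop("site position out of range")
  }
  (site_position - 1) < 3 | (sequence_length - site_position) < 4
}

#' Locate an octapeptide on a chain sequence
#'
#' Exact substring search anchored near the expected offset (site position
#' minus 3, with a +/-2 tolerance absorbing isoform numbering drift).
#' Matches far from the anchor are ignored; several distinct anchored
#' matches make the site ambiguous.
#'
#' @param chain_sequence chain primary sequence
#' @param octa 8-character octapeptide
#' @param site_position expected 1-based position of the phosphoresidue
#' @return list with `found` (logical), `positions` (the 8 sequence
#'   positions when found) and `ambiguous` (logical)
#' @export
locate_octapeptide <- function(chain_sequence, octa, site_position) {
  if (nchar(chain_sequence) == 0) stop("empty chain sequence")
  starts <- all_occurrences(chain_sequence, octa)
  expected <- site_position - 3
  anchored <- starts[abs(starts - expected) <= 2]
  if (length(anchored) == 0) {
    return(list(found = FALSE, positions = NULL, ambiguous = FALSE))
  }
  if (length(anchored) > 1) {
    return(list(found = FALSE, positions = NULL, ambiguous = TRUE))
  }
  list(found = TRUE, positions = anchored + 0:7, ambiguous = FALSE)
}

all_occurrences <- function(text, pattern) {
  # lookahead keeps overlapping occurrences (tandem repeats)
  hits <- gregexpr(paste0("(?=", pattern, ")"), text, perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

#' Discriminate mutation from disorder for an unmatched octapeptide
#'
#' When the octapeptide matches the sequence but one of its residues has
#' no coordinates, the site is disordered. Otherwise every residue of the
#' octapeptide is substituted by the 19 other amino acids one position at
#' a time; if the variants of exactly one position match the sequence the
#' site carries a point mutation at that position. Matches at two or more
#' positions are ambiguous and the site stays unmatched.
#'
#' @param octa 8-character octapeptide
#' @param chain_sequence chain primary sequence
#' @param residues residue tibble of the chain (with `seqpos`,
#'   `is_observed`)
#' @param site_position expected phosphoresidue position
#' @return list with `status` (disordered/mutated/unmatched), and for
#'   mutations `mut_position` (1-8 in the octapeptide) and `mut_residue`
#'   (the residue actually present in the structure sequence)
#' @export
classify_failure <- function(octa, chain_sequence, residues, site_position) {
  loc <- locate_octapeptide(chain_sequence, octa, site_position)
  if (loc$found) {
    obs <- residues$is_observed[match(loc$positions, residues$seqpos)]
    if (!all(obs)) {
      return(list(status = "disordered", mut_position = NA, mut_residue = NA))
    }
    stop("octapeptide matches and is fully observed; not a failure")
  }
  hit_pos <- integer(0)
  hit_res <- character(0)
  for (p in 1:8) {
    for (aa in setdiff(AA1, substr(octa, p, p))) {
      variant <- octa
      substr(variant, p, p) <- aa
      if (locate_octapeptide(chain_sequence, variant, site_position)$found) {
        hit_pos <- c(hit_pos, p)
        hit_res <- c(hit_res, aa)
      }
    }
  }
  if (length(unique(hit_pos)) == 1) {
    list(status = "mutated", mut_position = hit_pos[1], mut_residue = hit_res[1])
  } else {
    list(status = "unmatched", mut_position = NA, mut_residue = NA)
  }
}

#' Apply the sequence-coverage filter
#'
#' Sites on chains whose structure covers less than `threshold` of the
#' primary sequence (default 70 percent, boundary inclusive: "at least
#' 70%") are set to status `low_coverage`.
#'
#' @param matches tibble with at least `structure_id`, `chain` and
#'   `status` columns
#' @param structures named list of `phospho_structure` objects
#' @param threshold minimum coverage fraction
#' @return `matches` with statuses updated and a `coverage` column
#' @export
filter_by_coverage <- function(matches, structures, threshold = 0.7) {
  cov <- purrr::map2_dbl(matches$structure_id, matches$chain, function(sid, ch) {
    if (is.na(sid)) return(NA_real_)
    sequence_coverage(structures[[sid]], ch)
  })
  matches$coverage <- cov
  drop <- !is.na(cov) & cov < threshold & matches$status == "matched"
  matches$status[drop] <- "low_coverage"
  matches
}
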