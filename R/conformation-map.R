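#' The conformational map: allowed and disallowed phosphoconformation
#'
#' A phosphosite whose octapeptide rSASA reaches the accessibility
#' threshold (0.2 by default; 0.3 as the stringent variant) lies in the
#' allowed region of phosphoconformation, i.e. a kinase can reach it;
#' below the threshold it lies in the disallowed region. Apparently
#' buried sites can be rescued by removing oligomer partners (interface
#' burial), by an alternate deposited structure in which the site is
#' exposed, by matching a kinase consensus motif, or by low-energy
#' conformers from normal-mode dynamics.
#'
#' @name conformation_map
NULL

#' Classify an rSASA value
#'
#' @param rsasa rSASA value(s), non-negative
#' @param threshold accessibility threshold, 0.2 (default) or 0.3
#'   (stringent); the boundary is inclusive: `rsasa >= threshold` is
#'   allowed
#' @return character vector, "allowed" or "disallowed"
#' @export
#' @examples
#' classify_site(c(0.11, 0.73))
classify_site <- function(rsasa, threshold = 0.2) {
  if (any(rsasa < 0, na.rm = TRUE)) stop("rSASA cannot be negative")
  ifelse(rsasa >= threshold, "allowed", "disallowed")
}

#' Interface rescue: recompute rSASA on the isolated monomer
#'
#' A site buried at the interface of a homo-oligomer may be fully
#' accessible on the isolated subunit, where phosphorylation must have
#' occurred. Applicable only when the site is disallowed on an assembly
#' with more than one chain.
#'
#' @param structure the oligomeric `phospho_structure`
#' @param chain chain carrying the site
#' @param seqpos the 8 octapeptide sequence positions
#' @param assembly_rsasa the site's rSASA computed on the full assembly
#' @param threshold accessibility threshold
#' @param params a [sasa_params()] object
#' @return tibble with `label`, `rescue`, `assembly_rsasa`,
#'   `monomer_rsasa`
#' @export
rescue_interface <- function(structure, chain, seqpos, assembly_rsasa,
                             threshold = 0.2, params = sasa_params()) {
  if (structure$assembly_size <= 1) stop("interface rescue needs an oligomer")
  if (assembly_rsasa >= threshold) {
    return(tibble::tibble(label = "allowed", rescue = "none",
                          assembly_rsasa = assembly_rsasa,
                          monomer_rsasa = NA_real_))
  }
  mono <- extract_monomer(structure, chain)
  mr <- octapeptide_rsasa(mono, chain, seqpos, params)
  if (mr >= threshold) {
    tibble::tibble(label = "allowed", rescue = "interface",
                   assembly_rsasa = assembly_rsasa, monomer_rsasa = mr)
  } else {
    tibble::tibble(label = "disallowed", rescue = "none",
                   assembly_rsasa = assembly_rsasa, monomer_rsasa = mr)
  }
}

#' Alternate-structure rescue
#'
#' When a site maps to several deposited structures, burial in one
#' conformation is overruled by accessibility in any other (e.g. an
#' auto-inhibited versus an open conformation).
#'
#' @param rsasa_by_structure named numeric vector of the site's rSASA in
#'   each mapped structure
#' @param threshold accessibility threshold
#' @return tibble with `label`, `rescue`, `best_rsasa`, `best_structure`
#' @export
rescue_alternate <- function(rsasa_by_structure, threshold = 0.2) {
  if (length(rsasa_by_structure) == 0) stop("no structures mapped for the site")
  best <- which.max(rsasa_by_structure)
  mx <- unname(rsasa_by_structure[best])
  rescued <- mx >= threshold && min(rsasa_by_structure) < threshold
  tibble::tibble(
    label = ifelse(mx >= threshold, "allowed", "disallowed"),
    rescue = ifelse(rescued, "alternate_structure", "none"),
    best_rsasa = unname(mx),
    best_structure = names(rsasa_by_structure)[best] %||% NA_character_
  )
}

#' Cyclin-dependent-kinase consensus motif test
#'
#' TRUE when the octapeptide matches S/T-P-X-K/R anchored at the
#' phosphosite: position 4 in S/T, position 5 = P and position 7 in K/R.
#' A buried site matching a kinase's known specificity was presumably
#' accessible in an alternate cellular conformation.
#'
#' @param octa 8-character octapeptide (phosphoresidue at position 4)
#' @return logical
#' @export
#' @examples
#' consensus_override("AAASPAKA")
consensus_override <- function(octa) {
  vapply(octa, function(o) {
    substr(o, 4, 4) %in% c("S", "T") &&
      substr(o, 5, 5) == "P" &&
      substr(o, 7, 7) %in% c("K", "R")
  }, TRUE, USE.NAMES = FALSE)
}

#' Global flexibility from observed versus predicted SASA
#'
#' Predicted SASA follows the empirical mass scaling 4.44 * M^0.77
#' (Angstrom^2, M in Da); `a_rel` = observed / predicted, where values
#' above 1 indicate extended or flexible conformations. Restricted to
#' monomers with at most 5 residues lacking coordinates.
#'
#' @param structure a `phospho_structure`
#' @param params a [sasa_params()] object
#' @return one-row tibble with `mass`, `observed_sasa`, `predicted_sasa`,
#'   `a_rel`, `filtered` (TRUE with a `filter_reason` when the structure
#'   does not qualify, in which case the ratio columns are NA)
#' @export
compute_a_rel <- function(structure, params = sasa_params()) {
  n_chains <- nrow(structure$chains)
  n_disordered <- sum(!structure$residues$is_observed)
  reason <- if (n_chains > 1) {
    "multimer"
  } else if (n_disordered > 5) {
    "more than 5 disordered residues"
  } else {
    NA_character_
  }
  mass <- sum(AA_MASS[structure$residues$aa]) + WATER_MASS
  if (!is.na(reason)) {
    return(tibble::tibble(mass = mass, observed_sasa = NA_real_,
                          predicted_sasa = NA_real_, a_rel = NA_real_,
                          filtered = TRUE, filter_reason = reason))
  }
  obs <- sum(atom_sasa(structure, params)$sasa)
  pred <- 4.44 * mass^0.77
  tibble::tibble(mass = mass, observed_sasa = obs, predicted_sasa = pred,
                 a_rel = obs / pred, filtered = FALSE,
                 filter_reason = NA_character_)
}

#' Bin rSASA values and summarise the distribution
#'
#' Values are binned in blocks of 0.1 rSASA units (0-0.1, 0.1-0.2, ...,
#' 0.9-1.0); bins are half-open on the right with the last closed, and
#' values above 1 are clamped into the last bin for display only.
#'
#' @param values numeric rSASA values
#' @param width bin width
#' @return list with `histogram` (tibble `bin_lo`, `bin_hi`, `n`),
#'   `mode_bin` (label of the fullest bin) and `median`
#' @export
bin_and_summarize <- function(values, width = 0.1) {
  if (length(values) == 0) stop("no rSASA values to bin")
  lo <- seq(0, 1 - width, by = width)
  hi <- lo + width
  clamped <- pmin(values, 1)
  idx <- pmin(floor(clamped / width) + 1, length(lo))
  n <- tabulate(idx, nbins = length(lo))
  histogram <- tibble::tibble(bin_lo = lo, bin_hi = hi, n = n)
  mode_i <- which.max(n)
  list(histogram = histogram,
       mode_bin = sprintf("%.1f-%.1f", lo[mode_i], hi[mode_i]),
       median = stats::median(values))
}

#' Amino-acid composition of allowed versus disallowed octapeptides
#'
#' Per-set residue frequencies (summing to 1) and the difference in the
#' hydrophobic fraction (A/V/L/I/M/F/W/C); burial is expected to enrich
#' hydrophobic residues in the disallowed set.
#'
#' @param allowed_octas,disallowed_octas character vectors of octapeptides
#' @return list with `by_residue` (tibble `aa`, `freq_allowed`,
#'   `freq_disallowed`, `difference`) and `hydrophobic_difference`
#'   (disallowed minus allowed hydrophobic fraction)
#' @export
composition_compare <- function(allowed_octas, disallowed_octas) {
  if (length(allowed_octas) == 0 || length(disallowed_octas) == 0) {
    stop("both octapeptide sets must be non-empty")
  }
  freq <- function(octas) {
    ch <- unlist(strsplit(octas, ""))
    ch <- ch[ch %in% AA1]
    tab <- table(factor(ch, levels = AA1))
    as.numeric(tab) / sum(tab)
  }
  fa <- freq(allowed_octas)
  fd <- freq(disallowed_octas)
  by_residue <- tibble::tibble(aa = AA1, freq_allowed = fa,
                               freq_disallowed = fd, difference = fd - fa)
  hyd <- by_residue$aa %in% HYDROPHOBIC_AA
  list(by_residue = by_residue,
       hydrophobic_difference = sum(fd[hyd]) - sum(fa[hyd]))
}

#' Agreement between rSASA classification and residue depth
#'
#' Fraction of sites where the two accessibility measures concur:
#' accessible sites (rSASA >= `rsasa_threshold`) should lie near the
#' surface (depth < `depth_cutoff`) and buried sites far from it.
#'
#' @param sites tibble with `rsasa` and `depth` columns
#' @param rsasa_threshold accessibility threshold
#' @param depth_cutoff depth cutoff separating surface from interior (the
#'   reported scale uses 30; synthetic fixtures use a fixture-scale value)
#' @return agreement fraction in \[0, 1\]
#' @export
depth_consistency <- function(sites, rsasa_threshold = 0.2, depth_cutoff = 30) {
  agree <- (sites$rsasa >= rsasa_threshold & sites$depth < depth_cutoff) |
    (sites$rsasa < rsasa_threshold & sites$depth >= depth_cutoff)
  mean(agree)
}
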