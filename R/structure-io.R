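#' Protein structure container and PDB-format input/output
#'
#' A `phospho_structure` is a light hierarchical model of a PDB entry:
#'
#' * `atoms`: tibble with one row per atom (`serial`, `elety`, `element`,
#'   `aa`, `chain`, `resno`, `x`, `y`, `z`, `occ`, `modified`),
#' * `residues`: tibble with one row per primary-sequence position per
#'   chain (`chain`, `seqpos`, `resno`, `aa`, `is_observed`, `modified`),
#' * `chains`: tibble (`chain`, `sequence`) holding the full primary
#'   sequence including residues without coordinates,
#' * `assembly_size`: number of chain copies in the deposited assembly.
#'
#' Author residue numbers are kept verbatim in `resno`; `seqpos` is the
#' 1-based index into the primary sequence. Disordered residues (present
#' in SEQRES but without ATOM records) are kept with `is_observed = FALSE`.
#'
#' @name structure_model
NULL

new_structure <- function(id, atoms, residues, chains) {
  structure(
    list(id = id, atoms = atoms, residues = residues, chains = chains,
         assembly_size = nrow(chains)),
    class = "phospho_structure"
  )
}

#' @export
print.phospho_structure <- function(x, ...) {
  cat("<phospho_structure>", x$id, "\n")
  cat("  chains:", nrow(x$chains),
      " residues:", nrow(x$residues),
      " (", sum(x$residues$is_observed), "observed )",
      " atoms:", nrow(x$atoms), "\n")
  invisible(x)
}

#' Assemble a structure object from an atom table
#'
#' @param id structure identifier
#' @param atoms atom tibble (see [structure_model])
#' @param sequences optional named character vector of full primary
#'   sequences per chain; residues in a sequence but absent from `atoms`
#'   are recorded with `is_observed = FALSE`. When omitted the observed
#'   residues define the sequence.
#' @return a `phospho_structure`
#' @export
structure_from_atoms <- function(id, atoms, sequences = NULL) {
  stopifnot(all(c("chain", "resno", "aa", "elety", "element",
                  "x", "y", "z", "occ", "serial") %in% names(atoms)))
  if (!"modified" %in% names(atoms)) atoms$modified <- FALSE
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite atom coordinates")
  }
  obs <- dplyr::distinct(atoms, .data$chain, .data$resno, .data$aa, .data$modified)
  obs <- dplyr::arrange(obs, .data$chain, .data$resno)
  if (anyDuplicated(obs[c("chain", "resno")])) {
    stop("conflicting residue identities at a single (chain, resno)")
  }

  chain_ids <- unique(atoms$chain)
  res_list <- list()
  seq_list <- character(length(chain_ids))
  for (k in seq_along(chain_ids)) {
    cid <- chain_ids[k]
    oc <- obs[obs$chain == cid, ]
    if (is.null(sequences) || is.na(sequences[cid] %||% NA)) {
      seqchars <- oc$aa
      seqpos <- seq_along(seqchars)
      res <- tibble::tibble(chain = cid, seqpos = seqpos, resno = oc$resno,
                            aa = seqchars, is_observed = TRUE,
                            modified = oc$modified)
    } else {
      full <- strsplit(sequences[[cid]], "")[[1]]
      # author numbering is assumed to index the primary sequence, up to a
      # constant offset recovered by matching observed residue identities
      off <- resolve_offset(full, oc$resno, oc$aa)
      seqpos_obs <- oc$resno + off
      if (any(seqpos_obs < 1 | seqpos_obs > length(full))) {
        stop("observed residues fall outside the primary sequence (chain ", cid, ")")
      }
      res <- tibble::tibble(chain = cid, seqpos = seq_along(full),
                            resno = seq_along(full) - off,
                            aa = full, is_observed = FALSE, modified = FALSE)
      res$is_observed[seqpos_obs] <- TRUE
      res$aa[seqpos_obs] <- oc$aa
      res$modified[seqpos_obs] <- oc$modified
    }
    res_list[[k]] <- res
    seq_list[k] <- paste(res_list[[k]]$aa, collapse = "")
  }
  residues <- dplyr::bind_rows(res_list)
  chains <- tibble::tibble(chain = chain_ids, sequence = seq_list)
  new_structure(id, atoms, residues, chains)
}

# find integer offset o such that full[resno + o] == aa for the most
# observed residues; exact agreement is required
resolve_offset <- function(full, resno, aa) {
  for (off in c(0, seq(-5, 5))) {
    idx <- resno + off
    ok <- idx >= 1 & idx <= length(full)
    if (all(ok) && all(full[idx] == aa | aa == "X")) return(off)
  }
  stop("cannot align observed residues to the primary sequence")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Parse a PDB-format structure
#'
#' Reads fixed-column ATOM/HETATM/SEQRES/MODEL records into a validated
#' hierarchical model. Only the first MODEL of a multi-model file is used.
#' Alternate locations are resolved to the highest-occupancy conformer
#' (ties broken alphabetically). HETATM records of phosphorylated residues
#' (SEP/TPO/PTR) are mapped to their parent amino acid and flagged
#' `modified`. SEQRES (when present) defines the primary sequence and
#' residues without coordinates are marked unobserved.
#'
#' @param pdb_text character scalar or vector of PDB lines
#' @param id structure identifier (defaults to the HEADER id or "structure")
#' @return a `phospho_structure`
#' @export
parse_structure <- function(pdb_text, id = NULL) {
  lines <- if (length(pdb_text) == 1 && grepl("\n", pdb_text)) {
    strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  } else {
    pdb_text
  }
  rec <- substr(lines, 1, 6)

  # first model only
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) > 1) {
    endm <- which(trimws(rec) == "ENDMDL")
    lines <- lines[seq_len(endm[1])]
    rec <- rec[seq_len(endm[1])]
  }

  atom_idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(atom_idx) == 0) stop("no ATOM records: empty structure")

  al <- lines[atom_idx]
  bad <- which(nchar(al) < 54)
  if (length(bad)) {
    stop("malformed fixed-column ATOM record at line ", atom_idx[bad[1]])
  }
  f <- function(a, b) substr(al, a, b)
  x <- suppressWarnings(as.numeric(f(31, 38)))
  y <- suppressWarnings(as.numeric(f(39, 46)))
  z <- suppressWarnings(as.numeric(f(47, 54)))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    bad <- which(is.na(x) | is.na(y) | is.na(z))[1]
    stop("malformed coordinate field at line ", atom_idx[bad])
  }
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[is.na(occ)] <- 1
  atoms <- tibble::tibble(
    record = trimws(rec[atom_idx]),
    serial = suppressWarnings(as.integer(f(7, 11))),
    elety = trimws(f(13, 16)),
    alt = trimws(f(17, 17)),
    resid3 = trimws(f(18, 20)),
    chain = trimws(f(22, 22)),
    resno = suppressWarnings(as.integer(f(23, 26))),
    insert = trimws(f(27, 27)),
    x = x, y = y, z = z, occ = occ,
    element = trimws(f(77, 78))
  )
  if (anyNA(atoms$resno)) {
    stop("malformed residue number at line ",
         atom_idx[which(is.na(atoms$resno))[1]])
  }
  atoms$chain[atoms$chain == ""] <- "A"
  # keep canonical and known modified residues only (drops waters/ligands)
  keep <- atoms$resid3 %in% c(AA3, names(MODIFIED_AA))
  atoms <- atoms[keep, ]
  if (nrow(atoms) == 0) stop("no ATOM records with canonical residues")
  atoms$aa <- aa_one_letter(atoms$resid3)
  atoms$modified <- atoms$resid3 %in% names(MODIFIED_AA)
  atoms$element <- ifelse(atoms$element == "",
                          substr(atoms$elety, 1, 1), atoms$element)
  # insertion codes are opaque suffixes; fold them into resno ordering by
  # keeping rows as-is (numbering arithmetic never crosses an insertion)
  atoms <- resolve_altloc(atoms)
  atoms$occ[atoms$occ < 0] <- 0
  atoms$occ[atoms$occ > 1] <- 1

  seqres <- parse_seqres(lines[rec == "SEQRES"])
  hid <- id %||% "structure"
  structure_from_atoms(hid, atoms[, c("serial", "elety", "element", "aa", "chain",
                                      "resno", "x", "y", "z", "occ", "modified")],
                       sequences = seqres)
}

resolve_altloc <- function(atoms) {
  if (all(atoms$alt %in% c("", " "))) return(atoms)
  atoms <- dplyr::group_by(atoms, .data$chain, .data$resno, .data$elety)
  atoms <- dplyr::arrange(atoms, dplyr::desc(.data$occ), .data$alt, .by_group = TRUE)
  atoms <- dplyr::slice(atoms, 1)
  atoms <- dplyr::ungroup(atoms)
  dplyr::arrange(atoms, .data$serial)
}

parse_seqres <- function(sr_lines) {
  if (length(sr_lines) == 0) return(NULL)
  ch <- trimws(substr(sr_lines, 12, 12))
  out <- c()
  for (cid in unique(ch)) {
    toks <- unlist(strsplit(trimws(substr(sr_lines[ch == cid], 20, 70)), "\\s+"))
    out[cid] <- paste(aa_one_letter(toks), collapse = "")
  }
  out
}

#' Extract a single chain as a monomer
#'
#' Removes all partner chains of an oligomeric assembly, leaving the
#' selected chain with its coordinates untouched. Used to ask whether a
#' site buried in an assembly is accessible on the isolated subunit.
#'
#' @param structure a `phospho_structure`
#' @param chain_id chain to keep
#' @return a single-chain `phospho_structure`
#' @export
extract_monomer <- function(structure, chain_id) {
  if (!chain_id %in% structure$chains$chain) {
    stop("unknown chain: ", chain_id)
  }
  new_structure(
    paste0(structure$id, "_", chain_id),
    structure$atoms[structure$atoms$chain == chain_id, ],
    structure$residues[structure$residues$chain == chain_id, ],
    structure$chains[structure$chains$chain == chain_id, ]
  )
}

#' Fraction of the primary sequence with coordinates
#'
#' Structures are retained for accessibility analysis only when at least
#' 70 percent of the chain's primary sequence is observed; this computes
#' that coverage fraction.
#'
#' @param structure a `phospho_structure`
#' @param chain_id chain to assess
#' @return fraction in \[0, 1\]
#' @export
sequence_coverage <- function(structure, chain_id) {
  res <- structure$residues[structure$residues$chain == chain_id, ]
  if (nrow(res) == 0) stop("chain has no primary sequence: ", chain_id)
  sum(res$is_observed) / nrow(res)
}

#' Write a structure as PDB-format text
#'
#' Emits SEQRES records for the full primary sequence and ATOM records for
#' observed residues only; coordinates keep the PDB's 3-decimal precision,
#' so a parse/write round trip reproduces them to 0.001 Angstrom.
#'
#' @param structure a `phospho_structure`
#' @return character vector of PDB lines
#' @export
write_structure <- function(structure) {
  if (any(abs(c(structure$atoms$x, structure$atoms$y, structure$atoms$z)) >= 10000)) {
    stop("coordinates exceed PDB fixed-column width")
  }
  out <- character(0)
  for (k in seq_len(nrow(structure$chains))) {
    cid <- structure$chains$chain[k]
    aa <- strsplit(structure$chains$sequence[k], "")[[1]]
    res3 <- unname(AA3[aa])
    res3[is.na(res3)] <- "UNK"
    nres <- length(res3)
    ser <- 1
    for (i in seq(1, nres, by = 13)) {
      grp <- res3[i:min(i + 12, nres)]
      out <- c(out, sprintf("SEQRES %3d %1s %4d  %-51s", ser, cid, nres,
                            paste(grp, collapse = " ")))
      ser <- ser + 1
    }
  }
  a <- structure$atoms
  res3 <- unname(AA3[a$aa])
  res3[is.na(res3)] <- "UNK"
  out <- c(out, sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial %% 100000, format_elety(a$elety), res3, a$chain, a$resno,
    a$x, a$y, a$z, a$occ, 0, a$element
  ))
  c(out, "END")
}

format_elety <- function(elety) {
  # single-letter element names start in column 14 (one leading space)
  ifelse(nchar(elety) < 4, paste0(" ", elety), elety)
}

#' Read primary sequences from a FASTA file
#'
#' Convenience wrapper used when structures lack SEQRES records; returns a
#' named character vector keyed by FASTA record name.
#'
#' @param path FASTA file path
#' @return named character vector of sequences
#' @export
read_fasta_sequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package")
  }
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Coordinates of the C-alpha trace of one chain
#' @keywords internal
ca_coords <- function(structure, chain_id = NULL) {
  a <- structure$atoms
  if (!is.null(chain_id)) a <- a[a$chain == chain_id, ]
  ca <- a[a$elety == "CA", ]
  ca <- ca[order(ca$resno), ]
  list(coords = as.matrix(ca[, c("x", "y", "z")]),
       resno = ca$resno, aa = ca$aa)
}

# rigid-body transform helper shared by generators and tests
transform_structure <- function(structure, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")]) %*% t(R)
  structure$atoms$x <- xyz[, 1] + t[1]
  structure$atoms$y <- xyz[, 2] + t[2]
  structure$atoms$z <- xyz[, 3] + t[3]
  structure
}
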