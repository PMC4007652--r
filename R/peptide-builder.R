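#' Internal-coordinate peptide construction
#'
#' Backbone geometry is produced by chaining atoms with ideal bond lengths,
#' bond angles and user-supplied phi/psi torsions (the NeRF construction).
#' Generated residues carry N, CA, C, O and (except glycine) CB atoms;
#' side chains beyond CB are deliberately omitted, and the extended
#' tripeptide reference areas used for %SASA are computed under the same
#' reduced-atom convention so normalisation stays calibrated.
#'
#' @name peptide_builder
#' @keywords internal
NULL

# ideal backbone geometry (lengths in Angstrom, angles in degrees)
GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_ca_cb = 1.521,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_c_ca_cb = 110.1, omega = 180
)

deg2rad <- function(x) x * pi / 180

#' Place an atom from three reference atoms and internal coordinates
#'
#' Given positions `a`, `b`, `c`, returns the point `d` with bond length
#' |c-d|, bond angle b-c-d and torsion a-b-c-d.
#'
#' @param a,b,c numeric 3-vectors
#' @param bond bond length (Angstrom)
#' @param angle bond angle (degrees)
#' @param torsion dihedral angle (degrees)
#' @return numeric 3-vector
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(a - b, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(ang), -sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Build a peptide chain at fixed backbone torsions
#'
#' @param sequence one-letter amino acid string
#' @param phi,psi backbone torsions in degrees, recycled along the chain
#' @param chain_id chain identifier for the resulting atoms
#' @return tibble of atoms (chain, resno, aa, elety, element, x, y, z)
#' @keywords internal
build_peptide_atoms <- function(sequence, phi, psi, chain_id = "A") {
  aa <- strsplit(sequence, "")[[1]]
  if (!all(aa %in% AA1)) stop("non-canonical residue in sequence: ", sequence)
  n <- length(aa)
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)

  # seed the first residue explicitly
  N1 <- c(0, 0, 0)
  CA1 <- c(GEOM$b_n_ca, 0, 0)
  ang <- deg2rad(GEOM$a_n_ca_c)
  C1 <- CA1 + GEOM$b_ca_c * c(-cos(ang), sin(ang), 0)

  Npos <- matrix(NA_real_, n, 3)
  CApos <- matrix(NA_real_, n, 3)
  Cpos <- matrix(NA_real_, n, 3)
  Npos[1, ] <- N1; CApos[1, ] <- CA1; Cpos[1, ] <- C1

  for (i in seq_len(n)) {
    if (i > 1) {
      Npos[i, ] <- place_atom(Npos[i - 1, ], CApos[i - 1, ], Cpos[i - 1, ],
                              GEOM$b_c_n, GEOM$a_ca_c_n, psi[i - 1])
      CApos[i, ] <- place_atom(CApos[i - 1, ], Cpos[i - 1, ], Npos[i, ],
                               GEOM$b_n_ca, GEOM$a_c_n_ca, GEOM$omega)
      Cpos[i, ] <- place_atom(Cpos[i - 1, ], Npos[i, ], CApos[i, ],
                              GEOM$b_ca_c, GEOM$a_n_ca_c, phi[i])
    }
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    # carbonyl O: anti to the next N (torsion psi + 180 about N-CA-C)
    O <- place_atom(Npos[i, ], CApos[i, ], Cpos[i, ],
                    GEOM$b_c_o, GEOM$a_ca_c_o, psi[i] + 180)
    atoms <- list(N = Npos[i, ], CA = CApos[i, ], C = Cpos[i, ], O = O)
    if (aa[i] != "G") {
      # L-configuration beta carbon via an improper torsion
      atoms$CB <- place_atom(Npos[i, ], Cpos[i, ], CApos[i, ],
                             GEOM$b_ca_cb, GEOM$a_c_ca_cb, -121.5)
    }
    el <- substr(names(atoms), 1, 1)
    rows[[i]] <- tibble::tibble(
      chain = chain_id, resno = i, aa = aa[i],
      elety = names(atoms), element = el,
      x = vapply(atoms, `[`, 0, 1),
      y = vapply(atoms, `[`, 0, 2),
      z = vapply(atoms, `[`, 0, 3)
    )
  }
  out <- dplyr::bind_rows(rows)
  out$occ <- 1
  out$serial <- seq_len(nrow(out))
  out$modified <- FALSE
  out
}

#' Build an ideal alpha helix
#'
#' Backbone + CB atoms at ideal helical torsions (phi = -57, psi = -47).
#'
#' @param sequence one-letter amino acid string (length >= 6)
#' @param chain_id chain identifier
#' @return a [parse_structure()]-compatible structure object
#' @export
#' @examples
#' h <- build_ideal_helix(strrep("A", 12))
#' sequence_coverage(h, "A")
build_ideal_helix <- function(sequence, chain_id = "A") {
  if (nchar(sequence) < 6) stop("helix sequence must have >= 6 residues")
  atoms <- build_peptide_atoms(sequence, phi = -57, psi = -47, chain_id)
  structure_from_atoms("ideal_helix", atoms)
}

#' Build an extended peptide
#'
#' Backbone + CB atoms at extended torsions (phi = -120, psi = +120), the
#' conformation used for the Gly-X-Gly reference state.
#'
#' @inheritParams build_ideal_helix
#' @return a structure object
#' @export
build_extended_peptide <- function(sequence, chain_id = "A") {
  atoms <- build_peptide_atoms(sequence, phi = -120, psi = 120, chain_id)
  structure_from_atoms("extended_peptide", atoms)
}
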