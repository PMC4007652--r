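#' Amino acid lookup tables
#'
#' Internal constants shared across the package: one/three letter codes,
#' van der Waals radii, residue masses, side-chain volumes and the
#' hydrophobic residue set used in composition comparisons.
#'
#' @name aa_tables
#' @keywords internal
NULL

# 20 canonical residues, one-letter order
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
names(AA3) <- AA1

AA3_TO_1 <- stats::setNames(AA1, AA3)

# Phosphorylated residue HETATM names mapped to their parent amino acid
MODIFIED_AA <- c(SEP = "S", TPO = "T", PTR = "Y", HIP = "H", CSP = "C")

# Bondi van der Waals radii (Angstrom) by element
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52,
               S = 1.80, P = 1.80, SE = 1.90, F = 1.47)

# Average residue masses (Da); protein mass = sum + one water (18.02)
AA_MASS <- c(A = 71.08, R = 156.19, N = 114.10, D = 115.09, C = 103.14,
             Q = 128.13, E = 129.12, G = 57.05, H = 137.14, I = 113.16,
             L = 113.16, K = 128.17, M = 131.19, F = 147.18, P = 97.12,
             S = 87.08, T = 101.10, W = 186.21, Y = 163.18, V = 99.13)
WATER_MASS <- 18.02

# Mean residue volumes (Angstrom^3, Zamyatnin); used to size the single
# sphere that stands for a residue in the coarse-grained SASA model
AA_VOLUME <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
               Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
               L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
               S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)

# Kyte-Doolittle-positive residues, the hydrophobic set for composition
# comparisons between allowed and disallowed octapeptides
HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "F", "W", "C")

#' Coarse-grained residue radius
#'
#' Radius of the sphere representing a whole residue in the
#' coarse C-alpha model: the radius of a sphere with the residue's
#' mean volume.
#'
#' @param aa character vector of one-letter codes
#' @return numeric vector of radii in Angstrom
#' @keywords internal
coarse_radius <- function(aa) {
  v <- AA_VOLUME[aa]
  if (anyNA(v)) {
    stop("unknown residue code(s): ", paste(unique(aa[is.na(v)]), collapse = ", "))
  }
  unname((3 * v / (4 * pi))^(1 / 3))
}

aa_one_letter <- function(resid3) {
  out <- AA3_TO_1[resid3]
  mod <- MODIFIED_AA[resid3]
  out[!is.na(mod)] <- mod[!is.na(mod)]
  out[is.na(out)] <- "X"
  unname(out)
}
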