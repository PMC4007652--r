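#' Solvent accessible surface area by Shrake-Rupley sphere sampling
#'
#' Each atom is inflated by the probe radius and covered with a
#' deterministic generalized-spiral point lattice; the accessible fraction
#' of points (those not inside any neighbouring inflated sphere) times the
#' sphere area gives the atom's SASA. Per-residue areas are sums over
#' member atoms; %SASA divides by the residue's area in an extended
#' Gly-X-Gly tripeptide; rSASA averages %SASA over the octapeptide that
#' carries the phosphosite at position 4.
#'
#' @name sasa_engine
NULL

#' SASA computation parameters
#'
#' @param probe_radius solvent probe radius in Angstrom (water, 1.4)
#' @param n_sphere_points points per atom sphere (>= 92); more points give
#'   finer areas at linear cost
#' @param radii_set named van der Waals radius table by element symbol
#' @param reference_flank flanking residue of the extended reference
#'   tripeptide, `"G"` or `"A"`
#' @return a `sasa_params` list
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960,
                        radii_set = VDW_RADII, reference_flank = "G") {
  stopifnot(probe_radius > 0, n_sphere_points >= 92,
            reference_flank %in% c("G", "A"))
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 radii_set = radii_set,
                 reference_flank = reference_flank),
            class = "sasa_params")
}

#' Deterministic unit-sphere point lattice (generalized spiral)
#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

# core sampler on bare coordinates + radii; optionally returns the
# retained (solvent-accessible) sample points that define the surface
shrake_rupley <- function(xyz, radii, probe, n_points, return_surface = FALSE,
                          subset = NULL) {
  n <- nrow(xyz)
  pts <- fibonacci_sphere(n_points)
  R <- radii + probe
  areas <- rep(NA_real_, n)
  surface <- if (return_surface) vector("list", n) else NULL
  if (n == 0) return(list(areas = numeric(0), surface = NULL))
  d <- as.matrix(stats::dist(xyz))
  for (i in (subset %||% seq_len(n))) {
    sp <- sweep(pts * R[i], 2, xyz[i, ], "+")
    nb <- which(d[, i] < R[i] + R & seq_len(n) != i)
    acc <- rep(TRUE, n_points)
    if (length(nb)) {
      cj <- xyz[nb, , drop = FALSE]
      cross <- sp %*% t(cj)
      d2 <- outer(rowSums(sp^2), rep(1, length(nb))) +
        outer(rep(1, n_points), rowSums(cj^2)) - 2 * cross
      inside <- d2 < matrix(R[nb]^2, n_points, length(nb), byrow = TRUE)
      acc <- rowSums(inside) == 0
    }
    areas[i] <- 4 * pi * R[i]^2 * sum(acc) / n_points
    if (return_surface && any(acc)) surface[[i]] <- sp[acc, , drop = FALSE]
  }
  list(areas = areas,
       surface = if (return_surface) do.call(rbind, surface) else NULL)
}

atom_radii <- function(atoms, params) {
  el <- toupper(atoms$element)
  r <- params$radii_set[el]
  if (anyNA(r)) {
    bad <- unique(paste0(atoms$elety[is.na(r)], " (", el[is.na(r)], ")"))
    stop("no van der Waals radius for atom(s): ", paste(bad, collapse = ", "))
  }
  unname(r)
}

#' Per-atom solvent accessible surface area
#'
#' @param structure a `phospho_structure`
#' @param params a [sasa_params()] object
#' @return the `atoms` tibble with an added `sasa` column (Angstrom^2)
#' @export
atom_sasa <- function(structure, params = sasa_params()) {
  a <- structure$atoms
  res <- shrake_rupley(as.matrix(a[, c("x", "y", "z")]),
                       atom_radii(a, params),
                       params$probe_radius, params$n_sphere_points)
  a$sasa <- res$areas
  a
}

#' Per-residue solvent accessible surface area and %SASA
#'
#' Residue SASA is the sum of its atoms' areas; `percent_sasa` divides by
#' the residue's reference area in an extended Gly-X-Gly tripeptide
#' ([reference_sasa()]). The ratio is not clamped at 1.
#'
#' @inheritParams atom_sasa
#' @return tibble with `chain`, `resno`, `aa`, `sasa`, `ref_sasa`,
#'   `percent_sasa`, one row per observed residue
#' @export
residue_sasa <- function(structure, params = sasa_params()) {
  a <- atom_sasa(structure, params)
  out <- dplyr::summarise(
    dplyr::group_by(a, .data$chain, .data$resno, .data$aa),
    sasa = sum(.data$sasa), .groups = "drop"
  )
  out$ref_sasa <- vapply(out$aa, reference_sasa, 0, params = params)
  out$percent_sasa <- out$sasa / out$ref_sasa
  dplyr::arrange(out, .data$chain, .data$resno)
}

# cache of reference areas, keyed by residue + parameters
.ref_cache <- new.env(parent = emptyenv())

#' Extended-tripeptide reference area of a residue
#'
#' SASA of residue X in an extended (phi = -120, psi = +120) Gly-X-Gly (or
#' Ala-X-Ala) tripeptide built programmatically with backbone + CB atoms.
#' Values are computed once per parameter set and cached.
#'
#' @param aa one-letter amino acid code
#' @param params a [sasa_params()] object
#' @param flank flanking residue, defaults to the one in `params`
#' @return reference area in Angstrom^2
#' @export
reference_sasa <- function(aa, params = sasa_params(), flank = NULL) {
  flank <- flank %||% params$reference_flank
  if (!aa %in% AA1) stop("non-canonical residue: ", aa)
  key <- paste(aa, flank, params$probe_radius, params$n_sphere_points, sep = "|")
  hit <- .ref_cache[[key]]
  if (!is.null(hit)) return(hit)
  tri <- build_extended_peptide(paste0(flank, aa, flank))
  rs <- atom_sasa(tri, params)
  val <- sum(rs$sasa[rs$resno == 2])
  assign(key, val, envir = .ref_cache)
  val
}

# %SASA for a subset of residues without computing the whole structure:
# occluders are all atoms, but areas are sampled only for the subset
residue_percent_subset <- function(structure, chain, resnos, params) {
  a <- structure$atoms
  idx <- which(a$chain == chain & a$resno %in% resnos)
  if (length(idx) == 0) stop("no atoms for requested residues")
  res <- shrake_rupley(as.matrix(a[, c("x", "y", "z")]),
                       atom_radii(a, params),
                       params$probe_radius, params$n_sphere_points,
                       subset = idx)
  sub <- a[idx, ]
  sub$sasa <- res$areas[idx]
  out <- dplyr::summarise(
    dplyr::group_by(sub, .data$chain, .data$resno, .data$aa),
    sasa = sum(.data$sasa), .groups = "drop"
  )
  out$ref_sasa <- vapply(out$aa, reference_sasa, 0, params = params)
  out$percent_sasa <- out$sasa / out$ref_sasa
  dplyr::arrange(out, .data$resno)
}

#' Octapeptide rSASA
#'
#' Mean %SASA over the eight residues of the octapeptide surrounding a
#' phosphosite (phosphoresidue at window position 4). All eight residues
#' must be observed; a window touching a disordered residue belongs in the
#' disordered category, not here.
#'
#' @param structure a `phospho_structure`
#' @param chain chain identifier
#' @param seqpos integer vector of the 8 primary-sequence positions
#' @param params a [sasa_params()] object
#' @param percent optional precomputed [residue_sasa()] table, to avoid
#'   recomputing SASA per site
#' @return rSASA (dimensionless)
#' @export
octapeptide_rsasa <- function(structure, chain, seqpos,
                              params = sasa_params(), percent = NULL) {
  if (length(seqpos) != 8) stop("an octapeptide has exactly 8 residues")
  res <- structure$residues
  sel <- res[res$chain == chain & res$seqpos %in% seqpos, ]
  if (nrow(sel) != 8) stop("octapeptide positions absent from chain ", chain)
  if (!all(sel$is_observed)) {
    stop("incomplete octapeptide: residue(s) without coordinates (disordered)")
  }
  if (is.null(percent)) {
    percent <- residue_percent_subset(structure, chain, sel$resno, params)
  }
  p <- percent[percent$chain == chain & percent$resno %in% sel$resno, ]
  if (nrow(p) != 8) stop("SASA unavailable for some octapeptide residues")
  mean(p$percent_sasa)
}

#' Coarse-grained per-residue SASA on a C-alpha model
#'
#' Conformers generated from the elastic network model carry only C-alpha
#' positions, so each residue is represented by a single sphere sized to
#' the residue's mean volume. %SASA is normalised by coarse reference
#' values computed from the same single-sphere convention on an extended
#' three-residue trace (3.8 Angstrom C-alpha spacing).
#'
#' @param coords N x 3 matrix of C-alpha coordinates
#' @param aa character vector of one-letter residue codes, length N
#' @param params a [sasa_params()] object
#' @return tibble with `idx`, `aa`, `sasa`, `ref_sasa`, `percent_sasa`
#' @export
coarse_residue_sasa <- function(coords, aa, params = sasa_params(),
                                subset = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) != length(aa)) stop("coords/aa length mismatch")
  if (anyDuplicated(coords)) stop("duplicate residue positions")
  res <- shrake_rupley(coords, coarse_radius(aa),
                       params$probe_radius, params$n_sphere_points,
                       subset = subset)
  ref <- vapply(aa, coarse_reference_sasa, 0, params = params)
  out <- tibble::tibble(idx = seq_along(aa), aa = aa, sasa = res$areas,
                        ref_sasa = unname(ref),
                        percent_sasa = res$areas / unname(ref))
  if (!is.null(subset)) out <- out[subset, ]
  out
}

coarse_reference_sasa <- function(aa, params = sasa_params()) {
  key <- paste("coarse", aa, params$reference_flank,
               params$probe_radius, params$n_sphere_points, sep = "|")
  hit <- .ref_cache[[key]]
  if (!is.null(hit)) return(hit)
  flank <- params$reference_flank
  coords <- rbind(c(-3.8, 0, 0), c(0, 0, 0), c(3.8, 0, 0))
  res <- shrake_rupley(coords, coarse_radius(c(flank, aa, flank)),
                       params$probe_radius, params$n_sphere_points)
  val <- res$areas[2]
  assign(key, val, envir = .ref_cache)
  val
}

#' Residue depth below the solvent-accessible surface
#'
#' The accessible surface is the set of sphere-sample points retained by
#' the Shrake-Rupley sampler. An atom's depth is its distance to the
#' nearest surface point minus its own solvent-contact radius (so fully
#' exposed atoms score ~0); residue depth is the mean over its atoms.
#' Larger values mean the residue is farther below the protein surface.
#'
#' @inheritParams atom_sasa
#' @return tibble with `chain`, `resno`, `aa`, `depth` (Angstrom)
#' @export
residue_depth <- function(structure, params = sasa_params()) {
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- atom_radii(a, params)
  sr <- shrake_rupley(xyz, radii, params$probe_radius,
                      params$n_sphere_points, return_surface = TRUE)
  if (is.null(sr$surface)) stop("structure has zero accessible surface")
  surf <- sr$surface
  # nearest surface point per atom, blockwise to bound memory
  mind <- numeric(nrow(xyz))
  block <- 2000L
  s2 <- rowSums(surf^2)
  for (start in seq(1, nrow(xyz), by = block)) {
    idx <- start:min(start + block - 1, nrow(xyz))
    d2 <- outer(rowSums(xyz[idx, , drop = FALSE]^2), rep(1, nrow(surf))) +
      outer(rep(1, length(idx)), s2) -
      2 * xyz[idx, , drop = FALSE] %*% t(surf)
    mind[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  a$depth <- pmax(mind - (radii + params$probe_radius), 0)
  out <- dplyr::summarise(
    dplyr::group_by(a, .data$chain, .data$resno, .data$aa),
    depth = mean(.data$depth), .groups = "drop"
  )
  dplyr::arrange(out, .data$chain, .data$resno)
}
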