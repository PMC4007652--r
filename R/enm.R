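#' C-alpha elastic network model and normal mode analysis
#'
#' Each residue is a single node at its C-alpha position; pairs closer
#' than the cutoff `R_C` (10 Angstrom by default) are connected by
#' identical harmonic springs restrained to their distance in the input
#' structure:
#'
#'   E = 1/2 k sum over contacts (d_ij - d0_ij)^2
#'
#' Diagonalising the Hessian of this potential at the input structure
#' yields 3N-6 vibrational modes plus 6 zero-frequency rigid-body modes.
#' Conformer ensembles are generated by displacing the structure at
#' evenly spaced amplitudes along the lowest-frequency modes: with the
#' default 20 modes and 20 steps per mode the ensemble holds
#' 20 x 20 + 1 = 401 conformers including the input structure.
#'
#' @name enm_nma
NULL

#' Build a C-alpha elastic network model
#'
#' @param structure a `phospho_structure` (or an N x 3 C-alpha coordinate
#'   matrix with an `aa` attribute)
#' @param chain_id chain to model (default first chain)
#' @param R_C contact cutoff in Angstrom
#' @param k uniform spring constant (arbitrary units; only mode shapes
#'   and orderings matter)
#' @param max_gap interior stretches of up to this many consecutive
#'   unobserved residues are bridged by linear interpolation of C-alpha
#'   positions; larger gaps reject the structure
#' @return an object of class `phospho_enm` with `coords`, `aa`,
#'   `contacts` (tibble i, j, d0), `k`, `R_C`
#' @export
build_enm <- function(structure, chain_id = NULL, R_C = 10, k = 1, max_gap = 2) {
  seqpos <- NULL
  if (is.matrix(structure)) {
    coords <- structure
    aa <- attr(structure, "aa") %||% rep("A", nrow(coords))
    seqpos <- seq_len(nrow(coords))
  } else {
    chain_id <- chain_id %||% structure$chains$chain[1]
    res <- structure$residues[structure$residues$chain == chain_id, ]
    obs <- res[res$is_observed, ]
    ca <- ca_coords(structure, chain_id)
    if (nrow(ca$coords) < nrow(obs)) {
      missing_ca <- setdiff(obs$resno, ca$resno)
      stop("residue(s) without a C-alpha atom: ",
           paste(utils::head(missing_ca, 5), collapse = ", "))
    }
    filled <- fill_gaps(res, ca, max_gap)
    coords <- filled$coords
    aa <- filled$aa
    seqpos <- filled$seqpos
  }
  n <- nrow(coords)
  if (n < 4) stop("elastic network needs at least 4 residues")
  if (qr(sweep(coords, 2, colMeans(coords)))$rank < 2) {
    stop("collinear coordinates cannot form a 3D elastic network")
  }
  d <- as.matrix(stats::dist(coords))
  pair <- which(upper.tri(d) & d <= R_C & d > 0, arr.ind = TRUE)
  # d0 evaluated with the same expression enm_energy uses, so the energy
  # at the input structure is exactly zero
  d0 <- sqrt(rowSums((coords[pair[, 1], , drop = FALSE] -
                        coords[pair[, 2], , drop = FALSE])^2))
  contacts <- tibble::tibble(i = pair[, 1], j = pair[, 2], d0 = d0)
  structure(list(coords = coords, aa = aa, contacts = contacts,
                 k = k, R_C = R_C, seqpos = seqpos),
            class = "phospho_enm")
}

# interpolate C-alpha positions across short unobserved interior
# stretches; terminal gaps are dropped
fill_gaps <- function(res, ca, max_gap) {
  res <- res[order(res$seqpos), ]
  obs_idx <- which(res$is_observed)
  first <- min(obs_idx); last <- max(obs_idx)
  inner <- res[first:last, ]
  miss <- !inner$is_observed
  if (any(miss)) {
    runs <- rle(miss)
    if (any(runs$lengths[runs$values] > max_gap)) {
      stop("unobserved interior stretch longer than ", max_gap,
           " residues; structure not eligible for the elastic network")
    }
  }
  m <- match(inner$resno, ca$resno)
  coords <- matrix(NA_real_, nrow(inner), 3)
  coords[!is.na(m), ] <- ca$coords[m[!is.na(m)], ]
  for (ii in which(is.na(m))) {
    prev <- max(which(!is.na(m[1:ii])))
    nxt <- ii + min(which(!is.na(m[(ii + 1):length(m)])))
    w <- (ii - prev) / (nxt - prev)
    coords[ii, ] <- (1 - w) * coords[prev, ] + w * coords[nxt, ]
  }
  list(coords = coords, aa = inner$aa, seqpos = inner$seqpos)
}

#' Elastic network potential energy
#'
#' `E = 1/2 k sum (d_ij - d0_ij)^2` over the model's contacts. Exactly 0
#' at the input structure.
#'
#' @param coords N x 3 coordinate matrix
#' @param model a `phospho_enm`
#' @return energy in model units
#' @export
enm_energy <- function(coords, model) {
  coords <- as.matrix(coords)
  if (!all(dim(coords) == dim(model$coords))) {
    stop("coordinate matrix incongruent with the model")
  }
  dij <- sqrt(rowSums((coords[model$contacts$i, , drop = FALSE] -
                         coords[model$contacts$j, , drop = FALSE])^2))
  0.5 * model$k * sum((dij - model$contacts$d0)^2)
}

enm_hessian <- function(model) {
  n <- nrow(model$coords)
  H <- matrix(0, 3 * n, 3 * n)
  for (r in seq_len(nrow(model$contacts))) {
    i <- model$contacts$i[r]; j <- model$contacts$j[r]
    u <- (model$coords[i, ] - model$coords[j, ]) / model$contacts$d0[r]
    B <- model$k * tcrossprod(u)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, ii] <- H[ii, ii] + B
    H[jj, jj] <- H[jj, jj] + B
    H[ii, jj] <- H[ii, jj] - B
    H[jj, ii] <- H[jj, ii] - B
  }
  H
}

#' Normal modes of the elastic network
#'
#' Assembles the 3N x 3N Hessian of the harmonic potential at the input
#' structure (uniform unit masses) and diagonalises it. A connected
#' network has exactly 6 near-zero eigenvalues (rigid-body translations
#' and rotations); more indicate a disconnected network.
#'
#' @param model a `phospho_enm`
#' @return object of class `phospho_enm_modes`: `eigenvalues` (ascending),
#'   `eigenvectors` (orthonormal columns, same order), `n_zero`
#' @export
normal_modes <- function(model) {
  H <- enm_hessian(model)
  eig <- eigen(H, symmetric = TRUE)
  vals <- rev(eig$values)
  vecs <- eig$vectors[, rev(seq_along(eig$values)), drop = FALSE]
  tol <- 1e-8 * max(vals)
  n_zero <- sum(vals < tol)
  if (n_zero > 6) {
    stop("more than 6 near-zero modes: elastic network is disconnected ",
         "(increase R_C or reject the structure)")
  }
  structure(list(eigenvalues = pmax(vals, 0), eigenvectors = vecs,
                 n_zero = n_zero, n_atoms = nrow(model$coords)),
            class = "phospho_enm_modes")
}

#' @export
print.phospho_enm_modes <- function(x, ...) {
  cat("<phospho_enm_modes>", x$n_atoms, "residues;",
      length(x$eigenvalues) - x$n_zero, "vibrational modes,",
      x$n_zero, "rigid-body modes\n")
  invisible(x)
}

#' Generate a conformer ensemble along low-frequency modes
#'
#' For each of the `n_modes` lowest-frequency vibrational modes the
#' structure is displaced at `n_steps` evenly spaced amplitudes spanning
#' both directions of the mode (zero excluded); the input structure is
#' included, giving `n_modes * n_steps + 1` conformers (401 with the
#' defaults). Amplitudes are scaled so the largest single-residue
#' displacement of the extreme conformer equals `max_amp`.
#'
#' @param model a `phospho_enm`
#' @param mode_set a `phospho_enm_modes` (computed from `model` if NULL)
#' @param n_modes number of vibrational modes to sample
#' @param n_steps conformers per mode
#' @param max_amp maximum C-alpha displacement in Angstrom
#' @return object of class `phospho_conformers`: list with `conformers`
#'   (list of N x 3 matrices, input first) and `provenance` tibble
#'   (`mode`, `step`, `amplitude`; NA for the input structure)
#' @export
generate_conformers <- function(model, mode_set = NULL, n_modes = 20,
                                n_steps = 20, max_amp = 2.0) {
  if (max_amp <= 0) stop("max_amp must be positive")
  if (is.null(mode_set)) mode_set <- normal_modes(model)
  n_vib <- length(mode_set$eigenvalues) - mode_set$n_zero
  if (n_modes > n_vib) {
    warning("only ", n_vib, " vibrational modes available; using all")
    n_modes <- n_vib
  }
  n <- mode_set$n_atoms
  conformers <- list(model$coords)
  prov <- list(tibble::tibble(mode = NA_integer_, step = NA_integer_,
                              amplitude = NA_real_))
  half <- n_steps %/% 2
  fracs <- if (n_steps %% 2 == 0) {
    c(-rev(seq_len(half)), seq_len(half)) / half
  } else {
    c(-rev(seq_len(half)), seq_len(half + 1)) / (half + 1)
  }
  for (m in seq_len(n_modes)) {
    v <- mode_set$eigenvectors[, mode_set$n_zero + m]
    disp <- matrix(v, ncol = 3, byrow = TRUE)
    scale <- max_amp / max(sqrt(rowSums(disp^2)))
    for (s in seq_along(fracs)) {
      conformers[[length(conformers) + 1]] <-
        model$coords + fracs[s] * scale * disp
      prov[[length(prov) + 1]] <-
        tibble::tibble(mode = m, step = s, amplitude = fracs[s] * scale)
    }
  }
  structure(list(conformers = conformers,
                 provenance = dplyr::bind_rows(prov),
                 aa = model$aa, seqpos = model$seqpos),
            class = "phospho_conformers")
}

#' Octapeptide rSASA across a conformer ensemble
#'
#' Applies the coarse single-sphere-per-residue SASA to every conformer
#' and averages %SASA over the site's 8 residues.
#'
#' @param ensemble a `phospho_conformers`
#' @param site_idx indices (into the model's residues) of the 8
#'   octapeptide residues
#' @param params a [sasa_params()] object
#' @return tibble with one row per conformer (`conformer`, `mode`, `step`,
#'   `rsasa`); attribute `max_rsasa` holds the ensemble maximum
#' @export
ensemble_rsasa <- function(ensemble, site_idx, params = sasa_params()) {
  if (length(site_idx) != 8) stop("an octapeptide has exactly 8 residues")
  n <- nrow(ensemble$conformers[[1]])
  if (any(site_idx < 1 | site_idx > n)) stop("site residues outside the model")
  vals <- vapply(ensemble$conformers, function(xyz) {
    cs <- coarse_residue_sasa(xyz, ensemble$aa, params, subset = site_idx)
    mean(cs$percent_sasa)
  }, 0)
  out <- dplyr::bind_cols(
    tibble::tibble(conformer = seq_along(vals)),
    ensemble$provenance, tibble::tibble(rsasa = vals)
  )
  attr(out, "max_rsasa") <- max(vals)
  out
}

#' Reclassify a buried site from ensemble dynamics
#'
#' A site initially in the disallowed region is moved to the allowed
#' region when any low-energy conformer exposes it above the rSASA
#' threshold; otherwise it stays disallowed (the negative-control
#' behaviour, where every conformer remains buried).
#'
#' @param input_rsasa the site's rSASA in the input structure
#' @param ensemble_rsasa_values per-conformer rSASA values
#' @param threshold accessibility threshold (0.2)
#' @return tibble with `label`, `rescue`, `max_conformer_rsasa`
#' @export
reclassify_by_dynamics <- function(input_rsasa, ensemble_rsasa_values,
                                   threshold = 0.2) {
  if (input_rsasa >= threshold) {
    return(tibble::tibble(label = "allowed", rescue = "none",
                          max_conformer_rsasa = max(ensemble_rsasa_values)))
  }
  mx <- max(ensemble_rsasa_values)
  if (mx > threshold) {
    tibble::tibble(label = "allowed", rescue = "dynamics",
                   max_conformer_rsasa = mx)
  } else {
    tibble::tibble(label = "disallowed", rescue = "none",
                   max_conformer_rsasa = mx)
  }
}

#' @rdname tidiers
#' @export
tidy.phospho_enm_modes <- function(x, ...) {
  tibble::tibble(
    mode = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    rigid_body = seq_along(x$eigenvalues) <= x$n_zero
  )
}

#' @rdname tidiers
#' @export
glance.phospho_enm_modes <- function(x, ...) {
  tibble::tibble(
    n_residues = x$n_atoms,
    n_modes = length(x$eigenvalues),
    n_zero = x$n_zero,
    n_vibrational = length(x$eigenvalues) - x$n_zero,
    max_eigenvalue = max(x$eigenvalues)
  )
}
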