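#' Secondary structure assignment
#'
#' A DSSP/Stride-style assigner collapsed to four classes: H (helix),
#' E (sheet), T (turn), C (coil). Backbone amide hydrogens are placed
#' geometrically (N-H anti-parallel to the preceding C=O) and hydrogen
#' bonds are detected with the Kabsch-Sander electrostatic energy at the
#' conventional -0.5 kcal/mol threshold. Helices require the i -> i+4
#' H-bond ladder on helical phi/psi; strands require a cross-strand
#' H-bond on extended phi/psi; tight turns are i -> i+3 H-bonds outside
#' helices; everything else is coil.
#'
#' @name secondary_structure
NULL

ks_energy <- function(N, H, C, O) {
  # Kabsch-Sander electrostatic H-bond energy (kcal/mol)
  q1q2f <- 0.084 * 332
  d <- function(p, q) sqrt(sum((p - q)^2))
  q1q2f * (1 / d(O, N) + 1 / d(C, H) - 1 / d(O, H) - 1 / d(C, N))
}

backbone_frames <- function(structure, chain_id) {
  a <- structure$atoms[structure$atoms$chain == chain_id, ]
  res <- structure$residues[structure$residues$chain == chain_id &
                              structure$residues$is_observed, ]
  res <- res[order(res$seqpos), ]
  get <- function(rn, ety) {
    row <- a[a$resno == rn & a$elety == ety, ]
    if (nrow(row) == 0) return(NULL)
    c(row$x[1], row$y[1], row$z[1])
  }
  n <- nrow(res)
  bb <- vector("list", n)
  for (i in seq_len(n)) {
    bb[[i]] <- list(N = get(res$resno[i], "N"), CA = get(res$resno[i], "CA"),
                    C = get(res$resno[i], "C"), O = get(res$resno[i], "O"))
  }
  list(res = res, bb = bb)
}

dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Assign per-residue secondary structure
#'
#' @param structure a `phospho_structure`
#' @param chain_id chain to assign (default: first chain)
#' @return tibble with `chain`, `resno`, `seqpos`, `aa`, `ss`
#'   (`ss` in H/E/T/C); residues with missing backbone atoms are labelled
#'   C with a warning
#' @export
assign_secondary_structure <- function(structure, chain_id = NULL) {
  chain_id <- chain_id %||% structure$chains$chain[1]
  fr <- backbone_frames(structure, chain_id)
  res <- fr$res; bb <- fr$bb
  n <- nrow(res)
  complete <- vapply(bb, function(b) !any(vapply(b, is.null, TRUE)), TRUE)
  if (!all(complete)) warning("missing backbone atoms; residues labelled C")

  # amide H from the previous residue carbonyl: H = N + unit(C_prev - O_prev)
  H <- vector("list", n)
  for (i in 2:max(n, 2)) {
    if (i > n) break
    if (complete[i] && complete[i - 1] && res$seqpos[i] == res$seqpos[i - 1] + 1) {
      v <- bb[[i - 1]]$C - bb[[i - 1]]$O
      H[[i]] <- bb[[i]]$N + v / sqrt(sum(v^2))
    }
  }

  # H-bond matrix: donor i (N-H) to acceptor j (C=O)
  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    if (is.null(H[[i]]) || !complete[i]) next
    for (j in seq_len(n)) {
      if (abs(res$seqpos[i] - res$seqpos[j]) < 2 || !complete[j]) next
      if (sqrt(sum((bb[[i]]$N - bb[[j]]$O)^2)) > 5.2) next
      e <- ks_energy(bb[[i]]$N, H[[i]], bb[[j]]$C, bb[[j]]$O)
      hb[i, j] <- e < -0.5
    }
  }

  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1 && complete[i] && complete[i - 1] &&
        res$seqpos[i] == res$seqpos[i - 1] + 1) {
      phi[i] <- dihedral_deg(bb[[i - 1]]$C, bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C)
    }
    if (i < n && complete[i] && complete[i + 1] &&
        res$seqpos[i + 1] == res$seqpos[i] + 1) {
      psi[i] <- dihedral_deg(bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C, bb[[i + 1]]$N)
    }
  }
  helical_phipsi <- !is.na(phi) & !is.na(psi) &
    phi > -120 & phi < -20 & psi > -90 & psi < 10
  extended_phipsi <- (is.na(phi) | (phi > -180 & phi < -45)) &
    (is.na(psi) | (psi > 60 & psi <= 180) | (psi >= -180 & psi < -150))

  ss <- rep("C", n)
  # helix: i -> i+4 ladder (acceptor i, donor i+4) marks i+1..i+4
  hb44 <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (i + 4 <= n && res$seqpos[i + 4] == res$seqpos[i] + 4 && hb[i + 4, i]) {
      hb44[i] <- TRUE
    }
  }
  for (i in which(hb44)) {
    span <- (i + 1):(i + 4)
    ss[span][helical_phipsi[span]] <- "H"
  }
  # sheet: extended residue with a long-range H-bond (either direction)
  for (i in seq_len(n)) {
    if (ss[i] != "C" || !extended_phipsi[i]) next
    partners <- which(hb[i, ] | hb[, i])
    if (any(abs(res$seqpos[partners] - res$seqpos[i]) >= 5)) ss[i] <- "E"
  }
  # also label extended neighbours bracketed by sheet residues (the
  # non-H-bonded partner positions of an antiparallel ladder)
  for (i in 2:max(n - 1, 2)) {
    if (i >= n) break
    if (ss[i] == "C" && extended_phipsi[i] && ss[i - 1] == "E" && ss[i + 1] == "E") {
      ss[i] <- "E"
    }
  }
  # turn: i -> i+3 H-bond, residues in between not already helical
  for (i in seq_len(n)) {
    if (i + 3 <= n && res$seqpos[i + 3] == res$seqpos[i] + 3 && hb[i + 3, i]) {
      span <- (i + 1):(i + 2)
      ss[span][ss[span] == "C"] <- "T"
    }
  }
  tibble::tibble(chain = chain_id, resno = res$resno, seqpos = res$seqpos,
                 aa = res$aa, ss = ss)
}

#' Secondary-structure string of an octapeptide
#'
#' @param structure a `phospho_structure`
#' @param chain chain identifier
#' @param seqpos the 8 primary-sequence positions of the octapeptide
#' @param ss_table optional precomputed [assign_secondary_structure()] table
#' @return 8-character string over H/E/T/C
#' @export
octapeptide_ss <- function(structure, chain, seqpos, ss_table = NULL) {
  if (length(seqpos) != 8) stop("an octapeptide has exactly 8 residues")
  if (is.null(ss_table)) ss_table <- assign_secondary_structure(structure, chain)
  m <- match(seqpos, ss_table$seqpos)
  if (anyNA(m)) stop("octapeptide includes residues without coordinates")
  paste(ss_table$ss[m], collapse = "")
}

#' Octapeptide conformation-class composition
#'
#' Reduces each octapeptide's 8-label string to its dominant class
#' (majority label, ties resolved H > E > T > C) and returns the fraction
#' of sites per class.
#'
#' @param ss_strings character vector of 8-label strings
#' @return tibble with `class` (helix/sheet/turn/coil), `n`, `fraction`
#' @export
ss_composition <- function(ss_strings) {
  if (length(ss_strings) == 0) stop("no octapeptide secondary structures given")
  prio <- c(H = 1, E = 2, T = 3, C = 4)
  dom <- vapply(ss_strings, function(s) {
    tab <- table(strsplit(s, "")[[1]])
    cand <- names(tab)[tab == max(tab)]
    cand[order(prio[cand])][1]
  }, "")
  lab <- c(H = "helix", E = "sheet", T = "turn", C = "coil")
  out <- tibble::tibble(class = factor(lab[dom], levels = unname(lab)))
  out <- dplyr::count(out, .data$class, .drop = FALSE)
  out$fraction <- out$n / sum(out$n)
  out
}
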