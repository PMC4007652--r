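#' Synthetic structures and cohorts with planted ground truth
#'
#' Every stage of the pipeline is testable without external downloads:
#' the generator builds idealised protein architectures (helix bundles,
#' buried cores, oligomer interfaces, mobile flaps) whose accessibility
#' properties are known by construction and verified by rejection
#' sampling at generation time (the structure is rebuilt with perturbed
#' packing if a SASA assertion fails). Structures carry backbone + CB
#' atoms only; the extended-tripeptide reference areas use the same
#' reduced-atom convention, so %SASA stays calibrated.
#'
#' @name synthetic_data
NULL

rotation_about <- function(axis, ang) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) * cos(ang) + sin(ang) * K + (1 - cos(ang)) * tcrossprod(a)
}

# centre a segment on its C-alpha centroid with the principal axis on x
center_segment <- function(atoms, ca_subset = NULL) {
  ca <- atoms[atoms$elety == "CA", ]
  if (!is.null(ca_subset)) ca <- ca[ca$resno %in% ca_subset, ]
  cam <- as.matrix(ca[, c("x", "y", "z")])
  mu <- colMeans(cam)
  R <- t(stats::prcomp(cam)$rotation)
  if (det(R) < 0) R[3, ] <- -R[3, ]
  xyz <- sweep(as.matrix(atoms[, c("x", "y", "z")]), 2, mu) %*% t(R)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

shift_segment <- function(atoms, t) {
  atoms$x <- atoms$x + t[1]; atoms$y <- atoms$y + t[2]; atoms$z <- atoms$z + t[3]
  atoms
}

rotate_segment <- function(atoms, R) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

# concatenate placed segments into one chain with sequential numbering
combine_segments <- function(segs, id, chain_id = "A") {
  atoms <- dplyr::bind_rows(segs)
  key <- paste(rep(seq_along(segs), vapply(segs, nrow, 0L)), atoms$resno)
  atoms$resno <- as.integer(factor(key, levels = unique(key)))
  atoms$chain <- chain_id
  atoms$serial <- seq_len(nrow(atoms))
  structure_from_atoms(id, atoms)
}

# run code with a private RNG stream, leaving the global seed untouched
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_sequence <- function(n) paste(sample(AA1, n, replace = TRUE), collapse = "")

#' Build an antiparallel two-strand beta sheet
#'
#' Two extended strands (phi = -139, psi = +135) paired antiparallel; the
#' inter-strand placement is chosen by a deterministic grid search
#' maximising the number of backbone N...O contacts at hydrogen-bonding
#' distance. Used as the strand fixture for secondary-structure tests.
#'
#' @param n_res residues per strand
#' @return a `phospho_structure` with one chain of `2 * n_res` residues
#' @export
build_beta_hairpin <- function(n_res = 8) {
  s1 <- center_segment(build_peptide_atoms(strrep("A", n_res), -139, 135))
  s2_base <- center_segment(build_peptide_atoms(strrep("A", n_res), -139, 135))
  bb_of <- function(at) {
    g <- function(e) as.matrix(at[at$elety == e, c("x", "y", "z")])
    N <- g("N"); C <- g("C"); O <- g("O")
    # amide H anti to the preceding carbonyl (first residue has none)
    H <- N * NA
    for (i in 2:nrow(N)) {
      v <- C[i - 1, ] - O[i - 1, ]
      H[i, ] <- N[i, ] + v / sqrt(sum(v^2))
    }
    list(N = N, C = C, O = O, H = H)
  }
  b1 <- bb_of(s1)
  dmat <- function(A, B) {
    sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B), 0))
  }
  # count donor->acceptor pairs below the Kabsch-Sander -0.5 kcal/mol
  # threshold, both strand directions
  score <- function(at) {
    b2 <- bb_of(at)
    f <- 0.084 * 332
    e12 <- f * (1 / dmat(b1$N, b2$O) + 1 / dmat(b1$H, b2$C) -
                  1 / dmat(b1$H, b2$O) - 1 / dmat(b1$N, b2$C))
    e21 <- f * (1 / dmat(b2$N, b1$O) + 1 / dmat(b2$H, b1$C) -
                  1 / dmat(b2$H, b1$O) - 1 / dmat(b2$N, b1$C))
    sum(e12 < -0.5, na.rm = TRUE) + sum(e21 < -0.5, na.rm = TRUE)
  }
  best <- NULL; best_score <- -1
  # orientation search: reverse the strand direction (two flip choices),
  # spin about the strand axis, then translate into H-bond register
  for (flip_axis in list(c(0, 0, 1), c(0, 1, 0))) {
    flipped <- rotate_segment(s2_base, rotation_about(flip_axis, pi))
    for (spin in seq(0, 330, by = 30) * pi / 180) {
      oriented <- rotate_segment(flipped, rotation_about(c(1, 0, 0), spin))
      for (dy in seq(4.4, 5.4, by = 0.2)) {
        for (dx in seq(-2, 2, by = 0.5)) {
          for (dz in seq(-1.5, 1.5, by = 0.5)) {
            cand <- shift_segment(oriented, c(dx, dy, dz))
            sc <- score(cand)
            if (sc > best_score) { best_score <- sc; best <- cand }
          }
        }
      }
    }
  }
  # local refinement around the best placement
  anchor <- c(mean(best$x) - mean(s2_base$x),
              mean(best$y) - mean(s2_base$y),
              mean(best$z) - mean(s2_base$z))
  base_or <- shift_segment(best, -anchor)
  for (dy in seq(-0.3, 0.3, by = 0.1)) {
    for (dx in seq(-0.4, 0.4, by = 0.1)) {
      for (dz in seq(-0.4, 0.4, by = 0.1)) {
        cand <- shift_segment(base_or, anchor + c(dx, dy, dz))
        sc <- score(cand)
        if (sc > best_score) { best_score <- sc; best <- cand }
      }
    }
  }
  combine_segments(list(s1, best), "beta_hairpin")
}

# shared layout of the globular fixture: a buried helical core wrapped by
# a helix shell with end caps, plus a fully exposed extended surface
# segment; returns the structure and the seqpos ranges of core/surface
globule_layout <- function(core_seq, arm_seq, jitter = c(0, 0)) {
  segs <- list()
  segs$core <- center_segment(build_peptide_atoms(core_seq, -57, -47))
  r_shell <- 7.5 + jitter[1]
  for (k in 0:5) {
    ang <- 2 * pi * k / 6 + jitter[2]
    h <- center_segment(build_peptide_atoms(strrep("A", 14), -57, -47))
    segs[[paste0("shell", k)]] <-
      shift_segment(h, c(0, r_shell * cos(ang), r_shell * sin(ang)))
  }
  for (sgn in c(-1, 1)) {
    h <- center_segment(build_peptide_atoms(strrep("A", 12), -57, -47))
    h <- rotate_segment(h, rotation_about(c(0, 0, 1), pi / 2))
    segs[[paste0("cap", sgn)]] <- shift_segment(h, c(sgn * 10, 0, 0))
  }
  # the surface segment uses polyproline-II-like torsions: still open and
  # exposed, but compact enough that every residue keeps >= 3 elastic
  # network contacts (a fully extended strand leaves chain-end nodes with
  # 2 contacts, i.e. zero-frequency mechanisms)
  segs$arm <- shift_segment(
    center_segment(build_peptide_atoms(arm_seq, -75, 145)), c(0, 0, 16))
  n_before_arm <- 8 + 6 * 14 + 2 * 12
  list(segs = segs,
       core_range = 1:8,
       arm_range = n_before_arm + seq_len(nchar(arm_seq)))
}

#' Build a synthetic globule with a buried core and an exposed surface site
#'
#' A helical core octapeptide is wrapped in a shell of helices with end
#' caps; an extended surface segment is held away from the body. Ground
#' truth is asserted at generation time: the core octapeptide has rSASA
#' < 0.1 and the surface octapeptide > 0.4, with shell packing perturbed
#' and rebuilt (up to `max_tries`) if either check fails.
#'
#' @param seed integer seed controlling sequence and packing jitter
#' @param core_seq 8-residue core sequence (default carries S at
#'   position 4 without a kinase motif)
#' @param arm_seq extended surface segment sequence (>= 10 residues;
#'   the surface octapeptide is its residues 3-10)
#' @param max_tries rejection-sampling budget
#' @param params SASA parameters used for the generation-time checks
#' @return a `phospho_structure` with attributes `core_seqpos` and
#'   `surface_seqpos` (the planted octapeptide positions)
#' @export
build_globule <- function(seed = 1, core_seq = "LVASAILV",
                          arm_seq = "AAAVSLIAKAAA", max_tries = 5,
                          params = sasa_params()) {
  stopifnot(nchar(core_seq) == 8, nchar(arm_seq) >= 10)
  for (try in seq_len(max_tries)) {
    jit <- with_local_seed(seed * 131 + try, stats::runif(2, -0.2, 0.2))
    lay <- globule_layout(core_seq, arm_seq, jitter = jit)
    g <- combine_segments(lay$segs, paste0("globule_", seed))
    surf8 <- lay$arm_range[2:9]
    core_ok <- octapeptide_rsasa(g, "A", lay$core_range, params) < 0.1
    surf_ok <- octapeptide_rsasa(g, "A", surf8, params) > 0.4
    if (core_ok && surf_ok) {
      attr(g, "core_seqpos") <- lay$core_range
      attr(g, "surface_seqpos") <- surf8
      return(g)
    }
  }
  stop("could not build a globule satisfying the burial checks")
}

#' Assemble a homo-oligomer that buries a site at the interface
#'
#' Copies of the monomer are arranged by rigid transforms around the
#' first chain so a designated site is occluded by the partner chains.
#' Generation-time checks assert the planted truth: site rSASA < 0.2 in
#' the assembly and >= 0.3 in the monomer; candidate packing distances
#' are tried in order until both hold.
#'
#' @param monomer single-chain `phospho_structure`
#' @param n_copies chains in the assembly (1 returns the monomer)
#' @param interface_seqpos the 8 sequence positions of the buried site
#' @param params SASA parameters for the checks
#' @return a `phospho_structure` with `n_copies` chains
#' @export
make_multimer <- function(monomer, n_copies = 4, interface_seqpos,
                          params = sasa_params()) {
  stopifnot(nrow(monomer$chains) == 1)
  if (n_copies == 1) return(monomer)
  mono_r <- octapeptide_rsasa(monomer, monomer$chains$chain[1],
                              interface_seqpos, params)
  if (mono_r < 0.3) {
    stop("interface site is not accessible (>= 0.3) on the monomer")
  }
  base <- monomer$atoms
  for (dsep in c(9, 8.5, 9.5, 10, 8)) {
    segs <- list(base)
    for (k in seq_len(n_copies - 1)) {
      ang <- 2 * pi * k / n_copies + pi / n_copies
      at <- base
      at$chain <- LETTERS[k + 1]
      at$y <- at$y + dsep * cos(ang)
      at$z <- at$z + dsep * sin(ang)
      segs[[k + 1]] <- at
    }
    atoms <- dplyr::bind_rows(segs)
    atoms$serial <- seq_len(nrow(atoms))
    multi <- structure_from_atoms(paste0(monomer$id, "_x", n_copies), atoms)
    if (octapeptide_rsasa(multi, "A", interface_seqpos, params) < 0.2) {
      return(multi)
    }
  }
  stop("could not occlude the interface site in the assembly")
}

#' Helix monomer carrying a mid-helix phosphosite
#'
#' A 16-residue helix whose residues 5-12 form the site octapeptide;
#' accessible on the monomer, buried when packed into an oligomer by
#' [make_multimer()].
#'
#' @param site_seq 8-residue octapeptide (phosphoresidue at position 4)
#' @param id structure identifier
#' @return a `phospho_structure`; attribute `site_seqpos` gives positions
#'   5-12
#' @export
build_interface_monomer <- function(site_seq = "AVLSAILK", id = "helix_monomer") {
  stopifnot(nchar(site_seq) == 8)
  atoms <- center_segment(
    build_peptide_atoms(paste0("AAAA", site_seq, "AAAA"), -57, -47))
  s <- structure_from_atoms(id, atoms)
  attr(s, "site_seqpos") <- 5:12
  s
}

#' Rigid-cage fixture: a buried site that dynamics cannot expose
#'
#' The globule of [build_globule()] used as a negative control for the
#' normal-mode rescue: its core octapeptide is enclosed by the shell on
#' all sides, and every low-energy conformer keeps the coarse rSASA of
#' the core below 0.1 (asserted at generation time).
#'
#' @inheritParams build_globule
#' @return a `phospho_structure` with attribute `site_seqpos`
#' @export
build_rigid_cage <- function(seed = 1, params = sasa_params()) {
  g <- build_globule(seed, params = params)
  m <- build_enm(g)
  ens <- generate_conformers(m, normal_modes(m))
  er <- ensemble_rsasa(ens, match(attr(g, "core_seqpos"), m$seqpos), params)
  if (attr(er, "max_rsasa") >= 0.1) {
    stop("cage fixture failed: a conformer exposed the core above 0.1")
  }
  attr(g, "site_seqpos") <- attr(g, "core_seqpos")
  g
}

#' Mobile-flap fixture: a buried site exposed by low-frequency modes
#'
#' A hinged clamp of four helices holds an extended site octapeptide that
#' protrudes past the clamp mouth under two covering strands. In the
#' input structure the site is in the disallowed region (all-atom rSASA
#' < 0.2, coarse rSASA < 0.2), but scissor-like low-frequency normal
#' modes of the clamp swing the site clear of its covers, and at least
#' one of the default 401 conformers raises the coarse rSASA above 0.2.
#' All three properties are asserted at generation time.
#'
#' @param params SASA parameters for the generation-time checks
#' @param site_seq 8-residue site octapeptide
#' @return a `phospho_structure` with attribute `site_seqpos` (1-8)
#' @export
build_floppy_arm <- function(params = sasa_params(), site_seq = "AVLSAILV") {
  gap <- 5.2; hl <- 24L; dz <- 2.6; xoff <- 22; zret <- 4.2
  segs <- list()
  segs$site <- shift_segment(
    center_segment(build_peptide_atoms(site_seq, -120, 120)), c(xoff, 0, 0))
  segs$cover_top <- shift_segment(
    center_segment(build_peptide_atoms(strrep("A", 8), -120, 120)),
    c(xoff + 3, 0, zret))
  segs$cover_bottom <- shift_segment(
    center_segment(build_peptide_atoms(strrep("A", 8), -120, 120)),
    c(xoff + 3, 0, -zret))
  for (s in c(-1, 1)) {
    for (zz in c(-dz, dz)) {
      segs[[paste0("clamp", s, zz)]] <- shift_segment(
        center_segment(build_peptide_atoms(strrep("A", hl), -57, -47)),
        c(0, s * gap, zz))
    }
  }
  conn <- rotate_segment(
    center_segment(build_peptide_atoms("AAAAAA", -57, -47)),
    rotation_about(c(0, 0, 1), pi / 2))
  segs$conn <- shift_segment(conn, c(-hl * 0.75 - 3, 0, 0))
  g <- combine_segments(segs, "floppy_arm")

  aa_rsasa <- octapeptide_rsasa(g, "A", 1:8, params)
  m <- build_enm(g)
  idx <- match(1:8, m$seqpos)
  coarse_in <- mean(coarse_residue_sasa(m$coords, m$aa, params,
                                        subset = idx)$percent_sasa)
  ens <- generate_conformers(m, normal_modes(m))
  mx <- attr(ensemble_rsasa(ens, idx, params), "max_rsasa")
  if (!(aa_rsasa < 0.2 && coarse_in < 0.2 && mx > 0.2)) {
    stop(sprintf(paste0("flap fixture invariants violated: all-atom %.3f, ",
                        "coarse input %.3f, conformer max %.3f"),
                 aa_rsasa, coarse_in, mx))
  }
  attr(g, "site_seqpos") <- 1:8
  g
}

#' Specification of a synthetic phosphosite cohort
#'
#' @param n_proteins number of proteins (one planted site each)
#' @param rates named fractions per planted category; must sum to 1.
#'   Categories: exposed, buried, interface_buried, motif_buried,
#'   disordered, mutated, terminal, low_coverage. Defaults approximate
#'   the accounting of large phosphoproteome/structure matching studies:
#'   most sites accessible, a substantial buried minority, and smaller
#'   fractions lost to disorder, mutation, termini and poor coverage.
#' @param seed RNG seed; a fixed seed gives byte-identical cohorts
#' @return a `cohort_spec` list
#' @export
cohort_spec <- function(n_proteins = 50,
                        rates = c(exposed = 0.35, buried = 0.20,
                                  interface_buried = 0.08, motif_buried = 0.07,
                                  disordered = 0.15, mutated = 0.05,
                                  terminal = 0.05, low_coverage = 0.05),
                        seed = 42) {
  known <- c("exposed", "buried", "interface_buried", "motif_buried",
             "disordered", "mutated", "terminal", "low_coverage")
  stopifnot(all(names(rates) %in% known), abs(sum(rates) - 1) < 1e-9,
            n_proteins >= 1)
  structure(list(n_proteins = as.integer(n_proteins), rates = rates,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# largest-remainder apportionment of n among rates
apportion <- function(n, rates) {
  raw <- n * rates
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

window15_for <- function(sequence, position) {
  chars <- strsplit(sequence, "")[[1]]
  idx <- (position - 7):(position + 7)
  w <- ifelse(idx >= 1 & idx <= length(chars), chars[pmax(idx, 1)], "X")
  paste(w, collapse = "")
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Builds one structure and one phosphosite per protein, each with a
#' planted category, and returns the structures, a PhosphoSitePlus-style
#' site table and the truth table recording every planted label with its
#' expected pipeline outcome.
#'
#' @param spec a [cohort_spec()]
#' @param params SASA parameters used for generation-time verification
#' @param dir optional directory; when given, PDB files, the site TSV,
#'   the truth TSV and a manifest are written there
#' @return list with `structures` (named by accession), `sites` (tibble:
#'   accession, position, residue, window15), `truth` (tibble: accession,
#'   category, expected_status, expected_label, expected_rescue)
#' @export
generate_cohort <- function(spec = cohort_spec(), params = sasa_params(),
                            dir = NULL) {
  counts <- apportion(spec$n_proteins, spec$rates)
  labels <- rep(names(spec$rates), counts)
  structures <- list()
  site_rows <- list()
  truth_rows <- list()

  for (i in seq_along(labels)) {
    lab <- labels[i]
    acc <- sprintf("SYN%03d", i)
    pseed <- spec$seed * 1000 + i
    built <- build_cohort_protein(lab, acc, pseed, params)
    structures[[acc]] <- built$structure
    site_rows[[i]] <- built$site
    truth_rows[[i]] <- built$truth
  }
  out <- list(structures = structures,
              sites = dplyr::bind_rows(site_rows),
              truth = dplyr::bind_rows(truth_rows))
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

# one protein + site + truth row for a planted category
build_cohort_protein <- function(lab, acc, pseed, params) {
  core_seq <- "LVASAILV"
  if (lab == "motif_buried") core_seq <- "LVASPIKV"
  if (lab == "terminal") core_seq <- "LSAAAILV"   # phosphosite at chain position 2
  arm_seq <- with_local_seed(pseed, {
    mid <- random_sequence(4)
    paste0("AA", random_sequence(1), "VS", mid, "K", random_sequence(1), "AA")
  })
  # keep the surface octapeptide (arm residues 3-10) free of S/T/Y except
  # the planted phosphoresidue at arm residue 5, and free of the CDK motif
  arm_chars <- strsplit(arm_seq, "")[[1]]
  guard <- c(3, 6:9)
  arm_chars[guard][arm_chars[guard] %in% c("S", "T", "Y", "P", "X")] <- "A"
  arm_seq <- paste(arm_chars, collapse = "")

  if (lab == "interface_buried") {
    mono <- build_interface_monomer(id = acc)
    s <- make_multimer(mono, 4, attr(mono, "site_seqpos"), params)
    s$id <- acc
    seqn <- s$chains$sequence[1]
    pos <- 8L  # S of AVLSAILK at chain position 8
    return(list(
      structure = s,
      site = tibble::tibble(accession = acc, position = pos, residue = "S",
                            window15 = window15_for(seqn, pos)),
      truth = tibble::tibble(accession = acc, category = lab,
                             expected_status = "matched",
                             expected_label = "allowed",
                             expected_rescue = "interface")
    ))
  }

  g <- build_globule(pseed, core_seq = core_seq, arm_seq = arm_seq,
                     params = params)
  g$id <- acc
  seqn <- g$chains$sequence[1]
  core <- attr(g, "core_seqpos")
  surf <- attr(g, "surface_seqpos")
  surf_pos <- surf[4]   # phosphoresidue of the surface octapeptide
  core_pos <- core[4]

  drop_residues <- function(s, seqpos_drop) {
    keep <- !(s$atoms$resno %in% seqpos_drop)
    structure_from_atoms(s$id, s$atoms[keep, ],
                         sequences = c(A = s$chains$sequence[1]))
  }

  site <- switch(lab,
    exposed = ,
    low_coverage = ,
    disordered = ,
    mutated = tibble::tibble(accession = acc, position = surf_pos,
                             residue = "S",
                             window15 = window15_for(seqn, surf_pos)),
    buried = ,
    motif_buried = tibble::tibble(accession = acc, position = core_pos,
                                  residue = "S",
                                  window15 = window15_for(seqn, core_pos)),
    terminal = tibble::tibble(accession = acc, position = 2L,
                              residue = "S",
                              window15 = window15_for(seqn, 2L))
  )

  s <- g
  if (lab == "disordered") {
    s <- drop_residues(g, surf[4:5])
  } else if (lab == "low_coverage") {
    s <- drop_residues(g, 9:48)   # 40 of the shell residues: coverage 0.64
  } else if (lab == "mutated") {
    # the structure carries a point substitution at octapeptide position 6
    chars <- strsplit(seqn, "")[[1]]
    mut_seqpos <- surf[6]
    chars[mut_seqpos] <- if (chars[mut_seqpos] == "I") "L" else "I"
    mutated_seq <- paste(chars, collapse = "")
    atoms <- g$atoms
    atoms$aa[atoms$resno == mut_seqpos] <- chars[mut_seqpos]
    s <- structure_from_atoms(acc, atoms, sequences = c(A = mutated_seq))
  }
  s$id <- acc

  truth <- tibble::tibble(
    accession = acc, category = lab,
    expected_status = switch(lab,
      exposed = "matched", buried = "matched", motif_buried = "matched",
      disordered = "disordered", mutated = "mutated",
      terminal = "terminal", low_coverage = "low_coverage"),
    expected_label = switch(lab,
      exposed = "allowed", buried = "disallowed", motif_buried = "allowed",
      NA_character_),
    expected_rescue = switch(lab,
      exposed = "none", buried = "none", motif_buried = "consensus_motif",
      NA_character_)
  )
  list(structure = s, site = site, truth = truth)
}

write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (acc in names(cohort$structures)) {
    writeLines(write_structure(cohort$structures[[acc]]),
               file.path(dir, paste0(acc, ".pdb")))
  }
  utils::write.table(cohort$sites, file.path(dir, "phosphosites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- dplyr::left_join(cohort$truth,
                               cohort$sites[, c("accession", "position")],
                               by = "accession")
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
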