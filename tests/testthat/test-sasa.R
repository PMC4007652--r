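test_that("an isolated atom matches the closed-form sphere area", {
  s <- single_atom_structure("C")
  a <- atom_sasa(s, sasa_params(n_sphere_points = 960))
  expect_equal(a$sasa, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-9)
})

test_that("a fully enclosed atom has zero SASA", {
  # central atom caged by a dense shell of atoms at 3 Angstrom
  pts <- phosphoconform:::fibonacci_sphere(60) * 3
  atoms <- tibble::tibble(
    chain = "A", resno = c(1L, rep(2L, 60)), aa = "G",
    elety = c("CA", rep("C", 60)), element = "C",
    x = c(0, pts[, 1]), y = c(0, pts[, 2]), z = c(0, pts[, 3]),
    occ = 1, serial = seq_len(61))
  s <- structure_from_atoms("cage", atoms)
  a <- atom_sasa(s, params_fast)
  expect_equal(a$sasa[1], 0)
})

test_that("two-atom areas match an independent numerical integration", {
  p <- sasa_params(n_sphere_points = 960)
  r1 <- 1.70 + 1.4; r2 <- 1.52 + 1.4
  for (d in c(2.0, 3.0, 4.5)) {
    atoms <- tibble::tibble(
      chain = "A", resno = 1L, aa = "G", elety = c("C1", "O1"),
      element = c("C", "O"), x = c(0, d), y = 0, z = 0, occ = 1,
      serial = 1:2)
    s <- structure_from_atoms("pair", atoms)
    a <- atom_sasa(s, p)
    oracle <- two_sphere_sasa_numeric(c(0, 0, 0), r1, c(d, 0, 0), r2)
    expect_equal(a$sasa[1], oracle, tolerance = 0.02)
  }
})

test_that("unknown elements are reported by name", {
  atoms <- tibble::tibble(chain = "A", resno = 1L, aa = "G", elety = "XX",
                          element = "Q", x = 0, y = 0, z = 0, occ = 1,
                          serial = 1L)
  s <- structure_from_atoms("bad", atoms)
  expect_error(atom_sasa(s, params_fast), "radius")
})

test_that("residue areas are sums of atom areas (conservation)", {
  h <- build_ideal_helix("AVLSAILK")
  at <- atom_sasa(h, params_fast)
  rs <- residue_sasa(h, params_fast)
  expect_equal(sum(rs$sasa), sum(at$sasa))
  one <- single_atom_structure("C")
  expect_equal(residue_sasa(one, params_fast)$sasa,
               atom_sasa(one, params_fast)$sasa)
})

test_that("SASA is invariant under rigid-body transforms", {
  h <- build_ideal_helix("AVLSAILKAVLA")
  p <- sasa_params(n_sphere_points = 960)
  base <- residue_sasa(h, p)$sasa
  # translations leave the point lattice geometry unchanged: exact
  shifted <- phosphoconform:::transform_structure(h, diag(3), c(11, -7, 3))
  expect_equal(residue_sasa(shifted, p)$sasa, base, tolerance = 1e-9)
  # rotations re-sample the fixed lattice: equal to sampling resolution
  for (seed in 1:3) {
    moved <- phosphoconform:::transform_structure(
      h, random_rotation(seed), c(11, -7, 3) * seed)
    expect_equal(residue_sasa(moved, p)$sasa, base, tolerance = 0.02)
  }
})

test_that("adding atoms never increases any existing atom's SASA", {
  h <- build_ideal_helix("AVLSAILK")
  a1 <- atom_sasa(h, params_fast)
  extra <- h$atoms[1, ]
  extra$serial <- max(h$atoms$serial) + 1L
  extra$resno <- max(h$atoms$resno) + 1L
  extra$x <- mean(h$atoms$x) + 2
  h2 <- structure_from_atoms("plus", rbind(h$atoms, extra))
  a2 <- atom_sasa(h2, params_fast)
  expect_true(all(a2$sasa[seq_len(nrow(a1))] <= a1$sasa + 1e-9))
})

test_that("total SASA converges as the point lattice is refined", {
  g <- build_ideal_helix("AVLSAILKAVLA")
  t1 <- sum(atom_sasa(g, sasa_params(n_sphere_points = 480))$sasa)
  t2 <- sum(atom_sasa(g, sasa_params(n_sphere_points = 960))$sasa)
  expect_lt(abs(t1 - t2) / t2, 0.01)
})

test_that("per-residue SASA agrees with an independent implementation", {
  p <- sasa_params(n_sphere_points = 1920)
  for (s in list(build_ideal_helix("AVLSAILKAVLA"),
                 build_extended_peptide("GWG"),
                 build_globule(seed = 21))) {
    mine <- residue_sasa(s, p)
    ref <- biotite_residue_sasa(s, n_points = 1920)
    m <- dplyr::inner_join(mine, ref, by = c("chain", "resno"),
                           suffix = c("", "_ref"))
    big <- m$sasa_ref > 10  # relative deviation on meaningful areas
    expect_true(all(abs(m$sasa[big] - m$sasa_ref[big]) / m$sasa_ref[big] < 0.05))
    # buried residues: small absolute discrepancy, not relative
    expect_true(all(abs(m$sasa[!big] - m$sasa_ref[!big]) < 2))
  }
})

test_that("reference areas are deterministic, cached and size-ordered", {
  p <- sasa_params()
  g1 <- reference_sasa("G", p)
  expect_identical(reference_sasa("G", p), g1)
  expect_gt(reference_sasa("W", p), g1)
  expect_error(reference_sasa("X", p), "non-canonical")
  # flank choice matters but both are positive
  expect_gt(reference_sasa("A", p, flank = "A"), 0)
})

test_that("reference tripeptide area matches the oracle on the same coordinates", {
  p <- sasa_params(n_sphere_points = 960)
  tri <- build_extended_peptide("GAG")
  ref <- biotite_residue_sasa(tri)
  expect_equal(reference_sasa("A", p), ref$sasa[ref$resno == 2],
               tolerance = 0.05)
})

test_that("octapeptide rSASA is the mean of the eight %SASA values", {
  e <- build_extended_peptide("AAVSAILKAA")
  p <- params_fast
  percent <- residue_sasa(e, p)
  manual <- mean(percent$percent_sasa[percent$resno %in% 2:9])
  expect_equal(octapeptide_rsasa(e, "A", 2:9, p), manual)
  expect_equal(octapeptide_rsasa(e, "A", 2:9, p, percent = percent), manual)
  expect_error(octapeptide_rsasa(e, "A", 1:7, p), "8 residues")
})

test_that("an isolated extended octapeptide has rSASA near 1", {
  e <- build_extended_peptide("AAVSAILK")
  r <- octapeptide_rsasa(e, "A", 1:8, sasa_params())
  expect_gt(r, 0.85)
  expect_lt(r, 1.15)
})

test_that("rSASA errors on windows touching disordered residues", {
  co <- generate_cohort(cohort_spec(1, rates = c(disordered = 1), seed = 2))
  s <- co$structures[[1]]
  site <- co$sites$position[1]
  expect_error(octapeptide_rsasa(s, "A", (site - 3):(site + 4), params_fast),
               "disordered")
})

test_that("coarse single-sphere SASA mirrors the all-atom contract", {
  # isolated coarse sphere: closed form
  cs <- coarse_residue_sasa(matrix(c(0, 0, 0), 1), "A", params_fast)
  r <- phosphoconform:::coarse_radius("A") + 1.4
  expect_equal(cs$sasa, 4 * pi * r^2, tolerance = 1e-9)
  expect_error(coarse_residue_sasa(rbind(c(0, 0, 0), c(0, 0, 0)),
                                   c("A", "A"), params_fast),
               "duplicate")
  # buried core below surface, and rank agreement with all-atom values
  g <- build_globule(seed = 3)
  m <- build_enm(g)
  cc <- coarse_residue_sasa(m$coords, m$aa, params_fast)
  core <- match(attr(g, "core_seqpos"), m$seqpos)
  surf <- match(attr(g, "surface_seqpos"), m$seqpos)
  expect_lt(mean(cc$percent_sasa[core]), mean(cc$percent_sasa[surf]))
  aa_tab <- residue_sasa(g, params_fast)
  joined <- dplyr::inner_join(
    tibble::tibble(resno = m$seqpos, coarse = cc$percent_sasa),
    aa_tab[, c("resno", "percent_sasa")], by = "resno")
  expect_gt(stats::cor(joined$coarse, joined$percent_sasa,
                       method = "spearman"), 0.7)
})

test_that("residue depth separates buried from exposed and is isometric", {
  g <- build_globule(seed = 5)
  d <- residue_depth(g, params_fast)
  core <- attr(g, "core_seqpos")
  surf <- attr(g, "surface_seqpos")
  core_d <- d$depth[d$resno %in% core]
  surf_d <- d$depth[d$resno %in% surf]
  expect_gt(min(core_d), max(surf_d))
  # a single exposed residue lies essentially on the surface
  one <- single_atom_structure("C")
  expect_lt(residue_depth(one, params_fast)$depth, 2 * 1.4)
  # translation leaves depth unchanged exactly; rotation re-samples the
  # surface lattice, so agreement is at sampling resolution
  shifted <- phosphoconform:::transform_structure(g, diag(3), c(3, 9, -4))
  expect_equal(residue_depth(shifted, params_fast)$depth, d$depth,
               tolerance = 1e-9)
  rotated <- phosphoconform:::transform_structure(g, random_rotation(7), c(0, 0, 0))
  expect_equal(mean(abs(residue_depth(rotated, params_fast)$depth - d$depth)),
               0, tolerance = 0.2)
})
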