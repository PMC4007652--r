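test_that("contacts are all pairs within the cutoff", {
  two <- matrix(c(0, 0, 0, 5, 0, 0, 20, 0, 0, 20, 5, 0), ncol = 3, byrow = TRUE)
  m <- build_enm(two, R_C = 10)
  # brute force count
  d <- as.matrix(dist(two))
  expect_equal(nrow(m$contacts), sum(upper.tri(d) & d <= 10))
  expect_true(all(m$contacts$d0 <= 10))
  far <- matrix(c(0, 0, 0, 12, 0, 0, 0, 12, 0, 12, 12, 5), ncol = 3, byrow = TRUE)
  m2 <- build_enm(far, R_C = 10)
  df <- as.matrix(dist(far))
  expect_equal(nrow(m2$contacts), sum(df[upper.tri(df)] <= 10))
})

test_that("a helix's contact set equals the brute-force enumeration", {
  h <- build_ideal_helix(strrep("A", 20))
  m <- build_enm(h)
  ca <- as.matrix(m$coords)
  d <- as.matrix(dist(ca))
  brute <- which(upper.tri(d) & d <= 10, arr.ind = TRUE)
  expect_equal(nrow(m$contacts), nrow(brute))
})

test_that("build_enm validates its preconditions", {
  h <- build_ideal_helix(strrep("A", 8))
  no_ca <- h
  no_ca$atoms <- no_ca$atoms[no_ca$atoms$elety != "CA" | no_ca$atoms$resno != 3, ]
  expect_error(build_enm(structure_from_atoms("x", no_ca$atoms)), "C-alpha")
  expect_error(build_enm(matrix(rnorm(9), 3)), "at least 4")
  line <- cbind(seq(0, 30, by = 3), 0, 0)
  expect_error(build_enm(line), "collinear")
})

test_that("the energy is the harmonic contact sum with closed-form cases", {
  h <- build_ideal_helix(strrep("A", 12))
  m <- build_enm(h)
  expect_identical(enm_energy(m$coords, m), 0)   # exactly zero at input
  # single stretched contact: 1/2 k delta^2
  two <- matrix(c(0, 0, 0, 5, 0, 0, 0, 5, 0, 3, 3, 4), ncol = 3, byrow = TRUE)
  m2 <- build_enm(two, R_C = 8)
  delta <- 0.3
  # verify against direct summation on a random kick
  set.seed(1)
  kick <- two + matrix(rnorm(12, sd = 0.05), ncol = 3)
  direct <- 0
  for (r in seq_len(nrow(m2$contacts))) {
    i <- m2$contacts$i[r]; j <- m2$contacts$j[r]
    direct <- direct + 0.5 * (sqrt(sum((kick[i, ] - kick[j, ])^2)) -
                                m2$contacts$d0[r])^2
  }
  expect_equal(enm_energy(kick, m2), direct, tolerance = 1e-12)
  # two isolated-pair nodes: analytic half k delta^2
  pair <- matrix(c(0, 0, 0, 5, 0, 0, 100, 100, 100, 200, 200, 200),
                 ncol = 3, byrow = TRUE)
  mp <- build_enm(pair, R_C = 10)
  stretched <- pair
  stretched[2, 1] <- 5 + delta
  expect_equal(enm_energy(stretched, mp), 0.5 * delta^2)
  expect_error(enm_energy(pair[1:3, ], mp), "incongruent")
})

test_that("the Hessian matches finite differences of the energy", {
  h <- build_ideal_helix(strrep("A", 10))
  m <- build_enm(h)
  H <- phosphoconform:::enm_hessian(m)
  expect_equal(H, t(H))
  x0 <- as.vector(t(m$coords))
  f <- function(x) enm_energy(matrix(x, ncol = 3, byrow = TRUE), m)
  eps <- 1e-3
  set.seed(2)
  idx <- sample(length(x0), 6)
  for (a in idx) {
    for (b in idx) {
      xa <- numeric(length(x0)); xa[a] <- eps
      xb <- numeric(length(x0)); xb[b] <- eps
      fd <- (f(x0 + xa + xb) - f(x0 + xa - xb) -
               f(x0 - xa + xb) + f(x0 - xa - xb)) / (4 * eps^2)
      if (abs(H[a, b]) > 1e-6) {
        expect_equal(fd, H[a, b], tolerance = 1e-4)
      } else {
        expect_lt(abs(fd), 1e-4)
      }
    }
  }
})

test_that("normal modes have 6 rigid-body modes and orthonormal vectors", {
  g <- build_globule(seed = 13)
  ms <- normal_modes(build_enm(g))
  expect_equal(ms$n_zero, 6)
  expect_true(all(diff(ms$eigenvalues) >= -1e-10))
  V <- ms$eigenvectors[, 1:12]
  expect_equal(t(V) %*% V, diag(12), tolerance = 1e-8)
  # 10-residue connected model: 3N-6 = 24 vibrational modes
  h <- build_ideal_helix(strrep("A", 10))
  mh <- normal_modes(build_enm(h))
  expect_equal(length(mh$eigenvalues) - mh$n_zero, 24)
})

test_that("disconnected networks are rejected", {
  apart <- rbind(phosphoconform:::fibonacci_sphere(8) * 3,
                 sweep(phosphoconform:::fibonacci_sphere(8) * 3, 2,
                       c(50, 0, 0), "+"))
  m <- build_enm(apart, R_C = 10)
  expect_error(normal_modes(m), "disconnected")
})

test_that("the eigenvalue spectrum is invariant under isometries", {
  h <- build_ideal_helix(strrep("A", 12))
  m1 <- build_enm(h)
  ev1 <- normal_modes(m1)$eigenvalues
  moved <- phosphoconform:::transform_structure(h, random_rotation(5), c(4, 4, 4))
  ev2 <- normal_modes(build_enm(moved))$eigenvalues
  expect_equal(ev1, ev2, tolerance = 1e-8)
})

test_that("ensemble size follows the n_modes x n_steps + 1 law", {
  h <- build_ideal_helix(strrep("A", 15))
  m <- build_enm(h)
  ms <- normal_modes(m)
  expect_equal(length(generate_conformers(m, ms)$conformers), 401)
  expect_equal(length(generate_conformers(m, ms, n_modes = 1,
                                          n_steps = 2)$conformers), 3)
  for (nm in c(3, 7)) {
    for (st in c(4, 5)) {
      expect_equal(length(generate_conformers(m, ms, n_modes = nm,
                                              n_steps = st)$conformers),
                   nm * st + 1)
    }
  }
  expect_error(generate_conformers(m, ms, max_amp = 0), "positive")
  expect_warning(generate_conformers(m, ms, n_modes = 100), "available")
})

test_that("energy along a single mode follows the quadratic form", {
  h <- build_ideal_helix(strrep("A", 15))
  m <- build_enm(h)
  ms <- normal_modes(m)
  for (k in 1:3) {
    lam <- ms$eigenvalues[ms$n_zero + k]
    v <- matrix(ms$eigenvectors[, ms$n_zero + k], ncol = 3, byrow = TRUE)
    for (a in c(-0.2, 0.1, 0.2)) {
      E <- enm_energy(m$coords + a * v, m)
      expect_equal(E, 0.5 * lam * a^2, tolerance = 0.05)
    }
    # symmetry in +/- amplitude (equal to third-order anharmonic terms)
    expect_equal(enm_energy(m$coords + 0.15 * v, m),
                 enm_energy(m$coords - 0.15 * v, m), tolerance = 0.02)
  }
})

test_that("conformer amplitudes respect the displacement cap and determinism", {
  h <- build_ideal_helix(strrep("A", 15))
  m <- build_enm(h)
  ens1 <- generate_conformers(m, n_modes = 5, n_steps = 4, max_amp = 1.5)
  ens2 <- generate_conformers(m, n_modes = 5, n_steps = 4, max_amp = 1.5)
  expect_identical(ens1$conformers, ens2$conformers)
  maxdisp <- vapply(ens1$conformers[-1], function(x) {
    max(sqrt(rowSums((x - m$coords)^2)))
  }, 0)
  expect_lte(max(maxdisp), 1.5 + 1e-9)
  expect_equal(max(maxdisp), 1.5, tolerance = 1e-6)
})

test_that("ensemble rSASA reports all conformers and the maximum", {
  g <- build_globule(seed = 17)
  m <- build_enm(g)
  ms <- normal_modes(m)
  idx <- match(attr(g, "core_seqpos"), m$seqpos)
  ens <- generate_conformers(m, ms, n_modes = 2, n_steps = 2)
  er <- ensemble_rsasa(ens, idx, params_fast)
  expect_equal(nrow(er), 5)
  expect_equal(attr(er, "max_rsasa"), max(er$rsasa))
  expect_true(is.na(er$mode[1]))       # input structure included first
  expect_error(ensemble_rsasa(ens, idx[1:4], params_fast), "8 residues")
})

test_that("dynamics reclassification follows the threshold rule", {
  r1 <- reclassify_by_dynamics(0.15, c(0.15, 0.18, 0.25), 0.2)
  expect_equal(r1$label, "allowed")
  expect_equal(r1$rescue, "dynamics")
  r2 <- reclassify_by_dynamics(0.05, c(0.05, 0.08, 0.09), 0.2)
  expect_equal(r2$label, "disallowed")
  expect_equal(r2$rescue, "none")
  r3 <- reclassify_by_dynamics(0.3, c(0.3, 0.1), 0.2)
  expect_equal(r3$label, "allowed")
  expect_equal(r3$rescue, "none")    # already allowed, no rescue recorded
})

test_that("tidy and glance views of a mode set are consistent", {
  h <- build_ideal_helix(strrep("A", 10))
  ms <- normal_modes(build_enm(h))
  td <- tidy(ms)
  expect_equal(nrow(td), 30)
  expect_equal(sum(td$rigid_body), 6)
  gl <- glance(ms)
  expect_equal(gl$n_vibrational, 24)
  expect_equal(gl$n_residues, 10)
})
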