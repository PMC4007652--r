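# shared fixtures and independent oracles for the test suite

# moderate sphere sampling keeps unit tests fast; accuracy-sensitive
# tests pass their own params
params_fast <- sasa_params(n_sphere_points = 240)

# independent SASA oracle for a pair of spheres: theta/phi quadrature on
# sphere 1 with explicit area weights (not the spiral lattice the
# implementation uses)
two_sphere_sasa_numeric <- function(c1, r1, c2, r2, n_theta = 400) {
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
  area <- 0
  for (t in theta) {
    n_phi <- max(8, ceiling(2 * n_theta * sin(t)))
    phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
    pts <- cbind(r1 * sin(t) * cos(phi), r1 * sin(t) * sin(phi),
                 r1 * cos(t))
    pts <- sweep(pts, 2, c1, "+")
    d2 <- rowSums(sweep(pts, 2, c2)^2)
    w <- r1^2 * sin(t) * (pi / n_theta) * (2 * pi / n_phi)
    area <- area + w * sum(d2 >= r2^2)
  }
  area
}

# per-residue SASA from biotite (independent Shrake-Rupley
# implementation) on the same coordinates and radius table
biotite_residue_sasa <- function(structure, n_points = 960) {
  pdb <- tempfile(fileext = ".pdb")
  out <- tempfile(fileext = ".csv")
  writeLines(write_structure(structure), pdb)
  script <- sprintf('
import numpy as np, biotite.structure as struc, biotite.structure.io.pdb as pdb
f = pdb.PDBFile.read("%s")
arr = f.get_structure(model=1)
radii = {"H":1.20,"C":1.70,"N":1.55,"O":1.52,"S":1.80,"P":1.80}
vr = np.array([radii[e] for e in arr.element])
sasa = struc.sasa(arr, probe_radius=1.4, point_number=%d, vdw_radii=vr)
import csv
agg = {}
for cid, rid, a in zip(arr.chain_id, arr.res_id, sasa):
    agg[(cid, rid)] = agg.get((cid, rid), 0.0) + float(a)
with open("%s", "w") as fh:
    w = csv.writer(fh); w.writerow(["chain", "resno", "sasa"])
    for (cid, rid), a in sorted(agg.items()):
        w.writerow([cid, rid, a])
', pdb, n_points, out)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("biotite oracle failed")
  tibble::as_tibble(utils::read.csv(out, stringsAsFactors = FALSE))
}

# dihedral of four points, used as a geometric oracle
dihedral_of <- function(a, b, c, d) {
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

single_atom_structure <- function(element = "C", aa = "G") {
  structure_from_atoms("one_atom", tibble::tibble(
    chain = "A", resno = 1L, aa = aa, elety = "CA", element = element,
    x = 0, y = 0, z = 0, occ = 1, serial = 1L))
}

minimal_pdb_text <- function() {
  c(
    "SEQRES   1 A    3  ALA GLY SER                                        ",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       4.023   2.810   0.000  1.00  0.00           C",
    "ATOM      6  C   GLY A   2       5.530   2.600   0.000  1.00  0.00           C",
    "ATOM      7  N   SER A   3       6.280   3.690   0.000  1.00  0.00           N",
    "ATOM      8  CA  SER A   3       7.730   3.640   0.000  1.00  0.00           C",
    "ATOM      9  C   SER A   3       8.310   5.040   0.000  1.00  0.00           C",
    "END"
  )
}
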