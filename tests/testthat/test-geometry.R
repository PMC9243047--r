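test_that("torsion measurement honours planar limits and IUPAC range", {
  ## four coplanar atoms, cis then trans
  b <- c(0, 0, 0); cc <- c(1.5, 0, 0); a <- c(-0.5, 1, 0)
  g_cis <- geometry(rep("C", 4), rbind(a, b, cc, c(2.0, 1, 0)))
  g_trans <- geometry(rep("C", 4), rbind(a, b, cc, c(2.0, -1, 0)))
  s <- dihedral_spec(1:4)
  expect_equal(measure_dihedral(g_cis, s), 0)
  expect_equal(measure_dihedral(g_trans, s), 180)

  ## staggered gauche chain
  g60 <- make_chain(60)
  expect_equal(measure_dihedral(g60, s), 60, tolerance = 1e-9)
  ## mirror symmetry flips the sign
  gm <- g60; gm$coords[, 3] <- -gm$coords[, 3]
  expect_equal(measure_dihedral(gm, s), -60, tolerance = 1e-9)
})

test_that("torsion measurement rejects degenerate and invalid input", {
  lin <- geometry(rep("C", 4),
                  cbind(c(0, 1.5, 3.0, 4.5), 0, 0))
  expect_error(measure_dihedral(lin, dihedral_spec(1:4)), "collinear")
  g <- make_chain(60)
  expect_error(measure_dihedral(g, dihedral_spec(c(1, 2, 3, 9))),
               "out of range")
  expect_error(dihedral_spec(c(1, 2, 2, 3)), "distinct")
})

test_that("measure is invariant under rigid motion", {
  g <- make_chain(-107.3)
  s <- dihedral_spec(1:4)
  ref <- measure_dihedral(g, s)
  for (i in 1:10) {
    expect_equal(measure_dihedral(random_rigid(g, i), s), ref,
                 tolerance = 1e-9)
  }
})

test_that("set_dihedral round-trips, preserves structure, leaves anchors", {
  g <- make_chain(60)
  s <- dihedral_spec(1:4)
  for (theta in c(-170, -60, 0, 60, 170)) {
    g2 <- set_dihedral(g, s, theta)
    expect_equal(wrap_angle(measure_dihedral(g2, s) - theta), 0,
                 tolerance = 1e-9)
    ## anchor side unmoved
    expect_equal(g2$coords[1:2, ], g$coords[1:2, ], tolerance = 1e-12)
    ## all bond lengths and the bend angles preserved
    d0 <- as.matrix(stats::dist(g$coords))
    d2 <- as.matrix(stats::dist(g2$coords))
    expect_equal(d2[cbind(1:3, 2:4)], d0[cbind(1:3, 2:4)],
                 tolerance = 1e-9)
    expect_equal(d2[1, 3], d0[1, 3], tolerance = 1e-9)
    expect_equal(d2[2, 4], d0[2, 4], tolerance = 1e-9)
    ## formula conservation
    expect_identical(molecular_formula(g2), molecular_formula(g))
  }
  ## identity: setting the current angle moves nothing
  gid <- set_dihedral(g, s, measure_dihedral(g, s))
  expect_equal(gid$coords, g$coords, tolerance = 1e-9)
})

test_that("set_dihedral refuses torsions inside a ring", {
  tf <- toy_molecule("toy-furanose")
  ## central bond C1'-C2' (atoms 2-3) lies in the furanose ring
  ring_spec <- dihedral_spec(c(1, 2, 3, 4))
  expect_error(set_dihedral(tf$geometry, ring_spec, 30), "ring")
})

test_that("Hill formulas count the element multiset", {
  expect_identical(molecular_formula(geometry(character(0),
                                              matrix(0, 0, 3))), "")
  expect_identical(molecular_formula(toy_molecule("water")$geometry), "H2O")
  expect_identical(molecular_formula(toy_molecule("toy-furanose")$geometry),
                   "C5H10O5")
  expect_identical(molecular_formula(toy_molecule("toy-phosphate")$geometry),
                   "H2O4P")
})

test_that("XYZ text round-trips at printed precision and flags bad input", {
  for (kind in c("water", "methanol", "toy-furanose", "toy-phosphate")) {
    g <- toy_molecule(kind)$geometry
    g2 <- read_xyz(write_xyz(g))
    expect_identical(g2$elements, g$elements)
    expect_equal(g2$coords, round(g$coords, 6), tolerance = 1e-12)
    ## second pass is the identity
    expect_identical(write_xyz(g2), write_xyz(read_xyz(write_xyz(g2))))
  }
  expect_error(read_xyz("3\ncomment\nO 0 0 0\nH 1 0 0"), "line")
  expect_error(read_xyz("2\nc\nO 0 0 zz\nH 1 0 0"), "line 3")
})

test_that("Z-matrix fixture reconstructs its declared torsions", {
  path <- system.file("extdata", "ribofuranose_toy.zmat",
                      package = "nucanomer")
  lines <- readLines(path)
  g <- read_zmatrix(lines)
  expect_identical(molecular_formula(g), "C5H10O5")
  expect_length(select_rotatable_dihedrals(g), 5)
  ## every torsion entry of the Z-matrix must re-measure to its declared
  ## value in the reconstructed Cartesian geometry
  atoms <- lines[!startsWith(lines, "#")]
  for (i in seq_along(atoms)) {
    p <- strsplit(atoms[i], "\\s+")[[1]]
    if (length(p) < 7) next
    idx <- c(i, as.integer(p[2]), as.integer(p[4]), as.integer(p[6]))
    declared <- as.numeric(p[7])
    expect_equal(wrap_angle(measure_dihedral(g, dihedral_spec(idx)) -
                              declared), 0, tolerance = 1e-6)
  }
})

test_that("bond perception is symmetric, self-edge free and deterministic", {
  g <- toy_molecule("toy-furanose")$geometry
  bg <- bond_graph(g)
  expect_true(all(bg$pairs[, 1] < bg$pairs[, 2]))
  for (i in seq_len(n_atoms(g))) {
    expect_false(i %in% bg$adj[[i]])
    for (j in bg$adj[[i]]) expect_true(i %in% bg$adj[[j]])
  }
  expect_identical(bg$pairs, bond_graph(g)$pairs)
})
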