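test_that("surrogate energy decomposes as declared and vanishes at the reference", {
  tt <- torsion_toy()
  ## at all reference bond lengths and a torsion minimum the bond+torsion
  ## energy is zero (1-3 wells sit at their own reference too)
  g_min <- set_dihedral(tt$geometry, tt$spec, 60)
  nb_ref <- surrogate_params(bonds = tt$params$bonds,
                             torsions = tt$params$torsions)
  expect_equal(surrogate_energy(g_min, nb_ref), 0, tolerance = 1e-9)
  ## rigid-motion invariance
  for (i in 1:5) {
    expect_equal(surrogate_energy(random_rigid(tt$geometry, i), tt$params),
                 surrogate_energy(tt$geometry, tt$params),
                 tolerance = 1e-9)
  }
  ## singular-pair guard
  g_bad <- geometry(c("C", "C"), rbind(c(0, 0, 0), c(0.05, 0, 0)))
  p_bad <- surrogate_params(nonbonded = data.frame(i = 1, j = 2, eps = 1,
                                                   rmin = 3))
  expect_error(surrogate_energy(g_bad, p_bad), "singular pair")
})

test_that("a 3-fold torsion has minima at staggered and maxima at eclipsed angles", {
  tt <- torsion_toy(v = 2, n_fold = 3, gamma = 0)
  ## dense 1-degree brute-force grid on the bare torsion term
  grid <- seq(-179, 180, by = 1)
  prof <- torsion_term(grid, v = 2, n_fold = 3, gamma = 0)
  minima <- grid[which(prof < 1e-12)]
  maxima <- grid[which(prof > 2 - 1e-12)]
  expect_setequal(minima, c(-60, 60, 180))
  expect_setequal(maxima, c(-120, 0, 120))
  ## the full surrogate profile along the torsion reproduces the term up
  ## to a constant (other terms unchanged by the rotation)
  e_at <- vapply(c(-120, -60, 0, 60, 120, 180), function(a) {
    surrogate_energy(set_dihedral(tt$geometry, tt$spec, a), tt$params)
  }, numeric(1))
  expect_equal(e_at - min(e_at),
               torsion_term(c(-120, -60, 0, 60, 120, 180)),
               tolerance = 1e-9)
})

test_that("optimization descends, converges, and respects frozen torsions", {
  ## diatomic with a stretched harmonic bond relaxes to the reference
  di <- geometry(c("O", "O"), rbind(c(0, 0, 0), c(1.9, 0, 0)))
  pp <- surrogate_params(bonds = data.frame(i = 1, j = 2, k = 300,
                                            r0 = 1.45))
  be <- surrogate_backend(pp)
  res <- be$optimize(di)
  expect_true(res$converged)
  expect_equal(sqrt(sum((res$geometry$coords[1, ] -
                           res$geometry$coords[2, ])^2)), 1.45,
               tolerance = 1e-6)

  ## starting at a minimum stays put
  res0 <- be$optimize(res$geometry)
  expect_equal(res0$geometry$coords, res$geometry$coords, tolerance = 1e-6)

  ## frozen torsion: energy relaxes, torsion pinned to 40 degrees
  tt <- torsion_toy()
  g40 <- set_dihedral(tt$geometry, tt$spec, 40)
  bet <- surrogate_backend(tt$params)
  rf <- bet$optimize(g40, frozen = list(list(spec = tt$spec, target = 40)))
  expect_true(rf$converged)
  expect_equal(wrap_angle(measure_dihedral(rf$geometry, tt$spec) - 40), 0,
               tolerance = 1e-6)
  ## the frozen result must match freezing by hand: unconstrained
  ## optimization of the non-torsion terms with the torsion re-imposed
  runc <- bet$optimize(g40)
  manual <- set_dihedral(runc$geometry, tt$spec, 40)
  expect_equal(rf$energy, surrogate_energy(manual, tt$params),
               tolerance = 1e-4)

  ## descent property over random starts
  set.seed(5)
  for (k in 1:100) {
    gs <- tt$geometry
    gs$coords <- gs$coords + matrix(stats::rnorm(12, sd = 0.15), 4, 3)
    e_in <- surrogate_energy(gs, tt$params)
    r <- bet$optimize(gs)
    expect_lte(r$energy, e_in + 1e-9)
  }
})

test_that("surrogate frequencies match the analytic diatomic oscillator", {
  di <- geometry(c("O", "O"), rbind(c(0, 0, 0), c(1.45, 0, 0)))
  pp <- surrogate_params(bonds = data.frame(i = 1, j = 2, k = 300,
                                            r0 = 1.45))
  freqs <- surrogate_frequencies(di, pp)
  expect_length(freqs, 1)
  ## omega = sqrt(k_force/mu), k_force = 2k (E = k (r-r0)^2)
  mu <- 15.999 / 2
  conv <- (PHYS_CONST$cal * 1000 / PHYS_CONST$`NA`) /
    (1e-20 * PHYS_CONST$amu)
  nu_ref <- sqrt(2 * 300 * conv / mu) / (2 * pi * PHYS_CONST$c)
  expect_equal(freqs, nu_ref, tolerance = 1e-4)
})

test_that("qc output parsing extracts energies, frequencies and flags", {
  mop <- paste(
    " MOPAC fixture",
    "          FINAL HEAT OF FORMATION =      -123.45678 KCAL/MOL",
    "   FREQ.       100.2500",
    "   FREQ.      2000.5000",
    sep = "\n")
  rec <- parse_qc_output(mop, "mopac_out")
  expect_equal(rec$energy, -123.45678)
  expect_equal(rec$frequencies, c(100.25, 2000.5))
  expect_true(rec$is_minimum)

  gau <- paste(
    " fixture",
    " SCF Done:  E(RB3LYP) =      -0.200000000     A.U. after 1 cycles",
    " Frequencies --    500.0000   1000.0000",
    " Sum of electronic and thermal Free Energies=        -0.100000000",
    sep = "\n")
  rg <- parse_qc_output(gau, "gaussian_log")
  expect_equal(rg$gibbs, -62.75095, tolerance = 1e-9) # -0.1 hartree
  expect_equal(rg$energy, -125.5019, tolerance = 1e-4)
  expect_equal(rg$frequencies, c(500, 1000))

  neg <- sub("500.0000", "-500.0000", gau, fixed = TRUE)
  expect_false(parse_qc_output(neg, "gaussian_log")$is_minimum)
  expect_error(parse_qc_output("nothing here", "mopac_out"), "parse error")
  expect_error(parse_qc_output("nothing here", "gaussian_log"),
               "parse error")
})

test_that("input decks embed geometry and charge and round-trip", {
  ph <- toy_molecule("toy-phosphate")$geometry
  for (dialect in c("mop", "gjf")) {
    deck <- write_qc_input(ph, dialect, keywords = c("OPT"))
    if (dialect == "mop") {
      expect_match(deck, "CHARGE=-1")
    } else {
      expect_match(deck, "\n-1 1\n")
    }
    back <- read_qc_input(deck, dialect)
    expect_identical(back$elements, ph$elements)
    expect_identical(back$charge, -1L)
    expect_equal(back$coords, ph$coords, tolerance = 1e-6)
  }
  empty <- geometry(character(0), matrix(0, 0, 3))
  expect_error(write_qc_input(empty, "mop"), "empty")
})
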