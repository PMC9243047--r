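test_that("rotatable-dihedral selection finds the hydroxyl set", {
  expect_length(toy_molecule("toy-furanose")$rotatable, 5)      # 4 OH + beta
  expect_length(toy_molecule("toy-deoxyfuranose")$rotatable, 4) # 3 OH + beta
  expect_length(toy_molecule("methanol")$rotatable, 1)
  expect_warning(out <- select_rotatable_dihedrals(
    toy_molecule("water")$geometry), "no rotatable")
  expect_length(out, 0)
  ## deterministic ordering and validity
  tf <- toy_molecule("toy-furanose")
  again <- select_rotatable_dihedrals(tf$geometry)
  expect_identical(lapply(again, `[[`, "atoms"),
                   lapply(tf$rotatable, `[[`, "atoms"))
  for (s in tf$rotatable) expect_true(validate_dihedral(tf$geometry, s))
})

test_that("conformer generation is exact-count, seeded and non-mutating", {
  tm <- toy_molecule("toy-deoxyfuranose")
  before <- tm$geometry$coords
  plan <- sampling_plan(tm$rotatable, n = 50, seed = 11)
  cs1 <- generate_conformers(tm$geometry, plan)
  cs2 <- generate_conformers(tm$geometry, plan)
  expect_length(cs1, 50)
  expect_identical(tm$geometry$coords, before)
  d1 <- t(vapply(cs1, `[[`, numeric(4), "dihedrals"))
  d2 <- t(vapply(cs2, `[[`, numeric(4), "dihedrals"))
  expect_identical(d1, d2)
  expect_true(all(d1 >= -180 & d1 < 180))
  ## set angles are realized in the geometries
  for (i in c(1, 25, 50)) {
    meas <- vapply(tm$rotatable, function(s) {
      measure_dihedral(cs1[[i]]$geometry, s)
    }, numeric(1))
    expect_equal(wrap_angle(meas - d1[i, ]), rep(0, 4), tolerance = 1e-6)
  }
  expect_error(generate_conformers(tm$geometry,
                                   sampling_plan(list(), n = 5)),
               "degenerate plan")
})

test_that("sampled torsions are uniform over the circle", {
  tm <- toy_molecule("methanol")
  plan <- sampling_plan(tm$rotatable, n = 10000, seed = 42)
  cs <- generate_conformers(tm$geometry, plan)
  ang <- vapply(cs, `[[`, numeric(1), "dihedrals")
  counts <- table(cut(ang, breaks = seq(-180, 180, by = 30)))
  expect_length(counts, 12)
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.001)
})

test_that("deduplication merges planted clusters and matches a brute-force oracle", {
  tm <- toy_molecule("methanol")
  base <- tm$geometry
  spec_list <- tm$rotatable
  mk <- function(angle, energy, idx) {
    structure(list(geometry = set_dihedral(base, spec_list[[1]], angle),
                   dihedrals = angle, energy = energy,
                   provenance = list(seed = 1, index = idx, backend = "t")),
              class = "conformer")
  }
  ## 50 conformers around 3 planted centroids, jitter below tolerance
  set.seed(7)
  centroids <- c(-150, -30, 90)
  e0 <- c(0, 1, 2)
  picks <- sample(1:3, 50, replace = TRUE)
  cs <- structure(lapply(seq_len(50), function(i) {
    mk(wrap_angle(centroids[picks[i]] + stats::runif(1, -5, 5)),
       e0[picks[i]] + stats::runif(1, 0, 0.05), i)
  }), class = "conformer_set", dihedral_specs = spec_list)
  u <- deduplicate_minima(cs, energy_tol = 0.1, dihedral_tol = 15)
  expect_length(u, 3)
  en <- vapply(u, `[[`, numeric(1), "energy")
  expect_identical(order(en), seq_along(en)) # sorted ascending

  ## brute-force transitive-closure oracle on the same instance
  oracle_clusters <- function(cs, etol, dtol) {
    n <- length(cs)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        adj[i, j] <- abs(cs[[i]]$energy - cs[[j]]$energy) <= etol &&
          all(abs(wrap_angle(cs[[i]]$dihedrals - cs[[j]]$dihedrals)) <= dtol)
      }
    }
    reach <- adj
    for (k in seq_len(n)) {
      reach <- reach | (reach[, k] %o% reach[k, ])
    }
    length(unique(apply(reach, 1, function(r) paste(which(r),
                                                    collapse = ","))))
  }
  small <- structure(cs[1:25], class = "conformer_set",
                     dihedral_specs = spec_list)
  expect_length(deduplicate_minima(small, 0.1, 15),
                oracle_clusters(small, 0.1, 15))

  ## idempotence and trivial cases
  expect_length(deduplicate_minima(u, 0.1, 15), length(u))
  k_copies <- structure(rep(cs[1], 5), class = "conformer_set",
                        dihedral_specs = spec_list)
  expect_length(deduplicate_minima(k_copies), 1)
  two <- structure(list(mk(0, 0, 1), mk(120, 0, 2)),
                   class = "conformer_set", dihedral_specs = spec_list)
  expect_length(deduplicate_minima(two), 2)
  ## missing energies are a precondition error
  bad <- structure(list(structure(list(geometry = base, dihedrals = 0,
                                       energy = NA_real_,
                                       provenance = list(seed = 1, index = 1,
                                                         backend = "t")),
                                  class = "conformer")),
                   class = "conformer_set", dihedral_specs = spec_list)
  expect_error(deduplicate_minima(bad), "energies")
})
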