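## Shared fixtures, built in code.

## Butane-like 4-carbon chain with a prescribed 1-2-3-4 torsion.
make_chain <- function(phi = 60, angle = 111, r = 1.53) {
  p1 <- c(0, 0, 0)
  p2 <- c(r, 0, 0)
  p3 <- place_atom(p2, p1, c(0, 1, 0), r, angle, 0)
  p4 <- place_atom(p3, p2, p1, r, angle, phi)
  geometry(rep("C", 4), rbind(p1, p2, p3, p4), label = "chain")
}

## A random rigid motion, deterministic in `i`.
random_rigid <- function(geom, i) {
  set.seed(1000 + i)
  rigid_transform(geom,
                  axis = stats::rnorm(3),
                  angle = stats::runif(1, -180, 180),
                  shift = stats::rnorm(3, sd = 5))
}

## Minimal torsion toy: 4-atom chain with harmonic bonds, stiff 1-3
## wells, and one 3-fold torsion term (barrier 2, phase 0).
torsion_toy <- function(v = 2, n_fold = 3, gamma = 0) {
  g <- make_chain(40)
  d <- as.matrix(stats::dist(g$coords))
  params <- surrogate_params(
    bonds = data.frame(i = 1:3, j = 2:4, k = 300,
                       r0 = c(d[1, 2], d[2, 3], d[3, 4])),
    torsions = data.frame(i = 1, j = 2, k = 3, l = 4, v = v, n = n_fold,
                          gamma = gamma),
    nonbonded = data.frame(i = c(1, 2), j = c(3, 4), eps = 20,
                           rmin = c(d[1, 3], d[2, 4]))
  )
  list(geometry = g, params = params,
       spec = dihedral_spec(1:4, "C-C-C-C"))
}

## Bare torsion-only energy (dense-grid oracle helper): the surrogate
## torsion term evaluated on its own.
torsion_term <- function(phi, v = 2, n_fold = 3, gamma = 0) {
  v / 2 * (1 + cos((n_fold * phi - gamma) * pi / 180))
}
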