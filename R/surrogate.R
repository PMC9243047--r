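## Surrogate molecular-mechanics potential: harmonic bonds, cosine torsions,
## and 12-6 pairwise nonbonded terms.  It stands behind the same backend
## contract as external quantum-chemistry programs so the full pipeline runs
## self-contained; it makes no claim to quantitative chemistry.

#' Surrogate potential parameters
#'
#' @param bonds data.frame with columns `i`, `j` (atom indices), `k`
#'   (force constant, kcal/mol/A^2; E = k (r - r0)^2) and `r0` (reference
#'   length, Angstrom)
#' @param torsions data.frame with columns `i`, `j`, `k`, `l` (atom
#'   indices), `v` (barrier, kcal/mol), `n` (multiplicity) and `gamma`
#'   (phase, degrees); E = v/2 (1 + cos(n phi - gamma))
#' @param nonbonded data.frame with columns `i`, `j`, `eps` (well depth,
#'   kcal/mol) and `rmin` (minimum-energy distance, Angstrom);
#'   E = eps ((rmin/r)^12 - 2 (rmin/r)^6)
#' @return a `surrogate_params` object
#' @export
surrogate_params <- function(bonds = NULL, torsions = NULL, nonbonded = NULL) {
  empty <- function(cols) {
    stats::setNames(as.data.frame(rep(list(numeric(0)), length(cols))), cols)
  }
  if (is.null(bonds)) bonds <- empty(c("i", "j", "k", "r0"))
  if (is.null(torsions)) torsions <- empty(c("i", "j", "k", "l", "v", "n", "gamma"))
  if (is.null(nonbonded)) nonbonded <- empty(c("i", "j", "eps", "rmin"))
  stopifnot(all(bonds$k >= 0), all(bonds$r0 > 0),
            all(torsions$v >= 0), all(nonbonded$eps >= 0),
            all(nonbonded$rmin > 0))
  structure(list(bonds = bonds, torsions = torsions, nonbonded = nonbonded),
            class = "surrogate_params")
}

#' Build surrogate parameters around a reference geometry
#'
#' Bonds come from the perceived bond graph with reference lengths taken
#' from the input geometry; 1-3 pairs get a stiff 12-6 well at their current
#' separation (keeping angles near the reference without a separate angle
#' term); pairs four or more bonds apart get a soft long-range 12-6 term.
#' Each supplied rotatable dihedral gets a 3-fold cosine term.
#'
#' @param geom reference `geometry`
#' @param rotatable list of `dihedral_spec` to receive torsion terms
#' @param k_bond,v_torsion,eps_13,eps_far,rmin_far term parameters
#' @return a `surrogate_params`
#' @export
default_surrogate_params <- function(geom, rotatable = list(),
                                     k_bond = 300, v_torsion = 2,
                                     eps_13 = 20, eps_far = 0.05,
                                     rmin_far = 3.2) {
  bg <- bond_graph(geom)
  d <- as.matrix(stats::dist(geom$coords))
  bonds <- if (nrow(bg$pairs)) {
    data.frame(i = bg$pairs[, 1], j = bg$pairs[, 2], k = k_bond,
               r0 = d[bg$pairs])
  } else NULL
  ## graph distances (small molecules: BFS per atom)
  n <- n_atoms(geom)
  gd <- matrix(Inf, n, n); diag(gd) <- 0
  for (s in seq_len(n)) {
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in bg$adj[[v]]) {
        if (gd[s, w] > gd[s, v] + 1) {
          gd[s, w] <- gd[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  nb <- NULL
  if (n >= 3) {
    ut <- which(upper.tri(gd), arr.ind = TRUE)
    sep <- gd[ut]
    p13 <- ut[sep == 2, , drop = FALSE]
    pfar <- ut[sep >= 4, , drop = FALSE]
    nb <- rbind(
      if (nrow(p13)) data.frame(i = p13[, 1], j = p13[, 2], eps = eps_13,
                                rmin = d[p13]),
      if (nrow(pfar)) data.frame(i = pfar[, 1], j = pfar[, 2], eps = eps_far,
                                 rmin = rmin_far)
    )
  }
  tors <- if (length(rotatable)) {
    do.call(rbind, lapply(rotatable, function(s) {
      data.frame(i = s$atoms[1], j = s$atoms[2], k = s$atoms[3],
                 l = s$atoms[4], v = v_torsion, n = 3, gamma = 0)
    }))
  } else NULL
  surrogate_params(bonds = bonds, torsions = tors, nonbonded = nb)
}

#' Surrogate potential energy of a geometry
#'
#' @param geom a `geometry`
#' @param params a `surrogate_params`
#' @return energy in kcal/mol
#' @export
surrogate_energy <- function(geom, params) {
  xyz <- geom$coords
  e <- 0
  b <- params$bonds
  if (nrow(b)) {
    dv <- xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE]
    r <- sqrt(rowSums(dv^2))
    e <- e + sum(b$k * (r - b$r0)^2)
  }
  tt <- params$torsions
  if (nrow(tt)) {
    for (m in seq_len(nrow(tt))) {
      phi <- measure_dihedral(geom, dihedral_spec(
        c(tt$i[m], tt$j[m], tt$k[m], tt$l[m])))
      e <- e + tt$v[m] / 2 *
        (1 + cos((tt$n[m] * phi - tt$gamma[m]) * pi / 180))
    }
  }
  nb <- params$nonbonded
  if (nrow(nb)) {
    dv <- xyz[nb$i, , drop = FALSE] - xyz[nb$j, , drop = FALSE]
    r <- sqrt(rowSums(dv^2))
    if (any(r < 0.1)) stop("singular pair: atoms closer than 0.1 Angstrom")
    q <- (nb$rmin / r)^6
    e <- e + sum(nb$eps * (q^2 - 2 * q))
  }
  e
}

## Gradient of the surrogate energy, analytic for bonds and nonbonded
## terms, numeric (central difference on the torsion angle) for torsions.
## Returns an n x 3 matrix in kcal/mol/Angstrom.
surrogate_gradient <- function(geom, params, h = 1e-6) {
  xyz <- geom$coords
  g <- matrix(0, nrow(xyz), 3)
  b <- params$bonds
  if (nrow(b)) {
    dv <- xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE]
    r <- sqrt(rowSums(dv^2))
    coef <- 2 * b$k * (r - b$r0) / r
    for (m in seq_len(nrow(b))) {
      gi <- coef[m] * dv[m, ]
      g[b$i[m], ] <- g[b$i[m], ] + gi
      g[b$j[m], ] <- g[b$j[m], ] - gi
    }
  }
  nb <- params$nonbonded
  if (nrow(nb)) {
    dv <- xyz[nb$i, , drop = FALSE] - xyz[nb$j, , drop = FALSE]
    r <- sqrt(rowSums(dv^2))
    if (any(r < 0.1)) stop("singular pair: atoms closer than 0.1 Angstrom")
    q <- (nb$rmin / r)^6
    dEdr <- -12 * nb$eps * (q^2 - q) / r
    for (m in seq_len(nrow(nb))) {
      gi <- dEdr[m] * dv[m, ] / r[m]
      g[nb$i[m], ] <- g[nb$i[m], ] + gi
      g[nb$j[m], ] <- g[nb$j[m], ] - gi
    }
  }
  tt <- params$torsions
  if (nrow(tt)) {
    for (m in seq_len(nrow(tt))) {
      idx <- c(tt$i[m], tt$j[m], tt$k[m], tt$l[m])
      spec <- dihedral_spec(idx)
      tfun <- function(gg) {
        phi <- measure_dihedral(gg, spec)
        tt$v[m] / 2 * (1 + cos((tt$n[m] * phi - tt$gamma[m]) * pi / 180))
      }
      for (a in idx) {
        for (k in 1:3) {
          gp <- geom; gp$coords[a, k] <- gp$coords[a, k] + h
          gm <- geom; gm$coords[a, k] <- gm$coords[a, k] - h
          g[a, k] <- g[a, k] + (tfun(gp) - tfun(gm)) / (2 * h)
        }
      }
    }
  }
  g
}
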