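## Pluggable energy-backend contract.  A backend supplies evaluate /
## optimize / frequencies for a geometry; the built-in surrogate backend
## keeps the whole pipeline self-contained, and a fixture backend serves
## energies parsed from quantum-chemistry log files.

#' Construct a surrogate energy backend
#'
#' @param params a `surrogate_params`
#' @param phase phase tag, `"vacuum"` or `"aqueous"` (a pass-through label;
#'   no solvation physics is simulated)
#' @param grad_tol RMS-gradient convergence tolerance, kcal/mol/Angstrom
#' @param maxit maximum optimizer iterations
#' @return an `energy_backend`
#' @export
surrogate_backend <- function(params, phase = c("vacuum", "aqueous"),
                              grad_tol = 1e-4, maxit = 500) {
  phase <- match.arg(phase)
  be <- list(
    tag = "surrogate",
    phase = phase,
    evaluate = function(geom) surrogate_energy(geom, params),
    gradient = function(geom) surrogate_gradient(geom, params),
    optimize = function(geom, frozen = list()) {
      optimize_geometry(geom, params, frozen = frozen,
                        grad_tol = grad_tol, maxit = maxit)
    },
    frequencies = function(geom) surrogate_frequencies(geom, params)
  )
  structure(be, class = "energy_backend")
}

#' Construct a fixture-backed energy backend
#'
#' Serves energies looked up by geometry label from pre-parsed
#' [energy_record()]s (e.g. from [parse_qc_output()]).  Optimization is an
#' identity operation (the fixtures are already optimized structures).
#'
#' @param records named list of `energy_record`s keyed by geometry label
#' @param phase phase tag
#' @return an `energy_backend`
#' @export
fixture_backend <- function(records, phase = c("vacuum", "aqueous")) {
  phase <- match.arg(phase)
  lookup <- function(geom) {
    rec <- records[[geom$label]]
    if (is.null(rec)) stop("no fixture record for label: ", geom$label)
    rec
  }
  structure(list(
    tag = "fixtures",
    phase = phase,
    evaluate = function(geom) lookup(geom)$energy,
    optimize = function(geom, frozen = list()) {
      list(geometry = geom, converged = TRUE, grad_norm = 0,
           energy = lookup(geom)$energy)
    },
    frequencies = function(geom) lookup(geom)$frequencies
  ), class = "energy_backend")
}

#' Locally optimize a geometry on the surrogate potential
#'
#' BFGS minimization over Cartesian coordinates.  Frozen dihedrals are
#' enforced by projection: after each inner BFGS cycle the frozen torsions
#' are re-imposed exactly, and convergence is judged on the gradient
#' projected onto the constraint-satisfying subspace.
#'
#' @param geom starting `geometry`
#' @param params a `surrogate_params`
#' @param frozen list of constraints, each `list(spec = dihedral_spec,
#'   target = degrees)`; an unnamed `dihedral_spec` freezes the torsion at
#'   its current value
#' @param grad_tol RMS-gradient tolerance, kcal/mol/Angstrom
#' @param maxit total iteration budget
#' @return list with `geometry`, `converged`, `grad_norm`, `energy`
#' @export
optimize_geometry <- function(geom, params, frozen = list(),
                              grad_tol = 1e-4, maxit = 500) {
  frozen <- lapply(frozen, function(f) {
    if (inherits(f, "dihedral_spec")) {
      list(spec = f, target = measure_dihedral(geom, f))
    } else f
  })
  n <- n_atoms(geom)
  e_in <- surrogate_energy(geom, params)
  shape <- function(x) matrix(x, n, 3)
  impose <- function(g) {
    for (f in frozen) g <- set_dihedral(g, f$spec, f$target)
    g
  }
  project <- function(gvec, g) {
    ## remove components along the numeric constraint normals
    if (!length(frozen)) return(gvec)
    h <- 1e-5
    basis <- NULL
    for (f in frozen) {
      grad_phi <- numeric(3 * n)
      idx <- f$spec$atoms
      for (a in idx) {
        for (k in 1:3) {
          gp <- g; gp$coords[a, k] <- gp$coords[a, k] + h
          gm <- g; gm$coords[a, k] <- gm$coords[a, k] - h
          grad_phi[(k - 1) * n + a] <-
            wrap_angle(measure_dihedral(gp, f$spec) -
                         measure_dihedral(gm, f$spec)) / (2 * h)
        }
      }
      basis <- cbind(basis, grad_phi)
    }
    qb <- qr.Q(qr(basis))
    gvec - qb %*% (t(qb) %*% gvec)
  }
  g <- impose(geom)
  ## frozen torsions are held by a stiff harmonic restraint during the
  ## BFGS search; between rounds the restraint centre is shifted so the
  ## penalized minimum lands on the exact target angle, and any residual
  ## torsion error is finally removed by projection (set_dihedral).
  ## Convergence is judged on the gradient projected onto the
  ## constraint-satisfying subspace.
  k_pen <- 20000 # kcal/mol/rad^2
  centres <- vapply(frozen, function(f) f$target, numeric(1))
  penalty <- function(gg) {
    if (!length(frozen)) return(0)
    s <- 0
    for (i in seq_along(frozen)) {
      dphi <- wrap_angle(measure_dihedral(gg, frozen[[i]]$spec) -
                           centres[i]) * pi / 180
      s <- s + k_pen * dphi^2
    }
    s
  }
  penalty_grad <- function(gg) {
    gp <- matrix(0, n, 3)
    h <- 1e-6
    for (i in seq_along(frozen)) {
      f <- frozen[[i]]
      dphi0 <- wrap_angle(measure_dihedral(gg, f$spec) - centres[i]) *
        pi / 180
      for (a in f$spec$atoms) {
        for (k in 1:3) {
          gph <- gg; gph$coords[a, k] <- gph$coords[a, k] + h
          gmh <- gg; gmh$coords[a, k] <- gmh$coords[a, k] - h
          dphidx <- wrap_angle(measure_dihedral(gph, f$spec) -
                                 measure_dihedral(gmh, f$spec)) *
            pi / 180 / (2 * h)
          gp[a, k] <- gp[a, k] + 2 * k_pen * dphi0 * dphidx
        }
      }
    }
    gp
  }
  fn <- function(x) {
    gg <- g; gg$coords <- shape(x)
    surrogate_energy(gg, params) + penalty(gg)
  }
  gr <- function(x) {
    gg <- g; gg$coords <- shape(x)
    as.vector(surrogate_gradient(gg, params) + penalty_grad(gg))
  }
  used <- 0L
  converged <- FALSE
  grad_norm <- NA_real_
  repeat {
    inner <- maxit - used
    if (inner <= 0L) break
    res <- stats::optim(as.vector(g$coords), fn, gr, method = "BFGS",
                        control = list(maxit = inner, reltol = 1e-14))
    used <- used + max(res$counts[["gradient"]], 1L)
    cand <- g; cand$coords <- shape(res$par)
    if (length(frozen)) {
      ## shift restraint centres to cancel the torsion offset
      err <- vapply(seq_along(frozen), function(i) {
        wrap_angle(measure_dihedral(cand, frozen[[i]]$spec) -
                     frozen[[i]]$target)
      }, numeric(1))
      centres <- centres - err
      if (max(abs(err)) > 1e-7) {
        g <- cand
        next
      }
      cand <- impose(cand) # remove the (now sub-1e-7 degree) residual
    }
    if (surrogate_energy(cand, params) <=
          surrogate_energy(g, params) + penalty(g) + 1e-12) {
      g <- cand
    }
    gvec <- as.vector(surrogate_gradient(g, params))
    gproj <- project(gvec, g)
    grad_norm <- sqrt(mean(gproj^2))
    if (grad_norm <= grad_tol) { converged <- TRUE; break }
    if (used >= maxit) break
  }
  e_out <- surrogate_energy(g, params)
  if (e_out > e_in + 1e-9) { # never report an uphill "optimization"
    g <- impose(geom); e_out <- surrogate_energy(g, params)
  }
  list(geometry = g, converged = converged, grad_norm = grad_norm,
       energy = e_out)
}

#' Harmonic frequencies on the surrogate potential
#'
#' Numeric mass-weighted Hessian (central differences of the gradient),
#' eigen-decomposed into normal modes.  The six (five for linear tops)
#' near-zero external modes are dropped; negative-curvature modes are
#' reported as negative wavenumbers.
#'
#' @param geom a `geometry`
#' @param params a `surrogate_params`
#' @param h finite-difference step, Angstrom
#' @return numeric vector of wavenumbers in cm^-1, ascending
#' @export
surrogate_frequencies <- function(geom, params, h = 1e-4) {
  n <- n_atoms(geom)
  if (n < 2) return(numeric(0))
  H <- matrix(0, 3 * n, 3 * n)
  for (a in seq_len(n)) {
    for (k in 1:3) {
      gp <- geom; gp$coords[a, k] <- gp$coords[a, k] + h
      gm <- geom; gm$coords[a, k] <- gm$coords[a, k] - h
      col <- (as.vector(surrogate_gradient(gp, params)) -
                as.vector(surrogate_gradient(gm, params))) / (2 * h)
      H[, (k - 1) * n + a] <- col
    }
  }
  H <- (H + t(H)) / 2
  m <- rep(atomic_masses(geom$elements), times = 3)
  Hmw <- H / sqrt(outer(m, m))
  ev <- eigen(Hmw, symmetric = TRUE, only.values = TRUE)$values
  ## lambda [kcal/mol/A^2/amu] -> omega^2 [1/s^2]
  conv <- (PHYS_CONST$cal * 1000 / PHYS_CONST$`NA`) /
    (1e-20 * PHYS_CONST$amu)
  omega2 <- ev * conv
  nu <- sign(omega2) * sqrt(abs(omega2)) / (2 * pi * PHYS_CONST$c)
  n_external <- if (is_linear_geometry(geom)) 5L else 6L
  keep <- order(abs(nu))[-seq_len(min(n_external, length(nu)))]
  sort(nu[keep])
}

## Linear-top test from principal moments of inertia.
is_linear_geometry <- function(geom, tol = 1e-6) {
  pm <- principal_moments(geom)
  length(pm) && pm[1] < tol * max(pm[3], 1)
}

## Principal moments of inertia in amu * A^2, ascending.
principal_moments <- function(geom) {
  m <- atomic_masses(geom$elements)
  x <- geom$coords
  com <- colSums(x * m) / sum(m)
  x <- sweep(x, 2, com)
  I <- matrix(0, 3, 3)
  for (a in seq_along(m)) {
    r <- x[a, ]
    I <- I + m[a] * (sum(r^2) * diag(3) - r %o% r)
  }
  sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
}
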