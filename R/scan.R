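## Soft (relaxed) torsion scan driver: step one dihedral through a grid,
## relax everything else at each point, then refine the lowest grid point
## to a frequency-vetted minimum.  Mirrors the protocol used for the
## glycosidic-bond and 5'-phosphate torsions: 6 steps of 60 degrees from
## the initial angle, glycosidic bond started at 1.52 Angstrom with the
## H-C1'-N-Cx torsion at -161.9 degrees and the phosphate O-C5'-C4'-C3'
## torsion at 30.9 degrees.

#' Protocol constants for the two standard torsion scans
#'
#' @return named list: glycosidic bond length (Angstrom), glycosidic
#'   initial torsion (degrees), phosphate initial torsion (degrees), scan
#'   step (degrees), step count
#' @export
scan_constants <- function() {
  list(glycosidic_bond_length = 1.52,
       glycosidic_initial_angle = -161.9,
       phosphate_initial_angle = 30.9,
       step = 60,
       n_steps = 6L)
}

#' Declare a relaxed-scan protocol
#'
#' @param dihedral the `dihedral_spec` to scan
#' @param start starting angle in degrees; `NULL` means the current angle
#'   of the input geometry
#' @param step grid step in degrees (nonzero; default 60)
#' @param n_steps number of grid points (default 6)
#' @return a `scan_protocol`
#' @export
scan_protocol <- function(dihedral, start = NULL, step = 60, n_steps = 6L) {
  stopifnot(n_steps >= 1, step != 0)
  structure(list(dihedral = dihedral, start = start, step = step,
                 n_steps = as.integer(n_steps)),
            class = "scan_protocol")
}

#' Run a soft (relaxed) scan around one dihedral
#'
#' At each grid angle the scanned dihedral is frozen and all remaining
#' coordinates are relaxed; each grid point starts from the previous
#' relaxed structure (chain continuation).  Unconverged points are flagged
#' and excluded from the argmin.
#'
#' @param geom starting `geometry`
#' @param protocol a [scan_protocol()]
#' @param backend an `energy_backend` providing constrained optimization
#' @return a `scan_result`: data.frame-like list with `angles` (wrapped to
#'   (-180, 180]), `energies`, `converged`, `argmin` (index into the grid,
#'   NA if nothing converged), and the relaxed `geometries`
#' @export
soft_scan <- function(geom, protocol, backend) {
  spec <- protocol$dihedral
  validate_dihedral(geom, spec)
  start <- if (is.null(protocol$start)) measure_dihedral(geom, spec)
           else protocol$start
  raw_grid <- start + protocol$step * (seq_len(protocol$n_steps) - 1L)
  grid <- wrap_angle(raw_grid)
  energies <- rep(NA_real_, length(grid))
  converged <- logical(length(grid))
  geometries <- vector("list", length(grid))
  current <- geom
  for (i in seq_along(grid)) {
    current <- set_dihedral(current, spec, grid[i])
    res <- backend$optimize(current, frozen = list(
      list(spec = spec, target = grid[i])))
    energies[i] <- res$energy
    converged[i] <- res$converged
    geometries[[i]] <- res$geometry
    current <- res$geometry
  }
  ok <- which(converged)
  argmin <- if (length(ok)) {
    ## ties broken toward the smaller wrapped angle
    ok[order(energies[ok], grid[ok])][1]
  } else NA_integer_
  structure(list(angles = grid, energies = energies, converged = converged,
                 argmin = argmin, geometries = geometries,
                 dihedral = spec),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result>\n")
  for (i in seq_along(x$angles)) {
    cat(sprintf("  %8.1f deg  %12.6f kcal/mol  %s%s\n", x$angles[i],
                x$energies[i],
                if (x$converged[i]) "converged" else "UNCONVERGED",
                if (identical(i, x$argmin) ||
                      (!is.na(x$argmin) && i == x$argmin)) "  <- argmin"
                else ""))
  }
  invisible(x)
}

#' Refine the scan minimum to a vetted conformer
#'
#' Fully unconstrained optimization from the argmin grid structure,
#' followed by a harmonic-frequency vetting: the result is flagged a true
#' minimum only when no imaginary mode remains.
#'
#' @param scan a `scan_result` with a converged argmin
#' @param backend an `energy_backend`
#' @return a list with `geometry`, `energy`, `frequencies`,
#'   `is_minimum`, and `n_imaginary`
#' @export
refine_minimum <- function(scan, backend) {
  if (is.na(scan$argmin)) stop("scan has no converged grid point to refine")
  res <- backend$optimize(scan$geometries[[scan$argmin]])
  freqs <- backend$frequencies(res$geometry)
  n_imag <- sum(freqs < -1) # cm^-1; numeric-noise modes are not imaginary
  list(geometry = res$geometry, energy = res$energy,
       frequencies = freqs, is_minimum = n_imag == 0,
       n_imaginary = n_imag, converged = res$converged)
}

#' Write a scan profile CSV and multi-XYZ trajectory
#'
#' @param scan a `scan_result`
#' @param csv_path,xyz_path output paths
#' @return invisibly, the profile data.frame
#' @export
write_scan <- function(scan, csv_path, xyz_path = NULL) {
  df <- data.frame(angle = round(scan$angles, 6),
                   energy = round(scan$energies, 9),
                   converged = scan$converged)
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(xyz_path)) {
    xyz <- vapply(scan$geometries, function(g) write_xyz(g), character(1))
    writeLines(sub("\n$", "", xyz), xyz_path)
  }
  invisible(df)
}
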