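## Molecular geometry: construction, bond perception, torsion measurement and
## manipulation, Hill formulas, and XYZ / Z-matrix text I/O.
##
## Conventions: coordinates in Angstrom; torsions are signed IUPAC angles in
## (-180, 180]; atom indices are 1-based everywhere.

#' Create a molecular geometry
#'
#' @param elements character vector of element symbols
#' @param coords numeric matrix, one row per atom, columns x/y/z in Angstrom
#' @param charge integer net charge in elementary charges
#' @param label free-text label
#' @return an object of class `geometry`
#' @export
geometry <- function(elements, coords, charge = 0L, label = "") {
  elements <- as.character(elements)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(elements) != nrow(coords)) {
    stop("elements and coords disagree on atom count")
  }
  if (length(elements) && !all(is.finite(coords))) {
    stop("all coordinates must be finite")
  }
  unknown <- setdiff(unique(elements), names(.ATOMIC_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  structure(
    list(elements = elements, coords = coords,
         charge = as.integer(charge), label = as.character(label)),
    class = "geometry"
  )
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry> %s: %d atoms, charge %+d, formula %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              n_atoms(x), x$charge, molecular_formula(x)))
  invisible(x)
}

#' Number of atoms in a geometry
#' @param geom a `geometry`
#' @export
n_atoms <- function(geom) length(geom$elements)

#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below the sum of their covalent
#' radii times a tolerance factor.  Deterministic for a fixed geometry.
#'
#' @param geom a `geometry`
#' @param tol multiplicative tolerance on the covalent-radius sum
#' @return a `bond_graph`: list with `pairs` (two-column index matrix, i < j)
#'   and `adj` (list of sorted neighbour vectors per atom)
#' @export
bond_graph <- function(geom, tol = 1.15) {
  n <- n_atoms(geom)
  adj <- rep(list(integer(0)), n)
  pairs <- matrix(integer(0), ncol = 2)
  if (n >= 2) {
    r <- .COVALENT_RADIUS[geom$elements]
    d <- as.matrix(stats::dist(geom$coords))
    cutoff <- outer(r, r, "+") * tol
    hit <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit)) {
      pairs <- unname(hit[order(hit[, 1], hit[, 2]), , drop = FALSE])
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
      adj <- lapply(adj, sort)
    }
  }
  structure(list(pairs = pairs, adj = adj, n = n), class = "bond_graph")
}

#' Connected components of a bond graph
#' @param bg a `bond_graph`
#' @param drop_edge optional length-2 index vector: an edge to remove first
#' @return integer vector of component ids (1-based, deterministic)
#' @keywords internal
bond_components <- function(bg, drop_edge = NULL) {
  adj <- bg$adj
  if (!is.null(drop_edge)) {
    i <- drop_edge[1]; j <- drop_edge[2]
    adj[[i]] <- setdiff(adj[[i]], j)
    adj[[j]] <- setdiff(adj[[j]], i)
  }
  comp <- integer(bg$n)
  cid <- 0L
  for (s in seq_len(bg$n)) {
    if (comp[s] == 0L) {
      cid <- cid + 1L
      queue <- s
      comp[s] <- cid
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- adj[[v]][comp[adj[[v]]] == 0L]
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

#' Declare a torsion by four atom indices
#'
#' @param atoms integer vector of four 1-based atom indices (a-b-c-d); the
#'   torsion is about the central b-c bond
#' @param label free-text label such as "H-O-C-C" or "glycosidic"
#' @return a `dihedral_spec`
#' @export
dihedral_spec <- function(atoms, label = "") {
  atoms <- as.integer(atoms)
  if (length(atoms) != 4 || anyNA(atoms)) stop("need four atom indices")
  if (anyDuplicated(atoms)) stop("dihedral atom indices must be distinct")
  structure(list(atoms = atoms, label = as.character(label)),
            class = "dihedral_spec")
}

#' Validate a dihedral spec against a geometry
#'
#' Checks index range and that consecutive atom pairs are bonded under the
#' package's bond-perception rule.
#'
#' @param geom a `geometry`
#' @param spec a `dihedral_spec`
#' @param bg optional precomputed `bond_graph`
#' @export
validate_dihedral <- function(geom, spec, bg = bond_graph(geom)) {
  a <- spec$atoms
  if (any(a < 1L | a > n_atoms(geom))) {
    stop("dihedral index out of range for geometry with ",
         n_atoms(geom), " atoms")
  }
  for (k in 1:3) {
    if (!(a[k + 1] %in% bg$adj[[a[k]]])) {
      stop(sprintf("atoms %d and %d of the dihedral are not bonded",
                   a[k], a[k + 1]))
    }
  }
  invisible(TRUE)
}

#' Wrap angles into the IUPAC reporting range (-180, 180]
#' @param theta angle(s) in degrees
#' @return wrapped angle(s)
#' @export
wrap_angle <- function(theta) {
  w <- theta - 360 * floor((theta + 180) / 360)
  w[w <= -180] <- w[w <= -180] + 360
  w
}

#' Measure a signed torsion angle
#'
#' Returns the IUPAC torsion a-b-c-d in degrees in (-180, 180]: looking down
#' the b->c axis, positive when the far bond is rotated clockwise from the
#' near bond.  Invariant under rigid motion of the geometry.
#'
#' @inheritParams validate_dihedral
#' @return angle in degrees
#' @export
measure_dihedral <- function(geom, spec) {
  a <- spec$atoms
  if (any(a < 1L | a > n_atoms(geom))) stop("dihedral index out of range")
  p <- geom$coords[a, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop("degenerate torsion: consecutive bond vectors are collinear")
  }
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Rotate a torsion to a target angle
#'
#' Rotates the substructure on the far (c/d) side of the central b-c bond
#' about that bond so that the measured torsion equals `target`.  Atoms on
#' the anchor (a/b) side are unmoved; all bond lengths and angles are
#' preserved.  Fails when the central bond lies in a ring (removing it does
#' not split the molecule in two).
#'
#' @inheritParams validate_dihedral
#' @param target desired torsion in degrees
#' @return a new `geometry`
#' @export
set_dihedral <- function(geom, spec, target, bg = bond_graph(geom)) {
  validate_dihedral(geom, spec, bg)
  a <- spec$atoms
  comp <- bond_components(bg, drop_edge = a[2:3])
  if (comp[a[2]] == comp[a[3]]) {
    stop("ring torsion: central bond of the dihedral lies inside a ring")
  }
  moving <- which(comp == comp[a[3]])
  current <- measure_dihedral(geom, spec)
  delta <- -(target - current) * pi / 180
  axis <- geom$coords[a[3], ] - geom$coords[a[2], ]
  axis <- axis / sqrt(sum(axis^2))
  origin <- geom$coords[a[2], ]
  R <- rotation_matrix(axis, delta)
  coords <- geom$coords
  shifted <- sweep(coords[moving, , drop = FALSE], 2, origin)
  coords[moving, ] <- sweep(shifted %*% t(R), 2, origin, "+")
  out <- geom
  out$coords <- coords
  out
}

## Rodrigues rotation matrix about unit axis by angle (radians).
rotation_matrix <- function(axis, angle) {
  u <- axis; ct <- cos(angle); st <- sin(angle)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

#' Hill-notation molecular formula
#'
#' Carbon first, hydrogen second, remaining elements alphabetical; if no
#' carbon, all elements alphabetical.  Empty geometry gives "".
#'
#' @param geom a `geometry`
#' @return formula string such as "C5H10O5"
#' @export
molecular_formula <- function(geom) {
  if (!n_atoms(geom)) return("")
  counts <- table(geom$elements)
  format_formula(stats::setNames(as.integer(counts), names(counts)))
}

## Format a named element-count vector in Hill order.
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return("")
  els <- names(counts)
  if ("C" %in% els) {
    ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else {
    ord <- sort(els)
  }
  paste0(vapply(ord, function(e) {
    if (counts[[e]] == 1L) e else paste0(e, counts[[e]])
  }, character(1)), collapse = "")
}

## Parse a Hill formula string into a named integer count vector.
parse_formula <- function(formula) {
  if (!nzchar(formula)) return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  counts <- integer(0)
  for (t in toks) {
    el <- sub("[0-9]*$", "", t)
    nm <- sub("^[A-Za-z]+", "", t)
    k <- if (nzchar(nm)) as.integer(nm) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[el] else 0L) + k
  }
  counts
}

#' Read a geometry from XYZ text
#'
#' Standard dialect: atom-count line, comment line, then one
#' `element x y z` row per atom.
#'
#' @param text a single string or character vector of lines
#' @return a `geometry` (comment line becomes the label)
#' @export
read_xyz <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  if (length(lines) < 2) stop("XYZ parse error at line 1: missing header")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 0) stop("XYZ parse error at line 1: bad atom count")
  if (length(lines) < 2 + n) {
    stop(sprintf("XYZ parse error at line %d: expected %d atom rows",
                 length(lines) + 1L, n))
  }
  els <- character(n); xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- 2L + i
    parts <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (length(parts) < 4) {
      stop(sprintf("XYZ parse error at line %d: need element + 3 coordinates",
                   ln))
    }
    vals <- suppressWarnings(as.numeric(parts[2:4]))
    if (anyNA(vals)) {
      stop(sprintf("XYZ parse error at line %d: non-numeric coordinate", ln))
    }
    els[i] <- parts[1]
    xyz[i, ] <- vals
  }
  extra <- lines[-seq_len(2L + n)]
  if (any(nzchar(trimws(extra)))) {
    stop(sprintf("XYZ parse error at line %d: count line mismatches row count",
                 2L + n + 1L))
  }
  geometry(els, xyz, label = trimws(lines[2]))
}

#' Write a geometry as XYZ text
#'
#' @param geom a `geometry`
#' @param digits decimal places for coordinates (default 6)
#' @return a single string
#' @export
write_xyz <- function(geom, digits = 6) {
  fmt <- sprintf("%%-3s %%%d.%df %%%d.%df %%%d.%df",
                 digits + 6, digits, digits + 6, digits, digits + 6, digits)
  rows <- vapply(seq_len(n_atoms(geom)), function(i) {
    sprintf(fmt, geom$elements[i],
            geom$coords[i, 1], geom$coords[i, 2], geom$coords[i, 3])
  }, character(1))
  paste(c(n_atoms(geom), geom$label, rows, ""), collapse = "\n")
}

#' Place an atom by internal coordinates (distance, angle, torsion)
#'
#' Returns the Cartesian position of a new atom X given reference positions
#' a, b, c with |X-a| = r, angle X-a-b = theta and torsion X-a-b-c = phi.
#'
#' @param a,b,c reference positions (numeric length-3)
#' @param r bond length in Angstrom
#' @param theta angle in degrees
#' @param phi torsion in degrees
#' @return numeric length-3 position
#' @export
place_atom <- function(a, b, c, r, theta, phi) {
  theta <- theta * pi / 180; phi <- phi * pi / 180
  ab <- b - a
  u <- ab / sqrt(sum(ab^2))
  bc <- c - b
  n <- cross3(bc, u)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("degenerate reference frame: a, b, c are collinear")
  n <- n / nn
  m <- cross3(n, u)
  d <- r * (u * cos(theta) - m * sin(theta) * cos(phi) -
              n * sin(theta) * sin(phi))
  a + d
}

#' Read a geometry from Z-matrix text
#'
#' Plain-text Z-matrix: one atom per line, `element [ref1 r [ref2 theta
#' [ref3 phi]]]` with 1-based references, bond lengths in Angstrom and
#' angles/torsions in degrees.  Blank lines and `#` comments are ignored.
#'
#' @param text a single string or character vector of lines
#' @param charge,label passed to [geometry()]
#' @return a `geometry`
#' @export
read_zmatrix <- function(text, charge = 0L, label = "") {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  n <- length(lines)
  if (!n) stop("Z-matrix parse error: no atom lines")
  els <- character(n)
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    p <- strsplit(lines[i], "[[:space:]]+")[[1]]
    els[i] <- p[1]
    need <- min(i - 1L, 3L) * 2L + 1L
    if (length(p) < need) {
      stop(sprintf("Z-matrix parse error at atom %d: too few fields", i))
    }
    if (i == 1L) next
    j <- as.integer(p[2]); r <- as.numeric(p[3])
    if (is.na(j) || j >= i || j < 1 || is.na(r) || r <= 0) {
      stop(sprintf("Z-matrix parse error at atom %d: bad bond reference", i))
    }
    if (i == 2L) {
      xyz[i, ] <- xyz[j, ] + c(r, 0, 0)
      next
    }
    k <- as.integer(p[4]); theta <- as.numeric(p[5])
    if (is.na(k) || k >= i || k == j) {
      stop(sprintf("Z-matrix parse error at atom %d: bad angle reference", i))
    }
    if (i == 3L) {
      ## place in the xy-plane
      ab <- xyz[k, ] - xyz[j, ]
      u <- ab / sqrt(sum(ab^2))
      th <- theta * pi / 180
      perp <- c(-u[2], u[1], 0)
      if (sum(perp^2) < 1e-12) perp <- c(0, 1, 0)
      perp <- perp / sqrt(sum(perp^2))
      xyz[i, ] <- xyz[j, ] + r * (u * cos(th) + perp * sin(th))
      next
    }
    l <- as.integer(p[6]); phi <- as.numeric(p[7])
    if (is.na(l) || l >= i || l %in% c(j, k)) {
      stop(sprintf("Z-matrix parse error at atom %d: bad torsion reference", i))
    }
    xyz[i, ] <- place_atom(xyz[j, ], xyz[k, ], xyz[l, ], r, theta, phi)
  }
  geometry(els, xyz, charge = charge, label = label)
}

#' Apply a rigid motion (rotation + translation) to a geometry
#'
#' @param geom a `geometry`
#' @param axis rotation axis (normalized internally)
#' @param angle rotation angle in degrees
#' @param shift translation vector in Angstrom
#' @return a new `geometry`
#' @export
rigid_transform <- function(geom, axis = c(0, 0, 1), angle = 0,
                            shift = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  R <- rotation_matrix(axis, angle * pi / 180)
  out <- geom
  out$coords <- sweep(geom$coords %*% t(R), 2, shift, "+")
  out
}
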