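## Built-in toy molecules.  These are geometrically sensible stand-ins for
## the sugars, bases and phosphate of the real systems: correct bond
## graphs, hydroxyl patterns and rotatable-dihedral counts, but no claim
## to quantum-level realism.  Formula-level bookkeeping in the reaction
## ledger uses the real molecular formulas independently of these toys.

## Place an atom X bonded to `a` with angle X-a-b = theta, in the plane of
## u and `perp`.
angle_place <- function(a, b, r, theta, perp = c(0, 0, 1)) {
  u <- b - a; u <- u / sqrt(sum(u^2))
  perp <- perp - sum(perp * u) * u
  perp <- perp / sqrt(sum(perp^2))
  th <- theta * pi / 180
  a + r * (u * cos(th) + perp * sin(th))
}

#' Built-in toy molecule catalogue
#'
#' Kinds: `"water"`, `"methanol"`, `"peroxide-chain"` (H2O2, one torsion),
#' `"toy-furanose"` (ribofuranose-like C5H10O5: furanose ring, three ring
#' hydroxyls and an exocyclic CH2-OH arm; five rotatable dihedrals),
#' `"toy-deoxyfuranose"` (2'-deoxy analogue, C5H10O4, four rotatable
#' dihedrals), `"toy-base"` (imidazole-like C3H4N2; its ring N1 is the
#' glycosidic nitrogen of the catalogue), `"toy-phosphate"` (dihydrogen
#' phosphate anion H2PO4-).
#'
#' @param kind catalogue entry name
#' @return a list with `geometry`, `rotatable` (list of `dihedral_spec`,
#'   matching [select_rotatable_dihedrals()] on the geometry) and
#'   `scan_dihedral` (a torsion suitable for scan demos, or NULL)
#' @export
toy_molecule <- function(kind = c("water", "methanol", "peroxide-chain",
                                  "toy-furanose", "toy-deoxyfuranose",
                                  "toy-base", "toy-phosphate")) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown toy molecule kind: ",
                                            kind[1]))
  g <- switch(kind,
    "water" = {
      O <- c(0, 0, 0); H1 <- c(0.9572, 0, 0)
      H2 <- angle_place(O, H1, 0.9572, 104.52)
      geometry(c("O", "H", "H"), rbind(O, H1, H2), label = "water")
    },
    "methanol" = {
      C1 <- c(0, 0, 0); O2 <- c(1.42, 0, 0)
      H3 <- angle_place(O2, C1, 0.96, 108.5)          # hydroxyl H
      H4 <- place_atom(C1, O2, H3, 1.09, 109.5, 60)
      H5 <- place_atom(C1, O2, H3, 1.09, 109.5, 180)
      H6 <- place_atom(C1, O2, H3, 1.09, 109.5, -60)
      geometry(c("C", "O", "H", "H", "H", "H"),
               rbind(C1, O2, H3, H4, H5, H6), label = "methanol")
    },
    "peroxide-chain" = {
      O1 <- c(0, 0, 0); O2 <- c(1.45, 0, 0)
      H1 <- angle_place(O1, O2, 0.96, 100)
      H2 <- place_atom(O2, O1, H1, 0.96, 100, 111.8)
      geometry(c("H", "O", "O", "H"), rbind(H1, O1, O2, H2),
               label = "peroxide-chain")
    },
    "toy-furanose" = toy_furanose(deoxy = FALSE),
    "toy-deoxyfuranose" = toy_furanose(deoxy = TRUE),
    "toy-base" = {
      s <- 1.37; R <- s / (2 * sin(pi / 5))
      ang <- (90 + 72 * (0:4)) * pi / 180
      ring <- cbind(R * cos(ang), R * sin(ang), 0)
      ## N1 C2 N3 C4 C5
      els <- c("N", "C", "N", "C", "C")
      out <- function(i) {
        nb <- ring[c((i - 2) %% 5 + 1, i %% 5 + 1), , drop = FALSE]
        w <- ring[i, ] - colMeans(nb)
        ring[i, ] + 1.02 * w / sqrt(sum(w^2))
      }
      hs <- rbind(out(1), out(2), out(4), out(5))
      geometry(c(els, "H", "H", "H", "H"), rbind(ring, hs),
               label = "toy-base")
    },
    "toy-phosphate" = {
      P <- c(0, 0, 0)
      dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                    c(-1, -1, 1)) / sqrt(3)
      Os <- dirs * 1.54
      H1 <- place_atom(Os[1, ], P, Os[3, ], 0.97, 115, 180)
      H2 <- place_atom(Os[2, ], P, Os[4, ], 0.97, 115, 180)
      geometry(c("P", "O", "O", "O", "O", "H", "H"),
               rbind(P, Os, H1, H2), charge = -1L, label = "toy-phosphate")
    }
  )
  rotatable <- suppressWarnings(select_rotatable_dihedrals(g))
  scan_spec <- switch(kind,
    "peroxide-chain" = dihedral_spec(c(1, 2, 3, 4), label = "H-O-O-H"),
    "toy-furanose" = ,
    "toy-deoxyfuranose" = rotatable[[length(rotatable)]],
    "methanol" = rotatable[[1]],
    NULL
  )
  list(geometry = g, rotatable = rotatable, scan_dihedral = scan_spec)
}

## Furanose-like toy: planar C4O ring, ring hydroxyls, exocyclic CH2-OH.
toy_furanose <- function(deoxy = FALSE) {
  s <- 1.48; R <- s / (2 * sin(pi / 5))
  ang <- (90 + 72 * (0:4)) * pi / 180
  ring <- cbind(R * cos(ang), R * sin(ang), 0)
  ## atoms 1..5: O4' C1' C2' C3' C4'
  up <- c(0, 0, 1)
  subst_dir <- function(i, sign_z) {
    nb <- ring[c((i - 2) %% 5 + 1, i %% 5 + 1), , drop = FALSE]
    w <- ring[i, ] - colMeans(nb)
    w <- w / sqrt(sum(w^2))
    d <- 0.5774 * w + sign_z * 0.8165 * up
    d / sqrt(sum(d^2))
  }
  els <- c("O", "C", "C", "C", "C")
  xyz <- ring
  add <- function(el, pos) {
    els <<- c(els, el); xyz <<- rbind(xyz, pos)
    nrow(xyz)
  }
  ring_nb_C <- c(NA, 3, 4, 3, 4) # a ring carbon neighbour per ring carbon
  hydroxyl <- function(icarbon, sign_z) {
    o <- add("O", ring[icarbon, ] + 1.42 * subst_dir(icarbon, sign_z))
    h <- add("H", place_atom(xyz[o, ], ring[icarbon, ],
                             ring[ring_nb_C[icarbon], ], 0.96, 108, 180))
    add("H", ring[icarbon, ] + 1.09 * subst_dir(icarbon, -sign_z))
    invisible(o)
  }
  hydroxyl(2, +1)                       # C1' anomeric OH
  if (deoxy) {
    add("H", ring[3, ] + 1.09 * subst_dir(3, -1))
    add("H", ring[3, ] + 1.09 * subst_dir(3, +1))
  } else {
    hydroxyl(3, -1)                     # C2' OH
  }
  hydroxyl(4, +1)                       # C3' OH
  ## C4' exocyclic arm: C5'(H2)-O5'-H
  c5 <- add("C", ring[5, ] + 1.52 * subst_dir(5, +1))
  add("H", ring[5, ] + 1.09 * subst_dir(5, -1))
  o5 <- add("O", place_atom(xyz[c5, ], ring[5, ], ring[4, ], 1.42,
                            109.5, 180))
  add("H", place_atom(xyz[o5, ], xyz[c5, ], ring[5, ], 0.96, 108, 180))
  add("H", place_atom(xyz[c5, ], ring[5, ], ring[4, ], 1.09, 109.5, 60))
  add("H", place_atom(xyz[c5, ], ring[5, ], ring[4, ], 1.09, 109.5, -60))
  geometry(els, xyz,
           label = if (deoxy) "toy-deoxyfuranose" else "toy-furanose")
}
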