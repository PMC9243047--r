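## Randomized conformer generation over a declared set of rotatable
## dihedrals, and deduplication of optimized conformers into unique minima.
## The sampling emulates the hydroxyl-torsion randomization used to seed
## sugar conformer searches: each chosen torsion is drawn independently and
## uniformly from [-180, 180).

#' Select rotatable dihedrals by a named rule
#'
#' Rule `"hydroxyl_plus_beta"`: every H-O-C-X torsion whose oxygen is a
#' hydroxyl oxygen (bonded to exactly one H and one C; the fourth atom is
#' the lowest-index carbon neighbour of C, falling back to the lowest-index
#' non-oxygen neighbour), plus — when present — the exocyclic
#' O-C5'-C4'-C3' ("beta") torsion of a furanose bearing an exocyclic
#' CH2-OH arm.  Ordering is deterministic (by atom-index tuple).
#'
#' @param geom a `geometry`
#' @param rule rule name (only `"hydroxyl_plus_beta"`)
#' @return list of `dihedral_spec`; empty (with a warning) when the rule
#'   finds nothing to rotate
#' @export
select_rotatable_dihedrals <- function(geom, rule = "hydroxyl_plus_beta") {
  rule <- match.arg(rule, "hydroxyl_plus_beta")
  bg <- bond_graph(geom)
  specs <- list()
  hydroxyl_oxygens <- integer(0)
  for (o in which(geom$elements == "O")) {
    nb <- bg$adj[[o]]
    if (length(nb) != 2) next
    hs <- nb[geom$elements[nb] == "H"]
    cs <- nb[geom$elements[nb] == "C"]
    if (length(hs) == 1 && length(cs) == 1) {
      hydroxyl_oxygens <- c(hydroxyl_oxygens, o)
      cnb <- setdiff(bg$adj[[cs]], o)
      fourth <- cnb[geom$elements[cnb] == "C"]
      if (!length(fourth)) fourth <- cnb[geom$elements[cnb] != "O"]
      if (!length(fourth)) next
      specs <- c(specs, list(dihedral_spec(c(hs, o, cs, min(fourth)),
                                           label = "H-O-C-C")))
    }
  }
  ## beta torsion: hydroxyl-bearing exocyclic carbon attached to a ring
  ## carbon; torsion O-Cexo-Cring-Cring'
  ring <- ring_atoms(geom, bg)
  for (o in hydroxyl_oxygens) {
    cex <- bg$adj[[o]][geom$elements[bg$adj[[o]]] == "C"]
    if (!length(cex) || cex %in% ring) next
    cring <- bg$adj[[cex]]
    cring <- cring[geom$elements[cring] == "C" & cring %in% ring]
    if (!length(cring)) next
    cr <- min(cring)
    third <- setdiff(bg$adj[[cr]], cex)
    third <- third[geom$elements[third] == "C" & third %in% ring]
    if (!length(third)) next
    specs <- c(specs, list(dihedral_spec(c(o, cex, cr, min(third)),
                                         label = "O-C5'-C4'-C3' (beta)")))
  }
  if (!length(specs)) {
    warning("rule '", rule, "' found no rotatable dihedrals")
    return(list())
  }
  key <- vapply(specs, function(s) {
    sprintf("%05d%05d%05d%05d", s$atoms[1], s$atoms[2], s$atoms[3],
            s$atoms[4])
  }, character(1))
  specs[order(key)]
}

## Atoms belonging to any ring: endpoints of edges whose removal does not
## disconnect them.
ring_atoms <- function(geom, bg = bond_graph(geom)) {
  out <- integer(0)
  for (k in seq_len(nrow(bg$pairs))) {
    e <- bg$pairs[k, ]
    comp <- bond_components(bg, drop_edge = e)
    if (comp[e[1]] == comp[e[2]]) out <- c(out, e)
  }
  sort(unique(out))
}

#' Declare a conformer sampling plan
#'
#' @param dihedrals list of `dihedral_spec` to randomize
#' @param n number of conformers to draw (default 1000, the ensemble size
#'   used for the furanose searches this module emulates)
#' @param seed integer RNG seed; recorded in each conformer's provenance
#' @return a `sampling_plan`
#' @export
sampling_plan <- function(dihedrals, n = 1000, seed = 1L) {
  stopifnot(n >= 1)
  structure(list(dihedrals = dihedrals, n = as.integer(n),
                 seed = as.integer(seed)),
            class = "sampling_plan")
}

#' Generate random conformers of a geometry
#'
#' Each conformer sets every plan dihedral to an independent uniform draw
#' from [-180, 180).  A fixed plan (including seed) reproduces the output
#' exactly; the input geometry is never modified.
#'
#' @param geom base `geometry`
#' @param plan a [sampling_plan()]
#' @return a `conformer_set`: list of conformers, each with `geometry`,
#'   `dihedrals` (degrees), `energy` (NA until evaluated) and `provenance`
#'   (seed, sample index, backend tag)
#' @export
generate_conformers <- function(geom, plan) {
  if (!length(plan$dihedrals) && plan$n > 1) {
    stop("degenerate plan: no dihedrals to vary but n > 1")
  }
  bg <- bond_graph(geom)
  for (s in plan$dihedrals) validate_dihedral(geom, s, bg)
  rng <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(plan$seed)
    matrix(stats::runif(plan$n * length(plan$dihedrals), -180, 180),
           nrow = plan$n)
  })
  conformers <- vector("list", plan$n)
  for (i in seq_len(plan$n)) {
    g <- geom
    if (length(plan$dihedrals)) {
      for (d in seq_along(plan$dihedrals)) {
        g <- set_dihedral(g, plan$dihedrals[[d]], rng[i, d], bg)
      }
    }
    conformers[[i]] <- structure(list(
      geometry = g,
      dihedrals = if (length(plan$dihedrals)) rng[i, ] else numeric(0),
      energy = NA_real_,
      provenance = list(seed = plan$seed, index = i, backend = NA_character_)
    ), class = "conformer")
  }
  structure(conformers, class = "conformer_set",
            dihedral_specs = plan$dihedrals)
}

#' Evaluate or optimize every conformer with a backend
#'
#' @param conformers a `conformer_set`
#' @param backend an `energy_backend`
#' @param optimize if TRUE each conformer is locally optimized and its
#'   dihedral vector re-measured; otherwise a single-point evaluation
#' @return the conformer set with energies (and geometries) updated
#' @export
evaluate_conformers <- function(conformers, backend, optimize = TRUE) {
  specs <- attr(conformers, "dihedral_specs")
  out <- lapply(conformers, function(cf) {
    if (optimize) {
      res <- backend$optimize(cf$geometry)
      cf$geometry <- res$geometry
      cf$energy <- res$energy
      cf$converged <- res$converged
      if (length(specs)) {
        cf$dihedrals <- vapply(specs, function(s) {
          measure_dihedral(cf$geometry, s)
        }, numeric(1))
      }
    } else {
      cf$energy <- backend$evaluate(cf$geometry)
    }
    cf$provenance$backend <- backend$tag
    cf
  })
  structure(out, class = "conformer_set", dihedral_specs = specs)
}

#' Deduplicate optimized conformers into unique minima
#'
#' Two conformers are duplicates when their energies differ by at most
#' `energy_tol` AND every dihedral differs by at most `dihedral_tol` under
#' the periodic (wrapped) distance; clusters are the transitive closure of
#' that relation.  Each cluster is represented by its lowest-energy member
#' (ties: lowest sample index); output is sorted by energy ascending.
#'
#' @param conformers a `conformer_set` with energies
#' @param energy_tol kcal/mol (default 0.1)
#' @param dihedral_tol degrees (default 15)
#' @return a `conformer_set` of unique minima; attribute `n_input` records
#'   the input size
#' @export
deduplicate_minima <- function(conformers, energy_tol = 0.1,
                               dihedral_tol = 15) {
  n <- length(conformers)
  if (!n) return(conformers)
  en <- vapply(conformers, function(cf) cf$energy, numeric(1))
  if (anyNA(en)) stop("conformers must carry energies before deduplication")
  dmat <- do.call(rbind, lapply(conformers, function(cf) cf$dihedrals))
  same <- function(i, j) {
    if (abs(en[i] - en[j]) > energy_tol) return(FALSE)
    if (is.null(dmat) || !ncol(dmat)) return(TRUE)
    all(abs(wrap_angle(dmat[i, ] - dmat[j, ])) <= dihedral_tol)
  }
  ## union-find over the duplicate relation (transitive closure)
  parent <- seq_len(n)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (same(i, j)) {
          ri <- findp(i); rj <- findp(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), findp, integer(1))
  reps <- vapply(split(seq_len(n), root), function(members) {
    idx <- vapply(conformers[members], function(cf) cf$provenance$index,
                  numeric(1))
    members[order(en[members], idx)][1]
  }, integer(1))
  reps <- reps[order(en[reps])]
  structure(unname(conformers[reps]), class = "conformer_set",
            dihedral_specs = attr(conformers, "dihedral_specs"),
            n_input = n)
}

#' Serialize a conformer set to multi-record XYZ plus a CSV sidecar
#'
#' @param conformers a `conformer_set`
#' @param xyz_path,csv_path output file paths
#' @return invisibly, the sidecar data.frame (sample index, seed, dihedral
#'   vector, energy)
#' @export
write_conformers <- function(conformers, xyz_path, csv_path) {
  xyz <- vapply(conformers, function(cf) write_xyz(cf$geometry), character(1))
  writeLines(sub("\n$", "", xyz), xyz_path)
  dmat <- do.call(rbind, lapply(conformers, function(cf) cf$dihedrals))
  df <- data.frame(
    index = vapply(conformers, function(cf) cf$provenance$index, numeric(1)),
    seed = vapply(conformers, function(cf) cf$provenance$seed, numeric(1)),
    energy = vapply(conformers, function(cf) cf$energy, numeric(1))
  )
  if (!is.null(dmat) && ncol(dmat)) {
    colnames(dmat) <- paste0("dihedral_", seq_len(ncol(dmat)))
    df <- cbind(df, as.data.frame(round(dmat, 6)))
  }
  utils::write.csv(df, csv_path, row.names = FALSE)
  invisible(df)
}
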