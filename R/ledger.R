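## Reaction Gibbs-energy ledger: species thermochemistry registry, anomer
## (beta - alpha) differences, the two two-step condensation pathways
##   (a+b)  sugar + base -> nucleoside + H2O;
##          nucleoside + H2PO4- -> nucleotide + H2O
##   (c+d)  sugar + H2PO4- -> sugar-5'-monophosphate + H2O;
##          sugar-5'-MP + base -> nucleotide + H2O
## with stoichiometry/charge checks, the beta-vs-alpha pathway difference
## ddG = (dG_total)_beta - (dG_total)_alpha, sugar-exchange reactions
## between U and T species, and study-space enumeration.
##
## Nucleotide records are keyed by pathway provenance: the two pathways end
## in different local minima, so Hess consistency is only enforced within
## one provenance.

.SPECIES_FORMULA <- list(
  ribose = "C5H10O5", deoxyribose = "C5H10O4",
  A = "C5H5N5", G = "C5H5N5O", C = "C4H5N3O",
  T = "C5H6N2O2", U = "C4H4N2O2",
  phosphate = "H2O4P", water = "H2O"
)

.ROLES <- c("sugar", "base", "phosphate", "water", "nucleoside",
            "sugar5mp", "nucleotide")

## element-count arithmetic on formulas
formula_add <- function(...) {
  counts <- list(...)
  out <- integer(0)
  for (cc in counts) {
    for (el in names(cc)) {
      out[el] <- (if (el %in% names(out)) out[el] else 0L) + cc[el]
    }
  }
  out[out != 0L]
}
formula_negate <- function(cc) -cc

#' Molecular formula and charge of a ledger species
#'
#' Composite species follow condensation stoichiometry: each bond formed
#' releases one water.  The phosphate enters as the dihydrogen phosphate
#' anion, so every phosphate-bearing species carries charge -1.
#'
#' @param role one of sugar, base, phosphate, water, nucleoside, sugar5mp,
#'   nucleotide
#' @param sugar "ribose"/"deoxyribose" where applicable
#' @param base one of A, G, C, T, U where applicable
#' @return list with `formula` (Hill string) and `charge`
#' @export
species_formula <- function(role, sugar = NA, base = NA) {
  pf <- function(name) parse_formula(.SPECIES_FORMULA[[name]])
  w <- pf("water")
  out <- switch(role,
    sugar = list(f = pf(sugar), q = 0L),
    base = list(f = pf(base), q = 0L),
    phosphate = list(f = pf("phosphate"), q = -1L),
    water = list(f = w, q = 0L),
    nucleoside = list(f = formula_add(pf(sugar), pf(base),
                                      formula_negate(w)), q = 0L),
    sugar5mp = list(f = formula_add(pf(sugar), pf("phosphate"),
                                    formula_negate(w)), q = -1L),
    nucleotide = list(f = formula_add(pf(sugar), pf(base), pf("phosphate"),
                                      formula_negate(w), formula_negate(w)),
                      q = -1L),
    stop("unknown species role: ", role)
  )
  list(formula = format_formula(out$f), charge = out$q)
}

#' Build a species thermochemistry registry
#'
#' @param df data.frame with columns `role`, `sugar`, `base`, `anomer`
#'   ("alpha"/"beta"/NA), `phase` ("vacuum"/"aqueous"), `pathway`
#'   ("ab"/"cd"/NA; nucleotides only), `E`, `E_zpe`, `G` (kcal/mol).
#'   `formula` and `charge` are filled from the built-in composition table
#'   when absent.
#' @return a `species_registry` (a data.frame)
#' @export
species_registry <- function(df) {
  required <- c("role", "sugar", "base", "anomer", "phase", "pathway",
                "E", "E_zpe", "G")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("registry missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(df$role %in% .ROLES)) stop("unknown role in registry")
  if (!all(is.finite(df$G))) stop("registry G values must be finite")
  bad <- df$role == "nucleotide" &
    (is.na(df$anomer) | is.na(df$sugar) | is.na(df$base) | is.na(df$pathway))
  if (any(bad)) {
    stop("nucleotide records need anomer, sugar, base and pathway tags")
  }
  if (!"formula" %in% names(df) || !"charge" %in% names(df)) {
    fq <- lapply(seq_len(nrow(df)), function(i) {
      species_formula(df$role[i], df$sugar[i], df$base[i])
    })
    df$formula <- vapply(fq, `[[`, character(1), "formula")
    df$charge <- vapply(fq, `[[`, integer(1), "charge")
  }
  class(df) <- c("species_registry", "data.frame")
  df
}

#' Look up one species record in a registry
#'
#' Fields passed as NA must also be NA in the matching record; exactly one
#' record must match.
#'
#' @param registry a [species_registry()]
#' @param role,sugar,base,anomer,phase,pathway species tags
#' @return the matching one-row registry data.frame
#' @export
lookup_species <- function(registry, role, sugar = NA, base = NA,
                           anomer = NA, phase = "vacuum", pathway = NA) {
  eqna <- function(col, val) {
    if (is.na(val)) is.na(col) else !is.na(col) & col == val
  }
  hit <- registry$role == role & eqna(registry$sugar, sugar) &
    eqna(registry$base, base) & eqna(registry$anomer, anomer) &
    registry$phase == phase & eqna(registry$pathway, pathway)
  if (sum(hit) == 0) {
    stop(sprintf(
      "registry lookup failed: %s sugar=%s base=%s anomer=%s %s pathway=%s",
      role, sugar, base, anomer, phase, pathway))
  }
  if (sum(hit) > 1) stop("ambiguous registry lookup: ", role)
  registry[hit, , drop = FALSE]
}

#' Species selector for reaction steps
#'
#' @param role,sugar,base,anomer,phase,pathway species tags (NA where not
#'   applicable)
#' @return a species selector list
#' @export
sp <- function(role, sugar = NA, base = NA, anomer = NA, phase = "vacuum",
               pathway = NA) {
  list(role = role, sugar = sugar, base = base, anomer = anomer,
       phase = phase, pathway = pathway)
}

#' Beta-minus-alpha difference for one species pair
#'
#' Delta X = X_beta - X_alpha for X in {E, E+ZPE, G}; a negative value
#' means the beta anomer is the more stable.
#'
#' @param beta,alpha single registry rows (matching species up to anomer,
#'   same phase)
#' @param kind which quantity: `"G"`, `"E"` or `"E_zpe"`
#' @return an `anomer_delta`: list with `kind`, `delta`, and the pair tags
#' @export
anomer_delta <- function(beta, alpha, kind = c("G", "E", "E_zpe")) {
  kind <- match.arg(kind)
  beta <- as.list(beta); alpha <- as.list(alpha)
  same <- function(f) identical(is.na(beta[[f]]), is.na(alpha[[f]])) &&
    (is.na(beta[[f]]) || beta[[f]] == alpha[[f]])
  if (!same("role") || !same("sugar") || !same("base") || !same("pathway")) {
    stop("pairing error: records are not the same species up to anomer")
  }
  if (!same("phase")) stop("pairing error: records differ in phase")
  if (!identical(beta$anomer, "beta") || !identical(alpha$anomer, "alpha")) {
    stop("pairing error: expected a beta record and an alpha record")
  }
  structure(list(kind = kind, delta = beta[[kind]] - alpha[[kind]],
                 role = beta$role, sugar = beta$sugar, base = beta$base,
                 phase = beta$phase, pathway = beta$pathway),
            class = "anomer_delta")
}

#' Declare a reaction step
#'
#' @param reactants,products lists of species selectors (see [sp()])
#' @param label step label: "a", "b", "c", "d" or "exchange"
#' @return a `reaction_step`
#' @export
reaction_step <- function(reactants, products, label = "") {
  structure(list(reactants = reactants, products = products, label = label),
            class = "reaction_step")
}

## Check element and charge balance of a step; stop with the offending
## element on imbalance.
check_balance <- function(step) {
  tally <- function(side) {
    f <- integer(0); q <- 0L
    for (s in side) {
      sf <- species_formula(s$role, s$sugar, s$base)
      f <- formula_add(f, parse_formula(sf$formula))
      q <- q + sf$charge
    }
    list(f = f, q = q)
  }
  r <- tally(step$reactants); p <- tally(step$products)
  els <- union(names(r$f), names(p$f))
  for (el in els) {
    nr <- if (el %in% names(r$f)) r$f[[el]] else 0L
    np <- if (el %in% names(p$f)) p$f[[el]] else 0L
    if (nr != np) {
      stop(sprintf(
        "stoichiometry error in step '%s': element %s (%d reactant vs %d product)",
        step$label, el, nr, np))
    }
  }
  if (r$q != p$q) {
    stop(sprintf("stoichiometry error in step '%s': charge %+d vs %+d",
                 step$label, r$q, p$q))
  }
  invisible(TRUE)
}

#' Standard Gibbs energy of one reaction step
#'
#' dG = sum G(products) - sum G(reactants), after element and charge
#' balance are verified.
#'
#' @param step a [reaction_step()]
#' @param registry a [species_registry()]
#' @return dG in kcal/mol
#' @export
step_delta_g <- function(step, registry) {
  check_balance(step)
  gsum <- function(side) {
    sum(vapply(side, function(s) {
      lookup_species(registry, s$role, s$sugar, s$base, s$anomer, s$phase,
                     s$pathway)$G
    }, numeric(1)))
  }
  gsum(step$products) - gsum(step$reactants)
}

#' The two condensation steps of one pathway
#'
#' @param sugar "ribose" or "deoxyribose"
#' @param base one of A, G, C, T, U
#' @param anomer "alpha" or "beta"
#' @param phase "vacuum" or "aqueous"
#' @param pathway "ab" (base first) or "cd" (phosphate first)
#' @return list of two `reaction_step`s
#' @export
condensation_steps <- function(sugar, base, anomer, phase = "vacuum",
                               pathway = c("ab", "cd")) {
  pathway <- match.arg(pathway)
  su <- sp("sugar", sugar, anomer = anomer, phase = phase)
  ba <- sp("base", base = base, phase = phase)
  ph <- sp("phosphate", phase = phase)
  wa <- sp("water", phase = phase)
  nt <- sp("nucleotide", sugar, base, anomer, phase, pathway)
  if (pathway == "ab") {
    ns <- sp("nucleoside", sugar, base, anomer, phase)
    list(reaction_step(list(su, ba), list(ns, wa), "a"),
         reaction_step(list(ns, ph), list(nt, wa), "b"))
  } else {
    smp <- sp("sugar5mp", sugar, anomer = anomer, phase = phase)
    list(reaction_step(list(su, ph), list(smp, wa), "c"),
         reaction_step(list(smp, ba), list(nt, wa), "d"))
  }
}

#' Total Gibbs energy of a two-step pathway
#'
#' Verifies that the first step's non-water product feeds the second
#' step's reactants, then sums the step energies.
#'
#' @param steps list of two `reaction_step`s
#' @param registry a [species_registry()]
#' @return list with `dg_steps` (length 2) and `total`
#' @export
pathway_total <- function(steps, registry) {
  stopifnot(length(steps) == 2)
  inter <- Filter(function(s) s$role != "water", steps[[1]]$products)
  feeds <- vapply(inter, function(s) {
    any(vapply(steps[[2]]$reactants, function(r) {
      identical(r[c("role", "sugar", "base", "anomer", "phase")],
                s[c("role", "sugar", "base", "anomer", "phase")])
    }, logical(1)))
  }, logical(1))
  if (!all(feeds)) {
    stop("pathway-consistency error: step-1 product missing from step-2 reactants")
  }
  dg <- vapply(steps, step_delta_g, numeric(1), registry = registry)
  list(dg_steps = dg, total = sum(dg))
}

#' Pathway difference between the anomers
#'
#' ddG = total(beta) - total(alpha); negative values mean the beta-anomer
#' pathway is the more exergonic.
#'
#' @param beta_total,alpha_total `pathway_total()` results (or numbers)
#' @return ddG in kcal/mol
#' @export
ddg_compare <- function(beta_total, alpha_total) {
  tot <- function(x) if (is.list(x)) x$total else x
  tot(beta_total) - tot(alpha_total)
}

#' Full beta-vs-alpha comparison of one pathway
#'
#' @param registry a [species_registry()]
#' @inheritParams condensation_steps
#' @return a `pathway_comparison`: per-anomer step energies and totals,
#'   plus `ddg`
#' @export
pathway_comparison <- function(registry, sugar, base, phase = "vacuum",
                               pathway = c("ab", "cd")) {
  pathway <- match.arg(pathway)
  res <- lapply(c(alpha = "alpha", beta = "beta"), function(an) {
    pathway_total(condensation_steps(sugar, base, an, phase, pathway),
                  registry)
  })
  structure(list(sugar = sugar, base = base, phase = phase,
                 pathway = pathway,
                 alpha = res$alpha, beta = res$beta,
                 ddg = ddg_compare(res$beta, res$alpha)),
            class = "pathway_comparison")
}

#' @export
print.pathway_comparison <- function(x, ...) {
  cat(sprintf("<pathway_comparison> %s-%s, %s, pathway (%s)\n",
              x$sugar, x$base, x$phase,
              if (x$pathway == "ab") "a+b" else "c+d"))
  cat(sprintf("  alpha: steps %7.2f %7.2f  total %7.2f\n",
              x$alpha$dg_steps[1], x$alpha$dg_steps[2], x$alpha$total))
  cat(sprintf("  beta:  steps %7.2f %7.2f  total %7.2f\n",
              x$beta$dg_steps[1], x$beta$dg_steps[2], x$beta$total))
  cat(sprintf("  ddG(beta-alpha) = %7.2f kcal/mol\n", x$ddg))
  invisible(x)
}

#' Sugar-exchange reaction energy
#'
#' The double sugar swap  rT + dU -> dT + rU  (per anomer):
#' Delta X = [X(dT) + X(rU)] - [X(rT) + X(dU)].  Negative values favour
#' the canonical pairing (thymine on deoxyribose, uracil on ribose).
#'
#' @param registry a [species_registry()]
#' @param anomer "alpha" or "beta"
#' @param kind "G", "E" or "E_zpe"
#' @param role "nucleoside" or "nucleotide"
#' @param phase "vacuum" or "aqueous"
#' @param pathway for nucleotides, "ab" or "cd"
#' @return exchange energy in kcal/mol
#' @export
sugar_exchange_delta <- function(registry, anomer, kind = "G",
                                 role = c("nucleoside", "nucleotide"),
                                 phase = "vacuum", pathway = NA) {
  role <- match.arg(role)
  if (role == "nucleotide" && is.na(pathway)) {
    stop("nucleotide exchange needs a pathway tag")
  }
  pw <- if (role == "nucleotide") pathway else NA
  get <- function(sugar, base) {
    lookup_species(registry, role, sugar, base, anomer, phase, pw)[[kind]]
  }
  (get("deoxyribose", "T") + get("ribose", "U")) -
    (get("ribose", "T") + get("deoxyribose", "U"))
}

#' Enumerate the study space
#'
#' Cross-products of the declared factors: 2 sugars x 5 bases x 2 anomers
#' nucleosides; x 2 phases guess geometries; x 2 classes (nucleoside,
#' nucleotide) final structures; 2 pathways x 2 sugars x 5 bases x 2
#' anomers x 2 phases reactions.
#'
#' @return list with `nucleosides`, `guess_geometries`, `final_structures`,
#'   `reactions` (counts) and `grids` (the underlying expand.grid tables)
#' @export
enumerate_study <- function() {
  sugars <- c("ribose", "deoxyribose")
  bases <- c("A", "G", "C", "T", "U")
  anomers <- c("alpha", "beta")
  phases <- c("vacuum", "aqueous")
  classes <- c("nucleoside", "nucleotide")
  pathways <- c("ab", "cd")
  g_ns <- expand.grid(sugar = sugars, base = bases, anomer = anomers,
                      stringsAsFactors = FALSE)
  g_guess <- expand.grid(sugar = sugars, base = bases, anomer = anomers,
                         phase = phases, stringsAsFactors = FALSE)
  g_final <- expand.grid(sugar = sugars, base = bases, anomer = anomers,
                         phase = phases, class = classes,
                         stringsAsFactors = FALSE)
  g_rx <- expand.grid(pathway = pathways, sugar = sugars, base = bases,
                      anomer = anomers, phase = phases,
                      stringsAsFactors = FALSE)
  list(nucleosides = nrow(g_ns), guess_geometries = nrow(g_guess),
       final_structures = nrow(g_final), reactions = nrow(g_rx),
       grids = list(nucleosides = g_ns, guess_geometries = g_guess,
                    final_structures = g_final, reactions = g_rx))
}

#' Check element/charge balance of every enumerated condensation
#'
#' Builds the step pair for each of the 80 reactions and verifies, from
#' the built-in composition table alone, that every step balances with
#' exactly one water released.
#'
#' @return TRUE invisibly (errors describe the first failure)
#' @export
check_all_reactions_balanced <- function() {
  grid <- enumerate_study()$grids$reactions
  for (i in seq_len(nrow(grid))) {
    steps <- condensation_steps(grid$sugar[i], grid$base[i], grid$anomer[i],
                                grid$phase[i], grid$pathway[i])
    for (st in steps) {
      check_balance(st)
      nw <- sum(vapply(st$products, function(s) s$role == "water",
                       logical(1)))
      if (nw != 1) stop("condensation step must release exactly one water")
    }
  }
  invisible(TRUE)
}

#' Round half away from zero
#'
#' The printing convention of the report tables: one decimal, ties
#' rounded away from zero (so -12.76 prints as -12.8).
#'
#' @param x numeric
#' @param digits decimal places (default 1)
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Emit ledger report tables
#'
#' Writes CSV tables (one-decimal rounding, half away from zero) and a
#' JSON file retaining unrounded values: anomer differences per species
#' class, pathway totals and ddG, and sugar-exchange energies.  Missing
#' registry cells are listed and left blank rather than failing.
#'
#' @param registry a [species_registry()]
#' @param dir output directory (created if needed)
#' @return invisibly, a list of the report data.frames
#' @export
build_report <- function(registry, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sugars <- c("ribose", "deoxyribose")
  bases <- c("A", "G", "C", "T", "U")
  phases <- c("vacuum", "aqueous")
  missing_cells <- character(0)
  try_val <- function(expr) {
    tryCatch(expr, error = function(e) {
      missing_cells <<- c(missing_cells, conditionMessage(e))
      NA_real_
    })
  }
  ## anomer differences per class
  anomer_tabs <- list()
  for (role in c("sugar", "sugar5mp", "nucleoside")) {
    grid <- expand.grid(sugar = sugars,
                        base = if (role == "nucleoside") bases else NA,
                        phase = phases, stringsAsFactors = FALSE)
    for (kind in c("E", "E_zpe", "G")) {
      grid[[paste0("d", kind, "_ba")]] <- vapply(seq_len(nrow(grid)),
        function(i) {
          try_val({
            b <- lookup_species(registry, role, grid$sugar[i], grid$base[i],
                                "beta", grid$phase[i])
            a <- lookup_species(registry, role, grid$sugar[i], grid$base[i],
                                "alpha", grid$phase[i])
            anomer_delta(b, a, kind)$delta
          })
        }, numeric(1))
    }
    anomer_tabs[[role]] <- grid
  }
  ## pathway comparisons
  grid <- enumerate_study()$grids$reactions
  grid <- unique(grid[, c("pathway", "sugar", "base", "phase")])
  pw <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cmp <- try_val({
      x <- pathway_comparison(registry, grid$sugar[i], grid$base[i],
                              grid$phase[i], grid$pathway[i])
      c(x$alpha$dg_steps, x$alpha$total, x$beta$dg_steps, x$beta$total,
        x$ddg)
    })
    if (length(cmp) == 1 && is.na(cmp)) cmp <- rep(NA_real_, 7)
    data.frame(grid[i, , drop = FALSE],
               dg1_alpha = cmp[1], dg2_alpha = cmp[2], total_alpha = cmp[3],
               dg1_beta = cmp[4], dg2_beta = cmp[5], total_beta = cmp[6],
               ddg = cmp[7], row.names = NULL)
  }))
  ## sugar exchange
  ex_grid <- expand.grid(role = c("nucleoside", "nucleotide"),
                         anomer = c("alpha", "beta"), phase = phases,
                         pathway = NA, stringsAsFactors = FALSE)
  ex_grid$pathway[ex_grid$role == "nucleotide"] <- "ab"
  ex_cd <- ex_grid[ex_grid$role == "nucleotide", ]
  ex_cd$pathway <- "cd"
  ex_grid <- rbind(ex_grid, ex_cd)
  for (kind in c("E", "E_zpe", "G")) {
    ex_grid[[paste0("d", kind)]] <- vapply(seq_len(nrow(ex_grid)),
      function(i) {
        try_val(sugar_exchange_delta(registry, ex_grid$anomer[i], kind,
                                     ex_grid$role[i], ex_grid$phase[i],
                                     ex_grid$pathway[i]))
      }, numeric(1))
  }
  reports <- c(anomer_tabs, list(pathways = pw, sugar_exchange = ex_grid))
  for (nm in names(reports)) {
    rounded <- reports[[nm]]
    numcols <- vapply(rounded, is.numeric, logical(1))
    rounded[numcols] <- lapply(rounded[numcols], round_half_away)
    utils::write.csv(rounded, file.path(dir, paste0("table_", nm, ".csv")),
                     row.names = FALSE, na = "")
  }
  jsonlite::write_json(reports, file.path(dir, "report.json"),
                       dataframe = "rows", digits = NA, na = "null",
                       auto_unbox = TRUE)
  if (length(missing_cells)) {
    writeLines(missing_cells, file.path(dir, "missing_cells.txt"))
  }
  invisible(reports)
}
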