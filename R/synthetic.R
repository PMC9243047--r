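## Synthetic data with planted, exactly recoverable ground truth: conformer
## ensembles whose dominant Boltzmann weight is constructed in closed form,
## and species thermochemistry registries with a planted beta-vs-alpha
## offset and per-pathway effects.  Everything is a pure function of its
## spec (seed included).

#' Synthesize a conformer energy ensemble with planted structure
#'
#' Energies are drawn from a named distribution; when `wstar` is set the
#' non-lowest energies are shifted by a common constant so the lowest
#' conformer's Boltzmann weight at temperature `T` equals `wstar` exactly
#' (back-solved in closed form).
#'
#' @param n conformer count (>= 2 when `wstar` is set)
#' @param distribution "exponential-gap" (gaps ~ Exp(rate 1/scale)),
#'   "normal" (N(0, scale)), or "two-level" (0 and `scale` alternating)
#' @param scale distribution scale, kcal/mol
#' @param wstar planted dominant weight in (0, 1), or NULL
#' @param T temperature, kelvin
#' @param seed RNG seed
#' @return numeric energies (kcal/mol); attribute `ground_truth` records
#'   the spec
#' @export
synth_ensemble <- function(n, distribution = c("exponential-gap", "normal",
                                               "two-level"),
                           scale = 1, wstar = NULL, T = 298.15, seed = 1L) {
  distribution <- match.arg(distribution)
  stopifnot(n >= 1, scale >= 0)
  if (!is.null(wstar)) {
    stopifnot(wstar > 0, wstar < 1)
    if (n < 2) stop("construction error: planted weight needs n >= 2")
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  e <- switch(distribution,
    "exponential-gap" = cumsum(c(0, stats::rexp(n - 1, rate = 1 / max(scale, 1e-12)))),
    "normal" = sort(stats::rnorm(n, 0, scale)),
    "two-level" = rep(c(0, scale), length.out = n)
  )
  e <- e - min(e)
  if (!is.null(wstar)) {
    kT <- thermal_energy_kT(T)
    ord <- order(e)
    low <- ord[1]; rest <- ord[-1]
    s_rest <- sum(exp(-e[rest] / kT))
    if (s_rest <= 0) stop("construction error: degenerate tail")
    ## want w(low) = 1 / (1 + s_rest * exp(-c/kT)) = wstar
    shift <- -kT * log((1 - wstar) / (wstar * s_rest))
    e[rest] <- e[rest] + shift
    if (any(e[rest] <= e[low])) {
      stop("construction error: requested weight infeasible for this ensemble")
    }
  }
  structure(e, ground_truth = list(n = n, distribution = distribution,
                                   scale = scale, wstar = wstar, T = T,
                                   seed = seed))
}

#' Spec for a planted species registry
#'
#' @param delta planted beta-minus-alpha offset (kcal/mol), added to every
#'   beta record of anomer-bearing species
#' @param pathway_effects named numeric, extra offset added to beta
#'   nucleotide records per pathway (names "ab", "cd"); these are the
#'   planted ddG values of the two pathways
#' @param canonical_advantage planted sugar-exchange energy: split evenly
#'   (as x/2) over the dT and rU records of both anomers, so every
#'   exchange reaction recovers exactly this value
#' @param noise_sd standard deviation of independent normal noise on G
#'   (default 0: exact recovery)
#' @param seed RNG seed
#' @return a `planted_registry_spec`
#' @export
planted_registry_spec <- function(delta = -2.5,
                                  pathway_effects = c(ab = -8, cd = -3),
                                  canonical_advantage = 0,
                                  noise_sd = 0, seed = 1L) {
  stopifnot(all(c("ab", "cd") %in% names(pathway_effects)))
  structure(list(delta = delta, pathway_effects = pathway_effects,
                 canonical_advantage = canonical_advantage,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "planted_registry_spec")
}

#' Synthesize a full species registry with planted effects
#'
#' Builds an 80-reaction-capable registry (sugars, bases, phosphate,
#' water, nucleosides, sugar 5'-monophosphates, pathway-tagged
#' nucleotides; both phases).  Composite G values are sums of their
#' components minus a fixed condensation release, so that, with zero
#' noise:
#' * every beta-vs-alpha difference equals `delta` (plus the pathway
#'   effect for nucleotides),
#' * every pathway ddG equals `pathway_effects[pathway]`,
#' * every sugar-exchange energy equals `canonical_advantage`.
#' E and E+ZPE columns carry the same planted structure, offset by fixed
#' constants.
#'
#' @param spec a [planted_registry_spec()]
#' @return a [species_registry()]; attribute `ground_truth` carries the
#'   planted values
#' @export
synth_registry <- function(spec = planted_registry_spec()) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  sugars <- c("ribose", "deoxyribose")
  bases <- c("A", "G", "C", "T", "U")
  anomers <- c("alpha", "beta")
  phases <- c("vacuum", "aqueous")
  ## deterministic baseline G per elementary species and phase
  base_g <- function(role, sugar, base, phase) {
    key <- paste(role, sugar, base, sep = ":")
    h <- sum(utf8ToInt(key)) %% 97
    -300 - 5 * h + if (phase == "aqueous") -7.5 else 0
  }
  rows <- list()
  add <- function(role, sugar = NA, base = NA, anomer = NA, phase,
                  pathway = NA, G) {
    rows[[length(rows) + 1L]] <<- data.frame(
      role = role, sugar = sugar, base = base, anomer = anomer,
      phase = phase, pathway = pathway, E = G + 40, E_zpe = G + 25, G = G,
      stringsAsFactors = FALSE)
  }
  release <- -12 # condensation G drop per bond formed, kcal/mol
  for (phase in phases) {
    gw <- base_g("water", NA, NA, phase)
    add("water", phase = phase, G = gw)
    gp <- base_g("phosphate", NA, NA, phase)
    add("phosphate", phase = phase, G = gp)
    gb <- stats::setNames(vapply(bases, function(b) {
      base_g("base", NA, b, phase)
    }, numeric(1)), bases)
    for (b in bases) add("base", base = b, phase = phase, G = gb[[b]])
    for (s in sugars) {
      gs_alpha <- base_g("sugar", s, NA, phase)
      for (an in anomers) {
        d_an <- if (an == "beta") spec$delta else 0
        gs <- gs_alpha + d_an
        add("sugar", s, anomer = an, phase = phase, G = gs)
        add("sugar5mp", s, anomer = an, phase = phase,
            G = gs + gp - gw + release)
        for (b in bases) {
          canon <- if ((s == "deoxyribose" && b == "T") ||
                         (s == "ribose" && b == "U")) {
            spec$canonical_advantage / 2
          } else 0
          gns <- gs + gb[[b]] - gw + release + canon
          add("nucleoside", s, b, an, phase, G = gns)
          for (pw in c("ab", "cd")) {
            d_pw <- if (an == "beta") spec$pathway_effects[[pw]] else 0
            add("nucleotide", s, b, an, phase, pw,
                G = gns + gp - gw + release + d_pw)
          }
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  if (spec$noise_sd > 0) {
    df$G <- df$G + stats::rnorm(nrow(df), 0, spec$noise_sd)
    df$E <- df$E + stats::rnorm(nrow(df), 0, spec$noise_sd)
    df$E_zpe <- df$E_zpe + stats::rnorm(nrow(df), 0, spec$noise_sd)
  }
  reg <- species_registry(df)
  attr(reg, "ground_truth") <- list(
    delta = spec$delta, pathway_effects = spec$pathway_effects,
    canonical_advantage = spec$canonical_advantage,
    noise_sd = spec$noise_sd, seed = spec$seed)
  reg
}

#' Write a registry (and its ground truth) to CSV/JSON
#'
#' @param registry a [species_registry()]
#' @param csv_path output CSV path
#' @param truth_path optional JSON sidecar for the planted ground truth
#' @return invisibly, the registry
#' @export
write_registry <- function(registry, csv_path, truth_path = NULL) {
  utils::write.csv(as.data.frame(registry), csv_path, row.names = FALSE,
                   na = "")
  gt <- attr(registry, "ground_truth")
  if (!is.null(truth_path) && !is.null(gt)) {
    jsonlite::write_json(gt, truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(registry)
}

#' Read a registry CSV written by [write_registry()]
#'
#' @param csv_path path to the CSV
#' @return a [species_registry()]
#' @export
read_registry <- function(csv_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  species_registry(df)
}
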