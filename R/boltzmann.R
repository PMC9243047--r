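## Boltzmann populations over a conformer ensemble and the cumulative
## partition-function selection rule: keep the minimal set of conformers
## that together contribute at least a threshold fraction (default 50%)
## of Z.

#' Boltzmann weights of an ensemble
#'
#' w_i = exp(-(E_i - E_min)/kBT) / sum, stabilized by the minimum shift.
#'
#' @param energies conformer energies, kcal/mol
#' @param T temperature, kelvin
#' @return weights summing to 1
#' @export
boltzmann_weights <- function(energies, T = 298.15) {
  if (!length(energies)) stop("empty ensemble: no energies")
  energies <- as.vector(energies, mode = "numeric")
  stopifnot(T > 0, all(is.finite(energies)))
  u <- exp(-(energies - min(energies)) / thermal_energy_kT(T))
  u / sum(u)
}

#' Minimal cumulative-weight conformer selection
#'
#' Sorts conformers by weight descending (ties broken by original index
#' ascending) and keeps the shortest prefix whose cumulative weight reaches
#' the threshold — the rule used to decide which conformers of an ensemble
#' go forward to refinement.
#'
#' @param weights Boltzmann weights (nonnegative, summing to 1)
#' @param threshold required cumulative fraction of Z, in (0, 1]
#' @return an `ensemble_selection`: list with `n`, `n_selected`, `selected`
#'   (original indices, in selection order), `fraction` (cumulative weight
#'   of the selection) and `weights`
#' @export
select_cumulative <- function(weights, threshold = 0.5) {
  stopifnot(length(weights) >= 1, all(weights >= 0),
            threshold > 0, threshold <= 1)
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("weights must sum to 1")
  }
  ord <- order(-weights, seq_along(weights))
  csum <- cumsum(weights[ord])
  k <- which(csum >= threshold - 1e-12)[1]
  if (is.na(k)) k <- length(weights)
  structure(list(n = length(weights), n_selected = k,
                 selected = ord[seq_len(k)], fraction = csum[k],
                 threshold = threshold, weights = weights),
            class = "ensemble_selection")
}

#' @export
print.ensemble_selection <- function(x, ...) {
  cat(sprintf(
    "<ensemble_selection> n = %d, n' = %d, contributing %.1f%% of Z\n",
    x$n, x$n_selected, 100 * x$fraction))
  invisible(x)
}

#' Boltzmann-select conformers of an ensemble by energy
#'
#' Convenience wrapper: weights from energies, then cumulative selection.
#'
#' @param energies conformer energies, kcal/mol
#' @param threshold cumulative fraction of Z (default 0.5)
#' @param T temperature, kelvin
#' @return an `ensemble_selection`
#' @export
boltzmann_select <- function(energies, threshold = 0.5, T = 298.15) {
  select_cumulative(boltzmann_weights(energies, T), threshold)
}
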