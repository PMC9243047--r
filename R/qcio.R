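## Reading and writing quantum-chemistry program text: input decks
## (semiempirical .mop, DFT .gjf) and the energy/frequency markers of their
## output logs.  Only the markers handled here are contractual; everything
## else in a real log is ignored.

#' A per-structure energy record
#'
#' Holds the electronic (or heat-of-formation) energy, harmonic
#' frequencies, and derived thermochemistry for one structure.
#'
#' @param energy electronic energy / heat of formation, kcal/mol
#' @param frequencies harmonic wavenumbers, cm^-1 (negative = imaginary)
#' @param zpe zero-point vibrational energy, kcal/mol (NA if unknown)
#' @param e_zpe ZPE-corrected energy, kcal/mol
#' @param gibbs standard Gibbs energy, kcal/mol
#' @param backend backend tag ("surrogate", "mopac_out", "gaussian_log", ...)
#' @param phase phase tag, "vacuum" or "aqueous"
#' @return an `energy_record`; `$is_minimum` is FALSE when any frequency is
#'   imaginary
#' @export
energy_record <- function(energy, frequencies = numeric(0), zpe = NA_real_,
                          e_zpe = NA_real_, gibbs = NA_real_,
                          backend = "", phase = "vacuum") {
  stopifnot(is.finite(energy))
  n_imag <- sum(frequencies < 0)
  if (is.na(zpe) && length(frequencies) && n_imag == 0) {
    zpe <- zpe_from_frequencies(frequencies)
  }
  if (is.na(e_zpe) && !is.na(zpe)) e_zpe <- energy + zpe
  structure(list(energy = energy, frequencies = frequencies, zpe = zpe,
                 e_zpe = e_zpe, gibbs = gibbs, backend = backend,
                 phase = phase, n_imaginary = n_imag,
                 is_minimum = n_imag == 0),
            class = "energy_record")
}

#' @export
print.energy_record <- function(x, ...) {
  cat(sprintf(
    "<energy_record> E = %.5f kcal/mol, %d modes (%d imaginary), %s/%s\n",
    x$energy, length(x$frequencies), x$n_imaginary, x$backend, x$phase))
  invisible(x)
}

#' Parse a quantum-chemistry output log into an energy record
#'
#' Supported dialects: `"mopac_out"` (final heat of formation in kcal/mol,
#' `FREQ.` vibration lines) and `"gaussian_log"` (`SCF Done` electronic
#' energy and free-energy sums in hartree, converted at 627.5095
#' kcal/mol per hartree; `Frequencies --` lines).  A record containing any
#' imaginary (negative) frequency is flagged `is_minimum = FALSE`.
#'
#' @param text log text (single string or lines)
#' @param dialect `"mopac_out"` or `"gaussian_log"`
#' @param phase phase tag to attach
#' @return an `energy_record`
#' @export
parse_qc_output <- function(text, dialect = c("mopac_out", "gaussian_log"),
                            phase = "vacuum") {
  dialect <- match.arg(dialect)
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  num <- "[-+]?[0-9]*\\.?[0-9]+(?:[eEdD][-+]?[0-9]+)?"
  grab <- function(pattern, lns) {
    hits <- regmatches(lns, gregexpr(pattern, lns))
    as.numeric(gsub("[dD]", "e", unlist(hits)))
  }
  after_eq <- function(x) sub(".*=", "", x)
  if (dialect == "mopac_out") {
    el <- grep("FINAL HEAT OF FORMATION", lines, value = TRUE)
    if (!length(el)) stop("parse error: no FINAL HEAT OF FORMATION marker")
    e <- grab(num, after_eq(el[length(el)]))[1]
    fl <- grep("^\\s*FREQ\\.", lines, value = TRUE)
    freqs <- if (length(fl)) grab(num, sub("FREQ\\.", "", fl)) else numeric(0)
    energy_record(e, freqs, backend = "mopac_out", phase = phase)
  } else {
    gl <- grep("Sum of electronic and thermal Free Energies", lines,
               value = TRUE)
    sl <- grep("SCF Done", lines, value = TRUE)
    zl <- grep("Sum of electronic and zero-point Energies", lines,
               value = TRUE)
    if (!length(gl) && !length(sl)) {
      stop("parse error: no SCF Done or free-energy marker")
    }
    f <- PHYS_CONST$hartree_kcal
    e <- if (length(sl)) grab(num, after_eq(sl[length(sl)]))[1] * f
         else NA_real_
    g <- if (length(gl)) grab(num, after_eq(gl[length(gl)]))[1] * f
         else NA_real_
    ez <- if (length(zl)) grab(num, after_eq(zl[length(zl)]))[1] * f
          else NA_real_
    fl <- grep("Frequencies --", lines, value = TRUE)
    freqs <- if (length(fl)) grab(num, sub(".*Frequencies --", "", fl))
             else numeric(0)
    if (is.na(e)) e <- g
    energy_record(e, freqs, e_zpe = ez, gibbs = g,
                  backend = "gaussian_log", phase = phase)
  }
}

#' Write a quantum-chemistry input deck
#'
#' @param geom a non-empty `geometry`
#' @param dialect `"mop"` (semiempirical) or `"gjf"` (DFT)
#' @param keywords route keywords (character)
#' @return deck text; the embedded geometry parses back at the printed
#'   precision (6 decimals)
#' @export
write_qc_input <- function(geom, dialect = c("mop", "gjf"),
                           keywords = character(0)) {
  dialect <- match.arg(dialect)
  if (!n_atoms(geom)) stop("refusing to write a deck for an empty geometry")
  rows <- vapply(seq_len(n_atoms(geom)), function(i) {
    if (dialect == "mop") {
      sprintf("%-3s %12.6f 1 %12.6f 1 %12.6f 1", geom$elements[i],
              geom$coords[i, 1], geom$coords[i, 2], geom$coords[i, 3])
    } else {
      sprintf("%-3s %12.6f %12.6f %12.6f", geom$elements[i],
              geom$coords[i, 1], geom$coords[i, 2], geom$coords[i, 3])
    }
  }, character(1))
  if (dialect == "mop") {
    kw <- paste(c(keywords, sprintf("CHARGE=%d", geom$charge)), collapse = " ")
    paste(c(kw, geom$label, "", rows, ""), collapse = "\n")
  } else {
    route <- paste0("# ", paste(keywords, collapse = " "))
    paste(c(route, "", geom$label, "",
            sprintf("%d 1", geom$charge), rows, ""), collapse = "\n")
  }
}

#' Extract the geometry embedded in an input deck
#'
#' Inverse of [write_qc_input()] for round-trip checks.
#'
#' @param text deck text
#' @param dialect `"mop"` or `"gjf"`
#' @return a `geometry`
#' @export
read_qc_input <- function(text, dialect = c("mop", "gjf")) {
  dialect <- match.arg(dialect)
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  atom_re <- "^\\s*([A-Z][a-z]?)((\\s+[-+0-9.eE]+(\\s+1)?){3})\\s*$"
  rows <- grep(atom_re, lines, value = TRUE)
  if (!length(rows)) stop("parse error: no atom rows in deck")
  charge <- 0L
  if (dialect == "mop") {
    ch <- regmatches(lines[1], regexpr("CHARGE=(-?[0-9]+)", lines[1]))
    if (length(ch)) charge <- as.integer(sub("CHARGE=", "", ch))
  } else {
    cl <- grep("^\\s*-?[0-9]+\\s+[0-9]+\\s*$", lines, value = TRUE)
    if (length(cl)) {
      charge <- as.integer(strsplit(trimws(cl[1]), "\\s+")[[1]][1])
    }
  }
  els <- character(length(rows)); xyz <- matrix(0, length(rows), 3)
  for (i in seq_along(rows)) {
    p <- strsplit(trimws(rows[i]), "\\s+")[[1]]
    els[i] <- p[1]
    ## mop rows interleave "1" optimization flags; coordinates sit at
    ## fixed positions in both dialects
    if (dialect == "mop") {
      xyz[i, ] <- as.numeric(p[c(2, 4, 6)])
    } else {
      xyz[i, ] <- as.numeric(p[2:4])
    }
  }
  geometry(els, xyz, charge = charge)
}

#' Synthesize a quantum-chemistry output fixture
#'
#' Emits log text carrying the contractual markers so that
#' [parse_qc_output()] reproduces the record's energy and frequencies.
#' Values are printed at the dialect's native precision (mopac: kcal/mol,
#' 5 decimals; gaussian: hartree, 9 decimals).
#'
#' @param record an `energy_record`
#' @param dialect `"mopac_out"` or `"gaussian_log"`
#' @return log text
#' @export
make_fixture_qc_output <- function(record,
                                   dialect = c("mopac_out", "gaussian_log")) {
  dialect <- match.arg(dialect)
  if (dialect == "mopac_out") {
    out <- c(
      " *  SYNTHETIC FIXTURE LOG (surrogate data, not a real calculation)",
      sprintf("          FINAL HEAT OF FORMATION = %15.5f KCAL/MOL",
              record$energy))
    if (length(record$frequencies)) {
      out <- c(out, " NORMAL COORDINATE ANALYSIS",
               sprintf("   FREQ. %14.4f", record$frequencies))
    }
  } else {
    f <- PHYS_CONST$hartree_kcal
    out <- " Synthetic fixture log (surrogate data, not a real calculation)"
    out <- c(out, sprintf(
      " SCF Done:  E(RB3LYP) = %18.9f     A.U. after    1 cycles",
      record$energy / f))
    if (length(record$frequencies)) {
      fr <- record$frequencies
      for (i in seq(1, length(fr), by = 3)) {
        chunk <- fr[i:min(i + 2, length(fr))]
        out <- c(out, paste0(" Frequencies --",
                             paste(sprintf("%12.4f", chunk), collapse = "")))
      }
    }
    if (!is.na(record$e_zpe)) {
      out <- c(out, sprintf(
        " Sum of electronic and zero-point Energies= %18.9f",
        record$e_zpe / f))
    }
    if (!is.na(record$gibbs)) {
      out <- c(out, sprintf(
        " Sum of electronic and thermal Free Energies= %18.9f",
        record$gibbs / f))
    }
  }
  paste(c(out, ""), collapse = "\n")
}
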