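## End-to-end orchestration mirroring the workflow order of the study:
## sample conformers -> optimize -> deduplicate -> Boltzmann-select ->
## relaxed torsion scan -> refine -> assemble the species ledger ->
## report.  3D condensation products are not assembled geometrically;
## species thermochemistry enters the ledger as a registry (here the
## planted synthetic registry, or one read from file).

#' Pipeline configuration
#'
#' Defaults reproduce the study protocol constants: 1000 random conformers
#' per molecule, 50% partition-function selection at 298.15 K, and
#' 6 x 60-degree relaxed scans (glycosidic bond 1.52 Angstrom, initial
#' torsions -161.9 / 30.9 degrees, available via [scan_constants()]).
#'
#' @param molecules toy-catalogue kinds to process
#' @param n_conformers conformers per molecule
#' @param threshold cumulative partition-function selection threshold
#' @param temperature selection temperature, kelvin
#' @param scan_step,scan_steps relaxed-scan grid
#' @param pathway "ab", "cd" or "both": which condensation pathways the
#'   ledger reports
#' @param phase backend phase tag
#' @param backend "surrogate" or "fixtures"
#' @param registry_spec a [planted_registry_spec()] for the ledger stage
#' @param seed master seed; per-molecule sampling seeds derive from it
#' @return a validated `pipeline_config`
#' @export
pipeline_config <- function(molecules = c("toy-furanose",
                                          "toy-deoxyfuranose"),
                            n_conformers = 1000,
                            threshold = 0.5,
                            temperature = 298.15,
                            scan_step = 60,
                            scan_steps = 6L,
                            pathway = c("both", "ab", "cd"),
                            phase = c("vacuum", "aqueous"),
                            backend = c("surrogate", "fixtures"),
                            registry_spec = planted_registry_spec(),
                            seed = 1L) {
  pathway <- match.arg(pathway)
  phase <- match.arg(phase)
  backend <- match.arg(backend)
  stopifnot(n_conformers >= 1, threshold > 0, threshold <= 1,
            temperature > 0, scan_steps >= 1, scan_step != 0)
  structure(list(molecules = molecules, n_conformers = n_conformers,
                 threshold = threshold, temperature = temperature,
                 scan_step = scan_step, scan_steps = as.integer(scan_steps),
                 pathway = pathway, phase = phase, backend = backend,
                 registry_spec = registry_spec, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stages per molecule: random conformer generation over the rule-selected
#' rotatable dihedrals, local optimization of every conformer on the
#' surrogate potential, deduplication into unique minima, cumulative
#' Boltzmann selection, a relaxed scan around the molecule's scan torsion
#' from the selected minimum, and refinement with frequency vetting.
#' Ledger stage: synthetic registry, pathway comparisons for the requested
#' pathways, sugar-exchange energies, report tables.  Two runs with the
#' same config produce byte-identical artifacts.
#'
#' @param config a [pipeline_config()]
#' @param outdir output directory
#' @return invisibly, a manifest list (also written as manifest.json)
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config)[setdiff(names(config),
                                                    "registry_spec")],
                   registry_spec = unclass(config$registry_spec),
                   stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- res
    res
  }
  for (mi in seq_along(config$molecules)) {
    kind <- config$molecules[mi]
    tm <- toy_molecule(kind)
    slug <- gsub("[^a-z0-9]+", "_", kind)
    params <- default_surrogate_params(tm$geometry, rotatable = tm$rotatable)
    be <- surrogate_backend(params, phase = config$phase)

    plan <- sampling_plan(tm$rotatable, n = config$n_conformers,
                          seed = config$seed + mi)
    confs <- stage(paste0("sample_", slug), {
      cs <- generate_conformers(tm$geometry, plan)
      list(n = length(cs), seed = plan$seed, conformers = cs)
    })$conformers

    opt <- stage(paste0("optimize_", slug), {
      cs <- evaluate_conformers(confs, be, optimize = TRUE)
      list(n = length(cs),
           n_converged = sum(vapply(cs, function(x) isTRUE(x$converged),
                                    logical(1))),
           conformers = cs)
    })$conformers

    uniq <- stage(paste0("dedup_", slug), {
      u <- deduplicate_minima(opt)
      write_conformers(u, file.path(outdir, paste0(slug, "_minima.xyz")),
                       file.path(outdir, paste0(slug, "_minima.csv")))
      list(n_input = attr(u, "n_input"), n_unique = length(u),
           conformers = u)
    })$conformers

    sel <- stage(paste0("select_", slug), {
      en <- vapply(uniq, function(x) x$energy, numeric(1))
      s <- boltzmann_select(en, config$threshold, config$temperature)
      df <- data.frame(n = s$n, n_selected = s$n_selected,
                       percent_Z = round(100 * s$fraction, 1))
      utils::write.csv(df, file.path(outdir, paste0(slug, "_selection.csv")),
                       row.names = FALSE)
      list(n = s$n, n_selected = s$n_selected,
           fraction = s$fraction, best = s$selected[1])
    })

    if (!is.null(tm$scan_dihedral)) {
      stage(paste0("scan_", slug), {
        gbest <- uniq[[sel$best]]$geometry
        prot <- scan_protocol(tm$scan_dihedral, start = NULL,
                              step = config$scan_step,
                              n_steps = config$scan_steps)
        sc <- soft_scan(gbest, prot, be)
        write_scan(sc, file.path(outdir, paste0(slug, "_scan.csv")),
                   file.path(outdir, paste0(slug, "_scan.xyz")))
        ref <- refine_minimum(sc, be)
        writeLines(write_xyz(ref$geometry),
                   file.path(outdir, paste0(slug, "_refined.xyz")))
        list(angles = sc$angles, energies = sc$energies,
             argmin = sc$argmin, refined_energy = ref$energy,
             refined_is_minimum = ref$is_minimum)
      })
    }
  }

  ## ledger stage
  registry <- stage("registry", {
    reg <- synth_registry(config$registry_spec)
    write_registry(reg, file.path(outdir, "registry.csv"),
                   file.path(outdir, "registry_truth.json"))
    list(n_species = nrow(reg), registry = reg)
  })$registry

  stage("ledger", {
    pws <- switch(config$pathway, both = c("ab", "cd"), config$pathway)
    grid <- enumerate_study()$grids$reactions
    grid <- unique(grid[grid$pathway %in% pws,
                        c("pathway", "sugar", "base", "phase")])
    comps <- lapply(seq_len(nrow(grid)), function(i) {
      pathway_comparison(registry, grid$sugar[i], grid$base[i],
                         grid$phase[i], grid$pathway[i])
    })
    build_report(registry, file.path(outdir, "report"))
    list(n_comparisons = length(comps),
         enumeration = enumerate_study()[c("nucleosides",
                                           "guess_geometries",
                                           "final_structures",
                                           "reactions")])
  })

  ## strip bulky objects from the stored manifest, keep counts/config
  slim <- rapply(manifest, function(x) x, how = "replace")
  for (nm in names(slim$stages)) {
    slim$stages[[nm]]$conformers <- NULL
    slim$stages[[nm]]$registry <- NULL
  }
  jsonlite::write_json(slim, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(slim)
}
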