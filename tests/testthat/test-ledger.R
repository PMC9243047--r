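make_pair <- function(role = "nucleoside", G_beta = -100, G_alpha = -99,
                      phase = "vacuum", pathway = NA) {
  df <- data.frame(
    role = role, sugar = "ribose", base = "A",
    anomer = c("beta", "alpha"), phase = phase, pathway = pathway,
    E = c(G_beta, G_alpha), E_zpe = c(G_beta, G_alpha),
    G = c(G_beta, G_alpha), stringsAsFactors = FALSE)
  species_registry(df)
}

test_that("anomer differences subtract beta minus alpha with checks", {
  reg <- make_pair(G_beta = -100, G_alpha = -99)
  d <- anomer_delta(reg[1, ], reg[2, ], "G")
  expect_equal(d$delta, -1)
  ## swapping the roles is rejected; the quantity itself is antisymmetric
  expect_error(anomer_delta(reg[2, ], reg[1, ]), "pairing")
  reg2 <- make_pair(G_beta = -99, G_alpha = -100)
  expect_equal(anomer_delta(reg2[1, ], reg2[2, ], "G")$delta, 1)
  ## phase mismatch
  rega <- make_pair(phase = "aqueous")
  expect_error(anomer_delta(reg[1, ], rega[2, ]), "phase")
})

test_that("species formulas follow condensation stoichiometry", {
  expect_identical(species_formula("nucleoside", "ribose", "A")$formula,
                   "C10H13N5O4")   # adenosine
  expect_identical(species_formula("sugar5mp", "ribose")$formula,
                   "C5H10O8P")     # ribose 5-phosphate monoanion
  expect_identical(species_formula("nucleotide", "ribose", "A")$formula,
                   "C10H13N5O7P")  # AMP as the -1 anion
  expect_identical(species_formula("nucleotide", "ribose", "A")$charge, -1L)
})

test_that("step energies sum products minus reactants after balancing", {
  ## synthetic condensation: hand-assigned G values -10, -5 -> -12, -4
  df <- data.frame(
    role = c("sugar", "base", "nucleoside", "water"),
    sugar = c("ribose", NA, "ribose", NA),
    base = c(NA, "A", "A", NA),
    anomer = c("beta", NA, "beta", NA),
    phase = "vacuum", pathway = NA,
    E = 0, E_zpe = 0, G = c(-10, -5, -12, -4), stringsAsFactors = FALSE)
  reg <- species_registry(df)
  st <- reaction_step(
    list(sp("sugar", "ribose", anomer = "beta"), sp("base", base = "A")),
    list(sp("nucleoside", "ribose", "A", "beta"), sp("water")), "a")
  expect_equal(step_delta_g(st, reg), -1)
  ## identity reaction
  ident <- reaction_step(list(sp("water")), list(sp("water")), "x")
  expect_equal(step_delta_g(ident, reg), 0)
  ## omitting the released water breaks the element balance
  bad <- reaction_step(
    list(sp("sugar", "ribose", anomer = "beta"), sp("base", base = "A")),
    list(sp("nucleoside", "ribose", "A", "beta")), "a")
  expect_error(step_delta_g(bad, reg), "stoichiometry")
})

test_that("pathway totals reproduce the reference vacuum rows", {
  steps <- reference_pathway_steps()
  ## classic path, vacuum: printed steps sum to the printed totals
  for (case in list(c("dAMP", "beta"), c("dAMP", "alpha"),
                    c("TMP", "beta"), c("TMP", "alpha"),
                    c("AMP", "beta"), c("UMP", "alpha"))) {
    cmp <- reference_pathway_comparison(case[1], "ab", "vacuum", steps)
    expect_equal(cmp$total[[case[2]]], cmp$total_printed[[case[2]]],
                 tolerance = 1e-9)
  }
  ## and the beta-alpha differences match the printed ddG cells
  for (nt in c("dAMP", "TMP")) {
    cmp <- reference_pathway_comparison(nt, "ab", "vacuum", steps)
    expect_equal(round_half_away(cmp$ddg), cmp$ddg_printed)
  }
  ## two zero steps total zero
  expect_equal(ddg_compare(0, 0), 0)
})

test_that("pathway consistency requires the intermediate to carry over", {
  reg <- synth_registry(planted_registry_spec())
  steps <- condensation_steps("ribose", "A", "beta", "vacuum", "ab")
  ## swap step 2 with one whose reactant nucleoside differs
  other <- condensation_steps("ribose", "G", "beta", "vacuum", "ab")
  expect_error(pathway_total(list(steps[[1]], other[[2]]), reg),
               "consistency")
  tot <- pathway_total(steps, reg)
  expect_equal(tot$total, sum(tot$dg_steps), tolerance = 1e-12)
})

test_that("planted registry effects are recovered exactly", {
  spec <- planted_registry_spec(delta = -2.5,
                                pathway_effects = c(ab = -8.25, cd = 3.5),
                                canonical_advantage = -10)
  reg <- synth_registry(spec)
  ## every anomer-bearing non-nucleotide pair differs by exactly delta
  for (role in c("sugar", "sugar5mp", "nucleoside")) {
    for (phase in c("vacuum", "aqueous")) {
      b <- lookup_species(reg, role, "deoxyribose",
                          if (role == "nucleoside") "C" else NA,
                          "beta", phase)
      a <- lookup_species(reg, role, "deoxyribose",
                          if (role == "nucleoside") "C" else NA,
                          "alpha", phase)
      for (kind in c("E", "E_zpe", "G")) {
        expect_equal(anomer_delta(b, a, kind)$delta, -2.5,
                     tolerance = 1e-9)
      }
    }
  }
  ## nucleotide pairs carry delta plus the pathway effect
  b <- lookup_species(reg, "nucleotide", "ribose", "U", "beta", "vacuum",
                      "cd")
  a <- lookup_species(reg, "nucleotide", "ribose", "U", "alpha", "vacuum",
                      "cd")
  expect_equal(anomer_delta(b, a, "G")$delta, -2.5 + 3.5, tolerance = 1e-9)
  ## ddG recovers the planted pathway effects for every cell
  grid <- enumerate_study()$grids$reactions
  grid <- unique(grid[, c("pathway", "sugar", "base", "phase")])
  for (i in seq_len(nrow(grid))) {
    cmp <- pathway_comparison(reg, grid$sugar[i], grid$base[i],
                              grid$phase[i], grid$pathway[i])
    expect_equal(cmp$ddg, spec$pathway_effects[[grid$pathway[i]]],
                 tolerance = 1e-9)
  }
  ## sugar exchange recovers the planted canonical advantage, and
  ## relabelling canonical <-> minor negates it
  for (an in c("alpha", "beta")) {
    ex <- sugar_exchange_delta(reg, an, "G", "nucleoside")
    expect_equal(ex, -10, tolerance = 1e-9)
    swapped <- -((-10)) # X(minor) - X(canonical)
    expect_equal(-ex, swapped, tolerance = 1e-9)
    for (pw in c("ab", "cd")) {
      expect_equal(sugar_exchange_delta(reg, an, "G", "nucleotide",
                                        pathway = pw), -10,
                   tolerance = 1e-9)
    }
  }
  ## all four species equal means zero exchange
  spec0 <- planted_registry_spec(delta = 0, pathway_effects = c(ab = 0,
                                                                cd = 0),
                                 canonical_advantage = 0)
  reg0 <- synth_registry(spec0)
  expect_equal(sugar_exchange_delta(reg0, "beta", "G", "nucleotide",
                                    pathway = "ab"), 0, tolerance = 1e-9)
})

test_that("the study space enumerates 20/40/80/80", {
  en <- enumerate_study()
  expect_equal(en$nucleosides, 20)
  expect_equal(en$guess_geometries, 40)
  expect_equal(en$final_structures, 80)
  expect_equal(en$reactions, 80)
})

test_that("all 80 condensation reactions balance mass and charge", {
  expect_true(check_all_reactions_balanced())
})

test_that("report tables round half away from zero and flag gaps", {
  expect_equal(round_half_away(-12.76), -12.8)
  expect_equal(round_half_away(-12.75), -12.8)
  expect_equal(round_half_away(2.35), 2.4)
  dir <- withr::local_tempdir()
  reg <- synth_registry(planted_registry_spec())
  rep <- build_report(reg, dir)
  expect_true(file.exists(file.path(dir, "table_pathways.csv")))
  pw <- utils::read.csv(file.path(dir, "table_pathways.csv"))
  ## every cell is the recomputed value rounded to one decimal
  i <- which(pw$pathway == "ab" & pw$sugar == "ribose" & pw$base == "U" &
               pw$phase == "vacuum")
  cmp <- pathway_comparison(reg, "ribose", "U", "vacuum", "ab")
  expect_equal(pw$ddg[i], round_half_away(cmp$ddg))
  expect_equal(pw$total_beta[i], round_half_away(cmp$beta$total))
  ## an empty-but-valid registry yields header-only tables
  empty <- species_registry(data.frame(
    role = character(0), sugar = character(0), base = character(0),
    anomer = character(0), phase = character(0), pathway = character(0),
    E = numeric(0), E_zpe = numeric(0), G = numeric(0),
    formula = character(0), charge = integer(0)))
  dir2 <- withr::local_tempdir()
  expect_no_error(build_report(empty, dir2))
  expect_true(file.exists(file.path(dir2, "missing_cells.txt")))
})
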