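R_KJ <- 8.314462618e-3

test_that("standard Gibbs energy at 298.15 K is the plain formation sum", {
  # independent oracle: hand-sum the formation terms from the species table
  sp <- thermo_species_table()
  gf <- function(s) sp$gibbs_formation_298[sp$name == s]
  oracle <- gf("H2O") - gf("H2") - 0.5 * gf("O2")
  expect_equal(standard_gibbs(h2_oxidation(), 298.15), oracle,
               tolerance = 1e-12)
  expect_equal(oracle, -263.13, tolerance = 1e-3)  # approx -263.1 kJ/mol

  oracle_s <- gf("SO4") - gf("H2S") - 2 * gf("O2")
  expect_equal(standard_gibbs(h2s_oxidation(), 298.15), oracle_s,
               tolerance = 1e-12)
})

test_that("Gibbs-Helmholtz correction is linear in T with the expected slope", {
  rxn <- h2_oxidation()
  sp <- thermo_species_table()
  gf <- function(s, col) sp[[col]][sp$name == s]
  dG <- standard_gibbs(rxn, 298.15)
  dH <- gf("H2O", "enthalpy_formation_298") -
    gf("H2", "enthalpy_formation_298") -
    0.5 * gf("O2", "enthalpy_formation_298")
  slope <- (standard_gibbs(rxn, 280) - standard_gibbs(rxn, 270)) / 10
  expect_equal(slope, -(dH - dG) / 298.15, tolerance = 1e-10)
})

test_that("reaction construction enforces charge balance and donor sign", {
  expect_error(reaction("bad", c(H2S = -1, O2 = -2, SO4 = 1), 8L, "H2S"),
               "charge balanced")
  expect_error(reaction("bad", c(H2 = 1, O2 = -0.5, H2O = 1), 2L, "H2"),
               "negative coefficient")
  expect_error(reaction("bad", c(H2 = -1, O2 = -0.5, H2O = 1), 0, "H2"),
               "positive")
  expect_error(reaction("bad", c(Xe = -1), 1L, "Xe"), "unknown species")
})

test_that("conservative mixing is exact at the identity and scales by 1/d", {
  em <- endmember_fluid(c(H2 = 7.5e-3), "test")
  sw <- seawater_background()
  expect_equal(mix_conservative(em, sw, 1)$concentrations[["H2"]], 7.5e-3)
  expect_equal(mix_conservative(em, sw, 1e4)$concentrations[["H2"]], 7.5e-7)
  # CO at 1.9 uM diluted a million-fold lands in the picomolar range
  co <- mix_conservative(irinovskoe_endmember(), sw, 1e6)$concentrations[["CO"]]
  expect_equal(co, 1.9e-12, tolerance = 1e-9)
  expect_lt(co, 1e-11)
})

test_that("mixing is linear in 1/d and converges to seawater", {
  em <- irinovskoe_endmember()
  sw <- seawater_background()
  c_em <- em$concentrations[["H2"]]
  for (d in c(2, 10, 1e3, 1e5)) {
    st <- mix_conservative(em, sw, d)
    expect_equal(st$concentrations[["H2"]], c_em / d)
    # mixed O2 lies between endmember (0) and seawater values
    expect_gte(st$concentrations[["O2"]], 0)
    expect_lte(st$concentrations[["O2"]], sw$oxygen)
  }
  far <- mix_conservative(em, sw, 1e12)
  expect_equal(far$concentrations[["O2"]], sw$oxygen, tolerance = 1e-6)
  expect_equal(far$concentrations[["H2"]], 0, tolerance = 1e-12)
})

test_that("mixing rejects invalid dilution and unknown species", {
  sw <- seawater_background()
  expect_error(mix_conservative(irinovskoe_endmember(), sw, 0.5),
               "invalid dilution")
  expect_error(endmember_fluid(c(Kr = 1e-3)), "unknown species")
  expect_error(endmember_fluid(c(H2 = -1e-3)), "non-negative")
})

test_that("in-situ Gibbs energy reduces to the standard value at Q = 1", {
  # unit activities: all concentrations 1 mol/kg, gamma = 1, no H+ in reaction
  em <- endmember_fluid(c(H2 = 1, O2 = 1))
  sw <- seawater_background(activity_coefficients = c(SO4 = 0.12))
  st <- mix_conservative(em, sw, 1)
  st$concentrations[["O2"]] <- 1  # mixing restores seawater O2; force unit
  expect_equal(delta_rG(h2_oxidation(), st, sw),
               standard_gibbs(h2_oxidation(), sw$temperature),
               tolerance = 1e-10)
})

test_that("zero donor concentration is a degenerate activity", {
  em <- endmember_fluid(c(H2 = 7.5e-3))  # no H2S
  sw <- seawater_background()
  st <- mix_conservative(em, sw, 1e4)
  expect_error(delta_rG(h2s_oxidation(), st, sw), "degenerate activity")
})

test_that("per-electron and energy-density follow their definitions", {
  expect_equal(round_half_out(per_electron(-222.67, h2_oxidation()), 2),
               -111.34)
  expect_equal(round_half_out(per_electron(-773.33, h2s_oxidation()), 2),
               -96.67)
  one_e <- reaction("one_e", c(H2 = -1, O2 = -0.5, H2O = 1), 1L, "H2")
  expect_identical(per_electron(-5, one_e), -5)

  em <- irinovskoe_endmember()
  expect_equal(energy_density(-212.12, em, h2_oxidation()),
               -212.12 * 7.5e-3, tolerance = 1e-12)
  expect_equal(energy_density(-212.12, em, h2_oxidation()), -1.59,
               tolerance = 0.01)
  em0 <- endmember_fluid(c(H2 = 0))
  expect_equal(energy_density(-212.12, em0, h2_oxidation()), 0)
  expect_gt(energy_density(5, em, h2_oxidation()), 0)
  expect_error(energy_density(-1, endmember_fluid(c(H2S = 1e-3)),
                              h2_oxidation()),
               "unknown species")
})

test_that("energetics table has reaction-major rows, monotone in dilution", {
  tab <- energetics_table(dilutions = c(1e4, 1e5, 1e6))
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$reaction,
               rep(c("H2_oxidation", "H2S_oxidation"), each = 3L))
  expect_equal(tab$dilution, rep(c(1e4, 1e5, 1e6), 2L))
  for (rx in unique(tab$reaction)) {
    g <- tab$delta_rG_kJ_per_mol[tab$reaction == rx]
    expect_true(all(diff(g) > 0))  # less negative as the plume dilutes
  }
  # per-electron column is the per-mole column divided by n_e, exactly
  expect_equal(tab$delta_rG_per_e,
               tab$delta_rG_kJ_per_mol /
                 rep(c(2, 8), each = 3L), tolerance = 1e-12)
  # H2S oxidation yields more energy per mole than H2 at every dilution
  expect_true(all(tab$delta_rG_kJ_per_mol[4:6] < tab$delta_rG_kJ_per_mol[1:3]))

  one <- energetics_table(reactions = list(h2_oxidation()), dilutions = 1e4)
  expect_equal(nrow(one), 1L)
  expect_error(energetics_table(dilutions = numeric(0)), "non-empty")
})

test_that("consecutive decades differ by R T ln 10 when only the donor dilutes", {
  # hold oxidant and sulfate at seawater values so only the donor changes
  sw <- seawater_background()
  em <- endmember_fluid(c(H2 = 7.5e-3, H2S = 3.2e-3,
                          O2 = sw$oxygen, SO4 = sw$sulfate))
  for (rxn in list(h2_oxidation(), h2s_oxidation())) {
    g <- vapply(10^(3:6), function(d)
      delta_rG(rxn, mix_conservative(em, sw, d), sw), numeric(1))
    expect_equal(diff(g), rep(R_KJ * sw$temperature * log(10), 3L),
                 tolerance = 1e-9)
  }
  expect_equal(decade_shift(0, 275.9), 5.2821, tolerance = 1e-4)
})

test_that("half-away-from-zero rounding matches report conventions", {
  expect_equal(round_half_out(-111.335, 2), -111.34)
  expect_equal(round_half_out(111.335, 2), 111.34)
  expect_equal(round_half_out(2.5, 0), 3)
  expect_equal(round_half_out(-2.5, 0), -3)
})

test_that("YAML configuration round-trips concentrations and units", {
  cfg <- read_energetics_config(
    system.file("extdata", "irinovskoe.yaml", package = "hydroplume"))
  expect_s3_class(cfg$endmember, "plume_endmember")
  expect_equal(cfg$endmember$concentrations[["H2"]], 7.5e-3)
  expect_equal(cfg$endmember$concentrations[["CO"]], 1.9e-6)
  expect_equal(cfg$seawater$oxygen, 250e-6)
  expect_equal(cfg$seawater$activity_coefficients[["SO4"]], 0.12)
  # the config reproduces the built-in defaults
  expect_equal(energetics_table(cfg$endmember, cfg$seawater),
               energetics_table())
})
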