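test_that("bundled reactions are charge- and element-balanced", {
  for (rxn in REACTIONS) expect_true(validate_reaction(rxn, SPECIES))
  bad <- reaction("bad", c(acetate = -1, CO2 = 2, H2 = 4, H2O = -2))
  expect_error(validate_reaction(bad, SPECIES), "charge")
})

test_that("standard free energies sum formation energies over the stoichiometry", {
  std_ac <- delta_g_standard(EQ_AC, SPECIES)
  std_pr <- delta_g_standard(EQ_PR, SPECIES)
  std_me <- delta_g_standard(EQ_ME, SPECIES)
  expect_lt(abs(std_ac[["delta_g0_298"]] - 54.9), 1.0)
  expect_lt(abs(std_pr[["delta_g0_298"]] - 73.7), 1.0)
  expect_lt(abs(std_me[["delta_g0_298"]] - (-130.8)), 1.0)
  # empty stoichiometry sums to zero
  expect_equal(delta_g_standard(reaction("empty", numeric()), SPECIES),
               c(delta_g0_298 = 0, delta_h0_298 = 0))
  expect_error(delta_g_standard(reaction("x", c(glucose = -1)), SPECIES),
               "glucose")
})

test_that("pH-referenced standard free energy shifts by the proton term only", {
  dg0 <- delta_g_standard(EQ_AC, SPECIES)[["delta_g0_298"]]
  dg7 <- delta_g_standard_at_ph(EQ_AC, SPECIES, pH = 7)
  # one H+ reactant at activity 1e-7 makes the oxidation ~40 kJ/mol harder
  expect_equal(dg7, dg0 + (-1) * R_KJ * T_REF * log(10^-7))
  expect_equal(dg7, 94.9, tolerance = 0.02)
  # no H+ in propionate oxidation: the view is identical to dG0
  expect_equal(delta_g_standard_at_ph(EQ_PR, SPECIES, pH = 7),
               delta_g_standard(EQ_PR, SPECIES)[["delta_g0_298"]])
})

test_that("Gibbs-Helmholtz translation is exact, linear, and fixed at 298.15 K", {
  expect_equal(gibbs_helmholtz(73.7, 202.85, T_REF), 73.7)
  # entropy-free limit: dH = dG leaves dG unchanged at any temperature
  expect_equal(gibbs_helmholtz(-10, -10, 350), -10)
  # independent hand evaluation of the closed form
  h <- 150
  expect_equal(gibbs_helmholtz(73.7, h, 310.15),
               73.7 * (310.15 / 298.15) + h * (298.15 - 310.15) / 298.15)
  # linearity in both arguments
  set.seed(7)
  for (k in 1:20) {
    g1 <- runif(1, -200, 200); g2 <- runif(1, -200, 200)
    h1 <- runif(1, -300, 300); h2 <- runif(1, -300, 300)
    a <- runif(1, -2, 2); tt <- runif(1, 270, 340)
    expect_equal(gibbs_helmholtz(g1 + a * g2, h1 + a * h2, tt),
                 gibbs_helmholtz(g1, h1, tt) + a * gibbs_helmholtz(g2, h2, tt))
  }
  expect_error(gibbs_helmholtz(1, 1, -5), "positive")
})

test_that("reaction quotient follows the activity conventions", {
  # unit state: all activities 1
  st <- chemical_state(solutes = c(acetate = 1, propionate = 1),
                       gases = c(H2 = 1e5, CO2 = 1e5, CH4 = 1e5),
                       pH = 0, temperature = 310.15)
  expect_equal(reaction_quotient(EQ_AC, st, SPECIES), 1)
  expect_equal(reaction_quotient(EQ_ME, st, SPECIES), 1)
  # manual term-by-term product for propionate oxidation
  st2 <- chemical_state(solutes = c(acetate = 0.01, propionate = 0.058),
                        gases = c(H2 = 5.3, CO2 = 26700),
                        pH = 7.2, temperature = 310.15)
  manual <- 0.01 * (26700 / 1e5) * (5.3 / 1e5)^3 / 0.058
  expect_equal(reaction_quotient(EQ_PR, st2, SPECIES), manual,
               tolerance = 1e-12)
  # zero product activity gives Q = 0; zero reactant activity errors
  st3 <- chemical_state(solutes = c(acetate = 0, propionate = 0.058),
                        gases = c(H2 = 5.3, CO2 = 26700), temperature = 310.15)
  expect_equal(reaction_quotient(EQ_PR, st3, SPECIES), 0)
  expect_error(reaction_quotient(EQ_AC, st3, SPECIES), "zero activity")
  st4 <- chemical_state(solutes = c(propionate = 0.058),
                        gases = c(H2 = 5.3, CO2 = 26700), temperature = 310.15)
  expect_error(reaction_quotient(EQ_PR, st4, SPECIES), "missing measurement")
})

test_that("the gas standard state is configurable between bar and atm", {
  st_bar <- chemical_state(gases = c(H2 = 101325, CO2 = 101325, CH4 = 101325),
                           solutes = c(), temperature = 310.15)
  st_atm <- chemical_state(gases = c(H2 = 101325, CO2 = 101325, CH4 = 101325),
                           solutes = c(), temperature = 310.15,
                           standard_pressure_Pa = 101325)
  expect_equal(reaction_quotient(EQ_ME, st_atm, SPECIES), 1)
  expect_gt(abs(log(reaction_quotient(EQ_ME, st_bar, SPECIES))), 0)
})

test_that("compute_delta_g chains the standard, temperature and quotient steps", {
  st <- chemical_state(solutes = c(acetate = 1, propionate = 1),
                       gases = c(H2 = 1e5, CO2 = 1e5, CH4 = 1e5),
                       pH = 0, temperature = 310.15)
  res <- compute_delta_g(EQ_PR, st, SPECIES)
  expect_equal(res$delta_g, res$delta_g0_T)  # Q = 1 => ln Q = 0
  # spreadsheet-style recomputation for methanogenesis
  st2 <- chemical_state(solutes = c(),
                        gases = c(H2 = 10, CO2 = 3e4, CH4 = 6e4),
                        temperature = 310.15)
  res2 <- compute_delta_g(EQ_ME, st2, SPECIES)
  std <- delta_g_standard(EQ_ME, SPECIES)
  dg0_t <- std[["delta_g0_298"]] * 310.15 / 298.15 +
    std[["delta_h0_298"]] * (298.15 - 310.15) / 298.15
  q <- (6e4 / 1e5) * (1e5 / 1e5)^0 / ((10 / 1e5)^4 * (3e4 / 1e5))
  expect_equal(res2$delta_g, dg0_t + R_KJ * 310.15 * log(q), tolerance = 1e-12)
  # internal consistency invariant of the result object
  expect_equal(res2$delta_g,
               res2$delta_g0_T + R_KJ * 310.15 * log(res2$reaction_quotient),
               tolerance = 1e-9)
  # zero product => unbounded-exergonic sentinel, not an error
  st3 <- chemical_state(solutes = c(acetate = 0, propionate = 0.058),
                        gases = c(H2 = 5.3, CO2 = 26700), temperature = 310.15)
  res3 <- compute_delta_g(EQ_PR, st3, SPECIES)
  expect_true(res3$unbounded_exergonic)
  expect_identical(res3$delta_g, -Inf)
})

test_that("critical concentration solves dG = 0 in closed form", {
  # equilibrium at unit activity when dG0_T = 0 and everything else is 1
  flat <- SPECIES
  flat$dGf_kJ_mol[] <- 0
  flat$dHf_kJ_mol[] <- 0
  st1 <- chemical_state(solutes = c(acetate = 1, propionate = 1),
                        gases = c(H2 = 1e5, CO2 = 1e5), pH = 0,
                        temperature = 310.15)
  expect_equal(critical_concentration(EQ_PR, st1, flat, "acetate"), 1)
  # round trip: plugging the solution back gives dG = 0
  crit <- critical_concentration(EQ_PR, plateau_state(), SPECIES, "acetate")
  st_back <- plateau_state(acetate_M = crit)
  expect_lt(abs(compute_delta_g(EQ_PR, st_back, SPECIES)$delta_g), 1e-6)
  # gases and absent species are rejected
  expect_error(critical_concentration(EQ_PR, plateau_state(), SPECIES, "H2"),
               "aqueous")
  expect_error(critical_concentration(EQ_PR, plateau_state(), SPECIES, "CH4"),
               "zero coefficient")
})

test_that("dG is monotone in every measured activity", {
  set.seed(11)
  for (k in 1:60) {
    st <- random_state()
    rxn <- REACTIONS[[sample.int(3, 1)]]
    res0 <- compute_delta_g(rxn, st, SPECIES)$delta_g
    measurable <- intersect(names(rxn$stoichiometry),
                            c(names(st$solutes), names(st$gases)))
    s <- sample(measurable, 1)
    nu <- rxn$stoichiometry[[s]]
    st2 <- st
    if (s %in% names(st2$solutes)) st2$solutes[[s]] <- st2$solutes[[s]] * 1.5
    else st2$gases[[s]] <- st2$gases[[s]] * 1.5
    res1 <- compute_delta_g(rxn, st2, SPECIES)$delta_g
    if (nu > 0) expect_gt(res1, res0) else expect_lt(res1, res0)
  }
})

test_that("free energies are additive over summed reactions (Hess)", {
  set.seed(13)
  combined_st <- c(EQ_AC$stoichiometry)
  for (s in names(EQ_ME$stoichiometry)) {
    combined_st[s] <- (if (s %in% names(combined_st)) combined_st[[s]] else 0) +
      EQ_ME$stoichiometry[[s]]
  }
  combined <- reaction("acetoclastic_equivalent", combined_st)
  for (k in 1:25) {
    st <- random_state()
    total <- compute_delta_g(EQ_AC, st, SPECIES)$delta_g +
      compute_delta_g(EQ_ME, st, SPECIES)$delta_g
    expect_equal(compute_delta_g(combined, st, SPECIES)$delta_g, total,
                 tolerance = 1e-9)
  }
})

test_that("propionate oxidation has no proton term, so dG is pH-invariant", {
  set.seed(17)
  for (k in 1:25) {
    st <- random_state()
    st_acid <- st; st_acid$pH <- 2
    st_base <- st; st_base$pH <- 12
    expect_equal(compute_delta_g(EQ_PR, st_acid, SPECIES)$delta_g,
                 compute_delta_g(EQ_PR, st_base, SPECIES)$delta_g)
    # the acetate oxidation, which consumes a proton, is not pH-invariant
    expect_false(isTRUE(all.equal(
      compute_delta_g(EQ_AC, st_acid, SPECIES)$delta_g,
      compute_delta_g(EQ_AC, st_base, SPECIES)$delta_g)))
  }
})

test_that("gibbs_trace evaluates every record and flags missing products", {
  series <- simulate_batch(noiseless_params(seed = 5))
  tr <- gibbs_trace(series, EQ_PR, SPECIES)
  expect_equal(nrow(tr), nrow(series$records))
  # every record with propionate left is either finite or flagged
  has_reactant <- series$records$propionate_mM > 0
  expect_true(all(is.finite(tr$delta_g[has_reactant]) |
                    tr$unbounded_exergonic[has_reactant]))
  expect_true(all(is.na(tr$delta_g[!has_reactant])))
  # day-0 acetate is zero: propionate oxidation has no product acetate yet
  expect_true(tr$unbounded_exergonic[1])
  # acetate oxidation lacks its reactant on day 0 -> NA, or error if asked
  tr_ac <- gibbs_trace(series, EQ_AC, SPECIES)
  expect_true(is.na(tr_ac$delta_g[1]))
  expect_error(gibbs_trace(series, EQ_AC, SPECIES, on_zero_reactant = "error"),
               "zero activity")
})
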