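# shared fixtures: bundled constants and reactions, loaded once
SPECIES <- load_formation_energies()
REACTIONS <- load_reactions()

EQ_AC <- REACTIONS$acetate_oxidation
EQ_PR <- REACTIONS$propionate_oxidation
EQ_ME <- REACTIONS$hydrogenotrophic_methanogenesis

# the plateau-phase state used for the critical-concentration inversion:
# propionate 58 mM, pH2 5.3 Pa, pCO2 26,700 Pa at 37 C
plateau_state <- function(acetate_M = 0) {
  chemical_state(solutes = c(acetate = acetate_M, propionate = 0.058),
                 gases = c(H2 = 5.3, CO2 = 26700),
                 pH = 7, temperature = 310.15)
}

# random yet valid state over the bundled species, on log scales
random_state <- function() {
  chemical_state(
    solutes = c(acetate = 10^runif(1, -6, 0), propionate = 10^runif(1, -6, 0)),
    gases = c(H2 = 10^runif(1, 0, 5), CO2 = 10^runif(1, 3, 5),
              CH4 = 10^runif(1, 3, 5)),
    pH = runif(1, 5, 9), temperature = runif(1, 280, 330))
}

noiseless_params <- function(...) {
  batch_sim_params(noise_sd = c(vfa = 0, gas_fraction = 0, pressure = 0, pH = 0),
                   ...)
}

# phase-1 acetate-on-propionate regression slope for one simulated series
phase1_slope <- function(series) {
  sch <- attr(series, "truth")$schedule
  r <- series$records
  i <- r$day >= sch$lag_end & r$day <= sch$phase1_end
  gained <- r$acetate_mM[i] - r$acetate_mM[1]
  consumed <- r$propionate_mM[1] - r$propionate_mM[i]
  unname(coef(lm(gained ~ consumed))[2])
}
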