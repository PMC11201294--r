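#' @importFrom stats approx coef lm pt setNames rnorm runif var
#' @importFrom utils read.delim write.table
NULL

#' Gas constant in kJ/(mol K)
#'
#' Molar gas constant used throughout the free-energy calculations.
#' @export
R_KJ <- 8.314462618e-3

#' Reference temperature (K) of the bundled formation energies
#' @export
T_REF <- 298.15

# Gas constant in J/(mol K), for ideal-gas headspace mole accounting.
R_J <- 8.314462618

#' Load a formation-energy table
#'
#' Reads a tab-separated table of standard Gibbs free energies and enthalpies
#' of formation at 298.15 K. The bundled default covers the seven species of
#' the three default reactions (acetate, propionate, H+, H2, H2O, CO2, CH4),
#' each constant annotated with its literature source. H+ follows the
#' conventional standard state (zero formation energy at unit activity).
#'
#' @param path path to a TSV with columns `species, phase, charge, n_C, n_H,
#'   n_O, dGf_kJ_mol, dHf_kJ_mol, source`; `NULL` for the bundled table.
#' @return a `data.frame` of class `thermo_table`, one row per species.
#' @export
load_formation_energies <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "formation_energies.tsv", package = "syntherm")
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("species", "phase", "charge", "dGf_kJ_mol", "dHf_kJ_mol")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("formation-energy table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$species)) stop("duplicated species in formation-energy table")
  bad <- !tab$phase %in% c("aqueous", "gas", "liquid-water", "proton")
  if (any(bad)) stop("unknown phase for species: ", paste(tab$species[bad], collapse = ", "))
  if (any(!is.finite(tab$dGf_kJ_mol)) || any(!is.finite(tab$dHf_kJ_mol))) {
    stop("non-finite formation energy in table")
  }
  rownames(tab) <- tab$species
  class(tab) <- c("thermo_table", "data.frame")
  tab
}

#' Define a reaction
#'
#' A reaction is a signed stoichiometry over named species: reactants carry
#' negative coefficients, products positive. Zero coefficients are dropped.
#'
#' @param name identifier.
#' @param stoichiometry named numeric vector of signed coefficients.
#' @param reference free-text equation label.
#' @return an object of class `reaction`.
#' @export
reaction <- function(name, stoichiometry, reference = "") {
  stopifnot(is.numeric(stoichiometry))
  if (length(stoichiometry) > 0 &&
      (is.null(names(stoichiometry)) || any(names(stoichiometry) == ""))) {
    stop("stoichiometry must be a fully named vector")
  }
  stoichiometry <- stoichiometry[stoichiometry != 0]
  structure(list(name = name, stoichiometry = stoichiometry, reference = reference),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  cat("<reaction>", x$name, "\n")
  if (nzchar(x$reference)) cat("  ", x$reference, "\n")
  print(x$stoichiometry)
  invisible(x)
}

#' Load reaction definitions from a YAML file
#'
#' The bundled default defines acetate oxidation to CO2 and H2, propionate
#' oxidation to acetate, CO2 and H2, and hydrogenotrophic methanogenesis.
#'
#' @param path YAML file mapping reaction name to `reference` and
#'   `stoichiometry`; `NULL` for the bundled defaults.
#' @return named list of `reaction` objects.
#' @export
load_reactions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reactions.yaml", package = "syntherm")
  }
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    st <- unlist(entry$stoichiometry)
    reaction(nm, st, reference = if (is.null(entry$reference)) "" else entry$reference)
  })
  setNames(out, names(raw))
}

species_row <- function(species_table, name) {
  idx <- match(name, species_table$species)
  if (is.na(idx)) stop("species not in formation-energy table: ", name)
  species_table[idx, , drop = FALSE]
}

#' Validate charge and elemental balance of a reaction
#'
#' Checks that the signed sum of charges is zero and, when the table carries
#' elemental composition columns (`n_C`, `n_H`, `n_O`), that carbon, hydrogen
#' and oxygen balance as well.
#'
#' @param rxn a [reaction()].
#' @param species_table a [load_formation_energies()] table.
#' @param tol numeric tolerance on the balances.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_reaction <- function(rxn, species_table, tol = 1e-9) {
  st <- rxn$stoichiometry
  rows <- do.call(rbind, lapply(names(st), function(s) species_row(species_table, s)))
  q <- sum(st * rows$charge)
  if (abs(q) > tol) stop("charge not conserved in ", rxn$name, " (net ", q, ")")
  for (el in c("n_C", "n_H", "n_O")) {
    if (el %in% names(rows)) {
      b <- sum(st * rows[[el]])
      if (abs(b) > tol) stop(el, " not balanced in ", rxn$name, " (net ", b, ")")
    }
  }
  invisible(TRUE)
}

#' Standard reaction free energy and enthalpy at 298.15 K
#'
#' Sums formation energies over the signed stoichiometry. All species are at
#' unit activity, including H+ (pH 0 standard state); pH enters the
#' non-standard calculation exclusively through the reaction quotient. For a
#' pH-referenced view see [delta_g_standard_at_ph()].
#'
#' @param rxn a [reaction()].
#' @param species_table a [load_formation_energies()] table.
#' @return named numeric `c(delta_g0_298 =, delta_h0_298 =)` in kJ/mol.
#' @export
delta_g_standard <- function(rxn, species_table) {
  st <- rxn$stoichiometry
  if (length(st) == 0) return(c(delta_g0_298 = 0, delta_h0_298 = 0))
  dg <- 0; dh <- 0
  for (s in names(st)) {
    row <- species_row(species_table, s)
    if (!is.finite(row$dGf_kJ_mol) || !is.finite(row$dHf_kJ_mol)) {
      stop("non-finite formation energy for species: ", s)
    }
    dg <- dg + st[[s]] * row$dGf_kJ_mol
    dh <- dh + st[[s]] * row$dHf_kJ_mol
  }
  c(delta_g0_298 = dg, delta_h0_298 = dh)
}

#' Standard free energy referenced to a non-zero pH
#'
#' Convenience view of the standard free energy with H+ held at `10^-pH`
#' rather than unit activity (the biochemists' pH 7 convention):
#' `delta_g0 + nu_H * R T ln(10^-pH)` where `nu_H` is the signed H+
#' coefficient.
#'
#' @inheritParams delta_g_standard
#' @param pH reference pH (default 7).
#' @param temperature Kelvin (default 298.15).
#' @return kJ/mol.
#' @export
delta_g_standard_at_ph <- function(rxn, species_table, pH = 7, temperature = T_REF) {
  dg <- delta_g_standard(rxn, species_table)[["delta_g0_298"]]
  nu_h <- if ("H+" %in% names(rxn$stoichiometry)) rxn$stoichiometry[["H+"]] else 0
  dg + nu_h * R_KJ * temperature * log(10^(-pH))
}

#' Gibbs-Helmholtz temperature translation of a standard free energy
#'
#' Translates a standard reaction free energy from 298.15 K to `target_T`
#' using the standard enthalpy, assuming temperature-independent enthalpy:
#' `dG(T2) = dG(T1) * T2/T1 + dH(T1) * (1 - T2/T1)`.
#'
#' @param delta_g0_298 standard free energy at 298.15 K, kJ/mol.
#' @param delta_h0_298 standard enthalpy at 298.15 K, kJ/mol.
#' @param target_T target temperature, Kelvin.
#' @return kJ/mol at `target_T`.
#' @export
gibbs_helmholtz <- function(delta_g0_298, delta_h0_298, target_T) {
  if (any(!is.finite(target_T)) || any(target_T <= 0)) {
    stop("target_T must be positive and finite")
  }
  ratio <- target_T / T_REF
  delta_g0_298 * ratio + delta_h0_298 * (1 - ratio)
}

#' A chemical state for non-standard free-energy evaluation
#'
#' Solute concentrations in mol/L, gas partial pressures in Pa, plus pH and
#' temperature. Activity conventions: solutes against 1 mol/L, gases against
#' the standard pressure (1 bar = 1e5 Pa by default), liquid water at unit
#' activity, H+ at `10^-pH`.
#'
#' @param solutes named numeric, mol/L.
#' @param gases named numeric, Pa.
#' @param pH unitless.
#' @param temperature Kelvin.
#' @param standard_pressure_Pa gas standard state; 1e5 Pa (1 bar) by default,
#'   set to 101325 for an atm convention.
#' @return object of class `chemical_state`.
#' @export
chemical_state <- function(solutes = numeric(), gases = numeric(), pH = 7,
                           temperature = 310.15, standard_pressure_Pa = 1e5) {
  if (any(solutes < 0) || any(gases < 0)) stop("concentrations and partial pressures must be >= 0")
  if (!is.finite(temperature) || temperature <= 0) stop("temperature must be positive")
  if (!is.finite(pH)) stop("pH must be finite")
  structure(list(solutes = solutes, gases = gases, pH = pH,
                 temperature = temperature,
                 standard_pressure_Pa = standard_pressure_Pa),
            class = "chemical_state")
}

# activity of one species in a state; NA_real_ when no measurement present
state_activity <- function(species, phase, state) {
  switch(phase,
    "liquid-water" = 1,
    "proton" = 10^(-state$pH),
    "aqueous" = if (species %in% names(state$solutes)) state$solutes[[species]] else NA_real_,
    "gas" = if (species %in% names(state$gases))
      state$gases[[species]] / state$standard_pressure_Pa else NA_real_,
    stop("unknown phase: ", phase)
  )
}

#' Reaction quotient at a measured state
#'
#' `Q = prod(activity^coefficient)` with the activity conventions of
#' [chemical_state()]. A zero activity of a product gives `Q = 0` (the state
#' lies at the unbounded-exergonic limit); a zero activity of a reactant is
#' an error because `ln Q` diverges to `+Inf` and the free energy is
#' undefined.
#'
#' @param rxn a [reaction()].
#' @param state a [chemical_state()].
#' @param species_table a [load_formation_energies()] table (for phases).
#' @return unitless numeric.
#' @export
reaction_quotient <- function(rxn, state, species_table) {
  st <- rxn$stoichiometry
  log_q <- 0
  for (s in names(st)) {
    row <- species_row(species_table, s)
    a <- state_activity(s, row$phase, state)
    if (is.na(a)) stop("missing measurement for species: ", s)
    if (a == 0) {
      if (st[[s]] < 0) stop("reactant ", s, " has zero activity; ln Q divergent")
      return(0)
    }
    log_q <- log_q + st[[s]] * log(a)
  }
  exp(log_q)
}

#' Non-standard reaction free energy at a measured state
#'
#' Chains [delta_g_standard()], [gibbs_helmholtz()] at the state temperature
#' and [reaction_quotient()] into `dG = dG0_T + R T ln Q`. A zero reaction
#' quotient (a product not yet present) yields the sentinel `delta_g = -Inf`
#' with `unbounded_exergonic = TRUE` rather than an error.
#'
#' @inheritParams reaction_quotient
#' @return object of class `gibbs_result`: a list with `delta_g0_298`,
#'   `delta_h0_298`, `delta_g0_T`, `reaction_quotient`, `delta_g`,
#'   `temperature`, `unbounded_exergonic`.
#' @export
compute_delta_g <- function(rxn, state, species_table) {
  std <- delta_g_standard(rxn, species_table)
  dg0_t <- gibbs_helmholtz(std[["delta_g0_298"]], std[["delta_h0_298"]],
                           state$temperature)
  q <- reaction_quotient(rxn, state, species_table)
  dg <- if (q == 0) -Inf else dg0_t + R_KJ * state$temperature * log(q)
  structure(list(delta_g0_298 = std[["delta_g0_298"]],
                 delta_h0_298 = std[["delta_h0_298"]],
                 delta_g0_T = dg0_t,
                 reaction_quotient = q,
                 delta_g = dg,
                 temperature = state$temperature,
                 unbounded_exergonic = (q == 0)),
            class = "gibbs_result")
}

#' @export
print.gibbs_result <- function(x, ...) {
  cat(sprintf("<gibbs_result> dG = %.3f kJ/mol at %.2f K (dG0_T = %.3f, Q = %.4g)\n",
              x$delta_g, x$temperature, x$delta_g0_T, x$reaction_quotient))
  invisible(x)
}

#' Critical concentration of an aqueous species at thermodynamic equilibrium
#'
#' Solves `dG = 0` for the concentration of one aqueous species with all
#' other activities fixed at the supplied state, via the closed form
#' `c = exp((-dG0_T/(R T) - ln Q_rest)/nu)` where `Q_rest` excludes the
#' target species. With the default reactions this reproduces the critical
#' acetate concentration above which propionate oxidation becomes endergonic.
#'
#' @inheritParams reaction_quotient
#' @param target_species name of an aqueous species with nonzero coefficient;
#'   any concentration it has in `state` is ignored.
#' @return mol/L.
#' @export
critical_concentration <- function(rxn, state, species_table, target_species) {
  st <- rxn$stoichiometry
  if (!target_species %in% names(st) || st[[target_species]] == 0) {
    stop("target species has zero coefficient in reaction: ", target_species)
  }
  row <- species_row(species_table, target_species)
  if (row$phase != "aqueous") {
    stop("critical concentration is only solved for aqueous species, not ", row$phase)
  }
  nu <- st[[target_species]]
  log_q_rest <- 0
  for (s in setdiff(names(st), target_species)) {
    r <- species_row(species_table, s)
    a <- state_activity(s, r$phase, state)
    if (is.na(a)) stop("missing measurement for species: ", s)
    if (a == 0) stop("fixed species ", s, " has zero activity; equilibrium undefined")
    log_q_rest <- log_q_rest + st[[s]] * log(a)
  }
  std <- delta_g_standard(rxn, species_table)
  dg0_t <- gibbs_helmholtz(std[["delta_g0_298"]], std[["delta_h0_298"]],
                           state$temperature)
  exp((-dg0_t / (R_KJ * state$temperature) - log_q_rest) / nu)
}

#' Per-timepoint free-energy trace over a batch series
#'
#' Evaluates [compute_delta_g()] for one reaction at every record of a
#' [batch_series()], building the chemical state from the VFA concentrations
#' (mM converted to mol/L), the headspace partial pressures, pH and
#' temperature of each measurement.
#'
#' @param series a [batch_series()].
#' @param rxn a [reaction()].
#' @param species_table a [load_formation_energies()] table.
#' @param on_zero_reactant `"na"` (default) records `NA` for timepoints where
#'   a reactant has zero activity; `"error"` propagates the error.
#' @return data.frame: `day, delta_g0_298, delta_h0_298, delta_g0_T, Q,
#'   delta_g, unbounded_exergonic`.
#' @export
gibbs_trace <- function(series, rxn, species_table,
                        on_zero_reactant = c("na", "error")) {
  on_zero_reactant <- match.arg(on_zero_reactant)
  rec <- series$records
  out <- lapply(seq_len(nrow(rec)), function(i) {
    m <- rec[i, ]
    pp <- partial_pressures(m)
    solutes <- c(acetate = m$acetate_mM / 1000, propionate = m$propionate_mM / 1000)
    state <- chemical_state(solutes = solutes, gases = pp, pH = m$pH,
                            temperature = m$temp_K)
    res <- tryCatch(compute_delta_g(rxn, state, species_table),
                    error = function(e) {
                      if (on_zero_reactant == "error" ||
                          !grepl("zero activity", conditionMessage(e))) stop(e)
                      NULL
                    })
    if (is.null(res)) {
      data.frame(day = m$day, delta_g0_298 = NA_real_, delta_h0_298 = NA_real_,
                 delta_g0_T = NA_real_, Q = NA_real_, delta_g = NA_real_,
                 unbounded_exergonic = NA)
    } else {
      data.frame(day = m$day, delta_g0_298 = res$delta_g0_298,
                 delta_h0_298 = res$delta_h0_298, delta_g0_T = res$delta_g0_T,
                 Q = res$reaction_quotient, delta_g = res$delta_g,
                 unbounded_exergonic = res$unbounded_exergonic)
    }
  })
  do.call(rbind, out)
}
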