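Package: syntherm
Title: Reaction Energetics and Hydrogenase Screening for Syntrophic
    Acid-Oxidizing Cultures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing mesophilic, high-ammonia batch cultures that
    degrade propionate and acetate syntrophically. Computes standard and
    non-standard Gibbs free energies of acetate oxidation, propionate
    oxidation and hydrogenotrophic methanogenesis from bundled formation
    energies (Gibbs-Helmholtz temperature correction, reaction quotients
    from measured concentrations and headspace partial pressures), inverts
    the free-energy relation for critical concentrations at thermodynamic
    equilibrium, converts headspace gas measurements to partial pressures
    with venting-corrected cumulative methane accounting, speciates free
    ammonia from total ammonia nitrogen, estimates local degradation rates
    and their correlation with hydrogen partial pressure, classifies
    hydrogenases in annotated proteomes by conserved FeFe/NiFe binding
    motifs including the NuoF-proximity rule for bifurcating A3 enzymes,
    and generates synthetic batch-culture time series and planted-motif
    proteomes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
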