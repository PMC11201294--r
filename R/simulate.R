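#' Parameters of the synthetic batch-culture generator
#'
#' Defaults emulate a mesophilic, high-ammonia 100 mM propionate batch: a
#' lag, a first propionate degradation phase with stoichiometric 1:1 acetate
#' accumulation down to a 58 mM plateau, a plateau while the acetate
#' oxidizer consumes the accumulated acetate, and a second degradation phase
#' to depletion. Hydrogen partial pressure sits at a baseline and rises to
#' 5.3 Pa while acetate oxidation is active; the CO2 headspace fraction is
#' held at 0.267 (26,700 Pa at ~1 bar) by the bicarbonate buffer; the
#' headspace is vented to 100 mbar gauge whenever it exceeds 1000 mbar
#' gauge. Trajectories are piecewise linear; Gaussian measurement noise is
#' added per channel last.
#'
#' @param initial_propionate,initial_acetate mM.
#' @param lag_days days before degradation starts.
#' @param phase1_rate,phase2_rate propionate consumption, mM/day.
#' @param plateau_propionate mM of propionate left when phase 1 halts.
#' @param plateau_days length of the halt between the two phases.
#' @param acetate_yield mol acetate accumulated per mol propionate consumed.
#' @param acetate_ox_rate acetate consumption while the acetate oxidizer is
#'   active (plateau onward), mM/day.
#' @param h2_baseline_Pa,h2_pulse_Pa hydrogen partial pressure baseline and
#'   its increment during acetate-oxidizer activity.
#' @param co2_fraction headspace CO2 mole fraction held by the buffer.
#' @param duration_days,sampling_interval_days sampling schedule.
#' @param noise_sd named per-channel standard deviations: `vfa` (mM),
#'   `gas_fraction`, `pressure` (mbar), `pH`.
#' @param headspace_volume,liquid_volume litres.
#' @param temperature Kelvin.
#' @param pH_profile data.frame `day, pH` of piecewise-linear anchors.
#' @param vent_threshold_mbar,vent_target_mbar gauge venting thresholds.
#' @param seed integer; fixes the full output.
#' @return list of class `batch_sim_params`.
#' @export
batch_sim_params <- function(initial_propionate = 100,
                             initial_acetate = 0,
                             lag_days = 30,
                             phase1_rate = 1.0,
                             plateau_propionate = 58,
                             plateau_days = 62,
                             phase2_rate = 0.8,
                             acetate_yield = 1.0,
                             acetate_ox_rate = 0.67,
                             h2_baseline_Pa = 3,
                             h2_pulse_Pa = 2.3,
                             co2_fraction = 0.267,
                             duration_days = 210,
                             sampling_interval_days = 7,
                             noise_sd = c(vfa = 1.0, gas_fraction = 0.005,
                                          pressure = 5, pH = 0.05),
                             headspace_volume = 0.5,
                             liquid_volume = 0.5,
                             temperature = 310.15,
                             pH_profile = data.frame(day = c(0, 210),
                                                     pH = c(7.2, 7.4)),
                             vent_threshold_mbar = 1000,
                             vent_target_mbar = 100,
                             seed = 1L) {
  p <- as.list(environment())
  rates <- c(p$phase1_rate, p$phase2_rate, p$acetate_ox_rate)
  if (any(rates < 0)) stop("rates must be >= 0")
  if (p$acetate_yield < 0 || p$acetate_yield > 1) stop("acetate_yield must be in [0, 1]")
  if (p$initial_propionate < 0 || p$initial_acetate < 0) stop("initial concentrations must be >= 0")
  if (p$headspace_volume <= 0 || p$liquid_volume <= 0) stop("volumes must be > 0")
  if (any(p$noise_sd < 0)) stop("noise_sd must be >= 0")
  if (p$sampling_interval_days <= 0 || p$duration_days <= 0) stop("schedule must be positive")
  structure(p, class = "batch_sim_params")
}

# phase boundaries implied by a parameter set (days)
sim_schedule <- function(p) {
  plateau_level <- min(p$plateau_propionate, p$initial_propionate)
  t1 <- if (p$phase1_rate > 0) {
    (p$initial_propionate - plateau_level) / p$phase1_rate
  } else 0
  phase1_end <- p$lag_days + t1
  plateau_end <- phase1_end + p$plateau_days
  t2 <- if (p$phase2_rate > 0) plateau_level / p$phase2_rate else 0
  phase2_end <- plateau_end + t2
  list(lag_end = p$lag_days, phase1_end = phase1_end,
       plateau_end = plateau_end, phase2_end = phase2_end,
       plateau_level = plateau_level)
}

# noiseless state of the liquid phase at time t (days)
sim_liquid <- function(p, sch, t) {
  pr <- if (t <= sch$lag_end) {
    p$initial_propionate
  } else if (t <= sch$phase1_end) {
    p$initial_propionate - p$phase1_rate * (t - sch$lag_end)
  } else if (t <= sch$plateau_end) {
    sch$plateau_level
  } else if (t <= sch$phase2_end) {
    sch$plateau_level - p$phase2_rate * (t - sch$plateau_end)
  } else 0
  pr <- max(pr, 0)
  consumed <- p$initial_propionate - pr
  produced_ac <- p$acetate_yield * consumed
  ox_time <- max(0, min(t, sch$phase2_end) - sch$phase1_end)
  ox <- p$acetate_ox_rate * ox_time
  ac_raw <- p$initial_acetate + produced_ac - ox
  ac <- max(ac_raw, 0)
  ox <- ox - (ac - ac_raw)  # clamp: never oxidize acetate that was not there
  list(propionate_mM = pr, acetate_mM = ac,
       propionate_consumed_mM = consumed, acetate_oxidized_mM = ox)
}

#' Simulate a batch-culture measurement table
#'
#' Generates the full measurement table a weekly-sampled batch culture would
#' produce under the parameterized piecewise-linear schedule, including
#' headspace accounting. Per mol propionate oxidized, 3 mol H2 are produced
#' and converted to 3/4 mol CH4 by hydrogenotrophic methanogenesis (net 1/4
#' mol CO2); per mol acetate oxidized, 4 mol H2 yield 1 mol CH4 (net 1 mol
#' CO2). Venting events trigger at sampling days whose gauge pressure
#' exceeds the threshold; the recorded pressure is the pre-vent reading and
#' the post-vent pressure is stored alongside. The same seed reproduces the
#' table exactly.
#'
#' @param params a [batch_sim_params()].
#' @return a [batch_series()]; attribute `truth` carries the noiseless
#'   trajectories, the phase schedule, cumulative CH4/CO2 bookkeeping and
#'   the vent log.
#' @export
simulate_batch <- function(params) {
  p <- params
  sch <- sim_schedule(p)
  days <- seq(0, p$duration_days, by = p$sampling_interval_days)
  n <- length(days)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(p$seed)

  v_h <- p$headspace_volume / 1000          # m3
  f <- p$co2_fraction
  n_tot0 <- ATM_MBAR * 100 * v_h / (R_J * p$temperature) * 1000  # mmol at 1 atm
  n_n2 <- n_tot0 * (1 - f)
  n_ch4 <- 0
  ch4_cum <- 0

  truth <- vector("list", n)
  rows <- vector("list", n)
  vent_log <- list()
  prev_ch4_total <- 0

  for (i in seq_len(n)) {
    t <- days[i]
    liq <- sim_liquid(p, sch, t)
    ch4_total <- (0.75 * liq$propionate_consumed_mM +
                  1.0 * liq$acetate_oxidized_mM) * p$liquid_volume  # mmol
    co2_total <- (0.25 * liq$propionate_consumed_mM +
                  1.0 * liq$acetate_oxidized_mM) * p$liquid_volume
    n_ch4 <- n_ch4 + (ch4_total - prev_ch4_total)
    prev_ch4_total <- ch4_total
    ch4_cum <- ch4_total

    saob_active <- t > sch$phase1_end & t <= sch$phase2_end
    p_h2 <- p$h2_baseline_Pa + if (saob_active) p$h2_pulse_Pa else 0

    n_dry <- (n_n2 + n_ch4) / (1 - f)       # N2 + CH4 + buffered CO2, mmol
    p_total_pa <- n_dry / 1000 * R_J * p$temperature / v_h + p_h2
    p_total_mbar <- p_total_pa / 100
    gauge_mbar <- p_total_mbar - ATM_MBAR

    x_ch4 <- n_ch4 / n_dry * (1 - p_h2 / p_total_pa)
    x_co2 <- f * (1 - p_h2 / p_total_pa)
    x_h2 <- p_h2 / p_total_pa

    vented <- gauge_mbar > p$vent_threshold_mbar
    post_gauge <- NA_real_
    if (vented) {
      post_gauge <- p$vent_target_mbar
      lambda <- (post_gauge + ATM_MBAR) / p_total_mbar
      vent_log[[length(vent_log) + 1]] <-
        data.frame(day = t, removed_ch4_mmol = n_ch4 * (1 - lambda))
      n_n2 <- n_n2 * lambda
      n_ch4 <- n_ch4 * lambda
    }

    pH_t <- approx(p$pH_profile$day, p$pH_profile$pH, xout = t, rule = 2)$y

    truth[[i]] <- data.frame(
      day = t, propionate_mM = liq$propionate_mM, acetate_mM = liq$acetate_mM,
      propionate_consumed_mM = liq$propionate_consumed_mM,
      acetate_oxidized_mM = liq$acetate_oxidized_mM,
      ch4_cum_mmol = ch4_cum, co2_cum_mmol = co2_total,
      pH2_Pa = p_h2, pressure_gauge_mbar = gauge_mbar, pH = pH_t)

    sd <- p$noise_sd
    vfa_noise <- function(x, s) pmax(0, x + rnorm(length(x), 0, s))
    x_ch4_n <- min(1, max(0, x_ch4 + rnorm(1, 0, sd[["gas_fraction"]])))
    x_co2_n <- min(1, max(0, x_co2 + rnorm(1, 0, sd[["gas_fraction"]])))
    if (x_ch4_n + x_co2_n + x_h2 > 1) {  # noise cannot overfill the headspace
      x_ch4_n <- max(0, 1 - x_co2_n - x_h2)
    }
    rows[[i]] <- data.frame(
      day = t,
      acetate_mM = vfa_noise(liq$acetate_mM, sd[["vfa"]]),
      propionate_mM = vfa_noise(liq$propionate_mM, sd[["vfa"]]),
      butyrate_mM = 0, isobutyrate_mM = 0, valerate_mM = 0,
      isovalerate_mM = 0, caproate_mM = 0, isocaproate_mM = 0,
      xCH4 = x_ch4_n,
      xCO2 = x_co2_n,
      xH2 = x_h2,
      pressure_mbar = max(0, gauge_mbar + rnorm(1, 0, sd[["pressure"]])),
      gauge = TRUE,
      pH = min(13.99, max(0.01, pH_t + rnorm(1, 0, sd[["pH"]]))),
      temp_K = p$temperature,
      vented = vented,
      post_vent_pressure_mbar = post_gauge)
  }

  records <- do.call(rbind, rows)
  series <- batch_series(records, culture_id = sprintf("sim-seed%d", p$seed),
                         headspace_volume = p$headspace_volume,
                         liquid_volume = p$liquid_volume)
  attr(series, "truth") <- list(trajectory = do.call(rbind, truth),
                                schedule = sch,
                                vents = if (length(vent_log))
                                  do.call(rbind, vent_log) else
                                  data.frame(day = numeric(),
                                             removed_ch4_mmol = numeric()),
                                params = p)
  series
}

random_aa <- function(n_residues) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n_residues,
               replace = TRUE), collapse = "")
}

matches_any_rule <- function(seq, rules) {
  any(vapply(rules$pattern, function(pat) grepl(pat, seq, perl = TRUE),
             logical(1)))
}

plant_motif <- function(seq, probe, pos = NULL) {
  if (is.null(pos)) pos <- sample.int(nchar(seq) - nchar(probe) - 10, 1) + 5
  paste0(substr(seq, 1, pos - 1), probe,
         substr(seq, pos + nchar(probe), nchar(seq)))
}

#' Simulate a proteome with planted hydrogenase motifs
#'
#' Generates random background proteins (300-600 aa, rejected if they match
#' any rule by chance), plants the requested motifs at recorded positions
#' and, for each planted A3, places a NuoF-labelled gene on the same contig
#' within the requested CDS distance. Plain `FeFe A` plants receive a decoy
#' NuoF at `decoy_nuof_distance` (default 6, just outside the proximity
#' rule) so the negative control is always present.
#'
#' @param n_genes total genes.
#' @param planted data.frame `group, count`; groups start with `"FeFe"` or
#'   `"NiFe"` (e.g. `"FeFe A3"`, `"FeFe A"`, `"NiFe 1a"`).
#' @param seed integer.
#' @param rules a [load_motif_rules()] table (its `probe` column supplies
#'   the planted exemplars).
#' @param genes_per_contig contig size for the gene-order layout.
#' @param a3_distances NuoF distances for A3 plants, recycled (default
#'   `1:5`, so the inclusive boundary is always exercised when at least five
#'   A3 genes are planted).
#' @param decoy_nuof_distance CDS distance of the decoy NuoF near plain
#'   FeFe A plants; `NA` to omit decoys.
#' @return list: `records` (gene records with sequence), `truth`
#'   (`gene_id, group, metal_class, a3, rule, position, nuof_gene_id,
#'   nuof_distance`).
#' @export
simulate_proteome <- function(n_genes, planted = data.frame(group = character(),
                                                            count = integer()),
                              seed = 1L, rules = load_motif_rules(),
                              genes_per_contig = 50,
                              a3_distances = 1:5,
                              decoy_nuof_distance = 6) {
  if (nrow(planted) > 0 && any(planted$count < 0)) stop("counts must be >= 0")
  groups <- rep(planted$group, planted$count)
  bad <- !grepl("^(FeFe|NiFe)", groups)
  if (any(bad)) stop("unknown metal class in planted group: ", groups[bad][1])
  if (!"probe" %in% names(rules) || anyNA(rules$probe[rules$metal_class == "FeFe"])) {
    stop("rule file lacks probe exemplars for planting")
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  is_a3 <- grepl("^FeFe A3", groups)
  n_nuof <- sum(is_a3) +
    if (!is.na(decoy_nuof_distance)) sum(grepl("^FeFe A$", groups)) else 0
  if (length(groups) + n_nuof > n_genes) {
    stop("n_genes too small for the requested plants")
  }

  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  contig <- sprintf("contig%02d", (seq_len(n_genes) - 1) %/% genes_per_contig + 1)
  ordinal <- (seq_len(n_genes) - 1) %% genes_per_contig
  product <- rep("hypothetical protein", n_genes)
  sequence <- character(n_genes)
  for (i in seq_len(n_genes)) {
    repeat {
      s <- random_aa(sample(300:600, 1))
      if (!matches_any_rule(s, rules)) break
    }
    sequence[i] <- s
  }

  # choose slots: planted genes away from contig edges so NuoF partners fit;
  # a slot is retried when both candidate partner positions are taken
  per_contig <- split(seq_len(n_genes), contig)
  margin <- max(c(a3_distances, decoy_nuof_distance, 1), na.rm = TRUE)
  eligible <- unlist(lapply(per_contig, function(idx) {
    idx[ordinal[idx] >= margin & ordinal[idx] <= max(ordinal[idx]) - margin]
  }), use.names = FALSE)
  if (length(groups) > 0 && length(eligible) < length(groups)) {
    stop("n_genes too small for the requested plants")
  }
  used <- integer(0)
  fefe_used <- integer(0)  # FeFe plants stay >= 12 CDS apart so no NuoF can
                           # sit within the proximity rule of a foreign plant
  truth <- vector("list", length(groups))
  a3_i <- 0

  for (k in seq_along(groups)) {
    g <- groups[k]
    metal <- if (grepl("^FeFe", g)) "FeFe" else "NiFe"
    want_nuof <- grepl("^FeFe A3", g)
    want_decoy <- grepl("^FeFe A$", g) && !is.na(decoy_nuof_distance)
    d <- if (want_nuof) {
      a3_i <- a3_i + 1
      a3_distances[(a3_i - 1) %% length(a3_distances) + 1]
    } else if (want_decoy) decoy_nuof_distance else NA_integer_
    i <- NA_integer_; j <- NA_integer_
    free <- setdiff(eligible, used)
    for (cand in sample(free)) {
      if (metal == "FeFe" && length(fefe_used) > 0) {
        near <- fefe_used[contig[fefe_used] == contig[cand]]
        if (length(near) > 0 && any(abs(ordinal[near] - ordinal[cand]) < 12)) next
      }
      if (is.na(d)) { i <- cand; break }
      partners <- which(contig == contig[cand] &
                        abs(ordinal - ordinal[cand]) == d)
      partners <- setdiff(partners, c(used, cand))
      if (length(partners) > 0) {
        i <- cand
        j <- partners[sample.int(length(partners), 1)]
        break
      }
    }
    if (is.na(i)) stop("n_genes too small for the requested plants")
    used <- c(used, i)
    if (metal == "FeFe") fefe_used <- c(fefe_used, i)
    class_rules <- rules[rules$metal_class == metal & !is.na(rules$probe), ]
    rule_row <- class_rules[sample.int(nrow(class_rules), 1), ]
    repeat {
      pos <- sample.int(nchar(sequence[i]) - nchar(rule_row$probe) - 10, 1) + 5
      s2 <- plant_motif(sequence[i], rule_row$probe, pos)
      other <- rules[rules$metal_class != metal, ]
      if (!matches_any_rule(s2, other)) break
    }
    sequence[i] <- s2
    product[i] <- paste(metal, "hydrogenase")
    nuof_id <- NA_character_; nuof_d <- NA_integer_
    if (!is.na(j)) {
      product[j] <- "NADH-quinone oxidoreductase subunit NuoF"
      used <- c(used, j)
      if (want_nuof) { nuof_id <- gene_id[j]; nuof_d <- as.integer(d) }
    }
    truth[[k]] <- data.frame(gene_id = gene_id[i], group = g,
                             metal_class = metal, a3 = want_nuof,
                             rule = rule_row$name, position = pos,
                             nuof_gene_id = nuof_id, nuof_distance = nuof_d,
                             stringsAsFactors = FALSE)
  }

  records <- data.frame(gene_id = gene_id, contig = contig, ordinal = ordinal,
                        product = product, sequence = sequence,
                        stringsAsFactors = FALSE)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), group = character(),
               metal_class = character(), a3 = logical(), rule = character(),
               position = integer(), nuof_gene_id = character(),
               nuof_distance = integer(), stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Write a simulated proteome to FASTA plus gene-order TSV
#'
#' @param proteome output of [simulate_proteome()].
#' @param fasta_path,gene_order_path,truth_path output paths (`truth_path`
#'   optional).
#' @export
write_proteome <- function(proteome, fasta_path, gene_order_path,
                           truth_path = NULL) {
  aa <- Biostrings::AAStringSet(setNames(proteome$records$sequence,
                                         proteome$records$gene_id))
  Biostrings::writeXStringSet(aa, fasta_path)
  write.table(proteome$records[, c("gene_id", "contig", "ordinal", "product")],
              gene_order_path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path)) {
    write.table(proteome$truth, truth_path, sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  invisible(fasta_path)
}
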