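VFA_COLUMNS <- c("acetate_mM", "propionate_mM", "butyrate_mM", "isobutyrate_mM",
                 "valerate_mM", "isovalerate_mM", "caproate_mM", "isocaproate_mM")

ATM_MBAR <- 1013.25

#' Batch-culture time series
#'
#' Container for time-indexed culture measurements: VFA concentrations (mM),
#' headspace mole fractions of CH4/CO2/H2, total headspace pressure (mbar,
#' gauge or absolute per row), pH, temperature and venting events.
#'
#' @param records data.frame with columns `day`, the eight VFA columns
#'   (`acetate_mM` ... `isocaproate_mM`; absent ones are filled with 0 with a
#'   warning), `xCH4, xCO2, xH2, pressure_mbar, gauge, pH, temp_K, vented,
#'   post_vent_pressure_mbar`.
#' @param culture_id identifier.
#' @param headspace_volume,liquid_volume litres, both > 0.
#' @return object of class `batch_series`.
#' @export
batch_series <- function(records, culture_id = "culture",
                         headspace_volume = 0.5, liquid_volume = 0.5) {
  if (headspace_volume <= 0 || liquid_volume <= 0) stop("volumes must be > 0")
  if (nrow(records) > 0 && any(diff(records$day) <= 0)) {
    stop("record days must be strictly increasing")
  }
  missing_vfa <- setdiff(VFA_COLUMNS, names(records))
  if (length(missing_vfa) > 0) {
    warning("missing VFA columns set to 0: ", paste(missing_vfa, collapse = ", "))
    for (col in missing_vfa) records[[col]] <- 0
  }
  for (col in c("xCH4", "xCO2", "xH2")) {
    if (!col %in% names(records)) stop("records lack column ", col)
    if (any(records[[col]] < 0 | records[[col]] > 1)) {
      stop(col, " outside [0, 1]")
    }
  }
  fsum <- records$xCH4 + records$xCO2 + records$xH2
  if (any(fsum > 1 + 1e-9)) {
    stop("gas mole fractions sum above 1 at row ", which(fsum > 1 + 1e-9)[1])
  }
  if (!"gauge" %in% names(records)) records$gauge <- TRUE
  if (!"vented" %in% names(records)) records$vented <- FALSE
  if (!"post_vent_pressure_mbar" %in% names(records)) {
    records$post_vent_pressure_mbar <- NA_real_
  }
  if (any(records$pH <= 0 | records$pH >= 14)) stop("pH outside (0, 14)")
  if (any(records$pressure_mbar < 0, na.rm = TRUE)) stop("negative pressure")
  structure(list(records = records, culture_id = culture_id,
                 headspace_volume = headspace_volume,
                 liquid_volume = liquid_volume),
            class = "batch_series")
}

#' @export
print.batch_series <- function(x, ...) {
  cat(sprintf("<batch_series> %s: %d records over %s days (headspace %.2f L, liquid %.2f L)\n",
              x$culture_id, nrow(x$records),
              if (nrow(x$records)) paste0(max(x$records$day)) else "0",
              x$headspace_volume, x$liquid_volume))
  invisible(x)
}

#' Read a batch-culture measurement table
#'
#' @param path CSV with one row per day and the [batch_series()] columns.
#' @inheritParams batch_series
#' @return a [batch_series()].
#' @export
read_batch_series <- function(path, culture_id = basename(path),
                              headspace_volume = 0.5, liquid_volume = 0.5) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("gauge" %in% names(rec)) rec$gauge <- as.logical(rec$gauge)
  if ("vented" %in% names(rec)) rec$vented <- as.logical(rec$vented)
  batch_series(rec, culture_id = culture_id,
               headspace_volume = headspace_volume, liquid_volume = liquid_volume)
}

#' Write a batch-culture measurement table
#'
#' @param series a [batch_series()].
#' @param path output CSV path.
#' @export
write_batch_series <- function(series, path) {
  utils::write.csv(series$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

absolute_pressure_mbar <- function(pressure_mbar, gauge) {
  if (isTRUE(gauge)) pressure_mbar + ATM_MBAR else pressure_mbar
}

#' Headspace partial pressures of one measurement
#'
#' Converts mole fractions to partial pressures by multiplication with the
#' absolute total headspace pressure: `p_i = x_i * P_abs`. Gauge readings are
#' converted with a 1013.25 mbar atmosphere; 1 mbar = 100 Pa.
#'
#' @param m one measurement (a one-row data.frame or list with `xCH4, xCO2,
#'   xH2, pressure_mbar`, and optionally `gauge`).
#' @return named numeric `c(CH4 =, CO2 =, H2 =)` in Pa.
#' @export
partial_pressures <- function(m) {
  x <- c(CH4 = m$xCH4, CO2 = m$xCO2, H2 = m$xH2)
  if (sum(x) > 1 + 1e-9) stop("gas mole fractions sum above 1")
  gauge <- if (is.null(m$gauge)) TRUE else isTRUE(m$gauge)
  p_abs_pa <- absolute_pressure_mbar(m$pressure_mbar, gauge) * 100
  x * p_abs_pa
}

#' Venting-corrected cumulative methane production
#'
#' Converts headspace CH4 to moles with the ideal gas law
#' (`n = p V / (R T)`) at every timepoint and adds back the moles removed at
#' each venting event, computed from the recorded pre- and post-vent
#' pressures at unchanged composition. The recorded pressure of a vented row
#' is the pre-vent reading; its removal is credited to all later timepoints.
#'
#' @param series a [batch_series()].
#' @return data.frame `day, ch4_mmol` of cumulative CH4 produced (mmol).
#' @export
cumulative_methane <- function(series) {
  rec <- series$records
  if (nrow(rec) == 0) return(data.frame(day = numeric(), ch4_mmol = numeric()))
  v <- series$headspace_volume / 1000  # L -> m3
  n_ch4 <- numeric(nrow(rec))
  removed <- numeric(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    m <- rec[i, ]
    p_abs <- absolute_pressure_mbar(m$pressure_mbar, isTRUE(m$gauge)) * 100
    n_ch4[i] <- m$xCH4 * p_abs * v / (R_J * m$temp_K) * 1000  # mmol
    if (isTRUE(m$vented)) {
      if (is.na(m$post_vent_pressure_mbar)) {
        stop("vented record at day ", m$day, " lacks post-vent pressure")
      }
      p_post <- absolute_pressure_mbar(m$post_vent_pressure_mbar, isTRUE(m$gauge)) * 100
      removed[i] <- m$xCH4 * (p_abs - p_post) * v / (R_J * m$temp_K) * 1000
    }
  }
  vented_before <- c(0, cumsum(removed)[-length(removed)])
  data.frame(day = rec$day, ch4_mmol = n_ch4 + vented_before)
}

#' Free-ammonia speciation from total ammonia nitrogen
#'
#' Computes the unionized NH3 fraction of total ammonia nitrogen as a
#' function of pH and temperature via the ammonium acid dissociation
#' constant parameterized as `pKa(T) = 0.09018 + 2729.92 / T`, so that
#' `fraction = 1 / (1 + 10^(pKa - pH))`.
#'
#' @param tan total ammonia nitrogen, mol/L.
#' @param pH unitless.
#' @param temperature Kelvin.
#' @param pka_coef the two parameters of the pKa model, overridable.
#' @return list of class `ammonia_state`: `tan`, `free_nh3` (mol/L),
#'   `fraction_nh3`, `pH`, `temperature`.
#' @export
free_ammonia <- function(tan, pH, temperature,
                         pka_coef = c(intercept = 0.09018, slope = 2729.92)) {
  if (any(tan < 0)) stop("tan must be >= 0")
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("temperature must be positive")
  }
  pka <- pka_coef[["intercept"]] + pka_coef[["slope"]] / temperature
  fraction <- 1 / (1 + 10^(pka - pH))
  structure(list(tan = tan, free_nh3 = tan * fraction, fraction_nh3 = fraction,
                 pH = pH, temperature = temperature),
            class = "ammonia_state")
}

#' @export
print.ammonia_state <- function(x, ...) {
  cat(sprintf("<ammonia_state> TAN %.4g M, NH3 %.4g M (fraction %.4g) at pH %.2f, %.2f K\n",
              x$tan[1], x$free_nh3[1], x$fraction_nh3[1], x$pH[1], x$temperature[1]))
  invisible(x)
}
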