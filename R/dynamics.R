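#' Local degradation rate by windowed linear fit
#'
#' Ordinary least-squares slope of concentration against day over a window
#' of points centered (index-wise) on the focal day, truncated at the series
#' ends. Consumption carries a negative slope.
#'
#' @param day numeric vector of days, strictly increasing.
#' @param conc concentrations (mM) matching `day`.
#' @param focal_day one of `day`.
#' @param halfwidth points on each side of the focal day (default 2, i.e. a
#'   5-point window at interior days).
#' @return list: `day`, `rate` (mM/day), `window` (days used), `r2` (`NA`
#'   when the fit residuals are degenerate, e.g. a constant series), `n`.
#' @export
local_slope <- function(day, conc, focal_day, halfwidth = 2) {
  stopifnot(length(day) == length(conc))
  i <- match(focal_day, day)
  if (is.na(i)) stop("focal_day not in series")
  idx <- max(1, i - halfwidth):min(length(day), i + halfwidth)
  if (length(idx) < 2) stop("fewer than 2 points in window")
  fit <- lm(conc[idx] ~ day[idx])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (var(conc[idx]) == 0) r2 <- NA_real_
  list(day = focal_day, rate = unname(coef(fit)[2]), window = day[idx],
       r2 = r2, n = length(idx))
}

#' Rate series over all timepoints
#'
#' Applies [local_slope()] at every day of the series.
#'
#' @inheritParams local_slope
#' @return data.frame `day, rate_mM_per_day, r2, n`.
#' @export
rate_series <- function(day, conc, halfwidth = 2) {
  rows <- lapply(day, function(d) {
    s <- local_slope(day, conc, d, halfwidth)
    data.frame(day = d, rate_mM_per_day = s$rate, r2 = s$r2, n = s$n)
  })
  do.call(rbind, rows)
}

#' Pearson correlation between degradation rate and H2 partial pressure
#'
#' Matches the two inputs on day and computes the Pearson correlation with a
#' two-sided p-value from the t transform. Consumption slopes are negated so
#' that the correlation relates H2 partial pressure to a positive
#' "degradation rate": a negative `r` then means high H2 goes with slow
#' degradation.
#'
#' @param rates data.frame `day, rate_mM_per_day` (consumption negative, as
#'   produced by [rate_series()]).
#' @param pressures data.frame `day, pressure_Pa`.
#' @return list `r`, `p`, `n`.
#' @export
rate_pressure_correlation <- function(rates, pressures) {
  merged <- merge(rates, pressures, by = "day")
  if (nrow(merged) < 3) stop("fewer than 3 matched days")
  degradation <- -merged$rate_mM_per_day
  if (var(degradation) == 0 || var(merged$pressure_Pa) == 0) {
    stop("zero variance in rates or pressures")
  }
  ct <- stats::cor.test(merged$pressure_Pa, degradation, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(merged))
}

#' Label lag, degradation and plateau phases of a trajectory
#'
#' Classifies each timepoint by the magnitude of its local slope: runs of
#' sub-threshold rate before any degradation form the lag, sub-threshold runs
#' between degradation runs are plateaus, and super-threshold runs are
#' numbered degradation phases. Runs shorter than `min_run` are merged into
#' the preceding run. A trailing sub-threshold run after the last degradation
#' phase (substrate depletion) is folded into that degradation label so the
#' ordering lag < degradation-1 < plateau < degradation-2 always holds.
#'
#' @inheritParams local_slope
#' @param rate_threshold mM/day; `|rate| >= threshold` counts as degradation
#'   (default 0.5).
#' @param min_run minimum run length in points (default 2).
#' @return data.frame `day, rate_mM_per_day, phase`.
#' @export
label_phases <- function(day, conc, rate_threshold = 0.5, min_run = 2,
                         halfwidth = 2) {
  rates <- rate_series(day, conc, halfwidth)
  fast <- abs(rates$rate_mM_per_day) >= rate_threshold
  if (length(fast) == 0) {
    return(data.frame(day = day, rate_mM_per_day = numeric(), phase = character()))
  }
  r <- rle(fast)
  # absorb short runs into the preceding run
  while (length(r$lengths) > 1 && any(r$lengths[-1] < min_run)) {
    j <- which(r$lengths[-1] < min_run)[1] + 1
    r$lengths[j - 1] <- r$lengths[j - 1] + r$lengths[j]
    r$lengths <- r$lengths[-j]
    r$values <- r$values[-j]
    r <- rle(inverse.rle(r))
  }
  labels <- character(length(r$values))
  deg <- 0
  for (k in seq_along(r$values)) {
    if (r$values[k]) {
      deg <- deg + 1
      labels[k] <- paste0("degradation-", deg)
    } else if (deg == 0) {
      labels[k] <- "lag"
    } else if (k < length(r$values)) {
      labels[k] <- "plateau"
    } else {
      labels[k] <- paste0("degradation-", deg)  # depletion tail
    }
  }
  phase <- rep(labels, r$lengths)
  data.frame(day = day, rate_mM_per_day = rates$rate_mM_per_day, phase = phase)
}

#' Write a tidy rates-and-phases table
#'
#' @param labels output of [label_phases()] (optionally with `r2` merged in).
#' @param path output TSV path.
#' @export
write_rate_table <- function(labels, path) {
  write.table(labels, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
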