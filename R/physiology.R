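#' Gas and biomass configuration
#'
#' Constants for dissolved-oxygen conversions and carbon-mole arithmetic.
#' The air-saturation concentration (130.3 µM at the 52 degC culture
#' temperature) and the atmospheric O2 mole fraction (0.21) are anchored so
#' that a 0.59 atm pO2 treatment reports 366 µM and 281% of air saturation
#' under nearest-integer rounding; both are configurable.
#'
#' @param atm_O2_fraction O2 mole fraction of air (default 0.21).
#' @param air_sat_conc_uM dissolved O2 at air saturation, µM (default 130.3).
#' @param biomass_formula named numeric vector of element subscripts in the
#'   one-carbon biomass formula (default CH1.8O0.5N0.2).
#' @param temperature_C culture temperature (default 52).
#' @param gas_temperature_K temperature at which off-gas flow is metered
#'   (default 298.15 K).
#' @param pressure_atm headspace pressure (default 1).
#' @return A `gas_config` list; `grams_per_cmol` is derived from the formula.
#' @export
gas_config <- function(atm_O2_fraction = 0.21,
                       air_sat_conc_uM = 130.3,
                       biomass_formula = c(C = 1, H = 1.8, O = 0.5, N = 0.2),
                       temperature_C = 52,
                       gas_temperature_K = 298.15,
                       pressure_atm = 1) {
  check_scalar(atm_O2_fraction, "atm_O2_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_scalar(air_sat_conc_uM, "air_sat_conc_uM", lower = 0,
               strict_lower = TRUE)
  masses <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)
  el <- names(biomass_formula)
  if (!all(el %in% names(masses))) {
    stop("biomass_formula elements must be among C, H, O, N", call. = FALSE)
  }
  structure(list(
    atm_O2_fraction = atm_O2_fraction,
    air_sat_conc_uM = air_sat_conc_uM,
    biomass_formula = biomass_formula,
    grams_per_cmol = sum(biomass_formula * masses[el]),
    temperature_C = temperature_C,
    gas_temperature_K = gas_temperature_K,
    pressure_atm = pressure_atm,
    R_L_atm = 0.0820574
  ), class = "gas_config")
}

#' Dissolved oxygen concentration from partial pressure
#'
#' Henry-law proportionality anchored at the air-saturation concentration:
#' `conc = air_sat_conc_uM * pO2 / atm_O2_fraction`.
#'
#' @param pO2 oxygen partial pressure, atm (>= 0).
#' @param gas a [gas_config()].
#' @return Concentration in µM.
#' @export
dissolved_o2 <- function(pO2, gas = gas_config()) {
  if (any(pO2 < 0)) stop("pO2 must be >= 0", call. = FALSE)
  gas$air_sat_conc_uM * pO2 / gas$atm_O2_fraction
}

#' Percent of air saturation from partial pressure
#'
#' @inheritParams dissolved_o2
#' @return `100 * pO2 / atm_O2_fraction`, in percent.
#' @export
percent_air_saturation <- function(pO2, gas = gas_config()) {
  if (any(pO2 < 0)) stop("pO2 must be >= 0", call. = FALSE)
  100 * pO2 / gas$atm_O2_fraction
}

#' Minimum steady-state window length in rows
#'
#' Three residence times at growth rate `mu` (h^-1), logged at `cadence_min`
#' minutes per row: `floor(3 * 60 / (mu * cadence_min))`.
#'
#' @param mu specific growth rate, h^-1.
#' @param cadence_min logging cadence in minutes (default 1).
#' @return Integer number of rows.
#' @export
min_steady_rows <- function(mu, cadence_min = 1) {
  check_scalar(mu, "mu", lower = 0, strict_lower = TRUE)
  as.integer(floor(3 * (1 / mu) * 60 / cadence_min))
}

#' Detect the trailing steady-state window of a turbidostat log
#'
#' A steady state requires every monitored channel (dilution rate, OD730,
#' dissolved O2) to stay within 10% of its window mean — "variation" is read
#' strictly as the maximum absolute deviation from the mean divided by the
#' mean — over at least three residence times (3/mean dilution rate). The
#' maximal trailing window satisfying the spread rule is located first; it
#' qualifies only if it spans the minimum number of rows. A channel whose
#' window mean is zero (dissolved O2 under a pO2 = 0 treatment) passes only
#' if it is identically zero.
#'
#' @param log a `turbidostat_log` (see [simulate_turbidostat()]) or a data
#'   frame with columns `time_h`, `dilution_rate`, `od730`,
#'   `dissolved_o2_uM`.
#' @param max_rel_spread spread tolerance (default 0.10).
#' @return A `steady_window` list: `found`, `start`, `end`, `n_rows`,
#'   `tau_h`, `min_rows`, per-channel `spread`, and `reason` when no window
#'   qualifies.
#' @export
detect_steady_state <- function(log, max_rel_spread = 0.10) {
  channels <- c("dilution_rate", "od730", "dissolved_o2_uM")
  missing <- setdiff(c("time_h", channels), names(log))
  if (length(missing)) {
    stop("log is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(log)
  # Per channel, the smallest window start such that the suffix [start..n]
  # keeps max|x - mean|/mean below tolerance; computed with suffix cumulatives.
  channel_start <- function(x) {
    rx <- rev(x)
    means <- cumsum(rx) / seq_len(n)
    mx <- cummax(rx)
    mn <- cummin(rx)
    dev <- pmax(mx - means, means - mn)
    ok <- ifelse(means == 0, mx == 0 & mn == 0, dev / abs(means) < max_rel_spread)
    # suffix of length L corresponds to start index n - L + 1
    lens <- which(ok)
    if (!length(lens)) return(NA_integer_)
    n - max(lens) + 1L
  }
  starts <- vapply(log[channels], channel_start, integer(1))
  if (anyNA(starts)) {
    bad <- channels[is.na(starts)]
    return(structure(list(found = FALSE,
                          reason = paste0("channel(s) never stable: ",
                                          paste(bad, collapse = ", "))),
                     class = "steady_window"))
  }
  start <- max(starts)
  # Combining channels can shift the window; advance until every channel's
  # spread holds on the shared window.
  spread_ok <- function(x, rows) {
    m <- mean(x[rows])
    if (m == 0) all(x[rows] == 0) else max(abs(x[rows] - m)) / abs(m) < max_rel_spread
  }
  while (start < n &&
         !all(vapply(log[channels], spread_ok, logical(1),
                     rows = seq(start, n)))) {
    start <- start + 1L
  }
  window <- seq(start, n)
  mu <- mean(log$dilution_rate[window])
  if (mu <= 0) {
    return(structure(list(found = FALSE,
                          reason = "nonpositive mean dilution rate"),
                     class = "steady_window"))
  }
  cadence_min <- if (n > 1) {
    stats::median(diff(log$time_h)) * 60
  } else {
    1
  }
  need <- min_steady_rows(mu, cadence_min)
  if (length(window) < need) {
    limiting <- channels[which.max(starts)]
    return(structure(list(
      found = FALSE, start = start, end = n, n_rows = length(window),
      tau_h = 1 / mu, min_rows = need,
      reason = sprintf(
        "stable window (%d rows, limited by %s) shorter than 3 residence times (%d rows)",
        length(window), limiting, need)
    ), class = "steady_window"))
  }
  spread <- vapply(log[channels], function(x) {
    xw <- x[window]
    m <- mean(xw)
    if (m == 0) 0 else max(abs(xw - m)) / abs(m)
  }, numeric(1))
  structure(list(
    found = TRUE, start = start, end = n, n_rows = length(window),
    tau_h = 1 / mu, min_rows = need, spread = spread
  ), class = "steady_window")
}

#' @export
print.steady_window <- function(x, ...) {
  if (isTRUE(x$found)) {
    cat(sprintf(
      "Steady-state window: rows %d-%d (%d rows >= %d required), tau = %.3f h\n",
      x$start, x$end, x$n_rows, x$min_rows, x$tau_h))
  } else {
    cat("No steady-state window:", x$reason, "\n")
  }
  invisible(x)
}

#' Specific growth rate from a steady-state window
#'
#' At turbidostat steady state the dilution rate equals the specific growth
#' rate, so mu is the window mean of the dilution-rate channel.
#'
#' @param log a turbidostat log.
#' @param window a `steady_window` from [detect_steady_state()]; detected
#'   automatically when omitted.
#' @return List with `mu` (h^-1), `sd` (of the dilution rows), `doubling_h`
#'   (`ln 2 / mu`) and `n_rows`.
#' @export
growth_rate <- function(log, window = NULL) {
  window <- window %||% detect_steady_state(log)
  if (!isTRUE(window$found)) {
    stop("no steady-state window: ", window$reason, call. = FALSE)
  }
  d <- log$dilution_rate[seq(window$start, window$end)]
  mu <- mean(d)
  if (mu <= 0) stop("nonpositive growth rate", call. = FALSE)
  list(mu = mu, sd = stats::sd(d), doubling_h = log(2) / mu,
       n_rows = window$n_rows)
}

#' Growth rate on a carbon-mole basis
#'
#' Converts mu (h^-1) to Cmmol biomass per hour per gram cell dry weight
#' using the configured one-carbon biomass formula weight.
#'
#' @param mu specific growth rate, h^-1.
#' @param gas a [gas_config()].
#' @return mu * 1000 / grams_per_cmol, in Cmmol h^-1 g^-1.
#' @export
cmol_rate <- function(mu, gas = gas_config()) {
  if (any(mu < 0)) stop("mu must be >= 0", call. = FALSE)
  mu * 1000 / gas$grams_per_cmol
}

#' Specific net O2 production rate from a steady-state window
#'
#' Oxygen balance over the reactor: the off-gas term converts the O2 mole
#' fraction difference (outlet minus inlet) to mmol/h via the ideal gas law
#' at the gas-meter temperature, and the dilution term accounts for dissolved
#' O2 leaving with the effluent. The sum is normalized by biomass:
#' `q_O2 = (F * (y_out - y_in) * 1000 * P / (R * T) + D * C * V * 1e-3) / (X * V)`
#' with F in L/h, C in µM, V in L, X in g CDW/L.
#'
#' @param log a turbidostat log carrying metadata attributes `gas_flow_L_h`,
#'   `volume_L`, `biomass_g_L` and `y_in` (inlet O2 mole fraction).
#' @param gas a [gas_config()].
#' @param window optional `steady_window`; detected when omitted.
#' @return List with `q_o2` (mmol O2 h^-1 g^-1 CDW), `gas_term` and
#'   `dilution_term` contributions (mmol/h), and the window means used.
#' @export
net_o2_rate <- function(log, gas = gas_config(), window = NULL) {
  window <- window %||% detect_steady_state(log)
  if (!isTRUE(window$found)) {
    stop("no steady-state window: ", window$reason, call. = FALSE)
  }
  meta <- attributes(log)
  for (field in c("gas_flow_L_h", "volume_L", "biomass_g_L", "y_in")) {
    if (is.null(meta[[field]])) {
      stop("log is missing metadata attribute '", field, "'", call. = FALSE)
    }
  }
  X <- meta$biomass_g_L
  if (X <= 0) stop("biomass concentration must be > 0", call. = FALSE)
  rows <- seq(window$start, window$end)
  y_out <- mean(log$offgas_o2[rows])
  D <- mean(log$dilution_rate[rows])
  C <- mean(log$dissolved_o2_uM[rows])
  V <- meta$volume_L
  gas_term <- meta$gas_flow_L_h * (y_out - meta$y_in) * 1000 *
    gas$pressure_atm / (gas$R_L_atm * gas$gas_temperature_K)
  dilution_term <- D * C * V * 1e-3
  list(q_o2 = (gas_term + dilution_term) / (X * V),
       gas_term = gas_term, dilution_term = dilution_term,
       y_out = y_out, D = D, dissolved_uM = C)
}

#' Photosynthetic quotient across steady states
#'
#' Ordinary least squares of the carbon-mole growth rate on the net O2
#' production rate; the slope is the photosynthetic quotient (Cmol biomass
#' per mol O2).
#'
#' @param q_o2 net O2 rates (mmol h^-1 g^-1), one per steady state.
#' @param mu_cmol matching carbon-mole growth rates (Cmmol h^-1 g^-1).
#' @return List with `slope`, `se`, `intercept`, `n`.
#' @export
photosynthetic_quotient <- function(q_o2, mu_cmol) {
  if (length(q_o2) != length(mu_cmol) || length(q_o2) < 2) {
    stop("need >= 2 (q_O2, mu_Cmol) points", call. = FALSE)
  }
  if (stats::sd(q_o2) == 0) {
    stop("degenerate fit: all q_O2 values identical", call. = FALSE)
  }
  fit <- stats::lm(mu_cmol ~ q_o2)
  cf <- summary(fit)$coefficients
  list(slope = unname(cf["q_o2", "Estimate"]),
       se = unname(cf["q_o2", "Std. Error"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       n = length(q_o2))
}

#' Oxygen sensitivity coefficient
#'
#' Linear decrease of the specific growth rate with oxygen partial pressure;
#' the sensitivity coefficient is the absolute slope of mu versus pO2, with
#' its standard error from the ordinary least-squares fit.
#'
#' @param pO2 oxygen partial pressures, atm (>= 3 distinct values).
#' @param mu matching specific growth rates, h^-1.
#' @return A `sensitivity_fit` list: `sensitivity` (|slope|, h^-1 atm^-1),
#'   `se`, `intercept` (mu at pO2 = 0), `slope` (signed) and `n`.
#' @export
o2_sensitivity <- function(pO2, mu) {
  if (length(pO2) != length(mu)) {
    stop("pO2 and mu must have equal length", call. = FALSE)
  }
  if (length(unique(pO2)) < 3) {
    stop("need >= 3 distinct pO2 values", call. = FALSE)
  }
  fit <- stats::lm(mu ~ pO2)
  cf <- summary(fit)$coefficients
  structure(list(
    sensitivity = abs(unname(cf["pO2", "Estimate"])),
    se = unname(cf["pO2", "Std. Error"]),
    intercept = unname(cf["(Intercept)", "Estimate"]),
    slope = unname(cf["pO2", "Estimate"]),
    n = length(pO2)
  ), class = "sensitivity_fit")
}

#' @export
print.sensitivity_fit <- function(x, ...) {
  cat(sprintf("O2 sensitivity: %.4f +/- %.4f h^-1 atm^-1 (n = %d, mu0 = %.4f h^-1)\n",
              x$sensitivity, x$se, x$n, x$intercept))
  invisible(x)
}
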