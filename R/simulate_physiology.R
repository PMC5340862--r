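#' Turbidostat kinetics parameters
#'
#' Growth model `mu(Ii, pO2) = mu_at(Ii) - sensitivity * pO2`: a
#' piecewise-linear irradiance response and a linear O2 inhibition term. The
#' default sensitivities are the published coefficients of the axenic
#' cyanobacterium (0.127 h^-1 atm^-1) and the binary consortium (0.086).
#' The maximum-irradiance growth rate (0.289 h^-1, a 2.4-h doubling time) is
#' published; the low/mid-irradiance defaults (0.08, 0.18 h^-1) are
#' non-authoritative placeholders on the observed monotone response.
#' Photosynthetic quotients (0.30 axenic / 0.40 binary Cmol biomass per mol
#' O2) are free parameters of the simulator — what the analysis is expected
#' to recover is the configured slope, not a literature value.
#'
#' @param culture `"axenic"` or `"binary"`.
#' @param mu_irradiance named vector mapping irradiance (µmol photons m^-2
#'   s^-1) to mu (h^-1); interpolated piecewise-linearly.
#' @param sensitivity O2 sensitivity, h^-1 atm^-1.
#' @param pq photosynthetic quotient used to set the simulated O2 rate.
#' @param noise_rel relative Gaussian noise on logged channels, in `[0, 0.1]`.
#' @param od_setpoint turbidostat OD730 setpoint.
#' @param gas_flow_L_h sparging gas flow, L h^-1.
#' @param volume_L working volume, L (default 5.5).
#' @param biomass_g_L steady-state biomass concentration, g CDW L^-1.
#' @param temperature_C culture temperature (default 52).
#' @param gas a [gas_config()].
#' @return A `kinetics_params` list.
#' @export
kinetics_params <- function(culture = c("axenic", "binary"),
                            mu_irradiance = c("197" = 0.08, "1190" = 0.18,
                                              "1995" = 0.289),
                            sensitivity = NULL,
                            pq = NULL,
                            noise_rel = 0.02,
                            od_setpoint = 0.40,
                            gas_flow_L_h = 30,
                            volume_L = 5.5,
                            biomass_g_L = 0.25,
                            temperature_C = 52,
                            gas = gas_config()) {
  culture <- match.arg(culture)
  sensitivity <- sensitivity %||% if (culture == "axenic") 0.127 else 0.086
  pq <- pq %||% if (culture == "axenic") 0.30 else 0.40
  check_scalar(noise_rel, "noise_rel", lower = 0, upper = 0.1)
  check_scalar(sensitivity, "sensitivity", lower = 0)
  check_scalar(volume_L, "volume_L", lower = 0, strict_lower = TRUE)
  check_scalar(biomass_g_L, "biomass_g_L", lower = 0, strict_lower = TRUE)
  structure(list(
    culture = culture,
    mu_irradiance = mu_irradiance,
    sensitivity = sensitivity,
    pq = pq,
    noise_rel = noise_rel,
    od_setpoint = od_setpoint,
    gas_flow_L_h = gas_flow_L_h,
    volume_L = volume_L,
    biomass_g_L = biomass_g_L,
    temperature_C = temperature_C,
    gas = gas
  ), class = "kinetics_params")
}

#' Modeled growth rate at an irradiance and oxygen tension
#'
#' @param params a [kinetics_params()].
#' @param irradiance µmol photons m^-2 s^-1.
#' @param pO2 atm (default 0).
#' @return mu in h^-1 (may be <= 0 outside the viable range).
#' @export
mu_at <- function(params, irradiance, pO2 = 0) {
  x <- as.numeric(names(params$mu_irradiance))
  base <- stats::approx(x, params$mu_irradiance, xout = irradiance,
                        rule = 2)$y
  base - params$sensitivity * pO2
}

#' Simulate a turbidostat process log
#'
#' Emits 1-min rows of dilution rate (mean = the modeled mu), OD730 (mean =
#' setpoint), dissolved O2 (Henry-law equilibrium with the inlet pO2) and
#' off-gas O2/CO2 fractions. The off-gas O2 fraction is set so that the
#' oxygen balance used by [net_o2_rate()] returns the configured specific O2
#' production rate `q_O2 = cmol_rate(mu)/pq` — a round-trip closure that is
#' exact on a noise-free log. Every channel carries independent relative
#' Gaussian noise `noise_rel`.
#'
#' @param params a [kinetics_params()].
#' @param condition one-row data frame (or list) with `label`, `irradiance`,
#'   `pO2` — typically a row of a design's conditions.
#' @param duration_h log duration; must cover >= 3 residence times at the
#'   modeled mu.
#' @param seed integer seed.
#' @return A `turbidostat_log` data frame (`time_h`, `dilution_rate`,
#'   `od730`, `dissolved_o2_uM`, `offgas_o2`, `offgas_co2`) with metadata
#'   attributes `condition`, `gas_flow_L_h`, `volume_L`, `biomass_g_L`,
#'   `y_in`, `mu_model`, `q_o2_model`.
#' @export
simulate_turbidostat <- function(params, condition, duration_h, seed = 1) {
  stopifnot(inherits(params, "kinetics_params"))
  mu <- mu_at(params, condition$irradiance, condition$pO2)
  if (mu <= 0) {
    stop("modeled growth rate is nonpositive at irradiance ",
         condition$irradiance, ", pO2 ", condition$pO2, call. = FALSE)
  }
  tau <- 1 / mu
  if (duration_h < 3 * tau) {
    stop(sprintf(
      "duration (%.2f h) must cover 3 residence times (%.2f h) at mu = %.4f",
      duration_h, 3 * tau, mu), call. = FALSE)
  }
  gas <- params$gas
  n <- floor(duration_h * 60) + 1
  c_dis <- dissolved_o2(condition$pO2, gas)
  q_o2 <- cmol_rate(mu, gas) / params$pq          # mmol O2 h^-1 g^-1 CDW
  X <- params$biomass_g_L
  V <- params$volume_L
  y_in <- condition$pO2 / gas$pressure_atm
  # invert the net_o2_rate() balance for the outlet O2 mole fraction
  gas_term <- q_o2 * X * V - mu * c_dis * V * 1e-3
  y_out <- y_in + gas_term * gas$R_L_atm * gas$gas_temperature_K /
    (params$gas_flow_L_h * 1000 * gas$pressure_atm)
  co2_in <- 0.05
  co2_uptake <- cmol_rate(mu, gas) * X * V        # Cmmol h^-1
  y_co2 <- co2_in - co2_uptake * gas$R_L_atm * gas$gas_temperature_K /
    (params$gas_flow_L_h * 1000 * gas$pressure_atm)

  with_seed(seed, {
    noise <- function(center) {
      center * (1 + params$noise_rel * stats::rnorm(n))
    }
    log <- data.frame(
      time_h = (seq_len(n) - 1) / 60,
      dilution_rate = noise(mu),
      od730 = noise(params$od_setpoint),
      dissolved_o2_uM = noise(c_dis),
      offgas_o2 = noise(y_out),
      offgas_co2 = noise(y_co2)
    )
    structure(log,
              condition = condition$label,
              irradiance = condition$irradiance,
              pO2 = condition$pO2,
              gas_flow_L_h = params$gas_flow_L_h,
              volume_L = V,
              biomass_g_L = X,
              y_in = y_in,
              mu_model = mu,
              q_o2_model = q_o2,
              class = c("turbidostat_log", "data.frame"))
  })
}

#' Ground truth of the simulated flow-cytometry community
#'
#' Population fractions default to the study's composition (90.2%
#' cyanobacterium, 9.1% heterotroph; the remaining 0.7% is debris so the
#' fractions sum to one). Channel means/sds define well-separated Gaussian
#' populations in forward scatter, side scatter, red autofluorescence and a
#' green stain; the constructor enforces >= 4 pooled-sd separation between
#' every pair of populations in at least one channel so that gating is
#' unambiguous.
#'
#' @param fractions named numeric vector over `cyanobacterium`,
#'   `heterotroph`, `debris`, summing to 1.
#' @param channels named list per population of `mean` and `sd` vectors over
#'   channels `fsc`, `ssc`, `red`, `green`.
#' @return A `facs_truth` list.
#' @export
facs_truth <- function(fractions = c(cyanobacterium = 0.902,
                                     heterotroph = 0.091,
                                     debris = 0.007),
                       channels = NULL) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("population fractions must sum to 1", call. = FALSE)
  }
  if (any(fractions < 0)) stop("fractions must be >= 0", call. = FALSE)
  if (is.null(channels)) {
    channels <- list(
      cyanobacterium = list(mean = c(fsc = 120, ssc = 100, red = 1000, green = 50),
                            sd = c(fsc = 10, ssc = 10, red = 80, green = 10)),
      heterotroph = list(mean = c(fsc = 45, ssc = 40, red = 30, green = 40),
                         sd = c(fsc = 6, ssc = 6, red = 8, green = 10)),
      debris = list(mean = c(fsc = 6, ssc = 5, red = 5, green = 5),
                    sd = c(fsc = 1.8, ssc = 1.5, red = 2, green = 2))
    )
  }
  pops <- names(fractions)
  if (!setequal(pops, names(channels))) {
    stop("channels must be configured for exactly the named populations",
         call. = FALSE)
  }
  for (i in seq_along(pops)) {
    for (j in seq_len(i - 1)) {
      a <- channels[[pops[i]]]
      b <- channels[[pops[j]]]
      sep <- abs(a$mean - b$mean) / sqrt((a$sd^2 + b$sd^2) / 2)
      if (max(sep) < 4) {
        stop("populations ", pops[i], " and ", pops[j],
             " are separated by < 4 pooled sds in every channel",
             call. = FALSE)
      }
    }
  }
  structure(list(fractions = fractions, channels = channels),
            class = "facs_truth")
}

#' Simulate a flow-cytometry event table
#'
#' Event labels are multinomial draws from the configured population
#' fractions; channel intensities are Gaussian per population. The truth
#' label is stored per event.
#'
#' @param truth a [facs_truth()].
#' @param n_events number of events (default 50000).
#' @param seed integer seed.
#' @return Data frame with columns `label`, `fsc`, `ssc`, `red`, `green`.
#' @export
simulate_facs <- function(truth = facs_truth(), n_events = 50000, seed = 1) {
  stopifnot(inherits(truth, "facs_truth"))
  check_scalar(n_events, "n_events", lower = 1)
  with_seed(seed, {
    pops <- names(truth$fractions)
    label <- sample(pops, n_events, replace = TRUE, prob = truth$fractions)
    out <- data.frame(label = label)
    for (ch in c("fsc", "ssc", "red", "green")) {
      mu <- vapply(truth$channels, function(p) p$mean[[ch]], numeric(1))[label]
      sd <- vapply(truth$channels, function(p) p$sd[[ch]], numeric(1))[label]
      out[[ch]] <- stats::rnorm(n_events, mu, sd)
    }
    out
  })
}

#' Default rectangular size/complexity gates
#'
#' Rectangles in (forward scatter, side scatter) at +/- 4.5 population sds,
#' matched to [facs_truth()] defaults; non-overlapping by construction.
#'
#' @param truth a [facs_truth()].
#' @param width half-width in population sds (default 4.5).
#' @return Named list of gates, each `list(fsc = c(lo, hi), ssc = c(lo, hi))`.
#' @export
default_facs_gates <- function(truth = facs_truth(), width = 4.5) {
  gates <- lapply(truth$channels, function(p) {
    list(fsc = c(p$mean[["fsc"]] - width * p$sd[["fsc"]],
                 p$mean[["fsc"]] + width * p$sd[["fsc"]]),
         ssc = c(p$mean[["ssc"]] - width * p$sd[["ssc"]],
                 p$mean[["ssc"]] + width * p$sd[["ssc"]]))
  })
  gates
}

#' Community composition from gated flow-cytometry events
#'
#' Events are assigned to rectangular (forward scatter, side scatter) gates;
#' gates must not overlap so that assignment is unique. Percentages are of
#' total recorded events; the ungated remainder is reported separately.
#'
#' @param events event table from [simulate_facs()] or equivalent, with
#'   columns `fsc` and `ssc`.
#' @param gates named list of gates (`list(fsc = c(lo, hi), ssc = c(lo, hi))`).
#' @return List with `percent` (named, per gate), `ungated_percent`,
#'   `counts`, `n_events` and `assignment` (factor per event, `NA` when
#'   ungated).
#' @export
facs_composition <- function(events, gates = default_facs_gates()) {
  gate_names <- names(gates)
  if (is.null(gate_names) || any(!nzchar(gate_names))) {
    stop("gates must be a named list", call. = FALSE)
  }
  overlap1 <- function(a, b) a[1] < b[2] && b[1] < a[2]
  for (i in seq_along(gates)) {
    for (j in seq_len(i - 1)) {
      if (overlap1(gates[[i]]$fsc, gates[[j]]$fsc) &&
          overlap1(gates[[i]]$ssc, gates[[j]]$ssc)) {
        stop("gates '", gate_names[i], "' and '", gate_names[j],
             "' overlap; events must be uniquely assignable", call. = FALSE)
      }
    }
  }
  assignment <- rep(NA_character_, nrow(events))
  for (g in gate_names) {
    gt <- gates[[g]]
    inside <- events$fsc >= gt$fsc[1] & events$fsc <= gt$fsc[2] &
      events$ssc >= gt$ssc[1] & events$ssc <= gt$ssc[2]
    assignment[inside] <- g
  }
  counts <- table(factor(assignment, levels = gate_names))
  n <- nrow(events)
  percent <- stats::setNames(100 * as.numeric(counts) / n, gate_names)
  list(
    percent = percent,
    ungated_percent = 100 * sum(is.na(assignment)) / n,
    counts = stats::setNames(as.integer(counts), gate_names),
    n_events = n,
    assignment = factor(assignment, levels = gate_names)
  )
}

#' Simulate a background-corrected ROS plate assay
#'
#' Each group receives `n_reps` dye-treated wells around its configured mean
#' and `n_reps` solvent-control wells around the shared control mean, all
#' with Gaussian noise `sd`.
#'
#' @param group_means named numeric vector of treated-well means per group.
#' @param control_mean control-well mean (nonspecific fluorescence).
#' @param sd well-level Gaussian noise (0 gives exact means).
#' @param n_reps replicates per group (default 3, >= 2).
#' @param seed integer seed.
#' @return A `ros_plate` data frame: `group`, `replicate`, `treated`,
#'   `control`.
#' @export
simulate_ros_plate <- function(group_means, control_mean, sd = 50,
                               n_reps = 3, seed = 1) {
  if (any(group_means < 0) || control_mean < 0) {
    stop("means must be >= 0", call. = FALSE)
  }
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  check_scalar(sd, "sd", lower = 0)
  groups <- names(group_means)
  if (is.null(groups)) stop("group_means must be named", call. = FALSE)
  with_seed(seed, {
    n <- length(groups) * n_reps
    out <- data.frame(
      group = rep(groups, each = n_reps),
      replicate = rep(seq_len(n_reps), length(groups)),
      treated = stats::rnorm(n, rep(group_means, each = n_reps), sd),
      control = stats::rnorm(n, control_mean, sd),
      stringsAsFactors = FALSE
    )
    class(out) <- c("ros_plate", "data.frame")
    out
  })
}

#' Background-corrected ROS summary with all-pairs comparisons
#'
#' Corrected fluorescence is `treated - control` within each replicate
#' pairing. Group means and sds are reported together with Tukey's honestly
#' significant difference test over all group pairs at the requested level
#' (default 99% family confidence, i.e. alpha = 0.01); unequal group sizes
#' use the Tukey-Kramer variant, as implemented by [stats::TukeyHSD()].
#'
#' @param plate a `ros_plate` data frame (`group`, `replicate`, `treated`,
#'   `control`); every group needs matched treated/control wells and >= 2
#'   replicates.
#' @param alpha family-wise significance level (default 0.01).
#' @return List with `groups` (data frame `group`, `mean`, `sd`, `n`) and
#'   `comparisons` (data frame `pair`, `diff`, `p_adj`, `significant`).
#' @export
ros_corrected <- function(plate, alpha = 0.01) {
  required <- c("group", "replicate", "treated", "control")
  missing <- setdiff(required, names(plate))
  if (length(missing)) {
    stop("plate is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(plate$treated) || anyNA(plate$control)) {
    stop("unmatched wells: every replicate needs both a treated and a ",
         "control measurement", call. = FALSE)
  }
  reps <- table(plate$group)
  if (any(reps < 2)) {
    stop("every group needs >= 2 replicates", call. = FALSE)
  }
  corrected <- plate$treated - plate$control
  groups <- data.frame(
    group = names(tapply(corrected, plate$group, mean)),
    mean = as.numeric(tapply(corrected, plate$group, mean)),
    sd = as.numeric(tapply(corrected, plate$group, stats::sd)),
    n = as.integer(reps[names(tapply(corrected, plate$group, mean))]),
    stringsAsFactors = FALSE
  )
  comparisons <- NULL
  if (length(unique(plate$group)) >= 2) {
    fit <- stats::aov(corrected ~ group,
                      data = data.frame(corrected = corrected,
                                        group = factor(plate$group)))
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
    comparisons <- data.frame(
      pair = rownames(tk),
      diff = tk[, "diff"],
      p_adj = tk[, "p adj"],
      significant = tk[, "p adj"] < alpha,
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  }
  list(groups = groups, comparisons = comparisons, alpha = alpha)
}
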