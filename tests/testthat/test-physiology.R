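make_log <- function(n, d = 0.2976, od = 0.4, o2 = 100, attrs = list()) {
  log <- data.frame(time_h = (seq_len(n) - 1) / 60,
                    dilution_rate = rep(d, length.out = n),
                    od730 = rep(od, length.out = n),
                    dissolved_o2_uM = rep(o2, length.out = n),
                    offgas_o2 = 0.01, offgas_co2 = 0.04)
  for (a in names(attrs)) attr(log, a) <- attrs[[a]]
  log
}

test_that("a constant log is one full steady-state window", {
  log <- make_log(700)
  w <- detect_steady_state(log)
  expect_true(w$found)
  expect_equal(w$start, 1)
  expect_equal(w$n_rows, 700)
  expect_equal(w$min_rows, 604)   # floor(3 * 3.36 h * 60) at D = 0.2976
  expect_true(all(w$spread < 0.10))
})

test_that("a step change in OD is excluded from the trailing window", {
  log <- make_log(1400)
  log$od730[1:500] <- 0.8          # pre-step level
  w <- detect_steady_state(log)
  expect_true(w$found)
  expect_gt(w$start, 500)
  expect_equal(w$end, 1400)
})

test_that("logs shorter than three residence times yield no window", {
  log <- make_log(300)             # < 604 rows at tau = 3.36 h
  w <- detect_steady_state(log)
  expect_false(w$found)
  expect_match(w$reason, "3 residence times")
})

test_that("a zero-mean dissolved O2 channel passes only when identically zero", {
  log <- make_log(700, o2 = 0)
  expect_true(detect_steady_state(log)$found)
  log$dissolved_o2_uM[10] <- 1e-3
  w <- detect_steady_state(log)
  # the early blip is excluded; the trailing all-zero suffix qualifies
  expect_true(w$found)
  expect_gt(w$start, 10)
})

test_that("growth rate and doubling time follow the turbidostat identity", {
  log <- make_log(700, d = 0.289)
  gr <- growth_rate(log)
  expect_equal(gr$mu, 0.289, tolerance = 1e-12)
  expect_equal(gr$doubling_h, log(2) / 0.289, tolerance = 1e-12)
  expect_equal(round(gr$doubling_h, 1), 2.4)
  gr1 <- growth_rate(make_log(700, d = log(2)))
  expect_equal(gr1$doubling_h, 1.0, tolerance = 1e-12)
})

test_that("carbon-mole conversion uses the biomass formula weight", {
  gas <- gas_config()
  expect_equal(gas$grams_per_cmol,
               12.011 + 1.8 * 1.008 + 0.5 * 15.999 + 0.2 * 14.007,
               tolerance = 1e-12)
  expect_equal(cmol_rate(0.289, gas), 0.289 * 1000 / gas$grams_per_cmol,
               tolerance = 1e-12)
  expect_equal(cmol_rate(0.289, gas), 11.73, tolerance = 1e-3)
  expect_equal(cmol_rate(0, gas), 0)
  heavy <- gas_config(biomass_formula = c(C = 2, H = 3.6, O = 1, N = 0.4))
  expect_equal(cmol_rate(0.289, heavy), cmol_rate(0.289, gas) / 2,
               tolerance = 1e-12)
})

test_that("net O2 rate is zero without gradients and scales inversely with biomass", {
  attrs <- list(gas_flow_L_h = 30, volume_L = 5.5, biomass_g_L = 0.25,
                y_in = 0.01)
  log <- make_log(700, o2 = 0, attrs = attrs)
  log$offgas_o2 <- 0.01            # y_out = y_in, no dissolved term
  q <- net_o2_rate(log)
  expect_equal(q$q_o2, 0, tolerance = 1e-12)

  log2 <- make_log(700, o2 = 50, attrs = attrs)
  log2$offgas_o2 <- 0.02
  q1 <- net_o2_rate(log2)
  attrs2 <- attrs; attrs2$biomass_g_L <- 0.5
  log3 <- make_log(700, o2 = 50, attrs = attrs2)
  log3$offgas_o2 <- 0.02
  q2 <- net_o2_rate(log3)
  expect_equal(q2$q_o2, q1$q_o2 / 2, tolerance = 1e-12)
})

test_that("photosynthetic quotient fits exact lines exactly", {
  pq <- suppressWarnings(
    photosynthetic_quotient(c(0.5, 1.0, 1.5), c(1.0, 2.0, 3.0)))
  expect_equal(pq$slope, 2.0, tolerance = 1e-12)
  expect_equal(pq$se, 0, tolerance = 1e-10)
  expect_error(photosynthetic_quotient(c(1, 1), c(2, 2.5)), "degenerate")
  expect_error(photosynthetic_quotient(1, 2), ">= 2")
})

test_that("O2 sensitivity recovers constructed collinear points with zero SE", {
  fit <- suppressWarnings(
    o2_sensitivity(c(0, 0.30, 0.59), c(0.30, 0.2742, 0.24926)))
  expect_equal(fit$sensitivity, 0.086, tolerance = 1e-12)
  expect_equal(fit$se, 0, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.30, tolerance = 1e-12)
  flat <- suppressWarnings(o2_sensitivity(c(0, 0.3, 0.6), rep(0.2, 3)))
  expect_equal(flat$sensitivity, 0, tolerance = 1e-12)
  expect_error(o2_sensitivity(c(0.3, 0.3, 0.3), c(1, 2, 3)), "distinct")
})

test_that("sensitivity SE shrinks roughly as 1/sqrt(n) with replicated points", {
  ses <- vapply(c(3, 30, 300), function(n) {
    set.seed(42)
    po2 <- rep(c(0, 0.3, 0.59), length.out = n)
    mu <- 0.3 - 0.1 * po2 + rnorm(n, 0, 0.005)
    o2_sensitivity(po2, mu)$se
  }, numeric(1))
  expect_gt(ses[1] / ses[2], sqrt(10) * 0.4)
  expect_lt(ses[1] / ses[2], sqrt(10) * 2.5)
  expect_gt(ses[2] / ses[3], sqrt(10) * 0.4)
  expect_lt(ses[2] / ses[3], sqrt(10) * 2.5)
})

test_that("dissolved O2 conversions are linear and mutually consistent", {
  gas <- gas_config()
  expect_equal(dissolved_o2(0, gas), 0)
  expect_equal(percent_air_saturation(0, gas), 0)
  expect_equal(dissolved_o2(gas$atm_O2_fraction, gas), gas$air_sat_conc_uM)
  expect_equal(percent_air_saturation(gas$atm_O2_fraction, gas), 100)
  for (p in c(0.1, 0.3, 0.59, 0.8)) {
    expect_equal(dissolved_o2(p, gas) / percent_air_saturation(p, gas),
                 gas$air_sat_conc_uM / 100, tolerance = 1e-12)
  }
  expect_equal(percent_air_saturation(2 * 0.3, gas),
               2 * percent_air_saturation(0.3, gas), tolerance = 1e-12)
})

test_that("ROS correction subtracts controls and flags well-separated groups", {
  plate0 <- simulate_ros_plate(c(g1 = 1000, g2 = 1000), control_mean = 200,
                               sd = 0, n_reps = 3, seed = 1)
  res0 <- ros_corrected(plate0)
  expect_equal(res0$groups$mean, c(800, 800))
  expect_equal(res0$groups$sd, c(0, 0))

  # two identical groups: no significant pair at alpha 0.01 across seeds
  any_sig <- vapply(1:10, function(s) {
    plate <- simulate_ros_plate(c(g1 = 1000, g2 = 1000), 200, sd = 30,
                                n_reps = 3, seed = s)
    any(ros_corrected(plate)$comparisons$significant)
  }, logical(1))
  expect_lte(sum(any_sig), 1)

  # groups separated by ~10 pooled sds are flagged
  plate_sep <- simulate_ros_plate(c(lo = 800, hi = 1400), 200, sd = 40,
                                  n_reps = 3, seed = 2)
  res_sep <- ros_corrected(plate_sep)
  expect_true(all(res_sep$comparisons$significant))
})

test_that("unmatched ROS wells and tiny groups are rejected", {
  plate <- simulate_ros_plate(c(g1 = 1000, g2 = 1200), 200, sd = 10,
                              n_reps = 3, seed = 1)
  broken <- plate
  broken$control[2] <- NA
  expect_error(ros_corrected(broken), "unmatched|control")
  expect_error(simulate_ros_plate(c(g1 = 1000), 200, sd = 10, n_reps = 1),
               ">= 2")
  expect_error(simulate_ros_plate(c(g1 = -5), 200, sd = 10), ">= 0")
})
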