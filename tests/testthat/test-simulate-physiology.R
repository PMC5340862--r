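hl_ho <- function() {
  des <- default_design()
  des$conditions[des$conditions$label == "HL-HO", ]
}

test_that("noise-free logs carry the modeled dilution rate in every row", {
  params <- kinetics_params("binary", noise_rel = 0)
  log <- simulate_turbidostat(params, hl_ho(), duration_h = 20, seed = 1)
  expect_true(all(log$dilution_rate == 0.289 - 0.086 * 0.59))
  expect_equal(attr(log, "mu_model"), 0.289 - 0.086 * 0.59, tolerance = 1e-12)
  expect_equal(diff(log$time_h)[1] * 60, 1, tolerance = 1e-12)
})

test_that("the mean logged dilution rate stays within 0.5% of the model", {
  params <- kinetics_params("binary", noise_rel = 0.02)
  log <- simulate_turbidostat(params, hl_ho(), duration_h = 16, seed = 1)
  expect_gte(nrow(log), 604)
  expect_lt(abs(mean(log$dilution_rate) / attr(log, "mu_model") - 1), 0.005)
})

test_that("simulation demands three residence times and positive growth", {
  params <- kinetics_params("binary")
  expect_error(simulate_turbidostat(params, hl_ho(), duration_h = 5, seed = 1),
               "residence")
  hostile <- kinetics_params("binary", sensitivity = 1.0)
  expect_error(simulate_turbidostat(hostile, hl_ho(), duration_h = 50,
                                    seed = 1),
               "nonpositive")
})

test_that("turbidostat logs are reproducible under a fixed seed", {
  params <- kinetics_params("axenic")
  l1 <- simulate_turbidostat(params, hl_ho(), 16, seed = 4)
  l2 <- simulate_turbidostat(params, hl_ho(), 16, seed = 4)
  expect_identical(l1, l2)
})

test_that("noise-free simulator closure recovers mu and q_O2 to 1e-9", {
  des <- default_design()
  for (culture in c("axenic", "binary")) {
    params <- kinetics_params(culture, noise_rel = 0)
    for (lab in c("HL-LO", "HL-MO", "HL-HO")) {
      cnd <- des$conditions[des$conditions$label == lab, ]
      log <- simulate_turbidostat(params, cnd, duration_h = 40, seed = 1)
      w <- detect_steady_state(log)
      expect_true(w$found)
      gr <- growth_rate(log, w)
      expect_equal(gr$mu, attr(log, "mu_model"), tolerance = 1e-9)
      q <- net_o2_rate(log, params$gas, w)
      expect_equal(q$q_o2, attr(log, "q_o2_model"),
                   tolerance = 1e-9 * attr(log, "q_o2_model"))
    }
  }
})

test_that("noise-free steady states recover sensitivity and quotient to 1e-9", {
  des <- default_design()
  axes <- validate_design(des)
  for (culture in c("axenic", "binary")) {
    params <- kinetics_params(culture, noise_rel = 0)
    run <- function(lab) {
      cnd <- des$conditions[des$conditions$label == lab, ]
      log <- simulate_turbidostat(params, cnd, duration_h = 45, seed = 1)
      w <- detect_steady_state(log)
      gr <- growth_rate(log, w)
      q <- net_o2_rate(log, params$gas, w)
      c(mu = gr$mu, q = q$q_o2)
    }
    po2_pts <- vapply(axes$pO2$label, run, numeric(2))
    fit <- suppressWarnings(o2_sensitivity(axes$pO2$pO2, po2_pts["mu", ]))
    expect_equal(fit$sensitivity, params$sensitivity, tolerance = 1e-9)
    irr_pts <- vapply(axes$irradiance$label, run, numeric(2))
    pq <- suppressWarnings(photosynthetic_quotient(
      irr_pts["q", ], cmol_rate(irr_pts["mu", ], params$gas)))
    expect_equal(pq$slope, params$pq, tolerance = 1e-9)
  }
})

test_that("FACS events land on the configured fractions and are reproducible", {
  ev <- simulate_facs(facs_truth(), n_events = 50000, seed = 1)
  frac <- table(ev$label) / nrow(ev)
  expect_equal(unname(frac["cyanobacterium"]), 0.902, tolerance = 0.005)
  expect_equal(unname(frac["heterotroph"]), 0.091, tolerance = 0.005)
  expect_identical(ev, simulate_facs(facs_truth(), 50000, seed = 1))

  pure <- facs_truth(fractions = c(cyanobacterium = 1, heterotroph = 0,
                                   debris = 0))
  ev_pure <- simulate_facs(pure, 1000, seed = 1)
  expect_true(all(ev_pure$label == "cyanobacterium"))
  expect_error(facs_truth(fractions = c(cyanobacterium = 0.8,
                                        heterotroph = 0.1, debris = 0.2)),
               "sum to 1")
})

test_that("default gates agree with truth labels for nearly all events", {
  ev <- simulate_facs(facs_truth(), 50000, seed = 3)
  comp <- facs_composition(ev)
  correct <- !is.na(comp$assignment) &
    as.character(comp$assignment) == ev$label
  expect_gte(mean(correct), 0.999)
  expect_equal(sum(comp$counts) + comp$ungated_percent / 100 * comp$n_events,
               comp$n_events, tolerance = 1e-9)
})

test_that("gating rejects overlapping gates and handles single-gate input", {
  ev <- simulate_facs(facs_truth(), 1000, seed = 1)
  gates <- default_facs_gates()
  bad <- gates
  bad$heterotroph$fsc <- c(0, 200)
  bad$heterotroph$ssc <- c(0, 200)
  expect_error(facs_composition(ev, bad), "overlap")
  one <- facs_composition(ev, list(everything = list(fsc = c(-1e6, 1e6),
                                                     ssc = c(-1e6, 1e6))))
  expect_equal(unname(one$percent["everything"]), 100)
  expect_equal(one$ungated_percent, 0)
})

test_that("ROS plates have the configured layout and are reproducible", {
  plate <- simulate_ros_plate(c(a = 900, b = 1100), control_mean = 200,
                              sd = 25, n_reps = 3, seed = 9)
  expect_equal(nrow(plate), 6)
  expect_equal(as.integer(table(plate$group)), c(3L, 3L))
  expect_identical(plate,
                   simulate_ros_plate(c(a = 900, b = 1100), 200, 25, 3,
                                      seed = 9))
})
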