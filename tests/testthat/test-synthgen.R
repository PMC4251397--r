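test_that("pulse_spec rejects infeasible layouts", {
  expect_error(pulse_spec(880, 0), "sp_time")
  expect_error(pulse_spec(880, 220, pi_time = 220, pi_amp = 0.9), "inflection")
  expect_error(pulse_spec(880, 220, pi_time = 226, pi_amp = 0.9), "inflection")
  expect_error(pulse_spec(880, 220, pi_time = 119, pi_amp = 0.9,
                          true_aix = -10), "sign")
  expect_error(pulse_spec(880, 220, dw_time = 100), "dw_time")
})

test_that("the sign of the augmentation index encodes the Pi/SP order", {
  a <- pulse_spec(880, 220, pi_time = 119, pi_amp = 0.905)
  expect_equal(a$pi_order, "before_sp")
  expect_equal(a$true_aix, 9.5)
  c_ <- pulse_spec(880, 145, pi_time = 200, pi_amp = 0.80)
  expect_equal(c_$pi_order, "after_sp")
  expect_equal(c_$true_aix, -20)
})

test_that("a pulse without reflected and dicrotic components yields SP only", {
  g <- generate_pulse(pulse_spec(880, 220, noise_sd = 0), seed = 1)
  o <- g$truth$oracle
  expect_lt(abs(o$sp_time - 220), 2)
  expect_true(is.na(o$pi_time))
  expect_true(is.na(o$dw_time))
  expect_setequal(o$missing_flags, c("pi", "dw"))
})

test_that("generation without noise is deterministic across seeds", {
  s <- spec_type_c()
  g1 <- generate_pulse(s, seed = 1)
  g2 <- generate_pulse(s, seed = 99)
  expect_identical(g1$samples, g2$samples)
})

test_that("calibration places the oracle fiducials on the spec targets", {
  for (s in list(spec_type_c(), spec_type_a())) {
    cal <- calibrate_component_timing(s, strict = FALSE)
    expect_true(cal$converged)
    o <- cal$oracle
    expect_lt(abs(o$sp_time - s$sp_time), 2.5)
    expect_lt(abs(o$pi_time - s$pi_time), 2.5)
    expect_lt(abs(o$pi_amp - s$pi_amp), 0.016)
    expect_lt(abs(o$dw_time - s$dw_time), 3.5)
  }
})

test_that("adjusting the dicrotic component leaves the systolic peak fixed", {
  s1 <- pulse_spec(880, 145, pi_time = 200, pi_amp = 0.80,
                   dw_time = 280, dw_amp = 0.40, noise_sd = 0)
  s2 <- pulse_spec(880, 145, pi_time = 200, pi_amp = 0.80,
                   dw_time = 310, dw_amp = 0.40, noise_sd = 0)
  o1 <- calibrate_component_timing(s1, strict = FALSE)$oracle
  o2 <- calibrate_component_timing(s2, strict = FALSE)$oracle
  expect_lt(abs(o1$sp_time - o2$sp_time), 3)
})

test_that("the oracle classifies calibrated pulses by reflected-wave order", {
  oa <- calibrate_component_timing(spec_type_a(), strict = FALSE)$oracle
  expect_equal(oa$pi_order, "before_sp")
  expect_lt(oa$pi_time, oa$sp_time)
  oc <- calibrate_component_timing(spec_type_c(), strict = FALSE)$oracle
  expect_equal(oc$pi_order, "after_sp")
  expect_gt(oc$pi_time, oc$sp_time)
})

test_that("the oracle shares no helpers with the production detector", {
  body_txt <- paste(deparse(body(oracle_fiducials)), collapse = " ")
  for (banned in c("detect_sp", "detect_pi", "detect_dw", "sg_deriv",
                   "post_sp_events", "moving_average", "sgolayfilt"))
    expect_false(grepl(banned, body_txt, fixed = TRUE), label = banned)
})

test_that("sampled cohort fiducial times reproduce the configured means", {
  coh <- fixture_cohorts()
  set.seed(7)
  for (g in coh[c("groupI", "groupII")]) {
    p <- apwkit:::sample_pulse_params(g, 4000)
    for (fld in c("sp_time", "pi_time", "dw_time")) {
      tgt <- g[[paste0(sub("_time", "", fld), "_time_dist")]]
      tol <- 3 * sd(p[[fld]]) / sqrt(nrow(p)) + 1
      expect_lt(abs(mean(p[[fld]]) - tgt[1]), tol,
                label = paste(g$name, fld))
    }
    expect_lt(abs(mean(p$true_aix) - g$aix_dist[1]),
              3 * sd(p$true_aix) / sqrt(nrow(p)) + 0.3)
    # per-pulse sign consistency with the Pi/SP order
    expect_true(all((p$true_aix >= 0) == (p$pi_time < p$sp_time)))
  }
})

test_that("identical cohort and seed give bit-identical recordings", {
  g <- fixture_cohorts()$groupI
  r1 <- generate_recording(g, "S", n_pulses = 5, seed = 3)
  r2 <- generate_recording(g, "S", n_pulses = 5, seed = 3)
  expect_identical(r1$record$samples, r2$record$samples)
  expect_identical(r1$truth, r2$truth)
})

test_that("a single-pulse recording is one generated pulse plus disturbances", {
  g <- fixture_cohorts()$groupII
  g$noise_sd <- 0
  g$drift$amplitude <- 0
  r <- generate_recording(g, "S", n_pulses = 1, seed = 5)
  expect_equal(nrow(r$truth), 1)
  expect_equal(length(r$record$samples), r$truth$period_T[1])
  # the emitted samples are a normalized noiseless beat
  expect_equal(min(r$record$samples), 0, tolerance = 1e-9)
  expect_equal(max(r$record$samples), 1, tolerance = 1e-9)
})

test_that("cohort specs reject degenerate configurations", {
  expect_error(cohort_spec("x", c(200, 0), c(100, 10), c(300, 10),
                           c(10, 5), c(60, 5)), "sd > 0")
  expect_error(cohort_spec("x", c(2000, 10), c(100, 10), c(300, 10),
                           c(10, 5), c(60, 5)), "outside")
})
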