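noiseless_pulse <- function(spec) {
  as_pulse(generate_pulse(spec, strict = FALSE)$samples)
}

test_that("the systolic peak is the global maximum, earliest on ties", {
  p <- noiseless_pulse(spec_type_c())
  sp <- detect_sp(p)
  expect_lt(abs(sp$sp_time - 145), 3)
  expect_gt(sp$sp_amp, 0.98)

  plateau <- as_pulse(c(rep(0, 50), seq(0, 1, length.out = 100),
                        rep(1, 40), seq(1, 0, length.out = 100), rep(0, 50)))
  sp2 <- detect_sp(plateau)
  # ties across the flat top resolve to the earliest smoothed maximum
  expect_lt(sp2$sp_time, 160)
})

test_that("detection matches the oracle on noiseless calibrated pulses", {
  for (mk in list(spec_type_a, spec_type_c)) {
    s <- mk()
    cal <- calibrate_component_timing(s, strict = FALSE)
    p <- as_pulse(generate_pulse(s, strict = FALSE)$samples)
    f <- detect_fiducials(p)
    o <- cal$oracle
    expect_lt(abs(f$sp_time - o$sp_time), 5)
    expect_equal(f$pi_order, o$pi_order)
    expect_lt(abs(f$pi_time - o$pi_time), 10)
    expect_lt(abs(f$pi_amp - o$pi_amp), 0.02)
    expect_lt(abs(f$dw_time - o$dw_time), 10)
  }
})

test_that("a single-component pulse has no inflection or dicrotic wave", {
  p <- noiseless_pulse(pulse_spec(880, 220, noise_sd = 0))
  f <- detect_fiducials(p)
  expect_equal(f$pi_order, "missing")
  expect_true(is.na(f$pi_time))
  expect_true(is.na(f$dw_time))
  expect_setequal(f$missing_flags, c("pi", "dw"))
})

test_that("pi_order is always consistent with the time ordering", {
  coh <- fixture_cohorts()
  set.seed(11)
  for (g in coh[c("groupI", "groupII")]) {
    seg <- segmented_subject(g, 30, seed = 21)
    for (p in seg$pulses) {
      if (p$anomalous) next
      f <- detect_fiducials(p)
      if (is.na(f$pi_time)) {
        expect_equal(f$pi_order, "missing")
      } else if (f$pi_order == "before_sp") {
        expect_lt(f$pi_time, f$sp_time)
      } else {
        expect_gt(f$pi_time, f$sp_time)
      }
      if (!is.na(f$dw_time)) expect_gt(f$dw_time, f$sp_time)
    }
  }
})

test_that("strengthening the reflected wave never loses a detected Pi", {
  # missingness monotonicity on noiseless input
  found <- vapply(c(0.65, 0.75, 0.85), function(amp) {
    s <- pulse_spec(880, 145, pi_time = 205, pi_amp = amp,
                    dw_time = 300, dw_amp = 0.40, noise_sd = 0)
    !is.na(detect_fiducials(noiseless_pulse(s))$pi_time)
  }, TRUE)
  expect_true(all(diff(found) >= 0))
  expect_true(found[3])
})

test_that("most noisy beats stay within 15 ms of their oracle landmarks", {
  coh <- fixture_cohorts()
  set.seed(12)
  hits <- c(); total <- 0
  for (g in coh[c("groupI", "groupII")]) {
    pars <- apwkit:::sample_pulse_params(g, 40)
    for (i in seq_len(nrow(pars))) {
      pp <- pars[i, ]
      s <- try(pulse_spec(pp$period_T, pp$sp_time, pp$pi_time, pp$pi_amp,
                          pp$dw_time, pp$dw_amp, noise_sd = 0), silent = TRUE)
      if (inherits(s, "try-error")) next
      cal <- apwkit:::calibrate_pulse(s)
      x <- cal$samples + rnorm(length(cal$samples), 0, 0.01)
      f <- detect_fiducials(as_pulse((x - min(x)) / (max(x) - min(x))))
      o <- cal$oracle
      total <- total + 1
      hits <- c(hits, abs(f$sp_time - o$sp_time) <= 15,
                if (!is.na(o$pi_time) && !is.na(f$pi_time) &&
                      f$pi_order == o$pi_order)
                  abs(f$pi_time - o$pi_time) <= 15)
    }
  }
  expect_gt(mean(hits), 0.9)
})

test_that("a monotone-decay diastole yields a missing dicrotic wave", {
  t <- 0:699
  x <- exp(-((t - 150)^2) / (2 * 45^2))   # single bump, pure decay after
  f <- detect_fiducials(as_pulse(x))
  expect_true(is.na(f$dw_time))
})
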