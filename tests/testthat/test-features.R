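fid_stub <- function(sp_t = 220, sp_a = 1, pi_t = NA, pi_a = NA,
                     pi_order = "missing", dw_t = NA, dw_a = NA) {
  structure(list(sp_time = sp_t, sp_amp = sp_a, pi_time = pi_t,
                 pi_amp = pi_a, pi_order = pi_order, dw_time = dw_t,
                 dw_amp = dw_a, missing_flags = character(0)),
            class = "apw_fiducials")
}

test_that("intervals subtract from the beat period and reject inconsistency", {
  iv <- compute_intervals(fid_stub(sp_t = 220), period_T = 880)
  expect_equal(iv$ds_t, 660)
  expect_true(is.na(iv$pi_t))
  expect_error(compute_intervals(fid_stub(sp_t = 900), period_T = 880),
               "period_T")
})

test_that("the six ratios follow their defining formulas", {
  iv <- compute_intervals(fid_stub(sp_t = 220, pi_t = 119, pi_a = 0.85,
                                   pi_order = "before_sp",
                                   dw_t = 313, dw_a = 0.4), 880)
  rt <- compute_ratios(iv, 880)
  expect_equal(rt$r1, 0.25)
  expect_equal(signif(rt$r2, 3), -0.106)   # negative: DW after SP
  expect_equal(rt$r3, 660 / 220)
  expect_equal(rt$r4, 0.4)
  expect_equal(rt$r5, 0.15)
  expect_equal(rt$r6, 0.85)
})

test_that("missing operands propagate missing ratios", {
  iv <- compute_intervals(fid_stub(sp_t = 220), 880)
  rt <- compute_ratios(iv, 880)
  expect_true(is.na(rt$r2) && is.na(rt$r4) && is.na(rt$r5) && is.na(rt$r6))
  expect_false(is.na(rt$r1))
})

test_that("the augmentation index keeps its sign convention", {
  expect_equal(compute_aix(1.0, 0.85, "before_sp"), 15)
  expect_equal(compute_aix(1.0, 0.80, "after_sp"), -20)
  expect_equal(compute_aix(1.0, 1.0, "before_sp"), 0)
  expect_equal(compute_aix(1.0, 1.0, "after_sp"), 0)
  expect_true(is.na(compute_aix(1.0, NA, "missing")))
})

test_that("RMSSD matches hand values and a naive loop", {
  expect_equal(compute_rmssd(c(1, 2, 3)), 1)
  expect_equal(compute_rmssd(rep(4.2, 50)), 0)
  expect_error(compute_rmssd(3), "at least 2")
  set.seed(3)
  x <- rnorm(1000)
  naive <- sqrt(sum((x[-1] - x[-1000])^2) / 999)
  expect_equal(compute_rmssd(x), naive, tolerance = 1e-12)
})

test_that("RMSE has its closed-form behavior", {
  x <- runif(300)
  expect_equal(compute_rmse(x, x), 0)
  expect_equal(compute_rmse(x + 0.1, x), 0.1)
  expect_error(compute_rmse(x, x[-1]), "length")
})

test_that("FWHM matches analytic widths", {
  t <- 0:999
  gauss <- exp(-((t - 500)^2) / (2 * 40^2))
  expect_equal(compute_fwhm(as_pulse(gauss)), 2 * sqrt(2 * log(2)) * 40,
               tolerance = 1)
  tri <- c(seq(0, 1, length.out = 101), seq(1, 0, length.out = 101)[-1])
  expect_equal(compute_fwhm(as_pulse(tri)), 100, tolerance = 1.5)
  # brute-force scan over half-height crossings on an asymmetric pulse
  asym <- exp(-((t - 300)^2) / (2 * ifelse(t < 300, 30, 80)^2))
  half <- 0.5
  above <- which(asym >= half)
  brute <- max(above) - min(above)
  expect_equal(compute_fwhm(as_pulse(asym)), brute, tolerance = 2)
})

test_that("feature tables carry one row per usable pulse", {
  tab <- fixture_feature_table()
  expect_s3_class(tab, "apw_feature_table")
  expect_true(all(c(selected_feature_names(), "class", "subject")
                  %in% names(tab)))
  expect_setequal(unique(tab$class), c(1L, 2L))
  # canonical order: the selected attribute list leads the table
  expect_identical(names(tab)[1:12], selected_feature_names())
})

test_that("the augmentation index is numerically tied to R5", {
  tab <- fixture_feature_table()
  with_pi <- tab[tab$pi_t > 0, ]
  expect_true(all(abs(abs(with_pi$aix) / 100 - with_pi$r5) < 1e-9))
})

test_that("missing fiducials become zeros only under paper parity", {
  p_missing <- noiseless <- generate_pulse(pulse_spec(880, 220, noise_sd = 0),
                                           strict = FALSE)$samples
  pulses <- c(lapply(1:5, function(i) as_pulse(noiseless)),
              list(as_pulse(noiseless)))
  seg <- list(list(pulses = pulses, label = 1L, subject = "S"))
  parity <- build_feature_table(seg, paper_parity = TRUE, block_size = Inf)
  expect_true(all(parity$pi_t == 0))
  expect_true(all(parity$aix == 0))
  explicit <- build_feature_table(seg, paper_parity = FALSE, block_size = Inf)
  expect_true(all(is.na(explicit$pi_t)))
  expect_equal(nrow(explicit), 6)
})

test_that("mean absolute recovery error is small on noiseless cohorts", {
  g <- fixture_cohorts()$groupII
  g$noise_sd <- 0
  g$drift$amplitude <- 0
  err_sp <- c(); err_pi <- c(); err_aix <- c()
  for (s in 1:2) {
    r <- generate_recording(g, "S", n_pulses = 25, seed = 60 + s)
    rec <- remove_baseline(r$record)
    for (p in flag_anomalous(segment_pulses(rec))) {
      if (p$anomalous) next
      j <- which.min(abs(r$truth$onset - p$onset_index))
      if (abs(r$truth$onset[j] - p$onset_index) > 20) next
      f <- detect_fiducials(normalize_pulse(p))
      off <- p$onset_index - r$truth$onset[j]
      err_sp <- c(err_sp, f$sp_time + off - r$truth$sp_time[j])
      if (!is.na(f$pi_time) && !is.na(r$truth$pi_time[j]) &&
            f$pi_order == r$truth$pi_order[j]) {
        err_pi <- c(err_pi, f$pi_time + off - r$truth$pi_time[j])
        aix <- compute_aix(f$sp_amp, f$pi_amp, f$pi_order)
        err_aix <- c(err_aix, aix - r$truth$true_aix[j])
      }
    }
  }
  expect_lt(mean(abs(err_sp)), 5)
  expect_lt(mean(abs(err_pi)), 10)
  expect_lt(mean(abs(err_aix)), 3)
})
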