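make_clean_cohort <- function(base) {
  base$noise_sd <- 0
  base$drift <- list(amplitude = 0, period_s = 4)
  base
}

test_that("baseline removal is near-identity on a clean record", {
  g <- make_clean_cohort(fixture_cohorts()$groupII)
  r <- generate_recording(g, "S", n_pulses = 12, seed = 2)
  out <- remove_baseline(r$record)
  # the remover legitimately subtracts the ~1% foot level of the composite;
  # anything beyond 2% of pulse height would indicate real distortion
  expect_lt(max(abs(out$samples - r$record$samples)), 0.02)
})

test_that("baseline removal flattens an injected linear ramp", {
  g <- make_clean_cohort(fixture_cohorts()$groupII)
  r <- generate_recording(g, "S", n_pulses = 28, seed = 3)
  n <- length(r$record$samples)
  ramped <- r$record
  ramped$samples <- ramped$samples + seq(0, 0.5, length.out = n)
  out <- remove_baseline(ramped)
  # the corrected signal's own feet sit on the zero level
  feet <- vapply(segment_pulses(out), function(p) p$onset_index + 1L, 1L)
  feet <- feet[feet > 2000 & feet < n - 2000]
  expect_lt(stats::median(abs(out$samples[feet])), 0.012)
  expect_lt(as.numeric(quantile(abs(out$samples[feet]), 0.9)), 0.03)
})

test_that("baseline removal suppresses sinusoidal drift at the pulse feet", {
  g <- fixture_cohorts()$groupII
  g$noise_sd <- 0          # keep only the sinusoidal baseline
  r <- generate_recording(g, "S", n_pulses = 28, seed = 4)
  out <- remove_baseline(r$record)
  feet <- vapply(segment_pulses(out), function(p) p$onset_index + 1L, 1L)
  feet <- feet[feet > 1000 & feet < length(out$samples) - 1000]
  rms_before <- sqrt(mean(r$record$samples[feet]^2))
  rms_after <- sqrt(mean(out$samples[feet]^2))
  expect_lt(rms_after * 10, rms_before)
})

test_that("baseline removal is idempotent within tolerance", {
  g <- fixture_cohorts()$groupI
  r <- generate_recording(g, "S", n_pulses = 15, seed = 5)
  once <- remove_baseline(r$record)
  twice <- remove_baseline(once)
  expect_lt(max(abs(twice$samples - once$samples)), 0.05)
})

test_that("short signals are rejected", {
  expect_error(remove_baseline(apw_record(rnorm(500))), "2 s")
  expect_error(segment_pulses(apw_record(rnorm(500))), "2 s")
})

test_that("a constant signal yields no pulses", {
  expect_warning(p <- segment_pulses(apw_record(rep(0.5, 5000))), "upstrokes")
  expect_length(p, 0)
})

test_that("segmentation recovers the generated beat onsets", {
  g <- make_clean_cohort(fixture_cohorts()$groupII)
  r <- generate_recording(g, "S", n_pulses = 20, seed = 6)
  rec <- remove_baseline(r$record)
  pulses <- segment_pulses(rec)
  expect_gte(length(pulses), 17)
  offs <- vapply(pulses, function(p) {
    min(abs(r$truth$onset - p$onset_index))
  }, 0)
  expect_lt(stats::median(offs), 5)
  expect_gt(mean(offs <= 5), 0.85)
})

test_that("with default noise most onsets stay within 10 ms of truth", {
  g <- fixture_cohorts()$groupII
  r <- generate_recording(g, "S", n_pulses = 25, seed = 7)
  rec <- remove_baseline(r$record)
  pulses <- segment_pulses(rec)
  offs <- vapply(pulses, function(p) min(abs(r$truth$onset - p$onset_index)), 0)
  expect_gt(mean(offs <= 10), 0.75)
})

test_that("segmented pulses partition the corrected signal", {
  g <- fixture_cohorts()$groupI
  r <- generate_recording(g, "S", n_pulses = 12, seed = 8)
  rec <- remove_baseline(r$record)
  pulses <- segment_pulses(rec)
  joined <- unlist(lapply(pulses, function(p) p$samples))
  first <- pulses[[1]]$onset_index + 1
  expect_identical(joined,
                   rec$samples[first:(first + length(joined) - 1)])
})

test_that("segmentation of a noiseless record is deterministic", {
  g <- make_clean_cohort(fixture_cohorts()$groupII)
  r <- generate_recording(g, "S", n_pulses = 10, seed = 9)
  rec <- remove_baseline(r$record)
  o1 <- vapply(segment_pulses(rec), function(p) p$onset_index, 1L)
  o2 <- vapply(segment_pulses(rec), function(p) p$onset_index, 1L)
  expect_identical(o1, o2)
})

test_that("anomaly flagging marks width and amplitude outliers only", {
  g <- make_clean_cohort(fixture_cohorts()$groupII)
  r <- generate_recording(g, "S", n_pulses = 20, seed = 10)
  rec <- remove_baseline(r$record)
  pulses <- segment_pulses(rec)
  clean <- flag_anomalous(pulses)
  expect_false(any(vapply(clean, function(p) p$anomalous, TRUE)))

  wide <- pulses
  wide[[5]]$period_T <- wide[[5]]$period_T * 2
  flagged <- flag_anomalous(wide)
  expect_true(flagged[[5]]$anomalous)
  expect_match(flagged[[5]]$anomaly_reason, "width")
  expect_equal(sum(vapply(flagged, function(p) p$anomalous, TRUE)), 1)

  dim_ <- pulses
  dim_[[3]]$samples <- dim_[[3]]$samples * 0.2
  flagged2 <- flag_anomalous(dim_)
  expect_true(flagged2[[3]]$anomalous)
  expect_match(flagged2[[3]]$anomaly_reason, "amplitude")
})

test_that("too few pulses skip anomaly flagging with a warning", {
  p <- list(as_pulse(c(0, 1, 0)))
  expect_warning(out <- flag_anomalous(p), "fewer than 5")
  expect_false(out[[1]]$anomalous)
})

test_that("normalization is an idempotent affine map onto [0, 1]", {
  p <- as_pulse(seq(2, 6, length.out = 100))
  n1 <- normalize_pulse(p)
  expect_equal(range(n1$samples), c(0, 1))
  n2 <- normalize_pulse(n1)
  expect_identical(n1$samples, n2$samples)
  expect_error(normalize_pulse(as_pulse(rep(1, 50))), "flat")
})
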