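# Shared fixtures: representative pulse specs, a memoized calibrated cohort
# list, and lazily built detection corpora reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture_cohorts <- function() {
  if (is.null(.fixtures$cohorts)) .fixtures$cohorts <- default_cohorts()
  .fixtures$cohorts
}

# a clean type-C spec (healthy-like) and a type-A spec (stiffness-like)
spec_type_c <- function(noise_sd = 0) {
  pulse_spec(880, 145, pi_time = 200, pi_amp = 0.80,
             dw_time = 292, dw_amp = 0.40, noise_sd = noise_sd)
}
spec_type_a <- function(noise_sd = 0) {
  pulse_spec(880, 220, pi_time = 119, pi_amp = 0.905,
             dw_time = 313, dw_amp = 0.40, noise_sd = noise_sd)
}

as_pulse <- function(samples) {
  structure(list(samples = samples, onset_index = 0L,
                 period_T = length(samples), pulse_index = 1L,
                 anomalous = FALSE, anomaly_reason = NA_character_),
            class = "apw_pulse")
}

# one subject's segmented, flagged, normalized pulses
segmented_subject <- function(cohort, n_pulses = 40, seed = 1) {
  r <- generate_recording(cohort, "S", n_pulses = n_pulses, seed = seed)
  rec <- remove_baseline(r$record)
  pulses <- flag_anomalous(segment_pulses(rec))
  pulses <- lapply(pulses, function(p)
    if (p$anomalous) p else normalize_pulse(p))
  list(pulses = pulses, truth = r$truth, record = rec)
}

# small labeled feature table over both training cohorts (memoized)
fixture_feature_table <- function() {
  if (is.null(.fixtures$feature_table)) {
    coh <- fixture_cohorts()
    segs <- list()
    for (i in 1:3) {
      s1 <- segmented_subject(coh$groupI, 40, seed = 10 + i)
      segs[[length(segs) + 1]] <- list(pulses = s1$pulses, label = 1L,
                                       subject = paste0("g1_", i))
      s2 <- segmented_subject(coh$groupII, 40, seed = 40 + i)
      segs[[length(segs) + 1]] <- list(pulses = s2$pulses, label = 2L,
                                       subject = paste0("g2_", i))
    }
    .fixtures$feature_table <- build_feature_table(segs)
  }
  .fixtures$feature_table
}

# a tiny linearly separable two-feature table
separable_table <- function(n = 40, seed = 1) {
  set.seed(seed)
  d <- data.frame(
    f1 = c(rnorm(n, 0, 0.5), rnorm(n, 5, 0.5)),
    f2 = c(rnorm(n, 2, 0.5), rnorm(n, -2, 0.5)),
    class = rep(c(1L, 2L), each = n))
  class(d) <- c("apw_feature_table", "data.frame")
  d
}
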