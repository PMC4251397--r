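# Detection-recovery evaluation: generate a cohort corpus, run the full
# preprocessing and detection chain, and collect per-pulse detected
# quantities. Used by the acceptance machinery and by simulation studies.

#' Run the detection pipeline over a simulated cohort corpus
#'
#' Generates approximately `n_pulses` beats as multi-subject recordings,
#' removes the baseline, segments and flags beats, and detects the three
#' prominent points on every non-anomalous beat. The per-pulse true AIx is
#' drawn per beat (no subject-level component) so that the pooled detected
#' statistics can be compared directly against cohort-level targets.
#'
#' @param cohort A [cohort_spec()] (calibrated on the fly if needed).
#' @param n_pulses Total number of beats to generate.
#' @param seed Integer master seed.
#' @param pulses_per_subject Beats per simulated recording.
#' @param per_pulse_aix Draw the true AIx independently per beat (default)
#'   instead of splitting its variance across subjects.
#' @return List with `detections` (data frame: `sp_t`, `pi_t`, `pi_order`,
#'   `pi_a`, `sp_a`, `dw_t`, `aix` per usable beat) and `segments` (the
#'   normalized pulse lists, one entry per subject, for feature building).
#' @export
evaluate_detection <- function(cohort, n_pulses = 2000, seed = 1L,
                               pulses_per_subject = 20,
                               per_pulse_aix = TRUE) {
  stopifnot(inherits(cohort, "apw_cohort_spec"))
  if (per_pulse_aix) cohort$subject_aix_frac <- 0
  if (is.null(cohort$loc)) cohort <- calibrate_cohort(cohort)
  n_subj <- ceiling(n_pulses / pulses_per_subject)
  rows <- list(); segments <- list()
  for (i in seq_len(n_subj)) {
    sseed <- (as.numeric(seed) * 7919 + i * 104729) %% 2147483587
    r <- generate_recording(cohort, paste0(cohort$name, "_S", i),
                            n_pulses = pulses_per_subject,
                            seed = as.integer(sseed))
    rec <- remove_baseline(r$record)
    pulses <- flag_anomalous(segment_pulses(rec))
    pulses <- lapply(pulses, function(p)
      if (p$anomalous) p else normalize_pulse(p))
    segments[[i]] <- list(pulses = pulses,
                          subject = r$record$meta$id)
    for (p in pulses) {
      if (p$anomalous) next
      f <- detect_fiducials(p)
      rows[[length(rows) + 1]] <- data.frame(
        subject = r$record$meta$id,
        sp_t = f$sp_time, sp_a = f$sp_amp,
        pi_t = f$pi_time, pi_a = f$pi_amp, pi_order = f$pi_order,
        dw_t = f$dw_time, dw_a = f$dw_amp,
        aix = compute_aix(f$sp_amp, f$pi_amp, f$pi_order))
    }
  }
  list(detections = do.call(rbind, rows), segments = segments)
}

#' Summarize detection recovery against cohort targets
#'
#' @param detections Data frame from [evaluate_detection()].
#' @return Named list of means (`sp_t`, `pi_t`, `dw_t`, `aix`), standard
#'   errors, and detection rates.
#' @export
summarize_detection <- function(detections) {
  d <- detections
  pi_ok <- !is.na(d$pi_t)
  dw_ok <- !is.na(d$dw_t)
  aix_ok <- !is.na(d$aix)
  list(
    n = nrow(d),
    sp_mean = mean(d$sp_t), sp_se = sd(d$sp_t) / sqrt(nrow(d)),
    pi_mean = mean(d$pi_t[pi_ok]),
    pi_se = sd(d$pi_t[pi_ok]) / sqrt(sum(pi_ok)),
    pi_rate = mean(pi_ok),
    dw_mean = mean(d$dw_t[dw_ok]),
    dw_se = sd(d$dw_t[dw_ok]) / sqrt(sum(dw_ok)),
    dw_rate = mean(dw_ok),
    aix_mean = mean(d$aix[aix_ok]),
    aix_se = sd(d$aix[aix_ok]) / sqrt(sum(aix_ok)))
}
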