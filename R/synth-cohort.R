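# ---- truncated normal helpers ----------------------------------------------

#' @noRd
qtnorm <- function(u, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  clamp(qnorm(plo + u * (phi - plo), mean, sd), lo, hi)
}

#' @noRd
rtnorm <- function(n, mean, sd, lo, hi) qtnorm(runif(n), mean, sd, lo, hi)

# ---- CohortSpec -------------------------------------------------------------

#' Specification of a synthetic study cohort
#'
#' A `cohort_spec` holds the target pooled distributions of the fiducial
#' arrival times (systolic peak SP_t, inflection point Pi_t, dicrotic wave
#' DW_t), the signed augmentation index (AIx), and heart rate, together with
#' the cohort size. Arrival times and AIx are given as `c(mean, sd)` in ms
#' and percent respectively.
#'
#' Each sampled pulse keeps the sign of its augmentation index consistent with
#' its Pi/SP order (type A: Pi before SP, AIx >= 0; type C: after, AIx < 0),
#' which makes every cohort a two-type mixture. [calibrate_cohort()] solves
#' the majority-type Pi location so the pooled mean of the sampled Pi times
#' reproduces `pi_time_dist[1]` exactly; pooled SDs come out slightly wider
#' than the nominal values (see the methods vignette).
#'
#' @param name Cohort label, e.g. `"groupI"`.
#' @param sp_time_dist,pi_time_dist,dw_time_dist Numeric `c(mean, sd)` in ms.
#' @param aix_dist Numeric `c(mean, sd)` in percent; the mean's sign selects
#'   the majority pulse type.
#' @param hr_dist Numeric `c(mean, sd)` in beats/min.
#' @param n_subjects,pulses_per_subject Cohort size defaults.
#' @param dw_amp_dist Normalized dicrotic amplitude `c(mean, sd)`.
#' @param noise_sd White-noise standard deviation (normalized units).
#' @param drift Baseline drift description: `amplitude` (normalized units,
#'   at most ~0.3 of pulse height) and `period_s` (seconds).
#' @param subject_aix_frac Fraction of the AIx variance placed between
#'   subjects (the remainder is within-subject), preserving pooled moments.
#' @return An object of class `apw_cohort_spec`.
#' @export
cohort_spec <- function(name, sp_time_dist, pi_time_dist, dw_time_dist,
                        aix_dist, hr_dist, n_subjects = 20,
                        pulses_per_subject = 100,
                        dw_amp_dist = c(0.40, 0.07), noise_sd = 0.01,
                        drift = list(amplitude = 0.15, period_s = 4),
                        subject_aix_frac = 0.5) {
  dists <- list(sp_time = sp_time_dist, pi_time = pi_time_dist,
                dw_time = dw_time_dist, aix = aix_dist, hr = hr_dist,
                dw_amp = dw_amp_dist)
  for (nm in names(dists)) {
    d <- dists[[nm]]
    if (length(d) != 2 || !is.numeric(d) || d[2] <= 0)
      stop("config error: ", nm, "_dist must be c(mean, sd) with sd > 0")
  }
  mean_T <- 60000 / hr_dist[1]
  for (nm in c("sp_time", "pi_time", "dw_time")) {
    if (dists[[nm]][1] <= 0 || dists[[nm]][1] >= mean_T)
      stop("config error: mean ", nm, " outside (0, T) for the cohort heart rate")
  }
  structure(list(name = name, sp_time_dist = sp_time_dist,
                 pi_time_dist = pi_time_dist, dw_time_dist = dw_time_dist,
                 aix_dist = aix_dist, hr_dist = hr_dist,
                 n_subjects = n_subjects,
                 pulses_per_subject = pulses_per_subject,
                 dw_amp_dist = dw_amp_dist, noise_sd = noise_sd,
                 drift = drift, subject_aix_frac = subject_aix_frac,
                 loc = NULL),
            class = "apw_cohort_spec")
}

#' Default study cohorts
#'
#' Three cohorts emulating a carotid-pressure study population: group I
#' (hypertensive, predominantly type-A pulses with elevated AIx), group II
#' (healthy, predominantly type C with negative AIx), and group III (young
#' subjects with type-A-like waveforms, used for validation). Arrival-time
#' and AIx distributions follow the published cohort statistics; group III
#' shares group I's timing mixture and has its own AIx distribution.
#'
#' @param calibrated Solve each cohort's majority-type Pi location on the way
#'   out (see [calibrate_cohort()]).
#' @return Named list of [cohort_spec()] objects.
#' @export
default_cohorts <- function(calibrated = TRUE) {
  g1 <- cohort_spec("groupI",
                    sp_time_dist = c(219.99, 51.03),
                    pi_time_dist = c(118.94, 39.95),
                    dw_time_dist = c(313.52, 55.00),
                    aix_dist = c(9.57, 15.20),
                    hr_dist = c(68.00, 6.72),
                    n_subjects = 20, pulses_per_subject = 100)
  g2 <- cohort_spec("groupII",
                    sp_time_dist = c(144.12, 50.46),
                    pi_time_dist = c(200.46, 34.19),
                    dw_time_dist = c(291.84, 35.28),
                    aix_dist = c(-20.58, 20.03),
                    hr_dist = c(67.80, 11.02),
                    n_subjects = 20, pulses_per_subject = 98)
  g3 <- cohort_spec("groupIII",
                    sp_time_dist = c(219.99, 51.03),
                    pi_time_dist = c(118.94, 39.95),
                    dw_time_dist = c(313.52, 55.00),
                    aix_dist = c(10.62, 7.86),
                    hr_dist = c(63.50, 8.89),
                    n_subjects = 10, pulses_per_subject = 63)
  out <- list(groupI = g1, groupII = g2, groupIII = g3)
  if (calibrated) out <- lapply(out, calibrate_cohort)
  out
}

# ---- per-pulse parameter sampling ------------------------------------------

# Draw per-pulse morphology parameters for a cohort. Uses whatever RNG state
# is active. `aix_mean`/`aix_sd` allow a subject-level override while times
# are drawn from the cohort pool.
#' @noRd
sample_pulse_params <- function(cohort, n, loc = cohort$loc,
                                aix_mean = NULL, aix_sd = NULL,
                                period_T = NULL) {
  if (is.null(loc))
    loc <- list(aix = cohort$aix_dist[1], sp = cohort$sp_time_dist[1],
                dw = cohort$dw_time_dist[1], pi_major = cohort$pi_time_dist[1])
  if (is.null(aix_mean)) aix_mean <- loc$aix
  if (is.null(aix_sd)) aix_sd <- cohort$aix_dist[2]
  if (is.null(period_T)) {
    hr <- rtnorm(n, cohort$hr_dist[1], cohort$hr_dist[2], 40, 110)
    period_T <- round(60000 / hr)
  }
  aix <- rtnorm(n, aix_mean, aix_sd, -55, 55)
  aix <- ifelse(abs(aix) < 1, sign(aix + 1e-12), aix)  # keep Pi distinct from SP
  type_a <- aix >= 0
  majority_a <- cohort$aix_dist[1] >= 0

  # SP quantiles are rank-coupled with pulse type: type-A (stiff) pulses take
  # the upper tail, type-C the lower, as in real cohorts where late systolic
  # peaks co-occur with early reflections. The pooled SP marginal is unchanged.
  u_raw <- runif(n)
  frac_a <- mean(type_a)
  u_sp <- ifelse(type_a, (1 - frac_a) + frac_a * u_raw,
                 (1 - frac_a) * u_raw)
  sp <- qtnorm(u_sp, loc$sp, cohort$sp_time_dist[2], 55, 0.42 * period_T)
  # dicrotic timing comonotone with SP: preserves the marginal and keeps the
  # physiological ordering SP < DW without per-pulse rejection
  dw <- qtnorm(u_sp, loc$dw, cohort$dw_time_dist[2], 125, 0.78 * period_T)
  dw <- pmax(dw, sp + 70)
  # a type-C beat needs room on the falling limb for shoulder, notch and
  # wave; its valve closure sits correspondingly later after the early peak
  dw <- ifelse(type_a, dw, pmax(dw, sp + 125))

  pi_t <- numeric(n)
  # a reflected shoulder just past the systolic peak is absorbed by the
  # falling limb and has no realizable inflection; the deeper the reflection
  # (more negative AIx) the later it must arrive to stand out of the limb
  gap <- rtnorm(n, 55, 15, 30, 100)
  u_pi <- runif(n)
  maj <- type_a == majority_a
  c_lo <- sp + 30 + clamp(0.9 * (abs(aix) - 10), 0, 45)
  if (majority_a) {
    pi_t[maj] <- qtnorm(u_pi[maj], loc$pi_major, cohort$pi_time_dist[2],
                        28, sp[maj] - 18)
    pi_t[!maj] <- clamp(sp[!maj] + gap[!maj], c_lo[!maj], dw[!maj] - 45)
  } else {
    pi_t[maj] <- qtnorm(u_pi[maj], loc$pi_major, cohort$pi_time_dist[2],
                        c_lo[maj], dw[maj] - 45)
    pi_t[!maj] <- clamp(sp[!maj] - gap[!maj], 28, sp[!maj] - 18)
  }
  # degenerate window (very deep reflection on a late peak): pull inside
  pi_t <- ifelse(!type_a, pmin(pi_t, dw - 45), pi_t)
  pi_amp <- 1 - abs(aix) / 100
  dw_amp <- rtnorm(n, cohort$dw_amp_dist[1], cohort$dw_amp_dist[2], 0.22, 0.60)
  data.frame(period_T = period_T, sp_time = sp, pi_time = pi_t,
             pi_amp = pi_amp, dw_time = dw, dw_amp = dw_amp,
             true_aix = aix, type_a = type_a)
}

#' Calibrate a cohort's internal pulse-type mixture
#'
#' Per-pulse sign/order consistency makes each cohort a mixture of type-A and
#' type-C pulses whose Pi times live on opposite sides of SP. This solver
#' finds the majority-type Pi location parameter such that the pooled mean of
#' all sampled Pi times equals the cohort's nominal Pi mean. The expectation
#' is evaluated on a large fixed-seed Monte Carlo draw with common random
#' numbers, making the solved value deterministic for a given cohort.
#'
#' @param cohort A [cohort_spec()].
#' @param n Number of draws used to evaluate the pooled expectation.
#' @return The cohort with `pi_major_mean` filled in.
#' @export
calibrate_cohort <- function(cohort, n = 30000) {
  stopifnot(inherits(cohort, "apw_cohort_spec"))
  loc <- list(aix = cohort$aix_dist[1], sp = cohort$sp_time_dist[1],
              dw = cohort$dw_time_dist[1], pi_major = cohort$pi_time_dist[1])
  solve_loc <- function(field, target, column, lo, hi) {
    f <- function(mu) {
      loc[[field]] <- mu
      m <- with_seed(190501L,
                     mean(sample_pulse_params(cohort, n, loc = loc)[[column]]))
      m - target
    }
    if (f(lo) > 0 || f(hi) < 0)
      stop("config error: cohort '", cohort$name, "' cannot realize its ",
           column, " mean under the type mixture")
    stats::uniroot(f, c(lo, hi), tol = 0.05)$root
  }
  loc$aix <- solve_loc("aix", cohort$aix_dist[1], "true_aix",
                       cohort$aix_dist[1] - 25, cohort$aix_dist[1] + 25)
  loc$sp <- solve_loc("sp", cohort$sp_time_dist[1], "sp_time",
                      cohort$sp_time_dist[1] - 80, cohort$sp_time_dist[1] + 80)
  loc$dw <- solve_loc("dw", cohort$dw_time_dist[1], "dw_time",
                      cohort$dw_time_dist[1] - 80, cohort$dw_time_dist[1] + 80)
  loc$pi_major <- solve_loc("pi_major", cohort$pi_time_dist[1], "pi_time",
                            cohort$pi_time_dist[1] - 120,
                            cohort$pi_time_dist[1] + 160)
  cohort$loc <- loc
  cohort
}

# ---- recording generation ---------------------------------------------------

#' Generate a continuous synthetic recording for one subject
#'
#' Samples per-pulse morphology from the cohort distributions (the sign of
#' the drawn AIx deciding the Pi/SP order of each beat), calibrates and
#' concatenates the beats, and adds a slow sinusoidal baseline drift plus
#' white measurement noise. Ground truth (oracle fiducials of each noiseless
#' beat, the sampled spec, and the class label) is returned aligned with the
#' signal.
#'
#' @param cohort A calibrated [cohort_spec()] (uncalibrated cohorts are
#'   calibrated on the fly).
#' @param subject_id Identifier stored in the record metadata.
#' @param n_pulses Number of beats.
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @param label Class label attached to every pulse (1 = group I pattern,
#'   2 = group II pattern). Defaults by cohort name; for validation cohorts
#'   the per-pulse label follows the sign of the true AIx.
#' @return List with `record` (an `apw_record`: `samples`, `fs`, `meta`) and
#'   `truth` (data frame, one row per pulse: onset sample index, period,
#'   oracle fiducial times/amplitudes, type, true AIx, label).
#' @export
generate_recording <- function(cohort, subject_id = "S1", n_pulses = NULL,
                               seed = 1L, label = NULL) {
  stopifnot(inherits(cohort, "apw_cohort_spec"))
  if (n_pulses < 1 || is.null(n_pulses)) stop("n_pulses must be >= 1")
  if (is.null(cohort$loc)) cohort <- calibrate_cohort(cohort)
  with_seed(seed, {
    hr <- rtnorm(1, cohort$hr_dist[1], cohort$hr_dist[2], 40, 110)
    base_T <- 60000 / hr
    # beat-to-beat period jitter around the subject's heart rate
    period_T <- round(base_T * rtnorm(n_pulses, 1, 0.02, 0.9, 1.1))
    f <- cohort$subject_aix_frac
    subj_aix <- cohort$loc$aix +
      cohort$aix_dist[2] * sqrt(f) * stats::rnorm(1)
    pars <- sample_pulse_params(cohort, n_pulses,
                                aix_mean = subj_aix,
                                aix_sd = cohort$aix_dist[2] * sqrt(1 - f),
                                period_T = period_T)
    if (is.null(label)) {
      label <- switch(cohort$name, groupI = 1L, groupII = 2L, NA_integer_)
    }
    samples <- vector("list", n_pulses)
    rows <- vector("list", n_pulses)
    onset <- 0L
    for (i in seq_len(n_pulses)) {
      spec <- pulse_spec(pars$period_T[i], pars$sp_time[i],
                         pi_time = pars$pi_time[i], pi_amp = pars$pi_amp[i],
                         dw_time = pars$dw_time[i], dw_amp = pars$dw_amp[i],
                         noise_sd = 0, drift = cohort$drift)
      cal <- calibrate_pulse(spec)
      o <- cal$oracle
      samples[[i]] <- cal$samples
      lab_i <- if (is.na(label)) ifelse(pars$true_aix[i] >= 0, 1L, 2L) else label
      rows[[i]] <- data.frame(
        pulse = i, onset = onset, period_T = pars$period_T[i],
        sp_time = o$sp_time, sp_amp = o$sp_amp,
        pi_time = o$pi_time, pi_amp = o$pi_amp, pi_order = o$pi_order,
        dw_time = o$dw_time, dw_amp = o$dw_amp,
        true_aix = pars$true_aix[i], type_a = pars$true_aix[i] >= 0,
        label = lab_i, converged = cal$converged)
      onset <- onset + length(cal$samples)
    }
    sig <- unlist(samples)
    n <- length(sig)
    tsec <- (seq_len(n) - 1) / 1000
    if (!is.null(cohort$drift) && cohort$drift$amplitude > 0) {
      phase <- runif(1, 0, 2 * pi)
      sig <- sig + cohort$drift$amplitude *
        sin(2 * pi * tsec / cohort$drift$period_s + phase)
    }
    if (cohort$noise_sd > 0) sig <- sig + stats::rnorm(n, 0, cohort$noise_sd)
    record <- structure(list(samples = sig, fs = 1000,
                             meta = list(id = subject_id, group = cohort$name,
                                         hr = hr, seed = seed)),
                        class = "apw_record")
    list(record = record, truth = do.call(rbind, rows))
  })
}

#' Generate a whole cohort of subjects
#'
#' @param cohort A [cohort_spec()].
#' @param seed Integer master seed; per-subject seeds are derived from it.
#' @param n_subjects,pulses_per_subject Override the cohort defaults.
#' @return List with one `generate_recording()` result per subject.
#' @export
generate_cohort <- function(cohort, seed = 1L, n_subjects = NULL,
                            pulses_per_subject = NULL) {
  stopifnot(inherits(cohort, "apw_cohort_spec"))
  if (is.null(cohort$loc)) cohort <- calibrate_cohort(cohort)
  if (is.null(n_subjects)) n_subjects <- cohort$n_subjects
  if (is.null(pulses_per_subject)) pulses_per_subject <- cohort$pulses_per_subject
  lapply(seq_len(n_subjects), function(i) {
    sseed <- (as.numeric(seed) * 7919 + i * 104729) %% 2147483587
    generate_recording(cohort, subject_id = paste0(cohort$name, "_S", i),
                       n_pulses = pulses_per_subject, seed = as.integer(sseed))
  })
}
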