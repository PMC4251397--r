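# ---- record / pulse containers ---------------------------------------------

#' Construct a waveform record
#'
#' @param samples Numeric vector of pressure samples (arbitrary units).
#' @param fs Sampling rate in Hz (default 1000).
#' @param meta Optional list of subject metadata (id, group, SBP, DBP, HR, age).
#' @return An `apw_record`.
#' @export
apw_record <- function(samples, fs = 1000, meta = list()) {
  stopifnot(is.numeric(samples), fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs, meta = meta),
            class = "apw_record")
}

#' @export
print.apw_record <- function(x, ...) {
  cat("<apw_record>", length(x$samples), "samples @", x$fs, "Hz (",
      round(length(x$samples) / x$fs, 1), "s )\n")
  if (!is.null(x$meta$id)) cat("  subject:", x$meta$id, "\n")
  invisible(x)
}

#' @noRd
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  if (w %% 2 == 0) w <- w + 1
  k <- rep(1 / w, w)
  as.numeric(stats::filter(x, k, sides = 2)) -> y
  # fill filter edges with the original samples
  h <- (w - 1) %/% 2
  y[seq_len(h)] <- x[seq_len(h)]
  n <- length(x)
  y[(n - h + 1):n] <- x[(n - h + 1):n]
  y
}

# ---- onset detection --------------------------------------------------------

# Locate pulse onsets: maximal first-derivative upstroke points, then for each
# the last sample below 1% of the local upstroke height. Returns 1-based
# sample indices of onsets.
# Robust beat-period estimate from the autocorrelation of the signal.
#' @noRd
estimate_period <- function(samples, fs = 1000, lo_ms = 350, hi_ms = 2000) {
  x <- samples - mean(samples)
  n <- length(x)
  hi <- min(round(hi_ms * fs / 1000), n - 1)
  lo <- round(lo_ms * fs / 1000)
  if (hi <= lo) return(NA_real_)
  ac <- stats::acf(x, lag.max = hi, plot = FALSE, demean = FALSE)$acf[-1]
  lag <- lo + which.max(ac[lo:hi]) - 1
  # octave guard: if half the winning lag is almost as strong, the peak was
  # the second harmonic of the beat period
  half <- round(lag / 2)
  if (half >= lo && half <= hi && ac[half] >= 0.7 * ac[lag]) lag <- half
  lag * 1000 / fs
}

#' @noRd
find_onsets <- function(samples, fs = 1000, smooth = 5, refractory_ms = 200,
                        slope_frac = 0.35) {
  n <- length(samples)
  sm <- moving_average(samples, smooth)
  d1 <- c(0, diff(sm))
  d1 <- moving_average(d1, smooth)
  thr <- slope_frac * as.numeric(quantile(d1[d1 > 0], 0.98, na.rm = TRUE))
  if (!is.finite(thr) || thr <= 0) return(integer(0))
  hot <- which(d1 > thr)
  if (!length(hot)) return(integer(0))
  refr <- round(refractory_ms * fs / 1000)
  # split into runs separated by at least the refractory period
  brk <- c(0, which(diff(hot) > refr), length(hot))
  ups <- integer(0)
  for (j in seq_len(length(brk) - 1)) {
    run <- hot[(brk[j] + 1):brk[j + 1]]
    ups <- c(ups, run[which.max(d1[run])])
  }
  # secondary upstrokes (e.g. the dicrotic rise) can masquerade as onsets;
  # enforce the beat period estimated from the signal's autocorrelation by
  # dropping the weaker of any pair of upstrokes closer than 0.6 periods
  period <- estimate_period(samples, fs)
  if (is.finite(period) && length(ups) > 2) {
    min_gap <- 0.6 * period * fs / 1000
    repeat {
      gaps <- diff(ups)
      k <- which(gaps < min_gap)
      if (!length(gaps) || !length(k)) break
      k <- k[1]
      drop <- if (d1[ups[k]] >= d1[ups[k + 1]]) k + 1 else k
      ups <- ups[-drop]
    }
  }
  # two-stage foot location: a coarse 10%-height crossing brackets the foot
  # even for slow upstrokes whose maximal slope sits far up the limb, then
  # the 1%-of-upstroke-height rule is applied in a narrow local window
  onsets <- integer(0)
  for (k in ups) {
    lo <- max(1, k - round(0.4 * fs))
    seg <- sm[lo:k]
    b <- as.numeric(quantile(seg, 0.08))
    hi <- min(n, k + round(0.4 * fs))
    pk <- max(sm[k:hi])
    below10 <- which(seg < b + 0.10 * (pk - b))
    if (!length(below10)) next
    j10 <- lo + below10[length(below10)] - 1
    w <- max(1, j10 - round(0.09 * fs)):min(k, j10 + round(0.04 * fs))
    base <- min(sm[w])
    thr_amp <- base + 0.01 * (pk - base)
    below <- which(sm[w] < thr_amp)
    onsets <- c(onsets, if (length(below)) w[below[length(below)]] else j10)
  }
  sort(unique(onsets))
}

# ---- operations -------------------------------------------------------------

#' Remove baseline wander from a recording
#'
#' Subtracts a smoothed lower envelope when slow wander is present, then
#' detects the diastolic minima (pulse feet), interpolates a smoothed
#' piecewise-linear baseline through them, and subtracts it, leaving the
#' pulse feet on the zero level. The foot pass is run twice so that onsets
#' relocated after the first correction refine the baseline estimate.
#'
#' @param record An [apw_record()].
#' @return The corrected `apw_record`.
#' @export
remove_baseline <- function(record) {
  stopifnot(inherits(record, "apw_record"))
  x <- record$samples
  fs <- record$fs
  if (length(x) < 2 * fs)
    stop("input error: at least 2 s of signal required")
  # coarse pass: subtract a smoothed lower envelope (rolling minimum over
  # about one beat) so that the foot detector sees an almost level signal
  period <- estimate_period(x, fs)
  if (!is.finite(period)) period <- 900
  blk <- max(10, round(0.05 * fs))
  nblk <- ceiling(length(x) / blk)
  bmin <- vapply(seq_len(nblk), function(b) {
    i0 <- (b - 1) * blk + 1
    min(x[i0:min(i0 + blk - 1, length(x))])
  }, 0)
  k <- max(1, round(1.1 * period * fs / 1000 / blk))
  roll <- vapply(seq_len(nblk), function(b) {
    min(bmin[max(1, b - k):min(nblk, b + k)])
  }, 0)
  # a flat envelope means no appreciable wander: leave the signal untouched
  # (interquartile spread of the rolling minimum, so one deep local
  # excursion does not trigger the pass)
  spread <- diff(as.numeric(quantile(roll, c(0.25, 0.75))))
  if (spread > 0.04 * diff(range(x))) {
    centers <- (seq_len(nblk) - 0.5) * blk
    env <- approx(centers, roll, xout = seq_along(x), rule = 2)$y
    env <- moving_average(env, max(3, round(period / 3)))
    x <- x - env
  }
  for (pass in 1:2) {
    onsets <- find_onsets(x, fs)
    if (length(onsets) < 3) break
    sm <- moving_average(x, 9)
    v <- sm[onsets]
    # a mis-detected onset sits high on the pulse and would drag the spline
    # through the beat: keep only knots near the foot-level band
    keep <- abs(v - median(v)) <= 3 * stats::mad(v) + 0.03 * diff(range(x))
    if (sum(keep) < 3) break
    onsets <- onsets[keep]
    base <- approx(onsets, sm[onsets], xout = seq_along(x),
                   rule = 2)$y
    base <- moving_average(base, round(0.15 * fs))
    # beyond the outermost feet, hold the baseline constant
    base[seq_len(onsets[1])] <- base[onsets[1]]
    base[onsets[length(onsets)]:length(x)] <- base[onsets[length(onsets)]]
    x <- x - base
  }
  record$samples <- x
  record
}

#' Segment a recording into single pulses
#'
#' Onsets are placed at the foot preceding each maximal first-derivative
#' upstroke (the last sample below 1% of the local upstroke height); pulses
#' span onset to onset. The leading and trailing partial beats are discarded.
#'
#' @param record A baseline-corrected [apw_record()].
#' @param smooth Moving-average width (samples) used for derivative
#'   estimation.
#' @return List of `apw_pulse` objects: `samples`, `onset_index` (0-based
#'   sample offset into the record), `period_T` (ms), `pulse_index`,
#'   `anomalous`, `anomaly_reason`.
#' @export
segment_pulses <- function(record, smooth = 5) {
  stopifnot(inherits(record, "apw_record"))
  if (length(record$samples) < 2 * record$fs)
    stop("input error: at least 2 s of signal required")
  onsets <- find_onsets(record$samples, record$fs, smooth = smooth)
  if (length(onsets) < 2) {
    warning("no detectable upstrokes; returning empty pulse list")
    return(list())
  }
  ms <- 1000 / record$fs
  out <- vector("list", length(onsets) - 1)
  for (i in seq_len(length(onsets) - 1)) {
    idx <- onsets[i]:(onsets[i + 1] - 1)
    out[[i]] <- structure(list(
      samples = record$samples[idx],
      onset_index = as.integer(onsets[i] - 1),
      period_T = length(idx) * ms,
      pulse_index = i,
      anomalous = FALSE,
      anomaly_reason = NA_character_
    ), class = "apw_pulse")
  }
  out
}

#' Flag anomalous beats by amplitude and width deviation
#'
#' A pulse is flagged when its pre-normalization amplitude (max - min) or its
#' width (beat duration) deviates from the corpus median by more than
#' `k` median absolute deviations. Flagged pulses are retained, with the
#' reason recorded, so downstream feature tables can exclude them.
#'
#' @param pulses List of `apw_pulse` objects from [segment_pulses()].
#' @param k MAD multiplier (default 5).
#' @return The pulse list with `anomalous` / `anomaly_reason` set.
#' @export
flag_anomalous <- function(pulses, k = 5) {
  if (length(pulses) < 5) {
    warning("fewer than 5 pulses; anomaly flagging skipped")
    return(pulses)
  }
  amp <- vapply(pulses, function(p) max(p$samples) - min(p$samples), 0)
  wid <- vapply(pulses, function(p) p$period_T, 0)
  flag_one <- function(v) {
    med <- median(v)
    # MAD floor at 2% of the median level: ordinary beat-to-beat variation
    # must never look anomalous on very clean signals
    m <- max(stats::mad(v), 0.02 * abs(med), 1e-9)
    abs(v - med) > k * m
  }
  bad_amp <- flag_one(amp); bad_wid <- flag_one(wid)
  for (i in seq_along(pulses)) {
    if (bad_amp[i] || bad_wid[i]) {
      pulses[[i]]$anomalous <- TRUE
      pulses[[i]]$anomaly_reason <- paste(
        c("amplitude", "width")[c(bad_amp[i], bad_wid[i])], collapse = "+")
    }
  }
  pulses
}

#' Normalize a pulse to the unit amplitude range
#'
#' Linear rescale so the minimum (at the onset for a baseline-corrected beat)
#' maps to 0 and the maximum to 1.
#'
#' @param pulse An `apw_pulse`.
#' @return The normalized `apw_pulse`.
#' @export
normalize_pulse <- function(pulse) {
  stopifnot(inherits(pulse, "apw_pulse"))
  rng <- range(pulse$samples)
  if (diff(rng) < 1e-12)
    stop("degenerate input: flat pulse cannot be normalized")
  pulse$samples <- (pulse$samples - rng[1]) / diff(rng)
  pulse
}
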