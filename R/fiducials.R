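# Production detector for the three prominent points of a normalized pulse:
# systolic peak (SP), point of inflection (Pi) and dicrotic wave (DW).
# Derivatives are estimated with Savitzky-Golay filters so that curvature
# sign changes survive measurement noise at 1 kHz.

#' @noRd
sg_deriv <- function(x, order = 2, window = 37, poly = 3, post_smooth = 11) {
  n <- length(x)
  if (window >= n) window <- if (n %% 2) n - 2 else n - 1
  if (window < poly + 2) return(rep(0, n))
  if (window %% 2 == 0) window <- window - 1
  d <- as.numeric(signal::sgolayfilt(x, p = poly, n = window, m = order))
  # residual noise makes the curvature dither around zero near genuine
  # inflections, splitting one crossing into several; a short moving average
  # restores a single, clean sign change
  moving_average(d, post_smooth)
}

# Zero crossings of a series with sub-sample interpolation.
# dir = +1: - to +, dir = -1: + to -. Returns times in ms (0-based samples).
#' @noRd
zero_crossings <- function(d2, dir, fs = 1000) {
  i <- seq_len(length(d2) - 1)
  hit <- if (dir > 0) which(d2[i] < 0 & d2[i + 1] > 0)
         else          which(d2[i] > 0 & d2[i + 1] < 0)
  if (!length(hit)) return(numeric(0))
  (hit - 1 + d2[hit] / (d2[hit] - d2[hit + 1])) * 1000 / fs
}

# Curvature-magnitude screen. A crossing qualifies when the curvature lobes
# on both sides are sustained and rise above a floor set by the larger of a
# fraction of the pulse's maximal curvature and a noise estimate taken from
# the late-diastolic tail.
#' @noRd
screen_crossings <- function(cross_ms, d2, thresh, fs = 1000, lobe_ms = 18,
                             ref = NULL) {
  if (!length(cross_ms)) return(cross_ms)
  n <- length(d2)
  tail_i <- max(1, floor(0.88 * n)):n
  noise <- stats::mad(d2[tail_i], na.rm = TRUE)
  # the curvature scale of the search window, not of the whole pulse: the
  # systolic peak of a fast upstroke dwarfs every shoulder otherwise
  if (is.null(ref)) ref <- max(abs(d2))
  floor_ <- max(thresh * ref, 3 * noise)
  keep <- vapply(cross_ms, function(tm) {
    i <- round(tm * fs / 1000) + 1
    lo <- max(1, i - lobe_ms); hi <- min(n, i + lobe_ms)
    left <- d2[lo:max(lo, i - 3)]; right <- d2[min(hi, i + 3):hi]
    sl <- mean(left); sr <- mean(right)
    sign(sl) != sign(sr) && abs(sl) >= floor_ * 0.35 && abs(sr) >= floor_ * 0.35 &&
      max(abs(left)) >= floor_ && max(abs(right)) >= floor_
  }, TRUE)
  cross_ms[keep]
}

#' Detect the systolic peak
#'
#' Global maximum of the lightly smoothed pulse; ties broken to the earliest
#' sample. Amplitude is read from the raw normalized samples.
#'
#' @param pulse A normalized `apw_pulse`.
#' @param smooth Moving-average width in samples.
#' @return List with `sp_time` (ms from onset) and `sp_amp`.
#' @export
detect_sp <- function(pulse, smooth = 21) {
  stopifnot(inherits(pulse, "apw_pulse"))
  sm <- moving_average(pulse$samples, smooth)
  i <- which.max(sm)
  # amplitude from a lightly smoothed curve: all fiducial amplitudes are read
  # from the same curve so that amplitude differences (e.g. the augmentation
  # index) are unbiased by single-sample noise excursions
  amp <- moving_average(pulse$samples, 11)[i]
  list(sp_time = (i - 1) * 1000 / 1000, sp_amp = amp)
}

# ---- joint post-systolic event parsing --------------------------------------

# All prominent derivative-lift events on the falling limb: local maxima of
# the smoothed first derivative whose prominence clears a noise-adaptive
# floor. Both the reflected shoulder and the dicrotic wave appear here.
#' @noRd
post_sp_events <- function(x, sp_i, curv_thresh = 0.03, curv_window = 37,
                           hi_frac = 0.85) {
  n <- length(x)
  d1 <- sg_deriv(x, 1, curv_window)
  xs <- moving_average(x, 11)
  hi_i <- min(n - 1, floor(hi_frac * n), sp_i + 300)
  if (hi_i - sp_i < 25) return(NULL)
  win <- (sp_i + 8):hi_i
  ii <- win[win > 1 & win < n]
  if (length(ii) < 3) return(NULL)
  ev <- ii[d1[ii] >= d1[ii - 1] & d1[ii] > d1[ii + 1]]
  if (!length(ev)) return(NULL)
  reach <- 45
  pr <- vapply(ev, function(i) {
    lo <- max(1, i - reach); hi2 <- min(n, i + reach)
    min(d1[i] - min(d1[lo:i]), d1[i] - min(d1[i:hi2]))
  }, 0)
  noise <- stats::mad(d1[max(1, floor(0.88 * n)):n], na.rm = TRUE)
  ref <- max(abs(d1[ii]))
  keep <- pr >= max(curv_thresh * ref, 5 * noise)
  if (!any(keep)) return(NULL)
  ev <- ev[keep]; pr <- pr[keep]
  # drop trailing noise-grade events (late-diastole ripples); weak EARLY
  # events may be genuine faint shoulders and are kept
  while (length(ev) > 1 && pr[length(pr)] < 0.25 * max(pr)) {
    ev <- ev[-length(ev)]; pr <- pr[-length(pr)]
  }
  # trough drop: how far the signal has dipped below the event on the way
  # from SP. A reflected shoulder is approached from above (drop ~ 0); the
  # dicrotic wave rises off the notch (drop > 0).
  drop <- vapply(ev, function(i) xs[i] - min(xs[sp_i:i]), 0)
  data.frame(idx = ev, time = ev - 1, amp = xs[ev], prom = pr,
             score = pr / ref, drop = drop)
}

# Fraction of the upstroke spent above half height: augmented (type-A)
# pulses dwell long above half height before the peak, fast-rising type-C
# pulses do not. Used as the pulse-type prior.
#' @noRd
half_dwell_ms <- function(xs, sp_i, fs = 1000) {
  uh <- which(xs[seq_len(sp_i)] >= 0.5 * xs[sp_i])[1]
  if (is.na(uh)) return(0)
  (sp_i - uh) * 1000 / fs
}

#' Detect the dicrotic wave
#'
#' Locates the dicrotic wave among the prominent derivative-lift events of
#' the falling limb. On a predominantly augmented (type-A) pulse every such
#' event belongs to the dicrotic complex and the last non-noise event is
#' taken; on a fast-rising (type-C) pulse the first event is the reflected
#' shoulder, so the wave is searched past it. The position is refined to the
#' local maximum of the smoothed signal when the wave rises to one; the
#' dicrotic notch is the minimum between the systolic peak (or the shoulder)
#' and the wave.
#'
#' @param pulse A normalized `apw_pulse`.
#' @param sp Result of [detect_sp()].
#' @param pi_time Optional reflected-shoulder time (ms) to search past.
#' @param dw_limit Upper search bound as a fraction of the beat period.
#' @param prominence Unused placeholder kept for interface stability.
#' @param curv_window Savitzky-Golay window (samples).
#' @return List with `dw_time`, `dw_amp`, `notch_time` (or `NA`s).
#' @export
detect_dw <- function(pulse, sp, pi_time = NA, dw_limit = 0.85,
                      prominence = 0.02, curv_window = 37) {
  stopifnot(inherits(pulse, "apw_pulse"))
  x <- pulse$samples
  n <- length(x)
  xs <- moving_average(x, 11)
  sp_i <- round(sp$sp_time) + 1
  none <- list(dw_time = NA_real_, dw_amp = NA_real_, notch_time = NA_real_)
  # primary path: a local maximum of the smoothed signal rising from the
  # decline (the classic notch-plus-wave shape)
  start <- sp_i + 15
  if (!is.na(pi_time) && pi_time > sp$sp_time)
    start <- max(start, round(pi_time) + 20)
  hi <- min(n - 1, floor(dw_limit * n), sp_i + 280)
  if (hi - start >= 20) {
    ii <- start:hi
    ii <- ii[ii > 1 & ii < n]
    lm <- ii[xs[ii] > xs[ii - 1] & xs[ii] >= xs[ii + 1]]
    if (length(lm)) {
      pl <- vapply(lm, function(j) xs[j] - min(xs[sp_i:j]), 0)
      pr <- vapply(lm, function(j) xs[j] - min(xs[j:min(n, j + 120)]), 0)
      lm <- lm[pl >= 0.02 & pr >= 0.006 & xs[lm] >= 0.15 & xs[lm] <= 0.65]
      pl <- pl[pl >= 0.02 & TRUE][seq_along(lm)]
      if (length(lm)) {
        pl2 <- vapply(lm, function(j) xs[j] - min(xs[sp_i:j]), 0)
        j <- lm[which.max(pl2)]
        lo_n <- if (!is.na(pi_time) && pi_time > sp$sp_time)
          min(round(pi_time) + 1, j - 1) else sp_i
        notch <- which.min(xs[lo_n:j]) + lo_n - 1
        return(list(dw_time = j - 1, dw_amp = xs[j], notch_time = notch - 1))
      }
    }
  }
  ev <- post_sp_events(x, sp_i, curv_window = curv_window, hi_frac = dw_limit)
  if (is.null(ev)) return(none)
  if (!is.na(pi_time) && pi_time > sp$sp_time) {
    ev <- ev[ev$time >= pi_time + 20, , drop = FALSE]
  } else if (half_dwell_ms(xs, sp_i) <= max(60, 0.5 * sp_i) && nrow(ev) >= 2 &&
             ev$amp[1] >= 0.40) {
    # type-C pulse analyzed stand-alone: skip the reflected shoulder
    ev <- ev[-1, , drop = FALSE]
  }
  if (!nrow(ev)) return(none)
  # the dicrotic wave sits in the low-to-mid amplitude band; among such
  # events the most prominent one is the wave, which keeps late-diastolic
  # ripples and early decay-handover events out
  band <- ev[ev$amp <= 0.62, , drop = FALSE]
  e <- if (nrow(band)) band[which.max(band$prom), ] else ev[nrow(ev), ]
  j <- e$idx
  # refine to the local maximum of the smoothed signal when one rises
  wmax <- min(n, j + 60)
  seg <- xs[j:wmax]
  k <- which.max(seg)
  if (k > 1 && k < length(seg) && seg[k] > seg[1] + 0.003) j <- j + k - 1
  lo_n <- if (!is.na(pi_time) && pi_time > sp$sp_time)
    round(pi_time) + 1 else sp_i
  lo_n <- min(lo_n, j - 1)
  notch <- which.min(xs[lo_n:j]) + lo_n - 1
  list(dw_time = j - 1, dw_amp = xs[j], notch_time = notch - 1)
}

#' Detect the point of inflection
#'
#' The pulse is first classified by its upstroke profile: a pulse dwelling
#' above half height for more than half the time to its peak is augmented
#' (type A), otherwise fast-rising (type C). On a type-A pulse Pi is the
#' most prominent dip of the smoothed first derivative on the upstroke (the
#' shoulder); on a type-C pulse it is the first prominent derivative-lift
#' event on the falling limb with a plausible amplitude. If the required
#' shape cannot be found, Pi is reported missing -- on augmented pulses with
#' no resolvable dip the inflection is buried in the systolic peak.
#'
#' @param pulse A normalized `apw_pulse`.
#' @param sp Result of [detect_sp()].
#' @param curv_thresh Prominence threshold as a fraction of the search
#'   window's derivative scale.
#' @param curv_window Savitzky-Golay window (samples).
#' @param guard_ms Guard interval after the onset excluded from the search.
#' @param min_amp Minimal plausible normalized amplitude of a reflected-wave
#'   landmark.
#' @return List with `pi_time`, `pi_amp`, `pi_order`.
#' @export
detect_pi <- function(pulse, sp, curv_thresh = 0.05, curv_window = 37,
                      guard_ms = 20, min_amp = 0.40) {
  stopifnot(inherits(pulse, "apw_pulse"))
  x <- pulse$samples
  n <- length(x)
  d1 <- sg_deriv(x, 1, curv_window)
  none <- list(pi_time = NA_real_, pi_amp = NA_real_, pi_order = "missing")
  xs <- moving_average(x, 11)
  sp_i <- round(sp$sp_time) + 1

  if (half_dwell_ms(xs, sp_i) > max(60, 0.5 * sp_i)) {
    # type A: most prominent derivative dip on the upstroke
    if (sp_i - 10 <= guard_ms) return(none)
    win <- round(guard_ms):(sp_i - 8)
    ref <- max(d1[win])
    ii <- win[win > 1 & win < n]
    cand <- ii[d1[ii] <= d1[ii - 1] & d1[ii] < d1[ii + 1]]
    cand <- cand[xs[cand] >= min_amp]
    if (!length(cand) || ref <= 0) return(none)
    reach <- 45
    pr <- vapply(cand, function(i) {
      lo <- max(1, i - reach); hi2 <- min(n, i + reach)
      min(max(d1[lo:i]) - d1[i], max(d1[i:hi2]) - d1[i])
    }, 0)
    k <- which.max(pr)
    if (pr[k] < curv_thresh * ref) return(none)
    i <- cand[k]
    # refine on a lightly smoothed derivative: the heavy smoothing that
    # stabilizes candidate search drags the dip a few ms early
    d1f <- sg_deriv(x, 1, 21, post_smooth = 1)
    wlo <- max(1, i - 12); whi <- min(n, i + 12)
    i <- wlo + which.min(d1f[wlo:whi]) - 1
    return(list(pi_time = i - 1, pi_amp = xs[i], pi_order = "before_sp"))
  }
  # type C: first prominent post-systolic event with a plausible amplitude
  ev <- post_sp_events(x, sp_i, curv_thresh, curv_window)
  if (is.null(ev)) return(none)
  ev <- ev[ev$amp >= min_amp, , drop = FALSE]
  if (!nrow(ev)) return(none)
  e <- ev[1, ]
  list(pi_time = e$time, pi_amp = e$amp, pi_order = "after_sp")
}

#' Detect all prominent points of a normalized pulse
#'
#' Runs [detect_sp()], [detect_dw()] and [detect_pi()] and assembles an
#' `apw_fiducials` object matching the layout produced by
#' [oracle_fiducials()].
#'
#' @param pulse A normalized `apw_pulse`.
#' @param curv_thresh,curv_window,dw_limit,guard_ms Detector constants; see
#'   the individual detectors.
#' @return An `apw_fiducials` list.
#' @export
detect_fiducials <- function(pulse, curv_thresh = 0.05, curv_window = 37,
                             dw_limit = 0.8, guard_ms = 20) {
  sp <- detect_sp(pulse)
  pi_ <- detect_pi(pulse, sp, curv_thresh = curv_thresh,
                   curv_window = curv_window, guard_ms = guard_ms)
  dw <- detect_dw(pulse, sp, pi_time = pi_$pi_time, dw_limit = dw_limit,
                  curv_window = curv_window)
  missing <- character(0)
  if (is.na(pi_$pi_time)) missing <- c(missing, "pi")
  if (is.na(dw$dw_time)) missing <- c(missing, "dw")
  structure(list(sp_time = sp$sp_time, sp_amp = sp$sp_amp,
                 pi_time = pi_$pi_time, pi_amp = pi_$pi_amp,
                 pi_order = pi_$pi_order,
                 dw_time = dw$dw_time, dw_amp = dw$dw_amp,
                 missing_flags = missing),
            class = "apw_fiducials")
}

#' @export
print.apw_fiducials <- function(x, ...) {
  cat("<apw_fiducials> SP", round(x$sp_time, 1), "ms /", round(x$sp_amp, 3),
      "| Pi", round(x$pi_time, 1), "ms (", x$pi_order, ")",
      "| DW", round(x$dw_time, 1), "ms\n")
  invisible(x)
}
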