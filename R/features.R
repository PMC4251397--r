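# Hemodynamic feature extraction: per-pulse intervals, amplitude ratios,
# the signed augmentation index, and per-segment variability statistics.

#' Compute fiducial time intervals for one pulse
#'
#' Times are measured from the pulse onset in ms; the downstroke time is the
#' remainder of the beat after the systolic peak. Missing fiducials
#' propagate as `NA` markers (exported as 0 only under the paper-parity
#' convention of [build_feature_table()]).
#'
#' @param fid An `apw_fiducials` (from [detect_fiducials()] or
#'   [oracle_fiducials()]).
#' @param period_T Beat period in ms.
#' @return List with `sp_t`, `pi_t`, `dw_t`, `ds_t` (ms) and `sp_a`, `pi_a`,
#'   `dw_a` (normalized units).
#' @export
compute_intervals <- function(fid, period_T) {
  stopifnot(inherits(fid, "apw_fiducials"))
  if (period_T <= fid$sp_time)
    stop("inconsistent input: period_T must exceed sp_time")
  list(sp_t = fid$sp_time, pi_t = fid$pi_time, dw_t = fid$dw_time,
       ds_t = period_T - fid$sp_time,
       sp_a = fid$sp_amp, pi_a = fid$pi_amp, dw_a = fid$dw_amp)
}

#' Compute the six morphological ratios
#'
#' R1 = SP_t/T (upstroke time ratio), R2 = (SP_t - DW_t)/T, R3 = DS_t/SP_t,
#' R4 = DW_a/SP_a, R5 = |SP_a - Pi_a|, R6 = Pi_a/SP_a. A ratio whose operand
#' is missing is `NA`. R2 is negative whenever the dicrotic wave arrives
#' after the systolic peak, which is the physiological ordering.
#'
#' @param iv Interval list from [compute_intervals()].
#' @param period_T Beat period in ms.
#' @return Named list `r1` .. `r6`.
#' @export
compute_ratios <- function(iv, period_T) {
  r3 <- if (is.na(iv$sp_t) || iv$sp_t == 0) NA_real_ else iv$ds_t / iv$sp_t
  list(r1 = iv$sp_t / period_T,
       r2 = (iv$sp_t - iv$dw_t) / period_T,
       r3 = r3,
       r4 = iv$dw_a / iv$sp_a,
       r5 = abs(iv$sp_a - iv$pi_a),
       r6 = iv$pi_a / iv$sp_a)
}

#' Compute the signed augmentation index
#'
#' `AIx(%) = +/- (SP_a - Pi_a)/A x 100`: positive when the inflection
#' precedes the systolic peak (type A, the reflected wave augments the
#' peak), negative when it follows it (type C). `A` is the normalized pulse
#' amplitude (1 after normalization).
#'
#' @param sp_a,pi_a Normalized amplitudes of SP and Pi.
#' @param pi_order `"before_sp"` or `"after_sp"`.
#' @param A Normalized pulse amplitude.
#' @return Percent value, or `NA` when Pi is missing.
#' @export
compute_aix <- function(sp_a, pi_a, pi_order, A = 1) {
  if (is.na(pi_a) || identical(pi_order, "missing")) return(NA_real_)
  stopifnot(A > 0)
  if (pi_order == "before_sp") (sp_a - pi_a) / A * 100
  else (pi_a - sp_a) / A * 100
}

#' Root mean square of successive differences
#'
#' `sqrt( sum (x[i+1]-x[i])^2 / (n-1) )` over the non-missing entries of a
#' per-beat series, pairing consecutive available values.
#'
#' @param series Numeric vector (a fiducial coordinate across one segment's
#'   beats); `NA`s are excluded pairwise.
#' @param percent_of_mean Report as percent of the series mean.
#' @return Non-negative scalar (0 for a constant series).
#' @export
compute_rmssd <- function(series, percent_of_mean = FALSE) {
  x <- series[!is.na(series)]
  if (length(x) < 2) stop("input error: need at least 2 values")
  v <- sqrt(sum(diff(x)^2) / (length(x) - 1))
  if (percent_of_mean) {
    m <- mean(x)
    if (abs(m) < 1e-12) return(NA_real_)
    v <- 100 * v / m
  }
  v
}

#' Root-mean-square error against a reference pulse
#'
#' `sqrt( mean( (x - ref)^2 ) )` between two equal-length sample vectors,
#' typically a pulse and the segment's mean pulse.
#'
#' @param pulse Numeric vector or `apw_pulse`.
#' @param reference Numeric vector of the same length.
#' @return Non-negative scalar.
#' @export
compute_rmse <- function(pulse, reference) {
  x <- if (inherits(pulse, "apw_pulse")) pulse$samples else pulse
  if (length(x) != length(reference))
    stop("internal error: length mismatch between pulse and reference")
  sqrt(mean((x - reference)^2))
}

#' Full width at half maximum of a normalized pulse
#'
#' Width in ms between the first up-crossing and the last down-crossing of
#' half the maximum amplitude, with linear interpolation between samples.
#'
#' @param pulse A normalized `apw_pulse` (or numeric vector).
#' @param fs Sampling rate in Hz.
#' @return Width in ms.
#' @export
compute_fwhm <- function(pulse, fs = 1000) {
  x <- if (inherits(pulse, "apw_pulse")) pulse$samples else pulse
  half <- min(x) + 0.5 * (max(x) - min(x))
  above <- x >= half
  i_first <- which(above)[1]
  i_last <- which(above)[sum(above)]
  t_first <- if (i_first > 1) {
    (i_first - 1) - (x[i_first] - half) / (x[i_first] - x[i_first - 1])
  } else 0
  t_last <- if (i_last < length(x)) {
    (i_last - 1) + (x[i_last] - half) / (x[i_last] - x[i_last + 1])
  } else length(x) - 1
  (t_last - t_first) * 1000 / fs
}

# Resample a pulse to a fixed length by linear interpolation.
#' @noRd
resample_to <- function(x, len) {
  approx(seq_along(x), x, xout = seq(1, length(x), length.out = len))$y
}

#' The selected classification attribute set
#'
#' The twelve attributes retained for classification after merit ranking:
#' the inflection and systolic arrival times, the six ratios, the dicrotic
#' coordinates, the augmentation index and the beat-to-beat variability of
#' the inflection time.
#'
#' @return Character vector of column names.
#' @export
selected_feature_names <- function() {
  c("pi_t", "r6", "r5", "sp_t", "r1", "r2", "r3", "dw_a", "r4", "dw_t",
    "aix", "rmssd_pi_t")
}

# The canonical column order: the selected attribute list first.
#' @noRd
feature_columns <- function() {
  c("pi_t", "r6", "r5", "sp_t", "r1", "r2", "r3", "dw_a", "r4", "dw_t",
    "aix", "rmssd_pi_t",
    "sp_a", "pi_a", "ds_t", "rmssd_sp_t", "rmssd_sp_a", "rmssd_pi_a",
    "rmssd_dw_t", "rmssd_dw_a", "rmse", "fwhm")
}

#' Compute per-pulse features for one segment of pulses
#'
#' A segment is one subject's run of segmented, non-anomalous, normalized
#' pulses. Per-pulse columns (arrival times, amplitudes, ratios, AIx, FWHM,
#' RMSE against the segment mean pulse) are combined with segment-level
#' RMSSD columns replicated onto the member pulses.
#'
#' @param pulses List of normalized `apw_pulse` objects (anomalous ones are
#'   skipped).
#' @param label Optional class label (1 = group I pattern, 2 = group II).
#' @param subject Subject identifier replicated into the table.
#' @param detect_args List of arguments forwarded to [detect_fiducials()].
#' @return Data frame, one row per usable pulse, columns in the canonical
#'   order plus `subject` and `class`.
#' @export
segment_features <- function(pulses, label = NA_integer_, subject = "S1",
                             detect_args = list()) {
  keep <- Filter(function(p) !isTRUE(p$anomalous), pulses)
  if (!length(keep)) {
    warning("segment with no usable pulses skipped")
    return(NULL)
  }
  fids <- lapply(keep, function(p)
    do.call(detect_fiducials, c(list(p), detect_args)))
  rows <- vector("list", length(keep))
  med_len <- round(median(vapply(keep, function(p) length(p$samples), 0)))
  resampled <- lapply(keep, function(p) resample_to(p$samples, med_len))
  mean_pulse <- Reduce(`+`, resampled) / length(resampled)
  for (i in seq_along(keep)) {
    p <- keep[[i]]; f <- fids[[i]]
    iv <- compute_intervals(f, p$period_T)
    rt <- compute_ratios(iv, p$period_T)
    rows[[i]] <- data.frame(
      sp_t = iv$sp_t, pi_t = iv$pi_t, dw_t = iv$dw_t, ds_t = iv$ds_t,
      sp_a = iv$sp_a, pi_a = iv$pi_a, dw_a = iv$dw_a,
      r1 = rt$r1, r2 = rt$r2, r3 = rt$r3, r4 = rt$r4, r5 = rt$r5, r6 = rt$r6,
      aix = compute_aix(iv$sp_a, iv$pi_a, f$pi_order),
      fwhm = compute_fwhm(p),
      rmse = compute_rmse(resampled[[i]], mean_pulse))
  }
  out <- do.call(rbind, rows)
  out$rmssd_sp_t <- compute_rmssd(out$sp_t)
  out$rmssd_sp_a <- compute_rmssd(out$sp_a)
  rmssd_or_na <- function(v) if (sum(!is.na(v)) >= 2) compute_rmssd(v) else NA_real_
  out$rmssd_pi_t <- rmssd_or_na(out$pi_t)
  out$rmssd_pi_a <- rmssd_or_na(out$pi_a)
  out$rmssd_dw_t <- rmssd_or_na(out$dw_t)
  out$rmssd_dw_a <- rmssd_or_na(out$dw_a)
  out <- out[, feature_columns()]
  out$subject <- subject
  out$class <- label
  out
}

#' Assemble the feature table across segments
#'
#' One row per non-anomalous pulse, columns in the canonical order (the
#' selected attribute list first), a `subject` column, and a `class` column
#' when labels are given. Under the paper-parity convention missing
#' fiducial-derived values are exported as 0, mirroring the null-timing rule
#' used for histogram export; otherwise explicit `NA` markers are kept.
#'
#' @param segments List of segments; each is a list with `pulses` (list of
#'   normalized `apw_pulse`), optional `label` and `subject`.
#' @param paper_parity Replace missing values by 0 (default TRUE).
#' @param detect_args List of arguments forwarded to [detect_fiducials()].
#' @param block_size Number of beats per analysis segment: each subject's
#'   pulse train is subdivided into blocks of this size and the variability
#'   statistics (RMSSD, RMSE, FWHM reference) are computed per block, as
#'   they would be over successive stretches of a recording. `Inf` keeps
#'   whole subjects as single segments.
#' @return An `apw_feature_table` (data frame).
#' @export
build_feature_table <- function(segments, paper_parity = TRUE,
                                detect_args = list(), block_size = 15) {
  blocks <- list()
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    subj <- if (is.null(seg$subject)) paste0("S", i) else seg$subject
    np <- length(seg$pulses)
    nblk <- max(1, floor(np / block_size))
    cut_id <- pmin(ceiling(seq_len(np) / block_size), nblk)
    for (b in unique(cut_id)) {
      blocks[[length(blocks) + 1]] <- list(
        pulses = seg$pulses[cut_id == b],
        label = seg$label, subject = subj)
    }
  }
  tabs <- lapply(blocks, function(seg) {
    segment_features(seg$pulses,
                     label = if (is.null(seg$label)) NA_integer_ else seg$label,
                     subject = seg$subject,
                     detect_args = detect_args)
  })
  tabs <- Filter(Negate(is.null), tabs)
  if (!length(tabs)) stop("no usable segments")
  out <- do.call(rbind, tabs)
  if (paper_parity) {
    num <- setdiff(names(out), c("subject", "class"))
    for (cn in num) out[[cn]][is.na(out[[cn]])] <- 0
  }
  class(out) <- c("apw_feature_table", "data.frame")
  attr(out, "paper_parity") <- paper_parity
  out
}
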