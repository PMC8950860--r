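signal_rate <- function(series, rate = NULL) {
  r <- if (!is.null(rate)) rate else attr(series, "rate")
  if (is.null(r)) {
    dt <- diff(series$time)
    r <- 1 / stats::median(dt)
  }
  r
}

channel_cols <- function(series) setdiff(names(series), "time")

#' Fill flagged marker gaps by cubic-spline interpolation
#'
#' Missing samples (NA) are replaced channel by channel with the value of the
#' interpolating cubic spline through the observed samples. Gaps longer than
#' `max_gap` or touching either end of the series cannot be filled reliably
#' and raise an error naming the channel and time.
#'
#' @param series Tibble with a `time` column and one or more channels;
#'   missing samples are NA.
#' @param max_gap Longest fillable gap (s).
#' @param rate Sampling rate (Hz); inferred from `time` if omitted.
#' @return The series with all NAs replaced; other samples untouched.
#' @export
fill_gaps <- function(series, max_gap = 0.5, rate = NULL) {
  rate <- signal_rate(series, rate)
  out <- series
  for (ch in channel_cols(series)) {
    x <- series[[ch]]
    if (!anyNA(x)) next
    na <- is.na(x)
    runs <- rle(na)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (i in which(runs$values)) {
      if (starts[i] == 1L || ends[i] == length(x)) {
        abort(sprintf("Gap at series edge in channel '%s' (t = %.3f s): cannot fill.",
                      ch, series$time[starts[i]]))
      }
      if (runs$lengths[i] / rate > max_gap) {
        abort(sprintf("Gap of %.3f s in channel '%s' (t = %.3f s) exceeds max_gap = %g s.",
                      runs$lengths[i] / rate, ch, series$time[starts[i]], max_gap))
      }
    }
    f <- splinefun(series$time[!na], x[!na], method = "fmm")
    out[[ch]][na] <- f(series$time[na])
  }
  out
}

butter_coefs <- function(cutoff, rate, order) {
  if (cutoff >= rate / 2) abort("Filter cut-off must be below the Nyquist frequency.")
  signal::butter(order, cutoff / (rate / 2), type = "low")
}

# forward-backward filtering with odd-reflection padding of three filter
# lengths and steady-state initial conditions (the filter has unit DC gain,
# so the steady state for a constant input equals that constant), cancelling
# phase distortion and suppressing edge transients
filtfilt_padded <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1L, 3L * max(length(a), length(b)))
  front <- 2 * x[1] - x[seq(pad + 1, 2)]
  back <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xp <- c(front, x, back)
  one_pass <- function(z) {
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1], length(b) - 1),
                              init.y = rep(z[1], length(a) - 1)))
  }
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Zero-lag Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass filter forward and backward (zero phase
#' shift, unit DC gain, squared magnitude response) to every channel. Edges
#' are mitigated by odd-reflection padding.
#'
#' @inheritParams fill_gaps
#' @param cutoff Cut-off frequency (Hz), below Nyquist.
#' @param order Filter order of each pass (default 4).
#' @return The filtered series (same shape).
#' @export
lowpass_zero_lag <- function(series, cutoff, order = 4, rate = NULL) {
  rate <- signal_rate(series, rate)
  bf <- butter_coefs(cutoff, rate, order)
  out <- series
  for (ch in channel_cols(series)) {
    if (anyNA(series[[ch]])) {
      abort(sprintf("Channel '%s' contains NA; fill gaps before filtering.", ch))
    }
    out[[ch]] <- filtfilt_padded(bf$b, bf$a, series[[ch]])
  }
  out
}

#' Resample a series to a higher rate by spline interpolation
#'
#' Evaluates the interpolating cubic spline of each channel on a uniform
#' grid at `target_rate` spanning the same time interval. Original samples
#' are reproduced exactly at coincident timestamps; `target_rate == rate`
#' returns the input unchanged.
#'
#' @inheritParams fill_gaps
#' @param target_rate Target sampling rate (Hz), at least the input rate.
#' @return The resampled series with a `rate` attribute set to `target_rate`.
#' @export
resample_to <- function(series, target_rate, rate = NULL) {
  rate <- signal_rate(series, rate)
  if (target_rate < rate) abort("target_rate must be >= the input rate.")
  if (target_rate == rate) {
    attr(series, "rate") <- rate
    return(series)
  }
  t0 <- series$time[1]
  t1 <- series$time[nrow(series)]
  new_time <- t0 + seq(0, floor((t1 - t0) * target_rate)) / target_rate
  out <- tibble(time = new_time)
  for (ch in channel_cols(series)) {
    f <- splinefun(series$time, series[[ch]], method = "fmm")
    out[[ch]] <- f(new_time)
  }
  attr(out, "rate") <- target_rate
  out
}

#' Estimate the inter-stream clock offset from the synchronisation taps
#'
#' Differentiates the vertical marker channel twice (central differences),
#' windows both series around the tap artefacts, and locates the lag
#' maximising the normalised cross-correlation with the IMU vertical
#' acceleration. Positive lag means the IMU stream leads (an event appears
#' earlier in the IMU stream than in the marker stream).
#'
#' @param marker_vertical Numeric vector: vertical (z) marker coordinate of
#'   the tapped IMU's node, already resampled to the common rate.
#' @param imu_z_accel Numeric vector: z-acceleration of the same IMU.
#' @param rate Common sampling rate (Hz).
#' @param window Two-element time window (s) containing the taps.
#' @param max_lag Largest |lag| searched (s).
#' @return List of class `resp_lag`: `lag` (s), `peak` (normalised
#'   cross-correlation at the optimum).
#' @export
estimate_lag <- function(marker_vertical, imu_z_accel, rate,
                         window = c(0, 7), max_lag = 1.5) {
  d2 <- c(0, diff(marker_vertical, differences = 2), 0) * rate^2
  idx <- seq_along(d2) / rate
  L <- round(max_lag * rate)
  win <- which(idx >= window[1] & idx <= window[2])
  if (length(win) < 2 * L + 10) abort("Sync window too short for the requested max_lag.")
  x <- d2[win]
  lags <- -L:L
  cc <- vapply(lags, function(k) {
    j <- win - k
    ok <- j >= 1 & j <= length(imu_z_accel)
    if (sum(ok) < 10) return(NA_real_)
    suppressWarnings(cor(x[ok], imu_z_accel[j[ok]]))
  }, numeric(1))
  if (all(is.na(cc))) abort("no synchronization artifact found")
  best <- which.max(cc)
  peak <- cc[best]
  if (is.na(peak) || peak < 0.5) abort("no synchronization artifact found")
  structure(list(lag = lags[best] / rate, peak = peak), class = "resp_lag")
}

#' @export
print.resp_lag <- function(x, ...) {
  cat(sprintf("<resp_lag> lag = %+.4f s (peak normalized xcorr %.3f)\n", x$lag, x$peak))
  invisible(x)
}

#' Preprocess and time-align one trial
#'
#' Runs the full preprocessing chain on a trial: gap filling, zero-lag
#' low-pass filtering of all marker and IMU channels at the pre-filter
#' cut-off, spline upsampling of markers to the IMU rate, cross-correlation
#' lag estimation on the tap artefacts, stream shifting/cropping to the
#' common overlap, and removal of the initial tap window from the analysis
#' segment.
#'
#' @param trial A `resp_trial` (see [generate_trial()] / [load_trial()]).
#' @param config A [resp_config()].
#' @param drop_tap_window Discard the initial `sync_window` seconds after
#'   alignment (default), so the tap impulses do not contaminate volumes,
#'   PCA or model training. Keep it only to inspect the synchronisation
#'   artefacts themselves.
#' @return The aligned trial: markers and IMUs share the IMU rate, length
#'   and time base; attributes `lag` (the `resp_lag` estimate) and `aligned
#'   = TRUE` are set.
#' @export
align_trial <- function(trial, config = resp_config(), drop_tap_window = TRUE) {
  if (isTRUE(trial$aligned)) {
    # refiltering an aligned trial is permitted; the lag re-estimate should
    # be ~0 but the tap window is already gone, so just return
    return(trial)
  }
  rate <- config$imu_rate
  markers <- fill_gaps(trial$markers, max_gap = config$max_gap,
                       rate = config$marker_rate)
  markers <- lowpass_zero_lag(markers, config$prefilter_cutoff,
                              config$filter_order, rate = config$marker_rate)
  imus <- lowpass_zero_lag(trial$imus, config$prefilter_cutoff,
                           config$filter_order, rate = rate)
  markers <- resample_to(markers, rate, rate = config$marker_rate)

  tap_node <- imu_node_map()[["imu1"]]
  max_lag <- max(abs(cohort_defaults()$clock_offset_range)) + 0.3
  lag <- estimate_lag(
    markers[[paste0(tap_node, "_Z")]], imus[["imu1_az"]], rate,
    window = c(0, config$sync_window + max_lag), max_lag = max_lag
  )
  k <- round(lag$lag * rate)
  n_m <- nrow(markers); n_i <- nrow(imus)
  m_idx <- seq(max(1L, 1L + k), min(n_m, n_i + k))
  i_idx <- m_idx - k
  markers <- markers[m_idx, ]
  imus <- imus[i_idx, ]
  imus$time <- markers$time  # common (marker) clock after alignment

  if (drop_tap_window) {
    keep <- markers$time >= config$sync_window
    markers <- markers[keep, ]
    imus <- imus[keep, ]
  }
  attr(markers, "rate") <- rate
  attr(imus, "rate") <- rate

  out <- trial
  out$markers <- markers
  out$imus <- imus
  out$aligned <- TRUE
  out$lag <- lag
  out
}
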