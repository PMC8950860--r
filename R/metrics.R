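# topographic prominence of local maxima of x at candidate indices idx
peak_prominence <- function(x, idx) {
  vapply(idx, function(i) {
    h <- x[i]
    left <- i; lo_l <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) { if (x[j] < lo_l) lo_l <- x[j]; j <- j - 1L }
    j <- i + 1L; lo_r <- h
    while (j <= length(x) && x[j] <= h) { if (x[j] < lo_r) lo_r <- x[j]; j <- j + 1L }
    h - max(lo_l, lo_r)
  }, numeric(1))
}

local_extrema <- function(x) {
  dx <- diff(x)
  s <- sign(dx)
  # carry the previous non-zero slope through plateaus
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  ds <- diff(s)
  i_max <- which(ds < 0) + 1L
  i_min <- which(ds > 0) + 1L
  list(max = i_max, min = i_min)
}

# greedy minimum-separation suppression: keep the most extreme events first
enforce_distance <- function(idx, value, min_sep) {
  if (!length(idx) || min_sep <= 0) return(idx)
  ord <- order(value, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(idx[kept] - idx[i]) >= min_sep)) {
      kept <- c(kept, i)
    }
  }
  sort(idx[kept])
}

#' Segment breath cycles from a volume channel
#'
#' Identifies the relative minima (inhalation onsets) and maxima
#' (exhalation onsets) of a filtered, demeaned volume channel. Candidate
#' extrema are screened by a minimum topographic prominence (default 0.2 x
#' channel SD) and a minimum separation between same-type events (default
#' 1 s); both guards can be disabled (set to 0) to recover the pure
#' relative-extrema reading. Alternation is enforced by keeping the more
#' extreme of adjacent same-type events, and a leading maximum is dropped
#' so the list starts with a minimum.
#'
#' @param volume Numeric vector (L), ideally low-pass filtered at the model
#'   cut-off and demeaned.
#' @param rate Sampling rate (Hz).
#' @param config A [resp_config()] supplying `peak_prominence_sd` and
#'   `peak_min_distance`; these may also be overridden directly.
#' @param prominence,min_distance Optional overrides (absolute prominence in
#'   L; separation in s).
#' @param time Optional time vector (defaults to `(0:(n-1))/rate`).
#' @return Tibble of class `resp_breaths`: `time`, `value`, `type`
#'   (`"min"`/`"max"`), strictly alternating and starting with a minimum.
#' @export
segment_breaths <- function(volume, rate, config = resp_config(),
                            prominence = NULL, min_distance = NULL,
                            time = NULL) {
  if (is.null(time)) time <- (seq_along(volume) - 1) / rate
  if (is.null(prominence)) prominence <- config$peak_prominence_sd * sd(volume)
  if (is.null(min_distance)) min_distance <- config$peak_min_distance
  ext <- local_extrema(volume)
  i_max <- ext$max; i_min <- ext$min
  if (prominence > 0) {
    i_max <- i_max[peak_prominence(volume, i_max) >= prominence]
    i_min <- i_min[peak_prominence(-volume, i_min) >= prominence]
  }
  sep <- round(min_distance * rate)
  i_max <- enforce_distance(i_max, volume[i_max], sep)
  i_min <- enforce_distance(i_min, -volume[i_min], sep)

  ev <- rbind(
    data.frame(idx = i_min, type = rep("min", length(i_min))),
    data.frame(idx = i_max, type = rep("max", length(i_max)))
  )
  ev <- ev[order(ev$idx), , drop = FALSE]
  # collapse runs of same-type events, keeping the most extreme
  if (nrow(ev) > 1) {
    keep <- rep(TRUE, nrow(ev))
    i <- 1L
    while (i < nrow(ev)) {
      j <- i
      while (j < nrow(ev) && ev$type[j + 1] == ev$type[i]) j <- j + 1L
      if (j > i) {
        run <- i:j
        vals <- volume[ev$idx[run]]
        best <- if (ev$type[i] == "max") run[which.max(vals)] else run[which.min(vals)]
        keep[setdiff(run, best)] <- FALSE
      }
      i <- j + 1L
    }
    ev <- ev[keep, , drop = FALSE]
  }
  if (nrow(ev) && ev$type[1] == "max") ev <- ev[-1, , drop = FALSE]
  n_min <- sum(ev$type == "min")
  if (n_min < 3 || nrow(ev) < 5) {
    abort("Fewer than 2 complete breath cycles found in the volume channel.")
  }
  out <- tibble(time = time[ev$idx], value = volume[ev$idx], type = ev$type)
  class(out) <- c("resp_breaths", class(out))
  attr(out, "duration") <- time[length(time)] - time[1]
  out
}

#' Respiratory parameters from breath events
#'
#' Computes, over complete min-max-min cycles: `DI` (mean inhalation
#' duration, min to next max), `DE` (mean exhalation duration, max to next
#' min), `VI`/`VE` (mean volume rise/fall), and `RR` (default 60 / mean
#' min-to-min period; set `rr_from = "count"` for the raw cycle count per
#' elapsed minute). Incomplete leading or trailing phases are discarded.
#'
#' @param events A `resp_breaths` tibble.
#' @param duration Window length (s), used by the `"count"` RR variant;
#'   defaults to the events' recorded span.
#' @param rr_from `"period"` or `"count"`.
#' @return One-row tibble: `RR` (breaths/min), `DI`, `DE` (s), `VI`, `VE`
#'   (L), `cycles`.
#' @export
respiratory_parameters <- function(events, duration = attr(events, "duration"),
                                   rr_from = c("period", "count")) {
  rr_from <- match.arg(rr_from)
  mins <- which(events$type == "min")
  if (length(mins) < 3) abort("At least 2 complete cycles are required.")
  t <- events$time; v <- events$value
  di <- de <- vi <- ve <- periods <- numeric(0)
  for (i in head(seq_along(mins), -1)) {
    a <- mins[i]; b <- mins[i + 1]
    if (b != a + 2) next  # not a clean min-max-min triplet
    m <- a + 1
    di <- c(di, t[m] - t[a]); de <- c(de, t[b] - t[m])
    vi <- c(vi, v[m] - v[a]); ve <- c(ve, v[m] - v[b])
    periods <- c(periods, t[b] - t[a])
  }
  if (length(periods) < 2) abort("At least 2 complete cycles are required.")
  rr <- if (rr_from == "period") 60 / mean(periods)
        else 60 * length(periods) / duration
  tibble(RR = rr, DI = mean(di), DE = mean(de),
         VI = mean(vi), VE = mean(ve), cycles = length(periods))
}

#' Relative errors between measured and estimated respiratory parameters
#'
#' @param measured,estimated One-row parameter tibbles from
#'   [respiratory_parameters()].
#' @return One-row tibble `dRR`, `dDI`, `dDE`, `dVI`, `dVE`: signed relative
#'   errors in percent, `100 * (estimated - measured) / measured`.
#' @export
relative_errors <- function(measured, estimated) {
  out <- lapply(c("RR", "DI", "DE", "VI", "VE"), function(p) {
    m <- measured[[p]]
    if (!is.finite(m) || m == 0) abort(sprintf("Measured %s must be nonzero.", p))
    100 * (estimated[[p]] - m) / m
  })
  setNames(as_tibble(setNames(out, paste0("d", c("RR", "DI", "DE", "VI", "VE")))),
           paste0("d", c("RR", "DI", "DE", "VI", "VE")))
}

#' Descriptive summary of LOOCV error reports
#'
#' Mean and standard deviation of each relative-error metric per group
#' (descriptive only). Both the mean of signed errors (`mean`, the bar
#' height of a mean-error plot, with `abs_mean` its magnitude) and the mean
#' of absolute errors (`mean_abs`) are reported; groups of size 1 are
#' flagged by `n = 1` with `sd = NA`.
#'
#' @param errors Error tibble from [run_loocv()] (or several stacked).
#' @param by Grouping columns (default sex, compartment, model).
#' @return Tidy tibble: grouping columns, `metric`, `n`, `mean`, `sd`,
#'   `abs_mean`, `mean_abs`.
#' @export
summarize_cohort <- function(errors, by = c("sex", "compartment", "model")) {
  metrics <- paste0("d", c("RR", "DI", "DE", "VI", "VE"))
  long <- tidyr::pivot_longer(errors[, c(by, metrics)], all_of(metrics),
                              names_to = "metric", values_to = "value")
  long %>%
    group_by(across(all_of(c(by, "metric")))) %>%
    summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) sd(.data$value) else NA_real_,
      abs_mean = abs(mean(.data$value)),
      mean_abs = mean(abs(.data$value)),
      .groups = "drop"
    )
}
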