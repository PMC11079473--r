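# IED-triggered average potentials (IED-TP): epochs of the other site's
# signal in a +/-500 ms window time-locked to detected IED peaks, their
# pointwise average, peak-latency extraction against the pre-trigger
# baseline, and the follower/preceder/no-connection sign convention.

#' Extract peri-trigger epochs
#'
#' Each epoch is time-locked so that the trigger sample sits at 0 ms.
#' A trigger at `t` seconds maps to sample `round(t * fs)` (0-based), and
#' the epoch covers `fs * window_s` samples on each side (inclusive).
#' Triggers closer than `window_s` to either record edge are dropped and
#' counted.
#'
#' @param x Numeric signal vector (one channel).
#' @param fs Sampling rate, Hz.
#' @param trigger_times_s Trigger times, seconds.
#' @param window_s Half-window, seconds (default 0.5).
#' @return Matrix (epochs x samples) with attributes `fs`, `n_dropped`,
#'   `time_ms` (sample latencies).
#' @export
extract_epochs <- function(x, fs, trigger_times_s, window_s = 0.5) {
  h <- round(window_s * fs)
  centre <- round(trigger_times_s * fs) + 1L          # 1-based centre sample
  ok <- centre - h >= 1L & centre + h <= length(x)
  n_drop <- sum(!ok)
  centre <- centre[ok]
  if (!length(centre))
    stopf("no usable triggers: all %d are within %g s of a record edge",
          n_drop, window_s)
  ep <- t(vapply(centre, function(c0) x[(c0 - h):(c0 + h)],
                 numeric(2L * h + 1L)))
  attr(ep, "fs") <- fs
  attr(ep, "n_dropped") <- n_drop
  attr(ep, "time_ms") <- (seq_len(2L * h + 1L) - h - 1L) / fs * 1000
  ep
}

#' Average epochs into a triggered-average potential
#'
#' Pointwise mean across epochs; the baseline SD is computed on the
#' -500..-250 ms stretch of the average (the pre-trigger half furthest
#' from the response).
#'
#' @param epochs Epoch matrix from [extract_epochs()].
#' @return A `triggered_average`: `waveform`, `time_ms`, `n_triggers`,
#'   `baseline_sd`, `fs`.
#' @export
average_epochs <- function(epochs) {
  stopifnot(is.matrix(epochs), nrow(epochs) >= 1L)
  w <- colMeans(epochs)
  tm <- attr(epochs, "time_ms")
  bl <- tm <= -250
  structure(list(waveform = w, time_ms = tm,
                 n_triggers = nrow(epochs),
                 baseline_sd = stats::sd(w[bl]),
                 fs = attr(epochs, "fs")),
            class = "triggered_average")
}

#' @export
print.triggered_average <- function(x, ...) {
  cat(sprintf("<triggered average>: n=%d, baseline SD %.3g uV\n",
              x$n_triggers, x$baseline_sd))
  invisible(x)
}

#' Find the IED-TP peak latency of a triggered average
#'
#' Latency (ms, signed) of the maximal-absolute extremum exceeding
#' `peak_threshold` times the baseline SD, excluding `+/-min_lag_ms`
#' around 0 (sub-resolution latencies cannot carry a direction). Returns
#' `NA` when no suprathreshold peak exists ("no detectable IED-TP").
#'
#' @param avg A `triggered_average`.
#' @param peak_threshold Multiples of baseline SD (default 4).
#' @param min_lag_ms Dead zone around 0 ms (default 2, the smallest
#'   observed follower lag).
#' @return Latency in ms, or `NA_real_`.
#' @export
find_iedtp_peak <- function(avg, peak_threshold = 4, min_lag_ms = 2) {
  stopifnot(inherits(avg, "triggered_average"))
  w <- avg$waveform
  ok <- abs(avg$time_ms) >= min_lag_ms &
    abs(w) >= peak_threshold * avg$baseline_sd
  if (!any(ok)) return(NA_real_)
  i <- which(ok)[which.max(abs(w[ok]))]
  avg$time_ms[i]
}

#' Classify a condition's thalamo-cortical relationship
#'
#' The ANT is a follower when the scalp-triggered thalamic IED-TP has
#' positive latency, or the thalamus-triggered scalp IED-TP has negative
#' latency; the converse sign patterns make it a preceder. No detectable
#' peak means no connection. Lags are reported as absolute ms.
#'
#' @param direction `"scalp->thal"` or `"thal->scalp"` (trigger -> target).
#' @param latency_ms Signed latency from [find_iedtp_peak()], or `NA`.
#' @param min_lag_ms Latencies below this magnitude are `not_evaluable`
#'   (sign noise at 0 ms cannot be classified).
#' @return List: `direction`, `category`, `lag_ms` (absolute, `NA` unless
#'   follower/preceder).
#' @export
classify_connection <- function(direction = c("scalp->thal", "thal->scalp"),
                                latency_ms, min_lag_ms = 2) {
  direction <- match.arg(direction)
  if (is.na(latency_ms))
    return(list(direction = direction, category = "no_connection",
                lag_ms = NA_real_))
  if (abs(latency_ms) < min_lag_ms)
    return(list(direction = direction, category = "not_evaluable",
                lag_ms = NA_real_))
  thal_follows <- (direction == "scalp->thal" && latency_ms > 0) ||
    (direction == "thal->scalp" && latency_ms < 0)
  list(direction = direction,
       category = if (thal_follows) "follower" else "preceder",
       lag_ms = abs(latency_ms))
}

# Target channel for one direction: the bipolar channel of the target site
# with the largest absolute peak in its own average (channel selection is a
# package design choice; the source material does not state one).
best_target_average <- function(view, cols, fs, triggers, window_s = 0.5) {
  best <- NULL
  best_amp <- -Inf
  for (j in cols) {
    ep <- extract_epochs(view$signals[, j], fs, triggers, window_s)
    avg <- average_epochs(ep)
    amp <- max(abs(avg$waveform))
    if (amp > best_amp) { best_amp <- amp; best <- avg }
  }
  best
}

#' Enumerate the 8 per-patient conditions from signals
#'
#' 2 sides x 2 states x 2 directions. A condition is evaluable when the
#' side's lead hit the ANT and the trigger site has at least `min_triggers`
#' detected IEDs; otherwise it is `not_evaluable` (missing IEDs or missing
#' ANT hit) and excluded from category fractions.
#'
#' @param rec A [recording()].
#' @param events Event table from [detect_ieds()].
#' @param hits Named logical, `c(left = , right = )`: ANT hit per side.
#' @param params A [detection_params()] (unused except for future tuning).
#' @param peak_threshold,min_lag_ms Passed to [find_iedtp_peak()].
#' @param min_triggers Minimum trigger count per condition (default 5).
#' @return Data frame: one row per condition with `side`, `state`,
#'   `direction`, `category`, `lag_ms`, `n_triggers`.
#' @export
enumerate_conditions <- function(rec, events, hits,
                                 params = detection_params(),
                                 peak_threshold = 4, min_lag_ms = 2,
                                 min_triggers = 5) {
  scalp_bip <- tryCatch(make_bipolar(rec, "scalp-longitudinal"),
                        error = function(e) NULL)
  dbs_bip <- make_bipolar(rec, "dbs-adjacent")
  fs <- rec$fs
  rows <- list()
  for (side in c("left", "right")) {
    for (state in c("sleep", "awake")) {
      for (direction in c("scalp->thal", "thal->scalp")) {
        trig_site <- if (direction == "scalp->thal")
          paste0("scalp-", side) else paste0("thal-", side)
        trg <- events$time_s[events$site == trig_site &
                               events$state == state]
        row <- data.frame(side = side, state = state, direction = direction,
                          category = "not_evaluable", lag_ms = NA_real_,
                          n_triggers = length(trg))
        if (isTRUE(hits[[side]]) && length(trg) >= min_triggers) {
          target_view <- if (direction == "scalp->thal") dbs_bip else scalp_bip
          cols <- if (direction == "scalp->thal")
            view_side(dbs_bip, side) else view_side(scalp_bip, side)
          if (!is.null(target_view) && length(cols)) {
            avg <- tryCatch(
              best_target_average(target_view, cols, fs, trg),
              error = function(e) NULL)
            if (!is.null(avg)) {
              lat <- find_iedtp_peak(avg, peak_threshold, min_lag_ms)
              cl <- classify_connection(direction, lat, min_lag_ms)
              row$category <- cl$category
              row$lag_ms <- cl$lag_ms
            }
          }
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d
}

#' Summarize connection results over evaluable conditions
#'
#' @param results Data frame with at least `category` and `lag_ms`
#'   (`not_evaluable` rows are excluded from the denominator).
#' @return List: `n_evaluable`, counts and percentages (half-up integers)
#'   per category, and mean absolute lags for followers and preceders.
#' @export
summarize_connections <- function(results) {
  ev <- results[results$category != "not_evaluable", , drop = FALSE]
  n <- nrow(ev)
  cats <- c("follower", "preceder", "no_connection")
  counts <- vapply(cats, function(k) sum(ev$category == k), numeric(1))
  pct <- if (n > 0) round_half_up(100 * counts / n) else rep(NA_real_, 3L)
  names(pct) <- cats
  list(n_evaluable = n, counts = counts, percent = pct,
       mean_lag_follower =
         mean(ev$lag_ms[ev$category == "follower"], na.rm = TRUE),
       mean_lag_preceder =
         mean(ev$lag_ms[ev$category == "preceder"], na.rm = TRUE))
}
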