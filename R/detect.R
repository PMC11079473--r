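# Automated surrogate for the visual IED criteria: a spike is a fast
# (<50 ms) component prominent against the background in both montages,
# with a bipolar phase reversal and a following slow wave; an outstanding
# bipolar transient failing phase reversal or monopolar prominence is a
# sharp transient, regardless of its fast-component duration.
#
# The 1/f background concentrates variance at very low frequencies, so all
# amplitude criteria are evaluated on running-median detrended signals:
# a 0.4 s window for the fast component (a <=50 ms transient occupies a
# small fraction of it and passes through), a 1.6 s window when assessing
# the slow wave. Per-view detrended matrices and background-SD tracks are
# cached on the view so repeated classification stays cheap.

#' Detection parameters
#'
#' @param prominence_threshold Candidate threshold, multiples of the robust
#'   background SD (MAD * 1.4826). "Prominent amplitude" is not quantified
#'   by the visual criteria; 6 is this package's default and must be
#'   reported with results.
#' @param fast_max_ms Upper bound of a spike's fast component (50 ms).
#' @param slow_search_ms Two-element window after the fast peak searched
#'   for the slow wave, ms.
#' @param slow_area_ratio Slow wave is present when the opposite-polarity
#'   area in the search window exceeds this fraction of the fast-component
#'   area.
#' @param min_separation_ms Candidates closer than this merge into one.
#' @param background_window_s Length of the non-overlapping blocks on which
#'   the robust background SD is estimated.
#' @param phase_rev_window_ms Half-window around the peak in which opposite
#'   deflections on adjacent bipolar channels count as a phase reversal.
#' @param detrend_fast_s,detrend_slow_s Running-median windows (s) used to
#'   remove background drift before fast-component and slow-wave
#'   assessment.
#' @param absorb_window_s,absorb_ratio Afterglow absorption: a candidate is
#'   folded into a neighbour within `absorb_window_s` seconds whose
#'   prominence is at least `absorb_ratio` times larger (the slow-wave and
#'   recovery phases of one complex are not separate events).
#' @return A `detection_params` list.
#' @export
detection_params <- function(prominence_threshold = 6, fast_max_ms = 50,
                             slow_search_ms = c(80, 400),
                             slow_area_ratio = 0.25,
                             min_separation_ms = 200,
                             background_window_s = 60,
                             phase_rev_window_ms = 20,
                             detrend_fast_s = 0.4, detrend_slow_s = 1.6,
                             absorb_window_s = 1, absorb_ratio = 5) {
  p <- list(prominence_threshold = prominence_threshold,
            fast_max_ms = fast_max_ms, slow_search_ms = slow_search_ms,
            slow_area_ratio = slow_area_ratio,
            min_separation_ms = min_separation_ms,
            background_window_s = background_window_s,
            phase_rev_window_ms = phase_rev_window_ms,
            detrend_fast_s = detrend_fast_s,
            detrend_slow_s = detrend_slow_s,
            absorb_window_s = absorb_window_s,
            absorb_ratio = absorb_ratio)
  for (nm in c("prominence_threshold", "fast_max_ms", "slow_area_ratio",
               "min_separation_ms", "background_window_s",
               "phase_rev_window_ms", "detrend_fast_s", "detrend_slow_s"))
    assert_scalar_num(p[[nm]], nm, lower = 1e-9)
  structure(p, class = "detection_params")
}

# Running-median detrend (see header comment).
detrend_running_median <- function(x, fs, window_s = 0.4) {
  k <- round(window_s * fs)
  if (k %% 2L == 0L) k <- k + 1L
  if (k < 3L || k >= length(x)) return(x - stats::median(x))
  x - stats::runmed(x, k, endrule = "median")
}

# Robust background SD per sample: MAD * 1.4826 over non-overlapping
# blocks of background_window_s (the sliding window is block-quantized).
background_sd <- function(x, fs, window_s) {
  n <- length(x)
  block <- max(1L, round(window_s * fs))
  nb <- ceiling(n / block)
  sds <- numeric(nb)
  for (b in seq_len(nb)) {
    i <- ((b - 1L) * block + 1L):min(b * block, n)
    sds[b] <- robust_sd(x[i])
  }
  sds[sds == 0] <- max(sds, .Machine$double.eps)
  rep(sds, each = block)[seq_len(n)]
}

# Cached per-view derived matrices. montage_view carries a cache
# environment, so repeated calls reuse the detrended signals.
view_cache <- function(view) {
  if (is.null(view$cache)) stopf("montage view lacks a cache environment")
  view$cache
}

view_detrended <- function(view, params, scale = c("fast", "slow")) {
  scale <- match.arg(scale)
  key <- paste0("hp_", scale)
  cache <- view_cache(view)
  if (is.null(cache[[key]])) {
    win <- if (scale == "fast") params$detrend_fast_s else params$detrend_slow_s
    cache[[key]] <- apply(view$signals, 2L, detrend_running_median,
                          fs = view$fs, window_s = win)
  }
  cache[[key]]
}

# Background SD is estimated on the slow-detrended trace (the signal as a
# reviewer sees it at a ~0.5 Hz display high-pass), not on the heavily
# detrended trace used to measure the fast component: a spike's prominence
# is judged against the ongoing background activity, not against the
# high-frequency residue alone.
view_background <- function(view, params) {
  cache <- view_cache(view)
  if (is.null(cache$bg)) {
    hp <- view_detrended(view, params, "slow")
    cache$bg <- apply(hp, 2L, background_sd, fs = view$fs,
                      window_s = params$background_window_s)
  }
  cache$bg
}

segment_sample_mask <- function(n, fs, segments) {
  if (is.null(segments)) return(rep(TRUE, n))
  keep <- rep(FALSE, n)
  for (r in seq_len(nrow(segments))) {
    i0 <- floor(segments$start_s[r] * fs) + 1L
    i1 <- min(n, ceiling(segments$end_s[r] * fs))
    if (i1 >= i0) keep[i0:i1] <- TRUE
  }
  keep
}

#' Detect IED candidates on a montage view
#'
#' Flags local extrema of the detrended signals whose absolute amplitude
#' exceeds `prominence_threshold` times the robust background SD of their
#' channel, then merges suprathreshold deflections across derived channels
#' within `min_separation_ms` into single candidates (strongest channel
#' wins).
#'
#' @param view A `montage_view`.
#' @param segments Optional segment table (`start_s`, `end_s`) restricting
#'   the search; `NULL` searches the whole record.
#' @param params A [detection_params()].
#' @return Data frame: `time_s`, `channel`, `side`, `amplitude`,
#'   `prominence`, `fast_duration_ms`; zero rows if nothing found.
#' @export
detect_candidates <- function(view, segments = NULL,
                              params = detection_params()) {
  stopifnot(inherits(view, "montage_view"))
  fs <- view$fs
  n <- nrow(view$signals)
  hp <- view_detrended(view, params, "fast")
  bgm <- view_background(view, params)
  mask <- segment_sample_mask(n, fs, segments)
  min_sep <- round(params$min_separation_ms / 1000 * fs)
  cands <- list()
  for (j in seq_len(ncol(hp))) {
    x <- hp[, j]
    z <- abs(x) / bgm[, j]
    hit <- which(z >= params$prominence_threshold & mask)
    if (!length(hit)) next
    brk <- c(0L, which(diff(hit) > min_sep), length(hit))
    for (g in seq_len(length(brk) - 1L)) {
      i <- hit[(brk[g] + 1L):brk[g + 1L]]
      pk <- i[which.max(z[i])]
      cands[[length(cands) + 1L]] <- data.frame(
        time_s = (pk - 1L) / fs,
        channel = view$derivations$name[j],
        side = view$derivations$side[j],
        amplitude = x[pk], prominence = z[pk])
    }
  }
  empty <- data.frame(time_s = numeric(), channel = character(),
                      side = character(), amplitude = numeric(),
                      prominence = numeric(), fast_duration_ms = numeric())
  if (!length(cands)) return(empty)
  d <- do.call(rbind, cands)
  d <- d[order(d$time_s, -d$prominence), ]
  out <- list()
  cluster_t <- -Inf
  cluster_best <- 0L
  flush <- function() if (cluster_best > 0L)
    out[[length(out) + 1L]] <<- d[cluster_best, , drop = FALSE]
  for (r in seq_len(nrow(d))) {
    if (d$time_s[r] - cluster_t > params$min_separation_ms / 1000) {
      flush()
      cluster_best <- r
    } else if (d$prominence[r] > d$prominence[cluster_best]) {
      cluster_best <- r
    }
    cluster_t <- d$time_s[r]
  }
  flush()
  d <- do.call(rbind, out)
  # afterglow absorption: the slow-wave/recovery phase of a strong complex
  # must not surface as its own candidate
  if (nrow(d) > 1L) {
    drop <- vapply(seq_len(nrow(d)), function(r) {
      near <- abs(d$time_s - d$time_s[r]) <= params$absorb_window_s
      any(near & d$prominence >= params$absorb_ratio * d$prominence[r])
    }, logical(1))
    d <- d[!drop, , drop = FALSE]
  }
  d$fast_duration_ms <- vapply(seq_len(nrow(d)), function(r) {
    j <- match(d$channel[r], view$derivations$name)
    measure_fast_width(hp[, j], fs, d$time_s[r], params$fast_max_ms)
  }, numeric(1))
  rownames(d) <- NULL
  d
}

# Pre-event baseline: median of the raw trace over [-6, -2] fast_max
# windows before the peak, which lies outside the spike-and-wave complex.
# Width and area measurements use the raw signal against this baseline;
# running-median detrended traces distort the waveform when the complex
# fills most of the median window.
pre_event_baseline <- function(x, fs, pk, fast_max_ms) {
  lo <- max(1L, pk - round(6 * fast_max_ms / 1000 * fs))
  hi <- max(1L, pk - round(2 * fast_max_ms / 1000 * fs))
  stats::median(x[lo:hi])
}

# Full-width at half-prominence of the deflection at time_s. The
# reference level is the foot of the peak: the larger of the two flanking
# medians ([1, 2] x fast_max on each side), floored at the pre-event
# baseline, so a raised local plateau (or the onset of the following slow
# wave) does not bias the width.
measure_fast_width <- function(x, fs, time_s, fast_max_ms, base = NULL) {
  pk <- round(time_s * fs) + 1L
  half_w <- round(3 * fast_max_ms / 1000 * fs)
  i0 <- max(1L, pk - half_w)
  i1 <- min(length(x), pk + half_w)
  w <- x[i0:i1]
  if (is.null(base)) base <- pre_event_baseline(x, fs, pk, fast_max_ms)
  v <- w - base
  ctr <- pk - i0 + 1L
  s <- sign(v[ctr])
  if (s == 0) s <- 1
  v <- v * s
  fm <- round(fast_max_ms / 1000 * fs)
  lf <- max(1L, ctr - 2L * fm):max(1L, ctr - fm)
  rf <- min(length(v), ctr + fm):min(length(v), ctr + 2L * fm)
  ref <- max(stats::median(v[lf]), stats::median(v[rf]), 0)
  ref <- min(ref, 0.6 * v[ctr])
  half <- ref + (v[ctr] - ref) / 2
  l <- ctr
  while (l > 1L && v[l - 1L] >= half) l <- l - 1L
  r <- ctr
  while (r < length(v) && v[r + 1L] >= half) r <- r + 1L
  frac_l <- if (l > 1L && v[l] != v[l - 1L]) (v[l] - half) / (v[l] - v[l - 1L]) else 0
  frac_r <- if (r < length(v) && v[r] != v[r + 1L]) (v[r] - half) / (v[r] - v[r + 1L]) else 0
  ((r + frac_r) - (l - frac_l)) / fs * 1000
}

window_idx <- function(n, fs, time_s, half_ms) {
  pk <- round(time_s * fs) + 1L
  h <- round(half_ms / 1000 * fs)
  max(1L, pk - h):min(n, pk + h)
}

#' Identify the peak contact of a thalamic event
#'
#' The monopolar channel of the event's lead with the maximal absolute
#' fast-component amplitude around the peak; ties break toward the deepest
#' contact (lowest contact number; channels are stored deepest-first).
#'
#' @param time_s Event time (fast-component peak), s.
#' @param monopolar A monopolar `montage_view`.
#' @param side `"left"` or `"right"`.
#' @param params A [detection_params()].
#' @return Channel label, e.g. `"LTh1"`.
#' @export
peak_contact <- function(time_s, monopolar, side,
                         params = detection_params()) {
  cols <- view_side(monopolar, side)
  if (!length(cols)) stopf("monopolar view has no '%s' channels", side)
  hp <- view_detrended(monopolar, params, "fast")
  idx <- window_idx(nrow(hp), monopolar$fs, time_s,
                    params$phase_rev_window_ms)
  amps <- vapply(cols, function(j) max(abs(hp[idx, j])), numeric(1))
  best <- max(amps)
  monopolar$derivations$name[cols[which(amps >= best * (1 - 1e-9))[1L]]]
}

#' Classify a thalamic candidate as spike, sharp transient, or reject
#'
#' Applies the compound criterion: spike iff the fast component is shorter
#' than `fast_max_ms` AND a slow wave follows within the search window AND
#' the bipolar montage shows a phase reversal AND the monopolar amplitude
#' is prominent. An outstanding transient failing any of these is a sharp
#' transient regardless of its duration; `reject` is reserved for
#' candidates that are prominent in neither montage.
#'
#' @param time_s Candidate time, s.
#' @param side Lead side, `"left"` or `"right"`.
#' @param bipolar,monopolar The two `montage_view`s of the recording.
#' @param params A [detection_params()].
#' @return List: `class` (`"spike"`/`"sharp_transient"`/`"reject"`),
#'   `fast_duration_ms`, `peak_contact`, `has_phase_reversal`,
#'   `has_slow_wave`, `monopolar_prominent`, `prominence`.
#' @export
classify_event <- function(time_s, side, bipolar, monopolar,
                           params = detection_params()) {
  fs <- monopolar$fs
  hp_m <- view_detrended(monopolar, params, "fast")
  bg_m <- view_background(monopolar, params)
  n <- nrow(hp_m)
  contact <- peak_contact(time_s, monopolar, side, params)
  jm <- match(contact, monopolar$derivations$name)
  xm <- hp_m[, jm]
  idx <- window_idx(n, fs, time_s, params$phase_rev_window_ms)
  pk <- idx[which.max(abs(xm[idx]))]
  pk_t <- (pk - 1L) / fs
  prom_m <- abs(xm[pk]) / bg_m[pk, jm]
  monopolar_prominent <- prom_m >= params$prominence_threshold
  # duration and areas are measured on the raw trace against a pre-event
  # baseline (the detrended trace distorts the spike-and-wave complex)
  raw_m <- monopolar$signals[, jm]
  base <- pre_event_baseline(raw_m, fs, pk, params$fast_max_ms)
  width <- measure_fast_width(raw_m, fs, pk_t, params$fast_max_ms, base)
  # phase reversal: opposite-signed deflections > thr/2 * SD on two
  # adjacent bipolar channels of this lead within the window
  hp_b <- view_detrended(bipolar, params, "fast")
  bg_b <- view_background(bipolar, params)
  bcols <- view_side(bipolar, side)
  has_rev <- FALSE
  bip_prom <- 0
  if (length(bcols)) {
    w <- window_idx(n, fs, pk_t, params$phase_rev_window_ms)
    defl <- vapply(bcols, function(j) {
      i <- w[which.max(abs(hp_b[w, j]))]
      z <- abs(hp_b[i, j]) / bg_b[i, j]
      bip_prom <<- max(bip_prom, z)
      if (z >= params$prominence_threshold / 2) sign(hp_b[i, j]) else 0
    }, numeric(1))
    for (k in seq_len(length(defl) - 1L))
      if (defl[k] * defl[k + 1L] < 0) has_rev <- TRUE
  }
  # slow wave: opposite-polarity area in the post-peak search window
  s <- sign(raw_m[pk] - base)
  if (s == 0) s <- 1
  i_fast <- window_idx(n, fs, pk_t, max(width, 1))
  fast_area <- sum(pmax(0, s * (raw_m[i_fast] - base))) / fs
  lo <- min(n, pk + round(params$slow_search_ms[1L] / 1000 * fs))
  hi <- min(n, pk + round(params$slow_search_ms[2L] / 1000 * fs))
  slow_area <- sum(pmax(0, -s * (raw_m[lo:hi] - base))) / fs
  has_slow <- slow_area >= params$slow_area_ratio * fast_area
  outstanding <- bip_prom >= params$prominence_threshold ||
    monopolar_prominent
  cls <- if (width < params$fast_max_ms && has_slow && has_rev &&
             monopolar_prominent) "spike"
  else if (outstanding) "sharp_transient"
  else "reject"
  list(class = cls, fast_duration_ms = width, peak_contact = contact,
       has_phase_reversal = has_rev, has_slow_wave = has_slow,
       monopolar_prominent = monopolar_prominent,
       prominence = max(prom_m, bip_prom))
}

#' Detect and classify IEDs across all sites of a recording
#'
#' Scalp IEDs are detected on the bipolar scalp montage only. Thalamic
#' candidates are pooled from the bipolar and monopolar DBS views (a purely
#' common-mode event is invisible in bipolar) and then classified as spike
#' or sharp transient.
#'
#' @param rec A [recording()].
#' @param params A [detection_params()].
#' @param states Named list of segment tables (e.g. from
#'   [select_segments()]); `NULL` analyses the annotated state intervals
#'   directly.
#' @return Data frame of events: `site`, `state`, `time_s`, `class`,
#'   `peak_contact`, `prominence`, `fast_duration_ms`. Scalp events carry
#'   class `"spike"` (spike/sharp-transient refinement applies to thalamic
#'   events only).
#' @export
detect_ieds <- function(rec, params = detection_params(), states = NULL) {
  if (is.null(states)) {
    ann <- rec$annotations
    states <- list(
      sleep = ann[ann$label == "sleep", c("start_s", "end_s")],
      awake = ann[ann$label == "awake", c("start_s", "end_s")])
    states <- Filter(nrow, states)
  }
  scalp_bip <- tryCatch(make_bipolar(rec, "scalp-longitudinal"),
                        error = function(e) NULL)
  has_dbs <- any(rec$channels$kind %in% c("dbs-left", "dbs-right"))
  dbs_bip <- if (has_dbs) make_bipolar(rec, "dbs-adjacent") else NULL
  dbs_mono <- if (has_dbs) make_monopolar(rec) else NULL
  out <- list()
  for (state in names(states)) {
    segs <- states[[state]]
    if (!is.null(scalp_bip)) {
      sc <- detect_candidates(scalp_bip, segs, params)
      if (nrow(sc)) {
        out[[length(out) + 1L]] <- data.frame(
          site = paste0("scalp-", sc$side), state = state,
          time_s = sc$time_s, class = "spike",
          peak_contact = sc$channel, prominence = sc$prominence,
          fast_duration_ms = sc$fast_duration_ms)
      }
    }
    if (has_dbs) {
      cand <- rbind(detect_candidates(dbs_bip, segs, params),
                    detect_candidates(dbs_mono, segs, params))
      if (nrow(cand)) {
        cand <- cand[order(cand$time_s, -cand$prominence), ]
        # merge bipolar+monopolar duplicates of the same event
        keep <- c(TRUE, diff(cand$time_s) > params$min_separation_ms / 1000)
        grp <- cumsum(keep)
        cand <- do.call(rbind, lapply(split(cand, grp), function(g)
          g[which.max(g$prominence), , drop = FALSE]))
        for (r in seq_len(nrow(cand))) {
          cl <- classify_event(cand$time_s[r], cand$side[r],
                               dbs_bip, dbs_mono, params)
          if (cl$class == "reject") next
          out[[length(out) + 1L]] <- data.frame(
            site = paste0("thal-", cand$side[r]), state = state,
            time_s = cand$time_s[r], class = cl$class,
            peak_contact = cl$peak_contact, prominence = cl$prominence,
            fast_duration_ms = cl$fast_duration_ms)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(site = character(), state = character(),
                      time_s = numeric(), class = character(),
                      peak_contact = character(), prominence = numeric(),
                      fast_duration_ms = numeric()))
  d <- do.call(rbind, out)
  d <- d[order(d$time_s), ]
  rownames(d) <- NULL
  d
}

#' IED rate
#'
#' @param events Event data frame (or anything with `nrow`).
#' @param minutes Analysed minutes; must be > 0.
#' @return Events per minute.
#' @export
ied_rate <- function(events, minutes) {
  assert_scalar_num(minutes, "minutes", lower = 1e-12)
  nrow(events) / minutes
}
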