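# Ground-truthed synthetic scalp + thalamic recordings.
#
# The generator states the world the analysis assumes: 1/f^alpha Gaussian
# background (plus a slow-oscillation mixture in sleep), spike-and-slow-wave
# events placed by state-dependent Poisson processes with >=1 s same-site
# separation, and probabilistic scalp->thalamus coupling with truncated
# normal lags. Thalamic rates default to the observed medians (0.33/min
# sleep, 0.13/min awake).

SIM_SITES <- c("scalp-left", "scalp-right", "thal-left", "thal-right")
SIM_STATES <- c("sleep", "awake")

DEFAULT_RATES <- matrix(
  c(0.26, 0.10,    # scalp-left   sleep, awake
    0.26, 0.10,    # scalp-right
    0.33, 0.13,    # thal-left
    0.33, 0.13),   # thal-right
  nrow = 4, byrow = TRUE,
  dimnames = list(SIM_SITES, SIM_STATES))

SCALP_LEFT  <- c("Fp1", "F3", "C3", "P3", "O1", "F7", "T3", "T5")
SCALP_RIGHT <- c("Fp2", "F4", "C4", "P4", "O2", "F8", "T4", "T6")

#' Simulation configuration
#'
#' @param rates 4x2 matrix of event rates (events/min), rows
#'   `scalp-left`, `scalp-right`, `thal-left`, `thal-right`, columns
#'   `sleep`, `awake`. Defaults emulate the observed medians in the
#'   thalamus (0.33 sleep / 0.13 awake); the awake scalp default is a small
#'   representative nonzero rate (the observed median is 0).
#' @param coupling_probability Fraction of scalp events echoed by a
#'   time-locked thalamic event on the same side; a single value or a
#'   named pair `c(left = , right = )`.
#' @param lag_mean,lag_sd,lag_bounds Truncated-normal lag of the thalamic
#'   echo after the scalp trigger, ms. Defaults 51, 30, c(2, 180).
#' @param noise_sd Background standard deviation, microvolts.
#' @param spectral_exponent Background spectrum follows 1/f^alpha.
#' @param segment_minutes Minutes per state segment; the recording holds
#'   two segments per state (awake, sleep, awake, sleep).
#' @param fs Sampling rate, Hz (default 2048).
#' @param seed Integer seed; with the patient id it keys the RNG stream.
#' @param scalp_template,thal_template [spike_template()]s for inserted
#'   events (amplitudes are free parameters of the stated world).
#' @param st_fraction Fraction of independent thalamic events inserted
#'   common-mode across the lead (no phase reversal), which the classifier
#'   must call sharp transients.
#' @param sleep_osc_amplitude Amplitude (uV) of the 0.5-2 Hz slow-wave
#'   mixture added to sleep segments.
#' @return A `sim_config` list.
#' @export
sim_config <- function(rates = DEFAULT_RATES,
                       coupling_probability = 0.55,
                       lag_mean = 51, lag_sd = 30, lag_bounds = c(2, 180),
                       noise_sd = 10, spectral_exponent = 1.5,
                       segment_minutes = 10, fs = 2048, seed = 1L,
                       scalp_template = spike_template(fast_amplitude = 60,
                                                       slow_amplitude = 30),
                       thal_template = spike_template(),
                       st_fraction = 0.2,
                       sleep_osc_amplitude = noise_sd) {
  rates <- as.matrix(rates)
  if (!all(dim(rates) == c(4L, 2L))) stopf("'rates' must be a 4x2 matrix")
  dimnames(rates) <- list(SIM_SITES, SIM_STATES)
  if (any(rates < 0)) stopf("rates must be >= 0")
  if (length(coupling_probability) == 1L)
    coupling_probability <- c(left = unname(coupling_probability),
                              right = unname(coupling_probability))
  if (!all(c("left", "right") %in% names(coupling_probability)) ||
      any(coupling_probability < 0 | coupling_probability > 1))
    stopf("coupling_probability must be in [0, 1] (scalar or left/right pair)")
  assert_scalar_num(lag_mean, "lag_mean")
  assert_scalar_num(lag_sd, "lag_sd", lower = 0)
  if (length(lag_bounds) != 2L || any(abs(lag_bounds) > 500) ||
      lag_bounds[1L] > lag_bounds[2L])
    stopf("lag_bounds must be an ordered pair within [-500, 500] ms")
  assert_scalar_num(fs, "fs", lower = 1e-9)
  assert_scalar_num(segment_minutes, "segment_minutes", lower = 1e-9)
  assert_scalar_num(st_fraction, "st_fraction", 0, 1)
  structure(list(rates = rates, coupling_probability = coupling_probability,
                 lag_mean = lag_mean, lag_sd = lag_sd, lag_bounds = lag_bounds,
                 noise_sd = noise_sd, spectral_exponent = spectral_exponent,
                 segment_minutes = segment_minutes, fs = fs,
                 seed = as.integer(seed),
                 scalp_template = scalp_template,
                 thal_template = thal_template,
                 st_fraction = st_fraction,
                 sleep_osc_amplitude = sleep_osc_amplitude),
            class = "sim_config")
}

#' Gaussian 1/f^alpha noise
#'
#' Spectrally shaped white noise: the DFT of a white draw is weighted by
#' f^(-alpha/2) and inverted, then scaled to standard deviation `sd`.
#'
#' @param n Number of samples.
#' @param fs Sampling rate, Hz.
#' @param alpha Spectral exponent.
#' @param sd Target standard deviation.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, fs, alpha = 1.5, sd = 1) {
  if (n < 2L) return(stats::rnorm(n, 0, sd))
  m <- 2^ceiling(log2(n))
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  f <- c(1, seq_len(m - 1L)) * fs / m          # DC kept at weight of bin 1
  f <- pmin(f, fs - f + fs / m)                # mirror for negative freqs
  W <- W * f^(-alpha / 2)
  x <- Re(stats::fft(W, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x * sd / stats::sd(x)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n * 2L + 10L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Poisson event times within [0, total_s), thinned to >= min_sep seconds
# between consecutive same-site events and kept `margin` from the edges.
poisson_times <- function(rate_per_min, total_s, min_sep = 1, margin = 0.6) {
  n <- stats::rpois(1L, rate_per_min * total_s / 60)
  if (n == 0L) return(numeric(0))
  t <- sort(stats::runif(n, margin, max(margin, total_s - margin)))
  keep <- logical(length(t))
  last <- -Inf
  for (i in seq_along(t)) {
    if (t[i] - last >= min_sep) { keep[i] <- TRUE; last <- t[i] }
  }
  t[keep]
}

# Map a within-state offset to absolute record time given the state's
# segment table (two segments per state).
state_offset_to_abs <- function(offset_s, segs) {
  lens <- segs$end_s - segs$start_s
  cum <- cumsum(lens)
  i <- findInterval(offset_s, c(0, cum[-length(cum)] + 1e-12)) # segment index
  segs$start_s[i] + (offset_s - c(0, cum)[i])
}

#' Simulate a ground-truthed recording
#'
#' Produces a recording with two segments per state (awake, sleep, awake,
#' sleep), scalp and thalamic events placed by per-site/state Poisson
#' processes, and coupled thalamic echoes lagging their scalp trigger by a
#' truncated-normal draw. Coupled echoes are drawn out of (not on top of)
#' the thalamic rate budget, so per-site counts stay Poisson at the
#' configured rates. Same seed and config give identical output.
#'
#' @param config A [sim_config()].
#' @param patient_id Patient identifier; combined with `config$seed` to key
#'   an independent RNG stream per patient.
#' @return List with elements `recording` and `ground_truth` (data frame:
#'   `event_id`, `site`, `state`, `time_s`, `channel`, `class`,
#'   `linked_id`, `true_lag_ms`).
#' @export
simulate_recording <- function(config, patient_id = 1L) {
  stopifnot(inherits(config, "sim_config"))
  pid_num <- if (is.numeric(patient_id)) as.integer(patient_id) else
    sum(utf8ToInt(as.character(patient_id)))
  set.seed((config$seed %% 1000003L) * 2011L + pid_num * 7L)
  fs <- config$fs
  seg_s <- round(config$segment_minutes * 60)
  layout <- data.frame(
    label = c("awake", "sleep", "awake", "sleep"),
    start_s = seg_s * 0:3, end_s = seg_s * 1:4)
  total_n <- as.integer(4 * seg_s * fs)
  labels <- c(SCALP_LEFT, SCALP_RIGHT,
              paste0("LTh", 0:3), paste0("RTh", 0:3))
  kinds <- c(rep("scalp", 16L), rep("dbs-left", 4L), rep("dbs-right", 4L))
  data <- matrix(0, nrow = total_n, ncol = length(labels))
  for (j in seq_along(labels)) {
    data[, j] <- pink_noise(total_n, fs, config$spectral_exponent,
                            config$noise_sd)
  }
  # slow-wave mixture in sleep segments
  if (config$sleep_osc_amplitude > 0) {
    for (r in which(layout$label == "sleep")) {
      idx <- (layout$start_s[r] * fs + 1L):(layout$end_s[r] * fs)
      tt <- (seq_along(idx) - 1L) / fs
      freqs <- stats::runif(3L, 0.5, 2)
      phases <- stats::runif(3L, 0, 2 * pi)
      osc <- rowSums(vapply(1:3, function(k)
        sin(2 * pi * freqs[k] * tt + phases[k]), numeric(length(tt))))
      osc <- osc / 3 * config$sleep_osc_amplitude
      for (j in seq_along(labels)) data[idx, j] <- data[idx, j] + osc
    }
  }
  state_segs <- function(state) layout[layout$label == state, , drop = FALSE]
  gt <- list()
  ev_id <- 0L
  add_event <- function(site, state, time_s, channel, class,
                        linked_id = NA_integer_, true_lag_ms = NA_real_) {
    ev_id <<- ev_id + 1L
    gt[[length(gt) + 1L]] <<- data.frame(
      event_id = ev_id, site = site, state = state, time_s = time_s,
      channel = channel, class = class, linked_id = linked_id,
      true_lag_ms = true_lag_ms)
    ev_id
  }
  insert_wave <- function(chan_labels, weights, time_s, w) {
    i0 <- round(time_s * fs) + 1L - attr(w, "peak_index") + 1L
    idx <- i0:(i0 + length(w) - 1L)
    ok <- idx >= 1L & idx <= total_n
    cols <- match(chan_labels, labels)
    for (k in seq_along(cols))
      data[idx[ok], cols[k]] <<- data[idx[ok], cols[k]] + weights[k] * w[ok]
  }
  scalp_w <- make_spike_template(config$scalp_template, fs)
  thal_w <- make_spike_template(config$thal_template, fs)
  scalp_events <- list()
  for (site in c("scalp-left", "scalp-right")) {
    chans <- if (site == "scalp-left") SCALP_LEFT else SCALP_RIGHT
    # stable scalp focus per side, like the thalamic generator
    centre <- sample(seq_along(chans), 1L)
    for (state in SIM_STATES) {
      segs <- state_segs(state)
      total_s <- sum(segs$end_s - segs$start_s)
      off <- poisson_times(config$rates[site, state], total_s)
      if (!length(off)) next
      tt <- state_offset_to_abs(off, segs)
      for (t in tt) {
        nb <- intersect(centre + c(-1L, 1L), seq_along(chans))
        sel <- c(centre, nb)
        wts <- c(1, rep(0.5, length(nb)))     # distance-decayed spread
        insert_wave(chans[sel], wts, t, scalp_w)
        id <- add_event(site, state, t, chans[centre], "spike")
        scalp_events[[length(scalp_events) + 1L]] <-
          list(id = id, site = site, state = state, time = t)
      }
    }
  }
  # thalamic events: coupled echoes are taken out of the configured budget
  for (side in c("left", "right")) {
    site <- paste0("thal-", side)
    chans <- paste0(toupper(substr(side, 1L, 1L)), "Th", 0:3)
    # one stable generator per side: the peak contact of a patient's
    # thalamic discharges does not wander event to event
    side_contact <- sample(1:3, 1L)
    triggers <- Filter(function(e) e$site == paste0("scalp-", side),
                       scalp_events)
    for (state in SIM_STATES) {
      segs <- state_segs(state)
      total_s <- sum(segs$end_s - segs$start_s)
      n_budget <- stats::rpois(1L, config$rates[site, state] * total_s / 60)
      trg <- Filter(function(e) e$state == state, triggers)
      coupled <- Filter(function(e)
        stats::runif(1L) < config$coupling_probability[[side]], trg)
      placed <- 0L
      for (e in coupled) {
        lag <- rtruncnorm1(1L, config$lag_mean, config$lag_sd,
                           config$lag_bounds[1L], config$lag_bounds[2L])
        t <- e$time + lag / 1000
        seg_ok <- any(t >= segs$start_s + 0.6 & t <= segs$end_s - 0.6)
        if (!seg_ok) next
        sel <- c(side_contact, side_contact + 1L)
        insert_wave(chans[sel], c(1, 0.4), t, thal_w)
        add_event(site, state, t, chans[side_contact], "spike",
                  linked_id = e$id, true_lag_ms = lag)
        placed <- placed + 1L
      }
      n_indep <- max(0L, n_budget - placed)
      if (n_indep > 0L) {
        # draw exactly n_indep well-separated times
        off <- sort(stats::runif(n_indep * 3L + 5L, 0.6, total_s - 0.6))
        off <- off[c(TRUE, diff(off) >= 1)][seq_len(n_indep)]
        off <- off[!is.na(off)]
        tt <- state_offset_to_abs(off, segs)
        for (t in tt) {
          is_st <- stats::runif(1L) < config$st_fraction
          if (is_st) {
            insert_wave(chans, rep(1, 4L), t, thal_w)   # common mode
            add_event(site, state, t, chans[1L], "sharp_transient")
          } else {
            insert_wave(chans[c(side_contact, side_contact + 1L)],
                        c(1, 0.4), t, thal_w)
            add_event(site, state, t, chans[side_contact], "spike")
          }
        }
      }
    }
  }
  gt <- if (length(gt)) do.call(rbind, gt) else
    data.frame(event_id = integer(), site = character(), state = character(),
               time_s = numeric(), channel = character(), class = character(),
               linked_id = integer(), true_lag_ms = numeric())
  gt <- gt[order(gt$time_s), ]
  rownames(gt) <- NULL
  rec <- recording(data, fs,
                   data.frame(label = labels, kind = kinds),
                   annotations = layout,
                   patient_id = as.character(patient_id))
  list(recording = rec, ground_truth = gt)
}

#' Simulate a cohort of ground-truthed patients
#'
#' One recording + ground truth + outcome row per patient, all drawn from
#' per-patient RNG streams keyed by `(config$seed, patient)`. With
#' `fixture = paper15_cohort()` the per-patient event rates are modulated
#' by the fixture's region-level IED presence (patients without thalamic
#' IEDs get zero thalamic rates, sharp-transient-only patients get
#' common-mode insertions) and the outcome rows come from the fixture.
#'
#' @param n_patients Number of patients (ignored when `fixture` is given).
#' @param config A [sim_config()] shared by the cohort.
#' @param outcomes Optional data frame with one row per patient and
#'   columns `seizures_pre`, `seizures_post` (plus anything else to carry
#'   through). Must have `n_patients` rows.
#' @param fixture Optional cohort fixture, e.g. [paper15_cohort()].
#' @param dir Optional output directory; when set, each patient is written
#'   as EDF plus a ground-truth CSV, and the cohort table as CSV.
#' @return List of per-patient lists (`recording`, `ground_truth`,
#'   `outcome`), with the cohort table as attribute `"cohort"`.
#' @export
simulate_cohort <- function(n_patients = 15L, config = sim_config(),
                            outcomes = NULL, fixture = NULL, dir = NULL) {
  if (!is.null(fixture)) {
    pts <- fixture$patients
    n_patients <- nrow(pts)
    re <- fixture$region_events
  } else {
    if (n_patients < 1L) stopf("n_patients must be >= 1")
    pts <- data.frame(patient = sprintf("pt%02d", seq_len(n_patients)))
    if (!is.null(outcomes)) {
      if (nrow(outcomes) != n_patients)
        stopf("outcome table has %d rows for %d patients (inconsistent spec)",
              nrow(outcomes), n_patients)
      pts <- cbind(pts, outcomes)
    }
    re <- NULL
  }
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- vector("list", n_patients)
  names(out) <- pts$patient
  for (p in seq_len(n_patients)) {
    cfg_p <- config
    if (!is.null(re)) {
      g <- re[re$patient == pts$patient[p] & re$region %in% ANT_REGIONS, ]
      for (side in c("left", "right")) {
        gs <- g[g$side == side, ]
        if (!nrow(gs) || !any(gs$spike | gs$st)) {
          cfg_p$rates[paste0("thal-", side), ] <- 0
          cfg_p$coupling_probability[[side]] <- 0
        }
      }
      if (nrow(g) && !any(g$spike) && any(g$st)) cfg_p$st_fraction <- 1
    }
    sim <- simulate_recording(cfg_p, patient_id = p)
    sim$recording$patient_id <- pts$patient[p]
    sim$outcome <- pts[p, , drop = FALSE]
    if (!is.null(dir)) {
      write_edf(sim$recording,
                file.path(dir, paste0(pts$patient[p], ".edf")))
      utils::write.csv(sim$ground_truth,
                       file.path(dir, paste0(pts$patient[p],
                                             "_ground_truth.csv")),
                       row.names = FALSE)
    }
    out[[p]] <- sim
  }
  if (!is.null(dir))
    utils::write.csv(pts, file.path(dir, "cohort.csv"), row.names = FALSE)
  attr(out, "cohort") <- pts
  out
}
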