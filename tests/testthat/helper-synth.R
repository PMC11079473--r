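# Builders for small deterministic recordings used across the tests.

# Quiet recording: near-zero background (tiny jitter so robust SDs are
# positive), full DBS leads plus a minimal scalp set.
toy_recording <- function(fs = 512, dur_s = 120, noise_sd = 1e-3,
                          seed = 99, scalp = c("Fp1", "F3", "C3", "P3", "O1"),
                          annotate = TRUE) {
  set.seed(seed)
  labels <- c(scalp, paste0("LTh", 0:3), paste0("RTh", 0:3))
  kinds <- c(rep("scalp", length(scalp)),
             rep("dbs-left", 4), rep("dbs-right", 4))
  n <- round(dur_s * fs)
  data <- matrix(stats::rnorm(n * length(labels), 0, noise_sd), nrow = n)
  ann <- if (annotate)
    data.frame(label = c("awake", "sleep"),
               start_s = c(0, dur_s / 2), end_s = c(dur_s / 2, dur_s))
  else NULL
  recording(data, fs, data.frame(label = labels, kind = kinds),
            annotations = ann, patient_id = "toy")
}

# Add a rendered template to the named channels (weights recycled).
insert_template <- function(rec, channels, time_s, template = spike_template(),
                            weights = 1) {
  w <- make_spike_template(template, rec$fs)
  i0 <- round(time_s * rec$fs) + 1L - attr(w, "peak_index") + 1L
  idx <- i0:(i0 + length(w) - 1L)
  ok <- idx >= 1L & idx <= nrow(rec$data)
  weights <- rep_len(weights, length(channels))
  for (k in seq_along(channels)) {
    j <- match(channels[k], rec$channels$label)
    rec$data[idx[ok], j] <- rec$data[idx[ok], j] + weights[k] * w[ok]
  }
  rec
}

# Add a waveform into a vector at a 1-based start index, clipping at the
# vector's bounds.
add_clipped <- function(x, w, at) {
  idx <- at:(at + length(w) - 1L)
  keep <- idx >= 1L & idx <= length(x)
  x[idx[keep]] <- x[idx[keep]] + w[keep]
  x
}

# Epoch matrix of white noise with an optional template at a given latency.
noise_epochs <- function(n, fs, noise_sd = 10, template = NULL,
                         lag_ms = 0) {
  len <- fs + 1L
  centre <- fs %/% 2L + 1L
  ep <- t(vapply(seq_len(n), function(i) {
    x <- stats::rnorm(len, 0, noise_sd)
    if (!is.null(template)) {
      at <- centre + round(lag_ms / 1000 * fs) -
        attr(template, "peak_index") + 1L
      x <- add_clipped(x, template, at)
    }
    x
  }, numeric(len)))
  attr(ep, "fs") <- fs
  attr(ep, "time_ms") <- (seq_len(len) - centre) / fs * 1000
  ep
}

# Match detected events to ground truth by site and time tolerance.
match_gt <- function(events, gt, tol_s = 0.05) {
  used <- rep(FALSE, nrow(gt))
  tp <- 0L
  for (i in seq_len(nrow(events))) {
    hit <- which(!used & gt$site == events$site[i] &
                   abs(gt$time_s - events$time_s[i]) < tol_s)
    if (length(hit)) { used[hit[1L]] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fp = nrow(events) - tp, fn = nrow(gt) - tp)
}
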