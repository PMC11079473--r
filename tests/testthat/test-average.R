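test_that("epoch extraction uses the stated sample arithmetic", {
  fs <- 2048
  x <- seq_len(5 * fs)                       # value = 1-based sample index
  ep <- extract_epochs(x, fs, 1.0)
  # trigger at 1.0 s -> 0-based samples 1024..3072 inclusive
  expect_identical(ncol(ep), 2049L)
  expect_equal(ep[1, 1], 1025)               # 1-based index of sample 1024
  expect_equal(ep[1, 2049], 3073)
  expect_equal(attr(ep, "time_ms")[1025], 0)
})

test_that("edge triggers are dropped and counted", {
  fs <- 512
  x <- rnorm(5 * fs)
  ep <- extract_epochs(x, fs, c(0.3, 2.0, 4.8))
  expect_identical(nrow(ep), 1L)
  expect_identical(attr(ep, "n_dropped"), 2L)
  expect_error(extract_epochs(x, fs, 0.1), "no usable triggers")
})

test_that("averaging identical epochs returns the epoch", {
  fs <- 512
  w <- make_spike_template(spike_template(), fs)
  x <- c(numeric(fs), w, numeric(2 * fs))
  t0 <- (fs + attr(w, "peak_index") - 1) / fs
  ep <- extract_epochs(x, fs, rep(t0, 7))
  avg <- average_epochs(ep)
  expect_equal(avg$waveform, ep[1, ], ignore_attr = TRUE)
  expect_identical(avg$n_triggers, 7L)
  one <- average_epochs(extract_epochs(x, fs, t0))
  expect_equal(one$waveform, ep[1, ], ignore_attr = TRUE)
})

test_that("averaging residual shrinks like 1/sqrt(n)", {
  set.seed(8)
  fs <- 512
  w <- make_spike_template(spike_template(), fs)
  tmpl <- add_clipped(numeric(fs + 1), w, 200L)
  rms_at <- function(n) {
    r <- replicate(30, {
      ep <- t(vapply(seq_len(n), function(i) tmpl + rnorm(fs + 1, 0, 10),
                     numeric(fs + 1)))
      attr(ep, "fs") <- fs
      attr(ep, "time_ms") <- (seq_len(fs + 1) - fs / 2 - 1) / fs * 1000
      sqrt(mean((average_epochs(ep)$waveform - tmpl)^2))
    })
    mean(r)
  }
  ratio <- rms_at(25) / rms_at(100)
  expect_equal(ratio, 2, tolerance = 0.15)   # 1/sqrt(n) scaling
})

test_that("peak latency is recovered from injected responses", {
  set.seed(9)
  fs <- 512
  w <- make_spike_template(spike_template(), fs)
  for (lag_ms in c(40, 51)) {
    avg <- average_epochs(noise_epochs(50, fs, 10, w, lag_ms))
    lat <- find_iedtp_peak(avg)
    expect_equal(lat, lag_ms, tolerance = 2.5 / lag_ms)
  }
})

test_that("pure-noise averages rarely produce a suprathreshold peak", {
  set.seed(10)
  fs <- 256
  len <- fs + 1
  hits <- replicate(120, {
    ep <- matrix(rnorm(30 * len, 0, 10), nrow = 30)
    attr(ep, "fs") <- fs
    attr(ep, "time_ms") <- (seq_len(len) - fs / 2 - 1) / fs * 1000
    !is.na(find_iedtp_peak(average_epochs(ep), peak_threshold = 4))
  })
  expect_lt(mean(hits), 0.05)
})

test_that("the larger of two peaks wins", {
  fs <- 512
  len <- fs + 1
  centre <- fs / 2 + 1
  w <- numeric(len)
  w[centre + round(0.030 * fs)] <- 10        # +30 ms, larger
  w[centre + round(0.090 * fs)] <- 6         # +90 ms
  w[1:64] <- rnorm(64, 0, 0.5)               # nonzero baseline SD
  avg <- structure(list(waveform = w,
                        time_ms = (seq_len(len) - centre) / fs * 1000,
                        n_triggers = 10L, baseline_sd = 0.5, fs = fs),
                   class = "triggered_average")
  expect_equal(find_iedtp_peak(avg), 30, tolerance = (1000 / fs) / 30)
})

test_that("connection classification follows the sign convention", {
  f <- classify_connection("scalp->thal", 51)
  expect_identical(f$category, "follower")
  expect_equal(f$lag_ms, 51)
  p <- classify_connection("thal->scalp", 18)
  expect_identical(p$category, "preceder")
  expect_equal(p$lag_ms, 18)
  expect_identical(classify_connection("thal->scalp", -35)$category,
                   "follower")
  expect_identical(classify_connection("scalp->thal", -22)$category,
                   "preceder")
  expect_identical(classify_connection("scalp->thal", NA_real_)$category,
                   "no_connection")
  expect_identical(classify_connection("scalp->thal", 0.5)$category,
                   "not_evaluable")
})

test_that("category fractions over evaluable conditions sum to one", {
  res <- data.frame(
    category = c(rep("follower", 5), "preceder", rep("no_connection", 3),
                 rep("not_evaluable", 2)),
    lag_ms = c(40, 45, 50, 55, 60, 18, NA, NA, NA, NA, NA))
  s <- summarize_connections(res)
  expect_identical(s$n_evaluable, 9L)
  expect_equal(sum(s$counts), 9)
  expect_equal(s$mean_lag_follower, 50)
  expect_equal(s$mean_lag_preceder, 18)
})

test_that("a simulated scalp->thalamus coupling is follower both ways", {
  cfg <- sim_config(fs = 512, segment_minutes = 4, seed = 7, noise_sd = 10,
                    rates = matrix(c(3, 3, 3, 3, 0.2, 0.2, 0.2, 0.2),
                                   4, 2, byrow = TRUE),
                    coupling_probability = 1, lag_mean = 51, lag_sd = 0)
  sim <- simulate_recording(cfg)
  ev <- detect_ieds(sim$recording)
  cond <- enumerate_conditions(sim$recording, ev,
                               c(left = TRUE, right = TRUE))
  ok <- cond$category != "not_evaluable"
  expect_true(all(cond$category[ok] == "follower"))
  # detection jitter (+/-2 samples on the trigger) adds to the average's
  # peak-sample quantization at 512 Hz
  expect_true(all(abs(cond$lag_ms[ok] - 51) <= 8))
  # both directions of every evaluable (side, state) agree
  expect_gte(sum(ok), 6)
})

test_that("missing hits and missing IEDs make conditions not evaluable", {
  cfg <- sim_config(fs = 256, segment_minutes = 1, seed = 3,
                    rates = matrix(c(2, 2, 2, 2, 0, 0, 0, 0),
                                   4, 2, byrow = TRUE),
                    coupling_probability = 0)
  sim <- simulate_recording(cfg)
  ev <- detect_ieds(sim$recording)
  cond <- enumerate_conditions(sim$recording, ev,
                               c(left = TRUE, right = FALSE))
  expect_true(all(cond$category[cond$side == "right"] == "not_evaluable"))
  # no thalamic IEDs -> thal->scalp conditions lack triggers
  expect_true(all(cond$category[cond$direction == "thal->scalp"] ==
                    "not_evaluable"))
})
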