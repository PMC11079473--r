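test_that("a noise-free insertion yields exactly one candidate at its time", {
  rec <- toy_recording(fs = 512, dur_s = 200, annotate = FALSE)
  rec <- insert_template(rec, c("LTh1", "LTh2"), 100, weights = c(1, 0.4))
  cand <- detect_candidates(make_bipolar(rec, "dbs-adjacent"))
  expect_identical(nrow(cand), 1L)
  expect_equal(cand$time_s, 100, tolerance = 0.005 / 100)
})

test_that("insertions within the separation window merge into one", {
  rec <- toy_recording(fs = 512, dur_s = 60, annotate = FALSE)
  rec <- insert_template(rec, "LTh1", 30.000)
  rec <- insert_template(rec, "LTh1", 30.030)
  cand <- detect_candidates(make_bipolar(rec, "dbs-adjacent"),
                            params = detection_params(min_separation_ms = 200))
  expect_identical(nrow(cand), 1L)
})

test_that("empty segments yield an empty candidate list", {
  rec <- toy_recording(fs = 256, dur_s = 10, annotate = FALSE)
  cand <- detect_candidates(make_bipolar(rec, "dbs-adjacent"),
                            segments = data.frame(start_s = 2, end_s = 2))
  expect_identical(nrow(cand), 0L)
})

test_that("false positives on pure background stay below 1 per 20 min", {
  # Monte-Carlo over 50 seeds: one 4-contact lead, 20 min of 1/f noise
  fs <- 256
  n <- 20 * 60 * fs
  fp <- integer(50)
  for (s in 1:50) {
    set.seed(1000 + s)
    data <- vapply(1:4, function(j) thalied:::pink_noise(n, fs, 1.5, 10),
                   numeric(n))
    rec <- recording(data, fs,
                     data.frame(label = paste0("LTh", 0:3),
                                kind = "dbs-left"),
                     patient_id = "mc")
    fp[s] <- nrow(detect_candidates(make_bipolar(rec, "dbs-adjacent")))
  }
  expect_lt(mean(fp), 1)
})

test_that("raising the threshold never increases the detection count", {
  sim <- simulate_recording(sim_config(fs = 512, segment_minutes = 2,
                                       seed = 21))
  bip <- make_bipolar(sim$recording, "dbs-adjacent")
  n_prev <- Inf
  for (thr in c(5, 6, 8, 12)) {
    n_thr <- nrow(detect_candidates(bip, params =
                                      detection_params(prominence_threshold = thr)))
    expect_lte(n_thr, n_prev)
    n_prev <- n_thr
  }
})

test_that("classification implements the compound spike criterion", {
  base <- function() toy_recording(fs = 2048, dur_s = 60, annotate = FALSE)
  views <- function(rec)
    list(b = make_bipolar(rec, "dbs-adjacent"), m = make_monopolar(rec))
  # canonical spike: single-contact insertion with slow wave
  v <- views(insert_template(base(), c("LTh1", "LTh2"), 30,
                             weights = c(1, 0.4)))
  cls <- classify_event(30, "left", v$b, v$m)
  expect_identical(cls$class, "spike")
  expect_true(cls$has_phase_reversal && cls$has_slow_wave &&
                cls$monopolar_prominent)
  expect_identical(cls$peak_contact, "LTh1")
  # common-mode insertion: no phase reversal -> sharp transient
  v <- views(insert_template(base(), paste0("LTh", 0:3), 30))
  cls <- classify_event(30, "left", v$b, v$m)
  expect_identical(cls$class, "sharp_transient")
  expect_false(cls$has_phase_reversal)
  # long fast component with reversal and prominence -> sharp transient
  v <- views(insert_template(base(), c("LTh1", "LTh2"), 30,
                             spike_template(fast_duration = 80,
                                            slow_duration = 200),
                             weights = c(1, 0.4)))
  cls <- classify_event(30, "left", v$b, v$m)
  expect_identical(cls$class, "sharp_transient")
  expect_true(cls$has_phase_reversal)
})

test_that("spike class always satisfies the event invariant", {
  # randomized templates; whenever the classifier says spike, every
  # criterion it is defined by must hold
  set.seed(42)
  for (k in 1:12) {
    fd <- runif(1, 20, 70)
    tpl <- spike_template(fast_duration = fd,
                          fast_amplitude = runif(1, 60, 120),
                          slow_duration = fd + runif(1, 60, 150),
                          slow_amplitude = runif(1, 20, 60),
                          polarity = sample(c(-1, 1), 1))
    common <- runif(1) < 0.3
    rec <- toy_recording(fs = 1024, dur_s = 60, annotate = FALSE,
                         seed = 1000 + k)
    rec <- if (common) insert_template(rec, paste0("RTh", 0:3), 30, tpl)
    else insert_template(rec, c("RTh1", "RTh2"), 30, tpl, c(1, 0.4))
    cls <- classify_event(30, "right", make_bipolar(rec, "dbs-adjacent"),
                          make_monopolar(rec))
    if (cls$class == "spike") {
      expect_lt(cls$fast_duration_ms, 50)
      expect_true(cls$has_slow_wave)
      expect_true(cls$has_phase_reversal)
      expect_true(cls$monopolar_prominent)
      expect_false(common)
    }
    if (common) expect_false(cls$has_phase_reversal)
  }
})

test_that("peak contact follows the amplitude gradient with deep-tie rule", {
  rec <- toy_recording(fs = 512, dur_s = 20, annotate = FALSE)
  rec <- insert_template(rec, c("LTh0", "LTh1", "LTh2"), 10,
                         weights = c(0.5, 0.8, 1))   # gradient 2 > 1 > 0
  expect_identical(peak_contact(10, make_monopolar(rec), "left"), "LTh2")
  # an exact amplitude tie resolves toward the deepest contact
  rec2 <- toy_recording(fs = 512, dur_s = 20, annotate = FALSE, noise_sd = 0)
  rec2 <- insert_template(rec2, c("LTh1", "LTh2"), 10, weights = c(1, 1))
  expect_identical(peak_contact(10, make_monopolar(rec2), "left"), "LTh1")
})

test_that("ied_rate is count per minute", {
  ev <- data.frame(time_s = seq_len(5))
  expect_equal(ied_rate(ev, 20), 0.25)
  expect_equal(ied_rate(ev[0, , drop = FALSE], 20), 0)
  expect_error(ied_rate(ev, 0), "minutes")
})

test_that("detected thalamic rate recovers the simulated rate", {
  # 0.33/min sleep thalamic rate; pool seeds for a stable count
  cfg <- sim_config(fs = 512, segment_minutes = 5, seed = 1,
                    rates = matrix(c(0, 0, 0, 0, .33, .13, .33, .13),
                                   4, 2, byrow = TRUE),
                    coupling_probability = 0)
  n_det <- 0
  n_true <- 0
  minutes <- 0
  for (s in 1:4) {
    cfg$seed <- s
    sim <- simulate_recording(cfg)
    ev <- detect_ieds(sim$recording)
    sl <- ev[ev$state == "sleep" & grepl("thal", ev$site), ]
    gt <- sim$ground_truth
    n_det <- n_det + nrow(sl)
    n_true <- n_true + sum(gt$state == "sleep")
    minutes <- minutes + 10        # 2 x 5 min sleep per simulation
  }
  rate <- ied_rate(data.frame(x = seq_len(n_det)), 2 * minutes)
  se <- sqrt(n_true) / (2 * minutes)
  expect_lt(abs(rate - 0.33), 3 * se + 0.05)
})
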