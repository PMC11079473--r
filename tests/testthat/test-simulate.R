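small_cfg <- function(...) {
  sim_config(fs = 128, segment_minutes = 1, seed = 11, ...)
}

test_that("same seed and config give identical recordings", {
  a <- simulate_recording(small_cfg())
  b <- simulate_recording(small_cfg())
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- simulate_recording(small_cfg(), patient_id = 2L)
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("zero rates give pure background and empty ground truth", {
  sim <- simulate_recording(small_cfg(rates = matrix(0, 4, 2)))
  expect_identical(nrow(sim$ground_truth), 0L)
  expect_lt(max(abs(sim$recording$data)), 30 * 10)  # no template-sized spikes
})

test_that("degenerate coupling places every echo exactly lag_mean later", {
  cfg <- small_cfg(coupling_probability = 1, lag_mean = 51, lag_sd = 0,
                   rates = matrix(c(2, 2, 2, 2, 0, 0, 0, 0), 4, 2,
                                  byrow = TRUE))
  sim <- simulate_recording(cfg)
  gt <- sim$ground_truth
  scalp <- gt[grepl("scalp", gt$site), ]
  thal <- gt[grepl("thal", gt$site), ]
  expect_gt(nrow(scalp), 0)
  expect_true(all(thal$true_lag_ms == 51))
  for (i in seq_len(nrow(thal))) {
    trig <- gt[gt$event_id == thal$linked_id[i], ]
    expect_equal(thal$time_s[i] - trig$time_s, 0.051, tolerance = 1e-9)
  }
})

test_that("recording layout has two segments per state", {
  sim <- simulate_recording(small_cfg())
  ann <- sim$recording$annotations
  expect_identical(sum(ann$label == "sleep"), 2L)
  expect_identical(sum(ann$label == "awake"), 2L)
  expect_equal(sum(ann$end_s - ann$start_s), 4 * 60)
})

test_that("empirical event rates match configured rates (calibration)", {
  # 30 simulations x 4 site-state cells x 2 segments >= 100 segments
  rate <- 2
  cfg <- small_cfg(rates = matrix(rate, 4, 2), coupling_probability = 0,
                   st_fraction = 0)
  counts <- numeric(0)
  for (s in 1:30) {
    cfg$seed <- s
    gt <- simulate_recording(cfg)$ground_truth
    for (site in c("scalp-left", "thal-left", "thal-right")) {
      for (state in c("sleep", "awake"))
        counts <- c(counts, sum(gt$site == site & gt$state == state))
    }
  }
  # expected count under the stated model: Poisson rate over 2 min per
  # state, corrected for the 0.6 s edge margins and the >=1 s same-site
  # dead time (retention 1/(1 + lambda_s * tau) for a thinned process)
  lam_s <- rate / 60
  lambda <- rate * 2 * (118.8 / 120) / (1 + lam_s * 1)
  se <- sqrt(lambda / length(counts))
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("coupled lag distribution matches configured mean", {
  cfg <- small_cfg(coupling_probability = 1, lag_mean = 60, lag_sd = 20,
                   lag_bounds = c(2, 180),
                   rates = matrix(c(3, 3, 3, 3, 1, 1, 1, 1), 4, 2,
                                  byrow = TRUE))
  lags <- numeric(0)
  for (s in 1:12) {
    cfg$seed <- s
    gt <- simulate_recording(cfg)$ground_truth
    lags <- c(lags, gt$true_lag_ms[!is.na(gt$true_lag_ms)])
  }
  expect_gt(length(lags), 100)
  expect_true(all(lags >= 2 & lags <= 180))
  # truncation shifts the mean slightly; compare against the truncated mean
  tm <- 60 + 20 * (dnorm((2 - 60) / 20) - dnorm((180 - 60) / 20)) /
    (pnorm((180 - 60) / 20) - pnorm((2 - 60) / 20))
  expect_lt(abs(mean(lags) - tm), 3 * 20 / sqrt(length(lags)))
})

test_that("background periodogram slope matches the spectral exponent", {
  for (alpha in c(1, 1.5)) {
    set.seed(5)
    x <- thalied:::pink_noise(2^16, 256, alpha, 10)
    sp <- stats::spec.pgram(x, taper = 0, plot = FALSE, spans = 15)
    f_hz <- sp$freq * 256                 # spec.pgram freq is cycles/sample
    keep <- f_hz > 0.5 & f_hz < 50
    fit <- stats::lm(log10(sp$spec[keep]) ~ log10(f_hz[keep]))
    expect_equal(unname(stats::coef(fit)[2]), -alpha, tolerance = 0.3 / alpha)
  }
})

test_that("simulate_cohort writes byte-identical EDFs under one seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- small_cfg()
  simulate_cohort(2L, cfg, dir = d1)
  simulate_cohort(2L, cfg, dir = d2)
  for (f in c("pt01.edf", "pt02.edf")) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6))
  }
  expect_error(simulate_cohort(3L, cfg,
                               outcomes = data.frame(seizures_pre = 1:2,
                                                     seizures_post = 0:1)),
               "inconsistent")
})

test_that("paper15-driven cohort suppresses thalamic events where none occur", {
  fix <- paper15_cohort()
  sims <- simulate_cohort(config = small_cfg(), fixture = fix)
  expect_length(sims, 15L)
  gt14 <- sims[["pt14"]]$ground_truth      # patient without thalamic IEDs
  expect_identical(sum(grepl("thal", gt14$site)), 0L)
  expect_identical(attr(sims, "cohort")$patient, fix$patients$patient)
})
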