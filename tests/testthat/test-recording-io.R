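test_that("EDF write/read round-trips within quantization", {
  sim <- simulate_recording(sim_config(fs = 128, segment_minutes = 0.5,
                                       seed = 3))
  rec <- sim$recording
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  q <- 2 * 3276.7 / (2 * 32767)                  # one digital unit
  expect_lt(max(abs(back$data - rec$data)), q + 1e-9)
  expect_identical(back$channels$label, rec$channels$label)
  expect_identical(back$channels$kind, rec$channels$kind)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$annotations$label, rec$annotations$label)
  expect_equal(back$annotations$start_s, rec$annotations$start_s)
})

test_that("EDF edge cases error or degrade as specified", {
  rec <- toy_recording(fs = 64, dur_s = 2, annotate = FALSE)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_identical(nrow(back$annotations), 0L)   # no sidecar -> empty
  expect_error(recording(matrix(numeric(0), 10, 0), 64,
                         data.frame(label = character(),
                                    kind = character())),
               "at least one channel")
  expect_error(read_edf(withr::local_tempfile()), "no such file")
  big <- rec
  big$data[1, 1] <- 1e5
  expect_error(write_edf(big, path), "physical range")
})

test_that("bipolar DBS montage derives three channels per lead", {
  rec <- toy_recording(fs = 256, dur_s = 4, annotate = FALSE)
  bip <- make_bipolar(rec, "dbs-adjacent")
  expect_identical(sum(bip$derivations$side == "left"), 3L)
  expect_identical(sum(bip$derivations$side == "right"), 3L)
  expect_identical(bip$derivations$name[1], "LTh0-LTh1")
  # identical signals on both contacts -> zero derived channel
  rec$data[, "LTh0"] <- rec$data[, "LTh1"]
  bip <- make_bipolar(rec, "dbs-adjacent")
  expect_equal(max(abs(bip$signals[, "LTh0-LTh1"])), 0)
})

test_that("single-contact spike phase-reverses across adjacent bipolars", {
  rec <- toy_recording(fs = 512, dur_s = 10, annotate = FALSE)
  rec <- insert_template(rec, "LTh1", 5)
  bip <- make_bipolar(rec, "dbs-adjacent")
  i <- round(5 * 512) + 1L
  d01 <- bip$signals[i, "LTh0-LTh1"]
  d12 <- bip$signals[i, "LTh1-LTh2"]
  expect_lt(d01 * d12, 0)                        # opposite-signed deflections
})

test_that("monopolar montage supports identity and re-referencing", {
  rec <- toy_recording(fs = 256, dur_s = 4, annotate = FALSE)
  mono <- make_monopolar(rec)
  expect_equal(mono$signals[, "LTh2"], unname(rec$data[, "LTh2"]))
  rr <- make_monopolar(rec, reference = "RTh3")
  expect_equal(max(abs(rr$signals[, "RTh3"])), 0)
  expect_error(make_monopolar(rec, reference = "Cz"), "not in recording")
  # spike amplitude maximal on the insertion contact
  rec2 <- insert_template(toy_recording(fs = 512, dur_s = 10,
                                        annotate = FALSE),
                          c("LTh2", "LTh3"), 5, weights = c(1, 0.4))
  expect_identical(peak_contact(5, make_monopolar(rec2), "left"), "LTh2")
})

test_that("montages are linear in the underlying signals", {
  base <- toy_recording(fs = 128, dur_s = 4, annotate = FALSE, noise_sd = 1)
  add <- insert_template(base, "LTh1", 2)
  for (build in list(function(r) make_bipolar(r, "dbs-adjacent"),
                     function(r) make_monopolar(r, reference = "RTh0"))) {
    va <- build(base)$signals
    vb <- build(add)$signals
    diff_rec <- base
    diff_rec$data <- add$data - base$data
    vd <- build(diff_rec)$signals
    expect_equal(vb - va, vd, tolerance = 1e-12)
  }
})

test_that("segment selection takes the earliest eligible minutes", {
  rec <- toy_recording(fs = 64, dur_s = 40 * 60, annotate = FALSE)
  rec$annotations <- data.frame(label = "sleep", start_s = 300,
                                end_s = 300 + 30 * 60)
  seg <- select_segments(rec, "sleep", minutes = 20)
  expect_equal(seg$start_s, 300)
  expect_equal(seg$end_s, 300 + 20 * 60)
  expect_identical(select_segments(rec, "sleep", minutes = 20), seg)
})

test_that("segments respect the two-hour seizure gap", {
  rec <- toy_recording(fs = 64, dur_s = 4 * 3600, annotate = FALSE)
  rec$annotations <- data.frame(
    label = c("seizure", "sleep"),
    start_s = c(0, 3600), end_s = c(10, 3 * 3600))
  seg <- select_segments(rec, "sleep", minutes = 20)
  expect_true(all(seg$start_s >= 10 + 2 * 3600))
  expect_equal(sum(seg$end_s - seg$start_s), 1200)
})

test_that("insufficient eligible data names the shortfall", {
  rec <- toy_recording(fs = 64, dur_s = 1200, annotate = FALSE)
  rec$annotations <- data.frame(label = "sleep", start_s = 0, end_s = 600)
  expect_error(select_segments(rec, "sleep", minutes = 20),
               "short by 10.0 min")
  expect_error(select_segments(rec, "awake", minutes = 5), "no 'awake'")
})
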