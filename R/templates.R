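#' Spike-and-slow-wave template
#'
#' Describes the canonical interictal discharge morphology used by the
#' synthetic recording generator: a fast component (by definition shorter
#' than 50 ms for a spike) followed by a slower wave of opposite polarity.
#' Durations are full-width-at-half-maximum (FWHM) of the respective lobes.
#'
#' @param fast_duration FWHM of the fast component, ms. Must be > 0.
#' @param fast_amplitude Peak amplitude of the fast component, microvolts.
#' @param slow_duration FWHM of the slow wave, ms; must exceed
#'   `fast_duration`.
#' @param slow_amplitude Peak amplitude of the slow wave, microvolts.
#' @param polarity `+1` or `-1`, sign of the fast component.
#' @return An object of class `spike_template`.
#' @examples
#' tpl <- spike_template(fast_duration = 30)
#' w <- make_spike_template(tpl, fs = 2048)
#' @export
spike_template <- function(fast_duration = 30, fast_amplitude = 80,
                           slow_duration = 150, slow_amplitude = 40,
                           polarity = 1) {
  assert_scalar_num(fast_duration, "fast_duration", lower = 1e-9)
  assert_scalar_num(slow_duration, "slow_duration", lower = 1e-9)
  assert_scalar_num(fast_amplitude, "fast_amplitude", lower = 1e-9)
  assert_scalar_num(slow_amplitude, "slow_amplitude", lower = 1e-9)
  if (slow_duration <= fast_duration)
    stopf("slow_duration (%g ms) must exceed fast_duration (%g ms)",
          slow_duration, fast_duration)
  if (!polarity %in% c(-1, 1)) stopf("polarity must be +1 or -1")
  structure(list(fast_duration = fast_duration,
                 fast_amplitude = fast_amplitude,
                 slow_duration = slow_duration,
                 slow_amplitude = slow_amplitude,
                 polarity = polarity),
            class = "spike_template")
}

# Raised-cosine (Hann) pulse with FWHM = `fwhm_ms`; support is 2*fwhm_ms.
hann_pulse <- function(fwhm_ms, amplitude, fs) {
  half <- round(fwhm_ms / 1000 * fs)         # samples from centre to edge = FWHM
  n <- 2L * half + 1L
  t <- seq(-half, half, by = 1L)
  amplitude * 0.5 * (1 + cos(pi * t / half))
}

#' Render a spike template as a sampled waveform
#'
#' The fast lobe is a raised-cosine pulse whose FWHM equals
#' `fast_duration`; the slow wave is an opposite-going raised-cosine with
#' FWHM `slow_duration` starting where the fast lobe ends. A shallow
#' recovery lobe (FWHM twice the slow duration) is appended and scaled so
#' the waveform is exactly zero-mean over its support: inserted events
#' then neither bias the baseline nor sit on a DC pedestal that would
#' distort width measurements, while the fast and slow lobes keep exactly
#' their stated amplitudes.
#'
#' @param template A [spike_template()].
#' @param fs Sampling rate in Hz. Must resolve the fast component
#'   (`fs > 2 * 1000 / fast_duration`).
#' @return Numeric vector (microvolts) with attributes `peak_index` (sample
#'   index, 1-based, of the fast-component peak) and `fs`.
#' @export
make_spike_template <- function(template, fs) {
  stopifnot(inherits(template, "spike_template"))
  assert_scalar_num(fs, "fs", lower = 1e-9)
  if (fs <= 2 * (1000 / template$fast_duration))
    stopf("sampling rate %g Hz too low to represent a %g ms fast component",
          fs, template$fast_duration)
  fast <- hann_pulse(template$fast_duration, template$fast_amplitude, fs)
  slow <- hann_pulse(template$slow_duration, -template$slow_amplitude, fs)
  tail <- hann_pulse(2 * template$slow_duration, 1, fs)
  w <- c(fast, slow, tail * (-sum(c(fast, slow)) / sum(tail)))
  w <- template$polarity * w
  attr(w, "peak_index") <- (length(fast) + 1L) %/% 2L
  attr(w, "fs") <- fs
  w
}

#' Measure the FWHM of the dominant deflection of a waveform
#'
#' Width at half-prominence of the largest absolute deflection, relative to
#' the edge baseline (mean of the first and last samples); linear
#' interpolation between samples.
#'
#' @param w Numeric waveform.
#' @param fs Sampling rate, Hz.
#' @return Width in ms.
#' @export
fast_component_width <- function(w, fs) {
  base <- mean(c(w[1L], w[length(w)]))
  x <- w - base
  i <- which.max(abs(x))
  s <- sign(x[i])
  x <- x * s                                 # dominant deflection now positive
  half <- x[i] / 2
  # walk out from the peak to the half crossings
  l <- i
  while (l > 1L && x[l - 1L] >= half) l <- l - 1L
  r <- i
  while (r < length(x) && x[r + 1L] >= half) r <- r + 1L
  frac_l <- if (l > 1L) (x[l] - half) / (x[l] - x[l - 1L]) else 0
  frac_r <- if (r < length(x)) (x[r] - half) / (x[r] - x[r + 1L]) else 0
  ((r + frac_r) - (l - frac_l)) / fs * 1000
}
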