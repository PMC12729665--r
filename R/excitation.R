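#' Excitation specification
#'
#' Describes one of the three transmit waveforms of a signal train: a
#' two-period tone burst at 0.8 or 2.2 MHz enveloped by a half-period sine, or
#' a linear frequency sweep over 0.5--2.5 MHz. The default sample rate is the
#' 125 Msps of the reference digitizer.
#'
#' @param kind `"tone_burst"` or `"sweep"`.
#' @param freq_mhz Carrier frequency in MHz for bursts (0.8 or 2.2 in the
#'   reference setup); ignored for sweeps.
#' @param range_mhz Length-2 frequency range in MHz for sweeps (default
#'   `c(0.5, 2.5)`); ignored for bursts.
#' @param cycles Number of carrier periods in a burst (default 2).
#' @param sweep_us Sweep duration in microseconds (default 10; the reference
#'   publication does not state it, so it is configuration).
#' @param sample_rate_msps Sample rate in Msps (default 125).
#' @return An object of class `qus_excitation`.
#' @export
excitation_spec <- function(kind = c("tone_burst", "sweep"), freq_mhz = 0.8,
                            range_mhz = c(0.5, 2.5), cycles = 2,
                            sweep_us = 10, sample_rate_msps = 125) {
  kind <- match.arg(kind)
  if (kind == "tone_burst") {
    if (freq_mhz <= 0) stop("'freq_mhz' must be positive")
    if (sample_rate_msps < 10 * freq_mhz)
      stop("sample rate must be at least 10x the carrier frequency")
    duration_us <- cycles / freq_mhz
  } else {
    if (length(range_mhz) != 2L || range_mhz[1] <= 0 ||
        range_mhz[2] <= range_mhz[1])
      stop("'range_mhz' must be an increasing positive pair")
    if (sample_rate_msps < 10 * range_mhz[2])
      stop("sample rate must be at least 10x the highest sweep frequency")
    duration_us <- sweep_us
  }
  structure(list(kind = kind, freq_mhz = freq_mhz, range_mhz = range_mhz,
                 cycles = cycles, duration_us = duration_us,
                 sample_rate_msps = sample_rate_msps),
            class = "qus_excitation")
}

#' The default excitation set of a signal train
#'
#' @param sample_rate_msps Sample rate in Msps (default 125).
#' @param sweep_us Sweep duration in microseconds (default 10).
#' @return Named list with elements `burst_08`, `burst_22`, `sweep`.
#' @export
default_excitations <- function(sample_rate_msps = 125, sweep_us = 10) {
  list(
    burst_08 = excitation_spec("tone_burst", freq_mhz = 0.8,
                               sample_rate_msps = sample_rate_msps),
    burst_22 = excitation_spec("tone_burst", freq_mhz = 2.2,
                               sample_rate_msps = sample_rate_msps),
    sweep = excitation_spec("sweep", sweep_us = sweep_us,
                            sample_rate_msps = sample_rate_msps)
  )
}

# Evaluate the excitation amplitude at arbitrary times (microseconds).
# Continuous evaluation lets the simulator apply exact fractional delays.
excitation_amplitude <- function(spec, t_us) {
  T <- spec$duration_us
  a <- numeric(length(t_us))
  inside <- t_us >= 0 & t_us <= T
  tau <- t_us[inside]
  if (spec$kind == "tone_burst") {
    a[inside] <- sin(pi * tau / T) * sin(2 * pi * spec$freq_mhz * tau)
  } else {
    f0 <- spec$range_mhz[1]; f1 <- spec$range_mhz[2]
    phase <- f0 * tau + (f1 - f0) / (2 * T) * tau^2
    a[inside] <- sin(pi * tau / T) * sin(2 * pi * phase)
  }
  a
}

#' Synthesize an excitation waveform
#'
#' Tone bursts are `sin(pi*tau/T) * sin(2*pi*f*tau)` on `tau in [0, T]` with
#' `T = cycles/f`; sweeps are a half-sine-enveloped linear chirp across the
#' frequency range. Peak amplitude is normalized to 1.
#'
#' @param spec A [excitation_spec()] object.
#' @return Numeric vector of sampled amplitudes with attributes
#'   `sample_rate_msps` and `duration_us`.
#' @export
synth_excitation <- function(spec) {
  stopifnot(inherits(spec, "qus_excitation"))
  dt <- 1 / spec$sample_rate_msps
  t <- seq(0, spec$duration_us, by = dt)
  w <- excitation_amplitude(spec, t)
  peak <- max(abs(w))
  if (peak > 0) w <- w / peak
  attr(w, "sample_rate_msps") <- spec$sample_rate_msps
  attr(w, "duration_us") <- spec$duration_us
  w
}

#' Magnitude spectrum of a waveform
#'
#' Discrete Fourier transform magnitude with the frequency axis in MHz, used
#' for quality-control plots of excitation and received waveforms.
#'
#' @param waveform Numeric amplitude vector.
#' @param sample_rate_msps Sample rate in Msps; taken from the waveform's
#'   attribute if present.
#' @return Data frame with `freq_mhz` and `magnitude` up to the Nyquist bin.
#' @export
spectrum_mag <- function(waveform, sample_rate_msps = NULL) {
  if (length(waveform) == 0L) stop("empty waveform")
  if (is.null(sample_rate_msps))
    sample_rate_msps <- attr(waveform, "sample_rate_msps")
  if (is.null(sample_rate_msps)) stop("sample rate not supplied")
  n <- length(waveform)
  mag <- Mod(stats::fft(as.numeric(waveform)))
  keep <- seq_len(floor(n / 2) + 1L)
  data.frame(freq_mhz = (keep - 1L) * sample_rate_msps / n,
             magnitude = mag[keep])
}
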