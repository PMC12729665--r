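#' Detect the arrival time of a waveform
#'
#' The arrival is the time of the first zero-crossing that follows the first
#' sample whose absolute amplitude exceeds `threshold_fraction` times the peak
#' absolute amplitude, with linear interpolation between the bracketing
#' samples. This mirrors first-zero-crossing time-of-flight picking with a
#' pre-trigger threshold.
#'
#' @param waveform Numeric amplitude vector.
#' @param threshold_fraction Fraction of the peak in (0, 1); default 0.2.
#' @param sample_rate_msps Sample rate; taken from the waveform attribute if
#'   absent.
#' @return Arrival time in microseconds (time of sample 1 is 0).
#' @export
detect_arrival <- function(waveform, threshold_fraction = 0.2,
                           sample_rate_msps = NULL) {
  if (length(waveform) < 2L) stop("waveform too short")
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("'threshold_fraction' must be in (0, 1)")
  if (is.null(sample_rate_msps))
    sample_rate_msps <- attr(waveform, "sample_rate_msps")
  if (is.null(sample_rate_msps)) stop("sample rate not supplied")
  w <- as.numeric(waveform)
  peak <- max(abs(w))
  if (peak == 0) stop("no arrival: waveform is identically zero")
  idx <- which(abs(w) > threshold_fraction * peak)[1]
  if (is.na(idx)) stop("no arrival: no sample exceeds the threshold")
  dt <- 1 / sample_rate_msps
  for (j in idx:(length(w) - 1L)) {
    a <- w[j]; b <- w[j + 1L]
    if (a == 0) return((j - 1L) * dt)
    if (a * b < 0) return(((j - 1L) + a / (a - b)) * dt)
  }
  stop("no arrival: no zero-crossing after threshold exceedance")
}

#' Ultrasound velocity from path length and arrival time
#'
#' `C = L / (t - dt)`: path length over the arrival time corrected for the
#' instrumental (transducer plus detection) offset.
#'
#' @param L_mm Path length in mm (> 0).
#' @param t_us Arrival time in microseconds.
#' @param dt_us Time offset in microseconds (default 0).
#' @return Velocity in m/s.
#' @examples
#' compute_velocity(80, 52.632)  # 1520 m/s
#' @export
compute_velocity <- function(L_mm, t_us, dt_us = 0) {
  if (L_mm <= 0) stop("'L_mm' must be positive")
  if (any(t_us <= dt_us)) stop("arrival time must exceed the offset")
  L_mm / (t_us - dt_us) * 1000
}

#' Analysis window
#'
#' Half-open sample-index window `[start, end)`, 1-based.
#' @param start,end Integer sample indices, `1 <= start < end`.
#' @return List of class `qus_window`.
#' @export
window_spec <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start >= end)
    stop("invalid window: need 1 <= start < end")
  structure(list(start = start, end = end), class = "qus_window")
}

#' Windowed signal intensity
#'
#' Sum of absolute amplitudes over the half-open window `[start, end)`. The
#' rectified (absolute-value) sum is used as the intensity integral so that a
#' zero-mean burst does not cancel itself.
#'
#' @param waveform Numeric amplitude vector.
#' @param window A [window_spec()].
#' @return Scalar intensity in relative units.
#' @export
window_intensity <- function(waveform, window) {
  stopifnot(inherits(window, "qus_window"))
  if (window$end > length(waveform) + 1L)
    stop("window extends past the end of the waveform")
  sum(abs(as.numeric(waveform)[window$start:(window$end - 1L)]))
}

#' Attenuation coefficient from intensities
#'
#' `alpha = 20 * log10(I0 / I1) / L` in dB/cm, where `I0` is the
#' zero-distance (calibration) intensity and `I1` the intensity after
#' traversing `L_cm` of material.
#'
#' @param I0,I1 Positive intensities.
#' @param L_cm Path length in cm.
#' @return Attenuation in dB/cm.
#' @examples
#' compute_attenuation(10, 1, 8)  # 2.5 dB/cm
#' @export
compute_attenuation <- function(I0, I1, L_cm) {
  if (any(I0 <= 0) || any(I1 <= 0)) stop("intensities must be positive")
  if (L_cm <= 0) stop("'L_cm' must be positive")
  20 * log10(I0 / I1) / L_cm
}

#' Zero-distance calibration for criterion extraction
#'
#' Computes, from the clean excitation waveforms, everything extraction needs:
#' the zero-distance window intensities `I0` per excitation, the detection
#' offsets (arrival time of the clean excitation measured with the same
#' zero-crossing picker, which cancels the picker's systematic offset), the
#' analysis-window lengths (three excitation durations by default), the
#' transducer time offset and the sweep intensity unit.
#'
#' @param excitations Excitation set from [default_excitations()].
#' @param model Optional [acoustic_model()] supplying `transducer_offset_us`
#'   and `sweep_intensity_unit`; defaults are used if omitted.
#' @param window_durations Multiple of the excitation duration used as window
#'   length (default 3).
#' @param threshold_fraction Arrival picker threshold (default 0.2).
#' @return Object of class `qus_calibration`.
#' @export
calibration_record <- function(excitations = default_excitations(),
                               model = NULL, window_durations = 3,
                               threshold_fraction = 0.2) {
  one <- function(spec) {
    w <- synth_excitation(spec)
    fs <- spec$sample_rate_msps
    n_win <- round(window_durations * spec$duration_us * fs)
    wpad <- c(as.numeric(w), numeric(max(0L, n_win - length(w))))
    list(t0_us = detect_arrival(w, threshold_fraction, fs),
         I0 = sum(abs(wpad[seq_len(n_win)])),
         n_win = as.integer(n_win))
  }
  structure(list(
    burst_08 = one(excitations$burst_08),
    burst_22 = one(excitations$burst_22),
    sweep = one(excitations$sweep),
    transducer_offset_us = if (is.null(model)) 0 else model$transducer_offset_us,
    sweep_intensity_unit = if (is.null(model)) 1.9488 else model$sweep_intensity_unit,
    threshold_fraction = threshold_fraction,
    sample_rate_msps = excitations$burst_08$sample_rate_msps
  ), class = "qus_calibration")
}

#' Extract the six evaluation criteria from a signal train
#'
#' Computes, per signal train: velocity from the 0.8 MHz burst arrival (Cr1),
#' attenuation at 0.8 and 2.2 MHz from windowed intensities relative to the
#' zero-distance calibration (Cr2, Cr3), their ratio (Cr4), the relative
#' intensity of the direct sweep window (Cr5), and the ratio of direct to
#' triple-pass sweep intensities (Cr6). Analysis windows are anchored at the
#' detected waveform onset (arrival minus the calibration detection offset)
#' with a fixed length of three excitation durations; the triple-pass window
#' has the same length anchored at three times the direct travel time.
#'
#' @param train A [simulate_train()] result (or an equivalent list for real
#'   acquisitions).
#' @param calib A [calibration_record()].
#' @return One-row data frame: `phantom_id`, `repeat_index`, `imat`, `sat`,
#'   `cr1` (m/s), `cr2`, `cr3` (dB/cm), `cr4`, `cr5`, `cr6` (relative units).
#' @export
extract_criteria <- function(train, calib = calibration_record()) {
  stopifnot(inherits(calib, "qus_calibration"))
  fs <- train$sample_rate_msps
  L_mm <- train$path_length_mm
  L_cm <- L_mm / 10
  dt_off <- calib$transducer_offset_us
  thr <- calib$threshold_fraction

  onset_window <- function(waveform, cal) {
    t_arr <- detect_arrival(waveform, thr, fs)
    onset <- t_arr - cal$t0_us
    start <- max(1L, round(onset * fs) + 1L)
    list(t_arr = t_arr, onset = onset,
         window = window_spec(start, start + cal$n_win))
  }

  a08 <- onset_window(train$waveform_08, calib$burst_08)
  a22 <- onset_window(train$waveform_22, calib$burst_22)
  asw <- onset_window(train$waveform_sweep, calib$sweep)

  cr1 <- compute_velocity(L_mm, a08$t_arr, dt_off + calib$burst_08$t0_us)

  I1_08 <- window_intensity(train$waveform_08, a08$window)
  I1_22 <- window_intensity(train$waveform_22, a22$window)
  cr2 <- compute_attenuation(calib$burst_08$I0, I1_08, L_cm)
  cr3 <- compute_attenuation(calib$burst_22$I0, I1_22, L_cm)
  if (cr3 == 0) stop("undefined attenuation ratio: zero 2.2 MHz attenuation")
  cr4 <- cr2 / cr3

  I1_sw <- window_intensity(train$waveform_sweep, asw$window)
  cr5 <- (I1_sw / calib$sweep$I0) / calib$sweep_intensity_unit

  travel <- asw$onset - dt_off
  onset3 <- 3 * travel + dt_off
  start3 <- round(onset3 * fs) + 1L
  I3_sw <- window_intensity(train$waveform_sweep,
                            window_spec(start3, start3 + calib$sweep$n_win))
  if (I3_sw <= 0) stop("empty triple-pass window")
  cr6 <- I1_sw / I3_sw

  data.frame(phantom_id = train$phantom_id,
             repeat_index = train$repeat_index,
             imat = if (is.null(train$imat_pct)) NA_real_ else train$imat_pct,
             sat = if (is.null(train$sat_pct)) NA_real_ else train$sat_pct,
             cr1 = cr1, cr2 = cr2, cr3 = cr3, cr4 = cr4, cr5 = cr5, cr6 = cr6)
}

#' Extract criteria for every train of a dataset
#'
#' @param dataset A [generate_dataset()] result.
#' @param calib A [calibration_record()]; built from the dataset's model by
#'   default.
#' @return A criterion record data frame, one row per signal train.
#' @export
extract_dataset <- function(dataset, calib = NULL) {
  stopifnot(inherits(dataset, "qus_dataset"))
  if (is.null(calib))
    calib <- calibration_record(default_excitations(),
                                dataset$manifest$model)
  rec <- do.call(rbind, lapply(dataset$trains, extract_criteria,
                               calib = calib))
  rec$signal_number <- seq_len(nrow(rec))
  rec <- rec[, c("signal_number", "phantom_id", "repeat_index", "imat", "sat",
                 paste0("cr", 1:6))]
  class(rec) <- c("qus_records", "data.frame")
  rec
}
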