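# Seeding policy: one root seed; per-phantom and per-record substreams derived
# by hashing (phantom_id, repeat_index), so subsetting a dataset never changes
# the records that remain. Hash kept below 2^31 - 1.
substream_seed <- function(seed, phantom_id, repeat_index = 0L) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(as.character(phantom_id)))
    h <- (h * 131 + ch) %% m
  h <- (h * 131 + as.numeric(repeat_index) + 7) %% m
  as.integer(h)
}

# Between-object (fabrication) effects for one phantom, drawn once per
# (seed, phantom_id). The two burst attenuations share a common factor with
# correlation model$att_cor.
object_effects <- function(model, phantom_id, seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(substream_seed(seed, phantom_id, 0L))
  z <- stats::rnorm(5)
  rho <- model$att_cor
  s <- model$att_obj_sd
  list(velocity = model$velocity_obj_sd * z[1],
       att_08 = s[["att_08"]] * z[2],
       att_22 = s[["att_22"]] * (rho * z[2] + sqrt(1 - rho^2) * z[3]),
       att_sweep = s[["att_sweep"]] * z[4],
       att_triple = s[["att_triple"]] * z[5])
}

# Within-object disturbances for one repeat measurement. Acoustic contact is
# re-established between repeats, so a shared coupling factor scales all
# absolute through-transmission intensities together (loading sqrt(r) on the
# 0.8/2.2 MHz and sweep attenuations); the triple-pass excess is a
# within-waveform intensity ratio in which coupling cancels, so its repeat
# noise is independent. Marginal SDs equal model$att_noise_sd throughout.
record_noise <- function(model, phantom_id, repeat_index, seed) {
  set.seed(substream_seed(seed, phantom_id, repeat_index))
  z <- stats::rnorm(6)
  r <- model$noise_coupling
  a <- sqrt(r); b <- sqrt(1 - r)
  s <- model$att_noise_sd
  list(velocity = model$velocity_noise_sd * z[1],
       att_08 = s[["att_08"]] * (a * z[2] + b * z[3]),
       att_22 = s[["att_22"]] * (a * z[2] + b * z[4]),
       att_sweep = s[["att_sweep"]] * (a * z[2] + b * z[5]),
       att_triple = s[["att_triple"]] * z[6])
}

# Realized acoustic parameters of one measurement pass.
realized_params <- function(model, phantom, repeat_index, seed) {
  det <- model_params(model, phantom$sat_pct, phantom$imat_pct)
  eff <- object_effects(model, phantom$phantom_id, seed)
  eps <- record_noise(model, phantom$phantom_id, repeat_index, seed)
  clamp <- function(x) pmax(x, 1e-4)
  list(velocity = det$velocity + eff$velocity + eps$velocity,
       att_08 = clamp(det$att_08 + eff$att_08 + eps$att_08),
       att_22 = clamp(det$att_22 + eff$att_22 + eps$att_22),
       att_sweep = clamp(det$att_sweep + eff$att_sweep + eps$att_sweep),
       att_triple = clamp(det$att_triple + eff$att_triple + eps$att_triple))
}

#' Simulate one through-transmission signal train
#'
#' Generates the three received waveforms of one measurement pass through a
#' phantom: the 0.8 and 2.2 MHz tone bursts and the frequency sweep, the last
#' carrying both the direct arrival and the triple-pass (second reflection)
#' replica. The direct arrival is delayed by `L/C` plus the transducer offset
#' and scaled by `10^(-alpha * L / 20)`; the triple-pass replica is delayed by
#' `3 L / C` and additionally loses two reflection losses plus the excess
#' round-trip attenuation. Fractional delays are exact (the excitation is
#' evaluated continuously), and a small Gaussian noise floor is added.
#' Deterministic given `(seed, phantom_id, repeat_index)`.
#'
#' @param phantom One row of a [phantom_grid()] (or a list with `phantom_id`,
#'   `sat_pct`, `imat_pct`, `path_length_mm`).
#' @param model An [acoustic_model()].
#' @param repeat_index Repeat measurement index (1-based).
#' @param seed Root seed of the dataset.
#' @param excitations Excitation set from [default_excitations()].
#' @return Object of class `qus_train`: waveforms `waveform_08`,
#'   `waveform_22`, `waveform_sweep`, plus `sample_rate_msps`,
#'   `path_length_mm`, `transducer_offset_us`, ids and the true fractions.
#' @export
simulate_train <- function(phantom, model, repeat_index = 1L, seed = 1L,
                           excitations = default_excitations()) {
  stopifnot(inherits(model, "qus_model"))
  phantom <- as.list(phantom)
  L_mm <- phantom$path_length_mm
  if (is.null(L_mm) || L_mm <= 0) stop("invalid path length")
  p <- realized_params(model, phantom, repeat_index, seed)
  if (p$velocity <= 0) stop("negative effective velocity in simulation")
  L_cm <- L_mm / 10
  dt_off <- model$transducer_offset_us
  delay <- L_mm / p$velocity * 1000 + dt_off      # microseconds
  delay3 <- 3 * L_mm / p$velocity * 1000 + dt_off
  fs <- excitations$burst_08$sample_rate_msps
  amp_scale <- function(alpha) 10^(-alpha * L_cm / 20)

  # reseed once for the additive waveform noise so it is reproducible
  set.seed(substream_seed(seed, paste0(phantom$phantom_id, ":wf"), repeat_index))
  make_wave <- function(spec, scale, t_end) {
    # unit-peak normalization, matching the synthesized calibration excitation
    tau <- seq(0, spec$duration_us, by = 1 / spec$sample_rate_msps)
    scale <- scale / max(abs(excitation_amplitude(spec, tau)))
    n <- ceiling(t_end * spec$sample_rate_msps) + 1L
    t <- (seq_len(n) - 1L) / spec$sample_rate_msps
    w <- scale * excitation_amplitude(spec, t - delay)
    if (identical(spec$kind, "sweep")) {
      scale3 <- scale * 10^(-(2 * p$att_triple * L_cm +
                              2 * model$reflection_loss_db) / 20)
      if (delay3 + spec$duration_us > t_end + 1e-9)
        stop("triple-pass arrival exceeds the sweep waveform duration")
      w <- w + scale3 * excitation_amplitude(spec, t - delay3)
    }
    if (model$noise_floor > 0)
      w <- w + stats::rnorm(n, sd = model$noise_floor)
    attr(w, "sample_rate_msps") <- spec$sample_rate_msps
    w
  }
  pad <- 2  # microseconds of tail margin beyond the analysis windows
  w08 <- make_wave(excitations$burst_08, amp_scale(p$att_08),
                   delay + 3 * excitations$burst_08$duration_us + pad)
  w22 <- make_wave(excitations$burst_22, amp_scale(p$att_22),
                   delay + 3 * excitations$burst_22$duration_us + pad)
  wsw <- make_wave(excitations$sweep, amp_scale(p$att_sweep),
                   delay3 + 3 * excitations$sweep$duration_us + pad)

  structure(list(waveform_08 = w08, waveform_22 = w22, waveform_sweep = wsw,
                 sample_rate_msps = fs, path_length_mm = L_mm,
                 transducer_offset_us = dt_off,
                 phantom_id = phantom$phantom_id,
                 repeat_index = as.integer(repeat_index),
                 sat_pct = phantom$sat_pct, imat_pct = phantom$imat_pct),
            class = "qus_train")
}

#' @export
print.qus_train <- function(x, ...) {
  cat(sprintf("Signal train %s repeat %d (SAT %.1f%%, IMAT %.1f%%)\n",
              x$phantom_id, x$repeat_index, x$sat_pct, x$imat_pct))
  cat(sprintf("  waveforms: %d / %d / %d samples at %g Msps, path %.1f mm\n",
              length(x$waveform_08), length(x$waveform_22),
              length(x$waveform_sweep), x$sample_rate_msps, x$path_length_mm))
  invisible(x)
}

#' Dataset manifest
#'
#' Records everything needed to regenerate a simulated dataset: the phantom
#' grid, repeats per phantom, root seed, acoustic model and provenance notes.
#'
#' @param grid A [phantom_grid()].
#' @param repeats Repeat measurements per phantom (default 15).
#' @param seed Root seed.
#' @param model An [acoustic_model()].
#' @param notes Free-text provenance.
#' @return Object of class `qus_manifest`.
#' @export
dataset_manifest <- function(grid = phantom_grid(), repeats = 15L, seed = 1L,
                             model = acoustic_model(), notes = "") {
  stopifnot(repeats >= 1L, inherits(model, "qus_model"))
  structure(list(grid = grid, repeats = as.integer(repeats),
                 seed = as.integer(seed), model = model, notes = notes),
            class = "qus_manifest")
}

#' Generate a full dataset of signal trains
#'
#' @param manifest A [dataset_manifest()].
#' @return Object of class `qus_dataset`: list with `trains` (list of
#'   [simulate_train()] results), `truth` (data frame of ids and true
#'   fractions) and the manifest. Total records = phantoms x repeats.
#' @export
generate_dataset <- function(manifest) {
  stopifnot(inherits(manifest, "qus_manifest"))
  grid <- manifest$grid
  exc <- default_excitations()
  trains <- vector("list", nrow(grid) * manifest$repeats)
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    for (r in seq_len(manifest$repeats)) {
      k <- k + 1L
      trains[[k]] <- simulate_train(grid[i, ], manifest$model, r,
                                    manifest$seed, exc)
    }
  }
  truth <- do.call(rbind, lapply(trains, function(tr)
    data.frame(signal_number = NA_integer_, phantom_id = tr$phantom_id,
               repeat_index = tr$repeat_index, sat = tr$sat_pct,
               imat = tr$imat_pct)))
  truth$signal_number <- seq_len(nrow(truth))
  structure(list(trains = trains, truth = truth, manifest = manifest),
            class = "qus_dataset")
}

#' Simulate and extract criterion records in one streaming pass
#'
#' Memory-friendly equivalent of [generate_dataset()] followed by
#' [extract_criteria()] on every train: each signal train is synthesized,
#' reduced to its six evaluation criteria and discarded.
#'
#' @param grid A [phantom_grid()].
#' @param model An [acoustic_model()].
#' @param repeats Repeats per phantom (default 15).
#' @param seed Root seed (default 1).
#' @return A criterion record data frame (see [extract_criteria()]) with one
#'   row per signal: `signal_number`, `phantom_id`, `repeat_index`, `imat`,
#'   `sat`, `cr1` ... `cr6`.
#' @export
simulate_records <- function(grid = phantom_grid(), model = acoustic_model(),
                             repeats = 15L, seed = 1L) {
  exc <- default_excitations()
  calib <- calibration_record(exc, model)
  out <- vector("list", nrow(grid) * repeats)
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    for (r in seq_len(repeats)) {
      k <- k + 1L
      tr <- simulate_train(grid[i, ], model, r, seed, exc)
      out[[k]] <- extract_criteria(tr, calib)
    }
  }
  rec <- do.call(rbind, out)
  rec$signal_number <- seq_len(nrow(rec))
  rec <- rec[, c("signal_number", "phantom_id", "repeat_index", "imat", "sat",
                 paste0("cr", 1:6))]
  class(rec) <- c("qus_records", "data.frame")
  rec
}
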