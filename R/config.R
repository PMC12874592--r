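#' Configuration of the synthetic two-stream study
#'
#' Collects every generative parameter of the synthetic experiment. The
#' defaults reproduce the recorded study's conditions: 19 subjects, 45 trials
#' per (attended side x sequence type) cell (so about 1125 attended epochs
#' per condition and side), 25 gratings per 5 s stream at 5 Hz, a 5 degree
#' anticipatory orientation shift for rotational sequences, a 0.8 response
#' gain for rotational sequences and a 1.3 attention gain.
#'
#' The evoked response is split into an orientation-tuned component (mixed to
#' electrodes through a random weight matrix) and an untuned evoked component
#' with a fixed posterior-weighted topography. `gain_rtt` scales the untuned
#' evoked component and the SSVEP drive of rotational streams; the tuned
#' component is scaled by `gain_rtt_tuned` (default 1), so that by default
#' predictable sequences evoke less overall activity while carrying equally
#' decodable orientation information -- the regime the analyses are designed
#' to detect. Setting `gain_rtt_tuned < 1` instead emulates amplitude loss
#' with information loss.
#'
#' @param n_subjects number of synthetic subjects.
#' @param n_trials_per_cell trials per (attended side x sequence type) cell.
#' @param n_electrodes electrode count (32 default; 128 supported).
#' @param n_items gratings per stream (25 = 5 s at 5 Hz).
#' @param step rotation step / orientation grid spacing in degrees.
#' @param sfreq sampling rate, samples/s.
#' @param bias_rtt anticipatory orientation shift injected into the encoded
#'   orientation of rotational-stream epochs, degrees (clockwise positive).
#' @param gain_rtt gain (< 1 = suppression) on untuned evoked activity and
#'   SSVEP drive for rotational streams.
#' @param gain_rtt_tuned gain on the orientation-tuned evoked component for
#'   rotational streams.
#' @param gain_attended gain applied to the evoked response of attended
#'   streams and to the attended stream's SSVEP drive.
#' @param kernel_peak post-stimulus latency (s) of the evoked response peak.
#' @param kernel_width temporal width (SD, s) of the response kernel.
#' @param kernel_onset response onset latency (s); the kernel is zero before.
#' @param signal_amplitude amplitude scale of the tuned evoked component.
#' @param untuned_amplitude amplitude scale of the untuned evoked component.
#' @param noise_sd per-sample standard deviation of the additive noise.
#' @param noise_spatial_corr off-diagonal mass of the spatial noise
#'   correlation, in [0, 1).
#' @param noise_ar1 temporal AR(1) coefficient of the noise, in [0, 1).
#' @param ssvep_amplitude amplitude of the 5 Hz steady-state component at
#'   posterior electrodes contralateral to the driving stream.
#' @param bias_behavior forward shift (degrees) of the psychometric center
#'   for probes after attended rotational sequences.
#' @param sigma_behavior width (SD, degrees) of the same/different
#'   psychometric curve.
#' @param lapse lapse/guess floor of the psychometric curve, in [0, 0.5].
#' @param n_probe_per_cell behavioral probe trials per subject x condition x
#'   offset cell.
#' @param seed master seed; the whole simulation is a pure function of the
#'   config including this seed.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 19,
                       n_trials_per_cell = 45,
                       n_electrodes = 32,
                       n_items = 25,
                       step = 20,
                       sfreq = 250,
                       bias_rtt = 5,
                       gain_rtt = 0.8,
                       gain_rtt_tuned = 1,
                       gain_attended = 1.3,
                       kernel_peak = 0.12,
                       kernel_width = 0.05,
                       kernel_onset = 0.05,
                       signal_amplitude = 1,
                       untuned_amplitude = 1,
                       noise_sd = 2,
                       noise_spatial_corr = 0.3,
                       noise_ar1 = 0.5,
                       ssvep_amplitude = 0.8,
                       bias_behavior = 4,
                       sigma_behavior = 6,
                       lapse = 0.1,
                       n_probe_per_cell = 30,
                       seed = 1L) {
  cfg <- list(n_subjects = n_subjects, n_trials_per_cell = n_trials_per_cell,
              n_electrodes = n_electrodes, n_items = n_items, step = step,
              sfreq = sfreq, bias_rtt = bias_rtt, gain_rtt = gain_rtt,
              gain_rtt_tuned = gain_rtt_tuned, gain_attended = gain_attended,
              kernel_peak = kernel_peak, kernel_width = kernel_width,
              kernel_onset = kernel_onset,
              signal_amplitude = signal_amplitude,
              untuned_amplitude = untuned_amplitude,
              noise_sd = noise_sd, noise_spatial_corr = noise_spatial_corr,
              noise_ar1 = noise_ar1, ssvep_amplitude = ssvep_amplitude,
              bias_behavior = bias_behavior, sigma_behavior = sigma_behavior,
              lapse = lapse, n_probe_per_cell = n_probe_per_cell,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1, cfg$n_trials_per_cell >= 1,
            cfg$n_electrodes >= 8, cfg$n_items >= 1,
            cfg$gain_rtt > 0, cfg$gain_attended > 0, cfg$gain_rtt_tuned > 0,
            abs(cfg$bias_rtt) < 90,
            cfg$noise_spatial_corr >= 0, cfg$noise_spatial_corr < 1,
            cfg$noise_ar1 >= 0, cfg$noise_ar1 < 1,
            cfg$noise_sd >= 0, cfg$ssvep_amplitude >= 0,
            cfg$kernel_peak > cfg$kernel_onset,
            cfg$kernel_width > 0,
            cfg$lapse >= 0, cfg$lapse <= 0.5)
  invisible(cfg)
}

#' Serialize / restore a simulation config
#'
#' Configs round-trip losslessly through JSON so that runs are fully
#' reproducible from a text file.
#'
#' @param cfg a [sim_config()].
#' @param path file path.
#' @return `read_sim_config()` returns the restored `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, vals)
}
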