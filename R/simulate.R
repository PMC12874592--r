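#' Epoched EEG container
#'
#' The common currency of all EEG stages: a numeric array of
#' `n_epochs x n_electrodes x n_samples` with per-epoch metadata. Epochs span
#' -200 ms to +500 ms around grating onset (175 samples at 250 Hz).
#'
#' @param data numeric array `[n_epochs, n_electrodes, n_samples]`.
#' @param metadata data.frame with one row per epoch; columns `orientation`
#'   (degrees), `sequence_type` ("RTT"/"RDM"), `attended` (logical), `side`
#'   ("left"/"right": the stream's hemifield), `trial_id`,
#'   `position_in_trial` (1-based), `subject_id`.
#' @param sfreq sampling rate (samples/s).
#' @param t0 time of the first sample relative to grating onset (s).
#' @return object of class `epoch_array` with a `times` vector.
#' @export
epoch_array <- function(data, metadata, sfreq = 250, t0 = -0.2) {
  stopifnot(length(dim(data)) == 3, nrow(metadata) == dim(data)[1])
  structure(
    list(data = data, metadata = metadata, sfreq = sfreq, t0 = t0,
         times = t0 + (seq_len(dim(data)[3]) - 1) / sfreq),
    class = "epoch_array"
  )
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_array> %d epochs x %d electrodes x %d samples @ %g Hz, t0 = %g s\n",
              d[1], d[2], d[3], x$sfreq, x$t0))
  invisible(x)
}

#' Subset an epoch_array by epoch index
#' @param x an [epoch_array()].
#' @param i epoch indices or logical mask.
#' @return an `epoch_array` with the selected epochs.
#' @export
subset_epochs <- function(x, i) {
  epoch_array(x$data[i, , , drop = FALSE], x$metadata[i, , drop = FALSE],
              x$sfreq, x$t0)
}

#' Save / load an epoch container
#'
#' Single-file serialization of the epoch container (data array, metadata
#' table and sampling attributes) for hand-off between pipeline stages.
#'
#' @param epochs an [epoch_array()].
#' @param path file path.
#' @export
save_epochs <- function(epochs, path) {
  saveRDS(unclass(epochs), path)
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  x <- readRDS(path)
  epoch_array(x$data, x$metadata, x$sfreq, x$t0)
}

#' Post-stimulus response kernel
#'
#' Unimodal gamma-shaped evoked-response kernel: zero before `onset`, rising
#' to 1 at `peak` and decaying with temporal width `width` (SD of the
#' underlying gamma). The default (onset 50 ms, peak 120 ms, width 50 ms)
#' concentrates the evoked response inside roughly 50-300 ms post-onset, so
#' decodable signal falls where early visual responses live.
#'
#' @param t times in seconds (relative to grating onset).
#' @param peak peak latency (s).
#' @param width temporal width (s).
#' @param onset onset latency (s).
#' @return kernel values, max 1.
#' @export
response_kernel <- function(t, peak = 0.12, width = 0.05, onset = 0.05) {
  stopifnot(peak > onset, width > 0)
  m <- peak - onset
  r <- m / width
  sk <- (r + sqrt(r^2 + 4)) / 2     # sqrt(shape)
  shape <- sk^2
  theta <- width / sk
  u <- t - onset
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- (u[pos] / m)^(shape - 1) * exp(-(u[pos] - m) / theta)
  out
}

# spatially correlated (unit-variance) + AR(1) noise, dims [n_rep, e, s]
make_noise <- function(n_rep, chol_spatial, ar1, sd, n_samples) {
  e <- ncol(chol_spatial)
  z <- matrix(stats::rnorm(n_rep * e * n_samples), n_rep * e, n_samples)
  if (ar1 > 0) {
    a <- sqrt(1 - ar1^2)
    z[, 1] <- z[, 1]
    for (tt in 2:n_samples) z[, tt] <- ar1 * z[, tt - 1] + a * z[, tt]
  }
  x <- array(z, c(n_rep, e, n_samples))
  if (!is.null(chol_spatial)) {
    xm <- matrix(aperm(x, c(2, 1, 3)), e)           # e x (n_rep*s)
    xm <- crossprod(chol_spatial, xm)               # L' z, cov = L'L
    x <- aperm(array(xm, c(e, n_rep, n_samples)), c(2, 1, 3))
  }
  x * sd
}

# random spatial correlation with controllable off-diagonal mass
spatial_correlation <- function(n_electrodes, rho) {
  if (rho <= 0) return(diag(n_electrodes))
  a <- matrix(stats::rnorm(n_electrodes^2), n_electrodes)
  q <- stats::cov2cor(tcrossprod(a) + diag(1e-6, n_electrodes))
  (1 - rho) * diag(n_electrodes) + rho * q
}

subject_seeds <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  list(subjects = sample.int(.Machine$integer.max - 1, config$n_subjects),
       behavior = sample.int(.Machine$integer.max - 1, 1))
}

#' Simulate one subject of the synthetic two-stream EEG study
#'
#' Implements the forward model EEG = W C + N with known ground truth. Each
#' epoch's evoked signal is `k(t) *` (tuned + untuned component): the tuned
#' component is `W_true b(theta_enc)` where `b` is the channel basis response
#' and `theta_enc` is the true orientation shifted forward by `bias_rtt`
#' degrees for rotational-stream epochs; the untuned component has a fixed
#' posterior-weighted topography. Gains: `gain_attended` on attended-stream
#' epochs; `gain_rtt` on the untuned component and SSVEP of rotational
#' streams; `gain_rtt_tuned` on the tuned component. A 5 Hz sinusoid is added
#' at posterior electrodes contralateral to the attended side (amplitude
#' `ssvep_amplitude`, reduced by `gain_rtt` when the attended stream is
#' rotational). Noise is spatially correlated with AR(1) temporal structure
#' and is matched across conditions.
#'
#' Epochs are generated one grating at a time (no superposition of adjacent
#' gratings' responses); full 5 s trial arrays carrying the steady-state
#' (SSVEP) components of both streams plus noise are generated separately for
#' the spectral analyses.
#'
#' @param config a [sim_config()].
#' @param subject_id subject index in `1:config$n_subjects`.
#' @param layout optional shared [electrode_layout()]; built from the config
#'   when NULL.
#' @param keep_trials if FALSE, skip the 5 s trial arrays (saves memory when
#'   only epochs are needed).
#' @param keep_epochs if FALSE, skip the epoch arrays (e.g. when only the
#'   spectral trial data are needed); `epochs` is then NULL.
#' @return list with `epochs` (an [epoch_array()]), `trials` (list `data`
#'   `[n_trials, e, samples]`, `times`, `info`), `layout`, and
#'   `ground_truth` (list: `W_true`, `untuned_pattern`, per-epoch
#'   `theta_enc`, `gain_tuned`, `gain_untuned`, `ssvep_gain`, plus the
#'   spatial noise Cholesky factor).
#' @export
simulate_subject <- function(config, subject_id, layout = NULL,
                             keep_trials = TRUE, keep_epochs = TRUE) {
  validate_sim_config(config)
  stopifnot(subject_id >= 1, subject_id <= config$n_subjects)
  if (is.null(layout)) layout <- electrode_layout(config$n_electrodes)
  seeds <- subject_seeds(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seeds$subjects[subject_id])

  e <- config$n_electrodes
  basis <- basis_set()
  # orientation-tuned mixing: random but concentrated at posterior (visual)
  # electrodes, so SSVEP-driven electrode selection picks informative sites
  W_true <- matrix(stats::rnorm(e * basis$n_channels), e) / sqrt(basis$n_channels)
  row_gain <- rep(0.3, e)
  row_gain[layout$posterior] <- 1
  W_true <- W_true * row_gain
  untuned <- stats::rnorm(e, sd = 0.5)
  untuned[layout$posterior] <- untuned[layout$posterior] + 1  # posterior-weighted
  sigma_s <- spatial_correlation(e, config$noise_spatial_corr)
  Ls <- chol(sigma_s)

  design <- make_trial_design(config$n_trials_per_cell, config$n_items,
                              config$step)
  n_trials <- nrow(design)
  n_ep <- n_trials * 2L * config$n_items
  s <- as.integer(0.7 * config$sfreq)               # -0.2 .. 0.5 s
  times <- -0.2 + (seq_len(s) - 1) / config$sfreq
  kern <- response_kernel(times, config$kernel_peak, config$kernel_width,
                          config$kernel_onset)

  # per-epoch metadata
  md <- data.frame(
    trial_id = rep(design$trial_id, each = 2L * config$n_items),
    side = rep(rep(c("left", "right"), each = config$n_items), n_trials),
    position_in_trial = rep(seq_len(config$n_items), 2L * n_trials),
    stringsAsFactors = FALSE
  )
  md$orientation <- unlist(lapply(seq_len(n_trials), function(i)
    c(design$seq_left[[i]], design$seq_right[[i]])))
  md$attended <- md$side == rep(design$attended_side, each = 2L * config$n_items)
  rtt_side <- rep(design$rtt_side, each = 2L * config$n_items)
  md$sequence_type <- ifelse(md$side == rtt_side, "RTT", "RDM")
  md$attended_side <- rep(design$attended_side, each = 2L * config$n_items)
  md$condition <- rep(design$condition, each = 2L * config$n_items)
  md$subject_id <- subject_id

  # independent RNG streams for the epoch and trial sections so that either
  # can be skipped without changing the other (bit-reproducibility)
  epoch_seed <- sample.int(.Machine$integer.max - 1, 1)
  trial_seed <- sample.int(.Machine$integer.max - 1, 1)

  is_rtt <- md$sequence_type == "RTT"
  theta_enc <- wrap_orientation(md$orientation + ifelse(is_rtt, config$bias_rtt, 0))
  g_att <- ifelse(md$attended, config$gain_attended, 1)
  gain_tuned <- g_att * ifelse(is_rtt, config$gain_rtt_tuned, 1) *
    config$signal_amplitude
  gain_untuned <- g_att * ifelse(is_rtt, config$gain_rtt, 1) *
    config$untuned_amplitude
  ssvep_gain <- config$ssvep_amplitude *
    ifelse(md$condition == "RTT", config$gain_rtt, 1)

  post_x <- layout$positions[layout$posterior, 1]
  post_left <- layout$posterior[post_x < 0]
  post_right <- layout$posterior[post_x > 0]

  epochs <- NULL
  if (keep_epochs) {
    set.seed(epoch_seed)
    # spatial amplitude pattern per epoch: e x n_ep
    Benc <- channel_matrix(theta_enc, basis)
    A <- W_true %*% Benc
    A <- sweep(A, 2, gain_tuned, `*`) + outer(untuned, gain_untuned)
    arr <- outer(t(A), kern)                        # n_ep x e x s
    # SSVEP at posterior electrodes contralateral to the attended side
    s5 <- sin(2 * pi * 5 * times)
    for (side in c("left", "right")) {
      contra <- if (side == "left") post_right else post_left
      idx <- which(md$attended_side == side)
      if (length(idx) && length(contra)) {
        add <- outer(ssvep_gain[idx], s5)
        for (el in contra) arr[idx, el, ] <- arr[idx, el, ] + add
      }
    }
    if (config$noise_sd > 0) {
      arr <- arr + make_noise(n_ep, Ls, config$noise_ar1, config$noise_sd, s)
    }
    epochs <- epoch_array(arr, md, config$sfreq, -0.2)
  }

  trials <- NULL
  if (keep_trials) {
    set.seed(trial_seed)
    nts <- as.integer(5 * config$sfreq)
    ttimes <- (seq_len(nts) - 1) / config$sfreq
    drive <- sin(2 * pi * 5 * ttimes) + 0.5 * sin(2 * pi * 10 * ttimes)
    tarr <- if (config$noise_sd > 0) {
      make_noise(n_trials, Ls, config$noise_ar1, config$noise_sd, nts)
    } else array(0, c(n_trials, e, nts))
    for (stream in c("left", "right")) {
      contra <- if (stream == "left") post_right else post_left
      att <- design$attended_side == stream
      st_rtt <- design$rtt_side == stream
      amp <- config$ssvep_amplitude * ifelse(att, config$gain_attended, 1) *
        ifelse(st_rtt, config$gain_rtt, 1)
      add <- outer(amp, drive)
      for (el in contra) tarr[, el, ] <- tarr[, el, ] + add
    }
    trials <- list(data = tarr, times = ttimes,
                   info = design[, c("trial_id", "attended_side", "condition",
                                     "rtt_side")])
  }

  list(epochs = epochs, trials = trials, layout = layout,
       ground_truth = list(W_true = W_true, untuned_pattern = untuned,
                           theta_enc = theta_enc, gain_tuned = gain_tuned,
                           gain_untuned = gain_untuned,
                           ssvep_gain = ssvep_gain, chol_spatial = Ls,
                           kernel = kern, times = times))
}

#' Simulate the whole synthetic study
#'
#' Convenience wrapper returning all subjects at once. For large configs
#' prefer calling [simulate_subject()] inside a loop and discarding each
#' subject's raw arrays after analysis: the per-subject simulation is a pure
#' function of (config, subject_id), so subjects can be regenerated
#' bit-identically at any time.
#'
#' @inheritParams simulate_subject
#' @param subjects subject indices to generate.
#' @return list of per-subject results (see [simulate_subject()]).
#' @export
simulate_eeg_dataset <- function(config, subjects = seq_len(config$n_subjects),
                                 keep_trials = TRUE) {
  layout <- electrode_layout(config$n_electrodes)
  lapply(subjects, function(sid)
    simulate_subject(config, sid, layout = layout, keep_trials = keep_trials))
}

#' Simulate same/different probe responses
#'
#' After each trial a central probe is shown at the last attended orientation
#' plus an offset of -4, 0 or +4 degrees; the observer reports whether it
#' matched. Responses follow a Gaussian psychometric curve with a lapse
#' floor: `P(same | o) = lapse + (1 - 2 lapse) exp(-(o - mu)^2 / (2
#' sigma^2))` with `mu = bias_behavior` after attended rotational sequences
#' (the perceived final orientation is shifted forward) and `mu = 0` after
#' random sequences. Responses are drawn independently.
#'
#' @param config a [sim_config()].
#' @param n_probe_per_cell probe trials per subject x condition x offset
#'   cell; defaults to `config$n_probe_per_cell`.
#' @return data.frame (the behavioral table) with columns `subject_id`,
#'   `sequence_type`, `probe_offset`, `response` ("same"/"different").
#' @export
simulate_behavior <- function(config, n_probe_per_cell = NULL) {
  validate_sim_config(config)
  if (is.null(n_probe_per_cell)) n_probe_per_cell <- config$n_probe_per_cell
  seeds <- subject_seeds(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seeds$behavior)
  cells <- expand.grid(subject_id = seq_len(config$n_subjects),
                       sequence_type = c("RTT", "RDM"),
                       probe_offset = c(-4, 0, 4),
                       stringsAsFactors = FALSE)
  tab <- cells[rep(seq_len(nrow(cells)), each = n_probe_per_cell), ]
  mu <- ifelse(tab$sequence_type == "RTT", config$bias_behavior, 0)
  p <- config$lapse + (1 - 2 * config$lapse) *
    exp(-(tab$probe_offset - mu)^2 / (2 * config$sigma_behavior^2))
  tab$response <- ifelse(stats::runif(nrow(tab)) < p, "same", "different")
  rownames(tab) <- NULL
  tab
}
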