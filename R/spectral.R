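#' Trial-averaged power spectrum
#'
#' Periodogram of each trial's raw (untapered) signal, averaged over trials.
#' With a 5 s window at 250 Hz the frequency resolution is 0.2 Hz, so the
#' 5 Hz tagging frequency and its 10 Hz harmonic fall on exact bins and are
#' leakage-free. Power is one-sided amplitude-squared/2 per bin (a unit
#' sinusoid contributes 0.5 at its bin), so summed power over non-DC bins
#' equals the time-domain variance (Parseval).
#'
#' @param trials numeric array `[n_trials, n_electrodes, n_samples]`.
#' @param sfreq sampling rate (samples/s).
#' @param fmax keep frequencies up to `fmax` Hz (default: Nyquist).
#' @return list of class `power_spectrum`: `frequencies` (Hz), `power`
#'   (electrodes x frequencies, trial-averaged), `n_trials`, `window`
#'   (seconds).
#' @export
trial_power_spectrum <- function(trials, sfreq = 250, fmax = NULL) {
  stopifnot(length(dim(trials)) == 3)
  n <- dim(trials)[3]
  win <- n / sfreq
  if (win < 5 - 1e-9) {
    stop("trial span is ", win, " s; at least 5 s needed for 0.2 Hz resolution")
  }
  freqs <- (0:(n %/% 2)) * sfreq / n
  if (is.null(fmax)) fmax <- sfreq / 2
  keep <- freqs <= fmax + 1e-12
  ne <- dim(trials)[2]
  pw <- matrix(0, ne, sum(keep))
  m <- matrix(aperm(trials, c(3, 1, 2)), nrow = n)   # samples x (trials*elec)
  sp <- stats::mvfft(m)
  a2 <- Mod(sp[seq_len(n %/% 2 + 1), , drop = FALSE])^2 / n^2
  scale <- rep(2, n %/% 2 + 1)
  scale[1] <- 1
  if (n %% 2 == 0) scale[n %/% 2 + 1] <- 1
  a2 <- a2 * scale
  p_te <- array(a2, c(n %/% 2 + 1, dim(trials)[1], ne))
  pw <- t(apply(p_te, c(1, 3), mean))[, keep, drop = FALSE]
  structure(list(frequencies = freqs[keep], power = pw,
                 n_trials = dim(trials)[1], window = win),
            class = "power_spectrum")
}

#' Time-resolved power at the tagging frequency
#'
#' Amplitude envelope at `freq` (default 5 Hz) via convolution with a 1 s
#' Hann-tapered complex sinusoid (short-time Fourier style; a Gaussian-taper
#' variant is available), squared to power. Power is normalized so a
#' stationary sinusoid of amplitude a yields a constant a^2. The analysis
#' span (default 0.5-5 s) excludes onset transients and edge effects.
#'
#' @param trials array `[n_trials, n_electrodes, n_samples]`, time starting
#'   at 0 s.
#' @param sfreq sampling rate.
#' @param freq analysis frequency in Hz.
#' @param window taper length in seconds.
#' @param span `c(start, end)` of analysis window centers, seconds.
#' @param step spacing of window centers in seconds (default 20 ms; the
#'   5 Hz envelope varies slowly relative to the 1 s taper).
#' @param taper "hann" (default) or "gaussian" (SD = window/6).
#' @return list of class `tf_power`: `times` (s), `power`
#'   `[n_trials, n_electrodes, n_times]`.
#' @export
tf_power_5hz <- function(trials, sfreq = 250, freq = 5, window = 1,
                         span = c(0.5, 5), step = 0.02,
                         taper = c("hann", "gaussian")) {
  taper <- match.arg(taper)
  stopifnot(length(dim(trials)) == 3)
  n <- dim(trials)[3]
  if (window > n / sfreq) stop("taper window exceeds the trial length")
  wl <- round(window * sfreq)
  half <- wl %/% 2
  tt <- (seq_len(wl) - 1 - half) / sfreq
  w <- if (taper == "hann") {
    0.5 - 0.5 * cos(2 * pi * (seq_len(wl) - 1) / (wl - 1))
  } else {
    exp(-tt^2 / (2 * (window / 6)^2))
  }
  kern <- w * exp(-2i * pi * freq * tt)
  kern <- kern / sum(w) * 2                # unit-amplitude sinusoid -> |.| = 1
  centers <- which((seq_len(n) - 1) / sfreq >= span[1] &
                     (seq_len(n) - 1) / sfreq <= span[2] + 1e-12)
  centers <- centers[centers - half >= 1 & centers + (wl - 1 - half) <= n]
  centers <- centers[seq(1, length(centers), by = max(1L, round(step * sfreq)))]
  if (!length(centers)) stop("analysis span does not fit inside the trial")
  # gather matrix: window samples x centers
  idx <- outer((-half):(wl - 1 - half), centers, `+`)
  m <- matrix(aperm(trials, c(3, 1, 2)), nrow = n)   # samples x (tr*elec)
  env <- matrix(0, length(centers), ncol(m))
  # complex dot products per center on the gathered windows
  for (ci in seq_along(centers)) {
    seg <- m[idx[, ci], , drop = FALSE]
    env[ci, ] <- Mod(crossprod(seg, kern))
  }
  pw <- array(t(env^2), c(dim(trials)[1], dim(trials)[2], length(centers)))
  structure(list(times = (centers - 1) / sfreq, power = pw,
                 freq = freq, window = window),
            class = "tf_power")
}

#' Select electrodes with the strongest SSVEP response
#'
#' Takes the union of the electrodes whose trial-averaged power exceeds the
#' 75th percentile at the tagging frequency (5 Hz) and at its first harmonic
#' (10 Hz). With 128 electrodes each quartile set has 32 members, so the
#' union has between 32 and 64; the intersection could never reach the
#' 39-electrode subsets typical of this selection rule. Selection is
#' scale-invariant.
#'
#' @param psd a [trial_power_spectrum()].
#' @param percentile percentile cutoff (default 75).
#' @param freqs the two frequencies (Hz) whose quartile sets are united.
#' @return sorted integer vector of selected electrode indices.
#' @export
select_ssvep_electrodes <- function(psd, percentile = 75, freqs = c(5, 10)) {
  sel <- integer(0)
  for (f in freqs) {
    bin <- which.min(abs(psd$frequencies - f))
    if (abs(psd$frequencies[bin] - f) > 1e-6)
      stop("frequency ", f, " Hz is not an exact bin of this spectrum")
    p <- psd$power[, bin]
    q <- stats::quantile(p, percentile / 100, names = FALSE)
    sel <- union(sel, which(p > q))
  }
  sort(sel)
}

#' Global field power
#'
#' Standard deviation of the potential across electrodes at each time point
#' (sample SD, n-1 denominator), a reference-free index of overall response
#' strength, averaged over epochs within condition groups.
#'
#' @param epochs an [epoch_array()] (or a plain `[epochs, electrodes,
#'   samples]` array).
#' @param by metadata columns defining the condition groups (ignored for
#'   plain arrays).
#' @return list of class `gfp_series`: `times`, `series` (groups x samples
#'   matrix of epoch-averaged GFP), `groups`, and `epoch_gfp`
#'   (epochs x samples).
#' @export
gfp <- function(epochs, by = c("sequence_type", "attended")) {
  if (inherits(epochs, "epoch_array")) {
    arr <- epochs$data
    md <- epochs$metadata
    times <- epochs$times
  } else {
    arr <- epochs
    md <- NULL
    times <- seq_len(dim(arr)[3])
  }
  stopifnot(dim(arr)[2] >= 2)
  n_ep <- dim(arr)[1]; ne <- dim(arr)[2]; ns <- dim(arr)[3]
  m <- matrix(aperm(arr, c(2, 1, 3)), nrow = ne)    # elec x (ep*samples)
  mu <- colMeans(m)
  sdv <- sqrt(colSums((m - rep(mu, each = ne))^2) / (ne - 1))
  eg <- matrix(sdv, n_ep, ns)
  if (!is.null(md) && length(by)) {
    grp <- interaction(md[, by, drop = FALSE], sep = "_", drop = TRUE)
    series <- rowsum(eg, grp) / as.vector(table(grp))
  } else {
    series <- matrix(colMeans(eg), 1, ns, dimnames = list("all", NULL))
  }
  structure(list(times = times, series = series,
                 groups = rownames(series), epoch_gfp = eg),
            class = "gfp_series")
}
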