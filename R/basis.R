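#' Orientation channel basis set
#'
#' The encoding model assumes 18 orientation-tuned channels with preferred
#' orientations 0, 10, ..., 170 degrees. Each channel's tuning curve is a
#' half-wave rectified cosine raised to the 18th power of the wrapped
#' orientation difference: `max(0, cos(pi * delta / 180))^18`, which peaks at
#' 1 on the channel's preferred orientation, falls to 0 at +/-90 degrees, and
#' is 180-degree periodic.
#'
#' @param n_channels number of channels (default 18).
#' @param exponent power applied to the rectified cosine (default 18).
#' @return object of class `basis_set` with fields `centers` (degrees),
#'   `n_channels`, `exponent`, and `spacing` (degrees between centers).
#' @export
basis_set <- function(n_channels = 18, exponent = 18) {
  stopifnot(n_channels >= 2, 180 %% n_channels == 0 || n_channels == 18,
            exponent > 0)
  spacing <- 180 / n_channels
  structure(
    list(centers = seq(0, 180 - spacing, by = spacing),
         n_channels = n_channels, exponent = exponent, spacing = spacing),
    class = "basis_set"
  )
}

#' Ideal channel responses to an orientation
#'
#' @param theta orientation(s) in degrees.
#' @param basis a [basis_set()].
#' @return if `theta` is scalar, a vector of `n_channels` responses in
#'   [0, 1]; otherwise a `n_channels x length(theta)` matrix (the channel
#'   response matrix C with one column per stimulus).
#' @examples
#' b <- basis_set()
#' basis_responses(30, b)[4]   # channel at 30 deg responds 1
#' @export
basis_responses <- function(theta, basis = basis_set()) {
  delta <- outer(basis$centers, theta, function(cc, th) orientation_diff(th, cc))
  r <- pmax(cos(delta * pi / 180), 0)^basis$exponent  # matrix first: keep dims
  if (length(theta) == 1L) as.vector(r) else r
}

#' Channel response matrix for a set of epochs
#'
#' Column j is the ideal response of every channel to the orientation shown
#' on epoch j (the hypothetical channel output matrix C of the forward model
#' EEG = W C + N).
#'
#' @param orientations vector of epoch orientations in degrees.
#' @inheritParams basis_responses
#' @return `n_channels x n_epochs` matrix.
#' @export
channel_matrix <- function(orientations, basis = basis_set()) {
  m <- basis_responses(orientations, basis)
  if (is.vector(m)) m <- matrix(m, ncol = 1)
  m
}

#' Channel-offset axis of a realigned CTF
#'
#' Offsets in degrees relative to the true stimulus orientation, from -90 to
#' +80 in `spacing` steps; offset 0 is the channel preferring the presented
#' orientation.
#'
#' @inheritParams basis_responses
#' @return numeric vector of length `n_channels`.
#' @export
ctf_offsets <- function(basis = basis_set()) {
  basis$spacing * (seq_len(basis$n_channels) - 1) - 90
}

#' Circularly realign a raw CTF to the true orientation
#'
#' Reconstructed channel responses are indexed by preferred orientation;
#' realignment is a pure circular shift (no interpolation) placing the
#' channel preferring the presented orientation at offset 0 on the
#' [ctf_offsets()] axis. The true orientation must lie exactly on a channel
#' center (the 20-degree stimulus grid is a subset of the 10-degree centers).
#'
#' @param raw_ctf numeric vector of `n_channels` raw responses, ordered by
#'   channel center, or a `n_channels x k` matrix (each column realigned to
#'   the matching element of `true_orientation`).
#' @param true_orientation presented orientation(s) in degrees.
#' @inheritParams basis_responses
#' @return realigned vector/matrix; element at offset 0 is the response of
#'   the true-orientation channel.
#' @export
realign_ctf <- function(raw_ctf, true_orientation, basis = basis_set()) {
  k <- basis$n_channels
  mat <- if (is.matrix(raw_ctf)) raw_ctf else matrix(raw_ctf, ncol = 1)
  stopifnot(nrow(mat) == k,
            length(true_orientation) %in% c(1L, ncol(mat)))
  true_orientation <- rep_len(true_orientation, ncol(mat))
  idx0 <- true_orientation / basis$spacing
  if (any(abs(idx0 - round(idx0)) > 1e-9)) {
    stop("true orientation must lie on a channel center (multiple of ",
         basis$spacing, " degrees); realignment is a pure shift")
  }
  idx0 <- round(idx0)
  offs <- ctf_offsets(basis) / basis$spacing  # -9 .. 8 in channel units
  out <- mat
  for (j in seq_len(ncol(mat))) {
    src <- ((idx0[j] + offs) %% k) + 1L
    out[, j] <- mat[src, j]
  }
  if (is.matrix(raw_ctf)) out else as.vector(out)
}

#' Undo [realign_ctf()]
#'
#' @inheritParams realign_ctf
#' @param realigned_ctf vector/matrix on the channel-offset axis.
#' @return raw-channel-ordered vector/matrix.
#' @export
unalign_ctf <- function(realigned_ctf, true_orientation, basis = basis_set()) {
  k <- basis$n_channels
  mat <- if (is.matrix(realigned_ctf)) realigned_ctf else matrix(realigned_ctf, ncol = 1)
  true_orientation <- rep_len(true_orientation, ncol(mat))
  idx0 <- round(true_orientation / basis$spacing)
  offs <- ctf_offsets(basis) / basis$spacing
  out <- mat
  for (j in seq_len(ncol(mat))) {
    src <- ((idx0[j] + offs) %% k) + 1L
    out[src, j] <- mat[, j]
  }
  if (is.matrix(realigned_ctf)) out else as.vector(out)
}

#' Ideal realigned CTF
#'
#' The ground-truth tuning profile on the channel-offset axis: the basis
#' function centered at offset 0.
#'
#' @inheritParams basis_responses
#' @return numeric vector of length `n_channels`.
#' @export
ideal_ctf <- function(basis = basis_set()) {
  pmax(0, cos(ctf_offsets(basis) * pi / 180))^basis$exponent
}

#' Decoding score of a realigned CTF
#'
#' Slope of the ordinary least-squares regression (intercept included) of the
#' reconstructed CTF on the ideal tuning function centered at 0. A score of 1
#' means perfect shape recovery, 0 means no orientation tuning. The score is
#' invariant to adding a constant to the CTF and scales linearly with its
#' gain.
#'
#' @param realigned_ctf numeric vector on the channel-offset axis, or a
#'   matrix with one CTF per column.
#' @inheritParams basis_responses
#' @return numeric slope (vector if a matrix was supplied).
#' @export
decoding_score <- function(realigned_ctf, basis = basis_set()) {
  ideal <- ideal_ctf(basis)
  ic <- ideal - mean(ideal)
  denom <- sum(ic^2)
  if (is.matrix(realigned_ctf)) {
    as.vector(crossprod(ic, realigned_ctf)) / denom
  } else {
    sum(ic * realigned_ctf) / denom
  }
}

#' Gaussian fit of a realigned CTF
#'
#' Fits `a * exp(-(x - mu)^2 / (2 sigma^2)) + b` over the channel-offset axis
#' by Levenberg-Marquardt nonlinear least squares, with `mu` bounded to
#' [-45, 45] degrees and `sigma` to [5, 90]. `mu` estimates the bias of the
#' decoded orientation relative to the true one; positive values point in
#' the direction of clockwise rotation. Initialization: `mu` at the argmax
#' (lowest offset wins ties), `sigma` at 20, `a` at the observed range, `b`
#' at the minimum. Degenerate (flat) inputs and non-convergence are flagged
#' rather than fitted.
#'
#' @param ctf_avg realigned CTF (vector over channel offsets), typically
#'   averaged over epochs and a significant time cluster.
#' @inheritParams basis_responses
#' @return list with `amplitude`, `center`, `width`, `baseline`,
#'   `converged` (logical), and `fitted` values (NULL when flagged).
#' @export
fit_gaussian_bias <- function(ctf_avg, basis = basis_set()) {
  x <- ctf_offsets(basis)
  stopifnot(length(ctf_avg) == length(x), all(is.finite(ctf_avg)))
  rng <- diff(range(ctf_avg))
  failed <- list(amplitude = NA_real_, center = NA_real_, width = NA_real_,
                 baseline = NA_real_, converged = FALSE, fitted = NULL)
  if (rng < 1e-12) {
    warning("flat CTF: Gaussian fit is degenerate, excluded")
    return(failed)
  }
  i0 <- which(ctf_avg == max(ctf_avg))[1]  # lowest-offset tie-break
  b0 <- min(ctf_avg)
  if (abs(b0) < 1e-6 * rng) b0 <- 0  # tiny starts break LM parameter scaling
  dat <- data.frame(x = x, y = as.numeric(ctf_avg))
  lm_fit <- function(start) tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-(x - mu)^2 / (2 * sigma^2)) + b,
      data = dat, start = start,
      lower = c(a = 0, mu = -45, sigma = 5, b = -Inf),
      upper = c(a = Inf, mu = 45, sigma = 90, b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  fit <- lm_fit(list(a = rng, mu = max(-45, min(45, x[i0])), sigma = 20,
                     b = b0))
  if (is.null(fit)) fit <- lm_fit(list(a = rng, mu = 0, sigma = 30, b = b0))
  if (!is.null(fit)) {
    p <- stats::coef(fit)
    return(list(amplitude = unname(p["a"]), center = unname(p["mu"]),
                width = unname(p["sigma"]), baseline = unname(p["b"]),
                converged = TRUE, fitted = stats::fitted(fit)))
  }
  # bounded quasi-Newton fallback on the same least-squares objective
  sse <- function(par) sum((par[1] * exp(-(x - par[2])^2 / (2 * par[3]^2)) +
                              par[4] - ctf_avg)^2)
  opt <- tryCatch(
    stats::optim(c(rng, max(-45, min(45, x[i0])), 20, b0), sse,
                 method = "L-BFGS-B",
                 lower = c(0, -45, 5, -Inf), upper = c(Inf, 45, 90, Inf)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0) {
    warning("Gaussian CTF fit did not converge; excluded")
    return(failed)
  }
  list(amplitude = opt$par[1], center = opt$par[2], width = opt$par[3],
       baseline = opt$par[4], converged = TRUE,
       fitted = opt$par[1] * exp(-(x - opt$par[2])^2 / (2 * opt$par[3]^2)) +
         opt$par[4])
}
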