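#' Estimate encoding-model weights by least squares
#'
#' Fits the forward model `EEG = W C + N` on training data: `W` (electrodes x
#' channels) minimizes `||EEG - W C||^2` via the Moore-Penrose pseudoinverse,
#' `W = EEG C' (C C')^+`. With stimuli restricted to the 9-orientation grid,
#' `C` has rank 9 < 18; the pseudoinverse then yields the minimum-norm least
#' squares solution and a warning is emitted once.
#'
#' @param train_eeg numeric matrix `electrodes x n_train` (window features).
#' @param C_train channel response matrix `n_channels x n_train` (see
#'   [channel_matrix()]).
#' @param warn_rank warn when `C` is rank deficient.
#' @return weight matrix `electrodes x n_channels`.
#' @export
estimate_weights <- function(train_eeg, C_train, warn_rank = TRUE) {
  stopifnot(is.matrix(train_eeg), is.matrix(C_train),
            ncol(train_eeg) == ncol(C_train))
  if (ncol(C_train) < nrow(C_train)) {
    stop("need at least as many training epochs as channels (",
         nrow(C_train), "), got ", ncol(C_train))
  }
  r <- qr(C_train)$rank
  if (r == 0) stop("channel matrix is all zeros (rank 0); cannot train")
  if (r < nrow(C_train) && warn_rank) {
    warning("channel matrix has rank ", r, " < ", nrow(C_train),
            "; using minimum-norm pseudoinverse solution")
  }
  G <- tcrossprod(C_train)
  train_eeg %*% crossprod(C_train, MASS::ginv(G))
}

#' Shrinkage-regularized noise covariance of training residuals
#'
#' Sample covariance of the residuals shrunk toward its diagonal with the
#' analytic (Schafer-Strimmer) shrinkage intensity: off-diagonal entries are
#' scaled by `1 - lambda` where `lambda` balances the estimation variance of
#' the sample covariances against their squared magnitude. Degenerate
#' (near-zero) residuals fall back to the identity, which reduces the optimal
#' filter to the plain pseudoinverse.
#'
#' @param residuals matrix `electrodes x n` of training residuals
#'   (`EEG_train - W C_train`).
#' @param lambda shrinkage intensity in [0, 1]; "auto" (default) uses the
#'   analytic estimate.
#' @return list `sigma` (covariance), `lambda` (intensity used).
#' @export
shrinkage_cov <- function(residuals, lambda = "auto") {
  stopifnot(is.matrix(residuals), ncol(residuals) >= 2)
  n <- ncol(residuals)
  xc <- residuals - rowMeans(residuals)
  S <- tcrossprod(xc) / (n - 1)
  tot <- sum(diag(S))
  if (tot < 1e-14) {
    return(list(sigma = diag(nrow(residuals)), lambda = 1))
  }
  if (identical(lambda, "auto")) {
    wbar <- S * (n - 1) / n
    varS <- (n / (n - 1)^3) * (tcrossprod(xc^2) - n * wbar^2)
    off <- row(S) != col(S)
    denom <- sum(S[off]^2)
    lambda <- if (denom < 1e-14) 1 else sum(varS[off]) / denom
    lambda <- max(0, min(1, lambda))
  }
  sigma <- S
  sigma[row(S) != col(S)] <- (1 - lambda) * S[row(S) != col(S)]
  list(sigma = sigma, lambda = lambda)
}

#' Noise-covariance-aware inversion filter
#'
#' Derives the spatial filter used to reconstruct channel responses from
#' test data, accounting for the noise correlation structure across
#' electrodes: `V = Sigma^-1 W (W' Sigma^-1 W)^+`, where `Sigma` is the
#' shrinkage-regularized covariance of the training residuals. By
#' construction `V' W = I` (up to the rank of `W`); with white noise
#' (`Sigma` proportional to the identity) `V` reduces to the transposed
#' pseudoinverse of `W`.
#'
#' @param W weight matrix `electrodes x n_channels` from
#'   [estimate_weights()].
#' @param residuals training residuals `electrodes x n_train`; ignored when
#'   `noise_cov` is supplied.
#' @param noise_cov optional known noise covariance (electrodes x
#'   electrodes), bypassing estimation.
#' @param lambda shrinkage intensity passed to [shrinkage_cov()].
#' @return list of class `inversion_filter`: `V` (electrodes x n_channels),
#'   `noise_cov`, `lambda`.
#' @export
compute_filter <- function(W, residuals = NULL, noise_cov = NULL,
                           lambda = "auto") {
  stopifnot(is.matrix(W))
  lam <- NA_real_
  if (is.null(noise_cov)) {
    if (is.null(residuals)) stop("supply residuals or noise_cov")
    sc <- shrinkage_cov(residuals, lambda)
    noise_cov <- sc$sigma
    lam <- sc$lambda
  }
  isig <- tryCatch(solve(noise_cov),
                   error = function(e) stop(
                     "noise covariance is not invertible after shrinkage: ",
                     conditionMessage(e)))
  iw <- isig %*% W
  V <- iw %*% MASS::ginv(crossprod(W, iw))
  structure(list(V = V, noise_cov = noise_cov, lambda = lam),
            class = "inversion_filter")
}

#' Reconstruct channel responses from test data
#'
#' Applies the inversion filter: `C_test = V' EEG_test`.
#'
#' @param filter an `inversion_filter` from [compute_filter()] (or a plain
#'   matrix `V`).
#' @param test_eeg matrix `electrodes x n_test`.
#' @return raw channel responses `n_channels x n_test` (columns ordered by
#'   channel center; realign with [realign_ctf()]).
#' @export
reconstruct_ctf <- function(filter, test_eeg) {
  V <- if (inherits(filter, "inversion_filter")) filter$V else filter
  if (is.vector(test_eeg)) test_eeg <- matrix(test_eeg, ncol = 1)
  if (nrow(test_eeg) != nrow(V)) {
    stop("electrode dimension mismatch: filter has ", nrow(V),
         ", data has ", nrow(test_eeg))
  }
  crossprod(V, test_eeg)
}

# ---- sliding-window decoding ------------------------------------------------

# window features: mean amplitude per electrode in a win_samples window
# centered on each valid sample; returns list(features = [epochs, e, n_win],
# centers = sample indices, times)
window_features <- function(epochs, win_samples) {
  d <- dim(epochs$data)
  half_lo <- floor((win_samples - 1) / 2)
  half_hi <- win_samples - 1 - half_lo
  centers <- (1 + half_lo):(d[3] - half_hi)
  # banded averaging matrix: samples x n_windows
  Bmat <- matrix(0, d[3], length(centers))
  for (j in seq_along(centers)) {
    Bmat[(centers[j] - half_lo):(centers[j] + half_hi), j] <- 1 / win_samples
  }
  m <- matrix(epochs$data, d[1] * d[2], d[3])
  f <- m %*% Bmat
  list(features = array(f, c(d[1], d[2], length(centers))),
       centers = centers, times = epochs$times[centers])
}

# exact LOO reconstruction of the training pool via the reduced (class-mean)
# form of the OLS + optimal-filter equations; see package vignette.
# X: e x n features; cls: class index per epoch; B: channels x classes basis
# at the grid; S_raw: full-pool residual covariance (unshrunk); lambda:
# shrinkage intensity (held fixed across folds). Both the class means
# (weights) and the noise covariance are down-dated for each fold, so no
# epoch contributes to its own reconstruction through any estimated
# quantity. Returns channels x n raw CTFs.
loo_reconstruct <- function(X, cls, B, S_raw, lambda, loo_groups = NULL) {
  n <- ncol(X)
  k <- ncol(B)
  e <- nrow(X)
  ng <- tabulate(cls, nbins = k)
  Msum <- rowsum_cols(X, cls, k)                    # e x k class sums
  M <- sweep(Msum, 2, pmax(ng, 1), `/`)
  R <- X - M[, cls, drop = FALSE]                   # full-pool residuals
  offd <- row(S_raw) != col(S_raw)
  out <- matrix(0, nrow(B), n)
  if (is.null(loo_groups)) loo_groups <- seq_len(n) # one epoch per fold
  for (fold in unique(loo_groups)) {
    jj <- which(loo_groups == fold)
    gset <- cls[jj]
    # downdate class means for the held-out epochs
    Mf <- M
    ok <- TRUE
    for (g in unique(gset)) {
      sub <- jj[gset == g]
      nrem <- ng[g] - length(sub)
      if (nrem < 1) { ok <- FALSE; break }
      Mf[, g] <- (Msum[, g] - rowSums(X[, sub, drop = FALSE])) / nrem
    }
    if (!ok) next
    # downdate the residual covariance (drop the fold's residual outer
    # products; the within-class mean shift is O(1/n_g) and ignored)
    Rj <- R[, jj, drop = FALSE]
    Sf <- (S_raw * (n - 1) - tcrossprod(Rj)) / max(n - 1 - length(jj), 1)
    Sf[offd] <- (1 - lambda) * Sf[offd]
    sol_in <- tryCatch(solve(Sf, cbind(Mf, X[, jj, drop = FALSE])),
                       error = function(err) MASS::ginv(Sf) %*%
                         cbind(Mf, X[, jj, drop = FALSE]))
    iMf <- sol_in[, seq_len(k), drop = FALSE]
    iXj <- sol_in[, k + seq_along(jj), drop = FALSE]
    Gf <- crossprod(Mf, iMf)
    Vrhs <- crossprod(Mf, iXj)                      # k x |fold|
    sol <- tryCatch(solve(Gf, Vrhs), error = function(e) MASS::ginv(Gf) %*% Vrhs)
    out[, jj] <- B %*% sol
  }
  out
}

rowsum_cols <- function(X, groups, nbins = max(groups)) {
  # column-group sums of X (e x n) -> e x nbins (absent groups are zero)
  rs <- rowsum(t(X), group = groups, reorder = TRUE)
  out <- matrix(0, nrow(X), nbins)
  out[, as.integer(rownames(rs))] <- t(rs)
  out
}

# full-training reconstruction of independent test epochs (reduced form)
pool_reconstruct <- function(Xtrain, cls, B, isig, Xtest) {
  ng <- tabulate(cls, nbins = ncol(B))
  M <- sweep(rowsum_cols(Xtrain, cls, ncol(B)), 2, pmax(ng, 1), `/`)
  G <- crossprod(M, isig %*% M)
  rhs <- crossprod(M, isig %*% Xtest)
  sol <- tryCatch(solve(G, rhs), error = function(e) MASS::ginv(G) %*% rhs)
  B %*% sol
}

#' Sliding-window leave-one-out IEM decoding
#'
#' Runs the inverted encoding model across time. Features are per-electrode
#' mean amplitudes in a `window_ms` window centered on each sample (stepping
#' every `stride` samples). Decoders are trained on attended random-sequence
#' (RDM) epochs, separately per attended side, then results are collapsed
#' across sides. The attended-RDM pool is reconstructed with leave-one-out
#' cross-validation (weights are re-estimated without the held-out unit; the
#' noise covariance is estimated once per window on the full pool); all other
#' cells (attended RTT, unattended RDM/RTT) are reconstructed with the
#' full-pool decoder of the matching stream side, which is disjoint from them
#' by construction. Reconstructed CTFs are circularly realigned to each
#' epoch's true orientation and averaged per cell, and a decoding score
#' (slope against the ideal tuning curve) is computed per window.
#'
#' @param epochs an [epoch_array()] for one subject.
#' @param electrodes electrode indices to use (default: all).
#' @param basis a [basis_set()].
#' @param window_ms sliding window length in ms (default 40).
#' @param stride step between window centers, in samples.
#' @param time_range optional `c(start, end)` in seconds: decode only window
#'   centers inside this range (e.g. around the evoked-response peak).
#' @param n_train number of attended-RDM training epochs per side (the first
#'   `n_train` in metadata order); NULL uses all available. Sides with fewer
#'   epochs are rejected with a count report.
#' @param loo_unit "epoch" (default) leaves out single epochs; "trial"
#'   leaves out all epochs of the held-out epoch's trial that are in the
#'   training pool (guards against leakage between adjacent epochs).
#' @param lambda shrinkage intensity for the noise covariance
#'   ([shrinkage_cov()]).
#' @param keep_epoch_ctfs if TRUE, retain per-epoch realigned CTFs (needed
#'   by the channel-shift cluster permutation test); memory grows as
#'   epochs x windows x channels.
#' @param epoch_ctf_cells cells for which per-epoch CTFs are retained when
#'   `keep_epoch_ctfs` is TRUE (default: all four).
#' @return object of class `ctf_decode`: `times` (window centers, s),
#'   `offsets` (channel-offset axis, degrees), and `cells`, a list keyed by
#'   `"RDM_attended"`, `"RTT_attended"`, `"RDM_unattended"`,
#'   `"RTT_unattended"`, each with `ctf` (windows x channels mean realigned
#'   CTF), `score` (per-window decoding score), `n_epochs`, and optionally
#'   `epoch_ctf` (epochs x windows x channels) with `orientations`.
#' @export
sliding_window_decode <- function(epochs, electrodes = NULL,
                                  basis = basis_set(), window_ms = 40,
                                  stride = 1L, time_range = NULL,
                                  n_train = NULL,
                                  loo_unit = c("epoch", "trial"),
                                  lambda = "auto",
                                  keep_epoch_ctfs = FALSE,
                                  epoch_ctf_cells = c("RDM_attended",
                                                      "RTT_attended",
                                                      "RDM_unattended",
                                                      "RTT_unattended")) {
  loo_unit <- match.arg(loo_unit)
  md <- epochs$metadata
  if (is.null(electrodes)) electrodes <- seq_len(dim(epochs$data)[2])
  stopifnot(length(electrodes) >= 1)
  n_grid <- length(unique(md$orientation))
  if (length(electrodes) < n_grid + 3) {
    warning("decoding with ", length(electrodes), " electrodes and ", n_grid,
            " stimulus orientations is ill-conditioned (near-square ",
            "class-mean system); reconstructions at signal-free windows ",
            "can be unstable. Use more electrodes.")
  }
  win_samples <- max(1L, round(window_ms / 1000 * epochs$sfreq))
  wf <- window_features(epochs, win_samples)
  wsel <- seq(1, length(wf$centers), by = stride)
  if (!is.null(time_range)) {
    wsel <- wsel[wf$times[wsel] >= time_range[1] &
                   wf$times[wsel] <= time_range[2]]
    if (!length(wsel)) stop("time_range excludes every window center")
  }
  feats <- wf$features[, electrodes, wsel, drop = FALSE]
  times <- wf$times[wsel]
  n_win <- length(wsel)

  grid <- sort(unique(md$orientation))
  B <- channel_matrix(grid, basis)                  # 18 x n_grid
  cls_all <- match(md$orientation, grid)
  cells <- c("RDM_attended", "RTT_attended", "RDM_unattended",
             "RTT_unattended")
  cell_of <- paste0(md$sequence_type,
                    ifelse(md$attended, "_attended", "_unattended"))

  # training pools per stream side
  pools <- list()
  for (side in c("left", "right")) {
    idx <- which(md$sequence_type == "RDM" & md$attended & md$side == side)
    if (!is.null(n_train)) {
      if (length(idx) < n_train) {
        stop("attended-RDM pool for side '", side, "' has ", length(idx),
             " epochs; ", n_train, " required")
      }
      idx <- idx[seq_len(n_train)]
    }
    if (length(idx) < basis$n_channels) {
      stop("attended-RDM pool for side '", side, "' has ", length(idx),
           " epochs; at least ", basis$n_channels, " required")
    }
    pools[[side]] <- idx
  }

  cell_idx <- lapply(cells, function(cl) {
    if (cl == "RDM_attended") sort(unlist(pools, use.names = FALSE))
    else which(cell_of == cl)
  })
  names(cell_idx) <- cells
  epoch_store <- if (keep_epoch_ctfs) {
    stats::setNames(lapply(cells, function(cl) {
      if (!cl %in% epoch_ctf_cells) return(NULL)
      array(NA_real_, c(length(cell_idx[[cl]]), n_win, basis$n_channels))
    }), cells)
  } else NULL

  # circular realignment: realigned[o] = raw[(chan0 - 1 + offset_o) mod k + 1]
  offs_units <- as.integer(round(ctf_offsets(basis) / basis$spacing))
  k <- basis$n_channels
  shift_idx <- lapply(seq_len(k), function(i)
    as.integer(((i - 1L + offs_units) %% k) + 1L))
  chan0 <- as.integer(round(md$orientation / basis$spacing) %% k + 1L)

  sum_ctfs <- array(0, c(length(cells), n_win, k))
  dimnames(sum_ctfs)[[1]] <- cells

  store_cell <- function(cl, idx, raw, w) {
    # realign per epoch (group epochs by true-orientation channel), then
    # accumulate the sum and optionally keep per-epoch realigned CTFs
    realigned <- raw
    for (g in unique(chan0[idx])) {
      sel <- which(chan0[idx] == g)
      realigned[, sel] <- raw[shift_idx[[g]], sel, drop = FALSE]
    }
    sum_ctfs[cl, w, ] <<- sum_ctfs[cl, w, ] + rowSums(realigned)
    if (keep_epoch_ctfs && !is.null(epoch_store[[cl]])) {
      rows <- match(idx, cell_idx[[cl]])
      epoch_store[[cl]][rows, w, ] <<- t(realigned)
    }
    invisible(NULL)
  }

  for (side in c("left", "right")) {
    pool <- pools[[side]]
    cls_pool <- cls_all[pool]
    loo_groups <- if (loo_unit == "trial") md$trial_id[pool] else NULL
    test_sets <- list(
      RTT_attended = which(cell_of == "RTT_attended" & md$side == side),
      RDM_unattended = which(cell_of == "RDM_unattended" & md$side == side),
      RTT_unattended = which(cell_of == "RTT_unattended" & md$side == side))

    for (w in seq_len(n_win)) {
      X <- t(matrix(feats[, , w], nrow = dim(feats)[1])) # e x n_ep
      Xp <- X[, pool, drop = FALSE]
      # full-pool class means + residuals -> noise covariance (fixed across
      # leave-one-out folds; weights are strictly fold-wise)
      ng <- pmax(tabulate(cls_pool, nbins = ncol(B)), 1)
      Mg <- sweep(rowsum_cols(Xp, cls_pool, ncol(B)), 2, ng, `/`)
      R <- Xp - Mg[, cls_pool]
      sc <- shrinkage_cov(R, lambda)
      isig <- solve(sc$sigma)
      S_raw <- tcrossprod(R - rowMeans(R)) / (ncol(R) - 1)

      raw_loo <- loo_reconstruct(Xp, cls_pool, B, S_raw, sc$lambda,
                                 loo_groups)
      store_cell("RDM_attended", pool, raw_loo, w)

      for (cl in names(test_sets)) {
        idx <- test_sets[[cl]]
        if (!length(idx)) next
        raw <- pool_reconstruct(Xp, cls_pool, B, isig, X[, idx, drop = FALSE])
        store_cell(cl, idx, raw, w)
      }
    }
  }

  res_cells <- list()
  for (cl in cells) {
    idx <- cell_idx[[cl]]
    n <- length(idx)
    mean_ctf <- matrix(sum_ctfs[cl, , ], nrow = n_win) / max(n, 1)
    res_cells[[cl]] <- list(
      ctf = mean_ctf,
      score = decoding_score(t(mean_ctf), basis),
      n_epochs = n,
      epoch_ctf = if (keep_epoch_ctfs) epoch_store[[cl]] else NULL,
      orientations = md$orientation[idx])
  }

  structure(list(times = times, offsets = ctf_offsets(basis),
                 cells = res_cells, basis = basis,
                 electrodes = electrodes, window_ms = window_ms,
                 stride = stride, loo_unit = loo_unit),
            class = "ctf_decode")
}
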