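test_that("weight estimation solves least squares (normal-equations oracle)", {
  set.seed(10)
  # well-conditioned generic channel matrix: the estimator itself is tested,
  # independent of the cosine basis' conditioning
  e <- 8; n <- 200; k <- 18
  C <- matrix(runif(k * n), k)
  Wt <- matrix(rnorm(e * k), e)
  X <- Wt %*% C + matrix(rnorm(e * n), e)
  W <- estimate_weights(X, C)
  W_oracle <- X %*% t(C) %*% solve(C %*% t(C))      # brute-force normal eqs
  expect_lt(max(abs(W - W_oracle)), 1e-8)
  # noiseless fit reproduces training data even with rank-deficient C
  th <- rep(orientation_grid(), 4)
  Cg <- channel_matrix(th)
  Xg <- Wt %*% Cg
  expect_warning(Wg <- estimate_weights(Xg, Cg), "rank")
  expect_lt(max(abs(Wg %*% Cg - Xg)), 1e-8)
  expect_error(estimate_weights(Xg, Cg * 0), "rank 0")
  expect_error(estimate_weights(X[, 1:10], C[, 1:10]), "training epochs")
})

test_that("inversion filter satisfies V'W = I and the white-noise limit", {
  set.seed(11)
  e <- 24; k <- 18
  W <- matrix(rnorm(e * k), e)
  # white noise: V is the transposed pseudoinverse of W
  f_white <- compute_filter(W, noise_cov = diag(e))
  expect_lt(max(abs(f_white$V - t(MASS::ginv(W)))), 1e-6)
  expect_lt(max(abs(crossprod(f_white$V, W) - diag(k))), 1e-8)
  # estimated correlated covariance: construction identity still holds
  R <- matrix(rnorm(e * 500), e)
  R <- R + 0.5 * R[rep(1, e), ]                     # correlated rows
  f <- compute_filter(W, residuals = R)
  expect_lt(max(abs(crossprod(f$V, W) - diag(k))), 1e-8)
  expect_true(f$lambda >= 0 && f$lambda <= 1)
  # degenerate residuals fall back to the identity covariance
  f0 <- compute_filter(W, residuals = matrix(0, e, 20))
  expect_equal(f0$noise_cov, diag(e))
})

test_that("reconstruction inverts the forward model", {
  set.seed(12)
  e <- 24
  W <- matrix(rnorm(e * 18), e)
  f <- compute_filter(W, noise_cov = diag(e))
  cc <- basis_responses(60)
  rec <- reconstruct_ctf(f, W %*% cc)
  expect_equal(as.vector(rec), cc, tolerance = 1e-8)
  expect_equal(basis_set()$centers[which.max(rec)], 60)
  expect_equal(as.vector(reconstruct_ctf(f, rep(0, e))), rep(0, 18))
  expect_error(reconstruct_ctf(f, rep(0, e + 1)), "mismatch")
})

test_that("optimal filter beats the plain pseudoinverse under correlated noise", {
  set.seed(13)
  e <- 16; n_test <- 60
  b <- basis_set()
  # strongly correlated noise: a few dominant spatial components
  L <- matrix(rnorm(e * 3), e) %*% matrix(rnorm(3 * e), 3) + diag(e) * 0.2
  gain_v <- numeric(200); gain_p <- numeric(200)
  W <- matrix(rnorm(e * 18), e)
  for (r in 1:200) {
    th <- sample(orientation_grid(), n_test, replace = TRUE)
    C <- channel_matrix(th, b)
    noise_tr <- L %*% matrix(rnorm(e * 300), e)
    noise_te <- L %*% matrix(rnorm(e * n_test), e)
    f_opt <- compute_filter(W, residuals = noise_tr)
    f_pinv <- compute_filter(W, noise_cov = diag(e))
    score_of <- function(f) {
      rec <- reconstruct_ctf(f, W %*% C + noise_te)
      mean(decoding_score(realign_ctf(rec, th, b), b))
    }
    gain_v[r] <- score_of(f_opt)
    gain_p[r] <- score_of(f_pinv)
  }
  expect_gt(mean(gain_v), mean(gain_p))
})

test_that("sliding-window decode: noiseless forward model inverts exactly", {
  cfg <- noiseless_config()
  sub <- simulate_subject(cfg, 1, keep_trials = FALSE)
  dec <- sliding_window_decode(sub$epochs, stride = 10, keep_epoch_ctfs = TRUE)
  # every window overlapping the kernel support peaks at offset 0
  kern_win <- which(dec$times > 0.08 & dec$times < 0.2)
  off0 <- which(dec$offsets == 0)
  for (cl in names(dec$cells)) {
    ec <- dec$cells[[cl]]$epoch_ctf
    for (w in kern_win) {
      expect_true(all(apply(ec[, w, ], 1, which.max) == off0),
                  info = paste(cl, "window", w))
    }
  }
  # training-condition score reaches 1 at the kernel peak
  wpk <- which.min(abs(dec$times - 0.12))
  expect_gt(dec$cells$RDM_attended$score[wpk], 0.99)
  # unattended cells are scaled by the attention gain, shapes preserved
  expect_equal(dec$cells$RDM_unattended$score[wpk],
               dec$cells$RDM_attended$score[wpk] / cfg$gain_attended,
               tolerance = 1e-3)
})

test_that("reduced LOO path agrees with the generic weight/filter path", {
  set.seed(14)
  e <- 10; n <- 90
  b <- basis_set()
  th <- c(rep(orientation_grid(), 9), sample(orientation_grid(), 9, TRUE))
  X <- matrix(rnorm(e * n), e)
  grid <- orientation_grid()
  cls <- match(th, grid)
  B <- channel_matrix(grid, b)
  # generic path for held-out epoch j: weights + filter from the other epochs
  for (j in c(1, 37, 90)) {
    tr <- setdiff(seq_len(n), j)
    suppressWarnings(W <- estimate_weights(X[, tr], channel_matrix(th[tr], b)))
    resid <- X[, tr] - W %*% channel_matrix(th[tr], b)
    sc <- shrinkage_cov(resid)
    f <- compute_filter(W, noise_cov = sc$sigma)
    generic <- reconstruct_ctf(f, X[, j])
    # reduced path with the same covariance
    red <- momdecode:::pool_reconstruct(X[, tr], cls[tr], B,
                                        solve(sc$sigma), X[, j, drop = FALSE])
    expect_equal(as.vector(red), as.vector(generic), tolerance = 1e-6)
  }
})

test_that("decode rejects undersized training pools with a count report", {
  cfg <- tiny_config()
  sub <- simulate_subject(cfg, 1, keep_trials = FALSE)
  expect_error(sliding_window_decode(sub$epochs, n_train = 10000), "epochs")
})
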