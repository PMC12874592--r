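test_that("basis responses follow the rectified cosine^18 profile", {
  b <- basis_set()
  expect_equal(b$centers, seq(0, 170, by = 10))
  r <- basis_responses(30, b)
  expect_equal(r[b$centers == 30], 1)                    # own center
  expect_equal(r[b$centers == 120], 0)                   # 90 deg away
  expect_equal(r[b$centers == 40], cos(10 * pi / 180)^18)  # direct formula
  expect_true(all(r >= 0 & r <= 1))
  # circular smoothness: response depends only on wrapped distance
  r2 <- basis_responses(wrap_orientation(30 + 180), b)
  expect_equal(r, r2)
})

test_that("channel matrix columns are per-epoch basis responses", {
  th <- c(0, 20, 140)
  C <- channel_matrix(th)
  expect_equal(dim(C), c(18L, 3L))
  for (j in 1:3) expect_equal(C[, j], basis_responses(th[j]))
})

test_that("realignment is an exact circular shift with exact inverse", {
  b <- basis_set()
  # one-hot at channel 40, true orientation 40 -> one-hot at offset 0
  oh <- as.numeric(b$centers == 40)
  ra <- realign_ctf(oh, 40, b)
  expect_equal(which(ra == 1), which(ctf_offsets(b) == 0))
  # one-hot at channel 60, true orientation 40 -> one-hot at offset +20
  oh60 <- as.numeric(b$centers == 60)
  ra2 <- realign_ctf(oh60, 40, b)
  expect_equal(ctf_offsets(b)[which(ra2 == 1)], 20)
  # shift-group property: realign then inverse-realign is the identity
  set.seed(3)
  for (th in orientation_grid()) {
    v <- rnorm(18)
    expect_equal(unalign_ctf(realign_ctf(v, th, b), th, b), v)
  }
  expect_error(realign_ctf(rnorm(18), 15, b), "channel center")
})

test_that("decoding score is the slope against the ideal tuning curve", {
  b <- basis_set()
  ideal <- ideal_ctf(b)
  expect_equal(decoding_score(ideal, b), 1)
  expect_equal(decoding_score(rep(0.4, 18), b), 0)
  expect_equal(decoding_score(2 * ideal + 3, b), 2)
  # invariance to constants, linearity in gain, matrix input
  v <- rnorm(18)
  expect_equal(decoding_score(v + 5, b), decoding_score(v, b))
  expect_equal(decoding_score(3 * v, b), 3 * decoding_score(v, b))
  expect_equal(decoding_score(cbind(ideal, 2 * ideal + 3), b), c(1, 2))
})

test_that("Gaussian bias fit recovers exact parameters and flags degeneracy", {
  b <- basis_set()
  x <- ctf_offsets(b)
  y <- 1 * exp(-(x - 5)^2 / (2 * 15^2)) + 0.1
  f <- fit_gaussian_bias(y, b)
  expect_true(f$converged)
  expect_equal(f$center, 5, tolerance = 1e-6)
  expect_equal(f$width, 15, tolerance = 1e-6)
  expect_equal(f$amplitude, 1, tolerance = 1e-6)
  expect_equal(f$baseline, 0.1, tolerance = 1e-6)
  # the ideal basis profile fits with center at ~0
  f0 <- fit_gaussian_bias(ideal_ctf(b), b)
  expect_true(abs(f0$center) < 0.5)
  # flat input is flagged, not fitted
  expect_warning(ff <- fit_gaussian_bias(rep(1, 18), b), "degenerate")
  expect_false(ff$converged)
})
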