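make_trials <- function(f) {
  tt <- (0:1249) / 250
  tr <- array(0, c(2, 2, 1250))
  for (i in 1:2) for (e in 1:2) tr[i, e, ] <- f(tt, i, e)
  tr
}

test_that("power spectrum resolves the tagging frequency exactly", {
  tr <- make_trials(function(tt, i, e)
    if (e == 1) sin(2 * pi * 5 * tt) else
      sin(2 * pi * 5 * tt) + 2 * sin(2 * pi * 10 * tt))
  psd <- trial_power_spectrum(tr, 250)
  expect_equal(diff(psd$frequencies[1:2]), 0.2)     # 5 s window
  b5 <- which(psd$frequencies == 5); b10 <- which(psd$frequencies == 10)
  expect_equal(psd$power[1, b5], 0.5)               # amplitude^2 / 2
  expect_lt(max(psd$power[1, -b5]), 1e-10 * psd$power[1, b5])
  # two components: power ratio equals squared amplitude ratio
  expect_equal(psd$power[2, b10] / psd$power[2, b5], 4, tolerance = 1e-9)
  expect_true(all(psd$power >= 0))
  expect_error(trial_power_spectrum(tr[, , 1:1000], 250), "5 s")
})

test_that("white-noise spectrum satisfies Parseval", {
  set.seed(30)
  wn <- array(rnorm(3 * 2 * 1250), c(3, 2, 1250))
  psd <- trial_power_spectrum(wn, 250)
  # summed non-DC power per electrode ~ mean time-domain variance
  tv <- apply(wn, 2, function(m) mean(apply(m, 1, function(x)
    mean((x - mean(x))^2))))
  tot <- rowSums(psd$power[, -1])
  expect_equal(tot, tv, tolerance = 0.01)
  # trial-order permutation leaves the average unchanged
  psd2 <- trial_power_spectrum(wn[c(3, 1, 2), , , drop = FALSE], 250)
  expect_equal(psd2$power, psd$power)
})

test_that("time-frequency power tracks the 5 Hz envelope", {
  tr <- make_trials(function(tt, i, e) sin(2 * pi * 5 * tt))
  tf <- tf_power_5hz(tr, 250)
  expect_true(all(tf$power >= 0))
  expect_true(all(abs(tf$power - 1) < 0.01))        # stationary amp 1 -> 1
  # amplitude step x2 -> power x4 with transition within the window length
  tr2 <- make_trials(function(tt, i, e)
    ifelse(tt < 2.5, 1, 2) * sin(2 * pi * 5 * tt))
  tf2 <- tf_power_5hz(tr2, 250)
  early <- tf2$times < 2.5 - 0.55
  late <- tf2$times > 2.5 + 0.55
  expect_true(all(abs(tf2$power[1, 1, early] - 1) < 0.05))
  expect_true(all(abs(tf2$power[1, 1, late] - 4) < 0.2))
  # slowly modulated envelope is recovered away from edges
  env <- function(tt) 1 + 0.5 * sin(2 * pi * 0.3 * tt)
  tr3 <- make_trials(function(tt, i, e) env(tt) * sin(2 * pi * 5 * tt))
  tf3 <- tf_power_5hz(tr3, 250, step = 0.004)
  mid <- tf3$times > 1 & tf3$times < 4.5
  expect_gt(cor(sqrt(tf3$power[1, 1, mid]), env(tf3$times[mid])), 0.95)
  expect_error(tf_power_5hz(tr[, , 1:100], 250), "window exceeds")
})

test_that("electrode selection takes the union of the two quartile sets", {
  freqs <- seq(0, 40, by = 0.2)
  b5 <- which(freqs == 5); b10 <- which(freqs == 10)
  mkpsd <- function(p5, p10) {
    pw <- matrix(runif(128 * length(freqs)) * 1e-3, 128)
    pw[, b5] <- p5; pw[, b10] <- p10
    structure(list(frequencies = freqs, power = pw, n_trials = 1, window = 5),
              class = "power_spectrum")
  }
  set.seed(31)
  base <- rnorm(128)^2
  # identical power at both frequencies: one quartile set, size 32
  expect_length(select_ssvep_electrodes(mkpsd(base, base)), 32)
  # disjoint top quartiles: union of size 64
  p10 <- base; p10[order(base)] <- sort(base, decreasing = TRUE)
  expect_length(select_ssvep_electrodes(mkpsd(base, p10)), 64)
  # generic case stays within [32, 64] and is scale-invariant
  p10b <- rnorm(128)^2
  sel <- select_ssvep_electrodes(mkpsd(base, p10b))
  expect_gte(length(sel), 32); expect_lte(length(sel), 64)
  expect_identical(select_ssvep_electrodes(mkpsd(base * 10, p10b * 10)), sel)
})

test_that("GFP is the sample SD across electrodes, averaged by condition", {
  # two electrodes at +1/-1 -> sqrt(2); identical electrodes -> 0
  arr <- array(0, c(1, 2, 2))
  arr[1, , 1] <- c(1, -1); arr[1, , 2] <- c(3, 3)
  g <- gfp(arr)
  expect_equal(g$series[1, ], c(sqrt(2), 0))
  # homogeneity: scaling all electrodes scales GFP
  cfg <- tiny_config()
  sub <- simulate_subject(cfg, 1, keep_trials = FALSE)
  g1 <- gfp(sub$epochs)
  sub$epochs$data <- sub$epochs$data * 2.5
  g2 <- gfp(sub$epochs)
  expect_equal(g2$series, 2.5 * g1$series)
  expect_equal(sort(rownames(g1$series)),
               sort(c("RDM_FALSE", "RDM_TRUE", "RTT_FALSE", "RTT_TRUE")))
})
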