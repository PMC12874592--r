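test_that("simulation is a pure function of config and seed", {
  cfg <- tiny_config()
  a <- simulate_subject(cfg, 1)
  b <- simulate_subject(cfg, 1)
  expect_identical(a$epochs$data, b$epochs$data)
  expect_identical(a$trials$data, b$trials$data)
  expect_identical(a$ground_truth$W_true, b$ground_truth$W_true)
  # skipping trials leaves epochs bit-identical (and vice versa)
  c1 <- simulate_subject(cfg, 1, keep_trials = FALSE)
  expect_identical(a$epochs$data, c1$epochs$data)
  c2 <- simulate_subject(cfg, 1, keep_epochs = FALSE)
  expect_identical(a$trials$data, c2$trials$data)
  # different seeds and different subjects differ
  cfg2 <- tiny_config(seed = 43)
  expect_false(identical(simulate_subject(cfg2, 1)$epochs$data,
                         a$epochs$data))
  expect_false(identical(simulate_subject(cfg, 2)$epochs$data,
                         a$epochs$data))
})

test_that("epoch geometry and metadata match the experimental design", {
  cfg <- tiny_config()
  sub <- simulate_subject(cfg, 1, keep_trials = FALSE)
  d <- dim(sub$epochs$data)
  expect_equal(d[1], nrow(sub$epochs$metadata))
  expect_equal(d[1], cfg$n_trials_per_cell * 4 * 2 * cfg$n_items)
  expect_equal(d[3], 175L)                     # -0.2 .. 0.5 s at 250 Hz
  expect_equal(sub$epochs$times[1], -0.2)
  expect_equal(diff(sub$epochs$times[1:2]), 1 / 250)
  md <- sub$epochs$metadata
  expect_true(all(md$orientation %in% orientation_grid()))
  expect_true(all(md$position_in_trial %in% 1:25))
  # attended flag: exactly one stream attended per trial
  att_by_trial <- tapply(md$attended, list(md$trial_id, md$side), unique)
  expect_true(all(rowSums(matrix(unlist(att_by_trial), ncol = 2)) == 1))
})

test_that("noiseless forward model encodes the biased orientation", {
  cfg <- noiseless_config(bias_rtt = 10)
  sub <- simulate_subject(cfg, 1, keep_trials = FALSE)
  gt <- sub$ground_truth
  md <- sub$epochs$metadata
  expect_equal(gt$theta_enc[md$sequence_type == "RDM"],
               md$orientation[md$sequence_type == "RDM"])
  expect_equal(gt$theta_enc[md$sequence_type == "RTT"],
               wrap_orientation(md$orientation[md$sequence_type == "RTT"] + 10))
  # reconstructing with the true mixing matrix recovers the basis response
  # exactly at the kernel peak (no noise, no SSVEP)
  pk <- which.max(gt$kernel)
  W <- gt$W_true
  for (j in c(1, 50, 200)) {
    x <- sub$epochs$data[j, , pk]
    chat <- MASS::ginv(W) %*% (x - gt$untuned_pattern * gt$gain_untuned[j])
    expect_equal(as.vector(chat) / gt$gain_tuned[j],
                 basis_responses(gt$theta_enc[j]), tolerance = 1e-8)
  }
})

test_that("reduced RTT gain lowers GFP with matched noise", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 6, n_electrodes = 16,
                    seed = 99)
  sub <- simulate_subject(cfg, 1, keep_trials = FALSE)
  att <- subset_epochs(sub$epochs, sub$epochs$metadata$attended)
  g <- gfp(att, by = "sequence_type")
  # >= 500 epochs per condition; compare means over the evoked window
  expect_gte(min(table(att$metadata$sequence_type)), 300)
  win <- g$times > 0.05 & g$times < 0.3
  expect_lt(mean(g$series["RTT", win]), mean(g$series["RDM", win]))
})

test_that("response kernel is unimodal with the configured peak and support", {
  t <- seq(-0.2, 0.5, by = 1 / 250)
  k <- response_kernel(t)
  expect_equal(max(k), 1)
  expect_equal(t[which.max(k)], 0.12, tolerance = 0.005)
  expect_true(all(k[t <= 0.05] == 0))
  expect_lt(max(k[t > 0.35]), 0.05)
  expect_equal(sum(diff(sign(diff(k[k > 0]))) != 0), 1)  # single peak
})

test_that("behavioral generator follows the stated psychometric", {
  cfg <- sim_config(n_subjects = 2, seed = 5, n_probe_per_cell = 2000)
  tab <- simulate_behavior(cfg)
  p <- proportion_same(tab)
  # RDM peaks at offset 0
  rdm <- p[p$sequence_type == "RDM" & p$subject_id == 1, ]
  expect_equal(rdm$probe_offset[which.max(rdm$p_same)], 0)
  # RTT: closed-form gap between +4 and -4 within 3 binomial SE
  rtt <- p[p$sequence_type == "RTT" & p$subject_id == 1, ]
  p_plus <- cfg$lapse + (1 - 2 * cfg$lapse) *
    exp(-(4 - cfg$bias_behavior)^2 / (2 * cfg$sigma_behavior^2))
  p_minus <- cfg$lapse + (1 - 2 * cfg$lapse) *
    exp(-(-4 - cfg$bias_behavior)^2 / (2 * cfg$sigma_behavior^2))
  gap <- rtt$p_same[rtt$probe_offset == 4] - rtt$p_same[rtt$probe_offset == -4]
  se <- sqrt(p_plus * (1 - p_plus) / 2000 + p_minus * (1 - p_minus) / 2000)
  expect_lt(abs(gap - (p_plus - p_minus)), 3 * se)
  # degenerate lapse floor 0.5: all cells ~0.5
  cfg2 <- sim_config(n_subjects = 1, seed = 6, lapse = 0.5,
                     n_probe_per_cell = 2000)
  p2 <- proportion_same(simulate_behavior(cfg2))
  expect_true(all(abs(p2$p_same - 0.5) < 3 * sqrt(0.25 / 2000)))
  # determinism
  expect_identical(simulate_behavior(cfg), tab)
})

test_that("electrode layout partitions electrodes and adjacency is symmetric", {
  for (n in c(16, 32, 128)) {
    lay <- electrode_layout(n)
    covered <- sort(c(lay$midline, as.vector(lay$mirror_pairs)))
    expect_equal(covered, seq_len(n))
    expect_true(isSymmetric(lay$adjacency * 1))
    expect_true(all(diag(lay$adjacency) == FALSE))
    # mirror pairs reflect x
    expect_equal(lay$positions[lay$mirror_pairs[, 1], 1],
                 -lay$positions[lay$mirror_pairs[, 2], 1])
    expect_gt(length(lay$posterior), 1)
  }
})

test_that("lateralization flipping swaps mirror pairs and is an involution", {
  lay <- electrode_layout(16)
  v <- rnorm(16)
  # symmetric map invariant
  vs <- v
  vs[lay$mirror_pairs[, 2]] <- vs[lay$mirror_pairs[, 1]]
  expect_equal(flip_lateralization(vs, lay, "left"), vs)
  # flip twice = identity; right-attended maps are untouched by default
  expect_equal(flip_lateralization(flip_lateralization(v, lay, "left"),
                                   lay, "left"), v)
  expect_equal(flip_lateralization(v, lay, "right"), v)
  # unit value moves to its mirror
  u <- numeric(16); u[lay$mirror_pairs[3, 1]] <- 1
  fu <- flip_lateralization(u, lay, "left")
  expect_equal(which(fu == 1), unname(lay$mirror_pairs[3, 2]))
})

test_that("epoch containers round-trip through serialization", {
  cfg <- tiny_config()
  sub <- simulate_subject(cfg, 1, keep_trials = FALSE)
  path <- tempfile(fileext = ".rds")
  save_epochs(sub$epochs, path)
  back <- load_epochs(path)
  expect_identical(back$data, sub$epochs$data)
  expect_identical(back$metadata, sub$epochs$metadata)
  unlink(path)
  # config round-trips losslessly through JSON
  cfgfile <- tempfile(fileext = ".json")
  write_sim_config(cfg, cfgfile)
  expect_equal(read_sim_config(cfgfile), cfg)
  unlink(cfgfile)
})
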