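test_that("proportion aggregation counts correctly and is order-invariant", {
  tab <- data.frame(
    subject_id = 1,
    sequence_type = rep(c("RTT", "RDM"), each = 30),
    probe_offset = rep(c(-4, 0, 4), times = 20),
    response = "different", stringsAsFactors = FALSE)
  tab$response[tab$sequence_type == "RTT" & tab$probe_offset == 4][1:7] <- "same"
  p <- proportion_same(tab)
  expect_equal(p$p_same[p$sequence_type == "RTT" & p$probe_offset == 4], 0.7)
  expect_true(all(p$p_same[p$sequence_type == "RDM"] == 0))
  expect_true(all(p$n_trials == 10))
  p2 <- proportion_same(tab[sample(nrow(tab)), ])
  expect_equal(p2, p)
  expect_error(proportion_same(transform(tab, probe_offset = 5)), "offset")
})

test_that("behavioral analysis produces ANOVA plus the five planned contrasts", {
  cfg <- sim_config(n_subjects = 19, seed = 33, n_probe_per_cell = 60)
  res <- rm_behavior_analysis(proportion_same(simulate_behavior(cfg)))
  expect_equal(nrow(res$posthoc), 5)
  expect_equal(res$anova$table$effect,
               c("sequence_type", "probe_offset",
                 "sequence_type:probe_offset"))
  # forward-shifted psychometric: interaction and the +4 contrast both land
  expect_lt(res$anova$table$p[3], 0.05)
  plus4 <- res$posthoc[res$posthoc$contrast == "RTT vs RDM at +4", ]
  expect_gt(plus4$t, 0)
  expect_lt(plus4$p, 0.05)
  expect_equal(plus4$d_z, plus4$t / sqrt(19))
  # qualitative pattern: RTT p_same at +4 above RDM at +4; RDM peaks at 0
  cm <- res$cell_means
  expect_gt(cm["RTT", "4"], cm["RDM", "4"])
  expect_equal(names(which.max(cm["RDM", ])), "0")
  # constant table -> all F ~ 0
  const <- expand.grid(subject_id = 1:4, sequence_type = c("RTT", "RDM"),
                       probe_offset = c(-4, 0, 4))
  const$n_trials <- 10; const$p_same <- 0.5
  # constant data: contrasts degenerate (warned), all F collapse to 0
  suppressWarnings(res0 <- rm_behavior_analysis(const))
  expect_true(all(res0$anova$table$F < 1e-10))
  expect_true(all(is.na(res0$posthoc$t)))
})

test_that("null behavior yields nominal interaction rate", {
  # mu_RTT = mu_RDM = 0: interaction significant in about 5% of replicates
  hits <- vapply(1:60, function(i) {
    cfg <- sim_config(n_subjects = 8, seed = 400 + i, bias_behavior = 0,
                      n_probe_per_cell = 20)
    res <- rm_behavior_analysis(proportion_same(simulate_behavior(cfg)))
    res$anova$table$p[3] < 0.05
  }, logical(1))
  expect_lt(mean(hits), 0.18)   # 3 SE above 0.05 at 60 replicates
})
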