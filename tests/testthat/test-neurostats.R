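test_that("jackknife SE of linear statistics equals the classical SE", {
  x <- c(1, 2, 3, 4, 5)
  jk <- jackknife_test(x, mean)
  expect_equal(jk$se, sd(x) / sqrt(5), tolerance = 1e-12)
  expect_equal(jk$t, mean(x) / jk$se)
  expect_equal(jk$p, 2 * pt(-abs(jk$t), 4))
  # weighted mean (linear): identity still exact
  set.seed(20)
  y <- rnorm(12); w <- runif(12); w <- w / sum(w)
  jkw <- jackknife_test(seq_along(y), function(idx) {
    ww <- w[idx] / sum(w[idx]); sum(ww * y[idx])
  })
  # classical linearization SE for the weighted mean via the jackknife
  # definition itself is the oracle here; check non-degeneracy instead
  expect_gt(jkw$se, 0)
  # constant data: zero SE flagged
  expect_warning(jk0 <- jackknife_test(rep(2, 6), mean), "zero")
  expect_true(jk0$degenerate)
  expect_error(jackknife_test(1, mean), "2 subjects")
})

test_that("paired t and Cohen's d_z match the closed forms", {
  # d_z = t / sqrt(N): the printed pairing t = 3.00, N = 19 gives 0.688
  expect_equal(round(3.00 / sqrt(19), 3), 0.688)
  set.seed(21)
  x <- rnorm(5); y <- rnorm(5)
  r <- paired_t_dz(x, y)
  d <- x - y
  t_oracle <- mean(d) / (sd(d) / sqrt(5))           # direct formula
  expect_equal(r$t, t_oracle, tolerance = 1e-12)
  expect_equal(r$t, unname(t.test(x, y, paired = TRUE)$statistic))
  expect_equal(r$d_z, r$t / sqrt(5))
  expect_warning(r0 <- paired_t_dz(x, x), "zero-variance")
  expect_true(r0$degenerate)
})

test_that("two-way RM-ANOVA matches sums-of-squares and aov oracles", {
  # 3-subject 2x2 toy table (non-degenerate error terms)
  y <- array(c(1, 2, 3,  2, 4, 5,  2, 3, 6,  4, 7, 8), c(3, 2, 2))
  mine <- rm_anova_2way(y)
  df <- expand.grid(subject = factor(1:3), A = factor(1:2), B = factor(1:2))
  df$value <- as.vector(y)
  a <- summary(aov(value ~ A * B + Error(subject / (A * B)), data = df))
  f_aov <- c(a[["Error: subject:A"]][[1]]$F[1],
             a[["Error: subject:B"]][[1]]$F[1],
             a[["Error: subject:A:B"]][[1]]$F[1])
  expect_equal(mine$table$F, f_aov, tolerance = 1e-10)
  expect_equal(mine$table$df1, c(1, 1, 1))
  expect_equal(mine$table$df2, c(2, 2, 2))
  # subject-label permutation leaves F unchanged
  mine2 <- rm_anova_2way(y[c(3, 1, 2), , ])
  expect_equal(mine2$table$F, mine$table$F)
  # additive construction: B a pure copy of A's effect -> interaction ~ 0
  set.seed(22)
  s <- rnorm(6); eff <- c(0, 1)
  yy <- array(0, c(6, 2, 2))
  for (i in 1:6) for (a2 in 1:2) for (b2 in 1:2)
    yy[i, a2, b2] <- s[i] + eff[a2] + eff[b2]
  m3 <- rm_anova_2way(yy)
  expect_lt(m3$table$F[3], 1e-10)
  expect_error(rm_anova_2way(array(c(y[, , 1], NA)[1:12], c(3, 2, 2))),
               "missing")
})

test_that("permutation p-values are deterministic, floored and monotone", {
  set.seed(23)
  ep <- lapply(1:4, function(s) array(rnorm(15 * 6 * 18), c(15, 6, 18)))
  a <- suppressWarnings(ctf_cluster_permutation(ep, n_perm = 80, seed = 5))
  b <- suppressWarnings(ctf_cluster_permutation(ep, n_perm = 80, seed = 5))
  expect_identical(lapply(a$clusters, `[[`, "p"),
                   lapply(b$clusters, `[[`, "p"))
  expect_warning(ctf_cluster_permutation(ep, n_perm = 50, seed = 1),
                 "unstable")
  # p floor 1/(n_perm+1): a huge injected signal beats every surrogate
  ep_sig <- lapply(ep, function(x) {
    x[, 3:4, 9:11] <- x[, 3:4, 9:11] + 50; x
  })
  ct <- ctf_cluster_permutation(ep_sig, n_perm = 200, seed = 2)
  ps <- vapply(ct$clusters, `[[`, numeric(1), "p")
  expect_equal(min(ps), 1 / 201)
  expect_true(all(ps >= 1 / 201))
  # monotone in mass
  ms <- vapply(ct$clusters, `[[`, numeric(1), "mass")
  expect_true(all(diff(ps[order(ms)]) <= 0))
})

test_that("CTF cluster test finds the injected time-channel cluster", {
  set.seed(24)
  ep <- lapply(1:6, function(s) {
    x <- array(rnorm(30 * 10 * 18), c(30, 10, 18))
    x[, 4:7, 9:11] <- x[, 4:7, 9:11] + 1.2      # around offset 0 (index 10)
    x
  })
  ct <- ctf_cluster_permutation(ep, n_perm = 300, seed = 6)
  sig <- Filter(function(cl) cl$p < 0.05, ct$clusters)
  expect_gte(length(sig), 1)
  mem <- do.call(rbind, lapply(sig, `[[`, "members"))
  expect_true(any(mem[, "time"] %in% 4:7 & mem[, "channel"] %in% 9:11))
  # contiguity under the grid adjacency
  for (cl in ct$clusters) {
    m <- cl$members
    if (nrow(m) == 1) next
    d_t <- abs(outer(m[, 1], m[, 1], `-`))
    d_c <- pmin(abs(outer(m[, 2], m[, 2], `-`)),
                18 - abs(outer(m[, 2], m[, 2], `-`)))
    adj <- (d_t + d_c) == 1
    # connected: every member reachable (check via graph power)
    reach <- adj | diag(nrow(m))
    for (i in seq_len(nrow(m))) reach <- (reach %*% reach) > 0
    expect_true(all(reach))
  }
})

test_that("timewise ANOVA cluster test matches pointwise RM-ANOVA", {
  set.seed(25)
  sc <- array(rnorm(7 * 4 * 12), c(7, 4, 12))
  at <- timewise_anova_cluster(sc, n_perm = 200, seed = 7)
  # oracle: rm_anova_2way at a single time point
  for (tp in c(1, 6, 12)) {
    y <- array(sc[, , tp], c(7, 2, 2))
    # cells (A1B1, A1B2, A2B1, A2B2) -> [subject, A, B]
    y <- array(c(sc[, 1, tp], sc[, 3, tp], sc[, 2, tp], sc[, 4, tp]),
               c(7, 2, 2))
    oracle <- rm_anova_2way(y)
    expect_equal(unname(at$F[, tp]), oracle$table$F, tolerance = 1e-10)
  }
  # identical cells -> no suprathreshold points
  sc0 <- sc; sc0[, 2, ] <- sc0[, 1, ]; sc0[, 3, ] <- sc0[, 1, ]
  sc0[, 4, ] <- sc0[, 1, ]
  at0 <- timewise_anova_cluster(sc0, n_perm = 100, seed = 8)
  expect_equal(sum(lengths(at0$clusters)), 0)
  # injected attention effect -> significant main-effect cluster
  sc1 <- sc
  sc1[, 1:2, 4:9] <- sc1[, 1:2, 4:9] + 1.5
  at1 <- timewise_anova_cluster(sc1, n_perm = 300, seed = 9)
  ps <- vapply(at1$clusters$A, `[[`, numeric(1), "p")
  expect_true(any(ps < 0.05))
})

test_that("map cluster test is sign-symmetric and finds seeded effects", {
  set.seed(26)
  lay <- electrode_layout(16)
  d <- array(rnorm(8 * 16 * 10), c(8, 16, 10))
  mt <- map_cluster_permutation(d, NULL, lay$adjacency, n_perm = 200, seed = 3)
  mt_neg <- map_cluster_permutation(-d, NULL, lay$adjacency, n_perm = 200,
                                    seed = 3)
  expect_equal(sort(vapply(mt$clusters, `[[`, numeric(1), "p")),
               sort(vapply(mt_neg$clusters, `[[`, numeric(1), "p")))
  # seeded electrodes produce a significant cluster containing them
  seeded <- lay$posterior[1:3]
  d2 <- d; d2[, seeded, 3:8] <- d2[, seeded, 3:8] + 2
  mt2 <- map_cluster_permutation(d2, NULL, lay$adjacency, n_perm = 300,
                                 seed = 4)
  sig <- Filter(function(cl) cl$p < 0.05, mt2$clusters)
  expect_gte(length(sig), 1)
  mem <- do.call(rbind, lapply(sig, `[[`, "members"))
  expect_true(all(seeded %in% mem[, "electrode"]))
  expect_error(map_cluster_permutation(d, NULL, diag(3) > 0, n_perm = 10),
               "adjacency")
})
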