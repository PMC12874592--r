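#' Jackknife standard error and t statistic for a group-level estimate
#'
#' Leave-one-subject-out jackknife for statistics (such as the center of a
#' Gaussian fit to a group-mean CTF) that are computed from the whole sample
#' rather than per subject. The statistic is evaluated on the full sample
#' (`D`) and on the `N` subsamples leaving one subject out (`D_-i`); the
#' standard error is
#' `SE_D = sqrt((N-1)/N * sum_i (D_-i - Jbar)^2)` with `Jbar = mean(D_-i)`,
#' the t statistic is `t_j = D / SE_D`, and the p value uses `N - 1` degrees
#' of freedom (two-tailed). For a linear statistic (e.g. the mean) the
#' jackknife SE equals the classical plug-in SE exactly.
#'
#' @param data per-subject data: a vector, or a list with one element per
#'   subject.
#' @param statistic function mapping a data subset (same type as `data`) to
#'   a scalar.
#' @param ... passed on to `statistic`.
#' @return list of class `jackknife_result`: `estimate`, `subsamples`,
#'   `jbar`, `se`, `t`, `df`, `p`. With zero SE, `t` and `p` are `NA` and
#'   `degenerate = TRUE`.
#' @export
jackknife_test <- function(data, statistic = mean, ...) {
  n <- if (is.list(data)) length(data) else length(data)
  if (n < 2) stop("jackknife needs at least 2 subjects")
  take <- function(keep) if (is.list(data)) data[keep] else data[keep]
  D <- tryCatch(statistic(data, ...), error = function(e)
    stop("statistic failed on the full sample: ", conditionMessage(e)))
  subs <- vapply(seq_len(n), function(i) {
    tryCatch(statistic(take(setdiff(seq_len(n), i)), ...),
             error = function(e) stop("statistic failed leaving out subject ",
                                      i, ": ", conditionMessage(e)))
  }, numeric(1))
  if (anyNA(subs) || is.na(D)) {
    stop("statistic returned NA on subsample(s): subject ",
         paste(which(is.na(subs)), collapse = ", "))
  }
  jbar <- mean(subs)
  se <- sqrt((n - 1) / n * sum((subs - jbar)^2))
  if (se > 0) {
    tj <- D / se
    p <- 2 * stats::pt(-abs(tj), df = n - 1)
    degen <- FALSE
  } else {
    tj <- NA_real_; p <- NA_real_; degen <- TRUE
    warning("jackknife SE is zero; t undefined")
  }
  structure(list(estimate = D, subsamples = subs, jbar = jbar, se = se,
                 t = tj, df = n - 1, p = p, degenerate = degen),
            class = "jackknife_result")
}

#' Paired t test with Cohen's d_z
#'
#' Paired t on subject-level differences, with the within-subject effect
#' size `d_z = t / sqrt(N)`.
#'
#' @param x,y per-subject values, equal length >= 2.
#' @return list `t`, `df`, `p`, `d_z`, `mean_diff`. Zero-variance
#'   differences are flagged (`degenerate = TRUE`, `t`/`p`/`d_z` NA).
#' @export
paired_t_dz <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  s <- stats::sd(d)
  if (s < 1e-300) {
    warning("zero-variance differences; paired t undefined")
    return(list(t = NA_real_, df = n - 1, p = NA_real_, d_z = NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- mean(d) / (s / sqrt(n))
  list(t = tt, df = n - 1, p = 2 * stats::pt(-abs(tt), n - 1),
       d_z = tt / sqrt(n), mean_diff = mean(d), degenerate = FALSE)
}

#' Two-way repeated-measures ANOVA
#'
#' Standard within-subject decomposition for a complete balanced subject x
#' factor A x factor B table: each effect is tested against its own
#' subject-by-effect interaction (no sphericity correction, matching the
#' uncorrected degrees of freedom convention).
#'
#' @param data long data.frame with columns `subject`, `A`, `B`, `value`, or
#'   a 3-d array `[subject, A, B]`.
#' @return list of class `anova_result`: data.frame `table` with one row per
#'   effect (`A`, `B`, `A:B`): `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_2way <- function(data) {
  y <- if (is.array(data) && length(dim(data)) == 3) data else {
    stopifnot(all(c("subject", "A", "B", "value") %in% names(data)))
    tab <- tapply(data$value, list(data$subject, data$A, data$B), mean)
    if (anyNA(tab)) stop("incomplete design: every subject x A x B cell is required")
    cnt <- table(data$subject, data$A, data$B)
    if (length(unique(as.vector(cnt))) != 1)
      stop("unbalanced design: unequal cell counts")
    tab
  }
  if (anyNA(y)) stop("incomplete design: missing cells")
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  stopifnot(n >= 2, a >= 2, b >= 2)
  gm <- mean(y)
  m_s <- apply(y, 1, mean); m_a <- apply(y, 2, mean); m_b <- apply(y, 3, mean)
  m_sa <- apply(y, c(1, 2), mean); m_sb <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)
  ss_a <- n * b * sum((m_a - gm)^2)
  ss_b <- n * a * sum((m_b - gm)^2)
  ss_sa <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + gm)^2)
  ss_sb <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + gm)^2)
  resid <- y
  for (i in seq_len(n)) for (j in seq_len(a)) for (kk in seq_len(b)) {
    resid[i, j, kk] <- y[i, j, kk] - m_sa[i, j] - m_sb[i, kk] - m_ab[j, kk] +
      m_s[i] + m_a[j] + m_b[kk] - gm
  }
  ss_sab <- sum(resid^2)
  eff <- data.frame(
    effect = c("A", "B", "A:B"),
    F = c((ss_a / (a - 1)) / (ss_sa / ((n - 1) * (a - 1))),
          (ss_b / (b - 1)) / (ss_sb / ((n - 1) * (b - 1))),
          (ss_ab / ((a - 1) * (b - 1))) / (ss_sab / ((n - 1) * (a - 1) * (b - 1)))),
    df1 = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df2 = c((n - 1) * (a - 1), (n - 1) * (b - 1), (n - 1) * (a - 1) * (b - 1)),
    stringsAsFactors = FALSE
  )
  eff$F[!is.finite(eff$F)] <- 0   # guard 0/0 for degenerate constant data
  eff$p <- stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  structure(list(table = eff), class = "anova_result")
}

# ---- cluster utilities ------------------------------------------------------

# contiguous TRUE runs of a logical vector -> list of index vectors
cluster_runs_1d <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  mapply(function(s, e) s:e, starts[r$values], ends[r$values],
         SIMPLIFY = FALSE)
}

# connected components of suprathreshold pixels on a grid with an arbitrary
# neighbor function; pixels = integer indices, nbrs = function(p) -> ints
cluster_components <- function(pixels, nbrs) {
  if (!length(pixels)) return(list())
  inset <- new.env(hash = TRUE, size = length(pixels))
  for (p in pixels) assign(as.character(p), TRUE, envir = inset)
  seen <- new.env(hash = TRUE, size = length(pixels))
  out <- list()
  for (p in pixels) {
    key <- as.character(p)
    if (!is.null(seen[[key]])) next
    comp <- integer(0)
    stack <- p
    seen[[key]] <- TRUE
    while (length(stack)) {
      q <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      comp <- c(comp, q)
      for (nb in nbrs(q)) {
        nk <- as.character(nb)
        if (!is.null(inset[[nk]]) && is.null(seen[[nk]])) {
          seen[[nk]] <- TRUE
          stack <- c(stack, nb)
        }
      }
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}

# neighbor function for a T x K grid stored pixel-major as (t-1)*K + c;
# time is linear, channel axis optionally circular
grid_neighbors <- function(n_time, k, circular_k = TRUE) {
  function(p) {
    t0 <- (p - 1L) %/% k + 1L
    c0 <- (p - 1L) %% k + 1L
    nbs <- integer(0)
    if (t0 > 1L) nbs <- c(nbs, p - k)
    if (t0 < n_time) nbs <- c(nbs, p + k)
    cm <- if (c0 > 1L) c0 - 1L else if (circular_k) k else NA_integer_
    cp <- if (c0 < k) c0 + 1L else if (circular_k) 1L else NA_integer_
    if (!is.na(cm)) nbs <- c(nbs, (t0 - 1L) * k + cm)
    if (!is.na(cp)) nbs <- c(nbs, (t0 - 1L) * k + cp)
    nbs
  }
}

# neighbor function for electrode x time maps stored as (t-1)*E + e
map_neighbors <- function(adj_list, n_elec, n_time) {
  function(p) {
    t0 <- (p - 1L) %/% n_elec + 1L
    e0 <- (p - 1L) %% n_elec + 1L
    nbs <- (t0 - 1L) * n_elec + adj_list[[e0]]
    if (t0 > 1L) nbs <- c(nbs, p - n_elec)
    if (t0 < n_time) nbs <- c(nbs, p + n_elec)
    nbs
  }
}

max_cluster_mass <- function(values, mask, nbrs) {
  comps <- cluster_components(which(mask), nbrs)
  if (!length(comps)) return(0)
  max(vapply(comps, function(cc) sum(values[cc]), numeric(1)))
}

perm_p <- function(null_masses, observed) {
  (1 + sum(null_masses >= observed)) / (length(null_masses) + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# ---- CTF cluster permutation (channel-shift surrogates) ---------------------

#' Cluster-based permutation test on realigned CTFs
#'
#' Tests where (time x channel-offset pixels) the group-mean realigned CTF
#' exceeds chance. The surrogate distribution randomly shifts each epoch's
#' CTF center before realignment (implemented as an extra uniform circular
#' channel shift of the realigned per-epoch CTF, which is equivalent);
#' pixels of the observed map exceeding the pixelwise 95th percentile of the
#' surrogate distribution are grouped into contiguous clusters (time
#' adjacency x circular channel adjacency), and each observed cluster's
#' summed value is compared against the permutation null of maximum
#' surrogate cluster masses.
#'
#' @param epoch_ctfs list with one element per subject: array
#'   `[n_epochs, n_time, n_channels]` of realigned per-epoch CTFs (from
#'   [sliding_window_decode()] with `keep_epoch_ctfs = TRUE`).
#' @param n_perm number of permutations (< 100 triggers a warning:
#'   unstable percentiles).
#' @param seed RNG seed; the test is a pure function of (data, seed).
#' @param shift_unit "epoch" draws an independent shift per epoch
#'   (default); "subject" shifts each subject's mean CTF by a single draw.
#' @return object of class `cluster_test`: `clusters` (list of `members`
#'   two-column matrices (time, channel), `mass`, `p`), `observed` (time x
#'   channel group map), `threshold` (pixelwise), `n_perm`, `seed`.
#' @export
ctf_cluster_permutation <- function(epoch_ctfs, n_perm = 10000, seed = 1,
                                    shift_unit = c("epoch", "subject")) {
  shift_unit <- match.arg(shift_unit)
  stopifnot(length(epoch_ctfs) >= 2)
  if (n_perm < 100) warning("n_perm < 100: surrogate percentiles are unstable")
  dims <- dim(epoch_ctfs[[1]])
  n_time <- dims[2]; k <- dims[3]
  n_sub <- length(epoch_ctfs)
  npix <- n_time * k
  # flat layout: pixel = (t-1)*k + c (channel fastest); aperm to [ep, k, time]
  # then column-major flattening gives exactly that order
  flat <- lapply(epoch_ctfs, function(a) {
    stopifnot(dim(a)[2] == n_time, dim(a)[3] == k)
    matrix(aperm(a, c(1, 3, 2)), nrow = dim(a)[1])
  })
  subj_mean <- lapply(flat, colMeans)
  observed <- Reduce(`+`, subj_mean) / n_sub
  # rotation index vectors: rot_idx[[s+1]][p] = source pixel of p under an
  # s-channel circular shift
  rot_idx <- lapply(0:(k - 1), function(s) {
    cc <- rep(seq_len(k), n_time)
    tt <- rep(seq_len(n_time), each = k)
    src_c <- ((cc - 1L + s) %% k) + 1L
    (tt - 1L) * k + src_c
  })
  permmat <- with_seed(seed, {
    pm <- matrix(0, n_perm, npix)
    for (pp in seq_len(n_perm)) {
      acc <- numeric(npix)
      for (si in seq_len(n_sub)) {
        if (shift_unit == "subject") {
          s <- sample.int(k, 1) - 1L
          acc <- acc + subj_mean[[si]][rot_idx[[s + 1]]]
        } else {
          E <- flat[[si]]
          ne <- nrow(E)
          shifts <- sample.int(k, ne, replace = TRUE) - 1L
          gs <- rowsum(E, group = shifts, reorder = TRUE)
          labs <- as.integer(rownames(gs))
          sacc <- numeric(npix)
          for (gi in seq_along(labs)) {
            sacc <- sacc + gs[gi, rot_idx[[labs[gi] + 1]]]
          }
          acc <- acc + sacc / ne
        }
      }
      pm[pp, ] <- acc / n_sub
    }
    pm
  })
  thr <- apply(permmat, 2, stats::quantile, probs = 0.95, names = FALSE)
  nbrs <- grid_neighbors(n_time, k, circular_k = TRUE)
  obs_comps <- cluster_components(which(observed > thr), nbrs)
  null_mass <- vapply(seq_len(n_perm), function(pp)
    max_cluster_mass(permmat[pp, ], permmat[pp, ] > thr, nbrs), numeric(1))
  clusters <- lapply(obs_comps, function(cc) {
    mass <- sum(observed[cc])
    list(members = cbind(time = (cc - 1L) %/% k + 1L,
                         channel = (cc - 1L) %% k + 1L),
         mass = mass, p = perm_p(null_mass, mass))
  })
  structure(list(clusters = clusters,
                 observed = matrix(observed, n_time, k, byrow = TRUE),
                 threshold = matrix(thr, n_time, k, byrow = TRUE),
                 null_mass = null_mass, n_perm = n_perm, seed = seed),
            class = "cluster_test")
}

# ---- time-resolved RM-ANOVA with cluster permutation ------------------------

# fast pointwise 2x2 RM-ANOVA across time: y [n_sub, 4, n_time], cells
# ordered (a1b1, a1b2, a2b1, a2b2); returns 3 x n_time F matrix
f_series_2x2 <- function(y) {
  contr <- rbind(A = c(1, 1, -1, -1) / 2,
                 B = c(1, -1, 1, -1) / 2,
                 AB = c(1, -1, -1, 1))
  n <- dim(y)[1]
  out <- matrix(0, 3, dim(y)[3])
  rownames(out) <- c("A", "B", "A:B")
  for (ei in 1:3) {
    cv <- contr[ei, 1] * y[, 1, ] + contr[ei, 2] * y[, 2, ] +
      contr[ei, 3] * y[, 3, ] + contr[ei, 4] * y[, 4, ]
    cv <- matrix(cv, nrow = n)
    m <- colMeans(cv)
    v <- (colSums(cv^2) - n * m^2) / (n - 1)
    f <- ifelse(v > 0, n * m^2 / v, 0)
    out[ei, ] <- f
  }
  out
}

#' Time-resolved two-way RM-ANOVA with cluster permutation
#'
#' Computes a pointwise 2 x 2 repeated-measures ANOVA (factor A = attention,
#' factor B = sequence type) on per-subject decoding-score time series,
#' thresholds each effect's F series at uncorrected p < 0.05, groups
#' suprathreshold time points into temporal clusters, and builds each
#' effect's null distribution from the maximum summed F under within-subject
#' random relabeling of the four condition cells.
#'
#' @param scores array `[n_subjects, 4, n_time]`; cells ordered
#'   (A1B1, A1B2, A2B1, A2B2), e.g. (attended RDM, attended RTT,
#'   unattended RDM, unattended RTT).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param alpha uncorrected pointwise threshold (default 0.05).
#' @return list of class `anova_cluster_test`: `F` (3 x n_time), `df`,
#'   `threshold` (F cutoff), `clusters` (per effect: list of `members`
#'   (time indices), `mass`, `p`), `n_perm`, `seed`.
#' @export
timewise_anova_cluster <- function(scores, n_perm = 10000, seed = 1,
                                   alpha = 0.05) {
  stopifnot(length(dim(scores)) == 3, dim(scores)[2] == 4)
  if (anyNA(scores)) stop("unbalanced design: missing scores")
  n <- dim(scores)[1]
  stopifnot(n >= 2)
  fobs <- f_series_2x2(scores)
  fcrit <- stats::qf(1 - alpha, 1, n - 1)
  effects <- rownames(fobs)
  obs_cl <- lapply(seq_along(effects), function(ei)
    cluster_runs_1d(fobs[ei, ] > fcrit))
  null_mass <- with_seed(seed, {
    nm <- matrix(0, n_perm, 3)
    yp <- scores
    for (pp in seq_len(n_perm)) {
      for (si in seq_len(n)) {
        yp[si, , ] <- scores[si, sample.int(4), ]
      }
      fp <- f_series_2x2(yp)
      for (ei in 1:3) {
        nm[pp, ei] <- max_run_mass(fp[ei, ], fcrit)
      }
    }
    nm
  })
  clusters <- lapply(seq_along(effects), function(ei) {
    lapply(obs_cl[[ei]], function(ix) {
      mass <- sum(fobs[ei, ix])
      list(members = ix, mass = mass, p = perm_p(null_mass[, ei], mass))
    })
  })
  names(clusters) <- effects
  structure(list(F = fobs, df = c(1, n - 1), threshold = fcrit,
                 clusters = clusters, null_mass = null_mass,
                 n_perm = n_perm, seed = seed),
            class = "anova_cluster_test")
}

max_run_mass <- function(values, threshold) {
  mask <- values > threshold
  if (!any(mask)) return(0)
  runs <- cluster_runs_1d(mask)
  max(vapply(runs, function(ix) sum(values[ix]), numeric(1)))
}

# ---- electrode x time map cluster permutation -------------------------------

#' Paired cluster permutation test on electrode-by-time maps
#'
#' Paired t test per (electrode, time) pixel between two within-subject
#' conditions, two-tailed threshold at `alpha_crit`, spatio-temporal
#' clustering via electrode adjacency and time contiguity (positive and
#' negative clusters separately, cluster mass = summed t), and a max-cluster
#' null distribution from random sign flips of the subject-level difference
#' maps. By construction the test is symmetric: negating the maps leaves all
#' cluster p values unchanged.
#'
#' @param x,y arrays `[n_subjects, n_electrodes, n_time]` for the two
#'   conditions (or `y = NULL` and `x` already a difference).
#' @param adjacency symmetric logical electrode adjacency matrix.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param alpha_crit two-tailed pixel threshold (default 0.05).
#' @return list of class `cluster_test`: `clusters` (list of `members`
#'   two-column matrices (electrode, time), `mass` (signed summed t), `p`),
#'   `t_map` (electrode x time), `threshold`, `n_perm`, `seed`.
#' @export
map_cluster_permutation <- function(x, y = NULL, adjacency, n_perm = 10000,
                                    seed = 1, alpha_crit = 0.05) {
  d <- if (is.null(y)) x else x - y
  stopifnot(length(dim(d)) == 3)
  n <- dim(d)[1]; ne <- dim(d)[2]; nt <- dim(d)[3]
  stopifnot(n >= 2)
  if (!is.matrix(adjacency) || nrow(adjacency) != ne || ncol(adjacency) != ne)
    stop("adjacency must be ", ne, " x ", ne)
  D <- matrix(d, nrow = n)                 # n x (ne*nt), pixel = (t-1)*ne + e
  ssq <- colSums(D^2)
  tcrit <- stats::qt(1 - alpha_crit / 2, n - 1)
  adj_list <- lapply(seq_len(ne), function(e) which(adjacency[e, ]))
  nbrs <- map_neighbors(adj_list, ne, nt)
  t_of <- function(m) {
    v <- (ssq / n - m^2) * n / (n - 1)
    ifelse(v > 0, m / sqrt(v / n), 0)
  }
  tobs <- t_of(colMeans(D))
  signed_cluster_masses <- function(tv) {
    comps_p <- cluster_components(which(tv > tcrit), nbrs)
    comps_n <- cluster_components(which(tv < -tcrit), nbrs)
    list(pos = comps_p, neg = comps_n)
  }
  # sign-flip null: all perm means in one matrix product
  null_max <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    Mp <- S %*% D / n
    vapply(seq_len(n_perm), function(pp) {
      tv <- t_of(Mp[pp, ])
      over <- abs(tv) > tcrit
      if (!any(over)) return(0)
      cc <- signed_cluster_masses(tv)
      masses <- c(vapply(cc$pos, function(ix) sum(tv[ix]), numeric(1)),
                  vapply(cc$neg, function(ix) -sum(tv[ix]), numeric(1)))
      if (length(masses)) max(masses) else 0
    }, numeric(1))
  })
  cc <- signed_cluster_masses(tobs)
  mk <- function(ix, sign) {
    mass <- sum(tobs[ix])
    list(members = cbind(electrode = (ix - 1L) %% ne + 1L,
                         time = (ix - 1L) %/% ne + 1L),
         mass = mass, p = perm_p(null_max, abs(mass)))
  }
  clusters <- c(lapply(cc$pos, mk, sign = 1), lapply(cc$neg, mk, sign = -1))
  structure(list(clusters = clusters,
                 t_map = matrix(tobs, ne, nt),
                 threshold = tcrit, null_mass = null_max,
                 n_perm = n_perm, seed = seed),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d cluster(s), %d permutations\n",
              length(x$clusters), x$n_perm))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d: extent %d, mass %.3f, p = %.4g\n",
                i, nrow(as.matrix(cl$members)), cl$mass, cl$p))
  }
  invisible(x)
}
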