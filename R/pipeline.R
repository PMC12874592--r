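#' Run the full synthetic-study analysis pipeline
#'
#' Orchestrates simulate -> spectral -> decode -> stats -> behavior into one
#' reproducible run: (1) behavioral simulation and representational-momentum
#' ANOVA; (2) a first pass over subjects computing trial power spectra,
#' from which the SSVEP electrode subset is selected at the group level
#' (union of 75th-percentile sets at 5 and 10 Hz); (3) a second pass
#' re-generating each subject (bit-identical) and running time-frequency
#' SSVEP analysis, global field power, and sliding-window IEM decoding on
#' the selected electrodes; (4) group statistics: channel-shift cluster
#' permutation on the realigned CTFs, Gaussian bias fits over the first
#' significant cluster with jackknife tests against 0, time-resolved
#' attention x sequence ANOVA with cluster permutation on the decoding
#' scores, electrode-time cluster permutation of the SSVEP attention effect,
#' a 2 x 2 RM-ANOVA on contralateral SSVEP power, and paired GFP and
#' decoding-score contrasts.
#'
#' Stage seeds are derived from `config$seed` by fixed offsets, so stages
#' can be rerun in isolation; the whole run is a pure function of the
#' config and arguments (identical summaries byte for byte).
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, per-stage tables (CSV),
#'   the config (JSON) and the run summary (JSON) are written there.
#' @param n_perm permutations for all cluster tests.
#' @param decode_stride decoding window-center step in samples.
#' @param n_train attended-RDM training epochs per side (NULL = all).
#' @param window_ms decoding window length (ms).
#' @param percentile electrode-selection percentile.
#' @param tf_step spacing (s) of time-frequency window centers.
#' @param loo_unit leave-one-out unit, "epoch" or "trial".
#' @param verbose print stage progress.
#' @return list of class `pipeline_result` with elements `summary` (plain
#'   list mirrored in summary.json), `behavior`, `selection`, `decode`
#'   (per-subject cell CTFs and scores), `ctf_tests`, `bias`, `anova_scores`,
#'   `ssvep`, `gfp`, `seeds`.
#' @export
run_pipeline <- function(config, out_dir = NULL, n_perm = 1000,
                         decode_stride = 2L, n_train = NULL, window_ms = 40,
                         percentile = 75, tf_step = 0.1, loo_unit = "epoch",
                         verbose = TRUE) {
  t_start <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  fail <- function(stage, e) stop("pipeline stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)
  seeds <- list(ctf_perm = (config$seed + 101L) %% .Machine$integer.max,
                anova_perm = (config$seed + 202L) %% .Machine$integer.max,
                map_perm = (config$seed + 303L) %% .Machine$integer.max)
  layout <- electrode_layout(config$n_electrodes)
  ns <- config$n_subjects

  ## ---- behavior -------------------------------------------------------
  say("stage behavior: %d subjects", ns)
  behav <- tryCatch({
    responses <- simulate_behavior(config)
    props <- proportion_same(responses)
    list(responses = responses, proportions = props,
         analysis = rm_behavior_analysis(props))
  }, error = function(e) fail("behavior", e))

  ## ---- spectral pass: electrode selection -----------------------------
  say("stage spectral: trial spectra and electrode selection")
  sel <- tryCatch({
    pw5 <- matrix(0, ns, config$n_electrodes)
    pw10 <- matrix(0, ns, config$n_electrodes)
    psd_sum <- NULL
    for (sid in seq_len(ns)) {
      sub <- simulate_subject(config, sid, layout, keep_trials = TRUE,
                              keep_epochs = FALSE)
      psd <- trial_power_spectrum(sub$trials$data, config$sfreq, fmax = 40)
      if (is.null(psd_sum)) psd_sum <- psd$power else
        psd_sum <- psd_sum + psd$power
      b5 <- which.min(abs(psd$frequencies - 5))
      b10 <- which.min(abs(psd$frequencies - 10))
      pw5[sid, ] <- psd$power[, b5]
      pw10[sid, ] <- psd$power[, b10]
      freqs <- psd$frequencies
    }
    group_psd <- structure(list(frequencies = freqs, power = psd_sum / ns,
                                n_trials = NA, window = 5),
                           class = "power_spectrum")
    electrodes <- select_ssvep_electrodes(group_psd, percentile)
    list(group_psd = group_psd, electrodes = electrodes,
         power_5hz = pw5, power_10hz = pw10)
  }, error = function(e) fail("spectral", e))
  say("  selected %d / %d electrodes", length(sel$electrodes),
      config$n_electrodes)

  ## ---- per-subject decode + TF + GFP ----------------------------------
  say("stage decode: sliding-window IEM on %d electrodes",
      length(sel$electrodes))
  cells <- c("RDM_attended", "RTT_attended", "RDM_unattended",
             "RTT_unattended")
  per_subj <- tryCatch({
    out <- vector("list", ns)
    for (sid in seq_len(ns)) {
      sub <- simulate_subject(config, sid, layout)
      dec <- sliding_window_decode(
        sub$epochs, electrodes = sel$electrodes, window_ms = window_ms,
        stride = decode_stride, n_train = n_train, loo_unit = loo_unit,
        keep_epoch_ctfs = TRUE,
        epoch_ctf_cells = c("RDM_attended", "RTT_attended"))
      g <- gfp(subset_epochs(sub$epochs, sub$epochs$metadata$attended),
               by = "sequence_type")
      tf <- tf_power_5hz(sub$trials$data, config$sfreq, step = tf_step)
      info <- sub$trials$info
      tf_cell <- lapply(split(seq_len(nrow(info)),
                              list(info$attended_side, info$condition)),
                        function(ix) apply(tf$power[ix, , , drop = FALSE],
                                           c(2, 3), mean))
      out[[sid]] <- list(decode = dec, gfp = g, tf_cell = tf_cell,
                         tf_times = tf$times)
      say("  subject %d/%d done", sid, ns)
    }
    out
  }, error = function(e) fail("decode", e))
  times <- per_subj[[1]]$decode$times
  n_win <- length(times)

  ## ---- CTF cluster tests + Gaussian bias ------------------------------
  say("stage stats: CTF cluster permutation (%d permutations)", n_perm)
  ctf_tests <- tryCatch({
    res <- list()
    for (cl in c("RDM_attended", "RTT_attended")) {
      ep <- lapply(per_subj, function(s) s$decode$cells[[cl]]$epoch_ctf)
      res[[cl]] <- ctf_cluster_permutation(ep, n_perm = n_perm,
                                           seed = seeds$ctf_perm)
    }
    res
  }, error = function(e) fail("ctf_cluster", e))

  bias <- tryCatch({
    res <- list()
    # one shared analysis window for both conditions: the dominant
    # (largest-mass) significant cluster of the training (RDM) condition,
    # which has the cleanest CTF; fallback: windows overlapping the expected
    # evoked-response support
    sig <- Filter(function(x) x$p < 0.05, ctf_tests$RDM_attended$clusters)
    win <- if (length(sig)) {
      best <- sig[[which.max(vapply(sig, `[[`, numeric(1), "mass"))]]
      sort(unique(best$members[, "time"]))
    } else {
      which(times >= config$kernel_onset & times <= 0.3)
    }
    for (cl in c("RDM_attended", "RTT_attended")) {
      mats <- lapply(per_subj, function(s)
        colMeans(s$decode$cells[[cl]]$ctf[win, , drop = FALSE]))
      center_stat <- function(sub_mats) {
        m <- Reduce(`+`, sub_mats) / length(sub_mats)
        fit_gaussian_bias(m)$center
      }
      jk <- jackknife_test(mats, center_stat)
      res[[cl]] <- list(window = times[win], center = jk$estimate,
                        jackknife = jk,
                        fit = fit_gaussian_bias(Reduce(`+`, mats) / ns))
    }
    res
  }, error = function(e) fail("gaussian_bias", e))

  ## ---- time-resolved ANOVA on decoding scores -------------------------
  say("stage stats: time-resolved ANOVA on decoding scores")
  anova_scores <- tryCatch({
    sc <- array(0, c(ns, 4, n_win))
    # cells ordered (attended RDM, attended RTT, unattended RDM, unattended
    # RTT): factor A = attention, factor B = sequence type
    ord <- c("RDM_attended", "RTT_attended", "RDM_unattended",
             "RTT_unattended")
    for (sid in seq_len(ns)) for (ci in seq_along(ord)) {
      sc[sid, ci, ] <- per_subj[[sid]]$decode$cells[[ord[ci]]]$score
    }
    list(scores = sc,
         test = timewise_anova_cluster(sc, n_perm = n_perm,
                                       seed = seeds$anova_perm))
  }, error = function(e) fail("anova_scores", e))

  ## ---- SSVEP lateralization -------------------------------------------
  say("stage stats: SSVEP lateralization")
  ssvep <- tryCatch({
    tf_times <- per_subj[[1]]$tf_times
    nt <- length(tf_times)
    maps <- function(side, cond) {
      a <- array(0, c(ns, config$n_electrodes, nt))
      key <- paste(side, cond, sep = ".")
      for (sid in seq_len(ns)) a[sid, , ] <- per_subj[[sid]]$tf_cell[[key]]
      a
    }
    # laterality-normalized maps (right hemisphere = contralateral to the
    # attended hemifield): flip left-attended maps, average with right-attended
    lat_maps <- function(cond) {
      a <- array(0, c(ns, config$n_electrodes, nt))
      for (sid in seq_len(ns)) {
        ml <- flip_lateralization(per_subj[[sid]]$tf_cell[[paste0("left.", cond)]],
                                  layout, attended_side = "left")
        mr <- per_subj[[sid]]$tf_cell[[paste0("right.", cond)]]
        a[sid, , ] <- (ml + mr) / 2
      }
      a
    }
    tests <- list(
      RDM = map_cluster_permutation(maps("left", "RDM"), maps("right", "RDM"),
                                    layout$adjacency, n_perm = n_perm,
                                    seed = seeds$map_perm),
      RTT = map_cluster_permutation(maps("left", "RTT"), maps("right", "RTT"),
                                    layout$adjacency, n_perm = n_perm,
                                    seed = seeds$map_perm),
      RDM_vs_RTT_flipped = map_cluster_permutation(
        lat_maps("RDM"), lat_maps("RTT"), layout$adjacency,
        n_perm = n_perm, seed = seeds$map_perm))
    # 5 Hz power at a fixed right-posterior site set per attention side x
    # sequence type: attending left makes these sites contralateral
    post_x <- layout$positions[layout$posterior, 1]
    post_l <- layout$posterior[post_x < 0]
    post_r <- layout$posterior[post_x > 0]
    cellmean <- function(side, cond) {
      vapply(seq_len(ns), function(sid)
        mean(per_subj[[sid]]$tf_cell[[paste(side, cond, sep = ".")]][post_r, ]),
        numeric(1))
    }
    y <- array(0, c(ns, 2, 2), dimnames = list(NULL, c("left", "right"),
                                               c("RDM", "RTT")))
    for (a in c("left", "right")) for (b in c("RDM", "RTT"))
      y[, a, b] <- cellmean(a, b)
    lat_anova <- rm_anova_2way(y)
    lat_anova$table$effect <- c("attended_side", "sequence_type",
                                "attended_side:sequence_type")
    # contra - ipsi contrast per condition (collapsed over side)
    lat_index <- function(cond) {
      ipsi <- function(side) if (side == "left") post_l else post_r
      vapply(seq_len(ns), function(sid) {
        v <- 0
        for (side in c("left", "right")) {
          mcell <- per_subj[[sid]]$tf_cell[[paste(side, cond, sep = ".")]]
          contra <- if (side == "left") post_r else post_l
          v <- v + mean(mcell[contra, ]) - mean(mcell[ipsi(side), ])
        }
        v / 2
      }, numeric(1))
    }
    li_rdm <- lat_index("RDM"); li_rtt <- lat_index("RTT")
    list(tests = tests, lat_anova = lat_anova,
         lat_index = list(RDM = li_rdm, RTT = li_rtt),
         lat_contrast = paired_t_dz(li_rdm, li_rtt),
         contra_power = y)
  }, error = function(e) fail("ssvep", e))

  ## ---- GFP and score contrasts ----------------------------------------
  gfp_res <- tryCatch({
    gr <- function(cl) vapply(per_subj, function(s)
      mean(s$gfp$series[cl, ]), numeric(1))
    rdm <- gr("RDM"); rtt <- gr("RTT")
    sc_mean <- function(cl) vapply(per_subj, function(s)
      mean(s$decode$cells[[cl]]$score), numeric(1))
    list(gfp_rdm = rdm, gfp_rtt = rtt,
         contrast = paired_t_dz(rdm, rtt),
         score_contrast = paired_t_dz(sc_mean("RDM_attended"),
                                      sc_mean("RTT_attended")))
  }, error = function(e) fail("gfp", e))

  ## ---- summary ---------------------------------------------------------
  cluster_brief <- function(ct) lapply(ct$clusters, function(cc)
    list(extent = nrow(as.matrix(cc$members)), mass = cc$mass, p = cc$p))
  an <- behav$analysis$anova$table
  summary <- list(
    config = unclass(config),
    seeds = seeds,
    n_subjects = ns,
    behavior = list(
      anova = an,
      posthoc = behav$analysis$posthoc,
      cell_means = behav$analysis$cell_means),
    electrode_selection = list(n_selected = length(sel$electrodes),
                               electrodes = sel$electrodes),
    bias = list(
      rtt_center = bias$RTT_attended$center,
      rtt_jackknife_t = bias$RTT_attended$jackknife$t,
      rtt_jackknife_p = bias$RTT_attended$jackknife$p,
      rdm_center = bias$RDM_attended$center,
      rdm_jackknife_p = bias$RDM_attended$jackknife$p),
    decoding_clusters = lapply(ctf_tests, cluster_brief),
    anova_clusters = lapply(anova_scores$test$clusters, function(effect)
      lapply(effect, function(cc)
        list(extent = length(cc$members), mass = cc$mass, p = cc$p))),
    ssvep = list(
      lat_anova = ssvep$lat_anova$table,
      lat_contrast_t = ssvep$lat_contrast$t,
      lat_contrast_p = ssvep$lat_contrast$p,
      rdm_clusters = cluster_brief(ssvep$tests$RDM),
      rtt_clusters = cluster_brief(ssvep$tests$RTT),
      rdm_vs_rtt_clusters = cluster_brief(ssvep$tests$RDM_vs_RTT_flipped)),
    gfp = list(
      mean_rdm = mean(gfp_res$gfp_rdm), mean_rtt = mean(gfp_res$gfp_rtt),
      t = gfp_res$contrast$t, p = gfp_res$contrast$p,
      score_t = gfp_res$score_contrast$t,
      score_p = gfp_res$score_contrast$p),
    runtime_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    r_version = R.version.string
  )

  result <- structure(
    list(summary = summary, behavior = behav, selection = sel,
         decode = lapply(per_subj, function(s) {
           s$decode$cells <- lapply(s$decode$cells, function(cc) {
             cc$epoch_ctf <- NULL; cc
           })
           s$decode
         }),
         ctf_tests = ctf_tests, bias = bias, anova_scores = anova_scores,
         ssvep = ssvep, gfp = gfp_res, times = times, seeds = seeds),
    class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_outputs(result, config, out_dir)
  say("pipeline finished in %.1f s", summary$runtime_s)
  result
}

write_pipeline_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  summary <- result$summary
  summary$runtime_s <- NULL                # keep reruns byte-identical
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE,
                       dataframe = "rows")
  write_sim_config(config, p("config.json"))
  utils::write.csv(result$behavior$proportions, p("behavior_proportions.csv"),
                   row.names = FALSE)
  # long-format CTF and score series
  long <- do.call(rbind, lapply(seq_along(result$decode), function(sid) {
    dec <- result$decode[[sid]]
    do.call(rbind, lapply(names(dec$cells), function(cl) {
      data.frame(subject = sid, condition = cl,
                 time = rep(dec$times, length(dec$offsets)),
                 offset = rep(dec$offsets, each = length(dec$times)),
                 value = as.vector(dec$cells[[cl]]$ctf))
    }))
  }))
  utils::write.csv(long, p("ctf_series.csv"), row.names = FALSE)
  scores <- do.call(rbind, lapply(seq_along(result$decode), function(sid) {
    dec <- result$decode[[sid]]
    do.call(rbind, lapply(names(dec$cells), function(cl)
      data.frame(subject = sid, condition = cl, time = dec$times,
                 score = dec$cells[[cl]]$score)))
  }))
  utils::write.csv(scores, p("decoding_scores.csv"), row.names = FALSE)
  jsonlite::write_json(result$selection$electrodes, p("electrodes.json"))
  invisible(out_dir)
}
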