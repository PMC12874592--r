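#!/usr/bin/env Rscript
# Stage 3: SSVEP power spectrum, electrode selection, and lateralization.
#
# The 5 Hz flicker tags visual responses at 5 Hz and its 10 Hz harmonic.
# Electrodes whose trial-averaged power exceeds the 75th percentile at
# either frequency (union rule) are selected for decoding. Attention
# enhances 5 Hz power contralateral to the attended hemifield; the
# enhancement is attenuated when the attended stream is rotational.

library(momdecode)

cfg <- read_sim_config("results/run_config.json")
lay <- electrode_layout(cfg$n_electrodes)

pw_sum <- NULL
tf_cells <- list()
for (sid in seq_len(cfg$n_subjects)) {
  sub <- simulate_subject(cfg, sid, lay, keep_epochs = FALSE)
  psd <- trial_power_spectrum(sub$trials$data, cfg$sfreq, fmax = 40)
  pw_sum <- if (is.null(pw_sum)) psd$power else pw_sum + psd$power
  tf <- tf_power_5hz(sub$trials$data, cfg$sfreq, step = 0.1)
  info <- sub$trials$info
  for (key in c("left.RDM", "right.RDM", "left.RTT", "right.RTT")) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    ix <- which(info$attended_side == parts[1] & info$condition == parts[2])
    m <- apply(tf$power[ix, , , drop = FALSE], c(2, 3), mean)
    tf_cells[[key]][[sid]] <- m
  }
  freqs <- psd$frequencies
}
group_psd <- structure(list(frequencies = freqs,
                            power = pw_sum / cfg$n_subjects,
                            n_trials = NA, window = 5),
                       class = "power_spectrum")
sel <- select_ssvep_electrodes(group_psd)
cat(sprintf("Selected %d / %d electrodes (union of 75th-percentile sets at 5 and 10 Hz)\n",
            length(sel), cfg$n_electrodes))
jsonlite::write_json(sel, "results/selected_electrodes.json")
write.csv(data.frame(electrode = seq_len(cfg$n_electrodes),
                     label = lay$labels,
                     power_5hz = group_psd$power[, freqs == 5],
                     power_10hz = group_psd$power[, freqs == 10],
                     selected = seq_len(cfg$n_electrodes) %in% sel),
          "results/ssvep_electrode_power.csv", row.names = FALSE)

# lateralization: left- vs right-attended maps per condition
nt <- ncol(tf_cells[["left.RDM"]][[1]])
mk <- function(key) {
  a <- array(0, c(cfg$n_subjects, cfg$n_electrodes, nt))
  for (sid in seq_len(cfg$n_subjects)) a[sid, , ] <- tf_cells[[key]][[sid]]
  a
}
for (cond in c("RDM", "RTT")) {
  mt <- map_cluster_permutation(mk(paste0("left.", cond)),
                                mk(paste0("right.", cond)),
                                lay$adjacency, n_perm = 1000, seed = 404)
  ps <- vapply(mt$clusters, `[[`, numeric(1), "p")
  cat(sprintf("%s condition: %d electrode-time clusters, min p = %s\n",
              cond, length(ps),
              if (length(ps)) format(min(ps), digits = 3) else "none"))
  write.csv(data.frame(electrode = rep(seq_len(cfg$n_electrodes), nt),
                       time_bin = rep(seq_len(nt), each = cfg$n_electrodes),
                       t = as.vector(mt$t_map)),
            sprintf("results/ssvep_attention_tmap_%s.csv", cond),
            row.names = FALSE)
}
cat("A significant attention cluster in RDM but a weak/absent one in RTT",
    "reproduces the attenuated lateralization for rotational sequences.\n")
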