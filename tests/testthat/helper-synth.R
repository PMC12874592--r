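# small shared configurations for the synthetic study
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 2, n_trials_per_cell = 2, n_electrodes = 16, seed = 42),
    list(...))
  do.call(sim_config, args)
}

noiseless_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 2, n_trials_per_cell = 3, n_electrodes = 24,
         noise_sd = 0, bias_rtt = 0, ssvep_amplitude = 0, seed = 7),
    list(...))
  do.call(sim_config, args)
}

# group-mean Gaussian-fit center, the statistic used with the jackknife
group_center <- function(ctf_list) {
  fit_gaussian_bias(Reduce(`+`, ctf_list) / length(ctf_list))$center
}

# decode a subject and return per-condition CTFs averaged over an early
# post-stimulus window, plus mean scores
decode_subject_summary <- function(config, sid, window = c(0.07, 0.19),
                                   stride = 6, electrodes = NULL) {
  sub <- simulate_subject(config, sid, keep_trials = FALSE)
  dec <- sliding_window_decode(sub$epochs, electrodes = electrodes,
                               stride = stride, time_range = window)
  list(
    ctf = lapply(dec$cells, function(cc) colMeans(cc$ctf)),
    score = vapply(dec$cells, function(cc) mean(cc$score), numeric(1)))
}
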