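#' Proportion of "same" reports per cell
#'
#' Aggregates a behavioral table of same/different probe responses into per
#' subject x sequence type x probe offset proportions.
#'
#' @param responses data.frame with columns `subject_id`, `sequence_type`,
#'   `probe_offset` (-4, 0 or +4 degrees) and `response`
#'   ("same"/"different"), as produced by [simulate_behavior()].
#' @return data.frame with columns `subject_id`, `sequence_type`,
#'   `probe_offset`, `n_trials`, `p_same`.
#' @export
proportion_same <- function(responses) {
  stopifnot(all(c("subject_id", "sequence_type", "probe_offset", "response")
                %in% names(responses)))
  if (!all(responses$probe_offset %in% c(-4, 0, 4)))
    stop("probe_offset must be -4, 0 or +4")
  if (!all(responses$response %in% c("same", "different")))
    stop("response must be 'same' or 'different'")
  key <- interaction(responses$subject_id, responses$sequence_type,
                     responses$probe_offset, sep = "\r", drop = FALSE)
  n <- tapply(responses$response, key, length)
  k <- tapply(responses$response == "same", key, sum)
  keep <- !is.na(n)
  parts <- do.call(rbind, strsplit(names(n)[keep], "\r", fixed = TRUE))
  out <- data.frame(subject_id = type.convert(parts[, 1], as.is = TRUE),
                    sequence_type = parts[, 2],
                    probe_offset = as.numeric(parts[, 3]),
                    n_trials = as.integer(n[keep]),
                    p_same = as.numeric(k[keep] / n[keep]),
                    stringsAsFactors = FALSE)
  empty <- with(expand.grid(subject_id = unique(out$subject_id),
                            sequence_type = unique(out$sequence_type),
                            probe_offset = unique(out$probe_offset)),
                paste(subject_id, sequence_type, probe_offset))
  have <- with(out, paste(subject_id, sequence_type, probe_offset))
  if (!all(empty %in% have)) {
    stop("empty cells: ", paste(setdiff(empty, have), collapse = ", "))
  }
  out[order(out$subject_id, out$sequence_type, out$probe_offset), ]
}

#' Representational-momentum behavioral analysis
#'
#' Two-way repeated-measures ANOVA on the proportion of "same" reports with
#' factors sequence type (rotational vs random) and probe offset (-4, 0, +4
#' degrees), followed by the five planned paired contrasts: RTT vs RDM at
#' +4; within RTT, +4 vs 0 and +4 vs -4; within RDM, 0 vs -4 and 0 vs +4.
#' A forward perceptual shift shows up as an interaction driven by elevated
#' "same" reports at +4 after rotational sequences. Proportions are analyzed
#' untransformed.
#'
#' @param table a proportion table from [proportion_same()] with a complete
#'   2 x 3 within-subject design.
#' @return list of class `rm_behavior_result`: `anova` (an `anova_result`
#'   with A = sequence type, B = offset), `posthoc` (data.frame of the five
#'   contrasts: t, df, p, d_z), `cell_means`.
#' @export
rm_behavior_analysis <- function(table) {
  need <- expand.grid(sequence_type = c("RTT", "RDM"),
                      probe_offset = c(-4, 0, 4))
  subj <- sort(unique(table$subject_id))
  y <- array(NA_real_, c(length(subj), 2, 3),
             dimnames = list(NULL, c("RTT", "RDM"), c("-4", "0", "4")))
  for (i in seq_along(subj)) for (a in 1:2) for (b in 1:3) {
    v <- table$p_same[table$subject_id == subj[i] &
                        table$sequence_type == dimnames(y)[[2]][a] &
                        table$probe_offset == c(-4, 0, 4)[b]]
    if (length(v) != 1) stop("incomplete design for subject ", subj[i])
    y[i, a, b] <- v
  }
  res <- rm_anova_2way(y)
  res$table$effect <- c("sequence_type", "probe_offset",
                        "sequence_type:probe_offset")
  cmp <- list(
    c("RTT vs RDM at +4", "RTT", "4", "RDM", "4"),
    c("RTT +4 vs 0", "RTT", "4", "RTT", "0"),
    c("RTT +4 vs -4", "RTT", "4", "RTT", "-4"),
    c("RDM 0 vs -4", "RDM", "0", "RDM", "-4"),
    c("RDM 0 vs +4", "RDM", "0", "RDM", "4"))
  posthoc <- do.call(rbind, lapply(cmp, function(cc) {
    r <- paired_t_dz(y[, cc[2], cc[3]], y[, cc[4], cc[5]])
    data.frame(contrast = cc[1], t = r$t, df = r$df, p = r$p, d_z = r$d_z,
               mean_diff = r$mean_diff, stringsAsFactors = FALSE)
  }))
  structure(list(anova = res, posthoc = posthoc,
                 cell_means = apply(y, c(2, 3), mean)),
            class = "rm_behavior_result")
}
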