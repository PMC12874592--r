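#' Orientation arithmetic on the 180-degree circle
#'
#' Grating orientation is circular with period 180 degrees: 0 and 180 are the
#' same stimulus. All orientations in this package live in [0, 180) and
#' differences are wrapped to the half-open interval (-90, 90], so that the
#' sign of a difference is the direction of the shortest rotation.
#'
#' @param theta numeric vector of angles in degrees.
#' @return `wrap_orientation()` maps angles into [0, 180);
#'   `orientation_diff()` returns wrapped differences `a - b` in (-90, 90].
#' @examples
#' wrap_orientation(185)      # 5
#' orientation_diff(10, 170)  # 20, not -160
#' @export
wrap_orientation <- function(theta) {
  theta %% 180
}

#' @rdname wrap_orientation
#' @param a,b numeric vectors of angles in degrees.
#' @export
orientation_diff <- function(a, b) {
  d <- (a - b) %% 180
  ifelse(d > 90, d - 180, d)
}

#' The orientation grid used by the stimulus sequences
#'
#' Sequences draw orientations from a coarse grid spaced by `step` degrees
#' (default 20, giving the 9 orientations 0, 20, ..., 160).
#'
#' @param step grid spacing in degrees; must divide 180.
#' @return numeric vector of grid orientations.
#' @export
orientation_grid <- function(step = 20) {
  stopifnot(step > 0, 180 %% step == 0)
  seq(0, 180 - step, by = step)
}

is_on_grid <- function(theta, step = 20) {
  abs(orientation_diff(theta, round(theta / step) * step)) < 1e-9
}

#' Rotational (predictable) orientation sequence
#'
#' Builds the deterministic rotational sequence: an arithmetic progression of
#' orientations in fixed clockwise steps, wrapped on the 180-degree circle.
#' Clockwise is mapped to +`step` degrees per item; only the consistency of
#' the convention matters, and decoded biases are reported in the direction
#' of rotation.
#'
#' @param start starting orientation in degrees; must lie on the grid.
#' @param n_items number of gratings in the sequence (25 for a 5 s stream at
#'   5 Hz).
#' @param step rotation per item in degrees (default +20).
#' @return numeric vector of `n_items` orientations in [0, 180).
#' @examples
#' make_rotational_sequence(160, 3)  # 160 0 20
#' @export
make_rotational_sequence <- function(start, n_items, step = 20) {
  stopifnot(n_items >= 1)
  if (!is_on_grid(start, abs(step))) {
    stop("`start` must lie on the ", abs(step), "-degree orientation grid, got ",
         start)
  }
  wrap_orientation(start + step * (seq_len(n_items) - 1))
}

#' Random (unpredictable) orientation sequence
#'
#' Draws orientations i.i.d. uniformly from the grid, rejecting any draw that
#' would form a one-step (plus or minus `step` degrees) transition with the
#' previous item, so the sequence never contains the local rotational
#' structure of [make_rotational_sequence()]. Exact repeats and larger jumps
#' are allowed. Rejection is per step, so each item remains uniform over its
#' allowed set.
#'
#' @param n_items number of gratings.
#' @param step grid spacing / forbidden transition magnitude in degrees.
#' @return numeric vector of `n_items` grid orientations with no consecutive
#'   wrapped difference of magnitude `step`.
#' @export
make_random_sequence <- function(n_items, step = 20) {
  stopifnot(n_items >= 1)
  grid <- orientation_grid(step)
  out <- numeric(n_items)
  out[1] <- sample(grid, 1)
  if (n_items > 1) {
    for (i in 2:n_items) {
      allowed <- grid[abs(orientation_diff(grid, out[i - 1])) != step]
      out[i] <- sample(allowed, 1)
    }
  }
  out
}

#' Assemble the trial-level design of the two-stream experiment
#'
#' Each trial shows a rotational (RTT) stream in one hemifield and a random
#' (RDM) stream in the other; a cue directs attention to one side. The trial
#' is labeled by the sequence type of the *attended* stream. Sides and cue
#' are balanced so each of the four cells (attended side x attended type)
#' has `n_trials_per_cell` trials, in randomized order.
#'
#' @param n_trials_per_cell trials per (attended side x attended type) cell.
#' @param n_items gratings per stream.
#' @param step rotation step in degrees.
#' @return data.frame with one row per trial: `trial_id`, `attended_side`
#'   ("left"/"right"), `condition` ("RTT"/"RDM" = type of attended stream),
#'   `rtt_side`, and list columns `seq_left`, `seq_right` of orientations.
#' @export
make_trial_design <- function(n_trials_per_cell, n_items = 25, step = 20) {
  cells <- expand.grid(attended_side = c("left", "right"),
                       condition = c("RTT", "RDM"),
                       stringsAsFactors = FALSE)
  design <- cells[rep(seq_len(nrow(cells)), each = n_trials_per_cell), ]
  design <- design[sample(nrow(design)), , drop = FALSE]
  n <- nrow(design)
  design$trial_id <- seq_len(n)
  # attended stream type fixes which side carries the rotational stream
  design$rtt_side <- ifelse(design$condition == "RTT",
                            design$attended_side,
                            ifelse(design$attended_side == "left",
                                   "right", "left"))
  grid <- orientation_grid(step)
  seq_left <- vector("list", n)
  seq_right <- vector("list", n)
  for (i in seq_len(n)) {
    rtt <- make_rotational_sequence(sample(grid, 1), n_items, step)
    rdm <- make_random_sequence(n_items, step)
    if (design$rtt_side[i] == "left") {
      seq_left[[i]] <- rtt; seq_right[[i]] <- rdm
    } else {
      seq_left[[i]] <- rdm; seq_right[[i]] <- rtt
    }
  }
  design$seq_left <- seq_left
  design$seq_right <- seq_right
  rownames(design) <- NULL
  design
}
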