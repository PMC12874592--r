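#' Synthetic electrode layout with left/right mirror pairs
#'
#' Builds a schematic scalp montage: electrodes are placed on an
#' anterior-posterior grid, split into left/right mirror pairs plus a midline
#' column. The layout carries everything the analyses need from a montage:
#' 2-D positions, the mirror pairing used for lateralization flipping, a
#' posterior subset (where visual/SSVEP responses are injected and measured),
#' and a distance-based adjacency matrix for spatio-temporal clustering.
#'
#' @param n_electrodes total electrode count; even. 32 (default) gives 4
#'   midline + 14 mirror pairs; 128 gives 8 midline + 60 pairs, mirroring the
#'   scale of a BioSemi montage.
#' @return object of class `electrode_layout`: `n_electrodes`, `positions`
#'   (n x 2 matrix, x negative = left, y negative = posterior), `labels`,
#'   `mirror_pairs` (two-column matrix of left/right indices), `midline`
#'   (indices), `posterior` (indices), `adjacency` (symmetric logical matrix,
#'   zero diagonal).
#' @export
electrode_layout <- function(n_electrodes = 32) {
  stopifnot(n_electrodes >= 8, n_electrodes %% 2 == 0)
  n_mid <- if (n_electrodes >= 96) 8L else 4L
  n_pairs <- (n_electrodes - n_mid) / 2
  stopifnot(n_pairs == round(n_pairs))
  n_rows <- n_mid
  # distribute pairs over the anterior-posterior rows
  per_row <- rep(n_pairs %/% n_rows, n_rows)
  extra <- n_pairs %% n_rows
  if (extra > 0) per_row[seq_len(extra)] <- per_row[seq_len(extra)] + 1
  ys <- seq(1, -1, length.out = n_rows)
  pos <- matrix(0, n_electrodes, 2)
  labels <- character(n_electrodes)
  midline <- integer(n_mid)
  pairs <- matrix(0L, n_pairs, 2)
  colnames(pairs) <- c("left", "right")
  k <- 0L; p <- 0L
  for (r in seq_len(n_rows)) {
    k <- k + 1L
    pos[k, ] <- c(0, ys[r]); labels[k] <- sprintf("Mz%d", r); midline[r] <- k
    if (per_row[r] > 0) {
      xs <- seq(0.25, 1, length.out = per_row[r])
      for (j in seq_len(per_row[r])) {
        p <- p + 1L
        kl <- k + 1L; kr <- k + 2L
        pos[kl, ] <- c(-xs[j], ys[r]); labels[kl] <- sprintf("L%d_%d", r, j)
        pos[kr, ] <- c(xs[j], ys[r]);  labels[kr] <- sprintf("R%d_%d", r, j)
        pairs[p, ] <- c(kl, kr)
        k <- kr
      }
    }
  }
  posterior <- which(pos[, 2] <= -0.32)
  d <- as.matrix(stats::dist(pos))
  nn <- apply(d + diag(Inf, n_electrodes), 1, min)
  adj <- d <= 1.5 * stats::median(nn) & d > 0
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  structure(
    list(n_electrodes = n_electrodes, positions = pos, labels = labels,
         mirror_pairs = pairs, midline = midline, posterior = posterior,
         adjacency = adj),
    class = "electrode_layout"
  )
}

#' Swap mirror-paired electrode values to normalize laterality
#'
#' Remaps a per-electrode vector so that, after flipping, the right
#' hemisphere consistently represents the hemisphere contralateral to the
#' attended hemifield. Values of each left/right mirror pair are swapped;
#' midline electrodes are untouched. Flipping is applied when
#' `attended_side == flip_when`, i.e. by default maps are aligned to the
#' right-attended convention (flip left-attended maps). Applying the flip
#' twice is the identity.
#'
#' @param values numeric vector (one value per electrode) or matrix with
#'   electrodes in rows (e.g. electrode x time).
#' @param layout an [electrode_layout()].
#' @param attended_side "left" or "right" for this map.
#' @param flip_when side whose maps get flipped (default "left").
#' @return values with mirror pairs swapped when flipping applies.
#' @export
flip_lateralization <- function(values, layout, attended_side,
                                flip_when = "left") {
  vm <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  n <- layout$n_electrodes
  if (nrow(vm) != n) stop("values must have one row per electrode")
  covered <- sort(c(layout$midline, as.vector(layout$mirror_pairs)))
  if (!identical(covered, seq_len(n))) {
    stop("layout leaves electrodes without a mirror pair or midline tag")
  }
  if (identical(attended_side, flip_when)) {
    idx <- seq_len(n)
    idx[layout$mirror_pairs[, 1]] <- layout$mirror_pairs[, 2]
    idx[layout$mirror_pairs[, 2]] <- layout$mirror_pairs[, 1]
    vm <- vm[idx, , drop = FALSE]
  }
  if (is.matrix(values)) vm else as.vector(vm)
}
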