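#' Residue-motion correlations and correlation length
#'
#' Residue velocities are estimated from consecutive frames after removing
#' whole-molecule translation and rotation (all-atom RMSD superposition of
#' frame t+1 onto frame t); u_i = (x_i(t+1, aligned) - x_i(t)) / dt per
#' residue center. The spatial correlation C(r) is the mean normalized inner
#' product (cosine) of velocity pairs binned by their center distance at
#' frame t; the correlation length xi is the first zero crossing of C(r),
#' and curves plotted against x = r / xi collapse when the behavioral
#' correlation is scale-free.
#'
#' @name motion-correlation
NULL

frame_xyz <- function(frame) as.matrix(frame[, c("x", "y", "z")])

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` over all atoms,
#' with a proper rotation enforced (no reflection, det = +1).
#'
#' @param mobile,reference single-frame trajectory subsets with identical
#'   atom structure.
#' @return list(rotation 3x3, translation length-3, aligned frame tibble,
#'   rmsd in nm). Aligned coordinates are `rotation %*% x + translation`.
#' @export
kabsch_align <- function(mobile, reference) {
  if (nrow(mobile) != nrow(reference) ||
      !identical(mobile$residue, reference$residue)) {
    abort("mobile and reference must share an identical atom structure")
  }
  P <- frame_xyz(mobile); Q <- frame_xyz(reference)
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- cq - as.vector(R %*% cp)
  aligned_xyz <- t(R %*% t(P)) + matrix(tr, nrow(P), 3, byrow = TRUE)
  aligned <- mobile
  aligned$x <- aligned_xyz[, 1]; aligned$y <- aligned_xyz[, 2]
  aligned$z <- aligned_xyz[, 3]
  list(
    rotation = R, translation = tr, aligned = aligned,
    rmsd = sqrt(mean(rowSums((aligned_xyz - Q)^2)))
  )
}

#' Residue velocity field between frames t and t+1
#'
#' @param traj trajectory tibble with >= 2 frames.
#' @param t earlier frame index (1-based; velocities use frames t, t+1).
#' @return tibble (residue, vx, vy, vz) in nm/ps, with attributes
#'   frame_index and dt.
#' @export
residue_velocities <- function(traj, t) {
  if (t < 1 || t > n_frames(traj) - 1) abort("frame index out of range")
  dt <- traj_dt(traj)
  f0 <- traj[traj$frame == t, ]
  f1 <- traj[traj$frame == t + 1L, ]
  ali <- kabsch_align(f1, f0)
  c0 <- residue_centers(f0)
  c1 <- residue_centers(ali$aligned)
  structure(
    tibble(
      residue = c0$residue,
      vx = (c1$x - c0$x) / dt,
      vy = (c1$y - c0$y) / dt,
      vz = (c1$z - c0$z) / dt
    ),
    class = c("velocity_field", class(tibble())), frame_index = t, dt = dt
  )
}

#' Distance-binned velocity correlation function C(r)
#'
#' For every consecutive frame pair and every residue pair i < j the
#' normalized correlation cos(theta_ij) = u_i . u_j / (|u_i||u_j|) is
#' accumulated in the bin of the pair's center distance r_ij at the earlier
#' frame; C per bin is the mean over all frames and pairs. `normalize =
#' "frame"` (default) normalizes per pair per frame (cosine); `"global"`
#' divides raw inner products by the frame's mean squared speed instead
#' (normalization applied after averaging within the frame).
#'
#' @param traj trajectory tibble with >= 2 frames.
#' @param bin_width distance bin width in nm (default 0.1).
#' @param normalize "frame" or "global".
#' @return `correlation_curve` tibble (r, C, pairs) with attributes
#'   bin_width and n_skipped (zero-velocity pairs skipped).
#' @export
correlation_function <- function(traj, bin_width = 0.1, normalize = c("frame", "global")) {
  normalize <- match.arg(normalize)
  if (bin_width <= 0) abort("bin_width must be positive")
  if (n_frames(traj) < 2) abort("need at least 2 frames")
  acc_num <- numeric(0); acc_cnt <- integer(0)
  n_skipped <- 0L; any_motion <- FALSE
  for (t in seq_len(n_frames(traj) - 1L)) {
    vel <- residue_velocities(traj, t)
    V <- as.matrix(vel[, c("vx", "vy", "vz")])
    sp2 <- rowSums(V^2)
    if (all(sp2 < 1e-24)) { n_skipped <- n_skipped + choose(nrow(V), 2); next }
    any_motion <- TRUE
    ctr <- residue_centers(traj[traj$frame == t, ])
    D <- as.matrix(stats::dist(as.matrix(ctr[, c("x", "y", "z")])))
    G <- V %*% t(V)                       # u_i . u_j
    iu <- which(upper.tri(D), arr.ind = TRUE)
    dots <- G[iu]; rij <- D[iu]
    if (normalize == "frame") {
      norms <- sqrt(sp2[iu[, 1]] * sp2[iu[, 2]])
      ok <- norms > 1e-24
      n_skipped <- n_skipped + sum(!ok)
      cij <- dots[ok] / norms[ok]; rij <- rij[ok]
    } else {
      cij <- dots / mean(sp2)
    }
    if (length(rij) == 0) next
    b <- floor(rij / bin_width) + 1L
    nb <- max(b)
    if (nb > length(acc_num)) {
      acc_num <- c(acc_num, numeric(nb - length(acc_num)))
      acc_cnt <- c(acc_cnt, integer(nb - length(acc_cnt)))
    }
    acc_num[seq_len(nb)] <- acc_num[seq_len(nb)] +
      as.vector(tapply(cij, factor(b, levels = seq_len(nb)), sum, default = 0))
    acc_cnt[seq_len(nb)] <- acc_cnt[seq_len(nb)] +
      as.vector(tapply(rep(1L, length(b)), factor(b, levels = seq_len(nb)), sum,
                       default = 0L))
  }
  if (!any_motion) {
    abort("all velocity fields are zero; frames may be too close -- use a larger dt")
  }
  keep <- acc_cnt > 0
  structure(
    tibble(
      r = (which(keep) - 0.5) * bin_width,
      C = acc_num[keep] / acc_cnt[keep],
      pairs = acc_cnt[keep]
    ),
    class = c("correlation_curve", class(tibble())),
    bin_width = bin_width, n_skipped = n_skipped
  )
}

#' Correlation length: first zero crossing of C(r)
#'
#' Linear interpolation between the last positive bin and the first
#' non-positive bin of the first sign change. When the curve never crosses
#' zero, returns NA with attribute `no_crossing = TRUE` rather than erroring
#' (short or fully coherent systems legitimately lack a crossing).
#'
#' @param curve `correlation_curve` tibble.
#' @return xi in nm, or NA (attr no_crossing) when there is no crossing.
#' @export
correlation_length <- function(curve) {
  C <- curve$C; r <- curve$r
  idx <- which(C[-length(C)] > 0 & C[-1] <= 0)
  if (length(idx) == 0) {
    return(structure(NA_real_, no_crossing = TRUE))
  }
  i <- idx[1]
  r[i] + (r[i + 1] - r[i]) * C[i] / (C[i] - C[i + 1])
}

#' Rescale a correlation curve to x = r / xi
#'
#' @param curve `correlation_curve` tibble.
#' @param xi correlation length (computed from the curve when missing).
#' @return tibble (x, C, pairs); the rescaled curve crosses zero at x = 1.
#' @export
rescale_curve <- function(curve, xi = NULL) {
  if (is.null(xi)) xi <- correlation_length(curve)
  if (is.na(xi)) abort("no correlation length available (curve has no zero crossing)")
  out <- tibble(x = curve$r / xi, C = curve$C, pairs = curve$pairs)
  structure(out, class = c("correlation_curve_rescaled", class(tibble())), xi = xi)
}
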