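# fixtures built in code: bead frames, multi-frame trajectories, rigid motions

make_beads <- function(coords, dt = 100) {
  coords <- matrix(as.double(coords), ncol = 3)
  as_trajectory(tibble::tibble(
    frame = 1L, residue = seq_len(nrow(coords)), atom = seq_len(nrow(coords)),
    x = coords[, 1], y = coords[, 2], z = coords[, 3], mass = 1
  ), dt = dt)
}

make_traj <- function(frames, dt = 100, masses = NULL) {
  n <- nrow(frames[[1]])
  if (is.null(masses)) masses <- rep(1, n)
  df <- dplyr::bind_rows(lapply(seq_along(frames), function(t) {
    m <- matrix(as.double(frames[[t]]), ncol = 3)
    tibble::tibble(frame = t, residue = seq_len(n), atom = seq_len(n),
                   x = m[, 1], y = m[, 2], z = m[, 3], mass = masses)
  }))
  as_trajectory(df, dt = dt)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, determinant fixed to +1
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(traj, R, tvec) {
  xyz <- as.matrix(traj[, c("x", "y", "z")])
  new <- t(R %*% t(xyz)) + matrix(tvec, nrow(xyz), 3, byrow = TRUE)
  out <- traj
  out$x <- new[, 1]; out$y <- new[, 2]; out$z <- new[, 3]
  out
}
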