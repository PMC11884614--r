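test_that("Kabsch alignment inverts rigid motions exactly", {
  set.seed(1)
  ref <- make_beads(matrix(rnorm(30), ncol = 3))
  # rotate 90 degrees about z and shift
  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  mob <- apply_rigid(ref, Rz, c(1, 2, 3))
  out <- kabsch_align(mob, ref)
  expect_lt(out$rmsd, 1e-10)
  expect_lt(max(abs(out$rotation %*% Rz - diag(3))), 1e-10)

  idty <- kabsch_align(ref, ref)
  expect_lt(idty$rmsd, 1e-12)
  expect_lt(max(abs(idty$rotation - diag(3))), 1e-10)
  expect_error(kabsch_align(ref, make_beads(matrix(rnorm(12), ncol = 3))),
               "identical atom structure")
})

test_that("Kabsch transforms are proper rotations and beat random search", {
  set.seed(2)
  A <- make_beads(matrix(rnorm(90), ncol = 3))
  B <- make_beads(matrix(rnorm(90), ncol = 3))
  out <- kabsch_align(A, B)
  expect_lt(max(abs(crossprod(out$rotation) - diag(3))), 1e-10)
  expect_equal(det(out$rotation), 1, tolerance = 1e-10)

  # no random rigid transform does better than the optimum
  P <- as.matrix(A[, c("x", "y", "z")]); Q <- as.matrix(B[, c("x", "y", "z")])
  cq <- colMeans(Q)
  best <- min(vapply(1:20000, function(i) {
    R <- random_rotation()
    moved <- t(R %*% t(P))
    moved <- sweep(moved, 2, colMeans(moved) - cq)   # optimal translation given R
    sqrt(mean(rowSums((moved - Q)^2)))
  }, 1))
  expect_lte(out$rmsd, best + 1e-12)

  # independent cross-check against bio3d's superposition
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(Q)), mobile = as.vector(t(P))))
  rmsd_bio3d <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - Q)^2)))
  expect_equal(out$rmsd, rmsd_bio3d, tolerance = 1e-6)
})

test_that("velocity fields vanish for pure translations and rotations", {
  set.seed(3)
  f1 <- matrix(rnorm(60), ncol = 3)
  traj_t <- make_traj(list(f1, sweep(f1, 2, c(0.5, -0.2, 0.1), `+`)), dt = 100)
  v <- residue_velocities(traj_t, 1)
  expect_lt(max(abs(as.matrix(v[, c("vx", "vy", "vz")]))), 1e-10)

  R <- random_rotation()
  traj_r <- make_traj(list(f1, t(R %*% t(f1))), dt = 100)
  v <- residue_velocities(traj_r, 1)
  expect_lt(max(abs(as.matrix(v[, c("vx", "vy", "vz")]))), 1e-9)
  expect_error(residue_velocities(traj_t, 2), "out of range")
})

test_that("a single shifted residue produces the hand-computed velocity", {
  set.seed(4)
  f1 <- matrix(rnorm(30), ncol = 3)
  f2 <- f1; f2[3, ] <- f2[3, ] + c(0.1, 0, 0)
  traj <- make_traj(list(f1, f2), dt = 100)
  v <- residue_velocities(traj, 1)

  # independent two-step computation: bio3d alignment, then finite difference
  fitted <- matrix(suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(f1)),
                                  mobile = as.vector(t(f2)))), ncol = 3, byrow = TRUE)
  vref <- (fitted - f1) / 100
  expect_lt(max(abs(as.matrix(v[, c("vx", "vy", "vz")]) - vref)), 1e-9)
  # residue 3 dominates and moves along +x at ~1e-3 nm/ps
  expect_equal(v$vx[3], 1e-3, tolerance = 0.15)
})

test_that("correlation function separates coherent and anti-coherent motion", {
  hinge <- hinge_motion_pair(n_block = 15, separation = 3, displacement = 0.2,
                             block_radius = 0.6, seed = 5)
  curve <- correlation_function(hinge, bin_width = 0.2)
  expect_true(all(curve$C >= -1 - 1e-12 & curve$C <= 1 + 1e-12))
  # intra-block distances (< 1.2 nm): parallel; inter-block (> 1.8): antiparallel
  expect_true(all(curve$C[curve$r < 1.2] > 0.99))
  expect_true(all(curve$C[curve$r > 1.9] < -0.99))

  # direct double-loop oracle over the velocity field
  v <- residue_velocities(hinge, 1)
  V <- as.matrix(v[, c("vx", "vy", "vz")])
  ctr <- residue_centers(hinge[hinge$frame == 1, ])
  P <- as.matrix(ctr[, c("x", "y", "z")])
  n <- nrow(V)
  acc <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((P[i, ] - P[j, ])^2))
    cc <- sum(V[i, ] * V[j, ]) / sqrt(sum(V[i, ]^2) * sum(V[j, ]^2))
    b <- floor(r / 0.2) + 1
    acc[[length(acc) + 1]] <- c(b, cc)
  }
  m <- do.call(rbind, acc)
  or <- tapply(m[, 2], m[, 1], mean)
  mine <- setNames(curve$C, floor(curve$r / 0.2) + 1)
  expect_equal(as.numeric(mine[names(or)]), as.numeric(or), tolerance = 1e-10)
})

test_that("correlation curve is invariant to velocity scaling and rigid motion", {
  # halving dt doubles every velocity while leaving geometry untouched;
  # the cosine normalization must cancel the magnitudes exactly
  hinge <- hinge_motion_pair(displacement = 0.1, seed = 6, dt = 100)
  hinge_fast <- as_trajectory(hinge, dt = 50)
  c1 <- correlation_function(hinge)
  c2 <- correlation_function(hinge_fast)
  expect_equal(c1$C, c2$C, tolerance = 1e-12)
  hinge_small <- hinge

  set.seed(7)
  moved <- apply_rigid(hinge_small, random_rotation(), c(5, 5, 5))
  moved <- as_trajectory(moved, dt = 100)
  c3 <- correlation_function(moved)
  expect_equal(c1$C, c3$C, tolerance = 1e-7)
})

test_that("correlation length interpolates the first zero crossing", {
  mk_curve <- function(r, C) structure(
    tibble::tibble(r = r, C = C, pairs = rep(10L, length(r))),
    class = c("correlation_curve", class(tibble::tibble())))
  expect_equal(correlation_length(mk_curve(c(1, 2), c(0.5, -0.5))), 1.5)

  allpos <- mk_curve(1:5, rep(0.3, 5))
  xi <- correlation_length(allpos)
  expect_true(is.na(xi))
  expect_true(attr(xi, "no_crossing"))

  # planted root at r = 2.37 sampled on 0.1-nm bins
  r <- seq(0.05, 4, by = 0.1)
  C <- 0.4 * (2.37 - r) / 2.37
  xi <- correlation_length(mk_curve(r, C))
  expect_lt(abs(xi - 2.37), 0.05)

  # hinge fixture: crossing sits between block radius and separation
  hinge <- hinge_motion_pair(n_block = 15, separation = 3, displacement = 0.2,
                             block_radius = 0.6, seed = 8)
  xi <- correlation_length(correlation_function(hinge, bin_width = 0.2))
  expect_gt(xi, 0.6)
  expect_lt(xi, 3)
})

test_that("rescaled curves cross zero at x = 1 and similar systems collapse", {
  hinge <- hinge_motion_pair(n_block = 15, seed = 9)
  curve <- correlation_function(hinge, bin_width = 0.2)
  resc <- rescale_curve(curve)
  xi <- attr(resc, "xi")
  expect_equal(resc$x, curve$r / xi)
  # interpolated zero crossing of the rescaled curve sits at x = 1
  i <- which(resc$C[-nrow(resc)] > 0 & resc$C[-1] <= 0)[1]
  x0 <- resc$x[i] + (resc$x[i + 1] - resc$x[i]) * resc$C[i] / (resc$C[i] - resc$C[i + 1])
  expect_equal(x0, 1, tolerance = 1e-9)

  # geometrically similar system at twice the scale gives the same C(x)
  big <- hinge_motion_pair(n_block = 15, separation = 6, displacement = 0.4,
                           block_radius = 1.2, seed = 9)
  r1 <- rescale_curve(correlation_function(hinge, bin_width = 0.2))
  r2 <- rescale_curve(correlation_function(big, bin_width = 0.4))
  # interpolate onto a common grid of x
  grid <- seq(max(min(r1$x), min(r2$x)), min(max(r1$x), max(r2$x)), length.out = 20)
  a <- approx(r1$x, r1$C, grid)$y
  b <- approx(r2$x, r2$C, grid)$y
  expect_lt(mean((a - b)^2), 0.01)

  allpos <- structure(tibble::tibble(r = 1:5, C = rep(1, 5), pairs = rep(1L, 5)),
                      class = c("correlation_curve", class(tibble::tibble())))
  expect_error(rescale_curve(allpos), "no zero crossing|no correlation length")
})
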