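#' Synthetic inputs for validating the pipeline at desk scale
#'
#' Generators for every input the analysis stages consume: HP heteropolymer
#' Langevin trajectories (the coarse-grained control system), colored noise
#' with a prescribed spectral exponent, conformations with planted compact
#' residue clusters, power-law size samples, ideal Gaussian chains and
#' two-block hinge motions. All generators are reproducible under
#' (seed, parameters).
#'
#' @name synthetic-data
NULL

#' Random HP sequences
#'
#' Two-letter heteropolymer sequences with a fixed hydrophobic fraction;
#' the hydrophobic count is floor(frac_H * L) (36 H beads at the default
#' L = 73, frac_H = 0.5), positions uniformly random.
#'
#' @param L chain length (>= 2).
#' @param frac_H hydrophobic fraction in \[0, 1\] (default 0.5).
#' @param n number of independent sequences (default 100).
#' @param seed RNG seed.
#' @return list of character vectors over c("H", "P").
#' @export
generate_hp_sequences <- function(L = 73L, frac_H = 0.5, n = 100L, seed = 1L) {
  if (L < 2) abort("L must be >= 2")
  if (frac_H < 0 || frac_H > 1) abort("frac_H must lie in [0, 1]")
  nH <- floor(frac_H * L)
  withr::with_seed(seed, {
    lapply(seq_len(n), function(k) {
      s <- rep("P", L)
      s[sample.int(L, nH)] <- "H"
      s
    })
  })
}

#' HP model parameters
#'
#' Reduced units: bead mass 1, k_B = 1, energies in units of the LJ epsilon,
#' lengths in nm, `temperature` is k_B T in energy units. The attraction
#' scales lambda map sequence letters to pair interactions (lambda_pair is
#' the mean of the two beads' lambdas); lambda = 0 leaves a purely repulsive
#' core, lambda = 1 the full LJ attraction.
#'
#' @param bond_k spring constant, energy/nm^2.
#' @param bond_b equilibrium bond length, nm.
#' @param lj_sigma LJ diameter, nm.
#' @param lj_epsilon LJ well depth (energy unit).
#' @param lambda_H,lambda_P attraction scales in \[0, 1\].
#' @param temperature k_B T in energy units.
#' @param friction Langevin friction, 1/ps-equivalent.
#' @param timestep integration step, ps-equivalent.
#' @return parameter list.
#' @export
hp_params <- function(bond_k = 150, bond_b = 0.38, lj_sigma = 0.5,
                      lj_epsilon = 0.8, lambda_H = 1, lambda_P = 0,
                      temperature = 1, friction = 1, timestep = 0.01) {
  p <- list(bond_k = bond_k, bond_b = bond_b, lj_sigma = lj_sigma,
            lj_epsilon = lj_epsilon, lambda_H = lambda_H, lambda_P = lambda_P,
            temperature = temperature, friction = friction, timestep = timestep)
  pos <- c("bond_k", "bond_b", "lj_sigma", "lj_epsilon", "friction", "timestep")
  if (any(unlist(p[pos]) <= 0)) abort("bond/LJ/friction/timestep parameters must be positive")
  if (p$temperature < 0) abort("temperature must be >= 0")
  if (any(c(p$lambda_H, p$lambda_P) < 0 | c(p$lambda_H, p$lambda_P) > 1)) {
    abort("lambda values must lie in [0, 1]")
  }
  p
}

#' Simulate an HP heteropolymer under Langevin dynamics
#'
#' BAOAB integration of the bead chain: harmonic bonds, Ashbaugh-Hatch
#' lambda-scaled LJ between non-bonded pairs (truncated at 3 sigma, shifted).
#' The initial conformation is a random walk at the bond length unless
#' supplied. `mode = "descent"` runs noiseless gradient descent instead
#' (energy-minimization sanity mode).
#'
#' @param seq character vector over c("H", "P").
#' @param params list from [hp_params()].
#' @param n_steps total integration steps (>= save_every).
#' @param save_every save a frame every this many steps.
#' @param seed RNG seed (thermal noise and initial conformation).
#' @param init optional L x 3 matrix of starting coordinates, nm. The default
#'   is a self-avoiding random walk at the bond length (candidate directions
#'   rejected while any non-bonded bead sits closer than 0.8 sigma), followed
#'   by `minimize_steps` of capped steepest descent inside the integrator.
#' @param mode "langevin" (default) or "descent" (noiseless capped gradient
#'   descent; energy-minimization sanity mode).
#' @param minimize_steps capped-descent pre-relaxation steps (default 500;
#'   0 to integrate from `init` exactly as given).
#' @return trajectory tibble; dt = timestep * save_every. The per-frame
#'   potential energy is attached as attribute `energy`.
#' @export
simulate_hp_polymer <- function(seq, params = hp_params(), n_steps, save_every = 1L,
                                seed = 1L, init = NULL, mode = c("langevin", "descent"),
                                minimize_steps = 500L) {
  mode <- match.arg(mode)
  if (!all(seq %in% c("H", "P"))) abort("sequence letters must be H or P")
  if (n_steps < save_every || save_every < 1) abort("need n_steps >= save_every >= 1")
  L <- length(seq)
  lambdas <- ifelse(seq == "H", params$lambda_H, params$lambda_P)
  if (is.null(init)) {
    init <- withr::with_seed(seed, {
      xyz <- matrix(0, L, 3)
      min2 <- (0.8 * params$lj_sigma)^2
      for (i in seq_len(L)[-1]) {
        for (try in 1:200) {
          d <- rnorm(3)
          cand <- xyz[i - 1, ] + d / sqrt(sum(d^2)) * params$bond_b
          if (i <= 2) break
          prev <- xyz[seq_len(i - 2), , drop = FALSE]
          if (min(rowSums(sweep(prev, 2, cand)^2)) > min2) break
        }
        xyz[i, ] <- cand
      }
      xyz
    })
  }
  init <- matrix(as.double(init), ncol = 3)
  res <- .hp_simulate_cpp(
    init, lambdas,
    params$bond_k, params$bond_b, params$lj_sigma, params$lj_epsilon,
    params$temperature, params$friction, params$timestep,
    as.integer(n_steps), as.integer(save_every), as.integer(seed),
    mode == "descent", as.integer(minimize_steps), 0.005
  )
  nf <- nrow(res$coords)
  df <- tibble(
    frame = rep(seq_len(nf), each = L),
    residue = rep(seq_len(L), nf),
    atom = rep(seq_len(L), nf),
    x = as.vector(t(res$coords[, 3 * (seq_len(L) - 1) + 1, drop = FALSE])),
    y = as.vector(t(res$coords[, 3 * (seq_len(L) - 1) + 2, drop = FALSE])),
    z = as.vector(t(res$coords[, 3 * (seq_len(L) - 1) + 3, drop = FALSE])),
    mass = 1
  )
  traj <- as_trajectory(df, dt = params$timestep * save_every)
  attr(traj, "energy") <- as.double(res$energy)
  attr(traj, "sequence") <- seq
  traj
}

#' Potential energy of an HP conformation
#'
#' @param xyz L x 3 coordinate matrix (nm).
#' @param seq character vector over c("H", "P").
#' @param params list from [hp_params()].
#' @return total potential energy (reduced units).
#' @export
hp_energy <- function(xyz, seq, params = hp_params()) {
  lambdas <- ifelse(seq == "H", params$lambda_H, params$lambda_P)
  .hp_energy_cpp(matrix(as.double(xyz), ncol = 3), lambdas,
                 params$bond_k, params$bond_b, params$lj_sigma, params$lj_epsilon)
}

#' Colored noise with prescribed spectral exponent
#'
#' Spectral synthesis: Fourier amplitudes proportional to f^(-beta/2) with
#' i.i.d. uniform phases and Hermitian symmetry, inverse-transformed and
#' normalized to zero mean, unit variance. beta = 0 gives white noise,
#' beta = 2 Brownian noise, beta = 1 the 1/f family in between.
#'
#' @param beta spectral exponent in \[0, 3\].
#' @param n length (>= 16).
#' @param dt sampling interval (default 1).
#' @param seed RNG seed.
#' @return `idp_series` tibble.
#' @export
colored_noise <- function(beta, n, dt = 1, seed = 1L) {
  if (beta < 0 || beta > 3) abort("beta must lie in [0, 3]")
  if (n < 16) abort("n must be >= 16")
  half <- floor(n / 2)
  x <- withr::with_seed(seed, {
    amp <- (seq_len(half))^(-beta / 2)
    phi <- runif(half, 0, 2 * pi)
    X <- complex(modulus = amp, argument = phi)
    if (n %% 2 == 0) X[half] <- complex(real = amp[half] * sign(cos(phi[half])))
    full <- complex(real = numeric(n))
    ks <- seq_len(half)
    full[ks + 1] <- X
    conj_ks <- if (n %% 2 == 0) ks[-half] else ks   # Nyquist is self-conjugate
    full[n - conj_ks + 1] <- Conj(X[conj_ks])
    Re(fft(full, inverse = TRUE)) / n
  })
  x <- x - mean(x)
  x <- x / sd(x)
  time_series(x, dt = dt)
}

#' Conformation with planted compact residue clusters
#'
#' Ground truth for domain detection: every cluster's residues are placed
#' inside a ball of radius `intra_scale` (all pairwise distances below the
#' default contact cutoff, so the cluster is a contact clique whose 2-core
#' is the full cluster once its size is at least 5); the remaining residues
#' sit on an extended arc with all pairwise and arc-to-cluster distances
#' above the cutoff. The construction is validated before returning.
#'
#' @param N number of residues.
#' @param clusters list of disjoint residue-index vectors (1-based).
#' @param cluster_spacing distance between cluster centers, nm (> 0.7).
#' @param intra_scale cluster ball radius, nm (default 0.15; twice this must
#'   stay below the 0.35 nm contact cutoff).
#' @param cutoff contact cutoff used for validation, nm.
#' @param seed RNG seed.
#' @return single-frame trajectory tibble (one bead per residue).
#' @export
planted_domain_frame <- function(N, clusters = list(), cluster_spacing = 2,
                                 intra_scale = 0.15, cutoff = 0.35, seed = 1L) {
  idx <- unlist(clusters)
  if (anyDuplicated(idx)) abort("clusters must be disjoint")
  if (length(idx) > 0 && (min(idx) < 1 || max(idx) > N)) abort("cluster indices out of range")
  if (cluster_spacing <= 2 * cutoff) abort("cluster_spacing must exceed twice the cutoff")
  if (2 * intra_scale >= cutoff) {
    abort("infeasible spec: intra_scale too large for the contact cutoff")
  }
  coords <- matrix(NA_real_, N, 3)
  withr::with_seed(seed, {
    for (k in seq_along(clusters)) {
      members <- clusters[[k]]
      center <- c(k * cluster_spacing, 0, 0)
      # rejection-sample uniform points in the ball
      pts <- matrix(rnorm(3 * length(members) * 20), ncol = 3)
      pts <- pts / sqrt(rowSums(pts^2)) *
        (runif(nrow(pts))^(1 / 3) * intra_scale)
      coords[members, ] <- sweep(pts[seq_along(members), , drop = FALSE], 2,
                                 center, `+`)
    }
  })
  free <- setdiff(seq_len(N), idx)
  if (length(free) > 0) {
    coords[free, ] <- cbind(seq_along(free) * 2 * cutoff, 10, 0)
  }
  # internal validation: cluster cliques tight, everything else separated
  for (k in seq_along(clusters)) {
    members <- clusters[[k]]
    if (length(members) > 1) {
      dd <- stats::dist(coords[members, , drop = FALSE])
      if (max(dd) >= cutoff) abort("construction failed: cluster not a contact clique")
    }
    others <- setdiff(seq_len(N), members)
    if (length(others) > 0) {
      cross <- min(as.matrix(stats::dist(coords))[members, others])
      if (cross <= cutoff) abort("construction failed: cluster not isolated")
    }
  }
  if (length(free) > 1) {
    if (min(stats::dist(coords[free, , drop = FALSE])) <= cutoff) {
      abort("construction failed: arc residues too close")
    }
  }
  as_trajectory(tibble(
    frame = 1L, residue = seq_len(N), atom = seq_len(N),
    x = coords[, 1], y = coords[, 2], z = coords[, 3], mass = 1
  ), dt = 100)
}

#' Power-law distributed integer sizes
#'
#' i.i.d. draws from the discrete distribution proportional to s^-tau on
#' \[s_min, s_max\] via inverse-CDF sampling.
#'
#' @param tau exponent.
#' @param s_min,s_max integer truncation bounds.
#' @param n number of draws.
#' @param seed RNG seed.
#' @return integer vector.
#' @export
power_law_sizes <- function(tau, s_min, s_max, n, seed = 1L) {
  if (s_min > s_max) abort("s_min must be <= s_max")
  supp <- s_min:s_max
  w <- supp^(-tau)
  cdf <- cumsum(w) / sum(w)
  withr::with_seed(seed, {
    u <- runif(n)
    supp[findInterval(u, cdf) + 1L]
  })
}

#' Ideal Gaussian chain conformations
#'
#' Successive bead displacements i.i.d. isotropic Gaussian with RMS length
#' b; the random-walk null whose domains have fractal dimension near 2 and
#' whose mean squared end-to-end distance is (N-1) b^2.
#'
#' @param N beads per chain (>= 2).
#' @param b RMS bond length, nm.
#' @param seed RNG seed.
#' @param n_frames number of independent chains, returned as frames.
#' @return trajectory tibble (one bead per residue).
#' @export
gaussian_chain <- function(N, b = 0.38, seed = 1L, n_frames = 1L) {
  if (N < 2) abort("N must be >= 2")
  coords <- withr::with_seed(seed, {
    steps <- matrix(rnorm(3 * (N - 1) * n_frames, sd = b / sqrt(3)), ncol = 3)
    do.call(rbind, lapply(seq_len(n_frames), function(k) {
      s <- steps[((k - 1) * (N - 1) + 1):(k * (N - 1)), , drop = FALSE]
      apply(rbind(0, s), 2, cumsum)
    }))
  })
  as_trajectory(tibble(
    frame = rep(seq_len(n_frames), each = N),
    residue = rep(seq_len(N), n_frames),
    atom = rep(seq_len(N), n_frames),
    x = coords[, 1], y = coords[, 2], z = coords[, 3], mass = 1
  ), dt = 100)
}

#' Two-block hinge-motion frame pair
#'
#' Two compact blocks of beads; in the second frame the blocks counter-
#' translate along +-x by displacement/2 each, so net translation is zero
#' and rigid-body alignment is neutral. Intra-block velocity pairs are
#' parallel (C = +1), inter-block pairs antiparallel (C = -1), giving a
#' ground-truth sign structure and a zero crossing between the block radius
#' and the block separation.
#'
#' @param n_block beads per block.
#' @param separation block-center distance, nm.
#' @param displacement relative displacement between the frames, nm.
#' @param block_radius radius of each block's bead cloud, nm.
#' @param seed RNG seed.
#' @param dt frame interval, ps.
#' @return two-frame trajectory tibble.
#' @export
hinge_motion_pair <- function(n_block = 20L, separation = 3, displacement = 0.2,
                              block_radius = 0.6, seed = 1L, dt = 100) {
  pts <- withr::with_seed(seed, {
    p <- matrix(rnorm(3 * 2 * n_block), ncol = 3)
    p / sqrt(rowSums(p^2)) * (runif(2 * n_block)^(1 / 3) * block_radius)
  })
  a <- sweep(pts[seq_len(n_block), ], 2, c(-separation / 2, 0, 0), `+`)
  b <- sweep(pts[n_block + seq_len(n_block), ], 2, c(separation / 2, 0, 0), `+`)
  f1 <- rbind(a, b)
  shift <- c(displacement / 2, 0, 0)
  f2 <- rbind(sweep(a, 2, shift, `+`), sweep(b, 2, shift, `-`))
  n <- 2L * n_block
  as_trajectory(tibble(
    frame = rep(1:2, each = n),
    residue = rep(seq_len(n), 2),
    atom = rep(seq_len(n), 2),
    x = c(f1[, 1], f2[, 1]), y = c(f1[, 2], f2[, 2]), z = c(f1[, 3], f2[, 3]),
    mass = 1
  ), dt = dt)
}
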