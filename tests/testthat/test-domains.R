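test_that("contact definition: cutoff is strict, neighbors excluded, oracle agrees", {
  # beads on a line 1 nm apart: no contacts at 0.35 nm
  line <- make_beads(cbind(0:5, 0, 0))
  g <- contact_graph(line, cutoff = 0.35)
  expect_equal(nrow(g$edges), 0)

  # residues 1 and 3 at 0.30 nm -> edge; residues 1 and 2 at 0.30 nm -> excluded
  tight <- make_beads(rbind(c(0, 0, 0), c(0.3, 1, 0), c(0.3, 0, 0)))
  g <- contact_graph(tight, cutoff = 0.35)
  expect_equal(as.data.frame(g$edges), data.frame(i = 1, j = 3))

  # random multi-atom frames vs the double-loop oracle
  set.seed(21)
  for (rep in 1:3) {
    df <- tibble::tibble(
      frame = 1L,
      residue = rep(1:20, each = 3),
      atom = 1:60,
      x = rnorm(60, sd = 0.5), y = rnorm(60, sd = 0.5), z = rnorm(60, sd = 0.5),
      mass = 1
    )
    fr <- as_trajectory(df, dt = 1)
    g <- contact_graph(fr, cutoff = 0.35)
    or <- oracle_contacts(fr, cutoff = 0.35)
    expect_equal(as.data.frame(g$edges), as.data.frame(or))
  }
})

test_that("edge set grows monotonically with the cutoff", {
  fr <- gaussian_chain(40, b = 0.38, seed = 31)
  e_small <- contact_graph(fr, cutoff = 0.3)$edges
  e_big <- contact_graph(fr, cutoff = 0.6)$edges
  key <- function(e) paste(e$i, e$j)
  expect_true(all(key(e_small) %in% key(e_big)))
  expect_gt(nrow(e_big), nrow(e_small))
})

test_that("2-core: triangle fixed point, path peels empty, oracle and igraph agree", {
  tri <- structure(list(n_residues = 5,
                        edges = tibble::tibble(i = c(1, 1, 3), j = c(3, 5, 5))),
                   class = "contact_graph")
  expect_equal(nrow(k_core(tri, 2)$edges), 3)

  path <- structure(list(n_residues = 7,
                         edges = tibble::tibble(i = c(1, 3, 5), j = c(3, 5, 7))),
                    class = "contact_graph")
  expect_equal(nrow(k_core(path, 2)$edges), 0)
  expect_error(k_core(tri, 0), "k must be")

  # 200 random graphs vs brute-force peeling (several removal orders) and igraph
  set.seed(8)
  for (rep in 1:200) {
    n <- sample(5:25, 1)
    p <- sample(c(0.1, 0.2, 0.3), 1)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < p
    edges <- tibble::tibble(i = pairs[keep, 1], j = pairs[keep, 2])
    g <- structure(list(n_residues = n, edges = edges), class = "contact_graph")
    core <- k_core(g, 2)
    mine <- sort(unique(c(core$edges$i, core$edges$j)))
    expect_equal(mine, oracle_kcore_nodes(edges, 2))
    if (rep <= 20) {
      for (os in 1:3) expect_equal(mine, oracle_kcore_nodes(edges, 2, order_seed = os))
      if (nrow(edges) > 0) {
        ig <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                            vertices = data.frame(name = 1:n))
        ig_core <- sort(as.integer(igraph::V(ig)$name[igraph::coreness(ig) >= 2]))
        expect_equal(mine, ig_core)
      }
    }
  }
})

test_that("planted compact clusters are recovered exactly; small plants vanish", {
  fr <- planted_domain_frame(30, clusters = list(11:18), seed = 2)
  dec <- decompose_domains(fr)
  expect_equal(sort(dec$residue), 11:18)
  expect_equal(length(unique(dec$domain_id)), 1)

  # two clusters of sizes 6 and 9
  fr2 <- planted_domain_frame(40, clusters = list(3:8, 21:29), seed = 3)
  dec2 <- decompose_domains(fr2)
  sizes <- sort(domain_sizes(dec2))
  expect_equal(sizes, c(6, 9))

  # a fully extended chain has no domains
  ext <- make_beads(cbind(seq(0, 20, by = 0.5), 0, 0))
  expect_equal(nrow(decompose_domains(ext)), 0)

  # 4-residue plant: below the size-exceeding-4 threshold
  fr4 <- planted_domain_frame(30, clusters = list(10:13), seed = 4)
  expect_equal(nrow(decompose_domains(fr4)), 0)
})

test_that("decomposition is invariant under rigid-body motion and domains are valid", {
  fr <- planted_domain_frame(35, clusters = list(5:12, 20:26), seed = 5)
  dec <- decompose_domains(fr)
  set.seed(9)
  moved <- apply_rigid(fr, random_rotation(), c(10, -4, 2))
  dec2 <- decompose_domains(moved)
  expect_equal(as.data.frame(dec), as.data.frame(dec2))

  # every domain member keeps >= 2 within-domain contacts; domains disjoint
  g <- contact_graph(fr)
  for (d in split(dec$residue, dec$domain_id)) {
    sub <- g$edges[g$edges$i %in% d & g$edges$j %in% d, ]
    deg <- table(c(sub$i, sub$j))
    expect_true(all(deg >= 2))
  }
  expect_false(anyDuplicated(dec$residue) > 0)
})

test_that("size distributions pool additively and refuse degenerate fits", {
  sizes1 <- c(rep(10, 30))
  d <- size_distribution(sizes1, N = 100)
  expect_true(is.na(d$tau_hat))
  expect_match(d$fit_refused, "degenerate")

  few <- size_distribution(c(5, 6, 7), N = 100)
  expect_match(few$fit_refused, "fewer than 20")

  fr2 <- planted_domain_frame(40, clusters = list(3:8, 21:29), seed = 3)
  dec <- decompose_domains(fr2)
  merged <- size_distribution(list(dec, dec), N = 40)
  single <- size_distribution(dec, N = 40)
  expect_equal(merged$table$count, 2 * single$table$count)
})

test_that("tau is recovered from truncated power-law samples (LS and MLE)", {
  sizes <- power_law_sizes(1.15, 5, 200, 10000, seed = 17)
  d <- size_distribution(sizes, N = 200, fit_range = c(5, 60))
  expect_gt(d$tau_hat, 1.0)
  expect_lt(d$tau_hat, 1.3)
  mle <- fit_tau_mle(sizes, 5, 200)
  expect_lt(abs(mle$tau - 1.15), 0.05)
})

test_that("scaling collapse scores identical curves at zero and prefers true tau", {
  sizes <- power_law_sizes(1.15, 5, 128, 4000, seed = 23)
  d <- size_distribution(sizes, N = 128)
  col <- scaling_collapse(list(d, d), tau = 1.15)
  expect_equal(col$collapse_score, 0)
  expect_error(scaling_collapse(list(d), tau = 1.15), "at least 2")

  wins <- 0
  for (s in 1:8) {
    ds <- lapply(c(64, 128, 256), function(N) {
      size_distribution(power_law_sizes(1.15, 5, N, 4000, seed = s * 1000 + N), N = N)
    })
    sc_true <- scaling_collapse(ds, 1.15)$collapse_score
    sc_lo <- scaling_collapse(ds, 0.65)$collapse_score
    sc_hi <- scaling_collapse(ds, 1.65)$collapse_score
    if (sc_true < sc_lo && sc_true < sc_hi) wins <- wins + 1
  }
  expect_gte(wins, 7)
})

test_that("fractal dimension hits the rod, random-walk and compact limits", {
  # rods: collinear equally spaced beads
  rods <- dplyr::bind_rows(lapply(c(8, 12, 16, 24, 32, 48, 64), function(s) {
    tibble::tibble(size = s, rg = radius_of_gyration(cbind(seq_len(s) * 0.38, 0, 0)))
  }))
  rods <- dplyr::bind_rows(rods, rods, rods)   # replicate to pass the n >= 10 gate
  fit <- fractal_dimension(rods)
  expect_lt(abs(fit$d_f - 1), 0.02)

  # Gaussian-chain segments: d_f near 2
  set.seed(3)
  gauss <- dplyr::bind_rows(lapply(rep(c(8, 16, 32, 64, 128), 8), function(s) {
    ch <- gaussian_chain(s, b = 0.38, seed = sample.int(1e6, 1))
    tibble::tibble(size = s, rg = radius_of_gyration(as.matrix(ch[, c("x", "y", "z")])))
  }))
  fit <- fractal_dimension(gauss)
  expect_gt(fit$d_f, 1.8)
  expect_lt(fit$d_f, 2.2)

  # uniform balls with radius ~ s^(1/3): d_f near 3
  set.seed(4)
  balls <- dplyr::bind_rows(lapply(rep(c(8, 16, 32, 64, 128), 6), function(s) {
    p <- matrix(rnorm(3 * s), ncol = 3)
    p <- p / sqrt(rowSums(p^2)) * runif(s)^(1 / 3) * s^(1 / 3)
    tibble::tibble(size = s, rg = radius_of_gyration(p))
  }))
  fit <- fractal_dimension(balls)
  expect_lt(abs(fit$d_f - 3), 0.3)

  expect_error(fractal_dimension(rods[1:5, ]), "fewer than 10")
  same <- tibble::tibble(size = rep(10, 12), rg = runif(12, 0.9, 1.1))
  expect_error(fractal_dimension(same), "half a decade")
})

test_that("fractal dimension from decomposition + frames matches the manual route", {
  # fabricate a rod frame and mark segments of growing size as domains;
  # the decomposition table is plain data, so ground truth is constructible
  sizes <- c(8, 12, 18, 27, 40, 60, 8, 12, 18, 27, 40, 60)
  N <- sum(sizes)
  fr <- make_beads(cbind(seq_len(N) * 0.38, 0, 0))
  ends <- cumsum(sizes); starts <- ends - sizes + 1
  dec <- structure(
    tibble::tibble(
      frame = 1L,
      domain_id = rep(seq_along(sizes), sizes),
      residue = unlist(Map(seq, starts, ends))
    ),
    class = c("domain_decomposition", class(tibble::tibble())),
    n_residues = N, n_frames = 1L
  )
  fit <- fractal_dimension(dec, fr)
  expect_equal(fit$n_domains, length(sizes))
  expect_lt(abs(fit$d_f - 1), 0.02)   # rod segments: d_f = 1

  # agrees with the explicit (size, rg) route
  ctr <- residue_centers(fr)
  manual <- tibble::tibble(
    size = sizes,
    rg = vapply(Map(seq, starts, ends), function(d) {
      radius_of_gyration(as.matrix(ctr[ctr$residue %in% d, c("x", "y", "z")]))
    }, 1)
  )
  fit2 <- fractal_dimension(manual)
  expect_equal(fit$d_f, fit2$d_f, tolerance = 1e-12)
})

test_that("involvement profile counts dominant-domain membership over all frames", {
  # residues 6..15 form the unique domain in 60 of 100 frames
  dec <- structure(
    tibble::tibble(
      frame = rep(1:60, each = 10),
      domain_id = 1L,
      residue = rep(6:15, 60)
    ),
    class = c("domain_decomposition", class(tibble::tibble())),
    n_residues = 30L, n_frames = 100L
  )
  prof <- involvement_profile(dec)
  expect_equal(prof$involvement[6:15], rep(0.6, 10))
  expect_equal(prof$involvement[c(1:5, 16:30)], rep(0, 20))
  expect_error(involvement_profile(tibble::tibble()), "n_residues")

  # tie for largest: both domains count
  tie <- structure(
    tibble::tibble(frame = 1L, domain_id = c(1L, 1L, 2L, 2L),
                   residue = c(1L, 2L, 5L, 6L)),
    class = c("domain_decomposition", class(tibble::tibble())),
    n_residues = 6L, n_frames = 1L
  )
  prof <- involvement_profile(tie)
  expect_equal(prof$involvement, c(1, 1, 0, 0, 1, 1))
})

test_that("domain-prone region is the best one-third window with left tie-break", {
  v <- rep(0, 30); v[11:20] <- 1
  prof <- structure(tibble::tibble(residue = 1:30, involvement = v),
                    class = c("involvement_profile", class(tibble::tibble())))
  reg <- domain_prone_region(prof)
  expect_equal(c(reg$start, reg$end), c(11, 20))

  uniform <- structure(tibble::tibble(residue = 1:30, involvement = rep(0.4, 30)),
                       class = class(prof))
  reg <- domain_prone_region(uniform)
  expect_equal(c(reg$start, reg$end), c(1, 10))

  set.seed(13)
  for (rep in 1:20) {
    n <- sample(12:60, 1)
    v <- runif(n)
    prof <- structure(tibble::tibble(residue = 1:n, involvement = v),
                      class = class(uniform))
    reg <- domain_prone_region(prof)
    or <- oracle_prone_window(v, round(n / 3))
    expect_equal(c(reg$start, reg$end), unname(or))
  }
  short <- structure(tibble::tibble(residue = 1:4, involvement = rep(1, 4)),
                     class = class(uniform))
  expect_error(domain_prone_region(short), "too short")
})
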