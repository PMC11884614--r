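#' Residue domains from contact-graph 2-core decomposition
#'
#' A residue contact exists when the minimum distance between any atoms of
#' two residues is below a cutoff (default 0.35 nm), excluding sequence
#' neighbors i, i+-1. A residue domain is a connected component of the
#' 2-core of the per-frame contact graph (every member keeps at least two
#' within-domain contacts), retained when its size is at least `min_size`
#' (default 5, i.e. "exceeding 4"). Pooled domain sizes follow a power law
#' P(s) ~ s^-tau truncated by the chain length N, which finite-size scaling
#' P(s, N) ~ s^-tau G(s/N) collapses across proteins of different length.
#'
#' @name residue-domains
NULL

#' Contact graph of one conformation
#'
#' @param frame single-frame trajectory subset (tibble with residue/atom rows).
#' @param cutoff contact distance in nm, strict `<` (default 0.35).
#' @param exclude_neighbors exclude pairs with |i - j| <= this (default 1).
#' @return `contact_graph`: list with `n_residues` and an `edges` tibble (i < j).
#' @export
contact_graph <- function(frame, cutoff = 0.35, exclude_neighbors = 1L) {
  if (cutoff <= 0) abort("cutoff must be positive")
  if (length(unique(frame$frame)) != 1) abort("contact_graph expects a single frame")
  res <- frame$residue
  N <- max(res)
  xyz <- as.matrix(frame[, c("x", "y", "z")])
  # all-atom pairwise distances, then min per residue pair
  d <- as.matrix(stats::dist(xyz))
  close <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  if (nrow(close) == 0) {
    edges <- tibble(i = integer(), j = integer())
  } else {
    ri <- res[close[, 1]]; rj <- res[close[, 2]]
    i <- pmin(ri, rj); j <- pmax(ri, rj)
    keep <- (j - i) > exclude_neighbors
    edges <- distinct(tibble(i = i[keep], j = j[keep]))
    edges <- arrange(edges, .data$i, .data$j)
  }
  structure(list(n_residues = N, edges = edges), class = "contact_graph")
}

#' k-core of a contact graph
#'
#' Maximal subgraph in which every retained node has degree >= k, obtained by
#' iteratively peeling lower-degree nodes; the fixed point is independent of
#' removal order.
#'
#' @param graph `contact_graph`.
#' @param k minimum within-subgraph degree (default 2).
#' @return `contact_graph` restricted to the k-core (node labels preserved).
#' @export
k_core <- function(graph, k = 2L) {
  if (k < 1) abort("k must be >= 1")
  edges <- graph$edges
  repeat {
    if (nrow(edges) == 0) break
    deg <- table(c(edges$i, edges$j))
    drop <- as.integer(names(deg)[deg < k])
    if (length(drop) == 0) break
    edges <- edges[!(edges$i %in% drop) & !(edges$j %in% drop), ]
  }
  structure(list(n_residues = graph$n_residues, edges = edges),
            class = "contact_graph")
}

graph_components <- function(graph) {
  if (nrow(graph$edges) == 0) return(list())
  g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE)
  comp <- igraph::components(g)
  labs <- as.integer(igraph::V(g)$name)
  split(labs, comp$membership)
}

#' Decompose conformations into residue domains
#'
#' For every frame: contact graph, 2-core, connected components, size filter.
#'
#' @param frames trajectory tibble (one or many frames).
#' @param cutoff contact cutoff, nm.
#' @param min_size minimum domain size kept (default 5).
#' @param exclude_neighbors sequence-neighbor exclusion (default 1).
#' @return `domain_decomposition`: tibble with columns frame, domain_id,
#'   residue (long format; empty when no domain passes the filter).
#'   Attributes: n_residues, n_frames (frames processed, including
#'   domain-free ones, which involvement profiles must count).
#' @export
decompose_domains <- function(frames, cutoff = 0.35, min_size = 5L,
                              exclude_neighbors = 1L) {
  ids <- unique(frames$frame)
  rows <- lapply(ids, function(t) {
    fr <- frames[frames$frame == t, ]
    core <- k_core(contact_graph(fr, cutoff, exclude_neighbors), k = 2L)
    comps <- graph_components(core)
    comps <- comps[lengths(comps) >= min_size]
    if (length(comps) == 0) return(NULL)
    tibble(
      frame = t,
      domain_id = rep(seq_along(comps), lengths(comps)),
      residue = unlist(lapply(comps, sort), use.names = FALSE)
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) out <- tibble(frame = integer(), domain_id = integer(),
                                    residue = integer())
  structure(out, class = c("domain_decomposition", class(tibble())),
            n_residues = max(frames$residue), n_frames = length(ids))
}

#' Domain sizes of a decomposition
#'
#' @param decomp `domain_decomposition` tibble (or list of them, pooled).
#' @return integer vector of domain sizes.
#' @export
domain_sizes <- function(decomp) {
  if (is.data.frame(decomp)) decomp <- list(decomp)
  unlist(lapply(decomp, function(d) {
    if (nrow(d) == 0) return(integer())
    as.integer(table(paste(d$frame, d$domain_id)))
  }), use.names = FALSE)
}

#' Pooled domain-size distribution with power-law exponent fit
#'
#' Sizes from all frames (and trajectories) are pooled into one empirical
#' probability distribution. tau_hat comes from least squares of
#' log10 P(s) on log10 s after logarithmic binning over `fit_range`
#' (default `[min_size, 0.3 N]`, avoiding the finite-size tail). A fit is
#' refused -- distribution returned, tau_hat = NA, reason recorded -- when
#' fewer than 20 domains are pooled or the support is degenerate.
#'
#' @param decomps `domain_decomposition`, list of them, or an integer vector
#'   of sizes.
#' @param N system size (residues) of the source chains.
#' @param fit_range numeric length-2 (s_min, s_max) for the tau fit.
#' @param bins_per_decade log-binning density (default 8).
#' @return `size_distribution` object: table (size, count, p), N, n_domains,
#'   tau_hat, fit_range, fit_refused reason (NULL when fitted).
#' @export
size_distribution <- function(decomps, N, fit_range = NULL, bins_per_decade = 8L) {
  sizes <- if (is.numeric(decomps)) as.integer(decomps) else domain_sizes(decomps)
  tab <- tibble(size = sizes) |> count(.data$size, name = "count") |>
    mutate(p = .data$count / sum(.data$count))
  if (is.null(fit_range)) {
    fit_range <- c(if (nrow(tab)) min(tab$size) else 5, max(5, round(0.3 * N)))
  }
  out <- structure(
    list(table = tab, N = as.integer(N), n_domains = length(sizes),
         tau_hat = NA_real_, fit_range = fit_range, fit = NULL,
         fit_refused = NULL),
    class = "size_distribution"
  )
  if (length(sizes) < 20) {
    out$fit_refused <- "fewer than 20 pooled domains"
    return(out)
  }
  sel <- tab$size >= fit_range[1] & tab$size <= fit_range[2]
  if (length(unique(tab$size[sel])) < 3) {
    out$fit_refused <- "degenerate size support inside fit range"
    return(out)
  }
  # log-bin the pmf, then straight-line fit in log-log
  ls <- log10(tab$size[sel]); lp <- log10(tab$p[sel])
  bin <- floor((ls - min(ls)) * bins_per_decade + 1e-12)
  binned <- tibble(bin = bin, ls = ls, p = tab$p[sel]) |>
    group_by(.data$bin) |>
    summarise(ls = mean(.data$ls), p = mean(.data$p), .groups = "drop")
  if (nrow(binned) < 3) {
    out$fit_refused <- "fewer than 3 log bins inside fit range"
    return(out)
  }
  fit <- lm(log10(binned$p) ~ binned$ls)
  out$tau_hat <- -unname(coef(fit)[2])
  out$fit <- list(intercept = unname(coef(fit)[1]),
                  r_squared = r_squared_of(fit), n_bins = nrow(binned))
  out
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("Domain size distribution: %d domains, N = %d\n", x$n_domains, x$N))
  if (is.null(x$fit_refused)) {
    cat(sprintf("  tau_hat = %.4f over s in [%g, %g]\n",
                x$tau_hat, x$fit_range[1], x$fit_range[2]))
  } else {
    cat(sprintf("  fit refused: %s\n", x$fit_refused))
  }
  invisible(x)
}

#' @method tidy size_distribution
#' @export
tidy.size_distribution <- function(x, ...) x$table

#' @method glance size_distribution
#' @export
glance.size_distribution <- function(x, ...) {
  tibble(tau.hat = x$tau_hat, n.domains = x$n_domains, N = x$N,
         s.min = x$fit_range[1], s.max = x$fit_range[2],
         fit.refused = !is.null(x$fit_refused))
}

#' Discrete power-law exponent by maximum likelihood (cross-check)
#'
#' Clauset-style MLE for a discrete truncated power law on
#' `[s_min, s_max]`; provided as an independent cross-check of the
#' least-squares tau_hat, not as the default estimator.
#'
#' @param sizes integer sizes.
#' @param s_min,s_max truncation bounds.
#' @return list(tau, loglik).
#' @export
fit_tau_mle <- function(sizes, s_min = min(sizes), s_max = max(sizes)) {
  s <- sizes[sizes >= s_min & sizes <= s_max]
  if (length(s) < 10) abort("too few sizes for an MLE fit")
  supp <- s_min:s_max
  nll <- function(tau) {
    logz <- log(sum(supp^(-tau)))
    tau * sum(log(s)) + length(s) * logz
  }
  opt <- stats::optimize(nll, c(0.1, 10))
  list(tau = opt$minimum, loglik = -opt$objective)
}

#' Finite-size scaling collapse of domain-size distributions
#'
#' Each distribution is mapped to points (s/N, P(s) s^tau); curves from
#' different N are interpolated (log-log) onto a common log-spaced grid of
#' s/N covered by all of them, and the collapse score is the mean squared
#' log difference across curve pairs. At the true tau the rescaled curves
#' trace one scaling function G and the score is minimal.
#'
#' @param dists list of >= 2 `size_distribution` objects (different N).
#' @param tau rescaling exponent.
#' @param n_grid interpolation grid size (default 24).
#' @return `scaling_collapse`: list(curves tibble (N, x, y), collapse_score, tau).
#' @export
scaling_collapse <- function(dists, tau, n_grid = 24L, bins_per_decade = 8L) {
  if (length(dists) < 2) abort("need at least 2 distributions to collapse")
  curves <- bind_rows(imap(dists, function(d, k) {
    tab <- d$table[d$table$p > 0, ]
    # log-bin the empirical pmf in s first: the sparse large-s tail otherwise
    # contributes mostly counting noise to the score
    ls <- log10(tab$size)
    bin <- floor((ls - min(ls)) * bins_per_decade + 1e-12)
    tb <- tibble(bin = bin, ls = ls, p = tab$p) |>
      group_by(.data$bin) |>
      summarise(s = 10^mean(.data$ls), p = mean(.data$p), .groups = "drop")
    tibble(curve = k, N = d$N, x = tb$s / d$N, y = tb$p * tb$s^tau)
  }))
  per_curve <- split(curves, curves$curve)
  lo <- max(vapply(per_curve, function(c) min(c$x), 1))
  hi <- min(vapply(per_curve, function(c) max(c$x), 1))
  if (!(hi > lo)) abort("distributions share no overlapping s/N range")
  grid <- 10^seq(log10(lo), log10(hi), length.out = n_grid)
  interp <- lapply(per_curve, function(c) {
    approx(log10(c$x), log10(c$y), xout = log10(grid), rule = 2, ties = mean)$y
  })
  score <- 0; npair <- 0
  for (a in seq_along(interp)) for (b in seq_len(a - 1)) {
    score <- score + mean((interp[[a]] - interp[[b]])^2)
    npair <- npair + 1
  }
  structure(list(curves = curves, collapse_score = score / npair, tau = tau),
            class = "scaling_collapse")
}

#' Fractal dimension of residue domains
#'
#' Domain mass scales with extent as Rg ~ s^(1/d_f); d_f is 1/slope of the
#' least-squares line of log Rg against log s over all retained domains.
#' Random-walk-like domains give d_f near 2, rods 1, compact bodies 3.
#'
#' @param decomps `domain_decomposition` tibble, or a tibble with columns
#'   `size` and `rg` (pre-computed per-domain radii of gyration).
#' @param frames the trajectory the decomposition came from (required in the
#'   first form; residue centers of each domain give its Rg).
#' @return `fractal_fit`: list(d_f, slope, r_squared, n_domains, data).
#'   Refused (error) when fewer than 10 domains or the sizes span less than
#'   half a decade.
#' @export
fractal_dimension <- function(decomps, frames = NULL) {
  if (is.data.frame(decomps) && all(c("size", "rg") %in% names(decomps))) {
    data <- as_tibble(decomps[, c("size", "rg")])
  } else {
    if (is.null(frames)) abort("supply `frames` or a (size, rg) table")
    ctr <- residue_centers(frames)
    data <- decomps |>
      left_join(ctr, by = c("frame", "residue")) |>
      group_by(.data$frame, .data$domain_id) |>
      summarise(size = n(),
                rg = radius_of_gyration(cbind(.data$x, .data$y, .data$z)),
                .groups = "drop") |>
      select("size", "rg")
  }
  data <- data[data$rg > 0, ]
  if (nrow(data) < 10) abort("fit refused: fewer than 10 domains with Rg > 0")
  if (log10(max(data$size) / min(data$size)) < 0.5) {
    abort("fit refused: domain sizes span less than half a decade")
  }
  fit <- lm(log10(data$rg) ~ log10(data$size))
  slope <- unname(coef(fit)[2])
  structure(
    list(d_f = 1 / slope, slope = slope,
         r_squared = r_squared_of(fit), n_domains = nrow(data),
         data = data),
    class = "fractal_fit"
  )
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("Fractal dimension fit: d_f = %.3f (slope %.3f, r^2 %.3f, %d domains)\n",
              x$d_f, x$slope, x$r_squared, x$n_domains))
  invisible(x)
}

#' @method glance fractal_fit
#' @export
glance.fractal_fit <- function(x, ...) {
  tibble(d.f = x$d_f, slope = x$slope, r.squared = x$r_squared,
         n.domains = x$n_domains)
}

#' Per-residue involvement in the dominant domain
#'
#' `involvement[i]` = fraction of frames in which residue i belongs to the
#' largest domain of that frame. Frames without any retained domain count in
#' the denominator. When two or more domains tie for largest, all tied
#' domains count as dominant (avoids index-order bias).
#'
#' @param decomp `domain_decomposition` tibble.
#' @param n_residues,n_frames overrides for the decomposition attributes.
#' @return `involvement_profile` tibble (residue, involvement in \[0,1\]),
#'   with an `n_frames` attribute.
#' @export
involvement_profile <- function(decomp, n_residues = NULL, n_frames = NULL) {
  if (is.null(n_residues)) n_residues <- attr(decomp, "n_residues")
  if (is.null(n_frames)) n_frames <- attr(decomp, "n_frames")
  if (is.null(n_residues) || is.null(n_frames) || n_frames < 1) {
    abort("decomposition lacks n_residues/n_frames; pass them explicitly")
  }
  hits <- integer(n_residues)
  if (nrow(decomp) > 0) {
    sizes <- decomp |> count(.data$frame, .data$domain_id, name = "size")
    dom <- sizes |> group_by(.data$frame) |>
      filter(.data$size == max(.data$size)) |> ungroup()
    members <- decomp |>
      dplyr::semi_join(dom, by = c("frame", "domain_id")) |>
      distinct(.data$frame, .data$residue)
    tb <- table(members$residue)
    hits[as.integer(names(tb))] <- as.integer(tb)
  }
  structure(
    tibble(residue = seq_len(n_residues), involvement = hits / n_frames),
    class = c("involvement_profile", class(tibble())), n_frames = n_frames
  )
}

#' Domain-prone region of the sequence
#'
#' The contiguous window of length round(N/3) (the "top third" of the
#' sequence) maximizing mean involvement; ties resolve to the smallest start.
#'
#' @param profile `involvement_profile` tibble.
#' @return list(start, end, mean_involvement) with 1-based inclusive indices.
#' @export
domain_prone_region <- function(profile) {
  v <- profile$involvement
  N <- length(v)
  if (N < 6) abort("profile too short to define a one-third window")
  w <- round(N / 3)
  cs <- cumsum(c(0, v))
  means <- (cs[(w + 1):(N + 1)] - cs[1:(N - w + 1)]) / w
  # ties (within float noise of the running sums) resolve to the first window
  start <- which(means >= max(means) - 1e-12)[1]
  list(start = start, end = start + w - 1L, mean_involvement = means[start])
}

# r^2 without summary.lm (which warns on numerically exact fits)
r_squared_of <- function(fit) {
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((fit$model[[1]] - mean(fit$model[[1]]))^2)
  if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
}
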