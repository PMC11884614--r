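# independent brute-force oracles, deliberately naive O(n^2) implementations

# power spectrum as the direct discrete Fourier transform of the biased
# autocorrelation estimate, evaluated by explicit double loops
oracle_spectrum <- function(x, dt, center = TRUE) {
  n <- length(x)
  if (center) x <- x - mean(x)
  r <- vapply(0:(n - 1), function(m) sum(x[1:(n - m)] * x[(1 + m):n]) / n, 1)
  k <- seq_len(floor(n / 2))
  S <- vapply(k, function(kk) {
    ms <- -(n - 1):(n - 1)
    Re(sum(r[abs(ms) + 1] * exp(-2i * pi * kk * ms / n))) * dt
  }, 1)
  tibble::tibble(frequency = k / (n * dt), power = S)
}

# k-core by one-at-a-time peeling in a supplied (or random) order
oracle_kcore_nodes <- function(edges, k, order_seed = NULL) {
  nodes <- sort(unique(c(edges$i, edges$j)))
  if (!is.null(order_seed)) set.seed(order_seed)
  repeat {
    deg <- vapply(nodes, function(v) sum(edges$i == v) + sum(edges$j == v), 1L)
    low <- nodes[deg < k]
    if (length(low) == 0) break
    drop <- if (is.null(order_seed)) low[1] else low[sample.int(length(low), 1)]
    nodes <- setdiff(nodes, drop)
    edges <- edges[edges$i %in% nodes & edges$j %in% nodes, ]
  }
  nodes
}

# contact edges by an explicit double loop over residue pairs and atom pairs
oracle_contacts <- function(frame, cutoff, exclude_neighbors = 1) {
  res <- sort(unique(frame$residue))
  out <- list()
  for (a in seq_along(res)) for (b in seq_len(a - 1)) {
    i <- res[b]; j <- res[a]
    if (j - i <= exclude_neighbors) next
    A <- as.matrix(frame[frame$residue == i, c("x", "y", "z")])
    B <- as.matrix(frame[frame$residue == j, c("x", "y", "z")])
    mind <- Inf
    for (p in seq_len(nrow(A))) for (q in seq_len(nrow(B))) {
      mind <- min(mind, sqrt(sum((A[p, ] - B[q, ])^2)))
    }
    if (mind < cutoff) out[[length(out) + 1]] <- c(i, j)
  }
  if (length(out) == 0) return(tibble::tibble(i = integer(), j = integer()))
  m <- do.call(rbind, out)
  dplyr::arrange(tibble::tibble(i = m[, 1], j = m[, 2]), i, j)
}

# exhaustive window scan for the domain-prone region
oracle_prone_window <- function(v, w) {
  best <- -Inf; best_start <- NA
  for (s in 1:(length(v) - w + 1)) {
    m <- mean(v[s:(s + w - 1)])
    if (m > best + 1e-15) { best <- m; best_start <- s }
  }
  c(start = best_start, end = best_start + w - 1)
}
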