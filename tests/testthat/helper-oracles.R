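# Brute-force oracles, written independently of the package's
# implementation paths (explicit BFS loops, triangle enumeration over node
# triples, literal template counting, literal step-up definition).

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer(0)
      for (u in frontier)
        for (v in seq_len(n))
          if (adj[u, v] == 1 && is.infinite(d[s, v])) {
            d[s, v] <- depth
            nxt <- c(nxt, v)
          }
      frontier <- nxt
    }
  }
  d
}

oracle_cp <- function(adj) {
  n <- nrow(adj)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k)
        if (adj[nb[a], nb[b]] == 1) tri <- tri + 1
    vals[i] <- 2 * tri / (k * (k - 1))
  }
  mean(vals)
}

oracle_lp <- function(adj) {
  d <- oracle_distances(adj)
  v <- d[upper.tri(d)]
  mean(v[is.finite(v)])
}

oracle_eglob <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- oracle_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_enod <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

oracle_eloc <- function(adj) {
  n <- nrow(adj)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) next
    vals[i] <- oracle_eglob(adj[nb, nb, drop = FALSE])
  }
  mean(vals)
}

# Literal Richman-Moorman counting: both template lengths over the same
# N - m start points, Chebyshev distance, self-matches excluded.
oracle_sampen_counts <- function(x, m, r) {
  n <- length(x)
  np <- n - m
  A <- 0; B <- 0
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      if (max(abs(x[i + 0:(m - 1)] - x[j + 0:(m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  c(A, B)
}

# Literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- m * p[o][i:m] / (i:m)
    q[o[i]] <- min(1, min(cand))
  }
  q
}

random_graph <- function(n, p) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# small, fast generator settings shared by several tests
small_sim_config <- function(...) {
  simulation_config(n_subjects_per_group = 1, duration_s = 120, ...)
}

noiseless <- function(cfg) {
  cfg$noise_amplitudes[] <- 0
  cfg$spike_rate_per_min <- 0
  cfg
}

corr_rmsd <- function(a, b) {
  d <- a - b
  sqrt(mean(d[upper.tri(d)]^2))
}
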