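# Graph-theoretic metrics on binary undirected networks, plus degree-
# preserving null normalization (small-worldness) and integration of metric
# curves over the sparsity grid.

as_binary_adjacency <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  a <- (adj != 0) * 1L
  dimnames(a) <- NULL
  diag(a) <- 0L
  if (!identical(a, t(a))) stop("adjacency must be symmetric")
  a
}

# All-pairs shortest path lengths (Inf for disconnected pairs).
shortest_path_lengths <- function(adj) {
  d <- bfs_distances_cpp(as_binary_adjacency(adj))
  d[d < 0] <- Inf
  d
}

#' Mean clustering coefficient
#'
#' Average over nodes of the local clustering coefficient
#' `2 * triangles_i / (k_i (k_i - 1))`; nodes with degree below 2 contribute
#' zero.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @return Cp in `[0, 1]`.
#' @export
clustering_coefficient <- function(adj) {
  a <- as_binary_adjacency(adj)
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a)     # 2 * number of triangles through each node
  ci <- ifelse(k < 2, 0, tri / (k * (k - 1)))
  mean(ci)
}

#' Characteristic path length
#'
#' Mean shortest-path length over all connected node pairs; disconnected
#' pairs are excluded from the average.
#'
#' @param adj Binary symmetric adjacency matrix with at least one edge.
#' @return Lp (>= 1).
#' @export
characteristic_path_length <- function(adj) {
  a <- as_binary_adjacency(adj)
  if (sum(a) == 0) stop("graph has no edges; path length undefined")
  d <- shortest_path_lengths(a)
  vals <- d[upper.tri(d)]
  mean(vals[is.finite(vals)])
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest path length, with
#' `1/Inf = 0` for disconnected pairs.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @return Eglob in `[0, 1]`.
#' @export
global_efficiency <- function(adj) {
  a <- as_binary_adjacency(adj)
  n <- nrow(a)
  if (n < 2 || sum(a) == 0) return(0)
  d <- shortest_path_lengths(a)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbors; nodes with fewer than two neighbors contribute zero.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @return Eloc in `[0, 1]`.
#' @export
local_efficiency <- function(adj) {
  a <- as_binary_adjacency(adj)
  vals <- vapply(seq_len(nrow(a)), function(i) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) return(0)
    global_efficiency(a[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

#' Nodal efficiency
#'
#' For node i, `sum_j 1/d_ij / (N - 1)`: the node's average inverse distance
#' to every other node.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @param node Node index, or `NULL` for all nodes.
#' @return Numeric scalar (or vector over nodes) in `[0, 1]`.
#' @export
nodal_efficiency <- function(adj, node = NULL) {
  a <- as_binary_adjacency(adj)
  n <- nrow(a)
  d <- shortest_path_lengths(a)
  inv <- 1 / d
  diag(inv) <- 0
  e <- rowSums(inv) / (n - 1)
  if (is.null(node)) e else e[node]
}

#' Small-worldness against degree-preserving random networks
#'
#' `sigma = (Cp / <Cp_rand>) / (Lp / <Lp_rand>)`, where the null averages are
#' over `n_random` degree-preserving (double-edge-swap) randomizations of the
#' observed graph. Draws from the current R random stream, so results are
#' reproducible under [set.seed()].
#'
#' @param adj Binary symmetric adjacency matrix.
#' @param n_random Number of null networks (default 100).
#' @param n_iter_per_edge Attempted swaps per edge per null (default 10).
#' @return sigma (positive scalar; `NA` with a warning if the null clustering
#'   or path length degenerates to zero).
#' @export
small_worldness <- function(adj, n_random = 100, n_iter_per_edge = 10) {
  a <- as_binary_adjacency(adj)
  n_edges <- sum(a) / 2
  cp <- clustering_coefficient(a)
  lp <- characteristic_path_length(a)
  if (n_edges < 2) {
    warning("degree sequence admits no rewiring; normalizing against the graph itself")
    return((cp / cp) / (lp / lp))
  }
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  niter <- ceiling(n_iter_per_edge * n_edges)
  cp_r <- lp_r <- numeric(n_random)
  for (b in seq_len(n_random)) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
    cp_r[b] <- igraph::transitivity(gr, type = "localaverage",
                                    isolates = "zero")
    lp_r[b] <- igraph::mean_distance(gr, unconnected = TRUE)
  }
  mcp <- mean(cp_r); mlp <- mean(lp_r)
  if (mcp <= 0 || mlp <= 0 || !is.finite(mcp) || !is.finite(mlp)) {
    warning("degenerate null distribution; sigma undefined")
    return(NA_real_)
  }
  (cp / mcp) / (lp / mlp)
}

#' Integrate a metric curve over its grid
#'
#' Trapezoidal integral of metric values over a strictly increasing grid
#' (sparsity values or entropy timescales); the scalar the group statistics
#' operate on. `rule = "rectangle"` gives a left-point rectangle sum instead.
#'
#' @param values Metric values, finite, one per grid point.
#' @param grid Strictly increasing numeric grid, length >= 2.
#' @param rule `"trapezoid"` (default) or `"rectangle"`.
#' @return The integral (scalar).
#' @export
metric_auc <- function(values, grid, rule = c("trapezoid", "rectangle")) {
  rule <- match.arg(rule)
  if (length(values) != length(grid)) stop("values and grid differ in length")
  if (length(grid) < 2) stop("need at least two grid points to integrate")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (any(!is.finite(values))) stop("values must be finite")
  dg <- diff(grid)
  if (rule == "trapezoid") sum(dg * (head(values, -1) + values[-1]) / 2)
  else sum(dg * head(values, -1))
}

#' Metric curves and AUCs over a network ensemble
#'
#' Computes the global metrics (and nodal efficiency) on every binary network
#' of a sparsity ensemble and integrates each curve over the sparsity grid.
#'
#' @param ensemble A `network_ensemble` from [binarize_by_sparsity()].
#' @param include_sigma Compute small-worldness (costly: `n_random` null
#'   networks per sparsity)?
#' @param n_random,n_iter_per_edge Null-model settings for sigma.
#' @return A list with `sparsity`, per-metric value vectors (`cp`, `lp`,
#'   `eglob`, `eloc`, optionally `sigma`), `enod` (channels x sparsity
#'   matrix), and `auc` (named list of scalars; `enod` AUC is a per-channel
#'   vector).
#' @export
network_metric_curves <- function(ensemble, include_sigma = TRUE,
                                  n_random = 100, n_iter_per_edge = 10) {
  stopifnot(inherits(ensemble, "network_ensemble"))
  grid <- ensemble$sparsity
  ns <- length(grid)
  nchan <- dim(ensemble$adjacency)[1]
  cp <- lp <- eglob <- eloc <- sigma <- numeric(ns)
  enod <- matrix(0, nchan, ns)
  for (g in seq_len(ns)) {
    a <- ensemble$adjacency[, , g]
    m <- graph_metrics_cpp(as_binary_adjacency(a))  # one BFS pass per graph
    cp[g] <- m$cp
    lp[g] <- m$lp
    eglob[g] <- m$eglob
    eloc[g] <- m$eloc
    enod[, g] <- m$enod
    if (include_sigma)
      sigma[g] <- small_worldness(a, n_random, n_iter_per_edge)
  }
  auc <- list(cp = metric_auc(cp, grid), lp = metric_auc(lp, grid),
              eglob = metric_auc(eglob, grid), eloc = metric_auc(eloc, grid),
              enod = apply(enod, 1, metric_auc, grid = grid))
  out <- list(sparsity = grid, cp = cp, lp = lp, eglob = eglob, eloc = eloc,
              enod = enod, auc = auc,
              subject_id = ensemble$subject_id, group = ensemble$group)
  if (include_sigma) {
    out$sigma <- sigma
    out$auc$sigma <- metric_auc(sigma, grid)
  }
  class(out) <- "metric_curves"
  out
}
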