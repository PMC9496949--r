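# Connectivity: Fisher-z Pearson matrices and sparsity-thresholded binary
# network ensembles.

#' Pearson/Fisher-z connectivity matrix
#'
#' Pearson correlations between all channel pairs of an HbO series,
#' transformed to z-values with Fisher's r-to-z (`atanh`). The diagonal is
#' zero by convention.
#'
#' @param x A `hemo_series` (its `hbo` is used) or a channels x time matrix.
#' @param subject_id,group Metadata attached to the matrix (taken from the
#'   `hemo_series` when available).
#' @return A `conn_matrix`: symmetric numeric matrix of Fisher z values with
#'   zero diagonal and attributes `subject_id` and `group`.
#' @export
pearson_fisher_matrix <- function(x, subject_id = NULL, group = NULL) {
  if (inherits(x, "hemo_series")) {
    if (is.null(subject_id)) subject_id <- x$subject_id
    if (is.null(group)) group <- x$group
    x <- x$hbo
  }
  stopifnot(is.matrix(x), ncol(x) >= 3)
  sds <- apply(x, 1, sd)
  if (any(sds == 0))
    stop("constant channel(s): ", paste(which(sds == 0), collapse = ", "))
  r <- cor(t(x))
  off <- abs(r[upper.tri(r)])
  if (any(off >= 1 - 1e-10))
    stop("perfectly correlated channel pair (|r| = 1); duplicated channels?")
  z <- atanh(r)
  diag(z) <- 0
  structure(z, class = c("conn_matrix", "matrix"),
            subject_id = subject_id, group = group)
}

round_half_up <- function(x) floor(x + 0.5)

#' Binarize a connectivity matrix over a sparsity grid
#'
#' For each sparsity `s`, the `round(s * N(N-1)/2)` strongest edges are kept
#' (ranked by signed z, most positive first; set `rank_by = "abs"` to rank by
#' magnitude). Ties at the cutoff are broken by lexicographic channel order,
#' so the construction is deterministic, and because one fixed ranking serves
#' the whole grid the ensemble is nested: every edge present at sparsity `s`
#' is present at any larger sparsity.
#'
#' @param z A `conn_matrix` (or symmetric numeric matrix).
#' @param grid Sparsity values in (0, 1], default `seq(0.13, 0.40, 0.01)`.
#' @param rank_by `"signed"` (default) or `"abs"`.
#' @return A `network_ensemble`: list with `sparsity` (the grid), `adjacency`
#'   (N x N x length(grid) binary array) and the subject metadata.
#' @export
binarize_by_sparsity <- function(z, grid = seq(0.13, 0.40, by = 0.01),
                                 rank_by = c("signed", "abs")) {
  rank_by <- match.arg(rank_by)
  stopifnot(is.matrix(z), nrow(z) == ncol(z),
            all(grid > 0), all(grid <= 1))
  n <- nrow(z)
  m <- n * (n - 1) / 2
  ut <- which(upper.tri(z), arr.ind = TRUE)
  vals <- z[upper.tri(z)]
  key <- if (rank_by == "signed") -vals else -abs(vals)
  ord <- order(key, ut[, 1], ut[, 2])
  adj <- array(0L, dim = c(n, n, length(grid)))
  for (g in seq_along(grid)) {
    k <- round_half_up(grid[g] * m)
    if (k > 0) {
      sel <- ord[seq_len(min(k, m))]
      a <- matrix(0L, n, n)
      a[ut[sel, , drop = FALSE]] <- 1L
      adj[, , g] <- a + t(a)
    }
  }
  structure(list(sparsity = grid, adjacency = adj,
                 subject_id = attr(z, "subject_id"),
                 group = attr(z, "group")),
            class = "network_ensemble")
}

#' Element-wise mean of connectivity matrices
#'
#' @param matrices A non-empty list of equally sized `conn_matrix` objects.
#' @return The element-wise mean matrix (class `conn_matrix`).
#' @export
group_mean_matrix <- function(matrices) {
  if (length(matrices) == 0) stop("empty list of matrices")
  dims <- vapply(matrices, dim, integer(2))
  if (any(dims != dims[, 1])) stop("matrices differ in shape")
  out <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  structure(out, class = c("conn_matrix", "matrix"))
}
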