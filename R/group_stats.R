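# Between-group inference: network-based statistic, covariate-adjusted
# two-sample tests with FDR, partial correlations, and the power-based
# sample-size calculation.

# Edge-wise pooled-variance two-sample t statistics, vectorized over columns.
edgewise_t <- function(x, g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  x1 <- x[g1, , drop = FALSE]; x2 <- x[g2, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  ss1 <- colSums(x1 * x1) - n1 * m1^2
  ss2 <- colSums(x2 * x2) - n2 * m2^2
  sp <- (ss1 + ss2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
}

# Connected components of the graph spanned by a set of edges; returns the
# edge count and node set of each component.
edge_components <- function(edge_idx, ut, n) {
  if (length(edge_idx) == 0) return(list())
  a <- matrix(0L, n, n)
  a[ut[edge_idx, , drop = FALSE]] <- 1L
  a <- a + t(a)
  d <- bfs_distances_cpp(a)
  nodes <- unique(as.vector(ut[edge_idx, , drop = FALSE]))
  comp_of <- rep(NA_integer_, n)
  comp <- 0L
  for (v in nodes) {
    if (!is.na(comp_of[v])) next
    comp <- comp + 1L
    comp_of[d[v, ] >= 0] <- comp
  }
  lapply(seq_len(comp), function(cc) {
    members <- which(comp_of == cc)
    in_comp <- ut[edge_idx, 1] %in% members
    list(nodes = members,
         edges = ut[edge_idx[in_comp], , drop = FALSE],
         size = sum(in_comp))
  })
}

#' Network-based statistic (NBS) permutation test
#'
#' Edge-wise two-sample t-tests on Fisher-z connectivity; edges exceeding the
#' one-tailed cluster-defining threshold form a suprathreshold graph whose
#' connected components are tested against the permutation null distribution
#' of the maximum component size (edge count) under group-label shuffling.
#' Component p-values use the never-zero estimator
#' `(1 + #\{perm max >= observed\}) / (1 + n_perm)`.
#'
#' @param z_matrices List of symmetric Fisher-z matrices, one per subject.
#' @param groups Factor/character vector of group labels (two levels).
#' @param direction `"greater"` tests group1 > group2 edges, `"less"` the
#'   reverse, `"both"` uses two-tailed suprathreshold selection.
#' @param cluster_p Cluster-defining edge threshold (default 0.001).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed for the permutation stream.
#' @return An `nbs_result`: list with `components` (each with `nodes`,
#'   `edges`, `size`, `p_perm`), `direction`, `cluster_p`, `n_perm`,
#'   `null_max` (permutation distribution), and `t_threshold`. Zero
#'   suprathreshold edges give an empty component list, not an error.
#' @export
nbs <- function(z_matrices, groups, direction = c("greater", "less", "both"),
                cluster_p = 0.001, n_perm = 1000, seed = NULL) {
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2, length(z_matrices) == length(groups),
            all(table(groups) >= 2))
  n <- nrow(z_matrices[[1]])
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  x <- t(vapply(z_matrices, function(m) m[upper.tri(m)],
                numeric(nrow(ut))))
  g1 <- which(groups == levels(groups)[1])
  g2 <- which(groups == levels(groups)[2])
  df <- length(g1) + length(g2) - 2
  tcrit <- qt(1 - (if (direction == "both") cluster_p / 2 else cluster_p), df)
  supra <- function(tv) switch(direction,
                               greater = which(tv > tcrit),
                               less = which(-tv > tcrit),
                               both = which(abs(tv) > tcrit))
  obs_edges <- supra(edgewise_t(x, g1, g2))
  comps <- edge_components(obs_edges, ut, n)
  null_max <- integer(n_perm)
  ns <- length(groups)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(ns)
    tv <- edgewise_t(x, perm[g1], perm[g2])
    e <- supra(tv)
    null_max[b] <- if (length(e) == 0) 0L
      else max(vapply(edge_components(e, ut, n), `[[`, numeric(1), "size"))
  }
  comps <- lapply(comps, function(cc) {
    cc$p_perm <- (1 + sum(null_max >= cc$size)) / (1 + n_perm)
    cc
  })
  structure(list(components = comps, direction = direction,
                 cluster_p = cluster_p, n_perm = n_perm,
                 t_threshold = tcrit, null_max = null_max,
                 group_levels = levels(groups)),
            class = "nbs_result")
}

#' Covariate-adjusted two-sample comparison
#'
#' Residualizes the values on the covariates (pooled least squares with
#' intercept, both groups together), then applies a classical pooled-variance
#' two-sample t-test to the residuals. With no covariates this reduces
#' exactly to the textbook two-sample t-test.
#'
#' @param values Numeric vector, one value per subject.
#' @param groups Two-level factor/character vector.
#' @param covariates Optional data frame of covariates (e.g. age).
#' @param metric Name recorded in the result.
#' @return A one-row data frame: `metric`, per-group means (of the raw
#'   values), `t`, `df`, `p`.
#' @export
adjusted_group_test <- function(values, groups, covariates = NULL,
                                metric = "value") {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2, all(table(groups) >= 2),
            length(values) == length(groups))
  resid_vals <- values
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    cdf <- as.data.frame(covariates)
    mm <- cbind(1, as.matrix(cdf))
    if (qr(mm)$rank < ncol(mm)) stop("collinear covariates")
    fit <- lm(values ~ ., data = cdf)
    resid_vals <- stats::residuals(fit)
  }
  tt <- t.test(resid_vals[groups == levels(groups)[1]],
               resid_vals[groups == levels(groups)[2]], var.equal = TRUE)
  data.frame(metric = metric,
             mean_group1 = mean(values[groups == levels(groups)[1]]),
             mean_group2 = mean(values[groups == levels(groups)[2]]),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate correction (wraps the standard
#' implementation; a brute-force oracle checks it in the test suite).
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and names.
#' @export
fdr_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Partial Pearson correlation
#'
#' Pearson correlation between the residuals of `x` and `y` after
#' least-squares removal of the covariates; the p-value uses the t transform
#' with `n - 2 - k` degrees of freedom (`k` covariates).
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data frame of covariates.
#' @return A one-row data frame: `r`, `df`, `t`, `p`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- 0
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    cdf <- as.data.frame(covariates)
    k <- ncol(cdf)
    stopifnot(n > k + 2)
    x <- stats::residuals(lm(x ~ ., data = cdf))
    y <- stats::residuals(lm(y ~ ., data = cdf))
  }
  if (sd(x) == 0 || sd(y) == 0)
    return(data.frame(r = NA_real_, df = NA_real_, t = NA_real_,
                      p = NA_real_))
  r <- cor(x, y)
  df <- n - 2 - k
  tv <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  data.frame(r = r, df = df, t = tv, p = 2 * pt(-abs(tv), df))
}

#' Sample size for a two-sided two-sample t-test
#'
#' Smallest equal-allocation total N such that a two-sided two-sample t-test
#' at level `alpha` reaches the target power for standardized effect size
#' `d`, using the exact noncentral-t power function with noncentrality
#' `d * sqrt(n/2)` (the G*Power "a priori" computation).
#'
#' @param effect_size_d Cohen's d (> 0).
#' @param alpha Two-sided significance level.
#' @param power Target power in (0, 1).
#' @return Total sample size (even integer, both groups combined).
#' @export
sample_size_two_groups <- function(effect_size_d, alpha = 0.05,
                                   power = 0.8) {
  stopifnot(effect_size_d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  for (n in 2:1e6) {
    df <- 2 * n - 2
    tc <- qt(1 - alpha / 2, df)
    ncp <- effect_size_d * sqrt(n / 2)
    pw <- 1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
    if (pw >= power) return(2L * n)
  }
  stop("target power unreachable")
}
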