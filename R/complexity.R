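# Multiscale sample entropy: coarse-graining over timescales, sample entropy
# with pattern length m and tolerance r, AUC over the scale range.

#' Coarse-grain a time series
#'
#' Non-overlapping averages of `scale` adjacent samples; the trailing
#' remainder is discarded. When `m` is supplied, returns `NULL` (an
#' undefined marker, not an error) if the coarse-grained series would be too
#' short to support sample entropy with that pattern length.
#'
#' @param x Numeric series.
#' @param scale Positive integer timescale.
#' @param m Optional pattern length for the downstream length check.
#' @return Numeric vector of length `floor(length(x)/scale)`, or `NULL`.
#' @export
coarse_grain <- function(x, scale, m = NULL) {
  stopifnot(scale >= 1, scale == round(scale))
  n <- floor(length(x) / scale)
  if (!is.null(m) && n < m + 2) return(NULL)
  if (scale == 1) return(x)
  colMeans(matrix(x[seq_len(n * scale)], nrow = scale))
}

#' Sample entropy
#'
#' `-log(A/B)` where `B` is the number of template pairs (Chebyshev distance,
#' self-matches excluded) matching at length `m` and `A` the number also
#' matching at length `m + 1` (Richman-Moorman counting: both lengths use the
#' same `N - m` start points).
#'
#' @param x Numeric series, length > m + 1.
#' @param m Pattern length (default 2).
#' @param r_abs Absolute tolerance (> 0).
#' @return Non-negative scalar; `0` for a constant series; `NA` when no
#'   templates match (undefined, not an error).
#' @export
sample_entropy <- function(x, m = 2, r_abs) {
  stopifnot(length(x) > m + 1)
  if (sd(x) == 0) return(0)
  stopifnot(r_abs > 0)
  ab <- sampen_counts_cpp(as.numeric(x), as.integer(m), r_abs)
  if (ab[2] == 0 || ab[1] == 0) return(NA_real_)
  -log(ab[1] / ab[2])
}

#' Multiscale entropy profile of one channel
#'
#' Sample entropy of coarse-grained versions of the series over a range of
#' timescales. The tolerance is fixed at `r_fraction` times the SD of the
#' original (scale-1) series for every scale — the canonical multiscale-
#' entropy convention — unless `per_scale_r = TRUE` renormalizes per scale.
#' The AUC over scales is the trapezoidal integral over the longest defined
#' prefix of the curve (undefined scales are kept as `NA` and logged, never
#' fabricated).
#'
#' @param x Numeric series.
#' @param scales Integer timescales, default `1:25`.
#' @param m Pattern length (default 2).
#' @param r_fraction Tolerance as a fraction of SD (default 0.2).
#' @param per_scale_r Recompute the tolerance from each coarse-grained
#'   series' own SD?
#' @return An `mse_profile`: list with `scales`, `sampen` (per scale, `NA`
#'   where undefined), `auc`, and `params`.
#' @export
mse_profile <- function(x, scales = 1:25, m = 2, r_fraction = 0.2,
                        per_scale_r = FALSE) {
  stopifnot(all(scales >= 1), all(scales == round(scales)),
            r_fraction > 0)
  s0 <- sd(x)
  r_abs <- r_fraction * s0
  sampen <- vapply(scales, function(s) {
    y <- coarse_grain(x, s, m)
    if (is.null(y)) return(NA_real_)
    if (s0 == 0) return(0)
    r_use <- if (per_scale_r) r_fraction * sd(y) else r_abs
    if (r_use == 0) return(0)
    sample_entropy(y, m, r_use)
  }, numeric(1))
  prefix <- if (is.na(sampen[1])) integer(0)
            else seq_len(max(which(cumsum(is.na(sampen)) == 0)))
  auc <- if (length(prefix) >= 2)
    metric_auc(sampen[prefix], scales[prefix]) else NA_real_
  if (s0 == 0) auc <- 0
  structure(list(scales = scales, sampen = sampen, auc = auc,
                 params = list(m = m, r_fraction = r_fraction,
                               per_scale_r = per_scale_r)),
            class = "mse_profile")
}

#' Multiscale entropy for every channel of an HbO series
#'
#' @param x A `hemo_series` or channels x time matrix.
#' @param ... Passed to [mse_profile()].
#' @return A list with `sampen` (channels x scales matrix), `auc` (per
#'   channel), and `scales`.
#' @export
mse_by_channel <- function(x, ...) {
  if (inherits(x, "hemo_series")) x <- x$hbo
  stopifnot(is.matrix(x))
  profs <- lapply(seq_len(nrow(x)), function(i) mse_profile(x[i, ], ...))
  list(sampen = do.call(rbind, lapply(profs, `[[`, "sampen")),
       auc = vapply(profs, `[[`, numeric(1), "auc"),
       scales = profs[[1]]$scales)
}
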