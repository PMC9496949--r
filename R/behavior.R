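# N-back behavioral scoring: reaction-time cleaning, hit / false-alarm
# tabulation, and the non-parametric sensitivity index A'.

#' Filter reaction-time outliers
#'
#' Drops responded trials with RT below 150 ms, then trials with RT above
#' mean + 2.5 SD, where the mean and SD are computed per subject and
#' condition on the post-floor set and frozen (a second application of the
#' filter changes nothing). `symmetric = TRUE` also applies the lower
#' mean - 2.5 SD cut (largely vacuous given the floor). Non-response trials
#' are retained.
#'
#' @param trials A trial table as produced by [simulate_behavior()].
#' @param floor_ms RT floor in milliseconds (default 150).
#' @param sd_factor Outlier band width in SDs (default 2.5).
#' @param symmetric Apply the lower band cut too?
#' @return The filtered table; the number of dropped trials per
#'   subject/condition is attached as attribute `"exclusions"`.
#' @export
filter_rts <- function(trials, floor_ms = 150, sd_factor = 2.5,
                       symmetric = FALSE) {
  responded <- trials$response != "none" & !is.na(trials$rt_ms)
  drop <- responded & trials$rt_ms < floor_ms
  keyed <- interaction(trials$subject_id, trials$condition, drop = TRUE)
  for (k in levels(keyed)) {
    idx <- which(keyed == k & responded & !drop)
    if (length(idx) < 2) next
    m <- mean(trials$rt_ms[idx]); s <- sd(trials$rt_ms[idx])
    hi <- trials$rt_ms[idx] > m + sd_factor * s
    lo <- if (symmetric) trials$rt_ms[idx] < m - sd_factor * s else FALSE
    drop[idx[hi | lo]] <- TRUE
  }
  out <- trials[!drop, , drop = FALSE]
  excl <- if (any(drop))
    as.data.frame(table(subject_id = trials$subject_id[drop],
                        condition = trials$condition[drop]))
  else NULL
  attr(out, "exclusions") <- excl
  out
}

#' Non-parametric sensitivity index A'
#'
#' The two-branch formula: for `H >= FA`,
#' `0.5 + ((H - FA)(1 + H - FA)) / (4 H (1 - FA))`, and for `FA > H`,
#' `0.5 - ((FA - H)(1 + FA - H)) / (4 FA (1 - H))`. Satisfies the symmetry
#' identity `a_prime(H, FA) + a_prime(FA, H) = 1`; `H = FA` (chance) gives
#' 0.5, as does the degenerate `H = FA = 0`.
#'
#' @param H Hit rate(s) in `[0, 1]`.
#' @param FA False-alarm rate(s) in `[0, 1]`.
#' @return A' in `[0, 1]`, vectorized over inputs.
#' @export
a_prime <- function(H, FA) {
  stopifnot(all(H >= 0 & H <= 1), all(FA >= 0 & FA <= 1))
  out <- rep(0.5, length(H <- rep_len(H, max(length(H), length(FA)))))
  FA <- rep_len(FA, length(H))
  up <- H > FA
  dn <- FA > H
  out[up] <- 0.5 + ((H[up] - FA[up]) * (1 + H[up] - FA[up])) /
    (4 * H[up] * (1 - FA[up]))
  out[dn] <- 0.5 - ((FA[dn] - H[dn]) * (1 + FA[dn] - H[dn])) /
    (4 * FA[dn] * (1 - H[dn]))
  out
}

#' Summarize N-back performance per condition
#'
#' Tabulates hit rate (responding "yes" on targets; non-responses count as
#' misses), false-alarm rate ("yes" on non-targets), A', and mean RTs for
#' hits and correct rejections. Conditions with no targets or no non-targets
#' are returned as missing.
#'
#' @param trials A trial table (one subject), typically already passed
#'   through [filter_rts()] (set `filter = TRUE` to apply it here).
#' @param filter Apply [filter_rts()] first?
#' @return A data frame, one row per condition, with columns `subject_id`,
#'   `condition`, `n_trials_kept`, `hit_rate`, `fa_rate`, `a_prime`,
#'   `hit_rt_ms`, `rej_rt_ms`.
#' @export
summarize_behavior <- function(trials, filter = TRUE) {
  if (filter) trials <- filter_rts(trials)
  conditions <- unique(trials$condition)
  rows <- lapply(conditions, function(cond) {
    tt <- trials[trials$condition == cond, , drop = FALSE]
    n_t <- sum(tt$is_target)
    n_nt <- sum(!tt$is_target)
    if (n_t == 0 || n_nt == 0 || nrow(tt) == 0)
      return(data.frame(subject_id = tt$subject_id[1], condition = cond,
                        n_trials_kept = nrow(tt), hit_rate = NA_real_,
                        fa_rate = NA_real_, a_prime = NA_real_,
                        hit_rt_ms = NA_real_, rej_rt_ms = NA_real_))
    hits <- tt$is_target & tt$response == "yes"
    fas <- !tt$is_target & tt$response == "yes"
    crs <- !tt$is_target & tt$response == "no"
    H <- sum(hits) / n_t
    FA <- sum(fas) / n_nt
    data.frame(subject_id = tt$subject_id[1], condition = cond,
               n_trials_kept = nrow(tt), hit_rate = H, fa_rate = FA,
               a_prime = a_prime(H, FA),
               hit_rt_ms = if (any(hits)) mean(tt$rt_ms[hits]) else NA_real_,
               rej_rt_ms = if (any(crs)) mean(tt$rt_ms[crs]) else NA_real_)
  })
  do.call(rbind, rows)
}
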