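#' Configuration for the two-group synthetic resting-state generator
#'
#' Defines the study conditions the generator emulates: two groups of
#' subjects, a 27-channel prefrontal probe sampled at 25 Hz with two
#' measurement wavelengths (690/830 nm), block-structured inter-channel
#' correlation (rostral vs caudal prefrontal compartments), slow drift,
#' Mayer-wave (~0.1 Hz), respiratory (~0.3 Hz) and cardiac (~1 Hz)
#' oscillations, sparse motion spikes, and a spatial N-back task generated
#' from a signal-detection model with lognormal reaction times.
#'
#' The band-limited hemodynamic signal is drawn with an exact correlation
#' target: white noise is band-limited to 0.01-0.08 Hz, empirically whitened
#' and mixed through the Cholesky factor of the subject's target matrix, so
#' the realized channel correlations of the clean signal equal the attached
#' ground truth to machine precision. Each subject's target is the group's
#' block matrix plus symmetric edgewise heterogeneity
#' (`corr_heterogeneity_sd`), projected back to the nearest valid correlation
#' matrix; the projected matrix is the recorded ground truth.
#'
#' @param n_subjects_per_group Subjects per group.
#' @param n_channels Number of channels (default 27, the packaged probe).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param duration_s Recording duration in seconds. Must leave at least 60 s
#'   of signal after removing 15 s from each end.
#' @param block_assignment Character vector (`"rostral"`/`"caudal"`) per
#'   channel.
#' @param within_block_corr,between_block_corr Named numeric vectors
#'   (`control`, `exposed`) giving the target Pearson correlation for channel
#'   pairs in the same / in different blocks. The implied block matrix must be
#'   positive semi-definite for both groups.
#' @param corr_heterogeneity_sd SD of the per-subject edgewise jitter added to
#'   the group block matrix (individual differences in connectivity).
#' @param signal_sd_um SD of the clean band-limited HbO signal, in micromolar.
#' @param noise_amplitudes Named non-negative amplitudes (micromolar, peak) of
#'   the out-of-band contaminants: `drift` (< 0.006 Hz, independent per
#'   channel), `mayer` (~0.1 Hz), `respiration` (~0.3 Hz) and `cardiac`
#'   (~1 Hz); the three oscillations are spatially global (shared frequency,
#'   channel-specific amplitude and phase), the regime the PCA stage targets.
#' @param spike_rate_per_min Poisson rate of motion spikes per channel.
#' @param spike_amplitude_sd SD of spike amplitudes (micromolar); spikes decay
#'   exponentially with a 0.3 s time constant (the sharp, sub-second
#'   transient profile wavelet motion correction targets).
#' @param behavior_dprime Numeric length-3 vector of signal-detection d'
#'   values for the 0-/1-/2-back conditions (same for both groups; the study
#'   design expects no behavioral group difference).
#' @param behavior_criterion Signal-detection response criterion c.
#' @param rt_meanlog,rt_sdlog Lognormal reaction-time parameters per condition
#'   (`rt_meanlog` length 3, log-milliseconds).
#' @param response_window_ms Response window; simulated RTs exceeding it
#'   become non-responses.
#' @param seed Integer seed used by [simulate_cohort()].
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_subjects_per_group = 15L,
                              n_channels = 27L,
                              sampling_rate_hz = 25,
                              duration_s = 480,
                              block_assignment = default_block_assignment(n_channels),
                              within_block_corr = c(control = 0.60, exposed = 0.45),
                              between_block_corr = c(control = 0.15, exposed = 0.30),
                              corr_heterogeneity_sd = 0.10,
                              signal_sd_um = 1,
                              noise_amplitudes = c(drift = 1, mayer = 2.5,
                                                   respiration = 2, cardiac = 5),
                              spike_rate_per_min = 2,
                              spike_amplitude_sd = 10,
                              behavior_dprime = c(3.2, 2.9, 2.4),
                              behavior_criterion = 0.25,
                              rt_meanlog = log(c(450, 530, 700)),
                              rt_sdlog = 0.25,
                              response_window_ms = 1500,
                              seed = NULL) {
  stopifnot(n_subjects_per_group >= 1, n_channels >= 2,
            sampling_rate_hz > 0, duration_s > 0,
            length(block_assignment) == n_channels,
            all(block_assignment %in% c("rostral", "caudal")),
            corr_heterogeneity_sd >= 0, signal_sd_um > 0,
            all(noise_amplitudes >= 0), spike_rate_per_min >= 0,
            spike_amplitude_sd >= 0,
            length(behavior_dprime) == 3, length(rt_meanlog) == 3,
            rt_sdlog > 0, response_window_ms > 0)
  groups <- c("control", "exposed")
  if (!all(groups %in% names(within_block_corr)) ||
      !all(groups %in% names(between_block_corr)))
    stop("within_block_corr and between_block_corr need 'control' and 'exposed' entries")
  if (any(within_block_corr < 0 | within_block_corr >= 1) ||
      any(between_block_corr < 0 | between_block_corr >= 1))
    stop("block correlations must lie in [0, 1)")
  if (duration_s - 30 < 60)
    stop("duration_s must leave >= 60 s after trimming 15 s from each end")
  cfg <- list(n_subjects_per_group = as.integer(n_subjects_per_group),
              n_channels = as.integer(n_channels),
              sampling_rate_hz = sampling_rate_hz,
              duration_s = duration_s,
              block_assignment = block_assignment,
              within_block_corr = within_block_corr[groups],
              between_block_corr = between_block_corr[groups],
              corr_heterogeneity_sd = corr_heterogeneity_sd,
              signal_sd_um = signal_sd_um,
              noise_amplitudes = noise_amplitudes,
              spike_rate_per_min = spike_rate_per_min,
              spike_amplitude_sd = spike_amplitude_sd,
              behavior_dprime = behavior_dprime,
              behavior_criterion = behavior_criterion,
              rt_meanlog = rt_meanlog,
              rt_sdlog = rt_sdlog,
              response_window_ms = response_window_ms,
              seed = seed)
  class(cfg) <- "simulation_config"
  # the block target must be a valid correlation matrix for both groups
  for (g in groups) {
    ev <- min(eigen(target_correlation(cfg, g), symmetric = TRUE,
                    only.values = TRUE)$values)
    if (ev < -1e-8)
      stop(sprintf("target correlation for group '%s' is not positive semi-definite (min eigenvalue %.3g)",
                   g, ev))
  }
  cfg
}

#' Group-level block target correlation matrix
#'
#' @param config A [simulation_config()].
#' @param group `"control"` or `"exposed"`.
#' @return The `n_channels` x `n_channels` block correlation matrix.
#' @export
target_correlation <- function(config, group = c("control", "exposed")) {
  group <- match.arg(group)
  same <- outer(config$block_assignment, config$block_assignment, "==")
  r <- ifelse(same, config$within_block_corr[[group]],
              config$between_block_corr[[group]])
  diag(r) <- 1
  r
}

# Per-subject target: group block matrix + symmetric edgewise jitter,
# eigenvalue-clipped back to a valid correlation matrix.
subject_target_correlation <- function(config, group) {
  r <- target_correlation(config, group)
  h <- config$corr_heterogeneity_sd
  if (h > 0) {
    n <- nrow(r)
    e <- matrix(0, n, n)
    e[upper.tri(e)] <- rnorm(n * (n - 1) / 2, sd = h)
    r <- r + e + t(e)
    for (k in 1:3) {
      eg <- eigen(r, symmetric = TRUE)
      if (min(eg$values) >= 1e-8 && all(abs(diag(r) - 1) < 1e-12)) break
      vals <- pmax(eg$values, 1e-6)
      r <- eg$vectors %*% (vals * t(eg$vectors))
      d <- sqrt(diag(r))
      r <- r / outer(d, d)
      diag(r) <- 1
    }
    r <- (r + t(r)) / 2
  }
  r
}

#' Simulate band-limited hemodynamic (HbO) series with known connectivity
#'
#' Draws per-subject channels x time HbO concentration-change series whose
#' clean component has exactly the subject's ground-truth correlation matrix
#' (band-limited to 0.01-0.08 Hz), then adds the configured physiological
#' oscillations, slow drift and exponentially decaying motion spikes. HbR is
#' generated as a scaled mirror of the clean HbO (the generator targets HbO
#' covariance, not chromophore biophysics).
#'
#' @param config A [simulation_config()].
#' @param group Group label.
#' @param n Number of subjects (default `config$n_subjects_per_group`).
#' @return A list of length `n`; each element has `hbo`, `hbr` (channels x
#'   time, micromolar), `clean_hbo` (before noise), `target_corr` (the exact
#'   ground-truth correlation of `clean_hbo`), `group` and `sampling_rate_hz`.
#'   Uses the current RNG state; seed via [set.seed()] or [simulate_cohort()].
#' @export
simulate_hemodynamics <- function(config, group = c("control", "exposed"),
                                  n = config$n_subjects_per_group) {
  group <- match.arg(group)
  fs <- config$sampling_rate_hz
  nt <- round(config$duration_s * fs)
  nc <- config$n_channels
  lapply(seq_len(n), function(i) {
    r_subj <- subject_target_correlation(config, group)
    white <- matrix(rnorm(nc * nt), nc, nt)
    # Band-limit with the analysis band's response. White noise is
    # stationary, so plain circular filtering is unbiased here (the mirror
    # extension the preprocessing filter uses guards against slow-component
    # edge jumps, which white noise does not have); one forward FFT serves
    # both the single-pass signal and the double-pass whitening reference.
    gain <- butter_band_gain(nt, fs, 0.01, 0.08)
    np <- nc %/% 2
    band <- matrix(0, nc, nt)
    if (np > 0) {   # pack row pairs as complex; gain is real-symmetric
      xf <- mvfft(t(white[2 * seq_len(np) - 1, , drop = FALSE] +
                      1i * white[2 * seq_len(np), , drop = FALSE]))
      z1 <- mvfft(xf * gain, inverse = TRUE) / nt
      band[2 * seq_len(np) - 1, ] <- t(Re(z1))
      band[2 * seq_len(np), ] <- t(Im(z1))
    }
    if (nc %% 2 == 1) {
      xf1 <- fft(white[nc, ])
      band[nc, ] <- Re(fft(xf1 * gain, inverse = TRUE)) / nt
    }
    band <- band - rowMeans(band)
    # Whiten against the re-filtered central analysis window (the 15 s edge
    # trim and the 0.01-0.08 Hz band applied the way the preprocessing
    # filter applies them), so the ground-truth correlation is realized
    # exactly on the series a standard linear preprocessing path extracts.
    # A band-limited window carries about 2 * bandwidth * T independent
    # spectral coordinates; when that falls near or below the channel count
    # (short recordings) the window covariance is rank-deficient and exact
    # whitening is ill-posed, so the generator falls back to plain
    # standardized mixing and the target is realized only up to sampling
    # error.
    k <- round(15 * fs)
    win <- if (nt - 2 * k > nc + 1) (k + 1):(nt - k) else seq_len(nt)
    ref <- fft_bandpass_matrix(band[, win, drop = FALSE], fs, 0.01, 0.08)
    ref <- ref - rowMeans(ref)
    cv <- tcrossprod(ref) / (ncol(ref) - 1)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    exact <- ev[nc] > 1e-8 * ev[1]
    z <- if (exact) forwardsolve(t(chol(cv)), band)
         else band / sqrt(rowMeans(band^2))
    cu <- chol(r_subj + diag(1e-10, nc))
    hbo <- config$signal_sd_um * crossprod(cu, z)
    clean <- hbo
    hbo <- hbo + simulate_noise(config, nc, nt, fs)
    list(hbo = hbo, hbr = -clean / 3, clean_hbo = clean,
         target_corr = r_subj, target_exact = exact,
         group = group, sampling_rate_hz = fs)
  })
}

# Drift + global physiological oscillations + motion spikes, channels x time.
simulate_noise <- function(config, nc, nt, fs) {
  amp <- config$noise_amplitudes
  tt <- (seq_len(nt) - 1) / fs
  noise <- matrix(0, nc, nt)
  if (amp[["drift"]] > 0) {
    for (k in 1:2) {
      f <- runif(nc, 0.001, 0.006)
      ph <- runif(nc, 0, 2 * pi)
      noise <- noise + amp[["drift"]] *
        sin(outer(2 * pi * f, tt) + ph)
    }
  }
  freqs <- c(mayer = 0.1, respiration = 0.3, cardiac = 1.0)
  for (nm in names(freqs)) {
    if (amp[[nm]] <= 0) next
    f <- freqs[[nm]] * runif(1, 0.9, 1.1)      # subject-specific frequency
    ach <- amp[[nm]] * runif(nc, 0.5, 1.5)     # channel-specific gain
    # systemic oscillations cross the small prefrontal patch near-coherently:
    # one global phase plus small channel lags, i.e. a low-rank spatial
    # component of the kind the PCA stage removes
    ph <- runif(1, 0, 2 * pi) + rnorm(nc, 0, 0.3)
    st <- sin(2 * pi * f * tt); ct <- cos(2 * pi * f * tt)
    noise <- noise + (ach * cos(ph)) %o% st + (ach * sin(ph)) %o% ct
  }
  if (config$spike_rate_per_min > 0 && config$spike_amplitude_sd > 0) {
    tau <- 0.3 * fs                            # decay constant, samples
    lam <- config$spike_rate_per_min * nt / fs / 60
    for (ch in seq_len(nc)) {
      nsp <- rpois(1, lam)
      if (nsp == 0) next
      t0 <- sample.int(nt, nsp, replace = TRUE)
      a <- rnorm(nsp, 0, config$spike_amplitude_sd)
      for (s in seq_len(nsp)) {
        idx <- t0[s]:nt
        noise[ch, idx] <- noise[ch, idx] + a[s] * exp(-(idx - t0[s]) / tau)
      }
    }
  }
  noise
}

#' Forward model: hemoglobin concentrations to raw light intensities
#'
#' Applies the modified Beer-Lambert law in the forward direction: optical
#' density changes at both wavelengths from the HbO/HbR series, then
#' intensities `I = I0 * exp(-dOD)`. Inverting with [od_to_hemoglobin()] and
#' the same optics recovers the input up to a constant per channel (optical
#' density downstream is referenced to each channel's mean intensity, so
#' concentration changes are recovered relative to their own mean).
#'
#' @param hemo A list with `hbo` and `hbr` (channels x time, micromolar) and
#'   `sampling_rate_hz`, e.g. one element of [simulate_hemodynamics()].
#' @param optics Optical constants, see [optics_defaults()].
#' @param subject_id,group,covariates Metadata stored on the record.
#' @return A `fnirs_raw` object: list with `intensity` (wavelength x channel x
#'   time array), `wavelengths_nm`, `sampling_rate_hz`, `subject_id`, `group`,
#'   `covariates`.
#' @export
hemodynamics_to_intensity <- function(hemo, optics = optics_defaults(),
                                      subject_id = "sim", group = hemo$group,
                                      covariates = list()) {
  m <- mbll_matrix(optics)
  conc_mM <- rbind(as.vector(hemo$hbo), as.vector(hemo$hbr)) / 1000
  od <- m %*% conc_mM                      # wavelength x (channel*time)
  nc <- nrow(hemo$hbo); nt <- ncol(hemo$hbo)
  i0 <- optics$baseline_intensity
  intensity <- array(0, dim = c(2, nc, nt),
                     dimnames = list(rownames(optics$extinction), NULL, NULL))
  intensity[1, , ] <- i0 * exp(-matrix(od[1, ], nc, nt))
  intensity[2, , ] <- i0 * exp(-matrix(od[2, ], nc, nt))
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("forward model produced non-positive intensities; reduce concentration range")
  structure(list(intensity = intensity,
                 wavelengths_nm = as.numeric(rownames(optics$extinction)),
                 sampling_rate_hz = hemo$sampling_rate_hz,
                 subject_id = subject_id, group = group,
                 covariates = covariates),
            class = "fnirs_raw")
}

#' Simulate spatial N-back trial tables
#'
#' Generates per-trial outcomes of the blocked spatial N-back task (three
#' conditions, by default 5 blocks of 15 trials each) from a Gaussian
#' equal-variance signal-detection model: on target trials the probability of
#' a "yes" response is `pnorm(dprime/2 - criterion)`, on non-target trials
#' `pnorm(-dprime/2 - criterion)`. Reaction times are lognormal per condition;
#' trials whose RT exceeds the response window become non-responses.
#'
#' @param config A [simulation_config()].
#' @param group Group label (behavior parameters are shared across groups).
#' @param subject_id Subject identifier.
#' @param n_blocks,n_trials_per_block Task structure.
#' @param p_target Probability a trial is a target.
#' @return A data frame with columns `subject_id`, `condition` (`"0-back"`,
#'   `"1-back"`, `"2-back"`), `block`, `trial_index`, `is_target`, `response`
#'   (`"yes"`, `"no"`, `"none"`) and `rt_ms` (`NA` iff `response == "none"`).
#' @export
simulate_behavior <- function(config, group = c("control", "exposed"),
                              subject_id = "sim", n_blocks = 5L,
                              n_trials_per_block = 15L, p_target = 1 / 3) {
  group <- match.arg(group)
  conditions <- c("0-back", "1-back", "2-back")
  out <- lapply(seq_along(conditions), function(ci) {
    d <- config$behavior_dprime[ci]
    cc <- config$behavior_criterion
    stopifnot(is.finite(d), is.finite(cc))
    ntr <- n_blocks * n_trials_per_block
    is_target <- runif(ntr) < p_target
    p_yes <- ifelse(is_target, pnorm(d / 2 - cc), pnorm(-d / 2 - cc))
    says_yes <- runif(ntr) < p_yes
    rt <- rlnorm(ntr, config$rt_meanlog[ci], config$rt_sdlog)
    responded <- rt <= config$response_window_ms
    response <- ifelse(!responded, "none", ifelse(says_yes, "yes", "no"))
    data.frame(subject_id = subject_id, condition = conditions[ci],
               block = rep(seq_len(n_blocks), each = n_trials_per_block),
               trial_index = seq_len(ntr), is_target = is_target,
               response = response,
               rt_ms = ifelse(responded, rt, NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a full two-group cohort
#'
#' Draws, for every subject in both groups: the hemodynamic ground truth, the
#' raw two-wavelength intensity record (forward Beer-Lambert model), the
#' N-back trial table, and covariates (age in years, Raven's Progressive
#' Matrices score).
#'
#' @param config A [simulation_config()]; `config$seed` (if non-NULL) seeds
#'   the draw so cohorts are exactly reproducible.
#' @return A `fnirs_cohort` object: list with `config` and `subjects`, each
#'   subject a list with `subject_id`, `group`, `raw`, `hemo_truth`,
#'   `behavior` and `covariates`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  subjects <- list()
  for (group in c("control", "exposed")) {
    for (i in seq_len(config$n_subjects_per_group)) {
      sid <- sprintf("%s%02d", if (group == "control") "ctl" else "exp", i)
      hemo <- simulate_hemodynamics(config, group, n = 1)[[1]]
      covariates <- list(age = round(rnorm(1, 20.3, 0.7), 1),
                         rpm_score = max(10L, min(120L, round(rnorm(1, 59, 28)))))
      raw <- hemodynamics_to_intensity(hemo, subject_id = sid, group = group,
                                       covariates = covariates)
      behavior <- simulate_behavior(config, group, subject_id = sid)
      subjects[[sid]] <- list(subject_id = sid, group = group, raw = raw,
                              hemo_truth = hemo, behavior = behavior,
                              covariates = covariates)
    }
  }
  structure(list(config = config, subjects = subjects), class = "fnirs_cohort")
}
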