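# Preprocessing: raw two-wavelength intensity -> motion-corrected, denoised,
# band-limited HbO/HbR concentration changes, in the fixed order
# trim -> optical density -> wavelet -> PCA -> bandpass -> Beer-Lambert.

#' Default optical constants for the modified Beer-Lambert law
#'
#' Extinction coefficients (per mM per cm) of HbO and HbR at 690 and 830 nm
#' from the standard literature compilation used by fNIRS toolboxes, a
#' differential pathlength factor of 6.0 at both wavelengths, 3 cm
#' source-detector separation and unit baseline intensity.
#'
#' @return A list with `extinction` (2 x 2 matrix, wavelengths x
#'   `c("HbO","HbR")`), `dpf`, `distance_cm`, `baseline_intensity`.
#' @export
optics_defaults <- function() {
  list(extinction = matrix(c(0.276, 2.0520,
                             0.974, 0.6930), 2, 2, byrow = TRUE,
                           dimnames = list(c("690", "830"), c("HbO", "HbR"))),
       dpf = c(6, 6), distance_cm = 3, baseline_intensity = 1)
}

# 2x2 system relating chromophore concentration (mM) to OD change.
mbll_matrix <- function(optics) {
  m <- optics$extinction * optics$dpf * optics$distance_cm
  if (abs(det(m)) < 1e-12)
    stop("extinction matrix is singular; wavelengths do not separate HbO/HbR")
  m
}

# Zero-phase frequency-domain bandpass with the magnitude response of a
# forward-backward (filtfilt) 3rd-order Butterworth: gain |H(f)|^2 =
# 1 / (1 + Omega^(2*order)) with Omega = (f^2 - lo*hi) / (f * (hi - lo)).
# The series is mirror-extended (even extension) before the FFT so the
# implied circular signal is continuous at the boundaries; otherwise the
# end-to-start jump of large slow components leaks broadband energy into
# the passband.
butter_band_gain <- function(nt, fs, low_hz, high_hz, order = 3) {
  f <- (seq_len(nt) - 1) / nt * fs
  f <- pmin(f, fs - f)
  om <- (f^2 - low_hz * high_hz) / (pmax(f, 1e-12) * (high_hz - low_hz))
  gain <- 1 / (1 + om^(2 * order))
  gain[f <= 0] <- 0
  gain
}

fft_bandpass_matrix <- function(x, fs, low_hz, high_hz, order = 3) {
  nt_orig <- ncol(x)
  x <- cbind(x, x[, rev(seq_len(nt_orig)), drop = FALSE])
  nt <- ncol(x)
  gain <- butter_band_gain(nt, fs, low_hz, high_hz, order)
  # the gain is real and symmetric, so two real rows can share one complex
  # transform (row pair packed as re + i*im)
  nr <- nrow(x)
  np <- nr %/% 2
  out <- matrix(0, nr, nt_orig)
  if (np > 0) {
    z <- t(x[2 * seq_len(np) - 1, , drop = FALSE] +
             1i * x[2 * seq_len(np), , drop = FALSE])
    zf <- mvfft(mvfft(z) * gain, inverse = TRUE) / nt
    out[2 * seq_len(np) - 1, ] <- t(Re(zf))[, seq_len(nt_orig), drop = FALSE]
    out[2 * seq_len(np), ] <- t(Im(zf))[, seq_len(nt_orig), drop = FALSE]
  }
  if (nr %% 2 == 1) {
    zf <- fft(fft(x[nr, ]) * gain, inverse = TRUE) / nt
    out[nr, ] <- Re(zf)[seq_len(nt_orig)]
  }
  out
}

# extract wavelength plane w as a channels x time matrix (robust to nc = 1)
wl_plane <- function(arr, w) {
  matrix(arr[w, , ], dim(arr)[2], dim(arr)[3])
}

# apply a channels-x-time operation to both wavelength planes stacked once
apply_stacked <- function(arr, fun) {
  nc <- dim(arr)[2]
  x <- rbind(wl_plane(arr, 1), wl_plane(arr, 2))
  out <- fun(x)
  arr[1, , ] <- out[seq_len(nc), , drop = FALSE]
  arr[2, , ] <- out[nc + seq_len(nc), , drop = FALSE]
  arr
}

#' Trim the unstable edges of a recording
#'
#' Removes the first and last `trim_s` seconds, the conventional guard against
#' start-up and end-of-session instability.
#'
#' @param x A channels x time matrix, a wavelength x channel x time array, or
#'   a `fnirs_raw` record.
#' @param trim_s Seconds to drop from each end.
#' @param sampling_rate_hz Sampling rate; taken from `x` when it is a
#'   `fnirs_raw` record.
#' @return The trimmed object, same type as the input; length is reduced by
#'   `2 * round(trim_s * sampling_rate_hz)` samples.
#' @export
trim_edges <- function(x, trim_s = 15, sampling_rate_hz = NULL) {
  if (inherits(x, "fnirs_raw")) {
    x$intensity <- trim_edges(x$intensity, trim_s, x$sampling_rate_hz)
    return(x)
  }
  stopifnot(!is.null(sampling_rate_hz), trim_s >= 0)
  k <- round(trim_s * sampling_rate_hz)
  nt <- if (is.matrix(x)) ncol(x) else dim(x)[3]
  if (nt <= 2 * k)
    stop(sprintf("series too short to trim: %d samples, need > %d", nt, 2 * k))
  keep <- seq.int(k + 1, nt - k)
  if (is.matrix(x)) x[, keep, drop = FALSE] else x[, , keep, drop = FALSE]
}

#' Convert raw intensities to optical density changes
#'
#' `dOD(t) = -log(I(t) / mean(I))` per channel and wavelength.
#'
#' @param raw A `fnirs_raw` record with strictly positive intensities.
#' @return An `od_series` object: list with `od` (wavelength x channel x time
#'   array of unitless OD changes), `sampling_rate_hz` and subject metadata.
#' @export
intensity_to_od <- function(raw) {
  stopifnot(inherits(raw, "fnirs_raw"))
  bad <- which(apply(raw$intensity <= 0, 2, any))
  if (length(bad))
    stop("non-positive intensity in channel(s): ", paste(bad, collapse = ", "))
  od <- raw$intensity
  for (w in 1:2) {
    plane <- wl_plane(raw$intensity, w)
    od[w, , ] <- -log(plane / rowMeans(plane))
  }
  structure(list(od = od, sampling_rate_hz = raw$sampling_rate_hz,
                 wavelengths_nm = raw$wavelengths_nm,
                 subject_id = raw$subject_id, group = raw$group,
                 covariates = raw$covariates),
            class = "od_series")
}

#' Wavelet motion-artifact correction
#'
#' Per channel, a periodic Daubechies-2 discrete wavelet decomposition;
#' detail coefficients falling outside the outlier fences of their own level
#' and channel (quartiles +/- `iqr_factor` times the interquartile range,
#' the boxplot rule used by the standard fNIRS implementation) are set to
#' zero, and the series is reconstructed. Sharp transients (motion spikes)
#' concentrate in few large detail coefficients and are removed; smooth
#' in-band signal passes through essentially unchanged.
#'
#' @param x A channels x time matrix, wavelength x channel x time array, or
#'   `od_series`.
#' @param iqr_factor Outlier multiplier (default 1.5).
#' @param levels Decomposition depth; default `floor(log2(T)) - 4` capped at
#'   8. Levels with fewer than 32 coefficients are never thresholded: the
#'   quartile fences cannot be estimated from a handful of coefficients, and
#'   those deep levels carry the slow hemodynamics, not motion transients.
#' @return Corrected object of the same type as the input.
#' @export
wavelet_motion_correct <- function(x, iqr_factor = 1.5, levels = NULL) {
  if (inherits(x, "od_series")) {
    x$od <- apply_stacked(x$od, function(m)
      wavelet_motion_correct(m, iqr_factor, levels))
    return(x)
  }
  if (is.array(x) && length(dim(x)) == 3) {
    for (w in seq_len(dim(x)[1]))
      x[w, , ] <- wavelet_motion_correct(wl_plane(x, w), iqr_factor, levels)
    return(x)
  }
  stopifnot(is.matrix(x))
  nt <- ncol(x)
  if (is.null(levels)) levels <- max(1L, min(8L, floor(log2(nt)) - 4L))
  if (nt < 2^levels) return(x)
  xp <- reflect_pad(x, 2^levels)
  rec <- wavelet_correct_cpp(xp, levels, iqr_factor, 32L)
  rec[, seq_len(nt), drop = FALSE]
}

#' Remove global components by principal component analysis
#'
#' Decomposes the channels x time data across the channel dimension and
#' projects out the leading principal components: the largest `k` such that
#' at least one component is removed and the cumulative explained variance of
#' the removed set does not exceed `variance_threshold` (the convention of
#' the Homer-style global-noise filter; set `mode = "reach"` for the
#' alternative reading that removes components until the threshold is
#' reached). Global physiological noise -- shared across channels -- lives in
#' the leading components; the residual keeps the spatially diverse signal.
#'
#' @param x A channels x time matrix, wavelength x channel x time array, or
#'   `od_series`.
#' @param variance_threshold Fraction of variance in (0, 1); `NULL` or 0
#'   disables the stage (identity).
#' @param mode `"under"` (default: removed set stays at or under the
#'   threshold, at least one component) or `"reach"` (smallest set whose
#'   cumulative variance reaches the threshold).
#' @return Denoised object of the same type as the input.
#' @export
pca_global_denoise <- function(x, variance_threshold = 0.8,
                               mode = c("under", "reach")) {
  mode <- match.arg(mode)
  if (is.null(variance_threshold) || variance_threshold == 0) return(x)
  if (variance_threshold < 0 || variance_threshold >= 1)
    stop("variance_threshold must lie in (0, 1) or be NULL/0 to disable")
  if (inherits(x, "od_series")) {
    # both wavelength planes share one decomposition (the global component
    # is one physiological process seen at both wavelengths)
    x$od <- apply_stacked(x$od, function(m)
      pca_global_denoise(m, variance_threshold, mode))
    return(x)
  }
  if (is.array(x) && length(dim(x)) == 3) {
    for (w in seq_len(dim(x)[1]))
      x[w, , ] <- pca_global_denoise(wl_plane(x, w), variance_threshold, mode)
    return(x)
  }
  stopifnot(is.matrix(x), nrow(x) >= 2)
  mu <- rowMeans(x)
  xc <- x - mu
  cv <- tcrossprod(xc) / (ncol(x) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  cum <- cumsum(eg$values) / sum(eg$values)
  k <- if (mode == "under") max(1L, sum(cum <= variance_threshold))
       else which(cum >= variance_threshold)[1]
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  xc - v %*% crossprod(v, xc) + mu
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain filter with the magnitude response of a forward-backward
#' 3rd-order Butterworth band-pass (zero phase by construction). DC and slow
#' drift (`< low_hz`) and high-frequency physiology (`> high_hz`) are
#' suppressed; the passband is essentially unity gain.
#'
#' @param x A channels x time matrix, wavelength x channel x time array, or
#'   `od_series`.
#' @param low_hz,high_hz Band edges in Hz (`high_hz` below Nyquist).
#' @param sampling_rate_hz Sampling rate; taken from `od_series` input.
#' @param order Butterworth order of the underlying single-pass design.
#' @return Filtered object of the same type as the input.
#' @export
bandpass <- function(x, low_hz = 0.01, high_hz = 0.08,
                     sampling_rate_hz = NULL, order = 3) {
  if (low_hz >= high_hz) stop("low_hz must be below high_hz")
  if (inherits(x, "od_series")) {
    fs <- x$sampling_rate_hz
    if (high_hz >= fs / 2) stop("high_hz must be below the Nyquist frequency")
    x$od <- apply_stacked(x$od, function(m)
      fft_bandpass_matrix(m, fs, low_hz, high_hz, order))
    return(x)
  }
  stopifnot(!is.null(sampling_rate_hz))
  if (high_hz >= sampling_rate_hz / 2)
    stop("high_hz must be below the Nyquist frequency")
  if (is.array(x) && length(dim(x)) == 3) {
    for (w in seq_len(dim(x)[1]))
      x[w, , ] <- fft_bandpass_matrix(wl_plane(x, w), sampling_rate_hz,
                                      low_hz, high_hz, order)
    return(x)
  }
  stopifnot(is.matrix(x))
  fft_bandpass_matrix(x, sampling_rate_hz, low_hz, high_hz, order)
}

#' Optical density to hemoglobin concentration changes
#'
#' Inverts the modified Beer-Lambert law: per channel and time point the
#' 2 x 2 system `dOD = E * d * DPF * dC` is solved for the HbO/HbR
#' concentration changes (reported in micromolar).
#'
#' @param od An `od_series` or wavelength x channel x time array.
#' @param optics See [optics_defaults()].
#' @param sampling_rate_hz Required when `od` is a plain array.
#' @return A `hemo_series`: list with `hbo`, `hbr` (channels x time,
#'   micromolar), `sampling_rate_hz`, metadata and `processing_log`.
#' @export
od_to_hemoglobin <- function(od, optics = optics_defaults(),
                             sampling_rate_hz = NULL) {
  meta <- list(subject_id = NULL, group = NULL, covariates = NULL)
  if (inherits(od, "od_series")) {
    meta <- od[c("subject_id", "group", "covariates")]
    sampling_rate_hz <- od$sampling_rate_hz
    od <- od$od
  }
  stopifnot(is.array(od), length(dim(od)) == 3, dim(od)[1] == 2,
            !is.null(sampling_rate_hz))
  m <- mbll_matrix(optics)
  nc <- dim(od)[2]; nt <- dim(od)[3]
  od2 <- rbind(as.vector(od[1, , ]), as.vector(od[2, , ]))
  conc <- solve(m, od2) * 1000          # mM -> uM
  structure(list(hbo = matrix(conc[1, ], nc, nt),
                 hbr = matrix(conc[2, ], nc, nt),
                 sampling_rate_hz = sampling_rate_hz,
                 subject_id = meta$subject_id, group = meta$group,
                 covariates = meta$covariates,
                 processing_log = list()),
            class = "hemo_series")
}

#' Full preprocessing pipeline for one subject
#'
#' Applies, in this fixed order: edge trimming, optical-density conversion,
#' wavelet motion correction, PCA removal of global physiological noise,
#' zero-phase band-pass filtering, and the modified Beer-Lambert inversion.
#' Every stage and its parameters are appended to the `processing_log` of the
#' returned series, so a run is auditable and reproducible from its output.
#'
#' @param raw A `fnirs_raw` record.
#' @param trim_s Seconds trimmed from each end (default 15).
#' @param iqr_factor Wavelet outlier multiplier (default 1.5).
#' @param wavelet_levels Decomposition depth (`NULL` = automatic).
#' @param pca_threshold PCA cumulative-variance threshold (default 0.8;
#'   `NULL` disables the stage).
#' @param pca_mode See [pca_global_denoise()].
#' @param band Band edges in Hz (default `c(0.01, 0.08)`).
#' @param optics See [optics_defaults()].
#' @return A `hemo_series` with `hbo`/`hbr` in micromolar and a complete
#'   `processing_log`.
#' @export
preprocess <- function(raw, trim_s = 15, iqr_factor = 1.5,
                       wavelet_levels = NULL, pca_threshold = 0.8,
                       pca_mode = "under", band = c(0.01, 0.08),
                       optics = optics_defaults()) {
  stopifnot(inherits(raw, "fnirs_raw"))
  log <- list()
  note <- function(step, ...) {
    log[[length(log) + 1]] <<- c(list(step = step), list(...))
  }
  x <- trim_edges(raw, trim_s)
  note("trim", trim_s = trim_s)
  od <- intensity_to_od(x)
  note("optical_density", method = "-log(I/mean(I))")
  # fast path: both wavelength planes stacked once for the matrix stages
  fs <- od$sampling_rate_hz
  nc <- dim(od$od)[2]
  m <- rbind(wl_plane(od$od, 1), wl_plane(od$od, 2))
  m <- wavelet_motion_correct(m, iqr_factor, wavelet_levels)
  note("wavelet", family = "db2", iqr_factor = iqr_factor,
       levels = if (is.null(wavelet_levels)) "auto" else wavelet_levels)
  m <- pca_global_denoise(m, pca_threshold, pca_mode)
  note("pca", variance_threshold = pca_threshold, mode = pca_mode,
       skipped = is.null(pca_threshold) || identical(pca_threshold, 0))
  if (band[2] >= fs / 2) stop("band upper edge must be below Nyquist")
  m <- fft_bandpass_matrix(m, fs, band[1], band[2])
  note("bandpass", low_hz = band[1], high_hz = band[2],
       design = "zero-phase Butterworth magnitude, order 3")
  mi <- solve(mbll_matrix(optics)) * 1000       # mM -> uM
  od1 <- m[seq_len(nc), , drop = FALSE]
  od2 <- m[nc + seq_len(nc), , drop = FALSE]
  hemo <- structure(list(hbo = mi[1, 1] * od1 + mi[1, 2] * od2,
                         hbr = mi[2, 1] * od1 + mi[2, 2] * od2,
                         sampling_rate_hz = fs,
                         subject_id = od$subject_id, group = od$group,
                         covariates = od$covariates,
                         processing_log = list()),
                    class = "hemo_series")
  note("mbll", dpf = optics$dpf, distance_cm = optics$distance_cm,
       extinction = as.vector(optics$extinction))
  hemo$processing_log <- log
  hemo
}
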