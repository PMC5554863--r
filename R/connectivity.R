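# Windowed wavelet-coherence network construction.
#
# Coherence between two series x, y is the magnitude-squared wavelet
# coherence of their analytic Morlet transforms,
#
#   R2(s, t) = |S(Wxy / s)|^2 / ( S(|Wx|^2 / s) * S(|Wy|^2 / s) ),
#
# where S smooths in time (Gaussian of width = scale) and across scale
# (boxcar of 0.6 octave), following the standard estimator used throughout
# the geophysics and neuroimaging literature. Without smoothing the ratio is
# identically 1. The layer entry is R2 averaged over all time points and over
# scales whose equivalent Fourier frequency lies in the requested band.

.morlet_freq_to_scale <- function(f, omega0 = 6) {
  (omega0 + sqrt(2 + omega0^2)) / (4 * pi * f)
}

.morlet_scales <- function(f_low, f_high, omega0 = 6, voices = 12,
                           margin_octaves = 1) {
  # one octave of margin each side so edge scales of the band are smoothed
  # with real neighbours
  s_min <- .morlet_freq_to_scale(f_high * 2^margin_octaves, omega0)
  s_max <- .morlet_freq_to_scale(f_low / 2^margin_octaves, omega0)
  n_scales <- ceiling(voices * log2(s_max / s_min)) + 1L
  s_min * 2^((seq_len(n_scales) - 1L) / voices)
}

# Analytic Morlet CWT of one series; returns n_scales x n_samples complex.
.morlet_cwt <- function(x, dt, scales, omega0 = 6) {
  n <- length(x)
  x <- x - mean(x)
  npad <- 2^ceiling(log2(n))
  if (npad < 2 * n) npad <- 2 * npad  # zero padding halves wrap-around
  xhat <- stats::fft(c(x, rep(0, npad - n)))
  k <- 2 * pi * seq(0, npad - 1) / (npad * dt)
  k[k > pi / dt] <- k[k > pi / dt] - 2 * pi / dt
  pos <- k > 0
  w <- matrix(0 + 0i, length(scales), n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- numeric(npad)
    psi[pos] <- pi^(-0.25) * sqrt(2 * pi * s / dt) *
      exp(-(s * k[pos] - omega0)^2 / 2)
    full <- stats::fft(xhat * psi, inverse = TRUE) / npad
    w[j, ] <- full[seq_len(n)]
  }
  w
}

# Renormalized moving-average convolution: edges are divided by the kernel
# mass actually inside the signal, so no energy is invented at the borders.
.conv_renorm <- function(v, kern) {
  nv <- length(v)
  nk <- length(kern)
  half <- (nk - 1L) / 2L
  padded <- c(rep(0, half), v, rep(0, half))
  ones <- c(rep(0, half), rep(1, nv), rep(0, half))
  num <- stats::filter(padded, kern, sides = 2)
  den <- stats::filter(ones, kern, sides = 2)
  idx <- half + seq_len(nv)
  as.vector(num[idx] / den[idx])
}

# Time smoothing: per scale, Gaussian kernel with sd = scale (in time units).
.smooth_time <- function(m, scales, dt) {
  out <- m
  for (j in seq_along(scales)) {
    half <- max(1L, ceiling(3 * scales[j] / dt))
    lag <- (-half):half
    kern <- exp(-(lag * dt)^2 / (2 * scales[j]^2))
    kern <- kern / sum(kern)
    if (is.complex(m)) {
      out[j, ] <- complex(real = .conv_renorm(Re(m[j, ]), kern),
                          imaginary = .conv_renorm(Im(m[j, ]), kern))
    } else {
      out[j, ] <- .conv_renorm(m[j, ], kern)
    }
  }
  out
}

# Scale smoothing: boxcar over 0.6 octave (0.6 * voices scale bins).
.smooth_scale <- function(m, voices) {
  width <- max(1L, round(0.6 * voices))
  if (width %% 2 == 0) width <- width + 1L
  kern <- rep(1, width) / width
  if (is.complex(m)) {
    re <- apply(Re(m), 2, .conv_renorm, kern = kern)
    im <- apply(Im(m), 2, .conv_renorm, kern = kern)
    matrix(complex(real = re, imaginary = im), nrow = nrow(m))
  } else {
    apply(m, 2, .conv_renorm, kern = kern)
  }
}

.smooth_ts <- function(m, scales, dt, voices) {
  .smooth_scale(.smooth_time(m, scales, dt), voices)
}

#' Cut a time-series set into ordered windows
#'
#' Contiguous slices of `length` samples starting every `step` samples, in
#' temporal order; with `step = length` the windows are non-overlapping.
#' Trailing samples that do not fill a complete window are dropped.
#'
#' @param ts a [timeseries_set()].
#' @param length samples per window (>= 8).
#' @param step samples between window starts (default `length`).
#' @param count number of windows; default: as many as fit.
#' @return a list of `timeseries_set` windows.
#' @export
window_timeseries <- function(ts, length, step = length, count = NULL) {
  stopifnot(inherits(ts, "timeseries_set"), length >= 8, step >= 1)
  s <- ncol(ts$values)
  max_count <- if (s < length) 0L else (s - length) %/% step + 1L
  if (is.null(count)) count <- max_count
  if (count < 1 || count > max_count) {
    stop("window spec does not fit: ", count, " windows of ", length,
         " samples (step ", step, ") in a series of ", s, " samples",
         call. = FALSE)
  }
  lapply(seq_len(count), function(i) {
    idx <- (i - 1L) * step + seq_len(length)
    timeseries_set(ts$values[, idx, drop = FALSE], ts$sampling_interval,
                   node_ids = ts$node_ids)
  })
}

#' Band-averaged wavelet coherence layer of one window
#'
#' Magnitude-squared wavelet coherence for every pair of series, smoothed in
#' time and scale, then averaged over all time points and over the scales
#' whose equivalent Fourier frequency lies in `[f_low, f_high]`. Returns a
#' symmetric matrix with zero diagonal (self-coherence is excluded from the
#' network) and off-diagonal entries in `[0, 1]`.
#'
#' @param ts a [timeseries_set()] (one window).
#' @param f_low,f_high band edges in Hz; `0 < f_low < f_high < ` Nyquist.
#' @param omega0 Morlet centre frequency (default 6, the field standard).
#' @param voices scale-grid density, voices per octave (default 12).
#' @return an `N x N` coherence matrix.
#' @export
wavelet_band_coherence <- function(ts, f_low = 0.06, f_high = 0.12,
                                   omega0 = 6, voices = 12) {
  stopifnot(inherits(ts, "timeseries_set"))
  dt <- ts$sampling_interval
  nyq <- 1 / (2 * dt)
  if (!(f_low > 0 && f_low < f_high && f_high < nyq)) {
    stop("need 0 < f_low < f_high < Nyquist (", signif(nyq, 4), " Hz)",
         call. = FALSE)
  }
  x <- ts$values
  n <- nrow(x)
  ns <- ncol(x)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant (zero-variance) series for node ",
         paste(ts$node_ids[sds == 0], collapse = ", "), call. = FALSE)
  }
  if (ns * dt < 3 / f_low) {
    warning("window holds fewer than 3 cycles of f_low; coherence estimates ",
            "will be poorly resolved", call. = FALSE)
  }
  scales <- .morlet_scales(f_low, f_high, omega0, voices)
  freqs <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi * scales)
  in_band <- freqs >= f_low & freqs <= f_high
  cwt <- lapply(seq_len(n), function(i) .morlet_cwt(x[i, ], dt, scales,
                                                    omega0))
  spow <- lapply(cwt, function(w) .smooth_ts(Mod(w)^2 / scales, scales, dt,
                                             voices))
  layer <- matrix(0, n, n, dimnames = list(ts$node_ids, ts$node_ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cross <- .smooth_ts(cwt[[i]] * Conj(cwt[[j]]) / scales, scales, dt,
                          voices)
      r2 <- Mod(cross)^2 / (spow[[i]] * spow[[j]])
      r2 <- pmin(pmax(r2, 0), 1)
      layer[i, j] <- layer[j, i] <- mean(r2[in_band, ])
    }
  }
  layer
}

#' Build a multilayer coherence network from a time-series set
#'
#' Windows the series with [window_timeseries()] and computes one
#' [wavelet_band_coherence()] layer per window; layer `t` corresponds to
#' window `t`.
#'
#' @inheritParams window_timeseries
#' @inheritParams wavelet_band_coherence
#' @return a [multilayer_network()] in `"coherence"` mode.
#' @export
build_multilayer <- function(ts, length = 80, step = length, count = NULL,
                             f_low = 0.06, f_high = 0.12, omega0 = 6,
                             voices = 12) {
  windows <- window_timeseries(ts, length, step, count)
  layers <- lapply(windows, wavelet_band_coherence, f_low = f_low,
                   f_high = f_high, omega0 = omega0, voices = voices)
  multilayer_network(layers, node_ids = ts$node_ids, mode = "coherence")
}
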