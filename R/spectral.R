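#' Spectral estimate container
#'
#' One-sided frequency grid plus per-frequency values (real power, complex
#' cross-spectrum or transfer function, or squared coherence) with the
#' segment-averaging metadata.
#'
#' @param frequencies nonnegative, uniform frequency grid in Hz.
#' @param values per-frequency values.
#' @param n_segments number of averaged segments.
#' @param segment_length segment length in samples.
#' @param overlap overlap fraction.
#' @param window window name.
#' @param kind label such as "psd", "csd", "transfer", "coherence".
#' @export
spectral_estimate <- function(frequencies, values, n_segments,
                              segment_length, overlap, window,
                              kind = "psd") {
  stopifnot(length(frequencies) == length(values), all(frequencies >= 0))
  structure(list(frequencies = frequencies, values = values,
                 n_segments = n_segments, segment_length = segment_length,
                 overlap = overlap, window = window, kind = kind),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf(
    "<spectral_estimate:%s> %d bins, 0..%.5g Hz, %d segments of %d samples\n",
    x$kind, length(x$frequencies), max(x$frequencies), x$n_segments,
    x$segment_length))
  invisible(x)
}

## periodic Hann window (DFT-even), the standard choice for Welch averaging
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

## nearest power of two (log scale) to about 1 s of samples, capped by n
default_segment_length <- function(rate, n) {
  p <- round(log2(rate))
  min(2^p, 2^floor(log2(n)))
}

#' Welch-averaged auto- and cross-spectra
#'
#' Splits the stimulus `x` and each response trial into overlapping
#' segments (about 1 s each by default, matching the nearest power of two
#' in samples), de-trends each segment by subtracting its mean, applies a
#' Hann window, and averages periodograms over all segments of all trials.
#'
#' Cross-spectrum convention: `Pxy = <conj(X) Y>`, so the phase of `Pxy`
#' is the phase of `y` relative to `x`; a response that lags the stimulus
#' by `d` seconds has phase slope `-2 pi d` over frequency.
#'
#' @param x stimulus as a `sampled_signal`.
#' @param y_trials response trial(s): a `sampled_signal` or list of them,
#'   each sharing grid and rate with `x`.
#' @param segment_length samples per segment (default: nearest power of two
#'   to one second).
#' @param overlap overlap fraction in `[0, 1)`.
#' @param window window name; `"hann"` or `"rect"`.
#' @return list of `spectral_estimate`s `pxx`, `pyy`, `pxy` (one-sided
#'   densities; `pxy` complex).
#' @export
welch_spectra <- function(x, y_trials, segment_length = NULL, overlap = 0.5,
                          window = "hann") {
  if (inherits(y_trials, "sampled_signal")) y_trials <- list(y_trials)
  n <- length(x$values)
  fs <- x$rate
  for (y in y_trials)
    if (y$rate != fs || length(y$values) != n)
      stop("stimulus and responses must share sampling rate and length")
  if (is.null(segment_length)) segment_length <- default_segment_length(fs, n)
  L <- as.integer(segment_length)
  if (L > n) stop("signal shorter than one segment")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq.int(1L, n - L + 1L, by = step)
  win <- switch(match.arg(window, c("hann", "rect")),
                hann = hann_window(L), rect = rep(1, L))
  scale <- 1 / (fs * sum(win^2))
  nf <- L %/% 2L + 1L
  keep <- seq_len(nf)

  X <- lapply(starts, function(s) {
    seg <- x$values[s:(s + L - 1L)]
    fft((seg - mean(seg)) * win)[keep]
  })
  sxx <- syy <- numeric(nf)
  sxy <- complex(real = rep(0, nf), imaginary = rep(0, nf))
  nseg <- 0L
  for (y in y_trials) {
    for (j in seq_along(starts)) {
      s <- starts[j]
      seg <- y$values[s:(s + L - 1L)]
      Y <- fft((seg - mean(seg)) * win)[keep]
      sxx <- sxx + Mod(X[[j]])^2
      syy <- syy + Mod(Y)^2
      sxy <- sxy + Conj(X[[j]]) * Y
      nseg <- nseg + 1L
    }
  }
  one_sided <- rep(2, nf)
  one_sided[1L] <- 1
  if (L %% 2L == 0L) one_sided[nf] <- 1
  freq <- (keep - 1L) * fs / L
  mk <- function(v, kind)
    spectral_estimate(freq, v * one_sided * scale / nseg, nseg, L, overlap,
                      window, kind)
  list(pxx = mk(sxx, "psd"), pyy = mk(syy, "psd"), pxy = mk(sxy, "csd"))
}

#' Transfer function between stimulus and response
#'
#' `H(f) = Pxy(f) / Pxx(f)` from Welch-averaged spectra; `Mod(H)` is the
#' gain in response units per stimulus unit.  Frequencies with stimulus
#' power below `guard` times the peak stimulus power are masked (NA).
#'
#' @inheritParams welch_spectra
#' @param guard relative stimulus-power floor for the division.
#' @return A complex-valued `spectral_estimate` of kind `"transfer"`.
#' @export
transfer_function <- function(x, y_trials, segment_length = NULL,
                              overlap = 0.5, window = "hann",
                              guard = 1e-10) {
  sp <- welch_spectra(x, y_trials, segment_length, overlap, window)
  h <- sp$pxy$values / sp$pxx$values
  h[sp$pxx$values < guard * max(sp$pxx$values)] <- NA
  out <- sp$pxy
  out$values <- h
  out$kind <- "transfer"
  out
}

#' Stimulus-response coherence
#'
#' Squared coherence
#' \deqn{\gamma^2(f) = \frac{|P_{xy}(f)|^2}{P_{xx}(f) P_{yy}(f)} \in [0,1]}
#' from Welch-averaged spectra pooled across segments and trials.
#'
#' @inheritParams welch_spectra
#' @return A `spectral_estimate` of kind `"coherence"`.
#' @export
coherence <- function(x, y_trials, segment_length = NULL, overlap = 0.5,
                      window = "hann") {
  sp <- welch_spectra(x, y_trials, segment_length, overlap, window)
  denom <- sp$pxx$values * sp$pyy$values
  g <- numeric(length(denom))
  ok <- denom > 0
  g[ok] <- Mod(sp$pxy$values[ok])^2 / denom[ok]
  g <- pmin(pmax(g, 0), 1)
  out <- sp$pxy
  out$values <- g
  out$kind <- "coherence"
  out
}

## trapezoidal integral on the (uniform or not) grid
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Lower-bound mutual information rate
#'
#' Linear-decoding lower bound on the mutual information between stimulus
#' and response,
#' \deqn{MI = -\int_{f_{low}}^{f_{high}} \log_2(1 - \gamma^2(f))\, df}
#' in bit/s, by trapezoidal quadrature on the coherence grid with the band
#' edges obtained by linear interpolation.  Coherence is clipped at
#' `1 - 1e-12` before the logarithm.
#'
#' @param coh a coherence `spectral_estimate`.
#' @param f_low,f_high integration range in Hz (defaults: full grid).
#' @return Information rate in bit/s.
#' @export
lower_bound_mi <- function(coh, f_low = NULL, f_high = NULL) {
  f <- coh$frequencies
  if (is.null(f_low)) f_low <- min(f)
  if (is.null(f_high)) f_high <- max(f)
  if (f_high <= f_low) stop("empty integration range")
  g <- pmin(coh$values, 1 - 1e-12)
  integrand <- -log2(1 - g)
  inner <- f > f_low & f < f_high
  fx <- c(f_low, f[inner], f_high)
  fy <- c(approx(f, integrand, f_low, rule = 2)$y, integrand[inner],
          approx(f, integrand, f_high, rule = 2)$y)
  trapz(fx, fy)
}

#' Band-wise mutual information
#'
#' [lower_bound_mi()] restricted to each of a set of non-overlapping
#' frequency bands; bands that tile a range sum to the full-range value.
#'
#' @param coh a coherence `spectral_estimate`.
#' @param bands list of `c(f_low, f_high)` pairs, pairwise disjoint.
#' @return numeric vector of information rates, bit/s.
#' @export
band_mi <- function(coh, bands) {
  lo <- vapply(bands, `[`, numeric(1), 1L)
  hi <- vapply(bands, `[`, numeric(1), 2L)
  if (any(hi <= lo)) stop("each band needs f_low < f_high")
  o <- order(lo)
  if (any(lo[o][-1L] < hi[o][-length(o)] - 1e-9))
    stop("bands must not overlap")
  vapply(bands, function(b) lower_bound_mi(coh, b[1L], b[2L]), numeric(1))
}

#' Smooth a spectrum with a running average
#'
#' Centered moving average over `n_points` bins; at the edges the window is
#' truncated to the available bins.
#'
#' @param spectrum a `spectral_estimate` with real values.
#' @param n_points odd window length in bins.
#' @export
smooth_spectrum <- function(spectrum, n_points = 11) {
  if (n_points %% 2 != 1) stop("n_points must be odd")
  if (n_points == 1) return(spectrum)
  v <- spectrum$values
  n <- length(v)
  h <- (n_points - 1) / 2
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  spectrum$values <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  spectrum
}

#' Lower and upper cutoff frequencies
#'
#' Outermost frequencies at which the curve first falls below the
#' threshold, scanning outward from the peak, with linear interpolation
#' between grid bins.  In `"gain"` mode the threshold is `max/sqrt(2)`
#' (-3 dB); in `"coherence"` mode it is `max/2` (half maximum).  If the
#' curve never falls below threshold on a side, the cutoff is reported at
#' the range edge and flagged.
#'
#' @param spectrum a `spectral_estimate`; complex values are reduced with
#'   `Mod()`.
#' @param mode `"gain"` or `"coherence"`.
#' @return list with `lower`, `upper` (Hz), `at_edge` (logical pair) and
#'   the `threshold` used.
#' @export
cutoff_frequencies <- function(spectrum, mode = c("gain", "coherence")) {
  mode <- match.arg(mode)
  f <- spectrum$frequencies
  v <- spectrum$values
  if (is.complex(v)) v <- Mod(v)
  ok <- is.finite(v)
  f <- f[ok]; v <- v[ok]
  if (!length(v)) stop("spectrum has no finite values")
  thr <- max(v) / if (mode == "gain") sqrt(2) else 2
  ip <- which.max(v)
  cross <- function(idx) {            # first below-threshold bin outward
    for (j in idx) {
      if (v[j] < thr) {
        prev <- j - sign(j - ip)
        frac <- (thr - v[prev]) / (v[j] - v[prev])
        return(f[prev] + frac * (f[j] - f[prev]))
      }
    }
    NA_real_
  }
  up <- if (ip < length(v)) cross(seq(ip + 1L, length(v))) else NA_real_
  lo <- if (ip > 1L) cross(seq(ip - 1L, 1L)) else NA_real_
  at_edge <- c(lower = is.na(lo), upper = is.na(up))
  if (is.na(lo)) lo <- f[1L]
  if (is.na(up)) up <- f[length(f)]
  list(lower = lo, upper = up, at_edge = at_edge, threshold = thr)
}
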