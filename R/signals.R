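#' Uniformly sampled signal
#'
#' Container for a uniformly sampled waveform (stimulus, carrier, or firing
#' rate) with its sampling rate and start time.
#'
#' @param values numeric vector of samples.
#' @param rate sampling rate in Hz.
#' @param t0 time of the first sample in seconds.
#' @return An object of class `sampled_signal`.
#' @export
sampled_signal <- function(values, rate, t0 = 0) {
  stopifnot(is.numeric(values), length(values) >= 1L,
            is.numeric(rate), length(rate) == 1L, rate > 0)
  structure(list(values = as.numeric(values), rate = as.numeric(rate),
                 t0 = as.numeric(t0)),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<%s> %d samples @ %g Hz, duration %.6g s\n",
              class(x)[1L], length(x$values), x$rate, signal_duration(x)))
  invisible(x)
}

#' Signal duration in seconds
#' @param x a `sampled_signal`.
#' @export
signal_duration <- function(x) length(x$values) / x$rate

#' Sample times of a signal
#' @param x a `sampled_signal`.
#' @return numeric vector of times (seconds) of each sample.
#' @export
signal_times <- function(x) x$t0 + (seq_along(x$values) - 1) / x$rate

## population (divide-by-n) standard deviation, used throughout:
## the angle-bracket averages in the rate statistics are plain means.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Frozen band-limited Gaussian noise
#'
#' Synthesizes zero-mean Gaussian noise whose spectral power is confined to
#' `[band_low, band_high]` by construction: independent Gaussian Fourier
#' coefficients are drawn inside the band, all other coefficients (including
#' DC) are zero, and the inverse transform is rescaled to the exact target
#' standard deviation.  Identical seeds and parameters reproduce the
#' identical waveform ("frozen" noise).
#'
#' @param duration length in seconds.
#' @param rate sampling rate in Hz.
#' @param band_low,band_high band edges in Hz, `0 <= band_low < band_high
#'   <= rate/2`.
#' @param sigma target standard deviation of the waveform.
#' @param seed optional integer seed.
#' @return A `sampled_signal`.
#' @export
generate_band_noise <- function(duration, rate, band_low, band_high, sigma,
                                seed = NULL) {
  if (duration <= 0) stop("duration must be positive")
  if (band_low < 0 || band_high <= band_low)
    stop("need 0 <= band_low < band_high")
  if (band_high > rate / 2)
    stop("band_high exceeds the Nyquist frequency rate/2")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * rate)
  nf <- floor(n / 2)                       # positive-frequency bins 1..nf
  f <- (1:nf) * rate / n
  in_band <- f >= band_low & f <= band_high & (1:nf) < n / 2
  m <- sum(in_band)
  if (m == 0L) stop("band contains no Fourier bins at this duration/rate")
  spec <- complex(real = rep(0, nf), imaginary = rep(0, nf))
  spec[in_band] <- complex(real = rnorm(m), imaginary = rnorm(m))
  if (n %% 2 == 0) {                       # separate (real) Nyquist bin
    pos <- spec[seq_len(nf - 1L)]
    full <- c(0, pos, 0, Conj(rev(pos)))
  } else {
    full <- c(0, spec, Conj(rev(spec)))
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  x <- x * sigma / pop_sd(x)
  sampled_signal(x, rate)
}

#' Apply a random amplitude modulation to a carrier
#'
#' Multiplies the carrier with `1 + contrast * am / sd(am)` so that the
#' induced amplitude modulation has a standard deviation of `contrast`
#' relative to the unperturbed carrier amplitude.  If the modulation
#' waveform has zero variance it is taken to be expressed in
#' standard-deviation units already.
#'
#' @param carrier,am `sampled_signal`s on identical grids.
#' @param contrast modulation depth as a fraction of the carrier amplitude.
#' @return A `sampled_signal` holding the modulated carrier.
#' @export
generate_am_stimulus <- function(carrier, am, contrast) {
  if (carrier$rate != am$rate || length(carrier$values) != length(am$values))
    stop("carrier and am must share sampling rate and duration")
  if (contrast == 0) return(carrier)
  s <- pop_sd(am$values)
  unit <- if (s > 0) am$values / s else am$values
  sampled_signal(carrier$values * (1 + contrast * unit), carrier$rate,
                 carrier$t0)
}

## centered moving-window convolution with an odd-length kernel, zero-padded
## (FFT-based); returns a vector of length(x)
conv_same <- function(x, kernel) {
  n <- length(x)
  m <- length(kernel)
  stopifnot(m %% 2L == 1L)
  half <- (m - 1L) %/% 2L
  nn <- nextn(n + m - 1L, 2L)
  X <- fft(c(x, rep(0, nn - n)))
  K <- fft(c(kernel, rep(0, nn - m)))
  full <- Re(fft(X * K, inverse = TRUE)) / nn
  full[(half + 1L):(half + n)]
}
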