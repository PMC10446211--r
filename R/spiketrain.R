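#' Spike train for one trial of one cell
#'
#' Ordered spike times (seconds) within `[0, duration]`.
#'
#' @param times numeric vector of spike times in seconds, strictly
#'   increasing.
#' @param duration trial duration in seconds.
#' @param cell_id,trial_id optional identifiers.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, duration, cell_id = NA, trial_id = NA) {
  times <- as.numeric(times)
  if (any(is.na(times))) stop("spike times must not contain NA")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("spike times must be strictly increasing")
  if (length(times) && (times[1L] < 0 || times[length(times)] > duration))
    stop("spike times must lie within [0, duration]")
  structure(list(times = times, duration = as.numeric(duration),
                 cell_id = cell_id, trial_id = trial_id),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.4g s (%.1f Hz)%s\n",
              length(x$times), x$duration, length(x$times) / x$duration,
              if (!is.na(x$cell_id)) paste0(" [", x$cell_id, "]") else ""))
  invisible(x)
}

#' Number of spikes
#' @param train a `spike_train`.
#' @export
n_spikes <- function(train) length(train$times)

#' Time-resolved firing rate by Gaussian kernel convolution
#'
#' Convolves the spike train with a unit-mass Gaussian kernel
#' \deqn{F(t) = \frac{1}{\sqrt{2\pi\sigma^2}} e^{-t^2/2\sigma^2}}
#' on a uniform grid covering `[0, duration]`.  Edges are zero-padded, so a
#' small fraction of each edge spike's mass is lost.
#'
#' @param train a `spike_train`.
#' @param kernel_sigma kernel standard deviation in seconds (default 1 ms).
#' @param output_rate sampling rate of the rate grid in Hz.
#' @return A `rate_estimate` (subclass of [sampled_signal()]) with fields
#'   `kernel_sigma` and `n_trials`.
#' @export
firing_rate <- function(train, kernel_sigma = 0.001, output_rate = 20000) {
  if (kernel_sigma <= 0) stop("kernel_sigma must be positive")
  n <- max(1L, round(train$duration * output_rate))
  counts <- spike_counts(train$times, output_rate, n)
  rate_from_counts(counts, output_rate, kernel_sigma, n_trials = 1L)
}

## bin spike times at `rate`; n bins
spike_counts <- function(times, rate, n, shift = 0) {
  out <- .bin_spikes(as.numeric(times), shift, rate, as.integer(n),
                     numeric(n))
  out$counts
}

## Gaussian smoothing of binned counts -> rate in Hz; kernel has exactly
## unit mass on the grid
rate_from_counts <- function(counts, rate, kernel_sigma, n_trials = 1L,
                             n_members = 1L) {
  half <- ceiling(5 * kernel_sigma * rate)
  kern <- dnorm((-half:half) / rate, 0, kernel_sigma)
  kern <- kern / sum(kern) * rate
  vals <- conv_same(counts, kern) / n_members
  vals[vals < 0] <- 0
  out <- sampled_signal(vals, rate)
  out$kernel_sigma <- kernel_sigma
  out$n_trials <- n_trials
  class(out) <- c("rate_estimate", class(out))
  out
}

#' Across-trial average firing rate
#'
#' @param rates list of `rate_estimate`s on identical grids.
#' @return A `rate_estimate`; `n_trials` records the number averaged.
#' @export
average_rate <- function(rates) {
  stopifnot(length(rates) >= 1L)
  n <- length(rates[[1L]]$values)
  if (!all(vapply(rates, function(r) length(r$values) == n, logical(1))))
    stop("rates must share one grid")
  out <- rates[[1L]]
  out$values <- Reduce(`+`, lapply(rates, `[[`, "values")) / length(rates)
  out$n_trials <- length(rates)
  out
}

#' Rising zero-crossing times of a sinusoidal carrier
#'
#' Cycle onsets of `sin(2 pi f t + phase0)` within `[0, duration]`.
#'
#' @param frequency carrier frequency in Hz.
#' @param duration time span in seconds.
#' @param phase0 carrier phase at t = 0, radians.
#' @export
eod_cycle_onsets <- function(frequency, duration, phase0 = 0) {
  stopifnot(frequency > 0, duration > 0)
  t0 <- (-phase0 / (2 * pi)) / frequency
  k <- seq(ceiling(-t0 * frequency), floor((duration - t0) * frequency))
  t0 + k / frequency
}

#' Vector strength and preferred phase
#'
#' Phase locking of spikes to a carrier cycle.  Each spike is assigned the
#' phase `2 pi (t - onset) / cycle_length` relative to the preceding cycle
#' onset; the vector strength is the resultant length of the unit phase
#' vectors divided by the spike count,
#' \deqn{\rho = \frac{1}{n}\left|\sum_j e^{-i \phi_j}\right| \in [0, 1],}
#' so 1 indicates perfect locking and 0 a symmetric phase distribution.
#'
#' @param train a `spike_train`.
#' @param cycle_onsets increasing vector of cycle-onset times in seconds
#'   (e.g. from [eod_cycle_onsets()] for a sinusoidal carrier, or detected
#'   threshold crossings for a recorded carrier).
#' @return list with `vector_strength`, `preferred_phase` (circular mean in
#'   `[0, 2 pi)`), `n_spikes` and the per-spike `phases`.
#' @export
vector_strength <- function(train, cycle_onsets) {
  if (length(cycle_onsets) < 2L) stop("need at least two cycle onsets")
  times <- train$times
  times <- times[times >= cycle_onsets[1L] &
                 times < cycle_onsets[length(cycle_onsets)]]
  if (!length(times)) stop("no spikes within the cycle-onset range")
  i <- findInterval(times, cycle_onsets)
  cyc <- diff(cycle_onsets)
  phases <- 2 * pi * (times - cycle_onsets[i]) / cyc[i]
  z <- sum(exp(1i * phases))
  list(vector_strength = Mod(z) / length(phases),
       preferred_phase = Arg(z) %% (2 * pi),
       n_spikes = length(phases),
       phases = phases)
}

#' Coefficient of variation of interspike intervals
#'
#' `CV_ISI = sd(ISI) / mean(ISI)` with the population (divide-by-n)
#' standard deviation.  Zero indicates clock-like regularity, values near
#' one Poisson-like firing.
#'
#' @param train a `spike_train` with at least three spikes.
#' @export
cv_isi <- function(train) {
  if (n_spikes(train) < 3L) stop("cv_isi needs at least 3 spikes")
  isi <- diff(train$times)
  pop_sd(isi) / mean(isi)
}

#' Burst fraction
#'
#' Fraction of interspike intervals shorter than 1.5 times the carrier
#' (EOD) period.
#'
#' @param train a `spike_train` with at least two spikes.
#' @param eod_period carrier period in seconds.
#' @export
burst_fraction <- function(train, eod_period) {
  if (eod_period <= 0) stop("eod_period must be positive")
  if (n_spikes(train) < 2L) stop("burst_fraction needs at least 2 spikes")
  mean(diff(train$times) < 1.5 * eod_period)
}

#' Response modulation
#'
#' Standard deviation over time of the (trial-averaged) firing rate -- the
#' depth of the stimulus-driven rate modulation, in Hz.
#'
#' @param avg_rate a `rate_estimate`.
#' @export
response_modulation <- function(avg_rate) pop_sd(avg_rate$values)

#' Across-trial response variability
#'
#' Standard deviation of single-trial firing rates around the trial mean,
#' averaged over time:
#' \deqn{\sigma_{psth} = \sqrt{\langle\langle (y_k(t) - y(t))^2
#'   \rangle_k\rangle_t}.}
#'
#' @param trial_rates list of two or more `rate_estimate`s on one grid.
#' @export
response_variability <- function(trial_rates) {
  if (length(trial_rates) < 2L) stop("need at least 2 trials")
  n <- length(trial_rates[[1L]]$values)
  if (!all(vapply(trial_rates, function(r) length(r$values) == n,
                  logical(1))))
    stop("trial rates must share one grid")
  y <- vapply(trial_rates, `[[`, numeric(n), "values")   # time x trials
  dev2 <- (y - rowMeans(y))^2
  sqrt(mean(rowMeans(dev2)))
}

#' Spike-triggered average stimulus
#'
#' Average stimulus segment around each spike, pooled over trials.  The lag
#' axis is spike-relative: `sta$values[lag]` is the mean stimulus at
#' `t_spike + lag`, so a response that follows the stimulus by `d` seconds
#' peaks at lag `-d`.
#'
#' @param trains a `spike_train` or list of them.
#' @param stimulus the stimulus as a `sampled_signal`.
#' @param window half-width of the lag window in seconds.
#' @return list with `lags` (seconds), `average` (stimulus units),
#'   `n_spikes`.
#' @export
sta <- function(trains, stimulus, window = 0.02) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  if (window <= 0) stop("window must be positive")
  fs <- stimulus$rate
  half <- round(window * fs)
  nsig <- length(stimulus$values)
  centers <- unlist(lapply(trains, function(tr) {
    round((tr$times - stimulus$t0) * fs) + 1
  }))
  centers <- centers[centers - half >= 1 & centers + half <= nsig]
  if (!length(centers)) stop("no usable spikes within the stimulus support")
  idx <- outer(centers, -half:half, `+`)
  seg <- matrix(stimulus$values[idx], nrow = length(centers))
  list(lags = (-half:half) / fs,
       average = colMeans(seg),
       n_spikes = length(centers))
}

#' Response delay from the spike-triggered average
#'
#' Lag of the STA's global maximum before the spike; positive values mean
#' the stimulus precedes the spike.
#'
#' @inheritParams sta
#' @export
sta_delay <- function(trains, stimulus, window = 0.02) {
  s <- sta(trains, stimulus, window)
  -s$lags[which.max(s$average)]
}
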