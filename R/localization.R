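#' Power of a firing rate at a given frequency
#'
#' Welch power spectral density of the (mean-subtracted, Hann-windowed)
#' firing rate, evaluated at the grid frequency nearest `f`.  Segments of
#' about 1 s with 50% overlap.
#'
#' @param rate a `rate_estimate` (or any `sampled_signal`).
#' @param f target frequency in Hz.
#' @param segment_length samples per segment (default about 1 s).
#' @return Power density at the nearest grid frequency.
#' @export
power_at_frequency <- function(rate, f, segment_length = NULL) {
  sp <- welch_spectra(rate, rate, segment_length)$pxx
  sp$values[which.min(abs(sp$frequencies - f))]
}

#' Receptor position from a dipole scan
#'
#' Least-squares fit of a Gaussian with additive baseline,
#' `p(x) = b + a exp(-(x - c)^2 / (2 w^2))`, to response power versus
#' dipole position; the receptor location is the fitted center `c`.  The
#' estimate depends only on the relative power profile, so it is invariant
#' to stimulus intensity.
#'
#' @param positions strictly increasing scan positions.
#' @param powers response power at the AM frequency per position
#'   (nonnegative).
#' @return list with `position` (center), `width`, `amplitude`,
#'   `baseline`, and `quality` (R-squared of the fit).
#' @export
estimate_position <- function(positions, powers) {
  if (length(positions) < 4L) stop("need at least 4 scan points")
  if (length(positions) != length(powers)) stop("length mismatch")
  rng <- diff(range(powers))
  if (rng <= 0) stop("localization failure: flat scan (no dynamic range)")
  span <- diff(range(positions))
  df <- data.frame(x = positions, p = powers)
  start <- list(b = min(powers), a = rng, c = positions[which.max(powers)],
                w = span / 4)
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ b + a * exp(-(x - c)^2 / (2 * w^2)), data = df,
                      start = start,
                      lower = c(b = 0, a = 0, c = min(positions) - span,
                                w = span / length(positions) / 4),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("localization failure: Gaussian fit did not converge (",
           conditionMessage(e), ")"))
  cf <- as.list(coef(fit))
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((powers - mean(powers))^2)
  list(position = cf$c, width = abs(cf$w), amplitude = cf$a,
       baseline = cf$b, quality = 1 - ss_res / ss_tot)
}

#' Run a full scan-based localization
#'
#' Convenience wrapper over a [generate_position_scan()] result: firing
#' rates, power at the AM frequency, Gaussian fit.
#'
#' @param scan result of [generate_position_scan()] (or a compatible list
#'   with `positions`, `trains`, `am_frequency`).
#' @param kernel_sigma rate kernel in seconds.
#' @return As [estimate_position()], plus the `powers` profile.
#' @export
localize_scan <- function(scan, kernel_sigma = 0.001) {
  powers <- vapply(scan$trains, function(tr)
    power_at_frequency(firing_rate(tr, kernel_sigma), scan$am_frequency),
    numeric(1))
  out <- estimate_position(scan$positions, powers)
  out$powers <- powers
  out
}

#' Cluster preferred phases and unwrap the caudal cluster
#'
#' K-means (k = 2, 10 restarts) on per-axis standardized (phase, position)
#' pairs.  If the rostral cluster's mean phase exceeds the caudal
#' cluster's by at least `pi` -- the signature of phases having wrapped
#' around one carrier cycle along the body -- the caudal cluster is
#' shifted by +2*pi.  Data without such a gap (already monotone within one
#' cycle, or previously unwrapped) are returned unchanged, which makes the
#' operation idempotent.
#'
#' @param phases preferred phases in radians.
#' @param positions receptor positions (meters or body fraction).
#' @param seed seed for the k-means restarts.
#' @return list with `phases` (possibly shifted), `positions`, `cluster`
#'   (1 = rostral, 2 = caudal), `shifted` (logical).
#' @export
cluster_and_unwrap <- function(phases, positions, seed = 1) {
  stopifnot(length(phases) == length(positions))
  n <- length(phases)
  if (n < 4L || sd(phases) == 0 || sd(positions) == 0)
    return(list(phases = phases, positions = positions,
                cluster = rep(1L, n), shifted = FALSE))
  z <- cbind(scale(phases), scale(positions))
  set.seed(seed)
  km <- kmeans(z, centers = 2L, nstart = 10L)
  mean_pos <- tapply(positions, km$cluster, mean)
  caudal <- as.integer(names(which.max(mean_pos)))
  rostral <- 3L - caudal
  gap <- mean(phases[km$cluster == rostral]) -
    mean(phases[km$cluster == caudal])
  shifted <- FALSE
  out <- phases
  if (is.finite(gap) && gap >= pi) {
    out[km$cluster == caudal] <- out[km$cluster == caudal] + 2 * pi
    shifted <- TRUE
  }
  cluster <- ifelse(km$cluster == rostral, 1L, 2L)
  list(phases = out, positions = positions, cluster = cluster,
       shifted = shifted)
}

#' Conduction velocity from delays versus position
#'
#' Ordinary least-squares regression `delay = a + b * position`; the
#' conduction velocity is `1/b`.  Delays may come from the absolute phase
#' delay (`phase / (2 pi f_EOD)` after unwrapping) or from STA delays; a
#' constant offset (shared response latency) is absorbed by the intercept.
#'
#' @param positions receptor positions in meters.
#' @param delays response delays in seconds.
#' @return list with `velocity` (m/s), `slope`, `intercept`, Pearson `r`
#'   and `p`.
#' @export
velocity_from_delays <- function(positions, delays) {
  if (length(positions) < 3L) stop("need at least 3 points")
  if (sd(positions) == 0) stop("positions have no spread")
  fit <- lm(delays ~ positions)
  b <- unname(coef(fit)[2L])
  if (b <= 0)
    stop("implausible velocity: delay does not increase with position")
  ct <- cor.test(positions, delays)
  list(velocity = 1 / b, slope = b, intercept = unname(coef(fit)[1L]),
       r = unname(ct$estimate), p = ct$p.value)
}

#' Correlate response features with receptor position
#'
#' Pearson correlation of each feature with position, with Bonferroni
#' correction (two-sided p multiplied by `n_tests`, capped at 1).
#' Zero-variance features are flagged and reported with `r = NA`.
#'
#' @param features named list (or data.frame) of numeric feature vectors.
#' @param positions receptor positions, same length.
#' @param n_tests number of tests used for the Bonferroni factor; at least
#'   the number of features.
#' @return data.frame with `feature`, `r`, `p_raw`, `p_bonferroni`,
#'   `degenerate`.
#' @export
correlate_with_position <- function(features, positions,
                                    n_tests = length(features)) {
  features <- as.list(features)
  if (n_tests < length(features))
    stop("n_tests must cover at least every feature")
  rows <- lapply(names(features), function(nm) {
    v <- features[[nm]]
    if (length(v) != length(positions))
      stop("feature '", nm, "' length differs from positions")
    if (sd(v) == 0 || anyNA(v))
      return(data.frame(feature = nm, r = NA_real_, p_raw = NA_real_,
                        p_bonferroni = NA_real_, degenerate = TRUE))
    ct <- cor.test(v, positions)
    data.frame(feature = nm, r = unname(ct$estimate), p_raw = ct$p.value,
               p_bonferroni = min(1, ct$p.value * n_tests),
               degenerate = FALSE)
  })
  do.call(rbind, rows)
}

#' Preferred phases and absolute delays of a study's cells
#'
#' Baseline preferred phase of every cell relative to its own carrier
#' (rising zero-crossings), the cluster-unwrapped phases, and the absolute
#' delays `phase / (2 pi f_EOD)` together with absolute positions in
#' meters.
#'
#' @param study a `synthetic_study`.
#' @param seed seed for the k-means step.
#' @return data.frame with `cell`, `position_m`, `phase`,
#'   `phase_unwrapped`, `delay`, `cluster`.
#' @export
study_phase_delays <- function(study, seed = 1) {
  phases <- vapply(study$cells, function(cell) {
    vs <- vector_strength(cell$baseline,
                          eod_cycle_onsets(cell$params$eod_frequency,
                                           cell$baseline$duration))
    vs$preferred_phase
  }, numeric(1))
  pos <- vapply(study$cells, function(cell)
    cell$params$position * cell$params$body_length, numeric(1))
  un <- cluster_and_unwrap(phases, pos, seed = seed)
  freq <- vapply(study$cells, function(cell) cell$params$eod_frequency,
                 numeric(1))
  data.frame(cell = seq_along(study$cells), position_m = pos,
             phase = phases, phase_unwrapped = un$phases,
             delay = un$phases / (2 * pi * freq), cluster = un$cluster)
}
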