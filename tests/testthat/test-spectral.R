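test_that("welch spectra agree with an independent reference", {
  # deterministic tone mixture; expected values computed once with
  # scipy.signal.welch/coherence (periodic Hann, nperseg 512, 50% overlap,
  # constant detrend) and frozen here
  n <- 4096; fs <- 512
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 20 * t) + 0.5 * sin(2 * pi * 57 * t + 1) +
    0.25 * sin(2 * pi * 130.5 * t + 2)
  y <- 0.8 * c(x[-(1:16)], x[1:16]) + 0.3 * sin(2 * pi * 200 * t) +
    0.2 * cos(2 * pi * 33 * t)
  sx <- sampled_signal(x, fs)
  sy <- sampled_signal(y, fs)
  co <- coherence(sx, sy, segment_length = 512)
  sp <- welch_spectra(sx, sy, segment_length = 512)
  idx <- c(21, 58, 131, 201)           # 20, 57, 130, 200 Hz bins
  expect_equal(co$frequencies[idx], c(20, 57, 130, 200))
  expect_equal(co$values[idx],
               c(1, 1, 1, 0.0047393108), tolerance = 1e-6)
  expect_equal(co$values[5], 0.7811414911, tolerance = 1e-6)  # 4 Hz bin
  expect_equal(sp$pxx$values[idx],
               c(0.33333333266, 0.083333330717, 0.015010545722,
                 1.8615694837e-14), tolerance = 1e-6)
})

test_that("identical signals give pxy = pxx = pyy and unit coherence", {
  x <- generate_band_noise(4, 2000, 0, 300, 1, seed = 12)
  sp <- welch_spectra(x, x)
  expect_equal(Re(sp$pxy$values), sp$pxx$values, tolerance = 1e-10)
  expect_equal(sp$pyy$values, sp$pxx$values, tolerance = 1e-10)
  co <- coherence(x, x)
  expect_true(all(abs(co$values[co$frequencies < 300] - 1) < 1e-9))
})

test_that("coherence of independent signals scales as 1/n_segments", {
  x <- generate_band_noise(40, 2000, 0, 300, 1, seed = 13)
  set.seed(14)
  y <- sampled_signal(rnorm(length(x$values)), 2000)
  co <- coherence(x, y)
  inb <- co$frequencies > 5 & co$frequencies < 295
  expect_gt(co$n_segments, 40)
  expect_lt(mean(co$values[inb]), 3 / co$n_segments)
  expect_true(all(co$values >= 0 & co$values <= 1))
})

test_that("transfer function recovers gain, delay phase and derivative", {
  x <- generate_band_noise(8, 2000, 0, 400, 1, seed = 15)
  # static gain of 2
  h2 <- transfer_function(x, sampled_signal(2 * x$values, 2000))
  inb <- h2$frequencies > 5 & h2$frequencies < 390
  expect_equal(Mod(h2$values[inb]), rep(2, sum(inb)), tolerance = 1e-6)
  # pure delay: |H| = 1, phase slope -2 pi d
  shift <- 20                               # 10 ms at 2 kHz
  yv <- c(rep(0, shift), x$values[1:(length(x$values) - shift)])
  hd <- transfer_function(x, sampled_signal(yv, 2000))
  band <- hd$frequencies > 5 & hd$frequencies < 40
  expect_equal(Mod(hd$values[band]), rep(1, sum(band)), tolerance = 0.05)
  slope <- coef(lm(Arg(hd$values[band]) ~ hd$frequencies[band]))[2]
  expect_equal(unname(slope), -2 * pi * shift / 2000, tolerance = 0.02)
  # differentiator: |H| proportional to 2 pi f
  dv <- c(diff(x$values), 0) * 2000
  hg <- transfer_function(x, sampled_signal(dv, 2000))
  mid <- hg$frequencies > 20 & hg$frequencies < 200
  ratio <- Mod(hg$values[mid]) / (2 * pi * hg$frequencies[mid])
  expect_lt(sd(ratio) / mean(ratio), 0.05)
})

test_that("coherence of a noisy linear channel follows SNR/(1+SNR)", {
  x <- generate_band_noise(40, 2000, 0, 300, 1, seed = 16)
  for (snr in c(0.5, 2)) {
    set.seed(17)
    noise_sd <- sqrt(1000 / 300 / snr)      # in-band SNR target
    y <- sampled_signal(x$values + rnorm(length(x$values), 0, noise_sd),
                        2000)
    co <- coherence(x, y)
    inb <- co$frequencies > 10 & co$frequencies < 290
    expect_equal(mean(co$values[inb]), snr / (1 + snr), tolerance = 0.03)
  }
})

test_that("lower-bound MI reproduces the flat-coherence integrals", {
  expect_equal(lower_bound_mi(flat_coherence(0.5), 0, 300), 300,
               tolerance = 1e-9)
  expect_equal(lower_bound_mi(flat_coherence(0), 0, 300), 0)
  expect_equal(lower_bound_mi(flat_coherence(0.75, f_max = 100), 0, 100),
               200, tolerance = 1e-9)
  expect_error(lower_bound_mi(flat_coherence(0.5), 100, 100), "empty")
})

test_that("band MI is additive over a tiling and rejects overlap", {
  co <- flat_coherence(0.5)
  bands <- list(c(0, 100), c(100, 200), c(200, 300))
  bm <- band_mi(co, bands)
  expect_equal(bm, c(100, 100, 100), tolerance = 1e-9)
  expect_equal(sum(bm), lower_bound_mi(co, 0, 300), tolerance = 1e-9)
  expect_error(band_mi(co, list(c(0, 150), c(100, 300))), "overlap")
})

test_that("MI is insensitive to a rigid response shift well below the segment", {
  x <- generate_band_noise(20, 2000, 0, 300, 1, seed = 18)
  set.seed(19)
  y <- x$values + rnorm(length(x$values), 0, 1)
  mi0 <- lower_bound_mi(coherence(x, sampled_signal(y, 2000)), 0, 300)
  shift <- 10                               # 5 ms
  ys <- c(rep(0, shift), y[1:(length(y) - shift)])
  mi1 <- lower_bound_mi(coherence(x, sampled_signal(ys, 2000)), 0, 300)
  expect_lt(abs(mi1 - mi0) / mi0, 0.05)
})

test_that("cutoff extraction matches analytic filters", {
  f <- seq(0, 500, by = 0.5)
  mk <- function(v) spectral_estimate(f, v, 1, length(f), 0, "hann", "gain")
  # single-pole low-pass, -3 dB at 100 Hz
  lp <- mk(1 / sqrt(1 + (f / 100)^2))
  cut <- cutoff_frequencies(lp, "gain")
  expect_equal(cut$upper, 100, tolerance = 0.02)
  expect_true(cut$at_edge[["lower"]])
  # flat gain: both edges flagged
  flat <- cutoff_frequencies(mk(rep(1, length(f))), "gain")
  expect_true(all(flat$at_edge))
  expect_equal(c(flat$lower, flat$upper), c(0, 500))
  # symmetric band-pass about 150 Hz
  bp <- mk(exp(-(f - 150)^2 / (2 * 40^2)))
  cb <- cutoff_frequencies(bp, "gain")
  expect_equal((cb$lower + cb$upper) / 2, 150, tolerance = 0.01)
  # coherence mode uses half maximum
  ch <- cutoff_frequencies(
    spectral_estimate(f, exp(-(f - 150)^2 / (2 * 40^2)), 1, length(f), 0,
                      "hann", "coherence"), "coherence")
  expect_equal(ch$upper - 150, 40 * sqrt(2 * log(2)), tolerance = 0.01)
})

test_that("spectrum smoothing is a truncated running average", {
  f <- 0:100
  v <- numeric(101); v[51] <- 11
  sp <- spectral_estimate(f, v, 1, 101, 0, "hann", "psd")
  sm <- smooth_spectrum(sp, 11)
  expect_equal(sm$values[51], 1)
  expect_equal(sum(sm$values[46:56]), 11)
  expect_identical(smooth_spectrum(sp, 1)$values, v)
  const <- spectral_estimate(f, rep(3, 101), 1, 101, 0, "hann", "psd")
  expect_equal(smooth_spectrum(const, 11)$values, rep(3, 101))
  expect_error(smooth_spectrum(sp, 4), "odd")
})

test_that("short signals and bad overlaps are rejected", {
  x <- sinusoid_signal(10, 0.1, 1000)
  expect_error(welch_spectra(x, x, segment_length = 1000), "shorter")
  x2 <- sinusoid_signal(10, 2, 1000)
  expect_error(welch_spectra(x2, x2, overlap = 1), "overlap")
})
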