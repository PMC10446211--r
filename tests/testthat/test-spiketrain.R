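test_that("spike_train validates ordering and support", {
  expect_error(spike_train(c(0.2, 0.1), 1), "increasing")
  expect_error(spike_train(c(0.2, 1.5), 1), "within")
  tr <- spike_train(c(0.1, 0.2), 1)
  expect_s3_class(tr, "spike_train")
  expect_equal(n_spikes(tr), 2L)
})

test_that("kernel rate has unit mass per spike and the Gaussian peak", {
  tr <- spike_train(0.5, 1)
  r <- firing_rate(tr, kernel_sigma = 0.001, output_rate = 20000)
  expect_equal(max(r$values), 1 / (sqrt(2 * pi) * 0.001), tolerance = 1e-3)
  expect_equal(which.max(r$values) / r$rate, 0.5, tolerance = 2e-4)
  expect_equal(sum(r$values) / r$rate, 1, tolerance = 1e-6)

  empty <- spike_train(numeric(0), 1)
  expect_true(all(firing_rate(empty)$values == 0))

  many <- spike_train(sort(runif(50, 0.1, 0.9)), 1)
  rm2 <- firing_rate(many)
  expect_equal(sum(rm2$values) / rm2$rate, 50, tolerance = 0.005 * 50)
  expect_true(all(rm2$values >= 0))
})

test_that("rate estimation commutes with trial averaging", {
  set.seed(5)
  trains <- lapply(1:4, function(i)
    spike_train(sort(runif(30, 0.05, 0.95)), 1))
  avg <- average_rate(lapply(trains, firing_rate))
  merged <- sort(unlist(lapply(trains, `[[`, "times")))
  pooled <- firing_rate(spike_train(merged, 1))
  expect_equal(avg$values, pooled$values / 4, tolerance = 1e-10)
})

test_that("vector strength reproduces the worked phase examples", {
  f <- 100
  onsets <- eod_cycle_onsets(f, 1)
  # perfect locking
  same <- train_at_phases(rep(1.3, 20), f)
  vs <- vector_strength(same, onsets)
  expect_equal(vs$vector_strength, 1, tolerance = 1e-9)
  expect_equal(vs$preferred_phase, 1.3, tolerance = 1e-9)
  # symmetric cancellation
  sym <- train_at_phases(c(0, pi / 2, pi, 3 * pi / 2), f)
  expect_equal(vector_strength(sym, onsets)$vector_strength, 0,
               tolerance = 1e-9)
  # three spikes at {0, 0, pi}: |1 + 1 - 1| / 3
  tri <- train_at_phases(c(0, 0, pi), f)
  expect_equal(vector_strength(tri, onsets)$vector_strength, 1 / 3,
               tolerance = 1e-3)
})

test_that("vector strength is invariant to rigid phase rotation", {
  f <- 100
  onsets <- eod_cycle_onsets(f, 2)
  set.seed(6)
  phases <- runif(40, 0, 2 * pi)
  base <- vector_strength(train_at_phases(phases, f), onsets)
  for (rot in c(0.5, 1.7, 3.1)) {
    rotated <- vector_strength(train_at_phases(phases + rot, f), onsets)
    expect_equal(rotated$vector_strength, base$vector_strength,
                 tolerance = 1e-9)
  }
  expect_error(vector_strength(train_at_phases(phases, f), numeric(0)),
               "onsets")
})

test_that("cv_isi matches the closed-form example and is scale invariant", {
  tr <- train_from_isis(c(1, 1, 2) / 1000)
  expect_equal(cv_isi(tr), sqrt(2 / 9) / (4 / 3), tolerance = 1e-12)
  expect_equal(cv_isi(tr), 0.35355339, tolerance = 1e-7)
  # regular firing
  expect_equal(cv_isi(train_from_isis(rep(0.01, 20))), 0)
  # scale invariance
  tr10 <- train_from_isis(c(1, 1, 2) / 100)
  expect_equal(cv_isi(tr10), cv_isi(tr), tolerance = 1e-12)
  # a long exponential-ISI train approaches Poisson (CV ~ 1)
  set.seed(7)
  pois <- train_from_isis(rexp(5000, 200))
  expect_equal(cv_isi(pois), 1, tolerance = 0.05)
  expect_error(cv_isi(spike_train(c(0.1, 0.2), 1)), "3 spikes")
})

test_that("burst fraction counts short interspike intervals", {
  tr <- train_from_isis(c(1.2, 1.2, 5) / 1000)
  expect_equal(burst_fraction(tr, 0.001), 2 / 3)
  expect_equal(burst_fraction(train_from_isis(rep(0.005, 9)), 0.001), 0)
  expect_equal(burst_fraction(train_from_isis(rep(0.001, 9)), 0.001), 1)
  expect_error(burst_fraction(tr, 0), "positive")
})

test_that("response modulation is the temporal sd of the rate", {
  const <- sampled_signal(rep(120, 2000), 1000)
  expect_equal(response_modulation(const), 0)
  sine <- sinusoid_signal(10, 1, 1000, amplitude = 30, offset = 200)
  expect_equal(response_modulation(sine), 30 / sqrt(2), tolerance = 1e-6)
})

test_that("response variability matches the two-trial closed form", {
  r1 <- sinusoid_signal(7, 1, 1000, amplitude = 10, offset = 100)
  expect_equal(response_variability(list(r1, r1)), 0)
  r2 <- r1
  r2$values <- r2$values + 8
  expect_equal(response_variability(list(r1, r2)), 4, tolerance = 1e-12)
  expect_error(response_variability(list(r1)), "2 trials")
})

test_that("STA recovers a construction delay and rigid shifts add", {
  set.seed(8)
  stim <- generate_band_noise(10, 5000, 0, 100, 1, seed = 9)
  # spikes d = 3 ms after each strong upstroke of the stimulus
  d <- 0.003
  v <- stim$values
  peaks <- which(diff(sign(diff(v))) == -2) + 1
  peaks <- peaks[v[peaks] > quantile(v, 0.9)]
  t_spk <- peaks / stim$rate + d
  t_spk <- t_spk[t_spk < 9.9]
  tr <- spike_train(t_spk, 10)
  expect_lt(abs(sta_delay(tr, stim, window = 0.02) - d), 8e-4)
  # shift theorem: a delayed clone adds its delay
  delta <- 0.002
  tr2 <- spike_train(t_spk + delta, 10)
  expect_lt(abs(sta_delay(tr2, stim, window = 0.02) -
                  sta_delay(tr, stim, window = 0.02) - delta), 3e-4)
})

test_that("STA of stimulus-independent spikes is flat", {
  stim <- generate_band_noise(10, 5000, 0, 100, 1, seed = 10)
  set.seed(11)
  tr <- spike_train(sort(runif(800, 0.1, 9.9)), 10)
  s <- sta(tr, stim, window = 0.02)
  se <- 1 / sqrt(s$n_spikes)          # stimulus sd is 1
  expect_lt(max(abs(s$average)), 3.5 * se)
})
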