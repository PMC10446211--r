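# Shared fixtures, built in code at test time.

# spike train with prescribed interspike intervals
train_from_isis <- function(isis, t0 = 0.01, pad = 0.01) {
  times <- t0 + cumsum(c(0, isis))
  spike_train(times, max(times) + pad)
}

# spike train whose spikes sit at given phases (radians) of a carrier
train_at_phases <- function(phases, frequency = 100, n_cycles = NULL) {
  k <- seq_along(phases) - 1
  times <- (k + (phases %% (2 * pi)) / (2 * pi)) / frequency
  dur <- (length(phases) + 1) / frequency
  spike_train(sort(times), dur)
}

sinusoid_signal <- function(freq, duration, rate, amplitude = 1,
                            phase = 0, offset = 0) {
  t <- (seq_len(round(duration * rate)) - 1) / rate
  sampled_signal(offset + amplitude * sin(2 * pi * freq * t + phase), rate)
}

# coherence-like spectral estimate with prescribed values
flat_coherence <- function(value, f_max = 300, df = 1) {
  f <- seq(0, f_max, by = df)
  spectral_estimate(f, rep(value, length(f)), n_segments = 1,
                    segment_length = length(f), overlap = 0,
                    window = "hann", kind = "coherence")
}

# small driven study shared by the population tests (cached per session)
cached_study <- local({
  env <- new.env()
  function(name, builder) {
    if (is.null(env[[name]])) env[[name]] <- builder()
    env[[name]]
  }
})
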