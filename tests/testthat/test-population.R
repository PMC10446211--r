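make_trials <- function(n, seed = 41) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    spike_train(sort(runif(40, 0, 1)), 1, cell_id = 1L, trial_id = i))
}

test_that("homogeneous assembly enumerates unique trial combinations", {
  tr5 <- make_trials(5)
  one <- assemble_homogeneous(tr5, 5, n_populations = 10)
  expect_length(one, 1L)                 # choose(5,5) = 1
  expect_setequal(one[[1]]$members$trial_id, 1:5)

  tr10 <- make_trials(10)
  pairs <- assemble_homogeneous(tr10, 2, n_populations = 10, seed = 42)
  expect_length(pairs, 10L)
  keys <- vapply(pairs, function(a)
    paste(sort(a$members$trial_id), collapse = ","), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_error(assemble_homogeneous(tr5, 6), "exceeds")
})

test_that("assembly invariants are enforced", {
  m <- data.frame(cell_id = c(1, 1), trial_id = c(1, 2),
                  alignment_delay = 0, injected_delay = 0)
  expect_error(population_assembly(m, "heterogeneous"), "one trial per cell")
  m2 <- data.frame(cell_id = c(1, 2), trial_id = c(1, 1),
                   alignment_delay = 0, injected_delay = 0)
  expect_error(population_assembly(m2, "homogeneous"), "single cell")
  expect_s3_class(population_assembly(m, "homogeneous"),
                  "population_assembly")
})

test_that("heterogeneous assemblies draw distinct cells and honor counts", {
  st <- cached_study("pop", function()
    generate_study(10, n_trials = 3, duration = 4, baseline_duration = 0.5,
                   seed = 43))
  asm <- assemble_heterogeneous(st, 6, n_populations = 12, seed = 44)
  expect_length(asm, 12L)
  for (a in asm) {
    expect_equal(assembly_size(a), 6L)
    expect_equal(anyDuplicated(a$members$cell_id), 0L)
  }
  expect_error(assemble_heterogeneous(st, 11), "between 2")
})

test_that("alignment synchronizes the pooled population with the stimulus", {
  st <- cached_study("pop", function()
    generate_study(10, n_trials = 3, duration = 4, baseline_duration = 0.5,
                   seed = 43))
  asm <- assemble_heterogeneous(st, 8, n_populations = 1, seed = 45)[[1]]
  shifted <- lapply(seq_len(8), function(k) {
    tr <- st$cells[[asm$members$cell_id[k]]]$trials[[asm$members$trial_id[k]]]
    t <- tr$times - asm$members$alignment_delay[k]
    spike_train(t[t >= 0 & t <= tr$duration], tr$duration)
  })
  pooled <- sta_delay(shifted, st$stimulus)
  expect_lt(abs(pooled), 5e-4)
})

test_that("injected delays are rigid per member and unbiased in scale", {
  tr <- make_trials(6)
  a <- assemble_homogeneous(tr, 6, 1)[[1]]
  expect_identical(inject_delays(a, 0)$members$injected_delay, rep(0, 6))
  b <- inject_delays(a, 0.002, seed = 46)
  expect_equal(sd(b$members$injected_delay) > 0, TRUE)
  # Monte-Carlo scale check (clipping at 4 sigma barely matters)
  set.seed(47)
  draws <- replicate(2000, inject_delays(a, 0.002)$members$injected_delay)
  expect_equal(sd(as.numeric(draws)), 0.002, tolerance = 0.02)
})

test_that("delay injection never alters within-member intervals", {
  st <- cached_study("pop", function()
    generate_study(10, n_trials = 3, duration = 4, baseline_duration = 0.5,
                   seed = 43))
  a <- assemble_heterogeneous(st, 5, 1, seed = 48)[[1]]
  a <- inject_delays(a, 0.003, seed = 49)
  for (k in seq_len(5)) {
    tr <- st$cells[[a$members$cell_id[k]]]$trials[[a$members$trial_id[k]]]
    shifted <- tr$times + a$members$injected_delay[k]
    keep <- shifted >= 0 & shifted <= tr$duration
    expect_lt(max(abs(diff(shifted[keep]) - diff(tr$times[keep]))), 1e-12)
  }
})

test_that("size-one population response equals the single-trial rate", {
  tr <- make_trials(3)
  a <- population_assembly(
    data.frame(cell_id = 1, trial_id = 2, alignment_delay = 0,
               injected_delay = 0), "homogeneous")
  st <- list(cells = list(list(trials = tr)))
  r <- population_response(a, st)
  expect_equal(r$values, firing_rate(tr[[2]])$values, tolerance = 1e-9)
})

test_that("averaging independent members shrinks temporal variance", {
  st <- cached_study("pop", function()
    generate_study(10, n_trials = 3, duration = 4, baseline_duration = 0.5,
                   seed = 43))
  # baseline-like variance comparison: single trial vs size-8 average,
  # both with the driven trials of distinct cells
  single <- population_response(assemble_heterogeneous(st, 2, 1,
                                                       seed = 50)[[1]], st)
  avg8 <- population_response(assemble_heterogeneous(st, 8, 1,
                                                     seed = 50)[[1]], st)
  # high-frequency (noise-dominated) fluctuation shrinks with averaging
  hp <- function(v) v - stats::filter(v, rep(1 / 201, 201), sides = 2)
  v2 <- var(na.omit(as.numeric(hp(single$values))))
  v8 <- var(na.omit(as.numeric(hp(avg8$values))))
  expect_lt(v8, v2)
})

test_that("matched-modulation pairing honors the tolerance", {
  hom <- data.frame(size = c(4, 4), modulation = c(100, 200),
                    mi = c(10, 20))
  het <- data.frame(size = c(4, 4, 4), modulation = c(95, 119, 250),
                    mi = c(12, 14, 30))
  res <- matched_modulation_compare(hom, het, tolerance = 0.20)
  # hom 100 pairs with 95 and 119; hom 200 pairs with none within 20%
  expect_equal(nrow(res$pairs), 2L)
  expect_equal(res$pairs$mi_het, c(12, 14))
  expect_equal(res$n_unmatched, 1L)
  expect_equal(res$centroids$mi_hom, 10)
  # zero tolerance pairs only exact matches
  res0 <- matched_modulation_compare(
    data.frame(size = 2, modulation = 50, mi = 5),
    data.frame(size = 2, modulation = c(50, 51), mi = c(6, 7)),
    tolerance = 0)
  expect_equal(res0$pairs$mi_het, 6)
})

test_that("mi_vs_size summarizes per size", {
  st <- cached_study("pop", function()
    generate_study(10, n_trials = 3, duration = 4, baseline_duration = 0.5,
                   seed = 43))
  asm <- c(assemble_heterogeneous(st, 2, 3, seed = 51),
           assemble_heterogeneous(st, 4, 3, seed = 52))
  tab <- mi_vs_size(asm, st)
  expect_equal(tab$size, c(2L, 4L))
  expect_equal(tab$n, c(3L, 3L))
  expect_true(all(tab$min_mi <= tab$mean_mi & tab$mean_mi <= tab$max_mi))
})
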