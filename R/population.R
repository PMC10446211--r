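#' Population assembly
#'
#' A set of member trials forming one artificial population: for
#' homogeneous populations distinct trials of one cell, for heterogeneous
#' populations one trial from each of several distinct cells.  Each member
#' carries an `alignment_delay` (subtracted from its spike times to
#' synchronize the responses with the stimulus) and an `injected_delay`
#' (added to mimic a conduction delay).
#'
#' @param members data.frame with columns `cell_id`, `trial_id`,
#'   `alignment_delay`, `injected_delay`.
#' @param kind `"homogeneous"` or `"heterogeneous"`.
#' @param kernel_sigma rate-kernel standard deviation (seconds) used when
#'   forming the population response.
#' @export
population_assembly <- function(members,
                                kind = c("heterogeneous", "homogeneous"),
                                kernel_sigma = 0.001) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(members),
            all(c("cell_id", "trial_id", "alignment_delay",
                  "injected_delay") %in% names(members)))
  if (kind == "heterogeneous") {
    if (anyDuplicated(members$cell_id))
      stop("heterogeneous assemblies take at most one trial per cell")
  } else {
    if (length(unique(members$cell_id)) != 1L)
      stop("homogeneous assemblies use trials of a single cell")
    if (anyDuplicated(members$trial_id))
      stop("homogeneous assemblies need distinct trials")
  }
  structure(list(members = members, kind = kind,
                 kernel_sigma = kernel_sigma),
            class = "population_assembly")
}

#' @export
print.population_assembly <- function(x, ...) {
  cat(sprintf("<population_assembly> %s, size %d, kernel %g ms\n",
              x$kind, nrow(x$members), x$kernel_sigma * 1000))
  invisible(x)
}

#' Population size
#' @param assembly a [population_assembly()].
#' @export
assembly_size <- function(assembly) nrow(assembly$members)

## draw n_populations unique size-subsets of 1..n_avail
unique_combinations <- function(n_avail, size, n_populations) {
  total <- choose(n_avail, size)
  n_populations <- min(n_populations, total)
  seen <- character(0)
  combos <- list()
  while (length(combos) < n_populations) {
    cmb <- sort(sample.int(n_avail, size))
    key <- paste(cmb, collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      combos[[length(combos) + 1L]] <- cmb
    }
  }
  combos
}

#' Assemble homogeneous populations from one cell's trials
#'
#' Unique random combinations of distinct trials of a single cell; up to
#' `n_populations` populations per size.
#'
#' @param trials list of `spike_train`s of one cell.
#' @param size population size (at most the number of trials).
#' @param n_populations maximum number of assemblies (default 10).
#' @param seed optional integer seed.
#' @param cell_id identifier recorded in the members table.
#' @param kernel_sigma rate kernel in seconds (default 1 ms).
#' @return list of [population_assembly()] objects.
#' @export
assemble_homogeneous <- function(trials, size, n_populations = 10,
                                 seed = NULL, cell_id = 1L,
                                 kernel_sigma = 0.001) {
  if (size > length(trials))
    stop("size exceeds the number of available trials")
  if (!is.null(seed)) set.seed(seed)
  combos <- unique_combinations(length(trials), size, n_populations)
  lapply(combos, function(cmb) {
    population_assembly(
      data.frame(cell_id = cell_id, trial_id = cmb, alignment_delay = 0,
                 injected_delay = 0),
      kind = "homogeneous", kernel_sigma = kernel_sigma)
  })
}

#' Assemble heterogeneous populations across cells
#'
#' Each assembly draws `size` distinct cells and one random trial per
#' cell.  Members are aligned to the stimulus by their cell's
#' spike-triggered-average delay, so that the aligned responses are
#' synchronous with the stimulus before any delays are injected.
#'
#' @param study a `synthetic_study` (or a list with `cells`, each holding
#'   `trials`, and `stimulus`).
#' @param size population size (2 to the number of cells).
#' @param n_populations number of assemblies (default 50).
#' @param seed optional integer seed.
#' @param align align members by their STA delay (default TRUE).
#' @param kernel_sigma rate kernel in seconds (default 1 ms).
#' @param sta_window STA half-window in seconds.
#' @return list of [population_assembly()] objects.
#' @export
assemble_heterogeneous <- function(study, size, n_populations = 50,
                                   seed = NULL, align = TRUE,
                                   kernel_sigma = 0.001,
                                   sta_window = 0.02) {
  n_cells <- length(study$cells)
  if (size < 2 || size > n_cells)
    stop("size must be between 2 and the number of cells")
  if (!is.null(seed)) set.seed(seed)
  delays <- if (align) study_sta_delays(study, sta_window) else
    rep(0, n_cells)
  lapply(seq_len(n_populations), function(p) {
    cells <- sort(sample.int(n_cells, size))
    trials <- vapply(cells, function(ci)
      sample.int(length(study$cells[[ci]]$trials), 1L), integer(1))
    population_assembly(
      data.frame(cell_id = cells, trial_id = trials,
                 alignment_delay = delays[cells], injected_delay = 0),
      kind = "heterogeneous", kernel_sigma = kernel_sigma)
  })
}

#' Per-cell response delays from the spike-triggered average
#'
#' @param study a `synthetic_study`.
#' @param sta_window STA half-window in seconds.
#' @return numeric vector, one STA delay (seconds) per cell.
#' @export
study_sta_delays <- function(study, sta_window = 0.02) {
  vapply(study$cells, function(cell)
    sta_delay(cell$trials, study$stimulus, sta_window), numeric(1))
}

#' Inject Gaussian conduction delays into an assembly
#'
#' One zero-mean Gaussian draw of standard deviation `sigma_delay` per
#' member; the identical shift applies to every spike of that member, so
#' within-member interspike intervals are untouched (conduction delay, not
#' spike-time jitter).  Draws are clipped at four standard deviations to
#' bound spike loss at the trace edges.
#'
#' @param assembly a [population_assembly()].
#' @param sigma_delay standard deviation of the member delays, seconds.
#' @param seed optional integer seed.
#' @param draws optional standard-normal draws (one per member) to reuse
#'   across conditions (common random numbers); scaled by `sigma_delay`.
#' @return The assembly with `injected_delay` set.
#' @export
inject_delays <- function(assembly, sigma_delay, seed = NULL,
                          draws = NULL) {
  if (sigma_delay < 0) stop("sigma_delay must be nonnegative")
  n <- assembly_size(assembly)
  if (is.null(draws)) {
    if (!is.null(seed)) set.seed(seed)
    draws <- rnorm(n)
  }
  stopifnot(length(draws) == n)
  draws <- pmin(pmax(draws, -4), 4)
  assembly$members$injected_delay <- draws * sigma_delay
  assembly
}

## look up a member spike train inside a study
study_train <- function(study, cell_id, trial_id) {
  cell <- study$cells[[cell_id]]
  if (is.null(cell)) stop("unknown cell_id: ", cell_id)
  tr <- cell$trials[[trial_id]]
  if (is.null(tr)) stop("unknown trial_id ", trial_id, " of cell ", cell_id)
  tr
}

#' Population response of an assembly
#'
#' Average firing rate of the member trials after applying alignment and
#' injected delays: member spike times become
#' `t - alignment_delay + injected_delay`, are binned on a common grid and
#' smoothed with a Gaussian kernel.  Spikes shifted outside the trial are
#' dropped; their count is attached as attribute `dropped_spikes`.
#'
#' @param assembly a [population_assembly()].
#' @param study the study holding the member spike trains.
#' @param kernel_sigma kernel width in seconds; defaults to the assembly's.
#' @param output_rate rate-grid sampling rate in Hz.
#' @return A `rate_estimate`.
#' @export
population_response <- function(assembly, study, kernel_sigma = NULL,
                                output_rate = 20000) {
  if (is.null(kernel_sigma)) kernel_sigma <- assembly$kernel_sigma
  m <- assembly$members
  tr1 <- study_train(study, m$cell_id[1L], m$trial_id[1L])
  n_bins <- round(tr1$duration * output_rate)
  counts <- numeric(n_bins)
  dropped <- 0L
  for (k in seq_len(nrow(m))) {
    tr <- study_train(study, m$cell_id[k], m$trial_id[k])
    res <- .bin_spikes(tr$times,
                       m$injected_delay[k] - m$alignment_delay[k],
                       output_rate, n_bins, counts)
    counts <- res$counts
    dropped <- dropped + res$dropped
  }
  out <- rate_from_counts(counts, output_rate, kernel_sigma,
                          n_trials = nrow(m), n_members = nrow(m))
  attr(out, "dropped_spikes") <- dropped
  out
}

#' Coherence-based information rate of an assembly
#'
#' Convenience wrapper: population response, coherence against the
#' stimulus, and the lower-bound information rate integrated over
#' `[f_low, f_high]`.
#'
#' @inheritParams population_response
#' @param f_low,f_high integration band in Hz.
#' @param segment_length Welch segment length in samples (default: about
#'   1 s).
#' @return list with `mi` (bit/s), `modulation` (Hz), `coherence`.
#' @export
population_mi <- function(assembly, study, f_low = 0, f_high = 300,
                          kernel_sigma = NULL, output_rate = 20000,
                          segment_length = NULL) {
  resp <- population_response(assembly, study, kernel_sigma, output_rate)
  stim <- study$stimulus
  if (stim$rate != output_rate) {
    idx <- pmin(length(stim$values),
                floor((seq_len(length(resp$values)) - 1) / output_rate *
                        stim$rate) + 1L)
    stim <- sampled_signal(stim$values[idx], output_rate)
  }
  coh <- coherence(stim, resp, segment_length)
  list(mi = lower_bound_mi(coh, f_low, f_high),
       modulation = response_modulation(resp),
       coherence = coh)
}

#' Information versus population size
#'
#' Per-size summary of the lower-bound information rate over a set of
#' assemblies.
#'
#' @param assemblies list of [population_assembly()] objects (any mix of
#'   sizes).
#' @param study the study holding the spike trains.
#' @param f_low,f_high integration band in Hz.
#' @param ... passed to [population_mi()].
#' @return data.frame with `size`, `n`, `mean_mi`, `sd_mi`, `min_mi`,
#'   `max_mi`.
#' @export
mi_vs_size <- function(assemblies, study, f_low = 0, f_high = 300, ...) {
  sizes <- vapply(assemblies, assembly_size, integer(1))
  mis <- vapply(assemblies, function(a)
    population_mi(a, study, f_low, f_high, ...)$mi, numeric(1))
  out <- do.call(rbind, lapply(sort(unique(sizes)), function(s) {
    v <- mis[sizes == s]
    data.frame(size = s, n = length(v), mean_mi = mean(v),
               sd_mi = if (length(v) > 1) sd(v) else 0,
               min_mi = min(v), max_mi = max(v))
  }))
  out
}

#' Compare homogeneous and heterogeneous populations at matched drive
#'
#' Pairs each homogeneous population with the heterogeneous populations of
#' the same size whose response modulation lies within `tolerance` (a
#' fraction, default +/-20%) of its own, and reports the per-size centers
#' of gravity of the paired information rates.
#'
#' @param hom,het data.frames with columns `size`, `modulation`, `mi` (one
#'   row per population), e.g. built from [population_mi()] results.
#' @param tolerance relative modulation tolerance.
#' @param sizes sizes to include (default: all shared sizes).
#' @return list with `pairs` (data.frame `size`, `mi_hom`, `mi_het`),
#'   `centroids` (per-size means of the paired values) and `n_unmatched`.
#' @export
matched_modulation_compare <- function(hom, het, tolerance = 0.20,
                                       sizes = NULL) {
  if (is.null(sizes)) sizes <- intersect(unique(hom$size), unique(het$size))
  pairs <- list()
  unmatched <- 0L
  for (s in sizes) {
    h <- hom[hom$size == s, ]
    g <- het[het$size == s, ]
    for (i in seq_len(nrow(h))) {
      sel <- abs(g$modulation - h$modulation[i]) <=
        tolerance * h$modulation[i]
      if (!any(sel)) {
        unmatched <- unmatched + 1L
        next
      }
      pairs[[length(pairs) + 1L]] <- data.frame(
        size = s, mi_hom = h$mi[i], mi_het = g$mi[sel])
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(size = integer(), mi_hom = numeric(), mi_het = numeric())
  centroids <- do.call(rbind, lapply(unique(pairs$size), function(s) {
    p <- pairs[pairs$size == s, ]
    data.frame(size = s, mi_hom = mean(p$mi_hom), mi_het = mean(p$mi_het),
               n_pairs = nrow(p))
  }))
  list(pairs = pairs, centroids = centroids, n_unmatched = unmatched)
}

#' Information loss from conduction delays versus synaptic filtering
#'
#' Grid of population information rates for heterogeneous populations of a
#' fixed size: the x-axis injects Gaussian member delays of standard
#' deviation `sigma_delay`, the y-axis widens the Gaussian rate kernel to
#' `sigma_kernel` (the synaptic low-pass proxy; the kernel itself is
#' widened, not convolved on top of the baseline kernel).  Membership and
#' the member delay draws are reused across all grid points (common random
#' numbers), so differences across the grid reflect the filtering, not the
#' sampling.
#'
#' @param study a `synthetic_study`.
#' @param size population size (default 16).
#' @param sigma_delays,sigma_kernels grids in seconds.
#' @param n_populations assemblies averaged per grid point.
#' @param f_low,f_high integration band in Hz.
#' @param seed integer seed.
#' @param ... passed to [population_mi()].
#' @return list with `mi` (matrix, delays x kernels, mean over
#'   populations) and the grids.
#' @export
delay_kernel_grid <- function(study, size = 16,
                              sigma_delays = c(0, 5e-4, 1e-3, 2e-3, 4e-3),
                              sigma_kernels = c(1e-3, 2e-3, 4e-3),
                              n_populations = 5, f_low = 0, f_high = 300,
                              seed = 1, ...) {
  set.seed(seed)
  assemblies <- assemble_heterogeneous(study, size, n_populations)
  draws <- lapply(assemblies, function(a) rnorm(assembly_size(a)))
  mi <- matrix(NA_real_, length(sigma_delays), length(sigma_kernels),
               dimnames = list(paste0(sigma_delays * 1000, "ms"),
                               paste0(sigma_kernels * 1000, "ms")))
  for (di in seq_along(sigma_delays)) {
    for (ki in seq_along(sigma_kernels)) {
      vals <- vapply(seq_along(assemblies), function(ai) {
        a <- inject_delays(assemblies[[ai]], sigma_delays[di],
                           draws = draws[[ai]])
        population_mi(a, study, f_low, f_high,
                      kernel_sigma = sigma_kernels[ki], ...)$mi
      }, numeric(1))
      mi[di, ki] <- mean(vals)
    }
  }
  list(mi = mi, sigma_delays = sigma_delays, sigma_kernels = sigma_kernels)
}
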