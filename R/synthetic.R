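# Synthetic polysomnography-like data with known ground-truth connectivity.
#
# Background model per channel: a sum of three random-frequency sinusoids in
# the 0.5-30 Hz band (mimicking the EEG rhythm range, and band-limited so the
# FIR-based spike encoding is meaningful) plus white Gaussian noise. Directed
# coupling is injected as lagged copies: a channel named as the target of an
# edge carries gain * (source background delayed by `lag` samples) instead of
# its own background, plus its own noise. Lagged copies are evaluated
# analytically (the sinusoid at shifted time), so the cross-correlation of a
# noiseless coupled pair peaks exactly at the specified lag.

# Evaluate expressions under a temporary RNG seed, restoring caller RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Specify ground-truth directed coupling between channels
#'
#' @param edges Data frame with columns `source`, `target` (1-based channel
#'   indices), `lag` (delay in samples, >= 0) and `gain` (coupling strength),
#'   or `NULL` for no coupling.
#' @param noise_sd Standard deviation of the additive white noise on every
#'   channel.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(edges = NULL, noise_sd = 0.1) {
  if (is.null(edges)) {
    edges <- data.frame(source = integer(), target = integer(),
                        lag = integer(), gain = numeric())
  }
  edges <- as.data.frame(edges)
  need <- c("source", "target", "lag", "gain")
  if (!all(need %in% names(edges))) {
    stop("edges must have columns source, target, lag, gain")
  }
  if (any(edges$source == edges$target)) {
    stop("invalid coupling spec: source must differ from target")
  }
  if (any(edges$lag < 0)) stop("invalid coupling spec: lag must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(edges = edges, noise_sd = noise_sd), class = "coupling_spec")
}

# Draw sinusoid parameters for one channel. freq_offset shifts all component
# frequencies (a subject-level "domain" effect); frequencies are kept >= 0.1 Hz.
draw_background <- function(freq_offset, amp_scale, n_components = 3) {
  list(freq = pmax(0.1, stats::runif(n_components, 0.5, 30) + freq_offset),
       phase = stats::runif(n_components, 0, 2 * pi),
       amp = stats::runif(n_components, 0.5, 1.5),
       scale = amp_scale)
}

eval_background <- function(p, tt) {
  s <- numeric(length(tt))
  for (k in seq_along(p$freq)) {
    s <- s + p$amp[k] * sin(2 * pi * p$freq[k] * tt + p$phase[k])
  }
  p$scale * s
}

#' Generate one multichannel epoch with known directed coupling
#'
#' Uncoupled channels are independent band-limited noise (three sinusoids with
#' random frequencies in 0.5-30 Hz plus Gaussian noise). A channel that is the
#' target of one or more edges instead carries the sum of
#' `gain * source-background delayed by lag samples` over its incoming edges,
#' plus its own Gaussian noise, so the ground-truth direction of influence is
#' source -> target at the specified lag.
#'
#' @param spec A [coupling_spec()].
#' @param n_channels Number of channels (>= 2).
#' @param n_samples Samples per channel; must exceed every edge lag.
#' @param seed Integer seed; the epoch is a pure function of it.
#' @param sampling_rate Sampling rate in Hz (defaults to 100).
#' @param amp_scale Per-channel multiplicative amplitude (length 1 or
#'   `n_channels`); used by [generate_stage_dataset()] for subject shift.
#' @param freq_offset Per-channel additive frequency offset in Hz.
#' @return Numeric matrix `n_channels x n_samples` with attributes
#'   `sampling_rate` and `epoch_index`.
#' @export
generate_coupled_epoch <- function(spec, n_channels, n_samples, seed,
                                   sampling_rate = 100,
                                   amp_scale = 1, freq_offset = 0) {
  stopifnot(inherits(spec, "coupling_spec"), n_channels >= 2, n_samples >= 1)
  edges <- spec$edges
  if (nrow(edges) > 0) {
    if (max(edges$source, edges$target) > n_channels || min(edges$source, edges$target) < 1) {
      stop("invalid coupling spec: channel index out of range")
    }
    if (any(edges$lag >= n_samples)) {
      stop("invalid coupling spec: lag must be smaller than n_samples")
    }
  }
  amp_scale <- rep_len(amp_scale, n_channels)
  freq_offset <- rep_len(freq_offset, n_channels)
  tt <- (seq_len(n_samples) - 1) / sampling_rate
  with_seed(seed, {
    bg <- lapply(seq_len(n_channels), function(ch) {
      draw_background(freq_offset[ch], amp_scale[ch])
    })
    x <- matrix(0, n_channels, n_samples)
    is_target <- seq_len(n_channels) %in% edges$target
    for (ch in seq_len(n_channels)) {
      if (!is_target[ch]) x[ch, ] <- eval_background(bg[[ch]], tt)
    }
    if (nrow(edges) > 0) {
      for (r in seq_len(nrow(edges))) {
        src <- edges$source[r]
        tgt <- edges$target[r]
        x[tgt, ] <- x[tgt, ] +
          edges$gain[r] * eval_background(bg[[src]], tt - edges$lag[r] / sampling_rate)
      }
    }
    if (spec$noise_sd > 0) {
      for (ch in seq_len(n_channels)) {
        x[ch, ] <- x[ch, ] + stats::rnorm(n_samples, 0, spec$noise_sd)
      }
    }
    structure(x, sampling_rate = sampling_rate, epoch_index = NA_integer_)
  })
}

#' Simulate a Markov chain of sleep stages
#'
#' The chain starts in Wake and evolves with the given 5x5 row-stochastic
#' transition matrix over the stages in [stage_levels()] order.
#'
#' @param transition_matrix 5x5 matrix; rows must be nonnegative and sum to 1
#'   (within 1e-9).
#' @param length Number of epochs to simulate.
#' @param seed Integer seed.
#' @return Factor of length `length` over [stage_levels()].
#' @export
markov_stage_sequence <- function(transition_matrix, length, seed) {
  tm <- as.matrix(transition_matrix)
  if (!all(dim(tm) == c(5, 5))) stop("invalid matrix: must be 5x5")
  if (any(tm < 0)) stop("invalid matrix: negative transition probabilities")
  if (any(abs(rowSums(tm) - 1) > 1e-9)) {
    stop("invalid matrix: rows must sum to 1")
  }
  stopifnot(length >= 1)
  with_seed(seed, {
    states <- integer(length)
    states[1] <- 1L  # Wake
    if (length > 1) {
      for (t in 2:length) {
        states[t] <- sample.int(5L, 1L, prob = tm[states[t - 1], ])
      }
    }
    factor(stage_levels()[states], levels = stage_levels())
  })
}

#' Default stage-specific connectivity templates
#'
#' One [coupling_spec()] per AASM stage with distinct directed edge sets:
#' Wake is densely connected (the awake brain shows widespread functional
#' coupling), the NREM stages carry progressively different sparse motifs,
#' and REM uses a disjoint pair of edges. Lags span 5-20 samples.
#'
#' @param n_channels Number of channels (>= 6).
#' @param gain Coupling gain shared by all edges.
#' @param noise_sd Per-channel noise level shared by all stages.
#' @return Named list of `coupling_spec` objects over [stage_levels()].
#' @export
default_stage_specs <- function(n_channels = 8, gain = 1, noise_sd = 0.2) {
  stopifnot(n_channels >= 6)
  e <- function(s, t, l) data.frame(source = s, target = t, lag = l, gain = gain)
  specs <- list(
    Wake = e(c(1, 3, 5, 2), c(2, 4, 6, 5), c(5, 8, 12, 15)),
    N1   = e(1, 3, 10),
    N2   = e(c(2, 4), c(4, 6), c(6, 14)),
    N3   = e(c(1, 5, 3), c(5, 3, 6), c(20, 7, 9)),
    REM  = e(c(6, 4), c(2, 1), c(18, 11))
  )
  lapply(specs, coupling_spec, noise_sd = noise_sd)
}

#' Default sleep-stage transition matrix
#'
#' A sticky, physiologically plausible 5x5 transition matrix over
#' [stage_levels()]: stages persist (diagonal mass 0.5-0.73), Wake feeds N1,
#' N1 feeds N2, N2 exchanges with N3, and REM mostly returns to N1/N2.
#'
#' @return 5x5 row-stochastic matrix with stage dimnames.
#' @export
default_transition_matrix <- function() {
  tm <- rbind(
    Wake = c(0.70, 0.25, 0.03, 0.01, 0.01),
    N1   = c(0.10, 0.50, 0.35, 0.02, 0.03),
    N2   = c(0.03, 0.07, 0.70, 0.15, 0.05),
    N3   = c(0.01, 0.02, 0.25, 0.70, 0.02),
    REM  = c(0.07, 0.08, 0.10, 0.02, 0.73)
  )
  colnames(tm) <- stage_levels()
  tm
}

#' Generate a multi-subject synthetic staging dataset
#'
#' Each subject is a "domain": a per-channel multiplicative amplitude scale
#' (log-normal, sd `subject_shift_sd` on the log scale) and an additive
#' frequency offset (normal, sd `subject_shift_sd` Hz) are drawn once per
#' subject and applied to all of that subject's epochs. Stage labels follow a
#' Markov chain; each epoch's signals are drawn from the coupling template of
#' its stage, so the stage is encoded in the connectivity structure.
#'
#' @param n_subjects Number of subjects.
#' @param epochs_per_subject Epochs simulated per subject.
#' @param stage_specs Named list of [coupling_spec()] per stage
#'   (default [default_stage_specs()]).
#' @param transition_matrix Stage transition matrix
#'   (default [default_transition_matrix()]).
#' @param subject_shift_sd Magnitude of the subject-level domain shift
#'   (0 disables it).
#' @param n_channels,n_samples,sampling_rate Signal geometry; defaults give
#'   30-s epochs at 100 Hz.
#' @param seed Integer seed; the dataset is a pure function of it.
#' @return An object of class `psg_dataset`: list with `signals`
#'   (array `n_channels x n_samples x n_epochs`), `labels` (stage factor),
#'   `subject_ids` (integer vector), `sampling_rate`, `stage_specs`.
#' @export
generate_stage_dataset <- function(n_subjects, epochs_per_subject,
                                   stage_specs = default_stage_specs(n_channels),
                                   transition_matrix = default_transition_matrix(),
                                   subject_shift_sd = 0.2,
                                   n_channels = 8, n_samples = 3000,
                                   sampling_rate = 100, seed = 1) {
  stopifnot(n_subjects >= 1, epochs_per_subject >= 1)
  if (!setequal(names(stage_specs), stage_levels())) {
    stop("stage_specs must be a named list covering exactly: ",
         paste(stage_levels(), collapse = ", "))
  }
  n_total <- n_subjects * epochs_per_subject
  signals <- array(NA_real_, c(n_channels, n_samples, n_total))
  labels <- factor(rep(NA_character_, n_total), levels = stage_levels())
  subject_ids <- rep(seq_len(n_subjects), each = epochs_per_subject)
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects * 2L)
    epoch_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
    amp <- matrix(exp(stats::rnorm(n_subjects * n_channels, 0, subject_shift_sd)),
                  n_subjects, n_channels)
    foff <- matrix(stats::rnorm(n_subjects * n_channels, 0, subject_shift_sd),
                   n_subjects, n_channels)
    for (s in seq_len(n_subjects)) {
      lab <- markov_stage_sequence(transition_matrix, epochs_per_subject,
                                   seed = sub_seeds[s])
      idx <- which(subject_ids == s)
      labels[idx] <- lab
      for (k in seq_along(idx)) {
        ep <- generate_coupled_epoch(stage_specs[[as.character(lab[k])]],
                                     n_channels, n_samples,
                                     seed = epoch_seeds[idx[k]],
                                     sampling_rate = sampling_rate,
                                     amp_scale = amp[s, ],
                                     freq_offset = foff[s, ])
        signals[, , idx[k]] <- ep
      }
    }
  })
  structure(list(signals = signals, labels = labels,
                 subject_ids = subject_ids, sampling_rate = sampling_rate,
                 stage_specs = stage_specs, subject_shift_sd = subject_shift_sd,
                 seed = seed),
            class = "psg_dataset")
}

#' @export
print.psg_dataset <- function(x, ...) {
  d <- dim(x$signals)
  cat("Synthetic PSG dataset:", d[3], "epochs,", d[1], "channels,",
      d[2], "samples/epoch @", x$sampling_rate, "Hz\n")
  cat("Subjects:", length(unique(x$subject_ids)), "\n")
  print(table(x$labels))
  invisible(x)
}

# Subset a psg_dataset by epoch index, keeping alignment of all fields.
subset_dataset <- function(dataset, idx) {
  structure(list(signals = dataset$signals[, , idx, drop = FALSE],
                 labels = dataset$labels[idx],
                 subject_ids = dataset$subject_ids[idx],
                 sampling_rate = dataset$sampling_rate,
                 stage_specs = dataset$stage_specs,
                 subject_shift_sd = dataset$subject_shift_sd,
                 seed = dataset$seed),
            class = "psg_dataset")
}

#' Subset a dataset by epoch
#'
#' @param x A `psg_dataset`.
#' @param subset Logical or integer index over epochs.
#' @param ... Unused.
#' @return A `psg_dataset` with the selected epochs (labels, subjects and
#'   signals stay aligned).
#' @export
subset.psg_dataset <- function(x, subset, ...) {
  subset_dataset(x, subset)
}
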