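# Ben's Spiking Algorithm (BSA): deterministic analog-to-spike encoding. At
# each time instant the encoder compares the cost of explaining the upcoming
# window by the FIR kernel (error1 = sum |s - h|) against leaving it alone
# (error2 = sum |s|); when error1 <= error2 - threshold it emits a spike and
# subtracts the kernel from the signal in place. Decoding is the convolution
# of the spike train with the same kernel.

#' Design the BSA low-pass FIR filter
#'
#' Windowed-sinc (Hamming) low-pass taps, rescaled to unit sum so that encoded
#' amplitudes are commensurate with signals normalized to \[0, 1\].
#'
#' @param length Number of taps (default 20).
#' @param cutoff Cutoff as a fraction of the Nyquist frequency, in (0, 1)
#'   (default 0.8).
#' @return Object of class `fir_filter`: list with `taps`, `length`, `cutoff`.
#' @export
design_fir <- function(length = 20, cutoff = 0.8) {
  if (!(cutoff > 0 && cutoff < 1)) {
    stop("invalid parameter: cutoff must lie strictly in (0, 1)")
  }
  stopifnot(length >= 1)
  taps <- if (length == 1) 1 else as.numeric(signal::fir1(length - 1, cutoff))
  taps <- taps / sum(taps)
  structure(list(taps = taps, length = length, cutoff = cutoff),
            class = "fir_filter")
}

#' BSA encoder configuration
#'
#' @param threshold Spiking threshold (>= 0). Default 1.0; the classic BSA
#'   literature uses about 0.955 -- the parameter is exposed.
#' @param filter A [design_fir()] filter.
#' @return Object of class `bsa_config`.
#' @export
bsa_config <- function(threshold = 1.0, filter = design_fir()) {
  stopifnot(threshold >= 0, inherits(filter, "fir_filter"))
  structure(list(threshold = threshold, filter = filter), class = "bsa_config")
}

#' Min-max normalize a signal to \[0, 1\]
#'
#' Applied per channel per epoch before BSA encoding. A constant signal maps
#' to all zeros (degenerate-range rule).
#'
#' @param signal Finite numeric vector.
#' @return Numeric vector in \[0, 1\].
#' @export
normalize_signal <- function(signal) {
  if (!all(is.finite(signal))) stop("signal must be finite")
  rng <- range(signal)
  if (rng[2] - rng[1] <= 0) return(rep(0, length(signal)))
  (signal - rng[1]) / (rng[2] - rng[1])
}

#' Encode a normalized signal into a spike train
#'
#' @param signal Numeric vector with values in \[0, 1\] (see
#'   [normalize_signal()]); must be at least as long as the filter.
#' @param config A [bsa_config()].
#' @return Object of class `spike_train`: integer 0/1 vector `events` of the
#'   input length plus derived `firing_times` (sorted 1-based indices).
#' @export
bsa_encode <- function(signal, config = bsa_config()) {
  stopifnot(inherits(config, "bsa_config"))
  if (any(signal < -1e-9) || any(signal > 1 + 1e-9)) {
    stop("signal values outside [0, 1]; call normalize_signal() first")
  }
  if (length(signal) < config$filter$length) {
    stop("signal shorter than the FIR filter")
  }
  events <- bsa_encode_cpp(as.numeric(signal), config$filter$taps,
                           config$threshold)
  spike_train(events)
}

#' Construct a spike train from a binary event vector
#'
#' @param events Integer/logical vector of 0/1 events.
#' @return Object of class `spike_train`.
#' @export
spike_train <- function(events) {
  events <- as.integer(events)
  if (!all(events %in% c(0L, 1L))) stop("events must be binary")
  structure(list(events = events, firing_times = which(events == 1L)),
            class = "spike_train")
}

#' Decode a spike train back to an analog signal
#'
#' Discrete convolution of the event vector with the filter taps, truncated to
#' the input length.
#'
#' @param spikes A [spike_train()].
#' @param filter A [design_fir()] filter.
#' @return Numeric vector of the spike-train length.
#' @export
bsa_decode <- function(spikes, filter = design_fir()) {
  stopifnot(inherits(spikes, "spike_train"), inherits(filter, "fir_filter"))
  ev <- spikes$events
  as.numeric(signal::conv(ev, filter$taps))[seq_along(ev)]
}

#' Encode every channel of an epoch
#'
#' Per channel: [normalize_signal()] then [bsa_encode()]; channel order is
#' preserved.
#'
#' @param epoch Numeric matrix, channels x samples.
#' @param config A [bsa_config()].
#' @return List of [spike_train()] objects, one per channel.
#' @export
encode_epoch <- function(epoch, config = bsa_config()) {
  stopifnot(is.matrix(epoch))
  lapply(seq_len(nrow(epoch)), function(ch) {
    bsa_encode(normalize_signal(epoch[ch, ]), config)
  })
}

#' @export
print.spike_train <- function(x, ...) {
  cat("Spike train:", sum(x$events), "spikes over", length(x$events),
      "samples\n")
  invisible(x)
}

#' @export
print.fir_filter <- function(x, ...) {
  cat("FIR low-pass filter:", x$length, "taps, cutoff", x$cutoff,
      "x Nyquist, tap sum", format(sum(x$taps)), "\n")
  invisible(x)
}
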