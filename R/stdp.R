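# Trace-based spike-timing-dependent plasticity (STDP) graph learning.
#
# Each channel's spike train is treated as a neuron; for an ordered pair
# (pre j, post i) the synaptic change accumulates potentiation
# a_plus * exp(-(t_post - t_pre)/tau) over all pre-before-post spike pairs and
# depression a_minus * exp(-(t_pre - t_post)/tau) over all post-before-pre
# pairs (a_minus < 0). The trace implementation keeps one exponentially
# decaying trace per channel (incremented by 1 at its spikes) and is
# algebraically identical to the all-pairs sum; simultaneous spikes contribute
# nothing. Accumulated over an epoch this gives the directed adjacency entry
# a_ji; the full N x N matrix is the epoch's connectivity graph.

#' STDP parameters
#'
#' @param a_plus Potentiation rate (> 0). Default 1e-2, the STDP learning
#'   rate used throughout.
#' @param a_minus Depression rate (< 0). Default -1e-2, so potentiation and
#'   depression are balanced.
#' @param tau Trace time constant in samples (> 0); one shared constant for
#'   pre- and post-synaptic traces. Default 100.
#' @return Object of class `stdp_params`.
#' @export
stdp_params <- function(a_plus = 1e-2, a_minus = -1e-2, tau = 100) {
  stopifnot(a_plus > 0, a_minus < 0, tau > 0)
  structure(list(a_plus = a_plus, a_minus = a_minus, tau = tau, dt = 1),
            class = "stdp_params")
}

as_event_vector <- function(x) {
  if (inherits(x, "spike_train")) x$events else as.integer(x)
}

#' Accumulated synaptic weight change between two spike trains
#'
#' Timestep simulation of the trace-based rule for the ordered pair
#' (pre, post): per step the traces decay by `exp(-1/tau)`; a post spike adds
#' `a_plus * pre-trace` (potentiation), a pre spike adds
#' `a_minus * post-trace` (depression); traces are incremented after the
#' weight update, so coincident spikes contribute 0.
#'
#' @param pre,post Spike trains ([spike_train()] or binary vectors) of equal
#'   length.
#' @param params [stdp_params()].
#' @return Accumulated weight change (scalar).
#' @export
stdp_weight_change <- function(pre, post, params = stdp_params()) {
  pre <- as_event_vector(pre)
  post <- as_event_vector(post)
  if (length(pre) != length(post)) stop("spike trains differ in length")
  W <- stdp_graph_cpp(cbind(pre, post), params$a_plus, params$a_minus,
                      params$tau)
  W[1, 2]
}

#' All-pairs STDP oracle
#'
#' Brute-force double loop over every (pre-spike, post-spike) pair, summing
#' the exponential kernel directly: `a_plus * exp((t_pre - t_post)/tau)` when
#' the pre spike leads, `a_minus * exp(-(t_pre - t_post)/tau)` when it lags;
#' simultaneous spikes contribute 0. Reference implementation for
#' [stdp_weight_change()]; quadratic in spike counts.
#'
#' @inheritParams stdp_weight_change
#' @return Accumulated weight change (scalar).
#' @export
pairwise_stdp_oracle <- function(pre, post, params = stdp_params()) {
  tp <- which(as_event_vector(pre) == 1L)
  tq <- which(as_event_vector(post) == 1L)
  total <- 0
  for (a in tp) {
    for (b in tq) {
      d <- a - b  # t_pre - t_post
      if (d < 0) {
        total <- total + params$a_plus * exp(d / params$tau)
      } else if (d > 0) {
        total <- total + params$a_minus * exp(-d / params$tau)
      }
    }
  }
  total
}

#' Learn a directed connectivity graph from one epoch's spike trains
#'
#' For every ordered channel pair (j, i), entry `weights[j, i]` is the
#' accumulated STDP change treating channel j as pre-synaptic and channel i as
#' post-synaptic; the diagonal is zero. Implemented as one shared timestep
#' simulation over all channels, which equals the pairwise definition exactly.
#'
#' @param spikes List of [spike_train()] objects (or binary vectors) of equal
#'   length; at least 2 channels.
#' @param params [stdp_params()].
#' @return Object of class `adjacency_graph`: N x N numeric `weights` matrix.
#' @export
learn_epoch_graph <- function(spikes, params = stdp_params()) {
  if (length(spikes) < 2) stop("need at least 2 channels")
  ev <- lapply(spikes, as_event_vector)
  lens <- lengths(ev)
  if (length(unique(lens)) != 1) stop("spike trains differ in length")
  S <- do.call(cbind, ev)
  W <- stdp_graph_cpp(S, params$a_plus, params$a_minus, params$tau)
  adjacency_graph(W)
}

#' Construct an adjacency graph object
#'
#' @param weights Square numeric matrix of directed synapse weights
#'   (pre in rows, post in columns).
#' @return Object of class `adjacency_graph`.
#' @export
adjacency_graph <- function(weights) {
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == ncol(weights), all(is.finite(weights)))
  structure(list(weights = weights, n_channels = nrow(weights)),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("Adjacency graph over", x$n_channels, "channels; weight range [",
      format(min(x$weights)), ",", format(max(x$weights)), "]\n")
  invisible(x)
}

#' Learn one connectivity graph per epoch
#'
#' Encodes each epoch with BSA ([encode_epoch()]) and learns its graph with
#' [learn_epoch_graph()]; no state is carried across epochs (weights restart
#' from zero every epoch).
#'
#' @param epochs List of channel x sample matrices.
#' @param bsa [bsa_config()].
#' @param params [stdp_params()].
#' @return List of `adjacency_graph` objects, one per epoch.
#' @export
learn_graph_sequence <- function(epochs, bsa = bsa_config(),
                                 params = stdp_params()) {
  lapply(epochs, function(ep) learn_epoch_graph(encode_epoch(ep, bsa), params))
}

#' Post-process an adjacency graph for graph convolution
#'
#' The spectral graph convolution needs a nonnegative symmetric adjacency with
#' self-loops: the raw directed STDP weights are symmetrized as
#' `(|A| + |A'|)/2`, rescaled so the largest entry is 1 (when nonzero), and
#' unit self-loops are added.
#'
#' @param graph An `adjacency_graph` (raw STDP output) or matrix.
#' @return An `adjacency_graph` with symmetric nonnegative weights and unit
#'   diagonal.
#' @export
postprocess_adjacency <- function(graph) {
  A <- if (inherits(graph, "adjacency_graph")) graph$weights else as.matrix(graph)
  S <- (abs(A) + t(abs(A))) / 2
  m <- max(S)
  if (m > 0) S <- S / m
  diag(S) <- diag(S) + 1
  adjacency_graph(S)
}

#' Baseline graphs for comparison with STDP-learned connectivity
#'
#' `fully_connected`: every off-diagonal weight equal to 1 (each area
#' connected to every other with the same strength). `random`: symmetric
#' i.i.d. Uniform(0, 1) off-diagonal weights, seeded.
#'
#' @param kind `"fully_connected"` or `"random"`.
#' @param n_channels Number of channels (>= 2).
#' @param seed Integer seed (used by `"random"`).
#' @return An `adjacency_graph` with zero diagonal (pass through
#'   [postprocess_adjacency()] before graph convolution).
#' @export
build_baseline_graph <- function(kind = c("fully_connected", "random"),
                                 n_channels, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n_channels >= 2)
  W <- switch(kind,
    fully_connected = {
      m <- matrix(1, n_channels, n_channels)
      diag(m) <- 0
      m
    },
    random = with_seed(seed, {
      m <- matrix(0, n_channels, n_channels)
      upper <- upper.tri(m)
      m[upper] <- stats::runif(sum(upper))
      m <- m + t(m)
      m
    })
  )
  adjacency_graph(W)
}

#' Aggregate per-epoch graphs by sleep stage
#'
#' Elementwise sum of the adjacency matrices grouped by stage label (the
#' stage-wise functional connectivity summary); stages absent from `labels`
#' map to zero matrices.
#'
#' @param graphs List of `adjacency_graph` objects.
#' @param labels Stage labels aligned with `graphs`.
#' @return Named list over [stage_levels()] of `adjacency_graph` objects.
#' @export
aggregate_stage_connectivity <- function(graphs, labels) {
  if (length(graphs) != length(labels)) {
    stop("graphs and labels differ in length")
  }
  labels <- as_stage_factor(labels)
  n <- graphs[[1]]$n_channels
  out <- stats::setNames(
    lapply(stage_levels(), function(s) matrix(0, n, n)), stage_levels())
  for (k in seq_along(graphs)) {
    s <- as.character(labels[k])
    out[[s]] <- out[[s]] + graphs[[k]]$weights
  }
  lapply(out, adjacency_graph)
}
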