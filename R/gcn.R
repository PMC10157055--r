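# Spatio-temporal graph convolution building blocks: symmetric normalized
# adjacency, the one-layer spectral graph convolution
# H' = sigma(D^{-1/2} A D^{-1/2} H W), a temporal convolution over the epoch
# axis with feature-axis softmax normalization on both sides, the stage
# classification head, and the cross-entropy loss.

#' Symmetric degree-normalized adjacency
#'
#' For a post-processed adjacency A (nonnegative, symmetric, unit self-loops;
#' see [postprocess_adjacency()]) returns `D^{-1/2} A D^{-1/2}` with
#' `D = diag(rowSums(A))`. Zero-degree rows/columns map to zero (guarded
#' division). The result is symmetric with eigenvalues in \[-1, 1\].
#'
#' @param A An `adjacency_graph` or square matrix with nonnegative entries.
#' @return Square numeric matrix.
#' @export
normalized_laplacian <- function(A) {
  A <- if (inherits(A, "adjacency_graph")) A$weights else as.matrix(A)
  if (any(A < 0)) {
    stop("adjacency has negative entries; run postprocess_adjacency() first")
  }
  d <- rowSums(A)
  s <- ifelse(d > 0, 1 / sqrt(d), 0)
  A * outer(s, s)   # diag(s) %*% A %*% diag(s)
}

activation_fn <- function(name) {
  if (is.function(name)) return(name)
  switch(name,
         relu = relu,
         identity = identity,
         tanh = tanh,
         sigmoid = function(x) 1 / (1 + exp(-x)),
         stop("unknown activation: ", name))
}

#' Graph convolution layer parameters
#'
#' @param weight Numeric matrix `in_features x out_features`.
#' @param activation Activation name (`"relu"`, `"identity"`, `"tanh"`,
#'   `"sigmoid"`) or a function.
#' @return Object of class `gcn_params`.
#' @export
gcn_params <- function(weight, activation = "relu") {
  weight <- as.matrix(weight)
  stopifnot(all(is.finite(weight)))
  structure(list(weight = weight, activation = activation),
            class = "gcn_params")
}

#' One spectral graph-convolution layer
#'
#' Computes `sigma(A_norm %*% H %*% W)`: node features are averaged over
#' degree-normalized neighbourhoods, mixed by the learnable weight matrix and
#' passed through the activation.
#'
#' @param H Node-feature matrix `N x F`.
#' @param A_norm Normalized adjacency from [normalized_laplacian()]
#'   (`N x N`).
#' @param params A [gcn_params()].
#' @return Matrix `N x F'`.
#' @export
gcn_forward <- function(H, A_norm, params) {
  H <- as.matrix(H)
  stopifnot(inherits(params, "gcn_params"))
  if (nrow(H) != nrow(A_norm) || ncol(A_norm) != nrow(A_norm)) {
    stop("shape mismatch between adjacency and node features")
  }
  if (ncol(H) != nrow(params$weight)) {
    stop("shape mismatch between node features and layer weight")
  }
  act <- activation_fn(params$activation)
  act(A_norm %*% H %*% params$weight)
}

#' Temporal convolution parameters
#'
#' @param kernel Numeric taps applied along the epoch (time) axis; shared
#'   across features.
#' @param inner_softmax Apply the feature-axis softmax before the convolution
#'   as well as after (the literal double-softmax form). Default `TRUE`;
#'   set `FALSE` to normalize only the output.
#' @return Object of class `temporal_conv_params`.
#' @export
temporal_conv_params <- function(kernel = rep(1 / 3, 3), inner_softmax = TRUE) {
  kernel <- as.numeric(kernel)
  stopifnot(length(kernel) >= 1, all(is.finite(kernel)))
  structure(list(kernel = kernel, kernel_size = length(kernel),
                 inner_softmax = isTRUE(inner_softmax)),
            class = "temporal_conv_params")
}

# centered offsets for a length-k kernel: k = 3 -> -1, 0, +1
conv_offsets <- function(k) seq_len(k) - ((k + 1L) %/% 2L)

#' Temporal convolution across the epoch axis
#'
#' Input rows are consecutive epochs (length M), columns are features. The
#' feature axis is softmax-normalized, a 1-D convolution with the shared
#' kernel runs along the epoch axis ("same" length, edge rows replicated at
#' the boundaries), and the feature axis is softmax-normalized again, so every
#' output row is a probability profile over features.
#'
#' @param H_seq Matrix `M x F` of per-epoch feature rows.
#' @param params A [temporal_conv_params()]; the kernel must not be longer
#'   than M.
#' @return Matrix `M x F`; flatten it (row-major) to obtain the temporal
#'   feature vector that feeds the classifier head.
#' @export
temporal_conv <- function(H_seq, params = temporal_conv_params()) {
  H_seq <- as.matrix(H_seq)
  stopifnot(inherits(params, "temporal_conv_params"))
  M <- nrow(H_seq)
  k <- params$kernel_size
  if (k > M) stop("temporal kernel longer than the epoch sequence")
  S <- if (params$inner_softmax) softmax_rows(H_seq) else H_seq
  C <- matrix(0, M, ncol(H_seq))
  for (j in seq_len(k)) {
    rows <- pmin(M, pmax(1L, seq_len(M) + conv_offsets(k)[j]))
    C <- C + params$kernel[j] * S[rows, , drop = FALSE]
  }
  softmax_rows(C)
}

#' Stage classification head
#'
#' Feed-forward layers (ReLU hidden activations) ending in a softmax over the
#' five sleep stages.
#'
#' @param features Feature vector (length must match the network input) or a
#'   matrix of feature rows.
#' @param theta_y An `mlp_net` classifier head, e.g.
#'   `stage_classifier(input_dim)`.
#' @return Probability vector over [stage_levels()] (or a matrix of rows).
#' @export
classify <- function(features, theta_y) {
  stopifnot(inherits(theta_y, "mlp_net"))
  out <- mlp_forward(features, theta_y)$probs
  colnames(out) <- stage_levels()[seq_len(ncol(out))]
  if (is.null(dim(features))) out[1, ] else out
}

#' Construct a stage classifier head
#'
#' @param input_dim Feature dimension entering the head (default 450).
#' @param hidden Hidden width (default 100).
#' @param n_classes Number of stages (fixed at 5 for AASM staging).
#' @return An `mlp_net` with dims `input_dim-hidden-n_classes`.
#' @export
stage_classifier <- function(input_dim = 450, hidden = 100, n_classes = 5) {
  mlp_init(c(input_dim, hidden, n_classes))
}

#' Mean cross-entropy classification loss
#'
#' Mean over samples of `-log p(true class)`. Probabilities are clamped at
#' 1e-12 before the log (a message reports when clamping fires).
#'
#' @param probs Probability matrix `B x K` (rows sum to 1) or a single
#'   probability vector.
#' @param labels True classes: factor/integer vector of length B, or a one-hot
#'   matrix `B x K`.
#' @return Nonnegative scalar loss.
#' @export
classification_loss <- function(probs, labels) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  if (is.matrix(labels)) {
    stopifnot(nrow(labels) == nrow(probs), ncol(labels) == ncol(probs))
    p_true <- rowSums(probs * labels)
  } else {
    y <- if (is.factor(labels)) as.integer(labels) else as.integer(labels)
    stopifnot(length(y) == nrow(probs), all(y >= 1), all(y <= ncol(probs)))
    p_true <- probs[cbind(seq_len(nrow(probs)), y)]
  }
  if (any(p_true < 1e-12)) {
    message("classification_loss: probabilities clamped at 1e-12")
    p_true <- pmax(p_true, 1e-12)
  }
  mean(-log(p_true))
}
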