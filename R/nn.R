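# Small neural-network toolkit: dense layers, softmax, manual backprop and
# Adam. Everything is plain base-R matrix algebra; parameter containers are
# flat named lists of numeric arrays so the optimizer can treat them
# uniformly.

relu <- function(x) pmax(x, 0)

softmax_rows <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  z <- x - apply(x, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Backprop through a row-wise softmax: given s = softmax(z) and dL/ds,
# dL/dz = s * (g - rowSums(g * s)).
softmax_rows_backward <- function(s, g) {
  s * (g - rowSums(g * s))
}

# He-initialized dense feed-forward net with ReLU hidden activations and a
# softmax output. `dims` includes input and output widths.
mlp_init <- function(dims) {
  stopifnot(length(dims) >= 2)
  layers <- lapply(seq_len(length(dims) - 1), function(l) {
    fan_in <- dims[l]
    list(W = matrix(stats::rnorm(fan_in * dims[l + 1], 0, sqrt(2 / fan_in)),
                    fan_in, dims[l + 1]),
         b = numeric(dims[l + 1]))
  })
  structure(list(dims = dims, layers = layers), class = "mlp_net")
}

add_bias <- function(x, b) x + matrix(b, nrow(x), length(b), byrow = TRUE)

# Forward pass; returns softmax probabilities plus the per-layer caches needed
# for backprop.
mlp_forward <- function(x, net) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != net$dims[1]) {
    stop("feature dimension ", ncol(x), " does not match network input ",
         net$dims[1])
  }
  L <- length(net$layers)
  acts <- vector("list", L + 1)
  pre <- vector("list", L)
  acts[[1]] <- x
  for (l in seq_len(L)) {
    z <- add_bias(acts[[l]] %*% net$layers[[l]]$W, net$layers[[l]]$b)
    pre[[l]] <- z
    acts[[l + 1]] <- if (l < L) relu(z) else z
  }
  list(probs = softmax_rows(acts[[L + 1]]), logits = acts[[L + 1]],
       acts = acts, pre = pre)
}

# Backprop from a gradient w.r.t. the logits; returns per-layer parameter
# gradients and the gradient w.r.t. the input rows.
mlp_backward <- function(net, cache, glogits) {
  L <- length(net$layers)
  grads <- vector("list", L)
  g <- glogits
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(cache$acts[[l]], g), b = colSums(g))
    g <- g %*% t(net$layers[[l]]$W)
    if (l > 1) g <- g * (cache$pre[[l - 1]] > 0)
  }
  list(grads = grads, gx = g)
}

#' Count trainable parameters of a network
#'
#' @param net An `mlp_net` (e.g. from [domain_discriminator()]) or a plain
#'   list of numeric arrays.
#' @return Integer total number of scalar parameters.
#' @export
count_parameters <- function(net) {
  if (inherits(net, "mlp_net")) {
    sum(vapply(net$layers, function(l) length(l$W) + length(l$b), numeric(1)))
  } else {
    sum(vapply(net, length, numeric(1)))
  }
}

adam_init <- function(par) {
  zeros <- lapply(par, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p)))
  list(m = zeros, v = zeros, t = 0)
}

# One Adam step over a flat named list of arrays. Weight decay is added to the
# gradient (L2 regularization), matching the common Adam implementation.
adam_step <- function(par, grad, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grad[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * par[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}
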