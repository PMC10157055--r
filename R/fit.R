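# Model fitting. The feature extractor is: per epoch, an STDP-learned,
# degree-normalized connectivity graph aggregates per-channel features through
# one graph-convolution layer; the M epochs of a temporal context are then
# combined by a softmax-normalized temporal convolution, flattened, and
# linearly projected to the fixed feature width. A stage classifier head and
# (optionally) a gradient-reversed domain discriminator sit on top. All
# forward/backward passes are hand-written base-R matrix algebra; parameters
# are optimized with Adam.

#' Training and model configuration
#'
#' Full-scale defaults: Adam, learning rate
#' 1e-4, 500 training epochs, batch size 256, weight decay 1e-3, dropout 0.5,
#' one GCN layer, M = 5 temporal contexts, STDP trace constant tau = 100
#' samples with learning rate 1e-2, BSA spiking threshold 1.0 (FIR length 20,
#' cutoff 0.8), domain discriminator 450-512-100-2, gradient-reversal
#' lambda = 1. Desk-scale runs on small synthetic datasets typically lower
#' `epochs` and `batch_size` and raise `learning_rate` (see the vignette).
#'
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs (full passes over the source contexts).
#' @param batch_size Source samples per optimization step.
#' @param weight_decay L2 penalty added to gradients.
#' @param dropout Dropout probability on the flattened temporal features.
#' @param gcn_layers Number of graph-convolution layers (only 1 supported).
#' @param M Temporal context length (odd).
#' @param tau STDP trace time constant in samples.
#' @param spike_threshold BSA spiking threshold.
#' @param stdp_lr STDP learning rate (potentiation rate; depression is its
#'   negative).
#' @param discriminator_dims Domain discriminator layer widths; the first
#'   entry fixes the extracted feature dimension.
#' @param lambda Gradient-reversal strength.
#' @param adversarial Train the domain-adversarial branch when a target
#'   domain is supplied.
#' @param hidden_dim Graph-convolution output width per node.
#' @param temporal_kernel Temporal convolution kernel length.
#' @param classifier_hidden Hidden width of the stage classifier head.
#' @param pool_bins Average-pooling bins per channel for the node features
#'   (plus one log-amplitude feature).
#' @param node_identity Append a one-hot node-identity block to the node
#'   features, so the graph convolution retains the full connectivity
#'   pattern (the standard featureless-graph device) rather than only its
#'   degree profile.
#' @param inner_softmax Use the double-softmax temporal convolution form.
#' @param average_tail Fraction of final training epochs over which parameters
#'   are averaged for the returned model (0 disables). Tail averaging damps
#'   the step-to-step wander of Adam near convergence and typically improves
#'   held-out accuracy on small datasets.
#' @param n_models Number of independently seeded fits kept in the model;
#'   predictions average their probabilities (a small seed ensemble that
#'   damps run-to-run variance). Feature extraction uses the first fit.
#' @param fir_length,fir_cutoff BSA FIR filter design.
#' @return Object of class `stdpgcn_config` (a validated list).
#' @export
stdpgcn_config <- function(learning_rate = 1e-4, epochs = 500,
                           batch_size = 256, weight_decay = 1e-3,
                           dropout = 0.5, gcn_layers = 1, M = 5, tau = 100,
                           spike_threshold = 1.0, stdp_lr = 1e-2,
                           discriminator_dims = c(450, 512, 100, 2),
                           lambda = 1.0, adversarial = TRUE,
                           hidden_dim = 16, temporal_kernel = 3,
                           classifier_hidden = 100, pool_bins = 8,
                           node_identity = TRUE, inner_softmax = TRUE,
                           average_tail = 0.25, n_models = 1,
                           fir_length = 20, fir_cutoff = 0.8) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1,
            weight_decay >= 0, dropout >= 0, dropout < 1,
            tau > 0, spike_threshold >= 0, stdp_lr > 0,
            average_tail >= 0, average_tail <= 1, n_models >= 1,
            lambda >= 0, hidden_dim >= 1, temporal_kernel >= 1,
            classifier_hidden >= 1, pool_bins >= 1)
  if (gcn_layers != 1) stop("only a single graph-convolution layer is supported")
  if (M < 1 || M %% 2 == 0) stop("M must be odd (M = 2c + 1)")
  if (utils::tail(discriminator_dims, 1) != 2) {
    stop("discriminator_dims must end in 2")
  }
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, weight_decay = weight_decay,
                 dropout = dropout, gcn_layers = gcn_layers, M = M, tau = tau,
                 spike_threshold = spike_threshold, stdp_lr = stdp_lr,
                 discriminator_dims = discriminator_dims, lambda = lambda,
                 adversarial = adversarial, hidden_dim = hidden_dim,
                 temporal_kernel = temporal_kernel,
                 classifier_hidden = classifier_hidden,
                 pool_bins = pool_bins, node_identity = isTRUE(node_identity),
                 inner_softmax = inner_softmax, average_tail = average_tail,
                 n_models = as.integer(n_models),
                 fir_length = fir_length, fir_cutoff = fir_cutoff,
                 feature_dim_out = discriminator_dims[1], n_classes = 5),
            class = "stdpgcn_config")
}

# Per-channel node features: pool_bins average-pooled bins of the min-max
# normalized signal plus one log-amplitude feature (log1p of the raw SD).
node_features <- function(epoch, pool_bins = 8) {
  N <- nrow(epoch)
  L <- ncol(epoch)
  bin <- floor((seq_len(L) - 1) * pool_bins / L) + 1
  t(vapply(seq_len(N), function(ch) {
    s <- epoch[ch, ]
    ns <- normalize_signal(s)
    c(as.numeric(tapply(ns, bin, mean)), log1p(stats::sd(s)))
  }, numeric(pool_bins + 1)))
}

# Full unsupervised preprocessing of a dataset: BSA encoding, STDP graph,
# adjacency post-processing, degree normalization, node features, and the
# parameter-free product P_e = L_e %*% X_e that feeds the GCN weight matrix.
preprocess_dataset <- function(dataset, config) {
  stopifnot(inherits(dataset, "psg_dataset"))
  E <- dim(dataset$signals)[3]
  N <- dim(dataset$signals)[1]
  fir <- design_fir(config$fir_length, config$fir_cutoff)
  bsa <- bsa_config(config$spike_threshold, fir)
  stdp <- stdp_params(a_plus = config$stdp_lr, a_minus = -config$stdp_lr,
                      tau = config$tau)
  Fin <- config$pool_bins + 1 + if (config$node_identity) N else 0
  P <- array(NA_real_, c(N, Fin, E))
  lap <- array(NA_real_, c(N, N, E))
  graphs <- vector("list", E)
  for (e in seq_len(E)) {
    ep <- dataset$signals[, , e]
    g <- learn_epoch_graph(encode_epoch(ep, bsa), stdp)
    graphs[[e]] <- g
    L_e <- normalized_laplacian(postprocess_adjacency(g))
    lap[, , e] <- L_e
    X_e <- node_features(ep, config$pool_bins)
    if (config$node_identity) X_e <- cbind(X_e, diag(N))
    P[, , e] <- L_e %*% X_e
  }
  list(P = P, lap = lap, graphs = graphs,
       labels = dataset$labels, subject_ids = dataset$subject_ids,
       N = N, Fin = Fin)
}

# Context index windows: for each epoch of each subject, the M surrounding
# same-subject epoch indices (boundary epochs replicated at the edges).
contexts_from_subjects <- function(subject_ids, M) {
  c_half <- (M - 1) %/% 2
  rows <- list()
  centers <- integer(0)
  for (s in unique(subject_ids)) {
    idx <- which(subject_ids == s)
    K <- length(idx)
    for (p in seq_len(K)) {
      w <- pmin(K, pmax(1L, p + (-c_half):c_half))
      rows[[length(rows) + 1]] <- idx[w]
      centers <- c(centers, idx[p])
    }
  }
  list(indices = do.call(rbind, rows), centers = centers)
}

# Initialize all trainable parameters from the current RNG state, in a fixed
# order so runs with and without the adversarial branch consume identical
# random draws. Flat named list; the disc_ prefix marks discriminator layers.
init_params <- function(config, N) {
  Fin <- config$pool_bins + 1 + if (config$node_identity) N else 0
  h <- config$hidden_dim
  M <- config$M
  Fdim <- N * h
  fdo <- config$feature_dim_out
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  par <- list(
    Wg = he(Fin, h),
    phi = rep(1 / config$temporal_kernel, config$temporal_kernel),
    Wp = he(M * Fdim, fdo), bp = numeric(fdo),
    Wc1 = he(fdo, config$classifier_hidden),
    bc1 = numeric(config$classifier_hidden),
    Wc2 = he(config$classifier_hidden, config$n_classes),
    bc2 = numeric(config$n_classes)
  )
  dims <- config$discriminator_dims
  for (l in seq_len(length(dims) - 1)) {
    par[[paste0("Wd", l)]] <- he(dims[l], dims[l + 1])
    par[[paste0("bd", l)]] <- numeric(dims[l + 1])
  }
  par
}

trunk_param_names <- function() c("Wg", "phi", "Wp", "bp")
classifier_param_names <- function() c("Wc1", "bc1", "Wc2", "bc2")
disc_param_names <- function(par) grep("^[Wb]d", names(par), value = TRUE)

# Forward pass of the feature extractor over a batch of contexts.
# P: [N, Fin, E]; ctx: B x M matrix of epoch indices. Returns X_f plus every
# intermediate needed for backprop. Row bookkeeping: GCN rows are ordered
# channel-fastest, then epoch-within-context, then context.
forward_trunk <- function(P, ctx, par, config, dropout_mask = NULL) {
  B <- nrow(ctx)
  M <- config$M
  N <- dim(P)[1]
  h <- config$hidden_dim
  Fdim <- N * h
  k <- config$temporal_kernel
  e_vec <- as.vector(t(ctx))
  Pmat <- matrix(aperm(P[, , e_vec, drop = FALSE], c(1, 3, 2)),
                 nrow = N * B * M, ncol = dim(P)[2])
  Hpre <- Pmat %*% par$Wg
  Hr <- relu(Hpre)
  S <- t(matrix(t(Hr), nrow = h * N, ncol = B * M))
  S1 <- if (config$inner_softmax) softmax_rows(S) else S
  C <- matrix(0, B * M, Fdim)
  off <- conv_offsets(k)
  base <- rep((seq_len(B) - 1L) * M, each = M)
  idx_list <- lapply(seq_len(k), function(j) {
    base + pmin(M, pmax(1L, seq_len(M) + off[j]))
  })
  for (j in seq_len(k)) {
    C <- C + par$phi[j] * S1[idx_list[[j]], , drop = FALSE]
  }
  S2 <- softmax_rows(C)
  # flatten and center: softmax rows carry a constant 1/F offset that is two
  # orders of magnitude above their informative variance; dropout and the
  # projection act on the centered, rescaled residual (F*S2 - 1) so the
  # multiplicative dropout noise scales with the signal, not the offset
  V <- Fdim * t(matrix(t(S2), nrow = Fdim * M, ncol = B)) - 1
  if (!is.null(dropout_mask)) V <- V * dropout_mask
  Z <- add_bias(V %*% par$Wp, par$bp)
  # row layer-norm: the projected features otherwise inherit the softmax's
  # tiny scale, leaving both heads with near-zero logits
  mu <- rowMeans(Z)
  zc <- Z - mu
  sdr <- sqrt(rowMeans(zc^2) + 1e-6)
  Xf <- zc / sdr
  list(Xf = Xf, sdr = sdr, V = V, S2 = S2, S1 = S1, Hpre = Hpre, Pmat = Pmat,
       idx_list = idx_list, B = B, dropout_mask = dropout_mask)
}

# Backward pass of the feature extractor given dL/dXf; returns trunk grads.
backward_trunk <- function(cache, gXf, par, config) {
  B <- cache$B
  M <- config$M
  h <- config$hidden_dim
  N <- nrow(cache$Pmat) / (B * M)
  Fdim <- N * h
  k <- config$temporal_kernel
  # back through the row layer-norm
  Y <- cache$Xf
  gZ <- (gXf - rowMeans(gXf) - Y * rowMeans(gXf * Y)) / cache$sdr
  gWp <- crossprod(cache$V, gZ)
  gbp <- colSums(gZ)
  gV <- gZ %*% t(par$Wp)
  if (!is.null(cache$dropout_mask)) gV <- gV * cache$dropout_mask
  gS2 <- Fdim * t(matrix(t(gV), nrow = Fdim, ncol = M * B))
  gC <- softmax_rows_backward(cache$S2, gS2)
  gS1 <- matrix(0, B * M, Fdim)
  gphi <- numeric(k)
  for (j in seq_len(k)) {
    idx <- cache$idx_list[[j]]
    gphi[j] <- sum(gC * cache$S1[idx, , drop = FALSE])
    contrib <- rowsum(gC * par$phi[j], group = idx)
    rows <- as.integer(rownames(contrib))
    gS1[rows, ] <- gS1[rows, ] + contrib
  }
  gS <- if (config$inner_softmax) {
    softmax_rows_backward(cache$S1, gS1)
  } else gS1
  gHr <- t(matrix(t(gS), nrow = h, ncol = N * B * M))
  gHpre <- gHr * (cache$Hpre > 0)
  gWg <- crossprod(cache$Pmat, gHpre)
  list(Wg = gWg, phi = gphi, Wp = gWp, bp = gbp)
}

# Classifier head forward/backward on top of X_f.
forward_class <- function(Xf, par) {
  Z1p <- add_bias(Xf %*% par$Wc1, par$bc1)
  Z1 <- relu(Z1p)
  logits <- add_bias(Z1 %*% par$Wc2, par$bc2)
  list(probs = softmax_rows(logits), Z1 = Z1, Z1p = Z1p)
}

backward_class <- function(cache, glogits, Xf, par) {
  gWc2 <- crossprod(cache$Z1, glogits)
  gbc2 <- colSums(glogits)
  gZ1 <- (glogits %*% t(par$Wc2)) * (cache$Z1p > 0)
  gWc1 <- crossprod(Xf, gZ1)
  gbc1 <- colSums(gZ1)
  list(grads = list(Wc1 = gWc1, bc1 = gbc1, Wc2 = gWc2, bc2 = gbc2),
       gXf = gZ1 %*% t(par$Wc1))
}

# Discriminator forward/backward (arbitrary depth, ReLU hidden, softmax out).
disc_net <- function(par, dims) {
  layers <- lapply(seq_len(length(dims) - 1), function(l) {
    list(W = par[[paste0("Wd", l)]], b = par[[paste0("bd", l)]])
  })
  structure(list(dims = dims, layers = layers), class = "mlp_net")
}

# Cross-entropy gradient wrt logits for weighted rows: (p - onehot) * w.
ce_logit_grad <- function(probs, y_int, w) {
  g <- probs
  g[cbind(seq_len(nrow(g)), y_int)] <- g[cbind(seq_len(nrow(g)), y_int)] - 1
  g * w
}

#' @keywords internal
train_core <- function(prep_s, prep_t, config, seed, verbose = FALSE) {
  set.seed(seed)
  ctx_s <- contexts_from_subjects(prep_s$subject_ids, config$M)
  y_s <- as.integer(prep_s$labels[ctx_s$centers])
  have_target <- !is.null(prep_t)
  if (have_target) {
    ctx_t <- contexts_from_subjects(prep_t$subject_ids, config$M)
  }
  N <- prep_s$N
  par <- init_params(config, N)
  opt <- adam_init(par)
  dims <- config$discriminator_dims
  n_s <- nrow(ctx_s$indices)
  b <- min(config$batch_size, n_s)
  vdim <- config$M * N * config$hidden_dim
  lambda_eff <- if (config$adversarial) config$lambda else 0
  history <- matrix(NA_real_, config$epochs, 2,
                    dimnames = list(NULL, c("class_loss", "domain_loss")))
  avg_from <- if (config$average_tail > 0) {
    max(1L, ceiling((1 - config$average_tail) * config$epochs) + 1L)
  } else Inf
  par_avg <- NULL
  n_avg <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n_s)
    if (have_target) {
      n_t <- nrow(ctx_t$indices)
      tord <- sample.int(n_t)
    }
    steps <- ceiling(n_s / b)
    closses <- dlosses <- numeric(steps)
    for (st in seq_len(steps)) {
      rows_s <- ord[((st - 1) * b + 1):min(st * b, n_s)]
      bs <- length(rows_s)
      if (have_target) {
        tpos <- ((st - 1) * bs + seq_len(bs) - 1) %% n_t + 1
        rows_t <- tord[tpos]
        ctx_b <- rbind(ctx_s$indices[rows_s, , drop = FALSE],
                       ctx_t$indices[rows_t, , drop = FALSE])
        Pb <- combine_P(prep_s$P, prep_t$P, ctx_b, bs)
        src <- seq_len(bs)
        tgt <- bs + seq_len(bs)
      } else {
        ctx_b <- ctx_s$indices[rows_s, , drop = FALSE]
        Pb <- list(P = prep_s$P, ctx = ctx_b)
        src <- seq_len(bs)
        tgt <- integer(0)
      }
      Btot <- nrow(Pb$ctx)
      mask <- if (config$dropout > 0) {
        matrix((stats::runif(Btot * vdim) >= config$dropout) /
                 (1 - config$dropout), Btot, vdim)
      } else NULL
      cache <- forward_trunk(Pb$P, Pb$ctx, par, config, mask)
      cls <- forward_class(cache$Xf[src, , drop = FALSE], par)
      yb <- y_s[rows_s]
      closses[st] <- classification_loss(cls$probs, yb)
      glog_c <- ce_logit_grad(cls$probs, yb, 1 / bs)
      bc <- backward_class(cls, glog_c, cache$Xf[src, , drop = FALSE], par)
      gXf <- matrix(0, Btot, config$feature_dim_out)
      gXf[src, ] <- bc$gXf
      grads <- bc$grads
      if (have_target) {
        dnet <- disc_net(par, dims)
        dfw <- mlp_forward(gradient_reverse(cache$Xf, lambda_eff), dnet)
        dlab <- c(rep(1L, length(src)), rep(2L, length(tgt)))  # 1=source, 2=target
        dlosses[st] <- domain_loss(dfw$probs, dlab - 1L)
        w <- ifelse(dlab == 1L, 1 / length(src), 1 / length(tgt))
        glog_d <- ce_logit_grad(dfw$probs, dlab, w)
        bd <- mlp_backward(dnet, dfw, glog_d)
        if (config$adversarial) {
          for (l in seq_along(bd$grads)) {
            grads[[paste0("Wd", l)]] <- bd$grads[[l]]$W
            grads[[paste0("bd", l)]] <- bd$grads[[l]]$b
          }
        }
        gXf <- gXf + gradient_reverse_backward(bd$gx, lambda_eff)
      } else {
        dlosses[st] <- NA_real_
      }
      gtrunk <- backward_trunk(cache, gXf, par, config)
      grads <- c(grads, gtrunk)
      upd <- adam_step(par, grads, opt, config$learning_rate,
                       config$weight_decay)
      par <- upd$par
      opt <- upd$state
    }
    if (ep >= avg_from) {
      n_avg <- n_avg + 1L
      par_avg <- if (is.null(par_avg)) par else {
        Map(function(a, b) a + (b - a) / n_avg, par_avg, par)
      }
    }
    history[ep, ] <- c(mean(closses), mean(dlosses))
    if (!is.finite(history[ep, 1])) {
      stop("training diverged at epoch ", ep,
           ": non-finite classification loss")
    }
    if (verbose && ep %% 20 == 0) {
      message(sprintf("epoch %d: class loss %.4f domain loss %.4f",
                      ep, history[ep, 1], history[ep, 2]))
    }
  }
  if (!is.null(par_avg)) par <- par_avg
  list(par = par, history = as.data.frame(cbind(epoch = seq_len(config$epochs),
                                                history)),
       N = N)
}

# Stack source and target context batches over two preprocessed arrays by
# concatenating the epoch axis and offsetting the target context indices.
combine_P <- function(P_s, P_t, ctx_b, n_src_rows) {
  E_s <- dim(P_s)[3]
  Pall <- array(c(P_s, P_t), c(dim(P_s)[1], dim(P_s)[2], E_s + dim(P_t)[3]))
  ctx <- ctx_b
  if (nrow(ctx) > n_src_rows) {
    ctx[(n_src_rows + 1):nrow(ctx), ] <-
      ctx[(n_src_rows + 1):nrow(ctx), ] + E_s
  }
  list(P = Pall, ctx = ctx)
}

#' Fit the STDP-graph spatio-temporal GCN sleep stager
#'
#' Learns per-epoch connectivity graphs with the unsupervised STDP rule, then
#' trains the graph-convolutional stage classifier on the labeled `data`. If a
#' `target` dataset is supplied (e.g. the held-out subjects of a
#' subject-independent split, labels ignored) and `config$adversarial` is
#' `TRUE`, a domain discriminator with gradient reversal pushes the extracted
#' features to be indistinguishable between the two domains.
#'
#' @param data Labeled training data: a `psg_dataset` (see
#'   [generate_stage_dataset()]).
#' @param target Optional unlabeled target-domain `psg_dataset`.
#' @param config A [stdpgcn_config()].
#' @param seed Integer seed controlling initialization, batching and dropout.
#' @param verbose Print progress every 20 epochs.
#' @return Object of class `stdpgcn`: trained parameters, the config, and the
#'   per-epoch loss history (`$history` with columns epoch, class_loss,
#'   domain_loss).
#' @export
stdpgcn <- function(data, target = NULL, config = stdpgcn_config(), seed = 1,
                    verbose = FALSE) {
  stopifnot(inherits(config, "stdpgcn_config"))
  if (config$adversarial && is.null(target)) {
    warning("no target domain supplied; the adversarial branch is inactive")
  }
  prep_s <- preprocess_dataset(data, config)
  prep_t <- if (!is.null(target)) preprocess_dataset(target, config)
  fits <- lapply(seq_len(config$n_models) - 1L, function(k) {
    train_core(prep_s, prep_t, config, seed + k, verbose)
  })
  structure(list(par = fits[[1]]$par,
                 pars = lapply(fits, `[[`, "par"),
                 config = config, history = fits[[1]]$history,
                 N = fits[[1]]$N, stage_levels = stage_levels(), seed = seed,
                 n_train_epochs = dim(data$signals)[3],
                 call = match.call()),
            class = "stdpgcn")
}

#' @rdname stdpgcn
#' @param train_data,target_data Training / target-domain datasets (aliases
#'   used by the cross-validation driver).
#' @export
train_fold <- function(train_data, target_data = NULL,
                       config = stdpgcn_config(), seed = 1, verbose = FALSE) {
  stdpgcn(train_data, target = target_data, config = config, seed = seed,
          verbose = verbose)
}

# Deterministic (dropout-free) forward pass over all contexts of a
# preprocessed dataset, in memory-bounded chunks.
model_forward_eval <- function(object, prep, what = c("probs", "features")) {
  what <- match.arg(what)
  ctx <- contexts_from_subjects(prep$subject_ids, object$config$M)
  n <- nrow(ctx$indices)
  out <- NULL
  chunk <- 512L
  pars <- if (what == "features" || is.null(object$pars)) {
    list(object$par)
  } else object$pars
  for (start in seq(1, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    pieces <- lapply(pars, function(par) {
      cache <- forward_trunk(prep$P, ctx$indices[rows, , drop = FALSE],
                             par, object$config, NULL)
      if (what == "features") cache$Xf else forward_class(cache$Xf, par)$probs
    })
    out <- rbind(out, Reduce(`+`, pieces) / length(pieces))
  }
  list(out = out, centers = ctx$centers)
}

#' Extract domain-invariant features for every epoch context
#'
#' Runs the trained feature extractor (STDP graphs -> graph convolution ->
#' temporal convolution -> projection) in evaluation mode (no dropout).
#'
#' @param object A fitted [stdpgcn()] model.
#' @param data A `psg_dataset`.
#' @return Matrix `n_epochs x feature_dim_out`, rows aligned with the epochs
#'   of `data` (each epoch is the center of one temporal context).
#' @export
extract_features <- function(object, data) {
  stopifnot(inherits(object, "stdpgcn"))
  prep <- preprocess_dataset(data, object$config)
  res <- model_forward_eval(object, prep, "features")
  res$out[order(res$centers), , drop = FALSE]
}

#' Predict sleep stages
#'
#' @param object A fitted [stdpgcn()] model.
#' @param newdata A `psg_dataset`.
#' @param type `"class"` for stage labels, `"prob"` for the 5-column
#'   probability matrix.
#' @param ... Unused.
#' @return Factor over [stage_levels()] or a probability matrix, aligned with
#'   the epochs of `newdata`.
#' @export
predict.stdpgcn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  prep <- preprocess_dataset(newdata, object$config)
  res <- model_forward_eval(object, prep, "probs")
  probs <- res$out[order(res$centers), , drop = FALSE]
  colnames(probs) <- object$stage_levels
  if (type == "prob") return(probs)
  factor(object$stage_levels[max.col(probs, ties.method = "first")],
         levels = object$stage_levels)
}

#' @export
print.stdpgcn <- function(x, ...) {
  cat("STDP-graph spatio-temporal GCN sleep stager\n")
  cat("  channels:", x$N, " temporal context M:", x$config$M, "\n")
  cat("  feature dim:", x$config$feature_dim_out,
      " adversarial:", x$config$adversarial, "(lambda", x$config$lambda, ")\n")
  cat("  trained", nrow(x$history), "epochs on", x$n_train_epochs,
      "signal epochs; final class loss",
      format(utils::tail(x$history$class_loss, 1), digits = 4), "\n")
  invisible(x)
}

#' @export
summary.stdpgcn <- function(object, ...) {
  h <- object$history
  cat("Model: STDP connectivity graphs + 1-layer GCN + temporal conv ",
      "+ softmax head\n", sep = "")
  print(object)
  cat("  parameters:", count_parameters(object$par), "total;",
      count_parameters(object$par[disc_param_names(object$par)]),
      "in the domain discriminator\n")
  cat("  loss trajectory (class):",
      format(h$class_loss[1], digits = 4), "->",
      format(utils::tail(h$class_loss, 1), digits = 4), "\n")
  invisible(object)
}

#' @export
coef.stdpgcn <- function(object, ...) object$par

#' Plot training loss curves
#'
#' Stage-classifier loss (and, when present, domain-discriminator loss)
#' against the training epoch.
#'
#' @param x A fitted [stdpgcn()] model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.stdpgcn <- function(x, ...) {
  h <- x$history
  has_dom <- any(is.finite(h$domain_loss))
  y <- if (has_dom) cbind(h$class_loss, h$domain_loss) else h$class_loss
  graphics::matplot(h$epoch, y, type = "l", lty = 1,
                    col = c("firebrick", "steelblue")[seq_len(NCOL(y))],
                    xlab = "training epoch", ylab = "loss", ...)
  graphics::legend("topright",
                   legend = c("stage classifier",
                              if (has_dom) "domain discriminator"),
                   col = c("firebrick", "steelblue")[seq_len(NCOL(y))],
                   lty = 1, bty = "n")
  invisible(x)
}
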