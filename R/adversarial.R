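# Domain-adversarial training components: gradient reversal, the domain
# discriminator, the binary domain loss and the combined objective. The
# package trains with hand-written backprop, so gradient reversal is a pair of
# functions: the forward pass is the identity and the backward rule multiplies
# the incoming gradient by -lambda; the training loop applies the backward
# rule to the gradient flowing from the discriminator into the feature
# extractor, which turns the min-max objective into one ordinary backward
# pass.

#' Gradient reversal layer: forward pass
#'
#' Identity on the features; the reversal acts only on gradients (see
#' [gradient_reverse_backward()]).
#'
#' @param x Feature vector or matrix.
#' @param lambda Reversal strength (>= 0); recorded as an attribute.
#' @return `x` unchanged, with attribute `grl_lambda`.
#' @export
gradient_reverse <- function(x, lambda = 1) {
  stopifnot(lambda >= 0)
  attr(x, "grl_lambda") <- lambda
  x
}

#' Gradient reversal layer: backward rule
#'
#' @param grad Gradient arriving from the domain branch.
#' @param lambda Reversal strength.
#' @return `-lambda * grad`, exactly.
#' @export
gradient_reverse_backward <- function(grad, lambda = 1) {
  -lambda * grad
}

#' Construct the domain discriminator network
#'
#' Feed-forward net over the extracted features with ReLU hidden layers and a
#' 2-way softmax (source vs target). The default widths are 450-512-100-2.
#' Parameters are drawn from the current RNG state.
#'
#' @param dims Layer widths; the first entry must match the feature dimension,
#'   the last must be 2.
#' @return An `mlp_net`.
#' @export
domain_discriminator <- function(dims = c(450, 512, 100, 2)) {
  if (utils::tail(dims, 1) != 2) stop("domain discriminator must end in 2 units")
  mlp_init(dims)
}

#' Domain discrimination forward pass
#'
#' @param X_f Feature vector or matrix of feature rows; the width must match
#'   the discriminator input dimension.
#' @param theta_d An `mlp_net` from [domain_discriminator()].
#' @return Probability pair(s) `(P(source), P(target))`: a vector for a single
#'   feature vector, otherwise a `B x 2` matrix.
#' @export
discriminate_domain <- function(X_f, theta_d) {
  stopifnot(inherits(theta_d, "mlp_net"))
  out <- mlp_forward(X_f, theta_d)$probs
  colnames(out) <- c("source", "target")
  if (is.null(dim(X_f))) out[1, ] else out
}

#' Binary domain cross-entropy
#'
#' `-mean(d * log P(target) + (1 - d) * log P(source))`, with probabilities
#' clamped at 1e-12.
#'
#' @param y_hat Probability pairs from [discriminate_domain()] (vector of
#'   length 2 or `B x 2` matrix with columns source, target).
#' @param d Binary domain labels (0 = source, 1 = target).
#' @return Nonnegative scalar loss.
#' @export
domain_loss <- function(y_hat, d) {
  if (is.null(dim(y_hat))) y_hat <- matrix(y_hat, ncol = 2, byrow = TRUE)
  d <- as.numeric(d)
  stopifnot(length(d) == nrow(y_hat), all(d %in% c(0, 1)))
  p_true <- ifelse(d == 1, y_hat[, 2], y_hat[, 1])
  if (any(p_true < 1e-12)) {
    message("domain_loss: probabilities clamped at 1e-12")
    p_true <- pmax(p_true, 1e-12)
  }
  mean(-log(p_true))
}

#' Combined adversarial training objective
#'
#' `E = mean(class losses) - lambda * (mean(source domain losses) +
#' mean(target domain losses))`. Classification losses are computed on labeled
#' source samples only; the domain terms average separately over source and
#' target samples (an empty target term contributes 0). The feature extractor
#' and stage classifier are trained to decrease E while the discriminator is
#' trained to increase the domain term; with gradient reversal both happen in
#' a single backward pass.
#'
#' @param class_losses Per-sample classification losses (source batch).
#' @param domain_losses_source Per-sample domain losses on source samples.
#' @param domain_losses_target Per-sample domain losses on target samples.
#' @param lambda Adversarial weight (>= 0).
#' @return Scalar value of the objective.
#' @export
total_objective <- function(class_losses, domain_losses_source = numeric(0),
                            domain_losses_target = numeric(0), lambda = 1) {
  if (length(class_losses) == 0) stop("empty classification batch")
  dom <- 0
  if (length(domain_losses_source) > 0) dom <- dom + mean(domain_losses_source)
  if (length(domain_losses_target) > 0) dom <- dom + mean(domain_losses_target)
  mean(class_losses) - lambda * dom
}

#' Held-out domain accuracy of a probe discriminator on frozen features
#'
#' Trains a fresh domain discriminator on frozen feature rows from two
#' domains (70/30 stratified train/test split) and returns its held-out
#' accuracy. Features from a well-adapted extractor should leave the probe
#' near chance (0.5).
#'
#' @param X_source,X_target Feature matrices (rows = samples) from the two
#'   domains.
#' @param seed Integer seed (split, initialization, batching).
#' @param dims Probe layer widths; defaults to the standard discriminator
#'   sized to the feature width.
#' @param epochs,learning_rate Probe training schedule.
#' @param X_source_test,X_target_test Optional explicit held-out feature
#'   matrices; when supplied the probe trains on all of
#'   `X_source`/`X_target` and is evaluated on these instead of an internal
#'   70/30 split.
#' @return Held-out accuracy in \[0, 1\].
#' @export
probe_domain_accuracy <- function(X_source, X_target, seed = 1,
                                  dims = c(ncol(X_source), 512, 100, 2),
                                  epochs = 60, learning_rate = 1e-3,
                                  X_source_test = NULL,
                                  X_target_test = NULL) {
  stopifnot(ncol(X_source) == ncol(X_target))
  X <- rbind(X_source, X_target)
  d <- c(rep(1L, nrow(X_source)), rep(2L, nrow(X_target)))  # class index
  external_test <- !is.null(X_source_test)
  if (external_test) {
    stopifnot(!is.null(X_target_test),
              ncol(X_source_test) == ncol(X), ncol(X_target_test) == ncol(X))
    X_test <- rbind(X_source_test, X_target_test)
    d_test <- c(rep(1L, nrow(X_source_test)), rep(2L, nrow(X_target_test)))
  }
  with_seed(seed, {
    if (external_test) {
      test_idx <- integer(0)
    } else {
      test_idx <- unlist(lapply(1:2, function(k) {
        idx <- which(d == k)
        sample(idx, max(1, round(0.3 * length(idx))))
      }))
    }
    train_idx <- setdiff(seq_len(nrow(X)), test_idx)
    net <- mlp_init(dims)
    par <- list()
    for (l in seq_along(net$layers)) {
      par[[paste0("W", l)]] <- net$layers[[l]]$W
      par[[paste0("b", l)]] <- net$layers[[l]]$b
    }
    opt <- adam_init(par)
    b <- min(64L, length(train_idx))
    for (ep in seq_len(epochs)) {
      ord <- sample(train_idx)
      for (st in seq_len(ceiling(length(ord) / b))) {
        rows <- ord[((st - 1) * b + 1):min(st * b, length(ord))]
        for (l in seq_along(net$layers)) {
          net$layers[[l]]$W <- par[[paste0("W", l)]]
          net$layers[[l]]$b <- par[[paste0("b", l)]]
        }
        fw <- mlp_forward(X[rows, , drop = FALSE], net)
        glog <- ce_logit_grad(fw$probs, d[rows], 1 / length(rows))
        bk <- mlp_backward(net, fw, glog)
        grads <- list()
        for (l in seq_along(bk$grads)) {
          grads[[paste0("W", l)]] <- bk$grads[[l]]$W
          grads[[paste0("b", l)]] <- bk$grads[[l]]$b
        }
        upd <- adam_step(par, grads, opt, learning_rate)
        par <- upd$par
        opt <- upd$state
      }
    }
    for (l in seq_along(net$layers)) {
      net$layers[[l]]$W <- par[[paste0("W", l)]]
      net$layers[[l]]$b <- par[[paste0("b", l)]]
    }
    if (external_test) {
      pred <- max.col(mlp_forward(X_test, net)$probs)
      mean(pred == d_test)
    } else {
      pred <- max.col(mlp_forward(X[test_idx, , drop = FALSE], net)$probs)
      mean(pred == d[test_idx])
    }
  })
}

#' Measure how much adversarial training improves domain invariance
#'
#' Splits each domain's recording into a training part and a held-out tail,
#' then compares two domain discriminators on the held-out epochs:
#'
#' * the discriminator trained *jointly* with the feature extractor through
#'   gradient reversal (it is actively being defeated while the features are
#'   made domain-invariant), evaluated on the adversarial model's held-out
#'   features, and
#' * a fresh discriminator trained to convergence on the *frozen* features of
#'   a non-adversarially trained model, evaluated on that model's held-out
#'   features.
#'
#' The gap `|acc_plain - 0.5| - |acc_adversarial - 0.5|` is positive when
#' adversarial training left domains less distinguishable than ordinary
#' training did.
#'
#' @param source Labeled source-domain `psg_dataset`.
#' @param target Target-domain `psg_dataset` (labels unused).
#' @param config A [stdpgcn_config()]; `lambda` sets the adversarial strength.
#' @param seed Integer seed shared by both trainings.
#' @param holdout_frac Trailing fraction of each domain's epochs reserved for
#'   the held-out evaluation.
#' @return List with `acc_adversarial`, `acc_plain`, `gap`.
#' @export
domain_invariance_gap <- function(source, target, config = stdpgcn_config(),
                                  seed = 1, holdout_frac = 0.3) {
  split_tail <- function(ds) {
    n <- length(ds$labels)
    n_hold <- max(1L, round(holdout_frac * n))
    list(train = subset_dataset(ds, seq_len(n - n_hold)),
         hold = subset_dataset(ds, (n - n_hold + 1):n))
  }
  s_sp <- split_tail(source)
  t_sp <- split_tail(target)
  cfg_adv <- config
  cfg_adv$adversarial <- TRUE
  cfg_plain <- config
  cfg_plain$adversarial <- FALSE

  # adversarial model: evaluate its own jointly trained discriminator on the
  # held-out epochs of both domains
  fit_adv <- stdpgcn(s_sp$train, target = t_sp$train, config = cfg_adv,
                     seed = seed)
  dnet <- disc_net(fit_adv$par, config$discriminator_dims)
  Xs_hold <- extract_features(fit_adv, s_sp$hold)
  Xt_hold <- extract_features(fit_adv, t_sp$hold)
  pred <- max.col(rbind(discriminate_domain(Xs_hold, dnet),
                        discriminate_domain(Xt_hold, dnet)))
  truth <- c(rep(1L, nrow(Xs_hold)), rep(2L, nrow(Xt_hold)))
  acc_adv <- mean(pred == truth)

  # plain model: train a fresh discriminator on its frozen training features,
  # evaluate on its held-out features
  fit_plain <- stdpgcn(s_sp$train, target = t_sp$train, config = cfg_plain,
                       seed = seed)
  acc_plain <- probe_domain_accuracy(
    extract_features(fit_plain, s_sp$train),
    extract_features(fit_plain, t_sp$train),
    X_source_test = extract_features(fit_plain, s_sp$hold),
    X_target_test = extract_features(fit_plain, t_sp$hold),
    seed = seed)

  list(acc_adversarial = acc_adv, acc_plain = acc_plain,
       gap = abs(acc_plain - 0.5) - abs(acc_adv - 0.5))
}
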