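test_that("gradient reversal is the identity forward and -lambda backward", {
  x <- rnorm(10)
  expect_equal(as.numeric(gradient_reverse(x, 1)), x)
  g <- rnorm(10)
  expect_equal(gradient_reverse_backward(g, 1), -g)
  expect_equal(gradient_reverse_backward(g, 0), rep(0, 10))
  expect_equal(gradient_reverse_backward(g, 2.5), -2.5 * g)
})

test_that("reversed gradient matches -lambda times the numerical gradient", {
  set.seed(8)
  dnet <- domain_discriminator(c(12, 6, 2))
  x <- matrix(rnorm(12), 1, 12)
  d <- 1L
  loss_at <- function(xv) {
    domain_loss(discriminate_domain(matrix(xv, 1), dnet), d)
  }
  # analytic gradient through our backprop, then reversed
  fw <- stdpgcn:::mlp_forward(x, dnet)
  glog <- stdpgcn:::ce_logit_grad(fw$probs, d + 1L, 1)
  ganalytic <- stdpgcn:::mlp_backward(dnet, fw, glog)$gx
  for (lambda in c(0, 0.5, 1)) {
    grev <- gradient_reverse_backward(ganalytic, lambda)
    gnum <- vapply(1:12, function(i) {
      e <- numeric(12); e[i] <- 1e-5
      (loss_at(x + e) - loss_at(x - e)) / 2e-5
    }, numeric(1))
    expect_equal(as.numeric(grev), -lambda * gnum, tolerance = 1e-6)
  }
})

test_that("discriminator has the printed architecture and parameter count", {
  set.seed(1)
  dnet <- domain_discriminator(c(450, 512, 100, 2))
  expect_equal(count_parameters(dnet),
               450 * 512 + 512 + 512 * 100 + 100 + 100 * 2 + 2)
  expect_equal(count_parameters(dnet), 282414)
  p <- discriminate_domain(rnorm(450), dnet)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_error(discriminate_domain(rnorm(10), dnet), "dimension")
  # zero final layer: maximal confusion
  dnet$layers[[3]]$W[] <- 0
  dnet$layers[[3]]$b[] <- 0
  expect_equal(unname(discriminate_domain(rnorm(450), dnet)), c(0.5, 0.5))
})

test_that("domain loss matches closed forms and is label-symmetric", {
  expect_equal(domain_loss(c(0.5, 0.5), 0), log(2), tolerance = 1e-12)
  expect_equal(domain_loss(c(0.5, 0.5), 1), log(2), tolerance = 1e-12)
  expect_lt(domain_loss(c(0.999, 0.001), 0), 0.01)
  p <- c(0.8, 0.2)
  expect_equal(domain_loss(p, 1), domain_loss(rev(p), 0), tolerance = 1e-12)
  expect_message(domain_loss(c(1, 0), 1), "clamped")
})

test_that("the combined objective follows its definition", {
  expect_equal(total_objective(c(1, 3), numeric(0), numeric(0), lambda = 0), 2)
  expect_equal(total_objective(1.0, 0.5, numeric(0), lambda = 1), 0.5)
  e1 <- total_objective(c(2, 2), c(0.5, 0.7), c(0.3), lambda = 1)
  e2 <- total_objective(c(2, 2), c(0.5, 0.7), c(0.3), lambda = 2)
  expect_equal(2 - e1, (2 - e2) / 2, tolerance = 1e-12)
  expect_error(total_objective(numeric(0), 0.5, 0.5, 1), "empty")
})

test_that("a lambda-0 run matches the non-adversarial model exactly", {
  ds <- tiny_dataset(n_subjects = 3, epochs_per_subject = 12, seed = 21)
  src <- stdpgcn:::subset_dataset(ds, which(ds$subject_ids <= 2))
  tgt <- stdpgcn:::subset_dataset(ds, which(ds$subject_ids == 3))
  cfg0 <- desk_config(epochs = 8, lambda = 0, adversarial = TRUE)
  cfg_off <- desk_config(epochs = 8, adversarial = FALSE)
  f0 <- stdpgcn(src, target = tgt, config = cfg0, seed = 77)
  f_off <- suppressWarnings(stdpgcn(src, target = tgt, config = cfg_off,
                                    seed = 77))
  expect_identical(f0$history$class_loss, f_off$history$class_loss)
  for (nm in stdpgcn:::trunk_param_names()) {
    expect_identical(f0$par[[nm]], f_off$par[[nm]])
  }
  for (nm in stdpgcn:::classifier_param_names()) {
    expect_identical(f0$par[[nm]], f_off$par[[nm]])
  }
})
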