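test_that("single spike pairs reproduce the exponential closed form", {
  p <- stdp_params(a_plus = 0.01, a_minus = -0.01, tau = 100)
  pre <- integer(50); pre[1] <- 1L
  post <- integer(50); post[11] <- 1L
  expect_equal(stdp_weight_change(pre, post, p), 0.01 * exp(-10 / 100),
               tolerance = 1e-12)
  expect_equal(stdp_weight_change(post, pre, p), -0.01 * exp(-10 / 100),
               tolerance = 1e-12)
  expect_equal(pairwise_stdp_oracle(pre, post, p), 0.01 * exp(-0.1),
               tolerance = 1e-12)
  expect_equal(pairwise_stdp_oracle(post, pre, p), -0.01 * exp(-0.1),
               tolerance = 1e-12)
})

test_that("trace simulation equals the all-pairs oracle on random trains", {
  p <- stdp_params()
  for (i in 1:100) {
    pre <- rand_spike_train(500, 0.05, seed = 2 * i)
    post <- rand_spike_train(500, 0.05, seed = 2 * i + 1)
    fast <- stdp_weight_change(pre, post, p)
    slow <- pairwise_stdp_oracle(pre, post, p)
    expect_equal(fast, slow, tolerance = 1e-9)
  }
})

test_that("degenerate spike trains give zero weight change", {
  p <- stdp_params()
  expect_equal(stdp_weight_change(integer(100), integer(100), p), 0)
  pre_only <- rand_spike_train(200, 0.1, seed = 4)
  expect_equal(stdp_weight_change(pre_only, integer(200), p), 0)
  # simultaneous spikes contribute nothing
  both <- integer(100); both[c(10, 60)] <- 1L
  expect_equal(stdp_weight_change(both, both, p),
               pairwise_stdp_oracle(both, both, p), tolerance = 1e-12)
})

test_that("epoch graphs are directed with zero diagonal", {
  p <- stdp_params()
  silent <- replicate(3, integer(100), simplify = FALSE)
  g0 <- learn_epoch_graph(silent, p)
  expect_true(all(g0$weights == 0))
  # channel 2 = channel 1 delayed: forward weight positive, reverse negative
  e1 <- rand_spike_train(600, 0.05, seed = 11)
  e2 <- c(integer(5), e1[1:595])
  g <- learn_epoch_graph(list(e1, e2), p)
  expect_gt(g$weights[1, 2], 0)
  expect_lt(g$weights[2, 1], 0)
  expect_gt(g$weights[1, 2], g$weights[2, 1])
  # identical trains: symmetric weights
  gi <- learn_epoch_graph(list(e1, e1), p)
  expect_equal(gi$weights[1, 2], gi$weights[2, 1], tolerance = 1e-12)
  expect_equal(diag(g$weights), c(0, 0))
  expect_error(learn_epoch_graph(list(e1), p), "2 channels")
  expect_error(learn_epoch_graph(list(e1, e1[1:10]), p), "length")
})

test_that("shared timestep simulation equals the pairwise definition", {
  p <- stdp_params()
  trains <- lapply(1:4, function(i) rand_spike_train(300, 0.08, seed = 30 + i))
  g <- learn_epoch_graph(trains, p)
  for (j in 1:4) {
    for (i in 1:4) {
      if (i == j) next
      expect_equal(g$weights[j, i],
                   stdp_weight_change(trains[[j]], trains[[i]], p),
                   tolerance = 1e-12)
    }
  }
})

test_that("null coupling gives weights centered at zero", {
  p <- stdp_params()  # a_plus = |a_minus|
  w <- vapply(1:100, function(i) {
    stdp_weight_change(rand_spike_train(400, 0.05, seed = 1000 + 2 * i),
                       rand_spike_train(400, 0.05, seed = 1001 + 2 * i), p)
  }, numeric(1))
  expect_lt(abs(mean(w)), 3 * sd(w) / sqrt(length(w)))
})

test_that("graph sequences map epochs one-to-one with no carried state", {
  spec <- coupling_spec(NULL, 0.1)
  ep <- generate_coupled_epoch(spec, 2, 400, seed = 6)
  gs <- learn_graph_sequence(rep(list(ep), 5))
  expect_length(gs, 5)
  for (k in 2:5) expect_identical(gs[[k]]$weights, gs[[1]]$weights)
})

test_that("adjacency post-processing symmetrizes, rescales and adds self-loops", {
  A <- matrix(c(0, 2, 0, 0), 2, 2, byrow = TRUE)
  out <- postprocess_adjacency(A)
  expect_equal(out$weights, matrix(1, 2, 2))
  z <- postprocess_adjacency(matrix(0, 3, 3))
  expect_equal(z$weights, diag(3))
  g <- learn_epoch_graph(lapply(1:3, function(i) {
    rand_spike_train(300, 0.1, seed = 50 + i)
  }))
  pp <- postprocess_adjacency(g)$weights
  expect_equal(pp, t(pp))
  expect_equal(diag(pp), rep(1, 3))
  expect_true(all(pp >= 0))
})

test_that("baseline graphs match their definitions", {
  fc <- build_baseline_graph("fully_connected", 3)
  expect_equal(fc$weights, matrix(1, 3, 3) - diag(3))
  r1 <- build_baseline_graph("random", 5, seed = 2)
  r2 <- build_baseline_graph("random", 5, seed = 2)
  expect_identical(r1$weights, r2$weights)
  expect_equal(r1$weights, t(r1$weights))
  expect_true(all(diag(r1$weights) == 0))
  expect_error(build_baseline_graph("ring", 3), "arg")
})

test_that("stage aggregation partitions the total connectivity", {
  graphs <- lapply(1:6, function(i) {
    learn_epoch_graph(lapply(1:3, function(ch) {
      rand_spike_train(200, 0.1, seed = 100 + 3 * i + ch)
    }))
  })
  labels <- c("Wake", "Wake", "N2", "N3", "REM", "N2")
  agg <- aggregate_stage_connectivity(graphs, labels)
  expect_named(agg, stage_levels())
  expect_equal(agg$Wake$weights,
               graphs[[1]]$weights + graphs[[2]]$weights)
  expect_equal(agg$N1$weights, matrix(0, 3, 3))
  total <- Reduce(`+`, lapply(agg, function(g) g$weights))
  expect_equal(total, Reduce(`+`, lapply(graphs, function(g) g$weights)),
               tolerance = 1e-12)
  expect_error(aggregate_stage_connectivity(graphs, labels[1:3]), "length")
})

test_that("aggregated graphs recover the direction of lagged coupling", {
  # one trial = summed adjacency over several epochs sharing the coupling;
  # single-epoch direction estimates are noisy for quasi-periodic signals
  # (see vignette), the aggregate is reliable
  p <- stdp_params()
  cfg <- bsa_config()
  ok <- 0
  trials <- 20
  for (trial in seq_len(trials)) {
    lag <- 5 + (trial %% 16)
    spec <- pair_spec(lag = lag, noise_sd = 0.15)
    w <- 0
    for (e in 1:9) {
      ep <- generate_coupled_epoch(spec, 2, 3000, seed = trial * 1000 + e)
      g <- learn_epoch_graph(encode_epoch(ep, cfg), p)
      w <- w + g$weights[1, 2] - g$weights[2, 1]
    }
    ok <- ok + (w > 0)
  }
  expect_gte(ok / trials, 0.9)
})
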