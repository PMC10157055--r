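test_that("uncoupled channels are pairwise uncorrelated", {
  spec <- coupling_spec(NULL, noise_sd = 0.1)
  for (seed in 1:20) {
    ep <- generate_coupled_epoch(spec, 3, 3000, seed = seed)
    r <- cor(t(ep))
    expect_lt(max(abs(r[upper.tri(r)])), 0.2)
  }
})

test_that("a noiseless coupled channel is an exact lagged copy of its source", {
  spec <- pair_spec(lag = 5, gain = 1, noise_sd = 0)
  ep <- generate_coupled_epoch(spec, 2, 500, seed = 3)
  expect_equal(ep[2, 6:500], ep[1, 1:495], tolerance = 1e-12)
  # cross-correlation peaks exactly at the specified lag
  cc <- sapply(0:20, function(l) cor(ep[2, (l + 1):500], ep[1, 1:(500 - l)]))
  expect_equal(which.max(cc) - 1, 5)
})

test_that("epoch generation is a pure function of the seed", {
  spec <- pair_spec(lag = 7, noise_sd = 0.2)
  a <- generate_coupled_epoch(spec, 4, 800, seed = 42)
  b <- generate_coupled_epoch(spec, 4, 800, seed = 42)
  expect_identical(a, b)
  d <- generate_coupled_epoch(spec, 4, 800, seed = 43)
  expect_false(identical(a, d))
})

test_that("invalid coupling specs are rejected", {
  expect_error(coupling_spec(data.frame(source = 1, target = 1, lag = 3,
                                        gain = 1)), "source")
  expect_error(coupling_spec(data.frame(source = 1, target = 2, lag = -1,
                                        gain = 1)), "lag")
  expect_error(generate_coupled_epoch(pair_spec(lag = 600), 2, 500, seed = 1),
               "lag")
})

test_that("markov chain respects degenerate transition structures", {
  id <- diag(5)
  seq1 <- markov_stage_sequence(id, 50, seed = 1)
  expect_true(all(seq1 == "Wake"))
  cyc <- matrix(0, 5, 5)
  for (i in 1:5) cyc[i, i %% 5 + 1] <- 1
  seq2 <- markov_stage_sequence(cyc, 10, seed = 1)
  expect_equal(as.character(seq2), stage_levels()[(0:9) %% 5 + 1])
})

test_that("uniform transition matrix gives uniform stage frequencies", {
  u <- matrix(0.2, 5, 5)
  s <- markov_stage_sequence(u, 10000, seed = 7)
  freq <- table(s) / 10000
  expect_true(all(abs(freq - 0.2) < 0.02))
})

test_that("bad transition matrices are rejected", {
  m <- matrix(0.2, 5, 5)
  m[1, 1] <- -0.2
  m[1, 2] <- 0.6
  expect_error(markov_stage_sequence(m, 10, seed = 1), "negative")
  expect_error(markov_stage_sequence(matrix(0.25, 5, 5), 10, seed = 1),
               "sum to 1")
})

test_that("zero subject shift gives matching signal statistics across subjects", {
  ds <- generate_stage_dataset(2, 100,
                               stage_specs = default_stage_specs(6),
                               subject_shift_sd = 0, n_channels = 6,
                               n_samples = 1000, seed = 5)
  v <- tapply(seq_along(ds$subject_ids), ds$subject_ids, function(idx) {
    mean(apply(ds$signals[, , idx], 3, var))
  })
  expect_lt(abs(v[1] - v[2]) / mean(v), 0.05)
})

test_that("stage datasets are seeded deterministically and well formed", {
  a <- tiny_dataset(seed = 9, epochs_per_subject = 5)
  b <- tiny_dataset(seed = 9, epochs_per_subject = 5)
  expect_identical(a$signals, b$signals)
  expect_identical(a$labels, b$labels)
  expect_equal(length(a$labels), dim(a$signals)[3])
  expect_equal(length(a$subject_ids), dim(a$signals)[3])
  expect_true(all(is.finite(a$signals)))
})
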