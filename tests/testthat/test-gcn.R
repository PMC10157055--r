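test_that("degree normalization matches hand-computed cases", {
  expect_equal(normalized_laplacian(diag(2)), diag(2))
  expect_equal(normalized_laplacian(matrix(1, 2, 2)), matrix(0.5, 2, 2))
  expect_error(normalized_laplacian(matrix(c(1, -1, -1, 1), 2, 2)),
               "postprocess_adjacency")
  # zero-degree guard
  A <- diag(c(1, 0, 1))
  expect_true(all(is.finite(normalized_laplacian(A))))
})

test_that("normalized adjacency is symmetric with spectrum in [-1, 1]", {
  for (seed in 1:10) {
    g <- build_baseline_graph("random", 6, seed = seed)
    L <- normalized_laplacian(postprocess_adjacency(g))
    expect_equal(L, t(L), tolerance = 1e-12)
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-10 & ev <= 1 + 1e-10))
  }
})

test_that("graph convolution matches a dense elementwise oracle", {
  with_seed <- stdpgcn:::with_seed
  for (seed in 1:5) {
    n <- 2 + seed %% 4  # up to 5 nodes
    g <- postprocess_adjacency(build_baseline_graph("random", n, seed = seed))
    L <- normalized_laplacian(g)
    H <- with_seed(seed, matrix(rnorm(n * 3), n, 3))
    W <- with_seed(seed + 99, matrix(rnorm(3 * 2), 3, 2))
    out <- gcn_forward(H, L, gcn_params(W, "relu"))
    # oracle: naive triple loop over the definition sigma(L H W)
    oracle <- matrix(0, n, 2)
    for (i in seq_len(n)) {
      for (o in 1:2) {
        acc <- 0
        for (j in seq_len(n)) {
          for (f in 1:3) acc <- acc + L[i, j] * H[j, f] * W[f, o]
        }
        oracle[i, o] <- max(acc, 0)
      }
    }
    expect_equal(out, oracle, tolerance = 1e-10)
  }
})

test_that("identity graph and identity weights pass features through", {
  H <- matrix(rnorm(12), 4, 3)
  out <- gcn_forward(H, diag(4), gcn_params(diag(3), "identity"))
  expect_equal(out, H, tolerance = 1e-14)
  expect_error(gcn_forward(H, diag(3), gcn_params(diag(3))), "shape")
  expect_error(gcn_forward(H, diag(4), gcn_params(diag(2))), "shape")
})

test_that("graph convolution is permutation equivariant", {
  with_seed <- stdpgcn:::with_seed
  for (seed in 1:5) {
    n <- 5
    g <- postprocess_adjacency(build_baseline_graph("random", n, seed = seed))
    L <- normalized_laplacian(g)
    H <- with_seed(seed + 7, matrix(rnorm(n * 4), n, 4))
    W <- with_seed(seed + 13, matrix(rnorm(4 * 3), 4, 3))
    pm <- with_seed(seed + 21, sample(n))
    out <- gcn_forward(H, L, gcn_params(W))
    out_p <- gcn_forward(H[pm, ], L[pm, pm], gcn_params(W))
    expect_equal(out_p, out[pm, ], tolerance = 1e-12)
  }
})

test_that("a uniform fully-connected graph collapses node embeddings", {
  n <- 6
  g <- postprocess_adjacency(build_baseline_graph("fully_connected", n))
  L <- normalized_laplacian(g)
  H <- matrix(rnorm(n * 3), n, 3)
  out <- gcn_forward(H, L, gcn_params(matrix(rnorm(6), 3, 2)))
  expect_lt(max(apply(out, 2, function(col) diff(range(col)))), 1e-10)
})

test_that("temporal convolution emits probability rows and handles constants", {
  set.seed(2)
  H <- matrix(rnorm(5 * 8), 5, 8)
  out <- temporal_conv(H, temporal_conv_params(rep(1 / 3, 3)))
  expect_equal(dim(out), c(5, 8))
  expect_true(all(out >= 0))
  expect_equal(rowSums(out), rep(1, 5), tolerance = 1e-6)
  # averaging kernel on identical rows equals the single-epoch result
  v <- rnorm(8)
  Hc <- matrix(v, 5, 8, byrow = TRUE)
  out_c <- temporal_conv(Hc, temporal_conv_params(rep(1 / 3, 3)))
  single <- temporal_conv(matrix(v, 1), temporal_conv_params(1))
  for (m in 1:5) expect_equal(out_c[m, ], single[1, ], tolerance = 1e-12)
  expect_error(temporal_conv(H, temporal_conv_params(rep(1, 7))), "kernel")
})

test_that("classifier head outputs a simplex with softmax invariances", {
  set.seed(5)
  net <- stage_classifier(20, hidden = 8)
  x <- rnorm(20)
  p <- classify(x, net)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
  expect_named(p, stage_levels())
  # zero final layer: uniform prediction
  net0 <- net
  net0$layers[[2]]$W[] <- 0
  net0$layers[[2]]$b[] <- 0
  expect_equal(unname(classify(x, net0)), rep(0.2, 5), tolerance = 1e-12)
  # argmax invariant to constant logit shifts
  netb <- net
  netb$layers[[2]]$b <- netb$layers[[2]]$b + 3
  expect_equal(which.max(classify(x, net)), which.max(classify(x, netb)))
})

test_that("cross-entropy matches closed forms", {
  onehot <- diag(5)[c(1, 3), ]
  expect_equal(classification_loss(onehot, c(1, 3)), 0, tolerance = 1e-9)
  unif <- matrix(0.2, 4, 5)
  expect_equal(classification_loss(unif, c(1, 2, 3, 5)), log(5),
               tolerance = 1e-12)
  set.seed(1)
  p <- softmax_rows <- exp(matrix(rnorm(20), 4, 5))
  p <- p / rowSums(p)
  expect_gte(classification_loss(p, c(2, 2, 4, 1)), 0)
  expect_message(classification_loss(matrix(c(1, 0, 0, 0, 0), 1), 2),
                 "clamped")
})
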