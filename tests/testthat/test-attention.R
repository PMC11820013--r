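# The attention math: spec examples, loop oracles, stochasticity,
# identity-at-init, permutation equivariance.

test_that("spatial projections are affine maps of the instances", {
  p <- active_params(2, dim_model = 2)
  p$W_A <- diag(2); p$b_A <- c(0, 0)
  X <- matrix(rnorm(6), 3, 2)
  expect_equal(spatial_projections(X, p)$A, X)
  Z <- matrix(0, 3, 2)
  pr <- spatial_projections(Z, p)
  expect_equal(pr$B, matrix(p$b_B, 3, 2, byrow = TRUE))
  set.seed(1)
  X2 <- matrix(rnorm(6), 3, 2)
  pr2 <- spatial_projections(X2, p)
  expect_equal(pr2$A, oracle_affine(X2, p$W_A, p$b_A), tolerance = 1e-12)
  expect_equal(pr2$D, oracle_affine(X2, p$W_D, p$b_D), tolerance = 1e-12)
  p$W_A <- matrix(1, 3, 2)
  expect_error(spatial_projections(X, p), "dimension mismatch")
})

test_that("spatial attention matrix is the column softmax of A B^T", {
  Z <- matrix(0, 3, 2)
  expect_equal(spatial_attention_matrix(Z, Z), matrix(1 / 3, 3, 3))
  # scalar oracle: logits [0, ln 3] against B_j = 1 give weights 1/4, 3/4
  A <- matrix(c(0, log(3)), 2, 1)
  B <- matrix(c(1, 1), 2, 1)
  S <- spatial_attention_matrix(A, B)
  expect_equal(S, matrix(c(0.25, 0.75), 2, 2), tolerance = 1e-12)
  # shift invariance: adding a constant to one column's logits
  set.seed(2)
  A <- matrix(rnorm(8), 4, 2); B <- matrix(rnorm(8), 4, 2)
  S1 <- spatial_attention_matrix(A, B)
  S2 <- camil:::col_softmax(A %*% t(B) +
                              matrix(c(5, 0, 0, 0), 4, 4, byrow = TRUE))
  expect_equal(S1, S2, tolerance = 1e-12)
  expect_error(spatial_attention_matrix(A, B[1:2, ]), "shape")
})

test_that("applying spatial attention honors the gated residual", {
  set.seed(3)
  X <- matrix(rnorm(8), 4, 2); D <- matrix(rnorm(8), 4, 2)
  S <- camil:::col_softmax(matrix(rnorm(16), 4, 4))
  expect_equal(apply_spatial_attention(S, D, X, alpha = 0), X)
  Su <- matrix(1 / 4, 4, 4)
  E <- apply_spatial_attention(Su, D, X, alpha = 1)
  expect_equal(E, sweep(X, 2, colMeans(D), "+"), tolerance = 1e-12)
  S2 <- camil:::col_softmax(matrix(rnorm(4), 2, 2))
  X2 <- matrix(rnorm(4), 2, 2); D2 <- matrix(rnorm(4), 2, 2)
  expect_equal(apply_spatial_attention(S2, D2, X2, 0.5),
               oracle_apply_spatial(S2, D2, X2, 0.5), tolerance = 1e-12)
})

test_that("channel attention matrix softmaxes the channel Gram matrix", {
  expect_equal(channel_attention_matrix(matrix(0, 3, 4)),
               matrix(1 / 4, 4, 4))
  # orthogonal equal-norm columns: closed-form softmax
  r <- 2
  E <- sqrt(r) * diag(3)         # columns orthogonal, norm^2 = r
  Cm <- channel_attention_matrix(E)
  dexp <- exp(r) / (exp(r) + 2)
  expect_equal(diag(Cm), rep(dexp, 3), tolerance = 1e-12)
  expect_equal(Cm[1, 2], (1 - dexp) / 2, tolerance = 1e-12)
  # row-permutation invariance (Gram depends only on column inner products)
  set.seed(4)
  E2 <- matrix(rnorm(15), 5, 3)
  expect_equal(channel_attention_matrix(E2),
               channel_attention_matrix(E2[c(3, 1, 5, 2, 4), ]),
               tolerance = 1e-12)
})

test_that("applying channel attention honors the gated residual", {
  set.seed(5)
  E <- matrix(rnorm(6), 2, 3)
  Cm <- channel_attention_matrix(E)
  expect_equal(apply_channel_attention(Cm, E, beta = 0), E)
  expect_equal(apply_channel_attention(diag(3), E, beta = 1), 2 * E)
  expect_equal(apply_channel_attention(Cm, E, 0.7),
               oracle_apply_channel(Cm, E, 0.7), tolerance = 1e-12)
  expect_error(apply_channel_attention(Cm[1:2, 1:2], E, 1), "shape")
})

test_that("vectorized stages match loop oracles on random small inputs", {
  set.seed(6)
  for (rep in 1:50) {
    n <- sample(2:6, 1); cc <- sample(2:5, 1)
    X <- matrix(rnorm(n * cc), n, cc)
    p <- active_params(cc, dim_model = cc, seed = rep)
    pr <- spatial_projections(X, p)
    expect_equal(pr$A, oracle_affine(X, p$W_A, p$b_A), tolerance = 1e-8)
    S <- spatial_attention_matrix(pr$A, pr$B)
    expect_equal(S, oracle_spatial_matrix(pr$A, pr$B), tolerance = 1e-8)
    expect_equal(colSums(S), rep(1, n), tolerance = 1e-6)
    expect_true(all(S >= 0 & S <= 1))
    E <- apply_spatial_attention(S, pr$D, X, p$alpha)
    expect_equal(E, oracle_apply_spatial(S, pr$D, X, p$alpha),
                 tolerance = 1e-8)
    Cm <- channel_attention_matrix(E)
    expect_equal(Cm, oracle_channel_matrix(E), tolerance = 1e-8)
    expect_equal(colSums(Cm), rep(1, cc), tolerance = 1e-6)
    G <- apply_channel_attention(Cm, E, p$beta)
    expect_equal(G, oracle_apply_channel(Cm, E, p$beta), tolerance = 1e-8)
  }
})

test_that("column stochasticity holds for large random inputs", {
  set.seed(7)
  for (rep in 1:20) {
    X <- matrix(rnorm(40 * 16, sd = 4), 40, 16)
    p <- active_params(16, seed = rep)
    pr <- spatial_projections(X, p)
    S <- spatial_attention_matrix(pr$A, pr$B)
    expect_equal(colSums(S), rep(1, 40), tolerance = 1e-6)
    Cm <- channel_attention_matrix(X)
    expect_equal(colSums(Cm), rep(1, 16), tolerance = 1e-6)
  }
})

test_that("cascaded block is the identity at initialization (alpha=beta=0)", {
  set.seed(8)
  X <- matrix(rnorm(5 * 4), 5, 4)
  for (mode in c("spatial_then_channel", "channel_then_spatial",
                 "spatial_only", "channel_only")) {
    p <- camil_params(4, fusion = mode, seed = 1)
    H <- cascaded_block(X, p)
    expect_equal(unclass(H), X, ignore_attr = TRUE, tolerance = 0)
  }
})

test_that("fusion modes dispatch to the stated compositions", {
  set.seed(9)
  X <- matrix(rnorm(4 * 3), 4, 3)
  p <- active_params(3, dim_model = 3)
  pr <- spatial_projections(X, p)
  S <- spatial_attention_matrix(pr$A, pr$B)
  E <- apply_spatial_attention(S, pr$D, X, p$alpha)
  expect_equal(unclass(cascaded_block(X, p, "spatial_only")), E,
               ignore_attr = TRUE)
  G <- apply_channel_attention(channel_attention_matrix(E), E, p$beta)
  expect_equal(unclass(cascaded_block(X, p, "spatial_then_channel")), G,
               ignore_attr = TRUE)
  # parallel: concat of both single-mode outputs, projected
  Gch <- apply_channel_attention(channel_attention_matrix(X), X, p$beta)
  Hcat <- cbind(E, Gch)
  expect_equal(unclass(cascaded_block(X, p, "parallel_concat")),
               sweep(Hcat %*% p$W_fuse, 2, p$b_fuse, "+"),
               ignore_attr = TRUE)
  expect_error(cascaded_block(X, p, "bogus"))
})

test_that("cascaded block is permutation-equivariant in all modes", {
  set.seed(10)
  X <- matrix(rnorm(6 * 4), 6, 4)
  for (mode in c("spatial_then_channel", "channel_then_spatial",
                 "spatial_only", "channel_only", "parallel_concat")) {
    p <- active_params(4, dim_model = 4, fusion = mode)
    H <- unclass(cascaded_block(X, p, mode))
    for (k in 1:10) {
      perm <- sample(6)
      Hp <- unclass(cascaded_block(X[perm, ], p, mode))
      expect_equal(Hp, H[perm, ], tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("attention pooling weights form a convex combination", {
  p <- active_params(3, dim_model = 3)
  H1 <- matrix(rnorm(3), 1, 3)
  pool <- attention_pool(H1, p)
  expect_equal(pool$weights, 1)
  expect_equal(pool$bag_vector, drop(H1))
  # identical rows -> uniform weights
  H <- matrix(rep(c(1, -1, 2), each = 4), 4, 3)
  pool <- attention_pool(H, p)
  expect_equal(pool$weights, rep(0.25, 4), tolerance = 1e-12)
  # permutation: same bag vector, permuted weights
  set.seed(11)
  H <- matrix(rnorm(5 * 3), 5, 3)
  pool <- attention_pool(H, p)
  expect_equal(sum(pool$weights), 1, tolerance = 1e-12)
  expect_true(all(pool$weights >= 0))
  perm <- c(4, 2, 5, 1, 3)
  pool2 <- attention_pool(H[perm, ], p)
  expect_equal(pool2$bag_vector, pool$bag_vector, tolerance = 1e-10)
  expect_equal(pool2$weights, pool$weights[perm], tolerance = 1e-10)
  expect_error(attention_pool(H[0, , drop = FALSE], p), "empty")
})
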