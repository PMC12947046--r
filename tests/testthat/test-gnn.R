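test_that("shifted softplus has the right values and asymptotes", {
  expect_identical(shifted_softplus(0), 0)
  expect_equal(shifted_softplus(20), 20 + log(0.5), tolerance = 1e-8)
  expect_equal(shifted_softplus(-20), log(0.5), tolerance = 1e-8)
  # overflow safety far beyond double exp() range
  expect_equal(shifted_softplus(800), 800 + log(0.5))
  expect_identical(shifted_softplus(-800), 0 + log1p(exp(-800)) - log(2))
})

test_that("rbf expansion matches a per-component scalar oracle", {
  cfg <- rbf_config(25, seq(0, by = 0.3, length.out = 25),
                    width_coefficient = 1.7)
  set.seed(4)
  for (d in runif(20, 0, 8)) {
    got <- rbf_expand(d, cfg)
    want <- vapply(cfg$centers, function(mu) {
      exp(-cfg$width_coefficient * (d - mu)^2)
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got > 0 & got <= 1))
  }
  # exact peak at a center; specific closed-form value
  expect_equal(rbf_expand(0.9, cfg)[4], 1.0)
  expect_equal(rbf_expand(5, rbf_config(3, c(3, 4, 5)))[2], exp(-1),
               tolerance = 1e-12)
  # defaults: 300 components on the 0..29.9 grid
  def <- rbf_config()
  expect_identical(def$n_centers, 300L)
  expect_equal(def$centers, seq(0, 29.9, by = 0.1))
  expect_length(rbf_expand(3.14, def), 300)
  expect_error(rbf_expand(-0.1, def), "non-negative")
})

test_that("cutoff decay is a smooth monotone switch on [0, r_cut]", {
  for (rc in c(1, 5, 10)) {
    expect_equal(cutoff_decay(0, rc), 1.0)
    expect_equal(cutoff_decay(rc / 2, rc), 0.5)
    expect_equal(cutoff_decay(rc, rc), 0.0)
    expect_equal(cutoff_decay(rc * 1.7, rc), 0.0)  # clamped beyond cutoff
    grid <- seq(0, rc, length.out = 1000)
    vals <- cutoff_decay(grid, rc)
    expect_true(all(diff(vals) <= 1e-12))
    expect_true(all(vals >= 0 & vals <= 1))
    # vanishing slope at both ends (central differences)
    h <- 1e-4 * rc
    expect_lt(abs(cutoff_decay(h, rc) - cutoff_decay(0, rc)) / h, 1e-6)
    expect_lt(abs(cutoff_decay(rc, rc) - cutoff_decay(rc - h, rc)) / h,
              1e-6)
  }
})

test_that("atom embedding is a per-element table lookup", {
  m <- tiny_model()
  E <- embed_atoms(c(6L, 1L, 6L), m)
  expect_identical(dim(E), c(3L, m$n_features))
  expect_identical(E[1, ], E[3, ])
  perm <- c(2, 3, 1)
  expect_identical(embed_atoms(c(6L, 1L, 6L)[perm], m), E[perm, ])
  expect_error(embed_atoms(c(1L, 79L), m), "Z = 79")
})

test_that("atom-wise layer applies one shared affine map", {
  m <- tiny_model(n_features = 4)
  X <- matrix(rnorm(12), 3, 4)
  m$params$atomwise[[1]]$W <- diag(4)
  m$params$atomwise[[1]]$b <- rep(0, 4)
  expect_equal(atom_wise(X, 1, m), X)
  m$params$atomwise[[1]]$W <- matrix(0, 4, 4)
  m$params$atomwise[[1]]$b <- rep(2.5, 4)
  expect_true(all(atom_wise(X, 1, m) == 2.5))
  X[2, ] <- X[1, ]
  m2 <- tiny_model(n_features = 4, seed = 9)
  out <- atom_wise(X, 2, m2)
  expect_identical(out[1, ], out[2, ])
  expect_error(atom_wise(matrix(0, 3, 5), 1, m), "width")
})

test_that("interaction step validates inputs and respects degenerate cases", {
  m <- tiny_model(n_features = 6, n_interactions = 1)
  X <- matrix(rnorm(6), 1, 6)
  # single atom: empty neighbour sum; zero-bias update MLP maps 0 -> 0
  m0 <- m
  m0$params$update[[1]]$inner$b[] <- 0
  m0$params$update[[1]]$outer$b[] <- 0
  expect_equal(interaction_step(X, matrix(0, 1, 1), m0), X)
  # zero update MLP leaves features unchanged (residual form)
  mz <- m
  mz$params$update[[1]]$inner$W[] <- 0
  mz$params$update[[1]]$inner$b[] <- 0
  mz$params$update[[1]]$outer$W[] <- 0
  mz$params$update[[1]]$outer$b[] <- 0
  X2 <- matrix(rnorm(12), 2, 6)
  D2 <- matrix(c(0, 1.3, 1.3, 0), 2, 2)
  expect_equal(interaction_step(X2, D2, mz), X2)
  # two identical atoms stay identical after the update
  X3 <- rbind(X2[1, ], X2[1, ])
  out <- interaction_step(X3, D2, m)
  expect_equal(out[1, ], out[2, ], tolerance = 1e-12)
  # malformed distance matrices
  expect_error(interaction_step(X2, matrix(c(0, 1, 2, 0), 2, 2), m),
               "symmetric")
  expect_error(interaction_step(X2, matrix(c(0.5, 1, 1, 0), 2, 2), m),
               "diagonal")
})

test_that("prediction layer is the stated elementwise linear merge", {
  m <- tiny_model(n_features = 5)
  n <- 3
  E <- matrix(rnorm(15), n, 5)
  A1 <- matrix(rnorm(15), n, 5)
  A2 <- matrix(rnorm(15), n, 5)
  m$params$pred$u <- rep(1, 5)
  m$params$pred$w1 <- rep(0, 5)
  m$params$pred$w2 <- rep(0, 5)
  expect_equal(prediction_layer(E, A1, A2, m), E)
  m$params$pred$u[] <- 0
  expect_true(all(prediction_layer(E, A1, A2, m) == 0))
  m2 <- tiny_model(n_features = 5, seed = 2)
  expect_equal(prediction_layer(2 * E, 2 * A1, 2 * A2, m2),
               2 * prediction_layer(E, A1, A2, m2))
  expect_error(prediction_layer(E, A1[1:2, ], A2, m2), "shape")
})

test_that("forward score is invariant to rigid motions and permutations", {
  m <- tiny_model(seed = 11)
  for (k in 1:12) {
    s <- random_structure(sample(2:7, 1), seed = 100 + k)
    sc <- forward_score(m, s)
    st <- transformed_copy(s, seed = 200 + k, permute = TRUE)
    expect_lt(abs(forward_score(m, st) - sc), 1e-5 * (1 + abs(sc)))
  }
  # constant readout: score equals the bias whatever the structure
  mc <- tiny_model(seed = 3)
  mc$params$readout$W[] <- 0
  mc$params$readout$b <- 4.25
  expect_equal(forward_score(mc, random_structure(5, seed = 1)), 4.25)
  expect_equal(forward_score(mc, random_structure(3, seed = 2)), 4.25)
})

test_that("vectorised forward matches the loop-based oracle", {
  m <- tiny_model(n_features = 6, n_interactions = 2, seed = 21,
                  n_centers = 8)
  for (k in 1:5) {
    s <- random_structure(sample(2:6, 1), seed = 300 + k)
    expect_equal(forward_score(m, s), oracle_forward(m, s),
                 tolerance = 1e-6)
  }
  # depth 1 exercises the single-tap edge case
  m1 <- tiny_model(n_features = 5, n_interactions = 1, seed = 22,
                   n_centers = 8)
  s <- random_structure(4, seed = 9)
  expect_equal(forward_score(m1, s), oracle_forward(m1, s),
               tolerance = 1e-6)
})

test_that("the learned cutoff is a positive softplus of the raw parameter", {
  m <- tiny_model()
  expect_gt(r_cut(m), 0)
  expect_equal(r_cut(m), 6, tolerance = 1e-2)
  m$params$cutoff_raw <- -50
  expect_gt(r_cut(m), 0)
})
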