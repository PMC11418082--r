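test_that("identity-initialized flow is the composition of its permutations", {
  fl <- make_flow(2, n_blocks = 2, hidden = 16, seed = 1)
  w <- c(1.5, -0.3)
  ff <- flow_forward(w, fl)
  expect_equal(ff$u, w)           # two reversals cancel
  expect_equal(ff$logdet, 0)
  # closed-form standard normal log-densities
  expect_equal(log_density(c(0, 0), fl), -log(2 * pi), tolerance = 1e-10)
  expect_equal(log_density(c(1, 0), fl), -log(2 * pi) - 0.5,
               tolerance = 1e-10)
  # one block: the reversal permutation shows up in u
  fl1 <- make_flow(3, n_blocks = 1, hidden = 8, seed = 2)
  expect_equal(flow_forward(c(1, 2, 3), fl1)$u, c(3, 2, 1))
  expect_equal(flow_inverse(c(3, 2, 1), fl1), c(1, 2, 3))
  expect_error(flow_forward(c(NA, 1), fl), "non-finite")
})

test_that("log-determinant matches a finite-difference Jacobian", {
  fl <- make_flow(4, n_blocks = 2, hidden = 16, seed = 5)
  for (b in 1:2) {
    fl$blocks[[b]]$Wmu <- with_seed_test(b, matrix(rnorm(16 * 4, 0, 0.3),
                                                   16, 4))
    fl$blocks[[b]]$Wa <- with_seed_test(b + 9, matrix(rnorm(16 * 4, 0, 0.3),
                                                      16, 4))
  }
  w0 <- with_seed_test(3, rnorm(4))
  J <- matrix(0, 4, 4)
  for (i in 1:4) {
    e <- rep(0, 4); e[i] <- 1e-5
    J[, i] <- (flow_forward(w0 + e, fl)$u - flow_forward(w0 - e, fl)$u) / 2e-5
  }
  expect_equal(flow_forward(w0, fl)$logdet, log(abs(det(J))),
               tolerance = 1e-4)
  # change-of-variables consistency, exactly as computed
  ff <- flow_forward(w0, fl)
  expect_equal(log_density(w0, fl),
               sum(dnorm(ff$u, log = TRUE)) + ff$logdet)
  # bit-identical repeat calls
  expect_identical(flow_forward(w0, fl), flow_forward(w0, fl))
})

test_that("single-dimension affine block inverts by hand algebra", {
  fl <- make_flow(1, n_blocks = 1, hidden = 4, seed = 1)
  fl$blocks[[1]]$bmu <- 0.7
  fl$blocks[[1]]$ba <- 0.3
  cap <- fl$alpha_cap
  a <- cap * tanh(0.3 / cap)
  ff <- flow_forward(2.0, fl)
  expect_equal(ff$u, (2.0 - 0.7) * exp(-a))
  expect_equal(ff$logdet, -a)
  expect_equal(flow_inverse(ff$u, fl), 2.0, tolerance = 1e-12)
})

test_that("inverse round-trips a trained flow to 1e-4", {
  fl <- study_flow()
  U <- with_seed_test(21, matrix(rnorm(100 * fl$d), 100, fl$d))
  W <- flow_inverse(U, fl)
  expect_lt(max(abs(flow_forward(W, fl)$u - U)), 1e-4)
})

test_that("training approaches the entropy of a Gaussian source", {
  X <- with_seed_test(31, matrix(rnorm(5000 * 4), 5000, 4))
  fl <- train_flow(X, flow_config(n_blocks = 2, hidden = 32,
                                  n_samples = 5000, epochs = 10,
                                  learning_rate = 2e-3, seed = 1))
  expect_lt(abs(fl$final_nll / 4 - 0.5 * log(2 * pi * exp(1))), 0.1)
})

test_that("training recenters a shifted Gaussian", {
  X <- with_seed_test(32, matrix(rnorm(4000 * 2, 3, 1), 4000, 2))
  fl <- train_flow(X, flow_config(n_blocks = 2, hidden = 32,
                                  n_samples = 4000, epochs = 30,
                                  learning_rate = 2e-3, seed = 2))
  mu <- colMeans(flow_forward(X, fl)$u)
  expect_lt(sqrt(sum(mu^2)), 0.2)
})

test_that("zero-epoch training returns the identity initialization", {
  X <- with_seed_test(33, matrix(rnorm(600 * 3), 600, 3))
  fl <- train_flow(X, flow_config(n_blocks = 2, hidden = 16,
                                  n_samples = 600, epochs = 0, seed = 9))
  ref <- make_flow(3, 2, 16, seed = 9)
  expect_equal(fl$blocks, ref$blocks)
  expect_equal(flow_forward(X[1, ], fl)$logdet, 0)
})

test_that("trained density integrates to one on a grid", {
  X <- with_seed_test(7, cbind(rnorm(4000, 1, 0.8), rnorm(4000, -0.5, 1.2)))
  fl <- train_flow(X, flow_config(n_blocks = 2, hidden = 32,
                                  n_samples = 4000, epochs = 20,
                                  learning_rate = 2e-3, seed = 2))
  g <- seq(-6, 6, length.out = 121)
  gr <- as.matrix(expand.grid(g, g))
  expect_lt(abs(sum(exp(log_density(gr, fl))) * (g[2] - g[1])^2 - 1), 1e-2)
})

test_that("gaussianization report recovers chi-squared moments for Gaussian styles", {
  lo <- make_linear_oracle(16, c(1, 8, 8), seed = 3)  # identity mapping
  fl <- make_flow(16, n_blocks = 2, hidden = 16, seed = 1)  # identity flow
  rep <- gaussianization_report(fl, lo, n = 5000, seed = 12)
  d <- 16
  expect_lt(abs(rep$mean_sq_norm - d), 3 * sqrt(2 * d / 5000))
  expect_lt(abs(rep$var_sq_norm - 2 * d) / (2 * d), 0.2)
  expect_equal(rep$reference_mean, d)
  expect_equal(rep$reference_var, 2 * d)
  expect_true(all(rep$sq_norms >= 0))
})

test_that("flow checkpoints round-trip", {
  dir <- withr::local_tempdir()
  fl <- study_flow()
  p <- file.path(dir, "f.ckpt")
  save_flow(fl, p)
  fl2 <- load_flow(p)
  w <- with_seed_test(5, rnorm(fl$d))
  expect_equal(log_density(w, fl2), log_density(w, fl))
  expect_equal(fl2$final_nll, fl$final_nll)
})
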