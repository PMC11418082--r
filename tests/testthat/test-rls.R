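test_that("flow prior term has its closed forms under the identity flow", {
  fl <- make_flow(2, n_blocks = 2, hidden = 8, seed = 1)
  expect_equal(prior_flow_term(matrix(0, 1, 2), fl), log(2 * pi),
               tolerance = 1e-12)
  # identical copies average to the single-copy value
  w <- c(0.4, -1.1)
  expect_equal(prior_flow_term(matrix(rep(w, each = 4), 4, 2), fl),
               prior_flow_term(matrix(w, 1), fl))
  # monotone in the norm for a Gaussian density
  vals <- vapply(c(0.5, 1, 2, 4),
                 function(r) prior_flow_term(matrix(c(r, 0), 1), fl), 0)
  expect_true(all(diff(vals) > 0))
})

test_that("pairwise prior enumerates unordered pairs", {
  expect_equal(prior_pairwise_term(matrix(rep(c(1, 2), each = 5), 5, 2)), 0)
  expect_equal(prior_pairwise_term(rbind(c(0, 0), c(1, 1))), 2)
  expect_equal(prior_pairwise_term(matrix(c(0, 1, 2), 3, 1)),
               mean(c(1, 4, 1)))
  expect_equal(prior_pairwise_term(matrix(5, 1, 3)), 0)  # L = 1
  # unsquared variant
  expect_equal(prior_pairwise_term(rbind(c(0, 0), c(3, 4)), squared = FALSE),
               5)
})

test_that("objective adds its terms and closes the data-fit cases", {
  lo <- make_linear_oracle(4, c(1, 8, 8), seed = 3)
  fl <- make_flow(4, n_blocks = 1, hidden = 8, seed = 1)
  op <- forward_operator(op_step("bicubic_downscale", factor = 2))
  w <- with_seed_test(1, matrix(rnorm(4), 1))
  lr_exact <- apply_operator(op, synthesize(w, lo))
  cfg0 <- rls_config(lambda1 = 0, lambda2 = 0)
  expect_equal(objective(w, lr_exact, lo, op, fl, cfg0)$total, 0,
               tolerance = 1e-12)
  # constant offset delta gives |delta| under L1
  expect_equal(objective(w, lr_exact - 0.17, lo, op, fl, cfg0)$total, 0.17,
               tolerance = 1e-12)
  # total equals the sum of independently computed terms
  cfg <- rls_config(lambda1 = 3e-5, lambda2 = 0.02)
  wp <- with_seed_test(2, matrix(rnorm(4), 1))
  ob <- objective(wp, lr_exact, lo, op, fl, cfg)
  expect_equal(ob$total,
               unname(ob$terms[1] + cfg$lambda1 * ob$terms[2] +
                        cfg$lambda2 * ob$terms[3]),
               tolerance = 1e-10)
  expect_equal(unname(ob$terms["flow_prior"]), prior_flow_term(wp, fl))
})

test_that("objective gradient matches finite differences on the style generator", {
  gen <- tiny_gen()
  fl <- make_flow(gen$d, n_blocks = 2, hidden = 16, seed = 2)
  op <- forward_operator(op_step("bicubic_downscale", factor = 2))
  lr_img <- with_seed_test(3, array(runif(prod(gen$output_shape) / 4, -1, 1),
                                    c(3, 8, 8)))
  cfg <- rls_config(lambda1 = 1e-4, lambda2 = 0.01, data_norm = "L2")
  w <- with_seed_test(4, matrix(rnorm(gen$L * gen$d), gen$L, gen$d))
  ev <- latsr:::objective_grad(w, lr_img, gen, op, fl, cfg)
  h <- 1e-4
  idx <- rbind(c(1, 1), c(2, 5), c(4, 8), c(3, 2))
  for (r in seq_len(nrow(idx))) {
    l <- idx[r, 1]; k <- idx[r, 2]
    wp <- w; wp[l, k] <- wp[l, k] + h
    wm <- w; wm[l, k] <- wm[l, k] - h
    fd <- (objective(wp, lr_img, gen, op, fl, cfg)$total -
           objective(wm, lr_img, gen, op, fl, cfg)$total) / (2 * h)
    expect_equal(ev$grad[l, k], fd, tolerance = 1e-3)
  }
})

test_that("closed-form linear map solves the ridge normal equations", {
  # exact interpolation when the square system is invertible
  A <- with_seed_test(5, matrix(rnorm(16 * 4), 16, 4))
  Dmat <- with_seed_test(6, matrix(rnorm(4 * 16), 4, 16))
  w0 <- c(1, -2, 0.5, 3)
  y <- drop(Dmat %*% A %*% w0)
  expect_equal(closed_form_linear_map(y, A, Dmat, lam = 0), w0,
               tolerance = 1e-8)
  # ridge limit drives the solution to zero
  expect_lt(sqrt(sum(closed_form_linear_map(y, A, Dmat, lam = 1e8)^2)), 1e-4)
  # dominates 1000 random candidates on the penalized objective
  Dr <- with_seed_test(7, matrix(rnorm(16 * 16), 16, 16))
  yr <- with_seed_test(8, rnorm(16))
  lam <- 0.1
  what <- closed_form_linear_map(yr, A, Dr, lam)
  pen <- function(w) mean((Dr %*% A %*% w - yr)^2) + lam * sum(w^2)
  cands <- with_seed_test(9, matrix(rnorm(1000 * 4), 1000, 4))
  best_rand <- min(apply(cands, 1, pen))
  expect_lte(pen(what), best_rand)
})

test_that("the optimizer matches the closed-form oracle on the linear/L2 case", {
  d <- 6; sh <- c(1, 8, 8)
  lo <- make_linear_oracle(d, sh, seed = 7)
  fl <- make_flow(d, n_blocks = 1, hidden = 8, seed = 1)  # quadratic prior
  op <- forward_operator(op_step("bicubic_downscale", factor = 2))
  wstar <- with_seed_test(10, rnorm(d))
  lr_img <- apply_operator(op, synthesize(matrix(wstar, 1), lo))
  lam1 <- 0.01
  cfg <- suppressWarnings(
    rls_config(lambda1 = lam1, lambda2 = 0, iterations = 400,
               learning_rate = 0.1, init_samples = 100, data_norm = "L2",
               use_pairwise_prior = FALSE, seed = 3))
  res <- superresolve(lr_img, lo, op, fl, cfg)
  w_cf <- closed_form_linear_map(as.numeric(lr_img), lo$params$A,
                                 downscale_matrix(sh, 2), lam = lam1 / 2)
  expect_lt(sqrt(sum((res$wplus[1, ] - w_cf)^2)) / sqrt(sum(w_cf^2)), 1e-3)
})

test_that("superresolve returns coherent traces and the best-total iterate", {
  gen <- tiny_gen()
  fl <- make_flow(gen$d, n_blocks = 2, hidden = 16, seed = 2)
  op <- forward_operator(op_step("bicubic_downscale", factor = 2))
  tgt <- with_seed_test(11, matrix(rnorm(gen$L * gen$d), gen$L, gen$d))
  lr_img <- apply_operator(op, synthesize(tgt, gen))
  cfg <- rls_config(iterations = 40, seed = 5, init_samples = 200)
  res <- superresolve(lr_img, gen, op, fl, cfg)
  expect_length(res$loss_trace, 41)
  expect_identical(nrow(res$term_trace), 41L)
  expect_identical(names(res$term_trace),
                   c("iter", "total", "data", "flow_prior", "pairwise_prior"))
  expect_equal(res$converged_value, min(res$loss_trace))
  expect_equal(res$loss_trace[res$best_iter + 1], res$converged_value)
  expect_equal(res$sr_image, synthesize(res$wplus, gen))
  # running best is non-increasing along the trace
  expect_true(all(diff(cummin(res$loss_trace)) <= 0))
  # zero iterations returns the initialization
  res0 <- superresolve(lr_img, gen, op, fl,
                       rls_config(iterations = 0, seed = 5,
                                  init_samples = 200))
  w0 <- mean_latent(gen, 200, 5)
  expect_equal(res0$wplus, matrix(rep(w0, each = gen$L), gen$L, gen$d))
  expect_equal(res0$sr_image,
               synthesize(matrix(rep(w0, each = gen$L), gen$L, gen$d), gen))
  # determinism
  res_b <- superresolve(lr_img, gen, op, fl, cfg)
  expect_identical(res_b$wplus, res$wplus)
})

test_that("ablation variants share their initial loss and order data fit", {
  gen <- tiny_gen()
  fl <- make_flow(gen$d, n_blocks = 2, hidden = 16, seed = 2)
  op <- forward_operator(op_step("bicubic_downscale", factor = 2))
  tgt <- with_seed_test(12, matrix(rnorm(gen$L * gen$d), gen$L, gen$d))
  lr_img <- apply_operator(op, synthesize(tgt, gen))
  cfg <- rls_config(iterations = 60, seed = 6, init_samples = 200)
  suite <- run_ablation_suite(lr_img, gen, op, fl, cfg)
  expect_named(suite, c("full", "no_p1", "no_p2", "no_regu"))
  # identical iteration-0 data term (the total differs by the active priors)
  d0 <- vapply(suite, function(r) r$term_trace$data[1], 0)
  expect_true(all(abs(d0 - d0[1]) < 1e-12))
  # the unconstrained fit is at least as tight as the full model
  expect_lte(unname(suite$no_regu$final_terms["data"]),
             unname(suite$full$final_terms["data"]) + 1e-3)
  expect_true(all(vapply(suite, function(r)
    is.finite(r$diagnostics["flow_nll"]), TRUE)))
})

test_that("config validation warns outside the validated lambda ranges", {
  expect_warning(rls_config(lambda1 = 1e-3), "lambda1")
  expect_warning(rls_config(lambda2 = 0.5), "lambda2")
  expect_silent(rls_config())
  expect_error(rls_config(lambda1 = -1))
})
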