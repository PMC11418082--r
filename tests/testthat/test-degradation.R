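test_that("bicubic downscale matches the direct-convolution reference", {
  M <- matrix(rep(seq(0, 1, length.out = 8), each = 8), 8, 8)  # ramp
  mine <- bicubic_downscale(array(M, c(1, 8, 8)), 2)[1, , ]
  ref <- ref_bicubic_1d(8, 2) %*% M %*% t(ref_bicubic_1d(8, 2))
  expect_lt(max(abs(mine - ref)), 1e-6)
  X <- with_seed_test(2, array(rnorm(3 * 16 * 16), c(3, 16, 16)))
  for (f in c(2, 4)) {
    ref2 <- ref_bicubic_1d(16, f) %*% X[2, , ] %*% t(ref_bicubic_1d(16, f))
    expect_lt(max(abs(bicubic_downscale(X, f)[2, , ] - ref2)), 1e-6)
  }
})

test_that("bicubic downscale is linear, constant-preserving, and identity at 1", {
  img <- with_seed_test(1, array(rnorm(2 * 16 * 16), c(2, 16, 16)))
  expect_identical(bicubic_downscale(img, 1), img)
  expect_lt(max(abs(bicubic_downscale(array(0.37, c(2, 16, 16)), 4) - 0.37)),
            1e-12)
  x <- with_seed_test(2, array(rnorm(2 * 16 * 16), c(2, 16, 16)))
  y <- with_seed_test(3, array(rnorm(2 * 16 * 16), c(2, 16, 16)))
  lhs <- bicubic_downscale(2.5 * x - 1.3 * y, 4)
  rhs <- 2.5 * bicubic_downscale(x, 4) - 1.3 * bicubic_downscale(y, 4)
  expect_lt(max(abs(lhs - rhs)), 1e-8)
  expect_error(bicubic_downscale(img, 3), "power of 2")
  expect_error(bicubic_downscale(array(0, c(1, 10, 10)), 4), "divide")
})

test_that("the downscale adjoint satisfies the inner-product identity", {
  hr_dim <- c(2L, 16L, 16L)
  x <- with_seed_test(4, array(rnorm(prod(hr_dim)), hr_dim))
  y <- with_seed_test(5, array(rnorm(2 * 4 * 4), c(2, 4, 4)))
  lhs <- sum(bicubic_downscale(x, 4) * y)
  rhs <- sum(x * latsr:::bicubic_downscale_adjoint(y, hr_dim, 4L))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("gaussian noise has the stated moments and reproduces from its seed", {
  z <- array(0, c(1, 64, 64))
  expect_identical(add_gaussian_noise(z, 0, seed = 1), z)
  n1 <- add_gaussian_noise(z, 0.1, seed = 7)
  expect_identical(n1, add_gaussian_noise(z, 0.1, seed = 7))
  expect_lt(abs(sd(n1) - 0.1) / 0.1, 0.1)
  expect_true(all(add_gaussian_noise(array(0.99, c(1, 32, 32)), 0.3,
                                     seed = 2) <= 1))
  expect_error(add_gaussian_noise(z, -0.1, seed = 1), ">= 0")
})

test_that("salt-and-pepper corrupts the stated fraction with +/-1 values", {
  img <- array(0.2, c(1, 128, 128))
  expect_identical(add_salt_pepper(img, 0, seed = 1), img)
  all_sp <- add_salt_pepper(img, 1, seed = 2)
  expect_true(all(all_sp %in% c(-1, 1)))
  p <- 0.05
  sp <- add_salt_pepper(img, p, seed = 3)
  frac <- mean(sp != 0.2)
  n <- length(img)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
  expect_error(add_salt_pepper(img, 1.2, seed = 1), "\\[0, 1\\]")
})

test_that("gaussian blur normalizes, is identity at zero, and matches the kernel peak", {
  img <- with_seed_test(6, array(rnorm(1 * 32 * 32), c(1, 32, 32)))
  expect_identical(gaussian_blur(img, 0), img)
  expect_lt(max(abs(gaussian_blur(array(0.4, c(1, 32, 32)), 2) - 0.4)), 1e-10)
  # impulse response reproduces the independently built normalized kernel
  imp <- array(0, c(1, 33, 33)); imp[1, 17, 17] <- 1
  out <- gaussian_blur(imp, 1)
  k <- dnorm(-3:3, sd = 1); k <- k / sum(k)
  K2 <- outer(k, k)
  expect_equal(out[1, 17, 17], max(K2), tolerance = 1e-12)
  expect_equal(out[1, 14:20, 14:20], K2, tolerance = 1e-12)
})

test_that("operators compose in order and no-op steps vanish", {
  img <- with_seed_test(7, array(runif(3 * 16 * 16, -1, 1), c(3, 16, 16)))
  expect_identical(apply_operator(forward_operator(list()), img), img)
  op1 <- forward_operator(op_step("bicubic_downscale", factor = 2))
  expect_identical(apply_operator(op1, img), bicubic_downscale(img, 2))
  op2 <- forward_operator(op_step("bicubic_downscale", factor = 2),
                          op_step("gaussian_noise", sigma = 0, seed = 1))
  expect_identical(apply_operator(op2, img), bicubic_downscale(img, 2))
  expect_error(forward_operator(op_step("bicubic_downscale", factor = 2),
                                op_step("bicubic_downscale", factor = 4)),
               "at most one")
})

test_that("compact operator strings parse to the right steps", {
  op <- parse_operator("bicubic:4,gauss:0.05,sp:0.02,blur:1", seed = 5)
  kinds <- vapply(op$steps, function(s) s$kind, "")
  expect_identical(kinds, c("bicubic_downscale", "gaussian_noise",
                            "salt_pepper", "gaussian_blur"))
  expect_identical(op$steps[[1]]$params$factor, 4L)
  expect_equal(op$steps[[2]]$params$sigma, 0.05)
  img <- with_seed_test(8, array(runif(1 * 16 * 16, -1, 1), c(1, 16, 16)))
  out <- apply_operator(op, img)
  expect_identical(dim(out), c(1L, 4L, 4L))
  expect_true(all(out >= -1 & out <= 1))
})
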