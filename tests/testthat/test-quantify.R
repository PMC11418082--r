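test_that("translocation ratio separates the phenotype and is 1 for flat reporters", {
  r09 <- render_cell(phenotype_params("translocation", t = 0.9,
                                      photon_scale = 0, read_noise = 0,
                                      seed = 4), 64)$image
  r01 <- render_cell(phenotype_params("translocation", t = 0.1,
                                      photon_scale = 0, read_noise = 0,
                                      seed = 4), 64)$image
  expect_gt(translocation_ratio(r09)$value, 1)
  expect_lt(translocation_ratio(r01)$value, 1)
  flat <- r09
  flat[2, , ] <- 0.5
  expect_equal(translocation_ratio(flat)$value, 1, tolerance = 1e-3)
  # masks are disjoint and the nucleus sits inside the dilated region
  f <- translocation_ratio(r09)
  expect_false(any(f$masks_used$nucleus & f$masks_used$cytoplasm))
  expect_error(translocation_ratio(array(0, c(3, 64, 64))), "no nucleus")
})

test_that("mean spot area matches the rasterized disc and orders the presets", {
  one <- render_cell(phenotype_params("golgi", n_spots = 1, spot_radius = 5,
                                      photon_scale = 0, read_noise = 0,
                                      seed = 3), 64)$image
  f <- mean_spot_area(one)
  expect_identical(f$n_objects, 1L)
  expect_lt(abs(f$value - pi * 25) / (pi * 25), 0.15)
  # blank reporter: zero objects, zero value, no error
  blank <- one
  blank[2, , ] <- 0
  fb <- mean_spot_area(blank)
  expect_identical(fb$n_objects, 0L)
  expect_equal(fb$value, 0)
  # eight small spots average smaller than one compact spot
  many <- render_cell(phenotype_params("golgi", n_spots = 8,
                                       spot_radius = 1.5, photon_scale = 0,
                                       read_noise = 0, seed = 7), 64)$image
  expect_lt(mean_spot_area(many)$value, mean_spot_area(one)$value)
})

test_that("component labelling is 8-connected", {
  m <- matrix(FALSE, 7, 7)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE     # diagonal touch: one component
  m[6, 6] <- TRUE                      # isolated pixel
  lab <- latsr:::label_components8(m)
  expect_identical(max(lab), 2L)
  expect_identical(lab[2, 2], lab[3, 3])
})

test_that("psnr follows its closed form, caps, and is symmetric", {
  a <- with_seed_test(1, array(runif(3 * 16 * 16, 0.2, 0.8), c(3, 16, 16)))
  expect_equal(psnr(a, a), 100)
  expect_equal(psnr(a, a + 0.1), 20, tolerance = 1e-10)
  expect_equal(psnr(a, a + 0.01), 40, tolerance = 1e-8)
  b <- with_seed_test(2, array(runif(3 * 16 * 16), c(3, 16, 16)))
  expect_equal(psnr(a, b), psnr(b, a))
  expect_error(psnr(a, b[, 1:8, ]), "shape")
  expect_equal(l1_distance(a, a + 0.25), 0.25, tolerance = 1e-12)
})

test_that("ms-ssim is 1 on identical inputs and low on unrelated ones", {
  ramp <- array(matrix(rep(seq(0, 1, length.out = 96), each = 96), 96),
                c(1, 96, 96))
  expect_equal(ms_ssim(ramp, ramp), 1)
  expect_lt(ms_ssim(ramp, 1 - ramp), 0.5)
  n1 <- with_seed_test(3, array(runif(96 * 96), c(1, 96, 96)))
  n2 <- with_seed_test(4, array(runif(96 * 96), c(1, 96, 96)))
  expect_lt(abs(ms_ssim(n1, n2)), 0.2)
  # scale auto-reduction keeps small images valid
  s1 <- with_seed_test(5, array(runif(3 * 32 * 32), c(3, 32, 32)))
  expect_true(abs(ms_ssim(s1, s1) - 1) < 1e-12)
  expect_error(ms_ssim(array(0, c(1, 8, 8)), array(0, c(1, 8, 8))),
               "too small")
})

test_that("midpoint-of-medians classification is near the exhaustive optimum", {
  # perfectly separated classes
  expect_equal(threshold_classify(c(0, 0.1), c(0.9, 1))$accuracy, 1)
  # identical distributions sit at chance
  same <- c(1, 2, 3, 4, 5)
  expect_lt(abs(threshold_classify(same, same)$accuracy - 0.5), 0.26)
  # orientation flips when class b lies below class a
  expect_equal(threshold_classify(c(0.9, 1), c(0, 0.1))$accuracy, 1)
  # never beaten by more than 0.05 by the exhaustive threshold search
  va <- with_seed_test(6, rnorm(10, 0, 1))
  vb <- with_seed_test(7, rnorm(10, 1.2, 1))
  got <- threshold_classify(va, vb)$accuracy
  cands <- sort(c(va, vb))
  brute <- max(vapply(cands, function(thr) {
    acc1 <- (mean(va < thr) + mean(vb >= thr)) / 2
    acc2 <- (mean(va >= thr) + mean(vb < thr)) / 2
    max(acc1, acc2)
  }, 0))
  expect_lte(brute - got, 0.05 + 1e-9)
})

test_that("feature extraction tolerates failing images with NA", {
  imgs <- list(render_cell(phenotype_params("translocation", t = 0.9,
                                            seed = 1), 64)$image,
               array(0, c(3, 64, 64)))
  v <- extract_features(imgs, "translocation")
  expect_true(is.finite(v[1]))
  expect_true(is.na(v[2]))
})
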