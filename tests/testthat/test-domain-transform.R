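test_that("domain transform accumulates unit steps plus scaled gradients", {
  p <- nc_params(sigma_s = 2, sigma_r = 1)

  # constant scanline: increments collapse to 1
  const <- matrix(0.3, 4, 3)
  expect_equal(domain_transform_scanline(const, p), c(0, 1, 2, 3))

  # single effective channel [0,0,1,1], ratio 2 -> hand cumulative sum
  line <- cbind(c(0, 0, 1, 1), 0.5, 0.2)
  expect_equal(domain_transform_scanline(line, p), c(0, 1, 4, 5))

  expect_error(domain_transform_scanline(matrix(0, 0, 3), p), "empty")
})

test_that("transform is strictly increasing with increments >= 1", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:64, 1)
    line <- matrix(runif(n * 3), n, 3)
    ct <- domain_transform_scanline(line,
      nc_params(sigma_s = runif(1, 1, 100), sigma_r = runif(1, 0.05, 2)))
    expect_equal(ct[1], 0)
    expect_true(all(diff(ct) >= 1))
  }
})

test_that("kernel schedule conserves variance and collapses at N = 1", {
  expect_equal(kernel_schedule(nc_params(sigma_s = 7, n_iterations = 1)),
               sqrt(3) * 7)
  # N = 3, sigma_H = 60: direct evaluation of the shrinking schedule
  r <- kernel_schedule(nc_params(sigma_s = 60, n_iterations = 3))
  sig <- r / sqrt(3)
  expect_equal(sig, 60 * sqrt(3) * c(4, 2, 1) / sqrt(63), tolerance = 1e-12)
  expect_equal(round(sig, 3), c(52.372, 26.186, 13.093))
  for (n in 1:6) {
    sig <- kernel_schedule(nc_params(sigma_s = 60, n_iterations = n)) / sqrt(3)
    expect_equal(sum(sig^2), 60^2, tolerance = 1e-12)
    expect_true(all(diff(sig) < 0) || n == 1)
  }
})

test_that("box filter handles degenerate windows and the full-window limit", {
  p <- nc_params()
  # singleton windows: radius smaller than any gap
  out <- nc_box_filter_scanline(cbind(c(0, 1), c(0, 1), c(0, 1)),
                                c(0, 1), 0.5)
  expect_equal(out, cbind(c(0, 1), c(0, 1), c(0, 1)))
  # radius covering the whole line: every output is the scanline mean
  line <- matrix(runif(30), 10, 3)
  ct <- domain_transform_scanline(line, p)
  out <- nc_box_filter_scanline(line, ct, ct[10] + 1)
  expect_equal(out, matrix(rep(colMeans(line), each = 10), 10, 3))
  # constant scanline passes through unchanged
  const <- matrix(0.6, 8, 3)
  expect_equal(nc_box_filter_scanline(const, 0:7, 2.5), const)
  expect_error(nc_box_filter_scanline(line, ct, 0), "radius")
  expect_error(nc_box_filter_scanline(line, ct[-1], 1), "lengths")
})

test_that("moving-average filter matches the brute-force definition", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(2:128, 1)
    line <- matrix(runif(n * 3), n, 3)
    ct <- domain_transform_scanline(line,
      nc_params(sigma_s = runif(1, 1, 120), sigma_r = runif(1, 0.05, 2)))
    radius <- runif(1, 0.3, 60)
    expect_lt(max(abs(nc_box_filter_scanline(line, ct, radius) -
                      nc_brute_scanline(line, ct, radius))), 1e-9)
  }
})

test_that("nc_smooth equals direct per-pixel evaluation at N = 1", {
  set.seed(5)
  img <- random_color_image(8, 8)
  p <- nc_params(sigma_s = 4, sigma_r = 0.4, n_iterations = 1)
  expect_lt(max(abs(nc_smooth(img, p) - nc_brute_smooth1(img, p))), 1e-9)
})

test_that("nc_smooth preserves constants, range and degenerate sizes", {
  const <- array(0.42, c(6, 7, 3))
  expect_equal(nc_smooth(const, nc_params()), const, tolerance = 1e-14)

  img <- random_color_image(12, 9, seed = 3)
  J <- nc_smooth(img, nc_params(sigma_s = 10, sigma_r = 0.3))
  expect_gte(min(J), min(img))
  expect_lte(max(J), max(img))

  one <- array(0.7, c(1, 1, 3))
  expect_equal(nc_smooth(one, nc_params()), one)
})

test_that("large sigma_r limit reduces to a plain spatial box average", {
  # step-edge scanline; with sigma_r -> Inf the transform increments -> 1
  line <- matrix(rep(c(rep(0, 8), rep(1, 8)), 3), 16, 3)
  p <- nc_params(sigma_s = 1, sigma_r = 1e12)
  ct <- domain_transform_scanline(line, p)
  radius <- 2.2
  got <- nc_box_filter_scanline(line, ct, radius)
  plain <- sapply(1:16, function(i) {
    sel <- abs((1:16) - i) <= radius
    mean(line[sel, 1])
  })
  expect_equal(got[, 1], plain, tolerance = 1e-6)
})

test_that("smoothing strength grows with sigma_s on a noisy scanline", {
  set.seed(77)
  img <- array(rep(runif(64), 3), c(1, 64, 3))
  tv <- sapply(c(1, 5, 20, 60, 150), function(ss) {
    J <- nc_smooth(img, nc_params(sigma_s = ss, sigma_r = 0.4))
    total_variation(J[1, , 1])
  })
  expect_true(all(diff(tv) <= 1e-9))
})
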