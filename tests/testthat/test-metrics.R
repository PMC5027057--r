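toy_masks <- function() {
  vessels <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  list(vessels = vessels, fov = matrix(TRUE, 2, 2))
}

test_that("vessel contrast follows the masked-mean formula", {
  m <- toy_masks()
  img <- matrix(0.6, 2, 2); img[m$vessels] <- 0.4
  expect_equal(vessel_contrast(img, m$vessels, m$fov), 0.2, tolerance = 1e-12)
  # f = b gives zero contrast
  expect_equal(vessel_contrast(matrix(0.5, 2, 2), m$vessels, m$fov), 0)
  # dark vessels and bright vessels score the same magnitude
  inv <- matrix(0.4, 2, 2); inv[m$vessels] <- 0.6
  expect_equal(vessel_contrast(inv, m$vessels, m$fov), 0.2, tolerance = 1e-12)
})

test_that("vessel contrast agrees with an independent masked-mean oracle", {
  set.seed(19)
  for (rep in 1:10) {
    img <- matrix(runif(100, 0.05, 1), 10, 10)
    vessels <- matrix(runif(100) < 0.3, 10, 10)
    fov <- matrix(runif(100) < 0.8, 10, 10)
    if (!any(vessels & fov) || !any(!vessels & fov)) next
    f <- sum(img * (vessels & fov)) / sum(vessels & fov)
    b <- sum(img * (!vessels & fov)) / sum(!vessels & fov)
    expect_equal(vessel_contrast(img, vessels, fov), abs(f - b) / (f + b),
                 tolerance = 1e-12)
  }
})

test_that("degenerate masks and contrasts are rejected", {
  m <- toy_masks()
  img <- matrix(0.5, 2, 2)
  expect_error(vessel_contrast(img, matrix(FALSE, 2, 2), m$fov), "vessel")
  expect_error(vessel_contrast(img, matrix(TRUE, 2, 2), m$fov), "background")
  expect_error(vessel_contrast(matrix(0, 2, 2), m$vessels, m$fov),
               "degenerate")
  expect_error(cii(matrix(0.5, 2, 2), img, m$vessels, m$fov), "zero")
})

test_that("CII chains the two contrasts: toy case scores exactly 3", {
  m <- toy_masks()
  orig <- matrix(0.6, 2, 2); orig[m$vessels] <- 0.4
  enh <- matrix(0.8, 2, 2); enh[m$vessels] <- 0.2
  expect_equal(cii(orig, enh, m$vessels, m$fov), 3, tolerance = 1e-12)
  # identity enhancement and pure rescaling both score 1
  expect_equal(cii(orig, orig, m$vessels, m$fov), 1)
  expect_equal(cii(orig, 0.37 * orig, m$vessels, m$fov), 1,
               tolerance = 1e-12)
})

test_that("fuzziness closed forms and bounds", {
  # crisp binary image: memberships are 0 or 1
  bin <- matrix(c(0, 0.8, 0.8, 0), 2, 2)
  expect_equal(fuzziness(bin), 0, tolerance = 1e-12)
  # half at f_max, half at (2/3) f_max: those pixels give p = sin(pi/6)
  half <- matrix(c(0.9, 0.6, 0.9, 0.6), 2, 2)
  expect_equal(fuzziness(half), 0.5, tolerance = 1e-12)
  # general bound
  set.seed(29)
  for (rep in 1:10) {
    r <- fuzziness(matrix(runif(64, 0.01, 1), 8, 8))
    expect_gte(r, 0); expect_lte(r, 1)
  }
  expect_error(fuzziness(matrix(0, 3, 3)), "degenerate")
})

test_that("fuzziness FOV restriction changes f_max and the pixel set", {
  img <- matrix(0.3, 4, 4)
  img[1, 1] <- 1                       # bright pixel outside the FOV
  fov <- matrix(TRUE, 4, 4); fov[1, 1] <- FALSE
  full <- fuzziness(img)               # f_max = 1, memberships mid-range
  masked <- fuzziness(img, fov)        # f_max = 0.3, all pixels crisp
  expect_equal(masked, 0, tolerance = 1e-12)
  expect_gt(full, 0)
})

test_that("enhancement_report assembles green-channel metrics", {
  m <- toy_masks()
  wrap <- function(g) {
    img <- array(0.5, c(2, 2, 3)); img[, , 2] <- g; img
  }
  orig <- matrix(0.6, 2, 2); orig[m$vessels] <- 0.4
  enh <- matrix(0.8, 2, 2); enh[m$vessels] <- 0.2
  rep <- enhancement_report(wrap(orig), wrap(enh), m$vessels, m$fov)
  expect_equal(rep$cii, 3, tolerance = 1e-12)
  expect_equal(rep$cii, rep$contrast_enhanced / rep$contrast_original,
               tolerance = 1e-12)

  same <- enhancement_report(wrap(orig), wrap(orig), m$vessels, m$fov)
  expect_equal(same$cii, 1)
  expect_equal(same$fuzziness_original, same$fuzziness_enhanced)

  # ratio invariant on random inputs
  set.seed(37)
  a <- random_color_image(6, 6); b <- random_color_image(6, 6)
  vessels <- matrix(runif(36) < 0.4, 6, 6)
  r2 <- enhancement_report(a, b, vessels, matrix(TRUE, 6, 6))
  expect_equal(r2$cii, r2$contrast_enhanced / r2$contrast_original,
               tolerance = 1e-12)
  df <- as.data.frame(r2)
  expect_equal(df$cii, r2$cii)
  expect_output(print(r2), "CII")
})

test_that("inverting the enhanced channel flips bright vessels to dark", {
  m <- toy_masks()
  orig <- array(0, c(2, 2, 3)); orig[, , 2] <- 0.6
  orig[, , 2][m$vessels] <- 0.4
  # enhancement that made vessels brighter than background
  enh <- array(0, c(2, 2, 3)); enh[, , 2] <- 0.2
  enh[, , 2][m$vessels] <- 0.8
  flipped <- enhancement_report(orig, enh, m$vessels, m$fov, invert = TRUE)
  straight <- enhancement_report(orig, enh, m$vessels, m$fov)
  expect_equal(flipped$contrast_enhanced, straight$contrast_enhanced,
               tolerance = 1e-12)  # |f-b|/(f+b) on 0.2/0.8 both ways
})
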