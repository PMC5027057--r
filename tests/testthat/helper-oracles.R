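# Shared fixtures and independent brute-force oracles. The oracles evaluate
# the defining formulas directly (O(n^2) window enumeration, per-pixel
# sorting) and never share code with the implementation paths they check.

random_color_image <- function(h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}

# direct evaluation of the normalized box convolution: per pixel, enumerate
# every sample whose transformed coordinate falls inside the window
nc_brute_scanline <- function(line, ct, radius) {
  if (is.null(dim(line))) line <- matrix(line, ncol = 1L)
  out <- line
  for (p in seq_len(nrow(line))) {
    sel <- abs(ct - ct[p]) <= radius
    out[p, ] <- colMeans(line[sel, , drop = FALSE])
  }
  out
}

# direct evaluation of one smoothing iteration (rows then columns), using
# the brute-force scanline filter
nc_brute_smooth1 <- function(img, params) {
  radius <- kernel_schedule(params)[1]
  h <- dim(img)[1]; w <- dim(img)[2]
  for (i in seq_len(h)) {
    ct <- domain_transform_scanline(matrix(img[i, , ], ncol = 3), params)
    img[i, , ] <- nc_brute_scanline(matrix(img[i, , ], ncol = 3), ct, radius)
  }
  for (j in seq_len(w)) {
    ct <- domain_transform_scanline(matrix(img[, j, ], ncol = 3), params)
    img[, j, ] <- nc_brute_scanline(matrix(img[, j, ], ncol = 3), ct, radius)
  }
  img
}

# per-pixel sort-based relaxed median on one channel
rmf_brute_channel <- function(m, radius, alpha, omega) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ri <- pmin(pmax((i - radius):(i + radius), 1L), h)
    cj <- pmin(pmax((j - radius):(j + radius), 1L), w)
    win <- sort(as.vector(m[ri, cj]))
    v <- m[i, j]
    out[i, j] <- if (v >= win[alpha] && v <= win[omega]) v
                 else win[(length(win) + 1L) %/% 2L]
  }
  out
}

total_variation <- function(x) sum(abs(diff(x)))
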