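#' Specification of a synthetic fundus phantom
#'
#' Describes a seeded fundus-like test image with ground truth: a circular
#' field of view on a black surround, a smooth reddish background with
#' radial shading and a random low-frequency illumination field, a dark
#' branching vessel tree radiating from the optic-disk region (contrast
#' strongest in the green channel), an optional bright optic disk and dark
#' fovea, soft vessel edges and additive Gaussian noise inside the FOV.
#'
#' The defaults emulate the statistics the enhancement pipeline is designed
#' for: low vessel/background contrast, uneven illumination and mild noise
#' at a DRIVE-like field-of-view geometry.
#'
#' @param seed Integer seed; the phantom is a pure function of the spec.
#' @param height,width Image size in pixels (>= 64 each). Default 256.
#' @param fov_radius_frac FOV radius as a fraction of `min(height, width)`,
#'   in `(0, 0.5]`. Default 0.46.
#' @param n_vessel_roots Number of vessel trunks leaving the optic disk
#'   (>= 1). Default 6.
#' @param vessel_contrast Intensity dip of vessels below the local
#'   background, in `[0, 1]` (applied fully in green, attenuated in red and
#'   blue). Default 0.35.
#' @param illumination_amplitude Strength of the uneven illumination, in
#'   `[0, 1]`: the peak-to-trough amplitude of the random low-frequency
#'   field, which also scales the radial vignetting. 0 gives a perfectly
#'   flat background. Default 0.25.
#' @param noise_sigma Standard deviation of additive Gaussian noise on the
#'   unit scale (>= 0). Default 0.02.
#' @param include_optic_disk,include_fovea Include the bright optic-disk
#'   ellipse / the dark foveal disk?
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L, height = 256L, width = 256L,
                         fov_radius_frac = 0.46, n_vessel_roots = 5L,
                         vessel_contrast = 0.15,
                         illumination_amplitude = 0.25,
                         noise_sigma = 0.02,
                         include_optic_disk = TRUE, include_fovea = TRUE) {
  check_scalar(seed, "seed", integer = TRUE)
  check_scalar(height, "height", lower = 64, integer = TRUE)
  check_scalar(width, "width", lower = 64, integer = TRUE)
  check_scalar(fov_radius_frac, "fov_radius_frac", lower = 0, upper = 0.5,
               strict_lower = TRUE)
  check_scalar(n_vessel_roots, "n_vessel_roots", lower = 1, integer = TRUE)
  check_scalar(vessel_contrast, "vessel_contrast", lower = 0, upper = 1)
  check_scalar(illumination_amplitude, "illumination_amplitude",
               lower = 0, upper = 1)
  check_scalar(noise_sigma, "noise_sigma", lower = 0)
  structure(list(
    seed = as.integer(seed), height = as.integer(height),
    width = as.integer(width), fov_radius_frac = as.numeric(fov_radius_frac),
    n_vessel_roots = as.integer(n_vessel_roots),
    vessel_contrast = as.numeric(vessel_contrast),
    illumination_amplitude = as.numeric(illumination_amplitude),
    noise_sigma = as.numeric(noise_sigma),
    include_optic_disk = isTRUE(include_optic_disk),
    include_fovea = isTRUE(include_fovea)
  ), class = "phantom_spec")
}

#' Generate a synthetic fundus phantom with ground truth
#'
#' Deterministically renders the phantom described by a [phantom_spec()]:
#' identical specs yield bitwise-identical phantoms, and all randomness is
#' drawn from a private stream seeded by `spec$seed` (the caller's RNG
#' state is untouched). The vessel mask records the vessel support before
#' edge-softening blur, so it is exact ground truth for contrast metrics.
#'
#' @param spec A [phantom_spec()] object.
#' @return A list of class `phantom` with elements `image`
#'   (`H x W x 3` unit-scale array, zero outside the FOV), `vessel_mask`
#'   and `fov_mask` (logical matrices, `vessel_mask` a subset of
#'   `fov_mask`), and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop("`spec` must be a phantom_spec object", call. = FALSE)
  with_seed(spec$seed, render_phantom(spec))
}

render_phantom <- function(spec) {
  h <- spec$height; w <- spec$width
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  R <- spec$fov_radius_frac * min(h, w)
  dy <- matrix(seq_len(h) - cy, h, w)
  dx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  d <- sqrt(dy^2 + dx^2)
  fov <- d <= R

  # smooth background: reddish base with radial shading (scaled by the
  # illumination amplitude, so amplitude 0 means a perfectly flat field) ...
  shade <- 1 - 1.4 * spec$illumination_amplitude * pmin(d / R, 1)^2
  base <- c(0.62, 0.40, 0.18)
  # ... plus one shared low-frequency illumination field
  field <- matrix(stats::rnorm(36), 6, 6)
  field <- EBImage::resize(field, w = h, h = w)
  field <- field - mean(field)
  rng <- diff(range(field))
  if (rng > 0 && spec$illumination_amplitude > 0)
    field <- field * (spec$illumination_amplitude / rng)
  else field <- field * 0

  # vessel tree: branching random walks from the optic-disk region
  od <- c(cy, cx + 0.60 * R)                     # optic disk center (y, x)
  vm <- grow_vessel_tree(spec, h, w, cy, cx, R, od)

  vsoft <- EBImage::gblur(matrix(as.numeric(vm), h, w), sigma = 1)
  vweight <- c(0.45, 1, 0.3)                     # green carries most contrast

  img <- array(0, c(h, w, 3))
  for (k in 1:3) {
    ch <- base[k] * shade + field
    ch <- ch - spec$vessel_contrast * vweight[k] * vsoft
    if (spec$include_optic_disk) {
      odm <- ((dy - (od[1] - cy)) / (0.13 * R))^2 +
             ((dx - (od[2] - cx)) / (0.11 * R))^2 <= 1
      ch <- ch + c(0.30, 0.28, 0.12)[k] *
        EBImage::gblur(matrix(as.numeric(odm), h, w), sigma = 2)
    }
    if (spec$include_fovea) {
      fv <- (dy / (0.12 * R))^2 + ((dx + 0.25 * R) / (0.12 * R))^2 <= 1
      ch <- ch - c(0.08, 0.12, 0.05)[k] *
        EBImage::gblur(matrix(as.numeric(fv), h, w), sigma = 3)
    }
    img[, , k] <- ch
  }
  if (spec$noise_sigma > 0) {
    noise <- array(stats::rnorm(h * w * 3, sd = spec$noise_sigma),
                   c(h, w, 3))
    img <- img + noise * as.numeric(rep(fov, 3))
  }
  img <- clip01(img) * as.numeric(rep(fov, 3))

  structure(list(image = img, vessel_mask = vm & fov, fov_mask = fov,
                 spec = spec), class = "phantom")
}

# Seeded recursive branching random walks; stamps disks of tapering width
# (4 px down to 1 px) into a logical canvas. Returns the pre-blur support.
grow_vessel_tree <- function(spec, h, w, cy, cx, R, od) {
  vm <- matrix(FALSE, h, w)
  stamp <- function(y, x, width) {
    r <- width / 2
    rows <- max(1L, floor(y - r)):min(h, ceiling(y + r))
    cols <- max(1L, floor(x - r)):min(w, ceiling(x + r))
    for (rr in rows) for (cc in cols)
      if ((rr - y)^2 + (cc - x)^2 <= r^2 + 0.25) vm[rr, cc] <<- TRUE
  }
  walk <- function(y, x, ang, width, steps, depth) {
    for (s in seq_len(steps)) {
      ang <- ang + stats::rnorm(1, sd = 0.12)
      y <- y + sin(ang); x <- x + cos(ang)
      if (sqrt((y - cy)^2 + (x - cx)^2) > R - 2) return(invisible())
      wcur <- max(1, width * (1 - 0.6 * s / steps))
      stamp(y, x, wcur)
      if (depth > 0L && s > 10L && stats::runif(1) < 0.02) {
        side <- if (stats::runif(1) < 0.5) -1 else 1
        walk(y, x, ang + side * stats::runif(1, 0.4, 0.9),
             max(1, wcur - 1), ceiling(steps * 0.6), depth - 1L)
      }
    }
  }
  n <- spec$n_vessel_roots
  angs <- pi + seq(-1.1, 1.1, length.out = n) + stats::rnorm(n, sd = 0.1)
  for (i in seq_len(n))
    walk(od[1], od[2], angs[i], width = 4, steps = ceiling(1.4 * R),
         depth = 2L)
  vm
}

#' Write / re-read a phantom on disk
#'
#' `write_phantom()` writes `image.png`, `vessels.png`, `fov.png` (masks as
#' 0/255 PNGs) and `spec.json` into a directory. Binary masks survive 8-bit
#' I/O exactly, and `spec.json` re-read through
#' [read_phantom_spec()] regenerates an identical phantom.
#'
#' @param p A `phantom` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_phantom <- function(p, dir) {
  if (!inherits(p, "phantom")) stop("`p` must be a phantom", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(p$image, file.path(dir, "image.png"))
  write_mask(p$vessel_mask, file.path(dir, "vessels.png"))
  write_mask(p$fov_mask, file.path(dir, "fov.png"))
  jsonlite::write_json(unclass(p$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_phantom
#' @param path Path to a `spec.json` written by `write_phantom()`.
#' @return `read_phantom_spec()`: the [phantom_spec()] object.
#' @export
read_phantom_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(phantom_spec, x)
}
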