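#' Vessel/background contrast within the field of view
#'
#' Computes `C = |f - b| / (f + b)` where `f` is the mean gray value over
#' vessel pixels and `b` the mean over non-vessel pixels, both restricted
#' to the field of view (the black surround outside the pupil is excluded).
#' The magnitude is used because retinal vessels are darker than the
#' background, which would make the signed ratio negative.
#'
#' @param img `H x W` gray matrix (conventionally the green channel).
#' @param vessels Logical vessel mask, same shape.
#' @param fov Logical field-of-view mask, same shape.
#' @return The contrast C, a single non-negative number.
#' @export
vessel_contrast <- function(img, vessels, fov) {
  check_gray_image(img)
  check_mask(vessels, dim(img), "vessels")
  check_mask(fov, dim(img), "fov")
  v <- vessels & fov
  b <- (!vessels) & fov
  if (!any(v)) stop("no vessel pixels inside the FOV", call. = FALSE)
  if (!any(b)) stop("no background pixels inside the FOV", call. = FALSE)
  f <- mean(img[v]); g <- mean(img[b])
  if (f + g == 0) stop("degenerate contrast: f + b = 0", call. = FALSE)
  abs(f - g) / (f + g)
}

#' Contrast improvement index
#'
#' `CII = C_enhanced / C_original`, the ratio of vessel/background contrast
#' (see [vessel_contrast()]) after versus before enhancement, measured on
#' the same masks. Values above 1 mean the vessels stand out more after
#' enhancement. C is scale-invariant, so a plain rescaling of intensities
#' scores exactly 1.
#'
#' @param original,enhanced `H x W` gray matrices.
#' @inheritParams vessel_contrast
#' @return The CII, a single positive number.
#' @export
cii <- function(original, enhanced, vessels, fov) {
  c0 <- vessel_contrast(original, vessels, fov)
  if (c0 == 0) stop("original image has zero vessel contrast", call. = FALSE)
  vessel_contrast(enhanced, vessels, fov) / c0
}

#' Linear index of fuzziness
#'
#' Each pixel is mapped to a membership `p = sin(pi/2 * (1 - f / f_max))`
#' with `f_max` the maximum pixel of the (masked) image, and the index is
#' `r = 2 / (M * N) * sum min(p, 1 - p)`: the mean closeness of memberships
#' to the maximally ambiguous value 0.5, scaled to `[0, 1]`. A crisp image
#' whose pixels sit at 0 or `f_max` scores 0; mid-gray mass pushes the
#' index up. Smaller is better after enhancement.
#'
#' By default the whole `M x N` image is used, including any black
#' surround; pass `fov` to restrict the sum (and `f_max`) to the field of
#' view.
#'
#' @param img `H x W` gray matrix.
#' @param fov Optional logical mask restricting the computation.
#' @return The fuzziness index in `[0, 1]`.
#' @export
fuzziness <- function(img, fov = NULL) {
  check_gray_image(img)
  f <- if (is.null(fov)) as.vector(img) else {
    check_mask(fov, dim(img), "fov")
    img[fov]
  }
  if (!length(f)) stop("empty image region", call. = FALSE)
  fmax <- max(f)
  if (fmax <= 0)
    stop("degenerate input: maximum intensity is 0", call. = FALSE)
  p <- sin(pi / 2 * (1 - f / fmax))
  2 * mean(pmin(p, 1 - p))
}

#' Objective enhancement report
#'
#' Assembles the two objective quality measures for an enhancement result:
#' the contrast improvement index over the vessel mask and the linear index
#' of fuzziness before and after. Following the green-channel evaluation
#' convention, only the green channels of the two color images enter the
#' computation. An enhancement whose vessels come out brighter than the
#' background can be inverted first (`invert = TRUE`) so all methods are
#' compared under the dark-vessel convention.
#'
#' @param original,enhanced `H x W x 3` color arrays on the unit scale.
#' @param vessels,fov Logical masks matching the image shape.
#' @param invert Invert the enhanced green channel (`1 - g`) before
#'   computing the metrics?
#' @param fov_only Restrict the fuzziness index to the field of view
#'   instead of the full image?
#' @return A list of class `metric_report` with elements `cii`,
#'   `contrast_original`, `contrast_enhanced`, `fuzziness_original`,
#'   `fuzziness_enhanced`.
#' @export
enhancement_report <- function(original, enhanced, vessels, fov,
                               invert = FALSE, fov_only = FALSE) {
  check_color_image(original, "original")
  check_color_image(enhanced, "enhanced")
  g0 <- green_channel(original)
  g1 <- green_channel(enhanced)
  if (invert) g1 <- 1 - g1
  c0 <- vessel_contrast(g0, vessels, fov)
  c1 <- vessel_contrast(g1, vessels, fov)
  if (c0 == 0) stop("original image has zero vessel contrast", call. = FALSE)
  fmask <- if (fov_only) fov else NULL
  structure(list(
    cii = c1 / c0,
    contrast_original = c0,
    contrast_enhanced = c1,
    fuzziness_original = fuzziness(g0, fmask),
    fuzziness_enhanced = fuzziness(g1, fmask)
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Enhancement quality report (green channel)\n")
  cat(sprintf("  contrast C (original):  %.4f\n", x$contrast_original))
  cat(sprintf("  contrast C (enhanced):  %.4f\n", x$contrast_enhanced))
  cat(sprintf("  CII:                    %.4f\n", x$cii))
  cat(sprintf("  fuzziness r (original): %.4f\n", x$fuzziness_original))
  cat(sprintf("  fuzziness r (enhanced): %.4f\n", x$fuzziness_enhanced))
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(cii = x$cii,
             contrast_original = x$contrast_original,
             contrast_enhanced = x$contrast_enhanced,
             fuzziness_original = x$fuzziness_original,
             fuzziness_enhanced = x$fuzziness_enhanced)
}
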