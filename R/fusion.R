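#' Fusion parameters
#'
#' @param a Contrast factor (>= 0). `a = 0` returns the original image;
#'   larger values amplify the difference between the image and its
#'   background estimate. Default 5.
#' @return A list of class `fusion_params`.
#' @export
fusion_params <- function(a = 5) {
  check_scalar(a, "a", lower = 0)
  structure(list(a = as.numeric(a)), class = "fusion_params")
}

#' Background-suppressing fusion of an image with its background estimate
#'
#' Computes `P = I - a * (J - I) = (1 + a) * I - a * J` elementwise, then
#' clips to `[0, 1]`. Structures darker than the local background (vessels,
#' fovea) are pushed further down and bright details up, while flat regions
#' where `J` tracks `I` are left alone — an unsharp-mask-like background
#' suppression. At the default `a = 5` a substantial fraction of pixels
#' saturates; the clipping fraction is reported via a message when
#' `verbose = TRUE`.
#'
#' @param I Original `H x W x 3` image, unit scale.
#' @param J Background image of identical shape (from [nc_smooth()]).
#' @param params A [fusion_params()] object.
#' @param verbose Report the fraction of clipped pixels?
#' @return The fused image P, clipped to `[0, 1]`.
#' @export
fuse <- function(I, J, params = fusion_params(), verbose = FALSE) {
  check_color_image(I, "I")
  check_color_image(J, "J")
  if (!identical(dim(I), dim(J)))
    stop("`I` and `J` must have identical dimensions", call. = FALSE)
  a <- params$a
  if (a == 0) return(I)
  P <- (1 + a) * I - a * J
  if (verbose) {
    frac <- mean(P < 0 | P > 1)
    message(sprintf("fusion (a = %g): %.1f%% of values clipped",
                    a, 100 * frac))
  }
  clip01(P)
}

#' Fuse with a series of contrast factors
#'
#' Applies [fuse()] once per value of `a`; used by the parameter-study
#' sweep (the customary series is a = 1, 3, 5, 8, 10).
#'
#' @inheritParams fuse
#' @param values Non-empty numeric vector of contrast factors.
#' @return Named list of fused images, one per value of `a`.
#' @export
sweep_a <- function(I, J, values = c(1, 3, 5, 8, 10)) {
  if (!length(values)) stop("`values` must be non-empty", call. = FALSE)
  out <- lapply(values, function(a) fuse(I, J, fusion_params(a)))
  names(out) <- paste0("a=", values)
  out
}
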