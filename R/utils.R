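#' @keywords internal
"_PACKAGE"

# Internal validators. Images are plain numeric arrays: a color image is an
# H x W x 3 array on the unit scale [0, 1] (red, green, blue), a gray image
# an H x W matrix, a mask an H x W logical matrix. Row 1 is the top scanline.

check_color_image <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 numeric array", arg), call. = FALSE)
  if (!all(is.finite(img)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  invisible(img)
}

check_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be an H x W numeric matrix", arg), call. = FALSE)
  if (!all(is.finite(img)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  invisible(img)
}

check_mask <- function(mask, dim_ref = NULL, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("`%s` must be an H x W logical matrix", arg), call. = FALSE)
  if (!is.null(dim_ref) && !identical(dim(mask), dim_ref[1:2]))
    stop(sprintf("`%s` dimensions do not match the image", arg), call. = FALSE)
  invisible(mask)
}

check_scalar <- function(x, arg, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integer = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", arg), call. = FALSE)
  if (strict_lower) {
    if (x <= lower) stop(sprintf("`%s` must be > %s", arg, lower), call. = FALSE)
  } else if (x < lower) {
    stop(sprintf("`%s` must be >= %s", arg, lower), call. = FALSE)
  }
  if (x > upper) stop(sprintf("`%s` must be <= %s", arg, upper), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("`%s` must be an integer", arg), call. = FALSE)
  invisible(x)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Run `expr` under a private RNG stream seeded with `seed`, restoring any
# pre-existing global state afterwards (no global random state leaks).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
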