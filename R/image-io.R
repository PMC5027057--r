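#' Read a raster image as a unit-range color array
#'
#' Reads a PNG, TIFF or PPM/PGM raster and returns an `H x W x 3` numeric
#' array with values in `[0, 1]` (channels in red, green, blue order).
#' Integer rasters are divided by their type maximum, so an 8-bit 255 and a
#' 16-bit 65535 both map to 1. Grayscale files are replicated to three
#' channels; an alpha channel, if present, is dropped with a warning.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.ppm` or `.pgm` file.
#' @return An `H x W x 3` numeric array in `[0, 1]`.
#' @seealso [write_image()], [green_channel()]
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    ppm  = ,
    pgm  = read_pnm(path),
    stop("unsupported image format: .", ext, " (", path, ")", call. = FALSE)
  )
  if (is.matrix(px)) px <- array(px, c(dim(px), 1L))
  nc <- dim(px)[3]
  if (nc %in% c(2L, 4L)) {
    warning("alpha channel dropped: ", path, call. = FALSE)
    px <- px[, , seq_len(nc - 1L), drop = FALSE]
    nc <- dim(px)[3]
  }
  if (nc == 1L) px <- array(px, c(dim(px)[1:2], 3L))
  if (dim(px)[3] != 3L)
    stop("expected 1 or 3 color channels in ", path, call. = FALSE)
  check_color_image(px)
}

#' Write an image as an 8-bit raster
#'
#' Values are clipped to `[0, 1]`, scaled by 255 and rounded half-up to the
#' nearest byte. The format follows the file extension (PNG, TIFF or PPM).
#' Gray matrices are written as single-channel rasters.
#'
#' @param img `H x W x 3` array or `H x W` matrix on the unit scale.
#' @param path Output path; the parent directory must exist.
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path) {
  if (!dir.exists(dirname(path)))
    stop("cannot write image: no such directory: ", dirname(path),
         call. = FALSE)
  if (is.matrix(img)) check_gray_image(img) else check_color_image(img)
  bytes <- floor(clip01(img) * 255 + 0.5)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(bytes / 255, path),
    tif  = ,
    tiff = tiff::writeTIFF(bytes / 255, path, bits.per.sample = 8L),
    ppm  = ,
    pgm  = write_pnm(bytes, path),
    stop("unsupported output format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Read / write binary masks
#'
#' Masks are stored as single-channel 8-bit PNGs with 0 = FALSE and
#' 255 = TRUE; on reading, any value above 0.5 counts as TRUE.
#'
#' @param path Path to a mask PNG.
#' @return `read_mask()`: an `H x W` logical matrix.
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (!is.matrix(px)) px <- px[, , 1]
  px > 0.5
}

#' @rdname read_mask
#' @param mask `H x W` logical matrix.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Extract the green channel
#'
#' Vessel contrast is strongest in the green channel of fundus photographs,
#' which is the conventional basis for objective evaluation.
#'
#' @param img `H x W x 3` color array.
#' @return `H x W` matrix (values unchanged).
#' @export
green_channel <- function(img) {
  check_color_image(img)
  img[, , 2]
}

#' Estimate the circular field of view of a fundus photograph
#'
#' Fundus photographs show a bright circular field of view (FOV) on a black
#' surround. The mask is true where the per-pixel channel maximum exceeds
#' `threshold`; it is then cleaned up by a morphological closing with a disk
#' of radius 3 and hole filling, so a single illuminated pupil yields a
#' single filled region.
#'
#' @param img `H x W x 3` color array on the unit scale.
#' @param threshold Intensity threshold in `(0, 1)`; the default 0.06 suits
#'   DRIVE-style near-black surrounds.
#' @return `H x W` logical matrix.
#' @export
estimate_fov <- function(img, threshold = 0.06) {
  check_color_image(img)
  check_scalar(threshold, "threshold", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (threshold >= 1) stop("`threshold` must be < 1", call. = FALSE)
  chmax <- pmax(img[, , 1], img[, , 2], img[, , 3])
  raw <- chmax > threshold
  if (!any(raw)) {
    warning("image is entirely dark; empty FOV mask", call. = FALSE)
    return(raw)
  }
  m <- EBImage::closing(matrix(as.numeric(raw), nrow(raw)),
                        EBImage::makeBrush(7L, shape = "disc"))
  m <- EBImage::fillHull(m)
  m > 0.5
}

#' List a DRIVE-style dataset directory
#'
#' Scans the conventional `images/`, `1st_manual/` and `mask/` subfolders of
#' a DRIVE-layout retinal dataset and pairs files by their leading numeric
#' identifier. This is a reader only; no data are downloaded.
#'
#' @param dir Dataset root containing an `images/` subdirectory.
#' @return A data.frame with columns `id`, `image`, `vessels`, `fov`
#'   (absolute paths; `NA` where the annotation is absent).
#' @export
read_drive_layout <- function(dir) {
  img_dir <- file.path(dir, "images")
  if (!dir.exists(img_dir))
    stop("not a DRIVE-style layout (no images/ subdirectory): ", dir,
         call. = FALSE)
  imgs <- list.files(img_dir, pattern = "\\.(png|tif|tiff|ppm)$",
                     ignore.case = TRUE, full.names = TRUE)
  ids <- sub("^([0-9]+).*", "\\1", basename(imgs))
  find_for <- function(sub, id) {
    d <- file.path(dir, sub)
    if (!dir.exists(d)) return(NA_character_)
    hit <- list.files(d, pattern = paste0("^", id), full.names = TRUE)
    if (length(hit)) hit[[1]] else NA_character_
  }
  data.frame(
    id = ids,
    image = imgs,
    vessels = vapply(ids, find_for, character(1), sub = "1st_manual"),
    fov = vapply(ids, find_for, character(1), sub = "mask"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# --- minimal PNM (PPM/PGM) codec -------------------------------------------
# P2/P3 (ASCII) and P5/P6 (binary) at 8 or 16 bit. No installed R package
# reads this format, so it is implemented here.

read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok_buf <- character(0)
  next_token <- function() {
    while (!length(tok_buf)) {
      line <- readLines(con, n = 1L, warn = FALSE)
      if (!length(line)) stop("truncated PNM header: ", path, call. = FALSE)
      line <- sub("#.*", "", line)
      tok_buf <<- strsplit(trimws(line), "[ \t]+")[[1]]
      tok_buf <<- tok_buf[nzchar(tok_buf)]
    }
    t <- tok_buf[[1]]
    tok_buf <<- tok_buf[-1]
    t
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic '", magic, "' in ", path, call. = FALSE)
  w <- as.integer(next_token()); h <- as.integer(next_token())
  maxval <- as.integer(next_token())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    if (maxval < 256) as.numeric(readBin(con, "integer", n, size = 1L,
                                         signed = FALSE))
    else readBin(con, "integer", n, size = 2L, signed = FALSE,
                 endian = "big")
  } else {
    as.numeric(scan(con, what = integer(), n = n, quiet = TRUE,
                    comment.char = "#"))
  }
  if (length(vals) < n) stop("truncated PNM data: ", path, call. = FALSE)
  # pixel order: row-major, channels interleaved
  a <- array(vals / maxval, c(nch, w, h))
  aperm(a, c(3, 2, 1))[, , seq_len(nch), drop = (nch == 1L)]
}

write_pnm <- function(bytes, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  gray <- is.matrix(bytes)
  h <- dim(bytes)[1]; w <- dim(bytes)[2]
  writeLines(c(if (gray) "P5" else "P6", paste(w, h), "255"), con)
  dat <- if (gray) t(bytes) else aperm(bytes, c(3, 2, 1))
  writeBin(as.raw(as.integer(dat)), con)
  invisible(path)
}
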