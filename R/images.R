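#' Raster image containers
#'
#' The pipeline's raw input is an 8-bit RGB photograph of a cut, tip-painted
#' grass bunch. `rgb_image()` wraps an H x W x 3 integer array (values in
#' 0..255) and `gray_image()` an H x W matrix; both validate their invariants.
#'
#' @param pixels For `rgb_image()` an H x W x 3 numeric array; for
#'   `gray_image()` an H x W numeric matrix. Values must lie in \[0, 255\].
#' @return An object of class `rgb_image` (array) or `gray_image` (matrix).
#' @examples
#' img <- rgb_image(array(rep(c(10, 20, 30), each = 4), c(2, 2, 3)))
#' dim(img)
#' @export
rgb_image <- function(pixels) {
  pixels <- unclass(pixels)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort("`pixels` must be an H x W x 3 array.")
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) abort("image must be at least 1 x 1")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    abort("channel values must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, class = "rgb_image")
}

#' @rdname rgb_image
#' @export
gray_image <- function(pixels) {
  pixels <- unclass(pixels)
  if (!is.matrix(pixels)) abort("`pixels` must be an H x W matrix.")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    abort("grey values must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, class = "gray_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image> %d x %d px, 3 bands (8-bit)\n", nrow(x), ncol(x)))
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px (8-bit)\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read a photograph as an 8-bit RGB image
#'
#' Decodes a PNG or JPEG file into an [rgb_image()]. Grayscale inputs are
#' replicated across the three bands; an alpha channel, if present, is
#' dropped. Sample depths other than 8 bit are rescaled to \[0, 255\].
#' TIFF is not supported in this build (no TIFF decoder is available);
#' convert to PNG first.
#'
#' @param path Path to a PNG (`.png`) or JPEG (`.jpg`/`.jpeg`) file.
#' @return An [rgb_image()].
#' @seealso [write_image()], [to_blue_band()]
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) abort("`path` must be a single file path.")
  if (!file.exists(path)) abort(paste0("cannot read image: file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = tryCatch(png::readPNG(path), error = function(e) {
      abort(paste0("cannot decode PNG ", path, ": ", conditionMessage(e)))
    }),
    jpg = ,
    jpeg = tryCatch(jpeg::readJPEG(path), error = function(e) {
      abort(paste0("cannot decode JPEG ", path, ": ", conditionMessage(e)))
    }),
    tif = ,
    tiff = abort(paste0(
      "cannot read ", path,
      ": TIFF decoding is not available in this build; convert to PNG or JPEG"
    )),
    abort(paste0("unsupported image format '.", ext, "' for ", path))
  )
  # readPNG/readJPEG scale any sample depth into [0, 1]
  px <- round(px * 255)
  if (is.matrix(px)) px <- array(px, c(dim(px), 1L))
  if (dim(px)[3] == 1L) px <- array(px[, , 1L], c(dim(px)[1:2], 3L))
  if (dim(px)[3] >= 4L) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] == 2L) px <- array(px[, , 1L], c(dim(px)[1:2], 3L)) # gray+alpha
  rgb_image(px)
}

#' Write an image or mask to PNG
#'
#' `write_image()` writes an [rgb_image()] or [gray_image()]; `write_mask()`
#' writes a binary mask as a black/white PNG.
#'
#' @param img An [rgb_image()] or [gray_image()].
#' @param mask A logical matrix (`TRUE` = object of interest).
#' @param path Output file path (`.png`).
#' @return The path, invisibly.
#' @export
write_image <- function(img, path) {
  px <- unclass(img)
  png::writePNG(px / 255, path)
  invisible(path)
}

#' @rdname write_image
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Write / read a label map as a lossless PNG
#'
#' Label maps can exceed 255 objects, but the available PNG writer emits
#' 8-bit samples only. Labels are therefore split across two channels:
#' `label = R + 256 * G` (and B = 0), which is lossless for up to 65535
#' objects. `read_label_map()` inverts the encoding.
#'
#' @param label_map Integer matrix (0 = background, k >= 1 = object id).
#' @param path Output/input PNG path.
#' @return `write_label_map()` the path invisibly; `read_label_map()` an
#'   integer matrix.
#' @export
write_label_map <- function(label_map, path) {
  stopifnot(is.matrix(label_map))
  if (max(label_map) > 65535L) abort("label map has more than 65535 objects")
  lo <- label_map %% 256L
  hi <- label_map %/% 256L
  arr <- array(0, c(dim(label_map), 3L))
  arr[, , 1] <- lo / 255
  arr[, , 2] <- hi / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  arr <- png::readPNG(path)
  matrix(as.integer(round(arr[, , 1] * 255) + 256 * round(arr[, , 2] * 255)),
    nrow = dim(arr)[1]
  )
}

#' Extract one colour band as a grey image
#'
#' The segmentation works on a single band of the photograph. White-painted
#' shoot tips are bright in all bands while soil reflects the three bands in
#' roughly equal, low proportions and green leaves are dimmest in blue, so the
#' blue band gives the best tip/background contrast and is the default.
#'
#' @param img An [rgb_image()].
#' @param band `"blue"` (default), `"green"` or `"red"`.
#' @return A [gray_image()] with the same extent as `img`.
#' @examples
#' img <- rgb_image(array(c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100, 110, 120), c(2, 2, 3)))
#' to_blue_band(img)[1, 1] # blue channel of pixel (1,1)
#' @export
to_blue_band <- function(img, band = c("blue", "green", "red")) {
  if (!inherits(img, "rgb_image")) abort("`img` must be an rgb_image")
  band <- match.arg(band)
  k <- c(red = 1L, green = 2L, blue = 3L)[[band]]
  gray_image(unclass(img)[, , k])
}
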