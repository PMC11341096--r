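#' Construct an FPM stack
#'
#' An FPM stack holds the four registered intensity images acquired at
#' excitation polarizations 0, 45, 90 and 135 degrees (in that fixed order,
#' anticlockwise from the +x axis), together with the pixel size.
#'
#' @param images list of exactly 4 numeric matrices of identical dimensions;
#'   intensities in photoelectron counts, finite and >= 0.
#' @param pixel_size pixel size in micrometres per pixel (> 0).
#' @param name identifier string for the stack.
#' @return An object of class `fpm_stack` with fields `images`, `angles`
#'   (always `c(0, 45, 90, 135)`), `pixel_size`, `name`.
#' @examples
#' img <- matrix(1, 8, 8)
#' s <- fpm_stack(list(img, img, img, img), pixel_size = 0.1)
#' @export
fpm_stack <- function(images, pixel_size = 0.1, name = "stack") {
  if (!is.list(images) || length(images) != 4L)
    stopf("an FPM stack requires exactly 4 images, got %d", length(images))
  images <- lapply(images, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  d <- dim(images[[1L]])
  for (i in 2:4)
    if (!identical(dim(images[[i]]), d))
      stopf("stack pages have unequal dimensions (page %d)", i)
  for (i in 1:4) {
    if (any(!is.finite(images[[i]])))
      stopf("non-finite intensity in page %d", i)
    if (any(images[[i]] < 0))
      stopf("negative intensity in page %d", i)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stopf("pixel_size must be a single positive number (micrometres/pixel)")
  structure(
    list(images = images, angles = c(0, 45, 90, 135),
         pixel_size = as.numeric(pixel_size), name = as.character(name)),
    class = "fpm_stack")
}

#' @export
print.fpm_stack <- function(x, ...) {
  d <- dim(x$images[[1L]])
  cat(sprintf("<fpm_stack '%s'> %d x %d px, 4 polarizations (0/45/90/135 deg), %.4g um/px\n",
              x$name, d[1L], d[2L], x$pixel_size))
  invisible(x)
}

#' Construct a flat-field calibration stack
#'
#' Four rasters (one per excitation polarization) imaging a uniform sample,
#' used by [flat_field_correct()] to remove illumination nonuniformity.
#'
#' @param images list of 4 numeric matrices, strictly positive.
#' @return An object of class `fpm_flat_stack`.
#' @export
fpm_flat_stack <- function(images) {
  if (!is.list(images) || length(images) != 4L)
    stopf("a flat-field stack requires exactly 4 images, got %d", length(images))
  images <- lapply(images, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; m
  })
  d <- dim(images[[1L]])
  for (i in 2:4)
    if (!identical(dim(images[[i]]), d))
      stopf("flat-field pages have unequal dimensions (page %d)", i)
  structure(list(images = images), class = "fpm_flat_stack")
}

stack_dim <- function(stack) dim(stack$images[[1L]])
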