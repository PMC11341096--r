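# Pixelwise FPM statistics: flat-field correction, S0/S1/S2, order, azimuth,
# per-pixel sinusoid fitting, and the custom-statistic plug-in point.

# Registry of user-defined per-pixel statistics (name -> function of the four
# intensity rasters I0, I45, I90, I135).
.fpm_registry <- new.env(parent = emptyenv())

#' Register a custom per-pixel FPM statistic
#'
#' The supplied function receives the four intensity rasters (matrices for
#' the 0, 45, 90 and 135 degree polarizations) and must return a raster of
#' the same dimensions. Every subsequent [compute_pixel_maps()] call attaches
#' the statistic's raster under `maps$custom[[name]]`, and
#' [extract_features()] reports its per-object mean as a `custom_<name>`
#' column.
#'
#' @param name unique identifier (used in file and column names).
#' @param fn function `(I0, I45, I90, I135) -> matrix`.
#' @return The name, invisibly.
#' @examples
#' register_custom_statistic("total", function(I0, I45, I90, I135)
#'   I0 + I45 + I90 + I135)
#' clear_custom_statistics()
#' @export
register_custom_statistic <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", name))
    stopf("invalid statistic name '%s'", name)
  if (exists(name, envir = .fpm_registry, inherits = FALSE))
    stopf("a custom statistic named '%s' is already registered", name)
  assign(name, fn, envir = .fpm_registry)
  invisible(name)
}

#' List registered custom statistics
#' @return Character vector of names.
#' @export
list_custom_statistics <- function() sort(ls(.fpm_registry))

#' Remove all registered custom statistics
#' @return Invisibly, the names that were removed.
#' @export
clear_custom_statistics <- function() {
  nms <- ls(.fpm_registry)
  rm(list = nms, envir = .fpm_registry)
  invisible(nms)
}

#' Flat-field correction of an FPM stack
#'
#' For each polarization angle the flat-field images are averaged across the
#' supplied calibration stacks, the averaged flat is divided by its own mean
#' (so a uniform flat is a no-op and the intensity scale is preserved), and
#' the data image is divided pixelwise by the normalized flat. Output
#' intensities are clipped at 0.
#'
#' @param stack an [fpm_stack()].
#' @param flats a single [fpm_flat_stack()] or a list of them.
#' @return A corrected [fpm_stack()].
#' @export
flat_field_correct <- function(stack, flats) {
  stopifnot(inherits(stack, "fpm_stack"))
  if (inherits(flats, "fpm_flat_stack")) flats <- list(flats)
  if (!length(flats)) stopf("at least one flat-field stack is required")
  d <- stack_dim(stack)
  for (f in flats) {
    if (!inherits(f, "fpm_flat_stack")) stopf("flats must be fpm_flat_stack objects")
    if (!identical(dim(f$images[[1L]]), d))
      stopf("flat-field dimensions do not match the data stack")
  }
  corrected <- vector("list", 4L)
  for (a in 1:4) {
    avg <- Reduce(`+`, lapply(flats, function(f) f$images[[a]])) / length(flats)
    norm <- avg / mean(avg)
    if (any(!is.finite(norm)) || any(norm <= 0))
      stopf("normalized flat field contains nonpositive values (angle %d)",
            c(0, 45, 90, 135)[a])
    corrected[[a]] <- pmax(stack$images[[a]] / norm, 0)
  }
  fpm_stack(corrected, pixel_size = stack$pixel_size,
            name = stack$name)
}

#' Compute pixelwise FPM maps (S0, S1, S2, order, azimuth)
#'
#' From the four polarization-resolved intensities the Stokes-like parameters
#' are computed pixelwise:
#' \deqn{S_0 = (I_0 + I_{45} + I_{90} + I_{135})/2,\quad
#'       S_1 = I_0 - I_{90},\quad S_2 = I_{45} - I_{135}}
#' The orientational order is \eqn{p = \sqrt{S_1^2 + S_2^2} / S_0} (undefined,
#' NaN, where \eqn{S_0 = 0}; not clipped above 1, since noise can push it
#' there and clipping would bias signal-to-background analyses) and the
#' azimuth is \eqn{\alpha = \mathrm{atan2}(S_2, S_1)/2}, wrapped to
#' \eqn{[-\pi/2, \pi/2)} and undefined (NaN) where \eqn{S_1 = S_2 = 0},
#' because 0 is a valid direction and must remain distinguishable.
#'
#' @param stack an [fpm_stack()].
#' @return An object of class `fpm_pixel_maps`: list with matrices `S0`,
#'   `S1`, `S2`, `order`, `azimuth` (radians, axial) and `custom` (named list
#'   of rasters for registered custom statistics).
#' @examples
#' img <- function(v) matrix(v, 2, 2)
#' st <- fpm_stack(list(img(2), img(1), img(0), img(1)))
#' m <- compute_pixel_maps(st)
#' m$order[1, 1]    # 1
#' m$azimuth[1, 1]  # 0
#' @export
compute_pixel_maps <- function(stack) {
  stopifnot(inherits(stack, "fpm_stack"))
  I0 <- stack$images[[1L]]; I45 <- stack$images[[2L]]
  I90 <- stack$images[[3L]]; I135 <- stack$images[[4L]]
  S0 <- (I0 + I45 + I90 + I135) / 2
  S1 <- I0 - I90
  S2 <- I45 - I135
  p <- sqrt(S1^2 + S2^2) / S0
  p[S0 == 0] <- NaN
  a <- wrap_axial_rad(atan2(S2, S1) / 2)
  a[S1 == 0 & S2 == 0] <- NaN
  custom <- list()
  for (nm in list_custom_statistics()) {
    fn <- get(nm, envir = .fpm_registry)
    r <- fn(I0, I45, I90, I135)
    if (!identical(dim(r), dim(I0)))
      stopf("custom statistic '%s' returned wrong dimensions", nm)
    custom[[nm]] <- r
  }
  structure(list(S0 = S0, S1 = S1, S2 = S2, order = p, azimuth = a,
                 custom = custom),
            class = "fpm_pixel_maps")
}

#' @export
print.fpm_pixel_maps <- function(x, ...) {
  d <- dim(x$S0)
  cat(sprintf("<fpm_pixel_maps> %d x %d px; mean order %.3f; %d custom statistic(s)\n",
              d[1L], d[2L], mean(x$order, na.rm = TRUE), length(x$custom)))
  invisible(x)
}

#' Least-squares sinusoid fit for one pixel's polarization response
#'
#' Fits \eqn{I(\omega) = a + b \cos 2(\omega - \phi)} to the four measured
#' intensities by least squares. For the equally spaced design
#' (0/45/90/135 degrees) the normal equations decouple and the solution has
#' the closed form \eqn{a = S_0/2}, \eqn{b = \sqrt{S_1^2 + S_2^2}/2},
#' \eqn{\phi = \mathrm{atan2}(S_2, S_1)/2} — identical to the pixel-map
#' expressions. `b >= 0` is enforced by phase wrapping; in the degenerate
#' unmodulated case (`b = 0`) the phase is reported as 0 by convention.
#'
#' @param intensities numeric vector of 4 finite intensities
#'   (I0, I45, I90, I135).
#' @param angles polarization angles in degrees; must be `c(0, 45, 90, 135)`.
#' @return List with `offset` (a), `amplitude` (b >= 0), `phase` (radians in
#'   `[-pi/2, pi/2)`), `rss` (residual sum of squares over the 4 points).
#' @examples
#' fit_pixel_sinusoid(c(2, 1, 0, 1))  # a = 1, b = 1, phase = 0, rss = 0
#' @export
fit_pixel_sinusoid <- function(intensities, angles = c(0, 45, 90, 135)) {
  if (length(intensities) != 4L || any(!is.finite(intensities)))
    stopf("exactly 4 finite intensities are required")
  if (!isTRUE(all.equal(as.numeric(angles), c(0, 45, 90, 135))))
    stopf("angles must be 0, 45, 90, 135 degrees")
  S0 <- sum(intensities) / 2
  S1 <- intensities[1L] - intensities[3L]
  S2 <- intensities[2L] - intensities[4L]
  a <- S0 / 2
  b <- sqrt(S1^2 + S2^2) / 2
  phi <- if (b == 0) 0 else wrap_axial_rad(atan2(S2, S1) / 2)
  w <- deg2rad(c(0, 45, 90, 135))
  fitted <- a + b * cos(2 * (w - phi))
  rss <- sum((intensities - fitted)^2)
  list(offset = a, amplitude = b, phase = phi, rss = rss)
}
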