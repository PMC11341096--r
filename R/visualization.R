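# Composite image outputs: order-intensity overlay, azimuth-order-intensity
# HSV, azimuth stick overlays, and axial polar histograms.

# Normalize a raster to [0, 1] between percentile bounds.
normalize_percentile <- function(m, bounds = c(0.1, 99.9)) {
  stopifnot(length(bounds) == 2L, bounds[1L] < bounds[2L],
            all(bounds >= 0), all(bounds <= 100))
  v <- m[is.finite(m)]
  if (!length(v)) return(matrix(0, nrow(m), ncol(m)))
  lo <- quantile(v, bounds[1L] / 100, names = FALSE)
  hi <- quantile(v, bounds[2L] / 100, names = FALSE)
  if (hi <= lo) {
    # constant raster: render at full scale rather than black
    out <- matrix(as.numeric(m >= lo), nrow(m), ncol(m))
    out[!is.finite(m)] <- 0
    return(out)
  }
  out <- (m - lo) / (hi - lo)
  out[!is.finite(out)] <- 0
  pmin(pmax(out, 0), 1)
}

#' Order-intensity overlay
#'
#' Colormaps the order after clipping to the given percentile bounds and
#' uses the normalized average intensity as the alpha (opacity) channel, so
#' dim pixels fade out. Returns an RGBA array; optionally writes a PNG.
#'
#' @param maps an `fpm_pixel_maps`.
#' @param order_bounds,intensity_bounds percentile bounds `c(lo, hi)` in
#'   `[0, 100]`.
#' @param colormap an `hcl.colors` palette name (default `"viridis"`).
#' @param path optional PNG output path.
#' @return `nrow x ncol x 4` array in `[0, 1]` (invisibly when `path` is
#'   given).
#' @export
render_order_intensity <- function(maps, order_bounds = c(0.1, 99.9),
                                   intensity_bounds = c(0.1, 99.9),
                                   colormap = "viridis", path = NULL) {
  stopifnot(inherits(maps, "fpm_pixel_maps"))
  ord <- normalize_percentile(maps$order, order_bounds)
  alpha <- normalize_percentile(maps$S0, intensity_bounds)
  pal <- hcl.colors(256L, colormap)
  idx <- pmin(floor(ord * 255) + 1L, 256L)
  rgb <- col2rgb(pal[idx]) / 255
  out <- array(0, c(nrow(ord), ncol(ord), 4L))
  out[, , 1L] <- matrix(rgb[1L, ], nrow(ord))
  out[, , 2L] <- matrix(rgb[2L, ], nrow(ord))
  out[, , 3L] <- matrix(rgb[3L, ], nrow(ord))
  out[, , 4L] <- alpha
  if (!is.null(path)) { png::writePNG(out, path); return(invisible(out)) }
  out
}

#' Azimuth-order-intensity HSV composite
#'
#' Hue encodes the azimuth (axial, cyclic with period 180 degrees; azimuth 0
#' maps to hue 0), saturation the order clipped to `[0, 1]`, and value the
#' normalized average intensity. Pixels with undefined azimuth are rendered
#' with saturation 0 (gray).
#'
#' @inheritParams render_order_intensity
#' @return `nrow x ncol x 3` RGB array in `[0, 1]`.
#' @export
render_azimuth_hsv <- function(maps, intensity_bounds = c(0.1, 99.9),
                               path = NULL) {
  stopifnot(inherits(maps, "fpm_pixel_maps"))
  a <- wrap_axial_deg(rad2deg(maps$azimuth))
  hue <- a / 180
  sat <- pmin(pmax(maps$order, 0), 1)
  undef <- is.na(hue) | is.na(sat)
  hue[undef] <- 0; sat[is.na(maps$azimuth)] <- 0; sat[is.na(sat)] <- 0
  val <- normalize_percentile(maps$S0, intensity_bounds)
  cols <- hsv(h = pmin(as.numeric(hue), 1 - 1e-9), s = as.numeric(sat),
              v = as.numeric(val))
  rgb <- col2rgb(cols) / 255
  out <- array(0, c(nrow(a), ncol(a), 3L))
  out[, , 1L] <- matrix(rgb[1L, ], nrow(a))
  out[, , 2L] <- matrix(rgb[2L, ], nrow(a))
  out[, , 3L] <- matrix(rgb[3L, ], nrow(a))
  if (!is.null(path)) { png::writePNG(out, path); return(invisible(out)) }
  out
}

#' Azimuth stick overlay
#'
#' One centered line segment per sampled object pixel (every
#' `stick_spacing`-th row/column), oriented at the pixel azimuth with length
#' `stick_length` px, colored by an axial-cyclic map of either the image
#' azimuth or the midline-relative azimuth. Returns the stick table; when
#' `path` is given, also draws the sticks over the intensity image into a
#' PNG.
#'
#' @param maps an `fpm_pixel_maps`.
#' @param segmentation an `fpm_segmentation` (sticks are drawn on object
#'   pixels only).
#' @param objects optional object table carrying midlines (attribute
#'   `"midlines"`), required for `color_by = "alpha_midline"`.
#' @param stick_spacing sampling grid spacing, px.
#' @param stick_length stick length, px.
#' @param color_by `"alpha_image"` or `"alpha_midline"`.
#' @param path optional PNG output path.
#' @return Data frame with columns `x, y, angle_deg, color_angle_deg`
#'   (one row per stick).
#' @export
render_azimuth_sticks <- function(maps, segmentation, objects = NULL,
                                  stick_spacing = 3L, stick_length = 3,
                                  color_by = c("alpha_image", "alpha_midline"),
                                  path = NULL) {
  stopifnot(inherits(maps, "fpm_pixel_maps"),
            inherits(segmentation, "fpm_segmentation"))
  color_by <- match.arg(color_by)
  lab <- segmentation$labels
  nr <- nrow(lab); nc <- ncol(lab)
  grid_keep <- (row(lab) %% stick_spacing == 0L) &
    (col(lab) %% stick_spacing == 0L)
  sel <- which(segmentation$mask & grid_keep & !is.na(maps$azimuth))
  if (!length(sel))
    return(data.frame(x = numeric(0), y = numeric(0),
                      angle_deg = numeric(0), color_angle_deg = numeric(0)))
  rc <- arrayInd(sel, dim(lab))
  ang <- wrap_axial_deg(rad2deg(maps$azimuth[sel]))
  col_ang <- ang
  if (color_by == "alpha_midline") {
    if (is.null(objects)) stopf("objects with midlines required for alpha_midline")
    mls <- attr(objects, "midlines")
    col_ang <- rep(NA_real_, length(sel))
    for (k in unique(lab[sel])) {
      ml <- if (k <= length(mls)) mls[[k]] else NULL
      if (is.null(ml) || !isTRUE(ml$valid)) next
      here <- which(lab[sel] == k)
      tg <- assign_tangents(sel[here], ml, dim = dim(lab))
      col_ang[here] <- relative_azimuth(ang[here], tg)
    }
    keep <- !is.na(col_ang)
    rc <- rc[keep, , drop = FALSE]; ang <- ang[keep]; col_ang <- col_ang[keep]
  }
  out <- data.frame(x = rc[, 2L], y = rc[, 1L], angle_deg = ang,
                    color_angle_deg = col_ang)
  if (!is.null(path)) {
    png(path, width = nc * 4L, height = nr * 4L)
    op <- par(mar = c(0, 0, 0, 0))
    on.exit({ par(op); dev.off() })
    plot.new()
    plot.window(xlim = c(0.5, nc + 0.5), ylim = c(nr + 0.5, 0.5),
                xaxs = "i", yaxs = "i", asp = 1)
    img <- normalize_percentile(maps$S0)
    graphics::rasterImage(grDevices::as.raster(img), 0.5, nr + 0.5, nc + 0.5, 0.5)
    h <- stick_length / 2
    th <- deg2rad(out$color_angle_deg)
    cols <- hsv(out$color_angle_deg / 180, 1, 1)
    # axial direction: dy is negative in raster coords for positive angles
    segments(out$x - h * cos(deg2rad(out$angle_deg)),
             out$y + h * sin(deg2rad(out$angle_deg)),
             out$x + h * cos(deg2rad(out$angle_deg)),
             out$y - h * sin(deg2rad(out$angle_deg)),
             col = cols, lwd = 2)
  }
  out
}

#' Axial polar histogram plot
#'
#' Draws the 180-degree-duplicated polar histogram of an axial sample
#' ([axial_histogram()]) as a polar bar plot; the figure is symmetric under
#' 180-degree rotation by construction.
#'
#' @param angles_deg axial angles in degrees.
#' @param n_bins even number of bins over `[0, 360)`.
#' @param path PNG output path.
#' @return The histogram (list of `counts`, `breaks_deg`, `mid_deg`),
#'   invisibly.
#' @export
render_axial_polar_histogram <- function(angles_deg, n_bins = 24L, path) {
  h <- axial_histogram(angles_deg, n_bins)
  rmax <- max(h$counts, 1)
  png(path, width = 600, height = 600)
  op <- par(mar = c(1, 1, 1, 1))
  on.exit({ par(op); dev.off() })
  plot.new()
  plot.window(xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1)
  for (ring in seq(0.25, 1, 0.25)) {
    th <- seq(0, 2 * pi, length.out = 181L)
    lines(ring * cos(th), ring * sin(th), col = "gray85")
  }
  for (i in seq_along(h$counts)) {
    if (h$counts[i] == 0) next
    r <- h$counts[i] / rmax
    th <- seq(deg2rad(h$breaks_deg[i]), deg2rad(h$breaks_deg[i + 1L]),
              length.out = 20L)
    polygon(c(0, r * cos(th), 0), c(0, r * sin(th), 0),
            col = "steelblue3", border = "white")
  }
  invisible(h)
}
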