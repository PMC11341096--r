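# Synthetic FPM scenes with per-pixel ground truth.
#
# The forward model realizes the polarization-modulated intensity
#   I_w = Bg + A * (1 + p_true * cos 2(w - alpha_true)) / 2
# at the four excitation angles w in {0, 45, 90, 135} degrees, followed by
# optional Gaussian (PSF) blur and then detection noise. With this
# parameterization the pipeline's recovered order equals the scene's p_true
# exactly wherever Bg = 0 (and the mean S0 over an object with amplitude A
# on background Bg is 2*Bg + A, so the constructed S/B is
# (2*Bg + A) / (2*Bg)).

new_scene <- function(dim, pixel_size, background, amplitude, order, azimuth,
                      psf_sigma, noise, seed, objects) {
  structure(list(dim = dim, pixel_size = pixel_size, background = background,
                 amplitude = amplitude, order = order, azimuth = azimuth,
                 psf_sigma = psf_sigma, noise = noise, seed = seed,
                 objects = objects),
            class = "fpm_scene")
}

#' @export
print.fpm_scene <- function(x, ...) {
  cat(sprintf("<fpm_scene> %d x %d px, %d object(s), background %.3g, noise %s\n",
              x$dim[1L], x$dim[2L], length(x$objects), x$background,
              x$noise$type))
  invisible(x)
}

#' Render a synthetic scene into an FPM stack
#'
#' Applies the forward model at the four polarization angles, then optional
#' Gaussian blur (optics), then noise (detection): `none`, `gaussian`
#' (additive, `sd = sigma`), or `poisson` (counts drawn as
#' `rpois(I / gain) * gain`). All randomness is driven by the scene seed, so
#' rendering is reproducible.
#'
#' @param scene an `fpm_scene` from one of the `make_*` generators.
#' @return An [fpm_stack()]; the scene itself is the ground-truth sidecar.
#' @export
render_stack <- function(scene) {
  stopifnot(inherits(scene, "fpm_scene"))
  p <- scene$order
  if (any(p < 0 | p > 1)) stopf("p_true outside [0, 1]")
  a <- scene$azimuth        # radians, defined everywhere (0 on background)
  A <- scene$amplitude
  pages <- lapply(deg2rad(c(0, 45, 90, 135)), function(w)
    scene$background + A * (1 + p * cos(2 * (w - a))) / 2)
  if (scene$psf_sigma > 0)
    pages <- lapply(pages, function(m) as.matrix(EBImage::gblur(m, sigma = scene$psf_sigma)))
  pages <- with_seed(scene$seed, {
    switch(scene$noise$type,
      none = pages,
      gaussian = lapply(pages, function(m)
        pmax(m + matrix(rnorm(length(m), sd = scene$noise$sigma), nrow(m)), 0)),
      poisson = {
        g <- if (is.null(scene$noise$gain)) 1 else scene$noise$gain
        lapply(pages, function(m)
          matrix(rpois(length(m), as.numeric(m) / g) * g, nrow(m)))
      },
      stopf("unknown noise model '%s'", scene$noise$type))
  })
  fpm_stack(pages, pixel_size = scene$pixel_size, name = "synthetic")
}

# ---- morphology generators -------------------------------------------------

#' Generate a field of punctate objects
#'
#' Plants `n` disc-shaped puncta of radius `radius` px with uniform order `p`
#' and (by default) random axial azimuths, at centers separated by at least
#' `min_sep` px (rejection sampling under the scene seed).
#'
#' @param dim raster dimensions `c(rows, cols)`.
#' @param n number of puncta.
#' @param radius disc radius, px.
#' @param amplitude signal amplitude A (photoelectrons).
#' @param background background level Bg.
#' @param p orientational order of the puncta, in `[0, 1]`.
#' @param azimuth `"random"` or a fixed axial angle in degrees.
#' @param min_sep minimum center separation, px.
#' @param pixel_size micrometres per pixel.
#' @param psf_sigma Gaussian blur sigma, px (0 = off).
#' @param noise list, e.g. `list(type = "poisson", gain = 1)`,
#'   `list(type = "gaussian", sigma = 5)` or `list(type = "none")`.
#' @param seed scene seed.
#' @return An `fpm_scene`; each element of `$objects` records the punctum
#'   center, radius, amplitude, azimuth and ground-truth pixel indices.
#' @export
make_puncta_field <- function(dim = c(128L, 128L), n = 30L, radius = 3,
                              amplitude = 90, background = 10, p = 0.7,
                              azimuth = "random", min_sep = 10,
                              pixel_size = 0.1, psf_sigma = 0,
                              noise = list(type = "none"), seed = 1L) {
  nr <- dim[1L]; nc <- dim[2L]
  margin <- radius + 3
  centers <- with_seed(seed, {
    acc <- matrix(numeric(0), 0L, 2L)
    tries <- 0L
    while (nrow(acc) < n && tries < 20000L) {
      tries <- tries + 1L
      cand <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
      if (nrow(acc) == 0L ||
          min(sqrt(rowSums(sweep(acc, 2L, cand)^2))) >= min_sep)
        acc <- rbind(acc, cand)
    }
    acc
  })
  if (nrow(centers) < n)
    stopf("could not place %d puncta with min_sep %.1f in a %dx%d frame",
          n, min_sep, nr, nc)
  azis <- with_seed(seed + 1L, {
    if (identical(azimuth, "random")) runif(n, 0, 180) else rep(azimuth, n)
  })
  A <- matrix(0, nr, nc)
  pmat <- matrix(0, nr, nc)
  amat <- matrix(0, nr, nc)
  rows <- row(A); cols <- col(A)
  objects <- vector("list", n)
  for (i in seq_len(n)) {
    d2 <- (rows - centers[i, 1L])^2 + (cols - centers[i, 2L])^2
    pix <- which(d2 <= radius^2)
    A[pix] <- amplitude
    pmat[pix] <- p
    amat[pix] <- deg2rad(wrap_axial_deg(azis[i])) # radians
    objects[[i]] <- list(type = "punctum", center = centers[i, ],
                         radius = radius, amplitude = amplitude,
                         azimuth_deg = wrap_axial_deg(azis[i]), pixels = pix)
  }
  new_scene(c(nr, nc), pixel_size, background, A, pmat,
            wrap_axial_rad(amat), psf_sigma, noise, seed, objects)
}

# Dense samples of an S-shaped parametric curve (one full sine period along
# its long axis), rotated and translated; returns samples and tangent angles.
sample_scurve <- function(length_px, amplitude_px, rotation_deg, center,
                          n_samples = 600L) {
  t <- seq(-0.5, 0.5, length.out = n_samples)
  x0 <- t * length_px
  y0 <- amplitude_px * sin(2 * pi * t)
  dx0 <- rep(length_px, n_samples)
  dy0 <- amplitude_px * 2 * pi * cos(2 * pi * t)
  th <- deg2rad(rotation_deg)
  # rotate anticlockwise by th in the y-up frame; raster y points down
  xu <- x0; yu <- y0
  xr <- xu * cos(th) - yu * sin(th)
  yr <- xu * sin(th) + yu * cos(th)
  dxr <- dx0 * cos(th) - dy0 * sin(th)
  dyr <- dx0 * sin(th) + dy0 * cos(th)
  pts <- cbind(x = center[2L] + xr, y = center[1L] - yr)  # y-down raster
  tang <- wrap_axial_deg(rad2deg(atan2(dyr, dxr)))
  list(points = pts, tangent_deg = tang)
}

# Basic self-intersection test on a subsampled polyline.
polyline_self_intersects <- function(pts, skip = 4L) {
  idx <- seq(1L, nrow(pts), by = 4L)
  p <- pts[idx, , drop = FALSE]
  n <- nrow(p) - 1L
  seg_int <- function(a1, a2, b1, b2) {
    d1 <- (a2 - a1); d2 <- (b2 - b1)
    den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((b1[1L] - a1[1L]) * d2[2L] - (b1[2L] - a1[2L]) * d2[1L]) / den
    u <- ((b1[1L] - a1[1L]) * d1[2L] - (b1[2L] - a1[2L]) * d1[1L]) / den
    t > 0 && t < 1 && u > 0 && u < 1
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i + skip) next
    if (seg_int(p[i, ], p[i + 1L, ], p[j, ], p[j + 1L, ])) return(TRUE)
  }
  FALSE
}

# Rasterize a flat-capped ribbon around a sampled curve: pixels within
# width/2 of the curve, clipped at the ends by projection onto the end
# tangents (so the ribbon terminates flush with the curve endpoints and the
# generating curve coincides with the full-length ribbon centerline).
ribbon_pixels <- function(samples, width, dim) {
  pts <- samples$points
  nr <- dim[1L]; nc <- dim[2L]
  half <- width / 2
  bb_r <- pmax(1L, floor(min(pts[, 2L]) - half - 1)):pmin(nr, ceiling(max(pts[, 2L]) + half + 1))
  bb_c <- pmax(1L, floor(min(pts[, 1L]) - half - 1)):pmin(nc, ceiling(max(pts[, 1L]) + half + 1))
  grid <- expand.grid(y = bb_r, x = bb_c)
  gx <- grid$x; gy <- grid$y
  npix <- length(gx)
  best <- rep(Inf, npix); nearest <- rep(1L, npix)
  for (j in seq_len(nrow(pts))) {
    d2 <- (gx - pts[j, 1L])^2 + (gy - pts[j, 2L])^2
    upd <- d2 < best
    best[upd] <- d2[upd]; nearest[upd] <- j
  }
  ok <- best <= half^2
  # flat caps: drop pixels projecting beyond the curve endpoints
  n <- nrow(pts)
  t1 <- pts[2L, ] - pts[1L, ]
  tn <- pts[n, ] - pts[n - 1L, ]
  at_start <- nearest == 1L
  at_end <- nearest == n
  v1 <- cbind(gx - pts[1L, 1L], gy - pts[1L, 2L])
  vn <- cbind(gx - pts[n, 1L], gy - pts[n, 2L])
  ok[at_start & (v1[, 1L] * t1[1L] + v1[, 2L] * t1[2L]) < 0] <- FALSE
  ok[at_end & (vn[, 1L] * tn[1L] + vn[, 2L] * tn[2L]) > 0] <- FALSE
  list(pixels = (gx[ok] - 1L) * nr + gy[ok],   # column-major raster index
       nearest = nearest[ok])
}

#' Generate an S-shaped curvilinear object
#'
#' Draws a flat-capped ribbon of width `width` px around an S-shaped
#' parametric curve (a full sine period along the object's long axis). The
#' dipole rule sets the ground-truth azimuth at each pixel from the tangent
#' of the nearest curve point: `"parallel"` (azimuth = tangent), `"normal"`
#' (tangent + 90, so the true midline-relative azimuth is 90 degrees by
#' construction), or a fixed axial angle in degrees.
#'
#' @param dim raster dimensions.
#' @param length_px end-to-end extent of the curve's long axis, px.
#' @param wave_amplitude_px transverse amplitude of the S, px.
#' @param width ribbon width, px.
#' @param rotation_deg in-plane rotation of the whole object.
#' @param center object center `c(row, col)`; default frame center.
#' @param amplitude,background,p,pixel_size,psf_sigma,noise,seed as in
#'   [make_puncta_field()].
#' @param dipole `"normal"`, `"parallel"`, or a fixed angle in degrees.
#' @return An `fpm_scene`; `$objects[[1]]` records the generating curve
#'   (`centerline`, x/y px), its arc length, and the ground-truth pixel set.
#' @export
make_sshape_scene <- function(dim = c(96L, 96L), length_px = 48,
                              wave_amplitude_px = 10, width = 5,
                              rotation_deg = 0, center = NULL,
                              amplitude = 200, background = 5, p = 0.8,
                              dipole = "normal", pixel_size = 0.1,
                              psf_sigma = 0, noise = list(type = "none"),
                              seed = 1L) {
  if (is.null(center)) center <- dim / 2
  sam <- sample_scurve(length_px, wave_amplitude_px, rotation_deg, center)
  if (polyline_self_intersects(sam$points))
    stopf("generating curve is self-intersecting")
  if (any(sam$points[, 1L] < 2 | sam$points[, 1L] > dim[2L] - 1 |
          sam$points[, 2L] < 2 | sam$points[, 2L] > dim[1L] - 1))
    stopf("curve exceeds the frame; enlarge dim or shrink length_px")
  rb <- ribbon_pixels(sam, width, dim)
  A <- matrix(0, dim[1L], dim[2L])
  pmat <- matrix(0, dim[1L], dim[2L])
  amat <- matrix(0, dim[1L], dim[2L])
  A[rb$pixels] <- amplitude
  pmat[rb$pixels] <- p
  tang <- sam$tangent_deg[rb$nearest]
  truth_deg <- if (identical(dipole, "normal")) tang + 90
    else if (identical(dipole, "parallel")) tang
    else rep(as.numeric(dipole), length(tang))
  amat[rb$pixels] <- deg2rad(wrap_axial_deg(truth_deg))
  objects <- list(list(type = "sshape", centerline = sam$points,
                       tangent_deg = sam$tangent_deg,
                       curve_length_px = polyline_length(sam$points),
                       width = width, dipole = dipole, pixels = rb$pixels))
  new_scene(dim, pixel_size, background, A, pmat, wrap_axial_rad(amat),
            psf_sigma, noise, seed, objects)
}

#' Generate a field of straight filaments with known lengths
#'
#' Places one straight, flat-capped filament per requested length at random
#' non-overlapping positions and orientations (rejection sampling under the
#' scene seed). Dipoles are parallel to the filament by default, matching
#' phalloidin-labeled F-actin where absorption is polarized along the
#' filament axis.
#'
#' @param dim raster dimensions.
#' @param lengths_um planted filament lengths, micrometres.
#' @param width filament width, px.
#' @param min_sep minimum distance between filaments, px.
#' @param dipole `"parallel"`, `"normal"`, or a fixed axial angle (degrees).
#' @param amplitude,background,p,pixel_size,psf_sigma,noise,seed as in
#'   [make_puncta_field()].
#' @return An `fpm_scene`; each `$objects[[i]]` records the centerline, the
#'   planted `length_um`, and the ground-truth pixel set.
#' @export
make_filament_scene <- function(dim = c(256L, 256L), lengths_um = c(10, 25),
                                width = 4, min_sep = 12, dipole = "parallel",
                                amplitude = 150, background = 5, p = 0.8,
                                pixel_size = 0.2, psf_sigma = 0,
                                noise = list(type = "none"), seed = 1L) {
  nr <- dim[1L]; nc <- dim[2L]
  lengths_px <- lengths_um / pixel_size
  margin <- width + 4
  placed <- with_seed(seed, {
    out <- list()
    for (L in lengths_px) {
      ok <- FALSE
      for (try in seq_len(5000L)) {
        th <- runif(1, 0, pi)
        dx <- cos(th) * L / 2; dyu <- sin(th) * L / 2
        cy <- runif(1, margin + abs(dyu), nr - margin - abs(dyu))
        cx <- runif(1, margin + abs(dx), nc - margin - abs(dx))
        ns <- max(16L, ceiling(L / 2))
        t <- seq(-1, 1, length.out = ns)
        pts <- cbind(x = cx + t * dx, y = cy - t * dyu)
        clear <- TRUE
        for (o in out) {
          dmin <- min(outer(pts[, 1L], o$pts[, 1L], `-`)^2 +
                      outer(pts[, 2L], o$pts[, 2L], `-`)^2)
          if (sqrt(dmin) < min_sep) { clear <- FALSE; break }
        }
        if (clear) { out[[length(out) + 1L]] <- list(pts = pts, theta = th, L = L); ok <- TRUE; break }
      }
      if (!ok) stopf("could not place a %.1f px filament; enlarge dim", L)
    }
    out
  })
  A <- matrix(0, nr, nc); pmat <- matrix(0, nr, nc); amat <- matrix(0, nr, nc)
  objects <- vector("list", length(placed))
  for (i in seq_along(placed)) {
    pl <- placed[[i]]
    dense <- resample_polyline(pl$pts, 0.3)
    rb <- ribbon_pixels(list(points = dense), width, dim)
    A[rb$pixels] <- amplitude
    pmat[rb$pixels] <- p
    tang_deg <- wrap_axial_deg(rad2deg(pl$theta))
    truth_deg <- if (identical(dipole, "parallel")) tang_deg
      else if (identical(dipole, "normal")) tang_deg + 90
      else as.numeric(dipole)
    amat[rb$pixels] <- deg2rad(wrap_axial_deg(truth_deg))
    objects[[i]] <- list(type = "filament", centerline = pl$pts,
                         length_um = lengths_um[i],
                         length_px = pl$L, angle_deg = tang_deg,
                         width = width, pixels = rb$pixels)
  }
  new_scene(dim, pixel_size, background, A, pmat, wrap_axial_rad(amat),
            psf_sigma, noise, seed, objects)
}

#' Write a scene's ground truth to disk
#'
#' Truth rasters (`order`, `azimuth` in radians, `amplitude`) as float32
#' TIFFs and an object table (id, type, length where applicable) as CSV.
#'
#' @param scene an `fpm_scene`.
#' @param directory output directory.
#' @return Named character vector of written paths.
#' @export
write_scene_sidecar <- function(scene, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  out <- c(order = file.path(directory, "truth_order.tif"),
           azimuth = file.path(directory, "truth_azimuth.tif"),
           amplitude = file.path(directory, "truth_amplitude.tif"),
           objects = file.path(directory, "ground_truth.csv"))
  write_float_tiff(scene$order, out[["order"]])
  write_float_tiff(scene$azimuth, out[["azimuth"]])
  write_float_tiff(scene$amplitude, out[["amplitude"]])
  df <- data.frame(
    object_id = seq_along(scene$objects),
    type = vapply(scene$objects, function(o) o$type, character(1L)),
    n_pixels = vapply(scene$objects, function(o) length(o$pixels), numeric(1L)),
    length_um = vapply(scene$objects, function(o)
      if (!is.null(o$length_um)) o$length_um else NA_real_, numeric(1L)))
  write.csv(df, out[["objects"]], row.names = FALSE)
  out
}
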