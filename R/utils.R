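# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Axial angle (degrees in [0, 180)) of a displacement given in raster
# coordinates (dx = dcol, drow positive downward).
axial_angle_deg <- function(dx, drow) {
  a <- atan2(-drow, dx) * 180 / pi
  a %% 180
}

wrap_axial_deg <- function(a) a %% 180

# Wrap radians to [-pi/2, pi/2).
wrap_axial_rad <- function(a) {
  a <- (a + pi / 2) %% pi - pi / 2
  a[a >= pi / 2] <- -pi / 2
  a
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Disc structuring element of integer radius r (EBImage brush).
disc_brush <- function(r) {
  r <- as.integer(round(r))
  if (r < 1L) return(matrix(1L, 1L, 1L))
  EBImage::makeBrush(2L * r + 1L, shape = "disc")
}

# Binary dilation of a logical matrix by a disc of radius r.
dilate_mask <- function(mask, r) {
  if (r < 1) return(mask)
  m <- EBImage::dilate(matrix(as.numeric(mask), nrow(mask)), disc_brush(r))
  matrix(as.logical(m > 0.5), nrow(mask))
}

erode_mask <- function(mask, r) {
  if (r < 1) return(mask)
  m <- EBImage::erode(matrix(as.numeric(mask), nrow(mask)), disc_brush(r))
  matrix(as.logical(m > 0.5), nrow(mask))
}

# Moving average with circular (closed-curve) or truncated (open-curve)
# boundary handling; w is forced odd.
moving_average <- function(x, w, circular = FALSE) {
  n <- length(x)
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L || n < 3L) return(x)
  h <- (w - 1L) %/% 2L
  if (circular) {
    xp <- c(tail(x, h), x, head(x, h))
    out <- stats::filter(xp, rep(1 / w, w), sides = 2)
    as.numeric(out[(h + 1L):(h + n)])
  } else {
    # truncated window near the ends
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1L, i - h):min(n, i + h)
      out[i] <- mean(x[j])
    }
    out
  }
}

# Cumulative arc length of a polyline given as an n x 2 matrix.
polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# Resample a polyline at (approximately) uniform arc-length spacing.
resample_polyline <- function(pts, spacing, closed = FALSE) {
  if (closed) pts <- rbind(pts, pts[1L, , drop = FALSE])
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= 0) return(pts[1L, , drop = FALSE])
  n_out <- max(2L, as.integer(round(L / spacing)) + ifelse(closed, 0L, 1L))
  si <- seq(0, L, length.out = ifelse(closed, n_out + 1L, n_out))
  if (closed) si <- si[-length(si)]
  cbind(approx(s, pts[, 1L], xout = si, ties = "ordered")$y,
        approx(s, pts[, 2L], xout = si, ties = "ordered")$y)
}

# Point-in-polygon for an n x 2 matrix of query points.
points_in_polygon <- function(pts, poly) {
  if (!all(poly[1L, ] == poly[nrow(poly), ]))
    poly <- rbind(poly, poly[1L, , drop = FALSE])
  mgcv::in.out(poly, pts)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
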