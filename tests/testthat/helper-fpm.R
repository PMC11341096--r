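# Shared helpers: oracles and fixture builders (everything generated in code).

# True float32 quantization (R's as.single keeps double precision).
float32 <- function(x) {
  con <- rawConnection(raw(0), "wb")
  writeBin(as.numeric(x), con, size = 4L, endian = "little")
  v <- rawConnectionValue(con); close(con)
  con <- rawConnection(v)
  out <- readBin(con, "numeric", length(x), size = 4L, endian = "little")
  close(con)
  if (is.matrix(x)) matrix(out, nrow(x)) else out
}

# Build a noiseless forward-model stack from parameter rasters.
forward_stack <- function(A, p, alpha_rad, background = 0, pixel_size = 0.1) {
  pages <- lapply(c(0, 45, 90, 135) * pi / 180, function(w)
    background + A * (1 + p * cos(2 * (w - alpha_rad))) / 2)
  fpm_stack(pages, pixel_size = pixel_size)
}

# Symmetric Hausdorff distance between two point sets (n x 2 matrices).
hausdorff <- function(a, b) {
  d <- function(p, q) max(apply(p, 1L, function(x)
    min(sqrt((q[, 1L] - x[1L])^2 + (q[, 2L] - x[2L])^2))))
  max(d(a, b), d(b, a))
}

# Axial-mean oracle: 0.1-degree grid search minimizing the circular
# dispersion of the doubled angles.
axial_mean_grid_oracle <- function(angles_deg) {
  grid <- seq(0, 179.9, by = 0.1)
  th2 <- 2 * angles_deg * pi / 180
  disp <- vapply(grid, function(m)
    sum(1 - cos(th2 - 2 * m * pi / 180)), numeric(1L))
  grid[which.min(disp)]
}

# Otsu oracle: exhaustive search over the 256-bin cut points minimizing the
# count-weighted intra-class variance of the bin midpoints.
otsu_brute_oracle <- function(values) {
  rng <- range(values)
  nb <- 256L
  breaks <- seq(rng[1L], rng[2L], length.out = nb + 1L)
  idx <- pmin(floor((values - rng[1L]) / diff(rng) * nb) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  mids <- (breaks[-1L] + breaks[-(nb + 1L)]) / 2
  best_k <- NA_integer_; best_v <- Inf
  for (k in seq_len(nb - 1L)) {
    c0 <- counts[1:k]; c1 <- counts[(k + 1L):nb]
    m0 <- mids[1:k]; m1 <- mids[(k + 1L):nb]
    n0 <- sum(c0); n1 <- sum(c1)
    v0 <- if (n0 > 0) sum(c0 * (m0 - sum(c0 * m0) / n0)^2) else 0
    v1 <- if (n1 > 0) sum(c1 * (m1 - sum(c1 * m1) / n1)^2) else 0
    v <- v0 + v1
    if (v < best_v - 1e-12) { best_v <- v; best_k <- k }
  }
  breaks[best_k + 1L]
}

# Exhaustive best 1-D 2-means split by within-cluster sum of squares.
kmeans1d_oracle <- function(x) {
  xs <- sort(x)
  best <- Inf; assign <- NULL
  for (k in seq_len(length(xs) - 1L)) {
    a <- xs[1:k]; b <- xs[(k + 1L):length(xs)]
    w <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (w < best) { best <- w; cut <- (xs[k] + xs[k + 1L]) / 2 }
  }
  list(wss = best, cut = cut)
}

# Disc mask helper.
disc_mask <- function(dim, center, radius) {
  m <- matrix(FALSE, dim[1L], dim[2L])
  m[(row(m) - center[1L])^2 + (col(m) - center[2L])^2 <= radius^2] <- TRUE
  m
}

# Any two open polyline segments (excluding shared endpoints) intersect?
polygon_is_simple <- function(pts) {
  pts <- rbind(pts, pts[1L, , drop = FALSE])
  n <- nrow(pts) - 1L
  seg_int <- function(a1, a2, b1, b2) {
    d1 <- a2 - a1; d2 <- b2 - b1
    den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((b1[1L] - a1[1L]) * d2[2L] - (b1[2L] - a1[2L]) * d2[1L]) / den
    u <- ((b1[1L] - a1[1L]) * d1[2L] - (b1[2L] - a1[2L]) * d1[1L]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i + 1L || (i == 1L && j == n)) next
    if (seg_int(pts[i, ], pts[i + 1L, ], pts[j, ], pts[j + 1L, ]))
      return(FALSE)
  }
  TRUE
}
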