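# Mask construction and object labeling: the "puncta" scheme (morphological
# preprocessing + Otsu threshold + connected components) and the "filaments"
# scheme (multiscale ridge enhancement + skeletonization + branch splitting),
# plus programmatic mask editing. All labeling is 8-connected.

#' Otsu threshold over a 256-bin histogram
#'
#' Returns the threshold maximizing the between-class variance of the
#' 256-bin histogram spanning the sample range (equivalently, minimizing the
#' intra-class variance). Ties are broken toward the lower threshold. The
#' result is invariant under affine rescaling of the sample up to the same
#' rescaling of the returned threshold.
#'
#' @param values numeric sample (at least 2 distinct finite values).
#' @return Threshold on the sample's intensity scale; pixels strictly above
#'   it form the foreground class.
#' @export
otsu_threshold <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2L) stopf("otsu_threshold: need at least 2 values")
  rng <- range(v)
  if (rng[1L] == rng[2L]) stopf("otsu_threshold: all values equal")
  nb <- 256L
  breaks <- seq(rng[1L], rng[2L], length.out = nb + 1L)
  idx <- pmin(floor((v - rng[1L]) / (rng[2L] - rng[1L]) * nb) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  mids <- (breaks[-1L] + breaks[-(nb + 1L)]) / 2
  n <- length(v)
  cw <- cumsum(counts)                    # class-0 counts at cut k
  cm <- cumsum(counts * mids)             # class-0 mass
  k <- seq_len(nb - 1L)
  w0 <- cw[k] / n
  w1 <- 1 - w0
  mu0 <- ifelse(cw[k] > 0, cm[k] / cw[k], 0)
  mu1 <- ifelse(cw[k] < n, (cm[nb] - cm[k]) / (n - cw[k]), 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  best <- which.max(bcv)                  # which.max takes the first maximum
  breaks[best + 1L]
}

# 8-connected labeling: EBImage::bwlabel (4-connected) followed by union-find
# merging of diagonally adjacent labels.
label_components <- function(mask) {
  mask <- mask != 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  lab <- matrix(as.integer(lab), nrow(mask))
  k <- max(lab)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  for (shift in list(c(1L, 1L), c(1L, -1L))) {
    dr <- shift[1L]; dc <- shift[2L]
    r1 <- seq_len(nr - 1L); c1 <- if (dc > 0) seq_len(nc - 1L) else 2:nc
    a <- lab[r1, c1, drop = FALSE]
    b <- lab[r1 + dr, c1 + dc, drop = FALSE]
    sel <- which(a > 0L & b > 0L & a != b)
    for (i in sel) union2(a[i], b[i])
  }
  roots <- vapply(seq_len(k), find, integer(1L))
  newid <- integer(k)
  newid[sort(unique(roots))] <- seq_along(unique(roots))
  lut <- c(0L, newid[roots])
  matrix(lut[lab + 1L], nr, nc)
}

new_segmentation <- function(mask, labels, scheme, params) {
  structure(list(mask = mask, labels = labels, scheme = scheme,
                 params = params),
            class = "fpm_segmentation")
}

#' @export
print.fpm_segmentation <- function(x, ...) {
  cat(sprintf("<fpm_segmentation scheme='%s'> %d object(s), %d mask px\n",
              x$scheme, max(x$labels), sum(x$mask)))
  invisible(x)
}

#' Segment punctate structures
#'
#' The "puncta" scheme for diffraction-limited spots and small curvilinear
#' structures: white-top-hat with a disc (suppresses background larger than
#' `tophat_radius`), Gaussian smoothing, a global Otsu threshold on the
#' 256-bin histogram, optional hole filling, removal of components smaller
#' than `min_area`, and 8-connected labeling. The chain is intensity-scale
#' invariant. A constant (zero-variance) image yields an empty result with a
#' warning rather than an error.
#'
#' @param S0 average-intensity raster (finite, nonnegative), typically
#'   `maps$S0`.
#' @param tophat_radius disc radius in px for the white top-hat (default 8,
#'   suited to diffraction-limited puncta at ~0.1 um/px).
#' @param smooth_sigma Gaussian sigma in px (default 1).
#' @param min_area minimum component area in px^2 (default 10).
#' @param fill_holes fill enclosed background holes (default TRUE).
#' @return An `fpm_segmentation`: `mask` (logical), `labels` (integer matrix,
#'   0 = background), `scheme`, `params`.
#' @export
segment_puncta <- function(S0, tophat_radius = 8, smooth_sigma = 1,
                           min_area = 10, fill_holes = TRUE) {
  stopifnot(is.matrix(S0), all(is.finite(S0)))
  params <- list(tophat_radius = tophat_radius, smooth_sigma = smooth_sigma,
                 min_area = min_area, fill_holes = fill_holes)
  empty <- function() new_segmentation(matrix(FALSE, nrow(S0), ncol(S0)),
                                       matrix(0L, nrow(S0), ncol(S0)),
                                       "puncta", params)
  if (diff(range(S0)) == 0) {
    warnf("segment_puncta: constant image, empty mask")
    return(empty())
  }
  img <- S0 / max(S0)
  th <- EBImage::whiteTopHat(img, disc_brush(tophat_radius))
  sm <- if (smooth_sigma > 0) as.matrix(EBImage::gblur(th, sigma = smooth_sigma)) else as.matrix(th)
  if (diff(range(sm)) == 0) {
    warnf("segment_puncta: flat image after preprocessing, empty mask")
    return(empty())
  }
  thr <- otsu_threshold(as.numeric(sm))
  mask <- sm > thr
  if (fill_holes)
    mask <- matrix(as.logical(EBImage::fillHull(matrix(as.numeric(mask), nrow(mask))) > 0.5),
                   nrow(mask))
  lab <- label_components(mask)
  lab <- drop_small_components(lab, min_area)
  new_segmentation(lab > 0L, lab, "puncta", params)
}

drop_small_components <- function(lab, min_area) {
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes >= min_area)
  lut <- integer(max(lab) + 1L)
  lut[keep + 1L] <- seq_along(keep)
  matrix(lut[lab + 1L], nrow(lab))
}

# Multiscale ridge enhancement: scale-normalized magnitude of the most
# negative Hessian eigenvalue (bright ridges), maximized over sigmas.
ridge_filter <- function(img, sigmas = c(1, 2, 3)) {
  out <- matrix(0, nrow(img), ncol(img))
  for (s in sigmas) {
    g <- as.matrix(EBImage::gblur(img, sigma = s))
    # central-difference second derivatives with replicated borders
    pad <- function(m, dr, dc) {
      nr <- nrow(m); nc <- ncol(m)
      m[pmin(pmax(seq_len(nr) + dr, 1L), nr), pmin(pmax(seq_len(nc) + dc, 1L), nc)]
    }
    Lrr <- pad(g, 1L, 0L) - 2 * g + pad(g, -1L, 0L)
    Lcc <- pad(g, 0L, 1L) - 2 * g + pad(g, 0L, -1L)
    Lrc <- (pad(g, 1L, 1L) - pad(g, 1L, -1L) - pad(g, -1L, 1L) + pad(g, -1L, -1L)) / 4
    disc <- sqrt(((Lrr - Lcc) / 2)^2 + Lrc^2)
    lam2 <- (Lrr + Lcc) / 2 - disc        # most negative eigenvalue
    resp <- s^2 * pmax(-lam2, 0)
    out <- pmax(out, resp)
  }
  out
}

# Zhang-Suen thinning of a logical mask to a 1-px-wide skeleton.
skeletonize_mask <- function(mask) {
  m <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask != 0
  shift <- function(x, dr, dc) {
    nr <- nrow(x); nc <- ncol(x)
    out <- matrix(FALSE, nr, nc)
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P2 <- shift(m, -1L, 0L); P3 <- shift(m, -1L, 1L); P4 <- shift(m, 0L, 1L)
      P5 <- shift(m, 1L, 1L);  P6 <- shift(m, 1L, 0L);  P7 <- shift(m, 1L, -1L)
      P8 <- shift(m, 0L, -1L); P9 <- shift(m, -1L, -1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
           (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      if (step == 1L) {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
}

# Number of distinct foreground runs around each pixel's 8-neighborhood
# ring (the crossing number): 1 for line ends and interior staircase pixels,
# 2 for straight interior pixels, >= 3 at true junctions. Robust against
# the 4-connected staircases thinning produces on oblique lines, where a
# plain neighbor count overestimates junctions.
ring_transitions8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m != 0
  ring <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
               c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  nbr <- lapply(ring, function(d)
    p[2:(nr + 1L) + d[1L], 2:(nc + 1L) + d[2L]])
  A <- matrix(0L, nr, nc)
  for (i in 1:8) {
    j <- if (i == 8L) 1L else i + 1L
    A <- A + (!nbr[[i]] & nbr[[j]])
  }
  A
}

# Reduce a thinned skeleton to a minimal 8-connected skeleton by
# sequentially removing 8-simple pixels: pixels with >= 2 neighbors whose
# punctured 3x3 neighborhood forms a single 8-connected component (removal
# cannot change topology). Eliminates the 4-connected staircases and small
# crossing blobs thinning leaves behind, which would otherwise defeat the
# crossing-number junction test.
reduce_skeleton8 <- function(m) {
  m <- m != 0
  nr <- nrow(m); nc <- ncol(m)
  offs <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  # adjacency between ring positions (8-connectivity in the grid)
  ring_adj <- abs(outer(offs[, 1L], offs[, 1L], `-`)) <= 1L &
              abs(outer(offs[, 2L], offs[, 2L], `-`)) <= 1L
  diag(ring_adj) <- FALSE
  n_components <- function(present) {
    ids <- which(present)
    if (!length(ids)) return(0L)
    parent <- seq_along(ids)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (a in seq_along(ids)) for (b in seq_along(ids)) {
      if (a < b && ring_adj[ids[a], ids[b]]) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
    length(unique(vapply(seq_along(ids), find, integer(1L))))
  }
  repeat {
    removed <- FALSE
    for (i in which(m)) {
      r <- ((i - 1L) %% nr) + 1L
      c <- ((i - 1L) %/% nr) + 1L
      present <- logical(8L)
      for (k in 1:8) {
        rr <- r + offs[k, 1L]; cc <- c + offs[k, 2L]
        present[k] <- rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && m[rr, cc]
      }
      if (sum(present) >= 2L && n_components(present) == 1L) {
        m[r, c] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  m
}

# Count of 8-neighbors within a logical matrix.
neighbor_count8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m != 0
  tot <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    tot <- tot + p[2:(nr + 1L) + dr, 2:(nc + 1L) + dc]
  }
  tot
}

#' Segment filamentous structures
#'
#' The "filaments" scheme for linear, extended structures: multiscale ridge
#' enhancement (scale-normalized largest-magnitude negative Hessian
#' eigenvalue across `ridge_sigmas`), thresholding at the `ridge_threshold`
#' quantile of the enhanced image, skeletonization, cutting the skeleton at
#' junction pixels (three or more skeleton arms, measured as the
#' 8-neighborhood crossing number), pruning branches shorter than
#' `min_branch_length`, and dilating each branch by `dilation_radius` to form
#' its object mask — one label per branch. Where dilated branches overlap,
#' pixels are assigned to the geodesically nearest branch.
#'
#' @param S0 average-intensity raster.
#' @param ridge_sigmas Gaussian scales in px (default `c(1, 2, 3)`).
#' @param ridge_threshold quantile of the enhanced image used as threshold
#'   (default 0.95).
#' @param ridge_floor minimum ridge response as a fraction of the maximum
#'   response (default 0.05); guards the quantile threshold on fields where
#'   ridges cover much less than `1 - ridge_threshold` of the pixels.
#' @param min_branch_length minimum branch size in skeleton px (default 10).
#' @param dilation_radius disc radius in px used to rebuild branch masks
#'   (default 2).
#' @return An `fpm_segmentation` whose `branches` field holds the per-branch
#'   skeleton pixel indices.
#' @export
segment_filaments <- function(S0, ridge_sigmas = c(1, 2, 3),
                              ridge_threshold = 0.95, ridge_floor = 0.05,
                              min_branch_length = 10, dilation_radius = 2) {
  stopifnot(is.matrix(S0), all(is.finite(S0)))
  params <- list(ridge_sigmas = ridge_sigmas, ridge_threshold = ridge_threshold,
                 ridge_floor = ridge_floor,
                 min_branch_length = min_branch_length,
                 dilation_radius = dilation_radius)
  empty <- function(msg) {
    warnf("segment_filaments: %s", msg)
    res <- new_segmentation(matrix(FALSE, nrow(S0), ncol(S0)),
                            matrix(0L, nrow(S0), ncol(S0)), "filaments", params)
    res$branches <- list()
    res
  }
  if (diff(range(S0)) == 0) return(empty("constant image, empty mask"))
  resp <- ridge_filter(S0 / max(S0), ridge_sigmas)
  thr <- quantile(resp, ridge_threshold, names = FALSE)
  # the quantile alone misbehaves when ridges cover much less of the field
  # than (1 - ridge_threshold): a magnitude floor keeps near-zero background
  # responses out of the mask regardless of ridge density
  ridge_mask <- resp > max(thr, ridge_floor * max(resp)) & resp > 0
  if (!any(ridge_mask)) return(empty("no ridges above threshold"))
  skel <- reduce_skeleton8(skeletonize_mask(ridge_mask))
  if (!any(skel)) return(empty("empty skeleton"))
  A <- ring_transitions8(skel)
  branches_mask <- skel & A < 3L           # cut at junction pixels
  blab <- label_components(branches_mask)
  blab <- drop_small_components(blab, min_branch_length)
  nbr <- max(blab)
  if (nbr == 0L) return(empty("no branches above minimum length"))
  # rebuild object masks by dilating each branch; resolve overlaps by
  # geodesic nearest-branch propagation, ties to the lower label
  union <- dilate_mask(blab > 0L, dilation_radius)
  seeds <- EBImage::Image(blab)
  lab <- EBImage::propagate(EBImage::Image(matrix(0, nrow(S0), ncol(S0))),
                            seeds, mask = EBImage::Image(union))
  lab <- matrix(as.integer(lab), nrow(S0))
  res <- new_segmentation(lab > 0L, lab, "filaments", params)
  res$branches <- lapply(seq_len(nbr), function(k) which(blab == k))
  res
}

#' Edit a segmentation mask programmatically
#'
#' `op = "remove-labels"`: removes the given object labels and compacts the
#' remaining labels to `1..k`. `op = "add-region"`: ORs a logical region into
#' the mask; labels are then recomputed as the 8-connected components of the
#' edited mask, so a region bridging two objects merges them.
#'
#' @param result an `fpm_segmentation`.
#' @param op `"add-region"` or `"remove-labels"`.
#' @param payload for `add-region`, a logical matrix matching the mask; for
#'   `remove-labels`, an integer vector of existing labels.
#' @return The edited `fpm_segmentation`.
#' @export
edit_mask <- function(result, op = c("add-region", "remove-labels"), payload) {
  stopifnot(inherits(result, "fpm_segmentation"))
  op <- match.arg(op)
  if (op == "remove-labels") {
    labs <- as.integer(payload)
    if (any(!labs %in% result$labels))
      stopf("unknown label(s): %s",
            paste(setdiff(labs, unique(as.integer(result$labels))), collapse = ", "))
    lab <- result$labels
    lab[lab %in% labs] <- 0L
    keep <- sort(unique(lab[lab > 0L]))
    lut <- integer(max(result$labels) + 1L)
    lut[keep + 1L] <- seq_along(keep)
    lab <- matrix(lut[lab + 1L], nrow(lab))
    new_segmentation(lab > 0L, lab, result$scheme, result$params)
  } else {
    region <- payload != 0
    if (!identical(dim(region), dim(result$mask)))
      stopf("region dimensions do not match the mask")
    mask <- result$mask | region
    lab <- label_components(mask)
    new_segmentation(mask, lab, result$scheme, result$params)
  }
}
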