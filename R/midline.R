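# Object midlines from Voronoi diagrams of boundary points, and
# midline-relative azimuths.
#
# The midline of an elongated object is extracted as follows: trace the
# 8-connected perimeter of the object mask; dilate, smooth and resample the
# boundary polygon; build the Voronoi diagram of the boundary points; keep
# the finite Voronoi edges whose endpoints lie strictly inside the boundary
# (the interior Voronoi graph, a discrete medial-axis approximation); prune
# short spur branches; take the longest leaf-to-leaf geodesic; smooth,
# resample, and extend both ends along their tangents to the original object
# boundary so the midline spans the full structure.

#' Trace the ordered 8-connected boundary of one object
#'
#' Moore-neighbor tracing of the perimeter pixels of object `object_id` in a
#' label (or logical) raster. The returned polygon is ordered anticlockwise
#' in the standard orientation (x = column increasing right, y increasing
#' upward, i.e. against raster row order).
#'
#' @param labels integer label raster (or logical mask).
#' @param object_id object to trace (ignored for a logical mask).
#' @return n x 2 matrix of boundary pixel centers, columns `x` (col) and `y`
#'   (row). A single-pixel object gives one row.
#' @export
trace_boundary <- function(labels, object_id = 1L) {
  obj <- if (is.logical(labels)) labels else labels == object_id
  if (!any(obj)) stopf("object %d has no pixels", object_id)
  idx <- which(obj, arr.ind = TRUE)
  if (nrow(idx) == 1L)
    return(cbind(x = idx[1L, 2L], y = idx[1L, 1L]))
  nr <- nrow(obj); nc <- ncol(obj)
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && obj[r, c]
  # clockwise Moore neighborhood (in raster coords, y down)
  moves <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                 c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  # start at the topmost-leftmost pixel, backtracking from the west
  ord <- order(idx[, 1L], idx[, 2L])
  start <- idx[ord[1L], ]
  p <- start
  b_dir <- 7L                               # direction index of the backtrack (west)
  pts <- list()
  visited_states <- character(0)
  repeat {
    state <- paste(p[1L], p[2L], b_dir)
    if (state %in% visited_states) break
    visited_states <- c(visited_states, state)
    pts[[length(pts) + 1L]] <- p
    found <- FALSE
    for (k in 1:8) {
      dir <- ((b_dir - 1L + k - 1L) %% 8L) + 1L  # clockwise from backtrack
      q <- p + moves[dir, ]
      if (inside(q[1L], q[2L])) {
        b_dir <- ((dir - 2L + 4L) %% 8L) + 1L    # neighbor before q, reversed
        # backtrack for next step: direction from q to the previously
        # examined (background) neighbor of p
        prev_dir <- ((dir - 2L) %% 8L) + 1L
        bg <- p + moves[prev_dir, ]
        d <- c(bg[1L] - q[1L], bg[2L] - q[2L])
        b_dir <- which(moves[, 1L] == sign(d[1L]) * min(abs(d[1L]), 1L) &
                       moves[, 2L] == sign(d[2L]) * min(abs(d[2L]), 1L))
        if (length(b_dir) != 1L) b_dir <- prev_dir
        p <- q
        found <- TRUE
        break
      }
    }
    if (!found) break                        # isolated pixel cluster exhausted
    if (length(pts) > 4L * nrow(idx) + 8L) break
  }
  m <- do.call(rbind, pts)
  m <- m[!duplicated(m), , drop = FALSE]
  out <- cbind(x = m[, 2L], y = m[, 1L])
  # enforce anticlockwise orientation in the y-up frame
  if (nrow(out) >= 3L) {
    xu <- out[, 1L]; yu <- -out[, 2L]
    a2 <- sum(xu * c(yu[-1L], yu[1L]) - c(xu[-1L], xu[1L]) * yu)
    if (a2 < 0) out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
  }
  out
}

#' Dilate, smooth and resample a boundary polygon
#'
#' Offsets the closed boundary outward by `dilation` px along per-vertex
#' outward normals, smooths x and y with a circular moving average of
#' `smooth_window` points, and resamples at uniform arc-length `spacing`.
#' This regularizes the pixelated perimeter before Voronoi construction.
#'
#' @param boundary n x 2 matrix from [trace_boundary()] (n >= 3).
#' @param dilation outward offset in px (default 1).
#' @param smooth_window moving-average window in points (default 5).
#' @param spacing resampling arc-length spacing in px (default 1).
#' @return m x 2 matrix of adjusted boundary points (closed polygon, first
#'   point not repeated).
#' @export
prepare_boundary <- function(boundary, dilation = 1, smooth_window = 5,
                             spacing = 1) {
  if (nrow(boundary) < 3L) stopf("prepare_boundary: need >= 3 boundary points")
  pts <- boundary
  # orient counterclockwise in raster (y-down) coordinates
  x <- pts[, 1L]; y <- pts[, 2L]
  a2 <- sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)
  if (a2 < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  n <- nrow(pts)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  ex <- pts[nxt, 1L] - pts[, 1L]; ey <- pts[nxt, 2L] - pts[, 2L]
  len <- pmax(sqrt(ex^2 + ey^2), 1e-12)
  # outward normal of a CCW (y-down) polygon edge
  nx_e <- ey / len; ny_e <- -ex / len
  nx <- nx_e + nx_e[prv]; ny <- ny_e + ny_e[prv]
  nlen <- pmax(sqrt(nx^2 + ny^2), 1e-12)
  out <- cbind(pts[, 1L] + dilation * nx / nlen,
               pts[, 2L] + dilation * ny / nlen)
  out[, 1L] <- moving_average(out[, 1L], smooth_window, circular = TRUE)
  out[, 2L] <- moving_average(out[, 2L], smooth_window, circular = TRUE)
  res <- resample_polyline(out, spacing, closed = TRUE)
  if (nrow(res) < 4L) stopf("degenerate boundary after smoothing")
  colnames(res) <- c("x", "y")
  res
}

# Interior Voronoi graph of boundary points: finite Voronoi edges with both
# endpoints strictly inside the boundary polygon.
interior_voronoi_graph <- function(boundary_pts) {
  x <- boundary_pts[, 1L]; y <- boundary_pts[, 2L]
  # break exact collinearity/cocircularity, which the Voronoi construction
  # cannot handle; the perturbation (1e-3 px) is deterministic and far below
  # the midline tolerances
  i <- seq_along(x)
  dd <- NULL
  for (amp in c(1e-3, 1e-2, 5e-2)) {
    xj <- x + amp * sin(i * 12.9898)
    yj <- y + amp * sin(i * 78.233)
    dd <- tryCatch(
      suppressMessages(deldir::deldir(xj, yj, suppressMsge = TRUE)),
      error = function(e) NULL)
    if (!is.null(dd)) break
  }
  if (is.null(dd)) return(NULL)
  seg <- dd$dirsgs
  if (is.null(seg) || nrow(seg) == 0L) return(NULL)
  p1 <- cbind(seg$x1, seg$y1); p2 <- cbind(seg$x2, seg$y2)
  in1 <- points_in_polygon(p1, boundary_pts)
  in2 <- points_in_polygon(p2, boundary_pts)
  keep <- in1 & in2 & !seg$bp1 & !seg$bp2
  if (!any(keep)) return(NULL)
  p1 <- p1[keep, , drop = FALSE]; p2 <- p2[keep, , drop = FALSE]
  key <- function(p) sprintf("%.6f_%.6f", p[, 1L], p[, 2L])
  k1 <- key(p1); k2 <- key(p2)
  verts <- unique(rbind(p1, p2))
  vkey <- key(verts)
  i1 <- match(k1, vkey); i2 <- match(k2, vkey)
  w <- sqrt(rowSums((p1 - p2)^2))
  sel <- i1 != i2
  if (!any(sel)) return(NULL)
  g <- igraph::graph_from_edgelist(cbind(i1[sel], i2[sel]), directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = "first")
  # set weights on the simplified graph from vertex coordinates
  el <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$weight <- sqrt(rowSums((verts[el[, 1L], , drop = FALSE] -
                                       verts[el[, 2L], , drop = FALSE])^2))
  list(graph = g, coords = verts)
}

# Iteratively remove spur branches: leaf chains shorter than prune_px that
# terminate at a junction (degree >= 3). A bare path (no junctions) is never
# pruned. Vertices are addressed by their igraph `name` attribute, which
# indexes rows of the full coordinate matrix.
prune_spurs <- function(g, coords_full, prune_px) {
  xy <- function(v) coords_full[as.integer(igraph::V(g)$name[v]), , drop = FALSE]
  repeat {
    deg <- igraph::degree(g)
    if (!any(deg >= 3L)) break
    leaves <- which(deg == 1L)
    if (!length(leaves)) break
    to_drop <- character(0)
    for (lf in leaves) {
      chain <- lf
      cur <- lf; prev <- -1L; len <- 0
      hit_junction <- FALSE
      repeat {
        nbrs <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
        if (length(nbrs) != 1L) break
        nxt <- nbrs[1L]
        len <- len + sqrt(sum((xy(cur) - xy(nxt))^2))
        if (deg[nxt] >= 3L) { hit_junction <- TRUE; break }
        prev <- cur; cur <- nxt; chain <- c(chain, nxt)
        if (len >= prune_px) break
      }
      if (hit_junction && len < prune_px)
        to_drop <- c(to_drop, igraph::V(g)$name[chain])
    }
    to_drop <- unique(to_drop)
    if (!length(to_drop)) break
    g <- igraph::delete_vertices(g, to_drop)
  }
  g
}

#' Extract an object midline from its adjusted boundary
#'
#' Builds the Voronoi diagram of the boundary points, keeps the interior
#' edges (both endpoints strictly inside the boundary polygon), prunes spur
#' branches shorter than `prune_px`, takes the longest leaf-to-leaf geodesic
#' path through the remaining graph, smooths and resamples it, and — when
#' `original_boundary` is supplied — extends both ends along their end
#' tangents until they meet the original object boundary, so the midline
#' spans the full object. Per-point tangents are computed by central
#' differences (one-sided at the ends), as axial angles in degrees.
#'
#' @param adjusted_boundary m x 2 matrix from [prepare_boundary()].
#' @param smooth_window moving-average window for the midline (default 5).
#' @param spacing resampling spacing in px (default 1).
#' @param prune_px spur branches shorter than this are removed (default 4).
#' @param original_boundary optional n x 2 polygon (the undilated perimeter
#'   from [trace_boundary()]) used for end extension.
#' @param min_length minimum spine length in px (default 5). A midline is
#'   only valid when the pre-extension spine is at least this long AND at
#'   least twice the median spine-to-boundary distance, so near-isotropic
#'   objects (discs, compact puncta) have no meaningful axis and are flagged
#'   degenerate.
#' @param pixel_size micrometres per pixel, for `arc_length_um`.
#' @return An object of class `fpm_midline`: `points` (k x 2, x/y px),
#'   `tangents` (degrees, axial, `[0, 180)`), `arc_length_px`,
#'   `arc_length_um`, `valid`. Degenerate objects yield a single centroid
#'   point with `valid = FALSE`.
#' @export
voronoi_midline <- function(adjusted_boundary, smooth_window = 5, spacing = 1,
                            prune_px = 4, original_boundary = NULL,
                            min_length = 5, pixel_size = 0.1) {
  degenerate <- function() {
    ctr <- colMeans(adjusted_boundary)
    structure(list(points = matrix(ctr, 1L, 2L,
                                   dimnames = list(NULL, c("x", "y"))),
                   tangents = NA_real_, arc_length_px = 0,
                   arc_length_um = 0, valid = FALSE),
              class = "fpm_midline")
  }
  if (nrow(adjusted_boundary) < 4L) return(degenerate())
  iv <- interior_voronoi_graph(adjusted_boundary)
  if (is.null(iv)) return(degenerate())
  g <- iv$graph; coords_full <- iv$coords
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  # largest connected component
  comp <- igraph::components(g)
  g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  g <- prune_spurs(g, coords_full, prune_px)
  if (igraph::vcount(g) < 2L) return(degenerate())
  coords <- coords_full[as.integer(igraph::V(g)$name), , drop = FALSE]
  deg <- igraph::degree(g)
  ends <- which(deg == 1L)
  if (length(ends) < 2L) ends <- seq_len(igraph::vcount(g))
  if (length(ends) > 80L)
    ends <- ends[order(-apply(coords[ends, , drop = FALSE], 1L, function(p)
      sum((p - colMeans(coords))^2)))][1:80]
  D <- igraph::distances(g, v = ends, to = ends)
  D[!is.finite(D)] <- -1
  if (max(D) <= 0) return(degenerate())
  ij <- which(D == max(D), arr.ind = TRUE)[1L, ]
  vp <- igraph::shortest_paths(g, from = ends[ij[1L]], to = ends[ij[2L]],
                               output = "vpath")$vpath[[1L]]
  path <- coords_full[as.integer(igraph::V(g)$name[as.integer(vp)]), , drop = FALSE]
  if (nrow(path) < 2L) return(degenerate())
  path[, 1L] <- moving_average(path[, 1L], smooth_window)
  path[, 2L] <- moving_average(path[, 2L], smooth_window)
  path <- resample_polyline(path, spacing)
  # validity is judged on the medial spine itself, before end extension:
  # the spine must exceed min_length AND twice the local half-width (median
  # spine-to-boundary distance), so near-isotropic objects (discs, compact
  # puncta) are flagged degenerate instead of being given a spurious axis
  spine_length <- polyline_length(path)
  half_width <- median(vapply(seq_len(nrow(path)), function(i)
    min(sqrt((adjusted_boundary[, 1L] - path[i, 1L])^2 +
             (adjusted_boundary[, 2L] - path[i, 2L])^2)), numeric(1L)))
  if (spine_length < max(min_length, 2 * half_width)) return(degenerate())
  if (!is.null(original_boundary) && nrow(original_boundary) >= 3L &&
      nrow(path) >= 2L) {
    path <- extend_to_boundary(path, original_boundary)
    path <- resample_polyline(path, spacing)
  }
  L <- polyline_length(path)
  tang <- polyline_tangents(path)
  colnames(path) <- c("x", "y")
  structure(list(points = path, tangents = tang, arc_length_px = L,
                 arc_length_um = L * pixel_size, valid = TRUE),
            class = "fpm_midline")
}

#' @export
print.fpm_midline <- function(x, ...) {
  cat(sprintf("<fpm_midline> %d point(s), arc length %.2f px (%.3f um), %s\n",
              nrow(x$points), x$arc_length_px, x$arc_length_um,
              if (isTRUE(x$valid)) "valid" else "degenerate"))
  invisible(x)
}

# Extend both ends of an open polyline along their end tangents until they
# exit the given polygon (stepping 0.25 px, capped at 15 px per end).
extend_to_boundary <- function(path, poly) {
  extend_one <- function(pts) {
    n <- nrow(pts)
    k <- min(4L, n)
    d <- pts[1L, ] - pts[k, ]
    nd <- sqrt(sum(d^2))
    if (nd < 1e-9) return(pts)
    d <- d / nd
    step <- 0.25
    p <- pts[1L, ]
    added <- NULL
    for (i in seq_len(60L)) {
      q <- p + step * d * i
      if (!points_in_polygon(matrix(q, 1L, 2L), poly)) break
      added <- q
    }
    if (is.null(added)) pts else rbind(added, pts)
  }
  path <- extend_one(path)
  path <- extend_one(path[rev(seq_len(nrow(path))), , drop = FALSE])
  path[rev(seq_len(nrow(path))), , drop = FALSE]
}

# Per-point axial tangent angles (degrees) by central differences.
polyline_tangents <- function(pts) {
  n <- nrow(pts)
  if (n == 1L) return(NA_real_)
  ip <- pmin(seq_len(n) + 1L, n)
  im <- pmax(seq_len(n) - 1L, 1L)
  dx <- pts[ip, 1L] - pts[im, 1L]
  drow <- pts[ip, 2L] - pts[im, 2L]
  axial_angle_deg(dx, drow)
}

#' Assign the nearest midline tangent to each object pixel
#'
#' Each object pixel receives the tangent angle of its Euclidean-nearest
#' midline point; ties are broken toward the lower midline point index.
#'
#' @param pixels n x 2 matrix of pixel coordinates, columns x (col) and
#'   y (row), or an integer vector of raster indices with `dim` supplied.
#' @param midline an `fpm_midline` with `valid = TRUE`.
#' @param dim raster dimensions, required when `pixels` is an index vector.
#' @return Numeric vector of axial tangent angles (degrees) per pixel.
#' @export
assign_tangents <- function(pixels, midline, dim = NULL) {
  stopifnot(inherits(midline, "fpm_midline"))
  if (!isTRUE(midline$valid)) stopf("assign_tangents: midline is degenerate")
  if (is.vector(pixels) && !is.matrix(pixels)) {
    if (is.null(dim)) stopf("dim is required for index input")
    rc <- arrayInd(pixels, dim)
    pixels <- cbind(x = rc[, 2L], y = rc[, 1L])
  }
  mp <- midline$points
  n <- nrow(pixels); m <- nrow(mp)
  d2 <- outer(pixels[, 1L], mp[, 1L], `-`)^2 +
        outer(pixels[, 2L], mp[, 2L], `-`)^2
  nearest <- max.col(-d2, ties.method = "first")
  midline$tangents[nearest]
}

#' Azimuth relative to the local midline tangent
#'
#' `alpha_midline = (alpha_image - tangent) mod 180`; 90 degrees means the
#' dipole axis is perpendicular to the structure.
#'
#' @param alpha_image_deg axial azimuth(s), degrees.
#' @param tangent_deg axial tangent angle(s), degrees.
#' @return Axial angle(s) in `[0, 180)`; `NA` where either input is `NA`.
#' @examples
#' relative_azimuth(120, 30)   # 90: perpendicular
#' relative_azimuth(100, 170)  # 110
#' @export
relative_azimuth <- function(alpha_image_deg, tangent_deg) {
  wrap_axial_deg(alpha_image_deg - tangent_deg)
}

#' Compute the midline of one labeled object
#'
#' Convenience wrapper chaining [trace_boundary()], [prepare_boundary()] and
#' [voronoi_midline()] for object `object_id` of a segmentation.
#'
#' @param labels integer label raster.
#' @param object_id object label.
#' @param pixel_size micrometres per pixel.
#' @param dilation,smooth_window,spacing,prune_px,min_length see
#'   [prepare_boundary()] and [voronoi_midline()].
#' @return An `fpm_midline`.
#' @export
object_midline <- function(labels, object_id, pixel_size = 0.1, dilation = 1,
                           smooth_window = 5, spacing = 1, prune_px = 4,
                           min_length = 5) {
  bnd <- trace_boundary(labels, object_id)
  if (nrow(bnd) < 3L) {
    ctr <- colMeans(bnd)
    return(structure(list(points = matrix(ctr, 1L, 2L,
                                          dimnames = list(NULL, c("x", "y"))),
                          tangents = NA_real_, arc_length_px = 0,
                          arc_length_um = 0, valid = FALSE),
                     class = "fpm_midline"))
  }
  adj <- tryCatch(prepare_boundary(bnd, dilation, smooth_window, spacing),
                  error = function(e) NULL)
  if (is.null(adj)) {
    ctr <- colMeans(bnd)
    return(structure(list(points = matrix(ctr, 1L, 2L,
                                          dimnames = list(NULL, c("x", "y"))),
                          tangents = NA_real_, arc_length_px = 0,
                          arc_length_um = 0, valid = FALSE),
                     class = "fpm_midline"))
  }
  voronoi_midline(adj, smooth_window = smooth_window, spacing = spacing,
                  prune_px = prune_px, original_boundary = bnd,
                  min_length = min_length, pixel_size = pixel_size)
}
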