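# The project/group/image hierarchy, batch pipeline, and object
# filtering/labeling/clustering.

#' Build a project hierarchy
#'
#' A project is an ordered list of groups (experimental conditions or
#' biological replicates); each group holds images; each image holds its FPM
#' stack, optional flat-field stacks, and — after [run_pipeline()] — pixel
#' maps, the segmentation and the object table. Group names must be unique,
#' image names unique within a group.
#'
#' @param groups list of [fpm_group()] objects.
#' @return An `fpm_project`.
#' @export
fpm_project <- function(groups) {
  nms <- vapply(groups, function(g) g$name, character(1L))
  if (anyDuplicated(nms)) stopf("duplicate group names")
  structure(list(groups = groups), class = "fpm_project")
}

#' @rdname fpm_project
#' @param name group / image name.
#' @param images list of [fpm_image()] objects.
#' @export
fpm_group <- function(name, images) {
  nms <- vapply(images, function(im) im$name, character(1L))
  if (anyDuplicated(nms)) stopf("duplicate image names in group '%s'", name)
  structure(list(name = name, images = images), class = "fpm_group")
}

#' @rdname fpm_project
#' @param stack an [fpm_stack()].
#' @param flats optional list of [fpm_flat_stack()] objects.
#' @export
fpm_image <- function(name, stack, flats = NULL) {
  stopifnot(inherits(stack, "fpm_stack"))
  structure(list(name = name, stack = stack, flats = flats,
                 maps = NULL, segmentation = NULL, objects = NULL),
            class = "fpm_image")
}

#' @export
print.fpm_project <- function(x, ...) {
  ni <- sum(vapply(x$groups, function(g) length(g$images), numeric(1L)))
  cat(sprintf("<fpm_project> %d group(s), %d image(s)\n", length(x$groups), ni))
  invisible(x)
}

#' Default processing configuration
#'
#' All tunable parameters of the batch pipeline in one nested list:
#' segmentation scheme and per-scheme parameters, midline parameters,
#' signal-to-background annulus geometry, and whether flat-field correction
#' is applied when flats are present.
#'
#' @return Named list; see the vignette for parameter meanings and units.
#' @export
default_config <- function() {
  list(
    scheme = "puncta",
    flat_field = TRUE,
    puncta = list(tophat_radius = 8, smooth_sigma = 1, min_area = 10,
                  fill_holes = TRUE),
    filaments = list(ridge_sigmas = c(1, 2, 3), ridge_threshold = 0.95,
                     min_branch_length = 10, dilation_radius = 2),
    midline = list(dilation = 1, smooth_window = 5, spacing = 1,
                   prune_px = 4, min_length = 5),
    sb = list(buffer_px = 2, annulus_px = 2),
    compute_midlines = TRUE)
}

# Merge a partial user config over the defaults (one level deep).
merge_config <- function(config) {
  base <- default_config()
  for (nm in names(config)) {
    if (is.list(config[[nm]]) && is.list(base[[nm]]))
      base[[nm]][names(config[[nm]])] <- config[[nm]]
    else base[[nm]] <- config[[nm]]
  }
  base
}

segment_with_config <- function(S0, config) {
  if (config$scheme == "puncta") {
    do.call(segment_puncta, c(list(S0 = S0), config$puncta))
  } else if (config$scheme == "filaments") {
    do.call(segment_filaments, c(list(S0 = S0), config$filaments))
  } else stopf("unknown segmentation scheme '%s'", config$scheme)
}

process_image <- function(image, group_name, config) {
  stack <- image$stack
  if (isTRUE(config$flat_field) && length(image$flats))
    stack <- flat_field_correct(stack, image$flats)
  maps <- compute_pixel_maps(stack)
  seg <- segment_with_config(maps$S0, config)
  objects <- extract_features(
    seg, maps, stack, group = group_name, image = image$name,
    compute_midlines = isTRUE(config$compute_midlines),
    sb_buffer_px = config$sb$buffer_px, sb_annulus_px = config$sb$annulus_px,
    midline_params = config$midline)
  image$maps <- maps
  image$segmentation <- seg
  image$objects <- objects
  image
}

#' Run the full processing pipeline over a project
#'
#' For each image: flat-field correction (when flats are present and
#' enabled), pixelwise order/azimuth maps, segmentation with the configured
#' scheme, feature extraction, midlines and midline-relative azimuths. The
#' pipeline is deterministic for a given configuration. Per-image failures
#' are logged as warnings and skipped; an error is raised only if every
#' image fails.
#'
#' @param project an [fpm_project()].
#' @param config configuration list (missing entries take
#'   [default_config()] values).
#' @return The populated project.
#' @export
run_pipeline <- function(project, config = list()) {
  stopifnot(inherits(project, "fpm_project"))
  config <- merge_config(config)
  n_ok <- 0L; n_tot <- 0L
  for (gi in seq_along(project$groups)) {
    g <- project$groups[[gi]]
    for (ii in seq_along(g$images)) {
      n_tot <- n_tot + 1L
      res <- tryCatch(process_image(g$images[[ii]], g$name, config),
                      error = function(e) e)
      if (inherits(res, "error")) {
        warnf("image '%s/%s' failed: %s", g$name, g$images[[ii]]$name,
              conditionMessage(res))
      } else {
        project$groups[[gi]]$images[[ii]] <- res
        n_ok <- n_ok + 1L
      }
    }
  }
  if (n_tot > 0L && n_ok == 0L) stopf("all %d image(s) failed", n_tot)
  project
}

#' Collect all object tables of a project
#'
#' @param project a processed [fpm_project()].
#' @return One data frame with all objects of all images (0 rows if none).
#' @export
project_objects <- function(project) {
  stopifnot(inherits(project, "fpm_project"))
  dfs <- list()
  for (g in project$groups) for (im in g$images)
    if (!is.null(im$objects) && nrow(im$objects)) dfs[[length(dfs) + 1L]] <- im$objects
  if (!length(dfs))
    return(as.data.frame(setNames(rep(list(numeric(0)),
                                      length(object_table_columns())),
                                  object_table_columns())))
  cols <- Reduce(union, lapply(dfs, names))
  dfs <- lapply(dfs, function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
    d[, cols, drop = FALSE]
  })
  out <- do.call(rbind, dfs)
  rownames(out) <- NULL
  out
}

#' Property-based object filtering
#'
#' Selects the objects satisfying ALL supplied predicates (conjunction).
#' Each predicate is a list `list(feature, op, value)` with `op` one of
#' `">=", ">", "<=", "<", "==", "!="`; features are columns of the object
#' table.
#'
#' @param objects object data frame (from [extract_features()] or
#'   [project_objects()]).
#' @param filters list of predicates; a single predicate may be passed
#'   directly.
#' @return The filtered data frame (originals untouched).
#' @examples
#' \dontrun{filter_objects(objs, list(list("length_um", ">=", 17.5)))}
#' @export
filter_objects <- function(objects, filters) {
  if (length(filters) == 3L && is.character(filters[[1L]]))
    filters <- list(filters)
  keep <- rep(TRUE, nrow(objects))
  for (f in filters) {
    feat <- f[[1L]]; op <- f[[2L]]; val <- f[[3L]]
    if (!feat %in% names(objects)) stopf("unknown feature '%s'", feat)
    if (!op %in% c(">=", ">", "<=", "<", "==", "!="))
      stopf("unknown comparator '%s'", op)
    v <- objects[[feat]]
    ok <- do.call(op, list(v, val))
    ok[is.na(ok)] <- FALSE
    keep <- keep & ok
  }
  objects[keep, , drop = FALSE]
}

#' Label objects by a partition of filter rules
#'
#' Applies named filter rules (as in [filter_objects()]) and writes the rule
#' name into the `label` column. The rules must form a partition: an object
#' matching two rules (overlap) or none (gap) is an error.
#'
#' @param objects object data frame.
#' @param rules named list; each element is a filter list for
#'   [filter_objects()].
#' @return The data frame with `label` filled.
#' @export
label_objects <- function(objects, rules) {
  if (nrow(objects) == 0L) return(objects)
  if (is.null(names(rules)) || any(names(rules) == ""))
    stopf("rules must be named")
  hit <- matrix(FALSE, nrow(objects), length(rules))
  for (j in seq_along(rules)) {
    sel <- filter_objects(cbind(objects, .row = seq_len(nrow(objects))),
                          rules[[j]])
    hit[sel$.row, j] <- TRUE
  }
  nh <- rowSums(hit)
  if (any(nh > 1L)) stopf("overlapping label rules")
  if (any(nh < 1L)) stopf("label rules do not cover all objects")
  objects$label <- names(rules)[max.col(hit)]
  objects
}

#' Label filaments as short or long relative to a length cutoff
#'
#' Convenience rule for the persistence-length split: `label = "short"` when
#' `length_um < cutoff_um`, `"long"` when `length_um >= cutoff_um` (the
#' boundary value is "long"). The default cutoff, 17.5 um, approximates the
#' persistence length of phalloidin-stabilized F-actin.
#'
#' @param objects object data frame with a `length_um` column.
#' @param cutoff_um length cutoff in micrometres (default 17.5).
#' @return The data frame with `label` filled.
#' @export
label_by_length <- function(objects, cutoff_um = 17.5) {
  label_objects(objects, rules = list(
    short = list("length_um", "<", cutoff_um),
    long = list("length_um", ">=", cutoff_um)))
}

#' Cluster objects on selected features with k-means
#'
#' Standardizes the selected feature columns to z-scores, runs
#' `stats::kmeans` (20 restarts, 300 iterations) under a fixed seed, and
#' renumbers clusters so that cluster 1 has the lowest mean of the FIRST
#' feature — e.g. clustering on `local_sb` puts the low-S/B objects in
#' cluster 1. Objects with undefined feature values are excluded with a
#' warning and keep `cluster_id = NA`.
#'
#' @param objects object data frame.
#' @param features character vector of feature column names.
#' @param k number of clusters (>= 2).
#' @param seed RNG seed for the restarts.
#' @param standardize z-score the features first (default TRUE).
#' @return The data frame with `cluster_id` filled.
#' @export
kmeans_cluster <- function(objects, features, k = 2L, seed = 1L,
                           standardize = TRUE) {
  stopifnot(k >= 2L, nrow(objects) >= k)
  for (f in features) if (!f %in% names(objects)) stopf("unknown feature '%s'", f)
  X <- as.matrix(objects[, features, drop = FALSE])
  ok <- rowSums(!is.finite(X)) == 0L
  if (any(!ok))
    warnf("kmeans_cluster: %d object(s) with undefined features excluded",
          sum(!ok))
  if (sum(ok) < k) stopf("fewer defined objects than clusters")
  Xs <- X[ok, , drop = FALSE]
  if (standardize)
    Xs <- scale(Xs)
  Xs[!is.finite(Xs)] <- 0      # zero-variance column after scaling
  fit <- with_seed(seed,
    kmeans(Xs, centers = k, nstart = 20L, iter.max = 300L))
  # renumber: cluster 1 = lowest mean of the first feature
  m1 <- tapply(X[ok, 1L], fit$cluster, mean)
  ord <- order(m1)
  relab <- integer(k); relab[as.integer(names(m1))[ord]] <- seq_len(k)
  objects$cluster_id <- NA_integer_
  objects$cluster_id[ok] <- relab[fit$cluster]
  objects
}
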