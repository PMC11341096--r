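# Reading/writing FPM stacks, pixel maps, masks and object tables.
#
# Reading goes through tiff::readTIFF (libtiff), which handles integer and
# IEEE-float TIFFs alike. Map/stack WRITING uses a minimal uncompressed
# little-endian float32 TIFF encoder defined below, because intensity and
# azimuth rasters are unbounded floats (azimuth maps carry NaN at undefined
# pixels) and must round-trip bit-exactly at 32-bit precision.

# ---- minimal float32 TIFF writer -------------------------------------------

write_float_tiff <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  n <- length(pages)
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  # header
  writeBin(charToRaw("II"), con); u16(42L); u32(8L)
  ifd_size <- 2L + 10L * 12L + 4L
  data_off <- 8L + n * ifd_size
  offs <- integer(n)
  sizes <- integer(n)
  for (i in seq_len(n)) {
    d <- dim(pages[[i]])
    sizes[i] <- 4L * d[1L] * d[2L]
    offs[i] <- data_off
    data_off <- data_off + sizes[i]
  }
  entry <- function(tag, type, value) { u16(tag); u16(type); u32(1L)
    if (type == 3L) { u16(value); u16(0L) } else u32(value) }
  for (i in seq_len(n)) {
    d <- dim(pages[[i]])
    u16(10L)                               # entry count
    entry(256L, 4L, d[2L])                 # ImageWidth
    entry(257L, 4L, d[1L])                 # ImageLength
    entry(258L, 3L, 32L)                   # BitsPerSample
    entry(259L, 3L, 1L)                    # Compression: none
    entry(262L, 3L, 1L)                    # Photometric: BlackIsZero
    entry(273L, 4L, offs[i])               # StripOffsets
    entry(277L, 3L, 1L)                    # SamplesPerPixel
    entry(278L, 4L, d[1L])                 # RowsPerStrip
    entry(279L, 4L, sizes[i])              # StripByteCounts
    entry(339L, 3L, 3L)                    # SampleFormat: IEEE float
    u32(if (i < n) 8L + i * ifd_size else 0L)  # next IFD
  }
  for (i in seq_len(n))                    # strips are row-major
    writeBin(as.numeric(t(pages[[i]])), con, size = 4L, endian = "little")
  invisible(path)
}

read_tiff_pages <- function(path) {
  # as.is=TRUE returns raw integer counts for integer-sampled TIFFs but is
  # rejected for float TIFFs, which already come back unscaled
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) tiff::readTIFF(path, all = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] != 1L)
        stopf("multi-channel TIFF pages are not supported: %s", path)
      p <- p[, , 1L]
    }
    storage.mode(p) <- "double"
    p
  })
}

# ---- stacks ----------------------------------------------------------------

#' Read an FPM stack from a 4-page TIFF
#'
#' Pages are mapped to excitation polarizations in file order: page 1 is 0
#' degrees, page 2 is 45, page 3 is 90, page 4 is 135. This convention is
#' fixed, not configurable.
#'
#' @param path path to a 4-page TIFF / OME-TIFF file.
#' @param pixel_size pixel size in micrometres per pixel.
#' @param name stack identifier; defaults to the file name.
#' @return An [fpm_stack()].
#' @export
read_fpm_stack <- function(path, pixel_size = 0.1, name = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  pages <- read_tiff_pages(path)
  if (length(pages) != 4L)
    stopf("an FPM stack must have exactly 4 pages, '%s' has %d",
          path, length(pages))
  d <- dim(pages[[1L]])
  for (i in 2:4)
    if (!identical(dim(pages[[i]]), d))
      stopf("unequal page sizes in '%s'", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  fpm_stack(pages, pixel_size = pixel_size, name = name)
}

#' Write an FPM stack as a 4-page float32 TIFF
#'
#' @param stack an [fpm_stack()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_fpm_stack <- function(stack, path) {
  stopifnot(inherits(stack, "fpm_stack"))
  write_float_tiff(stack$images, path)
  invisible(path)
}

# ---- maps ------------------------------------------------------------------

#' Write pixel maps as float32 TIFFs
#'
#' Writes single-page 32-bit float TIFFs for the `S0`, `order` and `azimuth`
#' rasters (azimuth in radians; undefined pixels stored as NaN), plus one
#' file per registered custom statistic.
#'
#' @param maps an `fpm_pixel_maps` object from [compute_pixel_maps()].
#' @param directory output directory (created if missing).
#' @param prefix file-name prefix, default `"map"`.
#' @return Named character vector of written paths (the manifest).
#' @export
write_maps <- function(maps, directory, prefix = "map") {
  stopifnot(inherits(maps, "fpm_pixel_maps"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create directory '%s'", directory)
  }
  out <- c(S0 = file.path(directory, paste0(prefix, "_S0.tif")),
           order = file.path(directory, paste0(prefix, "_order.tif")),
           azimuth = file.path(directory, paste0(prefix, "_azimuth.tif")))
  write_float_tiff(maps$S0, out[["S0"]])
  write_float_tiff(maps$order, out[["order"]])
  write_float_tiff(maps$azimuth, out[["azimuth"]])
  for (nm in names(maps$custom)) {
    p <- file.path(directory, paste0(prefix, "_", nm, ".tif"))
    write_float_tiff(maps$custom[[nm]], p)
    out[nm] <- p
  }
  out
}

#' Read a single-page raster written by [write_maps()]
#' @param path TIFF path.
#' @return Numeric matrix.
#' @export
read_map <- function(path) {
  pages <- read_tiff_pages(path)
  if (length(pages) != 1L) stopf("expected a single-page TIFF: %s", path)
  pages[[1L]]
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#' @param mask logical or 0/1 matrix.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- matrix(as.numeric(mask != 0), nrow(mask))
  tiff::writeTIFF(m, path, bits.per.sample = 8L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#' @param path TIFF path.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  p <- read_tiff_pages(path)[[1L]]
  p > max(p) / 2
}

# ---- object tables ---------------------------------------------------------

# Fixed column schema of the object CSV; custom-statistic means are appended
# as custom_<name> columns after these.
object_table_columns <- function() {
  c("group", "image", "object_id", "area_px", "perimeter_px", "eccentricity",
    "length_um", "mean_intensity", "local_sb", "mean_order",
    "mean_azimuth_image_deg", "mean_azimuth_midline_deg", "azimuth_std_deg",
    "label", "cluster_id")
}

#' Write the per-object feature table as CSV
#'
#' One row per object; columns are the fixed schema
#' (`group, image, object_id, area_px, perimeter_px, eccentricity, length_um,
#' mean_intensity, local_sb, mean_order, mean_azimuth_image_deg,
#' mean_azimuth_midline_deg, azimuth_std_deg, label, cluster_id`) followed by
#' any `custom_*` statistic means. UTF-8, '.' decimal separator.
#'
#' @param objects data frame from [extract_features()] (possibly 0 rows).
#' @param path output CSV path.
#' @return Number of rows written.
#' @export
write_object_table <- function(objects, path) {
  cols <- object_table_columns()
  if (is.null(objects) || nrow(objects) == 0L) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  } else {
    df <- objects
    for (cn in cols) if (!cn %in% names(df)) df[[cn]] <- NA
    custom <- grep("^custom_", names(df), value = TRUE)
    df <- df[, c(cols, custom), drop = FALSE]
  }
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  nrow(df)
}

#' Write object midlines as a CSV polyline table
#'
#' Columns: `object_id, point_index, x, y, tangent_deg` (x = column, y = row,
#' pixel units; tangent axial degrees in `[0, 180)`).
#'
#' @param midlines list of `fpm_midline` objects (possibly with NULLs for
#'   objects without a valid midline), named or indexed by object id.
#' @param path output CSV path.
#' @return Number of rows written.
#' @export
write_midline_table <- function(midlines, path) {
  rows <- list()
  for (i in seq_along(midlines)) {
    ml <- midlines[[i]]
    if (is.null(ml) || !isTRUE(ml$valid)) next
    rows[[length(rows) + 1L]] <- data.frame(
      object_id = i, point_index = seq_len(nrow(ml$points)),
      x = ml$points[, 1L], y = ml$points[, 2L], tangent_deg = ml$tangents)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(object_id = integer(0), point_index = integer(0),
               x = numeric(0), y = numeric(0), tangent_deg = numeric(0))
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  nrow(df)
}
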