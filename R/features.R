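# Per-object morphological, intensity and FPM feature extraction.

#' Local signal-to-background ratio of one object
#'
#' Signal is the mean `S0` over the object's pixels; background is the mean
#' `S0` over an annulus obtained by dilating the object by
#' `buffer_px + annulus_px` and subtracting the dilation by `buffer_px`,
#' excluding pixels that belong to any object (so neighboring objects do not
#' contaminate the background estimate). The ratio is invariant under global
#' intensity scaling.
#'
#' @param object_mask logical matrix of the object's pixels.
#' @param S0 average-intensity raster.
#' @param all_objects_mask logical matrix of all object pixels in the image.
#' @param buffer_px gap between object and annulus (default 2).
#' @param annulus_px annulus thickness (default 2).
#' @return signal/background ratio, or `NA` if the annulus is empty.
#' @export
local_signal_to_background <- function(object_mask, S0, all_objects_mask,
                                       buffer_px = 2, annulus_px = 2) {
  stopifnot(buffer_px >= 1, annulus_px >= 1)
  sig <- mean(S0[object_mask])
  ring <- dilate_mask(object_mask, buffer_px + annulus_px) &
    !dilate_mask(object_mask, buffer_px)
  ring <- ring & !all_objects_mask
  if (!any(ring)) return(NA_real_)
  bg <- mean(S0[ring])
  if (bg <= 0) return(NA_real_)
  sig / bg
}

#' Azimuthal disorder of one object
#'
#' The axial circular standard deviation ([axial_std()]) of the object's
#' pixel azimuths, in degrees. Low values mean the pixel azimuths are
#' coherent along the object.
#'
#' @param azimuth_deg vector of axial azimuths (degrees) over the object's
#'   defined-azimuth pixels.
#' @return `s0` in degrees, or `NA` with fewer than 2 defined pixels.
#' @export
azimuthal_disorder <- function(azimuth_deg) {
  a <- azimuth_deg[!is.na(azimuth_deg)]
  if (length(a) < 2L) return(NA_real_)
  axial_std(a)
}

#' Image-level mean order over a mask
#'
#' Arithmetic mean of the order map over all masked pixels — the quantity an
#' image-based (non-object) analysis would report.
#'
#' @param maps an `fpm_pixel_maps`.
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @return Mean order.
#' @export
image_level_order <- function(maps, mask) {
  stopifnot(inherits(maps, "fpm_pixel_maps"))
  if (!any(mask)) stopf("image_level_order: empty mask")
  mean(maps$order[mask], na.rm = TRUE)
}

#' Extract per-object features
#'
#' For every labeled object computes: area, perimeter and eccentricity
#' (standard region properties of the 8-connected mask, via EBImage);
#' mean raw intensity (mean of `S0`); local signal-to-background
#' ([local_signal_to_background()]); mean order `p` (arithmetic mean over
#' defined pixels); the axial circular mean azimuth in image coordinates
#' (`mean_azimuth_image_deg`); the object midline and its arc length
#' (`length_um`); the axial mean of midline-relative azimuths
#' (`mean_azimuth_midline_deg`); the azimuthal disorder `azimuth_std_deg`;
#' and the per-object mean of every registered custom statistic
#' (`custom_*` columns). Azimuth features use only pixels with defined
#' azimuth and are `NA` when no such pixels exist; midline-relative features
#' are `NA` for objects without a valid midline.
#'
#' @param segmentation an `fpm_segmentation`.
#' @param maps an `fpm_pixel_maps` for the same image.
#' @param stack the source [fpm_stack()] (for pixel size).
#' @param group,image identifiers stored in the table.
#' @param compute_midlines set `FALSE` to skip midline-dependent features.
#' @param sb_buffer_px,sb_annulus_px geometry of the background annulus.
#' @param midline_params list of [object_midline()] parameters.
#' @return A data frame, one row per object (class `fpm_objects`), with the
#'   midlines attached as attribute `"midlines"`.
#' @export
extract_features <- function(segmentation, maps, stack,
                             group = "g1", image = NULL,
                             compute_midlines = TRUE,
                             sb_buffer_px = 2, sb_annulus_px = 2,
                             midline_params = list()) {
  stopifnot(inherits(segmentation, "fpm_segmentation"),
            inherits(maps, "fpm_pixel_maps"), inherits(stack, "fpm_stack"))
  if (is.null(image)) image <- stack$name
  lab <- segmentation$labels
  n <- max(lab)
  mls <- vector("list", n)
  if (n == 0L) {
    out <- as.data.frame(setNames(rep(list(numeric(0)),
                                      length(object_table_columns())),
                                  object_table_columns()))
    attr(out, "midlines") <- mls
    class(out) <- c("fpm_objects", "data.frame")
    return(out)
  }
  labimg <- EBImage::Image(lab)
  shp <- EBImage::computeFeatures.shape(labimg)
  mom <- EBImage::computeFeatures.moment(labimg)
  alpha_deg <- wrap_axial_deg(rad2deg(maps$azimuth))
  all_mask <- segmentation$mask
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    pix <- which(lab == k)
    omask <- lab == k
    p_obj <- maps$order[pix]
    a_obj <- alpha_deg[pix]
    a_def <- a_obj[!is.na(a_obj)]
    am <- if (length(a_def)) axial_mean(a_def)$mean_deg else NA_real_
    s0dis <- azimuthal_disorder(a_obj)
    sb <- local_signal_to_background(omask, maps$S0, all_mask,
                                     sb_buffer_px, sb_annulus_px)
    ml <- NULL
    len_um <- NA_real_
    am_mid <- NA_real_
    if (compute_midlines) {
      ml <- do.call(object_midline,
                    c(list(labels = lab, object_id = k,
                           pixel_size = stack$pixel_size), midline_params))
      mls[[k]] <- ml
      if (isTRUE(ml$valid)) {
        len_um <- ml$arc_length_um
        def <- which(!is.na(a_obj))
        if (length(def)) {
          tg <- assign_tangents(pix[def], ml, dim = dim(lab))
          rel <- relative_azimuth(a_obj[def], tg)
          am_mid <- axial_mean(rel)$mean_deg
        }
      }
    }
    row <- data.frame(
      group = group, image = image, object_id = k,
      area_px = length(pix),
      perimeter_px = as.numeric(shp[k, "s.perimeter"]),
      eccentricity = as.numeric(mom[k, "m.eccentricity"]),
      length_um = len_um,
      mean_intensity = mean(maps$S0[pix]),
      local_sb = sb,
      mean_order = mean(p_obj, na.rm = TRUE),
      mean_azimuth_image_deg = am,
      mean_azimuth_midline_deg = am_mid,
      azimuth_std_deg = s0dis,
      label = NA_character_, cluster_id = NA_integer_,
      stringsAsFactors = FALSE)
    for (nm in names(maps$custom))
      row[[paste0("custom_", nm)]] <- mean(maps$custom[[nm]][pix])
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "midlines") <- mls
  class(out) <- c("fpm_objects", "data.frame")
  out
}
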