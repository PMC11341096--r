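# Axial (period-180-degree) circular statistics via the doubled-angle
# transform: angles are doubled onto the full circle, the weighted circular
# resultant is computed there, and directional results are halved back to
# the axial scale.

#' Axial circular mean
#'
#' Doubles the angles, computes the (optionally weighted) circular resultant,
#' and halves the resultant direction back to the axial scale. The resultant
#' length `R` of the doubled sample measures concentration (1 = all angles
#' equal, 0 = balanced, e.g. an orthogonal axial pair). The mean is reported
#' as `NA` when `R < 1e-9`, where the direction is numerically meaningless.
#'
#' @param angles_deg axial angles in degrees (any representatives; reduced
#'   mod 180).
#' @param weights optional nonnegative weights, same length; must not sum
#'   to 0.
#' @return List with `mean_deg` (degrees in `[0, 180)`, or `NA`) and `R`
#'   (resultant length of the doubled sample, in `[0, 1]`).
#' @examples
#' axial_mean(c(80, 100))    # mean 90, R = cos(20 * pi / 180)
#' axial_mean(c(0, 90))$R    # 0: orthogonal axial pair cancels
#' @export
axial_mean <- function(angles_deg, weights = NULL) {
  angles_deg <- angles_deg[!is.na(angles_deg)]
  n <- length(angles_deg)
  if (n == 0L) stopf("axial_mean: empty sample")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stopf("axial_mean: invalid weights")
  th <- 2 * deg2rad(angles_deg)
  C <- sum(weights * cos(th)) / sum(weights)
  S <- sum(weights * sin(th)) / sum(weights)
  R <- sqrt(C^2 + S^2)
  mean_deg <- if (R < 1e-9) NA_real_ else wrap_axial_deg(rad2deg(atan2(S, C)) / 2)
  list(mean_deg = mean_deg, R = R)
}

#' Axial circular standard deviation
#'
#' The circular standard deviation of the doubled sample, halved back to the
#' axial scale: \eqn{s_0 = \frac{1}{2}\sqrt{-2 \ln R}} (converted to
#' degrees), with `R` the doubled-sample resultant length. 0 for a constant
#' sample; grows without bound as the sample approaches axial uniformity;
#' `NA` when `R` is numerically 0.
#'
#' @inheritParams axial_mean
#' @return `s0` in degrees (>= 0), or `NA` when undefined.
#' @examples
#' axial_std(c(44, 46))  # 0.5 * sqrt(-2 * log(cos(2 * pi / 180))) in degrees
#' @export
axial_std <- function(angles_deg, weights = NULL) {
  angles_deg <- angles_deg[!is.na(angles_deg)]
  if (length(angles_deg) < 2L) stopf("axial_std: need at least 2 angles")
  R <- axial_mean(angles_deg, weights)$R
  if (R <= 0) return(NA_real_)
  R <- min(R, 1)
  if (1 - R < 1e-12) return(0)   # constant sample up to rounding
  rad2deg(0.5 * sqrt(-2 * log(R)))
}

#' Axial polar histogram with 180-degree duplication
#'
#' Each axial angle contributes a count at its direction and at the opposite
#' direction (+180 degrees), so the histogram over `[0, 360)` shows each pair
#' of equivalent, opposite directions and the total count is `2 n`.
#'
#' @param angles_deg axial angles in degrees.
#' @param n_bins even number of bins over `[0, 360)`.
#' @return List with `counts` (length `n_bins`), `breaks_deg`
#'   (length `n_bins + 1`) and `mid_deg` (bin centers).
#' @export
axial_histogram <- function(angles_deg, n_bins = 24L) {
  angles_deg <- angles_deg[!is.na(angles_deg)]
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L || n_bins %% 2L != 0L) stopf("n_bins must be even and >= 2")
  a <- wrap_axial_deg(angles_deg)
  both <- c(a, a + 180) %% 360
  breaks <- seq(0, 360, length.out = n_bins + 1L)
  idx <- pmin(floor(both / (360 / n_bins)) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  list(counts = counts, breaks_deg = breaks,
       mid_deg = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2)
}
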