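test_that("object means reproduce uniform ground truth", {
  # one disc with uniform p = 0.5, alpha = 30 degrees
  dimr <- c(48L, 48L)
  obj <- disc_mask(dimr, c(24, 24), 6)
  A <- matrix(0, dimr[1], dimr[2]); A[obj] <- 100
  p <- matrix(0, dimr[1], dimr[2]); p[obj] <- 0.5
  al <- matrix(0, dimr[1], dimr[2]); al[obj] <- 30 * pi / 180
  st <- forward_stack(A, p, al, background = 0)
  maps <- compute_pixel_maps(st)
  lab <- matrix(as.integer(obj), dimr[1])
  seg <- fpmtools:::new_segmentation(obj, lab, "puncta", list())
  feats <- extract_features(seg, maps, st, compute_midlines = FALSE)
  expect_identical(nrow(feats), 1L)
  expect_equal(feats$mean_order, 0.5, tolerance = 1e-12)
  expect_equal(feats$mean_azimuth_image_deg, 30, tolerance = 1e-9)
  expect_equal(feats$azimuth_std_deg, 0, tolerance = 1e-9)
  expect_equal(feats$area_px, sum(obj))
})

test_that("noisy puncta recover ground-truth means within noise tolerance", {
  sc <- make_puncta_field(dim = c(96L, 96L), n = 8, p = 0.7, azimuth = 40,
                          amplitude = 400, background = 2,
                          noise = list(type = "poisson", gain = 1), seed = 6)
  st <- render_stack(sc)
  maps <- compute_pixel_maps(st)
  lab <- matrix(0L, 96, 96)
  for (i in seq_along(sc$objects)) lab[sc$objects[[i]]$pixels] <- i
  seg <- fpmtools:::new_segmentation(lab > 0L, lab, "puncta", list())
  feats <- extract_features(seg, maps, st, compute_midlines = FALSE)
  expect_equal(mean(feats$mean_order), 0.7, tolerance = 0.05)
  d <- abs(feats$mean_azimuth_image_deg - 40)
  expect_lt(max(pmin(d, 180 - d)), 5)
})

test_that("local S/B matches the forward-model construction", {
  sc <- make_puncta_field(dim = c(64L, 64L), n = 3, amplitude = 90,
                          background = 10, noise = list(type = "none"),
                          seed = 2)
  st <- render_stack(sc)
  maps <- compute_pixel_maps(st)
  lab <- matrix(0L, 64, 64)
  for (i in seq_along(sc$objects)) lab[sc$objects[[i]]$pixels] <- i
  truth_sb <- (2 * 10 + 90) / (2 * 10)     # S0-scale signal over background
  for (i in 1:3) {
    sb <- local_signal_to_background(lab == i, maps$S0, lab > 0L)
    expect_equal(sb, truth_sb, tolerance = 1e-9)
  }
  # scale invariance
  sb1 <- local_signal_to_background(lab == 1, maps$S0 * 37, lab > 0L)
  expect_equal(sb1, truth_sb, tolerance = 1e-9)
  # object filling the frame: undefined
  full <- matrix(TRUE, 16, 16)
  expect_true(is.na(local_signal_to_background(full, matrix(1, 16, 16), full)))
})

test_that("adjacent puncta are excluded from each other's background ring", {
  mk <- function(centers) {
    lab <- matrix(0L, 64, 64)
    A <- matrix(0, 64, 64)
    for (i in seq_along(centers)) {
      d <- disc_mask(c(64, 64), centers[[i]], 4)
      lab[d] <- i; A[d] <- 90
    }
    st <- forward_stack(A, matrix(0.5, 64, 64) * (A > 0), A * 0, background = 10)
    list(lab = lab, S0 = compute_pixel_maps(st)$S0)
  }
  iso <- mk(list(c(32, 32)))
  sb_iso <- local_signal_to_background(iso$lab == 1, iso$S0, iso$lab > 0L)
  pair <- mk(list(c(32, 32), c(32, 43)))    # annuli would overlap the neighbor
  sb_pair <- local_signal_to_background(pair$lab == 1, pair$S0, pair$lab > 0L)
  expect_lt(abs(sb_pair - sb_iso) / sb_iso, 0.05)
})

test_that("azimuthal disorder: constant, uniform, and two-point samples", {
  expect_equal(azimuthal_disorder(rep(25, 10)), 0)
  expect_equal(azimuthal_disorder(c(44, 46)),
               0.5 * sqrt(-2 * log(cos(2 * pi / 180))) * 180 / pi,
               tolerance = 1e-12)
  set.seed(61)
  u <- runif(5000, 0, 180)
  s <- azimuthal_disorder(u)
  # direct evaluation of the closed form on the same sample
  th <- 2 * u * pi / 180
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  expect_equal(s, 0.5 * sqrt(-2 * log(R)) * 180 / pi, tolerance = 1e-9)
  expect_true(is.na(azimuthal_disorder(c(10, NA))))
})

test_that("image-level order equals the area-weighted object mean", {
  maps <- structure(list(order = matrix(c(rep(0.2, 50), rep(0.8, 50)), 10, 10),
                         azimuth = matrix(0, 10, 10),
                         S0 = matrix(1, 10, 10), custom = list()),
                    class = "fpm_pixel_maps")
  mask <- matrix(TRUE, 10, 10)
  expect_equal(image_level_order(maps, mask), 0.5)
  half <- matrix(FALSE, 10, 10); half[, 1:5] <- TRUE
  expect_equal(image_level_order(maps, half), 0.2)
  expect_error(image_level_order(maps, matrix(FALSE, 10, 10)), "empty")

  # random scene: recomputation oracle over object pixels
  sc <- make_puncta_field(dim = c(64L, 64L), n = 6,
                          noise = list(type = "poisson", gain = 1), seed = 7)
  st <- render_stack(sc)
  m <- compute_pixel_maps(st)
  seg <- segment_puncta(m$S0)
  feats <- extract_features(seg, m, st, compute_midlines = FALSE)
  pooled <- image_level_order(m, seg$mask)
  weighted <- sum(feats$mean_order * feats$area_px) / sum(feats$area_px)
  expect_equal(pooled, weighted, tolerance = 1e-10)
})
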