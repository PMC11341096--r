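pixel_stack <- function(i0, i45, i90, i135)
  fpm_stack(lapply(c(i0, i45, i90, i135), function(v) matrix(v, 1, 1)))

test_that("pixel maps reproduce the closed-form examples", {
  m <- compute_pixel_maps(pixel_stack(2, 1, 0, 1))
  expect_equal(m$S0[1, 1], 2)
  expect_equal(m$S1[1, 1], 2)
  expect_equal(m$S2[1, 1], 0)
  expect_equal(m$order[1, 1], 1)
  expect_equal(m$azimuth[1, 1], 0)

  m2 <- compute_pixel_maps(pixel_stack(1, 1, 1, 1))
  expect_equal(m2$S0[1, 1], 2)
  expect_equal(m2$order[1, 1], 0)
  expect_true(is.na(m2$azimuth[1, 1]))

  # forward model at p = 0.5, alpha = 30 degrees
  iw <- 10 * (1 + 0.5 * cos(2 * (c(0, 45, 90, 135) - 30) * pi / 180))
  m3 <- compute_pixel_maps(pixel_stack(iw[1], iw[2], iw[3], iw[4]))
  expect_equal(m3$order[1, 1], 0.5, tolerance = 1e-14)
  expect_equal(m3$azimuth[1, 1], 30 * pi / 180, tolerance = 1e-14)
})

test_that("noiseless forward stacks are inverted to machine precision", {
  set.seed(21)
  for (rep in 1:5) {
    p <- matrix(runif(100), 10, 10)
    a <- matrix(runif(100, -pi / 2, pi / 2), 10, 10)
    A <- matrix(runif(100, 1, 500), 10, 10)
    m <- compute_pixel_maps(forward_stack(A, p, a))
    expect_lt(max(abs(m$order - p)), 1e-12)
    da <- abs(m$azimuth - a)
    expect_lt(max(pmin(da, pi - da)), 1e-10)
  }
})

test_that("order and azimuth are invariant under intensity scaling", {
  set.seed(22)
  st <- forward_stack(matrix(runif(64, 1, 100), 8, 8),
                      matrix(runif(64), 8, 8),
                      matrix(runif(64, -pi / 2, pi / 2), 8, 8),
                      background = 3)
  m1 <- compute_pixel_maps(st)
  for (c_scale in c(0.25, 7)) {
    st2 <- fpm_stack(lapply(st$images, function(x) x * c_scale),
                     pixel_size = st$pixel_size)
    m2 <- compute_pixel_maps(st2)
    expect_equal(m2$order, m1$order, tolerance = 1e-12)
    expect_equal(m2$azimuth, m1$azimuth, tolerance = 1e-12)
  }
})

test_that("flat-field correction: uniform flats are a no-op, gradients divide", {
  set.seed(23)
  img <- matrix(runif(64, 10, 100), 8, 8)
  st <- fpm_stack(list(img, img * 1.1, img * 0.9, img * 1.05))
  ones <- fpm_flat_stack(lapply(1:4, function(i) matrix(1, 8, 8)))
  expect_identical(flat_field_correct(st, ones)$images, st$images)
  const <- fpm_flat_stack(lapply(1:4, function(i) matrix(42.5, 8, 8)))
  expect_equal(flat_field_correct(st, const)$images, st$images,
               tolerance = 1e-12)
  # linear-gradient flat on a uniform image: brute-force quotient oracle
  grad <- matrix(rep(seq(1, 3, length.out = 8), each = 8), 8, 8)
  flat <- fpm_flat_stack(lapply(1:4, function(i) grad))
  uni <- fpm_stack(lapply(1:4, function(i) matrix(50, 8, 8)))
  got <- flat_field_correct(uni, flat)$images[[1]]
  oracle <- matrix(50, 8, 8) / (grad / mean(grad))
  expect_equal(got, oracle, tolerance = 1e-12)
  # averaging across multiple flat stacks
  f1 <- fpm_flat_stack(lapply(1:4, function(i) grad * 2))
  f2 <- fpm_flat_stack(lapply(1:4, function(i) grad * 4))
  got2 <- flat_field_correct(uni, list(f1, f2))$images[[1]]
  expect_equal(got2, oracle, tolerance = 1e-12)
  # errors
  expect_error(flat_field_correct(st, fpm_flat_stack(lapply(1:4, function(i)
    matrix(1, 4, 4)))), "dimensions")
})

test_that("sinusoid fit equals the closed form and a grid-search oracle", {
  f <- fit_pixel_sinusoid(c(2, 1, 0, 1))
  expect_equal(f$offset, 1)
  expect_equal(f$amplitude, 1)
  expect_equal(f$phase, 0)
  expect_equal(f$rss, 0, tolerance = 1e-20)

  f0 <- fit_pixel_sinusoid(c(1, 1, 1, 1))
  expect_equal(f0$amplitude, 0)
  expect_equal(f0$phase, 0)  # documented degenerate convention
  expect_equal(f0$rss, 0)

  set.seed(24)
  w <- c(0, 45, 90, 135) * pi / 180
  for (rep in 1:50) {
    iv <- runif(4, 0, 10)
    f <- fit_pixel_sinusoid(iv)
    m <- compute_pixel_maps(pixel_stack(iv[1], iv[2], iv[3], iv[4]))
    expect_equal(f$offset, m$S0[1, 1] / 2, tolerance = 1e-10)
    expect_equal(f$amplitude,
                 sqrt(m$S1[1, 1]^2 + m$S2[1, 1]^2) / 2, tolerance = 1e-10)
    if (f$amplitude > 1e-8) {
      da <- abs(f$phase - m$azimuth[1, 1])
      expect_lt(min(da, pi - da), 1e-10)
    }
  }
  # grid-search oracle confirms the least-squares minimum
  iv <- c(4.2, 1.3, 2.8, 5.1)
  f <- fit_pixel_sinusoid(iv)
  rss <- function(a, b, phi) sum((iv - (a + b * cos(2 * (w - phi))))^2)
  grid <- expand.grid(a = seq(f$offset - 1, f$offset + 1, length.out = 21),
                      b = seq(max(0, f$amplitude - 1), f$amplitude + 1,
                              length.out = 21),
                      phi = seq(-pi / 2, pi / 2, length.out = 181))
  gmin <- min(mapply(rss, grid$a, grid$b, grid$phi))
  expect_lte(f$rss, gmin + 1e-9)
})

test_that("custom statistics flow into maps and object means", {
  clear_custom_statistics()
  withr::defer(clear_custom_statistics())
  register_custom_statistic("total", function(I0, I45, I90, I135)
    I0 + I45 + I90 + I135)
  register_custom_statistic("one", function(I0, I45, I90, I135)
    matrix(1, nrow(I0), ncol(I0)))
  register_custom_statistic("p2", function(I0, I45, I90, I135) {
    S0 <- (I0 + I45 + I90 + I135) / 2
    (sqrt((I0 - I90)^2 + (I45 - I135)^2) / S0)^2
  })
  expect_error(register_custom_statistic("total", identity), "already registered")

  sc <- make_puncta_field(dim = c(64L, 64L), n = 4, seed = 5)
  st <- render_stack(sc)
  maps <- compute_pixel_maps(st)
  expect_equal(maps$custom$total, 2 * maps$S0, tolerance = 1e-12)
  seg <- segment_puncta(maps$S0)
  obj <- extract_features(seg, maps, st, compute_midlines = FALSE)
  expect_true(all(abs(obj$custom_one - 1) < 1e-12))
  # per-object mean of p^2 equals recomputation from the order map
  for (k in obj$object_id) {
    pix <- which(seg$labels == k)
    expect_equal(obj$custom_p2[obj$object_id == k],
                 mean(maps$order[pix]^2), tolerance = 1e-10)
  }
})
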