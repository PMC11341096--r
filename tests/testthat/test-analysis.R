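make_test_image <- function(seed, n = 10) {
  sc <- make_puncta_field(dim = c(96L, 96L), n = n,
                          noise = list(type = "poisson", gain = 1),
                          seed = seed)
  fpm_image(paste0("im", seed), render_stack(sc))
}

test_that("the pipeline populates the hierarchy deterministically", {
  proj <- fpm_project(list(
    fpm_group("ctrl", list(make_test_image(1), make_test_image(2))),
    fpm_group("treat", list(make_test_image(3)))))
  p1 <- run_pipeline(proj, config = list(compute_midlines = FALSE))
  p2 <- run_pipeline(proj, config = list(compute_midlines = FALSE))
  o1 <- project_objects(p1); o2 <- project_objects(p2)
  expect_gt(nrow(o1), 0)
  expect_identical(o1, o2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_object_table(o1, f1); write_object_table(o2, f2)
  expect_identical(readBin(f1, "raw", 1e7), readBin(f2, "raw", 1e7))
  # hierarchy integrity: every object's group/image pair exists, no orphans
  expect_setequal(unique(o1$group), c("ctrl", "treat"))
  for (g in p1$groups) for (im in g$images)
    expect_true(all(im$objects$image == im$name))
})

test_that("planted object counts are recovered across many images", {
  planted <- 0L; found <- 0L
  for (s in 1:6) {
    sc <- make_puncta_field(dim = c(96L, 96L), n = 12,
                            noise = list(type = "poisson", gain = 1),
                            seed = 100 + s)
    st <- render_stack(sc)
    seg <- segment_puncta(compute_pixel_maps(st)$S0)
    planted <- planted + 12L
    found <- found + max(seg$labels)
  }
  expect_lte(abs(found - planted) / planted, 0.02)
})

test_that("an image with empty segmentation yields 0 objects, pipeline continues", {
  blank <- fpm_image("blank",
                     fpm_stack(lapply(1:4, function(i) matrix(5, 48, 48))))
  proj <- fpm_project(list(fpm_group("g", list(blank, make_test_image(4)))))
  expect_warning(p <- run_pipeline(proj, config = list(compute_midlines = FALSE)),
                 "constant")
  objs <- project_objects(p)
  expect_true(all(objs$image == "im4"))
  expect_identical(nrow(p$groups[[1]]$images[[1]]$objects), 0L)
})

test_that("filtering is a conjunction over predicates and checks names", {
  df <- data.frame(area_px = c(5, 10, 20), length_um = c(1, 18, 30),
                   mean_order = c(0.1, 0.5, 0.9))
  expect_identical(filter_objects(df, list(list("area_px", ">=", 0))), df)
  both <- filter_objects(df, list(list("area_px", ">=", 10),
                                  list("mean_order", "<", 0.9)))
  single1 <- filter_objects(df, list(list("area_px", ">=", 10)))
  single2 <- filter_objects(df, list(list("mean_order", "<", 0.9)))
  expect_identical(rownames(both),
                   intersect(rownames(single1), rownames(single2)))
  expect_error(filter_objects(df, list(list("nope", ">", 1))), "unknown feature")
})

test_that("length labeling is inclusive at the cutoff and rejects bad rules", {
  df <- data.frame(length_um = c(17.4, 17.5, 3, 30))
  lab <- label_by_length(df)
  expect_identical(lab$label, c("short", "long", "short", "long"))
  expect_identical(label_by_length(df[0, , drop = FALSE]),
                   df[0, , drop = FALSE])
  expect_error(label_objects(df, list(a = list("length_um", ">=", 0),
                                      b = list("length_um", ">", 20))),
               "overlapping")
  expect_error(label_objects(df, list(a = list("length_um", ">", 100))),
               "cover")
})

test_that("the persistence-length filter recovers exactly the planted long set", {
  lengths <- c(6, 10, 14, 21, 26, 33)
  sc <- make_filament_scene(dim = c(256L, 256L), lengths_um = lengths, seed = 3)
  st <- render_stack(sc)
  maps <- compute_pixel_maps(st)
  seg <- segment_filaments(maps$S0)
  obj <- extract_features(seg, maps, st)
  expect_identical(nrow(obj), length(lengths))
  long <- filter_objects(obj, list(list("length_um", ">=", 17.5)))
  expect_identical(nrow(long), sum(lengths >= 17.5))
  # recovered long lengths pair up with the planted long lengths
  expect_equal(sort(long$length_um), sort(lengths[lengths >= 17.5]),
               tolerance = 0.1)
})

test_that("k-means clustering matches the 1-D exhaustive oracle and is stable", {
  df <- data.frame(local_sb = c(1, 1.1, 0.9, 10, 9, 11))
  out <- kmeans_cluster(df, "local_sb", k = 2, seed = 5)
  expect_identical(out$cluster_id, c(1L, 1L, 1L, 2L, 2L, 2L))

  set.seed(71)
  for (rep in 1:5) {
    x <- c(rnorm(12, 0, 1.5), rnorm(12, 6, 1.5))
    d <- data.frame(local_sb = x)
    got <- kmeans_cluster(d, "local_sb", k = 2, seed = rep)
    oracle_cut <- kmeans1d_oracle(x)$cut
    expect_identical(got$cluster_id, ifelse(x > oracle_cut, 2L, 1L))
  }
  # determinism under a fixed seed
  d <- data.frame(local_sb = rnorm(30))
  expect_identical(kmeans_cluster(d, "local_sb", seed = 3)$cluster_id,
                   kmeans_cluster(d, "local_sb", seed = 3)$cluster_id)
  # undefined features excluded with NA cluster
  d2 <- data.frame(local_sb = c(1, 2, NA, 10, 11))
  expect_warning(r2 <- kmeans_cluster(d2, "local_sb", seed = 1), "excluded")
  expect_true(is.na(r2$cluster_id[3]))
})

test_that("high-S/B cluster has the higher mean order (noise-bias ordering)", {
  sc_lo <- make_puncta_field(dim = c(96L, 96L), n = 10, amplitude = 90,
                             background = 30, seed = 81,
                             noise = list(type = "poisson", gain = 1))
  sc_hi <- make_puncta_field(dim = c(96L, 96L), n = 10, amplitude = 90,
                             background = 2, seed = 82,
                             noise = list(type = "poisson", gain = 1))
  feats <- do.call(rbind, lapply(list(sc_lo, sc_hi), function(sc) {
    st <- render_stack(sc)
    m <- compute_pixel_maps(st)
    lab <- matrix(0L, 96, 96)
    for (i in seq_along(sc$objects)) lab[sc$objects[[i]]$pixels] <- i
    seg <- fpmtools:::new_segmentation(lab > 0L, lab, "puncta", list())
    extract_features(seg, m, st, compute_midlines = FALSE)
  }))
  feats <- kmeans_cluster(feats, "local_sb", k = 2, seed = 2)
  m1 <- mean(feats$mean_order[feats$cluster_id == 1])
  m2 <- mean(feats$mean_order[feats$cluster_id == 2])
  expect_gt(m2, m1)
  # cluster 1 is the low-S/B cluster by construction
  expect_lt(mean(feats$local_sb[feats$cluster_id == 1]),
            mean(feats$local_sb[feats$cluster_id == 2]))
})
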