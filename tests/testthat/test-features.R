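cfg <- pcna_config()

make_disc_segment <- function(img, r = 20, c0 = 30) {
  mk <- disc_mask(nrow(img), ncol(img), list(c(c0, c0)), r)
  nucleus_segment(img, mk, 1L)
}

test_that("polar image of a uniform disc is constant and fully valid inside", {
  img <- matrix(5, 60, 60)
  seg <- make_disc_segment(img)
  pol <- to_polar(img, seg, 32L)
  expect_gte(nrow(pol$values), ceiling(2 * pi * pol$r_max))
  expect_true(all(abs(pol$values[pol$valid] - 5) < 1e-12))
  expect_gt(mean(pol$valid), 0.9)
})

test_that("rotation becomes a cyclic shift along the polar angle axis", {
  # quadrant-dependent image: rotating by 90 degrees permutes the pixels
  img <- matrix(10, 61, 61)
  img[1:30, 1:30] <- 40
  mk <- disc_mask(61, 61, list(c(31, 31)), 22)
  seg <- nucleus_segment(img, mk, 1L)
  pol <- to_polar(img, seg, 16L)
  rot <- t(img)[, rev(seq_len(61))]           # 90 degree rotation
  mkr <- t(mk)[, rev(seq_len(61))]; storage.mode(mkr) <- "integer"
  polr <- to_polar(rot, nucleus_segment(rot, mkr, 1L), 16L)
  n_ang <- nrow(polr$values)
  shift <- round(n_ang / 4)
  errs <- sapply(c(shift, n_ang - shift), function(s) {
    shifted <- polr$values[c((s + 1):n_ang, 1:s), ]
    ok <- pol$valid & !is.na(shifted)
    mean(abs(pol$values[ok] - shifted[ok]))
  })
  expect_lt(min(errs), 0.5)
})

test_that("polar column means track a radial gradient within 2%", {
  img0 <- matrix(5, 60, 60)
  seg <- make_disc_segment(img0)
  cx <- seg$centroid[["x"]]; cy <- seg$centroid[["y"]]
  xs <- matrix(rep(0:59, each = 60), 60); ys <- matrix(rep(0:59, 60), 60)
  img <- sqrt((xs - cx)^2 + (ys - cy)^2)
  pol <- to_polar(img, seg, 32L)
  radii <- (seq_len(32) - 0.5) / 32 * pol$r_max
  cm <- colMeans(pol$values, na.rm = TRUE)
  expect_true(all(abs(cm - radii) / pol$r_max < 0.02))
})

test_that("zone means read out the radial location of PCNA foci", {
  img <- matrix(5, 60, 60)
  seg <- make_disc_segment(img)
  expect_equal(zone_means(to_polar(img, seg, 32L), 4L), rep(5, 4))

  set.seed(2)
  spec <- scene_spec()
  late <- generate_nucleus("LATE_S", spec)
  seg_l <- nucleus_segment(late$texture, late$mask + 0L, 1L)
  zm_l <- zone_means(to_polar(late$texture, seg_l, cfg$n_radius), cfg$n_zones)
  expect_gt(zm_l[1], zm_l[cfg$n_zones])

  mid <- generate_nucleus("MID_S", spec)
  seg_m <- nucleus_segment(mid$texture, mid$mask + 0L, 1L)
  zm_m <- zone_means(to_polar(mid$texture, seg_m, cfg$n_radius), cfg$n_zones)
  expect_gt(max(zm_m[(cfg$n_zones - 2):cfg$n_zones]), zm_m[1])
  expect_error(zone_means(to_polar(img, seg, 32L), 1L), "n_zones")
})

test_that("basic histogram statistics match hand-computed values", {
  seg3 <- list(values = c(2, 2, 2)); class(seg3) <- "pcna_segment"
  f <- basic_histogram_features(seg3)
  expect_equal(unname(f), c(2, 2, 2, 0, 0, 0))

  seg123 <- list(values = c(1, 2, 3)); class(seg123) <- "pcna_segment"
  expect_equal(basic_histogram_features(seg123)[["skewness"]], 0)

  seg4 <- list(values = c(0, 0, 0, 1)); class(seg4) <- "pcna_segment"
  f4 <- basic_histogram_features(seg4)
  expect_equal(f4[["mean"]], 0.25)
  expect_equal(f4[["variance"]], 0.1875)

  seg1 <- list(values = 5); class(seg1) <- "pcna_segment"
  expect_error(basic_histogram_features(seg1), "2 pixels")
})

test_that("intensity histograms are normalized distributions", {
  ramp <- list(values = seq(0, 1, length.out = 6400))
  class(ramp) <- "pcna_segment"
  h <- intensity_histogram(ramp, 64L)
  expect_equal(sum(h), 1)
  expect_true(all(abs(h - 1 / 64) <= 1 / 6400 + 1e-12))

  two <- list(values = c(rep(3, 10), rep(9, 30))); class(two) <- "pcna_segment"
  h2 <- intensity_histogram(two, 64L)
  expect_equal(sum(h2 > 0), 2L)
  expect_equal(sum(h2), 1)

  set.seed(5)
  rnd <- list(values = runif(500)); class(rnd) <- "pcna_segment"
  expect_equal(sum(intensity_histogram(rnd)), 1)

  const <- list(values = rep(4, 10)); class(const) <- "pcna_segment"
  hc <- intensity_histogram(const, 64L)
  expect_equal(hc[1], 1)
})

test_that("surface curvature histogram reflects foci and flat regions", {
  flat <- matrix(7, 40, 40)
  mk <- disc_mask(40, 40, list(c(20, 20)), 14)
  seg <- nucleus_segment(flat, mk, 1L)
  h <- curvature_histogram(flat, seg, 1.5, 64L)
  expect_equal(sum(h), 1)
  expect_equal(h[33], 1)                       # all mass at zero curvature

  # one bright Gaussian focus: strongly negative curvature at the peak
  xs <- matrix(rep(0:39, each = 40), 40); ys <- matrix(rep(0:39, 40), 40)
  focus <- 50 * exp(-((xs - 19.5)^2 + (ys - 19.5)^2) / (2 * 2^2))
  hf <- curvature_histogram(focus + 7, seg, 1.5, 64L)
  expect_equal(sum(hf), 1)
  expect_gt(sum(hf[1:16]), 0)                  # mass in negative tail

  tiny <- nucleus_segment(flat, disc_mask(40, 40, list(c(20, 20)), 2), 1L)
  expect_error(curvature_histogram(flat, tiny, 1.5), "support")
})

test_that("GLCM matches brute-force pair counting on the worked grid", {
  p <- structure(list(values = matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE),
                      valid = matrix(TRUE, 2, 2)), class = "pcna_polar")
  gh <- glcm(p, 2L, 1L, "horizontal")
  expect_equal(unclass(gh)[1:4], c(0.5, 0, 0, 0.5), ignore_attr = TRUE)
  gv <- glcm(p, 2L, 1L, "vertical")
  expect_equal(unclass(gv)[1:4], c(0, 0.5, 0.5, 0), ignore_attr = TRUE)

  set.seed(9)
  pr <- structure(list(values = matrix(runif(900), 30, 30),
                       valid = matrix(runif(900) > 0.2, 30, 30)),
                  class = "pcna_polar")
  for (d in 1:2) for (dir in c("horizontal", "vertical"))
    expect_equal(sum(glcm(pr, 8L, d, dir)), 1)
  expect_error(glcm(p, 2L, 5L, "horizontal"), "offset")
})

test_that("Haralick features hit their degenerate and worked limits", {
  hc <- haralick_features(matrix(c(1, 0, 0, 0), 2))
  expect_equal(hc[["asm"]], 1)
  expect_equal(hc[["contrast"]], 0)
  expect_equal(hc[["entropy"]], 0)
  expect_equal(hc[["correlation"]], 1)         # zero-variance convention

  hd <- haralick_features(matrix(c(0.5, 0, 0, 0.5), 2))
  expect_equal(hd[["asm"]], 0.5)
  expect_equal(hd[["contrast"]], 0)

  ho <- haralick_features(matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(ho[["contrast"]], 1)
})

test_that("Haralick features agree with the direct-summation oracle", {
  set.seed(13)
  for (i in 1:25) {
    g <- random_glcm(8L)
    expect_equal(unname(haralick_features(g)), oracle_haralick(g),
                 tolerance = 1e-10)
  }
})

test_that("the polar Haralick vector has 104 dimensions in stable order", {
  set.seed(3)
  nu <- generate_nucleus("EARLY_S", scene_spec())
  seg <- nucleus_segment(nu$texture, nu$mask + 0L, 1L)
  v <- haralick_polar_vector(nu$texture, seg, cfg)
  expect_length(v, 104L)
  expect_true(all(is.finite(v)))
  expect_match(names(v)[1], "^har_inner_h_d1_")
  expect_match(names(v)[104], "^har_outer_v_d2_")
  v2 <- haralick_polar_vector(nu$texture, seg, cfg)
  expect_identical(v, v2)

  img <- matrix(5, 60, 60)
  mkd <- disc_mask(60, 60, list(c(30, 30)), 20)
  segd <- nucleus_segment(img, mkd, 1L)
  vd <- haralick_polar_vector(img, segd, cfg)
  expect_equal(vd[1:52], vd[53:104], ignore_attr = TRUE, tolerance = 0.05)
  expect_error(haralick_polar_vector(img, segd, pcna_config(n_radius = 4L)),
               "stripe")
})

test_that("feature sets assemble to their documented lengths", {
  set.seed(4)
  nu <- generate_nucleus("MID_S", scene_spec())
  img <- nu$texture; mk <- nu$mask + 0L
  seg <- nucleus_segment(img, mk, 1L)
  expect_length(assemble_features(img, seg, "proposed", cfg),
                6L + cfg$n_zones + 104L)
  expect_length(assemble_features(img, seg, "ersoy", cfg), 128L)
  expect_length(assemble_features(img, seg, "basic_hist", cfg,
                                  zones_in_basic = FALSE), 6L)
  expect_length(assemble_features(img, seg, "hist_intensity", cfg), 64L)
  expect_error(assemble_features(img, seg, "wavelet", cfg))
  expect_identical(assemble_features(img, seg, "proposed", cfg),
                   assemble_features(img, seg, "proposed", cfg))
})

test_that("histogram-family features are exactly invariant under 90-degree
           rotation and integer translation", {
  set.seed(3)
  for (ph in c("G", "LATE_S")) {
    nu <- generate_nucleus(ph, scene_spec())
    img <- nu$texture + 3; mk <- nu$mask + 0L
    seg <- nucleus_segment(img, mk, 1L)
    base_b <- assemble_features(img, seg, "basic_hist", cfg,
                                zones_in_basic = FALSE)
    base_e <- assemble_features(img, seg, "ersoy", cfg)

    rot <- t(img)[, rev(seq_len(ncol(img)))]
    mkr <- t(mk)[, rev(seq_len(ncol(mk)))]
    segr <- nucleus_segment(rot, mkr, 1L)
    expect_equal(assemble_features(rot, segr, "basic_hist", cfg,
                                   zones_in_basic = FALSE),
                 base_b, tolerance = 1e-8)
    expect_equal(assemble_features(rot, segr, "ersoy", cfg), base_e,
                 tolerance = 1e-8)

    big <- matrix(3, nrow(img) + 30, ncol(img) + 40)
    big[11:(10 + nrow(img)), 21:(20 + ncol(img))] <- img
    mkb <- matrix(0L, nrow(big), ncol(big))
    mkb[11:(10 + nrow(img)), 21:(20 + ncol(img))] <- mk
    segb <- nucleus_segment(big, mkb, 1L)
    expect_equal(assemble_features(big, segb, "basic_hist", cfg,
                                   zones_in_basic = FALSE),
                 base_b, tolerance = 1e-10)
    expect_equal(assemble_features(big, segb, "ersoy", cfg), base_e,
                 tolerance = 1e-8)
  }
})

test_that("feature_table returns one named row per nucleus", {
  set.seed(6)
  img <- matrix(5, 100, 170)
  mk <- matrix(0L, 100, 170)
  mk[disc_mask(100, 170, list(c(40, 50)), 18) == 1L] <- 1L
  mk[disc_mask(100, 170, list(c(120, 50)), 16) == 1L] <- 2L
  img <- img + matrix(runif(100 * 170, 0, 30), 100, 170)
  tab <- feature_table(img, mk, "basic_hist", cfg)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$segment_id, 1:2)
  expect_true("zone_mean_01" %in% names(tab))
})
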