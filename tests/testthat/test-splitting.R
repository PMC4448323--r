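cfg <- pcna_config()

test_that("contours of known shapes enclose the right area", {
  sq <- matrix(0L, 20, 20); sq[6:15, 6:15] <- 1L
  ct <- extract_contour(sq, 1L)
  expect_gte(nrow(ct$points), 8L)
  expect_lt(abs(abs(pcnaphase:::polygon_area(ct$points)) - 100), 6)

  d <- disc_mask(50, 50, list(c(25, 25)), 20)
  ctd <- extract_contour(d, 1L)
  expect_lt(abs(abs(pcnaphase:::polygon_area(ctd$points)) - pi * 400) / (pi * 400), 0.03)

  single <- matrix(0L, 5, 5); single[3, 3] <- 1L
  expect_error(extract_contour(single, 1L), "contour length")
  expect_error(extract_contour(sq, 9L), "not present")
})

test_that("curvature follows the closed forms: circle -1/r, straight ~ 0", {
  d <- disc_mask(60, 60, list(c(30, 30)), 22)
  k <- contour_curvature(extract_contour(d, 1L), 2)
  expect_lt(abs(mean(k) + 1 / 22.5) / (1 / 22.5), 0.1)
  expect_true(all(k < 0))

  sq <- matrix(0L, 40, 40); sq[5:35, 5:35] <- 1L
  ks <- contour_curvature(extract_contour(sq, 1L), 2)
  # most of a square's boundary is straight; corners are convex
  expect_lt(median(abs(ks)), 0.02)
  expect_lte(max(ks), 1e-6)
})

test_that("split points appear exactly at cluster necks", {
  ell <- ellipse_mask(50, 70, 35, 25, 25, 15)
  expect_equal(nrow(find_split_points(extract_contour(ell, 1L),
                                      cfg$kappa_min)), 0L)

  two <- disc_mask(60, 90, list(c(30, 30), c(60, 30)), 20)
  sp <- find_split_points(extract_contour(two, 1L), cfg$kappa_min)
  expect_equal(nrow(sp), 2L)
  # analytic intersection points of the two circles: (45, 30 +/- 13.2)
  expect_true(all(abs(sp$x - 45) < 3))
  expect_equal(sort(abs(sp$y - 30) - sqrt(400 - 225) < 3), c(TRUE, TRUE))

  three <- disc_mask(60, 130, list(c(30, 30), c(63, 30), c(96, 30)), 20)
  sp3 <- find_split_points(extract_contour(three, 1L), cfg$kappa_min)
  expect_equal(nrow(sp3), 4L)
})

test_that("constraint flags behave per definition", {
  two <- disc_mask(60, 90, list(c(30, 30), c(60, 30)), 20)
  ct <- extract_contour(two, 1L)
  sp <- find_split_points(ct, cfg$kappa_min)
  h <- check_constraints(ct, sp, matrix(1:2, 1), cfg)
  expect_true(all(h$flags))
  expect_true(h$admissible)
  expect_equal(length(h$parts), 2L)

  # kidney: disc minus off-center bite leaves two concavity shoulders whose
  # normals do not face each other across the object
  kid <- disc_mask(70, 70, list(c(35, 35)), 25)
  kid[disc_mask(70, 70, list(c(35, 8)), 18) == 1L] <- 0L
  ctk <- extract_contour(kid, 1L)
  spk <- find_split_points(ctk, cfg$kappa_min)
  if (nrow(spk) >= 2) {
    hk <- check_constraints(ctk, spk,
                            matrix(c(1L, nrow(spk)), 1), cfg)
    expect_false(hk$flags[["anti_parallel"]])
  }

  # undersized cluster: area < 2 * min_area
  small_cfg <- pcna_config(min_area = sum(two) / 1.5, max_area = 1e6)
  hs <- check_constraints(ct, sp, matrix(1:2, 1), small_cfg)
  expect_false(hs$flags[["size"]])
})

test_that("the neck split is the cheapest admissible hypothesis", {
  two <- disc_mask(60, 90, list(c(30, 30), c(60, 30)), 20)
  best <- oracle_best_pair_split(two, 1L, cfg)
  res <- split_cluster(two, 1L, cfg)
  expect_equal(res$n_parts, 2L)
  expect_equal(res$cost, best$cost)
  # the chosen chord is the neck (x ~ 45 for both endpoints)
  expect_identical(parts_signature(res$parts), parts_signature(best$parts))
})

test_that("hypothesis cost: lambda = 0 leaves only convexity deficits, and
           inadmissible hypotheses have no cost", {
  two <- disc_mask(60, 90, list(c(30, 30), c(60, 30)), 20)
  ct <- extract_contour(two, 1L)
  sp <- find_split_points(ct, cfg$kappa_min)
  h <- check_constraints(ct, sp, matrix(1:2, 1), cfg)
  c0 <- hypothesis_cost(h, ct, 0)
  deficits <- sum(vapply(h$parts, function(p)
    1 - pcnaphase:::pixel_solidity(p[, 1], p[, 2]), numeric(1)))
  expect_equal(c0, deficits)
  expect_gte(c0, 0)
  expect_gt(hypothesis_cost(h, ct, 0.5), c0)

  h_bad <- h; h_bad$admissible <- FALSE
  expect_error(hypothesis_cost(h_bad, ct), "admissible")
})

test_that("split_cluster resolves the canonical geometries", {
  ell <- ellipse_mask(50, 70, 35, 25, 25, 15)
  expect_equal(split_cluster(ell, 1L, cfg)$n_parts, 1L)

  two <- disc_mask(60, 90, list(c(30, 30), c(60, 30)), 20)
  r2 <- split_cluster(two, 1L, cfg)
  expect_equal(r2$n_parts, 2L)
  areas <- vapply(r2$parts, nrow, integer(1))
  expect_true(all(abs(areas - pi * 400) / (pi * 400) < 0.15))

  three <- disc_mask(60, 130, list(c(30, 30), c(63, 30), c(96, 30)), 20)
  r3 <- split_cluster(three, 1L, cfg)
  expect_equal(r3$n_parts, 3L)
})

test_that("splits conserve pixels: parts partition the object", {
  two <- disc_mask(60, 90, list(c(30, 30), c(58, 34)), 19)
  r <- split_cluster(two, 1L, cfg)
  all_px <- do.call(rbind, r$parts)
  keys <- all_px[, 1] * 1000 + all_px[, 2]
  expect_equal(length(keys), sum(two))
  expect_false(anyDuplicated(keys) > 0)
  lin <- which(two == 1L)
  truth_keys <- ((lin - 1) %/% nrow(two)) * 1000 + ((lin - 1) %% nrow(two))
  expect_setequal(keys, truth_keys)
})

test_that("split_cluster is invariant under translation and 90-degree rotation", {
  two <- disc_mask(60, 90, list(c(30, 30), c(60, 30)), 20)
  base <- split_cluster(two, 1L, cfg)

  shifted <- matrix(0L, 80, 120)
  shifted[13:72, 21:110] <- two
  rs <- split_cluster(shifted, 1L, cfg)
  expect_equal(rs$n_parts, base$n_parts)
  shifted_sig <- parts_signature(lapply(rs$parts, function(p)
    cbind(p[, 1] - 20L, p[, 2] - 12L)))
  expect_identical(shifted_sig, parts_signature(base$parts))

  rot <- t(two)[, rev(seq_len(nrow(two)))]
  storage.mode(rot) <- "integer"
  rr <- split_cluster(rot, 1L, cfg)
  expect_equal(rr$n_parts, base$n_parts)
  expect_equal(sort(vapply(rr$parts, nrow, integer(1))),
               sort(vapply(base$parts, nrow, integer(1))))
})

test_that("watershed splits round clusters but not circles", {
  two <- disc_mask(60, 90, list(c(30, 30), c(60, 30)), 20)
  w <- watershed_split(two, 1L)
  expect_equal(w$n_parts, 2L)
  areas <- vapply(w$parts, nrow, integer(1))
  expect_true(all(abs(areas - pi * 400) / (pi * 400) < 0.15))
  expect_equal(sum(areas), sum(two))

  circ <- disc_mask(50, 50, list(c(25, 25)), 20)
  expect_equal(watershed_split(circ, 1L)$n_parts, 1L)
  expect_error(watershed_split(circ, 9L), "not present")
})

test_that("watershed over-splits fringy single ellipses more than the
           geometric method", {
  set.seed(11)
  n <- 40L
  geo <- ws <- 0L
  for (i in seq_len(n)) {
    m <- noisy_ellipse_mask(runif(1, 12, 18), runif(1, 12, 18), 1.5)
    geo <- geo + (split_cluster(m, 1L, cfg)$n_parts > 1L)
    ws <- ws + (watershed_split(m, 1L)$n_parts > 1L)
  }
  expect_gt(ws, 0L)
  expect_lte(geo, ws)
})

test_that("split_all_clusters rebuilds a contiguous raster-ordered mask", {
  m <- matrix(0L, 60, 160)
  m[disc_mask(60, 160, list(c(30, 30), c(60, 30)), 18) == 1L] <- 1L
  m[disc_mask(60, 160, list(c(120, 30)), 16) == 1L] <- 2L
  out <- split_all_clusters(m, cfg, "geometric")
  expect_equal(max(out), 3L)
  expect_equal(sort(unique(as.vector(out))), 0:3)
  expect_equal(sum(out > 0L), sum(m > 0L))
})
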