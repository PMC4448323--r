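#' Nucleus segment
#'
#' Bundles one segmented nucleus: its pixel set, centroid, bounding box and
#' the source image intensities restricted to the mask. All downstream
#' features are computed from this object.
#'
#' @param image a [pcna_image()] or matrix.
#' @param labels integer label matrix.
#' @param label the nucleus label.
#' @return object of class `pcna_segment` with fields `id`, `pixels` (n x 2,
#'   0-based `(x, y)`), `centroid`, `bbox` (`x0, y0, x1, y1`), `values`.
#' @export
nucleus_segment <- function(image, labels, label) {
  px <- as_pixel_matrix(image)
  labels <- as.matrix(labels)
  if (!identical(dim(px), dim(labels)))
    stop("image and label mask dimensions differ")
  nr <- nrow(labels)
  lin <- which(labels == label)
  if (!length(lin)) stop("label ", label, " not present in mask")
  xs <- (lin - 1L) %/% nr
  ys <- (lin - 1L) %% nr
  structure(list(id = label,
                 pixels = cbind(x = xs, y = ys),
                 centroid = c(x = mean(xs), y = mean(ys)),
                 bbox = c(x0 = min(xs), y0 = min(ys),
                          x1 = max(xs), y1 = max(ys)),
                 values = px[lin]),
            class = "pcna_segment")
}

#' @export
print.pcna_segment <- function(x, ...) {
  cat(sprintf("pcna_segment %s: %d px, centroid (%.1f, %.1f)\n",
              format(x$id), nrow(x$pixels), x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Polar resampling of a nucleus
#'
#' Resamples the nucleus onto a (radius, angle) grid centered at its
#' centroid: radius on the x axis (`n_radius` columns spanning `(0, r_max]`),
#' angle on the y axis. The angle axis is sampled at `n_angle >= ceil(2 pi
#' r_max)` rows, fine enough that every pixel of the segment is visited at
#' least once; a rotation of the nucleus becomes a cyclic shift along the
#' angle axis, which is what makes features computed on this grid rotation
#' invariant. Samples falling outside the segment mask are flagged invalid
#' and excluded from every downstream statistic.
#'
#' @param image a [pcna_image()] or matrix.
#' @param segment a [nucleus_segment()].
#' @param n_radius number of radius samples.
#' @return object of class `pcna_polar`: `values` (n_angle x n_radius,
#'   bilinear samples), `valid` (logical), `center`, `r_max`.
#' @export
to_polar <- function(image, segment, n_radius = 32L) {
  px <- as_pixel_matrix(image)
  if (!nrow(segment$pixels)) stop("zero-area segment")
  cx <- segment$centroid[["x"]]; cy <- segment$centroid[["y"]]
  r_max <- sqrt(max((segment$pixels[, 1] - cx)^2 +
                    (segment$pixels[, 2] - cy)^2)) + 0.5
  n_angle <- max(32L, ceiling(2 * pi * r_max))
  radii <- (seq_len(n_radius) - 0.5) / n_radius * r_max
  angles <- 2 * pi * (seq_len(n_angle) - 1L) / n_angle
  xs <- cx + outer(cos(angles), radii)
  ys <- cy + outer(sin(angles), radii)
  mask <- matrix(FALSE, nrow(px), ncol(px))
  mask[cbind(segment$pixels[, 2] + 1L, segment$pixels[, 1] + 1L)] <- TRUE
  vals <- matrix(bilinear_sample(px, as.vector(xs), as.vector(ys)),
                 n_angle, n_radius)
  valid <- matrix(mask_at(mask, as.vector(xs), as.vector(ys)),
                  n_angle, n_radius)
  vals[!valid] <- NA_real_
  structure(list(values = vals, valid = valid, center = c(cx, cy),
                 r_max = r_max),
            class = "pcna_polar")
}

#' Radial zone means
#'
#' Mean intensity of the valid polar samples in each of `n_zones` equal-width
#' radius bands, ordered inner to outer. These zone means summarize the
#' radial location distribution of the PCNA foci: peripheral (mid S) patterns
#' raise the outer zones, central (late S) patterns the inner ones.
#'
#' @param polar a [to_polar()] result.
#' @param n_zones number of radial bands (>= 2).
#' @return numeric vector of length `n_zones`. A band with no valid samples
#'   borrows the nearest valid band's value (and the event is logged).
#' @export
zone_means <- function(polar, n_zones = 8L) {
  if (n_zones < 2L) stop("n_zones must be at least 2")
  n_radius <- ncol(polar$values)
  zone_of <- ceiling(seq_len(n_radius) / n_radius * n_zones)
  m <- vapply(seq_len(n_zones), function(z) {
    v <- polar$values[, zone_of == z, drop = FALSE]
    mean(v[!is.na(v)])
  }, numeric(1))
  if (anyNA(m) || any(is.nan(m))) {
    bad <- which(!is.finite(m)); good <- which(is.finite(m))
    if (!length(good)) stop("no valid polar samples in any zone")
    for (z in bad) m[z] <- m[good[which.min(abs(good - z))]]
    pcna_log("features", "%d empty zone(s) borrowed nearest valid value",
             length(bad))
  }
  m
}

#' Basic histogram statistics of a nucleus
#'
#' Minimum, maximum, mean, population variance, skewness and excess kurtosis
#' of the masked intensity sample. A zero-variance segment yields skewness
#' and kurtosis 0 by convention, keeping the vector finite.
#'
#' @param segment a [nucleus_segment()] (>= 2 pixels).
#' @return named numeric vector of length 6.
#' @export
basic_histogram_features <- function(segment) {
  v <- segment$values
  if (length(v) < 2L) stop("segment must have at least 2 pixels")
  m <- mean(v)
  v2 <- mean((v - m)^2)
  if (v2 > 0) {
    skew <- mean((v - m)^3) / v2^1.5
    kurt <- mean((v - m)^4) / v2^2 - 3
  } else skew <- kurt <- 0
  c(min = min(v), max = max(v), mean = m, variance = v2,
    skewness = skew, kurtosis = kurt)
}

#' Normalized intensity histogram of a nucleus
#'
#' Min-max normalizes the masked intensities and bins them into `n_bins`
#' equal bins; frequencies are normalized to sum to 1 so the vector is a
#' discrete distribution. A constant segment puts all mass in bin 1.
#'
#' @param segment a [nucleus_segment()].
#' @param n_bins number of bins (default 64).
#' @return numeric vector of length `n_bins`, summing to 1.
#' @export
intensity_histogram <- function(segment, n_bins = 64L) {
  v <- segment$values
  if (!length(v)) stop("empty segment")
  rng <- range(v)
  if (rng[2] <= rng[1]) {
    pcna_log("features", "constant segment: histogram collapses to bin 1")
    h <- numeric(n_bins); h[1] <- 1
    return(h)
  }
  u <- (v - rng[1]) / (rng[2] - rng[1])
  bins <- pmin(floor(u * n_bins) + 1L, n_bins)
  tabulate(bins, nbins = n_bins) / length(v)
}

#' Histogram of intensity surface curvature
#'
#' Treats the image as a surface and computes, at every masked pixel, the two
#' principal curvatures (eigenvalues of the Gaussian-derivative Hessian at
#' scale `sigma`). Bright foci produce strongly negative curvature at their
#' peaks, ridges one negative and one near-zero eigenvalue, homogeneous
#' regions near-zero curvature, so the pooled eigenvalue histogram is a
#' compact texture descriptor. Both eigenvalues are pooled, clipped to a
#' symmetric range at the 99th percentile of their absolute value, binned
#' into `n_bins` bins and normalized to sum 1.
#'
#' @param image a [pcna_image()] or matrix.
#' @param segment a [nucleus_segment()].
#' @param sigma Gaussian derivative scale in pixels (> 0).
#' @param n_bins number of bins (default 64).
#' @return numeric vector of length `n_bins`, summing to 1.
#' @export
curvature_histogram <- function(image, segment, sigma = 1.5, n_bins = 64L) {
  if (sigma <= 0) stop("sigma must be > 0")
  px <- as_pixel_matrix(image)
  bb <- segment$bbox
  if (bb["x1"] - bb["x0"] < 4 * sigma || bb["y1"] - bb["y0"] < 4 * sigma)
    stop("segment smaller than the 4 sigma filter support")
  # crop exactly the bounding box (replicate-padded inside the filters), so
  # the feature depends only on the segment's own pixels and is exactly
  # translation invariant by construction
  x0 <- bb[["x0"]]; x1 <- bb[["x1"]]
  y0 <- bb[["y0"]]; y1 <- bb[["y1"]]
  crop <- px[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)]
  g0 <- gaussian_kernel_1d(sigma, 0L)
  g2 <- gaussian_kernel_1d(sigma, 2L)
  g1 <- gaussian_kernel_1d(sigma, 1L)
  ixx <- conv2_sep(crop, g0, g2)               # d2/dx2 along columns (x)
  iyy <- conv2_sep(crop, g2, g0)
  ixy <- conv2_sep(crop, g1, g1)
  idx <- cbind(segment$pixels[, 2] - y0 + 1L, segment$pixels[, 1] - x0 + 1L)
  a <- ixx[idx]; b <- iyy[idx]; c_ <- ixy[idx]
  disc <- sqrt(pmax((a - b)^2 / 4 + c_^2, 0))
  k <- c((a + b) / 2 + disc, (a + b) / 2 - disc)
  cl <- stats::quantile(abs(k), 0.99, names = FALSE)
  if (cl <= 1e-9) {                             # flat surface: delta at zero
    h <- numeric(n_bins); h[n_bins %/% 2 + 1L] <- 1
    return(h)
  }
  k <- pmin(pmax(k, -cl), cl)
  u <- (k + cl) / (2 * cl)
  bins <- pmin(floor(u * n_bins) + 1L, n_bins)
  tabulate(bins, nbins = n_bins) / length(k)
}

#' Gray-level co-occurrence matrix of a polar image
#'
#' Bins the valid polar samples to `levels` gray levels (equal-width bins
#' over their range) and counts co-occurring level pairs at offset `d` along
#' the chosen polar axis: `"horizontal"` pairs along the radius axis,
#' `"vertical"` along the angle axis. Only pairs whose both samples are valid
#' contribute. Counts are symmetrized and normalized to sum 1.
#'
#' @param polar a [to_polar()] result.
#' @param levels number of gray levels (>= 2).
#' @param d pair offset in samples (>= 1).
#' @param direction `"horizontal"` (radius) or `"vertical"` (angle).
#' @return a `levels x levels` matrix of class `pcna_glcm`.
#' @export
glcm <- function(polar, levels = 32L, d = 1L,
                 direction = c("horizontal", "vertical")) {
  direction <- match.arg(direction)
  if (levels < 2L) stop("levels must be at least 2")
  if (d < 1L) stop("d must be at least 1")
  v <- polar$values
  ok <- polar$valid
  vv <- v[ok]
  if (!length(vv)) stop("polar image has no valid samples")
  # robust intensity range: the 1st-99th percentile band; extremes are
  # clamped so that single hot samples do not swallow the level resolution
  rng <- stats::quantile(vv, c(0.01, 0.99), names = FALSE)
  q <- matrix(NA_integer_, nrow(v), ncol(v))
  if (rng[2] > rng[1]) {
    u <- pmin(pmax(v[ok], rng[1]), rng[2])
    q[ok] <- pmin(floor((u - rng[1]) / (rng[2] - rng[1]) * levels) + 1L,
                  levels)
  } else q[ok] <- 1L
  if (direction == "horizontal") {
    if (ncol(q) <= d) stop("no valid pairs: offset exceeds radius samples")
    a <- q[, seq_len(ncol(q) - d), drop = FALSE]
    b <- q[, (d + 1L):ncol(q), drop = FALSE]
  } else {
    if (nrow(q) <= d) stop("no valid pairs: offset exceeds angle samples")
    a <- q[seq_len(nrow(q) - d), , drop = FALSE]
    b <- q[(d + 1L):nrow(q), , drop = FALSE]
  }
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("no valid pixel pairs for GLCM")
  ai <- a[keep]; bi <- b[keep]
  counts <- matrix(tabulate((ai - 1L) * levels + bi, nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  counts <- counts + t(counts)
  structure(counts / sum(counts), class = c("pcna_glcm", "matrix"),
            d = d, direction = direction)
}

#' Haralick texture statistics of a GLCM
#'
#' The 13 classical Haralick features of a normalized gray-level
#' co-occurrence matrix: angular second moment, contrast, correlation, sum of
#' squares variance, inverse difference moment, sum average, sum variance,
#' sum entropy, entropy, difference variance, difference entropy, and the two
#' information measures of correlation. The 14th feature (maximal correlation
#' coefficient) is excluded for numerical stability. Entropies use the
#' natural logarithm with the `0 log 0 = 0` convention; gray levels are
#' indexed from 0. Degenerate denominators are mapped to finite values: a
#' zero-variance GLCM has correlation 1 and information measure 1 equal to 0.
#'
#' @param g a [glcm()] result (any non-negative matrix summing to 1).
#' @return named numeric vector of length 13.
#' @export
haralick_features <- function(g) {
  p <- unclass(as.matrix(g))
  l <- nrow(p)
  i <- matrix(0:(l - 1L), l, l)               # row level index
  j <- t(i)
  px_ <- rowSums(p); py_ <- colSums(p)
  lev <- 0:(l - 1L)
  mu_x <- sum(lev * px_); mu_y <- sum(lev * py_)
  sd_x <- sqrt(sum((lev - mu_x)^2 * px_)); sd_y <- sqrt(sum((lev - mu_y)^2 * py_))
  plog <- function(z) ifelse(z > 0, log(z), 0)
  # sum and difference distributions
  psum <- vapply(0:(2L * l - 2L), function(k) sum(p[i + j == k]), numeric(1))
  pdif <- vapply(0:(l - 1L), function(k) sum(p[abs(i - j) == k]), numeric(1))
  asm <- sum(p^2)
  contrast <- sum((0:(l - 1L))^2 * pdif)
  correlation <- if (sd_x > 0 && sd_y > 0)
    (sum(i * j * p) - mu_x * mu_y) / (sd_x * sd_y) else 1
  variance <- sum((i - mu_x)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  ks <- 0:(2L * l - 2L)
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- -sum(psum * plog(psum))
  entropy <- -sum(p * plog(p))
  mu_d <- sum((0:(l - 1L)) * pdif)
  difference_variance <- sum(((0:(l - 1L)) - mu_d)^2 * pdif)
  difference_entropy <- -sum(pdif * plog(pdif))
  hx <- -sum(px_ * plog(px_)); hy <- -sum(py_ * plog(py_))
  pxy <- outer(px_, py_)
  hxy1 <- -sum(p * plog(pxy))
  hxy2 <- -sum(pxy * plog(pxy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - entropy)), 0))
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy,
    entropy = entropy, difference_variance = difference_variance,
    difference_entropy = difference_entropy, imc1 = imc1, imc2 = imc2)
}

#' Rotation-invariant Haralick vector on the polar image
#'
#' Computes the polar image of the nucleus, splits it into two equal-width
#' radius stripes (inner, outer), and for every combination of stripe,
#' direction (horizontal = along radius, vertical = along angle) and pair
#' distance in `config$glcm_distances` evaluates the 13 Haralick statistics:
#' 2 stripes x 2 directions x 2 distances x 13 features = 104 values in a
#' fixed, named order. Because the GLCMs live on the polar grid, rotating the
#' nucleus only shifts the angle axis cyclically and the features are
#' invariant up to resampling error.
#'
#' @param image a [pcna_image()] or matrix.
#' @param segment a [nucleus_segment()].
#' @param config a [pcna_config()].
#' @return named numeric vector of length
#'   `2 * 2 * length(glcm_distances) * 13` (104 with defaults).
#' @export
haralick_polar_vector <- function(image, segment, config = pcna_config()) {
  polar <- to_polar(image, segment, config$n_radius)
  half <- config$n_radius %/% 2L
  if (half <= max(config$glcm_distances))
    stop("polar stripe narrower than the maximal GLCM distance")
  stripes <- list(inner = seq_len(half),
                  outer = (half + 1L):config$n_radius)
  out <- numeric(0)
  for (s in names(stripes)) {
    sub <- structure(list(values = polar$values[, stripes[[s]], drop = FALSE],
                          valid = polar$valid[, stripes[[s]], drop = FALSE]),
                     class = "pcna_polar")
    for (dir in c("horizontal", "vertical")) {
      for (d in config$glcm_distances) {
        f <- haralick_features(glcm(sub, config$glcm_levels, d, dir))
        names(f) <- paste("har", s, substr(dir, 1, 1), paste0("d", d),
                          names(f), sep = "_")
        out <- c(out, f)
      }
    }
  }
  out
}

#' Assemble a named feature vector for a nucleus
#'
#' The available feature sets:
#' \describe{
#'   \item{basic_hist}{6 basic histogram statistics plus `n_zones` radial
#'     zone means (set `zones_in_basic = FALSE` to drop the zone means).}
#'   \item{haralick_polar}{the 104-dimensional polar Haralick vector.}
#'   \item{hist_intensity}{64-bin intensity histogram.}
#'   \item{hist_curvature}{64-bin intensity surface curvature histogram.}
#'   \item{proposed}{`basic_hist` followed by `haralick_polar` — the
#'     combination this pipeline advocates.}
#'   \item{ersoy}{`hist_intensity` followed by `hist_curvature` — the
#'     intensity + curvature histogram reference set.}
#' }
#'
#' @param image a [pcna_image()] or matrix.
#' @param segment a [nucleus_segment()].
#' @param feature_set_id one of the ids above.
#' @param config a [pcna_config()].
#' @param zones_in_basic include radial zone means in `basic_hist`.
#' @return named numeric vector with attribute `feature_set_id`.
#' @export
assemble_features <- function(image, segment,
                              feature_set_id = c("proposed", "ersoy",
                                                 "basic_hist",
                                                 "haralick_polar",
                                                 "hist_intensity",
                                                 "hist_curvature"),
                              config = pcna_config(), zones_in_basic = TRUE) {
  feature_set_id <- match.arg(feature_set_id)
  basic <- function() {
    f <- basic_histogram_features(segment)
    if (zones_in_basic) {
      z <- zone_means(to_polar(image, segment, config$n_radius),
                      config$n_zones)
      names(z) <- sprintf("zone_mean_%02d", seq_along(z))
      f <- c(f, z)
    }
    f
  }
  ihist <- function() {
    h <- intensity_histogram(segment, config$hist_bins)
    stats::setNames(h, sprintf("int_hist_%02d", seq_along(h)))
  }
  chist <- function() {
    h <- curvature_histogram(image, segment, config$curvature_sigma,
                             config$hist_bins)
    stats::setNames(h, sprintf("curv_hist_%02d", seq_along(h)))
  }
  out <- switch(feature_set_id,
                basic_hist = basic(),
                haralick_polar = haralick_polar_vector(image, segment, config),
                hist_intensity = ihist(),
                hist_curvature = chist(),
                proposed = c(basic(),
                             haralick_polar_vector(image, segment, config)),
                ersoy = c(ihist(), chist()))
  if (!all(is.finite(out)))
    stop("non-finite feature value in set ", feature_set_id)
  attr(out, "feature_set_id") <- feature_set_id
  out
}

#' Feature table for all nuclei of a label mask
#'
#' @param image a [pcna_image()] or matrix.
#' @param labels integer label matrix.
#' @param feature_set_id see [assemble_features()].
#' @param config a [pcna_config()].
#' @return data.frame with a `segment_id` column followed by one named
#'   feature column per dimension; one row per labeled nucleus.
#' @export
feature_table <- function(image, labels, feature_set_id = "proposed",
                          config = pcna_config()) {
  k <- max(labels)
  rows <- vector("list", k)
  for (l in seq_len(k)) {
    seg <- nucleus_segment(image, labels, l)
    rows[[l]] <- assemble_features(image, seg, feature_set_id, config)
  }
  tab <- as.data.frame(do.call(rbind, rows))
  cbind(segment_id = seq_len(k), tab)
}
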