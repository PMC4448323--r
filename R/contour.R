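#' Extract the outer contour of a labeled object
#'
#' Traces the outer boundary of one labeled component (Moore neighbor
#' tracing over pixel centers, holes ignored) and resamples it to a closed
#' polyline with uniform ~1 px vertex spacing and sub-pixel vertex positions.
#' Vertices are ordered counter-clockwise in the mathematical frame (y up),
#' i.e. the object interior lies to the left of the walking direction when
#' plotted with the y axis pointing up.
#'
#' @param labels integer label matrix.
#' @param label label to trace; must be present.
#' @return object of class `pcna_contour`: list with `points` (n x 2 matrix
#'   of 0-based `(x, y)`), `source_label`, and the object's binary `mask`.
#' @export
extract_contour <- function(labels, label) {
  labels <- as.matrix(labels)
  mask <- labels == label
  if (!any(mask)) stop("label ", label, " not present in mask")
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  row <- ((fg - 1L) %% nr) + 1L
  col <- ((fg - 1L) %/% nr) + 1L
  ord <- order(row, col)                       # raster scan: y, then x
  sr <- row[ord[1]]; sc <- col[ord[1]]
  # Moore tracing, clockwise on screen (y down) == CCW in the y-up frame.
  dx <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)   # E SE S SW W NW N NE
  dy <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]
  cr <- sr; cc <- sc; d <- 0L                  # entered start moving E from W
  px <- integer(0); py <- integer(0)
  d_first <- NA_integer_
  max_steps <- 4L * length(fg) + 8L
  for (step in seq_len(max_steps)) {
    px <- c(px, cc - 1L); py <- c(py, cr - 1L)
    found <- FALSE
    s0 <- (d + 6L) %% 8L
    for (k in 0:7) {
      dd <- (s0 + k) %% 8L
      r2 <- cr + dy[dd + 1L]; c2 <- cc + dx[dd + 1L]
      if (inside(r2, c2)) {
        cr <- r2; cc <- c2; d <- dd; found <- TRUE
        break
      }
    }
    if (!found) break                          # isolated pixel
    if (is.na(d_first)) d_first <- d
    else if (cr == sr && cc == sc && d == d_first) break
  }
  pts <- cbind(x = px, y = py)
  pts <- resample_closed(pts)
  if (nrow(pts) < 8L)
    stop("object ", label, " is below the minimum contour length")
  # enforce CCW in the y-up frame: signed area in stored (y-down) coords < 0
  if (polygon_area(pts) > 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  # push vertices half a pixel outward so the polyline follows the pixel
  # boundary (half-pixel resolution) instead of the pixel centers
  xs <- smooth_circular(pts[, 1], 1); ys <- smooth_circular(pts[, 2], 1)
  xp <- circ_diff1(xs); yp <- circ_diff1(ys)
  tl <- pmax(sqrt(xp^2 + yp^2), .Machine$double.eps)
  pts[, 1] <- pts[, 1] - 0.5 * yp / tl         # outward = -(inward normal)
  pts[, 2] <- pts[, 2] + 0.5 * xp / tl
  structure(list(points = pts, source_label = label, mask = mask),
            class = "pcna_contour")
}

# Resample a closed polyline to uniform arc-length spacing of ~1 px.
resample_closed <- function(pts, spacing = 1) {
  pts <- pts[!duplicated(pts), , drop = FALSE]
  n <- nrow(pts)
  if (n < 3L) return(pts)
  closed <- rbind(pts, pts[1L, ])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  m <- max(8L, round(total / spacing))
  at <- seq(0, total, length.out = m + 1L)[-(m + 1L)]
  cbind(x = stats::approx(s, closed[, 1], xout = at)$y,
        y = stats::approx(s, closed[, 2], xout = at)$y)
}

#' @export
print.pcna_contour <- function(x, ...) {
  cat(sprintf("pcna_contour of label %d: %d vertices, enclosed area %.1f px\n",
              x$source_label, nrow(x$points), abs(polygon_area(x$points))))
  invisible(x)
}

# Circular Gaussian smoothing of a periodic signal.
smooth_circular <- function(v, sigma) {
  if (sigma <= 0) return(v)
  n <- length(v)
  g <- gaussian_kernel_1d(sigma, 0L)
  if (length(g) >= n) {                        # clip overlong kernels
    r <- (n - 1L) %/% 2L
    mid <- (length(g) + 1L) %/% 2L
    g <- g[(mid - r):(mid + r)]
    g <- g / sum(g)
  }
  as.numeric(stats::filter(v, g, method = "convolution", sides = 2,
                           circular = TRUE))
}

#' Signed curvature along a contour
#'
#' Per-vertex signed curvature of the Gaussian-smoothed closed polyline, in
#' 1/pixels. The sign convention is concave-positive: indentations of the
#' object (the necks between touching nuclei) have positive curvature, and a
#' convex circle of radius r has curvature ~ -1/r everywhere.
#'
#' @param contour a [extract_contour()] result.
#' @param smoothing_scale Gaussian smoothing sigma in vertices (~pixels);
#'   `0` disables smoothing.
#' @return numeric vector of length `nrow(contour$points)`.
#' @export
contour_curvature <- function(contour, smoothing_scale = 2) {
  if (smoothing_scale < 0) stop("smoothing_scale must be >= 0")
  x <- smooth_circular(contour$points[, 1], smoothing_scale)
  y <- smooth_circular(contour$points[, 2], smoothing_scale)
  xp <- circ_diff1(x); yp <- circ_diff1(y)
  xpp <- circ_diff2(x); ypp <- circ_diff2(y)
  den <- (xp^2 + yp^2)^1.5
  k <- (xp * ypp - yp * xpp) / pmax(den, .Machine$double.eps)
  # stored y runs downward, so CCW-in-y-up contours make this convex-negative
  k
}

circ_diff1 <- function(v) {
  n <- length(v)
  (v[c(2:n, 1L)] - v[c(n, 1:(n - 1L))]) / 2
}

circ_diff2 <- function(v) {
  n <- length(v)
  v[c(2:n, 1L)] - 2 * v + v[c(n, 1:(n - 1L))]
}

#' Detect candidate split points on a contour
#'
#' Split points are local maxima of concave (positive) curvature exceeding
#' `kappa_min`, after non-maximum suppression within a circular window of
#' `window` vertices on each side. Each point carries its inward unit normal,
#' used by the anti-parallel pairing constraint.
#'
#' @param contour a [extract_contour()] result.
#' @param kappa_min concavity threshold (1/pixels).
#' @param smoothing_scale passed to [contour_curvature()].
#' @param window non-maximum-suppression half-window in vertices.
#' @return data.frame with columns `contour_index`, `x`, `y`, `curvature`,
#'   `normal_x`, `normal_y`; zero rows for convex objects.
#' @export
find_split_points <- function(contour, kappa_min = 0.15, smoothing_scale = 2,
                              window = 5L) {
  k <- contour_curvature(contour, smoothing_scale)
  n <- length(k)
  cand <- which(k > kappa_min)
  keep <- logical(n)
  for (i in cand) {
    idx <- ((i - 1L + seq(-window, window)) %% n) + 1L
    if (k[i] >= max(k[idx])) {
      tied <- idx[k[idx] == k[i]]              # tie-break: lowest index wins
      keep[i] <- i == min(tied)
    }
  }
  sel <- which(keep)
  pts <- contour$points
  x <- smooth_circular(pts[, 1], smoothing_scale)
  y <- smooth_circular(pts[, 2], smoothing_scale)
  xp <- circ_diff1(x); yp <- circ_diff1(y)
  out <- data.frame(contour_index = sel,
                    x = pts[sel, 1], y = pts[sel, 2],
                    curvature = k[sel],
                    normal_x = rep(NA_real_, length(sel)),
                    normal_y = rep(NA_real_, length(sel)))
  for (j in seq_along(sel)) {
    i <- sel[j]
    tl <- sqrt(xp[i]^2 + yp[i]^2)
    if (tl < .Machine$double.eps) next
    nx <- yp[i] / tl; ny <- -xp[i] / tl       # inward for this orientation
    # verify against the mask; flip if the geometric rule points outside
    if (!mask_at(contour$mask, out$x[j] + 2 * nx, out$y[j] + 2 * ny) &&
        mask_at(contour$mask, out$x[j] - 2 * nx, out$y[j] - 2 * ny)) {
      nx <- -nx; ny <- -ny
    }
    out$normal_x[j] <- nx; out$normal_y[j] <- ny
  }
  out[!is.na(out$normal_x), , drop = FALSE]
}
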