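# Internal numeric helpers shared across modules.

# 1-D Gaussian kernel (order 0) or its first/second derivative, truncated at
# 4 sigma and normalized so that order 0 sums to 1, order 1 responds with
# slope 1 to a unit ramp, and order 2 with 2 to a unit parabola.
gaussian_kernel_1d <- function(sigma, order = 0L) {
  if (sigma <= 0) stop("sigma must be > 0")
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
         "0" = g,
         "1" = {
           k <- -x / sigma^2 * g
           k - mean(k)
         },
         "2" = {
           k <- (x^2 - sigma^2) / sigma^4 * g
           k - mean(k)
         },
         stop("order must be 0, 1 or 2"))
}

# Separable 2-D convolution with replicate boundary; ky runs along rows (y),
# kx along columns (x). Kernels longer than the image are truncated (and
# renormalized when they are plain smoothing kernels).
conv2_sep <- function(img, ky, kx) {
  clip <- function(k, n) {
    if (length(k) <= n) return(k)
    r <- (n - 1L) %/% 2L
    mid <- (length(k) + 1L) %/% 2L
    k2 <- k[(mid - r):(mid + r)]
    if (all(k >= 0)) k2 / sum(k2) else k2 - mean(k2)
  }
  ky <- clip(ky, nrow(img)); kx <- clip(kx, ncol(img))
  EBImage::filter2(img, outer(ky, kx), boundary = "replicate")
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  g <- gaussian_kernel_1d(sigma, 0L)
  conv2_sep(img, g, g)
}

# Vectorized bilinear sampling at 0-based (x, y); NA outside the image.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= nc - 1 & y0 <= nr - 1
  # clamp the far corner so edge pixels interpolate against themselves
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  i00 <- (x0[ok]) * nr + y0[ok] + 1
  i01 <- (x1[ok]) * nr + y0[ok] + 1
  i10 <- (x0[ok]) * nr + y1[ok] + 1
  i11 <- (x1[ok]) * nr + y1[ok] + 1
  fxo <- fx[ok]; fyo <- fy[ok]
  out[ok] <- img[i00] * (1 - fxo) * (1 - fyo) + img[i01] * fxo * (1 - fyo) +
    img[i10] * (1 - fxo) * fyo + img[i11] * fxo * fyo
  out
}

# Nearest-pixel mask membership at 0-based (x, y).
mask_at <- function(mask, x, y) {
  nr <- nrow(mask); nc <- ncol(mask)
  xi <- round(x); yi <- round(y)
  ok <- xi >= 0 & yi >= 0 & xi <= nc - 1 & yi <= nr - 1
  res <- logical(length(x))
  res[ok] <- mask[cbind(yi[ok] + 1, xi[ok] + 1)] != 0
  res
}

# Shoelace area of a closed polygon given 0-based (x, y) vertex columns.
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

# Solidity of a pixel set: pixel count over the number of lattice pixels
# inside the convex hull of the pixel centers (hull area + boundary lattice
# points / 2 + 1, by Pick's theorem). A rasterized convex shape — disc,
# ellipse, truncated disc — scores exactly 1, so the measure is free of the
# perimeter/area rasterization bias that would penalize small parts. The
# mask is morphologically closed (3x3) first, making the measure robust to
# single-pixel boundary raggedness while leaving nucleus-scale neck
# concavities intact.
pixel_solidity <- function(xs, ys) {
  if (length(xs) < 3L) return(1)
  pad <- 2L
  x0 <- min(xs); y0 <- min(ys)
  m <- matrix(0L, max(ys) - y0 + 1L + 2L * pad, max(xs) - x0 + 1L + 2L * pad)
  m[cbind(ys - y0 + 1L + pad, xs - x0 + 1L + pad)] <- 1L
  mc <- EBImage::imageData(EBImage::closing(EBImage::Image(m),
                                            EBImage::makeBrush(3, "box")))
  lin <- which(mc != 0)
  nr <- nrow(mc)
  xs <- (lin - 1L) %/% nr
  ys <- (lin - 1L) %% nr
  n <- length(xs)
  h <- grDevices::chull(xs, ys)
  hx <- xs[h]; hy <- ys[h]
  hull_area <- abs(polygon_area(cbind(hx, hy)))
  dxs <- abs(diff(c(hx, hx[1]))); dys <- abs(diff(c(hy, hy[1])))
  b <- sum(mapply(function(a, b2) if (a == 0 && b2 == 0) 0 else
    gcd2(round(a), round(b2)), dxs, dys))
  lattice_in_hull <- hull_area + b / 2 + 1
  if (lattice_in_hull <= 0) return(1)
  min(1, n / lattice_in_hull)
}

gcd2 <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Shannon entropy (nats) of a label vector.
label_entropy <- function(labels) {
  p <- tabulate(as.integer(labels))
  p <- p[p > 0] / sum(p)
  -sum(p * log(p))
}
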