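#' Li cross-entropy threshold
#'
#' Selects the global intensity threshold separating nuclei from background by
#' minimizing the cross entropy between the image and its two-level
#' representation, in which each side of the threshold is replaced by its mean
#' intensity. Entropy-based thresholding suits fluorescence nuclei images,
#' which have a well-defined background but vary in overall brightness
#' between acquisitions.
#'
#' The criterion is evaluated on an `n_bins`-bin histogram over the intensity
#' range; for candidate threshold `t` with below/above means `mu0`, `mu1`,
#' the cross entropy is
#' `sum_{g <= t} g h(g) log(g / mu0) + sum_{g > t} g h(g) log(g / mu1)`
#' and the minimizing bin edge is returned. The minimum is located by direct
#' evaluation over all bin edges, which is exact for the binned criterion.
#'
#' @param image a [pcna_image()] or numeric matrix with at least two distinct
#'   values; intensities must be non-negative.
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold, strictly between the image minimum and maximum.
#'   Foreground is intensity strictly greater than the threshold.
#' @seealso [binarize()], [segment_image()]
#' @export
li_threshold <- function(image, n_bins = 256L) {
  px <- as_pixel_matrix(image)
  lo <- min(px); hi <- max(px)
  if (hi <= lo) stop("degenerate histogram: image has a single intensity value")
  # integer images with a narrow range get integer-aligned bins, making the
  # binned criterion exact; otherwise n_bins equal-width bins over [lo, hi]
  if (all(px == round(px)) && hi - lo < n_bins) {
    breaks <- seq(lo - 0.5, hi + 0.5, by = 1)
    n_bins <- length(breaks) - 1L
  } else {
    breaks <- seq(lo, hi, length.out = n_bins + 1L)
  }
  h <- tabulate(pmin(pmax(findInterval(px, breaks, all.inside = TRUE), 1L),
                     n_bins), nbins = n_bins)
  centers <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w <- h * centers
  cw <- cumsum(w); ch <- cumsum(as.numeric(h))
  tot_w <- cw[n_bins]; tot_h <- ch[n_bins]
  # candidate thresholds: between bin k and k+1, k = 1..n_bins-1
  k <- seq_len(n_bins - 1L)
  mu0 <- cw[k] / ch[k]
  mu1 <- (tot_w - cw[k]) / (tot_h - ch[k])
  ok <- is.finite(mu0) & is.finite(mu1) & mu0 > 0 & mu1 > 0 &
    ch[k] > 0 & ch[k] < tot_h
  # cross entropy up to the constant sum g h(g) log g
  ce <- -(cw[k] * log(mu0) + (tot_w - cw[k]) * log(mu1))
  ce[!ok] <- Inf
  best <- which.min(ce)
  thr <- breaks[best + 1L]
  pcna_log("segment", "li threshold %.4g over [%.4g, %.4g] (%d bins)",
           thr, lo, hi, n_bins)
  thr
}

#' Binarize an image at a threshold
#'
#' @param image a [pcna_image()] or numeric matrix.
#' @param threshold finite threshold; foreground is intensity `> threshold`.
#' @return integer 0/1 matrix of the image's shape.
#' @export
binarize <- function(image, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  px <- as_pixel_matrix(image)
  m <- (px > threshold) + 0L
  dim(m) <- dim(px)
  m
}

#' Label connected foreground components
#'
#' Maximal 4- or 8-connected foreground regions receive distinct labels
#' 1..K, numbered in raster-scan order (top-to-bottom, left-to-right) of each
#' component's first pixel.
#'
#' @param mask 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer label matrix; 0 is background.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  mask <- as.matrix(mask)
  if (!any(mask != 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  l4 <- EBImage::imageData(EBImage::bwlabel(mask != 0))  # 4-connected
  storage.mode(l4) <- "integer"
  k <- max(l4)
  if (connectivity == 8L && k > 1L) {
    nr <- nrow(l4); nc <- ncol(l4)
    # merge components touching diagonally (union-find on label ids)
    a1 <- l4[-nr, -nc]; b1 <- l4[-1L, -1L]     # (r, c) vs (r+1, c+1)
    a2 <- l4[-nr, -1L]; b2 <- l4[-1L, -nc]     # (r, c+1) vs (r+1, c)
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]),
                          cbind(a2[sel2], b2[sel2])))
    if (nrow(pairs)) {
      parent <- seq_len(k)
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      for (p in seq_len(nrow(pairs))) {
        ra <- find(pairs[p, 1]); rb <- find(pairs[p, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(k), find, integer(1))
      l4[l4 > 0L] <- root[l4[l4 > 0L]]
    }
  }
  relabel_raster_order(l4)
}

#' Filter labeled objects by area
#'
#' Removes components whose pixel area falls outside `[min_area, max_area]`
#' and relabels survivors contiguously, preserving raster order. Undersized
#' rejects are debris or shrunken dead cells; oversized rejects flag dense
#' clusters that could not be split into valid nuclei.
#'
#' @param labels integer label matrix.
#' @param min_area,max_area inclusive area bounds, `min_area < max_area`.
#' @return list with `labels` (relabeled mask), `rejected_small`,
#'   `rejected_large` (component counts).
#' @export
filter_by_size <- function(labels, min_area, max_area) {
  if (min_area >= max_area) stop("min_area must be smaller than max_area")
  labels <- as.matrix(labels)
  k <- max(labels)
  if (k == 0L)
    return(list(labels = matrix(0L, nrow(labels), ncol(labels)),
                rejected_small = 0L, rejected_large = 0L))
  areas <- tabulate(labels[labels > 0L], nbins = k)
  small <- which(areas < min_area)
  large <- which(areas > max_area)
  keep <- setdiff(seq_len(k), c(small, large))
  map <- integer(k + 1L)                    # map[old label + 1] -> new label
  map[keep + 1L] <- seq_along(keep)
  out <- matrix(map[labels + 1L], nrow(labels), ncol(labels))
  pcna_log("segment", "size filter [%g, %g]: kept %d, small %d, large %d",
           min_area, max_area, length(keep), length(small), length(large))
  list(labels = out, rejected_small = length(small),
       rejected_large = length(large))
}

#' Segment an image into labeled nuclei
#'
#' Convenience wrapper chaining optional Gaussian pre-smoothing, Li
#' thresholding, binarization and component labeling. Size filtering is left
#' to the caller so that touching-nucleus clusters survive until
#' [split_cluster()] has seen them.
#'
#' @param image a [pcna_image()] or matrix.
#' @param config a [pcna_config()].
#' @return integer label matrix.
#' @export
segment_image <- function(image, config = pcna_config()) {
  px <- as_pixel_matrix(image)
  work <- if (config$presmooth_sigma > 0)
    gaussian_blur(px, config$presmooth_sigma) else px
  thr <- li_threshold(work, config$n_bins)
  labs <- label_components(binarize(work, thr), config$connectivity)
  pcna_log("segment", "image %s: threshold %.4g -> %d components",
           if (inherits(image, "pcna_image")) image$id else "<matrix>",
           thr, max(labs))
  labs
}
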