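#' Constraint checks for a split hypothesis
#'
#' A split hypothesis cuts a cluster along one or more chords between split
#' points. Admissibility requires four constraints:
#' \describe{
#'   \item{anti_parallel}{each chord joins points whose inward normals face
#'     each other: the angle between a point's inward normal and the chord
#'     direction toward its partner is at most `theta_max`. This rejects
#'     pairs lying on the same side of the object.}
#'   \item{non_intersection}{chords run through the interior of the cluster
#'     and are pairwise disjoint.}
#'   \item{convexity}{every resulting part has solidity (area over convex
#'     hull area) at least `c_min`.}
#'   \item{size}{the cluster is large enough to contain `n_parts` nuclei:
#'     area >= `n_parts * min_area`.}
#' }
#'
#' @param contour a [extract_contour()] result for the cluster.
#' @param split_points data.frame from [find_split_points()].
#' @param pairs integer matrix with two columns; each row indexes a pair of
#'   rows of `split_points` forming one chord. `k` chords yield `k + 1`
#'   parts.
#' @param config a [pcna_config()].
#' @return list with `flags` (named logical vector `anti_parallel`,
#'   `non_intersection`, `convexity`, `size`), `admissible` (all four true),
#'   `parts` (list of 0-based `(x, y)` pixel coordinate matrices, or `NULL`
#'   when the chords fail before parts exist), `chord_length` and `n_parts`.
#' @export
check_constraints <- function(contour, split_points, pairs,
                              config = pcna_config()) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  n_parts <- nrow(pairs) + 1L
  flags <- c(anti_parallel = TRUE, non_intersection = TRUE,
             convexity = FALSE, size = FALSE)
  area <- sum(contour$mask)
  flags["size"] <- area >= n_parts * config$min_area
  chords <- vector("list", nrow(pairs))
  chord_len <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    p1 <- c(split_points$x[i], split_points$y[i])
    p2 <- c(split_points$x[j], split_points$y[j])
    if (!chord_anti_parallel(split_points, i, j, config$theta_max))
      flags["anti_parallel"] <- FALSE
    if (!chord_interior(contour$mask, p1, p2))
      flags["non_intersection"] <- FALSE
    chords[[r]] <- list(p1 = p1, p2 = p2)
    chord_len <- chord_len + sqrt(sum((p2 - p1)^2))
  }
  parts <- NULL
  if (flags["anti_parallel"] && flags["non_intersection"]) {
    parts <- cut_mask(contour$mask, chords)
    if (is.null(parts) || length(parts) != n_parts) {
      flags["non_intersection"] <- FALSE       # chords failed to separate
      parts <- NULL
    } else {
      sol <- vapply(parts, function(p) pixel_solidity(p[, 1], p[, 2]),
                    numeric(1))
      flags["convexity"] <- all(sol >= config$c_min)
    }
  }
  list(flags = flags, admissible = all(flags), parts = parts,
       chord_length = chord_len, n_parts = n_parts)
}

chord_anti_parallel <- function(split_points, i, j, theta_max) {
  d <- c(split_points$x[j] - split_points$x[i],
         split_points$y[j] - split_points$y[i])
  len <- sqrt(sum(d^2))
  if (len < 2) return(FALSE)
  d <- d / len
  cos_max <- cos(theta_max * pi / 180)
  ci <- split_points$normal_x[i] * d[1] + split_points$normal_y[i] * d[2]
  cj <- -(split_points$normal_x[j] * d[1] + split_points$normal_y[j] * d[2])
  ci >= cos_max && cj >= cos_max
}

# A chord is interior if it stays inside the mask away from its endpoints;
# the endpoints themselves sit on the (outward-pushed) boundary, so a 2 px
# margin at each end is excluded from the check.
chord_interior <- function(mask, p1, p2) {
  len <- sqrt(sum((p2 - p1)^2))
  lo <- min(2 / len, 0.45); hi <- 1 - lo
  t <- seq(lo, hi, length.out = max(5L, ceiling((hi - lo) * len / 0.5)))
  xs <- p1[1] + t * (p2[1] - p1[1])
  ys <- p1[2] + t * (p2[2] - p1[2])
  all(mask_at(mask, xs, ys))
}

# All pixels a segment passes through (dense sampling), 0-based (x, y).
supercover_pixels <- function(p1, p2) {
  len <- max(1, sqrt(sum((p2 - p1)^2)))
  t <- seq(0, 1, length.out = max(2L, ceiling(len / 0.2) + 1L))
  pts <- cbind(round(p1[1] + t * (p2[1] - p1[1])),
               round(p1[2] + t * (p2[2] - p1[2])))
  pts[!duplicated(pts), , drop = FALSE]
}

# Cut a binary mask along straight chords. Severed pixels are assigned to the
# part on the chord's left; remaining regions are labeled 4-connected so a
# one-pixel-wide cut separates. Returns a list of (x, y) matrices or NULL.
cut_mask <- function(mask, chords) {
  nr <- nrow(mask); nc <- ncol(mask)
  cut <- mask
  chord_lin <- integer(0)
  chord_of <- integer(0)
  for (r in seq_along(chords)) {
    pts <- supercover_pixels(chords[[r]]$p1, chords[[r]]$p2)
    ok <- pts[, 1] >= 0 & pts[, 1] < nc & pts[, 2] >= 0 & pts[, 2] < nr
    pts <- pts[ok, , drop = FALSE]
    lin <- pts[, 1] * nr + pts[, 2] + 1L
    lin <- lin[mask[lin]]
    chord_lin <- c(chord_lin, lin)
    chord_of <- c(chord_of, rep(r, length(lin)))
    cut[lin] <- FALSE
  }
  labs <- label_components(cut, 4L)
  k <- max(labs)
  if (k == 0L) return(NULL)
  # drop crumbs produced by the cut (< 9 px) by merging them with chords
  areas <- tabulate(labs[labs > 0L], nbins = k)
  real <- which(areas >= 9L)
  if (!length(real)) return(NULL)
  crumbs <- which(labs %in% which(areas < 9L))
  relab <- integer(k); relab[real] <- seq_along(real)
  labs[labs > 0L] <- relab[labs[labs > 0L]]
  reassign <- c(chord_lin, crumbs)
  reassign_chord <- c(chord_of, rep(NA_integer_, length(crumbs)))
  if (length(reassign)) {
    part_lin <- which(labs > 0L)
    pr <- ((part_lin - 1L) %% nr); pc <- ((part_lin - 1L) %/% nr)
    plab <- labs[part_lin]
    rx <- ((reassign - 1L) %/% nr); ry <- ((reassign - 1L) %% nr)
    for (q in seq_along(reassign)) {
      r <- reassign_chord[q]
      tx <- rx[q]; ty <- ry[q]
      if (!is.na(r)) {
        d <- chords[[r]]$p2 - chords[[r]]$p1
        dl <- sqrt(sum(d^2)); d <- d / max(dl, 1e-9)
        lx <- d[2]; ly <- -d[1]                 # left normal, stored frame
        cand <- cbind(round(tx + lx), round(ty + ly))
        cand <- rbind(cand, round(cbind(tx + 2 * lx, ty + 2 * ly)))
        assigned <- FALSE
        for (ci in seq_len(nrow(cand))) {
          cxx <- cand[ci, 1]; cyy <- cand[ci, 2]
          if (cxx >= 0 && cxx < nc && cyy >= 0 && cyy < nr) {
            l <- labs[cxx * nr + cyy + 1L]
            if (l > 0L) { labs[reassign[q]] <- l; assigned <- TRUE; break }
          }
        }
        if (assigned) next
      }
      # fallback: nearest part pixel
      nn <- which.min((pc - tx)^2 + (pr - ty)^2)
      labs[reassign[q]] <- plab[nn]
    }
  }
  lapply(seq_along(real), function(l) {
    lin <- which(labs == l)
    cbind(x = (lin - 1L) %/% nr, y = (lin - 1L) %% nr)
  })
}

#' Cost of a split hypothesis
#'
#' `cost = sum over parts of (1 - solidity(part)) + lambda * total chord
#' length / cluster perimeter`. Lower is better; a partition into exactly
#' convex parts along vanishing chords has cost approaching 0. The convexity
#' deficit term operationalizes the convexity constraint as a graded
#' preference; the chord term penalizes long, implausible cuts.
#'
#' @param hypothesis result of [check_constraints()]; must be admissible.
#' @param contour the cluster's contour (for its perimeter).
#' @param lambda chord-length weight.
#' @return non-negative cost.
#' @export
hypothesis_cost <- function(hypothesis, contour, lambda = 0.5) {
  if (!isTRUE(hypothesis$admissible))
    stop("cost is defined only for admissible hypotheses")
  perim <- contour_perimeter(contour)
  deficit <- sum(vapply(hypothesis$parts,
                        function(p) 1 - pixel_solidity(p[, 1], p[, 2]),
                        numeric(1)))
  deficit + lambda * hypothesis$chord_length / perim
}

contour_perimeter <- function(contour) {
  pts <- contour$points
  closed <- rbind(pts, pts[1L, ])
  sum(sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2))
}

#' Split a labeled cluster between concave contour points
#'
#' The geometric cluster splitting search: split points are concave curvature
#' maxima of the contour; candidate chords join anti-parallel point pairs
#' through the cluster interior; for increasing part count `n` starting at 2,
#' hypotheses with `n - 1` chords are enumerated and the admissible
#' hypothesis with the lowest [hypothesis_cost()] is chosen. A split is
#' accepted only if it improves on the current best (initially the unsplit
#' object, whose cost is its own convexity deficit) by the margin
#' `config$epsilon`; the search stops at the first `n` that brings no such
#' improvement. Convex objects therefore always come back unsplit.
#'
#' @param labels integer label matrix.
#' @param label the cluster to split.
#' @param config a [pcna_config()].
#' @return list with `parts` (list of 0-based `(x, y)` pixel matrices;
#'   length 1 when unsplit), `n_parts`, `cost`, `split` (logical), and
#'   `n_split_points`.
#' @export
split_cluster <- function(labels, label, config = pcna_config()) {
  contour <- extract_contour(labels, label)
  mask <- contour$mask
  nr <- nrow(mask)
  whole_lin <- which(mask)
  whole <- cbind(x = (whole_lin - 1L) %/% nr, y = (whole_lin - 1L) %% nr)
  unsplit <- list(parts = list(whole), n_parts = 1L,
                  cost = 1 - pixel_solidity(whole[, 1], whole[, 2]),
                  split = FALSE, n_split_points = 0L)
  sp <- find_split_points(contour, config$kappa_min, config$curvature_scale,
                          config$nms_window)
  unsplit$n_split_points <- nrow(sp)
  if (nrow(sp) < 2L) return(unsplit)
  n <- nrow(sp)
  cand <- t(utils::combn(n, 2L))
  ok <- vapply(seq_len(nrow(cand)), function(r) {
    i <- cand[r, 1]; j <- cand[r, 2]
    min_sep <- config$nms_window
    sep <- abs(sp$contour_index[i] - sp$contour_index[j])
    sep <- min(sep, nrow(contour$points) - sep)
    sep > min_sep &&
      chord_anti_parallel(sp, i, j, config$theta_max) &&
      chord_interior(mask, c(sp$x[i], sp$y[i]), c(sp$x[j], sp$y[j]))
  }, logical(1))
  chords <- cand[ok, , drop = FALSE]
  if (!nrow(chords)) return(unsplit)
  if (nrow(chords) > 1e4) {                    # combinatorial guard
    cl <- sqrt((sp$x[chords[, 1]] - sp$x[chords[, 2]])^2 +
               (sp$y[chords[, 1]] - sp$y[chords[, 2]])^2)
    chords <- chords[order(cl)[seq_len(1e4)], , drop = FALSE]
  }
  area <- sum(mask)
  best_h <- NULL
  for (np in 2:config$n_max) {
    if (nrow(chords) < np - 1L) break
    if (area < np * config$min_area) break     # size constraint, cheap
    level_chords <- chords
    # combinatorial guard for multi-chord levels: keep the shortest chords
    if (np > 2L && nrow(level_chords) > 14L) {
      cl <- sqrt((sp$x[level_chords[, 1]] - sp$x[level_chords[, 2]])^2 +
                 (sp$y[level_chords[, 1]] - sp$y[level_chords[, 2]])^2)
      level_chords <- level_chords[order(cl)[1:14], , drop = FALSE]
    }
    combs <- utils::combn(nrow(level_chords), np - 1L)
    any_admissible <- FALSE
    for (ci in seq_len(ncol(combs))) {
      rows <- level_chords[combs[, ci], , drop = FALSE]
      if (np > 2L && anyDuplicated(as.vector(rows))) next
      h <- check_constraints(contour, sp, rows, config)
      if (!h$admissible) next
      any_admissible <- TRUE
      h$cost <- hypothesis_cost(h, contour, config$lambda)
      if (is.null(best_h) || h$cost < best_h$cost) best_h <- h
    }
    if (!any_admissible) break                 # larger n cannot help either
  }
  if (!is.null(best_h) && best_h$cost < unsplit$cost - config$epsilon) {
    list(parts = best_h$parts, n_parts = best_h$n_parts, cost = best_h$cost,
         split = TRUE, n_split_points = nrow(sp))
  } else unsplit
}

#' Watershed baseline for cluster splitting
#'
#' Splits an object by the watershed transform of the negated Euclidean
#' distance map of its binary mask, seeded at the distance map's regional
#' maxima. Effective on round touching objects but notoriously sensitive to
#' boundary artifacts: fringy contours produce spurious distance maxima and
#' hence spurious splits.
#'
#' @param labels integer label matrix.
#' @param label object to split.
#' @param tolerance minimum depth (in distance-map units) separating two
#'   catchment basins before they count as distinct objects.
#' @return list with `parts` (list of 0-based `(x, y)` pixel matrices) and
#'   `n_parts`.
#' @export
watershed_split <- function(labels, label, tolerance = 0.1) {
  labels <- as.matrix(labels)
  mask <- labels == label
  if (!any(mask)) stop("label ", label, " not present in mask")
  nr <- nrow(mask)
  # crop to the bounding box (padded) to keep the transform local
  lin <- which(mask)
  rr <- range(((lin - 1L) %% nr) + 1L)
  cc <- range(((lin - 1L) %/% nr) + 1L)
  r0 <- max(1L, rr[1] - 2L); r1 <- min(nrow(mask), rr[2] + 2L)
  c0 <- max(1L, cc[1] - 2L); c1 <- min(ncol(mask), cc[2] + 2L)
  sub <- mask[r0:r1, c0:c1]
  dm <- EBImage::distmap(EBImage::Image(sub * 1))
  ws <- EBImage::imageData(EBImage::watershed(dm, tolerance = tolerance,
                                              ext = 1))
  ws[!sub] <- 0
  k <- max(ws)
  snr <- nrow(sub)
  # map crop coordinates back to image coordinates (0-based)
  parts <- lapply(seq_len(k), function(l) {
    pl <- which(ws == l)
    cbind(x = ((pl - 1L) %/% snr) + (c0 - 1L),
          y = ((pl - 1L) %% snr) + (r0 - 1L))
  })
  parts <- parts[vapply(parts, nrow, integer(1)) > 0]
  list(parts = parts, n_parts = length(parts))
}

#' Split every object of a label mask
#'
#' Applies [split_cluster()] (or [watershed_split()]) to each labeled object
#' and rebuilds a contiguous label mask, numbering parts in raster-scan
#' order. Objects whose contour cannot be traced (tiny specks) are kept
#' unchanged.
#'
#' @param labels integer label matrix.
#' @param config a [pcna_config()].
#' @param method `"geometric"` or `"watershed"`.
#' @return integer label matrix with split parts relabeled.
#' @export
split_all_clusters <- function(labels, config = pcna_config(),
                               method = c("geometric", "watershed")) {
  method <- match.arg(method)
  labels <- as.matrix(labels)
  nr <- nrow(labels)
  out <- matrix(0L, nr, ncol(labels))
  nxt <- 0L
  for (l in seq_len(max(labels))) {
    res <- tryCatch(
      if (method == "geometric") split_cluster(labels, l, config)
      else watershed_split(labels, l),
      error = function(e) NULL)
    parts <- if (is.null(res)) {
      lin <- which(labels == l)
      list(cbind(x = (lin - 1L) %/% nr, y = (lin - 1L) %% nr))
    } else res$parts
    for (p in parts) {
      nxt <- nxt + 1L
      out[cbind(p[, 2] + 1L, p[, 1] + 1L)] <- nxt
    }
  }
  relabel_raster_order(out)
}

# Renumber labels in raster-scan order of each component's first pixel.
relabel_raster_order <- function(labels) {
  k <- max(labels)
  if (k == 0L) return(labels)
  nr <- nrow(labels); nc <- ncol(labels)
  lin <- which(labels > 0L)
  key <- ((lin - 1L) %% nr) * nc + ((lin - 1L) %/% nr)
  first <- tapply(key, labels[lin], min)
  ord <- order(first)
  map <- integer(k)
  map[as.integer(names(first))[ord]] <- seq_along(ord)
  labels[lin] <- map[labels[lin]]
  labels
}
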