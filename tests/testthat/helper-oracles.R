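# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive loops and direct formula evaluation so they share no code with
# the implementation they check.

# Rasterize discs / ellipses onto a fresh mask.
disc_mask <- function(h, w, centers, r) {
  m <- matrix(0L, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) for (cc in centers)
    if ((x - cc[1])^2 + (y - cc[2])^2 <= r^2) m[y, x] <- 1L
  m
}

ellipse_mask <- function(h, w, cx, cy, a, b) {
  m <- matrix(0L, h, w)
  for (y in seq_len(h)) for (x in seq_len(w))
    if (((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1) m[y, x] <- 1L
  m
}

# Exhaustive Li cross-entropy minimizer over all distinct pixel values,
# computed from the raw pixels (no histogram). Returns the threshold; pixels
# <= t are background.
oracle_li_threshold <- function(px) {
  v <- sort(unique(as.vector(px)))
  best_t <- NA_real_; best_ce <- Inf
  for (k in seq_len(length(v) - 1L)) {
    t <- v[k]
    lo <- px[px <= t]; hi <- px[px > t]
    mu0 <- mean(lo); mu1 <- mean(hi)
    term <- function(vals, mu) {
      if (mu <= 0) return(0)
      vv <- vals[vals > 0]
      sum(vv * log(vv / mu))
    }
    ce <- term(lo, mu0) + term(hi, mu1)
    if (ce < best_ce) { best_ce <- ce; best_t <- t }
  }
  best_t
}

# Direct-summation Haralick features from the textbook formulas, explicit
# double loops, natural log, 0-based levels.
oracle_haralick <- function(p) {
  l <- nrow(p)
  lg <- function(z) if (z > 0) log(z) else 0
  px_ <- rowSums(p); py_ <- colSums(p)
  mu_x <- sum((0:(l - 1)) * px_); mu_y <- sum((0:(l - 1)) * py_)
  sd_x <- sqrt(sum(((0:(l - 1)) - mu_x)^2 * px_))
  sd_y <- sqrt(sum(((0:(l - 1)) - mu_y)^2 * py_))
  psum <- numeric(2 * l - 1); pdif <- numeric(l)
  f1 <- f2 <- f4 <- f5 <- f9 <- cor_num <- 0
  for (i in 1:l) for (j in 1:l) {
    pij <- p[i, j]; ii <- i - 1; jj <- j - 1
    f1 <- f1 + pij^2
    f2 <- f2 + (ii - jj)^2 * pij
    cor_num <- cor_num + ii * jj * pij
    f4 <- f4 + (ii - mu_x)^2 * pij
    f5 <- f5 + pij / (1 + (ii - jj)^2)
    f9 <- f9 - pij * lg(pij)
    psum[ii + jj + 1] <- psum[ii + jj + 1] + pij
    pdif[abs(ii - jj) + 1] <- pdif[abs(ii - jj) + 1] + pij
  }
  f3 <- if (sd_x > 0 && sd_y > 0) (cor_num - mu_x * mu_y) / (sd_x * sd_y) else 1
  f6 <- sum((0:(2 * l - 2)) * psum)
  f7 <- sum(((0:(2 * l - 2)) - f6)^2 * psum)
  f8 <- -sum(sapply(seq_along(psum), function(k) psum[k] * lg(psum[k])))
  mu_d <- sum((0:(l - 1)) * pdif)
  f10 <- sum(((0:(l - 1)) - mu_d)^2 * pdif)
  f11 <- -sum(sapply(seq_along(pdif), function(k) pdif[k] * lg(pdif[k])))
  hx <- -sum(sapply(px_, function(z) z * lg(z)))
  hy <- -sum(sapply(py_, function(z) z * lg(z)))
  hxy1 <- hxy2 <- 0
  for (i in 1:l) for (j in 1:l) {
    q <- px_[i] * py_[j]
    hxy1 <- hxy1 - p[i, j] * lg(q)
    hxy2 <- hxy2 - q * lg(q)
  }
  f12 <- if (max(hx, hy) > 0) (f9 - hxy1) / max(hx, hy) else 0
  f13 <- sqrt(max(1 - exp(-2 * (hxy2 - f9)), 0))
  c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12, f13)
}

# Random normalized symmetric GLCM.
random_glcm <- function(levels = 8L) {
  m <- matrix(stats::rexp(levels^2), levels, levels)
  m <- m + t(m)
  m / sum(m)
}

# Shannon entropy (nats) of a label vector, independent implementation.
oracle_entropy <- function(y) {
  p <- table(y) / length(y)
  -sum(ifelse(p > 0, p * log(p), 0))
}

# Exhaustive best root split (feature, midpoint threshold) by information
# gain.
oracle_best_root_split <- function(x, y) {
  best <- list(gain = -Inf)
  for (f in seq_len(ncol(x))) {
    vs <- sort(unique(x[, f]))
    if (length(vs) < 2L) next
    for (k in seq_len(length(vs) - 1L)) {
      thr <- (vs[k] + vs[k + 1L]) / 2
      left <- x[, f] <= thr
      gain <- oracle_entropy(y) -
        (sum(left) * oracle_entropy(y[left]) +
         sum(!left) * oracle_entropy(y[!left])) / length(y)
      if (gain > best$gain + 1e-12) best <- list(feature = f, threshold = thr,
                                                 gain = gain)
    }
  }
  best
}

# Exhaustive two-part split search over all split-point pairs, using the
# package's constraint/cost primitives but none of its search logic.
oracle_best_pair_split <- function(labels, label, config) {
  ct <- extract_contour(labels, label)
  sp <- find_split_points(ct, config$kappa_min, config$curvature_scale,
                          config$nms_window)
  if (nrow(sp) < 2L) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(sp) - 1L)) for (j in (i + 1L):nrow(sp)) {
    h <- check_constraints(ct, sp, matrix(c(i, j), 1), config)
    if (!h$admissible) next
    cost <- hypothesis_cost(h, ct, config$lambda)
    if (is.null(best) || cost < best$cost)
      best <- list(pair = c(i, j), cost = cost, parts = h$parts)
  }
  best
}

# Canonical form of a parts list for comparison: sorted pixel keys per part,
# parts sorted by first key.
parts_signature <- function(parts, nr = 10000L) {
  keys <- lapply(parts, function(p) sort(p[, 1] * nr + p[, 2]))
  keys[order(vapply(keys, `[`, numeric(1), 1L))]
}
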