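#' Synthetic scene specification
#'
#' Parameters of the synthetic fluorescence scene generator. The generator
#' emulates the four PCNA distribution patterns — homogeneous signal in G,
#' many small uniformly placed replication foci in early S, foci at the
#' nuclear periphery in mid S, few large central foci in late S — plus
#' touching-nucleus clusters and the blur/noise contrast between confocal
#' and widefield acquisition. Focus counts and sizes are not biological
#' measurements; they are plausible renderings of the qualitative patterns,
#' and every knob is exposed here.
#'
#' @param width,height image size in pixels.
#' @param n_nuclei nuclei per scene.
#' @param phase_mix named proportions over `G, EARLY_S, MID_S, LATE_S`;
#'   must sum to 1. `phase_mix = "paper_like"` selects an imbalanced preset
#'   (G-dominant, mid-S-scarce) for stress tests.
#' @param axes_range semi-axis range of the elliptical nuclei (px).
#' @param cluster_fraction fraction of nuclei placed as touching pairs.
#' @param overlap_range overlap depth of a touching pair, as a fraction of
#'   the smaller nucleus' minor axis.
#' @param mode `"confocal"` or `"widefield"`.
#' @param psf_sigma Gaussian point-spread sigma (px); default 0.8 confocal,
#'   2.0 widefield.
#' @param background additive background level; widefield additionally gets
#'   a smooth out-of-focus haze.
#' @param base_level nuclear base signal level.
#' @param poisson_scale photon noise scale s: pixel -> `s * rpois(value/s)`,
#'   so the variance is `s * value`.
#' @param gaussian_sd_frac read-noise sd as a fraction of the dynamic range.
#' @param rng_seed integer seed; scenes are byte-identical for equal seeds.
#' @return object of class `pcna_scenespec`.
#' @export
scene_spec <- function(width = 448L, height = 448L, n_nuclei = 16L,
                       phase_mix = c(G = 0.25, EARLY_S = 0.25,
                                     MID_S = 0.25, LATE_S = 0.25),
                       axes_range = c(12, 18),
                       cluster_fraction = 0.3,
                       overlap_range = c(0.15, 0.30),
                       mode = c("confocal", "widefield"),
                       psf_sigma = NULL,
                       background = NULL,
                       base_level = 60,
                       poisson_scale = 0.5,
                       gaussian_sd_frac = 0.02,
                       rng_seed = 0L) {
  mode <- match.arg(mode)
  if (identical(phase_mix, "paper_like"))
    phase_mix <- c(G = 0.54, EARLY_S = 0.21, MID_S = 0.07, LATE_S = 0.18)
  if (is.null(names(phase_mix)) || !setequal(names(phase_mix), phase_levels()))
    stop("phase_mix must be named with the four phase labels")
  phase_mix <- phase_mix[phase_levels()]
  if (any(phase_mix < 0)) stop("phase_mix proportions must be non-negative")
  if (abs(sum(phase_mix) - 1) > 1e-8) stop("phase_mix must sum to 1")
  if (is.null(psf_sigma)) psf_sigma <- if (mode == "confocal") 0.8 else 2.0
  if (is.null(background)) background <- if (mode == "confocal") 8 else 20
  if (overlap_range[2] >= 1) stop("overlap depth must stay below the minor axis")
  if (axes_range[1] <= 0 || axes_range[1] > axes_range[2])
    stop("invalid axes_range")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_nuclei = as.integer(n_nuclei), phase_mix = phase_mix,
                 axes_range = axes_range, cluster_fraction = cluster_fraction,
                 overlap_range = overlap_range, mode = mode,
                 psf_sigma = psf_sigma, background = background,
                 base_level = base_level, poisson_scale = poisson_scale,
                 gaussian_sd_frac = gaussian_sd_frac,
                 rng_seed = as.integer(rng_seed)),
            class = "pcna_scenespec")
}

#' Render one nucleus with its phase-specific PCNA pattern
#'
#' Draws an elliptical nucleus and paints the PCNA texture of the requested
#' phase onto a local canvas: G gets the smooth base signal with mild
#' mottling and no foci; early S gets 80-150 small foci (sigma 0.8-1.5 px)
#' uniformly over the nucleus; mid S gets 40-100 foci (sigma 1-2 px) at
#' normalized radius 0.75-0.98; late S gets 5-15 large foci (sigma 2-4 px)
#' at normalized radius below 0.5. Focus amplitudes are log-normal. Uses the
#' current RNG state; callers seed via [with_seed()] semantics.
#'
#' @param phase one of [phase_levels()].
#' @param spec a [scene_spec()].
#' @param circular force a circular nucleus (used for controlled-overlap
#'   cluster members).
#' @return list with `mask` (logical local matrix), `texture` (numeric local
#'   matrix, zero outside the mask), `axes` (semi-axes `a >= b`), `phi`
#'   (orientation), `foci` (data.frame with local 0-based `x`, `y`,
#'   normalized radius `norm_r`, `sigma`, `amp`).
#' @export
generate_nucleus <- function(phase, spec = scene_spec(), circular = FALSE) {
  phase <- as.character(parse_phase(phase))
  a <- stats::runif(1, spec$axes_range[1], spec$axes_range[2])
  b <- if (circular) a else stats::runif(1, spec$axes_range[1], spec$axes_range[2])
  if (b > a) { tmp <- a; a <- b; b <- tmp }
  phi <- stats::runif(1, 0, pi)
  r <- ceiling(a) + 3L
  n <- 2L * r + 1L
  xs <- matrix(rep(-r:r, each = n), n, n)      # x varies along columns
  ys <- matrix(rep(-r:r, times = n), n, n)     # y along rows
  ct <- cos(phi); st <- sin(phi)
  u <- (ct * xs + st * ys) / a
  v <- (-st * xs + ct * ys) / b
  nr2 <- u^2 + v^2
  mask <- nr2 <= 1
  # base nuclear signal with smooth mottling; G nuclei carry stronger
  # mottling (homogeneously distributed PCNA still images with a grainy
  # texture), S-phase nuclei a weaker one under their foci. The mottling
  # correlation length (~2 px) matches the scale a small focus reaches
  # after widefield blur, which is exactly why early S collapses onto G
  # when the PSF widens.
  mot <- gaussian_blur(matrix(stats::rnorm(n * n), n, n), 2)
  mot <- mot / max(stats::sd(mot), 1e-9)
  mot_amp <- if (phase == "G") 0.08 else 0.04
  # expression / staining efficiency varies from cell to cell
  brightness <- stats::rlnorm(1, 0, 0.3)
  tex <- brightness * spec$base_level * (1 + mot_amp * mot)
  f_n <- switch(phase, G = 0L,
                EARLY_S = sample(80:150, 1L),
                MID_S = sample(40:100, 1L),
                LATE_S = sample(5:15, 1L))
  foci <- data.frame(x = numeric(0), y = numeric(0), norm_r = numeric(0),
                     sigma = numeric(0), amp = numeric(0))
  if (f_n > 0L) {
    norm_r <- switch(phase,
                     EARLY_S = sqrt(stats::runif(f_n)),   # uniform over area
                     MID_S = stats::runif(f_n, 0.75, 0.98),
                     LATE_S = stats::runif(f_n, 0, 0.5))  # radius < 0.5
    theta <- stats::runif(f_n, 0, 2 * pi)
    sig <- switch(phase,
                  EARLY_S = stats::runif(f_n, 0.8, 1.5),
                  MID_S = stats::runif(f_n, 1, 2),
                  LATE_S = stats::runif(f_n, 2, 4))
    amp <- brightness * switch(phase,
                  EARLY_S = stats::rlnorm(f_n, log(10), 0.35),
                  MID_S = stats::rlnorm(f_n, log(18), 0.35),
                  LATE_S = stats::rlnorm(f_n, log(26), 0.3))
    fx <- ct * (norm_r * a * cos(theta)) - st * (norm_r * b * sin(theta))
    fy <- st * (norm_r * a * cos(theta)) + ct * (norm_r * b * sin(theta))
    tex <- tex + render_foci(fx, fy, sig, amp, r)
    foci <- data.frame(x = fx + r, y = fy + r, norm_r = norm_r,
                       theta = theta, sigma = sig, amp = amp)
  }
  tex[!mask] <- 0
  list(mask = mask, texture = tex, axes = c(a = a, b = b), phi = phi,
       foci = foci, r = r)
}

# Paint isotropic Gaussian foci at (fx, fy) (centered coordinates) onto a
# (2r+1)^2 zero canvas by direct evaluation of the Gaussian at pixel centers.
render_foci <- function(fx, fy, sig, amp, r) {
  tex <- matrix(0, 2L * r + 1L, 2L * r + 1L)
  for (i in seq_along(fx)) {
    w <- ceiling(3 * sig[i])
    cx <- round(fx[i]); cy <- round(fy[i])
    gx <- max(-r, cx - w):min(r, cx + w)
    gy <- max(-r, cy - w):min(r, cy + w)
    gxm <- matrix(rep(gx, each = length(gy)), length(gy), length(gx))
    gym <- matrix(rep(gy, times = length(gx)), length(gy), length(gx))
    blob <- amp[i] * exp(-((gxm - fx[i])^2 + (gym - fy[i])^2) /
                           (2 * sig[i]^2))
    idx <- cbind(as.vector(gym) + r + 1L, as.vector(gxm) + r + 1L)
    tex[idx] <- tex[idx] + as.vector(blob)
  }
  tex
}

#' Re-render a generated nucleus at an arbitrary orientation
#'
#' Renders the deterministic part of a [generate_nucleus()] result (ellipse
#' mask, base level and foci; the random mottling is omitted) with the whole
#' nucleus rotated by `rotation` radians. Because the ellipse and the
#' Gaussian foci are evaluated analytically at pixel centers, the rotated
#' image is an exact sampling of the rotated continuum scene — no image
#' interpolation is involved. This is the reference harness for testing the
#' rotation invariance of features.
#'
#' @param nucleus a [generate_nucleus()] result.
#' @param rotation additional rotation (radians, counter-clockwise).
#' @param base_level base signal level (default matches [scene_spec()]).
#' @return list with `mask` and `texture` matrices of the nucleus' canvas
#'   size.
#' @export
render_nucleus <- function(nucleus, rotation = 0, base_level = 60) {
  a <- nucleus$axes[["a"]]; b <- nucleus$axes[["b"]]
  phi <- nucleus$phi + rotation
  r <- nucleus$r
  n <- 2L * r + 1L
  xs <- matrix(rep(-r:r, each = n), n, n)
  ys <- matrix(rep(-r:r, times = n), n, n)
  ct <- cos(phi); st <- sin(phi)
  u <- (ct * xs + st * ys) / a
  v <- (-st * xs + ct * ys) / b
  mask <- u^2 + v^2 <= 1
  tex <- matrix(base_level, n, n)
  if (nrow(nucleus$foci)) {
    f <- nucleus$foci
    ex <- f$norm_r * a * cos(f$theta)
    ey <- f$norm_r * b * sin(f$theta)
    fx <- ct * ex - st * ey
    fy <- st * ex + ct * ey
    tex <- tex + render_foci(fx, fy, f$sigma, f$amp, r)
  }
  tex[!mask] <- 0
  list(mask = mask, texture = tex)
}

phase_counts <- function(n, mix) {
  raw <- n * mix
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  stats::setNames(as.integer(cnt), names(mix))
}

#' Generate a synthetic scene
#'
#' Places `n_nuclei` nuclei — a `cluster_fraction` of them as touching pairs
#' with controlled overlap depth, the rest isolated — renders their
#' phase-specific textures, convolves with the mode's Gaussian PSF, and
#' applies Poisson then Gaussian noise (plus a smooth haze in widefield
#' mode). Ground truth is exact: `truth_labels` assigns every nucleus pixel
#' to its nucleus (overlap pixels go to the nearer center) and one centroid
#' annotation per nucleus carries the phase.
#'
#' @param spec a [scene_spec()].
#' @return object of class `pcna_scene`: `image` ([pcna_image()]),
#'   `truth_labels` (integer matrix), `annotations` (data.frame `x`, `y`,
#'   `label`, `nucleus_id`, `clustered`), `spec`.
#' @export
generate_scene <- function(spec = scene_spec()) {
  with_seed(spec$rng_seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  w <- spec$width; h <- spec$height
  n <- spec$n_nuclei
  phases <- sample(rep(phase_levels(), phase_counts(n, spec$phase_mix)))
  n_pairs <- floor(spec$cluster_fraction * n / 2)
  clustered <- rep(FALSE, n)
  if (n_pairs > 0) clustered[seq_len(2L * n_pairs)] <- TRUE
  nuclei <- lapply(seq_len(n), function(i)
    generate_nucleus(phases[i], spec, circular = clustered[i]))
  margin <- max(vapply(nuclei, function(nu) nu$r, numeric(1))) + 2
  centers <- matrix(NA_real_, n, 2)
  eff_r <- vapply(nuclei, function(nu) nu$axes[["a"]], numeric(1))
  place_one <- function(i, anchor = NULL, dist = NULL, avoid_extra = 0) {
    for (try in seq_len(400L)) {
      if (is.null(anchor)) {
        cx <- stats::runif(1, margin, w - 1 - margin)
        cy <- stats::runif(1, margin, h - 1 - margin)
      } else {
        ang <- stats::runif(1, 0, 2 * pi)
        cx <- anchor[1] + dist * cos(ang)
        cy <- anchor[2] + dist * sin(ang)
        if (cx < margin || cx > w - 1 - margin ||
            cy < margin || cy > h - 1 - margin) next
      }
      ok <- TRUE
      for (j in seq_len(n)) {
        if (j == i || is.na(centers[j, 1])) next
        dmin <- eff_r[i] + eff_r[j] + 4 + avoid_extra
        if (!is.null(anchor) && all(abs(centers[j, ] - anchor) < 1e-9)) next
        if (sum((c(cx, cy) - centers[j, ])^2) < dmin^2) { ok <- FALSE; next }
      }
      if (ok) return(c(cx, cy))
    }
    stop("could not place ", n, " nuclei in a ", w, "x", h,
         " image; use a larger image or fewer nuclei")
  }
  i <- 1L
  while (i <= 2L * n_pairs) {
    centers[i, ] <- place_one(i, avoid_extra = 2 * max(eff_r))
    depth <- stats::runif(1, spec$overlap_range[1], spec$overlap_range[2])
    d <- eff_r[i] + eff_r[i + 1L] - depth * min(nuclei[[i]]$axes[["b"]],
                                                nuclei[[i + 1L]]$axes[["b"]])
    centers[i + 1L, ] <- place_one(i + 1L, anchor = centers[i, ], dist = d)
    i <- i + 2L
  }
  for (j in seq_len(n)) if (is.na(centers[j, 1]))
    centers[j, ] <- place_one(j)
  canvas <- matrix(0, h, w)
  truth <- matrix(0L, h, w)
  truth_d2 <- matrix(Inf, h, w)                # nearest-center tie-break
  for (j in seq_len(n)) {
    nu <- nuclei[[j]]
    r <- nu$r
    cx <- round(centers[j, 1]); cy <- round(centers[j, 2])
    rows <- (cy - r):(cy + r) + 1L
    cols <- (cx - r):(cx + r) + 1L
    canvas[rows, cols] <- canvas[rows, cols] + nu$texture
    m <- nu$mask
    loc <- which(m)
    lr <- ((loc - 1L) %% nrow(m)); lc <- ((loc - 1L) %/% nrow(m))
    gy <- cy - r + lr; gx <- cx - r + lc
    d2 <- (gx - centers[j, 1])^2 + (gy - centers[j, 2])^2
    lin <- gx * h + gy + 1L
    upd <- d2 < truth_d2[lin]
    truth[lin[upd]] <- j
    truth_d2[lin[upd]] <- d2[upd]
  }
  img <- canvas + spec$background
  if (spec$mode == "widefield") {              # out-of-focus haze
    haze <- gaussian_blur(matrix(stats::rnorm(h * w), h, w), 25)
    haze <- haze / max(stats::sd(haze), 1e-9)
    img <- img + 6 * (haze - min(haze))
  }
  img <- gaussian_blur(img, spec$psf_sigma)
  s <- spec$poisson_scale
  img <- s * matrix(stats::rpois(h * w, pmax(img, 0) / s), h, w)
  img <- img + stats::rnorm(h * w, 0, spec$gaussian_sd_frac * max(img))
  img <- pmax(img, 0)
  ann <- do.call(rbind, lapply(seq_len(n), function(j) {
    lin <- which(truth == j)
    data.frame(x = mean((lin - 1L) %/% h), y = mean((lin - 1L) %% h),
               label = phases[j], nucleus_id = j, clustered = clustered[j])
  }))
  structure(list(image = pcna_image(img, id = sprintf("synthetic_seed%d",
                                                      spec$rng_seed),
                                    bit_depth_hint = "float"),
                 truth_labels = truth, annotations = ann, spec = spec),
            class = "pcna_scene")
}

#' @export
print.pcna_scene <- function(x, ...) {
  cat(sprintf("pcna_scene (%s, seed %d): %d x %d px, %d nuclei (%d clustered)\n",
              x$spec$mode, x$spec$rng_seed, x$spec$width, x$spec$height,
              nrow(x$annotations), sum(x$annotations$clustered)))
  invisible(x)
}

#' Write a scene to disk
#'
#' Writes `image.tif` (16-bit), `truth_labels.tif` (16-bit),
#' `annotations.csv` and `spec.json` into a directory; the JSON spec is
#' sufficient to regenerate the identical scene.
#'
#' @param scene a [generate_scene()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  px <- round(scene$image$pixels)
  if (max(px) > 65535) px <- round(px / max(px) * 65535)
  write_image(px, file.path(dir, "image.tif"), bits = 16)
  write_labels(scene$truth_labels, file.path(dir, "truth_labels.tif"))
  write_annotations(scene$annotations, file.path(dir, "annotations.csv"))
  sp <- unclass(scene$spec)
  sp$phase_mix <- as.list(sp$phase_mix)        # keep the phase names in JSON
  jsonlite::write_json(sp, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a scene spec back from JSON
#'
#' @param path `spec.json` written by [write_scene()].
#' @return a [scene_spec()].
#' @export
read_scene_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$phase_mix <- unlist(raw$phase_mix)
  do.call(scene_spec, raw)
}

#' Ellipse mask with fringy boundary
#'
#' Rasterizes a single ellipse whose boundary radius is perturbed by smooth
#' periodic noise — the "fringy segmentation border" artifact that makes the
#' watershed baseline over-split single nuclei. Uses the current RNG state.
#'
#' @param a,b semi-axes in pixels.
#' @param noise_sd standard deviation of the radial boundary perturbation
#'   (px); 0 gives a clean ellipse.
#' @param noise_scale angular smoothing of the perturbation (harmonics below
#'   this period survive).
#' @return integer 0/1 mask matrix just large enough for the shape.
#' @export
noisy_ellipse_mask <- function(a, b, noise_sd = 1.5, noise_scale = 8) {
  r <- ceiling(max(a, b) + 4 * noise_sd) + 2L
  n <- 2L * r + 1L
  n_theta <- 720L
  pert <- smooth_circular(stats::rnorm(n_theta), noise_scale)
  if (stats::sd(pert) > 0) pert <- pert / stats::sd(pert) * noise_sd
  xs <- matrix(rep(-r:r, each = n), n, n)
  ys <- matrix(rep(-r:r, times = n), n, n)
  theta <- atan2(ys, xs)
  ti <- pmin(pmax(1L, 1L + as.integer(round((theta + pi) / (2 * pi) *
                                              (n_theta - 1L)))), n_theta)
  # ellipse boundary radius along each direction, plus the perturbation
  rb <- 1 / sqrt((cos(theta) / a)^2 + (sin(theta) / b)^2)
  mask <- (sqrt(xs^2 + ys^2) <= rb + pert[ti]) + 0L
  mask
}

#' Single-nucleus phase benchmark
#'
#' Generates `n_per_class` isolated nuclei per phase, each rendered on its
#' own small tile with the full imaging model (PSF, Poisson and Gaussian
#' noise, widefield haze), together with its exact mask. This is the
#' classification benchmark input: features are computed on the true masks,
#' so feature and classifier quality are measured free of segmentation
#' error.
#'
#' @param n_per_class nuclei per phase.
#' @param mode `"confocal"` or `"widefield"`.
#' @param seed integer seed.
#' @param spec optional [scene_spec()] template for the imaging parameters.
#' @return list with `images` (list of matrices), `masks` (list of 0/1
#'   integer matrices), `phases` (factor).
#' @export
phase_benchmark <- function(n_per_class = 100L,
                            mode = c("confocal", "widefield"),
                            seed = 42L, spec = NULL) {
  mode <- match.arg(mode)
  if (is.null(spec)) spec <- scene_spec(mode = mode, rng_seed = seed)
  phases <- factor(rep(phase_levels(), each = n_per_class),
                   levels = phase_levels())
  with_seed(seed, {
    tiles <- lapply(as.character(phases), function(ph) {
      nu <- generate_nucleus(ph, spec)
      pad <- 6L
      n <- nrow(nu$mask) + 2L * pad
      img <- matrix(0, n, n)
      ctr <- pad + seq_len(nrow(nu$mask))
      img[ctr, ctr] <- nu$texture
      img <- img + spec$background
      if (spec$mode == "widefield") {
        haze <- gaussian_blur(matrix(stats::rnorm(n * n), n, n), 15)
        haze <- haze / max(stats::sd(haze), 1e-9)
        img <- img + 6 * (haze - min(haze))
      }
      img <- gaussian_blur(img, spec$psf_sigma)
      s <- spec$poisson_scale
      img <- s * matrix(stats::rpois(n * n, pmax(img, 0) / s), n, n)
      img <- img + stats::rnorm(n * n, 0, spec$gaussian_sd_frac * max(img))
      msk <- matrix(0L, n, n)
      msk[ctr, ctr] <- nu$mask + 0L
      list(image = pmax(img, 0), mask = msk)
    })
    list(images = lapply(tiles, `[[`, "image"),
         masks = lapply(tiles, `[[`, "mask"),
         phases = phases)
  })
}

#' Feature table for a phase benchmark
#'
#' @param bench a [phase_benchmark()] result.
#' @param feature_set_id see [assemble_features()].
#' @param config a [pcna_config()].
#' @return data.frame of features, one row per nucleus, aligned with
#'   `bench$phases`.
#' @export
benchmark_feature_table <- function(bench, feature_set_id = "proposed",
                                    config = pcna_config()) {
  rows <- lapply(seq_along(bench$images), function(i) {
    seg <- nucleus_segment(bench$images[[i]], bench$masks[[i]], 1L)
    assemble_features(bench$images[[i]], seg, feature_set_id, config)
  })
  as.data.frame(do.call(rbind, rows))
}
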