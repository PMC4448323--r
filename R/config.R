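#' Pipeline configuration
#'
#' Builds a validated configuration object holding every tunable parameter of
#' the pipeline. All arguments have defaults, so `pcna_config()` with no
#' arguments is a complete, runnable configuration; [load_config()] reads the
#' same fields from a YAML or JSON file.
#'
#' @param n_bins histogram bins used by [li_threshold()].
#' @param presmooth_sigma Gaussian pre-smoothing scale (pixels) applied before
#'   thresholding; `0` disables it. Widefield images benefit from ~1 px.
#' @param connectivity pixel connectivity for component labeling, 4 or 8.
#' @param min_area,max_area nucleus area range (pixels); objects outside are
#'   rejected, oversized ones flagging unsplittable clusters.
#' @param curvature_scale Gaussian smoothing scale (contour vertices ~ pixels)
#'   for contour curvature estimation.
#' @param kappa_min concavity threshold (1/pixels) for split-point detection.
#' @param nms_window non-maximum-suppression half-window (vertices) around a
#'   split point.
#' @param theta_max maximal angle (degrees) between a split point's inward
#'   normal and the chord direction for the anti-parallel constraint.
#' @param c_min minimal solidity (area / convex hull area) each split part
#'   must reach for the convexity constraint.
#' @param n_max maximal number of parts attempted by the iterative split
#'   search.
#' @param lambda weight of the chord-length term in the split cost.
#' @param epsilon cost margin by which a split must beat leaving the object
#'   unsplit.
#' @param n_radius radius samples (columns) of the polar image.
#' @param n_zones radial zones for [zone_means()].
#' @param glcm_levels gray levels the co-occurrence matrix is binned to.
#' @param glcm_distances pixel pair offsets used for the polar Haralick
#'   vector.
#' @param curvature_sigma Gaussian derivative scale (pixels) for the intensity
#'   surface curvature histogram.
#' @param hist_bins bins of the intensity and curvature histogram features.
#' @param classifier one of `"decision_tree"`, `"svm_eccm"`, `"adaboost"`.
#' @param tree_depth decision tree depth limit.
#' @param tree_min_entropy stop growing a node whose class entropy (nats)
#'   falls below this value.
#' @param svm_C soft-margin penalty of the SVM.
#' @param svm_kernel `"linear"` or `"radial"`.
#' @param boost_rounds AdaBoost rounds.
#' @param cv_folds cross-validation folds.
#' @param rng_seed non-negative integer seed driving all randomness.
#'
#' @return an object of class `pcna_config` (a named list).
#' @examples
#' cfg <- pcna_config()
#' cfg$n_zones
#' @export
pcna_config <- function(n_bins = 256L,
                        presmooth_sigma = 0,
                        connectivity = 8L,
                        min_area = 250,
                        max_area = 2500,
                        curvature_scale = 2,
                        kappa_min = 0.15,
                        nms_window = 5L,
                        theta_max = 75,
                        c_min = 0.75,
                        n_max = 4L,
                        lambda = 0.3,
                        epsilon = 0.005,
                        n_radius = 32L,
                        n_zones = 8L,
                        glcm_levels = 32L,
                        glcm_distances = c(1L, 2L),
                        curvature_sigma = 1.5,
                        hist_bins = 64L,
                        classifier = "decision_tree",
                        tree_depth = 12L,
                        tree_min_entropy = 0,
                        svm_C = 1,
                        svm_kernel = "linear",
                        boost_rounds = 50L,
                        cv_folds = 10L,
                        rng_seed = 0L) {
  cfg <- list(
    n_bins = as.integer(n_bins), presmooth_sigma = presmooth_sigma,
    connectivity = as.integer(connectivity),
    min_area = min_area, max_area = max_area,
    curvature_scale = curvature_scale, kappa_min = kappa_min,
    nms_window = as.integer(nms_window), theta_max = theta_max,
    c_min = c_min, n_max = as.integer(n_max),
    lambda = lambda, epsilon = epsilon,
    n_radius = as.integer(n_radius), n_zones = as.integer(n_zones),
    glcm_levels = as.integer(glcm_levels),
    glcm_distances = as.integer(glcm_distances),
    curvature_sigma = curvature_sigma, hist_bins = as.integer(hist_bins),
    classifier = classifier, tree_depth = as.integer(tree_depth),
    tree_min_entropy = tree_min_entropy,
    svm_C = svm_C, svm_kernel = svm_kernel,
    boost_rounds = as.integer(boost_rounds),
    cv_folds = as.integer(cv_folds), rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num <- cfg[c("n_bins", "min_area", "max_area", "curvature_scale",
               "kappa_min", "nms_window", "theta_max", "c_min", "n_max",
               "lambda", "n_radius", "n_zones", "glcm_levels",
               "curvature_sigma", "hist_bins", "tree_depth", "svm_C",
               "boost_rounds", "cv_folds")]
  bad <- names(num)[!vapply(num, function(v) is.numeric(v) && all(is.finite(v)) && all(v > 0),
                            logical(1))]
  if (length(bad))
    stop("config: parameters must be positive and finite: ",
         paste(bad, collapse = ", "))
  if (!cfg$connectivity %in% c(4L, 8L))
    stop("config: connectivity must be 4 or 8")
  if (cfg$min_area >= cfg$max_area)
    stop("config: min_area must be smaller than max_area")
  if (cfg$n_zones < 2L)
    stop("config: n_zones must be at least 2")
  if (cfg$n_max < 2L)
    stop("config: n_max must be at least 2")
  if (cfg$rng_seed < 0L)
    stop("config: rng_seed must be a non-negative integer")
  if (cfg$epsilon < 0 || cfg$presmooth_sigma < 0 || cfg$tree_min_entropy < 0)
    stop("config: epsilon, presmooth_sigma and tree_min_entropy must be >= 0")
  if (!cfg$classifier %in% c("decision_tree", "svm_eccm", "adaboost"))
    stop("config: unknown classifier '", cfg$classifier, "'")
  if (!cfg$svm_kernel %in% c("linear", "radial"))
    stop("config: svm_kernel must be 'linear' or 'radial'")
  structure(cfg, class = "pcna_config")
}

#' Load a pipeline configuration from file
#'
#' Reads a YAML or JSON file of parameter overrides; unspecified fields take
#' the defaults of [pcna_config()]. The resolved configuration is validated
#' and echoed to the log.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file. Unknown keys are an
#'   error so that typos do not silently fall back to defaults.
#' @return a `pcna_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  known <- names(formals(pcna_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("config: unknown fields: ", paste(unknown, collapse = ", "))
  cfg <- do.call(pcna_config, raw)
  pcna_log("config", "loaded %s (%d overrides): seed=%d",
           basename(path), length(raw), cfg$rng_seed)
  cfg
}

#' @export
print.pcna_config <- function(x, ...) {
  cat("pcnaphase pipeline configuration\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

# Minimal stage logger; silenced unless option pcnaphase.verbose is TRUE.
pcna_log <- function(stage, fmt, ...) {
  if (isTRUE(getOption("pcnaphase.verbose", FALSE)))
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  invisible(NULL)
}
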