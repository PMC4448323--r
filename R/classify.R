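#' Z-score normalizer
#'
#' Estimates per-feature mean and standard deviation (population form) on
#' training data; [apply_normalizer()] transforms any table with the same
#' columns using those training statistics, so test data never leak into the
#' normalization. Features with zero training spread map to 0.
#'
#' @param features numeric data.frame or matrix (>= 2 rows), one feature per
#'   named column.
#' @return object of class `pcna_normalizer`.
#' @export
fit_normalizer <- function(features) {
  m <- as.matrix(features)
  if (nrow(m) < 2L) stop("need at least 2 samples to fit a normalizer")
  mu <- colMeans(m)
  sd_ <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  structure(list(mean = mu, sd = sd_, feature_names = colnames(m)),
            class = "pcna_normalizer")
}

#' @rdname fit_normalizer
#' @param normalizer a fitted `pcna_normalizer`.
#' @export
apply_normalizer <- function(normalizer, features) {
  m <- as.matrix(features)[, normalizer$feature_names, drop = FALSE]
  z <- sweep(m, 2L, normalizer$mean)
  sd_ <- normalizer$sd
  z <- sweep(z, 2L, ifelse(sd_ > 0, sd_, 1), "/")
  z[, sd_ == 0] <- 0
  z
}

check_features <- function(features, feature_names) {
  missing <- setdiff(feature_names, colnames(features))
  extra <- setdiff(colnames(features), feature_names)
  if (length(missing) || length(extra))
    stop("feature schema mismatch: missing [",
         paste(utils::head(missing, 3), collapse = ", "), "], extra [",
         paste(utils::head(extra, 3), collapse = ", "), "]")
  invisible(TRUE)
}

new_model <- function(kind, fit, feature_names, classes, normalizer) {
  structure(list(kind = kind, fit = fit, feature_names = feature_names,
                 classes = classes, normalizer = normalizer),
            class = c(paste0("pcna_", kind), "pcna_model"))
}

#' @export
print.pcna_model <- function(x, ...) {
  cat(sprintf("pcna_model (%s): %d features, classes: %s\n", x$kind,
              length(x$feature_names), paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Train an information-gain decision tree
#'
#' Greedy top-down induction over continuous features with binary threshold
#' splits: at each node every feature is scanned and the split threshold (a
#' midpoint between consecutive sorted distinct values) maximizing the
#' information gain — class entropy before the split minus the weighted class
#' entropy of the two children — is chosen. Growth stops when a node is pure,
#' the depth limit is reached, the node entropy falls below `min_entropy`, or
#' no split has positive gain. Leaves carry the majority class, ties going to
#' the lexicographically first label. Tree depth limiting and the entropy
#' floor are the pruning knobs guarding against overfitting.
#'
#' @param features numeric data.frame/matrix with named columns.
#' @param labels factor or character vector of class labels.
#' @param depth_limit maximal tree depth (0 = root only, a majority vote).
#' @param min_entropy stop splitting nodes whose entropy (nats) is below
#'   this.
#' @param normalize fit and embed a z-score normalizer (default TRUE).
#' @return a `pcna_model` of kind `decision_tree`.
#' @export
train_decision_tree <- function(features, labels, depth_limit = 12L,
                                min_entropy = 0, normalize = TRUE) {
  labels <- as.factor(labels)
  classes <- levels(droplevels(labels))
  labels <- factor(as.character(labels), levels = classes)
  if (length(classes) < 2L)
    warning("single-class training data: tree is a single leaf")
  norm <- if (normalize) fit_normalizer(features) else NULL
  x <- if (normalize) apply_normalizer(norm, features) else as.matrix(features)
  y <- as.integer(labels)
  tree <- grow_tree(x, y, length(classes), depth = 0L,
                    depth_limit = depth_limit, min_entropy = min_entropy)
  new_model("decision_tree", list(tree = tree), colnames(x), classes, norm)
}

majority_class <- function(y, n_classes) {
  cnt <- tabulate(y, nbins = n_classes)
  which.max(cnt)                               # ties: first (lexicographic)
}

grow_tree <- function(x, y, n_classes, depth, depth_limit, min_entropy) {
  ent <- label_entropy(y)
  if (length(unique(y)) == 1L || depth >= depth_limit ||
      ent < min_entropy || length(y) < 2L)
    return(list(leaf = TRUE, class = majority_class(y, n_classes),
                n = length(y)))
  sp <- best_split(x, y, n_classes)
  if (is.null(sp))
    return(list(leaf = TRUE, class = majority_class(y, n_classes),
                n = length(y)))
  left <- x[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       gain = sp$gain,
       left = grow_tree(x[left, , drop = FALSE], y[left], n_classes,
                        depth + 1L, depth_limit, min_entropy),
       right = grow_tree(x[!left, , drop = FALSE], y[!left], n_classes,
                         depth + 1L, depth_limit, min_entropy))
}

# Best (feature, midpoint threshold) by information gain; NULL if no split
# has positive gain. Vectorized over split positions per feature.
best_split <- function(x, y, n_classes) {
  n <- length(y)
  parent <- label_entropy(y)
  best <- NULL
  for (f in seq_len(ncol(x))) {
    xv <- x[, f]
    o <- order(xv, y)
    xs <- xv[o]; ys <- y[o]
    distinct <- which(diff(xs) > 0)
    if (!length(distinct)) next
    onehot <- matrix(0L, n, n_classes)
    onehot[cbind(seq_len(n), ys)] <- 1L
    cum <- apply(onehot, 2L, cumsum)
    cl <- cum[distinct, , drop = FALSE]        # left counts at each cut
    nl <- distinct; nr <- n - nl
    cr <- matrix(rep(cum[n, ], each = length(distinct)),
                 ncol = n_classes) - cl
    hl <- row_entropy(cl); hr <- row_entropy(cr)
    gain <- parent - (nl * hl + nr * hr) / n
    bi <- which.max(gain)
    if (gain[bi] > 1e-12 &&
        (is.null(best) || gain[bi] > best$gain + 1e-12)) {
      thr <- (xs[distinct[bi]] + xs[distinct[bi] + 1L]) / 2
      best <- list(feature = f, threshold = thr, gain = gain[bi])
    }
  }
  best
}

row_entropy <- function(counts) {
  tot <- rowSums(counts)
  p <- counts / ifelse(tot > 0, tot, 1)
  -rowSums(ifelse(p > 0, p * log(p), 0))
}

predict_tree_one <- function(node, xrow) {
  while (!node$leaf)
    node <- if (xrow[node$feature] <= node$threshold) node$left else node$right
  node$class
}

#' Train a multi-class SVM with error-correcting output decoding
#'
#' Reduces the multi-class problem to binary soft-margin SVMs via a coding
#' matrix, by default one-vs-all: one SVM per class separating it from the
#' rest (each binary machine minimizes `||w||^2 / 2 + C * sum(xi)` subject to
#' the margin constraints; the dual is solved by the libsvm solver in
#' \pkg{e1071}). Prediction evaluates all machines, concatenates the sign
#' bits, and assigns the class whose codeword has minimal Hamming distance,
#' ties going to the lowest class index.
#'
#' @param features numeric data.frame/matrix with named columns.
#' @param labels factor/character class labels (>= 2 classes).
#' @param C soft-margin penalty (> 0).
#' @param kernel `"linear"` or `"radial"`.
#' @param code_matrix optional `n_classes x n_machines` 0/1 matrix; default
#'   one-vs-all (identity).
#' @param normalize fit and embed a z-score normalizer (default TRUE).
#' @return a `pcna_model` of kind `svm_eccm`.
#' @export
train_svm_eccm <- function(features, labels, C = 1, kernel = "linear",
                           code_matrix = NULL, normalize = TRUE) {
  if (C <= 0) stop("C must be positive")
  labels <- as.factor(labels)
  classes <- levels(droplevels(labels))
  if (length(classes) < 2L) stop("need at least 2 classes")
  labels <- factor(as.character(labels), levels = classes)
  if (is.null(code_matrix)) code_matrix <- diag(length(classes))
  if (nrow(code_matrix) != length(classes))
    stop("code matrix must have one row per class")
  norm <- if (normalize) fit_normalizer(features) else NULL
  x <- if (normalize) apply_normalizer(norm, features) else as.matrix(features)
  machines <- vector("list", ncol(code_matrix))
  for (m in seq_len(ncol(code_matrix))) {
    bit <- code_matrix[as.integer(labels), m]
    if (length(unique(bit)) < 2L) { machines[m] <- list(NULL); next }
    yy <- factor(bit, levels = c(0, 1))
    machines[[m]] <- e1071::svm(x, yy, kernel = kernel, cost = C,
                                scale = FALSE)
  }
  new_model("svm_eccm",
            list(machines = machines, code_matrix = code_matrix,
                 C = C, kernel = kernel),
            colnames(x), classes, norm)
}

decode_hamming <- function(bits, code_matrix) {
  # bits: n x n_machines of 0/1; returns class indices, ties -> lowest
  d <- sapply(seq_len(nrow(code_matrix)), function(cl) {
    rowSums(sweep(bits, 2L, code_matrix[cl, ], function(a, b) a != b))
  })
  if (is.null(dim(d))) d <- matrix(d, nrow = 1L)
  apply(d, 1L, which.min)
}

#' Train a multi-class AdaBoost over decision stumps
#'
#' Stage-wise additive boosting (multi-class SAMME reweighting) of one-level
#' decision trees. Each round fits the best weighted stump — a single
#' feature, one threshold, one class predicted on each side — on the current
#' sample weights, giving the boosted ensemble an implicit feature selection:
#' the sequence of chosen features is recorded in the model. Training stops
#' early when the best stump is no better than chance for the current
#' weights.
#'
#' @param features numeric data.frame/matrix with named columns.
#' @param labels factor/character class labels.
#' @param rounds maximal boosting rounds (>= 1).
#' @param normalize fit and embed a z-score normalizer (default TRUE).
#' @return a `pcna_model` of kind `adaboost`; `model$fit$selected_features`
#'   lists the feature chosen at each round.
#' @export
train_adaboost <- function(features, labels, rounds = 50L, normalize = TRUE) {
  if (rounds < 1L) stop("rounds must be >= 1")
  labels <- as.factor(labels)
  classes <- levels(droplevels(labels))
  labels <- factor(as.character(labels), levels = classes)
  k <- length(classes)
  norm <- if (normalize) fit_normalizer(features) else NULL
  x <- if (normalize) apply_normalizer(norm, features) else as.matrix(features)
  y <- as.integer(labels)
  n <- length(y)
  w <- rep(1 / n, n)
  learners <- list(); alphas <- numeric(0); sel <- integer(0)
  for (t in seq_len(rounds)) {
    st <- best_stump(x, y, w, k)
    pred <- stump_predict(st, x)
    err <- sum(w * (pred != y))
    if (err >= 1 - 1 / k - 1e-12) break        # no better than chance
    err <- max(err, 1e-12)
    alpha <- log((1 - err) / err) + log(k - 1)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    learners[[length(learners) + 1L]] <- st
    alphas <- c(alphas, alpha)
    sel <- c(sel, st$feature)
    if (err < 1e-10) break                     # separable: done
  }
  new_model("adaboost",
            list(learners = learners, alphas = alphas,
                 selected_features = colnames(x)[sel]),
            colnames(x), classes, norm)
}

# Best weighted stump: per feature, threshold between sorted distinct values,
# majority class (by weight) on each side, minimizing weighted error.
best_stump <- function(x, y, w, n_classes) {
  best <- NULL
  n <- length(y)
  for (f in seq_len(ncol(x))) {
    o <- order(x[, f], y)
    xs <- x[o, f]; ys <- y[o]; ws <- w[o]
    distinct <- which(diff(xs) > 0)
    if (!length(distinct)) next
    wmat <- matrix(0, n, n_classes)
    wmat[cbind(seq_len(n), ys)] <- ws
    cum <- apply(wmat, 2L, cumsum)
    tot <- cum[n, ]
    cl <- cum[distinct, , drop = FALSE]
    cr <- matrix(rep(tot, each = length(distinct)), ncol = n_classes) - cl
    left_best <- max.col(cl, ties.method = "first")
    right_best <- max.col(cr, ties.method = "first")
    err <- (1 - (cl[cbind(seq_along(distinct), left_best)] +
                 cr[cbind(seq_along(distinct), right_best)]))
    bi <- which.min(err)
    if (is.null(best) || err[bi] < best$err - 1e-15) {
      best <- list(feature = f,
                   threshold = (xs[distinct[bi]] + xs[distinct[bi] + 1L]) / 2,
                   left_class = left_best[bi], right_class = right_best[bi],
                   err = err[bi])
    }
  }
  if (is.null(best)) {                          # all features constant
    best <- list(feature = 1L, threshold = Inf,
                 left_class = majority_class(y, n_classes),
                 right_class = majority_class(y, n_classes), err = 0.5)
  }
  best
}

stump_predict <- function(st, x) {
  ifelse(x[, st$feature] <= st$threshold, st$left_class, st$right_class)
}

#' Predict phase labels
#'
#' Applies the model's embedded normalizer, matches feature columns by name
#' (order-insensitive), and returns one label per row. Deterministic.
#'
#' @param object a `pcna_model`.
#' @param features numeric data.frame/matrix whose named columns match the
#'   training schema.
#' @param ... unused.
#' @return factor of predicted labels with the model's class levels.
#' @export
predict.pcna_model <- function(object, features, ...) {
  check_features(features, object$feature_names)
  x <- if (!is.null(object$normalizer))
    apply_normalizer(object$normalizer, features)
  else as.matrix(features)[, object$feature_names, drop = FALSE]
  idx <- switch(object$kind,
    decision_tree = apply(x, 1L, function(r)
      predict_tree_one(object$fit$tree, r)),
    svm_eccm = {
      bits <- sapply(seq_along(object$fit$machines), function(m) {
        mac <- object$fit$machines[[m]]
        if (is.null(mac)) return(rep(0L, nrow(x)))
        as.integer(as.character(predict(mac, x)))
      })
      if (is.null(dim(bits))) bits <- matrix(bits, nrow = nrow(x))
      decode_hamming(bits, object$fit$code_matrix)
    },
    adaboost = {
      score <- matrix(0, nrow(x), length(object$classes))
      for (t in seq_along(object$fit$learners)) {
        pr <- stump_predict(object$fit$learners[[t]], x)
        score[cbind(seq_len(nrow(x)), pr)] <-
          score[cbind(seq_len(nrow(x)), pr)] + object$fit$alphas[t]
      }
      max.col(score, ties.method = "first")
    },
    stop("unknown model kind ", object$kind))
  factor(object$classes[idx], levels = object$classes)
}

#' k-fold cross-validation
#'
#' Seeded random partition into `k` folds; for each fold the normalizer and
#' the classifier are fitted on the training part only and evaluated on the
#' held-out part. Per-fold and pooled confusion matrices are returned.
#' Unstratified sampling by default, matching a plain random split; set
#' `stratify = TRUE` to sample folds within classes, which matters when one
#' class is scarce.
#'
#' @param features numeric data.frame/matrix with named columns.
#' @param labels factor/character class labels.
#' @param k number of folds.
#' @param classifier `"decision_tree"`, `"svm_eccm"` or `"adaboost"`.
#' @param seed integer RNG seed for the fold assignment.
#' @param config a [pcna_config()] supplying classifier hyperparameters.
#' @param stratify sample folds within classes.
#' @return object of class `pcna_cv`: `folds` (assignment vector),
#'   `per_fold` (list of confusion matrices), `confusion` (pooled),
#'   `accuracy`, `predictions`, `seed`.
#' @export
cross_validate <- function(features, labels, k = 10L,
                           classifier = c("decision_tree", "svm_eccm",
                                          "adaboost"),
                           seed = 0L, config = pcna_config(),
                           stratify = FALSE) {
  classifier <- match.arg(classifier)
  labels <- as.factor(labels)
  classes <- levels(droplevels(labels))
  labels <- factor(as.character(labels), levels = classes)
  n <- length(labels)
  if (n < k) stop("need at least k samples")
  folds <- with_seed(seed, {
    if (stratify) {
      f <- integer(n)
      for (cl in classes) {
        idx <- which(labels == cl)
        f[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
      }
      f
    } else sample(rep(seq_len(k), length.out = n))
  })
  preds <- factor(rep(classes[1], n), levels = classes)
  per_fold <- vector("list", k)
  for (fold in seq_len(k)) {
    te <- folds == fold
    ytr <- droplevels(labels[!te])
    if (nlevels(ytr) < length(classes))
      warning("fold ", fold, ": class absent from training part")
    model <- switch(classifier,
      decision_tree = train_decision_tree(features[!te, , drop = FALSE],
                                          ytr, config$tree_depth,
                                          config$tree_min_entropy),
      svm_eccm = train_svm_eccm(features[!te, , drop = FALSE], ytr,
                                config$svm_C, config$svm_kernel),
      adaboost = train_adaboost(features[!te, , drop = FALSE], ytr,
                                config$boost_rounds))
    p <- predict(model, features[te, , drop = FALSE])
    preds[te] <- factor(as.character(p), levels = classes)
    per_fold[[fold]] <- table(true = labels[te], predicted = preds[te])
  }
  cm <- table(true = labels, predicted = preds)
  structure(list(folds = folds, per_fold = per_fold, confusion = cm,
                 accuracy = sum(diag(cm)) / sum(cm), predictions = preds,
                 classifier = classifier, seed = seed),
            class = "pcna_cv")
}

#' @export
print.pcna_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s, seed %d): accuracy %.3f\n",
              length(x$per_fold), x$classifier, x$seed, x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Save / load a trained model
#'
#' Serializes the model — including its embedded normalizer and feature
#' names — to a single file.
#'
#' @param model a `pcna_model`.
#' @param path file path.
#' @return `path` / the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "pcna_model")) stop("not a pcna_model file: ", path)
  m
}
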