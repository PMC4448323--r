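# Small separable 2-D toy: class A around (-2, 0), class B around (2, 0).
toy_2class <- function(n = 20, gap = 4) {
  set.seed(1)
  x <- rbind(cbind(rnorm(n, -gap / 2, 0.3), rnorm(n, 0, 0.3)),
             cbind(rnorm(n, gap / 2, 0.3), rnorm(n, 0, 0.3)))
  colnames(x) <- c("f1", "f2")
  list(x = as.data.frame(x),
       y = factor(rep(c("G", "LATE_S"), each = n),
                  levels = c("G", "LATE_S")))
}

test_that("z-score normalization uses training statistics only", {
  f <- data.frame(a = c(1, 2, 3), b = c(5, 5, 5))
  nz <- fit_normalizer(f)
  z <- apply_normalizer(nz, f)
  expect_equal(z[, "a"], c(-1.2247, 0, 1.2247), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(z[, "b"], c(0, 0, 0), ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(z))), 1e-10)

  test <- data.frame(a = c(10, 20), b = c(1, 2))
  zt <- apply_normalizer(nz, test)
  expect_equal(zt[1, "a"], (10 - 2) / sqrt(2 / 3), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("normalization leakage changes held-out results (leak detector)", {
  # training values cluster at 0/1; the single extreme test point shifts a
  # normalizer fitted on everything, which must not happen in cross_validate
  x <- data.frame(f = c(rep(0, 10), rep(1, 10), 100))
  y <- factor(c(rep("G", 10), rep("LATE_S", 11)))
  train <- 1:20
  nz_clean <- fit_normalizer(x[train, , drop = FALSE])
  nz_leaky <- fit_normalizer(x)
  expect_gt(abs(apply_normalizer(nz_clean, x)[21, 1] -
                apply_normalizer(nz_leaky, x)[21, 1]), 1)
})

test_that("decision tree solves the separable case at depth 1", {
  d <- data.frame(f = c(runif(10, 0, 0.4), runif(10, 0.6, 1)))
  y <- factor(rep(c("G", "MID_S"), each = 10))
  m <- train_decision_tree(d, y)
  expect_false(m$fit$tree$leaf)
  expect_true(m$fit$tree$left$leaf && m$fit$tree$right$leaf)
  expect_equal(as.character(predict(m, d)), as.character(y))
})

test_that("the root split matches the exhaustive information-gain oracle", {
  set.seed(8)
  for (rep in 1:3) {
    x <- matrix(rnorm(20 * 3), 20, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    y <- factor(sample(c("G", "EARLY_S", "MID_S"), 20, replace = TRUE))
    m <- train_decision_tree(as.data.frame(x), y, normalize = FALSE)
    oracle <- oracle_best_root_split(x, y)
    expect_equal(colnames(x)[oracle$feature],
                 m$feature_names[m$fit$tree$feature])
    expect_equal(m$fit$tree$threshold, oracle$threshold)
    expect_equal(m$fit$tree$gain, oracle$gain, tolerance = 1e-10)
  }
})

test_that("depth limit 0 yields the majority-class predictor", {
  d <- data.frame(f = 1:10)
  y <- factor(c(rep("G", 6), rep("MID_S", 4)))
  m <- train_decision_tree(d, y, depth_limit = 0L)
  expect_true(m$fit$tree$leaf)
  expect_true(all(predict(m, d) == "G"))
})

test_that("single-class input warns and returns a single leaf", {
  d <- data.frame(f = 1:5)
  expect_warning(m <- train_decision_tree(d, factor(rep("G", 5))),
                 "single-class")
  expect_true(m$fit$tree$leaf)
})

test_that("linear SVM recovers the maximal margin on parallel clusters", {
  # two lines of points at x = -1 and x = +1: maximal margin is exactly 2
  x <- data.frame(f1 = rep(c(-1, 1), each = 5), f2 = rep(seq(0, 2, 0.5), 2))
  y <- factor(rep(c("G", "LATE_S"), each = 5))
  m <- train_svm_eccm(x, y, C = 1e4, normalize = FALSE)
  expect_equal(as.character(predict(m, x)), as.character(y))
  sv <- m$fit$machines[[1]]
  w <- crossprod(sv$coefs, sv$SV)
  margin <- 2 / sqrt(sum(w^2))
  expect_equal(margin, 2, tolerance = 0.01)
  expect_error(train_svm_eccm(x, y, C = -1), "positive")
})

test_that("Hamming decoding follows the documented codeword and tie rules", {
  code <- diag(4)
  expect_equal(pcnaphase:::decode_hamming(matrix(c(0, 1, 0, 0), 1), code), 2L)
  # (1,1,0,0) ties classes 1 and 2 -> lowest index
  expect_equal(pcnaphase:::decode_hamming(matrix(c(1, 1, 0, 0), 1), code), 1L)
  expect_equal(pcnaphase:::decode_hamming(matrix(c(0, 0, 0, 0), 1), code), 1L)
})

test_that("four-class one-vs-all SVM predicts all classes on separated blobs", {
  set.seed(2)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6), c(6, 6))
  x <- do.call(rbind, lapply(1:4, function(k)
    cbind(rnorm(15, centers[k, 1], 0.4), rnorm(15, centers[k, 2], 0.4))))
  colnames(x) <- c("f1", "f2")
  y <- factor(rep(phase_levels(), each = 15), levels = phase_levels())
  m <- train_svm_eccm(as.data.frame(x), y)
  expect_equal(as.character(predict(m, as.data.frame(x))), as.character(y))
})

test_that("AdaBoost nails the separable case and guards against chance", {
  toy <- toy_2class()
  m <- train_adaboost(toy$x, toy$y, rounds = 10L)
  expect_equal(as.character(predict(m, toy$x)), as.character(toy$y))
  expect_lte(length(m$fit$selected_features), 10L)

  # pure-noise labels: training fit grows but held-out accuracy stays at
  # chance (overfitting guard)
  set.seed(5)
  xr <- as.data.frame(matrix(rnorm(200 * 5), 200, 5))
  names(xr) <- paste0("f", 1:5)
  yr <- factor(sample(c("G", "LATE_S"), 200, replace = TRUE))
  mr <- train_adaboost(xr[1:100, ], yr[1:100], rounds = 40L)
  train_acc <- mean(predict(mr, xr[1:100, ]) == yr[1:100])
  test_acc <- mean(predict(mr, xr[101:200, ]) == yr[101:200])
  expect_gt(train_acc, 0.6)
  expect_lt(test_acc, 0.65)
  expect_error(train_adaboost(toy$x, toy$y, rounds = 0L), "rounds")
})

test_that("prediction matches columns by name and rejects schema breaks", {
  toy <- toy_2class()
  m <- train_decision_tree(toy$x, toy$y)
  permuted <- toy$x[, c("f2", "f1")]
  expect_identical(predict(m, permuted), predict(m, toy$x))
  expect_error(predict(m, toy$x["f1"]), "schema")
  extra <- cbind(toy$x, f3 = 1)
  expect_error(predict(m, extra), "schema")
})

test_that("cross-validation partitions, pools, and reproduces", {
  set.seed(2)
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8), c(8, 8))
  x <- do.call(rbind, lapply(1:4, function(k)
    cbind(rnorm(25, centers[k, 1], 0.4), rnorm(25, centers[k, 2], 0.4))))
  colnames(x) <- c("f1", "f2")
  y <- factor(rep(phase_levels(), each = 25), levels = phase_levels())
  cv <- cross_validate(as.data.frame(x), y, k = 10L, "decision_tree",
                       seed = 3L)
  expect_equal(as.vector(sort(table(cv$folds))), rep(10L, 10))
  expect_equal(cv$accuracy, 1)
  expect_equal(sum(cv$confusion), 100)
  expect_equal(Reduce(`+`, lapply(cv$per_fold, sum)), 100)

  cv2 <- cross_validate(as.data.frame(x), y, k = 10L, "decision_tree",
                        seed = 3L)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$confusion, cv2$confusion)
  expect_identical(cv$predictions, cv2$predictions)

  cvs <- cross_validate(as.data.frame(x), y, k = 10L, "decision_tree",
                        seed = 3L, stratify = TRUE)
  expect_true(all(sapply(split(y, cvs$folds), function(f)
    all(table(f) > 0))))
  expect_error(cross_validate(as.data.frame(x)[1:5, ], y[1:5], k = 10L),
               "at least k")
})

test_that("models survive a save / load round trip", {
  toy <- toy_2class()
  m <- train_decision_tree(toy$x, toy$y)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  back <- load_model(f)
  expect_identical(predict(back, toy$x), predict(m, toy$x))
  saveRDS(1:3, f)
  expect_error(load_model(f), "pcna_model")
})
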