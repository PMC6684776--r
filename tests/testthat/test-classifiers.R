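# a small separable two-class fixture shared by several tests
separable_fixture <- function(n = 12, seed = 50) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(n / 2 * 4, mean = 0, sd = 0.3), n / 2, 4),
    matrix(rnorm(n / 2 * 4, mean = 3, sd = 0.3), n / 2, 4)
  )
  list(X = X, y = rep(c("RH", "RA"), each = n / 2))
}

test_that("PLS-DA separates a clean fixture and codes classes 0/1", {
  fx <- separable_fixture()
  fit <- fit_plsda(fx$X, fx$y, n_latent = 2)
  expect_equal(fit$classes, c("RA", "RH")) # alphabetical coding
  expect_equal(unname(predict(fit, fx$X)), fx$y)
  resp <- predict(fit, fx$X, type = "response")
  expect_true(all(resp[fx$y == "RH"] > 0.5) && all(resp[fx$y == "RA"] < 0.5))
  expect_error(fit_plsda(fx$X, rep("RH", 12)), "two classes")
})

test_that("PLS with all latent variables equals least squares", {
  set.seed(51)
  X <- matrix(rnorm(24), 8, 3)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  lab <- ifelse(y == 1, "b", "a")
  fit <- fit_plsda(X, lab, n_latent = 3)
  ols <- lm(y ~ X)
  expect_equal(
    predict(fit, X, type = "response"),
    unname(fitted(ols)),
    tolerance = 1e-8
  )
})

test_that("KNN matches a brute-force vote and K=1 resubstitutes perfectly", {
  X <- matrix(c(
    0, 0,
    1, 0,
    0, 1,
    5, 5
  ), 4, 2, byrow = TRUE)
  y <- c("A", "A", "B", "B")
  fit <- fit_knn(X, y, k = 3)
  q <- matrix(c(0.4, 0.1), 1, 2)
  # brute force: neighbors of q are rows 1,2,3 -> vote A,A,B -> A
  d <- sqrt(rowSums((X - matrix(q, 4, 2, byrow = TRUE))^2))
  nb <- order(d)[1:3]
  expect_equal(names(sort(table(y[nb]), decreasing = TRUE))[1], "A")
  expect_equal(unname(predict(fit, q)), "A")

  fx <- separable_fixture()
  f1 <- fit_knn(fx$X, fx$y, k = 1)
  expect_equal(unname(predict(f1, fx$X)), fx$y)
  expect_error(fit_knn(fx$X, fx$y, k = 12), "< the number")
})

test_that("LOO selection returns the best K, ties to the smallest", {
  fx <- separable_fixture(n = 16)
  sel <- select_k_loo(fx$X, fx$y, k_grid = c(1, 3, 5))
  expect_equal(sel$accuracy, rep(1, 3)) # all perfect on separable data
  fit <- fit_knn(fx$X, fx$y, k = NULL, k_grid = c(1, 3, 5))
  expect_equal(fit$k, 1L)
})

test_that("SIMCA accepts in-class queries and can refuse both classes", {
  fx <- separable_fixture(n = 16)
  fit <- fit_simca(fx$X, fx$y, n_pcs = 2, alpha = 0.05)
  pred <- predict(fit, fx$X)
  expect_equal(unname(pred), fx$y)
  # a far-off query is rejected by both class models
  far <- matrix(50, 1, 4)
  expect_equal(unname(predict(fit, far)), "unassigned")
  expect_error(fit_simca(fx$X, fx$y, n_pcs = 8), "class size")
})

test_that("SIMCA with zero calibration residual rejects off-model queries", {
  # 3 collinear points per class, 1 PC: residual variance is exactly 0
  dirv <- c(1, 2)
  Xa <- outer(c(-1, 0, 1), dirv)
  Xb <- outer(c(-1, 0, 1), dirv) + 10
  X <- rbind(Xa, Xb)
  y <- rep(c("A", "B"), each = 3)
  fit <- fit_simca(X, y, n_pcs = 1, alpha = 0.05)
  on_line <- matrix(0.5 * dirv, 1, 2)
  expect_equal(unname(predict(fit, on_line)), "A")
  off_line <- matrix(c(2, -1) * 3, 1, 2) # orthogonal to both class lines
  expect_equal(unname(predict(fit, off_line)), "unassigned")
})

test_that("CART grows pure unpruned trees with hand-checkable Gini", {
  # weighted child Gini of a perfect (5,5) -> (5,0)/(0,5) split is 0,
  # parent Gini 0.5
  X <- matrix(c(rep(0, 5), rep(1, 5)), 10, 1)
  y <- rep(c("A", "B"), each = 5)
  fit <- fit_cart(X, y)
  expect_false(fit$tree$leaf)
  expect_true(fit$tree$left$leaf && fit$tree$right$leaf)
  expect_equal(fit$tree$gain, 0.5) # parent 0.5 minus child 0
  expect_equal(unname(predict(fit, X)), y)
})

test_that("the CART root split matches exhaustive search on a toy table", {
  X <- matrix(c(
    1.0, 10,
    2.0, 9,
    3.0, 8,
    4.0, 1,
    5.0, 2,
    6.0, 3
  ), 6, 2, byrow = TRUE)
  y <- c("A", "A", "B", "B", "B", "A")
  gini2 <- function(pos, n) {
    if (n == 0) 0 else 2 * (pos / n) * (1 - pos / n)
  }
  best <- NULL
  for (j in 1:2) {
    xs <- sort(unique(X[, j]))
    for (i in seq_len(length(xs) - 1)) {
      thr <- (xs[i] + xs[i + 1]) / 2
      l <- X[, j] <= thr
      g <- (sum(l) * gini2(sum(y[l] == "B"), sum(l)) +
        sum(!l) * gini2(sum(y[!l] == "B"), sum(!l))) / 6
      if (is.null(best) || g < best$g - 1e-12) {
        best <- list(j = j, thr = thr, g = g)
      }
    }
  }
  fit <- fit_cart(X, y)
  expect_equal(fit$tree$feature, best$j)
  expect_equal(fit$tree$threshold, best$thr)
})

test_that("SVM-DA solves the 1-D analytic margin problem", {
  X <- matrix(c(-1, 1), 2, 1)
  y <- c("neg", "pos")
  fit <- fit_svmda(X, y, cost = 1000)
  # both points are support vectors; the boundary sits at 0
  expect_equal(length(fit$fit$index), 2)
  expect_equal(unname(predict(fit, matrix(c(-0.2, 0.2), 2, 1))),
    c("neg", "pos"))
  fx <- separable_fixture()
  fs <- fit_svmda(fx$X, fx$y)
  expect_equal(unname(predict(fs, fx$X)), fx$y)
  # conflicting duplicate labels: soft margin still returns a model
  Xd <- matrix(c(0, 0), 2, 1)
  expect_s3_class(fit_svmda(Xd, c("a", "b")), "crp_svmda")
  expect_error(fit_svmda(X, c("a", "a")), "two classes")
})

test_that("all five classifiers share the fit/predict contract", {
  fx <- separable_fixture(n = 16)
  fits <- list(
    fit_plsda(fx$X, fx$y),
    fit_knn(fx$X, fx$y, k = 3),
    fit_simca(fx$X, fx$y, n_pcs = 2),
    fit_cart(fx$X, fx$y),
    fit_svmda(fx$X, fx$y)
  )
  q <- fx$X[c(1, 9), ]
  for (f in fits) {
    expect_s3_class(f, "crp_classifier")
    p1 <- predict(f, q)
    expect_type(p1, "character")
    allowed <- c(f$classes, if (f$kind == "simca") "unassigned")
    expect_true(all(p1 %in% allowed))
    # predict is pure: repeated calls identical
    expect_identical(p1, predict(f, q))
  }
})

test_that("training-row permutation leaves predictions unchanged", {
  fx <- separable_fixture(n = 20, seed = 52)
  set.seed(53)
  perm <- sample(20)
  q <- matrix(rnorm(8 * 4, 1.5, 1.5), 8, 4)
  fitters <- list(
    function(X, y) fit_plsda(X, y),
    function(X, y) fit_knn(X, y, k = 3),
    function(X, y) fit_simca(X, y, n_pcs = 2),
    function(X, y) fit_cart(X, y),
    function(X, y) fit_svmda(X, y)
  )
  for (ft in fitters) {
    a <- predict(ft(fx$X, fx$y), q)
    b <- predict(ft(fx$X[perm, ], fx$y[perm]), q)
    expect_identical(unname(a), unname(b))
  }
})
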