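#' Supervised classifiers for two-class fingerprint authentication
#'
#' Five classifiers share one contract: `fit_*(X, y, ...)` returns a
#' `crp_classifier`, and `predict()` on new rows returns a character
#' vector of class labels. SIMCA is the only model allowed to return
#' `"unassigned"` (a sample rejected by both class models). Prediction is
#' pure and deterministic; row order of the training data never changes
#' the fitted model beyond documented tie-breaks.
#'
#' @name crp_classifiers
NULL

as_X <- function(m) {
  if (inherits(m, "crp_matrix")) m$X else as.matrix(m)
}

check_two_classes <- function(y) {
  y <- as.character(y)
  cls <- sort(unique(y))
  if (length(cls) != 2) {
    crp_abort("exactly two classes are required")
  }
  list(y = y, classes = cls)
}

new_classifier <- function(kind, fields, classes) {
  structure(
    c(list(kind = kind, classes = classes), fields),
    class = c(paste0("crp_", kind), "crp_classifier")
  )
}

#' @export
print.crp_classifier <- function(x, ...) {
  cat(sprintf(
    "<crp_classifier:%s> classes %s vs %s\n",
    x$kind, x$classes[1], x$classes[2]
  ))
  invisible(x)
}

#' @export
glance.crp_classifier <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    class_0 = x$classes[1],
    class_1 = x$classes[2],
    n_train = x$n_train
  )
}

#' Partial least squares discriminant analysis (PLS-DA)
#'
#' Classes are coded 0/1 (first and second element of `classes`, sorted
#' alphabetically by default) and a deflation-based (NIPALS) PLS1
#' regression of the code on the fingerprint matrix is fitted. Prediction
#' is the regression response, thresholded symmetrically at 0.5: a
#' response close to 1 assigns the 1-coded class, close to 0 the 0-coded
#' class. Two latent variables is the working default for MALDI
#' fingerprint matrices (one for UPLC matrices).
#'
#' @param X A [crp_matrix()] or numeric matrix of calibration rows.
#' @param y Class labels (two classes).
#' @param n_latent Number of latent variables.
#' @param classes Optional length-2 character vector fixing the 0/1
#'   coding, `c(class0, class1)`.
#' @return A `crp_plsda` classifier.
#' @export
fit_plsda <- function(X, y, n_latent = 2, classes = NULL) {
  X <- as_X(X)
  cc <- check_two_classes(y)
  if (!is.null(classes)) {
    stopifnot(setequal(classes, cc$classes))
    cc$classes <- classes
  }
  y01 <- as.double(cc$y == cc$classes[2])
  n <- nrow(X)
  a <- as.integer(n_latent)
  if (a < 1 || a > min(n - 1, ncol(X))) {
    crp_abort("`n_latent` out of range")
  }
  xm <- colMeans(X)
  ym <- mean(y01)
  Xc <- sweep(X, 2, xm)
  yc <- y01 - ym
  W <- matrix(0, ncol(X), a)
  P <- matrix(0, ncol(X), a)
  qv <- numeric(a)
  for (h in seq_len(a)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) {
      crp_abort("X carries no covariance with the class code; reduce n_latent")
    }
    w <- w / nw
    t_ <- drop(Xc %*% w)
    tt <- sum(t_^2)
    p <- drop(crossprod(Xc, t_)) / tt
    q <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, p)
    yc <- yc - q * t_
    W[, h] <- w
    P[, h] <- p
    qv[h] <- q
  }
  B <- W %*% solve(crossprod(P, W), qv)
  new_classifier("plsda", list(
    coefficients = drop(B), x_means = xm, y_mean = ym,
    n_latent = a, weights = W, loadings = P, q = qv,
    threshold = 0.5, n_train = n
  ), cc$classes)
}

#' @export
predict.crp_plsda <- function(object, newdata, type = c("class", "response"),
                              ...) {
  type <- match.arg(type)
  X <- as_X(newdata)
  yhat <- object$y_mean +
    drop(sweep(X, 2, object$x_means) %*% object$coefficients)
  if (type == "response") {
    return(yhat)
  }
  ifelse(yhat >= object$threshold, object$classes[2], object$classes[1])
}

#' @export
tidy.crp_plsda <- function(x, ...) {
  tibble::tibble(
    term = seq_along(x$coefficients),
    estimate = x$coefficients
  )
}

#' K-nearest neighbors (KNN)
#'
#' Euclidean-distance majority vote over the `k` nearest calibration
#' rows. A tied vote resolves to the class of the single nearest
#' neighbor. `k = 3` is the working default for both MALDI and UPLC
#' fingerprint matrices; `fit_knn(k = NULL)` selects `k` from `k_grid` by
#' leave-one-out cross-validation (ties to the smallest `k`).
#'
#' @param X Calibration rows.
#' @param y Class labels.
#' @param k Number of neighbors (`< n`), or `NULL` to select by LOO.
#' @param k_grid Candidate `k` values for LOO selection.
#' @return A `crp_knn` classifier.
#' @export
fit_knn <- function(X, y, k = 3, k_grid = c(1, 3, 5, 7, 9)) {
  X <- as_X(X)
  cc <- check_two_classes(y)
  if (is.null(k)) {
    sel <- select_k_loo(X, cc$y, k_grid)
    k <- sel$k[which.max(sel$accuracy)]
  }
  k <- as.integer(k)
  if (k >= nrow(X)) crp_abort("`k` must be < the number of training rows")
  if (k < 1) crp_abort("`k` must be >= 1")
  new_classifier("knn", list(
    X = X, y = cc$y, k = k, n_train = nrow(X)
  ), cc$classes)
}

knn_vote <- function(train, labels, k, newX) {
  apply(newX, 1, function(row) {
    d <- sqrt(colSums((t(train) - row)^2))
    nb <- order(d)[seq_len(k)] # stable: distance ties go to lower index
    tab <- table(labels[nb])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) top else labels[nb[1]]
  })
}

#' @export
predict.crp_knn <- function(object, newdata, ...) {
  knn_vote(object$X, object$y, object$k, as_X(newdata))
}

#' Select K for KNN by leave-one-out cross-validation
#'
#' @param X Calibration rows.
#' @param y Class labels.
#' @param k_grid Candidate `k` values.
#' @return A tibble with `k` and LOO `accuracy`, ordered as `k_grid`.
#' @export
select_k_loo <- function(X, y, k_grid = c(1, 3, 5, 7, 9)) {
  X <- as_X(X)
  y <- as.character(y)
  n <- nrow(X)
  k_grid <- k_grid[k_grid < n]
  if (length(k_grid) == 0) crp_abort("no candidate k is < n")
  D <- as.matrix(stats::dist(X))
  acc <- vapply(k_grid, function(k) {
    hits <- vapply(seq_len(n), function(i) {
      d <- D[i, -i]
      lab <- y[-i]
      nb <- order(d)[seq_len(k)]
      tab <- table(lab[nb])
      top <- names(tab)[tab == max(tab)]
      pred <- if (length(top) == 1) top else lab[nb[1]]
      pred == y[i]
    }, TRUE)
    mean(hits)
  }, 1)
  tibble::tibble(k = as.integer(k_grid), accuracy = acc)
}

#' Soft independent modeling of class analogy (SIMCA)
#'
#' One PCA model per class (class-mean centering). A query's residual
#' variance against each class model is compared to that class's
#' calibration residual variance by an F-ratio; the query is a member of
#' every class whose F-ratio is below the critical value at `1 - alpha`.
#' The label is the sole member class, the smaller-F class when both
#' accept, or `"unassigned"` when both reject — SIMCA is the only model
#' here that can refuse to classify. Five PCs per class is the working
#' default for MALDI fingerprint matrices (one for UPLC).
#'
#' @param X Calibration rows.
#' @param y Class labels.
#' @param n_pcs PCs per class: scalar or vector named by class.
#' @param alpha Significance level of the residual F-test (default 0.05).
#' @return A `crp_simca` classifier.
#' @export
fit_simca <- function(X, y, n_pcs = 5, alpha = 0.05) {
  X <- as_X(X)
  cc <- check_two_classes(y)
  p <- ncol(X)
  models <- lapply(cc$classes, function(cl) {
    rows <- X[cc$y == cl, , drop = FALSE]
    n_c <- nrow(rows)
    k <- if (length(n_pcs) > 1) n_pcs[[cl]] else n_pcs
    k <- as.integer(k)
    if (k >= n_c) {
      crp_abort(sprintf(
        "class %s: n_pcs (%d) must be < class size (%d)", cl, k, n_c
      ))
    }
    mu <- colMeans(rows)
    Rc <- sweep(rows, 2, mu)
    sv <- svd(Rc, nu = 0, nv = min(k, n_c - 1, p))
    V <- sv$v[, seq_len(k), drop = FALSE]
    resid <- Rc - Rc %*% V %*% t(V)
    df <- (p - k) * max(n_c - k - 1, 1)
    s0 <- sum(resid^2) / df
    list(
      class = cl, mean = mu, loadings = V, k = k, n = n_c,
      s0 = s0, df0 = df
    )
  })
  names(models) <- cc$classes
  new_classifier("simca", list(
    models = models, alpha = alpha, n_train = nrow(X)
  ), cc$classes)
}

simca_fratio <- function(model, X) {
  Xc <- sweep(X, 2, model$mean)
  resid <- Xc - Xc %*% model$loadings %*% t(model$loadings)
  s2 <- rowSums(resid^2) / (ncol(X) - model$k)
  if (model$s0 <= .Machine$double.eps) {
    # degenerate calibration (zero residual variance): any off-model
    # variance rejects, an exactly in-model query is accepted
    ifelse(s2 <= .Machine$double.eps^0.5, 0, Inf)
  } else {
    s2 / model$s0
  }
}

#' @export
predict.crp_simca <- function(object, newdata, type = c("class", "fratio"),
                              ...) {
  type <- match.arg(type)
  X <- as_X(newdata)
  FR <- vapply(
    object$models, function(mod) simca_fratio(mod, X),
    double(nrow(X))
  )
  FR <- matrix(FR, nrow = nrow(X))
  colnames(FR) <- object$classes
  if (type == "fratio") {
    return(tibble::as_tibble(FR))
  }
  crit <- vapply(object$models, function(mod) {
    stats::qf(1 - object$alpha, ncol(X) - mod$k, mod$df0)
  }, 1)
  apply(FR, 1, function(f) {
    member <- which(f <= crit)
    if (length(member) == 0) {
      "unassigned"
    } else if (length(member) == 1) {
      object$classes[member]
    } else {
      object$classes[which.min(f)]
    }
  })
}

#' @export
tidy.crp_simca <- function(x, ...) {
  purrr::map_dfr(x$models, function(mod) {
    tibble::tibble(
      class = mod$class, n = mod$n, n_pcs = mod$k,
      residual_variance = mod$s0, df = mod$df0
    )
  })
}

#' Classification tree (CART)
#'
#' Binary splits minimizing weighted Gini impurity, grown until leaves
#' are pure or no split improves — no pruning, matching the practice of
#' leaving tree size undetermined for fingerprint matrices. Ties break
#' deterministically to the lowest feature index, then the lowest
#' threshold (thresholds are midpoints between adjacent sorted values);
#' a tied leaf majority resolves to the alphabetically first class.
#'
#' @param X Calibration rows.
#' @param y Class labels.
#' @param min_n Minimum rows needed to attempt a split (default 2).
#' @return A `crp_cart` classifier.
#' @export
fit_cart <- function(X, y, min_n = 2) {
  X <- as_X(X)
  cc <- check_two_classes(y)
  tree <- cart_grow(X, cc$y == cc$classes[2], cc$classes, min_n)
  new_classifier("cart", list(tree = tree, n_train = nrow(X)), cc$classes)
}

gini <- function(pos, n) {
  if (n == 0) {
    return(0)
  }
  p <- pos / n
  2 * p * (1 - p)
}

# best Gini split over all features/thresholds; NULL when nothing improves
cart_best_split <- function(X, y1) {
  n <- length(y1)
  parent <- gini(sum(y1), n)
  best <- NULL
  best_gain <- 1e-12
  for (j in seq_len(ncol(X))) {
    o <- order(X[, j])
    xv <- X[o, j]
    ys <- y1[o]
    cum_pos <- cumsum(ys)
    distinct <- which(diff(xv) > 0)
    if (length(distinct) == 0) next
    for (i in distinct) {
      nl <- i
      nr <- n - i
      g <- (nl * gini(cum_pos[i], nl) +
        nr * gini(cum_pos[n] - cum_pos[i], nr)) / n
      gain <- parent - g
      if (gain > best_gain) {
        best_gain <- gain
        best <- list(
          feature = j, threshold = (xv[i] + xv[i + 1]) / 2,
          gain = gain
        )
      }
    }
  }
  best
}

cart_grow <- function(X, y1, classes, min_n) {
  n <- length(y1)
  pos <- sum(y1)
  majority <- if (pos > n - pos) {
    classes[2]
  } else {
    classes[1] # ties resolve to the first (alphabetically lower) class
  }
  if (pos == 0 || pos == n || n < min_n) {
    return(list(leaf = TRUE, class = majority, n = n))
  }
  sp <- cart_best_split(X, y1)
  if (is.null(sp)) {
    return(list(leaf = TRUE, class = majority, n = n))
  }
  left <- X[, sp$feature] <= sp$threshold
  list(
    leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
    gain = sp$gain, n = n,
    left = cart_grow(X[left, , drop = FALSE], y1[left], classes, min_n),
    right = cart_grow(X[!left, , drop = FALSE], y1[!left], classes, min_n)
  )
}

#' @export
predict.crp_cart <- function(object, newdata, ...) {
  X <- as_X(newdata)
  walk <- function(node, row) {
    while (!node$leaf) {
      node <- if (row[node$feature] <= node$threshold) {
        node$left
      } else {
        node$right
      }
    }
    node$class
  }
  apply(X, 1, function(r) walk(object$tree, r))
}

#' @export
tidy.crp_cart <- function(x, ...) {
  out <- list()
  visit <- function(node, depth) {
    if (node$leaf) {
      out[[length(out) + 1]] <<- tibble::tibble(
        depth = depth, leaf = TRUE, feature = NA_integer_,
        threshold = NA_real_, class = node$class, n = node$n
      )
    } else {
      out[[length(out) + 1]] <<- tibble::tibble(
        depth = depth, leaf = FALSE, feature = node$feature,
        threshold = node$threshold, class = NA_character_, n = node$n
      )
      visit(node$left, depth + 1)
      visit(node$right, depth + 1)
    }
  }
  visit(x$tree, 0)
  dplyr::bind_rows(out)
}

#' Support vector machine discriminant analysis (SVM-DA)
#'
#' Soft-margin SVM via `e1071::svm()` (libsvm), default linear kernel
#' with cost 1, no internal rescaling (fingerprints are preprocessed
#' upstream). With `probability = TRUE` class probability estimates are
#' fitted as well (seeded, so results are reproducible).
#'
#' @param X Calibration rows.
#' @param y Class labels.
#' @param kernel Kernel name passed to `e1071::svm()`.
#' @param cost Soft-margin cost C.
#' @param probability Fit probability estimates.
#' @param seed Seed for the internal cross-validation used by the
#'   probability model.
#' @return A `crp_svmda` classifier.
#' @export
fit_svmda <- function(X, y, kernel = "linear", cost = 1,
                      probability = FALSE, seed = 1L) {
  X <- as_X(X)
  cc <- check_two_classes(y)
  fit <- with_seed(seed, e1071::svm(
    x = X, y = factor(cc$y, levels = cc$classes),
    kernel = kernel, cost = cost, scale = FALSE,
    probability = probability
  ))
  new_classifier("svmda", list(
    fit = fit, kernel = kernel, cost = cost, n_train = nrow(X)
  ), cc$classes)
}

#' @export
predict.crp_svmda <- function(object, newdata, ...) {
  as.character(predict(object$fit, as_X(newdata)))
}
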