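#' Principal component analysis of a fingerprint matrix
#'
#' Centered SVD. Component signs are fixed deterministically — the
#' largest-magnitude element of each loading vector is made positive — so
#' score plots reproduce across runs and platforms.
#'
#' @param m A [crp_matrix()] or numeric matrix.
#' @param n_components Number of components,
#'   `<= min(n_samples - 1, n_points)`.
#' @return A `crp_pca` object with fields `means`, `loadings`
#'   (points x components, orthonormal columns), `scores`
#'   (samples x components), `explained_variance` (score variance per
#'   component), `total_variance`, `all_eigenvalues` (every nonzero
#'   eigenvalue, used for Q-residual limits) and `n_components`.
#' @export
fit_pca <- function(m, n_components = 3) {
  X <- if (inherits(m, "crp_matrix")) m$X else as.matrix(m)
  n <- nrow(X)
  p <- ncol(X)
  k <- as.integer(n_components)
  if (k < 1 || k > min(n - 1, p)) {
    crp_abort("`n_components` must be in 1 .. min(n_samples - 1, n_points)")
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  # deterministic sign: largest-|loading| element positive per component
  for (j in seq_along(sv$d)) {
    v <- sv$v[, j]
    i <- which.max(abs(v))
    if (v[i] < 0) {
      sv$v[, j] <- -v
      sv$u[, j] <- -sv$u[, j]
    }
  }
  eig <- sv$d^2 / (n - 1)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- rownames(X)
  structure(
    list(
      means = mu,
      loadings = sv$v[, seq_len(k), drop = FALSE],
      scores = scores,
      explained_variance = eig[seq_len(k)],
      total_variance = sum(eig),
      all_eigenvalues = eig,
      n_components = k,
      n_samples = n,
      sample_ids = if (inherits(m, "crp_matrix")) m$sample_ids else rownames(X),
      class_labels = if (inherits(m, "crp_matrix")) m$class_labels else NULL
    ),
    class = "crp_pca"
  )
}

#' @export
print.crp_pca <- function(x, ...) {
  pct <- 100 * x$explained_variance / x$total_variance
  cat(sprintf(
    "<crp_pca> %d component(s); explained variance: %s\n",
    x$n_components, paste(sprintf("%.1f%%", pct), collapse = ", ")
  ))
  invisible(x)
}

# project new rows into a PCA model (centering with the model's means)
pca_project <- function(model, X) {
  Xc <- sweep(as.matrix(X), 2, model$means)
  Xc %*% model$loadings
}

#' @export
tidy.crp_pca <- function(x, ...) {
  out <- tibble::as_tibble(x$scores, .name_repair = "minimal")
  names(out) <- sprintf("PC%d", seq_len(x$n_components))
  dplyr::bind_cols(
    tibble::tibble(
      sample_id = x$sample_ids %||% sprintf("sample_%d", seq_len(nrow(x$scores))),
      class_label = x$class_labels %||% NA_character_
    ),
    out
  )
}

#' @export
glance.crp_pca <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    explained_variance = sum(x$explained_variance),
    total_variance = x$total_variance,
    prop_explained = sum(x$explained_variance) / x$total_variance
  )
}

#' @export
autoplot.crp_pca <- function(object, components = c(1, 2), ...) {
  d <- tidy(object)
  pct <- 100 * object$explained_variance / object$total_variance
  xs <- sprintf("PC%d", components[1])
  ys <- sprintf("PC%d", components[2])
  ggplot2::ggplot(d, ggplot2::aes(
    .data[[xs]], .data[[ys]],
    colour = .data$class_label
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xs, pct[components[1]]),
      y = sprintf("%s (%.1f%%)", ys, pct[components[2]]),
      colour = "class"
    )
}

#' Hotelling's T-squared / Q-residual outlier detection
#'
#' Within-model distance (T-squared, the Mahalanobis distance of a
#' sample's scores) and off-model distance (Q, the squared reconstruction
#' residual) are computed for every row, with control limits at the given
#' confidence: the F-distribution limit `k(n-1)/(n-k) F(conf; k, n-k)`
#' for T-squared and the Jackson-Mudholkar approximation for Q. A sample
#' is flagged only when BOTH statistics exceed their limits — high
#' leverage alone, or high residual alone, is tolerated.
#'
#' @param model A `crp_pca` fitted on the calibration matrix.
#' @param m The matrix to screen (typically the one the model was fit on).
#' @param confidence Confidence level of the limits (default 0.95).
#' @return A `crp_outliers` object; its `report` field is a tibble with
#'   `sample_id`, `t2`, `q`, and logical `flagged`; limits are in fields
#'   `t2_limit` and `q_limit`.
#' @export
t2_q_outliers <- function(model, m, confidence = 0.95) {
  stopifnot(inherits(model, "crp_pca"))
  if (confidence <= 0 || confidence >= 1) {
    crp_abort("`confidence` must be strictly between 0 and 1")
  }
  X <- if (inherits(m, "crp_matrix")) m$X else as.matrix(m)
  if (ncol(X) != length(model$means)) {
    crp_abort("matrix columns do not match the PCA model")
  }
  ids <- if (inherits(m, "crp_matrix")) {
    m$sample_ids
  } else {
    rownames(X) %||% sprintf("sample_%d", seq_len(nrow(X)))
  }
  scores <- pca_project(model, X)
  lambda <- model$explained_variance
  t2 <- rowSums(sweep(scores^2, 2, lambda, "/"))
  recon <- scores %*% t(model$loadings)
  resid <- sweep(X, 2, model$means) - recon
  q <- rowSums(resid^2)
  n <- model$n_samples
  k <- model$n_components
  t2_limit <- if (n > k) {
    k * (n - 1) / (n - k) * stats::qf(confidence, k, n - k)
  } else {
    Inf
  }
  # Jackson-Mudholkar limit from the residual-space eigenvalues
  rest <- model$all_eigenvalues[-seq_len(k)]
  rest <- rest[rest > .Machine$double.eps * max(model$all_eigenvalues, 1)]
  if (length(rest) == 0) {
    q_limit <- 0
  } else {
    th1 <- sum(rest)
    th2 <- sum(rest^2)
    th3 <- sum(rest^3)
    h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
    if (!is.finite(h0) || h0 <= 0) h0 <- 1e-3
    ca <- stats::qnorm(confidence)
    q_limit <- th1 * (ca * sqrt(2 * th2 * h0^2) / th1 +
      1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
  }
  # numerically-zero residuals never flag, even when the Q limit is 0
  q_floor <- .Machine$double.eps^0.5 * max(model$total_variance, 1)
  flagged <- t2 > t2_limit & q > pmax(q_limit, q_floor)
  structure(
    list(
      report = tibble::tibble(
        sample_id = ids, t2 = t2, q = q, flagged = flagged
      ),
      t2_limit = t2_limit, q_limit = q_limit, confidence = confidence
    ),
    class = "crp_outliers"
  )
}

#' @export
print.crp_outliers <- function(x, ...) {
  cat(sprintf(
    "<crp_outliers> %d/%d flagged (T2 limit %.3g, Q limit %.3g, %.0f%%)\n",
    sum(x$report$flagged), nrow(x$report),
    x$t2_limit, x$q_limit, 100 * x$confidence
  ))
  if (any(x$report$flagged)) {
    cat(
      "flagged:",
      paste(x$report$sample_id[x$report$flagged], collapse = ", "), "\n"
    )
  }
  invisible(x)
}

#' @export
tidy.crp_outliers <- function(x, ...) x$report

#' @export
autoplot.crp_outliers <- function(object, ...) {
  ggplot2::ggplot(object$report, ggplot2::aes(
    .data$t2, .data$q,
    colour = .data$flagged
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$t2_limit, linetype = 2) +
    ggplot2::geom_hline(yintercept = object$q_limit, linetype = 2) +
    ggplot2::labs(x = "Hotelling's T²", y = "Q residual")
}

#' Ward hierarchical clustering of fingerprint rows
#'
#' Agglomerative clustering minimizing the Ward variance increase, run on
#' squared Euclidean distances (`hclust` method `"ward.D"` on `dist^2`,
#' the classic Ward/Lance-Williams formulation). Merge heights are
#' guaranteed non-decreasing.
#'
#' @param m A [crp_matrix()] or numeric matrix with >= 2 rows.
#' @return A `crp_dendrogram` wrapping the `hclust` result, with fields
#'   `merge`, `height`, `labels`.
#' @export
hca_ward <- function(m) {
  X <- if (inherits(m, "crp_matrix")) m$X else as.matrix(m)
  if (nrow(X) < 2) crp_abort("need >= 2 rows to cluster")
  d <- stats::dist(X)^2
  hc <- stats::hclust(d, method = "ward.D")
  hc$labels <- if (inherits(m, "crp_matrix")) {
    m$sample_ids
  } else {
    rownames(X) %||% as.character(seq_len(nrow(X)))
  }
  structure(list(hclust = hc), class = "crp_dendrogram")
}

#' @export
print.crp_dendrogram <- function(x, ...) {
  hc <- x$hclust
  cat(sprintf(
    "<crp_dendrogram> %d leaves, %d merges, heights [%.3g, %.3g]\n",
    length(hc$labels), nrow(hc$merge), min(hc$height), max(hc$height)
  ))
  invisible(x)
}

#' Cut a dendrogram into clusters
#'
#' Either `k` clusters (stop after `n - k` merges) or a height cut
#' (keep merges at height `<=` the cutoff).
#'
#' @param d A `crp_dendrogram` from [hca_ward()].
#' @param k Number of clusters.
#' @param height Height cutoff (used when `k` is missing).
#' @return A tibble with `sample_id` and integer `cluster`.
#' @export
cut_dendrogram <- function(d, k = NULL, height = NULL) {
  stopifnot(inherits(d, "crp_dendrogram"))
  n <- length(d$hclust$labels)
  if (!is.null(k)) {
    if (k < 1 || k > n) crp_abort("`k` must be in 1 .. n_leaves")
    cl <- stats::cutree(d$hclust, k = k)
  } else if (!is.null(height)) {
    if (height < 0) crp_abort("`height` must be >= 0")
    cl <- stats::cutree(d$hclust, h = height)
  } else {
    crp_abort("supply `k` or `height`")
  }
  tibble::tibble(sample_id = d$hclust$labels, cluster = unname(cl))
}

#' Export a dendrogram as Newick text
#'
#' Nested-parenthesis text with merge heights as branch lengths, suitable
#' for external tree viewers.
#'
#' @param d A `crp_dendrogram`.
#' @return A single Newick string ending in `;`.
#' @export
dendrogram_newick <- function(d) {
  stopifnot(inherits(d, "crp_dendrogram"))
  hc <- d$hclust
  node <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%.6g", hc$labels[-i], parent_h)
    } else {
      h <- hc$height[i]
      sprintf(
        "(%s,%s):%.6g",
        node(hc$merge[i, 1], h / 2), node(hc$merge[i, 2], h / 2),
        max(parent_h - h, 0)
      )
    }
  }
  top <- nrow(hc$merge)
  h <- hc$height[top]
  sprintf(
    "(%s,%s);",
    node(hc$merge[top, 1], h / 2), node(hc$merge[top, 2], h / 2)
  )
}
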