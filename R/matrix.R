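#' Fingerprint matrix: samples by data points
#'
#' A `crp_matrix` holds one row per sample and one column per point of the
#' shared axis — the study-scale object is 91 samples by 30935 m/z points.
#' The numeric block stays a base matrix (PCA, warping and classifier
#' numerics operate on it directly); labels travel alongside, and
#' [tidy.crp_matrix()] / [as_tibble.crp_matrix()] provide data-frame views.
#'
#' @param X Numeric matrix, `n_samples x n_points`.
#' @param axis Shared x-axis, length `ncol(X)`, strictly increasing.
#' @param sample_ids Character vector of unique sample ids, length `nrow(X)`.
#' @param class_labels Optional character vector of class labels per sample.
#' @return A `crp_matrix` object.
#' @export
crp_matrix <- function(X, axis, sample_ids = NULL, class_labels = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  axis <- as.double(axis)
  if (length(axis) != ncol(X)) {
    crp_abort("`axis` length must equal ncol(X)")
  }
  if (ncol(X) > 1 && any(diff(axis) <= 0)) {
    crp_abort("`axis` must be strictly increasing")
  }
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(rownames(X))) {
      rownames(X)
    } else {
      sprintf("sample_%d", seq_len(nrow(X)))
    }
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(X)) {
    crp_abort("`sample_ids` length must equal nrow(X)")
  }
  if (anyDuplicated(sample_ids)) crp_abort("duplicate sample_ids")
  if (is.null(class_labels)) {
    class_labels <- rep(NA_character_, nrow(X))
  }
  class_labels <- as.character(class_labels)
  if (length(class_labels) != nrow(X)) {
    crp_abort("`class_labels` length must equal nrow(X)")
  }
  rownames(X) <- sample_ids
  structure(
    list(
      X = X, axis = axis,
      sample_ids = sample_ids, class_labels = class_labels
    ),
    class = "crp_matrix"
  )
}

#' @export
print.crp_matrix <- function(x, ...) {
  cls <- unique(x$class_labels[!is.na(x$class_labels)])
  cat(sprintf(
    "<crp_matrix> %d samples x %d points, axis [%g, %g]%s\n",
    nrow(x$X), ncol(x$X), min(x$axis), max(x$axis),
    if (length(cls)) {
      paste0(
        ", classes: ",
        paste(sprintf(
          "%s (%d)", cls,
          vapply(cls, function(k) sum(x$class_labels == k, na.rm = TRUE), 1L)
        ), collapse = ", ")
      )
    } else {
      ""
    }
  ))
  invisible(x)
}

#' @export
dim.crp_matrix <- function(x) dim(x$X)

#' Assemble per-sample spectra into a fingerprint matrix
#'
#' All spectra must already share one axis (see [resample_to_grid()]) and
#' replicates must already be averaged to one spectrum per sample. Row
#' order follows input order; class labels are carried over from the
#' spectra.
#'
#' @param samples List of [crp_spectrum()] objects, one per sample.
#' @return A [crp_matrix()].
#' @export
assemble_matrix <- function(samples) {
  if (length(samples) < 1) crp_abort("need at least one spectrum")
  ax <- samples[[1]]$axis
  for (s in samples[-1]) {
    if (!isTRUE(all.equal(s$axis, ax, tolerance = 0))) {
      crp_abort("all spectra must share an identical axis; resample first")
    }
  }
  X <- t(vapply(samples, function(s) s$intensity, double(length(ax))))
  crp_matrix(
    X, ax,
    sample_ids = vapply(samples, sample_id, ""),
    class_labels = vapply(samples, class_label, "")
  )
}

#' Write / read a fingerprint matrix as CSV
#'
#' Layout: header row holds the axis values, first column `sample_id`,
#' second column `class_label`, remaining columns intensities. Values are
#' printed with 15 significant digits so a round-trip preserves them to
#' better than 12 significant digits.
#'
#' @param m A [crp_matrix()].
#' @param path Output (input) CSV path.
#' @return `write_matrix_csv()` returns `path` invisibly;
#'   `read_matrix_csv()` a [crp_matrix()].
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(inherits(m, "crp_matrix"))
  header <- paste(c(
    "sample_id", "class_label",
    sprintf("%.15g", m$axis)
  ), collapse = ",")
  body <- vapply(seq_len(nrow(m$X)), function(i) {
    paste(c(
      m$sample_ids[i], m$class_labels[i],
      sprintf("%.15g", m$X[i, ])
    ), collapse = ",")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) crp_abort("matrix CSV needs a header and >= 1 row")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  axis <- as.double(header[-(1:2)])
  cells <- strsplit(lines[-1], ",", fixed = TRUE)
  sample_ids <- vapply(cells, `[`, "", 1L)
  class_labels <- vapply(cells, `[`, "", 2L)
  class_labels[class_labels == "NA" | class_labels == ""] <- NA_character_
  X <- t(vapply(
    cells,
    function(f) as.double(f[-(1:2)]), double(length(axis))
  ))
  crp_matrix(X, axis, sample_ids, class_labels)
}

#' Tidy views of a fingerprint matrix
#'
#' `tidy()` returns the long form (one row per sample and axis point);
#' `as_tibble()` the wide form (one row per sample, one column per point).
#'
#' @param x A [crp_matrix()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.crp_matrix <- function(x, ...) {
  n <- nrow(x$X)
  p <- ncol(x$X)
  tibble::tibble(
    sample_id = rep(x$sample_ids, each = p),
    class_label = rep(x$class_labels, each = p),
    axis = rep(x$axis, times = n),
    intensity = as.vector(t(x$X))
  )
}

#' @rdname tidy.crp_matrix
#' @param .rows,.name_repair Ignored (present for generic compatibility).
#' @export
as_tibble.crp_matrix <- function(x, ..., .rows = NULL,
                                 .name_repair = NULL) {
  out <- tibble::as_tibble(x$X, .name_repair = "minimal")
  names(out) <- sprintf("%.15g", x$axis)
  dplyr::bind_cols(
    tibble::tibble(
      sample_id = x$sample_ids,
      class_label = x$class_labels
    ),
    out
  )
}

#' @export
autoplot.crp_matrix <- function(object, alpha = 0.5, ...) {
  d <- tidy.crp_matrix(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$axis, y = .data$intensity,
    group = .data$sample_id, colour = .data$class_label
  )) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::labs(x = "axis", y = "intensity", colour = "class")
}

#' @export
autoplot.crp_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$axis, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      title = sample_id(object),
      x = "axis", y = "intensity"
    )
}

# internal: subset rows of a crp_matrix
crp_matrix_rows <- function(m, idx) {
  crp_matrix(
    m$X[idx, , drop = FALSE], m$axis,
    m$sample_ids[idx], m$class_labels[idx]
  )
}
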