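#' Standard normal variate (SNV) row scaling
#'
#' Per-row standardization — subtract the row mean, divide by the row
#' standard deviation — removing multiplicative/slope variation between
#' spectra. Applied to a matrix it transforms each row independently.
#'
#' @param x Numeric vector (one spectrum row) or [crp_matrix()].
#' @return Same shape as the input; each row has mean 0 and sd 1.
#' @export
snv <- function(x) {
  if (inherits(x, "crp_matrix")) {
    sds <- apply(x$X, 1, stats::sd)
    if (any(sds == 0)) {
      crp_abort(sprintf(
        "row %d has zero standard deviation", which(sds == 0)[1]
      ))
    }
    X <- (x$X - rowMeans(x$X)) / sds
    return(crp_matrix(X, x$axis, x$sample_ids, x$class_labels))
  }
  snv_row(x)
}

snv_row <- function(x, idx = NULL) {
  if (length(x) < 2) crp_abort("SNV needs a row of length >= 2")
  s <- stats::sd(x)
  if (s == 0) {
    crp_abort(if (is.null(idx)) {
      "zero standard deviation row"
    } else {
      sprintf("row %s has zero standard deviation", idx)
    })
  }
  (x - mean(x)) / s
}

#' Sum-normalize a row
#'
#' Divides each variable by the sum of absolute values of the row, so
#' the output's absolute values sum to 1.
#'
#' @param x Numeric vector or [crp_matrix()].
#' @return Same shape as input.
#' @export
normalize_sum <- function(x) {
  if (inherits(x, "crp_matrix")) {
    X <- t(apply(x$X, 1, normalize_sum))
    return(crp_matrix(X, x$axis, x$sample_ids, x$class_labels))
  }
  tot <- sum(abs(x))
  if (tot == 0) crp_abort("cannot sum-normalize an all-zero row")
  x / tot
}

#' Column mean centering with stored means
#'
#' `mean_center()` learns column means on a calibration matrix and
#' subtracts them; `apply_centering()` subtracts those stored means from
#' new (validation) rows — the means are never refit, so no information
#' leaks from validation into the model.
#'
#' @param m A [crp_matrix()] or numeric matrix.
#' @return `mean_center()`: a list with `centered` (same class as input)
#'   and `means` (numeric vector of the learned column means).
#' @export
mean_center <- function(m) {
  X <- if (inherits(m, "crp_matrix")) m$X else as.matrix(m)
  mu <- colMeans(X)
  out <- sweep(X, 2, mu)
  if (inherits(m, "crp_matrix")) {
    out <- crp_matrix(out, m$axis, m$sample_ids, m$class_labels)
  }
  list(centered = out, means = mu)
}

#' @rdname mean_center
#' @param means Column means learned on the calibration set.
#' @export
apply_centering <- function(m, means) {
  X <- if (inherits(m, "crp_matrix")) m$X else as.matrix(m)
  if (ncol(X) != length(means)) {
    crp_abort("`means` length must equal the number of columns")
  }
  out <- sweep(X, 2, means)
  if (inherits(m, "crp_matrix")) {
    out <- crp_matrix(out, m$axis, m$sample_ids, m$class_labels)
  }
  out
}

#' Subtract a blank spectrum or chromatogram
#'
#' Point-wise difference removing baseline elevation (e.g. a blank UPLC
#' injection). Axes must match exactly; the result may be negative.
#'
#' @param sample,blank [crp_spectrum()] objects on the same axis.
#' @return A [crp_spectrum()].
#' @export
subtract_blank <- function(sample, blank) {
  stopifnot(inherits(sample, "crp_spectrum"), inherits(blank, "crp_spectrum"))
  if (!isTRUE(all.equal(sample$axis, blank$axis, tolerance = 0))) {
    crp_abort("sample and blank must share an identical axis")
  }
  crp_spectrum(sample$axis, sample$intensity - blank$intensity,
    sample_id = sample_id(sample), replicate_id = replicate_id(sample),
    class_label = class_label(sample)
  )
}

#' Preprocessing recipe: fit on calibration rows, apply anywhere
#'
#' An ordered sequence of steps from `cow`, `blank_subtract`, `snv`,
#' `normalize_sum`, `mean_center`. The default — SNV followed by mean
#' centering — is the combination that gives PLS-DA models the fewest
#' latent variables and the smallest calibration/prediction error on CRP
#' fingerprint matrices. Statistics with a fit/apply asymmetry (the
#' column means of `mean_center`) are learned by `prep()` on the
#' calibration matrix only and reapplied verbatim by `bake()`;
#' `mean_center` may appear at most once and must be the final step.
#'
#' @param steps Character vector of step names, in application order.
#' @param cow_params A [cow_params()] used when `"cow"` is a step.
#' @param blank A [crp_spectrum()] used when `"blank_subtract"` is a step.
#' @return A `crp_recipe` object; `prep()` returns a fitted recipe,
#'   `bake()` a preprocessed [crp_matrix()].
#' @export
crp_recipe <- function(steps = c("snv", "mean_center"),
                       cow_params = NULL, blank = NULL) {
  known <- c("cow", "blank_subtract", "snv", "normalize_sum", "mean_center")
  bad <- setdiff(steps, known)
  if (length(bad)) {
    crp_abort(sprintf("unknown step(s): %s", paste(bad, collapse = ", ")))
  }
  mc <- which(steps == "mean_center")
  if (length(mc) > 1) crp_abort("`mean_center` may appear at most once")
  if (length(mc) == 1 && mc != length(steps)) {
    crp_abort("`mean_center` must be the final step")
  }
  structure(
    list(
      steps = steps, cow_params = cow_params, blank = blank,
      cow_reference = NULL, means = NULL, fitted = FALSE
    ),
    class = "crp_recipe"
  )
}

apply_steps <- function(recipe, m, means) {
  for (st in recipe$steps) {
    m <- switch(st,
      cow = {
        prm <- recipe$cow_params %||% cow_params()
        if (!is.null(recipe$cow_reference)) {
          # warp every row onto the reference learned at prep() time
          X <- m$X
          for (i in seq_len(nrow(X))) {
            X[i, ] <- cow_align_pair(
              X[i, ], recipe$cow_reference,
              prm$segment_length, prm$slack
            )$warped
          }
          crp_matrix(X, m$axis, m$sample_ids, m$class_labels)
        } else {
          cow_align(m, prm)
        }
      },
      blank_subtract = {
        b <- recipe$blank
        if (is.null(b)) crp_abort("recipe step blank_subtract needs `blank`")
        crp_matrix(
          sweep(m$X, 2, b$intensity), m$axis,
          m$sample_ids, m$class_labels
        )
      },
      snv = snv(m),
      normalize_sum = normalize_sum(m),
      mean_center = apply_centering(m, means)
    )
  }
  m
}

#' @rdname crp_recipe
#' @param recipe A `crp_recipe`.
#' @param calibration A [crp_matrix()] of calibration rows.
#' @export
prep <- function(recipe, calibration) {
  stopifnot(inherits(recipe, "crp_recipe"), inherits(calibration, "crp_matrix"))
  if ("cow" %in% recipe$steps) {
    prm <- recipe$cow_params %||% cow_params()
    recipe$cow_reference <- calibration$X[prm$reference_index, ]
  }
  if ("mean_center" %in% recipe$steps) {
    pre <- recipe
    pre$steps <- setdiff(recipe$steps, "mean_center")
    pre$fitted <- TRUE
    m <- apply_steps(pre, calibration, NULL)
    recipe$means <- colMeans(m$X)
  }
  recipe$fitted <- TRUE
  recipe
}

#' @rdname crp_recipe
#' @param m A [crp_matrix()] (calibration or validation rows).
#' @export
bake <- function(recipe, m) {
  stopifnot(inherits(recipe, "crp_recipe"))
  if (!recipe$fitted) crp_abort("recipe must be prep()-ed before bake()")
  if ("mean_center" %in% recipe$steps && is.null(recipe$means)) {
    crp_abort("fitted recipe is missing stored column means")
  }
  apply_steps(recipe, m, recipe$means)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
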