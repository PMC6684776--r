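#' Venetian-blinds cross-validation folds
#'
#' Sample `i` belongs to block `((i - 1) mod n_blocks) + 1`; each block
#' is held out once. Ten blocks is the conventional default.
#'
#' @param n Number of samples.
#' @param n_blocks Number of blocks, `2 <= n_blocks <= n`.
#' @return A list of `n_blocks` elements, each `list(train, test)` of
#'   integer indices partitioning `1:n`.
#' @export
venetian_blinds <- function(n, n_blocks = 10) {
  n <- as.integer(n)
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2 || n_blocks > n) {
    crp_abort("`n_blocks` must be in 2 .. n")
  }
  block <- ((seq_len(n) - 1L) %% n_blocks) + 1L
  lapply(seq_len(n_blocks), function(b) {
    list(train = which(block != b), test = which(block == b))
  })
}

#' Regression-style error metrics
#'
#' `rmse_set()` is the root-mean-square error `sqrt(mean((y - yhat)^2))`
#' — RMSEC, RMSECV or RMSEP depending on which set the residuals come
#' from. `rsq()` is the squared Pearson correlation. `rmsep_deviation()`
#' is the percentage deviation between prediction and calibration error,
#' `100 * (rmsep - rmsec) / rmsep`; a small magnitude indicates the
#' model generalizes as well as it fits.
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return A single number.
#' @export
rmse_set <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred)) {
    crp_abort("`y_true` and `y_pred` must be non-empty and equal length")
  }
  sqrt(mean((y_true - y_pred)^2))
}

#' @rdname rmse_set
#' @export
rsq <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred)) {
    crp_abort("`y_true` and `y_pred` must be non-empty and equal length")
  }
  stats::cor(y_true, y_pred)^2
}

#' @rdname rmse_set
#' @param rmsec,rmsep Calibration and prediction RMSE (`rmsep > 0`).
#' @export
rmsep_deviation <- function(rmsec, rmsep) {
  if (any(rmsep <= 0)) crp_abort("`rmsep` must be > 0")
  100 * (rmsep - rmsec) / rmsep
}

#' Confusion summary with an "unassigned" outcome
#'
#' Builds the two-class confusion counts and the derived rates used to
#' compare classification models. Class-modeling methods (SIMCA) may
#' refuse to classify; those `"unassigned"` outcomes are handled
#' asymmetrically, the only convention consistent with published
#' confusion tables of this kind: an unassigned positive is a missed
#' positive (counted in the sensitivity denominator like a false
#' negative), while an unassigned negative is excluded from the
#' specificity calculation entirely (it is not a false positive — the
#' model made no claim).
#'
#' Rates:
#' \itemize{
#'   \item sensitivity = TP / (TP + FN + unassigned positives)
#'   \item specificity = TN / (TN + FP)
#'   \item `ner` (non-error rate) = the class-size-weighted mean of
#'     sensitivity and specificity, i.e. the fraction of non-errors over
#'     all samples the two rates cover; `er` = 1 - `ner`.
#'   \item `ner_macro` = (sensitivity + specificity) / 2, the unweighted
#'     mean over the two classes, also reported.
#' }
#' Values are kept at full precision; [tidy.crp_confusion()] and printing
#' round rates to 2 decimals.
#'
#' @param true_labels Character vector of true classes.
#' @param predicted_labels Character vector of predictions; may contain
#'   `"unassigned"`.
#' @param positive_class The class treated as positive.
#' @return A `crp_confusion` object.
#' @export
confusion_summary <- function(true_labels, predicted_labels,
                              positive_class) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    crp_abort("label vectors must have equal length")
  }
  classes <- sort(unique(true_labels))
  if (!positive_class %in% classes) {
    crp_abort("`positive_class` must be one of the true classes")
  }
  unknown <- setdiff(unique(predicted_labels), c(classes, "unassigned"))
  if (length(unknown)) {
    crp_abort(sprintf(
      "unknown predicted label(s): %s", paste(unknown, collapse = ", ")
    ))
  }
  pos <- true_labels == positive_class
  tp <- sum(pos & predicted_labels == positive_class)
  fn <- sum(pos & !predicted_labels %in% c(positive_class, "unassigned"))
  na_pos <- sum(pos & predicted_labels == "unassigned")
  tn <- sum(!pos & predicted_labels != positive_class &
    predicted_labels != "unassigned")
  fp <- sum(!pos & predicted_labels == positive_class)
  na_neg <- sum(!pos & predicted_labels == "unassigned")
  sens <- tp / (tp + fn + na_pos)
  spec <- tn / (tn + fp)
  # weighted over the samples the two rates cover; reproduces published
  # two-class NER/ER tables exactly, unlike the unweighted macro mean
  n_pos_eff <- tp + fn + na_pos
  n_neg_eff <- tn + fp
  ner <- (tp + tn) / (n_pos_eff + n_neg_eff)
  counts <- tibble::tibble(
    true_class = rep(classes, each = length(classes) + 1),
    predicted = rep(c(classes, "unassigned"), times = length(classes)),
    n = vapply(seq_len(length(classes) * (length(classes) + 1)), function(i) {
      tc <- rep(classes, each = length(classes) + 1)[i]
      pc <- rep(c(classes, "unassigned"), times = length(classes))[i]
      sum(true_labels == tc & predicted_labels == pc)
    }, 1L)
  )
  structure(
    list(
      counts = counts,
      positive_class = positive_class,
      tp = tp, fn = fn, tn = tn, fp = fp,
      unassigned_positive = na_pos, unassigned_negative = na_neg,
      sensitivity = sens, specificity = spec,
      ner = ner, er = 1 - ner,
      ner_macro = (sens + spec) / 2,
      accuracy = (tp + tn) /
        (tp + fn + na_pos + tn + fp + na_neg)
    ),
    class = "crp_confusion"
  )
}

#' @export
print.crp_confusion <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<crp_confusion> positive = %s\n",
      "  sensitivity %.2f  specificity %.2f  NER %.2f  ER %.2f\n"
    ),
    x$positive_class, x$sensitivity, x$specificity, x$ner, x$er
  ))
  if (x$unassigned_positive + x$unassigned_negative > 0) {
    cat(sprintf(
      "  unassigned: %d positive, %d negative\n",
      x$unassigned_positive, x$unassigned_negative
    ))
  }
  invisible(x)
}

#' @rdname confusion_summary
#' @param x A `crp_confusion`.
#' @param ... Unused.
#' @export
tidy.crp_confusion <- function(x, ...) x$counts

#' @rdname confusion_summary
#' @export
glance.crp_confusion <- function(x, ...) {
  tibble::tibble(
    positive_class = x$positive_class,
    sensitivity = round(x$sensitivity, 2),
    specificity = round(x$specificity, 2),
    ner = round(x$ner, 2),
    er = round(x$er, 2),
    ner_macro = round(x$ner_macro, 2),
    accuracy = round(x$accuracy, 2),
    n_unassigned = x$unassigned_positive + x$unassigned_negative
  )
}

#' Linear calibration curve with LOD/LOQ
#'
#' Ordinary least squares of instrument response on standard
#' concentration. The residual standard deviation sigma and the slope
#' give the detection and quantification limits: LOD = 3.3 sigma /
#' slope, LOQ = 10 sigma / slope (the conventional ICH factors).
#'
#' @param concentrations Standard concentrations (>= 3 points, >= 2
#'   distinct values).
#' @param responses Instrument responses (e.g. peak areas).
#' @return A `crp_calibration` object with `slope`, `intercept`, `r2`,
#'   `sigma`, `lod`, `loq`, `range` and the underlying `lm` fit.
#' @export
linear_calibration <- function(concentrations, responses) {
  if (length(concentrations) < 3 ||
    length(concentrations) != length(responses)) {
    crp_abort("need >= 3 paired points")
  }
  if (length(unique(concentrations)) < 2) {
    crp_abort("concentrations must span >= 2 distinct values")
  }
  fit <- stats::lm(responses ~ concentrations)
  slope <- unname(coef(fit)[2])
  if (slope == 0) crp_abort("zero slope: no reportable curve")
  sigma <- sqrt(sum(stats::residuals(fit)^2) / fit$df.residual)
  structure(
    list(
      slope = slope, intercept = unname(coef(fit)[1]),
      r2 = stats::cor(concentrations, responses)^2,
      sigma = sigma,
      lod = 3.3 * sigma / abs(slope),
      loq = 10 * sigma / abs(slope),
      range = range(concentrations),
      fit = fit
    ),
    class = "crp_calibration"
  )
}

#' @export
print.crp_calibration <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<crp_calibration> y = %.6g x + %.6g, r2 = %.4f\n",
      "  sigma %.4g, LOD %.4g, LOQ %.4g, range [%g, %g]\n"
    ),
    x$slope, x$intercept, x$r2, x$sigma, x$lod, x$loq,
    x$range[1], x$range[2]
  ))
  invisible(x)
}

#' @export
tidy.crp_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.crp_calibration <- function(x, ...) {
  tibble::tibble(
    r2 = x$r2, sigma = x$sigma, lod = x$lod, loq = x$loq,
    range_lo = x$range[1], range_hi = x$range[2]
  )
}

#' Precision and accuracy statistics for method validation
#'
#' `rsd_percent()` is the relative standard deviation `100 * sd / mean`
#' (sample sd, n - 1 denominator); from a reported mean and sd use
#' `rsd_from_summary()`. `accuracy_percent()` is the relative error of a
#' spiked recovery, `100 * (observed_mean - spiked) / spiked`.
#'
#' @param values Replicate measurements (>= 2).
#' @return A percentage.
#' @export
rsd_percent <- function(values) {
  if (length(values) < 2) crp_abort("RSD needs >= 2 values")
  m <- mean(values)
  if (m == 0) crp_abort("mean is zero; RSD undefined")
  100 * stats::sd(values) / m
}

#' @rdname rsd_percent
#' @param observed_mean,observed_sd Reported mean and standard deviation.
#' @export
rsd_from_summary <- function(observed_mean, observed_sd) {
  if (any(observed_mean == 0)) crp_abort("mean is zero; RSD undefined")
  100 * observed_sd / observed_mean
}

#' @rdname rsd_percent
#' @param spiked Spiked (nominal) concentration, > 0.
#' @export
accuracy_percent <- function(observed_mean, spiked) {
  if (any(spiked <= 0)) crp_abort("`spiked` must be > 0")
  100 * (observed_mean - spiked) / spiked
}
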