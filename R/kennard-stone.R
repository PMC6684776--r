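#' Kennard-Stone calibration/validation split
#'
#' Deterministic max-min-distance sample selection: within each class the
#' two samples at maximum Euclidean distance seed the calibration set,
#' then the sample with the greatest minimum distance to the already
#' selected set is added until `ceiling(fraction * n)` samples are chosen;
#' the remainder forms the validation set. Applied per class (the
#' default), a 60% split of 38 + 49 samples yields 23 + 30 = 53
#' calibration and 15 + 19 = 34 validation samples. Ties break to the
#' lowest row index.
#'
#' @param m A [crp_matrix()] or numeric matrix.
#' @param fraction Calibration fraction, strictly between 0 and 1.
#' @param per_class Split within each class separately (requires class
#'   labels and >= 2 samples per class).
#' @return A `crp_split` object whose `assignment` field is a tibble with
#'   `row`, `sample_id`, `class_label`, `set` and `pick_order`; `counts`
#'   summarizes per-class sizes. `calibration`/`validation` hold row
#'   indices into `m`.
#' @export
kennard_stone_split <- function(m, fraction = 0.6, per_class = TRUE) {
  X <- if (inherits(m, "crp_matrix")) m$X else as.matrix(m)
  ids <- if (inherits(m, "crp_matrix")) {
    m$sample_ids
  } else {
    rownames(X) %||% sprintf("sample_%d", seq_len(nrow(X)))
  }
  labs <- if (inherits(m, "crp_matrix")) {
    m$class_labels
  } else {
    rep(NA_character_, nrow(X))
  }
  if (fraction <= 0 || fraction >= 1) {
    crp_abort("`fraction` must be strictly between 0 and 1")
  }
  groups <- if (per_class && !all(is.na(labs))) {
    split(seq_len(nrow(X)), labs)
  } else {
    list(all = seq_len(nrow(X)))
  }
  pick <- function(rows) {
    n <- length(rows)
    if (n < 2) {
      crp_abort("each class needs >= 2 samples for Kennard-Stone")
    }
    n_cal <- ceiling(fraction * n)
    D <- as.matrix(stats::dist(X[rows, , drop = FALSE]))
    # seed: the pair at maximum distance, ties to the smallest index pair
    best <- c(1L, 2L)
    bestd <- -Inf
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (D[i, j] > bestd + 1e-12) {
          bestd <- D[i, j]
          best <- c(i, j)
        }
      }
    }
    sel <- best
    while (length(sel) < n_cal) {
      rem <- setdiff(seq_len(n), sel)
      mind <- apply(D[rem, sel, drop = FALSE], 1, min)
      sel <- c(sel, rem[which.max(mind)])
    }
    list(cal = rows[sel[seq_len(n_cal)]], order = sel)
  }
  picks <- lapply(groups, pick)
  cal <- sort(unlist(lapply(picks, `[[`, "cal"), use.names = FALSE))
  val <- setdiff(seq_len(nrow(X)), cal)
  if (length(val) == 0) {
    rlang::warn("validation set is empty: ceiling(fraction * n) == n")
  }
  pick_order <- rep(NA_integer_, nrow(X))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    ord <- picks[[g]]$order
    pick_order[rows[ord]] <- seq_along(ord)
  }
  assignment <- tibble::tibble(
    row = seq_len(nrow(X)),
    sample_id = ids,
    class_label = labs,
    set = ifelse(seq_len(nrow(X)) %in% cal, "calibration", "validation"),
    pick_order = pick_order
  )
  counts <- dplyr::count(assignment, .data$class_label, .data$set)
  structure(
    list(
      assignment = assignment, counts = counts,
      calibration = cal, validation = val, fraction = fraction
    ),
    class = "crp_split"
  )
}

#' @export
print.crp_split <- function(x, ...) {
  cat(sprintf(
    "<crp_split> %d calibration / %d validation (fraction %.2f)\n",
    length(x$calibration), length(x$validation), x$fraction
  ))
  print(x$counts)
  invisible(x)
}

#' @export
tidy.crp_split <- function(x, ...) x$assignment
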