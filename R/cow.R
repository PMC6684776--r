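#' COW parameters
#'
#' Correlation optimized warping is controlled by a segment length and a
#' slack: signals are partitioned into fixed-length segments and each
#' interior segment boundary of the query may move by at most `slack`
#' points, the moved segment being linearly stretched or compressed onto
#' the reference segment. The defaults (segment 150, slack 5) are the
#' values that align study-scale MALDI-TOF fingerprint matrices well.
#'
#' @param segment_length Segment length in points (>= slack + 3).
#' @param slack Maximum boundary shift in points (>= 1).
#' @param reference_index Row of the fingerprint matrix used as warping
#'   reference.
#' @return A `cow_params` object.
#' @export
cow_params <- function(segment_length = 150, slack = 5,
                       reference_index = 1L) {
  segment_length <- as.integer(segment_length)
  slack <- as.integer(slack)
  if (slack < 1) crp_abort("`slack` must be >= 1")
  if (segment_length < slack + 3) {
    crp_abort("`segment_length` must be >= slack + 3")
  }
  structure(
    list(
      segment_length = segment_length, slack = slack,
      reference_index = as.integer(reference_index)
    ),
    class = "cow_params"
  )
}

# fixed reference boundaries, 0-based: 0, L, 2L, ..., (m-1)L, n-1;
# the final segment absorbs the remainder
cow_boundaries <- function(n, segment_length) {
  m <- (n - 1L) %/% segment_length
  if (m < 2L) {
    crp_abort("signal too short: needs at least 2 segments")
  }
  c(seq(0L, by = segment_length, length.out = m), n - 1L)
}

# Pearson correlation between a reference segment and a query stretch
# interpolated to the same length; zero-variance on either side
# contributes 0 (keeps the DP total finite on flat baselines)
cow_seg_corr <- function(ref, query, ra, rb, qa, qb) {
  L <- rb - ra + 1L
  y <- query[qa:qb]
  if (qb - qa + 1L != L) {
    y <- stats::approx(qa:qb, y, xout = seq(qa, qb, length.out = L))$y
  }
  r <- ref[ra:rb]
  if (stats::sd(r) == 0 || stats::sd(y) == 0) {
    return(list(corr = 0, y = y))
  }
  list(corr = stats::cor(r, y), y = y)
}

#' Align one signal to a reference by correlation optimized warping
#'
#' Both signals are partitioned into `floor((n-1)/segment_length)`
#' fixed-length segments (the last absorbs the remainder); a dynamic
#' program over per-boundary shifts in `-slack ... +slack` maximizes the
#' sum over segments of the Pearson correlation between each reference
#' segment and the linearly stretched/compressed query segment. The
#' endpoints never move. Ties prefer the smaller boundary displacement, so
#' a query identical to the reference comes back unchanged.
#'
#' @param query,reference Equal-length numeric vectors
#'   (length >= 2 * segment_length).
#' @param segment_length,slack See [cow_params()].
#' @return A list of class `cow_warp` with elements `warped` (numeric,
#'   same length as input), `boundary_positions` (0-based warped
#'   positions of all segment boundaries, endpoints fixed) and `benefit`
#'   (total correlation achieved, one term per segment).
#' @export
cow_align_pair <- function(query, reference, segment_length = 150,
                           slack = 5) {
  prm <- cow_params(segment_length, slack) # validates
  n <- length(reference)
  if (length(query) != n) {
    crp_abort("query and reference must have equal length")
  }
  if (n < 2L * prm$segment_length) {
    crp_abort("signal too short: length must be >= 2 * segment_length")
  }
  B <- cow_boundaries(n, prm$segment_length) # 0-based
  m <- length(B) - 1L # number of segments
  s <- prm$slack
  offs <- (-s):s
  no <- length(offs)
  # F[j+1, u]: best cumulative benefit with boundary j at offset offs[u]
  FF <- matrix(-Inf, m + 1L, no)
  back <- matrix(NA_integer_, m + 1L, no)
  zero <- match(0L, offs)
  FF[1L, zero] <- 0
  # ties prefer the smaller |offset| predecessor, then the smaller offset
  for (j in seq_len(m)) { # segment j: boundary j-1 -> boundary j
    cur <- if (j == m) zero else seq_len(no)
    prev <- if (j == 1L) zero else seq_len(no)
    for (u in cur) {
      qb <- B[j + 1L] + if (j == m) 0L else offs[u]
      best <- -Inf
      barg <- NA_integer_
      for (up in prev[order(abs(offs[prev]), offs[prev])]) {
        if (!is.finite(FF[j, up])) next
        qa <- B[j] + if (j == 1L) 0L else offs[up]
        if (qb - qa < 1L) next
        cc <- cow_seg_corr(
          reference, query,
          B[j] + 1L, B[j + 1L] + 1L, qa + 1L, qb + 1L
        )$corr
        val <- FF[j, up] + cc
        if (val > best + 1e-12) {
          best <- val
          barg <- up
        }
      }
      FF[j + 1L, u] <- best
      back[j + 1L, u] <- barg
    }
  }
  # traceback from the fixed final boundary
  u <- zero
  upath <- integer(m + 1L)
  upath[m + 1L] <- 0L
  for (j in rev(seq_len(m))) {
    u <- back[j + 1L, u]
    upath[j] <- offs[u]
  }
  upath[1L] <- 0L
  qB <- B + upath
  # rebuild the warped query segment by segment
  warped <- numeric(n)
  for (j in seq_len(m)) {
    piece <- cow_seg_corr(
      reference, query,
      B[j] + 1L, B[j + 1L] + 1L, qB[j] + 1L, qB[j + 1L] + 1L
    )$y
    idx <- (B[j] + 1L):(B[j + 1L] + 1L)
    warped[idx] <- piece
  }
  structure(
    list(
      warped = warped, boundary_positions = qB,
      benefit = FF[m + 1L, zero]
    ),
    class = "cow_warp"
  )
}

#' Choose the COW reference row of a fingerprint matrix
#'
#' Returns the index of the row with the greatest total Pearson
#' correlation to all other rows — the most "central" fingerprint.
#' Constant (zero-variance) rows are excluded from candidacy; ties go to
#' the lowest index.
#'
#' @param m A [crp_matrix()] or numeric matrix with >= 2 rows.
#' @return Integer row index.
#' @export
choose_reference <- function(m) {
  X <- if (inherits(m, "crp_matrix")) m$X else as.matrix(m)
  if (nrow(X) < 2) crp_abort("need >= 2 rows to choose a reference")
  sds <- apply(X, 1, stats::sd)
  ok <- sds > 0
  if (!any(ok)) crp_abort("all rows are constant; no reference exists")
  C <- suppressWarnings(stats::cor(t(X)))
  C[is.na(C)] <- 0
  tot <- rowSums(C) - 1 # drop self-correlation
  tot[!ok] <- -Inf
  unname(which.max(tot))
}

#' Align every row of a fingerprint matrix by COW
#'
#' @param m A [crp_matrix()].
#' @param params A [cow_params()]; `reference_index` selects the row all
#'   others are warped onto (use [choose_reference()] to pick it
#'   automatically).
#' @return A [crp_matrix()] of warped rows (the reference row unchanged).
#' @export
cow_align <- function(m, params = cow_params()) {
  stopifnot(inherits(m, "crp_matrix"), inherits(params, "cow_params"))
  ref <- m$X[params$reference_index, ]
  X <- m$X
  for (i in seq_len(nrow(X))) {
    if (i == params$reference_index) next
    X[i, ] <- cow_align_pair(
      m$X[i, ], ref,
      params$segment_length, params$slack
    )$warped
  }
  crp_matrix(X, m$axis, m$sample_ids, m$class_labels)
}

#' Pick segment length and slack for COW by grid search
#'
#' Every (segment, slack) combination aligns the whole matrix to the
#' chosen reference and is scored by `simplicity + peak factor`:
#' simplicity is `sum(sv^4) / sum(sv^2)^2` over the singular values of the
#' aligned, row-normalized matrix (higher when alignment concentrates
#' variance in few components), and the peak factor penalizes area
#' distortion, `1 - mean(min(1, |area_warped - area_raw| / area_raw))`
#' with row areas as sums of absolute intensities. Ties prefer the
#' smaller segment, then the smaller slack.
#'
#' @param m A [crp_matrix()].
#' @param segment_grid,slack_grid Integer vectors of candidate values.
#' @param reference_index Reference row; `NULL` selects it with
#'   [choose_reference()].
#' @return A [cow_params()] carrying the winning combination, with the
#'   score table in attribute `"scores"`.
#' @export
optimize_cow <- function(m, segment_grid, slack_grid,
                         reference_index = NULL) {
  stopifnot(inherits(m, "crp_matrix"))
  if (length(segment_grid) == 0 || length(slack_grid) == 0) {
    crp_abort("candidate grids must be non-empty")
  }
  if (is.null(reference_index)) reference_index <- choose_reference(m)
  area <- function(X) rowSums(abs(X))
  a_raw <- area(m$X)
  grid <- expand.grid(
    segment = sort(as.integer(segment_grid)),
    slack = sort(as.integer(slack_grid))
  )
  grid <- grid[order(grid$segment, grid$slack), ]
  scores <- purrr::pmap_dfr(grid, function(segment, slack) {
    aligned <- cow_align(
      m, cow_params(segment, slack, reference_index)
    )
    Xn <- aligned$X / sqrt(rowSums(aligned$X^2))
    sv <- svd(Xn, nu = 0, nv = 0)$d
    simplicity <- sum(sv^4) / sum(sv^2)^2
    a_w <- area(aligned$X)
    peak <- 1 - mean(pmin(1, abs(a_w - a_raw) / a_raw))
    tibble::tibble(
      segment = segment, slack = slack,
      simplicity = simplicity, peak_factor = peak,
      score = simplicity + peak
    )
  })
  best <- scores[order(-scores$score, scores$segment, scores$slack), ][1, ]
  out <- cow_params(best$segment, best$slack, reference_index)
  attr(out, "scores") <- scores
  out
}
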