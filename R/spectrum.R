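#' Construct a single-sample spectrum or chromatogram
#'
#' A `crp_spectrum` is a tibble with an `axis` column (m/z in Da for
#' MALDI-TOF spectra, retention time in minutes for chromatograms) and an
#' `intensity` column, carrying `sample_id`, `replicate_id` and
#' `class_label` as attributes. The axis must be strictly increasing and
#' intensities are kept verbatim (negative values from instrument baseline
#' export are allowed; baseline handling belongs to preprocessing).
#'
#' @param axis Numeric vector of x-values, strictly increasing, length >= 2.
#' @param intensity Numeric vector, same length as `axis`.
#' @param sample_id Sample identifier (scalar character).
#' @param replicate_id Optional small integer replicate number.
#' @param class_label Optional class label (e.g. `"RH"` or `"RA"`).
#' @return A `crp_spectrum` tibble with columns `axis` and `intensity`.
#' @examples
#' s <- crp_spectrum(c(100, 101, 102), c(5, 7, 6), sample_id = "s1")
#' s
#' @export
crp_spectrum <- function(axis, intensity, sample_id = "sample",
                         replicate_id = NA_integer_,
                         class_label = NA_character_) {
  axis <- as.double(axis)
  intensity <- as.double(intensity)
  if (length(axis) < 2) {
    crp_abort("a spectrum needs at least 2 points")
  }
  if (length(axis) != length(intensity)) {
    crp_abort("`axis` and `intensity` must have the same length")
  }
  if (anyNA(axis) || anyNA(intensity)) {
    crp_abort("`axis` and `intensity` must not contain NA")
  }
  if (any(diff(axis) <= 0)) {
    if (anyDuplicated(axis)) {
      crp_abort("duplicate axis values", class = "crpfp_duplicate_axis")
    }
    crp_abort("`axis` must be strictly increasing")
  }
  out <- tibble::new_tibble(
    list(axis = axis, intensity = intensity),
    nrow = length(axis),
    class = "crp_spectrum",
    sample_id = as.character(sample_id),
    replicate_id = as.integer(replicate_id),
    class_label = as.character(class_label)
  )
  out
}

#' @export
print.crp_spectrum <- function(x, ...) {
  cat(sprintf(
    "<crp_spectrum> sample %s%s%s, %d points, axis [%g, %g]\n",
    sample_id(x),
    if (!is.na(replicate_id(x))) paste0(" rep ", replicate_id(x)) else "",
    if (!is.na(class_label(x))) paste0(" (", class_label(x), ")") else "",
    nrow(x), min(x$axis), max(x$axis)
  ))
  NextMethod()
}

#' Spectrum label accessors
#'
#' @param x A `crp_spectrum`.
#' @return `sample_id()` and `class_label()` return a character scalar,
#'   `replicate_id()` an integer scalar.
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' @rdname sample_id
#' @export
replicate_id <- function(x) attr(x, "replicate_id")

#' @rdname sample_id
#' @export
class_label <- function(x) attr(x, "class_label")

#' Read a two-column ASCII spectrum
#'
#' Parses the plain-text export format used by MALDI-TOF workstation
#' software (e.g. Data Explorer): two whitespace- or comma-delimited
#' numeric columns, x-axis value then intensity, with `#` comment lines.
#' If the axis arrives unsorted it is sorted ascending; duplicate axis
#' values are an error.
#'
#' @param path Path to the ASCII file.
#' @param sample_id,replicate_id,class_label Labels attached to the
#'   returned spectrum; `sample_id` defaults to the file name without
#'   extension.
#' @return A [crp_spectrum()].
#' @export
read_spectrum_ascii <- function(path, sample_id = NULL,
                                replicate_id = NA_integer_,
                                class_label = NA_character_) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) crp_abort(sprintf("no data lines in '%s'", path))
  fields <- strsplit(trimws(lines), "[,[:space:]]+")
  bad_n <- vapply(fields, length, 1L) != 2L
  if (any(bad_n)) {
    crp_abort(sprintf(
      "malformed line %d in '%s': expected 2 numeric columns",
      line_no[which(bad_n)[1]], path
    ), class = "crpfp_parse_error")
  }
  vals <- suppressWarnings(vapply(fields, function(f) as.double(f), double(2)))
  bad <- colSums(is.na(vals)) > 0
  if (any(bad)) {
    crp_abort(sprintf(
      "malformed numeric value on line %d in '%s'",
      line_no[which(bad)[1]], path
    ), class = "crpfp_parse_error")
  }
  axis <- vals[1, ]
  intensity <- vals[2, ]
  if (is.unsorted(axis, strictly = TRUE)) {
    o <- order(axis)
    axis <- axis[o]
    intensity <- intensity[o]
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  crp_spectrum(axis, intensity,
    sample_id = sample_id,
    replicate_id = replicate_id, class_label = class_label
  )
}

#' Write a spectrum as two-column ASCII
#'
#' @param s A [crp_spectrum()].
#' @param path Output path.
#' @param digits Significant digits to print (default 15, so that a
#'   write/read round-trip preserves values to better than 12 significant
#'   digits).
#' @return `path`, invisibly.
#' @export
write_spectrum_ascii <- function(s, path, digits = 15) {
  stopifnot(inherits(s, "crp_spectrum"))
  lines <- sprintf(
    paste0("%.", digits, "g %.", digits, "g"),
    s$axis, s$intensity
  )
  writeLines(c(sprintf("# sample %s", sample_id(s)), lines), path)
  invisible(path)
}

#' Resample a spectrum onto a target axis by linear interpolation
#'
#' Intensity is linearly interpolated onto `grid`; grid points falling
#' outside the spectrum's axis range are filled with 0. Labels are
#' preserved. This is the step that puts all samples on one shared axis
#' before matrix assembly.
#'
#' @param s A [crp_spectrum()].
#' @param grid Strictly increasing numeric vector of target x-values.
#' @return A [crp_spectrum()] on `grid`.
#' @export
resample_to_grid <- function(s, grid) {
  stopifnot(inherits(s, "crp_spectrum"))
  if (length(grid) == 0) crp_abort("`grid` must be non-empty")
  if (length(grid) > 1 && any(diff(grid) <= 0)) {
    crp_abort("`grid` must be strictly increasing")
  }
  y <- stats::approx(s$axis, s$intensity, xout = grid, rule = 1)$y
  y[is.na(y)] <- 0
  if (length(grid) == 1) {
    # crp_spectrum requires length >= 2; single-point queries come back
    # as a plain tibble
    return(tibble::tibble(axis = as.double(grid), intensity = y))
  }
  crp_spectrum(grid, y,
    sample_id = sample_id(s),
    replicate_id = replicate_id(s), class_label = class_label(s)
  )
}

#' Average technical replicates of one sample
#'
#' Point-wise arithmetic mean of replicate spectra sharing an axis and a
#' sample id. MALDI-TOF acquisitions are commonly run in triplicate and
#' the mean spectrum used as the sample's final fingerprint.
#'
#' @param replicates List of [crp_spectrum()] objects with identical axes
#'   and identical `sample_id`.
#' @return A single [crp_spectrum()] with `replicate_id` cleared.
#' @export
average_replicates <- function(replicates) {
  if (inherits(replicates, "crp_spectrum")) replicates <- list(replicates)
  if (length(replicates) < 1) crp_abort("need at least one replicate")
  ax <- replicates[[1]]$axis
  ids <- vapply(replicates, sample_id, "")
  if (length(unique(ids)) != 1) {
    crp_abort("replicates carry different sample_ids")
  }
  for (r in replicates[-1]) {
    if (!isTRUE(all.equal(r$axis, ax, tolerance = 0))) {
      crp_abort("replicates must share an identical axis")
    }
  }
  y <- rowMeans(vapply(replicates, function(r) r$intensity,
    double(length(ax))))
  crp_spectrum(ax, y,
    sample_id = ids[1], replicate_id = NA_integer_,
    class_label = class_label(replicates[[1]])
  )
}
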