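#' Class template for synthetic CRP fingerprints
#'
#' Describes the noiseless fingerprint of one botanical class as a set of
#' Gaussian marker peaks on a shared m/z axis. Plant cysteine-rich
#' peptides cluster between 2 and 6 kDa, so the default axis spans that
#' range; the default grid width of 30935 points mirrors the
#' study-scale matrix.
#'
#' @param class_label Class name, e.g. `"RA"`.
#' @param markers Tibble or data frame with columns `center` (Da),
#'   `amplitude` and `width` (Gaussian sd, Da).
#' @param axis_lo,axis_hi Axis range in Da.
#' @param n_points Number of grid points.
#' @return A `class_template` object.
#' @export
class_template <- function(class_label, markers,
                           axis_lo = 2000, axis_hi = 6000,
                           n_points = 30935) {
  markers <- tibble::as_tibble(markers)
  stopifnot(all(c("center", "amplitude", "width") %in% names(markers)))
  if (any(markers$amplitude <= 0) || any(markers$width <= 0)) {
    crp_abort("marker amplitudes and widths must be > 0")
  }
  if (any(markers$center < axis_lo | markers$center > axis_hi)) {
    crp_abort("marker centers must lie within the axis range")
  }
  structure(
    list(
      class_label = as.character(class_label), markers = markers,
      axis_lo = axis_lo, axis_hi = axis_hi, n_points = as.integer(n_points)
    ),
    class = "class_template"
  )
}

#' Default two-class templates: RA and RH marker peptides
#'
#' The default templates place Gaussian peaks at the four marker masses of
#' the astratide and hedytide peptides that distinguish Radix Astragali
#' (RA: aM1 at 3811.8 Da, bM1 at 4724.4 Da) from Radix Hedysarum
#' (RH: hP1 at 3944.3 Da, hP2 at 4780.1 Da), plus a small shared
#' background peak so the two classes are not trivially orthogonal.
#'
#' @param n_points Grid width shared by both templates.
#' @param axis_lo,axis_hi Axis range in Da.
#' @return A list with elements `RA` and `RH`, each a [class_template()].
#' @export
default_templates <- function(n_points = 30935, axis_lo = 2000,
                              axis_hi = 6000) {
  shared <- tibble::tibble(center = 2500, amplitude = 30, width = 8)
  ra <- dplyr::bind_rows(
    tibble::tibble(
      center = c(3811.8, 4724.4),
      amplitude = c(100, 80), width = c(6, 6)
    ),
    shared
  )
  rh <- dplyr::bind_rows(
    tibble::tibble(
      center = c(3944.3, 4780.1),
      amplitude = c(100, 80), width = c(6, 6)
    ),
    shared
  )
  list(
    RA = class_template("RA", ra, axis_lo, axis_hi, n_points),
    RH = class_template("RH", rh, axis_lo, axis_hi, n_points)
  )
}

#' Simulation parameters for synthetic fingerprints
#'
#' @param intensity_noise_cv Multiplicative amplitude noise, coefficient of
#'   variation (fraction).
#' @param additive_noise_sd Additive white-noise standard deviation
#'   (intensity units).
#' @param baseline_level Constant baseline offset.
#' @param global_shift_sd Standard deviation of the per-replicate global
#'   m/z shift (Da).
#' @param local_warp_sd Standard deviation of the smooth local axis warp
#'   (Da).
#' @param n_replicates Technical replicates per sample (triplicate
#'   acquisition is the norm).
#' @param seed Integer master seed; all randomness derives from it.
#' @return A `sim_params` object.
#' @export
sim_params <- function(intensity_noise_cv = 0.05, additive_noise_sd = 0.5,
                       baseline_level = 1, global_shift_sd = 2,
                       local_warp_sd = 1, n_replicates = 3, seed = 1L) {
  vals <- c(
    intensity_noise_cv, additive_noise_sd, baseline_level,
    global_shift_sd, local_warp_sd
  )
  if (any(vals < 0)) crp_abort("simulation parameters must be nonnegative")
  if (n_replicates < 1) crp_abort("n_replicates must be >= 1")
  structure(
    list(
      intensity_noise_cv = intensity_noise_cv,
      additive_noise_sd = additive_noise_sd,
      baseline_level = baseline_level,
      global_shift_sd = global_shift_sd,
      local_warp_sd = local_warp_sd,
      n_replicates = as.integer(n_replicates),
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

template_axis <- function(t) {
  seq(t$axis_lo, t$axis_hi, length.out = t$n_points)
}

# noiseless sum of Gaussian markers, with optional per-marker amplitude
# factors, global shift and smooth local warp of the peak centers
template_signal <- function(t, axis, amp_factor = 1, shift = 0,
                            warp_at_center = 0) {
  y <- numeric(length(axis))
  centers <- t$markers$center + shift + warp_at_center
  amps <- t$markers$amplitude * amp_factor
  for (j in seq_len(nrow(t$markers))) {
    w <- t$markers$width[j]
    y <- y + amps[j] * exp(-0.5 * ((axis - centers[j]) / w)^2)
  }
  y
}

#' Simulate replicate spectra for one sample
#'
#' Each replicate is `baseline + sum of Gaussians(center + shift + local
#' warp, width, amplitude * (1 + noise)) + additive white noise`, sampled
#' on the template grid. The global shift is one draw per replicate; the
#' local warp perturbs each marker's center independently but smoothly
#' (one draw per marker). Output is deterministic given `p$seed` and
#' `sample_index`, whatever order samples are generated in.
#'
#' @param t A [class_template()].
#' @param p A [sim_params()].
#' @param sample_id Sample identifier.
#' @param sample_index Integer counter used to derive this sample's
#'   random substream from the master seed.
#' @return A list of [crp_spectrum()] replicates.
#' @export
simulate_spectrum <- function(t, p, sample_id, sample_index = 1L) {
  stopifnot(inherits(t, "class_template"), inherits(p, "sim_params"))
  axis <- template_axis(t)
  nm <- nrow(t$markers)
  lapply(seq_len(p$n_replicates), function(r) {
    y <- with_seed(derive_seed(p$seed, sample_index * 1000L + r), {
      shift <- if (p$global_shift_sd > 0) {
        stats::rnorm(1, 0, p$global_shift_sd)
      } else {
        0
      }
      warp <- if (p$local_warp_sd > 0) {
        stats::rnorm(nm, 0, p$local_warp_sd)
      } else {
        rep(0, nm)
      }
      amp <- if (p$intensity_noise_cv > 0) {
        1 + stats::rnorm(nm, 0, p$intensity_noise_cv)
      } else {
        rep(1, nm)
      }
      sig <- template_signal(t, axis,
        amp_factor = amp, shift = shift,
        warp_at_center = warp
      )
      noise <- if (p$additive_noise_sd > 0) {
        stats::rnorm(length(axis), 0, p$additive_noise_sd)
      } else {
        0
      }
      p$baseline_level + sig + noise
    })
    crp_spectrum(axis, y,
      sample_id = sample_id, replicate_id = r,
      class_label = t$class_label
    )
  })
}

#' Simulate a two-class fingerprint dataset
#'
#' Generates `n_per_class` samples for each template (replicates drawn and
#' averaged per sample, as in triplicate MALDI acquisition) and assembles
#' the labeled fingerprint matrix, class A rows first. The default sample
#' sizes 38 + 49 reproduce the study-scale post-outlier-removal design
#' (38 RH vs 49 RA).
#'
#' @param tA,tB [class_template()] objects sharing axis settings.
#' @param n_per_class Length-2 integer vector: samples for `tA`, `tB`.
#' @param p A [sim_params()].
#' @return A [crp_matrix()].
#' @export
simulate_dataset <- function(tA, tB, n_per_class = c(38, 49),
                             p = sim_params()) {
  if (length(n_per_class) == 1) n_per_class <- rep(n_per_class, 2)
  if (any(n_per_class < 1)) crp_abort("n_per_class must be >= 1")
  if (tA$axis_lo != tB$axis_lo || tA$axis_hi != tB$axis_hi ||
    tA$n_points != tB$n_points) {
    crp_abort("templates must share axis range and n_points")
  }
  counter <- 0L
  one <- function(t, i) {
    counter <<- counter + 1L
    id <- sprintf("%s_%02d", t$class_label, counter)
    average_replicates(simulate_spectrum(t, p, id, sample_index = counter))
  }
  spectra <- c(
    lapply(seq_len(n_per_class[1]), function(i) one(tA, i)),
    lapply(seq_len(n_per_class[2]), function(i) one(tB, i))
  )
  assemble_matrix(spectra)
}

#' The package's reference synthetic two-class benchmark
#'
#' A fixed-condition dataset used throughout the test-suite and examples:
#' 38 RH and 49 RA samples, triplicate replicates averaged, marker masses
#' at the four astratide/hedytide peaks, moderate noise, and m/z
#' shift/warp distortion. The grid is 4001 points over 2-6 kDa (1 Da
#' spacing), wide enough to resolve 6 Da-wide peaks while keeping the
#' full pipeline fast.
#'
#' @param seed Master seed.
#' @param n_points Grid width.
#' @param n_rh,n_ra Samples per class.
#' @param p Optional [sim_params()] overriding the defaults.
#' @return A [crp_matrix()] with classes `RH` then `RA`.
#' @export
simulate_benchmark <- function(seed = 7L, n_points = 4001,
                               n_rh = 38, n_ra = 49, p = NULL) {
  tpl <- default_templates(n_points = n_points)
  if (is.null(p)) p <- sim_params(seed = seed) else p$seed <- as.integer(seed)
  simulate_dataset(tpl$RH, tpl$RA, c(n_rh, n_ra), p)
}
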