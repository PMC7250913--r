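#' Describe the layout of a longitudinal survival experiment
#'
#' An experiment is organised as plates > wells > imaging fields > neurons.
#' Each well carries exactly one experimental group label (the transfected
#' construct); each plate is a stratum with its own baseline toxicity; neurons
#' within a well share transfection conditions and therefore form a cluster
#' for variance estimation. Fields are imaged at a fixed cadence (typically
#' every 24 h) from time 0 (first image) up to the end of follow-up.
#'
#' @param plates Number of plates (strata).
#' @param wells_per_plate Number of wells on each plate.
#' @param fields_per_well Number of non-overlapping imaging positions per well.
#' @param neurons_per_field Number of neurons placed in each field.
#' @param group_of_well Character vector of group labels, either one per well
#'   within a plate (length `wells_per_plate`, repeated on every plate) or one
#'   per well overall (length `plates * wells_per_plate`, plate-major order).
#' @param frame_interval Hours between consecutive frames.
#' @param end_of_followup Total follow-up in hours; the last frame is the
#'   largest multiple of `frame_interval` not exceeding it.
#' @param image_shape Integer vector `c(height, width)` of each frame, pixels.
#'
#' @return An object of class `experiment_design`.
#' @examples
#' experiment_design(plates = 2, wells_per_plate = 4, fields_per_well = 15,
#'                   neurons_per_field = 10,
#'                   group_of_well = c("Ch", "Ch", "G93A", "G93A"))
#' @export
experiment_design <- function(plates = 1, wells_per_plate = 4,
                              fields_per_well = 15, neurons_per_field = 10,
                              group_of_well = "control",
                              frame_interval = 24, end_of_followup = 120,
                              image_shape = c(200L, 200L)) {
  counts <- c(plates = plates, wells_per_plate = wells_per_plate,
              fields_per_well = fields_per_well,
              neurons_per_field = neurons_per_field)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts (plates, wells, fields, neurons) must be integers >= 1")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (end_of_followup < frame_interval)
    stop("end_of_followup must be at least one frame_interval")
  if (length(image_shape) != 2 || any(image_shape < 8))
    stop("image_shape must be c(height, width) with both >= 8")

  n_wells <- plates * wells_per_plate
  group_of_well <- as.character(group_of_well)
  if (length(group_of_well) == 1)
    group_of_well <- rep(group_of_well, wells_per_plate)
  if (length(group_of_well) == wells_per_plate)
    group_of_well <- rep(group_of_well, plates)
  if (length(group_of_well) != n_wells)
    stop("group_of_well must have length wells_per_plate or plates * wells_per_plate")

  n_frames <- floor(end_of_followup / frame_interval) + 1L
  design <- list(
    plates = as.integer(plates),
    wells_per_plate = as.integer(wells_per_plate),
    fields_per_well = as.integer(fields_per_well),
    neurons_per_field = as.integer(neurons_per_field),
    group_of_well = group_of_well,
    frame_interval = frame_interval,
    end_of_followup = end_of_followup,
    image_shape = as.integer(image_shape),
    n_frames = as.integer(n_frames),
    frame_times = frame_interval * (seq_len(n_frames) - 1)
  )
  class(design) <- "experiment_design"
  design
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Experiment design:", x$plates, "plate(s) x", x$wells_per_plate,
      "wells x", x$fields_per_well, "fields x", x$neurons_per_field,
      "neurons/field\n")
  cat("  groups:", paste(unique(x$group_of_well), collapse = ", "), "\n")
  cat("  frames every", x$frame_interval, "h up to", x$end_of_followup,
      "h (", x$n_frames, "frames )\n")
  invisible(x)
}

#' Layout table of an experiment design
#'
#' Expands the design into one row per well with its plate, globally unique
#' well id (`p<plate>w<well>`) and group label. This is the clustering /
#' stratification map consumed by the survival stage.
#'
#' @param design An [experiment_design()].
#' @return A data.frame with columns `plate`, `well`, `group`.
#' @export
design_layout <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  plate <- rep(seq_len(design$plates), each = design$wells_per_plate)
  well_in_plate <- rep(seq_len(design$wells_per_plate), design$plates)
  data.frame(
    plate = plate,
    well = sprintf("p%dw%d", plate, well_in_plate),
    group = design$group_of_well,
    stringsAsFactors = FALSE
  )
}

#' Programmable proportional-hazards model for neuron death
#'
#' Death times follow `h(t | neuron) = h0(t) * exp(beta_group + gamma * z(t))`
#' where `h0` is a constant-rate or Weibull baseline, `beta_group` is the
#' log hazard ratio of the neuron's group relative to the reference, and
#' `z(t)` is the neuron's standardized log reporter level, held
#' piecewise-constant between frames. Reporter trajectories have a lognormal
#' cell-to-cell basal level, an optional group-dependent linear rise, and an
#' optional surge in the observed green signal during the last hours before
#' death (present in a configurable fraction of dying neurons); the surge is
#' a correlate of impending death and does not feed back into the hazard.
#'
#' An optional sign change of the group effect at `crossing_time_h`
#' (`group_log_hr_late`) generates non-proportional hazards for diagnostics
#' testing.
#'
#' @param baseline `"weibull"` (default) or `"constant"`.
#' @param rate Constant baseline rate per hour (used when `baseline = "constant"`).
#' @param shape,scale Weibull shape and scale (hours); cumulative baseline
#'   hazard `(t / scale)^shape`. The default shape 1.3 gives a mildly
#'   increasing hazard (convex cumulative hazard); scale 200 h puts control
#'   mortality near 40% by 120 h.
#' @param group_log_hr Named numeric: log hazard ratio per group. Reference
#'   groups carry 0. Every group in the design must be named here.
#' @param reporter_log_hr Gamma, log hazard ratio per standard deviation of
#'   log reporter level.
#' @param basal_red,basal_green Median integrated intensity (counts) of the
#'   red (construct) and green (reporter) channel of a neuron at time 0.
#' @param sdlog_red,sdlog_green Lognormal cell-to-cell dispersion of basal
#'   levels.
#' @param rise_per_24h Named numeric (per group) or scalar: fractional linear
#'   rise of the green reporter per 24 h (0.5 means +50% per day).
#' @param surge_amplitude Fold-increase of the observed green signal reached
#'   at the moment of death in responder neurons.
#' @param surge_lead_h Hours before death over which the surge ramps up.
#' @param responder_fraction Fraction of dying neurons showing the surge.
#' @param group_log_hr_late,crossing_time_h Optional non-proportional hazard:
#'   after `crossing_time_h` the group log-HRs switch to `group_log_hr_late`.
#'
#' @return An object of class `hazard_model`.
#' @export
hazard_model <- function(baseline = c("weibull", "constant"),
                         rate = 0.005, shape = 1.3, scale = 200,
                         group_log_hr = c(control = 0),
                         reporter_log_hr = 0,
                         basal_red = 5000, basal_green = 2000,
                         sdlog_red = 0.3, sdlog_green = 0.4,
                         rise_per_24h = 0,
                         surge_amplitude = 2, surge_lead_h = 48,
                         responder_fraction = 0.7,
                         group_log_hr_late = NULL, crossing_time_h = NULL) {
  baseline <- match.arg(baseline)
  if (baseline == "constant" && rate < 0)
    stop("baseline rate must be >= 0")
  if (baseline == "weibull" && (shape <= 0 || scale <= 0))
    stop("Weibull shape and scale must be > 0")
  if (is.null(names(group_log_hr)) || any(!nzchar(names(group_log_hr))))
    stop("group_log_hr must be a fully named numeric vector")
  if (basal_red <= 0 || basal_green <= 0)
    stop("basal intensities must be > 0 (reporter levels are strictly positive)")
  if (surge_amplitude < 1 || surge_lead_h < 0)
    stop("surge_amplitude must be >= 1 and surge_lead_h >= 0")
  if (responder_fraction < 0 || responder_fraction > 1)
    stop("responder_fraction must be in [0, 1]")
  if (!is.null(group_log_hr_late) != !is.null(crossing_time_h))
    stop("group_log_hr_late and crossing_time_h must be given together")

  model <- list(
    baseline = baseline, rate = rate, shape = shape, scale = scale,
    group_log_hr = group_log_hr, reporter_log_hr = reporter_log_hr,
    basal_red = basal_red, basal_green = basal_green,
    sdlog_red = sdlog_red, sdlog_green = sdlog_green,
    rise_per_24h = rise_per_24h,
    surge_amplitude = surge_amplitude, surge_lead_h = surge_lead_h,
    responder_fraction = responder_fraction,
    group_log_hr_late = group_log_hr_late, crossing_time_h = crossing_time_h
  )
  class(model) <- "hazard_model"
  model
}

#' Camera and optics model for rendering synthetic movies
#'
#' Living neurons are rendered as isotropic 2-D Gaussian blobs whose
#' integrated intensity equals their true trajectory value attenuated by
#' photobleaching; noise is Poisson on (signal + background) plus Gaussian
#' read noise, applied last.
#'
#' @param psf_sigma Gaussian blob sigma in pixels.
#' @param background_level Constant background in counts.
#' @param photobleach_rate Fractional signal loss per frame (multiplicative,
#'   `(1 - rate)^frame`).
#' @param poisson_noise Apply Poisson shot noise?
#' @param read_noise_sd Gaussian read noise standard deviation in counts
#'   (0 disables).
#' @param min_separation Minimum distance in pixels between neuron centres;
#'   must be at least `4 * psf_sigma` so blobs do not overlap appreciably.
#' @param motion_sd Per-frame isotropic jitter of rendered centres, pixels
#'   (0 = perfectly stationary neurons).
#'
#' @return An object of class `imaging_model`.
#' @export
imaging_model <- function(psf_sigma = 2, background_level = 100,
                          photobleach_rate = 0.02,
                          poisson_noise = TRUE, read_noise_sd = 2,
                          min_separation = 12, motion_sd = 0) {
  if (psf_sigma <= 0) stop("psf_sigma must be > 0")
  if (background_level < 0) stop("background_level must be >= 0")
  if (photobleach_rate < 0 || photobleach_rate >= 1)
    stop("photobleach_rate must be in [0, 1)")
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  if (min_separation < 4 * psf_sigma)
    stop("min_separation must be >= 4 * psf_sigma")
  if (motion_sd < 0) stop("motion_sd must be >= 0")
  model <- list(psf_sigma = psf_sigma, background_level = background_level,
                photobleach_rate = photobleach_rate,
                poisson_noise = poisson_noise, read_noise_sd = read_noise_sd,
                min_separation = min_separation, motion_sd = motion_sd)
  class(model) <- "imaging_model"
  model
}

#' Peak signal-to-noise ratio of a rendered blob
#'
#' SNR is defined as peak blob amplitude over the noise standard deviation at
#' the peak (Poisson shot noise on amplitude + background, plus read noise).
#' Useful for choosing basal intensities that hit a target SNR.
#'
#' @param intensity Integrated blob intensity in counts.
#' @param imaging An [imaging_model()].
#' @return The peak SNR (0 when the model is noise-free).
#' @export
blob_peak_snr <- function(intensity, imaging) {
  amp <- intensity / (2 * pi * imaging$psf_sigma^2)
  v <- imaging$read_noise_sd^2 +
    if (imaging$poisson_noise) amp + imaging$background_level else 0
  if (v == 0) return(Inf)
  amp / sqrt(v)
}

#' Integrated intensity needed for a target peak SNR
#'
#' Inverts [blob_peak_snr()] for a Poisson + read-noise camera.
#'
#' @param snr Target peak SNR.
#' @param imaging An [imaging_model()].
#' @return Integrated intensity in counts.
#' @export
intensity_for_snr <- function(snr, imaging) {
  b <- imaging$background_level + imaging$read_noise_sd^2
  if (!imaging$poisson_noise) {
    if (imaging$read_noise_sd == 0) stop("model is noise-free; SNR undefined")
    return(snr * imaging$read_noise_sd * 2 * pi * imaging$psf_sigma^2)
  }
  # solve A^2 = snr^2 (A + b) for the amplitude A
  amp <- (snr^2 + sqrt(snr^4 + 4 * snr^2 * b)) / 2
  amp * 2 * pi * imaging$psf_sigma^2
}
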