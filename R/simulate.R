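# Fate simulation: death times from h(t) = h0(t) exp(beta_group + gamma z(t))
# with z(t) the standardized log reporter level, piecewise-constant between
# frames. Inversion sampling: draw E ~ Exp(1) and walk the cumulative hazard
# across breakpoints (frame times, plus the optional group-effect crossing
# time), inverting the baseline within the interval where E is exhausted.

h0_cum <- function(t, model) {
  if (model$baseline == "constant") model$rate * t
  else (t / model$scale)^model$shape
}

h0_inv <- function(h, model) {
  if (model$baseline == "constant") {
    if (model$rate == 0) rep(Inf, length(h)) else h / model$rate
  } else {
    model$scale * h^(1 / model$shape)
  }
}

group_rise <- function(model, groups) {
  r <- model$rise_per_24h
  if (is.null(names(r))) rep(r[1], length(groups))
  else {
    if (!all(groups %in% names(r)))
      stop("rise_per_24h is named but missing groups: ",
           paste(setdiff(unique(groups), names(r)), collapse = ", "))
    unname(r[groups])
  }
}

# Standardized log reporter level at time t for lognormal deviates `dev`
# (log-scale) and per-neuron daily rise. The divisor is the population
# lognormal sd; when that is 0 the scale 1 keeps z well-defined.
reporter_z <- function(dev, rise, t, sdlog) {
  s <- if (sdlog > 0) sdlog else 1
  (dev + log1p(pmax(rise, -0.99) * t / 24)) / s
}

place_centers <- function(n, image_shape, min_separation, rng_ok = 2000) {
  h <- image_shape[1]; w <- image_shape[2]
  margin <- max(min_separation / 2, 4)
  if (w - 2 * margin < 1 || h - 2 * margin < 1)
    stop("image too small to place neurons at the requested separation")
  if (min_separation <= 0)   # statistics-only simulations skip the geometry
    return(data.frame(x = stats::runif(n, margin, w - margin),
                      y = stats::runif(n, margin, h - margin)))
  if (n * pi * min_separation^2 / 4 > 0.5 * (w - 2 * margin) * (h - 2 * margin))
    stop("image too small to place ", n, " neurons at min_separation ",
         min_separation)
  xs <- numeric(0); ys <- numeric(0)
  attempts <- 0L
  while (length(xs) < n) {
    attempts <- attempts + 1L
    if (attempts > rng_ok * n)
      stop("image too small to place ", n,
           " neurons at min_separation ", min_separation)
    x <- stats::runif(1, margin, w - margin)
    y <- stats::runif(1, margin, h - margin)
    if (length(xs) == 0 ||
        min(sqrt((xs - x)^2 + (ys - y)^2)) >= min_separation) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  data.frame(x = xs, y = ys)
}

#' Simulate neuron fates under a proportional-hazards model
#'
#' Draws one death (or censoring) time per neuron from
#' `h(t) = h0(t) * exp(beta_group + gamma * z(t))`, where `z(t)` is the
#' neuron's standardized log reporter level held piecewise-constant between
#' frames, places neurons in their imaging fields, and records the true
#' per-frame red/green trajectories. Neurons still alive at the end of
#' follow-up are right-censored. The result is exact ground truth for
#' testing the tracking and survival stages.
#'
#' @param design An [experiment_design()].
#' @param model A [hazard_model()]; its `group_log_hr` must name every group
#'   in the design.
#' @param seed Integer seed; the simulation is fully reproducible given it.
#' @param min_separation Minimum centre-to-centre distance in pixels used for
#'   placement (match the renderer's [imaging_model()]). Use 0 for
#'   statistics-only simulations that will never be rendered: placement is
#'   then unconstrained uniform, allowing arbitrarily many neurons per field.
#'
#' @return A `ground_truth` object: list with `fates` (one row per neuron:
#'   `neuron_id, plate, well, field, group, x, y, death_time_h, censored,
#'   responder`), `trajectories` (one row per neuron per frame alive:
#'   `neuron_id, frame, time_h, red, green`), and the `design` and `model`.
#' @examples
#' d <- experiment_design(plates = 1, wells_per_plate = 2, fields_per_well = 1,
#'                        neurons_per_field = 5, group_of_well = c("A", "B"))
#' m <- hazard_model(group_log_hr = c(A = 0, B = log(2)))
#' truth <- simulate_fates(d, m, seed = 1)
#' head(truth$fates)
#' @export
simulate_fates <- function(design, model, seed, min_separation = 12) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(model, "hazard_model"))
  layout <- design_layout(design)
  missing_groups <- setdiff(unique(layout$group), names(model$group_log_hr))
  if (length(missing_groups))
    stop("group_log_hr does not name group(s): ",
         paste(missing_groups, collapse = ", "))
  if (!is.null(model$group_log_hr_late)) {
    missing_late <- setdiff(unique(layout$group), names(model$group_log_hr_late))
    if (length(missing_late))
      stop("group_log_hr_late does not name group(s): ",
           paste(missing_late, collapse = ", "))
  }
  set.seed(as.integer(seed))

  per_well <- design$fields_per_well * design$neurons_per_field
  n <- nrow(layout) * per_well
  fates <- data.frame(
    neuron_id = seq_len(n),
    plate = rep(layout$plate, each = per_well),
    well = rep(layout$well, each = per_well),
    field = rep(rep(seq_len(design$fields_per_well),
                    each = design$neurons_per_field), nrow(layout)),
    group = rep(layout$group, each = per_well),
    stringsAsFactors = FALSE
  )

  # placement, field by field (deterministic draw order)
  pos <- do.call(rbind, lapply(split(fates$neuron_id,
                                     list(fates$well, fates$field),
                                     drop = FALSE),
                               function(ids) {
    p <- place_centers(length(ids), design$image_shape, min_separation)
    p$neuron_id <- ids
    p
  }))
  pos <- pos[order(pos$neuron_id), ]
  fates$x <- pos$x; fates$y <- pos$y

  # per-neuron reporter parameters
  dev_green <- stats::rnorm(n, 0, model$sdlog_green)
  dev_red <- stats::rnorm(n, 0, model$sdlog_red)
  responder <- stats::runif(n) < model$responder_fraction
  rise <- group_rise(model, fates$group)

  tf <- design$frame_times
  end <- design$end_of_followup
  z <- sapply(tf, function(t) reporter_z(dev_green, rise, t, model$sdlog_green))
  z <- matrix(z, nrow = n)

  beta_early <- unname(model$group_log_hr[fates$group])
  beta_late <- if (is.null(model$group_log_hr_late)) beta_early
               else unname(model$group_log_hr_late[fates$group])
  crossing <- model$crossing_time_h

  bp <- sort(unique(c(tf, crossing, end)))
  bp <- bp[bp <= end]
  E <- stats::rexp(n)
  cum <- numeric(n)
  death <- rep(NA_real_, n)
  alive <- rep(TRUE, n)
  for (k in seq_len(length(bp) - 1)) {
    a <- bp[k]; b <- bp[k + 1]
    zi <- findInterval(a, tf)
    eta <- (if (!is.null(crossing) && a >= crossing) beta_late else beta_early) +
      model$reporter_log_hr * z[, zi]
    inc <- (h0_cum(b, model) - h0_cum(a, model)) * exp(eta)
    hit <- alive & (E <= cum + inc)
    if (any(hit)) {
      death[hit] <- h0_inv(h0_cum(a, model) +
                             (E[hit] - cum[hit]) / exp(eta[hit]), model)
      alive[hit] <- FALSE
    }
    cum <- cum + inc
  }
  fates$death_time_h <- death
  fates$censored <- alive
  fates$responder <- responder

  # true per-frame trajectories while alive (t_j strictly before death)
  tmat <- matrix(tf, nrow = n, ncol = length(tf), byrow = TRUE)
  frame_alive <- sweep(tmat, 1, ifelse(alive, Inf, death), "<")
  idx <- which(frame_alive, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  ni <- idx[, 1]; fj <- idx[, 2]
  tj <- tf[fj]
  green <- model$basal_green * exp(dev_green[ni]) *
    (1 + pmax(rise[ni], -0.99) * tj / 24)
  surge_on <- responder[ni] & !alive[ni] & model$surge_lead_h > 0
  frac <- pmax(0, 1 - (death[ni] - tj) / model$surge_lead_h)
  green <- green * ifelse(surge_on, 1 + (model$surge_amplitude - 1) * frac, 1)
  red <- model$basal_red * exp(dev_red[ni])
  trajectories <- data.frame(
    neuron_id = fates$neuron_id[ni],
    frame = fj - 1L,
    time_h = tj,
    red = red,
    green = green
  )

  truth <- list(fates = fates, trajectories = trajectories,
                design = design, model = model)
  class(truth) <- "ground_truth"
  truth
}

#' @export
print.ground_truth <- function(x, ...) {
  n <- nrow(x$fates)
  cat("Ground truth:", n, "neurons;",
      sum(!x$fates$censored), "deaths,", sum(x$fates$censored),
      "censored at", x$design$end_of_followup, "h\n")
  invisible(x)
}

#' Write ground-truth tables to CSV
#'
#' Writes `fates.csv` (one row per neuron) and `trajectories.csv` (one row
#' per neuron per frame alive) under `path`. A subsequent
#' [read_truth_tables()] reproduces the tables (labels and integers exactly,
#' reals to full double precision).
#'
#' @param truth A `ground_truth` object from [simulate_fates()].
#' @param path Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_truth_tables <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", path)
  ff <- file.path(path, "fates.csv")
  tf <- file.path(path, "trajectories.csv")
  fates <- truth$fates
  for (col in c("x", "y", "death_time_h"))
    fates[[col]] <- sprintf("%.17g", fates[[col]])
  fates$death_time_h[truth$fates$censored] <- ""
  utils::write.csv(fates, ff, row.names = FALSE, quote = FALSE)
  traj <- truth$trajectories
  for (col in c("red", "green"))
    traj[[col]] <- sprintf("%.17g", traj[[col]])
  utils::write.csv(traj, tf, row.names = FALSE, quote = FALSE)
  invisible(c(fates = ff, trajectories = tf))
}

#' Read ground-truth tables written by [write_truth_tables()]
#'
#' @param path Directory containing `fates.csv` and `trajectories.csv`.
#' @return A list with data.frames `fates` and `trajectories`.
#' @export
read_truth_tables <- function(path) {
  ff <- file.path(path, "fates.csv")
  tf <- file.path(path, "trajectories.csv")
  if (!file.exists(ff) || !file.exists(tf))
    stop("missing fates.csv / trajectories.csv under ", path)
  fates <- utils::read.csv(ff, stringsAsFactors = FALSE,
                           colClasses = c(well = "character",
                                          group = "character"))
  fates$censored <- as.logical(fates$censored)
  fates$responder <- as.logical(fates$responder)
  traj <- utils::read.csv(tf, stringsAsFactors = FALSE)
  list(fates = fates, trajectories = traj)
}
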