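# Rendering: living neurons as isotropic Gaussian blobs, pixel-integrated
# (pnorm differences), photobleached multiplicatively per frame, with
# Poisson + read noise applied last. Coordinates: x = column, y = row,
# pixel centres at integers 1..width / 1..height.

add_blob <- function(img, x, y, intensity, sigma) {
  h <- nrow(img); w <- ncol(img)
  half <- ceiling(6 * sigma)
  c0 <- max(1L, floor(x - half)); c1 <- min(w, ceiling(x + half))
  r0 <- max(1L, floor(y - half)); r1 <- min(h, ceiling(y + half))
  if (c0 > c1 || r0 > r1) return(img)
  cols <- c0:c1; rows <- r0:r1
  px <- stats::pnorm(cols + 0.5, x, sigma) - stats::pnorm(cols - 0.5, x, sigma)
  py <- stats::pnorm(rows + 0.5, y, sigma) - stats::pnorm(rows - 0.5, y, sigma)
  img[rows, cols] <- img[rows, cols] + intensity * (py %o% px)
  img
}

#' Render one field of a simulated experiment as a two-channel movie
#'
#' Produces one red/green frame pair per time point. Each neuron alive at a
#' frame (true death time strictly after the frame time) is rendered as an
#' isotropic Gaussian blob whose integrated intensity equals its true
#' trajectory value attenuated by photobleaching; neurons contribute nothing
#' from the first frame at or after their death. Noise (Poisson shot noise on
#' signal + background, then Gaussian read noise) is applied last. With noise
#' disabled the frames are exact: background plus pixel-integrated Gaussians.
#'
#' @param truth A `ground_truth` object from [simulate_fates()].
#' @param plate,well,field Identify the field to render (defaults work when
#'   the truth contains a single field).
#' @param imaging An [imaging_model()].
#' @param seed Integer seed for noise and motion jitter; rendering is
#'   deterministic given it.
#' @return A `movie_stack`: list with `red` and `green` (lists of matrices,
#'   counts), `time_h`, `plate`, `well`, `field`, `frame_interval`.
#' @export
render_movie <- function(truth, plate = NULL, well = NULL, field = NULL,
                         imaging = imaging_model(), seed = 1) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(imaging, "imaging_model"))
  fates <- truth$fates
  if (is.null(plate)) plate <- unique(fates$plate)
  if (is.null(well)) well <- unique(fates$well)
  if (is.null(field)) field <- unique(fates$field)
  if (length(plate) != 1 || length(well) != 1 || length(field) != 1)
    stop("specify a single plate, well and field to render")
  sel <- fates$plate == plate & fates$well == well & fates$field == field
  fates <- fates[sel, , drop = FALSE]

  shape <- truth$design$image_shape
  if (nrow(fates) > 0) {
    if (any(fates$x < 1 | fates$x > shape[2] | fates$y < 1 | fates$y > shape[1]))
      stop("placement error: neuron centre outside image bounds")
    if (nrow(fates) > 1) {
      d <- as.matrix(stats::dist(fates[, c("x", "y")]))
      diag(d) <- Inf
      if (min(d) < imaging$min_separation)
        stop("placement error: neuron centres closer than min_separation")
    }
  }

  traj <- truth$trajectories[
    truth$trajectories$neuron_id %in% fates$neuron_id, , drop = FALSE]
  tf <- truth$design$frame_times
  set.seed(as.integer(seed))
  red <- green <- vector("list", length(tf))
  for (j in seq_along(tf)) {
    r <- matrix(0, shape[1], shape[2])
    g <- matrix(0, shape[1], shape[2])
    tr <- traj[traj$frame == j - 1L, , drop = FALSE]
    bleach <- (1 - imaging$photobleach_rate)^(j - 1)
    for (i in seq_len(nrow(tr))) {
      nid <- tr$neuron_id[i]
      fx <- fates$x[fates$neuron_id == nid]
      fy <- fates$y[fates$neuron_id == nid]
      if (imaging$motion_sd > 0) {
        fx <- fx + stats::rnorm(1, 0, imaging$motion_sd)
        fy <- fy + stats::rnorm(1, 0, imaging$motion_sd)
      }
      r <- add_blob(r, fx, fy, tr$red[i] * bleach, imaging$psf_sigma)
      g <- add_blob(g, fx, fy, tr$green[i] * bleach, imaging$psf_sigma)
    }
    camera <- function(img) {
      img <- img + imaging$background_level
      if (imaging$poisson_noise)
        img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                      nrow(img), ncol(img))
      if (imaging$read_noise_sd > 0)
        img <- img + stats::rnorm(length(img), 0, imaging$read_noise_sd)
      pmin(pmax(img, 0), 65535)
    }
    red[[j]] <- camera(r); green[[j]] <- camera(g)
  }
  stack <- list(red = red, green = green, time_h = tf,
                plate = plate, well = well, field = field,
                frame_interval = truth$design$frame_interval)
  class(stack) <- "movie_stack"
  stack
}

well_index <- function(well) {
  as.integer(sub("^p\\d+w(\\d+)$", "\\1", well))
}

movie_basename <- function(plate, well, field) {
  w <- if (is.character(well)) well_index(well) else well
  sprintf("plate%d_well%d_field%d", as.integer(plate), w, as.integer(field))
}

#' Write a movie stack as 16-bit multi-page TIFF
#'
#' Two dialects: one file per channel
#' (`plate{P}_well{W}_field{F}_{red|green}.tif`, default) or a single
#' page-interleaved two-channel stack (`..._rg.tif`; pages red0, green0,
#' red1, ...). Counts are rounded to integers and clipped to 0..65535.
#' Frame order is time order.
#'
#' @param stack A `movie_stack` from [render_movie()].
#' @param dir Output directory (created if absent).
#' @param split_channels One file per channel (`TRUE`) or an interleaved
#'   two-channel stack (`FALSE`).
#' @return Invisibly, the written file path(s).
#' @export
write_movie <- function(stack, dir, split_channels = TRUE) {
  stopifnot(inherits(stack, "movie_stack"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  base <- movie_basename(stack$plate, stack$well, stack$field)
  to16 <- function(m) pmin(pmax(round(m), 0), 65535) / 65535
  if (split_channels) {
    fr <- file.path(dir, paste0(base, "_red.tif"))
    fg <- file.path(dir, paste0(base, "_green.tif"))
    tiff::writeTIFF(lapply(stack$red, to16), fr, bits.per.sample = 16)
    tiff::writeTIFF(lapply(stack$green, to16), fg, bits.per.sample = 16)
    invisible(c(red = fr, green = fg))
  } else {
    f <- file.path(dir, paste0(base, "_rg.tif"))
    pages <- vector("list", 2 * length(stack$red))
    pages[seq(1, length(pages), 2)] <- lapply(stack$red, to16)
    pages[seq(2, length(pages), 2)] <- lapply(stack$green, to16)
    tiff::writeTIFF(pages, f, bits.per.sample = 16)
    invisible(c(rg = f))
  }
}

#' Read a two-channel movie stack written by [write_movie()]
#'
#' Accepts both dialects (per-channel files or a page-interleaved `_rg.tif`
#' stack) and returns counts on the original 0..65535 scale.
#'
#' @param dir Directory holding the TIFF file(s).
#' @param plate,well,field Field identity (well as number or `p<P>w<W>` id).
#' @param frame_interval Hours between frames (stored in the returned stack).
#' @return A `movie_stack`.
#' @export
read_movie <- function(dir, plate, well, field, frame_interval = 24) {
  base <- movie_basename(plate, well, field)
  from16 <- function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]
    round(m * 65535)
  }
  fr <- file.path(dir, paste0(base, "_red.tif"))
  fg <- file.path(dir, paste0(base, "_green.tif"))
  frg <- file.path(dir, paste0(base, "_rg.tif"))
  if (file.exists(fr) && file.exists(fg)) {
    red <- lapply(tiff::readTIFF(fr, all = TRUE), from16)
    green <- lapply(tiff::readTIFF(fg, all = TRUE), from16)
  } else if (file.exists(frg)) {
    pages <- lapply(tiff::readTIFF(frg, all = TRUE), from16)
    if (length(pages) %% 2 != 0)
      stop("interleaved stack has an odd number of pages: ", frg)
    red <- pages[seq(1, length(pages), 2)]
    green <- pages[seq(2, length(pages), 2)]
  } else {
    stop("no TIFF files for ", base, " under ", dir)
  }
  if (length(red) != length(green))
    stop("red/green page counts differ for ", base)
  wid <- if (is.character(well)) well else sprintf("p%dw%d", plate, well)
  stack <- list(red = red, green = green,
                time_h = frame_interval * (seq_along(red) - 1),
                plate = as.integer(plate), well = wid,
                field = as.integer(field), frame_interval = frame_interval)
  class(stack) <- "movie_stack"
  stack
}

#' Render and write every field of a simulated experiment
#'
#' @param truth A `ground_truth` object.
#' @param imaging An [imaging_model()].
#' @param dir Output directory for the TIFF stacks.
#' @param seed Integer seed; each field gets a distinct sub-seed derived
#'   deterministically from it.
#' @param split_channels Passed to [write_movie()].
#' @return Invisibly, a data.frame of written fields.
#' @export
render_experiment <- function(truth, imaging, dir, seed = 1,
                              split_channels = TRUE) {
  stopifnot(inherits(truth, "ground_truth"))
  fields <- unique(truth$fates[, c("plate", "well", "field")])
  fields <- fields[order(fields$plate, fields$well, fields$field), ]
  for (i in seq_len(nrow(fields))) {
    stack <- render_movie(truth, fields$plate[i], fields$well[i],
                          fields$field[i], imaging,
                          seed = (as.numeric(seed) * 1009 + i) %% 2147480009)
    write_movie(stack, dir, split_channels = split_channels)
  }
  invisible(fields)
}
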