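# Centroid linking: tracks are seeded at frame 0 and followed greedily. At
# each frame, candidate objects within search_radius of the track's previous
# centroid are considered; the nearest wins, conflicts resolve by smaller
# distance then lower track id, and a track with no candidate is declared
# absent from that frame onward (no re-acquisition) — disappearance is the
# death call.

greedy_match <- function(track_xy, track_ids, obj_xy, radius) {
  if (nrow(track_xy) == 0 || nrow(obj_xy) == 0)
    return(data.frame(track = integer(0), object = integer(0)))
  d <- sqrt(outer(track_xy[, 1], obj_xy[, 1], "-")^2 +
              outer(track_xy[, 2], obj_xy[, 2], "-")^2)
  cand <- which(d <= radius, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(track = integer(0), object = integer(0)))
  ord <- order(d[cand], track_ids[cand[, 1]])
  cand <- cand[ord, , drop = FALSE]
  used_t <- rep(FALSE, nrow(track_xy)); used_o <- rep(FALSE, nrow(obj_xy))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ti <- cand[k, 1]; oi <- cand[k, 2]
    if (!used_t[ti] && !used_o[oi]) {
      keep[k] <- TRUE; used_t[ti] <- TRUE; used_o[oi] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(track = cand[, 1], object = cand[, 2])
}

#' Link per-frame objects into neuron tracks
#'
#' @param frames List of per-frame object tables (the `objects` element of a
#'   [segment_frame()] result, or any data.frame with `object_id, x, y, area,
#'   mean_red, mean_green`), in time order starting at frame 0.
#' @param seeds Data.frame `track_id, x, y` of neurons selected at frame 0,
#'   or `NULL` to auto-seed one track per frame-0 object.
#' @param search_radius Pixels; candidate objects must lie within this
#'   distance of the track's previous centroid.
#' @param frame_interval Hours between frames.
#' @return A `neuron_tracks` object: list with `observations` (one row per
#'   track per frame: `track_id, frame, time_h, x, y, area, mean_red,
#'   mean_green, present`) and `fates` (`track_id, last_alive_frame,
#'   survival_time_h, died`). Survival time is the last frame observed
#'   alive times the frame interval; `died` is `TRUE` when the neuron
#'   disappeared before the final frame.
#' @export
link_tracks <- function(frames, seeds = NULL, search_radius = 10,
                        frame_interval = 24) {
  frames <- lapply(frames, function(f) {
    if (inherits(f, "segmentation")) f$objects else f
  })
  n_frames <- length(frames)
  if (n_frames == 0) stop("no frames to link")
  f0 <- frames[[1]]

  if (is.null(seeds)) {
    if (nrow(f0) == 0) stop("auto-seeding failed: no objects in frame 0")
    seeds <- data.frame(track_id = seq_len(nrow(f0)), x = f0$x, y = f0$y)
    match0 <- seq_len(nrow(f0))
  } else {
    stopifnot(all(c("track_id", "x", "y") %in% names(seeds)))
    m <- greedy_match(as.matrix(seeds[, c("x", "y")]), seeds$track_id,
                      as.matrix(f0[, c("x", "y")]), search_radius)
    missed <- setdiff(seq_len(nrow(seeds)), m$track)
    if (length(missed))
      stop("seeding error: no frame-0 object within ", search_radius,
           " px of seed(s) ",
           paste(sprintf("track %s (%.1f, %.1f)", seeds$track_id[missed],
                         seeds$x[missed], seeds$y[missed]), collapse = "; "))
    match0 <- rep(NA_integer_, nrow(seeds))
    match0[m$track] <- m$object
  }

  n_tracks <- nrow(seeds)
  obs <- vector("list", n_frames)
  cur_obj <- match0                    # index into frame objects, NA = absent
  cur_xy <- cbind(f0$x[cur_obj], f0$y[cur_obj])
  make_rows <- function(frame_ix, objects, obj_ix) {
    present <- !is.na(obj_ix)
    data.frame(track_id = seeds$track_id,
               frame = frame_ix,
               time_h = frame_ix * frame_interval,
               x = ifelse(present, objects$x[obj_ix], NA_real_),
               y = ifelse(present, objects$y[obj_ix], NA_real_),
               area = ifelse(present, objects$area[obj_ix], NA_integer_),
               mean_red = ifelse(present, objects$mean_red[obj_ix], NA_real_),
               mean_green = ifelse(present, objects$mean_green[obj_ix], NA_real_),
               present = present)
  }
  obs[[1]] <- make_rows(0L, f0, cur_obj)

  for (t in seq_len(n_frames - 1)) {
    ft <- frames[[t + 1]]
    active <- which(!is.na(cur_obj))
    nxt <- rep(NA_integer_, n_tracks)
    if (length(active) > 0 && nrow(ft) > 0) {
      m <- greedy_match(cur_xy[active, , drop = FALSE],
                        seeds$track_id[active],
                        as.matrix(ft[, c("x", "y")]), search_radius)
      nxt[active[m$track]] <- m$object
    }
    cur_obj <- nxt
    cur_xy <- cbind(ft$x[cur_obj], ft$y[cur_obj])
    obs[[t + 1]] <- make_rows(t, ft, cur_obj)
  }

  observations <- do.call(rbind, obs)
  observations <- observations[order(observations$track_id,
                                     observations$frame), ]
  rownames(observations) <- NULL
  last_alive <- tapply(observations$frame[observations$present],
                       observations$track_id[observations$present], max)
  fates <- data.frame(track_id = as.integer(names(last_alive)),
                      last_alive_frame = as.integer(last_alive))
  fates <- fates[order(fates$track_id), ]
  fates$survival_time_h <- fates$last_alive_frame * frame_interval
  fates$died <- fates$last_alive_frame < n_frames - 1
  rownames(fates) <- NULL
  structure(list(observations = observations, fates = fates,
                 frame_interval = frame_interval, n_frames = n_frames),
            class = "neuron_tracks")
}

#' @export
print.neuron_tracks <- function(x, ...) {
  cat("Neuron tracks:", nrow(x$fates), "tracks over", x$n_frames,
      "frames;", sum(x$fates$died), "deaths\n")
  invisible(x)
}

#' Reporter time series of tracked neurons
#'
#' One row per frame at which each neuron is present, with time in hours
#' from the first frame and background-subtracted red/green means.
#'
#' @param tracks A `neuron_tracks` object.
#' @return A data.frame `track_id, time_h, mean_red, mean_green`.
#' @export
extract_reporter_series <- function(tracks) {
  stopifnot(inherits(tracks, "neuron_tracks"))
  o <- tracks$observations
  out <- o[o$present, c("track_id", "time_h", "mean_red", "mean_green")]
  rownames(out) <- NULL
  out
}

#' Segment, measure and link one field's movie
#'
#' Runs [segment_frame()] on every red frame, [measure_fluorescence()] with
#' the red-channel masks on both channels, and [link_tracks()].
#'
#' @param stack A `movie_stack` (from [render_movie()] or [read_movie()]).
#' @param seeds Optional frame-0 seeds (`track_id, x, y`); `NULL` auto-seeds.
#' @param threshold,min_area,morph_radius,smooth_sigma Passed to
#'   [segment_frame()].
#' @param search_radius Passed to [link_tracks()].
#' @param background_method Passed to [measure_fluorescence()].
#' @return A `neuron_tracks` object with `plate`, `well`, `field` columns
#'   added to observations and fates.
#' @export
track_movie <- function(stack, seeds = NULL, threshold = "otsu",
                        min_area = 5, morph_radius = 1, smooth_sigma = 1,
                        search_radius = 10,
                        background_method = "median_outside_masks") {
  stopifnot(inherits(stack, "movie_stack"))
  frames <- lapply(seq_along(stack$red), function(j) {
    seg <- segment_frame(stack$red[[j]], threshold = threshold,
                         min_area = min_area, morph_radius = morph_radius,
                         smooth_sigma = smooth_sigma)
    measure_fluorescence(seg, stack$red[[j]], stack$green[[j]],
                         background_method = background_method)$objects
  })
  tracks <- link_tracks(frames, seeds = seeds, search_radius = search_radius,
                        frame_interval = stack$frame_interval)
  for (nm in c("observations", "fates")) {
    tracks[[nm]]$plate <- stack$plate
    tracks[[nm]]$well <- stack$well
    tracks[[nm]]$field <- stack$field
  }
  tracks
}

#' Track every field of an experiment from its TIFF stacks
#'
#' Reads each field's movie from `dir` (either TIFF dialect) and tracks it.
#' Seeds can be supplied per field (e.g. ground-truth positions, mirroring
#' the operator selecting neurons on the first frame) or auto-detected.
#'
#' @param dir Directory of TIFF stacks written by [write_movie()].
#' @param fields Data.frame `plate, well, field` of fields to process; when
#'   `NULL`, discovered from the filenames.
#' @param seeds Optional data.frame `plate, well, field, track_id, x, y`.
#' @param frame_interval Hours between frames.
#' @param ... Passed to [track_movie()].
#' @return A `neuron_tracks` object covering all fields (track ids are
#'   unique within a field; rows carry plate/well/field).
#' @export
track_experiment <- function(dir, fields = NULL, seeds = NULL,
                             frame_interval = 24, ...) {
  if (is.null(fields)) {
    fn <- list.files(dir, pattern = "^plate\\d+_well\\d+_field\\d+_(red|rg)\\.tif$")
    if (length(fn) == 0) stop("no movie TIFFs found under ", dir)
    parts <- regmatches(fn, regexec("^plate(\\d+)_well(\\d+)_field(\\d+)_", fn))
    fields <- unique(data.frame(
      plate = as.integer(vapply(parts, `[`, "", 2)),
      well = as.integer(vapply(parts, `[`, "", 3)),
      field = as.integer(vapply(parts, `[`, "", 4))))
    fields <- fields[order(fields$plate, fields$well, fields$field), ]
  }
  all_obs <- list(); all_fates <- list()
  n_frames <- NA_integer_
  for (i in seq_len(nrow(fields))) {
    stack <- read_movie(dir, fields$plate[i], fields$well[i], fields$field[i],
                        frame_interval = frame_interval)
    fseeds <- NULL
    if (!is.null(seeds)) {
      wid <- if (is.character(seeds$well[1])) stack$well
             else well_index(stack$well)
      fseeds <- seeds[seeds$plate == fields$plate[i] & seeds$well == wid &
                        seeds$field == fields$field[i],
                      c("track_id", "x", "y")]
    }
    tr <- track_movie(stack, seeds = fseeds, ...)
    all_obs[[i]] <- tr$observations
    all_fates[[i]] <- tr$fates
    n_frames <- tr$n_frames
  }
  structure(list(observations = do.call(rbind, all_obs),
                 fates = do.call(rbind, all_fates),
                 frame_interval = frame_interval, n_frames = n_frames),
            class = "neuron_tracks")
}
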