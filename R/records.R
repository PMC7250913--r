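# Survival-record assembly. Event coding: death = event, alive at end of
# follow-up = right-censored (the standard coding; toxic constructs then get
# HR > 1 relative to the control group). Survival time is the last time the
# neuron was observed alive.

#' Assemble per-neuron survival records
#'
#' Accepts either tracker fates ([link_tracks()]: `track_id,
#' survival_time_h, died`) or simulator ground truth ([simulate_fates()]:
#' `neuron_id, death_time_h, censored`). Ground-truth death times can be
#' used exactly (`time_scale = "exact"`, continuous times) or discretized to
#' the observation grid (`time_scale = "observed"`: last frame time strictly
#' before death), which reproduces what the tracker sees. Group labels come
#' from the fates table itself or from a `layout` mapping wells to groups.
#' Reporter levels at the requested reference times are attached as columns
#' `green_<t>h`.
#'
#' Neurons whose last-alive time is 0 (alive only on the first frame) carry
#' no at-risk time on the study clock and are dropped with a warning.
#'
#' @param fates Fates table (see above) with `plate` and `well` columns.
#' @param layout Optional data.frame `plate, well, group`; required when
#'   `fates` lacks a `group` column.
#' @param series Optional reporter series (`track_id`/`neuron_id`, `time_h`,
#'   `mean_green`, as from [extract_reporter_series()], or the simulator's
#'   trajectories with `green`).
#' @param end_of_followup Hours; censoring time for survivors.
#' @param frame_interval Hours between frames (used to discretize exact
#'   death times).
#' @param reporter_times Numeric vector of reference times (hours) at which
#'   to attach reporter levels.
#' @param time_scale `"observed"` (frame grid) or `"exact"` (continuous
#'   ground-truth death times).
#' @return A data.frame of class `survival_records`: `neuron_id, time,
#'   event, group, well, plate` plus any reporter columns; attributes
#'   `end_of_followup` and `frame_interval`.
#' @export
build_survival_records <- function(fates, layout = NULL, series = NULL,
                                   end_of_followup, frame_interval = 24,
                                   reporter_times = NULL,
                                   time_scale = c("observed", "exact")) {
  time_scale <- match.arg(time_scale)
  if (!all(c("plate", "well") %in% names(fates)))
    stop("fates must carry plate and well columns")
  id_col <- if ("neuron_id" %in% names(fates)) "neuron_id" else "track_id"

  if (all(c("survival_time_h", "died") %in% names(fates))) {
    time <- fates$survival_time_h
    event <- fates$died
  } else if (all(c("death_time_h", "censored") %in% names(fates))) {
    event <- !fates$censored
    if (time_scale == "exact") {
      time <- ifelse(event, fates$death_time_h, end_of_followup)
    } else {
      la <- floor(fates$death_time_h / frame_interval)
      on_grid <- !is.na(fates$death_time_h) &
        fates$death_time_h == la * frame_interval
      la[on_grid] <- la[on_grid] - 1
      time <- ifelse(event, la * frame_interval, end_of_followup)
    }
  } else {
    stop("fates must have survival_time_h/died or death_time_h/censored")
  }

  rec <- data.frame(neuron_id = fates[[id_col]], time = time, event = event,
                    well = fates$well, plate = fates$plate,
                    stringsAsFactors = FALSE)
  if ("group" %in% names(fates)) {
    rec$group <- fates$group
  } else {
    if (is.null(layout))
      stop("layout (plate, well, group) required when fates lack a group column")
    key <- paste(rec$plate, rec$well)
    lkey <- paste(layout$plate, layout$well)
    hit <- match(key, lkey)
    if (anyNA(hit))
      stop("layout error: unmapped well(s): ",
           paste(unique(key[is.na(hit)]), collapse = ", "))
    rec$group <- layout$group[hit]
  }

  if (!is.null(series) && !is.null(reporter_times)) {
    sid <- if ("neuron_id" %in% names(series)) "neuron_id" else "track_id"
    gcol <- if ("mean_green" %in% names(series)) "mean_green" else "green"
    skey <- paste(series[[sid]], series$time_h)
    for (rt in reporter_times) {
      hit <- match(paste(rec$neuron_id, rt), skey)
      rec[[sprintf("green_%gh", rt)]] <- series[[gcol]][hit]
    }
  }

  bad <- rec$time <= 0
  if (any(bad)) {
    warning(sum(bad), " neuron(s) with non-positive survival time dropped ",
            "(alive only on the first frame)")
    rec <- rec[!bad, , drop = FALSE]
  }
  if (any(!rec$event & rec$time != end_of_followup))
    stop("data error: censored record with time != end_of_followup")
  rownames(rec) <- NULL
  attr(rec, "end_of_followup") <- end_of_followup
  attr(rec, "frame_interval") <- frame_interval
  class(rec) <- c("survival_records", "data.frame")
  rec
}
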