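# Reporter-level analyses: normalization to the control condition,
# quartile binning at a reference time, and the quartile-binned Cox model
# with left truncation at the reference time.

#' Normalize reporter levels against the control condition
#'
#' Divides every green measurement by the mean green level of the control
#' group at the reference time, so the control mean at the reference maps
#' to 1.0. Scale-invariant: multiplying all raw values by a constant leaves
#' the normalized values unchanged.
#'
#' @param series Data.frame with `group`, `time_h` and a green column
#'   (`mean_green` or `green`).
#' @param control_group Group label of the control condition.
#' @param reference_time Hours; the normalization anchor.
#' @return `series` with an added `green_norm` column.
#' @export
normalize_reporter <- function(series, control_group, reference_time) {
  gcol <- if ("mean_green" %in% names(series)) "mean_green"
          else if ("green" %in% names(series)) "green"
          else stop("series lacks a green column (mean_green or green)")
  if (!"group" %in% names(series)) stop("series lacks a group column")
  ctrl <- series[[gcol]][series$group == control_group &
                           series$time_h == reference_time]
  ctrl <- ctrl[!is.na(ctrl)]
  if (length(ctrl) == 0)
    stop("control group '", control_group, "' has no measurement at ",
         reference_time, " h")
  f <- mean(ctrl)
  if (f <= 0) stop("normalization error: control mean is ", f, " (<= 0)")
  series$green_norm <- series[[gcol]] / f
  series
}

#' Assign reporter-level quartiles at a reference time
#'
#' Bins neurons by their reporter level at the reference time into quartiles
#' Q1 (lowest) to Q4 (highest) using the empirical 25/50/75 percentiles of
#' the measured distribution (type-7 linear interpolation). Values tied with
#' a boundary go to the lower quartile. Neurons without a measurement at the
#' reference time (e.g. dead before it) are excluded.
#'
#' @param records A `survival_records` data.frame.
#' @param covariate Column holding the reporter level at the reference time
#'   (e.g. `"green_24h"`).
#' @param reference_time Hours; recorded in the result and used by
#'   [quartile_hazard_model()] for left truncation.
#' @return A `quartile_assignment`: list with `assignment` (`neuron_id,
#'   value, quartile`), `boundaries`, `reference_time`, `covariate`.
#' @examples
#' rec <- data.frame(neuron_id = 1:8, g = 1:8)
#' assign_quartiles(rec, "g", reference_time = 24)  # 2 neurons per quartile
#' @export
assign_quartiles <- function(records, covariate, reference_time) {
  if (!covariate %in% names(records))
    stop("records lack covariate column '", covariate, "'")
  sel <- !is.na(records[[covariate]])
  v <- records[[covariate]][sel]
  if (length(v) < 4)
    stop("assignment error: fewer than 4 neurons measured at the reference time")
  qs <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (min(v) == max(v))
    warning("degenerate reporter distribution: all values identical; ",
            "every neuron assigned to Q1")
  qi <- 1L + (v > qs[1]) + (v > qs[2]) + (v > qs[3])
  assignment <- data.frame(
    neuron_id = records$neuron_id[sel],
    value = v,
    quartile = factor(paste0("Q", qi), levels = paste0("Q", 1:4))
  )
  out <- list(assignment = assignment, boundaries = qs,
              reference_time = reference_time, covariate = covariate)
  class(out) <- "quartile_assignment"
  out
}

#' Quartile-binned reporter-hazard Cox model
#'
#' Fits a Cox model of death on reporter-quartile indicators (Q1 = reference,
#' HR 1 by construction), clustered by well and stratified by plate, with
#' follow-up left-truncated at the reference time: only neurons alive and
#' measured at the reference time enter, and they enter the risk set at that
#' time (avoiding immortal-time bias). Optionally adjusts for group.
#'
#' With survival times recorded on the frame grid as last-seen-alive, a
#' death in the first interval after the reference time would make entry and
#' exit coincide; `event_time = "interval_end"` therefore dates each death at
#' the end of its 24-h observation interval (first frame absent). Use
#' `"as_recorded"` for continuous (exact) times.
#'
#' @param records A `survival_records` data.frame.
#' @param assignment A [assign_quartiles()] result.
#' @param adjust_by_group Add the group factor to the model?
#' @param ties Passed to [fit_cox()].
#' @param event_time `"interval_end"` (frame-grid times) or `"as_recorded"`.
#' @param frame_interval Hours; defaults to the records' attribute.
#' @return A `quartile_hr` object: list with `table` (one row per quartile,
#'   Q1 reference, plus group rows when adjusted: `term, hr, ci_lo, ci_hi,
#'   p, n`), `fit` (the underlying `cox_fit`), `reference_time`, `n`.
#' @export
quartile_hazard_model <- function(records, assignment,
                                  adjust_by_group = FALSE,
                                  ties = "breslow",
                                  event_time = c("interval_end", "as_recorded"),
                                  frame_interval = NULL) {
  stopifnot(inherits(assignment, "quartile_assignment"))
  event_time <- match.arg(event_time)
  if (is.null(frame_interval))
    frame_interval <- attr(records, "frame_interval")
  if (is.null(frame_interval) && event_time == "interval_end")
    stop("frame_interval required for interval_end event dating")
  ref <- assignment$reference_time

  rec <- as.data.frame(records)
  hit <- match(rec$neuron_id, assignment$assignment$neuron_id)
  rec$quartile <- assignment$assignment$quartile[hit]
  rec <- rec[!is.na(rec$quartile), , drop = FALSE]

  counts <- table(rec$quartile)
  if (any(counts == 0))
    stop("model error: empty quartile(s): ",
         paste(names(counts)[counts == 0], collapse = ", "))

  rec$entry <- ref
  if (event_time == "interval_end")
    rec$time <- ifelse(rec$event, rec$time + frame_interval, rec$time)
  drop <- rec$time <= rec$entry
  if (any(drop)) rec <- rec[!drop, , drop = FALSE]

  covs <- c("quartile", if (adjust_by_group) "group")
  fit <- fit_cox(rec, covariates = covs, cluster = "well",
                 strata = "plate", ties = ties)

  tb <- fit$table
  ref_row <- data.frame(term = "quartileQ1", hr = 1, ci_lo = NA_real_,
                        ci_hi = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE)
  table <- rbind(ref_row,
                 tb[, c("term", "hr", "ci_lo", "ci_hi", "p")])
  qorder <- c(paste0("quartileQ", 1:4),
              setdiff(table$term, paste0("quartileQ", 1:4)))
  table <- table[match(qorder, table$term), ]
  table$n <- nrow(rec)
  rownames(table) <- NULL
  out <- list(table = table, fit = fit, reference_time = ref, n = nrow(rec))
  class(out) <- "quartile_hr"
  out
}

#' @export
print.quartile_hr <- function(x, digits = 3, ...) {
  cat("Reporter-quartile Cox model at ", x$reference_time, " h (n = ", x$n,
      ")\n", sep = "")
  tb <- x$table
  for (cc in c("hr", "ci_lo", "ci_hi")) tb[[cc]] <- round(tb[[cc]], digits)
  tb$p <- signif(tb$p, 2)
  print(tb, row.names = FALSE)
  invisible(x)
}
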