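#' Nelson-Aalen cumulative hazard estimate
#'
#' Computes, per group, the nonparametric cumulative hazard
#' `H(t) = sum_{t_i <= t} d_i / n_i` over the distinct event times `t_i`,
#' with `d_i` the deaths at `t_i` and `n_i` the number at risk (subjects
#' censored at `t_i` count as at risk at `t_i`, the standard convention).
#' The variance is `sum d_i / n_i^2` and pointwise confidence intervals use
#' the log transform `H * exp(+/- z * sqrt(var) / H)`.
#'
#' @param records A `survival_records` data.frame (or any data.frame with
#'   `time` and `event`; `group` needed when `by_group = TRUE`).
#' @param by_group Estimate per group (default) or pooled.
#' @param conf_level Confidence level for the pointwise interval.
#' @return A data.frame of class `na_estimate`: `group, time, n_risk,
#'   n_event, cumhaz, var, ci_lo, ci_hi`, one row per distinct event time
#'   (step function; `H(0) = 0` implicitly). Groups without events
#'   contribute no rows (`H` identically 0).
#' @examples
#' rec <- data.frame(time = c(24, 48, 72), event = c(TRUE, TRUE, FALSE))
#' nelson_aalen(rec, by_group = FALSE)  # H(24) = 1/3, H(48) = 5/6
#' @export
nelson_aalen <- function(records, by_group = TRUE, conf_level = 0.95) {
  if (NROW(records) == 0) stop("no records")
  stopifnot(all(c("time", "event") %in% names(records)))
  groups <- if (by_group) {
    if (!"group" %in% names(records)) stop("records lack a group column")
    split(records, records$group)
  } else {
    list(all = records)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- lapply(names(groups), function(g) {
    r <- groups[[g]]
    et <- sort(unique(r$time[r$event]))
    if (length(et) == 0) return(NULL)
    n_risk <- vapply(et, function(t) sum(r$time >= t), numeric(1))
    n_event <- vapply(et, function(t) sum(r$event & r$time == t), numeric(1))
    H <- cumsum(n_event / n_risk)
    v <- cumsum(n_event / n_risk^2)
    data.frame(group = g, time = et, n_risk = n_risk, n_event = n_event,
               cumhaz = H, var = v,
               ci_lo = H * exp(-z * sqrt(v) / H),
               ci_hi = H * exp(z * sqrt(v) / H),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(group = character(0), time = numeric(0),
                      n_risk = numeric(0), n_event = numeric(0),
                      cumhaz = numeric(0), var = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("na_estimate", "data.frame")
  attr(out, "conf_level") <- conf_level
  out
}
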