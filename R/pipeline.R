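# Orchestration: one config (YAML/JSON or list) drives simulate -> track ->
# analyze, writing CSV intermediates so every stage can be re-run on its own,
# plus a manifest with the config hash and per-stage row counts.

config_from <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("configuration error: no such file: ", config)
    if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    stop("configuration error: config must be a file path or a list")
  }
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

design_from_config <- function(cd) {
  do.call(experiment_design, cd)
}

hazard_from_config <- function(ch) {
  for (nm in c("group_log_hr", "group_log_hr_late", "rise_per_24h"))
    if (!is.null(ch[[nm]]) && is.list(ch[[nm]])) ch[[nm]] <- unlist(ch[[nm]])
  do.call(hazard_model, ch)
}

#' Run the full simulate / track / analyze pipeline from one configuration
#'
#' The configuration (YAML/JSON file or list) has blocks `simulate`
#' (`design`, `hazard`, `imaging` parameter lists; optional
#' `write_movies: false` for a statistics-only run on ground truth),
#' `track` (segmentation/linking parameters; `auto_seed: true` to seed from
#' all frame-0 objects instead of the ground-truth positions) and `analyze`
#' (`reporter_times`, `adjust_group`, `ties`, `time_scale`), plus a global
#' `seed` and output directory `out`. Alternatively `truth_tables: <dir>`
#' analyzes previously written ground-truth CSVs without simulating.
#' All stage outputs are CSVs under `out`; a `manifest.json` records the
#' config hash, seed and per-stage row counts. Re-running with the same
#' config and seed reproduces identical outputs.
#'
#' @param config Path to a YAML/JSON config or an equivalent nested list.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- config_from(config)
  if (is.null(cfg$out)) stop("configuration error: 'out' directory missing")
  out <- cfg$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  counts <- list()
  warns <- character(0)

  truth <- NULL; design <- NULL
  if (!is.null(cfg$simulate)) {
    design <- design_from_config(cfg$simulate$design)
    hz <- hazard_from_config(cfg$simulate$hazard)
    im <- do.call(imaging_model, if (is.null(cfg$simulate$imaging)) list()
                                 else cfg$simulate$imaging)
    truth <- simulate_fates(design, hz, seed = seed,
                            min_separation = im$min_separation)
    write_truth_tables(truth, file.path(out, "truth"))
    utils::write.csv(design_layout(design), file.path(out, "layout.csv"),
                     row.names = FALSE)
    counts$neurons_simulated <- nrow(truth$fates)
    if (!identical(cfg$simulate$write_movies, FALSE)) {
      render_experiment(truth, im, file.path(out, "images"), seed = seed)
      counts$fields_rendered <- design$plates * design$wells_per_plate *
        design$fields_per_well
    }
  } else if (!is.null(cfg$truth_tables)) {
    if (!dir.exists(cfg$truth_tables))
      stop("configuration error: truth_tables directory not found: ",
           cfg$truth_tables)
  } else if (is.null(cfg$images)) {
    stop("configuration error: need 'simulate', 'truth_tables' or 'images'")
  }

  layout_path <- if (!is.null(cfg$layout)) cfg$layout
                 else file.path(out, "layout.csv")
  if (!is.null(cfg$layout) && !file.exists(cfg$layout))
    stop("configuration error: layout file not found: ", cfg$layout)

  an <- if (is.null(cfg$analyze)) list() else cfg$analyze
  reporter_times <- if (is.null(an$reporter_times)) 24 else
    unlist(an$reporter_times)
  ties <- if (is.null(an$ties)) "breslow" else an$ties
  end_fu <- if (!is.null(design)) design$end_of_followup
            else if (!is.null(an$end_of_followup)) an$end_of_followup
            else 120
  frame_int <- if (!is.null(design)) design$frame_interval
               else if (!is.null(an$frame_interval)) an$frame_interval else 24

  # --- assemble records: tracked images, or ground truth directly
  use_images <- !is.null(cfg$images) ||
    (!is.null(cfg$simulate) && !identical(cfg$simulate$write_movies, FALSE))
  if (use_images) {
    img_dir <- if (!is.null(cfg$images)) cfg$images else file.path(out, "images")
    if (!dir.exists(img_dir))
      stop("configuration error: images directory not found: ", img_dir)
    tp <- cfg$track
    seeds <- NULL
    if (!isTRUE(tp$auto_seed) && !is.null(truth)) {
      seeds <- truth$fates[, c("plate", "well", "field", "neuron_id", "x", "y")]
      names(seeds)[4] <- "track_id"
    }
    tracks <- track_experiment(
      img_dir, seeds = seeds, frame_interval = frame_int,
      threshold = if (is.null(tp$threshold)) "otsu" else tp$threshold,
      min_area = if (is.null(tp$min_area)) 5 else tp$min_area,
      morph_radius = if (is.null(tp$morph_radius)) 1 else tp$morph_radius,
      search_radius = if (is.null(tp$search_radius)) 10 else tp$search_radius)
    utils::write.csv(tracks$observations, file.path(out, "tracks.csv"),
                     row.names = FALSE)
    utils::write.csv(tracks$fates, file.path(out, "track_fates.csv"),
                     row.names = FALSE)
    counts$tracks <- nrow(tracks$fates)
    series <- extract_reporter_series(tracks)
    fates <- tracks$fates
    names(fates)[names(fates) == "survival_time_h"] <- "survival_time_h"
    layout <- utils::read.csv(layout_path, stringsAsFactors = FALSE)
    records <- build_survival_records(
      fates, layout = layout, series = series, end_of_followup = end_fu,
      frame_interval = frame_int, reporter_times = reporter_times)
  } else {
    tt <- if (!is.null(cfg$truth_tables)) read_truth_tables(cfg$truth_tables)
          else list(fates = truth$fates, trajectories = truth$trajectories)
    tscale <- if (is.null(an$time_scale)) "observed" else an$time_scale
    records <- build_survival_records(
      tt$fates, series = tt$trajectories, end_of_followup = end_fu,
      frame_interval = frame_int, reporter_times = reporter_times,
      time_scale = tscale)
    series <- tt$trajectories
  }
  utils::write.csv(records, file.path(out, "records.csv"), row.names = FALSE)
  counts$records <- nrow(records)
  counts$events <- sum(records$event)

  # --- analysis outputs
  na <- nelson_aalen(records)
  utils::write.csv(na, file.path(out, "na_curves.csv"), row.names = FALSE)

  fit <- fit_cox(records, covariates = "group", cluster = "well",
                 strata = "plate", ties = ties)
  cox_tab <- cbind(fit$table, n = fit$n, n_events = fit$n_events,
                   n_clusters = fit$n_clusters)
  utils::write.csv(cox_tab, file.path(out, "cox_fit.csv"), row.names = FALSE)
  counts$cox_terms <- nrow(fit$table)

  pht <- tryCatch(schoenfeld_ph_test(fit),
                  error = function(e) { warns <<- c(warns, conditionMessage(e)); NULL })
  if (!is.null(pht))
    utils::write.csv(pht, file.path(out, "ph_test.csv"), row.names = FALSE)

  adjust <- isTRUE(an$adjust_group)
  for (rt in reporter_times) {
    col <- sprintf("green_%gh", rt)
    if (!col %in% names(records)) next
    qa <- tryCatch(assign_quartiles(records, col, reference_time = rt),
                   error = function(e) { warns <<- c(warns, conditionMessage(e)); NULL })
    if (is.null(qa)) next
    qm <- tryCatch(
      quartile_hazard_model(records, qa, adjust_by_group = adjust, ties = ties,
                            event_time = if (identical(an$time_scale, "exact"))
                              "as_recorded" else "interval_end"),
      error = function(e) { warns <<- c(warns, conditionMessage(e)); NULL })
    if (is.null(qm)) next
    utils::write.csv(qm$table, file.path(out, sprintf("quartile_model_%g.csv", rt)),
                     row.names = FALSE)
  }

  manifest <- list(config_hash = config_hash(cfg), seed = seed,
                   package_version = as.character(utils::packageVersion("neuronsurv")),
                   counts = counts, warnings = warns)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

save_png <- function(plot, path, width = 7, height = 5) {
  grDevices::png(path, width = width, height = height, units = "in",
                 res = 150, type = "cairo")
  on.exit(grDevices::dev.off())
  print(plot)
}

#' Render summary figures from pipeline outputs
#'
#' Reads the stage CSVs under `dir` and writes figures next to them:
#' Nelson-Aalen step curves per group (`na_curves.png`), per-neuron reporter
#' trajectories (`reporter_trajectories.png`, when tracks are available) and
#' a forest plot of the quartile hazard ratios (`quartile_forest.png`). No
#' numbers are computed here; everything is read from the CSVs. Cumulative
#' hazard curves are asserted non-decreasing before plotting.
#'
#' @param dir Pipeline output directory.
#' @return Invisibly, the paths of the written figures.
#' @export
render_report <- function(dir) {
  na_path <- file.path(dir, "na_curves.csv")
  if (!file.exists(na_path))
    stop("report error: missing ", na_path)
  written <- character(0)

  na <- utils::read.csv(na_path, stringsAsFactors = FALSE)
  if (nrow(na) > 0) {
    mono <- tapply(na$cumhaz, na$group, function(h) all(diff(h) >= 0))
    if (!all(mono)) stop("report error: cumulative hazard not monotone")
    p <- ggplot2::ggplot(na, ggplot2::aes(x = time, y = cumhaz,
                                          colour = group)) +
      ggplot2::geom_step() +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "time (h)", y = "cumulative hazard",
                    title = "Nelson-Aalen cumulative hazard") +
      ggplot2::theme_minimal()
    f <- file.path(dir, "na_curves.png")
    save_png(p, f); written <- c(written, f)
  }

  tr_path <- file.path(dir, "tracks.csv")
  if (file.exists(tr_path)) {
    tr <- utils::read.csv(tr_path, stringsAsFactors = FALSE)
    tr <- tr[tr$present & !is.na(tr$mean_green), , drop = FALSE]
    if (nrow(tr) > 0) {
      tr$uid <- paste(tr$plate, tr$well, tr$field, tr$track_id)
      p <- ggplot2::ggplot(tr, ggplot2::aes(x = time_h, y = mean_green,
                                            group = uid)) +
        ggplot2::geom_line(alpha = 0.3) +
        ggplot2::labs(x = "time (h)", y = "green fluorescence (bg-subtracted)",
                      title = "Per-neuron reporter trajectories") +
        ggplot2::theme_minimal()
      f <- file.path(dir, "reporter_trajectories.png")
      save_png(p, f); written <- c(written, f)
    }
  }

  qfiles <- list.files(dir, pattern = "^quartile_model_.*\\.csv$",
                       full.names = TRUE)
  qtabs <- list()
  for (qf in qfiles) {
    qt <- utils::read.csv(qf, stringsAsFactors = FALSE)
    if (nrow(qt) == 0) next
    qt$reference_h <- sub("^quartile_model_(.*)\\.csv$", "\\1", basename(qf))
    qtabs[[qf]] <- qt
  }
  if (length(qtabs) > 0) {
    qt <- do.call(rbind, qtabs)
    qt <- qt[grepl("^quartileQ[2-4]$", qt$term), , drop = FALSE]
    if (nrow(qt) > 0) {
      p <- ggplot2::ggplot(qt, ggplot2::aes(x = hr, y = term)) +
        ggplot2::geom_point() +
        ggplot2::geom_errorbarh(ggplot2::aes(xmin = ci_lo, xmax = ci_hi),
                                height = 0.2) +
        ggplot2::geom_vline(xintercept = 1, linetype = 2) +
        ggplot2::scale_x_log10() +
        ggplot2::facet_wrap(~reference_h) +
        ggplot2::labs(x = "hazard ratio vs Q1 (log scale)", y = NULL,
                      title = "Reporter-quartile hazard ratios") +
        ggplot2::theme_minimal()
      f <- file.path(dir, "quartile_forest.png")
      save_png(p, f); written <- c(written, f)
    }
  } else if (length(qfiles) > 0) {
    warning("quartile tables empty; forest plot skipped")
  }
  invisible(written)
}
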