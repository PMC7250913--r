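# Reporter normalization, quartile assignment, quartile Cox model.

test_that("normalization anchors the control mean at 1 and is scale-free", {
  ser <- data.frame(group = rep(c("Ch", "G93A"), each = 4),
                    time_h = rep(c(24, 24, 48, 48), 2),
                    mean_green = c(90, 110, 120, 140, 250, 350, 400, 500))
  out <- normalize_reporter(ser, "Ch", 24)
  expect_equal(mean(out$green_norm[out$group == "Ch" & out$time_h == 24]), 1)
  out2 <- normalize_reporter(transform(ser, mean_green = mean_green * 13), "Ch", 24)
  expect_equal(out$green_norm, out2$green_norm)
  expect_error(normalize_reporter(ser, "Ch", 96), "no measurement")
  bad <- ser; bad$mean_green[bad$group == "Ch" & bad$time_h == 24] <- c(-5, 5)
  expect_error(normalize_reporter(bad, "Ch", 24), "normalization error")
})

test_that("a programmed reporter elevation survives normalization", {
  d <- tiny_design(neurons = 150, wells = 2, groups = c("Ch", "G93A"))
  m <- hazard_model(baseline = "constant", rate = 0,
                    group_log_hr = c(Ch = 0, G93A = 0),
                    rise_per_24h = c(Ch = 0, G93A = 2))  # 3x at 24 h
  truth <- simulate_fates(d, m, seed = 97, min_separation = 0)
  ser <- merge(truth$trajectories,
               truth$fates[, c("neuron_id", "group")])
  out <- normalize_reporter(ser, "Ch", 24)
  g <- out[out$time_h == 24, ]
  m_g93a <- mean(g$green_norm[g$group == "G93A"])
  expect_lt(abs(m_g93a - 3) / 3, 0.15)  # Monte-Carlo error on 150 cells
  expect_equal(mean(g$green_norm[g$group == "Ch"]), 1)
})

test_that("values 1..8 split two per quartile, boundary ties go low", {
  rec <- data.frame(neuron_id = 1:8, g = 1:8)
  qa <- assign_quartiles(rec, "g", reference_time = 24)
  expect_equal(as.vector(table(qa$assignment$quartile)), rep(2L, 4))
  # values exactly at the median boundary belong to the lower quartile
  rec2 <- data.frame(neuron_id = 1:8, g = c(1, 2, 3, 5, 5, 6, 7, 8))
  qa2 <- assign_quartiles(rec2, "g", reference_time = 24)
  expect_equal(qa2$boundaries[2], 5)
  expect_equal(as.character(qa2$assignment$quartile[4:5]), c("Q2", "Q2"))
})

test_that("degenerate and undersized distributions are handled", {
  rec <- data.frame(neuron_id = 1:6, g = rep(4, 6))
  expect_warning(qa <- assign_quartiles(rec, "g", 24), "degenerate")
  expect_true(all(qa$assignment$quartile == "Q1"))
  expect_error(assign_quartiles(data.frame(neuron_id = 1:3, g = 1:3), "g", 24),
               "fewer than 4")
})

test_that("continuous reporter levels give near-equal quartile sizes", {
  d <- tiny_design(neurons = 523)
  m <- hazard_model(baseline = "constant", rate = 0, group_log_hr = c(A = 0))
  truth <- simulate_fates(d, m, seed = 99, min_separation = 0)
  rec <- build_survival_records(truth$fates, series = truth$trajectories,
                                end_of_followup = 120, reporter_times = 24)
  qa <- assign_quartiles(rec, "green_24h", 24)
  sizes <- table(qa$assignment$quartile)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sum(sizes), 523)
})

test_that("the quartile model fixes Q1 at HR 1 and left-truncates follow-up", {
  d <- experiment_design(plates = 1, wells_per_plate = 4, fields_per_well = 3,
                         neurons_per_field = 30, group_of_well = "A",
                         image_shape = c(400, 400))
  m <- hazard_model(group_log_hr = c(A = 0), scale = 150)
  truth <- simulate_fates(d, m, seed = 101)
  rec <- suppressWarnings(build_survival_records(
    truth$fates, series = truth$trajectories, end_of_followup = 120,
    reporter_times = 24))
  qa <- assign_quartiles(rec, "green_24h", 24)
  qm <- quartile_hazard_model(rec, qa)
  expect_equal(qm$table$hr[1], 1)
  expect_equal(qm$table$term[1:4], paste0("quartileQ", 1:4))
  # left truncation: risk sets start at the reference time
  expect_true(all(qm$fit$coxph$y[, "start"] == 24))
  expect_true(all(qm$fit$coxph$y[, "stop"] > 24))
})

test_that("an empty quartile is a model error naming the quartile", {
  d <- tiny_design(neurons = 40, shape = c(400, 400))
  m <- hazard_model(group_log_hr = c(A = 0), scale = 150)
  truth <- simulate_fates(d, m, seed = 103)
  rec <- suppressWarnings(build_survival_records(
    truth$fates, series = truth$trajectories, end_of_followup = 120,
    reporter_times = 24))
  qa <- assign_quartiles(rec, "green_24h", 24)
  drop_q3 <- qa$assignment$neuron_id[qa$assignment$quartile == "Q3"]
  rec2 <- rec[!rec$neuron_id %in% drop_q3, ]
  attr(rec2, "frame_interval") <- 24
  expect_error(quartile_hazard_model(rec2, qa), "Q3")
})
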