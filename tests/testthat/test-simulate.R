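# Fate simulation against closed-form survival results.

test_that("zero hazard leaves every neuron censored at end of follow-up", {
  d <- tiny_design(neurons = 20)
  m <- hazard_model(baseline = "constant", rate = 0, group_log_hr = c(A = 0))
  truth <- simulate_fates(d, m, seed = 1)
  expect_true(all(truth$fates$censored))
  expect_true(all(is.na(truth$fates$death_time_h)))
})

test_that("constant-hazard death times match the exponential law", {
  # 10,000 neurons at 0.01/h: median ln(2)/0.01 and survival exp(-rate*t)
  d <- experiment_design(plates = 1, wells_per_plate = 1, fields_per_well = 1,
                         neurons_per_field = 10000, group_of_well = "A",
                         end_of_followup = 720)
  m <- hazard_model(baseline = "constant", rate = 0.01,
                    group_log_hr = c(A = 0), reporter_log_hr = 0)
  truth <- simulate_fates(d, m, seed = 7, min_separation = 0)
  dt <- truth$fates$death_time_h
  expect_lt(mean(truth$fates$censored), 0.002)
  med <- stats::median(dt, na.rm = TRUE)
  expect_lt(abs(med - log(2) / 0.01) / (log(2) / 0.01), 0.05)
  for (t in seq(24, 120, by = 24)) {
    p <- exp(-0.01 * t)
    alive <- mean(truth$fates$censored | dt > t)
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(alive - p), 3 * se + 1e-9)
  }
})

test_that("a programmed group hazard ratio shows up in early event counts", {
  d <- experiment_design(plates = 1, wells_per_plate = 2, fields_per_well = 1,
                         neurons_per_field = 5000,
                         group_of_well = c("A", "B"))
  m <- hazard_model(baseline = "constant", rate = 0.002,
                    group_log_hr = c(A = 0, B = log(2)))
  truth <- simulate_fates(d, m, seed = 11, min_separation = 0)
  f <- truth$fates
  # first-frame window: cumulative hazards small, so event ratio ~ HR
  dA <- sum(f$group == "A" & !f$censored & f$death_time_h <= 24)
  dB <- sum(f$group == "B" & !f$censored & f$death_time_h <= 24)
  expect_gt(dB / dA, 2 * 0.8)
  expect_lt(dB / dA, 2 * 1.25)
})

test_that("simulation is reproducible for a seed and varies across seeds", {
  d <- tiny_design(neurons = 40, shape = c(400, 400))
  m <- hazard_model(group_log_hr = c(A = 0))
  t1 <- simulate_fates(d, m, seed = 5)
  t2 <- simulate_fates(d, m, seed = 5)
  t3 <- simulate_fates(d, m, seed = 6)
  expect_identical(t1$fates, t2$fates)
  expect_identical(t1$trajectories, t2$trajectories)
  expect_false(identical(sort(t1$fates$death_time_h),
                         sort(t3$fates$death_time_h)))
})

test_that("trajectories cover exactly the frames each neuron is alive", {
  d <- tiny_design(neurons = 30, shape = c(300, 300))
  m <- hazard_model(group_log_hr = c(A = 0), scale = 100)
  truth <- simulate_fates(d, m, seed = 3)
  for (i in sample(truth$fates$neuron_id, 10)) {
    f <- truth$fates[truth$fates$neuron_id == i, ]
    tr <- truth$trajectories[truth$trajectories$neuron_id == i, ]
    expected_frames <- if (f$censored) 0:5 else
      0:true_last_alive(f, 6, 24)
    expect_equal(tr$frame, expected_frames)
    expect_true(all(tr$green > 0) && all(tr$red > 0))
  }
})

test_that("pre-death surge raises green in responders before death only", {
  d <- tiny_design(neurons = 200)
  m <- hazard_model(group_log_hr = c(A = 0), scale = 90,
                    responder_fraction = 1, surge_amplitude = 2,
                    surge_lead_h = 48, sdlog_green = 0, rise_per_24h = 0)
  truth <- simulate_fates(d, m, seed = 9, min_separation = 0)
  tr <- merge(truth$trajectories, truth$fates[, c("neuron_id", "death_time_h",
                                                  "censored")])
  dead <- tr[!tr$censored, ]
  far <- dead[dead$death_time_h - dead$time_h >= 48, ]
  near <- dead[dead$death_time_h - dead$time_h < 24, ]
  expect_true(all(abs(far$green - m$basal_green) < 1e-9))
  expect_true(all(near$green > m$basal_green))
  cens <- tr[tr$censored, ]
  expect_true(all(abs(cens$green - m$basal_green) < 1e-9))
})

test_that("unknown group labels and invalid placement are refused", {
  d <- tiny_design(neurons = 4, groups = "missing")
  m <- hazard_model(group_log_hr = c(A = 0))
  expect_error(simulate_fates(d, m, seed = 1), "group")
  d2 <- tiny_design(neurons = 200, shape = c(30, 30))
  expect_error(simulate_fates(d2, hazard_model(group_log_hr = c(A = 0)),
                              seed = 1), "image too small")
})
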