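# Centroid linking, death calls, and track invariants.

obj_df <- function(x, y = NULL) {
  if (is.null(y)) { y <- x$y; x <- x$x }
  data.frame(object_id = seq_along(x), x = x, y = y,
             area = rep(20L, length(x)), mean_red = rep(100, length(x)),
             mean_green = rep(50, length(x)))
}

test_that("a stationary object persisting through all frames never dies", {
  frames <- replicate(6, obj_df(50, 50), simplify = FALSE)
  tk <- link_tracks(frames, frame_interval = 24)
  expect_equal(nrow(tk$fates), 1)
  expect_false(tk$fates$died)
  expect_equal(tk$fates$survival_time_h, 120)
  expect_true(all(tk$observations$present))
})

test_that("disappearance from frame 3 of 6 gives survival 48 h and death", {
  frames <- c(replicate(3, obj_df(50, 50), simplify = FALSE),
              replicate(3, obj_df(numeric(0), numeric(0)), simplify = FALSE))
  tk <- link_tracks(frames, frame_interval = 24)
  expect_equal(tk$fates$last_alive_frame, 2L)
  expect_equal(tk$fates$survival_time_h, 48)
  expect_true(tk$fates$died)
})

test_that("no re-acquisition: once absent, a track stays absent", {
  # object vanishes at frame 2 and an identical one reappears at frame 4
  frames <- list(obj_df(50, 50), obj_df(50, 50), obj_df(numeric(0), numeric(0)),
                 obj_df(numeric(0), numeric(0)), obj_df(50, 50), obj_df(50, 50))
  tk <- link_tracks(frames, frame_interval = 24)
  expect_equal(tk$fates$last_alive_frame, 1L)
  pres <- tk$observations$present
  expect_equal(pres, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("conflicts resolve by distance then track id, objects never shared", {
  f0 <- obj_df(c(10, 20), c(10, 10))
  f1 <- obj_df(15.5, 10)   # within 10 px of both seeds, nearer to seed 2
  tk <- link_tracks(list(f0, f1), frame_interval = 24)
  o1 <- tk$observations
  expect_false(o1$present[o1$track_id == 1 & o1$frame == 1])
  expect_true(o1$present[o1$track_id == 2 & o1$frame == 1])

  # equidistant: lower track id wins
  f1b <- obj_df(15, 10)
  tk2 <- link_tracks(list(f0, f1b), frame_interval = 24)
  o2 <- tk2$observations
  expect_true(o2$present[o2$track_id == 1 & o2$frame == 1])
  expect_false(o2$present[o2$track_id == 2 & o2$frame == 1])
})

test_that("a seed with no frame-0 object within reach is a seeding error", {
  frames <- list(obj_df(50, 50), obj_df(50, 50))
  seeds <- data.frame(track_id = c(1, 7), x = c(50, 120), y = c(50, 120))
  expect_error(link_tracks(frames, seeds = seeds), "seeding error.*track 7")
})

test_that("presence is always a prefix and matching is always partial", {
  # randomized jittered fields with objects dropping out
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    x0 <- runif(n, 20, 180); y0 <- runif(n, 20, 180)
    alive_until <- sample(0:5, n, replace = TRUE)
    frames <- lapply(0:5, function(j) {
      keep <- which(alive_until >= j)
      obj_df(x0[keep] + rnorm(length(keep)), y0[keep] + rnorm(length(keep)))
    })
    tk <- link_tracks(frames, seeds = data.frame(track_id = 1:n, x = x0, y = y0),
                      search_radius = 10)
    for (id in 1:n) {
      pres <- tk$observations$present[tk$observations$track_id == id]
      expect_true(all(diff(pres) <= 0))  # never absent-then-present
    }
    for (j in 0:5) {
      oo <- tk$observations[tk$observations$frame == j & tk$observations$present, ]
      expect_equal(anyDuplicated(oo[, c("x", "y")]), 0)
    }
  }
})

test_that("fates on noise-free renders match ground truth exactly", {
  d <- experiment_design(plates = 1, wells_per_plate = 1, fields_per_well = 4,
                         neurons_per_field = 10, group_of_well = "A",
                         image_shape = c(200, 200))
  m <- hazard_model(group_log_hr = c(A = 0), scale = 150)
  im <- noise_free(photobleach_rate = 0.02)
  truth <- simulate_fates(d, m, seed = 61, min_separation = im$min_separation)
  dir <- withr::local_tempdir()
  render_experiment(truth, im, dir, seed = 61)
  tk <- track_experiment(dir, seeds = truth_seeds(truth), frame_interval = 24)
  ft <- merge(tk$fates, truth$fates, by.x = "track_id", by.y = "neuron_id")
  expect_equal(ft$last_alive_frame, true_last_alive(ft, d$n_frames))
})

test_that("reporter series covers exactly the frames a neuron was present", {
  frames <- c(replicate(5, obj_df(30, 30), simplify = FALSE),
              list(obj_df(numeric(0), numeric(0))))
  tk <- link_tracks(frames, frame_interval = 24)
  ser <- extract_reporter_series(tk)
  expect_equal(nrow(ser), 5)
  expect_equal(ser$time_h, seq(0, 96, by = 24))

  frames1 <- c(list(obj_df(30, 30)),
               replicate(5, obj_df(numeric(0), numeric(0)), simplify = FALSE))
  ser1 <- extract_reporter_series(link_tracks(frames1, frame_interval = 24))
  expect_equal(nrow(ser1), 1)
  expect_equal(ser1$time_h, 0)
})
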