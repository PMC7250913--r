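# Rendering geometry and noise model.

test_that("an empty field renders as pure background", {
  d <- tiny_design(neurons = 2)
  m <- hazard_model(group_log_hr = c(A = 0))
  truth <- simulate_fates(d, m, seed = 2)
  st <- render_movie(truth, plate = 1, well = "p1w1", field = 99,
                     imaging = noise_free(background_level = 50), seed = 1)
  for (fr in c(st$red, st$green))
    expect_true(all(fr == 50))
})

test_that("a single noise-free blob has the right peak and integral", {
  d <- tiny_design(neurons = 1)
  m <- hazard_model(baseline = "constant", rate = 0,
                    group_log_hr = c(A = 0), sdlog_red = 0, sdlog_green = 0)
  truth <- simulate_fates(d, m, seed = 4)
  im <- noise_free(background_level = 0, photobleach_rate = 0)
  st <- render_movie(truth, imaging = im, seed = 1)
  img <- st$red[[1]]
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  expect_lt(abs(pk["col"] - truth$fates$x), 0.5 + 1e-9)
  expect_lt(abs(pk["row"] - truth$fates$y), 0.5 + 1e-9)
  I <- truth$trajectories$red[truth$trajectories$frame == 0]
  expect_lt(abs(sum(img) - I) / I, 0.01)

  # 6-sigma window against independent midpoint-rule integration
  cx <- truth$fates$x; cy <- truth$fates$y; s <- im$psf_sigma
  rows <- max(1, floor(cy - 6 * s)):min(nrow(img), ceiling(cy + 6 * s))
  cols <- max(1, floor(cx - 6 * s)):min(ncol(img), ceiling(cx + 6 * s))
  expect_lt(abs(sum(img[rows, cols]) - I) / I, 0.005)
  oracle <- blob_pixel_oracle(rows, cols, cx, cy, s, I)
  expect_lt(max(abs(img[rows, cols] - oracle)) / max(oracle), 0.001)
})

test_that("rendering conserves signal before noise", {
  d <- tiny_design(neurons = 8, shape = c(200, 200))
  m <- hazard_model(group_log_hr = c(A = 0), scale = 120)
  truth <- simulate_fates(d, m, seed = 6)
  im <- noise_free(background_level = 100, photobleach_rate = 0.02)
  st <- render_movie(truth, imaging = im, seed = 1)
  npx <- prod(d$image_shape)
  for (j in seq_along(st$red)) {
    tr <- truth$trajectories[truth$trajectories$frame == j - 1, ]
    expected <- sum(tr$red) * (1 - 0.02)^(j - 1)
    got <- sum(st$red[[j]]) - 100 * npx
    if (expected > 0) expect_lt(abs(got - expected) / expected, 0.01)
    else expect_lt(abs(got), 1e-6)
  }
})

test_that("dead neurons vanish from the first frame at or after death", {
  d <- tiny_design(neurons = 5, shape = c(150, 150))
  m <- hazard_model(group_log_hr = c(A = 0), scale = 60)
  truth <- simulate_fates(d, m, seed = 8)
  dead <- truth$fates[!truth$fates$censored, ][1, ]
  expect_false(is.na(dead$neuron_id))  # scale 60 h makes deaths certain here
  im <- noise_free(background_level = 0)
  st <- render_movie(truth, imaging = im, seed = 1)
  first_gone <- true_last_alive(dead, d$n_frames) + 1
  cx <- round(dead$x); cy <- round(dead$y)
  for (j in (first_gone + 1):d$n_frames)  # 1-based frame list index
    expect_lt(st$red[[j]][cy, cx], 1e-9)
})

test_that("rendering is deterministic given a seed, and noise differs by seed", {
  d <- tiny_design(neurons = 3)
  m <- hazard_model(group_log_hr = c(A = 0))
  truth <- simulate_fates(d, m, seed = 10)
  im <- imaging_model()
  a <- render_movie(truth, imaging = im, seed = 42)
  b <- render_movie(truth, imaging = im, seed = 42)
  c <- render_movie(truth, imaging = im, seed = 43)
  expect_identical(a$red, b$red)
  expect_false(identical(a$red[[1]], c$red[[1]]))
})

test_that("overlapping centres are rejected as placement errors", {
  d <- tiny_design(neurons = 2)
  m <- hazard_model(group_log_hr = c(A = 0))
  truth <- simulate_fates(d, m, seed = 12)
  truth$fates$x <- c(50, 52); truth$fates$y <- c(50, 50)
  expect_error(render_movie(truth, imaging = imaging_model(), seed = 1),
               "placement error")
  truth$fates$x <- c(50, -3)
  expect_error(render_movie(truth, imaging = imaging_model(), seed = 1),
               "placement error")
})

test_that("movie TIFF round-trips in both dialects at 16-bit precision", {
  d <- tiny_design(neurons = 4)
  m <- hazard_model(group_log_hr = c(A = 0))
  truth <- simulate_fates(d, m, seed = 13)
  st <- render_movie(truth, imaging = imaging_model(), seed = 2)
  dir <- withr::local_tempdir()
  write_movie(st, dir, split_channels = TRUE)
  back <- read_movie(dir, 1, 1, 1, frame_interval = 24)
  expect_equal(length(back$red), length(st$red))
  expect_true(max(abs(back$red[[1]] - round(st$red[[1]]))) == 0)
  dir2 <- withr::local_tempdir()
  write_movie(st, dir2, split_channels = FALSE)
  back2 <- read_movie(dir2, 1, 1, 1, frame_interval = 24)
  expect_identical(back$red, back2$red)
  expect_identical(back$green, back2$green)
})
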