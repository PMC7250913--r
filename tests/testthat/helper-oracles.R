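# Independent oracles and small fixture builders used across the suite.

# Breslow log partial likelihood for a single binary covariate, vectorized
# over a beta grid (independent of the fitting code: direct risk-set sums).
breslow_loglik_grid <- function(grid, time, status, x) {
  ev <- which(status)
  n1 <- vapply(ev, function(i) sum(x[time >= time[i]] == 1), numeric(1))
  n0 <- vapply(ev, function(i) sum(x[time >= time[i]] == 0), numeric(1))
  sx <- sum(x[ev])
  eb <- exp(grid)
  denom <- vapply(seq_along(ev), function(k) log(n0[k] + n1[k] * eb),
                  numeric(length(grid)))
  grid * sx - rowSums(matrix(denom, nrow = length(grid)))
}

# Brute-force maximizer of the Breslow log partial likelihood.
grid_cox_beta <- function(time, status, x, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  grid[which.max(breslow_loglik_grid(grid, time, status, x))]
}

# Random small survival dataset with one binary covariate, distinct event
# times and an interior partial-likelihood maximum (regenerates otherwise).
random_cox_dataset <- function(n, seed) {
  set.seed(seed)
  repeat {
    x <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    time <- round(stats::runif(n, 1, 100), 3)
    if (anyDuplicated(time)) next
    status <- stats::runif(n) < 0.7
    if (sum(status & x == 1) < 1 || sum(status & x == 0) < 1) next
    b <- grid_cox_beta(time, status, x)
    if (abs(b) > 4.5) next
    return(data.frame(time = time, event = status, x = x))
  }
}

# Naive double-loop Nelson-Aalen: recompute every risk set from scratch.
na_oracle <- function(time, event) {
  et <- sort(unique(time[event]))
  H <- numeric(length(et)); V <- numeric(length(et))
  for (k in seq_along(et)) {
    h <- 0; v <- 0
    for (s in et[et <= et[k]]) {
      d <- sum(event & time == s)
      n <- sum(time >= s)
      h <- h + d / n
      v <- v + d / n^2
    }
    H[k] <- h; V[k] <- v
  }
  data.frame(time = et, cumhaz = H, var = V)
}

# Midpoint-rule pixel integration of an isotropic Gaussian blob
# (independent of the renderer's pnorm-difference construction).
blob_pixel_oracle <- function(rows, cols, cx, cy, sigma, intensity, sub = 41) {
  off <- seq(-0.5 + 0.5 / sub, 0.5 - 0.5 / sub, length.out = sub)
  val <- matrix(0, length(rows), length(cols))
  for (i in seq_along(rows)) for (j in seq_along(cols)) {
    gx <- stats::dnorm(cols[j] + off, cx, sigma)
    gy <- stats::dnorm(rows[i] + off, cy, sigma)
    val[i, j] <- intensity * mean(gy) * mean(gx)
  }
  val
}

# Ground-truth last-alive frame on the observation grid (frame j at time
# j * interval; a neuron is alive at a frame iff its death is strictly
# later).
true_last_alive <- function(fates, n_frames, interval = 24) {
  ifelse(fates$censored, n_frames - 1,
         ifelse(fates$death_time_h == floor(fates$death_time_h / interval) * interval,
                fates$death_time_h / interval - 1,
                floor(fates$death_time_h / interval)))
}

# One-field experiment with noise-free imaging, used by several files.
tiny_design <- function(neurons = 6, fields = 1, groups = "A", wells = 1,
                        plates = 1, shape = c(120, 120)) {
  experiment_design(plates = plates, wells_per_plate = wells,
                    fields_per_well = fields, neurons_per_field = neurons,
                    group_of_well = groups, image_shape = shape)
}

noise_free <- function(...) {
  imaging_model(poisson_noise = FALSE, read_noise_sd = 0, motion_sd = 0, ...)
}

truth_seeds <- function(truth) {
  s <- truth$fates[, c("plate", "well", "field", "neuron_id", "x", "y")]
  names(s)[4] <- "track_id"
  s
}
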