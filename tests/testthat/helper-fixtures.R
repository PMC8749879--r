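# shared fixtures: noiseless and small study configurations

noiseless_config <- function(...) {
  cohort_config(noise_cv = 0, gnss_jitter_m = 0, accel_noise_sd_g = 0, ...)
}

# null cohort: no week effect anywhere (constant trajectories)
null_config <- function(...) {
  cohort_config(hr_weekly_bpm = rep(150, 4),
                wingate_effect_by_week = rep(0.9, 4),
                bosco_effect_by_week = rep(0.95, 4),
                ...)
}

week_matrix_for_test <- function(grouped, parameter, phase) {
  rebound:::week_matrix(grouped, parameter, phase)
}

# brute-force signed-rank enumeration over an explicit 2^n sign matrix;
# deliberately different machinery from the package's convolution
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mu <- sum(r) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# brute-force Cliff's delta by explicit double loop
oracle_cliffs_delta <- function(x, y) {
  gt <- 0; lt <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) gt <- gt + 1
    if (xi < yj) lt <- lt + 1
  }
  (gt - lt) / (length(x) * length(y))
}
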