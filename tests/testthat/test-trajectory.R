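# MSD pooling, subdiffusion fitting, segregation events and the resampling
# test.

test_that("ballistic tracks give the exact quadratic MSD", {
  v <- 0.05; dt <- 2
  tt <- seq(0, 40, by = dt)
  tr <- make_tracks(cbind(tt, v * tt, 0))
  msd <- compute_msd(tr)
  expect_equal(msd$msd, v^2 * msd$tau^2, tolerance = 1e-12)
})

test_that("MSD pairing bridges missing frames", {
  tt <- c(0, 1, 3, 4)                     # frame at t = 2 missing
  tr <- make_tracks(cbind(tt, c(0, 1, 3, 4), 0))
  msd <- compute_msd(tr)
  expect_true(all(c(1, 2, 3, 4) %in% msd$tau))
  expect_equal(msd$n[msd$tau == 2], 1L)   # the 1 -> 3 pair spans the gap
  expect_equal(msd$msd[msd$tau == 2], 4)
})

test_that("MSD is invariant to track order", {
  set.seed(1)
  a <- cbind(0:10, cumsum(rnorm(11, sd = 0.1)), cumsum(rnorm(11, sd = 0.1)))
  b <- cbind(0:10, cumsum(rnorm(11, sd = 0.1)), cumsum(rnorm(11, sd = 0.1)))
  m1 <- compute_msd(make_tracks(a, b))
  m2 <- compute_msd(make_tracks(b, a))
  expect_equal(m1$msd, m2$msd)
  expect_equal(m1$n, m2$n)
})

test_that("Brownian track ensembles recover the diffusive MSD slope", {
  spec <- synth_track_spec(n_tracks = 300, duration = 60, frame_interval = 2,
                           alpha = 1, D = 5e-3, sigma = 0, pixel = 0,
                           seed = 10)
  tr <- generate_fbm_tracks(spec)$tracks
  msd <- compute_msd(tr, max_lag = 20)
  fit <- lm(msd ~ tau + 0, data = as.data.frame(msd[msd$tau <= 20, ]))
  # overlapping-window displacements are correlated, so compare the slope
  # at a sampling-scale relative tolerance rather than the naive lm SE
  expect_equal(unname(coef(fit)[1]), 4 * 5e-3, tolerance = 0.05)
})

test_that("pure Brownian tracks fit with alpha near 1 and beta near 0", {
  spec <- synth_track_spec(n_tracks = 400, duration = 60, frame_interval = 2,
                           alpha = 1, D = 5e-3, sigma = 0, pixel = 0, seed = 2)
  fit <- fit_subdiffusion(compute_msd(generate_fbm_tracks(spec)$tracks))
  expect_lt(abs(fit$alpha - 1), max(3 * fit$alpha_se, 0.05))
  expect_lt(abs(fit$beta), 3e-3)
  expect_lte(fit$r_squared, 1)
})

test_that("localization noise raises the offset by about 4 sigma^2", {
  base <- synth_track_spec(n_tracks = 500, duration = 60, frame_interval = 2,
                           alpha = 1, D = 5e-3, sigma = 0, pixel = 0, seed = 6)
  noisy <- base; noisy$sigma <- 0.05
  f0 <- fit_subdiffusion(compute_msd(generate_fbm_tracks(base)$tracks))
  f1 <- fit_subdiffusion(compute_msd(generate_fbm_tracks(noisy)$tracks))
  expect_equal(f1$beta - f0$beta, 4 * 0.05^2, tolerance = 0.35)
})

test_that("subdiffusion fit is unbiased over an exponent grid", {
  for (a in c(0.5, 0.73, 1.0)) {
    spec <- synth_track_spec(n_tracks = 500, duration = 64,
                             frame_interval = 4, alpha = a, D = 1e-3,
                             sigma = 0, pixel = 0, seed = 1000 + round(100 * a))
    fit <- fit_subdiffusion(compute_msd(generate_fbm_tracks(spec)$tracks))
    expect_lt(abs(fit$alpha - a), 0.03)
  }
})

test_that("the free-diffusion bound dominates the fitted subdiffusive law", {
  # analytic curves: 4 D_f tau >= 4 D tau^alpha + beta for all lags >= 4 s
  D_f <- 10e-4; D <- 9.7e-4; a <- 0.73; beta <- 1.6e-3
  tau <- seq(4, 900, by = 1)
  expect_true(all(4 * D_f * tau >= 4 * D * tau^a + beta))
})

test_that("the required free diffusivity for observed displacements is of order 1e-2", {
  D <- required_diffusivity(displacement = 3.5, time = 600)
  expect_equal(D, 3.5^2 / 1200)
  expect_gt(D, 1e-2 / 2); expect_lt(D, 1e-2 * 5)
})

test_that("segregation events follow the definition and windows", {
  mk_pair <- function(t, sep) {
    rbind(data.frame(cell = 1, focus = "a", t_s = t, x_um = 0, y_um = 0),
          data.frame(cell = 1, focus = "b", t_s = t, x_um = sep, y_um = 0))
  }
  # 0.2 um -> 1.1 um within 12 s: one event (extra 0.9 >= 0.8)
  d1 <- rbind(mk_pair(0, 0.2), mk_pair(4, 0.5), mk_pair(8, 0.8),
              mk_pair(12, 1.1))
  ev <- detect_segregation_events(trajectory_set(d1))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$init_separation, 0.2)
  expect_gte(ev$max_extra_separation, 0.8)

  # initial separation too large: no event
  d2 <- rbind(mk_pair(0, 0.5), mk_pair(10, 2.5))
  expect_equal(nrow(detect_segregation_events(trajectory_set(d2))), 0L)

  # merged foci that split count from separation zero
  d3 <- rbind(mk_pair(0, 0), mk_pair(10, 0.9))
  expect_equal(nrow(detect_segregation_events(trajectory_set(d3))), 1L)

  # +0.8 um reached only at 45 s: no event at window 20, one at window 60
  d4 <- rbind(mk_pair(0, 0.1), mk_pair(20, 0.4), mk_pair(45, 0.95))
  expect_equal(nrow(detect_segregation_events(trajectory_set(d4),
                                              window = 20)), 0L)
  expect_equal(nrow(detect_segregation_events(trajectory_set(d4),
                                              window = 60)), 1L)
})

test_that("max-MSD resampling test behaves at its extremes and under the null", {
  set.seed(3)
  mats <- lapply(1:40, function(i) {
    cbind(0:10, cumsum(rnorm(11, sd = 0.05 * i)), 0)
  })
  all_tr <- do.call(make_tracks, mats)
  # top-k trajectories by construction have the largest maxima
  top <- do.call(make_tracks, mats[31:40])
  r_top <- max_msd_resampling_test(top, all_tr, n_resample = 2000, seed = 1)
  expect_equal(r_top$p_value, 1 / 2001)
  # the whole dataset: p = 1
  r_all <- max_msd_resampling_test(all_tr, all_tr, n_resample = 500, seed = 1)
  expect_equal(r_all$p_value, 1)
  # a uniformly drawn event set gives calibrated (roughly uniform) p-values
  ps <- vapply(1:200, function(i) {
    set.seed(i)
    idx <- sample(40, 10)
    max_msd_resampling_test(do.call(make_tracks, mats[idx]), all_tr,
                            n_resample = 200, seed = 1e4 + i)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 1e-3)
  # event set larger than the dataset is rejected
  expect_error(max_msd_resampling_test(all_tr, top, n_resample = 10),
               "larger")
})
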