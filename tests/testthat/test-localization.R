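# Nucleoid edges, relative positions, the uniform null, asymmetry,
# focus-plane selection, first-harmonic scoring and colocalization.

test_that("half-maximum edges of simple profiles", {
  x <- seq(0, 2, by = 0.01)
  tri <- pmax(0, 1 - abs(x - 1))
  e <- nucleoid_edges(x, tri)
  expect_equal(e$edge_left, 0.5, tolerance = 1e-9)
  expect_equal(e$edge_right, 1.5, tolerance = 1e-9)
  expect_equal(e$length, 1, tolerance = 1e-9)
  expect_equal(e$n_lobes, 1L)

  rect <- as.numeric(x >= 0.5 & x <= 1.5)
  er <- nucleoid_edges(x, rect)
  expect_equal(er$edge_left, 0.5, tolerance = 0.011)   # within one sample
  expect_equal(er$edge_right, 1.5, tolerance = 0.011)

  # two-lobed (post-replication) profile: outermost crossings + lobe count
  two <- exp(-(x - 0.6)^2 / 0.02) + exp(-(x - 1.4)^2 / 0.02)
  et <- nucleoid_edges(x, two)
  expect_equal(et$n_lobes, 2L)
  expect_lt(et$edge_left, 0.6); expect_gt(et$edge_right, 1.4)

  expect_error(nucleoid_edges(x, rep(0, length(x))), "flat")
})

test_that("relative positions are normalized, sorted and rank-labeled", {
  e <- list(edge_left = 1, edge_right = 3, length = 2)
  r <- relative_positions(c(2), e)
  expect_equal(r$rel_pos, 0.5)
  r2 <- relative_positions(c(2.5, 1.5), e)
  expect_equal(r2$rel_pos, c(0.25, 0.75))
  expect_equal(r2$label, 1:2)
  expect_false(any(r2$outside))
  r3 <- relative_positions(c(0.5, 2), e)
  expect_true(r3$outside[1])
  # equal-spacing prediction maps onto thirds of the unit interval
  pred <- equal_spacing_positions(2, 3) + 1
  expect_equal(relative_positions(pred, e)$rel_pos, c(1, 3, 5) / 6)
})

test_that("uniform null label means are the order-statistic expectations", {
  n1 <- random_position_null(1, n_datasets = 2e4, seed = 1)
  expect_equal(n1$label_means, 0.5, tolerance = 0.01)
  # flat histogram for a single label
  expect_lt(diff(range(n1$histogram$density)), 0.25)

  n2 <- random_position_null(2, n_datasets = 2e4, seed = 2)
  expect_equal(unname(n2$label_means), c(1, 2) / 3, tolerance = 0.01)
  n4 <- random_position_null(4, n_datasets = 2e4, seed = 3)
  expect_equal(unname(n4$label_means), (1:4) / 5, tolerance = 0.01)
})

test_that("asymmetry is 0 for uniform, 1 for one-sided, and scale-invariant", {
  x <- seq(0, 3, by = 0.01)
  unif <- rep(2, length(x))
  for (f in c(0.7, 1.5, 2.6)) {
    expect_equal(asymmetry_measure(x, unif, f)$asymmetry, 0, tolerance = 1e-9)
  }
  one_side <- ifelse(x < 1.5, 1, 0)
  a1 <- asymmetry_measure(x, one_side, 1.5)
  expect_equal(a1$asymmetry, 1, tolerance = 0.02)
  # densities 1 vs 3 give |1 - 3| / 4 = 0.5
  prof <- ifelse(x < 1.5, 1, 3)
  expect_equal(asymmetry_measure(x, prof, 1.5)$asymmetry, 0.5,
               tolerance = 0.02)
  # invariance under intensity scaling
  a <- asymmetry_measure(x, prof, 1.1)$asymmetry
  b <- asymmetry_measure(x, 7.3 * prof, 1.1)$asymmetry
  expect_equal(a, b, tolerance = 1e-12)
  expect_error(asymmetry_measure(x, unif, 0), "strictly between")
})

test_that("asymmetry lies in [0, 1] for arbitrary nonnegative profiles", {
  set.seed(12)
  x <- seq(0, 2, by = 0.02)
  for (i in 1:25) {
    prof <- abs(rnorm(length(x)))^sample(1:3, 1)
    f <- runif(1, 0.1, 1.9)
    a <- asymmetry_measure(x, prof, f)$asymmetry
    expect_true(a >= 0 && a <= 1)
  }
})

test_that("oscillator reference asymmetry has the |sin| statistics", {
  expect_equal(mind_reference(amplitude = 0, n_samples = 100, seed = 1),
               rep(0, 100))
  s <- mind_reference(amplitude = 0.6, n_samples = 5e4, seed = 2)
  expect_equal(max(s), 0.6, tolerance = 1e-3)
  expect_equal(mean(s), 0.6 * 2 / pi, tolerance = 0.01)
  expect_true(all(s >= 0 & s <= 0.6))
})

test_that("focus-plane selection maximizes the summed per-plane maxima", {
  x <- seq(0, 2, by = 0.05)
  mk <- function(weights) {
    I <- outer(sin(pi * x / 2)^2, weights)
    intensity_stack(I, x, dz = 0.1)
  }
  # unimodal profile: window centered at the peak
  w <- dnorm(1:21, mean = 11, sd = 3)
  expect_equal(select_focus_planes(mk(w), 9), 7:15)
  # constant: tie resolves to the first window
  expect_equal(select_focus_planes(mk(rep(1, 15)), 9), 1:9)
  # known in-focus band recovered exactly
  w2 <- c(rep(0.1, 5), rep(1, 9), rep(0.1, 7))
  expect_equal(select_focus_planes(mk(w2), 9), 6:14)
  expect_error(select_focus_planes(mk(rep(1, 5)), 9), "fewer")
})

test_that("first-harmonic score is zero for half-sines and positive otherwise", {
  x <- seq(0.005, 2, by = 0.01)
  half_sine <- function(z_amp) {
    I <- outer(pmax(0, sin(pi * x / 2)), z_amp)
    intensity_stack(I, x, dz = 0.1)
  }
  # the half-maximum anchoring leaves a small intrinsic edge residual, so
  # "zero" means well below the plateau/helical scores
  hs <- first_harmonic_score(half_sine(c(1, 0.8, 0.6)))
  expect_lt(hs$SE_cell, 0.05)

  # uniform plateau between edges: closed-form residual integral
  # mean of (1 - sin(pi u))^2 over u in (0,1) = 1.5 - 4 / pi
  I_u <- matrix(rep(as.numeric(x >= 0.5 & x <= 1.5), 2), ncol = 2)
  hu <- first_harmonic_score(intensity_stack(I_u, x, dz = 0.1))
  expect_equal(hu$SE_cell, 1.5 - 4 / pi, tolerance = 0.03)
  expect_gt(hu$SE_cell, 0)
})

test_that("helical modulation scores worse than a flat nucleoid", {
  flat <- generate_cell_stack(synth_cell_spec(helical_amplitude = 0,
                                              seed = 4))
  hel <- generate_cell_stack(synth_cell_spec(helical_amplitude = 0.5,
                                             helical_period = 0.4, seed = 4))
  sf <- first_harmonic_score(flat$channel_a)
  sh <- first_harmonic_score(hel$channel_a)
  expect_gt(sh$SE_cell, sf$SE_cell)
})

test_that("colocalization: Pearson and Manders identities", {
  st <- generate_cell_stack(synth_cell_spec(seed = 5))
  same <- colocalize(st$channel_a, st$channel_a)
  expect_equal(same$r_P, 1)
  expect_equal(same$manders$M_A, same$manders$M_B)
  expect_equal(same$manders$M_A[same$manders$threshold == 0], 1)

  # Manders curves are non-increasing in the threshold
  two <- generate_cell_stack(synth_cell_spec(nested_fraction = 0.6,
                                             b_from_a = 0, seed = 6))
  cc <- colocalize(two$channel_a, two$channel_b)
  expect_true(all(diff(cc$manders$M_A) <= 1e-12))
  expect_true(all(diff(cc$manders$M_B) <= 1e-12))
  expect_equal(cc$manders$M_A[1], 1); expect_equal(cc$manders$M_B[1], 1)

  # spatially disjoint channels: overlap collapses above background
  x <- seq(0, 2, by = 0.02)
  a <- intensity_stack(matrix(as.numeric(x < 0.9), ncol = 1), x)
  b <- intensity_stack(matrix(as.numeric(x > 1.1), ncol = 1), x)
  cd <- colocalize(a, b, thresholds = c(0, 0.5))
  expect_equal(cd$manders$M_A[2], 0)
  expect_equal(cd$manders$M_B[2], 0)

  # zero-variance channel: undefined correlation, flagged
  z <- intensity_stack(matrix(1, length(x), 1), x)
  expect_warning(cz <- colocalize(z, a, thresholds = 0), "zero-variance")
  expect_true(is.na(cz$r_P))
})

test_that("a channel nested within the nucleoid overlaps more than the reverse", {
  st <- generate_cell_stack(synth_cell_spec(nested_fraction = 0.6,
                                            b_from_a = 0, seed = 7))
  cc <- colocalize(st$channel_a, st$channel_b,
                   thresholds = seq(0.05, 0.6, by = 0.05))
  # channel B (nested, ParA-like) lies where A (nucleoid) is bright, so
  # M_B > M_A at every positive threshold
  expect_true(all(cc$manders$M_B > cc$manders$M_A))
})
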