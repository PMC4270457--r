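# Directed-motion polymer model: named variants, decoupled limits,
# conservation, polymer statistics, positioning and asymmetry.

test_that("variant parameter sets match the standard values", {
  s <- dm_variant_params("short")
  expect_equal(s$k_p, 800); expect_equal(s$k_dp, 10)
  expect_equal(s$S, 0.030); expect_true(s$wall)
  expect_equal(s$k_mB, 40); expect_equal(s$k_B, 68.5)
  expect_equal(s$k_dm, 0.8); expect_equal(s$D_P, 3e-4)
  expect_equal(s$D_A, 1); expect_equal(s$k_W, 1 / 15)

  l <- dm_variant_params("long")
  expect_equal(l$k_p, 1e6); expect_equal(l$k_dp, 1e-4)
  expect_equal(l$S, 0.025); expect_true(l$wall)

  ps <- dm_variant_params("perturbed_short")
  expect_equal(ps$k_mB, 4); expect_false(ps$wall)
  expect_equal(ps$leak_fraction, 0.1); expect_equal(ps$S, 0.030)

  pl <- dm_variant_params("perturbed_long")
  expect_equal(pl$k_mB, 4); expect_false(pl$wall)
  expect_equal(pl$leak_fraction, 1); expect_equal(pl$S, 0.010)
  expect_equal(pl$k_p, 1e6)

  expect_error(dm_variant_params("bogus"))
})

test_that("with polymerization off, a plasmid performs free diffusion", {
  p <- dm_params(k_p = 0, k_on = 0, k_W = 0, density_per_um = NA)
  runs <- lapply(1:6, function(s) {
    simulate_dm(p, L = 3, plasmid_positions = 1.5, T = 600,
                events = scheduled_events(output_interval = 2),
                seed = 300 + s, coarse = 6,
                init = lattice_state(n_long = 100, n_short = 1, dx = 0.03,
                                     plasmid_site = 50L, plasmid_bound = 0L))
  })
  rows <- do.call(rbind, lapply(seq_along(runs), function(i) {
    d <- runs[[i]]$trajectory
    data.frame(cell = i, focus = 1L, t_s = d$t, x_um = d$pos_um, y_um = 0)
  }))
  msd <- compute_msd(trajectory_set(rows), max_lag = 60)
  for (k in which(msd$tau %in% c(10, 20, 40))) {
    expect_lt(abs(msd$msd[k] - 2 * 3e-4 * msd$tau[k]), 3 * msd$sem[k] + 1e-9)
  }
})

test_that("ParA mass is conserved across all polymer-model reactions", {
  r <- simulate_dm(dm_variant_params("short"), L = 1.5, n_p = 2, T = 60,
                   events = scheduled_events(output_interval = 5,
                                             duplication_times = 30),
                   seed = 4, coarse = 10)
  expect_equal(length(unique(r$pools$total_parA)), 1L)
  # and with growth the density target is restored after every extension
  gi <- growth_interval_for(1.5, 2.0, 60, 0.05)
  p <- dm_variant_params("short"); p$density_per_um <- 300
  rg <- simulate_dm(p, L = 1.5, n_p = 1, T = 60,
                    events = scheduled_events(growth_interval = gi,
                                              output_interval = 5),
                    seed = 5, coarse = 10)
  dens_t <- rg$pools$total_parA / (rg$pools$n_long * rg$dx)
  expect_true(all(abs(dens_t - 300) / 300 < 0.05))
})

test_that("plasmid-bearing steady state forms short polymers (~10 subunits)", {
  p <- dm_variant_params("short"); p$density_per_um <- 300
  lens <- unlist(lapply(1:4, function(s) {
    r <- simulate_dm(p, L = 1.5, n_p = 1, T = 400,
                     events = scheduled_events(output_interval = 5),
                     seed = 40 + s, coarse = 6)
    r$polymer_length$mean_length[r$polymer_length$t >= 100]
  }))
  m <- mean(lens, na.rm = TRUE)
  expect_gt(m, 5); expect_lt(m, 15)
})

test_that("a plasmid started at the nucleoid edge is repositioned to mid-nucleoid", {
  p <- dm_variant_params("short"); p$density_per_um <- 300
  pos <- unlist(lapply(1:6, function(s) {
    r <- simulate_dm(p, L = 1.5, plasmid_positions = 0.1, T = 500,
                     events = scheduled_events(output_interval = 5),
                     seed = s, coarse = 6)
    r$trajectory$pos_um[r$trajectory$t >= 150]
  }))
  h <- hist(pos / 1.5, breaks = seq(0, 1, by = 0.2), plot = FALSE)
  expect_equal(which.max(h$counts), 3L)            # mode in the central fifth
  expect_lt(mean(abs(pos - 0.75)), 0.3)            # tighter than uniform (0.375)
})

test_that("two plasmids settle near the quarter positions", {
  p <- dm_variant_params("short"); p$density_per_um <- 300
  rel <- do.call(rbind, lapply(1:6, function(s) {
    r <- simulate_dm(p, L = 2, n_p = 2, T = 600,
                     events = scheduled_events(output_interval = 5),
                     seed = 50 + s, coarse = 6)
    position_distribution(r, burn_in = 200)$samples
  }))
  m1 <- mean(rel$rel_pos[rel$label == 1])
  m2 <- mean(rel$rel_pos[rel$label == 2])
  expect_lt(abs(m1 - 0.25), 0.10)
  expect_lt(abs(m2 - 0.75), 0.10)
})

test_that("perturbed-nucleoid variants broaden the position distribution", {
  wt <- dm_variant_params("short"); wt$density_per_um <- 300
  pe <- dm_variant_params("perturbed_short"); pe$density_per_um <- 300
  spread <- function(params, seeds) {
    pos <- unlist(lapply(seeds, function(s) {
      r <- simulate_dm(params, L = 1.5, plasmid_positions = 0.75, T = 400,
                       events = scheduled_events(output_interval = 5),
                       seed = s, coarse = 6)
      r$trajectory$pos_um[r$trajectory$t >= 100]
    }))
    var(pos / 1.5)
  }
  expect_gt(spread(pe, 61:66), spread(wt, 61:66))
})

test_that("model asymmetry series matches its closed-form extremes", {
  # synthetic run objects: one plasmid at mid of a 10-site nucleoid
  mk_run <- function(mobile_left, mobile_right, cyto) {
    ns <- 11L
    kg <- data.frame(t = 0, site = 1:ns, mobile = 0L, polymer = 0L)
    kg$mobile[2] <- mobile_left; kg$mobile[10] <- mobile_right
    list(trajectory = data.frame(t = 0, plasmid = 1L, site = 6L,
                                 pos_um = 5.5 * 0.1, bound = NA),
         pools = data.frame(t = 0, A_ADP = cyto, A_CYTO = 0,
                            total_parA = cyto + mobile_left + mobile_right,
                            n_long = ns),
         kymograph = kg, dx = 0.1)
  }
  # all nucleoid ParA on one side, no cytoplasmic: asymmetry 1
  expect_equal(model_asymmetry_series(mk_run(100, 0, 0))$asymmetry, 1)
  # symmetric state: asymmetry 0
  expect_equal(model_asymmetry_series(mk_run(50, 50, 200))$asymmetry, 0)
  # cytoplasmic ParA only raises the denominator
  a1 <- model_asymmetry_series(mk_run(100, 0, 0))$asymmetry
  a2 <- model_asymmetry_series(mk_run(100, 0, 400))$asymmetry
  expect_lt(a2, a1)
})

test_that("wild-type ParA asymmetry stays below the pole-to-pole oscillator reference", {
  p <- dm_variant_params("short"); p$density_per_um <- 300
  asym <- unlist(lapply(1:4, function(s) {
    r <- simulate_dm(p, L = 1.5, plasmid_positions = 0.75, T = 120,
                     events = scheduled_events(output_interval = 5),
                     seed = 70 + s, coarse = 6, record_kymo = TRUE)
    model_asymmetry_series(r)$asymmetry
  }))
  mind <- mind_reference(amplitude = 0.6, n_samples = 1000, seed = 1)
  expect_lt(median(asym), median(mind))
})
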