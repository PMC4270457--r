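# Direct-method SSA kernel and the shared lattice events.

birth_death_reactions <- function(b, d) {
  list(
    list(propensity = function(s) b,
         fire = function(s) { s$n <- s$n + 1L; s }),
    list(propensity = function(s) d * s$n,
         fire = function(s) { s$n <- s$n - 1L; s }))
}

test_that("birth-death long-run mean matches the Poisson stationary law", {
  b <- 50; d <- 1 / 15                     # stationary mean 750
  res <- run_ssa(list(t = 0, n = 750L), birth_death_reactions(b, d),
                 scheduled_events(output_interval = 1), T = 1200, seed = 3)
  counts <- vapply(res$snapshots, function(s) s$n, numeric(1))
  expect_gt(res$n_events, 1e5)
  # autocorrelation time is 1/d = 15 s; use it for the effective sample size
  n_eff <- length(counts) / 15
  se <- sd(counts) / sqrt(n_eff)
  expect_lt(abs(mean(counts) - b / d), 3 * se + 1e-9)
})

test_that("SSA waiting times are exponential: unit-interval event counts are Poisson", {
  b <- 20                                  # pure birth = Poisson process
  res <- run_ssa(list(t = 0, n = 0L), birth_death_reactions(b, 0),
                 scheduled_events(output_interval = 1), T = 400, seed = 5)
  counts <- diff(vapply(res$snapshots, function(s) s$n, numeric(1)))
  # chi-square GOF against Poisson(b), pooling tails
  br <- c(-Inf, seq(b - 10, b + 10, by = 4), Inf)
  obs <- table(cut(counts, br))
  pr <- diff(ppois(c(-1, seq(b - 10, b + 10, by = 4), Inf), b))
  expect_gt(suppressWarnings(chisq.test(obs, p = pr)$p.value), 1e-3)
})

test_that("zero total propensity leaves the state unchanged until the horizon", {
  res <- run_ssa(list(t = 0, n = 5L),
                 list(list(propensity = function(s) 0,
                           fire = function(s) stop("must not fire"))),
                 scheduled_events(output_interval = 10), T = 25, seed = 1)
  expect_equal(res$state$n, 5L)
  expect_equal(res$state$t, 25)
  expect_equal(res$n_events, 0L)
})

test_that("identical seeds give identical event sequences", {
  r1 <- run_ssa(list(t = 0, n = 100L), birth_death_reactions(5, 0.05),
                scheduled_events(output_interval = 2), T = 50, seed = 11)
  r2 <- run_ssa(list(t = 0, n = 100L), birth_death_reactions(5, 0.05),
                scheduled_events(output_interval = 2), T = 50, seed = 11)
  expect_identical(vapply(r1$snapshots, `[[`, numeric(1), "n"),
                   vapply(r2$snapshots, `[[`, numeric(1), "n"))
  r3 <- run_ssa(list(t = 0, n = 100L), birth_death_reactions(5, 0.05),
                scheduled_events(output_interval = 2), T = 50, seed = 12)
  expect_false(identical(vapply(r1$snapshots, `[[`, numeric(1), "n"),
                         vapply(r3$snapshots, `[[`, numeric(1), "n")))
})

test_that("negative propensities abort with the channel identity", {
  expect_error(
    run_ssa(list(t = 0, n = 0L),
            list(list(propensity = function(s) -1,
                      fire = function(s) s)),
            scheduled_events(), T = 1, seed = 1),
    "negative propensity")
})

test_that("nucleoid growth inserts two empty columns and shifts indices", {
  st <- lattice_state(n_long = 300, dx = 0.005,
                      mobile = matrix(5L, 300, 1),
                      plasmid_site = 100L, plasmid_bound = 3L,
                      A_ADP = 100L)
  set.seed(21)
  grown <- grow_nucleoid(st, density_per_um = NA)
  expect_equal(grown$n_long, 302L)
  expect_equal(sum(grown$mobile), sum(st$mobile))   # new sites empty
  expect_equal(sum(grown$mobile == 0L), 2L)

  # deterministic insertion point: force insertion left of the plasmid
  st2 <- st
  repeat {
    g <- grow_nucleoid(st2, density_per_um = NA)
    pos <- which(g$mobile[, 1] == 0L)[1]
    if (pos <= 100) { expect_equal(g$plasmid_site, 102L); break }
  }
})

test_that("growth replenishes ParA-ADP to the target density", {
  dens <- 2400
  n0 <- 300
  total0 <- round(dens * n0 * 0.005)
  st <- lattice_state(n_long = n0, dx = 0.005, A_ADP = total0)
  set.seed(4)
  for (i in 1:5) st <- grow_nucleoid(st, density_per_um = dens)
  expect_equal(total_parA(st) / (st$n_long * st$dx), dens, tolerance = 1e-3)
})

test_that("plasmid duplication copies the site, zeroes the new bound count, picks uniformly", {
  st <- lattice_state(n_long = 50, plasmid_site = c(10L, 20L, 30L),
                      plasmid_bound = c(7L, 2L, 9L))
  set.seed(9)
  d1 <- duplicate_plasmid(st)
  expect_equal(length(d1$plasmid_site), 4L)
  expect_equal(d1$plasmid_bound[4], 0L)
  expect_equal(d1$plasmid_bound[1:3], st$plasmid_bound)   # originals intact
  expect_true(d1$plasmid_site[4] %in% st$plasmid_site)
  picks <- integer(3)
  ok <- TRUE
  for (i in 1:3000) {
    d <- duplicate_plasmid(st)
    ok <- ok && d$plasmid_bound[4] == 0L && length(d$plasmid_site) == 4L
    k <- match(d$plasmid_site[4], st$plasmid_site)
    picks[k] <- picks[k] + 1L
  }
  expect_true(ok)
  expect_gt(chisq.test(picks)$p.value, 1e-3)
  expect_error(duplicate_plasmid(lattice_state(10)), "no plasmid")
})
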