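# Diffusion/immobilization model: plasmids diffuse freely over the nucleoid
# and are anchored wherever enough nucleoid-bound ParA-ATP binds them (via the
# ParB-parC complex), which in turn is hydrolyzed at the plasmid. All lattice
# kinetics run through the exact-SSA kernel.

#' Parameters of the diffusion/immobilization model
#'
#' Defaults are the model's standard parameter set: diffusion constants in
#' um^2/s, first-order rates in s^-1.
#'
#' @param D_A Nucleoid-bound ParA-ATP diffusion constant (default 1e-2).
#' @param D_P Free plasmid diffusion constant (default 1e-1).
#' @param k_on Cytoplasmic ParA-ATP nucleoid-binding rate (default 50).
#' @param k_AB ParA-ATP to plasmid binding rate (default 100).
#' @param k_B Plasmid-bound ParA-ATP hydrolysis rate (default 68.5).
#' @param k_W Cytoplasmic ParA-ADP to ParA-ATP maturation rate (default 1/15).
#' @param k_off Spontaneous nucleoid-bound hydrolysis (default 0; a small
#'   value does not alter the behaviour of the system).
#' @param max_bound Maximum ParA-ATP bound per plasmid (default 35).
#' @param immobilize_threshold Bound count at which plasmid diffusion stops
#'   (default 2: more than one bound ParA-ATP immobilizes the plasmid).
#' @param dx Lattice site size (um, default 0.005 = 5 nm).
#' @param density_per_um Total ParA (dimers) per um of nucleoid (default
#'   2400); `NA` fixes the absolute count at initialization instead.
#' @return An object of class `"di_params"`.
#' @export
di_params <- function(D_A = 1e-2, D_P = 1e-1, k_on = 50, k_AB = 100,
                      k_B = 68.5, k_W = 1 / 15, k_off = 0,
                      max_bound = 35L, immobilize_threshold = 2L,
                      dx = 0.005, density_per_um = 2400) {
  stopifnot(D_A > 0, D_P >= 0, k_on >= 0, k_AB >= 0, k_B >= 0, k_W >= 0,
            k_off >= 0, max_bound >= immobilize_threshold, dx > 0)
  structure(list(D_A = D_A, D_P = D_P, k_on = k_on, k_AB = k_AB, k_B = k_B,
                 k_W = k_W, k_off = k_off, max_bound = as.integer(max_bound),
                 immobilize_threshold = as.integer(immobilize_threshold),
                 dx = dx, density_per_um = density_per_um),
            class = "di_params")
}

#' Growth interval realizing a target nucleoid elongation
#'
#' Each growth event adds two sites of size `dx`; this returns the regular
#' interval between events such that the nucleoid grows from `L0` to `L1`
#' um over `T` seconds.
#'
#' @param L0,L1 Initial and final nucleoid lengths (um).
#' @param T Total simulated time (s).
#' @param dx Site size (um).
#' @return Interval between growth events (s).
#' @export
growth_interval_for <- function(L0, L1, T, dx) {
  stopifnot(L1 > L0, T > 0, dx > 0)
  n_events <- (L1 - L0) / (2 * dx)
  T / n_events
}

# Shared initial condition: a quarter of the total ParA starts as cytoplasmic
# ParA-ADP, `bound_per_plasmid` ParA-ATP are pre-bound per plasmid (anchoring),
# and the remainder is placed uniformly at random on the nucleoid.
di_initial_state <- function(n_long, dx, density_per_um, plasmid_site,
                             bound_per_plasmid = 11L) {
  total <- round(density_per_um * n_long * dx)
  adp <- round(total / 4)
  np <- length(plasmid_site)
  bound <- rep(min(bound_per_plasmid, 35L), np)
  on_nucleoid <- max(0, total - adp - sum(bound))
  counts <- tabulate(sample.int(n_long, on_nucleoid, replace = TRUE), n_long)
  list(mobile = as.integer(counts), plasmid_bound = as.integer(bound),
       A_ADP = adp, A_CYTO = 0)
}

# Resolve user plasmid placement to 1-based lattice sites.
resolve_plasmid_sites <- function(positions, n_long, dx) {
  if (is.character(positions) && identical(positions, "random")) {
    stop("pass explicit positions; draw random ones in the caller")
  }
  site <- pmin(pmax(floor(positions / dx) + 1L, 1L), n_long)
  as.integer(site)
}

#' Simulate the diffusion/immobilization model
#'
#' Exact stochastic simulation of the 1d lattice model: nucleoid-bound
#' ParA-ATP hops at `D_A/dx^2` per direction, free plasmids hop at
#' `D_P/dx^2` while fewer than `immobilize_threshold` ParA-ATP are bound,
#' same-site binding at `k_AB`, bound hydrolysis at `k_B` per molecule (to
#' cytoplasmic ParA-ADP), maturation at `k_W`, and nucleoid binding of
#' cytoplasmic ParA-ATP at `k_on` to a uniformly random site. Reflecting
#' boundaries at both nucleoid ends.
#'
#' @param params A [di_params()] object.
#' @param L Initial nucleoid length (um).
#' @param plasmid_positions Numeric plasmid positions (um); `NULL` places
#'   `n_p` plasmids uniformly at random.
#' @param n_p Number of randomly placed plasmids when `plasmid_positions`
#'   is `NULL`.
#' @param T Simulated time horizon (s).
#' @param events A [scheduled_events()] object (growth, duplications, output
#'   sampling).
#' @param seed Integer RNG seed.
#' @param coarse Integer lattice coarsening factor: site size becomes
#'   `coarse * dx` with hop rates rescaled through `D/dx^2` and densities
#'   preserved per um. `coarse = 1` is the full-resolution model.
#' @param record_kymo Record a space-time table of ParA counts.
#' @param init Optional [lattice_state()] overriding the standard initial
#'   condition.
#' @return A list with elements `trajectory` (data frame: t, plasmid, site,
#'   pos_um, bound), `pools` (cytoplasmic counts and total ParA per sample),
#'   `kymograph` (if requested), `n_events`, `n_long`, `dx` and `params`.
#' @export
simulate_di <- function(params = di_params(), L = 1.5,
                        plasmid_positions = NULL, n_p = 1L, T = 600,
                        events = scheduled_events(), seed = 1L,
                        coarse = 1L, record_kymo = FALSE, init = NULL) {
  stopifnot(inherits(params, "di_params"), L > 0, T >= 0, coarse >= 1)
  dx <- params$dx * as.integer(coarse)
  n_long <- max(2L, round(L / dx))
  set.seed(seed)
  if (is.null(plasmid_positions)) {
    sites <- sample.int(n_long, n_p, replace = TRUE)
  } else {
    sites <- resolve_plasmid_sites(as.numeric(plasmid_positions), n_long, dx)
  }
  if (is.null(init)) {
    st <- di_initial_state(n_long, dx, params$density_per_um, sites)
  } else {
    stopifnot(inherits(init, "lattice_state"), init$n_long == n_long)
    st <- list(mobile = as.integer(init$mobile[, 1]),
               plasmid_bound = init$plasmid_bound,
               A_ADP = init$A_ADP, A_CYTO = init$A_CYTO)
    sites <- init$plasmid_site
  }
  dens <- params$density_per_um
  res <- cpp_simulate_di(
    n_long, dx, st$mobile, sites, st$plasmid_bound, st$A_ADP, st$A_CYTO,
    params$D_A, params$D_P, params$k_on, params$k_AB, params$k_B,
    params$k_W, params$k_off, params$max_bound, params$immobilize_threshold,
    if (is.na(dens)) -1 else dens,
    T, events$growth_interval, events$duplication_times,
    events$output_interval, record_kymo)
  res$trajectory$bound <- as.integer(res$trajectory$bound)
  res$dx <- dx
  res$params <- params
  res
}

#' Plasmid duplication assay
#'
#' Simulates repeated plasmid duplication events in the
#' diffusion/immobilization model and measures how far the daughter plasmids
#' separate. Each replicate relaxes a single plasmid (started mid-nucleoid)
#' on a fixed-length nucleoid, duplicates it, and then records the maximal
#' additional inter-plasmid separation reached within the observation
#' window. The headline statistic is the fraction of replicates separating
#' by at least `sep_threshold` um.
#'
#' @param params A [di_params()] object.
#' @param D_P_override If non-`NULL`, replaces `params$D_P` (the assay's
#'   central question is how the separating fraction depends on free plasmid
#'   mobility).
#' @param n_events Number of duplication replicates (>= 1).
#' @param seed Integer RNG seed; replicate r uses `seed + r`.
#' @param L Nucleoid length (um), fixed during the assay (default 3).
#' @param relax_T Pre-duplication relaxation time (s).
#' @param window Observation window after duplication (s, default 20).
#' @param sep_threshold Separation threshold (um, default 0.8).
#' @param coarse Lattice coarsening factor (see [simulate_di()]).
#' @param sample_dt Sampling period for the separation trace (s).
#' @return A list with `max_separation` (per replicate, um), `fraction`
#'   (fraction reaching `sep_threshold`) and the assay settings.
#' @export
duplication_assay <- function(params = di_params(), D_P_override = NULL,
                              n_events = 300L, seed = 1L, L = 3,
                              relax_T = 60, window = 20,
                              sep_threshold = 0.8, coarse = 1L,
                              sample_dt = 0.5) {
  stopifnot(n_events >= 1)
  if (!is.null(D_P_override)) {
    stopifnot(D_P_override >= 0)
    params$D_P <- D_P_override
  }
  max_sep <- numeric(n_events)
  for (r in seq_len(n_events)) {
    run <- simulate_di(
      params, L = L, plasmid_positions = L / 2,
      T = relax_T + window,
      events = scheduled_events(duplication_times = relax_T,
                                output_interval = sample_dt),
      seed = seed + r, coarse = coarse)
    tr <- run$trajectory
    post <- tr[tr$t >= relax_T, ]
    sep_by_t <- tapply(post$pos_um, post$t, function(p) {
      if (length(p) < 2) 0 else max(p) - min(p)
    })
    # additional separation relative to the duplication instant (same site,
    # separation zero)
    max_sep[r] <- max(sep_by_t)
  }
  list(max_separation = max_sep,
       fraction = mean(max_sep >= sep_threshold),
       n_events = n_events, D_P = params$D_P, L = L, window = window,
       sep_threshold = sep_threshold, relax_T = relax_T, coarse = coarse)
}
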