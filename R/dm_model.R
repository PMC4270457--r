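# Directed-motion polymer model: nucleoid-bound mobile ParA-ATP nucleates and
# elongates immobile polymers along the long axis of a thin 2d strip lattice;
# ParB/parC-stimulated disassembly of polymeric subunits adjacent to a plasmid
# steps the plasmid onto the retracting structure (burnt-bridge-like directed
# motion). Competition between the structures on either side of a plasmid
# yields equal spacing.

#' Parameters of the directed-motion polymer model
#'
#' Defaults are the short-polymer wild-type parameter set; use
#' [dm_variant_params()] for the named variants.
#'
#' @param D_A Mobile nucleoid-bound ParA-ATP diffusion constant (um^2/s,
#'   default 1).
#' @param D_P Plasmid diffusion constant (um^2/s, default 3e-4).
#' @param k_on Cytoplasmic ParA-ATP nucleoid-binding rate (s^-1, default 50).
#' @param k_B Hydrolysis of polymeric ParA-ATP in a plasmid column (s^-1,
#'   default 68.5).
#' @param k_mB Hydrolysis of mobile ParA-ATP in a plasmid column (s^-1,
#'   default 40; 4 in the perturbed-nucleoid variants).
#' @param k_W ParA-ADP to ParA-ATP maturation rate (s^-1, default 1/15).
#' @param k_dm Directed-motion rate per adjacent polymeric subunit (s^-1,
#'   default 0.8).
#' @param k_p Polymerization (nucleation and tip elongation) rate (s^-1,
#'   default 800 for short polymers; 1e6 for long).
#' @param k_dp Spontaneous depolymerization rate per subunit (s^-1, default
#'   10 for short polymers; 1e-4 for long).
#' @param S Short-axis width of the polymerization-competent nucleoid region
#'   (um; 0.030 short, 0.025 long, 0.010 perturbed-long).
#' @param wall Hard-wall flag: in the wild type a plasmid column blocks
#'   mobile ParA-ATP from diffusing past.
#' @param leak_fraction With `wall = FALSE`, the fraction of the normal hop
#'   rate at which mobile ParA-ATP crosses a plasmid column (0.1 perturbed
#'   short, 1.0 perturbed long).
#' @param dx Lattice site size (um, default 0.005).
#' @param density_per_um Total ParA (dimers) per um of nucleoid long axis
#'   (default 2400); `NA` fixes the absolute count.
#' @return An object of class `"dm_params"`.
#' @export
dm_params <- function(D_A = 1, D_P = 3e-4, k_on = 50, k_B = 68.5, k_mB = 40,
                      k_W = 1 / 15, k_dm = 0.8, k_p = 800, k_dp = 10,
                      S = 0.030, wall = TRUE, leak_fraction = 0.1,
                      dx = 0.005, density_per_um = 2400) {
  stopifnot(D_A > 0, D_P >= 0, k_on >= 0, k_B >= 0, k_mB >= 0, k_W >= 0,
            k_dm >= 0, k_p >= 0, k_dp >= 0, S > 0, dx > 0,
            leak_fraction >= 0, leak_fraction <= 1)
  structure(list(D_A = D_A, D_P = D_P, k_on = k_on, k_B = k_B, k_mB = k_mB,
                 k_W = k_W, k_dm = k_dm, k_p = k_p, k_dp = k_dp, S = S,
                 wall = wall, leak_fraction = leak_fraction, dx = dx,
                 density_per_um = density_per_um),
            class = "dm_params")
}

#' Named parameter variants of the directed-motion model
#'
#' @param variant One of `"short"`, `"long"`, `"perturbed_short"`,
#'   `"perturbed_long"`. The short/long variants differ in polymerization
#'   balance (`k_p`, `k_dp`) and strip width `S`; the perturbed-nucleoid
#'   variants switch the plasmid hard wall off (mobile ParA-ATP diffuses
#'   past a plasmid at 10% / 100% of the normal rate) and reduce `k_mB`
#'   ten-fold to 4 s^-1.
#' @return A [dm_params()] object.
#' @export
dm_variant_params <- function(variant = c("short", "long", "perturbed_short",
                                          "perturbed_long")) {
  variant <- match.arg(variant)
  switch(variant,
    short = dm_params(),
    long = dm_params(k_p = 1e6, k_dp = 1e-4, S = 0.025),
    perturbed_short = dm_params(k_mB = 4, wall = FALSE, leak_fraction = 0.1),
    perturbed_long = dm_params(k_p = 1e6, k_dp = 1e-4, S = 0.010, k_mB = 4,
                               wall = FALSE, leak_fraction = 1))
}

#' Simulate the directed-motion polymer model
#'
#' Exact stochastic simulation on the thin 2d strip: mobile ParA-ATP hops to
#' its four neighbours at `D_A/dx^2`; two mobile molecules on long-axis
#' adjacent sites of the same row nucleate an immobile two-subunit polymer at
#' `k_p`; a mobile molecule immediately beyond a polymer tip (same row) joins
#' at `k_p`; subunits depolymerize to mobile at `k_dp`. A plasmid occupies
#' one long-axis column across the full width, diffuses at `D_P/dx^2` only
#' when no polymeric subunit is in its own or either adjacent column, and is
#' stepped onto an adjacent column at `k_dm` per polymeric subunit there
#' (consuming that subunit to cytoplasmic ParA-ADP). Polymeric / mobile
#' ParA-ATP in a plasmid column is hydrolyzed at `k_B` / `k_mB`. In the wild
#' type, plasmid columns are hard walls to mobile diffusion.
#'
#' @inheritParams simulate_di
#' @param params A [dm_params()] object.
#' @return As [simulate_di()], plus a `polymer_length` data frame (mean
#'   polymer length per sample); the `bound` trajectory column is `NA` (this
#'   model has no plasmid-bound pool). The kymograph collapses the short
#'   axis by summation.
#' @export
simulate_dm <- function(params = dm_params(), L = 1.5,
                        plasmid_positions = NULL, n_p = 1L, T = 600,
                        events = scheduled_events(), seed = 1L,
                        coarse = 1L, record_kymo = FALSE, init = NULL) {
  stopifnot(inherits(params, "dm_params"), L > 0, T >= 0, coarse >= 1)
  dx <- params$dx * as.integer(coarse)
  n_long <- max(4L, round(L / dx))
  n_short <- max(1L, round(params$S / dx))
  set.seed(seed)
  if (is.null(plasmid_positions)) {
    sites <- sample.int(n_long, n_p, replace = TRUE)
  } else {
    sites <- resolve_plasmid_sites(as.numeric(plasmid_positions), n_long, dx)
  }
  if (is.null(init)) {
    if (is.na(params$density_per_um)) {
      stop("density_per_um = NA (fixed-count mode) requires an explicit `init`")
    }
    total <- round(params$density_per_um * n_long * dx)
    adp <- round(total / 4)
    on_nucleoid <- total - adp
    counts <- tabulate(sample.int(n_long * n_short, on_nucleoid,
                                  replace = TRUE), n_long * n_short)
    mobile <- as.integer(counts)
    polymer <- integer(n_long * n_short)
    A_ADP <- adp; A_CYTO <- 0
  } else {
    stopifnot(inherits(init, "lattice_state"), init$n_long == n_long,
              init$n_short == n_short)
    # lattice_state matrices are n_long x n_short; kernel wants column-major
    # blocks of the short axis per long-axis column
    mobile <- as.integer(t(init$mobile))
    polymer <- as.integer(t(init$polymer))
    sites <- init$plasmid_site
    A_ADP <- init$A_ADP; A_CYTO <- init$A_CYTO
  }
  dens <- params$density_per_um
  res <- cpp_simulate_dm(
    n_long, n_short, dx, mobile, polymer, sites, A_ADP, A_CYTO,
    params$D_A, params$D_P, params$k_on, params$k_B, params$k_mB,
    params$k_W, params$k_dm, params$k_p, params$k_dp,
    params$wall, params$leak_fraction,
    if (is.na(dens)) -1 else dens,
    T, events$growth_interval, events$duplication_times,
    events$output_interval, record_kymo)
  res$dx <- dx
  res$n_short <- n_short
  res$params <- params
  res
}

#' ParA asymmetry series from a single-plasmid simulation run
#'
#' For every sampled time point, computes per-side ParA densities about the
#' plasmid: nucleoid-bound ParA (mobile + polymeric) strictly left/right of
#' the plasmid column divided by the side length, with cytoplasmic ParA
#' (ADP + ATP pools) spread uniformly so it contributes equally to both
#' densities (raising the denominator only). Returns the normalized
#' asymmetry `|I_L - I_R| / (I_L + I_R)` per sample.
#'
#' @param run A [simulate_dm()] (or [simulate_di()]) result with
#'   `record_kymo = TRUE` and exactly one plasmid.
#' @param t_max Only samples with `t <= t_max` are used (e.g. the
#'   pre-duplication window); default all.
#' @return A data frame with columns `t`, `I_L`, `I_R`, `asymmetry`.
#'   Samples with no ParA at all are dropped with a warning.
#' @export
model_asymmetry_series <- function(run, t_max = Inf) {
  if (is.null(run$kymograph)) {
    stop("run must be produced with record_kymo = TRUE")
  }
  tr <- run$trajectory
  if (max(table(tr$t)) > 1L) stop("asymmetry series requires a single plasmid")
  kg <- run$kymograph
  pools <- run$pools
  times <- unique(tr$t)
  times <- times[times <= t_max]
  out <- lapply(times, function(tt) {
    row <- tr[tr$t == tt, ][1L, ]
    k <- kg[kg$t == tt, ]
    n_long <- max(k$site)
    L <- n_long * run$dx
    xp <- row$pos_um
    nuc <- k$mobile + k$polymer
    left <- sum(nuc[k$site < row$site])
    right <- sum(nuc[k$site > row$site])
    cyto <- pools$A_ADP[match(tt, pools$t)] + pools$A_CYTO[match(tt, pools$t)]
    I_L <- left / xp + cyto / L
    I_R <- right / (L - xp) + cyto / L
    data.frame(t = tt, I_L = I_L, I_R = I_R,
               asymmetry = if (I_L + I_R > 0) {
                 abs(I_L - I_R) / (I_L + I_R)
               } else NA_real_)
  })
  out <- do.call(rbind, out)
  if (anyNA(out$asymmetry)) {
    warning("samples with no ParA dropped from asymmetry series")
    out <- out[!is.na(out$asymmetry), ]
  }
  out
}

#' Time-averaged relative plasmid position distribution
#'
#' Pools sampled plasmid positions (relative to the instantaneous nucleoid
#' length) over one or more runs, with plasmids rank-labeled 1..n_p at every
#' sample, and bins them into a histogram — the standard summary used to
#' show equal spacing.
#'
#' @param runs A single run or list of runs from [simulate_di()] /
#'   [simulate_dm()].
#' @param n_bins Number of relative-position bins (default 40).
#' @param burn_in Discard samples with `t <` this value (s).
#' @return A list with `samples` (data frame: t, label, rel_pos) and
#'   `histogram` (data frame: label, bin midpoint, density).
#' @export
position_distribution <- function(runs, n_bins = 40L, burn_in = 0) {
  if (!is.null(runs$trajectory)) runs <- list(runs)
  samples <- do.call(rbind, lapply(runs, function(run) {
    tr <- run$trajectory[run$trajectory$t >= burn_in, ]
    if (nrow(tr) == 0L) return(NULL)
    # nucleoid length at each sample time (the lattice can grow)
    L_t <- run$pools$n_long[match(tr$t, run$pools$t)] * run$dx
    tr$rel_pos <- tr$pos_um / L_t
    do.call(rbind, lapply(split(tr, tr$t), function(d) {
      d <- d[order(d$rel_pos), ]
      data.frame(t = d$t, label = seq_len(nrow(d)), rel_pos = d$rel_pos)
    }))
  }))
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  hist_tab <- do.call(rbind, lapply(split(samples, samples$label),
    function(d) {
      x <- pmin(pmax(d$rel_pos, 0), 1 - 1e-12)
      cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                      nbins = n_bins)
      data.frame(label = d$label[1L], mid = mids,
                 density = cnt / (sum(cnt) * diff(breaks)[1]))
    }))
  rownames(hist_tab) <- NULL
  list(samples = samples, histogram = hist_tab)
}
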