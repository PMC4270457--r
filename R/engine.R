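# Exact-stochastic (Gillespie direct method) kernel and the shared lattice
# state with timed nucleoid-growth and plasmid-duplication events. The two
# production simulators (di_* and dm_*) run compiled kernels built on the
# same semantics; the R functions here define those semantics and serve the
# generic case (arbitrary reaction sets).

#' Construct a lattice state
#'
#' Shared state container for the lattice simulators: a 1d (or thin 2d) grid
#' of nucleoid sites carrying mobile ParA-ATP counts and (for the polymer
#' model) 0/1 polymeric occupancy, plus plasmids and the two well-mixed
#' cytoplasmic pools.
#'
#' @param n_long Number of long-axis sites.
#' @param n_short Number of short-axis sites (1 for the 1d model).
#' @param dx Site size (um); the standard fine value is 0.005 (5 nm).
#' @param mobile Integer matrix `n_long x n_short` of mobile / nucleoid-bound
#'   ParA-ATP counts (default all zero).
#' @param polymer Integer matrix of 0/1 polymeric occupancy (default zero).
#' @param plasmid_site Integer vector of plasmid long-axis site indices
#'   (1-based).
#' @param plasmid_bound Integer vector of ParA-ATP bound per plasmid.
#' @param A_ADP,A_CYTO Cytoplasmic ParA-ADP and DNA-binding-competent
#'   ParA-ATP counts.
#' @param t Simulated time (s).
#' @return An object of class `"lattice_state"`.
#' @export
lattice_state <- function(n_long, n_short = 1L, dx = 0.005,
                          mobile = NULL, polymer = NULL,
                          plasmid_site = integer(0),
                          plasmid_bound = integer(0),
                          A_ADP = 0L, A_CYTO = 0L, t = 0) {
  n_long <- as.integer(n_long); n_short <- as.integer(n_short)
  stopifnot(n_long >= 1L, n_short >= 1L, dx > 0)
  if (is.null(mobile)) mobile <- matrix(0L, n_long, n_short)
  if (is.null(polymer)) polymer <- matrix(0L, n_long, n_short)
  mobile <- matrix(as.integer(mobile), n_long, n_short)
  polymer <- matrix(as.integer(polymer), n_long, n_short)
  stopifnot(all(mobile >= 0L), all(polymer %in% c(0L, 1L)))
  plasmid_site <- as.integer(plasmid_site)
  plasmid_bound <- as.integer(plasmid_bound)
  if (length(plasmid_bound) == 0L && length(plasmid_site) > 0L) {
    plasmid_bound <- integer(length(plasmid_site))
  }
  stopifnot(length(plasmid_site) == length(plasmid_bound),
            all(plasmid_site >= 1L), all(plasmid_site <= n_long),
            all(plasmid_bound >= 0L), A_ADP >= 0, A_CYTO >= 0)
  structure(list(t = t, dx = dx, n_long = n_long, n_short = n_short,
                 mobile = mobile, polymer = polymer,
                 plasmid_site = plasmid_site, plasmid_bound = plasmid_bound,
                 A_ADP = as.integer(A_ADP), A_CYTO = as.integer(A_CYTO)),
            class = "lattice_state")
}

#' Total ParA in a lattice state
#'
#' Cytoplasmic + nucleoid-bound mobile + polymeric + plasmid-bound. Conserved
#' by every reaction; it changes only at scheduled growth events when new
#' protein is added.
#'
#' @param state A [lattice_state()].
#' @return Integer count.
#' @export
total_parA <- function(state) {
  stopifnot(inherits(state, "lattice_state"))
  state$A_ADP + state$A_CYTO + sum(state$mobile) + sum(state$polymer) +
    sum(state$plasmid_bound)
}

#' Scheduled (non-Markovian) events for a simulation run
#'
#' @param growth_interval Time between lattice-extension events (s); `Inf`
#'   disables growth.
#' @param duplication_times Numeric vector of times at which a plasmid
#'   duplicates (s).
#' @param output_interval State-sampling period (s); the field convention is
#'   5 s.
#' @return A list of class `"scheduled_events"`.
#' @export
scheduled_events <- function(growth_interval = Inf,
                             duplication_times = numeric(0),
                             output_interval = 5) {
  stopifnot(growth_interval > 0, output_interval > 0,
            all(duplication_times > 0))
  structure(list(growth_interval = growth_interval,
                 duplication_times = sort(as.numeric(duplication_times)),
                 output_interval = output_interval),
            class = "scheduled_events")
}

#' Run the direct-method SSA over an arbitrary reaction set
#'
#' Exact stochastic simulation: waiting times are exponential in the total
#' propensity and the firing channel is chosen proportionally to its
#' propensity. Scheduled events (growth, duplication, output sampling) are
#' interleaved at their exact times, which is valid because exponential
#' waiting times are memoryless.
#'
#' @param state Initial state (any R object the reactions understand; the
#'   lattice simulators use a [lattice_state()]).
#' @param reactions A list of channels, each a list with elements
#'   `propensity(state) -> rate` and `fire(state) -> state`.
#' @param events A [scheduled_events()] object.
#' @param T Time horizon (s).
#' @param seed Integer RNG seed; the run is reproducible given the seed.
#' @param time_field Name of the time element inside `state` (default "t").
#' @return A list with `state` (final), `snapshots` (list of states sampled at
#'   every output interval, including t = 0 and t = T) and `n_events` (number
#'   of reaction firings).
#' @export
run_ssa <- function(state, reactions, events = scheduled_events(), T,
                    seed = 1L, time_field = "t") {
  stopifnot(is.list(reactions), T >= 0)
  set.seed(seed)
  t <- state[[time_field]]
  t_end <- t + T
  snaps <- list(state)
  next_out <- t + events$output_interval
  next_growth <- if (is.finite(events$growth_interval)) {
    t + events$growth_interval
  } else Inf
  dup_times <- events$duplication_times[events$duplication_times > t]
  n_events <- 0L
  repeat {
    a <- vapply(reactions, function(r) r$propensity(state), numeric(1))
    if (any(a < 0)) {
      stop(sprintf("negative propensity in reaction channel %d",
                   which(a < 0)[1]))
    }
    a0 <- sum(a)
    tau <- if (a0 > 0) stats::rexp(1, a0) else Inf
    t_next_sched <- min(next_out, next_growth,
                        if (length(dup_times)) dup_times[1] else Inf, t_end)
    if (t + tau >= t_next_sched) {
      t <- t_next_sched
      state[[time_field]] <- t
      if (t >= t_end) {
        snaps[[length(snaps) + 1L]] <- state
        break
      }
      if (t == next_growth) {
        state <- grow_nucleoid(state)
        next_growth <- next_growth + events$growth_interval
      }
      if (length(dup_times) && t == dup_times[1]) {
        state <- duplicate_plasmid(state)
        dup_times <- dup_times[-1]
      }
      if (t == next_out) {
        snaps[[length(snaps) + 1L]] <- state
        next_out <- next_out + events$output_interval
      }
    } else {
      t <- t + tau
      state[[time_field]] <- t
      j <- sample.int(length(a), 1L, prob = a)
      state <- reactions[[j]]$fire(state)
      n_events <- n_events + 1L
    }
  }
  list(state = state, snapshots = snaps, n_events = n_events)
}

#' Extend the nucleoid lattice by two sites
#'
#' A growth event inserts two empty long-axis columns (no ParA, no plasmids)
#' at one uniformly random position; every site index at or right of the
#' insertion shifts by two. The cytoplasmic ParA-ADP pool is then replenished
#' so that the total ParA density returns to `density_per_um` dimers per um
#' of long axis (newly synthesized ParA enters through the ADP pool, i.e.
#' must mature through the slow ADP -> ATP step before binding).
#'
#' @param state A [lattice_state()].
#' @param density_per_um Target total ParA per um of nucleoid; the standard
#'   value is 2400 dimers/um. `NA` disables replenishment (fixed-count mode).
#' @return The grown state.
#' @export
grow_nucleoid <- function(state, density_per_um = 2400) {
  stopifnot(inherits(state, "lattice_state"))
  n <- state$n_long
  # Insertion point: new columns become indices pos, pos+1 (1-based),
  # chosen uniformly over the n+1 gaps between/around existing columns.
  pos <- sample.int(n + 1L, 1L)
  blank <- matrix(0L, 2L, state$n_short)
  ins <- function(m) {
    rbind(m[seq_len(pos - 1L), , drop = FALSE], blank,
          m[seq(pos, length.out = n - pos + 1L), , drop = FALSE])
  }
  state$mobile <- ins(state$mobile)
  state$polymer <- ins(state$polymer)
  shift <- state$plasmid_site >= pos
  state$plasmid_site[shift] <- state$plasmid_site[shift] + 2L
  state$n_long <- n + 2L
  if (!is.na(density_per_um)) {
    target <- round(density_per_um * state$n_long * state$dx)
    deficit <- target - total_parA(state)
    if (deficit > 0) state$A_ADP <- state$A_ADP + as.integer(deficit)
  }
  state
}

#' Duplicate a plasmid
#'
#' One existing plasmid is chosen uniformly at random and a new plasmid with
#' zero bound ParA appears at the same site; the original keeps its bound
#' count.
#'
#' @param state A [lattice_state()] with at least one plasmid.
#' @return The state with one extra plasmid.
#' @export
duplicate_plasmid <- function(state) {
  stopifnot(inherits(state, "lattice_state"))
  np <- length(state$plasmid_site)
  if (np < 1L) stop("cannot duplicate: no plasmid present")
  k <- sample.int(np, 1L)
  state$plasmid_site <- c(state$plasmid_site, state$plasmid_site[k])
  state$plasmid_bound <- c(state$plasmid_bound, 0L)
  state
}
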