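# Closed-form steady state of the 1d nucleoid-bound ParA-ATP gradient.
#
# The nucleoid is an interval [0, L]. ParA-ATP binds uniformly at flux R
# (molecules per um per s), diffuses with constant D, and is released only at
# plasmid positions x_1 < ... < x_np (ParB/parC-stimulated hydrolysis). At
# steady state each plasmid-free segment obeys D * A'' + R = 0 with no-flux
# edges, so A is piecewise quadratic with curvature -R/D.

#' Parameters of the 1d ParA-ATP gradient model
#'
#' @param L Nucleoid length (um), positive.
#' @param R Uniform ParA binding flux per unit length (molecules um^-1 s^-1),
#'   nonnegative.
#' @param D Diffusion constant of nucleoid-bound ParA-ATP (um^2/s), positive.
#' @param kB Hydrolysis rate at a plasmid (s^-1). `Inf` (the default) makes
#'   plasmids perfectly absorbing, i.e. A(x_i) = 0. A finite value imposes the
#'   mixed condition that the total diffusive flux arriving at plasmid i
#'   equals `kB * A(x_i)`.
#' @param plasmid_positions Strictly increasing positions in the open
#'   interval (0, L) (um).
#'
#' @return An object of class `"gradient_params"`.
#' @seealso [solve_steady_state()], [equal_spacing_positions()]
#' @export
gradient_params <- function(L, R, D, plasmid_positions, kB = Inf) {
  stopifnot(is.numeric(L), length(L) == 1L, L > 0)
  stopifnot(is.numeric(R), length(R) == 1L, R >= 0)
  stopifnot(is.numeric(D), length(D) == 1L, D > 0)
  if (length(kB) != 1L || is.na(kB) || kB <= 0) {
    stop("kB must be a single positive rate (use Inf for absorbing plasmids)")
  }
  x <- as.numeric(plasmid_positions)
  if (length(x) < 1L) stop("at least one plasmid position is required")
  if (any(x <= 0) || any(x >= L)) {
    stop("plasmid positions must lie strictly inside (0, L)")
  }
  if (is.unsorted(x, strictly = TRUE)) {
    stop("plasmid positions must be strictly increasing")
  }
  structure(list(L = L, R = R, D = D, kB = kB, plasmid_positions = x),
            class = "gradient_params")
}

#' Steady-state ParA-ATP profile and per-plasmid fluxes
#'
#' Solves `D A'' + R = 0` on every plasmid-free segment with reflecting
#' (zero-derivative) edges at `x = 0` and `x = L`. With absorbing plasmids
#' (`kB = Inf`) the concentration vanishes at every plasmid; with finite `kB`
#' the plasmid values `A(x_i)` solve the tridiagonal flux-balance system
#' `J_i^- + J_i^+ = kB * A(x_i)`.
#'
#' @param params A [gradient_params()] object.
#' @return An object of class `"gradient_solution"`: a list with
#'   * `segments`: data frame of per-segment quadratic coefficients
#'     (`A(x) = c2 x^2 + c1 x + c0` on `[x_from, x_to]`),
#'   * `fluxes`: data frame with nonnegative arrival rates `J_minus`,
#'     `J_plus` (molecules/s) per plasmid,
#'   * `plasmid_concentrations`: `A(x_i)` (um^-1),
#'   * `params`: the input.
#' @details Total arrival flux over all plasmids equals `R * L` exactly
#'   (everything bound must be released at a plasmid).
#' @export
solve_steady_state <- function(params) {
  stopifnot(inherits(params, "gradient_params"))
  L <- params$L; R <- params$R; D <- params$D; kB <- params$kB
  x <- params$plasmid_positions
  np <- length(x)

  # Segment endpoints including the reflecting edges.
  knots <- c(0, x, L)
  d <- diff(knots)                      # segment lengths, np + 1 of them

  # Plasmid concentrations c_i = A(x_i). The flux arriving at plasmid i is
  #   from the left end segment:   R * x_1                     (independent of c)
  #   from interior segment (i,i+1): R*d/2 + D*(c_other - c_i)/d  to each side
  #   from the right end segment:  R * (L - x_np)
  if (is.infinite(kB)) {
    conc <- rep(0, np)
  } else {
    # Tridiagonal system: sum of arrivals = kB * c_i.
    M <- matrix(0, np, np)
    b <- numeric(np)
    for (i in seq_len(np)) {
      if (i == 1L) {
        b[i] <- b[i] + R * x[1]
      } else {
        dd <- x[i] - x[i - 1]
        b[i] <- b[i] + R * dd / 2
        M[i, i] <- M[i, i] + D / dd
        M[i, i - 1] <- M[i, i - 1] - D / dd
      }
      if (i == np) {
        b[i] <- b[i] + R * (L - x[np])
      } else {
        dd <- x[i + 1] - x[i]
        b[i] <- b[i] + R * dd / 2
        M[i, i] <- M[i, i] + D / dd
        M[i, i + 1] <- M[i, i + 1] - D / dd
      }
      M[i, i] <- M[i, i] + kB
    }
    conc <- as.numeric(solve(M, b))
  }

  # Per-segment quadratic A(x) = -R/(2D) x^2 + a1 x + a0 given end conditions.
  vals <- c(NA_real_, conc, NA_real_)   # A at knots (edges determined below)
  seg <- data.frame(x_from = knots[-length(knots)], x_to = knots[-1],
                    c2 = -R / (2 * D), c1 = NA_real_, c0 = NA_real_)
  for (s in seq_len(np + 1L)) {
    x0 <- knots[s]; x1 <- knots[s + 1]
    if (s == 1L) {
      # A'(0) = 0 -> c1 = 0; value at right end is conc[1].
      seg$c1[s] <- 0
      seg$c0[s] <- conc[1] + R * x1^2 / (2 * D)
    } else if (s == np + 1L) {
      # A'(L) = 0 -> c1 = R*L/D; value at left end is conc[np].
      seg$c1[s] <- R * L / D
      seg$c0[s] <- conc[np] + R * x0^2 / (2 * D) - R * L * x0 / D
    } else {
      cL <- conc[s - 1L]; cR <- conc[s]
      seg$c1[s] <- (cR - cL) / (x1 - x0) + R * (x0 + x1) / (2 * D)
      seg$c0[s] <- cL + R * x0^2 / (2 * D) - seg$c1[s] * x0
    }
  }

  # Arrival fluxes: J^- from the left segment, J^+ from the right segment,
  # both reported as nonnegative arrival rates -/+ D A'(x_i -/+).
  dA <- function(s, xx) 2 * seg$c2[s] * xx + seg$c1[s]
  Jm <- Jp <- numeric(np)
  for (i in seq_len(np)) {
    Jm[i] <- -D * dA(i, x[i])          # flux flowing rightwards into plasmid
    Jp[i] <- D * dA(i + 1L, x[i])      # flux flowing leftwards into plasmid
  }

  structure(list(
    segments = seg,
    fluxes = data.frame(plasmid = seq_len(np), J_minus = Jm, J_plus = Jp),
    plasmid_concentrations = conc,
    params = params
  ), class = "gradient_solution")
}

#' Evaluate a steady-state gradient solution
#'
#' @param solution A `"gradient_solution"` from [solve_steady_state()].
#' @param x Positions (um) in `[0, L]`.
#' @return Concentrations `A(x)` (um^-1).
#' @export
gradient_profile <- function(solution, x) {
  stopifnot(inherits(solution, "gradient_solution"))
  seg <- solution$segments
  idx <- findInterval(x, c(seg$x_from, solution$params$L),
                      rightmost.closed = TRUE, all.inside = TRUE)
  seg$c2[idx] * x^2 + seg$c1[idx] * x + seg$c0[idx]
}

#' Equal-spacing plasmid positions
#'
#' Positions `x_i = (2 i - 1) L / (2 n_p)`: the unique configuration in which
#' the left and right arrival fluxes balance at every plasmid (spacing
#' `L / n_p`, half-spacing to each nucleoid end).
#'
#' @param L Nucleoid length (um), positive.
#' @param n_p Number of plasmids, at least 1.
#' @return Numeric vector of `n_p` positions.
#' @export
equal_spacing_positions <- function(L, n_p) {
  stopifnot(is.numeric(L), length(L) == 1L, L > 0)
  if (!is.numeric(n_p) || length(n_p) != 1L || n_p < 1 || n_p != round(n_p)) {
    stop("n_p must be a positive integer")
  }
  (2 * seq_len(n_p) - 1) * L / (2 * n_p)
}

#' Quasi-static relaxation of plasmid positions by flux imbalance
#'
#' Iteratively moves every plasmid a fixed step towards the side delivering
#' the larger ParA-ATP arrival flux (the side with the steeper gradient,
#' i.e. more free nucleoid), re-solving the steady-state profile after each
#' sweep. This is the separation-of-timescales picture: the ParA profile
#' equilibrates instantaneously relative to plasmid motion. The iteration
#' converges to [equal_spacing_positions()].
#'
#' @param params A [gradient_params()] object giving the initial positions.
#' @param step Displacement per iteration (um). Must be small enough that
#'   plasmids never cross or leave the nucleoid.
#' @param n_iter Maximum number of sweeps.
#' @param tol Convergence tolerance on the largest per-sweep displacement,
#'   as a fraction of `L`.
#' @return A list with `positions` (final), `trajectory` (matrix, one row per
#'   recorded sweep) and `converged`.
#' @export
flux_imbalance_relaxation <- function(params, step = NULL, n_iter = 10000L,
                                      tol = 1e-9) {
  stopifnot(inherits(params, "gradient_params"))
  L <- params$L
  x <- params$plasmid_positions
  np <- length(x)
  if (is.null(step)) step <- L / 2000
  stopifnot(step > 0, n_iter >= 1)
  traj <- matrix(NA_real_, nrow = n_iter + 1L, ncol = np)
  traj[1L, ] <- x
  converged <- FALSE
  used <- 1L
  for (it in seq_len(n_iter)) {
    sol <- solve_steady_state(gradient_params(L, params$R, params$D, x,
                                              kB = params$kB))
    imb <- sol$fluxes$J_plus - sol$fluxes$J_minus
    # Damp the step near balance so the fixed point is approached smoothly:
    # |imb|/(2R) is the displacement that would balance an isolated plasmid.
    move <- sign(imb) * pmin(step, abs(imb) / (2 * params$R + 1e-300))
    xn <- x + move
    if (any(xn <= 0) || any(xn >= L) ||
        (np > 1L && any(diff(xn) <= 0))) {
      stop("relaxation step caused plasmid collision or exit; reduce `step`")
    }
    used <- it + 1L
    traj[used, ] <- xn
    if (max(abs(xn - x)) < tol * L) {
      x <- xn
      converged <- TRUE
      break
    }
    x <- xn
  }
  list(positions = x, trajectory = traj[seq_len(used), , drop = FALSE],
       converged = converged)
}
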