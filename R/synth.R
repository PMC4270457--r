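# Seed-deterministic generators for every input the analysis consumes:
# subdiffusive (fractional Brownian) planar focus trajectories with
# localization noise and pixelation, and two-channel per-cell intensity
# stacks with nucleoid-shaped envelopes, optional helical modulation,
# nested second-channel structures and punctate foci.

#' Fractional Gaussian noise by circulant embedding
#'
#' Exact-covariance synthesis (Davies-Harte): the circulant embedding of the
#' fGn autocovariance is diagonalized by the FFT, giving increments whose
#' sample covariance matches the fBm kernel exactly in expectation.
#'
#' @param n Number of increments.
#' @param H Hurst exponent in (0, 1].
#' @param sigma2 Variance of one increment.
#' @return Numeric vector of `n` correlated increments.
#' @keywords internal
fgn_circulant <- function(n, H, sigma2 = 1) {
  stopifnot(n >= 1, H > 0, H <= 1)
  if (H == 0.5) return(stats::rnorm(n, sd = sqrt(sigma2)))
  k <- 0:n
  gamma <- sigma2 / 2 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                           abs(k - 1)^(2 * H))
  c_row <- c(gamma, rev(gamma[2:n]))          # circulant first row, length 2n
  m <- length(c_row)
  lambda <- Re(stats::fft(c_row))
  lambda[lambda < 0 & lambda > -1e-10] <- 0   # numerical guard
  if (any(lambda < 0)) stop("circulant embedding not nonnegative definite")
  w <- complex(length.out = m)
  w[1] <- sqrt(lambda[1] / m) * stats::rnorm(1)
  w[n + 1] <- sqrt(lambda[n + 1] / m) * stats::rnorm(1)
  z1 <- stats::rnorm(n - 1); z2 <- stats::rnorm(n - 1)
  idx <- 2:n
  w[idx] <- sqrt(lambda[idx] / (2 * m)) * complex(real = z1, imaginary = z2)
  w[m + 2 - idx] <- Conj(w[idx])
  x <- Re(stats::fft(w))
  x[seq_len(n)]
}

#' Specification for synthetic subdiffusive focus trajectories
#'
#' @param n_tracks Number of foci.
#' @param duration Track duration (s).
#' @param frame_interval Frame interval (s).
#' @param alpha Target anomalous exponent in (0, 1].
#' @param D Generalized diffusion coefficient (um^2 s^-alpha); the ensemble
#'   planar MSD is `4 D tau^alpha` before noise.
#' @param sigma Localization noise s.d. per coordinate (um).
#' @param pixel Pixel size for coordinate rounding (um); 0 disables
#'   pixelation.
#' @param confinement Optional reflecting box half-width (um) per
#'   coordinate; `NULL` for unconfined motion.
#' @param seed Integer RNG seed.
#' @return A list of class `"synth_track_spec"`.
#' @export
synth_track_spec <- function(n_tracks = 100L, duration = 60,
                             frame_interval = 4, alpha = 0.73,
                             D = 9.7e-4, sigma = 0.02, pixel = 0.066,
                             confinement = NULL, seed = 1L) {
  stopifnot(n_tracks >= 1, duration > 0, frame_interval > 0,
            alpha > 0, alpha <= 1, D > 0, sigma >= 0, pixel >= 0)
  structure(list(n_tracks = as.integer(n_tracks), duration = duration,
                 frame_interval = frame_interval, alpha = alpha, D = D,
                 sigma = sigma, pixel = pixel, confinement = confinement,
                 seed = as.integer(seed)),
            class = "synth_track_spec")
}

#' Generate planar fractional Brownian focus trajectories
#'
#' Each coordinate is an independent fractional Brownian motion with Hurst
#' exponent `alpha/2`, scaled so the ensemble planar MSD is
#' `4 D tau^alpha`; optional reflecting confinement folds coordinates into
#' a box, then i.i.d. localization noise `N(0, sigma^2)` is added per
#' coordinate and positions are rounded to the pixel grid.
#'
#' @param spec A [synth_track_spec()].
#' @return A list with `tracks` (a [trajectory_set()]) and `truth` (the
#'   noise-free coordinates, same layout).
#' @export
generate_fbm_tracks <- function(spec) {
  stopifnot(inherits(spec, "synth_track_spec"))
  set.seed(spec$seed)
  dt <- spec$frame_interval
  n_steps <- max(1L, floor(spec$duration / dt))
  H <- spec$alpha / 2
  sigma2_step <- 2 * spec$D * dt^spec$alpha   # per-coordinate step variance
  reflect <- function(v, half) {
    if (is.null(half)) return(v)
    # fold into [-half, half] by repeated reflection
    p <- (v + half) %% (4 * half)
    ifelse(p <= 2 * half, p - half, 3 * half - p)
  }
  rows <- vector("list", spec$n_tracks)
  truth_rows <- vector("list", spec$n_tracks)
  for (k in seq_len(spec$n_tracks)) {
    xs <- c(0, cumsum(fgn_circulant(n_steps, H, sigma2_step)))
    ys <- c(0, cumsum(fgn_circulant(n_steps, H, sigma2_step)))
    xs <- reflect(xs, spec$confinement)
    ys <- reflect(ys, spec$confinement)
    tt <- dt * (0:n_steps)
    truth_rows[[k]] <- data.frame(cell = k, focus = 1L, t_s = tt,
                                  x_um = xs, y_um = ys)
    xo <- xs + stats::rnorm(n_steps + 1L, sd = spec$sigma)
    yo <- ys + stats::rnorm(n_steps + 1L, sd = spec$sigma)
    if (spec$pixel > 0) {
      xo <- round(xo / spec$pixel) * spec$pixel
      yo <- round(yo / spec$pixel) * spec$pixel
    }
    rows[[k]] <- data.frame(cell = k, focus = 1L, t_s = tt,
                            x_um = xo, y_um = yo)
  }
  list(tracks = trajectory_set(do.call(rbind, rows),
                               frame_interval = dt,
                               pixel = if (spec$pixel > 0) spec$pixel else 0.066),
       truth = trajectory_set(do.call(rbind, truth_rows),
                              frame_interval = dt))
}

#' Specification for a synthetic two-channel cell stack
#'
#' @param cell_length Cell length (um).
#' @param nucleoid Nucleoid span `c(from, to)` (um) inside the cell.
#' @param dx Long-axis sampling (um).
#' @param dz Section spacing (um).
#' @param n_planes Number of z planes (at least 9).
#' @param focus_band Indices `c(first, last)` of the in-focus planes; planes
#'   outside get attenuated intensity.
#' @param envelope `"halfsine"` or `"flat"` long-axis envelope between the
#'   nucleoid edges.
#' @param helical_amplitude,helical_period Amplitude `a` and period `lambda`
#'   (um) of the helical intensity modulation
#'   `1 + a cos(2 pi x / lambda + phi(z))` with phase advancing over z.
#' @param nested_fraction Channel-B support as a fraction of the nucleoid
#'   span (1 = identical support; < 1 nests B strictly inside A).
#' @param b_from_a Mixing weight in `[0, 1]`: channel B's shape is
#'   `b_from_a * shape_A + (1 - b_from_a) * shape_B_own`, tuning the
#'   inter-channel correlation.
#' @param focus_positions,focus_width,focus_amplitude Punctate foci added to
#'   channel B as Gaussians (positions um).
#' @param photons Poisson photon scale per intensity unit (`Inf` =
#'   noiseless).
#' @param baseline Additive background level.
#' @param seed Integer RNG seed.
#' @return A list of class `"synth_cell_spec"`.
#' @export
synth_cell_spec <- function(cell_length = 3, nucleoid = c(0.5, 2.5),
                            dx = 0.05, dz = 0.1, n_planes = 15L,
                            focus_band = c(4L, 12L),
                            envelope = c("halfsine", "flat"),
                            helical_amplitude = 0, helical_period = 0.5,
                            nested_fraction = 1, b_from_a = 1,
                            focus_positions = numeric(0),
                            focus_width = 0.1, focus_amplitude = 0,
                            photons = Inf, baseline = 0, seed = 1L) {
  envelope <- match.arg(envelope)
  stopifnot(cell_length > 0, length(nucleoid) == 2L,
            nucleoid[1] >= 0, nucleoid[2] <= cell_length,
            nucleoid[2] > nucleoid[1], n_planes >= 9L,
            focus_band[1] >= 1, focus_band[2] <= n_planes,
            nested_fraction > 0, nested_fraction <= 1,
            b_from_a >= 0, b_from_a <= 1, helical_amplitude >= 0,
            helical_amplitude < 1)
  structure(as.list(environment()), class = "synth_cell_spec")
}

#' Generate a synthetic two-channel intensity stack
#'
#' Channel A emulates a DNA-stain nucleoid: a smooth envelope between the
#' nucleoid edges, optionally helically modulated across (x, z), shaped in z
#' by the in-focus band. Channel B emulates a protein channel nested within
#' the nucleoid support with tunable similarity to A, plus optional
#' punctate Gaussian foci. Scaled-Poisson noise and a baseline are applied.
#' Ground truth (edges, foci, band) is returned alongside.
#'
#' @param spec A [synth_cell_spec()].
#' @return List with `channel_a`, `channel_b` (both [intensity_stack()])
#'   and `truth`.
#' @export
generate_cell_stack <- function(spec) {
  stopifnot(inherits(spec, "synth_cell_spec"))
  set.seed(spec$seed)
  x <- seq(spec$dx / 2, spec$cell_length - spec$dx / 2, by = spec$dx)
  nx <- length(x); nz <- spec$n_planes
  shape_between <- function(from, to) {
    inr <- x >= from & x <= to
    s <- numeric(nx)
    if (spec$envelope == "halfsine") {
      s[inr] <- sin(pi * (x[inr] - from) / (to - from))
    } else {
      s[inr] <- 1
    }
    s
  }
  # z attenuation: full intensity inside the focus band, falling off outside
  zw <- numeric(nz)
  band <- spec$focus_band
  for (z in seq_len(nz)) {
    d <- if (z < band[1]) band[1] - z else if (z > band[2]) z - band[2] else 0
    zw[z] <- exp(-(d / 2)^2)
  }
  nuc <- spec$nucleoid
  mid <- mean(nuc)
  half_b <- diff(nuc) / 2 * spec$nested_fraction
  shape_a <- shape_between(nuc[1], nuc[2])
  shape_b_own <- shape_between(mid - half_b, mid + half_b)
  IA <- matrix(0, nx, nz); IB <- matrix(0, nx, nz)
  for (z in seq_len(nz)) {
    modz <- if (spec$helical_amplitude > 0) {
      1 + spec$helical_amplitude *
        cos(2 * pi * x / spec$helical_period + 2 * pi * (z - 1) / nz)
    } else rep(1, nx)
    IA[, z] <- zw[z] * shape_a * modz
    sb <- spec$b_from_a * shape_a + (1 - spec$b_from_a) * shape_b_own
    # B is strictly nested: zero outside its own support when nested
    if (spec$nested_fraction < 1) {
      sb[x < mid - half_b | x > mid + half_b] <- 0
    }
    IB[, z] <- zw[z] * sb * modz
    for (f in seq_along(spec$focus_positions)) {
      IB[, z] <- IB[, z] + spec$focus_amplitude * zw[z] *
        exp(-(x - spec$focus_positions[f])^2 / (2 * spec$focus_width^2))
    }
  }
  apply_noise <- function(I) {
    if (is.finite(spec$photons)) {
      I <- matrix(stats::rpois(length(I), I * spec$photons) / spec$photons,
                  nrow(I), ncol(I))
    }
    I + spec$baseline
  }
  truth <- list(edges = c(edge_left = nuc[1] + (nuc[2] - nuc[1]) / 12,
                          edge_right = nuc[2] - (nuc[2] - nuc[1]) / 12),
                nucleoid_span = nuc, focus_band = band,
                foci = spec$focus_positions)
  # For the half-sine envelope the half-maximum edges sit at 1/6 and 5/6 of
  # the span; for the flat envelope they are the span itself.
  if (spec$envelope == "flat") {
    truth$edges <- c(edge_left = nuc[1], edge_right = nuc[2])
  } else {
    truth$edges <- c(edge_left = nuc[1] + diff(nuc) / 6,
                     edge_right = nuc[2] - diff(nuc) / 6)
  }
  list(channel_a = intensity_stack(apply_noise(IA), x, dz = spec$dz),
       channel_b = intensity_stack(apply_noise(IB), x, dz = spec$dz),
       truth = truth)
}
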