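# Nucleoid-relative positioning, fluorescence asymmetry, nucleoid-shape
# ("first harmonic") scoring and colocalization statistics for per-cell
# intensity data.

#' Construct a two-dimensional intensity stack for one cell
#'
#' A per-cell, per-channel grid of fluorescence intensity I(x, z): `x` runs
#' along the long cell axis, `z` indexes optical sections.
#'
#' @param I Numeric matrix, rows = x positions, columns = z planes;
#'   nonnegative.
#' @param x Strictly increasing long-axis coordinates (um), length
#'   `nrow(I)`.
#' @param dz Section spacing (um; 0.1 or 0.2 in the standard acquisitions).
#' @param poles Optional cell pole positions `c(left, right)` (um); default
#'   `range(x)`.
#' @param foci Optional focus positions along x (um).
#' @return An object of class `"intensity_stack"`.
#' @export
intensity_stack <- function(I, x, dz = 0.1, poles = range(x),
                            foci = numeric(0)) {
  I <- as.matrix(I)
  stopifnot(is.numeric(I), all(I >= 0), length(x) == nrow(I),
            !is.unsorted(x, strictly = TRUE), dz > 0, length(poles) == 2L)
  structure(list(I = I, x = as.numeric(x), dz = dz,
                 poles = as.numeric(poles), foci = as.numeric(foci)),
            class = "intensity_stack")
}

#' Nucleoid edges from a linear intensity profile
#'
#' The nucleoid boundary convention: the outermost crossings of half the
#' profile maximum, linearly interpolated between bracketing samples.
#' Nucleoid length is the distance between the two edges. The number of
#' lobes (distinct above-half-maximum runs, e.g. two for post-replication
#' nucleoids) is reported alongside.
#'
#' @param x Strictly increasing positions (um).
#' @param intensity Nonnegative profile values.
#' @return List with `edge_left`, `edge_right`, `length`, `n_lobes`.
#' @export
nucleoid_edges <- function(x, intensity) {
  stopifnot(length(x) == length(intensity), all(is.finite(intensity)))
  m <- max(intensity)
  if (m <= 0) stop("flat zero profile: no half-maximum crossing")
  half <- m / 2
  above <- intensity >= half
  if (!any(above)) stop("profile never reaches half its maximum")
  iL <- which(above)[1L]
  iR <- which(above)[sum(above)]
  interp <- function(i0, i1) {
    # crossing between samples i0 (below) and i1 (above)
    x[i0] + (half - intensity[i0]) * (x[i1] - x[i0]) /
      (intensity[i1] - intensity[i0])
  }
  edge_left <- if (iL == 1L) x[1L] else interp(iL - 1L, iL)
  edge_right <- if (iR == length(x)) x[length(x)] else interp(iR + 1L, iR)
  runs <- rle(above)
  list(edge_left = edge_left, edge_right = edge_right,
       length = edge_right - edge_left,
       n_lobes = sum(runs$values))
}

#' Focus positions relative to the nucleoid
#'
#' Maps focus coordinates to the relative scale `[0, 1]` between the
#' nucleoid edges, sorts ascending and rank-labels them `1..n_p`.
#'
#' @param foci Focus positions along the long axis (um).
#' @param edges Result of [nucleoid_edges()] (or a list with `edge_left`,
#'   `length`).
#' @return Data frame with `label`, `rel_pos`, `outside` (flag for foci
#'   outside `[0, 1]`, reported as-is).
#' @export
relative_positions <- function(foci, edges) {
  rel <- (as.numeric(foci) - edges$edge_left) / edges$length
  rel <- sort(rel)
  data.frame(label = seq_along(rel), rel_pos = rel,
             outside = rel < 0 | rel > 1)
}

#' Uniform-random positioning null with rank labeling
#'
#' Draws `n_datasets` cells, each with `n_p` plasmid positions uniform and
#' independent on `[0, 1]`, then rank-labels them `1..n_p` per cell. The
#' labeling alone induces spatial ordering: label k follows the k-th order
#' statistic of the uniform, with mean `k / (n_p + 1)`.
#'
#' @param n_p Plasmids per cell.
#' @param n_datasets Number of cells (default 1e5).
#' @param seed Integer RNG seed.
#' @param n_bins Histogram bins over `[0, 1]` (default 40).
#' @return List with `positions` (matrix `n_datasets x n_p`, ranked),
#'   `histogram` (data frame: label, mid, density) and `label_means`.
#' @export
random_position_null <- function(n_p, n_datasets = 1e5, seed = 1L,
                                 n_bins = 40L) {
  stopifnot(n_p >= 1, n_datasets >= 1)
  set.seed(seed)
  pos <- matrix(stats::runif(n_datasets * n_p), n_datasets, n_p)
  pos <- t(apply(pos, 1L, sort))
  if (n_p == 1L) pos <- matrix(pos, ncol = 1L)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  hist_tab <- do.call(rbind, lapply(seq_len(n_p), function(k) {
    cnt <- tabulate(findInterval(pmin(pos[, k], 1 - 1e-12), breaks,
                                 rightmost.closed = TRUE), nbins = n_bins)
    data.frame(label = k, mid = mids,
               density = cnt / (sum(cnt) * diff(breaks)[1]))
  }))
  list(positions = pos, histogram = hist_tab,
       label_means = colMeans(pos))
}

#' Pole-side fluorescence asymmetry about a focus
#'
#' Sums the intensity from each pole to the focus and divides by the
#' respective pole-to-focus distance, giving per-side densities `I_L`,
#' `I_R`; the normalized asymmetry is `|I_L - I_R| / (I_L + I_R)`. A
#' uniform profile gives 0 regardless of focus position; a fully one-sided
#' profile gives 1.
#'
#' @param x Strictly increasing positions (um).
#' @param intensity Nonnegative profile.
#' @param focus Focus position, strictly between the poles.
#' @param poles Cell pole positions `c(left, right)` (um); default
#'   `range(x)`.
#' @return List with `I_L`, `I_R` (a.u./um) and `asymmetry` in `[0, 1]`.
#' @export
asymmetry_measure <- function(x, intensity, focus, poles = range(x)) {
  stopifnot(length(x) == length(intensity), all(intensity >= 0))
  if (focus <= poles[1] || focus >= poles[2]) {
    stop("focus must lie strictly between the poles")
  }
  # Side sums by trapezoidal integration normalized per unit length, so the
  # measure is sampling-density independent and a uniform profile is exact.
  trapz <- function(xx, yy) {
    if (length(xx) < 2L) return(0)
    sum(diff(xx) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
  }
  f_int <- stats::approx(x, intensity, xout = focus, rule = 2)$y
  left <- x < focus
  xl <- c(x[left], focus); yl <- c(intensity[left], f_int)
  xr <- c(focus, x[!left]); yr <- c(f_int, intensity[!left])
  I_L <- trapz(xl, yl) / (focus - poles[1])
  I_R <- trapz(xr, yr) / (poles[2] - focus)
  denom <- I_L + I_R
  list(I_L = I_L, I_R = I_R,
       asymmetry = if (denom > 0) abs(I_L - I_R) / denom else NA_real_)
}

#' Reference asymmetry distribution for a pole-to-pole oscillator
#'
#' The MinD-style spatiotemporal oscillator reference: the asymmetry of an
#' oscillating distribution follows `amplitude * |sin t|` over one period.
#' Sampling phases uniformly reproduces the asymmetry distribution of a
#' sustained oscillation with the given amplitude (mean
#' `amplitude * 2 / pi`).
#'
#' @param amplitude Oscillation amplitude (default 0.6, the large-cell
#'   value).
#' @param n_samples Number of uniform phase samples (default 1e3).
#' @param seed Integer RNG seed.
#' @return Numeric vector of asymmetry samples.
#' @export
mind_reference <- function(amplitude = 0.6, n_samples = 1e3, seed = 1L) {
  stopifnot(amplitude >= 0, n_samples >= 1)
  set.seed(seed)
  t <- stats::runif(n_samples, 0, 2 * pi)
  amplitude * abs(sin(t))
}

#' Select the in-focus planes of a Z-stack
#'
#' Finds the set of `n_planes` consecutive z sections maximizing the summed
#' per-plane maximum intensity `sum I_max(z)`; ties resolve to the lowest
#' starting index.
#'
#' @param stack An [intensity_stack()].
#' @param n_planes Number of consecutive planes (default 9).
#' @return Integer vector of selected plane indices.
#' @export
select_focus_planes <- function(stack, n_planes = 9L) {
  stopifnot(inherits(stack, "intensity_stack"))
  nz <- ncol(stack$I)
  if (nz < n_planes) stop("stack has fewer than ", n_planes, " planes")
  imax <- apply(stack$I, 2L, max)
  sums <- vapply(seq_len(nz - n_planes + 1L),
                 function(s) sum(imax[s:(s + n_planes - 1L)]), numeric(1))
  s <- which.max(sums)          # which.max returns the first (lowest) maximum
  seq.int(s, s + n_planes - 1L)
}

#' First-harmonic nucleoid-shape score
#'
#' For each plane z, a half-sine "first harmonic" of amplitude `I_max(z)` is
#' anchored between the plane's outermost half-maximum edges `x_L(z)`,
#' `x_R(z)`:
#' `H(x, z) = I_max(z) * sin(pi (x - x_L) / (x_R - x_L))`.
#' The squared residual normalized to the cell-wide maximum,
#' `SE(x, z) = ((I(x, z) - H(x, z)) / I_maxcell)^2`, is averaged over all
#' in-range grid points to give `SE_cell` — small for a smooth, uniform
#' nucleoid profile and larger for spatially modulated (e.g. helical)
#' structure, independent of nucleoid size and expression level.
#'
#' @param stack An [intensity_stack()] restricted to the in-focus planes
#'   (see [select_focus_planes()]).
#' @return An object of class `"harmonic_result"`: list with `SE` (matrix,
#'   `NA` outside the edge range), `SE_cell`, `edges` (per-plane x_L, x_R)
#'   and `I_maxcell`.
#' @export
first_harmonic_score <- function(stack) {
  stopifnot(inherits(stack, "intensity_stack"))
  I <- stack$I; x <- stack$x
  I_maxcell <- max(I)
  if (I_maxcell <= 0) stop("empty stack")
  SE <- matrix(NA_real_, nrow(I), ncol(I))
  edges <- data.frame(z = seq_len(ncol(I)), x_L = NA_real_, x_R = NA_real_)
  for (z in seq_len(ncol(I))) {
    prof <- I[, z]
    if (max(prof) <= 0) next
    e <- tryCatch(nucleoid_edges(x, prof), error = function(err) NULL)
    if (is.null(e) || e$length <= 0) {
      warning("degenerate edges in plane ", z, "; plane skipped")
      next
    }
    edges$x_L[z] <- e$edge_left; edges$x_R[z] <- e$edge_right
    inr <- x >= e$edge_left & x <= e$edge_right
    H <- max(prof) * sin(pi * (x[inr] - e$edge_left) / e$length)
    SE[inr, z] <- ((prof[inr] - H) / I_maxcell)^2
  }
  structure(list(SE = SE, SE_cell = mean(SE, na.rm = TRUE),
                 edges = edges, I_maxcell = I_maxcell),
            class = "harmonic_result")
}

#' Pearson and Manders colocalization of two channels
#'
#' Pearson's correlation `r_P` is computed over all grid points of the two
#' stacks. The Manders overlap coefficient of channel A onto B at threshold
#' T is the fraction of A's total intensity located where B's intensity,
#' normalized to B's cell-wide maximum, exceeds T (and symmetrically for B
#' onto A). At T = 0 both coefficients are 1 by construction; they are
#' non-increasing in T.
#'
#' @param stack_a,stack_b [intensity_stack()]s on identical grids
#'   (in-focus planes pre-selected).
#' @param thresholds Manders threshold grid on `[0, 1]` (default
#'   `seq(0, 0.95, by = 0.05)`).
#' @return An object of class `"colocalization_result"`: list with `r_P`
#'   and `manders` (data frame: threshold, M_A, M_B).
#' @export
colocalize <- function(stack_a, stack_b,
                       thresholds = seq(0, 0.95, by = 0.05)) {
  stopifnot(inherits(stack_a, "intensity_stack"),
            inherits(stack_b, "intensity_stack"),
            all(dim(stack_a$I) == dim(stack_b$I)))
  a <- as.numeric(stack_a$I); b <- as.numeric(stack_b$I)
  r_P <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance channel: Pearson correlation undefined")
    NA_real_
  } else {
    stats::cor(a, b)
  }
  an <- a / max(a); bn <- b / max(b)
  man <- do.call(rbind, lapply(thresholds, function(T) {
    data.frame(threshold = T,
               M_A = sum(a[bn > T | T == 0]) / sum(a),
               M_B = sum(b[an > T | T == 0]) / sum(b))
  }))
  structure(list(r_P = r_P, manders = man), class = "colocalization_result")
}
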