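# Shared oracles and fixture builders, independent of the implementation
# paths they check.

# Finite-difference oracle for the steady-state gradient: solves
# D A'' + R = 0 on a dense grid with no-flux edges and A = 0 clamped at the
# plasmid nodes, then reads the one-sided fluxes off the discrete gradient.
fd_gradient_oracle <- function(L, R, D, plasmids, n_grid = 2e4) {
  h <- L / (n_grid - 1)
  x <- seq(0, L, length.out = n_grid)
  ip <- vapply(plasmids, function(p) which.min(abs(x - p)), integer(1))
  # tridiagonal Laplacian with reflecting ends (ghost-node convention)
  main <- rep(-2, n_grid); main[1] <- -2; main[n_grid] <- -2
  lower <- rep(1, n_grid - 1); upper <- rep(1, n_grid - 1)
  upper[1] <- 2; lower[n_grid - 1] <- 2
  rhs <- rep(-R * h^2 / D, n_grid)
  for (k in ip) {          # Dirichlet rows at plasmid nodes
    main[k] <- 1; rhs[k] <- 0
    if (k > 1) lower[k - 1] <- 0
    if (k < n_grid) upper[k] <- 0
  }
  M <- Matrix::bandSparse(n_grid, n_grid, k = -1:1,
                          diagonals = list(lower, main, upper))
  A <- as.numeric(Matrix::solve(M, rhs))
  flux <- lapply(seq_along(ip), function(j) {
    k <- ip[j]
    # second-order one-sided derivatives (exact for the piecewise quadratic)
    Jm <- if (k > 2) {
      -D * (3 * A[k] - 4 * A[k - 1] + A[k - 2]) / (2 * h)
    } else 0
    Jp <- if (k < n_grid - 1) {
      D * (-3 * A[k] + 4 * A[k + 1] - A[k + 2]) / (2 * h)
    } else 0
    c(J_minus = Jm, J_plus = Jp)
  })
  list(x = x, A = A, fluxes = do.call(rbind, flux))
}

# Build a trajectory_set from a list of (t, x, y) matrices.
make_tracks <- function(...) {
  lst <- list(...)
  rows <- lapply(seq_along(lst), function(i) {
    m <- lst[[i]]
    data.frame(cell = i, focus = 1L, t_s = m[, 1], x_um = m[, 2],
               y_um = m[, 3])
  })
  trajectory_set(do.call(rbind, rows))
}

# Long-axis plasmid MSD curve from a lattice-simulation trajectory table.
sim_msd <- function(traj, plasmid = 1L) {
  d <- traj[traj$plasmid == plasmid, ]
  compute_msd(trajectory_set(data.frame(
    cell = 1L, focus = plasmid, t_s = d$t, x_um = d$pos_um, y_um = 0)))
}
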