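# Mobility statistics for plasmid focus trajectories: pooled MSD curves,
# weighted subdiffusion fitting, rapid-segregation-event detection, and the
# max-MSD resampling test.

#' Assemble a trajectory set
#'
#' @param records Data frame with columns `cell`, `focus`, `t_s`, `x_um`,
#'   `y_um` (one row per focus per frame). Times must be strictly increasing
#'   within each focus; gaps (missing frames) are allowed.
#' @param frame_interval Nominal frame interval (s), used for reporting only.
#' @param pixel Camera pixel size (um, default 0.066).
#' @return An object of class `"trajectory_set"`.
#' @export
trajectory_set <- function(records, frame_interval = NA_real_,
                           pixel = 0.066) {
  need <- c("cell", "focus", "t_s", "x_um", "y_um")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  records <- as.data.frame(records)[need]
  key <- interaction(records$cell, records$focus, drop = TRUE)
  ok <- vapply(split(records$t_s, key),
               function(tt) !is.unsorted(tt, strictly = TRUE), logical(1))
  if (!all(ok)) stop("times must be strictly increasing within each focus")
  structure(list(records = records, frame_interval = frame_interval,
                 pixel = pixel),
            class = "trajectory_set")
}

#' Pooled mean-square displacement curve
#'
#' Pools every overlapping-window planar squared displacement at each time
#' lag, across all foci and cells: every frame pair `(t, t + tau)` within a
#' focus contributes, so each trajectory contributes many short lags. Pairs
#' spanning missing frames still count at their actual lag.
#'
#' @param tracks A [trajectory_set()].
#' @param max_lag Largest lag to report (s); default all observed lags.
#' @return An object of class `"msd_curve"`: data frame with `tau` (s),
#'   `msd` (mean r^2, um^2), `sem` and `n` (displacement count).
#' @export
compute_msd <- function(tracks, max_lag = Inf) {
  stopifnot(inherits(tracks, "trajectory_set"))
  rec <- tracks$records
  if (nrow(rec) < 2L) stop("need at least one focus with two frames")
  key <- interaction(rec$cell, rec$focus, drop = TRUE)
  pieces <- lapply(split(rec, key), function(d) {
    n <- nrow(d)
    if (n < 2L) return(NULL)
    i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
    tau <- d$t_s[j] - d$t_s[i]
    r2 <- (d$x_um[j] - d$x_um[i])^2 + (d$y_um[j] - d$y_um[i])^2
    keep <- tau <= max_lag
    data.frame(tau = tau[keep], r2 = r2[keep])
  })
  all_disp <- do.call(rbind, pieces)
  if (is.null(all_disp) || nrow(all_disp) == 0L) {
    stop("no displacement pairs available")
  }
  tau_r <- round(all_disp$tau, 9)
  agg <- do.call(rbind, lapply(split(all_disp$r2, tau_r), function(v) {
    data.frame(msd = mean(v),
               sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0,
               n = length(v))
  }))
  out <- data.frame(tau = as.numeric(rownames(agg)), agg, row.names = NULL)
  out <- out[order(out$tau), ]
  rownames(out) <- NULL
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Weighted subdiffusion fit of an MSD curve
#'
#' Fits the planar anomalous-diffusion law
#' `msd(tau) = 4 D tau^alpha + beta` by nonlinear least squares weighted by
#' the standard error of the mean (residuals scaled by `1/SEM(tau)`). The
#' static offset `beta` absorbs time-independent localization error (an
#' i.i.d. error of variance `sigma^2` per coordinate inflates the planar MSD
#' by `4 sigma^2`); the exponent `alpha` is invariant to the planar
#' prefactor convention. The `tau = 0` point, if present, is excluded.
#'
#' @param msd An [compute_msd()] result (or data frame with `tau`, `msd`,
#'   `sem`).
#' @param start Optional named list of starting values (`alpha`, `D`,
#'   `beta`).
#' @return An object of class `"subdiffusion_fit"`: list with `alpha`, `D`
#'   (um^2 s^-alpha), `beta` (um^2), their standard errors, `ci` (95%
#'   intervals), `r_squared` and the underlying `nls` fit.
#' @export
fit_subdiffusion <- function(msd, start = NULL) {
  d <- as.data.frame(msd)
  d <- d[is.finite(d$tau) & d$tau > 0 & is.finite(d$msd), ]
  d <- d[d$sem > 0, ]
  if (nrow(d) < 4L) stop("need at least 4 lags with positive SEM")
  if (is.null(start)) {
    # log-log slope through the first/last points seeds alpha and D
    a0 <- (log(d$msd[nrow(d)]) - log(d$msd[1])) /
      (log(d$tau[nrow(d)]) - log(d$tau[1]))
    a0 <- min(max(a0, 0.1), 1.5)
    start <- list(alpha = a0, D = d$msd[1] / (4 * d$tau[1]^a0), beta = 0)
  }
  w <- 1 / d$sem^2
  fit <- minpack.lm::nlsLM(msd ~ 4 * D * tau^alpha + beta, data = d,
                           start = start, weights = w,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- summary(fit)$coefficients
  est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
  ci <- cbind(est - stats::qt(0.975, nrow(d) - 3) * se,
              est + stats::qt(0.975, nrow(d) - 3) * se)
  resid <- d$msd - stats::predict(fit)
  r2 <- 1 - sum(w * resid^2) / sum(w * (d$msd - stats::weighted.mean(d$msd, w))^2)
  structure(list(alpha = unname(est["alpha"]), D = unname(est["D"]),
                 beta = unname(est["beta"]),
                 alpha_se = unname(se["alpha"]), D_se = unname(se["D"]),
                 beta_se = unname(se["beta"]),
                 ci = ci, r_squared = r2, fit = fit),
            class = "subdiffusion_fit")
}

#' @export
print.subdiffusion_fit <- function(x, ...) {
  cat(sprintf("Subdiffusion fit: msd = 4 D tau^alpha + beta\n"))
  cat(sprintf("  alpha = %.3f +/- %.3f\n", x$alpha, x$alpha_se))
  cat(sprintf("  D     = %.3g +/- %.2g um^2 s^-alpha\n", x$D, x$D_se))
  cat(sprintf("  beta  = %.3g +/- %.2g um^2\n", x$beta, x$beta_se))
  cat(sprintf("  R^2   = %.4f\n", x$r_squared))
  invisible(x)
}

#' Minimum diffusivity implied by a displacement within a time
#'
#' The 1d free-diffusion law `<x^2> = 2 D t` inverted for D: the diffusion
#' constant required for an unbiased random walk to cover `displacement`
#' within `time`. Used to bound the free plasmid diffusivity needed by a
#' diffusion/immobilization mechanism given observed long-axis displacements
#' (3-4 um within 10 min implies D on the order of 1e-2 um^2/s).
#'
#' @param displacement Long-axis displacement (um).
#' @param time Time in which it occurs (s).
#' @return Required diffusion constant (um^2/s).
#' @export
required_diffusivity <- function(displacement = 3.5, time = 600) {
  stopifnot(displacement > 0, time > 0)
  displacement^2 / (2 * time)
}

#' Detect rapid segregation events
#'
#' An event is a per-cell focus pair whose separation is initially at most
#' `init_sep` (an initially merged pair that splits counts as separation 0)
#' and which moves at least `extra_sep` further apart within `window`
#' seconds of the event start.
#'
#' @param tracks A [trajectory_set()]; cells with at least two foci are
#'   scanned pairwise.
#' @param window Observation window (s, default 20; 60 is the relaxed
#'   variant).
#' @param init_sep Maximum initial separation (um, default 0.3).
#' @param extra_sep Required additional separation (um, default 0.8).
#' @return Data frame with one row per event: `cell`, `focus_a`, `focus_b`,
#'   `t_start`, `init_separation`, `max_extra_separation`, `t_reached`.
#'   Zero rows when nothing qualifies.
#' @export
detect_segregation_events <- function(tracks, window = 20, init_sep = 0.3,
                                      extra_sep = 0.8) {
  stopifnot(inherits(tracks, "trajectory_set"))
  rec <- tracks$records
  out <- list()
  for (cell in unique(rec$cell)) {
    d <- rec[rec$cell == cell, ]
    foci <- unique(d$focus)
    if (length(foci) < 2L) next
    for (a_i in seq_len(length(foci) - 1L)) {
      for (b_i in (a_i + 1L):length(foci)) {
        da <- d[d$focus == foci[a_i], ]
        db <- d[d$focus == foci[b_i], ]
        tt <- intersect(da$t_s, db$t_s)
        if (length(tt) < 2L) next
        tt <- sort(tt)
        sep <- sqrt((da$x_um[match(tt, da$t_s)] - db$x_um[match(tt, db$t_s)])^2 +
                    (da$y_um[match(tt, da$t_s)] - db$y_um[match(tt, db$t_s)])^2)
        # earliest qualifying start; report at most one event per pair
        for (s in seq_along(tt)) {
          if (sep[s] > init_sep) next
          in_win <- which(tt > tt[s] & tt <= tt[s] + window)
          if (!length(in_win)) next
          extra <- sep[in_win] - sep[s]
          if (max(extra) >= extra_sep) {
            hit <- in_win[which(extra >= extra_sep)[1L]]
            out[[length(out) + 1L]] <- data.frame(
              cell = cell, focus_a = foci[a_i], focus_b = foci[b_i],
              t_start = tt[s], init_separation = sep[s],
              max_extra_separation = max(extra), t_reached = tt[hit])
            break
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(cell = character(0), focus_a = character(0),
                      focus_b = character(0), t_start = numeric(0),
                      init_separation = numeric(0),
                      max_extra_separation = numeric(0),
                      t_reached = numeric(0)))
  }
  do.call(rbind, out)
}

# Per-trajectory maximal MSD: for one focus, the largest mean over lag-pairs
# is summarized by the maximum squared displacement from pooled pairs at the
# per-trajectory level; here max over all pair displacements.
per_track_max_msd <- function(tracks) {
  rec <- tracks$records
  key <- interaction(rec$cell, rec$focus, drop = TRUE)
  vapply(split(rec, key), function(d) {
    n <- nrow(d)
    if (n < 2L) return(NA_real_)
    i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
    max((d$x_um[j] - d$x_um[i])^2 + (d$y_um[j] - d$y_um[i])^2)
  }, numeric(1))
}

#' Resampling test for elevated maximal MSDs
#'
#' Tests whether a set of trajectories (e.g. those involved in segregation
#' events) has larger maximal MSDs than expected under random sampling from
#' the full dataset. The statistic is the mean over the event set of each
#' trajectory's maximal squared displacement; the null distribution is
#' obtained by repeatedly drawing equally sized subsets uniformly without
#' replacement. The empirical p-value uses the add-one correction
#' `p = (1 + #null >= observed) / (1 + n_resample)`.
#'
#' @param event_tracks A [trajectory_set()] of the event trajectories.
#' @param all_tracks A [trajectory_set()] of the full dataset.
#' @param n_resample Number of null draws (default 1e4).
#' @param seed Integer RNG seed.
#' @return List with `p_value`, `observed` (mean of maxima), `null`
#'   (resampled statistics) and `per_track_max` for the event set.
#' @export
max_msd_resampling_test <- function(event_tracks, all_tracks,
                                    n_resample = 1e4, seed = 1L) {
  m_all <- per_track_max_msd(all_tracks)
  m_evt <- per_track_max_msd(event_tracks)
  m_all <- m_all[!is.na(m_all)]; m_evt <- m_evt[!is.na(m_evt)]
  k <- length(m_evt)
  if (k > length(m_all)) stop("event set larger than the full dataset")
  obs <- mean(m_evt)
  set.seed(seed)
  null <- vapply(seq_len(n_resample),
                 function(i) mean(sample(m_all, k)), numeric(1))
  p <- (1 + sum(null >= obs)) / (1 + n_resample)
  list(p_value = p, observed = obs, null = null, per_track_max = m_evt)
}
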