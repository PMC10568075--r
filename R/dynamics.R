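#' Integrate a coupled system
#'
#' Stiff-capable integration (deSolve's `lsoda`) with tight default
#' tolerances; the returned trajectory carries the projection of every
#' sample onto the active coupling plane, consistent with the transform
#' used by [project_curve()].
#'
#' @param system a `pn_system` (or a full companion model via
#'   `use_full = TRUE` for systems that bundle one).
#' @param initial full state vector (non-negative); names optional.
#' @param t_end end time (model time units).
#' @param n_out number of output samples (dense enough for peak
#'   detection).
#' @param rtol,atol integrator tolerances.
#' @param use_full integrate the bundled unreduced companion model
#'   instead of the two-module system.
#' @return a `pn_trajectory`: list with `times`, `states` (matrix, one
#'   row per sample), `proj` (two-column matrix `u`, `v`; `NULL` when no
#'   projection applies), `diagnostics`.
#' @export
integrate_system <- function(system, initial, t_end, n_out = 4000L,
                             rtol = 1e-8, atol = 1e-10, use_full = FALSE) {
  stopifnot(t_end > 0)
  if (use_full) {
    fm <- system$full_model
    if (is.null(fm)) stop("system has no full companion model")
    rhs <- function(t, s, p) list(fm$rhs(s, system$params))
    snames <- fm$state_names
  } else {
    rhs <- function(t, s, p) list(full_rhs(system, s))
    snames <- system$state_names
  }
  if (length(initial) != length(snames))
    stop("initial state has length ", length(initial), ", expected ",
         length(snames))
  times <- seq(0, t_end, length.out = n_out)
  out <- deSolve::lsoda(y = stats::setNames(as.numeric(initial), snames),
                        times = times, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  ok <- attr(out, "istate")[1] >= 0
  if (!ok || nrow(out) < length(times))
    stop("integrator failed at t = ",
         if (nrow(out)) max(out[, 1]) else 0)
  states <- unname(out[, -1, drop = FALSE])
  colnames(states) <- snames
  proj <- NULL
  if (!use_full && !is.null(system$trajectory_projection)) {
    proj <- t(apply(states, 1, system$trajectory_projection,
                    params = system$params))
    colnames(proj) <- c("u", "v")
  }
  structure(list(times = times, states = states, proj = proj,
                 diagnostics = list(success = ok, rtol = rtol, atol = atol)),
            class = "pn_trajectory")
}

#' Detect a limit cycle on a trajectory
#'
#' Works on one observable: discards the transient (first half, extended
#' until peak amplitudes stabilize), finds local maxima with quadratic
#' interpolation of peak times, and reports a cycle when at least four
#' post-transient peaks have stable spacing. Amplitude is max minus min
#' over the last full period; the duty fraction is the fraction of a
#' period the observable exceeds its mid-range.
#'
#' @param traj a `pn_trajectory`.
#' @param observable state column name (or index).
#' @param period_tol relative tolerance on successive peak spacings.
#' @param amp_floor oscillations smaller than this fraction of the
#'   observable's overall scale are treated as absent.
#' @param min_peaks required number of stable post-transient peaks.
#' @return list with `exists`, `period`, `amplitude`, `duty`,
#'   `peak_times`, `inconclusive`.
#' @export
detect_limit_cycle <- function(traj, observable, period_tol = 0.01,
                               amp_floor = 1e-3, min_peaks = 4L) {
  y <- traj$states[, observable]
  tt <- traj$times
  n <- length(y)
  if (n < 50)
    return(list(exists = NA, period = NA_real_, amplitude = NA_real_,
                duty = NA_real_, peak_times = numeric(0),
                inconclusive = TRUE))
  scale <- max(abs(y)) + 1e-300
  half <- y[tt >= tt[n] / 2]
  late_range <- diff(range(half))
  if (late_range < amp_floor * scale)
    return(list(exists = FALSE, period = NA_real_,
                amplitude = late_range, duty = NA_real_,
                peak_times = numeric(0), inconclusive = FALSE))
  pk <- find_peaks(tt, y)
  if (nrow(pk) < 2) {
    # not settled, but no repeated peaks either: the trajectory is too
    # short to decide
    return(list(exists = FALSE, period = NA_real_, amplitude = late_range,
                duty = NA_real_, peak_times = pk$time,
                inconclusive = TRUE))
  }
  # transient discard: drop leading peaks until amplitudes of 3
  # successive peaks agree within 1%
  start <- 1L
  if (nrow(pk) >= 3) {
    for (s in seq_len(nrow(pk) - 2L)) {
      a <- pk$height[s:(s + 2)]
      if (diff(range(a)) <= 0.01 * max(abs(a) + 1e-300)) { start <- s; break }
      start <- s
    }
  }
  pk <- pk[seq.int(start, nrow(pk)), , drop = FALSE]
  if (nrow(pk) < min_peaks)
    return(list(exists = FALSE, period = NA_real_, amplitude = late_range,
                duty = NA_real_, peak_times = pk$time,
                inconclusive = nrow(pk) >= 2))
  gaps <- diff(pk$time)
  period <- stats::median(gaps)
  stable <- all(abs(gaps - period) <= period_tol * period)
  if (!stable) {
    # keep only the trailing run of stable gaps
    ok <- abs(gaps - period) <= period_tol * period
    runs <- rle(ok)
    if (sum(ok) >= min_peaks - 1L) {
      last_true <- max(which(ok))
      first_true <- last_true - (min_peaks - 2L)
      stable <- first_true >= 1 && all(ok[first_true:last_true])
    }
  }
  if (!stable)
    return(list(exists = FALSE, period = period, amplitude = late_range,
                duty = NA_real_, peak_times = pk$time, inconclusive = TRUE))
  # amplitude and duty over the last full period
  t1 <- pk$time[nrow(pk) - 1L]; t2 <- pk$time[nrow(pk)]
  win <- tt >= t1 & tt <= t2
  yy <- y[win]
  amplitude <- diff(range(yy))
  mid <- (max(yy) + min(yy)) / 2
  duty <- mean(yy > mid)
  list(exists = amplitude >= amp_floor * scale, period = period,
       amplitude = amplitude, duty = duty, peak_times = pk$time,
       inconclusive = FALSE)
}

# local maxima with quadratic (three-point) interpolation of peak time
find_peaks <- function(tt, y) {
  n <- length(y)
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  # ignore flat numerical ripples
  if (!length(i))
    return(data.frame(time = numeric(0), height = numeric(0)))
  tpk <- numeric(length(i)); hpk <- numeric(length(i))
  for (k in seq_along(i)) {
    j <- i[k]
    y0 <- y[j - 1]; y1 <- y[j]; y2 <- y[j + 1]
    den <- (y0 - 2 * y1 + y2)
    delta <- if (abs(den) > 1e-300) 0.5 * (y0 - y2) / den else 0
    delta <- max(-0.5, min(0.5, delta))
    dt <- tt[j + 1] - tt[j]
    tpk[k] <- tt[j] + delta * dt
    hpk[k] <- y1 - 0.25 * (y0 - y2) * delta
  }
  data.frame(time = tpk, height = hpk)
}

#' Probe excitability around a saddle
#'
#' Near a stable state coexisting with a saddle, perturbations on one
#' side of the saddle's stable set return directly while those beyond it
#' trigger a large phase-space excursion before returning. Each supplied
#' initial state is integrated and classified by comparing its maximum
#' distance from the stable state against `excursion_factor` times the
#' initial displacement.
#'
#' @param system a `pn_system`.
#' @param saddle,stable `pn_intersection` objects (classified saddle and
#'   stable state respectively).
#' @param perturbations list of full initial-state vectors.
#' @param t_end integration horizon.
#' @param excursion_factor excursion threshold multiplier.
#' @param settle_tol required closeness to the stable state at the end.
#' @return data frame with one row per initial state: `outcome`
#'   ("large_excursion", "direct_return" or "unclassified"),
#'   `max_distance`, `initial_distance`, `final_distance`.
#' @export
excitability_probe <- function(system, saddle, stable, perturbations,
                               t_end = 2000, excursion_factor = 5,
                               settle_tol = 1e-3) {
  if (saddle$stability != "saddle")
    stop("'saddle' intersection is not classified as a saddle")
  if (!startsWith(stable$stability, "stable"))
    stop("'stable' intersection is not classified stable")
  s_star <- stable$state
  scale <- max(1, max(abs(s_star)))
  rows <- lapply(perturbations, function(x0) {
    d0 <- sqrt(sum((x0 - s_star)^2))
    if (d0 == 0)
      return(data.frame(outcome = "direct_return", max_distance = 0,
                        initial_distance = 0, final_distance = 0))
    traj <- integrate_system(system, x0, t_end)
    d <- sqrt(rowSums(sweep(traj$states, 2, s_star)^2))
    dmax <- max(d)
    dfin <- d[length(d)]
    outcome <- if (dfin > settle_tol * scale) "unclassified"
               else if (dmax > excursion_factor * d0) "large_excursion"
               else "direct_return"
    data.frame(outcome = outcome, max_distance = dmax,
               initial_distance = d0, final_distance = dfin)
  })
  do.call(rbind, rows)
}
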