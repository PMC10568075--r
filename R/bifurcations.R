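#' All steady states of the full coupled system at the current parameters
#'
#' Deterministic multi-start damped Newton on the full vector field,
#' seeded by a Halton grid over the combined module state boxes plus any
#' warm starts. The independent full-system route used to cross-check the
#' pseudo-nullcline pipeline, and the engine behind parameter scans.
#'
#' @param system a `pn_system`.
#' @param n_starts Halton starts.
#' @param root_tol residual tolerance.
#' @param dedupe_tol relative dedup tolerance.
#' @param extra_starts optional warm-start matrix.
#' @param module_seeds also seed from the module decomposition (a
#'   coarse consistency sweep); default on unless warm starts are given.
#' @return matrix of steady states (one per row) with attribute
#'   `residuals`.
#' @export
full_system_roots <- function(system, n_starts = 40L, root_tol = 1e-9,
                              dedupe_tol = 1e-6, extra_starts = NULL,
                              module_seeds = is.null(extra_starts)) {
  b1 <- module_bounds(system$module1, system$params, NA)
  b2 <- module_bounds(system$module2, system$params, NA)
  lower <- c(b1[1, ], b2[1, ]); upper <- c(b1[2, ], b2[2, ])
  starts <- rbind(halton_points(n_starts, lower, upper, skip = 1L),
                  box_corner_starts(lower, upper))
  if (module_seeds && !is.null(system$input_grids)) {
    sd <- module_consistency_seeds(system)
    if (!is.null(sd) && nrow(sd)) starts <- rbind(sd, starts)
  }
  if (!is.null(extra_starts) && nrow(extra_starts) > 0)
    starts <- rbind(as.matrix(extra_starts), starts)
  f <- function(s) full_rhs(system, s)
  rng <- pmax(upper - lower, 1e-12)
  lo_ok <- lower - 0.25 * rng; hi_ok <- upper + 0.25 * rng
  roots <- NULL; resids <- numeric(0)
  for (i in seq_len(nrow(starts))) {
    sol <- newton_solve(f, starts[i, ], tol = root_tol, scale = rng)
    if (sol$converged && all(sol$root >= lo_ok) && all(sol$root <= hi_ok)) {
      roots <- rbind(roots, sol$root)
      resids <- c(resids, sol$resid)
    }
  }
  if (is.null(roots)) {
    out <- matrix(numeric(0), 0, system$dim,
                  dimnames = list(NULL, system$state_names))
    attr(out, "residuals") <- numeric(0)
    return(out)
  }
  scale <- max(1, max(abs(c(lower, upper))))
  mr <- merge_roots(roots, resids, f, root_tol, dedupe_tol * scale)
  roots <- mr$roots
  colnames(roots) <- system$state_names
  ord <- order(roots[, 1])
  roots <- roots[ord, , drop = FALSE]
  attr(roots, "residuals") <- mr$resids[ord]
  roots
}

# near-consistent full states from the module decomposition: sweep a
# coarse grid of module-1 inputs, solve module 1, push the coupling
# scalar through module 2, and pair the solutions; lands very close to
# every true steady state for a fraction of the cost of a full-box sweep
module_consistency_seeds <- function(system, n_a = 16L, n_starts = 8L) {
  grid <- input_grid_for(system, 1L, n_a)
  seeds <- NULL
  prev <- NULL
  for (a in grid) {
    rx <- tryCatch(
      sweep_module_roots(system$module1, a, system$params,
                         n_starts = n_starts, root_tol = 1e-8,
                         extra_starts = prev),
      error = function(e) NULL)
    if (is.null(rx) || !nrow(rx)) { prev <- NULL; next }
    prev <- rx
    for (i in seq_len(nrow(rx))) {
      b <- tryCatch(system$coupling$beta(rx[i, ], system$params),
                    error = function(e) NA_real_)
      if (!is.finite(b)) next
      ry <- tryCatch(
        sweep_module_roots(system$module2, b, system$params,
                           n_starts = n_starts, root_tol = 1e-8),
        error = function(e) NULL)
      if (is.null(ry) || !nrow(ry)) next
      for (j in seq_len(nrow(ry)))
        seeds <- rbind(seeds, c(rx[i, ], ry[j, ]))
    }
  }
  seeds
}

#' Scan steady-state branches over a model parameter
#'
#' At each grid value every full-system steady state is located (warm
#' starting from the previous grid value), its Jacobian eigenvalues and
#' stability recorded, and states are linked into branches across the
#' grid by nearest-neighbor continuation.
#'
#' @param system a `pn_system`.
#' @param param scanned parameter name (must exist in the parameter set).
#' @param grid sorted numeric vector of parameter values.
#' @param n_starts Halton starts per grid value.
#' @param root_tol residual tolerance.
#' @return a `pn_diagram`: list with `param`, `grid`, `roots` (per-grid
#'   state matrices), `eigen` (per-grid lists of eigenvalue vectors),
#'   `branches` (data frames with `param`, states, `stability`,
#'   `lambda_min`, `re_pair`, `im_pair`).
#' @export
scan_steady_states <- function(system, param, grid, n_starts = 80L,
                               root_tol = 1e-9) {
  if (!param %in% names(system$params))
    stop("unknown parameter: ", param)
  grid <- sort(as.numeric(grid))
  roots_at <- vector("list", length(grid))
  eig_at <- vector("list", length(grid))
  prev <- NULL; prev2 <- NULL
  for (i in seq_along(grid)) {
    sys_i <- set_param(system, param, grid[i])
    # warm-start from the previous two grid values AND re-seed from the
    # module decomposition at every point: warm starts alone can lose a
    # sheet when a root's Newton basin deforms between grid values
    r <- full_system_roots(sys_i, n_starts = n_starts,
                           root_tol = root_tol,
                           extra_starts = rbind(prev, prev2),
                           module_seeds = TRUE)
    ev <- lapply(seq_len(nrow(r)), function(k)
      eigen(full_jacobian(sys_i, r[k, ]), only.values = TRUE)$values)
    roots_at[[i]] <- r
    eig_at[[i]] <- ev
    prev2 <- prev
    prev <- r
  }
  branches <- link_diagram_branches(grid, roots_at, eig_at, system)
  structure(list(param = param, grid = grid, roots = roots_at,
                 eigen = eig_at, branches = branches, system = system),
            class = "pn_diagram")
}

link_diagram_branches <- function(grid, roots_at, eig_at, system) {
  b1 <- module_bounds(system$module1, system$params, NA)
  b2 <- module_bounds(system$module2, system$params, NA)
  scale <- pmax(c(b1[2, ] - b1[1, ], b2[2, ] - b2[1, ]), 1e-12)
  open <- list(); done <- list()
  for (i in seq_along(grid)) {
    r <- roots_at[[i]]
    ev <- eig_at[[i]]
    nr <- nrow(r)
    taken <- rep(FALSE, max(nr, 0))
    still <- logical(length(open))
    if (length(open) && nr > 0) {
      dm <- matrix(Inf, length(open), nr)
      for (bi in seq_along(open))
        for (ri in seq_len(nr))
          dm[bi, ri] <- max(abs((r[ri, ] - open[[bi]]$last) / scale))
      while (TRUE) {
        m <- which(dm == min(dm), arr.ind = TRUE)
        if (!nrow(m) || !is.finite(dm[m[1, 1], m[1, 2]]) ||
            dm[m[1, 1], m[1, 2]] > 0.25) break
        bi <- m[1, 1]; ri <- m[1, 2]
        open[[bi]]$rows[[length(open[[bi]]$rows) + 1L]] <-
          branch_row(grid[i], r[ri, ], ev[[ri]])
        open[[bi]]$last <- r[ri, ]
        still[bi] <- TRUE; taken[ri] <- TRUE
        dm[bi, ] <- Inf; dm[, ri] <- Inf
      }
    }
    done <- c(done, open[!still])
    open <- open[still]
    for (ri in which(!taken))
      open[[length(open) + 1L]] <-
        list(rows = list(branch_row(grid[i], r[ri, ], ev[[ri]])),
             last = r[ri, ])
  }
  done <- c(done, open)
  lapply(seq_along(done), function(k) {
    df <- do.call(rbind, done[[k]]$rows)
    df$branch_id <- k
    df
  })
}

branch_row <- function(p, state, ev) {
  cpx <- ev[abs(Im(ev)) > 1e-9]
  re_pair <- if (length(cpx)) max(Re(cpx)) else NA_real_
  im_pair <- if (length(cpx)) abs(Im(cpx[which.max(Re(cpx))])) else NA_real_
  df <- as.data.frame(as.list(state))
  df$param <- p
  df$stability <- stability_label(ev)
  df$lambda_min <- min(Mod(ev))
  df$re_max <- max(Re(ev))
  df$re_pair <- re_pair
  df$im_pair <- im_pair
  df
}

#' Detect saddle-node (fold) events on a branch diagram
#'
#' A fold is flagged wherever the steady-state count changes by two
#' between adjacent grid values; the event parameter is refined by
#' bisection on the appearance/disappearance of the coalescing root pair
#' and cross-checked against the smallest-magnitude Jacobian eigenvalue
#' at the fold state.
#'
#' @param diagram a `pn_diagram`.
#' @param par_tol bisection tolerance on the parameter.
#' @param sn_tol eigenvalue-magnitude tolerance for the cross-check.
#' @param n_starts multistart budget during bisection.
#' @return list of `pn_event` objects of type "SN" with fields
#'   `param_value`, `bracket`, `state`, `diagnostics` (`lambda_min`,
#'   `boundary`).
#' @export
detect_folds <- function(diagram, par_tol = 1e-7, sn_tol = 1e-5,
                         n_starts = 60L) {
  grid <- diagram$grid
  counts <- vapply(diagram$roots, nrow, 0L)
  events <- list()
  for (i in seq_len(length(grid) - 1L)) {
    dc <- counts[i + 1L] - counts[i]
    if (dc == 0) next
    rich <- if (dc < 0) diagram$roots[[i]] else diagram$roots[[i + 1L]]
    ev <- refine_fold(diagram$system, diagram$param,
                      grid[i], grid[i + 1L], rich,
                      par_tol = par_tol, sn_tol = sn_tol,
                      n_starts = n_starts)
    if (!is.null(ev)) events[[length(events) + 1L]] <- ev
  }
  # a fold sitting exactly on a grid value shows as two adjacent count
  # changes refining to the same parameter: merge them
  if (length(events) > 1) {
    pv <- vapply(events, function(e) e$param_value, 0)
    keep <- !duplicated_close(pv, max(1e-6, 100 * par_tol))
    events <- events[keep]
  }
  events
}

duplicated_close <- function(x, tol) {
  dup <- logical(length(x))
  for (i in seq_along(x)) {
    if (dup[i]) next
    later <- which(seq_along(x) > i & abs(x - x[i]) <= tol)
    dup[later] <- TRUE
  }
  dup
}

refine_fold <- function(system, param, lo, hi, warm,
                        par_tol = 1e-7, sn_tol = 1e-5, n_starts = 60L) {
  count_at <- function(p, w) {
    # warm starts from the bracket ends carry the coalescing pair;
    # module seeding is redundant (and slow) inside the bisection
    full_system_roots(set_param(system, param, p),
                      n_starts = n_starts, extra_starts = w,
                      module_seeds = FALSE)
  }
  r_lo <- count_at(lo, warm); r_hi <- count_at(hi, warm)
  c_lo <- nrow(r_lo); c_hi <- nrow(r_hi)
  if (c_lo == c_hi) return(NULL)
  while (hi - lo > par_tol) {
    mid <- (lo + hi) / 2
    r_mid <- count_at(mid, rbind(r_lo, r_hi))
    if (nrow(r_mid) == c_lo) { lo <- mid; r_lo <- r_mid }
    else { hi <- mid; r_hi <- r_mid; c_hi <- nrow(r_mid) }
  }
  # coalescing pair = two closest roots on the root-rich side
  rich <- if (c_lo > c_hi) r_lo else r_hi
  state <- fold_state_from(rich)
  p_star <- (lo + hi) / 2
  lam <- tryCatch({
    J <- full_jacobian(set_param(system, param, p_star), state)
    min(Mod(eigen(J, only.values = TRUE)$values))
  }, error = function(e) NA_real_)
  structure(list(type = "SN", param = param, param_value = p_star,
                 bracket = c(lo, hi), state = state,
                 diagnostics = list(lambda_min = lam,
                                    lambda_ok = is.finite(lam) && lam <= max(sn_tol, 1e-3),
                                    sn_tol = sn_tol)),
            class = "pn_event")
}

fold_state_from <- function(rich) {
  n <- nrow(rich)
  if (n < 2) return(rich[1, ])
  best <- c(1L, 2L); bd <- Inf
  for (a in seq_len(n - 1L)) for (b in seq.int(a + 1L, n)) {
    d <- max(abs(rich[a, ] - rich[b, ]))
    if (d < bd) { bd <- d; best <- c(a, b) }
  }
  (rich[best[1], ] + rich[best[2], ]) / 2
}

#' Detect Hopf events on a branch diagram
#'
#' A Hopf event is flagged wherever the real part of a branch state's
#' leading complex-conjugate eigenvalue pair changes sign along the
#' branch (real-eigenvalue sign changes are folds and are excluded), and
#' refined by bisection re-solving the steady state at intermediate
#' parameter values.
#'
#' @param diagram a `pn_diagram`.
#' @param par_tol bisection tolerance on the parameter.
#' @param hopf_tol tolerance on |Re| of the pair at the located point.
#' @return list of `pn_event` objects of type "Hopf" with diagnostics
#'   `re_pair`, `im_pair`.
#' @export
detect_hopf <- function(diagram, par_tol = 1e-7, hopf_tol = 1e-6) {
  system <- diagram$system
  param <- diagram$param
  events <- list()
  sn <- system$state_names
  for (br in diagram$branches) {
    if (nrow(br) < 2) next
    h <- br$re_pair
    for (i in seq_len(nrow(br) - 1L)) {
      if (any(!is.finite(h[c(i, i + 1L)]))) next
      if (h[i] == 0 || sign(h[i]) == sign(h[i + 1L])) next
      lo <- br$param[i]; hi <- br$param[i + 1L]
      s_lo <- unlist(br[i, sn]); h_lo <- h[i]
      s_hi <- unlist(br[i + 1L, sn])
      while (hi - lo > par_tol) {
        mid <- (lo + hi) / 2
        guess <- (s_lo + s_hi) / 2
        sys_m <- set_param(system, param, mid)
        sol <- newton_solve(function(s) full_rhs(sys_m, s), guess,
                            tol = 1e-10)
        if (!sol$converged) break
        ev <- eigen(full_jacobian(sys_m, sol$root),
                    only.values = TRUE)$values
        cpx <- ev[abs(Im(ev)) > 1e-9]
        if (!length(cpx)) break
        hm <- max(Re(cpx))
        if (sign(hm) == sign(h_lo)) { lo <- mid; s_lo <- sol$root }
        else { hi <- mid; s_hi <- sol$root }
      }
      p_star <- (lo + hi) / 2
      sys_s <- set_param(system, param, p_star)
      sol <- newton_solve(function(s) full_rhs(sys_s, s),
                          (s_lo + s_hi) / 2, tol = 1e-10)
      ev <- eigen(full_jacobian(sys_s, sol$root), only.values = TRUE)$values
      cpx <- ev[abs(Im(ev)) > 1e-9]
      if (!length(cpx)) next
      events[[length(events) + 1L]] <-
        structure(list(type = "Hopf", param = param, param_value = p_star,
                       bracket = c(lo, hi),
                       state = stats::setNames(sol$root, sn),
                       diagnostics = list(re_pair = max(Re(cpx)),
                                          im_pair = abs(Im(cpx[which.max(Re(cpx))])),
                                          hopf_tol = hopf_tol)),
                  class = "pn_event")
    }
  }
  events
}

#' Tangency gap between the two pseudo-nullclines
#'
#' A smooth non-negative scalar that vanishes exactly at a tangential
#' contact: the minimum, over closest-approach regions and crossings, of
#' the perpendicular curve separation plus `len_scale * (1 - |cos
#' theta|)` of the tangent misalignment. Locating its near-zero minima
#' along a parameter scan finds saddle-node geometry from the curves
#' alone.
#'
#' @param system a `pn_system` whose `input_param` field names the
#'   scanned parameter.
#' @param input_value value of that parameter.
#' @param n_grid curve-tracing resolution.
#' @param len_scale weight of the angular term, in plot units; defaults
#'   to a tenth of the combined curve bounding-box diagonal.
#' @param n_starts multistart budget per swept input.
#' @return the gap value, with attributes `location` (planar point) and
#'   `separation`, `angle_deg` at the minimizer.
#' @export
tangency_gap <- function(system, input_value, n_grid = 200L,
                         len_scale = NULL, n_starts = 40L) {
  sys <- set_param(system, system$input_param, input_value)
  gr1 <- input_grid_for(sys, 1L, n_grid)
  gr2 <- input_grid_for(sys, 2L, n_grid)
  pn1 <- trace_pseudo_nullcline(sys$module1, params = sys$params,
                                grid = gr1, module_id = 1L,
                                n_starts = n_starts)
  pn2 <- trace_pseudo_nullcline(sys$module2, params = sys$params,
                                grid = gr2, module_id = 2L,
                                n_starts = n_starts)
  c1 <- project_curve(pn1, sys)
  c2 <- project_curve(pn2, sys)
  planar_tangency_gap(c1, c2, len_scale = len_scale)
}

#' @rdname tangency_gap
#' @param c1,c2 projected `pn_planar` curves (alternative direct entry).
#' @export
planar_tangency_gap <- function(c1, c2, len_scale = NULL) {
  pts1 <- do.call(rbind, lapply(c1$branches, function(d) cbind(d$u, d$v)))
  pts2 <- do.call(rbind, lapply(c2$branches, function(d) cbind(d$u, d$v)))
  if (is.null(pts1) || is.null(pts2) || nrow(pts1) < 2 || nrow(pts2) < 2) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  if (is.null(len_scale)) {
    bb <- rbind(pts1, pts2)
    len_scale <- 0.1 * sqrt(sum((apply(bb, 2, max) - apply(bb, 2, min))^2))
  }
  best <- Inf; best_loc <- c(NA_real_, NA_real_)
  best_d <- NA_real_; best_ang <- NA_real_
  for (b1 in seq_along(c1$branches)) {
    A <- c1$branches[[b1]]
    if (nrow(A) < 3) next
    for (b2 in seq_along(c2$branches)) {
      B <- c2$branches[[b2]]
      if (nrow(B) < 2) next
      res <- curve_gap_minima(A$u, A$v, B$u, B$v, len_scale)
      if (nrow(res)) {
        k <- which.min(res$gap)
        if (res$gap[k] < best) {
          best <- res$gap[k]
          best_loc <- c(res$u[k], res$v[k])
          best_d <- res$d[k]; best_ang <- res$angle[k]
        }
      }
    }
  }
  out <- if (is.finite(best)) best else NA_real_
  attr(out, "location") <- best_loc
  attr(out, "separation") <- best_d
  attr(out, "angle_deg") <- best_ang
  attr(out, "len_scale") <- len_scale
  out
}

curve_gap_minima <- function(ax, ay, bx, by, len_scale) {
  nA <- length(ax)
  qx0 <- bx[-length(bx)]; qy0 <- by[-length(by)]
  qx <- diff(bx); qy <- diff(by)
  len2 <- pmax(qx^2 + qy^2, 1e-300)
  d <- numeric(nA); seg <- integer(nA); ang <- numeric(nA)
  for (k in seq_len(nA)) {
    t <- ((ax[k] - qx0) * qx + ((ay[k] - qy0) * qy)) / len2
    t <- pmin(1, pmax(0, t))
    ex <- qx0 + t * qx - ax[k]
    ey <- qy0 + t * qy - ay[k]
    dk <- ex^2 + ey^2
    m <- which.min(dk)
    d[k] <- sqrt(dk[m]); seg[k] <- m
    # tangents: curve A at k, curve B at segment m
    ka <- max(2L, min(k, nA - 1L))
    ta <- c(ax[ka + 1L] - ax[ka - 1L], ay[ka + 1L] - ay[ka - 1L])
    tb <- c(qx[m], qy[m])
    cs <- abs(sum(ta * tb)) / sqrt(sum(ta^2) * sum(tb^2) + 1e-300)
    ang[k] <- acos(pmin(1, cs)) * 180 / pi
  }
  gap <- d + len_scale * (1 - cos(ang * pi / 180))
  loc <- which(gap <= c(gap[-1], Inf) & gap <= c(Inf, gap[-nA]))
  data.frame(u = ax[loc], v = ay[loc], d = d[loc], angle = ang[loc],
             gap = gap[loc])
}

#' Locate a saddle-homoclinic / SNIC candidate by period divergence
#'
#' Bisects a parameter bracket that has a stable limit cycle at one end
#' and none at the other, monitoring the cycle period; near a
#' saddle-homoclinic connection the period diverges logarithmically. The
#' event is labelled `SHom_candidate` when a saddle steady state exists
#' inside the bracket, `SNIC_candidate` otherwise.
#'
#' @param system a `pn_system` with `input_param` set.
#' @param bracket length-2 parameter interval.
#' @param observable state name used for cycle detection.
#' @param x0 initial state for the probing integrations (default: the
#'   model's `default_initial`).
#' @param t_end base integration horizon, doubled (up to `t_max`) when
#'   detection is inconclusive near the divergence.
#' @param t_max cap on the integration horizon.
#' @param par_tol bracket width at which bisection stops.
#' @param period_cap factor over the period at the oscillatory end that
#'   the last oscillatory period must exceed.
#' @return a `pn_event` of type "SHom_candidate" or "SNIC_candidate"
#'   with diagnostics `period_series` (parameter, period) and
#'   `period_cap_met`.
#' @export
locate_shom <- function(system, bracket, observable, x0 = NULL,
                        t_end = 2000, t_max = 64000, par_tol = 1e-4,
                        period_cap = 20) {
  stopifnot(length(bracket) == 2)
  if (is.null(x0)) x0 <- system$default_initial
  if (is.null(x0)) stop("no initial state: pass x0")
  probe <- function(p) {
    sys_p <- set_param(system, system$input_param, p)
    te <- t_end
    repeat {
      traj <- integrate_system(sys_p, x0, te,
                               n_out = max(4000L, as.integer(te / 2)))
      lc <- detect_limit_cycle(traj, observable)
      if (!isTRUE(lc$inconclusive) || te >= t_max) return(lc)
      te <- te * 2
    }
  }
  lc_a <- probe(bracket[1]); lc_b <- probe(bracket[2])
  osc_a <- isTRUE(lc_a$exists); osc_b <- isTRUE(lc_b$exists)
  if (osc_a == osc_b)
    stop("bracket must have a limit cycle at exactly one end ",
         "(got ", osc_a, "/", osc_b, ")")
  lo <- bracket[1]; hi <- bracket[2]
  osc_lo <- osc_a
  base_period <- if (osc_a) lc_a$period else lc_b$period
  series <- data.frame(param = bracket,
                       period = c(lc_a$period, lc_b$period))
  last_osc_period <- base_period
  while (hi - lo > par_tol) {
    mid <- (lo + hi) / 2
    lc <- probe(mid)
    osc_mid <- isTRUE(lc$exists)
    series <- rbind(series, data.frame(param = mid, period = lc$period))
    if (osc_mid) last_osc_period <- lc$period
    if (osc_mid == osc_lo) lo <- mid else hi <- mid
  }
  p_star <- (lo + hi) / 2
  cap_met <- is.finite(last_osc_period) &&
    last_osc_period >= period_cap * base_period
  # saddle check at the candidate
  sys_s <- set_param(system, system$input_param, p_star)
  roots <- full_system_roots(sys_s)
  labs <- vapply(seq_len(nrow(roots)), function(k)
    stability_label(eigen(full_jacobian(sys_s, roots[k, ]),
                          only.values = TRUE)$values), "")
  type <- if (any(labs == "saddle")) "SHom_candidate" else "SNIC_candidate"
  structure(list(type = type, param = system$input_param,
                 param_value = p_star, bracket = c(lo, hi),
                 state = if (any(labs == "saddle"))
                   roots[which(labs == "saddle")[1], ] else NULL,
                 diagnostics = list(period_series =
                                      series[order(series$param), ],
                                    base_period = base_period,
                                    last_osc_period = last_osc_period,
                                    period_cap_met = cap_met)),
            class = "pn_event")
}

#' @export
print.pn_event <- function(x, ...) {
  cat("<pn_event> ", x$type, " at ", x$param, " = ",
      format(x$param_value, digits = 10), "\n", sep = "")
  invisible(x)
}
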