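#' Find all steady states of one module at a fixed scalar input
#'
#' Multi-start damped-Newton sweep: deterministic Halton start points over
#' the module's state box (plus any caller-supplied warm starts), each
#' polished to a root of `rhs(x, input) = 0`, converged roots deduplicated.
#' Returning *all* distinct roots is what makes fold handling work: on an
#' S-shaped solution set every sheet is found at every input.
#'
#' @param module a `pn_module`.
#' @param input_value scalar module input.
#' @param params parameter set.
#' @param n_starts number of Halton start points.
#' @param root_tol max-norm residual tolerance for an accepted root.
#' @param dedupe_tol relative max-norm tolerance for deduplication.
#' @param extra_starts optional matrix of additional start points (e.g.
#'   roots from a neighboring input during curve tracing).
#' @param margin_frac accepted roots may lie outside the state box by this
#'   fraction of its range (guards against dropping genuine roots near the
#'   box edge without accepting runaways).
#' @return matrix of roots (one per row, module state columns) with
#'   attribute `residuals`; zero rows if no root was found.
#' @export
sweep_module_roots <- function(module, input_value, params,
                               n_starts = 40L, root_tol = 1e-9,
                               dedupe_tol = 1e-6, extra_starts = NULL,
                               margin_frac = 0.25) {
  b <- module_bounds(module, params, input_value)
  lower <- b[1, ]; upper <- b[2, ]
  starts <- rbind(halton_points(n_starts, lower, upper, skip = 1L),
                  box_corner_starts(lower, upper))
  if (!is.null(extra_starts) && nrow(extra_starts) > 0)
    starts <- rbind(as.matrix(extra_starts), starts)
  f <- function(x) module$rhs(x, input_value, params)
  rng <- pmax(upper - lower, 1e-12)
  lo_ok <- lower - margin_frac * rng
  hi_ok <- upper + margin_frac * rng
  roots <- NULL; resids <- numeric(0)
  for (i in seq_len(nrow(starts))) {
    sol <- newton_solve(f, starts[i, ], tol = root_tol, scale = rng)
    if (sol$converged &&
        all(sol$root >= lo_ok) && all(sol$root <= hi_ok)) {
      roots <- rbind(roots, sol$root)
      resids <- c(resids, sol$resid)
    }
  }
  if (is.null(roots)) {
    out <- matrix(numeric(0), 0, module$dim,
                  dimnames = list(NULL, module$state_names))
    attr(out, "residuals") <- numeric(0)
    return(out)
  }
  scale <- max(1, max(abs(c(lower, upper))))
  mr <- merge_roots(roots, resids, f, root_tol, dedupe_tol * scale)
  roots <- mr$roots
  colnames(roots) <- module$state_names
  ord <- order(roots[, 1])
  roots <- roots[ord, , drop = FALSE]
  attr(roots, "residuals") <- mr$resids[ord]
  roots
}

module_bounds <- function(module, params, input_value) {
  b <- module$bounds
  if (is.function(b)) b <- b(params, input_value)
  as.matrix(b)
}

duplicated_within <- function(mat, tol) {
  n <- nrow(mat)
  dup <- logical(n)
  if (n < 2) return(dup)
  for (i in 2:n) {
    for (j in seq_len(i - 1L)) {
      if (!dup[j] && max(abs(mat[i, ] - mat[j, ])) <= tol) {
        dup[i] <- TRUE
        break
      }
    }
  }
  dup
}

#' Trace a module's pseudo-nullcline over a range of inputs
#'
#' Sweeps the module's steady-state equation over a grid of input values,
#' warm-starting each sweep from the neighboring grid value's roots, then
#' links the collected `(input, state)` points into branches by
#' nearest-neighbor continuation with a jump guard. Intervals where the
#' root count changes (folds) are refined adaptively.
#'
#' @param module a `pn_module`.
#' @param input_range length-2 numeric, scanned input interval; ignored
#'   when `grid` is given.
#' @param params parameter set.
#' @param grid optional explicit (sorted) input grid; otherwise uniform
#'   over `input_range`.
#' @param n_grid grid resolution (default 200).
#' @param refine_depth rounds of bisection refinement around root-count
#'   changes.
#' @param module_id 1 or 2, recorded for projection defaults.
#' @param link_tol nearest-neighbor linking tolerance, as a fraction of
#'   the state-box diagonal per grid step.
#' @inheritParams sweep_module_roots
#' @return a `pn_nullcline`: list with `branches` (data frames with
#'   columns `input`, the module states, `residual`), `module`,
#'   `module_id`, `input_range`.
#' @export
trace_pseudo_nullcline <- function(module, input_range = NULL, params,
                                   grid = NULL, n_grid = 200L,
                                   refine_depth = 3L, module_id = 1L,
                                   n_starts = 40L, root_tol = 1e-9,
                                   dedupe_tol = 1e-6, link_tol = 0.2) {
  if (is.null(grid)) {
    stopifnot(length(input_range) == 2, all(is.finite(input_range)))
    grid <- seq(input_range[1], input_range[2], length.out = n_grid)
  }
  grid <- sort(unique(as.numeric(grid)))
  if (is.null(input_range)) input_range <- range(grid)

  roots_at <- vector("list", length(grid))
  prev <- NULL
  for (i in seq_along(grid)) {
    roots_at[[i]] <- sweep_module_roots(module, grid[i], params,
                                        n_starts = n_starts,
                                        root_tol = root_tol,
                                        dedupe_tol = dedupe_tol,
                                        extra_starts = prev)
    prev <- roots_at[[i]]
  }

  # adaptive refinement where the root count changes between neighbors
  # (folds) or where the solution jumps by more than the linking
  # tolerance (steep knees that would otherwise break branches apart)
  b0 <- module_bounds(module, params, grid[1])
  jump_scale <- pmax(b0[2, ] - b0[1, ], 1e-12)
  for (round in seq_len(refine_depth)) {
    counts <- vapply(roots_at, nrow, 0L)
    n <- length(grid)
    jumpy <- vapply(seq_len(n - 1L), function(i) {
      a <- roots_at[[i]]; b <- roots_at[[i + 1L]]
      if (!nrow(a) || !nrow(b)) return(FALSE)
      gap <- max(vapply(seq_len(nrow(a)), function(k)
        min(vapply(seq_len(nrow(b)), function(l)
          max(abs((a[k, ] - b[l, ]) / jump_scale)), 0)), 0))
      gap > 0.5 * link_tol
    }, logical(1))
    ins <- which(counts[-1] != counts[-n] | jumpy)
    if (!length(ins)) break
    new_grid <- (grid[ins] + grid[ins + 1]) / 2
    new_roots <- vector("list", length(new_grid))
    for (k in seq_along(new_grid)) {
      warm <- rbind(roots_at[[ins[k]]], roots_at[[ins[k] + 1]])
      new_roots[[k]] <- sweep_module_roots(module, new_grid[k], params,
                                           n_starts = n_starts,
                                           root_tol = root_tol,
                                           dedupe_tol = dedupe_tol,
                                           extra_starts = warm)
    }
    grid <- c(grid, new_grid)
    roots_at <- c(roots_at, new_roots)
    ord <- order(grid)
    grid <- grid[ord]
    roots_at <- roots_at[ord]
  }

  branches <- link_branches(grid, roots_at, module, params, link_tol)
  if (!length(branches))
    warning("empty pseudo-nullcline: no module steady state in input range")
  structure(list(branches = branches, module = module,
                 module_id = module_id, input_range = input_range,
                 grid = grid),
            class = "pn_nullcline")
}

# nearest-neighbor branch linking across the input grid
link_branches <- function(grid, roots_at, module, params, link_tol) {
  scale <- NULL
  open <- list()    # each: list(rows = list of c(input, state, resid))
  done <- list()
  for (i in seq_along(grid)) {
    r <- roots_at[[i]]
    res <- attr(r, "residuals")
    if (is.null(scale)) {
      b <- module_bounds(module, params, grid[i])
      scale <- pmax(b[2, ] - b[1, ], 1e-12)
    }
    nr <- nrow(r)
    taken <- rep(FALSE, max(nr, 0))
    still_open <- logical(length(open))
    if (length(open) && nr > 0) {
      dm <- matrix(Inf, length(open), nr)
      for (bi in seq_along(open)) {
        last <- open[[bi]]$last
        for (ri in seq_len(nr))
          dm[bi, ri] <- max(abs((r[ri, ] - last) / scale))
      }
      # greedy closest-pair matching with jump guard
      while (TRUE) {
        m <- which(dm == min(dm), arr.ind = TRUE)
        if (!nrow(m) || !is.finite(dm[m[1, 1], m[1, 2]]) ||
            dm[m[1, 1], m[1, 2]] > link_tol) break
        bi <- m[1, 1]; ri <- m[1, 2]
        open[[bi]]$rows[[length(open[[bi]]$rows) + 1L]] <-
          c(grid[i], r[ri, ], res[ri])
        open[[bi]]$last <- r[ri, ]
        still_open[bi] <- TRUE
        taken[ri] <- TRUE
        dm[bi, ] <- Inf
        dm[, ri] <- Inf
      }
    }
    done <- c(done, open[!still_open & seq_along(open) > 0])
    open <- open[still_open]
    if (nr > 0) {
      for (ri in which(!taken)) {
        open[[length(open) + 1L]] <-
          list(rows = list(c(grid[i], r[ri, ], res[ri])), last = r[ri, ])
      }
    }
  }
  done <- c(done, open)
  done <- Filter(function(b) length(b$rows) >= 1, done)
  out <- lapply(seq_along(done), function(k) {
    m <- do.call(rbind, done[[k]]$rows)
    df <- as.data.frame(m)
    names(df) <- c("input", module$state_names, "residual")
    df$branch_id <- k
    df
  })
  out
}

#' Project a pseudo-nullcline onto the coupling plane
#'
#' Maps every traced branch point to planar coordinates `(u, v)`. The
#' default projection is the coupling plane itself: for module 1 the
#' point `(beta(x), input)` and for module 2 `(input, alpha(y))`, i.e.
#' the plane of the two coupling scalars. Models may override this with
#' a transform using the full module solution vector (the cell-cycle
#' model plots `(Cyc_tot, Cdk1_a)`; the 2+2 motif plots `(X, Z)`).
#'
#' @param pnc a `pn_nullcline`.
#' @param system the `pn_system` the module belongs to (provides the
#'   coupling map, parameters and any model-specific projection).
#' @param transform optional function `(input, state, params)` returning
#'   `c(u, v)`; overrides the system default.
#' @return a `pn_planar`: list with `branches` (data frames `u`, `v`,
#'   `input`, states, `residual`, `branch_id`), `labels`, `module_id`.
#' @export
project_curve <- function(pnc, system, transform = NULL) {
  mid <- pnc$module_id
  params <- system$params
  if (is.null(transform) && !is.null(system$projection))
    transform <- system$projection[[mid]]
  if (is.null(transform)) {
    transform <- if (mid == 1L) {
      function(input, state, params)
        c(system$coupling$beta(state, params), input)
    } else {
      function(input, state, params)
        c(input, system$coupling$alpha(state, params))
    }
  }
  labels <- if (!is.null(system$plane_labels)) system$plane_labels
            else system$coupling$labels
  sn <- pnc$module$state_names
  branches <- lapply(pnc$branches, function(df) {
    uv <- t(vapply(seq_len(nrow(df)), function(i) {
      p <- tryCatch(
        transform(df$input[i], unlist(df[i, sn]), params),
        error = function(e) c(NA_real_, NA_real_))
      as.numeric(p)
    }, numeric(2)))
    out <- cbind(data.frame(u = uv[, 1], v = uv[, 2]), df)
    dropped <- !is.finite(out$u) | !is.finite(out$v)
    out[!dropped, , drop = FALSE]
  })
  branches <- Filter(function(df) nrow(df) > 0, branches)
  structure(list(branches = branches, labels = labels,
                 module_id = mid, state_names = sn),
            class = "pn_planar")
}

#' Locate candidate intersections of two planar curves
#'
#' Exact segment-pair crossings of the two polylines, deduplicated within
#' `geom_tol`, plus "grazing" candidates: local closest approaches within
#' `graze_tol` that do not cross. Grazing contacts are the geometric
#' signature of a nearby saddle-node and are surfaced, not discarded.
#'
#' @param c1,c2 `pn_planar` curves in the same plane.
#' @param geom_tol deduplication tolerance in plot units.
#' @param graze_tol distance threshold for grazing candidates (default:
#'   no grazing detection unless set).
#' @return data frame with columns `u`, `v`, `type` ("crossing"/"grazing")
#'   and provenance columns (`b1`, `i1`, `t1`, `b2`, `i2`, `t2`: branch,
#'   segment index and segment parameter on each curve).
#' @export
find_intersections <- function(c1, c2, geom_tol = 1e-4, graze_tol = NULL) {
  if (!inherits(c1, "pn_planar") || !inherits(c2, "pn_planar"))
    stop("find_intersections expects two pn_planar curves")
  if (!identical(c1$labels, c2$labels))
    stop("curves live in different planes: ",
         paste(c1$labels, collapse = "/"), " vs ",
         paste(c2$labels, collapse = "/"))
  out <- NULL
  for (b1 in seq_along(c1$branches)) {
    A <- c1$branches[[b1]]
    if (nrow(A) < 2) next
    for (b2 in seq_along(c2$branches)) {
      B <- c2$branches[[b2]]
      if (nrow(B) < 2) next
      hits <- segment_crossings(A$u, A$v, B$u, B$v)
      if (nrow(hits)) {
        hits$b1 <- b1; hits$b2 <- b2
        hits$type <- "crossing"
        out <- rbind(out, hits)
      }
      if (!is.null(graze_tol)) {
        g <- grazing_contacts(A$u, A$v, B$u, B$v, graze_tol)
        if (nrow(g)) {
          g$b1 <- b1; g$b2 <- b2
          g$type <- "grazing"
          out <- rbind(out, g)
        }
      }
    }
  }
  if (is.null(out))
    return(data.frame(u = numeric(0), v = numeric(0), type = character(0),
                      b1 = integer(0), i1 = integer(0), t1 = numeric(0),
                      b2 = integer(0), i2 = integer(0), t2 = numeric(0)))
  # dedupe crossings within geom_tol (keep first), then grazings that
  # duplicate a crossing
  ord <- order(out$type)  # crossings first
  out <- out[ord, ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) {
      for (j in seq.int(i + 1L, nrow(out))) {
        if (keep[j] &&
            max(abs(c(out$u[i] - out$u[j], out$v[i] - out$v[j]))) <= geom_tol)
          keep[j] <- FALSE
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[, c("u", "v", "type", "b1", "i1", "t1", "b2", "i2", "t2")]
}

# all crossings between polyline (ax, ay) and polyline (bx, by)
segment_crossings <- function(ax, ay, bx, by) {
  n1 <- length(ax) - 1L
  n2 <- length(bx) - 1L
  empty <- data.frame(u = numeric(0), v = numeric(0), i1 = integer(0),
                      t1 = numeric(0), i2 = integer(0), t2 = numeric(0))
  if (n1 < 1 || n2 < 1) return(empty)
  i <- rep(seq_len(n1), each = n2)
  j <- rep(seq_len(n2), times = n1)
  px <- ax[i]; py <- ay[i]
  rx <- ax[i + 1] - px; ry <- ay[i + 1] - py
  qx0 <- bx[j]; qy0 <- by[j]
  qx <- bx[j + 1] - qx0; qy <- by[j + 1] - qy0
  den <- rx * qy - ry * qx
  dx <- qx0 - px; dy <- qy0 - py
  t1 <- (dx * qy - dy * qx) / den
  t2 <- (dx * ry - dy * rx) / den
  ok <- is.finite(t1) & is.finite(t2) &
    t1 >= 0 & t1 <= 1 & t2 >= 0 & t2 < 1
  if (!any(ok)) return(empty)
  data.frame(u = px[ok] + t1[ok] * rx[ok], v = py[ok] + t1[ok] * ry[ok],
             i1 = i[ok], t1 = t1[ok], i2 = j[ok], t2 = t2[ok])
}

# local closest-approach points of curve A to polyline B within tol
grazing_contacts <- function(ax, ay, bx, by, tol) {
  empty <- data.frame(u = numeric(0), v = numeric(0), i1 = integer(0),
                      t1 = numeric(0), i2 = integer(0), t2 = numeric(0))
  nA <- length(ax)
  n2 <- length(bx) - 1L
  if (nA < 3 || n2 < 1) return(empty)
  qx0 <- bx[-length(bx)]; qy0 <- by[-length(by)]
  qx <- diff(bx); qy <- diff(by)
  len2 <- pmax(qx^2 + qy^2, 1e-300)
  d <- numeric(nA); seg <- integer(nA); tpar <- numeric(nA)
  for (k in seq_len(nA)) {
    t <- ((ax[k] - qx0) * qx + (ay[k] - qy0) * qy) / len2
    t <- pmin(1, pmax(0, t))
    ex <- qx0 + t * qx - ax[k]
    ey <- qy0 + t * qy - ay[k]
    dk <- ex^2 + ey^2
    m <- which.min(dk)
    d[k] <- sqrt(dk[m]); seg[k] <- m; tpar[k] <- t[m]
  }
  loc <- which(d <= tol)
  interior <- loc[loc > 1 & loc < nA]
  interior <- interior[d[interior] <= d[interior - 1] &
                         d[interior] <= d[interior + 1]]
  # branch endpoints count too: a fold tip grazing the other curve is
  # exactly the saddle-node geometry this detector exists for
  ends <- integer(0)
  if (nA >= 2 && d[1] <= tol && d[1] <= d[2]) ends <- c(ends, 1L)
  if (nA >= 2 && d[nA] <= tol && d[nA] <= d[nA - 1]) ends <- c(ends, nA)
  loc <- sort(unique(c(interior, ends)))
  if (!length(loc)) return(empty)
  data.frame(u = ax[loc], v = ay[loc], i1 = pmin(loc, nA - 1L),
             t1 = ifelse(loc == nA, 1, 0), i2 = seg[loc], t2 = tpar[loc])
}

#' Refine a candidate intersection to a full-system steady state and
#' classify it
#'
#' Assembles a full-state initial guess from the branch points flanking
#' the candidate on both curves, Newton-refines it to a root of the full
#' vector field, then classifies the contact (tangential vs. transversal)
#' and the stability from the full Jacobian's eigenvalues. The contact is
#' tangential when the smallest-magnitude eigenvalue is within `sn_tol`
#' of zero (the limit-point criterion, authoritative) or when the local
#' curve tangents align within `angle_tol` (reported as a diagnostic;
#' the eigenvalue criterion wins when the two disagree).
#'
#' @param candidate one row of [find_intersections()] output.
#' @param system the `pn_system`.
#' @param c1,c2 the projected curves the candidate came from.
#' @param root_tol residual tolerance for the refined state.
#' @param sn_tol eigenvalue-magnitude tolerance for tangency.
#' @param angle_tol tangent-alignment tolerance in degrees.
#' @param marg_tol |Re| below which stability is "marginal".
#' @return a `pn_intersection`: refined state, residual, eigenvalues,
#'   `classification` ("tangential"/"transversal"), `stability`,
#'   `angle_deg`, `converged`.
#' @export
refine_and_classify <- function(candidate, system, c1, c2,
                                root_tol = 1e-9, sn_tol = 1e-5,
                                angle_tol = 5, marg_tol = 1e-6) {
  g1 <- branch_state_at(c1, candidate$b1, candidate$i1, candidate$t1)
  g2 <- branch_state_at(c2, candidate$b2, candidate$i2, candidate$t2)
  x0 <- c(g1, g2)
  sol <- newton_solve(function(s) full_rhs(system, s), x0, tol = root_tol)
  J <- tryCatch(full_jacobian(system, sol$root), error = function(e) NULL)
  ev <- if (!is.null(J)) eigen(J, only.values = TRUE)$values else complex(0)
  ang <- tangent_angle(c1, c2, candidate)
  lam_min <- if (length(ev)) min(Mod(ev)) else NA_real_
  classification <- if (!is.na(lam_min) && lam_min <= sn_tol) "tangential"
                    else "transversal"
  uv <- refined_planar_point(system, sol$root)
  if (any(!is.finite(uv))) uv <- c(candidate$u, candidate$v)
  structure(list(
    u = uv[1], v = uv[2], type = candidate$type,
    u_candidate = candidate$u, v_candidate = candidate$v,
    state = stats::setNames(sol$root, system$state_names),
    residual = sol$resid, converged = sol$converged,
    eigenvalues = ev, lambda_min = lam_min,
    angle_deg = ang, tangential_by_angle = is.finite(ang) && ang <= angle_tol,
    classification = classification,
    stability = stability_label(ev, marg_tol)),
    class = "pn_intersection")
}

# planar image of a refined full state, via the system's trajectory
# projection or the default coupling-plane map
refined_planar_point <- function(system, state) {
  if (!is.null(system$trajectory_projection))
    return(tryCatch(
      as.numeric(system$trajectory_projection(state, system$params)),
      error = function(e) c(NA_real_, NA_real_)))
  x <- state[system$idx1]; y <- state[system$idx2]
  tryCatch(c(system$coupling$beta(x, system$params, y),
             system$coupling$alpha(y, system$params, x)),
           error = function(e) c(NA_real_, NA_real_))
}

branch_state_at <- function(pc, b, i, t) {
  df <- pc$branches[[b]]
  sn <- pc$state_names
  i2 <- min(i + 1L, nrow(df))
  (1 - t) * unlist(df[i, sn]) + t * unlist(df[i2, sn])
}

tangent_angle <- function(c1, c2, cand) {
  t1 <- branch_tangent(c1, cand$b1, cand$i1)
  t2 <- branch_tangent(c2, cand$b2, cand$i2)
  if (any(!is.finite(c(t1, t2)))) return(NA_real_)
  cs <- abs(sum(t1 * t2)) / sqrt(sum(t1^2) * sum(t2^2))
  acos(pmin(1, cs)) * 180 / pi
}

branch_tangent <- function(pc, b, i) {
  df <- pc$branches[[b]]
  i2 <- min(i + 1L, nrow(df))
  i1 <- max(1L, i2 - 1L)
  c(df$u[i2] - df$u[i1], df$v[i2] - df$v[i1])
}

stability_label <- function(ev, marg_tol = 1e-6) {
  if (!length(ev)) return("marginal")
  re <- Re(ev)
  if (min(abs(re)) <= marg_tol) return("marginal")
  lead <- ev[which.max(re)]
  if (all(re < 0))
    return(if (abs(Im(lead)) > 1e-12) "stable_focus" else "stable_node")
  # unstable: classify by the leading (largest real part) direction; a
  # complex leading pair is a focus-type instability (the Hopf side of
  # the method), a real one with stable directions remaining is a saddle
  if (abs(Im(lead)) > 1e-12) return("unstable_focus")
  if (all(re > 0)) return("unstable_node")
  "saddle"
}

#' One-call pseudo-nullcline analysis of a coupled system
#'
#' Traces both modules' pseudo-nullclines at the system's current
#' parameters, projects them, locates intersection candidates and refines
#' each to a classified steady state.
#'
#' @param system a `pn_system` (bundled models carry default input grids).
#' @param n_grid grid resolution for both curves.
#' @param geom_tol,graze_tol,root_tol,sn_tol,angle_tol tolerances, see
#'   the individual operations; `graze_tol = NULL` (default) enables
#'   grazing detection at 1/100 of the plane's bounding-box diagonal.
#' @param refine_depth fold-refinement rounds passed to the tracer.
#' @param n_starts multistart budget per swept input.
#' @return list with elements `c1`, `c2` (projected `pn_planar` curves),
#'   `candidates` (raw planar candidates) and `intersections` (list of
#'   `pn_intersection`).
#' @export
analyze_plane <- function(system, n_grid = 200L, geom_tol = 1e-4,
                          graze_tol = NULL, root_tol = 1e-9,
                          sn_tol = 1e-5, angle_tol = 5,
                          refine_depth = 3L, n_starts = 40L) {
  gr1 <- input_grid_for(system, 1L, n_grid)
  gr2 <- input_grid_for(system, 2L, n_grid)
  pn1 <- trace_pseudo_nullcline(system$module1, params = system$params,
                                grid = gr1, module_id = 1L,
                                refine_depth = refine_depth,
                                root_tol = root_tol, n_starts = n_starts)
  pn2 <- trace_pseudo_nullcline(system$module2, params = system$params,
                                grid = gr2, module_id = 2L,
                                refine_depth = refine_depth,
                                root_tol = root_tol, n_starts = n_starts)
  c1 <- project_curve(pn1, system)
  c2 <- project_curve(pn2, system)
  if (is.null(graze_tol)) {
    # near-miss contacts at the sampling scale are refined like
    # crossings: a polyline can terminate a fraction of a grid step
    # short of a genuine transversal crossing near a fold tip
    pts <- do.call(rbind, lapply(c(c1$branches, c2$branches),
                                 function(d) cbind(d$u, d$v)))
    graze_tol <- sqrt(sum((apply(pts, 2, max) -
                             apply(pts, 2, min))^2)) / 100
  }
  cand <- find_intersections(c1, c2, geom_tol = geom_tol,
                             graze_tol = graze_tol)
  ints <- lapply(seq_len(nrow(cand)), function(i)
    refine_and_classify(cand[i, ], system, c1, c2, root_tol = root_tol,
                        sn_tol = sn_tol, angle_tol = angle_tol))
  # a grazing candidate that neither polishes to a steady state nor
  # represents a degenerate (tangential) contact is a sampling artifact
  ints <- Filter(function(z) z$converged ||
                   z$classification == "tangential", ints)
  # drop refined duplicates (two grazing/crossing candidates can polish
  # to the same steady state)
  if (length(ints) > 1) {
    st <- do.call(rbind, lapply(ints, function(z) z$state))
    scale <- max(1, max(abs(st)))
    keep <- !duplicated_within(st, 1e-6 * scale)
    ints <- ints[keep]
  }
  list(c1 = c1, c2 = c2, candidates = cand, intersections = ints,
       nullcline1 = pn1, nullcline2 = pn2)
}

input_grid_for <- function(system, module_id, n_grid) {
  gf <- system$input_grids[[module_id]]
  if (is.null(gf)) stop("system has no default input grid for module ",
                        module_id, "; pass one explicitly")
  if (is.function(gf)) gf(system$params, n_grid) else gf
}
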