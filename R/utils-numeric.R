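#' Deterministic low-discrepancy start points
#'
#' Radical-inverse Halton sequence in `dim` dimensions, scaled to a box.
#' Used to seed multi-start Newton sweeps; fully deterministic so that
#' repeated runs are byte-identical.
#'
#' @param n number of points.
#' @param lower,upper numeric vectors of box bounds (recycled to a common
#'   length, which sets the dimension).
#' @param skip leading sequence elements to drop (the first few Halton
#'   points cluster near the origin).
#' @return an `n x dim` matrix of points inside the box.
#' @keywords internal
halton_points <- function(n, lower, upper, skip = 0L) {
  dim <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  bases <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)[seq_len(dim)]
  idx <- seq.int(skip + 1L, skip + n)
  pts <- vapply(bases, function(b) vapply(idx, radical_inverse, 0, base = b),
                numeric(n))
  pts <- matrix(pts, nrow = n)
  sweep(sweep(pts, 2, upper - lower, `*`), 2, lower, `+`)
}

radical_inverse <- function(i, base) {
  f <- 1 / base
  r <- 0
  while (i > 0) {
    r <- r + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  r
}

#' Scale-aware finite-difference Jacobian
#'
#' Central differences with per-component step `h = h0 * max(1, |x_i|)`,
#' so entries stay accurate for states spanning orders of magnitude
#' (nM concentrations vs. dimensionless activities).
#'
#' @param f vector-valued function of a numeric vector.
#' @param x evaluation point.
#' @param h0 base relative step.
#' @return the Jacobian matrix `df_i/dx_j`.
#' @keywords internal
numeric_jacobian <- function(f, x, h0 = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), n)
  for (j in seq_len(n)) {
    h <- h0 * max(1, abs(x[j]))
    xp <- x; xm <- x
    xp[j] <- x[j] + h
    xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  if (any(!is.finite(J))) stop("non-finite Jacobian entries near state")
  J
}

#' Damped Newton root finder
#'
#' Newton iteration with backtracking line search on the residual norm.
#' The workhorse behind steady-state sweeps, intersection refinement and
#' the 2+2 conservation solves; no randomness anywhere.
#'
#' @param f vector-valued residual function.
#' @param x0 start point.
#' @param tol convergence tolerance on the max-norm of `f`.
#' @param maxit maximum Newton steps.
#' @param jac optional analytic Jacobian function; finite differences
#'   otherwise.
#' @param scale optional per-component state scale; iterating in scaled
#'   coordinates keeps steps well-conditioned when state components span
#'   orders of magnitude (nM concentrations next to unit activities).
#' @return list with `root`, `fval`, `resid` (max-norm), `converged`,
#'   `iters`.
#' @keywords internal
newton_solve <- function(f, x0, tol = 1e-11, maxit = 40L, jac = NULL,
                         scale = NULL) {
  if (!is.null(scale)) {
    scale <- pmax(as.numeric(scale), 1e-12)
    f_raw <- f
    f <- function(z) f_raw(z * scale)
    sol <- newton_solve(f, as.numeric(x0) / scale, tol = tol,
                        maxit = maxit, jac = NULL)
    sol$root <- sol$root * scale
    return(sol)
  }
  x <- as.numeric(x0)
  fx <- tryCatch(f(x), error = function(e) NULL)
  if (is.null(fx) || any(!is.finite(fx))) {
    return(list(root = x, fval = fx, resid = Inf, converged = FALSE, iters = 0L))
  }
  nf <- max(abs(fx))
  kicks <- 0L
  for (it in seq_len(maxit)) {
    if (nf <= tol) {
      return(list(root = x, fval = fx, resid = nf, converged = TRUE, iters = it - 1L))
    }
    J <- tryCatch(
      if (is.null(jac)) numeric_jacobian(f, x) else jac(x),
      error = function(e) NULL)
    if (is.null(J)) break
    step <- tryCatch(solve(J, -fx), error = function(e) {
      # near-singular Jacobian (folds): fall back to a regularized solve
      tryCatch(solve(J + diag(1e-10 * max(1, max(abs(J))), nrow(J)), -fx),
               error = function(e2) NULL)
    })
    if (is.null(step) || any(!is.finite(step))) break
    lambda <- 1
    improved <- FALSE
    for (k in 1:9) {
      xn <- x + lambda * step
      fn <- tryCatch(f(xn), error = function(e) NULL)
      if (!is.null(fn) && all(is.finite(fn)) && max(abs(fn)) < nf) {
        x <- xn; fx <- fn; nf <- max(abs(fn)); improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) {
      # line search stalled (strong nonlinearity can leave no tested
      # damping productive): kick the iterate deterministically and
      # retry a couple of times before giving up
      if (kicks >= 2L) break
      kicks <- kicks + 1L
      pert <- 1e-3 * kicks * pmax(1, abs(x)) *
        rep_len(c(1, -1), length(x))
      xn <- x + pert
      fn <- tryCatch(f(xn), error = function(e) NULL)
      if (is.null(fn) || any(!is.finite(fn))) break
      x <- xn; fx <- fn; nf <- max(abs(fn))
    }
  }
  list(root = x, fval = fx, resid = nf, converged = nf <= tol, iters = maxit)
}

# near-corner and center start points of a state box; steady states of
# saturated signaling cycles often sit close to a box corner (almost
# everything in one species), where a low-discrepancy interior grid is
# sparse
box_corner_starts <- function(lower, upper, inset = 0.02) {
  rng <- pmax(upper - lower, 1e-12)
  lo <- lower + inset * rng
  hi <- upper - inset * rng
  g <- as.matrix(expand.grid(lapply(seq_along(lower),
                                    function(j) c(lo[j], hi[j]))))
  dimnames(g) <- NULL
  rbind(g, (lower + upper) / 2)
}

#' Merge a set of polished roots into distinct steady states
#'
#' Two roots are the same steady state when they are within `tol` of each
#' other, or when the residual at their midpoint is still below
#' `root_tol`: near a fold the residual basin is flat and a whole cluster
#' of polished points represents one (degenerate) root, while genuinely
#' distinct transversal roots always have a residual bump between them.
#'
#' @param roots matrix, one root per row.
#' @param resids residual per root.
#' @param f residual function (for the midpoint test).
#' @param root_tol residual tolerance.
#' @param tol absolute distance below which roots merge outright.
#' @param span largest distance at which the midpoint test is attempted.
#' @return list with deduplicated `roots` and `resids`.
#' @keywords internal
merge_roots <- function(roots, resids, f, root_tol, tol, span = Inf) {
  n <- nrow(roots)
  if (n < 2) return(list(roots = roots, resids = resids))
  keep <- rep(TRUE, n)
  for (i in seq_len(n - 1L)) {
    if (!keep[i]) next
    for (j in seq.int(i + 1L, n)) {
      if (!keep[j]) next
      d <- max(abs(roots[i, ] - roots[j, ]))
      same <- d <= tol
      if (!same && d <= span) {
        fm <- tryCatch(f((roots[i, ] + roots[j, ]) / 2),
                       error = function(e) Inf)
        same <- all(is.finite(fm)) && max(abs(fm)) <= root_tol
      }
      if (same) {
        if (resids[j] < resids[i]) {
          roots[i, ] <- roots[j, ]
          resids[i] <- resids[j]
        }
        keep[j] <- FALSE
      }
    }
  }
  list(roots = roots[keep, , drop = FALSE], resids = resids[keep])
}
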