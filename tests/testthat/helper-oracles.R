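# Independent oracles shared across tests. These deliberately avoid the
# package's own sweep/trace machinery so that agreement between the two
# routes is informative.

# FitzHugh-Nagumo analytic nullclines (the fhn_toy modules' exact
# steady-state curves): w = v - v^3/3 + I  and  w = (v + a)/b
fhn_cubic_w <- function(v, p) v - v^3 / 3 + p[["I"]]
fhn_linear_w <- function(v, p) (v + p[["a"]]) / p[["b"]]

# all real roots of v - v^3/3 - w + I = 0 for a given w (closed form via
# polyroot), sorted
fhn_v_roots <- function(w, p) {
  z <- polyroot(c(p[["I"]] - w, 1, 0, -1 / 3))
  v <- Re(z[abs(Im(z)) < 1e-8])
  sort(v)
}

# dense-grid sign-change root counter for the cell-cycle Cdk1 module:
# at fixed apca the total-cyclin balance fixes cdk1a + cdk1i, leaving a
# one-dimensional residual in cdk1a
cellcycle_module1_roots_1d <- function(apca, params, n = 1e4) {
  kd <- params[["adeg"]] + params[["bdeg"]] * apca
  cyc <- params[["k_synth"]] / kd
  resid <- function(c) {
    x <- c(c, cyc - c)
    pseudonull::get_model("cellcycle")$module1$rhs(x, apca, params)[1]
  }
  cg <- seq(1e-9, cyc - 1e-9, length.out = n)
  h <- vapply(cg, resid, 0)
  s <- sign(h)
  idx <- which(s[-1] * s[-length(s)] < 0)
  roots <- vapply(idx, function(i)
    uniroot(resid, c(cg[i], cg[i + 1]), tol = 1e-12)$root, 0)
  roots
}

# brute-force full-system steady states: dense deterministic start grid,
# plain Newton via the generic solver, no module seeding or warm starts
brute_force_roots <- function(system, n_grid = 6L, tol = 1e-10) {
  b1 <- system$module1$bounds
  if (is.function(b1)) b1 <- b1(system$params, NA)
  b2 <- system$module2$bounds
  if (is.function(b2)) b2 <- b2(system$params, NA)
  lower <- c(b1[1, ], b2[1, ]); upper <- c(b1[2, ], b2[2, ])
  axes <- lapply(seq_along(lower), function(j)
    seq(lower[j], upper[j], length.out = n_grid))
  starts <- as.matrix(do.call(expand.grid, axes))
  f <- function(s) full_rhs(system, s)
  roots <- NULL
  for (i in seq_len(nrow(starts))) {
    sol <- pseudonull:::newton_solve(f, starts[i, ], tol = tol)
    if (sol$converged &&
        all(sol$root > lower - 0.25 * (upper - lower)) &&
        all(sol$root < upper + 0.25 * (upper - lower)))
      roots <- rbind(roots, sol$root)
  }
  if (is.null(roots)) return(matrix(numeric(0), 0, system$dim))
  # merge duplicates (and fold-degenerate clusters)
  keep <- rep(TRUE, nrow(roots))
  scale <- max(1, max(abs(c(lower, upper))))
  for (i in seq_len(nrow(roots))) {
    if (!keep[i]) next
    if (i < nrow(roots)) for (j in seq.int(i + 1, nrow(roots))) {
      if (keep[j] && max(abs(roots[i, ] - roots[j, ])) < 1e-5 * scale)
        keep[j] <- FALSE
    }
  }
  roots[keep, , drop = FALSE]
}

# deterministic admissible random states for property tests
random_states <- function(system, n, seed = 421L) {
  set.seed(seed)
  b1 <- system$module1$bounds
  if (is.function(b1)) b1 <- b1(system$params, NA)
  b2 <- system$module2$bounds
  if (is.function(b2)) b2 <- b2(system$params, NA)
  lower <- c(b1[1, ], b2[1, ]); upper <- c(b1[2, ], b2[2, ])
  t(replicate(n, lower + runif(length(lower)) * (upper - lower)))
}
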