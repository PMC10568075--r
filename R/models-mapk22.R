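#' MAPK 2+2 double-phosphorylation motif
#'
#' The last two levels of a MAPK cascade: an input kinase E1 drives a
#' two-step distributive phosphorylation cycle on the level-1 kinase
#' (K0 -> K1 -> K2, reversed by phosphatase P1), and the active form K2
#' drives a second two-step cycle on the level-2 substrate
#' (A -> Ap -> App, reversed by phosphatase P2). All steps are
#' elementary mass action through enzyme-substrate complexes, giving 17
#' species; the scan input is the kinase total `E1tot`.
#'
#' `mapk22_full_system()` returns the 17-equation mass-action model (as
#' the `full_model` companion of the reduced system, with its own `rhs`).
#' `mapk22_reduced_system()` returns the four-variable reduction onto
#' `(K0, X, A, App)` where `X = K2 + [K2.A] + [K2.Ap]` is total active
#' level-1 kinase and the coupling scalar into module 1 is
#' `Z = c1*A + c2*Ap` with `c1 = a5/(d5+k5)`, `c2 = a6/(d6+k6)`, so the
#' free active kinase is `K2 = X/(1+Z)`. Complexes are in rapid
#' equilibrium (`C = E*S/Km`); the auxiliaries `Ap` and `K1` are
#' recovered at every evaluation from the substrate and kinase
#' conservation totals by damped Newton (the "implicit conservation"
#' solves that block off-the-shelf continuation tools). The bundled
#' parameter values are a synthetic set calibrated so that both cycles
#' are bistable and the coupled motif oscillates inside an `E1tot`
#' window bounded by saddle-node bifurcations (see the methods
#' vignette).
#'
#' @param overrides named parameter overrides.
#' @return a `pn_system` (`mapk22_reduced_system`) or a plain list model
#'   (`mapk22_full_system`) with `rhs`, `state_names`, `conserved()` and
#'   `project()`.
#' @export
mapk22_reduced_system <- function(overrides = NULL) {
  p <- param_set(mapk22_defaults(), overrides)
  m1 <- module_spec(
    c("K0", "X"),
    mapk22_f,
    input_name = "Z",
    bounds = function(params, input)
      rbind(lower = c(0, 0),
            upper = c(params[["Ktot"]], params[["Ktot"]])))
  m2 <- module_spec(
    c("A", "App"),
    mapk22_g,
    input_name = "X",
    bounds = function(params, input)
      rbind(lower = c(0, 0),
            upper = c(params[["Atot"]], params[["Atot"]])))
  cp <- coupling_map(
    alpha = function(y, params, x = NULL) {
      # Z needs Ap, recovered from the substrate conservation given X
      X <- if (is.null(x)) stop("Z recovery needs the module-1 state") else x[2]
      cc <- mapk22_c1c2(params)
      aux <- mapk22_aux2(y[1], y[2], X, params)
      cc[1] * y[1] + cc[2] * aux$Ap
    },
    beta = function(x, params, y = NULL) x[2],
    labels = c("X", "Z"))
  sys <- coupled_system(m1, m2, cp, p, name = "mapk22_reduced")
  sys$input_param <- "E1tot"
  sys$plane_labels <- c("X", "Z")
  sys$projection <- list(
    function(input, state, params) c(state[2], input),     # C1: (X, Z=input)
    function(input, state, params) {                       # C2: (X=input, Z)
      cc <- mapk22_c1c2(params)
      aux <- mapk22_aux2(state[1], state[2], input, params)
      c(input, cc[1] * state[1] + cc[2] * aux$Ap)
    })
  sys$trajectory_projection <- function(state, params) {
    cc <- mapk22_c1c2(params)
    aux <- mapk22_aux2(state[3], state[4], state[2], params)
    c(state[2], cc[1] * state[3] + cc[2] * aux$Ap)
  }
  sys$input_grids <- list(
    function(params, n) {
      cc <- mapk22_c1c2(params)
      seq(0, max(cc) * params[["Atot"]], length.out = n)
    },
    function(params, n) seq(0, params[["Ktot"]], length.out = n))
  sys$default_initial <- mapk22_reduced_initial(p)
  sys$scan_window <- c(0.3, 0.8)
  sys$full_model <- mapk22_full_system(overrides)
  sys
}

# reduced initial condition: everything unphosphorylated. Free K0 is
# below Ktot because the input kinase instantaneously sequesters part of
# it into the E1.K0 complex under the quasi-equilibrium closure.
mapk22_reduced_initial <- function(params)
  c(K0 = mapk22_feasible_K0(params), X = 0,
    A = unname(params[["Atot"]]), App = 0)

mapk22_feasible_K0 <- function(p) {
  km1 <- (p[["d1"]] + p[["k1"]]) / p[["a1"]]
  km2 <- (p[["d2"]] + p[["k2"]]) / p[["a2"]]
  g <- function(K0) {
    u <- K0 / km1
    K0 + p[["E1tot"]] * u / (1 + u) - p[["Ktot"]]
  }
  uniroot(g, c(0, p[["Ktot"]]), tol = 1e-12)$root
}

# Synthetic calibration (see the methods vignette): Markevich-style
# asymmetric kinetics on the level-2 cycle (slow saturated first
# phosphorylation, fast unsaturated second, saturated phosphatase) make
# it bistable over X; the level-1 cycle runs ~75x slower with a
# weakly-bound phosphatase leg, acting as the slow recovery module whose
# sequestration-mediated coupling closes the relaxation loop. The motif
# oscillates for E1tot inside roughly (0.56, 0.68).
mapk22_defaults <- function() {
  c(E1tot = 0.6, P1tot = 0.24, P2tot = 0.24, Ktot = 1.2, Atot = 1.2,
    a1 = 8.5 / 3, d1 = 1 / 3, k1 = 0.05 / 3,
    a2 = 3.33 / 3, d2 = 1 / 3, k2 = 1,
    a3 = 2 / 3, d3 = 1 / 3, k3 = 0.8 / 3,
    a4 = 8 / 3, d4 = 1 / 3, k4 = 0.5 / 3,
    a5 = 8.5 * 25, d5 = 25, k5 = 0.5,
    a6 = 3.33 * 25, d6 = 25, k6 = 75,
    a7 = 22 * 25, d7 = 25, k7 = 4.25,
    a8 = 26 * 25, d8 = 25, k8 = 3)
}

# reference input inside the oscillatory window (used by examples and
# tests as the motif's showcase operating point)
mapk22_osc_input <- function() 0.6

mapk22_kms <- function(p) {
  list(Km1 = (p[["d1"]] + p[["k1"]]) / p[["a1"]],
       Km2 = (p[["d2"]] + p[["k2"]]) / p[["a2"]],
       Km3 = (p[["d3"]] + p[["k3"]]) / p[["a3"]],
       Km4 = (p[["d4"]] + p[["k4"]]) / p[["a4"]],
       Km5 = (p[["d5"]] + p[["k5"]]) / p[["a5"]],
       Km6 = (p[["d6"]] + p[["k6"]]) / p[["a6"]],
       Km7 = (p[["d7"]] + p[["k7"]]) / p[["a7"]],
       Km8 = (p[["d8"]] + p[["k8"]]) / p[["a8"]])
}

#' Embed a reduced 2+2 state into the 17-species state space
#'
#' At any steady state of the mass-action system every enzyme-substrate
#' complex satisfies `C = E*S/Km` exactly, so a steady state of the
#' reduced model maps to an exact steady state of the full model. This
#' embedding reconstructs all 17 species from `(K0, X, A, App)` via the
#' conservation solves; away from steady state it is the quasi-
#' equilibrium lift.
#'
#' @param state4 reduced state vector `(K0, X, A, App)`.
#' @param params 2+2 parameter set.
#' @return named 17-vector in the full model's state order.
#' @export
mapk22_embed_full <- function(state4, params) {
  km <- mapk22_kms(params)
  a2x <- mapk22_aux2(state4[3], state4[4], state4[2], params)
  a1x <- mapk22_aux1(state4[1], state4[2], a2x$Z, params)
  c(K0 = unname(state4[1]), K1 = unname(a1x$K1), K2 = unname(a1x$K),
    E1 = unname(a1x$E1),
    E1K0 = unname(a1x$E1 * state4[1] / km$Km1),
    E1K1 = unname(a1x$E1 * a1x$K1 / km$Km2),
    P1 = unname(a1x$P1),
    P1K1 = unname(a1x$P1 * a1x$K1 / km$Km4),
    P1K2 = unname(a1x$P1 * a1x$K / km$Km3),
    A = unname(state4[3]), Ap = unname(a2x$Ap), App = unname(state4[4]),
    AK = unname(a2x$AK), ApK = unname(a2x$ApK),
    P2 = unname(a2x$P2),
    P2Ap = unname(a2x$P2 * a2x$Ap / km$Km8),
    P2App = unname(a2x$P2 * state4[4] / km$Km7))
}

#' @rdname mapk22_reduced_system
#' @export
mapk22_c1c2 <- function(params) {
  c(c1 = unname(params[["a5"]] / (params[["d5"]] + params[["k5"]])),
    c2 = unname(params[["a6"]] / (params[["d6"]] + params[["k6"]])))
}

# --- auxiliary recovery -----------------------------------------------

# Ap from the substrate conservation, given (A, App, X). Writing the
# sequestered amounts as saturating fractions, the residual
#   r(Ap) = A + Ap + App + X z/(1+z) + P2tot w/(1+w) - Atot,
#   z = c1 A + c2 Ap,  w = Ap/Km8 + App/Km7,
# is strictly increasing in Ap, so a clamped analytic-derivative Newton
# (bisection fallback) converges unconditionally.
.mapk22_memo <- new.env(parent = emptyenv())

mapk22_aux2 <- function(A, App, X, p) {
  key <- .mapk22_memo$k2
  if (!is.null(key) && identical(key, c(A, App, X, p[["Atot"]], p[["P2tot"]])))
    return(.mapk22_memo$v2)
  km7 <- (p[["d7"]] + p[["k7"]]) / p[["a7"]]
  km8 <- (p[["d8"]] + p[["k8"]]) / p[["a8"]]
  c1 <- p[["a5"]] / (p[["d5"]] + p[["k5"]])
  c2 <- p[["a6"]] / (p[["d6"]] + p[["k6"]])
  P2t <- p[["P2tot"]]; At <- p[["Atot"]]
  rfun <- function(Ap) {
    z <- c1 * A + c2 * Ap
    w <- Ap / km8 + App / km7
    A + Ap + App + X * z / (1 + z) + P2t * w / (1 + w) - At
  }
  Ap <- monotone_newton(rfun, function(Ap) {
    z <- c1 * A + c2 * Ap
    w <- Ap / km8 + App / km7
    1 + X * c2 / (1 + z)^2 + P2t / km8 / (1 + w)^2
  }, lo = 0, hi = At, x0 = max(min(At - A - App, At) / 2, 1e-8))
  z <- c1 * A + c2 * Ap
  K <- X / (1 + z)
  w <- Ap / km8 + App / km7
  P2 <- P2t / (1 + w)
  out <- list(Ap = Ap, K = K, P2 = P2, AK = K * c1 * A, ApK = K * c2 * Ap,
              Z = z, resid = rfun(Ap))
  .mapk22_memo$k2 <- c(A, App, X, p[["Atot"]], p[["P2tot"]])
  .mapk22_memo$v2 <- out
  out
}

# K1 from the kinase conservation, given (K0, X, Z); same monotone
# structure with u = K0/Km1 + K1/Km2 (E1 branch), v = K1/Km4 + K/Km3
# (P1 branch)
mapk22_aux1 <- function(K0, X, Z, p) {
  km1 <- (p[["d1"]] + p[["k1"]]) / p[["a1"]]
  km2 <- (p[["d2"]] + p[["k2"]]) / p[["a2"]]
  km3 <- (p[["d3"]] + p[["k3"]]) / p[["a3"]]
  km4 <- (p[["d4"]] + p[["k4"]]) / p[["a4"]]
  E1t <- p[["E1tot"]]; P1t <- p[["P1tot"]]; Kt <- p[["Ktot"]]
  K <- X / (1 + Z)
  rfun <- function(K1) {
    u <- K0 / km1 + K1 / km2
    v <- K1 / km4 + K / km3
    K0 + K1 + X + E1t * u / (1 + u) + P1t * v / (1 + v) - Kt
  }
  K1 <- monotone_newton(rfun, function(K1) {
    u <- K0 / km1 + K1 / km2
    v <- K1 / km4 + K / km3
    1 + E1t / km2 / (1 + u)^2 + P1t / km4 / (1 + v)^2
  }, lo = 0, hi = Kt, x0 = max(min(Kt - K0 - X, Kt) / 2, 1e-8))
  u <- K0 / km1 + K1 / km2
  v <- K1 / km4 + K / km3
  list(K1 = K1, K = K, E1 = E1t / (1 + u), P1 = P1t / (1 + v),
       resid = rfun(K1))
}

# scalar Newton for a strictly increasing residual on [lo, hi], with
# interval clamping; falls back to plain bisection if Newton stalls
monotone_newton <- function(f, df, lo, hi, x0, tol = 1e-12, maxit = 60L) {
  flo <- f(lo)
  if (flo >= 0) return(lo)
  if (f(hi) <= 0) return(hi)
  x <- min(max(x0, lo), hi)
  for (i in seq_len(maxit)) {
    fx <- f(x)
    if (abs(fx) <= tol) return(x)
    if (fx > 0) hi <- x else lo <- x
    step <- fx / df(x)
    xn <- x - step
    if (!is.finite(xn) || xn <= lo || xn >= hi) xn <- (lo + hi) / 2
    x <- xn
  }
  x
}

# module 1 vector field: d(K0, X)/dt at input Z
mapk22_f <- function(x, Z, p) {
  aux <- mapk22_aux1(x[1], x[2], Z, p)
  v1 <- p[["k1"]] * aux$E1 * x[1] * p[["a1"]] / (p[["d1"]] + p[["k1"]])
  v2 <- p[["k2"]] * aux$E1 * aux$K1 * p[["a2"]] / (p[["d2"]] + p[["k2"]])
  v3 <- p[["k3"]] * aux$P1 * aux$K * p[["a3"]] / (p[["d3"]] + p[["k3"]])
  v4 <- p[["k4"]] * aux$P1 * aux$K1 * p[["a4"]] / (p[["d4"]] + p[["k4"]])
  c(v4 - v1, v2 - v3)
}

# module 2 vector field: d(A, App)/dt at input X
mapk22_g <- function(y, X, p) {
  aux <- mapk22_aux2(y[1], y[2], X, p)
  v5 <- p[["k5"]] * aux$AK
  v6 <- p[["k6"]] * aux$ApK
  v7 <- p[["k7"]] * aux$P2 * y[2] * p[["a7"]] / (p[["d7"]] + p[["k7"]])
  v8 <- p[["k8"]] * aux$P2 * aux$Ap * p[["a8"]] / (p[["d8"]] + p[["k8"]])
  c(v8 - v5, v6 - v7)
}

# --- full 17-species mass-action model --------------------------------

#' @rdname mapk22_reduced_system
#' @export
mapk22_full_system <- function(overrides = NULL) {
  p <- param_set(mapk22_defaults(), overrides)
  sn <- c("K0", "K1", "K2", "E1", "E1K0", "E1K1", "P1", "P1K1", "P1K2",
          "A", "Ap", "App", "AK", "ApK", "P2", "P2Ap", "P2App")
  rhs <- function(s, params = p) mapk22_full_rhs(s, params)
  list(name = "mapk22_full", state_names = sn, rhs = rhs, params = p,
       conserved = function(s, params = p) mapk22_conserved(s, params),
       initial = function(params = p) mapk22_full_initial(params),
       project = function(s, params = p) {
         cc <- mapk22_c1c2(params)
         c(X = unname(s[3] + s[13] + s[14]),
           Z = unname(cc[1] * s[10] + cc[2] * s[11]))
       })
}

mapk22_full_initial <- function(p)
  c(K0 = unname(p[["Ktot"]]), K1 = 0, K2 = 0,
    E1 = unname(p[["E1tot"]]), E1K0 = 0, E1K1 = 0,
    P1 = unname(p[["P1tot"]]), P1K1 = 0, P1K2 = 0,
    A = unname(p[["Atot"]]), Ap = 0, App = 0, AK = 0, ApK = 0,
    P2 = unname(p[["P2tot"]]), P2Ap = 0, P2App = 0)

mapk22_full_rhs <- function(s, p) {
  K0 <- s[1]; K1 <- s[2]; K2 <- s[3]; E1 <- s[4]; E1K0 <- s[5]
  E1K1 <- s[6]; P1 <- s[7]; P1K1 <- s[8]; P1K2 <- s[9]
  A <- s[10]; Ap <- s[11]; App <- s[12]; AK <- s[13]; ApK <- s[14]
  P2 <- s[15]; P2Ap <- s[16]; P2App <- s[17]
  b1 <- p[["a1"]] * E1 * K0 - p[["d1"]] * E1K0; c1r <- p[["k1"]] * E1K0
  b2 <- p[["a2"]] * E1 * K1 - p[["d2"]] * E1K1; c2r <- p[["k2"]] * E1K1
  b3 <- p[["a3"]] * P1 * K2 - p[["d3"]] * P1K2; c3r <- p[["k3"]] * P1K2
  b4 <- p[["a4"]] * P1 * K1 - p[["d4"]] * P1K1; c4r <- p[["k4"]] * P1K1
  b5 <- p[["a5"]] * K2 * A - p[["d5"]] * AK;    c5r <- p[["k5"]] * AK
  b6 <- p[["a6"]] * K2 * Ap - p[["d6"]] * ApK;  c6r <- p[["k6"]] * ApK
  b7 <- p[["a7"]] * P2 * App - p[["d7"]] * P2App; c7r <- p[["k7"]] * P2App
  b8 <- p[["a8"]] * P2 * Ap - p[["d8"]] * P2Ap;  c8r <- p[["k8"]] * P2Ap
  c(
    K0   = -b1 + c4r,
    K1   = c1r - b2 - b4 + c3r,
    K2   = c2r - b3 - b5 + c5r - b6 + c6r,
    E1   = -b1 + c1r - b2 + c2r,
    E1K0 = b1 - c1r,
    E1K1 = b2 - c2r,
    P1   = -b3 + c3r - b4 + c4r,
    P1K1 = b4 - c4r,
    P1K2 = b3 - c3r,
    A    = -b5 + c8r,
    Ap   = c5r - b6 - b8 + c7r,
    App  = c6r - b7,
    AK   = b5 - c5r,
    ApK  = b6 - c6r,
    P2   = -b7 + c7r - b8 + c8r,
    P2Ap = b8 - c8r,
    P2App = b7 - c7r
  )
}

mapk22_conserved <- function(s, p) {
  c(E1tot = unname(s[4] + s[5] + s[6]),
    P1tot = unname(s[7] + s[8] + s[9]),
    P2tot = unname(s[15] + s[16] + s[17]),
    Ktot = unname(s[1] + s[2] + s[3] + s[5] + s[6] + s[8] + s[9] +
                    s[13] + s[14]),
    Atot = unname(s[10] + s[11] + s[12] + s[13] + s[14] + s[16] + s[17]))
}
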