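#' Analytic toy systems
#'
#' Small coupled systems with closed-form nullclines or normal-form
#' bifurcations, used as oracles for the pseudo-nullcline machinery:
#'
#' * `fhn_toy` — FitzHugh–Nagumo split into two 1-D modules with identity
#'   couplings; its pseudo-nullclines are the textbook cubic and linear
#'   nullclines.
#' * `linear_toy` — a linear coupled pair with the closed-form fixed
#'   point (1, 1).
#' * `sn_normal_form` — `dx/dt = p - x^2` driving a relaxing follower;
#'   fold at `p = 0`.
#' * `hopf_normal_form` — the planar Hopf normal form split into two 1-D
#'   modules; Hopf at `p = 0`, cycle radius `sqrt(p)`.
#'
#' @param name one of the four names above.
#' @param overrides named parameter overrides.
#' @return a `pn_system`.
#' @export
toy_systems <- function(name, overrides = NULL) {
  switch(name,
         fhn_toy = fhn_toy(overrides),
         linear_toy = linear_toy(overrides),
         sn_normal_form = sn_normal_form(overrides),
         hopf_normal_form = hopf_normal_form(overrides),
         stop("unknown toy system: ", name))
}

fhn_toy <- function(overrides = NULL) {
  p <- param_set(c(I = 0.5, eps = 0.08, a = 0.7, b = 0.8), overrides)
  m1 <- module_spec(
    "v",
    function(x, w, params)
      x[1] - x[1]^3 / 3 - w + params[["I"]],
    input_name = "w",
    bounds = rbind(lower = -3, upper = 3))
  m2 <- module_spec(
    "w",
    function(y, v, params)
      params[["eps"]] * (v + params[["a"]] - params[["b"]] * y[1]),
    input_name = "v",
    bounds = rbind(lower = -2, upper = 3))
  cp <- coupling_map(alpha = function(y, params, x = NULL) y[1],
                     beta = function(x, params, y = NULL) x[1],
                     labels = c("v", "w"))
  sys <- coupled_system(m1, m2, cp, p, name = "fhn_toy")
  sys$input_grids <- list(function(params, n) seq(-1.2, 2.6, length.out = n),
                          function(params, n) seq(-3, 3, length.out = n))
  sys$plane_labels <- c("v", "w")
  sys$input_param <- "I"
  sys$default_initial <- c(v = -1, w = 0)
  sys$trajectory_projection <- function(state, params) state[1:2]
  sys
}

linear_toy <- function(overrides = NULL) {
  p <- param_set(c(c1 = 1, c2 = 2, k1 = 2, k2 = 3), overrides)
  m1 <- module_spec(
    "x",
    function(x, a, params) params[["c1"]] + a - params[["k1"]] * x[1],
    bounds = rbind(lower = -2, upper = 3))
  m2 <- module_spec(
    "y",
    function(y, b, params) params[["c2"]] + b - params[["k2"]] * y[1],
    bounds = rbind(lower = -2, upper = 3))
  cp <- coupling_map(alpha = function(y, params, x = NULL) y[1],
                     beta = function(x, params, y = NULL) x[1],
                     labels = c("x", "y"))
  sys <- coupled_system(m1, m2, cp, p, name = "linear_toy")
  sys$input_grids <- list(function(params, n) seq(-2, 3, length.out = n),
                          function(params, n) seq(-2, 3, length.out = n))
  sys$plane_labels <- c("x", "y")
  sys$input_param <- "c1"
  sys$default_initial <- c(x = 0, y = 0)
  sys$trajectory_projection <- function(state, params) state[1:2]
  sys
}

sn_normal_form <- function(overrides = NULL) {
  p <- param_set(c(p = 0.5), overrides)
  m1 <- module_spec(
    "x",
    function(x, a, params) params[["p"]] - x[1]^2,
    bounds = rbind(lower = -2, upper = 2))
  m2 <- module_spec(
    "y",
    function(y, b, params) b - y[1],
    bounds = rbind(lower = -2, upper = 2))
  cp <- coupling_map(alpha = function(y, params, x = NULL) y[1],
                     beta = function(x, params, y = NULL) x[1],
                     labels = c("x", "y"))
  sys <- coupled_system(m1, m2, cp, p, name = "sn_normal_form")
  sys$input_grids <- list(function(params, n) seq(-2, 2, length.out = n),
                          function(params, n) seq(-2, 2, length.out = n))
  sys$plane_labels <- c("x", "y")
  sys$input_param <- "p"
  sys$default_initial <- c(x = 1, y = 1)
  sys$trajectory_projection <- function(state, params) state[1:2]
  sys
}

hopf_normal_form <- function(overrides = NULL) {
  p <- param_set(c(p = 0.2), overrides)
  m1 <- module_spec(
    "x",
    function(x, a, params)
      params[["p"]] * x[1] - a - x[1] * (x[1]^2 + a^2),
    bounds = rbind(lower = -1.5, upper = 1.5))
  m2 <- module_spec(
    "y",
    function(y, b, params)
      b + params[["p"]] * y[1] - y[1] * (b^2 + y[1]^2),
    bounds = rbind(lower = -1.5, upper = 1.5))
  cp <- coupling_map(alpha = function(y, params, x = NULL) y[1],
                     beta = function(x, params, y = NULL) x[1],
                     labels = c("x", "y"))
  sys <- coupled_system(m1, m2, cp, p, name = "hopf_normal_form")
  sys$input_grids <- list(function(params, n) seq(-1.5, 1.5, length.out = n),
                          function(params, n) seq(-1.5, 1.5, length.out = n))
  sys$plane_labels <- c("x", "y")
  sys$input_param <- "p"
  sys$default_initial <- c(x = 0.5, y = 0)
  sys$trajectory_projection <- function(state, params) state[1:2]
  sys
}
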