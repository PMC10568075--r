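#' Parameter sets
#'
#' A named numeric vector of model parameters (rate constants, Hill
#' coefficients, EC50s, totals). `param_set()` validates finiteness and
#' applies overrides on top of defaults; unknown override names are an
#' error so typos cannot silently create parameters.
#'
#' @param defaults named numeric vector of default values.
#' @param overrides named numeric vector (or list) of replacements; names
#'   must be a subset of `names(defaults)` unless `allow_new = TRUE`.
#' @param allow_new allow overrides to introduce new names.
#' @return a named numeric vector of class `pn_params`.
#' @export
param_set <- function(defaults, overrides = NULL, allow_new = FALSE) {
  p <- unlist(defaults)
  if (is.null(names(p)) || any(names(p) == ""))
    stop("parameters must all be named")
  if (!is.null(overrides) && length(overrides)) {
    ov <- unlist(overrides)
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown) && !allow_new)
      stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
    p[names(ov)] <- ov
  }
  if (any(!is.finite(p))) stop("all parameter values must be finite")
  structure(p, class = c("pn_params", "numeric"))
}

#' Define one module of a two-module decomposition
#'
#' A module is a set of state variables whose dynamics depend on the rest
#' of the system only through one scalar input: `dx/dt = f(x, a)`.
#'
#' @param state_names ordered character vector of state variable names.
#' @param rhs function `(x, input, params)` returning the derivative
#'   vector, same length and order as `state_names`.
#' @param input_name label for the scalar input (used in exports).
#' @param bounds 2-row matrix (`lower`, `upper`) over the admissible state
#'   box, used to seed multi-start root sweeps.
#' @return an object of class `pn_module`.
#' @export
module_spec <- function(state_names, rhs, input_name = "input",
                        bounds = NULL) {
  stopifnot(is.character(state_names), length(state_names) >= 1,
            is.function(rhs))
  dim <- length(state_names)
  if (is.null(bounds)) bounds <- rbind(lower = rep(0, dim), upper = rep(1, dim))
  if (!is.function(bounds)) {
    bounds <- as.matrix(bounds)
    if (ncol(bounds) != dim) stop("bounds must have one column per state")
  }
  structure(list(state_names = state_names, rhs = rhs, dim = dim,
                 input_name = input_name, bounds = bounds),
            class = "pn_module")
}

#' Define the coupling between two modules
#'
#' `alpha` maps module-2 states to the scalar input of module 1; `beta`
#' maps module-1 states to the scalar input of module 2. Both may
#' optionally use the other module's state as well (some reductions, like
#' the 2+2 MAPK model, recover auxiliary variables from conservation
#' relations that mix the two modules).
#'
#' @param alpha function `(y, params, x = NULL)` returning a scalar.
#' @param beta function `(x, params, y = NULL)` returning a scalar.
#' @param labels character(2): names of the two coupling scalars
#'   (module-1 side, module-2 side), used as projection axis labels.
#' @return an object of class `pn_coupling`.
#' @export
coupling_map <- function(alpha, beta, labels = c("beta_x", "alpha_y")) {
  stopifnot(is.function(alpha), is.function(beta), length(labels) == 2)
  structure(list(alpha = alpha, beta = beta, labels = labels),
            class = "pn_coupling")
}

#' Assemble a coupled two-module system
#'
#' Builds the full vector field from two modules and a coupling map:
#' `dx/dt = f(x, alpha(y))`, `dy/dt = g(y, beta(x))`, with the full state
#' ordered as (module-1 variables, module-2 variables).
#'
#' @param module1,module2 `pn_module` objects.
#' @param coupling a `pn_coupling`.
#' @param params a `pn_params` (or named numeric vector).
#' @param name model name (for registries and file headers).
#' @param projection optional list of projection transforms, see
#'   [project_curve()]; when `NULL` the default coupling-plane projection
#'   is used.
#' @param full_model optional unreduced companion model (e.g. the
#'   17-equation 2+2 mass-action system), a list with elements `rhs`,
#'   `state_names`, and optionally `project`.
#' @return an object of class `pn_system` with elements `module1`,
#'   `module2`, `coupling`, `params`, `dim`, `idx1`, `idx2` and function
#'   `full_rhs(state, params)`.
#' @export
coupled_system <- function(module1, module2, coupling, params,
                           name = "system", projection = NULL,
                           full_model = NULL) {
  stopifnot(inherits(module1, "pn_module"), inherits(module2, "pn_module"),
            inherits(coupling, "pn_coupling"))
  n1 <- module1$dim
  n2 <- module2$dim
  idx1 <- seq_len(n1)
  idx2 <- n1 + seq_len(n2)
  sys <- structure(list(
    name = name,
    module1 = module1, module2 = module2, coupling = coupling,
    params = param_set(params), dim = n1 + n2, idx1 = idx1, idx2 = idx2,
    state_names = c(module1$state_names, module2$state_names),
    projection = projection, full_model = full_model),
    class = "pn_system")
  sys
}

#' Evaluate the full vector field of a coupled system
#'
#' @param system a `pn_system`.
#' @param state full state vector, ordered (module 1, module 2).
#' @param params optional parameter override (defaults to the system's).
#' @return derivative vector of length `system$dim`.
#' @export
full_rhs <- function(system, state, params = system$params) {
  x <- state[system$idx1]
  y <- state[system$idx2]
  a <- system$coupling$alpha(y, params, x)
  b <- system$coupling$beta(x, params, y)
  c(system$module1$rhs(x, a, params), system$module2$rhs(y, b, params))
}

#' Jacobian of the full vector field
#'
#' Central finite differences with a scale-aware step by default; an
#' exact Jacobian can be attached to a system as `system$jacobian`
#' (function of `(state, params)`) and is then used instead.
#'
#' @inheritParams full_rhs
#' @param h0 base relative finite-difference step.
#' @return square matrix of partial derivatives.
#' @export
full_jacobian <- function(system, state, params = system$params, h0 = 1e-6) {
  if (!is.null(system$jacobian)) return(system$jacobian(state, params))
  numeric_jacobian(function(s) full_rhs(system, s, params), state, h0 = h0)
}

#' @export
print.pn_system <- function(x, ...) {
  cat("<pn_system> ", x$name, ": ",
      x$module1$dim, "+", x$module2$dim, " states (",
      paste(x$state_names, collapse = ", "), ")\n", sep = "")
  cat("  coupling scalars: ", paste(x$coupling$labels, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Substitute one parameter value
#' @param system a `pn_system`.
#' @param name parameter name (must exist).
#' @param value new value.
#' @return the modified system.
#' @export
set_param <- function(system, name, value) {
  if (!name %in% names(system$params))
    stop("unknown parameter: ", name)
  system$params[name] <- value
  system
}
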