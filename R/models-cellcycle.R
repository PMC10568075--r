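#' Embryonic cell-cycle oscillator (Cdk1 / Plx1 / APC)
#'
#' A four-variable relaxation oscillator of the early Xenopus embryonic
#' cell cycle in the Tsai/Yang–Ferrell family: active and inactive
#' cyclin-B–Cdk1 complexes (`cdk1a`, `cdk1i`, nM) interconverted by
#' Cdc25 and Wee1 (each under Hill-type positive feedback from `cdk1a`,
#' with overall feedback strength `r`), cyclin synthesized at rate
#' `k_synth` (nM/min, the scan input) and degraded at a rate activated
#' by APC/C. The negative feedback runs Cdk1 -> Plx1 (`plxa`) -> APC/C
#' (`apca`), both Hill activations with first-order deactivation.
#'
#' Module 1 is (`cdk1a`, `cdk1i`) with scalar input `apca`; module 2 is
#' (`plxa`, `apca`) with scalar input `cdk1a`. The `extra` parameter adds
#' a constant basal APC/C activation (zero in the unmodified model); it
#' bounds `apca` away from zero and thereby caps total cyclin, which is
#' what lets the second pseudo-nullcline drop near the first one's
#' right-hand fold.
#'
#' The bundled parameter values are a synthetic reconstruction of the
#' published model family (the canonical rate constants and Hill
#' coefficients, with the degradation leg calibrated so the unmodified
#' model's oscillatory range opens between `k_synth` 0.04 and 0.05 at
#' `r = 0.5`); see the methods vignette.
#'
#' @param overrides named parameter overrides (unknown names error).
#' @return a `pn_system`; the plotting plane is `(Cyc_tot, Cdk1_a)` with
#'   `Cyc_tot = cdk1a + cdk1i` on the first curve and, on the second,
#'   the total-cyclin balance `Cyc_tot = k_synth / kdeg(apca)`.
#' @export
cellcycle_system <- function(overrides = NULL) {
  p <- param_set(cellcycle_defaults(), overrides)
  m1 <- module_spec(
    c("cdk1a", "cdk1i"),
    cellcycle_f,
    input_name = "apca",
    bounds = function(params, input) {
      cmax <- params[["k_synth"]] / cc_kdeg(if (is.finite(input)) input else 0,
                                            params)
      rbind(lower = c(0, 0), upper = c(cmax, cmax))
    })
  m2 <- module_spec(
    c("plxa", "apca"),
    cellcycle_g,
    input_name = "cdk1a",
    bounds = rbind(lower = c(0, 0), upper = c(1, 1)))
  cp <- coupling_map(
    alpha = function(y, params, x = NULL) y[2],   # apca
    beta = function(x, params, y = NULL) x[1],    # cdk1a
    labels = c("cdk1a", "apca"))
  sys <- coupled_system(m1, m2, cp, p, name = "cellcycle")
  sys$input_param <- "k_synth"
  sys$plane_labels <- c("Cyc_tot", "Cdk1_a")
  sys$projection <- list(
    function(input, state, params) c(state[1] + state[2], state[1]),
    function(input, state, params)
      c(params[["k_synth"]] / cc_kdeg(state[2], params), input))
  sys$trajectory_projection <- function(state, params)
    c(state[1] + state[2], state[1])
  sys$input_grids <- list(
    # C1 is parametrized by apca; log spacing resolves the low-apca
    # (high total-cyclin) region where the right-hand fold lives
    function(params, n) exp(seq(log(1e-6), log(1), length.out = n)),
    function(params, n) {
      cmax <- params[["k_synth"]] / params[["adeg"]]
      seq(0, min(1.05 * cmax, 150), length.out = n)
    })
  sys$default_initial <- c(cdk1a = 60, cdk1i = 0, plxa = 0, apca = 0)
  sys
}

cellcycle_defaults <- function() {
  c(k_synth = 1.5, r = 0.5,
    acdc25 = 0.16, bcdc25 = 0.8, ec50_cdc25 = 35, ncdc25 = 11,
    awee1 = 0.08, bwee1 = 0.4, ec50_wee1 = 30, nwee1 = 3.5,
    adeg = 0.0006, bdeg = 0.08,
    kplx_on = 1.5, kplx_off = 1.5, ec50_plx = 40, nplx = 8,
    kapc_on = 1.5, kapc_off = 0.15, ec50_apc = 0.25, napc = 4,
    extra = 0)
}

hill <- function(x, ec50, n) {
  xn <- (pmax(x, 0) / ec50)^n
  xn / (1 + xn)
}

cc_kdeg <- function(apca, params)
  params[["adeg"]] + params[["bdeg"]] * apca

cc_kcdc25 <- function(cdk1a, params)
  params[["acdc25"]] + params[["r"]] * params[["bcdc25"]] *
    hill(cdk1a, params[["ec50_cdc25"]], params[["ncdc25"]])

cc_kwee1 <- function(cdk1a, params)
  params[["awee1"]] + params[["r"]] * params[["bwee1"]] *
    (1 - hill(cdk1a, params[["ec50_wee1"]], params[["nwee1"]]))

cellcycle_f <- function(x, apca, params) {
  cdk1a <- x[1]; cdk1i <- x[2]
  kc <- cc_kcdc25(cdk1a, params)
  kw <- cc_kwee1(cdk1a, params)
  kd <- cc_kdeg(apca, params)
  c(params[["k_synth"]] + kc * cdk1i - kw * cdk1a - kd * cdk1a,
    kw * cdk1a - kc * cdk1i - kd * cdk1i)
}

cellcycle_g <- function(y, cdk1a, params) {
  plxa <- y[1]; apca <- y[2]
  c(params[["kplx_on"]] * (1 - plxa) *
      hill(cdk1a, params[["ec50_plx"]], params[["nplx"]]) -
      params[["kplx_off"]] * plxa,
    params[["kapc_on"]] * (1 - apca) *
      hill(plxa, params[["ec50_apc"]], params[["napc"]]) -
      params[["kapc_off"]] * apca + params[["extra"]])
}
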