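test_that("fold detection pins the saddle-node normal form at zero", {
  sys <- get_model("sn_normal_form")
  d <- scan_steady_states(sys, "p", seq(-1, 1, length.out = 21))
  counts <- vapply(d$roots, nrow, 0L)
  expect_true(all(counts[d$grid < -0.1] == 0))
  expect_true(all(counts[d$grid > 0.1] == 2))
  evs <- detect_folds(d)
  expect_equal(length(evs), 1L)
  expect_equal(evs[[1]]$type, "SN")
  expect_lt(abs(evs[[1]]$param_value), 1e-7)
  expect_true(evs[[1]]$param_value >= evs[[1]]$bracket[1] &&
                evs[[1]]$param_value <= evs[[1]]$bracket[2])
  # a fold sitting exactly on a grid value is still reported once
  d2 <- scan_steady_states(sys, "p", seq(-0.5, 0.5, length.out = 11))
  evs2 <- detect_folds(d2)
  expect_equal(length(evs2), 1L)
  expect_lt(abs(evs2[[1]]$param_value), 1e-7)
})

test_that("Hopf detection pins the Hopf normal form at zero", {
  sys <- get_model("hopf_normal_form")
  d <- scan_steady_states(sys, "p", seq(-0.5, 0.5, length.out = 11))
  evs <- detect_hopf(d)
  expect_equal(length(evs), 1L)
  expect_equal(evs[[1]]$type, "Hopf")
  expect_lt(abs(evs[[1]]$param_value), 1e-7)
  expect_equal(evs[[1]]$diagnostics$im_pair, 1, tolerance = 1e-3)
  # the fold normal form must not trigger Hopf events
  sysf <- get_model("sn_normal_form")
  df <- scan_steady_states(sysf, "p", seq(0.1, 1, length.out = 7))
  expect_equal(length(detect_hopf(df)), 0L)
})

test_that("cell-cycle oscillation onset brackets a Hopf in (0.04, 0.05)", {
  sys <- get_model("cellcycle")
  d <- scan_steady_states(sys, "k_synth",
                          seq(0.03, 0.06, length.out = 7))
  evs <- detect_hopf(d)
  expect_gte(length(evs), 1L)
  pv <- vapply(evs, `[[`, 0, "param_value")
  expect_true(any(pv > 0.04 & pv < 0.05))
})

test_that("tangency gap metric behaves on analytic curves", {
  u <- seq(-1, 1, length.out = 100)
  mk <- function(v) structure(
    list(branches = list(data.frame(u = u, v = v, input = u,
                                    residual = 0, branch_id = 1L)),
         labels = c("u", "v"), module_id = 1L, state_names = character(0)),
    class = "pn_planar")
  # parallel lines: gap equals the separation exactly
  g <- planar_tangency_gap(mk(rep(0, 100)), mk(rep(0.3, 100)))
  expect_equal(as.numeric(g), 0.3, tolerance = 1e-12)
  # transversal crossing: zero separation but positive gap
  g2 <- planar_tangency_gap(mk(u), mk(-u))
  expect_gt(as.numeric(g2), 0.05)
  # tangential contact (parabola touching its tangent line): gap ~ 0
  g3 <- planar_tangency_gap(mk(u^2), mk(rep(0, 100)))
  expect_lt(as.numeric(g3), 1e-3)
  # empty curves are flagged undefined
  e <- mk(rep(0, 100)); e$branches <- list()
  expect_true(is.na(planar_tangency_gap(e, mk(u))))
})

test_that("modified cell-cycle scan finds its fold pair, tangential at the SN", {
  sys <- get_model("cellcycle", c(r = 10, ec50_plx = 72, extra = 2.6e-5))
  d <- scan_steady_states(sys, "k_synth",
                          seq(0.02, 0.28, length.out = 14),
                          n_starts = 40L)
  counts <- vapply(d$roots, nrow, 0L)
  expect_true(any(counts == 3))
  evs <- detect_folds(d, par_tol = 1e-6)
  expect_equal(length(evs), 2L)
  pv <- sort(vapply(evs, `[[`, 0, "param_value"))
  expect_lt(pv[1], 0.05)
  expect_gt(pv[2], 0.2)
  # SN bracketing invariant: each count change by 2 contains one event
  ints <- which(abs(diff(counts)) == 2)
  expect_equal(length(ints), 2L)
  # at the upper SN the coalescing contact is tangential; the contact
  # grazes rather than crosses, so grazing candidates must be on
  sn <- set_param(sys, "k_synth", pv[2])
  res <- analyze_plane(sn, n_grid = 250, sn_tol = 1e-2, graze_tol = 3)
  cls <- vapply(res$intersections, `[[`, "", "classification")
  expect_true("tangential" %in% cls)
})

test_that("saddle-homoclinic/SNIC search demands a one-sided bracket", {
  sys <- get_model("hopf_normal_form")
  expect_error(locate_shom(sys, c(0.2, 0.4), "x"),
               "exactly one end")
})

test_that("period divergence localizes the cycle boundary on the 2+2 motif", {
  sys <- get_model("mapk22_reduced")
  ev <- locate_shom(sys, c(0.54, 0.62), "App", t_end = 3000,
                    t_max = 24000, par_tol = 2e-3)
  expect_true(ev$type %in% c("SHom_candidate", "SNIC_candidate"))
  expect_gt(ev$param_value, 0.54)
  expect_lt(ev$param_value, 0.62)
  ps <- ev$diagnostics$period_series
  ps <- ps[is.finite(ps$period), ]
  expect_gt(nrow(ps), 1)
  # periods grow monotonically toward the boundary from the cycle side
  osc <- ps[ps$param > ev$param_value, ]
  if (nrow(osc) > 1)
    expect_true(all(diff(osc$period[order(osc$param)]) <= 0))
})
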