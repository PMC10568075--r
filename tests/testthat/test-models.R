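test_that("registry resolves names and rejects unknowns", {
  for (nm in model_names()) expect_silent(invisible(get_model(nm)))
  expect_error(get_model("nope"), "unknown model")
  expect_error(get_model("cellcycle", c(bogus = 1)), "unknown parameter")
})

test_that("bundled parameter files match the in-code defaults", {
  for (nm in c("cellcycle", "mapk22")) {
    path <- system.file("extdata", paste0("params_", nm, ".txt"),
                        package = "pseudonull")
    expect_true(nzchar(path))
    vals <- read_params_file(path)
    ref <- if (nm == "cellcycle") get_model("cellcycle")$params
           else get_model("mapk22_reduced")$params
    expect_setequal(names(vals), names(ref))
    expect_equal(vals[names(ref)], unclass(ref), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("the basal-APC term enters the apca equation additively", {
  s0 <- get_model("cellcycle")
  s1 <- get_model("cellcycle", c(extra = 2.6e-5))
  st <- c(cdk1a = 20, cdk1i = 30, plxa = 0.2, apca = 0.1)
  delta <- full_rhs(s1, st) - full_rhs(s0, st)
  expect_lt(max(abs(delta - c(0, 0, 0, 2.6e-5))), 1e-12)
})

test_that("along C2 lower APC activity maps to higher total cyclin", {
  sys <- get_model("cellcycle")
  pn2 <- trace_pseudo_nullcline(sys$module2, params = sys$params,
                                grid = seq(0, 120, length.out = 80),
                                module_id = 2L)
  c2 <- project_curve(pn2, sys)
  for (df in c2$branches) {
    ord <- order(df$apca)
    expect_true(all(diff(df$u[ord]) <= 1e-9))
  }
})

test_that("cell-cycle oscillatory sequence: spiral, small cycle, relaxation", {
  sys <- get_model("cellcycle")
  run <- function(ks, t_end = 12000) {
    s <- set_param(sys, "k_synth", ks)
    traj <- integrate_system(s, s$default_initial, t_end, n_out = 6000)
    detect_limit_cycle(traj, "cdk1a")
  }
  expect_false(isTRUE(run(0.04)$exists))
  small <- run(0.05)
  big <- run(1.5, t_end = 2000)
  expect_true(small$exists)
  expect_true(big$exists)
  expect_lt(small$amplitude, 0.5 * big$amplitude)
})

test_that("relaxation cycle tracks the lower branch of C1 only", {
  sys <- get_model("cellcycle")  # k_synth = 1.5
  res <- analyze_plane(sys, n_grid = 200)
  traj <- integrate_system(sys, sys$default_initial, 1200, n_out = 4000)
  post <- traj$proj[traj$times > 600, ]
  # C1 branch points, keyed by total cyclin
  branches <- res$c1$branches
  vals <- lapply(branches, function(b) cbind(b$u, b$v))
  # for trajectory samples in the rising (interphase) phase, Cdk1a stays
  # near the lowest C1 sheet, far from the upper one
  rising <- post[c(diff(post[, 1]) > 0, FALSE), , drop = FALSE]
  expect_gt(nrow(rising), 50)
  near_low <- 0; near_up <- 0
  for (i in seq_len(nrow(rising))) {
    u0 <- rising[i, 1]; v0 <- rising[i, 2]
    sheet_v <- unlist(lapply(vals, function(m) {
      j <- which(abs(m[, 1] - u0) < 2)
      if (length(j)) m[j, 2] else numeric(0)
    }))
    if (length(sheet_v) < 2) next
    lo <- min(sheet_v); hi <- max(sheet_v)
    if (hi - lo < 5) next               # outside the folded region
    near_low <- near_low + (abs(v0 - lo) < abs(v0 - hi))
    near_up <- near_up + (abs(v0 - hi) <= abs(v0 - lo))
  }
  expect_gt(near_low, 5 * max(near_up, 1))
})

test_that("2+2 auxiliary recovery satisfies the definitional identities", {
  sys <- get_model("mapk22_reduced")
  p <- sys$params
  cc <- mapk22_c1c2(p)
  # sample along an actual trajectory: states there always satisfy the
  # conservation constraints the recovery inverts
  traj <- integrate_system(sys, sys$default_initial, 800, n_out = 30)
  for (i in seq(3, 30, by = 1)) {
    K0 <- traj$states[i, 1]; X <- traj$states[i, 2]
    A <- traj$states[i, 3]; App <- traj$states[i, 4]
    aux <- pseudonull:::mapk22_aux2(A, App, X, p)
    # Z = c1 A + c2 Ap identically
    expect_equal(unname(aux$Z), unname(cc[1] * A + cc[2] * aux$Ap),
                 tolerance = 1e-12)
    # X = K + AK + ApK identically
    expect_equal(unname(aux$K + aux$AK + aux$ApK), unname(X),
                 tolerance = 1e-10)
    # conservation residual solved to tolerance
    expect_lt(abs(aux$resid), 1e-10)
    aux1 <- pseudonull:::mapk22_aux1(K0, X, aux$Z, p)
    expect_lt(abs(aux1$resid), 1e-10)
  }
})

test_that("full 17-species model conserves its totals along trajectories", {
  sys <- get_model("mapk22_reduced")
  fm <- sys$full_model
  traj <- integrate_system(sys, fm$initial(), 1000, n_out = 500,
                           use_full = TRUE)
  cons <- t(apply(traj$states, 1, fm$conserved))
  for (j in seq_len(ncol(cons))) {
    ref <- cons[1, j]
    expect_lt(max(abs(cons[, j] - ref)) / max(ref, 1e-12), 1e-6)
  }
})

test_that("full-model equilibria project onto reduced-model equilibria", {
  # enzyme-substrate complexes sit exactly at C = E*S/Km at any steady
  # state of the mass-action system, so the reduced steady-state
  # equations are exact for the full model
  sys <- get_model("mapk22_reduced", c(E1tot = 0.4))
  fm <- sys$full_model
  traj <- integrate_system(sys, fm$initial(c(sys$params)), 4000,
                           n_out = 400, use_full = TRUE)
  end <- tail(traj$states, 1)[1, ]
  sol <- pseudonull:::newton_solve(function(s) fm$rhs(s, sys$params),
                                   end, tol = 1e-12)
  full_ss <- sol$root
  red <- c(full_ss[1], full_ss[3] + full_ss[13] + full_ss[14],
           full_ss[10], full_ss[12])
  expect_lt(max(abs(full_rhs(sys, red))), 1e-6)
  # and the projected planar point matches the reduced projection
  pf <- fm$project(full_ss, sys$params)
  pr <- sys$trajectory_projection(red, sys$params)
  expect_equal(unname(pf), unname(pr), tolerance = 1e-6)
})

test_that("reduced and full 2+2 trajectories agree after the transient", {
  sys <- get_model("mapk22_reduced", c(E1tot = 0.4))
  fm <- sys$full_model
  tr_red <- integrate_system(sys, sys$default_initial, 2500, n_out = 400)
  tr_full <- integrate_system(sys, fm$initial(c(sys$params)), 2500,
                              n_out = 400, use_full = TRUE)
  app_red <- tail(tr_red$states[, "App"], 1)
  app_full <- tail(tr_full$states[, "App"], 1)
  expect_lt(abs(app_red - app_full) / max(app_full, 1e-12), 0.02)
})

test_that("2+2 motif oscillates with narrow peaks inside its input window", {
  sys <- get_model("mapk22_reduced")
  osc <- set_param(sys, "E1tot", pseudonull:::mapk22_osc_input())
  traj <- integrate_system(osc, osc$default_initial, 3000, n_out = 3000)
  lc <- detect_limit_cycle(traj, "App")
  expect_true(lc$exists)
  expect_lt(lc$duty, 0.5)   # brief peaks, mostly-off output
  expect_gt(lc$amplitude, 0.5)
})

test_that("toy systems expose their analytic structure", {
  lin <- get_model("linear_toy")
  r <- full_system_roots(lin)
  expect_equal(nrow(r), 1L)
  expect_equal(unname(r[1, ]), c(1, 1), tolerance = 1e-9)
  sn <- get_model("sn_normal_form", c(p = 0.49))
  rs <- full_system_roots(sn)
  expect_equal(sort(unname(rs[, 1])), c(-0.7, 0.7), tolerance = 1e-8)
})
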