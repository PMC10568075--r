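test_that("integration reproduces simple exponential decay", {
  m1 <- module_spec("x", function(x, a, p) -x[1],
                    bounds = rbind(-2, 2))
  m2 <- module_spec("y", function(y, b, p) -y[1],
                    bounds = rbind(-2, 2))
  cp <- coupling_map(function(y, p, x = NULL) y[1],
                     function(x, p, y = NULL) x[1])
  sys <- coupled_system(m1, m2, cp, c(dummy = 0))
  traj <- integrate_system(sys, c(1, 1), 20)
  expect_lt(max(abs(tail(traj$states, 1))), 1e-8)
  expect_true(all(diff(traj$times) > 0))
  expect_error(integrate_system(sys, c(1, 1, 1), 10), "length")
})

test_that("limit-cycle detector separates cycles from damped spirals", {
  damped <- get_model("hopf_normal_form", c(p = -0.1))
  td <- integrate_system(damped, c(x = 0.5, y = 0), 300)
  expect_false(detect_limit_cycle(td, "x")$exists)

  osc <- get_model("hopf_normal_form", c(p = 0.25))
  to <- integrate_system(osc, c(x = 0.1, y = 0), 200)
  lc <- detect_limit_cycle(to, "x")
  expect_true(lc$exists)
  # normal form: angular frequency 1, radius sqrt(p)
  expect_equal(lc$period, 2 * pi, tolerance = 0.01)
  expect_equal(lc$amplitude, 2 * sqrt(0.25), tolerance = 0.01)
  expect_equal(lc$duty, 0.5, tolerance = 0.05)

  short <- integrate_system(osc, c(x = 0.1, y = 0), 1, n_out = 60)
  expect_true(detect_limit_cycle(short, "x")$inconclusive)
})

test_that("cell-cycle trajectory spirals into the refined intersection", {
  sys <- get_model("cellcycle", c(k_synth = 0.04))
  res <- analyze_plane(sys, n_grid = 150)
  stable <- Filter(function(z) startsWith(z$stability, "stable"),
                   res$intersections)
  expect_equal(length(stable), 1L)
  expect_equal(stable[[1]]$stability, "stable_focus")  # spiral approach
  traj <- integrate_system(sys, sys$default_initial, 30000, n_out = 4000)
  endpoint <- tail(traj$states, 1)[1, ]
  expect_lt(max(abs(endpoint - stable[[1]]$state)), 1e-3)
  lc <- detect_limit_cycle(traj, "cdk1a")
  expect_false(isTRUE(lc$exists))
})

test_that("excitability probe classifies both sides of a SNIC saddle", {
  # planar system: circle attractor r = 1 with angular drift
  # theta' = 1 - eta - cos(theta); for small eta a node/saddle pair sits
  # on the circle, and an above-saddle kick travels the whole loop
  # before returning -- the textbook large excursion
  eta <- 0.005
  om <- function(x, y) (1 - eta) - x / sqrt(x^2 + y^2 + 1e-6)
  m1 <- module_spec("x", function(x, a, p) {
    r2 <- x[1]^2 + a^2
    x[1] * (1 - r2) - a * om(x[1], a)
  }, bounds = rbind(-1.5, 1.5))
  m2 <- module_spec("y", function(y, b, p) {
    r2 <- b^2 + y[1]^2
    y[1] * (1 - r2) + b * om(b, y[1])
  }, bounds = rbind(-1.5, 1.5))
  cp <- coupling_map(function(y, p, x = NULL) y[1],
                     function(x, p, y = NULL) x[1])
  sys <- coupled_system(m1, m2, cp, c(dummy = 0), name = "snic_circle")
  th <- acos(1 - eta)
  roots <- full_system_roots(sys, n_starts = 80L)
  expect_equal(nrow(roots), 3L)   # origin plus the node/saddle pair
  labs <- vapply(seq_len(nrow(roots)), function(k)
    pseudonull:::stability_label(
      eigen(full_jacobian(sys, roots[k, ]), only.values = TRUE)$values), "")
  expect_true("stable_node" %in% labs)
  expect_true("saddle" %in% labs)
  saddle_st <- roots[labs == "saddle", , drop = FALSE][1, ]
  stable_st <- roots[labs == "stable_node", , drop = FALSE][1, ]
  expect_equal(unname(saddle_st), c(cos(th), sin(th)), tolerance = 1e-4)
  mk_int <- function(st, lab) structure(
    list(state = st, stability = lab, classification = "transversal"),
    class = "pn_intersection")
  kick <- c(cos(1.5 * th), sin(1.5 * th)) # just past the saddle
  soft <- c(cos(0.5 * th), sin(0.5 * th)) # between saddle and node
  rep <- excitability_probe(sys, mk_int(saddle_st, "saddle"),
                            mk_int(stable_st, "stable_node"),
                            list(kick, soft, stable_st), t_end = 400)
  expect_equal(rep$outcome, c("large_excursion", "direct_return",
                              "direct_return"))
  expect_gt(rep$max_distance[1], 1.5)   # reached the far side of the loop
  expect_error(excitability_probe(sys, mk_int(stable_st, "stable_node"),
                                  mk_int(stable_st, "stable_node"),
                                  list(kick)),
               "not classified as a saddle")
})

test_that("modified cell-cycle saddle separates the two basins", {
  sys <- get_model("cellcycle",
                   c(r = 10, ec50_plx = 72, extra = 2.6e-5,
                     k_synth = 0.15))
  res <- analyze_plane(sys, n_grid = 150)
  labs <- vapply(res$intersections, `[[`, "", "stability")
  expect_true("saddle" %in% labs)
  saddle <- res$intersections[[which(labs == "saddle")[1]]]
  stable_idx <- which(startsWith(labs, "stable"))
  expect_gt(length(stable_idx), 0)
  # probe relative to the low-Cdk1 stable state
  low <- stable_idx[which.min(vapply(stable_idx, function(i)
    res$intersections[[i]]$state[1], 0))]
  stable <- res$intersections[[low]]
  above <- saddle$state + c(2, 0, 0, 0)  # displaced along Cdk1_a
  below <- saddle$state - c(2, 0, 0, 0)
  rep <- excitability_probe(sys, saddle, stable,
                            list(above, below, stable$state),
                            t_end = 30000)
  expect_equal(rep$outcome[3], "direct_return")  # zero perturbation
  expect_equal(rep$outcome[2], "direct_return")  # below the saddle
  # above the saddle the trajectory leaves for the other attractor
  expect_false(rep$outcome[1] == "direct_return")
})
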