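test_that("module root sweep finds the unique root of a relaxing module", {
  m <- module_spec("x", function(x, a, p) a - x[1],
                   bounds = rbind(lower = -5, upper = 5))
  r <- sweep_module_roots(m, 2, c(dummy = 0))
  expect_equal(nrow(r), 1L)
  expect_equal(unname(r[1, 1]), 2, tolerance = 1e-9)
})

test_that("traced FHN pseudo-nullcline matches the analytic cubic", {
  sys <- get_model("fhn_toy")
  pnc <- trace_pseudo_nullcline(sys$module1, params = sys$params,
                                grid = seq(-1.2, 2.6, length.out = 150))
  expect_gt(length(pnc$branches), 0)
  npts <- 0
  for (br in pnc$branches) {
    for (i in seq_len(nrow(br))) {
      w <- br$input[i]; v <- br$v[i]
      # the point satisfies the cubic nullcline equation...
      expect_lt(abs(fhn_cubic_w(v, sys$params) - w), 1e-6)
      # ...and agrees with a closed-form root for that input
      expect_lt(min(abs(fhn_v_roots(w, sys$params) - v)), 1e-6)
      npts <- npts + i * 0 + 1
    }
  }
  expect_gt(npts, 100)
  # the folded cubic yields three sheets over the bistable input range
  mid <- fhn_v_roots(0.6, sys$params)
  expect_equal(length(mid), 3L)
  counts <- vapply(pnc$branches, function(b)
    sum(b$input > 0.45 & b$input < 0.7), 0L)
  expect_equal(sum(counts > 0), 3L)
})

test_that("every traced point passes the steady-state residual bound", {
  for (name in c("fhn_toy", "cellcycle")) {
    sys <- get_model(name)
    gr <- pseudonull:::input_grid_for(sys, 2L, 80L)
    pnc <- trace_pseudo_nullcline(sys$module2, params = sys$params,
                                  grid = gr, module_id = 2L)
    for (br in pnc$branches)
      expect_lt(max(br$residual), 1e-9)
  }
})

test_that("grid refinement is self-consistent on the FHN cubic", {
  sys <- get_model("fhn_toy")
  g1 <- seq(-1.2, 2.6, length.out = 100)
  g2 <- seq(-1.2, 2.6, length.out = 200)
  p1 <- trace_pseudo_nullcline(sys$module1, params = sys$params, grid = g1)
  p2 <- trace_pseudo_nullcline(sys$module1, params = sys$params, grid = g2)
  expect_equal(length(p1$branches), length(p2$branches))
  # every coarse-grid point is reproduced on the fine grid
  pts1 <- do.call(rbind, lapply(p1$branches, function(b)
    cbind(b$input, b$v)))
  pts2 <- do.call(rbind, lapply(p2$branches, function(b)
    cbind(b$input, b$v)))
  for (i in seq_len(nrow(pts1))) {
    d <- abs(pts2[, 1] - pts1[i, 1]) + abs(pts2[, 2] - pts1[i, 2])
    j <- which(abs(pts2[, 1] - pts1[i, 1]) < 1e-9)
    if (length(j))
      expect_lt(min(abs(pts2[j, 2] - pts1[i, 2])), 1e-6)
  }
})

test_that("projection applies transforms and drops undefined points", {
  sys <- get_model("fhn_toy")
  pnc <- trace_pseudo_nullcline(sys$module2, params = sys$params,
                                grid = seq(-2, 2, length.out = 50),
                                module_id = 2L)
  ident <- project_curve(pnc, sys,
                         transform = function(inp, st, p) c(inp, st[1]))
  n_id <- sum(vapply(ident$branches, nrow, 0L))
  n_src <- sum(vapply(pnc$branches, nrow, 0L))
  expect_equal(n_id, n_src)
  # affine round trip
  fwd <- function(inp, st, p) c(2 * inp + 1, -3 * st[1] + 0.5)
  pc <- project_curve(pnc, sys, transform = fwd)
  for (b in seq_along(pc$branches)) {
    df <- pc$branches[[b]]
    expect_equal((df$u - 1) / 2, df$input, tolerance = 1e-12)
    expect_equal((df$v - 0.5) / -3, df$w, tolerance = 1e-12)
  }
  # undefined points are dropped, not propagated
  bad <- project_curve(pnc, sys, transform = function(inp, st, p)
    if (inp < 0) stop("undefined") else c(inp, st[1]))
  expect_true(all(unlist(lapply(bad$branches, `[[`, "input")) >= 0))
})

test_that("segment intersection finds the analytic crossing of two lines", {
  mkline <- function(a, b, id) {
    u <- seq(-1, 1, length.out = 20)
    structure(list(branches = list(data.frame(u = u, v = a * u + b,
                                              input = u, residual = 0,
                                              branch_id = 1L)),
                   labels = c("u", "v"), module_id = id,
                   state_names = character(0)),
              class = "pn_planar")
  }
  c1 <- mkline(1, 0, 1L)
  c2 <- mkline(-1, 0.5, 2L)
  hits <- find_intersections(c1, c2)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$u, 0.25, tolerance = 1e-12)
  expect_equal(hits$v, 0.25, tolerance = 1e-12)
  # mismatched planes are a configuration error
  c3 <- mkline(0, 1, 2L)
  c3$labels <- c("p", "q")
  expect_error(find_intersections(c1, c3), "different planes")
})

test_that("grazing contacts are surfaced without a crossing", {
  u <- seq(-1, 1, length.out = 200)
  mk <- function(v) structure(
    list(branches = list(data.frame(u = u, v = v, input = u,
                                    residual = 0, branch_id = 1L)),
         labels = c("u", "v"), module_id = 1L, state_names = character(0)),
    class = "pn_planar")
  par1 <- mk(u^2)            # parabola grazing the axis at u = 0
  axis <- mk(rep(-1e-5, length(u)))
  hits <- find_intersections(par1, axis, graze_tol = 1e-3)
  expect_true(any(hits$type == "grazing"))
  g <- hits[hits$type == "grazing", ][1, ]
  expect_lt(abs(g$u), 0.02)
})

test_that("refined intersections equal analytic fixed points and classify", {
  sys <- get_model("linear_toy")
  res <- analyze_plane(sys, n_grid = 60)
  expect_equal(length(res$intersections), 1L)
  z <- res$intersections[[1]]
  expect_equal(unname(z$state), c(1, 1), tolerance = 1e-9)
  expect_equal(z$classification, "transversal")
  expect_equal(z$stability, "stable_node")
  expect_lt(z$residual, 1e-9)

  fhn <- get_model("fhn_toy")
  resf <- analyze_plane(fhn, n_grid = 120)
  expect_equal(length(resf$intersections), 1L)
  zf <- resf$intersections[[1]]
  vstar <- uniroot(function(v) fhn_cubic_w(v, fhn$params) -
                     fhn_linear_w(v, fhn$params), c(-2, 2),
                   tol = 1e-14)$root
  expect_equal(unname(zf$state[1]), vstar, tolerance = 1e-8)
  expect_equal(zf$stability, "unstable_focus")
})

test_that("refined intersections match brute-force full-system roots", {
  for (name in c("fhn_toy", "linear_toy", "hopf_normal_form")) {
    sys <- get_model(name)
    res <- analyze_plane(sys, n_grid = 100)
    bf <- brute_force_roots(sys, n_grid = 7L)
    expect_equal(length(res$intersections), nrow(bf), info = name)
    for (z in res$intersections) {
      d <- apply(bf, 1, function(r) max(abs(r - z$state)))
      expect_lt(min(d), 1e-6)
    }
  }
})

test_that("cell-cycle Cdk1 module is bistable inside its window", {
  sys <- get_model("cellcycle", c(k_synth = 0.05))
  p <- sys$params
  # dense-grid 1-D oracle fixes the expected root count per input
  for (a in c(2e-4, 5e-3, 0.3)) {
    oracle <- cellcycle_module1_roots_1d(a, p, n = 1e4)
    swept <- sweep_module_roots(sys$module1, a, p)
    expect_equal(nrow(swept), length(oracle), info = paste("apca =", a))
    if (length(oracle))
      expect_equal(sort(unname(swept[, 1])), oracle, tolerance = 1e-6)
  }
  counts <- vapply(c(2e-4, 5e-3, 0.3), function(a)
    nrow(sweep_module_roots(sys$module1, a, p)), 0L)
  expect_true(3 %in% counts)
})
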