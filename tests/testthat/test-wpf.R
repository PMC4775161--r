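test_that("model intensity is a linear sum of per-reflection profiles", {
  tc <- tiny_model_case()
  # doubling every F2 doubles every pixel
  r2 <- tc$refl
  r2$refl$F2 <- 2 * r2$refl$F2
  expect_equal(model_intensity(r2, tc$params, tc$geom)$I, 2 * tc$obs$I,
               tolerance = 1e-12)
  # a single-orbit set: any pixel equals the sum of the 4 orbit members'
  # profiles, evaluated independently at the pixel's exact q
  cell <- tc$cell
  one <- enumerate_reflections(cell, 60, quadrant_only = TRUE)
  expect_identical(nrow(one$refl), 1L)  # just the (1, 0) orbit
  one$refl$F2 <- 4
  m <- model_intensity(one, tc$params, tc$geom)
  q <- q_axis(tc$geom)
  px <- c(61L, 49L, 40L)
  py <- c(49L, 61L, 52L)
  mates_qx <- c(1, 0, -1, 0) / cell$a
  mates_qy <- c(0, 1, 0, -1) / cell$a
  for (i in seq_along(px)) {
    oracle <- sum(4 * profile2d(cbind(q[px[i]] - mates_qx,
                                      q[py[i]] - mates_qy), tc$params))
    expect_equal(m$I[px[i], py[i]], oracle, tolerance = 1e-10)
  }
})

test_that("midpoint between two peaks matches the closed-form tail sum", {
  # Laue class "1": only Friedel mates, easy to keep track of analytically
  cell <- unit_cell(50, 50, 50, laue_class = "1")
  geom <- grid_geometry(64, 0.05)
  refl <- enumerate_reflections(cell, 45, quadrant_only = TRUE)
  astar <- 1 / cell$a
  params <- peak_params(0, 0, astar, 0.3 * astar, astar, 0.3 * astar)
  refl$refl$F2 <- rep(5, nrow(refl$refl))
  m <- model_intensity(refl, params, geom)
  # midpoint on the x axis between (1,0) and its Friedel mate (-1,0) is the
  # origin-adjacent saddle at (0 + a*/2, 0); sum pure-Lorentzian terms from
  # all expanded peaks with the hand formula
  full <- symmetry_expand(refl)
  lor <- function(x, g) (g / (2 * pi)) / (x^2 + (g / 2)^2)
  mid <- c(astar / 2, 0)
  oracle <- sum(5 * lor(mid[1] - full$refl$qx, 0.3 * astar) *
                  lor(mid[2] - full$refl$qy, 0.3 * astar))
  ix <- wpfx:::q_to_index(geom, mid[1])
  iy <- wpfx:::q_to_index(geom, mid[2])
  expect_equal(m$I[ix, iy], oracle, tolerance = 0.01 * oracle)
})

test_that("the error-cost function has its closed-form values", {
  geom <- grid_geometry(20, 0.1)
  set.seed(2)
  I <- matrix(runif(400, 1, 5), 20, 20)
  p1 <- pattern(geom, I)
  expect_identical(fit_cost(p1, p1), 0)
  p2 <- pattern(geom, I + 0.25)
  expect_equal(fit_cost(p1, p2), 400 * 0.25^2, tolerance = 1e-10)
  # permutation invariance of the pixel sum
  perm <- sample(400)
  p3 <- pattern(geom, matrix(I[perm], 20, 20))
  p4 <- pattern(geom, matrix((I + 0.25)[perm], 20, 20))
  expect_equal(fit_cost(p3, p4), fit_cost(p1, p2), tolerance = 1e-10)
  expect_error(fit_cost(p1, pattern(grid_geometry(20, 0.2), I)),
               class = "wpfx_invalid_input")
})

test_that("observed peak intensities interpolate the grid bilinearly", {
  tc <- tiny_model_case()
  # constant pattern: every reflection reads the constant
  pc <- pattern(tc$geom, matrix(3.5, tc$geom$n, tc$geom$n))
  expect_equal(observed_peak_intensities(pc, tc$refl),
               rep(3.5, nrow(tc$refl$refl)))
  # a Bragg position moved onto an exact pixel center reads that pixel
  cell_al <- unit_cell(1 / (4 * tc$geom$dq), c = 90, laue_class = "4/m")
  rs_al <- enumerate_reflections(cell_al, 1 / (3 * 1 / cell_al$a),
                                 quadrant_only = TRUE)
  set.seed(3)
  I <- matrix(runif(tc$geom$n^2), tc$geom$n, tc$geom$n)
  pr <- pattern(tc$geom, I)
  got <- observed_peak_intensities(pr, rs_al)
  idx <- cbind(round(wpfx:::q_to_index(tc$geom, rs_al$refl$qx)),
               round(wpfx:::q_to_index(tc$geom, rs_al$refl$qy)))
  expect_equal(got, I[idx])
  # model-generated pattern at ~32 px between Bragg peaks: bilinear reads
  # match the analytic model within 0.5%
  cell <- langerin_cell()
  geom32 <- grid_geometry(128, 2 / cell$a)     # dq = a*/32
  rs32 <- enumerate_reflections(cell, cell$a / 1.9, quadrant_only = TRUE)
  astar <- 1 / cell$a
  p32 <- peak_params(0.6, 0.6, 0.25 * astar, 0.3 * astar, 0.25 * astar,
                     0.3 * astar)
  rs32$refl$F2 <- c(2, 5)
  obs32 <- model_intensity(rs32, p32, geom32)
  full32 <- symmetry_expand(rs32)
  direct <- sapply(seq_len(nrow(rs32$refl)), function(j) {
    sum(full32$refl$F2 *
          profile2d(cbind(rs32$refl$qx[j] - full32$refl$qx,
                          rs32$refl$qy[j] - full32$refl$qy), p32))
  })
  reads <- observed_peak_intensities(obs32, rs32)
  expect_lt(max(abs(reads - direct) / direct), 0.005)
})

test_that("reflections outside the grid are flagged with a warning", {
  cell <- langerin_cell()
  geom <- grid_geometry(32, 0.02)   # (1,0) inside, (2,0) beyond the edge
  rs <- enumerate_reflections(cell, 30)
  p <- pattern(geom, matrix(1, 32, 32))
  expect_warning(v <- observed_peak_intensities(p, rs), "outside")
  expect_true(any(is.na(v)))
})

test_that("the P matrix contains profile cross-contributions", {
  cell <- langerin_cell()
  astar <- 1 / cell$a
  rs <- enumerate_reflections(cell, 30)
  # isolated-peak limit: pure Gaussian widths far below the spacing (the
  # power-law Lorentzian tails never reach 1e-12 of the peak)
  p_narrow <- peak_params(1, 1, astar / 20, astar / 20,
                          astar / 20, astar / 20)
  P <- build_P(rs, p_narrow)
  expect_equal(unname(diag(P)), rep(peak_value(p_narrow), nrow(P)))
  off <- P - diag(diag(P))
  expect_lt(max(off) / peak_value(p_narrow), 1e-12)
  # entries equal the independently computed profile at the offset
  p_med <- peak_params(0.4, 0.6, 0.3 * astar, 0.5 * astar, 0.2 * astar,
                       0.4 * astar)
  P2 <- build_P(rs, p_med)
  expect_equal(P2, t(P2), tolerance = 1e-12)
  i <- 3L; j <- 7L
  dq <- c(rs$refl$qx[j] - rs$refl$qx[i], rs$refl$qy[j] - rs$refl$qy[i])
  expect_equal(P2[j, i],
               oracle_pv(dq[1], 0.4, 0.3 * astar, 0.5 * astar) *
                 oracle_pv(dq[2], 0.6, 0.2 * astar, 0.4 * astar),
               tolerance = 1e-12)
  expect_true(all(P2 >= 0))
})

test_that("Gaussian elimination solves the moduli system", {
  # hand-eliminated 2x2 case
  expect_equal(solve_moduli(matrix(c(1, 0.2, 0.2, 1), 2), c(1.2, 1.2)),
               c(1, 1), tolerance = 1e-12)
  # diagonal system divides through by the peak value
  pv <- 0.83
  expect_equal(solve_moduli(diag(pv, 5), c(1:5) * pv), as.numeric(1:5),
               tolerance = 1e-12)
  # identical rows are singular
  expect_error(solve_moduli(matrix(c(1, 1, 2, 2), 2, byrow = TRUE), c(1, 1)),
               class = "wpfx_singular_system")
  # random diagonally dominant system cross-checked against base::solve
  set.seed(4)
  A <- matrix(runif(64, 0, 0.1), 8, 8); diag(A) <- 1 + runif(8)
  b <- runif(8, 1, 3)
  expect_equal(solve_moduli(A, b, clamp = FALSE), as.numeric(solve(A, b)),
               tolerance = 1e-10)
  # negative components are clamped with a warning
  expect_warning(x <- solve_moduli(diag(2), c(1, -0.5)), "clamped")
  expect_equal(x, c(1, 0))
})

test_that("condition numbers come from the singular spectrum", {
  expect_equal(condition_number(diag(4)), 1)
  expect_equal(condition_number(matrix(c(1, 0.2, 0.2, 1), 2)), 1.5,
               tolerance = 1e-12)
  expect_equal(condition_number(diag(c(2, 1))), 2)
  expect_gt(condition_number(matrix(c(1, 1, 1, 1), 2)), 1e12)
})

test_that("R factors match their closed forms and a direct summation", {
  geom <- grid_geometry(16, 0.1)
  set.seed(5)
  Io <- matrix(runif(256, 0.5, 4), 16, 16)
  po <- pattern(geom, Io)
  expect_equal(r_factors(po, po), list(r_p = 0, r_wp = 0))
  eps <- 0.03
  pc <- pattern(geom, (1 + eps) * Io)
  rf <- r_factors(po, pc)
  expect_equal(rf$r_p, eps, tolerance = 1e-12)
  expect_equal(rf$r_wp, eps, tolerance = 1e-12)
  # random calculated pattern against the two-line oracle
  Ic <- matrix(runif(256, 0.5, 4), 16, 16)
  rf2 <- r_factors(po, pattern(geom, Ic))
  expect_equal(rf2$r_p, sum(abs(Io - Ic)) / sum(Io), tolerance = 1e-12)
  expect_equal(rf2$r_wp, sqrt(sum((Io - Ic)^2) / sum(Io^2)),
               tolerance = 1e-12)
})

test_that("refinement is a fixed point on exact model data", {
  tc <- tiny_model_case()
  fit <- refine(tc$obs, tc$refl, tc$params, fit_config(max_cycles = 5))
  expect_lt(fit$r_wp, 1e-10)
  expect_lte(fit$n_cycles, 2L)
  expect_lt(max(abs(fit$reflections$refl$F2 - tc$refl$refl$F2) /
                  tc$refl$refl$F2), 1e-8)
  expect_true(all(diff(fit$cost_trace) <= 0))
})

test_that("refinement recovers truth from perturbed starting shapes", {
  tc <- tiny_model_case()
  astar <- 1 / tc$cell$a
  init <- peak_params(0.5, 0.5, 1.5 * 0.25 * astar, 1.2 * astar * 0.25 / 1.5,
                      1.5 * 0.8 * 0.25 * astar, 0.25 * astar / 1.5)
  fit <- refine(tc$obs, tc$refl, init,
                fit_config(max_cycles = 20, cost_rel_tol = 1e-10,
                           optimizer = "least-squares"))
  expect_lt(max(abs(fit$reflections$refl$F2 - tc$refl$refl$F2) /
                  tc$refl$refl$F2), 1e-3)
  for (fld in c("eta_x", "eta_y", "gamma_gx", "gamma_lx", "gamma_gy",
                "gamma_ly")) {
    expect_lt(abs(fit$params[[fld]] - tc$params[[fld]]) /
                abs(tc$params[[fld]]), 0.01)
  }
})

test_that("extraction is equivariant under intensity rescaling", {
  tc <- tiny_model_case()
  fit1 <- refine(tc$obs, tc$refl, tc$params, fit_config(max_cycles = 3))
  scaled <- pattern(tc$geom, 7.5 * tc$obs$I)
  fit2 <- refine(scaled, tc$refl, tc$params, fit_config(max_cycles = 3))
  expect_equal(fit2$reflections$refl$F2, 7.5 * fit1$reflections$refl$F2,
               tolerance = 1e-8)
  expect_equal(fit2$r_p, fit1$r_p, tolerance = 1e-8)
  expect_equal(fit2$r_wp, fit1$r_wp, tolerance = 1e-8)
  expect_equal(fit2$cond, fit1$cond, tolerance = 1e-8)
})

test_that("P conditioning stays near 1 for narrow widths and grows with width", {
  cell <- langerin_cell()
  astar <- 1 / cell$a
  reps <- enumerate_reflections(cell, 5, quadrant_only = TRUE)
  conds <- vapply(c(0.1, 0.2, 0.3, 0.4, 0.8), function(w) {
    p <- peak_params(0.5, 0.5, w * astar, w * astar, w * astar, w * astar)
    condition_number(wpfx:::build_P_system(reps, p)$P)
  }, numeric(1))
  expect_true(all(diff(conds) > 0))
  expect_true(all(conds[1:4] < 2))   # widths up to 0.4 a*
  expect_gte(min(conds), 1)
})

test_that("overlap decomposition isolates neighbour contributions", {
  tc <- tiny_model_case()
  astar <- 1 / tc$cell$a
  reps <- wpfx:::quadrant_reduce(tc$refl)
  F2 <- reps$refl$F2
  radii <- seq(astar / 16, astar / 2, length.out = 8)
  # all other orbits zero: only the far symmetry mates of the peak itself
  # remain, so the neighbour share stays marginal and vanishes at the peak
  F2_solo <- rep(0, length(F2)); F2_solo[3] <- 5
  ov0 <- overlap_decomposition(reps, tc$params, F2_solo, 3, radii)
  expect_lt(ov0$percent[1], 0.1)
  expect_true(all(ov0$percent < 2))
  # equal neighbours around a strong peak: non-decreasing with radius
  F2_eq <- rep(1, length(F2)); F2_eq[3] <- 10
  ov1 <- overlap_decomposition(reps, tc$params, F2_eq, 3, radii)
  expect_true(all(diff(ov1$percent[!is.na(ov1$percent)]) > -1e-9))
  expect_error(overlap_decomposition(reps, tc$params, F2_eq, 0, radii),
               class = "wpfx_invalid_input")
})
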