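test_that("zero-yield-stress pressure gradient has its closed form", {
  expect_equal(q_powerlaw(1, 1, newtonian_fluid()), 8)   # Poiseuille
  fl <- power_law_fluid(0.8, 1.2)
  expect_equal(q_powerlaw(R_STEN, 1, fl), 17.7746, tolerance = 1e-4)
  expect_equal(q_powerlaw(R_DILA, 1, fl), 4.9801, tolerance = 1e-4)
})

test_that("implicit-relation residual vanishes at the root and guards its domain", {
  fl <- table_fluid(0.05)
  x <- 17.9423
  expect_lt(abs(flow_rate_residual(x, R_STEN, 1, fl)) /
              ((3 * 0.8 + 1) * x^3 / (0.8 * R_STEN^2)), 1e-4)
  # tau_y = 0: the power-law gradient is the exact root
  fl0 <- power_law_fluid(0.8, 1.2)
  expect_equal(flow_rate_residual(q_powerlaw(0.9, 1, fl0), 0.9, 1, fl0), 0,
               tolerance = 1e-10)
  expect_error(flow_rate_residual(0.1, R_STEN, 1, table_fluid(0.5)),
               "flowing state")
})

test_that("the root is bracketed by a sign change of the residual", {
  for (ty in c(0.05, 0.8, 2.4)) {
    fl <- table_fluid(ty)
    for (R in c(R_STEN, R_DILA)) {
      q0 <- q_powerlaw(R, 1, fl)
      q1 <- 2 * (3 * 0.8 + 1) / ((2 * 0.8 + 1) * R)
      lo <- max(0.5 * q0, 2 * ty / R + 1e-9)
      hi <- q0 + 2 * q1 * ty + 10
      expect_gt(flow_rate_residual(lo, R, 1, fl), 0)
      expect_lt(flow_rate_residual(hi, R, 1, fl), 0)
    }
  }
})

test_that("Newton-Raphson agrees with an independent bisection oracle", {
  cases <- expand.grid(n = c(0.6, 0.8, 1, 1.4), tau_y = c(0.05, 0.8, 2.4),
                       R = c(R_STEN, 1, R_DILA))
  for (i in seq_len(nrow(cases))) {
    fl <- hb_fluid(cases$n[i], 1.2, cases$tau_y[i])
    newton <- solve_pressure_gradient(cases$R[i], 1, fl)
    oracle <- bisect_pressure_gradient(cases$R[i], 1, fl)
    expect_equal(newton, oracle, tolerance = 1e-9)
  }
})

test_that("solver roundtrips the prescribed flow rate", {
  cases <- expand.grid(n = c(0.5, 0.8, 1, 1.5), k = c(1, 1.2, 1.4),
                       tau_y = c(0, 0.1, 1.2, 2.4), R = c(R_STEN, R_DILA),
                       Q = c(0.5, 1, 2))
  for (i in seq_len(nrow(cases))) {
    fl <- hb_fluid(cases$n[i], cases$k[i], cases$tau_y[i])
    q <- solve_pressure_gradient(cases$R[i], cases$Q[i], fl)
    expect_equal(hb_flow_rate(q, cases$R[i], fl), cases$Q[i],
                 tolerance = 1e-8)
  }
})

test_that("pressure gradient is monotone in yield stress, flow rate and radius", {
  base <- function(ty = 0.4, Q = 1, R = 0.9)
    solve_pressure_gradient(R, Q, hb_fluid(0.8, 1.2, ty))
  tys <- c(0.05, 0.4, 1.2, 2.4)
  expect_true(all(diff(vapply(tys, function(t) base(ty = t), 0)) > 0))
  Qs <- c(0.5, 1, 2, 4)
  expect_true(all(diff(vapply(Qs, function(q) base(Q = q), 0)) > 0))
  Rs <- c(0.7, 0.9, 1.1, 1.3)
  expect_true(all(diff(vapply(Rs, function(r) base(R = r), 0)) < 0))
})

test_that("solver edge cases: zero yield stress, vectorised radii, options", {
  fl0 <- power_law_fluid(0.8, 1.2)
  expect_identical(solve_pressure_gradient(0.9, 1, fl0),
                   q_powerlaw(0.9, 1, fl0))
  # vectorised call matches elementwise calls
  fl <- table_fluid(0.8)
  Rs <- c(0.78, 0.9, 1, 1.134)
  expect_equal(solve_pressure_gradient(Rs, 1, fl),
               vapply(Rs, function(r) solve_pressure_gradient(r, 1, fl), 0))
  expect_error(solve_pressure_gradient(1, 1, fl, tol = 1e-3), "tol")
  expect_error(solve_pressure_gradient(1, 1, fl, max_iter = 2), "max_iter")
})

test_that("small-yield-stress expansion reduces correctly", {
  fl0 <- power_law_fluid(0.8, 1.2)
  expect_identical(q_analytical(R_STEN, 1, fl0), q_powerlaw(R_STEN, 1, fl0))
  # Newtonian: both routes give exactly 8kQ/R^4
  expect_equal(q_analytical(1, 1, newtonian_fluid()), 8)
  expect_equal(solve_pressure_gradient(1, 1, newtonian_fluid()), 8)
  # Bingham linear correction: wall-shear tau_y coefficient is 4/3
  ty <- 1e-6
  tw0 <- wall_shear_analytical(0.9, 1, bingham_fluid(1, 0))
  tw <- wall_shear_analytical(0.9, 1, bingham_fluid(1, ty))
  expect_equal((tw - tw0) / ty, 4 / 3, tolerance = 1e-6)
})

test_that("analytical wall shear stress follows tau_w = R q_a / 2", {
  expect_equal(wall_shear_analytical(1, 1, newtonian_fluid()), 4)
  expect_equal(wall_shear_analytical(R_STEN, 1, table_fluid(0.1)),
               7.0631, tolerance = 1e-3)
})

test_that("the quadratic coefficient function is injectable", {
  fl <- table_fluid(2)
  a <- q_analytical(R_STEN, 1, fl)
  b <- q_analytical(R_STEN, 1, fl, quad_coef = function(n) 0)
  q1 <- 2 * (3 * 0.8 + 1) / ((2 * 0.8 + 1) * R_STEN)
  expect_equal(b, q_powerlaw(R_STEN, 1, fl) + q1 * 2)
  expect_gt(a, b)
  expect_equal(hb_quadratic_coef(0.8), 0.5548, tolerance = 1e-4)
})
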