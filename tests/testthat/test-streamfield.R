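test_that("Newtonian stream function has its closed form", {
  r <- seq(0, 1, by = 0.1)
  expect_equal(stream_function(r, 1, 8, newtonian_fluid()), r^2 - r^4 / 2)
  expect_equal(stream_function(1, 1, 8, newtonian_fluid()), 0.5)  # Q/2
})

test_that("wall streamline carries half the flow rate for any fluid", {
  cases <- expand.grid(n = c(0.5, 0.8, 1, 1.5), tau_y = c(0, 0.1, 0.4, 2.4),
                       R = c(R_STEN, R_DILA), Q = c(0.5, 1))
  for (i in seq_len(nrow(cases))) {
    fl <- hb_fluid(cases$n[i], 1.2, cases$tau_y[i])
    q <- solve_pressure_gradient(cases$R[i], cases$Q[i], fl)
    expect_equal(stream_function(cases$R[i], cases$R[i], q, fl),
                 cases$Q[i] / 2, tolerance = 1e-8)
  }
})

test_that("stream function differentiates to the velocity field", {
  fl <- hb_fluid(0.8, 1.2, 0.4)
  q <- solve_pressure_gradient(R_STEN, 1, fl)
  h <- 1e-4
  r <- seq(0.05, R_STEN - 2 * h, length.out = 40)
  dpsi <- (stream_function(r + h, R_STEN, q, fl) -
             stream_function(r - h, R_STEN, q, fl)) / (2 * h)
  expect_equal(dpsi / r, hb_velocity(r, R_STEN, q, fl), tolerance = 1e-5)
})

test_that("stream function is smooth across the plug boundary", {
  fl <- table_fluid(1.2)
  q <- solve_pressure_gradient(R_STEN, 1, fl)
  rp <- plug_radius(q, fl)
  expect_gt(rp, 0)
  h <- 1e-6
  # value continuity: the gap across the boundary vanishes linearly with h
  gap <- function(h) abs(stream_function(rp + h, R_STEN, q, fl) -
                           stream_function(rp - h, R_STEN, q, fl))
  expect_lt(gap(h), 10 * h)
  expect_lt(gap(h / 100), 10 * h / 100)
  # derivative continuity (one-sided differences agree to O(h))
  dl <- (stream_function(rp, R_STEN, q, fl) -
           stream_function(rp - h, R_STEN, q, fl)) / h
  dr <- (stream_function(rp + h, R_STEN, q, fl) -
           stream_function(rp, R_STEN, q, fl)) / h
  expect_equal(dl, dr, tolerance = 1e-4)
})

test_that("radial field solves the station and is internally consistent", {
  rf <- radial_field(default_geometry(), table_fluid(0.1), z = 2.5,
                     r_count = 50)
  expect_equal(rf$R, 0.78)
  expect_equal(rf$q, solve_pressure_gradient(0.78, 1, table_fluid(0.1)))
  expect_equal(rf$w[length(rf$w)], 0)
  expect_equal(rf$psi[length(rf$psi)], 0.5, tolerance = 1e-8)
  expect_output(print(rf), "Radial field")
})

test_that("field grid mirrors symmetrically and conserves mass along z", {
  geo <- default_geometry()
  fg <- field_grid(geo, table_fluid(0.1),
                   z_grid = seq(0, 7, by = 0.25), r_count = 20)
  np <- length(fg$r_fraction)
  expect_equal(fg$psi[, 1], fg$psi[, np])             # mirror symmetry
  expect_equal(fg$w[, 1], fg$w[, np])
  expect_equal(fg$psi[, (np + 1) / 2], rep(0, length(fg$z)))  # axis
  expect_equal(fg$psi[, np], rep(0.5, length(fg$z)), tolerance = 1e-8)

  # straight Newtonian tube: every axial column identical
  tube <- field_grid(vessel_geometry(0, list(), 7), newtonian_fluid(),
                     z_grid = c(0, 3, 7), r_count = 10)
  expect_equal(tube$w[1, ], tube$w[2, ])
  expect_equal(tube$psi[1, ], tube$psi[3, ])
})

test_that("centreline velocity rises through the stenosis and falls in the dilatation", {
  fg <- field_grid(default_geometry(), table_fluid(0.1),
                   z_grid = c(0, 2.5, 5.5), r_count = 10)
  mid <- (length(fg$r_fraction) + 1) / 2
  w0 <- fg$w[, mid]
  expect_gt(w0[2], w0[1])   # throat faster than inlet at fixed Q
  expect_lt(w0[3], w0[1])   # crest slower than inlet
})

test_that("streamline contours bend toward the axis in the stenosis and away in the dilatation", {
  geo <- default_geometry()
  fl <- table_fluid(0.1)
  zs <- seq(1.5, 6.5, by = 0.05)
  level <- 0.2
  # radius at which psi crosses the level, per station
  level_radius <- vapply(zs, function(z) {
    R <- vessel_radius(geo, z)
    q <- solve_pressure_gradient(R, 1, fl)
    r <- seq(0, R, length.out = 400)
    psi <- stream_function(r, R, q, fl)
    stats::approx(psi, r, xout = level)$y
  }, 0)
  expect_equal(zs[which.min(level_radius)], 2.5, tolerance = 0.051)
  expect_equal(zs[which.max(level_radius)], 5.5, tolerance = 0.051)
})
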