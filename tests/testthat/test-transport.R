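test_that("one-way endothelial exchange follows the valve rule", {
  expect_equal(exchange_rate_f(2.0, 0.5, 0.03), 0.045)
  expect_equal(exchange_rate_f(1.0, 1.0, 0.03), 0)
  expect_equal(exchange_rate_f(0.5, 2.0, 0.03), 0)   # no back-flux
  expect_true(all(exchange_rate_f(rnorm(50), rnorm(50), 0.1) >= 0))
  expect_error(exchange_rate_f(1, 0, -1), ">= 0")
})

test_that("sortion rate matches the printed expression", {
  expect_equal(sortion_rate_g(2.0, 0.10, 1.0, 0.5, 1.0), 0.9)
  expect_equal(sortion_rate_g(2.0, 0.10, 0.25, 0, 1.0), 0)
  expect_equal(sortion_rate_g(0, 0.10, 1.0, 0.5, 1.0), 0)
})

test_that("influx Gaussian peaks at 1/(sigma sqrt(2 pi)) and is symmetric", {
  expect_equal(influx_concentration_Q(25, sigma = 7, t_peak = 25),
               1 / (7 * sqrt(2 * pi)), tolerance = 1e-12)
  expect_equal(influx_concentration_Q(25, sigma = 7, t_peak = 25),
               0.0569917, tolerance = 1e-6)
  expect_lt(influx_concentration_Q(25 + 300, 7, 25), 1e-12)
  expect_lt(influx_concentration_Q(25 - 300, 7, 25), 1e-12)
  s <- seq(0.5, 20, by = 0.5)
  expect_equal(influx_concentration_Q(25 + s, 7, 25),
               influx_concentration_Q(25 - s, 7, 25))
  expect_equal(influx_concentration_Q(10, 7, 25, X = 0.3),
               influx_concentration_Q(10, 7, 25) + 0.3)
})

test_that("TOPUS preserves constants and falls back to upwind outside [0,1]", {
  expect_equal(topus_face_value(c(1, 1), c(1, 1), c(1, 1)), c(1, 1))
  # non-monotone stencil: normalized variable < 0 -> pure upwind
  expect_equal(topus_face_value(2, 0.5, 1), 0.5)
  # normalized variable > 1 -> pure upwind
  expect_equal(topus_face_value(0, 2, 1), 2)
  # truncated stencil (NA far-upwind) -> pure upwind
  expect_equal(topus_face_value(NA, 0.7, 1), 0.7)
  # inside [0,1]: bounded between upwind and downwind values
  xr <- 0; xd <- 1
  xu <- seq(0.05, 0.95, by = 0.05)
  fv <- topus_face_value(rep(xr, length(xu)), xu, rep(xd, length(xu)))
  expect_true(all(fv >= xu - 1e-12 & fv <= xd + 1e-12))
  # third-order point: normalized value 0.5 maps to 0.75
  expect_equal(topus_face_value(0, 0.5, 1), 0.75)
})

test_that("step advection of a discontinuity creates no new extrema", {
  dom <- strip_domain(40, h = 0.5)
  flow <- strip_flow(dom)                 # u = 0.6 mm/s to the right
  params <- transport_params(P = 0, k_e = 0, D_i = 0, D_e = 0)
  ws <- transport_workspace(dom, flow)
  st <- concentration_state(dom, C_i = c(rep(1, 10), rep(0, 30)))
  dt <- stable_dt(flow, params, dom$h)
  for (i in 1:100) st <- step_explicit(st, flow, params, dom, dt, Q = 0,
                                       workspace = ws)
  expect_gte(min(st$C_i), -1e-12)
  expect_lte(max(st$C_i), 1 + 1e-12)
  expect_equal(st$t, 100 * dt)
})

test_that("stable_dt scales with the binding guard", {
  p <- transport_params()                  # P = 0.03, D = 1e-3, phi = 0.1
  # advective bound with the porosity factor: 0.25 * phi * h / umax
  expect_equal(stable_dt(0.6, p, 0.5), 0.25 * 0.1 * 0.5 / 0.6)
  # halving h halves dt while advection binds
  expect_equal(stable_dt(0.6, p, 0.25), stable_dt(0.6, p, 0.5) / 2)
  # zero velocity: reactive guard P/phi = 0.3 binds (1/0.3 < h^2/4D = 62.5)
  expect_equal(stable_dt(0, p, 0.5), 0.25 / 0.3)
  expect_equal(stable_dt(NaN, p, 0.5), stable_dt(0, p, 0.5))
  # diffusion-only: no rates at all
  pd <- transport_params(P = 0, k_e = 0, D_i = 1e-3, D_e = 1e-3)
  expect_equal(stable_dt(0, pd, 0.5), 0.25 * 0.5^2 / (4 * 1e-3))
  expect_error(stable_dt(0, transport_params(P = 0, k_e = 0, D_i = 0,
                                             D_e = 0), 0.5),
               "no finite stability bound")
})

test_that("a step with all rates and velocities zero is the identity", {
  dom <- strip_domain(8, h = 1)
  flow <- strip_flow(dom, p_left = 1, p_right = 1)   # u = 0
  params <- transport_params(P = 0, k_e = 0, D_i = 0, D_e = 0)
  st0 <- concentration_state(dom, C_i = runif(8), C_e = runif(8))
  st1 <- step_explicit(st0, flow, params, dom, dt = 0.1, Q = 0.5)
  expect_equal(st1$C_i, st0$C_i)
  expect_equal(st1$C_e, st0$C_e)
  expect_equal(st1$t, 0.1)
})

test_that("interstitial washout matches the scalar ODE closed form", {
  dom <- segmented_domain(matrix(c(0L, 1L, 0L), 3, 1), 1)
  flow <- strip_flow(dom, p_left = 1, p_right = 1)
  params <- transport_params(P = 0, k_e = 0.1, D_i = 0, D_e = 0)
  st <- concentration_state(dom, C_e = 1)
  dt <- 1e-2
  for (i in seq_len(200)) st <- step_explicit(st, flow, params, dom, dt, 0)
  expect_equal(st$C_e, exp(-0.1 * 2), tolerance = 1e-3)
  expect_equal(st$C_i, 0)
})

test_that("fibrosis fills linearly from a held interstitial level when k_f = 0", {
  lab <- matrix(c(0L, 1L, 0L), 3, 1)
  dom <- segmented_domain(lab, 1, fibrosis_mask = 2L)
  flow <- strip_flow(dom, p_left = 1, p_right = 1)
  params <- transport_params(lambda = 1, lambda_f = 0.5, k_ef = 1.0,
                             P = 0, k_e = 0, k_f = 0, D_i = 0, D_e = 0)
  st <- concentration_state(dom, C_e = 2)
  dt <- 1e-3
  for (i in seq_len(500)) {
    st <- step_explicit(st, flow, params, dom, dt, 0)
    st$C_e[] <- 2                      # hold the interstitial level
  }
  # dC_f/dt = k_ef C_e - k_f C_f = 2 per second
  expect_equal(st$C_f[1], 1.0 * 2 * 0.5, tolerance = 1e-6)
})

test_that("transport mass budget closes over a first-pass run", {
  dom <- make_annulus_phantom(phantom_spec(h = 1.5))
  Kf <- permeability_field(dom, method = "direct")
  flow <- solve_pressure(assemble_pressure_system(dom, Kf, pressure_bc()),
                         method = "direct")
  params <- transport_params()
  ws <- transport_workspace(dom, flow)
  st <- concentration_state(dom)
  dt <- stable_dt(flow, params, dom$h)
  nsteps <- ceiling(50 / dt)
  for (i in seq_len(nsteps))
    st <- step_explicit(st, flow, params, dom, dt,
                        influx_concentration_Q((i - 1) * dt), workspace = ws)
  M <- total_mass(st, params, dom)
  net <- st$influx - st$outflow - st$sink
  expect_gt(st$influx, 0)
  expect_lt(abs(M - net) / st$influx, 0.005)
  expect_gte(min(st$C_i, st$C_e, st$C_f), -1e-12)
})

test_that("P = 0 keeps the extravascular space contrast-free", {
  dom <- make_annulus_phantom(phantom_spec(h = 1.5))
  Kf <- permeability_field(dom, method = "direct")
  flow <- solve_pressure(assemble_pressure_system(dom, Kf,
                                                  pressure_bc(p_sten = 0.4)),
                         method = "direct")
  params <- transport_params(P = 0, lambda = 1, lambda_f = 0.5, k_ef = 1,
                             k_e = 9e-4, k_f = 7e-4, D_i = 1e-7, D_e = 1e-7)
  ws <- transport_workspace(dom, flow)
  st <- concentration_state(dom)
  dt <- stable_dt(flow, params, dom$h)
  for (i in seq_len(ceiling(40 / dt)))
    st <- step_explicit(st, flow, params, dom, dt,
                        influx_concentration_Q((i - 1) * dt), workspace = ws)
  expect_gt(max(st$C_i), 0)            # contrast did arrive intravascularly
  expect_equal(max(abs(st$C_e)), 0)
  expect_equal(max(abs(st$C_f)), 0)
})

test_that("k_f = 0 makes the trapped fibrosis mass non-decreasing (plateau)", {
  dom <- make_annulus_phantom(phantom_spec(h = 1.5))
  Kf <- permeability_field(dom, method = "direct")
  flow <- solve_pressure(assemble_pressure_system(dom, Kf,
                                                  pressure_bc(p_sten = 0.4)),
                         method = "direct")
  params <- transport_params(P = 0.025, lambda = 1, lambda_f = 0.5,
                             k_ef = 1, k_e = 9e-4, k_f = 0,
                             D_i = 1e-7, D_e = 1e-7)
  ws <- transport_workspace(dom, flow)
  st <- concentration_state(dom)
  dt <- stable_dt(flow, params, dom$h)
  fib_mass <- numeric(0)
  for (i in seq_len(ceiling(60 / dt))) {
    st <- step_explicit(st, flow, params, dom, dt,
                        influx_concentration_Q((i - 1) * dt), workspace = ws)
    if (i %% 25 == 0) fib_mass <- c(fib_mass, sum(st$C_f))
  }
  expect_gt(utils::tail(fib_mass, 1), 0)
  expect_true(all(diff(fib_mass) >= -1e-12))
})

test_that("an unstable step raises the stability diagnostic", {
  dom <- strip_domain(20, h = 0.5)
  flow <- strip_flow(dom)
  params <- transport_params()
  st <- concentration_state(dom, C_i = c(rep(1, 5), rep(0, 15)))
  dt_bad <- 20 * stable_dt(flow, params, dom$h)
  expect_error({
    for (i in 1:50) st <- step_explicit(st, flow, params, dom, dt_bad, 0)
  }, "stability failure")
})
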