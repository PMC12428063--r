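test_that("Joule source scales with the duty-cycle rate", {
  fx <- sphere_fixture()
  expect_equal(joule_source(fx$field, 0), rep(0, nrow(fx$mesh$tri)))
  # continuous delivery (1e6 us/s) recovers sigma |E|^2 exactly
  e_si <- fx$field$E_elem * 100
  expect_equal(joule_source(fx$field, 1e6), 0.4 * e_si^2, tolerance = 1e-12)
  expect_error(joule_source(fx$field, -1), "non-negative")
})

test_that("integrated Joule power balances the electrical input power", {
  fx <- sphere_fixture()
  rate <- 50
  qe <- joule_source(fx$field, rate)
  total_W <- sum(nsablate:::.source_load(fx$mesh, qe))
  expect_equal(total_W, rate * 1e-6 * 6000 * fx$field$current,
               tolerance = 0.01)
})

test_that("equilibrium state is preserved for any step length", {
  mesh <- slab_mesh()
  mats <- material_properties()
  bnd <- thermal_boundary(baseline_temperature = 37)
  for (dt in c(0.1, 10)) {
    st <- make_thermal_stepper(mesh, mats, bnd, dt = dt)
    s0 <- thermal_init(st)
    s1 <- thermal_step(st, s0)
    expect_equal(s1$T, s0$T, tolerance = 1e-10)
    expect_equal(s1$time, dt)
  }
})

test_that("slab quench matches the Fourier series solution", {
  # 1 cm slab, both faces at 20 degC, initial 50 degC; compare the
  # mid-plane temperature with the classical series at Fo ~ 0.2
  mesh <- slab_mesh(r0 = 50, width = 0.5, thickness = 1, nr = 4, nz = 50)
  mats <- material_properties()
  bnd <- thermal_boundary(baseline_temperature = 20)
  st <- make_thermal_stepper(mesh, mats, bnd, dt = 0.5)
  state <- thermal_init(st, t0 = 50)
  t_end <- 150
  for (i in seq_len(t_end / 0.5)) state <- thermal_step(st, state)
  alpha <- mats$k / (mats$rho * mats$cp)
  L <- 0.01
  series <- function(z, t) {
    k <- seq(1, 99, by = 2)
    20 + (50 - 20) * sum(4 / (pi * k) * sin(k * pi * z / L) *
                           exp(-(k * pi / L)^2 * alpha * t))
  }
  mid <- probe_temperature(state, mesh, c(50.25, 0.5))
  expect_equal(mid, series(0.005, t_end), tolerance = 0.005 * 30 / mid)
  # steady state is the uniform boundary value
  for (i in seq_len(4000)) state <- thermal_step(st, state)
  expect_equal(max(abs(state$T - 20)), 0, tolerance = 0.02)
})

test_that("uniform source in an insulated domain heats by Qe dt / (rho cp)", {
  mesh <- slab_mesh(fix_z = FALSE)   # fully adiabatic
  mats <- material_properties()
  st <- make_thermal_stepper(mesh, mats, thermal_boundary(), dt = 2)
  state <- thermal_init(st, t0 = 30)
  qe <- rep(1e5, nrow(mesh$tri))     # W/m^3
  s1 <- thermal_step(st, state, qe)
  rise <- 1e5 * 2 / (mats$rho * mats$cp)
  expect_equal(s1$T, state$T + rise, tolerance = 1e-9)
})

test_that("source-free evolution obeys the maximum principle", {
  mesh <- slab_mesh(nr = 6, nz = 20)
  mats <- material_properties()
  st <- make_thermal_stepper(mesh, mats,
                             thermal_boundary(baseline_temperature = 20),
                             dt = 1)
  set.seed(7)
  state <- thermal_init(st, t0 = 20)
  state$T <- state$T + stats::runif(length(state$T), 0, 15)
  state$T[st$fixed] <- 20
  lo <- min(state$T); hi <- max(state$T)
  for (i in 1:50) {
    state <- thermal_step(st, state)
    expect_gte(min(state$T), lo - 1e-9)
    expect_lte(max(state$T), hi + 1e-9)
  }
})

test_that("each implicit step satisfies the discrete nodal balance", {
  mesh <- slab_mesh()
  mats <- material_properties()
  bnd <- thermal_boundary(baseline_temperature = 20)
  st <- make_thermal_stepper(mesh, mats, bnd, dt = 1)
  state <- thermal_init(st, t0 = 35)
  qe <- rep(5e4, nrow(mesh$tri))
  s1 <- thermal_step(st, state, qe)
  fq <- nsablate:::.source_load(mesh, qe)
  resid <- st$M / st$dt * (s1$T - state$T) +
    as.numeric(st$K %*% s1$T) - fq
  expect_lt(max(abs(resid[st$free])) / max(abs(fq)), 1e-9)
  # stored-energy change equals source plus the net boundary influx
  # (the fixed-node residual is the discrete influx through the boundary)
  stored <- sum(st$M * (s1$T - state$T)) / st$dt
  influx <- sum(resid[st$fixed])
  expect_equal(stored, sum(fq) + influx, tolerance = 1e-9)
})

test_that("probe interpolation is exact at nodes and rejects outside points", {
  fx <- needle_fixture()
  vals <- 33 + fx$mesh$nodes[, 1] * 0 + 1.5 * fx$mesh$nodes[, 2]
  i <- 1234L
  expect_equal(probe_temperature(vals, fx$mesh, fx$mesh$nodes[i, ]),
               vals[i])
  # uniform field returns the constant anywhere inside
  expect_equal(probe_temperature(rep(45, nrow(fx$mesh$nodes)), fx$mesh,
                                 c(3, 30)), 45)
  expect_error(probe_temperature(vals, fx$mesh, c(-5, 200)), "outside")
  # linear field is reproduced exactly by P1 interpolation
  expect_equal(probe_temperature(vals, fx$mesh, c(2.345, 31.7)),
               33 + 1.5 * 31.7, tolerance = 1e-9)
})
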