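test_that("null excitation gives an identically zero solution", {
  fx <- sphere_fixture()
  f0 <- solve_potential(fx$mesh, fx$materials, 0)
  expect_equal(max(abs(f0$V)), 0)
  expect_equal(max(f0$E_elem), 0)
  expect_equal(f0$current, 0)
})

test_that("spherical capacitor reproduces the closed-form solution", {
  fx <- sphere_fixture()
  # total current against R = (1/a - 1/b) / (4 pi sigma) ~ 197 ohm
  expect_equal(fx$field$current, fx$current_exact, tolerance = 0.01)
  expect_lt(charge_imbalance(fx$field), 1e-3)
  # potential profile against the 1/r form, max relative error < 1%
  rad <- sqrt(fx$mesh$nodes[, 1]^2 + fx$mesh$nodes[, 2]^2) / 100
  v_exact <- 6000 * (1 / rad - 1 / fx$b_m) / (1 / fx$a_m - 1 / fx$b_m)
  expect_lt(max(abs(fx$field$V - v_exact)) / 6000, 0.01)
})

test_that("solution scales linearly with the applied voltage", {
  fx <- sphere_fixture()
  f2 <- solve_potential(fx$mesh, fx$materials, 12000)
  expect_equal(f2$V, 2 * fx$field$V, tolerance = 1e-9)
  expect_equal(f2$E_elem, 2 * fx$field$E_elem, tolerance = 1e-9)
  expect_equal(f2$current, 2 * fx$field$current, tolerance = 1e-9)
})

test_that("a missing Dirichlet boundary is rejected as singular", {
  fx <- sphere_fixture()
  m <- fx$mesh
  m$edges$tag[m$edges$tag == "PAD"] <- "AXIS"
  expect_error(solve_potential(m, fx$materials, 6000), "singular")
})

test_that("conductivity law rejects non-physical temperatures", {
  mats <- material_properties()
  expect_equal(sigma_at(mats, 33), 0.4)
  expect_equal(sigma_at(mats, 43), 0.4 * 1.15)
  expect_error(sigma_at(mats, -100), "non-positive conductivity")
  expect_error(material_properties(sigma0 = -1))
})

test_that("uniform temperature rescales current but not the field", {
  fx <- needle_fixture()
  warm <- solve_potential(fx$mesh, material_properties(), 6000,
                          temperature = rep(43, nrow(fx$mesh$nodes)))
  expect_equal(warm$E_elem, fx$field$E_elem, tolerance = 1e-9)
  expect_equal(warm$current, 1.15 * fx$field$current, tolerance = 1e-9)
})

test_that("volume above field matches the 1/r^2 closed form", {
  fx <- sphere_fixture()
  e_set <- 1000  # V/cm
  rstar <- sqrt(6000 / (1e5 * (1 / fx$a_m - 1 / fx$b_m)))  # m
  v_exact <- 4 / 3 * pi * (rstar^3 - fx$a_m^3) * 1e6       # cm^3
  expect_equal(volume_above_field(fx$field, e_set), v_exact,
               tolerance = 0.01)
  # whole-domain case: shell volume between the spheres
  expect_equal(volume_above_field(fx$field, 0),
               4 / 3 * pi * (fx$b^3 - fx$a^3), tolerance = 2e-3)
})

test_that("iso-volumes are monotone over the calibration grid", {
  fx <- sphere_fixture()
  curve <- volume_field_curve(fx$field)
  expect_equal(curve$e_set_V_per_cm, seq(200, 2000, 10))
  expect_true(all(diff(curve$volume_cm3) <= 0))
  el <- volume_above_field(fx$field, c(500, 900), method = "element")
  expect_true(all(diff(el) <= 0))
})

test_that("volume above field is invariant under joint field scaling", {
  fx <- sphere_fixture()
  f2 <- solve_potential(fx$mesh, fx$materials, 3 * 6000)
  for (e in c(400, 1000)) {
    expect_equal(volume_above_field(f2, 3 * e),
                 volume_above_field(fx$field, e), tolerance = 1e-9)
  }
})

test_that("needle solve conserves charge and respects Dirichlet values", {
  fx <- needle_fixture()
  expect_lt(charge_imbalance(fx$field), 1e-3)
  elec <- nsablate:::.nodes_with_tag(fx$mesh, "ELECTRODE")
  pad <- nsablate:::.nodes_with_tag(fx$mesh, "PAD")
  expect_equal(unique(fx$field$V[elec]), 6000)
  expect_equal(unique(fx$field$V[pad]), 0)
  expect_true(all(fx$field$E_elem >= 0))
})
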