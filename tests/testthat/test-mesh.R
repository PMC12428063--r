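test_that("mesh area equals the analytic tissue cross-section", {
  fx <- needle_fixture()
  expect_equal(mesh_area(fx$mesh), geometry_cross_section(fx$geometry),
               tolerance = 1e-9)
})

test_that("elements near the electrode respect the near size cap", {
  geo <- build_geometry(applicator_geometry(1.0), domain_geometry())
  mesh <- generate_mesh(geo)  # defaults: 100 um near, 5.14 mm far
  sizes <- mesh_sizes(mesh)
  tg <- nsablate:::tri_geom(mesh)
  near <- tg$rbar < geo$r_wall + 0.1 & tg$rbar > geo$r_shaft - 1e-9
  zc <- (mesh$nodes[mesh$tri[, 1], 2] + mesh$nodes[mesh$tri[, 2], 2] +
           mesh$nodes[mesh$tri[, 3], 2]) / 3
  near <- near & zc > geo$z_tip - 0.1 & zc < geo$z_junction + 0.1
  # right-triangle diagonal of an h-sized cell is h * sqrt(2)
  expect_lte(max(sizes[near]), 0.01 * sqrt(2) * 1.01)
  expect_gt(max(sizes), 0.3)  # far field genuinely coarse
})

test_that("parameter collapse gives a uniform-size mesh", {
  geo <- build_geometry(applicator_geometry(1.5), domain_geometry())
  mesh <- generate_mesh(geo, max_size_near = 0.5, max_size_far = 0.5,
                        near_band = 0.5)
  sizes <- mesh_sizes(mesh)
  # no refinement band: sizes vary only by the feature-line snapping
  expect_lte(max(sizes), 0.5 * sqrt(2) * 1.01)
  expect_error(generate_mesh(geo, max_size_near = 1, max_size_far = 0.5),
               "must not exceed")
  expect_error(generate_mesh(geo, max_size_near = -1), "positive")
})

test_that("boundary tags are complete and exclusive", {
  fx <- needle_fixture()
  e <- fx$mesh$edges
  expect_false(anyNA(e$tag))
  expect_true(all(e$tag %in% c("ELECTRODE", "INSULATION", "PAD",
                               "FARFIELD", "AXIS", "CHANNEL")))
  # each boundary edge appears exactly once in the tag table
  expect_equal(anyDuplicated(paste(pmin(e$n1, e$n2), pmax(e$n1, e$n2))), 0L)
})

test_that("refinement identity cases leave the mesh unchanged", {
  fx <- needle_fixture()
  f0 <- fx$field
  expect_identical(refine_mesh(fx$mesh, f0, refinement_rule(rounds = 0)),
                   fx$mesh)
  quiet <- f0
  quiet$E_elem <- rep(1, nrow(fx$mesh$tri))  # uniform field below threshold
  expect_equal(nrow(refine_mesh(fx$mesh, quiet, refinement_rule(250, 1))$tri),
               nrow(fx$mesh$tri))
  bad <- f0
  bad$E_elem <- bad$E_elem[1:10]
  expect_error(refine_mesh(fx$mesh, bad, refinement_rule()),
               "field/mesh mismatch")
})

test_that("field-driven refinement subdivides hot elements conservatively", {
  fx <- needle_fixture()
  ref <- refine_mesh(fx$mesh, fx$field, refinement_rule(250, 1))
  expect_gt(nrow(ref$tri), nrow(fx$mesh$tri))
  expect_gt(nrow(ref$nodes), nrow(fx$mesh$nodes))
  # conforming and area-conserving after subdivision
  expect_equal(mesh_area(ref), geometry_cross_section(fx$geometry),
               tolerance = 1e-9)
  expect_false(anyNA(ref$edges$tag))
})

test_that("two adaptive rounds shrink the above-threshold elements", {
  geo <- build_geometry(applicator_geometry(1.5), domain_geometry())
  mesh <- generate_mesh(geo, max_size_near = 0.08, max_size_far = 1.5)
  ad <- adapt_mesh(mesh, material_properties(), 6000,
                   refinement_rule(250, 2))
  expect_equal(nrow(ad$history), 3L)
  expect_true(all(diff(ad$history$elements) > 0))
  expect_true(all(diff(ad$history$nodes) > 0))
  hot0 <- mesh_sizes(mesh)[solve_potential(mesh, material_properties(),
                                           6000)$E_elem > 250]
  hot2 <- mesh_sizes(ad$mesh)[ad$field$E_elem > 250]
  expect_lt(max(hot2), max(hot0))
})

test_that("mesh export writes a readable VTK file", {
  fx <- sphere_fixture()
  f <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(fx$mesh, f, point_data = list(V = fx$field$V),
            cell_data = list(E = fx$field$E_elem))
  lines <- readLines(f)
  expect_identical(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl(sprintf("^POINTS %d double", nrow(fx$mesh$nodes)),
                        lines)))
  expect_true(any(grepl("SCALARS V double 1", lines)))
})
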