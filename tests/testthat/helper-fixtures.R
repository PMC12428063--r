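# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# Concentric-sphere benchmark (closed-form oracle): inner a = 0.1 cm at
# 6000 V, outer b = 10 cm grounded, sigma = 0.4 S/m.
sphere_fixture <- function() {
  fixture("sphere", function() {
    mesh <- benchmark_spherical_mesh(a = 0.1, b = 10, n_rho = 80, n_theta = 64)
    mats <- material_properties()
    field <- solve_potential(mesh, mats, 6000)
    a_m <- 0.001; b_m <- 0.1
    list(mesh = mesh, materials = mats, field = field,
         a = 0.1, b = 10, a_m = a_m, b_m = b_m,
         current_exact = 4 * pi * 0.4 * 6000 / (1 / a_m - 1 / b_m))
  })
}

# Coarse 1.5 cm needle geometry and baseline solve (unit-test scale).
needle_fixture <- function() {
  fixture("needle", function() {
    geo <- build_geometry(applicator_geometry(1.5), domain_geometry())
    mesh <- generate_mesh(geo, max_size_near = 0.05, max_size_far = 1.0)
    field <- solve_potential(mesh, material_properties(), 6000)
    list(geometry = geo, mesh = mesh, field = field)
  })
}

# Structured rectangle mesh for 1-D conduction benchmarks: fixed-temperature
# faces in z (tag FARFIELD), adiabatic sides (tag AXIS).
slab_mesh <- function(r0 = 50, width = 0.5, thickness = 1, nr = 4, nz = 40,
                      fix_z = TRUE) {
  tagger <- function(nodes, be) {
    mz <- (nodes[be[, 1], 2] + nodes[be[, 2], 2]) / 2
    onz <- abs(mz) < 1e-9 | abs(mz - thickness) < 1e-9
    tag <- ifelse(fix_z & onz, "FARFIELD", "AXIS")
    data.frame(n1 = be[, 1], n2 = be[, 2], tag = tag,
               stringsAsFactors = FALSE)
  }
  nsablate:::axi_rect_mesh(r0, r0 + width, 0, thickness, nr, nz, tagger)
}

# Analytic monotone volume-field curves for cohort/recovery tests:
# v(e) = scale * (1000 / e)^1.5, one curve per exposure group, scaled so
# the group-mean volumes imply distinct thresholds.
toy_curve_set <- function(scales = c("0.5" = 6, "1" = 10, "1.5" = 12,
                                     "2" = 14)) {
  grid <- seq(200, 2000, by = 10)
  out <- lapply(scales, function(s) {
    cv <- data.frame(e_set_V_per_cm = grid,
                     volume_cm3 = s * (1000 / grid)^1.5)
    class(cv) <- c("volume_field_curve", "data.frame")
    cv
  })
  names(out) <- names(scales)
  out
}
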