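# Transient axisymmetric heat conduction
#   rho Cp dT/dt - div(k grad T) = Qe
# with a convective (or fixed-temperature) coolant condition on the
# applicator wall above the uncooled tip, fixed baseline temperature on the
# far boundaries, and the duty-cycle-scaled Joule source Qe = R(t) (J . E).
# Implicit Euler with a lumped mass matrix; the operator is factorised once
# per (mesh, dt) and reused every step.

#' Thermal boundary conditions
#'
#' The tissue starts at `baseline_temperature` and the far boundaries stay
#' there.  The coolant loop is reduced to a wall boundary condition on the
#' applicator above the uncooled distal tip: either a convective (Robin)
#' condition with film coefficient `film_coefficient` (bare electrode) and
#' `insulated_film_coefficient` (through the insulation sheath), or a fixed
#' wall temperature (`coolant_model = "fixed"`).
#'
#' @param baseline_temperature Initial and far-field tissue temperature,
#'   degC (default 33; see the methods vignette for the choice).
#' @param coolant_temperature Circulating-water temperature, degC.
#' @param coolant_model `"convective"` or `"fixed"`.
#' @param film_coefficient Film coefficient on the bare cooled electrode
#'   wall, W/(m^2 K).
#' @param insulated_film_coefficient Effective coefficient through the
#'   insulation; default adds a polyimide conduction resistance
#'   (k approximately 0.12 W/(m K)) in series with `film_coefficient`.
#' @param insulation_k Insulation thermal conductivity, W/(m K).
#' @param tip_film_coefficient Reduced effective coefficient on the distal
#'   uncooled electrode wall and tip face, representing axial heat
#'   conduction through the metal shaft to the cooled section (the tube is
#'   steel; it is not adiabatic even where no water flows).  Set to 0 for a
#'   fully adiabatic tip.
#' @return A `thermal_boundary` object.
#' @export
thermal_boundary <- function(baseline_temperature = 33,
                             coolant_temperature = 22,
                             coolant_model = c("convective", "fixed"),
                             film_coefficient = 5000,
                             insulated_film_coefficient = NULL,
                             insulation_k = 0.12,
                             tip_film_coefficient = 1000) {
  coolant_model <- match.arg(coolant_model)
  stopifnot(film_coefficient > 0, tip_film_coefficient >= 0)
  structure(list(baseline_temperature = baseline_temperature,
                 coolant_temperature = coolant_temperature,
                 coolant_model = coolant_model,
                 film_coefficient = film_coefficient,
                 insulated_film_coefficient = insulated_film_coefficient,
                 insulation_k = insulation_k,
                 tip_film_coefficient = tip_film_coefficient),
            class = "thermal_boundary")
}

#' Duty-cycle-scaled Joule source
#'
#' Qe = (rate x 1e-6) (J . E): the time-averaged volumetric power density
#' when pulses are delivered at an instantaneous rate of `rate` microseconds
#' of on-time per second.
#'
#' @param field A `field_solution`.
#' @param rate Energy delivery rate, microseconds/second (>= 0).
#' @return Element source density, W/m^3.
#' @export
joule_source <- function(field, rate) {
  if (rate < 0) stop("energy delivery rate must be non-negative")
  rate * 1e-6 * field$JdotE
}

# Classify applicator-wall boundary edges of a needle mesh: bare cooled
# electrode wall, distal uncooled electrode wall + tip face, insulated wall.
.cooled_wall_edges <- function(mesh) {
  g <- mesh$geometry
  e <- mesh$edges
  mz <- (mesh$nodes[e$n1, 2] + mesh$nodes[e$n2, 2]) / 2
  bare <- e$tag == "ELECTRODE" & mz > g$z_cool
  tip <- e$tag == "ELECTRODE" & mz <= g$z_cool
  ins <- e$tag == "INSULATION"
  list(bare = e[bare, , drop = FALSE], tip = e[tip, , drop = FALSE],
       insulated = e[ins, , drop = FALSE])
}

# Boundary mass/load contributions for Robin edges: integral of
# h phi_i phi_j 2 pi r ds and h T_cool phi_i 2 pi r ds (SI).
.robin_terms <- function(mesh, edges, h, t_cool) {
  if (!nrow(edges)) {
    n <- nrow(mesh$nodes)
    return(list(R = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                         x = numeric(0), dims = c(n, n)),
                f = numeric(n)))
  }
  p <- mesh$nodes * CM
  i1 <- edges$n1; i2 <- edges$n2
  len <- sqrt((p[i1, 1] - p[i2, 1])^2 + (p[i1, 2] - p[i2, 2])^2)
  r1 <- p[i1, 1]; r2 <- p[i2, 1]
  w11 <- h * 2 * pi * len * (3 * r1 + r2) / 12
  w22 <- h * 2 * pi * len * (r1 + 3 * r2) / 12
  w12 <- h * 2 * pi * len * (r1 + r2) / 12
  n <- nrow(mesh$nodes)
  R <- Matrix::sparseMatrix(i = c(i1, i2, i1, i2), j = c(i1, i2, i2, i1),
                            x = c(w11, w22, w12, w12), dims = c(n, n))
  f <- numeric(n)
  f1 <- h * t_cool * 2 * pi * len * (2 * r1 + r2) / 6
  f2 <- h * t_cool * 2 * pi * len * (r1 + 2 * r2) / 6
  f <- .accumulate(i1, f1, n) + .accumulate(i2, f2, n)
  list(R = R, f = f)
}

# Lumped axisymmetric mass vector: M_i = sum_e rho cp 2 pi A (2 r_i + r_j +
# r_k) / 12 (SI), exact for the linear variation of r over the element.
.lumped_mass <- function(mesh, rhocp) {
  tg <- tri_geom(mesh)
  A <- tg$area * CM^2
  r <- tg$r * CM
  n <- nrow(mesh$nodes)
  M <- numeric(n)
  for (i in 1:3) {
    w <- rhocp * 2 * pi * A *
      (2 * r[, i] + r[, i %% 3 + 1] + r[, (i + 1) %% 3 + 1]) / 12
    M <- M + .accumulate(mesh$tri[, i], w, n)
  }
  M
}

# Nodal load vector from an element source density (W/m^3, SI).
.source_load <- function(mesh, qe_elem) {
  tg <- tri_geom(mesh)
  A <- tg$area * CM^2
  r <- tg$r * CM
  n <- nrow(mesh$nodes)
  f <- numeric(n)
  for (i in 1:3) {
    w <- qe_elem * 2 * pi * A *
      (2 * r[, i] + r[, i %% 3 + 1] + r[, (i + 1) %% 3 + 1]) / 12
    f <- f + .accumulate(mesh$tri[, i], w, n)
  }
  f
}

#' Build a prefactorised implicit thermal stepper
#'
#' Assembles and factorises the implicit-Euler operator
#' (M/dt + K + R) for the bioheat problem on `mesh`, so each time step is a
#' single triangular solve.  Far boundaries (`FARFIELD`, `PAD`, bottom/top
#' faces) are fixed at the baseline temperature; the cooled applicator wall
#' carries the coolant condition from `boundary`; the uncooled tip and the
#' axis are adiabatic.
#'
#' @param mesh An `axi_mesh` (needle geometry, or any tagged mesh when
#'   `dirichlet_tags` / `robin` are supplied explicitly).
#' @param materials A [material_properties()].
#' @param boundary A [thermal_boundary()].
#' @param dt Time step, s.
#' @param dirichlet_tags Boundary tags held at `baseline_temperature`.
#' @return A `thermal_stepper` object; see [thermal_step()].
#' @export
make_thermal_stepper <- function(mesh, materials, boundary,
                                 dt = 0.25,
                                 dirichlet_tags = c("FARFIELD", "PAD")) {
  stopifnot(dt > 0)
  n <- nrow(mesh$nodes)
  M <- .lumped_mass(mesh, materials$rho * materials$cp)
  K <- .assemble_stiffness(mesh, rep(materials$k, nrow(mesh$tri)))

  robin <- list(R = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                         x = numeric(0), dims = c(n, n)),
                f = numeric(n))
  fixed <- .nodes_with_tag(mesh, dirichlet_tags)
  t_fixed <- rep(boundary$baseline_temperature, length(fixed))

  if (!is.null(mesh$geometry)) {
    cw <- .cooled_wall_edges(mesh)
    if (boundary$coolant_model == "fixed") {
      wall_nodes <- sort(unique(c(cw$bare$n1, cw$bare$n2,
                                  cw$insulated$n1, cw$insulated$n2)))
      wall_nodes <- setdiff(wall_nodes, fixed)
      fixed <- c(fixed, wall_nodes)
      t_fixed <- c(t_fixed, rep(boundary$coolant_temperature,
                                length(wall_nodes)))
      if (boundary$tip_film_coefficient > 0) {
        r3 <- .robin_terms(mesh, cw$tip, boundary$tip_film_coefficient,
                           boundary$coolant_temperature)
        robin <- list(R = robin$R + r3$R, f = robin$f + r3$f)
      }
    } else {
      h_ins <- boundary$insulated_film_coefficient
      if (is.null(h_ins)) {
        t_ins <- mesh$geometry$applicator$insulation_thickness * CM
        h_ins <- 1 / (1 / boundary$film_coefficient +
                        t_ins / boundary$insulation_k)
      }
      r1 <- .robin_terms(mesh, cw$bare, boundary$film_coefficient,
                         boundary$coolant_temperature)
      r2 <- .robin_terms(mesh, cw$insulated, h_ins,
                         boundary$coolant_temperature)
      robin <- list(R = r1$R + r2$R, f = r1$f + r2$f)
      if (boundary$tip_film_coefficient > 0) {
        r3 <- .robin_terms(mesh, cw$tip, boundary$tip_film_coefficient,
                           boundary$coolant_temperature)
        robin <- list(R = robin$R + r3$R, f = robin$f + r3$f)
      }
    }
  }

  A <- K + robin$R + Matrix::Diagonal(n, M / dt)
  free <- setdiff(seq_len(n), fixed)
  Aff <- Matrix::forceSymmetric(A[free, free, drop = FALSE])
  fact <- Matrix::Cholesky(Aff)
  Afd <- A[free, fixed, drop = FALSE]

  structure(list(mesh = mesh, materials = materials, boundary = boundary,
                 dt = dt, M = M, K = K, robin = robin, A = A,
                 free = free, fixed = fixed, t_fixed = t_fixed,
                 fact = fact, Afd = Afd),
            class = "thermal_stepper")
}

#' Initial thermal state
#'
#' @param stepper A [make_thermal_stepper()] result.
#' @param t0 Initial temperature, degC (default: boundary baseline).
#' @return A `thermal_state` (nodal temperatures plus simulation time).
#' @export
thermal_init <- function(stepper, t0 = NULL) {
  if (is.null(t0)) t0 <- stepper$boundary$baseline_temperature
  temp <- rep(t0, nrow(stepper$mesh$nodes))
  temp[stepper$fixed] <- stepper$t_fixed
  structure(list(T = temp, time = 0), class = "thermal_state")
}

#' Advance the temperature field by one implicit step
#'
#' Unconditionally stable implicit-Euler step of
#' rho Cp dT/dt = div(k grad T) + Qe.
#'
#' @param stepper A `thermal_stepper`.
#' @param state A `thermal_state`.
#' @param qe Element source density, W/m^3 (scalar 0 allowed), e.g. from
#'   [joule_source()].
#' @param dt Optional step length, s; defaults to the stepper's factorised
#'   step (any other value triggers a one-off refactorisation).
#' @return Updated `thermal_state`.
#' @export
thermal_step <- function(stepper, state, qe = 0, dt = NULL) {
  s <- stepper
  if (!is.null(dt) && abs(dt - s$dt) > 1e-12 * s$dt) {
    s <- make_thermal_stepper(s$mesh, s$materials, s$boundary, dt = dt)
  }
  n <- nrow(s$mesh$nodes)
  fq <- if (length(qe) == 1L && qe[1] == 0) numeric(n)
        else .source_load(s$mesh, qe)
  b <- s$M / s$dt * state$T + fq + s$robin$f
  temp <- state$T
  temp[s$fixed] <- s$t_fixed
  rhs <- b[s$free] - as.numeric(s$Afd %*% s$t_fixed)
  temp[s$free] <- as.numeric(Matrix::solve(s$fact, rhs))
  if (any(!is.finite(temp)))
    stop("thermal step produced non-finite temperatures")
  structure(list(T = temp, time = state$time + s$dt), class = "thermal_state")
}

#' Interpolate the temperature at a probe location
#'
#' Linear (barycentric) interpolation of the nodal temperature field at an
#' (r, z) point.  The physical probe sits at the insulation-electrode
#' junction on the applicator wall; see [probe_location()].
#'
#' @param state A `thermal_state` or a nodal numeric vector.
#' @param mesh The `axi_mesh` the state lives on.
#' @param location Numeric `c(r, z)` in cm.
#' @return Temperature, degC.
#' @export
probe_temperature <- function(state, mesh, location) {
  vals <- if (inherits(state, "thermal_state")) state$T else state
  interp_point(mesh, vals, location)
}

# Barycentric point interpolation with a small tolerance for points on
# element boundaries.
interp_point <- function(mesh, node_vals, location) {
  p <- mesh$nodes
  tri <- mesh$tri
  x <- location[1]; y <- location[2]
  x1 <- p[tri[, 1], 1]; y1 <- p[tri[, 1], 2]
  x2 <- p[tri[, 2], 1]; y2 <- p[tri[, 2], 2]
  x3 <- p[tri[, 3], 1]; y3 <- p[tri[, 3], 2]
  d <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  l1 <- ((y2 - y3) * (x - x3) + (x3 - x2) * (y - y3)) / d
  l2 <- ((y3 - y1) * (x - x3) + (x1 - x3) * (y - y3)) / d
  l3 <- 1 - l1 - l2
  tol <- -1e-9
  inside <- which(l1 >= tol & l2 >= tol & l3 >= tol)
  if (!length(inside))
    stop("probe location (", x, ", ", y, ") is outside the mesh")
  e <- inside[1]
  l1[e] * node_vals[tri[e, 1]] + l2[e] * node_vals[tri[e, 2]] +
    l3[e] * node_vals[tri[e, 3]]
}

#' Default probe location
#'
#' The temperature sensor sits at the insulation-electrode junction of the
#' applicator.  In the simplified geometry that junction is a reentrant
#' corner where the electric field (and hence the Joule source) is
#' singular, so the temperature at the exact corner node does not converge
#' under mesh refinement.  The probe therefore samples a point a small
#' radial offset into the tissue at the junction plane, emulating the
#' finite-size sensor embedded in the device wall.
#'
#' @param geometry An `ablation_geometry`.
#' @param offset Radial offset into tissue from the shaft wall, cm.
#' @return `c(r, z)` in cm.
#' @export
probe_location <- function(geometry, offset = 0.05) {
  c(geometry$r_shaft + offset, geometry$z_junction)
}

#' Tissue volume above a temperature
#'
#' Revolved volume of the super-level set of the nodal temperature field
#' (e.g. the 45/55/65 degC thermal iso-volumes), cm^3.
#'
#' @param state A `thermal_state` or nodal vector.
#' @param mesh The `axi_mesh`.
#' @param t_set Temperature level(s), degC.
#' @return Volume(s), cm^3.
#' @export
volume_above_temperature <- function(state, mesh, t_set) {
  vals <- if (inherits(state, "thermal_state")) state$T else state
  vapply(t_set, function(lv) iso_region(mesh, vals, lv)$volume_cm3,
         numeric(1))
}
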