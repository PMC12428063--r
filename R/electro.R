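# Quasi-static current continuity in axisymmetric coordinates:
#   div(sigma grad V) = 0,  V = applied voltage on ELECTRODE, 0 on PAD,
#   zero normal current elsewhere.
# P1 finite elements; the cylindrical measure enters as the factor
# 2 pi r in every integral.  Meshes store cm; assembly converts to SI.

CM <- 0.01  # metres per centimetre

#' Tissue material properties
#'
#' Baseline electrical conductivity is 0.4 S/m (liver at 1 MHz).  The
#' temperature dependence of conductivity is linear,
#' sigma(T) = sigma0 (1 + alpha (T - reference_temperature)).  Thermal
#' properties are liver values from the same public tissue-property
#' database (implementer defaults; see the methods vignette).
#'
#' @param sigma0 Baseline electrical conductivity, S/m.
#' @param alpha Linear temperature coefficient of conductivity, 1/degC.
#' @param reference_temperature Temperature at which sigma = sigma0, degC.
#' @param rho Density, kg/m^3.
#' @param cp Specific heat capacity, J/(kg K).
#' @param k Thermal conductivity, W/(m K).
#' @return A `material_properties` object.
#' @export
material_properties <- function(sigma0 = 0.4, alpha = 0.015,
                                reference_temperature = 33,
                                rho = 1079, cp = 3540, k = 0.52) {
  stopifnot(sigma0 > 0, rho > 0, cp > 0, k > 0)
  structure(list(sigma0 = sigma0, alpha = alpha,
                 reference_temperature = reference_temperature,
                 rho = rho, cp = cp, k = k),
            class = "material_properties")
}

#' Temperature-dependent conductivity
#'
#' @param materials A [material_properties()].
#' @param temperature Temperature(s), degC.
#' @return Conductivity, S/m.
#' @export
sigma_at <- function(materials, temperature) {
  s <- materials$sigma0 *
    (1 + materials$alpha * (temperature - materials$reference_temperature))
  if (any(s <= 0))
    stop("non-positive conductivity at T = ",
         signif(temperature[which(s <= 0)[1]], 4), " degC")
  s
}

# Assemble the axisymmetric stiffness matrix sum_e coef_e * 2 pi rbar *
# (b_i b_j + c_i c_j) / (4 A) with coef per element (SI units).
# Returns a dgCMatrix (n x n) including the 2 pi factor.
.assemble_stiffness <- function(mesh, coef_elem) {
  tg <- tri_geom(mesh)
  A <- tg$area * CM^2
  rbar <- tg$rbar * CM
  b <- tg$b * CM
  cc <- tg$c * CM
  if (any(A <= 0)) stop("mesh contains inverted or degenerate elements")
  scale <- coef_elem * 2 * pi * rbar / (4 * A)
  m <- nrow(mesh$tri)
  ii <- jj <- xx <- vector("list", 9)
  n <- 0L
  for (i in 1:3) for (j in 1:3) {
    n <- n + 1L
    ii[[n]] <- mesh$tri[, i]
    jj[[n]] <- mesh$tri[, j]
    xx[[n]] <- scale * (b[, i] * b[, j] + cc[, i] * cc[, j])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nrow(mesh$nodes), nrow(mesh$nodes)))
}

.nodes_with_tag <- function(mesh, tags) {
  e <- mesh$edges
  sort(unique(c(e$n1[e$tag %in% tags], e$n2[e$tag %in% tags])))
}

#' Solve the axisymmetric electrostatic problem
#'
#' Weak solution of div(sigma grad V) = 0 with Dirichlet conditions
#' V = `applied_voltage` on ELECTRODE and V = 0 on PAD, and zero normal
#' current on all other boundaries.  If a nodal temperature field is given,
#' the conductivity is evaluated per element through the linear law.
#'
#' @param mesh An `axi_mesh` with ELECTRODE and PAD boundary tags.
#' @param materials A [material_properties()].
#' @param applied_voltage Electrode potential, V (non-negative).
#' @param temperature Optional nodal temperature vector, degC; `NULL` uses
#'   the baseline conductivity everywhere.
#' @return A `field_solution`: nodal potential `V` (volts), element field
#'   magnitude `E_elem` and area-averaged nodal field `E_node` (V/cm),
#'   element current density `J_elem` (A/m^2), element Joule density at
#'   unit duty cycle `JdotE` (W/m^3), electrode and pad currents (A).
#' @export
solve_potential <- function(mesh, materials, applied_voltage,
                            temperature = NULL) {
  stopifnot(inherits(mesh, "axi_mesh"),
            inherits(materials, "material_properties"))
  if (applied_voltage < 0) stop("applied_voltage must be non-negative")

  elec <- .nodes_with_tag(mesh, "ELECTRODE")
  pad <- .nodes_with_tag(mesh, "PAD")
  if (!length(elec) || !length(pad))
    stop("singular system: mesh lacks an ELECTRODE or PAD Dirichlet boundary")

  if (is.null(temperature)) {
    sig <- rep(materials$sigma0, nrow(mesh$tri))
  } else {
    Tn <- temperature
    Te <- (Tn[mesh$tri[, 1]] + Tn[mesh$tri[, 2]] + Tn[mesh$tri[, 3]]) / 3
    sig <- sigma_at(materials, Te)
  }

  K <- .assemble_stiffness(mesh, sig)
  n <- nrow(mesh$nodes)
  V <- numeric(n)
  V[elec] <- applied_voltage
  fixed <- c(elec, pad)
  free <- setdiff(seq_len(n), fixed)
  if (applied_voltage > 0 && length(free)) {
    rhs <- -(K[free, fixed, drop = FALSE] %*% V[fixed])
    Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
    V[free] <- as.numeric(Matrix::solve(Matrix::Cholesky(Kff), rhs))
  }

  tg <- tri_geom(mesh)
  # element gradient of V in SI (V/m); mesh coords are cm
  gx <- (tg$b[, 1] * V[mesh$tri[, 1]] + tg$b[, 2] * V[mesh$tri[, 2]] +
           tg$b[, 3] * V[mesh$tri[, 3]]) / (2 * tg$area * CM)
  gz <- (tg$c[, 1] * V[mesh$tri[, 1]] + tg$c[, 2] * V[mesh$tri[, 2]] +
           tg$c[, 3] * V[mesh$tri[, 3]]) / (2 * tg$area * CM)
  E_SI <- sqrt(gx^2 + gz^2)            # |E| in V/m
  E_elem <- E_SI / 100                  # V/cm
  J_elem <- sig * E_SI
  JdotE <- sig * E_SI^2                 # W/m^3 at duty cycle 1

  resid <- as.numeric(K %*% V)
  current <- sum(resid[elec])
  current_pad <- sum(resid[pad])

  structure(list(
    V = V,
    E_elem = E_elem,
    E_node = .node_average(mesh, E_elem, tg),
    J_elem = J_elem,
    JdotE = JdotE,
    sigma_elem = sig,
    current = current,
    current_pad = current_pad,
    applied_voltage = applied_voltage,
    mesh = mesh
  ), class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("Axisymmetric field solution: %.0f V applied, %.3f A, max |E| = %.0f V/cm\n",
              x$applied_voltage, x$current, max(x$E_elem)))
  invisible(x)
}

# Area-weighted average of element values onto nodes.
.node_average <- function(mesh, elem_vals, tg = tri_geom(mesh)) {
  n <- nrow(mesh$nodes)
  w <- tg$area
  num <- den <- numeric(n)
  for (i in 1:3) {
    idx <- mesh$tri[, i]
    num <- num + .accumulate(idx, w * elem_vals, n)
    den <- den + .accumulate(idx, w, n)
  }
  num / den
}

.accumulate <- function(index, values, n) {
  out <- numeric(n)
  s <- rowsum(values, index)
  out[as.integer(rownames(s))] <- s
  out
}

# Revolved volume (cm^3) and extent of the region where a nodal scalar
# exceeds `level`, by exact clipping of the linear interpolant per element.
# Returns volume plus the (r, z) bounding box of the super-level set.
iso_region <- function(mesh, node_vals, level) {
  p <- mesh$nodes
  tri <- mesh$tri
  v <- matrix(node_vals[tri], ncol = 3)
  above <- v >= level
  nab <- rowSums(above)

  vol <- 0
  rmax <- 0; zmin <- Inf; zmax <- -Inf

  poly_moment <- function(px, py) {
    # shoelace area and first moment about r of a polygon (rows = polygons)
    nc <- ncol(px)
    A <- 0; M <- 0
    for (k in seq_len(nc)) {
      k2 <- if (k == nc) 1L else k + 1L
      cr <- px[, k] * py[, k2] - px[, k2] * py[, k]
      A <- A + cr
      M <- M + (px[, k] + px[, k2]) * cr
    }
    list(A = A / 2, M = M / 6)
  }

  upd_extent <- function(px, py) {
    rmax <<- max(rmax, px)
    zmin <<- min(zmin, py)
    zmax <<- max(zmax, py)
  }

  # fully above: whole triangle
  full <- which(nab == 3L)
  if (length(full)) {
    px <- matrix(p[tri[full, ], 1], ncol = 3)
    py <- matrix(p[tri[full, ], 2], ncol = 3)
    pm <- poly_moment(px, py)
    vol <- vol + sum(abs(pm$M))
    upd_extent(px, py)
  }

  crossing <- function(pa_x, pa_y, va, pb_x, pb_y, vb) {
    t <- (level - va) / (vb - va)
    list(x = pa_x + t * (pb_x - pa_x), y = pa_y + t * (pb_y - pa_y))
  }

  # one vertex above: clipped triangle (apex + two crossings)
  i1 <- which(nab == 1L)
  if (length(i1)) {
    wa <- max.col(above[i1, , drop = FALSE], ties.method = "first")
    ia <- tri[cbind(i1, wa)]
    ib <- tri[cbind(i1, wa %% 3L + 1L)]
    ic <- tri[cbind(i1, (wa + 1L) %% 3L + 1L)]
    c1 <- crossing(p[ia, 1], p[ia, 2], node_vals[ia],
                   p[ib, 1], p[ib, 2], node_vals[ib])
    c2 <- crossing(p[ia, 1], p[ia, 2], node_vals[ia],
                   p[ic, 1], p[ic, 2], node_vals[ic])
    px <- cbind(p[ia, 1], c1$x, c2$x)
    py <- cbind(p[ia, 2], c1$y, c2$y)
    pm <- poly_moment(px, py)
    vol <- vol + sum(abs(pm$M))
    upd_extent(px, py)
  }

  # two vertices above: clipped quadrilateral
  i2 <- which(nab == 2L)
  if (length(i2)) {
    wb <- max.col(!above[i2, , drop = FALSE], ties.method = "first")  # below
    ic <- tri[cbind(i2, wb)]                      # the below vertex
    ia <- tri[cbind(i2, wb %% 3L + 1L)]
    ib <- tri[cbind(i2, (wb + 1L) %% 3L + 1L)]
    c1 <- crossing(p[ib, 1], p[ib, 2], node_vals[ib],
                   p[ic, 1], p[ic, 2], node_vals[ic])
    c2 <- crossing(p[ia, 1], p[ia, 2], node_vals[ia],
                   p[ic, 1], p[ic, 2], node_vals[ic])
    px <- cbind(p[ia, 1], p[ib, 1], c1$x, c2$x)
    py <- cbind(p[ia, 2], p[ib, 2], c1$y, c2$y)
    pm <- poly_moment(px, py)
    vol <- vol + sum(abs(pm$M))
    upd_extent(px, py)
  }

  empty <- !length(full) && !length(i1) && !length(i2)
  list(volume_cm3 = 2 * pi * vol,
       r_max = if (empty) 0 else rmax,
       z_min = if (empty) NA_real_ else zmin,
       z_max = if (empty) NA_real_ else zmax,
       empty = empty)
}

#' Tissue volume exposed to fields above a level
#'
#' Volume of revolution of the region where the field magnitude exceeds
#' `e_set`, in cm^3.  The default interpolated mode clips the linear nodal
#' interpolant of |E| inside elements crossing the iso-contour; the
#' `"element"` mode counts whole elements selected by the element-wise
#' predicate |E| > e_set (the coarser estimate).
#'
#' @param field A `field_solution`.
#' @param e_set Field level, V/cm (vectorised).
#' @param method `"interpolated"` or `"element"`.
#' @return Volume(s) in cm^3.
#' @export
volume_above_field <- function(field, e_set,
                               method = c("interpolated", "element")) {
  method <- match.arg(method)
  stopifnot(inherits(field, "field_solution"), all(e_set >= 0))
  mesh <- field$mesh
  if (method == "element") {
    tg <- tri_geom(mesh)
    elem_vol <- 2 * pi * tg$rbar * tg$area
    return(vapply(e_set, function(e) sum(elem_vol[field$E_elem > e]),
                  numeric(1)))
  }
  vapply(e_set, function(e) {
    if (e == 0) {
      tg <- tri_geom(mesh)
      sum(2 * pi * tg$rbar * tg$area)
    } else {
      iso_region(mesh, field$E_node, e)$volume_cm3
    }
  }, numeric(1))
}

#' Volume-vs-field curve
#'
#' Evaluates [volume_above_field()] over a grid of field levels (the
#' calibration curve matched against measured ablation volumes).
#'
#' @param field A `field_solution`.
#' @param e_grid Field levels, V/cm; default 200 to 2000 in 10 V/cm steps.
#' @param method Passed to [volume_above_field()].
#' @return A `volume_field_curve`: data frame with columns `e_set_V_per_cm`
#'   and `volume_cm3`, carrying provenance attributes.
#' @export
volume_field_curve <- function(field, e_grid = seq(200, 2000, by = 10),
                               method = "interpolated") {
  stopifnot(all(diff(e_grid) > 0))
  vols <- volume_above_field(field, e_grid, method = method)
  out <- data.frame(e_set_V_per_cm = e_grid, volume_cm3 = vols)
  attr(out, "applied_voltage") <- field$applied_voltage
  attr(out, "method") <- method
  if (!is.null(field$mesh$geometry))
    attr(out, "exposure_cm") <- field$mesh$geometry$applicator$exposure_length
  class(out) <- c("volume_field_curve", "data.frame")
  out
}

#' Charge-conservation imbalance
#'
#' Relative mismatch between the current entering at the electrode and
#' leaving at the pad.
#' @param field A `field_solution`.
#' @return |I_electrode + I_pad| / |I_electrode|.
#' @export
charge_imbalance <- function(field) {
  abs(field$current + field$current_pad) / abs(field$current)
}
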