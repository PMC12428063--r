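# Triangular meshing of the axisymmetric (r, z) tissue domain.
#
# The mesh is a graded tensor-product grid (fine near the applicator, growing
# geometrically to the far-field cap size) whose lines pass through every
# material feature (shaft radius, insulation wall, tip depth, exposure
# junction, pad radius), so no element ever crosses a material boundary.
# Adaptive refinement is red-green edge subdivision driven by an element-wise
# field predicate.

# Graded 1-D point sequence from a to b: first spacing ~h0, growing by
# `ratio` per interval up to hmax, then uniform; rescaled to hit b exactly.
seq_graded <- function(a, b, h0, hmax = h0, ratio = 1.3) {
  len <- b - a
  stopifnot(len >= 0, h0 > 0, hmax >= 0, ratio >= 1)
  if (len <= h0 * 1.0001) return(c(a, b))
  h <- numeric(0)
  cur <- h0
  total <- 0
  while (total < len) {
    h <- c(h, cur)
    total <- total + cur
    cur <- min(cur * ratio, hmax)
  }
  a + c(0, cumsum(h * (len / total)))
}

# Uniform subdivision of [a, b] with spacing <= h.
seq_uniform <- function(a, b, h) {
  if (b - a <= 0) return(c(a, b))
  seq(a, b, length.out = max(2L, ceiling((b - a) / h) + 1L))
}

.merge_lines <- function(x, tol = 1e-9) {
  x <- sort(x)
  keep <- c(TRUE, diff(x) > tol)
  x[keep]
}

.new_axi_mesh <- function(nodes, tri, edges, geometry = NULL, extra = list()) {
  m <- c(list(nodes = nodes, tri = tri, edges = edges, geometry = geometry),
         extra)
  class(m) <- "axi_mesh"
  m
}

#' @export
print.axi_mesh <- function(x, ...) {
  cat(sprintf("Axisymmetric triangular mesh: %d nodes, %d elements\n",
              nrow(x$nodes), nrow(x$tri)))
  cat("  boundary tags: ",
      paste(sprintf("%s (%d)", names(table(x$edges$tag)), table(x$edges$tag)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Per-element geometry: signed areas (cm^2), centroid radii and the P1 shape
# gradient coefficients b, c (so that grad(phi_i) = (b_i, c_i) / (2A)).
tri_geom <- function(mesh) {
  p <- mesh$nodes
  t1 <- mesh$tri[, 1]; t2 <- mesh$tri[, 2]; t3 <- mesh$tri[, 3]
  x1 <- p[t1, 1]; y1 <- p[t1, 2]
  x2 <- p[t2, 1]; y2 <- p[t2, 2]
  x3 <- p[t3, 1]; y3 <- p[t3, 2]
  area <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  list(
    area = area,
    rbar = (x1 + x2 + x3) / 3,
    b = cbind(y2 - y3, y3 - y1, y1 - y2),
    c = cbind(x3 - x2, x1 - x3, x2 - x1),
    r = cbind(x1, x2, x3)
  )
}

#' Total meshed cross-section area
#'
#' Sum of element areas in the (r, z) plane, cm^2.
#' @param mesh An `axi_mesh`.
#' @return Area in cm^2.
#' @export
mesh_area <- function(mesh) sum(tri_geom(mesh)$area)

#' Analytic cross-section area of the tissue region
#'
#' Domain rectangle minus the applicator footprint in the (r, z) plane, cm^2.
#' Used as the meshing conservation oracle.
#' @param geometry An `ablation_geometry`.
#' @return Area in cm^2.
#' @export
geometry_cross_section <- function(geometry) {
  g <- geometry
  g$domain$domain_radius * g$domain$domain_length -
    g$r_wall * (g$z_top - g$z_junction) -
    g$r_shaft * (g$z_junction - g$z_tip)
}

# Longest edge per element (element "diameter"), cm.
#' Element sizes
#' @param mesh An `axi_mesh`.
#' @return Numeric vector, longest edge of each element in cm.
#' @export
mesh_sizes <- function(mesh) {
  p <- mesh$nodes
  e1 <- sqrt(rowSums((p[mesh$tri[, 1], , drop = FALSE] -
                      p[mesh$tri[, 2], , drop = FALSE])^2))
  e2 <- sqrt(rowSums((p[mesh$tri[, 2], , drop = FALSE] -
                      p[mesh$tri[, 3], , drop = FALSE])^2))
  e3 <- sqrt(rowSums((p[mesh$tri[, 3], , drop = FALSE] -
                      p[mesh$tri[, 1], , drop = FALSE])^2))
  pmax(e1, pmax(e2, e3))
}

# Boundary edges of a triangulation: edges referenced by exactly one element.
.boundary_edges <- function(tri, n_nodes) {
  ee <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  a <- pmin(ee[, 1], ee[, 2])
  b <- pmax(ee[, 1], ee[, 2])
  key <- a * (n_nodes + 1) + b
  tab <- table(key)
  bkey <- as.numeric(names(tab)[tab == 1L])
  sel <- match(bkey, key)
  cbind(a[sel], b[sel])
}

# Tag boundary edges of a needle-geometry mesh by midpoint location.
.tag_needle_edges <- function(nodes, be, geometry, tol = 1e-7) {
  g <- geometry
  mr <- (nodes[be[, 1], 1] + nodes[be[, 2], 1]) / 2
  mz <- (nodes[be[, 1], 2] + nodes[be[, 2], 2]) / 2
  tag <- rep(NA_character_, nrow(be))
  tag[abs(mr) < tol] <- "AXIS"
  onbot <- abs(mz) < tol
  tag[onbot & mr <= g$domain$pad_radius + tol] <- "PAD"
  tag[onbot & mr > g$domain$pad_radius + tol] <- "FARFIELD"
  tag[abs(mr - g$domain$domain_radius) < tol] <- "FARFIELD"
  tag[abs(mz - g$z_top) < tol & mr > g$r_wall - tol] <- "FARFIELD"
  tag[abs(mr - g$r_shaft) < tol & mz > g$z_tip - tol &
        mz < g$z_junction + tol] <- "ELECTRODE"
  tag[abs(mz - g$z_tip) < tol & mr < g$r_shaft + tol] <- "ELECTRODE"
  tag[abs(mr - g$r_wall) < tol & mz > g$z_junction - tol] <- "INSULATION"
  tag[abs(mz - g$z_junction) < tol & mr > g$r_shaft - tol &
        mr < g$r_wall + tol] <- "INSULATION"
  if (anyNA(tag))
    stop("meshing failure: untagged boundary edge near (r, z) = (",
         signif(mr[which(is.na(tag))[1]], 4), ", ",
         signif(mz[which(is.na(tag))[1]], 4), ")")
  data.frame(n1 = be[, 1], n2 = be[, 2], tag = tag, stringsAsFactors = FALSE)
}

# Tensor-product grid triangulation with a keep-predicate and tagger.
.grid_mesh <- function(r_lines, z_lines, keep_cell, tagger, geometry = NULL) {
  nr <- length(r_lines); nz <- length(z_lines)
  idx <- matrix(seq_len(nr * nz), nrow = nr)   # node (i, j) -> id
  rr <- rep(r_lines, times = nz)
  zz <- rep(z_lines, each = nr)

  ci <- rep(seq_len(nr - 1), times = nz - 1)
  cj <- rep(seq_len(nz - 1), each = nr - 1)
  rc <- (r_lines[ci] + r_lines[ci + 1]) / 2
  zc <- (z_lines[cj] + z_lines[cj + 1]) / 2
  keep <- keep_cell(rc, zc)
  ci <- ci[keep]; cj <- cj[keep]

  n00 <- idx[cbind(ci, cj)]
  n10 <- idx[cbind(ci + 1, cj)]
  n11 <- idx[cbind(ci + 1, cj + 1)]
  n01 <- idx[cbind(ci, cj + 1)]
  alt <- (ci + cj) %% 2L == 0L
  tri <- rbind(
    cbind(n00[alt],  n10[alt],  n11[alt]),
    cbind(n00[alt],  n11[alt],  n01[alt]),
    cbind(n00[!alt], n10[!alt], n01[!alt]),
    cbind(n10[!alt], n11[!alt], n01[!alt])
  )

  used <- sort(unique(as.vector(tri)))
  remap <- integer(nr * nz)
  remap[used] <- seq_along(used)
  tri <- matrix(remap[tri], ncol = 3)
  nodes <- cbind(rr[used], zz[used])
  colnames(nodes) <- c("r", "z")

  be <- .boundary_edges(tri, nrow(nodes))
  edges <- tagger(nodes, be)
  .new_axi_mesh(nodes, tri, edges, geometry)
}

#' Generate the graded axisymmetric mesh
#'
#' Builds a conforming triangulation of the tissue region with element size
#' at most `max_size_near` inside a band of width `near_band` around the
#' applicator and growing geometrically to at most `max_size_far` elsewhere.
#' Grid lines pass through every material feature so boundary tags are exact.
#'
#' @param geometry An `ablation_geometry` from [build_geometry()].
#' @param max_size_near Element size cap near the applicator, cm
#'   (default 0.01 cm = 100 micrometres).
#' @param max_size_far Element size cap in the far field, cm
#'   (default 0.514 cm = 5.14 mm).
#' @param near_band Width of the fine band around the applicator, cm.
#' @param growth Geometric growth ratio of element size outside the band.
#' @return An `axi_mesh`.
#' @export
generate_mesh <- function(geometry, max_size_near = 0.01,
                          max_size_far = 0.514, near_band = 0.1,
                          growth = 1.35) {
  stopifnot(inherits(geometry, "ablation_geometry"))
  if (max_size_near <= 0 || max_size_far <= 0)
    stop("mesh sizes must be positive")
  if (max_size_near > max_size_far)
    stop("max_size_near must not exceed max_size_far")
  g <- geometry
  hn <- max_size_near
  hf <- max_size_far
  R <- g$domain$domain_radius
  Z <- g$domain$domain_length

  r_fine_end <- min(g$r_wall + near_band, R)
  r_lines <- c(
    seq_uniform(0, g$r_shaft, hn),
    seq_uniform(g$r_shaft, g$r_wall, hn),
    seq_uniform(g$r_wall, r_fine_end, hn),
    seq_graded(r_fine_end, g$domain$pad_radius, hn, hf, growth),
    seq_uniform(g$domain$pad_radius, R, hf)
  )
  r_lines <- .merge_lines(r_lines)

  z_fine_lo <- max(g$z_tip - near_band, 0)
  z_fine_hi <- min(g$z_junction + near_band, Z)
  z_lines <- c(
    z_fine_hi + seq_graded(0, Z - z_fine_hi, hn, hf, growth),
    seq_uniform(z_fine_lo, z_fine_hi, hn),
    z_fine_lo - seq_graded(0, z_fine_lo, hn, hf, growth)
  )
  z_lines <- .merge_lines(c(z_lines, 0, g$z_tip, g$z_cool, g$z_junction, Z))

  keep <- function(rc, zc) {
    wall <- ifelse(zc > g$z_junction, g$r_wall, g$r_shaft)
    !(zc > g$z_tip & rc < wall)
  }
  tagger <- function(nodes, be) .tag_needle_edges(nodes, be, g)
  .grid_mesh(r_lines, z_lines, keep, tagger, geometry = g)
}

#' Field-based refinement rule
#'
#' Elements whose field magnitude exceeds `field_threshold` are subdivided;
#' [adapt_mesh()] applies the rule `rounds` times, re-solving in between.
#'
#' @param field_threshold Field magnitude threshold, V/cm (default 250).
#' @param rounds Number of refinement rounds (default 2).
#' @param shrink_factor Nominal per-round size reduction of selected elements
#'   (bisection gives 0.5).
#' @return A `refinement_rule` object.
#' @export
refinement_rule <- function(field_threshold = 250, rounds = 2,
                            shrink_factor = 0.5) {
  stopifnot(field_threshold > 0, rounds >= 0)
  structure(list(field_threshold = field_threshold, rounds = rounds,
                 shrink_factor = shrink_factor), class = "refinement_rule")
}

# One conforming red-green subdivision pass of the marked elements.
# `marked` is a logical vector over elements.
.subdivide <- function(mesh, marked) {
  tri <- mesh$tri
  n_nodes <- nrow(mesh$nodes)
  m <- nrow(tri)
  if (!any(marked)) return(mesh)

  ee <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  a <- pmin(ee[, 1], ee[, 2]); b <- pmax(ee[, 1], ee[, 2])
  key <- a * (n_nodes + 1) + b
  ukey <- unique(key)
  eid <- match(key, ukey)                      # 3m -> edge id
  elem_edge <- matrix(eid, nrow = m)           # m x 3
  ua <- a[match(ukey, key)]; ub <- b[match(ukey, key)]
  elen <- sqrt(rowSums((mesh$nodes[ua, , drop = FALSE] -
                        mesh$nodes[ub, , drop = FALSE])^2))
  el <- matrix(elen[elem_edge], nrow = m)
  longest <- max.col(el, ties.method = "first")

  split_edge <- rep(FALSE, length(ukey))
  split_edge[elem_edge[cbind(which(marked), longest[marked])]] <- TRUE
  # closure: any element touching a split edge must split its longest edge
  repeat {
    has <- matrix(split_edge[elem_edge], nrow = m)
    touch <- has[, 1] | has[, 2] | has[, 3]
    need <- touch & !split_edge[elem_edge[cbind(seq_len(m), longest)]]
    if (!any(need)) break
    split_edge[elem_edge[cbind(which(need), longest[need])]] <- TRUE
  }

  mid <- rep(NA_integer_, length(ukey))
  sid <- which(split_edge)
  mid[sid] <- n_nodes + seq_along(sid)
  new_nodes <- (mesh$nodes[ua[sid], , drop = FALSE] +
                mesh$nodes[ub[sid], , drop = FALSE]) / 2
  parent_edge <- cbind(ua[sid], ub[sid])       # per new node

  has <- matrix(split_edge[elem_edge], nrow = m)
  nsplit <- rowSums(has)
  out <- vector("list", 4)

  keep0 <- which(nsplit == 0L)
  out[[1]] <- tri[keep0, , drop = FALSE]

  i1 <- which(nsplit == 1L)
  if (length(i1)) {
    me <- max.col(has[i1, , drop = FALSE], ties.method = "first")
    va <- tri[cbind(i1, me)]
    vb <- tri[cbind(i1, me %% 3L + 1L)]
    vc <- tri[cbind(i1, (me + 1L) %% 3L + 1L)]
    mm <- mid[elem_edge[cbind(i1, me)]]
    out[[2]] <- rbind(cbind(va, mm, vc), cbind(mm, vb, vc))
  }

  i2 <- which(nsplit == 2L)
  if (length(i2)) {
    ue <- max.col(!has[i2, , drop = FALSE], ties.method = "first")
    # rotate so the unmarked edge is (v3', v1')
    rot <- ifelse(ue == 3L, 0L, ifelse(ue == 1L, 1L, 2L))
    v1 <- tri[cbind(i2, rot %% 3L + 1L)]
    v2 <- tri[cbind(i2, (rot + 1L) %% 3L + 1L)]
    v3 <- tri[cbind(i2, (rot + 2L) %% 3L + 1L)]
    m1 <- mid[elem_edge[cbind(i2, ue %% 3L + 1L)]]
    m2 <- mid[elem_edge[cbind(i2, (ue + 1L) %% 3L + 1L)]]
    out[[3]] <- rbind(cbind(v1, m1, v3), cbind(m1, v2, m2),
                      cbind(m1, m2, v3))
  }

  i3 <- which(nsplit == 3L)
  if (length(i3)) {
    v1 <- tri[i3, 1]; v2 <- tri[i3, 2]; v3 <- tri[i3, 3]
    m1 <- mid[elem_edge[i3, 1]]
    m2 <- mid[elem_edge[i3, 2]]
    m3 <- mid[elem_edge[i3, 3]]
    out[[4]] <- rbind(cbind(v1, m1, m3), cbind(m1, v2, m2),
                      cbind(m3, m2, v3), cbind(m1, m2, m3))
  }

  new_tri <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  dimnames(new_tri) <- NULL
  nodes <- rbind(mesh$nodes, new_nodes)

  # retag: every new boundary edge is an old boundary edge or half of one
  be <- .boundary_edges(new_tri, nrow(nodes))
  okey <- pmin(mesh$edges$n1, mesh$edges$n2) * (n_nodes + 1) +
    pmax(mesh$edges$n1, mesh$edges$n2)
  parent_of_node <- function(v) {
    i <- v - n_nodes
    pmin(parent_edge[i, 1], parent_edge[i, 2]) * (n_nodes + 1) +
      pmax(parent_edge[i, 1], parent_edge[i, 2])
  }
  hi <- pmax(be[, 1], be[, 2])
  lo <- pmin(be[, 1], be[, 2])
  k <- ifelse(hi > n_nodes, NA_real_, lo * (n_nodes + 1) + hi)
  k[is.na(k)] <- parent_of_node(hi[hi > n_nodes])
  tag <- mesh$edges$tag[match(k, okey)]
  if (anyNA(tag))
    stop("refinement produced an untagged boundary edge")
  edges <- data.frame(n1 = be[, 1], n2 = be[, 2], tag = tag,
                      stringsAsFactors = FALSE)
  .new_axi_mesh(nodes, new_tri, edges, mesh$geometry)
}

#' Refine a mesh where the field exceeds the rule threshold
#'
#' One conforming subdivision pass: every element whose field magnitude
#' exceeds `rule$field_threshold` is bisected (red-green closure keeps the
#' mesh conforming).  With `rule$rounds == 0` the mesh is returned unchanged.
#' [adapt_mesh()] is the caller-facing wrapper that re-solves and repeats.
#'
#' @param mesh An `axi_mesh`.
#' @param field A `field_solution` computed on `mesh` (see
#'   [solve_potential()]).
#' @param rule A [refinement_rule()].
#' @return A refined `axi_mesh`.
#' @export
refine_mesh <- function(mesh, field, rule = refinement_rule()) {
  stopifnot(inherits(mesh, "axi_mesh"), inherits(rule, "refinement_rule"))
  if (length(field$E_elem) != nrow(mesh$tri))
    stop("field/mesh mismatch: field has ", length(field$E_elem),
         " element values, mesh has ", nrow(mesh$tri), " elements")
  if (rule$rounds == 0L) return(mesh)
  .subdivide(mesh, field$E_elem > rule$field_threshold)
}

#' Solve-refine-resolve loop
#'
#' Applies the field-based refinement rule `rule$rounds` times, re-solving
#' the electrostatic problem after each pass, and returns the final mesh and
#' field.
#'
#' @param mesh Starting `axi_mesh`.
#' @param materials A [material_properties()].
#' @param applied_voltage Electrode voltage, V.
#' @param rule A [refinement_rule()].
#' @return List with elements `mesh`, `field` and `history` (element and node
#'   counts plus total current per round).
#' @export
adapt_mesh <- function(mesh, materials, applied_voltage,
                       rule = refinement_rule()) {
  field <- solve_potential(mesh, materials, applied_voltage)
  hist <- data.frame(round = 0L, elements = nrow(mesh$tri),
                     nodes = nrow(mesh$nodes), current_A = field$current)
  r <- 0L
  while (r < rule$rounds) {
    mesh <- .subdivide(mesh, field$E_elem > rule$field_threshold)
    field <- solve_potential(mesh, materials, applied_voltage)
    r <- r + 1L
    hist <- rbind(hist, data.frame(round = r, elements = nrow(mesh$tri),
                                   nodes = nrow(mesh$nodes),
                                   current_A = field$current))
  }
  list(mesh = mesh, field = field, history = hist)
}

#' Concentric-sphere benchmark mesh
#'
#' Axisymmetric mesh of the shell between two concentric spheres (inner
#' radius `a` held at the applied voltage, outer radius `b` grounded), built
#' on a polar grid.  The spherical capacitor has the closed-form resistance
#' (1/a - 1/b) / (4 pi sigma), making this the validation oracle for the
#' electrostatic solver and the volume-above-field integrator.
#'
#' @param a Inner sphere radius, cm.
#' @param b Outer sphere radius, cm.
#' @param n_rho Number of radial intervals (geometrically graded).
#' @param n_theta Number of polar-angle intervals.
#' @return An `axi_mesh` with tags ELECTRODE (inner), PAD (outer), AXIS.
#' @export
benchmark_spherical_mesh <- function(a = 0.1, b = 10, n_rho = 80,
                                     n_theta = 64) {
  stopifnot(a > 0, b > a)
  g <- (b / a)^(1 / n_rho)
  rho <- a * g^(0:n_rho)
  theta <- seq(0, pi, length.out = n_theta + 1)

  keep <- function(rc, zc) rep(TRUE, length(rc))
  tagger <- function(nodes, be) {
    mr <- (nodes[be[, 1], 1] + nodes[be[, 2], 1]) / 2
    mz <- (nodes[be[, 1], 2] + nodes[be[, 2], 2]) / 2
    rad <- sqrt(mr^2 + mz^2)
    tag <- rep("AXIS", nrow(be))
    tag[rad < a * 1.02] <- "ELECTRODE"
    tag[rad > b * 0.995] <- "PAD"
    data.frame(n1 = be[, 1], n2 = be[, 2], tag = tag,
               stringsAsFactors = FALSE)
  }
  # polar tensor grid mapped to (r, z)
  nr <- length(rho); nt <- length(theta)
  idx <- matrix(seq_len(nr * nt), nrow = nr)
  rr <- as.vector(outer(rho, theta, function(p, t) p * sin(t)))
  zz <- as.vector(outer(rho, theta, function(p, t) p * cos(t)))
  ci <- rep(seq_len(nr - 1), times = nt - 1)
  cj <- rep(seq_len(nt - 1), each = nr - 1)
  n00 <- idx[cbind(ci, cj)]; n10 <- idx[cbind(ci + 1, cj)]
  n11 <- idx[cbind(ci + 1, cj + 1)]; n01 <- idx[cbind(ci, cj + 1)]
  tri <- rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))
  nodes <- cbind(r = rr, z = zz)
  # orient all triangles counter-clockwise
  ar <- (nodes[tri[, 2], 1] - nodes[tri[, 1], 1]) *
    (nodes[tri[, 3], 2] - nodes[tri[, 1], 2]) -
    (nodes[tri[, 3], 1] - nodes[tri[, 1], 1]) *
    (nodes[tri[, 2], 2] - nodes[tri[, 1], 2])
  flip <- ar < 0
  tri[flip, ] <- tri[flip, c(1, 3, 2)]
  be <- .boundary_edges(tri, nrow(nodes))
  edges <- tagger(nodes, be)
  .new_axi_mesh(nodes, tri, edges, NULL,
                extra = list(benchmark = list(a = a, b = b)))
}

# Plain structured rectangle mesh (tests / 1-D benchmarks).
axi_rect_mesh <- function(r0, r1, z0, z1, nr, nz, tagger) {
  r_lines <- seq(r0, r1, length.out = nr + 1)
  z_lines <- seq(z0, z1, length.out = nz + 1)
  keep <- function(rc, zc) rep(TRUE, length(rc))
  .grid_mesh(r_lines, z_lines, keep, tagger)
}

#' Export a mesh (with optional fields) as legacy ASCII VTK
#'
#' @param mesh An `axi_mesh`.
#' @param file Output path.
#' @param point_data Named list of per-node numeric vectors.
#' @param cell_data Named list of per-element numeric vectors.
#' @return `file`, invisibly.
#' @export
write_vtk <- function(mesh, file, point_data = list(), cell_data = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  writeLines(c("# vtk DataFile Version 3.0", "axisymmetric mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)),
             con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4 * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", point_data[[nm]]), con)
    }
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", cell_data[[nm]]), con)
    }
  }
  invisible(file)
}
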