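#' Applicator (needle electrode) geometry
#'
#' Dimensions of the internally cooled single-needle applicator, in cm.
#' The needle is modelled as a tube of radius `shaft_radius` carrying a
#' coolant channel of radius `channel_radius`, sheathed in insulation of
#' thickness `insulation_thickness` everywhere except the exposed distal
#' segment of length `exposure_length`.  The distal `uncooled_tip_length`
#' of the electrode carries no internal cooling.
#'
#' @param exposure_length Exposed (uninsulated) electrode length, cm.
#'   The in vivo study used 0.5, 1.0, 1.5 or 2.0 cm.
#' @param shaft_radius Outer radius of the needle tube, cm.
#' @param channel_radius Radius of the internal coolant channel, cm.
#' @param insulation_thickness Insulation sheath thickness, cm.
#' @param uncooled_tip_length Distal electrode length without internal
#'   cooling, cm.
#' @param insertion_depth Depth of the electrode tip below the tissue top
#'   surface, cm.  Not reported by the source experiments; the default of
#'   10 cm keeps all lethal iso-contours at least 5 cm from every outer
#'   boundary (see the methods vignette).
#' @return An object of class `applicator_geometry`.
#' @export
applicator_geometry <- function(exposure_length,
                                shaft_radius = 0.08255,
                                channel_radius = 0.0228,
                                insulation_thickness = 0.02032,
                                uncooled_tip_length = 0.5,
                                insertion_depth = 10) {
  app <- structure(list(
    exposure_length = exposure_length,
    shaft_radius = shaft_radius,
    channel_radius = channel_radius,
    insulation_thickness = insulation_thickness,
    uncooled_tip_length = uncooled_tip_length,
    insertion_depth = insertion_depth
  ), class = "applicator_geometry")
  validate_applicator(app)
  app
}

validate_applicator <- function(app) {
  chk <- function(ok, constraint) {
    if (!isTRUE(ok)) stop("applicator geometry violates constraint \"",
                          constraint, "\"", call. = FALSE)
  }
  chk(app$exposure_length > 0, "exposure_length > 0")
  chk(app$shaft_radius > 0, "shaft_radius > 0")
  chk(app$channel_radius < app$shaft_radius, "channel_radius < shaft_radius")
  chk(app$insulation_thickness > 0, "insulation_thickness > 0")
  chk(app$uncooled_tip_length >= 0, "uncooled_tip_length >= 0")
  chk(app$uncooled_tip_length <= app$insertion_depth,
      "uncooled_tip_length <= insertion_depth")
  chk(app$insertion_depth > app$exposure_length,
      "insertion_depth > exposure_length")
  invisible(app)
}

#' Tissue domain geometry
#'
#' The abdomen/liver is modelled as a large cylinder in 2-D axisymmetric
#' (r, z) coordinates with a dispersive grounding pad on the bottom face.
#' All dimensions in cm.
#'
#' @param domain_length Axial extent of the tissue cylinder, cm.
#' @param domain_radius Radial extent of the tissue cylinder, cm.
#' @param pad_radius Radius of the grounding-pad disc on the bottom face, cm.
#' @param pad_height Physical pad height, cm (the pad is a grounded conductor;
#'   it enters the model only as a Dirichlet boundary on the bottom face).
#' @return An object of class `domain_geometry`.
#' @export
domain_geometry <- function(domain_length = 45,
                            domain_radius = 45,
                            pad_radius = 7.6,
                            pad_height = 0.2) {
  dom <- structure(list(
    domain_length = domain_length,
    domain_radius = domain_radius,
    pad_radius = pad_radius,
    pad_height = pad_height
  ), class = "domain_geometry")
  if (dom$pad_radius >= dom$domain_radius)
    stop("domain geometry violates constraint \"pad_radius < domain_radius\"",
         call. = FALSE)
  if (any(unlist(dom) <= 0))
    stop("domain geometry violates constraint \"all dimensions > 0\"",
         call. = FALSE)
  dom
}

#' Build the tagged axisymmetric problem geometry
#'
#' Combines applicator and domain dimensions into a single description of
#' the (r, z) computational domain: the tissue cylinder minus the applicator,
#' with every boundary segment tagged as one of `ELECTRODE`, `INSULATION`,
#' `PAD`, `FARFIELD` or `AXIS`.  The coolant channel is not meshed; cooling
#' enters as a boundary condition on the applicator wall (see
#' [thermal_boundary()]).
#'
#' Coordinates: z runs from 0 (bottom face, grounding pad) to `domain_length`
#' (tissue top surface through which the needle is inserted); r from 0 (axis)
#' to `domain_radius`.
#'
#' @param applicator An [applicator_geometry()].
#' @param domain A [domain_geometry()].
#' @return An object of class `ablation_geometry` with derived coordinates
#'   (`z_tip`, `z_junction`, `z_cool`, `r_wall`) and a `segments` data frame
#'   describing the tagged boundary.
#' @export
#' @examples
#' geo <- build_geometry(applicator_geometry(1.5), domain_geometry())
#' geo$z_junction - geo$z_tip   # exposed electrode length
build_geometry <- function(applicator, domain = domain_geometry()) {
  stopifnot(inherits(applicator, "applicator_geometry"),
            inherits(domain, "domain_geometry"))
  validate_applicator(applicator)

  z_top <- domain$domain_length
  z_tip <- z_top - applicator$insertion_depth
  z_junction <- z_tip + applicator$exposure_length
  z_cool <- z_tip + min(applicator$uncooled_tip_length,
                        applicator$exposure_length)
  r_shaft <- applicator$shaft_radius
  r_wall <- r_shaft + applicator$insulation_thickness

  if (z_tip <= 0)
    stop("geometry violates constraint \"applicator entirely inside domain\"",
         call. = FALSE)
  if (r_wall >= domain$domain_radius)
    stop("geometry violates constraint \"applicator entirely inside domain\"",
         call. = FALSE)

  # closed boundary walk of the tissue region (counter-clockwise from the
  # bottom axis corner)
  R <- domain$domain_radius
  segments <- data.frame(
    r0 = c(0, domain$pad_radius, R, R, r_wall, r_wall, r_shaft, r_shaft, 0),
    z0 = c(0, 0, 0, z_top, z_top, z_junction, z_junction, z_tip, z_tip),
    r1 = c(domain$pad_radius, R, R, r_wall, r_wall, r_shaft, r_shaft, 0, 0),
    z1 = c(0, 0, z_top, z_top, z_junction, z_junction, z_tip, z_tip, 0),
    tag = c("PAD", "FARFIELD", "FARFIELD", "FARFIELD",
            "INSULATION", "INSULATION", "ELECTRODE", "ELECTRODE", "AXIS"),
    stringsAsFactors = FALSE
  )

  structure(list(
    applicator = applicator,
    domain = domain,
    z_top = z_top,
    z_tip = z_tip,
    z_junction = z_junction,
    z_cool = z_cool,
    r_shaft = r_shaft,
    r_wall = r_wall,
    segments = segments
  ), class = "ablation_geometry")
}

#' @export
print.ablation_geometry <- function(x, ...) {
  cat("Axisymmetric ablation geometry\n")
  cat(sprintf("  tissue cylinder: %.1f cm long x %.1f cm radius\n",
              x$domain$domain_length, x$domain$domain_radius))
  cat(sprintf("  exposed electrode: %.2f cm (z = %.2f..%.2f cm), shaft radius %.5f cm\n",
              x$applicator$exposure_length, x$z_tip, x$z_junction, x$r_shaft))
  cat(sprintf("  grounding pad: %.1f cm radius disc on bottom face\n",
              x$domain$pad_radius))
  invisible(x)
}

#' Grounding-pad contact area
#'
#' Area of the grounded disc on the bottom face, in cm^2.
#'
#' @param geometry An [build_geometry()] result or a [domain_geometry()].
#' @return Pad area in cm^2.
#' @export
pad_area <- function(geometry) {
  dom <- if (inherits(geometry, "ablation_geometry")) geometry$domain else geometry
  pi * dom$pad_radius^2
}

#' Electrode boundary axial extent
#'
#' Length along z of the energised (exposed) electrode boundary, cm.
#'
#' @param geometry An `ablation_geometry`.
#' @return Axial extent in cm.
#' @export
electrode_extent <- function(geometry) {
  seg <- geometry$segments
  el <- seg[seg$tag == "ELECTRODE", ]
  max(c(el$z0, el$z1)) - min(c(el$z0, el$z1))
}
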