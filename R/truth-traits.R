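#' Analytic trait vector from simulation ground truth
#'
#' Computes all 32 traits in closed form from the exact geometry of a
#' simulated section: stem shape from the ellipse parameters, zone areas from
#' the convex inner-offset formula `A - P*d + pi*d^2` (exact for the depth
#' bands used by the simulator while the band depth stays below the minimum
#' radius of curvature `b^2/a`), and the moments from the point-mass sums over
#' the exact bundle centroids and disk areas. This is the oracle against which
#' the image-based pipeline ([segment_section()], [compute_section_traits()])
#' is validated.
#'
#' @param truth ground truth from [simulate_cross_section()].
#' @param spec the [section_spec()] that produced it.
#' @param axis an [axis_convention()].
#' @return Named numeric trait vector (see [trait_names()]).
#' @export
truth_traits <- function(truth, spec, axis = axis_convention()) {
  a <- spec$semi_axes_um[1] / 1000  # mm
  b <- spec$semi_axes_um[2] / 1000
  d1 <- spec$ez_thickness_um / 1000
  d2 <- d1 + spec$pz_thickness_um / 1000
  A  <- pi * a * b
  P  <- ellipse_perimeter(a, b)
  A1 <- offset_body_area(A, P, d1)   # area at depth >= d1 (PZ + IZ)
  A2 <- offset_body_area(A, P, d2)   # area at depth >= d2 (IZ)
  stem <- list(area_mm2 = A, perimeter_mm = P,
               long_axis_mm = 2 * a, short_axis_mm = 2 * b,
               center_um = truth$center_um,
               long_axis_dir = c(1, 0))
  zones <- list(EZ_A = A - A1, EZ_T = d1,
                PZ_A = A1 - A2, PZ_T = d2 - d1,
                IZ_A = A2, IZ_T = b - d2)
  bundles <- truth$bundles
  bundles$accepted <- rep(TRUE, nrow(bundles))
  assemble_traits(stem, zones, bundles, axis)
}
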