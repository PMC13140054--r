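#' Specification of a synthetic stem cross-section
#'
#' Describes the geometry, bundle population and imaging model of one simulated
#' CT-like cross-section. Defaults mirror a basal maize internode imaged at
#' 15 um/px: an elliptical section of roughly 17.6 x 15.6 mm with a thin dense
#' epidermis ring, a periphery zone carrying many small bright vascular
#' bundles and an inner zone with fewer, larger bundles.
#'
#' Zones are defined as depth bands of the Euclidean distance to the section
#' boundary: the epidermis zone (EZ) is the band within `ez_thickness_um` of
#' the boundary, the periphery zone (PZ) the next `pz_thickness_um`, and the
#' inner zone (IZ) the remainder. The same definition is used by
#' [partition_zones()], so simulator truth and segmentation share one
#' geometry.
#'
#' @param image_shape integer (height, width) in pixels.
#' @param pixel_size_um physical pixel size, um per pixel.
#' @param semi_axes_um ellipse semi-axes (a, b) in um, `a >= b`.
#' @param center_um stem centre (x, y) in um; default = image centre.
#' @param ez_thickness_um,pz_thickness_um zone band depths in um.
#' @param n_pz_bundles,n_iz_bundles bundle counts per zone.
#' @param pz_radius_um,iz_radius_um lognormal bundle-radius models,
#'   `c(median_um, sigma_log)`.
#' @param min_separation_um minimum distance between bundle centroids; disks
#'   are additionally required not to overlap (surface gap
#'   `bundle_gap_um`).
#' @param bundle_gap_um minimum free surface-to-surface gap between disks and
#'   between a disk and its zone boundary, um.
#' @param intensity 8-bit grey levels, named `background`, `tissue`,
#'   `epidermis`, `bundle`.
#' @param noise_sigma additive Gaussian noise, 8-bit units.
#' @param blur_sigma Gaussian blur, pixels.
#' @param invert_contrast if `TRUE`, grey levels are flipped (255 - g), for
#'   acquisitions where dense tissue images dark.
#' @param max_attempts bound on rejection-sampling attempts per bundle.
#' @param seed integer seed; simulation is deterministic given the spec.
#'
#' @return An object of class `section_spec` (a validated list).
#' @seealso [simulate_cross_section()], [truth_traits()]
#' @export
#' @examples
#' sp <- section_spec(image_shape = c(300, 300), semi_axes_um = c(2000, 1700),
#'                    n_pz_bundles = 12, n_iz_bundles = 5, seed = 1)
section_spec <- function(image_shape = c(1250, 1250),
                         pixel_size_um = 15,
                         semi_axes_um = c(8800, 7800),
                         center_um = NULL,
                         ez_thickness_um = 240,
                         pz_thickness_um = 2000,
                         n_pz_bundles = 110,
                         n_iz_bundles = 50,
                         pz_radius_um = c(140, 0.15),
                         iz_radius_um = c(260, 0.15),
                         min_separation_um = 500,
                         bundle_gap_um = 150,
                         intensity = c(background = 20, tissue = 100,
                                       epidermis = 230, bundle = 180),
                         noise_sigma = 6,
                         blur_sigma = 1,
                         invert_contrast = FALSE,
                         max_attempts = 10000,
                         seed = 1) {
  if (is.null(center_um)) {
    center_um <- c((image_shape[2] - 1) / 2, (image_shape[1] - 1) / 2) *
      pixel_size_um
  }
  spec <- list(image_shape = as.integer(image_shape),
               pixel_size_um = pixel_size_um,
               semi_axes_um = as.numeric(semi_axes_um),
               center_um = as.numeric(center_um),
               ez_thickness_um = ez_thickness_um,
               pz_thickness_um = pz_thickness_um,
               n_pz_bundles = as.integer(n_pz_bundles),
               n_iz_bundles = as.integer(n_iz_bundles),
               pz_radius_um = as.numeric(pz_radius_um),
               iz_radius_um = as.numeric(iz_radius_um),
               min_separation_um = min_separation_um,
               bundle_gap_um = bundle_gap_um,
               intensity = intensity,
               noise_sigma = noise_sigma,
               blur_sigma = blur_sigma,
               invert_contrast = isTRUE(invert_contrast),
               max_attempts = as.integer(max_attempts),
               seed = as.integer(seed))
  class(spec) <- "section_spec"
  validate_section_spec(spec)
  spec
}

validate_section_spec <- function(spec) {
  a <- spec$semi_axes_um[1]; b <- spec$semi_axes_um[2]
  if (!(a >= b && b > 0)) stop("invalid geometry: need a >= b > 0")
  if (spec$pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (spec$ez_thickness_um < 0 || spec$pz_thickness_um < 0)
    stop("zone thicknesses must be >= 0")
  if (b <= spec$ez_thickness_um + spec$pz_thickness_um)
    stop("invalid geometry: zone bands exceed the short semi-axis")
  if (spec$n_pz_bundles < 0 || spec$n_iz_bundles < 0)
    stop("bundle counts must be >= 0")
  if (any(spec$intensity < 0 | spec$intensity > 255))
    stop("intensity levels must lie in [0, 255]")
  stopifnot(length(spec$intensity) == 4,
            all(c("background", "tissue", "epidermis", "bundle") %in%
                  names(spec$intensity)))
  invisible(spec)
}

#' @export
print.section_spec <- function(x, ...) {
  cat(sprintf(
    "section_spec: %d x %d px @ %.1f um/px; semi-axes %.1f x %.1f mm\n",
    x$image_shape[1], x$image_shape[2], x$pixel_size_um,
    x$semi_axes_um[1] / 1000, x$semi_axes_um[2] / 1000))
  cat(sprintf("  zones: EZ %.2f mm, PZ %.2f mm; bundles: %d PZ + %d IZ; seed %d\n",
              x$ez_thickness_um / 1000, x$pz_thickness_um / 1000,
              x$n_pz_bundles, x$n_iz_bundles, x$seed))
  invisible(x)
}
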