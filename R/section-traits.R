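#' Compute the 32-trait vector of one segmented section
#'
#' Stem size and shape come from the stem mask (area by pixel count,
#' perimeter from a subsampled boundary contour, long/short axis from the
#' mask's best-fit ellipse via second moments); zone areas by pixel count of
#' the depth bands; zone thicknesses from the stem distance transform sampled
#' along each band's inner boundary (the inner-zone thickness is its
#' inradius); bundle counts, areas, densities and area ratios per zone from
#' the accepted bundle table; and the mechanical descriptors from the
#' point-mass sums of [compute_moa()] and [compute_pmoi_moia()].
#'
#' @param zones `zone_mask` from [partition_zones()].
#' @param bundles bundle table with zones assigned ([assign_zones()]).
#' @param pixel_size_um physical pixel size, um.
#' @param axis an [axis_convention()] selecting the neutral axis for MOA.
#' @return Named numeric vector of the 32 traits (mm-based units; see
#'   [trait_names()]). All trait-vector invariants are asserted before
#'   returning.
#' @export
compute_section_traits <- function(zones, bundles, pixel_size_um,
                                   axis = axis_convention()) {
  labels <- zones$labels
  if (!all(c(1L, 2L, 3L) %in% labels)) stop("missing zone in zone mask")
  stem <- labels > 0L
  s <- pixel_size_um
  px_mm2 <- s^2 / 1e6
  sz_a <- sum(stem) * px_mm2

  # perimeter: polygon length of the boundary contour subsampled every 5
  # points (suppresses pixel-staircase bias)
  ct <- EBImage::ocontour(EBImage::Image(stem * 1))[[1]]
  step <- 5
  idx <- seq(1, nrow(ct), by = step)
  poly <- ct[idx, , drop = FALSE]
  dp <- rbind(diff(poly), poly[1, ] - poly[nrow(poly), ])
  sz_p <- sum(sqrt(rowSums(dp^2))) * s / 1000

  # best-fit ellipse from second moments of the mask
  pix <- which(stem, arr.ind = TRUE)
  xs <- (pix[, 2] - 1); ys <- (pix[, 1] - 1)
  cx <- mean(xs); cy <- mean(ys)
  cv <- stats::cov(cbind(xs, ys))
  ei <- eigen(cv, symmetric = TRUE)
  la_mm <- 4 * sqrt(ei$values[1]) * s / 1000
  sa_mm <- 4 * sqrt(ei$values[2]) * s / 1000
  long_dir <- ei$vectors[, 1]

  depth <- zones$depth_px
  zone_area <- function(k) sum(labels == k) * px_mm2
  # mean stem depth along the inner boundary of each band
  inner_boundary_depth <- function(region) {
    er <- as.matrix(EBImage::erode(EBImage::Image(region * 1),
                                   EBImage::makeBrush(3, "box"))) > 0
    bnd <- region & !er
    mean(depth[bnd]) * s / 1000
  }
  d1_mm <- inner_boundary_depth(labels >= 2L)
  d2_mm <- inner_boundary_depth(labels == 3L)
  iz_depth <- depth[labels == 3L]
  zones_mm <- list(EZ_A = zone_area(1L), EZ_T = d1_mm,
                   PZ_A = zone_area(2L), PZ_T = d2_mm - d1_mm,
                   IZ_A = zone_area(3L),
                   IZ_T = (max(iz_depth) - d2_mm * 1000 / s) * s / 1000)
  stem_info <- list(area_mm2 = sz_a, perimeter_mm = sz_p,
                    long_axis_mm = la_mm, short_axis_mm = sa_mm,
                    center_um = c(cx, cy) * s,
                    long_axis_dir = long_dir)
  assemble_traits(stem_info, zones_mm, bundles, axis)
}
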