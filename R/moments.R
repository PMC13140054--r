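#' Engineering-mechanics descriptors of the bundle population
#'
#' Vascular bundles enter the section mechanics as point masses: each bundle
#' contributes its area times the squared distance of its centroid to a
#' reference axis or point. `compute_moa()` is the moment of area about a
#' neutral bending axis, `sum(A_i * y_i^2)`; `compute_pmoi_moia()` is the
#' polar moment of inertia about the section centroid, `sum(A_i * r_i^2)`,
#' together with its decomposition into area moments of inertia about the long
#' and short principal axes (`MOIAL`, `MOIAS`). By the perpendicular-axis
#' identity for point masses, `PMOI = MOIAL + MOIAS` exactly.
#'
#' @param bundles bundle table with columns `x_um`, `y_um`, `area_um2`
#'   (accepted bundles only; see [filter_candidates()]).
#' @param center_um section centroid `(x, y)` in um; the neutral axis and both
#'   principal axes pass through it.
#' @param axis_dir unit direction vector of the neutral axis (default: image
#'   horizontal).
#' @return `compute_moa()`: the moment of area in mm^4. `compute_pmoi_moia()`:
#'   named vector `c(PMOI, MOIAL, MOIAS)` in mm^4.
#' @export
#' @examples
#' b <- data.frame(x_um = 0, y_um = 2000, area_um2 = 1e6)  # 1 mm^2 at 2 mm
#' compute_moa(b, center_um = c(0, 0))                     # 4 mm^4
compute_moa <- function(bundles, center_um, axis_dir = c(1, 0)) {
  if (nrow(bundles) == 0) {
    warning("empty bundle table: MOA = 0")
    return(0)
  }
  stopifnot(all(bundles$area_um2 > 0))
  u <- axis_dir / sqrt(sum(axis_dir^2))
  dx <- bundles$x_um - center_um[1]
  dy <- bundles$y_um - center_um[2]
  # perpendicular distance to the line through center along u
  y <- abs(dx * u[2] - dy * u[1])
  sum(bundles$area_um2 * y^2) / 1e12
}

#' @rdname compute_moa
#' @param long_axis_dir unit direction of the section's long principal axis;
#'   the short axis is its perpendicular.
#' @export
compute_pmoi_moia <- function(bundles, center_um, long_axis_dir = c(1, 0)) {
  if (nrow(bundles) == 0) {
    warning("empty bundle table: PMOI/MOIA = 0")
    return(c(PMOI = 0, MOIAL = 0, MOIAS = 0))
  }
  u <- long_axis_dir / sqrt(sum(long_axis_dir^2))
  v <- c(-u[2], u[1])
  dx <- bundles$x_um - center_um[1]
  dy <- bundles$y_um - center_um[2]
  d_long  <- abs(dx * u[2] - dy * u[1])   # distance to the long axis
  d_short <- abs(dx * v[2] - dy * v[1])   # distance to the short axis
  moial <- sum(bundles$area_um2 * d_long^2) / 1e12
  moias <- sum(bundles$area_um2 * d_short^2) / 1e12
  c(PMOI = moial + moias, MOIAL = moial, MOIAS = moias)
}

#' Neutral-axis conventions for the moment of area
#'
#' The neutral axis always passes through the section centroid; its direction
#' is either the image horizontal (the default, matching a bending rig that
#' loads vertically in the image frame), or one of the section's principal
#' axes.
#'
#' @param neutral_axis one of `"image_horizontal"`, `"section_long_axis"`,
#'   `"section_short_axis"`.
#' @return An object of class `axis_convention`.
#' @export
axis_convention <- function(neutral_axis = c("image_horizontal",
                                             "section_long_axis",
                                             "section_short_axis")) {
  structure(list(neutral_axis = match.arg(neutral_axis)),
            class = "axis_convention")
}

# Resolve the neutral-axis direction given the section's long-axis direction.
neutral_axis_dir <- function(axis, long_axis_dir) {
  u <- long_axis_dir / sqrt(sum(long_axis_dir^2))
  switch(axis$neutral_axis,
         image_horizontal  = c(1, 0),
         section_long_axis = u,
         section_short_axis = c(-u[2], u[1]))
}
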