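#' Simulate a CT-like stem cross-section with exact ground truth
#'
#' Renders an 8-bit grayscale cross-section image following a
#' [section_spec()]: an elliptical stem on a dark background, a bright dense
#' epidermis ring, ground tissue, and circular vascular-bundle disks placed by
#' rejection sampling in the periphery (PZ) and inner (IZ) zones, followed by
#' Gaussian blur and additive Gaussian noise. The returned ground truth
#' records every bundle's exact centroid, radius and zone plus the zone
#' geometry, and serves as the oracle for the segmentation and trait modules.
#'
#' Bundle placement enforces (i) pairwise centroid distance >=
#' `min_separation_um`, (ii) a free gap of at least `bundle_gap_um` between
#' disk surfaces, and (iii) each disk fully inside its zone band with margin
#' `bundle_gap_um` (using the exact point-to-ellipse distance). Placement is
#' abandoned with an error after `max_attempts` rejections for any single
#' bundle.
#'
#' @param spec a [section_spec()].
#' @return A list of class `section_sim` with elements:
#'   \describe{
#'     \item{image}{integer matrix (rows = y, cols = x), grey values 0-255.}
#'     \item{truth}{list with `bundles` (data frame: `id, x_um, y_um,
#'       radius_um, area_um2, zone`), `zone_raster` (integer matrix with
#'       0 = background, 1 = EZ, 2 = PZ, 3 = IZ), `center_um`,
#'       `semi_axes_um`, `depths_um` (EZ and EZ+PZ band depths) and `seed`.}
#'     \item{spec}{the input spec.}
#'   }
#' @export
#' @examples
#' sim <- simulate_cross_section(section_spec(image_shape = c(250, 250),
#'   semi_axes_um = c(1700, 1500), ez_thickness_um = 150,
#'   pz_thickness_um = 600, n_pz_bundles = 8, n_iz_bundles = 3,
#'   pz_radius_um = c(80, 0.1), iz_radius_um = c(120, 0.1),
#'   min_separation_um = 300, seed = 42))
#' range(sim$image)
#' nrow(sim$truth$bundles)
simulate_cross_section <- function(spec) {
  validate_section_spec(spec)
  with_seed(spec$seed, {
    a <- spec$semi_axes_um[1]; b <- spec$semi_axes_um[2]
    d1 <- spec$ez_thickness_um
    d2 <- spec$ez_thickness_um + spec$pz_thickness_um
    bundles <- place_bundles(spec, a, b, d1, d2)
    zr <- zone_raster(spec)
    img <- render_section(spec, bundles, zr)
    truth <- list(bundles = bundles,
                  zone_raster = zr,
                  center_um = spec$center_um,
                  semi_axes_um = spec$semi_axes_um,
                  depths_um = c(ez = d1, pz = d2),
                  seed = spec$seed)
    structure(list(image = img, truth = truth, spec = spec),
              class = "section_sim")
  })
}

# Rejection-sample bundle disks for both zones. Coordinates are um relative to
# the image frame (x = column direction, y = row direction).
place_bundles <- function(spec, a, b, d1, d2) {
  gap <- spec$bundle_gap_um
  sep <- spec$min_separation_um
  placed <- list()
  sample_zone <- function(n, rmodel, depth_lo, depth_hi, zone) {
    # depth band (depth_lo, depth_hi]; depth_hi = Inf for the inner zone
    out <- vector("list", n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (att in seq_len(spec$max_attempts)) {
        r <- rlnorm(1, meanlog = log(rmodel[1]), sdlog = rmodel[2])
        # uniform proposal in the bounding box of the zone's outer boundary
        x <- runif(1, -a, a); y <- runif(1, -b, b)
        dep <- ellipse_depth(a, b, x, y)
        if (dep < depth_lo + r + gap) next
        if (is.finite(depth_hi) && dep > depth_hi - r - gap) next
        if (length(placed)) {
          px <- vapply(placed, `[[`, 0, "x"); py <- vapply(placed, `[[`, 0, "y")
          pr <- vapply(placed, `[[`, 0, "r")
          dd <- sqrt((px - x)^2 + (py - y)^2)
          if (any(dd < sep) || any(dd < pr + r + gap)) next
        }
        placed[[length(placed) + 1]] <<- list(x = x, y = y, r = r, zone = zone)
        ok <- TRUE
        break
      }
      if (!ok) stop("unplaceable: could not place bundle ", length(placed) + 1,
                    " in ", zone, " after ", spec$max_attempts, " attempts")
    }
  }
  sample_zone(spec$n_pz_bundles, spec$pz_radius_um, d1, d2, "PZ")
  sample_zone(spec$n_iz_bundles, spec$iz_radius_um, d2, Inf, "IZ")
  if (!length(placed)) {
    return(data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                      radius_um = numeric(), area_um2 = numeric(),
                      zone = character(), stringsAsFactors = FALSE))
  }
  data.frame(id = seq_along(placed),
             x_um = vapply(placed, `[[`, 0, "x") + spec$center_um[1],
             y_um = vapply(placed, `[[`, 0, "y") + spec$center_um[2],
             radius_um = vapply(placed, `[[`, 0, "r"),
             area_um2 = pi * vapply(placed, `[[`, 0, "r")^2,
             zone = vapply(placed, `[[`, "", "zone"),
             stringsAsFactors = FALSE)
}

# Pixel-centre coordinate grids in um (0-based pixel frame).
pixel_grid <- function(spec) {
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  list(x = (seq_len(W) - 1) * spec$pixel_size_um,
       y = (seq_len(H) - 1) * spec$pixel_size_um)
}

# Integer zone-label raster (0 bg, 1 EZ, 2 PZ, 3 IZ) from the exact Euclidean
# depth of each pixel centre inside the outer ellipse.
zone_raster <- function(spec) {
  g <- pixel_grid(spec)
  a <- spec$semi_axes_um[1]; b <- spec$semi_axes_um[2]
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  X <- matrix(g$x - spec$center_um[1], H, W, byrow = TRUE)
  Y <- matrix(g$y - spec$center_um[2], H, W)
  dep <- matrix(ellipse_depth(a, b, as.vector(X), as.vector(Y)), H, W)
  d1 <- spec$ez_thickness_um
  d2 <- d1 + spec$pz_thickness_um
  z <- matrix(0L, H, W)
  z[dep >= 0] <- 1L
  z[dep > d1] <- 2L
  z[dep > d2] <- 3L
  z
}

render_section <- function(spec, bundles, zr = zone_raster(spec)) {
  lv <- spec$intensity
  img <- matrix(as.numeric(lv[["background"]]), nrow(zr), ncol(zr))
  img[zr >= 2L] <- lv[["tissue"]]
  img[zr == 1L] <- lv[["epidermis"]]
  s <- spec$pixel_size_um
  # paint bundle disks over bounded sub-grids
  for (i in seq_len(nrow(bundles))) {
    cx <- bundles$x_um[i]; cy <- bundles$y_um[i]; r <- bundles$radius_um[i]
    jj <- seq(max(1L, floor((cx - r) / s)), min(ncol(img), ceiling((cx + r) / s) + 1L))
    ii <- seq(max(1L, floor((cy - r) / s)), min(nrow(img), ceiling((cy + r) / s) + 1L))
    dx <- ( (jj - 1) * s - cx )
    dy <- ( (ii - 1) * s - cy )
    disk <- outer(dy^2, dx^2, `+`) <= r^2
    sub <- img[ii, jj, drop = FALSE]
    sub[disk] <- lv[["bundle"]]
    img[ii, jj] <- sub
  }
  if (spec$blur_sigma > 0) {
    img <- EBImage::gblur(img / 255, sigma = spec$blur_sigma) * 255
  }
  if (spec$noise_sigma > 0) {
    img <- img + rnorm(length(img), 0, spec$noise_sigma)
  }
  img <- pmin(pmax(round(img), 0), 255)
  if (spec$invert_contrast) img <- 255 - img
  storage.mode(img) <- "integer"
  img
}

#' @export
print.section_sim <- function(x, ...) {
  cat(sprintf("section_sim: %d x %d px image, %d bundles (seed %d)\n",
              nrow(x$image), ncol(x$image), nrow(x$truth$bundles),
              x$truth$seed))
  invisible(x)
}
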