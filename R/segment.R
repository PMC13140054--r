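#' Segmentation configuration
#'
#' All tunable parameters of the stem/zone/bundle segmentation, with defaults
#' calibrated on rendered-disk fixtures. Distances are um, intensities 8-bit
#' grey units.
#'
#' @param min_stem_area_mm2 smallest acceptable stem mask, mm^2.
#' @param close_radius_px radius of the morphological closing brush applied to
#'   the thresholded stem mask.
#' @param ez_thickness_um,pz_thickness_um zone band depths used by
#'   [partition_zones()].
#' @param bg_median_radius_px radius of the large-window median filter used
#'   for background correction (should exceed the largest bundle radius).
#' @param smooth_sigma_px Gaussian smoothing applied before marker detection.
#' @param detect_margin_um stem-boundary margin excluded from bundle
#'   detection; the epidermis band carries no bundles, so the default equals
#'   `ez_thickness_um`.
#' @param k_thresh foreground threshold inside the stem:
#'   `median + k_thresh * MAD` of the background-corrected smoothed image.
#' @param thresh_floor_grey minimum contrast (grey levels) a candidate must
#'   rise above the in-stem median, regardless of the noise spread; guards
#'   the noise-free limit where the MAD vanishes.
#' @param h_factor watershed marker depth (h-maxima) as a multiple of the
#'   scaled MAD of in-stem intensities.
#' @param area_min_mm2,area_max_mm2 accepted bundle area window.
#' @param solidity_min,eccentricity_max shape acceptance thresholds.
#' @param intensity_min_quantile accepted bundles must have mean raw intensity
#'   at or above this quantile of in-stem intensity (default: the stem
#'   median).
#' @param halfmax_quantile quantile of in-region corrected intensity used as
#'   the peak estimate for half-maximum area refinement.
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(min_stem_area_mm2 = 1,
                       close_radius_px = 5,
                       ez_thickness_um = 240,
                       pz_thickness_um = 2000,
                       bg_median_radius_px = 45,
                       smooth_sigma_px = 2,
                       detect_margin_um = 240,
                       k_thresh = 4,
                       thresh_floor_grey = 2,
                       h_factor = 0.5,
                       area_min_mm2 = 0.005,
                       area_max_mm2 = 1.5,
                       solidity_min = 0.70,
                       eccentricity_max = 0.97,
                       intensity_min_quantile = 0.5,
                       halfmax_quantile = 0.95) {
  structure(as.list(environment()), class = "seg_config")
}

as_ebimage <- function(img) {
  EBImage::Image(img / 255)
}

# background-median radius, capped for small images
bg_radius <- function(image, config) {
  min(config$bg_median_radius_px, floor(min(dim(image)) / 2) - 1)
}

#' Segment the stem region of a cross-section image
#'
#' Global (Otsu) thresholding, morphological closing and hole filling,
#' followed by selection of the largest connected foreground component. The
#' returned mask is simply connected.
#'
#' @param image integer/numeric matrix, grey values 0-255 (rows = y).
#' @param pixel_size_um physical pixel size, um.
#' @param config a [seg_config()].
#' @return Logical matrix: the stem mask.
#' @export
segment_stem <- function(image, pixel_size_um, config = seg_config()) {
  x <- as_ebimage(image)
  thr <- EBImage::otsu(x)
  mask <- x > thr
  if (config$close_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * config$close_radius_px + 1, shape = "disc")
    mask <- EBImage::closing(mask, brush)
  }
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(as.integer(lab))
  min_px <- config$min_stem_area_mm2 * 1e6 / pixel_size_um^2
  if (length(sizes) == 0 || max(sizes) < min_px) stop("no stem found")
  keep <- which.max(sizes)
  m <- matrix(as.integer(lab) == keep, nrow(image), ncol(image))
  m
}

#' Partition the stem into epidermis, periphery and inner zones
#'
#' Zones are depth bands of the Euclidean distance to the stem boundary:
#' EZ within `ez_thickness_um` of the boundary, PZ the next
#' `pz_thickness_um`, IZ the remainder. Pixel-count conservation
#' (EZ + PZ + IZ = stem) holds exactly.
#'
#' @inheritParams segment_stem
#' @param stem_mask logical matrix from [segment_stem()].
#' @return A list of class `zone_mask`: `labels` (integer matrix, 0 background
#'   / 1 EZ / 2 PZ / 3 IZ), `depth_px` (distance transform of the stem mask)
#'   and `provenance` (the thicknesses used).
#' @export
partition_zones <- function(stem_mask, pixel_size_um, config = seg_config()) {
  if (!any(stem_mask)) stop("empty stem mask")
  depth <- as.matrix(EBImage::distmap(EBImage::Image(stem_mask * 1)))
  d1 <- config$ez_thickness_um / pixel_size_um
  d2 <- (config$ez_thickness_um + config$pz_thickness_um) / pixel_size_um
  labels <- matrix(0L, nrow(stem_mask), ncol(stem_mask))
  labels[stem_mask] <- 1L
  labels[stem_mask & depth > d1] <- 2L
  labels[stem_mask & depth > d2] <- 3L
  if (!any(labels == 3L)) stop("degenerate zones: inner zone is empty")
  structure(list(labels = labels, depth_px = depth,
                 provenance = list(ez_thickness_um = config$ez_thickness_um,
                                   pz_thickness_um = config$pz_thickness_um,
                                   pixel_size_um = pixel_size_um)),
            class = "zone_mask")
}

#' Detect vascular-bundle candidate regions
#'
#' Classical replacement for a learned bundle detector: large-window median
#' background correction, Gaussian smoothing, adaptive thresholding inside the
#' stem (median + k * MAD of in-stem intensities), and a marker-controlled
#' watershed whose marker depth (h-maxima height) adapts to the robust
#' intensity spread inside the stem. Over-segmentation is permitted here;
#' candidates are vetted by [filter_candidates()].
#'
#' @inheritParams segment_stem
#' @param stem_mask logical stem mask.
#' @return Integer label matrix of candidate regions (0 = none), with the
#'   background-corrected image attached as attribute `corrected` and the
#'   in-stem median/MAD as attribute `stats`.
#' @export
detect_vb_candidates <- function(image, stem_mask, pixel_size_um,
                                 config = seg_config()) {
  x <- as_ebimage(image)
  bg <- EBImage::medianFilter(x, bg_radius(image, config))
  corrected <- (as.matrix(x) - as.matrix(bg)) * 255
  # restrict detection to the bundle-carrying region (exclude the epidermis
  # band, which is dense and bundle-free)
  depth <- as.matrix(EBImage::distmap(EBImage::Image(stem_mask * 1)))
  margin_px <- config$detect_margin_um / pixel_size_um
  region <- stem_mask & depth > margin_px
  smooth <- if (config$smooth_sigma_px > 0) {
    as.matrix(EBImage::gblur(EBImage::Image(corrected / 255),
                             sigma = config$smooth_sigma_px)) * 255
  } else corrected
  # robust location/spread of the background-corrected signal inside the
  # stem (pre-smoothing, so the spread reflects the acquisition noise)
  vals <- corrected[region]
  med <- median(smooth[region])
  spread <- mad(vals)  # scaled MAD (consistent with a Gaussian sigma)
  thr <- med + max(config$k_thresh * spread, config$thresh_floor_grey)
  fg <- region & smooth > thr
  if (!any(fg)) {
    lab <- matrix(0L, nrow(image), ncol(image))
  } else {
    h <- max(config$h_factor * spread, 1 / 255)
    relief <- matrix(0, nrow(image), ncol(image))
    relief[fg] <- smooth[fg] - thr
    ws <- EBImage::watershed(EBImage::Image(relief / 255),
                             tolerance = h / 255, ext = 1)
    lab <- matrix(as.integer(ws), nrow(image), ncol(image))
  }
  attr(lab, "corrected") <- corrected
  attr(lab, "smooth") <- smooth
  attr(lab, "stats") <- c(median = med, mad = spread, threshold = thr)
  lab
}

#' Filter bundle candidates on geometric and morphological features
#'
#' Each candidate region is refined to its half-maximum support (pixels above
#' half of the region's peak background-corrected intensity), then accepted if
#' its area, solidity, eccentricity and mean raw intensity pass the configured
#' thresholds. Rejected candidates are retained with their rejection reasons.
#'
#' @inheritParams detect_vb_candidates
#' @param candidates label matrix from [detect_vb_candidates()].
#' @return A `data.frame` bundle table: `id, centroid x/y (um), area (um^2),
#'   zone (NA until [assign_zones()]), eccentricity, solidity,
#'   mean_intensity, accepted, reject_reason`.
#' @export
filter_candidates <- function(candidates, image, stem_mask, pixel_size_um,
                              config = seg_config()) {
  corrected <- attr(candidates, "corrected")
  if (is.null(corrected)) {
    x <- as_ebimage(image)
    bg <- EBImage::medianFilter(x, bg_radius(image, config))
    corrected <- (as.matrix(x) - as.matrix(bg)) * 255
  }
  # half-max refinement runs on the smoothed corrected image (noise-free
  # peak estimate); fall back to the corrected image if unavailable
  smooth <- attr(candidates, "smooth")
  if (is.null(smooth)) smooth <- corrected
  intensity_floor <- quantile(image[stem_mask], config$intensity_min_quantile,
                              names = FALSE)
  n <- max(candidates)
  empty <- data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                      area_um2 = numeric(), zone = character(),
                      eccentricity = numeric(), solidity = numeric(),
                      mean_intensity = numeric(), accepted = logical(),
                      reject_reason = character(), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  idx <- which(candidates > 0)
  lab <- candidates[idx]
  rows <- (idx - 1) %% nrow(candidates) + 1
  cols <- (idx - 1) %/% nrow(candidates) + 1
  px_area <- pixel_size_um^2
  groups <- split(seq_along(lab), lab)
  out <- vector("list", n)
  for (nm in names(groups)) {
    k <- as.integer(nm)
    sel <- groups[[nm]]
    r <- rows[sel]; cc <- cols[sel]
    # peak from the smoothed image (noise-free plateau estimate); support cut
    # on the corrected image, whose edge is sharper, so the half-maximum
    # contour tracks the true object radius more closely
    peak <- quantile(smooth[cbind(r, cc)], config$halfmax_quantile,
                     names = FALSE)
    cv <- corrected[cbind(r, cc)]
    keep <- cv >= peak / 2
    r <- r[keep]; cc <- cc[keep]
    if (length(r) == 0) next
    area_um2 <- length(r) * px_area
    cx <- mean(cc - 1) * pixel_size_um
    cy <- mean(r - 1) * pixel_size_um
    ecc <- region_eccentricity(cc, r)
    sol <- region_solidity(cc, r)
    mi <- mean(image[cbind(r, cc)])
    reasons <- character()
    if (area_um2 < config$area_min_mm2 * 1e6 ||
        area_um2 > config$area_max_mm2 * 1e6) reasons <- c(reasons, "area")
    if (sol < config$solidity_min) reasons <- c(reasons, "solidity")
    if (ecc > config$eccentricity_max) reasons <- c(reasons, "eccentricity")
    if (mi < intensity_floor) reasons <- c(reasons, "intensity")
    out[[k]] <- data.frame(id = k, x_um = cx, y_um = cy, area_um2 = area_um2,
                           zone = NA_character_, eccentricity = ecc,
                           solidity = sol, mean_intensity = mi,
                           accepted = length(reasons) == 0,
                           reject_reason = paste(reasons, collapse = ";"),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) empty else res
}

# Eccentricity of a pixel region from its coordinate covariance:
# sqrt(1 - lambda_min/lambda_max), in [0, 1).
region_eccentricity <- function(x, y) {
  if (length(x) < 3) return(0)
  cv <- stats::cov(cbind(x, y))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

# Solidity = pixel count / convex-hull area. Hull area from the shoelace
# formula over pixel centres, corrected by half the hull boundary length plus
# one (Pick-style) so a convex region scores ~1.
region_solidity <- function(x, y) {
  if (length(x) < 4) return(1)
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(1)
  h <- chull(pts)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  shoelace <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  # boundary lattice points of the hull polygon
  bnd <- sum(vapply(seq_along(h), function(i) {
    j <- if (i == length(h)) 1 else i + 1
    dgcd(abs(hx[j] - hx[i]), abs(hy[j] - hy[i]))
  }, 0))
  hull_area <- shoelace + bnd / 2 + 1
  min(1, length(x) / hull_area)
}

dgcd <- function(a, b) {
  a <- round(a); b <- round(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  max(a, 1)
}

#' Assign detected bundles to zones
#'
#' The zone is the zone label at the bundle centroid. Centroids falling in the
#' epidermis band (which is bundle-free by definition) are reassigned to PZ
#' with a message; centroids outside the stem raise an error.
#'
#' @param bundles bundle table from [filter_candidates()].
#' @param zones a `zone_mask` from [partition_zones()].
#' @return The bundle table with `zone` filled in for accepted bundles.
#' @export
assign_zones <- function(bundles, zones) {
  if (nrow(bundles) == 0) return(bundles)
  s <- zones$provenance$pixel_size_um
  r <- pmin(pmax(round(bundles$y_um / s) + 1, 1), nrow(zones$labels))
  cc <- pmin(pmax(round(bundles$x_um / s) + 1, 1), ncol(zones$labels))
  z <- zones$labels[cbind(r, cc)]
  if (any(z == 0L & bundles$accepted))
    stop("orphan bundle: accepted centroid outside the stem")
  n_ez <- sum(z == 1L & bundles$accepted)
  if (n_ez > 0)
    message(n_ez, " bundle centroid(s) in the epidermis band reassigned to PZ")
  zl <- c(NA, "PZ", "PZ", "IZ")[z + 1]
  bundles$zone <- ifelse(bundles$accepted, zl, NA_character_)
  bundles
}

#' Full segmentation of one cross-section image
#'
#' Convenience wrapper chaining [segment_stem()], [partition_zones()],
#' [detect_vb_candidates()], [filter_candidates()] and [assign_zones()].
#'
#' @inheritParams segment_stem
#' @return A list with `stem_mask`, `zones`, `bundles` and `candidates`.
#' @export
segment_section <- function(image, pixel_size_um, config = seg_config()) {
  stem <- segment_stem(image, pixel_size_um, config)
  zones <- partition_zones(stem, pixel_size_um, config)
  cand <- detect_vb_candidates(image, stem, pixel_size_um, config)
  bundles <- filter_candidates(cand, image, stem, pixel_size_um, config)
  bundles <- assign_zones(bundles, zones)
  list(stem_mask = stem, zones = zones, bundles = bundles, candidates = cand)
}
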