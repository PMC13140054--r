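#' Read and write section images and pipeline tables
#'
#' Images are 8-bit grayscale PNG; the truth sidecar is JSON (one per image)
#' holding the generating spec and ground truth; bundle and trait tables are
#' CSV with fixed column layouts.
#'
#' @param image integer matrix of grey values 0-255 (rows = y).
#' @param path file path.
#' @name section_io
NULL

#' @rdname section_io
#' @export
write_section_image <- function(image, path) {
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' @rdname section_io
#' @return `read_section_image()`: integer matrix 0-255.
#' @export
read_section_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  m <- round(x * 255)
  storage.mode(m) <- "integer"
  m
}

#' @rdname section_io
#' @param sim a `section_sim` from [simulate_cross_section()].
#' @export
write_truth_json <- function(sim, path) {
  spec <- unclass(sim$spec)
  truth <- sim$truth
  truth$zone_raster <- NULL  # raster lives in the image domain, not the sidecar
  jsonlite::write_json(list(spec = spec, truth = truth), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname section_io
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$spec$intensity <- unlist(x$spec$intensity)
  class(x$spec) <- "section_spec"
  x
}

#' @rdname section_io
#' @param bundles bundle table from [filter_candidates()] / [assign_zones()].
#' @export
write_bundle_csv <- function(bundles, path) {
  out <- data.frame(id = bundles$id,
                    centroid_x_um = bundles$x_um,
                    centroid_y_um = bundles$y_um,
                    area_um2 = bundles$area_um2,
                    zone = bundles$zone,
                    eccentricity = bundles$eccentricity,
                    solidity = bundles$solidity,
                    mean_intensity = bundles$mean_intensity,
                    accepted = bundles$accepted,
                    reject_reason = bundles$reject_reason)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname section_io
#' @export
read_bundle_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  data.frame(id = x$id, x_um = x$centroid_x_um, y_um = x$centroid_y_um,
             area_um2 = x$area_um2, zone = x$zone,
             eccentricity = x$eccentricity, solidity = x$solidity,
             mean_intensity = x$mean_intensity, accepted = x$accepted,
             reject_reason = x$reject_reason, stringsAsFactors = FALSE)
}

#' @rdname section_io
#' @param zones a `zone_mask` from [partition_zones()].
#' @export
write_zone_png <- function(zones, path) {
  png::writePNG(zones$labels / 3, target = path)
  invisible(path)
}

#' @rdname section_io
#' @param pixel_size_um pixel size recorded with the zone raster.
#' @export
read_zone_png <- function(path, pixel_size_um,
                          ez_thickness_um = NA, pz_thickness_um = NA) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  labels <- round(x * 3)
  storage.mode(labels) <- "integer"
  depth <- as.matrix(EBImage::distmap(EBImage::Image((labels > 0) * 1)))
  structure(list(labels = labels, depth_px = depth,
                 provenance = list(ez_thickness_um = ez_thickness_um,
                                   pz_thickness_um = pz_thickness_um,
                                   pixel_size_um = pixel_size_um)),
            class = "zone_mask")
}

#' @rdname section_io
#' @param traits named trait vector or data frame of trait rows.
#' @param sample_id,slice_index identifiers written before the trait columns.
#' @export
write_traits_csv <- function(traits, path, sample_id = "sample",
                             slice_index = NA) {
  if (is.numeric(traits)) traits <- as.data.frame(t(traits))
  out <- cbind(data.frame(sample_id = sample_id, slice_index = slice_index),
               traits[, trait_names(), drop = FALSE])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
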