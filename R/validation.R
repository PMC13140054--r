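#' Match detected bundles to simulation ground truth
#'
#' Greedy one-to-one matching: candidate pairs are all (true bundle, accepted
#' detection) whose centroid distance is at most the true bundle radius,
#' taken in increasing distance order. Recall = matched / true; precision =
#' matched / detected.
#'
#' @param bundles detected bundle table (accepted rows are matched).
#' @param truth ground truth from [simulate_cross_section()].
#' @return List with `matches` (data frame `truth_id, det_id, dist_um,
#'   true_area_um2, det_area_um2, true_zone, det_zone`), `recall`,
#'   `precision`, `n_true`, `n_detected`.
#' @export
match_to_truth <- function(bundles, truth) {
  tb <- truth$bundles
  db <- bundles[bundles$accepted %in% TRUE, , drop = FALSE]
  n_true <- nrow(tb); n_det <- nrow(db)
  if (n_true == 0 || n_det == 0) {
    return(list(matches = data.frame(), recall = as.numeric(n_true == 0),
                precision = as.numeric(n_det == 0),
                n_true = n_true, n_detected = n_det))
  }
  dd <- outer(tb$x_um, db$x_um, `-`)^2 + outer(tb$y_um, db$y_um, `-`)^2
  dd <- sqrt(dd)
  ok <- dd <= tb$radius_um  # recycled by column: radius per truth row
  cand <- which(ok, arr.ind = TRUE)
  if (nrow(cand)) cand <- cand[order(dd[cand]), , drop = FALSE]
  used_t <- logical(n_true); used_d <- logical(n_det)
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    ti <- cand[i, 1]; di <- cand[i, 2]
    if (used_t[ti] || used_d[di]) next
    used_t[ti] <- TRUE; used_d[di] <- TRUE
    rows[[length(rows) + 1]] <- data.frame(
      truth_id = tb$id[ti], det_id = db$id[di], dist_um = dd[ti, di],
      true_area_um2 = tb$area_um2[ti], det_area_um2 = db$area_um2[di],
      true_zone = tb$zone[ti], det_zone = db$zone[di])
  }
  matches <- if (length(rows)) do.call(rbind, rows) else data.frame()
  list(matches = matches,
       recall = nrow(matches) / n_true,
       precision = nrow(matches) / n_det,
       n_true = n_true, n_detected = n_det)
}

#' End-to-end validation of the image pipeline against simulator truth
#'
#' For each seed: simulate a section, segment it, match detections to truth,
#' and compare the image-derived 32-trait vector with the analytic
#' [truth_traits()]. Used by the package's acceptance checks.
#'
#' @param seeds integer seeds, one section each.
#' @param base_spec a [section_spec()]; its seed is replaced per section.
#' @param config a [seg_config()].
#' @param axis an [axis_convention()].
#' @return List with `per_section` (seed, n_true, n_detected, recall,
#'   precision, zone_match rate), `areas` (matched true/detected areas,
#'   pooled), `area_r2` (squared correlation of matched areas),
#'   `trait_rel_err` (matrix: sections x 32, |measured - truth| / truth).
#' @export
validate_pipeline <- function(seeds = 1:20, base_spec = section_spec(),
                              config = seg_config(),
                              axis = axis_convention()) {
  per <- list(); areas <- list(); errs <- list()
  for (sd in seeds) {
    spec <- base_spec
    spec$seed <- as.integer(sd)
    sim <- simulate_cross_section(spec)
    seg <- suppressMessages(
      segment_section(sim$image, spec$pixel_size_um, config))
    m <- match_to_truth(seg$bundles, sim$truth)
    zone_match <- if (nrow(m$matches))
      mean(m$matches$true_zone == m$matches$det_zone) else NA_real_
    per[[length(per) + 1]] <- data.frame(
      seed = sd, n_true = m$n_true, n_detected = m$n_detected,
      recall = m$recall, precision = m$precision, zone_match = zone_match)
    areas[[length(areas) + 1]] <-
      m$matches[, c("true_area_um2", "det_area_um2")]
    tv <- compute_section_traits(seg$zones, seg$bundles,
                                 spec$pixel_size_um, axis)
    tt <- truth_traits(sim$truth, spec, axis)
    errs[[length(errs) + 1]] <- abs(tv - tt) / abs(tt)
  }
  areas <- do.call(rbind, areas)
  list(per_section = do.call(rbind, per),
       areas = areas,
       area_r2 = cor(areas$true_area_um2, areas$det_area_um2)^2,
       trait_rel_err = do.call(rbind, errs))
}
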