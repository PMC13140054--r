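test_that("segment_stem rejects empty images and recovers the ellipse area", {
  expect_error(segment_stem(matrix(0L, 100, 100), 15), "no stem found")

  sim <- small_sim(7)
  mask <- segment_stem(sim$image, 15)
  analytic <- pi * prod(sim$spec$semi_axes_um) / 1e6
  expect_lt(abs(sum(mask) * 15^2 / 1e6 - analytic) / analytic, 0.02)
  # single component, no holes
  lab <- EBImage::bwlabel(mask * 1)
  expect_equal(max(lab), 1)
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  expect_equal(sum(as.matrix(filled) > 0), sum(mask))
})

test_that("zone partition conserves pixels and handles zero-thickness EZ", {
  sim <- small_sim(7)
  mask <- segment_stem(sim$image, 15)
  z <- partition_zones(mask, 15, seg_config(pz_thickness_um = 1000))
  counts <- table(factor(z$labels[z$labels > 0], levels = 1:3))
  expect_equal(sum(counts), sum(mask))

  z0 <- partition_zones(mask, 15, seg_config(ez_thickness_um = 0,
                                             pz_thickness_um = 1000))
  expect_equal(sum(z0$labels == 1L), 0)
  expect_equal(sum(z0$labels > 1L), sum(mask))

  expect_error(partition_zones(mask, 15,
                               seg_config(ez_thickness_um = 2000,
                                          pz_thickness_um = 2000)),
               "degenerate zones")
})

test_that("zone labels agree with simulator truth on >= 97% of stem pixels", {
  sim <- small_sim(7)
  seg <- small_seg(7)
  truth_z <- sim$truth$zone_raster
  both <- truth_z > 0 & seg$zones$labels > 0
  agree <- mean(truth_z[both] == seg$zones$labels[both])
  expect_gte(agree, 0.97)
})

test_that("a uniform-intensity stem yields no candidates", {
  sp <- small_spec(1, n_pz_bundles = 0, n_iz_bundles = 0, noise_sigma = 0,
                   blur_sigma = 0,
                   intensity = c(background = 20, tissue = 100,
                                 epidermis = 100, bundle = 100))
  sim <- simulate_cross_section(sp)
  mask <- segment_stem(sim$image, 15)
  cand <- detect_vb_candidates(sim$image, mask, 15,
                               seg_config(pz_thickness_um = 1000))
  expect_equal(max(cand), 0)
})

test_that("two disks separated by >= 3 blur sigma give two labels", {
  sp <- small_spec(1, n_pz_bundles = 0, n_iz_bundles = 0)
  zr <- stemCT:::zone_raster(sp)
  ctr <- sp$center_um
  bundles <- data.frame(id = 1:2,
                        x_um = ctr[1] + c(-300, 300), y_um = rep(ctr[2], 2),
                        radius_um = c(150, 150), zone = "IZ")
  img <- stemCT:::with_seed(1, stemCT:::render_section(sp, bundles, zr))
  mask <- segment_stem(img, 15)
  cfg <- seg_config(pz_thickness_um = 1000)
  cand <- detect_vb_candidates(img, mask, 15, cfg)
  tab <- filter_candidates(cand, img, mask, 15, cfg)
  expect_equal(sum(tab$accepted), 2)
})

test_that("filter_candidates rejects specks and accepts rendered disks", {
  # a 1-px candidate on a flat background is rejected for area
  img <- matrix(100L, 80, 80)
  img[40, 40] <- 200L
  cand <- matrix(0L, 80, 80); cand[40, 40] <- 1L
  mask <- matrix(TRUE, 80, 80)
  tab <- filter_candidates(cand, img, mask, 15, seg_config())
  expect_false(tab$accepted[1])
  expect_match(tab$reject_reason[1], "area")

  # a clean rendered disk passes with near-ideal shape scores
  img2 <- matrix(100, 120, 120)
  xy <- expand.grid(r = 1:120, c = 1:120)
  disk <- (xy$r - 60)^2 + (xy$c - 60)^2 <= 14^2
  img2[cbind(xy$r[disk], xy$c[disk])] <- 190
  cand2 <- matrix(0L, 120, 120)
  cand2[cbind(xy$r[disk], xy$c[disk])] <- 1L
  tab2 <- filter_candidates(cand2, img2, matrix(TRUE, 120, 120), 15,
                            seg_config())
  expect_true(tab2$accepted[1])
  expect_gte(tab2$solidity[1], 0.95)
  expect_lte(tab2$eccentricity[1], 0.3)
})

test_that("detection on synthetic sections finds at least the true bundles", {
  sim <- small_sim(7)
  seg <- small_seg(7)
  expect_gte(max(seg$candidates), nrow(sim$truth$bundles))
  m <- match_to_truth(seg$bundles, sim$truth)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("zone assignment follows the centroid rule", {
  seg <- small_seg(7)
  zones <- seg$zones
  s <- zones$provenance$pixel_size_um
  ctr_px <- dim(zones$labels) / 2
  mk <- function(x_um, y_um) {
    data.frame(id = 1L, x_um = x_um, y_um = y_um, area_um2 = 1e4,
               zone = NA_character_, eccentricity = 0.1, solidity = 1,
               mean_intensity = 180, accepted = TRUE, reject_reason = "")
  }
  ctr <- mk((ctr_px[2] - 1) * s, (ctr_px[1] - 1) * s)
  expect_equal(assign_zones(ctr, zones)$zone, "IZ")

  # a centroid just inside the EZ ring is reassigned to PZ with a message
  row_mid <- round(ctr_px[1])
  ez_cols <- which(zones$labels[row_mid, ] == 1L)
  ez <- mk((ez_cols[2] - 1) * s, (row_mid - 1) * s)
  expect_message(z <- assign_zones(ez, zones), "reassigned")
  expect_equal(z$zone, "PZ")

  orphan <- mk(0, 0)
  expect_error(assign_zones(orphan, zones), "orphan")
})

test_that("whole-pixel translation shifts centroids exactly and preserves areas", {
  sp <- small_spec(9)
  sim <- simulate_cross_section(sp)
  di <- 7L; dj <- 4L
  img2 <- matrix(sp$intensity[["background"]], nrow(sim$image), ncol(sim$image))
  img2[(1 + di):nrow(img2), (1 + dj):ncol(img2)] <-
    sim$image[1:(nrow(img2) - di), 1:(ncol(img2) - dj)]
  storage.mode(img2) <- "integer"
  cfg <- seg_config(pz_thickness_um = 1000)
  s1 <- suppressMessages(segment_section(sim$image, 15, cfg))
  s2 <- suppressMessages(segment_section(img2, 15, cfg))
  b1 <- s1$bundles[s1$bundles$accepted, ]
  b2 <- s2$bundles[s2$bundles$accepted, ]
  expect_equal(nrow(b1), nrow(b2))
  o1 <- order(b1$y_um, b1$x_um); o2 <- order(b2$y_um, b2$x_um)
  expect_equal(b2$x_um[o2] - b1$x_um[o1], rep(dj * 15, nrow(b1)))
  expect_equal(b2$y_um[o2] - b1$y_um[o1], rep(di * 15, nrow(b1)))
  expect_equal(b1$area_um2[o1], b2$area_um2[o2])
})
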