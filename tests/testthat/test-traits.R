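test_that("moment of area matches hand arithmetic and symmetry", {
  one <- data.frame(x_um = 0, y_um = 2000, area_um2 = 1e6, accepted = TRUE)
  expect_equal(compute_moa(one, c(0, 0)), 4)  # 1 mm^2 at 2 mm -> 4 mm^4

  pair <- data.frame(x_um = c(0, 0), y_um = c(2000, -2000),
                     area_um2 = c(1e6, 1e6))
  expect_equal(compute_moa(pair, c(0, 0)), 2 * compute_moa(one, c(0, 0)))

  expect_warning(res <- compute_moa(one[0, ], c(0, 0)), "empty")
  expect_equal(res, 0)
})

test_that("polar moment matches hand arithmetic and the centroid null case", {
  b <- data.frame(x_um = 3000, y_um = 0, area_um2 = 2e6)
  pm <- compute_pmoi_moia(b, c(0, 0))
  expect_equal(unname(pm["PMOI"]), 18)  # 2 mm^2 at 3 mm -> 18 mm^4

  at_ctr <- data.frame(x_um = 500, y_um = 700, area_um2 = 1e6)
  pm0 <- compute_pmoi_moia(at_ctr, c(500, 700))
  expect_equal(unname(pm0), c(0, 0, 0))
})

test_that("moments agree with an explicit-loop oracle to 1e-12 relative", {
  set.seed(42)
  tb <- random_bundle_table(200, center_um = c(9000, 8000))
  ctr <- c(9000, 8000)
  moa <- compute_moa(tb, ctr)                      # horizontal neutral axis
  pm <- compute_pmoi_moia(tb, ctr)
  # independent brute force, one bundle at a time
  moa_o <- 0; pmoi_o <- 0; moial_o <- 0; moias_o <- 0
  for (i in seq_len(nrow(tb))) {
    A <- tb$area_um2[i] / 1e6
    dx <- (tb$x_um[i] - ctr[1]) / 1000
    dy <- (tb$y_um[i] - ctr[2]) / 1000
    moa_o <- moa_o + A * dy^2
    pmoi_o <- pmoi_o + A * (dx^2 + dy^2)
    moial_o <- moial_o + A * dy^2
    moias_o <- moias_o + A * dx^2
  }
  expect_lt(abs(moa - moa_o) / moa_o, 1e-12)
  expect_lt(abs(pm[["PMOI"]] - pmoi_o) / pmoi_o, 1e-12)
  expect_lt(abs(pm[["MOIAL"]] - moial_o) / moial_o, 1e-12)
  expect_lt(abs(pm[["MOIAS"]] - moias_o) / moias_o, 1e-12)
  # perpendicular-axis identity
  expect_lt(abs(pm[["PMOI"]] - pm[["MOIAL"]] - pm[["MOIAS"]]) / pm[["PMOI"]],
            1e-9)
})

test_that("PMOI is rotation invariant; MOA about the long axis equals MOIAL", {
  set.seed(7)
  tb <- random_bundle_table(80)
  pm0 <- compute_pmoi_moia(tb, c(0, 0), long_axis_dir = c(1, 0))
  for (ang in c(0.3, 1.1, 2.5)) {
    Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    rb <- tb
    xy <- as.matrix(tb[, c("x_um", "y_um")]) %*% t(Rm)
    rb$x_um <- xy[, 1]; rb$y_um <- xy[, 2]
    pm1 <- compute_pmoi_moia(rb, c(0, 0), long_axis_dir = Rm %*% c(1, 0))
    expect_lt(abs(pm1[["PMOI"]] - pm0[["PMOI"]]) / pm0[["PMOI"]], 1e-6)
  }
  moa_long <- compute_moa(tb, c(0, 0), axis_dir = c(1, 0))
  expect_equal(moa_long, unname(pm0["MOIAL"]))
})

test_that("truth traits honour the single-bundle arithmetic of the oracle", {
  sp <- small_spec(1, n_pz_bundles = 0, n_iz_bundles = 0)
  truth <- list(bundles = data.frame(id = 1L,
                                     x_um = sp$center_um[1],
                                     y_um = sp$center_um[2] + 2000,
                                     radius_um = sqrt(1e6 / pi),
                                     area_um2 = 1e6, zone = "IZ"),
                center_um = sp$center_um,
                semi_axes_um = sp$semi_axes_um, seed = 1L)
  tv <- truth_traits(truth, sp)
  expect_equal(unname(tv["MOA"]), 4)
  expect_equal(unname(tv["VB_N"]), 1)
  # zone areas telescope to the full ellipse area
  expect_equal(unname(tv["EZ_A"] + tv["PZ_A"] + tv["IZ_A"]),
               unname(tv["SZ_A"]))
})

test_that("section traits recover truth and respect pixel-size scaling", {
  sim <- small_sim(7)
  seg <- small_seg(7)
  tv <- compute_section_traits(seg$zones, seg$bundles, 15)
  tt <- truth_traits(sim$truth, sim$spec)
  mech <- c("MOA", "PMOI", "MOIAL", "MOIAS",
            "aveMOA", "avePMOI", "aveMOIAL", "aveMOIAS")
  rel <- abs(tv - tt) / abs(tt)
  expect_lt(max(rel[setdiff(names(rel), mech)]), 0.05)
  expect_lt(max(rel[mech]), 0.07)

  # dimensional analysis: doubling the pixel size doubles lengths, quadruples
  # areas, scales moments by 16, leaves counts and ratios unchanged
  b2 <- seg$bundles
  b2$x_um <- b2$x_um * 2; b2$y_um <- b2$y_um * 2; b2$area_um2 <- b2$area_um2 * 4
  z2 <- seg$zones
  z2$provenance$pixel_size_um <- 30
  tv2 <- compute_section_traits(z2, b2, 30)
  areas <- c("SZ_A", "EZ_A", "PZ_A", "IZ_A", "VB_A", "VB_Aave",
             "PZ_VB_A", "IZ_VB_A")
  lengths <- c("SZ_P", "SZ_LA", "SZ_SA", "EZ_T", "PZ_T", "IZ_T")
  unitless <- c("SZ_LWR", "VB_N", "PZ_VB_N", "IZ_VB_N", "VB_AreaRatio",
                "PZ_VB_AreaRatio", "IZ_VB_AreaRatio")
  expect_equal(tv2[areas], tv[areas] * 4, tolerance = 1e-9)
  expect_equal(tv2[lengths], tv[lengths] * 2, tolerance = 1e-9)
  expect_equal(tv2[unitless], tv[unitless], tolerance = 1e-9)
  expect_equal(tv2[mech], tv[mech] * 16, tolerance = 1e-9)
})

test_that("zone-restricted bundle populations produce zero inner-zone traits", {
  seg <- small_seg(7)
  b <- seg$bundles[seg$bundles$accepted & seg$bundles$zone == "PZ", ]
  tv <- compute_section_traits(seg$zones, b, 15)
  expect_equal(unname(tv["IZ_VB_N"]), 0)
  expect_equal(unname(tv["IZ_VB_AreaRatio"]), 0)

  none <- seg$bundles[0, ]
  tv0 <- compute_section_traits(seg$zones, none, 15)
  expect_equal(unname(tv0["VB_N"]), 0)
  expect_true(all(is.na(tv0[c("VB_Aave", "aveMOA", "avePMOI",
                              "aveMOIAL", "aveMOIAS")])))
})

test_that("slice aggregation is a median with robustness to outliers", {
  seg <- small_seg(7)
  tv <- compute_section_traits(seg$zones, seg$bundles, 15)
  slices <- as.data.frame(rbind(tv, tv, tv))
  agg <- aggregate_slices(slices)
  expect_equal(agg$aggregate, tv)
  expect_equal(agg$n_slices, 3)

  out <- tv; out["SZ_A"] <- out["SZ_A"] * 100
  eleven <- as.data.frame(rbind(matrix(rep(tv, 10), 10, byrow = TRUE,
                                       dimnames = list(NULL, names(tv))),
                                out))
  agg11 <- aggregate_slices(eleven)
  expect_equal(unname(agg11$aggregate["SZ_A"]), unname(tv["SZ_A"]))

  expect_error(aggregate_slices(slices[0, ]), "no slices")
})

test_that("an i.i.d. slice ensemble aggregates near the distribution median", {
  set.seed(31)
  n <- 101
  base <- compute_section_traits(small_seg(7)$zones, small_seg(7)$bundles, 15)
  m <- matrix(rep(base, n), n, byrow = TRUE,
              dimnames = list(NULL, names(base)))
  m[, "SZ_A"] <- rnorm(n, mean = 200, sd = 5)
  agg <- aggregate_slices(as.data.frame(m))
  se_median <- 1.2533 * 5 / sqrt(n)
  expect_lt(abs(agg$aggregate[["SZ_A"]] - 200), 3 * se_median)
})
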