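test_that("simulation is deterministic under the spec seed", {
  s1 <- simulate_cross_section(small_spec(3))
  s2 <- simulate_cross_section(small_spec(3))
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth$bundles, s2$truth$bundles)
})

test_that("a bundle-free spec renders only the zone rings", {
  sp <- small_spec(2, n_pz_bundles = 0, n_iz_bundles = 0)
  sim <- simulate_cross_section(sp)
  expect_equal(nrow(sim$truth$bundles), 0)
  # no pixel should sit near the bundle grey level deep inside the stem
  lv <- sp$intensity
  inner <- sim$truth$zone_raster == 3L
  expect_lt(max(sim$image[inner]), (lv[["bundle"]] + lv[["tissue"]]) / 2)
})

test_that("invalid geometry and unplaceable requests raise errors", {
  expect_error(small_spec(1, ez_thickness_um = 1500, pz_thickness_um = 1200),
               "invalid geometry")
  expect_error(section_spec(semi_axes_um = c(100, 200)), "a >= b")
  # far too many bundles for the available band
  sp <- small_spec(1, n_iz_bundles = 2000, max_attempts = 200)
  expect_error(simulate_cross_section(sp), "unplaceable")
})

test_that("every placed disk lies inside its zone band (brute-force check)", {
  sp <- small_spec(7, n_pz_bundles = 20, n_iz_bundles = 8)
  sim <- simulate_cross_section(sp)
  tb <- sim$truth$bundles
  expect_equal(nrow(tb), 28)
  a <- sp$semi_axes_um[1]; b <- sp$semi_axes_um[2]
  d1 <- sp$ez_thickness_um; d2 <- d1 + sp$pz_thickness_um
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  for (i in seq_len(nrow(tb))) {
    # sample the disk boundary and check its depth band via an independent
    # dense-sampling distance to the outer ellipse
    px <- tb$x_um[i] + tb$radius_um[i] * cos(th) - sim$truth$center_um[1]
    py <- tb$y_um[i] + tb$radius_um[i] * sin(th) - sim$truth$center_um[2]
    stopifnot(all((px / a)^2 + (py / b)^2 < 1))
    depths <- mapply(function(x, y) brute_dist_ellipse(a, b, x, y, n = 4000),
                     px, py)
    if (tb$zone[i] == "PZ") {
      expect_true(all(depths > d1) && all(depths < d2))
    } else {
      expect_true(all(depths > d2))
    }
  }
  # pairwise separation and disk areas
  dd <- as.matrix(dist(tb[, c("x_um", "y_um")]))
  diag(dd) <- Inf
  expect_gte(min(dd), sp$min_separation_um)
  expect_equal(tb$area_um2, pi * tb$radius_um^2)
})

test_that("rendered disk pixel counts match analytic areas within 5%", {
  sp <- small_spec(5, noise_sigma = 0, blur_sigma = 0)
  sim <- simulate_cross_section(sp)
  s <- sp$pixel_size_um
  lv <- sp$intensity
  tb <- sim$truth$bundles
  tb <- tb[tb$radius_um >= 5 * s, , drop = FALSE]
  expect_gt(nrow(tb), 5)
  for (i in seq_len(nrow(tb))) {
    jj <- round(tb$x_um[i] / s) + 1; ii <- round(tb$y_um[i] / s) + 1
    w <- ceiling(tb$radius_um[i] / s) + 2
    sub <- sim$image[(ii - w):(ii + w), (jj - w):(jj + w)]
    n_px <- sum(sub == lv[["bundle"]])
    expect_lt(abs(n_px * s^2 - tb$area_um2[i]) / tb$area_um2[i], 0.05)
  }
})

test_that("phenotype simulator honours degenerate variance settings", {
  tab <- simulate_phenotypes(20, 2, 3, mu = 5, Vg = 0, V_env = 0, V_GL = 0,
                             V_rep = 0, Ve = 0, seed = 1)
  expect_equal(nrow(tab), 20 * 2 * 3)
  expect_true(all(tab$value == 5))
  expect_identical(tab, simulate_phenotypes(20, 2, 3, mu = 5, Vg = 0,
                                            V_env = 0, V_GL = 0, V_rep = 0,
                                            Ve = 0, seed = 1))
})

test_that("line-only variance reproduces the genetic variance at scale", {
  n <- 5000
  tab <- simulate_phenotypes(n, 1, 3, mu = 0, Vg = 2, Ve = 0, seed = 11)
  # within-line variance must vanish; between-line variance ~ Vg
  within_var <- tapply(tab$value, tab$line, var)
  expect_equal(max(within_var), 0)
  v <- var(tapply(tab$value, tab$line, mean))
  se <- sqrt(2 / (n - 1)) * 2  # SE of a sample variance of N(0, 2)
  expect_lt(abs(v - 2), 3 * se)
})

test_that("moment estimates from a large simulation recover the generating variances", {
  G <- 5000; L <- 2; R <- 3
  truth <- c(Vg = 2, V_env = 1, V_GL = 0.5, V_rep = 0.2, Ve = 1)
  tab <- simulate_phenotypes(G, L, R, mu = 10, Vg = truth[["Vg"]],
                             V_env = truth[["V_env"]], V_GL = truth[["V_GL"]],
                             V_rep = truth[["V_rep"]], Ve = truth[["Ve"]],
                             seed = 4)
  est <- vc_moments(tab)
  # 3-SE bands from the chi-square variance of the underlying mean squares
  ems <- c(line = truth[["Ve"]] + R * truth[["V_GL"]] + L * R * truth[["Vg"]],
           gl = truth[["Ve"]] + R * truth[["V_GL"]],
           err = truth[["Ve"]])
  sd_ms <- function(ms, df) ms * sqrt(2 / df)
  se_vg <- sqrt(sd_ms(ems[["line"]], G - 1)^2 + sd_ms(ems[["gl"]], (G - 1) * (L - 1))^2) / (L * R)
  se_gl <- sqrt(sd_ms(ems[["gl"]], (G - 1) * (L - 1))^2 +
                  sd_ms(ems[["err"]], (G - 1) * L * (R - 1))^2) / R
  se_ve <- sd_ms(ems[["err"]], (G - 1) * L * (R - 1))
  expect_lt(abs(est[["Vg"]] - 2), 3 * se_vg)
  expect_lt(abs(est[["V_GL"]] - 0.5), 3 * se_gl)
  expect_lt(abs(est[["Ve"]] - 1), 3 * se_ve)
})

test_that("bending-curve simulator peaks exactly at (d_peak, f_max)", {
  cv <- simulate_bending_curve(120, 15, seed = 2)
  expect_equal(max(cv$load_N), 120)
  expect_equal(cv$displacement_mm[which.max(cv$load_N)], 15)
  expect_true(attr(cv, "spans_10mm"))
  expect_true(any(cv$displacement_mm == 10))

  short <- simulate_bending_curve(100, 8, d_end = 9, seed = 2)
  expect_false(attr(short, "spans_10mm"))
  expect_true(all(short$displacement_mm < 10))
})
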