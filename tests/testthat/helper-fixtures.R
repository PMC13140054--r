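# Shared fixtures: a small, fast section spec for unit tests, and a cache so
# repeated tests reuse the same simulation/segmentation.

small_spec <- function(seed = 1, ...) {
  args <- list(image_shape = c(420, 420),
               pixel_size_um = 15,
               semi_axes_um = c(2900, 2500),
               ez_thickness_um = 240,
               pz_thickness_um = 1000,
               n_pz_bundles = 16,
               n_iz_bundles = 6,
               pz_radius_um = c(110, 0.12),
               iz_radius_um = c(180, 0.12),
               min_separation_um = 420,
               seed = seed)
  over <- list(...)
  do.call(section_spec, utils::modifyList(args, over))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_sim <- function(seed = 1) {
  cached(paste0("sim", seed), simulate_cross_section(small_spec(seed)))
}

small_seg <- function(seed = 1) {
  cached(paste0("seg", seed), {
    sim <- small_sim(seed)
    cfg <- seg_config(pz_thickness_um = 1000)
    suppressMessages(segment_section(sim$image, sim$spec$pixel_size_um, cfg))
  })
}

# Random bundle table in um units around a given centre (mm-scale section)
random_bundle_table <- function(n, center_um = c(0, 0), rmax_um = 8000) {
  r <- runif(n, 0, rmax_um)
  th <- runif(n, 0, 2 * pi)
  data.frame(id = seq_len(n),
             x_um = center_um[1] + r * cos(th),
             y_um = center_um[2] + r * sin(th),
             area_um2 = runif(n, 1e4, 2e5),
             zone = sample(c("PZ", "IZ"), n, replace = TRUE),
             accepted = TRUE,
             stringsAsFactors = FALSE)
}

# Brute-force distance from a point to an ellipse boundary: dense sampling of
# the boundary, independent of the Newton solver used by the package.
brute_dist_ellipse <- function(a, b, x, y, n = 20000) {
  th <- seq(0, 2 * pi, length.out = n)
  min(sqrt((a * cos(th) - x)^2 + (b * sin(th) - y)^2))
}
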