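#' The 32 microanatomical traits
#'
#' Canonical names and ordering of the trait vector computed per section.
#' Prefixes: `SZ` stem cross-section, `EZ`/`PZ`/`IZ` epidermis/periphery/inner
#' zone, `VB` vascular bundle. Suffixes: `_A` area (mm^2), `_P` perimeter
#' (mm), `_LA`/`_SA` long/short axis length (mm), `_LWR` length-width ratio,
#' `_T` zone thickness (mm), `_N` count, `_Aave` mean bundle area (mm^2),
#' `_D` bundle density (mm^-2), `_AreaRatio` bundle area fraction of the
#' carrying region. `MOA` is the moment of area about the neutral axis,
#' `PMOI` the polar moment of inertia, `MOIAL`/`MOIAS` its components about
#' the long/short principal axes (all mm^4); `ave*` are the same moments per
#' bundle (divided by `VB_N`).
#'
#' @return Character vector of the 32 trait names in canonical order.
#' @export
trait_names <- function() {
  c("SZ_A", "SZ_P", "SZ_LA", "SZ_SA", "SZ_LWR",
    "EZ_A", "EZ_T", "PZ_A", "PZ_T", "IZ_A", "IZ_T",
    "VB_N", "VB_A", "VB_Aave", "VB_D", "VB_AreaRatio",
    "PZ_VB_N", "PZ_VB_A", "PZ_VB_D", "PZ_VB_AreaRatio",
    "IZ_VB_N", "IZ_VB_A", "IZ_VB_D", "IZ_VB_AreaRatio",
    "MOA", "PMOI", "MOIAL", "MOIAS",
    "aveMOA", "avePMOI", "aveMOIAL", "aveMOIAS")
}

# Assemble the canonical trait vector from measured components. All inputs in
# mm-based units except the bundle table (um, per the internal unit policy).
# stem: list(area_mm2, perimeter_mm, long_axis_mm, short_axis_mm,
#            center_um, long_axis_dir)
# zones_mm: list(EZ_A, EZ_T, PZ_A, PZ_T, IZ_A, IZ_T)
assemble_traits <- function(stem, zones_mm, bundles, axis) {
  acc <- bundles[isTRUE_col(bundles$accepted), , drop = FALSE]
  n_pz <- sum(acc$zone == "PZ"); n_iz <- sum(acc$zone == "IZ")
  a_pz <- sum(acc$area_um2[acc$zone == "PZ"]) / 1e6
  a_iz <- sum(acc$area_um2[acc$zone == "IZ"]) / 1e6
  n_vb <- n_pz + n_iz
  a_vb <- a_pz + a_iz
  nd <- neutral_axis_dir(axis, stem$long_axis_dir)
  if (n_vb > 0) {
    moa <- compute_moa(acc, stem$center_um, nd)
    pm  <- compute_pmoi_moia(acc, stem$center_um, stem$long_axis_dir)
  } else {
    moa <- 0
    pm <- c(PMOI = 0, MOIAL = 0, MOIAS = 0)
  }
  ave <- function(x) if (n_vb > 0) x / n_vb else NA_real_
  tv <- c(
    SZ_A = stem$area_mm2, SZ_P = stem$perimeter_mm,
    SZ_LA = stem$long_axis_mm, SZ_SA = stem$short_axis_mm,
    SZ_LWR = stem$long_axis_mm / stem$short_axis_mm,
    EZ_A = zones_mm$EZ_A, EZ_T = zones_mm$EZ_T,
    PZ_A = zones_mm$PZ_A, PZ_T = zones_mm$PZ_T,
    IZ_A = zones_mm$IZ_A, IZ_T = zones_mm$IZ_T,
    VB_N = n_vb, VB_A = a_vb, VB_Aave = ave(a_vb),
    VB_D = n_vb / stem$area_mm2, VB_AreaRatio = a_vb / stem$area_mm2,
    PZ_VB_N = n_pz, PZ_VB_A = a_pz,
    PZ_VB_D = n_pz / zones_mm$PZ_A, PZ_VB_AreaRatio = a_pz / zones_mm$PZ_A,
    IZ_VB_N = n_iz, IZ_VB_A = a_iz,
    IZ_VB_D = n_iz / zones_mm$IZ_A, IZ_VB_AreaRatio = a_iz / zones_mm$IZ_A,
    MOA = moa, PMOI = unname(pm["PMOI"]),
    MOIAL = unname(pm["MOIAL"]), MOIAS = unname(pm["MOIAS"]),
    aveMOA = ave(moa), avePMOI = ave(unname(pm["PMOI"])),
    aveMOIAL = ave(unname(pm["MOIAL"])), aveMOIAS = ave(unname(pm["MOIAS"])))
  tv <- tv[trait_names()]
  validate_trait_vector(tv)
  tv
}

isTRUE_col <- function(x) if (is.null(x)) TRUE else x %in% TRUE

#' Assert the internal-consistency invariants of a trait vector
#'
#' Checks additivity of counts and areas across zones, ratio ranges, the
#' perpendicular-axis identity `PMOI = MOIAL + MOIAS`, density and per-bundle
#' consistency (`VB_Aave * VB_N = VB_A`, `aveX * VB_N = X`), zone-area
#' conservation and non-negativity of all moments. Called automatically by
#' every trait computation; exported so pipelines can validate external trait
#' tables.
#'
#' @param tv named numeric vector with the names of [trait_names()].
#' @param tol_rel relative tolerance for the exact identities.
#' @return `tv`, invisibly; stops on the first violated invariant.
#' @export
validate_trait_vector <- function(tv, tol_rel = 1e-9) {
  stopifnot(identical(names(tv), trait_names()))
  rel_ok <- function(x, y) {
    s <- max(abs(x), abs(y), 1e-300)
    abs(x - y) <= tol_rel * s
  }
  chk <- function(cond, what) if (!isTRUE(cond)) stop("trait invariant violated: ", what)
  chk(rel_ok(tv[["VB_N"]], tv[["PZ_VB_N"]] + tv[["IZ_VB_N"]]), "VB_N additivity")
  chk(rel_ok(tv[["VB_A"]], tv[["PZ_VB_A"]] + tv[["IZ_VB_A"]]), "VB_A additivity")
  chk(rel_ok(tv[["EZ_A"]] + tv[["PZ_A"]] + tv[["IZ_A"]], tv[["SZ_A"]]),
      "zone area conservation")
  chk(rel_ok(tv[["VB_D"]] * tv[["SZ_A"]], tv[["VB_N"]]), "VB_D definition")
  chk(tv[["SZ_LWR"]] >= 1 - 1e-12, "SZ_LWR >= 1")
  ratios <- tv[c("VB_AreaRatio", "PZ_VB_AreaRatio", "IZ_VB_AreaRatio")]
  chk(all(ratios >= 0 & ratios <= 1), "area ratios in [0, 1]")
  moments <- tv[c("MOA", "PMOI", "MOIAL", "MOIAS")]
  chk(all(moments >= 0), "moments >= 0")
  chk(rel_ok(tv[["PMOI"]], tv[["MOIAL"]] + tv[["MOIAS"]]),
      "perpendicular-axis identity")
  if (tv[["VB_N"]] > 0) {
    chk(rel_ok(tv[["VB_Aave"]] * tv[["VB_N"]], tv[["VB_A"]]), "VB_Aave consistency")
    for (m in c("MOA", "PMOI", "MOIAL", "MOIAS"))
      chk(rel_ok(tv[[paste0("ave", m)]] * tv[["VB_N"]], tv[[m]]),
          paste0("ave", m, " consistency"))
  } else {
    chk(all(is.na(tv[c("VB_Aave", "aveMOA", "avePMOI", "aveMOIAL", "aveMOIAS")])),
        "ave traits missing when VB_N = 0")
  }
  invisible(tv)
}

#' Aggregate per-slice trait vectors to sample level
#'
#' A CT scan yields on the order of a hundred cross-section slices per stem
#' sample; the sample-level trait is the per-trait median across slices
#' (robust to occasional poorly segmented slices), reported together with the
#' mean, standard deviation and slice count.
#'
#' @param slices data frame of per-slice trait rows (columns =
#'   [trait_names()], one row per slice), or a matrix with those columns.
#' @return A list with `aggregate` (named median vector), `mean`, `sd` (named
#'   vectors) and `n_slices`.
#' @export
aggregate_slices <- function(slices) {
  slices <- as.data.frame(slices)
  if (nrow(slices) == 0) stop("no slices to aggregate")
  stopifnot(all(trait_names() %in% names(slices)))
  m <- as.matrix(slices[, trait_names(), drop = FALSE])
  list(aggregate = apply(m, 2, median, na.rm = TRUE),
       mean = colMeans(m, na.rm = TRUE),
       sd = apply(m, 2, sd, na.rm = TRUE),
       n_slices = nrow(slices))
}
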