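#' Bending moments from a three-point-bending load-displacement curve
#'
#' For a specimen on two supports loaded centrally, the bending moment under
#' the load is `F * L / 4` with `F` the applied load and `L` the support
#' span. `compute_bmmax()` evaluates it at the global maximum load;
#' `compute_bm10()` at the load reached at 10 mm crosshead displacement
#' (linear interpolation between the bracketing samples; the sample itself is
#' used when one falls exactly at 10 mm).
#'
#' @param curve data frame with columns `displacement_mm` and `load_N`.
#' @param span support span; `span_unit` selects metres or centimetres
#'   (spans are normalised to metres internally, output is always N m).
#' @param span_unit `"m"` or `"cm"`.
#' @return Bending moment in N m.
#' @export
#' @examples
#' cv <- data.frame(displacement_mm = c(0, 10, 15), load_N = c(0, 50, 120))
#' compute_bmmax(cv, 0.5)            # 120 * 0.5 / 4 = 15
#' compute_bm10(cv, 40, "cm")        # 50 * 0.4 / 4 = 5
compute_bmmax <- function(curve, span, span_unit = c("m", "cm")) {
  L <- normalize_span(span, span_unit)
  check_curve(curve)
  max(curve$load_N) * L / 4
}

#' @rdname compute_bmmax
#' @param at_mm displacement at which the load is read (default 10 mm).
#' @export
compute_bm10 <- function(curve, span, span_unit = c("m", "cm"), at_mm = 10) {
  L <- normalize_span(span, span_unit)
  check_curve(curve)
  load_at_displacement(curve, at_mm) * L / 4
}

#' @rdname compute_bmmax
#' @return `bending_record()`: a one-row data frame with `f_max_N`,
#'   `f_at_10mm_N`, `BMMax_Nm`, `BM10mm_Nm` (`f_at_10mm_N` and `BM10mm_Nm`
#'   are `NA` when the curve ends before 10 mm).
#' @export
bending_record <- function(curve, span, span_unit = c("m", "cm")) {
  L <- normalize_span(span, span_unit)
  check_curve(curve)
  f_max <- max(curve$load_N)
  f10 <- tryCatch(load_at_displacement(curve, 10), error = function(e) NA_real_)
  data.frame(f_max_N = f_max, f_at_10mm_N = f10,
             BMMax_Nm = f_max * L / 4, BM10mm_Nm = f10 * L / 4)
}

normalize_span <- function(span, span_unit = c("m", "cm")) {
  span_unit <- match.arg(span_unit)
  if (span <= 0) stop("span must be > 0")
  if (span_unit == "cm") span / 100 else span
}

check_curve <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("displacement_mm", "load_N") %in% names(curve)))
  if (nrow(curve) == 0) stop("empty load-displacement curve")
  if (any(curve$load_N < 0)) stop("negative loads in curve")
  invisible(curve)
}

load_at_displacement <- function(curve, at_mm) {
  d <- curve$displacement_mm
  if (max(d) < at_mm || min(d) > at_mm)
    stop("displacement not reached: curve does not span ", at_mm, " mm")
  exact <- which(d == at_mm)
  if (length(exact)) return(curve$load_N[exact[1]])
  approx(d, curve$load_N, xout = at_mm, ties = "ordered")$y
}

#' Simulate a three-point-bending load-displacement curve
#'
#' Synthetic fixture for the bending-moment calculations: a monotone concave
#' rise to `f_max` at displacement `d_peak`, followed by a post-failure decay.
#' The sample grid always contains `d_peak` exactly, and contains samples
#' bracketing 10 mm whenever the record extends that far; the attribute
#' `spans_10mm` flags whether it does. Optional Gaussian noise is applied to
#' the rising/decaying shape but never moves the global maximum off
#' (`d_peak`, `f_max`).
#'
#' @param f_max peak load, N.
#' @param d_peak displacement at peak load, mm.
#' @param n_points number of samples.
#' @param d_end end of the record, mm (default `1.4 * d_peak`).
#' @param noise_sd load noise, N.
#' @param seed integer seed.
#' @return Data frame `displacement_mm`, `load_N` with attribute
#'   `spans_10mm`.
#' @export
simulate_bending_curve <- function(f_max, d_peak, n_points = 200,
                                   d_end = 1.4 * d_peak, noise_sd = 0,
                                   seed = 1) {
  stopifnot(f_max > 0, d_peak > 0, d_end >= d_peak, n_points >= 5)
  with_seed(seed, {
    d <- sort(unique(c(seq(0, d_end, length.out = n_points), d_peak,
                       if (d_end >= 10) 10)))
    rise <- d <= d_peak
    load <- numeric(length(d))
    load[rise] <- f_max * sin(pi / 2 * d[rise] / d_peak)
    load[!rise] <- f_max * (0.4 + 0.6 * exp(-3 * (d[!rise] - d_peak) / d_peak))
    if (noise_sd > 0) {
      load <- load + rnorm(length(load), 0, noise_sd)
      load <- pmax(load, 0)
    }
    load[d == d_peak] <- f_max
    load[load > f_max] <- f_max * 0.999
    load[d == d_peak] <- f_max
    curve <- data.frame(displacement_mm = d, load_N = load)
    attr(curve, "spans_10mm") <- max(d) >= 10
    curve
  })
}
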