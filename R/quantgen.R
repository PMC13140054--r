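#' Simulate a balanced multi-environment phenotype table
#'
#' Draws observations from the random-effects model
#' `Y_ikm = mu + g_i + tau_k + (g tau)_ik + delta_(k)m + eps_ikm`,
#' with line effects `g_i ~ N(0, Vg)`, environment effects
#' `tau_k ~ N(0, V_env)`, line-by-environment interactions
#' `(g tau)_ik ~ N(0, V_GL)`, replicate-within-environment effects
#' `delta_(k)m ~ N(0, V_rep)` and residuals `eps ~ N(0, Ve)`, all mutually
#' independent. The table is balanced: every line is observed in every
#' environment and replicate.
#'
#' @param n_lines,n_envs,n_reps design dimensions (lines, environments L,
#'   replicates per environment R).
#' @param mu population mean, trait units.
#' @param Vg,V_env,V_GL,V_rep,Ve variance components, trait units squared.
#' @param trait trait name recorded in the table.
#' @param seed integer seed.
#' @return Long-format data frame `line, env, rep, trait, value` with the
#'   drawn effects attached as attribute `effects` (for recovery tests).
#' @export
simulate_phenotypes <- function(n_lines, n_envs = 2, n_reps = 3, mu = 0,
                                Vg = 1, V_env = 0, V_GL = 0, V_rep = 0,
                                Ve = 1, trait = "trait", seed = 1) {
  stopifnot(n_lines >= 1, n_envs >= 1, n_reps >= 1,
            Vg >= 0, V_env >= 0, V_GL >= 0, V_rep >= 0, Ve >= 0)
  with_seed(seed, {
    g <- rnorm(n_lines, 0, sqrt(Vg))
    tau <- rnorm(n_envs, 0, sqrt(V_env))
    gl <- matrix(rnorm(n_lines * n_envs, 0, sqrt(V_GL)), n_lines, n_envs)
    dl <- matrix(rnorm(n_envs * n_reps, 0, sqrt(V_rep)), n_envs, n_reps)
    d <- expand.grid(line = seq_len(n_lines), env = seq_len(n_envs),
                     rep = seq_len(n_reps))
    d$value <- mu + g[d$line] + tau[d$env] + gl[cbind(d$line, d$env)] +
      dl[cbind(d$env, d$rep)] +
      rnorm(nrow(d), 0, sqrt(Ve))
    out <- data.frame(line = sprintf("L%04d", d$line),
                      env = sprintf("E%d", d$env),
                      rep = sprintf("R%d", d$rep),
                      trait = trait, value = d$value,
                      stringsAsFactors = FALSE)
    attr(out, "effects") <- list(g = g, tau = tau, gl = gl, delta = dl)
    out
  })
}

#' REML variance components of the multi-environment model
#'
#' Fits `value ~ 1 + (1|line) + (1|env) + (1|line:env) + (1|env:rep)` by
#' restricted maximum likelihood (via lme4) and returns the variance
#' components with broad-sense heritability on an entry-mean basis. Variance
#' components are non-negative by construction of the REML parameterisation.
#'
#' @param table long-format phenotype table (`line, env, rep, value`, and
#'   optionally `trait`).
#' @param trait trait to analyse when the table holds several.
#' @return Object of class `variance_components`: list with `components`
#'   (named vector `Vg, V_env, V_GL, V_rep, Ve`), `L`, `R`, `H2`, `mu`,
#'   `logLik`, `converged`, `n_dropped` and the underlying `fit`.
#' @export
fit_variance_components <- function(table, trait = NULL) {
  if (!is.null(trait) && "trait" %in% names(table))
    table <- table[table$trait == trait, , drop = FALSE]
  stopifnot(all(c("line", "env", "rep", "value") %in% names(table)))
  n_dropped <- sum(!is.finite(table$value))
  if (n_dropped > 0) {
    message("dropping ", n_dropped, " missing observation(s)")
    table <- table[is.finite(table$value), , drop = FALSE]
  }
  table$line <- factor(table$line)
  table$env <- factor(table$env)
  table$rep <- factor(table$rep)
  if (nlevels(table$line) < 2) stop("need at least 2 lines")
  if (nlevels(table$env) < 2)
    stop("single environment: line-by-environment variance is inestimable; ",
         "fit a reduced model without the interaction term")
  fit <- suppressMessages(lme4::lmer(
    value ~ 1 + (1 | line) + (1 | env) + (1 | line:env) + (1 | env:rep),
    data = table, REML = TRUE,
    control = lme4::lmerControl(
      optimizer = "bobyqa", calc.derivs = FALSE,
      check.conv.singular = "ignore",
      optCtrl = list(rhoend = 1e-12))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  comps <- c(Vg = getv("line"), V_env = getv("env"), V_GL = getv("line:env"),
             V_rep = getv("env:rep"), Ve = getv("Residual"))
  L <- nlevels(table$env)
  R <- length(unique(table$rep))
  out <- list(components = comps, L = L, R = R,
              H2 = h2_from_components(comps, L, R),
              mu = unname(lme4::fixef(fit)[1]),
              logLik = as.numeric(logLik(fit)),
              converged = length(fit@optinfo$conv$lme4) == 0,
              n_dropped = n_dropped,
              fit = fit, data = table)
  class(out) <- "variance_components"
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (REML):\n")
  print(round(x$components, 6))
  cat(sprintf("L = %d environments, R = %d replicates; H2 = %.4f\n",
              x$L, x$R, x$H2))
  invisible(x)
}

h2_from_components <- function(comps, L, R) {
  denom <- comps[["Vg"]] + comps[["V_GL"]] / L + comps[["Ve"]] / (L * R)
  if (denom <= 0) stop("all variance components are zero: H2 undefined")
  unname(comps[["Vg"]] / denom)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `H2 = Vg / (Vg + V_GL / L + Ve / (L R))`, the fraction of entry-mean
#' phenotypic variance attributable to genotype across `L` environments with
#' `R` replicates each.
#'
#' @param vc a `variance_components` object, or a named vector with at least
#'   `Vg`, `V_GL`, `Ve` (then `L` and `R` must be given).
#' @param L,R numbers of environments and replicates (taken from `vc` when it
#'   is a fitted object).
#' @return H2 in `[0, 1]`.
#' @export
#' @examples
#' heritability(c(Vg = 1, V_GL = 1, Ve = 1), L = 2, R = 3)  # 0.6
heritability <- function(vc, L = NULL, R = NULL) {
  if (inherits(vc, "variance_components")) {
    comps <- vc$components; L <- vc$L; R <- vc$R
  } else {
    comps <- vc
    stopifnot(!is.null(L), !is.null(R))
  }
  stopifnot(L >= 1, R >= 1, all(comps >= 0))
  h2_from_components(comps, L, R)
}

#' Line BLUPs (or BLUEs) from a fitted multi-environment model
#'
#' In the default `"blup"` mode, line effects are the best linear unbiased
#' predictions (conditional modes) of the random genotype effects: shrunken
#' line-mean deviations. The `"blue"` mode refits with genotype as a fixed
#' effect (environment, interaction and replicate still random) and returns
#' the estimated line means.
#'
#' @param vc fitted `variance_components` from [fit_variance_components()].
#' @param mode `"blup"` or `"blue"`.
#' @return Data frame `line, effect, value` where `value = mu + effect`.
#' @export
compute_blups <- function(vc, mode = c("blup", "blue")) {
  mode <- match.arg(mode)
  stopifnot(inherits(vc, "variance_components"))
  if (!vc$converged) stop("variance-component fit did not converge")
  if (mode == "blup") {
    re <- lme4::ranef(vc$fit)$line
    data.frame(line = rownames(re), effect = re[["(Intercept)"]],
               value = vc$mu + re[["(Intercept)"]],
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    fit <- suppressMessages(lme4::lmer(
      value ~ 0 + line + (1 | env) + (1 | line:env) + (1 | env:rep),
      data = vc$data, REML = TRUE,
      control = lme4::lmerControl(
        optimizer = "bobyqa", calc.derivs = FALSE,
        check.conv.singular = "ignore")))
    fe <- lme4::fixef(fit)
    lv <- sub("^line", "", names(fe))
    data.frame(line = lv, effect = unname(fe) - mean(fe),
               value = unname(fe), stringsAsFactors = FALSE)
  }
}

#' Method-of-moments variance components for balanced designs
#'
#' Closed-form (expected-mean-squares / Henderson) estimates for the balanced
#' two-way design with replicates nested in environments. Serves as an
#' independent cross-check of the REML fit: on balanced data with an interior
#' optimum the two coincide.
#'
#' The ANOVA/REML equivalence holds when all untruncated ANOVA solutions are
#' non-negative (an interior REML optimum); the untruncated solutions are
#' attached so callers can check that precondition. The environment component
#' has only `L - 1` degrees of freedom and is the usual boundary case.
#'
#' @inheritParams fit_variance_components
#' @return Named vector `Vg, V_env, V_GL, V_rep, Ve` (negative solutions
#'   truncated at zero), with attributes `untruncated` and `mean_squares`.
#' @export
vc_moments <- function(table, trait = NULL) {
  if (!is.null(trait) && "trait" %in% names(table))
    table <- table[table$trait == trait, , drop = FALSE]
  table$line <- factor(table$line)
  table$env <- factor(table$env)
  table$rep <- factor(table$rep)
  G <- nlevels(table$line); L <- nlevels(table$env)
  R <- length(unique(table$rep))
  if (nrow(table) != G * L * R)
    stop("vc_moments requires a balanced table")
  # balanced orthogonal design: sums of squares by direct aggregation
  y <- table$value
  gm <- mean(y)
  m_line <- tapply(y, table$line, mean)
  m_env <- tapply(y, table$env, mean)
  m_cell <- tapply(y, list(table$line, table$env), mean)
  m_er <- tapply(y, list(table$env, table$rep), mean)
  MS_line <- L * R * sum((m_line - gm)^2) / (G - 1)
  MS_env <- G * R * sum((m_env - gm)^2) / (L - 1)
  dev_gl <- sweep(sweep(m_cell, 1, m_line), 2, m_env) + gm
  MS_gl <- R * sum(dev_gl^2) / ((G - 1) * (L - 1))
  MS_rep <- G * sum(sweep(m_er, 1, m_env)^2) / (L * (R - 1))
  fit_cell <- m_cell[cbind(table$line, table$env)]
  fit_rep <- m_er[cbind(table$env, table$rep)]
  resid <- y - fit_cell - fit_rep + m_env[table$env]
  MS_err <- sum(resid^2) / ((G - 1) * L * (R - 1))
  Ve <- MS_err
  V_GL <- (MS_gl - MS_err) / R
  Vg <- (MS_line - MS_gl) / (L * R)
  V_rep <- (MS_rep - MS_err) / G
  V_env <- (MS_env - MS_gl - MS_rep + MS_err) / (G * R)
  raw <- c(Vg = Vg, V_env = V_env, V_GL = V_GL, V_rep = V_rep, Ve = Ve)
  out <- pmax(raw, 0)
  names(out) <- names(raw)
  attr(out, "untruncated") <- raw
  attr(out, "mean_squares") <- c(line = MS_line, env = MS_env, gl = MS_gl,
                                 rep = MS_rep, err = MS_err)
  out
}
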