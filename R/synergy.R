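#' Construct a dose-response series
#'
#' @param dose strictly positive doses (molar units).
#' @param fa fraction affected per dose (`1 - viability fraction`); values at
#'   the assay floor/ceiling are clamped into `(clamp, 1 - clamp)` with a
#'   warning.
#' @param drug drug identifier.
#' @param ratio for a fixed-ratio combination series, the molar ratio of
#'   component A to component B as a length-2 numeric (e.g. `c(3, 1)`).
#' @param clamp clamping epsilon (default 0.005).
#' @return A list of class `dose_response` with `dose`, `fa`, `drug`,
#'   `ratio`.
#' @export
dose_response_series <- function(dose, fa, drug = "drug", ratio = NULL,
                                 clamp = 0.005) {
  stopifnot(length(dose) == length(fa), all(dose > 0))
  if (any(fa <= clamp | fa >= 1 - clamp)) {
    warning(sum(fa <= clamp | fa >= 1 - clamp),
            " fraction-affected value(s) clamped into (",
            clamp, ", ", 1 - clamp, ")")
    fa <- pmin(pmax(fa, clamp), 1 - clamp)
  }
  structure(list(dose = dose, fa = fa, drug = drug, ratio = ratio),
            class = "dose_response")
}

#' Fit the median-effect equation to a dose-response series
#'
#' The median-effect model `fa/fu = (D/Dm)^m` linearizes to
#' `log(fa/(1-fa)) = m log(D) - m log(Dm)`; a least-squares line on that
#' scale yields the sigmoidicity `m` (slope) and the median-effect dose `Dm`
#' (from the intercept `-m log(Dm)`). Assay noise is additive on the
#' fraction affected, so by the delta method the logit-scale variance
#' inflates by `1 / (fa (1 - fa))^2` near the floor and ceiling; the default
#' fit therefore weights each point by `(fa (1 - fa))^2`, which stabilizes
#' `Dm` against high-leverage extreme doses. Set `weighted = FALSE` for the
#' plain unweighted regression. On noiseless model data both fits are exact.
#'
#' @param s a [dose_response_series()] with at least 3 usable points.
#' @param weighted use variance-stabilizing weights (default `TRUE`).
#' @return A list of class `median_effect_fit`: `Dm`, `m`, `r2`, `n_points`.
#' @export
fit_median_effect <- function(s, weighted = TRUE) {
  stopifnot(inherits(s, "dose_response"))
  usable <- s$fa > 0 & s$fa < 1
  if (sum(usable) < 3L)
    stop("median-effect fit needs at least 3 doses with fa strictly in (0,1)")
  fa <- s$fa[usable]
  y <- log(fa / (1 - fa))
  x <- log(s$dose[usable])
  w <- if (weighted) (fa * (1 - fa))^2 else rep(1, length(fa))
  fit <- stats::lm(y ~ x, weights = w)
  m <- unname(stats::coef(fit)[2])
  if (!is.finite(m) || m == 0)
    stop("degenerate median-effect fit: zero or undefined slope")
  dm <- exp(-unname(stats::coef(fit)[1]) / m)
  # weighted R^2, computed directly (summary.lm warns on exact fits)
  ybar <- stats::weighted.mean(y, w)
  r2 <- 1 - sum(w * stats::residuals(fit)^2) / sum(w * (y - ybar)^2)
  structure(list(Dm = dm, m = m, r2 = r2, n_points = sum(usable)),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("median_effect_fit: Dm = %.4g, m = %.4g, r2 = %.4f (%d doses)\n",
              x$Dm, x$m, x$r2, x$n_points))
  invisible(x)
}

# Dose of a single agent producing effect level fa under its fit.
dose_at_fa <- function(fit, fa) fit$Dm * (fa / (1 - fa))^(1 / fit$m)

#' Chou-Talalay combination index
#'
#' For a fixed-ratio combination of drugs A and B, the combination index at
#' effect level `fa` is `CI = d_A / D_A(fa) + d_B / D_B(fa)`, where
#' `(d_A, d_B)` are the component doses of the combination producing effect
#' `fa` (from the combination's own median-effect fit and the fixed molar
#' ratio) and `D_X(fa)` is the dose of drug X alone producing the same
#' effect. CI below 1 indicates synergism, 1 additivity, above 1 antagonism.
#' The default is the mutually exclusive (two-term) form; setting
#' `mutually_exclusive = FALSE` adds the product term
#' `d_A d_B / (D_A D_B)` of the mutually nonexclusive variant.
#'
#' @param fit_a,fit_b single-agent [fit_median_effect()] results.
#' @param fit_combo median-effect fit of the fixed-ratio combination, doses
#'   expressed as total dose (A + B).
#' @param ratio molar ratio A:B as a length-2 numeric, e.g. `c(3, 1)`.
#' @param fa_level effect level(s) in (0, 1) at which to evaluate CI.
#' @param mutually_exclusive use the two-term form (default `TRUE`).
#' @return Numeric vector of combination indices, one per `fa_level`.
#' @export
combination_index <- function(fit_a, fit_b, fit_combo, ratio = c(1, 1),
                              fa_level = 0.5, mutually_exclusive = TRUE) {
  stopifnot(inherits(fit_a, "median_effect_fit"),
            inherits(fit_b, "median_effect_fit"),
            inherits(fit_combo, "median_effect_fit"),
            length(ratio) == 2L, all(ratio > 0))
  if (any(fa_level <= 0 | fa_level >= 1))
    stop("fa_level must lie strictly in (0, 1)")
  vapply(fa_level, function(fa) {
    d_total <- dose_at_fa(fit_combo, fa)
    d_a <- d_total * ratio[1] / sum(ratio)
    d_b <- d_total * ratio[2] / sum(ratio)
    ci <- d_a / dose_at_fa(fit_a, fa) + d_b / dose_at_fa(fit_b, fa)
    if (!mutually_exclusive)
      ci <- ci + (d_a * d_b) / (dose_at_fa(fit_a, fa) * dose_at_fa(fit_b, fa))
    ci
  }, numeric(1))
}

#' Isobologram coordinates at a fixed effect level
#'
#' The additivity line connects the single-agent equi-effect doses
#' `(D_A(fa), 0)` and `(0, D_B(fa))`; the combination point `(d_A, d_B)` is
#' the component-dose pair of the fixed-ratio combination at the same effect.
#' A point strictly under the line corresponds to CI < 1 (synergy).
#'
#' @inheritParams combination_index
#' @param fa_level single effect level (default 0.5, the IC50 isobologram).
#' @return A list with `intercept_a`, `intercept_b` (axis intercepts),
#'   `combo_point` (length-2 numeric `c(d_A, d_B)`) and `ci`.
#' @export
isobologram_points <- function(fit_a, fit_b, fit_combo, ratio = c(1, 1),
                               fa_level = 0.5) {
  ci <- combination_index(fit_a, fit_b, fit_combo, ratio, fa_level)
  d_total <- dose_at_fa(fit_combo, fa_level)
  list(intercept_a = dose_at_fa(fit_a, fa_level),
       intercept_b = dose_at_fa(fit_b, fa_level),
       combo_point = c(d_total * ratio[1] / sum(ratio),
                       d_total * ratio[2] / sum(ratio)),
       ci = ci)
}
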