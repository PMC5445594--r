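#' Generate a synthetic pharmacogenomic panel with planted ground truth
#'
#' Emulates the statistical structure the signature-discovery pipeline
#' assumes: one latent sensitivity factor per cell line drives both the drug
#' response and the expression of a planted gene set. Per sample a latent
#' `s ~ N(0, 1)` is drawn; the two drugs' sensitivity z-scores are
#' `z = sqrt(rho) * s + sqrt(1 - rho) * noise`, so their pairwise correlation
#' is `rho`, and IC50-like values are `exp(z)` (natural-log z-scoring
#' recovers z up to the panel's standardization). Planted gene `g` has
#' expression `baseline_g + sign_g * effect_size * s + N(0, 1)`; all other
#' genes are baseline plus unit noise. Because responders are the *low*-z
#' (sensitive) lines, the expected signature weight of a planted gene is
#' `-sign_g * effect_size * gap`, where `gap > 0` is the latent-mean
#' separation of the responder and non-responder classes; the truth object
#' records the expected weight sign.
#'
#' @param n_genes,n_samples panel dimensions (defaults 2000 x 200).
#' @param n_planted number of planted sensitivity genes (default 60), half
#'   with positive and half with negative sign.
#' @param effect_size latent-factor loading of planted genes, in noise-SD
#'   units (default 1.2).
#' @param rho drug-pair z-score correlation in \[0, 1\] (default 0.8).
#' @param tissues character vector of tissue labels assigned round-robin.
#' @param seed integer RNG seed.
#' @return A list with `expr` (an `expr_matrix`, log2 scale), `response`
#'   (a [drug_response_table()] with drugs `"drugA"`, `"drugB"`) and `truth`
#'   (class `synthetic_truth`: planted gene ids, planted signs, expected
#'   weight signs, latent sensitivities, parameters, seed).
#' @export
generate_panel <- function(n_genes = 2000L, n_samples = 200L,
                           n_planted = 60L, effect_size = 1.2, rho = 0.8,
                           tissues = c("breast", "ovary"), seed = 1L) {
  stopifnot(n_planted < n_genes, effect_size >= 0, rho >= 0, rho <= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  genes <- sprintf("g%04d", seq_len(n_genes))
  samples <- sprintf("cl%03d", seq_len(n_samples))
  s <- stats::rnorm(n_samples)

  z1 <- sqrt(rho) * s + sqrt(1 - rho) * stats::rnorm(n_samples)
  z2 <- sqrt(rho) * s + sqrt(1 - rho) * stats::rnorm(n_samples)

  planted <- sample(genes, n_planted)
  sign_g <- stats::setNames(rep(c(1, -1), length.out = n_planted), planted)
  baseline <- stats::rnorm(n_genes, mean = 7, sd = 1.5)

  x <- matrix(stats::rnorm(n_genes * n_samples), nrow = n_genes,
              dimnames = list(genes, samples)) + baseline
  x[planted, ] <- x[planted, ] + outer(sign_g * effect_size, s)

  tissue <- stats::setNames(rep(tissues, length.out = n_samples), samples)
  expr <- expression_matrix(x, tissue, scale = "log2")

  response <- drug_response_table(
    sample_id = rep(samples, 2L),
    drug_id = rep(c("drugA", "drugB"), each = n_samples),
    value = exp(c(z1, z2)),
    metric = "IC50")

  truth <- structure(list(
    planted_genes = planted,
    planted_sign = sign_g,
    expected_weight_sign = -sign_g,
    effect_size = effect_size,
    latent_sensitivity = stats::setNames(s, samples),
    drug_pair_correlation = rho,
    n_genes = n_genes, n_samples = n_samples, seed = seed),
    class = "synthetic_truth")

  list(expr = expr, response = response, truth = truth)
}

#' Generate a synthetic survival cohort with a planted score effect
#'
#' Scores are standard normal; event times are exponential with hazard
#' `lambda0 * hr^score`, so `hr` is the true hazard ratio per score unit.
#' Censoring is independent uniform on `(0, C)` with `C` solved numerically
#' so the expected censored fraction matches `censor_rate`.
#'
#' @param n_patients cohort size.
#' @param true_hr true hazard ratio per score unit (> 0).
#' @param censor_rate target censoring fraction in \[0, 1).
#' @param lambda0 baseline hazard (default 0.05 per time unit).
#' @param seed integer RNG seed.
#' @return A `survival_table` with columns `id`, `time`, `event`, `score`.
#' @export
generate_survival <- function(n_patients = 500L, true_hr = 0.5,
                              censor_rate = 0.2, lambda0 = 0.05,
                              seed = 1L) {
  stopifnot(true_hr > 0, censor_rate >= 0, censor_rate < 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  score <- stats::rnorm(n_patients)
  rate <- lambda0 * true_hr^score
  t_event <- stats::rexp(n_patients, rate = rate)

  if (censor_rate == 0) {
    time <- t_event
    event <- rep(1L, n_patients)
  } else {
    # expected censored fraction for uniform(0, C) censoring given t_event
    cens_frac <- function(C) mean(pmin(t_event / C, 1)) - censor_rate
    upper <- max(t_event) * 2
    C <- stats::uniroot(cens_frac, lower = min(t_event) * 1e-3,
                        upper = upper, extendInt = "downX")$root
    t_cens <- stats::runif(n_patients, 0, C)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  }
  survival_table(data.frame(id = sprintf("pt%04d", seq_len(n_patients)),
                            time = time, event = event, score = score,
                            stringsAsFactors = FALSE))
}

#' Generate a synthetic dose-response series from the median-effect model
#'
#' Fraction affected follows `fa = (D/Dm)^m / (1 + (D/Dm)^m)` plus Gaussian
#' noise, clamped strictly inside (0, 1). The default dose ladder is a
#' three-fold serial dilution over seven doses.
#'
#' @param Dm median-effect dose (> 0).
#' @param m sigmoidicity.
#' @param doses dose vector; default seven 3-fold dilutions from `9 * Dm`.
#' @param noise_sd Gaussian noise SD on fa (default 0).
#' @param seed integer RNG seed.
#' @param drug drug identifier.
#' @param ratio forwarded to [dose_response_series()].
#' @return A [dose_response_series()].
#' @export
generate_dose_response <- function(Dm, m = 1, doses = Dm * 9 / 3^(0:6),
                                   noise_sd = 0, seed = 1L, drug = "drug",
                                   ratio = NULL) {
  stopifnot(Dm > 0, all(doses > 0))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  r <- (doses / Dm)^m
  fa <- r / (1 + r)
  if (noise_sd > 0) fa <- fa + stats::rnorm(length(fa), sd = noise_sd)
  fa <- pmin(pmax(fa, 1e-4), 1 - 1e-4)
  dose_response_series(doses, fa, drug = drug, ratio = ratio, clamp = 1e-6)
}
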