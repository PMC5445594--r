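#' Z-score drug sensitivity values
#'
#' Sensitivity values for one drug are standardized across the cell lines
#' that have a measurement: `z = (x - mean) / sd`, with the sample (n-1)
#' standard deviation. IC50 values are natural-log transformed before
#' standardization by default, matching common practice for concentration
#' metrics; dose-response AUC values are standardized directly.
#'
#' @param d a [drug_response_table()].
#' @param drug drug identifier.
#' @param samples optional sample ids to restrict to (standardization is then
#'   computed over this panel).
#' @param log_ic50 take the natural log of IC50-metric values first
#'   (default `TRUE`).
#' @return Named numeric vector of z-scores, one per sample with data.
#' @export
zscore_sensitivity <- function(d, drug, samples = NULL, log_ic50 = TRUE) {
  stopifnot(inherits(d, "drug_response"))
  rec <- d[d$drug_id == drug, , drop = FALSE]
  if (!is.null(samples)) rec <- rec[rec$sample_id %in% samples, , drop = FALSE]
  if (nrow(rec) < 2L)
    stop("need at least 2 samples with values for drug '", drug, "'")
  x <- rec$value
  if (log_ic50 && any(rec$metric == "IC50")) {
    is_ic50 <- rec$metric == "IC50"
    if (any(x[is_ic50] <= 0))
      stop("IC50 values must be positive for log transformation")
    x[is_ic50] <- log(x[is_ic50])
  }
  s <- stats::sd(x)
  if (s == 0) stop("zero variance in sensitivity values for drug '",
                   drug, "'")
  stats::setNames((x - mean(x)) / s, rec$sample_id)
}

new_sensitivity_calls <- function(sample_id, z, combined_z, label, drugs) {
  structure(
    data.frame(sample_id = sample_id, combined_z = combined_z,
               label = label, stringsAsFactors = FALSE,
               row.names = NULL) |>
      cbind(z),
    class = c("sensitivity_calls", "data.frame"),
    drugs = drugs
  )
}

#' Call responders and non-responders from single-agent z-scores
#'
#' A cell line is a responder when its sensitivity z-score is below -1, a
#' non-responder when it is above 0, and belongs to neither class otherwise
#' (boundary values included in "neither"; the inequalities are strict).
#'
#' @param z named numeric vector of finite z-scores.
#' @return A `data.frame` of class `sensitivity_calls` with columns
#'   `sample_id`, `combined_z`, `label` and the per-drug z column `z1`.
#' @export
call_single <- function(z) {
  if (!all(is.finite(z))) stop("z-scores must be finite")
  label <- ifelse(z < -1, "responder",
                  ifelse(z > 0, "non_responder", "neither"))
  new_sensitivity_calls(names(z), data.frame(z1 = unname(z)),
                        combined_z = unname(z), label = unname(label),
                        drugs = 1L)
}

#' Call responders and non-responders from a dual-inhibitor pair
#'
#' When two inhibitors of the same target are available, the average of the
#' two z-scores defines sensitivity. Responders must have a mean z below -1
#' *and* each individual z at or below -0.5 (the guard excludes lines driven
#' by a single drug); non-responders must have both z-scores above 0.
#' Samples missing either drug are dropped (count reported as an attribute).
#'
#' @param z1,z2 named numeric z-score vectors for the two drugs.
#' @return A `sensitivity_calls` data frame with per-drug columns `z1`, `z2`,
#'   the mean `combined_z` and the label; attribute `n_dropped` counts
#'   samples present in only one vector.
#' @export
call_dual <- function(z1, z2) {
  common <- intersect(names(z1), names(z2))
  dropped <- length(union(names(z1), names(z2))) - length(common)
  if (dropped > 0)
    message(dropped, " sample(s) missing one of the two drugs were dropped")
  a <- z1[common]; b <- z2[common]
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("z-scores must be finite")
  mz <- (a + b) / 2
  label <- ifelse(mz < -1 & a <= -0.5 & b <= -0.5, "responder",
                  ifelse(a > 0 & b > 0, "non_responder", "neither"))
  out <- new_sensitivity_calls(common,
                               data.frame(z1 = unname(a), z2 = unname(b)),
                               combined_z = unname(mz),
                               label = unname(label), drugs = 2L)
  attr(out, "n_dropped") <- dropped
  out
}
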