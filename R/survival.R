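#' Two-group log-rank test
#'
#' The standard chi-square log-rank statistic with one degree of freedom.
#' At every distinct event time the observed events in group A are compared
#' with the expectation under the pooled-risk-set null; simultaneous events
#' at a time are all counted against that time's risk set (the usual tie
#' convention), with the hypergeometric variance term.
#'
#' @param time_a,event_a times and event indicators (1 = event, 0 =
#'   censored) for group A.
#' @param time_b,event_b the same for group B.
#' @return A list with `statistic` (>= 0), `p_value` (1 df chi-square),
#'   `observed` and `expected` events in group A.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  stopifnot(length(time_a) == length(event_a),
            length(time_b) == length(event_b),
            length(time_a) >= 1L, length(time_b) >= 1L)
  if (sum(event_a) + sum(event_b) == 0L)
    stop("log-rank statistic undefined with zero events")
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))

  event_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  obs <- 0; exp_ <- 0
  for (t in event_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp_a)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & grp_a)
    obs <- obs + d1
    e1 <- d * n1 / n
    exp_ <- exp_ + e1
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) o_minus_e^2 / v else 0
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = obs, expected = exp_)
}

#' Optimal score cutpoint for survival stratification
#'
#' Scans every midpoint between consecutive distinct sorted signature scores
#' whose split leaves at least `min_group_frac` of the patients on each side,
#' computes the two-group log-rank statistic at each candidate, and returns
#' the cutpoint maximizing it — the minimum-p-value split. The selected
#' p-value is reported *unadjusted*; because the cutpoint was chosen to
#' maximize separation it is optimistic (anti-conservative), which the
#' result flags explicitly.
#'
#' @param s a `survival_table` with a `score` column.
#' @param min_group_frac smallest admissible group as a fraction of the
#'   cohort (default 0.2).
#' @return A list of class `cutpoint_result`: `cutpoint`, `statistic`,
#'   `p_value`, `n_low`, `n_high`, `candidates` (data frame of every scanned
#'   cutpoint with its statistic and p-value) and
#'   `p_value_unadjusted_for_scan = TRUE`.
#' @export
optimal_cutpoint <- function(s, min_group_frac = 0.2) {
  stopifnot(inherits(s, "survival_table"))
  if (is.null(s$score)) stop("survival table has no `score` column")
  if (nrow(s) < 10L) stop("need at least 10 patients")
  sc <- sort(unique(s$score))
  if (length(sc) < 2L) stop("scores are all equal; no split possible")
  mids <- (sc[-1] + sc[-length(sc)]) / 2
  n <- nrow(s)
  min_n <- ceiling(min_group_frac * n)

  cand <- lapply(mids, function(ct) {
    lo <- s$score <= ct
    if (sum(lo) < min_n || sum(!lo) < min_n) return(NULL)
    lr <- logrank_test(s$time[lo], s$event[lo], s$time[!lo], s$event[!lo])
    data.frame(cutpoint = ct, statistic = lr$statistic,
               p_value = lr$p_value, n_low = sum(lo), n_high = sum(!lo))
  })
  cand <- do.call(rbind, cand)
  if (is.null(cand) || !nrow(cand))
    stop("no admissible split leaves at least ", min_n,
         " patients on each side")
  best <- cand[which.max(cand$statistic), ]
  structure(list(cutpoint = best$cutpoint, statistic = best$statistic,
                 p_value = best$p_value,
                 n_low = best$n_low, n_high = best$n_high,
                 candidates = cand,
                 p_value_unadjusted_for_scan = TRUE),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(paste0("cutpoint_result: score cut at %.4g ",
                     "(%d low / %d high), log-rank chi-sq %.3f, p %.3g\n"),
              x$cutpoint, x$n_low, x$n_high, x$statistic, x$p_value))
  cat("  note: p-value is unadjusted for the cutpoint scan (optimistic)\n")
  invisible(x)
}

#' Covariate-adjusted hazard ratios via Cox proportional hazards
#'
#' A thin wrapper over [survival::coxph()] fitting
#' `Surv(time, event) ~ score + covariates`. Rows with missing covariates are
#' dropped with a message. This is deliberate plumbing: the proportional-
#' hazards machinery is delegated to the survival package, not re-derived.
#'
#' @param s a `survival_table` with a `score` column.
#' @param covariates character vector of additional column names (e.g.
#'   `c("stage", "grade")`), or `NULL` for the unadjusted score model.
#' @return A data frame with one row per model term: `term`, `hr`,
#'   `ci_lower`, `ci_upper` (95%), `p_value`.
#' @export
cox_adjusted <- function(s, covariates = NULL) {
  stopifnot(inherits(s, "survival_table"))
  if (is.null(s$score)) stop("survival table has no `score` column")
  vars <- c("score", covariates)
  miss <- !stats::complete.cases(s[, c("time", "event", vars)])
  if (any(miss)) {
    message(sum(miss), " row(s) with missing covariates dropped")
    s <- s[!miss, , drop = FALSE]
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(vars, collapse = " + ")))
  fit <- survival::coxph(fml, data = s)
  sm <- summary(fit)
  data.frame(term = rownames(sm$coefficients),
             hr = sm$conf.int[, "exp(coef)"],
             ci_lower = sm$conf.int[, "lower .95"],
             ci_upper = sm$conf.int[, "upper .95"],
             p_value = sm$coefficients[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}
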