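#' Per-gene differential expression between responders and non-responders
#'
#' A two-sided Welch unequal-variance t-test per gene, vectorized over the
#' expression matrix. The fold change is reported as the difference of group
#' means on the log2 scale (responders minus non-responders); the ratio-scale
#' fold change is `2^log2_fc`. Samples labeled "neither" are excluded.
#'
#' @param m an `expr_matrix` (log2 scale).
#' @param calls a `sensitivity_calls` data frame covering (a subset of) the
#'   matrix samples.
#' @param min_group_size smallest admissible group (default 5). A smaller
#'   group raises a condition of class `iraps_group_too_small`, which the
#'   resampling engine treats as an iteration skip.
#' @return A `data.frame` with columns `gene`, `p_value`, `log2_fc` plus the
#'   group sizes as attributes `n_resp` / `n_nonresp`.
#' @export
differential_expression <- function(m, calls, min_group_size = 5L) {
  stopifnot(inherits(m, "expr_matrix"), inherits(calls, "sensitivity_calls"))
  resp <- intersect(calls$sample_id[calls$label == "responder"],
                    colnames(m$values))
  nonr <- intersect(calls$sample_id[calls$label == "non_responder"],
                    colnames(m$values))
  if (length(resp) < min_group_size || length(nonr) < min_group_size)
    stop(structure(class = c("iraps_group_too_small", "error", "condition"),
                   list(message = sprintf(
                     "group below min_group_size (%d responders, %d non-responders)",
                     length(resp), length(nonr)), call = sys.call())))
  stats <- welch_rows(m$values[, resp, drop = FALSE],
                      m$values[, nonr, drop = FALSE])
  out <- data.frame(gene = rownames(m$values),
                    p_value = stats$p, log2_fc = stats$diff,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_resp") <- length(resp)
  attr(out, "n_nonresp") <- length(nonr)
  out
}

# Row-wise Welch t-test: x, y matrices with genes in rows. Returns the mean
# difference (x minus y) and two-sided p-value per row. Degenerate rows with
# zero pooled standard error get p = 1 when the difference is zero and the
# smallest representable p otherwise.
welch_rows <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  diff <- mx - my
  tstat <- ifelse(se2 > 0, diff / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1))),
               nx + ny - 2)
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0 & diff != 0] <- .Machine$double.xmin
  p[se2 == 0 & diff == 0] <- 1
  p <- pmin(p, 1)
  p[p == 0] <- .Machine$double.xmin
  list(diff = diff, p = p, t = tstat, df = df)
}

#' Iterative resampling of cell lines with per-iteration differential
#' expression
#'
#' The engine behind signature discovery: cell lines with both expression and
#' response data are repeatedly half-sampled (without replacement), each
#' sample is classified as responder / non-responder / neither from z-scored
#' sensitivity (single drug or a dual-inhibitor pair), and a per-gene Welch
#' test is run on each resample. The default 1000 iterations yield 1000
#' per-gene lists of (p-value, log2 fold change).
#'
#' Samples are sorted canonically before seeding so results do not depend on
#' input file ordering; the same seed always yields an identical archive.
#' Iterations whose responder or non-responder group falls below
#' `min_group_size` are skipped and counted.
#'
#' @param m an `expr_matrix` (log2 scale, normalized).
#' @param d a [drug_response_table()].
#' @param drugs one drug id (single-agent rule) or two (dual-inhibitor rule).
#' @param iterations number of resampling iterations (default 1000).
#' @param fraction fraction of candidate cell lines drawn per iteration
#'   (default 0.5).
#' @param seed integer RNG seed; fully determines the archive.
#' @param exclude_samples held-out test sample ids removed from the candidate
#'   pool before any sampling.
#' @param min_group_size smallest admissible class size per iteration.
#' @param rescore_per_iteration if `TRUE`, z-scores are recomputed within
#'   each resample; by default sensitivity is z-scored once on the full
#'   candidate pool and the resulting calls are fixed across iterations.
#' @param log_ic50 forwarded to [zscore_sensitivity()].
#' @return A `resampling_archive`: genes x iterations matrices `p` and
#'   `log2_fc`, per-iteration group sizes, the gene universe, seed, fraction
#'   and the number of skipped iterations.
#' @export
run_resampling <- function(m, d, drugs, iterations = 1000L, fraction = 0.5,
                           seed = 1L, exclude_samples = NULL,
                           min_group_size = 5L,
                           rescore_per_iteration = FALSE,
                           log_ic50 = TRUE) {
  stopifnot(inherits(m, "expr_matrix"), inherits(d, "drug_response"),
            length(drugs) %in% 1:2, fraction > 0, fraction <= 1)

  with_drug <- Reduce(intersect, lapply(drugs, function(dr)
    d$sample_id[d$drug_id == dr]))
  pool <- sort(intersect(colnames(m$values), with_drug))
  pool <- setdiff(pool, exclude_samples)
  if (length(pool) < 2L * min_group_size)
    stop("too few cell lines with both expression and response data (",
         length(pool), ")")

  zs <- lapply(drugs, function(dr)
    zscore_sensitivity(d, dr, samples = pool, log_ic50 = log_ic50))
  full_calls <- if (length(drugs) == 2L) call_dual(zs[[1]], zs[[2]])
                else call_single(zs[[1]])

  n_draw <- floor(fraction * length(pool))
  genes <- rownames(m$values)
  P <- matrix(NA_real_, nrow = length(genes), ncol = iterations,
              dimnames = list(genes, NULL))
  FC <- P
  n_resp <- n_nonresp <- integer(iterations)
  kept <- logical(iterations)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  for (i in seq_len(iterations)) {
    drawn <- sample(pool, n_draw)
    if (rescore_per_iteration) {
      zi <- lapply(drugs, function(dr)
        zscore_sensitivity(d, dr, samples = drawn, log_ic50 = log_ic50))
      calls <- if (length(drugs) == 2L) call_dual(zi[[1]], zi[[2]])
               else call_single(zi[[1]])
    } else {
      calls <- full_calls[full_calls$sample_id %in% drawn, , drop = FALSE]
    }
    de <- tryCatch(
      differential_expression(subset_expression(m, samples = drawn), calls,
                              min_group_size = min_group_size),
      iraps_group_too_small = function(e) NULL)
    if (is.null(de)) next
    kept[i] <- TRUE
    P[, i] <- de$p_value
    FC[, i] <- de$log2_fc
    n_resp[i] <- attr(de, "n_resp")
    n_nonresp[i] <- attr(de, "n_nonresp")
  }

  if (!any(kept))
    stop("all ", iterations, " iterations were skipped: every resample had ",
         "fewer than ", min_group_size, " responders or non-responders; ",
         "consider a smaller min_group_size or a different drug")

  structure(list(p = P[, kept, drop = FALSE],
                 log2_fc = FC[, kept, drop = FALSE],
                 n_resp = n_resp[kept], n_nonresp = n_nonresp[kept],
                 genes = genes,
                 seed = seed, fraction = fraction,
                 skipped = sum(!kept)),
            class = "resampling_archive")
}

#' @export
print.resampling_archive <- function(x, ...) {
  cat(sprintf(paste0("resampling_archive: %d genes x %d iterations ",
                     "(%d skipped), median groups %d resp / %d nonresp\n"),
              nrow(x$p), ncol(x$p), x$skipped,
              stats::median(x$n_resp), stats::median(x$n_nonresp)))
  invisible(x)
}
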