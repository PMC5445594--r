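#' Log2-transform raw expression values
#'
#' @param m an `expr_matrix` on the raw scale.
#' @param offset nonnegative pseudo-count added before the log; default 1,
#'   the usual choice for raw intensities that may contain zeros.
#' @return The matrix with values `log2(value + offset)` and scale `"log2"`.
#' @export
log2_transform <- function(m, offset = 1) {
  stopifnot(inherits(m, "expr_matrix"), offset >= 0)
  if (m$scale != "raw")
    stop("log2_transform expects a raw-scale matrix (scale is '",
         m$scale, "')")
  shifted <- m$values + offset
  if (any(shifted <= 0)) {
    bad <- which(shifted <= 0, arr.ind = TRUE)
    stop(sprintf(
      "nonpositive value(s) under offset %g, e.g. gene '%s' sample '%s'",
      offset, rownames(m$values)[bad[1, 1]], colnames(m$values)[bad[1, 2]]))
  }
  expression_matrix(log2(shifted), m$tissue, scale = "log2")
}

# Quantile-normalize the columns of a plain matrix. Ties within a column
# receive the mean of the reference values at their tied ranks.
quantile_normalize_matrix <- function(x) {
  if (ncol(x) < 2L) return(x)
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    assigned <- numeric(length(col))
    assigned[order(col)] <- ref
    out[, j] <- stats::ave(assigned, col) # mean of ref values over ties
  }
  out
}

#' Quantile normalization across samples
#'
#' Forces every column (sample) to share the distribution given by the
#' across-column mean of order statistics. Ties within a column receive the
#' mean of the reference values at their tied ranks, so the map is
#' deterministic and idempotent.
#'
#' @param m an `expr_matrix` with no missing values.
#' @return The normalized `expr_matrix` (same scale flag).
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!all(is.finite(m$values)))
    stop("quantile normalization requires a complete matrix")
  if (ncol(m$values) < 2L) {
    warning("single-sample matrix: quantile normalization is a no-op")
    return(m)
  }
  expression_matrix(quantile_normalize_matrix(m$values), m$tissue,
                    scale = m$scale)
}

#' Tukey median polish
#'
#' Decomposes a matrix into overall + row + column effects + residuals by
#' alternating row- and column-median sweeps. Iteration stops when the sum of
#' absolute residuals changes by less than `tol` (relative) or after
#' `max_iter` sweeps. The reconstruction
#' `overall + row + col + residual == input` holds exactly at every step.
#'
#' @param x a numeric matrix with at least 2 rows and 2 columns (an
#'   `expr_matrix` is also accepted).
#' @param max_iter maximum number of full sweeps (default 10).
#' @param tol relative convergence tolerance on the sum of absolute
#'   residuals (default 1e-6).
#' @return A list of class `median_polish` with `overall`, `row_effects`,
#'   `col_effects`, `residuals` and `iterations_used`.
#' @export
median_polish <- function(x, max_iter = 10L, tol = 1e-6) {
  if (inherits(x, "expr_matrix")) x <- x$values
  stopifnot(is.matrix(x), nrow(x) >= 2L, ncol(x) >= 2L)
  overall <- 0
  row_eff <- numeric(nrow(x))
  col_eff <- numeric(ncol(x))
  resid <- x
  old_sum <- sum(abs(resid))
  iters <- 0L
  for (i in seq_len(max_iter)) {
    iters <- i
    rm_ <- apply(resid, 1, stats::median)
    row_eff <- row_eff + rm_
    resid <- resid - rm_
    d <- stats::median(col_eff)
    overall <- overall + d
    col_eff <- col_eff - d

    cm_ <- apply(resid, 2, stats::median)
    col_eff <- col_eff + cm_
    resid <- sweep(resid, 2, cm_)
    d <- stats::median(row_eff)
    overall <- overall + d
    row_eff <- row_eff - d

    new_sum <- sum(abs(resid))
    if (new_sum == 0 || abs(old_sum - new_sum) < tol * new_sum) break
    old_sum <- new_sum
  }
  # fold any residual offset of the effect medians into the overall term so
  # that median(row_effects) == median(col_effects) == 0 exactly
  d <- stats::median(row_eff)
  overall <- overall + d; row_eff <- row_eff - d
  d <- stats::median(col_eff)
  overall <- overall + d; col_eff <- col_eff - d
  structure(list(overall = overall,
                 row_effects = stats::setNames(row_eff, rownames(x)),
                 col_effects = stats::setNames(col_eff, colnames(x)),
                 residuals = resid,
                 iterations_used = iters),
            class = "median_polish")
}

#' Per-tissue normalization: quantile normalize then median polish
#'
#' For each tissue group independently, the samples are quantile normalized
#' within the group and median polished; the gene (row) effects and the
#' overall effect are removed while column effects and residuals are kept, so
#' each gene is centered within its tissue and cross-tissue baseline
#' differences cannot dominate downstream differential expression. Groups of
#' a single sample pass through centered at zero.
#'
#' @param m an `expr_matrix` with tissue labels.
#' @param max_iter,tol forwarded to [median_polish()].
#' @param quantile_within if `TRUE` (default) quantile normalization is done
#'   within each tissue group; if `FALSE` it is applied once across all
#'   samples before the per-tissue polish.
#' @return The normalized `expr_matrix` (scale `"log2"` preserved).
#' @export
preprocess_per_tissue <- function(m, max_iter = 10L, tol = 1e-6,
                                  quantile_within = TRUE) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  if (!quantile_within) v <- quantile_normalize_matrix(v)
  out <- v
  for (tis in unique(m$tissue)) {
    cols <- which(m$tissue == tis)
    if (length(cols) == 1L) {
      out[, cols] <- 0 # single-sample tissue: genes centered at zero
      next
    }
    g <- v[, cols, drop = FALSE]
    if (quantile_within) g <- quantile_normalize_matrix(g)
    mp <- median_polish(g, max_iter = max_iter, tol = tol)
    out[, cols] <- mp$residuals +
      matrix(mp$col_effects, nrow = nrow(g), ncol = length(cols),
             byrow = TRUE)
  }
  expression_matrix(out, m$tissue, scale = "log2")
}
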