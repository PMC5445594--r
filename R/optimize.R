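#' Conservation fraction of a gene across resampling iterations
#'
#' The fraction of retained iterations in which a gene passes the p-value and
#' fold-change thresholds. By default a direction-consistency rule is
#' applied: only iterations whose fold-change sign matches the gene's
#' majority sign among qualifying iterations are counted, so that a gene
#' flipping direction between resamples cannot accumulate conservation.
#'
#' @param archive a `resampling_archive`.
#' @param gene gene id (or ids) to evaluate; default all genes.
#' @param p_thr p-value threshold (qualify when `p < p_thr`).
#' @param fc_thr fold-change threshold on the ratio scale, >= 1 (qualify
#'   when `|log2_fc| > log2(fc_thr)`).
#' @param direction_consistent apply the majority-sign rule (default `TRUE`).
#' @return Named numeric vector of fractions in \[0, 1\].
#' @export
conservation_fraction <- function(archive, gene = NULL, p_thr, fc_thr,
                                  direction_consistent = TRUE) {
  stopifnot(inherits(archive, "resampling_archive"), fc_thr >= 1)
  q <- qualify_matrix(archive, p_thr, fc_thr, direction_consistent)
  res <- rowMeans(q)
  if (is.null(gene)) res else res[gene]
}

# Logical genes x iterations matrix of qualification under (p_thr, fc_thr),
# optionally restricted to each gene's majority fold-change sign.
qualify_matrix <- function(archive, p_thr, fc_thr,
                           direction_consistent = TRUE) {
  pass <- archive$p < p_thr & abs(archive$log2_fc) > log2(fc_thr)
  if (!direction_consistent) return(pass)
  up <- rowSums(pass & archive$log2_fc > 0)
  down <- rowSums(pass & archive$log2_fc < 0)
  maj_up <- up >= down # ties resolved toward up; irrelevant when up == down == 0
  pass & (archive$log2_fc > 0) == maj_up
}

#' Build a candidate signature at fixed thresholds
#'
#' Genes whose [conservation_fraction()] reaches `cons_thr` enter the
#' signature; each weight is the mean signed log2 fold change over the
#' iterations in which the gene qualified. An empty candidate is returned as
#' `NULL` with a warning rather than an error, so grid sweeps can proceed.
#'
#' @param archive a `resampling_archive`.
#' @param p_thr,fc_thr thresholds as in [conservation_fraction()].
#' @param cons_thr conservation threshold in (0, 1].
#' @param direction_consistent apply the majority-sign rule.
#' @return A [signature()] or `NULL` when no gene qualifies.
#' @export
build_candidate <- function(archive, p_thr, fc_thr, cons_thr,
                            direction_consistent = TRUE) {
  stopifnot(cons_thr > 0, cons_thr <= 1)
  q <- qualify_matrix(archive, p_thr, fc_thr, direction_consistent)
  frac <- rowMeans(q)
  keep <- frac >= cons_thr
  if (!any(keep)) {
    warning(sprintf("no gene conserved at p<%g, fc>%g, conservation>=%g",
                    p_thr, fc_thr, cons_thr))
    return(NULL)
  }
  fc <- archive$log2_fc[keep, , drop = FALSE]
  qk <- q[keep, , drop = FALSE]
  w <- rowSums(fc * qk) / rowSums(qk)
  signature(w, thresholds = list(p = p_thr, fc = fc_thr,
                                 conservation = cons_thr))
}

#' Grid-search threshold optimization of a signature
#'
#' Sweeps all combinations of p-value, fold-change and conservation
#' thresholds; at each grid point the candidate signature is built from the
#' archive, the training samples (restricted to the target tissue by the
#' caller) are scored by [score_samples()], and the ROC AUC over responders
#' vs non-responders is recorded.
#'
#' Selection uses a one-standard-error rule rather than the raw argmax: on a
#' well-separated training set many grid points reach statistically
#' indistinguishable AUCs (often differing by a single concordant pair), and
#' picking the literal maximum would let sampling noise choose among nested
#' candidate gene sets. All grid points whose AUC lies within one
#' Hanley-McNeil standard error of the maximum are treated as equivalent,
#' and the tie breaks toward the *largest* candidate, then the larger
#' conservation threshold, then the smaller p threshold: the most inclusive
#' conserved gene set gives the lowest-variance correlation score, while
#' parsimony is already enforced by the conservation filter itself.
#' Candidates with fewer than `min_genes` genes are skipped.
#'
#' @param archive a `resampling_archive`.
#' @param train_expr `expr_matrix` of the training samples (target tissues).
#' @param train_calls `sensitivity_calls` for the training samples.
#' @param p_grid,fc_grid,cons_grid threshold grids. The defaults bracket the
#'   conventional working point (p 1e-4, fold change 1.25, conservation 0.8).
#' @param min_genes smallest admissible signature (default 5).
#' @param direction_consistent forwarded to [build_candidate()].
#' @return A list with `signature` (the winner, thresholds and training AUC
#'   filled in) and `grid`, a data frame of all grid points
#'   (p_thr, fc_thr, cons_thr, n_genes, train_auc).
#' @export
optimize_signature <- function(archive, train_expr, train_calls,
                               p_grid = c(1e-2, 1e-3, 1e-4, 1e-5),
                               fc_grid = c(1.1, 1.25, 1.5, 2.0),
                               cons_grid = c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95),
                               min_genes = 5L,
                               direction_consistent = TRUE) {
  stopifnot(inherits(archive, "resampling_archive"),
            inherits(train_expr, "expr_matrix"),
            inherits(train_calls, "sensitivity_calls"))
  grid <- expand.grid(p_thr = p_grid, fc_thr = fc_grid,
                      cons_thr = cons_grid, KEEP.OUT.ATTRS = FALSE)
  grid$n_genes <- 0L
  grid$train_auc <- NA_real_

  labels <- train_calls$label[match(colnames(train_expr$values),
                                    train_calls$sample_id)]
  usable <- labels %in% c("responder", "non_responder")
  if (sum(labels[usable] == "responder") < 1L ||
      sum(labels[usable] == "non_responder") < 1L)
    stop("training set needs at least one responder and one non-responder")

  candidates <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cand <- suppressWarnings(
      build_candidate(archive, grid$p_thr[k], grid$fc_thr[k],
                      grid$cons_thr[k], direction_consistent))
    if (is.null(cand)) next
    grid$n_genes[k] <- length(cand$weights)
    if (length(cand$weights) < min_genes) next
    sc <- score_samples(cand, train_expr)
    grid$train_auc[k] <- roc_auc(sc$score[usable],
                                 labels[usable] == "responder")
    candidates[[k]] <- cand
  }

  if (all(is.na(grid$train_auc))) {
    cond <- structure(
      class = c("iraps_optimize_failed", "error", "condition"),
      list(message = paste0(
        "every grid point was skipped: no candidate reached min_genes = ",
        min_genes, " (max candidate size ", max(grid$n_genes),
        "); the archive carries no conserved signal at these thresholds"),
        call = sys.call(-1), grid = grid))
    stop(cond)
  }

  max_auc <- max(grid$train_auc, na.rm = TRUE)
  if (max_auc < 0.5)
    stop("best training AUC ", round(max_auc, 3),
         " is worse than chance; refusing to select a signature")
  se <- auc_se_hanley(max_auc,
                      sum(labels[usable] == "responder"),
                      sum(labels[usable] == "non_responder"))
  near <- which(!is.na(grid$train_auc) &
                  grid$train_auc >= max(max_auc - se, 0.5))
  ord <- near[order(-grid$n_genes[near], -grid$cons_thr[near],
                    grid$p_thr[near], -grid$train_auc[near])]
  pick <- ord[1]

  best <- candidates[[pick]]
  best$training_auc <- grid$train_auc[pick]
  best$provenance <- c(best$provenance,
                       list(n_iterations = ncol(archive$p),
                            seed = archive$seed,
                            fraction = archive$fraction,
                            max_grid_auc = max_auc,
                            auc_se = se))
  list(signature = best, grid = grid)
}

# Hanley-McNeil (1982) standard error of a trapezoid ROC AUC.
auc_se_hanley <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}
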