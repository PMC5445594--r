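#' Score samples against a signature by correlation
#'
#' Each sample's score is the Pearson correlation between the signature's
#' gene weights and that sample's expression over the signature genes, after
#' centering every gene at its cohort median. Centering keeps the score a
#' measure of the sample's *relative* expression pattern; without it absolute
#' expression scale dominates the correlation. Signature genes absent from
#' the matrix are dropped symmetrically and counted.
#'
#' @param sig a [signature()].
#' @param m an `expr_matrix` (log2 scale).
#' @param min_overlap smallest admissible number of shared genes (default 3).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param center center genes at the cohort median first (default `TRUE`).
#' @return A `data.frame` of class `score_vector` with columns `sample_id`,
#'   `score` (in \[-1, 1\]) and `n_genes_used`.
#' @export
score_samples <- function(sig, m, min_overlap = 3L,
                          method = c("pearson", "spearman"),
                          center = TRUE) {
  stopifnot(inherits(sig, "signature"), inherits(m, "expr_matrix"))
  method <- match.arg(method)
  shared <- intersect(names(sig$weights), rownames(m$values))
  if (length(shared) < min_overlap) {
    missing <- setdiff(names(sig$weights), rownames(m$values))
    stop("only ", length(shared), " signature gene(s) present in the ",
         "matrix (min_overlap = ", min_overlap, "); missing: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  x <- m$values[shared, , drop = FALSE]
  if (center) x <- x - apply(x, 1, stats::median)
  w <- sig$weights[shared]
  scores <- as.vector(stats::cor(w, x, method = method))
  structure(data.frame(sample_id = colnames(m$values), score = scores,
                       n_genes_used = length(shared),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("score_vector", "data.frame"),
            n_missing = length(sig$weights) - length(shared))
}

# Trapezoid-rule AUC over the ROC curve, ties grouped. `positive` is a
# logical vector; higher scores are taken to indicate the positive class.
roc_auc <- function(score, positive) {
  roc_points(score, positive)$auc
}

roc_points <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC needs at least one sample in each class")
  o <- order(score, decreasing = TRUE)
  s <- score[o]; y <- positive[o]
  # one ROC point per distinct score value (ties grouped)
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]; fp <- cumsum(!y)[last]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, s[last]), auc = auc)
}

#' Evaluate signature scores against responder labels
#'
#' Builds the ROC curve over responder vs non-responder samples ("neither"
#' excluded), computes the AUC by the trapezoid rule with tied scores
#' grouped, and reports accuracy at a classification threshold chosen by
#' policy: the Youden point (maximizing TPR - FPR, default), a fixed
#' threshold, or the threshold matching the responder prevalence.
#'
#' @param scores a `score_vector` from [score_samples()].
#' @param calls a `sensitivity_calls` data frame for the same samples.
#' @param threshold_policy `"youden"`, `"fixed"` or `"prevalence"`.
#' @param threshold the threshold used when `threshold_policy = "fixed"`
#'   (e.g. a Youden point frozen on the training set).
#' @return A list of class `eval_report`: `auc`, `roc` (data frame of
#'   fpr/tpr/threshold), `accuracy`, `threshold_used` and the confusion
#'   counts (`tp`, `fp`, `tn`, `fn`).
#' @export
evaluate_scores <- function(scores, calls,
                            threshold_policy = c("youden", "fixed",
                                                 "prevalence"),
                            threshold = NULL) {
  stopifnot(inherits(scores, "score_vector"),
            inherits(calls, "sensitivity_calls"))
  threshold_policy <- match.arg(threshold_policy)
  lab <- calls$label[match(scores$sample_id, calls$sample_id)]
  use <- lab %in% c("responder", "non_responder")
  s <- scores$score[use]
  pos <- lab[use] == "responder"
  roc <- roc_points(s, pos)

  thr <- switch(threshold_policy,
    youden = {
      j <- roc$tpr - roc$fpr
      roc$thresholds[which.max(j)]
    },
    fixed = {
      if (is.null(threshold))
        stop("threshold_policy = 'fixed' requires `threshold`")
      threshold
    },
    prevalence = stats::quantile(s, probs = 1 - mean(pos), names = FALSE)
  )
  pred <- s >= thr
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  tn <- sum(!pred & !pos); fn <- sum(!pred & pos)
  structure(list(auc = roc$auc,
                 roc = data.frame(fpr = roc$fpr, tpr = roc$tpr,
                                  threshold = roc$thresholds),
                 accuracy = (tp + tn) / length(s),
                 threshold_used = unname(thr),
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: AUC %.3f, accuracy %.3f at threshold %.4g\n",
              x$auc, x$accuracy, x$threshold_used))
  cat(sprintf("  confusion: TP %d  FP %d  TN %d  FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Signature-stratified drug-sensitivity screen
#'
#' Splits cell lines into a signature-high stratum (score more than one
#' standard deviation above the cohort mean) and a signature-low stratum
#' (score below the mean), then asks, drug by drug, whether sensitivity
#' differs between strata (two-sided Welch test; effect = mean high minus
#' mean low, so a negative effect on an IC50/AUC-type metric means the
#' high-score lines are more sensitive). Drugs whose mean response AUC in the
#' high stratum exceeds `exclude_auc_above` are dropped first — a toxicity
#' filter keeping only drugs with real activity in the signature-high group.
#'
#' @param scores a `score_vector` over the cell lines.
#' @param d a [drug_response_table()].
#' @param exclude_auc_above toxicity-filter cutoff on the mean response value
#'   in the high stratum (default 10; dataset-specific units).
#' @param min_group_size smallest stratum size per drug (default 5).
#' @return A data frame with one row per surviving drug: `drug_id`, `effect`,
#'   `p_value`, `mean_auc_in_high`, `n_high`, `n_low`, ranked by p-value.
#'   Zero surviving drugs yields an empty data frame with an explanatory
#'   `reason` attribute.
#' @export
stratified_drug_screen <- function(scores, d, exclude_auc_above = 10,
                                   min_group_size = 5L) {
  stopifnot(inherits(scores, "score_vector"), inherits(d, "drug_response"))
  mu <- mean(scores$score); sdev <- stats::sd(scores$score)
  high <- scores$sample_id[scores$score > mu + sdev]
  low <- scores$sample_id[scores$score < mu]

  rows <- list()
  dropped <- character()
  for (drug in unique(d$drug_id)) {
    rec <- d[d$drug_id == drug, ]
    vh <- rec$value[rec$sample_id %in% high]
    vl <- rec$value[rec$sample_id %in% low]
    if (length(vh) < min_group_size || length(vl) < min_group_size) {
      dropped <- c(dropped, sprintf("%s (stratum too small)", drug))
      next
    }
    if (mean(vh) > exclude_auc_above) {
      dropped <- c(dropped, sprintf("%s (mean high-stratum AUC %.2f > %g)",
                                    drug, mean(vh), exclude_auc_above))
      next
    }
    tt <- stats::t.test(vh, vl)
    rows[[drug]] <- data.frame(drug_id = drug,
                               effect = mean(vh) - mean(vl),
                               p_value = tt$p.value,
                               mean_auc_in_high = mean(vh),
                               n_high = length(vh), n_low = length(vl),
                               stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(drug_id = character(), effect = numeric(),
                      p_value = numeric(), mean_auc_in_high = numeric(),
                      n_high = integer(), n_low = integer())
    attr(out, "reason") <- paste0("no drug survived the filters: ",
                                  paste(dropped, collapse = "; "))
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$p_value), ]
}
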