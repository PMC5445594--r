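# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# Tiny expression matrix with explicit values.
tiny_expr <- function(values, tissue = "breast", scale = "log2") {
  expression_matrix(values, tissue, scale = scale)
}

# A hand-rolled archive: p and log2_fc as genes x iterations matrices.
fake_archive <- function(p, log2_fc) {
  stopifnot(all(dim(p) == dim(log2_fc)))
  structure(list(p = p, log2_fc = log2_fc,
                 n_resp = rep(10L, ncol(p)), n_nonresp = rep(30L, ncol(p)),
                 genes = rownames(p), seed = 0L, fraction = 0.5,
                 skipped = 0L),
            class = "resampling_archive")
}

# Independent AUC oracle: Mann-Whitney U / (n_pos * n_neg), ties counted 1/2.
auc_u_oracle <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Independent brute-force median polish sweep (mirrors Tukey's algorithm but
# written separately from the implementation under test).
brute_median_polish <- function(x, iter = 10L) {
  overall <- 0; re <- numeric(nrow(x)); ce <- numeric(ncol(x)); r <- x
  for (i in seq_len(iter)) {
    rm_ <- apply(r, 1, median); re <- re + rm_; r <- r - rm_
    overall <- overall + median(ce); ce <- ce - median(ce)
    cm_ <- apply(r, 2, median); ce <- ce + cm_
    r <- sweep(r, 2, cm_)
    overall <- overall + median(re); re <- re - median(re)
  }
  list(overall = overall, row = re, col = ce, residuals = r)
}

# Labeled calls straight from a label vector (bypasses the z-score rules).
calls_from_labels <- function(sample_id, label, z = NULL) {
  if (is.null(z)) z <- numeric(length(sample_id))
  structure(data.frame(sample_id = sample_id, combined_z = z, label = label,
                       z1 = z, stringsAsFactors = FALSE),
            class = c("sensitivity_calls", "data.frame"), drugs = 1L)
}

# Exact median-effect series with no noise.
exact_me_series <- function(Dm, m, doses = Dm * 4^seq(-3, 3), drug = "d",
                            ratio = NULL) {
  r <- (doses / Dm)^m
  dose_response_series(doses, r / (1 + r), drug = drug, ratio = ratio,
                       clamp = 1e-9)
}
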