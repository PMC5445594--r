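# A printed toy archive: 3 genes x 10 iterations.
toy_archive <- function() {
  p <- rbind(
    gA = c(1e-6, 1e-6, 1e-6, 1e-6, 1e-6, 1e-6, 1e-6, 1e-6, 0.5, 0.5),
    gB = c(1e-6, 1e-6, 1e-6, 1e-6, 1e-6, 1e-6, 0.5, 0.5, 0.5, 0.5),
    gC = rep(0.5, 10))
  fc <- rbind(
    gA = c(1, 1.2, 0.8, 1.1, 0.9, 1.0, 1.3, 0.7, 0.0, 0.0),
    gB = c(-1, -1, -1, 1, 1, 1, 0, 0, 0, 0),
    gC = rep(2, 10))
  colnames(p) <- colnames(fc) <- NULL
  fake_archive(p, fc)
}

test_that("conservation fraction counts qualifying iterations", {
  set.seed(41)
  n_it <- 1000
  p <- matrix(0.5, nrow = 2, ncol = n_it,
              dimnames = list(c("hit", "cold"), NULL))
  fc <- matrix(0, nrow = 2, ncol = n_it,
               dimnames = list(c("hit", "cold"), NULL))
  qual <- sample(n_it, 850)
  p["hit", qual] <- 1e-5
  fc["hit", qual] <- 1
  a <- fake_archive(p, fc)
  expect_equal(unname(conservation_fraction(a, "hit", p_thr = 1e-4,
                                            fc_thr = 1.25)), 0.85)
  expect_equal(unname(conservation_fraction(a, "cold", p_thr = 1e-4,
                                            fc_thr = 1.25)), 0)
})

test_that("the majority-sign rule discounts direction-flipping iterations", {
  n_it <- 1000
  p <- matrix(1e-5, nrow = 1, ncol = n_it, dimnames = list("flip", NULL))
  fc <- matrix(0, nrow = 1, ncol = n_it, dimnames = list("flip", NULL))
  fc[1, 1:600] <- 1    # 600 qualifying up
  fc[1, 601:900] <- -1 # 300 qualifying down
  p[1, 901:1000] <- 0.5 # 100 not qualifying at all
  a <- fake_archive(p, fc)
  expect_equal(unname(conservation_fraction(a, "flip", 1e-4, 1.25)), 0.6)
  expect_equal(unname(conservation_fraction(a, "flip", 1e-4, 1.25,
                                            direction_consistent = FALSE)),
               0.9)
})

test_that("candidate weights average the fold change over qualifying runs", {
  a <- toy_archive()
  # gA qualifies (p<1e-4, |fc|>log2(1.25)=0.32) in iterations 1:8 except
  # those with |fc| <= 0.32: none of 1:8 (min |fc| 0.7) -> 8/10
  sig <- build_candidate(a, p_thr = 1e-4, fc_thr = 1.25, cons_thr = 0.8)
  expect_equal(sig$weights[["gA"]], mean(c(1, 1.2, 0.8, 1.1, 0.9, 1, 1.3,
                                           0.7)))
  expect_false("gB" %in% names(sig$weights)) # sign-split 3 up / 3 down
  expect_false("gC" %in% names(sig$weights)) # never significant
})

test_that("a gene qualifying in all iterations has weight = its fold change", {
  p <- matrix(1e-9, 1, 10, dimnames = list("g", NULL))
  fc <- matrix(1, 1, 10, dimnames = list("g", NULL))
  sig <- build_candidate(fake_archive(p, fc), 1e-4, 1.25, 1.0)
  expect_equal(sig$weights[["g"]], 1.0)
})

test_that("conservation threshold 1.0 excludes a 999/1000 gene", {
  p <- matrix(1e-9, 1, 1000, dimnames = list("g", NULL))
  fc <- matrix(1, 1, 1000, dimnames = list("g", NULL))
  p[1, 1000] <- 0.9
  expect_warning(out <- build_candidate(fake_archive(p, fc), 1e-4, 1.25, 1),
                 "no gene conserved")
  expect_null(out)
})

test_that("build_candidate matches a brute-force enumeration oracle", {
  a <- toy_archive()
  grid <- expand.grid(p_thr = c(1e-4, 0.6), fc_thr = c(1.25, 1.8),
                      cons_thr = c(0.5, 0.8, 1.0))
  for (k in seq_len(nrow(grid))) {
    p_thr <- grid$p_thr[k]; fc_thr <- grid$fc_thr[k]
    cons_thr <- grid$cons_thr[k]
    # oracle: explicit loops over genes and iterations
    expected <- list()
    for (g in rownames(a$p)) {
      qual <- which(a$p[g, ] < p_thr & abs(a$log2_fc[g, ]) > log2(fc_thr))
      if (!length(qual)) next
      sgn <- sign(a$log2_fc[g, qual])
      maj <- if (sum(sgn > 0) >= sum(sgn < 0)) 1 else -1
      qual <- qual[sgn == maj]
      if (length(qual) / ncol(a$p) >= cons_thr)
        expected[[g]] <- mean(a$log2_fc[g, qual])
    }
    got <- suppressWarnings(build_candidate(a, p_thr, fc_thr, cons_thr))
    if (!length(expected)) {
      expect_null(got)
    } else {
      expect_mapequal(as.list(got$weights), expected)
    }
  }
})

test_that("raising the conservation threshold never adds genes", {
  set.seed(42)
  p <- matrix(runif(50 * 30), 50, 30,
              dimnames = list(paste0("g", 1:50), NULL))
  fc <- matrix(rnorm(50 * 30), 50, 30,
               dimnames = list(paste0("g", 1:50), NULL))
  a <- fake_archive(p, fc)
  prev <- NULL
  for (ct in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    sig <- suppressWarnings(build_candidate(a, 0.5, 1.1, ct))
    genes <- if (is.null(sig)) character() else names(sig$weights)
    if (!is.null(prev)) expect_true(all(genes %in% prev))
    prev <- genes
  }
})

test_that("a single-point grid returns exactly that candidate", {
  p <- generate_panel(n_genes = 200, n_samples = 120, n_planted = 15,
                      seed = 43)
  a <- run_resampling(p$expr, p$response, "drugA", iterations = 20,
                      seed = 44)
  calls <- call_single(zscore_sensitivity(p$response, "drugA"))
  res <- optimize_signature(a, p$expr, calls, p_grid = 1e-3,
                            fc_grid = 1.25, cons_grid = 0.6)
  direct <- build_candidate(a, 1e-3, 1.25, 0.6)
  expect_equal(res$signature$weights, direct$weights)
  expect_equal(nrow(res$grid), 1L)
})

test_that("optimization recovers planted genes with high training AUC", {
  p <- generate_panel(n_genes = 500, n_samples = 160, n_planted = 30,
                      effect_size = 1.2, seed = 45)
  a <- run_resampling(p$expr, p$response, "drugA", iterations = 50,
                      seed = 46)
  calls <- call_single(zscore_sensitivity(p$response, "drugA"))
  res <- optimize_signature(a, p$expr, calls)
  recovered <- intersect(names(res$signature$weights),
                         p$truth$planted_genes)
  expect_gte(length(recovered), 0.8 * 30)
  expect_gte(res$signature$training_auc, 0.9)
  # signs match the ground-truth direction of association
  expect_equal(sign(res$signature$weights[recovered]),
               p$truth$expected_weight_sign[recovered])
})

test_that("permuted labels cannot produce a confident signature", {
  p <- generate_panel(n_genes = 400, n_samples = 100, n_planted = 20,
                      effect_size = 1.2, seed = 47)
  a <- run_resampling(p$expr, p$response, "drugA", iterations = 30,
                      seed = 48)
  z <- zscore_sensitivity(p$response, "drugA")
  set.seed(49)
  names(z) <- sample(names(z)) # break the score-sample link
  calls <- call_single(z)
  res <- tryCatch(optimize_signature(a, p$expr, calls),
                  iraps_optimize_failed = function(e) NULL,
                  error = function(e) NULL)
  if (!is.null(res)) expect_lte(res$signature$training_auc, 0.75)
  else succeed("no grid point produced an admissible candidate")
})

test_that("stored training AUC survives signature serialization", {
  p <- generate_panel(n_genes = 300, n_samples = 120, n_planted = 20,
                      seed = 50)
  a <- run_resampling(p$expr, p$response, "drugA", iterations = 25,
                      seed = 51)
  calls <- call_single(zscore_sensitivity(p$response, "drugA"))
  res <- optimize_signature(a, p$expr, calls)
  path <- withr::local_tempfile(fileext = ".json")
  write_signature(res$signature, path)
  back <- read_signature(path)
  sc <- score_samples(back, p$expr)
  lab <- calls$label[match(sc$sample_id, calls$sample_id)]
  use <- lab %in% c("responder", "non_responder")
  rescored <- evaluate_scores(sc, calls)
  expect_equal(rescored$auc, res$signature$training_auc, tolerance = 1e-12)
  expect_true(all(use | lab == "neither"))
})
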