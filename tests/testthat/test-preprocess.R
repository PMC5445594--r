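test_that("log2 transform applies the offset and flips the scale flag", {
  v <- matrix(c(8, 0, 3, 1), nrow = 2,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  m <- tiny_expr(v, scale = "raw")
  out <- log2_transform(m, offset = 0 + 1)
  expect_equal(out$values["gA", "s1"], log2(9))
  expect_equal(out$scale, "log2")

  m8 <- tiny_expr(matrix(8, 2, 2, dimnames = list(c("a", "b"),
                                                  c("x", "y"))),
                  scale = "raw")
  expect_equal(log2_transform(m8, offset = 0)$values[1, 1], 3)

  m0 <- tiny_expr(matrix(c(0, 1, 2, 3), 2,
                         dimnames = list(c("a", "b"), c("x", "y"))),
                  scale = "raw")
  expect_equal(log2_transform(m0, offset = 1)$values["a", "x"], 0)
  expect_error(log2_transform(m0, offset = 0), "nonpositive")
  expect_error(log2_transform(log2_transform(m0)), "raw-scale")
})

test_that("quantile normalization maps two columns to their rank means", {
  v <- matrix(c(1, 3, 2, 4), nrow = 2,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  out <- quantile_normalize(tiny_expr(v))
  expect_equal(unname(out$values[, "s1"]), c(1.5, 3.5))
  expect_equal(unname(out$values[, "s2"]), c(1.5, 3.5))
})

test_that("quantile normalization is idempotent and fixes identical columns", {
  set.seed(11)
  v <- matrix(rnorm(60), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  m <- tiny_expr(v)
  once <- quantile_normalize(m)
  twice <- quantile_normalize(once)
  expect_equal(twice$values, once$values, tolerance = 1e-12)

  same <- tiny_expr(matrix(rep(sort(rnorm(10)), 3), nrow = 10,
                           dimnames = list(paste0("g", 1:10),
                                           paste0("s", 1:3))))
  expect_equal(quantile_normalize(same)$values, same$values)
})

test_that("quantile normalization preserves within-column rank order", {
  set.seed(12)
  for (rep in 1:5) {
    v <- matrix(rnorm(200), nrow = 40,
                dimnames = list(paste0("g", 1:40), paste0("s", 1:5)))
    out <- quantile_normalize(tiny_expr(v))$values
    for (j in 1:5)
      expect_equal(order(out[, j]), order(v[, j]))
  }
})

test_that("quantile normalization matches the limma oracle on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(13)
  v <- matrix(rnorm(500), nrow = 50,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
  ours <- quantile_normalize(tiny_expr(v))$values
  ref <- limma::normalizeQuantiles(v)
  expect_equal(unname(ours), unname(as.matrix(ref)), tolerance = 1e-10)
})

test_that("tied values receive the mean reference value of their tied ranks", {
  # column s1 has a tie at 2; reference = rowMeans of sorted columns
  v <- matrix(c(2, 2, 5, 1, 3, 6), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  ref <- rowMeans(cbind(sort(v[, 1]), sort(v[, 2])))
  out <- quantile_normalize(tiny_expr(v))$values
  expect_equal(unname(out[1:2, "s1"]), rep(mean(ref[1:2]), 2))
  expect_equal(unname(out[3, "s1"]), unname(ref[3]))
})

test_that("single-sample quantile normalization warns and passes through", {
  m <- tiny_expr(matrix(1:3, ncol = 1,
                        dimnames = list(paste0("g", 1:3), "s1")))
  expect_warning(out <- quantile_normalize(m), "single-sample")
  expect_equal(out$values, m$values)
})

test_that("median polish reconstructs the input exactly", {
  set.seed(14)
  for (rep in 1:5) {
    x <- matrix(rnorm(48), nrow = 8)
    dimnames(x) <- list(paste0("g", 1:8), paste0("s", 1:6))
    mp <- median_polish(x, max_iter = 10)
    recon <- mp$overall + outer(unname(mp$row_effects),
                                unname(mp$col_effects), "+") + mp$residuals
    expect_lt(max(abs(x - recon)), 1e-9)
    expect_lt(abs(median(mp$row_effects)), 1e-9)
    expect_lt(abs(median(mp$col_effects)), 1e-9)
  }
})

test_that("exactly additive matrices polish to zero residuals", {
  r <- c(1, 4, -2)
  cc <- c(0.5, -1, 2, 3)
  x <- outer(r, cc, "+")
  dimnames(x) <- list(paste0("g", 1:3), paste0("s", 1:4))
  mp <- median_polish(x)
  expect_lt(max(abs(mp$residuals)), 1e-12)

  const <- matrix(7, 3, 3, dimnames = list(paste0("g", 1:3),
                                           paste0("s", 1:3)))
  mpc <- median_polish(const)
  expect_equal(mpc$overall, 7)
  expect_lt(max(abs(mpc$row_effects)), 1e-12)
  expect_lt(max(abs(mpc$col_effects)), 1e-12)
  expect_lt(max(abs(mpc$residuals)), 1e-12)
})

test_that("median polish agrees with an independent sweep and stats::medpolish", {
  x <- matrix(c(1, 3, 2, 5), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  mp <- median_polish(x)
  oracle <- brute_median_polish(x)
  expect_equal(unname(mp$residuals), unname(oracle$residuals),
               tolerance = 1e-12)
  expect_equal(mp$overall, oracle$overall, tolerance = 1e-12)

  set.seed(15)
  y <- matrix(rnorm(35), nrow = 7,
              dimnames = list(paste0("g", 1:7), paste0("s", 1:5)))
  ref <- stats::medpolish(y, eps = 1e-9, maxiter = 50, trace.iter = FALSE)
  ours <- median_polish(y, max_iter = 50, tol = 1e-9)
  expect_equal(unname(ours$residuals), unname(ref$residuals),
               tolerance = 1e-6)
})

test_that("per-tissue preprocessing centers genes within tissue", {
  set.seed(16)
  n <- 40
  v <- matrix(rnorm(20 * n), nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:n)))
  tissue <- setNames(rep(c("breast", "ovary"), each = n / 2),
                     colnames(v))
  # give the two tissues very different gene baselines
  v[, tissue == "ovary"] <- v[, tissue == "ovary"] + (1:20)
  out <- preprocess_per_tissue(tiny_expr(v, tissue = tissue))
  for (tis in c("breast", "ovary")) {
    rm_ <- rowMeans(out$values[, tissue == tis])
    expect_lt(max(abs(rm_)), 0.75) # baselines of up to 20 are gone
  }
})

test_that("a tissue whose samples are identical maps to zero", {
  v <- matrix(rep(c(1, 5, 3), 4), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  out <- preprocess_per_tissue(tiny_expr(v, tissue = "breast"))
  expect_lt(max(abs(out$values)), 1e-12)
})

test_that("per-tissue preprocessing composes quantile normalization and polish", {
  set.seed(17)
  v <- matrix(rnorm(15 * 9), nrow = 15,
              dimnames = list(paste0("g", 1:15), paste0("s", 1:9)))
  tissue <- setNames(rep(c("a", "b", "c"), each = 3), colnames(v))
  out <- preprocess_per_tissue(tiny_expr(v, tissue = tissue))
  for (tis in unique(tissue)) {
    cols <- which(tissue == tis)
    qn <- quantile_normalize(tiny_expr(v[, cols], tissue = "x"))$values
    mp <- median_polish(qn)
    manual <- mp$residuals + matrix(mp$col_effects, nrow = nrow(qn),
                                    ncol = ncol(qn), byrow = TRUE)
    expect_equal(unname(out$values[, cols]), unname(manual),
                 tolerance = 1e-12)
  }
})

test_that("per-tissue output is invariant to sample order within tissue", {
  set.seed(18)
  v <- matrix(rnorm(10 * 8), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  tissue <- setNames(rep(c("a", "b"), each = 4), colnames(v))
  out1 <- preprocess_per_tissue(tiny_expr(v, tissue = tissue))
  perm <- c(3, 1, 4, 2, 7, 8, 5, 6)
  out2 <- preprocess_per_tissue(tiny_expr(v[, perm],
                                          tissue = tissue[perm]))
  expect_equal(out1$values[, colnames(v)],
               out2$values[, colnames(v)], tolerance = 1e-12)

  single <- preprocess_per_tissue(
    tiny_expr(v, tissue = setNames(c(rep("a", 7), "lone"), colnames(v))))
  expect_equal(unname(single$values[, "s8"]), rep(0, 10))
})
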