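test_that("total-count normalization rescales rows to the target sum", {
  m <- modality_table(matrix(c(1, 1, 2,
                               0, 0, 0,
                               3, 3, 4), 3, 3, byrow = TRUE),
                      paste0("c", 1:3), c("A", "B", "A"))
  out <- normalize_total(m, target_sum = 1e4)
  expect_equal(out$values[1, ], c(2500, 2500, 5000))
  expect_equal(out$values[2, ], c(0, 0, 0))  # all-zero row untouched
  rs <- rowSums(out$values)[c(1, 3)]
  expect_true(all(abs(rs - 1e4) / 1e4 < 1e-6))
  neg <- m; neg$values[1, 1] <- -1
  expect_error(normalize_total(neg), "nonnegative")
})

test_that("log1p transform has its closed-form values and is monotone", {
  m <- modality_table(matrix(c(0, exp(1) - 1, 2, 7), 2, 2),
                      c("c1", "c2"), c("A", "B"))
  out <- log1p_transform(m)
  expect_equal(out$values[1, 1], 0)
  expect_equal(out$values[2, 1], 1)
  x <- sort(stats::runif(50, 0, 100))
  mt <- modality_table(matrix(x, 1, 50), "c1", "A")
  expect_true(all(diff(log1p_transform(mt)$values[1, ]) > 0))
})

test_that("fit_scale centers and scales with population variance", {
  m <- modality_table(cbind(c(1, 2, 3), c(5, 5, 5)),
                      paste0("c", 1:3), c("A", "A", "B"))
  sc <- fit_scale(m)
  out <- apply_transform(sc, m)
  # population sd of (1,2,3) is sqrt(2/3); 1 -> (1-2)/sqrt(2/3)
  expect_equal(out$values[, 1], c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-7)
  expect_equal(out$values[, 1], c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  # zero-variance column: centered, unit divisor, no NaN
  expect_equal(out$values[, 2], c(0, 0, 0))
  expect_false(anyNA(out$values))
  expect_error(fit_scale(tiny_table(1, 2)), "at least 2")
})

test_that("scaled training data has mean 0 and unit population variance", {
  m <- tiny_table(40, 6, seed = 5)
  out <- apply_transform(fit_scale(m), m)
  expect_true(all(abs(colMeans(out$values)) < 1e-8))
  v <- colMeans(sweep(out$values, 2, colMeans(out$values))^2)
  nonconst <- apply(m$values, 2, function(x) length(unique(x)) > 1)
  expect_true(all(abs(v[nonconst] - 1) < 1e-6))
})

test_that("fit_pca reproduces the covariance eigendecomposition subspace", {
  withr::local_seed(11)
  m <- modality_table(matrix(rnorm(5 * 3), 5, 3), paste0("c", 1:5),
                      rep(c("A", "B"), length.out = 5))
  pc <- fit_pca(m, 3)
  rot <- pc$stats$rotation
  # orthonormal loadings
  expect_equal(crossprod(rot), diag(3), tolerance = 1e-8)
  # same subspace as the covariance eigenvectors: principal angles ~ 0
  xc <- sweep(m$values, 2, colMeans(m$values))
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)$vectors
  angles <- acos(pmin(1, svd(crossprod(ev, rot))$d))
  expect_true(all(angles < 1e-6))
  # explained variance non-increasing
  expect_true(all(diff(pc$stats$explained_variance) <= 1e-12))
})

test_that("full-rank PCA reconstructs centered data; errors when too large", {
  withr::local_seed(12)
  m <- modality_table(matrix(rnorm(8 * 4), 8, 4), paste0("c", 1:8),
                      rep(c("A", "B"), 4))
  pc <- fit_pca(m, 4)
  proj <- apply_transform(pc, m)$values
  xc <- sweep(m$values, 2, colMeans(m$values))
  expect_equal(proj %*% t(pc$stats$rotation), xc, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(fit_pca(m, 5), "n_components")
})

test_that("PCA component signs are deterministic", {
  withr::local_seed(13)
  m <- modality_table(matrix(rnorm(20 * 5), 20, 5), paste0("c", 1:20),
                      rep(c("A", "B"), 10))
  pc <- fit_pca(m, 4)
  for (j in 1:4) {
    col <- pc$stats$rotation[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
})

test_that("transforms use training statistics only (no refitting)", {
  train <- tiny_table(20, 4, seed = 21)
  # held-out set with a deliberately shifted mean
  test <- tiny_table(10, 4, seed = 22)
  test$values <- test$values + 50
  sc_train <- fit_scale(train)
  both <- modality_table(rbind(train$values, test$values),
                         paste0("c", 1:30), rep("A", 30))
  sc_both <- fit_scale(both)
  # refit on train+test differs from train-only on this shifted example
  expect_false(isTRUE(all.equal(sc_train$stats$mean, sc_both$stats$mean)))
  # applying the train-fitted transform to test cells uses train stats:
  out <- apply_transform(sc_train, test)
  manual <- sweep(sweep(test$values, 2, sc_train$stats$mean),
                  2, sc_train$stats$sd, "/")
  expect_equal(out$values, manual)
  # single held-out cell embeds without refit
  one <- subset_cells(test, 1)
  expect_equal(apply_transform(sc_train, one)$values, manual[1, , drop = FALSE])
  # fitted statistics are not mutated by application
  expect_identical(sc_train$stats$mean, fit_scale(train)$stats$mean)
  # dimension mismatch is an error
  expect_error(apply_transform(sc_train, tiny_table(5, 3)), "dimension")
})

test_that("the fitted chain records fitted_on and caps n_pcs at the rank", {
  train <- tiny_table(15, 6, seed = 31)
  expect_message(
    prep <- fit_preprocess(train, preprocess_config(n_pcs = 50)),
    "capped")
  expect_equal(prep$fitted_on, 15)
  expect_equal(preprocess_dim(prep), 6)
  out <- apply_preprocess(prep, train)
  expect_equal(ncol(out$values), 6)
  # config can skip count steps for pre-normalized inputs
  prep2 <- fit_preprocess(train, preprocess_config(normalize = FALSE,
                                                   log1p = FALSE, n_pcs = 3))
  expect_equal(preprocess_dim(prep2), 3)
})
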