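test_that("recall@k boundary behavior: identity embeddings and k = N", {
  pair <- random_embedding_pair(20, 6, seed = 1)
  self <- list(e1 = pair$e1,
               e2 = embedding_set(pair$e1$vectors, pair$e1$cell_ids,
                                  pair$e1$cell_types, "m2"))
  expect_equal(recall_at_k(self$e1, self$e2, 1), 1.0)
  expect_equal(recall_at_k(pair$e1, pair$e2, 20), 1.0)
  expect_error(recall_at_k(pair$e1, pair$e2, 0), ">= 1")
  expect_warning(r <- recall_at_k(pair$e1, pair$e2, 50), "clipped")
  expect_equal(r, 1.0)
})

test_that("rank metrics reject unpaired inputs", {
  pair <- random_embedding_pair(10, 4, seed = 2)
  shuffled <- embedding_set(pair$e2$vectors, rev(pair$e2$cell_ids),
                            rev(pair$e2$cell_types), "m2")
  expect_error(recall_at_k(pair$e1, shuffled, 2), "paired")
  expect_error(median_rank(pair$e1, shuffled), "paired")
})

test_that("retrieval metrics match exhaustive brute-force oracles", {
  for (seed in 1:15) {
    pair <- random_embedding_pair(30, 5, n_types = 4, seed = seed)
    k <- sample(1:10, 1)
    expect_equal(recall_at_k(pair$e1, pair$e2, k),
                 oracle_recall_at_k(pair$e1, pair$e2, k))
    expect_equal(cell_type_at_k(pair$e1, pair$e2, k),
                 oracle_cell_type_at_k(pair$e1, pair$e2, k),
                 tolerance = 1e-12)
    mr <- median_rank(pair$e1, pair$e2)
    expect_equal(mr$raw, oracle_median_rank(pair$e1, pair$e2))
    expect_equal(mr$normalized, mr$raw / 30)
  }
})

test_that("cell_type_at_k(k = 1) is identically cell_type_accuracy", {
  for (seed in 1:10) {
    pair <- random_embedding_pair(25, 4, n_types = 3, seed = 100 + seed)
    expect_identical(cell_type_accuracy(pair$e1, pair$e2),
                     cell_type_at_k(pair$e1, pair$e2, 1))
  }
})

test_that("recall@k is non-decreasing in k and hits 1 at k = N", {
  pair <- random_embedding_pair(40, 6, seed = 3)
  vals <- vapply(1:40, function(k) recall_at_k(pair$e1, pair$e2, k),
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[40], 1.0)
})

test_that("median rank has the stated best and worst cases", {
  # identical matrices: every rank 1
  pair <- random_embedding_pair(15, 5, seed = 4)
  self2 <- embedding_set(pair$e1$vectors, pair$e1$cell_ids,
                         pair$e1$cell_types, "m2")
  mr <- median_rank(pair$e1, self2)
  expect_equal(mr$raw, 1)
  expect_equal(mr$normalized, 1 / 15)
  # crafted worst case on the 1-sphere in 2D: reference rotated so the match
  # is always antipodal, hence the farthest of all references
  n <- 8
  ang <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  q <- cbind(cos(ang), sin(ang))
  r <- -q  # antipodes
  ids <- paste0("c", 1:n); lab <- rep(c("A", "B"), n / 2)
  mr2 <- median_rank(embedding_set(q, ids, lab, "m1"),
                     embedding_set(r, ids, lab, "m2"))
  expect_equal(mr2$raw, n)
})

test_that("single-type and perfectly separated cases give cell type@k = 1", {
  withr::local_seed(5)
  v <- matrix(rnorm(20 * 4), 20, 4); v <- v / sqrt(rowSums(v^2))
  one <- embedding_set(v, paste0("c", 1:20), rep("A", 20), "m1")
  two <- embedding_set(v[sample(20), ], paste0("c", 1:20), rep("A", 20), "m2")
  expect_equal(cell_type_at_k(one, two, 5), 1.0)
  # two tight clusters at orthogonal anchors, k below cluster size
  emb <- generate_eval_embeddings(30, 5, 2, noise = 0.01, seed = 6)
  expect_equal(cell_type_at_k(emb$mod1, emb$mod2, 3), 1.0)
  expect_equal(cell_type_accuracy(emb$mod1, emb$mod2), 1.0)
})

test_that("joint embeddings concatenate or stack as requested", {
  pair <- random_embedding_pair(3, 128, seed = 7)
  j <- build_joint_embedding(pair$e1, pair$e2, matched = TRUE)
  expect_equal(dim(j), c(3, 256))
  expect_identical(attr(j, "cell_ids"), pair$e1$cell_ids)
  other <- random_embedding_pair(5, 128, seed = 8)
  j2 <- build_joint_embedding(pair$e1, other$e2, matched = FALSE)
  expect_equal(dim(j2), c(8, 128))
  expect_error(build_joint_embedding(pair$e1, other$e2, matched = TRUE),
               "same cells")
})

test_that("normalized ASW applies the affine map and matches the oracle", {
  # boundary map via direct arithmetic on the formula
  expect_equal((-1 + 1) / 2, 0)
  expect_equal((0 + 1) / 2, 0.5)
  expect_equal((1 + 1) / 2, 1)
  # two tight, far-separated clusters score near 1
  withr::local_seed(9)
  x <- rbind(matrix(rnorm(40, 0, 0.05), 20, 2),
             matrix(rnorm(40, 10, 0.05), 20, 2))
  labs <- rep(c("A", "B"), each = 20)
  expect_gt(asw_normalized(x, labs), 0.9)
  # random instances match the from-scratch silhouette implementation
  for (seed in 1:5) {
    withr::local_seed(200 + seed)
    y <- matrix(rnorm(60 * 3), 60, 3)
    l <- sample(c("A", "B", "C"), 60, replace = TRUE)
    expect_equal(asw_normalized(y, l), (oracle_asw(y, l) + 1) / 2,
                 tolerance = 1e-8)
  }
  expect_error(asw_normalized(x, rep("A", 40)), "2 distinct")
})

test_that("all metrics are invariant under a common orthogonal rotation", {
  withr::local_seed(10)
  pair <- random_embedding_pair(25, 6, seed = 11)
  q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  rot <- function(e) embedding_set(e$vectors %*% q, e$cell_ids,
                                   e$cell_types, e$modality_name)
  r1 <- rot(pair$e1); r2 <- rot(pair$e2)
  expect_equal(recall_at_k(r1, r2, 5), recall_at_k(pair$e1, pair$e2, 5))
  expect_equal(cell_type_at_k(r1, r2, 5),
               cell_type_at_k(pair$e1, pair$e2, 5))
  expect_equal(median_rank(r1, r2)$raw, median_rank(pair$e1, pair$e2)$raw)
  expect_equal(
    asw_normalized(build_joint_embedding(r1, r2)),
    asw_normalized(build_joint_embedding(pair$e1, pair$e2)),
    tolerance = 1e-10)
})

test_that("evaluate_embeddings reports both directions in long format", {
  pair <- random_embedding_pair(30, 5, seed = 12)
  tbl <- evaluate_embeddings(pair$e1, pair$e2, paired = TRUE,
                             k_grid = c(5, 10))
  expect_s3_class(tbl, "tbl_df")
  expect_named(tbl, c("direction", "metric", "k", "value"))
  expect_setequal(unique(tbl$direction), c("1to2", "2to1", "joint"))
  # recall and cell type@k at both k values in both directions
  expect_equal(sum(tbl$metric == "recall_at_k"), 4)
  expect_equal(sum(tbl$metric == "cell_type_at_k"), 4)
  expect_equal(sum(tbl$metric == "asw_normalized"), 1)
  # unpaired evaluation drops the rank-based metrics
  tbl2 <- evaluate_embeddings(pair$e1, pair$e2, paired = FALSE,
                              k_grid = c(5))
  expect_false(any(tbl2$metric %in% c("recall_at_k", "median_rank_raw")))
  expect_true("cell_type_accuracy" %in% tbl2$metric)
})
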