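make_paired <- function(labels, p = 4, q = 3, seed = 1) {
  n <- length(labels)
  withr::with_seed(seed, {
    paired_dataset(
      modality_table(matrix(rnorm(n * p), n, p), paste0("c", 1:n), labels,
                     modality_name = "m1"),
      modality_table(matrix(rnorm(n * q), n, q), paste0("c", 1:n), labels,
                     modality_name = "m2")
    )
  })
}

test_that("paired epoch plans use every cell once and keep types distinct", {
  pd <- make_paired(c("A", "A", "B", "B", "C", "C"))
  withr::with_seed(1, {
    plan <- plan_paired_epoch(pd)
    expect_length(plan, 2)  # max type count
    used <- unlist(lapply(plan, `[[`, "idx1"))
    expect_setequal(used, 1:6)  # every cell exactly once here
    for (b in plan) {
      expect_false(anyDuplicated(b$types) > 0)
      expect_identical(b$idx1, b$idx2)  # paired mode: same cell both sides
      expect_identical(pd$mod1$cell_types[b$idx1], b$types)
    }
  })
})

test_that("imbalanced types are topped up with replacement", {
  pd <- make_paired(c("A", "A", "A", "B"))
  withr::with_seed(2, {
    plan <- plan_paired_epoch(pd)
    expect_length(plan, 3)  # largest type count
    a_cells <- unlist(lapply(plan, function(b) b$idx1[b$types == "A"]))
    b_cells <- unlist(lapply(plan, function(b) b$idx1[b$types == "B"]))
    expect_setequal(a_cells, 1:3)          # each A cell once
    expect_identical(unique(b_cells), 4L)  # the single B cell reappears
  })
  expect_error(plan_paired_epoch(make_paired(rep("A", 4))), "2 cell types")
})

test_that("unpaired plans pair same-type cells from different modalities", {
  m1 <- modality_table(matrix(rnorm(8), 4, 2), paste0("x", 1:4),
                       c("A", "B", "A", "B"), modality_name = "m1")
  m2 <- modality_table(matrix(rnorm(9), 3, 3), paste0("y", 1:3),
                       c("B", "A", "C"), modality_name = "m2")
  ud <- unpaired_dataset(m1, m2)
  withr::with_seed(3, {
    expect_warning(plan <- plan_unpaired_epoch(ud), "excluded.*C")
    for (b in plan) {
      expect_identical(ud$mod1$cell_types[b$idx1], b$types)
      expect_identical(ud$mod2$cell_types[b$idx2], b$types)
      # positives are always different physical cells
      expect_false(any(ud$mod1$cell_ids[b$idx1] == ud$mod2$cell_ids[b$idx2]))
    }
  })
})

test_that("the early-stopping rule fires exactly on schedule", {
  # constant losses: first epoch sets the best, then patience epochs of stall
  expect_equal(early_stop_epoch(rep(1, 150), patience = 10, min_delta = 1e-4),
               11)
  # strictly improving by more than min_delta: never stops
  expect_equal(early_stop_epoch(seq(5, by = -0.01, length.out = 150),
                                patience = 10, min_delta = 1e-4), 150)
  # a late improvement resets the stall counter: last real improvement at
  # epoch 20, then exactly patience stalled epochs
  losses <- c(seq(5, by = -2e-4, length.out = 20), rep(4.9962, 10))
  expect_equal(early_stop_epoch(losses, patience = 10, min_delta = 1e-4), 30)
  # improvements relative to the running best that never exceed min_delta
  # do not reset the counter
  expect_equal(early_stop_epoch(c(5, 5 - 5e-5, rep(5 - 9e-5, 20)),
                                patience = 10, min_delta = 1e-4), 11)
  # never stops before the stall reaches patience
  expect_equal(early_stop_epoch(rep(1, 5), patience = 10), 5)
})

test_that("training is deterministic given a seed and loss decreases", {
  syn <- generate_paired(synthetic_spec(n_cells = 120, n_types = 3, p = 20,
                                        q = 15, latent_dim = 5,
                                        separation = 6, seed = 4))
  cfg <- train_config(max_epochs = 8, seed = 9, learning_rate = 1e-3)
  prep <- preprocess_config(normalize = FALSE, log1p = FALSE, n_pcs = 10)
  f1 <- fit_modalign(syn$dataset, prep, prep, hidden_dim = 32,
                     latent_dim = 16, config = cfg)
  f2 <- fit_modalign(syn$dataset, prep, prep, hidden_dim = 32,
                     latent_dim = 16, config = cfg)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$enc1$W1, f2$enc1$W1)
  expect_lt(tail(f1$loss_history, 1), f1$loss_history[1])
})

test_that("hold-out embedding is deterministic and per-cell independent", {
  syn <- generate_paired(synthetic_spec(n_cells = 80, n_types = 3, p = 15,
                                        q = 12, latent_dim = 4, seed = 5))
  split <- make_split(80, 0.25, seed = 1)
  train <- subset_cells(syn$dataset, split$train)
  test <- subset_cells(syn$dataset, split$test)
  prep <- preprocess_config(normalize = FALSE, log1p = FALSE, n_pcs = 8)
  fit <- fit_modalign(train, prep, prep, hidden_dim = 16, latent_dim = 8,
                      config = train_config(max_epochs = 3, seed = 2))
  e1 <- embed_holdout(fit, test)
  e2 <- embed_holdout(fit, test)
  expect_identical(e1$mod1$vectors, e2$mod1$vectors)
  # a single test cell can be embedded (evaluation-mode batch norm)
  one <- embed_modality(fit, subset_cells(test$mod1, 1), which = 1)
  expect_equal(dim(one$vectors), c(1, 8))
  # embeddings are unchanged when other test cells are removed
  sub <- embed_holdout(fit, subset_cells(test, 1:3))
  expect_equal(sub$mod1$vectors, e1$mod1$vectors[1:3, ], ignore_attr = TRUE)
  expect_equal(one$vectors[1, ], e1$mod1$vectors[1, ])
})

test_that("mutating the hold-out set leaves fitted statistics and weights unchanged", {
  syn <- generate_paired(synthetic_spec(n_cells = 100, n_types = 3, p = 15,
                                        q = 12, latent_dim = 4, seed = 6))
  split <- make_split(100, 0.3, seed = 3)
  train <- subset_cells(syn$dataset, split$train)
  prep <- preprocess_config(normalize = FALSE, log1p = FALSE, n_pcs = 8)
  cfg <- train_config(max_epochs = 3, seed = 4)
  fit_a <- fit_modalign(train, prep, prep, hidden_dim = 16, latent_dim = 8,
                        config = cfg)
  # rebuild the dataset with garbage in the hold-out rows; training rows same
  mutated <- syn$dataset
  mutated$mod1$values[split$test, ] <- 999
  mutated$mod2$values[split$test, ] <- -999
  fit_b <- fit_modalign(subset_cells(mutated, split$train), prep, prep,
                        hidden_dim = 16, latent_dim = 8, config = cfg)
  expect_identical(fit_a$enc1, fit_b$enc1)
  expect_identical(fit_a$enc2, fit_b$enc2)
  expect_identical(fit_a$prep1$steps, fit_b$prep1$steps)
  expect_identical(fit_a$loss_history, fit_b$loss_history)
})

test_that("the model bundle round-trips through disk", {
  syn <- generate_paired(synthetic_spec(n_cells = 60, n_types = 2, p = 10,
                                        q = 10, latent_dim = 3, seed = 7))
  prep <- preprocess_config(normalize = FALSE, log1p = FALSE, n_pcs = 5)
  fit <- fit_modalign(syn$dataset, prep, prep, hidden_dim = 8, latent_dim = 4,
                      config = train_config(max_epochs = 2, seed = 5))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model_bundle(fit, path)
  back <- load_model_bundle(path)
  emb_a <- embed_holdout(fit, syn$dataset)
  emb_b <- embed_holdout(back, syn$dataset)
  expect_identical(emb_a$mod1$vectors, emb_b$mod1$vectors)
})

test_that("tidy and glance summarize the fitted model", {
  syn <- generate_paired(synthetic_spec(n_cells = 60, n_types = 2, p = 10,
                                        q = 10, latent_dim = 3, seed = 8))
  prep <- preprocess_config(normalize = FALSE, log1p = FALSE, n_pcs = 5)
  fit <- fit_modalign(syn$dataset, prep, prep, hidden_dim = 8, latent_dim = 4,
                      config = train_config(max_epochs = 3, seed = 6))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("epoch", "mean_loss"))
  expect_equal(nrow(td), fit$epochs_run)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$epochs_run, fit$epochs_run)
  expect_s3_class(autoplot(fit), "ggplot")
})
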