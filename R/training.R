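#' Training configuration
#'
#' @param max_epochs Maximum epochs; default 150.
#' @param patience Early-stopping patience in epochs; default 10.
#' @param min_delta Minimum improvement of the best epoch-mean loss that
#'   counts as progress; default 1e-4.
#' @param learning_rate Adam learning rate; default 1e-3.
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @param type_cap If the number of cell types exceeds this, each batch
#'   subsamples this many types (with a warning); default 512.
#' @return A `train_config` list.
#' @export
train_config <- function(max_epochs = 150, patience = 10, min_delta = 1e-4,
                         learning_rate = 1e-3, seed = 0L, type_cap = 512L) {
  stopifnot(max_epochs >= 1, patience >= 1, min_delta >= 0,
            learning_rate > 0, type_cap >= 2)
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 min_delta = min_delta,
                 learning_rate = learning_rate,
                 seed = as.integer(seed),
                 type_cap = as.integer(type_cap)),
            class = "train_config")
}

#' Number of epochs run under the early-stopping rule
#'
#' Pure function over a (possibly hypothetical) sequence of epoch-mean
#' losses: training stops after the epoch at which the best loss so far has
#' failed to improve by more than `min_delta` for `patience` consecutive
#' epochs. Useful for verifying the stopping rule on crafted sequences; the
#' trainer applies the same logic incrementally.
#'
#' @param losses Numeric vector of epoch-mean losses, in epoch order.
#' @param patience Consecutive non-improving epochs tolerated.
#' @param min_delta Minimum decrease that counts as improvement.
#' @return Number of epochs that would run (`length(losses)` if the rule
#'   never triggers).
#' @export
early_stop_epoch <- function(losses, patience = 10, min_delta = 1e-4) {
  best <- Inf
  stall <- 0L
  for (e in seq_along(losses)) {
    if (best - losses[e] > min_delta) {
      best <- losses[e]
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) return(e)
    }
  }
  length(losses)
}

# One cell index per type per batch, consumed in shuffled order without
# replacement; types with fewer cells than the batch count are topped up with
# replacement so every batch stays full and every cell appears >= once per
# epoch. Returns an n_batches x n_types index matrix (columns = types).
type_schedule <- function(labels, types, n_batches) {
  out <- matrix(0L, n_batches, length(types))
  for (j in seq_along(types)) {
    idx <- which(labels == types[j])
    seqn <- idx[sample.int(length(idx))]
    if (length(seqn) < n_batches) {
      extra <- idx[sample.int(length(idx), n_batches - length(seqn),
                              replace = TRUE)]
      seqn <- c(seqn, extra)
    }
    out[, j] <- seqn[seq_len(n_batches)]
  }
  out
}

# Subsample types per batch when their number exceeds the cap.
batch_types <- function(types, type_cap, n_batches) {
  if (length(types) <= type_cap) {
    return(replicate(n_batches, seq_along(types), simplify = FALSE))
  }
  warning("Number of cell types (", length(types), ") exceeds type_cap (",
          type_cap, "); subsampling types per batch.", call. = FALSE)
  replicate(n_batches, sort(sample.int(length(types), type_cap)),
            simplify = FALSE)
}

#' Plan one epoch of cell-type-structured mini-batches for paired data
#'
#' Every batch holds exactly one cell per cell type, with the same cell used
#' in both modalities (matched positives on the diagonal, cross-type
#' negatives off it). Within an epoch each type's cells are consumed in
#' shuffled order without replacement, then topped up with replacement, so
#' the number of batches equals the largest type count and every training
#' cell appears at least once.
#'
#' @param dataset A [paired_dataset()].
#' @param config A [train_config()] (used for the type cap). Shuffling uses
#'   the current RNG stream; seed it (the trainer does).
#' @return A `batch_plan`: list of batches, each a list with integer vectors
#'   `idx1`, `idx2` and character `types`.
#' @export
plan_paired_epoch <- function(dataset, config = train_config()) {
  stopifnot(inherits(dataset, "paired_dataset"))
  labels <- dataset$mod1$cell_types
  types <- sort(unique(labels))
  if (length(types) < 2) {
    stop("Need at least 2 cell types to form negative pairs.", call. = FALSE)
  }
  n_batches <- max(tabulate(factor(labels, levels = types)))
  sched <- type_schedule(labels, types, n_batches)
  tsel <- batch_types(types, config$type_cap, n_batches)
  plan <- lapply(seq_len(n_batches), function(b) {
    sel <- tsel[[b]]
    list(idx1 = sched[b, sel], idx2 = sched[b, sel], types = types[sel])
  })
  structure(plan, class = "batch_plan", mode = "paired")
}

#' Plan one epoch of mini-batches for unpaired data
#'
#' For each batch and each cell type shared by both modalities, one cell is
#' drawn independently from each modality; the diagonal pairs are same-type,
#' different-cell positives. Types present in only one modality are excluded
#' with a warning. The number of batches is the largest per-type cell count
#' across both modalities, so every usable cell appears at least once.
#'
#' @inheritParams plan_paired_epoch
#' @param dataset An [unpaired_dataset()].
#' @return A `batch_plan` as in [plan_paired_epoch()], with `idx1` indexing
#'   modality 1 rows and `idx2` modality 2 rows.
#' @export
plan_unpaired_epoch <- function(dataset, config = train_config()) {
  stopifnot(inherits(dataset, "unpaired_dataset"))
  l1 <- dataset$mod1$cell_types
  l2 <- dataset$mod2$cell_types
  shared <- sort(intersect(unique(l1), unique(l2)))
  only <- setdiff(union(unique(l1), unique(l2)), shared)
  if (length(only) > 0) {
    warning("Cell types present in only one modality are excluded from ",
            "training batches: ", paste(only, collapse = ", "), call. = FALSE)
  }
  if (length(shared) == 0) {
    stop("No shared cell types between the two modalities.", call. = FALSE)
  }
  if (length(shared) < 2) {
    stop("Need at least 2 shared cell types to form negative pairs.",
         call. = FALSE)
  }
  n_batches <- max(tabulate(factor(l1[l1 %in% shared], levels = shared)),
                   tabulate(factor(l2[l2 %in% shared], levels = shared)))
  s1 <- type_schedule(l1, shared, n_batches)
  s2 <- type_schedule(l2, shared, n_batches)
  tsel <- batch_types(shared, config$type_cap, n_batches)
  plan <- lapply(seq_len(n_batches), function(b) {
    sel <- tsel[[b]]
    list(idx1 = s1[b, sel], idx2 = s2[b, sel], types = shared[sel])
  })
  structure(plan, class = "batch_plan", mode = "unpaired")
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

#' Train the two modality encoders with the symmetric contrastive loss
#'
#' Jointly optimizes both encoders with Adam on cell-type-structured
#' mini-batches: per batch, the M x M cosine similarity matrix between the
#' two modalities' embeddings is pushed toward large diagonal (positive
#' pairs) and small off-diagonal (cross-type negatives) values. Runs up to
#' `max_epochs` epochs over fresh per-epoch batch plans and stops early when
#' the epoch-mean loss has not improved by more than `min_delta` for
#' `patience` consecutive epochs.
#'
#' Inputs are the already-preprocessed (post-PCA) matrices; the higher-level
#' [fit_modalign()] wires preprocessing, training and bundling together.
#'
#' @param dataset A [paired_dataset()] or [unpaired_dataset()] holding
#'   preprocessed values.
#' @param spec1,spec2 [encoder_spec()]s for the two modalities (must share
#'   `latent_dim`).
#' @param config A [train_config()].
#' @param temperature Optional softmax temperature (default 1 = the plain
#'   loss).
#' @return A list with `enc1`, `enc2` (parameter sets), `spec1`, `spec2`,
#'   `loss_history` (numeric per-epoch mean loss), `epochs_run`,
#'   `stopped_early`.
#' @export
train_encoders <- function(dataset, spec1, spec2, config = train_config(),
                           temperature = 1) {
  stopifnot(inherits(spec1, "encoder_spec"), inherits(spec2, "encoder_spec"))
  if (spec1$latent_dim != spec2$latent_dim) {
    stop("Both encoders must share latent_dim.", call. = FALSE)
  }
  paired <- inherits(dataset, "paired_dataset")
  if (!paired && !inherits(dataset, "unpaired_dataset")) {
    stop("`dataset` must be a paired_dataset or unpaired_dataset.",
         call. = FALSE)
  }
  x1 <- dataset$mod1$values
  x2 <- dataset$mod2$values

  withr::local_seed(config$seed)
  enc1 <- init_encoder(spec1)
  enc2 <- init_encoder(spec2)
  st1 <- adam_init(enc1[c("W1", "b1", "gamma", "beta", "W2", "b2")])
  st2 <- adam_init(enc2[c("W1", "b1", "gamma", "beta", "W2", "b2")])

  loss_history <- numeric(0)
  best <- Inf
  stall <- 0L
  stopped_early <- FALSE
  t_step <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    plan <- if (paired) plan_paired_epoch(dataset, config)
            else plan_unpaired_epoch(dataset, config)
    batch_losses <- numeric(length(plan))
    for (b in seq_along(plan)) {
      bt <- plan[[b]]
      f1 <- encoder_forward(enc1, x1[bt$idx1, , drop = FALSE], spec1,
                            training = TRUE)
      f2 <- encoder_forward(enc2, x2[bt$idx2, , drop = FALSE], spec2,
                            training = TRUE)
      enc1 <- f1$params  # running batch-norm statistics updated
      enc2 <- f2$params
      s <- tcrossprod(f1$cache$z, f2$cache$z)
      loss <- contrastive_loss(s, temperature)
      if (!is.finite(loss)) {
        stop("Non-finite loss at epoch ", epoch, ", batch ", b,
             "; try a smaller learning_rate.", call. = FALSE)
      }
      batch_losses[b] <- loss
      g <- contrastive_loss_grad(s, temperature)
      dz1 <- g %*% f2$cache$z
      dz2 <- t(g) %*% f1$cache$z
      g1 <- encoder_backward(enc1, f1$cache, dz1, spec1)
      g2 <- encoder_backward(enc2, f2$cache, dz2, spec2)
      t_step <- t_step + 1L
      up1 <- adam_step(enc1, g1, st1, config$learning_rate, t_step)
      enc1[names(up1$params)] <- up1$params; st1 <- up1$state
      up2 <- adam_step(enc2, g2, st2, config$learning_rate, t_step)
      enc2[names(up2$params)] <- up2$params; st2 <- up2$state
    }
    loss_history <- c(loss_history, mean(batch_losses))
    if (best - loss_history[epoch] > config$min_delta) {
      best <- loss_history[epoch]
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) {
        stopped_early <- TRUE
        break
      }
    }
  }

  list(enc1 = enc1, enc2 = enc2, spec1 = spec1, spec2 = spec2,
       loss_history = loss_history, epochs_run = length(loss_history),
       stopped_early = stopped_early, temperature = temperature)
}

#' Fit the full alignment model: preprocessing plus contrastive encoders
#'
#' Fits the per-modality preprocessing chains on the supplied (training)
#' dataset, trains both encoders on the transformed values, and seals
#' everything — fitted transforms, encoder weights, batch-norm running
#' statistics and configuration — into one model bundle. The function only
#' ever sees training cells; held-out data is embedded later with
#' [embed_holdout()] using the frozen statistics.
#'
#' @param dataset A [paired_dataset()] or [unpaired_dataset()] of raw
#'   training cells.
#' @param prep1,prep2 [preprocess_config()]s for each modality.
#' @param hidden_dim,latent_dim Encoder dimensions (defaults 256 / 128).
#' @param config A [train_config()].
#' @param temperature Optional softmax temperature; default 1.
#' @return A `modalign_model` bundle.
#' @examples
#' \donttest{
#' syn <- generate_paired(synthetic_spec(n_cells = 300, n_types = 3,
#'                                       p = 40, q = 30, seed = 1))
#' fit <- fit_modalign(syn$dataset, prep1 = preprocess_config(n_pcs = 20),
#'                     prep2 = preprocess_config(n_pcs = 20),
#'                     config = train_config(max_epochs = 5, seed = 1))
#' glance(fit)
#' }
#' @export
fit_modalign <- function(dataset,
                         prep1 = preprocess_config(),
                         prep2 = preprocess_config(),
                         hidden_dim = 256, latent_dim = 128,
                         config = train_config(),
                         temperature = 1) {
  paired <- inherits(dataset, "paired_dataset")
  fp1 <- fit_preprocess(dataset$mod1, prep1)
  fp2 <- fit_preprocess(dataset$mod2, prep2)
  t1 <- apply_preprocess(fp1, dataset$mod1)
  t2 <- apply_preprocess(fp2, dataset$mod2)
  td <- if (paired) paired_dataset(t1, t2) else unpaired_dataset(t1, t2)
  spec1 <- encoder_spec(preprocess_dim(fp1), hidden_dim, latent_dim)
  spec2 <- encoder_spec(preprocess_dim(fp2), hidden_dim, latent_dim)
  tr <- train_encoders(td, spec1, spec2, config, temperature)
  structure(list(
    version = "modalign-bundle-1",
    prep1 = fp1, prep2 = fp2,
    enc1 = tr$enc1, enc2 = tr$enc2,
    spec1 = spec1, spec2 = spec2,
    config = config, temperature = temperature,
    paired = paired,
    modality_names = c(dataset$mod1$modality_name, dataset$mod2$modality_name),
    loss_history = tr$loss_history,
    epochs_run = tr$epochs_run,
    stopped_early = tr$stopped_early,
    n_train = if (paired) nrow(dataset$mod1$values)
              else c(nrow(dataset$mod1$values), nrow(dataset$mod2$values))
  ), class = "modalign_model")
}

#' @export
print.modalign_model <- function(x, ...) {
  cat("<modalign_model> latent dim ", x$spec1$latent_dim, "; ",
      x$epochs_run, " epochs",
      if (x$stopped_early) " (early stop)", "; final mean loss ",
      format(utils::tail(x$loss_history, 1), digits = 5), "\n", sep = "")
  invisible(x)
}

#' Embed one modality's cells with a trained model
#'
#' Applies the train-fitted preprocessing chain and the evaluation-mode
#' encoder (batch-norm running averages, no statistic updates), so the result
#' is deterministic and each cell's embedding is independent of which other
#' cells are embedded alongside it. A single cell can be embedded.
#'
#' @param model A `modalign_model` from [fit_modalign()].
#' @param table A [modality_table()] of raw cells.
#' @param which Which modality the table belongs to: 1 or 2.
#' @return An [embedding_set()].
#' @export
embed_modality <- function(model, table, which = 1) {
  stopifnot(inherits(model, "modalign_model"), which %in% c(1, 2))
  prep <- if (which == 1) model$prep1 else model$prep2
  enc <- if (which == 1) model$enc1 else model$enc2
  spec <- if (which == 1) model$spec1 else model$spec2
  tt <- apply_preprocess(prep, table)
  fw <- encoder_forward(enc, tt$values, spec, training = FALSE)
  embedding_set(fw$z, table$cell_ids, table$cell_types,
                modality_name = table$modality_name)
}

#' Embed a held-out dataset with a trained model
#'
#' @param model A `modalign_model`.
#' @param test A [paired_dataset()] or [unpaired_dataset()] of held-out cells.
#' @return A list of two [embedding_set()]s, one per modality.
#' @export
embed_holdout <- function(model, test) {
  list(mod1 = embed_modality(model, test$mod1, 1),
       mod2 = embed_modality(model, test$mod2, 2))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training losses of a fitted model
#' @param x A `modalign_model`.
#' @param ... Unused.
#' @return A tibble with columns `epoch` and `mean_loss`.
#' @method tidy modalign_model
#' @export
tidy.modalign_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), mean_loss = x$loss_history)
}

#' One-row summary of a fitted model
#' @param x A `modalign_model`.
#' @param ... Unused.
#' @return A one-row tibble: latent dimension, epochs run, early-stop flag,
#'   initial and final epoch-mean loss.
#' @method glance modalign_model
#' @export
glance.modalign_model <- function(x, ...) {
  tibble::tibble(
    latent_dim = x$spec1$latent_dim,
    epochs_run = x$epochs_run,
    stopped_early = x$stopped_early,
    initial_loss = x$loss_history[1],
    final_loss = utils::tail(x$loss_history, 1)
  )
}

#' Save / load a trained model bundle
#'
#' The bundle contains both encoders' weights and batch-norm running
#' statistics, the fitted preprocessing transforms, the configuration and a
#' version tag, so held-out data can be embedded later without any original
#' training data.
#'
#' @param model A `modalign_model`.
#' @param path File path (RDS format).
#' @return `path` (save) or the restored `modalign_model` (load).
#' @export
save_model_bundle <- function(model, path) {
  stopifnot(inherits(model, "modalign_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "modalign_model")) {
    stop("File does not contain a modalign model bundle.", call. = FALSE)
  }
  if (!identical(model$version, "modalign-bundle-1")) {
    stop("Unsupported bundle version: ", model$version, call. = FALSE)
  }
  model
}
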