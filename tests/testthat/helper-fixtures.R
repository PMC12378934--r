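# Shared fixtures and independent brute-force oracles. The oracles are
# deliberate re-derivations (plain loops, no shared code with the package)
# used to pin down the vectorized implementations.

tiny_table <- function(n = 3, p = 2, labels = NULL, seed = 1,
                       name = "mod", nonneg = TRUE) {
  withr::with_seed(seed, {
    v <- matrix(stats::rpois(n * p, 5), n, p)
    if (!nonneg) v <- v - mean(v)
    modality_table(v, paste0("c", seq_len(n)),
                   labels %||% rep(c("A", "B"), length.out = n),
                   modality_name = name)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_embedding_pair <- function(n, d, n_types = 3, seed = 1) {
  withr::with_seed(seed, {
    mk <- function(name) {
      v <- matrix(stats::rnorm(n * d), n, d)
      v <- v / sqrt(rowSums(v^2))
      embedding_set(v, paste0("c", seq_len(n)),
                    paste0("t", sample(n_types, n, replace = TRUE)), name)
    }
    # labels must match across modalities for a paired hold-out
    e1 <- mk("m1")
    v2 <- matrix(stats::rnorm(n * d), n, d)
    v2 <- v2 / sqrt(rowSums(v2^2))
    e2 <- embedding_set(v2, e1$cell_ids, e1$cell_types, "m2")
    list(e1 = e1, e2 = e2)
  })
}

# --- independent oracles ----------------------------------------------------

# direct transcription of the per-anchor loss: row and column softmax
# cross-entropy on the diagonal, averaged, summed over anchors
oracle_contrastive_loss <- function(s) {
  m <- nrow(s)
  total <- 0
  for (i in seq_len(m)) {
    row_den <- 0
    col_den <- 0
    for (j in seq_len(m)) {
      row_den <- row_den + exp(s[i, j])
      col_den <- col_den + exp(s[j, i])
    }
    total <- total - 0.5 * log(exp(s[i, i]) / row_den) -
      0.5 * log(exp(s[i, i]) / col_den)
  }
  total
}

oracle_dist <- function(q, r) {
  n1 <- nrow(q); n2 <- nrow(r)
  d <- matrix(0, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) d[i, j] <- sqrt(sum((q[i, ] - r[j, ])^2))
  }
  d
}

oracle_recall_at_k <- function(q, r, k) {
  d <- oracle_dist(q$vectors, r$vectors)
  hits <- 0
  for (i in seq_len(nrow(d))) {
    ord <- order(d[i, ])
    if (which(ord == i) <= k) hits <- hits + 1
  }
  hits / nrow(d)
}

oracle_cell_type_at_k <- function(q, r, k) {
  d <- oracle_dist(q$vectors, r$vectors)
  acc <- 0
  for (i in seq_len(nrow(d))) {
    nn <- order(d[i, ])[1:k]
    acc <- acc + mean(r$cell_types[nn] == q$cell_types[i])
  }
  acc / nrow(d)
}

oracle_median_rank <- function(q, r) {
  d <- oracle_dist(q$vectors, r$vectors)
  ranks <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    ranks[i] <- 1 + sum(d[i, ] < d[i, i])
  }
  stats::median(ranks)
}

# from-scratch silhouette: a(i) mean distance within own cluster, b(i) the
# smallest mean distance to another cluster; singleton clusters get 0
oracle_asw <- function(x, labels) {
  n <- nrow(x)
  d <- oracle_dist(x, x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- setdiff(own, i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(d[i, labels == cl]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
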