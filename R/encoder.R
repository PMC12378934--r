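#' Encoder architecture specification
#'
#' Both modality encoders share this architecture: a linear map from the
#' post-PCA input dimension to a hidden layer (default 256), batch
#' normalization, ReLU, a second linear map to the latent dimension (default
#' 128), and row-wise L2 normalization so every embedding lies on the unit
#' sphere. The nonlinearity sits between the two linear maps; a ReLU after
#' the final layer would confine embeddings to the nonnegative orthant and
#' cripple cosine contrast.
#'
#' @param input_dim Input (post-PCA) feature count.
#' @param hidden_dim Hidden width; default 256.
#' @param latent_dim Shared latent dimension d; default 128.
#' @param use_batch_norm Include batch normalization? Default TRUE.
#' @return An `encoder_spec` list.
#' @export
encoder_spec <- function(input_dim, hidden_dim = 256, latent_dim = 128,
                         use_batch_norm = TRUE) {
  stopifnot(input_dim >= 1, hidden_dim >= 1, latent_dim >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 latent_dim = as.integer(latent_dim),
                 use_batch_norm = isTRUE(use_batch_norm)),
            class = "encoder_spec")
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Fresh parameter set for one encoder. Uses the current RNG stream; callers
# seed it.
init_encoder <- function(spec) {
  list(
    W1 = glorot(spec$input_dim, spec$hidden_dim),
    b1 = numeric(spec$hidden_dim),
    gamma = rep(1, spec$hidden_dim),
    beta = numeric(spec$hidden_dim),
    run_mean = numeric(spec$hidden_dim),
    run_var = rep(1, spec$hidden_dim),
    W2 = glorot(spec$hidden_dim, spec$latent_dim),
    b2 = numeric(spec$latent_dim)
  )
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

l2_normalize_rows <- function(z) {
  nrm <- sqrt(rowSums(z^2))
  nrm[nrm < 1e-12] <- 1e-12
  list(z = z / nrm, norm = nrm)
}

# Forward pass. training = TRUE uses batch statistics (and updates running
# averages); FALSE uses the running averages, so single cells embed fine.
# Returns the unit-norm embeddings plus the cache needed for backprop.
encoder_forward <- function(params, x, spec, training = FALSE) {
  if (ncol(x) != spec$input_dim) {
    stop("Input has ", ncol(x), " features; encoder expects ",
         spec$input_dim, ".", call. = FALSE)
  }
  if (training && spec$use_batch_norm && nrow(x) < 2) {
    stop("Batch normalization in training mode needs a batch of >= 2 cells.",
         call. = FALSE)
  }
  a1 <- sweep(x %*% params$W1, 2, params$b1, "+")
  if (spec$use_batch_norm) {
    if (training) {
      mu <- colMeans(a1)
      va <- colMeans(sweep(a1, 2, mu, "-")^2)  # population variance
      params$run_mean <- (1 - BN_MOMENTUM) * params$run_mean + BN_MOMENTUM * mu
      params$run_var  <- (1 - BN_MOMENTUM) * params$run_var + BN_MOMENTUM * va
    } else {
      mu <- params$run_mean
      va <- params$run_var
    }
    inv_sd <- 1 / sqrt(va + BN_EPS)
    xhat <- sweep(sweep(a1, 2, mu, "-"), 2, inv_sd, "*")
    h_pre <- sweep(sweep(xhat, 2, params$gamma, "*"), 2, params$beta, "+")
  } else {
    xhat <- NULL; inv_sd <- NULL
    h_pre <- a1
  }
  h <- pmax(h_pre, 0)
  u <- sweep(h %*% params$W2, 2, params$b2, "+")
  nrm <- l2_normalize_rows(u)
  list(z = nrm$z, params = params,
       cache = list(x = x, a1 = a1, xhat = xhat, inv_sd = inv_sd,
                    h_pre = h_pre, h = h, u = u, norm = nrm$norm, z = nrm$z))
}

# Backward pass: dz is dLoss/dEmbedding (n x latent). Returns gradients with
# the same shapes as the learnable parameters.
encoder_backward <- function(params, cache, dz, spec) {
  # through L2 row normalization: u -> u / ||u||
  zdot <- rowSums(dz * cache$z)
  du <- (dz - cache$z * zdot) / cache$norm
  # linear 2
  dW2 <- crossprod(cache$h, du)
  db2 <- colSums(du)
  dh <- du %*% t(params$W2)
  # ReLU
  dh_pre <- dh * (cache$h_pre > 0)
  if (spec$use_batch_norm) {
    n <- nrow(dh_pre)
    dgamma <- colSums(dh_pre * cache$xhat)
    dbeta <- colSums(dh_pre)
    dxhat <- sweep(dh_pre, 2, params$gamma, "*")
    # standard batch-norm backward (population variance)
    term <- sweep(dxhat * n, 2, colSums(dxhat), "-") -
      cache$xhat * rep(colSums(dxhat * cache$xhat), each = n)
    da1 <- sweep(term, 2, cache$inv_sd / n, "*")
  } else {
    dgamma <- NULL; dbeta <- NULL
    da1 <- dh_pre
  }
  dW1 <- crossprod(cache$x, da1)
  db1 <- colSums(da1)
  list(W1 = dW1, b1 = db1, gamma = dgamma, beta = dbeta, W2 = dW2, b2 = db2)
}

#' Unit-norm embeddings for one modality's cells
#'
#' Wraps an n x d matrix of L2-normalized latent vectors together with cell
#' identifiers, cell-type labels and the modality name. Construction checks
#' that every row has unit Euclidean norm (within 1e-5).
#'
#' @param vectors Numeric n x d matrix; rows must be unit-norm.
#' @param cell_ids,cell_types Per-row annotations.
#' @param modality_name Modality tag.
#' @return An `embedding_set`.
#' @export
embedding_set <- function(vectors, cell_ids, cell_types, modality_name = "mod") {
  vectors <- as.matrix(vectors)
  if (length(cell_ids) != nrow(vectors) || length(cell_types) != nrow(vectors)) {
    stop("Annotation lengths must match the number of embedding rows.",
         call. = FALSE)
  }
  nrm <- sqrt(rowSums(vectors^2))
  if (any(abs(nrm - 1) > 1e-5)) {
    stop("Embedding rows must be unit-norm (max deviation ",
         format(max(abs(nrm - 1))), ").", call. = FALSE)
  }
  structure(list(vectors = unname(vectors),
                 cell_ids = as.character(cell_ids),
                 cell_types = as.character(cell_types),
                 modality_name = as.character(modality_name)[1]),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat("<embedding_set> '", x$modality_name, "': ", nrow(x$vectors),
      " cells x ", ncol(x$vectors), " latent dims\n", sep = "")
  invisible(x)
}

#' Cosine similarity matrix between two embedding sets
#'
#' Entry (i, j) is the inner product of row i of the first set with row j of
#' the second; since rows are unit-norm this is the cosine similarity. In a
#' training mini-batch the two sets hold one cell per cell type in the same
#' type order, so the diagonal entries are the positive pairs and every
#' off-diagonal entry is a cross-type negative.
#'
#' @param emb1,emb2 `embedding_set`s with equal cell counts and latent dims.
#' @return An M x M numeric matrix with `row_labels`/`col_labels` attributes.
#' @export
similarity_matrix <- function(emb1, emb2) {
  stopifnot(inherits(emb1, "embedding_set"), inherits(emb2, "embedding_set"))
  if (nrow(emb1$vectors) != nrow(emb2$vectors)) {
    stop("Batch sizes differ (", nrow(emb1$vectors), " vs ",
         nrow(emb2$vectors), ").", call. = FALSE)
  }
  if (ncol(emb1$vectors) != ncol(emb2$vectors)) {
    stop("Latent dimensions differ.", call. = FALSE)
  }
  s <- tcrossprod(emb1$vectors, emb2$vectors)
  attr(s, "row_labels") <- emb1$cell_types
  attr(s, "col_labels") <- emb2$cell_types
  s
}

row_logsumexp <- function(s) {
  m <- apply(s, 1, max)
  m + log(rowSums(exp(s - m)))
}

#' Symmetric contrastive loss of a mini-batch similarity matrix
#'
#' For anchor i with similarity matrix S (diagonal = positive pairs), the
#' per-anchor loss is
#' \deqn{L(i) = -\tfrac12 \log\frac{e^{S_{ii}}}{\sum_j e^{S_{ij}}}
#'             -\tfrac12 \log\frac{e^{S_{ii}}}{\sum_j e^{S_{ji}}}}
#' i.e. the average of a row-wise and a column-wise softmax cross-entropy on
#' the diagonal; the returned value is the sum of L(i) over the M anchors.
#' There is no temperature in the base form; `temperature` (default 1)
#' divides S before the softmax for experimentation.
#'
#' @param sim Square M x M numeric similarity matrix.
#' @param temperature Positive scalar; similarities are divided by it.
#' @return Nonnegative scalar loss.
#' @examples
#' contrastive_loss(diag(2))  # 2 * log(1 + exp(-1))
#' @export
contrastive_loss <- function(sim, temperature = 1) {
  sim <- as.matrix(sim)
  if (nrow(sim) != ncol(sim)) {
    stop("Similarity matrix must be square.", call. = FALSE)
  }
  if (temperature <= 0) stop("`temperature` must be positive.", call. = FALSE)
  s <- sim / temperature
  d <- diag(s)
  row_half <- -(d - row_logsumexp(s))
  col_half <- -(d - row_logsumexp(t(s)))
  sum(0.5 * row_half + 0.5 * col_half)
}

# Gradient of contrastive_loss w.r.t. the similarity entries:
# 0.5 * (row_softmax - I) + 0.5 * (col_softmax - I), summed-over-anchors
# reduction (no division by M).
contrastive_loss_grad <- function(sim, temperature = 1) {
  s <- as.matrix(sim) / temperature
  m1 <- apply(s, 1, max)
  p_row <- exp(s - m1)
  p_row <- p_row / rowSums(p_row)
  st <- t(s)
  m2 <- apply(st, 1, max)
  p_col <- exp(st - m2)
  p_col <- t(p_col / rowSums(p_col))
  i_mat <- diag(nrow(s))
  (0.5 * (p_row - i_mat) + 0.5 * (p_col - i_mat)) / temperature
}

#' Check that the loss is symmetric under modality swap
#'
#' Swapping the two modalities transposes the similarity matrix and exchanges
#' the row and column halves of each per-anchor term, leaving the total loss
#' unchanged. This utility verifies that identity numerically.
#'
#' @param sim Square similarity matrix.
#' @param tol Tolerance; default 1e-8.
#' @return TRUE if `contrastive_loss(sim)` equals
#'   `contrastive_loss(t(sim))` within `tol`.
#' @export
loss_symmetry_check <- function(sim, tol = 1e-8) {
  abs(contrastive_loss(sim) - contrastive_loss(t(sim))) <= tol
}
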