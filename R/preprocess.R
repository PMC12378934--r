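#' Per-cell total-count normalization
#'
#' Rescales each cell (row) so its counts sum to `target_sum`, the standard
#' library-size correction for UMI counts. All-zero cells are left all-zero.
#'
#' @param table A [modality_table()] with nonnegative values.
#' @param target_sum Positive target row sum; default `1e4` (counts per 10k).
#' @return A `modality_table` with rescaled values.
#' @export
normalize_total <- function(table, target_sum = 1e4) {
  validate_modality_table(table)
  if (target_sum <= 0) stop("`target_sum` must be positive.", call. = FALSE)
  v <- table$values
  if (any(v < 0)) {
    stop("normalize_total() requires nonnegative counts.", call. = FALSE)
  }
  rs <- rowSums(v)
  scale_by <- ifelse(rs > 0, target_sum / rs, 0)
  table$values <- v * scale_by
  # all-zero rows: scale_by = 0 keeps them zero without dividing by zero
  table$values[rs == 0, ] <- 0
  table
}

#' Elementwise log(1 + x) transform
#'
#' @param table A [modality_table()] with nonnegative values.
#' @return A `modality_table` with `log1p`-transformed values.
#' @export
log1p_transform <- function(table) {
  validate_modality_table(table)
  if (any(table$values < 0)) {
    stop("log1p_transform() requires nonnegative values.", call. = FALSE)
  }
  table$values <- log1p(table$values)
  table
}

#' Fit a zero-mean/unit-variance scaling transform on training cells
#'
#' Stores per-feature means and population standard deviations (divide-by-n)
#' of the training matrix. Zero-variance features get a unit divisor, so they
#' are centered and passed through rather than producing NaN.
#'
#' @param train A [modality_table()] with at least 2 cells.
#' @return A `fitted_transform` of kind `"scale"`.
#' @export
fit_scale <- function(train) {
  validate_modality_table(train)
  v <- train$values
  n <- nrow(v)
  if (n < 2) stop("fit_scale() needs at least 2 training cells.", call. = FALSE)
  mu <- colMeans(v)
  sd_pop <- sqrt(colMeans(sweep(v, 2, mu, "-")^2))
  sd_pop[sd_pop < 1e-12] <- 1
  new_fitted_transform("scale", list(mean = mu, sd = sd_pop), fitted_on = n,
                       dim_in = ncol(v), dim_out = ncol(v))
}

#' Fit a PCA transform on training cells
#'
#' Principal axes of the centered training matrix via singular value
#' decomposition; columns of the loading matrix are orthonormal and ordered by
#' decreasing explained variance. Each component's sign is fixed so that its
#' largest-magnitude loading is positive, making results reproducible across
#' platforms. Training feature means are stored for centering held-out cells.
#'
#' @param train A [modality_table()].
#' @param n_components Number of components; must not exceed
#'   `min(n_cells, n_features)`.
#' @return A `fitted_transform` of kind `"pca"` carrying `rotation`
#'   (features x components), `mean`, and `explained_variance`.
#' @export
fit_pca <- function(train, n_components) {
  validate_modality_table(train)
  v <- train$values
  n <- nrow(v); p <- ncol(v)
  n_components <- as.integer(n_components)
  if (n_components < 1 || n_components > min(n, p)) {
    stop("`n_components` must be in [1, min(n_cells, n_features)] = [1, ",
         min(n, p), "].", call. = FALSE)
  }
  mu <- colMeans(v)
  xc <- sweep(v, 2, mu, "-")
  sv <- svd(xc, nu = 0, nv = n_components)
  rot <- sv$v
  # deterministic sign: largest-|loading| entry of each axis made positive
  for (j in seq_len(ncol(rot))) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) rot[, j] <- -rot[, j]
  }
  new_fitted_transform(
    "pca",
    list(rotation = rot, mean = mu,
         explained_variance = (sv$d[seq_len(n_components)]^2) / n),
    fitted_on = n, dim_in = p, dim_out = n_components
  )
}

new_fitted_transform <- function(kind, stats, fitted_on, dim_in, dim_out) {
  structure(list(kind = kind, stats = stats, fitted_on = fitted_on,
                 dim_in = dim_in, dim_out = dim_out),
            class = "fitted_transform")
}

#' @export
print.fitted_transform <- function(x, ...) {
  cat("<fitted_transform:", x$kind, "> ", x$dim_in, " -> ", x$dim_out,
      " features, fitted on ", x$fitted_on, " cells\n", sep = "")
  invisible(x)
}

#' Apply a fitted transform to (possibly held-out) cells
#'
#' Uses only the statistics stored at fit time; never refits, so applying to a
#' single held-out cell is valid and fitted statistics are immutable.
#'
#' @param transform A `fitted_transform` from [fit_scale()] or [fit_pca()].
#' @param table A [modality_table()] whose feature dimension matches the
#'   fitted one.
#' @return The transformed `modality_table`.
#' @export
apply_transform <- function(transform, table) {
  stopifnot(inherits(transform, "fitted_transform"))
  validate_modality_table(table)
  v <- table$values
  if (ncol(v) != transform$dim_in) {
    stop("Feature dimension (", ncol(v), ") does not match fitted dimension (",
         transform$dim_in, ").", call. = FALSE)
  }
  if (transform$kind == "scale") {
    v <- sweep(v, 2, transform$stats$mean, "-")
    v <- sweep(v, 2, transform$stats$sd, "/")
    table$values <- v
  } else if (transform$kind == "pca") {
    xc <- sweep(v, 2, transform$stats$mean, "-")
    table$values <- xc %*% transform$stats$rotation
    table$feature_ids <- paste0("PC", seq_len(transform$dim_out))
  } else {
    stop("Unknown transform kind: ", transform$kind, call. = FALSE)
  }
  table
}

#' Default per-modality preprocessing configuration
#'
#' The chain is fixed in this order: total-count normalization, log1p,
#' zero-mean/unit-variance scaling, PCA. Pre-processed inputs (e.g. provider-
#' normalized CITE-seq matrices) can skip the count-specific first two steps.
#'
#' @param normalize Run total-count normalization? Default TRUE.
#' @param log1p Run log1p? Default TRUE.
#' @param scale Run feature scaling? Default TRUE.
#' @param n_pcs Number of principal components (capped at the data rank with a
#'   message); default 100. `NULL` skips PCA.
#' @param target_sum Library-size target for normalization; default 1e4.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(normalize = TRUE, log1p = TRUE, scale = TRUE,
                              n_pcs = 100, target_sum = 1e4) {
  structure(list(normalize = normalize, log1p = log1p, scale = scale,
                 n_pcs = n_pcs, target_sum = target_sum),
            class = "preprocess_config")
}

#' Fit the full preprocessing chain on training cells of one modality
#'
#' All statistics (scaling moments, PCA axes) are functions of the training
#' rows only; the returned object applies them unchanged to held-out cells via
#' [apply_preprocess()]. The object records `fitted_on`, the number of
#' training cells, which the replicate runner asserts against the split.
#'
#' @param train A [modality_table()] of training cells.
#' @param config A [preprocess_config()].
#' @return A `fitted_preprocess` object.
#' @export
fit_preprocess <- function(train, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  validate_modality_table(train)
  tab <- train
  if (isTRUE(config$normalize)) tab <- normalize_total(tab, config$target_sum)
  if (isTRUE(config$log1p)) tab <- log1p_transform(tab)
  steps <- list()
  if (isTRUE(config$scale)) {
    sc <- fit_scale(tab)
    steps <- c(steps, list(sc))
    tab <- apply_transform(sc, tab)
  }
  if (!is.null(config$n_pcs)) {
    k <- min(as.integer(config$n_pcs), nrow(tab$values), ncol(tab$values))
    if (k < config$n_pcs) {
      message("n_pcs capped at data rank bound: ", k)
    }
    pc <- fit_pca(tab, k)
    steps <- c(steps, list(pc))
  }
  structure(list(config = config, steps = steps,
                 fitted_on = nrow(train$values),
                 dim_in = ncol(train$values)),
            class = "fitted_preprocess")
}

#' Apply a fitted preprocessing chain to any cells
#'
#' @param prep A `fitted_preprocess` from [fit_preprocess()].
#' @param table A [modality_table()] with the same feature dimension the chain
#'   was fitted on.
#' @return The fully transformed `modality_table` (post-PCA if configured).
#' @export
apply_preprocess <- function(prep, table) {
  stopifnot(inherits(prep, "fitted_preprocess"))
  if (ncol(table$values) != prep$dim_in) {
    stop("Feature dimension mismatch vs. fitted preprocessing (",
         ncol(table$values), " vs ", prep$dim_in, ").", call. = FALSE)
  }
  tab <- table
  if (isTRUE(prep$config$normalize)) {
    tab <- normalize_total(tab, prep$config$target_sum)
  }
  if (isTRUE(prep$config$log1p)) tab <- log1p_transform(tab)
  for (st in prep$steps) tab <- apply_transform(st, tab)
  tab
}

#' Output dimension of a fitted preprocessing chain
#' @param prep A `fitted_preprocess`.
#' @return Integer feature count after the chain.
#' @export
preprocess_dim <- function(prep) {
  if (length(prep$steps) == 0) return(prep$dim_in)
  prep$steps[[length(prep$steps)]]$dim_out
}
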