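#' Specification for the synthetic paired two-modality generator
#'
#' The generator emulates the structure the alignment model assumes: every
#' cell has a cell type drawn from `type_proportions` and a shared latent
#' vector drawn from that type's Gaussian (unit within-type standard
#' deviation; centroids separated by `separation` in those units). Each
#' modality observes the same latent vector through its own fixed random
#' linear map plus independent noise, emulating the distributional
#' discrepancies and distinct feature spaces of real multi-omics assays.
#' With `count_model = "nb"` the linear output is softplus-transformed into
#' a negative-binomial mean and nonnegative integer counts are emitted, so
#' the full UMI preprocessing chain can be exercised; `"gaussian"` gives
#' real-valued data for fast tests.
#'
#' @param n_cells Number of cells.
#' @param n_types Number of cell types (>= 2).
#' @param type_proportions Simplex vector of type frequencies; default
#'   uniform.
#' @param latent_dim Shared latent dimension; default 10.
#' @param p,q Feature counts of the two modalities.
#' @param separation Between-centroid distance in units of the within-type
#'   standard deviation; default 6.
#' @param noise_sd Standard deviation of modality-specific additive noise;
#'   default 0.5.
#' @param count_model `"gaussian"` or `"nb"`.
#' @param nb_dispersion Negative-binomial dispersion (var = mu + disp*mu^2);
#'   default 0.3.
#' @param count_scale Mean count scale for the NB model; default 5.
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_cells = 1000, n_types = 5,
                           type_proportions = NULL, latent_dim = 10,
                           p = 200, q = 200, separation = 6, noise_sd = 0.5,
                           count_model = c("gaussian", "nb"),
                           nb_dispersion = 0.3, count_scale = 5, seed = 0L) {
  count_model <- match.arg(count_model)
  if (is.null(type_proportions)) {
    type_proportions <- rep(1 / n_types, n_types)
  }
  if (abs(sum(type_proportions) - 1) > 1e-9) {
    stop("`type_proportions` must sum to 1.", call. = FALSE)
  }
  if (length(type_proportions) != n_types) {
    stop("`type_proportions` must have length n_types.", call. = FALSE)
  }
  stopifnot(n_types >= 2, separation > 0, noise_sd >= 0, latent_dim >= 1)
  if (p < latent_dim || q < latent_dim) {
    stop("Feature counts p and q must be >= latent_dim.", call. = FALSE)
  }
  structure(list(n_cells = as.integer(n_cells), n_types = as.integer(n_types),
                 type_proportions = type_proportions,
                 latent_dim = as.integer(latent_dim),
                 p = as.integer(p), q = as.integer(q),
                 separation = separation, noise_sd = noise_sd,
                 count_model = count_model, nb_dispersion = nb_dispersion,
                 count_scale = count_scale, seed = as.integer(seed)),
            class = "synthetic_spec")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Type centroids with pairwise distance `separation` (exact when
# latent_dim >= n_types via scaled orthonormal axes; otherwise random
# directions rescaled to that mean pairwise distance).
make_centroids <- function(n_types, latent_dim, separation) {
  if (latent_dim >= n_types) {
    basis <- diag(latent_dim)[, seq_len(n_types), drop = FALSE]
    t(basis) * (separation / sqrt(2))
  } else {
    c0 <- matrix(stats::rnorm(n_types * latent_dim), n_types, latent_dim)
    d <- stats::dist(c0)
    c0 * (separation / mean(d))
  }
}

#' Generate a paired two-modality synthetic dataset
#'
#' See [synthetic_spec()] for the generative model. Deterministic given the
#' spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `dataset` (a [paired_dataset()]) and `truth` (the
#'   latent vectors, type assignments, centroids and modality maps).
#' @examples
#' syn <- generate_paired(synthetic_spec(n_cells = 100, n_types = 3,
#'                                       p = 30, q = 25, seed = 1))
#' syn$dataset
#' @export
generate_paired <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::local_seed(spec$seed)
  n <- spec$n_cells
  types <- sample(seq_len(spec$n_types), n, replace = TRUE,
                  prob = spec$type_proportions)
  centroids <- make_centroids(spec$n_types, spec$latent_dim, spec$separation)
  z <- centroids[types, , drop = FALSE] +
    matrix(stats::rnorm(n * spec$latent_dim), n, spec$latent_dim)
  a1 <- matrix(stats::rnorm(spec$latent_dim * spec$p, sd = 1 / sqrt(spec$latent_dim)),
               spec$latent_dim, spec$p)
  a2 <- matrix(stats::rnorm(spec$latent_dim * spec$q, sd = 1 / sqrt(spec$latent_dim)),
               spec$latent_dim, spec$q)
  x1 <- z %*% a1 + matrix(stats::rnorm(n * spec$p, sd = spec$noise_sd), n, spec$p)
  x2 <- z %*% a2 + matrix(stats::rnorm(n * spec$q, sd = spec$noise_sd), n, spec$q)
  if (spec$count_model == "nb") {
    mu1 <- softplus(x1) * spec$count_scale
    mu2 <- softplus(x2) * spec$count_scale
    size <- 1 / spec$nb_dispersion
    x1 <- matrix(stats::rnbinom(length(mu1), mu = mu1, size = size),
                 n, spec$p)
    x2 <- matrix(stats::rnbinom(length(mu2), mu = mu2, size = size),
                 n, spec$q)
  }
  ids <- sprintf("cell%0*d", nchar(n), seq_len(n))
  labels <- paste0("type", types)
  ds <- paired_dataset(
    modality_table(x1, ids, labels, modality_name = "mod1"),
    modality_table(x2, ids, labels, modality_name = "mod2")
  )
  list(dataset = ds,
       truth = list(latent = z, types = types, centroids = centroids,
                    map1 = a1, map2 = a2, spec = spec))
}

#' Generate matched evaluation embeddings that bypass training
#'
#' Metric-test fixture: each cell type gets a unit anchor direction
#' (orthonormal, requires `d >= n_types`) and each cell a small jitter
#' around its anchor that is shared by both modalities, so cells are
#' distinguishable from one another. Each modality then adds independent
#' spherical noise of standard deviation `noise` and re-normalizes to the
#' unit sphere. With `noise = 0` the matched embeddings are identical across
#' modalities (every retrieval metric attains its optimum); large noise
#' drives them to chance.
#'
#' @param n Number of cells.
#' @param d Latent dimension (>= n_types).
#' @param n_types Number of cell types.
#' @param noise Per-modality noise standard deviation before
#'   re-normalization.
#' @param jitter Shared per-cell jitter standard deviation; default 0.1
#'   (small enough to keep types separated).
#' @param seed Integer seed.
#' @return A list of two matched [embedding_set()]s (`mod1`, `mod2`).
#' @export
generate_eval_embeddings <- function(n, d, n_types, noise, jitter = 0.1,
                                     seed = 0L) {
  stopifnot(d >= n_types, n_types >= 1)
  withr::local_seed(as.integer(seed))
  types <- sample(seq_len(n_types), n, replace = TRUE)
  anchors <- diag(d)[seq_len(n_types), , drop = FALSE]
  base <- anchors[types, , drop = FALSE] +
    matrix(stats::rnorm(n * d, sd = jitter), n, d)
  mk <- function() {
    v <- base + matrix(stats::rnorm(n * d, sd = noise), n, d)
    l2_normalize_rows(v)$z
  }
  ids <- paste0("cell", seq_len(n))
  labels <- paste0("type", types)
  list(mod1 = embedding_set(mk(), ids, labels, "mod1"),
       mod2 = embedding_set(mk(), ids, labels, "mod2"))
}
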