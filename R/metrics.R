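# Cross-modal retrieval metrics. All use full Euclidean distance matrices —
# hold-out sets in this protocol are small enough that exhaustive search is
# both exact and fast, and it keeps tie-handling explicit.

euclidean_cross <- function(a, b) {
  # ||a_i - b_j||^2 = |a_i|^2 + |b_j|^2 - 2 a_i.b_j ; clip tiny negatives
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

check_embeddings <- function(query, reference, paired = FALSE) {
  stopifnot(inherits(query, "embedding_set"),
            inherits(reference, "embedding_set"))
  if (ncol(query$vectors) != ncol(reference$vectors)) {
    stop("Latent dimensions differ between query and reference.",
         call. = FALSE)
  }
  if (nrow(reference$vectors) == 0) stop("Empty reference set.", call. = FALSE)
  if (paired) {
    if (nrow(query$vectors) != nrow(reference$vectors) ||
        !identical(query$cell_ids, reference$cell_ids)) {
      stop("This metric needs paired hold-out embeddings: same cells in the ",
           "same order in both modalities.", call. = FALSE)
    }
  }
  invisible(TRUE)
}

clip_k <- function(k, n) {
  k <- as.integer(k)
  if (k < 1) stop("`k` must be >= 1.", call. = FALSE)
  if (k > n) {
    warning("k = ", k, " exceeds reference size ", n, "; clipped.",
            call. = FALSE)
    k <- n
  }
  k
}

#' Recall@k: is the matched cell among the k nearest cross-modal neighbors?
#'
#' For each query cell i, the k nearest reference embeddings (Euclidean
#' distance) are found in the other modality; Recall@k is the fraction of
#' cells whose matched counterpart (same index, since the hold-out set is
#' paired) is among them. Distance ties are broken by reference index order.
#'
#' @param query,reference Paired [embedding_set()]s (same cells, same order).
#' @param k Neighborhood size, `1 <= k <= N` (clipped to N with a warning).
#' @return A value in \[0, 1\].
#' @export
recall_at_k <- function(query, reference, k) {
  check_embeddings(query, reference, paired = TRUE)
  n <- nrow(reference$vectors)
  k <- clip_k(k, n)
  d <- euclidean_cross(query$vectors, reference$vectors)
  hits <- vapply(seq_len(n), function(i) {
    ord <- order(d[i, ])          # stable: ties broken by reference index
    match(i, ord) <= k
  }, logical(1))
  mean(hits)
}

#' Cell type@k: label agreement of the k nearest cross-modal neighbors
#'
#' For each query cell, the fraction of its k nearest reference embeddings
#' (other modality) sharing its cell-type label, averaged over query cells.
#' No index matching is needed, so it applies to unpaired hold-outs too.
#'
#' @param query,reference Labeled [embedding_set()]s.
#' @param k Neighborhood size (clipped to the reference size with a warning).
#' @return A value in \[0, 1\].
#' @export
cell_type_at_k <- function(query, reference, k) {
  check_embeddings(query, reference, paired = FALSE)
  n_ref <- nrow(reference$vectors)
  k <- clip_k(k, n_ref)
  d <- euclidean_cross(query$vectors, reference$vectors)
  fracs <- vapply(seq_len(nrow(d)), function(i) {
    nn <- order(d[i, ])[seq_len(k)]
    mean(reference$cell_types[nn] == query$cell_types[i])
  }, numeric(1))
  mean(fracs)
}

#' Cell type accuracy: one-nearest-neighbor label transfer across modalities
#'
#' The fraction of query cells whose single nearest reference embedding
#' carries the same cell-type label; identical by definition to
#' [cell_type_at_k()] with `k = 1`.
#'
#' @param query,reference Labeled [embedding_set()]s.
#' @return A value in \[0, 1\].
#' @export
cell_type_accuracy <- function(query, reference) {
  cell_type_at_k(query, reference, 1L)
}

#' Median rank of the matched cell among cross-modal distances
#'
#' For each query cell, its matched reference embedding is ranked (1-based)
#' among all N reference distances sorted ascending; the matched pair is
#' assigned the best rank among distance ties. Returns the median raw rank
#' and the normalized value raw / N, so perfect alignment gives 1/N (near
#' zero).
#'
#' @param query,reference Paired [embedding_set()]s.
#' @return A list with `raw` (in \[1, N\]) and `normalized` (in (0, 1\]).
#' @export
median_rank <- function(query, reference) {
  check_embeddings(query, reference, paired = TRUE)
  n <- nrow(reference$vectors)
  d <- euclidean_cross(query$vectors, reference$vectors)
  ranks <- vapply(seq_len(n), function(i) {
    1 + sum(d[i, ] < d[i, i])   # optimistic tie rule: match wins ties
  }, numeric(1))
  raw <- stats::median(ranks)
  list(raw = raw, normalized = raw / n)
}

#' Build the joint embedding of two modalities
#'
#' Matched cells (paired hold-out): per-cell concatenation along features,
#' giving an N x 2d matrix with one label per cell. Unmatched cells: stacking
#' along rows, giving an (n1 + n2) x d matrix where each cell keeps its own
#' label. ASW is computed on this joint matrix.
#'
#' @param emb1,emb2 [embedding_set()]s.
#' @param matched Concatenate per cell (requires same cells/order) or stack?
#' @return A numeric matrix with a `cell_types` attribute (and `cell_ids`).
#' @export
build_joint_embedding <- function(emb1, emb2, matched = TRUE) {
  stopifnot(inherits(emb1, "embedding_set"), inherits(emb2, "embedding_set"))
  if (matched) {
    if (!identical(emb1$cell_ids, emb2$cell_ids)) {
      stop("matched = TRUE requires the same cells in the same order.",
           call. = FALSE)
    }
    joint <- cbind(emb1$vectors, emb2$vectors)
    attr(joint, "cell_types") <- emb1$cell_types
    attr(joint, "cell_ids") <- emb1$cell_ids
  } else {
    if (ncol(emb1$vectors) != ncol(emb2$vectors)) {
      stop("Stacking requires equal latent dimensions.", call. = FALSE)
    }
    joint <- rbind(emb1$vectors, emb2$vectors)
    attr(joint, "cell_types") <- c(emb1$cell_types, emb2$cell_types)
    attr(joint, "cell_ids") <- c(emb1$cell_ids, emb2$cell_ids)
  }
  joint
}

#' Normalized average silhouette width over cell-type clusters
#'
#' Mean silhouette width of the joint embedding's cells using cell-type
#' labels as clusters and Euclidean distance, mapped from \[-1, 1\] to
#' \[0, 1\] via (ASW + 1) / 2. Cells in singleton clusters get silhouette 0.
#'
#' @param joint A matrix from [build_joint_embedding()], or any numeric
#'   matrix with labels supplied via `labels`.
#' @param labels Cell-type labels; defaults to the matrix's `cell_types`
#'   attribute.
#' @return A value in \[0, 1\].
#' @export
asw_normalized <- function(joint, labels = attr(joint, "cell_types")) {
  if (is.null(labels)) stop("No cell-type labels supplied.", call. = FALSE)
  if (length(labels) != nrow(joint)) {
    stop("Label length does not match the number of rows.", call. = FALSE)
  }
  if (length(unique(labels)) < 2) {
    stop("Silhouette needs at least 2 distinct cell types.", call. = FALSE)
  }
  cl <- as.integer(factor(labels))
  sil <- cluster::silhouette(cl, stats::dist(joint))
  asw <- mean(sil[, "sil_width"])
  (asw + 1) / 2
}

#' Evaluate a pair of hold-out embedding sets with all five metrics
#'
#' Computes Recall@k and cell type@k over a k-grid, cell type accuracy,
#' median rank (raw and normalized) and normalized ASW of the joint
#' embedding, in both retrieval directions (modality 1 to 2 and 2 to 1).
#' Rank-based metrics (Recall@k, median rank) require a paired hold-out;
#' with `paired = FALSE` only the label-based metrics are reported and the
#' joint embedding is stacked row-wise instead of concatenated.
#'
#' @param emb1,emb2 Hold-out [embedding_set()]s.
#' @param paired Is the hold-out paired (same cells, same order)?
#' @param k_grid Neighborhood sizes; default `c(10, 20, 30, 40, 50)`.
#' @return A tibble in long format: `direction`, `metric`, `k` (NA for
#'   k-free metrics), `value`.
#' @export
evaluate_embeddings <- function(emb1, emb2, paired = TRUE,
                                k_grid = c(10, 20, 30, 40, 50)) {
  dirs <- list("1to2" = list(q = emb1, r = emb2),
               "2to1" = list(q = emb2, r = emb1))
  rows <- purrr::map_dfr(names(dirs), function(dn) {
    q <- dirs[[dn]]$q; r <- dirs[[dn]]$r
    out <- purrr::map_dfr(k_grid, function(kk) {
      metrics <- c(if (paired) "recall_at_k", "cell_type_at_k")
      vals <- c(if (paired) recall_at_k(q, r, kk),
                cell_type_at_k(q, r, kk))
      tibble::tibble(direction = dn, metric = metrics,
                     k = as.integer(kk), value = vals)
    })
    extra <- tibble::tibble(
      direction = dn,
      metric = "cell_type_accuracy",
      k = NA_integer_,
      value = cell_type_accuracy(q, r)
    )
    if (paired) {
      mr <- median_rank(q, r)
      extra <- dplyr::bind_rows(extra, tibble::tibble(
        direction = dn,
        metric = c("median_rank_raw", "median_rank_normalized"),
        k = NA_integer_,
        value = c(mr$raw, mr$normalized)
      ))
    }
    dplyr::bind_rows(out, extra)
  })
  joint <- build_joint_embedding(emb1, emb2, matched = paired)
  dplyr::bind_rows(rows, tibble::tibble(
    direction = "joint", metric = "asw_normalized",
    k = NA_integer_, value = asw_normalized(joint)
  ))
}
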