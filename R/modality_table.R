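#' A single-modality cells-by-features table
#'
#' The basic container for one omics modality: a numeric matrix with one row
#' per cell and one column per feature, together with unique cell identifiers,
#' per-cell cell-type labels and unique feature identifiers. Cell-type labels
#' are required: both training (type-structured mini-batches) and evaluation
#' (type-aware retrieval metrics) are supervised by them.
#'
#' @param values Numeric matrix (cells x features), dense or a `Matrix` sparse
#'   matrix (coerced to dense). All entries must be finite.
#' @param cell_ids Character vector of unique cell identifiers, one per row.
#' @param cell_types Character or factor vector of cell-type labels, one per
#'   row. Missing labels are an error, not imputed.
#' @param feature_ids Character vector of unique feature identifiers, one per
#'   column. Defaults to existing column names or `feat1..featP`.
#' @param modality_name Free-form modality tag, e.g. `"rna"`, `"atac"`, `"adt"`.
#'
#' @return An object of class `modality_table`.
#' @examples
#' m <- modality_table(matrix(rpois(6, 5), 3, 2),
#'                     cell_ids = c("c1", "c2", "c3"),
#'                     cell_types = c("A", "A", "B"))
#' n_cells(m)
#' @export
modality_table <- function(values, cell_ids, cell_types,
                           feature_ids = NULL, modality_name = "mod") {
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (cells x features).", call. = FALSE)
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("feat", seq_len(ncol(values)))
  }
  if (missing(cell_types) || is.null(cell_types)) {
    stop("`cell_types` is required: the model is supervised by cell type.",
         call. = FALSE)
  }
  out <- structure(
    list(
      values        = unname(values),
      cell_ids      = as.character(cell_ids),
      cell_types    = as.character(cell_types),
      feature_ids   = as.character(feature_ids),
      modality_name = as.character(modality_name)[1]
    ),
    class = "modality_table"
  )
  validate_modality_table(out)
}

#' Validate a modality table's invariants
#'
#' Checks uniqueness of cell and feature identifiers, length agreement between
#' annotations and the matrix, and finiteness of all values. Returns the table
#' unchanged when everything holds; otherwise raises a descriptive error.
#'
#' @param table A [modality_table()].
#' @return The validated `modality_table`, invisibly identical to the input.
#' @export
validate_modality_table <- function(table) {
  stopifnot(inherits(table, "modality_table"))
  v <- table$values
  n <- nrow(v); p <- ncol(v)
  if (length(table$cell_ids) != n) {
    stop("cell_ids length (", length(table$cell_ids),
         ") does not match row count (", n, ").", call. = FALSE)
  }
  if (length(table$cell_types) != n) {
    stop("cell_types length (", length(table$cell_types),
         ") does not match row count (", n, ").", call. = FALSE)
  }
  if (length(table$feature_ids) != p) {
    stop("feature_ids length (", length(table$feature_ids),
         ") does not match column count (", p, ").", call. = FALSE)
  }
  if (anyDuplicated(table$cell_ids)) {
    stop("Duplicate cell_ids: ",
         paste(unique(table$cell_ids[duplicated(table$cell_ids)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(table$feature_ids)) {
    stop("Duplicate feature_ids.", call. = FALSE)
  }
  if (anyNA(v) || any(!is.finite(v))) {
    stop("`values` contains NaN/NA/Inf entries.", call. = FALSE)
  }
  if (anyNA(table$cell_types)) {
    stop("cell_types contains missing labels.", call. = FALSE)
  }
  table
}

#' @export
print.modality_table <- function(x, ...) {
  cat("<modality_table> '", x$modality_name, "': ",
      nrow(x$values), " cells x ", ncol(x$values), " features, ",
      length(unique(x$cell_types)), " cell types\n", sep = "")
  invisible(x)
}

#' Number of cells in a modality table or dataset
#' @param x A `modality_table`, `paired_dataset` or `unpaired_dataset`.
#' @return Integer cell count (for unpaired datasets, a length-2 vector).
#' @export
n_cells <- function(x) UseMethod("n_cells")

#' @export
n_cells.modality_table <- function(x) nrow(x$values)

#' @export
n_cells.paired_dataset <- function(x) nrow(x$mod1$values)

#' @export
n_cells.unpaired_dataset <- function(x) {
  c(mod1 = nrow(x$mod1$values), mod2 = nrow(x$mod2$values))
}

#' Two modalities measured in the same cells
#'
#' Bundles two [modality_table()]s whose rows are the same physical cells in
#' the same order: cell identifiers and cell-type labels must agree
#' element-wise. This is the ground-truth correspondence that paired assays
#' (SHARE-seq, CITE-seq, 10x Multiome) provide.
#'
#' @param mod1,mod2 Two `modality_table`s over identical, identically ordered
#'   cells.
#' @return A `paired_dataset`.
#' @export
paired_dataset <- function(mod1, mod2) {
  validate_modality_table(mod1)
  validate_modality_table(mod2)
  if (!identical(mod1$cell_ids, mod2$cell_ids)) {
    stop("Paired modalities must have identical cell_ids in identical order.",
         call. = FALSE)
  }
  if (!identical(mod1$cell_types, mod2$cell_types)) {
    stop("Paired modalities must carry identical cell_types.", call. = FALSE)
  }
  structure(list(mod1 = mod1, mod2 = mod2), class = "paired_dataset")
}

#' Two modalities measured in disjoint cells sharing a type vocabulary
#'
#' The unpaired setting: each cell is observed in exactly one modality, so no
#' row-level correspondence exists; only the shared cell-type vocabulary links
#' the two tables. Cell identifier sets must be disjoint and the type
#' vocabularies must intersect.
#'
#' @param mod1,mod2 Two `modality_table`s over disjoint cell sets.
#' @return An `unpaired_dataset`.
#' @export
unpaired_dataset <- function(mod1, mod2) {
  validate_modality_table(mod1)
  validate_modality_table(mod2)
  if (length(intersect(mod1$cell_ids, mod2$cell_ids)) > 0) {
    stop("Unpaired modalities must have disjoint cell_ids.", call. = FALSE)
  }
  shared <- intersect(unique(mod1$cell_types), unique(mod2$cell_types))
  if (length(shared) == 0) {
    stop("Unpaired modalities share no cell types; nothing links them.",
         call. = FALSE)
  }
  structure(list(mod1 = mod1, mod2 = mod2), class = "unpaired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat("<paired_dataset> ", nrow(x$mod1$values), " matched cells; modalities '",
      x$mod1$modality_name, "' (", ncol(x$mod1$values), " features) + '",
      x$mod2$modality_name, "' (", ncol(x$mod2$values), " features)\n",
      sep = "")
  invisible(x)
}

#' @export
print.unpaired_dataset <- function(x, ...) {
  cat("<unpaired_dataset> '", x$mod1$modality_name, "': ",
      nrow(x$mod1$values), " cells; '", x$mod2$modality_name, "': ",
      nrow(x$mod2$values), " cells (disjoint)\n", sep = "")
  invisible(x)
}

#' Subset cells of a table or paired dataset by row index
#'
#' For a paired dataset both modalities are subset by the same indices, so the
#' pairing invariant is preserved. Indices are 1-based row positions.
#'
#' @param x A `modality_table` or `paired_dataset`.
#' @param indices Integer vector of valid, non-empty row positions.
#' @return The same class as `x`, restricted to `indices` in order.
#' @export
subset_cells <- function(x, indices) UseMethod("subset_cells")

check_indices <- function(indices, n) {
  if (length(indices) == 0) {
    stop("`indices` is empty; a dataset needs at least one cell.", call. = FALSE)
  }
  indices <- as.integer(indices)
  if (anyNA(indices) || any(indices < 1L) || any(indices > n)) {
    stop("`indices` out of range [1, ", n, "].", call. = FALSE)
  }
  indices
}

#' @export
subset_cells.modality_table <- function(x, indices) {
  indices <- check_indices(indices, nrow(x$values))
  modality_table(x$values[indices, , drop = FALSE],
                 cell_ids = x$cell_ids[indices],
                 cell_types = x$cell_types[indices],
                 feature_ids = x$feature_ids,
                 modality_name = x$modality_name)
}

#' @export
subset_cells.paired_dataset <- function(x, indices) {
  paired_dataset(subset_cells(x$mod1, indices), subset_cells(x$mod2, indices))
}

#' Convert a modality table to a tibble
#'
#' One row per cell: `cell_id`, `cell_type`, then feature columns. Convenient
#' for dplyr-style inspection of small tables; the matrix form remains the
#' computational representation.
#'
#' @param x A `modality_table`.
#' @param ... Unused.
#' @return A tibble with `2 + n_features` columns.
#' @method as_tibble modality_table
#' @export
as_tibble.modality_table <- function(x, ...) {
  vals <- x$values
  colnames(vals) <- x$feature_ids
  dplyr::bind_cols(
    tibble::tibble(cell_id = x$cell_ids, cell_type = x$cell_types),
    tibble::as_tibble(vals)
  )
}
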