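#' Simulate an unpaired dataset from a paired one
#'
#' Emulates the unpaired setting from paired ground truth: a uniformly random
#' subset of `round(proportion * N)` cells keeps only its second-modality
#' profile (the "minor" modality — ATAC or ADT in typical designs) and the
#' complementary cells keep only the first modality, so the two resulting
#' cell sets are disjoint and linked only by their cell-type labels. Applied
#' to the training portion only; the hold-out set stays paired so rank-based
#' metrics remain computable.
#'
#' @param paired A [paired_dataset()].
#' @param proportion Fraction of cells retained in the minor modality, in
#'   (0, 1); values where `round(proportion * N)` is 0 or N are errors.
#' @param seed Integer seed; the partition is deterministic given it.
#' @param which_modality_minor Which modality keeps the minority subset: 1
#'   or 2 (default 2).
#' @param stratified Sample the subset within each cell type (guaranteeing
#'   every type survives in both modalities at small proportions)? Default
#'   FALSE: uniform over cells, so at tiny proportions a type may vanish from
#'   one modality and is then excluded from training batches.
#' @return An [unpaired_dataset()] with an attribute `minor_indices` (the
#'   row indices of `paired` retained in the minor modality).
#' @export
simulate_unpaired <- function(paired, proportion, seed = 0L,
                              which_modality_minor = 2,
                              stratified = FALSE) {
  stopifnot(inherits(paired, "paired_dataset"),
            which_modality_minor %in% c(1, 2))
  n <- nrow(paired$mod1$values)
  if (!is.numeric(proportion) || proportion <= 0 || proportion > 1) {
    stop("`proportion` must lie in (0, 1].", call. = FALSE)
  }
  n_minor <- round(proportion * n)
  if (n_minor < 1 || n_minor >= n) {
    stop("round(proportion * N) = ", n_minor,
         " leaves one modality empty; choose a different proportion.",
         call. = FALSE)
  }
  minor <- withr::with_seed(as.integer(seed), {
    if (stratified) {
      types <- paired$mod1$cell_types
      unlist(lapply(split(seq_len(n), types), function(idx) {
        m <- max(1L, round(proportion * length(idx)))
        sample(idx, min(m, length(idx) - 1L))
      }), use.names = FALSE)
    } else {
      sample.int(n, n_minor)
    }
  })
  minor <- sort(minor)
  major <- setdiff(seq_len(n), minor)
  tabs <- list(subset_cells(paired$mod1, major),
               subset_cells(paired$mod2, minor))
  if (which_modality_minor == 1) {
    tabs <- list(subset_cells(paired$mod1, minor),
                 subset_cells(paired$mod2, major))
  }
  out <- unpaired_dataset(tabs[[1]], tabs[[2]])
  attr(out, "minor_indices") <- minor
  out
}

#' Randomly permute cell-type labels (random baseline)
#'
#' Replaces the label vector by a uniform random permutation of itself, so
#' the marginal type counts are preserved while any association between
#' profile and type is destroyed — the random baseline against which
#' trained models are compared.
#'
#' @param table A [modality_table()].
#' @param seed Integer seed.
#' @return The table with permuted `cell_types`; values untouched.
#' @export
permute_labels <- function(table, seed = 0L) {
  validate_modality_table(table)
  perm <- withr::with_seed(as.integer(seed),
                           sample.int(length(table$cell_types)))
  table$cell_types <- table$cell_types[perm]
  table
}
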