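#' Deterministic train/test split of cells
#'
#' Draws a uniformly random hold-out set of `round(test_fraction * n_cells)`
#' cells. The random stream is seeded with `seed + replicate_index`, so the
#' same specification always yields the identical split, and consecutive
#' replicate indices give independent splits — the basis of the replicated
#' leakage-free evaluation protocol.
#'
#' @param n_cells Number of cells (>= 2).
#' @param test_fraction Hold-out fraction in (0, 1). Default 0.3.
#' @param seed Base integer seed.
#' @param replicate_index Replicate number (>= 0); added to `seed`.
#' @return A list with sorted integer vectors `train` and `test`, disjoint and
#'   jointly covering `1:n_cells`, plus the effective `seed` used.
#' @examples
#' s <- make_split(10, test_fraction = 0.3, seed = 1)
#' length(s$test)  # 3
#' @export
make_split <- function(n_cells, test_fraction = 0.3, seed = 0L,
                       replicate_index = 0L) {
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 2L) {
    stop("`n_cells` must be >= 2.", call. = FALSE)
  }
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must lie strictly between 0 and 1.", call. = FALSE)
  }
  if (replicate_index < 0) stop("`replicate_index` must be >= 0.", call. = FALSE)
  n_test <- round(test_fraction * n_cells)
  n_test <- max(1L, min(n_cells - 1L, as.integer(n_test)))
  eff_seed <- as.integer(seed) + as.integer(replicate_index)
  perm <- withr::with_seed(eff_seed, sample.int(n_cells))
  list(
    train = sort(perm[(n_test + 1L):n_cells]),
    test  = sort(perm[seq_len(n_test)]),
    seed  = eff_seed
  )
}

#' Write a split to a plain-text manifest for audit
#'
#' Records the exact train and test index sets of one replicate so a run can
#' be re-executed or audited without re-deriving the random stream.
#'
#' @param split A list as returned by [make_split()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  lines <- c(
    paste0("# split manifest; seed=", split$seed),
    paste0("train\t", paste(split$train, collapse = ",")),
    paste0("test\t", paste(split$test, collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a split manifest written by [write_split_manifest()]
#' @param path Manifest file path.
#' @return A list with integer vectors `train` and `test`.
#' @export
read_split_manifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- list()
  for (p in parts) {
    out[[p[[1]]]] <- as.integer(strsplit(p[[2]], ",", fixed = TRUE)[[1]])
  }
  out
}
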