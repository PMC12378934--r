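#' Run the replicated leakage-free train/test protocol
#'
#' For each replicate r: split the cells with seed `base_seed + r`, fit the
#' preprocessing chains and encoders on the training rows only, embed the
#' held-out cells with the frozen model, and compute all metrics in both
#' retrieval directions. With `unpaired_proportion` set, the training
#' portion is first turned into a simulated unpaired dataset (the hold-out
#' set stays paired, so rank-based metrics remain computable). Replicate
#' failures are recorded and surfaced without discarding completed rows.
#'
#' @param paired A [paired_dataset()] of raw cells.
#' @param n_replicates Number of train/test splits; default 10.
#' @param test_fraction Hold-out fraction; default 0.3.
#' @param unpaired_proportion `NULL` for paired training, or a proportion in
#'   (0, 1) passed to [simulate_unpaired()] on the training rows.
#' @param prep1,prep2 Per-modality [preprocess_config()]s.
#' @param hidden_dim,latent_dim Encoder dimensions.
#' @param config A [train_config()]; its seed is re-derived per replicate as
#'   `base_seed + replicate`.
#' @param k_grid Neighborhood sizes for the k-based metrics.
#' @param base_seed Base seed for splits, unpairing and training.
#' @param manifest_dir Optional directory; per-replicate split manifests are
#'   written there as plain text.
#' @return A tibble: `replicate`, `direction`, `metric`, `k`, `value`, plus
#'   attributes `failures` (list) and `models` if `keep_models = TRUE`.
#' @param keep_models Keep each replicate's fitted model in an attribute?
#'   Default FALSE.
#' @export
run_replicates <- function(paired, n_replicates = 10, test_fraction = 0.3,
                           unpaired_proportion = NULL,
                           prep1 = preprocess_config(),
                           prep2 = preprocess_config(),
                           hidden_dim = 256, latent_dim = 128,
                           config = train_config(),
                           k_grid = c(10, 20, 30, 40, 50),
                           base_seed = 0L, manifest_dir = NULL,
                           keep_models = FALSE) {
  stopifnot(inherits(paired, "paired_dataset"), n_replicates >= 1)
  n <- nrow(paired$mod1$values)
  failures <- list()
  models <- list()
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      split <- make_split(n, test_fraction, base_seed, replicate_index = r)
      if (!is.null(manifest_dir)) {
        write_split_manifest(
          split, file.path(manifest_dir, sprintf("split_rep%02d.txt", r)))
      }
      train_ds <- subset_cells(paired, split$train)
      test_ds <- subset_cells(paired, split$test)
      if (!is.null(unpaired_proportion)) {
        train_ds <- simulate_unpaired(train_ds, unpaired_proportion,
                                      seed = split$seed)
      }
      cfg <- config
      cfg$seed <- as.integer(base_seed) + r
      fit <- fit_modalign(train_ds, prep1, prep2, hidden_dim, latent_dim, cfg)
      emb <- embed_holdout(fit, test_ds)
      tbl <- evaluate_embeddings(emb$mod1, emb$mod2, paired = TRUE, k_grid)
      if (keep_models) models[[r]] <- fit
      dplyr::mutate(tbl, replicate = r, .before = 1)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("Replicate ", r, " failed: ", conditionMessage(res),
              call. = FALSE)
      failures[[as.character(r)]] <- conditionMessage(res)
    } else {
      rows[[r]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "failures") <- failures
  if (keep_models) attr(out, "models") <- models
  out
}

#' Aggregate long-format metric reports into a mean/sd summary
#'
#' @param reports A long-format metric tibble (e.g. from [run_replicates()]
#'   or [evaluate_embeddings()]) or a list of such tibbles / paths to CSV
#'   files written by [write_metric_report()].
#' @return A tibble grouped by `direction`, `metric`, `k` with columns
#'   `mean`, `sd`, `n`.
#' @export
aggregate_reports <- function(reports) {
  if (is.character(reports)) {
    reports <- lapply(reports, function(p) {
      df <- utils::read.csv(p, stringsAsFactors = FALSE)
      needed <- c("direction", "metric", "k", "value")
      if (!all(needed %in% names(df))) {
        stop("Report ", p, " lacks required columns ",
             paste(setdiff(needed, names(df)), collapse = ", "), ".",
             call. = FALSE)
      }
      tibble::as_tibble(df)
    })
  }
  if (is.data.frame(reports)) reports <- list(reports)
  if (length(reports) == 0) stop("No reports supplied.", call. = FALSE)
  long <- dplyr::bind_rows(reports)
  dplyr::summarise(
    dplyr::group_by(long, .data$direction, .data$metric, .data$k),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    n = dplyr::n(), .groups = "drop"
  )
}

#' Write / read a metric report as CSV
#'
#' Long format (one row per replicate x direction x metric x k), suitable
#' for direct plotting or language-agnostic downstream use.
#'
#' @param report A metric tibble.
#' @param path CSV file path.
#' @return `path` (write) or the tibble (read).
#' @export
write_metric_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metric_report
#' @export
read_metric_report <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
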