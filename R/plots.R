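#' Plot the training loss curve of a fitted model
#'
#' @param object A `modalign_model`.
#' @param ... Unused.
#' @return A ggplot object: epoch-mean contrastive loss per epoch.
#' @method autoplot modalign_model
#' @export
autoplot.modalign_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$mean_loss)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_point(size = 0.8, color = "#2c7fb8") +
    ggplot2::labs(x = "Epoch", y = "Mean contrastive loss",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}

#' Box plot of replicate metric values
#'
#' One box per metric (faceted by retrieval direction), mirroring the usual
#' presentation of replicated integration benchmarks.
#'
#' @param report A long-format metric tibble from [run_replicates()].
#' @param metrics Optional character vector restricting the metrics shown.
#' @return A ggplot object.
#' @export
plot_metric_report <- function(report, metrics = NULL) {
  df <- report
  if (!is.null(metrics)) df <- dplyr::filter(df, .data$metric %in% metrics)
  df <- dplyr::mutate(df, label = ifelse(is.na(.data$k), .data$metric,
                                         paste0(.data$metric, "@", .data$k)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "#a6bddb") +
    ggplot2::facet_wrap(~direction, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# 2-D coordinates of a joint embedding for plotting. "pca" is the native
# deterministic default; "tsne" delegates to python scikit-learn when a
# suitable interpreter is on the PATH.
embed_2d <- function(joint, method = c("pca", "tsne"), seed = 0L) {
  method <- match.arg(method)
  if (method == "pca") {
    xc <- sweep(joint, 2, colMeans(joint), "-")
    sv <- svd(xc, nu = 0, nv = 2)
    return(xc %*% sv$v)
  }
  if (!nzchar(Sys.which("python"))) {
    stop("t-SNE needs a `python` interpreter with scikit-learn on the PATH; ",
         "use method = 'pca' instead.", call. = FALSE)
  }
  tmp <- tempfile("tsne_"); dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  utils::write.table(joint, file.path(tmp, "x.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  script <- file.path(tmp, "tsne.py")
  writeLines(c(
    "import sys, numpy as np",
    "from sklearn.manifold import TSNE",
    "x = np.loadtxt(sys.argv[1])",
    "y = TSNE(n_components=2, random_state=int(sys.argv[3]),",
    "         perplexity=min(30, (x.shape[0] - 1) / 3)).fit_transform(x)",
    "np.savetxt(sys.argv[2], y)"
  ), script)
  status <- suppressWarnings(system2("python", c(script, file.path(tmp, "x.tsv"),
                                file.path(tmp, "y.tsv"), as.integer(seed)),
                    stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(status, "status"))) {
    stop("t-SNE failed: ", paste(status, collapse = "\n"), call. = FALSE)
  }
  as.matrix(utils::read.table(file.path(tmp, "y.tsv")))
}

#' Scatter plot of a joint embedding colored by cell type
#'
#' Projects the joint embedding to two dimensions (PCA by default; t-SNE via
#' an external python scikit-learn call) and draws a labeled scatter. A
#' visual aid with no numerical contract.
#'
#' @param joint A matrix from [build_joint_embedding()].
#' @param labels Cell-type labels; defaults to the matrix's `cell_types`
#'   attribute.
#' @param method `"pca"` (default) or `"tsne"`.
#' @param seed Seed passed to t-SNE.
#' @param out_path Optional file path; when given the plot is also saved
#'   there with [ggplot2::ggsave()].
#' @return A ggplot object.
#' @export
plot_joint_embedding <- function(joint, labels = attr(joint, "cell_types"),
                                 method = c("pca", "tsne"), seed = 0L,
                                 out_path = NULL) {
  method <- match.arg(method)
  coords <- embed_2d(joint, method, seed)
  df <- tibble::tibble(dim1 = coords[, 1], dim2 = coords[, 2],
                       cell_type = labels)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                         color = .data$cell_type)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::labs(x = paste0(method, " 1"), y = paste0(method, " 2"),
                  color = "Cell type") +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) {
    ok <- tryCatch({ggplot2::ggsave(out_path, gg, width = 6, height = 5); TRUE},
                   error = function(e) {
                     message("Could not save plot: ", conditionMessage(e))
                     FALSE
                   })
  }
  gg
}
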