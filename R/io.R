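# h5ad import/export. R in this package's dependency set has no native HDF5
# reader, so the bridge delegates to the `python` interpreter with the
# `anndata` package (standard in single-cell environments), exchanging the
# matrix as MatrixMarket and the annotations as TSV through a temp directory.

python_available <- function(python = "python") {
  nzchar(Sys.which(python)) &&
    system2(python, c("-c", shQuote("import anndata, scipy.io")),
            stdout = FALSE, stderr = FALSE) == 0
}

#' Read one modality from an h5ad (AnnData) file
#'
#' Loads the main matrix layer (`X`, dense or CSR/CSC sparse), the cell
#' identifiers (`obs_names`), a cell-type observation column and the feature
#' identifiers (`var_names`). Requires a `python` interpreter with the
#' `anndata` package on the PATH; the conversion goes through temporary
#' MatrixMarket/TSV files.
#'
#' @param path Path to the .h5ad file.
#' @param cell_type_col Name of the obs column holding cell-type labels;
#'   default `"cell_type"`.
#' @param modality_name Modality tag for the returned table.
#' @param python Python interpreter to invoke; default `"python"`.
#' @return A [modality_table()].
#' @export
read_h5ad_modality <- function(path, cell_type_col = "cell_type",
                               modality_name = "mod", python = "python") {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  if (!python_available(python)) {
    stop("h5ad import needs a `python` interpreter with the `anndata` ",
         "package on the PATH.", call. = FALSE)
  }
  tmp <- tempfile("h5ad_bridge_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  script <- file.path(tmp, "export.py")
  writeLines(c(
    "import sys, anndata, numpy as np, scipy.sparse as sp, scipy.io as sio",
    "path, out, col = sys.argv[1], sys.argv[2], sys.argv[3]",
    "ad = anndata.read_h5ad(path)",
    "x = ad.X",
    "x = sp.coo_matrix(x) if sp.issparse(x) else sp.coo_matrix(np.asarray(x))",
    "sio.mmwrite(out + '/x.mtx', x)",
    "if col not in ad.obs.columns:",
    "    sys.exit('missing obs column: ' + col)",
    "with open(out + '/obs.tsv', 'w') as f:",
    "    f.write('cell_id\\tcell_type\\n')",
    "    for i, t in zip(ad.obs_names, ad.obs[col].astype(str)):",
    "        f.write(str(i) + '\\t' + t + '\\n')",
    "with open(out + '/var.tsv', 'w') as f:",
    "    f.write('\\n'.join(map(str, ad.var_names)) + '\\n')"
  ), script)
  status <- suppressWarnings(system2(python, c(script, shQuote(path), shQuote(tmp),
                              shQuote(cell_type_col)),
                    stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(status, "status"))) {
    stop("h5ad export failed: ", paste(status, collapse = "\n"),
         call. = FALSE)
  }
  x <- as.matrix(Matrix::readMM(file.path(tmp, "x.mtx")))
  obs <- utils::read.delim(file.path(tmp, "obs.tsv"),
                           stringsAsFactors = FALSE)
  vars <- readLines(file.path(tmp, "var.tsv"))
  modality_table(x, obs$cell_id, obs$cell_type, feature_ids = vars,
                 modality_name = modality_name)
}

#' Write a modality table to an h5ad (AnnData) file
#'
#' Counterpart of [read_h5ad_modality()]; the cell-type labels go into the
#' obs column named by `cell_type_col`.
#'
#' @param table A [modality_table()].
#' @param path Output .h5ad path.
#' @inheritParams read_h5ad_modality
#' @return `path`, invisibly.
#' @export
write_h5ad_modality <- function(table, path, cell_type_col = "cell_type",
                                python = "python") {
  validate_modality_table(table)
  if (!python_available(python)) {
    stop("h5ad export needs a `python` interpreter with the `anndata` ",
         "package on the PATH.", call. = FALSE)
  }
  tmp <- tempfile("h5ad_bridge_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  Matrix::writeMM(Matrix::Matrix(table$values, sparse = TRUE),
                  file.path(tmp, "x.mtx"))
  utils::write.table(
    data.frame(cell_id = table$cell_ids, cell_type = table$cell_types),
    file.path(tmp, "obs.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(table$feature_ids, file.path(tmp, "var.tsv"))
  script <- file.path(tmp, "import.py")
  writeLines(c(
    "import sys, anndata, pandas as pd, scipy.io as sio",
    "tmp, out, col = sys.argv[1], sys.argv[2], sys.argv[3]",
    "x = sio.mmread(tmp + '/x.mtx').tocsr()",
    "obs = pd.read_csv(tmp + '/obs.tsv', sep='\\t', dtype=str)",
    "var_names = [l.strip() for l in open(tmp + '/var.tsv')]",
    "ad = anndata.AnnData(X=x,",
    "    obs=pd.DataFrame({col: obs['cell_type'].values},",
    "                     index=obs['cell_id'].values),",
    "    var=pd.DataFrame(index=var_names))",
    "ad.write_h5ad(out)"
  ), script)
  status <- suppressWarnings(system2(python, c(script, shQuote(tmp), shQuote(path),
                              shQuote(cell_type_col)),
                    stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(status, "status"))) {
    stop("h5ad write failed: ", paste(status, collapse = "\n"),
         call. = FALSE)
  }
  invisible(path)
}
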