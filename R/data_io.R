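#' Load an expression dataset from disk
#'
#' Reads a cells-by-genes expression matrix, with optional 2-D coordinates
#' and cell-type labels, from one of three on-disk layouts:
#'
#' * `"csv"` — a single comma-separated file with a header row and cell ids
#'   in the first column; gene columns hold expression, and coordinates may
#'   be present either as columns named by `coord_keys` (default `x`, `y`)
#'   or in a sidecar CSV given by `coords_path` (columns: cell id, x, y).
#'   A column named `cell_type` is read as labels.
#' * `"mtx_dir"` — a directory with `matrix.mtx` (genes in rows, cells in
#'   columns, as written by CellRanger), `features.tsv`, `barcodes.tsv`,
#'   and optionally `coords.csv` / `cell_types.tsv`.
#' * `"h5ad"` — an AnnData file; the main matrix is read as expression,
#'   coordinates from `obsm[coord_keys[1]]` (default `"spatial"`) or obs
#'   columns, and `obs$cell_type` as labels. Requires a `python`
#'   interpreter with the `anndata` package on the PATH.
#'
#' @param path file (csv, h5ad) or directory (mtx_dir).
#' @param format one of `"csv"`, `"mtx_dir"`, `"h5ad"`. Guessed from the
#'   path when missing.
#' @param coord_keys names of the coordinate columns (csv) or the obsm slot
#'   (h5ad).
#' @param coords_path optional sidecar CSV of coordinates (csv format only).
#' @param platform platform tag attached when coordinates are found.
#' @param is_lognorm set `TRUE` when the stored values are already
#'   log-normalized.
#'
#' @return A [spatial_dataset()] when coordinates are present, otherwise an
#'   [expression_profile()]. Gene and cell ordering of the file is kept.
#' @export
load_dataset <- function(path, format = c("csv", "mtx_dir", "h5ad"),
                         coord_keys = NULL, coords_path = NULL,
                         platform = "single_cell", is_lognorm = FALSE) {
  if (missing(format)) {
    format <- if (dir.exists(path)) "mtx_dir"
      else if (grepl("\\.h5ad$", path)) "h5ad" else "csv"
  }
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path)
  switch(format,
    csv = load_csv(path, coord_keys %||% c("x", "y"), coords_path,
                   platform, is_lognorm),
    mtx_dir = load_mtx_dir(path, platform, is_lognorm),
    h5ad = load_h5ad(path, coord_keys %||% "spatial", platform, is_lognorm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_csv <- function(path, coord_keys, coords_path, platform, is_lognorm) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed CSV: need cell ids plus data columns")
  cell_ids <- as.character(df[[1L]])
  header <- names(df)[-1L]        # before subsetting: data-frame
  df <- df[, -1L, drop = FALSE]   # extraction deduplicates names
  names(df) <- header
  special <- c(coord_keys, "cell_type")
  coords <- NULL
  if (all(coord_keys %in% names(df))) {
    coords <- as.matrix(df[, coord_keys, drop = FALSE])
  } else if (!is.null(coords_path)) {
    cdf <- utils::read.csv(coords_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    idx <- match(cell_ids, as.character(cdf[[1L]]))
    if (anyNA(idx))
      stop("coords sidecar is missing cells: ",
           paste(utils::head(cell_ids[is.na(idx)], 5L), collapse = ", "))
    coords <- as.matrix(cdf[idx, 2:3, drop = FALSE])
  }
  cell_types <- if ("cell_type" %in% names(df))
    as.character(df[["cell_type"]]) else NULL
  keep <- !(names(df) %in% special)
  values <- as.matrix(df[, keep, drop = FALSE])
  prof <- expression_profile(values, gene_ids = names(df)[keep],
                             cell_ids = cell_ids,
                             cell_types = cell_types,
                             is_lognorm = is_lognorm)
  if (is.null(coords)) prof
  else spatial_dataset(prof, coords, platform)
}

load_mtx_dir <- function(path, platform, is_lognorm) {
  mtx <- file.path(path, "matrix.mtx")
  feat <- file.path(path, "features.tsv")
  barc <- file.path(path, "barcodes.tsv")
  for (f in c(mtx, feat, barc))
    if (!file.exists(f)) stop("missing file in mtx directory: ", f)
  m <- Matrix::readMM(mtx)          # genes x cells
  genes <- utils::read.delim(feat, header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  cells <- utils::read.delim(barc, header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  values <- t(as.matrix(m))
  types_file <- file.path(path, "cell_types.tsv")
  cell_types <- if (file.exists(types_file))
    utils::read.delim(types_file, header = FALSE,
                      stringsAsFactors = FALSE)[[1L]] else NULL
  prof <- expression_profile(values, gene_ids = genes, cell_ids = cells,
                             cell_types = cell_types,
                             is_lognorm = is_lognorm)
  coords_file <- file.path(path, "coords.csv")
  if (file.exists(coords_file)) {
    cdf <- utils::read.csv(coords_file, stringsAsFactors = FALSE)
    idx <- match(cells, as.character(cdf[[1L]]))
    if (anyNA(idx)) stop("coords.csv is missing cells")
    spatial_dataset(prof, as.matrix(cdf[idx, 2:3]), platform)
  } else prof
}

#' Write a dataset to disk
#'
#' Inverse of [load_dataset()] for the `csv`, `mtx_dir` and `h5ad` layouts;
#' coordinates and cell types are stored alongside expression so that a
#' round trip reproduces the object.
#'
#' @param x an [expression_profile()] or [spatial_dataset()].
#' @param path output file (csv, h5ad) or directory (mtx_dir).
#' @param format one of `"csv"`, `"mtx_dir"`, `"h5ad"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path, format = c("csv", "mtx_dir", "h5ad")) {
  format <- match.arg(format)
  prof <- as_profile(x)
  coords <- if (inherits(x, "spatial_dataset")) x$coords else NULL
  switch(format,
    csv = {
      df <- data.frame(cell_id = prof$cell_ids, check.names = FALSE)
      df <- cbind(df, as.data.frame(prof$values, check.names = FALSE))
      if (!is.null(coords)) { df$x <- coords[, 1L]; df$y <- coords[, 2L] }
      if (!is.null(prof$cell_types)) df$cell_type <- prof$cell_types
      utils::write.csv(df, path, row.names = FALSE)
    },
    mtx_dir = {
      dir.create(path, showWarnings = FALSE, recursive = TRUE)
      Matrix::writeMM(Matrix::Matrix(t(prof$values), sparse = TRUE),
                      file.path(path, "matrix.mtx"))
      writeLines(prof$gene_ids, file.path(path, "features.tsv"))
      writeLines(prof$cell_ids, file.path(path, "barcodes.tsv"))
      if (!is.null(coords))
        utils::write.csv(data.frame(cell_id = prof$cell_ids,
                                    x = coords[, 1L], y = coords[, 2L]),
                         file.path(path, "coords.csv"), row.names = FALSE)
      if (!is.null(prof$cell_types))
        writeLines(prof$cell_types, file.path(path, "cell_types.tsv"))
    },
    h5ad = write_h5ad(prof, coords, path))
  invisible(path)
}

# ---- h5ad via the python interpreter (anndata) --------------------------

find_python <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("h5ad support needs a python interpreter with the anndata ",
         "package on the PATH")
  py
}

run_python <- function(code) {
  py <- find_python()
  f <- tempfile(fileext = ".py")
  on.exit(unlink(f))
  writeLines(code, f)
  out <- suppressWarnings(system2(py, f, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L)
    stop("python h5ad bridge failed:\n", paste(out, collapse = "\n"))
  invisible(out)
}

load_h5ad <- function(path, coord_key, platform, is_lognorm) {
  tmp <- tempfile("h5ad_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  code <- sprintf('
import anndata, numpy as np, pandas as pd, scipy.sparse as sp
ad = anndata.read_h5ad(%s)
X = ad.X.toarray() if sp.issparse(ad.X) else np.asarray(ad.X)
df = pd.DataFrame(X, index=ad.obs_names, columns=ad.var_names)
df.to_csv(%s)
key = %s
if key in ad.obsm:
    c = np.asarray(ad.obsm[key])[:, :2]
    pd.DataFrame({"cell_id": ad.obs_names, "x": c[:,0], "y": c[:,1]}).to_csv(%s, index=False)
elif "x" in ad.obs.columns and "y" in ad.obs.columns:
    pd.DataFrame({"cell_id": ad.obs_names, "x": ad.obs["x"], "y": ad.obs["y"]}).to_csv(%s, index=False)
if "cell_type" in ad.obs.columns:
    pd.DataFrame({"cell_type": ad.obs["cell_type"].astype(str)}).to_csv(%s, index=False)
', deparse(path), deparse(file.path(tmp, "X.csv")), deparse(coord_key),
   deparse(file.path(tmp, "coords.csv")), deparse(file.path(tmp, "coords.csv")),
   deparse(file.path(tmp, "types.csv")))
  run_python(code)
  df <- utils::read.csv(file.path(tmp, "X.csv"), check.names = FALSE,
                        stringsAsFactors = FALSE)
  cell_ids <- as.character(df[[1L]])
  values <- as.matrix(df[, -1L, drop = FALSE])
  types_file <- file.path(tmp, "types.csv")
  cell_types <- if (file.exists(types_file))
    utils::read.csv(types_file, stringsAsFactors = FALSE)$cell_type else NULL
  prof <- expression_profile(values, gene_ids = colnames(values),
                             cell_ids = cell_ids, cell_types = cell_types,
                             is_lognorm = is_lognorm)
  coords_file <- file.path(tmp, "coords.csv")
  if (file.exists(coords_file)) {
    cdf <- utils::read.csv(coords_file, stringsAsFactors = FALSE)
    spatial_dataset(prof, as.matrix(cdf[, c("x", "y")]), platform)
  } else prof
}

write_h5ad <- function(prof, coords, path) {
  tmp <- tempfile("h5ad_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  df <- data.frame(cell_id = prof$cell_ids, check.names = FALSE)
  df <- cbind(df, as.data.frame(prof$values, check.names = FALSE))
  utils::write.csv(df, file.path(tmp, "X.csv"), row.names = FALSE)
  if (!is.null(coords))
    utils::write.csv(data.frame(x = coords[, 1L], y = coords[, 2L]),
                     file.path(tmp, "coords.csv"), row.names = FALSE)
  if (!is.null(prof$cell_types))
    utils::write.csv(data.frame(cell_type = prof$cell_types),
                     file.path(tmp, "types.csv"), row.names = FALSE)
  code <- sprintf('
import anndata, numpy as np, pandas as pd, os
df = pd.read_csv(%s, index_col=0)
ad = anndata.AnnData(X=df.values.astype("float64"),
                     obs=pd.DataFrame(index=df.index.astype(str)),
                     var=pd.DataFrame(index=df.columns.astype(str)))
cf = %s
if os.path.exists(cf):
    ad.obsm["spatial"] = pd.read_csv(cf).values.astype("float64")
tf = %s
if os.path.exists(tf):
    ad.obs["cell_type"] = pd.read_csv(tf)["cell_type"].astype(str).values
ad.write_h5ad(%s)
', deparse(file.path(tmp, "X.csv")), deparse(file.path(tmp, "coords.csv")),
   deparse(file.path(tmp, "types.csv")), deparse(path))
  run_python(code)
}

# ---- normalization and gene selection -----------------------------------

#' Library-size log-normalization
#'
#' Scales each cell's counts to a common total and applies `log1p`. The
#' common total is either a fixed number or the median library size across
#' cells (`target_sum = "median"`, the default). This is the standard
#' size-factor/log1p transform; pooling-based size-factor estimation is
#' deliberately not performed — pre-normalized data can be supplied with
#' `is_lognorm = TRUE` instead.
#'
#' @param profile an [expression_profile()] of raw counts
#'   (`is_lognorm = FALSE`).
#' @param target_sum positive number, or `"median"`.
#' @return A log-normalized [expression_profile()].
#' @export
log_normalize <- function(profile, target_sum = "median") {
  profile <- as_profile(profile)
  if (profile$is_lognorm)
    stop("profile is already log-normalized; refusing to re-apply")
  totals <- rowSums(profile$values)
  if (any(totals <= 0)) {
    bad <- profile$cell_ids[totals <= 0]
    stop("cells with zero total counts: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  ts <- if (identical(target_sum, "median")) stats::median(totals)
        else as.numeric(target_sum)
  if (!is.finite(ts) || ts <= 0) stop("target_sum must be positive")
  scaled <- profile$values * (ts / totals)
  expression_profile(log1p(scaled), gene_ids = profile$gene_ids,
                     cell_ids = profile$cell_ids,
                     cell_types = profile$cell_types, is_lognorm = TRUE)
}

#' Restrict two profiles to their shared genes
#'
#' Subsets both profiles to the intersection of their gene ids, in the
#' order the genes appear in `st`. Matching is by exact, case-sensitive
#' string identity.
#'
#' @param sc,st [expression_profile()] objects (a [spatial_dataset()] is
#'   accepted for `st`; its profile is used and the dataset returned intact
#'   apart from the gene subset).
#' @return A list with elements `sc` and `st` restricted to the shared
#'   genes.
#' @export
align_genes <- function(sc, st) {
  sc <- as_profile(sc)
  st_ds <- if (inherits(st, "spatial_dataset")) st else NULL
  stp <- as_profile(st)
  shared <- intersect(stp$gene_ids, sc$gene_ids)  # ST order
  if (!length(shared))
    stop("no shared genes between the two profiles")
  message("align_genes: ", length(shared), " shared genes")
  sub <- function(p) expression_profile(
    p$values[, shared, drop = FALSE], gene_ids = shared,
    cell_ids = p$cell_ids, cell_types = p$cell_types,
    is_lognorm = p$is_lognorm)
  st_out <- sub(stp)
  if (!is.null(st_ds))
    st_out <- spatial_dataset(st_out, st_ds$coords, st_ds$platform)
  list(sc = sub(sc), st = st_out)
}

#' Select highly variable genes
#'
#' Keeps the `n_top` genes with the largest variance of log-normalized
#' expression (raw counts are `log1p`-transformed internally for the
#' ranking only). Gene order of the input is preserved.
#'
#' @param profile an [expression_profile()].
#' @param n_top number of genes to keep; must not exceed the gene count.
#' @return The subset [expression_profile()].
#' @export
select_hvg <- function(profile, n_top) {
  profile <- as_profile(profile)
  n_top <- as.integer(n_top)
  if (n_top < 1L || n_top > ncol(profile$values))
    stop("n_top must be between 1 and the number of genes (",
         ncol(profile$values), ")")
  v <- if (profile$is_lognorm) profile$values else log1p(profile$values)
  disp <- apply(v, 2L, stats::var)
  keep <- sort(order(disp, decreasing = TRUE)[seq_len(n_top)])
  expression_profile(profile$values[, keep, drop = FALSE],
                     gene_ids = profile$gene_ids[keep],
                     cell_ids = profile$cell_ids,
                     cell_types = profile$cell_types,
                     is_lognorm = profile$is_lognorm)
}
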