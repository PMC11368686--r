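#' Construct an expression profile
#'
#' A light container for a cells-by-genes expression matrix together with
#' gene/cell identifiers, optional cell-type labels, and a flag recording
#' whether the values have already been log-normalized.
#'
#' @param values numeric matrix, cells in rows, genes in columns. Entries
#'   must be finite and non-negative (raw counts or log-normalized values).
#' @param gene_ids character vector of unique gene identifiers, one per
#'   column. Defaults to the column names of `values`.
#' @param cell_ids character vector of unique cell identifiers, one per row.
#'   Defaults to the row names of `values`, or `cell_1..cell_n`.
#' @param cell_types optional character vector of per-cell labels.
#' @param is_lognorm logical; `TRUE` when `values` already hold
#'   log-normalized expression.
#'
#' @return An object of class `expression_profile`.
#' @export
expression_profile <- function(values, gene_ids = colnames(values),
                               cell_ids = rownames(values),
                               cell_types = NULL, is_lognorm = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != ncol(values))
    stop("gene_ids length (", length(gene_ids),
         ") does not match the number of columns (", ncol(values), ")")
  if (length(cell_ids) != nrow(values))
    stop("cell_ids length (", length(cell_ids),
         ") does not match the number of rows (", nrow(values), ")")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene ids: ", paste(dup, collapse = ", "))
  dupc <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dupc))
    stop("duplicate cell ids: ", paste(dupc, collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values contain NA or non-finite entries")
  if (any(values < 0))
    stop("expression values contain negative entries")
  if (!is.null(cell_types)) {
    cell_types <- as.character(cell_types)
    if (length(cell_types) != nrow(values))
      stop("cell_types length does not match the number of cells")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_types = cell_types, is_lognorm = isTRUE(is_lognorm)),
            class = "expression_profile")
}

#' Construct a spatial dataset
#'
#' Couples an [expression_profile()] with 2-D coordinates and a platform
#' tag. This is the training reference for the contrastive encoder and the
#' ground truth for evaluation.
#'
#' @param profile an [expression_profile()].
#' @param coords numeric matrix with one `(x, y)` row per cell, finite.
#' @param platform `"single_cell"` for single-cell-resolution references
#'   (e.g. SeqFISH, MERSCOPE) or `"spot"` for multi-cell spots
#'   (e.g. 10X Visium, Stereo-seq). Drives the default positive-pair
#'   neighborhood size during training.
#'
#' @return An object of class `spatial_dataset`.
#' @export
spatial_dataset <- function(profile, coords,
                            platform = c("single_cell", "spot")) {
  stopifnot(inherits(profile, "expression_profile"))
  platform <- match.arg(platform)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L)
    stop("coords must have exactly two columns (x, y)")
  if (nrow(coords) != nrow(profile$values))
    stop("coords row count (", nrow(coords),
         ") does not match the number of cells (", nrow(profile$values), ")")
  if (anyNA(coords) || any(!is.finite(coords)))
    stop("coords contain NA or non-finite entries")
  colnames(coords) <- c("x", "y")
  rownames(coords) <- profile$cell_ids
  structure(list(profile = profile, coords = coords, platform = platform),
            class = "spatial_dataset")
}

#' @export
#' @method print expression_profile
print.expression_profile <- function(x, ...) {
  cat("expression_profile: ", nrow(x$values), " cells x ",
      ncol(x$values), " genes (",
      if (x$is_lognorm) "log-normalized" else "raw", ")\n", sep = "")
  if (!is.null(x$cell_types))
    cat("cell types: ", length(unique(x$cell_types)), " levels\n", sep = "")
  invisible(x)
}

#' @export
#' @method print spatial_dataset
print.spatial_dataset <- function(x, ...) {
  cat("spatial_dataset [", x$platform, "]: ", nrow(x$profile$values),
      " cells x ", ncol(x$profile$values), " genes, 2-D coordinates\n",
      sep = "")
  invisible(x)
}

#' @export
dim.expression_profile <- function(x) dim(x$values)

#' @export
dim.spatial_dataset <- function(x) dim(x$profile$values)

# internal: accept a profile, a spatial dataset, or a bare matrix and return
# an expression_profile
as_profile <- function(x) {
  if (inherits(x, "spatial_dataset")) return(x$profile)
  if (inherits(x, "expression_profile")) return(x)
  if (is.matrix(x) || is.data.frame(x))
    return(expression_profile(as.matrix(x)))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as an expression profile")
}
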