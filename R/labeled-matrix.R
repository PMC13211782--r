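#' Labelled expression matrix
#'
#' Container for a sparse cells x genes count matrix with optional per-cell
#' ground-truth subtype labels and FACS-fraction labels (`"PE"` for
#' CD133-antibody-positive, `"NC"` for negative).
#'
#' @param counts A non-negative integer matrix, cells in rows, genes in
#'   columns; coerced to a sparse `dgCMatrix`. Row and column names are the
#'   cell and gene identifiers and must be unique.
#' @param truth_subtype Optional character/factor of length `nrow(counts)`.
#' @param facs_fraction Optional character/factor of length `nrow(counts)`
#'   with values in `PE`/`NC`.
#' @return An object of class `labeled_expression_matrix`.
#' @export
labeled_matrix <- function(counts, truth_subtype = NULL, facs_fraction = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"),
                        "CsparseMatrix")
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("cell%05d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("gene%05d", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate gene ids")
  if (length(counts@x) && min(counts@x) < 0) stop("counts must be non-negative")
  if (!is.null(truth_subtype) && length(truth_subtype) != nrow(counts)) {
    stop("truth_subtype length does not match number of cells")
  }
  if (!is.null(facs_fraction)) {
    if (length(facs_fraction) != nrow(counts)) {
      stop("facs_fraction length does not match number of cells")
    }
    bad <- setdiff(unique(as.character(facs_fraction)), c("PE", "NC", NA))
    if (length(bad)) stop("facs_fraction values must be 'PE' or 'NC'")
  }
  structure(
    list(
      counts = counts,
      truth_subtype = if (is.null(truth_subtype)) NULL else as.character(truth_subtype),
      facs_fraction = if (is.null(facs_fraction)) NULL else as.character(facs_fraction)
    ),
    class = "labeled_expression_matrix"
  )
}

#' @export
dim.labeled_expression_matrix <- function(x) dim(x$counts)

#' @export
print.labeled_expression_matrix <- function(x, ...) {
  d <- dim(x$counts)
  cat("labeled_expression_matrix: ", d[1], " cells x ", d[2], " genes (",
      length(x$counts@x), " nonzeros)\n", sep = "")
  if (!is.null(x$truth_subtype)) {
    tab <- table(x$truth_subtype)
    cat("  truth_subtype: ",
        paste0(names(tab), "=", as.integer(tab), collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$facs_fraction)) {
    tab <- table(x$facs_fraction)
    cat("  facs_fraction: ",
        paste0(names(tab), "=", as.integer(tab), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Cell identifiers
#' @param x A `labeled_expression_matrix`.
#' @return Character vector of cell ids.
#' @export
cell_ids <- function(x) rownames(x$counts)

#' Gene identifiers
#' @param x A `labeled_expression_matrix`.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(x) colnames(x$counts)

#' Subset cells of a labelled matrix
#'
#' @param x A `labeled_expression_matrix`.
#' @param keep Logical, integer or character index of cells to keep.
#' @return A `labeled_expression_matrix` restricted to the selected cells.
#' @export
subset_cells <- function(x, keep) {
  stopifnot(inherits(x, "labeled_expression_matrix"))
  if (is.character(keep)) keep <- match(keep, rownames(x$counts))
  labeled_matrix(
    x$counts[keep, , drop = FALSE],
    truth_subtype = if (!is.null(x$truth_subtype)) x$truth_subtype[keep],
    facs_fraction = if (!is.null(x$facs_fraction)) x$facs_fraction[keep]
  )
}

#' Subset genes of a labelled matrix
#' @param x A `labeled_expression_matrix`.
#' @param keep Logical, integer or character index of genes to keep.
#' @return A `labeled_expression_matrix` restricted to the selected genes.
#' @export
subset_genes <- function(x, keep) {
  stopifnot(inherits(x, "labeled_expression_matrix"))
  labeled_matrix(
    x$counts[, keep, drop = FALSE],
    truth_subtype = x$truth_subtype,
    facs_fraction = x$facs_fraction
  )
}
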