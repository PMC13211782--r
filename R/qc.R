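#' Quality-control parameters
#'
#' Thresholds for the stated cell and gene filters, applied in order:
#' (1) cells expressing fewer than `min_genes_at_creation` genes are dropped,
#' (2) genes expressed in fewer than `min_cells_per_gene` cells are dropped,
#' (3) cells with fewer than `min_features` or more than `max_features`
#' detected genes are dropped, and (4) cells with a mitochondrial UMI
#' fraction above `max_mito_fraction` are dropped. A "feature" is a gene
#' detected at count >= 1 in the cell; the mitochondrial fraction is
#' mitochondrial UMIs over total UMIs.
#'
#' Note that with the defaults the lower arm of rule 3 (< 180 features) can
#' remove nothing after rule 1 (< 200) has run; both are applied anyway, in
#' order, and the report records each rule's removals separately.
#'
#' @param min_genes_at_creation Minimum detected genes per cell at object
#'   creation (default 200).
#' @param min_cells_per_gene Minimum cells a gene must be detected in
#'   (default 5).
#' @param min_features,max_features Feature-count window per cell
#'   (defaults 180 and 8000).
#' @param max_mito_fraction Maximum mitochondrial UMI fraction (default 0.10).
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes
#'   (default `"mt-"`).
#' @return A `qc_params` object.
#' @export
qc_params <- function(min_genes_at_creation = 200, min_cells_per_gene = 5,
                      min_features = 180, max_features = 8000,
                      max_mito_fraction = 0.10, mito_prefix = "mt-") {
  if (min_features > max_features) stop("min_features must be <= max_features")
  if (max_mito_fraction < 0 || max_mito_fraction > 1) {
    stop("max_mito_fraction must be in [0, 1]")
  }
  structure(
    list(min_genes_at_creation = min_genes_at_creation,
         min_cells_per_gene = min_cells_per_gene,
         min_features = min_features, max_features = max_features,
         max_mito_fraction = max_mito_fraction, mito_prefix = mito_prefix),
    class = "qc_params"
  )
}

#' Apply quality-control filters
#'
#' Runs the four filters of [qc_params()] in their stated order and reports
#' what each removed. An optional per-cell exclusion mask (e.g. predicted
#' doublets from an upstream tool) is applied first.
#'
#' @param x A [labeled_matrix()] (counts must be non-negative integers).
#' @param params A [qc_params()].
#' @param exclude Optional logical vector, `TRUE` for cells to drop before
#'   filtering.
#' @return A list with elements `matrix` (the filtered
#'   `labeled_expression_matrix`) and `report` (a `qc_report`: per-rule
#'   removal counts in application order, surviving dimensions, warnings).
#' @examples
#' cfg <- sim_config(300, seed = 2)
#' res <- apply_qc(generate_expression(cfg))
#' res$report
#' @export
apply_qc <- function(x, params = qc_params(), exclude = NULL) {
  stopifnot(inherits(x, "labeled_expression_matrix"), inherits(params, "qc_params"))
  dims_in <- dim(x)
  steps <- list()
  warnings <- character(0)

  if (!is.null(exclude)) {
    stopifnot(is.logical(exclude), length(exclude) == nrow(x$counts))
    steps$exclusion_mask <- list(axis = "cell", removed = sum(exclude),
                                 ids = rownames(x$counts)[exclude])
    x <- subset_cells(x, !exclude)
  }

  # rule 1: cells with too few detected genes
  feats <- Matrix::rowSums(x$counts > 0)
  drop1 <- feats < params$min_genes_at_creation
  steps$min_genes_at_creation <- list(axis = "cell", removed = sum(drop1),
                                      ids = rownames(x$counts)[drop1])
  x <- subset_cells(x, !drop1)

  # rule 2: genes detected in too few cells
  ncell <- Matrix::colSums(x$counts > 0)
  drop2 <- ncell < params$min_cells_per_gene
  steps$min_cells_per_gene <- list(axis = "gene", removed = sum(drop2),
                                   ids = colnames(x$counts)[drop2])
  x <- subset_genes(x, !drop2)

  # rule 3: feature-count window (features recomputed on the filtered genes)
  feats <- Matrix::rowSums(x$counts > 0)
  low <- feats < params$min_features
  high <- feats > params$max_features
  steps$feature_window <- list(axis = "cell", removed = sum(low | high),
                               removed_low = sum(low), removed_high = sum(high),
                               ids = rownames(x$counts)[low | high])
  x <- subset_cells(x, !(low | high))

  # rule 4: mitochondrial UMI fraction
  mito <- startsWith(colnames(x$counts) %||% character(0), params$mito_prefix)
  if (!any(mito)) {
    warnings <- c(warnings, paste0("no gene matches mito_prefix '",
                                   params$mito_prefix, "'; rule skipped"))
    warning(warnings[length(warnings)], call. = FALSE)
    drop4 <- rep(FALSE, nrow(x$counts))
  } else {
    total <- Matrix::rowSums(x$counts)
    frac <- ifelse(total > 0, Matrix::rowSums(x$counts[, mito, drop = FALSE]) / total, 0)
    drop4 <- frac > params$max_mito_fraction
  }
  steps$max_mito_fraction <- list(axis = "cell", removed = sum(drop4),
                                  ids = rownames(x$counts)[drop4])
  x <- subset_cells(x, !drop4)

  report <- structure(
    list(steps = steps, dims_in = dims_in, dims_out = dim(x),
         params = params, warnings = warnings),
    class = "qc_report"
  )
  list(matrix = x, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report: ", x$dims_in[1], " cells x ", x$dims_in[2], " genes -> ",
      x$dims_out[1], " x ", x$dims_out[2], "\n", sep = "")
  for (nm in names(x$steps)) {
    s <- x$steps[[nm]]
    cat(sprintf("  %-22s removed %d %s(s)\n", nm, s$removed, s$axis))
  }
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' QC report as a tibble
#' @param report A `qc_report`.
#' @return Tibble with columns `rule`, `axis`, `removed`.
#' @export
qc_report_table <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  tibble::tibble(
    rule = names(report$steps),
    axis = unname(vapply(report$steps, `[[`, character(1), "axis")),
    removed = unname(vapply(report$steps, function(s) as.integer(s$removed),
                            integer(1)))
  )
}
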