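#' Binarize marker expression
#'
#' Converts counts into a boolean cells x markers table: a cell is positive
#' for a gene when its count is at least `threshold`. The default threshold
#' of 1 equates positivity with any detected transcript, the conventional
#' reading of "expressing" for droplet single-cell counts; it is configurable
#' because the underlying expression call is a modelling choice, not a
#' measured quantity.
#'
#' @param x A [labeled_matrix()] or a counts matrix (cells x genes).
#' @param genes Genes to binarize; default all genes in `x`.
#' @param threshold Positive integer count threshold (>= 1).
#' @return A logical matrix (cells x genes) of class `binary_marker_matrix`
#'   with the threshold stored in `attr(, "threshold")`.
#' @examples
#' cfg <- sim_config(200, seed = 3)
#' b <- binarize(generate_expression(cfg), genes = c("Prom1", "Vim"))
#' colMeans(b)
#' @export
binarize <- function(x, genes = NULL, threshold = 1L) {
  if (threshold < 1) stop("threshold must be >= 1")
  counts <- if (inherits(x, "labeled_expression_matrix")) x$counts else x
  if (is.null(genes)) genes <- colnames(counts)
  missing <- setdiff(genes, colnames(counts))
  if (length(missing)) {
    stop("marker gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  }
  b <- as.matrix(counts[, genes, drop = FALSE] >= threshold)
  dimnames(b) <- list(rownames(counts), genes)
  structure(b, threshold = as.integer(threshold),
            class = c("binary_marker_matrix", "matrix", "array"))
}

#' Serial-depletion partitioning
#'
#' Assigns every cell to the first bin of the scheme whose marker it
#' expresses; cells expressing none of the markers fall into the remainder
#' bin. The bins plus remainder are a disjoint, exhaustive partition of the
#' cells, so the fractions sum to one; the remainder fraction is invariant
#' to the marker order (it is the all-negative set), while individual bin
#' sizes depend on the order.
#'
#' @param binary A [binarize()]d matrix containing the scheme's markers.
#' @param scheme A [gating_scheme()].
#' @return A list of class `serial_depletion` with elements
#'   `composition` (tibble: `bin`, `marker`, `n_cells`, `fraction`, with the
#'   remainder as the last row) and `assignment` (per-cell factor of bin
#'   names).
#' @examples
#' b <- binarize(generate_expression(sim_config(500, seed = 4)),
#'               genes = gating_scheme()$markers)
#' serial_depletion(b, gating_scheme())$composition
#' @export
serial_depletion <- function(binary, scheme = gating_scheme()) {
  stopifnot(inherits(scheme, "gating_scheme"))
  if (length(scheme$markers) == 0L) stop("empty gating scheme")
  missing <- setdiff(scheme$markers, colnames(binary))
  if (length(missing)) {
    stop("scheme marker(s) absent from binary matrix: ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(binary)
  K <- length(scheme$markers)
  assign_idx <- rep.int(K + 1L, n)          # remainder by default
  unassigned <- rep.int(TRUE, n)
  for (k in seq_len(K)) {
    hit <- unassigned & binary[, scheme$markers[k]]
    assign_idx[hit] <- k
    unassigned[hit] <- FALSE
  }
  levels <- c(scheme$bin_names, scheme$remainder_name)
  assignment <- factor(levels[assign_idx], levels = levels)
  counts <- as.integer(table(assignment))
  composition <- tibble::tibble(
    bin = levels,
    marker = c(scheme$markers, NA_character_),
    n_cells = counts,
    fraction = if (n > 0) counts / n else rep(NaN, K + 1L)
  )
  structure(list(composition = composition, assignment = assignment,
                 total_cells = n, scheme = scheme),
            class = "serial_depletion")
}

#' @export
print.serial_depletion <- function(x, ...) {
  cat("Serial depletion over", x$total_cells, "cells\n")
  print(x$composition)
  invisible(x)
}

#' Pairwise co-expression table
#'
#' For each (condition A, target B) pair, the fraction of A-positive cells
#' that are also B-positive. Pairs with no A-positive cells are reported as
#' undefined (`NA`), not zero.
#'
#' @param binary A [binarize()]d matrix.
#' @param pairs A list of length-2 character vectors `c(condition, target)`,
#'   or a 2-column matrix / data frame.
#' @return Tibble with columns `condition`, `target`, `n_condition`,
#'   `n_both`, `conditional`.
#' @export
coexpression <- function(binary, pairs) {
  if (is.matrix(pairs) || is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) as.character(pairs[i, 1:2]))
  }
  genes <- unique(unlist(pairs))
  missing <- setdiff(genes, colnames(binary))
  if (length(missing)) {
    stop("marker gene(s) absent from binary matrix: ",
         paste(missing, collapse = ", "))
  }
  rows <- lapply(pairs, function(p) {
    a <- binary[, p[1]]; b <- binary[, p[2]]
    n_a <- sum(a); n_ab <- sum(a & b)
    tibble::tibble(condition = p[1], target = p[2],
                   n_condition = n_a, n_both = n_ab,
                   conditional = if (n_a > 0) n_ab / n_a else NA_real_)
  })
  do.call(rbind, rows)
}

#' Marginal marker-positive rates
#'
#' @param binary A [binarize()]d matrix.
#' @param genes Genes to report; default all columns.
#' @return Tibble with columns `gene`, `n_positive`, `rate`. Rates are
#'   undefined (`NaN`) on an empty matrix.
#' @export
marker_positive_rates <- function(binary, genes = colnames(binary)) {
  missing <- setdiff(genes, colnames(binary))
  if (length(missing)) {
    stop("marker gene(s) absent from binary matrix: ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(binary)
  npos <- unname(vapply(genes, function(g) sum(binary[, g]), numeric(1)))
  tibble::tibble(gene = genes, n_positive = as.integer(npos),
                 rate = if (n > 0) npos / n else rep(NaN, length(genes)))
}

SUBTYPE_LABELS <- c(
  "CD133+ endothelial-like", "CD133+ Foxj1-ependymal", "CD133+ pericyte-like",
  "CD133+ endo-peri-like", "CD133+ Foxj1-endo-like",
  "CD133- endothelial-like", "CD133- Foxj1-ependymal", "CD133- pericyte-like",
  "CD133- endo-peri-like", "CD133- Foxj1-endo-like",
  "CD133- Vim-only", "CD133- negative-for-all",
  # audit classes: co-labels the partition keeps explicit rather than merging
  "CD133+ Foxj1-peri-like", "CD133- Foxj1-peri-like", "CD133+ unclassified"
)

#' Assign the 12 ependymal subtype labels
#'
#' Splits cells on Prom1 (CD133) first, then labels each stratum by the
#' representative subgroup markers: endothelial (Flt1), Foxj1-ependymal
#' (Sox2) and pericyte (Pdgfrb), with explicit overlap classes. In the
#' CD133-negative stratum, cells negative for all three subgroup markers are
#' `Vim-only` if Vim-positive, else `negative-for-all`.
#'
#' The 12 core classes are the five subgroup labels per stratum plus the two
#' extra CD133-negative classes. Two kinds of rare cells receive explicit
#' audit labels instead of being silently merged: Foxj1/pericyte co-labelled
#' cells (`Foxj1-peri-like`; the transcriptomic data show few, if any, such
#' cells) and CD133-positive cells negative for every subgroup marker
#' (`CD133+ unclassified`). Cells positive for endothelial and pericyte
#' markers (with or without Sox2) are `endo-peri-like`. An optional
#' cluster-style relabelling map can merge classes afterwards (e.g. folding
#' endo-peri-like into pericyte-like, as done when annotating clusters).
#'
#' @param binary A [binarize()]d matrix containing the five representative
#'   markers.
#' @param markers Named character vector giving the representative marker for
#'   `prom1`, `endo`, `foxj1`, `peri`, `vim`.
#' @param relabel Optional named character vector mapping emitted labels to
#'   replacement labels.
#' @return Per-cell factor over the subtype labels.
#' @export
assign_subtypes <- function(binary,
                            markers = c(prom1 = "Prom1", endo = "Flt1",
                                        foxj1 = "Sox2", peri = "Pdgfrb",
                                        vim = "Vim"),
                            relabel = NULL) {
  need <- unname(markers)
  missing <- setdiff(need, colnames(binary))
  if (length(missing)) {
    stop("marker gene(s) absent from binary matrix: ",
         paste(missing, collapse = ", "))
  }
  p <- binary[, markers[["prom1"]]]
  e <- binary[, markers[["endo"]]]
  f <- binary[, markers[["foxj1"]]]
  d <- binary[, markers[["peri"]]]
  v <- binary[, markers[["vim"]]]

  group <- ifelse(e & d, "endo-peri-like",
           ifelse(e & f, "Foxj1-endo-like",
           ifelse(f & d, "Foxj1-peri-like",
           ifelse(e, "endothelial-like",
           ifelse(f, "Foxj1-ependymal",
           ifelse(d, "pericyte-like", "none"))))))
  stratum <- ifelse(p, "CD133+", "CD133-")
  label <- paste(stratum, group)
  none <- group == "none"
  label[none & p] <- "CD133+ unclassified"
  label[none & !p & v] <- "CD133- Vim-only"
  label[none & !p & !v] <- "CD133- negative-for-all"
  if (!is.null(relabel)) {
    hit <- label %in% names(relabel)
    label[hit] <- relabel[label[hit]]
  }
  factor(label, levels = union(SUBTYPE_LABELS, unique(label)))
}
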