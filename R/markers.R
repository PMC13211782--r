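#' Marker panel for ependymal-surface subtypes
#'
#' The marker genes used throughout the package, grouped by the subtype they
#' report on. The groups mirror the co-segregation of published ependymal,
#' endothelial, pericyte and neural-stem-cell markers on the ventricular
#' surface: an endothelial-like group, a pericyte-like group, a
#' Foxj1-ependymal group, two pan-ependymal genes, a subependymal-NSC group,
#' housekeeping controls, and the multi-cilia marker *Prom1* (CD133), which is
#' the primary stratifier.
#'
#' @param ... Named character vectors overriding or extending the default
#'   groups. A gene may belong to one group only.
#' @return A named list of character vectors, class `marker_panel`.
#' @examples
#' panel <- marker_panel()
#' panel$pericyte_like
#' @export
marker_panel <- function(...) {
  panel <- list(
    endothelial_like = c("Flt1", "Pecam1", "Sox17", "Cldn5", "Nes", "Notch1"),
    pericyte_like    = c("Pdgfrb", "Cspg4", "Vtn"),
    foxj1_ependymal  = c("Sox2", "Foxj1", "S100b", "Acta2", "Cd24a"),
    pan_ependymal    = c("Vim", "Vps35"),
    subependymal_nsc = c("Ccn1", "Gfap", "Vcam1", "Egfr"),
    housekeeping     = c("Actb", "Malat1"),
    cilia            = c("Prom1")
  )
  override <- list(...)
  for (nm in names(override)) panel[[nm]] <- as.character(override[[nm]])
  if (any(lengths(panel) == 0L)) {
    stop("marker_panel: every group must contain at least one gene")
  }
  genes <- unlist(panel, use.names = FALSE)
  if (anyDuplicated(genes)) {
    stop("marker_panel: gene(s) listed in more than one group: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  structure(panel, class = "marker_panel")
}

#' All genes of a marker panel
#' @param panel A [marker_panel()].
#' @return Character vector of gene symbols.
#' @export
panel_genes <- function(panel = marker_panel()) {
  unlist(panel, use.names = FALSE)
}

#' Serial-depletion gating scheme
#'
#' An ordered list of markers defining a serial depletion: each cell is
#' assigned to the first bin whose marker it expresses, so later bins are
#' depleted of earlier-marker-positive cells and the bins partition the cells.
#' Cells expressing none of the markers fall into a named remainder bin.
#'
#' The default order is the five representative subtype markers
#' `Prom1 -> Flt1 -> Sox2 -> Pdgfrb -> Vim`; the remainder is the
#' housekeeping-only "undefined" class.
#'
#' @param markers Ordered character vector of marker genes (unique).
#' @param remainder_name Label for cells negative for every marker.
#' @return A `gating_scheme` object with cumulative bin names such as
#'   `"Prom1+"`, `"Prom1-/Flt1+"`, ...
#' @examples
#' gating_scheme()
#' gating_scheme(c("Prom1", "Sox2", "Vim", "Pdgfrb", "Flt1"))
#' @export
gating_scheme <- function(markers = c("Prom1", "Flt1", "Sox2", "Pdgfrb", "Vim"),
                          remainder_name = "undefined") {
  markers <- as.character(markers)
  if (length(markers) == 0L) stop("gating_scheme: 'markers' must be non-empty")
  if (anyDuplicated(markers)) {
    stop("gating_scheme: duplicated marker(s): ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  }
  bins <- character(length(markers))
  for (k in seq_along(markers)) {
    neg <- if (k > 1L) paste0(markers[seq_len(k - 1L)], "-", collapse = "/") else ""
    bins[k] <- paste0(if (nzchar(neg)) paste0(neg, "/") else "", markers[k], "+")
  }
  structure(
    list(markers = markers, bin_names = bins, remainder_name = remainder_name),
    class = "gating_scheme"
  )
}

#' @export
print.gating_scheme <- function(x, ...) {
  cat("Serial-depletion gating scheme (", length(x$markers), " bins + remainder)\n",
      sep = "")
  cat(paste0("  ", seq_along(x$bin_names), ". ", x$bin_names, collapse = "\n"), "\n")
  cat("  remainder: ", x$remainder_name, "\n", sep = "")
  invisible(x)
}
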