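SECTORS <- c("endothelial", "foxj1_ependymal", "pericyte",
             "endo_peri", "foxj1_endo", "foxj1_peri",
             "vim_only", "all_negative")
STRATA <- c("CD133pos", "CD133neg")

# measurement channels emitted per stratum by the z-stack generator
STRATUM_CHANNELS <- c("FLT1", "CD31", "NESTIN",        # endothelial trio
                      "SOX2", "FOXJ1", "S100B",        # Foxj1 trio
                      "PDGFRB", "VIM",
                      "ENDO_PERI", "FOXJ1_ENDO", "FOXJ1_PERI")

#' Validate a composition table
#'
#' A composition table assigns a fraction of all cells to each
#' (CD133 stratum, sector) pair. Sectors are the named subtype classes:
#' `endothelial`, `foxj1_ependymal`, `pericyte`, the overlap classes
#' `endo_peri`, `foxj1_endo`, `foxj1_peri`, and (CD133-negative stratum only)
#' `vim_only` and `all_negative`.
#'
#' @param x A data frame with columns `stratum`, `sector`, `fraction`.
#' @return The validated table as a tibble.
#' @export
composition_table <- function(x) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("stratum", "sector", "fraction") %in% names(x)))
  if (!all(x$stratum %in% STRATA)) {
    stop("unknown stratum: ", paste(setdiff(x$stratum, STRATA), collapse = ", "))
  }
  if (!all(x$sector %in% SECTORS)) {
    stop("unknown sector: ", paste(setdiff(x$sector, SECTORS), collapse = ", "))
  }
  bad <- x$stratum == "CD133pos" & x$sector %in% c("vim_only", "all_negative")
  if (any(bad)) stop("vim_only / all_negative sectors exist only in CD133neg")
  if (anyDuplicated(paste(x$stratum, x$sector))) stop("duplicate sector rows")
  if (any(x$fraction < -1e-12 | x$fraction > 1 + 1e-12)) {
    stop("fractions must be in [0, 1]")
  }
  if (sum(x$fraction) > 1 + 1e-9) stop("fractions sum to more than 1")
  x
}

#' Shipped default 12-sector composition
#'
#' The default final composition of the ependymal surface used to plant
#' synthetic z-stack counts. The CD133 split (67.6% positive / 32.4%
#' negative) and the CD133-positive single- and double-marker rates (FLT1 40%,
#' SOX2 34%, PDGFRB 12% of all cells) are the published immunostaining
#' values; the individual overlap sectors and the CD133-negative sectors are
#' a synthetic calibration chosen to be self-consistent with those rates
#' (the published per-sector arithmetic is not printed, and the printed
#' single-marker rates are not mutually consistent as a partition).
#'
#' @return A [composition_table()] whose fractions sum to exactly 1;
#'   the CD133-positive sectors sum to 0.676.
#' @export
final_composition_default <- function() {
  composition_table(tibble::tibble(
    stratum = c(rep("CD133pos", 5), rep("CD133neg", 7)),
    sector = c("endothelial", "foxj1_ependymal", "pericyte",
               "foxj1_endo", "endo_peri",
               "endothelial", "foxj1_ependymal", "pericyte",
               "foxj1_endo", "endo_peri", "vim_only", "all_negative"),
    fraction = c(0.216, 0.200, 0.076, 0.140, 0.044,
                 0.070, 0.130, 0.030, 0.020, 0.010, 0.044, 0.020)
  ))
}

# which sectors make a measurement channel positive
sector_is_positive <- function(sector, channel) {
  switch(channel,
    FLT1 = , CD31 = , NESTIN =
      sector %in% c("endothelial", "endo_peri", "foxj1_endo"),
    SOX2 = , FOXJ1 = , S100B =
      sector %in% c("foxj1_ependymal", "foxj1_endo", "foxj1_peri"),
    PDGFRB = sector %in% c("pericyte", "endo_peri", "foxj1_peri"),
    VIM = sector != "all_negative",
    ENDO_PERI = sector == "endo_peri",
    FOXJ1_ENDO = sector == "foxj1_endo",
    FOXJ1_PERI = sector == "foxj1_peri",
    stop("unknown channel: ", channel)
  )
}

#' Example layered detection profile
#'
#' Per-layer detection probabilities illustrating how subcellular protein
#' localisation shapes layered counts: CD133 decorates cilia and is seen
#' mostly in the 0 and -1 um layers; SOX2 is nuclear and appears in the
#' -1 and -2 um layers; cytoplasmic markers sit in between. Channels not
#' listed are detected with the given base probability in every layer.
#'
#' @param base Detection probability for unlisted channels.
#' @return Named list of length-3 vectors (layers A = 0, B = -1, C = -2 um).
#' @export
layered_detection_example <- function(base = 0.85) {
  list(
    CD133 = c(A = 0.95, B = 0.90, C = 0.10),
    SOX2  = c(A = 0.20, B = 0.90, C = 0.90),
    FOXJ1 = c(A = 0.25, B = 0.90, C = 0.85),
    VIM   = c(A = 0.30, B = 0.85, C = 0.90),
    .default = c(A = base, B = base, C = base)
  )
}

resolve_detection <- function(detection, channel) {
  if (is.null(detection)) return(c(1, 1, 1))
  # full channel name first, then the suffix after the stratum prefix
  key <- channel
  if (!key %in% names(detection)) {
    key <- sub("^CD133(pos|neg)_", "", channel)
  }
  d <- detection[[key]]
  if (is.null(d)) d <- detection[[".default"]]
  if (is.null(d)) d <- c(1, 1, 1)
  if (length(d) == 1L) d <- rep(d, 3)
  if (any(d < 0 | d > 1)) stop("detection probabilities must be in [0, 1]")
  unname(d)
}

#' Generate synthetic z-stack immunostaining counts
#'
#' Emulates per-field confocal counting of marker-positive cells over three
#' optical layers (A = 0, B = -1, C = -2 um) plus their merged projection
#' (D). Each field receives a fixed number of nuclei, assigned to sectors by
#' the planted composition. A truth-positive cell is detected in each layer
#' independently with the channel's per-layer detection probability; the
#' merged layer counts a cell positive if it was detected in any layer.
#'
#' Channels: `CD133` (positive for the whole CD133-positive stratum) and,
#' within each stratum, the endothelial trio (FLT1/CD31/NESTIN), the Foxj1
#' trio (SOX2/FOXJ1/S100B), PDGFRB, VIM and the three pairwise co-label
#' classes.
#'
#' @param composition A [composition_table()]; fractions may sum to < 1, in
#'   which case the leftover cells are negative for every channel.
#' @param detection `NULL` for full detection, or a named list of per-layer
#'   probabilities as in [layered_detection_example()].
#' @param n_fields Number of imaging fields (>= 1).
#' @param cells_per_field Nuclei per field (>= 1).
#' @param seed Integer seed.
#' @return A tibble of class `zstack_counts` with columns
#'   `field_id`, `marker`, `layer` (A/B/C/D), `positive`, `nuclei`.
#' @examples
#' z <- generate_zstack(final_composition_default(), n_fields = 5,
#'                      cells_per_field = 100, seed = 1)
#' head(z)
#' @export
generate_zstack <- function(composition, detection = NULL,
                            n_fields = 30, cells_per_field = 200, seed = 1L) {
  composition <- composition_table(composition)
  if (n_fields < 1) stop("n_fields must be >= 1")
  if (cells_per_field < 1) stop("cells_per_field must be >= 1")
  withr::with_seed(seed, {
    key <- paste(composition$stratum, composition$sector, sep = ".")
    probs <- c(composition$fraction, max(0, 1 - sum(composition$fraction)))
    channels <- c("CD133",
                  paste0("CD133pos_", STRATUM_CHANNELS),
                  paste0("CD133neg_", STRATUM_CHANNELS))
    out <- vector("list", n_fields)
    for (f in seq_len(n_fields)) {
      cnt <- as.integer(stats::rmultinom(1, cells_per_field, probs))
      sector_n <- stats::setNames(cnt[seq_along(key)], key)
      rows <- lapply(channels, function(ch) {
        if (ch == "CD133") {
          truth <- sum(sector_n[composition$stratum == "CD133pos"])
        } else {
          stratum <- sub("_.*$", "", ch)
          base <- sub("^CD133(pos|neg)_", "", ch)
          in_str <- composition$stratum == stratum
          posi <- vapply(composition$sector, sector_is_positive, logical(1),
                         channel = base)
          truth <- sum(sector_n[in_str & posi])
        }
        det <- resolve_detection(detection, ch)
        if (truth > 0) {
          seen <- matrix(stats::runif(3 * truth), truth, 3) <
            matrix(det, truth, 3, byrow = TRUE)
          layer_pos <- colSums(seen)
          merged <- sum(rowSums(seen) > 0)
        } else {
          layer_pos <- c(0, 0, 0); merged <- 0
        }
        tibble::tibble(
          field_id = f, marker = ch, layer = c("A", "B", "C", "D"),
          positive = as.integer(c(layer_pos, merged)),
          nuclei = as.integer(cells_per_field)
        )
      })
      out[[f]] <- do.call(rbind, rows)
    }
    res <- do.call(rbind, out)
    class(res) <- c("zstack_counts", class(res))
    res
  })
}
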