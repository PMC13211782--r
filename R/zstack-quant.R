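validate_zstack <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- c("field_id", "marker", "layer", "positive", "nuclei")
  if (!all(need %in% names(counts))) {
    stop("z-stack counts need columns: ", paste(need, collapse = ", "))
  }
  if (!all(counts$layer %in% c("A", "B", "C", "D"))) {
    stop("layers must be A, B, C or D")
  }
  if (any(counts$positive < 0) || any(counts$positive > counts$nuclei)) {
    stop("positive counts must satisfy 0 <= positive <= nuclei")
  }
  counts
}

#' Pooled per-layer positive rates
#'
#' For each (marker, layer), the positive rate pooled over fields:
#' sum of positives divided by sum of nuclei. Pooling weights every nucleus
#' equally; per-field rates (for mean +/- SD reporting) are available from
#' [field_rates()].
#'
#' @param counts A `zstack_counts` table (see [generate_zstack()] for the
#'   schema); rows with zero nuclei contribute nothing, and a (marker, layer)
#'   with zero nuclei everywhere is reported as `NaN`.
#' @return Tibble with columns `marker`, `layer`, `positive`, `nuclei`,
#'   `rate`.
#' @export
layer_rates <- function(counts) {
  counts <- validate_zstack(counts)
  agg <- stats::aggregate(cbind(positive, nuclei) ~ marker + layer,
                          data = counts, FUN = sum)
  agg$rate <- ifelse(agg$nuclei > 0, agg$positive / agg$nuclei, NaN)
  tibble::as_tibble(agg[order(agg$marker, agg$layer), ])
}

#' Per-field positive rates
#' @param counts A `zstack_counts` table.
#' @return Tibble with one rate per (field, marker, layer).
#' @export
field_rates <- function(counts) {
  counts <- validate_zstack(counts)
  counts$rate <- ifelse(counts$nuclei > 0, counts$positive / counts$nuclei, NaN)
  counts
}

#' Quantify marker rates from layered counts
#'
#' Combines the pooled per-layer rates into the layered-imaging estimators:
#' * `added` - mean of the three single-layer rates, (A + B + C) / 3
#'   (each layer counted separately, then averaged);
#' * `merged` - the rate counted on the merged projection, D;
#' * `average1` - (A + B + C + D) / 4, the grand mean of all four rates;
#' * `average2_literal` - (A + B + C) / 3 + D / 2, the averaging formula as
#'   printed; it is not a mean (it equals 1.5 r when all four rates are r)
#'   and can exceed 1, in which case it is flagged;
#' * `average2_corrected` - ((A + B + C) / 3 + D) / 2, the mean of the Added
#'   and Merged estimates, which the literal formula presumably intends.
#'
#' `average1` is the default estimator downstream, having tracked
#' single-cell transcriptomic positive rates most closely.
#'
#' @param counts A `zstack_counts` table with all four layers per marker.
#' @return A tibble of class `zstack_quant`, one row per marker, with the
#'   per-layer rates, the five estimators, `literal_flag` (TRUE when the
#'   literal Average 2 exceeds 1), and `partial` (TRUE when a layer is
#'   missing, in which case estimators needing it are `NA`).
#' @examples
#' z <- generate_zstack(final_composition_default(), n_fields = 4,
#'                      cells_per_field = 50, seed = 2)
#' quantify_zstack(z)[, c("marker", "average1")]
#' @export
quantify_zstack <- function(counts) {
  lr <- layer_rates(counts)
  markers <- unique(lr$marker)
  rows <- lapply(markers, function(m) {
    r <- stats::setNames(rep(NA_real_, 4), c("A", "B", "C", "D"))
    sub <- lr[lr$marker == m, ]
    r[sub$layer] <- sub$rate
    partial <- any(is.na(r))
    added <- (r[["A"]] + r[["B"]] + r[["C"]]) / 3
    merged <- r[["D"]]
    tibble::tibble(
      marker = m,
      rate_A = r[["A"]], rate_B = r[["B"]], rate_C = r[["C"]], rate_D = r[["D"]],
      added = added, merged = merged,
      average1 = (r[["A"]] + r[["B"]] + r[["C"]] + r[["D"]]) / 4,
      average2_literal = added + merged / 2,
      average2_corrected = (added + merged) / 2,
      literal_flag = isTRUE(added + merged / 2 > 1),
      partial = partial
    )
  })
  res <- do.call(rbind, rows)
  class(res) <- c("zstack_quant", class(res))
  res
}
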