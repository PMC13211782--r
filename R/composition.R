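#' Average a marker trio
#'
#' Arithmetic mean of three positive rates measured with different antibodies
#' against the same subgroup (e.g. FLT1 / CD31 / NESTIN for the
#' endothelial-like subgroup), used to dampen antibody-specific bias.
#'
#' @param rates Numeric vector of three fractions in \[0, 1\].
#' @return Their mean.
#' @export
trio_average <- function(rates) {
  if (length(rates) != 3L) stop("trio_average expects exactly three rates")
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  mean(rates)
}

#' Subgroup rates per CD133 stratum
#'
#' Bundle of the measured inputs to [reconstitute()], all expressed as
#' fractions of total nuclei: per stratum, the endothelial subgroup rate
#' (a single value or a trio to be averaged), the Foxj1 subgroup rate
#' (single or trio), the pericyte rate, the Vim rate, and the three pairwise
#' co-label rates.
#'
#' @param cd133pos,cd133neg Named lists with entries `endo`, `foxj1`, `peri`,
#'   `vim`, `endo_peri`, `foxj1_endo`, `foxj1_peri`. `endo` and `foxj1` may
#'   be length-3 vectors (averaged via [trio_average()]). `vim` may be `NA`
#'   in the positive stratum (unused there).
#' @return A `subgroup_rates` object.
#' @export
subgroup_rates <- function(cd133pos, cd133neg) {
  squash <- function(s, stratum) {
    need <- c("endo", "foxj1", "peri", "vim", "endo_peri", "foxj1_endo",
              "foxj1_peri")
    missing <- setdiff(need, names(s))
    if (length(missing)) {
      stop(stratum, ": missing rate(s): ", paste(missing, collapse = ", "))
    }
    s$endo <- if (length(s$endo) == 3L) trio_average(s$endo) else s$endo
    s$foxj1 <- if (length(s$foxj1) == 3L) trio_average(s$foxj1) else s$foxj1
    vals <- unlist(s[need])
    ok <- is.na(vals) | (vals >= 0 & vals <= 1)
    if (!all(ok)) stop(stratum, ": rates must be in [0, 1]")
    as.list(vals)
  }
  structure(list(CD133pos = squash(cd133pos, "CD133pos"),
                 CD133neg = squash(cd133neg, "CD133neg")),
            class = "subgroup_rates")
}

#' Extract subgroup rates from quantified z-stack counts
#'
#' Maps the channels emitted by [generate_zstack()] (or real counts using
#' the same channel names) through the chosen estimator into the
#' [subgroup_rates()] structure, averaging the endothelial and Foxj1 trios.
#'
#' @param quant A [quantify_zstack()] result.
#' @param estimator One of `"average1"`, `"average2_corrected"`, `"added"`,
#'   `"merged"`.
#' @return A list with `cd133_rate` (overall CD133-positive fraction) and
#'   `rates` (a `subgroup_rates`).
#' @export
rates_from_zstack <- function(quant, estimator = c("average1",
                                                   "average2_corrected",
                                                   "added", "merged")) {
  estimator <- match.arg(estimator)
  get <- function(marker) {
    row <- quant[quant$marker == marker, ]
    if (nrow(row) != 1L) stop("channel not found in quantified counts: ", marker)
    row[[estimator]]
  }
  stratum <- function(prefix) {
    list(
      endo = c(get(paste0(prefix, "_FLT1")), get(paste0(prefix, "_CD31")),
               get(paste0(prefix, "_NESTIN"))),
      foxj1 = c(get(paste0(prefix, "_SOX2")), get(paste0(prefix, "_FOXJ1")),
                get(paste0(prefix, "_S100B"))),
      peri = get(paste0(prefix, "_PDGFRB")),
      vim = get(paste0(prefix, "_VIM")),
      endo_peri = get(paste0(prefix, "_ENDO_PERI")),
      foxj1_endo = get(paste0(prefix, "_FOXJ1_ENDO")),
      foxj1_peri = get(paste0(prefix, "_FOXJ1_PERI"))
    )
  }
  list(cd133_rate = get("CD133"),
       rates = subgroup_rates(stratum("CD133pos"), stratum("CD133neg")))
}

#' Reconstitute the full composition partition
#'
#' Converts per-stratum subgroup and co-label rates into the disjoint
#' 12-sector composition of the whole ependymal surface by
#' inclusion-exclusion within each CD133 stratum:
#' exclusive endothelial = endo - endo_peri - foxj1_endo, exclusive Foxj1 =
#' foxj1 - foxj1_endo - foxj1_peri, exclusive pericyte = peri - endo_peri -
#' foxj1_peri, with the pairwise overlap sectors kept explicit (triple
#' overlaps are taken as negligible). In the CD133-negative stratum, the
#' Vim-only sector is the Vim rate minus the union of the subgroup sectors,
#' and the all-negative sector is whatever remains of the stratum.
#'
#' Negative intermediate sector values (possible when measurement noise makes
#' an overlap exceed its parent) are clipped to zero with a warning. Each
#' stratum is then renormalised to its total (the CD133 rate and its
#' complement), so the final fractions sum to exactly 1; the
#' pre-normalisation sums are attached as an audit attribute.
#'
#' @param cd133_rate Fraction of cells that are CD133-positive, in \[0, 1\].
#' @param rates A [subgroup_rates()], all rates as fractions of total nuclei.
#' @return A [composition_table()] with audit attributes
#'   `pre_norm_stratum_sums` and `clipped` (names of clipped sectors).
#' @examples
#' z <- generate_zstack(final_composition_default(), seed = 3)
#' r <- rates_from_zstack(quantify_zstack(z))
#' reconstitute(r$cd133_rate, r$rates)
#' @export
reconstitute <- function(cd133_rate, rates) {
  if (is.na(cd133_rate) || cd133_rate < 0 || cd133_rate > 1) {
    stop("cd133_rate must be in [0, 1]")
  }
  if (!inherits(rates, "subgroup_rates")) {
    stop("'rates' must be a subgroup_rates object")
  }
  clipped <- character(0)
  build <- function(s, stratum, total) {
    endo_ex <- s$endo - s$endo_peri - s$foxj1_endo
    foxj1_ex <- s$foxj1 - s$foxj1_endo - s$foxj1_peri
    peri_ex <- s$peri - s$endo_peri - s$foxj1_peri
    sec <- c(endothelial = endo_ex, foxj1_ependymal = foxj1_ex,
             pericyte = peri_ex, endo_peri = s$endo_peri,
             foxj1_endo = s$foxj1_endo, foxj1_peri = s$foxj1_peri)
    union <- s$endo + s$foxj1 + s$peri - s$endo_peri - s$foxj1_endo -
      s$foxj1_peri
    if (stratum == "CD133neg") {
      vim_only <- if (is.na(s$vim)) 0 else s$vim - union
      all_negative <- total - union - max(vim_only, 0)
      sec <- c(sec, vim_only = vim_only, all_negative = all_negative)
    }
    neg <- names(sec)[sec < 0]
    if (length(neg)) {
      clipped <<- c(clipped, paste(stratum, neg, sep = "."))
      warning("clipped negative sector(s) to 0: ",
              paste(stratum, neg, sep = ".", collapse = ", "), call. = FALSE)
      sec[sec < 0] <- 0
    }
    sec
  }
  pos <- build(rates$CD133pos, "CD133pos", cd133_rate)
  neg <- build(rates$CD133neg, "CD133neg", 1 - cd133_rate)
  if (sum(pos) <= 0 && sum(neg) <= 0) {
    stop("no stratum rates: nothing to reconstitute")
  }
  pre_norm <- c(CD133pos = sum(pos), CD133neg = sum(neg))
  # renormalise each stratum to its CD133-split share
  if (sum(pos) > 0) pos <- pos * cd133_rate / sum(pos)
  if (sum(neg) > 0) neg <- neg * (1 - cd133_rate) / sum(neg)
  out <- composition_table(tibble::tibble(
    stratum = c(rep("CD133pos", length(pos)), rep("CD133neg", length(neg))),
    sector = c(names(pos), names(neg)),
    fraction = c(unname(pos), unname(neg))
  ))
  attr(out, "pre_norm_stratum_sums") <- pre_norm
  attr(out, "clipped") <- clipped
  out
}
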