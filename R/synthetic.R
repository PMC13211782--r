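#' Subtype expression profile
#'
#' One mixture component of the synthetic generator: a named subtype with a
#' mixture weight, per-gene probabilities that a cell of this subtype
#' expresses the gene (before mRNA dropout), and the mean true transcript
#' count of an expressed marker.
#'
#' Within a profile, genes are expressed independently unless a single
#' coupled pair is supplied via `couple`, in which case the pair is drawn
#' from the 2x2 joint distribution with the given joint-positive probability
#' and the stated marginals.
#'
#' @param name Subtype label (recorded as ground truth per cell).
#' @param weight Mixture fraction in \[0, 1\].
#' @param marker_probs Named numeric vector of expression probabilities.
#' @param mean_count Mean transcript count (> 0) of an expressed marker,
#'   before capture thinning. Counts are drawn as `1 + Poisson(mean_count - 1)`
#'   so an expressed marker always has at least one true transcript.
#' @param couple Optional `list(genes = c(a, b), joint = p11)` coupling two
#'   genes of `marker_probs`; `p11` must satisfy the Frechet bounds implied by
#'   the two marginals.
#' @return A `subtype_profile` object.
#' @export
subtype_profile <- function(name, weight, marker_probs, mean_count = 20,
                            couple = NULL) {
  if (!is.character(name) || length(name) != 1L) stop("'name' must be a string")
  if (!is.numeric(weight) || weight < 0 || weight > 1) {
    stop("profile '", name, "': field 'weight' must be in [0, 1]")
  }
  marker_probs <- unlist(marker_probs)
  if (is.null(names(marker_probs)) || any(!nzchar(names(marker_probs)))) {
    stop("profile '", name, "': 'marker_probs' must be a named vector")
  }
  if (any(marker_probs < 0 | marker_probs > 1)) {
    stop("profile '", name, "': field 'marker_probs' has values outside [0, 1]")
  }
  if (!is.numeric(mean_count) || mean_count <= 0) {
    stop("profile '", name, "': field 'mean_count' must be > 0")
  }
  if (!is.null(couple)) {
    a <- couple$genes[1]; b <- couple$genes[2]; p11 <- couple$joint
    if (!all(c(a, b) %in% names(marker_probs))) {
      stop("profile '", name, "': coupled genes must appear in marker_probs")
    }
    pa <- marker_probs[[a]]; pb <- marker_probs[[b]]
    if (p11 < max(0, pa + pb - 1) - 1e-12 || p11 > min(pa, pb) + 1e-12) {
      stop("profile '", name, "': coupled joint probability infeasible")
    }
  }
  structure(
    list(name = name, weight = weight, marker_probs = marker_probs,
         mean_count = mean_count, couple = couple),
    class = "subtype_profile"
  )
}

#' Simulation configuration
#'
#' @param n_cells Number of cells to generate (>= 1).
#' @param profiles List of [subtype_profile()]s; weights must sum to 1.
#' @param capture_rate Per-transcript detection probability in \[0, 1\].
#'   The default 0.3 models the low mRNA capture (< 30%) of droplet
#'   single-cell platforms; observed counts are binomial thinnings of the
#'   true transcript counts.
#' @param background_genes Number of non-marker genes expressed at a low
#'   Poisson rate in every cell.
#' @param background_mean Mean true transcript count per background gene.
#' @param mito_genes Number of mitochondrial (`mt-` prefixed) genes, used to
#'   exercise the mitochondrial-fraction filter.
#' @param mito_mean Mean true transcript count per mitochondrial gene.
#' @param seed Integer seed; the whole generation is a deterministic
#'   function of the configuration.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_cells, profiles = default_profiles(),
                       capture_rate = 0.3,
                       background_genes = 400, background_mean = 5,
                       mito_genes = 10, mito_mean = 8,
                       seed = 1L) {
  if (!is.numeric(n_cells) || n_cells < 1) stop("'n_cells' must be >= 1")
  if (length(profiles) == 0L) {
    stop("field 'profiles' is empty: at least one subtype_profile is required")
  }
  if (!all(vapply(profiles, inherits, logical(1), "subtype_profile"))) {
    stop("'profiles' must be a list of subtype_profile objects")
  }
  w <- vapply(profiles, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) {
    stop("field 'weight': profile weights sum to ", format(sum(w)),
         ", expected 1")
  }
  if (capture_rate < 0 || capture_rate > 1) {
    stop("'capture_rate' must be in [0, 1]")
  }
  names(profiles) <- vapply(profiles, `[[`, character(1), "name")
  if (anyDuplicated(names(profiles))) stop("duplicate profile names")
  structure(
    list(n_cells = as.integer(n_cells), profiles = profiles,
         capture_rate = capture_rate,
         background_genes = as.integer(background_genes),
         background_mean = background_mean,
         mito_genes = as.integer(mito_genes), mito_mean = mito_mean,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default calibrated subtype profiles
#'
#' The shipped default mixture plants, as ground truth, the published
#' composition of the EPE compartment (endothelial-like, pericyte-like and
#' Foxj1-ependymal cells) of the mouse forebrain ependymal surface. It has
#' six components: five serial-depletion bins defined by the representative
#' markers Prom1, Flt1, Sox2, Pdgfrb and Vim, plus a housekeeping-only
#' remainder.
#'
#' Calibration is solved in closed form from the published fractions so that
#' they are the planted truth:
#' * bin weights 50.2 / 16.2 / 14.9 / 9.7 / 6.5 (%), rescaled proportionally
#'   so the five bins sum to the stated 97.7% coverage with a 2.3% remainder
#'   (the printed bins sum to 97.5%, a rounding artefact);
#' * P(Prom1+ | Flt1+) = 0.723 fixes P(Flt1 | Prom1 bin);
#' * marginal Pdgfrb = 0.16, P(Flt1+ | Pdgfrb+) = 0.38 and
#'   P(Prom1+ | Pdgfrb+) = 0.05 fix the Pdgfrb conditionals per bin;
#' * marginal Vim = 0.80 fixes the shared Vim conditional of the first three
#'   bins (the pericyte bin expresses Vim rarely);
#' * marginal Sox2 = 0.25 and P(Sox2+ | Prom1+) = 0.19 fix the Sox2
#'   conditionals, with Flt1 and Sox2 negatively coupled inside the Prom1 bin
#'   so that the Prom1+/Flt1+/Sox2+ triple overlap is 4.56% of Prom1+ cells.
#'
#' Non-representative panel genes (e.g. Pecam1, Cspg4, Foxj1, Acta2, Vps35,
#' housekeeping genes) carry plausible group-consistent probabilities for
#' reporting; they do not enter the calibration.
#'
#' @param mean_count Mean transcript count per expressed marker (see
#'   [subtype_profile()]); at the default capture rate of 0.3 an expressed
#'   marker is lost to dropout with probability ~2e-3, so planted fractions
#'   are recovered to well within binomial sampling error.
#' @return Named list of six [subtype_profile()]s whose weights sum to 1.
#' @export
default_profiles <- function(mean_count = 20) {
  bins <- c(prom1 = 0.502, flt1 = 0.162, sox2 = 0.149,
            pdgfrb = 0.097, vim = 0.065)
  coverage <- 0.977
  w <- bins / sum(bins) * coverage            # five bins sum to 97.7%
  w_rem <- 1 - coverage                       # housekeeping-only remainder

  # printed co-expression targets
  p_prom1_given_flt1   <- 0.723
  p_flt1_given_pdgfrb  <- 0.38
  p_prom1_given_pdgfrb <- 0.05
  marg_vim    <- 0.80
  marg_pdgfrb <- 0.16
  marg_sox2   <- 0.25
  p_sox2_given_prom1 <- 0.19
  p_triple_given_prom1 <- 0.24 * 0.19         # Prom1+ & Flt1+ & Sox2+
  vim_in_pericyte <- 0.10

  f1 <- p_prom1_given_flt1 * w[["flt1"]] /
    ((1 - p_prom1_given_flt1) * w[["prom1"]])
  d1 <- p_prom1_given_pdgfrb * marg_pdgfrb / w[["prom1"]]
  d2 <- (p_flt1_given_pdgfrb * marg_pdgfrb - w[["prom1"]] * f1 * d1) / w[["flt1"]]
  d3 <- (marg_pdgfrb - w[["prom1"]] * d1 - w[["flt1"]] * d2 - w[["pdgfrb"]]) /
    w[["sox2"]]
  s1 <- p_sox2_given_prom1
  s2 <- (marg_sox2 - w[["prom1"]] * s1 - w[["sox2"]]) / w[["flt1"]]
  v123 <- (marg_vim - w[["vim"]] - w[["pdgfrb"]] * vim_in_pericyte) /
    (w[["prom1"]] + w[["flt1"]] + w[["sox2"]])

  hk <- c(Actb = 0.95, Malat1 = 0.95)
  nsc <- c(Ccn1 = 0.03, Gfap = 0.03, Vcam1 = 0.03, Egfr = 0.03)
  endo_co <- function(p) c(Pecam1 = p, Sox17 = p, Cldn5 = p, Nes = p, Notch1 = p)
  peri_co <- function(p) c(Cspg4 = p, Vtn = p)
  foxj_co <- function(p) c(Foxj1 = p, S100b = p, Acta2 = p, Cd24a = p)

  list(
    prom1_multiciliated = subtype_profile(
      "prom1_multiciliated", w[["prom1"]],
      c(Prom1 = 1, Flt1 = f1, Sox2 = s1, Pdgfrb = d1, Vim = v123,
        endo_co(0.6), peri_co(0.03), foxj_co(0.12), Vps35 = 0.8, hk, nsc),
      mean_count = mean_count,
      couple = list(genes = c("Flt1", "Sox2"), joint = p_triple_given_prom1)
    ),
    flt1_endothelial = subtype_profile(
      "flt1_endothelial", w[["flt1"]],
      c(Prom1 = 0, Flt1 = 1, Sox2 = s2, Pdgfrb = d2, Vim = v123,
        endo_co(0.7), peri_co(0.25), foxj_co(0.05), Vps35 = 0.8, hk, nsc),
      mean_count = mean_count
    ),
    sox2_foxj1_ependymal = subtype_profile(
      "sox2_foxj1_ependymal", w[["sox2"]],
      c(Prom1 = 0, Flt1 = 0, Sox2 = 1, Pdgfrb = d3, Vim = v123,
        endo_co(0.03), peri_co(0.01), foxj_co(0.7), Vps35 = 0.85, hk, nsc),
      mean_count = mean_count
    ),
    pdgfrb_pericyte = subtype_profile(
      "pdgfrb_pericyte", w[["pdgfrb"]],
      c(Prom1 = 0, Flt1 = 0, Sox2 = 0, Pdgfrb = 1, Vim = vim_in_pericyte,
        endo_co(0.08), peri_co(0.7), foxj_co(0.02), Vps35 = 0.5, hk, nsc),
      mean_count = mean_count
    ),
    vim_only = subtype_profile(
      "vim_only", w[["vim"]],
      c(Prom1 = 0, Flt1 = 0, Sox2 = 0, Pdgfrb = 0, Vim = 1,
        endo_co(0.02), peri_co(0.02), foxj_co(0.02), Vps35 = 0.85, hk, nsc),
      mean_count = mean_count
    ),
    housekeeping_only = subtype_profile(
      "housekeeping_only", w_rem,
      c(Prom1 = 0, Flt1 = 0, Sox2 = 0, Pdgfrb = 0, Vim = 0,
        endo_co(0), peri_co(0), foxj_co(0), Vps35 = 0,
        Actb = 0.98, Malat1 = 0.98, nsc * 0),
      mean_count = mean_count
    )
  )
}

#' Spike-in profiles for non-ependymal cells
#'
#' Optional mixture components emulating cell types that contaminate the
#' dissociated ventricular-wall preparation: neuroblasts (enriched in the
#' CD133-negative FACS fraction) and microglia-like cells (enriched in the
#' CD133-positive fraction but excluded from composition analysis). Weights
#' are taken from the EPE components proportionally, see
#' [add_spike_ins()].
#'
#' @param mean_count Mean transcript count per expressed marker.
#' @return Named list of two `subtype_profile`s with weight 0 (set by
#'   [add_spike_ins()]).
#' @export
spike_in_profiles <- function(mean_count = 20) {
  list(
    neuroblast = subtype_profile(
      "neuroblast", 0,
      c(Dcx = 0.9, Sox2 = 0.3, Vim = 0.6, Prom1 = 0.02, Flt1 = 0.01,
        Pdgfrb = 0.01, Actb = 0.95, Malat1 = 0.95),
      mean_count = mean_count
    ),
    microglia_like = subtype_profile(
      "microglia_like", 0,
      c(Aif1 = 0.9, Itgam = 0.85, Cx3cr1 = 0.9, Prom1 = 0.02, Vim = 0.3,
        Actb = 0.95, Malat1 = 0.95),
      mean_count = mean_count
    )
  )
}

#' Mix spike-in profiles into a profile set
#'
#' Rescales the weights of `profiles` by `1 - sum(weights)` and appends the
#' spike-ins at the requested weights, preserving the relative composition of
#' the original mixture.
#'
#' @param profiles List of [subtype_profile()]s summing to weight 1.
#' @param weights Named numeric vector of spike-in weights, names matching
#'   [spike_in_profiles()].
#' @param mean_count Passed to [spike_in_profiles()].
#' @return Extended profile list with weights summing to 1.
#' @export
add_spike_ins <- function(profiles,
                          weights = c(neuroblast = 0.1, microglia_like = 0.1),
                          mean_count = 20) {
  if (sum(weights) >= 1) stop("spike-in weights must sum to < 1")
  spikes <- spike_in_profiles(mean_count)[names(weights)]
  for (nm in names(weights)) spikes[[nm]]$weight <- weights[[nm]]
  scaled <- lapply(profiles, function(p) {
    p$weight <- p$weight * (1 - sum(weights))
    p
  })
  c(scaled, spikes)
}

# Mouse mitochondrial gene symbols used for synthetic mito counts.
MITO_GENE_POOL <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp8",
                    "mt-Atp6", "mt-Co3", "mt-Nd3", "mt-Nd4l", "mt-Nd4",
                    "mt-Nd5", "mt-Nd6", "mt-Cytb")

#' Generate a synthetic expression matrix with planted ground truth
#'
#' Draws `n_cells` cells from the profile mixture. For each marker gene the
#' cell expresses (Bernoulli with the profile's probability, with at most one
#' coupled pair per profile), the true transcript count is
#' `1 + Poisson(mean_count - 1)`; the observed count is a binomial thinning
#' with the capture rate, emulating mRNA dropout. Background and
#' mitochondrial genes are independent low-rate Poisson in every cell
#' (thinned exactly). The generating subtype is recorded per cell so planted
#' fractions are recoverable by gating.
#'
#' @param config A [sim_config()].
#' @return A [labeled_matrix()] with `truth_subtype` set.
#' @examples
#' cfg <- sim_config(500, seed = 7)
#' mat <- generate_expression(cfg)
#' table(mat$truth_subtype)
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_expression_impl(config))
}

generate_expression_impl <- function(config) {
  n <- config$n_cells
  profiles <- config$profiles
  K <- length(profiles)
  w <- vapply(profiles, `[[`, numeric(1), "weight")
  capture <- config$capture_rate

  subtype_idx <- sample.int(K, n, replace = TRUE, prob = w)
  truth <- names(profiles)[subtype_idx]

  marker_genes <- unique(unlist(lapply(profiles, function(p) names(p$marker_probs))))
  G <- length(marker_genes)
  P <- matrix(0, K, G, dimnames = list(names(profiles), marker_genes))
  for (k in seq_len(K)) {
    mp <- profiles[[k]]$marker_probs
    P[k, names(mp)] <- mp
  }

  expressed <- matrix(stats::runif(n * G), n, G) < P[subtype_idx, , drop = FALSE]

  # redraw coupled pairs from their 2x2 joint
  for (k in seq_len(K)) {
    cp <- profiles[[k]]$couple
    if (is.null(cp)) next
    cells <- which(subtype_idx == k)
    if (!length(cells)) next
    a <- match(cp$genes[1], marker_genes); b <- match(cp$genes[2], marker_genes)
    pa <- P[k, a]; pb <- P[k, b]; p11 <- cp$joint
    cuts <- cumsum(c(p11, pa - p11, pb - p11))
    u <- stats::runif(length(cells))
    expressed[cells, a] <- u < cuts[2]               # both or A-only
    expressed[cells, b] <- u < cuts[1] | (u >= cuts[2] & u < cuts[3])
  }

  pos <- which(expressed)
  cell_of <- ((pos - 1L) %% n) + 1L
  gene_of <- ((pos - 1L) %/% n) + 1L
  mc <- vapply(profiles, `[[`, numeric(1), "mean_count")[subtype_idx]
  true_count <- 1L + stats::rpois(length(pos), mc[cell_of] - 1)
  obs <- stats::rbinom(length(pos), true_count, capture)
  keep <- obs > 0L
  ii <- list(cell_of[keep])
  jj <- list(gene_of[keep])
  xx <- list(obs[keep])

  # background + mitochondrial genes: Poisson(rate * capture) per cell
  bg_names <- if (config$background_genes > 0) {
    sprintf("Bg%04d", seq_len(config$background_genes))
  } else character(0)
  mito_names <- if (config$mito_genes > 0) {
    if (config$mito_genes <= length(MITO_GENE_POOL)) {
      MITO_GENE_POOL[seq_len(config$mito_genes)]
    } else {
      c(MITO_GENE_POOL,
        sprintf("mt-Bg%03d", seq_len(config$mito_genes - length(MITO_GENE_POOL))))
    }
  } else character(0)
  extra <- c(bg_names, mito_names)
  lam <- c(rep(config$background_mean, length(bg_names)),
           rep(config$mito_mean, length(mito_names))) * capture
  for (j in seq_along(extra)) {
    x <- stats::rpois(n, lam[j])
    nz <- which(x > 0L)
    if (length(nz)) {
      ii[[j + 1L]] <- nz
      jj[[j + 1L]] <- rep.int(G + j, length(nz))
      xx[[j + 1L]] <- x[nz]
    }
  }

  all_genes <- c(marker_genes, extra)
  counts <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = as.numeric(unlist(xx)),
    dims = c(n, length(all_genes)),
    dimnames = list(sprintf("cell%06d", seq_len(n)), all_genes)
  )
  labeled_matrix(counts, truth_subtype = truth)
}

#' Default FACS enrichment probabilities
#'
#' Probability that a cell of each subtype is sorted into the
#' CD133-antibody-positive (PE) fraction. EPE subtypes and microglia-like
#' cells are enriched (0.8); neuroblast-like cells are depleted (0.2), as
#' the antibody does not detect them.
#'
#' @param labels Character vector of truth-subtype labels.
#' @return Named numeric vector of PE probabilities over `unique(labels)`.
#' @export
default_enrichment <- function(labels) {
  u <- unique(labels)
  stats::setNames(ifelse(grepl("neuroblast", u), 0.2, 0.8), u)
}

#' Emulate a FACS split into PE / NC fractions
#'
#' Each cell is assigned to the PE (antibody-positive) fraction with the
#' enrichment probability of its ground-truth subtype, otherwise to NC.
#'
#' @param x A [labeled_matrix()] with `truth_subtype` present.
#' @param enrichment Named numeric vector, one PE probability per subtype
#'   label in `x`; values in \[0, 1\].
#' @param seed Integer seed.
#' @return `x` with `facs_fraction` filled in.
#' @export
generate_facs_split <- function(x, enrichment = default_enrichment(x$truth_subtype),
                                seed = 1L) {
  stopifnot(inherits(x, "labeled_expression_matrix"))
  if (is.null(x$truth_subtype)) {
    stop("generate_facs_split requires truth_subtype labels")
  }
  if (any(enrichment < 0 | enrichment > 1)) {
    stop("enrichment probabilities must be in [0, 1]")
  }
  missing <- setdiff(unique(x$truth_subtype), names(enrichment))
  if (length(missing)) {
    stop("no enrichment probability for subtype(s): ",
         paste(missing, collapse = ", "))
  }
  p <- unname(enrichment[x$truth_subtype])
  x$facs_fraction <- withr::with_seed(
    seed,
    ifelse(stats::runif(length(p)) < p, "PE", "NC")
  )
  x
}

#' Drop cells by ground-truth label
#'
#' Convenience used to mirror the exclusion of microglia-like cells from
#' composition analysis: removes all cells whose truth label is in `labels`.
#'
#' @param x A [labeled_matrix()] with `truth_subtype`.
#' @param labels Labels to exclude.
#' @return A `labeled_expression_matrix` without the excluded cells.
#' @export
exclude_truth <- function(x, labels) {
  stopifnot(inherits(x, "labeled_expression_matrix"))
  if (is.null(x$truth_subtype)) stop("no truth_subtype labels present")
  subset_cells(x, !(x$truth_subtype %in% labels))
}
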