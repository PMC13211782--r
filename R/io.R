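find_file <- function(dir, base) {
  for (f in c(file.path(dir, base), file.path(dir, paste0(base, ".gz")))) {
    if (file.exists(f)) return(f)
  }
  NULL
}

read_tsv_plain <- function(path) {
  lines <- if (endsWith(path, ".gz")) readLines(gzfile(path)) else readLines(path)
  if (!length(lines)) return(data.frame(V1 = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- max(lengths(parts))
  as.data.frame(do.call(rbind, lapply(parts, function(p) {
    length(p) <- ncol
    p
  })), stringsAsFactors = FALSE)
}

#' Read a 10x-style MatrixMarket directory
#'
#' Reads `matrix.mtx`, `barcodes.tsv` and `features.tsv` (plain or gzipped)
#' from a directory. The matrix file stores genes x cells, as written by the
#' upstream vendor pipeline, and is transposed to cells x genes on load.
#' If a `truth.csv` sidecar is present (columns `cell_id`, `truth_subtype`,
#' `facs_fraction`), the labels are attached.
#'
#' @param path Directory containing the three files.
#' @return A [labeled_matrix()].
#' @export
read_mtx_dir <- function(path) {
  mtx <- find_file(path, "matrix.mtx")
  bc <- find_file(path, "barcodes.tsv")
  ft <- find_file(path, "features.tsv")
  for (f in list(mtx = mtx, bc = bc, ft = ft)) {
    if (is.null(f)) stop("missing matrix.mtx / barcodes.tsv / features.tsv in ", path)
  }
  m <- Matrix::readMM(if (endsWith(mtx, ".gz")) gzfile(mtx) else mtx)
  barcodes <- read_tsv_plain(bc)[[1]]
  features <- read_tsv_plain(ft)
  if (anyDuplicated(barcodes)) {
    stop("duplicate barcodes in ", bc, " (line ",
         which(duplicated(barcodes))[1], ")")
  }
  if (nrow(m) != nrow(features)) {
    stop("dimension mismatch: ", mtx, " has ", nrow(m), " rows but ", ft,
         " lists ", nrow(features), " features")
  }
  if (ncol(m) != length(barcodes)) {
    stop("dimension mismatch: ", mtx, " has ", ncol(m), " columns but ", bc,
         " lists ", length(barcodes), " barcodes")
  }
  counts <- Matrix::t(m)
  dimnames(counts) <- list(barcodes, features[[1]])
  truth_file <- file.path(path, "truth.csv")
  truth <- facs <- NULL
  if (file.exists(truth_file)) {
    tr <- utils::read.csv(truth_file, colClasses = "character",
                          comment.char = "#")
    ord <- match(barcodes, tr$cell_id)
    if ("truth_subtype" %in% names(tr)) truth <- tr$truth_subtype[ord]
    if ("facs_fraction" %in% names(tr)) {
      facs <- tr$facs_fraction[ord]
      facs[facs == ""] <- NA
    }
  }
  labeled_matrix(counts, truth_subtype = truth, facs_fraction = facs)
}

#' Write a 10x-style MatrixMarket directory
#'
#' Inverse of [read_mtx_dir()]: writes `matrix.mtx` (genes x cells,
#' 1-based MatrixMarket triplets), `barcodes.tsv` and a three-column
#' `features.tsv` (`gene_id`, `gene_name`, `feature_type`). Truth labels,
#' when present, go to a `truth.csv` sidecar.
#'
#' @param x A [labeled_matrix()].
#' @param path Output directory (created if needed).
#' @param gzip Compress the three vendor-format files.
#' @return `path`, invisibly.
#' @export
write_mtx_dir <- function(x, path, gzip = FALSE) {
  stopifnot(inherits(x, "labeled_expression_matrix"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".gz" else ""
  open_out <- function(base) {
    f <- file.path(path, paste0(base, ext))
    if (gzip) gzfile(f, "wb") else file(f, "wb")
  }
  mtx_plain <- file.path(path, "matrix.mtx")
  Matrix::writeMM(Matrix::t(x$counts), mtx_plain)
  if (gzip) {
    raw <- readBin(mtx_plain, "raw", file.size(mtx_plain))
    con <- gzfile(file.path(path, "matrix.mtx.gz"), "wb")
    writeBin(raw, con); close(con)
    unlink(mtx_plain)
  }
  con <- open_out("barcodes.tsv")
  writeLines(rownames(x$counts), con); close(con)
  con <- open_out("features.tsv")
  writeLines(paste(colnames(x$counts), colnames(x$counts), "Gene Expression",
                   sep = "\t"), con)
  close(con)
  if (!is.null(x$truth_subtype) || !is.null(x$facs_fraction)) {
    df <- data.frame(
      cell_id = rownames(x$counts),
      truth_subtype = if (is.null(x$truth_subtype)) "" else x$truth_subtype,
      facs_fraction = if (is.null(x$facs_fraction)) "" else x$facs_fraction
    )
    utils::write.csv(df, file.path(path, "truth.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

provenance_header <- function(seed = NULL) {
  paste0("# ependymap v", as.character(utils::packageVersion("ependymap")),
         if (!is.null(seed)) paste0(" seed=", seed) else "")
}

write_table_with_header <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed), con)
  utils::write.csv(as.data.frame(df), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read z-stack counts as CSV
#'
#' Plain CSV with a one-line `#` provenance header; columns `field_id`,
#' `marker`, `layer`, `positive`, `nuclei`.
#'
#' @param counts A `zstack_counts` table.
#' @param path Output file.
#' @param seed Seed recorded in the header, if any.
#' @return `path` (writer) / the counts tibble (reader).
#' @export
write_zstack_csv <- function(counts, path, seed = NULL) {
  counts <- validate_zstack(counts)
  write_table_with_header(counts, path, seed)
}

#' @rdname write_zstack_csv
#' @export
read_zstack_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  df$positive <- as.integer(df$positive)
  df$nuclei <- as.integer(df$nuclei)
  res <- validate_zstack(df)
  class(res) <- c("zstack_counts", class(res))
  res
}

#' Write / read a composition table as CSV
#'
#' Fractions are written with full double precision so a round trip
#' preserves them to better than 1e-12.
#'
#' @param composition A [composition_table()].
#' @param path Output file.
#' @param seed Seed recorded in the header, if any.
#' @return `path` (writer) / the validated composition (reader).
#' @export
write_composition_csv <- function(composition, path, seed = NULL) {
  composition <- composition_table(composition)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed), con)
  writeLines("stratum,sector,fraction", con)
  writeLines(paste(composition$stratum, composition$sector,
                   formatC(composition$fraction, digits = 17, format = "g"),
                   sep = ","), con)
  invisible(path)
}

#' @rdname write_composition_csv
#' @export
read_composition_csv <- function(path) {
  composition_table(utils::read.csv(path, comment.char = "#"))
}

#' Write a QC report as JSON
#' @param report A `qc_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_qc_report_json <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  payload <- list(
    package = "ependymap",
    version = as.character(utils::packageVersion("ependymap")),
    dims_in = report$dims_in, dims_out = report$dims_out,
    steps = lapply(report$steps, function(s) s[setdiff(names(s), "ids")]),
    warnings = report$warnings
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run configuration
#'
#' One object holding everything a reproducible run needs: the master seed,
#' the simulation configuration, QC thresholds, the gating scheme and the
#' output directory. Serialisable to YAML.
#'
#' @param seed Master integer seed; every random step derives from it.
#' @param sim A [sim_config()].
#' @param qc A [qc_params()].
#' @param scheme A [gating_scheme()].
#' @param out_dir Output directory for artifacts.
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1L, sim = sim_config(10000, seed = seed),
                       qc = qc_params(), scheme = gating_scheme(),
                       out_dir = "results") {
  structure(list(seed = as.integer(seed), sim = sim, qc = qc, scheme = scheme,
                 out_dir = out_dir),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' Profiles are stored by field (name, weight, marker probabilities,
#' mean count, optional coupled pair) so a configuration round-trips
#' exactly.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `path` (writer) / a `run_config` (reader).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  profiles <- lapply(config$sim$profiles, function(p) {
    list(name = p$name, weight = p$weight,
         marker_probs = as.list(p$marker_probs),
         mean_count = p$mean_count,
         couple = if (is.null(p$couple)) NULL else
           list(genes = as.list(p$couple$genes), joint = p$couple$joint))
  })
  yaml::write_yaml(list(
    seed = config$seed,
    out_dir = config$out_dir,
    sim = list(n_cells = config$sim$n_cells,
               capture_rate = config$sim$capture_rate,
               background_genes = config$sim$background_genes,
               background_mean = config$sim$background_mean,
               mito_genes = config$sim$mito_genes,
               mito_mean = config$sim$mito_mean,
               seed = config$sim$seed,
               profiles = profiles),
    qc = unclass(config$qc),
    scheme = list(markers = as.list(config$scheme$markers),
                  remainder_name = config$scheme$remainder_name)
  ), path, precision = 17)   # enough digits for an exact double round trip
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  profiles <- lapply(y$sim$profiles, function(p) {
    subtype_profile(p$name, p$weight, unlist(p$marker_probs),
                    mean_count = p$mean_count,
                    couple = if (is.null(p$couple)) NULL else
                      list(genes = unlist(p$couple$genes),
                           joint = p$couple$joint))
  })
  sim <- sim_config(y$sim$n_cells, profiles,
                    capture_rate = y$sim$capture_rate,
                    background_genes = y$sim$background_genes,
                    background_mean = y$sim$background_mean,
                    mito_genes = y$sim$mito_genes, mito_mean = y$sim$mito_mean,
                    seed = y$sim$seed)
  run_config(seed = y$seed, sim = sim,
             qc = do.call(qc_params, y$qc[setdiff(names(y$qc), NULL)]),
             scheme = gating_scheme(unlist(y$scheme$markers),
                                    y$scheme$remainder_name),
             out_dir = y$out_dir)
}
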