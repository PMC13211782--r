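# Independent brute-force oracles and shared fixtures.

# First-match serial depletion, one cell at a time: the reference the
# vectorised implementation is checked against.
oracle_serial_depletion <- function(binary, markers, remainder = "undefined") {
  bins <- character(nrow(binary))
  for (i in seq_len(nrow(binary))) {
    bins[i] <- remainder
    for (m in markers) {
      if (binary[i, m]) {
        bins[i] <- m
        break
      }
    }
  }
  bins
}

# Rule-by-rule QC enumeration with explicit loops.
oracle_qc <- function(counts, params) {
  keep_cells <- rownames(counts)
  keep_genes <- colnames(counts)
  sub <- function() counts[keep_cells, keep_genes, drop = FALSE]
  # rule 1
  keep_cells <- keep_cells[apply(sub(), 1, function(r) sum(r > 0)) >=
                             params$min_genes_at_creation]
  # rule 2
  keep_genes <- keep_genes[apply(sub(), 2, function(g) sum(g > 0)) >=
                             params$min_cells_per_gene]
  # rule 3
  feats <- apply(sub(), 1, function(r) sum(r > 0))
  keep_cells <- keep_cells[feats >= params$min_features &
                             feats <= params$max_features]
  # rule 4
  m <- sub()
  mito <- startsWith(colnames(m), params$mito_prefix)
  if (any(mito)) {
    frac <- vapply(seq_len(nrow(m)), function(i) {
      tot <- sum(m[i, ])
      if (tot > 0) sum(m[i, mito]) / tot else 0
    }, numeric(1))
    keep_cells <- keep_cells[frac <= params$max_mito_fraction]
  }
  list(cells = keep_cells, genes = keep_genes)
}

binom_se <- function(p, n) sqrt(p * (1 - p) / n)

# random small boolean marker matrices for oracle equivalence checks
rand_binary <- function(n_cells, markers, p = 0.4) {
  b <- matrix(runif(n_cells * length(markers)) < p, n_cells, length(markers),
              dimnames = list(NULL, markers))
  structure(b, threshold = 1L,
            class = c("binary_marker_matrix", "matrix", "array"))
}

# hand-built 10-cell QC fixture with small thresholds; counts chosen so each
# rule removes a known set (enumerated by oracle_qc and frozen in the tests):
# c03/c08 fail the creation gene count, g6 is detected in too few surviving
# cells, c06 exceeds the feature window once g6 is gone, c04 is 75%
# mitochondrial; the filtered fixture is a fixed point of the filters.
qc_fixture <- function() {
  genes <- c("g1", "g2", "g3", "g4", "g5", "g6", "mt-a", "mt-b")
  m <- matrix(0, 10, 8, dimnames = list(sprintf("c%02d", 1:10), genes))
  m["c01", c("g1", "g2", "g3", "g4", "mt-a")] <- c(5, 3, 2, 1, 1)
  m["c02", c("g1", "g2", "g5", "mt-b")] <- c(4, 2, 6, 1)
  m["c03", c("g1", "g2")] <- c(7, 1)
  m["c04", c("g1", "g3", "g4", "mt-a")] <- c(1, 1, 1, 9)
  m["c05", c("g2", "g3", "g4", "g5", "mt-a")] <- c(2, 2, 4, 3, 1)
  m["c06", c("g1", "g2", "g3", "g4", "g5", "g6", "mt-a")] <- 1
  m["c07", c("g3", "g4", "g5", "mt-a")] <- c(8, 1, 2, 1)
  m["c08", "g6"] <- 9
  m["c09", c("g1", "g4", "g5", "mt-b")] <- c(3, 2, 1, 1)
  m["c10", c("g2", "g5", "g6", "mt-b")] <- c(2, 3, 1, 1)
  labeled_matrix(m)
}

qc_fixture_params <- function() {
  qc_params(min_genes_at_creation = 3, min_cells_per_gene = 3,
            min_features = 2, max_features = 5, max_mito_fraction = 0.2,
            mito_prefix = "mt-")
}
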