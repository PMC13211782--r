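scheme5 <- gating_scheme()

test_that("binarize thresholds counts and validates its inputs", {
  m <- matrix(0, 4, 3, dimnames = list(NULL, c("Prom1", "Flt1", "Vim")))
  expect_false(any(binarize(labeled_matrix(m))))

  counts <- matrix(c(0, 1, 2, 5, 0, 1, 3, 0), 4, 2,
                   dimnames = list(NULL, c("A", "B")))
  b1 <- binarize(counts, threshold = 1)
  b2 <- binarize(counts, threshold = 2)
  expect_true(all(which(b2) %in% which(b1)))  # positives(2) subset positives(1)
  expect_error(binarize(counts, genes = c("A", "Zzz", "Yyy")), "Zzz, Yyy")
  expect_error(binarize(counts, threshold = 0), "threshold")
})

test_that("serial depletion follows the first-match rule on hand-made cells", {
  b <- rand_binary(4, scheme5$markers, p = 0)
  b[1, "Prom1"] <- TRUE
  b[2, "Flt1"] <- TRUE
  b[3, "Vim"] <- TRUE                  # negative for the four earlier markers
  sd <- serial_depletion(b, scheme5)
  expect_identical(sd$composition$n_cells, c(1L, 1L, 0L, 0L, 1L, 1L))

  all_pos <- rand_binary(10, scheme5$markers, p = 1)
  sd <- serial_depletion(all_pos, scheme5)
  expect_identical(sd$composition$fraction[1], 1)

  expect_error(serial_depletion(b, gating_scheme("Nope")), "absent")
})

test_that("serial depletion equals the exhaustive first-match oracle", {
  # all 32 outcomes of five binary markers
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 5)))
  colnames(grid) <- scheme5$markers
  b <- structure(grid, threshold = 1L,
                 class = c("binary_marker_matrix", "matrix", "array"))
  got <- serial_depletion(b, scheme5)$assignment
  want <- oracle_serial_depletion(grid, scheme5$markers)
  marker_of_bin <- setNames(c(scheme5$markers, "undefined"),
                            c(scheme5$bin_names, "undefined"))
  expect_identical(unname(marker_of_bin[as.character(got)]), want)

  withr::with_seed(81, {
    for (i in 1:100) {
      b <- rand_binary(10, scheme5$markers, p = runif(1, 0.1, 0.9))
      got <- serial_depletion(b, scheme5)$assignment
      want <- oracle_serial_depletion(b, scheme5$markers)
      expect_identical(unname(marker_of_bin[as.character(got)]), want)
    }
  })
})

test_that("bins plus remainder are a disjoint exhaustive partition", {
  withr::with_seed(82, b <- rand_binary(500, scheme5$markers, p = 0.3))
  sd <- serial_depletion(b, scheme5)
  expect_identical(sum(sd$composition$n_cells), 500L)
  expect_false(anyNA(sd$assignment))
  expect_equal(sum(sd$composition$fraction), 1, tolerance = 1e-12)
})

test_that("the remainder fraction is invariant to marker order", {
  withr::with_seed(83, b <- rand_binary(300, scheme5$markers, p = 0.25))
  base <- serial_depletion(b, scheme5)$composition
  rem0 <- base$fraction[base$bin == "undefined"]
  for (perm in list(c(1, 3, 5, 4, 2), c(5, 4, 3, 2, 1), c(2, 1, 4, 3, 5))) {
    sc <- gating_scheme(scheme5$markers[perm])
    comp <- serial_depletion(b, sc)$composition
    expect_identical(comp$fraction[comp$bin == "undefined"], rem0)
  }
})

test_that("co-expression conditionals are counted and left undefined at 0/0", {
  b <- rand_binary(6, c("A", "B"), p = 0)
  b[1:3, "A"] <- TRUE
  b[3:4, "B"] <- TRUE
  tab <- coexpression(b, list(c("A", "A"), c("A", "B"), c("B", "A")))
  expect_equal(tab$conditional, c(1, 1 / 3, 1 / 2))

  none <- rand_binary(5, c("A", "B"), p = 0)
  none[1, "B"] <- TRUE
  tab <- coexpression(none, list(c("A", "B")))
  expect_true(is.na(tab$conditional))   # undefined, not zero

  disj <- rand_binary(4, c("A", "B"), p = 0)
  disj[1:2, "A"] <- TRUE; disj[3:4, "B"] <- TRUE
  expect_identical(coexpression(disj, list(c("A", "B")))$conditional, 0)
})

test_that("joint fractions agree in both conditioning directions", {
  withr::with_seed(84, b <- rand_binary(400, c("A", "B", "C"), p = 0.5))
  n <- nrow(b)
  for (pair in list(c("A", "B"), c("B", "C"), c("A", "C"))) {
    ab <- coexpression(b, list(pair, rev(pair)))
    pa <- sum(b[, pair[1]]) / n
    pb <- sum(b[, pair[2]]) / n
    expect_equal(ab$conditional[1] * pa, ab$conditional[2] * pb,
                 tolerance = 1e-12)
  }
})

test_that("marker rates handle empty inputs and all-zero matrices", {
  b <- rand_binary(10, c("A", "B"), p = 0)
  expect_identical(marker_positive_rates(b)$rate, c(0, 0))
  expect_identical(nrow(marker_positive_rates(b, character(0))), 0L)
})

test_that("every five-marker outcome maps to exactly one subtype label", {
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 5)))
  colnames(grid) <- c("Prom1", "Flt1", "Sox2", "Pdgfrb", "Vim")
  lab <- assign_subtypes(grid)
  expect_identical(length(lab), 32L)
  expect_false(anyNA(lab))
  # the twelve core classes all occur in the truth table
  core <- c(outer(c("CD133+", "CD133-"),
                  c("endothelial-like", "Foxj1-ependymal", "pericyte-like",
                    "endo-peri-like", "Foxj1-endo-like"), paste),
            "CD133- Vim-only", "CD133- negative-for-all")
  expect_true(all(core %in% as.character(lab)))
})

test_that("named cells receive the published subtype labels", {
  b <- rand_binary(4, c("Prom1", "Flt1", "Sox2", "Pdgfrb", "Vim"), p = 0)
  b[1, c("Prom1", "Flt1", "Pdgfrb")] <- TRUE  # endothelial-pericyte co-label
  b[3, c("Sox2", "Pdgfrb")] <- TRUE           # rare co-label kept explicit
  b[4, "Prom1"] <- TRUE
  lab <- as.character(assign_subtypes(b))
  expect_identical(lab[1], "CD133+ endo-peri-like")
  expect_identical(lab[2], "CD133- negative-for-all")
  expect_identical(lab[3], "CD133- Foxj1-peri-like")
  expect_identical(lab[4], "CD133+ unclassified")
  # optional cluster-style relabelling folds overlaps into pericyte-like
  lab2 <- assign_subtypes(b, relabel = c("CD133+ endo-peri-like" =
                                           "CD133+ pericyte-like"))
  expect_identical(as.character(lab2)[1], "CD133+ pericyte-like")
})
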