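test_that("generation is a deterministic function of the configuration", {
  cfg <- sim_config(400, seed = 11)
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$truth_subtype, b$truth_subtype)
  cfg2 <- sim_config(400, seed = 12)
  expect_false(identical(as.matrix(a$counts),
                         as.matrix(generate_expression(cfg2)$counts)))
})

test_that("expression and capture behave at the boundaries", {
  one <- list(subtype_profile("only", 1, c(Prom1 = 1)))
  full <- generate_expression(sim_config(200, one, capture_rate = 1,
                                         background_genes = 0, mito_genes = 0,
                                         seed = 1))
  expect_true(all(full$counts[, "Prom1"] >= 1))
  none <- generate_expression(sim_config(200, capture_rate = 0, seed = 1))
  expect_equal(length(none$counts@x), 0)
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(100, profiles = list()), "profiles")
  bad_w <- list(subtype_profile("a", 0.4, c(Prom1 = 1)),
                subtype_profile("b", 0.4, c(Vim = 1)))
  expect_error(sim_config(100, profiles = bad_w), "weight")
  expect_error(subtype_profile("a", 0.5, c(Prom1 = 1.2)), "marker_probs")
  expect_error(subtype_profile("a", 0.5, c(Prom1 = 0.5), mean_count = 0),
               "mean_count")
  expect_error(
    subtype_profile("a", 1, c(X = 0.1, Y = 0.1),
                    couple = list(genes = c("X", "Y"), joint = 0.5)),
    "infeasible")
})

test_that("planted marker fractions are recovered at scale", {
  profs <- default_profiles()
  mat <- generate_expression(sim_config(20000, profs, seed = 21))
  b <- binarize(mat, genes = c("Prom1", "Vim", "Pdgfrb"))
  n <- nrow(b)
  planted_prom1 <- profs$prom1_multiciliated$weight  # only bin 1 has Prom1
  expect_lt(abs(mean(b[, "Prom1"]) - planted_prom1),
            3 * binom_se(planted_prom1, n))
  expect_lt(abs(mean(b[, "Vim"]) - 0.80), 3 * binom_se(0.80, n))
  expect_lt(abs(mean(b[, "Pdgfrb"]) - 0.16), 3 * binom_se(0.16, n))
})

test_that("lowering the capture rate never raises detected fractions", {
  profs <- default_profiles()
  hi <- generate_expression(sim_config(4000, profs, capture_rate = 0.9,
                                       seed = 31))
  lo <- generate_expression(sim_config(4000, profs, capture_rate = 0.15,
                                       seed = 31))
  for (g in gating_scheme()$markers) {
    f_hi <- mean(binarize(hi, g)[, g])
    f_lo <- mean(binarize(lo, g)[, g])
    expect_lte(f_lo, f_hi + 2 * binom_se(max(f_hi, 0.01), 4000))
  }
})

test_that("FACS split honours per-subtype enrichment probabilities", {
  mat <- generate_expression(sim_config(2000, seed = 41))
  labs <- unique(mat$truth_subtype)

  pure <- setNames(rep(0, length(labs)), labs)
  pure["prom1_multiciliated"] <- 1
  split <- generate_facs_split(mat, pure, seed = 1)
  expect_true(all(split$truth_subtype[split$facs_fraction == "PE"] ==
                    "prom1_multiciliated"))

  half <- setNames(rep(0.5, length(labs)), labs)
  split <- generate_facs_split(mat, half, seed = 2)
  pe <- mean(split$facs_fraction == "PE")
  expect_lt(abs(pe - 0.5), 3 * binom_se(0.5, 2000))

  expect_error(generate_facs_split(mat, setNames(rep(1.5, length(labs)), labs)),
               "\\[0, 1\\]")
  unlab <- labeled_matrix(mat$counts)
  expect_error(generate_facs_split(unlab), "truth_subtype")
})

test_that("default enrichment over-represents ependymal subtypes in PE", {
  profs <- add_spike_ins(default_profiles(),
                         weights = c(neuroblast = 0.15, microglia_like = 0.05))
  mat <- generate_expression(sim_config(6000, profs, seed = 51))
  split <- generate_facs_split(mat, seed = 52)
  epe <- mat$truth_subtype %in% c("prom1_multiciliated", "flt1_endothelial",
                                  "sox2_foxj1_ependymal")
  pe <- split$facs_fraction == "PE"
  expect_gt(mean(epe[pe]), mean(epe[!pe]))
  # neuroblasts deplete from PE
  nb <- mat$truth_subtype == "neuroblast"
  expect_lt(mean(nb[pe]), mean(nb[!pe]))
})

test_that("z-stack generator plants per-layer rates and merged union", {
  comp <- final_composition_default()
  z <- generate_zstack(comp, n_fields = 25, cells_per_field = 200, seed = 61)
  lr <- layer_rates(z)
  planted <- sum(comp$fraction[comp$stratum == "CD133pos"])
  for (ly in c("A", "B", "C", "D")) {
    r <- lr$rate[lr$marker == "CD133" & lr$layer == ly]
    expect_lt(abs(r - planted), 3 * binom_se(planted, 25 * 200))
  }
  # layered detection: cilia-like channel nearly absent from the deep layer
  zl <- generate_zstack(comp, detection = layered_detection_example(),
                        n_fields = 25, cells_per_field = 200, seed = 62)
  lrl <- layer_rates(zl)
  deep <- lrl$rate[lrl$marker == "CD133" & lrl$layer == "C"]
  surface <- lrl$rate[lrl$marker == "CD133" & lrl$layer == "A"]
  expect_lt(deep, 0.25 * surface)
  # merged projection counts any-layer detections, so it dominates each layer
  for (ly in c("A", "B", "C")) {
    expect_gte(lrl$rate[lrl$marker == "CD133" & lrl$layer == "D"],
               lrl$rate[lrl$marker == "CD133" & lrl$layer == ly])
  }
  expect_error(generate_zstack(comp, n_fields = 0), "n_fields")
  expect_error(generate_zstack(comp, cells_per_field = 0), "cells_per_field")
})
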