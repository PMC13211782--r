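test_that("trio averaging is the plain mean with validated inputs", {
  expect_equal(trio_average(c(0.3, 0.3, 0.3)), 0.3)
  expect_equal(trio_average(c(0, 0, 0)), 0)
  expect_equal(trio_average(c(0.50, 0.52, 0.48)), 0.50)
  expect_error(trio_average(c(0.5, 0.5)), "three")
  expect_error(trio_average(c(0.5, 0.5, 1.2)), "\\[0, 1\\]")
})

test_that("subgroup rates average trios and validate completeness", {
  pos <- list(endo = c(0.39, 0.41, 0.40), foxj1 = 0.34, peri = 0.12,
              vim = NA, endo_peri = 0.04, foxj1_endo = 0.14, foxj1_peri = 0)
  neg <- list(endo = 0.1, foxj1 = 0.15, peri = 0.04, vim = 0.3,
              endo_peri = 0.01, foxj1_endo = 0.02, foxj1_peri = 0)
  sr <- subgroup_rates(pos, neg)
  expect_equal(sr$CD133pos$endo, 0.40)
  expect_error(subgroup_rates(pos[-2], neg), "foxj1")
  pos$peri <- 1.4
  expect_error(subgroup_rates(pos, neg), "\\[0, 1\\]")
})

test_that("a single saturated subgroup reconstitutes to a single sector", {
  pos <- list(endo = 1, foxj1 = 0, peri = 0, vim = NA,
              endo_peri = 0, foxj1_endo = 0, foxj1_peri = 0)
  neg <- list(endo = 0, foxj1 = 0, peri = 0, vim = 0,
              endo_peri = 0, foxj1_endo = 0, foxj1_peri = 0)
  fc <- reconstitute(1, subgroup_rates(pos, neg))
  expect_equal(fc$fraction[fc$stratum == "CD133pos" &
                             fc$sector == "endothelial"], 1)
  expect_equal(sum(fc$fraction), 1)
})

test_that("reconstitution matches hand inclusion-exclusion arithmetic", {
  # measured rates implied by the shipped default composition, as fractions
  # of total nuclei; the expected sectors below are worked out by hand:
  # e.g. CD133+ exclusive endothelial = 0.40 - 0.044 - 0.14 = 0.216
  pos <- list(endo = 0.40, foxj1 = 0.34, peri = 0.12, vim = NA,
              endo_peri = 0.044, foxj1_endo = 0.14, foxj1_peri = 0)
  neg <- list(endo = 0.10, foxj1 = 0.15, peri = 0.04, vim = 0.304,
              endo_peri = 0.01, foxj1_endo = 0.02, foxj1_peri = 0)
  fc <- reconstitute(0.676, subgroup_rates(pos, neg))
  get <- function(str, sec) fc$fraction[fc$stratum == str & fc$sector == sec]
  expect_equal(get("CD133pos", "endothelial"), 0.216, tolerance = 1e-12)
  expect_equal(get("CD133pos", "foxj1_ependymal"), 0.200, tolerance = 1e-12)
  expect_equal(get("CD133pos", "pericyte"), 0.076, tolerance = 1e-12)
  expect_equal(get("CD133pos", "endo_peri"), 0.044, tolerance = 1e-12)
  expect_equal(get("CD133pos", "foxj1_endo"), 0.140, tolerance = 1e-12)
  expect_equal(get("CD133neg", "endothelial"), 0.070, tolerance = 1e-12)
  expect_equal(get("CD133neg", "foxj1_ependymal"), 0.130, tolerance = 1e-12)
  expect_equal(get("CD133neg", "pericyte"), 0.030, tolerance = 1e-12)
  expect_equal(get("CD133neg", "vim_only"), 0.044, tolerance = 1e-12)
  expect_equal(get("CD133neg", "all_negative"), 0.020, tolerance = 1e-12)
  expect_equal(sum(fc$fraction), 1, tolerance = 1e-12)
  expect_equal(sum(fc$fraction[fc$stratum == "CD133pos"]), 0.676,
               tolerance = 1e-12)
  expect_length(attr(fc, "clipped"), 0)
})

test_that("negative intermediate sectors are clipped with a warning", {
  pos <- list(endo = 0.10, foxj1 = 0.30, peri = 0.10, vim = NA,
              endo_peri = 0.08, foxj1_endo = 0.09, foxj1_peri = 0)
  neg <- list(endo = 0.1, foxj1 = 0.1, peri = 0.05, vim = 0.25,
              endo_peri = 0, foxj1_endo = 0, foxj1_peri = 0)
  # endo_ex = 0.10 - 0.08 - 0.09 < 0
  expect_warning(fc <- reconstitute(0.6, subgroup_rates(pos, neg)),
                 "clipped")
  expect_true("CD133pos.endothelial" %in% attr(fc, "clipped"))
  expect_true(all(fc$fraction >= 0))
  expect_equal(sum(fc$fraction), 1, tolerance = 1e-12)
})

test_that("raising an exclusive input rate never shrinks its sector", {
  base <- list(endo = 0.3, foxj1 = 0.2, peri = 0.1, vim = NA,
               endo_peri = 0.02, foxj1_endo = 0.03, foxj1_peri = 0)
  neg <- list(endo = 0.1, foxj1 = 0.1, peri = 0.05, vim = 0.3,
              endo_peri = 0.01, foxj1_endo = 0.01, foxj1_peri = 0)
  prev <- -Inf
  for (e in seq(0.3, 0.6, by = 0.1)) {
    pos <- base; pos$endo <- e
    fc <- reconstitute(0.65, subgroup_rates(pos, neg))
    cur <- fc$fraction[fc$stratum == "CD133pos" & fc$sector == "endothelial"]
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("degenerate inputs are rejected", {
  neg <- list(endo = 0, foxj1 = 0, peri = 0, vim = 0,
              endo_peri = 0, foxj1_endo = 0, foxj1_peri = 0)
  expect_error(reconstitute(1, subgroup_rates(neg, neg)), "nothing")
  expect_error(reconstitute(1.2, subgroup_rates(neg, neg)), "cd133_rate")
  expect_error(reconstitute(0.5, list(a = 1)), "subgroup_rates")
})

test_that("composition round-trips through the imaging pathway", {
  planted <- final_composition_default()
  z <- generate_zstack(planted, n_fields = 20, cells_per_field = 200,
                       seed = 101)
  r <- rates_from_zstack(quantify_zstack(z))
  fc <- reconstitute(r$cd133_rate, r$rates)
  n <- 20 * 200
  for (i in seq_len(nrow(planted))) {
    p <- planted$fraction[i]
    got <- fc$fraction[fc$stratum == planted$stratum[i] &
                         fc$sector == planted$sector[i]]
    expect_lt(abs(got - p), 3 * binom_se(p, n) + 1e-9)
  }
})
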