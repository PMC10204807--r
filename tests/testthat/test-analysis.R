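test_that("flux_sum computes half the absolute stoichiometric throughput", {
  m <- toy_chain_model()
  sol <- solve_fba(m)
  ## A_c: produced by uptake at 10, consumed by R1 at 10 -> phi = 10
  fs <- flux_sum(m, sol, "A_c")
  expect_equal(fs$value, 10)
  expect_equal(sum(fs$producer_breakdown), sum(fs$consumer_breakdown))
  expect_equal(sum(fs$producer_breakdown), fs$value)

  ## metabolite untouched by any active reaction
  ml <- toy_loop_model()
  can <- canonicalize(ml, solve_fba(ml))
  expect_equal(flux_sum(ml, can, "C_c")$value, 0)
  expect_error(flux_sum(m, sol, "nope_c"), "unknown metabolite")
})

test_that("steady-state bookkeeping holds for every internal metabolite", {
  m <- leaf_fixture()
  base <- leaf_baseline()
  for (mid in m$metabolites$id[!m$metabolites$boundary]) {
    fs <- flux_sum(m, base$solution, mid)
    expect_equal(sum(fs$producer_breakdown), fs$value, tolerance = 1e-6)
    expect_equal(sum(fs$consumer_breakdown), fs$value, tolerance = 1e-6)
  }
})

test_that("CO2 attribution normalizes and isolates the sole producer", {
  m <- leaf_fixture()
  base <- leaf_baseline()
  att <- co2_source_attribution(m, base$solution)
  expect_equal(sum(att$table$fraction), 1, tolerance = 1e-9)
  expect_true(att$total_flux_sum > 0)
  expect_false("transport" %in% att$table$pathway)

  ## toy with a single decarboxylase -> that pathway's fraction is 1
  toy <- cbm_model(
    id = "decarb",
    compartments = data.frame(id = "c", name = "cytosol"),
    metabolites = data.frame(
      id = c("X_c", "co2_c"), name = c("X", "CO2"), compartment = "c",
      formula = c("C2", "C"), boundary = FALSE,
      annotation = c(NA, "co2")),
    reactions = data.frame(
      id = c("EX_X", "DC", "EX_co2"), name = c("X in", "decarboxylase", "co2 out"),
      lb = c(-5, 0, 0), ub = c(1000, 1000, 1000), gpr = NA,
      pathway = c("exchange", "respiration", "exchange"), ec = NA),
    stoich = data.frame(
      reaction = c("EX_X", "DC", "DC", "EX_co2"),
      metabolite = c("X_c", "X_c", "co2_c", "co2_c"),
      coef = c(-1, -1, 2, -1)),
    objective = c(EX_co2 = 1))
  sol <- solve_fba(toy)
  att2 <- co2_source_attribution(toy, sol)
  expect_identical(att2$table$pathway, "respiration")
  expect_equal(att2$table$fraction, 1)

  ## attribution fractions are invariant to uniform flux rescaling
  half <- base$solution
  half$fluxes <- half$fluxes / 2
  att_h <- co2_source_attribution(m, half)
  expect_equal(att_h$table$fraction[order(att_h$table$pathway)],
               att$table$fraction[order(att$table$pathway)],
               tolerance = 1e-9)
})

test_that("energy turnover report agrees with direct flux-sums", {
  m <- leaf_fixture()
  base <- leaf_baseline()
  rep <- energy_turnover_report(m, base$solution, baseline = base$solution)
  expect_true(all(abs(rep$turnover$fold_change - 1) < 1e-12))
  ## every reported value equals flux_sum called directly on the species
  for (i in seq_len(nrow(rep$turnover))) {
    row <- rep$turnover[i, ]
    mets <- annotated_metabolites(m, row$currency, compartment = row$compartment)
    direct <- sum(vapply(mets, function(mid)
      flux_sum(m, base$solution, mid)$value, numeric(1)))
    expect_equal(row$flux_sum, direct)
  }
  ## a compartment with no currency-touching activity reports zero
  expect_true(all(rep$turnover$flux_sum >= 0))
  ## shuttles are present and named
  expect_true(all(c("atp_chl_to_cyt", "nadh_chl_to_cyt") %in%
                    rep$shuttles$name))
})

test_that("concordance handles perfect, inverted and planted agreement", {
  m <- leaf_fixture()
  base <- leaf_baseline()
  dr <- run_drought(m, 0.5, baseline = base)
  fc <- fold_change_table(dr, base)

  perfect <- synth_expression(m, fc, agreement_p = 1, seed = 7)
  rep1 <- concordance(fc, perfect, m)
  expect_equal(rep1$agreement_fraction, 1)
  expect_gt(rep1$n_comparable, 10)

  inverted <- perfect
  inverted$log2fc <- -inverted$log2fc
  ## flip only genes of directional reactions; unchanged stays unchanged
  rep0 <- concordance(fc, inverted, m)
  dir_rows <- rep0$rows[rep0$rows$comparable &
                          rep0$rows$predicted_direction %in% c("up", "down"), ]
  expect_true(all(!dir_rows$agrees))

  ## invariance to gene order and duplicated records
  shuf <- perfect[rev(seq_len(nrow(perfect))), ]
  dup <- rbind(perfect, perfect)
  expect_equal(concordance(fc, shuf, m)$agreement_fraction, 1)
  expect_equal(concordance(fc, dup, m)$agreement_fraction, 1)

  ## reactions without GPR are not comparable
  no_gpr <- rep1$rows[rep1$rows$reaction == "NGAM_c", ]
  expect_false(no_gpr$comparable)
})

test_that("synth_expression is deterministic and respects the planted rate", {
  m <- leaf_fixture()
  base <- leaf_baseline()
  fc <- fold_change_table(run_drought(m, 0.5, baseline = base), base)
  a <- synth_expression(m, fc, 0.8, seed = 42)
  b <- synth_expression(m, fc, 0.8, seed = 42)
  expect_identical(a, b)
  c2 <- synth_expression(m, fc, 0.8, seed = 43)
  expect_false(identical(a, c2))
})
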