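test_that("fold change table: identity, doubling, epsilon stability", {
  base <- leaf_baseline()
  ## identical solutions give all-zero log2 changes
  fc0 <- fold_change_table(base, base)
  expect_lt(max(abs(fc0$log2fc)), 1e-12)
  expect_true(all(fc0$direction %in% c("unchanged", "inactive-both")))

  ## doubling a flux gives log2 = 1 exactly (closed form, far from eps)
  doubled <- base
  doubled$solution$fluxes[["NGAM_c"]] <- 2 * base$solution$fluxes[["NGAM_c"]]
  fc1 <- fold_change_table(doubled, base)
  expect_equal(fc1$log2fc[fc1$reaction == "NGAM_c"], 1, tolerance = 1e-6)
  expect_identical(fc1$direction[fc1$reaction == "NGAM_c"], "up")

  ## zero baseline, positive perturbed: large positive value, stable in eps
  pert <- base
  pert$solution$fluxes[["PEPCK_c"]] <- 5
  for (eps in c(1e-9, 1e-8)) {
    fc <- fold_change_table(pert, base, epsilon = eps)
    row <- fc[fc$reaction == "PEPCK_c", ]
    expect_identical(row$direction, "up")
    expect_gt(row$log2fc, 20)
  }
})

test_that("drought scenario: identity, starvation, monotone stress response", {
  m <- leaf_fixture()
  base <- leaf_baseline()

  d1 <- run_drought(m, 1.0, baseline = base)
  expect_identical(d1$solution$status, "optimal")
  expect_equal(d1$derived$growth, base$derived$growth, tolerance = 1e-6)
  expect_equal(unname(d1$solution$fluxes), unname(base$solution$fluxes),
               tolerance = 1e-5)

  d0 <- run_drought(m, 0.0, baseline = base)
  expect_identical(d0$solution$status, "optimal")
  expect_lt(abs(d0$derived$growth), 1e-8)      # no carbon, no growth

  fr <- c(0.3, 0.5, 0.8, 1.0)
  runs <- lapply(fr, run_drought, model = m, baseline = base)
  growth <- vapply(runs, function(r) r$derived$growth, numeric(1))
  pepc <- vapply(runs, function(r) r$derived$pepc, numeric(1))
  expect_true(all(diff(growth) >= -1e-8))      # growth non-decreasing in f
  expect_true(all(diff(pepc) <= 1e-8))         # PEPC non-increasing in f
  ## the drought mechanism: PEPC far above baseline, carboxylation
  ## retained at more than half its baseline value at 50% uptake
  half <- runs[[2]]
  expect_gt(half$derived$pepc / base$derived$pepc, 1)
  expect_gt(half$derived$vc / base$derived$vc, 0.5)
  expect_error(run_drought(m, 1.2), "\\[0, 1\\]")
})

test_that("PEPC elevation: no-op at factor 1, trade-off at factor 10", {
  m <- leaf_fixture()
  base <- leaf_baseline()
  p1 <- run_pepc_elevation(m, 1, baseline = base)
  expect_equal(p1$derived$growth, base$derived$growth, tolerance = 1e-6)
  expect_equal(p1$derived$pepc, base$derived$pepc, tolerance = 1e-5)

  p10 <- run_pepc_elevation(m, 10, baseline = base)
  expect_identical(p10$solution$status, "optimal")
  expect_gte(p10$derived$pepc, 10 * base$derived$pepc - 1e-6)
  expect_lt(p10$derived$growth, base$derived$growth)       # biomass down
  expect_gt(p10$derived$sucrose_export,
            base$derived$sucrose_export + 1e-6)            # sucrose up
  ## an impossible demand is surfaced as infeasible, not masked
  sky <- run_pepc_elevation(m, 1e6, baseline = base)
  expect_identical(sky$solution$status, "infeasible")
})

test_that("photorespiration sweep reproduces the stress trend", {
  m <- leaf_fixture()
  sw <- run_photorespiration_sweep(m, ratios = c(1, 2, 3, 4, 5))
  s <- sw$summary[order(sw$summary$ratio), ]
  expect_true(all(s$status == "optimal"))
  ## growth and CO2 uptake fall as photorespiration rises (ratio falls)
  expect_true(all(diff(s$growth) > 0))
  expect_true(all(diff(s$co2_uptake) > 0))
  ## self-comparison at the baseline ratio: all fold changes 1 (log2 = 0)
  sw3 <- run_photorespiration_sweep(m, ratios = 3)
  expect_true(is.null(sw3$fold_changes) ||
                max(abs(sw3$fold_changes$log2fc)) < 1e-9)
  ## severe photorespiration: growth drop vs baseline ratio
  g1 <- s$growth[s$ratio == 1]; g3 <- s$growth[s$ratio == 3]
  expect_lt(g1, g3)
  ## an infeasible point is recorded, the sweep continues: at a
  ## near-zero Vc/Vo the network cannot regenerate RuBP or absorb the
  ## pinned photon influx
  sw_t <- run_photorespiration_sweep(m, ratios = c(0.01, 3))
  expect_identical(nrow(sw_t$summary), 2L)
  st <- sw_t$summary$status[sw_t$summary$ratio == 0.01]
  expect_false(identical(st, "optimal"))
  expect_identical(sw_t$summary$status[sw_t$summary$ratio == 3], "optimal")
})

test_that("sweep sign structure matches the photorespiration response", {
  m <- leaf_fixture()
  sw <- run_photorespiration_sweep(m, ratios = c(1, 3))
  fc <- sw$fold_changes[sw$fold_changes$ratio == 1, ]
  photoresp <- fc$reaction[fc$pathway == "photorespiration"]
  dirs <- fc$direction[match(photoresp, fc$reaction)]
  expect_true(all(dirs == "up"))
  expect_identical(fc$direction[fc$reaction == "PEPC_c"], "down")
})
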