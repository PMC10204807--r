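test_that("FBA solves textbook cases exactly", {
  m <- toy_chain_model(uptake = 10)
  sol <- solve_fba(m)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)          # single bottleneck
  expect_lt(max(abs(stoichiometric_matrix(m) %*% sol$fluxes)), 1e-6)

  ## closing every exchange forces the zero optimum
  closed <- m
  for (ex in exchange_reactions(closed))
    closed <- set_bounds(closed, ex, lb = 0, ub = 0)
  sol0 <- solve_fba(closed)
  expect_identical(sol0$status, "optimal")
  expect_equal(sol0$objective_value, 0)
})

test_that("FBA objective matches the enumeration oracle on random models", {
  for (seed in 21:28) {
    rm_ <- random_toy_model(seed, m = sample(4:5, 1), n = sample(8:10, 1))
    sol <- solve_fba(rm_)
    S <- stoichiometric_matrix(rm_)
    cvec <- rep(0, ncol(S)); cvec[match(names(rm_$objective), colnames(S))] <-
      rm_$objective
    ref <- enum_lp_oracle(cvec, S, rep(0, nrow(S)), rm_$reactions$lb,
                          rm_$reactions$ub, "max")
    expect_identical(sol$status, "optimal")
    expect_lt(abs(sol$objective_value - ref), 1e-6 * max(1, abs(ref)))
  }
})

test_that("canonicalize preserves the optimum and minimizes total flux", {
  ## unique optimum: canonical fluxes coincide with the FBA solution
  m <- toy_chain_model()
  sol <- solve_fba(m)
  can <- canonicalize(m, sol)
  expect_equal(can$objective_value, sol$objective_value, tolerance = 1e-9)
  expect_equal(unname(can$fluxes), unname(sol$fluxes), tolerance = 1e-8)
  expect_true(can$canonicalized)

  ## a futile loop is driven to zero
  ml <- toy_loop_model()
  can_l <- canonicalize(ml, solve_fba(ml))
  expect_lt(abs(can_l$fluxes[["L1"]]), 1e-9)
  expect_lt(abs(can_l$fluxes[["L2"]]), 1e-9)

  ## degenerate toy: total |v| equals the enumeration oracle on the
  ## irreversible-split problem with the objective pinned
  lp <- random_toy_lp(31, m = 3, n = 5)
  rm_ <- random_toy_model(31, m = 3, n = 5)
  sol_r <- solve_fba(rm_)
  can_r <- canonicalize(rm_, sol_r)
  S <- stoichiometric_matrix(rm_)
  n <- ncol(S)
  cvec <- rep(0, n); cvec[n] <- 1
  A2 <- rbind(cbind(S, -S), c(cvec, -cvec))
  b2 <- c(rep(0, nrow(S)), sol_r$objective_value)
  lb <- rm_$reactions$lb; ub <- rm_$reactions$ub
  ref <- enum_lp_oracle(rep(1, 2 * n), A2, b2,
                        c(pmax(lb, 0), pmax(-ub, 0)),
                        c(pmax(ub, 0), pmax(-lb, 0)), "min")
  expect_equal(sum(abs(can_r$fluxes)), ref, tolerance = 1e-6)
  ## and never above the plain FBA solution's total flux
  expect_lte(sum(abs(can_r$fluxes)), sum(abs(sol_r$fluxes)) + 1e-8)
})

test_that("ratio constraints hold and match the augmented-matrix oracle", {
  m <- leaf_fixture()
  for (r in c(1, 2, 3, 4, 5)) {
    mr <- apply_ratio_constraint(m, ratio_constraint("RBC_carb", "RBC_oxy", r))
    sol <- solve_fba(mr)
    expect_identical(sol$status, "optimal")
    expect_lt(abs(sol$fluxes[["RBC_carb"]] - r * sol$fluxes[["RBC_oxy"]]),
              1e-6)
  }
  ## oxygenation forced to zero drags carboxylation to zero through the
  ## equality (photon influx capped instead of pinned, so the absorbed
  ## light constraint does not dominate)
  m0 <- set_bounds(m, "RBC_oxy", lb = 0, ub = 0)
  i <- match("EX_photon", m0$reactions$id)
  m0 <- set_bounds(m0, "EX_photon", ub = 0)
  sol0 <- solve_fba(m0)
  expect_identical(sol0$status, "optimal")
  expect_lt(abs(sol0$fluxes[["RBC_carb"]]), 1e-6)

  ## sweep on a random toy equals a direct dense LP with the ratio row
  ## appended to the explicit matrix
  rm_ <- random_toy_model(41, m = 4, n = 8)
  rm_$reactions$lb[c(2, 3)] <- 0      # irreversible operands
  for (r in c(0.5, 2)) {
    mr <- apply_ratio_constraint(rm_, ratio_constraint("R2", "R3", r))
    sol <- solve_fba(mr)
    S <- stoichiometric_matrix(rm_)
    row <- rep(0, ncol(S)); row[2] <- 1; row[3] <- -r
    cvec <- rep(0, ncol(S)); cvec[ncol(S)] <- 1
    ref <- enum_lp_oracle(cvec, rbind(S, row), c(rep(0, nrow(S)), 0),
                          rm_$reactions$lb, rm_$reactions$ub, "max")
    expect_equal(sol$objective_value, ref, tolerance = 1e-6)
  }
  expect_error(ratio_constraint("a", "b", -1), "positive")
  expect_error(apply_ratio_constraint(
    toy_chain_model(), ratio_constraint("EX_A", "R1", 2)), "reversible")
})

test_that("flux variability brackets every reaction", {
  m <- toy_chain_model()
  fva <- flux_variability(m, fraction_of_optimum = 1.0)
  ## a bottleneck chain at full optimum is fully determined
  expect_lt(max(abs(fva$max - fva$min)), 1e-8)
  expect_true(all(fva$min <= fva$max + 1e-9))

  ## near-zero fraction: the zero vector is admissible, so every range
  ## contains zero
  fva0 <- flux_variability(m, fraction_of_optimum = 1e-9)
  expect_true(all(fva0$min <= 1e-6 & fva0$max >= -1e-6))

  ## parallel pathway pair: alternates span [0, 10] each, sum pinned
  mp <- toy_chain_model()
  mp$reactions <- rbind(mp$reactions, data.frame(
    id = "R1b", name = "parallel path", lb = 0, ub = 1000, gpr = NA,
    pathway = "respiration", ec = NA))
  mp$stoich <- rbind(mp$stoich, data.frame(
    reaction = c("R1b", "R1b"), metabolite = c("A_c", "B_c"),
    coef = c(-1, 1)))
  fvp <- flux_variability(mp, fraction_of_optimum = 1.0,
                          reactions = c("R1", "R1b", "DM_B"))
  expect_equal(fvp$min[1:2], c(0, 0), tolerance = 1e-8)
  expect_equal(fvp$max[1:2], c(10, 10), tolerance = 1e-8)
  expect_equal(fvp$min[3], 10, tolerance = 1e-8)
  expect_error(flux_variability(m, fraction_of_optimum = 0), "\\(0, 1\\]")
})

test_that("photon constraint sets the uptake bound from P_N / LUE", {
  m <- leaf_fixture()
  m2 <- set_photon_constraint(m, net_photosynthesis = 10, lue = 0.05)
  i <- match("EX_photon", m2$reactions$id)
  expect_equal(m2$reactions$lb[i], -200)
  expect_equal(m2$reactions$ub[i], -200)   # pinned influx
  m3 <- set_photon_constraint(m, 10, 0.05, pin = FALSE)
  expect_equal(m3$reactions$lb[match("EX_photon", m3$reactions$id)], -200)
  expect_error(set_photon_constraint(m, 10, 0), "positive")
  expect_error(set_photon_constraint(toy_chain_model(), 10, 0.05), "photon")

  ## light-limited toy: biomass is homogeneous in the photon bound
  light <- cbm_model(
    id = "light",
    compartments = data.frame(id = "c", name = "cytosol"),
    metabolites = data.frame(
      id = c("photon_c", "co2_c", "sugar_c"),
      name = c("photon", "co2", "sugar"), compartment = "c",
      formula = c("Z0", "C", "C"), boundary = FALSE,
      annotation = c("photon", "co2", NA)),
    reactions = data.frame(
      id = c("EX_photon", "EX_co2", "FIX", "DM_sugar"),
      name = c("photon", "co2", "fixation", "growth"),
      lb = c(-40, -1000, 0, 0), ub = c(0, 1000, 1000, 1000),
      gpr = NA, pathway = c("exchange", "exchange", "calvin_cycle",
                            "exchange"), ec = NA),
    stoich = data.frame(
      reaction = c("EX_photon", "EX_co2", "FIX", "FIX", "FIX", "DM_sugar"),
      metabolite = c("photon_c", "co2_c", "photon_c", "co2_c", "sugar_c",
                     "sugar_c"),
      coef = c(-1, -1, -4, -1, 1, -1)),
    objective = c(DM_sugar = 1))
  z1 <- solve_fba(light)$objective_value
  light2 <- set_photon_constraint(light, net_photosynthesis = 5, lue = 0.25,
                                  pin = FALSE)  # photon bound 20 = half
  z2 <- solve_fba(light2)$objective_value
  expect_equal(z2, z1 / 2, tolerance = 1e-9)
})

test_that("scaling exchange bounds and maintenance scales the optimum", {
  ## LP positive homogeneity on the leaf model, k in {0.5, 2}
  m <- leaf_fixture()
  z1 <- leaf_baseline()$derived$growth
  for (k in c(0.5, 2)) {
    ms <- m
    scale_ids <- c(exchange_reactions(ms), "NGAM_c")
    for (rid in scale_ids) {
      i <- match(rid, ms$reactions$id)
      ms$reactions$lb[i] <- ms$reactions$lb[i] * k
      ms$reactions$ub[i] <- ms$reactions$ub[i] * k
    }
    zk <- solve_fba(ms)$objective_value
    expect_equal(zk, k * z1, tolerance = 1e-6)
  }
})
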