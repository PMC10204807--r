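test_that("TSV round trip is bit-exact", {
  m <- leaf_fixture()
  path <- tempfile(fileext = ".tsv")
  write_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$reactions$id, m$reactions$id)
  expect_identical(m2$reactions$lb, m$reactions$lb)
  expect_identical(m2$reactions$ub, m$reactions$ub)
  expect_identical(m2$metabolites$id, m$metabolites$id)
  s1 <- m$stoich[order(m$stoich$reaction, m$stoich$metabolite), ]
  s2 <- m2$stoich[order(m2$stoich$reaction, m2$stoich$metabolite), ]
  expect_identical(s2$coef, s1$coef)
  expect_identical(sort(names(m2$objective)), sort(names(m$objective)))
  unlink(path)
})

test_that("SBML round trip preserves structure to 1e-9", {
  m <- toy_chain_model()
  path <- tempfile(fileext = ".xml")
  write_model(m, path, format = "sbml")
  m2 <- load_model(path, format = "sbml")
  expect_identical(m2$reactions$id, m$reactions$id)
  expect_lt(max(abs(m2$reactions$lb - m$reactions$lb)), 1e-9)
  expect_lt(max(abs(m2$reactions$ub - m$reactions$ub)), 1e-9)
  expect_identical(m2$reactions$gpr[2], "g1 or g2")
  expect_identical(m2$metabolites$formula[1], "C1")
  expect_equal(m2$objective, m$objective)
  s1 <- m$stoich[order(m$stoich$reaction, m$stoich$metabolite), ]
  s2 <- m2$stoich[order(m2$stoich$reaction, m2$stoich$metabolite), ]
  expect_lt(max(abs(s1$coef - s2$coef)), 1e-9)
  ## and the leaf fixture survives SBML too
  leaf <- leaf_fixture()
  p2 <- tempfile(fileext = ".xml")
  write_model(leaf, p2, format = "sbml")
  leaf2 <- load_model(p2, format = "sbml")
  expect_identical(nrow(leaf2$reactions), nrow(leaf$reactions))
  expect_lt(max(abs(sort(leaf2$reactions$lb) - sort(leaf$reactions$lb))), 1e-9)
  unlink(c(path, p2))
})

test_that("validate_model reports violated invariants and nothing else", {
  m <- toy_chain_model()
  expect_identical(nrow(validate_model(m)), 0L)

  bad <- m
  bad$reactions$lb[2] <- 5; bad$reactions$ub[2] <- 1
  d <- validate_model(bad)
  expect_identical(d$rule, "bound_order")
  expect_identical(d$entity, "R1")

  ## carbon-imbalanced internal reaction: A (C1) -> B with B declared C2
  imb <- m
  imb$metabolites$formula[imb$metabolites$id == "B_c"] <- "C2"
  d2 <- validate_model(imb)
  expect_true(any(d2$rule == "element_balance" & d2$entity == "R1"))
  eb <- element_balance(imb)
  expect_identical(eb$element, "C")
  expect_equal(eb$imbalance, 1)   # hand-summed: -1 C consumed, +2 C produced

  dangle <- m
  dangle$stoich$metabolite[2] <- "ghost_c"
  d3 <- validate_model(dangle)
  expect_true(any(d3$rule == "metabolite_exists" & d3$entity == "ghost_c"))
})

test_that("load_model errors name the offending entity", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("!model", "id", "broken", "!compartments", "id\tname",
               "c\tcytosol", "!metabolites",
               "id\tname\tcompartment\tformula\tboundary\tannotation",
               "A_c\tA\tc\tC1\tfalse\t", "!reactions",
               "id\tname\tequation\tlb\tub\tgpr\tpathway\tec\tobjective",
               "R1\tbad\tA_c -> ghost_c\t0\t10\t\t\t\t1"), path)
  expect_error(load_model(path), "ghost_c")
  unlink(path)
  expect_error(load_model(tempfile()), "not found")
})

test_that("find_gaps flags dead ends and blocked reactions (FVA oracle)", {
  ## producer-only internal metabolite is a dead end
  m <- toy_chain_model()
  m$metabolites <- rbind(m$metabolites, data.frame(
    id = "D_c", name = "D", compartment = "c", formula = "C1",
    boundary = FALSE, annotation = NA))
  m$reactions <- rbind(m$reactions, data.frame(
    id = "R2", name = "B to D", lb = 0, ub = 1000, gpr = NA,
    pathway = "respiration", ec = NA))
  m$stoich <- rbind(m$stoich, data.frame(
    reaction = c("R2", "R2"), metabolite = c("B_c", "D_c"), coef = c(-1, 1)))
  g <- find_gaps(m)
  expect_identical(g$dead_end_metabolites, "D_c")
  expect_identical(g$blocked_reactions, "R2")

  ## fully coupled open chain has no gaps
  g0 <- find_gaps(toy_chain_model())
  expect_identical(length(g0$dead_end_metabolites), 0L)
  expect_identical(length(g0$blocked_reactions), 0L)

  ## random toys: blocked set equals brute-force per-reaction max |v|
  for (seed in c(3, 7, 11)) {
    rm_ <- random_toy_model(seed)
    S <- stoichiometric_matrix(rm_)
    lb <- rm_$reactions$lb; ub <- rm_$reactions$ub
    blocked_ref <- character()
    for (j in seq_len(ncol(S))) {
      cj <- rep(0, ncol(S)); cj[j] <- 1
      vmax <- enum_lp_oracle(cj, S, rep(0, nrow(S)), lb, ub, "max")
      vmin <- enum_lp_oracle(cj, S, rep(0, nrow(S)), lb, ub, "min")
      if (max(abs(c(vmax, vmin))) <= 1e-7)
        blocked_ref <- c(blocked_ref, colnames(S)[j])
    }
    g <- find_gaps(rm_, open_span = 100)
    expect_setequal(g$blocked_reactions, blocked_ref)
  }
})

test_that("homology filter applies inclusive thresholds and is monotone", {
  hits <- data.frame(
    gene = c("g1", "g2", "g3", "g4", "g5"),
    evalue = c(1e-12, 1e-9, 1e-10, 1e-15, 1e-11),
    identity_pct = c(65, 95, 60, 59.9, 80),
    coverage_pct = c(85, 95, 80, 99, 79.5))
  kept <- filter_homology_hits(hits)
  ## g1 passes all three; g2 fails E-value; g3 sits exactly on every
  ## threshold (inclusive); g4 fails identity; g5 fails coverage
  expect_identical(kept$gene, c("g1", "g3"))
  ## order preserved and idempotent
  expect_identical(filter_homology_hits(kept), kept)
  ## loosening any threshold never removes a retained row
  looser <- list(homology_criterion(max_evalue = 1e-8),
                 homology_criterion(min_identity_pct = 50),
                 homology_criterion(min_coverage_pct = 70))
  for (cr in looser)
    expect_true(all(kept$gene %in% filter_homology_hits(hits, cr)$gene))
  expect_error(filter_homology_hits(hits[, -2]), "evalue")
  expect_error(homology_criterion(max_evalue = 0), "positive")
  expect_error(homology_criterion(min_identity_pct = 120), "\\[0, 100\\]")
})
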