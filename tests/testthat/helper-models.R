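## Shared fixtures: tiny hand-built models, a random toy-model generator,
## and a brute-force vertex-enumeration LP oracle that is independent of
## the package's simplex implementation.

## internal helpers under test
lp_solve_bounded <- leafcbm:::lp_solve_bounded
parse_formula <- leafcbm:::parse_formula

toy_chain_model <- function(uptake = 10) {
  cbm_model(
    id = "chain",
    compartments = data.frame(id = "c", name = "cytosol"),
    metabolites = data.frame(
      id = c("A_c", "B_c"), name = c("A", "B"), compartment = "c",
      formula = c("C1", "C1"), boundary = FALSE,
      annotation = c("co2", NA)),
    reactions = data.frame(
      id = c("EX_A", "R1", "DM_B"),
      name = c("A exchange", "A to B", "B drain"),
      lb = c(-uptake, 0, 0), ub = c(1000, 1000, 1000),
      gpr = c(NA, "g1 or g2", NA),
      pathway = c("exchange", "respiration", "exchange"),
      ec = NA),
    stoich = data.frame(
      reaction = c("EX_A", "R1", "R1", "DM_B"),
      metabolite = c("A_c", "A_c", "B_c", "B_c"),
      coef = c(-1, -1, 1, -1)),
    objective = c(DM_B = 1))
}

## chain with a reversible futile loop B <-> C that can carry arbitrary
## flux without changing the objective
toy_loop_model <- function() {
  m <- toy_chain_model()
  m$metabolites <- rbind(m$metabolites, data.frame(
    id = "C_c", name = "C", compartment = "c", formula = "C1",
    boundary = FALSE, annotation = NA))
  m$reactions <- rbind(m$reactions, data.frame(
    id = c("L1", "L2"), name = c("loop fwd", "loop back"),
    lb = c(-1000, -1000), ub = c(1000, 1000), gpr = NA,
    pathway = "respiration", ec = NA))
  m$stoich <- rbind(m$stoich, data.frame(
    reaction = c("L1", "L1", "L2", "L2"),
    metabolite = c("B_c", "C_c", "C_c", "B_c"),
    coef = c(-1, 1, -1, 1)))
  m
}

## random small stoichiometric toy (irreversible/reversible mix, one
## bounded uptake, objective on the last reaction)
random_toy_lp <- function(seed, m = 5, n = 10) {
  set.seed(seed)
  repeat {
    S <- matrix(0, m, n)
    for (j in seq_len(n)) {
      rows <- sample(m, sample(2:3, 1))
      S[rows, j] <- sample(c(-2, -1, 1, 2), length(rows), replace = TRUE)
    }
    lb <- rep(0, n); ub <- rep(100, n)
    lb[sample(n, max(1, n %/% 3))] <- -100
    lb[sample(n, 2)] <- -10
    cvec <- rep(0, n); cvec[n] <- 1
    if (any(S[, n] != 0)) break
  }
  list(S = S, b = rep(0, m), lb = lb, ub = ub, obj = cvec)
}

random_toy_model <- function(seed, m = 5, n = 10) {
  lp <- random_toy_lp(seed, m, n)
  mets <- sprintf("M%d_c", seq_len(m))
  rxns <- sprintf("R%d", seq_len(n))
  idx <- which(lp$S != 0, arr.ind = TRUE)
  cbm_model(
    id = sprintf("rand%d", seed),
    compartments = data.frame(id = "c", name = "cytosol"),
    metabolites = data.frame(id = mets, name = mets, compartment = "c",
                             formula = NA, boundary = FALSE, annotation = NA),
    reactions = data.frame(id = rxns, name = rxns, lb = lp$lb, ub = lp$ub,
                           gpr = NA, pathway = "respiration", ec = NA),
    stoich = data.frame(reaction = rxns[idx[, 2]],
                        metabolite = mets[idx[, 1]],
                        coef = lp$S[idx]),
    objective = stats::setNames(1, rxns[n]))
}

## Brute-force LP oracle: enumerate every vertex of {Ax = b, l <= x <= u}
## by fixing n-m variables at a bound and solving the square system for
## the rest. Independent of the simplex code path.
enum_lp_oracle <- function(obj, A, b, lb, ub, sense = "max") {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  best <- NULL
  free_sets <- utils::combn(n, m, simplify = FALSE)
  for (B in free_sets) {
    Fix <- setdiff(seq_len(n), B)
    AB <- A[, B, drop = FALSE]
    qrAB <- qr(AB)
    if (qrAB$rank < m) next
    nf <- length(Fix)
    for (mask in 0:(2^nf - 1)) {
      xf <- lb[Fix]
      if (nf > 0) {
        at_ub <- as.logical(bitwAnd(mask, 2^(seq_len(nf) - 1)))
        xf[at_ub] <- ub[Fix][at_ub]
      }
      rhs <- b - if (nf) A[, Fix, drop = FALSE] %*% xf else 0
      xB <- tryCatch(qr.coef(qrAB, rhs), error = function(e) NULL)
      if (is.null(xB) || anyNA(xB)) next
      if (any(xB < lb[B] - 1e-8) || any(xB > ub[B] + 1e-8)) next
      x <- numeric(n); x[B] <- xB; x[Fix] <- xf
      val <- sum(obj * x)
      if (is.null(best) ||
          (sense == "max" && val > best) ||
          (sense == "min" && val < best)) best <- val
      if (nf == 0) break
    }
  }
  best   # NULL when infeasible
}

## leaf fixture shared within a test file (built once)
.leaf_env <- new.env()
leaf_fixture <- function() {
  if (is.null(.leaf_env$model)) .leaf_env$model <- leaf_core_model()
  .leaf_env$model
}
leaf_baseline <- function() {
  if (is.null(.leaf_env$base)) .leaf_env$base <- run_baseline(leaf_fixture())
  .leaf_env$base
}

## total elemental carbon crossing the system boundary for a solution:
## exchange fluxes weighted by the carbon content of their metabolite
boundary_carbon_balance <- function(model, solution) {
  ex <- exchange_reactions(model)
  total <- 0
  for (rid in ex) {
    mid <- exchange_metabolite(model, rid)
    f <- parse_formula(model$metabolites$formula[match(mid, model$metabolites$id)])
    cC <- if ("C" %in% names(f)) as.numeric(f["C"]) else 0
    total <- total + cC * unname(solution$fluxes[[rid]])
  }
  total
}
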