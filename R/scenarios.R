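#' Declarative scenario specification
#'
#' A named set of constraint edits defining a condition: bound overrides,
#' ratio couplings and flux multipliers (lower bounds at a multiple of the
#' baseline canonical flux).
#'
#' @param name scenario name.
#' @param bound_overrides named list `reaction id -> c(lb, ub)` (`NA`
#'   keeps the current bound).
#' @param ratio_constraints list of [ratio_constraint()]s.
#' @param flux_multipliers named numeric vector; each entry `m > 0` sets
#'   the reaction's lower bound to `m` times its baseline canonical flux.
#' @param baseline name of the reference scenario (default `"baseline"`).
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, bound_overrides = list(),
                          ratio_constraints = list(),
                          flux_multipliers = numeric(),
                          baseline = "baseline") {
  if (length(flux_multipliers) && any(flux_multipliers <= 0))
    stop("flux multipliers must be positive")
  structure(list(name = name, bound_overrides = bound_overrides,
                 ratio_constraints = ratio_constraints,
                 flux_multipliers = flux_multipliers, baseline = baseline),
            class = "scenario_spec")
}

key_reactions <- function(model) {
  kr <- model$annotations$key_reactions
  if (is.null(kr))
    stop("model annotations carry no key_reactions map; see build_fixture_leaf_model()")
  kr
}

derive_quantities <- function(model, solution) {
  kr <- key_reactions(model)
  get <- function(id) if (id %in% names(solution$fluxes))
    unname(solution$fluxes[[id]]) else NA_real_
  list(growth = get(kr$growth),
       co2_uptake = -get(kr$co2_exchange),
       vc = get(kr$vc), vo = get(kr$vo),
       pepc = get(kr$pepc), pepck = get(kr$pepck),
       sucrose_export = get(kr$sucrose_export))
}

new_scenario_result <- function(model, spec, solution) {
  structure(list(spec = spec, solution = solution,
                 derived = if (identical(solution$status, "optimal"))
                   derive_quantities(model, solution) else NULL,
                 model = model),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> '%s': status %s\n", x$spec$name,
              x$solution$status))
  if (!is.null(x$derived)) {
    d <- x$derived
    cat(sprintf("  growth %.4g  CO2 uptake %.4g  Vc %.4g  Vo %.4g  PEPC %.4g  sucrose export %.4g\n",
                d$growth, d$co2_uptake, d$vc, d$vo, d$pepc, d$sucrose_export))
  }
  invisible(x)
}

#' Apply a scenario and solve it canonically
#'
#' Applies bound overrides, ratio constraints and flux multipliers (the
#' latter resolved against `baseline`), then runs FBA followed by
#' total-flux minimization.
#'
#' @param model a [cbm_model()].
#' @param spec a [scenario_spec()].
#' @param baseline a `scenario_result` supplying baseline canonical fluxes
#'   for `flux_multipliers`; required when multipliers are present.
#' @return a `scenario_result` (non-optimal solver status is carried, not
#'   raised).
#' @export
run_scenario <- function(model, spec, baseline = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  for (rid in names(spec$bound_overrides)) {
    bo <- spec$bound_overrides[[rid]]
    model <- set_bounds(model, rid, lb = bo[1], ub = bo[2])
  }
  for (rc in spec$ratio_constraints)
    model <- apply_ratio_constraint(model, rc)
  if (length(spec$flux_multipliers)) {
    if (is.null(baseline))
      stop("flux_multipliers need a baseline scenario_result")
    for (rid in names(spec$flux_multipliers)) {
      v0 <- baseline$solution$fluxes[[rid]]
      i <- match(rid, model$reactions$id)
      if (is.na(i)) stop(sprintf("no reaction '%s'", rid))
      ## a demand beyond the reaction's capacity must surface as an
      ## infeasible solve, not an error
      model$reactions$lb[i] <- spec$flux_multipliers[[rid]] * v0
    }
  }
  sol <- solve_fba(model)
  if (identical(sol$status, "optimal")) sol <- canonicalize(model, sol)
  new_scenario_result(model, spec, sol)
}

#' Baseline canonical solution as a scenario result
#'
#' The reference condition for all fold changes: the model's own bounds
#' (unrestricted CO2 uptake, pinned photon influx) with its attached Vc/Vo
#' ratio constraint, solved and canonicalized.
#'
#' @param model a [cbm_model()].
#' @return a `scenario_result` named `"baseline"`.
#' @export
run_baseline <- function(model) {
  res <- run_scenario(model, scenario_spec("baseline"))
  if (!identical(res$solution$status, "optimal"))
    stop(sprintf("baseline solve failed (status: %s)", res$solution$status))
  res
}

#' Photorespiration sweep over Vc/Vo ratios
#'
#' Re-solves the model with the RuBisCO carboxylation/oxygenation ratio
#' pinned at each requested value, with photon and maintenance constraints
#' unchanged. Fold changes of every reaction are reported relative to the
#' `baseline_ratio` solution. Infeasible points are recorded and skipped.
#'
#' @param model a [cbm_model()] with `vc`/`vo` key reactions annotated.
#' @param ratios numeric vector of positive Vc/Vo ratios.
#' @param baseline_ratio reference ratio (ambient-air value 3).
#' @param epsilon pseudo-flux for [fold_change_table()].
#' @return list with `results` (named list of `scenario_result`),
#'   `summary` (data.frame ratio/status/growth/co2_uptake/vc/vo/pepc) and
#'   `fold_changes` (long data.frame with one block per non-baseline
#'   ratio).
#' @export
run_photorespiration_sweep <- function(model, ratios = c(1, 2, 3, 4, 5),
                                       baseline_ratio = 3, epsilon = 1e-9) {
  if (any(ratios <= 0)) stop("ratios must be positive")
  kr <- key_reactions(model)
  all_r <- unique(c(baseline_ratio, ratios))
  results <- list()
  for (r in all_r) {
    sp <- scenario_spec(sprintf("vcvo_%g", r),
                        ratio_constraints = list(
                          ratio_constraint(kr$vc, kr$vo, r)))
    results[[sp$name]] <- run_scenario(model, sp)
  }
  base <- results[[sprintf("vcvo_%g", baseline_ratio)]]
  if (!identical(base$solution$status, "optimal"))
    stop("baseline ratio point is infeasible")
  summary <- do.call(rbind, lapply(all_r, function(r) {
    res <- results[[sprintf("vcvo_%g", r)]]
    ok <- identical(res$solution$status, "optimal")
    data.frame(ratio = r, status = res$solution$status,
               growth = if (ok) res$derived$growth else NA_real_,
               co2_uptake = if (ok) res$derived$co2_uptake else NA_real_,
               vc = if (ok) res$derived$vc else NA_real_,
               vo = if (ok) res$derived$vo else NA_real_,
               pepc = if (ok) res$derived$pepc else NA_real_)
  }))
  fc <- NULL
  for (r in setdiff(all_r, baseline_ratio)) {
    res <- results[[sprintf("vcvo_%g", r)]]
    if (!identical(res$solution$status, "optimal")) next
    tab <- fold_change_table(res, base, epsilon = epsilon)
    tab$ratio <- r
    fc <- rbind(fc, tab)
  }
  list(results = results, summary = summary, fold_changes = fc)
}

#' Drought as a restricted CO2 uptake rate
#'
#' Stomatal closure is modeled by pinning the atmospheric CO2 exchange at
#' `uptake_fraction` of the baseline canonical uptake; internally produced
#' CO2 remains free to be refixed (the mechanism under study). The photon
#' influx stays at its baseline pin, so surplus absorbed light must be
#' rerouted through the metabolic network.
#'
#' @param model a [cbm_model()].
#' @param uptake_fraction value in `[0, 1]`.
#' @param baseline optional precomputed [run_baseline()] result.
#' @return a `scenario_result`.
#' @export
run_drought <- function(model, uptake_fraction, baseline = NULL) {
  if (uptake_fraction < 0 || uptake_fraction > 1)
    stop("uptake_fraction must lie in [0, 1]")
  if (is.null(baseline)) baseline <- run_baseline(model)
  kr <- key_reactions(model)
  u <- uptake_fraction * baseline$derived$co2_uptake
  sp <- scenario_spec(sprintf("drought_%g", uptake_fraction),
                      bound_overrides = stats::setNames(
                        list(c(-u, -u)), kr$co2_exchange),
                      baseline = "baseline")
  run_scenario(model, sp, baseline = baseline)
}

#' Elevated PEP carboxylase activity
#'
#' Forces the PEPC flux to at least `factor` times its baseline canonical
#' value (a lower bound, not an equality, so the program stays feasible
#' while guaranteeing the stated activity). The CO2 exchange is pinned at
#' the baseline uptake: carbon supply is unchanged while PEPC is
#' perturbed, so carbon that energy-starved biomass synthesis cannot use
#' is redirected to sucrose export.
#'
#' @param model a [cbm_model()].
#' @param factor multiple of the baseline PEPC flux (default 10).
#' @param baseline optional precomputed [run_baseline()] result.
#' @return a `scenario_result`; infeasibility is surfaced in
#'   `$solution$status`, not masked.
#' @export
run_pepc_elevation <- function(model, factor = 10, baseline = NULL) {
  if (factor <= 0) stop("factor must be positive")
  if (is.null(baseline)) baseline <- run_baseline(model)
  kr <- key_reactions(model)
  u <- baseline$derived$co2_uptake
  sp <- scenario_spec(sprintf("pepc_x%g", factor),
                      bound_overrides = stats::setNames(
                        list(c(-u, -u)), kr$co2_exchange),
                      flux_multipliers = stats::setNames(factor, kr$pepc),
                      baseline = "baseline")
  run_scenario(model, sp, baseline = baseline)
}

#' Per-reaction log2 flux fold changes between two scenario solutions
#'
#' `log2((|v| + eps) / (|v0| + eps))` for every reaction, with a
#' categorical direction: `"inactive-both"` when both fluxes are
#' essentially zero, `"unchanged"` within `+/- band` log2 units, else
#' `"up"`/`"down"`.
#'
#' @param result,baseline `scenario_result`s computed on the same model.
#' @param epsilon pseudo-flux guarding zero baselines (default `1e-9`).
#' @param band no-change half-width in log2 units (default 0.1).
#' @param active_tol absolute flux below which a reaction counts inactive.
#' @return data.frame with columns `reaction`, `pathway`, `flux`,
#'   `baseline_flux`, `log2fc`, `direction`.
#' @export
fold_change_table <- function(result, baseline, epsilon = 1e-9, band = 0.1,
                              active_tol = 1e-9) {
  if (!identical(result$solution$model_id, baseline$solution$model_id))
    stop("fold changes need solutions of the same model")
  v <- result$solution$fluxes
  v0 <- baseline$solution$fluxes
  stopifnot(identical(names(v), names(v0)))
  l2 <- log2((abs(v) + epsilon) / (abs(v0) + epsilon))
  direction <- ifelse(abs(v) <= active_tol & abs(v0) <= active_tol,
                      "inactive-both",
                      ifelse(l2 > band, "up",
                             ifelse(l2 < -band, "down", "unchanged")))
  mdl <- result$model
  data.frame(reaction = names(v),
             pathway = mdl$reactions$pathway[match(names(v), mdl$reactions$id)],
             flux = as.numeric(v), baseline_flux = as.numeric(v0),
             log2fc = as.numeric(l2), direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}
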