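#' Linear objective specification
#'
#' @param coefficients named numeric vector, reaction id -> coefficient.
#' @param sense `"maximize"` or `"minimize"`.
#' @return object of class `objective_spec`.
#' @export
objective_spec <- function(coefficients, sense = c("maximize", "minimize")) {
  sense <- match.arg(sense)
  if (!length(coefficients) || is.null(names(coefficients)))
    stop("objective needs a non-empty named coefficient vector")
  structure(list(coefficients = coefficients, sense = sense),
            class = "objective_spec")
}

#' Flux-ratio coupling constraint
#'
#' Encodes the linear equality `v_num - ratio * v_den = 0`, used to pin the
#' RuBisCO carboxylation/oxygenation ratio (Vc/Vo). Both reactions must be
#' irreversible (non-negative flux) so the ratio is well defined; reversible
#' operands are rejected rather than silently split.
#'
#' @param numerator_reaction reaction id of the numerator flux (Vc).
#' @param denominator_reaction reaction id of the denominator flux (Vo).
#' @param ratio positive real `r` in `v_num = r * v_den`.
#' @return object of class `ratio_constraint`.
#' @export
ratio_constraint <- function(numerator_reaction, denominator_reaction, ratio) {
  if (!(is.numeric(ratio) && length(ratio) == 1 && ratio > 0))
    stop("ratio must be a positive number")
  structure(list(numerator_reaction = numerator_reaction,
                 denominator_reaction = denominator_reaction,
                 ratio = ratio), class = "ratio_constraint")
}

check_ratio_constraint <- function(model, rc) {
  for (rid in c(rc$numerator_reaction, rc$denominator_reaction)) {
    i <- match(rid, model$reactions$id)
    if (is.na(i)) stop(sprintf("ratio constraint references unknown reaction '%s'", rid))
    if (model$reactions$lb[i] < 0)
      stop(sprintf("ratio constraint operand '%s' is reversible; ratios are only defined between irreversible reactions", rid))
  }
  invisible(rc)
}

#' Attach a ratio constraint to a model
#'
#' Returns a constrained model handle: every subsequent [solve_fba()],
#' [canonicalize()] or [flux_variability()] call on it honours the
#' equality `v_num = r * v_den` (to solver tolerance).
#'
#' @param model a [cbm_model()].
#' @param rc a [ratio_constraint()].
#' @return the model with the constraint attached.
#' @export
apply_ratio_constraint <- function(model, rc) {
  stopifnot(inherits(rc, "ratio_constraint"))
  check_ratio_constraint(model, rc)
  ## replace an existing constraint on the same reaction pair
  keep <- vapply(model$ratio_constraints, function(x)
    !(identical(x$numerator_reaction, rc$numerator_reaction) &&
        identical(x$denominator_reaction, rc$denominator_reaction)), logical(1))
  model$ratio_constraints <- c(model$ratio_constraints[keep], list(rc))
  model
}

#' Constrain photon influx from a measured photosynthetic rate
#'
#' The photon uptake is `net_photosynthesis / lue` where `lue` is the
#' light-use efficiency (mol CO2 fixed per mol photons absorbed). With
#' `pin = TRUE` (default) the influx is fixed rather than capped: absorbed
#' photons drive electron transport and the network must route the energy,
#' which is the premise of the drought scenarios.
#'
#' @param model a [cbm_model()].
#' @param net_photosynthesis net CO2 assimilation rate (mmol/gDW/day, >= 0).
#' @param lue light-use efficiency, > 0.
#' @param rxn photon exchange reaction id; default: the exchange whose
#'   metabolite carries the `"photon"` annotation tag.
#' @param pin fix the influx (lb = ub) instead of capping it.
#' @return the modified model.
#' @export
set_photon_constraint <- function(model, net_photosynthesis, lue, rxn = NULL,
                                  pin = TRUE) {
  if (!(lue > 0)) stop("lue must be positive")
  if (net_photosynthesis < 0) stop("net_photosynthesis must be non-negative")
  if (is.null(rxn)) rxn <- find_exchange_by_tag(model, "photon")
  set_uptake_bound(model, rxn, net_photosynthesis / lue, pin = pin)
}

#' Find the exchange reaction of an annotated species
#' @param model a [cbm_model()].
#' @param tag metabolite annotation tag (e.g. `"photon"`, `"co2"`).
#' @return exchange reaction id.
#' @export
find_exchange_by_tag <- function(model, tag) {
  mets <- annotated_metabolites(model, tag)
  ex <- exchange_reactions(model)
  hit <- ex[vapply(ex, function(r) exchange_metabolite(model, r) %in% mets,
                   logical(1))]
  if (!length(hit))
    stop(sprintf("model has no exchange reaction for a metabolite tagged '%s'", tag))
  hit[1]
}

## Build the LP rows for a model: S rows (internal metabolites) plus one
## equality row per ratio constraint.
fba_matrices <- function(model, extra_constraints = list()) {
  S <- stoichiometric_matrix(model)
  rcs <- c(model$ratio_constraints, extra_constraints)
  for (rc in rcs) {
    check_ratio_constraint(model, rc)
    row <- stats::setNames(rep(0, ncol(S)), colnames(S))
    row[rc$numerator_reaction] <- 1
    row[rc$denominator_reaction] <- -rc$ratio
    S <- rbind(S, row)
    rownames(S)[nrow(S)] <- sprintf("ratio_%s_%s", rc$numerator_reaction,
                                    rc$denominator_reaction)
  }
  list(A = S, b = rep(0, nrow(S)),
       lb = model$reactions$lb, ub = model$reactions$ub)
}

resolve_objective <- function(model, objective) {
  if (is.null(objective)) {
    if (!length(model$objective)) stop("model has no objective and none was supplied")
    objective <- objective_spec(model$objective, "maximize")
  }
  if (!inherits(objective, "objective_spec"))
    objective <- objective_spec(objective, "maximize")
  bad <- setdiff(names(objective$coefficients), model$reactions$id)
  if (length(bad))
    stop(sprintf("objective references unknown reaction(s): %s",
                 paste(bad, collapse = ", ")))
  objective
}

new_flux_solution <- function(model, x, objval, status, canonicalized = FALSE) {
  fluxes <- if (is.null(x)) NULL else stats::setNames(x, model$reactions$id)
  structure(list(fluxes = fluxes, objective_value = objval, status = status,
                 canonicalized = canonicalized, model_id = model$id),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> model %s: status %s", x$model_id, x$status))
  if (identical(x$status, "optimal"))
    cat(sprintf(", Z = %.6g%s", x$objective_value,
                if (x$canonicalized) " (canonical)" else ""))
  cat("\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Solves `max c.v` subject to steady state `S.v = 0`, flux bounds, and
#' any ratio-coupling equalities attached to the model or passed in
#' `extra_constraints`. Solver status is reported faithfully; optimal
#' solutions satisfy `|S.v| <= 1e-6` and the bounds to 1e-9.
#'
#' @param model a [cbm_model()].
#' @param objective an [objective_spec()], a named coefficient vector, or
#'   `NULL` to use the model's own objective (maximized).
#' @param extra_constraints list of [ratio_constraint()]s applied for this
#'   solve only.
#' @return a `flux_solution` with `fluxes`, `objective_value`, `status`.
#' @export
solve_fba <- function(model, objective = NULL, extra_constraints = list()) {
  objective <- resolve_objective(model, objective)
  mats <- fba_matrices(model, extra_constraints)
  cvec <- stats::setNames(rep(0, nrow(model$reactions)), model$reactions$id)
  cvec[names(objective$coefficients)] <- objective$coefficients
  sense <- if (objective$sense == "maximize") "max" else "min"
  res <- lp_solve_bounded(as.numeric(cvec), mats$A, mats$b, mats$lb, mats$ub,
                          sense = sense)
  if (res$status != "optimal")
    return(new_flux_solution(model, NULL, NULL, res$status))
  resid <- max(abs(mats$A %*% res$x - mats$b))
  if (resid > 1e-6)
    stop(sprintf("steady-state residual %.3g exceeds 1e-6", resid))
  new_flux_solution(model, res$x, res$objval, "optimal")
}

#' Canonical (minimum total flux) solution
#'
#' FBA optima are generically non-unique; reported per-reaction fluxes are
#' therefore taken from the flux vector minimizing the total absolute flux
#' `sum |v_j|` subject to the original constraints with the objective
#' pinned at its optimum (parsimonious FBA). Implemented by splitting each
#' flux into irreversible forward/backward parts.
#'
#' @param model the [cbm_model()] that produced `solution`.
#' @param solution an optimal `flux_solution` from [solve_fba()].
#' @param objective same objective used for `solution` (default: model's).
#' @param extra_constraints same extra constraints used for `solution`.
#' @return a `flux_solution` with `canonicalized = TRUE`; the objective
#'   value is preserved to 1e-9 relative.
#' @export
canonicalize <- function(model, solution, objective = NULL,
                         extra_constraints = list()) {
  if (!identical(solution$status, "optimal"))
    stop("canonicalize() needs an optimal solution")
  objective <- resolve_objective(model, objective)
  mats <- fba_matrices(model, extra_constraints)
  n <- ncol(mats$A)
  cvec <- stats::setNames(rep(0, n), colnames(mats$A))
  cvec[names(objective$coefficients)] <- objective$coefficients
  zstar <- solution$objective_value

  lb <- mats$lb; ub <- mats$ub
  p_lb <- pmax(lb, 0); p_ub <- pmax(ub, 0)
  q_lb <- pmax(-ub, 0); q_ub <- pmax(-lb, 0)
  A2 <- cbind(mats$A, -mats$A)
  A2 <- rbind(A2, c(as.numeric(cvec), -as.numeric(cvec)))
  b2 <- c(mats$b, zstar)
  obj2 <- rep(-1, 2 * n)   # maximize -(sum p + sum q)
  res <- lp_solve_bounded(obj2, A2, b2, c(p_lb, q_lb), c(p_ub, q_ub), "max")
  if (res$status != "optimal")
    stop(sprintf("canonicalization failed (solver status: %s)", res$status))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  z <- sum(cvec * v)
  if (abs(z - zstar) > 1e-9 * max(1, abs(zstar)))
    stop("canonicalization moved the objective value")
  new_flux_solution(model, v, z, "optimal", canonicalized = TRUE)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux with the objective constrained to
#' at least `fraction_of_optimum` of its optimal value.
#'
#' @param model a [cbm_model()].
#' @param objective as in [solve_fba()].
#' @param fraction_of_optimum value in (0, 1].
#' @param reactions reaction ids to scan (default: all).
#' @param extra_constraints list of [ratio_constraint()]s.
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, objective = NULL, fraction_of_optimum = 1.0,
                             reactions = NULL, extra_constraints = list()) {
  if (!(fraction_of_optimum > 0 && fraction_of_optimum <= 1))
    stop("fraction_of_optimum must lie in (0, 1]")
  objective <- resolve_objective(model, objective)
  base <- solve_fba(model, objective, extra_constraints)
  if (base$status != "optimal")
    stop(sprintf("base problem not optimal (status: %s)", base$status))
  mats <- fba_matrices(model, extra_constraints)
  n <- ncol(mats$A)
  cvec <- stats::setNames(rep(0, n), colnames(mats$A))
  cvec[names(objective$coefficients)] <- objective$coefficients
  ## c.v - s = f * Z*, s >= 0  (for a maximized objective)
  sgn <- if (objective$sense == "maximize") 1 else -1
  A2 <- rbind(cbind(mats$A, 0), c(sgn * as.numeric(cvec), -1))
  b2 <- c(mats$b, sgn * fraction_of_optimum * base$objective_value)
  lb2 <- c(mats$lb, 0); ub2 <- c(mats$ub, Inf)
  if (is.null(reactions)) reactions <- model$reactions$id
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_)
  for (k in seq_along(reactions)) {
    j <- match(reactions[k], model$reactions$id)
    cj <- rep(0, n + 1); cj[j] <- 1
    for (dir in c("min", "max")) {
      r <- lp_solve_bounded(cj, A2, b2, lb2, ub2, dir)
      if (r$status != "optimal")
        stop(sprintf("flux variability infeasible at fraction %g (reaction %s)",
                     fraction_of_optimum, reactions[k]))
      out[[dir]][k] <- r$objval
    }
  }
  out
}
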