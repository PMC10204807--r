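## Structural validation and gap detection.

#' Parse an elemental formula
#'
#' Supports multi-letter elements and fractional counts (`"C3.5N0.25"`),
#' which occur in lumped biomass precursors.
#'
#' @param formula formula string, e.g. `"C6H12O6"`.
#' @return named numeric vector of element counts.
#' @keywords internal
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(numeric())
  toks <- regmatches(formula,
                     gregexpr("[A-Z][a-z]?[0-9]*\\.?[0-9]*", formula))[[1]]
  els <- sub("^([A-Z][a-z]?).*$", "\\1", toks)
  cnt <- sub("^[A-Z][a-z]?", "", toks)
  cnt <- ifelse(nzchar(cnt), as.numeric(cnt), 1)
  tapply(cnt, els, sum)
}

#' Per-element balance of every internal reaction
#'
#' Only the elements C, N, P and S are audited: the models track carbon,
#' nitrogen, phosphorus and sulfur skeletons, while protons, water-bound
#' oxygen and charge are deliberately untracked (standard practice for
#' lumped central-metabolism reconstructions). Exchange reactions are
#' skipped (they cross the system boundary by design), as are reactions
#' with any participant lacking a formula.
#'
#' @param model a [cbm_model()].
#' @param elements elements to audit.
#' @return data.frame reaction/element/imbalance for non-zero imbalances.
#' @export
element_balance <- function(model, elements = c("C", "N", "P", "S")) {
  ex <- exchange_reactions(model)
  met <- model$metabolites
  formulas <- lapply(stats::setNames(met$formula, met$id), parse_formula)
  out <- NULL
  for (rid in setdiff(model$reactions$id, ex)) {
    st <- model$stoich[model$stoich$reaction == rid, ]
    fs <- formulas[st$metabolite]
    if (any(vapply(fs, function(f) length(f) == 0, logical(1)))) next
    for (el in elements) {
      bal <- sum(st$coef * vapply(fs, function(f) {
        v <- f[el]; if (is.na(v)) 0 else as.numeric(v)
      }, numeric(1)))
      if (abs(bal) > 1e-6)
        out <- rbind(out, data.frame(reaction = rid, element = el,
                                     imbalance = bal))
    }
  }
  if (is.null(out)) data.frame(reaction = character(), element = character(),
                               imbalance = numeric())
  else out
}

#' Validate model invariants
#'
#' Returns a diagnostics table rather than raising: an empty table means
#' every invariant holds. Checked: id uniqueness, compartment references,
#' bound ordering, non-empty stoichiometry, dangling metabolite and
#' objective references, and (when formulas are present) per-reaction
#' elemental balance for internal reactions.
#'
#' @param model a [cbm_model()].
#' @return data.frame with columns `entity`, `rule`, `message`, `severity`
#'   (`"error"` for structural violations, `"warn"` for advisories).
#' @export
validate_model <- function(model) {
  d <- list()
  add <- function(entity, rule, message, severity = "error")
    d[[length(d) + 1]] <<- data.frame(entity = entity, rule = rule,
                                      message = message, severity = severity)

  dup <- unique(model$metabolites$id[duplicated(model$metabolites$id)])
  for (id in dup) add(id, "unique_metabolite_id", "duplicated metabolite id")
  dup <- unique(model$reactions$id[duplicated(model$reactions$id)])
  for (id in dup) add(id, "unique_reaction_id", "duplicated reaction id")

  badc <- !model$metabolites$compartment %in% model$compartments$id
  for (id in model$metabolites$id[badc])
    add(id, "compartment_exists", sprintf(
      "metabolite assigned to unknown compartment '%s'",
      model$metabolites$compartment[match(id, model$metabolites$id)]))

  badb <- model$reactions$lb > model$reactions$ub
  for (id in model$reactions$id[badb])
    add(id, "bound_order", "lower bound exceeds upper bound")

  no_st <- setdiff(model$reactions$id, unique(model$stoich$reaction))
  for (id in no_st) add(id, "nonempty_stoichiometry", "reaction has no stoichiometry")

  dangling <- setdiff(unique(model$stoich$metabolite), model$metabolites$id)
  for (id in dangling) add(id, "metabolite_exists", "stoichiometry references unknown metabolite")
  dangling_r <- setdiff(unique(model$stoich$reaction), model$reactions$id)
  for (id in dangling_r) add(id, "reaction_exists", "stoichiometry references unknown reaction")

  bado <- setdiff(names(model$objective), model$reactions$id)
  for (id in bado) add(id, "objective_reaction_exists", "objective references unknown reaction")

  eb <- element_balance(model)
  for (i in seq_len(nrow(eb)))
    add(eb$reaction[i], "element_balance",
        sprintf("element %s imbalanced by %g", eb$element[i], eb$imbalance[i]))

  if (!length(d))
    return(data.frame(entity = character(), rule = character(),
                      message = character(), severity = character()))
  do.call(rbind, d)
}

#' Emit validation diagnostics as JSON lines
#' @param diagnostics output of [validate_model()].
#' @param con connection or file path (default stdout).
#' @return invisibly, the JSON lines.
#' @export
diagnostics_jsonl <- function(diagnostics, con = stdout()) {
  lines <- vapply(seq_len(nrow(diagnostics)), function(i)
    jsonlite::toJSON(as.list(diagnostics[i, ]), auto_unbox = TRUE), character(1))
  if (length(lines)) writeLines(lines, con)
  invisible(lines)
}

#' Detect network gaps
#'
#' Dead-end metabolites are internal species with no producing or no
#' consuming reaction under the directionality allowed by the bounds.
#' Blocked reactions carry zero flux in every feasible steady state with
#' all exchange bounds opened to the default span; they are found by flux
#' variability (independent min/max LP per reaction). Detection only:
#' filling gaps is left to manual curation.
#'
#' @param model a validated [cbm_model()].
#' @param open_span bound span used to open every exchange.
#' @param tol flux threshold below which a reaction counts as blocked.
#' @return list with `dead_end_metabolites` and `blocked_reactions`.
#' @export
find_gaps <- function(model, open_span = 1000, tol = 1e-7) {
  mets <- model$metabolites$id[!model$metabolites$boundary]
  rx <- model$reactions
  st <- model$stoich
  dead <- character()
  for (mid in mets) {
    s <- st[st$metabolite == mid, ]
    k <- match(s$reaction, rx$id)
    producer <- any((s$coef > 0 & rx$ub[k] > tol) | (s$coef < 0 & rx$lb[k] < -tol))
    consumer <- any((s$coef < 0 & rx$ub[k] > tol) | (s$coef > 0 & rx$lb[k] < -tol))
    if (!producer || !consumer) dead <- c(dead, mid)
  }

  open <- model
  for (ex in exchange_reactions(open)) {
    i <- match(ex, open$reactions$id)
    open$reactions$lb[i] <- -open_span
    open$reactions$ub[i] <- open_span
  }
  S <- stoichiometric_matrix(open)
  lb <- open$reactions$lb; ub <- open$reactions$ub
  n <- ncol(S)
  feas <- lp_solve_bounded(rep(0, n), S, rep(0, nrow(S)), lb, ub)
  if (feas$status != "optimal")
    stop(sprintf("base model infeasible during gap search (solver status: %s)",
                 feas$status))
  blocked <- character()
  for (j in seq_len(n)) {
    cj <- rep(0, n); cj[j] <- 1
    vmax <- lp_solve_bounded(cj, S, rep(0, nrow(S)), lb, ub, "max")
    if (vmax$status == "optimal" && abs(vmax$objval) > tol) next
    vmin <- lp_solve_bounded(cj, S, rep(0, nrow(S)), lb, ub, "min")
    if (vmin$status == "optimal" && abs(vmin$objval) > tol) next
    blocked <- c(blocked, colnames(S)[j])
  }
  list(dead_end_metabolites = dead, blocked_reactions = blocked)
}
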