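#' Construct a compartmentalized stoichiometric model
#'
#' A `cbm_model` bundles compartments, metabolites, reactions, sparse
#' stoichiometry and a linear objective. Reactions follow the SBML-FBC
#' community sign convention: consumed metabolites carry negative
#' coefficients, and exchange reactions are written export-positive, so
#' uptake is the negative flux region of the exchange (see
#' [set_uptake_bound()]).
#'
#' @param id model identifier.
#' @param compartments data.frame with columns `id`, `name`.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula` (elemental formula, may be `NA`), `boundary` (logical flag
#'   for external/boundary species) and `annotation` (comma-separated tags
#'   such as `"co2"`, `"atp"`; used by the analysis layer to find currency
#'   and gas species without name matching).
#' @param reactions data.frame with columns `id`, `name`, `lb`, `ub`
#'   (mmol/gDW/day), `gpr` (boolean gene association, may be `""`),
#'   `pathway` and `ec`.
#' @param stoich data.frame with columns `reaction`, `metabolite`, `coef`.
#' @param objective named numeric vector of objective coefficients keyed by
#'   reaction id.
#' @param annotations free-form metadata list.
#' @return object of class `cbm_model`.
#' @export
cbm_model <- function(id, compartments, metabolites, reactions, stoich,
                      objective = numeric(), annotations = list()) {
  metabolites$boundary <- as.logical(metabolites$boundary)
  for (col in c("formula", "annotation"))
    if (is.null(metabolites[[col]])) metabolites[[col]] <- NA_character_
  for (col in c("gpr", "pathway", "ec"))
    if (is.null(reactions[[col]])) reactions[[col]] <- NA_character_
  reactions$lb <- as.numeric(reactions$lb)
  reactions$ub <- as.numeric(reactions$ub)
  stoich$coef <- as.numeric(stoich$coef)
  m <- structure(list(
    id = id,
    compartments = as.data.frame(compartments, stringsAsFactors = FALSE),
    metabolites = as.data.frame(metabolites, stringsAsFactors = FALSE),
    reactions = as.data.frame(reactions, stringsAsFactors = FALSE),
    stoich = as.data.frame(stoich, stringsAsFactors = FALSE),
    objective = objective,
    annotations = annotations
  ), class = "cbm_model")
  m
}

#' @export
print.cbm_model <- function(x, ...) {
  cat(sprintf("<cbm_model> %s\n", x$id))
  cat(sprintf("  %d compartments, %d metabolites (%d boundary), %d reactions\n",
              nrow(x$compartments), nrow(x$metabolites),
              sum(x$metabolites$boundary), nrow(x$reactions)))
  if (length(x$objective))
    cat("  objective:", paste(sprintf("%g*%s", x$objective, names(x$objective)),
                              collapse = " + "), "\n")
  invisible(x)
}

#' Dense stoichiometric matrix
#'
#' One row per internal (non-boundary) metabolite, one column per reaction.
#' Boundary species are dropped: they are not subject to steady state.
#'
#' @param model a [cbm_model()].
#' @return numeric matrix with dimnames (metabolite ids x reaction ids).
#' @export
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id[!model$metabolites$boundary]
  rxns <- model$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  st <- model$stoich[model$stoich$metabolite %in% mets, ]
  S[cbind(match(st$metabolite, mets), match(st$reaction, rxns))] <- st$coef
  S
}

#' Reaction ids of exchange reactions
#'
#' An exchange reaction touches exactly one internal metabolite (boundary
#' species, if written out, do not count). Written export-positive: a
#' positive flux expels the metabolite from the system.
#'
#' @param model a [cbm_model()].
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  internal <- model$metabolites$id[!model$metabolites$boundary]
  st <- model$stoich[model$stoich$metabolite %in% internal, ]
  tab <- table(st$reaction)
  ids <- names(tab)[tab == 1]
  model$reactions$id[model$reactions$id %in% ids]
}

#' Look up the single internal metabolite of an exchange reaction
#' @param model a [cbm_model()].
#' @param rxn exchange reaction id.
#' @return metabolite id.
#' @export
exchange_metabolite <- function(model, rxn) {
  internal <- model$metabolites$id[!model$metabolites$boundary]
  st <- model$stoich[model$stoich$reaction == rxn &
                       model$stoich$metabolite %in% internal, ]
  if (nrow(st) != 1)
    stop(sprintf("'%s' is not an exchange reaction", rxn))
  st$metabolite
}

#' Set the uptake bound of an exchange reaction
#'
#' Exchanges are export-positive, so a maximum uptake rate `u` corresponds
#' to lower bound `-u`. With `pin = TRUE` both bounds are set to `-u`,
#' forcing the influx (used for the photon exchange, where absorbed light
#' must be processed by the network).
#'
#' @param model a [cbm_model()].
#' @param rxn exchange reaction id.
#' @param max_uptake maximum uptake rate (non-negative, mmol/gDW/day).
#' @param pin force influx exactly at `max_uptake`.
#' @return the modified model.
#' @export
set_uptake_bound <- function(model, rxn, max_uptake, pin = FALSE) {
  if (!rxn %in% model$reactions$id) stop(sprintf("no reaction '%s'", rxn))
  if (max_uptake < 0) stop("max_uptake must be non-negative")
  i <- match(rxn, model$reactions$id)
  model$reactions$lb[i] <- -max_uptake
  if (pin) model$reactions$ub[i] <- -max_uptake
  model
}

#' Set reaction flux bounds
#' @param model a [cbm_model()].
#' @param rxn reaction id.
#' @param lb,ub new bounds; `NA` keeps the current value.
#' @return the modified model.
#' @export
set_bounds <- function(model, rxn, lb = NA, ub = NA) {
  i <- match(rxn, model$reactions$id)
  if (is.na(i)) stop(sprintf("no reaction '%s'", rxn))
  if (!is.na(lb)) model$reactions$lb[i] <- lb
  if (!is.na(ub)) model$reactions$ub[i] <- ub
  if (model$reactions$lb[i] > model$reactions$ub[i])
    stop(sprintf("reaction '%s': lower bound exceeds upper bound", rxn))
  model
}

#' Metabolite ids carrying a given annotation tag
#' @param model a [cbm_model()].
#' @param tag annotation tag, e.g. `"co2"`, `"atp"`, `"nadh"`.
#' @param compartment optional compartment filter.
#' @return character vector of metabolite ids.
#' @export
annotated_metabolites <- function(model, tag, compartment = NULL) {
  met <- model$metabolites
  hit <- vapply(strsplit(ifelse(is.na(met$annotation), "", met$annotation), ","),
                function(tags) tag %in% trimws(tags), logical(1))
  if (!is.null(compartment)) hit <- hit & met$compartment %in% compartment
  met$id[hit]
}
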