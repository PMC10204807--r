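#' Flux-sum turnover of a metabolite
#'
#' The flux-sum of metabolite `i` is half the sum of absolute
#' stoichiometry-weighted fluxes through it,
#' `0.5 * sum_j |S_ij v_j|` -- a turnover-rate proxy for the pool. At
#' steady state the producing half equals the consuming half, so the
#' producer and consumer breakdowns each sum to the flux-sum.
#'
#' @param model a [cbm_model()].
#' @param solution an optimal (preferably canonicalized) `flux_solution`.
#' @param metabolite metabolite id.
#' @param tol contribution threshold below which terms are dropped from
#'   the breakdowns (the value itself is exact).
#' @return object of class `flux_sum_result`: `metabolite`, `value`,
#'   `producer_breakdown`, `consumer_breakdown` (named numeric, positive).
#' @export
flux_sum <- function(model, solution, metabolite, tol = 1e-12) {
  if (!metabolite %in% model$metabolites$id)
    stop(sprintf("unknown metabolite '%s'", metabolite))
  if (!identical(solution$status, "optimal"))
    stop("flux_sum needs an optimal solution")
  st <- model$stoich[model$stoich$metabolite == metabolite, ]
  contrib <- st$coef * as.numeric(solution$fluxes[st$reaction])
  names(contrib) <- st$reaction
  producers <- contrib[contrib > tol]
  consumers <- -contrib[contrib < -tol]
  structure(list(metabolite = metabolite,
                 value = 0.5 * sum(abs(contrib)),
                 producer_breakdown = producers,
                 consumer_breakdown = consumers),
            class = "flux_sum_result")
}

#' @export
print.flux_sum_result <- function(x, ...) {
  cat(sprintf("<flux_sum> %s: %.6g (in %d, out %d reactions)\n",
              x$metabolite, x$value, length(x$producer_breakdown),
              length(x$consumer_breakdown)))
  invisible(x)
}

#' Flux-sums for many metabolites at once
#' @param model a [cbm_model()].
#' @param solution optimal `flux_solution`.
#' @param metabolites metabolite ids; default all internal species.
#' @return data.frame `metabolite`, `compartment`, `flux_sum`.
#' @export
flux_sum_all <- function(model, solution, metabolites = NULL) {
  if (is.null(metabolites))
    metabolites <- model$metabolites$id[!model$metabolites$boundary]
  vals <- vapply(metabolites, function(mid)
    flux_sum(model, solution, mid)$value, numeric(1))
  data.frame(metabolite = metabolites,
             compartment = model$metabolites$compartment[
               match(metabolites, model$metabolites$id)],
             flux_sum = as.numeric(vals), row.names = NULL)
}

#' Attribute CO2 production to pathways
#'
#' Collects the producer breakdowns of every intracellular CO2 species
#' (annotation tag `"co2"`, external compartment excluded), groups the
#' metabolic producers by pathway tag (transports and exchanges only move
#' CO2 between pools and are not producers of the combined pool), and
#' normalizes to fractions. Also reports the total CO2 flux-sum -- the
#' "intracellular CO2 pool" turnover -- and its per-species values.
#'
#' @param model a [cbm_model()] whose CO2 species carry the `"co2"` tag.
#' @param solution optimal `flux_solution`.
#' @param exclude_compartments compartments whose CO2 species are outside
#'   the pool (default the external space `"e"`).
#' @return list with `table` (pathway, production, fraction),
#'   `by_reaction` (reaction, pathway, production), `total_flux_sum`,
#'   `per_species` (data.frame).
#' @export
co2_source_attribution <- function(model, solution,
                                   exclude_compartments = "e") {
  species <- annotated_metabolites(model, "co2")
  species <- species[!model$metabolites$compartment[
    match(species, model$metabolites$id)] %in% exclude_compartments]
  if (!length(species))
    stop("no metabolite carries the 'co2' annotation tag")
  internal_moves <- c("transport", "exchange")
  prod_rxn <- list()
  per_species <- data.frame(metabolite = species, flux_sum = NA_real_)
  for (k in seq_along(species)) {
    fs <- flux_sum(model, solution, species[k])
    per_species$flux_sum[k] <- fs$value
    for (rid in names(fs$producer_breakdown)) {
      pw <- model$reactions$pathway[match(rid, model$reactions$id)]
      if (pw %in% internal_moves) next
      prod_rxn[[rid]] <- (if (is.null(prod_rxn[[rid]])) 0 else prod_rxn[[rid]]) +
        fs$producer_breakdown[[rid]]
    }
  }
  by_reaction <- data.frame(
    reaction = names(prod_rxn),
    pathway = model$reactions$pathway[match(names(prod_rxn),
                                            model$reactions$id)],
    production = as.numeric(unlist(prod_rxn)), row.names = NULL)
  tab <- stats::aggregate(production ~ pathway, by_reaction, sum)
  tab$fraction <- tab$production / sum(tab$production)
  list(table = tab[order(-tab$production), ],
       by_reaction = by_reaction[order(-by_reaction$production), ],
       total_flux_sum = sum(per_species$flux_sum),
       per_species = per_species)
}

#' Energy and redox turnover report
#'
#' Per-compartment flux-sums of the currency metabolites (found by
#' annotation tag, not name matching) plus the named shuttle fluxes
#' (ATP/ADP translocators, malate/oxaloacetate shuttles) recorded in the
#' model annotations, each with fold changes against a baseline solution
#' when one is given.
#'
#' @param model a [cbm_model()] with currency tags and (optionally) a
#'   `shuttles` annotation (named list reaction ids; positive flux is the
#'   shuttle's canonical export direction).
#' @param solution optimal `flux_solution`.
#' @param currencies annotation tags to report.
#' @param by_compartment split flux-sums per compartment (default) or
#'   aggregate over all compartments.
#' @param baseline optional baseline `flux_solution` for fold changes.
#' @return list with `turnover` (currency, compartment, flux_sum,
#'   baseline_flux_sum, fold_change) and `shuttles` (name, reaction, flux,
#'   baseline_flux, fold_change).
#' @export
energy_turnover_report <- function(model, solution,
                                   currencies = c("atp", "nadh", "nadph"),
                                   by_compartment = TRUE, baseline = NULL) {
  rows <- NULL
  for (cur in currencies) {
    mets <- annotated_metabolites(model, cur)
    if (!length(mets))
      stop(sprintf("no metabolite carries the '%s' annotation tag", cur))
    comps <- if (by_compartment)
      unique(model$metabolites$compartment[match(mets, model$metabolites$id)])
    else "all"
    for (cp in comps) {
      ms <- if (identical(cp, "all")) mets else
        mets[model$metabolites$compartment[match(mets, model$metabolites$id)] == cp]
      val <- sum(vapply(ms, function(mid)
        flux_sum(model, solution, mid)$value, numeric(1)))
      bval <- if (is.null(baseline)) NA_real_ else
        sum(vapply(ms, function(mid)
          flux_sum(model, baseline, mid)$value, numeric(1)))
      rows <- rbind(rows, data.frame(currency = cur, compartment = cp,
                                     flux_sum = val,
                                     baseline_flux_sum = bval,
                                     fold_change = val / bval))
    }
  }
  sh <- model$annotations$shuttles
  shuttles <- NULL
  for (nm in names(sh)) {
    rid <- sh[[nm]]
    v <- unname(solution$fluxes[[rid]])
    b <- if (is.null(baseline)) NA_real_ else unname(baseline$fluxes[[rid]])
    shuttles <- rbind(shuttles, data.frame(
      name = nm, reaction = rid, flux = v, baseline_flux = b,
      fold_change = v / b))
  }
  list(turnover = rows, shuttles = shuttles)
}

#' Genes referenced by a boolean gene-protein-reaction rule
#' @param gpr GPR string (`"g1 and (g2 or g3)"`); `NA` gives `character(0)`.
#' @return character vector of gene ids.
#' @export
gpr_genes <- function(gpr) {
  if (is.na(gpr) || !nzchar(gpr)) return(character())
  toks <- regmatches(gpr, gregexpr("[A-Za-z0-9_.]+", gpr))[[1]]
  unique(setdiff(toks, c("and", "or", "AND", "OR")))
}

#' Flux-change versus expression-change concordance
#'
#' Compares, reaction by reaction, the sign of the predicted flux change
#' (from a [fold_change_table()]) with the sign of the measured expression
#' change of the reaction's genes. A reaction's expression direction is
#' the sign of the mean log2 fold change over its detected GPR genes, with
#' an `"unchanged"` band of `|mean| <= unchanged_band`. Reactions without
#' a GPR, without detected genes, or inactive in both conditions are
#' not comparable.
#'
#' @param fold_changes data.frame from [fold_change_table()].
#' @param expression data.frame with columns `gene`, `log2fc`, `detected`
#'   (see [synth_expression()] / [read_expression_table()]).
#' @param model the [cbm_model()] supplying GPRs.
#' @param unchanged_band expression no-change half width (default 0.1,
#'   treating ratios near 1 as unchanged).
#' @return object of class `concordance_report`: `rows` (per-reaction),
#'   `per_gene` (gene-level rows), `agreement_fraction` over comparable
#'   rows, `n_comparable`.
#' @export
concordance <- function(fold_changes, expression, model,
                        unchanged_band = 0.1) {
  stopifnot(all(c("gene", "log2fc", "detected") %in% names(expression)))
  expression <- expression[!duplicated(expression$gene), ]
  rows <- NULL; per_gene <- NULL
  for (i in seq_len(nrow(fold_changes))) {
    rid <- fold_changes$reaction[i]
    gpr <- model$reactions$gpr[match(rid, model$reactions$id)]
    genes <- gpr_genes(gpr)
    pred <- fold_changes$direction[i]
    ex <- expression[expression$gene %in% genes & expression$detected, ]
    if (nrow(ex)) {
      m <- mean(ex$log2fc)
      edir <- if (abs(m) <= unchanged_band) "unchanged" else
        if (m > 0) "up" else "down"
      per_gene <- rbind(per_gene, data.frame(
        reaction = rid, gene = ex$gene, gene_log2fc = ex$log2fc,
        predicted_direction = pred))
    } else edir <- NA_character_
    comparable <- !is.na(edir) && length(genes) > 0 &&
      pred %in% c("up", "down", "unchanged")
    rows <- rbind(rows, data.frame(
      reaction = rid, predicted_direction = pred,
      expression_direction = if (is.na(edir)) "not-detected" else edir,
      comparable = comparable,
      agrees = if (comparable) identical(pred, edir) else NA))
  }
  comp <- rows[rows$comparable, ]
  structure(list(rows = rows, per_gene = per_gene,
                 agreement_fraction = if (nrow(comp))
                   mean(comp$agrees) else NA_real_,
                 n_comparable = nrow(comp)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d comparable reactions, agreement %.3f\n",
              x$n_comparable, x$agreement_fraction))
  invisible(x)
}
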