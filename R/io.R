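## Model I/O: a human-editable TSV dialect plus SBML Level 3 + FBC.

fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  trimws(out)
}

na_to_empty <- function(x) ifelse(is.na(x), "", x)
empty_to_na <- function(x) ifelse(!nzchar(x), NA_character_, x)

#' Load a stoichiometric model from disk
#'
#' Reads either the package's TSV dialect (see [write_model()] for the
#' layout) or SBML Level 3 with the FBC extension. Bounds absent in the
#' file default to (-1000, 1000) for reversible reactions and (0, 1000)
#' for irreversible ones.
#'
#' @param path file path.
#' @param format `"tsv"` or `"sbml"`; default guessed from the extension
#'   (`.xml`/`.sbml` mean SBML).
#' @param validate run [validate_model()] and stop on hard violations
#'   (dangling references, bound order).
#' @return a [cbm_model()].
#' @export
load_model <- function(path, format = c("auto", "tsv", "sbml"), validate = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml" else "tsv"
  }
  model <- switch(format, tsv = read_model_tsv(path), sbml = read_model_sbml(path))
  if (validate) {
    diag <- validate_model(model)
    hard <- diag[diag$severity == "error", ]
    if (nrow(hard))
      stop(sprintf("model '%s' failed validation:\n%s", model$id,
                   paste(sprintf("  [%s] %s: %s", hard$rule, hard$entity,
                                 hard$message), collapse = "\n")))
  }
  model
}

#' Write a stoichiometric model to disk
#'
#' The TSV dialect is a single UTF-8 tab-separated file with `!model`,
#' `!compartments`, `!metabolites` and `!reactions` sections. Reaction
#' stoichiometry is an equation string (`"2 rubp_h + co2_h -> 2 pga_h"`,
#' `"<=>"` for reversible) and the `objective` column carries the
#' objective coefficient. Numbers are written with 17 significant digits
#' so a TSV round trip reproduces every coefficient bit-exactly.
#'
#' @param model a [cbm_model()].
#' @param path destination file.
#' @param format `"tsv"` or `"sbml"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "tsv", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml" else "tsv"
  }
  switch(format, tsv = write_model_tsv(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

reaction_equation <- function(model, rxn) {
  st <- model$stoich[model$stoich$reaction == rxn, ]
  lhs <- st[st$coef < 0, ]
  rhs <- st[st$coef > 0, ]
  side <- function(s, sgn) {
    if (!nrow(s)) return("")
    coefs <- abs(s$coef)
    paste(ifelse(abs(coefs - 1) < 1e-15, s$metabolite,
                 paste(fmt_num(coefs), s$metabolite)), collapse = " + ")
  }
  i <- match(rxn, model$reactions$id)
  arrow <- if (model$reactions$lb[i] < 0) "<=>" else "->"
  paste(side(lhs), arrow, side(rhs))
}

parse_equation <- function(eq, rxn_id) {
  rev <- grepl("<=>", eq, fixed = TRUE)
  arrow <- if (rev) "<=>" else "->"
  if (!grepl(arrow, eq, fixed = TRUE))
    stop(sprintf("reaction '%s': equation lacks '->' or '<=>': %s", rxn_id, eq))
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1) sides <- c(sides, "")
  parse_side <- function(txt, sgn) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(NULL)
    terms <- trimws(strsplit(txt, " + ", fixed = TRUE)[[1]])
    out <- lapply(terms, function(term) {
      parts <- strsplit(term, "\\s+")[[1]]
      if (length(parts) == 2) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef))
          stop(sprintf("reaction '%s': bad coefficient in term '%s'", rxn_id, term))
        data.frame(metabolite = parts[2], coef = sgn * coef)
      } else if (length(parts) == 1) {
        data.frame(metabolite = parts[1], coef = sgn)
      } else stop(sprintf("reaction '%s': unparseable term '%s'", rxn_id, term))
    })
    do.call(rbind, out)
  }
  st <- rbind(parse_side(sides[1], -1), parse_side(sides[2], 1))
  list(stoich = st, reversible = rev)
}

read_model_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines)]
  sec_at <- grep("^!", lines)
  if (!length(sec_at)) stop(sprintf("%s: no '!' section headers found", path))
  sections <- list()
  for (k in seq_along(sec_at)) {
    name <- sub("^!", "", trimws(lines[sec_at[k]]))
    end <- if (k < length(sec_at)) sec_at[k + 1] - 1 else length(lines)
    body <- lines[(sec_at[k] + 1):end]
    body <- body[nzchar(trimws(body))]
    sections[[name]] <- body
  }
  parse_table <- function(body, what) {
    if (is.null(body) || !length(body))
      stop(sprintf("%s: missing '!%s' section", path, what))
    cells <- strsplit(body, "\t", fixed = TRUE)
    header <- cells[[1]]
    rows <- cells[-1]
    out <- as.data.frame(do.call(rbind, lapply(rows, function(r) {
      length(r) <- length(header); r[is.na(r)] <- ""; r
    })), stringsAsFactors = FALSE)
    names(out) <- header
    out
  }
  modinfo <- parse_table(sections$model, "model")
  comps <- parse_table(sections$compartments, "compartments")
  mets <- parse_table(sections$metabolites, "metabolites")
  rxns <- parse_table(sections$reactions, "reactions")

  mets$boundary <- toupper(mets$boundary) %in% c("TRUE", "1", "YES")
  mets$formula <- empty_to_na(mets$formula)
  mets$annotation <- empty_to_na(mets$annotation)

  st_all <- NULL
  lb <- ub <- numeric(nrow(rxns))
  for (i in seq_len(nrow(rxns))) {
    pe <- parse_equation(rxns$equation[i], rxns$id[i])
    if (is.null(pe$stoich) || !nrow(pe$stoich))
      stop(sprintf("reaction '%s': empty stoichiometry", rxns$id[i]))
    st_all <- rbind(st_all, cbind(reaction = rxns$id[i], pe$stoich))
    lb[i] <- if (nzchar(rxns$lb[i])) as.numeric(rxns$lb[i]) else
      if (pe$reversible) -1000 else 0
    ub[i] <- if (nzchar(rxns$ub[i])) as.numeric(rxns$ub[i]) else 1000
  }
  obj_coef <- if (!is.null(rxns$objective))
    suppressWarnings(as.numeric(ifelse(nzchar(rxns$objective), rxns$objective, "0")))
  else rep(0, nrow(rxns))
  objective <- obj_coef[obj_coef != 0]
  names(objective) <- rxns$id[obj_coef != 0]

  cbm_model(
    id = if (nrow(modinfo) && "id" %in% names(modinfo)) modinfo$id[1] else
      tools::file_path_sans_ext(basename(path)),
    compartments = comps,
    metabolites = mets[, c("id", "name", "compartment", "formula", "boundary",
                           "annotation")],
    reactions = data.frame(id = rxns$id, name = rxns$name, lb = lb, ub = ub,
                           gpr = empty_to_na(rxns$gpr),
                           pathway = empty_to_na(rxns$pathway),
                           ec = empty_to_na(rxns$ec),
                           stringsAsFactors = FALSE),
    stoich = st_all,
    objective = objective
  )
}

write_model_tsv <- function(model, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste(..., sep = "\t"), con)
  writeLines("# leafcbm model TSV v1", con)
  writeLines("!model", con); w("id"); w(model$id)
  writeLines("!compartments", con); w("id", "name")
  for (i in seq_len(nrow(model$compartments)))
    w(model$compartments$id[i], model$compartments$name[i])
  writeLines("!metabolites", con)
  w("id", "name", "compartment", "formula", "boundary", "annotation")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    w(m$id, m$name, m$compartment, na_to_empty(m$formula),
      ifelse(m$boundary, "true", "false"), na_to_empty(m$annotation))
  }
  writeLines("!reactions", con)
  w("id", "name", "equation", "lb", "ub", "gpr", "pathway", "ec", "objective")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    obj <- if (r$id %in% names(model$objective)) fmt_num(model$objective[[r$id]]) else "0"
    w(r$id, r$name, reaction_equation(model, r$id), fmt_num(r$lb), fmt_num(r$ub),
      na_to_empty(r$gpr), na_to_empty(r$pathway), na_to_empty(r$ec), obj)
  }
  invisible(path)
}

## ---- SBML Level 3 / FBC ----

sbml_notes <- function(node) {
  ps <- xml2::xml_find_all(node, ".//p")
  txt <- xml2::xml_text(ps)
  out <- list()
  for (line in txt) {
    kv <- strsplit(line, ":", fixed = TRUE)[[1]]
    if (length(kv) >= 2)
      out[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  out
}

write_model_sbml <- function(model, path) {
  fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = fbc, level = "3", version = "1", "fbc:required" = "false")
  mod <- xml2::xml_add_child(doc, "model", id = model$id, "fbc:strict" = "true")

  loc <- xml2::xml_add_child(mod, "listOfCompartments")
  for (i in seq_len(nrow(model$compartments)))
    xml2::xml_add_child(loc, "compartment", id = model$compartments$id[i],
                        name = model$compartments$name[i], constant = "true")

  los <- xml2::xml_add_child(mod, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(los, "species", id = m$id, name = m$name,
                              compartment = m$compartment,
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = tolower(as.character(m$boundary)),
                              constant = "false")
    if (!is.na(m$formula)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    if (!is.na(m$annotation)) {
      notes <- xml2::xml_add_child(sp, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("annotation: ", m$annotation))
    }
  }

  lop <- xml2::xml_add_child(mod, "listOfParameters")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    xml2::xml_add_child(lop, "parameter", id = paste0("bnd_lb_", r$id),
                        value = fmt_num(r$lb), constant = "true")
    xml2::xml_add_child(lop, "parameter", id = paste0("bnd_ub_", r$id),
                        value = fmt_num(r$ub), constant = "true")
  }

  lor <- xml2::xml_add_child(mod, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rx <- xml2::xml_add_child(lor, "reaction", id = r$id, name = r$name,
                              reversible = tolower(as.character(r$lb < 0)),
                              fast = "false",
                              "fbc:lowerFluxBound" = paste0("bnd_lb_", r$id),
                              "fbc:upperFluxBound" = paste0("bnd_ub_", r$id))
    meta <- c(pathway = r$pathway, ec = r$ec, GENE_ASSOCIATION = r$gpr)
    meta <- meta[!is.na(meta)]
    if (length(meta)) {
      notes <- xml2::xml_add_child(rx, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      for (k in names(meta))
        xml2::xml_add_child(body, "p", paste0(k, ": ", meta[[k]]))
    }
    st <- model$stoich[model$stoich$reaction == r$id, ]
    rea <- st[st$coef < 0, ]; pro <- st[st$coef > 0, ]
    if (nrow(rea)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (k in seq_len(nrow(rea)))
        xml2::xml_add_child(lr, "speciesReference", species = rea$metabolite[k],
                            stoichiometry = fmt_num(abs(rea$coef[k])),
                            constant = "true")
    }
    if (nrow(pro)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (k in seq_len(nrow(pro)))
        xml2::xml_add_child(lp, "speciesReference", species = pro$metabolite[k],
                            stoichiometry = fmt_num(pro$coef[k]),
                            constant = "true")
    }
  }

  loo <- xml2::xml_add_child(mod, "fbc:listOfObjectives",
                             "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  for (rid in names(model$objective))
    xml2::xml_add_child(lfo, "fbc:fluxObjective", "fbc:reaction" = rid,
                        "fbc:coefficient" = fmt_num(model$objective[[rid]]))

  xml2::write_xml(doc, path)
  invisible(path)
}

attr1 <- function(attrs, keys, default = NA_character_) {
  for (k in keys) if (k %in% names(attrs)) return(attrs[[k]])
  default
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf("SBML parse failure in %s: %s",
                                                   path, conditionMessage(e))))
  xml2::xml_ns_strip(doc)
  mod <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mod, "xml_missing")) stop(sprintf("%s: no <model> element", path))

  comps <- do.call(rbind, lapply(
    xml2::xml_find_all(doc, ".//listOfCompartments/compartment"), function(nd) {
      a <- as.list(xml2::xml_attrs(nd))
      data.frame(id = a$id, name = attr1(a, "name", a$id))
    }))

  mets <- do.call(rbind, lapply(
    xml2::xml_find_all(doc, ".//listOfSpecies/species"), function(nd) {
      a <- as.list(xml2::xml_attrs(nd))
      notes <- sbml_notes(nd)
      data.frame(id = a$id, name = attr1(a, "name", a$id),
                 compartment = a$compartment,
                 formula = attr1(a, c("fbc:chemicalFormula", "chemicalFormula")),
                 boundary = identical(attr1(a, "boundaryCondition", "false"), "true"),
                 annotation = if (!is.null(notes$annotation)) notes$annotation
                 else NA_character_)
    }))

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- NULL; st_all <- NULL
  for (nd in rx_nodes) {
    a <- as.list(xml2::xml_attrs(nd))
    notes <- sbml_notes(nd)
    lbp <- attr1(a, c("fbc:lowerFluxBound", "lowerFluxBound"))
    ubp <- attr1(a, c("fbc:upperFluxBound", "upperFluxBound"))
    rev <- identical(attr1(a, "reversible", "false"), "true")
    lb <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]] else
      if (rev) -1000 else 0
    ub <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else 1000
    rxns <- rbind(rxns, data.frame(
      id = a$id, name = attr1(a, "name", a$id), lb = lb, ub = ub,
      gpr = if (!is.null(notes$GENE_ASSOCIATION)) notes$GENE_ASSOCIATION else NA_character_,
      pathway = if (!is.null(notes$pathway)) notes$pathway else NA_character_,
      ec = if (!is.null(notes$ec)) notes$ec else NA_character_,
      stringsAsFactors = FALSE))
    for (side in c(-1, 1)) {
      tagpath <- if (side < 0) "./listOfReactants/speciesReference"
      else "./listOfProducts/speciesReference"
      refs <- xml2::xml_find_all(nd, tagpath)
      if (length(refs))
        st_all <- rbind(st_all, data.frame(
          reaction = a$id, metabolite = xml2::xml_attr(refs, "species"),
          coef = side * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
          stringsAsFactors = FALSE))
    }
  }

  fo <- xml2::xml_find_all(doc, ".//*[local-name()='fluxObjective']")
  objective <- numeric()
  if (length(fo)) {
    ats <- lapply(fo, function(nd) as.list(xml2::xml_attrs(nd)))
    objective <- stats::setNames(
      vapply(ats, function(a) as.numeric(attr1(a, c("fbc:coefficient", "coefficient"), "1")), numeric(1)),
      vapply(ats, function(a) attr1(a, c("fbc:reaction", "reaction")), character(1)))
  }

  dangling <- setdiff(st_all$metabolite, mets$id)
  if (length(dangling))
    stop(sprintf("%s: reactions reference unknown metabolites: %s", path,
                 paste(dangling, collapse = ", ")))

  cbm_model(id = attr1(as.list(xml2::xml_attrs(mod)), "id", "model"),
            compartments = comps, metabolites = mets, reactions = rxns,
            stoich = st_all, objective = objective)
}
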