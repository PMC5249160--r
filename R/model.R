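# A metabolic_model is a list:
#   mets      character vector of metabolite ids
#   rxn       data.frame: id, lb, ub, is_exchange
#   S         sparse stoichiometric matrix (Matrix::dgCMatrix), mets x rxns
#   objective reaction id of the biomass pseudo-reaction
#   gpr       named list reaction id -> gpr_expr (reactions without a rule
#             are spontaneous / unmapped and carry no entry)
#   genes     character vector of gene ids

#' Construct a metabolic model
#'
#' Builds and validates the constraint-based model container used throughout
#' the package: a stoichiometric matrix, per-reaction flux bounds
#' (mmol/gDW/h), a biomass objective reaction, and boolean gene-protein-
#' reaction rules. Exchange reactions (the environmental interface) are
#' auto-detected as reactions touching exactly one metabolite.
#'
#' @param reactions list of reaction descriptions; each a list with elements
#'   `id`, `metabolites` (named numeric: metabolite -> stoichiometric
#'   coefficient, negative = consumed), `lb`, `ub`, and optionally `gpr`
#'   (a rule string, parsed with [parse_gpr()]).
#' @param objective id of the biomass (objective) reaction.
#' @param metabolites optional character vector fixing metabolite order;
#'   defaults to order of first appearance.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(reactions, objective, metabolites = NULL) {
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate reaction ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (is.null(metabolites)) {
    metabolites <- unique(unlist(lapply(reactions, function(r) names(r$metabolites))))
  }
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(reactions)) {
    sm <- reactions[[k]]$metabolites
    sm <- sm[sm != 0]
    if (!all(names(sm) %in% metabolites)) {
      stop("reaction '", ids[k], "' references unknown metabolites: ",
           paste(setdiff(names(sm), metabolites), collapse = ", "))
    }
    i <- c(i, match(names(sm), metabolites))
    j <- c(j, rep.int(k, length(sm)))
    x <- c(x, as.numeric(sm))
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(metabolites), length(reactions)),
                            dimnames = list(metabolites, ids))
  lb <- vapply(reactions, function(r) as.numeric(r$lb), numeric(1))
  ub <- vapply(reactions, function(r) as.numeric(r$ub), numeric(1))
  if (any(lb > ub)) stop("lower bound exceeds upper bound for: ",
                         paste(ids[lb > ub], collapse = ", "))
  if (!objective %in% ids) stop("objective reaction '", objective, "' not in model")
  n_mets <- Matrix::colSums(S != 0)
  gpr <- list()
  for (k in seq_along(reactions)) {
    rule <- reactions[[k]]$gpr
    if (!is.null(rule) && is.character(rule) && nzchar(trimws(rule))) {
      gpr[[ids[k]]] <- parse_gpr(rule, reaction = ids[k])
    } else if (!is.null(rule) && inherits(rule, "gpr_expr")) {
      gpr[[ids[k]]] <- rule
    }
  }
  structure(list(
    mets = metabolites,
    rxn = data.frame(id = ids, lb = lb, ub = ub,
                     # single-metabolite reactions are the environmental
                     # interface; the biomass drain is never an exchange
                     is_exchange = as.vector(n_mets == 1L) & ids != objective,
                     stringsAsFactors = FALSE),
    S = S,
    objective = objective,
    gpr = gpr,
    genes = sort(unique(unlist(lapply(gpr, gpr_genes))))
  ), class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", length(x$mets), " metabolites, ",
      nrow(x$rxn), " reactions (", sum(x$rxn$is_exchange), " exchanges), ",
      length(x$genes), " genes; objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Reaction ids of a model
#' @param model a `metabolic_model`.
#' @return character vector.
#' @export
reaction_ids <- function(model) model$rxn$id

#' Exchange reaction ids of a model
#' @param model a `metabolic_model`.
#' @return character vector.
#' @export
exchange_reactions <- function(model) model$rxn$id[model$rxn$is_exchange]

#' Map each gene to its associated reactions
#'
#' A gene is associated with every reaction in whose GPR it appears.
#'
#' @param model a `metabolic_model`.
#' @return named list: gene id -> character vector of reaction ids.
#' @export
gene_reactions <- function(model) {
  out <- stats::setNames(vector("list", length(model$genes)), model$genes)
  for (g in model$genes) out[[g]] <- character(0)
  for (rid in names(model$gpr)) {
    for (g in gpr_genes(model$gpr[[rid]])) out[[g]] <- c(out[[g]], rid)
  }
  out
}

#' Classify the genes of a model
#'
#' Produces the per-gene catalog used to define analysis subsets: isoenzymes
#' (members of an isoenzyme set of at least one unblocked reaction),
#' multifunctional genes (associated with two or more unblocked reactions),
#' and blocked-only genes (all associated reactions blocked), which are
#' purged from downstream analyses.
#'
#' @param model a `metabolic_model`.
#' @param blocked character vector of blocked reaction ids (see
#'   [find_blocked_reactions()]); defaults to none.
#' @return data.frame with columns `gene`, `n_reactions`, `n_unblocked`,
#'   `is_isoenzyme`, `is_multifunctional`, `is_blocked_only`.
#' @export
classify_genes <- function(model, blocked = character(0)) {
  gr <- gene_reactions(model)
  iso_by_rxn <- lapply(model$gpr, isoenzyme_set)
  unblocked_gpr <- setdiff(names(model$gpr), blocked)
  iso_genes <- unique(unlist(iso_by_rxn[unblocked_gpr]))
  genes <- model$genes
  n_rxn <- vapply(gr[genes], length, integer(1))
  n_unb <- vapply(gr[genes], function(r) length(setdiff(r, blocked)), integer(1))
  data.frame(
    gene = genes,
    n_reactions = n_rxn,
    n_unblocked = n_unb,
    is_isoenzyme = genes %in% iso_genes,
    is_multifunctional = n_unb >= 2L,
    is_blocked_only = n_rxn > 0L & n_unb == 0L,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Read a model from COBRA-style JSON
#'
#' Reads the JSON dialect used by COBRA tools: top-level `metabolites`,
#' `reactions` (each with `id`, `metabolites` map, `lower_bound`,
#' `upper_bound`, `gene_reaction_rule`, `objective_coefficient`) and `genes`.
#'
#' @param path file path.
#' @return a `metabolic_model`.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  mets <- vapply(doc$metabolites, `[[`, character(1), "id")
  objective <- NULL
  rxns <- lapply(doc$reactions, function(r) {
    oc <- r$objective_coefficient
    if (!is.null(oc) && as.numeric(oc) != 0) objective <<- c(objective, r$id)
    list(id = r$id,
         metabolites = unlist(r$metabolites),
         lb = if (is.null(r$lower_bound)) -1000 else as.numeric(r$lower_bound),
         ub = if (is.null(r$upper_bound)) 1000 else as.numeric(r$upper_bound),
         gpr = r$gene_reaction_rule)
  })
  if (is.null(objective)) stop("no reaction with a nonzero objective_coefficient in ", path)
  if (length(objective) > 1) {
    warning("multiple objective reactions; using the first: ", objective[1])
  }
  metabolic_model(rxns, objective = objective[1], metabolites = mets)
}

#' Write a model to COBRA-style JSON
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  Sd <- as.matrix(model$S)
  rxns <- lapply(seq_len(nrow(model$rxn)), function(k) {
    rid <- model$rxn$id[k]
    sm <- Sd[, k]
    sm <- sm[sm != 0]
    out <- list(id = rid, metabolites = as.list(sm),
                lower_bound = model$rxn$lb[k], upper_bound = model$rxn$ub[k],
                gene_reaction_rule = if (rid %in% names(model$gpr))
                  serialize_gpr(model$gpr[[rid]]) else "",
                objective_coefficient = if (rid == model$objective) 1 else 0)
    out
  })
  doc <- list(
    metabolites = lapply(model$mets, function(m) list(id = m)),
    reactions = rxns,
    genes = lapply(model$genes, function(g) list(id = g))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# --- SBML Level 3 / FBC ------------------------------------------------------

# attribute lookup tolerant of an fbc: prefix surviving namespace stripping
sbml_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) v <- xml2::xml_attr(node, paste0("fbc:", name))
  v
}

sbml_gpr_tree <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    return(gpr_leaf(sbml_attr(node, "geneProduct")))
  }
  if (nm %in% c("and", "or")) {
    kids <- lapply(xml2::xml_children(node), sbml_gpr_tree)
    kids <- kids[!vapply(kids, is.null, logical(1))]
    if (length(kids) == 0) return(NULL)
    return(gpr_node(nm, kids))
  }
  if (nm == "geneProductAssociation") {
    kids <- xml2::xml_children(node)
    if (length(kids) == 0) return(NULL)
    return(sbml_gpr_tree(kids[[1]]))
  }
  NULL
}

#' Read a model from SBML Level 3 with FBC
#'
#' Parses species, reactions with stoichiometries, flux bounds given as FBC
#' parameter references, gene associations (`fbc:and` / `fbc:or` /
#' `fbc:geneProductRef`), and the active FBC objective. Species flagged
#' `boundaryCondition="true"` are treated as external and excluded from the
#' mass-balance constraints.
#'
#' @param path file path to an SBML file.
#' @return a `metabolic_model`.
#' @export
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  # FBC elements live in their own namespace; match by local name so the
  # reader is indifferent to the prefix a writer chose
  ln <- function(...) paste0(".//", paste(sprintf("*[local-name()='%s']", c(...)),
                                          collapse = "/"))
  params <- xml2::xml_find_all(doc, ln("listOfParameters", "parameter"))
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  sp <- xml2::xml_find_all(doc, ln("listOfSpecies", "species"))
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  mets <- xml2::xml_attr(sp, "id")[!boundary]
  bmets <- xml2::xml_attr(sp, "id")[boundary]

  obj_nodes <- xml2::xml_find_all(doc, ln("listOfObjectives", "objective",
                                          "listOfFluxObjectives", "fluxObjective"))
  if (length(obj_nodes) == 0) stop("no FBC flux objective found in ", path)
  objective <- sbml_attr(obj_nodes[[1]], "reaction")

  rnodes <- xml2::xml_find_all(doc, ln("listOfReactions", "reaction"))
  rxns <- lapply(rnodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    stoich <- c()
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rn, paste0("./*[local-name()='", side,
                                            "']/*[local-name()='speciesReference']"))
      if (length(refs) == 0) next
      s <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      s[is.na(s)] <- 1
      if (side == "listOfReactants") s <- -s
      stoich <- c(stoich, stats::setNames(s, xml2::xml_attr(refs, "species")))
    }
    stoich <- stoich[!names(stoich) %in% bmets]
    stoich <- tapply(stoich, names(stoich), sum)  # merge duplicate species refs
    lbid <- sbml_attr(rn, "lowerFluxBound")
    ubid <- sbml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lbid) && lbid %in% names(pval)) pval[[lbid]] else
      if (identical(xml2::xml_attr(rn, "reversible"), "false")) 0 else -1000
    ub <- if (!is.na(ubid) && ubid %in% names(pval)) pval[[ubid]] else 1000
    gnode <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gnode, "xml_missing")) NULL else sbml_gpr_tree(gnode)
    list(id = rid, metabolites = stats::setNames(as.numeric(stoich), names(stoich)),
         lb = lb, ub = ub, gpr = gpr)
  })
  metabolic_model(rxns, objective = objective, metabolites = mets)
}
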