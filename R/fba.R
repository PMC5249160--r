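#' Define a growth medium
#'
#' A medium names the exchange reactions open for import and caps their
#' uptake flux (mmol/gDW/h); `Inf` means unbounded import. Every exchange
#' reaction not listed is restricted to export only.
#'
#' @param name medium name.
#' @param uptake named numeric vector: exchange reaction id -> maximum
#'   import flux (>= 0, `Inf` allowed).
#' @return object of class `medium`.
#' @export
medium <- function(name, uptake) {
  if (is.null(names(uptake)) || any(!nzchar(names(uptake)))) {
    stop("uptake must be a named numeric vector of exchange reaction ids")
  }
  if (any(uptake < 0)) stop("uptake limits must be >= 0")
  structure(list(name = name, uptake = uptake), class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat("<medium> ", x$name, ": ", length(x$uptake), " open exchanges\n", sep = "")
  invisible(x)
}

# Direction in which an exchange reaction imports its metabolite:
# -1 when the metabolite is a reactant (A ->, import = negative flux, the
# usual COBRA convention), +1 when it is a product (-> A).
exchange_import_sign <- function(model) {
  ex <- which(model$rxn$is_exchange)
  s <- integer(nrow(model$rxn))
  for (k in ex) {
    coef <- model$S[, k]
    s[k] <- if (sum(coef) < 0) -1L else 1L
  }
  stats::setNames(s, model$rxn$id)
}

# Bounds under a medium: listed exchanges get their import bound set to the
# cap; all other exchanges are export-only. Internal reactions keep model
# bounds. Returns list(lb, ub).
medium_bounds <- function(model, med) {
  lb <- model$rxn$lb
  ub <- model$rxn$ub
  if (is.null(med)) return(list(lb = lb, ub = ub))
  stopifnot(inherits(med, "medium"))
  unknown <- setdiff(names(med$uptake), model$rxn$id)
  if (length(unknown)) {
    stop("medium '", med$name, "' references unknown exchanges: ",
         paste(unknown, collapse = ", "))
  }
  isign <- exchange_import_sign(model)
  not_ex <- names(med$uptake)[!model$rxn$is_exchange[match(names(med$uptake), model$rxn$id)]]
  if (length(not_ex)) {
    stop("medium '", med$name, "' references non-exchange reactions: ",
         paste(not_ex, collapse = ", "))
  }
  for (k in which(model$rxn$is_exchange)) {
    rid <- model$rxn$id[k]
    cap <- med$uptake[rid]
    if (isign[k] < 0) {
      lb[k] <- if (!is.na(cap)) -cap else max(lb[k], 0)
    } else {
      ub[k] <- if (!is.na(cap)) cap else min(ub[k], 0)
    }
  }
  list(lb = lb, ub = ub)
}

# dense stoichiometric matrix, cached on the model's environment-free list
# via attribute (models are small; the dense copy makes repeated LP calls cheap)
dense_S <- function(model) {
  d <- attr(model, "dense_S")
  if (is.null(d)) d <- as.matrix(model$S)
  d
}

#' Cache the dense stoichiometric matrix on a model
#'
#' Optional speed-up for workflows that run many FBA solves on one model.
#' @param model a `metabolic_model`.
#' @return the model with a dense copy of S attached.
#' @export
cache_dense <- function(model) {
  attr(model, "dense_S") <- as.matrix(model$S)
  model
}

fba_optimize <- function(model, lb, ub, obj_col, big = 1e6) {
  lb[lb < -big] <- -big
  ub[ub > big] <- big
  n <- length(lb)
  obj <- numeric(n)
  obj[obj_col] <- 1
  .simplex_lp(dense_S(model), numeric(length(model$mets)), obj, lb, ub)
}

#' Flux balance analysis
#'
#' Maximizes flux through the model's biomass objective subject to
#' steady-state mass balance (S v = 0), reaction bounds, the medium's uptake
#' limits, and zero flux through each blocked reaction (knockouts). An
#' infeasible program is reported as zero growth: biologically the mutant
#' cannot grow.
#'
#' @param model a `metabolic_model`.
#' @param medium a [medium()], or `NULL` to use the model's own bounds.
#' @param blocked character vector of reaction ids forced to zero flux.
#' @return object of class `fba_solution`: `status` ("optimal" or
#'   "infeasible"), `objective` (growth rate), `fluxes` (named vector; note
#'   the flux vector at a degenerate optimum is not unique — only the
#'   objective value is contractual).
#' @export
solve_fba <- function(model, medium = NULL, blocked = character(0)) {
  bb <- medium_bounds(model, medium)
  if (length(blocked)) {
    bad <- setdiff(blocked, model$rxn$id)
    if (length(bad)) stop("unknown blocked reactions: ", paste(bad, collapse = ", "))
    k <- match(blocked, model$rxn$id)
    bb$lb[k] <- 0
    bb$ub[k] <- 0
  }
  res <- fba_optimize(model, bb$lb, bb$ub, match(model$objective, model$rxn$id))
  if (res$status != "optimal") {
    return(structure(list(status = "infeasible", objective = 0,
                          fluxes = stats::setNames(rep(NA_real_, nrow(model$rxn)),
                                                   model$rxn$id)),
                     class = "fba_solution"))
  }
  structure(list(status = "optimal", objective = max(res$objective, 0),
                 fluxes = stats::setNames(res$x, model$rxn$id)),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("<fba_solution> status: ", x$status, ", objective: ",
      format(x$objective), "\n", sep = "")
  invisible(x)
}

#' Detect blocked reactions
#'
#' A reaction is blocked when it cannot carry nonzero steady-state flux under
#' any of the supplied media: both its maximum and minimum achievable flux
#' are zero, in the style of flux variability analysis. Genes associated only
#' with blocked reactions are purged from downstream analyses.
#'
#' @param model a `metabolic_model`.
#' @param media non-empty list of [medium()] objects (or a single medium).
#' @param tol fluxes below `tol` in magnitude count as zero.
#' @return character vector of blocked reaction ids.
#' @export
find_blocked_reactions <- function(model, media, tol = 1e-9) {
  if (inherits(media, "medium")) media <- list(media)
  if (length(media) == 0) stop("at least one medium is required")
  candidates <- seq_len(nrow(model$rxn))
  for (med in media) {
    if (length(candidates) == 0) break
    bb <- medium_bounds(model, med)
    keep <- logical(length(candidates))
    for (i in seq_along(candidates)) {
      k <- candidates[i]
      hi <- fba_optimize(model, bb$lb, bb$ub, k)
      if (hi$status == "optimal" && hi$objective > tol) next
      lo <- .simplex_lp(dense_S(model), numeric(length(model$mets)),
                        replace(numeric(nrow(model$rxn)), k, -1),
                        pmax(bb$lb, -1e6), pmin(bb$ub, 1e6))
      if (lo$status == "optimal" && lo$objective > tol) next
      keep[i] <- TRUE
    }
    candidates <- candidates[keep]
  }
  model$rxn$id[candidates]
}

#' Reactions knocked out by a gene deletion
#'
#' Translates a gene deletion into reaction constraints through the GPR map.
#' Under `redundant` semantics (the standard FBA assumption) a reaction is
#' knocked out only if the gene is a necessary prerequisite: the GPR goes
#' false with this gene absent and all others present, so isoenzyme partners
#' provide full backup. Under `nonredundant` semantics every `or` in the GPR
#' is first rewritten to `and` ([or_to_and()]), making each isoenzyme-set
#' member necessary.
#'
#' @param model a `metabolic_model`.
#' @param gene gene id (must be in the model).
#' @param semantics `"redundant"` or `"nonredundant"`.
#' @return character vector of reaction ids.
#' @export
knockout_reactions_for_gene <- function(model, gene,
                                        semantics = c("redundant", "nonredundant")) {
  knockout_reactions_for_genes(model, gene, semantics)
}

#' Reactions knocked out by a joint deletion of several genes
#'
#' Evaluates each GPR with all listed genes absent simultaneously; a reaction
#' is knocked out when the rule goes false. This subsumes the union of the
#' single-deletion sets (a pair may jointly falsify a rule neither falsifies
#' alone, e.g. an isoenzyme pair).
#'
#' @inheritParams knockout_reactions_for_gene
#' @param genes character vector of gene ids.
#' @return character vector of reaction ids.
#' @export
knockout_reactions_for_genes <- function(model, genes,
                                         semantics = c("redundant", "nonredundant")) {
  semantics <- match.arg(semantics)
  unknown <- setdiff(genes, model$genes)
  if (length(unknown)) stop("unknown genes: ", paste(unknown, collapse = ", "))
  out <- character(0)
  for (rid in names(model$gpr)) {
    expr <- model$gpr[[rid]]
    if (!any(genes %in% gpr_genes(expr))) next
    if (semantics == "nonredundant") expr <- or_to_and(expr)
    if (!evaluate_gpr(expr, setdiff(gpr_genes(expr), genes))) out <- c(out, rid)
  }
  out
}
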