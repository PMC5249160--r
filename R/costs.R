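# Growth threshold shared by the cost and media machinery: predicted growth
# at or below this value counts as "no growth".
GROWTH_TOL <- 1e-6
# Fluxes smaller than this in magnitude are treated as zero.
FLUX_TOL <- 1e-9

wt_or_solve <- function(model, medium, wt) {
  if (is.null(wt)) wt <- solve_fba(model, medium)
  if (wt$objective <= GROWTH_TOL) {
    stop("medium '", if (is.null(medium)) "<model bounds>" else medium$name,
         "' does not support wild-type growth")
  }
  wt
}

#' Fitness cost of removing a single reaction
#'
#' The relative drop in predicted growth of the single-reaction knockout
#' mutant: `(w_wt - w_dr) / w_wt`, clipped to [0, 1] (FBA cannot predict
#' fitness gains from deletions; small negative values are solver noise).
#' If the wild-type optimum found carries zero flux through the reaction the
#' cost is zero without re-solving, since that optimum stays feasible.
#'
#' @param model a `metabolic_model`.
#' @param reaction reaction id.
#' @param medium a [medium()] (or `NULL` for the model's own bounds); must
#'   support wild-type growth.
#' @param wt optional precomputed wild-type [solve_fba()] solution.
#' @return cost in [0, 1].
#' @export
reaction_loss_cost <- function(model, reaction, medium = NULL, wt = NULL) {
  wt <- wt_or_solve(model, medium, wt)
  if (!reaction %in% model$rxn$id) stop("unknown reaction: ", reaction)
  if (wt$status == "optimal" && abs(wt$fluxes[[reaction]]) < FLUX_TOL) return(0)
  ko <- solve_fba(model, medium, blocked = reaction)
  min(max((wt$objective - ko$objective) / wt$objective, 0), 1)
}

#' Gene-loss cost
#'
#' The classical FBA knockout cost of a gene: all reactions for which the
#' gene is a necessary prerequisite (under the chosen GPR semantics) are
#' blocked simultaneously, and the relative fitness drop of the mutant is
#' reported. Under the default `redundant` semantics an isoenzyme-set member
#' incurs zero cost because its partners back it up.
#'
#' @inheritParams reaction_loss_cost
#' @param gene gene id.
#' @param semantics `"redundant"` (standard FBA) or `"nonredundant"`
#'   (`or`s rewritten to `and`s before the necessity test).
#' @return cost in [0, 1].
#' @export
gene_loss_cost <- function(model, gene, medium = NULL,
                           semantics = c("redundant", "nonredundant"),
                           wt = NULL) {
  semantics <- match.arg(semantics)
  wt <- wt_or_solve(model, medium, wt)
  rset <- knockout_reactions_for_gene(model, gene, semantics)
  if (length(rset) == 0) return(0)
  if (wt$status == "optimal" && all(abs(wt$fluxes[rset]) < FLUX_TOL)) return(0)
  ko <- solve_fba(model, medium, blocked = rset)
  min(max((wt$objective - ko$objective) / wt$objective, 0), 1)
}

#' Function-loss cost
#'
#' Sums the individual single-reaction removal costs over every reaction the
#' gene is associated with (appears anywhere in the GPR), one by one. This
#' treats isoenzymes as non-redundant: an isoenzyme pays the full cost of
#' its reaction even though a partner could, in the model, back it up.
#' Blocked reactions contribute zero. The optional `"max"` aggregation
#' replaces the sum with the maximum single-reaction cost.
#'
#' @inheritParams reaction_loss_cost
#' @param gene gene id.
#' @param blocked character vector of blocked reaction ids (excluded).
#' @param aggregate `"sum"` (the defining choice) or `"max"`.
#' @param reaction_costs optional named vector of precomputed single-reaction
#'   costs to draw from (for batch workflows).
#' @return non-negative real (at most the number of associated unblocked
#'   reactions under `"sum"`).
#' @export
function_loss_cost <- function(model, gene, medium = NULL,
                               blocked = character(0),
                               aggregate = c("sum", "max"),
                               wt = NULL, reaction_costs = NULL) {
  aggregate <- match.arg(aggregate)
  if (!gene %in% model$genes) stop("unknown gene: ", gene)
  wt <- wt_or_solve(model, medium, wt)
  rids <- names(model$gpr)[vapply(model$gpr, gene_is_associated, logical(1), gene = gene)]
  rids <- setdiff(rids, blocked)
  if (length(rids) == 0) return(0)
  costs <- vapply(rids, function(r) {
    if (!is.null(reaction_costs) && r %in% names(reaction_costs)) {
      reaction_costs[[r]]
    } else {
      reaction_loss_cost(model, r, medium, wt = wt)
    }
  }, numeric(1))
  if (aggregate == "sum") sum(costs) else max(costs)
}

#' Hybrid loss costs
#'
#' The two diagnostic mixtures of the cost metrics. Hybrid 1 uses the
#' function-loss cost for multifunctional genes and the gene-loss cost for
#' everyone else; hybrid 2 uses the function-loss cost for isoenzyme-
#' associated genes and the gene-loss cost for everyone else. Comparing
#' their behaviour isolates which gene category drives differences between
#' the two base metrics.
#'
#' @param glc,flc the gene's gene-loss and function-loss costs.
#' @param is_isoenzyme,is_multifunctional the gene's category flags
#'   (see [classify_genes()]).
#' @return named numeric vector `c(hybrid1 = ..., hybrid2 = ...)`.
#' @export
hybrid_loss_costs <- function(glc, flc, is_isoenzyme, is_multifunctional) {
  c(hybrid1 = if (is_multifunctional) flc else glc,
    hybrid2 = if (is_isoenzyme) flc else glc)
}

#' Call gene essentiality from a cost
#'
#' @param cost normalized loss cost.
#' @param threshold essentiality cutoff (default 0.99).
#' @return logical: essential or not.
#' @export
essentiality_call <- function(cost, threshold = 0.99) {
  cost >= threshold
}

#' Cost table over genes and media
#'
#' Computes, for every unpurged gene and every medium, the gene-loss cost,
#' the function-loss cost, both hybrids, and the wild-type growth rate.
#' Single-reaction costs are computed once per medium and shared across
#' genes. Media in which the wild type cannot grow are skipped with a
#' warning (the enumeration machinery only emits growth-supporting media;
#' this is a defensive check).
#'
#' @param model a `metabolic_model`.
#' @param media a `media_set`, a list of [medium()], or one medium.
#' @param blocked blocked reaction ids (see [find_blocked_reactions()]);
#'   genes associated only with blocked reactions are excluded.
#' @param catalog optional precomputed [classify_genes()] result.
#' @param semantics GPR semantics for the gene-loss cost.
#' @param aggregate aggregation for the function-loss cost (see
#'   [function_loss_cost()]).
#' @return data.frame: `gene`, `medium`, `glc`, `flc`, `hybrid1`, `hybrid2`,
#'   `wt_growth`.
#' @export
cost_table <- function(model, media, blocked = character(0), catalog = NULL,
                       semantics = c("redundant", "nonredundant"),
                       aggregate = c("sum", "max")) {
  semantics <- match.arg(semantics)
  aggregate <- match.arg(aggregate)
  if (inherits(media, "media_set")) media <- media$media
  if (inherits(media, "medium")) media <- list(media)
  model <- cache_dense(model)
  if (is.null(catalog)) catalog <- classify_genes(model, blocked)
  keep <- catalog[!catalog$is_blocked_only, , drop = FALSE]
  gr <- gene_reactions(model)
  ko_sets <- lapply(stats::setNames(keep$gene, keep$gene),
                    function(g) knockout_reactions_for_gene(model, g, semantics))
  gpr_rxns <- names(model$gpr)
  obj_idx <- match(model$objective, model$rxn$id)
  out <- vector("list", length(media))
  for (mi in seq_along(media)) {
    med <- media[[mi]]
    bb <- medium_bounds(model, med)
    wt <- fba_optimize(model, bb$lb, bb$ub, obj_idx)
    if (wt$status != "optimal" || wt$objective <= GROWTH_TOL) {
      warning("medium '", med$name, "' does not support growth; skipped")
      next
    }
    wt_flux <- stats::setNames(wt$x, model$rxn$id)
    ko_obj <- function(rset) {
      k <- match(rset, model$rxn$id)
      lb2 <- bb$lb; ub2 <- bb$ub
      lb2[k] <- 0; ub2[k] <- 0
      sol <- fba_optimize(model, lb2, ub2, obj_idx)
      if (sol$status != "optimal") 0 else max(sol$objective, 0)
    }
    # single-reaction removal costs, shared across genes; a reaction with
    # zero flux at the wild-type optimum costs nothing (that optimum stays
    # feasible when it is blocked), so no re-solve is needed
    rcost <- stats::setNames(numeric(length(gpr_rxns)), gpr_rxns)
    for (r in gpr_rxns) {
      if (r %in% blocked || abs(wt_flux[[r]]) < FLUX_TOL) next
      rcost[[r]] <- min(max((wt$objective - ko_obj(r)) / wt$objective, 0), 1)
    }
    glc <- vapply(keep$gene, function(g) {
      rset <- ko_sets[[g]]
      if (length(rset) == 0 || all(abs(wt_flux[rset]) < FLUX_TOL)) return(0)
      if (length(rset) == 1 && rset %in% gpr_rxns && !rset %in% blocked) {
        return(rcost[[rset]])  # same LP as the single-reaction removal
      }
      min(max((wt$objective - ko_obj(rset)) / wt$objective, 0), 1)
    }, numeric(1))
    flc <- vapply(keep$gene, function(g) {
      rids <- setdiff(gr[[g]], blocked)
      if (length(rids) == 0) return(0)
      if (aggregate == "sum") sum(rcost[rids]) else max(rcost[rids])
    }, numeric(1))
    out[[mi]] <- data.frame(
      gene = keep$gene, medium = med$name, glc = glc, flc = flc,
      hybrid1 = ifelse(keep$is_multifunctional, flc, glc),
      hybrid2 = ifelse(keep$is_isoenzyme, flc, glc),
      wt_growth = wt$objective,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  do.call(rbind, out)
}
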