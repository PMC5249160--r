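# Deterministic toy-model generators. Every generated object is a function
# of (spec, seed) only; the global RNG state is saved and restored.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Minimal hand-solvable scenario models
#'
#' Builds the elementary gene-to-reaction configurations in their simplest
#' form, each with an analytically known wild-type optimum and per-reaction
#' removal costs:
#' \describe{
#'   \item{complex}{one essential reaction gated by `g1 and g2`; gene-loss
#'     and function-loss costs coincide (both 1).}
#'   \item{isoenzyme}{one essential reaction gated by `g1 or g2`; gene-loss
#'     cost is 0 for either gene (the partner backs it up) while the
#'     function-loss cost equals the full reaction cost, 1.}
#'   \item{multifunctional}{one gene `g1` alone on two reactions, each with a
#'     partial-capacity gene-free bypass (`bypass`, default `c(4, 2)` against
#'     an uptake cap of 10, giving reaction costs 0.6 and 0.8); the
#'     function-loss cost is their sum. `bypass = c(0, 0)` makes both
#'     reactions essential (cost 1 each, sum 2).}
#'   \item{branch}{a gene-free branched network (uptake 10, bypass capacity
#'     4) whose optima are hand-checkable; used to exercise the LP layer.}
#' }
#' The matching minimal medium is attached as attribute `default_medium`.
#'
#' @param scenario one of `"complex"`, `"isoenzyme"`, `"multifunctional"`,
#'   `"branch"`.
#' @param uptake uptake cap on the single carbon source (default 10).
#' @param bypass bypass capacities for the multifunctional scenario.
#' @return a `metabolic_model` with a `default_medium` attribute.
#' @export
make_scenario_model <- function(scenario = c("complex", "isoenzyme",
                                             "multifunctional", "branch"),
                                uptake = 10, bypass = c(4, 2)) {
  scenario <- match.arg(scenario)
  ex <- function(id, met) list(id = id, metabolites = stats::setNames(-1, met),
                               lb = -1000, ub = 1000)
  model <- switch(scenario,
    complex = metabolic_model(list(
      ex("EX_A", "A"),
      list(id = "R1", metabolites = c(A = -1, B = 1), lb = 0, ub = 1000,
           gpr = "g1 and g2"),
      list(id = "GROWTH", metabolites = c(B = -1), lb = 0, ub = 1000)
    ), objective = "GROWTH"),
    isoenzyme = metabolic_model(list(
      ex("EX_A", "A"),
      list(id = "R1", metabolites = c(A = -1, B = 1), lb = 0, ub = 1000,
           gpr = "g1 or g2"),
      list(id = "GROWTH", metabolites = c(B = -1), lb = 0, ub = 1000)
    ), objective = "GROWTH"),
    multifunctional = metabolic_model(list(
      ex("EX_A", "A"),
      list(id = "R1", metabolites = c(A = -1, B = 1), lb = 0, ub = 1000,
           gpr = "g1"),
      list(id = "B1", metabolites = c(A = -1, B = 1), lb = 0, ub = bypass[1]),
      list(id = "R2", metabolites = c(B = -1, C = 1), lb = 0, ub = 1000,
           gpr = "g1"),
      list(id = "B2", metabolites = c(B = -1, C = 1), lb = 0, ub = bypass[2]),
      list(id = "GROWTH", metabolites = c(C = -1), lb = 0, ub = 1000)
    ), objective = "GROWTH"),
    branch = metabolic_model(list(
      ex("EX_A", "A"),
      list(id = "R1", metabolites = c(A = -1, B = 1), lb = 0, ub = 1000),
      list(id = "R2", metabolites = c(A = -1, C = 1), lb = 0, ub = 1000),
      list(id = "R3", metabolites = c(B = -1, C = 1), lb = 0, ub = 4),
      list(id = "GROWTH", metabolites = c(C = -1), lb = 0, ub = 1000)
    ), objective = "GROWTH")
  )
  attr(model, "default_medium") <- medium("minimal", c(EX_A = uptake))
  model
}

#' Specification for the random toy-model generator
#'
#' Size and composition parameters for [make_random_toy_model()]. The
#' defaults describe the simulation used throughout the package's own
#' analyses: 200 metabolic genes, ten alternative carbon and five
#' alternative nitrogen sources (so the minimal-media enumeration yields a
#' 10 x 5 grid), roughly 30% of genes in isoenzyme sets and 10%
#' multifunctional, and partial-capacity gene-free bypasses that give graded
#' (not all-or-none) reaction removal costs.
#'
#' @param n_genes total genes.
#' @param n_carbon,n_nitrogen number of alternative carbon / nitrogen sources.
#' @param iso_fraction fraction of genes in isoenzyme sets (sets of 2-3).
#' @param multi_fraction fraction of genes made multifunctional (added to a
#'   second reaction's requirement).
#' @param bypass_fraction fraction of core reactions with a partial bypass.
#' @param uptake uptake cap for primary sources (mmol/gDW/h).
#' @param seed integer seed; same spec + seed gives a bit-identical model.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 200, n_carbon = 10, n_nitrogen = 5,
                         iso_fraction = 0.3, multi_fraction = 0.1,
                         bypass_fraction = 0.7, uptake = 10, seed = 1) {
  structure(list(n_genes = n_genes, n_carbon = n_carbon,
                 n_nitrogen = n_nitrogen, iso_fraction = iso_fraction,
                 multi_fraction = multi_fraction,
                 bypass_fraction = bypass_fraction,
                 uptake = uptake, seed = seed),
            class = "fixture_spec")
}

#' Random toy metabolic network
#'
#' Generates a connected, growth-supporting toy network with a hub
#' architecture: alternative carbon sources feed a carbon pool through
#' gene-associated conversion reactions of random capacity (likewise
#' nitrogen), and a set of core "module" reactions each drain both pools to
#' make one biomass precursor; the biomass objective consumes every
#' precursor. A fraction of core reactions carries a gene-free bypass with a
#' random partial capacity, so single-reaction removal costs take graded
#' values in [0, 1], and source-reaction costs are medium-dependent (a
#' source's pathway only matters in media that use it). GPRs mix isoenzyme
#' `or`-sets, multi-gene `and`-complexes, and multifunctional genes.
#'
#' The wild type grows on every carbon x nitrogen pairing by construction,
#' so [enumerate_minimal_media()] yields the full
#' `n_carbon * n_nitrogen` grid.
#'
#' @param spec a [fixture_spec()].
#' @return a `metabolic_model` with attributes `default_medium` (reference
#'   medium: first carbon + first nitrogen source), `carbon_exchanges`,
#'   `nitrogen_exchanges`.
#' @export
make_random_toy_model <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    genes <- sprintf("g%03d", seq_len(spec$n_genes))
    n_iso <- round(spec$iso_fraction * spec$n_genes)
    # partition isoenzyme genes into sets of 2-3
    iso_pool <- genes[seq_len(n_iso)]
    iso_sets <- list()
    while (length(iso_pool) >= 2) {
      k <- if (length(iso_pool) >= 3 && stats::runif(1) < 0.4) 3 else 2
      iso_sets[[length(iso_sets) + 1L]] <- iso_pool[seq_len(k)]
      iso_pool <- iso_pool[-seq_len(k)]
    }
    # remaining genes (incl. any unpaired isoenzyme leftover) form
    # and-complexes of 2-5 members (occasionally a lone gene)
    used <- n_iso - length(iso_pool)
    rest <- if (used > 0) genes[-seq_len(used)] else genes
    and_groups <- list()
    while (length(rest) >= 1) {
      k <- min(sample(c(1, 2, 3, 4, 5), 1, prob = c(.1, .2, .3, .25, .15)),
               length(rest))
      and_groups[[length(and_groups) + 1L]] <- rest[seq_len(k)]
      rest <- rest[-seq_len(k)]
    }
    rules <- c(
      lapply(iso_sets, function(s) paste(s, collapse = " or ")),
      lapply(and_groups, function(s) paste(s, collapse = " and "))
    )
    rules <- sample(rules)  # shuffle which reactions get which rule

    n_src <- spec$n_carbon + spec$n_nitrogen
    n_core <- length(rules) - n_src
    if (n_core < 2) stop("fixture spec yields too few core reactions; increase n_genes")

    rxns <- list()
    carb_ex <- sprintf("EX_carb%02d", seq_len(spec$n_carbon))
    nit_ex <- sprintf("EX_nit%02d", seq_len(spec$n_nitrogen))
    for (i in seq_len(spec$n_carbon)) {
      met <- sprintf("carb%02d", i)
      rxns[[length(rxns) + 1L]] <- list(id = carb_ex[i],
                                        metabolites = stats::setNames(-1, met),
                                        lb = -1000, ub = 1000)
      cap <- stats::runif(1, 5, 10)
      rxns[[length(rxns) + 1L]] <- list(
        id = sprintf("SRC_C%02d", i),
        metabolites = stats::setNames(c(-1, 1), c(met, "Cpool")),
        lb = 0, ub = cap, gpr = rules[[i]])
      if (stats::runif(1) < spec$bypass_fraction) {
        rxns[[length(rxns) + 1L]] <- list(
          id = sprintf("SRCB_C%02d", i),
          metabolites = stats::setNames(c(-1, 1), c(met, "Cpool")),
          lb = 0, ub = stats::runif(1, 0.2, 0.8) * cap)
      }
    }
    for (i in seq_len(spec$n_nitrogen)) {
      met <- sprintf("nit%02d", i)
      rxns[[length(rxns) + 1L]] <- list(id = nit_ex[i],
                                        metabolites = stats::setNames(-1, met),
                                        lb = -1000, ub = 1000)
      cap <- stats::runif(1, 1, 3)
      rxns[[length(rxns) + 1L]] <- list(
        id = sprintf("SRC_N%02d", i),
        metabolites = stats::setNames(c(-1, 1), c(met, "Npool")),
        lb = 0, ub = cap, gpr = rules[[spec$n_carbon + i]])
      if (stats::runif(1) < spec$bypass_fraction) {
        rxns[[length(rxns) + 1L]] <- list(
          id = sprintf("SRCB_N%02d", i),
          metabolites = stats::setNames(c(-1, 1), c(met, "Npool")),
          lb = 0, ub = stats::runif(1, 0.2, 0.8) * cap)
      }
    }
    # Core modules: Cpool + 0.2 Npool -> precursor P_k; biomass drains all
    # precursors, so each module is on the objective path and the maximum
    # conceivable growth is uptake / n_core per unit carbon.
    g_ref <- spec$uptake / n_core
    biomass_stoich <- c()
    for (k in seq_len(n_core)) {
      met <- sprintf("P%03d", k)
      biomass_stoich[met] <- -1
      rxns[[length(rxns) + 1L]] <- list(
        id = sprintf("MOD%03d", k),
        metabolites = stats::setNames(c(-1, -0.2, 1), c("Cpool", "Npool", met)),
        lb = 0, ub = 1000, gpr = rules[[n_src + k]])
      if (stats::runif(1) < spec$bypass_fraction) {
        rxns[[length(rxns) + 1L]] <- list(
          id = sprintf("MODB%03d", k),
          metabolites = stats::setNames(c(-1, -0.2, 1), c("Cpool", "Npool", met)),
          lb = 0, ub = stats::runif(1, 0.1, 0.9) * g_ref)
      }
    }
    rxns[[length(rxns) + 1L]] <- list(id = "GROWTH", metabolites = biomass_stoich,
                                      lb = 0, ub = 1000)

    # multifunctional genes get a second function: half become the sole
    # catalyst of a previously spontaneous bypass (creating synthetic-lethal
    # partners with the bypassed module's genes), half are added as an extra
    # required subunit of another and-rule reaction
    n_multi <- round(spec$multi_fraction * spec$n_genes)
    and_genes <- unlist(and_groups)
    multi <- sample(and_genes, min(n_multi, length(and_genes)))
    gpr_idx <- which(vapply(rxns, function(r) !is.null(r$gpr), logical(1)))
    gene_of <- lapply(rxns[gpr_idx], function(r) gpr_genes(parse_gpr(r$gpr)))
    # only and-rule reactions can host an extra required gene: adding one to
    # an or-set would destroy the set's individual sufficiency
    and_hosts <- !grepl(" or ", vapply(rxns[gpr_idx], `[[`, character(1), "gpr"),
                        fixed = TRUE)
    free_bypasses <- which(grepl("^(MODB|SRCB)", vapply(rxns, `[[`, character(1), "id")))
    for (mi in seq_along(multi)) {
      g <- multi[mi]
      if (mi %% 2 == 1 && length(free_bypasses) > 0) {
        pick <- sample(seq_along(free_bypasses), 1)
        rxns[[free_bypasses[pick]]]$gpr <- g
        free_bypasses <- free_bypasses[-pick]
      } else {
        host <- which(and_hosts &
                      !vapply(gene_of, function(gs) g %in% gs, logical(1)))
        pick <- sample(host, 1)
        i <- gpr_idx[pick]
        rxns[[i]]$gpr <- paste0("(", rxns[[i]]$gpr, ") and ", g)
        gene_of[[pick]] <- c(gene_of[[pick]], g)
      }
    }

    model <- metabolic_model(rxns, objective = "GROWTH")
    ref <- medium("reference",
                  stats::setNames(c(spec$uptake, spec$uptake),
                                  c(carb_ex[1], nit_ex[1])))
    attr(model, "default_medium") <- ref
    attr(model, "carbon_exchanges") <- carb_ex
    attr(model, "nitrogen_exchanges") <- nit_ex
    wt <- solve_fba(model, ref)
    if (wt$objective <= GROWTH_TOL) stop("generated fixture does not grow; adjust spec")
    model
  })
}

#' Synthetic per-species evolutionary-rate table
#'
#' Generates dN/dS-like rates for each gene in several species as a noisy
#' decreasing function of the gene's functional burden (its mean
#' function-loss cost across the cost table):
#' `k = exp(-a * burden + N(0, noise_sd))`, independently per species. The
#' anticorrelation between burden and rate is therefore recoverable by
#' construction, with `noise_sd` controlling how strongly. A fraction of
#' gene-species entries is deleted to emulate missing orthologs; genes that
#' lose every species drop out of rank averaging downstream.
#'
#' @param costs a [cost_table()] data.frame (uses columns `gene`, `flc`).
#' @param n_species number of comparison species.
#' @param a burden-to-rate slope on the log scale.
#' @param noise_sd standard deviation of the per-species log-rate noise.
#' @param missing_fraction probability a gene lacks an ortholog in a species.
#' @param seed integer seed.
#' @return data.frame `gene`, `species`, `dnds` (missing entries omitted).
#' @export
make_synthetic_rates <- function(costs, n_species = 5, a = 3, noise_sd = 0.6,
                                 missing_fraction = 0.1, seed = 1) {
  burden <- tapply(costs$flc, costs$gene, mean)
  genes <- names(burden)
  with_seed(seed, {
    out <- list()
    for (s in seq_len(n_species)) {
      k <- exp(-a * as.numeric(burden) + stats::rnorm(length(genes), 0, noise_sd))
      keep <- stats::runif(length(genes)) >= missing_fraction
      out[[s]] <- data.frame(gene = genes[keep],
                             species = sprintf("species_%d", s),
                             dnds = k[keep], stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out)
    row.names(df) <- NULL
    df
  })
}

#' Synthetic experimental genetic-interaction table
#'
#' Builds an interaction table shaped like the experimental input the
#' epistasis comparison consumes: epsilon and single-mutant fitnesses are the
#' model's own non-redundant-semantics predictions plus Gaussian measurement
#' noise, and p-values are drawn small for pairs with substantial predicted
#' interaction. Useful for self-consistency checks of the scoring pipeline;
#' it is a synthetic stand-in, not experimental data.
#'
#' @param model a `metabolic_model`.
#' @param med the [medium()] in which to predict.
#' @param pairs data.frame (`gene_i`, `gene_j`); default: a random sample of
#'   gene pairs enriched for isoenzyme partners and for genes on parallel
#'   reactions (same product metabolites), where synergistic interactions
#'   can arise.
#' @param n_pairs number of random pairs when `pairs` is NULL.
#' @param noise_sd measurement noise on epsilon and fitness.
#' @param seed integer seed.
#' @return data.frame `gene_i`, `gene_j`, `epsilon`, `p_value`, `fitness_i`,
#'   `fitness_j`.
#' @export
make_synthetic_interactions <- function(model, med, pairs = NULL, n_pairs = 100,
                                        noise_sd = 0.02, seed = 1) {
  with_seed(seed, {
    if (is.null(pairs)) {
      iso_pairs <- do.call(rbind, lapply(isoenzyme_sets(model), function(s) {
        if (length(s) >= 2) t(utils::combn(s, 2)) else NULL
      }))
      # genes on parallel reactions (identical product sets): main/bypass
      # partners, where joint loss can be far worse than either alone
      Sd <- as.matrix(model$S)
      prod_key <- apply(Sd[, names(model$gpr), drop = FALSE] > 0, 2,
                        function(v) paste(which(v), collapse = ","))
      par_pairs <- do.call(rbind, lapply(split(names(prod_key), prod_key),
        function(rids) {
          if (length(rids) < 2) return(NULL)
          gsets <- lapply(model$gpr[rids], gpr_genes)
          do.call(rbind, lapply(utils::combn(length(rids), 2, simplify = FALSE),
            function(ij) expand.grid(gsets[[ij[1]]], gsets[[ij[2]]],
                                     stringsAsFactors = FALSE)))
        }))
      if (!is.null(par_pairs)) {
        par_pairs <- unname(as.matrix(par_pairs))
        if (nrow(par_pairs) > n_pairs) {
          par_pairs <- par_pairs[sample(nrow(par_pairs), n_pairs), , drop = FALSE]
        }
      }
      rnd <- t(replicate(n_pairs, sample(model$genes, 2)))
      pm <- rbind(iso_pairs, par_pairs, rnd)
      pairs <- data.frame(gene_i = pm[, 1], gene_j = pm[, 2],
                          stringsAsFactors = FALSE)
      pairs <- pairs[pairs$gene_i != pairs$gene_j, , drop = FALSE]
      pairs <- pairs[!duplicated(t(apply(pairs, 1, sort))), , drop = FALSE]
    }
    pred <- predict_pairwise(model, pairs, med, semantics = "nonredundant")
    n <- nrow(pred)
    eps <- pred$epsilon + stats::rnorm(n, 0, noise_sd)
    interacting <- abs(pred$epsilon) > 0.08
    p <- ifelse(interacting, stats::runif(n, 0, 0.04), stats::runif(n, 0, 1))
    data.frame(gene_i = pred$gene_i, gene_j = pred$gene_j,
               epsilon = eps, p_value = p,
               fitness_i = pmax(pred$w_i + stats::rnorm(n, 0, noise_sd), 0),
               fitness_j = pmax(pred$w_j + stats::rnorm(n, 0, noise_sd), 0),
               stringsAsFactors = FALSE)
  })
}
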