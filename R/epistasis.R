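#' Epistasis score
#'
#' Deviation of double-mutant fitness from the multiplicative expectation:
#' `epsilon = w_ij - w_i * w_j`. Negative values are synergistic (the double
#' mutant is worse than expected, e.g. synthetic lethality), positive values
#' antagonistic. Vectorized.
#'
#' @param w_i,w_j single-mutant relative fitnesses (wild type = 1).
#' @param w_ij double-mutant relative fitness.
#' @return epsilon.
#' @export
epistasis_score <- function(w_i, w_j, w_ij) {
  w_ij - w_i * w_j
}

#' Classify a predicted epistasis value
#'
#' Magnitude-only thresholding for deterministic FBA predictions:
#' synergistic below `-cutoff`, antagonistic above `+cutoff`, otherwise
#' non-interacting.
#'
#' @param epsilon predicted epsilon (vectorized).
#' @param cutoff magnitude cutoff (default 1e-4).
#' @return character vector in `{"synergistic", "antagonistic", "none"}`.
#' @export
classify_prediction <- function(epsilon, cutoff = 1e-4) {
  ifelse(epsilon < -cutoff, "synergistic",
         ifelse(epsilon > cutoff, "antagonistic", "none"))
}

#' Classify an experimental epistasis measurement
#'
#' The intermediate stringency criteria: a pair interacts only when
#' `|epsilon| > eps_cutoff` and `p < p_cutoff`; the sign of epsilon gives
#' the class.
#'
#' @param epsilon measured epsilon (vectorized).
#' @param p measurement p-value.
#' @param eps_cutoff magnitude cutoff (default 0.08).
#' @param p_cutoff significance cutoff (default 0.05).
#' @return character vector in `{"synergistic", "antagonistic", "none"}`.
#' @export
classify_experimental <- function(epsilon, p, eps_cutoff = 0.08, p_cutoff = 0.05) {
  ifelse(abs(epsilon) > eps_cutoff & p < p_cutoff,
         ifelse(epsilon < 0, "synergistic", "antagonistic"),
         "none")
}

#' Filter an experimental pair table on single-mutant fitness
#'
#' Keeps pairs whose experimental single-mutant fitnesses are no greater
#' than two standard deviations above wild-type fitness; FBA cannot predict
#' fitness gains from deletions, so faster-growing mutants are outside the
#' model's reach. The boundary value (exactly `wt + 2 sd`) is kept.
#'
#' @param pairs data.frame with columns `fitness_i`, `fitness_j`.
#' @param wt_fitness experimental wild-type fitness (default 1).
#' @param wt_sd its standard deviation.
#' @param n_sd allowance multiplier (default 2).
#' @return the filtered data.frame.
#' @export
filter_deletion_fitness <- function(pairs, wt_fitness = 1, wt_sd = 0, n_sd = 2) {
  lim <- wt_fitness + n_sd * wt_sd
  pairs[pairs$fitness_i <= lim & pairs$fitness_j <= lim, , drop = FALSE]
}

#' Predict pairwise epistasis with FBA
#'
#' For each gene pair, computes single- and double-knockout relative
#' fitnesses under the chosen GPR semantics and the epistasis score.
#' The double knockout evaluates each GPR with both genes absent (which
#' subsumes the union of the single-deletion reaction sets: an isoenzyme
#' pair jointly falsifies a rule neither falsifies alone). Fitnesses are
#' normalized by wild-type growth and clipped to [0, 1].
#'
#' @param model a `metabolic_model`.
#' @param pairs data.frame (or 2-column matrix) of gene pairs.
#' @param med [medium()] for the predictions (or `NULL` for model bounds);
#'   must support wild-type growth.
#' @param semantics `"redundant"` or `"nonredundant"` (see
#'   [knockout_reactions_for_gene()]).
#' @param cutoff classification cutoff passed to [classify_prediction()].
#' @return data.frame: `gene_i`, `gene_j`, `w_i`, `w_j`, `w_ij`, `epsilon`,
#'   `predicted_class`.
#' @export
predict_pairwise <- function(model, pairs, med = NULL,
                             semantics = c("redundant", "nonredundant"),
                             cutoff = 1e-4) {
  semantics <- match.arg(semantics)
  model <- cache_dense(model)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs)[1:2] <- c("gene_i", "gene_j")
  wt <- wt_or_solve(model, med, NULL)
  fit_of <- function(genes) {
    rset <- knockout_reactions_for_genes(model, genes, semantics)
    if (length(rset) == 0 || all(abs(wt$fluxes[rset]) < FLUX_TOL)) return(1)
    ko <- solve_fba(model, med, blocked = rset)
    min(max(ko$objective / wt$objective, 0), 1)
  }
  singles <- unique(c(pairs$gene_i, pairs$gene_j))
  w1 <- vapply(stats::setNames(singles, singles), fit_of, numeric(1))
  w_ij <- mapply(function(a, b) fit_of(c(a, b)), pairs$gene_i, pairs$gene_j)
  eps <- epistasis_score(w1[pairs$gene_i], w1[pairs$gene_j], w_ij)
  data.frame(gene_i = pairs$gene_i, gene_j = pairs$gene_j,
             w_i = unname(w1[pairs$gene_i]), w_j = unname(w1[pairs$gene_j]),
             w_ij = unname(w_ij), epsilon = unname(eps),
             predicted_class = classify_prediction(unname(eps), cutoff),
             stringsAsFactors = FALSE, row.names = NULL)
}

interaction_classes <- c("synergistic", "antagonistic", "none")

#' Score predicted interactions against experimental classes
#'
#' Builds the 3x3 confusion matrix (experimental class x predicted class)
#' over `{synergistic, antagonistic, none}`, per-class precision and recall,
#' and, for each interacting class, a 2x2 Fisher's exact enrichment test of
#' predicted-in-class against experimentally-in-class.
#'
#' @param predicted character vector of predicted classes (or a
#'   [predict_pairwise()] data.frame).
#' @param experimental character vector of experimental classes, same order.
#' @return object of class `interaction_comparison`: list with `confusion`,
#'   `precision`, `recall`, `fisher_p` (named by class), `n`.
#' @export
compare_with_experiment <- function(predicted, experimental) {
  if (is.data.frame(predicted)) predicted <- predicted$predicted_class
  stopifnot(length(predicted) == length(experimental))
  pf <- factor(predicted, levels = interaction_classes)
  ef <- factor(experimental, levels = interaction_classes)
  confusion <- table(experimental = ef, predicted = pf)
  precision <- recall <- fisher_p <- stats::setNames(
    rep(NA_real_, 3), interaction_classes)
  for (cl in interaction_classes) {
    tp <- sum(pf == cl & ef == cl)
    precision[cl] <- if (sum(pf == cl) > 0) tp / sum(pf == cl) else NA_real_
    recall[cl] <- if (sum(ef == cl) > 0) tp / sum(ef == cl) else NA_real_
    tab <- table(factor(pf == cl, levels = c(TRUE, FALSE)),
                 factor(ef == cl, levels = c(TRUE, FALSE)))
    fisher_p[cl] <- stats::fisher.test(tab, alternative = "greater")$p.value
  }
  structure(list(confusion = confusion, precision = precision,
                 recall = recall, fisher_p = fisher_p,
                 n = length(predicted)),
            class = "interaction_comparison")
}

#' @export
print.interaction_comparison <- function(x, ...) {
  cat("<interaction_comparison> n =", x$n, "\n")
  print(x$confusion)
  cat("precision:", paste(names(x$precision),
                          format(x$precision, digits = 3), collapse = "  "), "\n")
  cat("recall:   ", paste(names(x$recall),
                          format(x$recall, digits = 3), collapse = "  "), "\n")
  invisible(x)
}

#' Precision-recall curve over the prediction cutoff
#'
#' Re-classifies the raw predicted epsilon values over a grid of magnitude
#' cutoffs while holding the experimental classification fixed, and reports
#' precision and recall for the two interacting classes at each cutoff.
#'
#' @param predictions [predict_pairwise()] data.frame (raw `epsilon` used).
#' @param experimental character vector of experimental classes.
#' @param cutoffs cutoff grid (default: 20 log-spaced values in
#'   `[1e-4, 1e-2]`).
#' @return data.frame: `class`, `cutoff`, `precision`, `recall`,
#'   `n_predicted`.
#' @export
precision_recall_curve <- function(predictions, experimental,
                                   cutoffs = 10^seq(-4, -2, length.out = 20)) {
  out <- list()
  for (ct in cutoffs) {
    pred <- classify_prediction(predictions$epsilon, ct)
    for (cl in c("synergistic", "antagonistic")) {
      tp <- sum(pred == cl & experimental == cl)
      np <- sum(pred == cl)
      ne <- sum(experimental == cl)
      out[[length(out) + 1L]] <- data.frame(
        class = cl, cutoff = ct,
        precision = if (np > 0) tp / np else NA_real_,
        recall = if (ne > 0) tp / ne else NA_real_,
        n_predicted = np, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
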