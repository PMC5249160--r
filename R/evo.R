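#' Isoenzyme sets of a model
#'
#' The distinct isoenzyme sets across (unblocked) reactions: for every
#' reaction whose GPR admits two or more individually sufficient genes,
#' those genes form one set (see [isoenzyme_set()]).
#'
#' @param model a `metabolic_model`.
#' @param blocked reaction ids to ignore.
#' @return list of character vectors (duplicates removed).
#' @export
isoenzyme_sets <- function(model, blocked = character(0)) {
  sets <- lapply(model$gpr[setdiff(names(model$gpr), blocked)], isoenzyme_set)
  sets <- sets[vapply(sets, length, integer(1)) >= 2]
  unique(lapply(sets, sort))
}

#' Read a per-species evolutionary-rate table
#'
#' @param path TSV with columns `gene`, `species`, `dnds`.
#' @return data.frame.
#' @export
read_rates_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "species", "dnds")
  if (!all(need %in% names(df))) {
    stop("rates table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Rank-averaged evolutionary rate per gene
#'
#' Within each species, genes with a rate are ranked ascending (1 = slowest;
#' ties receive average ranks); each gene's score is the mean of its ranks
#' over the species in which it has data. A gene need not have orthologs in
#' every species. Genes with no rate in any species are excluded and
#' reported via the `excluded` attribute. Because the score is rank-based,
#' it is invariant under any strictly monotone transform of each species'
#' raw rates.
#'
#' @param rates data.frame with columns `gene`, `species`, `dnds` (missing
#'   ortholog = absent row or `NA` rate).
#' @return named numeric vector of averaged ranks, attribute `excluded`
#'   listing genes dropped for lack of data.
#' @export
average_rank_rate <- function(rates) {
  all_genes <- unique(rates$gene)
  rates <- rates[!is.na(rates$dnds), , drop = FALSE]
  if (nrow(rates) == 0) stop("no gene has a rate in any species")
  ranks <- unlist(lapply(split(rates, rates$species), function(d) {
    stats::setNames(rank(d$dnds, ties.method = "average"), d$gene)
  }), use.names = FALSE)
  genes <- unlist(lapply(split(rates, rates$species), function(d) d$gene),
                  use.names = FALSE)
  khat <- tapply(ranks, genes, mean)
  out <- stats::setNames(as.numeric(khat), names(khat))
  attr(out, "excluded") <- setdiff(all_genes, names(khat))
  out
}

#' Spearman rank correlation
#'
#' Pairs observations by position, drops pairs with a missing value, and
#' computes Spearman's rho with average-rank tie handling. At least three
#' complete pairs are required.
#'
#' @param x,y numeric vectors of equal length.
#' @return rho in [-1, 1], or `NA` if either variable is constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  suppressWarnings(stats::cor(x[ok], y[ok], method = "spearman"))
}

#' Select a gene subset from a gene catalog
#'
#' Subsets mirror the analysis panels: all genes, non-isoenzymes,
#' isoenzymes, and multifunctional genes that are not isoenzymes. Blocked-
#' only genes are always excluded.
#'
#' @param catalog a [classify_genes()] data.frame.
#' @param subset subset name.
#' @return character vector of gene ids.
#' @export
gene_subset <- function(catalog,
                        subset = c("all", "non_isoenzymes", "isoenzymes",
                                   "multifunctional_non_isoenzymes")) {
  subset <- match.arg(subset)
  cat2 <- catalog[!catalog$is_blocked_only, , drop = FALSE]
  keep <- switch(subset,
    all = rep(TRUE, nrow(cat2)),
    non_isoenzymes = !cat2$is_isoenzyme,
    isoenzymes = cat2$is_isoenzyme,
    multifunctional_non_isoenzymes = cat2$is_multifunctional & !cat2$is_isoenzyme
  )
  cat2$gene[keep]
}

#' Per-medium correlation distribution of a cost metric with evolutionary rate
#'
#' For each medium in the cost table, computes Spearman's rho between the
#' chosen cost column and the rank-averaged evolutionary rate over the given
#' genes. Media where fewer than three genes have both values, or where
#' either variable is constant, are skipped with a warning.
#'
#' @param costs a [cost_table()] data.frame.
#' @param metric cost column: `"glc"`, `"flc"`, `"hybrid1"` or `"hybrid2"`.
#' @param khat named vector from [average_rank_rate()].
#' @param genes gene subset (default: all genes in the table).
#' @return object of class `correlation_distribution`: list with `metric`,
#'   `rho` (named per medium), `mean`, `sd`.
#' @export
correlation_distribution <- function(costs, metric, khat, genes = NULL) {
  stopifnot(metric %in% c("glc", "flc", "hybrid1", "hybrid2"))
  if (is.null(genes)) genes <- unique(costs$gene)
  costs <- costs[costs$gene %in% genes, , drop = FALSE]
  rhos <- c()
  for (m in unique(costs$medium)) {
    d <- costs[costs$medium == m, , drop = FALSE]
    x <- d[[metric]]
    y <- khat[d$gene]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning("medium '", m, "' skipped for metric ", metric,
              ": <3 genes with data or zero variance")
      next
    }
    rhos[m] <- spearman_rho(x, y)
  }
  structure(list(metric = metric, rho = rhos,
                 mean = mean(rhos), sd = stats::sd(rhos)),
            class = "correlation_distribution")
}

#' @export
print.correlation_distribution <- function(x, ...) {
  cat("<correlation_distribution> ", x$metric, ": mean rho ",
      format(x$mean, digits = 3), " (sd ", format(x$sd, digits = 3),
      ") over ", length(x$rho), " media\n", sep = "")
  invisible(x)
}

#' Label isoenzymes as fast-, slow-, or neutral-evolving within their set
#'
#' In each isoenzyme set with at least two rated members, the member with
#' the highest averaged rank is labelled fast-evolving, the lowest slow-
#' evolving, and the rest neutral. Ties are broken by identifier order
#' (first id wins) with a warning. A gene in several sets takes its
#' majority label; a tied majority is resolved by the order fast, slow,
#' neutral, with a warning.
#'
#' @param sets list of isoenzyme sets (see [isoenzyme_sets()]).
#' @param khat named vector from [average_rank_rate()].
#' @return named character vector gene -> `"fast"`, `"slow"` or `"neutral"`.
#' @export
classify_isoenzyme_speed <- function(sets, khat) {
  labels <- list()
  for (s in sets) {
    s <- sort(s)
    rated <- s[s %in% names(khat)]
    lab <- stats::setNames(rep("neutral", length(s)), s)
    if (length(rated) >= 2) {
      v <- khat[rated]
      if (sum(v == max(v)) > 1 || sum(v == min(v)) > 1) {
        warning("tied rates in isoenzyme set {", paste(s, collapse = ","),
                "}; broken by identifier order")
      }
      fast_g <- rated[which.max(v)]
      rest <- setdiff(rated, fast_g)
      slow_g <- rest[which.min(khat[rest])]
      lab[fast_g] <- "fast"
      lab[slow_g] <- "slow"
    }
    for (g in names(lab)) labels[[g]] <- c(labels[[g]], lab[[g]])
  }
  vapply(labels, function(v) {
    tab <- table(factor(v, levels = c("fast", "slow", "neutral")))
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1 && length(v) > 1) {
      warning("tied majority label; resolved in order fast/slow/neutral")
    }
    top[1]
  }, character(1))
}

#' Compare two per-medium correlation distributions
#'
#' Paired Wilcoxon signed-rank test on the per-medium rho values, matched by
#' medium name.
#'
#' @param d1,d2 `correlation_distribution` objects over the same media.
#' @return list: `statistic`, `p_value`, `mean_difference` (d2 - d1 means),
#'   `n` media compared.
#' @export
compare_distributions <- function(d1, d2) {
  common <- intersect(names(d1$rho), names(d2$rho))
  if (length(common) == 0) stop("no common media between distributions")
  a <- d1$rho[common]
  b <- d2$rho[common]
  if (isTRUE(all.equal(a, b))) {
    return(list(statistic = NA_real_, p_value = 1,
                mean_difference = 0, n = length(common)))
  }
  ht <- suppressWarnings(stats::wilcox.test(b, a, paired = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       mean_difference = mean(b) - mean(a), n = length(common))
}
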