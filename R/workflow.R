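#' End-to-end cost-vs-evolutionary-rate correlation study
#'
#' Runs the full single-deletion pipeline on one model: blocked-reaction
#' detection (on the supplied media plus an all-open environment), gene
#' classification, the cost table over all media, rank-averaging of the rate
#' table, and per-medium Spearman correlation distributions for each cost
#' metric and gene subset.
#'
#' @param model a `metabolic_model`.
#' @param rates data.frame (`gene`, `species`, `dnds`) or path to such a TSV.
#' @param media a `media_set` or list of [medium()] objects.
#' @param subsets gene subsets to analyse (see [gene_subset()]).
#' @param metrics cost columns to correlate.
#' @param blocked blocked reaction ids; `NULL` (default) to detect them.
#' @return list: `costs`, `catalog`, `blocked`, `khat`, `distributions`
#'   (nested list metric -> subset -> `correlation_distribution`), and
#'   `summary` (long data.frame of mean/sd rho).
#' @export
run_correlation_study <- function(model, rates, media,
                                  subsets = c("all", "non_isoenzymes",
                                              "isoenzymes",
                                              "multifunctional_non_isoenzymes"),
                                  metrics = c("glc", "flc", "hybrid1", "hybrid2"),
                                  blocked = NULL) {
  if (is.character(rates)) rates <- read_rates_tsv(rates)
  if (inherits(media, "media_set")) media <- media$media
  if (inherits(media, "medium")) media <- list(media)
  model <- cache_dense(model)
  if (is.null(blocked)) {
    open_all <- medium("all_open",
                       stats::setNames(rep(Inf, length(exchange_reactions(model))),
                                       exchange_reactions(model)))
    blocked <- find_blocked_reactions(model, c(media, list(open_all)))
  }
  catalog <- classify_genes(model, blocked)
  costs <- cost_table(model, media, blocked = blocked, catalog = catalog)
  khat <- average_rank_rate(rates)
  distributions <- list()
  rows <- list()
  for (metric in metrics) {
    distributions[[metric]] <- list()
    for (ss in subsets) {
      genes <- gene_subset(catalog, ss)
      d <- tryCatch(
        suppressWarnings(correlation_distribution(costs, metric, khat, genes)),
        error = function(e) NULL)
      if (is.null(d) || length(d$rho) == 0) {
        warning("subset '", ss, "' for metric ", metric, " skipped")
        next
      }
      distributions[[metric]][[ss]] <- d
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, subset = ss, mean_rho = d$mean, sd_rho = d$sd,
        n_media = length(d$rho), stringsAsFactors = FALSE)
    }
  }
  list(costs = costs, catalog = catalog, blocked = blocked, khat = khat,
       distributions = distributions, summary = do.call(rbind, rows))
}

#' End-to-end epistasis prediction study
#'
#' Predicts pairwise epistasis for the experimental table's pairs under both
#' GPR semantics, applies the single-mutant fitness filter and the
#' experimental classification, and scores predictions (confusion matrices,
#' precision/recall, Fisher enrichment, precision-recall curves over the
#' cutoff grid).
#'
#' @param model a `metabolic_model`.
#' @param experimental data.frame (`gene_i`, `gene_j`, `epsilon`, `p_value`,
#'   `fitness_i`, `fitness_j`) or path to such a TSV.
#' @param med [medium()] mimicking the experimental condition.
#' @param wt_fitness,wt_sd experimental wild-type fitness and its sd for
#'   [filter_deletion_fitness()].
#' @param cutoff prediction cutoff (default 1e-4).
#' @param eps_cutoff,p_cutoff experimental classification cutoffs.
#' @return list: `pairs` (filtered table with experimental classes),
#'   `predictions` (list redundant / nonredundant), `comparison` (list of
#'   `interaction_comparison`), `pr_curves` (list of data.frames).
#' @export
run_epistasis_study <- function(model, experimental, med,
                                wt_fitness = 1, wt_sd = 0,
                                cutoff = 1e-4, eps_cutoff = 0.08,
                                p_cutoff = 0.05) {
  if (is.character(experimental)) {
    experimental <- utils::read.delim(experimental, stringsAsFactors = FALSE)
  }
  if (nrow(experimental) == 0) {
    return(list(pairs = experimental, predictions = list(),
                comparison = list(), pr_curves = list()))
  }
  keep <- experimental[experimental$gene_i %in% model$genes &
                       experimental$gene_j %in% model$genes, , drop = FALSE]
  keep <- filter_deletion_fitness(keep, wt_fitness, wt_sd)
  keep$experimental_class <- classify_experimental(keep$epsilon, keep$p_value,
                                                   eps_cutoff, p_cutoff)
  predictions <- comparison <- pr_curves <- list()
  for (sem in c("redundant", "nonredundant")) {
    pred <- predict_pairwise(model, keep[, c("gene_i", "gene_j")], med,
                             semantics = sem, cutoff = cutoff)
    predictions[[sem]] <- pred
    comparison[[sem]] <- compare_with_experiment(pred, keep$experimental_class)
    pr_curves[[sem]] <- precision_recall_curve(pred, keep$experimental_class)
  }
  list(pairs = keep, predictions = predictions, comparison = comparison,
       pr_curves = pr_curves)
}

#' Build a run manifest
#'
#' Records what a workflow run consumed and produced: the command label,
#' seed, input/output file digests (md5), and per-stage timings. Identical
#' inputs reproduce identical output digests for deterministic stages.
#'
#' @param command free-text command label.
#' @param inputs,outputs named character vectors of file paths (digested
#'   when the files exist).
#' @param seed integer seed used (if any).
#' @param timings named numeric vector of stage timings (seconds).
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(command, inputs = character(0),
                         outputs = character(0), seed = NULL,
                         timings = numeric(0)) {
  digest_files <- function(paths) {
    if (length(paths) == 0) return(list())
    md5 <- tools::md5sum(paths[file.exists(paths)])
    as.list(stats::setNames(unname(md5), names(paths)[file.exists(paths)]))
  }
  structure(list(
    command = command,
    version = as.character(utils::packageVersion("fluxcost")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = digest_files(inputs),
    outputs = digest_files(outputs),
    timings = as.list(timings)
  ), class = "run_manifest")
}

#' Write a run manifest to JSON
#'
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
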