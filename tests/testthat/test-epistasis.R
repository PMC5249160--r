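test_that("epistasis score follows the multiplicative model", {
  expect_equal(epistasis_score(1, 1, 0), -1)        # synthetic lethal
  expect_equal(epistasis_score(0.5, 0.5, 0.25), 0)  # multiplicative
  expect_equal(epistasis_score(0.5, 0.5, 0.5), 0.25)
})

test_that("prediction and experimental classification apply their cutoffs", {
  expect_equal(classify_prediction(-0.5), "synergistic")
  expect_equal(classify_prediction(0), "none")
  expect_equal(classify_prediction(0.00005), "none")
  expect_equal(classify_prediction(0.001), "antagonistic")
  expect_equal(classify_experimental(-0.2, 0.001), "synergistic")
  expect_equal(classify_experimental(-0.2, 0.2), "none")
  expect_equal(classify_experimental(0.05, 0.001), "none")
  expect_equal(classify_experimental(0.2, 0.01), "antagonistic")
})

test_that("fitness filter keeps pairs up to wt + 2 sd inclusive", {
  tab <- data.frame(gene_i = c("a", "b", "c"), gene_j = c("x", "y", "z"),
                    fitness_i = c(1, 1.2, 1.06), fitness_j = c(1, 1, 1))
  out <- filter_deletion_fitness(tab, wt_fitness = 1, wt_sd = 0.03)
  expect_setequal(out$gene_i, c("a", "c"))   # 1.06 = wt + 2 sd exactly: kept
})

test_that("isoenzyme pair epistasis flips from -1 to 0 with semantics", {
  m <- make_scenario_model("isoenzyme")
  med <- attr(m, "default_medium")
  pair <- data.frame(gene_i = "g1", gene_j = "g2")
  red <- predict_pairwise(m, pair, med, semantics = "redundant")
  expect_equal(red$w_i, 1)
  expect_equal(red$w_j, 1)
  expect_equal(red$w_ij, 0)
  expect_equal(red$epsilon, -1)
  expect_equal(red$predicted_class, "synergistic")
  nr <- predict_pairwise(m, pair, med, semantics = "nonredundant")
  expect_equal(nr$w_i, 0)   # singles already lethal
  expect_equal(nr$epsilon, 0)
  expect_equal(nr$predicted_class, "none")
})

test_that("independent fully-bypassable branches show no epistasis", {
  m <- independent_branch_model()
  med <- medium("min", c(EX_A = 10))
  p <- predict_pairwise(m, data.frame(gene_i = "g1", gene_j = "g2"), med)
  expect_equal(p$epsilon, 0)
  expect_equal(p$predicted_class, "none")
})

test_that("epsilon is symmetric in gene order", {
  m <- make_random_toy_model(fixture_spec(n_genes = 30, n_carbon = 2,
                                          n_nitrogen = 2, seed = 6))
  med <- attr(m, "default_medium")
  set.seed(41)
  gs <- t(replicate(8, sample(m$genes, 2)))
  a <- predict_pairwise(m, data.frame(gene_i = gs[, 1], gene_j = gs[, 2]), med,
                        semantics = "nonredundant")
  b <- predict_pairwise(m, data.frame(gene_i = gs[, 2], gene_j = gs[, 1]), med,
                        semantics = "nonredundant")
  expect_equal(a$epsilon, b$epsilon)
})

test_that("redundant semantics mask interactions of lone isoenzyme members", {
  # an isoenzyme member paired with an unrelated gene: no necessary reaction,
  # so epsilon is exactly zero under the backup assumption
  m <- metabolic_model(list(
    list(id = "EX_A", metabolites = c(A = -1), lb = -10, ub = 1000),
    list(id = "R1", metabolites = c(A = -1, B = 1), lb = 0, ub = 1000,
         gpr = "g1 or g2"),
    list(id = "R2", metabolites = c(B = -1, C = 1), lb = 0, ub = 1000,
         gpr = "g3"),
    list(id = "GROWTH", metabolites = c(C = -1), lb = 0, ub = 1000)
  ), objective = "GROWTH")
  med <- medium("min", c(EX_A = 10))
  red <- predict_pairwise(m, data.frame(gene_i = "g1", gene_j = "g3"), med,
                          semantics = "redundant")
  expect_equal(red$epsilon, 0)
  # under non-redundancy the masked interaction surfaces
  nr <- predict_pairwise(m, data.frame(gene_i = "g1", gene_j = "g3"), med,
                         semantics = "nonredundant")
  expect_true(abs(nr$epsilon) > 1e-4 || nr$w_i == 0)
})

test_that("confusion matrix, precision and recall score degenerate cases", {
  classes <- c("synergistic", "antagonistic", "none", "synergistic")
  perfect <- compare_with_experiment(classes, classes)
  expect_equal(unname(perfect$precision), c(1, 1, 1))
  expect_equal(unname(perfect$recall), c(1, 1, 1))
  expect_equal(sum(perfect$confusion), 4)
  all_none <- compare_with_experiment(rep("none", 4), classes)
  expect_equal(unname(all_none$recall[c("synergistic", "antagonistic")]), c(0, 0))
  expect_true(is.na(all_none$precision[["synergistic"]]))
})

test_that("fisher enrichment p matches the hypergeometric oracle", {
  set.seed(47)
  for (i in 1:25) {
    n <- sample(8:50, 1)
    pred_in <- runif(n) < runif(1, 0.2, 0.8)
    exp_in <- runif(n) < runif(1, 0.2, 0.8)
    tab <- table(factor(pred_in, levels = c(TRUE, FALSE)),
                 factor(exp_in, levels = c(TRUE, FALSE)))
    got <- stats::fisher.test(tab, alternative = "greater")$p.value
    expect_equal(got, fisher_greater_oracle(tab), tolerance = 1e-9)
  }
})

test_that("precision-recall curves behave monotonically at the extremes", {
  set.seed(53)
  preds <- data.frame(epsilon = c(runif(20, -0.5, 0.5), rep(0, 5)))
  expcl <- sample(c("synergistic", "antagonistic", "none"), 25, replace = TRUE)
  curve <- precision_recall_curve(preds, expcl,
                                  cutoffs = c(1e-4, 1e-3, 1e-2, 1))
  for (cl in c("synergistic", "antagonistic")) {
    d <- curve[curve$class == cl, ]
    d <- d[order(d$cutoff), ]
    # recall never increases as the cutoff grows
    expect_true(all(diff(d$recall[!is.na(d$recall)]) <= 1e-12))
  }
  # cutoff above max |epsilon|: nothing predicted, recall 0
  top <- precision_recall_curve(preds, expcl, cutoffs = 1)
  expect_true(all(top$n_predicted == 0))
  expect_true(all(top$recall[!is.na(top$recall)] == 0))
})
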