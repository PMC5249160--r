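rates_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene = r[[1]], species = r[[2]], dnds = as.numeric(r[[3]]),
               stringsAsFactors = FALSE)
  }))
}

test_that("rank averaging reproduces forced arithmetic and handles gaps", {
  # species1 ranks a,b,c = 1,2,3; species2 ranks = 3,1,2
  df <- rates_df(list("a", "s1", 0.1), list("b", "s1", 0.2), list("c", "s1", 0.3),
                 list("a", "s2", 0.9), list("b", "s2", 0.2), list("c", "s2", 0.5))
  kh <- average_rank_rate(df)
  expect_equal(kh[["a"]], 2)
  expect_equal(kh[["b"]], 1.5)
  expect_equal(kh[["c"]], 2.5)
  # gene with data in only some species: mean over those species only
  df2 <- rbind(df, rates_df(list("d", "s1", 0.15)))
  kh2 <- average_rank_rate(df2)
  expect_equal(kh2[["d"]], 2)  # rank 2 of 4 in s1 alone
  # gene with no data anywhere is excluded and reported
  df3 <- rbind(df, data.frame(gene = "e", species = "s1", dnds = NA))
  kh3 <- average_rank_rate(df3)
  expect_false("e" %in% names(kh3))
  expect_identical(attr(kh3, "excluded"), "e")
})

test_that("rank averaging is invariant under monotone per-species transforms", {
  set.seed(31)
  df <- do.call(rbind, lapply(1:3, function(s) {
    data.frame(gene = sprintf("g%d", 1:10), species = paste0("s", s),
               dnds = runif(10), stringsAsFactors = FALSE)
  }))
  kh <- average_rank_rate(df)
  df2 <- df
  df2$dnds <- ifelse(df2$species == "s1", exp(df2$dnds),
                     ifelse(df2$species == "s2", df2$dnds^3, 10 * df2$dnds + 2))
  expect_equal(average_rank_rate(df2), kh)
})

test_that("spearman matches the rank-formula oracle, with and without ties", {
  expect_equal(spearman_rho(1:3, 3:1), -1)
  expect_equal(spearman_rho(1:3, 1:3), 1)
  set.seed(17)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    x <- sample(1:5, n, replace = TRUE)   # ties guaranteed
    y <- sample(1:5, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_rho(x, y), spearman_oracle(x, y), tolerance = 1e-12)
  }
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("correlation distributions recover a planted anticorrelation", {
  m <- make_random_toy_model(fixture_spec(n_genes = 60, n_carbon = 3,
                                          n_nitrogen = 2, seed = 2))
  ms <- enumerate_minimal_media(m, attr(m, "default_medium"),
                                attr(m, "carbon_exchanges")[1],
                                attr(m, "nitrogen_exchanges")[1])
  ct <- cost_table(m, ms)
  rates <- make_synthetic_rates(ct, noise_sd = 0.3, seed = 2)
  kh <- average_rank_rate(rates)
  d <- correlation_distribution(ct, "flc", kh)
  expect_equal(length(d$rho), length(ms$media))
  expect_true(all(abs(d$rho) <= 1))
  expect_lt(d$mean, -0.5)
  # permuted rates carry no signal
  set.seed(99)
  kh_perm <- setNames(sample(as.numeric(kh)), names(kh))
  dp <- correlation_distribution(ct, "flc", kh_perm)
  expect_lt(abs(dp$mean), 0.3)
  # constant-cost subset: media skipped with a warning
  const_genes <- names(which(tapply(ct$flc, ct$gene, function(v) all(v == 0))))
  if (length(const_genes) >= 3) {
    expect_warning(correlation_distribution(ct, "flc", kh, const_genes),
                   "zero variance|skipped")
  }
})

test_that("gene subsets mirror the analysis panels", {
  catalog <- data.frame(
    gene = c("a", "b", "c", "d"),
    n_reactions = c(1, 2, 1, 1), n_unblocked = c(1, 2, 1, 0),
    is_isoenzyme = c(TRUE, FALSE, FALSE, FALSE),
    is_multifunctional = c(FALSE, TRUE, FALSE, FALSE),
    is_blocked_only = c(FALSE, FALSE, FALSE, TRUE))
  expect_setequal(gene_subset(catalog, "all"), c("a", "b", "c"))
  expect_setequal(gene_subset(catalog, "non_isoenzymes"), c("b", "c"))
  expect_setequal(gene_subset(catalog, "isoenzymes"), "a")
  expect_setequal(gene_subset(catalog, "multifunctional_non_isoenzymes"), "b")
})

test_that("fast/slow isoenzyme labels follow within-set extremes", {
  kh <- c(a = 5, b = 2, c = 3, x = 5, y = 5)
  lab <- classify_isoenzyme_speed(list(c("a", "b")), kh)
  expect_equal(lab[["a"]], "fast")
  expect_equal(lab[["b"]], "slow")
  lab3 <- classify_isoenzyme_speed(list(c("a", "b", "c")), kh)
  expect_equal(lab3[["c"]], "neutral")
  # tie broken by identifier order, with a warning
  expect_warning(labt <- classify_isoenzyme_speed(list(c("x", "y")), kh), "tie")
  expect_equal(labt[["x"]], "fast")
  expect_equal(labt[["y"]], "slow")
  # fewer than two rated members: all neutral
  labn <- classify_isoenzyme_speed(list(c("a", "z")), kh)
  expect_equal(unname(labn[c("a", "z")]), c("neutral", "neutral"))
})

test_that("distribution comparison detects shifts and matches the exact oracle", {
  set.seed(23)
  rho <- setNames(runif(10, -0.5, -0.1), paste0("m", 1:10))
  d1 <- structure(list(metric = "glc", rho = rho, mean = mean(rho), sd = sd(rho)),
                  class = "correlation_distribution")
  d2 <- d1; d2$rho <- d1$rho - 0.1
  cmp <- compare_distributions(d1, d2)
  expect_lt(cmp$p_value, 0.01)
  expect_lt(cmp$mean_difference, 0)
  expect_equal(compare_distributions(d1, d1)$p_value, 1)
  # Wilcoxon p agrees with full sign-flip enumeration (n <= 12, no ties)
  # continuous draws: ties in |differences| would forfeit the exact path
  for (i in 1:10) {
    n <- sample(5:12, 1)
    x <- runif(n, 0, 10)
    y <- x + rnorm(n, 0.3, 1)
    got <- suppressWarnings(stats::wilcox.test(y, x, paired = TRUE, exact = TRUE))
    ora <- wilcoxon_signed_rank_oracle(y, x)
    expect_equal(unname(got$statistic), ora$statistic)
    expect_equal(got$p.value, ora$p_value, tolerance = 1e-12)
  }
})
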