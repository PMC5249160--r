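# Independent oracles and small fixture builders shared across tests.
# Each oracle deliberately takes a different computational route from the
# implementation it checks.

# -- LP oracle: enumerate candidate vertices of {Ax = b, l <= x <= u} --------
# A vertex fixes n - m variables at bounds; enumerate all basic subsets and
# bound assignments, solve the square system, keep feasible points.
lp_vertex_oracle <- function(obj, A, b, lb, ub) {
  A <- as.matrix(A)
  n <- ncol(A); m <- nrow(A)
  best <- -Inf; feasible <- FALSE
  combos <- utils::combn(n, min(m, n), simplify = FALSE)
  for (basic in combos) {
    nb <- setdiff(seq_len(n), basic)
    grid <- if (length(nb)) expand.grid(rep(list(c(1, 2)), length(nb)))
            else data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      xn <- numeric(length(nb))
      for (k in seq_along(nb)) xn[k] <- if (grid[g, k] == 1) lb[nb[k]] else ub[nb[k]]
      rhs <- b - if (length(nb)) A[, nb, drop = FALSE] %*% xn else 0
      xb <- tryCatch(solve(A[, basic, drop = FALSE], rhs), error = function(e) NULL)
      if (is.null(xb)) next
      x <- numeric(n); x[nb] <- xn; x[basic] <- xb
      if (all(x >= lb - 1e-8) && all(x <= ub + 1e-8)) {
        feasible <- TRUE
        best <- max(best, sum(obj * x))
      }
    }
  }
  list(feasible = feasible, objective = best)
}

# small random flux networks (<= 6 reactions) with a guaranteed feasible point
random_small_network <- function(seed) {
  set.seed(seed)
  m <- sample(1:3, 1)
  n <- m + sample(1:3, 1)           # n <= 6
  A <- matrix(round(runif(m * n, -2, 2), 1), m, n)
  lb <- round(runif(n, -5, 0), 1)
  ub <- lb + round(runif(n, 0, 6), 1)
  x0 <- lb + runif(n) * (ub - lb)
  list(A = A, b = as.numeric(A %*% x0), lb = lb, ub = ub,
       obj = round(runif(n, -3, 3), 1))
}

# -- GPR truth-table oracle: evaluate via a generated R boolean expression ---
gpr_to_r_expression <- function(expr) {
  if (expr$type == "gene") return(sprintf("`%s`", expr$gene))
  op <- if (expr$type == "and") " & " else " | "
  paste0("(", paste(vapply(expr$children, gpr_to_r_expression, character(1)),
                    collapse = op), ")")
}

eval_gpr_oracle <- function(expr, present) {
  genes <- gpr_genes(expr)
  env <- as.list(stats::setNames(genes %in% present, genes))
  eval(parse(text = gpr_to_r_expression(expr)), envir = env)
}

random_gpr_tree <- function(genes, depth = 2) {
  if (depth == 0 || (length(genes) == 1) || runif(1) < 0.3) {
    return(parse_gpr(sample(genes, 1)))
  }
  k <- sample(2:min(3, length(genes)), 1)
  kids <- lapply(seq_len(k), function(i) random_gpr_tree(genes, depth - 1))
  structure(list(type = sample(c("and", "or"), 1), children = kids),
            class = "gpr_expr")
}

# -- Spearman oracle: Pearson product-moment formula on hand-built ranks -----
avg_rank <- function(v) {
  # average ranks computed from scratch via pairwise comparisons
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }, numeric(1))
}

spearman_oracle <- function(x, y) {
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# -- Wilcoxon signed-rank oracle: enumerate all 2^n sign assignments --------
wilcoxon_signed_rank_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- avg_rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vdist <- apply(signs, 1, function(s) sum(r[s == 1]))
  p <- min(2 * min(mean(vdist <= v_obs), mean(vdist >= v_obs)), 1)
  list(statistic = v_obs, p_value = p)
}

# -- Fisher one-sided oracle: hypergeometric tail from binomial coefficients -
fisher_greater_oracle <- function(tab) {
  # tab: 2x2, rows = predicted in/out, cols = experimental in/out
  x <- tab[1, 1]
  m1 <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  total <- sum(tab)
  probs <- vapply(max(0, k - n2):min(m1, k), function(i) {
    choose(m1, i) * choose(n2, k - i) / choose(total, k)
  }, numeric(1))
  names(probs) <- max(0, k - n2):min(m1, k)
  sum(probs[as.numeric(names(probs)) >= x])
}

# -- tiny hand-built models --------------------------------------------------
chain_model <- function() {
  metabolic_model(list(
    list(id = "EX_A", metabolites = c(A = -1), lb = -10, ub = 1000),
    list(id = "R1", metabolites = c(A = -1, B = 1), lb = 0, ub = 1000, gpr = "g1"),
    list(id = "GROWTH", metabolites = c(B = -1), lb = 0, ub = 1000)
  ), objective = "GROWTH")
}

# two genes on parallel, individually fully-bypassable branches
independent_branch_model <- function() {
  metabolic_model(list(
    list(id = "EX_A", metabolites = c(A = -1), lb = -1000, ub = 1000),
    list(id = "R1", metabolites = c(A = -1, B = 1), lb = 0, ub = 1000, gpr = "g1"),
    list(id = "B1", metabolites = c(A = -1, B = 1), lb = 0, ub = 1000),
    list(id = "R2", metabolites = c(B = -1, C = 1), lb = 0, ub = 1000, gpr = "g2"),
    list(id = "B2", metabolites = c(B = -1, C = 1), lb = 0, ub = 1000),
    list(id = "GROWTH", metabolites = c(C = -1), lb = 0, ub = 1000)
  ), objective = "GROWTH")
}

toy_json_path <- function() {
  system.file("extdata", "toy_fbc.json", package = "fluxcost")
}
toy_sbml_path <- function() {
  system.file("extdata", "toy_fbc.xml", package = "fluxcost")
}
toy_media_path <- function() {
  system.file("extdata", "toy_media.json", package = "fluxcost")
}
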