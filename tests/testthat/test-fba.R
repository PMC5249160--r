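test_that("FBA reproduces hand-solved optima on chain and branch models", {
  m <- chain_model()
  expect_equal(solve_fba(m)$objective, 10)
  expect_equal(solve_fba(m, blocked = "R1")$objective, 0)

  mb <- make_scenario_model("branch")
  med <- attr(mb, "default_medium")
  expect_equal(solve_fba(mb, med)$objective, 10)
  # bottleneck at the capacity-4 bypass once the direct branch is blocked
  expect_equal(solve_fba(mb, med, blocked = "R2")$objective, 4)
})

test_that("optimal solutions are mass balanced within tolerance", {
  for (sc in c("complex", "isoenzyme", "multifunctional", "branch")) {
    m <- make_scenario_model(sc)
    sol <- solve_fba(m, attr(m, "default_medium"))
    expect_equal(sol$status, "optimal")
    expect_lt(max(abs(as.matrix(m$S) %*% sol$fluxes)), 1e-6)
  }
})

test_that("adding knockouts never increases the optimum", {
  m <- make_scenario_model("multifunctional")
  med <- attr(m, "default_medium")
  rids <- reaction_ids(m)
  set.seed(5)
  for (i in 1:20) {
    a <- sample(rids, sample(0:2, 1))
    b <- union(a, sample(rids, 1))
    expect_lte(solve_fba(m, med, blocked = b)$objective,
               solve_fba(m, med, blocked = a)$objective + 1e-9)
  }
})

test_that("infeasible knockouts report zero growth", {
  # a maintenance-like forced flux (lb > 0) downstream of R1: blocking R1
  # leaves no way to satisfy it, so the LP is infeasible
  m <- metabolic_model(list(
    list(id = "EX_A", metabolites = c(A = -1), lb = -10, ub = 1000),
    list(id = "R1", metabolites = c(A = -1, B = 1), lb = 0, ub = 1000),
    list(id = "MAINT", metabolites = c(B = -1), lb = 1, ub = 1000),
    list(id = "R2", metabolites = c(B = -1, C = 1), lb = 0, ub = 1000),
    list(id = "GROWTH", metabolites = c(C = -1), lb = 0, ub = 1000)
  ), objective = "GROWTH")
  expect_gt(solve_fba(m)$objective, 0)
  sol <- solve_fba(m, blocked = "R1")
  expect_equal(sol$status, "infeasible")
  expect_equal(sol$objective, 0)
  # blocking a reaction that itself has a forced bound replaces the bound
  # (alpha = 0 <= v <= beta = 0): feasible, zero growth
  sol2 <- solve_fba(m, blocked = "MAINT")
  expect_equal(sol2$status, "optimal")
})

test_that("blocked-reaction detection finds dead ends but not active paths", {
  m <- metabolic_model(list(
    list(id = "EX_A", metabolites = c(A = -1), lb = -10, ub = 1000),
    list(id = "R1", metabolites = c(A = -1, B = 1), lb = 0, ub = 1000),
    list(id = "DEAD", metabolites = c(A = -1, D = 1), lb = 0, ub = 1000),
    list(id = "GROWTH", metabolites = c(B = -1), lb = 0, ub = 1000)
  ), objective = "GROWTH")
  med <- medium("min", c(EX_A = 10))
  blocked <- find_blocked_reactions(m, med)
  expect_true("DEAD" %in% blocked)   # D has no consumer: steady state forces 0
  expect_false("R1" %in% blocked)    # carries wild-type flux
  expect_error(find_blocked_reactions(m, list()), "at least one")
})

test_that("a reaction usable in only one medium is not blocked across the set", {
  m <- metabolic_model(list(
    list(id = "EX_A", metabolites = c(A = -1), lb = -1000, ub = 1000),
    list(id = "EX_B", metabolites = c(B = -1), lb = -1000, ub = 1000),
    list(id = "RA", metabolites = c(A = -1, C = 1), lb = 0, ub = 1000),
    list(id = "RB", metabolites = c(B = -1, C = 1), lb = 0, ub = 1000),
    list(id = "GROWTH", metabolites = c(C = -1), lb = 0, ub = 1000)
  ), objective = "GROWTH")
  med1 <- medium("onlyA", c(EX_A = 10))
  med2 <- medium("onlyB", c(EX_B = 10))
  expect_true("RB" %in% find_blocked_reactions(m, med1))
  expect_false("RB" %in% find_blocked_reactions(m, list(med1, med2)))
})

test_that("gene knockouts translate through GPR semantics", {
  m <- make_scenario_model("isoenzyme")
  expect_equal(knockout_reactions_for_gene(m, "g1", "redundant"), character(0))
  expect_equal(knockout_reactions_for_gene(m, "g1", "nonredundant"), "R1")
  mc <- make_scenario_model("complex")
  expect_equal(knockout_reactions_for_gene(mc, "g1", "redundant"), "R1")
  expect_equal(knockout_reactions_for_gene(mc, "g1", "nonredundant"), "R1")
  expect_error(knockout_reactions_for_gene(m, "gX"), "unknown genes")
  # joint deletion: the isoenzyme pair jointly falsifies the rule
  expect_equal(knockout_reactions_for_genes(m, c("g1", "g2"), "redundant"), "R1")
})

test_that("knockout of a gene with no necessary reaction leaves wild type intact", {
  m <- make_scenario_model("isoenzyme")
  med <- attr(m, "default_medium")
  wt <- solve_fba(m, med)$objective
  ko <- solve_fba(m, med,
                  blocked = knockout_reactions_for_gene(m, "g1", "redundant"))
  expect_identical(ko$objective, wt)
})

test_that("media bounds honour uptake caps and export-only defaults", {
  m <- chain_model()
  expect_equal(solve_fba(m, medium("cap3", c(EX_A = 3)))$objective, 3)
  # unlisted exchange: export only, so nothing can be imported
  m2 <- metabolic_model(list(
    list(id = "EX_A", metabolites = c(A = -1), lb = -1000, ub = 1000),
    list(id = "EX_B", metabolites = c(B = -1), lb = -1000, ub = 1000),
    list(id = "R1", metabolites = c(A = -1, C = 1), lb = 0, ub = 1000),
    list(id = "R2", metabolites = c(B = -1, C = 1), lb = 0, ub = 1000),
    list(id = "GROWTH", metabolites = c(C = -1), lb = 0, ub = 1000)
  ), objective = "GROWTH")
  expect_equal(solve_fba(m2, medium("onlyA", c(EX_A = 5)))$objective, 5)
  expect_equal(solve_fba(m2, medium("both", c(EX_A = 5, EX_B = 2)))$objective, 7)
  expect_error(solve_fba(m2, medium("bad", c(EX_Z = 5))), "unknown exchanges")
  expect_error(solve_fba(m2, medium("bad", c(R1 = 5))), "non-exchange")
  expect_error(medium("neg", c(EX_A = -1)), ">= 0")
})
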