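# a two-carbon-entry toy: glucose-like and pyruvate-like both feed the
# carbon branch; a sulfate-like exchange cannot provide carbon
two_carbon_model <- function() {
  metabolic_model(list(
    list(id = "EX_glc", metabolites = c(glc = -1), lb = -1000, ub = 1000),
    list(id = "EX_pyr", metabolites = c(pyr = -1), lb = -1000, ub = 1000),
    list(id = "EX_so4", metabolites = c(so4 = -1), lb = -1000, ub = 1000),
    list(id = "EX_nh4", metabolites = c(nh4 = -1), lb = -1000, ub = 1000),
    list(id = "CG", metabolites = c(glc = -1, C = 1), lb = 0, ub = 1000),
    list(id = "CP", metabolites = c(pyr = -1, C = 1), lb = 0, ub = 1000),
    list(id = "N1", metabolites = c(nh4 = -1, N = 1), lb = 0, ub = 1000),
    list(id = "SU", metabolites = c(so4 = -1, S = 1), lb = 0, ub = 1000),
    list(id = "GROWTH", metabolites = c(C = -1, N = -1, S = -1), lb = 0, ub = 1000)
  ), objective = "GROWTH")
}

two_carbon_reference <- function() {
  medium("ref", c(EX_glc = 10, EX_nh4 = 10, EX_so4 = Inf))
}

test_that("alternative sources are found by exhaustive substitution", {
  m <- two_carbon_model()
  ref <- two_carbon_reference()
  carbons <- find_alternative_sources(m, ref, "EX_glc")
  expect_setequal(carbons, c("EX_glc", "EX_pyr"))
  # nitrogen: only the original source works
  expect_setequal(find_alternative_sources(m, ref, "EX_nh4"), "EX_nh4")
  expect_error(find_alternative_sources(m, medium("bad", c(EX_glc = 0)), "EX_glc"),
               "does not support growth")
  expect_error(find_alternative_sources(m, ref, "EX_pyr"), "not in the reference")
})

test_that("minimal media enumeration crosses carbons with nitrogens", {
  m <- two_carbon_model()
  ref <- two_carbon_reference()
  ms <- enumerate_minimal_media(m, ref, "EX_glc", "EX_nh4")
  expect_s3_class(ms, "media_set")
  expect_length(ms$media, 2)  # 2 carbons x 1 nitrogen
  expect_true(all(c("EX_glc|EX_nh4", "EX_pyr|EX_nh4") %in% names(ms$media)))
  # every emitted medium supports growth and retains secondary nutrients
  for (med in ms$media) {
    expect_gt(solve_fba(m, med)$objective, 1e-6)
    expect_true("EX_so4" %in% names(med$uptake))
  }
  # enumeration is order-independent
  ms2 <- enumerate_minimal_media(m, ref, "EX_glc", "EX_nh4",
                                 carbon_sources = c("EX_pyr", "EX_glc"),
                                 nitrogen_sources = "EX_nh4")
  expect_setequal(names(ms2$media), names(ms$media))
})

test_that("non-growing pairings are dropped; a 1x1 grid is the reference", {
  m <- two_carbon_model()
  ref <- two_carbon_reference()
  # sulfate cannot serve as carbon: pairing fails the growth test
  ms <- enumerate_minimal_media(m, ref, "EX_glc", "EX_nh4",
                                carbon_sources = c("EX_glc", "EX_so4"),
                                nitrogen_sources = "EX_nh4")
  expect_length(ms$media, 1)
  ms1 <- enumerate_minimal_media(m, ref, "EX_glc", "EX_nh4",
                                 carbon_sources = "EX_glc",
                                 nitrogen_sources = "EX_nh4")
  expect_length(ms1$media, 1)
  med <- ms1$media[[1]]
  expect_setequal(names(med$uptake), names(ref$uptake))
})

test_that("dual-role single sources are permitted unless disabled", {
  # one amino-acid-like metabolite feeds both pools
  m <- metabolic_model(list(
    list(id = "EX_glc", metabolites = c(glc = -1), lb = -1000, ub = 1000),
    list(id = "EX_aa", metabolites = c(aa = -1), lb = -1000, ub = 1000),
    list(id = "EX_nh4", metabolites = c(nh4 = -1), lb = -1000, ub = 1000),
    list(id = "CG", metabolites = c(glc = -1, C = 1), lb = 0, ub = 1000),
    list(id = "CA", metabolites = c(aa = -1, C = 1, N = 1), lb = 0, ub = 1000),
    list(id = "N1", metabolites = c(nh4 = -1, N = 1), lb = 0, ub = 1000),
    list(id = "GROWTH", metabolites = c(C = -1, N = -1), lb = 0, ub = 1000)
  ), objective = "GROWTH")
  ref <- medium("ref", c(EX_glc = 10, EX_nh4 = 10))
  with_same <- enumerate_minimal_media(m, ref, "EX_glc", "EX_nh4",
                                       carbon_sources = c("EX_glc", "EX_aa"),
                                       nitrogen_sources = c("EX_nh4", "EX_aa"))
  expect_true("EX_aa|EX_aa" %in% names(with_same$media))
  without <- enumerate_minimal_media(m, ref, "EX_glc", "EX_nh4",
                                     carbon_sources = c("EX_glc", "EX_aa"),
                                     nitrogen_sources = c("EX_nh4", "EX_aa"),
                                     allow_same = FALSE)
  expect_false("EX_aa|EX_aa" %in% names(without$media))
})

test_that("media configs load with unbounded caps and validate exchange ids", {
  m <- read_model_json(toy_json_path())
  cfg <- load_media_config(toy_media_path(), m)
  expect_length(cfg$rich_media, 2)
  expect_identical(cfg$rich_media$rich_open$uptake[["EX_A"]], Inf)
  expect_identical(cfg$rich_media$rich_capped$uptake[["EX_A"]], 20)
  expect_equal(cfg$reference$name, "minimal_glc_nh4")
  # unbounded phosphate-like import: no cap constrains growth
  expect_gt(solve_fba(m, cfg$rich_media$rich_open)$objective, 100)
  # unknown exchange ids are reported
  bad <- list(rich_media = list(list(name = "x", uptake = list(EX_missing = 1))))
  expect_error(load_media_config(bad, m), "EX_missing")
  # empty media list loads as empty
  expect_length(load_rich_media(list(rich_media = list()), m), 0)
})
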