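chain_model <- function(stoich_a = 1) {
  # EX_A (<= 10) -> A -> B -> BM_TAG; `stoich_a` units of A per B
  metabolic_model(list(
    list(id = "EX_A", stoich = c(A = 1), lb = 0, ub = 10),
    list(id = "R1", stoich = setNames(c(-stoich_a, 1), c("A", "B"))),
    list(id = "BM_TAG", stoich = c(B = -1))),
    bm_tag = "BM_TAG")
}

test_that("FBA solves analytic chain problems", {
  expect_equal(fba(chain_model(1), "BM_TAG")$objective_value, 10, tolerance = 1e-9)
  expect_equal(fba(chain_model(2), "BM_TAG")$objective_value, 5, tolerance = 1e-9)
})

test_that("FBA signals infeasibility instead of erroring", {
  m <- metabolic_model(list(
    list(id = "SINK", stoich = c(A = -1), lb = 1, ub = 5),  # forced drain, no source
    list(id = "OBJ", stoich = c(B = 1, A = 0), lb = 0, ub = 1)))
  f <- fba(m, "OBJ")
  expect_equal(f$status, "infeasible")
  expect_true(is.na(f$objective_value))
})

test_that("FBA agrees with the vertex-enumeration oracle on random networks", {
  set.seed(99)
  for (i in 1:8) {
    m <- random_network(n_rxns = sample(5:8, 1), n_mets = sample(3:5, 1))
    f <- fba(m, "SINK")
    oracle <- lp_vertex_oracle(as.numeric(m$rxns == "SINK"), m$S, m$lb, m$ub)
    expect_equal(f$objective_value, oracle, tolerance = 1e-6,
                 info = sprintf("network %d", i))
    if (f$status == "optimal") {
      expect_lt(max(abs(m$S %*% f$fluxes)), 1e-6)
    }
  }
})

test_that("parsimonious FBA removes futile cycles while keeping the optimum", {
  # A <-> B loop alongside the productive chain: plain bounds admit a cycle
  m <- metabolic_model(list(
    list(id = "EX_A", stoich = c(A = 1), lb = 0, ub = 10),
    list(id = "R1", stoich = c(A = -1, B = 1), lb = -50, ub = 50),
    list(id = "R2", stoich = c(B = -1, A = 1), lb = 0, ub = 50),
    list(id = "BM_TAG", stoich = c(B = -1))),
    bm_tag = "BM_TAG")
  plain <- fba(m, "BM_TAG")
  pars <- pfba(m, "BM_TAG")
  expect_equal(pars$objective_value, plain$objective_value, tolerance = 1e-6)
  expect_lte(sum(abs(pars$fluxes)), sum(abs(plain$fluxes)) + 1e-6)
  expect_equal(unname(pars$fluxes["R2"]), 0, tolerance = 1e-6)
  expect_lt(max(abs(m$S %*% pars$fluxes)), 1e-6)
})

test_that("FVA finds the flux ranges at the optimum", {
  m <- metabolic_model(list(
    list(id = "EX_A", stoich = c(A = 1), lb = 0, ub = 10),
    list(id = "R1a", stoich = c(A = -1, B = 1), gpr = "g1"),
    list(id = "R1b", stoich = c(A = -1, B = 1), gpr = "g2"),
    list(id = "BM_TAG", stoich = c(B = -1))),
    bm_tag = "BM_TAG")
  ranges <- fva(m, "BM_TAG", reactions = c("R1a", "R1b"))
  # isozyme-style parallel routes: either branch can carry the full flux
  expect_equal(ranges$max, c(10, 10), tolerance = 1e-6)
  expect_equal(ranges$min, c(0, 0), tolerance = 1e-6)
})

test_that("the JSON dialect round-trips a model", {
  toy <- toy_metabolic_model("branch")
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(toy$model, path)
  back <- load_model_json(path)
  expect_equal(back$S[toy$model$mets, toy$model$rxns], toy$model$S)
  expect_equal(back$lb, toy$model$lb)
  expect_equal(back$ub, toy$model$ub)
  expect_equal(back$gpr, toy$model$gpr)
  expect_equal(back$bm_tag, "BM_TAG")
  # designated-reaction validation
  crippled <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  crippled$reactions <- Filter(function(r) r$id != "EX_TAG", crippled$reactions)
  crippled$ex_tag <- NULL
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(crippled, path2, auto_unbox = TRUE)
  expect_error(load_model_json(path2), "designated")
  expect_s3_class(load_model_json(path2, require_designated = FALSE),
                  "metabolic_model")
})

test_that("the SBML reader recovers species, bounds and GPRs", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml_chain_text(), path)
  m <- read_sbml_model(path)
  expect_setequal(m$rxns, c("SRC", "R1", "BM_TAG", "EX_TAG"))
  expect_equal(unname(m$ub["SRC"]), 10)
  expect_equal(unname(m$S["A", "R1"]), -1)
  expect_setequal(gpr_genes(m$gpr_tree[["R1"]]), c("g1", "g2"))
  expect_equal(fba(m, "BM_TAG")$objective_value, 10, tolerance = 1e-9)
})

test_that("splitting TAG out of biomass creates consistent objectives", {
  m <- metabolic_model(list(
    list(id = "SRC_P", stoich = c(protein = 1), lb = 0, ub = 10),
    list(id = "SRC_T", stoich = c(tag = 1), lb = 0, ub = 10),
    list(id = "BIOMASS", stoich = c(protein = -1, tag = -0.2))))
  split <- split_tag_from_biomass(m, "tag", "BIOMASS")
  expect_equal(unname(split$S["tag", "EX_TAG"]), -0.2)
  expect_equal(unname(split$S["protein", "BM_TAG"]), -1)
  expect_true(all(split$S["tag", "BM_TAG"] == 0))
  expect_equal(unname(split$ub["BIOMASS"]), 0)       # original closed
  expect_error(split_tag_from_biomass(split, "tag", "BIOMASS"), "twice")
  expect_error(split_tag_from_biomass(m, character(0), "BIOMASS"), "non-empty")
  expect_error(split_tag_from_biomass(m, "starch", "BIOMASS"), "not consumed")
})
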