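test_that("knockdown bounds cap affected fluxes in the wild-type direction", {
  toy <- toy_metabolic_model("chain")
  wt <- pfba(toy$model, "BM_TAG")
  kd <- gene_knockdown_bounds(toy$model, wt, "g1", knockdown_config(kd_factor = 16))
  expect_equal(attr(kd, "affected"), "R1")
  expect_equal(unname(kd$ub["R1"]), wt$fluxes[["R1"]] / 16)
  expect_equal(unname(kd$lb["R1"]), 0)
  # 8 flux units / 16 = 0.5 (single-gene reaction worked example)
  m8 <- metabolic_model(list(
    list(id = "EX_A", stoich = c(A = 1), lb = 0, ub = 8),
    list(id = "R1", stoich = c(A = -1, B = 1), gpr = "gx"),
    list(id = "BM_TAG", stoich = c(B = -1))), bm_tag = "BM_TAG")
  kd8 <- gene_knockdown_bounds(m8, pfba(m8, "BM_TAG"), "gx", knockdown_config())
  expect_equal(unname(kd8$ub["R1"]), 0.5)
  # reactions carrying no wild-type flux close completely
  expect_equal(unname(kd$ub["EX_TAG"]), unname(toy$model$ub["EX_TAG"]))  # untouched, no gene
  # isozymes rescue under boolean GPR; any-association still constrains
  iso <- toy_metabolic_model("isozyme")
  wt_iso <- pfba(iso$model, "BM_TAG")
  kd_bool <- gene_knockdown_bounds(iso$model, wt_iso, "g1", knockdown_config())
  expect_equal(attr(kd_bool, "affected"), character(0))
  kd_any <- gene_knockdown_bounds(iso$model, wt_iso, "g1",
                                  knockdown_config(gpr_mode = "any"))
  expect_equal(attr(kd_any, "affected"), "R1")
  expect_warning(gene_knockdown_bounds(iso$model, wt_iso, "ghost",
                                       knockdown_config()),
                 "absent from every GPR")
})

test_that("rho reproduces the hand-solved toy outcomes", {
  # unperturbed model: rho is exactly 1
  toy <- toy_metabolic_model("branch")
  null_kd <- suppressWarnings(knockdown_rho(toy$model, "ghost", toy$cfg))
  expect_equal(null_kd$rho, 1)
  expect_true(null_kd$viable)
  # branch: knocking the sole C-producing gene halves biomass, TAG untouched
  res <- knockdown_rho(toy$model, "gC", toy$cfg)
  expect_equal(res$rho, 2, tolerance = 1e-9)
  expect_equal(res$bm_ratio, 0.5, tolerance = 1e-9)
  expect_equal(res$tag_ratio, 1, tolerance = 1e-9)
  expect_true(res$viable)
  expect_equal(knockdown_rho(toy$model, "gB", toy$cfg)$rho, 0.5, tolerance = 1e-9)
  expect_equal(knockdown_rho(toy$model, "gS", toy$cfg)$rho, 1, tolerance = 1e-9)
  # chain at 1/16: biomass ratio 0.0625 < 0.10 -> inviable, rho undefined
  chain <- toy_metabolic_model("chain")
  res_c <- knockdown_rho(chain$model, "g1", chain$cfg)
  expect_equal(res_c$bm_ratio, 0.0625, tolerance = 1e-9)
  expect_false(res_c$viable)
  expect_true(is.na(res_c$rho))
  expect_equal(res_c$tag_ratio / res_c$bm_ratio, 1, tolerance = 1e-9)
  # isozyme rescue: rho exactly 1 under boolean GPR
  iso <- toy_metabolic_model("isozyme")
  expect_equal(knockdown_rho(iso$model, "g1", iso$cfg)$rho, 1)
})

test_that("deeper knockdowns never increase the perturbed objectives", {
  toy <- toy_metabolic_model("branch")
  factors <- c(2, 4, 8, 16)
  res <- lapply(factors, function(k)
    knockdown_rho(toy$model, "gB", knockdown_config(kd_factor = k)))
  bm <- sapply(res, `[[`, "bm_pert")
  tag <- sapply(res, `[[`, "tag_pert")
  expect_true(all(diff(bm) <= 1e-9))
  expect_true(all(diff(tag) <= 1e-9))
})

test_that("screening ranks by rho and flags exactly the planted target", {
  toy <- toy_metabolic_model("branch")
  scr <- screen_targets(toy$model, c("gS", "gB", "gC"), toy$cfg)
  expect_equal(scr$gene[scr$target], "gC")
  expect_equal(scr$gene, c("gC", "gS", "gB"))        # rho descending
  # invariance to candidate order
  scr2 <- screen_targets(toy$model, c("gC", "gS", "gB"), toy$cfg)
  expect_equal(scr, scr2, ignore_attr = TRUE)
  # disjoint candidates
  scr3 <- screen_targets(toy$model, c("x1", "x2"), toy$cfg)
  expect_equal(nrow(scr3), 0)
  expect_setequal(attr(scr3, "unmapped"), c("x1", "x2"))
  # truth table agreement for every toy fixture
  for (kind in c("chain", "branch", "isozyme")) {
    fix <- toy_metabolic_model(kind)
    got <- screen_targets(fix$model, fix$truth$gene, fix$cfg)
    m <- merge(got, fix$truth, by = "gene")
    expect_equal(m$rho.x, m$rho.y, tolerance = 1e-9, info = kind)
    expect_equal(m$viable.x, m$viable.y, info = kind)
    expect_equal(m$bm_ratio.x, m$bm_ratio.y, tolerance = 1e-9, info = kind)
  }
})

test_that("precursor gene search follows producible routes", {
  m <- metabolic_model(list(
    list(id = "EX_A", stoich = c(A = 1), lb = 0, ub = 10),
    list(id = "R1", stoich = c(A = -1, accoa = 1), gpr = "g1"),
    list(id = "R2a", stoich = c(accoa = -1, malcoa = 1), gpr = "gia"),
    list(id = "R2b", stoich = c(accoa = -1, malcoa = 1), gpr = "gib"),
    list(id = "R_dead", stoich = c(X = -1, Y = 1), gpr = "gdead"),
    list(id = "EX_MAL", stoich = c(malcoa = -1))))
  genes <- precursor_genes(m, "accoa")
  expect_true("g1" %in% genes)
  expect_false("gdead" %in% genes)        # disconnected reaction
  genes2 <- precursor_genes(m, "malcoa")
  expect_true(all(c("g1", "gia", "gib") %in% genes2))  # isozymes both count
  expect_warning(precursor_genes(m, "Y"), "no producible flux")
  expect_error(precursor_genes(m, "unknown"), "not in model")
})

test_that("condition overlap classes follow set membership", {
  out <- classify_condition_overlap(c("a", "b", "c", "d"),
                                    s_down = c("b", "c"),
                                    p_down = c("c", "d"))
  expect_equal(setNames(out$class, out$gene),
               c(a = "N-only", b = "N+S", c = "N+S+P", d = "N+P"))
  none <- classify_condition_overlap("x")
  expect_equal(none$class, "N-only")
})
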