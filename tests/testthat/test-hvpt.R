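test_that("compose_levels reproduces the printed level hierarchy for the most potent ligand", {
  # components obtained by successive subtraction of the printed level totals
  t20 <- hvpt_terms("20", "total", eel_mtp = -89.2, eel_pen = -12.1,
                    eex = 34.8, edel = -17.0, ecorr = -19.2,
                    edas = -28.8)
  lv <- compose_levels(t20)
  expect_equal(lv$eel_mtp10, -89.2)
  expect_equal(lv$eel10, -101.3)
  expect_equal(lv$e10, -66.5)
  expect_equal(lv$escf, -83.5)
  expect_equal(lv$emp2, -102.7)
  expect_equal(lv$eelmtp_plus_edas, -118.0)
})

test_that("compose_levels is additive over residue groups and linear in the components", {
  set.seed(42)
  mk <- function(id, grp) hvpt_terms(id, grp,
    eel_mtp = -runif(1, 10, 90), eel_pen = -runif(1, 1, 10),
    eex = runif(1, 5, 30), edel = -runif(1, 2, 15),
    ecorr = -runif(1, 2, 20), edas = -runif(1, 2, 25))
  for (rep in 1:5) {
    a <- mk("L", "G1"); b <- mk("L", "G2")
    both <- compose_levels(rbind(a, b))
    solo <- compose_levels(a)
    solo_b <- compose_levels(b)
    for (lv in c("eel_mtp10", "eel10", "e10", "escf", "emp2",
                 "eelmtp_plus_edas"))
      expect_equal(both[[lv]], solo[[lv]] + solo_b[[lv]])
    # linearity: scaling every component scales every level
    alpha <- runif(1, 0.1, 3)
    sc <- a
    for (f in c("eel_mtp", "eel_pen", "eex", "edel", "ecorr", "edas"))
      sc[[f]] <- alpha * sc[[f]]
    lv_sc <- compose_levels(sc)
    for (lv in c("eel_mtp10", "eel10", "e10", "escf", "emp2"))
      expect_equal(lv_sc[[lv]], alpha * solo[[lv]])
  }
})

test_that("all-zero components compose to all-zero levels", {
  z <- compose_levels(hvpt_terms("L", "G", 0, 0, 0, 0, 0, 0))
  expect_true(all(unlist(z[-1]) == 0))
})

test_that("compose_levels rejects mixed ligands and names missing fields", {
  mixed <- rbind(hvpt_terms("A", "G1", -1, -1, 1, -1, -1),
                 hvpt_terms("B", "G2", -1, -1, 1, -1, -1))
  expect_error(compose_levels(mixed), "mixed ligand IDs")
  bad <- hvpt_terms("A", "G1", -1, -1, 1, -1, -1)
  bad$ecorr <- NULL
  expect_error(compose_levels(bad), "ecorr")
  bad2 <- hvpt_terms("A", "G1", -1, -1, 1, -1, NA)
  expect_error(compose_levels(bad2), "ecorr")
  expect_error(compose_levels(hvpt_terms(character(0), character(0),
                                         numeric(0), numeric(0), numeric(0),
                                         numeric(0), numeric(0))),
               "at least one")
})

test_that("eelmtp_plus_edas is only composed when every record carries edas", {
  t1 <- rbind(hvpt_terms("L", "G1", -10, -1, 2, -1, -2, -3),
              hvpt_terms("L", "G2", -5, -1, 1, -1, -1, NA))
  expect_true(is.na(compose_levels(t1)$eelmtp_plus_edas))
})

test_that("levels round-trip through component reconstruction", {
  lv <- fixture_levels()
  comp <- levels_to_components(lv)
  back <- compose_levels_all(comp)
  expect_equal(back$eel_mtp10, lv$eel_mtp10)
  expect_equal(back$eel10, lv$eel10)
  expect_equal(back$e10, lv$e10)
  expect_equal(back$escf, lv$escf)
  expect_equal(back$emp2, lv$emp2)
  expect_equal(back$eelmtp_plus_edas, lv$eelmtp_plus_edas)
})

test_that("residue aggregation conserves the ligand total for every component", {
  set.seed(7)
  terms <- do.call(rbind, lapply(sprintf("G%d", 1:4), function(g)
    hvpt_terms("L", g, eel_mtp = -runif(1, 1, 50), eel_pen = -runif(1),
               eex = runif(1, 1, 10), edel = -runif(1, 1, 5),
               ecorr = -runif(1, 1, 8), edas = -runif(1, 1, 10))))
  lv <- compose_levels(terms)
  for (comp in c("eel_mtp10", "eel10", "e10", "escf", "emp2",
                 "eelmtp_plus_edas")) {
    m <- aggregate_residue_contributions(terms, comp)
    expect_length(m, 4L)
    expect_equal(sum(m), lv[[comp]])
  }
  m <- aggregate_residue_contributions(terms, "eex")
  expect_equal(sum(m), sum(terms$eex))
})

test_that("a dominant charged group is the arg-max contribution and edge cases behave", {
  terms <- rbind(
    hvpt_terms("L", "Arg103", -80, -8, 25, -12, -15, -20),
    hvpt_terms("L", "Cys70-Cys188", -4, -0.5, 2, -1, -2, -3),
    hvpt_terms("L", "Val72-Met73", -3, -0.4, 2, -1, -2, -3),
    hvpt_terms("L", "Phe108", -3, -0.3, 1, -1, -2, -3))
  m <- aggregate_residue_contributions(terms, "eel10")
  expect_identical(names(which.max(abs(m))), "Arg103")
  empty <- aggregate_residue_contributions(terms[0, ], "eel10")
  expect_length(empty, 0L)
  expect_error(aggregate_residue_contributions(terms, "nonsense"),
               "valid names")
})

test_that("validate_decomposition passes consistent printed data and flags violations", {
  lv <- fixture_levels()
  comp <- levels_to_components(lv)
  expect_identical(nrow(validate_decomposition(comp, lv, tol = 0.15)), 0L)
  # exchange repulsion must be non-negative
  bad <- hvpt_terms("L", "G", -1, -1, eex = -1.0, edel = -1, ecorr = -1)
  rep1 <- validate_decomposition(bad)
  expect_true(any(grepl("exchange repulsion negative", rep1$check)))
  # a perturbed MP2 total leaves a residual of exactly its perturbation
  lv2 <- lv
  lv2$emp2[1] <- lv2$emp2[1] + 1.0
  rep2 <- validate_decomposition(comp, lv2, tol = 0.15)
  expect_true(any(grepl("EMP2 residual", rep2$check)))
  expect_equal(rep2$residual[grepl("EMP2", rep2$check)], 1.0)
})

test_that("printed levels obey the physical ordering on all 15 ligands", {
  lv <- fixture_levels()
  expect_identical(nrow(lv), 15L)
  # exchange is repulsive, correlation is stabilizing
  expect_true(all(lv$eel10 <= lv$e10))
  expect_true(all(lv$emp2 <= lv$escf))
})

test_that("the default binding-site grouping pairs the disulfide and Val/Met residues", {
  g <- binding_site_groups()
  expect_named(g, c("Arg103", "Cys70-Cys188", "Val72-Met73", "Phe108"))
  expect_identical(g[["Cys70-Cys188"]], c("Cys70", "Cys188"))
  expect_identical(g[["Val72-Met73"]], c("Val72", "Met73"))
})
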