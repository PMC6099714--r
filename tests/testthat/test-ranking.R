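energy_column <- function(levels, name)
  score_column(name, setNames(levels[[name]], levels$ligand_id),
               orientation = "lower_is_better")

test_that("Pearson R reproduces the printed correlations at printed precision", {
  act <- fixture_activities()
  lv <- fixture_levels()
  expect_equal(round(pearson_r(energy_column(lv, "emp2"), act), 2), -0.69)
  expect_equal(round(pearson_r(energy_column(lv, "eel10"), act), 2), -0.65)
  sol <- fixture_solvation()
  expect_equal(round(pearson_r(energy_column(sol, "dg_solv"), act), 2),
               -0.43)
})

test_that("orientation handling flips the sign for higher-is-better columns", {
  act <- fixture_activities()
  sc <- score_column("perfect", setNames(act$pic50, act$ligand_id),
                     orientation = "higher_is_better")
  expect_equal(pearson_r(sc, act), -1.0)
  # negating an energy-like column negates r
  lv <- fixture_levels()
  neg <- score_column("neg", setNames(-lv$emp2, lv$ligand_id),
                      orientation = "lower_is_better")
  expect_equal(pearson_r(neg, act),
               -pearson_r(energy_column(lv, "emp2"), act))
})

test_that("Npred counts concordant pairs with the single experimental tie excluded", {
  act <- fixture_activities()
  lv <- fixture_levels()
  np <- npred(energy_column(lv, "eelmtp_plus_edas"), act)
  expect_identical(np$n_pairs_total, 105L)
  expect_identical(np$n_pairs_excluded_ties, 1L)   # ligands 14 and 15
  expect_identical(np$n_pairs_concordant, 81L)
  expect_equal(round(np$npred_percent, 1), 77.9)
})

test_that("Npred is 100 for strictly anti-monotone energies and handles hand-enumerated ties", {
  act <- data.frame(ligand_id = letters[1:5],
                    pic50 = c(5.1, 4.8, 4.3, 4.1, 3.7))
  sc <- score_column("e", setNames(c(-9, -8, -6, -5, -2), act$ligand_id))
  expect_equal(npred(sc, act)$npred_percent, 100)
  # 4 ligands, one experimental tie: 6 pairs, denominator 5
  act4 <- data.frame(ligand_id = c("a", "b", "c", "d"),
                     pic50 = c(5, 5, 4, 3))
  sc4 <- score_column("e", c(a = -10, b = -9, c = -8, d = -7))
  np <- npred(sc4, act4)
  expect_identical(np$n_pairs_total, 6L)
  expect_identical(np$n_pairs_excluded_ties, 1L)
  expect_identical(np$n_pairs_concordant, 5L)
  expect_equal(np$npred_percent, 100)
  # a predicted-score tie is a failed prediction, not an exclusion
  sc_tie <- score_column("e", c(a = -10, b = -9, c = -8, d = -8))
  np_tie <- npred(sc_tie, act4)
  expect_identical(np_tie$n_pairs_excluded_ties, 1L)
  expect_identical(np_tie$n_pairs_concordant, 4L)
  expect_equal(np_tie$npred_percent, 80)
})

test_that("Npred is invariant under strictly monotone transforms of the score", {
  set.seed(41)
  act <- data.frame(ligand_id = sprintf("L%d", 1:10),
                    pic50 = runif(10, 4, 6))
  vals <- setNames(rnorm(10, -80, 10), act$ligand_id)
  base <- npred(score_column("e", vals), act)
  for (f in list(function(x) 2 * x + 5, function(x) -exp(-x / 50))) {
    tr <- npred(score_column("t", f(vals)), act)
    expect_equal(tr$npred_percent, base$npred_percent)
  }
  # without activity ties the denominator is n(n-1)/2
  expect_identical(base$n_pairs_total - base$n_pairs_excluded_ties, 45L)
})

test_that("the standard error of estimate matches the printed footer values", {
  act <- fixture_activities()
  lv <- fixture_levels()
  expect_equal(round(standard_error_estimate(
    energy_column(lv, "eel_mtp10"), act), 1), 10.1)
  expect_equal(round(standard_error_estimate(
    energy_column(lv, "eel10"), act), 1), 11.5)
  # collinear data have zero residual error
  coll <- score_column("c", setNames(2 * act$pic50 - 1, act$ligand_id))
  expect_equal(standard_error_estimate(coll, act), 0)
})

test_that("degenerate inputs are rejected", {
  act <- fixture_activities()
  flat <- score_column("flat", setNames(rep(-5, nrow(act)),
                                        act$ligand_id))
  expect_error(pearson_r(flat, act), "degenerate")
  act3 <- act[1:2, ]
  sc <- score_column("e", setNames(c(-1, -2), act3$ligand_id))
  expect_error(pearson_r(sc, act3), "at least 3")
  expect_error(score_column("x", setNames(c(1, Inf), c("a", "b"))),
               "finite")
  expect_error(npred(score_column("e", c(a = -1)),
                     data.frame(ligand_id = "a", pic50 = 5)), "at least 2")
})

test_that("evaluate_model reproduces all six footer rows and is permutation invariant", {
  act <- fixture_activities()
  lv <- fixture_levels()
  ev <- evaluate_model(lv, act)
  ev <- ev[match(c("eel_mtp10", "eel10", "e10", "escf", "emp2",
                   "eelmtp_plus_edas"), ev$column), ]
  expect_equal(round(ev$r, 2), c(-0.63, -0.65, -0.44, -0.55, -0.69, -0.72))
  expect_equal(round(ev$npred_percent, 1),
               c(75.0, 76.9, 65.4, 69.2, 75.0, 77.9))
  expect_equal(ev$r_squared, ev$r^2)
  expect_equal(ev$npred_percent,
               100 * ev$n_pairs_concordant /
                 (ev$n_pairs_total - ev$n_pairs_excluded_ties))
  # shuffled row order leaves every statistic unchanged
  set.seed(42)
  perm <- sample(nrow(lv))
  ev2 <- evaluate_model(lv[perm, ], act[sample(nrow(act)), ])
  expect_equal(ev2[order(ev2$column), ], ev[order(ev$column), ],
               ignore_attr = TRUE)
  # single column in, single row out; empty in, empty out
  expect_identical(nrow(evaluate_model(lv[, c("ligand_id", "emp2")], act)),
                   1L)
  expect_identical(nrow(evaluate_model(list(), act)), 0L)
})
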