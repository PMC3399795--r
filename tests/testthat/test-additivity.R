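two_parents <- function(pp, aa) {
  list(P = expression_profile(setNames(pp, sprintf("m%d", seq_along(pp))),
                              "PP"),
       A = expression_profile(setNames(aa, sprintf("m%d", seq_along(aa))),
                              "AA"))
}

test_that("dosage expectations reproduce the mid-parent formulas exactly", {
  parents <- two_parents(c(0.4, 0.6) * 10, c(0.2, 0.8) * 10)
  pa <- expected_profile(parents, genome_composition(c(P = 1, A = 1)))
  expect_equal(pa$expected[pa$mirna == "m1"], 0.3)     # (0.4+0.2)/2

  parents2 <- two_parents(c(0.9, 0.1) * 10, c(0.3, 0.7) * 10)
  paa <- expected_profile(parents2, genome_composition(c(P = 1, A = 2)))
  expect_equal(paa$expected[paa$mirna == "m1"], 0.5)   # (0.9+2*0.3)/3
  expect_equal(sum(paa$expected), 1)

  solo <- expected_profile(parents2, genome_composition(c(P = 1)))
  expect_equal(solo$expected,
               parents2$P$proportion[match(solo$mirna, parents2$P$mirna)])

  expect_error(expected_profile(parents["P"],
                                genome_composition(c(P = 1, A = 1))),
               class = "polymir_missing_parent")
})

test_that("deviations vanish when observed equals expected", {
  set.seed(139)
  v <- sort(runif(30), decreasing = TRUE)
  obs <- expression_profile(setNames(v, sprintf("m%d", 1:30)), "H")
  expd <- tibble::tibble(mirna = sprintf("m%d", 1:30),
                         expected = v / sum(v))
  res <- additivity_deviation(obs, expd, pseudocount = 0)
  expect_true(all(res$table$log2_deviation == 0))
  expect_equal(res$within_band_fraction, 1.0)
  expect_equal(res$median, 0)
  expect_equal(res$chi2_stat, 0)
})

test_that("uniform two-fold excess lands exactly on the strict band edge", {
  v <- rep(0.1, 10)
  obs <- expression_profile(setNames(v, sprintf("m%d", 1:10)), "H")
  expd <- tibble::tibble(mirna = sprintf("m%d", 1:10), expected = v / 2)
  res <- additivity_deviation(obs, expd, pseudocount = 0)
  expect_true(all(res$table$log2_deviation == 1.0))
  expect_equal(res$within_band_fraction, 0)  # boundary counts as outside
  expect_true(all(res$table$outside_band))
})

test_that("over/under chi-square matches the textbook formula", {
  set.seed(149)
  # 143 miRNAs slightly over, 61 slightly under expectation
  delta <- c(rep(0.2, 143), rep(-0.3, 61))
  expd <- rep(1 / 204, 204)
  obs_counts <- 1000 * expd * 2^delta
  obs <- expression_profile(setNames(obs_counts, sprintf("m%d", 1:204)), "PAA")
  res <- additivity_deviation(
    obs, setNames(expd, sprintf("m%d", 1:204)), pseudocount = 0)
  # renormalization shifts all deviations by the same constant; the sign
  # split stays 143 / 61 because shifts are well below the planted effects
  expect_equal(res$n_over, 143)
  expect_equal(res$n_under, 61)
  manual <- (143 - 102)^2 / 102 + (61 - 102)^2 / 102
  expect_equal(res$chi2_stat, manual)
  expect_equal(res$chi2_stat, 32.96, tolerance = 1e-3)
  expect_equal(res$chi2_p, pchisq(manual, 1, lower.tail = FALSE))
  expect_lt(res$chi2_p, 0.01)
})

test_that("dosage moves the triploid expectation toward the doubled parent", {
  set.seed(151)
  pp <- runif(20); aa <- runif(20)
  parents <- two_parents(pp, aa)
  pa <- expected_profile(parents, genome_composition(c(P = 1, A = 1)))
  paa <- expected_profile(parents, genome_composition(c(P = 1, A = 2)))
  p_v <- setNames(parents$P$proportion, parents$P$mirna)
  a_v <- setNames(parents$A$proportion, parents$A$mirna)
  for (m in pa$mirna) {
    if (p_v[m] == a_v[m]) next
    e_pa <- pa$expected[pa$mirna == m]
    e_paa <- paa$expected[paa$mirna == m]
    expect_true(e_paa > min(p_v[m], a_v[m]) && e_paa < max(p_v[m], a_v[m]))
    expect_lt(abs(e_paa - a_v[m]), abs(e_pa - a_v[m]))
  }
})

test_that("PA and PAA expectations coincide only for identical parents", {
  parents_eq <- two_parents(c(1, 2, 3), c(1, 2, 3))
  pa <- expected_profile(parents_eq, genome_composition(c(P = 1, A = 1)))
  paa <- expected_profile(parents_eq, genome_composition(c(P = 1, A = 2)))
  expect_equal(pa$expected, paa$expected)

  parents_ne <- two_parents(c(1, 2, 3), c(3, 2, 1))
  pa2 <- expected_profile(parents_ne, genome_composition(c(P = 1, A = 1)))
  paa2 <- expected_profile(parents_ne, genome_composition(c(P = 1, A = 2)))
  expect_false(isTRUE(all.equal(pa2$expected, paa2$expected)))
})

test_that("closure: exact truth proportions show no deviation from additivity", {
  mirnas <- sprintf("m%02d", 1:40)
  props <- random_parental_proportions(mirnas, c("P", "A"), seed = 157)
  truth <- simulation_truth(mirnas, props)
  paa_truth <- compose_hybrid_truth(truth, genome_composition("PAA"))
  parents <- list(P = expression_profile(props$P * 1e6, "PP"),
                  A = expression_profile(props$A * 1e6, "AA"))
  expd <- expected_profile(parents, genome_composition(c(P = 1, A = 2)))
  obs <- expression_profile(paa_truth * 1e6, "PAA")
  res <- additivity_deviation(obs, expd, pseudocount = 0)
  expect_true(all(abs(res$table$log2_deviation) < 1e-9))
  expect_equal(res$chi2_p, 1)
})

test_that("additivity_report binds one row per hybrid with ordered medians", {
  v <- rep(0.05, 20)
  obs0 <- expression_profile(setNames(v, sprintf("m%d", 1:20)), "flat")
  expd <- tibble::tibble(mirna = sprintf("m%d", 1:20), expected = v / sum(v))
  r0 <- additivity_deviation(obs0, expd, pseudocount = 0)
  shifted <- v * 2^c(rep(1, 15), rep(-0.2, 5))
  obs1 <- expression_profile(setNames(shifted, sprintf("m%d", 1:20)), "up")
  r1 <- additivity_deviation(obs1, expd, pseudocount = 0)
  rep_tbl <- additivity_report(list(r0, r1))
  expect_equal(nrow(rep_tbl), 2)
  expect_equal(rep_tbl$median[rep_tbl$hybrid == "flat"], 0)
  expect_gt(rep_tbl$median[rep_tbl$hybrid == "up"],
            rep_tbl$median[rep_tbl$hybrid == "flat"])
})
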