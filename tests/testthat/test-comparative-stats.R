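prof_from <- function(x, label) {
  expression_profile(setNames(x, sprintf("m%d", seq_along(x))), label)
}

test_that("profile correlation equals the covariance/sd definition", {
  a <- prof_from(c(5, 10, 20, 40, 25), "a")
  expect_equal(profile_correlation(a, a), 1.0)

  # affine rescaling with positive slope leaves r at 1
  av <- setNames(a$proportion, a$mirna)
  b <- expression_profile(av * 3 + 0.01, "b")
  expect_equal(profile_correlation(a, b), 1.0)

  # hand computation from the definition on 5 paired values
  x <- c(0.05, 0.10, 0.20, 0.40, 0.25)
  y <- c(0.30, 0.05, 0.25, 0.20, 0.20)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1) /
    (sd(x) * sd(y))
  c_prof <- expression_profile(setNames(y, sprintf("m%d", 1:5)), "c")
  expect_equal(profile_correlation(a, c_prof), r_manual)

  flat <- expression_profile(setNames(rep(0.2, 5), sprintf("m%d", 1:5)), "f")
  expect_error(profile_correlation(a, flat),
               class = "polymir_undefined_correlation")
})

test_that("fold changes are antisymmetric and zero for identical profiles", {
  a <- prof_from(c(10, 20, 30, 40), "a")
  same <- fold_changes(a, a)
  expect_true(all(same$log2_ratio == 0))

  b <- prof_from(c(20, 40, 60, 80), "b")  # same proportions
  expect_true(all(abs(fold_changes(a, b)$log2_ratio) < 1e-12))

  # a_m = 2 * b_m with no pseudocount gives exactly 1
  x <- prof_from(c(2, 2, 6), "x")   # proportions 0.2, 0.2, 0.6
  y <- prof_from(c(2, 2, 16), "y")  # proportions 0.1, 0.1, 0.8
  fc <- fold_changes(x, y, pseudocount = 0)
  expect_equal(fc$log2_ratio[fc$mirna == "m1"], 1.0)

  swapped <- fold_changes(y, x, pseudocount = 0)
  expect_equal(swapped$log2_ratio, -fc$log2_ratio)
  expect_error(fold_changes(x, y, pseudocount = -1))
})

test_that("the default pseudocount is half a read of the shallower library", {
  a <- prof_from(c(10, 90), "a")     # depth 100
  b <- prof_from(c(300, 700), "b")   # depth 1000
  expect_equal(default_pseudocount(a, b), 0.5 / 100)
})

test_that("crescent summaries match the brute-force oracle on random fixtures", {
  set.seed(113)
  for (i in 1:100) {
    n <- sample(4:200, 1)
    ratios <- round(rnorm(n, sd = 1.5), 2)
    if (i %% 3 == 0) ratios[sample(n, min(n, 3))] <- 0  # exact zeros
    fc <- structure(tibble::tibble(mirna = sprintf("m%d", 1:n),
                                   log2_ratio = ratios),
                    numerator = "a", denominator = "b", pseudocount = 0,
                    class = c("fold_change_set", "tbl_df", "tbl",
                              "data.frame"))
    if (all(ratios == 0)) next
    cs <- crescent_summary(fc)
    orc <- oracle_crescent(ratios)
    expect_equal(cs$n_up, orc$n_up)
    expect_equal(cs$n_down, orc$n_down)
    expect_equal(cs$n_zero, orc$n_zero)
    expect_equal(cs$median, orc$median)
    expect_equal(cs$chi2_stat, orc$chi2_stat)
    expect_equal(cs$chi2_p, orc$chi2_p)
    expect_equal(cs$n_up + cs$n_down + cs$n_zero, n)
    # sorted ascending
    expect_true(!is.unsorted(cs$ratios$log2_ratio))

    bins <- fold_change_bins(fc)
    expect_equal(bins$n, oracle_bins(ratios))
    expect_equal(sum(bins$n), n)
  }
})

test_that("crescent summaries flip under argument swap", {
  set.seed(127)
  ratios <- rnorm(60)
  fcv <- setNames(abs(ratios) + 0.01, sprintf("m%d", 1:60))
  a <- expression_profile(fcv * 2^ratios, "a")
  b <- expression_profile(fcv, "b")
  cs_ab <- crescent_summary(fold_changes(a, b, pseudocount = 0))
  cs_ba <- crescent_summary(fold_changes(b, a, pseudocount = 0))
  expect_equal(cs_ab$n_up, cs_ba$n_down)
  expect_equal(cs_ab$n_down, cs_ba$n_up)
  expect_equal(cs_ab$median, -cs_ba$median)
  expect_equal(cs_ab$chi2_stat, cs_ba$chi2_stat)
})

test_that("all-positive and balanced splits behave as expected", {
  up <- structure(tibble::tibble(mirna = sprintf("m%d", 1:10),
                                 log2_ratio = runif(10, 0.1, 2)),
                  numerator = "a", denominator = "b", pseudocount = 0,
                  class = c("fold_change_set", "tbl_df", "tbl",
                            "data.frame"))
  cs <- crescent_summary(up)
  expect_equal(cs$pct_up, 100)
  expect_gt(cs$median, 0)

  bal <- structure(tibble::tibble(mirna = sprintf("m%d", 1:200),
                                  log2_ratio = rep(c(1, -1), 100)),
                   numerator = "a", denominator = "b", pseudocount = 0,
                   class = c("fold_change_set", "tbl_df", "tbl",
                             "data.frame"))
  cs2 <- crescent_summary(bal)
  expect_equal(cs2$chi2_stat, 0)
  expect_equal(cs2$chi2_p, 1)
})

test_that("fold-change bin edges follow the two-fold window", {
  fc <- structure(tibble::tibble(mirna = c("m1", "m2", "m3"),
                                 log2_ratio = c(0, 1.5, -1.2)),
                  numerator = "a", denominator = "b", pseudocount = 0,
                  class = c("fold_change_set", "tbl_df", "tbl",
                            "data.frame"))
  bins <- fold_change_bins(fc)
  expect_equal(bins$n, c(1L, 1L, 1L))  # 2^1.5 > 2; 2^-1.2 < 0.5; 2^0 middle
})

test_that("cross-comparison consistency reduces to set algebra", {
  mk <- function(r) structure(
    tibble::tibble(mirna = sprintf("m%d", seq_along(r)), log2_ratio = r),
    numerator = "a", denominator = "b", pseudocount = 0,
    class = c("fold_change_set", "tbl_df", "tbl", "data.frame"))
  prim <- mk(c(1, 0.5, -0.5, 2, -2))
  self <- consistency_across(prim, list(prim, prim))
  expect_equal(self$frac_any, c(1, 1))
  expect_equal(self$frac_all, c(1, 1))

  negated <- consistency_across(prim, list(mk(-c(1, 0.5, -0.5, 2, -2))))
  expect_equal(negated$frac_any, c(0, 0))

  # planted concordance: up in others for a known subset
  set.seed(131)
  for (i in 1:30) {
    r0 <- runif(20, -2, 2)
    o1 <- r0 * sample(c(1, -1), 20, TRUE)
    o2 <- r0 * sample(c(1, -1), 20, TRUE)
    res <- consistency_across(mk(r0), list(mk(o1), mk(o2)))
    up <- which(r0 > 0)
    any_manual <- mean(o1[up] > 0 | o2[up] > 0)
    all_manual <- mean(o1[up] > 0 & o2[up] > 0)
    expect_equal(res$frac_any[res$direction == "up"], any_manual)
    expect_equal(res$frac_all[res$direction == "up"], all_manual)
  }

  # cutoff restricts to |ratio| > 1 and names the consistent set
  cut <- consistency_across(prim, list(prim), cutoff = 1)
  expect_equal(cut$n_primary, c(1L, 1L))   # only m4 (2) and m5 (-2)
  expect_equal(cut$mirnas_all[[which(cut$direction == "up")]], "m4")
})
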