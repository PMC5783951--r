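test_that("worked triplets land in the categories the definitions force", {
  # PC = 0.5, GC = 0.4 opposite, TC = 0.1 <= cutoff: restored reversion
  t1 <- classify_trait(1.0, 1.5, 1.1, theta = 0.2)
  expect_identical(t1$category, "reversing")
  expect_identical(t1$restoration, "restored")
  expect_equal(t1$pc, 0.5)
  expect_equal(t1$gc, 0.4)
  expect_equal(t1$tc, 0.1, tolerance = 1e-12)

  # PC = 0.3, GC = 0.5 same direction; GC < TC = 0.8: facilitating
  t2 <- classify_trait(1.0, 1.3, 1.8, theta = 0.2)
  expect_identical(t2$category, "reinforcing")
  expect_identical(t2$plasticity_role, "facilitating")

  # PC = 0.5 down, GC = 1.1 up: over-restored (GC > PC), hindering (GC > TC)
  t3 <- classify_trait(1.0, 0.5, 1.6, theta = 0.2)
  expect_identical(t3$category, "reversing")
  expect_identical(t3$restoration, "over_restored")
  expect_identical(t3$plasticity_role, "hindering")

  expect_error(classify_trait(1, 2, 3, theta = 0), "positive")
  expect_error(classify_trait(1, NA, 3), "finite")
})

test_that("classification agrees with the brute-force oracle across cutoffs", {
  trips <- random_triplets(20000, seed = 101)
  for (theta in c(0.05, 0.2, 0.5))
    for (eps in c(0, 1e-4))
      expect_oracle_agreement(trips, theta, eps)
})

test_that("the absolute floor silences sub-tolerance changes at zero baselines", {
  # L_o = 0 makes the relative cutoff vanish; eps restores the dead zone
  noisy <- classify_trait(0, 5e-5, -5e-5, theta = 0.2, eps = 1e-4)
  expect_identical(noisy$category, "unchanged")
  seen <- classify_trait(0, 5e-5, -5e-5, theta = 0.2, eps = 0)
  expect_identical(seen$category, "reversing")
})

test_that("summaries count categories over all analyzed traits", {
  trips <- data.frame(
    trait_id = 1:5,
    L_o = c(1, 1, 1, 1, 1),
    L_p = c(1.5, 0.5, 1.3, 1.4, 1.05),   # rev, rev, reinf, plastic, none
    L_a = c(1.1, 1.1, 1.8, 1.45, 1.0))
  s <- summarize_adaptation(classify_traits(trips, theta = 0.2))
  expect_equal(s$n_traits, 5)
  expect_equal(s$c_rv, 0.4)
  expect_equal(s$c_ri, 0.2)
  expect_equal(s$plastic_only, 0.2)
  expect_equal(s$restored + s$over_restored + s$under_restored, s$c_rv)
  expect_equal(s$p_two_tailed, binom_two_tailed(1, 3))

  flat <- data.frame(trait_id = 1:3, L_o = 1:3, L_p = 1:3, L_a = 1:3)
  s0 <- summarize_adaptation(classify_traits(flat))
  expect_equal(s0$c_ri + s0$c_rv, 0)
  expect_true(s0$zero_counts)
  expect_equal(s0$p_two_tailed, 1)

  expect_error(summarize_adaptation(data.frame()), "empty")
})

test_that("exact binomial tests reproduce the published worked values", {
  # 50 of 50 adaptations in one direction: 2 * 0.5^50
  expect_equal(binom_two_tailed(50, 50), 2 * 0.5^50)
  expect_equal(binom_two_tailed(50, 50), 1.8e-15, tolerance = 0.02)
  # 42 of 44 cases
  expect_equal(binom_two_tailed(42, 44), 1.1e-10, tolerance = 0.03)
  # 43 of 50 fitness asymmetries, one-tailed
  expect_equal(binom_one_tailed(43, 50), 1.0e-7, tolerance = 0.06)
})

test_that("binomial tests obey symmetry, boundaries and input checks", {
  expect_equal(binom_two_tailed(1, 2), 1)
  for (n in c(5, 17, 44)) for (k in 0:n)
    expect_equal(binom_two_tailed(k, n), binom_two_tailed(n - k, n))
  expect_equal(binom_one_tailed(0, 10), 1)
  for (n in c(3, 10)) expect_equal(binom_one_tailed(n, n), 0.5^n)
  expect_error(binom_two_tailed(5, 4), "integer")
  expect_error(binom_two_tailed(-1, 4), "integer")
  expect_error(binom_one_tailed(2.5, 4), "integer")
})

test_that("the geometric null ratio has the right limits and arithmetic", {
  expect_equal(expected_ratio(0), 1)
  expect_equal(expected_ratio(1), 0)
  expect_equal(expected_ratio(1 / 3), 0.5)
  expect_error(expected_ratio(-0.1), "\\[0, 1\\]")
  expect_error(expected_ratio(1.1), "\\[0, 1\\]")
})

test_that("TC conditioning keeps appreciable totals and drops restored traits", {
  cl <- classify_traits(data.frame(
    trait_id = 1:3, L_o = c(1, 1, 1), L_p = c(1.5, 0.7, 1.5),
    L_a = c(1.1, 1.3, 2.0)), theta = 0.2)
  kept <- condition_on_tc(cl)
  expect_identical(kept$trait_id, c(2L, 3L))   # TC = 0.1 excluded
  # every restored reversion has TC <= cutoff, so none can survive
  trips <- gen_planted_q(2000, q = 0.6, seed = 9)
  cl2 <- classify_traits(trips, theta = 0.2)
  kept2 <- condition_on_tc(cl2)
  expect_false(any(kept2$restoration %in% "restored"))
})

test_that("dropping PC > TC traits removes exactly the forced reversions", {
  cl <- classify_traits(data.frame(
    trait_id = 1:2, L_o = c(1, 1), L_p = c(1.5, 1.3), L_a = c(1.1, 1.8)),
    theta = 0.2)
  expect_identical(drop_pc_gt_tc(cl)$trait_id, 2L)
})

test_that("raising the cutoff never increases the appreciable fraction", {
  trips <- random_triplets(5000, seed = 77)
  appreciable <- vapply(c(0.05, 0.2, 0.5), function(th) {
    s <- summarize_adaptation(classify_traits(trips, theta = th))
    s$c_ri + s$c_rv
  }, numeric(1))
  expect_true(all(diff(appreciable) <= 0))
})

test_that("under the symmetric null the reversion excess is centred on zero", {
  # 200 seeded replicates of the geometric generator, PC <= TC only
  diffs <- vapply(1:200, function(s) {
    cl <- classify_traits(gen_planted_q(500, q = 0.3, seed = s), theta = 0.2)
    cl <- drop_pc_gt_tc(cl)
    sm <- summarize_adaptation(cl)
    sm$c_ri - sm$c_rv
  }, numeric(1))
  ci <- mean(diffs) + c(-1.96, 1.96) * stats::sd(diffs) / sqrt(length(diffs))
  expect_lte(ci[1], 0)
  expect_gte(ci[2], 0)
})

test_that("observed C_RI/C_RV tracks (1-q)/(1+q) at planted q", {
  for (q in c(0.2, 0.5, 0.85)) {
    s <- summarize_adaptation(
      classify_traits(gen_planted_q(10000, q, seed = 11), theta = 0.2))
    expect_equal(s$ri_rv_ratio, expected_ratio(q), tolerance = 0.1)
    expect_equal(s$q, q, tolerance = 0.02)
  }
})
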