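test_that("an identity shift leaves every trait and the fitness unchanged", {
  ts <- toy_two_source()
  run <- run_adaptation(ts$model, flux_environment("C1"),
                        flux_environment("C1"))
  expect_equal(run$f_p, 1, tolerance = 1e-6)
  expect_equal(run$f_a, 1, tolerance = 1e-6)
  expect_true(all(abs(run$traits$L_p - run$traits$L_o) < 1e-6))
  cl <- classify_traits(run$traits, theta = 0.2, eps = flux_tolerance())
  expect_true(all(cl$category == "unchanged"))
})

test_that("the carbon swap reproduces the closed-form fitness trajectory", {
  # yields 1 -> 0.5: u* = y1 y2 U/(2 + y2^2) = 20/9, f_p = 1/9, f_a = 1/2
  ts <- toy_two_source()
  run <- run_adaptation(ts$model, flux_environment("C1"),
                        flux_environment("C2"))
  expect_equal(run$f_p, 1 / 9, tolerance = 1e-6)
  expect_equal(run$f_a, 1 / 2, tolerance = 1e-6)
  expect_equal(run$f_p, ts$solutions$f_p, tolerance = 1e-9)
  expect_gte(run$f_a, run$f_p)
  # equal yields: full recovery, f_p = 1/3 from u* = 10/3
  eq <- toy_two_source(yield2 = 1)
  run2 <- run_adaptation(eq$model, flux_environment("C1"),
                         flux_environment("C2"))
  expect_equal(run2$f_p, 1 / 3, tolerance = 1e-6)
  expect_equal(run2$f_a, 1, tolerance = 1e-6)
  expect_gt(run2$asymmetry, 0)     # plastic stage further from 1 than stage a
})

test_that("stage a via MOMA-b hits the FBA biomass at minimal adjustment", {
  ts <- toy_two_source()
  run <- run_adaptation(ts$model, flux_environment("C1"),
                        flux_environment("C2"), stage_a_method = "moma_b")
  m_a <- apply_environment(ts$model, flux_environment("C2"))
  expect_equal(run$biomass[["a"]], fba(m_a)$biomass, tolerance = 1e-6)
  expect_gte(run$f_a, run$f_p - 1e-9)
})

test_that("zero growth in the original environment is an error", {
  ts <- toy_two_source(yield2 = 0)
  expect_error(run_adaptation(ts$model, flux_environment("C2"),
                              flux_environment("C1")),
               "does not grow")
})

test_that("screening keeps exactly the environments MOMA can grow in", {
  # yield2 = 0: no biomass through the C2 path, C2 must be screened out
  dead <- toy_two_source(yield2 = 0)
  keep <- screen_environments(dead$model, flux_environment("C1"),
                              list(C2 = flux_environment("C2")))
  expect_length(keep, 0)

  ts <- toy_two_source()
  cands <- list(C2 = flux_environment("C2"))
  keep <- screen_environments(ts$model, flux_environment("C1"), cands)
  expect_length(keep, 1)
  expect_equal(unname(attr(keep, "f_p")), 1 / 9, tolerance = 1e-6)

  # monotone in the threshold: raising it never adds environments
  k_lo <- screen_environments(ts$model, flux_environment("C1"), cands,
                              threshold = 1e-4)
  k_hi <- screen_environments(ts$model, flux_environment("C1"), cands,
                              threshold = 0.5)
  expect_true(all(names(k_hi) %in% names(k_lo)))
  expect_length(k_hi, 0)           # f_p = 1/9 < 0.5
})

test_that("random environments match the truncated-exponential marginal", {
  sources <- paste0("s", 1:258)
  envs <- random_environments(10000, sources, seed = 7)
  counts <- lengths(lapply(envs, function(e) e$sources))
  n_draws <- 258 * 10000
  p_hat <- sum(counts) / n_draws
  p_true <- (1 - exp(-10)) / 10          # E[min(g, 1)], Exp(mean 0.1)
  half <- 2.576 * sqrt(p_true * (1 - p_true) / n_draws)
  expect_lt(abs(p_hat - p_true), half)   # 99% binomial interval
  expect_equal(mean(counts), 258 * p_true, tolerance = 0.02)

  # substreams: extending the ensemble never reshuffles earlier draws
  e5 <- random_environments(5, sources, seed = 3)
  e9 <- random_environments(9, sources, seed = 3)
  expect_identical(lapply(e5, function(e) e$sources),
                   lapply(e9[1:5], function(e) e$sources))
  # reproducible given the seed
  expect_identical(lapply(random_environments(4, sources, seed = 11),
                          function(e) e$sources),
                   lapply(random_environments(4, sources, seed = 11),
                          function(e) e$sources))
})

test_that("per-environment draws give right-skewed source counts", {
  sources <- paste0("s", 1:258)
  envs <- random_environments(3000, sources, mode = "per_environment",
                              seed = 5)
  counts <- lengths(lapply(envs, function(e) e$sources))
  expect_gt(mean(counts), stats::median(counts))
})

test_that("ensemble summaries reduce to the member runs and their medians", {
  a <- toy_two_source()                 # f_p = 1/9
  b <- toy_two_source(yield2 = 1)       # f_p = 1/3
  env_o <- flux_environment("C1")
  cands <- list(C2 = flux_environment("C2"))

  one <- run_ensemble(list(A = a$model), env_o, cands)
  expect_equal(nrow(one$per_run), 1)
  expect_equal(one$medians$median_f_p, one$per_run$f_p)

  two <- run_ensemble(list(A = a$model, B = b$model), env_o, cands)
  expect_equal(nrow(two$per_run), 2)
  expect_equal(two$medians$median_f_p, stats::median(c(1 / 9, 1 / 3)),
               tolerance = 1e-6)
  # permutation invariance in model order
  swapped <- run_ensemble(list(B = b$model, A = a$model), env_o, cands)
  expect_equal(swapped$medians$median_f_p, two$medians$median_f_p)

  # a non-growing model is skipped with a warning
  dead <- toy_two_source(yield1 = 0)
  expect_warning(
    res <- run_ensemble(list(A = a$model, DEAD = dead$model), env_o, cands),
    "skipped")
  expect_identical(unique(res$per_run$model), "A")
})
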