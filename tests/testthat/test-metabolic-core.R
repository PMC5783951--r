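test_that("model construction enforces the structural invariants", {
  S <- rbind(C = c(-1, -1), P = c(0, -1))
  expect_error(
    metabolic_model("bad", S, lb = c(5, 0), ub = c(-5, 10), obj = c(0, 1)),
    "lower bound exceeds upper bound")
  expect_error(
    metabolic_model("bad", S, lb = c(-5, 0), ub = c(5, 10), obj = c(1, 1)),
    "exactly one biomass objective")
  expect_error(
    metabolic_model("bad", S, lb = c(-5, 0), ub = c(5, 10), obj = c(0, 1),
                    is_exchange = c(TRUE, TRUE),
                    carbon_source = c("C", "C")),
    "more than one exchange")
})

test_that("FBA solves the toy chains to their analytic optima", {
  lin <- toy_linear()
  sol <- fba(lin$model)
  expect_equal(sol$biomass, 10, tolerance = 1e-6)
  expect_equal(sol$biomass, lin$solutions$fba_biomass, tolerance = 1e-6)
  expect_lt(sol$residual, 1e-4)

  # no carbon, no growth
  starved <- apply_environment(lin$model, flux_environment(character(0)))
  expect_equal(fba(starved)$biomass, 0, tolerance = 1e-6)

  dia <- toy_diamond()
  sd_ <- fba(dia$model)
  expect_equal(sd_$biomass, 10, tolerance = 1e-6)
  # path split is degenerate but must sum to the uptake
  expect_equal(unname(sd_$flux["PATH_A"] + sd_$flux["PATH_B"]), 10,
               tolerance = 1e-6)

  # yield scales the optimum
  expect_equal(fba(toy_linear(yield = 0.5)$model)$biomass, 5,
               tolerance = 1e-6)
})

test_that("FBA dominates random feasible points", {
  dia <- toy_diamond()
  best <- fba(dia$model)$biomass
  set.seed(42)
  for (i in 1:100) {
    v0 <- stats::rnorm(4, 0, 20)
    feas <- moma(dia$model, v0)   # projection: an arbitrary feasible point
    expect_equal(feas$status, "optimal")
    expect_lte(feas$biomass, best + 1e-6)
  }
})

test_that("MOMA projects a feasible reference onto itself", {
  dia <- toy_diamond()
  v0 <- c(EX_C = -4, PATH_A = 1, PATH_B = 3, BIOMASS = 4)
  sol <- moma(dia$model, v0)
  expect_equal(sol$flux, v0, tolerance = 1e-6)
  expect_equal(sol$distance, 0, tolerance = 1e-9)
})

test_that("MOMA matches the hand-solved diamond and carbon-swap QPs", {
  dia <- toy_diamond()
  # uptake halved with all flux on path A: chain shrinks, path B stays off
  m <- dia$model
  m$lb[m$rxn_id == "EX_C"] <- -5
  sol <- moma(m, c(EX_C = -10, PATH_A = 10, PATH_B = 0, BIOMASS = 10))
  expect_equal(sol$flux,
               c(EX_C = -5, PATH_A = 5, PATH_B = 0, BIOMASS = 5),
               tolerance = 1e-6)
  expect_equal(sol$flux, dia$solutions$moma_half_uptake, tolerance = 1e-6)

  # two-source swap: closed form u* = y1 y2 U / (2 + y2^2)
  ts <- toy_two_source()           # yields 1 and 0.5, uptake 10
  m_o <- apply_environment(ts$model, flux_environment("C1"))
  v0 <- fba(m_o)$flux
  expect_equal(unname(v0["BIOMASS"]), 10, tolerance = 1e-6)
  m_a <- apply_environment(ts$model, flux_environment("C2"))
  sol <- moma(m_a, v0)
  u_star <- 1 * 0.5 * 10 / (2 + 0.5^2)
  expect_equal(sol$flux,
               c(EX_C1 = 0, EX_C2 = -u_star, CNV1 = 0, CNV2 = u_star,
                 BIOMASS = 0.5 * u_star),
               tolerance = 1e-6)
  expect_equal(sol$distance,
               2 * 100 + 2 * u_star^2 + (0.5 * u_star - 10)^2,
               tolerance = 1e-6)
  expect_gt(sol$biomass, 0)        # growth resumes through the C2 path
  expect_equal(unname(sol$flux["EX_C1"]), 0, tolerance = 1e-6)
})

test_that("MOMA-b reproduces v0, resolves degeneracy, and detects infeasible targets", {
  dia <- toy_diamond()
  v0 <- c(EX_C = -6, PATH_A = 2, PATH_B = 4, BIOMASS = 6)
  sol <- moma_b(dia$model, v0, b = 6)
  expect_equal(sol$flux, v0, tolerance = 1e-6)

  # from the zero vector with biomass pinned at the optimum the symmetric
  # path split is the unique least-distance solution
  sol0 <- moma_b(dia$model, rep(0, 4), b = 10)
  expect_equal(sol0$flux, dia$solutions$moma_b_from_zero, tolerance = 1e-6)

  expect_equal(moma_b(dia$model, rep(0, 4), b = 11)$status, "infeasible")
})

test_that("the MOMA-b distance is never below the plain MOMA distance", {
  ts <- toy_two_source()
  m_o <- apply_environment(ts$model, flux_environment("C1"))
  v0 <- fba(m_o)$flux
  m_a <- apply_environment(ts$model, flux_environment("C2"))
  plain <- moma(m_a, v0)
  constrained <- moma_b(m_a, v0, b = fba(m_a)$biomass)
  expect_gte(constrained$distance, plain$distance - 1e-9)
})

test_that("optimal solutions satisfy steady state and bounds within tolerance", {
  for (fix in list(toy_linear(), toy_diamond(), toy_two_source())) {
    model <- fix$model
    for (sol in list(fba(model), moma(model, rep(1, length(model$rxn_id))))) {
      expect_equal(sol$status, "optimal")
      expect_lte(sol$residual, 1e-4)
      expect_true(all(sol$flux >= model$lb - 1e-4))
      expect_true(all(sol$flux <= model$ub + 1e-4))
    }
  }
})

test_that("the unique MOMA optimum is invariant to reaction order", {
  ts <- toy_two_source()
  m_a <- apply_environment(ts$model, flux_environment("C2"))
  v0 <- fba(apply_environment(ts$model, flux_environment("C1")))$flux
  ref <- moma(m_a, v0)$flux
  for (seed in 1:3) {
    shuf <- shuffle_reaction_order(m_a, seed)
    got <- moma(shuf, v0[shuf$rxn_id])$flux
    expect_equal(got[names(ref)], ref, tolerance = 1e-6)
  }
  # same seed, same permutation; FBA objective unaffected
  expect_identical(shuffle_reaction_order(m_a, 7)$rxn_id,
                   shuffle_reaction_order(m_a, 7)$rxn_id)
  expect_equal(fba(shuffle_reaction_order(m_a, 7))$biomass,
               fba(m_a)$biomass, tolerance = 1e-6)
})

test_that("mutable_reactions drops diffusion reactions and warns when empty", {
  lin <- toy_linear()$model
  expect_identical(mutable_reactions(lin), lin$rxn_id)
  lin$is_diffusion[1] <- TRUE
  expect_identical(mutable_reactions(lin), lin$rxn_id[-1])
  lin$is_diffusion[] <- TRUE
  expect_warning(out <- mutable_reactions(lin), "empty")
  expect_length(out, 0)
})

test_that("environments rewire only carbon uptake bounds", {
  ts <- toy_two_source()$model
  m <- apply_environment(ts, flux_environment("C1", uptake = 10))
  expect_equal(m$lb[m$rxn_id == "EX_C1"], -10)
  expect_equal(m$lb[m$rxn_id == "EX_C2"], 0)
  expect_equal(m$ub, ts$ub)                      # secretion untouched
  expect_error(apply_environment(ts, flux_environment("C9")),
               "unknown carbon source.*C1, C2")
})
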