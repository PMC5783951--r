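# Shared fixtures: toy models and a literal brute-force re-implementation of
# the trait classifier used as an independent oracle.

toy_linear <- function(...) gen_toy_model("linear", ...)
toy_diamond <- function(...) gen_toy_model("diamond", ...)
toy_two_source <- function(...) gen_toy_model("two_source", ...)

# Enumerates the category definitions one literal branch at a time, on a
# single triplet; deliberately scalar and definition-by-definition, not a
# refactor of the vectorized implementation.
oracle_classify <- function(L_o, L_p, L_a, theta = 0.2, eps = 0) {
  cutoff <- max(theta * abs(L_o), eps)
  pc <- abs(L_p - L_o)
  gc <- abs(L_a - L_p)
  tc <- abs(L_a - L_o)
  same_dir <- (L_p - L_o) * (L_a - L_p) > 0
  opp_dir <- (L_p - L_o) * (L_a - L_p) < 0
  category <-
    if (pc > cutoff && gc > cutoff && same_dir) "reinforcing"
    else if (pc > cutoff && gc > cutoff && opp_dir) "reversing"
    else if (pc > cutoff && gc <= cutoff) "plastic_only"
    else if (pc <= cutoff && gc > cutoff) "genetic_only"
    else "unchanged"
  restoration <-
    if (category != "reversing") NA_character_
    else if (tc <= cutoff) "restored"
    else if (gc > pc) "over_restored"
    else "under_restored"
  role <-
    if (!(pc > cutoff && gc > cutoff)) NA_character_
    else if (gc < tc) "facilitating"
    else if (gc > tc) "hindering"
    else NA_character_
  list(category = category, restoration = restoration, role = role,
       pc_exceeds_tc = pc > tc)
}

# Random triplets that exercise sign flips, zero baselines and values
# straddling the cutoff.
random_triplets <- function(n, seed) {
  set.seed(seed)
  L_o <- c(stats::runif(n %/% 2, -2, 2),
           sample(c(0, 1, -1), n - n %/% 2, replace = TRUE))
  step <- function() {
    mult <- sample(c(0, 0.05, 0.19, 0.2, 0.21, 0.5, 1.5), length(L_o),
                   replace = TRUE)
    sgn <- sample(c(-1, 1), length(L_o), replace = TRUE)
    ifelse(stats::runif(length(L_o)) < 0.5,
           sgn * mult * abs(L_o), stats::rnorm(length(L_o), 0, 0.5))
  }
  data.frame(trait_id = seq_along(L_o), L_o = L_o,
             L_p = L_o + step(), L_a = L_o + step() + step())
}

expect_oracle_agreement <- function(trips, theta, eps) {
  got <- classify_traits(trips, theta = theta, eps = eps)
  want <- lapply(seq_len(nrow(trips)), function(i)
    oracle_classify(trips$L_o[i], trips$L_p[i], trips$L_a[i], theta, eps))
  expect_identical(got$category, vapply(want, `[[`, character(1), "category"))
  expect_identical(got$restoration,
                   vapply(want, `[[`, character(1), "restoration"))
  expect_identical(got$plasticity_role,
                   vapply(want, `[[`, character(1), "role"))
  expect_identical(got$pc_exceeds_tc,
                   vapply(want, `[[`, logical(1), "pc_exceeds_tc"))
}
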