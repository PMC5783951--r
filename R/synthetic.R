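# Seeded generators for every input the pipeline consumes: trait triplets
# with planted categories, fitness-coupled triplets embodying the PC > TC
# mechanism, toy metabolic models with closed-form optima, and a multi-case
# expression bundle emulating an experimental-evolution compendium.

#' Specification for planted-category trait triplets
#'
#' @param n_genes number of traits.
#' @param reversing,reinforcing,plastic_only planted category fractions
#'   (must sum to at most 1; the remainder is `unchanged`).
#' @param meanlog,sdlog log-normal parameters of the baseline `L_o`.
#' @param effect range (multiples of `L_o`) from which appreciable plastic
#'   and genetic effects are drawn; the default `[0.3, 1]` leaves a 0.1
#'   margin above the conventional `0.2 L_o` cutoff.
#' @param margin half-width (multiples of `L_o`) of non-appreciable
#'   changes, i.e. a 0.1 margin below the cutoff.
#' @param noise_sd standard deviation of the multiplicative log-normal
#'   measurement noise applied after construction.
#' @param seed integer seed.
#' @return An object of class `triplet_spec`.
#' @export
triplet_spec <- function(n_genes = 1811, reversing = 0.302,
                         reinforcing = 0.010, plastic_only = 0.0062,
                         meanlog = 0, sdlog = 1, effect = c(0.3, 1),
                         margin = 0.1, noise_sd = 0.02, seed = 1L) {
  fr <- c(reversing, reinforcing, plastic_only)
  if (any(fr < 0) || sum(fr) > 1)
    stopf("planted fractions must be non-negative and sum to at most 1")
  if (n_genes < 1) stopf("n_genes must be >= 1")
  if (margin >= 0.2) stopf("margin must stay below the 0.2 cutoff")
  structure(list(n_genes = as.integer(n_genes), reversing = reversing,
                 reinforcing = reinforcing, plastic_only = plastic_only,
                 meanlog = meanlog, sdlog = sdlog, effect = effect,
                 margin = margin, noise_sd = noise_sd, seed = seed),
            class = "triplet_spec")
}

#' Generate trait triplets with planted categories
#'
#' Each gene is assigned a category (multinomial draw with the planted
#' fractions) and `L_p`, `L_a` are constructed to realize it at the 0.2
#' cutoff with margin: appreciable effects are drawn from
#' `spec$effect * L_o` (two stacked downward moves are jointly capped so
#' expression stays non-negative), non-appreciable ones from
#' `[-margin, margin] * L_o`.
#' Multiplicative log-normal noise is applied afterwards.
#'
#' @param spec a [triplet_spec()].
#' @return A data frame with `trait_id`, `L_o`, `L_p`, `L_a` and the
#'   ground-truth `truth` column.
#' @export
gen_triplets <- function(spec) {
  stopifnot(inherits(spec, "triplet_spec"))
  withr_seed(spec$seed, {
    n <- spec$n_genes
    cats <- sample(c("reversing", "reinforcing", "plastic_only", "unchanged"),
                   n, replace = TRUE,
                   prob = c(spec$reversing, spec$reinforcing,
                            spec$plastic_only,
                            1 - spec$reversing - spec$reinforcing -
                              spec$plastic_only))
    L_o <- stats::rlnorm(n, spec$meanlog, spec$sdlog)
    s <- sample(c(-1, 1), n, replace = TRUE)
    lo <- spec$effect[1]; hi <- spec$effect[2]
    small <- function() stats::runif(n, -spec$margin, spec$margin)
    # appreciable effects as multiples of L_o. A single move of at most
    # 1.0 L_o (or an opposing pair) can never push a value below zero; only
    # two stacked downward moves (reinforcing, s = -1) can, so only there
    # the pair is capped to a total drop of 0.95 L_o.
    stack_down <- cats == "reinforcing" & s < 0
    u1 <- stats::runif(n, lo, ifelse(stack_down, pmin(hi, 0.55), hi))
    u2_same <- stats::runif(n, lo,
                            ifelse(stack_down, pmin(hi, 0.95 - u1), hi))
    u2_opp <- stats::runif(n, lo, hi)
    dp <- ifelse(cats == "unchanged", small() * L_o, s * u1 * L_o)
    dg <- ifelse(cats == "reversing", -s * u2_opp * L_o,
          ifelse(cats == "reinforcing", s * u2_same * L_o, small() * L_o))
    L_p <- L_o + dp
    L_a <- L_p + dg
    noise <- function(x) x * exp(stats::rnorm(n, 0, spec$noise_sd))
    data.frame(trait_id = sprintf("g%05d", seq_len(n)),
               L_o = noise(L_o), L_p = noise(L_p), L_a = noise(L_a),
               truth = cats)
  })
}

#' Specification for fitness-coupled (mechanism) triplets
#'
#' Encodes the proposed cause of the reversion excess: organismal fitness
#' drops to `f_p` right after the shift and recovers to `f_a` after
#' re-adaptation, and fitness-coupled traits deviate in proportion to the
#' fitness deviation -- so the plastic stage is the outlier and PC > TC for
#' strongly coupled traits.
#'
#' @param f_p relative fitness at the plastic stage, in (0, 1].
#' @param f_a relative fitness after re-adaptation (> 0; typically near 1).
#' @param coupling standard deviation of the per-trait fitness-coupling
#'   strength (log scale); 0 decouples traits from fitness.
#' @param n_traits number of traits.
#' @param shift_sd standard deviation of the per-trait adaptive shift
#'   between stages o and a (log scale), independent of the plastic
#'   direction.
#' @param noise_sd log-scale measurement noise.
#' @param seed integer seed.
#' @return An object of class `mechanism_spec`.
#' @export
mechanism_spec <- function(f_p = 0.1, f_a = 1.0, coupling = 1.0,
                           n_traits = 10000L, shift_sd = 0.3,
                           noise_sd = 0.02, seed = 1L) {
  if (f_p <= 0 || f_p > 1) stopf("f_p must lie in (0, 1]")
  if (f_a <= 0) stopf("f_a must be positive")
  structure(list(f_p = f_p, f_a = f_a, coupling = coupling,
                 n_traits = as.integer(n_traits), shift_sd = shift_sd,
                 noise_sd = noise_sd, seed = seed),
            class = "mechanism_spec")
}

#' Generate fitness-coupled trait triplets
#'
#' On the log scale each trait `i` follows its coupling `k_i ~ N(0,
#' coupling^2)` times the fitness drop `-log(f)` of the stage, plus an
#' independent adaptive shift at stage a and measurement noise:
#' the plastic stage deviates most when `f_p` is small, making
#' `q = Pr(PC > TC)` rise as `f_p` falls, while the symmetric shift keeps
#' reinforcement and reversion balanced among traits with PC <= TC -- the
#' regime in which the observed `C_RI/C_RV` tracks [expected_ratio()].
#'
#' @param spec a [mechanism_spec()].
#' @return A data frame with `trait_id`, `L_o`, `L_p`, `L_a`.
#' @export
gen_mechanism_triplets <- function(spec) {
  stopifnot(inherits(spec, "mechanism_spec"))
  withr_seed(spec$seed, {
    n <- spec$n_traits
    mu <- stats::rnorm(n, 0, 1)
    k <- stats::rnorm(n, 0, spec$coupling)
    d_p <- -log(spec$f_p)
    d_a <- -log(spec$f_a)
    delta <- stats::rnorm(n, 0, spec$shift_sd)
    eps <- function() stats::rnorm(n, 0, spec$noise_sd)
    data.frame(trait_id = sprintf("t%05d", seq_len(n)),
               L_o = exp(mu + eps()),
               L_p = exp(mu + k * d_p + eps()),
               L_a = exp(mu + k * d_a + delta + eps()))
  })
}

#' Generate triplets realizing the geometric null at a planted q
#'
#' Implements the geometric argument behind [expected_ratio()] directly:
#' a planted fraction `q` of traits gets PC > TC (the genetic change is
#' then forced to reverse the plastic change), while for the remainder
#' PC <= TC and the direction of the genetic change is a fair coin. All
#' plastic and genetic changes are appreciable at `theta = 0.2` by
#' construction, so the observed `C_RI/C_RV` converges to
#' `(1 - q)/(1 + q)` and dropping the PC > TC traits leaves reinforcement
#' and reversion balanced.
#'
#' @param n number of traits.
#' @param q planted probability of PC > TC, in `[0, 1]`.
#' @param meanlog,sdlog log-normal parameters of the baseline `L_o`.
#' @param seed integer seed.
#' @return A data frame with `trait_id`, `L_o`, `L_p`, `L_a` and a logical
#'   `forced` column marking the planted PC > TC traits.
#' @export
gen_planted_q <- function(n, q, meanlog = 0, sdlog = 1, seed = 1L) {
  if (q < 0 || q > 1) stopf("'q' must lie in [0, 1]")
  withr_seed(seed, {
    L_o <- stats::rlnorm(n, meanlog, sdlog)
    s <- sample(c(-1, 1), n, replace = TRUE)
    forced <- stats::runif(n) < q
    u1 <- stats::runif(n, 0.4, 0.8)
    # forced: GC opposes PC with |GC| within (0.8, 1.2) PC, so TC < PC
    # while both stay well above the 0.2 |L_o| cutoff
    u2_forced <- u1 * stats::runif(n, 0.8, 1.2)
    # free: fair-coin direction; opposing moves overshoot (|GC| >= 2 PC)
    # so that TC >= PC either way
    coin <- sample(c(-1, 1), n, replace = TRUE)
    u2_free <- ifelse(coin == s, stats::runif(n, 0.4, 0.8),
                      2 * u1 + stats::runif(n, 0.1, 0.4))
    dp <- s * u1 * L_o
    dg <- ifelse(forced, -s * u2_forced, coin * u2_free) * L_o
    data.frame(trait_id = sprintf("t%05d", seq_len(n)),
               L_o = L_o, L_p = L_o + dp, L_a = L_o + dp + dg,
               forced = forced)
  })
}

#' Construct toy metabolic models with closed-form optima
#'
#' Three shapes, each with a documented analytic solution sheet:
#'
#' * `linear`: a single chain, uptake -> conversion -> biomass; the FBA
#'   optimum is `uptake * yield`.
#' * `diamond`: two parallel, redundant paths from the carbon source to the
#'   biomass precursor; the FBA optimum is degenerate in the path split,
#'   while MOMA resolves it uniquely.
#' * `two_source`: two carbon sources with different yields (`yield1`,
#'   `yield2`), supporting a full o -> p -> a carbon-swap adaptation. The
#'   solution sheet carries the closed-form MOMA flux after the C1 -> C2
#'   swap (`u* = yield1 * yield2 * uptake / (2 + yield2^2)` through the C2
#'   path) and the resulting `f_p` and `f_a`.
#'
#' @param kind `"linear"`, `"diamond"` or `"two_source"`.
#' @param uptake uptake bound of each carbon source (default 10).
#' @param yield,yield1,yield2 biomass-precursor yields of the conversion
#'   reactions.
#' @return A list with `model` (a [metabolic_model()]) and `solutions`
#'   (named closed-form reference values used as solver fixtures).
#' @export
gen_toy_model <- function(kind = c("linear", "diamond", "two_source"),
                          uptake = 10, yield = 1, yield1 = 1, yield2 = 0.5) {
  kind <- match.arg(kind)
  big <- 1000
  if (kind == "linear") {
    S <- rbind(C = c(-1, -1, 0), P = c(0, yield, -1))
    colnames(S) <- c("EX_C", "CONV", "BIOMASS")
    model <- metabolic_model(
      id = "toy_linear", S = S,
      lb = c(-uptake, 0, 0), ub = c(big, big, big), obj = c(0, 0, 1),
      is_exchange = c(TRUE, FALSE, FALSE),
      carbon_source = c("C", NA, NA))
    sols <- list(fba_biomass = uptake * yield)
  } else if (kind == "diamond") {
    S <- rbind(C = c(-1, -1, -1, 0), P = c(0, 1, 1, -1))
    colnames(S) <- c("EX_C", "PATH_A", "PATH_B", "BIOMASS")
    model <- metabolic_model(
      id = "toy_diamond", S = S,
      lb = c(-uptake, 0, 0, 0), ub = c(big, big, big, big),
      obj = c(0, 0, 0, 1),
      is_exchange = c(TRUE, FALSE, FALSE, FALSE),
      carbon_source = c("C", NA, NA, NA))
    sols <- list(
      fba_biomass = uptake,
      # v0 all on path A at full uptake, then uptake halved: the nearest
      # feasible point keeps path B off and scales the chain
      moma_half_uptake = c(EX_C = -uptake / 2, PATH_A = uptake / 2,
                           PATH_B = 0, BIOMASS = uptake / 2),
      # v0 = 0 with biomass pinned at the optimum: symmetry forces an
      # even path split (unique MOMA-b optimum on the degenerate face)
      moma_b_from_zero = c(EX_C = -uptake, PATH_A = uptake / 2,
                           PATH_B = uptake / 2, BIOMASS = uptake))
  } else {
    S <- rbind(C1 = c(-1, 0, -1, 0, 0),
               C2 = c(0, -1, 0, -1, 0),
               P  = c(0, 0, yield1, yield2, -1))
    colnames(S) <- c("EX_C1", "EX_C2", "CNV1", "CNV2", "BIOMASS")
    model <- metabolic_model(
      id = "toy_two_source", S = S,
      lb = c(-uptake, -uptake, 0, 0, 0), ub = rep(big, 5),
      obj = c(0, 0, 0, 0, 1),
      is_exchange = c(TRUE, TRUE, FALSE, FALSE, FALSE),
      carbon_source = c("C1", "C2", NA, NA, NA))
    # C1 -> C2 swap: v0 = (-U, 0, U, 0, y1 U); in the C2-only environment
    # the C1 branch is forced to zero and the C2 path flux u minimizes
    # 2 u^2 + (y2 u - y1 U)^2, giving u* = y1 y2 U / (2 + y2^2).
    u_star <- yield1 * yield2 * uptake / (2 + yield2^2)
    sols <- list(
      fba_biomass_c1 = uptake * yield1,
      fba_biomass_c2 = uptake * yield2,
      moma_swap = c(EX_C1 = 0, EX_C2 = -u_star, CNV1 = 0, CNV2 = u_star,
                    BIOMASS = yield2 * u_star),
      moma_swap_distance = 2 * (uptake^2) + 2 * u_star^2 +
        (yield2 * u_star - yield1 * uptake)^2,
      f_p = yield2 * u_star / (uptake * yield1),
      f_a = yield2 / yield1)
  }
  list(model = model, solutions = sols)
}

#' Generate a synthetic multi-case adaptation bundle
#'
#' Emulates a compendium of experimental-evolution cases: `n_cases` trait
#' tables with planted category structure, of which `n_reversion_excess`
#' have an excess of reversion over reinforcement and the remainder the
#' opposite. Used to exercise the cross-case sign test with known ground
#' truth.
#'
#' @param n_cases number of adaptation cases (default 44).
#' @param n_reversion_excess cases planted with `C_RV > C_RI` (default 42).
#' @param n_genes traits per case.
#' @param strong,weak planted fractions for the majority and minority
#'   category within a case.
#' @param seed master seed; case `i` uses a derived substream.
#' @return A list with `cases` (named list of triplet tables carrying a
#'   `truth` column) and `truth` (data frame of the planted per-case
#'   direction).
#' @export
gen_case_bundle <- function(n_cases = 44, n_reversion_excess = 42,
                            n_genes = 2000, strong = 0.30, weak = 0.05,
                            seed = 1L) {
  stopifnot(n_reversion_excess <= n_cases)
  cases <- lapply(seq_len(n_cases), function(i) {
    rev_excess <- i <= n_reversion_excess
    gen_triplets(triplet_spec(
      n_genes = n_genes,
      reversing = if (rev_excess) strong else weak,
      reinforcing = if (rev_excess) weak else strong,
      plastic_only = 0.11,
      seed = substream_seed(seed, i)))
  })
  names(cases) <- sprintf("case_%02d", seq_len(n_cases))
  list(cases = cases,
       truth = data.frame(case = names(cases),
                          planted_rv_excess =
                            seq_len(n_cases) <= n_reversion_excess))
}
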