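#' Classify o/p/a trait triplets into plastic/genetic change categories
#'
#' For each trait measured at the three adaptation stages -- `L_o` (adapted
#' ancestor, original environment), `L_p` (ancestor right after the shift),
#' `L_a` (re-adapted organism) -- computes the plastic change
#' `PC = |L_p - L_o|`, the genetic change `GC = |L_a - L_p|`, and the total
#' change `TC = |L_a - L_o|`, and assigns one category per trait:
#'
#' * `reinforcing`: PC and GC both exceed the cutoff and point in the same
#'   direction;
#' * `reversing`: both exceed the cutoff with opposite directions;
#' * `plastic_only`: only PC exceeds the cutoff;
#' * `genetic_only`: only GC exceeds the cutoff;
#' * `unchanged`: neither does.
#'
#' The effective cutoff is `max(theta * |L_o|, eps)`: relative to the
#' original trait value, floored by the absolute tolerance used to ignore
#' numerically meaningless flux differences. Exceeding means strictly
#' greater; a change exactly at the cutoff is not appreciable.
#'
#' Reversing traits are further split by how far the original value is
#' recovered: `restored` when `TC <= cutoff`, else `over_restored` when
#' `GC > PC` and `under_restored` otherwise. Whenever PC and GC are both
#' appreciable, the plastic change is `facilitating` if `GC < TC` (it
#' reduced the genetic change needed) and `hindering` if `GC > TC`.
#'
#' @param traits data frame with columns `trait_id`, `L_o`, `L_p`, `L_a`
#'   (extra columns are preserved).
#' @param theta relative cutoff fraction (> 0); 0.05, 0.2 and 0.5 are the
#'   conventional choices, 0.2 the default.
#' @param eps absolute cutoff floor; use [flux_tolerance()] for fluxes and
#'   0 (default) for expression data.
#' @return The input with columns `pc`, `gc`, `tc`, `cutoff`, `category`,
#'   `restoration`, `plasticity_role`, `pc_exceeds_tc` appended.
#' @export
classify_traits <- function(traits, theta = 0.2, eps = 0) {
  if (!is.data.frame(traits) ||
      !all(c("L_o", "L_p", "L_a") %in% names(traits)))
    stopf("'traits' must be a data frame with columns L_o, L_p, L_a")
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0)
    stopf("'theta' must be a single positive number")
  if (eps < 0) stopf("'eps' must be non-negative")
  L_o <- traits$L_o; L_p <- traits$L_p; L_a <- traits$L_a
  if (!all(is.finite(L_o) & is.finite(L_p) & is.finite(L_a)))
    stopf("trait values must be finite")
  dp <- L_p - L_o
  dg <- L_a - L_p
  pc <- abs(dp)
  gc <- abs(dg)
  tc <- abs(L_a - L_o)
  cutoff <- pmax(theta * abs(L_o), eps)
  p_app <- pc > cutoff
  g_app <- gc > cutoff
  category <- rep("unchanged", length(pc))
  category[p_app & !g_app] <- "plastic_only"
  category[!p_app & g_app] <- "genetic_only"
  category[p_app & g_app & dp * dg > 0] <- "reinforcing"
  category[p_app & g_app & dp * dg < 0] <- "reversing"
  restoration <- rep(NA_character_, length(pc))
  rv <- category == "reversing"
  restoration[rv & tc <= cutoff] <- "restored"
  restoration[rv & tc > cutoff & gc > pc] <- "over_restored"
  restoration[rv & tc > cutoff & gc <= pc] <- "under_restored"
  role <- rep(NA_character_, length(pc))
  both <- p_app & g_app
  role[both & gc < tc] <- "facilitating"
  role[both & gc > tc] <- "hindering"
  traits$pc <- pc
  traits$gc <- gc
  traits$tc <- tc
  traits$cutoff <- cutoff
  traits$category <- category
  traits$restoration <- restoration
  traits$plasticity_role <- role
  traits$pc_exceeds_tc <- pc > tc
  traits
}

#' @rdname classify_traits
#' @param L_o,L_p,L_a single trait values for the scalar convenience form.
#' @export
classify_trait <- function(L_o, L_p, L_a, theta = 0.2, eps = 0) {
  classify_traits(data.frame(trait_id = "trait", L_o = L_o, L_p = L_p,
                             L_a = L_a),
                  theta = theta, eps = eps)
}

#' Summarize classified traits for one adaptation
#'
#' Computes the per-adaptation fractions over all analyzed traits: `c_ri`
#' (reinforcing), `c_rv` (reversing) and their ratio, the restoration
#' breakdown of reversion, `c_fac`/`c_hin` (facilitating/hindering
#' plasticity), `q` (fraction of traits with PC > TC, the quantity driving
#' the analytic null ratio `(1-q)/(1+q)`), the plastic-only and
#' genetic-only fractions, mean PC and mean TC, and the exact two-tailed
#' binomial test of reinforcement vs reversion counts. With zero traits in
#' both classes the p-value is reported as 1 with `zero_counts = TRUE`.
#'
#' @param classified output of [classify_traits()] (non-empty).
#' @return A one-row data frame.
#' @export
summarize_adaptation <- function(classified) {
  if (!is.data.frame(classified) || nrow(classified) == 0L)
    stopf("cannot summarize an empty trait set")
  if (!"category" %in% names(classified))
    stopf("traits must be classified first (see classify_traits)")
  n <- nrow(classified)
  n_ri <- sum(classified$category == "reinforcing")
  n_rv <- sum(classified$category == "reversing")
  data.frame(
    n_traits = n,
    n_ri = n_ri,
    n_rv = n_rv,
    c_ri = n_ri / n,
    c_rv = n_rv / n,
    ri_rv_ratio = if (n_rv > 0) n_ri / n_rv else NA_real_,
    restored = sum(classified$restoration %in% "restored") / n,
    over_restored = sum(classified$restoration %in% "over_restored") / n,
    under_restored = sum(classified$restoration %in% "under_restored") / n,
    c_fac = sum(classified$plasticity_role %in% "facilitating") / n,
    c_hin = sum(classified$plasticity_role %in% "hindering") / n,
    q = mean(classified$pc_exceeds_tc),
    plastic_only = sum(classified$category == "plastic_only") / n,
    genetic_only = sum(classified$category == "genetic_only") / n,
    mean_pc = mean(classified$pc),
    mean_tc = mean(classified$tc),
    p_two_tailed = if (n_ri + n_rv > 0) binom_two_tailed(n_ri, n_ri + n_rv)
                   else 1,
    zero_counts = n_ri + n_rv == 0L
  )
}

check_kn <- function(k, n) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      k != round(k) || n != round(n) || n < 1 || k < 0 || k > n)
    stopf("'k' must be an integer in [0, n] and 'n' a positive integer")
}

#' Exact binomial tests with null probability 1/2
#'
#' `binom_two_tailed()` doubles the smaller tail of the Binomial(n, 0.5)
#' distribution and caps at 1: `min(1, 2 * min(P(X <= k), P(X >= k)))`.
#' `binom_one_tailed()` is the upper tail `P(X >= k)`. Used to compare
#' reinforcement vs reversion counts within an adaptation and direction
#' counts across adaptations.
#'
#' @param k number of successes.
#' @param n number of trials.
#' @return The exact p-value.
#' @export
binom_two_tailed <- function(k, n) {
  check_kn(k, n)
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' @rdname binom_two_tailed
#' @export
binom_one_tailed <- function(k, n) {
  check_kn(k, n)
  stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
}

#' Expected reinforcement/reversion ratio under the geometric null
#'
#' When a fraction `q` of traits has PC > TC, those traits must be
#' reversing, while the remaining traits split evenly between
#' reinforcement and reversion absent any other bias. The expected ratio is
#' therefore `0.5 * (1 - q) / (0.5 * (1 - q) + q) = (1 - q) / (1 + q)`,
#' which is below 1 whenever `q > 0`.
#'
#' @param q fraction of traits with PC > TC, in `[0, 1]`.
#' @return The expected `C_RI / C_RV`.
#' @export
expected_ratio <- function(q) {
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1))
    stopf("'q' must lie in [0, 1]")
  (1 - q) / (1 + q)
}

#' Subset classified traits to those with an appreciable total change
#'
#' Keeps traits with `TC > cutoff`, the subset visible to comparative
#' studies that can only contrast organisms adapted to different
#' environments (stage p being inaccessible). Restored reversing traits
#' have `TC <= cutoff` by definition and are always excluded.
#'
#' @param classified output of [classify_traits()].
#' @return The retained rows.
#' @export
condition_on_tc <- function(classified) {
  classified[classified$tc > classified$cutoff, , drop = FALSE]
}

#' Drop traits whose plastic change exceeds the total change
#'
#' Removes every trait with PC > TC. Since such traits can only revert,
#' removing them tests whether the excess of reversion over reinforcement
#' is fully explained by their presence: on the remaining set the two
#' categories should be symmetric absent any other bias.
#'
#' @param classified output of [classify_traits()].
#' @return The rows with `PC <= TC`.
#' @export
drop_pc_gt_tc <- function(classified) {
  classified[!classified$pc_exceeds_tc, , drop = FALSE]
}
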