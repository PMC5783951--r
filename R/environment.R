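#' Define a growth environment by its available carbon sources
#'
#' An environment is the set of carbon sources the model may take up,
#' together with the maximal uptake rate of each (mmol gDW^-1 h^-1).
#' Non-carbon exchange settings are inherited from the model.
#'
#' @param sources character vector of carbon-source identifiers (may be
#'   empty: no carbon, no growth).
#' @param uptake maximal uptake rate, either a single value applied to every
#'   source (default 10) or a named vector with one entry per source.
#' @return An object of class `flux_environment`.
#' @export
flux_environment <- function(sources, uptake = 10) {
  sources <- as.character(sources)
  if (length(uptake) == 1L && is.null(names(uptake)))
    uptake <- stats::setNames(rep(as.numeric(uptake), length(sources)), sources)
  uptake <- uptake[sources]
  if (length(sources) && (anyNA(uptake) || any(uptake < 0)))
    stopf("every source needs a non-negative uptake bound")
  names(uptake) <- sources
  structure(list(sources = sources, uptake = uptake),
            class = "flux_environment")
}

#' @export
print.flux_environment <- function(x, ...) {
  cat(sprintf("<flux_environment> %d carbon source(s): %s\n",
              length(x$sources),
              paste(sprintf("%s (%.3g)", x$sources, x$uptake), collapse = ", ")))
  invisible(x)
}

env_label <- function(env) {
  if (!length(env$sources)) "none" else paste(env$sources, collapse = "+")
}

#' Impose an environment on a model's exchange bounds
#'
#' The lower bound of each available carbon exchange is set to minus its
#' uptake bound; uptake through every other carbon exchange is closed
#' (lower bound 0) while secretion (the upper bound) is left untouched.
#' Non-carbon exchanges keep the model defaults.
#'
#' @param model a [metabolic_model()].
#' @param env a [flux_environment()]; every source must exist in the model.
#' @return The modified `metabolic_model`.
#' @export
apply_environment <- function(model, env) {
  known <- model$carbon_source[!is.na(model$carbon_source)]
  unknown <- setdiff(env$sources, known)
  if (length(unknown))
    stopf("unknown carbon source(s): %s. Valid sources: %s",
          paste(unknown, collapse = ", "), paste(known, collapse = ", "))
  carbon <- !is.na(model$carbon_source)
  model$lb[carbon] <- 0                       # close all carbon uptake
  avail <- carbon & model$carbon_source %in% env$sources
  model$lb[avail] <- -env$uptake[model$carbon_source[avail]]
  validate_model(model)
  model
}

#' Screen candidate environments for adaptability
#'
#' An environment counts as adaptable when the MOMA-predicted biomass of the
#' ancestor immediately after the shift, relative to its biomass in the
#' original environment, exceeds `threshold` -- i.e. the plastic response
#' alone sustains some growth, so the population can persist long enough to
#' adapt genetically.
#'
#' @param model a [metabolic_model()].
#' @param env_o original [flux_environment()] (the model must grow in it).
#' @param candidates list of candidate [flux_environment()]s, excluding
#'   `env_o`.
#' @param threshold relative-fitness cutoff (default [flux_tolerance()]).
#' @return The adaptable subset of `candidates`, input order preserved, with
#'   the relative fitness of every candidate in attribute `"f_p"`.
#' @export
screen_environments <- function(model, env_o, candidates,
                                threshold = flux_tolerance()) {
  sol_o <- fba(apply_environment(model, env_o))
  if (sol_o$status != "optimal" || sol_o$biomass <= flux_tolerance())
    stopf("model does not grow in the original environment")
  f_p <- vapply(candidates, function(env) {
    sol <- moma(apply_environment(model, env), sol_o$flux)
    if (sol$status != "optimal") return(NA_real_)
    sol$biomass / sol_o$biomass
  }, numeric(1))
  keep <- !is.na(f_p) & f_p > threshold
  structure(candidates[keep], f_p = f_p[keep])
}

#' Draw random mixed-carbon environments
#'
#' Each candidate carbon source is present with a probability `g` drawn from
#' an exponential distribution (mean `mean_avail`), truncated to `[0, 1]`;
#' presence is then a Bernoulli event with that probability. Under
#' `"per_source"` mode a fresh `g` is drawn for every (environment, source)
#' pair; under `"per_environment"` one `g` is shared by all sources of an
#' environment, which produces right-skewed source counts.
#'
#' @param n number of environments.
#' @param sources character vector of candidate carbon-source identifiers.
#' @param mean_avail mean of the exponential availability distribution
#'   (default 0.1).
#' @param uptake uptake bound given to every available source (default 10).
#' @param mode `"per_source"` or `"per_environment"`.
#' @param seed master seed; each environment uses a derived substream so the
#'   first `k` environments are identical for any `n >= k`.
#' @return A list of `n` [flux_environment()]s.
#' @export
random_environments <- function(n, sources, mean_avail = 0.1, uptake = 10,
                                mode = c("per_source", "per_environment"),
                                seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, mean_avail > 0)
  lapply(seq_len(n), function(i) {
    withr_seed(substream_seed(seed, i), {
      ns <- length(sources)
      g <- if (mode == "per_source") stats::rexp(ns, rate = 1 / mean_avail)
           else rep(stats::rexp(1, rate = 1 / mean_avail), ns)
      present <- stats::runif(ns) < pmin(g, 1)
      flux_environment(sources[present], uptake)
    })
  })
}
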