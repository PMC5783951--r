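#' Simulate one o -> p -> a environmental adaptation
#'
#' Runs the three-stage protocol on a metabolic model: stage o is the FBA
#' optimum in the original environment (the adapted ancestor); stage p is
#' the MOMA projection of the stage-o fluxes onto the new environment (the
#' plastic state immediately after the shift, before any mutation); stage a
#' is the re-adapted state in the new environment, predicted either by FBA
#' (default) or by [moma_b()] from the stage-p fluxes at the FBA-optimal
#' biomass. Relative fitnesses are biomass rates divided by the stage-o
#' rate.
#'
#' @param model a [metabolic_model()].
#' @param env_o,env_a original and new [flux_environment()]s.
#' @param stage_a_method `"fba"` or `"moma_b"`.
#' @param tol numeric tolerance (default [flux_tolerance()]).
#' @return An object of class `adaptation_run` with elements `v_o`, `v_p`,
#'   `v_a` (flux solutions), `biomass` (named o/p/a rates), `f_p`, `f_a`,
#'   `asymmetry` (`|log10 f_p| - |log10 f_a|`), and `traits`, a data frame
#'   of `trait_id`, `L_o`, `L_p`, `L_a` over the [mutable_reactions()].
#' @export
run_adaptation <- function(model, env_o, env_a,
                           stage_a_method = c("fba", "moma_b"),
                           tol = flux_tolerance()) {
  stage_a_method <- match.arg(stage_a_method)
  m_o <- apply_environment(model, env_o)
  sol_o <- fba(m_o)
  if (sol_o$status != "optimal" || sol_o$biomass <= tol)
    stopf("model does not grow in the original environment '%s'; relative fitness is undefined",
          env_label(env_o))
  m_a <- apply_environment(model, env_a)
  sol_p <- moma(m_a, sol_o$flux)
  if (sol_p$status != "optimal")
    stopf("MOMA failed in the new environment '%s' (status %s)",
          env_label(env_a), sol_p$status)
  sol_fba_a <- fba(m_a)
  if (sol_fba_a$status != "optimal")
    stopf("FBA failed in the new environment '%s' (status %s)",
          env_label(env_a), sol_fba_a$status)
  sol_a <- if (stage_a_method == "fba") sol_fba_a
           else moma_b(m_a, sol_p$flux, sol_fba_a$biomass)
  if (sol_a$status != "optimal")
    stopf("stage-a solver failed in '%s' (status %s)",
          env_label(env_a), sol_a$status)
  b <- c(o = sol_o$biomass, p = sol_p$biomass, a = sol_a$biomass)
  f_p <- unname(b["p"] / b["o"])
  f_a <- unname(b["a"] / b["o"])
  traits <- mutable_reactions(model)
  structure(list(
    env_o = env_o, env_a = env_a, stage_a_method = stage_a_method,
    v_o = sol_o, v_p = sol_p, v_a = sol_a,
    biomass = b, f_p = f_p, f_a = f_a,
    asymmetry = if (f_p > 0 && f_a > 0) abs(log10(f_p)) - abs(log10(f_a))
                else NA_real_,
    traits = data.frame(trait_id = traits,
                        L_o = unname(sol_o$flux[traits]),
                        L_p = unname(sol_p$flux[traits]),
                        L_a = unname(sol_a$flux[traits]))
  ), class = "adaptation_run")
}

#' @export
print.adaptation_run <- function(x, ...) {
  cat(sprintf("<adaptation_run> %s -> %s (stage a: %s)\n",
              env_label(x$env_o), env_label(x$env_a), x$stage_a_method))
  cat(sprintf("  f_p = %.4g, f_a = %.4g, asymmetry = %.4g, %d traits\n",
              x$f_p, x$f_a, x$asymmetry, nrow(x$traits)))
  invisible(x)
}

#' Run the adaptation protocol over an ensemble of models
#'
#' Applies [screen_environments()] and [run_adaptation()] to each model,
#' classifies the flux traits of every adaptable shift, and summarizes per
#' model x environment; models that fail to grow in the original
#' environment are skipped with a warning. Across-model medians per
#' environment let a focal model (e.g. a real organism's network) be placed
#' against the ensemble distribution.
#'
#' @param models named list of [metabolic_model()]s.
#' @param env_o original [flux_environment()].
#' @param candidates list of candidate new environments.
#' @param theta relative cutoff for the trait classifier (default 0.2).
#' @param stage_a_method passed to [run_adaptation()].
#' @param tol numeric tolerance.
#' @return A list with `per_run` (one row per model x adaptable
#'   environment: fitnesses plus the [summarize_adaptation()] columns) and
#'   `medians` (per-environment medians of `c_rv`, `c_ri`, `ri_rv_ratio`,
#'   `q`, `f_p`, `asymmetry` across models).
#' @export
run_ensemble <- function(models, env_o, candidates, theta = 0.2,
                         stage_a_method = "fba", tol = flux_tolerance()) {
  if (is.null(names(models)))
    names(models) <- paste0("model_", seq_along(models))
  if (is.null(names(candidates)))
    names(candidates) <- vapply(candidates, env_label, character(1))
  rows <- list()
  for (mid in names(models)) {
    model <- models[[mid]]
    ok <- tryCatch({
      sol <- fba(apply_environment(model, env_o))
      sol$status == "optimal" && sol$biomass > tol
    }, error = function(e) FALSE)
    if (!ok) {
      warning(sprintf("model '%s' does not grow in the original environment; skipped", mid))
      next
    }
    adaptable <- screen_environments(model, env_o, candidates, threshold = tol)
    for (eid in names(adaptable)) {
      run <- run_adaptation(model, env_o, adaptable[[eid]],
                            stage_a_method = stage_a_method, tol = tol)
      cl <- classify_traits(run$traits, theta = theta, eps = tol)
      smry <- summarize_adaptation(cl)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(model = mid, environment = eid, f_p = run$f_p,
                         f_a = run$f_a, asymmetry = run$asymmetry),
              smry)
    }
  }
  if (!length(rows))
    return(list(per_run = data.frame(), medians = data.frame()))
  per_run <- do.call(rbind, rows)
  med_cols <- c("c_rv", "c_ri", "ri_rv_ratio", "q", "f_p", "asymmetry")
  medians <- do.call(rbind, lapply(split(per_run, per_run$environment),
    function(d) {
      out <- data.frame(environment = d$environment[1], n_models = nrow(d))
      for (cc in med_cols)
        out[[paste0("median_", cc)]] <- stats::median(d[[cc]], na.rm = TRUE)
      out
    }))
  rownames(medians) <- NULL
  list(per_run = per_run, medians = medians)
}
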