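# End-to-end orchestration: configuration-driven adaptation runs and
# multi-case triplet classification, with deterministic TSV/JSON reporting.
# The numbered scripts under analysis/ are thin drivers over these
# functions.

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

load_model_any <- function(x) {
  if (inherits(x, "metabolic_model")) return(x)
  if (grepl("\\.json$", x)) read_model_json(x)
  else read_sbml_model(x)
}

build_env <- function(cfg) flux_environment(cfg$sources,
                                            uptake = cfg$uptake %||% 10)

#' Run the screen/adapt/classify/summarize workflow from a configuration
#'
#' Executes, for every candidate new environment that passes the
#' adaptability screen, the full o -> p -> a protocol and trait
#' classification, and writes a per-adaptation summary table plus a JSON
#' run manifest. Outputs are deterministic: identical configuration and
#' seed give byte-identical tables.
#'
#' @param config either a YAML file path or a list with elements:
#'   `model` (path to SBML/JSON or a [metabolic_model()]); `original`
#'   (list with `sources`, optional `uptake`); `candidates` (either
#'   `"all_single_carbon"`, a list of environment specs, or a list with
#'   `random = list(n, mean_avail, mode)`); optional `theta` (vector of
#'   cutoffs, default 0.2), `stage_a_method`, `epsilon`, `seed`.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return Invisibly, a list with `summary` (data frame, one row per
#'   adaptable environment x cutoff), `manifest`, and `runs` (the
#'   `adaptation_run` objects).
#' @export
run_adapt_workflow <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  model <- load_model_any(config$model)
  env_o <- build_env(config$original)
  theta <- as.numeric(config$theta %||% 0.2)
  eps <- as.numeric(config$epsilon %||% flux_tolerance())
  seed <- as.integer(config$seed %||% 1L)
  method <- config$stage_a_method %||% "fba"
  all_sources <- model$carbon_source[!is.na(model$carbon_source)]
  cand_cfg <- config$candidates %||% "all_single_carbon"
  candidates <-
    if (identical(cand_cfg, "all_single_carbon")) {
      lapply(setdiff(all_sources, env_o$sources), flux_environment,
             uptake = config$original$uptake %||% 10)
    } else if (!is.null(cand_cfg$random)) {
      rc <- cand_cfg$random
      random_environments(rc$n, setdiff(all_sources, env_o$sources),
                          mean_avail = rc$mean_avail %||% 0.1,
                          uptake = rc$uptake %||% 10,
                          mode = rc$mode %||% "per_source", seed = seed)
    } else {
      lapply(cand_cfg, build_env)
    }
  names(candidates) <- vapply(candidates, env_label, character(1))
  adaptable <- screen_environments(model, env_o, candidates, threshold = eps)
  rows <- list()
  runs <- list()
  for (eid in names(adaptable)) {
    run <- tryCatch(
      run_adaptation(model, env_o, adaptable[[eid]],
                     stage_a_method = method, tol = eps),
      error = function(e) e)
    if (inherits(run, "error")) {
      warning(sprintf("environment '%s' skipped: %s", eid,
                      conditionMessage(run)))
      next
    }
    runs[[eid]] <- run
    for (th in theta) {
      smry <- summarize_adaptation(classify_traits(run$traits, theta = th,
                                                   eps = eps))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(environment = eid, theta = th, f_p = run$f_p,
                   f_a = run$f_a, asymmetry = run$asymmetry), smry)
    }
  }
  summary <- if (length(rows)) do.call(rbind, rows) else {
    warning("no adaptable candidate environments")
    data.frame()
  }
  manifest <- list(
    package = "plastevo",
    version = as.character(utils::packageVersion("plastevo")),
    model = model$id,
    original = env_o$sources,
    n_candidates = length(candidates),
    n_adaptable = length(adaptable),
    theta = theta, epsilon = eps, seed = seed,
    stage_a_method = method,
    solver = list(lp = "two-phase simplex (Bland)",
                  qp = "Goldfarb-Idnani dual active set"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(summary, file.path(out_dir, "adaptation_summary.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(summary = summary, manifest = manifest, runs = runs))
}

read_triplet_tsv <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) stopf("malformed triplet TSV '%s': %s", path,
                              conditionMessage(e)))
  need <- c("trait_id", "L_o", "L_p", "L_a")
  if (!all(need %in% names(df)))
    stopf("'%s' must have columns %s", path, paste(need, collapse = ", "))
  if (anyDuplicated(df$trait_id))
    stopf("'%s' contains duplicate trait ids (e.g. '%s')", path,
          df$trait_id[duplicated(df$trait_id)][1])
  df
}

#' Classify and summarize many adaptation cases across cutoffs
#'
#' @param cases either a character vector of triplet TSV paths (columns
#'   `trait_id`, `L_o`, `L_p`, `L_a`) or a named list of triplet data
#'   frames.
#' @param theta vector of relative cutoffs (default `c(0.05, 0.2, 0.5)`).
#' @param eps absolute cutoff floor (0 for expression data).
#' @param out_dir optional output directory for `case_summaries.tsv` and
#'   `sign_tests.tsv`.
#' @return A list with `summaries` (one row per case x cutoff) and
#'   `sign_tests` (per cutoff: how many cases show `C_RV > C_RI`, how many
#'   the reverse, ties excluded, with the exact two-tailed binomial
#'   p-value).
#' @export
classify_cases <- function(cases, theta = c(0.05, 0.2, 0.5), eps = 0,
                           out_dir = NULL) {
  if (is.character(cases)) {
    paths <- cases
    cases <- lapply(paths, read_triplet_tsv)
    names(cases) <- sub("\\.tsv$", "", basename(paths))
  }
  if (is.null(names(cases)))
    names(cases) <- paste0("case_", seq_along(cases))
  rows <- list()
  for (cs in names(cases)) for (th in theta) {
    smry <- summarize_adaptation(classify_traits(cases[[cs]], theta = th,
                                                 eps = eps))
    rows[[length(rows) + 1L]] <- cbind(data.frame(case = cs, theta = th),
                                       smry)
  }
  summaries <- do.call(rbind, rows)
  sign_tests <- do.call(rbind, lapply(theta, function(th) {
    d <- summaries[summaries$theta == th, ]
    k_rv <- sum(d$c_rv > d$c_ri)
    k_ri <- sum(d$c_ri > d$c_rv)
    data.frame(theta = th, n_cases = nrow(d), rv_excess = k_rv,
               ri_excess = k_ri, ties = nrow(d) - k_rv - k_ri,
               p_two_tailed = if (k_rv + k_ri > 0)
                 binom_two_tailed(k_rv, k_rv + k_ri) else 1)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(summaries, file.path(out_dir, "case_summaries.tsv"))
    write_tsv(sign_tests, file.path(out_dir, "sign_tests.tsv"))
  }
  list(summaries = summaries, sign_tests = sign_tests)
}

#' Full single-carbon adaptation analysis of a genome-scale model
#'
#' The complete fluxome protocol on a genome-scale reconstruction: load
#' the SBML model, set the original single-carbon environment, screen all
#' other carbon-source environments for adaptability, run every adaptable
#' o -> p -> a shift, classify fluxes at `theta = 0.2`, and collect the
#' headline statistics (mean/median reversion and reinforcement fractions,
#' restoration breakdown, `q`, fitness asymmetry counts, Spearman
#' correlations of mean PC with `f_p` and mean TC with `f_a`, the
#' TC-appreciable reaction count, and the plastic-only fraction).
#'
#' A genome-scale run takes hours with the built-in dense solvers; this
#' entry point exists for completeness and for down-scaled models.
#'
#' @param sbml_path path to the SBML model (e.g. a BiGG reconstruction).
#' @param original_source carbon source of the original environment
#'   (default the BiGG glucose identifier).
#' @param theta classifier cutoff (default 0.2).
#' @param out_dir optional output directory.
#' @return A list with `per_adaptation` (data frame) and `stats` (named
#'   list of the headline numbers).
#' @export
reproduce_single_carbon <- function(sbml_path, original_source = "glc__D",
                                    theta = 0.2, out_dir = NULL) {
  model <- read_sbml_model(sbml_path)
  eps <- flux_tolerance()
  res <- run_adapt_workflow(list(
    model = model,
    original = list(sources = original_source),
    candidates = "all_single_carbon",
    theta = theta, epsilon = eps), out_dir = out_dir)
  d <- res$summary
  cl_runs <- lapply(res$runs, function(r)
    classify_traits(r$traits, theta = theta, eps = eps))
  tc_counts <- vapply(cl_runs, function(cl) nrow(condition_on_tc(cl)),
                      numeric(1))
  stats_list <- list(
    n_carbon_exchanges = sum(!is.na(model$carbon_source)),
    n_traits = length(mutable_reactions(model)),
    n_adaptable = nrow(d),
    mean_c_rv = mean(d$c_rv), median_c_rv = stats::median(d$c_rv),
    mean_c_ri = mean(d$c_ri), median_c_ri = stats::median(d$c_ri),
    mean_restored = mean(d$restored),
    mean_over_restored = mean(d$over_restored),
    mean_under_restored = mean(d$under_restored),
    mean_q = mean(d$q), median_q = stats::median(d$q),
    asymmetry_positive = sum(d$asymmetry > 0),
    asymmetry_p = binom_one_tailed(sum(d$asymmetry > 0), nrow(d)),
    rho_fp_meanpc = stats::cor(d$f_p, d$mean_pc, method = "spearman"),
    rho_fa_meantc = stats::cor(d$f_a, d$mean_tc, method = "spearman"),
    mean_tc_appreciable = mean(tc_counts),
    mean_plastic_only = mean(d$plastic_only))
  if (!is.null(out_dir))
    jsonlite::write_json(stats_list,
                         file.path(out_dir, "headline_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(per_adaptation = d, stats = stats_list)
}
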