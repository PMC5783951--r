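#' Construct a constraint-based metabolic model
#'
#' A light container for a stoichiometric model: the stoichiometric matrix
#' `S` (metabolites x reactions), flux bounds, the biomass objective, and the
#' per-reaction annotations needed for environment handling and trait
#' selection (exchange status, transported carbon source, diffusion status,
#' gene association).
#'
#' @param id model identifier.
#' @param S stoichiometric matrix, metabolites in rows, reactions in columns.
#'   Dimnames, when present, must agree with `met_id` / `rxn_id`.
#' @param rxn_id,met_id character vectors of reaction and metabolite
#'   identifiers; defaults taken from `dimnames(S)`.
#' @param lb,ub numeric lower/upper flux bounds per reaction
#'   (mmol gDW^-1 h^-1).
#' @param obj numeric biomass-contribution vector; exactly one reaction must
#'   carry a non-zero coefficient.
#' @param is_exchange logical flags marking boundary exchange reactions.
#' @param carbon_source character vector naming, for each carbon-transporting
#'   exchange reaction, the carbon source it imports; `NA` elsewhere.
#' @param is_diffusion logical flags for enzyme-free diffusion reactions
#'   (excluded from the trait list, see [mutable_reactions()]).
#' @param has_gene logical flags for the presence of a gene association.
#'
#' @return An object of class `metabolic_model`.
#' @seealso [read_sbml_model()], [gen_toy_model()], [fba()], [moma()]
#' @export
metabolic_model <- function(id, S, rxn_id = colnames(S), met_id = rownames(S),
                            lb, ub, obj,
                            is_exchange = NULL, carbon_source = NULL,
                            is_diffusion = NULL, has_gene = NULL) {
  S <- as.matrix(S)
  n <- ncol(S)
  m <- nrow(S)
  if (is.null(rxn_id)) rxn_id <- paste0("R", seq_len(n))
  if (is.null(met_id)) met_id <- paste0("M", seq_len(m))
  dimnames(S) <- list(met_id, rxn_id)
  model <- structure(list(
    id = as.character(id),
    rxn_id = as.character(rxn_id),
    met_id = as.character(met_id),
    S = S,
    lb = as.numeric(lb),
    ub = as.numeric(ub),
    obj = as.numeric(obj),
    is_exchange = as.logical(is_exchange %||% rep(FALSE, n)),
    carbon_source = as.character(carbon_source %||% rep(NA_character_, n)),
    is_diffusion = as.logical(is_diffusion %||% rep(FALSE, n)),
    has_gene = as.logical(has_gene %||% rep(TRUE, n))
  ), class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model's structural invariants
#'
#' Checks dimension consistency, elementwise `lb <= ub`, the presence of
#' exactly one biomass objective reaction, and that every annotated carbon
#' source maps to exactly one exchange reaction.
#'
#' @param model a [metabolic_model()].
#' @return `model`, invisibly; errors describe the violated invariant.
#' @export
validate_model <- function(model) {
  n <- length(model$rxn_id)
  m <- length(model$met_id)
  if (!all(dim(model$S) == c(m, n)))
    stopf("stoichiometric matrix is %d x %d but model has %d metabolites and %d reactions",
          nrow(model$S), ncol(model$S), m, n)
  for (f in c("lb", "ub", "obj", "is_exchange", "carbon_source",
              "is_diffusion", "has_gene"))
    if (length(model[[f]]) != n)
      stopf("field '%s' has length %d, expected %d", f, length(model[[f]]), n)
  bad <- which(model$lb > model$ub)
  if (length(bad))
    stopf("lower bound exceeds upper bound for reaction(s): %s",
          paste(model$rxn_id[bad], collapse = ", "))
  if (sum(model$obj != 0) != 1L)
    stopf("model must have exactly one biomass objective reaction (found %d)",
          sum(model$obj != 0))
  cs <- model$carbon_source[!is.na(model$carbon_source)]
  if (anyDuplicated(cs))
    stopf("carbon source(s) mapped to more than one exchange reaction: %s",
          paste(unique(cs[duplicated(cs)]), collapse = ", "))
  if (any(!is.na(model$carbon_source) & !model$is_exchange))
    stopf("carbon_source annotation on a non-exchange reaction")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d reactions, %d metabolites\n",
              x$id, length(x$rxn_id), length(x$met_id)))
  cat(sprintf("  exchanges: %d (%d carbon-transporting), biomass: %s\n",
              sum(x$is_exchange), sum(!is.na(x$carbon_source)),
              x$rxn_id[x$obj != 0]))
  invisible(x)
}

#' Reaction identifier of the biomass objective
#' @param model a [metabolic_model()].
#' @return length-1 character.
#' @export
biomass_reaction <- function(model) model$rxn_id[model$obj != 0]

#' List the mutable (trait) reactions of a model
#'
#' Enzyme-free diffusion reactions have no gene whose mutation could alter
#' them, so they are excluded from the set of phenotypic traits; all other
#' reactions define the flux traits used by the classifier.
#'
#' @param model a [metabolic_model()].
#' @return character vector of reaction identifiers, in model order. A model
#'   in which every reaction is flagged as diffusion yields an empty vector
#'   with a warning.
#' @export
mutable_reactions <- function(model) {
  keep <- model$rxn_id[!model$is_diffusion]
  if (!length(keep))
    warning("all reactions are flagged as diffusion; trait list is empty")
  keep
}

#' Randomly permute the reaction order of a model
#'
#' The optimum of a degenerate FBA problem can depend on the order in which
#' the solver sees the reactions. Shuffling the columns of `S` (carrying all
#' bounds and annotations along) produces a semantically identical model and
#' exposes that degeneracy; the unique MOMA optimum must be invariant to it.
#'
#' @param model a [metabolic_model()].
#' @param seed integer seed controlling the permutation.
#' @return a `metabolic_model` with permuted reaction order.
#' @export
shuffle_reaction_order <- function(model, seed) {
  n <- length(model$rxn_id)
  perm <- withr_seed(seed, sample.int(n))
  metabolic_model(
    id = model$id,
    S = model$S[, perm, drop = FALSE],
    rxn_id = model$rxn_id[perm], met_id = model$met_id,
    lb = model$lb[perm], ub = model$ub[perm], obj = model$obj[perm],
    is_exchange = model$is_exchange[perm],
    carbon_source = model$carbon_source[perm],
    is_diffusion = model$is_diffusion[perm],
    has_gene = model$has_gene[perm]
  )
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
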