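# SBML and JSON model I/O. Reading supports the two dialects genome-scale
# reconstructions ship in: Level 3 with the FBC extension (bounds as global
# parameters, objective and gene associations in fbc elements) and legacy
# Level 2 (bounds as LOWER_BOUND/UPPER_BOUND kinetic-law parameters, gene
# associations and formulas in notes). Writing emits Level 3 + FBC v2 and is
# used for toy fixtures.

# Attribute access that tolerates namespace prefixes (after xml_ns_strip()
# attribute names may or may not keep their "fbc:" prefix).
attr_any <- function(node, name) {
  a <- xml2::xml_attrs(node)
  hit <- which(names(a) == name | endsWith(names(a), paste0(":", name)))
  if (length(hit)) unname(a[hit[1]]) else NA_character_
}

strip_met_id <- function(x) {
  x <- sub("^M_", "", x)
  sub("_[a-zA-Z]{1,2}$", "", x)
}

# Does an elemental formula contain carbon? "C" must not be followed by a
# lowercase letter (which would make it Cl, Ca, Cu, ...).
formula_has_carbon <- function(formula) {
  !is.na(formula) & grepl("C(?![a-z])", formula, perl = TRUE)
}

#' Read a constraint-based model from SBML
#'
#' Populates a [metabolic_model()] from an SBML file (Level 3 FBC or Level
#' 2 with COBRA-style notes). Boundary-condition species are dropped;
#' exchange reactions are auto-detected as reactions touching a single
#' remaining metabolite; an exchange is annotated as carbon-transporting
#' when its metabolite's elemental formula contains carbon and is not on
#' the blocklist of non-nutritive inorganics. Enzyme-free diffusion
#' reactions are flagged by `diffusion_rule` and excluded from the trait
#' list by [mutable_reactions()].
#'
#' @param path SBML file path.
#' @param carbon_blocklist formulas never counted as carbon sources
#'   (defaults cover CO2, bicarbonate, carbonate).
#' @param diffusion_rule predicate receiving a data frame with columns
#'   `rxn_id`, `has_gene`, `is_exchange`, `n_mets`, `is_transport`
#'   (two-metabolite 1:1 movement of one compound between compartments)
#'   and returning the logical diffusion flags. The default flags
#'   gene-less 1:1 transport plus all exchanges. The operational rule
#'   behind published trait counts is not uniquely determined, hence the
#'   predicate is configurable.
#' @param default_bound bound magnitude used when a reaction carries no
#'   explicit bounds (1000, the COBRA convention).
#' @return A [metabolic_model()].
#' @export
read_sbml_model <- function(path,
                            carbon_blocklist = c("CO2", "CHO3", "CO3",
                                                 "H2CO3"),
                            diffusion_rule = NULL,
                            default_bound = 1000) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stopf("malformed SBML in '%s': %s", path, conditionMessage(e)))
  xml2::xml_ns_strip(doc)

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp_nodes)) stopf("malformed SBML: no species elements")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  if (anyNA(sp_id)) stopf("malformed SBML: species #%d lacks an id",
                          which(is.na(sp_id))[1])
  sp_boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  sp_formula <- vapply(sp_nodes, attr_any, character(1),
                       name = "chemicalFormula")
  # Level 2 fallback: FORMULA in the notes block
  no_f <- which(is.na(sp_formula))
  if (length(no_f)) {
    notes <- vapply(sp_nodes[no_f], function(nd)
      paste(xml2::xml_text(xml2::xml_find_all(nd, ".//text()")),
            collapse = " "), character(1))
    got <- grepl("FORMULA:", notes)
    sp_formula[no_f[got]] <- sub("FORMULA:\\s*", "",
                                 regmatches(notes, regexpr("FORMULA:\\s*\\S+",
                                                           notes)))
  }
  names(sp_formula) <- sp_id
  boundary <- stats::setNames(sp_boundary, sp_id)

  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rx_nodes)) stopf("malformed SBML: no reaction elements")
  n <- length(rx_nodes)
  rxn_id <- xml2::xml_attr(rx_nodes, "id")
  if (anyNA(rxn_id)) stopf("malformed SBML: reaction #%d lacks an id",
                           which(is.na(rxn_id))[1])

  stoich <- vector("list", n)
  lb <- ub <- numeric(n)
  has_gene <- logical(n)
  for (i in seq_len(n)) {
    r <- rx_nodes[[i]]
    take <- function(xpath, sign) {
      refs <- xml2::xml_find_all(r, xpath)
      if (!length(refs)) return(numeric(0))
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(sign * st, xml2::xml_attr(refs, "species"))
    }
    sto <- c(take("./listOfReactants/speciesReference", -1),
             take("./listOfProducts/speciesReference", +1))
    unknown <- setdiff(names(sto), sp_id)
    if (length(unknown))
      stopf("malformed SBML: reaction '%s' references unknown species '%s'",
            rxn_id[i], unknown[1])
    stoich[[i]] <- sto
    reversible <- !(xml2::xml_attr(r, "reversible") %in% "false")
    lref <- attr_any(r, "lowerFluxBound")
    uref <- attr_any(r, "upperFluxBound")
    if (!is.na(lref) || !is.na(uref)) {
      lb[i] <- if (is.na(lref)) -default_bound else par_val[[lref]]
      ub[i] <- if (is.na(uref)) default_bound else par_val[[uref]]
    } else {
      kl <- xml2::xml_find_all(r, ".//kineticLaw//parameter")
      kid <- xml2::xml_attr(kl, "id")
      kval <- as.numeric(xml2::xml_attr(kl, "value"))
      lb[i] <- if ("LOWER_BOUND" %in% kid) kval[match("LOWER_BOUND", kid)]
               else if (reversible) -default_bound else 0
      ub[i] <- if ("UPPER_BOUND" %in% kid) kval[match("UPPER_BOUND", kid)]
               else default_bound
    }
    gpa <- xml2::xml_find_first(r, ".//geneProductAssociation")
    if (!inherits(gpa, "xml_missing")) {
      has_gene[i] <- TRUE
    } else {
      notes <- paste(xml2::xml_text(
        xml2::xml_find_all(r, "./notes//text()")), collapse = " ")
      has_gene[i] <- grepl("GENE[_ ]ASSOCIATION:\\s*\\S", notes)
    }
  }

  # objective: fbc flux objectives, else a biomass-named reaction
  fo <- xml2::xml_find_all(doc, ".//fluxObjective")
  obj_rxn <- if (length(fo)) attr_any(fo[[1]], "reaction")
             else {
               hit <- grep("biomass", rxn_id, ignore.case = TRUE, value = TRUE)
               if (length(hit)) hit[1] else NA_character_
             }
  if (is.na(obj_rxn) || !obj_rxn %in% rxn_id)
    stopf("model in '%s' has no biomass objective", path)

  met_id <- sort(unique(unlist(lapply(stoich, names))))
  met_id <- met_id[!boundary[met_id]]
  S <- matrix(0, length(met_id), n, dimnames = list(met_id, rxn_id))
  for (i in seq_len(n)) {
    sto <- stoich[[i]]
    sto <- sto[names(sto) %in% met_id]
    S[names(sto), i] <- sto
  }

  n_mets <- colSums(S != 0)
  is_exchange <- n_mets == 1L
  carbon_source <- rep(NA_character_, n)
  for (i in which(is_exchange)) {
    met <- met_id[S[, i] != 0]
    f <- sp_formula[[met]]
    if (formula_has_carbon(f) && !(f %in% carbon_blocklist))
      carbon_source[i] <- strip_met_id(met)
  }
  dup <- duplicated(carbon_source) & !is.na(carbon_source)
  if (any(dup)) {
    warning(sprintf("carbon source(s) with multiple exchanges, keeping the first: %s",
                    paste(unique(carbon_source[dup]), collapse = ", ")))
    carbon_source[dup] <- NA_character_
  }

  is_transport <- vapply(seq_len(n), function(i) {
    mets <- met_id[S[, i] != 0]
    length(mets) == 2L &&
      length(unique(strip_met_id(mets))) == 1L &&
      all(sort(S[mets, i]) == c(-1, 1))
  }, logical(1))
  info <- data.frame(rxn_id = rxn_id, has_gene = has_gene,
                     is_exchange = is_exchange, n_mets = as.integer(n_mets),
                     is_transport = is_transport)
  is_diffusion <- if (is.null(diffusion_rule))
    (!has_gene & is_transport) | is_exchange
  else as.logical(diffusion_rule(info))

  metabolic_model(
    id = sub("\\.(xml|sbml)$", "", basename(path)),
    S = S, rxn_id = rxn_id, met_id = met_id, lb = lb, ub = ub,
    obj = as.numeric(rxn_id == obj_rxn),
    is_exchange = is_exchange, carbon_source = carbon_source,
    is_diffusion = is_diffusion, has_gene = has_gene)
}

#' Write a model as SBML Level 3 with the FBC extension
#'
#' Counterpart of [read_sbml_model()], mainly used to materialize toy
#' fixtures. Carbon-transporting exchanges are given a carbon-containing
#' chemical formula on their metabolite (and all other metabolites a
#' carbon-free one) so that carbon-source annotation survives a
#' round-trip; gene associations are emitted for reactions flagged
#' `has_gene`.
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @param met_formula optional named character vector of metabolite
#'   formulas overriding the automatic assignment.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(model, path, met_formula = NULL) {
  if (is.null(met_formula)) {
    met_formula <- stats::setNames(rep("H2O", length(model$met_id)),
                                   model$met_id)
    for (i in which(!is.na(model$carbon_source))) {
      met <- model$met_id[model$S[, i] != 0]
      met_formula[met] <- "C6H12O6"
    }
  }
  esc <- function(x) gsub("&", "&amp;", x)
  bounds <- sort(unique(c(model$lb, model$ub)))
  bref <- function(v) sprintf("bnd_%d", match(v, bounds))
  species <- vapply(seq_along(model$met_id), function(j) {
    sprintf('      <species id="%s" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false" fbc:chemicalFormula="%s"/>',
            esc(model$met_id[j]), met_formula[[model$met_id[j]]])
  }, character(1))
  params <- vapply(seq_along(bounds), function(j) {
    sprintf('      <parameter id="bnd_%d" value="%s" constant="true"/>',
            j, format(bounds[j], digits = 15))
  }, character(1))
  reactions <- vapply(seq_along(model$rxn_id), function(i) {
    sto <- model$S[, i]
    side <- function(sel, tag) {
      idx <- which(sel)
      if (!length(idx)) return("")
      refs <- vapply(idx, function(j) sprintf(
        '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
        esc(model$met_id[j]), format(abs(sto[j]), digits = 15)), character(1))
      sprintf("        <listOf%s>\n%s\n        </listOf%s>",
              tag, paste(refs, collapse = "\n"), tag)
    }
    gpa <- if (model$has_gene[i]) sprintf(
      '        <fbc:geneProductAssociation>\n          <fbc:geneProductRef fbc:geneProduct="G_%s"/>\n        </fbc:geneProductAssociation>',
      esc(model$rxn_id[i])) else ""
    body <- paste(Filter(nzchar, c(side(sto < 0, "Reactants"),
                                   side(sto > 0, "Products"), gpa)),
                  collapse = "\n")
    sprintf('      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">\n%s\n      </reaction>',
            esc(model$rxn_id[i]),
            if (model$lb[i] < 0) "true" else "false",
            bref(model$lb[i]), bref(model$ub[i]), body)
  }, character(1))
  gps <- vapply(which(model$has_gene), function(i) sprintf(
    '      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
    esc(model$rxn_id[i]), esc(model$rxn_id[i])), character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">\n',
    sprintf('  <model id="%s" fbc:strict="true">\n', esc(model$id)),
    "    <listOfCompartments>\n",
    '      <compartment id="c" constant="true"/>\n',
    "    </listOfCompartments>\n",
    "    <listOfSpecies>\n", paste(species, collapse = "\n"), "\n",
    "    </listOfSpecies>\n",
    "    <listOfParameters>\n", paste(params, collapse = "\n"), "\n",
    "    </listOfParameters>\n",
    "    <listOfReactions>\n", paste(reactions, collapse = "\n"), "\n",
    "    </listOfReactions>\n",
    '    <fbc:listOfObjectives fbc:activeObjective="obj">\n',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">\n',
    "        <fbc:listOfFluxObjectives>\n",
    sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>\n',
            esc(biomass_reaction(model))),
    "        </fbc:listOfFluxObjectives>\n",
    "      </fbc:objective>\n",
    "    </fbc:listOfObjectives>\n",
    if (length(gps)) paste0("    <fbc:listOfGeneProducts>\n",
                            paste(gps, collapse = "\n"), "\n",
                            "    </fbc:listOfGeneProducts>\n") else "",
    "  </model>\n</sbml>\n")
  writeLines(xml, path)
  invisible(path)
}

#' Model I/O in an explicit JSON dialect
#'
#' A plain serialization of every [metabolic_model()] field (stoichiometric
#' matrix included), convenient for fixtures and round-tripping without an
#' SBML toolchain.
#'
#' @param model a [metabolic_model()].
#' @param path file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns the model.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(
    id = model$id, rxn_id = model$rxn_id, met_id = model$met_id,
    S = as.vector(model$S),      # column-major, metabolites x reactions
    lb = model$lb, ub = model$ub, obj = model$obj,
    is_exchange = model$is_exchange, carbon_source = model$carbon_source,
    is_diffusion = model$is_diffusion, has_gene = model$has_gene),
    path, auto_unbox = TRUE, digits = NA, na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  S <- matrix(as.numeric(unlist(j$S)), nrow = length(j$met_id),
              dimnames = list(j$met_id, j$rxn_id))
  metabolic_model(id = j$id, S = S, rxn_id = j$rxn_id, met_id = j$met_id,
                  lb = j$lb, ub = j$ub, obj = j$obj,
                  is_exchange = j$is_exchange,
                  carbon_source = as.character(j$carbon_source),
                  is_diffusion = j$is_diffusion, has_gene = j$has_gene)
}
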