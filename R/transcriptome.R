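#' Bundle an expression matrix with its sample annotations
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Values are whatever the
#'   source study provides (FPKM, normalized counts, ...); the classifier's
#'   relative cutoff makes categories invariant to a per-dataset rescaling.
#' @param samples data frame with one row per column of `values`: `sample`
#'   (matching the column names), `stage` (`"o"`, `"p"`, `"a"` or `NA`),
#'   and optionally `line` and `case`.
#' @param id dataset identifier.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, samples, id = "dataset") {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    stopf("'values' must have sample ids as column names")
  samples <- as.data.frame(samples)
  if (!"sample" %in% names(samples))
    stopf("'samples' needs a 'sample' column")
  if (!identical(as.character(samples$sample), colnames(values)))
    stopf("samples$sample must match colnames(values) in order")
  if ("stage" %in% names(samples)) {
    bad <- !is.na(samples$stage) & !samples$stage %in% c("o", "p", "a")
    if (any(bad)) stopf("stage labels must be 'o', 'p' or 'a'")
  }
  structure(list(id = id, values = values, samples = samples),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s: %d genes x %d samples\n",
              x$id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Drop genes with missing expression values
#'
#' `NA` always counts as missing; additional numeric sentinels (and,
#' optionally, any negative value) can be declared missing to normalize the
#' conventions of different source studies.
#'
#' @param ds an [expression_dataset()].
#' @param sentinels numeric values to treat as missing (e.g. `-999`).
#' @param negative_missing treat all negative values as missing.
#' @return The filtered dataset; the number of dropped genes is reported
#'   via `message()`. All genes missing is an error.
#' @export
filter_missing <- function(ds, sentinels = numeric(0),
                           negative_missing = FALSE) {
  v <- ds$values
  miss <- is.na(v)
  if (length(sentinels)) miss <- miss | (v %in% sentinels)
  if (negative_missing) miss <- miss | (!is.na(v) & v < 0)
  keep <- rowSums(miss) == 0L
  if (!any(keep)) stopf("no genes left after removing missing values")
  message(sprintf("filter_missing: dropped %d of %d genes",
                  sum(!keep), length(keep)))
  ds$values <- v[keep, , drop = FALSE]
  ds
}

#' Rescale datasets to a common grand mean
#'
#' Each dataset is multiplied by one scalar so that the mean expression
#' level over all of its genes and samples equals `target`. Within-dataset
#' ratios -- and therefore every classifier category, whose cutoff is
#' relative to `L_o` -- are unchanged.
#'
#' @param datasets a list of [expression_dataset()]s (a single dataset is
#'   accepted and returned unwrapped).
#' @param target the common grand mean (default 1).
#' @return The rescaled dataset(s).
#' @export
normalize_mean <- function(datasets, target = 1) {
  single <- inherits(datasets, "expression_dataset")
  if (single) datasets <- list(datasets)
  out <- lapply(datasets, function(ds) {
    mu <- mean(ds$values)
    if (!is.finite(mu) || abs(mu) < .Machine$double.eps)
      stopf("dataset '%s' has zero mean expression; cannot normalize", ds$id)
    ds$values <- ds$values * (target / mu)
    ds
  })
  if (single) out[[1]] else out
}

#' Average expression across replicate samples
#'
#' @param ds an [expression_dataset()].
#' @param grouping either the name of a column in `ds$samples` (e.g.
#'   `"line"`) or a vector with one group label per sample. Samples sharing
#'   a label are averaged gene-wise (arithmetic mean on the provided
#'   expression scale).
#' @return An `expression_dataset` with one column per group; `stage` (and
#'   `line`, `case`) are carried over when unambiguous within a group.
#' @export
average_replicates <- function(ds, grouping) {
  if (length(grouping) == 1L && is.character(grouping) &&
      grouping %in% names(ds$samples)) {
    grouping <- ds$samples[[grouping]]
  }
  if (length(grouping) != ncol(ds$values))
    stopf("grouping must have one entry per sample")
  if (anyNA(grouping)) stopf("grouping labels must not be missing")
  grouping <- as.character(grouping)
  groups <- unique(grouping)
  vals <- vapply(groups,
                 function(g) rowMeans(ds$values[, grouping == g, drop = FALSE]),
                 numeric(nrow(ds$values)))
  sizes <- vapply(groups, function(g) sum(grouping == g), integer(1))
  message(sprintf("average_replicates: %d groups (sizes %s)",
                  length(groups), paste(sizes, collapse = ", ")))
  carry <- function(field) {
    vapply(groups, function(g) {
      u <- unique(ds$samples[[field]][grouping == g])
      if (length(u) == 1L) as.character(u) else NA_character_
    }, character(1))
  }
  samples <- data.frame(sample = groups)
  for (f in intersect(c("stage", "line", "case"), names(ds$samples)))
    samples[[f]] <- carry(f)
  expression_dataset(vals, samples, id = ds$id)
}

#' Build per-case o/p/a trait triplets from a dataset and a manifest
#'
#' A case manifest maps every adaptation case to the sample ids providing
#' its three stages; several cases may share stage-o or stage-p samples
#' (e.g. one ancestor, many evolved lines). Samples listed for a stage are
#' averaged gene-wise.
#'
#' @param ds an [expression_dataset()].
#' @param manifest a named list of cases, each a list with character
#'   elements `o`, `p` and `a` (sample ids), as returned by
#'   [read_case_manifest()].
#' @return A named list of data frames (`trait_id`, `L_o`, `L_p`, `L_a`),
#'   one per case, ready for [classify_traits()].
#' @export
build_triplets <- function(ds, manifest) {
  if (!length(manifest)) stopf("manifest contains no cases")
  if (is.null(names(manifest)))
    names(manifest) <- paste0("case_", seq_along(manifest))
  stage_mean <- function(case, stage, ids) {
    ids <- as.character(unlist(ids))
    if (is.null(ids) || !length(ids))
      stopf("case '%s' is missing stage '%s'", case, stage)
    absent <- setdiff(ids, colnames(ds$values))
    if (length(absent))
      stopf("case '%s', stage '%s': sample(s) not in dataset: %s",
            case, stage, paste(absent, collapse = ", "))
    rowMeans(ds$values[, ids, drop = FALSE])
  }
  out <- lapply(names(manifest), function(cs) {
    spec <- manifest[[cs]]
    data.frame(trait_id = rownames(ds$values),
               L_o = stage_mean(cs, "o", spec$o),
               L_p = stage_mean(cs, "p", spec$p),
               L_a = stage_mean(cs, "a", spec$a),
               row.names = NULL)
  })
  names(out) <- names(manifest)
  out
}

#' Read a YAML case manifest
#'
#' Expected layout: a top-level `cases` mapping (or the mapping directly),
#' each case naming its `o`, `p` and `a` sample ids.
#'
#' @param path YAML file path.
#' @return A named list of cases usable by [build_triplets()].
#' @export
read_case_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cases)) y <- y$cases
  if (!length(y) || is.null(names(y)))
    stopf("manifest '%s' has no named cases", path)
  y
}

#' Flag genes whose expression is independent of growth rate
#'
#' Given expression measured at several ordered growth rates, a gene is
#' growth-rate-dependent when its values are monotone across the rates and
#' growth-rate-independent otherwise. Under the default (non-strict)
#' convention ties are allowed within a monotone profile; with
#' `strict = TRUE` only strictly monotone profiles count as dependent.
#'
#' @param mat numeric matrix, genes x rates, columns ordered by increasing
#'   growth rate (at least 3 columns).
#' @param rates optional numeric vector of the growth rates themselves;
#'   supplying an unsorted vector is an error, guarding against shuffled
#'   column order.
#' @param strict logical; see above.
#' @return A logical vector, `TRUE` for growth-rate-independent genes.
#' @export
growth_independent_mask <- function(mat, rates = NULL, strict = FALSE) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 3L)
    stopf("need expression at >= 3 ordered growth rates (got %d)", ncol(mat))
  if (!is.null(rates)) {
    if (length(rates) != ncol(mat)) stopf("one rate per column required")
    if (is.unsorted(rates, strictly = TRUE))
      stopf("growth rates must be provided in strictly increasing order")
  }
  d <- mat[, -1, drop = FALSE] - mat[, -ncol(mat), drop = FALSE]
  dependent <- if (strict) {
    rowSums(d <= 0) == 0L | rowSums(d >= 0) == 0L
  } else {
    rowSums(d < 0) == 0L | rowSums(d > 0) == 0L
  }
  stats::setNames(!dependent, rownames(mat))
}

#' Read a delimited expression matrix
#'
#' Genes in rows, a header row of sample ids, first column holding gene
#' identifiers.
#'
#' @param path TSV/CSV file path.
#' @param sep field separator (default tab).
#' @return A numeric matrix with gene ids as rownames.
#' @export
read_expression_matrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}
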