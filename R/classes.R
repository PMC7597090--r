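# S3 containers shared across the package. Matrices carry entity ids as
# rownames and condition labels as colnames; column order encodes time order.

#' Construct an abundance matrix
#'
#' An abundance matrix is a numeric matrix of nonnegative abundances with
#' unique, nonempty entity identifiers as rownames and ordered condition
#' labels as colnames (column order encodes experimental time order).
#'
#' @param values Numeric matrix, entities in rows, conditions in columns.
#'   Must have complete dimnames.
#' @return The validated matrix with class `"abundance_matrix"` prepended.
#' @examples
#' x <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("t0", "t1", "t2")))
#' abundance_matrix(x)
#' @export
abundance_matrix <- function(values) {
  values <- validate_entity_matrix(values, allow_negative = FALSE)
  class(values) <- c("abundance_matrix", class(unclass(values)))
  values
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d entities x %d conditions\n",
              nrow(x), ncol(x)))
  print(utils::head(unclass(x), 4L))
  if (nrow(x) > 4L) cat(sprintf("... (%d more entities)\n", nrow(x) - 4L))
  invisible(x)
}

# shared matrix validation for abundance and log matrices
validate_entity_matrix <- function(values, allow_negative) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  ids <- rownames(values)
  conds <- colnames(values)
  if (is.null(ids) || is.null(conds))
    stop("matrix must carry entity ids (rownames) and condition labels (colnames)")
  if (anyNA(values) || any(!is.finite(values)))
    stop("matrix entries must be finite and non-missing")
  if (any(!nzchar(ids)))
    stop("entity ids must be nonempty strings")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate entity ID: %s", ids[duplicated(ids)][1L]))
  if (!allow_negative && any(values < 0))
    stop("abundance values must be nonnegative")
  values
}

new_log_matrix <- function(values) {
  values <- validate_entity_matrix(values, allow_negative = TRUE)
  class(values) <- c("log_matrix", class(unclass(values)))
  values
}

#' @export
print.log_matrix <- function(x, ...) {
  cat(sprintf("log_matrix: %d entities x %d conditions\n", nrow(x), ncol(x)))
  print(utils::head(unclass(x), 4L))
  invisible(x)
}

#' Construct an annotation catalog
#'
#' A catalog maps identifiers of functionally annotated sets (FAS) to their
#' member entity ids. Sets may overlap and an entity may belong to many sets;
#' FAS ids must be unique. Hierarchical ontology paths (e.g. dot-separated
#' MapMan name paths) are kept as plain strings.
#'
#' @param sets Named list of character vectors (FAS id -> member entity ids).
#' @param descriptions Optional named character vector of free-text
#'   descriptions, names matching FAS ids.
#' @return Object of class `"annotation_catalog"`.
#' @examples
#' annotation_catalog(list(S1 = c("A", "B"), S2 = c("B", "C")))
#' @export
annotation_catalog <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a named list of member vectors")
  if (anyDuplicated(names(sets)))
    stop(sprintf("duplicate FAS id: %s", names(sets)[duplicated(names(sets))][1L]))
  sets <- lapply(sets, function(m) {
    m <- as.character(m)
    if (any(!nzchar(m)) || anyNA(m))
      stop("set members must be nonempty strings")
    unique(m)
  })
  if (!is.null(descriptions)) {
    nm <- names(descriptions)
    descriptions <- as.character(descriptions)
    names(descriptions) <- nm
    if (is.null(names(descriptions)) ||
        !all(names(descriptions) %in% names(sets)))
      stop("descriptions must be named by FAS ids present in sets")
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("annotation_catalog: %d sets, member counts %d-%d (median %g)\n",
              length(x$sets), if (length(sz)) min(sz) else 0L,
              if (length(sz)) max(sz) else 0L,
              if (length(sz)) stats::median(sz) else 0))
  invisible(x)
}

#' @export
length.annotation_catalog <- function(x) length(x$sets)

#' Construct a replicate design
#'
#' Maps sample column labels to condition labels so biological replicates can
#' be aggregated into one column per condition.
#'
#' @param sample_to_condition Named character vector: names are sample column
#'   labels, values are condition labels.
#' @return Object of class `"replicate_design"`.
#' @examples
#' replicate_design(c(s1 = "t0", s2 = "t0", s3 = "t1"))
#' @export
replicate_design <- function(sample_to_condition) {
  x <- as.character(sample_to_condition)
  names(x) <- names(sample_to_condition)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("sample labels (names) are required")
  if (anyDuplicated(names(x)))
    stop(sprintf("sample %s mapped more than once",
                 names(x)[duplicated(names(x))][1L]))
  if (any(!nzchar(x)) || anyNA(x))
    stop("every sample must map to exactly one nonempty condition")
  structure(x, class = "replicate_design")
}

new_surprisal_decomposition <- function(weights, potentials, singular_values,
                                        entity_ids, condition_labels) {
  structure(list(weights = weights, potentials = potentials,
                 singular_values = singular_values, entity_ids = entity_ids,
                 condition_labels = condition_labels),
            class = "surprisal_decomposition")
}

#' @export
print.surprisal_decomposition <- function(x, ...) {
  r <- length(x$singular_values) - 1L
  cat(sprintf(paste0("surprisal_decomposition: %d entities, %d conditions, ",
                     "baseline + %d constraints\n"),
              length(x$entity_ids), length(x$condition_labels), r))
  cat("singular values:", format(x$singular_values, digits = 4), "\n")
  invisible(x)
}

#' Number of constraints (excluding the baseline) in a decomposition
#' @param decomp A `surprisal_decomposition`.
#' @return Integer r: constraint indices run 1..r; index 0 is the baseline.
#' @export
n_constraints <- function(decomp) {
  stopifnot(inherits(decomp, "surprisal_decomposition"))
  length(decomp$singular_values) - 1L
}

#' Per-entity weights of one constraint
#'
#' @param decomp A `surprisal_decomposition`.
#' @param constraint Constraint index alpha (0 = baseline).
#' @return Named numeric vector of weights `G_i alpha`.
#' @export
constraint_weights <- function(decomp, constraint) {
  stopifnot(inherits(decomp, "surprisal_decomposition"))
  r <- n_constraints(decomp)
  if (length(constraint) != 1L || constraint < 0 || constraint > r)
    stop(sprintf("constraint index %s out of range 0..%d",
                 as.character(constraint), r))
  w <- decomp$weights[, constraint + 1L]
  names(w) <- decomp$entity_ids
  w
}
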