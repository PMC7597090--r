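# Readers/writers for the plain-text formats the package consumes and emits:
# abundance TSV, MapMan mapping files, GMT gene sets, enrichment tables.

#' Read an entity-by-condition abundance matrix
#'
#' Expects a delimited text file whose first row is a header of
#' condition/sample labels and whose first column holds entity identifiers.
#' Rows are returned in file order.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter, default tab.
#' @return An [abundance_matrix()].
#' @export
read_abundance_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  # A header naming only the condition columns (one field fewer than the data
  # rows) is accepted; the id column is then unnamed.
  first_two <- readLines(path, n = 2L)
  header_fields <- length(strsplit(first_two[1L], delimiter, fixed = TRUE)[[1L]])
  data_fields <- if (length(first_two) > 1L)
    length(strsplit(first_two[2L], delimiter, fixed = TRUE)[[1L]]) else
      header_fields
  bare_header <- header_fields == data_fields - 1L
  df <- tryCatch(
    utils::read.delim(path, sep = delimiter, header = !bare_header,
                      skip = if (bare_header) 1L else 0L,
                      check.names = FALSE, colClasses = "character",
                      na.strings = character(0), quote = "", fill = FALSE),
    error = function(e) stop(sprintf("cannot parse %s (ragged rows?): %s",
                                     path, conditionMessage(e))))
  if (bare_header)
    colnames(df) <- c("entity_id",
                      strsplit(first_two[1L], delimiter, fixed = TRUE)[[1L]])
  if (ncol(df) < 2L) stop("need at least one entity id column and one condition column")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate entity ID: %s", ids[duplicated(ids)][1L]))
  conds <- colnames(df)[-1L]
  vals <- matrix(NA_real_, nrow(df), length(conds),
                 dimnames = list(ids, conds))
  for (j in seq_along(conds)) {
    cell <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at row %d (entity %s), column %s",
                   cell[bad[1L]], bad[1L], ids[bad[1L]], conds[j]))
    vals[, j] <- num
  }
  abundance_matrix(vals)
}

#' Write an abundance matrix as TSV
#'
#' @param x An [abundance_matrix()] (or any entity matrix with dimnames).
#' @param path Output path; first column is named `entity_id`.
#' @export
write_abundance_matrix <- function(x, path) {
  df <- data.frame(entity_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MapMan ontology mapping file
#'
#' MapMan mapping files are tab-separated with columns BINCODE, NAME,
#' IDENTIFIER, DESCRIPTION and TYPE; fields may be wrapped in single quotes.
#' One FAS is created per distinct NAME path. Identifiers are uppercased and
#' stripped of quotes/whitespace (MapMan ships lowercase AGI codes while
#' expression matrices are typically uppercase). Rows with an empty
#' IDENTIFIER contribute the FAS id but no member.
#'
#' By default an identifier annotated to a child bin (e.g. `a.b.c`) is a
#' member of that bin only; FASs at different ontology depths are distinct
#' test units. Set `propagate_ancestors = TRUE` to additionally add each
#' identifier to every ancestor path (`a.b`, `a`).
#'
#' @param path Path to the mapping file.
#' @param propagate_ancestors Logical; default `FALSE`.
#' @return An [annotation_catalog()]; descriptions hold the BINCODE of each
#'   NAME path.
#' @export
read_mapman_mapping <- function(path, propagate_ancestors = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "'",
                          check.names = FALSE, colClasses = "character",
                          na.strings = character(0))
  colnames(df) <- toupper(trimws(colnames(df)))
  required <- c("BINCODE", "NAME", "IDENTIFIER", "DESCRIPTION", "TYPE")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  if (nrow(df) == 0L) stop("empty MapMan mapping file")
  name <- trimws(df$NAME)
  identifier <- toupper(trimws(df$IDENTIFIER))
  bincode <- trimws(df$BINCODE)

  sets <- split(identifier, factor(name, levels = unique(name)))
  sets <- lapply(sets, function(m) unique(m[nzchar(m)]))
  descriptions <- vapply(split(bincode, factor(name, levels = unique(name))),
                         `[`, character(1), 1L)

  if (propagate_ancestors) {
    for (i in seq_along(name)) {
      if (!nzchar(identifier[i])) next
      parts <- strsplit(name[i], ".", fixed = TRUE)[[1L]]
      if (length(parts) < 2L) next
      for (d in seq_len(length(parts) - 1L)) {
        anc <- paste(parts[seq_len(d)], collapse = ".")
        cur <- if (anc %in% names(sets)) sets[[anc]] else character(0)
        sets[[anc]] <- unique(c(cur, identifier[i]))
      }
    }
    descriptions <- descriptions[intersect(names(descriptions), names(sets))]
  }
  annotation_catalog(sets, descriptions)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `set-name TAB description TAB member...`.
#' Duplicate members within a line are deduplicated; lines with fewer than
#' three fields (including empty lines) are skipped with a warning and counted
#' in the parse report attached as attribute `"parse_report"`.
#'
#' @param path Path to the GMT file.
#' @return An [annotation_catalog()] with attribute `parse_report`, a list
#'   with `n_lines`, `n_sets` and `n_skipped`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= 3L
  n_skipped <- sum(!ok)
  if (n_skipped > 0L)
    warning(sprintf("skipped %d malformed GMT line(s) (fewer than 3 fields)",
                    n_skipped))
  fields <- fields[ok]
  ids <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate set name in GMT: %s", ids[duplicated(ids)][1L]))
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)][nzchar(f[-c(1L, 2L)])]))
  names(sets) <- ids
  descriptions <- vapply(fields, `[`, character(1), 2L)
  names(descriptions) <- ids
  cat_ <- annotation_catalog(sets, descriptions)
  attr(cat_, "parse_report") <- list(n_lines = length(lines),
                                     n_sets = length(sets),
                                     n_skipped = n_skipped)
  cat_
}

#' Write an annotation catalog as GMT
#'
#' @param catalog An [annotation_catalog()].
#' @param path Output path.
#' @export
write_gmt <- function(catalog, path) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  desc <- catalog$descriptions
  lines <- vapply(names(catalog$sets), function(id) {
    d <- if (!is.null(desc) && id %in% names(desc)) desc[[id]] else "na"
    paste(c(id, d, catalog$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Aggregate biological replicates into one column per condition
#'
#' Conditions appear in the output in order of first appearance among the
#' matrix columns. Aggregation is applied per entity on the raw abundance
#' scale (intended to run before [log_transform()]).
#'
#' @param matrix An [abundance_matrix()] whose columns are sample labels.
#' @param design A [replicate_design()] covering every matrix column.
#' @param method `"mean"` (default) or `"median"`.
#' @return An [abundance_matrix()] with one column per condition.
#' @export
aggregate_replicates <- function(matrix, design, method = c("mean", "median")) {
  method <- match.arg(method)
  samples <- colnames(matrix)
  missing <- setdiff(samples, names(design))
  if (length(missing))
    stop(sprintf("column(s) absent from replicate design: %s",
                 paste(missing, collapse = ", ")))
  cond_of <- unclass(design)[samples]
  conds <- unique(cond_of)
  agg_fun <- if (method == "mean") rowMeans else
    function(m) apply(m, 1L, stats::median)
  out <- vapply(conds, function(cc) {
    cols <- samples[cond_of == cc]
    m <- unclass(matrix)[, cols, drop = FALSE]
    if (ncol(m) == 1L) m[, 1L] else agg_fun(m)
  }, numeric(nrow(matrix)))
  dimnames(out) <- list(rownames(matrix), conds)
  abundance_matrix(out)
}

# fixed-vs-scientific rendering for probabilities; >= 6 significant digits
format_pvalue_column <- function(x) {
  ifelse(x > 0 & x < 1e-4, sprintf("%.6e", x), sprintf("%.8f", x))
}

#' Write an enrichment result table as TSV
#'
#' Writes the columns `fas_id`, `constraint`, `direction`, `set_size`,
#' `subset_size`, `weight_sum`, `p_empirical`, `q_bh` with at least six
#' significant digits for floats (p/q in scientific notation below 1e-4),
#' rows ordered by ascending (constraint, direction, q_bh, fas_id).
#'
#' @param records Data frame of enrichment records, e.g. from [run_tmea()].
#'   May be empty (header-only output).
#' @param path Output path.
#' @export
write_enrichment_table <- function(records, path) {
  cols <- c("fas_id", "constraint", "direction", "set_size", "subset_size",
            "weight_sum", "p_empirical", "q_bh")
  if (nrow(records) == 0L) {
    out <- data.frame(matrix(character(0), 0L, length(cols),
                             dimnames = list(NULL, cols)),
                      check.names = FALSE)
  } else {
    missing <- setdiff(cols, colnames(records))
    if (length(missing))
      stop(sprintf("records lack column(s): %s", paste(missing, collapse = ", ")))
    ord <- order(records$constraint, records$direction, records$q_bh,
                 records$fas_id)
    records <- records[ord, , drop = FALSE]
    out <- data.frame(
      fas_id = records$fas_id,
      constraint = records$constraint,
      direction = records$direction,
      set_size = records$set_size,
      subset_size = records$subset_size,
      weight_sum = sprintf("%.10g", records$weight_sum),
      p_empirical = format_pvalue_column(records$p_empirical),
      q_bh = format_pvalue_column(records$q_bh),
      check.names = FALSE)
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop(sprintf("cannot write enrichment table to %s: %s", path,
                 conditionMessage(ok)))
  invisible(path)
}

#' Read back an enrichment table written by [write_enrichment_table()]
#'
#' @param path Path to the TSV.
#' @return Data frame with typed columns.
#' @export
read_enrichment_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c(fas_id = "character",
                                         constraint = "integer",
                                         direction = "character",
                                         set_size = "integer",
                                         subset_size = "integer",
                                         weight_sum = "numeric",
                                         p_empirical = "numeric",
                                         q_bh = "numeric"),
                          check.names = FALSE)
  df
}
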