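# Surprisal-analysis decomposition of a log-abundance matrix. The thin SVD
# L = U S V' identifies the baseline state (alpha = 0, the leading component,
# interpreted as the minimum free-energy steady state) and r constraints
# (alpha >= 1) with per-entity weights G_{i alpha} = U_{i alpha} and
# time-dependent potentials lambda_alpha(t) = sigma_alpha V_{t alpha}.

#' Log-transform an abundance matrix
#'
#' Computes `L = ln(X + pseudocount)` elementwise. When `pseudocount` is
#' `NULL` it defaults to 1 for integer count matrices (the conventional count
#' offset avoiding ln 0) and 0 otherwise; strict positivity of
#' `X + pseudocount` is enforced.
#'
#' @param matrix An [abundance_matrix()].
#' @param pseudocount Nonnegative real, or `NULL` for the automatic default.
#' @return A `log_matrix` (numeric matrix with the same dimnames).
#' @examples
#' x <- abundance_matrix(matrix(c(1, exp(1)), 1, 2,
#'   dimnames = list("g1", c("t0", "t1"))))
#' log_transform(x, pseudocount = 0)
#' @export
log_transform <- function(matrix, pseudocount = NULL) {
  if (is.null(pseudocount))
    pseudocount <- if (all(matrix == floor(matrix))) 1 else 0
  if (length(pseudocount) != 1L || !is.finite(pseudocount) || pseudocount < 0)
    stop("pseudocount must be a single nonnegative number")
  shifted <- unclass(matrix) + pseudocount
  bad <- which(shifted <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(paste0("entity %s has abundance + pseudocount <= 0; ",
                        "increase the pseudocount"),
                 rownames(matrix)[bad[1L, 1L]]))
  new_log_matrix(log(shifted))
}

#' Scale each column to the mean column total
#'
#' Optional per-column total-count scaling applied before the log transform
#' (off by default throughout the package): each column is multiplied so that
#' its sum equals the mean column sum.
#'
#' @param matrix An [abundance_matrix()].
#' @return An [abundance_matrix()].
#' @export
normalize_columns <- function(matrix) {
  tot <- colSums(matrix)
  if (any(tot == 0)) stop("cannot scale a column with zero total")
  scaled <- sweep(unclass(matrix), 2L, mean(tot) / tot, `*`)
  abundance_matrix(scaled)
}

# Deterministic SVD sign convention: for alpha = 0 flip (G, lambda) jointly so
# that sum_i G_i0 >= 0 (first nonzero G entry decides an exact-zero sum); for
# alpha >= 1 flip so that lambda_alpha at the first condition with nonzero
# potential is positive. Removes the sign ambiguity of the SVD so the
# decomposition is a deterministic function of L.
apply_sign_convention <- function(u, d, v) {
  k <- length(d)
  for (a in seq_len(k)) {
    flip <- FALSE
    if (a == 1L) {
      s0 <- sum(u[, 1L])
      if (s0 < 0) flip <- TRUE
      else if (s0 == 0) {
        j <- which(u[, 1L] != 0)[1L]
        if (!is.na(j) && u[j, 1L] < 0) flip <- TRUE
      }
    } else {
      lam <- d[a] * v[, a]
      j <- which(lam != 0)[1L]
      if (!is.na(j) && lam[j] < 0) flip <- TRUE
    }
    if (flip) {
      u[, a] <- -u[, a]
      v[, a] <- -v[, a]
    }
  }
  list(u = u, v = v)
}

#' Surprisal-analysis decomposition by SVD
#'
#' Thin SVD of the log matrix with `r + 1 = min(entities, conditions)`
#' components. Column `alpha` of the weight matrix holds `G_{i alpha}`
#' (orthonormal columns), row `alpha` of the potential matrix holds
#' `lambda_alpha(t) = sigma_alpha V_{t alpha}`. Index 0 is the baseline
#' state; the surprisal of entity i at time t, expressed as deviation from
#' the baseline, is `-sum_{alpha>=1} G_{i alpha} lambda_alpha(t)` (see
#' [surprisal_values()]). A fixed sign convention makes the result a
#' deterministic function of the input.
#'
#' @param log_matrix A `log_matrix` from [log_transform()] (any numeric
#'   matrix with dimnames and finite entries is accepted).
#' @return A `surprisal_decomposition` with elements `weights`
#'   (entities x (r+1)), `potentials` ((r+1) x conditions),
#'   `singular_values`, `entity_ids`, `condition_labels`.
#' @export
surprisal_decompose <- function(log_matrix) {
  L <- validate_entity_matrix(unclass(log_matrix), allow_negative = TRUE)
  if (nrow(L) < 2L || ncol(L) < 2L)
    stop("need at least 2 entities and 2 conditions")
  k <- min(dim(L))
  sv <- svd(L, nu = k, nv = k)
  fixed <- apply_sign_convention(sv$u, sv$d, sv$v)
  G <- fixed$u
  Lambda <- sv$d * t(fixed$v) # row alpha = sigma_alpha * V[, alpha]
  alpha_names <- paste0("alpha", seq_len(k) - 1L)
  dimnames(G) <- list(rownames(L), alpha_names)
  dimnames(Lambda) <- list(alpha_names, colnames(L))
  new_surprisal_decomposition(G, Lambda, sv$d, rownames(L), colnames(L))
}

#' Reconstruct the log matrix from the leading components
#'
#' `L_hat = sum_{alpha=0}^{k} G_{. alpha} lambda_alpha(.)`.
#'
#' @param decomp A `surprisal_decomposition`.
#' @param max_constraint Highest constraint index k to include (0 = baseline
#'   only; k = r gives the exact reconstruction).
#' @return A `log_matrix`.
#' @export
reconstruct <- function(decomp, max_constraint) {
  stopifnot(inherits(decomp, "surprisal_decomposition"))
  r <- n_constraints(decomp)
  if (length(max_constraint) != 1L || max_constraint < 0 || max_constraint > r)
    stop(sprintf("max_constraint %s out of range 0..%d",
                 as.character(max_constraint), r))
  idx <- seq_len(max_constraint + 1L)
  new_log_matrix(decomp$weights[, idx, drop = FALSE] %*%
                   decomp$potentials[idx, , drop = FALSE])
}

#' Surprisal values (deviation from the baseline state)
#'
#' Returns `-(L - G_0 lambda_0) = -sum_{alpha>=1} G_{i alpha}
#' lambda_alpha(t)`, the negative log deviation of each entity from the
#' baseline (steady-state) reconstruction.
#'
#' @param decomp A `surprisal_decomposition`.
#' @return Numeric matrix, entities x conditions.
#' @export
surprisal_values <- function(decomp) {
  stopifnot(inherits(decomp, "surprisal_decomposition"))
  r <- n_constraints(decomp)
  if (r == 0L)
    return(matrix(0, length(decomp$entity_ids), length(decomp$condition_labels),
                  dimnames = list(decomp$entity_ids, decomp$condition_labels)))
  idx <- seq_len(r) + 1L
  -(decomp$weights[, idx, drop = FALSE] %*%
      decomp$potentials[idx, , drop = FALSE])
}

#' Fraction of the data recovered by the leading components
#'
#' `sum_{alpha<=k} sigma_alpha^2 / sum_alpha sigma_alpha^2`, equivalently
#' `1 - ||L - L_hat_k||_F^2 / ||L||_F^2`. Nondecreasing in k and exactly 1
#' at k = r. A zero matrix is defined as perfectly recovered (fraction 1).
#'
#' @inheritParams reconstruct
#' @return Fraction in `[0, 1]`.
#' @export
recovery_fraction <- function(decomp, max_constraint) {
  stopifnot(inherits(decomp, "surprisal_decomposition"))
  r <- n_constraints(decomp)
  if (length(max_constraint) != 1L || max_constraint < 0 || max_constraint > r)
    stop(sprintf("max_constraint %s out of range 0..%d",
                 as.character(max_constraint), r))
  tot <- sum(decomp$singular_values^2)
  if (tot == 0) return(1)
  sum(decomp$singular_values[seq_len(max_constraint + 1L)]^2) / tot
}

#' Importance-loss spectrum of the singular values
#'
#' Relative loss between consecutive singular values,
#' `(sigma_alpha - sigma_{alpha+1}) / sigma_alpha` (defined as 0 where
#' `sigma_alpha = 0`), the quantity behind the elbow criterion used to choose
#' how many constraints to retain.
#'
#' @param decomp A `surprisal_decomposition`.
#' @return Object of class `"importance_spectrum"`: list with
#'   `singular_values` and `relative_losses` (length r).
#' @export
importance_spectrum <- function(decomp) {
  stopifnot(inherits(decomp, "surprisal_decomposition"))
  d <- decomp$singular_values
  k <- length(d)
  losses <- if (k < 2L) numeric(0) else {
    num <- d[-k] - d[-1L]
    ifelse(d[-k] == 0, 0, num / d[-k])
  }
  structure(list(singular_values = d, relative_losses = losses),
            class = "importance_spectrum")
}

#' @export
print.importance_spectrum <- function(x, ...) {
  cat("importance_spectrum\n  singular values:",
      format(x$singular_values, digits = 4), "\n  relative losses:",
      format(x$relative_losses, digits = 4), "\n")
  invisible(x)
}

#' Suggest the number of constraints to retain
#'
#' Returns the constraint index alpha >= 1 with the largest relative
#' importance loss (the elbow); a reporting aid, the choice stays with the
#' user.
#'
#' @param spectrum An `importance_spectrum`.
#' @return Integer constraint index.
#' @export
suggest_constraints <- function(spectrum) {
  stopifnot(inherits(spectrum, "importance_spectrum"))
  losses <- spectrum$relative_losses
  if (length(losses) < 2L)
    stop("need at least two components beyond the baseline")
  which.max(losses[-1L])
}

#' Free-energy landscape of selected constraints
#'
#' `F_alpha(t) = -lambda_alpha(t) * sum_i X_i(t) G_{i alpha}`, the work
#' attributable to constraint alpha (arbitrary units), and the total over the
#' requested constraints. The baseline alpha = 0 is excluded by definition:
#' the total free energy sums over alpha >= 1. `matrix` must be the same
#' abundance matrix (same entity/condition ordering) that produced the
#' decomposed log matrix.
#'
#' @param decomp A `surprisal_decomposition`.
#' @param matrix The [abundance_matrix()] on the raw scale.
#' @param constraint_indices Integer vector of constraint indices, all >= 1.
#' @return Object of class `"free_energy_table"`: list with `per_constraint`
#'   (constraints x conditions), `total` (vector over conditions) and
#'   `constraint_indices`.
#' @export
free_energy <- function(decomp, matrix, constraint_indices) {
  stopifnot(inherits(decomp, "surprisal_decomposition"))
  if (length(constraint_indices) == 0L)
    stop("constraint_indices must be nonempty")
  r <- n_constraints(decomp)
  if (any(constraint_indices == 0))
    stop("the baseline (alpha = 0) is excluded from the free-energy sum")
  if (any(constraint_indices < 1 | constraint_indices > r))
    stop(sprintf("constraint indices must lie in 1..%d", r))
  if (!identical(rownames(matrix), decomp$entity_ids) ||
      !identical(colnames(matrix), decomp$condition_labels))
    stop("matrix and decomposition must share entity/condition ordering")
  X <- unclass(matrix)
  per <- t(vapply(constraint_indices, function(a) {
    m_t <- as.numeric(crossprod(X, decomp$weights[, a + 1L]))
    -decomp$potentials[a + 1L, ] * m_t
  }, numeric(ncol(X))))
  dimnames(per) <- list(paste0("alpha", constraint_indices),
                        decomp$condition_labels)
  structure(list(per_constraint = per, total = colSums(per),
                 constraint_indices = as.integer(constraint_indices)),
            class = "free_energy_table")
}

#' @export
print.free_energy_table <- function(x, ...) {
  cat(sprintf("free_energy_table: constraints {%s} x %d conditions\n",
              paste(x$constraint_indices, collapse = ","),
              ncol(x$per_constraint)))
  print(rbind(x$per_constraint, total = x$total))
  invisible(x)
}

#' Export a decomposition as TSV tables
#'
#' Writes `weights.tsv` (entity x alpha), `potentials.tsv`
#' (alpha x condition) and `singular_values.tsv` into `dir`, with the sign
#' convention applied.
#'
#' @param decomp A `surprisal_decomposition`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_decomposition <- function(decomp, dir) {
  stopifnot(inherits(decomp, "surprisal_decomposition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("weights.tsv", "potentials.tsv",
                            "singular_values.tsv"))
  wdf <- data.frame(entity_id = decomp$entity_ids,
                    format(decomp$weights, digits = 10, trim = TRUE,
                           scientific = FALSE),
                    check.names = FALSE)
  utils::write.table(wdf, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pdf <- data.frame(constraint = rownames(decomp$potentials),
                    format(decomp$potentials, digits = 10, trim = TRUE,
                           scientific = FALSE),
                    check.names = FALSE)
  utils::write.table(pdf, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sdf <- data.frame(singular_value = sprintf("%.10g", decomp$singular_values))
  utils::write.table(sdf, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
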