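# Shared helpers: independent oracles and small fixture builders. These stay
# deliberately naive (enumeration, direct formulas) so they cannot share a
# defect with the implementation paths they check.

# Exact permutation p-value by exhaustive enumeration of all size-s subsets.
exact_subset_pvalue <- function(pool, s, w_hat, direction) {
  sums <- utils::combn(seq_along(pool), s, FUN = function(i) sum(pool[i]))
  if (direction == "positive") mean(sums >= w_hat) else mean(sums <= w_hat)
}

# Kolmogorov-Smirnov distance of a sample from the uniform(0, 1) cdf.
ks_uniform_distance <- function(p) {
  p <- sort(p)
  n <- length(p)
  i <- seq_len(n)
  max(i / n - p, p - (i - 1) / n)
}

# Random strictly-positive abundance matrix with dimnames.
random_abundance <- function(n, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  abundance_matrix(matrix(exp(rnorm(n * m, 5, 1)), n, m,
                          dimnames = list(sprintf("g%03d", seq_len(n)),
                                          sprintf("t%02d", seq_len(m)))))
}

# Random log matrix (possibly negative entries) with dimnames.
random_logmat <- function(n, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * m), n, m,
         dimnames = list(sprintf("g%03d", seq_len(n)),
                         sprintf("t%02d", seq_len(m))))
}

# Sign aligning an estimated component with its planted truth.
alignment_sign <- function(estimated, truth) {
  s <- sign(sum(estimated * truth))
  if (s == 0) 1 else s
}

# Direction in which a set planted as `direction` appears in the estimated
# decomposition, given the alignment sign of the constraint.
aligned_direction <- function(direction, align) {
  if (align >= 0) direction else
    if (direction == "positive") "negative" else "positive"
}

# Minimal hand-built decomposition for micro-examples.
manual_decomposition <- function(weights, potentials, singular_values,
                                 entity_ids, condition_labels) {
  dimnames(weights) <- list(entity_ids,
                            paste0("alpha", seq_len(ncol(weights)) - 1L))
  dimnames(potentials) <- list(paste0("alpha", seq_len(nrow(potentials)) - 1L),
                               condition_labels)
  tmea:::new_surprisal_decomposition(weights, potentials, singular_values,
                                     entity_ids, condition_labels)
}
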