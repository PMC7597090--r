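# Directional weight-sum enrichment test. For one FAS and constraint the
# members with strictly positive / strictly negative weights form the
# directional subsets E+ / E-; their weight sums w_hat+/- are compared with b
# Monte Carlo resamples of equal cardinality drawn from all same-sign weights
# of the constraint, giving empirical p-values (ties count as extreme).

#' Split a FAS into directional weight subsets
#'
#' Members with strictly positive weights form the positive subset, strictly
#' negative weights the negative subset; zero weights belong to neither.
#' Members absent from the weight map are dropped and counted.
#'
#' @param weights Named numeric vector: entity -> weight in constraint
#'   `constraint` (e.g. [constraint_weights()]).
#' @param members Character vector of FAS member entity ids (nonempty).
#' @param fas_id FAS identifier (for bookkeeping).
#' @param constraint Constraint index alpha (for bookkeeping).
#' @return Object of class `"directional_split"`: list with `fas_id`,
#'   `constraint`, `positive`/`negative` (named weight vectors), `s_plus`,
#'   `s_minus`, `w_hat_plus`, `w_hat_minus`, `n_zero`, `n_unmeasured`.
#' @examples
#' w <- c(a = 1, b = 2, c = -3, d = 0)
#' split_directional(w, c("a", "b", "c", "d"), "S1", 1)
#' @export
split_directional <- function(weights, members, fas_id, constraint) {
  if (length(members) == 0L) stop("empty member set")
  if (is.null(names(weights))) stop("weights must be a named vector")
  present <- members %in% names(weights)
  n_unmeasured <- sum(!present)
  if (n_unmeasured > 0L)
    message(sprintf("%s: dropped %d unmeasured member(s)", fas_id,
                    n_unmeasured))
  w <- weights[members[present]]
  pos <- w[w > 0]
  neg <- w[w < 0]
  structure(list(fas_id = fas_id, constraint = constraint,
                 positive = pos, negative = neg,
                 s_plus = length(pos), s_minus = length(neg),
                 w_hat_plus = sum(pos), w_hat_minus = sum(neg),
                 n_zero = sum(w == 0), n_unmeasured = n_unmeasured),
            class = "directional_split")
}

#' Empirical Monte Carlo p-value for a directional weight sum
#'
#' Draws `b` independent subsets of size `subset_size` from `pool` (without
#' replacement by default, the permutation null; `replace = TRUE` gives the
#' bootstrap variant), sums each, and reports the fraction at least as
#' extreme as `observed_sum`: `P(W >= w_hat)` for the positive direction,
#' `P(W <= w_hat)` for the negative one, with ties counting as extreme. The
#' plain estimator can return exactly 0; its resolution 1/b is stored
#' alongside. `estimator = "add_one"` uses `(n_extreme + 1) / (b + 1)` for
#' conservative FDR work.
#'
#' @param pool Numeric vector of all same-sign weights of the constraint.
#' @param subset_size Cardinality s+/- of the observed directional subset.
#' @param observed_sum Observed directional weight sum w_hat+/-.
#' @param b Number of Monte Carlo replicates (>= 1).
#' @param direction `"positive"` or `"negative"`.
#' @param seed Optional integer; when given, `set.seed(seed)` is applied so
#'   the result is a deterministic function of (seed, b, pool order).
#' @param replace Resample with replacement (bootstrap) instead of the
#'   default without-replacement permutation null.
#' @param estimator `"plain"` (the empirical estimator) or `"add_one"`.
#' @return Object of class `"empirical_pvalue"`: list with `p`, `b`,
#'   `n_extreme`, `direction`, `resolution` (1/b) and `estimator`.
#' @examples
#' monte_carlo_pvalue(c(1, 2, 3), 2, 5, b = 1000, direction = "positive",
#'                    seed = 1)
#' @export
monte_carlo_pvalue <- function(pool, subset_size, observed_sum, b,
                               direction = c("positive", "negative"),
                               seed = NULL, replace = FALSE,
                               estimator = c("plain", "add_one")) {
  direction <- match.arg(direction)
  estimator <- match.arg(estimator)
  if (length(pool) == 0L) stop("empty pool")
  if (subset_size < 1L) stop("subset_size must be >= 1")
  if (!replace && length(pool) < subset_size)
    stop(sprintf("pool size %d smaller than subset size %d", length(pool),
                 subset_size))
  if (b < 1L) stop("b must be >= 1")
  if (direction == "positive" && any(pool <= 0))
    stop("positive-direction pool must contain strictly positive weights")
  if (direction == "negative" && any(pool >= 0))
    stop("negative-direction pool must contain strictly negative weights")
  if (!is.null(seed)) set.seed(as.integer(seed))
  sums <- .mc_subset_sums(as.numeric(pool), as.integer(subset_size),
                          as.integer(b), isTRUE(replace))
  # ties count as extreme; resampled sums are accumulated in draw order, so a
  # sum over the very same weights can differ from observed_sum by summation
  # roundoff. The tolerance sits at that roundoff scale (far below any
  # genuine gap between distinct subset sums).
  tie_tol <- 1e-12 * subset_size * max(abs(pool))
  n_extreme <- if (direction == "positive")
    sum(sums >= observed_sum - tie_tol)
  else sum(sums <= observed_sum + tie_tol)
  p <- if (estimator == "plain") n_extreme / b else (n_extreme + 1) / (b + 1)
  structure(list(p = p, b = as.integer(b), n_extreme = as.integer(n_extreme),
                 direction = direction, resolution = 1 / b,
                 estimator = estimator),
            class = "empirical_pvalue")
}

#' @export
print.empirical_pvalue <- function(x, ...) {
  cat(sprintf("empirical p = %g (%s direction, %d/%d extreme, resolution %g)\n",
              x$p, x$direction, x$n_extreme, x$b, x$resolution))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (m p_(j) / j)`, clipped at 1 and mapped back to the
#' input order (delegates to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# Deterministic substream seed per (constraint, direction, FAS id), so test
# order and parallel scheduling never change results. Polynomial rolling hash
# modulo 2^31 - 1; exact in doubles (intermediates < 2^36 << 2^53).
derive_stream_seed <- function(seed, constraint, direction, fas_id) {
  m <- 2147483647
  h <- as.double(seed) %% m
  mix <- function(h, x) (h * 31 + x) %% m
  h <- mix(h, as.double(constraint))
  h <- mix(h, if (direction == "positive") 1 else 2)
  for (code in utf8ToInt(fas_id)) h <- mix(h, code)
  as.integer(h)
}

#' Run the TMEA directional weight-sum enrichment test
#'
#' For every requested constraint and every FAS with at least `min_set_size`
#' measured members, tests both directions (skipping a direction with an
#' empty subset) against the directional weight pools of the constraint
#' restricted to measured entities, and applies Benjamini-Hochberg correction
#' within the chosen family.
#'
#' @param decomp A `surprisal_decomposition`.
#' @param catalog An [annotation_catalog()]; members absent from the
#'   decomposition are ignored (a message reports the dropped count).
#' @param constraint_indices Constraint indices (all >= 1); default the first
#'   `min(3, r)` constraints.
#' @param b Monte Carlo replicates per test (default 10000).
#' @param min_set_size Minimum measured-member count s for a FAS to be tested
#'   (inclusive, default 5).
#' @param seed Integer seed for the run; per-test substreams are derived from
#'   it so results do not depend on evaluation order. When `NULL` a seed is
#'   drawn from the session RNG (and recorded in the result's
#'   `"seed"` attribute).
#' @param sampling `"permutation"` (without replacement, default) or
#'   `"bootstrap"`.
#' @param bh_family BH correction family: `"per_constraint_direction"`
#'   (default, the narrowest defensible family), `"per_constraint"`, or
#'   `"global"`.
#' @param estimator Passed to [monte_carlo_pvalue()].
#' @return Data frame (class `"tmea_result"`) with columns `fas_id`,
#'   `constraint`, `direction`, `set_size`, `subset_size`, `weight_sum`,
#'   `p_empirical`, `q_bh`, `n_extreme`, `p_resolution`, sorted by
#'   (constraint, direction, q_bh, fas_id).
#' @export
run_tmea <- function(decomp, catalog, constraint_indices = NULL, b = 10000,
                     min_set_size = 5, seed = NULL,
                     sampling = c("permutation", "bootstrap"),
                     bh_family = c("per_constraint_direction",
                                   "per_constraint", "global"),
                     estimator = c("plain", "add_one")) {
  stopifnot(inherits(decomp, "surprisal_decomposition"),
            inherits(catalog, "annotation_catalog"))
  sampling <- match.arg(sampling)
  bh_family <- match.arg(bh_family)
  estimator <- match.arg(estimator)
  r <- n_constraints(decomp)
  if (is.null(constraint_indices)) constraint_indices <- seq_len(min(3L, r))
  if (any(constraint_indices < 1 | constraint_indices > r))
    stop(sprintf("constraint indices must lie in 1..%d", r))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)

  entities <- decomp$entity_ids
  measured <- lapply(catalog$sets, function(m) m[m %in% entities])
  n_dropped <- sum(lengths(catalog$sets) - lengths(measured))
  if (n_dropped > 0L)
    message(sprintf("ignoring %d annotation member(s) absent from the matrix",
                    n_dropped))
  keep <- lengths(measured) >= min_set_size
  empty_result <- function() {
    res <- data.frame(fas_id = character(0), constraint = integer(0),
                      direction = character(0), set_size = integer(0),
                      subset_size = integer(0), weight_sum = numeric(0),
                      p_empirical = numeric(0), q_bh = numeric(0),
                      n_extreme = integer(0), p_resolution = numeric(0))
    class(res) <- c("tmea_result", "data.frame")
    attr(res, "seed") <- as.integer(seed)
    res
  }
  if (!any(keep)) {
    warning(sprintf("no FAS has >= %d measured members", min_set_size))
    return(empty_result())
  }
  measured <- measured[keep]
  fas_ids <- names(measured)

  acc <- vector("list", 2L * length(constraint_indices) * length(fas_ids))
  n_rec <- 0L
  for (a in constraint_indices) {
    w <- constraint_weights(decomp, a)
    pools <- list(positive = w[w > 0], negative = w[w < 0])
    for (fas in fas_ids) {
      sp <- split_directional(w, measured[[fas]], fas, a)
      for (direction in c("positive", "negative")) {
        s_dir <- if (direction == "positive") sp$s_plus else sp$s_minus
        if (s_dir == 0L) next
        w_hat <- if (direction == "positive") sp$w_hat_plus else sp$w_hat_minus
        pv <- monte_carlo_pvalue(
          pools[[direction]], s_dir, w_hat, b, direction,
          seed = derive_stream_seed(seed, a, direction, fas),
          replace = sampling == "bootstrap", estimator = estimator)
        n_rec <- n_rec + 1L
        acc[[n_rec]] <- list(fas_id = fas, constraint = a,
                             direction = direction,
                             set_size = length(measured[[fas]]),
                             subset_size = s_dir, weight_sum = w_hat,
                             p_empirical = pv$p, n_extreme = pv$n_extreme,
                             p_resolution = pv$resolution)
      }
    }
  }
  if (n_rec == 0L) {
    warning("no testable direction in any FAS")
    return(empty_result())
  }
  acc <- acc[seq_len(n_rec)]
  grab <- function(f, mode) vapply(acc, `[[`, vector(mode, 1L), f)
  res <- data.frame(fas_id = grab("fas_id", "character"),
                    constraint = as.integer(grab("constraint", "numeric")),
                    direction = grab("direction", "character"),
                    set_size = as.integer(grab("set_size", "numeric")),
                    subset_size = as.integer(grab("subset_size", "numeric")),
                    weight_sum = grab("weight_sum", "numeric"),
                    p_empirical = grab("p_empirical", "numeric"),
                    n_extreme = as.integer(grab("n_extreme", "numeric")),
                    p_resolution = grab("p_resolution", "numeric"))
  fam <- switch(bh_family,
                per_constraint_direction = paste(res$constraint, res$direction),
                per_constraint = as.character(res$constraint),
                global = rep("all", nrow(res)))
  res$q_bh <- NA_real_
  for (g in unique(fam)) {
    i <- fam == g
    res$q_bh[i] <- bh_adjust(res$p_empirical[i])
  }
  res <- res[order(res$constraint, res$direction, res$q_bh, res$fas_id),
             c("fas_id", "constraint", "direction", "set_size", "subset_size",
               "weight_sum", "p_empirical", "q_bh", "n_extreme",
               "p_resolution")]
  rownames(res) <- NULL
  class(res) <- c("tmea_result", "data.frame")
  attr(res, "seed") <- as.integer(seed)
  res
}
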