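# Weight-ratio vs count-ratio diagnostics: how much of the directional
# weight-sum signal in annotated sets is explained by merely counting members
# beyond a quantile threshold of the constraint's weight pool. High R^2 of
# WR ~ CR across sets means counts suffice; outliers with high WR at low CR
# mark sets driven by few heavy-weight members.

#' Weight ratio and count ratio of one set at one quantile threshold
#'
#' The threshold is the empirical quantile (type 7, linear interpolation) of
#' the directional pool. For a positive pool, "beyond" means strictly above
#' the threshold; for a negative pool, strictly below. Ratios use absolute
#' values in the negative direction so both stay in `[0, 1]`. With within-set
#' denominators (default) WR is the member weight mass beyond the threshold
#' over the total member mass and CR the analogous count fraction; the
#' `"global"` variant divides by the pool's mass/count beyond nothing (the
#' whole pool).
#'
#' @param weights Directional member weights (all the same sign as `pool`).
#' @param pool Directional weight pool of the constraint (nonempty, all
#'   strictly positive or all strictly negative).
#' @param quantile Quantile in (0, 1) defining the threshold.
#' @param denominators `"within"` (default) or `"global"`.
#' @return Named numeric vector `c(WR = ..., CR = ...)`.
#' @examples
#' wrcr_for_set(c(1, 2, 3, 4), pool = c(1, 2, 3, 4), quantile = 0.5)
#' @export
wrcr_for_set <- function(weights, pool, quantile,
                         denominators = c("within", "global")) {
  denominators <- match.arg(denominators)
  if (length(weights) == 0L) stop("empty member set")
  if (length(pool) == 0L) stop("empty pool")
  if (length(quantile) != 1L || quantile <= 0 || quantile >= 1)
    stop("quantile must lie strictly in (0, 1)")
  positive <- all(pool > 0)
  if (!positive && !all(pool < 0))
    stop("pool must be all-positive or all-negative")
  if (positive && any(weights <= 0) || !positive && any(weights >= 0))
    stop("member weights must share the pool's sign")
  thr <- stats::quantile(pool, quantile, names = FALSE, type = 7)
  beyond <- if (positive) weights > thr else weights < thr
  pool_beyond <- if (positive) pool > thr else pool < thr
  num_w <- sum(abs(weights[beyond]))
  num_c <- sum(beyond)
  if (denominators == "within") {
    c(WR = num_w / sum(abs(weights)), CR = num_c / length(weights))
  } else {
    c(WR = num_w / sum(abs(pool)), CR = num_c / length(pool))
  }
}

#' R-squared of the linear regression WR ~ CR
#'
#' Ordinary least squares of WR on an intercept and CR;
#' `R^2 = 1 - SS_res / SS_tot`. Needs at least 3 pairs and nonzero CR
#' variance, otherwise `NA` is returned (flagged missing). Constant WR with
#' varying CR gives 0.
#'
#' @param cr Numeric vector of count ratios.
#' @param wr Numeric vector of weight ratios (same length).
#' @return R-squared in `[0, 1]`, or `NA_real_`.
#' @export
linear_r2 <- function(cr, wr) {
  if (length(cr) != length(wr)) stop("cr and wr must have equal length")
  if (length(cr) < 3L) return(NA_real_)
  sxx <- sum((cr - mean(cr))^2)
  if (sxx == 0) return(NA_real_)
  syy <- sum((wr - mean(wr))^2)
  if (syy == 0) return(0)
  sxy <- sum((cr - mean(cr)) * (wr - mean(wr)))
  ss_res <- syy - sxy^2 / sxx
  1 - ss_res / syy
}

#' Trimmed mean
#'
#' Drops `floor(fraction * n)` smallest and largest values and averages the
#' rest (the rule implemented by `mean(x, trim = fraction)`).
#'
#' @param values Nonempty numeric vector.
#' @param fraction Trim fraction in `[0, 0.5)`.
#' @return The trimmed mean.
#' @examples
#' trimmed_mean(1:10, 0.15) # drops 1 and 10 -> 5.5
#' @export
trimmed_mean <- function(values, fraction = 0.15) {
  if (length(values) == 0L) stop("empty value list")
  if (length(fraction) != 1L || fraction < 0 || fraction >= 0.5)
    stop("fraction must lie in [0, 0.5)")
  mean(values, trim = fraction)
}

#' WR/CR regression profile over quantiles
#'
#' For each quantile (default 1%..99%) and direction, gathers the (CR, WR)
#' pair of every FAS with at least `min_set_size` measured members (pooled
#' across the requested constraints; thresholds are computed per constraint),
#' fits WR ~ CR, and summarizes each direction by the 15% trimmed mean of the
#' per-quantile R-squared values.
#'
#' @inheritParams run_tmea
#' @param quantiles Quantile grid, default `seq(0.01, 0.99, by = 0.01)`.
#' @param denominators Passed to [wrcr_for_set()].
#' @param trim Trim fraction for the summary, default 0.15.
#' @return Object of class `"wrcr_profile"`: list with `r2` (data frame:
#'   quantile, direction, r2, n_sets), `trimmed_mean_r2` (named vector,
#'   positive/negative), `n_flagged` (count of quantiles with undefined R^2,
#'   dropped from the trimmed mean), and the parameters used.
#' @export
wrcr_profile <- function(decomp, catalog, constraint_indices = NULL,
                         min_set_size = 5,
                         quantiles = seq(0.01, 0.99, by = 0.01),
                         denominators = c("within", "global"), trim = 0.15) {
  stopifnot(inherits(decomp, "surprisal_decomposition"),
            inherits(catalog, "annotation_catalog"))
  denominators <- match.arg(denominators)
  r <- n_constraints(decomp)
  if (is.null(constraint_indices)) constraint_indices <- seq_len(min(3L, r))
  if (any(constraint_indices < 1 | constraint_indices > r))
    stop(sprintf("constraint indices must lie in 1..%d", r))
  entities <- decomp$entity_ids
  measured <- lapply(catalog$sets, function(m) m[m %in% entities])
  measured <- measured[lengths(measured) >= min_set_size]
  if (length(measured) == 0L)
    stop(sprintf("no FAS has >= %d measured members", min_set_size))

  # pairs[[direction]][[q]] accumulates CR and WR across constraints and sets
  pairs <- list(positive = rep(list(list(cr = NULL, wr = NULL)),
                               length(quantiles)),
                negative = rep(list(list(cr = NULL, wr = NULL)),
                               length(quantiles)))
  for (a in constraint_indices) {
    w <- constraint_weights(decomp, a)
    for (direction in c("positive", "negative")) {
      pool <- if (direction == "positive") w[w > 0] else w[w < 0]
      if (length(pool) == 0L) next
      thr <- stats::quantile(pool, quantiles, names = FALSE, type = 7)
      for (fas in names(measured)) {
        mw <- w[measured[[fas]]]
        mw <- if (direction == "positive") mw[mw > 0] else mw[mw < 0]
        if (length(mw) == 0L) next
        for (qi in seq_along(quantiles)) {
          beyond <- if (direction == "positive") mw > thr[qi] else mw < thr[qi]
          if (denominators == "within") {
            wr <- sum(abs(mw[beyond])) / sum(abs(mw))
            cr <- sum(beyond) / length(mw)
          } else {
            wr <- sum(abs(mw[beyond])) / sum(abs(pool))
            cr <- sum(beyond) / length(pool)
          }
          pairs[[direction]][[qi]]$cr <- c(pairs[[direction]][[qi]]$cr, cr)
          pairs[[direction]][[qi]]$wr <- c(pairs[[direction]][[qi]]$wr, wr)
        }
      }
    }
  }
  rows <- list()
  trimmed <- c(positive = NA_real_, negative = NA_real_)
  n_flagged <- c(positive = 0L, negative = 0L)
  for (direction in c("positive", "negative")) {
    r2 <- vapply(seq_along(quantiles), function(qi) {
      pq <- pairs[[direction]][[qi]]
      if (is.null(pq$cr)) return(NA_real_)
      linear_r2(pq$cr, pq$wr)
    }, numeric(1))
    n_sets <- vapply(seq_along(quantiles), function(qi)
      length(pairs[[direction]][[qi]]$cr), integer(1))
    rows[[direction]] <- data.frame(quantile = quantiles,
                                    direction = direction, r2 = r2,
                                    n_sets = n_sets)
    n_flagged[[direction]] <- sum(is.na(r2))
    ok <- r2[!is.na(r2)]
    if (length(ok) > 0L) trimmed[[direction]] <- trimmed_mean(ok, trim)
  }
  structure(list(r2 = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 trimmed_mean_r2 = trimmed, n_flagged = n_flagged,
                 constraint_indices = as.integer(constraint_indices),
                 denominators = denominators, trim = trim),
            class = "wrcr_profile")
}

#' @export
print.wrcr_profile <- function(x, ...) {
  cat(sprintf(paste0("wrcr_profile over constraints {%s} (%s denominators)\n",
                     "  %.0f%% trimmed mean R^2: positive %.4f, negative %.4f\n"),
              paste(x$constraint_indices, collapse = ","), x$denominators,
              100 * x$trim, x$trimmed_mean_r2[["positive"]],
              x$trimmed_mean_r2[["negative"]]))
  invisible(x)
}

#' Write a WR/CR profile as TSV
#'
#' Columns `quantile`, `direction`, `r2`, `n_sets`, followed by one summary
#' row per direction (`quantile = "trimmed_mean"`).
#'
#' @param profile A `wrcr_profile`.
#' @param path Output path.
#' @export
write_wrcr_profile <- function(profile, path) {
  stopifnot(inherits(profile, "wrcr_profile"))
  body <- data.frame(quantile = sprintf("%.2f", profile$r2$quantile),
                     direction = profile$r2$direction,
                     r2 = sprintf("%.8g", profile$r2$r2),
                     n_sets = profile$r2$n_sets)
  summ <- data.frame(quantile = "trimmed_mean",
                     direction = names(profile$trimmed_mean_r2),
                     r2 = sprintf("%.8g", profile$trimmed_mean_r2),
                     n_sets = NA_integer_)
  utils::write.table(rbind(body, summ), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
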