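# Classical one-sided hypergeometric overrepresentation test over binary
# differential-expression labels, the baseline TMEA is compared against.
# The labeling itself (e.g. DESeq2 DEG calls) is an input, never computed here.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: from an urn with `N`
#' entities of which `K` are labeled, draw `n`; probability of at least `k`
#' labeled. Computed via [stats::phyper()] (numerically stable tail
#' evaluation). No mid-p correction is applied.
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param N Background size.
#' @param K Labeled-true count in the background.
#' @param n Set size drawn.
#' @return Upper-tail probability; 1 exactly when `k = 0`.
#' @examples
#' hypergeom_upper_tail(4, 10, 5, 5) # 26/252
#' @export
hypergeom_upper_tail <- function(k, N, K, n) {
  vals <- c(k = k, N = N, K = K, n = n)
  if (any(vals != floor(vals)) || any(vals < 0))
    stop("k, N, K, n must be nonnegative integers")
  if (K > N || n > N) stop("need K <= N and n <= N")
  if (k > min(K, n)) stop("need k <= min(K, n)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read a binary label table
#'
#' Two-column TSV with header: `entity_id` and `is_significant` (0/1 or
#' TRUE/FALSE).
#'
#' @param path Path to the TSV.
#' @return Named logical vector (names = entity ids).
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, na.strings = character(0))
  if (ncol(df) < 2L) stop("label table needs entity_id and is_significant columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate entity ID: %s", ids[duplicated(ids)][1L]))
  raw <- df[[2L]]
  lab <- if (is.logical(raw)) raw else {
    v <- suppressWarnings(as.numeric(raw))
    if (anyNA(v) || any(!v %in% c(0, 1)))
      stop("is_significant must be 0/1 or TRUE/FALSE")
    v == 1
  }
  names(lab) <- ids
  lab
}

#' Hypergeometric overrepresentation GSEA baseline
#'
#' One one-sided upper-tail hypergeometric test per FAS whose measured size
#' meets `min_set_size`; Benjamini-Hochberg correction across all tested FASs
#' (a single family). The background N is, by default, the labeled entities
#' that carry at least one annotation (`background_mode = "annotated"`,
#' common GSEA practice); `"all"` uses every labeled entity.
#'
#' @param background Named logical vector: entity id -> differential label
#'   (e.g. DEG flag). Needs unique names; a meaningful test needs at least
#'   one `TRUE` and one `FALSE`.
#' @param catalog An [annotation_catalog()].
#' @param min_set_size Minimum measured FAS size n (inclusive, default 5).
#' @param background_mode `"annotated"` (default) or `"all"`.
#' @return Data frame (class `"hypgsea_result"`) with columns `fas_id`, `N`,
#'   `K`, `n`, `k`, `p`, `q_bh`, sorted by (q_bh, fas_id).
#' @export
run_hypgsea <- function(background, catalog, min_set_size = 5,
                        background_mode = c("annotated", "all")) {
  background_mode <- match.arg(background_mode)
  stopifnot(inherits(catalog, "annotation_catalog"))
  ids <- names(background)
  if (is.null(ids) || anyDuplicated(ids))
    stop("background must be a named logical vector with unique names")
  background <- as.logical(background)
  names(background) <- ids
  universe <- if (background_mode == "annotated")
    intersect(ids, unique(unlist(catalog$sets, use.names = FALSE))) else ids
  if (length(universe) == 0L)
    stop("catalog members do not intersect the background")
  N <- length(universe)
  K <- sum(background[universe])
  if (K == 0L)
    warning("no entity is labeled significant; all p-values are 1")

  memb <- lapply(catalog$sets, function(m) m[m %in% universe])
  sizes <- lengths(memb)
  keep <- sizes >= min_set_size
  if (!any(keep)) {
    warning(sprintf("no FAS has >= %d measured members", min_set_size))
    res <- data.frame(fas_id = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p = numeric(0),
                      q_bh = numeric(0))
    class(res) <- c("hypgsea_result", "data.frame")
    return(res)
  }
  memb <- memb[keep]
  n_set <- sizes[keep]
  k_set <- vapply(memb, function(m) sum(background[m]), integer(1))
  p <- vapply(seq_along(memb), function(i)
    hypergeom_upper_tail(k_set[i], N, K, n_set[i]), numeric(1))
  res <- data.frame(fas_id = names(memb), N = N, K = as.integer(K),
                    n = as.integer(n_set), k = as.integer(k_set), p = p,
                    q_bh = bh_adjust(p))
  res <- res[order(res$q_bh, res$fas_id), ]
  rownames(res) <- NULL
  class(res) <- c("hypgsea_result", "data.frame")
  res
}
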