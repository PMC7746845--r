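# Hypergeometric over-representation analysis against a gene-set collection.

#' Exact hypergeometric upper tail P(X >= k)
#'
#' `X` counts genes of interest falling in a set when `n` genes are drawn
#' without replacement from a background of `N` genes of which `m` belong to
#' the set.
#'
#' @param N background size.
#' @param n query (genes-of-interest) size, `n <= N`.
#' @param m set size within the background, `m <= N`.
#' @param k overlap threshold, `0 <= k <= min(n, m)`.
#' @return upper-tail probability; `k = 0` gives 1.
#' @export
hypergeom_tail <- function(N, n, m, k) {
  stopifnot(length(N) == 1L, length(n) == 1L, length(m) == 1L, length(k) == 1L)
  if (m > N || n > N) stop("m and n must not exceed N")
  if (k < 0 || k > min(n, m)) stop("k must lie in [0, min(n, m)]")
  phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation test of a gene list
#'
#' For each set, `m` counts the set's genes present in the background and `k`
#' the query genes in that intersection; sets with `m = 0` are skipped. Query
#' genes absent from the background are dropped with a logged count. BH
#' adjustment across all tested sets.
#'
#' @param query character vector of genes of interest.
#' @param background character vector (>= 10 genes), e.g. all genes on the
#'   expression matrix.
#' @param sets gene-set collection ([read_gmt()]): named list of gene vectors.
#' @param fdr reporting threshold recorded in the `called` column (q < fdr).
#' @return data.frame set_id / N / n / m / k / p / q / called, ordered by p.
#' @export
enrich <- function(query, background, sets, fdr = 0.2) {
  stopifnot(fdr > 0, fdr <= 1)
  background <- unique(as.character(background))
  if (length(background) < 10L) stop("background must contain >= 10 genes")
  query <- unique(as.character(query))
  outside <- setdiff(query, background)
  if (length(outside)) {
    log_msg("enrich: dropped %d query gene(s) absent from background", length(outside))
    query <- intersect(query, background)
  }
  if (!length(query)) stop("query is empty after intersecting with background")
  if (!length(sets)) stop("gene-set collection is empty")
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets), function(id) {
    set_bg <- intersect(sets[[id]], background)
    m <- length(set_bg)
    if (m == 0L) return(NULL)
    k <- length(intersect(query, set_bg))
    data.frame(set_id = id, N = N, n = n, m = m, k = k,
               p = hypergeom_tail(N, n, m, k), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no gene set overlaps the background")
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$called <- out$q < fdr
  out[order(out$p), , drop = FALSE]
}
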